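#' Circuit specifications
#'
#' A circuit is a directed acyclic network of parameterized nodes assigned to
#' strains. Node roles: `sensor` (reads one named inducer from the
#' environment), `not_gate` / `nor_gate` (CRISPRi gates reading upstream
#' node outputs in MEFL), `ahl_sender` (LuxI expression driven by one
#' upstream node; parameterized by the AHL production rate `k_prod` in
#' nM/h per OD600 per MEFL), `ahl_receiver` (LuxR-activated promoter reading
#' the shared AHL pool, nM) and `reporter` (probes one node). Every node's
#' output is its reporter-equivalent MEFL, so fitted Hill parameters compose
#' directly.
#'
#' @param nodes A list of nodes, each a list with `id`, `role`, `params`
#'   (a [hill_params()] for sensors/gates/receivers; `list(k_prod = )` for
#'   senders; `NULL` for reporters), `inputs` (character: upstream node ids,
#'   an inducer name for sensors, or `"AHL"` for receivers) and `strain`.
#' @return A `circuit_spec` tibble with list-columns `params` and `inputs`.
#' @seealso [cs_circuit()] for the full channel-selector circuit.
#' @export
circuit_spec <- function(nodes) {
  spec <- tibble::tibble(
    id = vapply(nodes, function(n) n$id, character(1)),
    role = vapply(nodes, function(n) n$role, character(1)),
    params = lapply(nodes, function(n) n$params),
    inputs = lapply(nodes, function(n) as.character(n$inputs)),
    strain = vapply(nodes, function(n) {
      if (is.null(n$strain)) "main" else n$strain
    }, character(1))
  )
  roles <- c(
    "sensor", "not_gate", "nor_gate", "ahl_sender", "ahl_receiver", "reporter"
  )
  if (!all(spec$role %in% roles)) {
    stop("unknown node role", call. = FALSE)
  }
  if (anyDuplicated(spec$id)) stop("node ids must be unique", call. = FALSE)
  need <- c(
    sensor = 1L, not_gate = 1L, nor_gate = 2L, ahl_sender = 1L,
    ahl_receiver = 1L, reporter = 1L
  )
  arity <- lengths(spec$inputs)
  if (any(arity != need[spec$role])) {
    stop("wrong number of inputs for a node role", call. = FALSE)
  }
  for (i in seq_len(nrow(spec))) {
    role <- spec$role[i]
    p <- spec$params[[i]]
    if (role %in% c("not_gate", "nor_gate")) {
      if (!inherits(p, "hill_params") || p$mode != "repression") {
        stop("gates need repression-mode hill_params", call. = FALSE)
      }
    } else if (role %in% c("sensor", "ahl_receiver")) {
      if (!inherits(p, "hill_params") || p$mode != "activation") {
        stop("sensors/receivers need activation-mode hill_params",
          call. = FALSE
        )
      }
    } else if (role == "ahl_sender") {
      if (!is.list(p) || is.null(p$k_prod) || p$k_prod < 0) {
        stop("ahl_sender needs params = list(k_prod >= 0)", call. = FALSE)
      }
    }
    if (role == "ahl_receiver" && spec$inputs[[i]] != "AHL") {
      stop("ahl_receiver input must be the shared \"AHL\" species",
        call. = FALSE
      )
    }
  }
  # node-to-node references (sensors read inducers, receivers read AHL)
  ref_rows <- spec$role %in% c("not_gate", "nor_gate", "ahl_sender", "reporter")
  refs <- unlist(spec$inputs[ref_rows])
  if (length(refs) && !all(refs %in% spec$id)) {
    stop("gate/sender/reporter inputs must reference node ids", call. = FALSE)
  }
  out <- structure(spec, class = c("circuit_spec", class(spec)))
  circuit_topo_order(out) # errors on cycles
  out
}

# Topological order treating the AHL pool as an edge from every sender to
# every receiver.
circuit_topo_order <- function(spec) {
  idx <- stats::setNames(seq_len(nrow(spec)), spec$id)
  senders <- which(spec$role == "ahl_sender")
  preds <- lapply(seq_len(nrow(spec)), function(i) {
    if (spec$role[i] %in% c("sensor")) return(integer(0))
    if (spec$role[i] == "ahl_receiver") return(senders)
    unname(idx[spec$inputs[[i]]])
  })
  indeg <- lengths(preds)
  succs <- vector("list", nrow(spec))
  for (i in seq_len(nrow(spec))) for (p in preds[[i]]) {
    succs[[p]] <- c(succs[[p]], i)
  }
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue)) {
    v <- queue[1]
    queue <- queue[-1]
    ord <- c(ord, v)
    for (s in succs[[v]]) {
      indeg[s] <- indeg[s] - 1L
      if (indeg[s] == 0L) queue <- c(queue, s)
    }
  }
  if (length(ord) != nrow(spec)) {
    stop("circuit contains a cycle", call. = FALSE)
  }
  ord
}

#' Longest computation path through a circuit
#'
#' Counts layers along the longest input-to-output path. Sensors, NOT/NOR
#' gates and the AHL receiver each count as one layer; the AHL sender (LuxI
#' expression plus the diffusible pool) belongs to the same communication
#' layer as the receiving promoter and is not counted separately; reporters
#' are probes and add no layer.
#'
#' @param circuit A [circuit_spec()].
#' @return Integer number of layers.
#' @export
circuit_depth <- function(circuit) {
  ord <- circuit_topo_order(circuit)
  counted <- c("sensor", "not_gate", "nor_gate", "ahl_receiver")
  depth <- stats::setNames(rep(0L, nrow(circuit)), circuit$id)
  senders <- circuit$id[circuit$role == "ahl_sender"]
  for (i in ord) {
    role <- circuit$role[i]
    ups <- if (role == "sensor") {
      character(0)
    } else if (role == "ahl_receiver") senders else circuit$inputs[[i]]
    base <- if (length(ups)) max(depth[ups]) else 0L
    depth[[circuit$id[i]]] <- base + if (role %in% counted) 1L else 0L
  }
  max(depth)
}

#' Steady-state outputs of a circuit
#'
#' Evaluates the circuit in one topological pass: sensors read the inducer
#' environment, gates compose upstream MEFL through their Hill models, and
#' the AHL receiver reads the wire. AHL itself accumulates rather than
#' reaching a true steady state, so when the environment does not fix an
#' `AHL` concentration the quasi-steady wire level is taken as
#' `k_prod * od_sender * LuxI * ahl_exposure_h` — the amount accrued over one
#' dilution interval at the sender's working density.
#'
#' @param circuit A [circuit_spec()].
#' @param env Named list/vector of inducer concentrations (unknown names are
#'   an error; missing inducers an error). May include `AHL` to clamp the
#'   wire.
#' @param od_sender Sender-strain OD600 used for the quasi-steady wire level.
#' @param ahl_exposure_h Accumulation time (h) for the quasi-steady wire
#'   level; defaults to the 1.5-h dilution interval.
#' @return A tibble with `id`, `role`, `strain`, `output_mefl`, plus an
#'   `ahl_nM` attribute (also returned as a pseudo-row `AHL`).
#' @export
steady_state <- function(circuit, env, od_sender = 0.2, ahl_exposure_h = 1.5) {
  stopifnot(inherits(circuit, "circuit_spec"))
  env <- as.list(env)
  inducers <- unlist(circuit$inputs[circuit$role == "sensor"])
  unknown <- setdiff(names(env), c(unique(inducers), "AHL"))
  if (length(unknown)) {
    stop("unknown inducer name(s): ", paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  missing <- setdiff(unique(inducers), names(env))
  if (length(missing)) {
    stop("environment missing inducer(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  ord <- circuit_topo_order(circuit)
  val <- stats::setNames(rep(NA_real_, nrow(circuit)), circuit$id)
  ahl <- NA_real_
  for (i in ord) {
    role <- circuit$role[i]
    p <- circuit$params[[i]]
    ins <- circuit$inputs[[i]]
    val[[circuit$id[i]]] <- switch(role,
      sensor = sensor_response(env[[ins]], p),
      not_gate = not_response(val[[ins]], p),
      nor_gate = nor_response(val[[ins[1]]], val[[ins[2]]], p),
      ahl_sender = val[[ins]],
      ahl_receiver = {
        if (is.na(ahl)) {
          ahl <- if (!is.null(env$AHL)) {
            env$AHL
          } else {
            senders <- which(circuit$role == "ahl_sender")
            if (length(senders)) {
              sum(vapply(senders, function(s) {
                circuit$params[[s]]$k_prod * od_sender *
                  val[[circuit$id[s]]] * ahl_exposure_h
              }, numeric(1)))
            } else 0
          }
        }
        sensor_response(ahl, p)
      },
      reporter = val[[ins]]
    )
  }
  if (is.na(ahl)) ahl <- if (!is.null(env$AHL)) env$AHL else 0
  out <- tibble::tibble(
    id = circuit$id, role = circuit$role, strain = circuit$strain,
    output_mefl = unname(val[circuit$id])
  )
  attr(out, "ahl_nM") <- ahl
  out
}

#' Dilution/induction protocols for co-culture simulation
#'
#' @param phases A list of phases, each a list with `duration_h` (> 0), `env`
#'   (named list of inducer concentrations for the phase),
#'   `dilution_period_h` (`NA` for none) and `retained_fraction` (in (0, 1];
#'   the volume fraction of co-culture carried through each media
#'   replacement).
#' @param initial_od Named numeric: starting OD600 per strain (> 0).
#' @param growth_rate Named numeric: specific growth rate per strain, 1/h.
#' @param initial_ahl Starting AHL concentration, nM.
#' @return A `protocol` object.
#' @export
protocol <- function(phases, initial_od, growth_rate, initial_ahl = 0) {
  for (ph in phases) {
    if (!(ph$duration_h > 0)) stop("phase durations must be > 0", call. = FALSE)
    f <- ph$retained_fraction
    if (!is.null(ph$dilution_period_h) && !is.na(ph$dilution_period_h)) {
      if (is.null(f) || f <= 0 || f > 1) {
        stop("retained_fraction must be in (0, 1]", call. = FALSE)
      }
    }
  }
  if (any(initial_od <= 0)) stop("initial ODs must be > 0", call. = FALSE)
  stopifnot(!is.null(names(initial_od)), !is.null(names(growth_rate)))
  structure(
    list(
      phases = phases, initial_od = initial_od, growth_rate = growth_rate,
      initial_ahl = initial_ahl
    ),
    class = "protocol"
  )
}

#' Simulate co-culture gene-expression dynamics over the AHL wire
#'
#' Every node output `X` (reporter-equivalent MEFL) follows
#' `dX/dt = lambda * (f(upstream) - X)` where `f` is the node's Hill response
#' and `lambda` the strain growth rate: production is balanced against
#' dilution-by-growth, so the long-time limit under a constant environment is
#' the topological steady state. The model assumes excess dCas9 and stable,
#' quickly forming dCas9:sgRNA complexes — repression depends only on the
#' sgRNA-producing promoter's output. LuxI is stable (sender tracks its
#' driving promoter with the same first-order lag) and the AHL pool obeys
#' `dA/dt = sum(k_prod * OD_sender * LuxI)` with no degradation; media
#' replacement scales ODs — and, by default, AHL, since fresh medium
#' contains none — by the retained fraction.
#'
#' @param circuit A [circuit_spec()].
#' @param proto A [protocol()].
#' @param init `"steady"` (equilibrate to the first phase's environment with
#'   AHL at its initial value), `"zero"` (all node outputs 0), or a named
#'   numeric vector of initial node outputs.
#' @param dt_record Output grid spacing, h.
#' @param dilute_ahl Scale AHL by the retained fraction at dilution events?
#' @param rtol,atol Integrator tolerances (deSolve lsoda).
#' @return A `trajectory`: tidy tibble with columns `time` (h), `variable`
#'   (node ids, `OD600:<strain>`, `AHL`) and `value`; the circuit is kept as
#'   an attribute.
#' @export
simulate_dynamics <- function(circuit, proto, init = "steady",
                              dt_record = 0.1, dilute_ahl = TRUE,
                              rtol = 1e-6, atol = 1e-8) {
  stopifnot(inherits(circuit, "circuit_spec"), inherits(proto, "protocol"))
  strains <- unique(circuit$strain)
  if (!all(strains %in% names(proto$initial_od)) ||
    !all(strains %in% names(proto$growth_rate))) {
    stop("protocol must give initial_od and growth_rate for every strain",
      call. = FALSE
    )
  }
  dyn <- which(circuit$role != "reporter")
  dyn_ids <- circuit$id[dyn]
  lambda <- proto$growth_rate[circuit$strain[dyn]]
  senders <- which(circuit$role == "ahl_sender")

  node_target <- function(val, env, ahl) {
    vapply(dyn, function(i) {
      role <- circuit$role[i]
      p <- circuit$params[[i]]
      ins <- circuit$inputs[[i]]
      switch(role,
        sensor = sensor_response(env[[ins]], p),
        not_gate = not_response(max(val[[ins]], 0), p),
        nor_gate = nor_response(
          max(val[[ins[1]]], 0), max(val[[ins[2]]], 0), p
        ),
        ahl_sender = max(val[[ins]], 0),
        ahl_receiver = sensor_response(max(ahl, 0), p)
      )
    }, numeric(1))
  }

  deriv <- function(t, state, parms) {
    env <- parms$env
    x <- state[seq_along(dyn_ids)]
    names(x) <- dyn_ids
    ahl <- state[["AHL"]]
    od <- state[paste0("OD600:", strains)]
    names(od) <- strains
    tgt <- node_target(as.list(x), env, ahl)
    dx <- unname(lambda) * (tgt - x)
    dahl <- if (length(senders)) {
      sum(vapply(senders, function(s) {
        circuit$params[[s]]$k_prod * od[[circuit$strain[s]]] *
          max(x[[circuit$id[s]]], 0)
      }, numeric(1)))
    } else 0
    dod <- unname(proto$growth_rate[strains]) * unname(od)
    list(c(dx, dahl, dod))
  }

  # initial state
  env1 <- proto$phases[[1]]$env
  x0 <- if (identical(init, "steady")) {
    ss <- steady_state(circuit, c(env1, list(AHL = proto$initial_ahl)))
    stats::setNames(ss$output_mefl[match(dyn_ids, ss$id)], dyn_ids)
  } else if (identical(init, "zero")) {
    stats::setNames(rep(0, length(dyn_ids)), dyn_ids)
  } else {
    if (!all(dyn_ids %in% names(init))) {
      stop("named init must cover every non-reporter node", call. = FALSE)
    }
    init[dyn_ids]
  }
  state <- c(
    x0,
    stats::setNames(proto$initial_ahl, "AHL"),
    stats::setNames(
      unname(proto$initial_od[strains]), paste0("OD600:", strains)
    )
  )

  rows <- list()
  t_now <- 0
  for (ph in proto$phases) {
    t_end <- t_now + ph$duration_h
    ev_times <- numeric(0)
    if (!is.null(ph$dilution_period_h) && !is.na(ph$dilution_period_h)) {
      k <- seq_len(floor(ph$duration_h / ph$dilution_period_h + 1e-9))
      ev_times <- t_now + k * ph$dilution_period_h
      ev_times <- ev_times[ev_times < t_end - 1e-9]
    }
    seg_bounds <- c(t_now, ev_times, t_end)
    for (s in seq_len(length(seg_bounds) - 1L)) {
      a <- seg_bounds[s]
      b <- seg_bounds[s + 1L]
      times <- unique(sort(c(seq(a, b, by = dt_record), b)))
      sol <- deSolve::ode(
        y = state, times = times, func = deriv,
        parms = list(env = ph$env), method = "lsoda",
        rtol = rtol, atol = atol
      )
      if (attr(sol, "istate")[1] < 0) {
        stop("ODE integration failed; try smaller dt_record or looser rtol",
          call. = FALSE
        )
      }
      rows[[length(rows) + 1L]] <- as.data.frame(sol)
      state <- sol[nrow(sol), -1]
      if (s < length(seg_bounds) - 1L) { # dilution event at b
        f <- ph$retained_fraction
        odn <- paste0("OD600:", strains)
        state[odn] <- state[odn] * f
        if (dilute_ahl) state[["AHL"]] <- state[["AHL"]] * f
      }
    }
    t_now <- t_end
  }
  wide <- dplyr::bind_rows(rows)
  # at segment boundaries keep the later (post-dilution) state so times
  # stay strictly increasing
  wide <- wide[!duplicated(wide$time, fromLast = TRUE), ]
  long <- tidyr::pivot_longer(
    tibble::as_tibble(wide), -"time",
    names_to = "variable", values_to = "value"
  )
  # reporters mirror their probed node
  reps <- which(circuit$role == "reporter")
  if (length(reps)) {
    rep_rows <- lapply(reps, function(i) {
      src <- long[long$variable == circuit$inputs[[i]], ]
      src$variable <- circuit$id[i]
      src
    })
    long <- dplyr::bind_rows(long, rep_rows)
  }
  long <- dplyr::arrange(long, .data$variable, .data$time)
  structure(long,
    circuit = circuit, class = c("trajectory", class(long))
  )
}

#' First activation time of a node in a trajectory
#'
#' Returns the first time the node's output crosses
#' `y_min + threshold_fraction * (y_max - y_min)` from below, with linear
#' interpolation between saved steps, or `NA` if the trajectory never
#' crosses ("never").
#'
#' @param traj A `trajectory` from [simulate_dynamics()].
#' @param node_id Node to inspect (a reporter resolves to its probed node's
#'   parameters).
#' @param threshold_fraction Fraction of the node's dynamic range, in (0, 1).
#' @return Time in hours, or `NA_real_` if the threshold is never crossed.
#' @export
activation_time <- function(traj, node_id, threshold_fraction = 0.5) {
  stopifnot(threshold_fraction > 0, threshold_fraction < 1)
  circuit <- attr(traj, "circuit")
  if (!(node_id %in% circuit$id)) {
    stop("node '", node_id, "' not in the simulated circuit", call. = FALSE)
  }
  i <- match(node_id, circuit$id)
  while (circuit$role[i] %in% c("reporter", "ahl_sender")) {
    i <- match(circuit$inputs[[i]], circuit$id)
  }
  p <- circuit$params[[i]]
  thr <- p$y_min + threshold_fraction * (p$y_max - p$y_min)
  ser <- traj[traj$variable == node_id, ]
  tt <- ser$time
  vv <- ser$value
  above <- vv >= thr
  if (!any(above)) return(NA_real_)
  k <- which(above)[1]
  if (k == 1L) return(tt[1])
  # linear interpolation on the crossing segment
  t0 <- tt[k - 1L]; t1 <- tt[k]
  v0 <- vv[k - 1L]; v1 <- vv[k]
  t0 + (thr - v0) / (v1 - v0) * (t1 - t0)
}

#' Estimate the AHL production rate of LuxI from sender/biosensor series
#'
#' Receiver (biosensor) readouts taken on sampled supernatants are inverted
#' through the receiver's activation Hill model to AHL concentrations; these
#' are regressed through the origin against the cumulative (trapezoidal)
#' integral of `OD600 * LuxI` over time. The slope is the production rate
#' `k_prod` in nM/h per OD600 per MEFL. Readouts outside the receiver's
#' strictly monotone (invertible) range are flagged and excluded with a
#' warning.
#'
#' @param times Sample times, h.
#' @param od600 Sender OD600 at each sample.
#' @param luxi_mefl LuxI-proxy fluorescence (MEFL) at each sample.
#' @param receiver_readout Biosensor mean MEFL per sampled supernatant.
#' @param receiver_params Activation-mode [hill_params()] of the biosensor.
#' @return A list with `k_prod` and a `samples` tibble (`time`, `ahl_nM`,
#'   `exposure` = integral of OD * LuxI, `used`).
#' @export
estimate_ahl_rate <- function(times, od600, luxi_mefl, receiver_readout,
                              receiver_params) {
  stopifnot(
    inherits(receiver_params, "hill_params"),
    receiver_params$mode == "activation",
    length(times) == length(od600),
    length(times) == length(luxi_mefl),
    length(times) == length(receiver_readout)
  )
  p <- receiver_params
  invertible <- receiver_readout > p$y_min & receiver_readout < p$y_max
  ahl <- rep(NA_real_, length(times))
  ahl[invertible] <- p$K *
    ((receiver_readout[invertible] - p$y_min) /
      (p$y_max - receiver_readout[invertible]))^(1 / p$n)
  flux <- od600 * luxi_mefl
  exposure <- c(0, cumsum(diff(times) * (utils::head(flux, -1) +
    utils::tail(flux, -1)) / 2))
  used <- invertible & exposure > 0
  if (any(!invertible)) {
    warning(sum(!invertible),
      " sample(s) outside the receiver's invertible range were excluded"
    )
  }
  k <- if (sum(exposure[used]^2) == 0) {
    0
  } else {
    sum(ahl[used] * exposure[used]) / sum(exposure[used]^2)
  }
  list(
    k_prod = k,
    samples = tibble::tibble(
      time = times, ahl_nM = ahl, exposure = exposure, used = used
    )
  )
}

#' Plot a simulated trajectory
#'
#' @param object A `trajectory`.
#' @param variables Optional subset of variables to show.
#' @param ... Unused.
#' @return A ggplot (log10 value axis, one line per variable).
#' @export
autoplot.trajectory <- function(object, variables = NULL, ...) {
  d <- object
  if (!is.null(variables)) d <- d[d$variable %in% variables, ]
  ggplot2::ggplot(
    d, ggplot2::aes(.data$time, .data$value, color = .data$variable)
  ) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (h)", y = "value (MEFL / nM / OD600)")
}

# ---- circuit serialization ---------------------------------------------------

#' Read or write a circuit specification as JSON
#'
#' @param circuit A [circuit_spec()].
#' @param path File path.
#' @return `read_circuit_json()` returns a [circuit_spec()];
#'   `write_circuit_json()` invisibly returns `path`.
#' @export
write_circuit_json <- function(circuit, path) {
  nodes <- lapply(seq_len(nrow(circuit)), function(i) {
    p <- circuit$params[[i]]
    list(
      id = circuit$id[i], role = circuit$role[i],
      params = if (inherits(p, "hill_params")) unclass(p) else p,
      inputs = circuit$inputs[[i]], strain = circuit$strain[i]
    )
  })
  jsonlite::write_json(nodes, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_circuit_json
#' @export
read_circuit_json <- function(path) {
  nodes <- jsonlite::read_json(path, simplifyVector = FALSE)
  circuit_spec(lapply(nodes, function(n) {
    p <- n$params
    if (!is.null(p$mode)) {
      p <- hill_params(
        p$y_min, p$y_max, p$K, p$n, p$mode,
        input_units = if (is.null(p$input_units)) "MEFL" else p$input_units
      )
    }
    list(
      id = n$id, role = n$role, params = p,
      inputs = unlist(n$inputs), strain = n$strain
    )
  }))
}

# ---- the full channel-selector circuit --------------------------------------

#' The composed two-conversation channel-selector circuit
#'
#' Builds the full sensor-fronted channel selector: a MUX strain in which
#' aTc, IPTG and DAPG sensors drive `IN1 = NOT(aTc)`, `IN2 = NOT(IPTG)` and
#' `SELECT = NOT(DAPG)` into the 4-gate MUX whose output expresses LuxI
#' (the AHL sender), and a DEMUX strain in which an AHL receiver provides
#' the DEMUX input and a second DAPG sensor provides SELECT, again through a
#' NOT gate. Twelve CRISPRi gates in total. Default parameters are
#' synthetic but digitally consistent (every gate's low output falls well
#' below the next gate's repression threshold and the high output well
#' above); they are not fitted values.
#'
#' @param gate Default repression [hill_params()] used for every CRISPRi
#'   gate.
#' @param k_prod AHL production rate, nM/h/OD600/MEFL.
#' @param receiver Activation [hill_params()] of the AHL receiver (vs nM
#'   AHL).
#' @return A [circuit_spec()] with an `outputs` attribute naming `OUT_MUX`,
#'   `OUT1` and `OUT2`.
#' @examples
#' cs <- cs_circuit()
#' circuit_depth(cs)
#' @export
cs_circuit <- function(gate = hill_params(50, 20000, K = 2000, n = 2),
                       k_prod = 0.089,
                       receiver = hill_params(
                         50, 20000, K = 30, n = 2,
                         mode = "activation", input_units = "nM"
                       )) {
  sens <- function(K, units) {
    hill_params(50, 20000, K = K, n = 2, mode = "activation",
      input_units = units
    )
  }
  node <- function(id, role, params, inputs, strain) {
    list(id = id, role = role, params = params, inputs = inputs,
      strain = strain
    )
  }
  cs <- circuit_spec(list(
    # --- MUX strain -----------------------------------------------------
    node("sens_aTc", "sensor", sens(2, "ng/ml"), "aTc", "mux"),
    node("sens_IPTG", "sensor", sens(0.05, "mM"), "IPTG", "mux"),
    node("sens_DAPG_mux", "sensor", sens(20, "uM"), "DAPG", "mux"),
    node("NOT1", "not_gate", gate, "sens_aTc", "mux"), # IN1
    node("NOT9m", "not_gate", gate, "sens_IPTG", "mux"), # IN2
    node("NOT4", "not_gate", gate, "sens_DAPG_mux", "mux"), # SELECT
    node("NOT2", "not_gate", gate, "NOT4", "mux"),
    node("NOR5", "nor_gate", gate, c("NOT1", "NOT4"), "mux"),
    node("NOR6", "nor_gate", gate, c("NOT9m", "NOT2"), "mux"),
    node("NOR3", "nor_gate", gate, c("NOR5", "NOR6"), "mux"), # OUT_MUX
    node("luxI", "ahl_sender", list(k_prod = k_prod), "NOR3", "mux"),
    # --- DEMUX strain ---------------------------------------------------
    node("sens_DAPG_demux", "sensor", sens(20, "uM"), "DAPG", "demux"),
    node("P_lux", "ahl_receiver", receiver, "AHL", "demux"), # IN_DEMUX
    node("NOT3", "not_gate", gate, "sens_DAPG_demux", "demux"), # SELECT_D
    node("NOT8", "not_gate", gate, "P_lux", "demux"),
    node("NOT9d", "not_gate", gate, "NOT3", "demux"),
    node("NOR7", "nor_gate", gate, c("NOT8", "NOT3"), "demux"), # OUT1
    node("NOR2", "nor_gate", gate, c("NOT8", "NOT9d"), "demux") # OUT2
  ))
  attr(cs, "outputs") <- c(OUT_MUX = "NOR3", OUT1 = "NOR7", OUT2 = "NOR2")
  cs
}
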