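#' Truth tables for combinational logic
#'
#' A truth table enumerates the output bit-vector for every assignment of the
#' input bits. Rows are ordered by assignment index: row `r` (1-based)
#' corresponds to the assignment in which input `j` equals bit `j - 1` of
#' `r - 1`, so input 1 is the least-significant bit and row 1 is all-zeros.
#'
#' @param outputs A logical/0-1 matrix (or data frame) with `2^n_inputs` rows,
#'   one column per output, in assignment-index row order.
#' @param input_names,output_names Optional names for the input and output
#'   signals; defaults are `IN1..` and `OUT1..`.
#' @return A `truth_table` object: a list with `n_inputs`, `n_outputs`,
#'   `input_names`, `output_names` and the 0/1 `outputs` matrix.
#' @examples
#' # a 1-input inverter
#' truth_table(matrix(c(1, 0), ncol = 1))
#' @export
truth_table <- function(outputs, input_names = NULL, output_names = NULL) {
  outputs <- as.matrix(outputs)
  storage.mode(outputs) <- "integer"
  if (!all(outputs %in% c(0L, 1L))) {
    stop("truth table outputs must be 0/1", call. = FALSE)
  }
  n_rows <- nrow(outputs)
  n_inputs <- as.integer(round(log2(n_rows)))
  if (n_rows < 2L || 2L^n_inputs != n_rows) {
    stop("a truth table needs exactly 2^n_inputs rows", call. = FALSE)
  }
  n_outputs <- ncol(outputs)
  if (is.null(input_names)) input_names <- paste0("IN", seq_len(n_inputs))
  if (is.null(output_names)) output_names <- paste0("OUT", seq_len(n_outputs))
  stopifnot(length(input_names) == n_inputs, length(output_names) == n_outputs)
  colnames(outputs) <- output_names
  structure(
    list(
      n_inputs = n_inputs, n_outputs = n_outputs,
      input_names = input_names, output_names = output_names,
      outputs = outputs
    ),
    class = "truth_table"
  )
}

#' Build a truth table from a Boolean function
#'
#' @param n_inputs Number of inputs.
#' @param f A function taking a 0/1 input vector and returning the 0/1 output
#'   vector.
#' @inheritParams truth_table
#' @return A [truth_table()].
#' @export
truth_table_from_function <- function(n_inputs, f, input_names = NULL,
                                      output_names = NULL) {
  rows <- lapply(0:(2L^n_inputs - 1L), function(r) {
    bits <- as.integer(bitwAnd(bitwShiftR(r, 0:(n_inputs - 1L)), 1L))
    as.integer(f(bits))
  })
  truth_table(do.call(rbind, rows), input_names, output_names)
}

#' @rdname truth_table
#' @export
tt_not <- function() {
  truth_table_from_function(1L, function(b) 1L - b,
    input_names = "IN", output_names = "OUT"
  )
}

#' @rdname truth_table
#' @details `tt_mux()` is the 2-input multiplexer (inputs IN1, IN2, SELECT;
#'   output follows IN1 when SELECT = 0 and IN2 when SELECT = 1).
#'   `tt_demux()` is the 2-output demultiplexer (inputs IN, SELECT; OUT1 =
#'   IN AND NOT SELECT, OUT2 = IN AND SELECT).
#' @export
tt_mux <- function() {
  truth_table_from_function(
    3L,
    function(b) if (b[3] == 0L) b[1] else b[2],
    input_names = c("IN1", "IN2", "SELECT"), output_names = "OUT_MUX"
  )
}

#' @rdname truth_table
#' @export
tt_demux <- function() {
  truth_table_from_function(
    2L,
    function(b) c(b[1] * (1L - b[2]), b[1] * b[2]),
    input_names = c("IN", "SELECT"), output_names = c("OUT1", "OUT2")
  )
}

#' @export
print.truth_table <- function(x, ...) {
  cat(
    "<truth_table> ", x$n_inputs, " input(s), ", x$n_outputs,
    " output(s)\n",
    sep = ""
  )
  grid <- expand.grid(lapply(seq_len(x$n_inputs), function(i) 0:1))
  names(grid) <- x$input_names
  print(cbind(grid, as.data.frame(x$outputs)), row.names = FALSE)
  invisible(x)
}

#' NOT/NOR gate networks
#'
#' A gate network is a directed acyclic netlist over three node kinds:
#' `INPUT` (no inputs), `NOT` (one input) and `NOR` (two inputs). This is the
#' gate basis realizable with CRISPRi transcriptional repressors: a promoter
#' repressed by one sgRNA input is a NOT gate, and by either of two sgRNA
#' inputs a NOR gate.
#'
#' @param nodes A data frame with columns `id` (unique character), `kind`
#'   (`"INPUT"`, `"NOT"` or `"NOR"`), `in1` and `in2` (ids of upstream nodes;
#'   `NA` where unused).
#' @param outputs Character vector of node ids designated as network outputs.
#' @return A `gate_network`: a tibble of nodes with an `outputs` attribute.
#' @examples
#' inv <- gate_network(
#'   data.frame(
#'     id = c("A", "g1"), kind = c("INPUT", "NOT"),
#'     in1 = c(NA, "A"), in2 = NA
#'   ),
#'   outputs = "g1"
#' )
#' evaluate_network(inv, 1)
#' @export
gate_network <- function(nodes, outputs) {
  nodes <- tibble::as_tibble(nodes)
  stopifnot(all(c("id", "kind", "in1", "in2") %in% names(nodes)))
  nodes <- nodes[, c("id", "kind", "in1", "in2")]
  nodes$id <- as.character(nodes$id)
  nodes$kind <- as.character(nodes$kind)
  nodes$in1 <- as.character(nodes$in1)
  nodes$in2 <- as.character(nodes$in2)
  if (anyDuplicated(nodes$id)) stop("node ids must be unique", call. = FALSE)
  if (!all(nodes$kind %in% c("INPUT", "NOT", "NOR"))) {
    stop("node kind must be INPUT, NOT or NOR", call. = FALSE)
  }
  bad_arity <-
    (nodes$kind == "INPUT" & !(is.na(nodes$in1) & is.na(nodes$in2))) |
      (nodes$kind == "NOT" & !(!is.na(nodes$in1) & is.na(nodes$in2))) |
      (nodes$kind == "NOR" & !(!is.na(nodes$in1) & !is.na(nodes$in2)))
  if (any(bad_arity)) {
    stop("NOT nodes take exactly 1 input, NOR exactly 2, INPUT none",
      call. = FALSE
    )
  }
  refs <- stats::na.omit(c(nodes$in1, nodes$in2))
  if (!all(refs %in% nodes$id)) {
    stop("node inputs reference unknown ids", call. = FALSE)
  }
  outputs <- as.character(outputs)
  if (!all(outputs %in% nodes$id)) {
    stop("outputs reference unknown ids", call. = FALSE)
  }
  net <- structure(nodes, outputs = outputs,
    class = c("gate_network", class(nodes))
  )
  topo_order(net) # errors on cycles
  net
}

network_outputs <- function(network) attr(network, "outputs")

network_inputs <- function(network) network$id[network$kind == "INPUT"]

# Kahn topological sort; errors if the netlist has a cycle.
topo_order <- function(network) {
  ids <- network$id
  idx <- stats::setNames(seq_along(ids), ids)
  preds <- lapply(seq_along(ids), function(i) {
    p <- c(network$in1[i], network$in2[i])
    idx[p[!is.na(p)]]
  })
  indeg <- lengths(preds)
  succs <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    for (p in preds[[i]]) succs[[p]] <- c(succs[[p]], i)
  }
  queue <- which(indeg == 0L)
  order <- integer(0)
  while (length(queue)) {
    v <- queue[1]
    queue <- queue[-1]
    order <- c(order, v)
    for (s in succs[[v]]) {
      indeg[s] <- indeg[s] - 1L
      if (indeg[s] == 0L) queue <- c(queue, s)
    }
  }
  if (length(order) != length(ids)) {
    stop("gate network contains a cycle", call. = FALSE)
  }
  order
}

#' Evaluate a gate network on one input assignment
#'
#' Performs deterministic Boolean evaluation in topological order, with
#' `NOT(x) = !x` and `NOR(a, b) = !(a | b)`.
#'
#' @param network A [gate_network()].
#' @param assignment 0/1 (or logical) vector, one value per `INPUT` node in
#'   declaration order (names are ignored).
#' @return Named integer vector of 0/1 output values, one per network output.
#' @export
evaluate_network <- function(network, assignment) {
  ins <- network_inputs(network)
  assignment <- as.integer(assignment)
  if (length(assignment) != length(ins)) {
    stop("assignment length must equal the number of INPUT nodes",
      call. = FALSE
    )
  }
  if (!all(assignment %in% c(0L, 1L))) {
    stop("assignment values must be 0/1", call. = FALSE)
  }
  ord <- topo_order(network)
  val <- stats::setNames(rep(NA_integer_, nrow(network)), network$id)
  val[ins] <- assignment
  for (i in ord) {
    kind <- network$kind[i]
    if (kind == "INPUT") next
    a <- val[[network$in1[i]]]
    if (kind == "NOT") {
      val[[network$id[i]]] <- 1L - a
    } else {
      b <- val[[network$in2[i]]]
      val[[network$id[i]]] <- as.integer(!(a | b))
    }
  }
  val[network_outputs(network)]
}

#' Truth table realized by a gate network
#'
#' @inheritParams evaluate_network
#' @return A [truth_table()] obtained by exhaustive evaluation.
#' @export
network_truth_table <- function(network) {
  n_in <- length(network_inputs(network))
  truth_table_from_function(
    n_in,
    function(bits) evaluate_network(network, bits),
    input_names = network_inputs(network),
    output_names = network_outputs(network)
  )
}

#' Structural metrics of a gate network
#'
#' Depth is the longest INPUT-to-output path counted in gate nodes (an
#' INPUT passed straight through contributes 0); fan-out of a node is the
#' number of gate inputs it drives.
#'
#' @inheritParams evaluate_network
#' @return A one-row tibble with `n_gates`, `n_not`, `n_nor`, `depth`,
#'   `max_fan_in` and `max_fan_out`.
#' @export
network_metrics <- function(network) {
  ord <- topo_order(network)
  depth <- stats::setNames(rep(0L, nrow(network)), network$id)
  for (i in ord) {
    if (network$kind[i] == "INPUT") next
    up <- c(network$in1[i], network$in2[i])
    up <- up[!is.na(up)]
    depth[[network$id[i]]] <- 1L + max(depth[up])
  }
  outs <- network_outputs(network)
  refs <- c(network$in1, network$in2)
  refs <- refs[!is.na(refs)]
  fan_out <- if (length(refs)) max(table(refs)) else 0L
  gates <- network$kind != "INPUT"
  tibble::tibble(
    n_gates = sum(gates),
    n_not = sum(network$kind == "NOT"),
    n_nor = sum(network$kind == "NOR"),
    depth = if (length(outs)) max(depth[outs]) else 0L,
    max_fan_in = if (any(network$kind == "NOR")) 2L
    else if (any(network$kind == "NOT")) 1L else 0L,
    max_fan_out = as.integer(fan_out)
  )
}

# ---- exhaustive minimal synthesis ------------------------------------------

# Bitmask of a signal over all 2^n_in assignments: bit r is the signal value
# under assignment r (input j = bit j-1 of r).
input_masks <- function(n_in) {
  n_rows <- 2L^n_in
  vapply(seq_len(n_in), function(j) {
    m <- 0L
    for (r in 0:(n_rows - 1L)) {
      if (bitwAnd(r, bitwShiftL(1L, j - 1L)) != 0L) {
        m <- bitwOr(m, bitwShiftL(1L, r))
      }
    }
    m
  }, integer(1))
}

target_masks <- function(tt) {
  n_rows <- 2L^tt$n_inputs
  vapply(seq_len(tt$n_outputs), function(k) {
    m <- 0L
    for (r in seq_len(n_rows)) {
      if (tt$outputs[r, k] == 1L) m <- bitwOr(m, bitwShiftL(1L, r - 1L))
    }
    m
  }, integer(1))
}

#' Synthesize the minimal NOT/NOR network for a truth table
#'
#' Exhaustive iterative-deepening search over the total gate count: netlists
#' with `g = 0, 1, 2, ...` gates are enumerated (NOR gates take two distinct
#' inputs; constant signals are not available, matching the biological
#' setting where an absent promoter reads as 0) until one matches the truth
#' table on all rows, so the returned network provably has the minimum gate
#' count under the declared conventions. Among equal-count solutions, ties
#' are broken by fewer layers, then fewer NOR gates, then the canonical
#' (lexicographically smallest) serialized netlist, making the result
#' deterministic.
#'
#' By default each output is realized by a dedicated terminal gate whose
#' signal is not reused inside the network (`outputs_terminal = TRUE`): an
#' output promoter drives its payload (LuxI, a reporter) rather than further
#' sgRNAs. This is the convention under which the classic 2-output
#' demultiplexer is 4 gates (2 NOT + 2 NOR in 2 layers); if outputs may
#' drive other gates (`outputs_terminal = FALSE`) a 3-gate realization
#' exists in which the second output is computed from the first. Outputs
#' identical to an input are passed through without a gate.
#'
#' @param tt A [truth_table()].
#' @param gate_budget Maximum total gate count to search (default 6).
#' @param outputs_terminal Require outputs to be dedicated terminal gates?
#' @return A `synthesis_result` list: `found` (logical), `network` (a
#'   [gate_network()] or `NULL`), `metrics` (via [network_metrics()]),
#'   `gate_budget`. When no network within budget exists, `found` is `FALSE`.
#' @examples
#' res <- synthesize_minimal(tt_demux())
#' res$metrics
#' @export
synthesize_minimal <- function(tt, gate_budget = 6L, outputs_terminal = TRUE) {
  stopifnot(inherits(tt, "truth_table"), gate_budget >= 1L)
  n_in <- tt$n_inputs
  n_rows <- 2L^n_in
  full <- bitwShiftL(1L, n_rows) - 1L
  in_masks <- input_masks(n_in)
  tgt <- target_masks(tt)
  utgt <- unique(tgt[!(tgt %in% in_masks)]) # non-passthrough targets
  n_t <- length(utgt)

  not_mask <- function(m) bitwAnd(bitwNot(m), full)
  nor_mask <- function(a, b) bitwAnd(bitwNot(bitwOr(a, b)), full)

  # all one-step realizations of mask tau over the current node masks
  realizations <- function(masks, tau) {
    m <- length(masks)
    out <- list()
    for (a in seq_len(m)) {
      if (not_mask(masks[a]) == tau) {
        out[[length(out) + 1L]] <- c(1L, a, NA_integer_)
      }
    }
    if (m >= 2L) {
      for (a in seq_len(m - 1L)) {
        for (b in (a + 1L):m) {
          if (nor_mask(masks[a], masks[b]) == tau) {
            out[[length(out) + 1L]] <- c(2L, a, b)
          }
        }
      }
    }
    out
  }

  found <- list()

  emit_terminal <- function(masks, gates) {
    if (n_t == 0L) {
      # pure passthrough: valid only with no (necessarily dead) gates
      if (length(gates) == 0L) {
        found[[length(found) + 1L]] <<- list(inter = list(), term = list())
      }
      return(invisible(NULL))
    }
    # every intermediate must be consumed by a later intermediate or terminal
    n_nodes <- length(masks)
    consumed <- rep(FALSE, n_nodes)
    for (gg in gates) {
      consumed[gg[2]] <- TRUE
      if (!is.na(gg[3])) consumed[gg[3]] <- TRUE
    }
    opts <- lapply(utgt, function(tau) realizations(masks, tau))
    if (any(lengths(opts) == 0L)) {
      return(invisible(NULL))
    }
    # cartesian product of terminal realizations (small)
    combos <- expand.grid(lapply(opts, seq_along))
    for (ci in seq_len(nrow(combos))) {
      terms <- lapply(seq_len(n_t), function(k) opts[[k]][[combos[ci, k]]])
      used <- consumed
      for (tg in terms) {
        used[tg[2]] <- TRUE
        if (!is.na(tg[3])) used[tg[3]] <- TRUE
      }
      if (all(used[(n_in + 1L):n_nodes]) || n_nodes == n_in) {
        found[[length(found) + 1L]] <<- list(inter = gates, term = terms)
      }
    }
    invisible(NULL)
  }

  dfs_unconstrained <- function(masks, gates, g) {
    remaining <- g - length(gates)
    missing <- utgt[!(utgt %in% masks)]
    if (length(missing) == 0L) {
      if (remaining == 0L) {
        found[[length(found) + 1L]] <<- list(inter = gates, term = list())
      }
      return(invisible(NULL))
    }
    if (remaining == 0L || length(missing) > remaining) {
      return(invisible(NULL))
    }
    expand_gates(masks, gates, function(nm, cand) {
      if (remaining == 1L && !(nm %in% missing)) {
        return(invisible(NULL))
      }
      dfs_unconstrained(c(masks, nm), c(gates, list(cand)), g)
    })
  }

  dfs_intermediates <- function(masks, gates, n_i) {
    if (length(gates) == n_i) {
      return(emit_terminal(masks, gates))
    }
    expand_gates(masks, gates, function(nm, cand) {
      dfs_intermediates(c(masks, nm), c(gates, list(cand)), n_i)
    })
  }

  expand_gates <- function(masks, gates, k) {
    m <- length(masks)
    prev <- if (length(gates)) gates[[length(gates)]] else NULL
    prev_idx <- n_in + length(gates)
    admissible <- function(cand) {
      # symmetry break: two consecutive independent gates must be ordered
      if (is.null(prev)) {
        return(TRUE)
      }
      consumes_prev <- cand[2] == prev_idx ||
        (!is.na(cand[3]) && cand[3] == prev_idx)
      if (consumes_prev) {
        return(TRUE)
      }
      pk <- c(prev[1], prev[2], if (is.na(prev[3])) 0L else prev[3])
      ck <- c(cand[1], cand[2], if (is.na(cand[3])) 0L else cand[3])
      d <- ck - pk
      nz <- which(d != 0L)
      length(nz) == 0L || d[nz[1]] > 0L
    }
    for (a in seq_len(m)) {
      nm <- not_mask(masks[a])
      cand <- c(1L, a, NA_integer_)
      if (!(nm %in% masks) && admissible(cand)) k(nm, cand)
    }
    if (m >= 2L) {
      for (a in seq_len(m - 1L)) {
        for (b in (a + 1L):m) {
          nm <- nor_mask(masks[a], masks[b])
          cand <- c(2L, a, b)
          if (!(nm %in% masks) && admissible(cand)) k(nm, cand)
        }
      }
    }
    invisible(NULL)
  }

  for (g in 0:gate_budget) {
    found <- list()
    if (outputs_terminal) {
      n_i <- g - n_t
      if (n_i < 0L) next
      dfs_intermediates(in_masks, list(), n_i)
    } else {
      if (g == 0L) {
        if (n_t == 0L) found <- list(list(inter = list(), term = list()))
      } else {
        dfs_unconstrained(in_masks, list(), g)
      }
    }
    if (length(found)) {
      nets <- lapply(found, function(sol) {
        gates_to_network(
          sol, tt, in_masks, not_mask, nor_mask, tgt,
          terminal = outputs_terminal
        )
      })
      mets <- lapply(nets, network_metrics)
      keys <- vapply(nets, serialize_netlist, character(1))
      ord <- order(
        vapply(mets, function(m) m$depth, integer(1)),
        vapply(mets, function(m) m$n_nor, integer(1)),
        keys
      )
      best <- ord[1]
      return(structure(
        list(
          found = TRUE, network = nets[[best]], metrics = mets[[best]],
          gate_budget = gate_budget
        ),
        class = "synthesis_result"
      ))
    }
  }
  structure(
    list(
      found = FALSE, network = NULL, metrics = NULL,
      gate_budget = gate_budget
    ),
    class = "synthesis_result"
  )
}

#' @export
print.synthesis_result <- function(x, ...) {
  if (!x$found) {
    cat("<synthesis_result> not synthesizable within budget",
      x$gate_budget, "gates\n"
    )
    return(invisible(x))
  }
  cat("<synthesis_result> minimal network:",
    x$metrics$n_not, "NOT +", x$metrics$n_nor, "NOR in",
    x$metrics$depth, "layer(s)\n"
  )
  print(x$network)
  invisible(x)
}

gates_to_network <- function(sol, tt, in_masks, not_mask, nor_mask, tgt,
                             terminal = TRUE) {
  n_in <- length(in_masks)
  gates <- c(sol$inter, sol$term)
  ids <- c(tt$input_names, if (length(gates)) paste0("g", seq_along(gates)))
  masks <- in_masks
  rows <- lapply(seq_along(gates), function(k) {
    g <- gates[[k]]
    nm <- if (g[1] == 1L) {
      not_mask(masks[g[2]])
    } else {
      nor_mask(masks[g[2]], masks[g[3]])
    }
    masks[n_in + k] <<- nm
    tibble::tibble(
      id = ids[n_in + k],
      kind = if (g[1] == 1L) "NOT" else "NOR",
      in1 = ids[g[2]],
      in2 = if (g[1] == 1L) NA_character_ else ids[g[3]]
    )
  })
  nodes <- dplyr::bind_rows(
    tibble::tibble(
      id = tt$input_names, kind = "INPUT",
      in1 = NA_character_, in2 = NA_character_
    ),
    rows
  )
  outs <- if (terminal && length(sol$term)) {
    # terminal gates occupy the last positions, one per distinct
    # non-passthrough target mask, in utgt order
    utgt <- unique(tgt[!(tgt %in% in_masks)])
    term_ids <- ids[n_in + length(sol$inter) + seq_along(sol$term)]
    vapply(tgt, function(t) {
      if (t %in% in_masks) {
        ids[match(t, in_masks)]
      } else {
        term_ids[match(t, utgt)]
      }
    }, character(1))
  } else {
    vapply(tgt, function(t) ids[match(t, masks)], character(1))
  }
  net <- gate_network(nodes, outputs = outs)
  attr(net, "outputs") <- stats::setNames(outs, tt$output_names)
  net
}

serialize_netlist <- function(network) {
  gates <- network[network$kind != "INPUT", ]
  paste(
    sprintf(
      "%s(%s,%s)", gates$kind, gates$in1,
      ifelse(is.na(gates$in2), "", gates$in2)
    ),
    collapse = ";"
  )
}

# ---- channel-selector construction -----------------------------------------

# Mutable netlist builder used by build_cs_network().
netlist_builder <- function(input_ids) {
  env <- new.env(parent = emptyenv())
  env$nodes <- tibble::tibble(
    id = input_ids, kind = "INPUT", in1 = NA_character_, in2 = NA_character_
  )
  env$counter <- 0L
  env$add <- function(kind, in1, in2 = NA_character_) {
    # force args first: they may be nested add() calls mutating env$nodes
    force(kind)
    force(in1)
    force(in2)
    env$counter <- env$counter + 1L
    id <- paste0("g", env$counter)
    env$nodes <- dplyr::bind_rows(
      env$nodes,
      tibble::tibble(id = id, kind = kind, in1 = in1, in2 = in2)
    )
    id
  }
  env
}

# Shared per-strain inverter cache: one NOT gate per distinct signal.
make_inverter <- function(bld) {
  cache <- new.env(parent = emptyenv())
  function(sig) {
    if (!is.null(cache[[sig]])) return(cache[[sig]])
    cache[[sig]] <- bld$add("NOT", sig)
    cache[[sig]]
  }
}

# OR-tree over >= 1 signals: OR(a, b) = NOT(NOR(a, b)).
or_tree <- function(bld, inv, sigs) {
  if (length(sigs) == 1L) return(sigs)
  half <- length(sigs) %/% 2L
  a <- or_tree(bld, inv, sigs[seq_len(half)])
  b <- or_tree(bld, inv, sigs[-seq_len(half)])
  bld$add("NOT", bld$add("NOR", a, b))
}

# NOR-tree: complement of the OR of >= 2 signals.
big_nor <- function(bld, inv, sigs) {
  if (length(sigs) == 2L) return(bld$add("NOR", sigs[1], sigs[2]))
  half <- length(sigs) %/% 2L
  bld$add(
    "NOR",
    or_tree(bld, inv, sigs[seq_len(half)]),
    or_tree(bld, inv, sigs[-seq_len(half)])
  )
}

# Complemented-minterm signal for channel i (0-based) over select lines:
# the OR of complement literals; for one select line it is a bare literal.
anti_minterm <- function(bld, inv, selects, i) {
  lits <- vapply(seq_along(selects), function(j) {
    if (bitwAnd(bitwShiftR(i, j - 1L), 1L) == 1L) inv(selects[j])
    else selects[j]
  }, character(1))
  or_tree(bld, inv, lits)
}

# 2-input MUX cell: OUT = NOR(NOR(a, s), NOR(b, NOT(s))); routes a when s=0.
mux2_cell <- function(bld, inv, a, b, s) {
  bld$add("NOR", bld$add("NOR", a, s), bld$add("NOR", b, inv(s)))
}

build_mux <- function(bld, xs, selects, style) {
  inv <- make_inverter(bld)
  if (style == "recursive") {
    rec <- function(xs, sels) {
      if (length(xs) == 1L) return(xs)
      half <- length(xs) %/% 2L
      s <- sels[length(sels)]
      a <- rec(xs[seq_len(half)], sels[-length(sels)])
      b <- rec(xs[-seq_len(half)], sels[-length(sels)])
      mux2_cell(bld, inv, a, b, s)
    }
    rec(xs, selects)
  } else {
    terms <- vapply(seq_along(xs), function(i) {
      bld$add("NOR", xs[i], anti_minterm(bld, inv, selects, i - 1L))
    }, character(1))
    big_nor(bld, inv, terms)
  }
}

build_demux <- function(bld, wire, selects, style) {
  inv <- make_inverter(bld)
  if (style == "recursive") {
    rec <- function(w, sels) {
      if (length(sels) == 0L) return(w)
      s <- sels[length(sels)]
      nw <- bld$add("NOT", w)
      w0 <- bld$add("NOR", nw, s)
      w1 <- bld$add("NOR", nw, inv(s))
      c(rec(w0, sels[-length(sels)]), rec(w1, sels[-length(sels)]))
    }
    rec(wire, selects)
  } else {
    nw <- bld$add("NOT", wire)
    vapply(seq_len(2L^length(selects)), function(i) {
      bld$add("NOR", nw, anti_minterm(bld, inv, selects, i - 1L))
    }, character(1))
  }
}

#' Construct an n-channel channel-selector gate network
#'
#' Builds the MUX and DEMUX halves of a channel selector from NOT/NOR gates
#' and joins them by an abstract wire (the MUX output feeds the DEMUX input
#' directly; the two halves live in separate strains so no gates are shared
#' between them). Two composition styles are supported: `"recursive"`
#' (a tree of 2-input MUX / 2-output DEMUX cells) and `"two_layer"`
#' (single-level select decoding: each channel is gated by its select
#' minterm and the results are merged by a NOR tree). For `n_channels = 2`
#' both styles reduce to the same minimal 8-gate design (MUX: 1 NOT + 3 NOR
#' in 3 layers; DEMUX: 2 NOT + 2 NOR in 2 layers). `n_channels = 1` returns
#' the degenerate pass-through network with 0 gates.
#'
#' @param n_channels Number of channels; a power of two.
#' @param style `"two_layer"` or `"recursive"`.
#' @return A list with `network` (a [gate_network()]) and `metrics`
#'   (via [network_metrics()]).
#' @examples
#' build_cs_network(2, "recursive")$metrics
#' @export
build_cs_network <- function(n_channels, style = c("two_layer", "recursive")) {
  style <- match.arg(style)
  if (n_channels < 1 || bitwAnd(n_channels, n_channels - 1L) != 0L) {
    stop("n_channels must be a power of two", call. = FALSE)
  }
  n_channels <- as.integer(n_channels)
  k <- as.integer(round(log2(n_channels)))
  xs <- paste0("X", seq_len(n_channels))
  selects <- if (k > 0L) paste0("S", seq_len(k)) else character(0)
  bld <- netlist_builder(c(xs, selects))
  if (n_channels == 1L) {
    net <- gate_network(bld$nodes, outputs = xs)
  } else {
    wire <- build_mux(bld, xs, selects, style)
    outs <- build_demux(bld, wire, selects, style)
    net <- gate_network(bld$nodes, outputs = outs)
  }
  list(network = net, metrics = network_metrics(net))
}
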