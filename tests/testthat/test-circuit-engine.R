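# A sensor-fronted MUX spec used across the steady-state tests.
mux_circuit <- function() {
  g <- test_gate()
  circuit_spec(list(
    list(id = "sIN1", role = "sensor", params = test_sensor(), inputs = "A",
      strain = "m"),
    list(id = "sIN2", role = "sensor", params = test_sensor(), inputs = "B",
      strain = "m"),
    list(id = "sSEL", role = "sensor", params = test_sensor(), inputs = "S",
      strain = "m"),
    list(id = "notS", role = "not_gate", params = g, inputs = "sSEL",
      strain = "m"),
    list(id = "norA", role = "nor_gate", params = g,
      inputs = c("sIN1", "sSEL"), strain = "m"),
    list(id = "norB", role = "nor_gate", params = g,
      inputs = c("sIN2", "notS"), strain = "m"),
    list(id = "out", role = "nor_gate", params = g,
      inputs = c("norA", "norB"), strain = "m")
  ))
}

test_that("steady state routes the MUX per its select line", {
  cir <- mux_circuit()
  hi <- 20
  # the sensed signals are active-high here, so the composed NOR-NOR MUX
  # relays (inverted) IN1 when the select sensor is low and IN2 when high
  out_of <- function(env) {
    ss <- steady_state(cir, env)
    ss$output_mefl[ss$id == "out"]
  }
  on_thr <- 10000
  expect_gt(out_of(list(A = hi, B = 0, S = 0)), on_thr) # tracks IN1
  expect_lt(out_of(list(A = 0, B = hi, S = 0)), on_thr)
  expect_gt(out_of(list(A = 0, B = hi, S = hi)), on_thr) # tracks IN2
  expect_lt(out_of(list(A = hi, B = 0, S = hi)), on_thr)
})

test_that("steady state matches closed-form composition and trivial cases", {
  g <- test_gate()
  cir <- circuit_spec(list(
    list(id = "sen", role = "sensor", params = test_sensor(), inputs = "I",
      strain = "a"),
    list(id = "n1", role = "not_gate", params = g, inputs = "sen",
      strain = "a"),
    list(id = "n2", role = "not_gate", params = g, inputs = "n1",
      strain = "a"),
    list(id = "rep", role = "reporter", params = NULL, inputs = "n2",
      strain = "a")
  ))
  set.seed(31)
  for (conc in stats::runif(50, 0, 40)) {
    ss <- steady_state(cir, list(I = conc))
    direct <- not_response(
      not_response(sensor_response(conc, test_sensor()), g), g
    )
    expect_equal(ss$output_mefl[ss$id == "n2"], direct)
    expect_equal(ss$output_mefl[ss$id == "rep"], direct)
  }
  # a constitutive node (sensor pinned near y_max) reports y_max at any env
  const <- hill_params(9999.999, 10000, K = 1, n = 1, mode = "activation")
  cc <- circuit_spec(list(
    list(id = "c", role = "sensor", params = const, inputs = "I", strain = "a")
  ))
  for (conc in c(0, 5, 500)) {
    expect_equal(
      steady_state(cc, list(I = conc))$output_mefl, 10000,
      tolerance = 1e-4
    )
  }
  expect_error(steady_state(cir, list(I = 1, bogus = 2)), "unknown inducer")
  expect_error(steady_state(cir, list()), "missing inducer")
})

test_that("circuit specs reject cycles and malformed nodes", {
  g <- test_gate()
  expect_error(
    circuit_spec(list(
      list(id = "a", role = "not_gate", params = g, inputs = "b",
        strain = "s"),
      list(id = "b", role = "not_gate", params = g, inputs = "a",
        strain = "s")
    )),
    "cycle"
  )
  expect_error(
    circuit_spec(list(
      list(id = "a", role = "nor_gate", params = g, inputs = "a",
        strain = "s")
    )),
    "wrong number"
  )
  expect_error(
    circuit_spec(list(
      list(id = "r", role = "ahl_receiver", params = test_sensor(),
        inputs = "x", strain = "s")
    )),
    "AHL"
  )
})

test_that("dynamics settle to the topological steady state", {
  # random 3-gate circuits under a constant environment: the long-time ODE
  # limit must match the single-pass steady state within 1%
  set.seed(11)
  for (trial in 1:5) {
    g1 <- hill_params(
      stats::runif(1, 20, 100), stats::runif(1, 1e4, 4e4),
      K = stats::runif(1, 500, 5000), n = stats::runif(1, 1, 3)
    )
    cir <- circuit_spec(list(
      list(id = "sen", role = "sensor", params = test_sensor(),
        inputs = "I", strain = "a"),
      list(id = "n1", role = "not_gate", params = g1, inputs = "sen",
        strain = "a"),
      list(id = "n2", role = "nor_gate", params = g1,
        inputs = c("n1", "sen"), strain = "a"),
      list(id = "n3", role = "not_gate", params = g1, inputs = "n2",
        strain = "a")
    ))
    conc <- stats::runif(1, 0, 30)
    lambda <- 0.6
    proto <- protocol(
      phases = list(list(
        duration_h = 12 / lambda, env = list(I = conc),
        dilution_period_h = NA, retained_fraction = 1
      )),
      initial_od = c(a = 0.05), growth_rate = c(a = lambda)
    )
    traj <- simulate_dynamics(cir, proto, init = "zero")
    ss <- steady_state(cir, list(I = conc))
    for (id in c("n1", "n2", "n3")) {
      final <- utils::tail(traj$value[traj$variable == id], 1)
      expect_equal(final, ss$output_mefl[ss$id == id], tolerance = 0.01)
    }
  }
})

test_that("dynamics reproduce first-order closed forms", {
  # rise toward P/lambda: X(t) = Xss (1 - e^(-lambda t)); half-time ln2/l
  g0 <- hill_params(1e-9, 10000, K = 1000, n = 2)
  lambda <- 0.8
  cir <- circuit_spec(list(
    list(id = "sen", role = "sensor",
      params = hill_params(1e-7, 1e-4, K = 1, n = 1, mode = "activation"),
      inputs = "I", strain = "a"),
    list(id = "n1", role = "not_gate", params = g0, inputs = "sen",
      strain = "a")
  ))
  proto <- protocol(
    phases = list(list(duration_h = 10, env = list(I = 0),
      dilution_period_h = NA, retained_fraction = 1)),
    initial_od = c(a = 0.1), growth_rate = c(a = lambda)
  )
  traj <- simulate_dynamics(cir, proto, init = "zero", dt_record = 0.01)
  expect_equal(activation_time(traj, "n1", 0.5), log(2) / lambda,
    tolerance = 1e-3
  )
  n1 <- traj[traj$variable == "n1", ]
  i5 <- which.min(abs(n1$time - 5))
  expect_equal(
    n1$value[i5], 10000 * (1 - exp(-lambda * n1$time[i5])),
    tolerance = 1e-3
  )
  # relaxation from a displaced initial value follows the same first-order
  # closed form (the e^(-lambda t) decay of the initial condition)
  traj2 <- simulate_dynamics(cir, proto,
    init = c(sen = 1e-7, n1 = 8000), dt_record = 0.01
  )
  n1b <- traj2[traj2$variable == "n1", ]
  i2 <- which.min(abs(n1b$time - 2))
  t2 <- n1b$time[i2]
  expect_equal(
    n1b$value[i2],
    8000 * exp(-lambda * t2) + 10000 * (1 - exp(-lambda * t2)),
    tolerance = 1e-3
  )
})

test_that("AHL accumulates linearly at the measured production rate", {
  # constant OD 0.2 and LuxI 1000 MEFL, k = 0.089 nM/h/OD600/MEFL,
  # no losses: A(t) = 0.089 * 0.2 * 1000 * t
  const <- hill_params(999.9999, 1000, K = 1, n = 1, mode = "activation")
  cir <- circuit_spec(list(
    list(id = "src", role = "sensor", params = const, inputs = "X",
      strain = "s"),
    list(id = "luxI", role = "ahl_sender", params = list(k_prod = 0.089),
      inputs = "src", strain = "s")
  ))
  proto <- protocol(
    phases = list(list(duration_h = 10, env = list(X = 1e6),
      dilution_period_h = NA, retained_fraction = 1)),
    initial_od = c(s = 0.2), growth_rate = c(s = 0)
  )
  traj <- simulate_dynamics(cir, proto, init = "steady", dt_record = 0.5)
  a <- traj[traj$variable == "AHL", ]
  expect_equal(a$value, 0.089 * 0.2 * 1000 * a$time, tolerance = 1e-6)
})

test_that("dilution events behave as media replacement", {
  cir <- mux_circuit()
  base <- list(
    duration_h = 6, env = list(A = 0, B = 0, S = 0),
    dilution_period_h = 1.5, retained_fraction = 1
  )
  proto_noop <- protocol(list(base),
    initial_od = c(m = 0.1), growth_rate = c(m = 0.5)
  )
  base$dilution_period_h <- NA
  proto_none <- protocol(list(base),
    initial_od = c(m = 0.1), growth_rate = c(m = 0.5)
  )
  t1 <- simulate_dynamics(cir, proto_noop, init = "zero", dt_record = 0.25)
  t2 <- simulate_dynamics(cir, proto_none, init = "zero", dt_record = 0.25)
  # retained fraction 1 is a no-op (up to integrator restart tolerance)
  expect_equal(t1$value, t2$value, tolerance = 1e-5)

  base$dilution_period_h <- 1.5
  base$retained_fraction <- 0.28
  proto_dil <- protocol(list(base),
    initial_od = c(m = 0.1), growth_rate = c(m = 0.5)
  )
  t3 <- simulate_dynamics(cir, proto_dil, init = "zero", dt_record = 0.25)
  od <- t3[t3$variable == "OD600:m", ]
  # the boundary sample holds the post-dilution state; the pre-dilution OD
  # is the previous grid point grown for 0.25 h
  v_125 <- od$value[which.min(abs(od$time - 1.25))]
  v_150 <- od$value[which.min(abs(od$time - 1.5))]
  expect_equal(v_150 / (v_125 * exp(0.5 * 0.25)), 0.28, tolerance = 1e-6)
  # everything stays non-negative
  expect_true(all(t3$value >= 0))
  expect_error(
    protocol(list(list(duration_h = 1, env = list(),
      dilution_period_h = 1, retained_fraction = 1.5)),
    initial_od = c(m = 1), growth_rate = c(m = 1)),
    "retained_fraction"
  )
})

test_that("activation_time interpolates, is unique, and can report never", {
  cir <- mux_circuit()
  proto <- protocol(
    list(list(duration_h = 8, env = list(A = 0, B = 0, S = 0),
      dilution_period_h = NA, retained_fraction = 1)),
    initial_od = c(m = 0.1), growth_rate = c(m = 0.5)
  )
  traj <- simulate_dynamics(cir, proto, init = "zero", dt_record = 0.1)
  # with the select sensor silent, its inverter rises toward y_max
  t_out <- activation_time(traj, "notS", 0.5)
  expect_true(is.finite(t_out))
  # monotone rise: crossing is unique; before it the value is below
  ser <- traj[traj$variable == "notS", ]
  expect_lt(max(ser$value[ser$time < t_out - 0.1]),
    min(ser$value[ser$time > t_out + 0.1]))
  # norB = NOR(IN2, notS) is held down by the rising inverter: never active
  expect_true(is.na(activation_time(traj, "norB", 0.9)))
  expect_error(activation_time(traj, "nope", 0.5), "not in the simulated")
})

test_that("the AHL production rate is recovered from biosensor series", {
  recv <- hill_params(50, 20000, K = 30, n = 1.6, mode = "activation",
    input_units = "nM")
  tt <- seq(0, 2.5, by = 0.5)
  od <- 0.0129 * exp(0.7 * tt)
  luxi <- rep(15000, length(tt))
  flux <- od * luxi
  expo <- c(0, cumsum(diff(tt) * (utils::head(flux, -1) +
    utils::tail(flux, -1)) / 2))
  k_true <- 0.1
  readout <- sensor_response(k_true * expo, recv)
  est <- suppressWarnings(
    estimate_ahl_rate(tt, od, luxi, readout, recv)
  )
  expect_equal(est$k_prod, k_true, tolerance = 0.02)
  # LuxI = 0: regression through the origin gives 0
  est0 <- suppressWarnings(estimate_ahl_rate(
    tt, od, rep(0, length(tt)), rep(recv$y_min + 1e-6, length(tt)), recv
  ))
  expect_equal(est0$k_prod, 0)
  # saturated readouts are flagged and excluded
  sat <- readout
  sat[length(sat)] <- recv$y_max
  expect_warning(
    est_s <- estimate_ahl_rate(tt, od, luxi, sat, recv),
    "excluded"
  )
  expect_false(est_s$samples$used[length(tt)])
  expect_equal(est_s$k_prod, k_true, tolerance = 0.02)
})

test_that("relabeling MUX inputs and inverting SELECT is symmetric", {
  # the spec with IN1/IN2 exchanged and the two select legs swapped is a
  # pure relabeling: its steady-state output map must coincide with the
  # original evaluated at the exchanged input environment, exactly
  g <- test_gate()
  swapped <- circuit_spec(list(
    list(id = "sIN1", role = "sensor", params = test_sensor(), inputs = "A",
      strain = "m"),
    list(id = "sIN2", role = "sensor", params = test_sensor(), inputs = "B",
      strain = "m"),
    list(id = "sSEL", role = "sensor", params = test_sensor(), inputs = "S",
      strain = "m"),
    list(id = "notS", role = "not_gate", params = g, inputs = "sSEL",
      strain = "m"),
    list(id = "norA", role = "nor_gate", params = g,
      inputs = c("sIN2", "sSEL"), strain = "m"),
    list(id = "norB", role = "nor_gate", params = g,
      inputs = c("sIN1", "notS"), strain = "m"),
    list(id = "out", role = "nor_gate", params = g,
      inputs = c("norA", "norB"), strain = "m")
  ))
  cir <- mux_circuit()
  for (env in list(
    list(A = 20, B = 0, S = 0), list(A = 0, B = 20, S = 7),
    list(A = 3, B = 11, S = 20)
  )) {
    env_sw <- list(A = env$B, B = env$A, S = env$S)
    o1 <- steady_state(cir, env)
    o2 <- steady_state(swapped, env_sw)
    expect_equal(
      o1$output_mefl[o1$id == "out"],
      o2$output_mefl[o2$id == "out"]
    )
  }
})

test_that("circuit JSON serialization round-trips", {
  cir <- cs_circuit()
  path <- withr::local_tempfile(fileext = ".json")
  write_circuit_json(cir, path)
  back <- read_circuit_json(path)
  expect_equal(back$id, cir$id)
  expect_equal(back$role, cir$role)
  expect_equal(back$inputs, cir$inputs)
  ss1 <- steady_state(cir, list(aTc = 0, IPTG = 0, DAPG = 100))
  ss2 <- steady_state(back, list(aTc = 0, IPTG = 0, DAPG = 100))
  expect_equal(ss1$output_mefl, ss2$output_mefl)
})

test_that("the composed channel selector has an 8-layer longest path", {
  expect_equal(circuit_depth(cs_circuit()), 8L)
})
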