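# Independent oracles used across the suite. These deliberately avoid the
# package's internal representations: masks are built from an explicit
# assignment grid, and searches are breadth-first over sets of realized
# functions rather than depth-first over netlists.

# Truth masks of the inputs from an explicit assignment grid (input 1 is the
# least-significant bit of the row index).
oracle_input_masks <- function(n_in) {
  grid <- expand.grid(rep(list(0:1), n_in))
  vapply(seq_len(n_in), function(j) {
    sum(2^(which(grid[[j]] == 1) - 1))
  }, numeric(1))
}

oracle_not <- function(m, n_rows) (2^n_rows - 1) - m

oracle_nor <- function(a, b, n_rows) {
  (2^n_rows - 1) - bitwOr(as.integer(a), as.integer(b))
}

# Can mask tau be made by a single NOT or NOR over the available masks?
oracle_one_step <- function(masks, tau, n_rows) {
  for (a in masks) {
    if (oracle_not(a, n_rows) == tau) {
      return(TRUE)
    }
  }
  if (length(masks) >= 2) {
    cmb <- utils::combn(masks, 2)
    for (k in seq_len(ncol(cmb))) {
      if (oracle_nor(cmb[1, k], cmb[2, k], n_rows) == tau) {
        return(TRUE)
      }
    }
  }
  FALSE
}

# Breadth-first minimal gate count for a truth table under the
# terminal-output convention: k intermediate gates (distinct new functions)
# plus one dedicated output gate per distinct non-input target. Returns NA
# when nothing within budget realizes the table.
oracle_min_gates <- function(tt, budget = 6) {
  n_in <- tt$n_inputs
  n_rows <- 2^n_in
  in_masks <- oracle_input_masks(n_in)
  tgt <- vapply(seq_len(tt$n_outputs), function(k) {
    sum(2^(which(tt$outputs[, k] == 1) - 1))
  }, numeric(1))
  utgt <- unique(tgt[!(tgt %in% in_masks)])
  n_t <- length(utgt)
  if (n_t == 0) {
    return(0L)
  }
  states <- list(sort(in_masks))
  seen <- new.env(parent = emptyenv())
  seen[[paste(sort(in_masks), collapse = ",")]] <- TRUE
  for (k in 0:(budget - n_t)) {
    for (st in states) {
      if (all(vapply(utgt, function(tau) {
        oracle_one_step(st, tau, n_rows)
      }, logical(1)))) {
        return(as.integer(k + n_t))
      }
    }
    if (k == budget - n_t) break
    nxt <- list()
    for (st in states) {
      cand <- unique(c(
        vapply(st, oracle_not, numeric(1), n_rows = n_rows),
        if (length(st) >= 2) {
          cmb <- utils::combn(st, 2)
          vapply(seq_len(ncol(cmb)), function(i) {
            oracle_nor(cmb[1, i], cmb[2, i], n_rows)
          }, numeric(1))
        }
      ))
      for (nm in setdiff(cand, st)) {
        ns <- sort(c(st, nm))
        key <- paste(ns, collapse = ",")
        if (is.null(seen[[key]])) {
          seen[[key]] <- TRUE
          nxt[[length(nxt) + 1]] <- ns
        }
      }
    }
    states <- nxt
    if (!length(states)) break
  }
  NA_integer_
}

# Naive O(genome x operator) sliding-window off-target oracle over an
# explicit character matrix; mirrors the three screening rules directly.
oracle_offtarget <- function(design, genome_chr, essential = NULL) {
  op <- strsplit(design$operator_pam, "")[[1]]
  n_op <- length(op)
  seed <- strsplit(
    substr(design$sgrna_operator, 8, 20), ""
  )[[1]] # 3'-most 13 operator nt
  strands <- list(
    `+` = genome_chr,
    `-` = as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(genome_chr))
    )
  )
  L <- nchar(genome_chr)
  ess <- essential
  overlap <- function(lo, hi) { # 0-based half-open
    !is.null(ess) && nrow(ess) > 0 &&
      any(lo < ess$end & ess$start < hi)
  }
  # longest 3'-suffix of op matching at each genome position, per strand
  hit10_ess <- FALSE
  hit12 <- FALSE
  hit_seed <- FALSE
  for (sn in names(strands)) {
    s <- strsplit(strands[[sn]], "")[[1]]
    for (pos in seq_len(L)) { # pos = 1-based END of the suffix match
      run <- 0
      while (run < n_op && pos - run >= 1 &&
        s[pos - run] == op[n_op - run]) {
        run <- run + 1
      }
      if (run >= 12) hit12 <- TRUE
      if (run >= 10) {
        lo_local <- pos - run # 0-based
        hi_local <- pos
        if (sn == "+") {
          if (overlap(lo_local, hi_local)) hit10_ess <- TRUE
        } else {
          if (overlap(L - hi_local, L - lo_local)) hit10_ess <- TRUE
        }
      }
    }
    # seed with <= 1 mismatch followed by NGG/NAG
    for (start in seq_len(L - 15)) {
      mm <- sum(s[start:(start + 12)] != seed)
      if (mm <= 1 &&
        s[start + 14] %in% c("G", "A") && s[start + 15] == "G") {
        hit_seed <- TRUE
      }
    }
  }
  if (hit10_ess) {
    return("fail_10nt_essential")
  }
  if (hit12) {
    return("fail_12nt_anywhere")
  }
  if (hit_seed) {
    return("fail_seed_mismatch")
  }
  "pass"
}

# Random DNA of a given length (uniform base composition).
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Convenience: a digitally consistent repression gate and activation sensor.
test_gate <- function() hill_params(50, 20000, K = 2000, n = 2)

test_sensor <- function(K = 2, units = "ng/ml") {
  hill_params(50, 20000, K = K, n = 2, mode = "activation",
    input_units = units
  )
}

# Hand-built paper MUX network: OUT = NOR(NOR(IN1, S), NOR(IN2, NOT(S))).
paper_mux_network <- function() {
  gate_network(
    data.frame(
      id = c("IN1", "IN2", "SELECT", "notS", "norA", "norB", "out"),
      kind = c("INPUT", "INPUT", "INPUT", "NOT", "NOR", "NOR", "NOR"),
      in1 = c(NA, NA, NA, "SELECT", "IN1", "IN2", "norA"),
      in2 = c(NA, NA, NA, NA, "SELECT", "notS", "norB")
    ),
    outputs = "out"
  )
}

# Hand-built paper DEMUX network: OUT1 = NOR(NOT(IN), S),
# OUT2 = NOR(NOT(IN), NOT(S)).
paper_demux_network <- function() {
  gate_network(
    data.frame(
      id = c("IN", "SELECT", "notIN", "notS", "out1", "out2"),
      kind = c("INPUT", "INPUT", "NOT", "NOT", "NOR", "NOR"),
      in1 = c(NA, NA, "IN", "SELECT", "notIN", "notIN"),
      in2 = c(NA, NA, NA, NA, "SELECT", "notS")
    ),
    outputs = c("out1", "out2")
  )
}
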