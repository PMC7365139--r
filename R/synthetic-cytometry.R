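# Synthetic event-level and summary cytometry data with the statistical
# structure the analysis assumes: log-normal single-cell fluorescence in
# calibrated MEFL/MECY units with an additive autofluorescence floor,
# two-strain mixtures separable on FL3, and transfer-function datasets
# generated from known Hill parameters.

#' Specification of one cell population's fluorescence distribution
#'
#' @param log10_mean Mean of log10 FL1 signal (MEFL decades). Use `-Inf` for
#'   a zero-signal (autofluorescence-only) population.
#' @param log10_sd Population SD in decades (> 0); applies to FL1, FL3 and
#'   the scatter channels.
#' @param autofluorescence_mean Mean autofluorescence, MEFL (added to the
#'   FL1 signal draw on the linear scale).
#' @param fl3_log10_mean Mean of log10 FL3 (MECY decades) — the strain
#'   classification channel.
#' @param n_events Number of events (>= 1). Default follows typical
#'   acquisition counts for E. coli-sized events.
#' @return A `population_spec` list.
#' @export
population_spec <- function(log10_mean, log10_sd = 0.2,
                            autofluorescence_mean = 50,
                            fl3_log10_mean = 1, n_events = 20000) {
  stopifnot(log10_sd > 0, n_events >= 1, autofluorescence_mean > 0)
  structure(
    list(
      log10_mean = log10_mean, log10_sd = log10_sd,
      autofluorescence_mean = autofluorescence_mean,
      fl3_log10_mean = fl3_log10_mean, n_events = as.integer(n_events)
    ),
    class = "population_spec"
  )
}

ln_base <- log(10)

# Log-normal draws parameterized by the mean and SD of log10(x).
rlnorm10 <- function(n, log10_mean, log10_sd) {
  10^stats::rnorm(n, mean = log10_mean, sd = log10_sd)
}

#' Sample an event-level cytometry table for one population
#'
#' FL1 is an autofluorescence draw plus a log-normal signal draw (linear
#' sum, matching an sfGFP signal riding on cellular background); FL3 is
#' log-normal around its specified decade mean; FSC and SSC are correlated
#' log-normal nuisance channels (cell-size proxy) used only to exercise
#' density gating.
#'
#' @param spec A [population_spec()].
#' @param seed Optional RNG seed; fixed seed gives a bit-identical table.
#' @return A `cytometry_sample` tibble with columns `fl1_mefl`, `fl3_mecy`,
#'   `fsc`, `ssc`.
#' @export
sample_population <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "population_spec"))
  with_seed(seed, {
    n <- spec$n_events
    auto <- rlnorm10(n, log10(spec$autofluorescence_mean), 0.25)
    signal <- if (is.finite(spec$log10_mean)) {
      rlnorm10(n, spec$log10_mean, spec$log10_sd)
    } else {
      0
    }
    fl3 <- rlnorm10(n, spec$fl3_log10_mean, spec$log10_sd)
    scatter <- matrix(MASS::mvrnorm(
      n,
      mu = c(2.5, 2.2),
      Sigma = 0.15^2 * matrix(c(1, 0.7, 0.7, 1), 2)
    ), ncol = 2)
    out <- tibble::tibble(
      fl1_mefl = auto + signal,
      fl3_mecy = fl3,
      fsc = 10^scatter[, 1],
      ssc = 10^scatter[, 2]
    )
    class(out) <- c("cytometry_sample", class(out))
    out
  })
}

#' Generate a transfer-function dataset from known Hill parameters
#'
#' Evaluates the Hill model on an input grid, perturbs each replicate by
#' multiplicative log-normal noise, and averages replicates on the linear
#' MEFL scale (mean fluorescence is always an arithmetic mean of linear
#' MEFL). The default grid is the 7-level aTc dose series used for NOT-gate
#' characterization (0, 1, 1.5, 2, 3, 4, 20 ng/ml).
#'
#' @param true_params A [hill_params()]; its `mode` decides whether the grid
#'   is inducer (activation) or input MEFL (repression).
#' @param input_grid Input values; default the 7-point aTc series.
#' @param noise_sd Log-normal noise SD in decades (0 gives exact model
#'   values).
#' @param replicates Number of replicates averaged per grid point.
#' @param seed Optional RNG seed.
#' @return A [transfer_dataset()] with per-point `sem` across replicates.
#' @export
generate_transfer_dataset <- function(true_params,
                                      input_grid = c(0, 1, 1.5, 2, 3, 4, 20),
                                      noise_sd = 0.05, replicates = 3,
                                      seed = NULL) {
  stopifnot(inherits(true_params, "hill_params"), length(input_grid) >= 1)
  with_seed(seed, {
    mu <- hill_response(input_grid, true_params)
    reps <- vapply(seq_len(replicates), function(r) {
      mu * 10^stats::rnorm(length(mu), 0, noise_sd)
    }, numeric(length(mu)))
    reps <- matrix(reps, nrow = length(mu))
    y <- rowMeans(reps)
    sem <- if (replicates > 1) {
      apply(reps, 1, stats::sd) / sqrt(replicates)
    } else {
      rep(NA_real_, length(mu))
    }
    transfer_dataset(input_grid, y,
      sem = sem,
      input_units = true_params$input_units
    )
  })
}

#' Generate a two-strain co-culture cytometry sample with true labels
#'
#' Events are drawn from two population specs mixed at the expected
#' `ratio_a:ratio_b` proportions (per-event multinomial labels); strain
#' separation on FL3 is controlled by the two specs' `fl3_log10_mean`.
#'
#' @param spec_a,spec_b [population_spec()]s for the two strains.
#' @param ratio_a,ratio_b Mixing ratio (e.g. 10 and 1 for the 10:1
#'   sender:receiver co-culture).
#' @param n_events Total events.
#' @param labels Labels for the two strains.
#' @param seed Optional RNG seed.
#' @return A `cytometry_sample` tibble with an extra `label` column (the
#'   true strain of each event).
#' @export
generate_coculture_sample <- function(spec_a, spec_b, ratio_a = 10,
                                      ratio_b = 1, n_events = 22000,
                                      labels = c("A", "B"), seed = NULL) {
  stopifnot(ratio_a >= 0, ratio_b >= 0, ratio_a + ratio_b > 0)
  with_seed(seed, {
    p_a <- ratio_a / (ratio_a + ratio_b)
    from_a <- stats::rbinom(n_events, 1, p_a) == 1
    sa <- spec_a
    sa$n_events <- max(sum(from_a), 1L)
    sb <- spec_b
    sb$n_events <- max(sum(!from_a), 1L)
    ev_a <- sample_population(sa)
    ev_b <- sample_population(sb)
    out <- dplyr::bind_rows(
      dplyr::mutate(ev_a[seq_len(sum(from_a)), ], label = labels[1]),
      dplyr::mutate(ev_b[seq_len(sum(!from_a)), ], label = labels[2])
    )
    out <- out[sample.int(nrow(out)), ] # shuffle acquisition order
    class(out) <- c("cytometry_sample", class(out))
    out
  })
}

#' Generate a synthetic sgRNA x promoter orthogonality panel
#'
#' Emulates the all-pairs repression assay: every sgRNA is strongly induced
#' against every promoter and the fold change in reporter fluorescence is
#' recorded. Diagonal (cognate) entries are drawn around `on_target_fold`,
#' off-diagonal entries around `off_target_fold` (about 1 = no
#' cross-repression), with multiplicative log-normal noise.
#'
#' @param n_pairs Panel dimension (default 9 for a 9 x 9 = 81-strain panel).
#' @param on_target_fold Expected cognate fold repression.
#' @param off_target_fold Expected non-cognate fold (default 1).
#' @param noise_sd Log10 noise SD in decades.
#' @param seed Optional RNG seed.
#' @return A tibble with `sgrna`, `promoter`, `fold_change`, `cognate`.
#' @export
generate_orthogonality_panel <- function(n_pairs = 9, on_target_fold = 100,
                                         off_target_fold = 1,
                                         noise_sd = 0.05, seed = NULL) {
  stopifnot(on_target_fold > 0, off_target_fold > 0)
  with_seed(seed, {
    grid <- tidyr::expand_grid(
      sgrna = paste0("S", seq_len(n_pairs)),
      promoter = paste0("P", seq_len(n_pairs))
    )
    grid$cognate <- sub("S", "", grid$sgrna) == sub("P", "", grid$promoter)
    base <- ifelse(grid$cognate, on_target_fold, off_target_fold)
    grid$fold_change <- base * 10^stats::rnorm(nrow(grid), 0, noise_sd)
    grid[, c("sgrna", "promoter", "fold_change", "cognate")]
  })
}
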