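# Evaluation and data-reduction procedures: RMSE in MEFL decades, density
# gating, FL3 strain classification, and the logarithmic binning rules used
# for frequency distributions and violins.

#' RMSE between predicted and measured fluorescence, in MEFL decades
#'
#' `sqrt(mean((log10(predicted) - log10(measured))^2))` over all usable
#' pairs. A pair in which either value equals zero cannot be log-transformed
#' and is omitted from the calculation.
#'
#' @param predicted,measured Paired mean fluorescence values (MEFL);
#'   non-negative, equal length.
#' @return RMSE in MEFL decades (a factor-of-10 mismatch across all pairs
#'   gives exactly 1).
#' @examples
#' rmse_decades(100, 1000) # one decade
#' @export
rmse_decades <- function(predicted, measured) {
  if (length(predicted) != length(measured)) {
    stop("predicted and measured must be paired (equal length)", call. = FALSE)
  }
  if (any(predicted < 0) || any(measured < 0)) {
    stop("fluorescence values must be non-negative", call. = FALSE)
  }
  use <- predicted > 0 & measured > 0
  if (!any(use)) {
    stop("no comparable pairs: every pair contains a zero", call. = FALSE)
  }
  sqrt(mean((log10(predicted[use]) - log10(measured[use]))^2))
}

#' Density gate: retain events in the densest FSC x SSC region
#'
#' Estimates the event density on a deterministic 64 x 64 histogram over
#' (log10 FSC, log10 SSC), ranks events by the density of their bin (ties
#' broken by acquisition order) and retains the top `round(fraction * n)`
#' events.
#'
#' @param sample A `cytometry_sample` (needs `fsc` and `ssc` columns).
#' @param fraction Fraction of events to retain, in (0, 1]; default 0.85.
#' @return The gated sample (same columns); with fewer than 10 events the
#'   sample is passed through unchanged with a warning.
#' @export
density_gate <- function(sample, fraction = 0.85) {
  stopifnot(fraction > 0, fraction <= 1)
  n <- nrow(sample)
  if (n < 10) {
    warning("fewer than 10 events: refusing to gate, passing sample through")
    return(sample)
  }
  if (fraction == 1) {
    return(sample)
  }
  lx <- log10(sample$fsc)
  ly <- log10(sample$ssc)
  bx <- findInterval(lx, seq(min(lx), max(lx), length.out = 65),
    rightmost.closed = TRUE, all.inside = TRUE
  )
  by <- findInterval(ly, seq(min(ly), max(ly), length.out = 65),
    rightmost.closed = TRUE, all.inside = TRUE
  )
  bin <- (bx - 1L) * 64L + by
  counts <- table(bin)
  dens <- as.integer(counts[as.character(bin)])
  keep_n <- round(fraction * n)
  ord <- order(-dens, seq_len(n)) # stable: ties keep acquisition order
  keep <- sort(ord[seq_len(keep_n)])
  sample[keep, ]
}

#' Classify events into strains by an FL3 threshold
#'
#' Events at or above the threshold get `high_label`, the rest `low_label`
#' (boundary equality assigned high, a declared convention). This is the
#' rule used to separate co-cultured strains carrying different red
#' (mCherry) markers — e.g. a 1,000-MECY threshold for sender/receiver
#' pairs, 600 MECY for the channel-selector co-cultures.
#'
#' @param sample A `cytometry_sample` (needs `fl3_mecy` and `fl1_mefl`).
#' @param threshold FL3 threshold, MECY (> 0).
#' @param high_label,low_label Class labels.
#' @return A list: `events` (the sample plus a `class` column) and `summary`
#'   (per-class event count and mean FL1, arithmetic mean of linear MEFL).
#' @export
classify_fl3 <- function(sample, threshold, high_label = "high",
                         low_label = "low") {
  stopifnot(threshold > 0)
  cls <- ifelse(sample$fl3_mecy >= threshold, high_label, low_label)
  events <- dplyr::mutate(sample, class = cls)
  summary <- dplyr::summarise(
    dplyr::group_by(events, .data$class),
    n_events = dplyr::n(),
    mean_fl1_mefl = mean(.data$fl1_mefl),
    .groups = "drop"
  )
  list(events = events, summary = summary)
}

#' Logarithmic binning of fluorescence values
#'
#' Two binning rules used for visualization:
#' \describe{
#'   \item{`frequency64`}{values (spanning the 1,024-channel instrument
#'     range) are down-sampled into 64 logarithmic bins over the sample's
#'     value range — 1 bin per 16 adjacent instrument values — and the
#'     frequencies normalized so the most frequent bin (the peak) is 0.5.}
#'   \item{`violin125`}{values are binned into 125 logarithmic bins from
#'     10 MEFL to 1,000,000 MEFL (25 bins per decade); the top and bottom 1%
#'     of measurements (`floor(0.01 * n)` from each tail) are trimmed before
#'     binning, while the mean is computed before trimming.}
#' }
#'
#' @param values Positive fluorescence values (MEFL).
#' @param mode `"frequency64"` or `"violin125"`.
#' @return A `fluor_histogram` tibble with `bin_lo`, `bin_hi`, `count` and
#'   `height` (normalized frequency), with attributes `mode`,
#'   `mean_mefl` (pre-trim arithmetic mean) and `n_trimmed`.
#' @export
bin_events <- function(values, mode = c("frequency64", "violin125")) {
  mode <- match.arg(mode)
  if (!length(values)) stop("no values to bin", call. = FALSE)
  if (any(values <= 0)) {
    stop("fluorescence values must be positive", call. = FALSE)
  }
  mean_mefl <- mean(values)
  n_trimmed <- 0L
  if (mode == "frequency64") {
    lo <- min(values)
    hi <- max(values)
    if (lo == hi) hi <- lo * (1 + 1e-9) # single occupied bin
    edges <- 10^seq(log10(lo), log10(hi), length.out = 65)
    idx <- findInterval(values, edges, rightmost.closed = TRUE,
      all.inside = TRUE
    )
    counts <- tabulate(idx, nbins = 64)
    height <- 0.5 * counts / max(counts)
  } else {
    k <- floor(0.01 * length(values))
    n_trimmed <- 2L * k
    v <- sort(values)
    if (k > 0) v <- v[(k + 1):(length(v) - k)]
    edges <- 10^seq(1, 6, length.out = 126) # 25 bins per decade, 5 decades
    inside <- v >= 10 & v <= 1e6
    idx <- findInterval(v[inside], edges, rightmost.closed = TRUE)
    counts <- tabulate(idx, nbins = 125)
    height <- if (max(counts) > 0) counts / max(counts) else counts
  }
  out <- tibble::tibble(
    bin_lo = edges[-length(edges)],
    bin_hi = edges[-1],
    count = counts,
    height = height
  )
  structure(out,
    mode = mode, mean_mefl = mean_mefl, n_trimmed = n_trimmed,
    class = c("fluor_histogram", class(out))
  )
}

#' Fold repression of a promoter
#'
#' Uninduced (sgRNA off) over induced (sgRNA on) mean fluorescence; values
#' above 1 indicate repression. This is the quantity reported per
#' sgRNA:promoter combination in the orthogonality panel.
#'
#' @param off_mean Mean output with the sgRNA uninduced, MEFL (> 0).
#' @param on_mean Mean output with the sgRNA induced, MEFL (> 0).
#' @return The fold repression `off_mean / on_mean`.
#' @export
fold_repression <- function(off_mean, on_mean) {
  if (any(off_mean <= 0) || any(on_mean <= 0)) {
    stop("means must be positive", call. = FALSE)
  }
  off_mean / on_mean
}

#' Plot a binned fluorescence histogram
#'
#' @param object A `fluor_histogram` from [bin_events()].
#' @param ... Unused.
#' @return A ggplot of normalized frequency vs fluorescence (log axis).
#' @export
autoplot.fluor_histogram <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = sqrt(.data$bin_lo * .data$bin_hi), y = .data$height
  )) +
    ggplot2::geom_col(width = NULL) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "fluorescence (MEFL)",
      y = "normalized frequency"
    )
}
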