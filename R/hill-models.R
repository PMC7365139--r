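#' Hill transfer-function parameters
#'
#' Parameters of the steady-state input/output curve of one CRISPRi gate or
#' small-molecule sensor. For a repressive gate the input is the
#' sgRNA-producing promoter's activity in MEFL; for a sensor it is an inducer
#' concentration (units carried alongside, not enforced).
#'
#' @param y_min,y_max Output floor and ceiling, MEFL. `0 <= y_min < y_max`.
#' @param K Half-maximal input (MEFL for gates, inducer units for sensors);
#'   positive.
#' @param n Hill coefficient; positive.
#' @param mode `"repression"` (NOT/NOR gates) or `"activation"` (sensors).
#' @param input_units Optional unit label for the input axis (e.g. `"MEFL"`,
#'   `"ng/ml"`, `"nM"`).
#' @return A `hill_params` object (named list).
#' @examples
#' hill_params(100, 10000, K = 500, n = 1)
#' @export
hill_params <- function(y_min, y_max, K, n = 1,
                        mode = c("repression", "activation"),
                        input_units = "MEFL") {
  mode <- match.arg(mode)
  if (!(is.finite(y_min) && is.finite(y_max) && y_min >= 0 && y_min < y_max)) {
    stop("require 0 <= y_min < y_max", call. = FALSE)
  }
  if (!(is.finite(K) && K > 0)) stop("require K > 0", call. = FALSE)
  if (!(is.finite(n) && n > 0)) stop("require n > 0", call. = FALSE)
  structure(
    list(
      y_min = y_min, y_max = y_max, K = K, n = n, mode = mode,
      input_units = input_units
    ),
    class = "hill_params"
  )
}

#' @export
print.hill_params <- function(x, ...) {
  cat(sprintf(
    "<hill_params> %s: y_min=%.4g y_max=%.4g MEFL, K=%.4g %s, n=%.3g\n",
    x$mode, x$y_min, x$y_max, x$K, x$input_units, x$n
  ))
  invisible(x)
}

#' Repressive Hill response of a NOT gate
#'
#' `y = y_min + (y_max - y_min) / (1 + (x / K)^n)`: continuous and monotone
#' non-increasing in the input. At `x = 0` the gate sits at `y_max`; at
#' `x = K` it is exactly halfway between the asymptotes.
#'
#' @param x Input promoter activity, MEFL (vectorized, non-negative).
#' @param p A [hill_params()] with `mode = "repression"`.
#' @return Output MEFL, same length as `x`.
#' @export
not_response <- function(x, p) {
  stopifnot(inherits(p, "hill_params"))
  if (p$mode != "repression") {
    stop("not_response needs repression-mode parameters", call. = FALSE)
  }
  if (any(x < 0)) stop("input MEFL must be non-negative", call. = FALSE)
  p$y_min + (p$y_max - p$y_min) / (1 + (x / p$K)^p$n)
}

#' NOR gate response as a two-input extension of the NOT model
#'
#' The two input promoters transcribe the same sgRNA species, so their
#' transcription fluxes add before the repressive nonlinearity:
#' `nor_response(x1, x2, p) = not_response(x1 + x2, p)`. The function is
#' symmetric in its inputs and reduces exactly to the NOT gate when one
#' input is silent.
#'
#' @param x1,x2 Input promoter activities, MEFL (vectorized).
#' @inheritParams not_response
#' @return Output MEFL.
#' @export
nor_response <- function(x1, x2, p) {
  if (any(x1 < 0) || any(x2 < 0)) {
    stop("input MEFL must be non-negative", call. = FALSE)
  }
  not_response(x1 + x2, p)
}

#' Activating Hill response of a small-molecule sensor
#'
#' `y = y_min + (y_max - y_min) * (c/K)^n / (1 + (c/K)^n)`: monotone
#' non-decreasing, `y_min` at zero inducer, midpoint at `c = K`.
#'
#' @param c Inducer concentration (vectorized, non-negative; units per `p`).
#' @param p A [hill_params()] with `mode = "activation"`.
#' @return Output MEFL.
#' @export
sensor_response <- function(c, p) {
  stopifnot(inherits(p, "hill_params"))
  if (p$mode != "activation") {
    stop("sensor_response needs activation-mode parameters", call. = FALSE)
  }
  if (any(c < 0)) stop("inducer concentration must be non-negative",
    call. = FALSE
  )
  r <- (c / p$K)^p$n
  p$y_min + (p$y_max - p$y_min) * r / (1 + r)
}

# Response under either mode; used by the circuit engine and the fitter.
hill_response <- function(x, p) {
  if (p$mode == "repression") not_response(x, p) else sensor_response(x, p)
}

#' Transfer-function measurement table
#'
#' @param x Input values (MEFL for gates, inducer concentration for sensors);
#'   non-negative.
#' @param y Mean output MEFL; strictly positive (autofluorescence-floored).
#' @param sem Optional per-point standard error of the mean.
#' @param input_units Unit label for `x`.
#' @return A tibble of class `transfer_dataset` with columns `input`,
#'   `input_units`, `mean_output_mefl` and `sem`.
#' @export
transfer_dataset <- function(x, y, sem = NULL, input_units = "MEFL") {
  stopifnot(length(x) == length(y))
  if (any(x < 0)) stop("inputs must be non-negative", call. = FALSE)
  if (any(y <= 0)) {
    stop("outputs must be positive (autofluorescence-floored)", call. = FALSE)
  }
  if (!is.null(sem)) stopifnot(length(sem) == length(y))
  out <- tibble::tibble(
    input = as.numeric(x),
    input_units = input_units,
    mean_output_mefl = as.numeric(y),
    sem = if (is.null(sem)) NA_real_ else as.numeric(sem)
  )
  class(out) <- c("transfer_dataset", class(out))
  out
}

#' Fit a Hill transfer function in log space
#'
#' Least-squares fit of `log10(model)` to `log10(y)`. Fluorescence spans
#' decades, so fitting in log space weights the two asymptotes equally.
#' Bounds keep the fit identifiable: `y_min` in `[floor, min(y)]`, `y_max`
#' in `[max(y), 10 * max(y)]`, `n` in `[0.5, 4]`, and `K` within a decade of
#' the observed input range; `K` is multi-started at the data quantiles to
#' avoid local minima. With `constrain_n = TRUE` the Hill coefficient is
#' fixed at 1.
#'
#' @param d A [transfer_dataset()] (or data frame with `input` and
#'   `mean_output_mefl` columns).
#' @param mode `"repression"` or `"activation"`.
#' @param constrain_n Fix the Hill coefficient at 1?
#' @param floor Lower bound for `y_min` (autofluorescence floor, MEFL).
#' @return A `hill_fit` object: list with `params` ([hill_params()] or `NULL`
#'   when degenerate), `rmse_decades`, `constrained`, `identifiable`,
#'   `logLik`, `aic`, `n_obs` and the fitted `data`.
#' @examples
#' p <- hill_params(200, 20000, K = 1000, n = 1.5)
#' d <- transfer_dataset(10^seq(1, 5, length.out = 7),
#'                       not_response(10^seq(1, 5, length.out = 7), p))
#' fit_transfer_function(d)$params
#' @export
fit_transfer_function <- function(d, mode = c("repression", "activation"),
                                  constrain_n = FALSE, floor = 1) {
  mode <- match.arg(mode)
  stopifnot(all(c("input", "mean_output_mefl") %in% names(d)))
  x <- d$input
  y <- d$mean_output_mefl
  units <- if ("input_units" %in% names(d)) d$input_units[1] else "MEFL"
  if (any(y <= 0)) stop("outputs must be positive", call. = FALSE)
  n_obs <- length(y)

  if (diff(range(y)) == 0) {
    # degenerate: flat data; K and n are unidentifiable
    return(structure(
      list(
        params = NULL, y_min = y[1], y_max = y[1],
        rmse_decades = 0, constrained = constrain_n, identifiable = FALSE,
        logLik = NA_real_, aic = NA_real_, n_obs = n_obs, data = d,
        mode = mode
      ),
      class = "hill_fit"
    ))
  }

  ly <- log10(y)
  lo_ymin <- log10(max(floor, .Machine$double.eps))
  hi_ymin <- log10(min(y))
  lo_ymax <- log10(max(y))
  hi_ymax <- log10(10 * max(y))
  xp <- x[x > 0]
  lo_k <- log10(min(xp) / 10)
  hi_k <- log10(max(xp) * 10)
  k_starts <- log10(stats::quantile(xp, c(0.25, 0.5, 0.75), names = FALSE))

  model_ly <- function(lymin, lymax, lk, n) {
    p <- list(
      y_min = 10^lymin, y_max = 10^lymax, K = 10^lk, n = n, mode = mode
    )
    r <- (x / p$K)^p$n
    val <- if (mode == "repression") {
      p$y_min + (p$y_max - p$y_min) / (1 + r)
    } else {
      p$y_min + (p$y_max - p$y_min) * r / (1 + r)
    }
    log10(val)
  }

  best <- NULL
  ctrl <- minpack.lm::nls.lm.control(
    maxiter = 1000, ftol = 1e-14, ptol = 1e-14
  )
  n_starts <- if (constrain_n) 1 else c(1, 2)
  for (lk0 in k_starts) {
    for (n0 in n_starts) {
      start <- list(
        lymin = max(lo_ymin, hi_ymin - 0.5),
        lymax = min(hi_ymax, lo_ymax + 0.25),
        lk = lk0
      )
      lower <- c(lo_ymin, lo_ymax, lo_k)
      upper <- c(hi_ymin, hi_ymax, hi_k)
      if (!constrain_n) {
        start$n <- n0
        lower <- c(lower, 0.5)
        upper <- c(upper, 4)
      }
      fit <- tryCatch(
        if (constrain_n) {
          minpack.lm::nlsLM(
            ly ~ model_ly(lymin, lymax, lk, 1),
            start = start, lower = lower, upper = upper, control = ctrl
          )
        } else {
          minpack.lm::nlsLM(
            ly ~ model_ly(lymin, lymax, lk, n),
            start = start, lower = lower, upper = upper, control = ctrl
          )
        },
        error = function(e) NULL
      )
      if (is.null(fit)) next
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) stop("Hill fit failed to converge", call. = FALSE)

  cf <- stats::coef(best$fit)
  params <- hill_params(
    y_min = 10^cf[["lymin"]], y_max = 10^cf[["lymax"]],
    K = 10^cf[["lk"]], n = if (constrain_n) 1 else cf[["n"]],
    mode = mode, input_units = units
  )
  rmse <- sqrt(best$rss / n_obs)
  ll <- stats::logLik(best$fit)
  structure(
    list(
      params = params, rmse_decades = rmse, constrained = constrain_n,
      identifiable = TRUE, logLik = as.numeric(ll),
      aic = stats::AIC(best$fit), n_obs = n_obs, data = d, mode = mode
    ),
    class = "hill_fit"
  )
}

#' Compare constrained and unconstrained Hill fits
#'
#' Fits both the n = 1 (constrained) and free-n models and reports an
#' information-criterion comparison. The constrained model is nested in the
#' unconstrained one, so its residual error is never smaller; whether the
#' extra parameter is warranted is summarized by AIC.
#'
#' @inheritParams fit_transfer_function
#' @return A list with `constrained`, `unconstrained` (both `hill_fit`) and
#'   `preferred` (`"constrained"` or `"unconstrained"` by lower AIC).
#' @export
compare_hill_fits <- function(d, mode = c("repression", "activation"),
                              floor = 1) {
  mode <- match.arg(mode)
  fc <- fit_transfer_function(d, mode = mode, constrain_n = TRUE, floor = floor)
  fu <- fit_transfer_function(d, mode = mode, constrain_n = FALSE, floor = floor)
  list(
    constrained = fc, unconstrained = fu,
    preferred = if (isTRUE(fc$aic <= fu$aic)) "constrained" else "unconstrained"
  )
}

#' @export
print.hill_fit <- function(x, ...) {
  if (!x$identifiable) {
    cat(sprintf(
      "<hill_fit> degenerate (flat data): y_min = y_max = %.4g MEFL; K, n unidentifiable\n",
      x$y_min
    ))
    return(invisible(x))
  }
  cat(sprintf(
    "<hill_fit> %s (%s n), RMSE = %.4g MEFL decades\n",
    x$mode, if (x$constrained) "constrained" else "free", x$rmse_decades
  ))
  print(x$params)
  invisible(x)
}

#' Tidy a fitted Hill model
#'
#' @param x A `hill_fit`.
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
tidy.hill_fit <- function(x, ...) {
  if (!x$identifiable) {
    return(tibble::tibble(
      term = c("y_min", "y_max"), estimate = c(x$y_min, x$y_max)
    ))
  }
  p <- x$params
  tibble::tibble(
    term = c("y_min", "y_max", "K", "n"),
    estimate = c(p$y_min, p$y_max, p$K, p$n)
  )
}

#' One-row model summary of a fitted Hill model
#'
#' @inheritParams tidy
#' @return A one-row tibble: `rmse_decades`, `aic`, `logLik`, `n_obs`,
#'   `constrained`, `identifiable`.
#' @export
glance <- function(x, ...) UseMethod("glance")

#' @rdname glance
#' @export
glance.hill_fit <- function(x, ...) {
  tibble::tibble(
    rmse_decades = x$rmse_decades, aic = x$aic, logLik = x$logLik,
    n_obs = x$n_obs, constrained = x$constrained,
    identifiable = x$identifiable
  )
}

#' Predict from a fitted Hill model
#'
#' @param object A `hill_fit`.
#' @param newdata Optional vector of input values; defaults to the fitted
#'   inputs.
#' @param ... Unused.
#' @return Predicted mean output MEFL.
#' @export
predict.hill_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$input else newdata
  if (!object$identifiable) return(rep(object$y_min, length(x)))
  hill_response(x, object$params)
}

#' Plot a transfer dataset and (optionally) its Hill fit
#'
#' @param object A `hill_fit` or `transfer_dataset`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hill_fit <- function(object, ...) {
  d <- object$data
  xs <- d$input
  pos <- xs[xs > 0]
  grid <- c(0, 10^seq(log10(min(pos)) - 0.5, log10(max(pos)) + 0.5,
    length.out = 200
  ))
  pred <- tibble::tibble(input = grid, fit = predict(object, grid))
  ggplot2::ggplot(d, ggplot2::aes(x = pmax(.data$input, min(pos) / 10))) +
    ggplot2::geom_point(ggplot2::aes(y = .data$mean_output_mefl)) +
    ggplot2::geom_line(
      data = pred,
      ggplot2::aes(x = pmax(.data$input, min(pos) / 10), y = .data$fit),
      color = "firebrick"
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = paste0("input (", d$input_units[1], ")"),
      y = "mean output (MEFL)"
    )
}
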