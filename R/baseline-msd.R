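## Non-learned MSD-fit baseline predictor.
##
## For each trajectory the time-averaged MSD is computed with overlapping
## windows; K comes from a linear fit of MSD vs lag over the first quarter
## of lags (slope / 4), alpha from the log-log slope over the same range.
## The baseline never predicts changepoints (one segment per trajectory)
## and never emits the "confined" type identifier — both documented
## limitations that make it the floor any real method must beat.

#' Time-averaged mean-squared displacement of one trajectory
#'
#' Overlapping-window TA-MSD:
#' `msd(tau) = mean_t [ (x(t+tau)-x(t))^2 + (y(t+tau)-y(t))^2 ]`.
#'
#' @param x,y coordinate vectors of one trajectory (pixels).
#' @param max_lag largest lag, frames; default a quarter of the
#'   trajectory length (at least 2).
#' @return tibble of class `"msd_curve"`: `lag`, `msd`, `n_pairs`.
#' @export
tamsd <- function(x, y, max_lag = NULL) {
  n <- length(x)
  stopifnot(length(y) == n)
  max_lag <- max_lag %||% max(2L, floor((n - 1) / 4))
  if (n < max_lag + 1) {
    stop("trajectory shorter than max_lag + 1", call. = FALSE)
  }
  lags <- seq_len(max_lag)
  out <- tibble::tibble(
    lag = lags,
    msd = vapply(lags, function(tau) {
      dx <- x[(1 + tau):n] - x[1:(n - tau)]
      dy <- y[(1 + tau):n] - y[1:(n - tau)]
      mean(dx^2 + dy^2)
    }, numeric(1)),
    n_pairs = n - lags
  )
  class(out) <- c("msd_curve", class(out))
  out
}

## lags used by the fits: first quarter of the available lags (>= 2 lags)
fit_lags <- function(curve) {
  k <- max(2L, floor(nrow(curve) / 4))
  curve[seq_len(min(k, nrow(curve))), ]
}

#' Estimate K by a linear fit of the MSD
#'
#' Least-squares line over the first quarter of lags; `K = slope / 4`
#' (2-D). An intercept is kept so static localization noise does not bias
#' the slope. Negative estimates are clamped to 0.
#'
#' @param curve an [tamsd()] curve.
#' @return K estimate, pixel^2/frame^alpha.
#' @export
fit_K_linear <- function(curve) {
  d <- fit_lags(curve)
  if (nrow(d) < 2 || all(d$msd == 0)) {
    return(0)
  }
  slope <- stats::coef(stats::lm(msd ~ lag, data = d))[["lag"]]
  max(slope / 4, 0)
}

#' Estimate alpha by a log-log fit of the MSD
#'
#' Slope of `log(msd)` vs `log(lag)` over the first quarter of lags,
#' clipped to `[0.01, 1.99]`. Non-positive MSD values are dropped (with a
#' warning); if fewer than 2 usable lags remain the immobile value 0.01
#' is returned.
#'
#' @param curve an [tamsd()] curve.
#' @return alpha estimate in `[0.01, 1.99]`.
#' @export
fit_alpha_loglog <- function(curve) {
  d <- fit_lags(curve)
  bad <- d$msd <= 0
  if (any(bad)) {
    warning("dropping ", sum(bad), " non-positive MSD value(s)")
    d <- d[!bad, ]
  }
  if (nrow(d) < 2) {
    return(ALPHA_MIN)
  }
  slope <- stats::coef(stats::lm(log(msd) ~ log(lag), data = d))[["log(lag)"]]
  min(max(slope, ALPHA_MIN), ALPHA_MAX)
}

#' Classify the diffusion type from (K, alpha) estimates
#'
#' 0 = immobile (`K` below `k_immobile` or `alpha < 0.05`), 3 = directed
#' (`alpha >= 1.9`), otherwise 2 = free. The baseline has no confinement
#' detector, so type 1 is never emitted.
#'
#' @param K,alpha estimates.
#' @param k_immobile immobility threshold on K (default 1e-3).
#' @return integer type identifier in `{0, 2, 3}`.
#' @export
classify_type <- function(K, alpha, k_immobile = 1e-3) {
  ifelse(K < k_immobile | alpha < 0.05, TYPE_IMMOBILE,
    ifelse(alpha >= 1.9, TYPE_DIRECTED, TYPE_FREE)
  )
}

#' Fit the MSD baseline to one trajectory
#'
#' @param x,y coordinates of one trajectory.
#' @param k_immobile immobility threshold passed to [classify_type()].
#' @return list of class `"msd_fit"`: `K`, `alpha`, `type`, `curve`,
#'   `n_frames`.
#' @export
fit_msd <- function(x, y, k_immobile = 1e-3) {
  curve <- tamsd(x, y)
  K <- fit_K_linear(curve)
  alpha <- fit_alpha_loglog(curve)
  structure(
    list(
      K = K, alpha = alpha,
      type = as.integer(classify_type(K, alpha, k_immobile)),
      curve = curve, n_frames = length(x)
    ),
    class = "msd_fit"
  )
}

#' @export
print.msd_fit <- function(x, ...) {
  cat(sprintf(
    "<msd_fit> K = %.4g, alpha = %.3f, type = %d (%d frames)\n",
    x$K, x$alpha, x$type, x$n_frames
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an MSD baseline fit
#'
#' @param x an `"msd_fit"` object.
#' @param ... unused.
#' @return one row per estimated quantity: `term`, `estimate`.
#' @exportS3Method generics::tidy
tidy.msd_fit <- function(x, ...) {
  tibble::tibble(
    term = c("K", "alpha", "type"),
    estimate = c(x$K, x$alpha, x$type)
  )
}

#' One-row summary of an MSD baseline fit
#'
#' @param x an `"msd_fit"` object.
#' @param ... unused.
#' @return one-row tibble: `K`, `alpha`, `type`, `n_frames`, `max_lag`.
#' @exportS3Method generics::glance
glance.msd_fit <- function(x, ...) {
  tibble::tibble(
    K = x$K, alpha = x$alpha, type = x$type,
    n_frames = x$n_frames, max_lag = max(x$curve$lag)
  )
}

#' MSD-baseline predictions for a whole trajectory table
#'
#' Applies [fit_msd()] to every trajectory and emits a prediction segment
#' table in the same schema the scorer consumes: one segment (no
#' changepoints) per trajectory.
#'
#' @param traj trajectory tibble with columns `traj`, `frame`, `x`, `y`.
#' @param k_immobile immobility threshold.
#' @return segment tibble: `traj`, `segment`, `start`, `end`, `K`,
#'   `alpha`, `type`.
#' @export
baseline_predict <- function(traj, k_immobile = 1e-3) {
  traj |>
    dplyr::group_by(.data$traj) |>
    dplyr::arrange(.data$frame, .by_group = TRUE) |>
    dplyr::reframe({
      fr <- .data$frame
      fit <- fit_msd(.data$x, .data$y, k_immobile)
      tibble::tibble(
        segment = 1L,
        start = fr[1],
        end = fr[length(fr)],
        K = fit$K,
        alpha = fit$alpha,
        type = fit$type
      )
    })
}

#' Pool per-trajectory baseline estimates into an ensemble prediction
#'
#' Single-state summary: the weighted mean/sd of the per-segment K and
#' alpha estimates (weights proportional to segment length). A deliberate
#' floor, not a clustering method.
#'
#' @param pred_segments segment table from [baseline_predict()].
#' @param model model label to report (default `"ssm"`).
#' @return list with `model` and a one-row `states` tibble.
#' @export
baseline_ensemble <- function(pred_segments, model = "ssm") {
  w <- pred_segments$end - pred_segments$start + 1
  w <- w / sum(w)
  wmean <- function(v) sum(w * v)
  wsd <- function(v) sqrt(max(sum(w * (v - wmean(v))^2), 0))
  list(
    model = model,
    states = tibble::tibble(
      state = 1L,
      weight = 1,
      mean_K = wmean(pred_segments$K),
      sd_K = wsd(pred_segments$K),
      mean_alpha = wmean(pred_segments$alpha),
      sd_alpha = wsd(pred_segments$alpha)
    )
  )
}
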