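## Fractional Gaussian noise engine.
##
## All heterogeneous-diffusion models in this package are built on 2-D
## fractional Brownian motion: X and Y are independent FBM processes with
## Hurst exponent H = alpha/2, so the ensemble MSD of an unconstrained walk
## is MSD(t) = 4 K t^alpha. Increments (fractional Gaussian noise, fGn) have
## the stationary autocovariance
##   gamma(k) = 1/2 (|k+1|^alpha - 2|k|^alpha + |k-1|^alpha)
## for a unit-variance process; they are generated exactly by Davies-Harte
## circulant embedding (O(n log n)), with a Hosking / Durbin-Levinson
## recursion fallback should the embedding ever fail to be non-negative
## definite numerically.

## alpha is clipped away from the open-interval endpoints: the covariance
## matrix degenerates numerically at alpha -> 0 and alpha -> 2.
ALPHA_MIN <- 0.01
ALPHA_MAX <- 1.99
K_SUPPORT <- c(1e-12, 1e6)

#' Construct a diffusive state
#'
#' A diffusive state is a (K, alpha) pair: the generalized diffusion
#' coefficient K (pixel^2/frame^alpha) and the anomalous diffusion exponent
#' alpha, with the Hurst exponent H = alpha/2. `K = 0` is the degenerate
#' immobile state (allowed; it is how trapped particles are encoded).
#'
#' @param K generalized diffusion coefficient, `>= 0`; positive values are
#'   clamped into the support `[1e-12, 1e6]`.
#' @param alpha anomalous diffusion exponent, strictly in (0, 2); clipped to
#'   `[0.01, 1.99]` before generation. For the immobile state (`K = 0`)
#'   `alpha = 0` is accepted as a conventional label.
#' @return a list of class `"diffusive_state"` with fields `K`, `alpha`,
#'   `hurst`.
#' @examples
#' diffusive_state(K = 1, alpha = 0.5)
#' @export
diffusive_state <- function(K, alpha) {
  stopifnot(length(K) == 1, length(alpha) == 1, is.finite(K), is.finite(alpha))
  if (K < 0) stop("K must be non-negative", call. = FALSE)
  if (K == 0) {
    # immobile state: alpha is a label only
    alpha <- 0
  } else {
    if (alpha <= 0 || alpha >= 2) {
      stop("alpha must lie strictly in (0, 2)", call. = FALSE)
    }
    K <- min(max(K, K_SUPPORT[1]), K_SUPPORT[2])
    alpha <- min(max(alpha, ALPHA_MIN), ALPHA_MAX)
  }
  structure(
    list(K = K, alpha = alpha, hurst = alpha / 2),
    class = "diffusive_state"
  )
}

#' @export
print.diffusive_state <- function(x, ...) {
  cat(sprintf(
    "<diffusive_state> K = %g px^2/frame^alpha, alpha = %g (H = %g)\n",
    x$K, x$alpha, x$hurst
  ))
  invisible(x)
}

#' Autocovariance of unit-variance fractional Gaussian noise
#'
#' @param k integer lag(s), `>= 0`.
#' @param alpha anomalous exponent in (0, 2) (`alpha = 2H`).
#' @return `gamma(k) = 0.5 * (|k+1|^alpha - 2|k|^alpha + |k-1|^alpha)`.
#' @export
fgn_autocov <- function(k, alpha) {
  0.5 * (abs(k + 1)^alpha + abs(k - 1)^alpha - 2 * abs(k)^alpha)
}

## Memoised circulant-embedding eigenvalues for (n, alpha).
.fgn_cache <- new.env(parent = emptyenv())

fgn_spectrum <- function(n, alpha) {
  key <- sprintf("%d|%.10g", n, alpha)
  ev <- .fgn_cache[[key]]
  if (is.null(ev)) {
    g <- fgn_autocov(0:n, alpha)
    circ <- c(g, rev(g[2:n])) # length 2n
    ev <- Re(stats::fft(circ))
    if (length(ls(.fgn_cache)) > 512) {
      rm(list = ls(.fgn_cache), envir = .fgn_cache)
    }
    .fgn_cache[[key]] <- ev
  }
  ev
}

## Hosking (Durbin-Levinson) exact fGn sampler, O(n^2): fallback path and
## independent cross-check for the spectral sampler. Vectorized across series.
fgn_hosking <- function(n, alpha, n_series = 1L) {
  g <- fgn_autocov(0:n, alpha) # g[k+1] = gamma(k), gamma(0) = 1
  X <- matrix(0, n, n_series)
  X[1, ] <- stats::rnorm(n_series)
  if (n == 1L) {
    return(X)
  }
  phi <- g[2] / g[1]
  v <- g[1] * (1 - phi^2)
  X[2, ] <- phi * X[1, ] + sqrt(v) * stats::rnorm(n_series)
  if (n > 2L) {
    for (t in 2:(n - 1)) {
      kap <- (g[t + 1] - sum(phi * g[t:2])) / v
      phi <- c(phi - kap * rev(phi), kap)
      v <- v * (1 - kap^2)
      cond_mean <- colSums(phi * X[t:1, , drop = FALSE])
      X[t + 1, ] <- cond_mean + sqrt(v) * stats::rnorm(n_series)
    }
  }
  X
}

## Batched Davies-Harte sampler: one column per independent fGn series.
## Exact for the fGn covariance whenever the circulant eigenvalues are
## non-negative (always true analytically for fGn; tiny numerical negatives
## are clamped, larger ones trigger the Hosking fallback).
fgn_matrix <- function(n, alpha, n_series = 1L) {
  n <- as.integer(n)
  stopifnot(n >= 1, n_series >= 1)
  if (alpha <= 0 || alpha >= 2) {
    stop("alpha must lie strictly in (0, 2)", call. = FALSE)
  }
  alpha <- min(max(alpha, ALPHA_MIN), ALPHA_MAX)
  if (n == 1L) {
    return(matrix(stats::rnorm(n_series), 1L, n_series))
  }
  if (n <= 64L) {
    # short blocks: cached Cholesky of the Toeplitz covariance is exact
    # and much cheaper than the FFT path (frequent in segment-wise use)
    key <- sprintf("chol|%d|%.10g", n, alpha)
    L <- .fgn_cache[[key]]
    if (is.null(L)) {
      L <- t(chol(stats::toeplitz(fgn_autocov(0:(n - 1), alpha))))
      .fgn_cache[[key]] <- L
    }
    return(L %*% matrix(stats::rnorm(n * n_series), n, n_series))
  }
  ev <- fgn_spectrum(n, alpha)
  if (any(ev < 0)) {
    if (min(ev) < -1e-8 * max(ev)) {
      return(fgn_hosking(n, alpha, n_series))
    }
    ev <- pmax(ev, 0)
  }
  m <- 2L * n
  # Spectral coefficients: E|Z_j|^2 = ev_j, Hermitian-symmetric
  Z <- matrix(0+0i, m, n_series)
  Z[1, ] <- sqrt(ev[1]) * stats::rnorm(n_series)
  Z[n + 1, ] <- sqrt(ev[n + 1]) * stats::rnorm(n_series)
  if (n > 1L) {
    U <- matrix(stats::rnorm((n - 1) * n_series), n - 1, n_series)
    V <- matrix(stats::rnorm((n - 1) * n_series), n - 1, n_series)
    Z[2:n, ] <- sqrt(ev[2:n] / 2) * (U + 1i * V)
    Z[(n + 2):m, ] <- Conj(Z[n:2, , drop = FALSE])
  }
  X <- stats::mvfft(Z)
  matrix(Re(X[1:n, ]), n, n_series) / sqrt(m)
}

#' Sample unit-variance fractional Gaussian noise
#'
#' Draws one realization of length `n` with the exact fGn autocovariance
#' for the given anomalous exponent (`alpha = 1` gives i.i.d. white noise,
#' `alpha < 1` anti-persistent, `alpha > 1` persistent increments).
#'
#' @param n number of increments, `>= 1`.
#' @param alpha anomalous diffusion exponent, strictly in (0, 2).
#' @param seed optional integer seed; when given, the draw is reproducible
#'   and the caller's RNG state is left untouched.
#' @return numeric vector of length `n` with unit marginal variance.
#' @examples
#' z <- sample_fgn(1000, alpha = 0.5, seed = 1)
#' @export
sample_fgn <- function(n, alpha, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1 || n < 1) {
    stop("n must be a positive integer", call. = FALSE)
  }
  with_seed(seed, fgn_matrix(as.integer(n), alpha, 1L)[, 1])
}

#' Sample a block of 2-D FBM displacements for one diffusive state
#'
#' The two axes are independent fGn streams, each rescaled so the per-axis
#' increment variance is `2 * K * dt^alpha` (at the default sampling
#' interval `dt = 1` this is the standard `sigma^2 = 2 K dt`).
#'
#' @param n number of displacements, `>= 1`.
#' @param state a [diffusive_state()] (or a list with `K` and `alpha`).
#' @param dt sampling interval in frames (default 1).
#' @param seed optional integer seed.
#' @return a tibble with columns `dx`, `dy` (pixels) and attributes `state`
#'   and `dt`.
#' @examples
#' blk <- make_displacements(100, diffusive_state(1, 1), seed = 7)
#' @export
make_displacements <- function(n, state, dt = 1, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1 || n < 1) {
    stop("n must be a positive integer", call. = FALSE)
  }
  if (is.numeric(state) && length(state) == 2) {
    state <- diffusive_state(state[1], state[2])
  }
  if (state$K < 0) stop("K must be non-negative", call. = FALSE)
  n <- as.integer(n)
  out <- with_seed(seed, {
    if (state$K == 0) {
      matrix(0, n, 2L)
    } else {
      sd_inc <- sqrt(2 * state$K * dt^state$alpha)
      fgn_matrix(n, state$alpha, 2L) * sd_inc
    }
  })
  res <- tibble::tibble(dx = out[, 1], dy = out[, 2])
  attr(res, "state") <- state
  attr(res, "dt") <- dt
  res
}

#' Theoretical ensemble MSD of unconstrained 2-D FBM
#'
#' @param t time lag(s), `>= 0`, in frames.
#' @param state a [diffusive_state()].
#' @return `4 * K * t^alpha`, pixel^2.
#' @examples
#' theoretical_msd(5, diffusive_state(1, 1)) # 20
#' @export
theoretical_msd <- function(t, state) {
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  ifelse(t == 0, 0, 4 * state$K * t^state$alpha)
}

#' Simulate a set of unconstrained 2-D FBM trajectories
#'
#' Bulk generator for homogeneous (single-state, boundary-free) FBM, used
#' for calibration and ensemble-MSD checks. All trajectories start at the
#' origin; generation is batched through the spectral sampler so large
#' ensembles are cheap.
#'
#' @param n_traj number of trajectories.
#' @param n_frames frames per trajectory (positions 0..n_frames-1).
#' @param K,alpha diffusive state parameters.
#' @param dt sampling interval, frames.
#' @param seed optional integer seed.
#' @return tibble with columns `traj`, `frame` (0-based), `x`, `y`.
#' @examples
#' fbm_trajectories(10, 50, K = 1, alpha = 1, seed = 1)
#' @export
fbm_trajectories <- function(n_traj, n_frames, K = 1, alpha = 1, dt = 1,
                             seed = NULL) {
  stopifnot(n_traj >= 1, n_frames >= 2)
  state <- diffusive_state(K, alpha)
  with_seed(seed, {
    n_inc <- as.integer(n_frames) - 1L
    sd_inc <- sqrt(2 * state$K * dt^state$alpha)
    # one batched draw per axis
    dx <- fgn_matrix(n_inc, state$alpha, n_traj) * sd_inc
    dy <- fgn_matrix(n_inc, state$alpha, n_traj) * sd_inc
    x <- rbind(0, apply(dx, 2, cumsum))
    y <- rbind(0, apply(dy, 2, cumsum))
    tibble::tibble(
      traj = rep(seq_len(n_traj), each = n_frames),
      frame = rep(0:(n_frames - 1L), times = n_traj),
      x = as.vector(x),
      y = as.vector(y)
    )
  })
}

#' Ensemble mean-squared displacement
#'
#' Mean over trajectories of the squared displacement from each
#' trajectory's first frame, at the requested lags.
#'
#' @param traj tibble with columns `traj`, `frame`, `x`, `y`.
#' @param lags integer lags in frames (default `1:10`).
#' @return tibble with columns `lag`, `msd`, `n` (trajectories contributing).
#' @export
ensemble_msd <- function(traj, lags = 1:10) {
  stopifnot(all(c("traj", "frame", "x", "y") %in% names(traj)))
  traj |>
    dplyr::group_by(.data$traj) |>
    dplyr::arrange(.data$frame, .by_group = TRUE) |>
    dplyr::reframe(
      lag = lags[lags <= dplyr::n() - 1],
      sq = (.data$x[1 + lag] - .data$x[1])^2 +
        (.data$y[1 + lag] - .data$y[1])^2
    ) |>
    dplyr::group_by(.data$lag) |>
    dplyr::summarise(msd = mean(.data$sq), n = dplyr::n(), .groups = "drop")
}
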