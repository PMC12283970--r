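## Ensemble-task scoring: Gaussian-mixture state distributions compared by
## the first Wasserstein distance on their supports, model-label and
## state-count checks, and mean-reciprocal-rank aggregation across methods.

ALPHA_SUPPORT <- c(0, 2)

#' Evaluate the CDF of a Gaussian-mixture state distribution
#'
#' Components with `sd = 0` contribute Heaviside steps at their means;
#' Gaussian components are evaluated untruncated (the Wasserstein integral
#' later restricts to the support).
#'
#' @param mixture tibble/data frame with columns `weight`, `mean`, `sd`
#'   (weights are renormalized to sum to 1).
#' @param grid increasing numeric vector of evaluation points.
#' @return numeric vector of CDF values on `grid`.
#' @export
mixture_cdf <- function(mixture, grid) {
  stopifnot(all(c("weight", "mean", "sd") %in% names(mixture)))
  if (any(mixture$weight < 0) || any(mixture$sd < 0)) {
    stop("weights and sds must be non-negative", call. = FALSE)
  }
  w <- mixture$weight / sum(mixture$weight)
  out <- numeric(length(grid))
  for (i in seq_along(w)) {
    out <- out + w[i] * if (mixture$sd[i] == 0) {
      as.numeric(grid >= mixture$mean[i])
    } else {
      stats::pnorm(grid, mixture$mean[i], mixture$sd[i])
    }
  }
  out
}

## quadrature grids over the two parameter supports:
## alpha - uniform over (0, 2); K - uniform in log10 over [1e-12, 1e6]
## (a linear grid over 18 decades resolves nothing near K ~ 1)
w1_grid <- function(support = c("alpha", "K"), n = NULL) {
  support <- match.arg(support)
  if (support == "alpha") {
    n <- n %||% 2001L
    list(x = seq(ALPHA_SUPPORT[1], ALPHA_SUPPORT[2], length.out = n))
  } else {
    n <- n %||% 6001L
    y <- seq(log10(K_SUPPORT[1]), log10(K_SUPPORT[2]), length.out = n)
    list(x = 10^y)
  }
}

#' First Wasserstein distance between two mixture distributions
#'
#' `W1(P, Q) = integral over supp(Q) of |CDF_P(x) - CDF_Q(x)| dx`, by
#' trapezoidal quadrature: a uniform grid on (0, 2) for `alpha`, and a
#' log10-spaced grid over `[1e-12, 1e6]` for `K` (integrated in the linear
#' variable).
#'
#' @param P,Q mixtures (tibbles with `weight`, `mean`, `sd`); `Q` is the
#'   ground truth whose support defines the integration domain.
#' @param support `"alpha"` or `"K"` — selects the default grid; or pass
#'   `grid` directly.
#' @param grid optional increasing numeric vector of quadrature nodes.
#' @return non-negative W1 distance, in the units of the parameter.
#' @examples
#' P <- tibble::tibble(weight = 1, mean = 1, sd = 0)
#' Q <- tibble::tibble(weight = 1, mean = 1.5, sd = 0)
#' wasserstein1(P, Q, "alpha") # 0.5
#' @export
wasserstein1 <- function(P, Q, support = c("alpha", "K"), grid = NULL) {
  x <- grid %||% w1_grid(match.arg(support))$x
  # point-mass components make the CDF difference piecewise constant; adding
  # nodes at each step renders the trapezoidal rule exact there
  steps <- c(P$mean[P$sd == 0], Q$mean[Q$sd == 0])
  steps <- steps[steps > min(x) & steps < max(x)]
  if (length(steps) > 0) {
    eps <- max(abs(x)) * 1e-12
    x <- sort(unique(c(x, steps, steps - eps)))
  }
  f <- abs(mixture_cdf(P, x) - mixture_cdf(Q, x))
  sum(diff(x) * (utils::head(f, -1) + utils::tail(f, -1)) / 2)
}

#' Score a model-label prediction
#'
#' @param pred,truth model labels in `c("ssm","msm","dim","tcm","qtm")`.
#' @return 1 if correct, 0 if wrong.
#' @export
score_model <- function(pred, truth) {
  labs <- tolower(c(pred, truth))
  if (!all(labs %in% MODELS)) {
    stop("unknown model label: ", paste(setdiff(labs, MODELS), collapse = ", "),
      call. = FALSE
    )
  }
  as.numeric(tolower(pred) == tolower(truth))
}

#' Absolute error of the predicted number of states
#'
#' @param pred_S,true_S state counts (`>= 1`).
#' @return `|pred_S - true_S|`.
#' @export
state_count_error <- function(pred_S, true_S) {
  if (min(pred_S, true_S) < 1) stop("state counts must be >= 1", call. = FALSE)
  abs(pred_S - true_S)
}

#' Score an ensemble prediction against the ground truth
#'
#' @param pred list with `model` and `states` (tibble `weight`, `mean_K`,
#'   `sd_K`, `mean_alpha`, `sd_alpha`), as read by [read_predictions()].
#' @param truth ground-truth summary from [ensemble_truth()].
#' @return one-row tibble: `model_correct`, `state_count_err`, `w1_K`,
#'   `w1_alpha`.
#' @export
score_ensemble <- function(pred, truth) {
  mix <- function(states, par) {
    tibble::tibble(
      weight = states$weight,
      mean = states[[paste0("mean_", par)]],
      sd = states[[paste0("sd_", par)]]
    )
  }
  tibble::tibble(
    model_correct = score_model(pred$model, truth$model),
    state_count_err = state_count_error(
      nrow(pred$states), nrow(truth$states)
    ),
    w1_K = wasserstein1(mix(pred$states, "K"), mix(truth$states, "K"), "K"),
    w1_alpha = wasserstein1(
      mix(pred$states, "alpha"), mix(truth$states, "alpha"), "alpha"
    )
  )
}

#' Mean reciprocal rank of competing methods
#'
#' Ranks every method on each metric (ties share the average rank) and
#' averages the reciprocal ranks across metrics.
#'
#' @param scores tibble: one row per method, a `team` column plus one
#'   column per metric.
#' @param higher_better named logical vector over the metric columns:
#'   `TRUE` if larger values rank first (e.g. JSC, F1), `FALSE` for error
#'   metrics (RMSE, MSLE, MAE, W1).
#' @return tibble of class `"rank_table"`: `team`, one `rank_*` column per
#'   metric, `mrr`, and the final ordering by decreasing MRR.
#' @examples
#' s <- tibble::tibble(team = c("a", "b"), jsc = c(0.9, 0.5), rmse = c(1, 3))
#' mrr_rank(s, c(jsc = TRUE, rmse = FALSE))
#' @export
mrr_rank <- function(scores, higher_better) {
  metrics <- names(higher_better)
  stopifnot(all(metrics %in% names(scores)))
  ranks <- purrr::map_dfc(metrics, function(m) {
    v <- scores[[m]]
    r <- if (higher_better[[m]]) rank(-v) else rank(v)
    stats::setNames(tibble::tibble(r), paste0("rank_", m))
  })
  out <- dplyr::bind_cols(scores["team"], ranks)
  out$mrr <- rowMeans(1 / as.matrix(ranks))
  out <- dplyr::arrange(out, dplyr::desc(.data$mrr))
  class(out) <- c("rank_table", class(out))
  out
}

#' Mean reciprocal rank from a vector of ranks
#'
#' @param ranks positive ranks of one method across metrics.
#' @return `mean(1 / ranks)`, in (0, 1\].
#' @examples
#' mrr(c(1, 2, 4)) # 0.5833...
#' @export
mrr <- function(ranks) {
  if (any(ranks < 1)) stop("ranks must be >= 1", call. = FALSE)
  mean(1 / ranks)
}

#' Relative improvement of a metric between two conditions
#'
#' `(m_a - m_b) / m_b * 100` percent — e.g. the gain a method obtains on a
#' physically-triggered switching dataset relative to a purely temporal
#' one with identical diffusive parameters.
#'
#' @param m_a,m_b metric values; `m_b` must be nonzero.
#' @return percent change.
#' @export
relative_improvement <- function(m_a, m_b) {
  if (any(m_b == 0)) {
    stop("reference metric is zero; relative improvement undefined",
      call. = FALSE
    )
  }
  (m_a - m_b) / m_b * 100
}
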