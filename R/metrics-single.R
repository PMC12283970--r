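## Single-trajectory scoring: gated changepoint pairing (rectangular
## assignment / Hungarian), CP pairing and localization metrics, Jaccard
## similarity and RMSE over an experiment, temporal-Jaccard segment
## pairing, and per-segment parameter / type errors.

## Worst-case parameter errors used when a prediction is missing entirely:
## alpha support has width 2; the K support is [1e-12, 1e6] so the largest
## possible squared log-error is (log(1e6 + 1) - log(1 + 1e-12))^2.
WORST_MAE <- 2
WORST_MSLE <- log(K_SUPPORT[2] + 1)^2

#' Gated absolute distance between two changepoints
#'
#' @param t_gt,t_pred changepoint frames.
#' @param eps_cp gate: maximum penalty, frames (`> 0`).
#' @return `min(|t_gt - t_pred|, eps_cp)`.
#' @examples
#' gated_distance(5, 50, 10) # 10
#' @export
gated_distance <- function(t_gt, t_pred, eps_cp) {
  if (eps_cp <= 0) stop("eps_cp must be positive", call. = FALSE)
  pmin(abs(t_gt - t_pred), eps_cp)
}

## Minimum-cost rectangular assignment (Hungarian). Returns an integer
## vector over rows: the assigned column, or NA. Delegates to
## clue::solve_LSAP; deterministic for ties by the solver's construction.
solve_assignment <- function(cost, maximize = FALSE) {
  n <- nrow(cost)
  m <- ncol(cost)
  if (n == 0 || m == 0) {
    return(rep(NA_integer_, n))
  }
  if (maximize) cost <- max(cost) - cost
  transposed <- FALSE
  if (n > m) {
    cost <- t(cost)
    transposed <- TRUE
  }
  sol <- as.integer(clue::solve_LSAP(cost))
  if (transposed) {
    out <- rep(NA_integer_, n)
    out[sol] <- seq_along(sol)
    out
  } else {
    sol
  }
}

#' Pair ground-truth and predicted changepoints
#'
#' Solves the rectangular assignment problem minimizing the total gated
#' distance (Hungarian algorithm). Pairs at distance `< eps_cp` are true
#' positives; unmatched (or gate-saturated) predictions are false
#' positives and unmatched ground truths false negatives. The total
#' distance `d_cp` charges the full gate `eps_cp` for every unmatched
#' ground-truth changepoint.
#'
#' @param gt_cps,pred_cps sorted changepoint frames (either may be empty).
#' @param eps_cp gate, frames.
#' @return list of class `"cp_pairing"`: `pairs` (tibble `gt`, `pred`,
#'   `d`), `d_cp`, `d_cp_max` (`= length(gt_cps) * eps_cp`), `d_bar`
#'   (gate penalty accumulated by unassigned predictions), `TP`, `FP`,
#'   `FN`, `eps_cp`.
#' @export
pair_changepoints <- function(gt_cps, pred_cps, eps_cp = 10) {
  if (eps_cp <= 0) stop("eps_cp must be positive", call. = FALSE)
  gt_cps <- sort(as.numeric(gt_cps))
  pred_cps <- sort(as.numeric(pred_cps))
  M_gt <- length(gt_cps)
  M_p <- length(pred_cps)
  if (M_gt == 0 || M_p == 0) {
    pairs <- tibble::tibble(gt = numeric(0), pred = numeric(0), d = numeric(0))
    out <- list(
      pairs = pairs,
      d_cp = M_gt * eps_cp,
      d_cp_max = M_gt * eps_cp,
      d_bar = M_p * eps_cp,
      TP = 0L, FP = M_p, FN = M_gt,
      eps_cp = eps_cp
    )
    return(structure(out, class = "cp_pairing"))
  }
  cost <- outer(gt_cps, pred_cps, gated_distance, eps_cp = eps_cp)
  assn <- solve_assignment(cost)
  paired_gt <- which(!is.na(assn))
  pairs <- tibble::tibble(
    gt = gt_cps[paired_gt],
    pred = pred_cps[assn[paired_gt]],
    d = cost[cbind(paired_gt, assn[paired_gt])]
  )
  tp <- sum(pairs$d < eps_cp)
  unmatched_gt <- M_gt - nrow(pairs)
  unmatched_pred <- M_p - nrow(pairs)
  d_cp <- sum(pairs$d) + unmatched_gt * eps_cp
  structure(
    list(
      pairs = pairs,
      d_cp = d_cp,
      d_cp_max = M_gt * eps_cp,
      d_bar = unmatched_pred * eps_cp,
      TP = as.integer(tp),
      FP = as.integer(unmatched_pred + (nrow(pairs) - tp)),
      FN = as.integer(unmatched_gt + (nrow(pairs) - tp)),
      eps_cp = eps_cp
    ),
    class = "cp_pairing"
  )
}

#' Changepoint pairing metric
#'
#' `alpha_cp = 1 - d_cp / d_cp_max`, in \[0, 1\]; 1 when every ground-truth
#' changepoint is matched exactly. Undefined (NA) for trajectories without
#' ground-truth changepoints; such trajectories are excluded from
#' experiment averages.
#'
#' @param pairing a [pair_changepoints()] result.
#' @return numeric scalar in \[0, 1\], or NA when `d_cp_max = 0`.
#' @export
alpha_cp <- function(pairing) {
  if (pairing$d_cp_max == 0) {
    return(NA_real_)
  }
  1 - pairing$d_cp / pairing$d_cp_max
}

#' Changepoint localization metric
#'
#' `beta_cp = (d_cp_max - d_cp) / (d_cp_max + d_bar)`, in
#' \[0, alpha_cp\]; equals `alpha_cp` when no spurious predictions are
#' present.
#'
#' @inheritParams alpha_cp
#' @return numeric scalar, or NA when `d_cp_max = 0`.
#' @export
beta_cp <- function(pairing) {
  if (pairing$d_cp_max == 0) {
    return(NA_real_)
  }
  (pairing$d_cp_max - pairing$d_cp) / (pairing$d_cp_max + pairing$d_bar)
}

#' Jaccard similarity coefficient from detection counts
#'
#' `TP / (TP + FN + FP)`; the empty case (no changepoints exist and none
#' were predicted) scores 1 by convention.
#'
#' @param TP,FP,FN non-negative counts, aggregated experiment-wide.
#' @return numeric in \[0, 1\].
#' @export
jsc_cp <- function(TP, FP, FN) {
  if (min(TP, FP, FN) < 0) stop("counts must be non-negative", call. = FALSE)
  if (TP + FP + FN == 0) {
    return(1)
  }
  TP / (TP + FN + FP)
}

#' RMSE of true-positive changepoint pairs
#'
#' Root mean square of the (ungated) frame differences over all TP pairs
#' pooled across an experiment. With zero TP pairs the worst-value
#' sentinel `eps_cp` is returned — except in the fully empty case (no
#' changepoints existed and none were predicted), which scores a perfect
#' 0.
#'
#' @param pairings list of [pair_changepoints()] results (or a single one).
#' @param eps_cp gate used, frames (sentinel value).
#' @return RMSE in frames.
#' @export
rmse_cp <- function(pairings, eps_cp = 10) {
  if (inherits(pairings, "cp_pairing")) pairings <- list(pairings)
  diffs <- unlist(lapply(pairings, function(p) {
    d <- p$pairs
    (d$gt - d$pred)[d$d < p$eps_cp]
  }))
  if (length(diffs) == 0) {
    contested <- sum(vapply(
      pairings, function(p) p$TP + p$FP + p$FN, numeric(1)
    ))
    return(if (contested == 0) 0 else eps_cp)
  }
  sqrt(mean(diffs^2))
}

## temporal Jaccard of two inclusive frame intervals
interval_jaccard <- function(s1, e1, s2, e2) {
  inter <- pmax(0, pmin(e1, e2) - pmax(s1, s2) + 1)
  union <- (e1 - s1 + 1) + (e2 - s2 + 1) - inter
  inter / union
}

#' Pair ground-truth and predicted segments of one trajectory
#'
#' One-to-one assignment maximizing the summed temporal Jaccard index
#' (overlap/union of the frame supports), via the Hungarian algorithm.
#'
#' @param gt_segments,pred_segments tibbles with columns `start`, `end`
#'   (inclusive frames) and optionally `K`, `alpha`, `type`.
#' @return tibble of class `"segment_pairing"`: one row per pair with the
#'   temporal `jaccard` and both sides' parameters (suffixes `_gt`,
#'   `_pred`), plus attributes `n_gt_unpaired`, `n_pred_unpaired` and the
#'   unpaired rows themselves.
#' @export
pair_segments <- function(gt_segments, pred_segments) {
  n_gt <- nrow(gt_segments)
  n_p <- nrow(pred_segments)
  if (n_gt == 0 || n_p == 0) {
    out <- tibble::tibble(
      gt = integer(0), pred = integer(0), jaccard = numeric(0)
    )
    attr(out, "gt_unpaired") <- gt_segments
    attr(out, "pred_unpaired") <- pred_segments
    return(out)
  }
  jac <- outer(seq_len(n_gt), seq_len(n_p), function(i, j) {
    interval_jaccard(
      gt_segments$start[i], gt_segments$end[i],
      pred_segments$start[j], pred_segments$end[j]
    )
  })
  assn <- solve_assignment(jac, maximize = TRUE)
  paired_gt <- which(!is.na(assn))
  out <- tibble::tibble(
    gt = paired_gt,
    pred = assn[paired_gt],
    jaccard = jac[cbind(paired_gt, assn[paired_gt])]
  )
  for (col in intersect(c("K", "alpha", "type"), names(gt_segments))) {
    out[[paste0(col, "_gt")]] <- gt_segments[[col]][out$gt]
  }
  for (col in intersect(c("K", "alpha", "type"), names(pred_segments))) {
    out[[paste0(col, "_pred")]] <- pred_segments[[col]][out$pred]
  }
  attr(out, "gt_unpaired") <- gt_segments[setdiff(seq_len(n_gt), out$gt), ]
  attr(out, "pred_unpaired") <- pred_segments[setdiff(seq_len(n_p), out$pred), ]
  out
}

#' Mean squared logarithmic error of K over paired segments
#'
#' `mean((log(K_gt + 1) - log(K_pred + 1))^2)` (natural log) over all
#' paired segments of an experiment.
#'
#' @param paired tibble from [pair_segments()] (with `K_gt`, `K_pred`), or
#'   a list of them; rows are pooled.
#' @return MSLE (`NA` if there are no paired segments).
#' @export
msle_K <- function(paired) {
  if (is.data.frame(paired)) paired <- list(paired)
  d <- dplyr::bind_rows(lapply(paired, function(p) {
    p[, c("K_gt", "K_pred")]
  }))
  if (nrow(d) == 0) {
    return(NA_real_)
  }
  if (any(d$K_gt < 0 | d$K_pred < 0)) {
    stop("K must be non-negative", call. = FALSE)
  }
  mean((log(d$K_gt + 1) - log(d$K_pred + 1))^2)
}

#' Mean absolute error of alpha over paired segments
#'
#' @param paired tibble(s) from [pair_segments()] with `alpha_gt`,
#'   `alpha_pred`; rows are pooled.
#' @return MAE (`NA` if there are no paired segments).
#' @export
mae_alpha <- function(paired) {
  if (is.data.frame(paired)) paired <- list(paired)
  d <- dplyr::bind_rows(lapply(paired, function(p) {
    p[, c("alpha_gt", "alpha_pred")]
  }))
  if (nrow(d) == 0) {
    return(NA_real_)
  }
  mean(abs(d$alpha_gt - d$alpha_pred))
}

#' Micro-averaged F1 of diffusion-type classification
#'
#' Paired segments are compared label-to-label; unpaired ground-truth
#' segments count as false negatives of their class and unpaired predicted
#' segments as false positives of theirs. Micro-averaging pools the
#' per-class counts: `F1 = 2 TP / (2 TP + FP + FN)`.
#'
#' @param paired tibble(s) from [pair_segments()] with `type_gt`,
#'   `type_pred` (attributes carry the unpaired rows).
#' @return F1 in \[0, 1\] (1 when there are no segments at all).
#' @export
f1_type <- function(paired) {
  if (is.data.frame(paired)) paired <- list(paired)
  tp <- 0
  fp <- 0
  fn <- 0
  for (p in paired) {
    if (nrow(p) > 0) {
      hit <- p$type_gt == p$type_pred
      tp <- tp + sum(hit)
      fp <- fp + sum(!hit)
      fn <- fn + sum(!hit)
    }
    gu <- attr(p, "gt_unpaired")
    pu <- attr(p, "pred_unpaired")
    if (!is.null(gu)) fn <- fn + nrow(gu)
    if (!is.null(pu)) fp <- fp + nrow(pu)
  }
  if (tp + fp + fn == 0) {
    return(1)
  }
  2 * tp / (2 * tp + fp + fn)
}

#' Score single-trajectory predictions against ground truth
#'
#' Experiment-level evaluation: changepoints are paired per trajectory
#' with the gated Hungarian assignment, segments by temporal Jaccard, and
#' all metrics aggregated experiment-wide — `alpha_cp` /
#' `beta_cp` averaged over trajectories that have ground-truth
#' changepoints, `JSC` and `RMSE` from pooled TP/FP/FN counts and TP
#' pairs, `MSLE`/`MAE`/`F1` over pooled paired segments. Trajectories
#' missing from the prediction table are scored with the worst value of
#' every metric.
#'
#' @param gt_segments ground-truth segment table ([derive_segments()]).
#' @param pred_segments predicted segment table, same columns (`traj`,
#'   `segment`, `start`, `end`, `K`, `alpha`, `type`).
#' @param eps_cp changepoint gate, frames (default 10).
#' @return one-row tibble: `alpha_cp`, `beta_cp`, `jsc`, `rmse`, `msle`,
#'   `mae`, `f1`, `TP`, `FP`, `FN`, `n_traj`, `n_missing`, `eps_cp`.
#' @export
score_trajectories <- function(gt_segments, pred_segments, eps_cp = 10) {
  gt_by <- split(gt_segments, gt_segments$traj)
  pred_by <- split(pred_segments, pred_segments$traj)
  a_vals <- c()
  b_vals <- c()
  TP <- 0L
  FP <- 0L
  FN <- 0L
  pairings <- list()
  seg_pairs <- list()
  n_missing <- 0L
  worst_msle_terms <- c()
  worst_mae_terms <- c()
  for (id in names(gt_by)) {
    g <- dplyr::arrange(gt_by[[id]], .data$segment)
    g_cps <- g$start[-1]
    p <- pred_by[[id]]
    if (is.null(p) || nrow(p) == 0) {
      n_missing <- n_missing + 1L
      # worst-value sentinels for a fully missing trajectory
      if (length(g_cps) > 0) {
        a_vals <- c(a_vals, 0)
        b_vals <- c(b_vals, 0)
      }
      FN <- FN + length(g_cps)
      worst_msle_terms <- c(worst_msle_terms, rep(WORST_MSLE, nrow(g)))
      worst_mae_terms <- c(worst_mae_terms, rep(WORST_MAE, nrow(g)))
      empty <- tibble::tibble(
        gt = integer(0), pred = integer(0), jaccard = numeric(0)
      )
      attr(empty, "gt_unpaired") <- g
      attr(empty, "pred_unpaired") <- g[0, ]
      seg_pairs <- c(seg_pairs, list(empty))
      next
    }
    p <- dplyr::arrange(p, .data$segment)
    p_cps <- p$start[-1]
    cp <- pair_changepoints(g_cps, p_cps, eps_cp)
    pairings <- c(pairings, list(cp))
    TP <- TP + cp$TP
    FP <- FP + cp$FP
    FN <- FN + cp$FN
    if (length(g_cps) > 0) {
      a_vals <- c(a_vals, alpha_cp(cp))
      b_vals <- c(b_vals, beta_cp(cp))
    }
    seg_pairs <- c(seg_pairs, list(pair_segments(g, p)))
  }
  msle <- {
    base <- dplyr::bind_rows(lapply(seg_pairs, function(p) {
      if (nrow(p) > 0) p[, c("K_gt", "K_pred")] else NULL
    }))
    terms <- c(
      if (nrow(base) > 0) (log(base$K_gt + 1) - log(base$K_pred + 1))^2,
      worst_msle_terms
    )
    if (length(terms) == 0) NA_real_ else mean(terms)
  }
  mae <- {
    base <- dplyr::bind_rows(lapply(seg_pairs, function(p) {
      if (nrow(p) > 0) p[, c("alpha_gt", "alpha_pred")] else NULL
    }))
    terms <- c(
      if (nrow(base) > 0) abs(base$alpha_gt - base$alpha_pred),
      worst_mae_terms
    )
    if (length(terms) == 0) NA_real_ else mean(terms)
  }
  tibble::tibble(
    alpha_cp = if (length(a_vals)) mean(a_vals) else NA_real_,
    beta_cp = if (length(b_vals)) mean(b_vals) else NA_real_,
    jsc = jsc_cp(TP, FP, FN),
    rmse = {
      r <- rmse_cp(pairings, eps_cp)
      # sentinel when CPs were contested anywhere (incl. missing trajectories)
      if (r == 0 && sum(vapply(pairings, function(p) p$TP, numeric(1))) == 0 &&
        TP + FP + FN > 0) {
        eps_cp
      } else {
        r
      }
    },
    msle = msle,
    mae = mae,
    f1 = f1_type(seg_pairs),
    TP = TP, FP = FP, FN = FN,
    n_traj = length(gt_by),
    n_missing = n_missing,
    eps_cp = eps_cp
  )
}
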