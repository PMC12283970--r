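test_that("gated distance saturates at the gate", {
  expect_equal(gated_distance(5, 7, 10), 2)
  expect_equal(gated_distance(5, 50, 10), 10)
  expect_equal(gated_distance(9, 9, 10), 0)
  expect_error(gated_distance(1, 2, 0), "positive")
})

test_that("changepoint pairing matches hand-worked cases", {
  p <- pair_changepoints(10, 12, eps_cp = 10)
  expect_equal(p$d_cp, 2)
  expect_equal(p$TP, 1L)
  expect_equal(p$FP, 0L)
  expect_equal(p$FN, 0L)
  # optimal pairing over the two possible assignments
  p2 <- pair_changepoints(c(10, 20), c(11, 19), eps_cp = 10)
  expect_equal(p2$d_cp, 2)
  expect_equal(alpha_cp(p2), 0.9)
  # empty prediction: all ground truths unpaired at full gate penalty
  p3 <- pair_changepoints(10, numeric(0), eps_cp = 10)
  expect_equal(p3$d_cp, p3$d_cp_max)
  expect_equal(p3$TP, 0L)
  expect_equal(p3$FN, 1L)
  expect_equal(alpha_cp(p3), 0)
})

test_that("alpha_cp and beta_cp behave at their fixed points", {
  perfect <- pair_changepoints(c(40, 120), c(40, 120), eps_cp = 10)
  expect_equal(alpha_cp(perfect), 1)
  expect_equal(beta_cp(perfect), 1)
  # one exact pair plus one spurious prediction at gate penalty
  sp <- pair_changepoints(10, c(10, 90), eps_cp = 10)
  expect_equal(alpha_cp(sp), 1)
  expect_equal(beta_cp(sp), 0.5)
  # no ground-truth changepoints: metrics undefined
  none <- pair_changepoints(numeric(0), numeric(0), eps_cp = 10)
  expect_true(is.na(alpha_cp(none)))
  expect_true(is.na(beta_cp(none)))
})

test_that("experiment-wide JSC and RMSE follow their definitions", {
  expect_equal(jsc_cp(3, 1, 1), 0.6)
  expect_equal(jsc_cp(0, 0, 0), 1)
  expect_equal(jsc_cp(0, 5, 0), 0)
  expect_error(jsc_cp(-1, 0, 0), "non-negative")
  p <- pair_changepoints(c(10, 20), c(11, 22), eps_cp = 10)
  expect_equal(rmse_cp(p), sqrt(mean(c(1, 4))))
  exact <- pair_changepoints(c(10, 20), c(10, 20), eps_cp = 10)
  expect_equal(rmse_cp(exact), 0)
  single <- pair_changepoints(50, 53, eps_cp = 10)
  expect_equal(rmse_cp(single), 3)
  # zero TP with contested changepoints: worst-value sentinel
  expect_equal(rmse_cp(pair_changepoints(10, numeric(0), 10), eps_cp = 10), 10)
  # fully empty case is perfect, not worst
  expect_equal(rmse_cp(pair_changepoints(numeric(0), numeric(0), 10), 10), 0)
})

test_that("assignment equals the exhaustive-search optimum (randomized)", {
  set.seed(123)
  for (i in 1:300) {
    n_gt <- sample(0:4, 1)
    n_p <- sample(0:4, 1)
    gt <- sort(sample(0:199, n_gt))
    pr <- sort(sample(0:199, n_p))
    eps <- sample(c(5, 10, 20), 1)
    p <- pair_changepoints(gt, pr, eps)
    cost <- if (n_gt > 0 && n_p > 0) {
      outer(gt, pr, gated_distance, eps_cp = eps)
    } else {
      matrix(0, n_gt, n_p)
    }
    brute <- brute_assignment_cost(cost) +
      max(n_gt - n_p, 0) * eps # unmatched ground truths
    expect_equal(p$d_cp, brute)
  }
})

test_that("segment pairing maximizes the temporal Jaccard sum", {
  gt <- tibble::tibble(
    start = c(0, 100), end = c(99, 199),
    K = c(1, 2), alpha = c(1, 0.5), type = c(2L, 2L)
  )
  same <- pair_segments(gt, gt)
  expect_true(all(same$jaccard == 1))
  pr <- tibble::tibble(
    start = c(0, 90), end = c(89, 199),
    K = c(1, 2), alpha = c(1, 0.5), type = c(2L, 2L)
  )
  sp <- pair_segments(gt, pr)
  # order-preserving optimum: overlaps 90/100 and 100/110
  expect_equal(sort(sp$jaccard), sort(c(0.9, 100 / 110)))
  expect_equal(sp$pred[sp$gt == 1], 1)
  # rectangular case: one prediction against two ground truths
  one <- pair_segments(gt, pr[2, ])
  expect_equal(nrow(one), 1)
  expect_equal(nrow(attr(one, "gt_unpaired")), 1)
})

test_that("parameter errors over paired segments follow their formulas", {
  mk <- function(K_gt, K_pred, a_gt, a_pred) {
    tibble::tibble(
      gt = seq_along(K_gt), pred = seq_along(K_gt), jaccard = 1,
      K_gt = K_gt, K_pred = K_pred,
      alpha_gt = a_gt, alpha_pred = a_pred,
      type_gt = 2L, type_pred = 2L
    )
  }
  expect_equal(msle_K(mk(1, 1, 1, 1)), 0)
  expect_equal(msle_K(mk(exp(1) - 1, 0, 1, 1)), 1) # natural log
  expect_equal(msle_K(mk(0, 0, 1, 1)), 0)
  expect_equal(mae_alpha(mk(1, 1, c(1, 1), c(1.1, 0.7))), 0.2)
  expect_equal(mae_alpha(mk(1, 1, 1, 1)), 0)
  # all predictions fixed at 1 against uniform truths: E|U - 1| = 0.5
  set.seed(99)
  u <- stats::runif(2e4, 0, 2)
  expect_lt(abs(mae_alpha(mk(1, 1, u, rep(1, 2e4))) - 0.5), 0.02)
})

test_that("micro-averaged F1 equals accuracy for fully paired single labels", {
  mk_types <- function(true_types, pred_types) {
    p <- tibble::tibble(
      gt = seq_along(true_types), pred = seq_along(true_types), jaccard = 1,
      K_gt = 1, K_pred = 1, alpha_gt = 1, alpha_pred = 1,
      type_gt = true_types, type_pred = pred_types
    )
    attr(p, "gt_unpaired") <- p[0, ]
    attr(p, "pred_unpaired") <- p[0, ]
    p
  }
  expect_equal(f1_type(mk_types(c(0, 1, 2, 3), c(0, 1, 2, 3))), 1)
  expect_equal(f1_type(mk_types(rep(2L, 10), c(rep(2L, 8), 0L, 3L))), 0.8)
  expect_equal(f1_type(mk_types(c(0, 1), c(1, 0))), 0)
})

test_that("metric bounds hold on randomized prediction sets", {
  set.seed(7)
  for (i in 1:100) {
    gt <- sort(sample(1:198, sample(1:4, 1)))
    pr <- sort(sample(1:198, sample(0:5, 1)))
    p <- pair_changepoints(gt, pr, 10)
    a <- alpha_cp(p)
    b <- beta_cp(p)
    expect_gte(a, 0)
    expect_lte(a, 1)
    expect_gte(b, 0)
    expect_lte(b, a + 1e-12)
    j <- jsc_cp(p$TP, p$FP, p$FN)
    expect_gte(j, 0)
    expect_lte(j, 1)
  }
})

test_that("jittering predictions degrades alpha_cp on average", {
  set.seed(8)
  gt <- c(50, 100, 150)
  a_at_noise <- vapply(c(0, 3, 8), function(s) {
    mean(vapply(1:200, function(i) {
      alpha_cp(pair_changepoints(gt, gt + round(stats::rnorm(3, 0, s)), 10))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(a_at_noise) < 0))
})

test_that("scoring a ground-truth prediction is a perfect fixed point", {
  e <- simulate_experiment(tiny_config("msm"))
  segs <- derive_segments(crop_to_fov(e))
  sc <- score_trajectories(segs, segs, eps_cp = 10)
  expect_equal(sc$jsc, 1)
  expect_equal(sc$rmse, 0)
  expect_equal(sc$msle, 0)
  expect_equal(sc$mae, 0)
  expect_equal(sc$f1, 1)
  if (!is.na(sc$alpha_cp)) {
    expect_equal(sc$alpha_cp, 1)
    expect_equal(sc$beta_cp, 1)
  }
})

test_that("missing trajectory predictions score at the worst values", {
  gt <- tibble::tibble(
    traj = c(1L, 1L, 2L),
    segment = c(1L, 2L, 1L),
    start = c(0, 100, 0), end = c(99, 199, 199),
    K = c(1, 2, 1), alpha = c(1, 0.5, 1), type = c(2L, 2L, 2L)
  )
  pred <- gt[3, ] # trajectory 1 entirely missing
  sc <- score_trajectories(gt, pred, eps_cp = 10)
  expect_equal(sc$n_missing, 1L)
  expect_equal(sc$alpha_cp, 0)
  expect_equal(sc$beta_cp, 0)
  expect_equal(sc$FN, 1L)
  expect_equal(sc$rmse, 10) # sentinel: no TP but contested CPs
  expect_gt(sc$msle, 10) # worst-K contribution dominates
  expect_equal(sc$mae, (2 + 2 + 0) / 3)
  expect_lt(sc$f1, 1)
})
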