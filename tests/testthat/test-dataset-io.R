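test_that("localization noise has the configured SD and independent axes", {
  tr <- tibble::tibble(x = rep(0, 1e5), y = rep(0, 1e5))
  noisy <- add_localization_noise(tr, 0.5, seed = 1)
  expect_lt(abs(stats::sd(noisy$x) - 0.5), 0.01)
  expect_lt(abs(stats::sd(noisy$y) - 0.5), 0.01)
  expect_lt(abs(stats::cor(noisy$x, noisy$y)), 0.01)
  expect_identical(add_localization_noise(tr, 0), tr)
  expect_error(add_localization_noise(tr, -1), "non-negative")
})

test_that("trajectory CSVs round-trip at the declared precision", {
  tr <- tibble::tibble(
    traj = rep(1:2, each = 30), frame = rep(0:29, 2),
    x = stats::runif(60, 0, 128), y = stats::runif(60, 0, 128)
  )
  f <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_table(tr, f)
  back <- read_trajectory_table(f)
  expect_equal(back$traj, tr$traj)
  expect_equal(back$frame, tr$frame)
  expect_equal(back$x, round(tr$x, 3))
  # gap detection
  bad <- tr[-5, ]
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_table(bad, f2)
  expect_error(read_trajectory_table(f2), "gap-free")
})

test_that("TIFF videos and label maps round-trip losslessly", {
  frames <- lapply(1:5, function(i) {
    m <- matrix(sample(0:255, 64 * 64, replace = TRUE), 64, 64)
    storage.mode(m) <- "integer"
    m
  })
  f <- withr::local_tempfile(fileext = ".tiff")
  fbmbench:::write_video_tiff(frames, f)
  back <- fbmbench:::read_video_tiff(f)
  expect_length(back, 5)
  expect_true(all(mapply(function(a, b) all(a == b), frames, back)))
  lab <- matrix(0L, 64, 64)
  lab[10:14, 20:24] <- 7L
  lab[40:44, 50:54] <- 301L # beyond 8-bit range
  f2 <- withr::local_tempfile(fileext = ".tiff")
  fbmbench:::write_label_tiff(lab, f2)
  expect_identical(fbmbench:::read_label_tiff(f2), lab)
})

test_that("challenge dataset layout is complete and reproducible", {
  root <- withr::local_tempdir()
  cfgs <- list(
    EXP_1 = experiment_config("ssm", N = 10),
    EXP_2 = experiment_config("msm", N = 10)
  )
  write_challenge_dataset(cfgs, root, n_fov = 3, seed = 5)
  lay <- check_layout(root, n_fov = 3)
  expect_equal(nrow(lay), 2)
  expect_true(all(lay$complete))
  # manifest records per-FOV seeds
  man <- jsonlite::read_json(file.path(root, "manifest.json"), simplifyVector = TRUE)
  expect_equal(length(man$experiments$EXP_1$fov_seeds), 3)
  # identical seed regenerates identical files
  root2 <- withr::local_tempdir()
  write_challenge_dataset(cfgs, root2, n_fov = 3, seed = 5)
  f1 <- file.path(root, "track_2", "EXP_1", "FOV_2.csv")
  f2 <- file.path(root2, "track_2", "EXP_1", "FOV_2.csv")
  expect_identical(readLines(f1), readLines(f2))
  # trajectory lengths within [T_min, T_total]
  d <- read_trajectory_table(f1, T_min = 20, T_total = 200)
  lens <- table(d$traj)
  expect_true(all(lens >= 20 & lens <= 200))
})

test_that("prediction files validate schema, tiling and weights", {
  seg <- tibble::tibble(
    traj = c(1L, 1L), segment = c(1L, 2L),
    start = c(0, 100), end = c(99, 199),
    K = c(1, 2), alpha = c(1, 0.5), type = c(2L, 2L)
  )
  f <- withr::local_tempfile(fileext = ".csv")
  write_predictions(seg, f, "single")
  back <- read_predictions(f, "single")
  expect_equal(back$start, seg$start)
  # non-tiling segments (gap) rejected
  bad <- seg
  bad$start[2] <- 120
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_predictions(bad, f2, "single")
  expect_error(read_predictions(f2, "single"), "non-tiling")
  # ensemble: weights renormalized with a warning
  ens <- list(model = "msm", states = tibble::tibble(
    state = 1:2, weight = c(0.5, 0.3),
    mean_K = c(0.1, 1), sd_K = c(0, 0.1),
    mean_alpha = c(0.8, 1.2), sd_alpha = c(0.05, 0.05)
  ))
  f3 <- withr::local_tempfile(fileext = ".json")
  write_predictions(ens, f3, "ensemble")
  expect_warning(got <- read_predictions(f3, "ensemble"), "renormalizing")
  expect_equal(sum(got$states$weight), 1)
  f4 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(model = "unknown"), f4, auto_unbox = TRUE)
  expect_error(read_predictions(f4, "ensemble"), "model label")
})

test_that("scoring handles missing prediction files at worst value", {
  root <- withr::local_tempdir()
  write_challenge_dataset(
    list(EXP_1 = experiment_config("msm", N = 10)),
    root,
    n_fov = 1, seed = 6
  )
  empty_pred <- withr::local_tempdir()
  sc <- score_dataset(root, empty_pred, task = "single")
  expect_equal(sc$jsc, 0)
  expect_equal(sc$alpha_cp, 0)
  expect_equal(sc$rmse, 10)
})
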