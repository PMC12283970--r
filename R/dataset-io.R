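## Challenge-layout dataset I/O.
##
## On disk a dataset root contains one folder per experiment (EXP_1,
## EXP_2, ...) under track_2/ (trajectory CSVs) and optionally track_1/
## (8-bit multi-frame TIFF videos + VIP label maps), a ground_truth/
## sidecar tree (true coordinates, segment tables, ensemble summaries)
## that mirrors the blind-challenge separation, and a manifest.json
## recording every derived seed so identical manifests reproduce
## bit-identical datasets.

#' Add Gaussian localization noise to reported coordinates
#'
#' I.i.d. zero-mean Gaussian offsets with SD `sigma_N` per coordinate —
#' the finite localization precision of a tracking experiment. Ground
#' truth is left untouched; only the returned copy is corrupted.
#'
#' @param traj tibble with columns `x`, `y`.
#' @param sigma_N noise SD, pixels (`>= 0`).
#' @param seed optional integer seed.
#' @return the tibble with noisy `x`, `y`.
#' @export
add_localization_noise <- function(traj, sigma_N, seed = NULL) {
  if (sigma_N < 0) stop("sigma_N must be non-negative", call. = FALSE)
  if (sigma_N == 0) {
    return(traj)
  }
  with_seed(seed, {
    traj$x <- traj$x + stats::rnorm(nrow(traj), 0, sigma_N)
    traj$y <- traj$y + stats::rnorm(nrow(traj), 0, sigma_N)
    traj
  })
}

## ---- TIFF helpers (8-bit multi-frame videos, 16-bit label maps) ----

write_video_tiff <- function(frames, path) {
  # frames: list of integer matrices in [0, 255]
  tiff::writeTIFF(
    lapply(frames, function(f) f / 255),
    path,
    bits.per.sample = 8L, compression = "none"
  )
  invisible(path)
}

read_video_tiff <- function(path) {
  imgs <- tiff::readTIFF(path, all = TRUE)
  lapply(imgs, function(m) {
    out <- round(m * 255)
    storage.mode(out) <- "integer"
    out
  })
}

write_label_tiff <- function(label, path) {
  tiff::writeTIFF(label / 65535, path, bits.per.sample = 16L,
    compression = "none"
  )
  invisible(path)
}

read_label_tiff <- function(path) {
  out <- round(tiff::readTIFF(path) * 65535)
  storage.mode(out) <- "integer"
  out
}

#' Write a trajectory table in the challenge CSV schema
#'
#' Columns `traj`, `frame`, `x`, `y`; coordinates at 3-decimal precision
#' (sub-pixel), 0-based frame indices.
#'
#' @param traj trajectory tibble.
#' @param path output CSV path.
#' @export
write_trajectory_table <- function(traj, path) {
  out <- data.frame(
    traj = traj$traj,
    frame = traj$frame,
    x = round(traj$x, 3),
    y = round(traj$y, 3)
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a challenge trajectory CSV
#'
#' Validates the invariants of the layout: within each trajectory, frames
#' strictly increasing and gap-free, and lengths within
#' `[T_min, T_total]` when those are supplied.
#'
#' @param path CSV path.
#' @param T_min,T_total optional length bounds to enforce.
#' @return tibble with columns `traj`, `frame`, `x`, `y`.
#' @export
read_trajectory_table <- function(path, T_min = NULL, T_total = NULL) {
  d <- tibble::as_tibble(utils::read.csv(path))
  stopifnot(all(c("traj", "frame", "x", "y") %in% names(d)))
  chk <- d |>
    dplyr::group_by(.data$traj) |>
    dplyr::summarise(
      gapfree = all(diff(.data$frame) == 1),
      len = dplyr::n(),
      .groups = "drop"
    )
  if (!all(chk$gapfree)) {
    stop("trajectory frames must be strictly increasing and gap-free",
      call. = FALSE
    )
  }
  if (!is.null(T_min) && any(chk$len < T_min)) {
    stop("trajectory shorter than T_min found", call. = FALSE)
  }
  if (!is.null(T_total) && any(chk$len > T_total)) {
    stop("trajectory longer than T_total found", call. = FALSE)
  }
  d
}

## segment tables round-trip as plain CSV
write_segment_table <- function(segments, path) {
  utils::write.csv(
    as.data.frame(segments)[
      , c("traj", "segment", "start", "end", "K", "alpha", "type")
    ],
    path,
    row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Write one experiment's worth of FOVs plus ground truth
#'
#' Simulates `n_fov` fields of view from one configuration (a fresh child
#' seed per FOV), writes the public trajectory CSVs (with localization
#' noise) and optional videos, and the hidden ground-truth sidecars.
#'
#' @param config an [experiment_config()].
#' @param exp_dir,gt_dir target directories for the public files and the
#'   ground-truth sidecars.
#' @param n_fov number of fields of view (challenge layout: 30).
#' @param tracks subset of `c("trajectory", "video")`.
#' @param img_config an [imaging_config()] (video track).
#' @param seed root seed for this experiment.
#' @return (invisibly) tibble manifest of per-FOV seeds.
#' @keywords internal
write_experiment <- function(config, exp_dir, gt_dir, n_fov = 30,
                             tracks = "trajectory",
                             img_config = imaging_config(), seed = 1) {
  dir.create(exp_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(gt_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- purrr::map(seq_len(n_fov), function(fov) {
    fov_seed <- derive_seed(seed, fov)
    cfg <- config
    cfg$seed <- fov_seed
    exper <- simulate_experiment(cfg)
    cropped <- crop_to_fov(exper)
    segs <- derive_segments(cropped)
    # public trajectory table: localization noise, ground truth untouched
    noisy <- add_localization_noise(
      cropped, config$sigma_N,
      seed = derive_seed(fov_seed, 1L)
    )
    if ("trajectory" %in% tracks) {
      write_trajectory_table(noisy, file.path(exp_dir, sprintf("FOV_%d.csv", fov)))
    }
    if ("video" %in% tracks) {
      vid <- render_video(
        cropped, img_config,
        seed = derive_seed(fov_seed, 2L)
      )
      write_video_tiff(
        vid$frames, file.path(exp_dir, sprintf("FOV_%d.tiff", fov))
      )
      write_label_tiff(
        vid$vip_map, file.path(exp_dir, sprintf("FOV_%d_vip.tiff", fov))
      )
    }
    # hidden sidecars: true coordinates + per-frame labels, segments
    utils::write.csv(
      as.data.frame(cropped),
      file.path(gt_dir, sprintf("FOV_%d_traj.csv", fov)),
      row.names = FALSE, quote = FALSE
    )
    write_segment_table(
      segs, file.path(gt_dir, sprintf("FOV_%d_segments.csv", fov))
    )
    tibble::tibble(fov = fov, seed = fov_seed, n_traj = length(unique(cropped$traj)))
  })
  # experiment-level ensemble ground truth (pooled over FOVs via weights
  # recomputed from the first FOV's realization and the config's moments)
  cfg1 <- config
  cfg1$seed <- derive_seed(seed, 1L)
  exper <- simulate_experiment(cfg1)
  truth <- ensemble_truth(exper)
  jsonlite::write_json(
    list(model = truth$model, states = truth$states),
    file.path(gt_dir, "ensemble.json"),
    dataframe = "columns", auto_unbox = TRUE, digits = NA
  )
  invisible(dplyr::bind_rows(rows))
}

#' Write a full challenge-style dataset
#'
#' One folder per experiment under `track_2/` (trajectory CSVs) and
#' optionally `track_1/` (videos + VIP maps), a `ground_truth/` sidecar
#' tree, and a `manifest.json` with every derived seed.
#'
#' @param configs named list of [experiment_config()] objects; names
#'   become folder names (unnamed lists get `EXP_1`, `EXP_2`, ...).
#' @param root output directory.
#' @param n_fov fields of view per experiment (default 30).
#' @param tracks subset of `c("trajectory", "video")`.
#' @param img_config an [imaging_config()] for the video track.
#' @param seed root seed.
#' @return the root path, invisibly.
#' @export
write_challenge_dataset <- function(configs, root, n_fov = 30,
                                    tracks = "trajectory",
                                    img_config = imaging_config(),
                                    seed = 1) {
  stopifnot(all(tracks %in% c("trajectory", "video")))
  if (is.null(names(configs)) || any(names(configs) == "")) {
    names(configs) <- sprintf("EXP_%d", seq_along(configs))
  }
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = seed, experiments = list())
  for (i in seq_along(configs)) {
    nm <- names(configs)[i]
    exp_seed <- derive_seed(seed, i)
    exp_dir2 <- file.path(root, "track_2", nm)
    exp_dir1 <- file.path(root, "track_1", nm)
    gt_dir <- file.path(root, "ground_truth", nm)
    fovs <- write_experiment(
      configs[[i]],
      exp_dir = if ("trajectory" %in% tracks) exp_dir2 else exp_dir1,
      gt_dir = gt_dir, n_fov = n_fov, tracks = tracks,
      img_config = img_config, seed = exp_seed
    )
    if (all(c("trajectory", "video") %in% tracks)) {
      # both tracks requested: videos were written next to the CSVs; move
      dir.create(exp_dir1, recursive = TRUE, showWarnings = FALSE)
      for (f in list.files(exp_dir2, pattern = "\\.tiff$", full.names = TRUE)) {
        file.rename(f, file.path(exp_dir1, basename(f)))
      }
    }
    manifest$experiments[[nm]] <- list(
      model = configs[[i]]$model, seed = exp_seed, fov_seeds = fovs$seed
    )
  }
  jsonlite::write_json(
    manifest, file.path(root, "manifest.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(root)
}

#' Check a dataset folder for layout completeness
#'
#' @param root dataset root.
#' @param n_fov expected FOV count per experiment.
#' @return tibble with one row per experiment folder: `experiment`,
#'   `n_csv`, `complete`.
#' @export
check_layout <- function(root, n_fov = 30) {
  track <- file.path(root, "track_2")
  exps <- list.dirs(track, recursive = FALSE)
  if (length(exps) == 0) stop("no experiment folders under ", track, call. = FALSE)
  purrr::map_dfr(exps, function(e) {
    files <- list.files(e, pattern = "^FOV_\\d+\\.csv$")
    idx <- sort(as.integer(sub("^FOV_(\\d+)\\.csv$", "\\1", files)))
    tibble::tibble(
      experiment = basename(e),
      n_csv = length(files),
      complete = identical(idx, seq_len(n_fov))
    )
  })
}

#' Write prediction files
#'
#' Single-trajectory predictions are per-segment rows (`traj`, `segment`,
#' `start`, `end`, `K`, `alpha`, `type`): the inner changepoints are the
#' starts of segments 2..n. Ensemble predictions are one file per
#' experiment with the model label and per-state mixture parameters.
#'
#' @param pred a segment tibble (single-trajectory task) or a list with
#'   `model` and `states` (ensemble task).
#' @param path output path (CSV for segments, JSON for ensemble).
#' @param task `"single"` or `"ensemble"`.
#' @export
write_predictions <- function(pred, path, task = c("single", "ensemble")) {
  task <- match.arg(task)
  if (task == "single") {
    write_segment_table(pred, path)
  } else {
    jsonlite::write_json(
      list(model = pred$model, states = pred$states),
      path,
      dataframe = "columns", auto_unbox = TRUE, digits = NA
    )
  }
  invisible(path)
}

#' Read and validate prediction files
#'
#' Single-trajectory files must contain per-segment rows whose segments
#' tile each trajectory (so `#segments = #changepoints + 1` by
#' construction); malformed rows raise descriptive errors. Ensemble files
#' must carry a known model label and per-state weights; weights that do
#' not sum to 1 are renormalized with a warning.
#'
#' @param path prediction file (CSV or JSON, see [write_predictions()]).
#' @param task `"single"` or `"ensemble"`.
#' @return a segment tibble, or a list with `model` and `states`.
#' @export
read_predictions <- function(path, task = c("single", "ensemble")) {
  task <- match.arg(task)
  if (task == "single") {
    d <- tibble::as_tibble(utils::read.csv(path))
    need <- c("traj", "segment", "start", "end", "K", "alpha", "type")
    if (!all(need %in% names(d))) {
      stop(
        "prediction file ", path, " is missing columns: ",
        paste(setdiff(need, names(d)), collapse = ", "),
        call. = FALSE
      )
    }
    bad <- d |>
      dplyr::group_by(.data$traj) |>
      dplyr::arrange(.data$segment, .by_group = TRUE) |>
      dplyr::summarise(
        ok = all(diff(.data$start) > 0) &&
          all(.data$end >= .data$start) &&
          (dplyr::n() == 1 || all(.data$start[-1] == .data$end[-dplyr::n()] + 1)),
        .groups = "drop"
      ) |>
      dplyr::filter(!.data$ok)
    if (nrow(bad) > 0) {
      stop(
        "non-tiling segments for trajectory ids: ",
        paste(utils::head(bad$traj, 5), collapse = ", "),
        call. = FALSE
      )
    }
    if (!all(d$type %in% 0:3)) {
      stop("type identifiers must be in {0, 1, 2, 3}", call. = FALSE)
    }
    d
  } else {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.null(j$model) || !tolower(j$model) %in% MODELS) {
      stop("unknown or missing model label in ", path, call. = FALSE)
    }
    states <- tibble::as_tibble(j$states)
    need <- c("weight", "mean_K", "sd_K", "mean_alpha", "sd_alpha")
    if (!all(need %in% names(states)) || nrow(states) < 1) {
      stop("ensemble prediction needs columns ",
        paste(need, collapse = ", "),
        call. = FALSE
      )
    }
    tot <- sum(states$weight)
    if (abs(tot - 1) > 1e-6) {
      warning(sprintf(
        "state weights sum to %.4g; renormalizing", tot
      ))
      states$weight <- states$weight / tot
    }
    list(model = tolower(j$model), states = states)
  }
}

#' Score a dataset against a directory of predictions
#'
#' Walks the ground-truth sidecars of a dataset and scores, per
#' experiment, the single-trajectory predictions (`<EXP>/FOV_<n>.csv`
#' under `pred_dir`) and/or the ensemble prediction
#' (`<EXP>/ensemble.json`). Missing prediction files score every
#' trajectory at the worst value.
#'
#' @param root dataset root (as written by [write_challenge_dataset()]).
#' @param pred_dir prediction directory mirroring the experiment layout.
#' @param task `"single"`, `"ensemble"`, or both.
#' @param eps_cp changepoint gate, frames.
#' @return tibble with one row per experiment and task.
#' @export
score_dataset <- function(root, pred_dir, task = c("single", "ensemble"),
                          eps_cp = 10) {
  gt_root <- file.path(root, "ground_truth")
  exps <- basename(list.dirs(gt_root, recursive = FALSE))
  if (length(exps) == 0) stop("no ground truth under ", gt_root, call. = FALSE)
  out <- list()
  for (nm in exps) {
    if ("single" %in% task) {
      seg_files <- list.files(
        file.path(gt_root, nm),
        pattern = "^FOV_\\d+_segments\\.csv$", full.names = TRUE
      )
      res <- purrr::map_dfr(seg_files, function(f) {
        fov <- as.integer(sub("^FOV_(\\d+)_segments\\.csv$", "\\1", basename(f)))
        gt <- tibble::as_tibble(utils::read.csv(f))
        pf <- file.path(pred_dir, nm, sprintf("FOV_%d.csv", fov))
        pred <- if (file.exists(pf)) {
          read_predictions(pf, "single")
        } else {
          gt[0, ]
        }
        dplyr::mutate(
          score_trajectories(gt, pred, eps_cp),
          fov = fov, .before = 1
        )
      })
      # experiment-level aggregation: pooled counts, averaged trajectory
      # metrics weighted by trajectory counts
      agg <- tibble::tibble(
        experiment = nm, task = "single",
        alpha_cp = stats::weighted.mean(res$alpha_cp, res$n_traj, na.rm = TRUE),
        beta_cp = stats::weighted.mean(res$beta_cp, res$n_traj, na.rm = TRUE),
        jsc = jsc_cp(sum(res$TP), sum(res$FP), sum(res$FN)),
        rmse = sqrt(stats::weighted.mean(res$rmse^2, pmax(res$TP, 1))),
        msle = stats::weighted.mean(res$msle, res$n_traj, na.rm = TRUE),
        mae = stats::weighted.mean(res$mae, res$n_traj, na.rm = TRUE),
        f1 = stats::weighted.mean(res$f1, res$n_traj, na.rm = TRUE)
      )
      out <- c(out, list(agg))
    }
    if ("ensemble" %in% task) {
      truth_j <- jsonlite::read_json(
        file.path(gt_root, nm, "ensemble.json"),
        simplifyVector = TRUE
      )
      truth <- list(
        model = truth_j$model,
        states = tibble::as_tibble(truth_j$states)
      )
      pf <- file.path(pred_dir, nm, "ensemble.json")
      if (file.exists(pf)) {
        pred <- read_predictions(pf, "ensemble")
        sc <- score_ensemble(pred, truth)
      } else {
        sc <- tibble::tibble(
          model_correct = 0, state_count_err = NA_real_,
          w1_K = NA_real_, w1_alpha = NA_real_
        )
      }
      out <- c(out, list(
        dplyr::mutate(sc, experiment = nm, task = "ensemble", .before = 1)
      ))
    }
  }
  dplyr::bind_rows(out)
}
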