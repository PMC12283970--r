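## Heterogeneous-diffusion simulators.
##
## Five interaction models generate full-box trajectories with per-frame
## ground-truth state labels:
##   ssm - single state, no switching (negative control for CP detection)
##   msm - Markov multi-state switching with transition matrix M
##   dim - transient dimerization: pairs closer than 2r bind with P_b,
##         move with shared displacements, unbind with P_u
##   tcm - transient confinement in osmotic circular compartments
##         (enter freely, exit with probability `transmittance`)
##   qtm - quenched traps: circular regions immobilize (K = 0, alpha = 0)
##         with P_b, release with P_u
## Diffusion within a state is 2-D FBM; at every state change the increment
## stream is restarted with the new state's parameters (positions stay
## continuous, increment memory resets at changepoints).

TYPE_IMMOBILE <- 0L
TYPE_CONFINED <- 1L
TYPE_FREE <- 2L
TYPE_DIRECTED <- 3L

MODELS <- c("ssm", "msm", "dim", "tcm", "qtm")

## Built-in per-model parameter presets: realistic single-molecule regimes
## (slow membrane-protein scale diffusion, ~100-frame dwell times).
model_preset <- function(model) {
  switch(model,
    ssm = list(K_mean = 1, K_sd = 0.2, alpha_mean = 1, alpha_sd = 0.1),
    msm = list(
      K_mean = c(0.05, 1), K_sd = c(0.01, 0.1),
      alpha_mean = c(0.8, 1.2), alpha_sd = c(0.05, 0.05),
      M = matrix(c(0.98, 0.02, 0.02, 0.98), 2, 2, byrow = TRUE)
    ),
    dim = list(
      K_mean = c(1, 0.3), K_sd = c(0.1, 0.02),
      alpha_mean = c(1, 0.5), alpha_sd = c(0.05, 0.02),
      r = 1, P_b = 1, P_u = 0.02
    ),
    tcm = list(
      K_mean = c(1, 0.5), K_sd = c(0.1, 0.05),
      alpha_mean = c(1, 0.8), alpha_sd = c(0.05, 0.05),
      N_c = 15, r_c = 6, transmittance = 0.1
    ),
    qtm = list(
      K_mean = 1, K_sd = 0.1, alpha_mean = 1, alpha_sd = 0.05,
      N_t = 100, r_t = 1, P_b = 1, P_u = 0.05
    ),
    stop("unknown model: ", model, call. = FALSE)
  )
}

n_model_states <- function(model, M = NULL) {
  switch(model,
    ssm = 1L,
    msm = if (is.null(M)) 2L else nrow(M),
    dim = 2L, # monomer, dimer
    tcm = 2L, # outside, inside
    qtm = 1L # free (trapped state is implicit K = 0)
  )
}

#' Build an experiment configuration
#'
#' Defines one simulated experiment: the interaction model, the Gaussian
#' hyper-parameters of each diffusive state, the geometry, and the recording
#' settings. Unspecified state parameters come from built-in per-model
#' presets; everything is overridable.
#'
#' State vectors are ordered as: `msm` one entry per Markov state;
#' `dim` (monomer, dimer); `tcm` (outside, inside); `qtm` the free state
#' (the trapped state is implicitly `K = 0, alpha = 0`).
#'
#' @param model one of `"ssm"`, `"msm"`, `"dim"`, `"tcm"`, `"qtm"`.
#' @param K_mean,K_sd per-state Gaussian mean / sd of the generalized
#'   diffusion coefficient (pixel^2/frame^alpha); `sd = 0` is a point mass.
#' @param alpha_mean,alpha_sd per-state Gaussian mean / sd of the anomalous
#'   exponent; draws are redrawn/clamped into (0, 2).
#' @param N number of particles in the box.
#' @param L simulation box side, pixels (reflecting boundaries).
#' @param L_FOV field-of-view side, pixels (centered square).
#' @param dt sampling interval, frames.
#' @param T_total recording length, frames.
#' @param T_min minimum trajectory duration kept after FOV cropping, frames.
#' @param t_min minimum segment duration enforced by the majority filter.
#' @param M row-stochastic transition matrix (msm only).
#' @param r particle interaction radius (dim), pixels.
#' @param P_b per-step binding probability (dim, qtm).
#' @param P_u per-step unbinding probability (dim, qtm).
#' @param N_c,r_c,transmittance compartment count, radius (pixels) and
#'   boundary exit probability (tcm).
#' @param N_t,r_t trap count and radius, pixels (qtm).
#' @param sigma_N localization-noise SD applied to reported coordinates,
#'   pixels (trajectory track).
#' @param seed optional integer seed for the experiment.
#' @param label optional experiment label (e.g. `"EXP_1"`).
#' @return a list of class `"experiment_config"`.
#' @examples
#' experiment_config("msm", N = 20, seed = 1)
#' @export
experiment_config <- function(model = MODELS,
                              K_mean = NULL, K_sd = NULL,
                              alpha_mean = NULL, alpha_sd = NULL,
                              N = 100, L = 192, L_FOV = 128,
                              dt = 1, T_total = 200, T_min = 20, t_min = 3,
                              M = NULL,
                              r = NULL, P_b = NULL, P_u = NULL,
                              N_c = NULL, r_c = NULL, transmittance = NULL,
                              N_t = NULL, r_t = NULL,
                              sigma_N = 0.12,
                              seed = NULL, label = NULL) {
  model <- match.arg(model)
  preset <- model_preset(model)
  pick <- function(x, name) x %||% preset[[name]]
  K_mean <- pick(K_mean, "K_mean")
  K_sd <- pick(K_sd, "K_sd")
  alpha_mean <- pick(alpha_mean, "alpha_mean")
  alpha_sd <- pick(alpha_sd, "alpha_sd")
  M <- pick(M, "M")
  cfg <- list(
    model = model,
    K_mean = K_mean, K_sd = K_sd,
    alpha_mean = alpha_mean, alpha_sd = alpha_sd,
    N = as.integer(N), L = L, L_FOV = L_FOV, dt = dt,
    T_total = as.integer(T_total), T_min = as.integer(T_min),
    t_min = as.integer(t_min),
    M = M,
    r = pick(r, "r"), P_b = pick(P_b, "P_b"), P_u = pick(P_u, "P_u"),
    N_c = pick(N_c, "N_c"), r_c = pick(r_c, "r_c"),
    transmittance = pick(transmittance, "transmittance"),
    N_t = pick(N_t, "N_t"), r_t = pick(r_t, "r_t"),
    sigma_N = sigma_N,
    seed = seed, label = label
  )
  validate_config(cfg)
}

validate_config <- function(cfg) {
  S <- n_model_states(cfg$model, cfg$M)
  rec <- function(x) rep_len(x, S)
  cfg$K_mean <- rec(cfg$K_mean)
  cfg$K_sd <- rec(cfg$K_sd)
  cfg$alpha_mean <- rec(cfg$alpha_mean)
  cfg$alpha_sd <- rec(cfg$alpha_sd)
  if (cfg$L_FOV >= cfg$L) stop("L_FOV must be smaller than L", call. = FALSE)
  if (cfg$T_min > cfg$T_total) stop("T_min must not exceed T_total", call. = FALSE)
  if (any(cfg$K_sd < 0) || any(cfg$alpha_sd < 0)) {
    stop("state sds must be non-negative", call. = FALSE)
  }
  if (any(cfg$alpha_mean <= 0 | cfg$alpha_mean >= 2)) {
    stop("alpha_mean must lie strictly in (0, 2)", call. = FALSE)
  }
  if (any(cfg$K_mean < 0 | cfg$K_mean > K_SUPPORT[2])) {
    stop("K_mean outside the supported range", call. = FALSE)
  }
  if (cfg$model == "msm") {
    M <- cfg$M
    if (!is.matrix(M) || nrow(M) != ncol(M)) {
      stop("M must be a square matrix", call. = FALSE)
    }
    if (nrow(M) != S) stop("state vectors must match nrow(M)", call. = FALSE)
    if (any(M < 0) || any(abs(rowSums(M) - 1) > 1e-8)) {
      stop("M must be row-stochastic", call. = FALSE)
    }
  }
  for (p in c("P_b", "P_u", "transmittance")) {
    v <- cfg[[p]]
    if (!is.null(v) && (v < 0 || v > 1)) {
      stop(p, " must lie in [0, 1]", call. = FALSE)
    }
  }
  for (p in c("r", "r_c", "r_t")) {
    v <- cfg[[p]]
    if (!is.null(v) && v <= 0) stop(p, " must be positive", call. = FALSE)
  }
  if (cfg$sigma_N < 0) stop("sigma_N must be non-negative", call. = FALSE)
  structure(cfg, class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf(
    "<experiment_config> model=%s  N=%d  L=%g (FOV %g)  T=%d  states=%d\n",
    x$model, x$N, x$L, x$L_FOV, x$T_total, n_model_states(x$model, x$M)
  ))
  invisible(x)
}

#' Draw the realized parameters of one diffusive state
#'
#' Gaussian draw around the state's hyper-parameters, redrawn (up to 100
#' attempts) and finally clamped into the supported ranges
#' (`alpha` in (0, 2), `K` in `[1e-12, 1e6]`; `mean_K = sd_K = 0` gives the
#' exact immobile state).
#'
#' @param mean_K,sd_K Gaussian mean and sd of K.
#' @param mean_alpha,sd_alpha Gaussian mean and sd of alpha.
#' @param rng unused placeholder kept for API symmetry; draws use R's RNG.
#' @return a [diffusive_state()].
#' @export
sample_state_params <- function(mean_K, sd_K, mean_alpha, sd_alpha,
                                rng = NULL) {
  if (sd_K < 0 || sd_alpha < 0) stop("sds must be non-negative", call. = FALSE)
  if (mean_alpha < 0 || mean_alpha >= 2) {
    stop("mean_alpha outside the support (0, 2)", call. = FALSE)
  }
  if (mean_K < 0 || mean_K > K_SUPPORT[2]) {
    stop("mean_K outside the support", call. = FALSE)
  }
  draw <- function(mean, sd, lo, hi) {
    if (sd == 0) {
      return(min(max(mean, lo), hi))
    }
    for (i in 1:100) {
      v <- stats::rnorm(1, mean, sd)
      if (v > lo && v < hi) {
        return(v)
      }
    }
    min(max(stats::rnorm(1, mean, sd), lo), hi)
  }
  if (mean_K == 0 && sd_K == 0) {
    return(diffusive_state(0, 0))
  }
  K <- draw(mean_K, sd_K, K_SUPPORT[1], K_SUPPORT[2])
  alpha <- draw(mean_alpha, sd_alpha, ALPHA_MIN, ALPHA_MAX)
  diffusive_state(K, alpha)
}

draw_state_table <- function(cfg, n_states = NULL) {
  S <- n_states %||% n_model_states(cfg$model, cfg$M)
  purrr::map(seq_len(S), function(s) {
    sample_state_params(
      cfg$K_mean[s], cfg$K_sd[s],
      cfg$alpha_mean[s], cfg$alpha_sd[s]
    )
  })
}

#' Reflect a proposed move at the box walls
#'
#' Mirror reflection about the violated wall(s) of the square box
#' `[0, L]^2`; steps larger than L are folded repeatedly.
#'
#' @param position current coordinate(s) in `[0, L]`.
#' @param step proposed displacement(s).
#' @param L box side.
#' @return corrected coordinate(s) in `[0, L]`.
#' @examples
#' reflect_boundary(1, -3, 100) # 2
#' @export
reflect_boundary <- function(position, step, L) {
  z <- (position + step) %% (2 * L)
  ifelse(z > L, 2 * L - z, z)
}

#' Majority-filter a per-frame state-label sequence
#'
#' Replaces each frame's label by the modal label of its centered window
#' (ties keep the current label), iterated to a fixed point; any remaining
#' run shorter than `t_min` is absorbed into its longer neighbouring run,
#' so every surviving segment lasts at least `t_min` frames.
#'
#' @param labels integer vector of per-frame state labels.
#' @param window odd window width (default 5).
#' @param t_min minimum run length to keep (default 3).
#' @return filtered integer label vector, same length.
#' @examples
#' majority_filter_labels(c(0L, 0L, 1L, 0L, 0L))
#' @export
majority_filter_labels <- function(labels, window = 5, t_min = 3) {
  if (window %% 2 != 1) stop("window must be odd", call. = FALSE)
  n <- length(labels)
  if (n == 0 || length(unique(labels)) == 1) {
    return(labels)
  }
  half <- window %/% 2
  f <- labels
  labs <- sort(unique(labels))
  idx <- seq_len(n)
  lo <- pmax(idx - half, 1L)
  hi <- pmin(idx + half, n)
  for (iter in 1:25) {
    # windowed label counts via cumulative sums (truncated at the edges)
    cnt <- vapply(labs, function(l) {
      S <- cumsum(f == l)
      S[hi] - c(0L, S)[lo]
    }, integer(n))
    best <- max.col(cnt, "first")
    maxc <- cnt[cbind(idx, best)]
    cur_cnt <- cnt[cbind(idx, match(f, labs))]
    g <- ifelse(cur_cnt == maxc, f, labs[best])
    if (identical(g, f)) break
    f <- g
  }
  # guarantee minimum run length
  repeat {
    runs <- rle(f)
    if (length(runs$lengths) == 1) break
    short <- which(runs$lengths < t_min)
    if (length(short) == 0) break
    i <- short[which.min(runs$lengths[short])]
    left <- if (i > 1) runs$lengths[i - 1] else -1L
    right <- if (i < length(runs$lengths)) runs$lengths[i + 1] else -1L
    take <- if (left >= right) runs$values[i - 1] else runs$values[i + 1]
    ends <- cumsum(runs$lengths)
    f[(ends[i] - runs$lengths[i] + 1):ends[i]] <- take
  }
  f
}

#' Expected residence time of a Markov diffusive state
#'
#' @param M row-stochastic transition matrix.
#' @param i state index.
#' @return `1 / (1 - M[i, i])` frames; `Inf` for an absorbing state.
#' @examples
#' residence_time(matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE), 1) # 10
#' @export
residence_time <- function(M, i) {
  p <- M[i, i]
  if (p < 0 || p > 1) stop("M[i,i] must lie in [0, 1]", call. = FALSE)
  if (p == 1) {
    return(Inf)
  }
  1 / (1 - p)
}

## ---------------------------------------------------------------------
## model simulators (internal cores return, per particle, positions and
## raw per-frame labels/parameters; simulate_experiment postprocesses)

## scaled displacement block for `n` steps of a given state
state_block <- function(n, st, dt) {
  if (st$K == 0) {
    return(matrix(0, n, 2L))
  }
  fgn_matrix(n, st$alpha, 2L) * sqrt(2 * st$K * dt^st$alpha)
}

sim_core_ssm <- function(cfg) {
  Tn <- cfg$T_total
  purrr::map(seq_len(cfg$N), function(i) {
    st <- draw_state_table(cfg)[[1]]
    d <- state_block(Tn - 1L, st, cfg$dt)
    x <- numeric(Tn)
    y <- numeric(Tn)
    x[1] <- stats::runif(1, 0, cfg$L)
    y[1] <- stats::runif(1, 0, cfg$L)
    for (t in 1:(Tn - 1)) {
      x[t + 1] <- reflect_boundary(x[t], d[t, 1], cfg$L)
      y[t + 1] <- reflect_boundary(y[t], d[t, 2], cfg$L)
    }
    list(
      x = x, y = y, label = rep(1L, Tn),
      K = rep(st$K, Tn), alpha = rep(st$alpha, Tn)
    )
  })
}

## Markov state chains for all particles at once
markov_chain_states <- function(N, Tn, M) {
  S <- nrow(M)
  cumM <- t(apply(M, 1, cumsum))
  states <- matrix(0L, N, Tn)
  states[, 1] <- sample.int(S, N, replace = TRUE)
  for (t in 2:Tn) {
    u <- stats::runif(N)
    states[, t] <- rowSums(u > cumM[states[, t - 1], , drop = FALSE]) + 1L
  }
  states
}

sim_core_msm <- function(cfg) {
  Tn <- cfg$T_total
  chains <- markov_chain_states(cfg$N, Tn, cfg$M)
  purrr::map(seq_len(cfg$N), function(i) {
    sts <- draw_state_table(cfg)
    lab <- chains[i, ]
    # displacement t (frame t -> t+1) uses the state of frame t
    d <- matrix(0, Tn - 1L, 2L)
    runs <- label_runs(lab[1:(Tn - 1)])
    for (k in seq_len(nrow(runs))) {
      idx <- runs$start[k]:runs$end[k]
      d[idx, ] <- state_block(length(idx), sts[[runs$value[k]]], cfg$dt)
    }
    x <- numeric(Tn)
    y <- numeric(Tn)
    x[1] <- stats::runif(1, 0, cfg$L)
    y[1] <- stats::runif(1, 0, cfg$L)
    for (t in 1:(Tn - 1)) {
      x[t + 1] <- reflect_boundary(x[t], d[t, 1], cfg$L)
      y[t + 1] <- reflect_boundary(y[t], d[t, 2], cfg$L)
    }
    Kv <- vapply(sts, `[[`, numeric(1), "K")[lab]
    av <- vapply(sts, `[[`, numeric(1), "alpha")[lab]
    list(x = x, y = y, label = lab, K = Kv, alpha = av)
  })
}

sim_core_dim <- function(cfg) {
  Tn <- cfg$T_total
  N <- cfg$N
  if (N < 2) stop("dim requires at least 2 particles", call. = FALSE)
  mono <- purrr::map(seq_len(N), function(i) {
    sample_state_params(
      cfg$K_mean[1], cfg$K_sd[1],
      cfg$alpha_mean[1], cfg$alpha_sd[1]
    )
  })
  draw_dimer <- function() {
    sample_state_params(
      cfg$K_mean[2], cfg$K_sd[2],
      cfg$alpha_mean[2], cfg$alpha_sd[2]
    )
  }
  pos <- cbind(stats::runif(N, 0, cfg$L), stats::runif(N, 0, cfg$L))
  inc <- purrr::map(seq_len(N), function(i) state_block(Tn - 1L, mono[[i]], cfg$dt))
  partner <- rep(0L, N) # 0 = monomeric
  dimer_par <- vector("list", N) # dimer state stored with lead member
  X <- matrix(0, Tn, N)
  Y <- matrix(0, Tn, N)
  LAB <- matrix(1L, Tn, N)
  KM <- matrix(0, Tn, N)
  AM <- matrix(0, Tn, N)
  X[1, ] <- pos[, 1]
  Y[1, ] <- pos[, 2]
  KM[1, ] <- vapply(mono, `[[`, numeric(1), "K")
  AM[1, ] <- vapply(mono, `[[`, numeric(1), "alpha")
  for (t in 1:(Tn - 1)) {
    just_unbound <- rep(FALSE, N)
    # unbinding
    leads <- which(partner > seq_len(N)) # each dimer once (lead = lower index)
    for (i in leads) {
      if (stats::runif(1) < cfg$P_u) {
        j <- partner[i]
        partner[c(i, j)] <- 0L
        just_unbound[c(i, j)] <- TRUE
        dimer_par[i] <- list(NULL)
        for (m in c(i, j)) {
          inc[[m]][t:(Tn - 1), ] <- state_block(Tn - t, mono[[m]], cfg$dt)
        }
      }
    }
    # binding among free particles that did not just unbind
    free <- which(partner == 0L & !just_unbound)
    if (length(free) >= 2 && cfg$P_b > 0) {
      dd <- as.matrix(stats::dist(pos[free, , drop = FALSE]))
      cand <- which(upper.tri(dd) & dd < 2 * cfg$r, arr.ind = TRUE)
      if (nrow(cand) > 0) {
        ord <- sample.int(nrow(cand))
        for (row in ord) {
          i <- free[cand[row, 1]]
          j <- free[cand[row, 2]]
          if (partner[i] != 0L || partner[j] != 0L) next
          if (stats::runif(1) < cfg$P_b) {
            partner[i] <- j
            partner[j] <- i
            lead <- min(i, j)
            st <- draw_dimer()
            dimer_par[[lead]] <- st
            inc[[lead]][t:(Tn - 1), ] <- state_block(Tn - t, st, cfg$dt)
          }
        }
      }
    }
    # move
    for (i in seq_len(N)) {
      src <- if (partner[i] != 0L) min(i, partner[i]) else i
      d <- inc[[src]][t, ]
      pos[i, 1] <- reflect_boundary(pos[i, 1], d[1], cfg$L)
      pos[i, 2] <- reflect_boundary(pos[i, 2], d[2], cfg$L)
    }
    X[t + 1, ] <- pos[, 1]
    Y[t + 1, ] <- pos[, 2]
    bound <- partner != 0L
    LAB[t + 1, ] <- ifelse(bound, 2L, 1L)
    for (i in seq_len(N)) {
      if (bound[i]) {
        st <- dimer_par[[min(i, partner[i])]]
        KM[t + 1, i] <- st$K
        AM[t + 1, i] <- st$alpha
      } else {
        KM[t + 1, i] <- mono[[i]]$K
        AM[t + 1, i] <- mono[[i]]$alpha
      }
    }
  }
  purrr::map(seq_len(N), function(i) {
    list(x = X[, i], y = Y[, i], label = LAB[, i], K = KM[, i], alpha = AM[, i])
  })
}

#' Place non-overlapping circular compartments
#'
#' Rejection sampling of `n` circle centers uniform in the box so that
#' circles are pairwise disjoint; errors out after `max_attempts` draws.
#'
#' @param n number of circles.
#' @param radius circle radius, pixels.
#' @param L box side.
#' @param max_attempts rejection budget (default 1e4).
#' @param overlap allow overlapping circles (used for traps).
#' @return tibble with columns `x`, `y`, `r`.
#' @export
place_circles <- function(n, radius, L, max_attempts = 1e4, overlap = FALSE) {
  cx <- numeric(0)
  cy <- numeric(0)
  attempts <- 0
  while (length(cx) < n) {
    attempts <- attempts + 1
    if (attempts > max_attempts) {
      stop("could not place ", n, " non-overlapping compartments in the box",
        call. = FALSE
      )
    }
    px <- stats::runif(1, 0, L)
    py <- stats::runif(1, 0, L)
    if (!overlap && length(cx) > 0 &&
      any((cx - px)^2 + (cy - py)^2 < (2 * radius)^2)) {
      next
    }
    cx <- c(cx, px)
    cy <- c(cy, py)
  }
  tibble::tibble(x = cx, y = cy, r = radius)
}

## specular reflection of a blocked exit step about the tangent at the
## crossing point of the circular boundary; projected inside if numerics
## leave the point outside
reflect_circle <- function(p0, p1, center, R) {
  d <- p1 - p0
  f <- p0 - center
  A <- sum(d * d)
  B <- 2 * sum(f * d)
  C <- sum(f * f) - R^2
  disc <- B^2 - 4 * A * C
  if (A == 0 || disc < 0) {
    u <- p1 - center
    return(center + u / max(sqrt(sum(u^2)), 1e-12) * (R * 0.999))
  }
  s <- (-B + sqrt(disc)) / (2 * A)
  s <- min(max(s, 0), 1)
  q <- p0 + s * d
  nrm <- q - center
  nn <- sqrt(sum(nrm^2))
  if (nn < 1e-12) {
    return(p0)
  }
  nrm <- nrm / nn
  p_ref <- p1 - 2 * sum((p1 - q) * nrm) * nrm
  if (sum((p_ref - center)^2) >= R^2) {
    u <- p_ref - center
    p_ref <- center + u / sqrt(sum(u^2)) * (R * 0.999)
  }
  p_ref
}

sim_core_tcm <- function(cfg, env) {
  Tn <- cfg$T_total
  N <- cfg$N
  centers <- as.matrix(env[, c("x", "y")])
  R <- cfg$r_c
  which_comp <- function(p) {
    d2 <- (centers[, 1] - p[1])^2 + (centers[, 2] - p[2])^2
    k <- which(d2 < R^2)
    if (length(k) == 0) 0L else k[1]
  }
  purrr::map(seq_len(N), function(i) {
    sts <- draw_state_table(cfg) # 1 = outside, 2 = inside
    x <- numeric(Tn)
    y <- numeric(Tn)
    lab <- integer(Tn)
    p <- c(stats::runif(1, 0, cfg$L), stats::runif(1, 0, cfg$L))
    comp <- which_comp(p)
    lab[1] <- if (comp > 0) 2L else 1L
    x[1] <- p[1]
    y[1] <- p[2]
    inc <- state_block(Tn - 1L, sts[[lab[1]]], cfg$dt)
    for (t in 1:(Tn - 1)) {
      d <- inc[t, ]
      prop <- c(
        reflect_boundary(p[1], d[1], cfg$L),
        reflect_boundary(p[2], d[2], cfg$L)
      )
      if (comp > 0) {
        out_of_comp <- sum((prop - centers[comp, ])^2) >= R^2
        if (out_of_comp && stats::runif(1) >= cfg$transmittance) {
          prop <- reflect_circle(p, prop, centers[comp, ], R)
          prop[1] <- min(max(prop[1], 0), cfg$L)
          prop[2] <- min(max(prop[2], 0), cfg$L)
        }
      }
      p <- prop
      comp <- which_comp(p)
      lab[t + 1] <- if (comp > 0) 2L else 1L
      x[t + 1] <- p[1]
      y[t + 1] <- p[2]
      if (lab[t + 1] != lab[t] && t < Tn - 1) {
        inc[(t + 1):(Tn - 1), ] <-
          state_block(Tn - 1L - t, sts[[lab[t + 1]]], cfg$dt)
      }
    }
    Kv <- vapply(sts, `[[`, numeric(1), "K")[lab]
    av <- vapply(sts, `[[`, numeric(1), "alpha")[lab]
    list(x = x, y = y, label = lab, K = Kv, alpha = av)
  })
}

sim_core_qtm <- function(cfg, env) {
  Tn <- cfg$T_total
  N <- cfg$N
  centers <- as.matrix(env[, c("x", "y")])
  rt2 <- cfg$r_t^2
  in_trap <- function(p) {
    any((centers[, 1] - p[1])^2 + (centers[, 2] - p[2])^2 < rt2)
  }
  purrr::map(seq_len(N), function(i) {
    st <- draw_state_table(cfg)[[1]]
    x <- numeric(Tn)
    y <- numeric(Tn)
    lab <- integer(Tn)
    p <- c(stats::runif(1, 0, cfg$L), stats::runif(1, 0, cfg$L))
    x[1] <- p[1]
    y[1] <- p[2]
    lab[1] <- 1L
    inc <- state_block(Tn - 1L, st, cfg$dt)
    trapped <- FALSE
    for (t in 1:(Tn - 1)) {
      if (trapped) {
        if (stats::runif(1) < cfg$P_u) {
          # released: takes a step immediately with a fresh stream
          trapped <- FALSE
          inc[t:(Tn - 1), ] <- state_block(Tn - t, st, cfg$dt)
          d <- inc[t, ]
          p <- c(
            reflect_boundary(p[1], d[1], cfg$L),
            reflect_boundary(p[2], d[2], cfg$L)
          )
        }
      } else {
        if (in_trap(p) && stats::runif(1) < cfg$P_b) {
          trapped <- TRUE # immobilized at the current position
        } else {
          d <- inc[t, ]
          p <- c(
            reflect_boundary(p[1], d[1], cfg$L),
            reflect_boundary(p[2], d[2], cfg$L)
          )
        }
      }
      x[t + 1] <- p[1]
      y[t + 1] <- p[2]
      lab[t + 1] <- if (trapped) 2L else 1L
    }
    Kv <- ifelse(lab == 2L, 0, st$K)
    av <- ifelse(lab == 2L, 0, st$alpha)
    list(x = x, y = y, label = lab, K = Kv, alpha = av)
  })
}

## per-frame diffusion-type identifiers:
## 0 immobile, 1 confined, 2 free (0.05 <= alpha < 1.9), 3 directed
assign_type_id <- function(model, label, K, alpha) {
  type <- rep(TYPE_FREE, length(label))
  type[alpha >= 1.9] <- TYPE_DIRECTED
  type[alpha < 0.05 | K == 0] <- TYPE_IMMOBILE
  if (model == "tcm") type[label == 2L] <- TYPE_CONFINED
  if (model == "qtm") type[label == 2L] <- TYPE_IMMOBILE
  as.integer(type)
}

## run-wise parameter refill after label filtering: each filtered run takes
## the parameters observed on frames whose raw label matches the run label
refill_params <- function(filtered, raw, K, alpha) {
  runs <- label_runs(filtered)
  for (k in seq_len(nrow(runs))) {
    idx <- runs$start[k]:runs$end[k]
    ok <- idx[raw[idx] == runs$value[k]]
    src <- if (length(ok) > 0) {
      ok[1]
    } else {
      cand <- which(raw == runs$value[k])
      if (length(cand) > 0) cand[which.min(abs(cand - runs$start[k]))] else NA
    }
    if (!is.na(src)) {
      K[idx] <- K[src]
      alpha[idx] <- alpha[src]
    }
  }
  list(K = K, alpha = alpha)
}

#' Simulate one experiment
#'
#' Runs the configured interaction model for all particles over the full
#' box, majority-filters the per-frame state labels (so every ground-truth
#' segment lasts at least `t_min` frames) and attaches per-frame realized
#' parameters and diffusion-type identifiers.
#'
#' @param config an [experiment_config()].
#' @return an object of class `"fbm_experiment"`: a list with
#'   `trajectories` (tibble: `particle`, `frame` (0-based), `x`, `y`,
#'   `state` (filtered label), `state_raw`, `K`, `alpha`, `type`),
#'   `environment` (tibble of circles for tcm/qtm, else `NULL`) and
#'   `config`.
#' @examples
#' exp <- simulate_experiment(experiment_config("ssm", N = 5, seed = 1))
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  with_seed(config$seed, {
    env <- switch(config$model,
      tcm = dplyr::mutate(
        place_circles(config$N_c, config$r_c, config$L),
        kind = "compartment"
      ),
      qtm = dplyr::mutate(
        place_circles(config$N_t, config$r_t, config$L, overlap = TRUE),
        kind = "trap"
      ),
      NULL
    )
    cores <- switch(config$model,
      ssm = sim_core_ssm(config),
      msm = sim_core_msm(config),
      dim = sim_core_dim(config),
      tcm = sim_core_tcm(config, env),
      qtm = sim_core_qtm(config, env)
    )
    Tn <- config$T_total
    trajs <- purrr::imap(cores, function(tr, i) {
      filt <- majority_filter_labels(tr$label, 5, config$t_min)
      pars <- refill_params(filt, tr$label, tr$K, tr$alpha)
      if (config$model == "qtm") {
        pars$K[filt == 2L] <- 0
        pars$alpha[filt == 2L] <- 0
      }
      tibble::tibble(
        particle = i,
        frame = 0:(Tn - 1L),
        x = tr$x, y = tr$y,
        state = filt,
        state_raw = tr$label,
        K = pars$K,
        alpha = pars$alpha,
        type = assign_type_id(config$model, filt, pars$K, pars$alpha)
      )
    })
    structure(
      list(
        trajectories = dplyr::bind_rows(trajs),
        environment = env,
        config = config
      ),
      class = "fbm_experiment"
    )
  })
}

#' @export
print.fbm_experiment <- function(x, ...) {
  cat(sprintf(
    "<fbm_experiment> model=%s  particles=%d  frames=%d\n",
    x$config$model, x$config$N, x$config$T_total
  ))
  invisible(x)
}

#' Crop full-box trajectories to the field of view
#'
#' The FOV is the centered square of side `L_FOV`. Every maximal run of
#' consecutive in-FOV frames of a particle that lasts at least `T_min`
#' frames becomes a new trajectory (fresh id, coordinates shifted to FOV
#' pixel coordinates); shorter visits are discarded. Frame numbers keep
#' the recording time base.
#'
#' @param trajectories trajectory tibble (from [simulate_experiment()]) or
#'   an `fbm_experiment`.
#' @param L_FOV FOV side, pixels.
#' @param T_min minimum trajectory duration, frames.
#' @param L full box side (taken from the experiment config when an
#'   `fbm_experiment` is given).
#' @return tibble with columns `traj`, `particle`, `frame`, `x`, `y`,
#'   `state`, `K`, `alpha`, `type`.
#' @export
crop_to_fov <- function(trajectories, L_FOV = NULL, T_min = NULL, L = NULL) {
  if (inherits(trajectories, "fbm_experiment")) {
    cfg <- trajectories$config
    L_FOV <- L_FOV %||% cfg$L_FOV
    T_min <- T_min %||% cfg$T_min
    L <- L %||% cfg$L
    trajectories <- trajectories$trajectories
  }
  stopifnot(!is.null(L_FOV), !is.null(T_min), !is.null(L), L_FOV < L)
  off <- (L - L_FOV) / 2
  tr <- trajectories |>
    dplyr::mutate(.in_fov = .data$x >= off & .data$x < off + L_FOV &
      .data$y >= off & .data$y < off + L_FOV)
  pieces <- tr |>
    dplyr::group_by(.data$particle) |>
    dplyr::arrange(.data$frame, .by_group = TRUE) |>
    dplyr::mutate(.run = cumsum(c(TRUE, diff(.data$.in_fov) != 0))) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$.in_fov) |>
    dplyr::group_by(.data$particle, .data$.run) |>
    dplyr::filter(dplyr::n() >= T_min) |>
    dplyr::ungroup()
  if (nrow(pieces) == 0) {
    return(tibble::tibble(
      traj = integer(), particle = integer(), frame = integer(),
      x = numeric(), y = numeric(), state = integer(),
      K = numeric(), alpha = numeric(), type = integer()
    ))
  }
  pieces |>
    dplyr::mutate(traj = dplyr::dense_rank(
      paste(.data$particle, .data$.run, sep = "_") |>
        factor(levels = unique(paste(.data$particle, .data$.run, sep = "_")))
    )) |>
    dplyr::transmute(
      traj = .data$traj,
      particle = .data$particle,
      frame = .data$frame,
      x = .data$x - off,
      y = .data$y - off,
      state = .data$state,
      K = .data$K,
      alpha = .data$alpha,
      type = .data$type
    )
}

#' Derive ground-truth segments (and changepoints) from cropped trajectories
#'
#' Segments are maximal runs of constant state label within each
#' trajectory; changepoints are the first frames of segments 2..n (strictly
#' inside the trajectory).
#'
#' @param fov_traj tibble from [crop_to_fov()] (needs `traj`, `frame`,
#'   `state`, `K`, `alpha`, `type`).
#' @return tibble with columns `traj`, `segment`, `start`, `end`
#'   (inclusive frames), `K`, `alpha`, `type`.
#' @export
derive_segments <- function(fov_traj) {
  fov_traj |>
    dplyr::group_by(.data$traj) |>
    dplyr::arrange(.data$frame, .by_group = TRUE) |>
    dplyr::reframe({
      st <- .data$state
      fr <- .data$frame
      Kv <- .data$K
      av <- .data$alpha
      ty <- .data$type
      runs <- label_runs(st)
      tibble::tibble(
        segment = seq_len(nrow(runs)),
        start = fr[runs$start],
        end = fr[runs$end],
        K = Kv[runs$start],
        alpha = av[runs$start],
        type = ty[runs$start]
      )
    })
}

#' Changepoint list per trajectory from a segment table
#'
#' @param segments tibble from [derive_segments()] (or a prediction table
#'   with the same columns).
#' @return named list: for each trajectory id, the ordered vector of inner
#'   changepoint frames (empty for single-segment trajectories).
#' @export
segment_changepoints <- function(segments) {
  segments |>
    dplyr::group_by(.data$traj) |>
    dplyr::arrange(.data$segment, .by_group = TRUE) |>
    dplyr::summarise(cps = list(.data$start[-1]), .groups = "drop") |>
    (\(d) stats::setNames(d$cps, d$traj))()
}

#' Ground-truth ensemble summary of an experiment
#'
#' One row per diffusive state: the generating Gaussian parameters of K
#' and alpha plus the realized fraction of frames spent in the state
#' (computed from the simulated data). For qtm the trapped state is the
#' point mass at `K = 0, alpha = 0`.
#'
#' @param experiment an `fbm_experiment`.
#' @param fov_traj optional cropped tibble; defaults to cropping the
#'   experiment with its configured FOV.
#' @return list with `model` and `states` (tibble: `state`, `weight`,
#'   `mean_K`, `sd_K`, `mean_alpha`, `sd_alpha`).
#' @export
ensemble_truth <- function(experiment, fov_traj = NULL) {
  cfg <- experiment$config
  fov_traj <- fov_traj %||% crop_to_fov(experiment)
  S <- n_model_states(cfg$model, cfg$M)
  labels <- seq_len(S)
  means_K <- cfg$K_mean
  sds_K <- cfg$K_sd
  means_a <- cfg$alpha_mean
  sds_a <- cfg$alpha_sd
  if (cfg$model == "qtm") {
    labels <- 1:2
    means_K <- c(means_K, 0)
    sds_K <- c(sds_K, 0)
    means_a <- c(means_a, 0)
    sds_a <- c(sds_a, 0)
  }
  counts <- vapply(labels, function(s) sum(fov_traj$state == s), numeric(1))
  if (sum(counts) == 0) counts <- rep(1, length(labels))
  states <- tibble::tibble(
    state = labels,
    weight = counts / sum(counts),
    mean_K = means_K,
    sd_K = sds_K,
    mean_alpha = means_a,
    sd_alpha = sds_a
  )
  list(model = cfg$model, states = states)
}
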