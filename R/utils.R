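#' @keywords internal
#' @importFrom rlang .data %||%
#' @importFrom dplyr n
"_PACKAGE"

#' Derive a reproducible child seed from a root seed and integer ids
#'
#' A small multiplicative hash keeps every derived seed a valid 32-bit
#' R integer, so one root seed deterministically fans out into independent
#' per-experiment / per-FOV / per-trajectory streams.
#'
#' @param root integer root seed.
#' @param ... further integer ids (experiment index, FOV index, ...).
#' @return a single integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(root, ...) {
  ids <- c(root, ...)
  stopifnot(length(ids) >= 1, all(is.finite(ids)))
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  h <- 0
  for (v in ids) {
    h <- (h * 69069 + (as.numeric(v) %% m) + 1) %% m
  }
  as.integer(h)
}

## Run with a local seed if one is given, without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(expr)
  }
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

## Split an integer label vector into maximal constant runs.
## Returns a tibble with value, start, end (1-based inclusive indices).
label_runs <- function(labels) {
  r <- rle(labels)
  end <- cumsum(r$lengths)
  tibble::tibble(
    value = r$values,
    start = end - r$lengths + 1L,
    end = end
  )
}
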