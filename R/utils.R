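#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds the generator, evaluates `expr`, and
#' restores the previous state so generator functions never leak RNG side
#' effects into the session.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Deterministic per-stage seed fan-out from one root seed; keeps every stream
# below 2^31 - 1.
stage_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- sum(utf8ToInt(stage) * seq_len(nchar(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483629)
}

#' Spatially correlated Gaussian noise field
#'
#' White Gaussian noise smoothed with a separable Gaussian kernel and rescaled
#' to unit marginal standard deviation; `corr_len` is the kernel sigma in
#' pixels. `corr_len = 0` returns plain white noise.
#'
#' @param nrow,ncol field dimensions.
#' @param corr_len correlation length in pixels (Gaussian kernel sigma).
#' @param sd marginal standard deviation of the returned field.
#' @return A `nrow` x `ncol` numeric matrix.
#' @export
noise_field <- function(nrow, ncol, corr_len = 0, sd = 1) {
  z <- matrix(stats::rnorm(nrow * ncol), nrow, ncol)
  if (sd == 0) return(matrix(0, nrow, ncol))
  if (corr_len > 0) {
    half <- max(1L, ceiling(3 * corr_len))
    k <- stats::dnorm(seq(-half, half), sd = corr_len)
    k <- k / sum(k)
    z <- smooth_1d(z, k, margin = 1L)
    z <- smooth_1d(z, k, margin = 2L)
    z <- z / stats::sd(as.vector(z))
  }
  z * sd
}

# Convolve each row (margin = 2) or column (margin = 1) with kernel k,
# replicating edges so the variance stays roughly stationary.
smooth_1d <- function(m, k, margin) {
  half <- (length(k) - 1L) / 2L
  if (margin == 2L) m <- t(m)
  n <- nrow(m)
  idx <- clamp(seq(1L - half, n + half), 1L, n)
  padded <- m[idx, , drop = FALSE]
  out <- matrix(0, n, ncol(m))
  for (j in seq_along(k)) {
    out <- out + k[j] * padded[seq(j, j + n - 1L), , drop = FALSE]
  }
  if (margin == 2L) t(out) else out
}

#' Area-weighted overlap weights between two 1-D pixel grids
#'
#' Both grids start at the same origin; source pixels have width `src_gsd`,
#' destination pixels width `dst_gsd`. Entry (i, j) is the fraction of
#' destination pixel i covered by source pixel j, so rows sum to 1 whenever
#' the destination pixel lies inside the source extent.
#'
#' @param n_src,n_dst number of source and destination pixels.
#' @param src_gsd,dst_gsd pixel widths in meters.
#' @return An `n_dst` x `n_src` weight matrix.
#' @keywords internal
overlap_weights <- function(n_src, src_gsd, n_dst, dst_gsd) {
  w <- matrix(0, n_dst, n_src)
  for (i in seq_len(n_dst)) {
    a <- (i - 1) * dst_gsd
    b <- i * dst_gsd
    j0 <- max(1L, floor(a / src_gsd) + 1L)
    j1 <- min(n_src, ceiling(b / src_gsd))
    for (j in seq.int(j0, j1)) {
      ov <- min(b, j * src_gsd) - max(a, (j - 1) * src_gsd)
      if (ov > 0) w[i, j] <- ov / dst_gsd
    }
  }
  w
}

# Area-weighted box average of a field from a fine grid to a coarse grid
# sharing the same origin. Rows index y, columns x.
box_average <- function(values, src_gsd, n_dst_row, n_dst_col, dst_gsd) {
  wr <- overlap_weights(nrow(values), src_gsd, n_dst_row, dst_gsd)
  wc <- overlap_weights(ncol(values), src_gsd, n_dst_col, dst_gsd)
  wr %*% values %*% t(wc)
}

# Nearest source pixel index along one axis for each destination pixel
# center; exact ties go to the smaller (row-major first) index.
nearest_index_1d <- function(n_src, src_gsd, src_origin, dst_centers) {
  u <- (dst_centers - src_origin) / src_gsd  # src centers at j - 0.5
  lo <- clamp(floor(u + 0.5), 1, n_src)
  hi <- clamp(lo + 1, 1, n_src)
  d_lo <- abs(u - (lo - 0.5))
  d_hi <- abs(u - (hi - 0.5))
  ifelse(d_lo <= d_hi, lo, hi)
}
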