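# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Draw from a Laplace (double-exponential) distribution
#'
#' @param n number of draws.
#' @param location location parameter.
#' @param scale scale parameter (b); variance is 2 b^2.
#' @return numeric vector of length `n`.
#' @keywords internal
#' @noRd
rlaplace <- function(n, location = 0, scale = 1) {
  stopifnot(scale >= 0)
  u <- stats::runif(n) - 0.5
  location - scale * sign(u) * log1p(-2 * abs(u))
}

# Draw from a symmetric Dirichlet via normalised Gamma draws.
rdirichlet1 <- function(k, concentration) {
  g <- stats::rgamma(k, shape = concentration, rate = 1)
  if (sum(g) <= 0) g <- rep(1, k)
  g / sum(g)
}

# Largest-remainder rounding of non-negative reals to integers with a fixed
# total; ties broken deterministically by index.
round_to_total <- function(x, total) {
  stopifnot(all(x >= 0), total >= 0)
  scaled <- x / sum(x) * total
  base <- floor(scaled)
  rem <- scaled - base
  short <- total - sum(base)
  if (short > 0) {
    ord <- order(rem, seq_along(rem), decreasing = c(TRUE, FALSE), method = "radix")
    base[ord[seq_len(short)]] <- base[ord[seq_len(short)]] + 1
  }
  as.integer(base)
}

# Remove the row means (e.g. demean each timepoint across voxels).
demean_rows <- function(x) {
  x - rowMeans(x)
}

# Remove the column means (e.g. demean each voxel's timeseries).
demean_cols <- function(x) {
  sweep(x, 2L, colMeans(x), "-")
}

# Column z-scoring; errors on constant columns unless `scale = FALSE`.
standardise_cols <- function(x, scale = TRUE, label = "column") {
  x <- demean_cols(x)
  if (scale) {
    s <- sqrt(colMeans(x^2) * nrow(x) / (nrow(x) - 1))
    bad <- which(s < .Machine$double.eps^0.5)
    if (length(bad)) {
      stop(sprintf("constant %s(s): %s", label, paste(bad, collapse = ", ")),
           call. = FALSE)
    }
    x <- sweep(x, 2L, s, "/")
  }
  x
}

# Derive a stream of per-repeat RNG seeds from a root seed, all below 2^31.
derive_seeds <- function(seed, n) {
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  sample.int(.Machine$integer.max - 1L, n)
}

# Pairwise check that a modes x voxels design is not collinear; names the
# offending pair in the error to help diagnose degenerate map sets.
check_design <- function(maps, what = "map", kappa_max = 1e8) {
  g <- tcrossprod(maps)
  if (nrow(maps) > 1L) {
    kap <- kappa(g, exact = TRUE)
    if (!is.finite(kap) || kap > kappa_max) {
      cors <- abs(stats::cor(t(maps)))
      diag(cors) <- 0
      idx <- sort(which(cors == max(cors), arr.ind = TRUE)[1L, ])
      stop(sprintf(
        "collinear %ss: pair (%d, %d) has |r| = %.6f (condition number %.3g)",
        what, idx[1L], idx[2L], max(cors), kap), call. = FALSE)
    }
  } else if (sum(maps^2) < .Machine$double.eps) {
    stop(sprintf("degenerate all-zero %s", what), call. = FALSE)
  }
  invisible(g)
}

is_count <- function(x, min = 1) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= min &&
    abs(x - round(x)) < 1e-8
}

stop_config <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}
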