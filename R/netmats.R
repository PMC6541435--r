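# Network matrices: temporal edges from timeseries, spatial edges from maps.

new_netmat <- function(values, kind, subject = NA, stage = NA_character_) {
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  structure(values, class = c("netmat", "matrix"),
            kind = kind, subject = subject, stage = stage)
}

#' Temporal network matrix
#'
#' Full Pearson correlation matrix between node timecourses; each element is
#' a temporal edge.
#'
#' @param ts timepoints x modes matrix (>= 3 timepoints, no constant
#'   column).
#' @param subject,stage optional provenance labels stored as attributes.
#' @return a `netmat` object (symmetric, unit diagonal, entries in
#'   \[-1, 1\]).
#' @export
temporal_netmat <- function(ts, subject = NA, stage = NA_character_) {
  ts <- cbind(ts)
  if (nrow(ts) < 3L) stop_config("need at least 3 timepoints")
  s <- apply(ts, 2L, stats::sd)
  bad <- which(s < .Machine$double.eps^0.5)
  if (length(bad)) {
    stop_config("constant timecourse for mode(s) %s", paste(bad, collapse = ", "))
  }
  new_netmat(stats::cor(ts), kind = "temporal", subject = subject,
             stage = stage)
}

#' Spatial overlap matrix
#'
#' Full Pearson correlation matrix between vectorised node spatial maps;
#' each element is a spatial edge. Group ICA maps have near-zero spatial
#' edges by construction, while stage-2 subject maps (and the ground truth)
#' need not.
#'
#' @param maps modes x voxels matrix (>= 3 voxels, no all-zero or constant
#'   map).
#' @inheritParams temporal_netmat
#' @return a `netmat` object.
#' @export
spatial_netmat <- function(maps, subject = NA, stage = NA_character_) {
  maps <- rbind(maps)
  if (ncol(maps) < 3L) stop_config("need at least 3 voxels")
  s <- apply(maps, 1L, stats::sd)
  bad <- which(s < .Machine$double.eps^0.5)
  if (length(bad)) {
    stop_config("all-zero or constant map for mode(s) %s",
                paste(bad, collapse = ", "))
  }
  new_netmat(stats::cor(t(maps)), kind = "spatial", subject = subject,
             stage = stage)
}

#' @export
print.netmat <- function(x, ...) {
  cat(sprintf("%s network matrix (%d x %d)%s%s\n",
              attr(x, "kind") %||% "unknown", nrow(x), ncol(x),
              if (!is.na(attr(x, "subject"))) paste0(", subject ", attr(x, "subject")) else "",
              if (!is.na(attr(x, "stage"))) paste0(", ", attr(x, "stage")) else ""))
  print(round(unclass(x), 4))
  invisible(x)
}

#' Fisher R-to-Z transform
#'
#' @param r correlation value(s), `|r| < 1`.
#' @return `atanh(r)`.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1, na.rm = TRUE)) {
    stop_config("fisher_z requires |r| < 1")
  }
  atanh(r)
}

#' Vectorise the upper triangle of a network matrix
#'
#' Returns the row-major upper triangle excluding the diagonal (length
#' `n (n - 1) / 2`), the standard edge ordering used for cross-subject edge
#' analyses.
#'
#' @param nm a square matrix or `netmat`.
#' @return numeric edge vector.
#' @export
edge_vector <- function(nm) {
  m <- unclass(nm)
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  t(m)[lower.tri(m)]
}

# Indices (i, j) of the edges in edge_vector() order.
edge_index <- function(n_modes) {
  idx <- which(upper.tri(matrix(0, n_modes, n_modes)), arr.ind = TRUE)
  idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
}
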