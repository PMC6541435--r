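#' Fit a Gaussian/Gamma mixture model to a spatial map
#'
#' Models the voxelwise weights of one component map as a mixture of a
#' Gaussian background and two Gamma tails (one for positive, one for
#' negative excursions), fitted by EM. The Gamma components are offset to
#' start at the background mean: during a short initial anchoring phase the
#' offsets track the current background mean, after which they are frozen
#' and the EM iterations — whose recorded log-likelihood trace is then
#' guaranteed non-decreasing — run to convergence. The Gamma M-step uses the
#' proper weighted maximum-likelihood update (digamma equation solved by
#' Newton's method), not moment matching.
#'
#' A tail component is dropped (and the remaining components refitted) when
#' its mixing proportion falls below `drop_prop` or its responsibility-
#' weighted voxel count below `drop_count`.
#'
#' For large maps the mixture is fitted to the weight histogram (binned
#' likelihood with bin counts as weights), the standard approach for
#' component-map mixture modelling; small inputs are fitted exactly.
#'
#' @param map numeric vector of voxel weights (>= 100 finite values with
#'   nonzero spread).
#' @param max_iter EM iteration cap; if reached, the best fit so far is
#'   returned with `converged = FALSE`.
#' @param tol relative log-likelihood convergence tolerance.
#' @param anchor_iter iterations of the offset-anchoring phase.
#' @param drop_prop,drop_count tail-dropping thresholds.
#' @param bins histogram resolution for the binned fit; inputs with at most
#'   `4 * bins` values are fitted exactly.
#' @return an object of class `ggm_fit` with elements `mu`, `sigma`
#'   (background), `pos` and `neg` (each `shape`, `scale`, `offset`, or
#'   `NULL` if dropped), `prop` (mixing proportions: background, positive,
#'   negative), `loglik`, `ll_trace`, `iterations`, `converged`,
#'   `components_dropped`, `n`.
#' @examples
#' set.seed(1)
#' x <- c(rnorm(8000), 4 + rgamma(1500, 3, scale = 2),
#'        -4 - rgamma(500, 3, scale = 2))
#' fit <- fit_ggm(x)
#' fit
#' coef(fit)[c("mu", "sigma")]
#' @export
fit_ggm <- function(map, max_iter = 2000L, tol = 1e-8, anchor_iter = 5L,
                    drop_prop = 0.001, drop_count = 10, bins = 512L) {
  x <- as.numeric(map)
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 100L) stop_config("need at least 100 finite values, got %d", n)
  if (stats::sd(x) < .Machine$double.eps^0.5) {
    stop_config("degenerate all-constant map")
  }

  # EM support points: raw values for small inputs, histogram bin centres
  # weighted by counts for large ones
  if (n > 4L * bins) {
    breaks <- seq(min(x), max(x), length.out = bins + 1L)
    h <- graphics::hist(x, breaks = breaks, plot = FALSE)
    keep <- h$counts > 0L
    xv <- h$mids[keep]
    w <- as.numeric(h$counts[keep])
    # the background scale cannot be resolved below the bin resolution
    sigma_floor <- breaks[2] - breaks[1]
  } else {
    xv <- x
    w <- rep(1, n)
    sigma_floor <- 1e-8
  }

  # robust initialisation: IQR-trimmed background moments; method-of-moments
  # Gammas on the excursions beyond +/- 1 trimmed SD; mixing proportions
  # from the excess tail mass beyond +/- 2 trimmed SD
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
  iqr <- q[2] - q[1]
  kept <- x[x >= q[1] - 1.5 * iqr & x <= q[2] + 1.5 * iqr]
  mu <- mean(kept)
  sigma <- max(stats::sd(kept), sigma_floor, 1e-8)
  gamma_init <- function(y) {
    if (length(y) < 10L || stats::var(y) == 0) {
      c(shape = 2, scale = sigma)
    } else {
      v <- stats::var(y)
      c(shape = max(mean(y)^2 / v, 1 + 1e-6), scale = v / mean(y))
    }
  }
  gp <- gamma_init(x[x > mu + sigma] - mu)
  gn <- gamma_init(mu - x[x < mu - sigma])
  # initial mixing from the tail mass in excess of the Gaussian prediction:
  # a tail with no excess mass to explain starts inactive and is pruned,
  # which keeps tail-free maps identifiable as a pure background
  gauss_tail <- stats::pnorm(-2)
  p_pos <- max(0, mean(x > mu + 2 * sigma) - gauss_tail)
  p_neg <- max(0, mean(x < mu - 2 * sigma) - gauss_tail)
  active <- c(p_pos >= drop_prop, p_neg >= drop_prop)
  dropped <- c(pos = !active[1], neg = !active[2])
  prop <- c(1 - p_pos * active[1] - p_neg * active[2],
            p_pos * active[1], p_neg * active[2])
  off_p <- off_n <- mu

  dens <- function() {
    f <- cbind(stats::dnorm(xv, mu, sigma), 0, 0)
    if (active[1]) {
      up <- xv > off_p
      f[up, 2] <- stats::dgamma(xv[up] - off_p, shape = gp["shape"],
                                scale = gp["scale"])
    }
    if (active[2]) {
      dn <- xv < off_n
      f[dn, 3] <- stats::dgamma(off_n - xv[dn], shape = gn["shape"],
                                scale = gn["scale"])
    }
    f
  }

  # weighted Gamma MLE: solve log(k) - digamma(k) = log(wmean) - wmean(log y)
  gamma_mstep <- function(y, w) {
    sw <- sum(w)
    wm <- sum(w * y) / sw
    s <- log(wm) - sum(w * log(y)) / sw
    s <- max(s, 1e-10)
    k <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
    for (i in 1:25) {
      step <- (log(k) - digamma(k) - s) / (1 / k - trigamma(k))
      k_new <- k - step
      if (!is.finite(k_new) || k_new <= 0) k_new <- k / 2
      if (abs(k_new - k) < 1e-12 * k) {
        k <- k_new
        break
      }
      k <- k_new
    }
    k <- min(max(k, 1 + 1e-6), 1e4)
    c(shape = k, scale = wm / k)
  }

  # components may be pruned only while `drop_enabled`; with a fixed
  # component set each pass is a proper (generalised) EM step, so the
  # recorded log-likelihood trace is non-decreasing
  drop_enabled <- TRUE
  em_pass <- function() {
    f <- dens()
    wf <- sweep(f, 2L, prop, "*")
    tot <- rowSums(wf)
    tot[tot < 1e-300] <- 1e-300
    r <- wf / tot
    ll <- sum(w * log(tot))

    # M-step (all sums weighted by the support-point weights w)
    wr <- w * r
    prop_new <- colSums(wr) / n
    for (j in 2:3) {
      i <- j - 1L
      if (drop_enabled && active[i] &&
          (prop_new[j] < drop_prop || sum(wr[, j]) < drop_count)) {
        active[i] <<- FALSE
        dropped[i] <<- TRUE
        r[, j] <- 0
        r <- r / pmax(rowSums(r), 1e-300)
        wr <- w * r
        prop_new <- colSums(wr) / n
      }
    }
    prop <<- prop_new / sum(prop_new)
    sw0 <- sum(wr[, 1])
    if (sw0 > 1e-12) {
      mu <<- sum(wr[, 1] * xv) / sw0
      sigma <<- max(sqrt(sum(wr[, 1] * (xv - mu)^2) / sw0), sigma_floor, 1e-8)
    }
    if (active[1]) {
      up <- xv > off_p
      if (sum(wr[up, 2]) >= drop_count) {
        gp <<- gamma_mstep(xv[up] - off_p, wr[up, 2])
      }
    }
    if (active[2]) {
      dn <- xv < off_n
      if (sum(wr[dn, 3]) >= drop_count) {
        gn <<- gamma_mstep(off_n - xv[dn], wr[dn, 3])
      }
    }
    ll
  }

  # anchoring phase: offsets follow the background mean (not part of the
  # monotone EM trace)
  for (i in seq_len(anchor_iter)) {
    em_pass()
    off_p <- off_n <- mu
  }
  drop_enabled <- FALSE

  # frozen-offset EM phase
  ll_trace <- numeric(0)
  converged <- FALSE
  iterations <- 0L
  ll_prev <- -Inf
  for (i in seq_len(max_iter)) {
    ll <- em_pass()
    ll_trace <- c(ll_trace, ll)
    iterations <- i
    if (is.finite(ll_prev) && ll - ll_prev < tol * (abs(ll) + 1)) {
      converged <- TRUE
      break
    }
    ll_prev <- ll
  }
  # final log-likelihood at the last parameter values
  f <- dens()
  tot <- pmax(as.numeric(f %*% prop), 1e-300)
  loglik <- sum(w * log(tot))

  structure(list(
    mu = mu, sigma = sigma,
    pos = if (active[1]) list(shape = unname(gp["shape"]),
                              scale = unname(gp["scale"]), offset = off_p),
    neg = if (active[2]) list(shape = unname(gn["shape"]),
                              scale = unname(gn["scale"]), offset = off_n),
    prop = stats::setNames(prop, c("background", "positive", "negative")),
    loglik = loglik, ll_trace = ll_trace, iterations = iterations,
    converged = converged, components_dropped = dropped, n = n
  ), class = "ggm_fit")
}

#' @export
print.ggm_fit <- function(x, ...) {
  cat("Gaussian/Gamma mixture fit\n")
  cat(sprintf("  background: mu = %.4f, sigma = %.4f (prop %.3f)\n",
              x$mu, x$sigma, x$prop[1]))
  if (!is.null(x$pos)) {
    cat(sprintf("  positive tail: Gamma(shape %.3f, scale %.3f) + %.4f (prop %.3f)\n",
                x$pos$shape, x$pos$scale, x$pos$offset, x$prop[2]))
  } else cat("  positive tail: dropped\n")
  if (!is.null(x$neg)) {
    cat(sprintf("  negative tail: Gamma(shape %.3f, scale %.3f) below %.4f (prop %.3f)\n",
                x$neg$shape, x$neg$scale, x$neg$offset, x$prop[3]))
  } else cat("  negative tail: dropped\n")
  cat(sprintf("  log-likelihood %.2f after %d EM iterations (converged: %s)\n",
              x$loglik, x$iterations, x$converged))
  invisible(x)
}

#' @export
coef.ggm_fit <- function(object, ...) {
  c(mu = object$mu, sigma = object$sigma,
    prop_background = unname(object$prop[1]),
    prop_positive = unname(object$prop[2]),
    prop_negative = unname(object$prop[3]),
    pos_shape = if (is.null(object$pos)) NA_real_ else object$pos$shape,
    pos_scale = if (is.null(object$pos)) NA_real_ else object$pos$scale,
    neg_shape = if (is.null(object$neg)) NA_real_ else object$neg$shape,
    neg_scale = if (is.null(object$neg)) NA_real_ else object$neg$scale)
}

#' @export
logLik.ggm_fit <- function(object, ...) {
  p <- 3L + 2L * (!is.null(object$pos)) + 2L * (!is.null(object$neg))
  structure(object$loglik, df = p, nobs = object$n, class = "logLik")
}

#' Posterior component membership under a Gaussian/Gamma mixture fit
#'
#' @param object a [fit_ggm()] result.
#' @param newdata numeric vector of weights; defaults cannot be stored, so
#'   this is required.
#' @param ... unused.
#' @return matrix of posterior probabilities with columns `background`,
#'   `positive`, `negative`.
#' @export
predict.ggm_fit <- function(object, newdata, ...) {
  x <- as.numeric(newdata)
  f <- cbind(stats::dnorm(x, object$mu, object$sigma), 0, 0)
  if (!is.null(object$pos)) {
    up <- x > object$pos$offset
    f[up, 2] <- stats::dgamma(x[up] - object$pos$offset,
                              shape = object$pos$shape,
                              scale = object$pos$scale)
  }
  if (!is.null(object$neg)) {
    dn <- x < object$neg$offset
    f[dn, 3] <- stats::dgamma(object$neg$offset - x[dn],
                              shape = object$neg$shape,
                              scale = object$neg$scale)
  }
  wf <- sweep(f, 2L, object$prop, "*")
  r <- wf / pmax(rowSums(wf), 1e-300)
  colnames(r) <- c("background", "positive", "negative")
  r
}

#' @export
plot.ggm_fit <- function(x, data = NULL, breaks = 100, ...) {
  if (is.null(data)) {
    stop("supply the fitted map via `data` to plot the fit", call. = FALSE)
  }
  h <- graphics::hist(data, breaks = breaks, freq = FALSE,
                      main = "Gaussian/Gamma mixture fit",
                      xlab = "voxel weight", border = "grey70", ...)
  grid <- seq(min(h$breaks), max(h$breaks), length.out = 512)
  f0 <- x$prop[1] * stats::dnorm(grid, x$mu, x$sigma)
  graphics::lines(grid, f0, col = "steelblue", lwd = 2)
  if (!is.null(x$pos)) {
    fp <- ifelse(grid > x$pos$offset,
                 x$prop[2] * stats::dgamma(grid - x$pos$offset,
                                           shape = x$pos$shape,
                                           scale = x$pos$scale), 0)
    graphics::lines(grid, fp, col = "firebrick", lwd = 2)
  }
  if (!is.null(x$neg)) {
    fn <- ifelse(grid < x$neg$offset,
                 x$prop[3] * stats::dgamma(x$neg$offset - grid,
                                           shape = x$neg$shape,
                                           scale = x$neg$scale), 0)
    graphics::lines(grid, fn, col = "darkorange", lwd = 2)
  }
  invisible(x)
}

#' Stage 3: mixture-model thresholding of subject maps
#'
#' Transforms each map to pseudo-z values using its fitted background
#' parameters, `z = (w - mu) / sigma`, zeroes entries with `|z| < threshold`
#' and keeps the signed z-value of surviving entries (the scale cancels in
#' downstream regressions and correlations). The boundary value
#' `|z| = threshold` survives.
#'
#' @param maps modes x voxels matrix of stage-2 subject maps.
#' @param fits list of [fit_ggm()] objects, one per map row.
#' @param threshold pseudo-z threshold (default 2, applied as +/- 2).
#' @return thresholded modes x voxels matrix; the attribute `all_zero` flags
#'   maps with no surviving voxels. Unconverged fits are used with a
#'   warning.
#' @export
stage3_threshold <- function(maps, fits, threshold = 2) {
  maps <- rbind(maps)
  stopifnot(length(fits) == nrow(maps), threshold >= 0)
  out <- matrix(0, nrow(maps), ncol(maps))
  all_zero <- logical(nrow(maps))
  for (j in seq_len(nrow(maps))) {
    fit <- fits[[j]]
    stopifnot(inherits(fit, "ggm_fit"))
    if (!fit$converged) {
      warning(sprintf("mixture fit for mode %d did not converge; thresholding with best fit", j),
              call. = FALSE)
    }
    if (fit$sigma <= 0) stop_config("zero background sigma for mode %d", j)
    z <- (maps[j, ] - fit$mu) / fit$sigma
    keep <- abs(z) >= threshold
    out[j, keep] <- z[keep]
    all_zero[j] <- !any(keep)
  }
  attr(out, "all_zero") <- all_zero
  out
}
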