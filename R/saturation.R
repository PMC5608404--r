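# Theta-resampling across subset sizes: how many individuals of a species
# are enough before mean intraspecific distance stops moving?
#
# theta of a subset = mean pairwise K2P distance among its members.  For
# every subset size n in 2..N, `replicates` random subsets are drawn and
# their thetas recorded; the trend statistic at n is the maximum of the
# replicate thetas.  A species is sufficiently sampled at the smallest n
# from which the trend stays at or below the upper limit of the
# high-confidence (default 99.99%) Student-t interval of the full-sample
# mean distance.

#' Mean pairwise distance of a subset (theta)
#'
#' @param mat Distance matrix.
#' @param subset Character vector of at least two sample IDs.
#' @return Arithmetic mean of the `C(n,2)` pairwise distances.
#' @export
theta <- function(mat, subset) {
  stopifnot(length(subset) >= 2L)
  m <- mat[subset, subset, drop = FALSE]
  vals <- m[upper.tri(m)]
  if (anyNA(vals)) {
    bad <- which(is.na(m) & upper.tri(m), arr.ind = TRUE)[1L, ]
    stop(sprintf("UNDEFINED distance between '%s' and '%s'",
                 subset[bad[1L]], subset[bad[2L]]))
  }
  mean(vals)
}

#' Student-t confidence interval of a mean
#'
#' `mean +/- t[(1+c)/2, m-1] * sd / sqrt(m)`.  Here the observations are the
#' individual pairwise distances of the full sample, treated as independent
#' (they are not -- each individual appears in many pairs -- but this is the
#' interval a one-sample analysis of the distance matrix produces, and the
#' procedure is reproduced as practised).  Zero variance gives the
#' degenerate interval (mean, mean).
#'
#' @param x Numeric vector, length >= 2.
#' @param confidence Confidence level in (0, 1); default 0.9999.
#' @return Named numeric: `low`, `high`.
#' @export
mean_ci <- function(x, confidence = 0.9999) {
  m <- length(x)
  stopifnot(m >= 2L, confidence > 0, confidence < 1)
  mu <- mean(x)
  s <- sd(x)
  if (s == 0) return(c(low = mu, high = mu))
  half <- qt((1 + confidence) / 2, df = m - 1) * s / sqrt(m)
  c(low = mu - half, high = mu + half)
}

#' Theta-resampling saturation curve for one species
#'
#' @param mat Distance matrix covering at least the chosen samples, with all
#'   within-species entries defined.
#' @param sample_ids Sample IDs of the species (>= 3); defaults to all rows.
#' @param replicates Random subsets drawn per size (default 20).
#' @param seed Integer seed (mandatory).
#' @param confidence Confidence level of the full-sample interval
#'   (default 0.9999).
#' @param species Optional species name carried into the result.
#' @return Object of class `saturation_curve`: `species`, `N`, `table`
#'   (data frame: `n`, `mean_theta`, `trend_theta`), `replicate_thetas`
#'   (matrix, `replicates` x sizes), `theta_full`, `ci_low`, `ci_high`,
#'   `n_min`, `replicates`, `seed`, `confidence`.
#' @export
saturation_curve <- function(mat, sample_ids = NULL, replicates = 20L, seed,
                             confidence = 0.9999, species = NA_character_) {
  if (missing(seed)) stop("a seed is mandatory")
  if (is.null(sample_ids)) sample_ids <- rownames(mat)
  N <- length(sample_ids)
  if (N < 3L) stop("need at least 3 samples")
  sub <- mat[sample_ids, sample_ids]
  pd <- sub[upper.tri(sub)]
  if (anyNA(pd)) theta(mat, sample_ids)  # raises the informative error
  theta_full <- mean(pd)
  ci <- mean_ci(pd, confidence)
  sizes <- 2L:N
  reps <- matrix(NA_real_, nrow = replicates, ncol = length(sizes),
                 dimnames = list(NULL, sizes))
  set.seed(seed)
  for (k in seq_along(sizes)) {
    for (r in seq_len(replicates)) {
      s <- sample(sample_ids, sizes[k])
      reps[r, k] <- theta(sub, s)
    }
  }
  tab <- data.frame(n = sizes,
                    mean_theta = colMeans(reps),
                    trend_theta = apply(reps, 2L, max),
                    row.names = NULL)
  out <- structure(list(species = species, N = N, table = tab,
                        replicate_thetas = reps, theta_full = theta_full,
                        ci_low = unname(ci["low"]), ci_high = unname(ci["high"]),
                        n_min = NA_integer_, replicates = replicates,
                        seed = seed, confidence = confidence),
                   class = "saturation_curve")
  out$n_min <- minimum_sample_size(out)
  out
}

#' Minimum sufficient sample size from a saturation curve
#'
#' Under the default stability rule, the minimum sample size is the smallest
#' `n` such that the trend statistic (max replicate theta) is at or below
#' the full-sample upper confidence limit for every size `n' >= n` -- a
#' single momentary dip does not qualify.  `rule = "first"` instead takes
#' the first crossing, for sensitivity analysis.  `NA` means the criterion
#' was never reached (NOT_REACHED).
#'
#' @param curve A [saturation_curve()], or a data frame with columns `n` and
#'   `trend_theta` (then `ci_high` must be supplied).
#' @param ci_high Upper confidence limit (taken from the curve if absent).
#' @param rule `"stable"` (default) or `"first"`.
#' @return Integer sample size, or `NA_integer_`.
#' @export
minimum_sample_size <- function(curve, ci_high = NULL,
                                rule = c("stable", "first")) {
  rule <- match.arg(rule)
  if (inherits(curve, "saturation_curve")) {
    tab <- curve$table
    if (is.null(ci_high)) ci_high <- curve$ci_high
  } else {
    tab <- as.data.frame(curve)
    if (is.null(ci_high)) stop("ci_high must be supplied with a bare table")
  }
  ok <- tab$trend_theta <= ci_high
  idx <- if (rule == "first") {
    which(ok)[1L]
  } else {
    below_from_here <- rev(cumprod(rev(ok))) > 0
    which(below_from_here)[1L]
  }
  if (is.na(idx)) NA_integer_ else as.integer(tab$n[idx])
}

#' @export
print.saturation_curve <- function(x, ...) {
  cat(sprintf("Saturation curve for %s: N = %d, %d replicates, seed %d\n",
              x$species, x$N, x$replicates, x$seed))
  cat(sprintf("  full-sample theta %.5f, %.2f%% CI upper limit %.5f\n",
              x$theta_full, 100 * x$confidence, x$ci_high))
  cat(sprintf("  minimum sufficient sample size: %s\n",
              if (is.na(x$n_min)) "NOT REACHED" else x$n_min))
  invisible(x)
}

#' Scatter + trend plot of a saturation curve
#'
#' Replicate thetas as points, the max-trend line, the upper confidence
#' limit as a horizontal line, and an arrow at the minimum sufficient size.
#'
#' @param x A `saturation_curve`.
#' @param ... Passed to `plot()`.
#' @export
plot_saturation <- function(x, ...) {
  sizes <- x$table$n
  matplot(sizes, t(x$replicate_thetas), pch = 1, col = "grey60",
          xlab = "sample size", ylab = expression(theta), ...)
  lines(sizes, x$table$trend_theta, col = "red", lwd = 2)
  abline(h = x$ci_high, lty = 2)
  if (!is.na(x$n_min))
    arrows(x$n_min, max(x$table$trend_theta), x$n_min,
           x$table$trend_theta[x$table$n == x$n_min],
           col = "red", length = 0.1)
  invisible(x)
}
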