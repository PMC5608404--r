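# Principal coordinate analysis of a distance matrix (Gower double
# centering), with explicit reporting of negative eigenvalues.

#' Principal coordinate analysis
#'
#' Classical metric ordination: the squared distance matrix is double-centred
#' (`B = -1/2 J (D*D) J`), eigendecomposed, and coordinates are the
#' eigenvectors scaled by the square roots of the positive eigenvalues.
#' Negative eigenvalues (non-Euclidean input) are dropped from the
#' coordinates and reported; no Lingoes/Cailliez correction is applied.
#' Each axis is flipped so its largest-magnitude loading is positive, which
#' makes plots reproducible across platforms.
#'
#' @param mat Symmetric distance matrix with no UNDEFINED (NA) entries:
#'   callers must filter or impute explicitly first.
#' @return List of class `pcoa_result`: `coordinates` (samples x axes, only
#'   positive-eigenvalue axes), `eigenvalues` (all, descending),
#'   `proportion_explained` (percent of the positive-eigenvalue sum, one per
#'   retained axis), `negative_count`, `negative_magnitude` (sum of absolute
#'   negative eigenvalues).
#' @export
principal_coordinates <- function(mat) {
  stopifnot(is.matrix(mat), nrow(mat) == ncol(mat), nrow(mat) >= 2L)
  na_idx <- which(is.na(mat) & upper.tri(mat), arr.ind = TRUE)
  if (nrow(na_idx))
    stop("UNDEFINED distances for pairs: ",
         paste(sprintf("(%s,%s)", rownames(mat)[na_idx[, 1L]],
                       colnames(mat)[na_idx[, 2L]]),
               collapse = " "), "; filter these samples first")
  n <- nrow(mat)
  A <- -0.5 * unclass(mat)^2
  J <- diag(n) - matrix(1 / n, n, n)
  B <- J %*% A %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  tol <- max(abs(e$values), 0) * 1e-10
  pos <- which(e$values > tol)
  neg <- which(e$values < -tol)
  coords <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), length(pos))
  # sign convention: largest-|loading| entry of each axis made positive
  for (k in seq_len(ncol(coords))) {
    i <- which.max(abs(coords[, k]))
    if (coords[i, k] < 0) coords[, k] <- -coords[, k]
  }
  rownames(coords) <- rownames(mat)
  if (ncol(coords))
    colnames(coords) <- paste0("Axis", seq_len(ncol(coords)))
  prop <- if (length(pos)) 100 * e$values[pos] / sum(e$values[pos])
          else numeric(0)
  structure(list(coordinates = coords,
                 eigenvalues = e$values,
                 proportion_explained = prop,
                 negative_count = length(neg),
                 negative_magnitude = sum(abs(e$values[neg]))),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat(sprintf("PCoA: %d samples, %d positive axes (%d negative eigenvalues, |sum| = %.3g)\n",
              nrow(x$coordinates), ncol(x$coordinates),
              x$negative_count, x$negative_magnitude))
  if (length(x$proportion_explained))
    cat("  % explained:",
        paste(sprintf("%.2f", head(x$proportion_explained, 5L)),
              collapse = ", "), "\n")
  invisible(x)
}

#' Export PCoA coordinates with sample metadata
#'
#' @param res A [principal_coordinates()] result.
#' @param meta Metadata data frame (`sample_id`, `species`, `group`).
#' @return Data frame ready for plotting or [write_table()].
#' @export
pcoa_scores <- function(res, meta) {
  stopifnot(inherits(res, "pcoa_result"))
  ids <- rownames(res$coordinates)
  m <- meta[match(ids, meta$sample_id), c("sample_id", "species", "group")]
  cbind(m, as.data.frame(res$coordinates), row.names = NULL)
}

#' Scatter plot of the first two principal coordinates, coloured by habitat
#'
#' @param x A `pcoa_result`.
#' @param meta Metadata with `sample_id` and `group`.
#' @param ... Passed to `plot()`.
#' @export
plot_pcoa <- function(x, meta, ...) {
  co <- x$coordinates
  if (ncol(co) < 2L)
    stop("fewer than two positive axes; a 2-D plot cannot be drawn")
  grp <- meta$group[match(rownames(co), meta$sample_id)]
  col <- c(inland = "darkgreen", coastal = "orange",
           unassigned = "grey50")[grp]
  plot(co[, 1L], co[, 2L], col = col, pch = 19,
       xlab = sprintf("Axis 1 (%.1f%%)", x$proportion_explained[1L]),
       ylab = sprintf("Axis 2 (%.1f%%)", x$proportion_explained[2L]), ...)
  invisible(x)
}
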