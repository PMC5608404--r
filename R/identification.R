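# Best-close-match identification (TaxonDNA-style) and the pairwise-summary
# intraspecific distance threshold.

#' Intraspecific distance threshold ("pairwise summary")
#'
#' Returns a percentile of all defined intraspecific pairwise distances, the
#' usual way a best-close-match threshold is derived when it is not fixed a
#' priori (the conventional fixed value for plant barcodes is 0.03).
#' Interpolation follows `stats::quantile()` type 7 (the R default).
#'
#' @param mat A distance matrix from [pairwise_matrix()].
#' @param species Character vector of species labels, one per sample (in
#'   matrix order), or NULL to take them from the matrix's originating set.
#' @param percentile Percentile in (0, 100]; default 95.
#' @return The threshold distance (a single number).
#' @export
intraspecific_threshold <- function(mat, species, percentile = 95) {
  stopifnot(is.matrix(mat), nrow(mat) == ncol(mat),
            length(species) == nrow(mat), percentile > 0, percentile <= 100)
  same <- outer(species, species, `==`)
  vals <- mat[upper.tri(mat) & same]
  vals <- vals[!is.na(vals)]
  if (!length(vals))
    stop("no defined intraspecific pairs: supply a fixed threshold instead")
  unname(quantile(vals, percentile / 100, type = 7))
}

#' Best close match classification
#'
#' Each sample is treated as a query against all other samples.  With `m` the
#' smallest defined distance from the query: if `m > threshold` the query
#' gets `no_id`; otherwise let `S` be the set of species found within
#' `tie_tol` of `m` -- `correct` if `S` is exactly the query's species,
#' `ambiguous` if the query's species is in `S` along with others, and
#' `incorrect` otherwise.  The threshold comparison is inclusive.  Queries
#' with no defined distance to any other sample are reported as
#' `uncomparable` and excluded from the percentages.
#'
#' @param mat Distance matrix ([pairwise_matrix()]).
#' @param species Species label per sample, in matrix order.
#' @param threshold Distance threshold (default 0.03, the conventional 3%).
#' @param tie_tol Absolute tolerance for "equal minimum distance"
#'   (default 1e-12, collapsing floating-point ties only).
#' @return An object of class `bcm_summary`: list with `per_query` (data
#'   frame: `sample_id`, `species`, `category`, `closest_distance`,
#'   `closest_species`), `summary` (one-row data frame with percentages
#'   `a` correct, `b` ambiguous, `c` incorrect, `d` no_id, rounded to 2
#'   decimals), `threshold`, `n_queries`, `n_uncomparable`.
#' @export
best_close_match <- function(mat, species, threshold = 0.03,
                             tie_tol = 1e-12) {
  stopifnot(is.matrix(mat), nrow(mat) >= 2L, length(species) == nrow(mat),
            threshold >= 0)
  ids <- rownames(mat)
  n <- nrow(mat)
  category <- character(n)
  closest <- rep(NA_real_, n)
  closest_sp <- character(n)
  for (q in seq_len(n)) {
    dq <- mat[q, -q]
    sp <- species[-q]
    ok <- !is.na(dq)
    if (!any(ok)) {
      category[q] <- "uncomparable"
      closest_sp[q] <- ""
      next
    }
    m <- min(dq[ok])
    closest[q] <- m
    S <- unique(sp[ok & dq <= m + tie_tol])
    closest_sp[q] <- paste(sort(S), collapse = ",")
    category[q] <- if (m > threshold) {
      "no_id"
    } else if (length(S) == 1L && S == species[q]) {
      "correct"
    } else if (species[q] %in% S) {
      "ambiguous"
    } else {
      "incorrect"
    }
  }
  per_query <- data.frame(sample_id = ids, species = species,
                          category = category, closest_distance = closest,
                          closest_species = closest_sp,
                          stringsAsFactors = FALSE)
  scored <- category[category != "uncomparable"]
  pct <- function(k) round(100 * sum(scored == k) / length(scored), 2)
  summary <- data.frame(a = pct("correct"), b = pct("ambiguous"),
                        c = pct("incorrect"), d = pct("no_id"),
                        n = length(scored))
  structure(list(per_query = per_query, summary = summary,
                 threshold = threshold, n_queries = length(scored),
                 n_uncomparable = sum(category == "uncomparable")),
            class = "bcm_summary")
}

#' @export
print.bcm_summary <- function(x, ...) {
  cat(sprintf("Best close match at threshold %g (%d queries, %d uncomparable)\n",
              x$threshold, x$n_queries, x$n_uncomparable))
  cat(sprintf("  correct %.2f%%  ambiguous %.2f%%  incorrect %.2f%%  no ID %.2f%%\n",
              x$summary$a, x$summary$b, x$summary$c, x$summary$d))
  invisible(x)
}
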