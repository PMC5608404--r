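# Species discrimination rate from a support-annotated tree, and a
# neighbor-joining builder used to create test fixtures.

#' Species discrimination rate from a support-annotated tree
#'
#' A species with two or more tips counts as discriminated when its tips form
#' an exclusive clade (all of and only that species' samples) whose node
#' support is strictly greater than `support_cutoff`.  Missing supports are
#' treated as untrustworthy.  Singleton species are reported separately and,
#' by default, excluded from both numerator and denominator.
#'
#' @param tree A [support_tree()].
#' @param support_cutoff Support above which a branch is trusted
#'   (default 0.95, i.e. "over 95%", strict).
#' @param singletons `"exclude"` (default) or `"count_as_fail"`.
#' @param outgroup Sample IDs to prune before evaluation; defaults to samples
#'   whose metadata has a truthy `outgroup` column.  For an unrooted tree the
#'   outgroup is used to root it first; an unrooted tree without an outgroup
#'   is an error.
#' @return List of class `discrimination_result` with `rate` (percent),
#'   `per_species` (data frame: `species`, `n_tips`, `status`, `support`),
#'   `support_cutoff`.
#' @export
discrimination_rate <- function(tree, support_cutoff = 0.95,
                                singletons = c("exclude", "count_as_fail"),
                                outgroup = NULL) {
  stopifnot(inherits(tree, "support_tree"))
  singletons <- match.arg(singletons)
  phy <- tree$phy
  support <- tree$support
  meta <- tree$meta
  if (is.null(outgroup) && !is.null(meta$outgroup))
    outgroup <- meta$sample_id[as.logical(meta$outgroup) %in% TRUE]
  if (!ape::is.rooted(phy)) {
    if (length(outgroup)) {
      phy$node.label <- as.character(support)
      phy <- ape::root(phy, outgroup = outgroup, resolve.root = TRUE)
      support <- suppressWarnings(as.numeric(phy$node.label))
    } else {
      stop("unrooted tree: supply an outgroup to root it")
    }
  }
  if (length(outgroup)) {
    keep <- setdiff(phy$tip.label, outgroup)
    if (length(keep) < 2L) stop("fewer than two tips after outgroup pruning")
    phy$node.label <- as.character(support)
    phy <- ape::keep.tip(phy, keep)
    support <- suppressWarnings(as.numeric(phy$node.label))
  }
  meta <- meta[match(phy$tip.label, meta$sample_id), , drop = FALSE]
  species <- split(phy$tip.label, meta$species)
  ntip <- length(phy$tip.label)
  status <- character(length(species))
  supp_out <- rep(NA_real_, length(species))
  for (k in seq_along(species)) {
    tips <- species[[k]]
    if (length(tips) == 1L) {
      status[k] <- "singleton"
      next
    }
    node <- ape::getMRCA(phy, tips)
    clade_tips <- ape::extract.clade(phy, node)$tip.label
    exclusive <- length(clade_tips) == length(tips)
    s <- support[node - ntip]
    supp_out[k] <- if (exclusive) s else NA_real_
    status[k] <- if (exclusive && !is.na(s) && s > support_cutoff)
      "discriminated" else "not_discriminated"
  }
  per_species <- data.frame(species = names(species),
                            n_tips = lengths(species),
                            status = status, support = supp_out,
                            stringsAsFactors = FALSE, row.names = NULL)
  denom_status <- if (singletons == "exclude")
    c("discriminated", "not_discriminated") else unique(status)
  denom <- sum(status %in% denom_status)
  rate <- if (denom == 0L) NA_real_
          else 100 * sum(status == "discriminated") / denom
  structure(list(rate = rate, per_species = per_species,
                 support_cutoff = support_cutoff),
            class = "discrimination_result")
}

#' @export
print.discrimination_result <- function(x, ...) {
  cat(sprintf("Tree discrimination rate: %.2f%% (support cutoff > %g)\n",
              x$rate, x$support_cutoff))
  print(x$per_species)
  invisible(x)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Thin wrapper over the Saitou-Nei agglomeration (as implemented in
#' `ape::nj()`), used in this package to build tree fixtures; supports are
#' absent from the result.  Refuses matrices with UNDEFINED (NA) entries.
#'
#' @param mat Symmetric distance matrix with >= 3 samples, no NA entries.
#' @return An `ape::phylo` tree (unrooted, no node supports).
#' @export
neighbor_joining <- function(mat) {
  stopifnot(is.matrix(mat), nrow(mat) >= 3L)
  if (anyNA(mat[upper.tri(mat)]))
    stop("distance matrix has UNDEFINED entries; cannot build a tree")
  ape::nj(unclass(mat))
}
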