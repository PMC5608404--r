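# DnaSP-style haplotype collapsing, the habitat-stratified haplotype table,
# and haplotype-proportional subsampling.

#' Collapse identical sequences into haplotypes
#'
#' Under `exclude_sites` (the default, mirroring DnaSP's "sites with
#' gaps/missing: not considered"), every column containing a gap, `N` or an
#' ambiguity code in any retained row is removed once; identical remaining
#' rows then share a haplotype.  Under `include`, rows are compared verbatim.
#' Haplotype indices are assigned in order of first occurrence.
#'
#' @param set An [aln_set()], typically one species at one locus.
#' @param gap_mode `"exclude_sites"` (default) or `"include"`.
#' @return Named integer vector: haplotype index per sample.
#' @export
collapse_haplotypes <- function(set, gap_mode = c("exclude_sites", "include")) {
  gap_mode <- match.arg(gap_mode)
  stopifnot(inherits(set, "aln_set"))
  keys <- set$seq
  if (gap_mode == "exclude_sites") {
    m <- .encode_alignment(set)
    keep <- colSums(m == 0L) == 0L
    if (!any(keep))
      stop(sprintf("all %d sites contain gaps/missing data; nothing left to compare",
                   ncol(m)))
    keys <- apply(m[, keep, drop = FALSE], 1L, paste, collapse = "")
  }
  idx <- match(keys, unique(keys))
  names(idx) <- names(set$seq)
  idx
}

#' Habitat-stratified haplotype table
#'
#' For every species, haplotypes are collapsed independently within the
#' inland samples, within the coastal samples, and within the combined set
#' (under `exclude_sites` the masked columns may differ between strata, which
#' is why the combined count need not equal a naive union).  Every sample
#' must carry a known habitat group.
#'
#' @param set An [aln_set()] (may hold several species).
#' @param gap_mode Passed to [collapse_haplotypes()].
#' @return Data frame of class `haplotype_table` with columns `species`,
#'   `group` (`inland`, `coastal`, `combined`), `a` (sample size) and `b`
#'   (haplotype count).
#' @export
haplotype_table <- function(set, gap_mode = c("exclude_sites", "include")) {
  gap_mode <- match.arg(gap_mode)
  stopifnot(inherits(set, "aln_set"))
  if (any(!set$meta$group %in% c("inland", "coastal")))
    stop("unknown group label: every sample must be inland or coastal")
  count_haps <- function(ids) {
    if (!length(ids)) return(0L)
    max(collapse_haplotypes(subset_samples(set, ids), gap_mode))
  }
  rows <- list()
  for (sp in unique(set$meta$species)) {
    sp_ids <- set$meta$sample_id[set$meta$species == sp]
    grp <- set$meta$group[match(sp_ids, set$meta$sample_id)]
    for (g in c("inland", "coastal", "combined")) {
      ids <- if (g == "combined") sp_ids else sp_ids[grp == g]
      rows[[length(rows) + 1L]] <- data.frame(
        species = sp, group = g, a = length(ids), b = count_haps(ids),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("haplotype_table", class(out))
  out
}

# Largest-remainder (Hamilton) apportionment of `target` seats over counts,
# with ties favouring unrepresented haplotypes, then larger haplotypes, then
# first occurrence; a repair pass guarantees one seat per haplotype whenever
# target >= number of haplotypes.
.largest_remainder <- function(counts, target, min_one = TRUE) {
  k <- length(counts)
  quota <- target * counts / sum(counts)
  alloc <- floor(quota)
  rem <- quota - alloc
  leftover <- target - sum(alloc)
  if (leftover > 0L) {
    ord <- order(-rem, alloc > 0L, -counts, seq_len(k))
    alloc[ord[seq_len(leftover)]] <- alloc[ord[seq_len(leftover)]] + 1L
  }
  if (min_one && target >= k) {
    while (any(alloc == 0L)) {
      need <- which(alloc == 0L)[order(-counts[which(alloc == 0L)])][1L]
      donor <- which(alloc == max(alloc))[1L]
      alloc[donor] <- alloc[donor] - 1L
      alloc[need] <- alloc[need] + 1L
    }
  }
  as.integer(alloc)
}

#' Haplotype-proportional subsampling
#'
#' Reduces a set to `target_n` samples while preserving the haplotype
#' frequency spectrum: per-haplotype quotas are allocated by
#' largest-remainder rounding of `target_n * frequency` (every observed
#' haplotype keeps at least one representative when `target_n` is at least
#' the number of haplotypes), and members within a haplotype are chosen
#' uniformly at random under the given seed.  This is the reduction applied
#' to over-collected species before saturation analysis.
#'
#' @param set An [aln_set()] (typically one species).
#' @param target_n Number of samples to keep.
#' @param seed Integer seed (mandatory; the choice within haplotypes is
#'   random).
#' @param gap_mode Passed to [collapse_haplotypes()].
#' @param allow_loss If FALSE (default), `target_n` below the number of
#'   haplotypes is an error.
#' @return An `aln_set` with `target_n` samples, in original input order.
#' @export
proportional_subsample <- function(set, target_n, seed,
                                   gap_mode = c("exclude_sites", "include"),
                                   allow_loss = FALSE) {
  gap_mode <- match.arg(gap_mode)
  stopifnot(inherits(set, "aln_set"), target_n >= 1L)
  if (missing(seed)) stop("a seed is mandatory")
  n <- length(set$seq)
  if (target_n > n) stop("target_n exceeds the current sample size")
  hap <- collapse_haplotypes(set, gap_mode)
  k <- max(hap)
  if (target_n < k && !allow_loss)
    stop(sprintf("target_n = %d cannot preserve all %d haplotypes (set allow_loss = TRUE to drop some)",
                 target_n, k))
  counts <- tabulate(hap, nbins = k)
  alloc <- .largest_remainder(counts, target_n, min_one = !allow_loss)
  set.seed(seed)
  keep <- character(0)
  for (h in seq_len(k)) {
    members <- names(hap)[hap == h]
    if (alloc[h] > 0L)
      keep <- c(keep, sample(members, alloc[h]))
  }
  keep <- names(set$seq)[names(set$seq) %in% keep]
  subset_samples(set, keep)
}
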