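# Aligned-sequence container, FASTA/metadata/newick readers and the
# tab-delimited writers shared by all downstream stages.

# Residues legal in an aligned barcode row (after upper-casing, U -> T).
.VALID_RESIDUES <- c("A", "C", "G", "T", "-", "N",
                     "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")
.GROUP_LEVELS <- c("inland", "coastal", "unassigned")

#' Aligned sequence set with sample metadata
#'
#' The universal input container: one locus, one row per sample, all rows the
#' same aligned length.  Residues are upper-cased and `U` is mapped to `T`;
#' gaps (`-`), `N` and IUPAC ambiguity codes are retained and masked later by
#' the site filters of the distance and haplotype stages.
#'
#' @param seqs Named character vector of aligned rows (names = sample IDs).
#' @param meta Data frame with columns `sample_id`, `species` and optionally
#'   `group` (`"inland"`, `"coastal"`; missing values become `"unassigned"`).
#'   Extra columns (e.g. `outgroup`) are kept.
#' @param locus Locus name (single string).
#'
#' @return An object of class `aln_set`: a list with elements `locus`,
#'   `meta` (one row per sample, same order as `seqs`) and `seq`.
#' @seealso [read_alignment()] to build one from files, [simulate_dataset()]
#'   to simulate one.
#' @export
aln_set <- function(seqs, meta, locus = NA_character_) {
  if (length(seqs) == 0L) stop("empty sequence set")
  if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == ""))
    stop("all sequences must be named by sample_id")
  if (anyDuplicated(names(seqs)))
    stop("duplicate sample_id: ", names(seqs)[duplicated(names(seqs))][1L])
  seqs <- toupper(seqs)
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  widths <- nchar(seqs)
  if (any(widths != widths[1L]))
    stop("alignment error: rows have unequal lengths (",
         paste(unique(widths), collapse = ", "), ")")
  if (widths[1L] < 1L) stop("alignment error: zero-length rows")
  bad <- .first_bad_residue(seqs)
  if (!is.null(bad))
    stop(sprintf("parse error: unknown residue '%s' in sample '%s' at position %d",
                 bad$char, bad$id, bad$pos))
  meta <- as.data.frame(meta)
  if (!all(c("sample_id", "species") %in% names(meta)))
    stop("metadata must contain columns sample_id and species")
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample_id in metadata")
  missing_meta <- setdiff(names(seqs), meta$sample_id)
  if (length(missing_meta))
    stop("reconciliation error: sample '", missing_meta[1L],
         "' present in sequences but missing from metadata")
  extra_meta <- setdiff(meta$sample_id, names(seqs))
  if (length(extra_meta))
    stop("reconciliation error: sample '", extra_meta[1L],
         "' present in metadata but missing from sequences")
  meta <- meta[match(names(seqs), meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  if (anyNA(meta$species) || any(meta$species == ""))
    stop("every sample must have a species label")
  if (is.null(meta$group)) meta$group <- "unassigned"
  meta$group <- as.character(meta$group)
  meta$group[is.na(meta$group) | meta$group == ""] <- "unassigned"
  unknown <- setdiff(unique(meta$group), .GROUP_LEVELS)
  if (length(unknown))
    stop("unknown group label: ", unknown[1L])
  structure(list(locus = locus, meta = meta, seq = seqs), class = "aln_set")
}

.first_bad_residue <- function(seqs) {
  res <- c(setdiff(.VALID_RESIDUES, "-"), "-")  # "-" must close the class
  pat <- paste0("[^", paste(res, collapse = ""), "]")
  hit <- regexpr(pat, seqs)
  i <- which(hit > 0L)
  if (!length(i)) return(NULL)
  i <- i[1L]
  list(id = names(seqs)[i], pos = as.integer(hit[i]),
       char = substr(seqs[i], hit[i], hit[i]))
}

#' @export
print.aln_set <- function(x, ...) {
  cat(sprintf("Aligned sequence set: %d samples x %d sites, locus %s\n",
              length(x$seq), nchar(x$seq[1L]), x$locus))
  cat(sprintf("  species: %d; groups: %s\n",
              length(unique(x$meta$species)),
              paste(sprintf("%s=%d", names(table(x$meta$group)),
                            table(x$meta$group)), collapse = ", ")))
  invisible(x)
}

#' Subset an aligned set by sample ID
#'
#' @param set An [aln_set()].
#' @param ids Sample IDs to keep (order preserved as given).
#' @return An `aln_set` restricted to `ids`.
#' @export
subset_samples <- function(set, ids) {
  stopifnot(inherits(set, "aln_set"))
  missing <- setdiff(ids, names(set$seq))
  if (length(missing)) stop("unknown sample_id: ", missing[1L])
  aln_set(set$seq[ids], set$meta[match(ids, set$meta$sample_id), , drop = FALSE],
          set$locus)
}

#' Read an aligned FASTA plus its sidecar metadata table
#'
#' FASTA headers carry the sample ID only; everything else (species, habitat
#' group, locus) lives in a tab-separated metadata table with columns
#' `sample_id`, `species`, and optionally `group` and `locus`.  The FASTA IDs
#' and the metadata `sample_id` column must match as sets; any discrepancy is
#' reported by name.
#'
#' @param fasta_path Path to an aligned FASTA file.
#' @param metadata_path Path to the TSV metadata table.
#' @return An [aln_set()].
#' @export
read_alignment <- function(fasta_path, metadata_path) {
  recs <- Biostrings::readBStringSet(fasta_path)
  seqs <- as.character(recs)
  # FASTA description lines may carry trailing comments; ID = first word
  names(seqs) <- vapply(strsplit(names(recs), "[ \t]"), `[`, "", 1L)
  meta <- read.delim(metadata_path, stringsAsFactors = FALSE,
                     colClasses = "character")
  locus <- if (!is.null(meta$locus)) unique(meta$locus)[1L] else NA_character_
  aln_set(seqs, meta, locus = locus)
}

#' Write an aligned set back to FASTA + metadata TSV
#'
#' @param set An [aln_set()].
#' @param fasta_path,metadata_path Output paths.
#' @return Invisibly, the paths.
#' @export
write_alignment <- function(set, fasta_path, metadata_path) {
  stopifnot(inherits(set, "aln_set"))
  writeLines(paste0(">", names(set$seq), "\n", unname(set$seq)), fasta_path)
  meta <- set$meta
  if (!is.null(set$locus) && !is.na(set$locus)) meta$locus <- set$locus
  write_table(meta, metadata_path)
  invisible(c(fasta_path, metadata_path))
}

#' Support-annotated tree tied to sample metadata
#'
#' Wraps an `ape` phylo object whose tips are sample IDs, together with the
#' metadata that maps each tip to a species.  Internal-node supports (Bayesian
#' posterior probabilities or bootstrap percentages) are normalised to the
#' [0, 1] scale: if any value exceeds 1 the whole tree is taken to be in
#' percent and divided by 100.
#'
#' @param phy An `ape::phylo` object with tip labels = sample IDs.
#' @param meta Metadata data frame (`sample_id`, `species`, ...).
#' @param support Numeric vector of internal-node supports in node order
#'   (length `phy$Nnode`); defaults to `phy$node.label` parsed as numbers.
#' @return An object of class `support_tree`.
#' @export
support_tree <- function(phy, meta, support = NULL) {
  stopifnot(inherits(phy, "phylo"))
  meta <- as.data.frame(meta)
  missing <- setdiff(phy$tip.label, meta$sample_id)
  if (length(missing))
    stop("reconciliation error: tip '", missing[1L], "' not in metadata")
  if (is.null(support)) {
    support <- if (is.null(phy$node.label)) rep(NA_real_, phy$Nnode)
               else suppressWarnings(as.numeric(phy$node.label))
  }
  if (length(support) != phy$Nnode)
    stop("support vector must have one entry per internal node")
  if (any(support > 1, na.rm = TRUE)) support <- support / 100
  if (any(support < 0 | support > 1, na.rm = TRUE))
    stop("supports outside [0, 1] after normalisation")
  meta <- meta[match(phy$tip.label, meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  structure(list(phy = phy, support = support, meta = meta),
            class = "support_tree")
}

#' Read a support-annotated newick tree
#'
#' @param newick_path Path to a newick file whose internal node labels carry
#'   support values (fractions or percentages, auto-detected).
#' @param meta Metadata data frame covering every tip.
#' @return A [support_tree()].
#' @export
read_tree <- function(newick_path, meta) {
  phy <- tryCatch(ape::read.tree(newick_path),
                  error = function(e) stop("parse error: malformed newick: ",
                                           conditionMessage(e)))
  if (is.null(phy)) stop("parse error: malformed newick")
  support_tree(phy, meta)
}

#' @export
print.support_tree <- function(x, ...) {
  cat(sprintf("Support tree: %d tips, %d internal nodes (%d with support)\n",
              length(x$phy$tip.label), x$phy$Nnode, sum(!is.na(x$support))))
  invisible(x)
}

#' Write / read a square distance matrix as TSV
#'
#' Values are written with 17 significant digits so that a write/read
#' round-trip reproduces the matrix to within 1e-12 relative error.
#'
#' @param mat Square numeric matrix with sample IDs as dimnames.
#' @param path Output path.
#' @return Invisibly, `path` (write) or the matrix (read).
#' @export
write_matrix <- function(mat, path) {
  if (is.null(mat) || length(mat) == 0L)
    stop("refusing to write an empty matrix")
  stopifnot(is.matrix(mat), nrow(mat) == ncol(mat))
  txt <- matrix(formatC(mat, digits = 17, format = "g"),
                nrow = nrow(mat), dimnames = dimnames(mat))
  txt[is.na(mat)] <- "NA"
  out <- cbind(sample_id = rownames(mat), txt)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- df[[1L]]
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  dimnames(m) <- list(ids, colnames(df)[-1L])
  m
}

#' Write a result table as TSV
#'
#' Refuses to write empty results: an empty file is never produced.
#'
#' @param df Data frame with at least one row.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_table <- function(df, path) {
  df <- as.data.frame(df)
  if (nrow(df) == 0L) stop("refusing to write an empty table")
  num <- vapply(df, is.double, TRUE)
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 17, format = "g"))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
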