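# Kimura 2-parameter and p-distances from aligned rows.
#
# Sites where either residue is a gap, N or an IUPAC ambiguity code are
# excluded from a comparison (full masking, the common MEGA setting).
# An entry whose comparison has no valid sites, or whose K2P logarithm
# argument is non-positive, is UNDEFINED and carried as NA -- never clamped.

# Encode rows as integers: A=1, C=2, G=3, T=4, everything else 0 (masked).
.encode_alignment <- function(set) {
  stopifnot(inherits(set, "aln_set"))
  m <- matrix(0L, nrow = length(set$seq), ncol = nchar(set$seq[1L]),
              dimnames = list(names(set$seq), NULL))
  chars <- strsplit(set$seq, "", fixed = TRUE)
  code <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  for (i in seq_along(chars)) {
    v <- code[chars[[i]]]
    v[is.na(v)] <- 0L
    m[i, ] <- v
  }
  m
}

# Transition / transversion counts for two encoded rows.  Among distinct
# ACGT pairs, code sums 4 (A+G) and 6 (C+T) identify the transitions.
.site_counts <- function(a, b) {
  v <- a > 0L & b > 0L
  nv <- sum(v)
  if (nv == 0L)
    return(list(valid_sites = 0L, transitions = 0L, transversions = 0L))
  d <- v & (a != b)
  s <- a + b
  ts <- sum(d & (s == 4L | s == 6L))
  list(valid_sites = nv, transitions = ts, transversions = sum(d) - ts)
}

#' Transition/transversion proportions for one aligned pair
#'
#' Compares two aligned rows site by site, masking every column where either
#' residue is a gap, `N` or an ambiguity code.  `P` and `Q` are the transition
#' (A<->G, C<->T) and transversion proportions over the remaining valid sites.
#'
#' @param row_a,row_b Aligned residue strings of equal length.
#' @return A list of class `site_comparison` with elements `P`, `Q`,
#'   `valid_sites`, `transitions`, `transversions`.  When no valid site
#'   remains, `valid_sites` is 0 and `P`, `Q` are `NA` (the comparison is
#'   undefined).
#' @examples
#' compare_sites("AAAA", "GAAA")  # one transition: P = 0.25
#' @export
compare_sites <- function(row_a, row_b) {
  if (length(row_a) != 1L || length(row_b) != 1L)
    stop("compare_sites() expects two single strings")
  if (nchar(row_a) != nchar(row_b))
    stop("alignment error: rows have unequal lengths")
  set <- aln_set(c(a = row_a, b = row_b),
                 data.frame(sample_id = c("a", "b"), species = "x"))
  m <- .encode_alignment(set)
  cnt <- .site_counts(m[1L, ], m[2L, ])
  P <- if (cnt$valid_sites > 0L) cnt$transitions / cnt$valid_sites else NA_real_
  Q <- if (cnt$valid_sites > 0L) cnt$transversions / cnt$valid_sites else NA_real_
  structure(list(P = P, Q = Q, valid_sites = cnt$valid_sites,
                 transitions = cnt$transitions,
                 transversions = cnt$transversions),
            class = "site_comparison")
}

#' Kimura 2-parameter distance from site proportions
#'
#' `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)`.  Returns `NA` (UNDEFINED)
#' when the comparison itself is undefined or either logarithm argument is
#' non-positive (saturation).
#'
#' @param cmp A `site_comparison` from [compare_sites()], or a list with
#'   numeric elements `P` and `Q`.
#' @return The K2P distance, or `NA_real_`.
#' @export
k2p_distance <- function(cmp) {
  P <- cmp$P
  Q <- cmp$Q
  if (is.na(P) || is.na(Q)) return(NA_real_)
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) return(NA_real_)
  -0.5 * log(w1) - 0.25 * log(w2)
}

#' @rdname k2p_distance
#' @details `p_distance()` is the uncorrected proportion of differing valid
#'   sites, `P + Q`.
#' @export
p_distance <- function(cmp) {
  if (is.na(cmp$P) || is.na(cmp$Q)) return(NA_real_)
  cmp$P + cmp$Q
}

#' Pairwise distance matrix for an aligned set
#'
#' @param set An [aln_set()].
#' @param model `"K2P"` (default) or `"p"` (uncorrected).
#' @param site_mode `"pairwise_deletion"` (default; each pair masks only its
#'   own invalid sites) or `"complete_deletion"` (columns with any invalid
#'   residue in any row are removed once, before all comparisons).
#' @return A symmetric numeric matrix of class `pairdist` with zero diagonal,
#'   sample IDs as dimnames and attributes `model`, `site_mode` and
#'   `n_undefined` (count of UNDEFINED off-diagonal pairs, stored as NA).
#' @export
pairwise_matrix <- function(set,
                            model = c("K2P", "p"),
                            site_mode = c("pairwise_deletion",
                                          "complete_deletion")) {
  model <- match.arg(model)
  site_mode <- match.arg(site_mode)
  m <- .encode_alignment(set)
  if (site_mode == "complete_deletion") {
    keep <- colSums(m == 0L) == 0L
    if (!any(keep))
      stop("complete deletion removed every site")
    m <- m[, keep, drop = FALSE]
  }
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  n_undef <- 0L
  if (n > 1L) {
    for (i in 1L:(n - 1L)) {
      for (j in (i + 1L):n) {
        cnt <- .site_counts(m[i, ], m[j, ])
        val <- if (cnt$valid_sites == 0L) {
          NA_real_
        } else {
          P <- cnt$transitions / cnt$valid_sites
          Q <- cnt$transversions / cnt$valid_sites
          if (model == "p") P + Q else k2p_distance(list(P = P, Q = Q))
        }
        if (is.na(val)) n_undef <- n_undef + 1L
        d[i, j] <- d[j, i] <- val
      }
    }
  }
  structure(d, model = model, site_mode = site_mode, n_undefined = n_undef,
            class = c("pairdist", class(d)))
}

#' @export
print.pairdist <- function(x, ...) {
  cat(sprintf("%s distance matrix (%s): %d samples, %d undefined pairs\n",
              attr(x, "model"), attr(x, "site_mode"), nrow(x),
              attr(x, "n_undefined")))
  print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x)))])
  invisible(x)
}
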