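# Kimura-1980 sequence simulation: habitat-structured multi-species
# alignments with known haplotype composition, used as ground truth for
# every pipeline stage.

.BASES <- c("A", "C", "G", "T")
# transition partner, and the two transversion partners, per base
.TS_PARTNER <- c(A = "G", C = "T", G = "A", T = "C")
.TV_PARTNER1 <- c(A = "C", C = "A", G = "C", T = "A")
.TV_PARTNER2 <- c(A = "T", C = "G", G = "T", T = "G")

#' Evolve a sequence under the Kimura 1980 model
#'
#' Each site is substituted independently using the exact K80 transition
#' probabilities at evolutionary distance `d` (expected substitutions per
#' site) with transition/transversion rate ratio `kappa`; rates are scaled
#' so that `alpha + 2 beta = 1`.  The expected K2P distance estimated
#' between input and output is `d`.  Uses the current RNG state: seed before
#' calling for reproducibility.
#'
#' @param ancestor Character vector of bases (`A/C/G/T`), one per site.
#' @param d Evolutionary distance >= 0.
#' @param kappa Transition/transversion rate ratio (> 0); 2 is typical for
#'   nuclear barcode loci.
#' @return Character vector: the derived sequence.
#' @export
mutate_k80 <- function(ancestor, d, kappa = 2) {
  stopifnot(d >= 0, kappa > 0, all(ancestor %in% .BASES))
  L <- length(ancestor)
  if (d == 0) return(ancestor)
  beta <- 1 / (kappa + 2)
  alpha <- kappa * beta
  e1 <- exp(-4 * beta * d)
  e2 <- exp(-2 * (alpha + beta) * d)
  p_same <- 0.25 + 0.25 * e1 + 0.5 * e2
  p_ts <- 0.25 + 0.25 * e1 - 0.5 * e2
  p_tv <- 0.25 - 0.25 * e1  # each of the two transversion targets
  u <- runif(L)
  out <- ancestor
  i_ts <- u >= p_same & u < p_same + p_ts
  i_tv1 <- u >= p_same + p_ts & u < p_same + p_ts + p_tv
  i_tv2 <- u >= p_same + p_ts + p_tv
  out[i_ts] <- .TS_PARTNER[ancestor[i_ts]]
  out[i_tv1] <- .TV_PARTNER1[ancestor[i_tv1]]
  out[i_tv2] <- .TV_PARTNER2[ancestor[i_tv2]]
  out
}

#' Specification of a simulated habitat-structured dataset
#'
#' @param species A list; each element is a list with `name`, `n_inland`,
#'   `n_coastal`, and `haplotypes`, a data frame with columns `divergence`
#'   (expected substitutions/site from the species ancestor), `habitat`
#'   (`"inland"`, `"coastal"` or `"both"`) and `weight` (> 0, relative
#'   sampling frequency).
#' @param L Alignment length in bp (default 600, a realistic barcode
#'   amplicon).
#' @param kappa Transition/transversion rate ratio (default 2).
#' @param D Divergence between species ancestors (default 0.10, well above
#'   typical intraspecific distances of 0 - 0.03 so that a barcode gap
#'   exists; lower it deliberately to create hard cases).
#' @param seed Master seed (mandatory).
#' @return List of class `sim_spec`.
#' @export
simulation_spec <- function(species, L = 600L, kappa = 2, D = 0.10, seed) {
  if (missing(seed)) stop("a seed is mandatory")
  stopifnot(L >= 1L, kappa > 0, D >= 0, length(species) >= 1L)
  for (sp in species) {
    stopifnot(!is.null(sp$name), sp$n_inland >= 0L, sp$n_coastal >= 0L,
              sp$n_inland + sp$n_coastal >= 1L,
              is.data.frame(sp$haplotypes),
              all(sp$haplotypes$divergence >= 0),
              all(sp$haplotypes$weight > 0),
              all(sp$haplotypes$habitat %in% c("inland", "coastal", "both")))
  }
  structure(list(species = species, L = as.integer(L), kappa = kappa,
                 D = D, seed = as.integer(seed)), class = "sim_spec")
}

#' Simulate a habitat-structured dataset with known truth
#'
#' Draws one random ancestor per species (species ancestors sit at mutual
#' distance ~ `D`), realises each haplotype by [mutate_k80()] at its stated
#' divergence, and assigns samples to haplotypes by weighted sampling
#' restricted to the habitats where each haplotype is available.  Haplotype
#' realisations that collide with an existing haplotype of the same species
#' are redrawn (up to 100 times), so the returned truth tables are exact.
#' No indels are simulated unless `gap_rate > 0`.
#'
#' @param spec A [simulation_spec()].
#' @param gap_rate Per-site probability of replacing a residue with a gap,
#'   applied independently per sample (default 0); exists only to exercise
#'   site-masking code paths -- it destroys exact haplotype truth.
#' @param assignment `"weighted"` (default): each sample independently draws
#'   a haplotype with probability proportional to weight, so realised
#'   composition is multinomial.  `"balanced"`: per habitat group, quotas
#'   proportional to weight are fixed by largest-remainder rounding, giving
#'   a deterministic composition -- use this when a design needs exact
#'   haplotype frequencies (e.g. an equifrequent reference population).
#' @return List: `alignment` (an [aln_set()]), `truth` (list with
#'   `assignment` data frame (`sample_id`, `species`, `group`, `haplotype`),
#'   `haplotype_counts` (per species x group realised haplotype counts, same
#'   shape as [haplotype_table()]), `theta_expected` (per species expected
#'   mean pairwise distance given the assignment)), and `spec`.
#' @export
simulate_dataset <- function(spec, gap_rate = 0,
                             assignment = c("weighted", "balanced")) {
  assignment_mode <- match.arg(assignment)
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  root <- sample(.BASES, spec$L, replace = TRUE)
  seqs <- character(0)
  meta <- list()
  assignment <- list()
  theta_exp <- list()
  for (si in seq_along(spec$species)) {
    sp <- spec$species[[si]]
    hp <- sp$haplotypes
    k <- nrow(hp)
    avail_inland <- which(hp$habitat %in% c("inland", "both"))
    avail_coastal <- which(hp$habitat %in% c("coastal", "both"))
    if (sp$n_inland > 0L && !length(avail_inland))
      stop("infeasible spec: species ", sp$name,
           " has inland samples but no inland-available haplotype")
    if (sp$n_coastal > 0L && !length(avail_coastal))
      stop("infeasible spec: species ", sp$name,
           " has coastal samples but no coastal-available haplotype")
    if (!sp$n_coastal && any(hp$habitat == "coastal"))
      stop("infeasible spec: coastal-only haplotype but n_coastal = 0 for ",
           sp$name)
    if (!sp$n_inland && any(hp$habitat == "inland"))
      stop("infeasible spec: inland-only haplotype but n_inland = 0 for ",
           sp$name)
    anc <- mutate_k80(root, spec$D / 2, spec$kappa)
    hseq <- vector("list", k)
    for (h in seq_len(k)) {
      for (try in seq_len(100L)) {
        cand <- mutate_k80(anc, hp$divergence[h], spec$kappa)
        dup <- h > 1L && any(vapply(hseq[seq_len(h - 1L)],
                                    identical, TRUE, y = cand))
        if (!dup) break
        if (try == 100L)
          stop("haplotypes of ", sp$name,
               " are not distinguishable at this divergence/length")
      }
      hseq[[h]] <- cand
    }
    draw <- function(n_samp, avail, grp, tag) {
      if (!n_samp) return(NULL)
      hap <- if (assignment_mode == "weighted") {
        avail[sample.int(length(avail), n_samp, replace = TRUE,
                         prob = hp$weight[avail])]
      } else {
        quota <- .largest_remainder(hp$weight[avail], n_samp,
                                    min_one = n_samp >= length(avail))
        rep(avail, quota)
      }
      ids <- sprintf("%s_%s%02d", gsub("[^A-Za-z0-9]", "", sp$name),
                     tag, seq_len(n_samp))
      list(hap = hap, ids = ids, grp = rep(grp, n_samp))
    }
    din <- draw(sp$n_inland, avail_inland, "inland", "i")
    dco <- draw(sp$n_coastal, avail_coastal, "coastal", "c")
    hap <- c(din$hap, dco$hap)
    ids <- c(din$ids, dco$ids)
    grp <- c(din$grp, dco$grp)
    rows <- vapply(hseq[hap], paste, "", collapse = "")
    names(rows) <- ids
    seqs <- c(seqs, rows)
    meta[[si]] <- data.frame(sample_id = ids, species = sp$name,
                             group = grp, stringsAsFactors = FALSE)
    assignment[[si]] <- data.frame(sample_id = ids, species = sp$name,
                                   group = grp, haplotype = hap,
                                   stringsAsFactors = FALSE)
    # expected theta: same haplotype -> 0, else additive divergence
    dv <- hp$divergence
    n <- length(hap)
    exp_pair <- outer(dv[hap], dv[hap], `+`) *
      (outer(hap, hap, `!=`) + 0)
    theta_exp[[si]] <- data.frame(
      species = sp$name, n = n,
      theta_expected = if (n >= 2L) mean(exp_pair[upper.tri(exp_pair)])
                       else NA_real_,
      stringsAsFactors = FALSE)
  }
  meta <- do.call(rbind, meta)
  assignment <- do.call(rbind, assignment)
  if (gap_rate > 0) {
    chars <- strsplit(seqs, "", fixed = TRUE)
    chars <- lapply(chars, function(v) {
      v[runif(length(v)) < gap_rate] <- "-"
      v
    })
    seqs <- vapply(chars, paste, "", collapse = "")
    names(seqs) <- assignment$sample_id
  }
  counts <- list()
  for (sp in unique(assignment$species)) {
    a <- assignment[assignment$species == sp, ]
    for (g in c("inland", "coastal", "combined")) {
      sel <- if (g == "combined") a else a[a$group == g, ]
      counts[[length(counts) + 1L]] <- data.frame(
        species = sp, group = g, a = nrow(sel),
        b = length(unique(sel$haplotype)), stringsAsFactors = FALSE)
    }
  }
  list(alignment = aln_set(seqs, meta, locus = "simulated"),
       truth = list(assignment = assignment,
                    haplotype_counts = do.call(rbind, counts),
                    theta_expected = do.call(rbind, theta_exp)),
       spec = spec)
}
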