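# Fixtures built in code: small aligned sets, distance matrices and
# simulation specs shared across the test files.

# A tiny aligned set: ids/species/groups supplied positionally.
make_set <- function(seqs, species, group = NULL, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("s%02d", seq_along(seqs))
  names(seqs) <- ids
  meta <- data.frame(sample_id = ids, species = species,
                     stringsAsFactors = FALSE)
  if (!is.null(group)) meta$group <- group
  aln_set(seqs, meta)
}

# Symmetric distance matrix from the upper triangle given row-wise.
dist_mat <- function(upper, ids) {
  n <- length(ids)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  m[upper.tri(m)] <- upper
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

# Random aligned pair of length L with controlled differences.
random_pair <- function(L, seed) {
  set.seed(seed)
  a <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  b <- a
  k <- max(1L, rbinom(1L, L, 0.05))
  pos <- sample(L, k)
  b[pos] <- vapply(b[pos], function(x)
    sample(setdiff(c("A", "C", "G", "T"), x), 1L), "")
  list(a = paste(a, collapse = ""), b = paste(b, collapse = ""))
}

# One-species simulation spec with the given haplotype structure.
species_spec <- function(name, n_inland, n_coastal, divergence, habitat,
                         weight = rep(1, length(divergence))) {
  list(name = name, n_inland = n_inland, n_coastal = n_coastal,
       haplotypes = data.frame(divergence = divergence, habitat = habitat,
                               weight = weight, stringsAsFactors = FALSE))
}

# A random feasible simulation spec (no gaps), for truth-recovery tests.
random_spec <- function(seed) {
  set.seed(seed)
  n_species <- sample(1:3, 1L)
  species <- lapply(seq_len(n_species), function(i) {
    k <- sample(1:4, 1L)
    habitat <- sample(c("inland", "coastal", "both"), k, replace = TRUE)
    n_inland <- sample(3:12, 1L)
    n_coastal <- sample(0:8, 1L)
    # keep the spec feasible for both groups
    if (!any(habitat %in% c("inland", "both"))) habitat[1L] <- "both"
    if (n_coastal == 0L) habitat[habitat == "coastal"] <- "both"
    if (n_coastal > 0L && !any(habitat %in% c("coastal", "both")))
      habitat[k] <- "both"
    if (n_inland == 0L) habitat[habitat == "inland"] <- "both"
    species_spec(paste0("sp", i), n_inland, n_coastal,
                 divergence = c(0, runif(k - 1L, 0.004, 0.03))[seq_len(k)],
                 habitat = habitat, weight = sample(1:5, k, replace = TRUE))
  })
  simulation_spec(species, L = sample(500:900, 1L), kappa = 2, D = 0.1,
                  seed = seed + 1000L)
}

# The criterion-8 style paired populations: a species whose only coastal
# sample is one rare divergent haplotype, and an equifrequent two-haplotype
# population matched for N = 20 and mean pairwise diversity 0.003.
paired_populations <- function(seed) {
  sp_priv <- list(species_spec("Priv", 19L, 1L,
                               divergence = c(0, 0.03),
                               habitat = c("inland", "coastal"),
                               weight = c(19, 1)))
  r <- 0.003 / (100 / 190) / 2
  sp_unif <- list(species_spec("Unif", 20L, 0L,
                               divergence = c(r, r),
                               habitat = c("inland", "inland")))
  priv <- simulate_dataset(simulation_spec(sp_priv, L = 600L, kappa = 2,
                                           D = 0.1, seed = seed),
                           assignment = "balanced")
  unif <- simulate_dataset(simulation_spec(sp_unif, L = 600L, kappa = 2,
                                           D = 0.1, seed = seed + 100000L),
                           assignment = "balanced")
  list(priv = priv, unif = unif)
}

# Three well-separated species, easy identification conditions.
easy_three_species <- function(seed, n_inland = 5L, n_coastal = 3L) {
  species <- lapply(1:3, function(i)
    species_spec(paste0("Species", i), n_inland, n_coastal,
                 divergence = c(0, 0.005, 0.01),
                 habitat = c("both", "inland", "coastal"),
                 weight = c(3, 1, 1)))
  simulate_dataset(simulation_spec(species, L = 600L, kappa = 2, D = 0.1,
                                   seed = seed))
}
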