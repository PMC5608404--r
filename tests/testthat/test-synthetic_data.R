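test_that("K80 mutation: identity at d = 0, consistency, kappa limit", {
  set.seed(50)
  anc <- sample(c("A", "C", "G", "T"), 500, replace = TRUE)
  expect_identical(mutate_k80(anc, 0), anc)
  # estimator consistency at d = 0.05 (oracle shared with the distance tests)
  est <- replicate(200, {
    a <- sample(c("A", "C", "G", "T"), 10000, replace = TRUE)
    b <- mutate_k80(a, 0.05, kappa = 2)
    k2p_distance(compare_sites(paste(a, collapse = ""),
                               paste(b, collapse = "")))
  })
  expect_lt(abs(mean(est) - 0.05), 3 * sd(est) / sqrt(200))
  # large kappa drives the transversion proportion to zero
  q_at <- function(kappa) {
    mean(replicate(50, {
      a <- sample(c("A", "C", "G", "T"), 2000, replace = TRUE)
      b <- mutate_k80(a, 0.1, kappa = kappa)
      compare_sites(paste(a, collapse = ""), paste(b, collapse = ""))$Q
    }))
  }
  expect_lt(q_at(1000), q_at(2) / 10)
})

test_that("simulation is bit-reproducible and respects habitat availability", {
  spec <- random_spec(61)
  s1 <- simulate_dataset(spec)
  s2 <- simulate_dataset(spec)
  expect_identical(s1$alignment$seq, s2$alignment$seq)
  expect_identical(s1$truth$assignment, s2$truth$assignment)
  # habitat-restricted haplotypes never appear in the other group
  for (si in seq_along(spec$species)) {
    sp <- spec$species[[si]]
    a <- s1$truth$assignment[s1$truth$assignment$species == sp$name, ]
    hab <- sp$haplotypes$habitat[a$haplotype]
    expect_false(any(hab == "coastal" & a$group == "inland"))
    expect_false(any(hab == "inland" & a$group == "coastal"))
  }
  # infeasible specs are refused
  bad <- simulation_spec(list(species_spec("x", 0L, 3L,
                                           divergence = c(0, 0.01),
                                           habitat = c("inland", "coastal"))),
                         seed = 1)
  expect_error(simulate_dataset(bad), "infeasible")
})

test_that("truth tables match the haplotype module when no gaps are simulated", {
  sim <- simulate_dataset(simulation_spec(
    list(species_spec("one", 10L, 0L, divergence = 0, habitat = "both")),
    seed = 3))
  tab <- haplotype_table(sim$alignment, gap_mode = "include")
  expect_true(all(tab$b[tab$a > 0] == 1L))
  # truth assignment agrees with sequence-level collapsing
  sim2 <- simulate_dataset(random_spec(73))
  for (sp in unique(sim2$alignment$meta$species)) {
    ids <- sim2$alignment$meta$sample_id[sim2$alignment$meta$species == sp]
    hap <- collapse_haplotypes(subset_samples(sim2$alignment, ids), "include")
    truth <- sim2$truth$assignment$haplotype[match(ids, sim2$truth$assignment$sample_id)]
    # same partition: equal number of classes and identical co-membership
    expect_equal(max(hap), length(unique(truth)))
    expect_true(all(outer(hap, hap, `==`) == outer(truth, truth, `==`)))
  }
})

test_that("recovered theta converges to the spec-implied expectation", {
  spec <- simulation_spec(
    list(species_spec("big", 12L, 0L, divergence = c(0, 0.02),
                      habitat = c("both", "both"), weight = c(1, 1))),
    L = 5000L, seed = 7)
  est <- vapply(1:60, function(i) {
    sp2 <- spec; sp2$seed <- spec$seed + i
    sim <- simulate_dataset(sp2)
    d <- pairwise_matrix(sim$alignment)
    theta(d, rownames(d)) - sim$truth$theta_expected$theta_expected
  }, 0)
  expect_lt(abs(mean(est)), 3 * sd(est) / sqrt(length(est)))
})

test_that("well-separated species are fully identified end to end", {
  sim <- easy_three_species(91)
  d <- pairwise_matrix(sim$alignment)
  bcm <- best_close_match(d, sim$alignment$meta$species, 0.03)
  expect_equal(bcm$summary$a, 100)
  nj <- neighbor_joining(d)
  og <- sim$alignment$meta$sample_id[sim$alignment$meta$species == "Species3"]
  phy <- ape::root(nj, outgroup = og, resolve.root = TRUE)
  tr <- support_tree(phy, sim$alignment$meta, support = rep(1, phy$Nnode))
  expect_equal(discrimination_rate(tr)$rate, 100)
})

test_that("gap injection only exercises masking, not the default path", {
  spec <- simulation_spec(
    list(species_spec("g", 6L, 0L, divergence = c(0, 0.01),
                      habitat = c("both", "both"))),
    seed = 5)
  sim <- simulate_dataset(spec, gap_rate = 0.05)
  expect_true(any(grepl("-", sim$alignment$seq, fixed = TRUE)))
  d <- pairwise_matrix(sim$alignment)
  expect_true(all(!is.na(d)))
})
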