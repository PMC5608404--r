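# Independent oracle: haplotype count as the number of distinct strings,
# after dropping masked columns when requested.
hap_count_oracle <- function(seqs, exclude_sites = TRUE) {
  rows <- strsplit(toupper(seqs), "")
  if (exclude_sites) {
    keep <- Reduce(`&`, lapply(rows, function(v) v %in% c("A", "C", "G", "T")))
    rows <- lapply(rows, `[`, keep)
  }
  length(unique(vapply(rows, paste, "", collapse = "")))
}

test_that("haplotype collapsing follows first-occurrence order and gap modes", {
  s <- make_set(c("ACGT", "ACGA", "ACGT"), rep("x", 3))
  expect_equal(unname(collapse_haplotypes(s)), c(1L, 2L, 1L))
  expect_equal(unname(collapse_haplotypes(make_set(c("AAAA", "AAAA"), c("x", "x")))),
               c(1L, 1L))
  # gap column dropped under exclude_sites merges the two rows
  s2 <- make_set(c("AC-T", "ACGT"), c("x", "x"))
  expect_equal(max(collapse_haplotypes(s2, "exclude_sites")), 1L)
  expect_equal(max(collapse_haplotypes(s2, "include")), 2L)
  # nothing left to compare
  s3 <- make_set(c("--", "AA"), c("x", "x"))
  expect_error(collapse_haplotypes(s3), "sites")
  # invariant under reordering and renaming
  s4 <- make_set(c("ACGT", "ACCT", "ACGT", "TCGT"), rep("x", 4))
  s4r <- make_set(c("TCGT", "ACGT", "ACCT", "ACGT"), rep("x", 4),
                  ids = c("w", "x", "y", "z"))
  expect_equal(max(collapse_haplotypes(s4)), max(collapse_haplotypes(s4r)))
})

test_that("the habitat-stratified table collapses within each stratum", {
  # coastal contributes one private haplotype
  s <- make_set(c("ACGT", "ACGT", "ACGA", "ACGT", "AGGT", "ACGA"),
                rep("x", 6),
                group = c(rep("inland", 4), "coastal", "coastal"))
  tab <- haplotype_table(s)
  b <- setNames(tab$b, tab$group)
  expect_equal(unname(b[c("inland", "coastal", "combined")]), c(2L, 2L, 3L))
  expect_equal(unname(setNames(tab$a, tab$group)[c("inland", "coastal", "combined")]),
               c(4L, 2L, 6L))
  # coastal adds only already-seen haplotypes
  s2 <- make_set(c("ACGT", "ACGA", "ACGT", "ACGA"), rep("x", 4),
                 group = c("inland", "inland", "coastal", "coastal"))
  tab2 <- haplotype_table(s2)
  expect_equal(tab2$b[tab2$group == "combined"],
               tab2$b[tab2$group == "inland"])
  expect_error(haplotype_table(make_set(c("AA", "AA"), c("x", "x"))),
               "group")
})

test_that("table invariants hold on random synthetic sets (string-set oracle)", {
  for (seed in 1:30) {
    sim <- simulate_dataset(random_spec(seed))
    set <- sim$alignment
    tab <- haplotype_table(set, gap_mode = "include")
    for (sp in unique(tab$species)) {
      row <- function(g) tab[tab$species == sp & tab$group == g, ]
      inl <- row("inland"); coa <- row("coastal"); com <- row("combined")
      expect_equal(com$a, inl$a + coa$a)
      expect_gte(com$b, max(inl$b, coa$b))
      expect_lte(com$b, inl$b + coa$b)
      ids <- set$meta$sample_id[set$meta$species == sp]
      expect_equal(com$b, hap_count_oracle(set$seq[ids], exclude_sites = FALSE))
    }
  }
})

test_that("adding a sample never decreases counts under gap_mode = include", {
  set.seed(77)
  sim <- simulate_dataset(random_spec(101))
  set <- sim$alignment
  sp <- set$meta$species[1L]
  ids <- set$meta$sample_id[set$meta$species == sp]
  if (length(ids) >= 3L) {
    for (k in 2:(length(ids) - 1L)) {
      b1 <- max(collapse_haplotypes(subset_samples(set, ids[1:k]), "include"))
      b2 <- max(collapse_haplotypes(subset_samples(set, ids[1:(k + 1)]), "include"))
      expect_gte(b2, b1)
    }
  }
})

test_that("proportional subsampling allocates by largest remainder", {
  # frequencies {6, 3, 1}, target 5 -> quotas {3, 1, 1}
  seqs <- c(rep("AAAA", 6), rep("CCCC", 3), "GGGG")
  s <- make_set(seqs, rep("x", 10))
  out <- proportional_subsample(s, 5L, seed = 1)
  hap <- collapse_haplotypes(s)
  kept <- table(factor(hap[names(out$seq)], levels = 1:3))
  expect_equal(unname(c(kept)), c(3L, 1L, 1L))
  # symmetric frequencies split evenly
  s2 <- make_set(c(rep("AAAA", 10), rep("CCCC", 10)), rep("x", 20))
  out2 <- proportional_subsample(s2, 10L, seed = 2)
  kept2 <- table(factor(collapse_haplotypes(s2)[names(out2$seq)], levels = 1:2))
  expect_equal(unname(c(kept2)), c(5L, 5L))
  # target == n is the identity
  out3 <- proportional_subsample(s, 10L, seed = 3)
  expect_identical(out3$seq, s$seq)
  # cannot preserve all haplotypes below k
  expect_error(proportional_subsample(s, 2L, seed = 4), "haplotypes")
  expect_equal(length(proportional_subsample(s, 2L, seed = 4,
                                             allow_loss = TRUE)$seq), 2L)
})

test_that("every haplotype keeps a representative when target allows", {
  seqs <- c(rep("AAAA", 97), "CCCC", "GGGG", "TTTT")
  s <- make_set(seqs, rep("x", 100))
  out <- proportional_subsample(s, 4L, seed = 5)
  expect_equal(max(collapse_haplotypes(out)), 4L)
})
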