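test_that("generators are pure functions of parameters and seed", {
  f1 <- make_family_proteome(n_members = 6, n_decoys = 4, seed = 11)
  f2 <- make_family_proteome(n_members = 6, n_decoys = 4, seed = 11)
  expect_identical(f1$proteome, f2$proteome)
  expect_identical(f1$truth, f2$truth)
  f3 <- make_family_proteome(n_members = 6, n_decoys = 4, seed = 12)
  expect_false(identical(f1$proteome, f3$proteome))

  p1 <- make_promoters(n = 3, plant = tibble::tibble(promoter = 1:2,
                                                     element = "P1BS"),
                       length = 500, seed = 2)
  p2 <- make_promoters(n = 3, plant = tibble::tibble(promoter = 1:2,
                                                     element = "P1BS"),
                       length = 500, seed = 2)
  expect_identical(p1$promoters, p2$promoters)

  g1 <- make_geno_pheno(n_samples = 40, n_snps = 10, seed = 5)
  g2 <- make_geno_pheno(n_samples = 40, n_snps = 10, seed = 5)
  expect_identical(g1$geno, g2$geno)
  expect_identical(g1$trait, g2$trait)

  c1 <- make_ct_table(seed = 7)
  c2 <- make_ct_table(seed = 7)
  expect_identical(c1$table, c2$table)

  m1 <- make_gene_models(n = 2, seed = 9)
  m2 <- make_gene_models(n = 2, seed = 9)
  expect_identical(m1$genes, m2$genes)
})

test_that("every generated record appears in the truth table exactly once", {
  fam <- make_family_proteome(n_members = 10, n_decoys = 7, seed = 3)
  expect_setequal(names(fam$proteome), fam$truth$id)
  expect_equal(anyDuplicated(fam$truth$id), 0L)

  prom <- make_promoters(n = 5, plant = tibble::tibble(promoter = c(1, 2, 2),
                                                       element = "P1BS"),
                         length = 400, seed = 3)
  expect_equal(nrow(prom$truth), 3L)
  expect_true(all(prom$truth$promoter_id %in% names(prom$promoters)))
})

test_that("planted family members are detected and decoys rejected", {
  fam <- make_family_proteome(seed = 7)
  prof <- build_profile(fam$seed_msa)
  hits <- scan_proteome(prof, fam$proteome) # default 10-bit threshold
  members <- fam$truth$id[fam$truth$role != "decoy"]
  expect_setequal(hits$protein_id, members)
  ## decoy scores sit well below the threshold
  all_scores <- scan_proteome(prof, fam$proteome, score_threshold = -Inf)
  decoys <- fam$truth$id[fam$truth$role == "decoy"]
  expect_lt(max(all_scores$score_bits[all_scores$protein_id %in% decoys]), 10)
})

test_that("members with no planted family yield only rejects", {
  fam0 <- make_family_proteome(n_members = 0, n_decoys = 8,
                               degradation_spec = list(),
                               n_y2f_complete = 0, seed = 5)
  expect_equal(sum(fam0$truth$role == "decoy"), 8L)
  ## no members: screen every decoy directly against the blocks
  for (id in names(fam0$proteome)) {
    h <- scan_blocks(fam0$proteome[[id]])
    cls <- classify_candidate(h, tibble::tibble(
      score_bits = 0, n_half_coverage = 0, c_half_coverage = 0
    ))
    expect_equal(cls$verdict, "reject")
  }
})

test_that("planted promoter elements are recovered exactly after scrubbing", {
  prom <- make_promoters(n = 8, plant = tibble::tibble(promoter = 1:6,
                                                       element = "P1BS"),
                         length = 1500, seed = 13)
  hits <- purrr::imap_dfr(prom$promoters, function(sq, id) {
    scan_promoter(sq, promoter_id = id)
  })
  got <- hits[hits$element == "P1BS", ]
  expect_equal(nrow(got), nrow(prom$truth))
  key <- function(df, s, w) paste(df$promoter_id, df$element, df[[s]], df[[w]])
  expect_setequal(key(got, "start", "matched_word"),
                  key(prom$truth, "start", "word"))
})

test_that("unscrubbed background matches the degeneracy false-positive rate", {
  ## expected P1BS chance hits per window: 16/4^8 (palindromic: one strand)
  prom <- make_promoters(n = 40, plant = tibble::tibble(promoter = integer(),
                                                        element = character()),
                         length = 3000, seed = 17, scrub = FALSE)
  hits <- purrr::imap_dfr(prom$promoters, function(sq, id) {
    scan_promoter(sq, cis_element_defs()[1, ], promoter_id = id)
  })
  n_windows <- 40 * (3000 - 8 + 1)
  expected <- n_windows * 16 / 4^8
  ## Poisson-ish: allow 4 sd around the expectation
  expect_lt(abs(nrow(hits) - expected), 4 * sqrt(expected) + 1)
})

test_that("evolved alignments respect the substitution process", {
  tree <- ape::unroot(ape::read.tree(
    text = "((a:1,b:1):1,(c:1,d:1):1);"
  ))
  ## zero substitution probability: identical leaves
  sim0 <- evolve_msa(tree, n_columns = 50, subst_prob = 0, seed = 1)
  expect_equal(length(unique(sim0$msa)), 1L)
  ## empirical substitution counts near the branch probability (3 SE)
  p <- 0.2
  sim <- evolve_msa(ape::read.tree(text = "(x:1,y:1);"), n_columns = 2000,
                    subst_prob = p, seed = 3)
  ## x and y each differ from the root by p; observed x-y difference rate
  ## is p2 = 2p(1 - p/ (20/19)) under the uniform-replacement model; use
  ## the simpler bound: each site differs with prob <= 2p and >= p
  diff_rate <- mean(strsplit(sim$msa[["x"]], "")[[1]] !=
                      strsplit(sim$msa[["y"]], "")[[1]])
  expect_gt(diff_rate, p)
  expect_lt(diff_rate, 2 * p)
  ## NJ recovers the true split on well-separated clades
  sim2 <- evolve_msa(tree, n_columns = 400, subst_prob = 0.1, seed = 9)
  nj <- neighbor_joining(pairwise_distance(sim2$msa))
  expect_equal(as.numeric(ape::dist.topo(nj, tree)), 0)
})

test_that("panel simulation solves beta for the requested variance share", {
  sim <- make_geno_pheno(n_samples = 60, n_snps = 5,
                         causal_spec = list(snp = 2L, pve_theoretical = 30),
                         seed = 21)
  tr <- sim$truth
  ## back-compute the within-structure variance share from the truth
  share <- 100 * tr$var_genetic /
    (tr$var_genetic + tr$var_genetic_between + tr$var_structure +
       tr$var_noise)
  expect_equal(share, 30, tolerance = 1e-9)
  ## pve 0: beta 0
  sim0 <- make_geno_pheno(n_samples = 30, n_snps = 3,
                          causal_spec = list(snp = 1L, pve_theoretical = 0),
                          seed = 22)
  expect_equal(sim0$truth$beta, 0)
  ## pve 100 with structure/noise present is infeasible
  expect_error(make_geno_pheno(n_samples = 30, n_snps = 3,
                               causal_spec = list(snp = 1L,
                                                  pve_theoretical = 100),
                               seed = 23),
               "PVE 100")
  ## pve 100, no structure, no noise: trait is affine in the genotype
  sim1 <- make_geno_pheno(
    n_samples = 30, n_snps = 3,
    causal_spec = list(snp = 1L, pve_theoretical = 100),
    structure_spec = list(proportions = 1, mean_shifts = 0,
                          freq_spread = 0),
    noise_sd = 0, seed = 24
  )
  expect_equal(sim1$trait, sim1$truth$beta * sim1$geno[, 1] + 0,
               tolerance = 1e-12)
})

test_that("empirical allele frequencies track the structure specification", {
  sim <- make_geno_pheno(n_samples = 3000, n_snps = 20, seed = 25,
                         causal_spec = list(snp = NULL, pve_theoretical = 0))
  tr <- sim$truth
  for (s in 1:20) {
    for (kp in seq_along(tr$proportions)) {
      idx <- which(tr$pop == kp)
      f_hat <- mean(sim$geno[idx, s]) / 2
      f <- tr$pop_freq[s, kp]
      se <- sqrt(f * (1 - f) / (2 * length(idx)))
      expect_lt(abs(f_hat - f), 3.5 * se + 1e-9)
    }
  }
})

test_that("null fold changes give approximately uniform t-test p-values", {
  set.seed(43)
  ps <- vapply(1:200, function(k) {
    sim <- make_ct_table(true_fold_change = 1, replicate_sd = 0.1,
                         n_reps = 3, seed = k)
    delta_delta_ct(sim$table)$p
  }, numeric(1))
  ## KS-style check at coarse tolerance
  expect_gt(mean(ps < 0.5), 0.35)
  expect_lt(mean(ps < 0.5), 0.65)
  expect_lt(mean(ps < 0.05), 0.12)
})

test_that("degradation outside blocks 1..5 is rejected", {
  expect_error(
    make_family_proteome(n_members = 3, n_decoys = 0,
                         degradation_spec = list(list(label = "bad",
                                                      drop_blocks = 7L)),
                         seed = 1),
    "1..5"
  )
})
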