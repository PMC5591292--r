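test_that("delta-delta-Ct follows the textbook arithmetic", {
  ct <- tibble::tibble(
    condition = rep(c("control", "treated"), each = 2),
    gene = rep(c("target", "reference"), 2),
    replicate = 1L,
    ct = c(25, 20, 23, 20)
  )
  res <- delta_delta_ct(ct)
  expect_equal(res$ddct, -2)
  expect_equal(res$fold_change, 4)
  ## treated == control: fold 1
  ct1 <- ct; ct1$ct <- c(25, 20, 25, 20)
  expect_equal(delta_delta_ct(ct1)$fold_change, 1)
  ## missing reference is an error
  expect_error(delta_delta_ct(ct[ct$gene == "target", ]), "reference")
})

test_that("replicate t statistic matches the closed form", {
  ## three replicates per cell, hand-computable delta-Ct sets
  ct <- dplyr::bind_rows(
    tibble::tibble(condition = "control", gene = "target",
                   replicate = 1:3, ct = c(25.1, 25.0, 24.9)),
    tibble::tibble(condition = "control", gene = "reference",
                   replicate = 1:3, ct = c(20.0, 20.0, 20.0)),
    tibble::tibble(condition = "treated", gene = "target",
                   replicate = 1:3, ct = c(23.2, 23.0, 22.8)),
    tibble::tibble(condition = "treated", gene = "reference",
                   replicate = 1:3, ct = c(20.1, 20.0, 19.9))
  )
  res <- delta_delta_ct(ct)
  d_c <- c(5.1, 5.0, 4.9)
  d_t <- c(3.1, 3.0, 2.9)
  want <- t.test(d_t, d_c)
  expect_equal(res$p, want$p.value, tolerance = 1e-12)
  expect_equal(res$ddct, mean(d_t) - mean(d_c))
})

test_that("fold changes are reciprocal under sign flip of ddct", {
  for (dd in c(-3, -0.5, 0, 1.2, 4)) {
    expect_equal(2^(-dd) * 2^(dd), 1)
  }
  ## via the estimator: swapping condition labels inverts the fold change
  ct <- make_ct_table(true_fold_change = 4, replicate_sd = 0.1, seed = 8)$table
  swapped <- ct
  swapped$condition <- ifelse(ct$condition == "control", "treated", "control")
  f1 <- delta_delta_ct(ct)$fold_change
  f2 <- delta_delta_ct(swapped)$fold_change
  expect_equal(f1 * f2, 1, tolerance = 1e-9)
})

test_that("2^-dCt expression recovers planted genotype ordering", {
  expr <- c(g1 = 8, g2 = 2, g3 = 1, g4 = 0.25)
  sim <- make_ct_table(genotypes = expr, replicate_sd = 0, seed = 4)
  res <- relative_expression_2dct(sim$table)
  got <- setNames(res$expression, res$genotype_id)[names(expr)]
  expect_equal(got, expr, tolerance = 1e-9)
  ## dCt = 3 -> 0.125; dCt = 0 -> 1
  tab <- tibble::tibble(
    genotype_id = "g", gene = c("target", "reference"),
    replicate = 1L, ct = c(23, 20)
  )
  expect_equal(relative_expression_2dct(tab)$expression, 0.125)
})

test_that("zero-noise fold change is recovered exactly", {
  sim <- make_ct_table(true_fold_change = 4, replicate_sd = 0, seed = 1)
  expect_equal(delta_delta_ct(sim$table)$fold_change, 4, tolerance = 1e-12)
})

test_that("expression-trait correlation is plain Pearson with guards", {
  expect_equal(expression_trait_correlation(c(4, 3, 2, 1), c(1, 2, 3, 4)), -1)
  x <- c(1.2, 3.4, 2.2, 5.0)
  expect_equal(expression_trait_correlation(x, x), 1)
  y <- c(2, 1, 4, 8)
  expect_equal(expression_trait_correlation(x, y), cor(x, y))
  expect_error(expression_trait_correlation(c(1, 1, 1), c(1, 2, 3)),
               "constant")
  expect_error(expression_trait_correlation(c(1, 2), c(1, 2)), ">= 3")
})

test_that("MAF filtering uses the non-missing denominator and >= rule", {
  g <- cbind(
    rare = c(rep(0, 88), 1, 1, 1, 1),      # MAF 4/184 ~ 0.0217
    common = c(rep(0, 46), rep(1, 46)),    # MAF 0.25
    mono = rep(0, 92),
    boundary = c(rep(0, 82), rep(1, 10)),  # with 2 NAs below: recompute
    na_heavy = c(rep(NA, 50), rep(0, 38), 1, 1, 1, 1) # 4/84 ~ 0.048
  )
  kept <- maf_filter(g, 0.05)
  expect_setequal(colnames(kept), c("common", "boundary"))
  ## boundary case: exactly at threshold is retained
  g3 <- cbind(exact = c(rep(0, 18), 1, 1)) # MAF = 2/40 = 0.05
  expect_equal(ncol(maf_filter(g3, 0.05)), 1L)
  ## monomorphic SNP removed for any positive cutoff
  expect_equal(ncol(maf_filter(cbind(m = rep(0, 10)), 0.01)), 0L)
  expect_equal(ncol(maf_filter(cbind(m = rep(2, 10)), 0.01)), 0L)
  expect_error(maf_filter(g, 0.6), "0.5")
})

test_that("a trait equal to the SNP code gives PVE 100 and p ~ 0", {
  set.seed(3)
  g <- cbind(s1 = sample(0:2, 60, replace = TRUE),
             s2 = sample(0:2, 60, replace = TRUE))
  res <- marker_trait_assoc(g, trait = g[, "s1"])
  row <- res[res$snp_id == "s1", ]
  expect_equal(row$pve, 100, tolerance = 1e-9)
  expect_lt(row$p, 1e-200)
  expect_equal(row$high_allele, "alt")
  ## negative coding direction
  res2 <- marker_trait_assoc(g, trait = -g[, "s1"])
  expect_equal(res2$high_allele[res2$snp_id == "s1"], "ref")
})

test_that("association p-values are calibrated under the null", {
  set.seed(17)
  n <- 92
  g <- matrix(rbinom(n * 1000, 2, 0.3), n, 1000)
  trait <- rnorm(n)
  res <- marker_trait_assoc(g, trait)
  frac <- mean(res$p < 0.05, na.rm = TRUE)
  ## binomial 99% bounds around 0.05 with 1000 tests
  bounds <- qbinom(c(0.005, 0.995), 1000, 0.05) / 1000
  expect_gte(frac, bounds[1])
  expect_lte(frac, bounds[2])
})

test_that("BH q-values are monotone in rank-ordered p and q >= p", {
  set.seed(23)
  g <- matrix(rbinom(50 * 40, 2, 0.4), 50, 40)
  res <- marker_trait_assoc(g, rnorm(50) + 0.8 * g[, 1])
  ok <- !is.na(res$p)
  expect_true(all(res$q[ok] >= res$p[ok] - 1e-12))
  ord <- order(res$p[ok])
  expect_true(all(diff(res$q[ok][ord]) >= -1e-12))
  expect_equal(res$q[ok], p.adjust(res$p[ok], "BH"))
})

test_that("association is invariant to affine trait rescaling", {
  set.seed(29)
  g <- matrix(rbinom(80 * 10, 2, 0.4), 80, 10)
  q <- cbind(rnorm(80))
  y <- rnorm(80) + g[, 3]
  a <- marker_trait_assoc(g, y, covariates = q)
  b <- marker_trait_assoc(g, 3.7 * y - 11, covariates = q)
  expect_equal(a$p, b$p, tolerance = 1e-9)
  expect_equal(a$pve, b$pve, tolerance = 1e-9)
})

test_that("covariate misuse is rejected", {
  g <- matrix(rbinom(30 * 3, 2, 0.4), 30, 3)
  y <- rnorm(30)
  expect_error(marker_trait_assoc(g, y, covariates = cbind(1:30, 2 * (1:30))),
               "rank-deficient")
  expect_error(marker_trait_assoc(g[1:4, ], y[1:4],
                                  covariates = cbind(rnorm(4), rnorm(4))),
               "too few")
})

test_that("structured panels recover the planted PVE at large n", {
  set.seed(31)
  pves <- replicate(25, {
    sim <- make_geno_pheno(n_samples = 2000, n_snps = 3,
                           causal_spec = list(snp = 1L, pve_theoretical = 20),
                           seed = sample.int(1e6, 1))
    res <- marker_trait_assoc(sim$geno, sim$trait, covariates = sim$covariates)
    res$pve[res$snp_id == sim$truth$causal_snp]
  })
  expect_lt(abs(mean(pves) - 20), 2)
})

test_that("tidy, glance and autoplot work on association results", {
  set.seed(37)
  g <- matrix(rbinom(60 * 8, 2, 0.4), 60, 8)
  res <- marker_trait_assoc(g, rnorm(60) + g[, 2],
                            snp_info = tibble::tibble(
                              snp_id = paste0("snp", 1:8),
                              chromosome = "chr1", position = 1:8 * 1000
                            ))
  td <- tidy(res)
  expect_false(inherits(td, "pap_assoc"))
  gl <- glance(res)
  expect_equal(gl$n_snps, 8L)
  p <- autoplot(res)
  expect_s3_class(p, "ggplot")
})
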