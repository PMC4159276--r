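test_that("HWE exact test matches full enumeration on random margins", {
  expect_equal(hwe_exact_test(10, 0, 0), 1.0)
  expect_equal(hwe_exact_test(0, 0, 25), 1.0)
  expect_lt(hwe_exact_test(0, 100, 0), 1e-8)
  expect_equal(hwe_exact_test(57, 14, 50), oracle_hwe(57, 14, 50),
               tolerance = 1e-12)
  set.seed(7)
  for (i in 1:60) {
    n <- sample(200, 1)
    aa <- sample(0:n, 1)
    het <- if (n - aa > 0) sample(0:(n - aa), 1) else 0
    bb <- n - aa - het
    expect_equal(hwe_exact_test(aa, het, bb), oracle_hwe(aa, het, bb),
                 tolerance = 1e-12,
                 label = sprintf("margin (%d,%d,%d)", aa, het, bb))
  }
  expect_error(hwe_exact_test(0, 0, 0), "at least one")
})

test_that("SNP missingness is an exact per-column recount", {
  g <- gm(rbind(c(0L, NA, 2L), c(1L, NA, NA), c(0L, 0L, 2L), c(2L, 1L, 0L)))
  expect_equal(unname(snp_missingness(g)), c(0, 0.5, 0.25))
})

test_that("cross-array concordance counts jointly called identical pairs", {
  g1 <- gm(rbind(c(0L, 1L, 2L), c(1L, 1L, 0L), c(2L, NA, 1L)))
  g2 <- gm(rbind(c(0L, 1L, 0L), c(1L, 0L, 0L), c(2L, 2L, 1L)))
  conc <- cross_array_concordance(g1, g2)
  expect_equal(unname(conc["v001"]), 1.0)
  expect_equal(unname(conc["v002"]), 0.5)  # of 2 joint calls, 1 matches
  expect_equal(unname(conc["v003"]), 2 / 3)
  # identical matrices are fully concordant
  expect_true(all(cross_array_concordance(g1, g1) == 1, na.rm = TRUE))
})

test_that("IBS matrix follows the (2 - |gi - gj|)/2 formula", {
  g <- gm(rbind(c(0L, 1L, 2L, 2L), c(0L, 1L, 0L, 2L)))
  ibs <- ibs_matrix(g, maf_min = 0)
  expect_equal(ibs["S01", "S02"], 0.75)  # (2+2+0+2)/2 / 4
  expect_equal(diag(ibs), c(S01 = 1, S02 = 1))
  # duplicates share everything; full opposites share nothing
  g2 <- gm(rbind(c(0L, 0L, 0L), c(0L, 0L, 0L), c(2L, 2L, 2L)))
  ibs2 <- ibs_matrix(g2, maf_min = 0)
  expect_equal(ibs2["S01", "S02"], 1.0)
  expect_equal(ibs2["S01", "S03"], 0.0)
  # symmetric and invariant to sample order
  set.seed(11)
  g3 <- gm(matrix(sample(c(0:2, NA), 60, replace = TRUE), nrow = 6))
  i3 <- ibs_matrix(g3, maf_min = 0)
  expect_equal(i3, t(i3))
  perm <- sample(6)
  g4 <- genotype_matrix(g3$variants, g3$geno[perm, ], g3$sample_ids[perm])
  i4 <- ibs_matrix(g4, maf_min = 0)
  expect_equal(i4[g3$sample_ids, g3$sample_ids], i3, ignore_attr = TRUE)
})

test_that("excess-IBS flagging retains the higher-call-rate sample", {
  ibs <- matrix(c(1, .99, .2, .99, 1, .2, .2, .2, 1), 3, 3,
                dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  expect_equal(flag_excess_ibs(ibs, c(a = 0.99, b = 0.97, c = 1), 0.9), "b")
  expect_equal(flag_excess_ibs(ibs, c(a = 0.97, b = 0.99, c = 1), 0.9), "a")
  # tie removes the lexicographically later id
  expect_equal(flag_excess_ibs(ibs, c(a = 0.99, b = 0.99, c = 1), 0.9), "b")
  # nothing above threshold
  expect_length(flag_excess_ibs(ibs, c(a = 1, b = 1, c = 1), 0.995), 0)
  # a mutually-excess triple loses exactly two members
  ibs3 <- matrix(0.95, 3, 3, dimnames = dimnames(ibs)); diag(ibs3) <- 1
  expect_length(flag_excess_ibs(ibs3, c(a = .99, b = .98, c = .97), 0.9), 2)
})

test_that("PCA outlier screen flags admixture but not clean populations", {
  set.seed(3)
  # two separated populations in genotype space
  pop1 <- matrix(rbinom(20 * 40, 2, 0.15), nrow = 20)
  pop2 <- matrix(rbinom(20 * 40, 2, 0.85), nrow = 20)
  clean <- gm(rbind(pop1, pop2))
  labels <- rep(c("p1", "p2"), each = 20)
  expect_length(pca_flag_outliers(clean, maf_min = 0.05, 2, 6, labels), 0)
  expect_length(pca_flag_outliers(clean, maf_min = 0.05, 2, Inf, labels), 0)
  # one 50/50 admixed sample labelled p1 sits between the clusters
  adm <- matrix(rbinom(1 * 40, 2, 0.5), nrow = 1)
  mixed <- gm(rbind(pop1, adm, pop2))
  labels2 <- c(rep("p1", 21), rep("p2", 20))
  out <- pca_flag_outliers(mixed, maf_min = 0.05, 2, 3, labels2)
  expect_true(mixed$sample_ids[21] %in% out)
  expect_error(pca_flag_outliers(gm(matrix(1L, 5, 4)), 0, 2, 3,
                                 rep("p", 5)), "degenerate")
})

test_that("run_qc attributes removals to the first triggering rule", {
  set.seed(5)
  base <- matrix(rbinom(40 * 30, 2, 0.4), nrow = 40)
  v <- vt(30)
  # plant: v010 high missingness (A.vi); v020 extreme HWE (A.vii);
  # v005 fails both -> attributed to A.vi
  base2 <- base
  base2[1:10, 10] <- NA
  base2[, 20] <- rep(1L, 40)       # all-het: gross HWE departure
  base2[1:10, 5] <- NA
  base2[11:40, 5] <- 1L
  m <- genotype_matrix(v, base2, sprintf("S%02d", 1:40))
  th <- qc_thresholds(snp_missing_max = 0.2, hwe_p_prelim = 1e-8,
                      hwe_p_final = 1e-12)
  res <- run_qc(list(arr = m), th, labels = rep("p1", 40))
  rem <- res$report$removed_snps
  expect_equal(rem$reason[rem$vid == "v010"], "A.vi")
  expect_equal(rem$reason[rem$vid == "v020"], "A.vii")
  expect_equal(rem$reason[rem$vid == "v005"], "A.vi")
})

test_that("run_qc is the identity on clean data and idempotent", {
  set.seed(9)
  geno <- matrix(rbinom(30 * 25, 2, 0.5), nrow = 30)
  m <- gm(geno)
  res <- run_qc(list(arr = m), qc_thresholds(), labels = rep("p1", 30))
  expect_equal(nrow(res$report$removed_snps), 0)
  expect_equal(nrow(res$report$removed_samples), 0)
  expect_identical(res$matrices$arr$geno, m$geno)
  # idempotence: a second pass removes nothing
  res2 <- run_qc(res$matrices, qc_thresholds(), labels = rep("p1", 30))
  expect_equal(nrow(res2$report$removed_snps), 0)
  expect_identical(res2$matrices$arr$geno, res$matrices$arr$geno)
})

test_that("cross-array removals: allele conflicts and low concordance", {
  set.seed(13)
  geno <- matrix(rbinom(40 * 20, 2, 0.5), nrow = 40)
  v1 <- vt(20)
  m1 <- genotype_matrix(v1, geno, sprintf("S%02d", 1:40))
  v2 <- v1
  v2$alt[3] <- "T"                      # allele conflict at v003
  geno2 <- geno
  geno2[1:10, 7] <- (geno[1:10, 7] + 1L) %% 3L  # discordance at v007
  m2 <- genotype_matrix(v2, geno2, sprintf("S%02d", 1:40))
  res <- run_qc(list(a = m1, b = m2), qc_thresholds(),
                labels = rep("p1", 40))
  rem <- res$report$removed_snps
  expect_equal(rem$reason[rem$vid == "v003"], "A.iv")
  expect_equal(rem$reason[rem$vid == "v007"], "A.v")
  # boundary: exactly 99.5% concordance is retained
  g <- matrix(rep(c(0L, 1L), each = 100), ncol = 1)
  ga <- gm(g); gb <- g; gb[1, 1] <- 1L
  gb <- gm(gb)
  conc <- cross_array_concordance(ga, gb)
  expect_equal(unname(conc), 0.995)
  res2 <- run_qc(list(a = ga, b = gb),
                 qc_thresholds(hwe_p_prelim = 1e-300, hwe_p_final = 1e-300),
                 labels = rep("p1", 200))
  expect_false("v001" %in% res2$report$removed_snps$vid[
    res2$report$removed_snps$reason == "A.v"])
})
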