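test_that("chunk plans tile, clip and cover the chromosome", {
  p <- make_chunk_plan(12e6, core_bp = 5e6, buffer_bp = 5e6)
  expect_equal(p$core_start, c(1, 5e6 + 1, 10e6 + 1))
  expect_equal(p$core_end, c(5e6, 10e6, 12e6))
  expect_true(all(p$buffer_start >= 1 & p$buffer_end <= 12e6))
  expect_true(all(p$buffer_start <= p$core_start &
                    p$buffer_end >= p$core_end))
  # single chunk when the chromosome fits in one core
  p2 <- make_chunk_plan(2e6, core_bp = 5e6)
  expect_equal(nrow(p2), 1)
  expect_equal(p2$core_end, 2e6)
})

test_that("threshold boundaries are inclusive at the calling cutoff", {
  post <- pt(rbind(c(0.95, 0.04, 0.01),
                   c(0.60, 0.30, 0.10),
                   c(0.90, 0.05, 0.05),
                   c(0.05, 0.05, 0.90)), 1, 4)
  calls <- threshold_calls(post, 0.9)
  expect_equal(unname(calls[1, ]), c(0L, NA, 0L, 2L))
  expect_error(threshold_calls(post, 0.2), "threshold")
})

test_that("a single reference haplotype is copied exactly", {
  ref <- hp(matrix(c(0L, 1L, 0L, 1L, 1L), nrow = 1), spacing = 1e5)
  params <- hmm_params(map = uniform_genetic_map(5e5))
  p <- ls_haploid_posteriors(c(0L, 1L), c("v001", "v003"), ref, params)
  expect_equal(unname(p), c(0, 1, 0, 1, 1))
})

test_that("a target identical to a reference haplotype copies it", {
  set.seed(61)
  h <- matrix(rbinom(3 * 12, 1, 0.5), nrow = 3)
  h[2, ] <- 1L - h[1, ]          # make haplotypes distinct
  h[3, 1] <- 1L - h[1, 1]        # ...including at a typed site
  ref <- hp(h, spacing = 1e5, name = "r")
  # a near-zero-recombination map keeps switch mass negligible, so the
  # copy limit is exact at this small panel size
  params <- hmm_params(error_rate = 1e-8,
                       map = uniform_genetic_map(1.2e6, 1e-9))
  typed <- ref$variants$vid[seq(1, 12, by = 2)]
  p <- ls_haploid_posteriors(h[1, seq(1, 12, by = 2)], typed, ref, params)
  expect_equal(unname(p), h[1, ], tolerance = 1e-6)
})

test_that("forward-backward equals path enumeration on small instances", {
  # a fixed small case: 3 haplotypes x 4 sites, 2 typed
  set.seed(3)
  h <- matrix(rbinom(12, 1, 0.5), 3)
  ref <- hp(h, spacing = 2e5)
  params <- hmm_params(error_rate = 0.05,
                       map = uniform_genetic_map(8e5))
  got <- ls_haploid_posteriors(c(1L, 0L), c("v002", "v004"), ref, params)
  want <- oracle_ls(c(1L, 0L), c("v002", "v004"), ref, params)
  expect_equal(got, want, tolerance = 1e-10)
  # property: random instances with k <= 4 and <= 6 sites
  for (i in 1:20) {
    inst <- random_ls_instance(k_ref = sample(1:4, 1),
                               n_sites = sample(3:6, 1),
                               n_typed = sample(1:3, 1), seed = 100 + i)
    got <- ls_haploid_posteriors(inst$target, inst$typed_vids, inst$ref,
                                 inst$params)
    want <- oracle_ls(inst$target, inst$typed_vids, inst$ref, inst$params)
    expect_equal(got, want, tolerance = 1e-10,
                 label = sprintf("instance %d", i))
  }
})

test_that("near-uniform copying error drives posteriors to panel freq", {
  set.seed(71)
  h <- matrix(rbinom(8 * 10, 1, 0.4), nrow = 8)
  ref <- hp(h, spacing = 1e5)
  params <- hmm_params(error_rate = 0.4999,
                       map = uniform_genetic_map(1e6))
  p <- ls_haploid_posteriors(c(1L, 1L, 0L), ref$variants$vid[c(2, 5, 9)],
                             ref, params)
  expect_equal(unname(p), colMeans(h), tolerance = 0.02)
})

test_that("genotype posteriors combine haplotypes independently", {
  # both haplotypes certain: genotype is certain hom-alt
  ref <- hp(matrix(c(0L, 1L, 1L), nrow = 1), spacing = 1e5)
  params <- hmm_params(map = uniform_genetic_map(3e5))
  post <- impute_genotypes(
    haplotype_panel(ref$variants[1, , drop = FALSE],
                    matrix(c(0L, 0L), ncol = 1), "T1"),
    ref, params, make_chunk_plan(3e5))
  expect_equal(unname(post[1, 3, ]), c(0, 0, 1))
  expect_equal(unname(post[1, 1, ]), c(1, 0, 0))
  # p1 = p2 = 0.5 gives the (0.25, 0.5, 0.25) independence triple
  ref2 <- hp(rbind(c(0L, 0L, 1L), c(0L, 1L, 0L)), spacing = 1e5)
  params2 <- hmm_params(error_rate = 0.4999,
                        map = uniform_genetic_map(3e5))
  post2 <- impute_genotypes(
    haplotype_panel(ref2$variants[1, , drop = FALSE],
                    matrix(c(0L, 0L), ncol = 1), "T1"),
    ref2, params2, make_chunk_plan(3e5))
  expect_equal(unname(post2[1, 2, ]), c(0.25, 0.5, 0.25),
               tolerance = 0.01)
})

test_that("posterior triples always sum to one", {
  set.seed(81)
  h <- matrix(rbinom(10 * 30, 1, 0.5), nrow = 10)
  ref <- hp(h, spacing = 1e5, name = "r")
  typed_idx <- seq(2, 30, by = 4)
  tgt <- haplotype_panel(ref$variants[typed_idx, , drop = FALSE],
                         matrix(rbinom(4 * length(typed_idx), 1, 0.5),
                                nrow = 4),
                         c("T1", "T2"))
  params <- hmm_params(map = uniform_genetic_map(3e6))
  post <- impute_genotypes(tgt, ref, params, make_chunk_plan(3e6))
  sums <- post[, , 1] + post[, , 2] + post[, , 3]
  expect_true(all(abs(sums - 1) < 1e-6))
})

test_that("chunked and unchunked imputation produce identical tensors", {
  set.seed(91)
  h <- matrix(rbinom(12 * 40, 1, 0.5), nrow = 12)
  ref <- hp(h, spacing = 5e4, name = "r")  # 2 Mb fixture
  typed_idx <- seq(1, 40, by = 3)
  tgt <- haplotype_panel(ref$variants[typed_idx, , drop = FALSE],
                         h[1:4, typed_idx], c("T1", "T2"))
  params <- hmm_params(map = uniform_genetic_map(2e6))
  single <- impute_genotypes(tgt, ref, params,
                             make_chunk_plan(2e6, core_bp = 5e6))
  chunked <- impute_genotypes(tgt, ref, params,
                              make_chunk_plan(2e6, core_bp = 4e5,
                                              buffer_bp = 2e6))
  expect_equal(unclass(single), unclass(chunked), tolerance = 1e-12)
})

test_that("panel merging unions sites and copies known haplotypes", {
  set.seed(101)
  h <- matrix(rbinom(6 * 20, 1, 0.5), nrow = 6)
  # make every haplotype identifiable at the shared (odd) sites
  for (i in 1:6) h[i, c(1, 3, 5)] <- as.integer(intToBits(i)[1:3])
  a <- hp(h, spacing = 1e5, name = "a")
  params <- hmm_params(error_rate = 1e-6,
                       map = uniform_genetic_map(2e6, 0.001))
  # identical panels: site union equals the input sites
  m1 <- merge_panels(a, a, params)
  expect_equal(m1$variants$vid, a$variants$vid)
  expect_equal(nrow(m1$haps), 12)
  # panel_b typed on a subset, haplotypes exact copies of panel_a's:
  # cross-imputed alleles equal the copied originals
  sub <- seq(1, 20, by = 2)
  b <- haplotype_panel(a$variants[sub, , drop = FALSE],
                       h[1:2, sub], "B1", name = "b")
  m2 <- merge_panels(a, b, params)
  bi <- match(c("B1_1", "B1_2"), rownames(m2$haps))
  expect_equal(unname(m2$haps[bi, ]), unname(h[1:2, ]))
  # disjoint extra sites in b: union size adds b-exclusive count
  expect_equal(ncol(m2$haps), 20)
  # allele conflicts are refused
  bad <- b
  bad$variants$alt[1] <- "T"
  expect_error(merge_panels(a, bad, params), "conflict")
})

test_that("imputation accuracy improves when target-population haplotypes
           join the panel", {
  sim <- simulation_config(seed = 5L, n_sites = 400L,
                           chrom_length_bp = 4e6,
                           pop_sizes = c(popA = 25L, popB = 25L,
                                         popC = 30L))
  founders <- simulate_founders(sim)
  map <- uniform_genetic_map(sim$chrom_length_bp, sim$map_rate_cm_per_mb)
  pops <- lapply(names(sim$pop_sizes), function(p)
    simulate_population(founders, p, sim, map))
  names(pops) <- names(sim$pop_sizes)
  cosmo <- imprecover:::panel_polymorphic(
    pool_panels(pops[c("popA", "popB")], name = "cosmo"))
  donors <- imprecover:::panel_samples(pops$popC, 1:10, name = "donors")
  specific <- imprecover:::panel_polymorphic(donors)
  targets <- imprecover:::panel_samples(pops$popC, 11:30, name = "targets")
  params <- hmm_params(map = map)
  dense <- design_dense_array(pool_panels(pops[c("popA", "popB")]), 150,
                              0.01)
  typed <- intersect(dense$vids, cosmo$variants$vid)
  tp <- imprecover:::panel_subset(
    targets, sort(match(typed, targets$variants$vid)))
  merged <- merge_panels(cosmo, specific, params)
  plan <- make_chunk_plan(sim$chrom_length_bp)
  disc_of <- function(ref) {
    post <- impute_genotypes(
      imprecover:::panel_subset(tp, which(tp$variants$vid %in%
                                            ref$variants$vid)),
      ref, params, plan)
    calls <- threshold_calls(post, 0.9)
    n <- length(targets$sample_ids)
    truth <- targets$haps[seq(1, 2 * n, 2), ] +
      targets$haps[seq(2, 2 * n, 2), ]
    tix <- match(colnames(calls), targets$variants$vid)
    tr <- truth[, tix]
    joint <- !is.na(calls)
    # minor-allele discordance against the truth at untyped sites
    untyped <- !(colnames(calls) %in% typed)
    minor <- tr > 0 & joint & rep(untyped, each = nrow(tr))
    1 - sum(calls[minor] == tr[minor]) / sum(minor)
  }
  expect_lt(disc_of(merged), disc_of(cosmo))
})
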