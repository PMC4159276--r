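# Small in-code fixtures shared across test files.

# A variant table with evenly spaced positions.
vt <- function(n, spacing = 1000, chrom = "1", exonic = FALSE) {
  variant_table(chrom = chrom, pos = spacing * seq_len(n),
                vid = sprintf("v%03d", seq_len(n)), ref = "A", alt = "G",
                exonic = exonic)
}

# A haplotype panel from a plain 0/1 matrix (rows = haplotypes).
hp <- function(haps, spacing = 1000, name = "panel") {
  haps <- as.matrix(haps)
  n <- nrow(haps)
  ids <- if (n %% 2 == 0) sprintf("S%02d", seq_len(n / 2)) else
    sprintf("H%02d", seq_len(n))
  haplotype_panel(vt(ncol(haps), spacing), haps, ids, name = name)
}

# A genotype matrix from a plain matrix (rows = samples, NA = missing).
gm <- function(geno, spacing = 1000) {
  geno <- as.matrix(geno)
  genotype_matrix(vt(ncol(geno), spacing), geno,
                  sprintf("S%02d", seq_len(nrow(geno))))
}

# A posterior tensor from a matrix of triples: one row per (sample,
# variant) in sample-major order.
pt <- function(triples, n_samples, n_variants) {
  probs <- array(0, dim = c(n_samples, n_variants, 3))
  r <- 1
  for (s in seq_len(n_samples)) for (v in seq_len(n_variants)) {
    probs[s, v, ] <- triples[r, ]
    r <- r + 1
  }
  posterior_tensor(probs, sprintf("S%02d", seq_len(n_samples)),
                   sprintf("v%03d", seq_len(n_variants)))
}

# Random small reference panel + typed target for LS property tests.
random_ls_instance <- function(k_ref, n_sites, n_typed, seed) {
  set.seed(seed)
  haps <- matrix(rbinom(k_ref * n_sites, 1, 0.5), nrow = k_ref)
  # ensure no all-identical degenerate panel
  if (k_ref >= 2) haps[1, 1] <- 1L - haps[2, 1]
  ref <- hp(haps, spacing = 2e5)
  typed <- sort(sample(n_sites, n_typed))
  target <- rbinom(n_typed, 1, 0.5)
  params <- hmm_params(error_rate = runif(1, 0.01, 0.2),
                       map = uniform_genetic_map(2e5 * n_sites))
  list(ref = ref, typed_vids = ref$variants$vid[typed],
       target = target, params = params)
}
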