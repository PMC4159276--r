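#' Quality-control thresholds
#'
#' Default values follow the three-step array QC protocol: SNP missingness
#' above 5% removed, gross Hardy-Weinberg departure at p < 1e-8 in the
#' preliminary pass and p < 0.001 in the per-population pass, sample
#' missingness above 2%, cross-array genotype concordance below 99.5%
#' removed, and a 5% MAF floor for the IBS/PCA screens. The excessive-IBS
#' threshold and the PCA outlier rule are not pinned down by the protocol;
#' the defaults (0.9, 6 standard deviations on the top 2 components) are
#' explicit knobs.
#'
#' @param snp_missing_max,hwe_p_prelim,hwe_p_final,sample_missing_max
#'   proportions/p-values as described above.
#' @param cross_array_concordance_min retention floor for SNPs typed on
#'   both arrays.
#' @param ibs_maf_min MAF floor applied before IBS and PCA.
#' @param ibs_excess_threshold pairwise IBS above which a pair is treated
#'   as duplicate/related.
#' @param pca_sd_k outlier distance in within-population standard
#'   deviations.
#' @param pca_components number of leading components screened.
#' @export
qc_thresholds <- function(snp_missing_max = 0.05, hwe_p_prelim = 1e-8,
                          hwe_p_final = 0.001, sample_missing_max = 0.02,
                          cross_array_concordance_min = 0.995,
                          ibs_maf_min = 0.05, ibs_excess_threshold = 0.9,
                          pca_sd_k = 6, pca_components = 2L) {
  props <- c(snp_missing_max, sample_missing_max,
             cross_array_concordance_min, ibs_maf_min, ibs_excess_threshold)
  if (any(props < 0 | props > 1)) stop("proportions must lie in [0, 1]")
  if (hwe_p_prelim <= 0 || hwe_p_prelim >= 1 ||
      hwe_p_final <= 0 || hwe_p_final >= 1)
    stop("HWE thresholds must lie in (0, 1)")
  structure(list(snp_missing_max = snp_missing_max,
                 hwe_p_prelim = hwe_p_prelim, hwe_p_final = hwe_p_final,
                 sample_missing_max = sample_missing_max,
                 cross_array_concordance_min = cross_array_concordance_min,
                 ibs_maf_min = ibs_maf_min,
                 ibs_excess_threshold = ibs_excess_threshold,
                 pca_sd_k = pca_sd_k,
                 pca_components = as.integer(pca_components)),
            class = "qc_thresholds")
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact conditional two-sided p-value for a biallelic genotype table: the
#' sum of the probabilities of all heterozygote counts compatible with the
#' observed allele-count margin (same parity) whose conditional probability
#' does not exceed that of the observed table. Computed with the standard
#' stable recurrence over heterozygote counts.
#'
#' @param n_hom_ref,n_het,n_hom_alt genotype counts, all >= 0, total >= 1.
#' @return p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  if (n_hom_ref < 0 || n_het < 0 || n_hom_alt < 0)
    stop("genotype counts must be non-negative")
  n <- n_hom_ref + n_het + n_hom_alt
  if (n < 1) stop("at least one genotype is required")
  n_ref <- 2 * n_hom_ref + n_het
  rare <- min(n_ref, 2 * n - n_ref)
  if (rare == 0) return(1.0)
  hets <- seq(rare %% 2, rare, by = 2)
  probs <- numeric(length(hets))
  # anchor the recurrence at the modal-ish midpoint for stability
  mid_i <- which.min(abs(hets - rare * (2 * n - rare) / (2 * n)))
  probs[mid_i] <- 1
  up <- function(h, p) {
    n_aa <- (rare - h) / 2
    n_bb <- n - n_aa - h
    p * 4 * n_aa * n_bb / ((h + 2) * (h + 1))
  }
  if (mid_i < length(hets))
    for (i in seq(mid_i, length(hets) - 1))
      probs[i + 1] <- up(hets[i], probs[i])
  if (mid_i > 1)
    for (i in seq(mid_i, 2))
      probs[i - 1] <- probs[i] / up(hets[i - 1], 1)
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_het, hets)]
  if (is.na(p_obs)) stop("heterozygote count incompatible with the margin")
  min(1, sum(probs[probs <= p_obs * (1 + 1e-10)]))
}

#' Per-SNP missingness
#' @param matrix a `genotype_matrix`.
#' @return named proportion of missing calls per variant.
#' @export
snp_missingness <- function(matrix) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  colMeans(is.na(matrix$geno))
}

#' Cross-array genotype concordance at shared SNPs
#'
#' SNPs are matched by variant id and must carry the identical allele pair
#' (allele conflicts are a separate QC removal, not a concordance 0). For
#' each shared SNP the proportion of samples with identical non-missing
#' calls on both arrays is returned, the denominator being the samples
#' called on both.
#'
#' @param m1,m2 `genotype_matrix` objects over the same sample set.
#' @return named vector over shared vids; `NaN` where no sample is jointly
#'   called.
#' @export
cross_array_concordance <- function(m1, m2) {
  common_samples <- intersect(m1$sample_ids, m2$sample_ids)
  if (length(common_samples) == 0) stop("no shared samples between arrays")
  shared <- intersect(m1$variants$vid, m2$variants$vid)
  i1 <- match(shared, m1$variants$vid); i2 <- match(shared, m2$variants$vid)
  same_alleles <- m1$variants$ref[i1] == m2$variants$ref[i2] &
    m1$variants$alt[i1] == m2$variants$alt[i2]
  shared <- shared[same_alleles]
  g1 <- m1$geno[match(common_samples, m1$sample_ids),
                match(shared, m1$variants$vid), drop = FALSE]
  g2 <- m2$geno[match(common_samples, m2$sample_ids),
                match(shared, m2$variants$vid), drop = FALSE]
  joint <- !is.na(g1) & !is.na(g2)
  num <- colSums(joint & g1 == g2, na.rm = TRUE)
  den <- colSums(joint)
  stats::setNames(num / den, shared)
}

#' Pairwise identity-by-state matrix
#'
#' IBS between two samples is the mean, over jointly called SNPs passing
#' the MAF filter, of `(2 - |g_i - g_j|) / 2`. Symmetric with unit
#' diagonal. Pairs with no jointly called SNP are `NaN` and flagged in the
#' `"undefined_pairs"` attribute.
#'
#' @param matrix a `genotype_matrix` with at least two samples.
#' @param maf_min MAF floor (computed from observed calls) applied before
#'   the calculation.
#' @export
ibs_matrix <- function(matrix, maf_min = 0.05) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  if (nrow(matrix$geno) < 2) stop("at least two samples are required")
  g <- matrix$geno
  keep <- which(apply(g, 2, function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) return(FALSE)
    f <- sum(x) / (2 * length(x))
    min(f, 1 - f) >= maf_min
  }))
  g <- g[, keep, drop = FALSE]
  A <- (!is.na(g) & g == 0) * 1
  B <- (!is.na(g) & g == 1) * 1
  C <- (!is.na(g) & g == 2) * 1
  M <- (!is.na(g)) * 1
  sim <- tcrossprod(A) + tcrossprod(B) + tcrossprod(C) +
    0.5 * (tcrossprod(A, B) + tcrossprod(B, A) +
             tcrossprod(B, C) + tcrossprod(C, B))
  joint <- tcrossprod(M)
  ibs <- sim / joint
  diag(ibs) <- 1
  dimnames(ibs) <- list(matrix$sample_ids, matrix$sample_ids)
  undef <- which(joint == 0 & upper.tri(joint), arr.ind = TRUE)
  attr(ibs, "undefined_pairs") <- undef
  ibs
}

#' Flag samples with excessive IBS sharing
#'
#' Pairs above the threshold are processed greedily by descending IBS; in
#' each still-intact pair the member with the lower call rate is removed
#' (the higher-call-rate sample is retained), ties broken by removing the
#' lexicographically later sample id.
#'
#' @param ibs pairwise IBS matrix (see [ibs_matrix()]).
#' @param call_rates named per-sample call rates.
#' @param threshold IBS value above which a pair counts as excessive.
#' @return character vector of removed sample ids (possibly empty).
#' @export
flag_excess_ibs <- function(ibs, call_rates, threshold = 0.9) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  ids <- rownames(ibs)
  hits <- which(upper.tri(ibs) & ibs > threshold, arr.ind = TRUE)
  if (nrow(hits) == 0) return(character(0))
  hits <- hits[order(-ibs[hits]), , drop = FALSE]
  removed <- character(0)
  for (r in seq_len(nrow(hits))) {
    a <- ids[hits[r, 1]]; b <- ids[hits[r, 2]]
    if (a %in% removed || b %in% removed) next
    ca <- call_rates[[a]]; cb <- call_rates[[b]]
    removed <- c(removed,
                 if (ca > cb) b else if (cb > ca) a else max(a, b))
  }
  removed
}

#' Flag population outliers by principal components analysis
#'
#' Genotypes are encoded 0/1/2 with missing data as -1, restricted to SNPs
#' with observed MAF at least `maf_min`, column-centered, and the sample
#' covariance matrix eigendecomposed. A sample is flagged when, on any of
#' the leading `n_components`, its score lies more than `k_sd` standard
#' deviations from its own self-reported population's score mean.
#'
#' @param matrix a `genotype_matrix`.
#' @param maf_min MAF floor.
#' @param n_components number of leading components screened.
#' @param k_sd outlier distance in within-population standard deviations.
#' @param labels named (or positionally aligned) population label per
#'   sample.
#' @return character vector of removed sample ids.
#' @export
pca_flag_outliers <- function(matrix, maf_min = 0.05, n_components = 2,
                              k_sd = 6, labels) {
  g <- matrix$geno
  if (nrow(g) < n_components + 1)
    stop("need more samples than components")
  labels <- rep_len(as.character(labels), nrow(g))
  keep <- apply(g, 2, function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) return(FALSE)
    f <- sum(x) / (2 * length(x))
    min(f, 1 - f) >= maf_min
  })
  x <- g[, keep, drop = FALSE]
  x[is.na(x)] <- -1L
  xc <- scale(x, center = TRUE, scale = FALSE)
  if (all(abs(xc) < 1e-12)) stop("degenerate zero-variance genotype data")
  cv <- tcrossprod(xc) / max(1, ncol(xc) - 1)
  ev <- eigen(cv, symmetric = TRUE)
  if (ev$values[1] <= 1e-12) stop("degenerate zero-variance genotype data")
  scores <- ev$vectors[, seq_len(n_components), drop = FALSE]
  out <- rep(FALSE, nrow(g))
  if (!is.finite(k_sd)) return(character(0))
  for (j in seq_len(n_components)) {
    s <- scores[, j]
    for (pop in unique(labels)) {
      i <- labels == pop
      mu <- mean(s[i]); sdev <- stats::sd(s[i])
      out[i] <- out[i] | abs(s[i] - mu) > k_sd * sdev
    }
  }
  matrix$sample_ids[out]
}

# Internal: HWE p-values per column of a genotype matrix, optionally by
# population subset; monomorphic or all-missing columns return 1.
hwe_pvalues <- function(geno) {
  apply(geno, 2, function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) return(1.0)
    hwe_exact_test(sum(x == 0), sum(x == 1), sum(x == 2))
  })
}

#' Run the full three-step QC
#'
#' Step A is a joint SNP pass across all samples: (i) unknown/duplicate
#' coordinates, (ii) off-target chromosomes, (iii) unknown strand, (iv)
#' conflicting allele designation between arrays, (v) cross-array
#' concordance below the floor, (vi) missingness above the cap, (vii)
#' gross HWE departure. Step B screens samples: (i) high missingness,
#' (ii) excessive IBS (lower-call-rate member removed), (iii) PCA outliers
#' from the self-reported population. Step C repeats SNP missingness and a
#' milder HWE test within each population; a SNP failing in any population
#' is removed. Each removed item carries its first-triggering reason code.
#'
#' @param matrices named list of `genotype_matrix` objects (one per array)
#'   over the same sample set.
#' @param thresholds a [qc_thresholds()].
#' @param labels per-sample population labels, aligned with the sample ids
#'   of the first matrix.
#' @return list with `matrices` (cleaned, same names) and `report`
#'   (class `qc_report`: `removed_snps`, `removed_samples`, `counts`).
#' @export
run_qc <- function(matrices, thresholds = qc_thresholds(), labels) {
  stopifnot(length(matrices) >= 1)
  samples <- matrices[[1]]$sample_ids
  for (m in matrices)
    if (!setequal(m$sample_ids, samples))
      stop("all arrays must cover the same sample set")
  labels <- stats::setNames(rep_len(as.character(labels), length(samples)),
                            samples)
  snp_reason <- character(0)  # named by vid
  mark_snp <- function(vids, reason) {
    new <- setdiff(vids, names(snp_reason))
    if (length(new))
      snp_reason[new] <<- reason
  }

  # --- Step A: joint SNP QC -------------------------------------------
  for (m in matrices) {
    v <- m$variants
    bad_coord <- v$vid[is.na(v$pos) |
                         duplicated(paste(v$chrom, v$pos)) |
                         duplicated(paste(v$chrom, v$pos), fromLast = TRUE)]
    mark_snp(bad_coord, "A.i")
    mark_snp(v$vid[!v$chrom %in% c(as.character(1:22), "X", "Y")], "A.ii")
    mark_snp(v$vid[is.na(v$strand) | !v$strand %in% c("+", "-")], "A.iii")
  }
  if (length(matrices) >= 2) {
    for (i in seq_along(matrices)) for (j in seq_along(matrices)) {
      if (j <= i) next
      v1 <- matrices[[i]]$variants; v2 <- matrices[[j]]$variants
      shared <- intersect(v1$vid, v2$vid)
      i1 <- match(shared, v1$vid); i2 <- match(shared, v2$vid)
      conflict <- shared[v1$ref[i1] != v2$ref[i2] |
                           v1$alt[i1] != v2$alt[i2]]
      mark_snp(conflict, "A.iv")
      conc <- cross_array_concordance(matrices[[i]], matrices[[j]])
      mark_snp(names(conc)[!is.nan(conc) &
                             conc < thresholds$cross_array_concordance_min],
               "A.v")
    }
  }
  for (m in matrices) {
    miss <- snp_missingness(m)
    mark_snp(names(miss)[miss > thresholds$snp_missing_max], "A.vi")
  }
  for (m in matrices) {
    left <- setdiff(m$variants$vid, names(snp_reason))
    p <- hwe_pvalues(m$geno[, left, drop = FALSE])
    mark_snp(left[p < thresholds$hwe_p_prelim], "A.vii")
  }
  drop_snps <- function(mats) lapply(mats, function(m) {
    keep <- !(m$variants$vid %in% names(snp_reason))
    genotype_matrix(m$variants[keep, , drop = FALSE],
                    m$geno[, keep, drop = FALSE], m$sample_ids)
  })
  mats <- drop_snps(matrices)

  # --- Step B: sample QC ----------------------------------------------
  combined_geno <- do.call(cbind, lapply(mats, `[[`, "geno"))
  combined_vt <- do.call(rbind, lapply(mats, `[[`, "variants"))
  combined_vt$vid <- make.unique(combined_vt$vid)
  ord <- order(combined_vt$pos)
  sample_reason <- character(0)
  miss_s <- rowMeans(is.na(combined_geno))
  bad <- samples[miss_s > thresholds$sample_missing_max]
  sample_reason[bad] <- "B.miss"
  call_rates <- stats::setNames(1 - miss_s, samples)
  comb_gm <- genotype_matrix(combined_vt[ord, , drop = FALSE],
                             combined_geno[, ord, drop = FALSE], samples)
  ibs <- ibs_matrix(comb_gm, maf_min = thresholds$ibs_maf_min)
  for (s in flag_excess_ibs(ibs, call_rates,
                            thresholds$ibs_excess_threshold))
    if (!s %in% names(sample_reason)) sample_reason[s] <- "B.ibs"
  pca_out <- pca_flag_outliers(comb_gm, maf_min = thresholds$ibs_maf_min,
                               n_components = thresholds$pca_components,
                               k_sd = thresholds$pca_sd_k,
                               labels = labels[samples])
  for (s in pca_out)
    if (!s %in% names(sample_reason)) sample_reason[s] <- "B.pca"
  keep_s <- setdiff(samples, names(sample_reason))
  if (length(keep_s) == 0) stop("sample QC removed every sample")
  mats <- lapply(mats, function(m) {
    i <- match(keep_s, m$sample_ids)
    genotype_matrix(m$variants, m$geno[i, , drop = FALSE], keep_s)
  })
  labels <- labels[keep_s]

  # --- Step C: per-population SNP QC ----------------------------------
  for (m in mats) {
    for (pop in unique(labels)) {
      rows <- which(labels == pop)
      sub <- m$geno[rows, , drop = FALSE]
      miss <- colMeans(is.na(sub))
      mark_snp(m$variants$vid[miss > thresholds$snp_missing_max], "C.miss")
      left <- setdiff(m$variants$vid, names(snp_reason))
      p <- hwe_pvalues(sub[, left, drop = FALSE])
      mark_snp(left[p < thresholds$hwe_p_final], "C.hwe")
    }
  }
  mats <- drop_snps(mats)
  if (all(vapply(mats, function(m) ncol(m$geno), 1L) == 0))
    stop("SNP QC removed every variant")

  report <- structure(
    list(removed_snps = data.frame(
           vid = names(snp_reason), reason = unname(snp_reason),
           stringsAsFactors = FALSE),
         removed_samples = data.frame(
           sample_id = names(sample_reason),
           reason = unname(sample_reason), stringsAsFactors = FALSE),
         counts = c(samples_in = length(samples),
                    samples_out = length(keep_s),
                    snps_removed = length(snp_reason))),
    class = "qc_report")
  list(matrices = mats, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC report: %d SNP removal(s), %d sample removal(s)\n",
              nrow(x$removed_snps), nrow(x$removed_samples)))
  if (nrow(x$removed_snps))
    print(table(x$removed_snps$reason))
  if (nrow(x$removed_samples))
    print(table(x$removed_samples$reason))
  invisible(x)
}
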