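#' Minor allele frequency of one site
#'
#' Computed from observed (non-missing) calls; heterozygotes contribute
#' one of each allele.
#'
#' @param calls genotype values 0/1/2 (ploidy 2) or haplotype alleles 0/1
#'   (ploidy 1), `NA` allowed.
#' @param ploidy 2 for genotypes (default), 1 for haplotypes.
#' @return MAF in [0, 0.5].
#' @export
maf_of <- function(calls, ploidy = 2) {
  calls <- calls[!is.na(calls)]
  if (length(calls) == 0) stop("MAF undefined: all calls missing")
  f <- sum(calls) / (ploidy * length(calls))
  min(f, 1 - f)
}

#' Classify MAF into the standard frequency bins
#'
#' Bins: monomorphic (MAF = 0), rare (0 < MAF <= 0.01), low_frequency
#' (0.01 < MAF < 0.05), common (MAF >= 0.05).
#'
#' @param maf numeric vector of minor allele frequencies in [0, 0.5].
#' @return factor with levels `monomorphic, rare, low_frequency, common`.
#' @export
maf_bin <- function(maf) {
  if (any(maf < 0 | maf > 0.5, na.rm = TRUE))
    stop("MAF must lie in [0, 0.5]")
  lv <- c("monomorphic", "rare", "low_frequency", "common")
  out <- ifelse(maf == 0, "monomorphic",
                ifelse(maf <= 0.01, "rare",
                       ifelse(maf < 0.05, "low_frequency", "common")))
  factor(out, levels = lv)
}

#' Imputation info score at one SNP
#'
#' The ratio-of-variances information measure: with per-sample expected
#' dosage `e_i = p_i(1) + 2 p_i(2)`, second moment `f_i = p_i(1) + 4
#' p_i(2)` and estimated allele frequency `theta = sum(e_i) / (2N)`,
#' `info = 1 - sum(f_i - e_i^2) / (2N theta (1 - theta))`. When theta is
#' 0 or 1 the score is 1 by convention; negative values are clipped to 0.
#'
#' @param posteriors_at_snp numeric matrix N x 3 of genotype posterior
#'   triples at one SNP.
#' @return info score in [0, 1].
#' @export
info_score <- function(posteriors_at_snp) {
  p <- rbind(posteriors_at_snp)
  n <- nrow(p)
  e <- p[, 2] + 2 * p[, 3]
  f <- p[, 2] + 4 * p[, 3]
  theta <- sum(e) / (2 * n)
  if (theta <= 0 || theta >= 1) return(1.0)
  info <- 1 - sum(f - e^2) / (2 * n * theta * (1 - theta))
  min(1, max(0, info))
}

#' Call rate of thresholded genotypes at one SNP
#' @param calls_at_snp per-sample calls with `NA` for no-calls.
#' @return fraction of non-missing calls.
#' @export
snp_call_rate <- function(calls_at_snp) {
  if (length(calls_at_snp) == 0) stop("at least one sample is required")
  mean(!is.na(calls_at_snp))
}

#' Is a SNP well imputed?
#'
#' A SNP is well imputed when info is at least 0.3 AND the call rate is at
#' least 0.95 (both boundaries inclusive); otherwise it is poorly imputed.
#'
#' @param info,call_rate numeric vectors in [0, 1].
#' @return logical vector.
#' @export
classify_well_imputed <- function(info, call_rate) {
  info >= 0.3 & call_rate >= 0.95
}

#' Per-SNP imputation quality from a posterior tensor
#'
#' @param posteriors a `posterior_tensor`.
#' @param threshold calling threshold used for the call rate, default 0.90.
#' @return data.frame with `vid`, `info`, `call_rate`, `well_imputed`.
#' @export
snp_quality <- function(posteriors, threshold = 0.9) {
  calls <- threshold_calls(posteriors, threshold)
  m <- dim(posteriors)[2]
  info <- vapply(seq_len(m), function(j)
    info_score(posteriors[, j, , drop = TRUE]), 1.0)
  cr <- colMeans(!is.na(calls))
  data.frame(vid = dimnames(posteriors)[[2]], info = info, call_rate = cr,
             well_imputed = classify_well_imputed(info, cr),
             stringsAsFactors = FALSE)
}

# Internal: align two genotype matrices on shared samples and vids.
align_calls <- function(imputed, observed, vids) {
  samples <- intersect(rownames(imputed), observed$sample_ids)
  vids <- intersect(intersect(vids, colnames(imputed)),
                    observed$variants$vid)
  list(imp = imputed[match(samples, rownames(imputed)),
                     match(vids, colnames(imputed)), drop = FALSE],
       obs = observed$geno[match(samples, observed$sample_ids),
                           match(vids, observed$variants$vid),
                           drop = FALSE],
       vids = vids)
}

#' Overall concordance between imputed and observed genotypes, by MAF bin
#'
#' The proportion of imputed genotype calls identical to the observed
#' genotypes, per MAF bin, restricted to the supplied evaluation variants
#' (typically the well-imputed SNPs present on both sides). Pairs where
#' either call is missing are excluded from the denominator.
#'
#' @param imputed integer call matrix (samples x variants, `NA` no-call)
#'   with dimnames, e.g. from [threshold_calls()].
#' @param observed a `genotype_matrix` of observed genotypes.
#' @param bins named factor of MAF bins per evaluation variant (see
#'   [maf_bin()]).
#' @param at optional character vector restricting the evaluation variant
#'   set; defaults to the names of `bins`.
#' @return data.frame per bin: `n_joint`, `n_match`, `concordance`,
#'   `discordance` (`NA` where a bin has no jointly called pair).
#' @export
overall_concordance <- function(imputed, observed, bins, at = names(bins)) {
  al <- align_calls(imputed, observed, at)
  bins <- bins[al$vids]
  joint <- !is.na(al$imp) & !is.na(al$obs)
  match_m <- joint & al$imp == al$obs
  n_joint <- tapply(colSums(joint), bins, sum, default = 0)
  n_match <- tapply(colSums(match_m, na.rm = TRUE), bins, sum, default = 0)
  conc <- ifelse(n_joint > 0, n_match / n_joint, NA_real_)
  data.frame(bin = levels(bins), n_joint = as.integer(n_joint),
             n_match = as.integer(n_match), concordance = as.numeric(conc),
             discordance = 1 - as.numeric(conc), stringsAsFactors = FALSE)
}

#' Minor-allele concordance at rare and low-frequency SNPs
#'
#' Concordance restricted to observed genotypes carrying at least one
#' minor allele (heterozygous or minor-homozygous), over the well-imputed
#' rare and low-frequency SNPs. The denominator counts observed
#' minor-allele genotypes with a non-missing imputed call; the numerator
#' counts those where the imputed call equals the observed genotype. This
#' exposes the failure mode where imputing everything as the major
#' homozygote looks near-perfect under overall concordance.
#'
#' @param imputed integer call matrix with dimnames.
#' @param observed a `genotype_matrix`.
#' @param bins named factor of MAF bins per variant; only variants binned
#'   rare or low_frequency enter.
#' @return data.frame for bins rare, low_frequency and pooled
#'   (`rare_low_combined`): `n_minor_obs`, `n_match`, `concordance`,
#'   `discordance`.
#' @export
minor_allele_concordance <- function(imputed, observed, bins) {
  keep <- names(bins)[bins %in% c("rare", "low_frequency")]
  al <- align_calls(imputed, observed, keep)
  res <- lapply(c("rare", "low_frequency", "rare_low_combined"),
                function(b) {
    vids <- if (b == "rare_low_combined") al$vids else
      al$vids[bins[al$vids] == b]
    obs <- al$obs[, match(vids, al$vids), drop = FALSE]
    imp <- al$imp[, match(vids, al$vids), drop = FALSE]
    # minor allele orientation from the observed genotype frequencies
    minor_is_alt <- vapply(seq_along(vids), function(j) {
      x <- obs[, j]; x <- x[!is.na(x)]
      if (length(x) == 0) return(TRUE)
      sum(x) / (2 * length(x)) <= 0.5
    }, TRUE)
    carries <- obs
    for (j in seq_along(vids))
      carries[, j] <- if (minor_is_alt[j]) obs[, j] >= 1 else obs[, j] <= 1
    denom_m <- !is.na(obs) & !is.na(imp) & carries
    num_m <- denom_m & imp == obs
    n_den <- sum(denom_m, na.rm = TRUE)
    n_num <- sum(num_m, na.rm = TRUE)
    data.frame(bin = b, n_minor_obs = n_den, n_match = n_num,
               concordance = if (n_den > 0) n_num / n_den else NA_real_,
               discordance = if (n_den > 0) 1 - n_num / n_den else
                 NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Coverage accounting of chip content against reference panels
#'
#' Each chip SNP is binned by its MAF in the target population's observed
#' genotypes and classified as covered (present in at least one reference
#' panel, hence imputable in principle) or not covered.
#'
#' @param chip an `array_design`.
#' @param panels list of `haplotype_panel`s (the available reference
#'   panels).
#' @param target_obs `genotype_matrix` of the target population's observed
#'   genotypes at (at least) the chip sites.
#' @return data.frame per bin x covered state with counts, proportion of
#'   the chip total and proportion of the polymorphic subtotal; attribute
#'   `"n_polymorphic"` carries the polymorphic subtotal (0 is flagged with
#'   a message).
#' @export
coverage_accounting <- function(chip, panels, target_obs) {
  idx <- match(chip$vids, target_obs$variants$vid)
  if (anyNA(idx)) stop("target_obs must cover every chip site")
  maf <- vapply(idx, function(j) maf_of(target_obs$geno[, j]), 1.0)
  bins <- maf_bin(maf)
  panel_vids <- unique(unlist(lapply(panels,
                                     function(p) p$variants$vid)))
  covered <- chip$vids %in% panel_vids
  grid <- expand.grid(bin = levels(bins), covered = c(TRUE, FALSE),
                      stringsAsFactors = FALSE)
  grid$n <- mapply(function(b, cv) sum(bins == b & covered == cv),
                   grid$bin, grid$covered)
  n_total <- length(chip$vids)
  n_poly <- sum(bins != "monomorphic")
  if (n_poly == 0) message("chip is monomorphic everywhere in the target")
  grid$prop_total <- grid$n / n_total
  grid$prop_polymorphic <- ifelse(grid$bin == "monomorphic", NA_real_,
                                  if (n_poly > 0) grid$n / n_poly else
                                    NA_real_)
  attr(grid, "n_polymorphic") <- n_poly
  grid
}

#' Recoverable exonic content by frequency group
#'
#' Mirrors the actual-coverage accounting of exonic variants: for each
#' frequency group (rare and low-frequency pooled, versus common, binned
#' from the target truth) the number of exonic target-polymorphic sites in
#' total, overlapping the study array, present on the chip, and well
#' imputed per panel configuration. Array-overlap sites are excluded from
#' the imputed counts: they were typed, not recovered.
#'
#' @param truth a `truth_set` (see [genotype_samples()]).
#' @param region_flags logical per-variant exonic flag aligned with the
#'   truth variants (defaults to the truth variant table's `exonic`
#'   column).
#' @param array the study `array_design`.
#' @param chip the exome-style `array_design`.
#' @param quality named list (one entry per panel configuration) of
#'   quality data.frames with columns `vid` and `well_imputed` (see
#'   [snp_quality()]).
#' @return data.frame: `metric`, `rare_low`, `common` counts.
#' @export
recoverable_content <- function(truth, region_flags = NULL, array, chip,
                                quality) {
  gm <- truth$true_genotypes
  if (is.null(region_flags)) region_flags <- gm$variants$exonic
  maf <- apply(gm$geno, 2, maf_of)
  bins <- maf_bin(maf)
  exonic_poly <- which(region_flags & bins != "monomorphic")
  vids <- gm$variants$vid[exonic_poly]
  grp <- ifelse(bins[exonic_poly] == "common", "common", "rare_low")
  on_array <- vids %in% array$vids
  row_of <- function(sel, metric)
    data.frame(metric = metric,
               rare_low = sum(sel & grp == "rare_low"),
               common = sum(sel & grp == "common"),
               stringsAsFactors = FALSE)
  out <- rbind(row_of(rep(TRUE, length(vids)), "in_total"),
               row_of(on_array, "overlap_array"),
               row_of(vids %in% chip$vids, "on_chip"))
  for (cfg in names(quality)) {
    q <- quality[[cfg]]
    wi <- vids %in% q$vid[q$well_imputed] & !on_array
    out <- rbind(out, row_of(wi, paste0("imputed_", cfg)))
  }
  out
}
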