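#' Construct a variant table
#'
#' Builds and validates the per-variant metadata table shared by haplotype
#' panels and genotype matrices. Only biallelic SNPs are representable:
#' both alleles must be single nucleotides and differ.
#'
#' @param chrom character vector of chromosome labels.
#' @param pos integer vector of 1-based base-pair positions, strictly
#'   increasing within a chromosome.
#' @param vid character vector of variant identifiers, unique.
#' @param ref,alt single-character alleles in \code{A,C,G,T}.
#' @param exonic optional logical flag per variant (used by the coverage
#'   accounting of exonic content); defaults to \code{FALSE}.
#' @param strand optional strand annotation (\code{"+"}, \code{"-"} or
#'   \code{NA} for unknown); defaults to \code{"+"}.
#' @return a \code{data.frame} with columns \code{chrom, pos, vid, ref, alt,
#'   exonic, strand}.
#' @export
variant_table <- function(chrom, pos, vid, ref, alt, exonic = FALSE,
                          strand = "+") {
  n <- length(pos)
  chrom <- rep_len(as.character(chrom), n)
  exonic <- rep_len(as.logical(exonic), n)
  strand <- rep_len(as.character(strand), n)
  ref <- rep_len(as.character(ref), n)
  alt <- rep_len(as.character(alt), n)
  stopifnot(length(vid) == n)
  if (anyDuplicated(vid)) stop("variant ids must be unique within a panel")
  if (any(pos < 1)) stop("positions must be >= 1")
  bases <- c("A", "C", "G", "T")
  if (!all(ref %in% bases) || !all(alt %in% bases))
    stop("alleles must be single nucleotides in A,C,G,T")
  if (any(ref == alt)) stop("ref and alt alleles must differ")
  for (ch in unique(chrom)) {
    p <- pos[chrom == ch]
    if (is.unsorted(p, strictly = TRUE))
      stop("positions must be strictly increasing within chromosome ", ch)
  }
  data.frame(chrom = chrom, pos = as.integer(pos), vid = as.character(vid),
             ref = ref, alt = alt, exonic = exonic, strand = strand,
             stringsAsFactors = FALSE)
}

#' Phased haplotype panel
#'
#' The unit of reference data and of simulation truth: a matrix of phased
#' 0/1 alleles with two haplotype rows per sample, plus the variant table.
#'
#' @param variants a variant table (see [variant_table()]).
#' @param haps integer matrix of 0/1 alleles, `2 * length(sample_ids)` rows
#'   (haplotypes) by `nrow(variants)` columns (variants). Rows are ordered
#'   sample-major: the two haplotypes of sample i are rows `2i - 1` and `2i`.
#' @param sample_ids character vector of sample labels.
#' @param name panel label.
#' @return an object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(variants, haps, sample_ids,
                            name = "panel") {
  haps <- as.matrix(haps)
  storage.mode(haps) <- "integer"
  if (ncol(haps) != nrow(variants))
    stop("haplotype column count must equal variant count")
  diploid <- nrow(haps) == 2L * length(sample_ids)
  if (!diploid && nrow(haps) != length(sample_ids))
    stop("expected two haplotype rows per sample (or one, for a haploid ",
         "panel)")
  if (anyNA(haps) || !all(haps %in% c(0L, 1L)))
    stop("haplotype alleles must be 0/1 with no missing values")
  colnames(haps) <- variants$vid
  rownames(haps) <- if (diploid)
    paste0(rep(sample_ids, each = 2L), "_", c(1L, 2L)) else sample_ids
  structure(list(variants = variants, haps = haps,
                 sample_ids = as.character(sample_ids), name = name),
            class = "haplotype_panel")
}

#' Genotype matrix
#'
#' Unphased genotype calls coded 0/1/2 (count of alt alleles) with `NA` as
#' the missing-genotype sentinel. Missing values never enter arithmetic:
#' every consumer handles them explicitly.
#'
#' @param variants a variant table.
#' @param geno integer matrix, samples x variants, values in
#'   `{0, 1, 2, NA}`.
#' @param sample_ids character vector of sample labels.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(variants, geno, sample_ids) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (ncol(geno) != nrow(variants))
    stop("genotype column count must equal variant count")
  if (nrow(geno) != length(sample_ids))
    stop("one genotype row per sample required")
  ok <- is.na(geno) | geno %in% c(0L, 1L, 2L)
  if (!all(ok)) stop("genotype values must be 0, 1, 2 or NA")
  colnames(geno) <- variants$vid
  rownames(geno) <- sample_ids
  structure(list(variants = variants, geno = geno,
                 sample_ids = as.character(sample_ids)),
            class = "genotype_matrix")
}

#' Genetic map with linear interpolation
#'
#' IMPUTE-dialect genetic map: physical position, local recombination rate
#' (cM/Mb) and cumulative genetic distance (cM). Queries between entries
#' interpolate linearly in base pairs; queries beyond the last entry
#' extrapolate at the last rate; queries before the first entry extrapolate
#' at the first rate (floored at 0 cM).
#'
#' @param pos integer positions (bp), strictly increasing.
#' @param rate recombination rate in cM/Mb at each position.
#' @param cm cumulative genetic distance in cM, non-decreasing.
#' @return an object of class `genetic_map`.
#' @export
genetic_map <- function(pos, rate, cm) {
  stopifnot(length(pos) == length(rate), length(pos) == length(cm))
  if (is.unsorted(pos, strictly = TRUE))
    stop("genetic map positions must be strictly increasing")
  if (is.unsorted(cm)) stop("cumulative cM must be non-decreasing")
  structure(list(pos = as.numeric(pos), rate = as.numeric(rate),
                 cm = as.numeric(cm)), class = "genetic_map")
}

#' Uniform-rate genetic map
#'
#' Convenience constructor for a constant-rate map over `[1, length_bp]`.
#'
#' @param length_bp chromosome length in bp.
#' @param rate_cm_per_mb constant rate, default 1 cM/Mb.
#' @export
uniform_genetic_map <- function(length_bp, rate_cm_per_mb = 1) {
  genetic_map(pos = c(1, length_bp),
              rate = c(rate_cm_per_mb, rate_cm_per_mb),
              cm = c(0, (length_bp - 1) / 1e6 * rate_cm_per_mb))
}

#' Interpolate genetic position
#'
#' @param map a `genetic_map`.
#' @param pos physical positions (bp) to query.
#' @return cumulative genetic distance in cM at each query position.
#' @export
map_cm <- function(map, pos) {
  stopifnot(inherits(map, "genetic_map"))
  n <- length(map$pos)
  out <- numeric(length(pos))
  for (i in seq_along(pos)) {
    p <- pos[i]
    if (p <= map$pos[1]) {
      out[i] <- max(0, map$cm[1] - (map$pos[1] - p) / 1e6 * map$rate[1])
    } else if (p >= map$pos[n]) {
      out[i] <- map$cm[n] + (p - map$pos[n]) / 1e6 * map$rate[n]
    } else {
      j <- findInterval(p, map$pos)
      w <- (p - map$pos[j]) / (map$pos[j + 1] - map$pos[j])
      out[i] <- map$cm[j] + w * (map$cm[j + 1] - map$cm[j])
    }
  }
  out
}

#' Array design: a named variant subset
#'
#' @param name design label (e.g. "dense", "legacy550", "exome_chip").
#' @param vids character vector of variant ids on the array, non-empty.
#' @param design_rule one of `"dense"`, `"legacy_rebuilt"`, `"exome_style"`.
#' @return an object of class `array_design`.
#' @export
array_design <- function(name, vids,
                         design_rule = c("dense", "legacy_rebuilt",
                                         "exome_style")) {
  design_rule <- match.arg(design_rule)
  vids <- unique(as.character(vids))
  if (length(vids) == 0) stop("array design must contain at least one variant")
  structure(list(name = name, vids = vids, design_rule = design_rule),
            class = "array_design")
}

#' Posterior tensor constructor
#'
#' Per-sample, per-variant genotype posterior triples, stored as an
#' N x M x 3 array. Every triple must be non-negative and sum to 1 within
#' 1e-6.
#'
#' @param probs numeric array N x M x 3.
#' @param sample_ids,vids dimension labels.
#' @export
posterior_tensor <- function(probs, sample_ids = NULL, vids = NULL) {
  stopifnot(length(dim(probs)) == 3, dim(probs)[3] == 3)
  if (any(probs < 0)) stop("posterior probabilities must be non-negative")
  s <- probs[, , 1, drop = FALSE] + probs[, , 2, drop = FALSE] +
    probs[, , 3, drop = FALSE]
  if (any(abs(s - 1) > 1e-6))
    stop("posterior triples must sum to 1 within 1e-6")
  dimnames(probs) <- list(sample_ids, vids, c("g0", "g1", "g2"))
  structure(probs, class = c("posterior_tensor", "array"))
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("haplotype panel '%s': %d haplotypes (%d samples) x %d variants\n",
              x$name, nrow(x$haps), length(x$sample_ids), ncol(x$haps)))
  invisible(x)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  nm <- sum(is.na(x$geno))
  cat(sprintf("genotype matrix: %d samples x %d variants (%d missing calls)\n",
              nrow(x$geno), ncol(x$geno), nm))
  invisible(x)
}

#' @export
print.array_design <- function(x, ...) {
  cat(sprintf("array design '%s' (%s): %d variants\n",
              x$name, x$design_rule, length(x$vids)))
  invisible(x)
}

# Internal: subset a haplotype panel by variant index, keeping order.
panel_subset <- function(panel, idx) {
  haplotype_panel(panel$variants[idx, , drop = FALSE],
                  panel$haps[, idx, drop = FALSE],
                  panel$sample_ids, panel$name)
}

# Internal: alt-allele frequency per variant from phased haplotypes.
panel_freq <- function(panel) colMeans(panel$haps)

# Internal: minor allele frequency per variant from phased haplotypes.
panel_maf <- function(panel) pmin(panel_freq(panel), 1 - panel_freq(panel))
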