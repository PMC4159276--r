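#' Read a VCF file into a haplotype panel or genotype matrix
#'
#' Parses a VCF 4.x file (through vcfR) keeping biallelic SNP records only;
#' multi-allelic, indel or otherwise non-SNP records are skipped and their
#' count is reported via `attr(, "n_skipped")` and a message. With
#' `require_phased = TRUE` every genotype must use the `|` separator and the
#' result is a [haplotype_panel()]; otherwise genotypes are collapsed to
#' 0/1/2 counts (`./.` becomes `NA`) in a [genotype_matrix()].
#'
#' @param path path to an uncompressed or gzipped VCF.
#' @param require_phased logical; demand fully phased genotypes and return
#'   haplotypes.
#' @param panel_name label for the returned panel.
#' @return a `haplotype_panel` (phased mode) or `genotype_matrix`, with
#'   attribute `n_skipped` holding the skipped-record count.
#' @export
read_vcf <- function(path, require_phased = FALSE, panel_name = "panel") {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  is_snp <- !is.na(alt) & nchar(ref) == 1 & nchar(alt) == 1 &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T") &
    ref != alt
  n_skipped <- sum(!is_snp)
  if (n_skipped > 0)
    message(n_skipped, " non-biallelic-SNP record(s) skipped")
  if (!any(is_snp)) stop("no biallelic SNP records in ", path)
  fix <- fix[is_snp, , drop = FALSE]
  gt <- vcfR::extract.gt(v, element = "GT")[is_snp, , drop = FALSE]
  samples <- colnames(gt)
  vid <- fix[, "ID"]
  fill <- is.na(vid) | vid == "."
  vid[fill] <- paste0(fix[fill, "CHROM"], "_", fix[fill, "POS"])
  variants <- variant_table(chrom = fix[, "CHROM"],
                            pos = as.integer(fix[, "POS"]),
                            vid = vid, ref = fix[, "REF"], alt = fix[, "ALT"])

  miss <- is.na(gt) | gt %in% c("./.", ".|.", ".")
  ploidy <- nchar(gsub("[^/|]", "", gt[!miss]))
  if (length(ploidy) && length(unique(ploidy)) > 1)
    stop("mixed ploidy in ", path)
  if (require_phased) {
    unphased <- !miss & grepl("/", gt, fixed = TRUE)
    if (any(miss))
      stop("missing genotypes are not allowed in a phased haplotype panel")
    if (any(unphased)) {
      w <- which(unphased, arr.ind = TRUE)[1, ]
      stop(sprintf("unphased genotype at variant %s, sample %s",
                   variants$vid[w[1]], samples[w[2]]))
    }
    a1 <- substr(gt, 1, 1); a2 <- substr(gt, 3, 3)
    n <- length(samples); m <- nrow(variants)
    haps <- matrix(0L, nrow = 2 * n, ncol = m)
    haps[seq(1, 2 * n, by = 2), ] <- t(matrix(as.integer(a1), nrow = m))
    haps[seq(2, 2 * n, by = 2), ] <- t(matrix(as.integer(a2), nrow = m))
    out <- haplotype_panel(variants, haps, samples, name = panel_name)
  } else {
    g1 <- suppressWarnings(as.integer(substr(gt, 1, 1)))
    g2 <- suppressWarnings(as.integer(substr(gt, 3, 3)))
    g <- g1 + g2
    g[miss] <- NA_integer_
    out <- genotype_matrix(variants, t(matrix(g, nrow = nrow(variants))),
                           samples)
  }
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write genotype calls and posteriors as a VCF with GT and GP fields
#'
#' Emits a plain-text VCF 4.2 whose GT field carries the thresholded calls
#' (`NA` as `./.`) and whose GP field carries the three genotype posteriors
#' rounded to 3 decimals. Reading the file back with [read_vcf()] recovers
#' the genotype matrix exactly.
#'
#' @param matrix a `genotype_matrix`.
#' @param posteriors a `posterior_tensor` with matching dimensions, or NULL
#'   to write GT only.
#' @param path output path.
#' @export
write_vcf_with_gp <- function(matrix, posteriors, path) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  g <- matrix$geno
  if (!is.null(posteriors)) {
    d <- dim(posteriors)
    if (d[1] != nrow(g) || d[2] != ncol(g))
      stop("posterior dimensions do not match the genotype matrix")
  }
  v <- matrix$variants
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GP,Number=3,Type=Float,Description=\"Genotype posterior probabilities\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", matrix$sample_ids), collapse = "\t")), con)
  for (j in seq_len(nrow(v))) {
    gj <- g[, j]
    gt <- ifelse(is.na(gj), "./.", gt_code[as.character(gj)])
    if (is.null(posteriors)) {
      cells <- gt
      fmt <- "GT"
    } else {
      gp <- sprintf("%.3f,%.3f,%.3f", posteriors[, j, 1], posteriors[, j, 2],
                    posteriors[, j, 3])
      cells <- paste0(gt, ":", gp)
      fmt <- "GT:GP"
    }
    writeLines(paste(c(v$chrom[j], v$pos[j], v$vid[j], v$ref[j], v$alt[j],
                       ".", "PASS", ".", fmt, cells), collapse = "\t"), con)
  }
  invisible(path)
}

#' Write a phased panel as VCF
#'
#' @param panel a `haplotype_panel`.
#' @param path output path.
#' @export
write_vcf_phased <- function(panel, path) {
  stopifnot(inherits(panel, "haplotype_panel"))
  v <- panel$variants
  n <- length(panel$sample_ids)
  h1 <- panel$haps[seq(1, 2 * n, by = 2), , drop = FALSE]
  h2 <- panel$haps[seq(2, 2 * n, by = 2), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$sample_ids), collapse = "\t")), con)
  for (j in seq_len(nrow(v))) {
    cells <- paste0(h1[, j], "|", h2[, j])
    writeLines(paste(c(v$chrom[j], v$pos[j], v$vid[j], v$ref[j], v$alt[j],
                       ".", "PASS", ".", "GT", cells), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read an IMPUTE-dialect genetic map file
#'
#' Whitespace-delimited text with a header row and three columns: physical
#' position (bp), recombination rate (cM/Mb) and cumulative genetic distance
#' (cM). Positions must be strictly increasing.
#'
#' @param path path to the map file.
#' @return a [genetic_map()].
#' @export
read_genetic_map <- function(path) {
  tab <- utils::read.table(path, header = TRUE)
  if (ncol(tab) < 3) stop("genetic map must have 3 columns")
  genetic_map(pos = tab[[1]], rate = tab[[2]], cm = tab[[3]])
}

#' Write a genetic map file (IMPUTE dialect)
#' @param map a `genetic_map`.
#' @param path output path.
#' @export
write_genetic_map <- function(map, path) {
  utils::write.table(
    data.frame(position = map$pos, rate_cM_Mb = map$rate, cM = map$cm),
    path, quote = FALSE, row.names = FALSE, sep = " ")
  invisible(path)
}

#' Write a phased panel in hap/legend/sample form
#'
#' IMPUTE-dialect triplet: `<prefix>.hap` (variants x haplotypes, space
#' separated 0/1), `<prefix>.legend` (id, position, a0, a1) and
#' `<prefix>.sample` (one id per line).
#'
#' @param panel a `haplotype_panel`.
#' @param prefix file path prefix.
#' @export
write_hap_legend_sample <- function(panel, prefix) {
  stopifnot(inherits(panel, "haplotype_panel"))
  utils::write.table(t(panel$haps), paste0(prefix, ".hap"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = " ")
  utils::write.table(
    data.frame(id = panel$variants$vid, position = panel$variants$pos,
               a0 = panel$variants$ref, a1 = panel$variants$alt),
    paste0(prefix, ".legend"), quote = FALSE, row.names = FALSE, sep = " ")
  writeLines(panel$sample_ids, paste0(prefix, ".sample"))
  invisible(prefix)
}

#' Read a hap/legend/sample triplet into a haplotype panel
#' @param prefix file path prefix used by [write_hap_legend_sample()].
#' @param chrom chromosome label to assign (the legend does not carry one).
#' @param panel_name label for the returned panel.
#' @export
read_hap_legend_sample <- function(prefix, chrom = "1", panel_name = "panel") {
  leg <- utils::read.table(paste0(prefix, ".legend"), header = TRUE,
                           colClasses = c("character", "integer",
                                          "character", "character"))
  hap <- as.matrix(utils::read.table(paste0(prefix, ".hap"), header = FALSE))
  samples <- readLines(paste0(prefix, ".sample"))
  variants <- variant_table(chrom = chrom, pos = leg$position, vid = leg$id,
                            ref = leg$a0, alt = leg$a1)
  haplotype_panel(variants, t(hap), samples, name = panel_name)
}

#' Write an evaluation report as TSV tables
#'
#' One tab-separated file per report table, with a fixed column order:
#' `coverage_by_maf.tsv`, `well_imputed_by_panel.tsv`,
#' `discordance_overall.tsv`, `discordance_minor_allele.tsv` and
#' `recoverable_content.tsv`. Empty tables produce headers-only files.
#'
#' @param report an `evaluation_report` (see [run_scenario()]) or any list
#'   holding the five data frames under those names.
#' @param directory output directory, created if absent.
#' @return invisibly, the written file paths.
#' @export
write_report <- function(report, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  tables <- c("coverage_by_maf", "well_imputed_by_panel",
              "discordance_overall", "discordance_minor_allele",
              "recoverable_content")
  paths <- character(0)
  for (tb in tables) {
    df <- report[[tb]]
    if (is.null(df)) df <- data.frame()
    p <- file.path(directory, paste0(tb, ".tsv"))
    utils::write.table(df, p, quote = FALSE, row.names = FALSE, sep = "\t")
    paths <- c(paths, p)
  }
  invisible(paths)
}
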