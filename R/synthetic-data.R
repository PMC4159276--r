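#' Simulation configuration
#'
#' Bundles every knob of the synthetic haplotype world: a shared ancestral
#' founder pool from which each population's haplotypes are built as
#' recombining mosaics, with population specificity arising from
#' post-split drift at polymorphic sites and single-origin private
#' mutations at sites monomorphic in the shared founders. Defaults
#' describe the study conditions used throughout the package: a 10 Mb
#' chromosome with 2,000 SNPs (30% exonic, with a rare-shifted exonic
#' frequency spectrum), 80 ancestral founder haplotypes fully shared
#' across two ascertainment populations of 60 samples and one target
#' population of 70.
#'
#' @param seed integer root seed; every stage derives its own substream.
#' @param chrom_length_bp chromosome length in base pairs.
#' @param n_sites number of segregating sites (>= 2).
#' @param n_founders number of founder haplotypes (even).
#' @param founder_sharing fraction of founders accessible to every
#'   population; the remainder are split evenly as population-exclusive.
#' @param pop_sizes named integer vector of diploid sample counts.
#' @param map_rate_cm_per_mb recombination rate of the (uniform) genetic
#'   map, cM/Mb. The default, together with `crossover_rate_per_cM`, is
#'   chosen so that the mosaic's physical switch density equals the
#'   Li-Stephens transition intensity `4 Ne / (100 K)` at the default
#'   panel size — the copying model is then correctly specified for the
#'   haplotypes it imputes.
#' @param crossover_rate_per_cM expected crossovers per cM in mosaic
#'   copying.
#' @param private_mutation_rate per-site, per-accessible-founder-lineage
#'   probability of a population-private mutation event. Private variation
#'   follows the infinite-sites convention: each candidate site
#'   (monomorphic in the shared founders) is pre-assigned to exactly one
#'   population, and an event flips one founder lineage's allele for that
#'   population only, so every carrier shares the founder segment the
#'   mutation arose on.
#' @param drift_rate per-site, per-accessible-founder-lineage probability
#'   that a population's private copy of that lineage carries the opposite
#'   allele at a founder-polymorphic site. This is post-split drift: it
#'   gives each population its own haplotype signature at common sites,
#'   which is what lets a population-specific reference panel out-compete
#'   a cosmopolitan one for matching target haplotypes.
#' @param site_freq_alpha shape of the founder allele-frequency spectrum
#'   at non-exonic sites, density proportional to f^(-alpha) truncated to
#'   [1/(2 n_founders), 0.5]; 0 gives a uniform spectrum, 1 the classic
#'   neutral-like 1/f shape.
#' @param exonic_freq_alpha spectrum shape at exonic sites; the larger
#'   default reflects purifying selection keeping coding variation rare,
#'   which is what makes exome-chip content rare-heavy in the first
#'   place.
#' @param genotyping_error per-genotype probability that an array call is
#'   replaced by one of the two other genotypes, uniformly.
#' @param missing_rate per-genotype probability of a missing array call.
#' @param exonic_fraction fraction of sites flagged exonic, for the
#'   coverage accounting of exonic content.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              chrom_length_bp = 10e6,
                              n_sites = 2000L,
                              n_founders = 80L,
                              founder_sharing = 1.0,
                              pop_sizes = c(popA = 60L, popB = 60L,
                                            popC = 70L),
                              map_rate_cm_per_mb = 0.4,
                              crossover_rate_per_cM = 2.5,
                              private_mutation_rate = 0.03,
                              drift_rate = 0.01,
                              site_freq_alpha = 1,
                              exonic_freq_alpha = 3,
                              genotyping_error = 2e-3,
                              missing_rate = 5e-3,
                              exonic_fraction = 0.3) {
  rates <- c(founder_sharing, private_mutation_rate, drift_rate,
             genotyping_error, missing_rate, exonic_fraction)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  if (n_sites < 2) stop("n_sites must be >= 2")
  if (any(pop_sizes <= 0)) stop("population sizes must be positive")
  if (is.null(names(pop_sizes))) stop("pop_sizes must be named")
  if (n_founders %% 2 != 0) stop("n_founders must be even")
  structure(list(seed = as.integer(seed),
                 chrom_length_bp = chrom_length_bp, n_sites = as.integer(n_sites),
                 n_founders = as.integer(n_founders),
                 founder_sharing = founder_sharing, pop_sizes = pop_sizes,
                 map_rate_cm_per_mb = map_rate_cm_per_mb,
                 crossover_rate_per_cM = crossover_rate_per_cM,
                 private_mutation_rate = private_mutation_rate,
                 drift_rate = drift_rate,
                 site_freq_alpha = site_freq_alpha,
                 exonic_freq_alpha = exonic_freq_alpha,
                 genotyping_error = genotyping_error,
                 missing_rate = missing_rate,
                 exonic_fraction = exonic_fraction),
            class = "simulation_config")
}

# Internal: derived per-stage seed, kept inside 32-bit integer range.
stage_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(k) * 104729) %% 2147483629 + 1)
}

# Internal: inverse-CDF draw from a spectrum with density proportional to
# f^(-alpha) truncated to [a, b].
draw_freq_spectrum <- function(n, alpha, a, b) {
  u <- stats::runif(n)
  if (abs(alpha - 1) < 1e-12) {
    a * (b / a)^u
  } else {
    t <- 1 - alpha
    (a^t + u * (b^t - a^t))^(1 / t)
  }
}

#' Simulate founder haplotypes
#'
#' Draws site positions uniformly on the chromosome (sorted, unique),
#' flags an `exonic_fraction` share of sites as exonic, and draws a
#' per-site derived-allele probability from the configured frequency
#' spectrum (`site_freq_alpha` at non-exonic sites, the rare-shifted
#' `exonic_freq_alpha` at exonic sites), then fills founder alleles as
#' independent Bernoulli draws. Seeded deterministically from
#' `config$seed`.
#'
#' @param config a [simulation_config()].
#' @return a `haplotype_panel` of `n_founders` haplotypes named "founders";
#'   the attribute `"site_freq"` carries the drawn spectrum.
#' @export
simulate_founders <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(stage_seed(config$seed, 1L))
  m <- config$n_sites
  pos <- sort(sample.int(config$chrom_length_bp, m))
  a <- 1 / (2 * config$n_founders)
  exonic <- stats::runif(m) < config$exonic_fraction
  freq <- draw_freq_spectrum(m, config$site_freq_alpha, a, 0.5)
  freq[exonic] <- draw_freq_spectrum(sum(exonic), config$exonic_freq_alpha,
                                     a, 0.5)
  f <- config$n_founders
  haps <- matrix(stats::rbinom(f * m, 1L, rep(freq, each = f)), nrow = f)
  variants <- variant_table(chrom = "1", pos = pos,
                            vid = sprintf("snp%05d", seq_len(m)),
                            ref = "A", alt = "G", exonic = exonic)
  panel <- haplotype_panel(variants, haps,
                           sprintf("F%02d", seq_len(f %/% 2)),
                           name = "founders")
  attr(panel, "site_freq") <- freq
  panel
}

# Internal: indices of founder haplotypes accessible to a population:
# the shared block first, then that population's exclusive block.
accessible_founders <- function(config, pop_label) {
  f <- config$n_founders
  pops <- names(config$pop_sizes)
  if (!pop_label %in% pops) stop("unknown population: ", pop_label)
  n_shared <- floor(config$founder_sharing * f)
  rest <- f - n_shared
  bounds <- n_shared + round(seq(0, rest, length.out = length(pops) + 1))
  i <- match(pop_label, pops)
  excl <- if (bounds[i + 1] > bounds[i]) seq(bounds[i] + 1, bounds[i + 1]) else integer(0)
  list(shared = seq_len(n_shared), exclusive = excl)
}

#' Simulate a population as founder mosaics
#'
#' Each haplotype copies a mosaic of the population's accessible founders
#' (the shared block plus its own exclusive block), with crossover
#' breakpoints laid down as a Poisson process on the genetic map at
#' `crossover_rate_per_cM`, and the copied founder redrawn uniformly at
#' each breakpoint. Two population-specific perturbations are applied to
#' this population's private copy of the founder pool before the mosaics
#' are drawn. Private mutations follow a single-origin
#' (infinite-sites) convention: only sites monomorphic in the shared
#' founders are candidates (so "population specific" is unambiguous in the
#' truth), each candidate site is deterministically pre-assigned to one
#' population, and for each accessible founder lineage a mutation event
#' occurs with probability `private_mutation_rate`, flipping that
#' lineage's allele for this population. Carriers therefore share the
#' founder segment the mutation arose on, which is what makes such
#' variants imputable from a reference panel that contains carriers.
#' Post-split drift then flips each accessible lineage's allele with
#' probability `drift_rate` at sites already polymorphic among the
#' founders, giving the population its own haplotype signature at common
#' sites.
#'
#' @param founders the founder panel from [simulate_founders()].
#' @param pop_label population name (must appear in `config$pop_sizes`).
#' @param config a [simulation_config()].
#' @param map genetic map; defaults to a uniform 1 cM/Mb map over the
#'   configured chromosome.
#' @return a `haplotype_panel` of `2 * pop_sizes[pop_label]` haplotypes.
#' @export
simulate_population <- function(founders, pop_label, config, map = NULL) {
  stopifnot(inherits(founders, "haplotype_panel"))
  if (is.null(map))
    map <- uniform_genetic_map(config$chrom_length_bp,
                               config$map_rate_cm_per_mb)
  acc <- accessible_founders(config, pop_label)
  acc_idx <- c(acc$shared, acc$exclusive)
  if (length(acc_idx) == 0) stop("population ", pop_label,
                                 " has no accessible founders")
  m <- ncol(founders$haps)
  pop_names <- names(config$pop_sizes)

  # single-origin assignment of candidate sites, shared by all populations
  set.seed(stage_seed(config$seed, 9L))
  assigned <- sample(pop_names, m, replace = TRUE)

  set.seed(stage_seed(config$seed, 10L + match(pop_label, pop_names)))
  pool <- founders$haps
  if (config$private_mutation_rate > 0 && length(acc$shared) > 0) {
    shared <- founders$haps[acc$shared, , drop = FALSE]
    candidate <- which(colSums(shared) %in% c(0L, nrow(shared)) &
                         assigned == pop_label)
    if (length(candidate) > 0) {
      consensus <- shared[1, candidate]
      events <- matrix(stats::runif(length(acc_idx) * length(candidate)) <
                         config$private_mutation_rate,
                       nrow = length(acc_idx))
      derived <- matrix(rep(1L - consensus, each = length(acc_idx)),
                        nrow = length(acc_idx))
      block <- pool[acc_idx, candidate, drop = FALSE]
      block[events] <- derived[events]
      pool[acc_idx, candidate] <- block
    }
  }
  if (config$drift_rate > 0) {
    fc <- colSums(founders$haps)
    poly <- which(fc > 0L & fc < nrow(founders$haps))
    if (length(poly) > 0) {
      flips <- matrix(stats::runif(length(acc_idx) * length(poly)) <
                        config$drift_rate, nrow = length(acc_idx))
      block <- pool[acc_idx, poly, drop = FALSE]
      block[flips] <- 1L - block[flips]
      pool[acc_idx, poly] <- block
    }
  }

  n_h <- 2L * config$pop_sizes[[pop_label]]
  site_cm <- map_cm(map, founders$variants$pos)
  cm_lo <- min(site_cm); cm_hi <- max(site_cm)
  total_cm <- cm_hi - cm_lo
  haps <- matrix(0L, nrow = n_h, ncol = m)
  for (h in seq_len(n_h)) {
    n_x <- stats::rpois(1, config$crossover_rate_per_cM * total_cm)
    breaks <- sort(stats::runif(n_x, cm_lo, cm_hi))
    seg <- findInterval(site_cm, breaks) + 1L
    donors <- acc_idx[sample.int(length(acc_idx), n_x + 1L, replace = TRUE)]
    haps[h, ] <- pool[cbind(donors[seg], seq_len(m))]
  }
  haplotype_panel(founders$variants, haps,
                  sprintf("%s_S%03d", pop_label, seq_len(n_h %/% 2)),
                  name = pop_label)
}

#' Pool several haplotype panels over the same variant set
#'
#' @param panels list of `haplotype_panel`s with identical variant tables.
#' @param name label for the pooled panel.
#' @export
pool_panels <- function(panels, name = "pooled") {
  vids <- panels[[1]]$variants$vid
  for (p in panels)
    if (!identical(p$variants$vid, vids))
      stop("panels must share an identical variant set to be pooled")
  haplotype_panel(panels[[1]]$variants,
                  do.call(rbind, lapply(panels, `[[`, "haps")),
                  unlist(lapply(panels, `[[`, "sample_ids")), name = name)
}

#' Design a dense GWAS array by even spacing
#'
#' Selects `n_select` sites with MAF at least `min_maf`, chosen to be as
#' evenly spaced in base pairs as possible: an even grid of target
#' positions is laid over the eligible span and each grid point greedily
#' claims the nearest unused eligible site (ties broken by higher MAF, then
#' lower position). Deterministic.
#'
#' @param panel haplotype panel whose frequencies drive eligibility.
#' @param n_select number of array sites.
#' @param min_maf eligibility floor on the panel MAF.
#' @param name design label.
#' @return an `array_design` with `design_rule = "dense"`.
#' @export
design_dense_array <- function(panel, n_select, min_maf = 0.01,
                               name = "dense") {
  maf <- panel_maf(panel)
  elig <- which(maf >= min_maf)
  if (n_select > length(elig))
    stop(sprintf("too few eligible sites: need %d, have %d (shortfall %d)",
                 n_select, length(elig), n_select - length(elig)))
  pos <- panel$variants$pos[elig]
  emaf <- maf[elig]
  grid <- min(pos) + (seq_len(n_select) - 0.5) / n_select *
    (max(pos) - min(pos))
  used <- rep(FALSE, length(elig))
  pick <- integer(n_select)
  for (j in seq_len(n_select)) {
    d <- abs(pos - grid[j])
    d[used] <- Inf
    # order: distance, then -MAF, then position
    best <- order(d, -emaf, pos)[1]
    used[best] <- TRUE
    pick[j] <- elig[best]
  }
  array_design(name, panel$variants$vid[sort(pick)], "dense")
}

#' Design an exome-style chip with ascertainment bias
#'
#' Chip content is chosen only from exonic sites (it is an exome chip)
#' polymorphic in the pooled design panels, with a `common_fraction`
#' share of genuinely common markers (the GWAS-tag backbone real exome
#' chips carried), a `rare_fraction` share drawn from the rare bin
#' (design-panel MAF <= 0.01) and the remainder drawn from the
#' low-frequency bin first and the common bin only after that, matching
#' the strong low-frequency skew of real exome-chip content. The target
#' panel plays no role in selection: the resulting depletion of
#' target-population polymorphism is the ascertainment bias the design
#' emulates. If the rare bin runs short, the shortfall is filled from the
#' other bins. Within each bin the lowest-frequency sites are taken first
#' (ties by position), mirroring the prioritisation of the rarest
#' consistently-observed coding variants in real chip designs; the whole
#' selection is deterministic.
#'
#' @param design_panels list of `haplotype_panel`s from the ascertainment
#'   populations (must exclude the target population).
#' @param target_panel the target population's panel; ignored for
#'   selection, retained in the interface as documentation of intent.
#' @param n_select number of chip sites.
#' @param rare_fraction share of chip content drawn from the rare bin.
#' @param common_fraction share reserved for common markers (highest MAF
#'   first), emulating the chip's GWAS-tag backbone.
#' @param exonic_only restrict content to exonic sites (default); set
#'   FALSE for panels without exonic annotation.
#' @param name design label.
#' @return an `array_design` with `design_rule = "exome_style"`.
#' @export
design_exome_chip <- function(design_panels, target_panel, n_select,
                              rare_fraction = 0.8, common_fraction = 0,
                              exonic_only = TRUE, name = "exome_chip") {
  pooled <- pool_panels(design_panels, name = "design_pool")
  maf <- panel_maf(pooled)
  eligible <- if (exonic_only && any(pooled$variants$exonic))
    pooled$variants$exonic else rep(TRUE, length(maf))
  poly <- which(maf > 0 & eligible)
  if (length(poly) < n_select)
    stop(sprintf(
      "insufficient polymorphic design-panel sites: need %d, have %d",
      n_select, length(poly)))
  rare <- poly[maf[poly] <= 0.01]
  low <- poly[maf[poly] > 0.01 & maf[poly] < 0.05]
  common <- poly[maf[poly] >= 0.05]
  take <- function(idx, k, decreasing = FALSE) {
    if (k >= length(idx)) return(idx)
    o <- order(if (decreasing) -maf[idx] else maf[idx],
               pooled$variants$pos[idx])
    idx[o][seq_len(k)]
  }
  n_common <- min(round(common_fraction * n_select), length(common))
  n_rare <- min(round(rare_fraction * n_select), length(rare))
  n_low <- min(n_select - n_rare - n_common, length(low))
  n_common <- min(n_select - n_rare - n_low, length(common))
  if (n_rare + n_low + n_common < n_select)
    n_rare <- n_select - n_low - n_common
  pick <- sort(c(take(rare, n_rare), take(low, n_low),
                 take(common, n_common, decreasing = TRUE)))
  array_design(name, pooled$variants$vid[pick], "exome_style")
}

#' Genotype samples on an array, with error and missingness
#'
#' Observed genotypes are the haplotype-pair sums at the design sites; with
#' probability `genotyping_error` a call is replaced by one of the two
#' other genotypes uniformly, and with probability `missing_rate` it is set
#' missing. The returned truth set holds the error-free genotypes at ALL
#' panel sites. Uses the current RNG stream.
#'
#' @param panel the population's `haplotype_panel` (simulation truth).
#' @param design the `array_design` to genotype on (sites must be a subset
#'   of the panel's).
#' @param config a [simulation_config()] supplying the error rates.
#' @param private_flags optional per-variant character vector naming the
#'   population(s) carrying the derived allele exclusively (see
#'   [private_site_flags()]); stored in the truth set.
#' @return a list with elements `observed` (`genotype_matrix` at design
#'   sites) and `truth` (class `truth_set`: `true_genotypes` at all sites,
#'   `population_labels`, `private_site_flags`).
#' @export
genotype_samples <- function(panel, design, config, private_flags = NULL) {
  stopifnot(inherits(panel, "haplotype_panel"),
            inherits(design, "array_design"))
  idx <- match(design$vids, panel$variants$vid)
  if (anyNA(idx)) stop("design contains sites absent from the panel")
  idx <- sort(idx)
  n <- length(panel$sample_ids)
  h1 <- panel$haps[seq(1, 2 * n, by = 2), , drop = FALSE]
  h2 <- panel$haps[seq(2, 2 * n, by = 2), , drop = FALSE]
  truth_all <- h1 + h2
  obs <- truth_all[, idx, drop = FALSE]
  k <- length(obs)
  err <- stats::runif(k) < config$genotyping_error
  if (any(err)) {
    shift <- sample(c(1L, 2L), sum(err), replace = TRUE)
    obs[err] <- (obs[err] + shift) %% 3L
  }
  obs[stats::runif(k) < config$missing_rate] <- NA_integer_
  truth <- structure(
    list(true_genotypes = genotype_matrix(panel$variants, truth_all,
                                          panel$sample_ids),
         population_labels = stats::setNames(rep(panel$name, n),
                                             panel$sample_ids),
         private_site_flags = private_flags),
    class = "truth_set")
  list(observed = genotype_matrix(panel$variants[idx, , drop = FALSE],
                                  obs, panel$sample_ids),
       truth = truth)
}

#' Which populations carry each derived allele exclusively
#'
#' @param panels named list of population `haplotype_panel`s over the same
#'   variants.
#' @return character vector per variant: the population name if exactly one
#'   population carries the derived allele, `"shared"` if several do,
#'   `"none"` if the site is monomorphic ancestral everywhere.
#' @export
private_site_flags <- function(panels) {
  counts <- sapply(panels, function(p) colSums(p$haps))
  carriers <- counts > 0
  n_car <- rowSums(carriers)
  out <- rep("none", nrow(carriers))
  one <- n_car == 1
  out[one] <- colnames(carriers)[apply(carriers[one, , drop = FALSE], 1,
                                       which)]
  out[n_car > 1] <- "shared"
  out
}
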