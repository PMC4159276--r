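#' Scenario configuration for the end-to-end evaluation
#'
#' Bundles the simulation world, QC thresholds, array design sizes, HMM
#' settings and evaluation thresholds for [run_scenario()]. The default
#' scenario has three populations; two (`cosmo_pops`) play the role of the
#' well-sequenced cosmopolitan ancestries that drive both the reference
#' panel and the chip ascertainment, while the third (`target_pop`)
#' provides a small population-specific reference panel
#' (`n_specific_donors` samples) and the imputation targets (the remaining
#' samples, never overlapping the donors).
#'
#' @param simulation a [simulation_config()].
#' @param qc a [qc_thresholds()].
#' @param n_e,hmm_error_rate Li-Stephens parameters (see [hmm_params()]).
#' @param n_dense,dense_min_maf dense GWAS array size and MAF floor.
#' @param n_legacy,legacy_min_maf legacy array manifest size and MAF
#'   floor (the manifest is designed on the first cosmopolitan population
#'   alone, then rebuilt on the dense array by surrogate search).
#' @param n_chip,chip_rare_fraction exome-style chip size and rare share.
#' @param n_cosmo_panel_per_pop how many samples per ascertainment
#'   population enter the cosmopolitan reference panel. Array and chip
#'   content is designed on the full cohorts, so rare chip content is
#'   only partially represented in the panel -- the same sampling gap
#'   that separates a chip-design cohort from a public reference panel,
#'   and the reason rare content often cannot be imputed at all.
#' @param n_specific_donors target-population samples donated to the
#'   population-specific reference panel (>= 18, so the panel holds at
#'   least 36 haplotypes).
#' @param target_pop,cosmo_pops population roles, by name.
#' @param posterior_threshold genotype-calling threshold, default 0.90.
#' @param core_bp,buffer_bp imputation chunking, default 5 Mb each.
#' @param window_bp,r2_floor surrogate search window and floor.
#' @param verbose log stage boundaries with record counts.
#' @export
scenario_config <- function(simulation = simulation_config(),
                            qc = qc_thresholds(),
                            n_e = 15000, hmm_error_rate = 0.01,
                            n_dense = 600L, dense_min_maf = 0.01,
                            n_legacy = 450L, legacy_min_maf = 0.05,
                            n_chip = 200L, chip_rare_fraction = 0.8,
                            n_cosmo_panel_per_pop = 45L,
                            n_specific_donors = 20L,
                            target_pop = "popC",
                            cosmo_pops = c("popA", "popB"),
                            posterior_threshold = 0.9,
                            core_bp = 5e6, buffer_bp = 5e6,
                            window_bp = 1e6, r2_floor = 0.80,
                            verbose = FALSE) {
  pops <- names(simulation$pop_sizes)
  if (!target_pop %in% pops) stop("target_pop not in pop_sizes")
  if (!all(cosmo_pops %in% pops)) stop("cosmo_pops not in pop_sizes")
  if (n_specific_donors < 1) stop("n_specific_donors must be positive")
  if (n_specific_donors >= simulation$pop_sizes[[target_pop]])
    stop("donors would leave no target samples")
  structure(list(simulation = simulation, qc = qc, n_e = n_e,
                 hmm_error_rate = hmm_error_rate, n_dense = n_dense,
                 dense_min_maf = dense_min_maf, n_legacy = n_legacy,
                 legacy_min_maf = legacy_min_maf, n_chip = n_chip,
                 chip_rare_fraction = chip_rare_fraction,
                 n_cosmo_panel_per_pop = as.integer(n_cosmo_panel_per_pop),
                 n_specific_donors = as.integer(n_specific_donors),
                 target_pop = target_pop, cosmo_pops = cosmo_pops,
                 posterior_threshold = posterior_threshold,
                 core_bp = core_bp, buffer_bp = buffer_bp,
                 window_bp = window_bp, r2_floor = r2_floor,
                 verbose = verbose),
            class = "scenario_config")
}

# Internal: subset a haplotype panel by sample index.
panel_samples <- function(panel, sample_idx, name = panel$name) {
  rows <- as.vector(rbind(2 * sample_idx - 1, 2 * sample_idx))
  haplotype_panel(panel$variants, panel$haps[rows, , drop = FALSE],
                  panel$sample_ids[sample_idx], name = name)
}

# Internal: restrict a panel to its polymorphic sites (a reference panel
# only carries variants discovered in its own samples).
panel_polymorphic <- function(panel) {
  f <- panel_freq(panel)
  panel_subset(panel, which(f > 0 & f < 1))
}

#' Run the full evaluation scenario
#'
#' Seeded end-to-end orchestration: simulate the founder world and the
#' three populations; build the reference panels (cosmopolitan from the
#' ascertainment populations, population-specific from the target-pop
#' donors); design the dense array, the legacy manifest with its surrogate
#' rebuild, and the ascertainment-biased chip; genotype the target samples
#' (never the donors) on the dense array and the chip; run QC; impute each
#' study array against each panel configuration; and evaluate coverage,
#' well-imputed rates and concordances by MAF bin.
#'
#' @param config a [scenario_config()].
#' @return an object of class `evaluation_report`: the five report tables
#'   (`coverage_by_maf`, `well_imputed_by_panel`, `discordance_overall`,
#'   `discordance_minor_allele`, `recoverable_content`) plus the QC
#'   report, the surrogate decisions, per-run SNP quality tables and run
#'   metadata.
#' @export
run_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  sim <- config$simulation
  say <- function(...) if (config$verbose) message(sprintf(...))

  # --- simulate -------------------------------------------------------
  founders <- simulate_founders(sim)
  map <- uniform_genetic_map(sim$chrom_length_bp, sim$map_rate_cm_per_mb)
  pops <- lapply(names(sim$pop_sizes), function(p)
    simulate_population(founders, p, sim, map))
  names(pops) <- names(sim$pop_sizes)
  flags <- private_site_flags(pops)
  say("simulated %d sites, %s samples", sim$n_sites,
      paste(sim$pop_sizes, collapse = "/"))

  # --- panels and the over-fitting guard ------------------------------
  target_panel_full <- pops[[config$target_pop]]
  donor_idx <- seq_len(config$n_specific_donors)
  donor_ids <- target_panel_full$sample_ids[donor_idx]
  target_idx <- setdiff(seq_along(target_panel_full$sample_ids), donor_idx)
  target_ids <- target_panel_full$sample_ids[target_idx]
  design_pool <- pool_panels(pops[config$cosmo_pops], name = "design_pool")
  cosmo_pool <- pool_panels(
    lapply(pops[config$cosmo_pops], function(p)
      panel_samples(p, seq_len(min(config$n_cosmo_panel_per_pop,
                                   length(p$sample_ids))))),
    name = "cosmopolitan")
  panel_donor_ids <- c(cosmo_pool$sample_ids, donor_ids)
  if (length(intersect(target_ids, panel_donor_ids)) > 0)
    stop("over-fitting: target samples appear among the reference-panel ",
         "donors")
  cosmo <- panel_polymorphic(cosmo_pool)
  specific <- panel_polymorphic(
    panel_samples(target_panel_full, donor_idx, name = "specific"))
  targets_all_sites <- panel_samples(target_panel_full, target_idx,
                                     name = "targets")
  say("panels: cosmopolitan %d haps x %d sites; specific %d haps x %d sites",
      nrow(cosmo$haps), ncol(cosmo$haps), nrow(specific$haps),
      ncol(specific$haps))

  # --- array designs --------------------------------------------------
  set.seed(stage_seed(sim$seed, 20L))
  dense <- design_dense_array(design_pool, config$n_dense,
                              config$dense_min_maf, name = "dense")
  manifest <- design_dense_array(pops[[config$cosmo_pops[1]]],
                                 config$n_legacy, config$legacy_min_maf,
                                 name = "legacy_manifest")
  rebuild <- rebuild_array(manifest$vids, dense,
                           pops[[config$cosmo_pops[1]]],
                           pops[[config$cosmo_pops[2]]],
                           window_bp = config$window_bp,
                           r2_floor = config$r2_floor, name = "legacy")
  set.seed(stage_seed(sim$seed, 21L))
  chip <- design_exome_chip(pops[config$cosmo_pops], target_panel_full,
                            config$n_chip, config$chip_rare_fraction)
  say("arrays: dense %d; legacy manifest %d -> rebuilt %d (recovered %d); chip %d",
      length(dense$vids), length(manifest$vids),
      length(rebuild$design$vids), rebuild$n_recovered, length(chip$vids))

  # --- genotype targets and QC ----------------------------------------
  set.seed(stage_seed(sim$seed, 22L))
  gs_dense <- genotype_samples(targets_all_sites, dense, sim, flags)
  set.seed(stage_seed(sim$seed, 23L))
  gs_chip <- genotype_samples(targets_all_sites, chip, sim, flags)
  truth <- gs_dense$truth
  qc_res <- run_qc(list(dense = gs_dense$observed,
                        chip = gs_chip$observed),
                   config$qc,
                   labels = rep(config$target_pop, length(target_ids)))
  dense_obs <- qc_res$matrices$dense
  chip_obs <- qc_res$matrices$chip
  say("QC: %d SNP removal(s), %d sample removal(s); %d samples remain",
      nrow(qc_res$report$removed_snps),
      nrow(qc_res$report$removed_samples), length(dense_obs$sample_ids))

  # --- panel configurations -------------------------------------------
  params <- hmm_params(n_e = config$n_e, error_rate = config$hmm_error_rate,
                       map = map)
  refs <- list(cosmopolitan = cosmo,
               cosmopolitan_specific = merge_panels(cosmo, specific,
                                                    params))
  arrays <- list(dense = dense, legacy = rebuild$design)
  plan <- make_chunk_plan(sim$chrom_length_bp, config$core_bp,
                          config$buffer_bp)
  surviving <- dense_obs$sample_ids
  targets_kept <- panel_samples(
    targets_all_sites, match(surviving, targets_all_sites$sample_ids),
    name = "targets")

  # --- impute and evaluate --------------------------------------------
  chip_maf <- vapply(seq_along(chip_obs$variants$vid), function(j)
    maf_of(chip_obs$geno[, j]), 1.0)
  chip_bins <- stats::setNames(maf_bin(chip_maf), chip_obs$variants$vid)
  well_tab <- disc_tab <- mac_tab <- NULL
  quality <- list()
  for (an in names(arrays)) {
    for (rn in names(refs)) {
      ref <- refs[[rn]]
      typed <- intersect(intersect(arrays[[an]]$vids,
                                   dense_obs$variants$vid),
                         ref$variants$vid)
      tsel <- match(typed, targets_kept$variants$vid)
      tpanel <- panel_subset(targets_kept, sort(tsel))
      post <- impute_genotypes(tpanel, ref, params, plan)
      q <- snp_quality(post, config$posterior_threshold)
      calls <- threshold_calls(post, config$posterior_threshold)
      quality[[paste(an, rn, sep = ".")]] <- q
      say("imputed %s x %s: %d typed -> %d sites", an, rn,
          length(typed), nrow(q))

      # well-imputed accounting: denominator = all polymorphic chip sites
      # off the study array that survived chip QC, whether or not the
      # reference panel carries them -- a panel-absent site cannot be
      # recovered and counts against the percentage
      denom_vids <- setdiff(intersect(chip$vids, chip_obs$variants$vid),
                            typed)
      bins_d <- chip_bins[denom_vids]
      covered <- denom_vids %in% ref$variants$vid
      wi_flag <- rep(FALSE, length(denom_vids))
      wi_flag[covered] <- q$well_imputed[match(denom_vids[covered], q$vid)]
      for (b in c("rare", "low_frequency", "common")) {
        i <- which(bins_d == b)
        well_tab <- rbind(well_tab, data.frame(
          array = an, panel_config = rn, bin = b, n_sites = length(i),
          n_covered = sum(covered[i]), n_well = sum(wi_flag[i]),
          pct_well = if (length(i)) 100 * mean(wi_flag[i]) else NA_real_,
          stringsAsFactors = FALSE))
      }
      # concordance evaluation: covered, well-imputed sites only
      eval_vids <- denom_vids[covered]
      bins_e <- chip_bins[eval_vids]
      wi_vids <- eval_vids[wi_flag[covered]]
      oc <- overall_concordance(calls, chip_obs, bins_e, at = wi_vids)
      oc <- data.frame(array = an, panel_config = rn, oc,
                       stringsAsFactors = FALSE)
      disc_tab <- rbind(disc_tab, oc)
      mac <- minor_allele_concordance(calls, chip_obs,
                                      bins_e[names(bins_e) %in% wi_vids])
      mac <- data.frame(array = an, panel_config = rn, mac,
                        stringsAsFactors = FALSE)
      mac_tab <- rbind(mac_tab, mac)
    }
  }

  # coverage is assessed on the pre-QC chip observations so that every
  # chip site is accounted for
  coverage <- coverage_accounting(chip, list(cosmo, specific),
                                  gs_chip$observed)
  coverage <- data.frame(population = config$target_pop, coverage,
                         stringsAsFactors = FALSE)
  recov <- recoverable_content(
    truth, NULL, dense, chip,
    quality = list(cosmopolitan = quality$dense.cosmopolitan,
                   cosmopolitan_specific =
                     quality$dense.cosmopolitan_specific))

  structure(list(coverage_by_maf = coverage,
                 well_imputed_by_panel = well_tab,
                 discordance_overall = disc_tab,
                 discordance_minor_allele = mac_tab,
                 recoverable_content = recov,
                 qc_report = qc_res$report,
                 surrogate_decisions = rebuild$decisions,
                 n_recovered = rebuild$n_recovered,
                 quality = quality,
                 designs = list(dense = dense, legacy = rebuild$design,
                                chip = chip,
                                legacy_manifest = manifest),
                 meta = list(seed = sim$seed,
                             target_ids = surviving,
                             donor_ids = donor_ids,
                             panel_donor_ids = panel_donor_ids,
                             n_chip = length(chip$vids),
                             chip_mono_truth = {
                               tg <- truth$true_genotypes$geno[
                                 , chip$vids, drop = FALSE]
                               mean(colSums(tg) %in%
                                      c(0L, 2L * nrow(tg)))
                             })),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("evaluation report\n")
  cov <- x$coverage_by_maf
  mono <- sum(cov$n[cov$bin == "monomorphic"])
  cat(sprintf("  chip: %d sites, %.1f%% monomorphic in target\n",
              x$meta$n_chip, 100 * mono / x$meta$n_chip))
  cat(sprintf("  legacy rebuild: %d/%d manifest entries recovered\n",
              x$n_recovered, nrow(x$surrogate_decisions)))
  cat("  well-imputed % by array x panel x MAF bin:\n")
  print(x$well_imputed_by_panel, row.names = FALSE)
  invisible(x)
}

#' Compare two panel configurations within a report
#'
#' Per MAF bin, the differences in well-imputed percentage, overall
#' discordance and minor-allele discordance between two panel
#' configurations, signed so that positive means configuration 2 improves
#' on configuration 1.
#'
#' @param report an `evaluation_report`.
#' @param config1,config2 panel-configuration names in the report.
#' @param array study-array name, default `"dense"`.
#' @return data.frame with `metric`, `bin`, values under both configs and
#'   `delta`.
#' @export
compare_panel_configs <- function(report,
                                  config1 = "cosmopolitan",
                                  config2 = "cosmopolitan_specific",
                                  array = "dense") {
  pick <- function(tab, cfg) tab[tab$panel_config == cfg &
                                   tab$array == array, , drop = FALSE]
  rows <- NULL
  w1 <- pick(report$well_imputed_by_panel, config1)
  w2 <- pick(report$well_imputed_by_panel, config2)
  if (nrow(w1) == 0 || nrow(w2) == 0)
    stop("panel configuration absent from the report")
  if (!identical(w1$bin, w2$bin)) stop("mismatched MAF-bin grids")
  rows <- rbind(rows, data.frame(
    metric = "well_imputed_pct", bin = w1$bin, config1 = w1$pct_well,
    config2 = w2$pct_well, delta = w2$pct_well - w1$pct_well,
    stringsAsFactors = FALSE))
  d1 <- pick(report$discordance_overall, config1)
  d2 <- pick(report$discordance_overall, config2)
  if (!identical(d1$bin, d2$bin)) stop("mismatched MAF-bin grids")
  rows <- rbind(rows, data.frame(
    metric = "overall_discordance", bin = d1$bin,
    config1 = d1$discordance, config2 = d2$discordance,
    delta = d1$discordance - d2$discordance, stringsAsFactors = FALSE))
  m1 <- pick(report$discordance_minor_allele, config1)
  m2 <- pick(report$discordance_minor_allele, config2)
  if (!identical(m1$bin, m2$bin)) stop("mismatched MAF-bin grids")
  rows <- rbind(rows, data.frame(
    metric = "minor_allele_discordance", bin = m1$bin,
    config1 = m1$discordance, config2 = m2$discordance,
    delta = m1$discordance - m2$discordance, stringsAsFactors = FALSE))
  rows
}

#' Write a miniature fixture bundle to disk
#'
#' Generates a complete small dataset through the simulator and writes it
#' in the package's interchange formats: phased panel VCFs, a
#' hap/legend/sample triplet, observed genotype VCFs for the dense array
#' and chip, the genetic map, array manifests and the scenario
#' configuration, all derived from one seed.
#'
#' @param size `"tiny"` (12 samples x 200 sites) or `"small"`
#'   (45 samples x 600 sites).
#' @param seed integer seed.
#' @param dir output directory.
#' @return invisibly, the scenario config used.
#' @export
make_fixtures <- function(size = c("tiny", "small"), seed = 1L, dir) {
  size <- match.arg(size)
  cfg <- fixture_scenario(size, seed)
  sim <- cfg$simulation
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  founders <- simulate_founders(sim)
  map <- uniform_genetic_map(sim$chrom_length_bp, sim$map_rate_cm_per_mb)
  pops <- lapply(names(sim$pop_sizes), function(p)
    simulate_population(founders, p, sim, map))
  names(pops) <- names(sim$pop_sizes)
  cosmo <- panel_polymorphic(pool_panels(pops[cfg$cosmo_pops],
                                         name = "cosmopolitan"))
  set.seed(stage_seed(sim$seed, 20L))
  dense <- design_dense_array(pool_panels(pops[cfg$cosmo_pops]),
                              cfg$n_dense, cfg$dense_min_maf)
  set.seed(stage_seed(sim$seed, 21L))
  chip <- design_exome_chip(pops[cfg$cosmo_pops], pops[[cfg$target_pop]],
                            cfg$n_chip, cfg$chip_rare_fraction)
  set.seed(stage_seed(sim$seed, 22L))
  gs <- genotype_samples(pops[[cfg$target_pop]], dense, sim)
  set.seed(stage_seed(sim$seed, 23L))
  gs_chip <- genotype_samples(pops[[cfg$target_pop]], chip, sim)
  write_vcf_phased(cosmo, file.path(dir, "cosmopolitan.vcf"))
  write_hap_legend_sample(cosmo, file.path(dir, "cosmopolitan"))
  write_vcf_phased(pops[[cfg$target_pop]], file.path(dir, "target.vcf"))
  write_vcf_with_gp(gs$observed, NULL, file.path(dir, "dense_obs.vcf"))
  write_vcf_with_gp(gs_chip$observed, NULL, file.path(dir, "chip_obs.vcf"))
  write_genetic_map(map, file.path(dir, "genetic.map"))
  writeLines(dense$vids, file.path(dir, "dense.manifest"))
  writeLines(chip$vids, file.path(dir, "chip.manifest"))
  write_scenario_config(cfg, file.path(dir, "scenario.cfg"))
  invisible(cfg)
}

# Internal: down-scaled scenario configs for fixtures and quick runs.
fixture_scenario <- function(size, seed) {
  if (size == "tiny") {
    scenario_config(
      simulation = simulation_config(
        seed = seed, chrom_length_bp = 2e6, n_sites = 200L,
        n_founders = 16L, pop_sizes = c(popA = 4L, popB = 4L, popC = 4L)),
      n_dense = 50L, n_legacy = 25L, n_chip = 12L,
      n_specific_donors = 2L, core_bp = 5e6, buffer_bp = 5e6)
  } else {
    scenario_config(
      simulation = simulation_config(
        seed = seed, chrom_length_bp = 4e6, n_sites = 600L,
        n_founders = 24L,
        pop_sizes = c(popA = 15L, popB = 15L, popC = 15L)),
      n_dense = 150L, n_legacy = 80L, n_chip = 40L,
      n_specific_donors = 5L)
  }
}

#' Write a scenario configuration as flat key/value text
#' @param config a [scenario_config()].
#' @param path output path.
#' @export
write_scenario_config <- function(config, path) {
  sim <- config$simulation
  kv <- c(
    seed = sim$seed, chrom_length_bp = sim$chrom_length_bp,
    n_sites = sim$n_sites, n_founders = sim$n_founders,
    founder_sharing = sim$founder_sharing,
    pop_sizes = paste(sprintf("%s:%d", names(sim$pop_sizes),
                              sim$pop_sizes), collapse = ","),
    map_rate_cm_per_mb = sim$map_rate_cm_per_mb,
    crossover_rate_per_cM = sim$crossover_rate_per_cM,
    private_mutation_rate = sim$private_mutation_rate,
    drift_rate = sim$drift_rate,
    site_freq_alpha = sim$site_freq_alpha,
    exonic_freq_alpha = sim$exonic_freq_alpha,
    genotyping_error = sim$genotyping_error,
    missing_rate = sim$missing_rate,
    exonic_fraction = sim$exonic_fraction,
    n_e = config$n_e, hmm_error_rate = config$hmm_error_rate,
    n_dense = config$n_dense, dense_min_maf = config$dense_min_maf,
    n_legacy = config$n_legacy, legacy_min_maf = config$legacy_min_maf,
    n_chip = config$n_chip,
    chip_rare_fraction = config$chip_rare_fraction,
    n_cosmo_panel_per_pop = config$n_cosmo_panel_per_pop,
    n_specific_donors = config$n_specific_donors,
    target_pop = config$target_pop,
    cosmo_pops = paste(config$cosmo_pops, collapse = ","),
    posterior_threshold = config$posterior_threshold,
    core_bp = config$core_bp, buffer_bp = config$buffer_bp,
    window_bp = config$window_bp, r2_floor = config$r2_floor)
  writeLines(paste(names(kv), kv, sep = "="), path)
  invisible(path)
}

#' Read a flat key/value scenario configuration
#' @param path path written by [write_scenario_config()].
#' @export
read_scenario_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  num <- function(k) as.numeric(vals[[k]])
  ps <- strsplit(strsplit(vals[["pop_sizes"]], ",")[[1]], ":")
  pop_sizes <- stats::setNames(as.integer(vapply(ps, `[`, "", 2)),
                               vapply(ps, `[`, "", 1))
  scenario_config(
    simulation = simulation_config(
      seed = as.integer(num("seed")),
      chrom_length_bp = num("chrom_length_bp"),
      n_sites = as.integer(num("n_sites")),
      n_founders = as.integer(num("n_founders")),
      founder_sharing = num("founder_sharing"), pop_sizes = pop_sizes,
      map_rate_cm_per_mb = num("map_rate_cm_per_mb"),
      crossover_rate_per_cM = num("crossover_rate_per_cM"),
      private_mutation_rate = num("private_mutation_rate"),
      drift_rate = num("drift_rate"),
      site_freq_alpha = num("site_freq_alpha"),
      exonic_freq_alpha = num("exonic_freq_alpha"),
      genotyping_error = num("genotyping_error"),
      missing_rate = num("missing_rate"),
      exonic_fraction = num("exonic_fraction")),
    n_e = num("n_e"), hmm_error_rate = num("hmm_error_rate"),
    n_dense = as.integer(num("n_dense")),
    dense_min_maf = num("dense_min_maf"),
    n_legacy = as.integer(num("n_legacy")),
    legacy_min_maf = num("legacy_min_maf"),
    n_chip = as.integer(num("n_chip")),
    chip_rare_fraction = num("chip_rare_fraction"),
    n_cosmo_panel_per_pop = as.integer(num("n_cosmo_panel_per_pop")),
    n_specific_donors = as.integer(num("n_specific_donors")),
    target_pop = vals[["target_pop"]],
    cosmo_pops = strsplit(vals[["cosmo_pops"]], ",")[[1]],
    posterior_threshold = num("posterior_threshold"),
    core_bp = num("core_bp"), buffer_bp = num("buffer_bp"),
    window_bp = num("window_bp"), r2_floor = num("r2_floor"))
}
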