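#' Haplotype-copying HMM parameters
#'
#' Parameters of the Li-Stephens copying model: the query haplotype is an
#' imperfect mosaic of the reference haplotypes, switching template with
#' probability `1 - exp(-4 n_e d_cM / (100 k_ref))` between adjacent typed
#' sites `d_cM` apart (uniform over templates on a switch) and miscopying
#' each allele with probability `error_rate`.
#'
#' @param n_e effective population size, default 15000.
#' @param error_rate per-site copying-mismatch probability, in (0, 0.5).
#'   The default 0.01 absorbs both genotyping-level noise and
#'   target-versus-panel haplotype divergence.
#' @param map a [genetic_map()] supplying genetic distances.
#' @export
hmm_params <- function(n_e = 15000, error_rate = 0.01, map) {
  if (n_e <= 0) stop("n_e must be positive")
  if (error_rate <= 0 || error_rate >= 0.5)
    stop("error_rate must lie in (0, 0.5)")
  stopifnot(inherits(map, "genetic_map"))
  structure(list(n_e = n_e, error_rate = error_rate, map = map),
            class = "hmm_params")
}

#' Chunk plan for block-wise imputation
#'
#' Core intervals `[1, core], [core+1, 2 core], ...` tile the chromosome
#' without overlap (the last core is clipped); each buffered interval
#' extends the core by up to `buffer_bp` on each side, clipped to
#' `[1, chrom_length]`.
#'
#' @param chrom_length chromosome length in bp.
#' @param core_bp core block length, default 5 Mb.
#' @param buffer_bp buffer on each side, default 5 Mb.
#' @return a data.frame of class `chunk_plan` with columns `core_start`,
#'   `core_end`, `buffer_start`, `buffer_end`.
#' @export
make_chunk_plan <- function(chrom_length, core_bp = 5e6, buffer_bp = 5e6) {
  if (core_bp <= 0) stop("core_bp must be positive")
  starts <- seq(1, chrom_length, by = core_bp)
  ends <- pmin(starts + core_bp - 1, chrom_length)
  plan <- data.frame(core_start = starts, core_end = ends,
                     buffer_start = pmax(1, starts - buffer_bp),
                     buffer_end = pmin(chrom_length, ends + buffer_bp))
  class(plan) <- c("chunk_plan", "data.frame")
  plan
}

#' Haploid Li-Stephens posteriors at all reference sites
#'
#' Forward-backward over the hidden copied-haplotype state at the typed
#' sites, then read-off of the allele-1 probability at every reference
#' site. At a typed site the probability is the state-posterior-weighted
#' mean of the reference alleles there; at an untyped site it is the same
#' read-off under the two flanking typed-site posteriors, interpolated
#' linearly in genetic distance (no transitions are charged within the
#' untyped gap). Untyped sites outside the typed span use the nearest
#' typed-site posterior.
#'
#' @param target_hap integer 0/1 alleles of the query haplotype at the
#'   typed sites, in the order of `typed_vids`.
#' @param typed_vids variant ids of the typed sites; must be a subset of
#'   the reference panel's sites, at least one.
#' @param ref reference `haplotype_panel`.
#' @param params an [hmm_params()].
#' @return numeric vector, named by reference vid: allele-1 probability at
#'   every reference site, in [0, 1].
#' @export
ls_haploid_posteriors <- function(target_hap, typed_vids, ref, params) {
  m <- ncol(ref$haps)
  ti <- match(typed_vids, ref$variants$vid)
  if (length(ti) == 0 || anyNA(ti))
    stop("typed sites must be a non-empty subset of the reference sites")
  ord <- order(ti)
  ti <- ti[ord]
  target_hap <- target_hap[ord]
  k <- nrow(ref$haps)
  tt <- length(ti)
  theta <- params$error_rate
  cm <- map_cm(params$map, ref$variants$pos)

  ht <- ref$haps[, ti, drop = FALSE]
  eq <- ht == matrix(target_hap, nrow = k, ncol = tt, byrow = TRUE)
  emis <- theta + (1 - 2 * theta) * eq

  rho <- if (tt > 1) {
    d <- diff(cm[ti])
    1 - exp(-4 * params$n_e * d / (100 * k))
  } else numeric(0)

  fwd <- matrix(0, nrow = k, ncol = tt)
  f <- emis[, 1]
  fwd[, 1] <- f / sum(f)
  if (tt > 1) for (t in seq_len(tt - 1)) {
    f <- emis[, t + 1] * ((1 - rho[t]) * fwd[, t] + rho[t] / k)
    fwd[, t + 1] <- f / sum(f)
  }
  bwd <- matrix(0, nrow = k, ncol = tt)
  bwd[, tt] <- 1 / k
  if (tt > 1) for (t in seq(tt - 1, 1)) {
    eb <- emis[, t + 1] * bwd[, t + 1]
    b <- (1 - rho[t]) * eb + rho[t] / k * sum(eb)
    bwd[, t] <- b / sum(b)
  }
  gam <- fwd * bwd
  gam <- sweep(gam, 2, colSums(gam), "/")

  p <- numeric(m)
  p[ti] <- colSums(gam * ht)
  untyped <- setdiff(seq_len(m), ti)
  if (length(untyped) > 0) {
    # flanking typed index (0 = before first, tt = at/after last typed)
    left <- findInterval(untyped, ti)
    for (grp in split(untyped, left)) {
      l <- findInterval(grp[1], ti)
      hu <- ref$haps[, grp, drop = FALSE]
      if (l == 0) {
        p[grp] <- as.numeric(gam[, 1] %*% hu)
      } else if (l == tt) {
        p[grp] <- as.numeric(gam[, tt] %*% hu)
      } else {
        span <- cm[ti[l + 1]] - cm[ti[l]]
        w <- if (span <= 0) rep(0.5, length(grp)) else
          (cm[ti[l + 1]] - cm[grp]) / span
        pl <- as.numeric(gam[, l] %*% hu)
        pr <- as.numeric(gam[, l + 1] %*% hu)
        p[grp] <- w * pl + (1 - w) * pr
      }
    }
  }
  stats::setNames(pmin(1, pmax(0, p)), ref$variants$vid)
}

#' Impute genotype posteriors for phased target samples
#'
#' Runs the haploid Li-Stephens engine on each of a sample's two phased
#' haplotypes per buffered chunk, combines the two independent allele-1
#' probabilities into genotype posteriors
#' (`P(0) = (1-p1)(1-p2)`, `P(1) = p1 (1-p2) + (1-p1) p2`,
#' `P(2) = p1 p2`), keeps the core-interval results only and renormalizes
#' each triple.
#'
#' @param targets `haplotype_panel` of phased target haplotypes at the
#'   typed (array) sites only.
#' @param ref reference `haplotype_panel`; typed sites must be a subset of
#'   its sites.
#' @param params an [hmm_params()].
#' @param plan a [make_chunk_plan()] covering every reference site.
#' @return a [posterior_tensor()], samples x reference sites x 3.
#' @export
impute_genotypes <- function(targets, ref, params, plan = NULL) {
  stopifnot(inherits(targets, "haplotype_panel"),
            inherits(ref, "haplotype_panel"))
  if (is.null(plan))
    plan <- make_chunk_plan(max(ref$variants$pos), core_bp = 5e6,
                            buffer_bp = 5e6)
  rpos <- ref$variants$pos
  in_core <- vapply(rpos, function(p)
    any(p >= plan$core_start & p <= plan$core_end), TRUE)
  if (!all(in_core))
    stop("reference site outside every chunk core: ",
         ref$variants$vid[which(!in_core)[1]])
  typed_vids <- targets$variants$vid
  if (anyNA(match(typed_vids, ref$variants$vid)))
    stop("target typed sites must be a subset of the reference sites")
  tpos <- targets$variants$pos
  n <- length(targets$sample_ids)
  m <- length(rpos)
  probs <- array(NA_real_, dim = c(n, m, 3))
  for (ck in seq_len(nrow(plan))) {
    rsel <- which(rpos >= plan$buffer_start[ck] &
                    rpos <= plan$buffer_end[ck])
    core <- rpos[rsel] >= plan$core_start[ck] &
      rpos[rsel] <= plan$core_end[ck]
    if (!any(core)) next
    tsel <- which(tpos >= plan$buffer_start[ck] &
                    tpos <= plan$buffer_end[ck])
    if (length(tsel) == 0)
      stop("chunk ", ck, " contains no typed sites")
    ref_ck <- panel_subset(ref, rsel)
    fill <- rsel[core]
    for (s in seq_len(n)) {
      h1 <- targets$haps[2 * s - 1, tsel]
      h2 <- targets$haps[2 * s, tsel]
      p1 <- ls_haploid_posteriors(h1, typed_vids[tsel], ref_ck, params)[core]
      p2 <- ls_haploid_posteriors(h2, typed_vids[tsel], ref_ck, params)[core]
      probs[s, fill, 1] <- (1 - p1) * (1 - p2)
      probs[s, fill, 2] <- p1 * (1 - p2) + (1 - p1) * p2
      probs[s, fill, 3] <- p1 * p2
    }
  }
  tot <- probs[, , 1, drop = FALSE] + probs[, , 2, drop = FALSE] +
    probs[, , 3, drop = FALSE]
  for (g in 1:3) probs[, , g] <- probs[, , g] / tot[, , 1]
  posterior_tensor(probs, targets$sample_ids, ref$variants$vid)
}

#' Threshold genotype posteriors into discrete calls
#'
#' The call at each sample/site is the argmax genotype class if its
#' posterior reaches the threshold (boundary inclusive), otherwise
#' missing.
#'
#' @param posteriors a `posterior_tensor`.
#' @param threshold calling threshold in (1/3, 1], default 0.90.
#' @param variants optional variant table matching the tensor's site
#'   dimension; when supplied a [genotype_matrix()] is returned, otherwise
#'   a bare integer matrix with `NA` for no-calls.
#' @export
threshold_calls <- function(posteriors, threshold = 0.9, variants = NULL) {
  if (threshold <= 1 / 3 || threshold > 1)
    stop("threshold must lie in (1/3, 1]")
  d <- dim(posteriors)
  flat <- matrix(c(posteriors[, , 1], posteriors[, , 2], posteriors[, , 3]),
                 ncol = 3)
  best <- max.col(flat, ties.method = "first")
  calls <- ifelse(flat[cbind(seq_len(nrow(flat)), best)] >= threshold,
                  best - 1L, NA_integer_)
  g <- matrix(as.integer(calls), nrow = d[1], ncol = d[2])
  dimnames(g) <- dimnames(posteriors)[1:2]
  if (is.null(variants)) return(g)
  genotype_matrix(variants, g, dimnames(posteriors)[[1]])
}

#' Merge two reference panels by reciprocal cross-imputation
#'
#' Builds a panel over the union of both panels' sites. At sites absent
#' from one panel, each of that panel's haplotypes receives the modal
#' allele of its own haploid copying posterior computed against the other
#' panel (one deterministic pass each way; posterior ties resolve to
#' allele 0), so the merged panel has no missing alleles.
#'
#' @param panel_a,panel_b `haplotype_panel`s on the same chromosome,
#'   allele-consistent at shared sites, sharing at least one site.
#' @param params an [hmm_params()].
#' @return the merged `haplotype_panel`.
#' @export
merge_panels <- function(panel_a, panel_b, params) {
  va <- panel_a$variants; vb <- panel_b$variants
  if (!identical(unique(va$chrom), unique(vb$chrom)))
    stop("panels must be on the same chromosome")
  shared <- intersect(va$vid, vb$vid)
  if (length(shared) == 0)
    stop("panels share no sites; cross-imputation is impossible")
  ia <- match(shared, va$vid); ib <- match(shared, vb$vid)
  if (any(va$ref[ia] != vb$ref[ib] | va$alt[ia] != vb$alt[ib] |
            va$pos[ia] != vb$pos[ib]))
    stop("allele or position conflict at a shared variant id")
  union_v <- rbind(va, vb[is.na(match(vb$vid, va$vid)), , drop = FALSE])
  union_v <- union_v[order(union_v$pos), , drop = FALSE]
  if (anyDuplicated(union_v$pos))
    stop("distinct variant ids at the same position cannot be merged")
  mu <- nrow(union_v)
  fill_side <- function(panel, other) {
    idx_own <- match(panel$variants$vid, union_v$vid)
    missing_vids <- setdiff(union_v$vid, panel$variants$vid)
    out <- matrix(0L, nrow = nrow(panel$haps), ncol = mu)
    out[, idx_own] <- panel$haps
    if (length(missing_vids) > 0) {
      typed <- intersect(panel$variants$vid, other$variants$vid)
      fill_idx <- match(missing_vids, union_v$vid)
      src_idx <- match(missing_vids, other$variants$vid)
      t_own <- match(typed, panel$variants$vid)
      for (h in seq_len(nrow(panel$haps))) {
        p <- ls_haploid_posteriors(panel$haps[h, t_own], typed, other,
                                   params)
        out[h, fill_idx] <- as.integer(p[src_idx] > 0.5)
      }
    }
    out
  }
  haps <- rbind(fill_side(panel_a, panel_b), fill_side(panel_b, panel_a))
  haplotype_panel(union_v, haps, c(panel_a$sample_ids, panel_b$sample_ids),
                  name = paste(panel_a$name, panel_b$name, sep = "+"))
}
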