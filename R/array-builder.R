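#' Haplotype r-squared between two sites
#'
#' The squared correlation of phased alleles:
#' `r2 = D^2 / (p_a (1 - p_a) p_b (1 - p_b))` with `D = p_ab - p_a p_b`
#' estimated from haplotype counts. Both sites must be polymorphic in the
#' panel.
#'
#' @param panel a `haplotype_panel`.
#' @param vid_a,vid_b variant ids.
#' @return r-squared in [0, 1].
#' @export
haplotype_r2 <- function(panel, vid_a, vid_b) {
  ia <- match(vid_a, panel$variants$vid)
  ib <- match(vid_b, panel$variants$vid)
  if (is.na(ia) || is.na(ib)) stop("variant id not present in panel")
  a <- panel$haps[, ia]; b <- panel$haps[, ib]
  pa <- mean(a); pb <- mean(b)
  if (pa %in% c(0, 1) || pb %in% c(0, 1))
    stop("r-squared undefined at a monomorphic site")
  d <- mean(a * b) - pa * pb
  d^2 / (pa * (1 - pa) * pb * (1 - pb))
}

# Internal: r2 of one target site against many candidate sites, NA where
# either side is monomorphic. haps is the 0/1 haplotype matrix.
r2_against <- function(haps, target_idx, cand_idx) {
  t_al <- haps[, target_idx]
  pa <- mean(t_al)
  if (pa %in% c(0, 1)) return(rep(NA_real_, length(cand_idx)))
  cc <- haps[, cand_idx, drop = FALSE]
  pb <- colMeans(cc)
  pab <- as.numeric(crossprod(t_al, cc)) / nrow(haps)
  d <- pab - pa * pb
  r2 <- d^2 / (pa * (1 - pa) * pb * (1 - pb))
  r2[pb %in% c(0, 1)] <- NA_real_
  r2
}

#' Find an LD surrogate on a dense array for a target SNP
#'
#' Implements the hierarchical surrogate search used to rebuild legacy
#' array content from a dense array. If the target is itself on the dense
#' array the decision is `direct`. Otherwise dense-array sites within
#' `window_bp` of the target are scored strictly in this order, returning
#' the first rule satisfied: (i) perfect correlation (r2 = 1) with the
#' target in both panels; (ii) perfect correlation in panel 1 only;
#' (iii) perfect correlation in panel 2 only; (iv) the highest r2 in the
#' pooled (concatenated) haplotypes of both panels, provided that r2 is at
#' least `r2_floor`. Perfect correlation means r2 >= 1 - 1e-9. Within a
#' rule, ties are broken by smaller physical distance to the target, then
#' lower position, so the outcome is independent of candidate order.
#'
#' @param target_vid the SNP to recover.
#' @param dense_design `array_design` of the dense array.
#' @param panel1,panel2 reference `haplotype_panel`s over the same
#'   variants (the two ancestry panels of the hierarchy).
#' @param window_bp search window, default 1 Mb.
#' @param r2_floor minimum pooled r2 for rule (iv), default 0.80.
#' @return a one-row data.frame: `target_vid`, `surrogate_vid` (NA if
#'   none), `rule` in `{direct, i, ii, iii, iv, none}`, `r2_panel1`,
#'   `r2_panel2`, `distance_bp`.
#' @export
find_surrogate <- function(target_vid, dense_design, panel1, panel2,
                           window_bp = 1e6, r2_floor = 0.80) {
  dec <- function(surrogate, rule, r1 = NA_real_, r2 = NA_real_,
                  dist = NA_real_)
    data.frame(target_vid = target_vid, surrogate_vid = surrogate,
               rule = rule, r2_panel1 = r1, r2_panel2 = r2,
               distance_bp = dist, stringsAsFactors = FALSE)
  if (target_vid %in% dense_design$vids)
    return(dec(target_vid, "direct", dist = 0))
  v <- panel1$variants
  ti <- match(target_vid, v$vid)
  if (is.na(ti)) return(dec(NA_character_, "none"))
  cand <- match(intersect(dense_design$vids, v$vid), v$vid)
  cand <- cand[abs(v$pos[cand] - v$pos[ti]) <= window_bp & cand != ti]
  if (length(cand) == 0) return(dec(NA_character_, "none"))

  r2_1 <- r2_against(panel1$haps, ti, cand)
  r2_2 <- r2_against(panel2$haps, ti, cand)
  dist <- abs(v$pos[cand] - v$pos[ti])
  pick <- function(ok) {
    i <- which(ok)[order(dist[ok], v$pos[cand[ok]])[1]]
    dec(v$vid[cand[i]], rule_name, r2_1[i], r2_2[i], dist[i])
  }
  perfect <- function(x) !is.na(x) & x >= 1 - 1e-9
  rule_name <- "i"
  ok <- perfect(r2_1) & perfect(r2_2)
  if (any(ok)) return(pick(ok))
  rule_name <- "ii"
  ok <- perfect(r2_1)
  if (any(ok)) return(pick(ok))
  rule_name <- "iii"
  ok <- perfect(r2_2)
  if (any(ok)) return(pick(ok))
  pooled <- rbind(panel1$haps, panel2$haps)
  r2_p <- r2_against(pooled, ti, cand)
  ok <- !is.na(r2_p) & r2_p >= r2_floor
  if (any(ok)) {
    best <- max(r2_p[ok])
    at_best <- ok & !is.na(r2_p) & r2_p >= best - 1e-12
    i <- which(at_best)[order(dist[at_best], v$pos[cand[at_best]])[1]]
    return(dec(v$vid[cand[i]], "iv", r2_1[i], r2_2[i], dist[i]))
  }
  dec(NA_character_, "none")
}

#' Rebuild a legacy array from a dense array by surrogate search
#'
#' Applies [find_surrogate()] to every manifest entry. The rebuilt design
#' is the deduplicated union of direct hits and surrogate sites; a dense
#' site may serve several targets. The recovered count is the number of
#' manifest entries whose rule is not `none`.
#'
#' @param target_manifest character vector of target variant ids (the
#'   legacy array's content).
#' @param dense_design the dense `array_design` to draw surrogates from.
#' @param panel1,panel2 reference panels for the hierarchy.
#' @param window_bp,r2_floor as in [find_surrogate()].
#' @param name label for the rebuilt design.
#' @return list with `design` (`array_design`, rule `legacy_rebuilt`),
#'   `decisions` (data.frame, one row per manifest entry) and
#'   `n_recovered`.
#' @export
rebuild_array <- function(target_manifest, dense_design, panel1, panel2,
                          window_bp = 1e6, r2_floor = 0.80,
                          name = "legacy_rebuilt") {
  decisions <- do.call(rbind, lapply(target_manifest, find_surrogate,
                                     dense_design = dense_design,
                                     panel1 = panel1, panel2 = panel2,
                                     window_bp = window_bp,
                                     r2_floor = r2_floor))
  hit <- decisions$rule != "none"
  if (!any(hit)) {
    design <- NULL
  } else {
    design <- array_design(name, unique(decisions$surrogate_vid[hit]),
                           "legacy_rebuilt")
  }
  list(design = design, decisions = decisions, n_recovered = sum(hit))
}
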