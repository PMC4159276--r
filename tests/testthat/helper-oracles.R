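# Independent oracles used to cross-check the package's implementations.
# Each oracle is written from first principles (closed forms or exhaustive
# enumeration) and stays independent of the code path it checks.

# Exact HWE p-value by closed-form enumeration with log-factorials:
# P(n_het = h | n, rare allele count) = n! / (nAA! h! nBB!) * 2^h *
#   nRare! nCommon! / (2n)!
oracle_hwe <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  n_ref <- 2 * n_hom_ref + n_het
  rare <- min(n_ref, 2 * n - n_ref)
  if (rare == 0) return(1.0)
  hets <- seq(rare %% 2, rare, by = 2)
  logp <- vapply(hets, function(h) {
    naa <- (rare - h) / 2
    nbb <- n - naa - h
    lgamma(n + 1) - lgamma(naa + 1) - lgamma(h + 1) - lgamma(nbb + 1) +
      h * log(2) + lgamma(rare + 1) + lgamma(2 * n - rare + 1) -
      lgamma(2 * n + 1)
  }, 1.0)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(n_het, hets)]
  min(1, sum(p[p <= obs * (1 + 1e-10)]))
}

# r-squared from first-principles haplotype counts.
oracle_r2 <- function(a, b) {
  pa <- mean(a); pb <- mean(b)
  d <- mean(a * b) - pa * pb
  d^2 / (pa * (1 - pa) * pb * (1 - pb))
}

# Haploid Li-Stephens posteriors by exhaustive enumeration over all K^T
# hidden-state paths at the typed sites, with the same flanking-state
# read-off at untyped sites.
oracle_ls <- function(target_hap, typed_vids, ref, params) {
  k <- nrow(ref$haps)
  ti <- match(typed_vids, ref$variants$vid)
  ord <- order(ti); ti <- ti[ord]; target_hap <- target_hap[ord]
  tt <- length(ti)
  theta <- params$error_rate
  cm <- map_cm(params$map, ref$variants$pos)
  rho <- if (tt > 1)
    1 - exp(-4 * params$n_e * diff(cm[ti]) / (100 * k)) else numeric(0)
  emis <- function(state, t)
    if (ref$haps[state, ti[t]] == target_hap[t]) 1 - theta else theta
  trans <- function(s1, s2, t)
    (1 - rho[t]) * (s1 == s2) + rho[t] / k
  paths <- as.matrix(expand.grid(rep(list(seq_len(k)), tt)))
  gamma <- matrix(0, nrow = k, ncol = tt)
  for (r in seq_len(nrow(paths))) {
    pth <- paths[r, ]
    pr <- emis(pth[1], 1) / k
    if (tt > 1) for (t in seq_len(tt - 1))
      pr <- pr * trans(pth[t], pth[t + 1], t) * emis(pth[t + 1], t + 1)
    for (t in seq_len(tt)) gamma[pth[t], t] <- gamma[pth[t], t] + pr
  }
  gamma <- sweep(gamma, 2, colSums(gamma), "/")
  m <- ncol(ref$haps)
  p <- numeric(m)
  p[ti] <- colSums(gamma * ref$haps[, ti, drop = FALSE])
  for (u in setdiff(seq_len(m), ti)) {
    l <- findInterval(u, ti)
    if (l == 0) {
      p[u] <- sum(gamma[, 1] * ref$haps[, u])
    } else if (l == tt) {
      p[u] <- sum(gamma[, tt] * ref$haps[, u])
    } else {
      span <- cm[ti[l + 1]] - cm[ti[l]]
      w <- if (span <= 0) 0.5 else (cm[ti[l + 1]] - cm[u]) / span
      p[u] <- w * sum(gamma[, l] * ref$haps[, u]) +
        (1 - w) * sum(gamma[, l + 1] * ref$haps[, u])
    }
  }
  stats::setNames(p, ref$variants$vid)
}

# Brute-force surrogate search: score every in-window candidate under
# every rule independently and apply the hierarchy with positional
# tie-breaks.
oracle_surrogate <- function(target_vid, dense_design, panel1, panel2,
                             window_bp = 1e6, r2_floor = 0.80) {
  if (target_vid %in% dense_design$vids)
    return(list(vid = target_vid, rule = "direct"))
  v <- panel1$variants
  ti <- match(target_vid, v$vid)
  if (is.na(ti)) return(list(vid = NA_character_, rule = "none"))
  cand <- setdiff(match(intersect(dense_design$vids, v$vid), v$vid), ti)
  cand <- cand[abs(v$pos[cand] - v$pos[ti]) <= window_bp]
  if (length(cand) == 0) return(list(vid = NA_character_, rule = "none"))
  r2_of <- function(haps, i, j) {
    a <- haps[, i]; b <- haps[, j]
    if (mean(a) %in% c(0, 1) || mean(b) %in% c(0, 1)) return(NA_real_)
    oracle_r2(a, b)
  }
  r1 <- vapply(cand, function(j) r2_of(panel1$haps, ti, j), 1.0)
  r2 <- vapply(cand, function(j) r2_of(panel2$haps, ti, j), 1.0)
  rp <- vapply(cand, function(j)
    r2_of(rbind(panel1$haps, panel2$haps), ti, j), 1.0)
  dist <- abs(v$pos[cand] - v$pos[ti])
  best_of <- function(ok) {
    i <- which(ok)[order(dist[ok], v$pos[cand[ok]])[1]]
    list(vid = v$vid[cand[i]], i = i)
  }
  perf <- function(x) !is.na(x) & x >= 1 - 1e-9
  if (any(perf(r1) & perf(r2)))
    return(c(best_of(perf(r1) & perf(r2)), rule = "i"))
  if (any(perf(r1))) return(c(best_of(perf(r1)), rule = "ii"))
  if (any(perf(r2))) return(c(best_of(perf(r2)), rule = "iii"))
  ok <- !is.na(rp) & rp >= r2_floor
  if (any(ok)) {
    mx <- max(rp[ok])
    return(c(best_of(ok & !is.na(rp) & rp >= mx - 1e-12), rule = "iv"))
  }
  list(vid = NA_character_, rule = "none")
}
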