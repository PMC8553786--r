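# Differential methylation calling between two replicated groups:
# window smoothing, beta-binomial dispersion shrinkage, site-level Wald
# tests, DMC thresholding, DMC-to-DMR merging and post-filtering.

#' Smooth per-site methylation levels
#'
#' Each site's smoothed level is the coverage-weighted mean of the raw
#' levels of all sites within +/- `span_bp/2` of it on the same chromosome
#' (which equals the pooled-count level of the window). Isolated sites keep
#' their raw level.
#'
#' @param records a sorted record table (`chrom, pos, mC, total`).
#' @param span_bp full window width in bp (default 500).
#' @return copy of `records` with added columns `level` (raw) and
#'   `smoothed`.
#' @export
smooth_levels <- function(records, span_bp = 500L) {
  .validate_records(records)
  rec <- copy(as.data.table(records))
  setkey(rec, chrom, pos)
  half <- as.integer(span_bp) %/% 2L
  rec[, level := mC / total]
  rec[, smoothed := {
    cm <- c(0, cumsum(as.numeric(mC)))
    ct <- c(0, cumsum(as.numeric(total)))
    lo <- findInterval(pos - half - 1L, pos)      # sites before window
    hi <- findInterval(pos + half, pos)           # last site in window
    (cm[hi + 1L] - cm[lo + 1L]) / (ct[hi + 1L] - ct[lo + 1L])
  }, by = chrom]
  rec[]
}

# method-of-moments beta-binomial dispersion per site for one group.
# mC, total: site x replicate matrices with NA at uncovered entries.
# Var(m_i/n_i) = mu(1-mu) * (1/n_i + rho*(n_i-1)/n_i); solve for rho from
# the between-replicate variance of the observed proportions.
.dispersion_raw <- function(mC, total) {
  covered <- !is.na(total) & total > 0
  k <- rowSums(covered)
  tot <- ifelse(covered, total, NA_real_)
  m <- ifelse(covered, mC, NA_real_)
  mu <- rowSums(m, na.rm = TRUE) / rowSums(tot, na.rm = TRUE)
  pij <- m / tot
  s2 <- rowSums((pij - mu)^2, na.rm = TRUE) / pmax(k - 1L, 1L)
  a <- rowMeans(1 / tot, na.rm = TRUE)
  b <- rowMeans((tot - 1) / tot, na.rm = TRUE)
  v <- mu * (1 - mu)
  raw <- (s2 - v * a) / (v * b)
  raw[!is.finite(raw)] <- NA_real_
  raw[k < 2L] <- NA_real_
  raw <- pmin(pmax(raw, 0), 0.99)
  list(raw = raw, k = k, mu = mu)
}

#' Shrink site-level beta-binomial dispersions
#'
#' Method-of-moments dispersion per site, shrunk toward the mean
#' dispersion over all sites (an empirical prior) with a weight
#' proportional to the within-site information:
#' `w = (k - 1) / (k - 1 + shrink_df)` for `k` covered replicates. Sites
#' with fewer than two covered replicates take the prior mean.
#'
#' @param mC,total site-by-replicate count matrices of one group (NA =
#'   uncovered).
#' @param shrink_df prior strength in pseudo-replicates (default 4).
#' @param prior optional fixed prior mean dispersion; estimated from the
#'   data when `NULL`.
#' @return `data.table(raw, shrunk, n_rep)`; the prior mean is attached as
#'   attribute `prior`.
#' @export
estimate_dispersion <- function(mC, total, shrink_df = 4, prior = NULL) {
  est <- .dispersion_raw(as.matrix(mC), as.matrix(total))
  if (is.null(prior)) {
    ok <- !is.na(est$raw)
    prior <- if (any(ok)) mean(est$raw[ok]) else 0.01
    prior <- min(max(prior, 1e-4), 0.5)
  }
  w <- pmax(est$k - 1, 0) / (pmax(est$k - 1, 0) + shrink_df)
  shrunk <- ifelse(is.na(est$raw), prior, w * est$raw + (1 - w) * prior)
  out <- data.table(raw = est$raw, shrunk = shrunk, n_rep = est$k)
  setattr(out, "prior", prior)
  out
}

# window sums of arbitrary numeric columns around each site (same window
# convention as smooth_levels)
.window_sums <- function(track, cols, span_bp) {
  half <- as.integer(span_bp) %/% 2L
  out <- copy(track)
  out[, (paste0("w_", cols)) := {
    lo <- findInterval(pos - half - 1L, pos)
    hi <- findInterval(pos + half, pos)
    lapply(cols, function(cc) {
      cs <- c(0, cumsum(as.numeric(.SD[[cc]])))
      cs[hi + 1L] - cs[lo + 1L]
    })
  }, by = chrom, .SDcols = cols]
  out
}

# build site x sample matrices for one group from a list of record tables
.count_matrices <- function(samples, sites) {
  n <- nrow(sites)
  mC <- matrix(NA_real_, n, length(samples))
  total <- matrix(NA_real_, n, length(samples))
  key <- paste(sites$chrom, sites$pos)
  for (j in seq_along(samples)) {
    s <- samples[[j]]
    idx <- match(paste(s$chrom, s$pos), key)
    keep <- !is.na(idx)
    mC[idx[keep], j] <- s$mC[keep]
    total[idx[keep], j] <- s$total[keep]
  }
  list(mC = mC, total = total)
}

#' Site-level Wald tests for differential methylation
#'
#' For every CpG covered in at least one sample of each group, tests the
#' difference of smoothed group methylation levels with a Wald statistic.
#' Group levels are the window-smoothed pooled levels of the group track;
#' the standard error is the beta-binomial variance of each group's
#' windowed pooled estimator given the shrunk site dispersions and the
#' observed per-replicate coverages contributing to the window, floored
#' at the binomial variance of one continuity-corrected
#' pseudo-observation so that fixated sites never yield infinite
#' statistics. Two-sided p-values come from the normal reference and are
#' BH-adjusted across all tested sites.
#'
#' @param control,stress lists of record tables (one per replicate),
#'   already coverage-filtered.
#' @param span_bp smoothing window width (default 500).
#' @param shrink_df dispersion shrinkage strength, see
#'   [estimate_dispersion()].
#' @return `data.table(chrom, pos, beta_control, beta_stress, delta_beta,
#'   disp_control, disp_stress, wald, p, fdr)` with
#'   `delta_beta = beta_stress - beta_control`.
#' @export
wald_test_sites <- function(control, stress, span_bp = 500L,
                            shrink_df = 4) {
  stopifnot(length(control) >= 1L, length(stress) >= 1L)
  # one group's smoothed track: per-site windowed pooled level plus the
  # windowed beta-binomial variance weight
  group_track <- function(samples) {
    pooled <- rbindlist(samples)[, .(mC = sum(mC), total = sum(total)),
                                 by = .(chrom, pos)]
    setkey(pooled, chrom, pos)
    mat <- .count_matrices(samples, pooled)
    disp <- estimate_dispersion(mat$mC, mat$total, shrink_df)
    # per-site sum over replicates of n_ij (1 + (n_ij - 1) rho_i)
    pooled[, bb := rowSums(mat$total * (1 + (mat$total - 1) *
                                          disp$shrunk), na.rm = TRUE)]
    pooled[, rho := disp$shrunk]
    tr <- .window_sums(pooled, c("mC", "total", "bb"), span_bp)
    tr[, smoothed := w_mC / w_total]
    tr
  }
  tc <- group_track(control)
  ts <- group_track(stress)
  sites <- merge(
    tc[, .(chrom, pos, bc = smoothed, n_c = w_total, bb_c = w_bb,
           mc_c = w_mC, rho_c = rho)],
    ts[, .(chrom, pos, bs = smoothed, n_s = w_total, bb_s = w_bb,
           mc_s = w_mC, rho_s = rho)],
    by = c("chrom", "pos"))
  if (nrow(sites) == 0L)
    return(data.table(chrom = character(), pos = integer(),
                      beta_control = numeric(), beta_stress = numeric(),
                      delta_beta = numeric(), disp_control = numeric(),
                      disp_stress = numeric(), wald = numeric(),
                      p = numeric(), fdr = numeric()))
  grp_var <- function(mu, bb, n, mc) {
    v <- mu * (1 - mu) * bb / n^2
    muc <- (mc + 0.5) / (n + 1)
    pmax(v, muc * (1 - muc) / (n + 1))
  }
  v <- grp_var(sites$bc, sites$bb_c, sites$n_c, sites$mc_c) +
       grp_var(sites$bs, sites$bb_s, sites$n_s, sites$mc_s)
  delta <- sites$bs - sites$bc
  wald <- delta / sqrt(v)
  p <- 2 * pnorm(-abs(wald))
  p[delta == 0] <- 1
  out <- data.table(chrom = sites$chrom, pos = sites$pos,
                    beta_control = sites$bc, beta_stress = sites$bs,
                    delta_beta = delta,
                    disp_control = sites$rho_c,
                    disp_stress = sites$rho_s,
                    wald = wald, p = p,
                    fdr = p.adjust(p, method = "BH"))
  setkey(out, chrom, pos)
  out[]
}

#' Call differentially methylated cytosines
#'
#' A tested site is a DMC iff `|delta_beta| > effect_min` and
#' `fdr < fdr_max`.
#'
#' @param tests site test table from [wald_test_sites()].
#' @param effect_min minimum absolute level difference (default 0.1).
#' @param fdr_max FDR threshold (default 0.01).
#' @return the DMC subset of `tests`.
#' @export
call_dmcs <- function(tests, effect_min = 0.1, fdr_max = 0.01) {
  tests[abs(delta_beta) > effect_min & fdr < fdr_max]
}

#' Merge DMCs into differentially methylated regions
#'
#' Consecutive DMCs of the same direction are chained when they lie within
#' `merge_gap_bp` of each other and no intervening tested CpG reverses the
#' sign of the smoothed difference. A chain of at least `min_cpg` DMCs
#' spanning at least `min_len` bp becomes a DMR covering the CpG
#' dinucleotides of its first and last members. Region group levels are
#' the means of the smoothed levels of all tested sites in the span;
#' `area_stat` sums their Wald statistics; the region `fdr` is the
#' smallest member-DMC FDR.
#'
#' @param dmcs DMC table from [call_dmcs()].
#' @param tests full site test table (for intervening sites and region
#'   means).
#' @param min_len minimum region span in bp (default 50).
#' @param min_cpg minimum number of DMCs in the chain (default 4).
#' @param merge_gap_bp maximum distance between consecutive chained DMCs
#'   (default 100).
#' @return `data.table(dmr_id, chrom, start, end, n_cpg, n_dmc,
#'   beta_control, beta_stress, delta_beta, direction, area_stat, fdr)`
#'   with 0-based half-open coordinates.
#' @export
merge_dmcs_to_dmrs <- function(dmcs, tests, min_len = 50L, min_cpg = 4L,
                               merge_gap_bp = 100L) {
  empty <- data.table(dmr_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      n_cpg = integer(), n_dmc = integer(),
                      beta_control = numeric(), beta_stress = numeric(),
                      delta_beta = numeric(), direction = character(),
                      area_stat = numeric(), fdr = numeric())
  if (nrow(dmcs) == 0L) return(empty)
  dmcs <- copy(dmcs); setkey(dmcs, chrom, pos)
  tests <- copy(tests); setkey(tests, chrom, pos)
  res <- list()
  for (ch in unique(dmcs$chrom)) {
    d <- dmcs[chrom == ch]
    t <- tests[chrom == ch]
    sgn <- sign(d$delta_beta)
    tpos <- t$pos
    tsgn <- sign(t$delta_beta)
    cum_neg <- c(0L, cumsum(tsgn < 0))
    cum_pos <- c(0L, cumsum(tsgn > 0))
    cum_bc <- c(0, cumsum(t$beta_control))
    cum_bs <- c(0, cumsum(t$beta_stress))
    cum_w <- c(0, cumsum(t$wald))
    # break chain on: gap, direction change, or sign-reversing
    # intervening tested site
    brk <- logical(nrow(d))
    if (nrow(d) > 1L) {
      i <- 2L:nrow(d)
      gap_brk <- (d$pos[i] - d$pos[i - 1L]) > merge_gap_bp
      dir_brk <- sgn[i] != sgn[i - 1L]
      # tested sites strictly between consecutive DMCs
      lo <- findInterval(d$pos[i - 1L], tpos)        # last idx <= prev
      hi <- findInterval(d$pos[i] - 1L, tpos)        # last idx <  cur
      n_rev <- ifelse(sgn[i] > 0,
                      cum_neg[hi + 1L] - cum_neg[lo + 1L],
                      cum_pos[hi + 1L] - cum_pos[lo + 1L])
      brk[i] <- gap_brk | dir_brk | (n_rev > 0L)
    }
    d[, chain := cumsum(brk)]
    cl <- d[, .(n_dmc = .N, first = pos[1L], last = pos[.N],
                dir_sign = sign(delta_beta)[1L], fdr = min(fdr)),
            by = chain]
    cl <- cl[n_dmc >= min_cpg & (last + 1L) - (first - 1L) >= min_len]
    if (nrow(cl) == 0L) next
    i0 <- findInterval(cl$first - 1L, tpos) + 1L     # first idx >= first
    i1 <- findInterval(cl$last, tpos)                # last idx <= last
    n_cpg <- i1 - i0 + 1L
    bc <- (cum_bc[i1 + 1L] - cum_bc[i0]) / n_cpg
    bs <- (cum_bs[i1 + 1L] - cum_bs[i0]) / n_cpg
    res[[length(res) + 1L]] <- data.table(
      chrom = ch, start = cl$first - 1L, end = cl$last + 1L,
      n_cpg = n_cpg, n_dmc = cl$n_dmc,
      beta_control = bc, beta_stress = bs, delta_beta = bs - bc,
      direction = ifelse(cl$dir_sign < 0, "hypo", "hyper"),
      area_stat = cum_w[i1 + 1L] - cum_w[i0],
      fdr = cl$fdr)
  }
  if (!length(res)) return(empty)
  out <- rbindlist(res)
  setkey(out, chrom, start, end)
  out[, dmr_id := sprintf("dmr_%05d", .I)]
  setcolorder(out, "dmr_id")
  out[]
}

#' Post-filter candidate DMRs
#'
#' Merging in non-significant CpGs can dilute a region's difference below
#' the site threshold; a candidate is kept iff its absolute difference is
#' at least `abs_min` or its relative change exceeds `rel_min`, where the
#' relative change is `|delta_beta| / max(beta_control, beta_floor)` (a
#' low-to-high methylation switch is large relative to its origin even
#' when the absolute difference is small).
#'
#' @param dmrs DMR table.
#' @param abs_min absolute difference threshold (default 0.1).
#' @param rel_min relative change threshold (default 0.2).
#' @param beta_floor denominator floor (default 0.01).
#' @return filtered DMR table.
#' @export
postfilter_dmrs <- function(dmrs, abs_min = 0.1, rel_min = 0.2,
                            beta_floor = 0.01) {
  rel <- abs(dmrs$delta_beta) / pmax(dmrs$beta_control, beta_floor)
  dmrs[abs(dmrs$delta_beta) >= abs_min | rel > rel_min]
}

#' Annotate DMRs with overlapping regions
#'
#' A DMR is assigned every region it overlaps by at least one base
#' (half-open coordinates on both sides); DMRs overlapping nothing are
#' labelled `intergenic`.
#'
#' @param dmrs DMR table.
#' @param regions region table (`chrom,start,end,label,class`).
#' @return `data.table(dmr_id, label, class)`, one row per (DMR, region)
#'   pair.
#' @export
annotate_dmrs <- function(dmrs, regions) {
  if (nrow(dmrs) == 0L)
    return(data.table(dmr_id = character(), label = character(),
                      class = character()))
  gd <- GenomicRanges::GRanges(dmrs$chrom,
                               IRanges::IRanges(dmrs$start + 1L, dmrs$end))
  gr <- GenomicRanges::GRanges(regions$chrom,
                               IRanges::IRanges(regions$start + 1L,
                                                regions$end))
  ov <- GenomicRanges::findOverlaps(gd, gr, minoverlap = 1L)
  hit <- data.table(dmr_id = dmrs$dmr_id[S4Vectors::queryHits(ov)],
                    label = regions$label[S4Vectors::subjectHits(ov)],
                    class = regions$class[S4Vectors::subjectHits(ov)])
  nohit <- setdiff(dmrs$dmr_id, hit$dmr_id)
  rbind(hit, data.table(dmr_id = nohit, label = "intergenic",
                        class = "intergenic"))
}

#' Call DMRs between two groups end to end
#'
#' Convenience wrapper: [wald_test_sites()] then [call_dmcs()],
#' [merge_dmcs_to_dmrs()] and [postfilter_dmrs()] with the conventional
#' defaults.
#'
#' @param control,stress lists of coverage-filtered record tables.
#' @param span_bp,shrink_df see [wald_test_sites()].
#' @param effect_min,fdr_max see [call_dmcs()].
#' @param min_len,min_cpg,merge_gap_bp see [merge_dmcs_to_dmrs()].
#' @param abs_min,rel_min see [postfilter_dmrs()].
#' @return list with `tests` (site tests), `dmcs` and `dmrs`.
#' @export
call_dmrs <- function(control, stress, span_bp = 500L, shrink_df = 4,
                      effect_min = 0.1, fdr_max = 0.01, min_len = 50L,
                      min_cpg = 4L, merge_gap_bp = 100L, abs_min = 0.1,
                      rel_min = 0.2) {
  tests <- wald_test_sites(control, stress, span_bp, shrink_df)
  dmcs <- call_dmcs(tests, effect_min, fdr_max)
  dmrs <- merge_dmcs_to_dmrs(dmcs, tests, min_len, min_cpg, merge_gap_bp)
  dmrs <- postfilter_dmrs(dmrs, abs_min, rel_min)
  list(tests = tests, dmcs = dmcs, dmrs = dmrs)
}

#' Write DMRs as extended BED
#'
#' Columns: `chrom start end dmr_id area_stat strand beta_control
#' beta_stress delta_beta direction n_cpg fdr`.
#' @param dmrs DMR table.
#' @param path output path.
#' @export
write_dmr_bed <- function(dmrs, path) {
  out <- data.table(dmrs$chrom, dmrs$start, dmrs$end, dmrs$dmr_id,
                    dmrs$area_stat, "*", dmrs$beta_control,
                    dmrs$beta_stress, dmrs$delta_beta, dmrs$direction,
                    dmrs$n_cpg, dmrs$fdr)
  fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
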