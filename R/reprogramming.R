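# Embryonic reprogramming analysis: per-stage category classification of
# DMRs relative to paternal sperm, heritable-vs-unheritable contrasts,
# trajectory enumeration and escape analysis for special region classes.

.BASE_CATEGORIES <- c("free_hypo", "other_hypo", "unchanged",
                      "other_hyper", "full_hyper")
.EMBRYO_STAGES <- c("ICM", "PS", "PGC")

#' Classify an embryo-stage level against paternal sperm
#'
#' A region is de-methylated (`hypo` branch) when the embryo level falls
#' at least `delta_min` below the sperm level, and re-methylated (`hyper`
#' branch) when it rises at least `delta_min` above it; otherwise it is
#' `unchanged`. Within the hypo branch, levels at or below `free_max` are
#' `free_hypo` (completely erased); within the hyper branch, levels at or
#' above `full_min` are `full_hyper` (completely methylated). The derived
#' supersets total-hypo (= free + other hypo) and total-hyper (= full +
#' other hyper) complete the field's seven-category scheme.
#'
#' @param sperm_beta,embryo_beta region methylation levels (vectorised).
#' @param delta_min minimum level change (default 0.1).
#' @param free_max complete-erasure ceiling (default 0.1).
#' @param full_min complete-methylation floor (default 0.9).
#' @return character vector over `free_hypo, other_hypo, unchanged,
#'   other_hyper, full_hyper` (`NA` propagates for uncovered input).
#' @export
classify_vs_sperm <- function(sperm_beta, embryo_beta, delta_min = 0.1,
                              free_max = 0.1, full_min = 0.9) {
  d <- embryo_beta - sperm_beta
  out <- rep(NA_character_, length(d))
  ok <- !is.na(d)
  out[ok] <- "unchanged"
  out[ok & d <= -delta_min] <-
    ifelse(embryo_beta[ok & d <= -delta_min] <= free_max,
           "free_hypo", "other_hypo")
  out[ok & d >= delta_min] <-
    ifelse(embryo_beta[ok & d >= delta_min] >= full_min,
           "full_hyper", "other_hyper")
  out
}

#' Per-DMR reprogramming states across embryo stages
#'
#' For each DMR, stage and group: the paternal sperm level is the pooled
#' region level over the F0 sperm replicates of that group; the embryo
#' level comes from the (single-profile) embryo sample of that stage,
#' group and offspring generation. DMRs uncovered in either side carry
#' `NA` category and are excluded from denominators downstream.
#'
#' @param dmrs DMR table.
#' @param sperm_samples named list of all sperm record tables.
#' @param embryo_samples named list of embryo record tables.
#' @param sheet sample sheet covering both.
#' @param generation offspring generation of the embryos (default
#'   `"F1"`).
#' @param min_coverage site coverage threshold (default 5).
#' @param delta_min,free_max,full_min see [classify_vs_sperm()].
#' @return `data.table(dmr_id, stage, group, sperm_beta, embryo_beta,
#'   category)`.
#' @export
reprogramming_states <- function(dmrs, sperm_samples, embryo_samples,
                                 sheet, generation = "F1",
                                 min_coverage = 5L, delta_min = 0.1,
                                 free_max = 0.1, full_min = 0.9) {
  sheet <- as.data.table(sheet)
  regions <- data.table(region_id = dmrs$dmr_id, chrom = dmrs$chrom,
                        start = dmrs$start, end = dmrs$end)
  gen <- generation
  out <- list()
  for (grp in .SAMPLE_GROUPS) {
    f0 <- sheet[stage == "sperm" & generation == "F0" & group == grp,
                sample_id]
    pooled <- rbindlist(sperm_samples[f0])[
      , .(mC = sum(mC), total = sum(total)), by = .(chrom, pos)]
    sp <- .region_levels(pooled, regions, min_coverage)
    for (stg in .EMBRYO_STAGES) {
      eid <- sheet[stage == stg & group == grp & generation == gen,
                   sample_id]
      if (length(eid) == 0L) next
      em <- .region_levels(embryo_samples[[eid[1L]]], regions,
                           min_coverage)
      st <- data.table(dmr_id = regions$region_id, stage = stg,
                       group = grp)
      st[, sperm_beta := sp$pooled_level[match(dmr_id, sp$region_id)]]
      st[, embryo_beta := em$pooled_level[match(dmr_id, em$region_id)]]
      st[, category := classify_vs_sperm(sperm_beta, embryo_beta,
                                         delta_min, free_max, full_min)]
      out[[length(out) + 1L]] <- st
    }
  }
  rbindlist(out)
}

#' Heritable vs un-heritable category contrast at one stage
#'
#' Compares the reprogramming category composition of heritable DMRs
#' against an equal-sized set of un-heritable F0 DMRs with Fisher's exact
#' test, one 2x2 table per category (the five base categories plus the
#' derived total-hypo/total-hyper supersets). The un-heritable set is
#' sampled without replacement (seeded); when `match_deltas` is supplied
#' (named `|delta beta|` values per DMR) sampling is stratified on
#' deciles of the absolute F0 difference, with shortfalls filled at
#' random.
#'
#' @param states state table from [reprogramming_states()].
#' @param heritable_ids DMR ids of the heritable set.
#' @param stage one of `"ICM", "PS", "PGC"`.
#' @param group which group's states to compare (default `"stress"`).
#' @param match_deltas optional named numeric for decile matching.
#' @param seed RNG seed for the control-set draw.
#' @return `data.table(stage, group, category, h_in, h_out, u_in, u_out,
#'   odds_ratio, p, degenerate)`.
#' @export
compare_category_distributions <- function(states, heritable_ids, stage,
                                           group = "stress",
                                           match_deltas = NULL,
                                           seed = 1L) {
  stg <- stage; grp <- group
  st <- as.data.table(states)[stage == stg & group == grp &
                                !is.na(category)]
  h <- st[dmr_id %in% heritable_ids]
  pool <- st[!dmr_id %in% heritable_ids]
  n <- min(nrow(h), nrow(pool))
  pick <- local({
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    if (is.null(match_deltas)) {
      sample(nrow(pool), n)
    } else {
      hd <- abs(match_deltas[h$dmr_id])
      pd <- abs(match_deltas[pool$dmr_id])
      br <- unique(quantile(c(hd, pd), probs = seq(0, 1, 0.1),
                            na.rm = TRUE))
      hb <- cut(hd, br, include.lowest = TRUE)
      pb <- cut(pd, br, include.lowest = TRUE)
      idx <- integer(0)
      for (lev in levels(hb)) {
        want <- sum(hb == lev, na.rm = TRUE)
        avail <- setdiff(which(pb == lev), idx)
        idx <- c(idx, sample(avail, min(want, length(avail))))
      }
      short <- n - length(idx)
      if (short > 0)
        idx <- c(idx, sample(setdiff(seq_len(nrow(pool)), idx), short))
      idx[seq_len(n)]
    }
  })
  u <- pool[pick]
  in_cat <- function(cats, cat) switch(cat,
    total_hypo = cats %in% c("free_hypo", "other_hypo"),
    total_hyper = cats %in% c("full_hyper", "other_hyper"),
    cats == cat)
  cats <- c(.BASE_CATEGORIES, "total_hypo", "total_hyper")
  res <- lapply(cats, function(cat) {
    a <- sum(in_cat(h$category, cat)); b <- nrow(h) - a
    c_ <- sum(in_cat(u$category, cat)); d <- nrow(u) - c_
    tab <- matrix(c(a, b, c_, d), 2L)
    degen <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
    if (degen) {
      pv <- 1; or <- NA_real_
    } else {
      ft <- fisher.test(tab)
      pv <- ft$p.value; or <- unname(ft$estimate)
    }
    data.table(stage = stg, group = grp, category = cat, h_in = a,
               h_out = b, u_in = c_, u_out = d, odds_ratio = or,
               p = pv, degenerate = degen)
  })
  rbindlist(res)
}

#' Enumerate cross-stage trajectories of the group contrast
#'
#' For DMRs covered in all three embryo stages of both groups, the
#' stress-minus-control level difference at each stage is thresholded at
#' +/- `delta_min` into `hypo`, `hyper` or `unchanged`, and the
#' ICM-PS-PGC pattern string is tallied. The frequency table enumerates
#' all 27 combinations of three states over three stages (zero-filled),
#' ranked by count.
#'
#' @param stage_levels `data.table(dmr_id, stage, beta_control,
#'   beta_stress)` of embryo-stage region levels.
#' @param delta_min state threshold (default 0.1).
#' @return list with `trajectories` (`dmr_id`, per-stage states,
#'   `pattern`) and `pattern_freq` (all 27 patterns with counts).
#' @export
enumerate_trajectories <- function(stage_levels, delta_min = 0.1) {
  sl <- as.data.table(stage_levels)
  state <- function(d) fifelse(d <= -delta_min, "hypo",
                               fifelse(d >= delta_min, "hyper",
                                       "unchanged"))
  sl[, state := state(beta_stress - beta_control)]
  wide <- dcast(sl, dmr_id ~ stage, value.var = "state")
  need <- .EMBRYO_STAGES
  miss <- setdiff(need, names(wide))
  if (length(miss)) for (m in miss) wide[, (m) := NA_character_]
  wide <- wide[stats::complete.cases(wide[, ..need])]
  wide[, pattern := paste(ICM, PS, PGC, sep = "-")]
  states <- c("hypo", "hyper", "unchanged")
  all_pat <- apply(expand.grid(ICM = states, PS = states, PGC = states),
                   1L, paste, collapse = "-")
  freq <- data.table(pattern = all_pat)
  cnt <- wide[, .N, by = pattern]
  freq[, n := cnt$N[match(pattern, cnt$pattern)]]
  freq[is.na(n), n := 0L]
  setorder(freq, -n, pattern)
  list(trajectories = wide[, c("dmr_id", need, "pattern"), with = FALSE],
       pattern_freq = freq[])
}

#' Escape profile of a region class across embryo stages
#'
#' For regions of each class that are highly methylated in the pooled
#' sperm reference (`sperm level > high`), classifies each region at each
#' embryo stage as *maintained* (level within `delta_min` of sperm, i.e.
#' escaping erasure), *erased* (level at or below `free_max`, and not
#' maintained) or *intermediate*; fractions are over regions covered in
#' both sperm and the stage profile. Setting `high = 0` profiles all
#' covered regions.
#'
#' @param regions region table with `label`, `class` (and coordinates).
#' @param sperm_samples named list of sperm record tables to pool as the
#'   reference.
#' @param embryo_samples named list: one record table per embryo stage
#'   (names = stage).
#' @param high sperm-level floor for inclusion (default 0.8).
#' @param delta_min,free_max thresholds (defaults 0.1).
#' @param min_coverage site coverage threshold (default 5).
#' @return `data.table(class, stage, n_regions, maintained, erased,
#'   intermediate, frac_maintained, frac_erased, frac_intermediate)`.
#' @export
escape_profile <- function(regions, sperm_samples, embryo_samples,
                           high = 0.8, delta_min = 0.1, free_max = 0.1,
                           min_coverage = 5L) {
  regions <- as.data.table(regions)
  if (!"region_id" %in% names(regions))
    regions[, region_id := sprintf("reg_%05d", .I)]
  pooled <- rbindlist(sperm_samples)[
    , .(mC = sum(mC), total = sum(total)), by = .(chrom, pos)]
  sp <- .region_levels(pooled, regions, min_coverage)
  regions[, sperm_beta := sp$pooled_level[match(region_id,
                                                sp$region_id)]]
  keep <- regions[!is.na(sperm_beta) & sperm_beta > high]
  out <- list()
  for (stg in names(embryo_samples)) {
    em <- .region_levels(embryo_samples[[stg]], keep, min_coverage)
    kb <- copy(keep)
    kb[, embryo_beta := em$pooled_level[match(region_id, em$region_id)]]
    kb <- kb[!is.na(embryo_beta)]
    kb[, maintained := abs(embryo_beta - sperm_beta) < delta_min]
    kb[, erased := !maintained & embryo_beta <= free_max]
    sm <- kb[, .(n_regions = .N, maintained = sum(maintained),
                 erased = sum(erased),
                 intermediate = sum(!maintained & !erased)),
             by = class]
    sm[, stage := stg]
    out[[length(out) + 1L]] <- sm
  }
  res <- rbindlist(out)
  res[, `:=`(frac_maintained = maintained / n_regions,
             frac_erased = erased / n_regions,
             frac_intermediate = intermediate / n_regions)]
  setcolorder(res, c("class", "stage"))
  res[]
}

#' Variably methylated IAP analysis
#'
#' Filters VM-IAP regions whose sperm methylation level varies across all
#' sperm samples (sample standard deviation above `sd_max`), then, on the
#' retained regions, classifies every CpG site against the pooled sperm
#' reference at each embryo stage: *de-methylated* (at least `delta_min`
#' below sperm), *completely erased* (level at or below `free_max`), and,
#' for sites de-methylated in ICM, *reestablished in PS* (at least
#' `delta_min` above the ICM level and reaching within `delta_min` of the
#' sperm level or above); among the re-methylated (PS above ICM) sites
#' the fraction remaining below sperm is also reported.
#'
#' @param vm_regions VM-IAP region table.
#' @param sperm_samples named list of all sperm record tables.
#' @param embryo_samples named list with elements `ICM`, `PS` and
#'   optionally `PGC` (record tables).
#' @param sd_max sperm-variability cutoff (default 0.1).
#' @param delta_min,free_max thresholds (defaults 0.1).
#' @param min_coverage site coverage threshold (default 5).
#' @return list with `retained`/`removed` region tables (with the sperm
#'   SD) and `site_stats`, a one-row `data.table` of site counts and
#'   proportions.
#' @export
vm_iap_analysis <- function(vm_regions, sperm_samples, embryo_samples,
                            sd_max = 0.1, delta_min = 0.1,
                            free_max = 0.1, min_coverage = 5L) {
  vm <- as.data.table(vm_regions)
  if (!"region_id" %in% names(vm))
    vm[, region_id := sprintf("vmiap_%04d", .I)]
  lv <- region_levels_by_sample(sperm_samples, vm, min_coverage)
  sds <- lv[, .(sperm_sd = stats::sd(pooled_level),
                n_samples = .N), by = region_id]
  vm[, sperm_sd := sds$sperm_sd[match(region_id, sds$region_id)]]
  retained <- vm[!is.na(sperm_sd) & sperm_sd <= sd_max]
  removed <- vm[is.na(sperm_sd) | sperm_sd > sd_max]

  pooled <- rbindlist(sperm_samples)[
    , .(mC = sum(mC), total = sum(total)), by = .(chrom, pos)]
  pooled <- pooled[total >= min_coverage]
  # sites inside retained regions
  gs <- GenomicRanges::GRanges(pooled$chrom,
                               IRanges::IRanges(pooled$pos, pooled$pos))
  gr <- GenomicRanges::GRanges(retained$chrom,
                               IRanges::IRanges(retained$start + 1L,
                                                retained$end))
  ov <- GenomicRanges::findOverlaps(gs, gr)
  sites <- pooled[unique(S4Vectors::queryHits(ov))]
  sites[, sperm := mC / total]
  stage_level <- function(stg) {
    if (!stg %in% names(embryo_samples)) return(rep(NA_real_,
                                                    nrow(sites)))
    em <- embryo_samples[[stg]][total >= min_coverage]
    idx <- match(paste(sites$chrom, sites$pos),
                 paste(em$chrom, em$pos))
    (em$mC / em$total)[idx]
  }
  sites[, `:=`(icm = stage_level("ICM"), ps = stage_level("PS"),
               pgc = stage_level("PGC"))]
  icm_ok <- sites[!is.na(icm)]
  icm_demeth <- icm_ok[icm <= sperm - delta_min]
  ps_eval <- icm_demeth[!is.na(ps)]
  remeth <- ps_eval[ps >= icm + delta_min]
  reest <- remeth[ps >= sperm - delta_min]
  pgc_ok <- sites[!is.na(pgc)]
  site_stats <- data.table(
    n_sites = nrow(sites),
    n_icm_covered = nrow(icm_ok),
    frac_icm_demethylated = nrow(icm_demeth) / max(nrow(icm_ok), 1L),
    frac_icm_erased_of_demeth =
      mean(icm_demeth$icm <= free_max) ,
    n_ps_evaluable = nrow(ps_eval),
    frac_ps_remethylated = nrow(remeth) / max(nrow(ps_eval), 1L),
    frac_ps_reestablished = nrow(reest) / max(nrow(ps_eval), 1L),
    frac_ps_below_sperm_of_remeth =
      if (nrow(remeth)) mean(remeth$ps < remeth$sperm - delta_min)
      else NA_real_,
    n_pgc_covered = nrow(pgc_ok),
    frac_pgc_demethylated =
      if (nrow(pgc_ok)) mean(pgc_ok$pgc <= pgc_ok$sperm - delta_min)
      else NA_real_,
    frac_pgc_erased =
      if (nrow(pgc_ok)) mean(pgc_ok$pgc <= free_max) else NA_real_)
  list(retained = retained, removed = removed, site_stats = site_stats)
}
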