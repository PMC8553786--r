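# Cross-generation inheritance classification of F0 DMRs: per-generation
# replicate t-tests and the generation-paired Wilcoxon alternative.

# vectorised Welch t-test over rows of two level matrices (3 v 3 design).
# Rows with < 2 finite values on either side get NA (uncallable); rows
# with zero pooled variance get p = 1 when the means agree, else the
# variance is floored so the difference registers as extreme.
.welch_rows <- function(x, y, var_floor = 1e-16) {
  nx <- rowSums(is.finite(x)); ny <- rowSums(is.finite(y))
  mx <- rowMeans(x, na.rm = TRUE); my <- rowMeans(y, na.rm = TRUE)
  vx <- apply(x, 1L, stats::var, na.rm = TRUE)
  vy <- apply(y, 1L, stats::var, na.rm = TRUE)
  se2 <- vx / nx + vy / ny
  dfv <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  zero <- is.finite(se2) & se2 <= var_floor
  se2f <- pmax(se2, var_floor)
  tstat <- (my - mx) / sqrt(se2f)
  dfv[zero | !is.finite(dfv)] <- nx[zero | !is.finite(dfv)] +
    ny[zero | !is.finite(dfv)] - 2
  p <- 2 * pt(-abs(tstat), pmax(dfv, 1))
  p[zero & abs(my - mx) < 1e-12] <- 1
  p[nx < 2 | ny < 2] <- NA_real_
  list(t = tstat, p = p, mean_x = mx, mean_y = my, n_x = nx, n_y = ny)
}

#' Per-generation replicate test of an F0 DMR set
#'
#' For one sperm generation, tests each DMR's replicate region levels
#' (control vs stress, unpaired Welch t-test on the 3 v 3 replicate
#' levels). A DMR is significant iff its t-test passes `p < p_max` and
#' its level difference is at least `effect_min` in absolute value or
#' exceeds `rel_min` in relative change (`|delta| / max(beta_control,
#' beta_floor)`); the candidate regions enter already carrying the
#' region-calling FDR criterion, so the per-generation threshold is the
#' raw t-test p-value. BH-adjusted values across the DMR set within the
#' generation are reported alongside, and supplying `fdr_max`
#' additionally requires `fdr < fdr_max` (a much more stringent mode:
#' with three replicates per arm it is rarely attainable). DMRs with
#' fewer than two replicate levels on either side are uncallable
#' (`p = NA`, never significant).
#'
#' @param dmrs DMR table (needs `dmr_id, chrom, start, end`).
#' @param rep_levels per-replicate region levels from
#'   [region_levels_by_sample()].
#' @param sheet sample sheet restricted to sperm samples.
#' @param generation `"F0"`, `"F1"` or `"F2"`.
#' @param effect_min,rel_min,beta_floor effect-size criteria.
#' @param p_max raw p-value threshold (default 0.05).
#' @param fdr_max optional additional BH-FDR threshold (default `NULL`).
#' @return `data.table(dmr_id, generation, beta_control, beta_stress,
#'   delta_beta, t, p, fdr, significant)`.
#' @export
test_generation <- function(dmrs, rep_levels, sheet, generation,
                            effect_min = 0.1, rel_min = 0.2,
                            beta_floor = 0.01, p_max = 0.05,
                            fdr_max = NULL) {
  gen <- generation
  sperm <- sheet[sheet$stage == "sperm" & sheet$generation == gen, ]
  lv <- function(grp) {
    ids <- sperm$sample_id[sperm$group == grp]
    m <- matrix(NA_real_, nrow(dmrs), length(ids),
                dimnames = list(dmrs$dmr_id, ids))
    sub <- rep_levels[sample_id %in% ids]
    m[cbind(match(sub$region_id, dmrs$dmr_id),
            match(sub$sample_id, ids))] <- sub$pooled_level
    m
  }
  xc <- lv("control"); xs <- lv("stress")
  w <- .welch_rows(xc, xs)
  delta <- w$mean_y - w$mean_x
  out <- data.table(dmr_id = dmrs$dmr_id, generation = gen,
                    beta_control = w$mean_x, beta_stress = w$mean_y,
                    delta_beta = delta, t = w$t, p = w$p,
                    fdr = p.adjust(w$p, method = "BH"))
  rel <- abs(delta) / pmax(w$mean_x, beta_floor)
  sig <- !is.na(out$p) & out$p < p_max &
    (abs(delta) >= effect_min | rel > rel_min)
  if (!is.null(fdr_max)) sig <- sig & !is.na(out$fdr) & out$fdr < fdr_max
  out[, significant := sig]
  out[]
}

#' Classify inheritance from per-generation tests
#'
#' Truth table over per-generation significance of an F0 DMR:
#' significant in F0, F1 and F2 is `transgenerational`; in F0 and F1 but
#' not F2 is `intergenerational`; in F0 only is `F0_only`; every other
#' pattern (including uncallable generations) is `irregular`. Direction
#' consistency across generations is reported (`direction_consistent`)
#' but not required unless `strict_direction = TRUE`, in which case
#' inherited labels additionally require all significant generations to
#' share the F0 sign.
#'
#' @param gen_tests row-bound [test_generation()] results for F0, F1, F2.
#' @param strict_direction require a common direction for inherited
#'   labels.
#' @return one row per DMR with the label, per-generation statistics and
#'   `method = "per_generation_ttest"`.
#' @export
classify_inheritance <- function(gen_tests, strict_direction = FALSE) {
  wide <- dcast(as.data.table(gen_tests), dmr_id ~ generation,
                value.var = c("delta_beta", "p", "fdr", "significant"))
  need <- paste0("significant_", .GENERATIONS)
  if (!all(need %in% names(wide)))
    stop("gen_tests must cover generations F0, F1 and F2")
  s0 <- wide$significant_F0; s1 <- wide$significant_F1
  s2 <- wide$significant_F2
  callable <- !is.na(s0) & !is.na(s1) & !is.na(s2)
  s0[is.na(s0)] <- FALSE; s1[is.na(s1)] <- FALSE; s2[is.na(s2)] <- FALSE
  lab <- rep("irregular", nrow(wide))
  lab[callable & s0 & s1 & s2] <- "transgenerational"
  lab[callable & s0 & s1 & !s2] <- "intergenerational"
  lab[callable & s0 & !s1 & !s2] <- "F0_only"
  sg <- sign(cbind(wide$delta_beta_F0, wide$delta_beta_F1,
                   wide$delta_beta_F2))
  consist <- vapply(seq_len(nrow(wide)), function(i) {
    s <- sg[i, c(s0[i], s1[i], s2[i])]
    length(s) == 0L || all(s == s[1L], na.rm = TRUE)
  }, logical(1L))
  if (strict_direction)
    lab[lab %in% c("transgenerational", "intergenerational") &
          !consist] <- "irregular"
  out <- data.table(dmr_id = wide$dmr_id, label = lab,
                    direction_consistent = consist,
                    method = "per_generation_ttest")
  cbind(out, wide[, !"dmr_id"])
}

#' Classify inheritance with generation-paired Wilcoxon tests
#'
#' The alternative route: generations are treated as paired replicates of
#' the control/stress contrast. For each DMR a one-tailed exact Wilcoxon
#' signed-rank test (tail set by the F0 direction, zero differences
#' excluded) is run on the generation-mean pairs — F0/F1/F2 (n = 3) for
#' the transgenerational call and F0/F1 (n = 2) for the intergenerational
#' call — with BH adjustment across DMRs within each scope reported
#' alongside. Significance uses the raw p (`p_max`), optionally also the
#' BH value (`fdr_max`), and further requires the mean difference over
#' the scope to pass the effect criteria. Note that the exact one-sided
#' signed-rank p cannot fall below 1/8 at n = 3 (1/4 at n = 2), so this
#' route is conservative by construction at any threshold below those
#' floors; it is provided as the cross-check the per-generation t-test
#' route is compared against.
#'
#' @param gen_means `data.table(dmr_id, generation, beta_control,
#'   beta_stress)` of generation-mean region levels.
#' @param effect_min,rel_min,beta_floor,p_max,fdr_max as in
#'   [test_generation()].
#' @return one row per DMR: `label`, scope p-values/FDRs and
#'   `method = "cross_generation_wilcoxon"`.
#' @export
classify_inheritance_wilcoxon <- function(gen_means, effect_min = 0.1,
                                          rel_min = 0.2,
                                          beta_floor = 0.01,
                                          p_max = 0.05,
                                          fdr_max = NULL) {
  gm <- as.data.table(gen_means)
  gm[, generation := factor(generation, .GENERATIONS)]
  setkey(gm, dmr_id, generation)
  one <- function(sub, gens) {
    sub <- sub[generation %in% gens]
    if (nrow(sub) < length(gens) || anyNA(sub$beta_control) ||
        anyNA(sub$beta_stress))
      return(list(p = NA_real_, delta = NA_real_,
                  bc = NA_real_))
    d0 <- sub$beta_stress[sub$generation == "F0"] -
      sub$beta_control[sub$generation == "F0"]
    alt <- if (isTRUE(d0 < 0)) "less" else "greater"
    diffs <- sub$beta_stress - sub$beta_control
    diffs <- diffs[diffs != 0]              # zero-exclusion rule
    p <- if (length(diffs) == 0L) 1 else
      suppressWarnings(wilcox.test(diffs, alternative = alt,
                                   exact = TRUE)$p.value)
    list(p = p, delta = mean(sub$beta_stress - sub$beta_control),
         bc = mean(sub$beta_control))
  }
  res <- gm[, {
    tr <- one(.SD, .GENERATIONS)
    ig <- one(.SD, c("F0", "F1"))
    .(p_trans = tr$p, delta_trans = tr$delta, bc_trans = tr$bc,
      p_inter = ig$p, delta_inter = ig$delta, bc_inter = ig$bc)
  }, by = dmr_id]
  res[, fdr_trans := p.adjust(p_trans, "BH")]
  res[, fdr_inter := p.adjust(p_inter, "BH")]
  sig <- function(pv, f, d, bc) {
    s <- !is.na(pv) & pv < p_max &
      (abs(d) >= effect_min | abs(d) / pmax(bc, beta_floor) > rel_min)
    if (!is.null(fdr_max)) s <- s & !is.na(f) & f < fdr_max
    s
  }
  st <- sig(res$p_trans, res$fdr_trans, res$delta_trans, res$bc_trans)
  si <- sig(res$p_inter, res$fdr_inter, res$delta_inter, res$bc_inter)
  res[, label := fifelse(st, "transgenerational",
                         fifelse(si, "intergenerational", "F0_only"))]
  res[, method := "cross_generation_wilcoxon"]
  res[]
}

#' Inheritance proportions
#'
#' Counts and percentages per inheritance label. Following the field's
#' reporting convention, the `inherited` row is the inclusive set
#' (intergenerational-or-better, i.e. transgenerational DMRs are a subset
#' of the inherited DMRs), while the exclusive labels also appear
#' individually. Percentages are `100 * n / total` rounded to two
#' decimals.
#'
#' @param calls classification table with a `label` column (one row per
#'   DMR).
#' @return `data.table(label, n, total, percent)`.
#' @export
inheritance_summary <- function(calls) {
  total <- nrow(calls)
  cnt <- function(l) sum(calls$label == l)
  n_tr <- cnt("transgenerational")
  n_in <- cnt("intergenerational")
  out <- data.table(
    label = c("inherited", "transgenerational", "intergenerational",
              "F0_only", "irregular"),
    n = c(n_in + n_tr, n_tr, n_in, cnt("F0_only"), cnt("irregular")),
    total = total)
  out[, percent := fifelse(total > 0, round(100 * n / total, 2),
                           NA_real_)]
  out[]
}

#' Attenuation of inherited differences across generations
#'
#' Mean absolute level difference per generation over the selected DMRs,
#' with one-sided paired t-tests that the difference shrinks from each
#' generation to the next (`|delta|(F1) < |delta|(F0)`,
#' `|delta|(F2) < |delta|(F1)`). With fewer than two DMRs the means are
#' reported and the tests are skipped (`NA`).
#'
#' @param calls classification table.
#' @param gen_tests per-generation test table (long, as fed to
#'   [classify_inheritance()]).
#' @param labels which labels count as heritable (default the inherited
#'   set).
#' @return list with `means` (`data.table(generation, mean_abs_delta,
#'   n)`) and `p_attenuation` (named vector for the two transitions).
#' @export
delta_trend <- function(calls, gen_tests,
                        labels = c("transgenerational",
                                   "intergenerational")) {
  ids <- calls$dmr_id[calls$label %in% labels]
  sub <- as.data.table(gen_tests)[dmr_id %in% ids]
  wide <- dcast(sub, dmr_id ~ generation, value.var = "delta_beta")
  means <- sub[, .(mean_abs_delta = mean(abs(delta_beta), na.rm = TRUE),
                   n = sum(!is.na(delta_beta))), by = generation]
  setorder(means, generation)
  pair_p <- function(a, b) {           # H1: |b| < |a|
    d <- abs(b) - abs(a)
    d <- d[is.finite(d)]
    if (length(d) < 2L || stats::sd(d) == 0) return(NA_real_)
    stats::t.test(d, alternative = "less")$p.value
  }
  p <- c(F0_to_F1 = if (all(c("F0", "F1") %in% names(wide)))
           pair_p(wide$F0, wide$F1) else NA_real_,
         F1_to_F2 = if (all(c("F1", "F2") %in% names(wide)))
           pair_p(wide$F1, wide$F2) else NA_real_)
  list(means = means, p_attenuation = p)
}

#' Write an inheritance call table
#'
#' TSV with one row per DMR: label, per-generation p/FDR/difference and
#' the method tag.
#' @param calls output of [classify_inheritance()].
#' @param path output path.
#' @export
write_inheritance_calls <- function(calls, path) {
  fwrite(calls, path, sep = "\t")
  invisible(path)
}
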