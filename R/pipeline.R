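# End-to-end orchestration on synthetic or on-disk inputs: stage
# execution, report tables and a manifest recording the configuration
# hash and seed for reproducibility.

#' Pipeline configuration
#'
#' Flat named list of every analysis threshold, each defaulting to the
#' field's conventional value, plus the simulation config and RNG seed.
#' Deviations from the defaults are therefore always explicit in the
#' manifest.
#'
#' @param sim a [sim_config()] describing the synthetic inputs.
#' @param min_coverage site coverage threshold.
#' @param span_bp smoothing window.
#' @param dmc_effect_min,dmc_fdr_max DMC thresholds.
#' @param dmr_min_len,dmr_min_cpg,merge_gap_bp DMR merging parameters.
#' @param post_abs_min,post_rel_min DMR post-filter.
#' @param herit_effect_min,herit_rel_min,herit_p_max heritability test
#'   criteria.
#' @param rep_delta_min,rep_free_max,rep_full_min reprogramming category
#'   thresholds.
#' @param snc_min_count_sum,snc_min_rpm_sum,snc_p_max sncRNA screen.
#' @param seed_len seed window length for sequence matching.
#' @param vmiap_sd_max VM-IAP variability cutoff.
#' @param seed pipeline RNG seed (control-set sampling etc.).
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(),
                            min_coverage = 5L, span_bp = 500L,
                            dmc_effect_min = 0.1, dmc_fdr_max = 0.01,
                            dmr_min_len = 50L, dmr_min_cpg = 4L,
                            merge_gap_bp = 100L, post_abs_min = 0.1,
                            post_rel_min = 0.2,
                            herit_effect_min = 0.1,
                            herit_rel_min = 0.2, herit_p_max = 0.05,
                            rep_delta_min = 0.1, rep_free_max = 0.1,
                            rep_full_min = 0.9,
                            snc_min_count_sum = 15,
                            snc_min_rpm_sum = 1, snc_p_max = 0.05,
                            seed_len = 7L, vmiap_sd_max = 0.1,
                            seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  validate_pipeline_config(cfg)
  cfg
}

#' Validate a pipeline configuration
#'
#' Fails fast (before any stage runs) on out-of-range thresholds.
#' @param config a `pipeline_config`.
#' @return the config, invisibly.
#' @export
validate_pipeline_config <- function(config) {
  with(config, {
    if (min_coverage < 1) stop("min_coverage must be >= 1")
    if (span_bp < 0) stop("span_bp must be non-negative")
    for (x in c(dmc_effect_min, dmc_fdr_max, post_abs_min,
                herit_effect_min, herit_p_max, rep_delta_min,
                rep_free_max, rep_full_min, snc_p_max, vmiap_sd_max))
      if (x < 0 || x > 1) stop("probability/level thresholds must lie in [0,1]")
    if (dmr_min_len < 1 || dmr_min_cpg < 1 || merge_gap_bp < 0)
      stop("DMR merging parameters out of range")
    if (seed_len < 1) stop("seed_len must be >= 1")
  })
  stopifnot(inherits(config$sim, "sim_config"))
  invisible(config)
}

.config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config, f)
  unname(tools::md5sum(f))
}

#' Run the full analysis pipeline on synthetic data
#'
#' Simulates sperm methylomes, embryo profiles and an sncRNA table under
#' `config$sim`, then runs DMR calling (F0 control vs stress),
#' heritability classification (both statistical routes), reprogramming
#' and escape analysis, sncRNA differential enrichment with seed matching
#' to DMR sequences, and the summary report. Stage outputs are written as
#' TSV under `outdir` together with a JSON manifest recording the config
#' hash, seed and output checksums; identical config implies identical
#' manifest checksums.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory.
#' @return list of in-memory stage results (invisibly also on disk).
#' @export
run_pipeline <- function(config, outdir) {
  validate_pipeline_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  meth <- simulate_methylomes(config$sim)
  emb <- simulate_embryos(config$sim, meth)
  snc <- simulate_sncrna(config$sim, meth)
  filt <- lapply(meth$samples, function(s)
    s[total >= config$min_coverage])
  sheet <- meth$sheet
  grp_ids <- function(gen, grp)
    sheet[sheet$generation == gen & sheet$group == grp, sample_id]

  dmr_res <- call_dmrs(filt[grp_ids("F0", "control")],
                       filt[grp_ids("F0", "stress")],
                       span_bp = config$span_bp,
                       effect_min = config$dmc_effect_min,
                       fdr_max = config$dmc_fdr_max,
                       min_len = config$dmr_min_len,
                       min_cpg = config$dmr_min_cpg,
                       merge_gap_bp = config$merge_gap_bp,
                       abs_min = config$post_abs_min,
                       rel_min = config$post_rel_min)
  dmrs <- dmr_res$dmrs
  write_dmr_bed(dmrs, file.path(outdir, "dmrs_F0.bed"))

  regions <- data.table(region_id = dmrs$dmr_id, chrom = dmrs$chrom,
                        start = dmrs$start, end = dmrs$end)
  rl <- region_levels_by_sample(filt, regions, config$min_coverage)
  gt <- rbindlist(lapply(.GENERATIONS, function(g)
    test_generation(dmrs, rl, sheet, g,
                    effect_min = config$herit_effect_min,
                    rel_min = config$herit_rel_min,
                    p_max = config$herit_p_max)))
  calls <- classify_inheritance(gt)
  write_inheritance_calls(calls, file.path(outdir, "inheritance.tsv"))
  gm <- gt[, .(dmr_id, generation, beta_control, beta_stress)]
  calls_w <- classify_inheritance_wilcoxon(
    gm, effect_min = config$herit_effect_min,
    rel_min = config$herit_rel_min, p_max = config$herit_p_max)
  fwrite(calls_w, file.path(outdir, "inheritance_wilcoxon.tsv"),
         sep = "\t")
  summ <- inheritance_summary(calls)
  fwrite(summ, file.path(outdir, "inheritance_summary.tsv"), sep = "\t")

  herit_ids <- calls[label %in% c("transgenerational",
                                  "intergenerational"), dmr_id]
  states <- reprogramming_states(dmrs, meth$samples, emb$samples,
                                 rbind(sheet, emb$sheet, fill = TRUE),
                                 min_coverage = config$min_coverage,
                                 delta_min = config$rep_delta_min,
                                 free_max = config$rep_free_max,
                                 full_min = config$rep_full_min)
  fwrite(states, file.path(outdir, "reprogramming_states.tsv"),
         sep = "\t")
  f0_delta <- setNames(abs(gt[generation == "F0", delta_beta]),
                       gt[generation == "F0", dmr_id])
  # contrast de-methylated and re-methylated DMRs separately: pooled
  # directions cancel at the reestablishment stage
  fisher_tabs <- rbindlist(lapply(c("hypo", "hyper"), function(dd) {
    ids_d <- dmrs[direction == dd, dmr_id]
    st_d <- states[dmr_id %in% ids_d]
    tab <- rbindlist(lapply(.EMBRYO_STAGES, function(stg)
      compare_category_distributions(st_d,
                                     intersect(herit_ids, ids_d), stg,
                                     match_deltas = f0_delta,
                                     seed = config$seed)))
    tab[, dmr_direction := dd]
    tab
  }))
  fwrite(fisher_tabs, file.path(outdir, "category_contrasts.tsv"),
         sep = "\t")
  stage_lv <- .stage_contrast_levels(dmrs, emb, config$min_coverage)
  traj <- enumerate_trajectories(stage_lv,
                                 delta_min = config$rep_delta_min)
  fwrite(traj$pattern_freq, file.path(outdir, "trajectories.tsv"),
         sep = "\t")
  esc <- escape_profile(
    meth$regions[class %in% c("TE", "imprinted", "VM_IAP")],
    meth$samples[grp_ids("F0", "control")],
    .stage_profiles(emb, "control"),
    min_coverage = config$min_coverage)
  fwrite(esc, file.path(outdir, "escape_profile.tsv"), sep = "\t")
  vm <- vm_iap_analysis(meth$regions[class == "VM_IAP"],
                        meth$samples,
                        .stage_profiles(emb, "control"),
                        sd_max = config$vmiap_sd_max,
                        min_coverage = config$min_coverage)
  fwrite(vm$site_stats, file.path(outdir, "vmiap_site_stats.tsv"),
         sep = "\t")

  diff_seq <- differential_sequences(
    snc$tbl, snc$groups, snc$library_sizes,
    min_count_sum = config$snc_min_count_sum,
    min_rpm_sum = config$snc_min_rpm_sum, p_max = config$snc_p_max)
  diff_sub <- differential_subclasses(
    snc$tbl, snc$groups, snc$library_sizes,
    min_count_sum = config$snc_min_count_sum,
    min_rpm_sum = config$snc_min_rpm_sum, p_max = config$snc_p_max)
  comp <- composition_report(diff_sub)
  fwrite(diff_seq, file.path(outdir, "differential_sequences.tsv"),
         sep = "\t")
  fwrite(comp, file.path(outdir, "snc_composition.tsv"), sep = "\t")
  diff_ids <- snc$tbl$snc_id[match(diff_seq[differential == TRUE,
                                            sequence],
                                   snc$tbl$sequence)]
  snc_seqs <- setNames(snc$tbl$sequence, snc$tbl$snc_id)[diff_ids]
  matches <- if (length(snc_seqs) && length(snc$dmr_seqs))
    seed_match(snc_seqs, snc$dmr_seqs, config$seed_len)
  else data.table()
  if (nrow(matches))
    fwrite(matches, file.path(outdir, "seed_matches.tsv"), sep = "\t")

  report <- make_report(list(summary = summ, contrasts = fisher_tabs,
                             trajectories = traj$pattern_freq,
                             composition = comp))
  writeLines(report, file.path(outdir, "report.txt"))

  outputs <- list.files(outdir, full.names = TRUE)
  manifest <- list(config_hash = .config_hash(config),
                   seed = config$seed, sim_seed = config$sim$seed,
                   outputs = as.list(tools::md5sum(sort(outputs))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(dmrs = dmrs, gen_tests = gt, calls = calls,
                 calls_wilcoxon = calls_w, summary = summ,
                 states = states, contrasts = fisher_tabs,
                 trajectories = traj, escape = esc, vmiap = vm,
                 diff_sequences = diff_seq, composition = comp,
                 matches = matches, manifest = manifest))
}

# per-stage stress-vs-control region levels for the trajectory analysis
.stage_contrast_levels <- function(dmrs, emb, min_coverage) {
  regions <- data.table(region_id = dmrs$dmr_id, chrom = dmrs$chrom,
                        start = dmrs$start, end = dmrs$end)
  sheet <- as.data.table(emb$sheet)[generation == "F1" &
                                      stage %in% .EMBRYO_STAGES]
  lv <- region_levels_by_sample(emb$samples[sheet$sample_id], regions,
                                min_coverage)
  lv <- merge(lv, sheet[, .(sample_id, stage, group)],
              by = "sample_id")
  dcast(lv, region_id + stage ~ group,
        value.var = "pooled_level")[
    , .(dmr_id = region_id, stage, beta_control = control,
        beta_stress = stress)]
}

# named per-stage record tables of one group's F1 embryos
.stage_profiles <- function(emb, grp) {
  sheet <- as.data.table(emb$sheet)
  ids <- sheet[group == grp & generation == "F1" &
                 stage %in% .EMBRYO_STAGES]
  setNames(emb$samples[ids$sample_id], ids$stage)
}

#' Compose a plain-text summary report
#'
#' Renders the inheritance summary, per-stage category contrasts, top
#' trajectory patterns and sncRNA composition as aligned text sections;
#' empty sections render as zero counts rather than failing.
#'
#' @param tables named list with `summary`, `contrasts`,
#'   `trajectories`, `composition` tables.
#' @param top_k trajectory patterns to show (default 5).
#' @return character vector of report lines.
#' @export
make_report <- function(tables, top_k = 5L) {
  fmt <- function(dt) c(capture.output(print(as.data.frame(dt),
                                             row.names = FALSE)), "")
  c("== Inheritance proportions ==", fmt(tables$summary),
    "== Heritable vs un-heritable category contrasts ==",
    fmt(tables$contrasts[, .(stage, category, odds_ratio, p)]),
    paste0("== Top ", top_k, " reprogramming trajectories =="),
    fmt(utils::head(tables$trajectories, top_k)),
    "== Differential sncRNA composition ==",
    fmt(tables$composition))
}
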