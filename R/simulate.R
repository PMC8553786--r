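# Synthetic-data generator: sperm methylomes with planted heritable DMRs,
# embryo-stage profiles with erase/reestablish dynamics and escape
# regions, and annotated sncRNA count tables with planted fold changes
# and DMR-embedded complements. Everything is deterministic under the
# config seed.

#' Simulation configuration
#'
#' Defaults describe the study design the package targets: two groups of
#' three sperm replicates in each of three generations, planted region
#' effects of |delta beta| 0.3 attenuated by 0.8 per generation, ~20x
#' Poisson coverage with beta-binomial replicate noise, single-profile
#' embryo stages with an erase-then-reestablish trajectory and a
#' primitive-streak group offset for heritable regions, a small fraction
#' of transposable elements and VM-IAPs escaping the first erasure, and
#' negative-binomial sncRNA counts with type-specific planted fold
#' changes.
#'
#' @param seed integer RNG seed; all generator randomness derives from
#'   it.
#' @param chrom_lengths named integer vector of chromosome lengths (bp).
#' @param cpg_per_kb background CpG density.
#' @param n_dmrs planted region counts per class
#'   (`transgenerational`, `intergenerational`, `F0_only`, `null`).
#' @param effect planted |delta beta| of stress vs control in affected
#'   generations.
#' @param attenuation per-generation multiplier on the planted effect.
#' @param dmr_len,dmr_n_cpg planted region span (bp) and CpG count.
#' @param coverage,embryo_coverage mean sequencing depth (Poisson) for
#'   sperm and embryo profiles.
#' @param dispersion beta-binomial dispersion of replicate counts.
#' @param n_te,n_imprinted,n_vmiap auxiliary region counts (transposable
#'   elements, imprinted genes, VM-IAPs).
#' @param escape_fraction fraction of TE/VM-IAP regions that keep sperm
#'   methylation at ICM.
#' @param vmiap_variable_fraction fraction of VM-IAPs with variable sperm
#'   methylation (to exercise the SD filter).
#' @param icm_retention,pgc_retention multiplicative residue of sperm
#'   methylation at ICM / PGC.
#' @param ps_reest_prob per-site probability of reestablishment at the
#'   primitive streak (bimodal PS profile).
#' @param ps_offset group offset of the reestablished PS level at
#'   heritable regions (applied along the planted direction in the
#'   stress embryos).
#' @param sncrna list: `n_per_type` (named counts), `n_diff` (named
#'   planted differential counts, e.g. `up_tsRNA`), `fold`, `libsize`,
#'   `nb_dispersion`.
#' @param planted_complementarity fraction of heritable DMR sequences
#'   carrying an embedded 8-10 bp complement of a planted differential
#'   sncRNA.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       chrom_lengths = c(chr1 = 5e6, chr2 = 5e6),
                       cpg_per_kb = 10,
                       n_dmrs = c(transgenerational = 100L,
                                  intergenerational = 400L,
                                  F0_only = 1500L, null = 200L),
                       effect = 0.3, attenuation = 0.8,
                       dmr_len = 300L, dmr_n_cpg = 8L,
                       coverage = 20, embryo_coverage = 15,
                       dispersion = 0.03,
                       n_te = 100L, n_imprinted = 30L, n_vmiap = 105L,
                       escape_fraction = 0.03,
                       vmiap_variable_fraction = 18 / 105,
                       icm_retention = 0.1, pgc_retention = 0.05,
                       ps_reest_prob = 0.55, ps_offset = 0.3,
                       sncrna = list(), planted_complementarity = 0.5) {
  snc_default <- list(
    n_per_type = c(miRNA = 300L, tsRNA = 300L, rsRNA = 200L,
                   piRNA = 200L),
    n_diff = c(up_tsRNA = 60L, down_miRNA = 90L, down_rsRNA = 20L),
    fold = 3, libsize = 2e6, nb_dispersion = 0.02,
    embeds_per_dmr = 5L)
  sncrna <- utils::modifyList(snc_default, sncrna)
  cfg <- list(seed = as.integer(seed), chrom_lengths = chrom_lengths,
              cpg_per_kb = cpg_per_kb, n_dmrs = n_dmrs, effect = effect,
              attenuation = attenuation, dmr_len = as.integer(dmr_len),
              dmr_n_cpg = as.integer(dmr_n_cpg), coverage = coverage,
              embryo_coverage = embryo_coverage,
              dispersion = dispersion, n_te = n_te,
              n_imprinted = n_imprinted, n_vmiap = n_vmiap,
              escape_fraction = escape_fraction,
              vmiap_variable_fraction = vmiap_variable_fraction,
              icm_retention = icm_retention,
              pgc_retention = pgc_retention,
              ps_reest_prob = ps_reest_prob, ps_offset = ps_offset,
              sncrna = sncrna,
              planted_complementarity = planted_complementarity)
  stopifnot(cfg$coverage > 0, cfg$embryo_coverage > 0,
            cfg$dispersion >= 0, cfg$dispersion < 1,
            cfg$effect > 0, cfg$effect <= 1,
            cfg$attenuation >= 0, cfg$attenuation <= 1,
            cfg$escape_fraction >= 0, cfg$escape_fraction <= 1,
            cfg$planted_complementarity >= 0,
            cfg$planted_complementarity <= 1,
            all(cfg$chrom_lengths > 0), cfg$cpg_per_kb > 0)
  class(cfg) <- "sim_config"
  cfg
}

.clamp01 <- function(x, lo = 0.02, hi = 0.98) pmin(pmax(x, lo), hi)

# beta-binomial draw; rho -> 0 degrades to binomial
.rbetabinom <- function(n, size, mu, rho) {
  mu <- .clamp01(mu, 1e-4, 1 - 1e-4)
  if (rho < 1e-8) return(rbinom(n, size, mu))
  a <- mu * (1 - rho) / rho
  b <- (1 - mu) * (1 - rho) / rho
  rbinom(n, size, rbeta(n, a, b))
}

# lay out non-overlapping planted regions on a grid and draw background
# CpGs outside them
.layout_genome <- function(cfg) {
  classes <- c(rep(names(cfg$n_dmrs), cfg$n_dmrs),
               rep("TE", cfg$n_te), rep("imprinted", cfg$n_imprinted),
               rep("VM_IAP", cfg$n_vmiap))
  n_reg <- length(classes)
  slot <- cfg$dmr_len + 400L
  slots <- rbindlist(lapply(names(cfg$chrom_lengths), function(ch) {
    n <- floor(cfg$chrom_lengths[[ch]] / slot) - 1L
    data.table(chrom = ch, slot_i = seq_len(n))
  }))
  if (nrow(slots) < n_reg)
    stop("genome too small for ", n_reg, " planted regions")
  pick <- slots[sample(nrow(slots), n_reg)]
  regions <- data.table(
    region_id = sprintf("reg_%05d", seq_len(n_reg)),
    chrom = pick$chrom,
    start = (pick$slot_i - 1L) * slot + 200L,
    class = sample(classes))
  regions[, end := start + cfg$dmr_len]
  if (n_reg == 0L)
    return(list(
      regions = data.table(region_id = character(), chrom = character(),
                           start = integer(), end = integer(),
                           class = character()),
      reg_sites = data.table(region_id = character(),
                             chrom = character(), start = integer(),
                             end = integer(), class = character(),
                             pos = integer()),
      background = rbindlist(lapply(names(cfg$chrom_lengths),
        function(ch) {
          len <- cfg$chrom_lengths[[ch]]
          n <- as.integer(round(len * cfg$cpg_per_kb / 1000))
          data.table(chrom = ch, pos = sort(sample(len - 2L, n)) + 1L)
        }))))
  # region CpGs: evenly spaced with jitter
  reg_sites <- regions[, {
    base <- seq(start + 10L, end - 10L, length.out = cfg$dmr_n_cpg)
    p <- as.integer(round(base + runif(cfg$dmr_n_cpg, -5, 5)))
    .(pos = sort(unique(p)))
  }, by = .(region_id, chrom, start, end, class)]
  # background CpGs outside regions
  bg <- rbindlist(lapply(names(cfg$chrom_lengths), function(ch) {
    len <- cfg$chrom_lengths[[ch]]
    n <- as.integer(round(len * cfg$cpg_per_kb / 1000))
    data.table(chrom = ch, pos = sort(sample(len - 2L, n)) + 1L)
  }))
  occ <- reg_sites[, .(chrom, lo = start, hi = end), by = region_id]
  setkey(regions, chrom, start, end)
  gb <- GenomicRanges::GRanges(bg$chrom,
                               IRanges::IRanges(bg$pos, bg$pos))
  gr <- GenomicRanges::GRanges(regions$chrom,
                               IRanges::IRanges(regions$start + 1L,
                                                regions$end))
  inside <- unique(S4Vectors::queryHits(
    GenomicRanges::findOverlaps(gb, gr)))
  if (length(inside)) bg <- bg[-inside]
  list(regions = regions, reg_sites = reg_sites, background = bg)
}

#' Simulate sperm methylomes with planted heritable DMRs
#'
#' Generates 18 sperm samples (control/stress x F0/F1/F2 x 3 replicates).
#' Per site and sample, total coverage is Poisson and the methylated
#' count is beta-binomial around the site's group mean. Background site
#' means follow a bimodal sperm-like distribution (mass near 0 and above
#' 0.8); planted regions carry a class-dependent stress shift: the full
#' effect in F0, attenuated copies in F1/F2 for inherited classes, none
#' for `null`. Auxiliary TE/imprinted/VM-IAP regions (for the escape and
#' VM-IAP analyses) are placed alongside, a configured fraction of
#' TE/VM-IAPs flagged as reprogramming escapees and of VM-IAPs as
#' between-sample variable.
#'
#' @param config a [sim_config()].
#' @return list with `samples` (named list of record tables), `sheet`
#'   (sample metadata), `truth` (planted region table with class,
#'   direction and per-generation delta), `sites` (site table with the
#'   baseline mean) and `regions` (auxiliary region sets).
#' @export
simulate_methylomes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  lay <- .layout_genome(config)
  dmr_classes <- names(config$n_dmrs)
  truth <- lay$regions[class %in% dmr_classes]
  aux <- lay$regions[!class %in% dmr_classes]
  # baseline means
  bg <- lay$background
  hi <- runif(nrow(bg)) < 0.75
  bg[, mu := ifelse(hi, rbeta(.N, 8, 0.8), rbeta(.N, 0.8, 8))]
  rs <- copy(lay$reg_sites)
  truth[, direction := sample(c("hypo", "hyper"), .N, replace = TRUE)]
  truth[class == "null", direction := NA_character_]
  base_of <- function(cls, dir, n) {
    b <- numeric(n)
    high <- runif(n, 0.75, 0.92); low <- runif(n, 0.08, 0.25)
    b <- ifelse(is.na(dir), ifelse(runif(n) < 0.75, high, low),
                ifelse(dir == "hypo", high, low))
    b[cls %in% c("TE", "VM_IAP")] <- runif(sum(cls %in%
                                                 c("TE", "VM_IAP")),
                                           0.82, 0.95)
    b[cls == "imprinted"] <- runif(sum(cls == "imprinted"), 0.35, 0.6)
    b
  }
  reg_meta <- rbind(
    truth[, .(region_id, class, direction)],
    aux[, .(region_id, class, direction = NA_character_)])
  reg_meta[, base := base_of(class, direction, .N)]
  reg_meta[, escape := FALSE]
  esc_pool <- which(reg_meta$class %in% c("TE", "VM_IAP"))
  n_esc <- round(config$escape_fraction * length(esc_pool))
  if (n_esc > 0)
    reg_meta$escape[sample(esc_pool, n_esc)] <- TRUE
  reg_meta[, variable := FALSE]
  vm_pool <- which(reg_meta$class == "VM_IAP")
  n_var <- round(config$vmiap_variable_fraction * length(vm_pool))
  if (n_var > 0) reg_meta$variable[sample(vm_pool, n_var)] <- TRUE

  rs[, mu := reg_meta$base[match(region_id, reg_meta$region_id)]]
  sites <- rbind(bg[, .(chrom, pos, mu, region_id = NA_character_)],
                 rs[, .(chrom, pos, mu, region_id)])
  setkey(sites, chrom, pos)

  gen_mult <- c(F0 = 1, F1 = config$attenuation,
                F2 = config$attenuation^2)
  active <- list(transgenerational = c("F0", "F1", "F2"),
                 intergenerational = c("F0", "F1"),
                 F0_only = "F0", null = character())
  truth[, `:=`(delta_F0 = 0, delta_F1 = 0, delta_F2 = 0)]
  if (nrow(truth)) {
    for (g in .GENERATIONS) {
      col <- paste0("delta_", g)
      on <- vapply(truth$class, function(cl) g %in% active[[cl]],
                   logical(1L))
      sgn <- ifelse(truth$direction == "hypo", -1, 1)
      truth[, (col) := ifelse(on & !is.na(direction),
                              sgn * config$effect * gen_mult[[g]], 0)]
    }
  }

  sheet <- CJ(group = .SAMPLE_GROUPS, generation = .GENERATIONS,
              replicate = 1:3)
  sheet[, `:=`(stage = "sperm",
               sample_id = paste(generation, group, replicate,
                                 sep = "_"))]
  setcolorder(sheet, c("sample_id", "group", "generation", "stage",
                       "replicate"))

  site_reg <- match(sites$region_id, truth$region_id)
  var_reg <- reg_meta[variable == TRUE, region_id]
  samples <- list()
  for (i in seq_len(nrow(sheet))) {
    grp <- sheet$group[i]; gen <- sheet$generation[i]
    mu <- sites$mu
    if (grp == "stress") {
      dlt <- truth[[paste0("delta_", gen)]][site_reg]
      dlt[is.na(dlt)] <- 0
      mu <- .clamp01(mu + dlt)
    }
    # metastable VM-IAP epialleles: per-sample level shifts
    if (length(var_reg)) {
      shift <- setNames(rnorm(length(var_reg), 0, 0.25), var_reg)
      vs <- shift[sites$region_id]
      vs[is.na(vs)] <- 0
      mu <- .clamp01(mu + vs)
    }
    total <- rpois(nrow(sites), config$coverage)
    keep <- total > 0L
    mC <- integer(sum(keep))
    mC <- .rbetabinom(sum(keep), total[keep], mu[keep],
                      config$dispersion)
    rec <- data.table(chrom = sites$chrom[keep], pos = sites$pos[keep],
                      mC = as.integer(mC),
                      total = as.integer(total[keep]))
    setkey(rec, chrom, pos)
    samples[[sheet$sample_id[i]]] <- rec
  }
  regions_out <- merge(lay$regions, reg_meta,
                       by = c("region_id", "class"), all.x = TRUE)
  setkey(regions_out, chrom, start, end)
  list(samples = samples, sheet = sheet,
       truth = truth[, .(region_id, chrom, start, end, class,
                         direction, delta_F0, delta_F1, delta_F2)],
       sites = sites, regions = regions_out)
}

#' Simulate embryo-stage methylation profiles
#'
#' Produces one profile per (stage, group, offspring generation) for ICM,
#' PS and PGC of F1 and F2 plus one oocyte, following the two-wave
#' template: near-complete erasure at ICM (escape regions and, partially,
#' imprinted genes retain sperm levels), bimodal reestablishment at PS
#' (a per-site coin decides reestablished-high vs still-low, shared
#' across samples), deepest erasure at PGC. Heritable planted regions
#' receive a group offset of the reestablished PS level along the planted
#' direction in the stress embryos.
#'
#' @param config a [sim_config()].
#' @param meth output of [simulate_methylomes()] under the same config.
#' @return list with `samples` (named list of record tables) and `sheet`.
#' @export
simulate_embryos <- function(config, meth) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  sites <- meth$sites
  reg <- meth$regions
  esc_ids <- reg[escape == TRUE, region_id]
  imp_ids <- reg[class == "imprinted", region_id]
  herit_ids <- meth$truth[class %in% c("transgenerational",
                                       "intergenerational"), region_id]
  herit_dir <- setNames(
    ifelse(meth$truth$direction == "hypo", -1, 1),
    meth$truth$region_id)[herit_ids]
  mu <- sites$mu
  in_esc <- sites$region_id %in% esc_ids
  in_imp <- sites$region_id %in% imp_ids
  reest <- runif(nrow(sites)) < config$ps_reest_prob
  mu_icm <- mu * config$icm_retention
  mu_icm[in_esc] <- mu[in_esc]
  mu_icm[in_imp] <- mu[in_imp] * 0.85
  mu_ps0 <- ifelse(reest, mu, 0.05)
  mu_pgc <- mu * config$pgc_retention
  mu_pgc[in_imp] <- mu[in_imp] * 0.02

  sheet <- CJ(group = .SAMPLE_GROUPS, generation = c("F1", "F2"),
              stage = .EMBRYO_STAGES)
  sheet[, `:=`(replicate = 1L,
               sample_id = paste(generation, group, stage, sep = "_"))]
  oo <- data.table(group = "control", generation = NA_character_,
                   stage = "oocyte", replicate = 1L,
                   sample_id = "oocyte")
  sheet <- rbind(sheet, oo)
  setcolorder(sheet, c("sample_id", "group", "generation", "stage",
                       "replicate"))

  off <- setNames(rep(0, nrow(sites)), NULL)
  hidx <- sites$region_id %in% herit_ids
  off[hidx] <- config$ps_offset * herit_dir[sites$region_id[hidx]]

  draw <- function(mu_vec) {
    total <- rpois(length(mu_vec), config$embryo_coverage)
    keep <- total > 0L
    mC <- .rbetabinom(sum(keep), total[keep], mu_vec[keep],
                      config$dispersion)
    rec <- data.table(chrom = sites$chrom[keep], pos = sites$pos[keep],
                      mC = as.integer(mC),
                      total = as.integer(total[keep]))
    setkey(rec, chrom, pos)
    rec
  }
  samples <- list()
  for (i in seq_len(nrow(sheet))) {
    stg <- sheet$stage[i]; grp <- sheet$group[i]
    mu_vec <- switch(stg,
                     ICM = mu_icm,
                     PS = if (grp == "stress") .clamp01(mu_ps0 + off)
                          else mu_ps0,
                     PGC = mu_pgc,
                     oocyte = mu)
    samples[[sheet$sample_id[i]]] <- draw(mu_vec)
  }
  list(samples = samples, sheet = sheet)
}

.random_dna <- function(n, len)
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len[i], replace = TRUE),
          collapse = ""), character(1L))

#' Simulate an annotated sncRNA count table
#'
#' Random 18-35 nt sequences are assigned types and subclass annotations
#' (tRNA isodecoders, rRNA parents, miRNA families, piRNA clusters);
#' counts per sample are negative-binomial around a lognormal baseline
#' scaled by each sample's library size. Planted differential sequences
#' of the configured types receive a stress-group fold change in their
#' planted direction. When `meth` is supplied, a DMR sequence set is
#' also generated and a configured fraction of heritable DMR sequences
#' carries an embedded 8-10 bp exact complement of a planted
#' differential sequence.
#'
#' @param config a [sim_config()].
#' @param meth optional output of [simulate_methylomes()] (enables DMR
#'   sequence generation).
#' @return list with `tbl` (count table), `groups`, `library_sizes`,
#'   `truth` (planted differential ids and directions), and, with
#'   `meth`, `dmr_seqs` plus `embedded` (which DMR carries which
#'   sequence's complement).
#' @export
simulate_sncrna <- function(config, meth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  sc <- config$sncrna
  types <- rep(names(sc$n_per_type), sc$n_per_type)
  n <- length(types)
  subclass_of <- function(ty, i) switch(
    ty,
    miRNA = paste0("let-", 1 + i %% 30),
    tsRNA = paste0(c("mt-HisGTG", "GluTTC", "AspGTC", "GlyGCC",
                     "ValCAC")[1 + i %% 5], "-", 1 + i %% 12),
    rsRNA = paste0(c("18S", "4.5S")[1 + i %% 2], "-frag", 1 + i %% 40),
    piRNA = paste0("pi-cluster-", 1 + i %% 25),
    paste0("other-", i))
  tbl <- data.table(
    sequence = .random_dna(n, sample(18:35, n, replace = TRUE)),
    type = types)
  tbl[, subclass := vapply(seq_len(.N),
                           function(i) subclass_of(type[i], i),
                           character(1L))]
  groups <- setNames(rep(c("control", "stress"), each = 3L),
                     c(paste0("control_", 1:3), paste0("stress_", 1:3)))
  library_sizes <- setNames(round(sc$libsize * runif(6, 0.85, 1.15)),
                            names(groups))
  base_rpm <- rlnorm(n, meanlog = 3.5, sdlog = 1.2)
  # planted differential sequences, biased to abundant ones
  fold <- rep(1, n)
  planted <- data.table(snc_id = character(), type = character(),
                        direction = character())
  for (nm in names(sc$n_diff)) {
    dir <- sub("_.*$", "", nm); ty <- sub("^[a-z]+_", "", nm)
    # differential sequences are drawn from the abundant pool: the
    # screen discards rare ones anyway and replicate noise is count-
    # limited at low abundance
    cand <- which(tbl$type == ty & fold == 1 & base_rpm > 25)
    k <- min(sc$n_diff[[nm]], length(cand))
    idx <- sample(cand, k)
    fold[idx] <- if (dir == "up") sc$fold else 1 / sc$fold
    planted <- rbind(planted,
                     data.table(snc_id = sprintf("snc_%05d", idx),
                                type = ty, direction = dir))
  }
  tbl[, snc_id := sprintf("snc_%05d", .I)]
  for (s in names(groups)) {
    f <- if (groups[[s]] == "stress") fold else rep(1, n)
    mu <- base_rpm / 1e6 * library_sizes[[s]] * f
    tbl[, (s) := rnbinom(n, mu = mu, size = 1 / sc$nb_dispersion)]
  }
  setcolorder(tbl, c("snc_id", "sequence", "subclass", "type"))
  out <- list(tbl = tbl, groups = groups,
              library_sizes = library_sizes, truth = planted)
  if (!is.null(meth)) {
    dmr_truth <- meth$truth[class != "null"]
    lens <- pmax(dmr_truth$end - dmr_truth$start, 60L)
    seqs <- setNames(.random_dna(nrow(dmr_truth), lens),
                     dmr_truth$region_id)
    herit <- dmr_truth[class %in% c("transgenerational",
                                    "intergenerational"), region_id]
    emb <- data.table(region_id = character(), snc_id = character(),
                      match_len = integer())
    if (nrow(planted) && config$planted_complementarity > 0) {
      carry <- herit[runif(length(herit)) <
                       config$planted_complementarity]
      # each carrier embeds complements of several distinct
      # differential sequences: a single 8-10 bp fragment is not
      # separable from the random seed-match background
      k <- min(sc$embeds_per_dmr, nrow(planted))
      for (rid in carry) {
        pids <- planted$snc_id[sample(nrow(planted), k)]
        s <- seqs[[rid]]
        for (pid in pids) {
          src <- tbl$sequence[tbl$snc_id == pid]
          L <- sample(8:10, 1L)
          if (nchar(src) < L) next
          st <- sample(nchar(src) - L + 1L, 1L)
          frag <- .revcomp(substr(src, st, st + L - 1L))
          at <- sample(nchar(s) - L + 1L, 1L)
          substr(s, at, at + L - 1L) <- frag
          emb <- rbind(emb, data.table(region_id = rid, snc_id = pid,
                                       match_len = L))
        }
        seqs[[rid]] <- s
      }
    }
    out$dmr_seqs <- seqs
    out$embedded <- emb
  }
  out
}

#' Write simulated methylomes to disk
#'
#' Emits one coverage-format count file per sample plus the sample sheet
#' (with relative paths), in the dialects the readers consume.
#' @param sim output of [simulate_methylomes()] or [simulate_embryos()].
#' @param dir output directory (created if needed).
#' @return the sheet path, invisibly.
#' @export
write_simulated_samples <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sheet <- copy(as.data.table(sim$sheet))
  sheet[, path := file.path(dir, paste0(sample_id, ".cov"))]
  for (sid in names(sim$samples))
    write_cytosine_report(sim$samples[[sid]],
                          file.path(dir, paste0(sid, ".cov")))
  sheet_path <- file.path(dir, "samples.tsv")
  fwrite(sheet, sheet_path, sep = "\t")
  invisible(sheet_path)
}
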