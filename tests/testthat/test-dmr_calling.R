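# site tests fixture: hand-built table in the shape wald_test_sites
# returns, for exercising the merging/filtering stages in isolation
site_tests <- function(pos, delta, fdr = rep(0.001, length(pos)),
                       bc = rep(0.8, length(pos)), chrom = "chr1") {
  data.table(chrom = chrom, pos = as.integer(pos),
             beta_control = bc, beta_stress = bc + delta,
             delta_beta = delta, disp_control = 0.01,
             disp_stress = 0.01, wald = delta * 10, p = fdr, fdr = fdr,
             key = c("chrom", "pos"))
}

test_that("smoothing is a coverage-weighted window mean", {
  # an isolated site keeps its raw level
  s1 <- smooth_levels(rec_levels(1000L, 0.7, 10L))
  expect_equal(s1$smoothed, 0.7)
  # two nearby equally covered sites average to 0.5
  s2 <- smooth_levels(rec_levels(c(100L, 110L), c(0, 1), 10L))
  expect_equal(s2$smoothed, c(0.5, 0.5))
  # window is +/- span/2: site at 600 sees neither site at 0/100
  s3 <- smooth_levels(rec_levels(c(1L, 101L, 601L), c(0.9, 0.9, 0.1),
                                 10L), span_bp = 500L)
  expect_equal(s3$smoothed, c(0.9, 0.9, 0.1))
  # coverage weighting: 0.0 at 30x vs 1.0 at 10x -> pooled 0.25
  s4 <- smooth_levels(rec("chr1", c(100L, 120L), c(0L, 10L),
                          c(30L, 10L)))
  expect_equal(s4$smoothed, c(0.25, 0.25))
})

test_that("dispersion estimation recovers a planted value and shrinks", {
  set.seed(42)
  ns <- 1000L; nr <- 10L; rho <- 0.1
  tot <- matrix(rpois(ns * nr, 30), ns)
  mu <- runif(ns, 0.2, 0.8)
  a <- mu * (1 - rho) / rho; b <- (1 - mu) * (1 - rho) / rho
  p <- matrix(rbeta(ns * nr, rep(a, nr), rep(b, nr)), ns)
  mC <- matrix(rbinom(ns * nr, tot, p), ns)
  d <- estimate_dispersion(mC, tot)
  expect_lt(abs(mean(d$shrunk) - rho) / rho, 0.2)
  # no between-replicate variation => near-zero raw component
  tot0 <- matrix(100L, 50L, 4L)
  mC0 <- matrix(50L, 50L, 4L)
  d0 <- estimate_dispersion(mC0, tot0)
  expect_true(all(d0$raw < 0.02, na.rm = TRUE))
  # a wildly variable site is pulled toward the common mean
  tot2 <- matrix(50L, 2L, 4L)
  mC2 <- rbind(c(25L, 26L, 24L, 25L), c(0L, 50L, 0L, 50L))
  d2 <- estimate_dispersion(mC2, tot2)
  prior <- attr(d2, "prior")
  expect_true(d2$shrunk[2] < d2$raw[2] && d2$shrunk[2] > prior)
})

test_that("Wald test handles null identity and detects planted effects", {
  x <- rec_levels(seq(100L, 400L, by = 50L), rep(0.5, 7), 30L)
  same <- wald_test_sites(list(x, x, x), list(x, x, x))
  expect_equal(same$delta_beta, rep(0, nrow(same)))
  expect_equal(same$p, rep(1, nrow(same)))
  # planted delta 0.5 at 30x, 3v3: strong site signal
  set.seed(1)
  mk <- function(mu) rec("chr1", seq(100L, 400L, by = 50L),
                         rbinom(7, 30, mu), rep(30L, 7))
  ctrl <- replicate(3, mk(0.2), simplify = FALSE)
  strs <- replicate(3, mk(0.7), simplify = FALSE)
  tst <- wald_test_sites(ctrl, strs)
  expect_true(all(tst$p < 1e-4))
  # cross-check against a Fisher exact test on pooled window counts
  i <- 4L  # central site; window spans all 7 sites
  pool <- function(lst) colSums(t(vapply(lst, function(s)
    c(sum(s$mC), sum(s$total)), numeric(2L))))
  cp <- pool(ctrl); sp <- pool(strs)
  fp <- fisher.test(matrix(c(cp[1], cp[2] - cp[1],
                             sp[1], sp[2] - sp[1]), 2L))$p.value
  expect_lt(fp, 1e-4)
  # deep in the tail the normal reference and the exact hypergeometric
  # agree on the magnitude of the evidence, not its last digits
  expect_lt(abs(log10(tst$p[i]) / log10(fp) - 1), 0.6)
})

test_that("Wald p-values rank like Fisher exact on high-coverage sites", {
  set.seed(8)
  n <- 150L
  pos <- seq(1000L, by = 2000L, length.out = n)  # isolated sites
  muc <- runif(n, 0.2, 0.8)
  mus <- pmin(pmax(muc + runif(n, -0.3, 0.3), 0.02), 0.98)
  mk <- function(mu) rec("chr1", pos, rbinom(n, 60, mu), rep(60L, n))
  ctrl <- replicate(3, mk(muc), simplify = FALSE)
  strs <- replicate(3, mk(mus), simplify = FALSE)
  tst <- wald_test_sites(ctrl, strs)
  fis <- vapply(seq_len(n), function(i) {
    cm <- sum(vapply(ctrl, function(s) s$mC[i], numeric(1)))
    sm <- sum(vapply(strs, function(s) s$mC[i], numeric(1)))
    fisher.test(matrix(c(cm, 180 - cm, sm, 180 - sm), 2L))$p.value
  }, numeric(1))
  expect_gt(cor(rank(tst$p), rank(fis), method = "spearman"), 0.95)
})

test_that("DMC thresholds require both effect and FDR", {
  tt <- site_tests(c(100L, 200L, 300L), c(0.3, 0.3, 0.08),
                   fdr = c(0.001, 0.05, 1e-9))
  d <- call_dmcs(tt)
  expect_equal(d$pos, 100L)
})

test_that("DMC chains become DMRs only past the length and count gates", {
  # chain of 3 DMCs: too few
  t3 <- site_tests(c(100L, 140L, 180L), rep(0.3, 3))
  expect_equal(nrow(merge_dmcs_to_dmrs(call_dmcs(t3), t3)), 0L)
  # 5 DMCs spanning 40 bp: too short
  t5 <- site_tests(seq(100L, 140L, by = 10L), rep(0.3, 5))
  expect_equal(nrow(merge_dmcs_to_dmrs(call_dmcs(t5), t5)), 0L)
  # 6 same-direction DMCs over 300 bp: one DMR
  pos6 <- seq(100L, 400L, by = 60L)
  t6 <- site_tests(pos6, rep(-0.3, 6))
  d6 <- merge_dmcs_to_dmrs(call_dmcs(t6), t6)
  expect_equal(nrow(d6), 1L)
  expect_equal(d6$n_dmc, 6L)
  expect_gte(d6$n_cpg, 6L)
  expect_equal(d6$direction, "hypo")
  expect_equal(d6$start, min(pos6) - 1L)
  expect_equal(d6$end, max(pos6) + 1L)
  expect_equal(d6$area_stat, sum(t6$wald))
})

test_that("chains break on gaps, direction flips and sign reversals", {
  # gap over merge_gap_bp splits a would-be chain
  tg <- site_tests(c(seq(100L, 250L, 50L), seq(600L, 750L, 50L)),
                   rep(0.3, 8))
  expect_equal(nrow(merge_dmcs_to_dmrs(call_dmcs(tg), tg,
                                       merge_gap_bp = 100L)), 2L)
  # an intervening tested CpG of opposite sign severs the chain
  pos <- seq(100L, 500L, by = 50L)
  delta <- rep(0.3, 9); fdr <- rep(0.001, 9)
  delta[5] <- -0.05; fdr[5] <- 0.9       # non-DMC, reversed sign
  tr <- site_tests(pos, delta, fdr)
  expect_equal(nrow(merge_dmcs_to_dmrs(call_dmcs(tr), tr)), 2L)
  # same-sign intervening non-DMC does not sever
  delta[5] <- 0.05
  ts <- site_tests(pos, delta, fdr)
  expect_equal(nrow(merge_dmcs_to_dmrs(call_dmcs(ts), ts)), 1L)
})

test_that("post-filter keeps large absolute or large relative changes", {
  dm <- data.table(dmr_id = c("a", "b", "c"),
                   beta_control = c(0.05, 0.5, 0.80),
                   delta_beta = c(0.07, 0.15, -0.05))
  kept <- postfilter_dmrs(dm)
  # a: relative 1.4 -> kept; b: absolute -> kept; c: neither -> dropped
  expect_equal(kept$dmr_id, c("a", "b"))
})

test_that("annotation assigns every >=1 bp overlap, half-open", {
  dmrs <- data.table(dmr_id = c("d1", "d2", "d3"),
                     chrom = "chr1",
                     start = c(100L, 100L, 1000L),
                     end = c(200L, 200L, 1100L))
  regs <- data.table(chrom = "chr1",
                     start = c(199L, 200L, 120L, 110L),
                     end = c(300L, 300L, 180L, 190L),
                     label = c("geneA", "geneB", "outer", "inner"),
                     class = c("gene", "gene", "gene", "promoter"))
  ann <- annotate_dmrs(dmrs[1], regs[1:2])
  expect_equal(ann$label, "geneA")       # 1 bp overlap in, bookended out
  ann2 <- annotate_dmrs(dmrs[2], regs[3:4])
  expect_setequal(ann2$label, c("outer", "inner"))
  ann3 <- annotate_dmrs(dmrs[3], regs)
  expect_equal(ann3$label, "intergenic")
})

test_that("called DMRs respect their structural invariants", {
  cfg <- sim_config(seed = 21, chrom_lengths = c(chr1 = 1e6),
                    n_dmrs = c(transgenerational = 5,
                               intergenerational = 10, F0_only = 25,
                               null = 10), n_te = 0, n_imprinted = 0,
                    n_vmiap = 0)
  m <- simulate_methylomes(cfg)
  filt <- lapply(m$samples, function(s) s[total >= 5])
  ids <- function(g, gr)
    m$sheet[generation == g & group == gr, sample_id]
  res <- call_dmrs(filt[ids("F0", "control")], filt[ids("F0", "stress")])
  d <- res$dmrs
  expect_gt(nrow(d), 0L)
  expect_true(all(d$end - d$start >= 50L))
  expect_true(all(d$n_dmc >= 4L))
  expect_true(all(d$n_cpg >= d$n_dmc))
  expect_true(all(abs(d$delta_beta) <= 1))
  expect_true(all((d$delta_beta < 0) == (d$direction == "hypo")))
  # member DMCs share the region direction
  dmcs <- res$dmcs
  for (i in seq_len(nrow(d))) {
    mm <- dmcs[chrom == d$chrom[i] & pos > d$start[i] & pos <= d$end[i]]
    expect_true(all(sign(mm$delta_beta) ==
                      ifelse(d$direction[i] == "hypo", -1, 1)))
  }
})
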