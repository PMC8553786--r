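# build the inputs test_generation expects from per-replicate levels
gen_fixture <- function(ctrl, strs, generation = "F0") {
  sh <- sperm_sheet()
  dmrs <- data.table(dmr_id = "d1", chrom = "chr1", start = 0L,
                     end = 100L)
  lv <- rbindlist(lapply(1:3, function(i) rbind(
    data.table(region_id = "d1",
               sample_id = paste(generation, "control", i, sep = "_"),
               mean_level = ctrl[i], pooled_level = ctrl[i],
               n_covered = 10L),
    data.table(region_id = "d1",
               sample_id = paste(generation, "stress", i, sep = "_"),
               mean_level = strs[i], pooled_level = strs[i],
               n_covered = 10L))))
  test_generation(dmrs, lv, sh, generation)
}

test_that("generation test matches Welch t-test and the effect gates", {
  g <- gen_fixture(c(0.80, 0.82, 0.81), c(0.40, 0.42, 0.41))
  expect_equal(g$delta_beta, -0.40, tolerance = 0.02)
  tt <- t.test(c(0.40, 0.42, 0.41), c(0.80, 0.82, 0.81))
  expect_equal(g$p, tt$p.value, tolerance = 1e-8)
  expect_lt(g$p, 0.001)
  expect_true(g$significant)
  # identical replicate vectors: null identity
  g0 <- gen_fixture(c(0.5, 0.6, 0.7), c(0.5, 0.6, 0.7))
  expect_equal(g0$p, 1)
  expect_false(g0$significant)
  # tiny effect fails the thresholds regardless of p
  g2 <- gen_fixture(c(0.50, 0.51, 0.49), c(0.45, 0.46, 0.44))
  expect_equal(g2$delta_beta, -0.05, tolerance = 1e-9)
  expect_false(g2$significant)
  # a low-baseline region passes on relative change alone
  g3 <- gen_fixture(c(0.04, 0.05, 0.06), c(0.12, 0.13, 0.11))
  expect_lt(abs(g3$delta_beta), 0.1)
  expect_true(g3$significant)
})

test_that("vectorised Welch statistics agree with stats::t.test", {
  set.seed(5)
  for (i in 1:20) {
    x <- runif(3); y <- runif(3)
    g <- gen_fixture(x, y)
    tt <- t.test(y, x)
    expect_equal(g$p, tt$p.value, tolerance = 1e-10)
    expect_equal(g$t, unname(tt$statistic), tolerance = 1e-10)
  }
})

test_that("uncallable generations are flagged, not guessed", {
  sh <- sperm_sheet()
  dmrs <- data.table(dmr_id = "d1", chrom = "chr1", start = 0L,
                     end = 100L)
  lv <- data.table(region_id = "d1", sample_id = "F0_control_1",
                   mean_level = 0.5, pooled_level = 0.5,
                   n_covered = 5L)
  g <- test_generation(dmrs, lv, sh, "F0")
  expect_true(is.na(g$p))
  expect_false(g$significant)
})

test_that("inheritance labels follow the significance truth table", {
  mk <- function(s0, s1, s2) {
    rbindlist(lapply(list(c("F0", s0), c("F1", s1), c("F2", s2)),
                     function(z)
      data.table(dmr_id = "d", generation = z[1],
                 beta_control = 0.8, beta_stress = 0.5,
                 delta_beta = -0.3, t = -5, p = 0.01, fdr = 0.02,
                 significant = as.logical(z[2]))))
  }
  lab <- function(...) classify_inheritance(mk(...))$label
  expect_equal(lab(TRUE, TRUE, TRUE), "transgenerational")
  expect_equal(lab(TRUE, TRUE, FALSE), "intergenerational")
  expect_equal(lab(TRUE, FALSE, FALSE), "F0_only")
  expect_equal(lab(TRUE, FALSE, TRUE), "irregular")
  expect_equal(lab(FALSE, TRUE, TRUE), "irregular")
  # an uncallable generation always yields irregular
  g <- mk(TRUE, TRUE, TRUE)
  g[generation == "F1", `:=`(p = NA_real_, significant = NA)]
  expect_equal(classify_inheritance(g)$label, "irregular")
})

test_that("strict direction mode demotes sign-flipping inherited calls", {
  g <- rbindlist(lapply(c("F0", "F1", "F2"), function(gen)
    data.table(dmr_id = "d", generation = gen, beta_control = 0.5,
               beta_stress = ifelse(gen == "F1", 0.8, 0.2),
               delta_beta = ifelse(gen == "F1", 0.3, -0.3), t = 5,
               p = 0.01, fdr = 0.02, significant = TRUE)))
  expect_equal(classify_inheritance(g)$label, "transgenerational")
  expect_equal(classify_inheritance(g, strict_direction = TRUE)$label,
               "irregular")
})

test_that("Wilcoxon route p-values equal exact sign-pattern enumeration", {
  gm <- function(ctrl, strs) data.table(
    dmr_id = "d", generation = c("F0", "F1", "F2"),
    beta_control = ctrl, beta_stress = strs)
  # consistent negative differences: minimal one-sided p = 1/8 at n = 3
  w <- classify_inheritance_wilcoxon(gm(c(0.8, 0.7, 0.75),
                                        c(0.5, 0.45, 0.5)))
  expect_equal(w$p_trans,
               signed_rank_oracle(c(-0.3, -0.25, -0.25), "less"))
  expect_equal(w$p_trans, 0.125)
  # equal means: zero differences excluded, p = 1
  w0 <- classify_inheritance_wilcoxon(gm(c(0.5, 0.6, 0.7),
                                         c(0.5, 0.6, 0.7)))
  expect_equal(w0$p_trans, 1)
  expect_equal(w0$label, "F0_only")
  # one reversed generation: enumeration still matches
  d <- c(-0.3, 0.1, -0.2)
  w1 <- classify_inheritance_wilcoxon(gm(c(0.8, 0.7, 0.75),
                                         c(0.8, 0.7, 0.75) + d))
  expect_equal(w1$p_trans, signed_rank_oracle(d, "less"))
  # random magnitude sets across all sign patterns
  set.seed(11)
  for (i in 1:8) {
    sgn <- c(-1, 1)[1 + as.integer(intToBits(i))[1:3]]
    mags <- runif(3, 0.05, 0.4)
    d <- sgn * mags
    d[1] <- -abs(d[1])                 # F0 sets the tail to "less"
    w <- classify_inheritance_wilcoxon(gm(rep(0.7, 3), 0.7 + d))
    expect_equal(w$p_trans, signed_rank_oracle(d, "less"))
  }
})

test_that("inheritance summary reports inclusive inherited percentages", {
  calls <- data.table(label = c(
    rep("transgenerational", 118),
    rep("intergenerational", 2775 - 118),
    rep("F0_only", 24427 - 2775)))
  s <- inheritance_summary(calls)
  expect_equal(s[label == "inherited", n], 2775L)
  expect_equal(s[label == "inherited", percent], 11.36)
  expect_equal(s[label == "transgenerational", percent], 0.48)
  expect_equal(s[, sum(n) - n[label == "inherited"]], 24427L)
  s0 <- inheritance_summary(data.table(label = rep("F0_only", 10)))
  expect_equal(s0[label == "inherited", percent], 0)
})

test_that("delta_trend detects planted attenuation and not its absence", {
  mk_gt <- function(n, atten, seed) {
    set.seed(seed)
    base <- runif(n, 0.25, 0.35)
    rbindlist(lapply(0:2, function(g)
      data.table(dmr_id = sprintf("d%03d", 1:n),
                 generation = c("F0", "F1", "F2")[g + 1],
                 beta_control = 0.7,
                 beta_stress = 0.7 - base * atten^g +
                   rnorm(n, 0, 0.02),
                 delta_beta = -base * atten^g + rnorm(n, 0, 0.02),
                 t = -3, p = 0.01, fdr = 0.02, significant = TRUE)))
  }
  calls <- data.table(dmr_id = sprintf("d%03d", 1:200),
                      label = "transgenerational")
  tr <- delta_trend(calls, mk_gt(200, 0.6, 1))
  expect_true(all(diff(tr$means$mean_abs_delta) < 0))
  expect_lt(tr$p_attenuation[["F0_to_F1"]], 0.01)
  expect_lt(tr$p_attenuation[["F1_to_F2"]], 0.01)
  # no attenuation planted: non-significant in most runs
  ps <- vapply(1:10, function(s)
    delta_trend(calls, mk_gt(200, 1, s + 100))$p_attenuation[["F0_to_F1"]],
    numeric(1))
  expect_gte(mean(ps > 0.01), 0.9)
  # single DMR: means reported, test skipped
  one <- delta_trend(calls[1], mk_gt(200, 0.6, 2)[dmr_id == "d001"])
  expect_equal(nrow(one$means), 3L)
  expect_true(is.na(one$p_attenuation[["F0_to_F1"]]))
})

test_that("labels partition the DMR set", {
  set.seed(3)
  n <- 50L
  g <- CJ(dmr_id = sprintf("d%02d", 1:n), generation = c("F0", "F1", "F2"))
  g[, `:=`(beta_control = 0.7, beta_stress = 0.5, delta_beta = -0.2,
           t = -3, p = 0.01, fdr = 0.02,
           significant = sample(c(TRUE, FALSE), .N, replace = TRUE))]
  calls <- classify_inheritance(g)
  expect_equal(nrow(calls), n)
  expect_true(all(calls$label %in% c("transgenerational",
                                     "intergenerational", "F0_only",
                                     "irregular")))
  s <- inheritance_summary(calls)
  expect_equal(s[label != "inherited", sum(n)], n)
})
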