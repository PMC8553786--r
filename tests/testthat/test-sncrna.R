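snc_groups <- setNames(rep(c("control", "stress"), each = 3),
                       c(paste0("c", 1:3), paste0("s", 1:3)))

# minimal count table with explicit per-sample counts
snc_tbl <- function(counts, type = "tsRNA", subclass = "GluTTC") {
  n <- nrow(counts)
  dt <- data.table(
    sequence = vapply(seq_len(n), function(i) random_dna_str(22),
                      character(1)),
    subclass = rep_len(subclass, n), type = rep_len(type, n))
  for (j in seq_along(snc_groups)) dt[, (names(snc_groups)[j]) :=
                                        counts[, j]]
  dt
}

test_that("RPM normalisation is the per-million count ratio", {
  cnt <- matrix(c(100, 0, 5), 3, 1)
  r <- rpm_normalize(cnt, c(1e6))
  expect_equal(as.numeric(r), c(100, 0, 5))
  expect_equal(as.numeric(rpm_normalize(matrix(5), 2e6)), 2.5)
  expect_error(rpm_normalize(matrix(1), 0), "positive")
  # conservation: complete table sums to 1e6 per sample
  set.seed(1)
  m <- matrix(rpois(60, 50), 10)
  expect_equal(unname(colSums(rpm_normalize(m))), rep(1e6, 6))
})

test_that("differential screen applies abundance filters before testing", {
  set.seed(2)
  low <- matrix(c(2, 2, 2, 1, 2, 1), 1)        # sum 10: excluded
  tbl <- snc_tbl(rbind(low, matrix(c(10, 11, 12, 30, 31, 29), 1)))
  lib <- setNames(rep(1e5, 6), names(snc_groups))
  res <- differential_sequences(tbl, snc_groups, lib)
  expect_false(res$tested[1])
  expect_true(is.na(res$p[1]))
  expect_true(res$tested[2] && res$differential[2])
  expect_equal(res$direction[2], "up")
  expect_lt(res$p[2], 0.001)
  # identical vectors are never differential
  same <- snc_tbl(matrix(rep(20, 6), 1))
  r2 <- differential_sequences(same, snc_groups, lib)
  expect_equal(r2$p, 1)
  expect_false(r2$differential)
  # p passes but RPM sum fails: excluded
  tiny_lib <- setNames(rep(1e9, 6), names(snc_groups))
  r3 <- differential_sequences(
    snc_tbl(matrix(c(10, 11, 12, 30, 31, 29), 1)), snc_groups, tiny_lib)
  expect_false(r3$differential)
})

test_that("subclass aggregation pools sequence counts before testing", {
  cnt <- rbind(c(5, 6, 5, 15, 16, 14), c(6, 5, 6, 16, 15, 17))
  tbl <- snc_tbl(cnt)
  lib <- setNames(rep(1e5, 6), names(snc_groups))
  res <- differential_subclasses(tbl, snc_groups, lib)
  expect_equal(nrow(res), 1L)
  expect_equal(res$count_sum, sum(cnt))
  expect_true(res$differential)
})

test_that("composition report reproduces printed percentages", {
  d <- data.table(
    type = c(rep("tsRNA", 52), rep("miRNA", 5), rep("rsRNA", 4),
             rep("miRNA", 93), rep("tsRNA", 3), rep("rsRNA", 2)),
    direction = c(rep("up", 61), rep("down", 98)),
    differential = TRUE)
  comp <- composition_report(d)
  expect_equal(comp[direction == "up" & type == "tsRNA", percent],
               85.25)
  expect_equal(comp[direction == "down" & type == "miRNA", percent],
               94.90)
  expect_equal(comp[direction == "up", unique(total)], 61L)
  empty <- composition_report(d[direction == "up"])
  expect_true(all(is.na(empty[direction == "down", percent])))
})

test_that("planted differential sequences are recovered", {
  cfg <- sim_config(seed = 13, sncrna = list(
    n_per_type = c(miRNA = 200L, tsRNA = 300L, rsRNA = 100L,
                   piRNA = 100L),
    n_diff = c(up_tsRNA = 100L)))
  s <- simulate_sncrna(cfg)
  res <- differential_sequences(s$tbl, s$groups, s$library_sizes)
  hit <- res[differential == TRUE & direction == "up"]
  planted_seqs <- s$tbl[snc_id %in% s$truth$snc_id, sequence]
  expect_gte(sum(planted_seqs %in% hit$sequence), 90L)
})

test_that("seed matching finds and extends direct and antisense hits", {
  m <- seed_match(c(q = "ACGTACGTAC"), c(d = "TTACGTACGTTT"))
  expect_equal(m[mode == "direct", longest_match_bp], 8L)
  m2 <- seed_match(c(q = "AAAACCC"), c(d = "CCGGGTTTTCC"))
  expect_equal(m2$mode, "antisense")
  expect_equal(m2$longest_match_bp, 7L)
  # no shared 7-mer in either orientation
  m3 <- seed_match(c(q = "AAAAAAAA"), c(d = "CACACACACACAC"))
  expect_equal(nrow(m3), 0L)
  # U is treated as T; N never matches
  m4 <- seed_match(c(q = "ACGUACGUAC"), c(d = "TTACGTACGTTT"))
  expect_equal(m4[mode == "direct", longest_match_bp], 8L)
  m5 <- seed_match(c(q = "ACGTNCGTACGT"), c(d = "ACGTNCGTACGT"))
  expect_equal(m5[mode == "direct", longest_match_bp], 7L)
})

test_that("longest match equals the dynamic-programming oracle", {
  set.seed(4)
  for (i in 1:40) {
    q <- random_dna_str(30)
    d <- random_dna_str(200)
    if (i %% 3 == 0) {   # plant a shared fragment in some pairs
      frag <- substr(q, 5, 5 + sample(7:12, 1))
      at <- sample(nchar(d) - nchar(frag), 1)
      substr(d, at, at + nchar(frag) - 1) <- frag
    }
    m <- seed_match(c(q = q), c(d = d))
    lcs_dir <- lcs_oracle(q, d)
    lcs_anti <- lcs_oracle(revcomp_chr(q), d)
    got_dir <- m[mode == "direct", longest_match_bp]
    got_anti <- m[mode == "antisense", longest_match_bp]
    expect_equal(length(got_dir) == 1L, lcs_dir >= 7L)
    if (lcs_dir >= 7L) expect_equal(got_dir, lcs_dir)
    expect_equal(length(got_anti) == 1L, lcs_anti >= 7L)
    if (lcs_anti >= 7L) expect_equal(got_anti, lcs_anti)
  }
})

test_that("matching is symmetric under joint reverse complementation", {
  set.seed(6)
  for (i in 1:10) {
    q <- random_dna_str(25); d <- random_dna_str(120)
    frag <- substr(q, 3, 12)
    substr(d, 50, 59) <- if (i %% 2) frag else revcomp_chr(frag)
    a <- seed_match(c(q = q), c(d = d))
    b <- seed_match(c(q = revcomp_chr(q)), c(d = revcomp_chr(d)))
    expect_equal(a[order(mode), .(mode, longest_match_bp)],
                 b[order(mode), .(mode, longest_match_bp)])
  }
})

test_that("alignment burden separates seeded from unseeded DMRs", {
  set.seed(12)
  sncs <- setNames(vapply(1:30, function(i) random_dna_str(25),
                          character(1)), sprintf("s%02d", 1:30))
  herit <- sprintf("h%02d", 1:40); unherit <- sprintf("u%02d", 1:40)
  mk_dmr <- function(seeded) {
    s <- random_dna_str(300)
    if (seeded) {
      # several distinct embedded complements: one fragment is not
      # separable from the random seed-hit background
      for (j in sample(30, 5)) {
        frag <- revcomp_chr(substr(sncs[[j]], 8, 19))
        at <- sample(288, 1)
        substr(s, at, at + 11) <- frag
      }
    }
    s
  }
  dmrs <- c(setNames(vapply(herit, function(x) mk_dmr(TRUE),
                            character(1)), herit),
            setNames(vapply(unherit, function(x) mk_dmr(FALSE),
                            character(1)), unherit))
  m <- seed_match(sncs, dmrs)
  out <- dmr_alignment_burden(m, herit, unherit)
  expect_lt(out$p, 0.01)
  expect_gt(mean(out$burden[set == "heritable", burden]),
            mean(out$burden[set == "unheritable", burden]))
  # zero-match DMRs report burden 0
  lonely <- dmr_alignment_burden(m[0], "h01", "u01")
  expect_equal(lonely$burden$burden, c(0L, 0L))
})

test_that("identical pools on both arms give a null burden contrast", {
  set.seed(22)
  ps <- vapply(1:5, function(r) {
    sncs <- setNames(vapply(1:20, function(i) random_dna_str(25),
                            character(1)), sprintf("s%02d", 1:20))
    dmrs <- setNames(vapply(1:60, function(i) random_dna_str(300),
                            character(1)), sprintf("d%02d", 1:60))
    m <- seed_match(sncs, dmrs)
    dmr_alignment_burden(m, sprintf("d%02d", 1:30),
                         sprintf("d%02d", 31:60))$p
  }, numeric(1))
  expect_gte(mean(ps > 0.01), 0.8)
})

test_that("tsRNA targets require a perfect antisense 7-mer", {
  ts <- c(t1 = paste0(random_dna_str(10), "GGGGGGG",
                      random_dna_str(5)))
  mr <- c(m1 = paste0(random_dna_str(20), "CCCCCCC",
                      random_dna_str(20)),
          m2 = "ATATATATATATATATAT")
  hits <- tsrna_targets(ts, mr)
  expect_equal(hits, data.table(tsrna_id = "t1", mrna_id = "m1"),
               ignore_attr = TRUE)
  # oracle equivalence: revcomp 7-mer set intersection
  set.seed(31)
  for (i in 1:50) {
    t <- setNames(random_dna_str(20), "t")
    m <- setNames(random_dna_str(400), "m")
    kmers <- function(s) unique(substring(
      s, 1:(nchar(s) - 6), 7:nchar(s)))
    expected <- length(intersect(kmers(revcomp_chr(t)), kmers(m))) > 0
    expect_equal(nrow(tsrna_targets(t, m)) == 1L, expected)
  }
})

test_that("sncRNA table reader validates structure", {
  f <- tempfile(fileext = ".tsv")
  tbl <- snc_tbl(matrix(rpois(12, 10), 2))
  fwrite(tbl, f, sep = "\t")
  back <- read_sncrna_table(f)
  expect_equal(back$sequence, tbl$sequence)
  fwrite(tbl[, !"subclass"], f, sep = "\t")
  expect_error(read_sncrna_table(f), "subclass")
})
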