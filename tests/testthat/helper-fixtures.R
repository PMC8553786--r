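library(data.table)

# record table constructor
rec <- function(chrom, pos, mC, total) {
  dt <- data.table(chrom = chrom, pos = as.integer(pos),
                   mC = as.integer(mC), total = as.integer(total))
  setkey(dt, chrom, pos)
  dt
}

# uniform-coverage record table with exact levels (level = mC/total)
rec_levels <- function(pos, levels, coverage = 10L, chrom = "chr1") {
  rec(chrom, pos, round(levels * coverage), rep(coverage, length(pos)))
}

# random record table for round-trip tests
random_records <- function(n = 200L, seed = 1L) {
  set.seed(seed)
  pos <- sort(sample(1e6L, n))
  total <- rpois(n, 20) + 1L
  rec(sample(c("chr1", "chr2"), n, replace = TRUE) |> sort(),
      pos, rbinom(n, total, runif(n)), total)
}

# write a cytosine-report (CX dialect) fixture
write_cx_fixture <- function(lines) {
  f <- tempfile(fileext = ".txt")
  writeLines(lines, f)
  f
}

# sperm sample sheet for 3v3 x 3 generations
sperm_sheet <- function() {
  sh <- CJ(group = c("control", "stress"), generation = c("F0", "F1", "F2"),
           replicate = 1:3)
  sh[, `:=`(stage = "sperm",
            sample_id = paste(generation, group, replicate, sep = "_"))]
  sh
}

# replicate region-level table for one region set from a named list of
# per-sample level vectors (names = sample ids, aligned with dmr ids)
levels_table <- function(dmr_ids, sample_levels) {
  rbindlist(lapply(names(sample_levels), function(sid)
    data.table(region_id = dmr_ids, sample_id = sid,
               mean_level = sample_levels[[sid]],
               pooled_level = sample_levels[[sid]],
               n_covered = 10L)))
}

# independent dynamic-programming longest-common-substring oracle
lcs_oracle <- function(a, b) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  best <- 0L
  prev <- integer(length(b))
  for (i in seq_along(a)) {
    cur <- integer(length(b))
    for (j in seq_along(b)) {
      if (a[i] == b[j] && a[i] != "N") {
        cur[j] <- if (j == 1L) 1L else prev[j - 1L] + 1L
        if (cur[j] > best) best <- cur[j]
      }
    }
    prev <- cur
  }
  best
}

revcomp_chr <- function(x)
  paste(rev(strsplit(chartr("ACGTU", "TGCAA", toupper(x)), "")[[1]]),
        collapse = "")

random_dna_str <- function(len)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")

# two-sided Fisher p by direct hypergeometric enumeration (oracle)
fisher_oracle <- function(a, b, c_, d) {
  m <- a + b; n <- c_ + d; k <- a + c_
  lo <- max(0L, k - n); hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n, k)
  p0 <- dhyper(a, m, n, k)
  sum(probs[probs <= p0 * (1 + 1e-7)])
}

# exact one-sided signed-rank p by enumeration over all sign patterns
signed_rank_oracle <- function(diffs, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  diffs <- diffs[diffs != 0]
  n <- length(diffs)
  if (n == 0L) return(1)
  r <- rank(abs(diffs))
  w_obs <- sum(r[diffs > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.numeric(signs %*% r)
  if (alternative == "greater") mean(w_all >= w_obs)
  else mean(w_all <= w_obs)
}
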