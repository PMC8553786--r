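# Small non-coding RNA analysis: RPM normalisation, differential
# enrichment at subclass and sequence resolution, composition summaries,
# seed-window alignment of differential sequences to DMR sequences and
# 7-mer antisense target matching.

.SNC_TYPES <- c("miRNA", "tsRNA", "rsRNA", "piRNA", "other")

#' Reads-per-million normalisation
#'
#' `rpm[i, j] = 1e6 * counts[i, j] / library_size[j]`.
#'
#' @param counts count matrix (sequences/subclasses x samples).
#' @param library_sizes per-sample totals; defaults to the column sums
#'   (exact when the table is library-complete).
#' @return RPM matrix of the same shape.
#' @export
rpm_normalize <- function(counts, library_sizes = NULL) {
  counts <- as.matrix(counts)
  if (is.null(library_sizes)) library_sizes <- colSums(counts)
  if (any(library_sizes <= 0)) stop("library sizes must be positive")
  if (length(library_sizes) != ncol(counts))
    stop("one library size per sample required")
  sweep(counts, 2L, library_sizes, `/`) * 1e6
}

# shared differential machinery; tbl must have a count column per sample
.differential <- function(tbl, groups, library_sizes, unit_cols,
                          min_count_sum, min_rpm_sum, p_max, var_equal,
                          adjust) {
  tbl <- as.data.table(tbl)
  samples <- names(groups)
  if (!all(samples %in% names(tbl)))
    stop("count columns missing for samples: ",
         paste(setdiff(samples, names(tbl)), collapse = ", "))
  agg <- tbl[, lapply(.SD, sum), by = unit_cols, .SDcols = samples]
  counts <- as.matrix(agg[, ..samples])
  rpm <- rpm_normalize(counts, library_sizes[samples])
  keep <- rowSums(counts) > min_count_sum & rowSums(rpm) > min_rpm_sum
  res <- agg[, ..unit_cols]
  res[, `:=`(count_sum = rowSums(counts), rpm_sum = rowSums(rpm),
             tested = keep)]
  ctrl <- samples[groups == "control"]; strs <- samples[groups == "stress"]
  mx <- rpm[, ctrl, drop = FALSE]; my <- rpm[, strs, drop = FALSE]
  if (var_equal) {
    n1 <- ncol(mx); n2 <- ncol(my)
    m1 <- rowMeans(mx); m2 <- rowMeans(my)
    sp <- ((n1 - 1) * apply(mx, 1, stats::var) +
           (n2 - 1) * apply(my, 1, stats::var)) / (n1 + n2 - 2)
    se <- sqrt(pmax(sp, 1e-16) * (1 / n1 + 1 / n2))
    tt <- (m2 - m1) / se
    pv <- 2 * pt(-abs(tt), n1 + n2 - 2)
    pv[sp <= 1e-16 & abs(m2 - m1) < 1e-12] <- 1
    w <- list(t = tt, p = pv, mean_x = m1, mean_y = m2)
  } else {
    w <- .welch_rows(mx, my)
  }
  res[, `:=`(mean_rpm_control = w$mean_x, mean_rpm_stress = w$mean_y,
             t = w$t, p = w$p)]
  res[!keep, p := NA_real_]
  res[, p_adj := if (adjust == "none") p else
    p.adjust(p, method = adjust)]
  res[, differential := tested & !is.na(p_adj) & p_adj < p_max]
  res[, direction := fifelse(!differential, NA_character_,
                             fifelse(mean_rpm_stress > mean_rpm_control,
                                     "up", "down"))]
  res[]
}

#' Differential sncRNA subclasses
#'
#' Aggregates counts by annotation subclass, then applies the abundance
#' screen (sum of counts over all six samples above `min_count_sum` and
#' sum of RPM above `min_rpm_sum`) and a two-sample t-test on RPM (3 v 3;
#' pooled-variance Student by default, Welch with
#' `var_equal = FALSE`; at three replicates per arm the pooled test
#' holds the nominal 5% rate where Welch is conservative). A subclass is
#' differential iff tested and `p < p_max` (no multiplicity correction
#' by default, matching the field's raw-p convention; set
#' `adjust = "BH"` to correct). Direction is the sign of the
#' stress-minus-control mean RPM.
#'
#' @param tbl `data.table` with `subclass`, `type` and one count column
#'   per sample.
#' @param groups named character vector mapping sample column name to
#'   `"control"`/`"stress"`.
#' @param library_sizes named per-sample library sizes (default: column
#'   sums of the table).
#' @param min_count_sum,min_rpm_sum abundance screen (defaults 15 and 1).
#' @param p_max significance threshold (default 0.05).
#' @param var_equal pooled-variance (Student) t-test; `FALSE` for Welch.
#' @param adjust p-value adjustment method (default `"none"`).
#' @return per-subclass table with test results, `differential` and
#'   `direction`.
#' @export
differential_subclasses <- function(tbl, groups, library_sizes = NULL,
                                    min_count_sum = 15,
                                    min_rpm_sum = 1, p_max = 0.05,
                                    var_equal = TRUE,
                                    adjust = "none") {
  if (is.null(library_sizes)) {
    samples <- names(groups)
    library_sizes <- colSums(as.matrix(as.data.table(tbl)[, ..samples]))
  }
  .differential(tbl, groups, library_sizes, c("subclass", "type"),
                min_count_sum, min_rpm_sum, p_max, var_equal, adjust)
}

#' Differential sncRNA sequences
#'
#' Same screen and test as [differential_subclasses()] applied per unique
#' sequence.
#'
#' @inheritParams differential_subclasses
#' @param tbl table with `sequence`, `subclass`, `type` and count
#'   columns.
#' @return per-sequence table with test results.
#' @export
differential_sequences <- function(tbl, groups, library_sizes = NULL,
                                   min_count_sum = 15, min_rpm_sum = 1,
                                   p_max = 0.05, var_equal = TRUE,
                                   adjust = "none") {
  if (is.null(library_sizes)) {
    samples <- names(groups)
    library_sizes <- colSums(as.matrix(as.data.table(tbl)[, ..samples]))
  }
  .differential(tbl, groups, library_sizes,
                c("sequence", "subclass", "type"),
                min_count_sum, min_rpm_sum, p_max, var_equal, adjust)
}

#' Type composition of a differential set
#'
#' Per direction, the count of differential units per sncRNA type and its
#' percentage of the direction's total (two decimals). Empty directions
#' yield `NA` percentages.
#'
#' @param diff differential table (rows with `differential == TRUE` are
#'   used) carrying `type` and `direction`.
#' @return `data.table(direction, type, n, total, percent)`.
#' @export
composition_report <- function(diff) {
  d <- as.data.table(diff)
  if ("differential" %in% names(d)) d <- d[differential == TRUE]
  out <- CJ(direction = c("up", "down"), type = .SNC_TYPES)
  cnt <- d[, .N, by = .(direction, type)]
  tot <- d[, .(total = .N), by = direction]
  out[, n := cnt$N[match(paste(direction, type),
                         paste(cnt$direction, cnt$type))]]
  out[is.na(n), n := 0L]
  out[, total := tot$total[match(direction, tot$direction)]]
  out[is.na(total), total := 0L]
  out[, percent := fifelse(total > 0, round(100 * n / total, 2),
                           NA_real_)]
  out[]
}

.revcomp <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(
    chartr("U", "T", toupper(x)))))

# k-mer table of one sequence: kmer + start position; kmers containing N
# are dropped (ambiguous bases never match)
.kmer_table <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(data.table(kmer = character(), ipos = integer()))
  starts <- seq_len(n - k + 1L)
  km <- substring(seq, starts, starts + k - 1L)
  ok <- !grepl("N", km, fixed = TRUE)
  data.table(kmer = km[ok], ipos = starts[ok])
}

# longest run of exact matches between query and subject along one
# diagonal (offset = subject_pos - query_pos); raw-byte comparison with N
# pre-mapped to distinct non-matching bytes
.diag_longest <- function(qraw, sraw, off) {
  i0 <- max(1L, 1L - off); i1 <- min(length(qraw), length(sraw) - off)
  if (i1 < i0) return(0L)
  eq <- qraw[i0:i1] == sraw[(i0:i1) + off]
  r <- rle(eq)
  if (!any(r$values)) return(0L)
  max(r$lengths[r$values])
}

#' Seed-window alignment of sncRNA sequences to DMR sequences
#'
#' Every `seed`-length window of an sncRNA sequence is searched in every
#' DMR sequence directly, and every window of its reverse complement is
#' searched for antisense pairing; each hit is extended maximally in both
#' directions and, per (sncRNA, DMR, mode), the longest ungapped exact
#' alignment is recorded. Pairs sharing no seed-length window in a mode
#' are absent from the result. `U` is mapped to `T` and ambiguous `N`
#' bases never match.
#'
#' @param snc_seqs named character vector of sncRNA sequences.
#' @param dmr_seqs named character vector of DMR sequences.
#' @param seed seed window length (default 7).
#' @return `data.table(snc_id, dmr_id, mode, longest_match_bp)` with
#'   `mode` in `direct`/`antisense` and `longest_match_bp >= seed`.
#' @export
seed_match <- function(snc_seqs, dmr_seqs, seed = 7L) {
  stopifnot(!is.null(names(snc_seqs)), !is.null(names(dmr_seqs)))
  seed <- as.integer(seed)
  clean <- function(x) chartr("U", "T", toupper(x))
  snc <- clean(snc_seqs); dmr <- clean(dmr_seqs)
  # subject index over all DMR sequences
  idx <- rbindlist(lapply(names(dmr), function(id) {
    kt <- .kmer_table(dmr[[id]], seed)
    if (nrow(kt)) kt[, dmr_id := id]
    kt
  }), fill = TRUE)
  if (nrow(idx) == 0L)
    return(data.table(snc_id = character(), dmr_id = character(),
                      mode = character(), longest_match_bp = integer()))
  setnames(idx, "ipos", "jpos")
  setkey(idx, kmer)
  raw_of <- function(s, nbyte) {
    r <- charToRaw(s)
    r[r == charToRaw("N")] <- as.raw(nbyte)
    r
  }
  dmr_raw <- lapply(dmr, raw_of, nbyte = 2L)
  out <- list()
  for (sid in names(snc)) {
    for (md in c("direct", "antisense")) {
      q <- if (md == "direct") snc[[sid]] else .revcomp(snc[[sid]])
      kt <- .kmer_table(q, seed)
      if (nrow(kt) == 0L) next
      hits <- idx[kt, on = "kmer", nomatch = NULL]
      if (nrow(hits) == 0L) next
      hits[, diag_off := jpos - ipos]
      diags <- unique(hits[, .(dmr_id, diag_off)])
      qraw <- raw_of(q, 1L)
      best <- diags[, .(len = max(vapply(diag_off, function(o)
        .diag_longest(qraw, dmr_raw[[dmr_id[1L]]], o), integer(1L)))),
        by = dmr_id]
      best <- best[len >= seed]
      if (nrow(best))
        out[[length(out) + 1L]] <- data.table(
          snc_id = sid, dmr_id = best$dmr_id, mode = md,
          longest_match_bp = best$len)
    }
  }
  if (!length(out))
    return(data.table(snc_id = character(), dmr_id = character(),
                      mode = character(), longest_match_bp = integer()))
  res <- rbindlist(out)
  setkey(res, snc_id, dmr_id, mode)
  res[]
}

#' Aligned-sequence burden of DMRs
#'
#' Counts, per DMR, the distinct differential sncRNA sequences with at
#' least one seed match (either mode), zero-filling DMRs without hits,
#' and compares the burden distributions of the heritable and
#' un-heritable sets with a Mann-Whitney (Wilcoxon rank-sum) test.
#'
#' @param matches seed-match table from [seed_match()].
#' @param heritable_ids,unheritable_ids DMR id vectors for the two arms.
#' @param snc_ids optional restriction to a set of sncRNA ids (e.g. the
#'   differential sequences).
#' @param alternative test alternative (default `"two.sided"`).
#' @return list with `burden` (`data.table(dmr_id, set, burden)`), `p`
#'   and the rank-sum `statistic`.
#' @export
dmr_alignment_burden <- function(matches, heritable_ids,
                                 unheritable_ids, snc_ids = NULL,
                                 alternative = "two.sided") {
  m <- as.data.table(matches)
  if (!is.null(snc_ids)) m <- m[snc_id %in% snc_ids]
  per <- m[, .(burden = uniqueN(snc_id)), by = dmr_id]
  burden_of <- function(ids, setname) {
    b <- per$burden[match(ids, per$dmr_id)]
    b[is.na(b)] <- 0L
    data.table(dmr_id = ids, set = setname, burden = b)
  }
  burden <- rbind(burden_of(heritable_ids, "heritable"),
                  burden_of(unheritable_ids, "unheritable"))
  h <- burden[set == "heritable", burden]
  u <- burden[set == "unheritable", burden]
  wt <- suppressWarnings(wilcox.test(h, u, alternative = alternative))
  list(burden = burden, p = wt$p.value, statistic = unname(wt$statistic))
}

#' Antisense 7-mer target pairs for tsRNAs
#'
#' Reports a (tsRNA, mRNA) pair iff some `k`-mer of the tsRNA's reverse
#' complement occurs exactly in the mRNA sequence (perfect antisense
#' seed match).
#'
#' @param tsrna_seqs named character vector of tsRNA sequences.
#' @param mrna_seqs named character vector of mRNA (3'UTR or transcript)
#'   sequences.
#' @param k match length (default 7).
#' @return `data.table(tsrna_id, mrna_id)` of unique pairs.
#' @export
tsrna_targets <- function(tsrna_seqs, mrna_seqs, k = 7L) {
  stopifnot(!is.null(names(tsrna_seqs)), !is.null(names(mrna_seqs)))
  k <- as.integer(k)
  midx <- rbindlist(lapply(names(mrna_seqs), function(id) {
    kt <- unique(.kmer_table(chartr("U", "T", toupper(mrna_seqs[[id]])),
                             k)[, .(kmer)])
    if (nrow(kt)) kt[, mrna_id := id]
    kt
  }), fill = TRUE)
  if (nrow(midx) == 0L)
    return(data.table(tsrna_id = character(), mrna_id = character()))
  setkey(midx, kmer)
  out <- lapply(names(tsrna_seqs), function(id) {
    kt <- unique(.kmer_table(.revcomp(tsrna_seqs[[id]]), k)[, .(kmer)])
    if (nrow(kt) == 0L) return(NULL)
    hits <- midx[kt, on = "kmer", nomatch = NULL]
    if (nrow(hits) == 0L) return(NULL)
    data.table(tsrna_id = id, mrna_id = unique(hits$mrna_id))
  })
  res <- rbindlist(out[!vapply(out, is.null, logical(1L))])
  if (nrow(res) == 0L)
    return(data.table(tsrna_id = character(), mrna_id = character()))
  setkey(res, tsrna_id, mrna_id)
  res[]
}

#' Read an sncRNA count table
#'
#' TSV with header: `sequence subclass type` followed by one count column
#' per sample.
#' @param path table path.
#' @return `data.table`.
#' @export
read_sncrna_table <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE)
  need <- c("sequence", "subclass", "type")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("sncRNA table lacks columns: ", paste(miss, collapse = ", "))
  cnt <- setdiff(names(dt), need)
  for (cc in cnt) if (any(dt[[cc]] < 0))
    stop("negative count in column ", cc)
  dt
}
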