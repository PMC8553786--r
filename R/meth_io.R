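#' @import data.table
#' @importFrom stats p.adjust pnorm pt rbeta rbinom rnbinom rnorm rpois runif
#'   sd fisher.test wilcox.test rlnorm setNames quantile
#' @importFrom utils count.fields head capture.output modifyList
NULL

# silence R CMD check notes for data.table NSE column names
utils::globalVariables(c(
  ".", ".N", ".SD", "chrom", "pos", "mC", "total", "umC", "strand", "context",
  "level", "smoothed", "delta_beta", "fdr", "dmc", "direction", "dmr_id",
  "region_id", "label", "class", "start", "end", "generation", "stage",
  "group", "replicate", "sample_id", "beta_control", "beta_stress",
  "significant", "category", "pattern", "n_covered", "pooled_level",
  "mean_level", "subclass", "type", "sequence", "snc_id", "mode",
  "longest_match_bp", "kmer", "ipos", "jpos", "diag_off", "p", "wald",
  "differential", "rpm_sum", "count_sum", "n_cpg", "n_dmc", "area_stat",
  "score", "name", "i.label", "i.class", "escape", "variable", "mu",
  "delta_F0", "delta_F1", "delta_F2", "set", "chain", "dir_sign",
  "p_trans", "p_inter", "fdr_trans", "fdr_inter", "delta_trans",
  "delta_inter", "bc_trans", "bc_inter", "method", "percent", "t",
  "sperm_beta", "embryo_beta", "maintained", "erased", "state", "ICM",
  "PS", "PGC", "frac_maintained", "frac_erased", "frac_intermediate",
  "sperm_sd", "sperm", "icm", "ps", "pgc", "tested", "p_adj",
  "mean_rpm_control", "mean_rpm_stress", "slot_i", "path", "len",
  "control", "stress", "burden", "intermediate", "n_regions",
  "n_samples", "..samples", "..need", "..unit_cols", "base", "bb", "dmr_direction",
  "rho", "w_mC", "w_total", "w_bb", "smoothed"
))

#' Region class vocabulary
#'
#' Region classes understood by the BED reader and the annotation/escape
#' analyses. In BED6 region files the `score` column carries the 1-based
#' index into this vector.
#' @export
REGION_CLASSES <- c(
  "gene", "promoter", "imprinted_maternal", "imprinted_paternal",
  "LTR", "LINE", "SINE", "satellite", "pseudogene", "DNA_transposon",
  "VM_IAP", "DMR"
)

.SAMPLE_GROUPS <- c("control", "stress")
.GENERATIONS <- c("F0", "F1", "F2")
.STAGES <- c("sperm", "oocyte", "ICM", "PS", "PGC")

.validate_records <- function(x, what = "records") {
  stopifnot(is.data.frame(x))
  miss <- setdiff(c("chrom", "pos", "mC", "total"), names(x))
  if (length(miss))
    stop(what, " lack required columns: ", paste(miss, collapse = ", "))
  if (any(x$pos < 1L)) stop(what, ": positions must be >= 1")
  if (any(x$mC < 0L) || any(x$total < 0L))
    stop(what, ": counts must be non-negative")
  if (any(x$mC > x$total))
    stop(what, ": methylated count exceeds total at ",
         sum(x$mC > x$total), " site(s)")
  invisible(x)
}

#' Read a per-CpG methylation count file
#'
#' Reads either a Bismark-style CX/cytosine report
#' (`chrom pos strand count_methylated count_unmethylated context
#' trinucleotide`, CpG rows selected by `context == "CG"`) or a Bismark
#' coverage-format file (`chrom start end pct count_meth count_unmeth`,
#' positions 1-based). Cytosine-report strands of a symmetric CpG are, by
#' default, collapsed onto the plus-strand C (the minus-strand C at
#' position p+1 is added to the unit at p) before the coverage filter is
#' applied, so that a CpG dinucleotide is one observation.
#'
#' Sites whose collapsed total coverage is below `min_coverage` are
#' dropped, not zero-filled: absence of a record means absence of data.
#'
#' @param path file path of a tab-separated table (no header).
#' @param min_coverage minimum total read count for a site to be kept
#'   (default 5, the conventional fivefold rule).
#' @param format `"auto"` detects by column count (7 = cytosine report,
#'   6 = coverage).
#' @param collapse_strands collapse the two strands of a CpG before
#'   filtering (cytosine-report input only).
#' @return a `data.table` with columns `chrom`, `pos` (1-based position of
#'   the plus-strand C), `mC`, `total`, sorted and unique on
#'   `(chrom, pos)`.
#' @export
read_cytosine_report <- function(path, min_coverage = 5L,
                                 format = c("auto", "cytosine", "coverage"),
                                 collapse_strands = TRUE) {
  format <- match.arg(format)
  nf <- utils::count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (length(nf) == 0L || is.null(nf))
    return(data.table(chrom = character(), pos = integer(),
                      mC = integer(), total = integer()))
  expected <- if (format == "cytosine") 7L else if (format == "coverage") 6L
    else nf[1L]
  if (format == "auto" && !expected %in% c(6L, 7L))
    stop("cannot auto-detect format of ", path, ": line 1 has ",
         expected, " fields (expected 6 or 7)")
  bad <- which(nf != expected)
  if (length(bad))
    stop("malformed line ", bad[1L], " in ", path, ": ", nf[bad[1L]],
         " fields, expected ", expected)
  dt <- fread(path, sep = "\t", header = FALSE, quote = "",
              colClasses = list(character = 1L))
  if (expected == 7L) {
    setnames(dt, c("chrom", "pos", "strand", "mC", "umC", "context", "tri"))
    if (!all(dt$strand %in% c("+", "-")))
      stop("invalid strand value in ", path)
    dt <- dt[context == "CG"]
    dt[, total := mC + umC]
    if (collapse_strands) dt[strand == "-", pos := pos - 1L]
    dt <- dt[, .(mC = sum(mC), total = sum(total)), by = .(chrom, pos)]
  } else {
    setnames(dt, c("chrom", "pos", "end", "pct", "mC", "umC"))
    dt[, total := mC + umC]
    dt <- dt[, .(mC = sum(mC), total = sum(total)), by = .(chrom, pos)]
  }
  dt[, `:=`(pos = as.integer(pos), mC = as.integer(mC),
            total = as.integer(total))]
  .validate_records(dt, path)
  dt <- dt[total >= min_coverage]
  setkey(dt, chrom, pos)
  dt[]
}

#' Write per-CpG counts
#'
#' Writes records in Bismark coverage dialect (1-based position repeated as
#' start and end). `read_cytosine_report(path, min_coverage = 1)` on the
#' output reproduces the input exactly.
#'
#' @param records a record table as returned by [read_cytosine_report()].
#' @param path output file path.
#' @export
write_cytosine_report <- function(records, path) {
  .validate_records(records)
  out <- data.table(
    chrom = records$chrom, pos = records$pos, end = records$pos,
    pct = ifelse(records$total > 0, 100 * records$mC / records$total, 0),
    mC = records$mC, umC = records$total - records$mC
  )
  fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Methylation level of a site
#'
#' The level is `mC / total`, i.e. methylated reads over all reads covering
#' the site. Undefined for uncovered sites: callers must filter first.
#'
#' @param mC methylated read count(s).
#' @param total total read count(s), all `>= 1`.
#' @return numeric vector in `[0, 1]`.
#' @export
compute_beta <- function(mC, total) {
  if (any(total == 0))
    stop("methylation level undefined at zero coverage; filter sites first")
  if (any(mC > total) || any(mC < 0)) stop("require 0 <= mC <= total")
  mC / total
}

#' Summarize methylation over a genomic interval
#'
#' Intervals are 0-based half-open; a site belongs to the region iff its
#' 1-based C position `p` satisfies `start < p <= end`.
#'
#' @param records one sample's record table.
#' @param chrom chromosome name.
#' @param start,end 0-based half-open interval.
#' @return list with `mean_level` (unweighted mean of per-site levels),
#'   `pooled_level` (sum mC / sum total) and `n_covered`; levels are `NA`
#'   when `n_covered == 0`.
#' @export
summarize_region <- function(records, chrom, start, end) {
  stopifnot(start < end)
  ch <- chrom
  sub <- records[chrom == ch & pos > start & pos <= end]
  if (nrow(sub) == 0L)
    return(list(mean_level = NA_real_, pooled_level = NA_real_,
                n_covered = 0L))
  list(mean_level = mean(sub$mC / sub$total),
       pooled_level = sum(sub$mC) / sum(sub$total),
       n_covered = nrow(sub))
}

# vectorised variant: pooled level of each region in each sample;
# regions need columns region_id, chrom, start, end (0-based half-open)
.region_levels <- function(records, regions, min_coverage = 1L) {
  rec <- records[total >= min_coverage]
  if (nrow(rec) == 0L)
    return(data.table(region_id = character(), mean_level = numeric(),
                      pooled_level = numeric(), n_covered = integer()))
  sites <- GenomicRanges::GRanges(rec$chrom,
                                  IRanges::IRanges(rec$pos, rec$pos))
  regs <- GenomicRanges::GRanges(regions$chrom,
                                 IRanges::IRanges(regions$start + 1L,
                                                  regions$end))
  ov <- GenomicRanges::findOverlaps(sites, regs)
  if (length(ov) == 0L)
    return(data.table(region_id = character(), mean_level = numeric(),
                      pooled_level = numeric(), n_covered = integer()))
  hit <- data.table(region_id = regions$region_id[S4Vectors::subjectHits(ov)],
                    mC = rec$mC[S4Vectors::queryHits(ov)],
                    total = rec$total[S4Vectors::queryHits(ov)])
  hit[, .(mean_level = mean(mC / total),
          pooled_level = sum(mC) / sum(total),
          n_covered = .N), by = region_id]
}

#' Per-sample region methylation levels
#'
#' Pooled-count methylation level of every region in every sample, from
#' sites meeting the coverage threshold. Regions with no covered site in a
#' sample are absent from the result (missing data, never imputed).
#'
#' @param samples named list of record tables (names = sample ids).
#' @param regions `data.table` with `region_id`, `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param min_coverage per-site coverage threshold (default 5).
#' @return `data.table(region_id, sample_id, mean_level, pooled_level,
#'   n_covered)`.
#' @export
region_levels_by_sample <- function(samples, regions, min_coverage = 5L) {
  stopifnot(!is.null(names(samples)))
  out <- lapply(names(samples), function(sid) {
    lv <- .region_levels(samples[[sid]], regions, min_coverage)
    if (nrow(lv)) lv[, sample_id := sid]
    lv
  })
  rbindlist(out, fill = TRUE)
}

#' Read a sample sheet
#'
#' Tab-separated with header columns
#' `sample_id group generation stage replicate path` (`path` optional,
#' `generation` may be `NA` for the oocyte). Enforces enum values and
#' uniqueness of `(group, generation, stage, replicate)`.
#'
#' @param path sample sheet path.
#' @return a `data.table`.
#' @export
read_sample_sheet <- function(path) {
  sh <- fread(path, sep = "\t", header = TRUE, colClasses = list(
    character = c("sample_id", "group", "generation", "stage")))
  need <- c("sample_id", "group", "generation", "stage", "replicate")
  miss <- setdiff(need, names(sh))
  if (length(miss))
    stop("sample sheet lacks columns: ", paste(miss, collapse = ", "))
  sh[generation == "", generation := NA_character_]
  if (!all(sh$group %in% .SAMPLE_GROUPS))
    stop("group must be one of: ", paste(.SAMPLE_GROUPS, collapse = ", "))
  if (!all(is.na(sh$generation) | sh$generation %in% .GENERATIONS))
    stop("generation must be F0/F1/F2 or NA")
  if (!all(sh$stage %in% .STAGES))
    stop("stage must be one of: ", paste(.STAGES, collapse = ", "))
  if (any(sh$stage == "sperm" & is.na(sh$generation)))
    stop("sperm samples must carry a generation")
  if (anyDuplicated(sh[, .(group, generation, stage, replicate)]))
    stop("duplicate (group, generation, stage, replicate) in sample sheet")
  if (anyDuplicated(sh$sample_id)) stop("duplicate sample_id")
  sh
}

#' Read a BED6 region set
#'
#' `chrom start end name score strand`; the `name` field is the region
#' label and `score` is the 1-based index into [REGION_CLASSES].
#'
#' @param path BED file path.
#' @param merge merge overlapping regions of the same class into single
#'   non-overlapping regions (labels of merged members joined with `,`).
#' @return `data.table(chrom, start, end, label, class, strand)`, 0-based
#'   half-open coordinates.
#' @export
read_region_bed <- function(path, merge = FALSE) {
  dt <- fread(path, sep = "\t", header = FALSE,
              col.names = c("chrom", "start", "end", "name", "score",
                            "strand"),
              colClasses = list(character = 1L))
  if (any(dt$start >= dt$end)) stop("BED regions require start < end")
  if (!all(dt$score %in% seq_along(REGION_CLASSES)))
    stop("BED score must index REGION_CLASSES (1..",
         length(REGION_CLASSES), ")")
  out <- dt[, .(chrom, start, end, label = name,
                class = REGION_CLASSES[score], strand)]
  if (merge) out <- merge_regions(out)
  setkey(out, chrom, start, end)
  out[]
}

#' Merge overlapping same-class regions
#'
#' Overlapping (or bookended) regions of the same class are merged into a
#' single region whose label joins the member labels; regions of different
#' classes never merge.
#'
#' @param regions region table as from [read_region_bed()].
#' @return merged region table.
#' @export
merge_regions <- function(regions) {
  out <- lapply(split(regions, by = "class"), function(sub) {
    gr <- GenomicRanges::GRanges(sub$chrom,
                                 IRanges::IRanges(sub$start + 1L, sub$end))
    red <- GenomicRanges::reduce(gr)
    ov <- GenomicRanges::findOverlaps(gr, red)
    lab <- tapply(sub$label[S4Vectors::queryHits(ov)],
                  S4Vectors::subjectHits(ov),
                  function(l) paste(unique(l), collapse = ","))
    data.table(chrom = as.character(GenomicRanges::seqnames(red)),
               start = GenomicRanges::start(red) - 1L,
               end = GenomicRanges::end(red),
               label = as.character(lab[as.character(seq_along(red))]),
               class = sub$class[1L], strand = "*")
  })
  res <- rbindlist(out)
  setkey(res, chrom, start, end)
  res[]
}

#' Write a BED6 region set
#' @param regions region table (`chrom,start,end,label,class`, optional
#'   `strand`).
#' @param path output path.
#' @export
write_region_bed <- function(regions, path) {
  sc <- match(regions$class, REGION_CLASSES)
  if (anyNA(sc)) stop("unknown region class")
  strand <- if ("strand" %in% names(regions)) regions$strand else "*"
  out <- data.table(regions$chrom, regions$start, regions$end,
                    regions$label, sc, strand)
  fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read sequences from FASTA
#' @param path FASTA path.
#' @return named character vector of uppercase DNA sequences (U mapped to
#'   T).
#' @export
read_fasta_seqs <- function(path) {
  x <- Biostrings::readBStringSet(path)
  s <- toupper(as.character(x))
  s <- chartr("U", "T", s)
  names(s) <- sub("\\s.*$", "", names(x))
  s
}

#' Write sequences to FASTA
#' @param seqs named character vector.
#' @param path output path.
#' @export
write_fasta_seqs <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
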