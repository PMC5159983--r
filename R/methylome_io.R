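#' @importFrom data.table as.data.table data.table setkey setkeyv foverlaps := .N .SD rbindlist setorder fread setDF
#' @importFrom stats sd var
NULL

# ---------------------------------------------------------------------------
# CpG track container
# ---------------------------------------------------------------------------

#' Construct a per-CpG methylation count track
#'
#' A CpG track holds strand-combined bisulfite counts for one sample: for each
#' CpG, the number of methylated read calls (`meth`) and the total number of
#' read calls (`total`) at the position of the C on the plus strand (0-based).
#'
#' @param records data.frame with columns `chrom`, `pos`, `meth`, `total`.
#' @param sample_id character scalar identifying the sample.
#' @param genome optional named numeric vector of chromosome lengths (bp);
#'   when supplied, every record must fall on a known chromosome and within
#'   its length.
#' @return A `cpg_track`: a data.frame of records sorted by (chrom, pos) with
#'   attributes `sample_id` and `genome`.
#' @export
cpg_track <- function(records, sample_id = "sample", genome = NULL) {
  stopifnot(is.data.frame(records))
  needed <- c("chrom", "pos", "meth", "total")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols))
    stop("cpg_track records lack columns: ", paste(missing_cols, collapse = ", "))
  rec <- as.data.frame(records)[needed]
  rec$chrom <- as.character(rec$chrom)
  if (nrow(rec)) {
    if (any(rec$pos < 0)) stop("cpg_track: negative position")
    if (any(rec$meth < 0 | rec$total < 0)) stop("cpg_track: negative count")
    if (any(rec$meth > rec$total)) stop("cpg_track: meth > total")
    rec <- rec[order(rec$chrom, rec$pos), , drop = FALSE]
    if (anyDuplicated(rec[c("chrom", "pos")]))
      stop("cpg_track: duplicate (chrom, pos) records")
    rownames(rec) <- NULL
  }
  if (!is.null(genome)) {
    if (is.null(names(genome)) || any(!nzchar(names(genome))))
      stop("genome must be a named vector of chromosome lengths")
    bad <- !(rec$chrom %in% names(genome))
    if (any(bad))
      stop("cpg_track: unknown chromosome(s): ",
           paste(unique(rec$chrom[bad]), collapse = ", "))
    over <- rec$pos >= genome[rec$chrom]
    if (any(over))
      stop("cpg_track: position beyond chromosome end on ",
           paste(unique(rec$chrom[over]), collapse = ", "))
  }
  structure(rec, class = c("cpg_track", "data.frame"),
            sample_id = sample_id, genome = genome)
}

#' @export
print.cpg_track <- function(x, ...) {
  cat(sprintf("<cpg_track> sample '%s': %d CpGs on %d chromosome(s)\n",
              attr(x, "sample_id"), nrow(x), length(unique(x$chrom))))
  if (nrow(x)) {
    cat(sprintf("  total calls: %d, pooled methylation %.3f\n",
                sum(x$total), sum(x$meth) / sum(x$total)))
  }
  invisible(x)
}

track_genome <- function(track) attr(track, "genome")

# ---------------------------------------------------------------------------
# Reading CpG count files
# ---------------------------------------------------------------------------

#' Read per-CpG bisulfite counts
#'
#' Two tab-delimited dialects are supported and must be named explicitly:
#' \describe{
#'   \item{`cpg_report`}{columns chrom, position (1-based), methylated count,
#'     total count. Positions are converted to the package's 0-based
#'     convention.}
#'   \item{`bedgraph`}{count-carrying bedGraph: chrom, start (0-based), end,
#'     methylated count, total count, one CpG per line. A 4-column
#'     fraction-only bedGraph is rejected: fractions alone cannot be pooled,
#'     counts are required.}
#' }
#' Records with `total == 0` carry no information and are dropped; the number
#' dropped is reported in the track's `io_summary` attribute.
#'
#' @param path file path.
#' @param dialect `"cpg_report"` or `"bedgraph"`.
#' @param sample_id sample identifier stored on the track.
#' @param genome optional named chromosome-length vector used for validation.
#' @return A [cpg_track()] with attribute `io_summary`
#'   (list with `n_dropped_zero_total`).
#' @export
read_cpg_counts <- function(path, dialect = c("cpg_report", "bedgraph"),
                            sample_id = basename(path), genome = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  empty <- file.size(path) == 0
  dt <- if (empty) data.table() else
    fread(path, header = FALSE, sep = "\t", colClasses = list(character = 1),
          fill = TRUE, data.table = TRUE)
  if (nrow(dt) == 0L) {
    tr <- cpg_track(data.frame(chrom = character(), pos = integer(),
                               meth = integer(), total = integer()),
                    sample_id = sample_id, genome = genome)
    attr(tr, "io_summary") <- list(n_dropped_zero_total = 0L)
    return(tr)
  }
  ncol_want <- if (dialect == "cpg_report") 4L else 5L
  if (ncol(dt) != ncol_want) {
    if (dialect == "bedgraph" && ncol(dt) == 4L)
      stop("bedgraph input has 4 columns (fraction-only); ",
           "methylated and total counts are required")
    stop(sprintf("%s: expected %d tab-delimited columns, found %d",
                 path, ncol_want, ncol(dt)))
  }
  if (dialect == "cpg_report") {
    rec <- data.frame(chrom = dt[[1]], pos = as.numeric(dt[[2]]) - 1,
                      meth = as.numeric(dt[[3]]), total = as.numeric(dt[[4]]))
  } else {
    rec <- data.frame(chrom = dt[[1]], pos = as.numeric(dt[[2]]),
                      meth = as.numeric(dt[[4]]), total = as.numeric(dt[[5]]))
    width <- as.numeric(dt[[3]]) - rec$pos
    bad <- which(!is.finite(width) | width <= 0)
    if (length(bad))
      stop(sprintf("%s line %d: interval end not beyond start", path, bad[1]))
  }
  bad <- which(!is.finite(rec$pos) | !is.finite(rec$meth) | !is.finite(rec$total))
  if (length(bad))
    stop(sprintf("%s line %d: non-numeric field", path, bad[1]))
  bad <- which(rec$pos < 0 | rec$meth < 0 | rec$total < 0)
  if (length(bad))
    stop(sprintf("%s line %d: negative value", path, bad[1]))
  bad <- which(rec$meth > rec$total)
  if (length(bad))
    stop(sprintf("%s line %d: methylated count exceeds total", path, bad[1]))
  drop0 <- rec$total == 0
  rec <- rec[!drop0, , drop = FALSE]
  tr <- cpg_track(rec, sample_id = sample_id, genome = genome)
  attr(tr, "io_summary") <- list(n_dropped_zero_total = sum(drop0))
  tr
}

#' Write a CpG track as a cpg_report file
#'
#' Tab-delimited chrom, 1-based position, meth, total; the inverse of
#' [read_cpg_counts()] with `dialect = "cpg_report"`.
#'
#' @param track a [cpg_track()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cpg_counts <- function(track, path) {
  out <- data.frame(chrom = track$chrom, pos = track$pos + 1,
                    meth = track$meth, total = track$total)
  write_tsv_plain(out, path, col.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Strand combining and read bookkeeping
# ---------------------------------------------------------------------------

#' Combine CpG calls from the two DNA strands
#'
#' A CpG covers two positions: the C on the plus strand at `p` and the C of
#' the reverse complement at `p + 1`. Calls from both strands of one CpG are
#' summed onto the plus-strand coordinate. Minus-strand calls whose partner
#' position was never observed on the plus strand are still remapped to
#' `p - 1` (never discarded) and their number is reported in the summary.
#'
#' @param plus_records data.frame (chrom, pos, meth, total) of calls on
#'   plus-strand Cs.
#' @param minus_records same, for minus-strand Cs (positions are the C on the
#'   minus strand, i.e. plus-strand CpG position + 1).
#' @param sample_id,genome passed to [cpg_track()].
#' @return A strand-combined [cpg_track()] with attribute `strand_summary`
#'   (list with `n_unpaired_minus`).
#' @export
combine_strands <- function(plus_records, minus_records,
                            sample_id = "sample", genome = NULL) {
  cols <- c("chrom", "pos", "meth", "total")
  p <- as.data.table(as.data.frame(plus_records)[cols])
  m <- as.data.table(as.data.frame(minus_records)[cols])
  if (nrow(m)) {
    if (any(m$pos < 1)) stop("minus-strand record at position < 1 cannot be remapped")
    m[, pos := pos - 1L]
  }
  n_unpaired <- if (nrow(m)) {
    sum(!paste(m$chrom, m$pos) %in% paste(p$chrom, p$pos))
  } else 0L
  both <- rbind(p, m)
  comb <- both[, list(meth = sum(meth), total = sum(total)), by = c("chrom", "pos")]
  tr <- cpg_track(setDF(comb), sample_id = sample_id, genome = genome)
  attr(tr, "strand_summary") <- list(n_unpaired_minus = n_unpaired)
  tr
}

#' Remove clonal PCR duplicate reads
#'
#' Keeps exactly one read per distinct (chrom, start, strand) key — the first
#' encountered in input order — mirroring standard post-alignment clonal
#' deduplication for bisulfite libraries.
#'
#' @param reads data.frame with columns `chrom`, `start`, `strand` and
#'   optionally `length`.
#' @return The retained reads, with attribute `n_duplicates_removed`.
#' @export
deduplicate_reads <- function(reads) {
  stopifnot(all(c("chrom", "start", "strand") %in% names(reads)))
  if (nrow(reads) && "length" %in% names(reads) && any(reads$length <= 0))
    stop("deduplicate_reads: read length must be positive")
  dup <- duplicated(reads[c("chrom", "start", "strand")])
  out <- reads[!dup, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_duplicates_removed") <- sum(dup)
  out
}

#' Estimate fold coverage of a genome from mapped reads
#'
#' Fold coverage is the summed mapped read length divided by the genome size:
#' `n_reads * read_length / genome_size` for constant-length reads, or
#' `sum(read_length) / genome_size` when `read_length` is a per-read vector
#' (in which case `n_reads` is ignored).
#'
#' @param n_reads number of mapped reads (ignored when `read_length` is a
#'   vector of per-read lengths).
#' @param read_length read length in bp, scalar or per-read vector.
#' @param genome_size genome size in bp, must be positive.
#' @return Fold coverage (numeric scalar).
#' @export
estimate_fold_coverage <- function(n_reads, read_length, genome_size) {
  if (!is.numeric(genome_size) || length(genome_size) != 1 || genome_size <= 0)
    stop("genome_size must be a positive scalar")
  if (length(read_length) > 1) return(sum(as.numeric(read_length)) / genome_size)
  as.numeric(n_reads) * as.numeric(read_length) / genome_size
}

# ---------------------------------------------------------------------------
# BED interval I/O
# ---------------------------------------------------------------------------

validate_intervals <- function(x, what = "interval set", allow_overlap = TRUE) {
  stopifnot(is.data.frame(x))
  if (!all(c("chrom", "start", "end") %in% names(x)))
    stop(what, " needs columns chrom, start, end")
  if (!nrow(x)) return(x)
  if (any(x$start < 0)) stop(what, ": negative start")
  bad <- which(x$start >= x$end)
  if (length(bad)) stop(sprintf("%s: start >= end at row %d", what, bad[1]))
  x <- x[order(x$chrom, x$start, x$end), , drop = FALSE]
  rownames(x) <- NULL
  if (!allow_overlap) {
    ov <- x$chrom[-1] == x$chrom[-nrow(x)] & x$start[-1] < x$end[-nrow(x)]
    if (nrow(x) > 1 && any(ov))
      stop(what, ": overlapping intervals not allowed")
  }
  x
}

#' Read a BED interval file
#'
#' BED intervals are 0-based half-open. An optional 4th column carries a
#' label (`name`), e.g. PMD/HMD for domain calls or a ChromHMM state name for
#' chromatin-state elements.
#'
#' @param path file path.
#' @param domain_set if `TRUE` the payload is interpreted as a PMD/HMD domain
#'   call set: overlaps are rejected and a [domain_set()] is returned.
#' @return A sorted data.frame (chrom, start, end\[, name\]), or a
#'   [domain_set()] when `domain_set = TRUE`.
#' @export
read_bed <- function(path, domain_set = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", quote = "",
                           blank.lines.skip = TRUE)
  if (ncol(raw) < 3) stop(path, ": BED needs at least 3 columns")
  x <- data.frame(chrom = raw[[1]],
                  start = as.numeric(raw[[2]]),
                  end = as.numeric(raw[[3]]))
  bad <- which(!is.finite(x$start) | !is.finite(x$end))
  if (length(bad)) stop(sprintf("%s line %d: non-numeric coordinate", path, bad[1]))
  bad <- which(x$start >= x$end)
  if (length(bad)) stop(sprintf("%s line %d: start >= end", path, bad[1]))
  if (ncol(raw) >= 4) x$name <- raw[[4]]
  if (domain_set) {
    if (is.null(x$name)) stop(path, ": domain BED needs a 4th PMD/HMD column")
    return(domain_set(x$chrom, x$start, x$end, x$name))
  }
  validate_intervals(x, what = path, allow_overlap = TRUE)
}

#' Write intervals as BED
#'
#' Tab-delimited, newline-terminated, coordinates printed as plain integers —
#' the output is bit-stable so a write/read round trip is the identity.
#'
#' @param x data.frame with chrom, start, end and optionally name (a
#'   [domain_set()]'s state column is written as the name).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  x <- as.data.frame(x)
  if ("state" %in% names(x) && !"name" %in% names(x)) x$name <- x$state
  cols <- intersect(c("chrom", "start", "end", "name"), names(x))
  out <- x[cols]
  out$start <- format(out$start, scientific = FALSE, trim = TRUE)
  out$end <- format(out$end, scientific = FALSE, trim = TRUE)
  write_tsv_plain(out, path, col.names = FALSE)
  invisible(path)
}

write_tsv_plain <- function(x, path, col.names = TRUE) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = col.names)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Sample sheet
# ---------------------------------------------------------------------------

DIAGNOSES <- c("ASD", "TD", "ODC")

#' Read a cohort sample sheet
#'
#' CSV with a header row and columns `sample_id`, `diagnosis` (ASD/TD/ODC),
#' `sex` (M/F), `run`, `order`, `coverage`, `race_ethnicity`.
#'
#' @param path CSV path.
#' @return Validated data.frame of samples.
#' @export
read_sample_sheet <- function(path) {
  # sex must stay character: a column of bare F values would otherwise be
  # sniffed as logical
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(sex = "character"))
  validate_sample_sheet(x)
}

validate_sample_sheet <- function(x) {
  needed <- c("sample_id", "diagnosis", "sex", "run", "order", "coverage",
              "race_ethnicity")
  miss <- setdiff(needed, names(x))
  if (length(miss)) stop("sample sheet lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(x$sample_id)) stop("sample sheet: duplicate sample_id")
  if (!all(x$diagnosis %in% DIAGNOSES))
    stop("sample sheet: diagnosis must be one of ", paste(DIAGNOSES, collapse = "/"))
  if (!all(x$sex %in% c("M", "F")))
    stop("sample sheet: sex must be M or F")
  x
}
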