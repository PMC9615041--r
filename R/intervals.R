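#' Read a BED file of genomic intervals
#'
#' Reads a 3-6 column BED file (0-based half-open coordinates) into a data
#' frame.  Records with `start >= end` raise an error naming the offending
#' line.
#'
#' @param path file path.
#' @return data frame with columns chrom, start, end, name, strand (name and
#'   strand are `NA` when the file lacks them).
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  stop_if(any(nf < 3), sprintf("malformed BED record at line %d: fewer than 3 columns",
                               which(nf < 3)[1]))
  chrom <- vapply(fields, `[`, "", 1)
  start <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2)))
  end <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3)))
  bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end)
  stop_if(length(bad) > 0,
          sprintf("malformed BED record at line %d: requires 0 <= start < end",
                  bad[1]))
  name <- vapply(fields, function(f) {
    if (length(f) >= 4) f[4] else NA_character_
  }, "")
  strand <- vapply(fields, function(f) {
    if (length(f) >= 6) f[6] else NA_character_
  }, "")
  name[name == "."] <- NA_character_
  strand[!strand %in% c("+", "-")] <- NA_character_
  data.frame(chrom = chrom, start = start, end = end, name = name,
             strand = strand, stringsAsFactors = FALSE)
}

#' Write intervals to BED
#'
#' Inverse of [read_bed()]: writing then reading returns the same
#' (chrom, start, end, name, strand) tuples.
#'
#' @param intervals data frame with chrom, start, end and optionally name
#'   and strand.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_bed <- function(intervals, path) {
  stop_if(any(intervals$start >= intervals$end),
          "intervals must satisfy start < end")
  name <- intervals$name %||% rep(NA_character_, nrow(intervals))
  strand <- intervals$strand %||% rep(NA_character_, nrow(intervals))
  has_strand <- any(!is.na(strand))
  has_name <- any(!is.na(name)) || has_strand
  cols <- list(intervals$chrom, intervals$start, intervals$end)
  if (has_name) cols <- c(cols, list(ifelse(is.na(name), ".", name)))
  if (has_strand) {
    cols <- c(cols, list(rep(0L, nrow(intervals)),
                         ifelse(is.na(strand), ".", strand)))
  }
  lines <- do.call(paste, c(cols, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

# data frame of 0-based half-open intervals -> GRanges (1-based closed)
intervals_to_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end))
}

granges_to_intervals <- function(gr, name = NULL) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             name = name %||% rep(NA_character_, length(gr)),
             strand = NA_character_,
             stringsAsFactors = FALSE)
}

#' Merge one or more peak sets into disjoint intervals
#'
#' Combines the input interval sets and merges, per chromosome, every run of
#' intervals whose pairwise gap is at most `max_gap` base pairs.  At the
#' default `max_gap = 0`, bookended intervals (end of one equals start of
#' the next) are merged, matching the common merge-tool default.  Strand is
#' ignored.
#'
#' @param intervals a data frame of intervals (as from [read_bed()]) or a
#'   list of such data frames (e.g. the peak sets of two timepoints).
#' @param max_gap maximum gap (bp) across which two intervals still merge.
#' @return list with `merged` (data frame of disjoint, sorted intervals
#'   named `merged_1 ...`) and `provenance` (data frame mapping each input
#'   interval to exactly one merged interval).
#' @export
merge_intervals <- function(intervals, max_gap = 0L) {
  if (is.data.frame(intervals)) intervals <- list(intervals)
  combined <- do.call(rbind, lapply(intervals, function(x) {
    x[, c("chrom", "start", "end", "name"), drop = FALSE]
  }))
  if (nrow(combined) == 0) {
    return(list(merged = combined,
                provenance = data.frame(input_name = character(),
                                        merged_name = character())))
  }
  stop_if(any(combined$start >= combined$end),
          "intervals must satisfy start < end")
  gr <- intervals_to_granges(combined)
  merged_gr <- GenomicRanges::reduce(GenomicRanges::sort(gr),
                                     min.gapwidth = max_gap + 1L)
  merged <- granges_to_intervals(
    merged_gr, name = sprintf("merged_%d", seq_along(merged_gr)))
  hits <- GenomicRanges::findOverlaps(gr, merged_gr)
  input_name <- combined$name
  if (all(is.na(input_name))) input_name <- as.character(seq_len(nrow(combined)))
  provenance <- data.frame(
    input_name = input_name[S4Vectors::queryHits(hits)],
    merged_name = merged$name[S4Vectors::subjectHits(hits)],
    stringsAsFactors = FALSE)
  list(merged = merged, provenance = provenance)
}

#' Count fragments overlapping peaks
#'
#' A fragment is assigned to a peak when they overlap by at least 1 bp.
#' Fragments overlapping more than one peak are discarded by default
#' (set `count_multi_overlap = TRUE` to increment every overlapped peak).
#' Peaks are expected to be disjoint per chromosome (post-merge).
#'
#' @param fragments a data frame of fragment intervals for one sample, or a
#'   named list of such data frames (one per sample).
#' @param peaks data frame of peak intervals with a `name` column.
#' @param count_multi_overlap count a multi-peak fragment in every peak it
#'   overlaps instead of discarding it.
#' @return integer matrix of counts, peaks by samples.
#' @export
count_fragments <- function(fragments, peaks, count_multi_overlap = FALSE) {
  if (is.data.frame(fragments)) fragments <- list(sample_1 = fragments)
  peak_gr <- intervals_to_granges(peaks)
  peak_names <- peaks$name %||% sprintf("peak_%d", seq_len(nrow(peaks)))
  counts <- matrix(0L, nrow(peaks), length(fragments),
                   dimnames = list(peak_names, names(fragments)))
  for (j in seq_along(fragments)) {
    frag <- fragments[[j]]
    if (nrow(frag) == 0) next
    hits <- GenomicRanges::findOverlaps(intervals_to_granges(frag), peak_gr,
                                        minoverlap = 1L)
    q <- S4Vectors::queryHits(hits)
    s <- S4Vectors::subjectHits(hits)
    if (!count_multi_overlap) {
      multi <- unique(q[duplicated(q)])
      keep <- !(q %in% multi)
      s <- s[keep]
    }
    tab <- tabulate(s, nbins = nrow(peaks))
    counts[, j] <- as.integer(tab)
  }
  counts
}

write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a peak-by-sample count matrix as TSV
#'
#' The TSV has a `peak_id` first column followed by one column per sample.
#'
#' @param counts integer matrix with peak row names and sample column names.
#' @param path file path.
#' @return `write_counts` invisibly returns `path`; `read_counts` returns
#'   the integer matrix.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(peak_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$peak_id
  stop_if(any(m < 0), "counts must be non-negative")
  m
}

#' Read a sample sheet (sample_id, day, replicate)
#'
#' @param path TSV with columns sample_id, day, replicate.
#' @return data frame; (day, replicate) pairs must be unique.
#' @export
read_sample_sheet <- function(path) {
  s <- read.delim(path, stringsAsFactors = FALSE)
  stop_if(!all(c("sample_id", "day", "replicate") %in% names(s)),
          "sample sheet needs columns sample_id, day, replicate")
  stop_if(anyDuplicated(s[, c("day", "replicate")]) > 0,
          "(day, replicate) pairs must be unique")
  s
}
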