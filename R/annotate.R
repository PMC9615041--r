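#' Read a gene table
#'
#' Reads the tab-delimited gene model table produced by
#' [simulate_annotation()] (or prepared by the user): gene_id, chrom,
#' strand, start, end, tss, tes, exon_starts, exon_ends, biotype, with
#' 0-based half-open coordinates and comma-separated exon blocks.
#'
#' @param path TSV path.
#' @return data frame of gene models.
#' @export
read_gene_table <- function(path) {
  g <- read.delim(path, stringsAsFactors = FALSE,
                  colClasses = c(exon_starts = "character",
                                 exon_ends = "character"))
  needed <- c("gene_id", "chrom", "strand", "start", "end", "tss", "tes",
              "biotype")
  stop_if(!all(needed %in% names(g)),
          paste("gene table needs columns:", paste(needed, collapse = ", ")))
  g
}

# split comma-separated exon block strings into one row per exon
exon_table <- function(genes) {
  starts <- strsplit(as.character(genes$exon_starts), ",", fixed = TRUE)
  ends <- strsplit(as.character(genes$exon_ends), ",", fixed = TRUE)
  n <- lengths(starts)
  data.frame(gene_idx = rep(seq_len(nrow(genes)), n),
             chrom = rep(genes$chrom, n),
             start = as.integer(unlist(starts)),
             end = as.integer(unlist(ends)),
             stringsAsFactors = FALSE)
}

# GRanges of single-base midpoints (0-based positions -> 1-based bases)
midpoint_granges <- function(peaks) {
  mid <- floor((peaks$start + peaks$end) / 2)
  GenomicRanges::GRanges(peaks$chrom,
                         IRanges::IRanges(start = mid + 1L, width = 1L))
}

# strand-aware window around an anchor (0-based position), window given as
# (upstream, downstream) signed offsets; returns GRanges (1-based closed)
anchor_window_granges <- function(chrom, anchor, strand, window) {
  lo <- ifelse(strand == "+", anchor + window[1], anchor - window[2])
  hi <- ifelse(strand == "+", anchor + window[2], anchor - window[1])
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = lo + 1L,
                                                 end = hi + 1L))
}

# For Hits between midpoints and per-gene windows, keep for every peak the
# gene with the smallest |offset|, ties broken by lexicographic gene_id.
pick_best_gene <- function(q, g, offset, gene_ids) {
  if (length(q) == 0) {
    return(data.frame(peak = integer(), gene = integer(),
                      offset = integer()))
  }
  ord <- order(q, abs(offset), gene_ids[g])
  first <- !duplicated(q[ord])
  data.frame(peak = q[ord][first], gene = g[ord][first],
             offset = offset[ord][first])
}

#' Annotate peaks with location and transcript classes
#'
#' Classifies each peak by its midpoint with precedence
#' promoter-TSS > TES > exon > intergenic, and assigns a gene: for
#' promoter/TES/exon peaks the gene whose feature window contains the
#' midpoint (nearest anchor wins, ties broken by lexicographic gene id,
#' relevant e.g. for bidirectional promoters shared by two genes); for
#' intergenic peaks the nearest TSS within `search_radius`, else no gene.
#' Windows are strand-aware `(upstream, downstream)` offsets relative to
#' the anchor; negative = upstream.
#'
#' @param peaks data frame of peak intervals with a `name` or `peak_id`
#'   column.
#' @param genes gene table (see [read_gene_table()]).
#' @param promoter_window window around the TSS classed promoter-TSS.
#' @param tes_window window around the TES classed TES.
#' @param search_radius maximum distance (bp) to the nearest TSS for a gene
#'   to be assigned at all.
#' @return data frame: peak_id, gene_id, distance_to_tss (signed, negative
#'   = upstream of the assigned gene's TSS), location_class,
#'   transcript_class.
#' @export
annotate_peaks <- function(peaks, genes,
                           promoter_window = c(-1000, 100),
                           tes_window = c(-100, 1000),
                           search_radius = 10000) {
  peak_id <- peaks$peak_id %||% peaks$name %||%
    sprintf("peak_%d", seq_len(nrow(peaks)))
  n <- nrow(peaks)
  out <- data.frame(peak_id = peak_id,
                    gene_id = NA_character_,
                    distance_to_tss = NA_integer_,
                    location_class = rep("intergenic", n),
                    transcript_class = rep("other", n),
                    stringsAsFactors = FALSE)
  if (is.null(genes) || nrow(genes) == 0) {
    warning("empty gene model: all peaks classed intergenic")
    return(out)
  }
  mid_gr <- midpoint_granges(peaks)
  mid <- floor((peaks$start + peaks$end) / 2)
  sign_g <- ifelse(genes$strand == "+", 1L, -1L)
  tss_off <- function(p, g) (mid[p] - genes$tss[g]) * sign_g[g]
  tes_off <- function(p, g) (mid[p] - genes$tes[g]) * sign_g[g]

  ov <- function(windows) {
    h <- GenomicRanges::findOverlaps(mid_gr, windows)
    list(q = S4Vectors::queryHits(h), g = S4Vectors::subjectHits(h))
  }

  assigned <- rep(FALSE, n)
  set_class <- function(best, class) {
    idx <- best$peak
    out$location_class[idx] <<- class
    out$gene_id[idx] <<- genes$gene_id[best$gene]
    out$distance_to_tss[idx] <<- tss_off(idx, best$gene)
    bt <- genes$biotype[best$gene]
    out$transcript_class[idx] <<- ifelse(bt %in% c("mRNA", "tRNA"), bt,
                                         "other")
    assigned[idx] <<- TRUE
  }

  prom <- ov(anchor_window_granges(genes$chrom, genes$tss, genes$strand,
                                   promoter_window))
  best <- pick_best_gene(prom$q, prom$g, tss_off(prom$q, prom$g),
                         genes$gene_id)
  set_class(best, "promoter-TSS")

  tes <- ov(anchor_window_granges(genes$chrom, genes$tes, genes$strand,
                                  tes_window))
  keep <- !assigned[tes$q]
  best <- pick_best_gene(tes$q[keep], tes$g[keep],
                         tes_off(tes$q[keep], tes$g[keep]), genes$gene_id)
  set_class(best, "TES")

  exons <- exon_table(genes)
  if (nrow(exons) > 0) {
    ex_gr <- GenomicRanges::GRanges(exons$chrom,
                                    IRanges::IRanges(start = exons$start + 1L,
                                                     end = exons$end))
    h <- GenomicRanges::findOverlaps(mid_gr, ex_gr)
    q <- S4Vectors::queryHits(h)
    g <- exons$gene_idx[S4Vectors::subjectHits(h)]
    keep <- !assigned[q]
    best <- pick_best_gene(q[keep], g[keep], tss_off(q[keep], g[keep]),
                           genes$gene_id)
    set_class(best, "exon")
  }

  # intergenic remainder: nearest TSS within the search radius
  if (any(!assigned)) {
    tss_win <- anchor_window_granges(genes$chrom, genes$tss, genes$strand,
                                     c(-search_radius, search_radius))
    h <- ov(tss_win)
    keep <- !assigned[h$q]
    best <- pick_best_gene(h$q[keep], h$g[keep],
                           tss_off(h$q[keep], h$g[keep]), genes$gene_id)
    idx <- best$peak
    out$gene_id[idx] <- genes$gene_id[best$gene]
    out$distance_to_tss[idx] <- best$offset
    bt <- genes$biotype[best$gene]
    out$transcript_class[idx] <- ifelse(bt %in% c("mRNA", "tRNA"), bt,
                                        "other")
  }
  out
}
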