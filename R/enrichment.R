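#' Read / write gene sets in GMT format
#'
#' GMT: one record per line, tab-separated: set name, description, member
#' gene ids.
#'
#' @param path file path.
#' @return `read_gmt`: named list of character vectors; `write_gmt`
#'   invisibly returns `path`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  stop_if(any(lengths(fields) < 3),
          "GMT records need name, description and at least one member")
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[`, "", 1)
  sets
}

#' @rdname read_gmt
#' @param sets named list of gene-id vectors.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Assemble a gene-set collection over a gene universe
#'
#' Restricts each set to the universe and drops sets left empty.
#'
#' @param sets named list of gene-id vectors.
#' @param universe character vector of all gene ids.
#' @return list of class `gene_set_collection`: sets, universe.
#' @export
gene_set_collection <- function(sets, universe) {
  universe <- unique(universe)
  sets <- lapply(sets, function(s) intersect(unique(s), universe))
  sets <- sets[lengths(sets) > 0]
  structure(list(sets = sets, universe = universe),
            class = "gene_set_collection")
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric p-value for each set's overlap with the query
#' list (`P(overlap >= observed)`), Benjamini-Hochberg adjusted across
#' sets.
#'
#' @param gene_list character vector of query gene ids.
#' @param collection a [gene_set_collection()].
#' @return data frame: set, set_size, overlap, p, fdr.
#' @export
hypergeometric_ora <- function(gene_list, collection) {
  stopifnot(inherits(collection, "gene_set_collection"))
  gene_list <- unique(gene_list)
  inter <- intersect(gene_list, collection$universe)
  if (length(inter) == 0) {
    warning("query list does not intersect the universe; all p = 1")
  }
  N <- length(collection$universe)
  n <- length(inter)
  res <- do.call(rbind, lapply(names(collection$sets), function(nm) {
    set <- collection$sets[[nm]]
    k <- length(intersect(inter, set))
    K <- length(set)
    p <- if (k == 0) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, set_size = K, overlap = k, p = p,
               stringsAsFactors = FALSE)
  }))
  res$fdr <- bh_adjust(res$p)
  res
}

#' Build a preranked peak-level list from differential results
#'
#' Keeps only significant records (`padj < threshold`); every retained peak
#' contributes one entry carrying its annotated gene id and log2
#' fold-change, so a gene associated with several peaks appears several
#' times.  Entries are sorted by decreasing statistic, ties broken by peak
#' id.
#'
#' @param records one pair's differential table (see
#'   [consecutive_comparisons()]).
#' @param annotations peak annotations supplying `gene_id` per peak.
#' @param padj_threshold significance cutoff.
#' @return data frame: peak_id, gene_id, stat (log2FC), sorted descending.
#' @export
build_ranked_list <- function(records, annotations, padj_threshold = 0.05) {
  gene <- annotations$gene_id[match(records$peak_id, annotations$peak_id)]
  keep <- !is.na(records$padj) & records$padj < padj_threshold & !is.na(gene)
  if (!any(keep)) {
    warning("no significant peaks; returning an empty ranked list")
    return(data.frame(peak_id = character(), gene_id = character(),
                      stat = numeric(), stringsAsFactors = FALSE))
  }
  out <- data.frame(peak_id = records$peak_id[keep],
                    gene_id = gene[keep],
                    stat = records$log2FC[keep],
                    stringsAsFactors = FALSE)
  out[order(-out$stat, out$peak_id), , drop = FALSE]
}

# Signed maximum deviation of the GSEA running sum, from hit positions.
# idx: positions of the set's entries in the ranked list (any order);
# wts: |stat|^weight at every position of the list.
gsea_es_from_positions <- function(idx, wts, N) {
  k <- length(idx)
  idx <- sort(idx)
  w <- wts[idx]
  tot <- sum(w)
  if (tot <= 0) w <- rep(1 / k, k) else w <- w / tot
  chit <- cumsum(w)
  miss_rate <- 1 / (N - k)
  after <- chit - (idx - seq_len(k)) * miss_rate      # just after each hit
  before <- c(0, chit[-k]) - (idx - 1 - (seq_len(k) - 1)) * miss_rate
  hi <- max(after)
  lo <- min(before)
  if (hi >= -lo) hi else lo
}

#' Preranked gene-set enrichment with a label-permutation null
#'
#' Weighted running-sum enrichment: walking down the ranked list, hits
#' increment proportionally to `|stat|^weight` and misses decrement by
#' `1 / (N - Nh)`; the enrichment score (ES) is the maximum deviation of
#' the running sum.  The null permutes entry-to-set membership labels
#' (equivalently, redraws the hit positions uniformly).  NES divides the
#' ES by the mean |permutation ES| of the same sign; `perm_p` is the
#' same-sign permutation tail with the usual +1 correction; FDR follows
#' the standard same-sign NES ratio procedure across sets.
#'
#' @param ranked data frame from [build_ranked_list()] (columns gene_id,
#'   stat, in ranked order).
#' @param collection a [gene_set_collection()].
#' @param n_perm number of membership permutations per set.
#' @param weight exponent on `|stat|` for hit increments (0 = unweighted).
#' @param seed permutation seed.
#' @param min_size sets with fewer matching entries are dropped.
#' @param fdr_threshold significance cutoff on the FDR.
#' @param collapse collapse duplicate gene entries to the one with the
#'   largest `|stat|` before scoring (off by default: every peak-level
#'   entry counts separately).
#' @return data frame: set, n_hits, ES, NES, perm_p, FDR, direction
#'   (`increased` / `decreased`), significant; `NULL` rows for dropped
#'   sets are omitted.
#' @export
preranked_gsea <- function(ranked, collection, n_perm = 1000, weight = 1,
                           seed = 1, min_size = 3, fdr_threshold = 0.1,
                           collapse = FALSE) {
  stopifnot(inherits(collection, "gene_set_collection"))
  stop_if(nrow(ranked) == 0, "ranked list is empty")
  if (collapse) {
    ord <- order(ranked$gene_id, -abs(ranked$stat))
    ranked <- ranked[ord[!duplicated(ranked$gene_id[ord])], , drop = FALSE]
    ranked <- ranked[order(-ranked$stat, ranked$peak_id), , drop = FALSE]
  }
  N <- nrow(ranked)
  wts <- abs(ranked$stat)^weight
  rows <- list()
  perm_nes <- list()
  with_seed(seed, {
    for (nm in names(collection$sets)) {
      hits <- which(ranked$gene_id %in% collection$sets[[nm]])
      k <- length(hits)
      if (k < min_size || k >= N) next
      es <- gsea_es_from_positions(hits, wts, N)
      es_perm <- vapply(seq_len(n_perm), function(b) {
        gsea_es_from_positions(sample(N, k), wts, N)
      }, numeric(1))
      same <- es_perm[sign(es_perm) == sign(es)]
      denom <- if (length(same) > 0) mean(abs(same)) else mean(abs(es_perm))
      nes <- es / denom
      perm_p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
      rows[[nm]] <- data.frame(set = nm, n_hits = k, ES = es, NES = nes,
                               perm_p = perm_p, stringsAsFactors = FALSE)
      perm_nes[[nm]] <- es_perm / denom
    }
  })
  if (length(rows) == 0) {
    return(data.frame(set = character(), n_hits = integer(), ES = numeric(),
                      NES = numeric(), perm_p = numeric(), FDR = numeric(),
                      direction = character(), significant = logical()))
  }
  res <- do.call(rbind, rows)
  all_perm <- unlist(perm_nes, use.names = FALSE)
  res$FDR <- vapply(res$NES, function(nes) {
    if (nes >= 0) {
      num_pool <- all_perm[all_perm >= 0]
      obs_pool <- res$NES[res$NES >= 0]
      num <- if (length(num_pool) == 0) 0 else mean(num_pool >= nes)
      den <- mean(obs_pool >= nes)
    } else {
      num_pool <- all_perm[all_perm < 0]
      obs_pool <- res$NES[res$NES < 0]
      num <- if (length(num_pool) == 0) 0 else mean(num_pool <= nes)
      den <- mean(obs_pool <= nes)
    }
    min(1, num / max(den, .Machine$double.eps))
  }, numeric(1))
  res$direction <- ifelse(res$ES >= 0, "increased", "decreased")
  res$significant <- res$FDR <= fdr_threshold
  rownames(res) <- NULL
  res
}

#' Top enriched sets in each direction
#'
#' @param results a [preranked_gsea()] table.
#' @param n number of sets per direction.
#' @return the top `n` sets by NES among increased and among decreased.
#' @export
top_sets <- function(results, n = 5) {
  up <- results[results$NES > 0, , drop = FALSE]
  dn <- results[results$NES < 0, , drop = FALSE]
  rbind(head(up[order(-up$NES), , drop = FALSE], n),
        head(dn[order(dn$NES), , drop = FALSE], n))
}

#' Flag gene sets with reversed enrichment between two comparisons
#'
#' A set is reversible when it appears in both result tables with opposite
#' NES signs (typically the selection-onset day 0 vs 3 and
#' selection-release day 7 vs 10 comparisons).  FDR significance in each
#' comparison is reported alongside but not required.
#'
#' @param results_a,results_b [preranked_gsea()] tables for the two
#'   comparisons.
#' @return data frame: set, NES_a, NES_b, significant_a, significant_b,
#'   reversible.
#' @export
flag_reversible_sets <- function(results_a, results_b) {
  common <- intersect(results_a$set, results_b$set)
  ia <- match(common, results_a$set)
  ib <- match(common, results_b$set)
  data.frame(set = common,
             NES_a = results_a$NES[ia],
             NES_b = results_b$NES[ib],
             significant_a = results_a$significant[ia],
             significant_b = results_b$significant[ib],
             reversible = sign(results_a$NES[ia]) *
               sign(results_b$NES[ib]) == -1,
             stringsAsFactors = FALSE)
}
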