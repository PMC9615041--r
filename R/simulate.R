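#' Configuration for the synthetic ATAC-seq study generator
#'
#' Bundles and validates every knob of the synthetic-data generator.  The
#' defaults emulate the count structure of a 28-day yeast evolution time
#' course assayed at days 0, 3, 7, 10 and 28 with duplicate libraries:
#' roughly 3,500 peaks, a small dynamic fraction (7.8%) following smooth
#' temporal archetypes, and differential effects concentrated at the
#' selection-onset (day 0 to 3) and selection-release (day 7 to 10)
#' transitions.
#'
#' @param n_peaks number of peaks to simulate.
#' @param timepoints_days strictly increasing assay days.
#' @param n_replicates libraries per timepoint.
#' @param frac_dynamic fraction of peaks given a temporal archetype.
#' @param n_archetypes number of distinct temporal mean shapes.
#' @param nb_dispersion negative-binomial dispersion alpha (variance =
#'   mu + alpha * mu^2); scalar or one value per peak.
#' @param baseline_log_mean_range range (natural-log scale) from which
#'   per-peak baseline mean counts are drawn uniformly.
#' @param effect_size_sd standard deviation of the normal distribution from
#'   which archetype amplitudes (log2-fold-change units) are drawn.
#' @param size_factors optional per-sample positive scaling factors; when
#'   `NULL` they are drawn log-uniformly from `[0.7, 1.4]` so that
#'   normalization is exercised.
#' @param transition_effect_pairs list of two day pairs at which the
#'   archetype mean steps occur; all other consecutive transitions have
#'   true log2 fold-change zero.
#' @param class_proportions named proportions of peak location classes
#'   (`promoter-TSS`, `TES`, `exon`, `intergenic`); must sum to 1.
#' @param biotype_proportions named proportions of gene biotypes
#'   (`mRNA`, `tRNA`, `other`); must sum to 1.
#' @param n_genes number of genes in the toy genome; default scales with
#'   `n_peaks` so that peaks can target distinct genes.
#' @param genes_per_set approximate gene-set size used when partitioning
#'   mRNA genes into GMT records (at least 10 sets are always produced).
#' @param replicate_batch_sd standard deviation of an optional per-replicate
#'   log-scale batch offset (0 = i.i.d. replicates, the default).
#' @param seed integer seed; identical configurations yield byte-identical
#'   outputs.
#' @return a validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_peaks = 3500L,
                              timepoints_days = c(0, 3, 7, 10, 28),
                              n_replicates = 2L,
                              frac_dynamic = 0.078,
                              n_archetypes = 6L,
                              nb_dispersion = 0.05,
                              baseline_log_mean_range = log(c(50, 500)),
                              effect_size_sd = 1,
                              size_factors = NULL,
                              transition_effect_pairs = list(c(0, 3), c(7, 10)),
                              class_proportions = c("promoter-TSS" = 0.55,
                                                    "TES" = 0.10,
                                                    "exon" = 0.15,
                                                    "intergenic" = 0.20),
                              biotype_proportions = c(mRNA = 0.80,
                                                      tRNA = 0.10,
                                                      other = 0.10),
                              n_genes = NULL,
                              genes_per_set = 50L,
                              replicate_batch_sd = 0,
                              seed = 1L) {
  stop_if(n_peaks < 1, "n_peaks must be a positive integer")
  stop_if(length(timepoints_days) < 2 || any(diff(timepoints_days) <= 0),
          "timepoints_days must be strictly increasing")
  stop_if(n_replicates < 1, "n_replicates must be >= 1")
  stop_if(frac_dynamic < 0 || frac_dynamic > 1,
          "frac_dynamic must lie in [0, 1]")
  stop_if(any(nb_dispersion < 0), "nb_dispersion must be >= 0")
  stop_if(length(baseline_log_mean_range) != 2 ||
            diff(baseline_log_mean_range) < 0,
          "baseline_log_mean_range must be an increasing interval")
  stop_if(effect_size_sd <= 0, "effect_size_sd must be > 0")
  n_samples <- length(timepoints_days) * n_replicates
  if (!is.null(size_factors)) {
    stop_if(length(size_factors) != n_samples,
            "size_factors must have one entry per sample")
    stop_if(any(size_factors <= 0), "size factors must be strictly positive")
  }
  stop_if(abs(sum(class_proportions) - 1) > 1e-8,
          "class_proportions must sum to 1")
  stop_if(!all(names(class_proportions) %in%
                 c("promoter-TSS", "TES", "exon", "intergenic")),
          "unknown location class in class_proportions")
  stop_if(abs(sum(biotype_proportions) - 1) > 1e-8,
          "biotype_proportions must sum to 1")
  for (p in transition_effect_pairs) {
    stop_if(!all(p %in% timepoints_days),
            "transition_effect_pairs must reference assay days")
  }
  cfg <- list(n_peaks = as.integer(n_peaks),
              timepoints_days = as.numeric(timepoints_days),
              n_replicates = as.integer(n_replicates),
              frac_dynamic = frac_dynamic,
              n_archetypes = as.integer(n_archetypes),
              nb_dispersion = nb_dispersion,
              baseline_log_mean_range = baseline_log_mean_range,
              effect_size_sd = effect_size_sd,
              size_factors = size_factors,
              transition_effect_pairs = transition_effect_pairs,
              class_proportions = class_proportions,
              biotype_proportions = biotype_proportions,
              n_genes = if (is.null(n_genes)) {
                max(60L, as.integer(ceiling(1.2 * n_peaks)))
              } else as.integer(n_genes),
              genes_per_set = as.integer(genes_per_set),
              replicate_batch_sd = replicate_batch_sd,
              seed = as.integer(seed))
  class(cfg) <- "simulation_config"
  cfg
}

# Fixed chromosome naming of the toy genome (yeast-like, up to 16).
toy_chromosomes <- function(n) paste0("chr", as.roman(seq_len(min(n, 16L))))

#' Simulate a toy annotation: stranded genes and GMT gene sets
#'
#' Lays out stranded genes (with TSS, TES and exon blocks) on a small set of
#' chromosomes, assigns each gene a biotype (`mRNA`, `tRNA`, `other`) and
#' partitions the mRNA genes into at least 10 named gene sets.  Output is a
#' deterministic function of the configuration (including its seed).
#'
#' @param config a [simulation_config()].
#' @return list with `genes` (data frame: gene_id, chrom, strand, start, end,
#'   tss, tes, exon_starts, exon_ends, biotype; 0-based half-open
#'   coordinates), `gene_sets` (named list of gene-id vectors) and
#'   `chrom_sizes` (named integer vector).
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    n_genes <- config$n_genes
    chroms <- toy_chromosomes(max(2L, ceiling(n_genes / 300)))
    chrom <- rep(chroms, length.out = n_genes)
    idx_on_chrom <- stats::ave(seq_len(n_genes), chrom, FUN = seq_along)
    spacing <- 6000L
    offset <- 2000L
    len <- sample(500:3000, n_genes, replace = TRUE)
    start <- offset + (idx_on_chrom - 1L) * spacing
    end <- start + len
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    biotype <- sample(names(config$biotype_proportions), n_genes,
                      replace = TRUE, prob = config$biotype_proportions)
    gene_id <- sprintf("G%04d", seq_len(n_genes))
    tss <- ifelse(strand == "+", start, end)
    tes <- ifelse(strand == "+", end, start)
    # mostly single-exon genes; a minority get two exons with a short gap
    two_exon <- runif(n_genes) < 0.2 & len > 1200
    exon_starts <- ifelse(two_exon,
                          paste(start, start + floor(len * 0.55), sep = ","),
                          as.character(start))
    exon_ends <- ifelse(two_exon,
                        paste(start + floor(len * 0.45), end, sep = ","),
                        as.character(end))
    genes <- data.frame(gene_id, chrom, strand,
                        start = as.integer(start), end = as.integer(end),
                        tss = as.integer(tss), tes = as.integer(tes),
                        exon_starts, exon_ends, biotype,
                        stringsAsFactors = FALSE)
    chrom_sizes <- vapply(split(genes$end, genes$chrom), max, numeric(1)) +
      spacing
    chrom_sizes <- as.integer(chrom_sizes[chroms])
    names(chrom_sizes) <- chroms

    mrna <- genes$gene_id[genes$biotype == "mRNA"]
    n_sets <- max(10L, floor(length(mrna) / config$genes_per_set))
    shuffled <- sample(mrna)
    assignment <- rep(seq_len(n_sets), length.out = length(shuffled))
    gene_sets <- split(shuffled, sprintf("SET_%03d", assignment))
    gene_sets <- lapply(gene_sets, sort)

    list(genes = genes, gene_sets = gene_sets, chrom_sizes = chrom_sizes)
  })
}

# Archetype step templates: log2-scale steps applied at the two configured
# transitions.  Six shapes mirror the study design: gradual monotone
# up/down, early shift then flat, and shift-then-reversal.
archetype_steps <- function(n_archetypes) {
  templates <- rbind(c(0.5, 0.5),    # monotone up
                     c(-0.5, -0.5),  # monotone down
                     c(1, 0),        # early up, then flat
                     c(-1, 0),       # early down, then flat
                     c(1, -1),       # up, reversed after release
                     c(-1, 1))       # down, reversed after release
  templates[rep(seq_len(nrow(templates)), length.out = n_archetypes), ,
            drop = FALSE]
}

# Per-timepoint log2 offsets of one archetype with unit amplitude.
archetype_profile <- function(archetype, config) {
  steps <- archetype_steps(config$n_archetypes)[archetype, ]
  days <- config$timepoints_days
  prof <- numeric(length(days))
  for (i in seq_along(config$transition_effect_pairs)) {
    pair <- config$transition_effect_pairs[[i]]
    prof <- prof + steps[i] * as.numeric(days >= pair[2])
  }
  prof
}

#' Lay out synthetic peaks with known annotation and dynamic ground truth
#'
#' Places each peak relative to a target gene so that its location class
#' (promoter-TSS, TES, exon or intergenic) is known by construction, then
#' marks a random fraction as dynamic, assigning each dynamic peak a
#' temporal archetype and a normal amplitude.
#'
#' @param annotation output of [simulate_annotation()].
#' @param config a [simulation_config()].
#' @return data frame (one row per peak): peak_id, chrom, start, end,
#'   gene_id, location_class, transcript_class, is_dynamic, archetype,
#'   amplitude, baseline_log_mean.
#' @export
simulate_peaks <- function(annotation, config) {
  stopifnot(inherits(config, "simulation_config"))
  genes <- annotation$genes
  with_seed(config$seed + 1L, {
    n <- config$n_peaks
    classes <- sample(names(config$class_proportions), n, replace = TRUE,
                      prob = config$class_proportions)
    gi <- if (n <= nrow(genes)) sample(nrow(genes), n) else
      sample(nrow(genes), n, replace = TRUE)
    g <- genes[gi, ]
    width <- sample(200:600, n, replace = TRUE)
    offset <- sample(150:800, n, replace = TRUE)
    plus <- g$strand == "+"
    mid <- integer(n)
    mid[classes == "promoter-TSS"] <-
      ifelse(plus, g$tss - offset, g$tss + offset)[classes == "promoter-TSS"]
    mid[classes == "TES"] <-
      ifelse(plus, g$tes + offset, g$tes - offset)[classes == "TES"]
    # first quarter of the gene body always lies inside exon 1 and outside
    # both the promoter (TSS +100) and TES (-100) windows for len >= 500
    mid[classes == "exon"] <-
      (g$start + floor((g$end - g$start) / 4))[classes == "exon"]
    # intergenic: the middle of the gap between this gene's body and the
    # next gene slot (spacing 6000); the gap is >= 3000 so the midpoint
    # clears every promoter and TES window by >= 1500 bp
    mid[classes == "intergenic"] <-
      (g$end + (6000L - (g$end - g$start)) %/% 2L)[classes == "intergenic"]
    start <- pmax(0L, as.integer(mid - floor(width / 2)))
    end <- as.integer(start + width)
    as_tclass <- function(b) ifelse(b %in% c("mRNA", "tRNA"), b, "other")
    transcript_class <- as_tclass(g$biotype)
    # intergenic peaks inherit the transcript class of the nearer flanking
    # TSS (the class an annotator assigns), not of the placement gene
    inter <- which(classes == "intergenic")
    if (length(inter) > 0) {
      nxt <- match(paste(g$chrom, g$start + 6000L),
                   paste(genes$chrom, genes$start))
      d_target <- abs(mid - g$tss)
      d_next <- abs(mid - genes$tss[nxt])
      use_next <- !is.na(nxt) & !is.na(d_next) &
        (d_next < d_target |
           (d_next == d_target & genes$gene_id[nxt] < g$gene_id))
      idx <- inter[use_next[inter]]
      transcript_class[idx] <- as_tclass(genes$biotype[nxt[idx]])
    }
    n_dyn <- round(config$frac_dynamic * n)
    is_dynamic <- rep(FALSE, n)
    is_dynamic[sample(n, n_dyn)] <- TRUE
    archetype <- rep(NA_integer_, n)
    amplitude <- rep(0, n)
    archetype[is_dynamic] <- sample(config$n_archetypes, n_dyn,
                                    replace = TRUE)
    amplitude[is_dynamic] <- rnorm(n_dyn, 0, config$effect_size_sd)
    data.frame(peak_id = sprintf("peak_%05d", seq_len(n)),
               chrom = g$chrom, start = start, end = end,
               gene_id = ifelse(classes == "intergenic", NA_character_,
                                g$gene_id),
               location_class = classes,
               transcript_class = transcript_class,
               is_dynamic = is_dynamic,
               archetype = archetype,
               amplitude = amplitude,
               baseline_log_mean = runif(n, config$baseline_log_mean_range[1],
                                         config$baseline_log_mean_range[2]),
               stringsAsFactors = FALSE)
  })
}

#' Simulate replicated negative-binomial counts with known truth
#'
#' Draws a peak-by-sample integer count matrix under the mean model
#' `mu[i, (j,r)] = s[(j,r)] * exp(b_i + f_i(t_j))`, where `f_i` is the
#' archetype mean profile (identically zero for static peaks) and counts are
#' negative-binomial with dispersion `alpha` (variance `mu + alpha mu^2`).
#'
#' @param peaks output of [simulate_peaks()] (the truth layout).
#' @param config a [simulation_config()].
#' @return list with `counts` (integer matrix, peaks x samples), `samples`
#'   (data frame: sample_id, day, replicate), `size_factors`, and `truth`
#'   (the layout augmented with one `lfc_<a>_<b>` column of true log2
#'   fold-changes per consecutive-day transition).
#' @export
simulate_counts <- function(peaks, config) {
  stopifnot(inherits(config, "simulation_config"))
  days <- config$timepoints_days
  n_rep <- config$n_replicates
  samples <- data.frame(
    sample_id = sprintf("d%g_r%d", rep(days, each = n_rep),
                        rep(seq_len(n_rep), length(days))),
    day = rep(days, each = n_rep),
    replicate = rep(seq_len(n_rep), length(days)),
    stringsAsFactors = FALSE)
  n_samples <- nrow(samples)
  with_seed(config$seed + 2L, {
    sf <- config$size_factors
    if (is.null(sf)) sf <- exp(runif(n_samples, log(0.7), log(1.4)))
    stop_if(any(sf <= 0), "size factors must be strictly positive")
    batch <- if (config$replicate_batch_sd > 0) {
      rnorm(n_rep, 0, config$replicate_batch_sd)[samples$replicate]
    } else rep(0, n_samples)

    n <- nrow(peaks)
    # per-peak log2 temporal offsets at each day
    f <- matrix(0, n, length(days))
    dyn <- which(peaks$is_dynamic)
    for (i in dyn) {
      f[i, ] <- peaks$amplitude[i] * archetype_profile(peaks$archetype[i],
                                                       config)
    }
    log_mu <- outer(peaks$baseline_log_mean, rep(0, n_samples), `+`) +
      f[, match(samples$day, days), drop = FALSE] * log(2) +
      matrix(batch, n, n_samples, byrow = TRUE)
    mu <- exp(log_mu) * matrix(sf, n, n_samples, byrow = TRUE)
    alpha <- rep(config$nb_dispersion, length.out = n)
    counts <- matrix(0L, n, n_samples,
                     dimnames = list(peaks$peak_id, samples$sample_id))
    for (j in seq_len(n_samples)) {
      counts[, j] <- ifelse(alpha < 1e-12,
                            rpois(n, mu[, j]),
                            rnbinom(n, mu = mu[, j], size = 1 / alpha))
    }
    truth <- peaks
    for (k in seq_len(length(days) - 1)) {
      truth[[sprintf("lfc_%g_%g", days[k], days[k + 1])]] <-
        f[, k + 1] - f[, k]
    }
    list(counts = counts, samples = samples, size_factors = sf,
         truth = truth)
  })
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper running [simulate_annotation()], [simulate_peaks()]
#' and [simulate_counts()] in sequence.
#'
#' @param config a [simulation_config()].
#' @return list with `config`, `genes`, `gene_sets`, `chrom_sizes`, `peaks`,
#'   `counts`, `samples`, `size_factors` and `truth`.
#' @export
simulate_study <- function(config = simulation_config()) {
  ann <- simulate_annotation(config)
  peaks <- simulate_peaks(ann, config)
  cm <- simulate_counts(peaks, config)
  c(list(config = config, genes = ann$genes, gene_sets = ann$gene_sets,
         chrom_sizes = ann$chrom_sizes, peaks = peaks), cm)
}

#' Write a synthetic study to plain-text files
#'
#' Writes peaks as BED, the gene table and sample sheet as TSV, gene sets as
#' GMT, and the count and truth tables as TSV into `dir`.
#'
#' @param study output of [simulate_study()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths written.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(peaks = file.path(dir, "peaks.bed"),
             genes = file.path(dir, "genes.tsv"),
             gene_sets = file.path(dir, "gene_sets.gmt"),
             counts = file.path(dir, "counts.tsv"),
             samples = file.path(dir, "samples.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_bed(data.frame(chrom = study$peaks$chrom, start = study$peaks$start,
                       end = study$peaks$end, name = study$peaks$peak_id,
                       strand = NA_character_),
            paths["peaks"])
  write_tsv(study$genes, paths["genes"])
  write_gmt(study$gene_sets, paths["gene_sets"])
  write_counts(study$counts, paths["counts"])
  write_tsv(study$samples, paths["samples"])
  write_tsv(study$truth, paths["truth"])
  invisible(paths)
}
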