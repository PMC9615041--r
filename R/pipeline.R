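#' Pipeline configuration
#'
#' Thresholds follow the study conventions: differential peaks at adjusted
#' p < 0.05, loose-dynamic peaks at LR < -0.25 (strict at chi-square
#' p < 0.05), gene-set significance at FDR <= 0.1.
#'
#' @param sim a [simulation_config()] describing the synthetic study (used
#'   when no `input_dir` is given).
#' @param input_dir optional directory holding counts.tsv, samples.tsv,
#'   peaks.bed, genes.tsv and gene_sets.gmt (as written by
#'   [write_study()]); when supplied, data are read instead of simulated.
#' @param pairs consecutive day pairs to test.
#' @param enrich_pairs day pairs fed to gene-set enrichment (the two
#'   transition comparisons by default).
#' @param padj_threshold,lr_threshold,chi2_alpha,fdr_threshold stage
#'   thresholds.
#' @param n_perm GSEA permutations.
#' @param gp_starts optimizer starts per peak in the dynamics stage.
#' @param K_max,min_cluster_profiles clustering truncation and the minimum
#'   number of loose-dynamic profiles required to attempt clustering.
#' @param run_dynamics,run_clustering,run_composition,run_enrichment stage
#'   toggles.
#' @param seed master seed for every stochastic stage.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = simulation_config(),
                            input_dir = NULL,
                            pairs = list(c(0, 3), c(3, 7), c(7, 10),
                                         c(10, 28)),
                            enrich_pairs = list(c(0, 3), c(7, 10)),
                            padj_threshold = 0.05,
                            lr_threshold = -0.25,
                            chi2_alpha = 0.05,
                            fdr_threshold = 0.1,
                            n_perm = 1000,
                            gp_starts = 8,
                            K_max = 12,
                            min_cluster_profiles = 24,
                            run_dynamics = TRUE,
                            run_clustering = TRUE,
                            run_composition = TRUE,
                            run_enrichment = TRUE,
                            seed = 1L) {
  stop_if(padj_threshold <= 0 || padj_threshold > 1,
          "padj_threshold must lie in (0, 1]")
  stop_if(lr_threshold > 0, "lr_threshold must be <= 0")
  stop_if(chi2_alpha <= 0 || chi2_alpha > 1, "chi2_alpha must lie in (0, 1]")
  stop_if(fdr_threshold <= 0 || fdr_threshold > 1,
          "fdr_threshold must lie in (0, 1]")
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Per-pair significant-peak counts (the two-wave summary)
#'
#' @param diff_results named list of per-pair differential tables from
#'   [consecutive_comparisons()].
#' @return data frame: pair, day_a, day_b, n_up, n_down, n_sig
#'   (`n_sig = n_up + n_down`).
#' @export
summarize_wave <- function(diff_results) {
  rows <- lapply(names(diff_results), function(nm) {
    tab <- diff_results[[nm]]
    n_up <- sum(tab$direction == "up_later")
    n_down <- sum(tab$direction == "up_earlier")
    data.frame(pair = nm, day_a = tab$pair_a[1], day_b = tab$pair_b[1],
               n_up = n_up, n_down = n_down, n_sig = n_up + n_down,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Dynamic-fraction summary (doughnut-chart numbers)
#'
#' Percentages of strictly and loosely dynamic peaks among all peaks.
#'
#' @param n_strict,n_loose,n_total peak counts (strict is a subset of
#'   loose).
#' @param digits decimals for the rounded percentage columns.
#' @return one-row data frame: n_total, n_strict, n_loose, strict_pct,
#'   loose_pct (exact), strict_pct_rounded, loose_pct_rounded.
#' @export
dynamic_fraction_summary <- function(n_strict, n_loose, n_total,
                                     digits = c(2, 1)) {
  stop_if(n_strict > n_loose || n_loose > n_total,
          "expected n_strict <= n_loose <= n_total")
  strict_pct <- 100 * n_strict / n_total
  loose_pct <- 100 * n_loose / n_total
  data.frame(n_total = n_total, n_strict = n_strict, n_loose = n_loose,
             strict_pct = strict_pct, loose_pct = loose_pct,
             strict_pct_rounded = round(strict_pct, digits[1]),
             loose_pct_rounded = round(loose_pct, digits[2]))
}

pipeline_log <- function(fmt, ...) {
  message(sprintf("[atacwave %s] %s", format(Sys.time(), "%H:%M:%S"),
                  sprintf(fmt, ...)))
}

# tiny config checksum for the run manifest (not cryptographic)
config_hash <- function(config) {
  json <- jsonlite::toJSON(config[!vapply(config, is.function, TRUE)],
                           auto_unbox = TRUE, force = TRUE, digits = NA)
  sprintf("%08x", sum(utf8ToInt(json) * (seq_along(utf8ToInt(json)) %% 97))
          %% .Machine$integer.max)
}

#' Run the full time-course analysis pipeline
#'
#' Simulates (or loads) a study, then runs differential testing between
#' consecutive days, the GP dynamics test, GP-mixture clustering of
#' loose-dynamic peaks, composition Z tests, and preranked gene-set
#' enrichment with reversibility flags, writing every stage's table plus a
#' summary report and a machine-readable manifest into `out_dir`.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @return invisibly, a list with every stage result (`study`,
#'   `annotations`, `differential`, `wave`, `dynamics`,
#'   `dynamic_fraction`, `clustering`, `cluster_sizes`, `composition`,
#'   `enrichment`, `reversible`, `manifest`).
#' @export
run_full <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    pipeline_log("stage %s ...", name)
    t0 <- Sys.time()
    value <- tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    pipeline_log("stage %s done (%.1fs)", name,
                 as.numeric(difftime(Sys.time(), t0, units = "secs")))
    value
  }

  study <- stage("data", {
    if (!is.null(config$input_dir)) {
      list(counts = read_counts(file.path(config$input_dir, "counts.tsv")),
           samples = read_sample_sheet(file.path(config$input_dir,
                                                 "samples.tsv")),
           peaks = read_bed(file.path(config$input_dir, "peaks.bed")),
           genes = read_gene_table(file.path(config$input_dir,
                                             "genes.tsv")),
           gene_sets = read_gmt(file.path(config$input_dir,
                                          "gene_sets.gmt")))
    } else {
      s <- simulate_study(config$sim)
      write_study(s, file.path(out_dir, "input"))
      s
    }
  })
  res <- list(study = study)

  res$annotations <- stage("annotation", {
    ann <- annotate_peaks(study$peaks, study$genes)
    write_tsv(ann, file.path(out_dir, "annotations.tsv"))
    ann
  })

  res$differential <- stage("differential", {
    d <- consecutive_comparisons(study$counts, study$samples,
                                 pairs = config$pairs,
                                 padj_threshold = config$padj_threshold)
    for (nm in names(d)) {
      write_tsv(d[[nm]], file.path(out_dir, sprintf("differential_%s.tsv",
                                                    nm)))
    }
    d
  })
  res$wave <- summarize_wave(res$differential)
  write_tsv(res$wave, file.path(out_dir, "wave_summary.tsv"))

  size_factors <- size_factors_median_of_ratios(study$counts)

  if (config$run_dynamics) {
    res$dynamics <- stage("dynamics", {
      dyn <- test_dynamics(study$counts, study$samples,
                           size_factors = size_factors,
                           n_starts = config$gp_starts, seed = config$seed,
                           strict_alpha = config$chi2_alpha,
                           loose_lr = config$lr_threshold)
      write_tsv(dyn, file.path(out_dir, "dynamics.tsv"))
      dyn
    })
    res$dynamic_fraction <- dynamic_fraction_summary(
      sum(res$dynamics$dynamic_strict), sum(res$dynamics$dynamic_loose),
      nrow(res$dynamics))
    write_tsv(res$dynamic_fraction,
              file.path(out_dir, "dynamic_fraction.tsv"))
  }

  if (config$run_clustering && config$run_dynamics) {
    loose <- res$dynamics$peak_id[res$dynamics$dynamic_loose]
    if (length(loose) >= config$min_cluster_profiles) {
      res$clustering <- stage("clustering", {
        q <- sweep(study$counts[loose, , drop = FALSE], 2, size_factors,
                   "/")
        times <- study$samples$day[match(colnames(q),
                                         study$samples$sample_id)]
        Y <- t(apply(q, 1, function(x) standardize_profile(x, times)$y))
        rownames(Y) <- loose
        fit <- fit_gp_mixture(Y, times = times, K_max = config$K_max,
                              seed = config$seed)
        write_tsv(fit$result$assignments,
                  file.path(out_dir, "cluster_assignments.tsv"))
        write_tsv(fit$model$curves,
                  file.path(out_dir, "cluster_curves.tsv"))
        fit
      })
      res$cluster_sizes <- cluster_summary(res$clustering)
      write_tsv(res$cluster_sizes, file.path(out_dir,
                                             "cluster_summary.tsv"))
    } else {
      pipeline_log("clustering skipped: only %d loose-dynamic profiles",
                   length(loose))
    }
  }

  if (config$run_composition && config$run_dynamics) {
    res$composition <- stage("composition", {
      flags <- res$dynamics$dynamic_loose[match(res$annotations$peak_id,
                                                res$dynamics$peak_id)]
      comp <- compare_composition(res$annotations, flags)
      write_tsv(comp, file.path(out_dir, "composition.tsv"))
      comp
    })
  }

  if (config$run_enrichment) {
    res$enrichment <- stage("enrichment", {
      collection <- gene_set_collection(study$gene_sets,
                                        study$genes$gene_id)
      out <- list()
      for (pair in config$enrich_pairs) {
        nm <- sprintf("day%g_vs_day%g", pair[1], pair[2])
        tab <- res$differential[[nm]]
        if (is.null(tab)) next
        ranked <- tryCatch(
          build_ranked_list(tab, res$annotations,
                            padj_threshold = config$padj_threshold),
          warning = function(w) NULL)
        if (is.null(ranked) || nrow(ranked) == 0) {
          pipeline_log("enrichment skipped for %s: no significant peaks",
                       nm)
          next
        }
        g <- preranked_gsea(ranked, collection, n_perm = config$n_perm,
                            seed = config$seed,
                            fdr_threshold = config$fdr_threshold)
        write_tsv(g, file.path(out_dir, sprintf("gsea_%s.tsv", nm)))
        out[[nm]] <- g
      }
      out
    })
    if (length(res$enrichment) >= 2) {
      res$reversible <- flag_reversible_sets(res$enrichment[[1]],
                                             res$enrichment[[2]])
      write_tsv(res$reversible, file.path(out_dir, "reversible_sets.tsv"))
    }
  }

  manifest <- list(
    package = "atacwave",
    version = as.character(utils::packageVersion("atacwave")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    config_hash = config_hash(config),
    stages = names(res))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  res$manifest <- manifest

  report <- c(
    "atacwave run summary",
    "====================",
    "",
    if (!is.null(res$dynamic_fraction)) c(
      sprintf("Peaks: %d; strictly dynamic: %d (%.2f%%); loosely dynamic: %d (%.1f%%)",
              res$dynamic_fraction$n_total, res$dynamic_fraction$n_strict,
              res$dynamic_fraction$strict_pct, res$dynamic_fraction$n_loose,
              res$dynamic_fraction$loose_pct), ""),
    "Significant differential peaks per consecutive-day pair:",
    sprintf("  %s: %d up, %d down (%d total)", res$wave$pair,
            res$wave$n_up, res$wave$n_down, res$wave$n_sig),
    "",
    if (!is.null(res$cluster_sizes)) c(
      "Cluster sizes:",
      sprintf("  cluster %d: %d peaks", res$cluster_sizes$cluster,
              res$cluster_sizes$size), ""),
    if (!is.null(res$composition)) c(
      "Composition tests (dynamic vs rest):",
      sprintf("  %s/%s: Z = %.2f, p = %.3g%s", res$composition$axis,
              res$composition$class, res$composition$Z, res$composition$p,
              ifelse(res$composition$significant, " *", "")), ""),
    if (!is.null(res$reversible)) c(
      sprintf("Reversible gene sets: %d of %d shared sets",
              sum(res$reversible$reversible), nrow(res$reversible))))
  writeLines(report, file.path(out_dir, "report.txt"))
  invisible(res)
}
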