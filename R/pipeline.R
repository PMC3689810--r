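#' Pipeline run configuration
#'
#' Bundles the analysis thresholds and the simulation design for a complete
#' run: consensus quality cutoff (Q20, strict), majority fraction (0.8,
#' strict), the minimum polymorphism count per analysed region (50,
#' inclusive), the scaffold length cutoff for X assignment (100 kb,
#' exclusive), the Fst outlier threshold (0.5, inclusive) and the Tajima's-D
#' decile width (0.10).
#'
#' @param sim A [sim_config()] describing the synthetic study design.
#' @param populations Population label per line (defaults to a roughly
#'   half-and-half split emulating two regional collections).
#' @param qmin,majority Consensus rule cutoffs.
#' @param min_S Minimum segregating sites per analysed region/scaffold.
#' @param min_length Minimum scaffold length for X assignment (bp).
#' @param fst_outlier Fst threshold for the outlier gene list.
#' @param decile Tail fraction for the Tajima's-D outlier lists.
#' @param seed Global seed.
#' @return A `run_config` list.
#' @export
run_config <- function(sim = sim_config(),
                       populations = NULL,
                       qmin = 20, majority = 0.8,
                       min_S = 50, min_length = 1e5,
                       fst_outlier = 0.5, decile = 0.10,
                       seed = 1L) {
  if (majority <= 0 || majority >= 1) stop_config("`majority` must lie in (0, 1)")
  if (decile <= 0 || decile >= 0.5) stop_config("`decile` must lie in (0, 0.5)")
  if (min_S < 0 || min_length < 0 || qmin < 0) {
    stop_config("thresholds must be non-negative")
  }
  if (fst_outlier < 0 || fst_outlier > 1) stop_config("`fst_outlier` must lie in [0, 1]")
  populations <- populations %||% rep(c("northeast", "california"),
                                      c(ceiling(sim$n_lines / 2),
                                        floor(sim$n_lines / 2)))
  if (length(populations) != sim$n_lines) {
    stop_config("`populations` must have one label per line")
  }
  structure(
    list(sim = sim, populations = populations, qmin = qmin,
         majority = majority, min_S = min_S, min_length = min_length,
         fst_outlier = fst_outlier, decile = decile, seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Run the full analysis pipeline on a synthetic study
#'
#' Chains the stages: simulate the study (reference, genotypes, sequencing,
#' consensus, per-scaffold and per-region statistics), assign scaffolds to
#' the X or autosomes via corrected differences and the t-mixture, then
#' build the summary artifacts (region summary table, group comparisons,
#' outlier gene lists, depth-ratio check).  When `out_dir` is given, all
#' tables are written as TSV (with a `#`-prefixed provenance header), the
#' mixture fit and provenance as JSON.
#'
#' @param config A [run_config()].
#' @param out_dir Optional output directory.
#' @return An `aphid_pipeline` list with elements `study`, `assignment`,
#'   `region_summary`, `comparisons`, `outliers`, `provenance`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  study <- simulate_study(config$sim, seed = config$seed,
                          populations = config$populations)
  assignment <- assign_x_scaffolds(study, min_length = config$min_length,
                                   min_S = config$min_S)
  regions_kept <- polymorphism_filter(study$regions, config$min_S)
  region_summary <- region_summary_table(regions_kept, assignment$calls)
  comparisons <- dplyr::bind_rows(
    group_comparison_report(regions_kept, grouping = "kind_vs_syn"),
    group_comparison_report(regions_kept, grouping = "x_vs_a",
                            calls = assignment$calls)
  )
  gene_stats <- regions_kept |>
    dplyr::filter(.data$kind == "gene") |>
    dplyr::select("gene_id", "scaffold", "S", "theta_w", "pi",
                  "tajimas_d", "fst")
  outliers <- outlier_gene_lists(gene_stats, fst_threshold = config$fst_outlier,
                                 decile = config$decile)
  provenance <- list(
    package = "aphidpop",
    version = as.character(utils::packageVersion("aphidpop")),
    seed = config$seed,
    config_hash = rlang::hash(config),
    thresholds = config[c("qmin", "majority", "min_S", "min_length",
                          "fst_outlier", "decile")],
    n_scaffolds = nrow(study$scaffolds),
    n_lines = config$sim$n_lines,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  out <- structure(
    list(study = study, assignment = assignment,
         region_summary = region_summary, comparisons = comparisons,
         outliers = outliers, provenance = provenance, config = config),
    class = "aphid_pipeline"
  )
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

#' Write pipeline outputs to a directory
#'
#' @param pipeline An `aphid_pipeline` result.
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_outputs <- function(pipeline, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- pipeline$provenance$config_hash
  write_tsv_commented <- function(tbl, name) {
    path <- file.path(out_dir, name)
    con <- file(path, "w")
    writeLines(sprintf("# aphidpop config_hash=%s seed=%d", hash,
                       pipeline$provenance$seed), con)
    close(con)
    readr::write_tsv(tbl, path, append = TRUE, col_names = TRUE)
    path
  }
  write_tsv_commented(pipeline$study$scaffolds, "scaffold_stats.tsv")
  write_tsv_commented(pipeline$study$regions, "region_stats.tsv")
  write_tsv_commented(pipeline$assignment$calls, "scaffold_x_calls.tsv")
  write_tsv_commented(pipeline$region_summary, "region_summary.tsv")
  write_tsv_commented(pipeline$comparisons, "group_comparisons.tsv")
  write_tsv_commented(pipeline$outliers$high_fst, "high_fst_genes.tsv")
  write_tsv_commented(pipeline$outliers$low_d, "low_tajimas_d_genes.tsv")
  write_tsv_commented(pipeline$outliers$high_d, "high_tajimas_d_genes.tsv")
  jsonlite::write_json(
    c(tidy_fit = list(tidy(pipeline$assignment$fit)),
      glance_fit = list(glance(pipeline$assignment$fit))),
    file.path(out_dir, "mixture_fit.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA
  )
  jsonlite::write_json(pipeline$provenance,
                       file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Region summary table stratified by chromosome class
#'
#' Builds the region-by-stratum summary: for each region kind and each
#' stratum (overall, autosomal, X — stratified by the *predicted* scaffold
#' labels), the mean coverage, Watterson's theta, pi and Tajima's D across
#' genes passing the polymorphism filter.  Strata with no qualifying
#' regions are flagged (`n = 0`, statistics `NA`), never reported as zeros.
#'
#' @param regions Filtered region statistics (see [simulate_study()],
#'   [polymorphism_filter()]).
#' @param calls Scaffold calls from [classify_scaffolds()] /
#'   [assign_x_scaffolds()].
#' @param kinds Region kinds to report.
#' @return Tibble: kind, stratum, n, coverage, theta_w, pi, tajimas_d.
#' @export
region_summary_table <- function(regions, calls,
                                 kinds = c("gene", "cds", "utr5", "utr3",
                                           "intron", "upstream", "downstream")) {
  labelled <- dplyr::left_join(
    regions, dplyr::select(calls, "scaffold", pred_label = "label"),
    by = "scaffold"
  )
  strata <- list(overall = c("A", "X", NA_character_, "unresolved"),
                 autosomal = "A", x = "X")
  rows <- purrr::map(kinds, function(k) {
    purrr::imap_dfr(strata, function(labels, stratum) {
      sub <- labelled |>
        dplyr::filter(.data$kind == k,
                      stratum == "overall" | .data$pred_label %in% labels)
      tibble(kind = k, stratum = stratum, n = nrow(sub),
             coverage = if (nrow(sub)) mean(sub$coverage, na.rm = TRUE) else NA_real_,
             theta_w = if (nrow(sub)) mean(sub$theta_w, na.rm = TRUE) else NA_real_,
             pi = if (nrow(sub)) mean(sub$pi, na.rm = TRUE) else NA_real_,
             tajimas_d = if (nrow(sub)) mean(sub$tajimas_d, na.rm = TRUE) else NA_real_)
    })
  })
  dplyr::bind_rows(rows)
}

#' Group comparisons of Tajima's D (and diversity) across region classes
#'
#' Two groupings are supported: every region kind against synonymous sites
#' (the neutral yardstick), and X-linked against autosomal regions of each
#' kind.  Each comparison reports per-group means with four-standard-error
#' intervals (mean +/- 4 * SD/sqrt(n)) and a two-sided Mann-Whitney p value.
#' Comparisons with an empty group, or a single-element group (SE
#' undefined), are skipped with a note.
#'
#' @param regions Filtered region statistics.
#' @param grouping `"kind_vs_syn"` or `"x_vs_a"`.
#' @param statistic Column to compare (default `"tajimas_d"`).
#' @param calls Scaffold calls (required for `"x_vs_a"`), used to stratify
#'   by predicted label.
#' @return Tibble: comparison, group_a, group_b, n_a, n_b, mean_a, mean_b,
#'   lo/hi four-SE bounds, p, note.
#' @export
group_comparison_report <- function(regions, grouping = c("kind_vs_syn", "x_vs_a"),
                                    statistic = "tajimas_d", calls = NULL) {
  grouping <- match.arg(grouping)
  val <- function(tbl) tbl[[statistic]][is.finite(tbl[[statistic]])]
  four_se <- function(v) if (length(v) > 1) 4 * sd(v) / sqrt(length(v)) else NA_real_
  cmp_row <- function(comparison, ga, gb, va, vb) {
    if (length(va) == 0 || length(vb) == 0) {
      return(tibble(comparison = comparison, group_a = ga, group_b = gb,
                    n_a = length(va), n_b = length(vb),
                    mean_a = NA_real_, mean_b = NA_real_,
                    lo_a = NA_real_, hi_a = NA_real_, lo_b = NA_real_,
                    hi_b = NA_real_, p = NA_real_, note = "empty group"))
    }
    if (length(va) < 2 || length(vb) < 2) {
      return(tibble(comparison = comparison, group_a = ga, group_b = gb,
                    n_a = length(va), n_b = length(vb),
                    mean_a = mean(va), mean_b = mean(vb),
                    lo_a = NA_real_, hi_a = NA_real_, lo_b = NA_real_,
                    hi_b = NA_real_, p = NA_real_,
                    note = "single-element group: SE undefined"))
    }
    p <- mw_test(va, vb)$p
    tibble(comparison = comparison, group_a = ga, group_b = gb,
           n_a = length(va), n_b = length(vb),
           mean_a = mean(va), mean_b = mean(vb),
           lo_a = mean(va) - four_se(va), hi_a = mean(va) + four_se(va),
           lo_b = mean(vb) - four_se(vb), hi_b = mean(vb) + four_se(vb),
           p = p, note = NA_character_)
  }
  if (grouping == "kind_vs_syn") {
    syn <- val(regions[regions$kind == "syn", ])
    kinds <- setdiff(unique(regions$kind), "syn")
    return(dplyr::bind_rows(purrr::map(kinds, function(k) {
      cmp_row(paste0(k, " vs syn"), k, "syn",
              val(regions[regions$kind == k, ]), syn)
    })))
  }
  if (is.null(calls)) stop_input("`calls` is required for the X-vs-autosome grouping")
  labelled <- dplyr::left_join(
    regions, dplyr::select(calls, "scaffold", pred_label = "label"),
    by = "scaffold")
  dplyr::bind_rows(purrr::map(unique(labelled$kind), function(k) {
    sub <- labelled[labelled$kind == k, ]
    cmp_row(paste0(k, ": X vs A"), "X", "A",
            val(sub[!is.na(sub$pred_label) & sub$pred_label == "X", ]),
            val(sub[!is.na(sub$pred_label) & sub$pred_label == "A", ]))
  }))
}

#' Outlier gene lists by Fst and Tajima's D
#'
#' Returns genes with `Fst >= fst_threshold` (inclusive) and the genes in
#' the lowest and highest `decile` of Tajima's D (empirical quantiles with
#' linear interpolation; boundary ties are all included, so a list may
#' slightly exceed the nominal fraction), plus the overlap between the
#' high-Fst and high-D lists.
#'
#' @param gene_stats Tibble with columns gene_id, fst, tajimas_d.
#' @param fst_threshold Fst cutoff (inclusive).
#' @param decile Tail fraction.
#' @return A list: `high_fst`, `low_d`, `high_d` (tibbles), `overlap_n`
#'   (genes in both `high_fst` and `high_d`), `d_range_low`, `d_range_high`.
#' @export
outlier_gene_lists <- function(gene_stats, fst_threshold = 0.5, decile = 0.10) {
  high_fst <- gene_stats |>
    dplyr::filter(is.finite(.data$fst), .data$fst >= fst_threshold) |>
    dplyr::arrange(dplyr::desc(.data$fst))
  d_ok <- gene_stats[is.finite(gene_stats$tajimas_d), , drop = FALSE]
  if (nrow(d_ok) < 10) {
    return(list(high_fst = high_fst, low_d = NULL, high_d = NULL,
                overlap_n = NA_integer_, d_range_low = NULL, d_range_high = NULL,
                note = "fewer than 10 genes with defined D: decile lists skipped"))
  }
  q_lo <- quantile(d_ok$tajimas_d, decile, type = 7, names = FALSE)
  q_hi <- quantile(d_ok$tajimas_d, 1 - decile, type = 7, names = FALSE)
  low_d <- dplyr::arrange(d_ok[d_ok$tajimas_d <= q_lo, ], .data$tajimas_d)
  high_d <- dplyr::arrange(d_ok[d_ok$tajimas_d >= q_hi, ],
                           dplyr::desc(.data$tajimas_d))
  list(high_fst = high_fst, low_d = low_d, high_d = high_d,
       overlap_n = length(intersect(high_fst$gene_id, high_d$gene_id)),
       d_range_low = range(low_d$tajimas_d),
       d_range_high = range(high_d$tajimas_d))
}
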