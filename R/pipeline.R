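#' Per-archetype recovery of planted profiles
#'
#' Compares gene-level profile calls against the planted truth of a
#' simulated study. A gene counts as recovered when its (non-ambiguous)
#' call equals the class implied by its archetype (`up -> UP`,
#' `up_down -> UP_DOWN`, `down -> DOWN`, `flat -> UNCLASSIFIED`); genes
#' missing from `gene_calls` count as `UNCLASSIFIED`.
#'
#' @param truth Truth table of [simulate_study()] (`gene_id`, `archetype`).
#' @param gene_calls Gene-level calls (`gene_id`, `call`, optional
#'   `ambiguous`).
#' @return A tibble `archetype`, `n`, `n_recovered`, `recovery`.
#' @export
archetype_recovery <- function(truth, gene_calls) {
  expected <- c(up = "UP", up_down = "UP_DOWN", down = "DOWN",
                flat = "UNCLASSIFIED")
  calls <- dplyr::mutate(
    gene_calls,
    call = ifelse(!is.na(.data$call), .data$call, "AMBIGUOUS")
  )
  joined <- dplyr::left_join(
    dplyr::select(truth, "gene_id", "archetype"),
    dplyr::select(calls, "gene_id", "call"),
    by = "gene_id"
  )
  joined$call[is.na(joined$call)] <- "UNCLASSIFIED"
  dplyr::summarise(
    dplyr::group_by(joined, .data$archetype),
    n = dplyr::n(),
    n_recovered = sum(.data$call == expected[.data$archetype[1]]),
    recovery = .data$n_recovered / .data$n,
    .groups = "drop"
  )
}

#' Run the full cross-species analysis on a simulated study
#'
#' Orchestrates every stage of the pipeline on a [simulate_study()] result:
#' moderated stage-transition tests and profile classification on both
#' human arrays, cross-dataset intersection and probe-to-gene collapse, the
#' mouse qPCR \eqn{-\Delta}Ct pipeline (control normalisation, floor
#' imputation, stage averages, Student stage-pair tests), the RPKM
#' fold-change screens, ortholog concordance classification, cross-platform
#' stage correlations and hierarchical clustering of the human profiles.
#'
#' @param study A `simulated_study` (or `NULL` to simulate from `config`).
#' @param config A [sim_config()] used when `study` is `NULL`.
#' @param alpha Raw-p threshold for qPCR and RPKM significance.
#' @param q_threshold q-value threshold for microarray significance.
#' @param method Test for the arrays: `"moderated"` or `"student"`.
#' @param fc_threshold,pseudocount RPKM screen parameters.
#' @param relax_updown Passed to [classify_concordance()].
#' @param welch Use Welch instead of pooled tests throughout.
#' @param out_dir Optional directory; when given, result tables are written
#'   as TSV and the report as JSON.
#' @return A list of class `pipeline_report`; see [glance.pipeline_report()]
#'   for the one-row summary.
#' @export
run_pipeline <- function(study = NULL, config = sim_config(),
                         alpha = 0.05, q_threshold = 0.05,
                         method = "moderated",
                         fc_threshold = 5, pseudocount = 0.1,
                         relax_updown = FALSE, welch = FALSE,
                         out_dir = NULL) {
  stopifnot(alpha > 0, alpha < 1, q_threshold > 0, q_threshold < 1,
            fc_threshold > 0, pseudocount >= 0)
  study <- study %||% simulate_study(config)

  # human arrays: DE, classify, intersect, collapse
  design_a <- attr(study$human_array_a, "design")
  design_b <- attr(study$human_array_b, "design")
  tests_a <- transition_tests(study$human_array_a, design_a, method = method,
                              welch = welch)
  tests_b <- transition_tests(study$human_array_b, design_b, method = method,
                              welch = welch)
  calls_a <- classify_profiles(tests_a, design_a, alpha = q_threshold)
  calls_b <- classify_profiles(tests_b, design_b, alpha = q_threshold)
  consensus <- suppressMessages(intersect_datasets(calls_a, calls_b))
  genes <- collapse_probes_to_genes(consensus, study$probe_map)
  genes_a <- collapse_probes_to_genes(calls_a, study$probe_map)

  # mouse qPCR
  ndct <- impute_undetected(
    neg_delta_ct(study$mouse_ct, c("Hprt1", "Psmb6"))
  )
  mouse_tests <- stage_pair_tests(ndct, welch = welch)
  mouse_avg <- qpcr_stage_averages(ndct)

  # concordance on planted (non-flat) pairs with classified human genes
  pairs <- suppressMessages(map_orthologs(
    dplyr::filter(genes, !.data$ambiguous, !is.na(.data$call)),
    study$ortholog_map
  ))
  verdicts <- classify_concordance(pairs, mouse_tests, alpha = alpha,
                                   relax_updown = relax_updown)

  # RPKM screens on the human sequencing matrix
  rpkm_design <- attr(study$human_rpkm, "design")
  early <- design_stages(rpkm_design)[1]
  fc_4c <- fold_change_filter(study$human_rpkm, rpkm_design, early, "4cell",
                              pseudocount, fc_threshold, alpha, welch)
  fc_8c <- fold_change_filter(study$human_rpkm, rpkm_design, early, "8cell",
                              pseudocount, fc_threshold, alpha, welch)

  # cross-platform correlation: mouse -dCt averages vs ln(RPKM+1) averages
  mouse_avg_wide <- tidyr::pivot_wider(
    dplyr::mutate(mouse_avg, stage = as.character(.data$stage)),
    id_cols = "assay_id", names_from = "stage", values_from = "mean_ndct"
  )
  mouse_avg_wide <- dplyr::rename(mouse_avg_wide, feature_id = "assay_id")
  mouse_ln <- stage_means(ln_rpkm_transform(study$mouse_rpkm),
                          attr(study$mouse_rpkm, "design"))
  correlations <- pearson_stage_correlation(mouse_avg_wide, mouse_ln)

  # unsupervised clustering of human gene profiles (dataset A averages)
  clusters <- hierarchical_cluster(
    stage_means(study$human_array_a, design_a), k = 3
  )

  recovery <- archetype_recovery(study$truth, genes_a)
  classified <- verdicts$verdict != "UNCLASSIFIED"
  report <- list(
    config = study$config,
    transitions = list(a = tests_a, b = tests_b),
    calls = list(a = calls_a, b = calls_b, consensus = consensus,
                 genes = genes, genes_a = genes_a),
    qpcr = list(ndct = ndct, tests = mouse_tests, averages = mouse_avg,
                floor_value = attr(ndct, "floor_value")),
    rpkm = list(fc_4cell = fc_4c, fc_8cell = fc_8c),
    concordance = verdicts,
    correlations = correlations,
    clusters = clusters,
    recovery = recovery,
    tallies = list(
      consensus_counts = attr(genes, "class_counts"),
      n_pairs = nrow(verdicts),
      n_similar = sum(verdicts$verdict == "SIMILAR"),
      n_different = sum(verdicts$verdict == "DIFFERENT_MATERNAL"),
      similar_fraction_classified =
        if (any(classified)) mean(verdicts$verdict[classified] == "SIMILAR")
        else NA_real_,
      n_upregulated_4cell = sum(fc_4c$passed),
      n_upregulated_8cell = sum(fc_8c$passed)
    )
  )
  class(report) <- "pipeline_report"
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat("  archetype recovery:\n")
  for (i in seq_len(nrow(x$recovery))) {
    cat(sprintf("    %-8s %5.1f%% (%d/%d)\n", x$recovery$archetype[i],
                100 * x$recovery$recovery[i], x$recovery$n_recovered[i],
                x$recovery$n[i]))
  }
  cat(sprintf("  concordance: %d SIMILAR / %d DIFFERENT_MATERNAL of %d pairs\n",
              x$tallies$n_similar, x$tallies$n_different, x$tallies$n_pairs))
  cat(sprintf("  RPKM screens: %d (4-cell), %d (8-cell) genes passed\n",
              x$tallies$n_upregulated_4cell, x$tallies$n_upregulated_8cell))
  invisible(x)
}

#' One-row summary of a pipeline report
#'
#' @param x A `pipeline_report` from [run_pipeline()].
#' @param ... Unused.
#' @return A one-row tibble of headline tallies.
#' @method glance pipeline_report
#' @export
glance.pipeline_report <- function(x, ...) {
  rec <- setNames(x$recovery$recovery, x$recovery$archetype)
  tibble::tibble(
    recovery_up = rec[["up"]],
    recovery_up_down = rec[["up_down"]],
    recovery_down = rec[["down"]],
    flat_unclassified = rec[["flat"]],
    similar_fraction = x$tallies$similar_fraction_classified,
    n_pairs = x$tallies$n_pairs,
    qpcr_floor = x$qpcr$floor_value,
    n_upregulated_4cell = x$tallies$n_upregulated_4cell,
    n_upregulated_8cell = x$tallies$n_upregulated_8cell
  )
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(dplyr::bind_rows(a = report$transitions$a,
                                    b = report$transitions$b,
                                    .id = "dataset"),
                   file.path(out_dir, "transitions.tsv"), progress = FALSE)
  readr::write_tsv(dplyr::select(report$calls$genes, -dplyr::any_of("evidence")),
                   file.path(out_dir, "gene_calls.tsv"), progress = FALSE)
  readr::write_tsv(report$concordance, file.path(out_dir, "concordance.tsv"),
                   progress = FALSE)
  readr::write_tsv(report$qpcr$tests, file.path(out_dir, "mouse_tests.tsv"),
                   progress = FALSE)
  readr::write_tsv(report$correlations, file.path(out_dir, "correlations.tsv"),
                   progress = FALSE)
  summary <- c(
    as.list(glance(report)),
    list(recovery = report$recovery,
         consensus_counts = report$tallies$consensus_counts)
  )
  jsonlite::write_json(summary, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(out_dir)
}
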