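#' \eqn{-\Delta}Ct values against endogenous controls
#'
#' Computes, per reaction, `-dCt = -(Ct_gene - mean(Ct_controls))` within
#' the same sample, so higher values mean more transcript. Undetected
#' reactions enter the arithmetic with the instrument limit Ct (40.0 by
#' default, carried on the table) and are flagged for floor imputation by
#' [impute_undetected()]. The transform removes per-sample offsets: adding
#' a constant to every Ct of a sample leaves the result unchanged.
#'
#' @param ct A `ct_table` (see [read_ct_table()] / [simulate_study()]).
#' @param control_assays Assay IDs of the endogenous controls (e.g.
#'   `c("Hprt1", "Psmb6")`); they must be detected in every sample.
#' @param ct_limit Ct substituted for undetected reactions (default 40).
#' @return A tibble of class `ndct_table` with columns `assay_id`,
#'   `sample`, `stage`, `replicate`, `neg_delta_ct`, `detected`, `imputed`
#'   and attributes `"design"`, `"protocol"`, `"control_assays"`,
#'   `"floor_value"` (`NA` until imputation).
#' @export
neg_delta_ct <- function(ct, control_assays, ct_limit = 40) {
  missing <- setdiff(control_assays, unique(ct$assay_id))
  if (length(missing) > 0) {
    stop("Control assays absent from table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ctrl <- dplyr::filter(ct, .data$assay_id %in% control_assays)
  bad <- dplyr::filter(ctrl, !.data$detected)
  if (nrow(bad) > 0) {
    stop("Endogenous control undetected in sample(s): ",
         paste(unique(bad$sample), collapse = ", "), call. = FALSE)
  }
  ctrl_mean <- dplyr::summarise(dplyr::group_by(ctrl, .data$sample),
                                ctrl_mean = mean(.data$ct), .groups = "drop")
  out <- dplyr::left_join(tibble::as_tibble(ct), ctrl_mean, by = "sample")
  out <- dplyr::mutate(
    out,
    neg_delta_ct = -(ifelse(.data$detected, .data$ct, ct_limit) - .data$ctrl_mean),
    imputed = FALSE
  )
  out <- dplyr::select(out, "assay_id", "sample", "stage", "replicate",
                       "neg_delta_ct", "detected", "imputed")
  attr(out, "design") <- attr(ct, "design")
  attr(out, "protocol") <- attr(ct, "protocol")
  attr(out, "control_assays") <- control_assays
  attr(out, "floor_value") <- NA_real_
  class(out) <- c("ndct_table", class(out))
  out
}

#' Floor-impute undetected \eqn{-\Delta}Ct values
#'
#' Sets every undetected reaction to the lowest calculated \eqn{-\Delta}Ct
#' among the detected reactions of the same protocol (the table is one
#' protocol). Control assays are excluded from the floor computation —
#' being the normalisation reference they sit near 0 by construction.
#'
#' @param table An `ndct_table` from [neg_delta_ct()].
#' @return The table with undetected cells set to the floor and flagged
#'   `imputed`; the floor is stored in attribute `"floor_value"`.
#' @export
impute_undetected <- function(table) {
  stopifnot(inherits(table, "ndct_table"))
  controls <- attr(table, "control_assays") %||% character(0)
  eligible <- table$detected & !table$assay_id %in% controls
  if (!any(eligible)) {
    stop("No detected non-control reactions; cannot compute an imputation floor.",
         call. = FALSE)
  }
  floor_value <- min(table$neg_delta_ct[eligible])
  out <- dplyr::mutate(
    table,
    imputed = !.data$detected,
    neg_delta_ct = ifelse(.data$detected, .data$neg_delta_ct, floor_value)
  )
  attr(out, "floor_value") <- floor_value
  out
}

#' Per-stage average \eqn{-\Delta}Ct for plotting
#'
#' Averages detected replicates only; a (assay, stage) cell whose
#' replicates are all undetected is reported at the imputation floor. This
#' plotting policy deliberately differs from the testing policy of
#' [stage_pair_tests()], which keeps imputed values in the arithmetic.
#'
#' @param table An imputed `ndct_table` (see [impute_undetected()]).
#' @return A tibble `assay_id` x `stage` with columns `mean_ndct`,
#'   `n_detected`, `all_undetected`.
#' @export
qpcr_stage_averages <- function(table) {
  stopifnot(inherits(table, "ndct_table"))
  floor_value <- attr(table, "floor_value")
  out <- dplyr::summarise(
    dplyr::group_by(table, .data$assay_id, .data$stage),
    n_detected = sum(.data$detected),
    all_undetected = !any(.data$detected),
    mean_ndct = if (any(.data$detected)) {
      mean(.data$neg_delta_ct[.data$detected])
    } else floor_value,
    .groups = "drop"
  )
  dplyr::select(out, "assay_id", "stage", "mean_ndct", "n_detected",
                "all_undetected")
}

#' Stage-pair Student t-tests on \eqn{-\Delta}Ct values
#'
#' Pooled-variance two-sided t-tests per assay for the requested stage
#' pairs. Imputed (floored) values are included in the test arithmetic, but
#' a pair is only tested when both stages have at least two *detected*
#' replicates; otherwise it is reported `skipped`.
#'
#' @param table An imputed `ndct_table`.
#' @param pairs Tibble of stage pairs (`earlier`, `later`); defaults to the
#'   design's consecutive pairs (MII vs 1-cell, 1-cell vs 2-cell,
#'   2-cell vs 8-cell for the default mouse design).
#' @param welch Use the Welch statistic instead of the pooled one.
#' @return A [transition_tests()]-shaped tibble (`feature_id` holds the
#'   assay ID; q-values are BH within each stage pair).
#' @export
stage_pair_tests <- function(table, pairs = NULL, welch = FALSE) {
  stopifnot(inherits(table, "ndct_table"))
  design <- attr(table, "design")
  pairs <- pairs %||% stage_pairs(design)
  bad <- setdiff(c(pairs$earlier, pairs$later), design_stages(design))
  if (length(bad) > 0) {
    stop("Unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  # detectability gate, per assay and stage
  det <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(table), .data$assay_id, .data$stage),
    n_detected = sum(.data$detected), .groups = "drop"
  )
  det$stage <- as.character(det$stage)
  wide <- tidyr::pivot_wider(
    tibble::as_tibble(table),
    id_cols = "assay_id", names_from = "sample",
    values_from = "neg_delta_ct"
  )
  res <- transition_tests(
    dplyr::rename(wide, feature_id = "assay_id"),
    design, method = "student", welch = welch, pairs = pairs
  )
  res <- dplyr::left_join(
    res,
    dplyr::rename(det, feature_id = "assay_id", n_det_earlier = "n_detected"),
    by = c("feature_id", earlier = "stage")
  )
  res <- dplyr::left_join(
    res,
    dplyr::rename(det, feature_id = "assay_id", n_det_later = "n_detected"),
    by = c("feature_id", later = "stage")
  )
  res <- dplyr::mutate(
    res,
    status = ifelse(.data$n_det_earlier >= 2 & .data$n_det_later >= 2,
                    .data$status, "skipped"),
    log_fc = ifelse(.data$status == "tested", .data$log_fc, NA_real_),
    t_stat = ifelse(.data$status == "tested", .data$t_stat, NA_real_),
    df = ifelse(.data$status == "tested", .data$df, NA_real_),
    p_value = ifelse(.data$status == "tested", .data$p_value, NA_real_)
  )
  # recompute q within family over the surviving tests
  res <- dplyr::mutate(
    dplyr::group_by(res, .data$earlier, .data$later),
    q_value = {
      q <- rep(NA_real_, dplyr::n())
      ok <- .data$status == "tested"
      if (any(ok)) q[ok] <- bh_fdr(.data$p_value[ok])
      q
    }
  )
  dplyr::select(dplyr::ungroup(res), -"n_det_earlier", -"n_det_later")
}
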