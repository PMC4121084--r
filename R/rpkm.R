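#' Fold-change + significance filter on RPKM values
#'
#' Implements the sequencing-dataset upregulation screen: a pseudocount
#' (0.1 by default) is added to every RPKM value, the ratio of late- to
#' early-stage means is computed, and a two-sided pooled t-test is run on
#' the pseudocounted replicate values. A gene passes when its ratio
#' strictly exceeds `fc_threshold` (default 5, "more than 5 times") and
#' its p-value is at or below `alpha`.
#'
#' @param rpkm Wide non-negative RPKM tibble (`feature_id` + samples).
#' @param design A [stage_design()] for the sample columns.
#' @param early_stage,late_stage Stage names to compare (e.g. oocyte vs
#'   4-cell).
#' @param pseudocount Value added to every RPKM before analysis.
#' @param fc_threshold Ratio that must be strictly exceeded.
#' @param alpha Significance threshold on the raw p-value.
#' @param welch Use the Welch statistic instead of the pooled one.
#' @return A tibble with `gene_id`, `mean_early`, `mean_late`, `ratio`,
#'   `p_value`, `passed`, ordered as the input.
#' @export
fold_change_filter <- function(rpkm, design, early_stage, late_stage,
                               pseudocount = 0.1, fc_threshold = 5,
                               alpha = 0.05, welch = FALSE) {
  stages <- design_stages(design)
  if (!early_stage %in% stages || !late_stage %in% stages) {
    stop("Stages must belong to the design.", call. = FALSE)
  }
  rpkm <- align_to_design(rpkm, design)
  mat <- as.matrix(rpkm[, setdiff(names(rpkm), "feature_id")])
  if (any(mat < 0)) stop("Negative RPKM values.", call. = FALSE)
  mat <- mat + pseudocount
  c1 <- design$sample[design$stage == early_stage]
  c2 <- design$sample[design$stage == late_stage]
  if (length(c1) < 2 || length(c2) < 2) {
    stop("Both stages need at least two replicates.", call. = FALSE)
  }
  wide <- tibble::as_tibble(as.data.frame(mat[, c(c1, c2), drop = FALSE]))
  wide <- tibble::add_column(wide, feature_id = rpkm$feature_id, .before = 1)
  sub_design <- stage_design(c(early_stage, late_stage),
                             c(length(c1), length(c2)),
                             design_species(design))
  names(wide) <- c("feature_id", sub_design$sample)
  tests <- transition_tests(wide, sub_design, method = "student",
                            welch = welch)
  m1 <- rowMeans(mat[, c1, drop = FALSE])
  m2 <- rowMeans(mat[, c2, drop = FALSE])
  ratio <- m2 / m1
  p <- tests$p_value[match(rpkm$feature_id, tests$feature_id)]
  tibble::tibble(
    gene_id = rpkm$feature_id,
    mean_early = m1,
    mean_late = m2,
    ratio = ratio,
    p_value = p,
    passed = ratio > fc_threshold & !is.na(p) & p <= alpha
  )
}

#' ln(RPKM + 1) transform
#'
#' The plotting transform for sequencing data: `value -> ln(value + 1)`,
#' strictly increasing and 0 at RPKM 0. Note the plotting pseudocount (1)
#' is distinct from the filtering pseudocount (0.1) of
#' [fold_change_filter()].
#'
#' @param rpkm Wide non-negative RPKM tibble.
#' @return The transformed tibble (attribute `"scale"` set to
#'   `"ln_rpkm_plus1"`).
#' @export
ln_rpkm_transform <- function(rpkm) {
  cols <- setdiff(names(rpkm), "feature_id")
  mat <- as.matrix(rpkm[, cols])
  if (any(mat < 0)) stop("Negative RPKM values.", call. = FALSE)
  out <- rpkm
  out[cols] <- as.data.frame(log(mat + 1))
  attr(out, "scale") <- "ln_rpkm_plus1"
  attr(out, "design") <- attr(rpkm, "design")
  out
}

#' Per-stage average expression
#'
#' Averages same-stage replicate columns of a wide expression tibble on
#' its current scale.
#'
#' @param data Wide expression tibble (`feature_id` + samples).
#' @param design A [stage_design()] for the sample columns.
#' @return A tibble `feature_id` + one column per stage.
#' @export
stage_means <- function(data, design) {
  data <- align_to_design(data, design)
  mat <- as.matrix(data[, setdiff(names(data), "feature_id")])
  out <- vapply(design_stages(design), function(s) {
    rowMeans(mat[, design$sample[design$stage == s], drop = FALSE])
  }, numeric(nrow(mat)))
  out <- tibble::as_tibble(as.data.frame(out))
  tibble::add_column(out, feature_id = data$feature_id, .before = 1)
}
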