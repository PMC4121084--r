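#' Classify features into Up / Up-down / Down expression profiles
#'
#' Turns per-transition test results into one of the three canonical
#' preimplantation expression profiles. A transition counts as a
#' significant increase (decrease) when its `log_fc` is positive (negative)
#' and its significance value is at or below `alpha`.
#'
#' * `UP_DOWN`: a significant increase into a ZGA-window stage followed by
#'   a later significant decrease into a late-window stage.
#' * `UP`: a significant increase into a ZGA-window stage with no
#'   subsequent significant decrease.
#' * `DOWN` (maternal): at least one significant decrease with no earlier
#'   significant increase — maternal transcripts are "down by" the late
#'   stages, so the qualifying decrease may occur at any transition.
#' * `UNCLASSIFIED` otherwise.
#'
#' Precedence is `UP_DOWN > UP > DOWN`: up-down is the only class needing
#' both signals, so it is tested first.
#'
#' @param transitions A [transition_tests()] tibble (one or many features).
#' @param design The [stage_design()] the transitions were computed on.
#' @param zga_window Stages whose incoming increase counts as a ZGA
#'   upregulation; defaults to the stages named `4cell`/`8cell` (human) or
#'   `2cell` (mouse) present in the design.
#' @param late_window Stages whose incoming decrease counts as late
#'   downregulation; defaults to the last two stages of the design.
#' @param sig_col Column holding the significance value: `"q_value"`
#'   (microarray convention) or `"p_value"` (qPCR/RPKM convention).
#' @param alpha Significance threshold (default 0.05).
#' @return A tibble with one row per feature: `feature_id`, `call` and a
#'   list-column `evidence` of the significant transitions
#'   (`earlier`, `later`, `direction`, `sig`).
#' @export
classify_profiles <- function(transitions, design,
                              zga_window = NULL, late_window = NULL,
                              sig_col = c("q_value", "p_value"),
                              alpha = 0.05) {
  sig_col <- match.arg(sig_col)
  stages <- design_stages(design)
  zga_window <- zga_window %||% (
    if (design_species(design) == "mouse") intersect(c("1cell", "2cell"), stages)
    else intersect(c("4cell", "8cell"), stages)
  )
  late_window <- late_window %||% tail(stages, 2)
  if (!all(zga_window %in% stages) || !all(late_window %in% stages)) {
    stop("zga_window/late_window stages must belong to the design.",
         call. = FALSE)
  }
  tr <- dplyr::mutate(
    transitions,
    later_idx = match(.data$later, stages),
    sig = .data[[sig_col]],
    significant = .data$status == "tested" & !is.na(.data$sig) &
      .data$sig <= alpha & .data$log_fc != 0,
    direction = dplyr::case_when(.data$log_fc > 0 ~ "up",
                                 .data$log_fc < 0 ~ "down",
                                 TRUE ~ "none")
  )
  classify_one <- function(d) {
    d <- d[order(d$later_idx), ]
    sig_up <- d$significant & d$direction == "up"
    sig_down <- d$significant & d$direction == "down"
    zga_up <- sig_up & d$later %in% zga_window
    late_down <- sig_down & d$later %in% late_window
    call <- "UNCLASSIFIED"
    if (any(zga_up) &&
        any(late_down & d$later_idx > min(d$later_idx[zga_up]))) {
      call <- "UP_DOWN"
    } else if (any(zga_up) &&
               !any(sig_down & d$later_idx > min(d$later_idx[zga_up]))) {
      call <- "UP"
    } else if (any(sig_down) &&
               !any(sig_up & d$later_idx < min(d$later_idx[sig_down]))) {
      call <- "DOWN"
    }
    ev <- d[d$significant, c("earlier", "later", "direction", "sig")]
    tibble::tibble(call = call, evidence = list(ev))
  }
  out <- dplyr::reframe(dplyr::group_by(tr, .data$feature_id),
                        classify_one(dplyr::pick(dplyr::everything())))
  dplyr::ungroup(out)
}

#' Intersect profile calls from two independent datasets
#'
#' Keeps a feature only when both datasets assign it the same non-trivial
#' class, the conservative consensus rule for combining two independent
#' studies of the same platform.
#'
#' @param calls_a,calls_b [classify_profiles()] tibbles sharing a feature
#'   ID space.
#' @return Consensus tibble (`feature_id`, `call`) restricted to agreeing,
#'   classified features; per-class counts are reported via `message()`.
#' @export
intersect_datasets <- function(calls_a, calls_b) {
  joined <- dplyr::inner_join(
    dplyr::select(calls_a, "feature_id", call_a = "call"),
    dplyr::select(calls_b, "feature_id", call_b = "call"),
    by = "feature_id"
  )
  consensus <- dplyr::filter(joined, .data$call_a == .data$call_b,
                             .data$call_a != "UNCLASSIFIED")
  out <- dplyr::select(consensus, "feature_id", call = "call_a")
  counts <- table(factor(out$call, levels = c("UP", "UP_DOWN", "DOWN")))
  message(sprintf("Consensus: %d UP, %d UP_DOWN, %d DOWN (of %d shared features)",
                  counts[["UP"]], counts[["UP_DOWN"]], counts[["DOWN"]],
                  nrow(joined)))
  out
}

#' Collapse probe-level profile calls to gene level
#'
#' A gene takes class `C` when at least one of its probes carries consensus
#' call `C`. Genes whose probes fall in conflicting classes are flagged
#' ambiguous and excluded from the per-class counts rather than silently
#' resolved.
#'
#' @param calls Probe-level consensus calls (`feature_id`, `call`).
#' @param probe_map Tibble with columns `probe_id` and `gene_id` covering
#'   every probe in `calls`.
#' @return A tibble with `gene_id`, `call` (`NA` for ambiguous genes),
#'   `ambiguous` and `n_probes`; per-class probe and gene counts are
#'   attached as attribute `"class_counts"`.
#' @export
collapse_probes_to_genes <- function(calls, probe_map) {
  missing <- setdiff(calls$feature_id, probe_map$probe_id)
  if (length(missing) > 0) {
    stop("Probes missing from probe_map: ",
         paste(head(missing, 10), collapse = ", "), call. = FALSE)
  }
  mapped <- dplyr::mutate(
    calls,
    gene_id = probe_map$gene_id[match(.data$feature_id, probe_map$probe_id)]
  )
  genes <- dplyr::summarise(
    dplyr::group_by(mapped, .data$gene_id),
    n_probes = dplyr::n(),
    n_classes = dplyr::n_distinct(.data$call),
    call = ifelse(dplyr::n_distinct(.data$call) == 1, .data$call[1], NA_character_),
    .groups = "drop"
  )
  genes <- dplyr::mutate(genes, ambiguous = .data$n_classes > 1,
                         n_classes = NULL)
  probe_counts <- table(factor(mapped$call, c("UP", "UP_DOWN", "DOWN")))
  gene_counts <- table(factor(genes$call[!genes$ambiguous],
                              c("UP", "UP_DOWN", "DOWN")))
  attr(genes, "class_counts") <- tibble::tibble(
    call = c("UP", "UP_DOWN", "DOWN"),
    n_probes = as.integer(probe_counts),
    n_genes = as.integer(gene_counts)
  )
  genes
}
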