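#' Build a stage design
#'
#' A stage design records the ordered developmental stages of a study, how
#' many biological replicates each stage has, and which species the design
#' describes. It is the single source of truth for mapping sample columns to
#' `(stage, replicate)` pairs: samples are named `"<stage>_<replicate>"` and
#' all stage comparisons use the declared order, never lexical order.
#'
#' @param stages Character vector of unique stage names, in developmental
#'   order (e.g. `c("MII", "4cell", "8cell", "blastocyst")`).
#' @param replicates Integer vector of replicate counts, either length 1
#'   (recycled) or one count per stage.
#' @param species Species label, `"human"` or `"mouse"`.
#'
#' @return A tibble of class `stage_design` with one row per sample and
#'   columns `sample`, `stage` (factor with levels in developmental order)
#'   and `replicate`.
#'
#' @examples
#' stage_design(c("MII", "1cell", "2cell", "8cell"), c(2, 2, 3, 3), "mouse")
#' @export
stage_design <- function(stages, replicates = 3L, species = c("human", "mouse")) {
  species <- match.arg(species)
  if (length(stages) == 0) stop("`stages` must be non-empty.", call. = FALSE)
  if (anyDuplicated(stages)) stop("`stages` must be unique.", call. = FALSE)
  if (length(replicates) == 1) replicates <- rep(replicates, length(stages))
  if (length(replicates) != length(stages)) {
    stop("`replicates` must have length 1 or one entry per stage.", call. = FALSE)
  }
  replicates <- as.integer(replicates)
  if (any(is.na(replicates)) || any(replicates < 1)) {
    stop("Replicate counts must be positive integers.", call. = FALSE)
  }
  design <- tibble::tibble(
    stage = factor(rep(stages, replicates), levels = stages),
    replicate = unlist(lapply(replicates, seq_len), use.names = FALSE)
  )
  design <- tibble::add_column(
    design,
    sample = paste(as.character(design$stage), design$replicate, sep = "_"),
    .before = 1
  )
  attr(design, "species") <- species
  class(design) <- c("stage_design", class(design))
  design
}

#' @export
print.stage_design <- function(x, ...) {
  cat(sprintf(
    "<stage_design> %s: %s (%d samples)\n",
    attr(x, "species"),
    paste(levels(x$stage), collapse = " > "),
    nrow(x)
  ))
  NextMethod()
}

design_stages <- function(design) levels(design$stage)

design_species <- function(design) attr(design, "species") %||% "human"

#' Consecutive stage pairs of a design
#'
#' @param design A [stage_design()].
#' @return A tibble with columns `earlier` and `later`, one row per
#'   consecutive pair in developmental order.
#' @export
stage_pairs <- function(design) {
  st <- design_stages(design)
  if (length(st) < 2) stop("Design needs at least two stages.", call. = FALSE)
  tibble::tibble(earlier = st[-length(st)], later = st[-1])
}

# Checks that the non-feature columns of a wide table are exactly the
# design's samples; returns the table with sample columns in design order.
align_to_design <- function(data, design, id_col = "feature_id") {
  sample_cols <- setdiff(names(data), id_col)
  missing <- setdiff(design$sample, sample_cols)
  extra <- setdiff(sample_cols, design$sample)
  if (length(missing) > 0 || length(extra) > 0) {
    msg <- "Sample columns do not match the design."
    if (length(missing) > 0) {
      msg <- paste0(msg, " Missing (stage_replicate): ",
                    paste(missing, collapse = ", "), ".")
    }
    if (length(extra) > 0) {
      msg <- paste0(msg, " Unexpected: ", paste(extra, collapse = ", "), ".")
    }
    stop(msg, call. = FALSE)
  }
  dplyr::select(data, dplyr::all_of(c(id_col, design$sample)))
}
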