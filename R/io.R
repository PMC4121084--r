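#' Read a stage-structured expression matrix from TSV
#'
#' Reads a tab-delimited table whose first column holds feature identifiers
#' (probes or genes) and whose remaining columns are samples named
#' `"<stage>_<replicate>"`. Columns are checked against the design and
#' reordered to match it; positional inference is refused, so a file whose
#' header does not name every `(stage, replicate)` of the design is an error.
#'
#' @param path Path to a TSV file (UTF-8, `.` decimal separator).
#' @param design A [stage_design()] describing the expected samples.
#' @param scale Scale tag recorded on the result: `"linear"`, `"log2"`,
#'   `"neg_delta_ct"` or `"ln_rpkm_plus1"`.
#'
#' @return A tibble with column `feature_id` followed by one numeric column
#'   per sample, in design order; the design and scale are attached as
#'   attributes `"design"` and `"scale"`.
#'
#' @seealso [write_expression_matrix()] for the exact inverse.
#' @export
read_expression_matrix <- function(path, design,
                                   scale = c("linear", "log2",
                                             "neg_delta_ct", "ln_rpkm_plus1")) {
  scale <- match.arg(scale)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(raw) < 2) stop("Expression TSV needs a feature column and >=1 sample.", call. = FALSE)
  names(raw)[1] <- "feature_id"
  dup <- unique(raw$feature_id[duplicated(raw$feature_id)])
  if (length(dup) > 0) {
    stop("Duplicated feature IDs: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  for (col in setdiff(names(raw), "feature_id")) {
    parsed <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(parsed) & !is.na(raw[[col]]))
    if (length(bad) > 0) {
      stop(sprintf(
        "Non-numeric value '%s' at row %d (feature '%s'), column '%s' of %s.",
        raw[[col]][bad[1]], bad[1], raw$feature_id[bad[1]], col, path
      ), call. = FALSE)
    }
    if (anyNA(parsed)) {
      stop(sprintf("Missing value in column '%s' of %s; expression matrices must be complete.",
                   col, path), call. = FALSE)
    }
    raw[[col]] <- parsed
  }
  out <- align_to_design(raw, design)
  attr(out, "design") <- design
  attr(out, "scale") <- scale
  out
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression_matrix()]: feature IDs round-trip exactly and
#' numeric values round-trip to full double precision.
#'
#' @param data Wide expression tibble (`feature_id` + sample columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(data, path) {
  out <- data
  for (col in setdiff(names(out), "feature_id")) {
    out[[col]] <- sprintf("%.17g", out[[col]])
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a TaqMan Ct table from TSV
#'
#' Reads an assay-by-sample table of qPCR Ct values in which undetected
#' reactions carry a token (default `"Undetermined"`). The result is a tidy
#' (long) table with one row per reaction and an explicit detection flag;
#' the Ct value is `NA` where no amplification was called.
#'
#' @param path Path to a TSV file with first column assay IDs and sample
#'   columns named `"<stage>_<replicate>"`.
#' @param design A [stage_design()] for the samples.
#' @param undetected_token String marking undetected reactions.
#' @param protocol Protocol label attached to the table (e.g.
#'   `"12ng-random-hexamer"`); imputation floors are computed per protocol.
#'
#' @return A tibble of class `ct_table` with columns `assay_id`, `sample`,
#'   `stage`, `replicate`, `ct`, `detected` and attributes `"design"` and
#'   `"protocol"`.
#' @export
read_ct_table <- function(path, design, undetected_token = "Undetermined",
                          protocol = "unspecified") {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  names(raw)[1] <- "assay_id"
  dup <- unique(raw$assay_id[duplicated(raw$assay_id)])
  if (length(dup) > 0) {
    stop("Duplicated assay IDs: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  raw <- align_to_design(raw, design, id_col = "assay_id")
  long <- tidyr::pivot_longer(raw, -"assay_id",
                              names_to = "sample", values_to = "raw")
  detected <- long$raw != undetected_token
  ct <- rep(NA_real_, nrow(long))
  parsed <- suppressWarnings(as.numeric(long$raw[detected]))
  bad <- which(is.na(parsed))
  if (length(bad) > 0) {
    i <- which(detected)[bad[1]]
    stop(sprintf("Cell '%s' (assay '%s', sample '%s') is neither numeric nor '%s'.",
                 long$raw[i], long$assay_id[i], long$sample[i], undetected_token),
         call. = FALSE)
  }
  if (any(parsed < 0)) {
    i <- which(detected)[which(parsed < 0)[1]]
    stop(sprintf("Negative Ct %s for assay '%s', sample '%s'.",
                 long$raw[i], long$assay_id[i], long$sample[i]), call. = FALSE)
  }
  ct[detected] <- parsed
  out <- tibble::tibble(
    assay_id = long$assay_id,
    sample = long$sample,
    stage = design$stage[match(long$sample, design$sample)],
    replicate = design$replicate[match(long$sample, design$sample)],
    ct = ct,
    detected = detected
  )
  attr(out, "design") <- design
  attr(out, "protocol") <- protocol
  class(out) <- c("ct_table", class(out))
  out
}

#' Write a Ct table as TSV
#'
#' Writes the wide assay-by-sample layout read by [read_ct_table()];
#' undetected cells are written as `undetected_token`.
#'
#' @param ct A `ct_table` from [read_ct_table()] or [simulate_study()].
#' @param path Output path.
#' @param undetected_token Token for undetected cells.
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(ct, path, undetected_token = "Undetermined") {
  wide <- tidyr::pivot_wider(
    dplyr::mutate(ct, text = ifelse(.data$detected, sprintf("%.17g", .data$ct),
                                    undetected_token)),
    id_cols = "assay_id", names_from = "sample", values_from = "text"
  )
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}

#' Read a two-column ortholog map
#'
#' Reads a TSV pairing human gene identifiers with mouse orthologs.
#' One-to-many relationships are allowed (a gene may appear in several
#' pairs); exact duplicate pairs are dropped with a message.
#'
#' @param path Path to a two-column TSV; a header row is detected when its
#'   second field matches no later mouse identifier pattern requirement —
#'   practically, a first line equal to `human<TAB>mouse` (case-insensitive
#'   match on "human") is treated as a header.
#' @return A tibble with columns `human_gene` and `mouse_gene`.
#' @export
read_ortholog_map <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("Empty ortholog map: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, integer(1)) != 2)
  if (length(bad) > 0) {
    stop(sprintf("Ortholog map line %d of %s has %d fields; expected 2.",
                 bad[1], path, length(fields[[bad[1]]])), call. = FALSE)
  }
  if (grepl("human", fields[[1]][1], ignore.case = TRUE)) fields <- fields[-1]
  pairs <- tibble::tibble(
    human_gene = vapply(fields, `[`, character(1), 1),
    mouse_gene = vapply(fields, `[`, character(1), 2)
  )
  n_dup <- sum(duplicated(pairs))
  if (n_dup > 0) {
    message(sprintf("read_ortholog_map: dropped %d duplicate pair(s).", n_dup))
    pairs <- dplyr::distinct(pairs)
  }
  pairs
}
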