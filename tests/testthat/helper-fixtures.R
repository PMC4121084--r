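# Small in-code fixtures shared across test files.

human_design <- function(reps = 3L) {
  stage_design(c("MII", "4cell", "8cell", "blastocyst"), reps, "human")
}

mouse_design <- function(reps = 3L) {
  stage_design(c("MII", "1cell", "2cell", "8cell"), reps, "mouse")
}

# wide expression tibble with the given per-feature values (list of numeric
# vectors in design sample order)
make_expr <- function(values, design, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("F%02d", seq_along(values))
  out <- tibble::as_tibble(as.data.frame(do.call(rbind, values)))
  names(out) <- design$sample
  tibble::add_column(out, feature_id = ids, .before = 1)
}

# long ct_table from a wide matrix of Ct values; NA cells mean undetected
make_ct <- function(ct_matrix, design, assay_ids,
                    protocol = "12ng-random-hexamer") {
  long <- tibble::tibble(
    assay_id = rep(assay_ids, times = nrow(design)),
    sample = rep(design$sample, each = length(assay_ids)),
    stage = rep(design$stage, each = length(assay_ids)),
    replicate = rep(design$replicate, each = length(assay_ids)),
    ct = as.vector(ct_matrix),
    detected = !is.na(as.vector(ct_matrix))
  )
  attr(long, "design") <- design
  attr(long, "protocol") <- protocol
  class(long) <- c("ct_table", class(long))
  long
}

# hand-built transition rows for classifier tests
make_transitions <- function(feature_id, design, sig) {
  # sig: named numeric log_fc for significant pairs "earlier->later";
  # everything else is tested but non-significant
  pairs <- stage_pairs(design)
  key <- paste0(pairs$earlier, "->", pairs$later)
  lfc <- ifelse(key %in% names(sig), sig[key], 0.01)
  p <- ifelse(key %in% names(sig), 1e-4, 0.8)
  tibble::tibble(
    feature_id = feature_id,
    earlier = pairs$earlier, later = pairs$later,
    log_fc = unname(lfc), t_stat = unname(lfc * 10), df = 4,
    p_value = unname(p), q_value = unname(p),
    status = "tested"
  )
}

# brute-force BH step-up straight from the definition
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    js <- i:m
    q[o[i]] <- min(1, min(p[o[js]] * m / js))
  }
  q
}
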