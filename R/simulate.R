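#' Per-stage mean profile for an expression archetype
#'
#' The four archetypes mirror the canonical behaviours of preimplantation
#' transcripts around zygotic genome activation (ZGA): `up` steps up at the
#' ZGA stage and stays high; `up_down` steps up at ZGA and returns to
#' baseline by the final stage; `down` (the maternal profile) is high
#' through the maternal stages and steps down at ZGA; `flat` is constant.
#'
#' @param archetype One of `"up"`, `"up_down"`, `"down"`, `"flat"`.
#' @param stages Ordered character vector of at least three stage names.
#' @param effect_log2 Step size in log2 units (positive).
#' @param zga_stage Stage at which zygotic transcription starts. Defaults to
#'   `"4cell"` when present (human), else `"2cell"` (mouse), else the second
#'   stage.
#'
#' @return A tibble with columns `stage` and `mean_log2` (baseline 0).
#'
#' @examples
#' profile_template("up_down", c("MII", "4cell", "8cell", "blastocyst"), 2)
#' @export
profile_template <- function(archetype, stages, effect_log2,
                             zga_stage = NULL) {
  if (length(stages) < 3) stop("Need at least 3 stages.", call. = FALSE)
  if (!archetype %in% c("up", "up_down", "down", "flat")) {
    stop("Unknown archetype: ", archetype, call. = FALSE)
  }
  if (is.null(zga_stage)) {
    zga_stage <- if ("4cell" %in% stages) "4cell"
                 else if ("2cell" %in% stages) "2cell"
                 else stages[2]
  }
  if (!zga_stage %in% stages) {
    stop("zga_stage '", zga_stage, "' is not in `stages`.", call. = FALSE)
  }
  zga_i <- match(zga_stage, stages)
  n <- length(stages)
  mean_log2 <- switch(archetype,
    flat = rep(0, n),
    up = ifelse(seq_len(n) >= zga_i, effect_log2, 0),
    up_down = ifelse(seq_len(n) >= zga_i & seq_len(n) < n, effect_log2, 0),
    down = ifelse(seq_len(n) < zga_i, effect_log2, 0)
  )
  tibble::tibble(stage = stages, mean_log2 = mean_log2)
}

#' Convert a log2 expression value to a qPCR Ct value
#'
#' Inverts the comparative-Ct quantification convention: every doubling of
#' template lowers Ct by one cycle, so `ct = ct_intercept - log2_expr`.
#' Reactions whose Ct would reach the instrument limit are reported
#' undetected and carry no Ct value.
#'
#' @param log2_expr Numeric vector of log2 expression values.
#' @param ct_intercept Ct (cycles) of a transcript at log2 expression 0.
#' @param ct_limit Detection limit in cycles (default 40).
#' @return A tibble with columns `ct` (NA where undetected) and `detected`.
#' @export
expression_to_ct <- function(log2_expr, ct_intercept, ct_limit = 40) {
  stopifnot(all(is.finite(log2_expr)), is.finite(ct_intercept), is.finite(ct_limit))
  ct <- ct_intercept - log2_expr
  detected <- ct < ct_limit
  ct[!detected] <- NA_real_
  tibble::tibble(ct = ct, detected = detected)
}

#' Simulation configuration
#'
#' Collects the parameters of [simulate_study()]. The defaults encode the
#' study conditions of a two-dataset human microarray comparison with a
#' mouse TaqMan follow-up: a 2 log2-unit archetype step, 0.25 log2 units of
#' replicate noise, human arrays and RPKM with 3 replicates per stage, and
#' the mouse qPCR card run with 2 replicas at MII and 1-cell and 3 at
#' 2-cell and 8-cell.
#'
#' @param seed Integer seed; the study is fully reproducible given the seed.
#' @param n_per_archetype Genes simulated per archetype (four archetypes).
#' @param effect_log2 Archetype step size, log2 units.
#' @param noise_sd_log2 Replicate noise SD, log2 units.
#' @param probe_affinity_sd SD of per-probe affinity offsets (arrays only).
#' @param baseline_log2_mean,baseline_log2_sd Per-gene baseline abundance
#'   distribution, log2 units.
#' @param ct_intercept Cycles at log2 expression 0 (see [expression_to_ct()]).
#' @param ct_limit qPCR detection limit in cycles.
#' @param rpkm_floor Linear abundance subtracted before clipping RPKM at 0.
#' @param concordant_fraction Fraction of mouse orthologs (per non-flat
#'   archetype) that follow the human profile; the rest show a divergent
#'   profile (maternal for human up/up-down genes).
#' @param human_stages,human_stages_b,mouse_stages,human_rpkm_stages,mouse_rpkm_stages
#'   Optional [stage_design()] overrides for the five simulated datasets.
#' @param zga_human,zga_mouse ZGA stage labels used by the templates.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_per_archetype = 100L,
                       effect_log2 = 2,
                       noise_sd_log2 = 0.25,
                       probe_affinity_sd = 0.3,
                       baseline_log2_mean = 5,
                       baseline_log2_sd = 1.5,
                       ct_intercept = 38,
                       ct_limit = 40,
                       rpkm_floor = 1,
                       concordant_fraction = 0.7,
                       human_stages = NULL,
                       human_stages_b = NULL,
                       mouse_stages = NULL,
                       human_rpkm_stages = NULL,
                       mouse_rpkm_stages = NULL,
                       zga_human = "4cell",
                       zga_mouse = "2cell") {
  stopifnot(effect_log2 > 0, noise_sd_log2 >= 0, probe_affinity_sd >= 0,
            n_per_archetype >= 1)
  if (concordant_fraction < 0 || concordant_fraction > 1) {
    stop("concordant_fraction must be in [0, 1].", call. = FALSE)
  }
  cfg <- list(
    seed = as.integer(seed),
    n_per_archetype = as.integer(n_per_archetype),
    effect_log2 = effect_log2,
    noise_sd_log2 = noise_sd_log2,
    probe_affinity_sd = probe_affinity_sd,
    baseline_log2_mean = baseline_log2_mean,
    baseline_log2_sd = baseline_log2_sd,
    ct_intercept = ct_intercept,
    ct_limit = ct_limit,
    rpkm_floor = rpkm_floor,
    concordant_fraction = concordant_fraction,
    human_stages = human_stages %||%
      stage_design(c("MII", "4cell", "8cell", "blastocyst"), 3L, "human"),
    human_stages_b = human_stages_b %||%
      stage_design(c("1cell", "4cell", "8cell", "blastocyst"), 3L, "human"),
    mouse_stages = mouse_stages %||%
      stage_design(c("MII", "1cell", "2cell", "8cell"), c(2L, 2L, 3L, 3L), "mouse"),
    human_rpkm_stages = human_rpkm_stages %||%
      stage_design(c("MII", "1cell", "4cell", "8cell", "morula", "blastocyst"),
                   3L, "human"),
    mouse_rpkm_stages = mouse_rpkm_stages %||%
      stage_design(c("MII", "1cell", "2cell", "8cell"), 3L, "mouse"),
    zga_human = zga_human,
    zga_mouse = zga_mouse
  )
  class(cfg) <- "sim_config"
  cfg
}

# template means per gene for one design: genes x stages matrix
template_matrix <- function(archetypes, design, effect, zga) {
  stages <- design_stages(design)
  templates <- vapply(
    c("up", "up_down", "down", "flat"),
    function(a) profile_template(a, stages, effect, zga_stage = zga)$mean_log2,
    numeric(length(stages))
  )
  t(templates)[match(archetypes, c("up", "up_down", "down", "flat")), ,
               drop = FALSE]
}

# genes x samples matrix of noisy log2 values (one row per feature)
noisy_log2 <- function(baseline, tmpl, design, noise_sd) {
  stage_idx <- match(as.character(design$stage), design_stages(design))
  mu <- tmpl[, stage_idx, drop = FALSE] + baseline
  mu + matrix(rnorm(length(mu), 0, noise_sd), nrow = nrow(mu))
}

as_wide <- function(values, feature_ids, design, scale) {
  out <- tibble::as_tibble(as.data.frame(values))
  names(out) <- design$sample
  out <- tibble::add_column(out, feature_id = feature_ids, .before = 1)
  attr(out, "design") <- design
  attr(out, "scale") <- scale
  out
}

#' Simulate a two-species preimplantation study with planted ground truth
#'
#' Generates a full synthetic study: two independent human probe-level
#' arrays (the second with a 1-cell rather than MII first stage), a mouse
#' TaqMan Ct table with endogenous control assays, human and mouse
#' RPKM-like matrices, an ortholog map, and a truth table recording every
#' gene's planted archetype and its mouse ortholog's concordance.
#'
#' Arrays carry 1–3 probes per gene with fixed per-probe affinity offsets.
#' A planted fraction of mouse orthologs follows the human archetype; the
#' rest diverge — orthologs of human `up`/`up_down` genes take the maternal
#' (`down`) profile, orthologs of human `down` genes take the `up_down`
#' profile. The fraction is planted exactly (per-archetype allocation of
#' `round(f * n)` concordant genes), so the planted proportion equals the
#' configured one up to rounding.
#'
#' @param config A [sim_config()].
#' @return A list of class `simulated_study` with elements `truth`,
#'   `probe_map`, `ortholog_map`, `human_array_a`, `human_array_b`,
#'   `mouse_ct`, `human_rpkm`, `mouse_rpkm` and `config`. Matrices are wide
#'   tibbles carrying their design as an attribute.
#' @export
simulate_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  sub <- sample.int(.Machine$integer.max - 1L, 10L)

  n <- config$n_per_archetype
  archetypes <- rep(c("up", "up_down", "down", "flat"), each = n)
  gene_ids <- sprintf("HG%04d", seq_along(archetypes))
  mouse_ids <- sprintf("Mg%04d", seq_along(archetypes))

  # concordance: exact allocation per archetype; flat pairs carry no label
  concordant <- rep(NA, length(archetypes))
  for (a in c("up", "up_down", "down")) {
    idx <- which(archetypes == a)
    k <- round(config$concordant_fraction * length(idx))
    concordant[idx] <- c(rep(TRUE, k), rep(FALSE, length(idx) - k))
  }
  mouse_archetype <- ifelse(
    archetypes == "flat", "flat",
    ifelse(concordant, archetypes,
           ifelse(archetypes == "down", "up_down", "down"))
  )
  truth <- tibble::tibble(
    gene_id = gene_ids, mouse_gene = mouse_ids, archetype = archetypes,
    concordant = concordant, mouse_archetype = mouse_archetype
  )

  set.seed(sub[1])
  baseline <- rnorm(length(gene_ids), config$baseline_log2_mean,
                    config$baseline_log2_sd)
  n_probes <- sample(1:3, length(gene_ids), replace = TRUE)
  probe_map <- tibble::tibble(
    probe_id = unlist(mapply(function(g, k) sprintf("%s_p%d", g, seq_len(k)),
                             gene_ids, n_probes, SIMPLIFY = FALSE),
                      use.names = FALSE),
    gene_id = rep(gene_ids, n_probes)
  )
  set.seed(sub[2])
  affinity <- rnorm(nrow(probe_map), 0, config$probe_affinity_sd)

  probe_rows <- match(probe_map$gene_id, gene_ids)
  array_of <- function(design, stream) {
    tmpl <- template_matrix(archetypes, design, config$effect_log2,
                            config$zga_human)[probe_rows, , drop = FALSE]
    set.seed(stream)
    vals <- noisy_log2(baseline[probe_rows] + affinity, tmpl, design,
                       config$noise_sd_log2)
    as_wide(vals, probe_map$probe_id, design, "log2")
  }
  human_array_a <- array_of(config$human_stages, sub[3])
  human_array_b <- array_of(config$human_stages_b, sub[4])

  # mouse qPCR: gene assays plus two flat endogenous controls
  md <- config$mouse_stages
  tmpl_m <- template_matrix(mouse_archetype, md, config$effect_log2,
                            config$zga_mouse)
  controls <- c("Hprt1", "Psmb6")
  tmpl_m <- rbind(tmpl_m, matrix(0, 2, ncol(tmpl_m)))
  set.seed(sub[5])
  log2_m <- noisy_log2(c(baseline, 8, 8), tmpl_m, md, config$noise_sd_log2)
  ctv <- expression_to_ct(as.vector(log2_m), config$ct_intercept,
                          config$ct_limit)
  mouse_ct <- tibble::tibble(
    assay_id = rep(c(mouse_ids, controls), times = nrow(md)),
    sample = rep(md$sample, each = length(mouse_ids) + 2),
    stage = rep(md$stage, each = length(mouse_ids) + 2),
    replicate = rep(md$replicate, each = length(mouse_ids) + 2),
    ct = ctv$ct,
    detected = ctv$detected
  )
  attr(mouse_ct, "design") <- md
  attr(mouse_ct, "protocol") <- "12ng-random-hexamer"
  class(mouse_ct) <- c("ct_table", class(mouse_ct))

  rpkm_of <- function(design, arche, zga, ids, stream) {
    tmpl <- template_matrix(arche, design, config$effect_log2, zga)
    set.seed(stream)
    vals <- noisy_log2(baseline, tmpl, design, config$noise_sd_log2)
    as_wide(pmax(2^vals - config$rpkm_floor, 0), ids, design, "linear")
  }
  human_rpkm <- rpkm_of(config$human_rpkm_stages, archetypes,
                        config$zga_human, gene_ids, sub[6])
  mouse_rpkm <- rpkm_of(config$mouse_rpkm_stages, mouse_archetype,
                        config$zga_mouse, mouse_ids, sub[7])

  structure(list(
    truth = truth,
    probe_map = probe_map,
    ortholog_map = tibble::tibble(human_gene = gene_ids,
                                  mouse_gene = mouse_ids),
    human_array_a = human_array_a,
    human_array_b = human_array_b,
    mouse_ct = mouse_ct,
    human_rpkm = human_rpkm,
    mouse_rpkm = mouse_rpkm,
    config = config
  ), class = "simulated_study")
}

#' @export
print.simulated_study <- function(x, ...) {
  cat(sprintf(
    "<simulated_study> %d genes (%d per archetype), seed %d\n",
    nrow(x$truth), x$config$n_per_archetype, x$config$seed
  ))
  cat(sprintf("  arrays: %d probes; mouse qPCR assays: %d (+2 controls)\n",
              nrow(x$probe_map), nrow(x$truth)))
  invisible(x)
}

#' Write all matrices of a simulated study as TSV
#'
#' @param study A [simulate_study()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "simulated_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression_matrix(study$human_array_a, file.path(dir, "human_array_a.tsv"))
  write_expression_matrix(study$human_array_b, file.path(dir, "human_array_b.tsv"))
  write_expression_matrix(study$human_rpkm, file.path(dir, "human_rpkm.tsv"))
  write_expression_matrix(study$mouse_rpkm, file.path(dir, "mouse_rpkm.tsv"))
  write_ct_table(study$mouse_ct, file.path(dir, "mouse_ct.tsv"))
  readr::write_tsv(study$ortholog_map, file.path(dir, "orthologs.tsv"),
                   progress = FALSE)
  readr::write_tsv(study$probe_map, file.path(dir, "probe_map.tsv"),
                   progress = FALSE)
  readr::write_tsv(study$truth, file.path(dir, "truth.tsv"), progress = FALSE)
  invisible(dir)
}
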