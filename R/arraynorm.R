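#' Select rank-invariant probes between two arrays
#'
#' Iteratively retains probes whose proportional rank difference between the
#' reference and target arrays, `|rank_ref - rank_target| / n`, stays below
#' `rank_threshold`; ranks are recomputed within the retained set each
#' iteration until a fixed point (or `max_iter`). These rank-stable probes
#' anchor between-array normalisation without assuming most genes are
#' unchanged.
#'
#' @param reference,target Equal-length numeric vectors (>= 10 probes).
#' @param rank_threshold Proportional rank difference allowed (default 0.05).
#' @param max_iter Maximum refinement iterations.
#' @param min_probes Error if fewer probes survive.
#' @return Integer vector of retained probe indices (into the input).
#' @export
select_invariant_set <- function(reference, target, rank_threshold = 0.05,
                                 max_iter = 10, min_probes = 5) {
  stopifnot(length(reference) == length(target))
  if (length(reference) < 10) stop("Need at least 10 probes.", call. = FALSE)
  if (!all(is.finite(reference)) || !all(is.finite(target))) {
    stop("Non-finite probe values.", call. = FALSE)
  }
  keep <- seq_along(reference)
  for (it in seq_len(max_iter)) {
    n <- length(keep)
    prd <- abs(rank(reference[keep]) - rank(target[keep])) / n
    retained <- keep[prd < rank_threshold]
    if (length(retained) < min_probes) {
      stop(sprintf(
        "Only %d probe(s) survive invariant-set selection (minimum %d); loosen rank_threshold.",
        length(retained), min_probes), call. = FALSE)
    }
    if (length(retained) == length(keep)) break
    keep <- retained
  }
  keep
}

#' Normalise a target array onto a reference through its invariant set
#'
#' Fits a non-decreasing piecewise-linear map from target to reference
#' intensities through the invariant probes (sorted by target value, tied
#' targets averaged, reference values forced monotone) and applies it to
#' every probe. Values beyond the invariant range are extrapolated linearly
#' using the slope of the outermost segment.
#'
#' @param reference,target Numeric vectors over the same probes.
#' @param invariant Probe indices from [select_invariant_set()].
#' @return Normalised target values, same length as `target`.
#' @export
invariant_set_normalize <- function(reference, target, invariant) {
  stopifnot(length(reference) == length(target))
  if (!all(is.finite(reference)) || !all(is.finite(target))) {
    stop("Non-finite values.", call. = FALSE)
  }
  x <- target[invariant]
  y <- reference[invariant]
  o <- order(x)
  x <- x[o]; y <- y[o]
  # collapse ties in target, then enforce a non-decreasing map
  ux <- unique(x)
  uy <- vapply(ux, function(v) mean(y[x == v]), numeric(1))
  uy <- cummax(uy)
  if (length(ux) == 1) return(target - ux + uy)
  interp <- approx(ux, uy, xout = target, rule = 2)$y
  lo_slope <- (uy[2] - uy[1]) / (ux[2] - ux[1])
  hi_slope <- (uy[length(uy)] - uy[length(uy) - 1]) /
              (ux[length(ux)] - ux[length(ux) - 1])
  below <- target < ux[1]
  above <- target > ux[length(ux)]
  interp[below] <- uy[1] + lo_slope * (target[below] - ux[1])
  interp[above] <- uy[length(uy)] + hi_slope * (target[above] - ux[length(ux)])
  interp
}

#' Rescale a set of expression matrices to a common median intensity
#'
#' Each matrix is multiplied by a scalar so that its median equals the
#' grand median of the per-matrix medians (even counts take the midpoint of
#' the two central medians). Within-matrix relative values and rank order
#' are unchanged.
#'
#' @param matrices A list of wide expression tibbles (`feature_id` +
#'   sample columns), linear scale.
#' @return The list with rescaled values; scale factors are attached as
#'   attribute `"scale_factors"`.
#' @export
rescale_to_common_median <- function(matrices) {
  stopifnot(length(matrices) >= 1)
  meds <- vapply(matrices, function(m) {
    median(as.matrix(m[, setdiff(names(m), "feature_id")]))
  }, numeric(1))
  if (any(meds <= 0)) stop("Non-positive matrix median.", call. = FALSE)
  grand <- median(meds)
  factors <- grand / meds
  out <- Map(function(m, f) {
    cols <- setdiff(names(m), "feature_id")
    m[cols] <- lapply(m[cols], function(v) v * f)
    m
  }, matrices, factors)
  attr(out, "scale_factors") <- factors
  out
}

#' Model-based expression index (Li–Wong) by alternating least squares
#'
#' Fits the multiplicative probe-set model `value[i, j] ~ phi[i] * theta[j]`
#' (probe affinity times array expression index) by alternating least
#' squares, rescaling `phi` each iteration so that `sum(phi^2)` equals the
#' probe count (the identifiability constraint). `theta` is the expression
#' summary per array. Outlier pruning is not performed; the plain
#' least-squares fit is returned.
#'
#' @param probe_matrix Numeric matrix, probes x arrays (>= 1 probe,
#'   >= 2 arrays).
#' @param tol Convergence tolerance on the largest parameter change.
#' @param max_iter Maximum ALS iterations.
#' @return An object of class `mbei_fit`: list with `theta`, `phi`,
#'   `residual_ss`, `iterations` and the per-iteration residual trace
#'   `residual_trace`.
#' @export
mbei_summarize <- function(probe_matrix, tol = 1e-10, max_iter = 100) {
  x <- as.matrix(probe_matrix)
  if (nrow(x) < 1 || ncol(x) < 2) {
    stop("Need >= 1 probe and >= 2 arrays.", call. = FALSE)
  }
  if (!all(is.finite(x))) stop("Non-finite probe values.", call. = FALSE)
  if (all(x == 0)) stop("All-zero probe matrix: degenerate fit.", call. = FALSE)
  n_probe <- nrow(x)
  phi <- rep(1, n_probe)
  theta <- colSums(x * phi) / sum(phi^2)
  trace <- numeric(0)
  iterations <- 0L
  for (it in seq_len(max_iter)) {
    theta_new <- colSums(x * phi) / sum(phi^2)
    phi_new <- as.vector(x %*% theta_new) / sum(theta_new^2)
    phi_new <- phi_new * sqrt(n_probe / sum(phi_new^2))
    theta_new <- colSums(x * phi_new) / sum(phi_new^2)
    rss <- sum((x - outer(phi_new, theta_new))^2)
    trace <- c(trace, rss)
    delta <- max(abs(c(theta_new - theta, phi_new - phi)))
    theta <- theta_new; phi <- phi_new
    iterations <- it
    if (delta < tol) break
  }
  structure(list(theta = theta, phi = phi,
                 residual_ss = trace[length(trace)],
                 iterations = iterations,
                 residual_trace = trace),
            class = "mbei_fit")
}

#' @export
print.mbei_fit <- function(x, ...) {
  cat(sprintf("<mbei_fit> %d probes x %d arrays, residual SS %.3g (%d iterations)\n",
              length(x$phi), length(x$theta), x$residual_ss, x$iterations))
  invisible(x)
}

#' @rdname mbei_summarize
#' @param x An `mbei_fit`.
#' @param ... Unused.
#' @method tidy mbei_fit
#' @export
tidy.mbei_fit <- function(x, ...) {
  tibble::tibble(probe = seq_along(x$phi), phi = x$phi)
}

#' @rdname mbei_summarize
#' @method glance mbei_fit
#' @export
glance.mbei_fit <- function(x, ...) {
  tibble::tibble(residual_ss = x$residual_ss, iterations = x$iterations,
                 n_probes = length(x$phi), n_arrays = length(x$theta))
}

#' Summarise probe-level arrays to probe-set expression indices
#'
#' Applies [mbei_summarize()] per probe set after between-array
#' normalisation is assumed done. Single-probe sets pass through as the
#' probe row itself.
#'
#' @param probe_data Wide tibble, `feature_id` (probe IDs) + sample columns.
#' @param probe_map Tibble with columns `probe_id` and a grouping column
#'   (second column, e.g. `probeset_id` or `gene_id`).
#' @return Wide tibble of expression indices, one row per probe set.
#' @export
summarize_probesets <- function(probe_data, probe_map) {
  group_col <- names(probe_map)[2]
  missing <- setdiff(probe_data$feature_id, probe_map$probe_id)
  if (length(missing) > 0) {
    stop("Probes missing from probe_map: ",
         paste(head(missing, 5), collapse = ", "), call. = FALSE)
  }
  sample_cols <- setdiff(names(probe_data), "feature_id")
  groups <- split(probe_data$feature_id,
                  probe_map[[group_col]][match(probe_data$feature_id,
                                               probe_map$probe_id)])
  mat <- as.matrix(probe_data[, sample_cols])
  rownames(mat) <- probe_data$feature_id
  rows <- lapply(names(groups), function(g) {
    sub <- mat[groups[[g]], , drop = FALSE]
    if (nrow(sub) == 1) as.vector(sub) else mbei_summarize(sub)$theta
  })
  out <- tibble::as_tibble(do.call(rbind, rows), .name_repair = "minimal")
  names(out) <- sample_cols
  out <- tibble::add_column(out, feature_id = names(groups), .before = 1)
  attr(out, "design") <- attr(probe_data, "design")
  attr(out, "scale") <- attr(probe_data, "scale")
  out
}
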