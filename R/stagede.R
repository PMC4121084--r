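#' Comparative expression against endogenous controls
#'
#' Converts a linear-scale expression table to
#' `log2(comparative expression) = log2(gene) - log2(mean of controls)`
#' per sample, the transform that puts microarray values on the same
#' footing as qPCR \eqn{-\Delta}Ct values. Doubling every value within a
#' sample leaves the output unchanged.
#'
#' @param data Wide linear-scale expression tibble (`feature_id` + samples).
#' @param control_ids Feature IDs of the endogenous controls (e.g. the
#'   probes for Hprt1 and Psmb6).
#' @return A tibble of the same shape on the log2 comparative scale, with
#'   attribute `"control_ids"`.
#' @export
comparative_expression <- function(data, control_ids) {
  missing <- setdiff(control_ids, data$feature_id)
  if (length(missing) > 0) {
    stop("Control IDs not in matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  cols <- setdiff(names(data), "feature_id")
  mat <- as.matrix(data[, cols])
  if (any(mat <= 0)) stop("Comparative expression needs positive linear values.",
                          call. = FALSE)
  ctrl_mean <- colMeans(mat[match(control_ids, data$feature_id), , drop = FALSE])
  out <- data
  out[cols] <- sweep(log2(mat), 2, log2(ctrl_mean), "-")
  attr(out, "control_ids") <- control_ids
  attr(out, "scale") <- "log2"
  attr(out, "design") <- attr(data, "design")
  out
}

#' Benjamini–Hochberg step-up q-values
#'
#' Computes `q(i) = min over j >= i of p(j) * m / j` on the sorted
#' p-values, returned in the input order and capped at 1.
#'
#' @param p_values Numeric vector in `[0, 1]`.
#' @return q-values, same length and order as the input.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1].", call. = FALSE)
  }
  m <- length(p_values)
  o <- order(p_values)
  q_sorted <- pmin(1, rev(cummin(rev(p_values[o] * m / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Newton solve of trigamma(y) = x (x > 0), as needed for the moments fit.
trigamma_inverse <- function(x) {
  vapply(x, function(xi) {
    if (!is.finite(xi) || xi <= 0) return(Inf)
    if (xi > 1e7) return(1 / sqrt(xi))
    if (xi < 1e-6) return(1 / xi)
    y <- 0.5 + 1 / xi
    for (i in 1:50) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xi) / psigamma(y, deriv = 2)
      y <- y + dif
      if (-dif / y < 1e-10) break
    }
    y
  }, numeric(1))
}

#' Empirical-Bayes moderation of per-feature variances
#'
#' Fits the scaled inverse-chi-squared prior of the moderated t-statistic
#' by method of moments on `log(s^2)`: the prior degrees of freedom `d0`
#' solve a trigamma matching equation and the prior variance `s0^2` a
#' digamma one. The posterior variance per feature is
#' `s_tilde^2 = (d0 s0^2 + df s^2) / (d0 + df)` and the moderated t-test
#' gains `d0` degrees of freedom. Estimated `d0` above `1e6` is treated as
#' infinite (complete shrinkage to `s0^2`).
#'
#' @param s_sq Per-feature sample variances (>= 0).
#' @param df Per-feature residual degrees of freedom (>= 1).
#' @return An object of class `moderated_fit`: list with `d0`, `s0_sq` and
#'   `s_tilde_sq`.
#' @export
fit_moderated <- function(s_sq, df) {
  stopifnot(length(s_sq) == length(df))
  if (any(df < 1)) stop("All residual df must be >= 1.", call. = FALSE)
  if (any(s_sq < 0)) stop("Variances must be non-negative.", call. = FALSE)
  ok <- s_sq > 0
  if (sum(ok) < 2) {
    warning("Fewer than 2 features with positive variance; no moderation applied (d0 = 0).")
    return(structure(list(d0 = 0, s0_sq = NA_real_, s_tilde_sq = s_sq),
                     class = "moderated_fit"))
  }
  if (length(unique(s_sq[ok])) == 1) {
    # degenerate limit: no spread in the sample variances, complete shrinkage
    s0 <- s_sq[ok][1]
    return(structure(list(d0 = Inf, s0_sq = s0,
                          s_tilde_sq = rep(s0, length(s_sq))),
                     class = "moderated_fit"))
  }
  z <- log(s_sq[ok])
  e <- z - digamma(df[ok] / 2) + log(df[ok] / 2)
  ebar <- mean(e)
  n <- length(e)
  rhs <- mean((e - ebar)^2 * n / (n - 1) - trigamma(df[ok] / 2))
  if (rhs > 0) {
    d0 <- 2 * trigamma_inverse(rhs)
    if (!is.finite(d0) || d0 > 1e6) d0 <- Inf
  } else {
    d0 <- Inf
  }
  s0_sq <- if (is.finite(d0)) {
    exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  } else {
    exp(ebar)
  }
  s_tilde_sq <- if (is.finite(d0)) {
    (d0 * s0_sq + df * s_sq) / (d0 + df)
  } else {
    rep(s0_sq, length(s_sq))
  }
  structure(list(d0 = d0, s0_sq = s0_sq, s_tilde_sq = s_tilde_sq),
            class = "moderated_fit")
}

#' @export
print.moderated_fit <- function(x, ...) {
  cat(sprintf("<moderated_fit> d0 = %s, s0^2 = %.4g\n",
              format(x$d0), x$s0_sq))
  invisible(x)
}

#' @rdname fit_moderated
#' @param x A `moderated_fit`.
#' @param ... Unused.
#' @method glance moderated_fit
#' @export
glance.moderated_fit <- function(x, ...) {
  tibble::tibble(d0 = x$d0, s0_sq = x$s0_sq,
                 n_features = length(x$s_tilde_sq))
}

#' Differential expression between consecutive developmental stages
#'
#' Runs a two-sided two-sample t-test per feature for every consecutive
#' stage pair of the design, on log-scale values. `method = "student"`
#' uses the pooled-variance Student test; `method = "moderated"` first
#' shrinks per-feature variances across all features of a stage pair with
#' [fit_moderated()] and tests with `df + d0` degrees of freedom. Features
#' with fewer than two usable (non-missing) replicates in either stage are
#' reported `skipped` and carry no statistics. Benjamini–Hochberg q-values
#' are computed within each stage-pair family over the tested features.
#'
#' @param data Wide log-scale expression tibble (`feature_id` + samples);
#'   `NA` cells count as unusable replicates.
#' @param design A [stage_design()] for the sample columns.
#' @param method `"student"` (pooled) or `"moderated"`.
#' @param welch Use the Welch (unequal-variance) statistic instead of the
#'   pooled one (`method = "student"` only).
#' @param prior_df Optional fixed prior degrees of freedom overriding the
#'   estimated `d0` (e.g. `0` makes the moderated test equal the ordinary
#'   one).
#' @param pairs Optional tibble of stage pairs (`earlier`, `later`);
#'   defaults to all consecutive pairs.
#' @return A tibble with one row per (feature, stage pair): `feature_id`,
#'   `earlier`, `later`, `log_fc` (later minus earlier mean), `t_stat`,
#'   `df`, `p_value`, `q_value`, `status`.
#' @export
transition_tests <- function(data, design,
                             method = c("student", "moderated"),
                             welch = FALSE, prior_df = NULL, pairs = NULL) {
  method <- match.arg(method)
  data <- align_to_design(data, design)
  pairs <- pairs %||% stage_pairs(design)
  mat <- as.matrix(data[, setdiff(names(data), "feature_id")])
  results <- purrr::pmap(pairs, function(earlier, later) {
    c1 <- design$sample[design$stage == earlier]
    c2 <- design$sample[design$stage == later]
    x1 <- mat[, c1, drop = FALSE]
    x2 <- mat[, c2, drop = FALSE]
    n1 <- rowSums(!is.na(x1)); n2 <- rowSums(!is.na(x2))
    m1 <- rowMeans(x1, na.rm = TRUE); m2 <- rowMeans(x2, na.rm = TRUE)
    v1 <- apply(x1, 1, var, na.rm = TRUE)
    v2 <- apply(x2, 1, var, na.rm = TRUE)
    tested <- n1 >= 2 & n2 >= 2
    log_fc <- ifelse(tested, m2 - m1, NA_real_)
    t_stat <- df <- p <- rep(NA_real_, nrow(mat))
    if (any(tested)) {
      if (method == "student" && welch) {
        se2 <- v1 / n1 + v2 / n2
        df_w <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
        t_stat[tested] <- (log_fc / sqrt(se2))[tested]
        df[tested] <- df_w[tested]
      } else {
        df_p <- n1 + n2 - 2
        s2p <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df_p
        if (method == "moderated") {
          fit <- fit_moderated(s2p[tested], df_p[tested])
          if (!is.null(prior_df)) {
            fit <- override_prior(fit, prior_df, s2p[tested], df_p[tested])
          }
          s2use <- s2p
          s2use[tested] <- fit$s_tilde_sq
          df_tot <- df_p + fit$d0
        } else {
          s2use <- s2p
          df_tot <- df_p
        }
        t_stat[tested] <- (log_fc / sqrt(s2use * (1 / n1 + 1 / n2)))[tested]
        df[tested] <- pmin(df_tot, Inf)[tested]
      }
      # zero-variance degenerate cases: 0/0 (identical groups) -> t = 0,
      # p = 1; a pure shift with zero variance stays +-Inf with p = 0
      t_stat[tested & is.nan(t_stat)] <- 0
      p[tested] <- 2 * pt(-abs(t_stat[tested]), df[tested])
    }
    q <- rep(NA_real_, nrow(mat))
    if (any(tested)) q[tested] <- bh_fdr(p[tested])
    tibble::tibble(
      feature_id = data$feature_id,
      earlier = earlier, later = later,
      log_fc = log_fc, t_stat = t_stat, df = df,
      p_value = p, q_value = q,
      status = ifelse(tested, "tested", "skipped")
    )
  })
  dplyr::bind_rows(results)
}

# Replace an estimated prior with a fixed one (used for d0 = 0 checks and
# sensitivity analyses).
override_prior <- function(fit, d0, s_sq, df) {
  s0 <- fit$s0_sq
  if (d0 == 0) {
    s_tilde <- s_sq
  } else if (is.infinite(d0)) {
    s_tilde <- rep(s0, length(s_sq))
  } else {
    s_tilde <- (d0 * s0 + df * s_sq) / (d0 + df)
  }
  structure(list(d0 = d0, s0_sq = s0, s_tilde_sq = s_tilde),
            class = "moderated_fit")
}
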