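# qPCR standard-curve relative quantification and the screening-versus-
# validation concordance statistic: Spearman correlation with an empirical
# permutation probability.

#' Fit a qPCR standard curve
#'
#' Least-squares line of Ct against log10(quantity) over a dilution
#' series. Amplification efficiency is derived as 10^(-1/slope) - 1
#' (1.0 = perfect doubling per cycle).
#'
#' @param dilution_quantities positive quantities (>= 3 distinct points).
#' @param ct_values observed Ct values, same length.
#' @return list of class `standard_curve` with `slope`, `intercept`,
#'   `r_squared`, `efficiency`.
#' @export
#' @examples
#' fit_standard_curve(c(1, 10, 100), c(30, 26.6781, 23.3562))
fit_standard_curve <- function(dilution_quantities, ct_values) {
  q <- dilution_quantities
  if (length(q) != length(ct_values)) stop("length mismatch")
  if (length(q) < 3) stop("need at least 3 dilution points")
  if (any(q <= 0)) stop("quantities must be positive")
  lq <- log10(q)
  if (stats::var(lq) == 0) stop("zero variance in log10(quantity)")
  fit <- stats::lm(ct_values ~ lq)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (!is.finite(slope) || slope >= -1e-9)
    stop("invalid standard curve: slope must be negative (Ct decreasing ",
         "with quantity)")
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((ct_values - mean(ct_values))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  structure(list(slope = slope, intercept = intercept, r_squared = r2,
                 efficiency = 10^(-1 / slope) - 1),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("standard_curve: slope %.4f, intercept %.2f, R^2 %.4f, efficiency %.2f\n",
              x$slope, x$intercept, x$r_squared, x$efficiency))
  invisible(x)
}

#' Relative quantity from Ct values via fitted standard curves
#'
#' Technical replicates are averaged on the Ct scale first, then inverted
#' through each curve: log10(q) = (Ct - intercept) / slope. The result is
#' the target quantity divided by the reference quantity.
#'
#' @param ct_target Ct value(s) of the target (replicates averaged).
#' @param curve_target `standard_curve` for the target assay.
#' @param ct_reference Ct value(s) of the reference gene.
#' @param curve_reference `standard_curve` for the reference assay
#'   (defaults to `curve_target`).
#' @return relative expression (target / reference).
#' @export
relative_quantity <- function(ct_target, curve_target, ct_reference,
                              curve_reference = curve_target) {
  q_t <- 10^((mean(ct_target) - curve_target$intercept) / curve_target$slope)
  q_r <- 10^((mean(ct_reference) - curve_reference$intercept) /
               curve_reference$slope)
  if (!is.finite(q_r) || q_r == 0) stop("reference quantity is zero")
  q_t / q_r
}

#' Spearman rank correlation (tie-safe)
#'
#' Pearson correlation of midranks; equal to the classical
#' 1 - 6 sum(d^2) / (n (n^2 - 1)) formula on tie-free input.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return rho in \[-1, 1\].
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 3) stop("need at least 3 observations")
  rx <- rank(x); ry <- rank(y)
  if (stats::var(rx) == 0 || stats::var(ry) == 0)
    stop("zero rank variance; correlation undefined")
  stats::cor(rx, ry)
}

#' Permutation test of screening-versus-validation concordance
#'
#' The observed Spearman rho between matched screening and validation
#' values is compared to `k` re-computations in which the association
#' between the two vectors is permuted uniformly at random (validation
#' entries matched to randomly picked screening entries). The empirical
#' probability uses the add-one correction
#' `p = (#\{|rho_perm| >= |rho_obs|\} + 1) / (k + 1)`, so it can never be
#' below `1/(k+1)`. The signed one-sided version is also reported.
#'
#' @param screening_values,validation_values matched numeric vectors.
#' @param k number of permutations (>= 1).
#' @param seed RNG seed; the result is deterministic for a fixed seed.
#' @param alternative `"two.sided"` (on |rho|, default) or `"greater"`
#'   (signed).
#' @return list of class `concordance_result`: `rho_observed`, `k`,
#'   `rho_permuted` (length k), `p_empirical` (per `alternative`),
#'   `p_two_sided`, `p_greater`, `seed`.
#' @export
permutation_concordance <- function(screening_values, validation_values,
                                    k = 10000, seed = 1,
                                    alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  if (k < 1) stop("k must be >= 1")
  rho_obs <- spearman_rho(screening_values, validation_values)
  n <- length(screening_values)
  rx <- rank(screening_values)
  ry <- rank(validation_values)
  perm <- with_seed(seed, {
    # permuting the validation ranks is equivalent to permuting the values
    m <- vapply(seq_len(k), function(b) ry[sample.int(n)], numeric(n))
    as.numeric(stats::cor(rx, m))
  })
  p_two <- (sum(abs(perm) >= abs(rho_obs) - 1e-12) + 1) / (k + 1)
  p_gt <- (sum(perm >= rho_obs - 1e-12) + 1) / (k + 1)
  structure(list(rho_observed = rho_obs, k = as.integer(k),
                 rho_permuted = perm,
                 p_empirical = if (alternative == "two.sided") p_two else p_gt,
                 p_two_sided = p_two, p_greater = p_gt,
                 seed = as.integer(seed)),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("concordance_result: rho = %.4f, k = %d, empirical p = %.3g\n",
              x$rho_observed, x$k, x$p_empirical))
  invisible(x)
}

#' Relative expression matrix from a tidy qPCR table
#'
#' Aggregates technical replicates (mean Ct; optionally dropping features
#' whose replicate range exceeds `max_ct_range` in a sample), inverts the
#' standard curve, and normalizes each sample to the reference feature.
#'
#' @param qpcr data.frame with columns `feature_id`, `sample_id`,
#'   `replicate`, `ct`.
#' @param curve a `standard_curve` applied to all assays.
#' @param reference_id feature id of the reference gene (must be present
#'   for every sample).
#' @param max_ct_range if non-NULL, replicate sets with range above this
#'   many Ct are set to NA (outlier handling).
#' @return matrix features x samples of relative expression (reference row
#'   excluded).
#' @export
qpcr_relative_expression <- function(qpcr, curve, reference_id,
                                     max_ct_range = NULL) {
  need <- c("feature_id", "sample_id", "replicate", "ct")
  if (!all(need %in% names(qpcr)))
    stop("qPCR table needs columns: ", paste(need, collapse = ", "))
  if (!reference_id %in% qpcr$feature_id)
    stop("unknown reference feature id: ", reference_id)
  key <- paste(qpcr$feature_id, qpcr$sample_id, sep = "\r")
  mean_ct <- tapply(qpcr$ct, key, function(v) {
    if (!is.null(max_ct_range) && diff(range(v)) > max_ct_range)
      return(NA_real_)
    mean(v)
  })
  parts <- do.call(rbind, strsplit(names(mean_ct), "\r", fixed = TRUE))
  feats <- sort(unique(qpcr$feature_id))
  samps <- sort(unique(qpcr$sample_id))
  ctm <- matrix(NA_real_, length(feats), length(samps),
                dimnames = list(feats, samps))
  ctm[cbind(parts[, 1], parts[, 2])] <- as.numeric(mean_ct)
  if (any(is.na(ctm[reference_id, ])))
    stop("reference feature missing (or outlier-dropped) in sample(s): ",
         paste(samps[is.na(ctm[reference_id, ])], collapse = ", "))
  q <- 10^((ctm - curve$intercept) / curve$slope)
  rel <- sweep(q, 2, q[reference_id, ], "/")
  rel[setdiff(feats, reference_id), , drop = FALSE]
}
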