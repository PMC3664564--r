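# Rank-based differential expression for small two-group designs.
#
# The per-feature statistic is the between-group rank-sum difference over
# pooled midranks; a feature whose difference attains the theoretical
# maximum for the group sizes shows complete separation between groups and
# is flagged "distinct". Two-sided p-values come from the Mann-Whitney U
# test, by exact enumeration of the permutation distribution for small
# samples and by a tie-corrected normal approximation otherwise.

# cache of exact rank-sum count tables, keyed by "N.k"
.de_cache <- new.env(parent = emptyenv())

# Number of k-subsets of {1..N} with each possible rank sum, by dynamic
# programming. Returns counts indexed by sum = k(k+1)/2 .. (sum of top k),
# as a vector over U = sum - k(k+1)/2 in 0..k(N-k).
ranksum_u_counts <- function(N, k) {
  key <- paste(N, k, sep = ".")
  if (!is.null(.de_cache[[key]])) return(.de_cache[[key]])
  maxs <- N * (N + 1) / 2
  # dp[i+1, s+1]: number of i-subsets with sum s
  dp <- matrix(0, nrow = k + 1, ncol = maxs + 1)
  dp[1, 1] <- 1
  for (j in seq_len(N)) {
    for (i in rev(seq_len(min(j, k)))) {
      dp[i + 1, (j + 1):(maxs + 1)] <- dp[i + 1, (j + 1):(maxs + 1)] +
        dp[i, 1:(maxs + 1 - j)]
    }
  }
  sums <- dp[k + 1, ]
  smin <- k * (k + 1) / 2
  u_counts <- sums[(smin + 1):(smin + 1 + k * (N - k))]
  .de_cache[[key]] <- u_counts
  u_counts
}

# Two-sided p from a discrete U distribution given as (u_values, weights).
two_sided_from_dist <- function(u_obs, u_values, weights) {
  tot <- sum(weights)
  eps <- 1e-9
  p_le <- sum(weights[u_values <= u_obs + eps]) / tot
  p_ge <- sum(weights[u_values >= u_obs - eps]) / tot
  min(1, 2 * min(p_le, p_ge))
}

#' Rank-sum difference and complete-separation flag
#'
#' Computes group rank sums over pooled midranks, their difference
#' (case minus control), the theoretical maximum of that difference in the
#' observed direction, and whether the feature is "distinctly expressed":
#' the difference attains the maximum, equivalently the two groups' value
#' ranges do not overlap. Cross-group ties preclude distinctness because
#' midranks then fall short of the extreme configuration.
#'
#' @param case_values,control_values numeric vectors, both non-empty.
#' @return list with `rank_sum_case`, `rank_sum_control`, `rank_sum_diff`,
#'   `max_rank_sum_diff` (maximum attainable |difference| in the observed
#'   direction), `distinct` (logical).
#' @export
#' @examples
#' rank_sum_difference(c(5, 6, 7), c(1, 2, 3))  # diff 9 = max, distinct
rank_sum_difference <- function(case_values, control_values) {
  n1 <- length(case_values); n2 <- length(control_values)
  if (n1 == 0 || n2 == 0) stop("both groups must be non-empty")
  r <- rank(c(case_values, control_values))
  rs1 <- sum(r[seq_len(n1)])
  rs2 <- sum(r[n1 + seq_len(n2)])
  d <- rs1 - rs2
  # case occupying the top n1 ranks / the bottom n1 ranks
  max_up <- (n1 * n2 + n1 * (n1 + 1) / 2) - n2 * (n2 + 1) / 2
  max_dn <- n1 * (n1 + 1) / 2 - (n1 * n2 + n2 * (n2 + 1) / 2)
  max_in_dir <- if (d >= 0) max_up else -max_dn
  distinct <- (d == max_up) || (d == max_dn)
  list(rank_sum_case = rs1, rank_sum_control = rs2, rank_sum_diff = d,
       max_rank_sum_diff = max_in_dir, distinct = distinct)
}

#' Mann-Whitney U test (exact enumeration or normal approximation)
#'
#' Exact mode enumerates the permutation distribution of U: for tie-free
#' data via a closed dynamic program over rank sums, and with within-group
#' ties via full enumeration of midrank subsets. Exact mode refuses
#' cross-group ties (the observed U is then not a point of the tie-free
#' lattice); use normal mode, which applies the tie-corrected normal
#' approximation with a continuity correction. `"auto"` picks exact when
#' n1 + n2 <= 16 and there are no cross-group ties.
#'
#' @param case_values,control_values numeric vectors.
#' @param mode `"auto"`, `"exact"` or `"normal"`.
#' @return list with `U` (for the case group) and `p_value` (two-sided).
#' @export
#' @examples
#' mann_whitney_p(c(5, 6, 7), c(1, 2, 3), mode = "exact")$p_value  # 0.1
mann_whitney_p <- function(case_values, control_values,
                           mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  n1 <- length(case_values); n2 <- length(control_values)
  if (n1 == 0 || n2 == 0) stop("both groups must be non-empty")
  N <- n1 + n2
  pooled <- c(case_values, control_values)
  r <- rank(pooled)
  rs1 <- sum(r[seq_len(n1)])
  U <- rs1 - n1 * (n1 + 1) / 2
  cross_ties <- any(case_values %in% control_values)
  any_ties <- anyDuplicated(pooled) > 0

  if (mode == "auto") {
    mode <- if (N <= 16 && !cross_ties) "exact" else "normal"
  }

  if (mode == "exact") {
    if (cross_ties)
      stop("exact Mann-Whitney is not defined with cross-group ties; ",
           "use mode = 'normal'")
    if (!any_ties) {
      w <- ranksum_u_counts(N, n1)
      p <- two_sided_from_dist(U, seq_along(w) - 1, w)
    } else {
      # within-group ties: enumerate subsets of the observed midranks
      if (choose(N, n1) > 5e5)
        stop("exact enumeration infeasible for n1 + n2 = ", N,
             " with ties; use mode = 'normal'")
      idx <- utils::combn(N, n1)
      sums <- colSums(matrix(r[idx], nrow = n1))
      us <- sums - n1 * (n1 + 1) / 2
      p <- two_sided_from_dist(U, us, rep(1, length(us)))
    }
  } else {
    mu <- n1 * n2 / 2
    t_tab <- table(pooled)
    tie_term <- sum(t_tab^3 - t_tab) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * (N + 1 - tie_term)
    if (sigma2 <= 0) return(list(U = U, p_value = 1))
    cc <- if (U > mu) -0.5 else if (U < mu) 0.5 else 0
    z <- (U - mu + cc) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(U = U, p_value = p)
}

#' Signed fold change between group means
#'
#' Ratio r of case to control aggregate expression (linear scale), reported
#' as +r when r >= 1 and -1/r when r < 1, so magnitude is always >= 1 and
#' the sign gives the direction of regulation in cases.
#'
#' @param case_values,control_values positive numeric vectors.
#' @param agg aggregate: `"mean"` (default) or `"median"`.
#' @return list with `fold_change_signed` and `direction`
#'   (`"up"`, `"down"` or `"flat"`).
#' @export
#' @examples
#' signed_fold_change(c(4, 4), c(2, 2))  # +2, up
signed_fold_change <- function(case_values, control_values,
                               agg = c("mean", "median")) {
  agg <- match.arg(agg)
  f <- if (agg == "mean") mean else stats::median
  m1 <- f(case_values); m2 <- f(control_values)
  if (!is.finite(m1) || !is.finite(m2) || m1 <= 0 || m2 <= 0)
    stop("group aggregates must be positive")
  r <- m1 / m2
  fc <- if (r >= 1) r else -1 / r
  dir <- if (r > 1) "up" else if (r < 1) "down" else "flat"
  list(fold_change_signed = fc, direction = dir)
}

#' Present-call features
#'
#' A feature is called present when its log2 expression exceeds `floor` in
#' at least `min_frac` of the samples of at least one group.
#'
#' @param dataset an [expression_dataset].
#' @param floor detection floor on the log2 scale.
#' @param min_frac minimum fraction of samples above floor, in (0, 1].
#' @return named logical vector of presence flags.
#' @export
call_present <- function(dataset, floor = 4, min_frac = 0.5) {
  if (!(min_frac > 0 && min_frac <= 1)) stop("min_frac must be in (0, 1]")
  g <- split_groups(dataset)
  frac_case <- rowMeans(log2(g$case) > floor)
  frac_control <- rowMeans(log2(g$control) > floor)
  present <- frac_case >= min_frac | frac_control >= min_frac
  names(present) <- rownames(dataset$values)
  present
}

#' Run the full differential-expression stage
#'
#' Present-calls features, then per present feature computes rank sums, the
#' complete-separation flag, the Mann-Whitney U and two-sided p, and the
#' signed fold change. A feature is "regulated" when p <= alpha; the
#' distinct flag is reported among regulated features.
#'
#' @param dataset an [expression_dataset].
#' @param alpha regulation threshold on the raw two-sided p (inclusive).
#' @param floor,min_frac present-call parameters, see [call_present()].
#' @param mode Mann-Whitney mode, see [mann_whitney_p()].
#' @param agg fold-change aggregate, see [signed_fold_change()].
#' @param adjust `"none"` (default; raw p governs regulation) or `"BH"`
#'   (adds a Benjamini-Hochberg column `p_adjusted`; regulation then uses
#'   the adjusted value).
#' @return data.frame (one row per feature) with columns `feature_id`,
#'   `present`, `rank_sum_case`, `rank_sum_control`, `rank_sum_diff`,
#'   `max_rank_sum_diff`, `distinct`, `U`, `p_value`, `fold_change_signed`,
#'   `direction`, `regulated`; absent features carry NA statistics.
#'   Attribute `summary` holds the counts (present, regulated, up, down,
#'   distinct).
#' @export
run_de <- function(dataset, alpha = 0.05, floor = 4, min_frac = 0.5,
                   mode = c("auto", "exact", "normal"),
                   agg = c("mean", "median"),
                   adjust = c("none", "BH")) {
  mode <- match.arg(mode); agg <- match.arg(agg); adjust <- match.arg(adjust)
  present <- call_present(dataset, floor = floor, min_frac = min_frac)
  g <- split_groups(dataset)
  ids <- rownames(dataset$values)
  n <- length(ids)

  res <- data.frame(feature_id = ids, present = as.logical(present),
                    rank_sum_case = NA_real_, rank_sum_control = NA_real_,
                    rank_sum_diff = NA_real_, max_rank_sum_diff = NA_real_,
                    distinct = NA, U = NA_real_, p_value = NA_real_,
                    fold_change_signed = NA_real_,
                    direction = NA_character_, regulated = NA,
                    stringsAsFactors = FALSE)

  for (i in which(present)) {
    cv <- g$case[i, ]; xv <- g$control[i, ]
    rs <- rank_sum_difference(cv, xv)
    mw <- mann_whitney_p(cv, xv, mode = mode)
    fc <- signed_fold_change(cv, xv, agg = agg)
    res$rank_sum_case[i] <- rs$rank_sum_case
    res$rank_sum_control[i] <- rs$rank_sum_control
    res$rank_sum_diff[i] <- rs$rank_sum_diff
    res$max_rank_sum_diff[i] <- rs$max_rank_sum_diff
    res$distinct[i] <- rs$distinct
    res$U[i] <- mw$U
    res$p_value[i] <- mw$p_value
    res$fold_change_signed[i] <- fc$fold_change_signed
    res$direction[i] <- fc$direction
  }

  if (adjust == "BH") {
    res$p_adjusted <- NA_real_
    res$p_adjusted[res$present] <- stats::p.adjust(res$p_value[res$present],
                                                   method = "BH")
    p_gov <- res$p_adjusted
  } else {
    p_gov <- res$p_value
  }
  res$regulated <- res$present & !is.na(p_gov) & p_gov <= alpha
  # distinctness is reported among regulated features
  res$distinct <- res$present & res$distinct & res$regulated

  summ <- c(present = sum(res$present),
            regulated = sum(res$regulated, na.rm = TRUE),
            up = sum(res$regulated & res$direction == "up", na.rm = TRUE),
            down = sum(res$regulated & res$direction == "down", na.rm = TRUE),
            distinct = sum(res$distinct, na.rm = TRUE))
  attr(res, "summary") <- summ
  res
}
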