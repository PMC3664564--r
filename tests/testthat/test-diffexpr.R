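# Rank statistics, exact Mann-Whitney, fold changes, present-calling.

test_that("rank-sum difference and complete separation on hand-ranked cases", {
  rs <- rank_sum_difference(c(5, 6, 7), c(1, 2, 3))
  expect_equal(rs$rank_sum_case, 15)
  expect_equal(rs$rank_sum_control, 6)
  expect_equal(rs$rank_sum_diff, 9)
  expect_equal(rs$max_rank_sum_diff, 9)
  expect_true(rs$distinct)

  # interleaved groups overlap
  expect_false(rank_sum_difference(c(1, 3), c(2, 4))$distinct)

  # 7 vs 7 complete separation: sum(8..14) - sum(1..7) = 49
  rs7 <- rank_sum_difference(8:14 + stats::runif(7, 0, 0.5), 1:7)
  expect_equal(rs7$max_rank_sum_diff, 49)
  expect_equal(rs7$rank_sum_diff, 49)
  expect_true(rs7$distinct)

  # downward separation mirrors
  rs_dn <- rank_sum_difference(c(1, 2, 3), c(5, 6, 7))
  expect_equal(rs_dn$rank_sum_diff, -9)
  expect_true(rs_dn$distinct)

  # cross-group tie at the boundary forbids distinctness
  expect_false(rank_sum_difference(c(2, 3, 4), c(1, 2, 2))$distinct)

  expect_error(rank_sum_difference(numeric(0), 1:3), "non-empty")
})

test_that("distinct flag is equivalent to the value-overlap definition", {
  set.seed(11)
  for (i in 1:500) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    # mix continuous and heavily tied data
    v <- if (i %% 2 == 0) stats::rnorm(n1 + n2) else
      sample(1:4, n1 + n2, replace = TRUE)
    cs <- v[seq_len(n1)]; ct <- v[n1 + seq_len(n2)]
    # overlap definition forbids boundary ties too
    expected <- (max(cs) < min(ct)) || (max(ct) < min(cs))
    expect_identical(rank_sum_difference(cs, ct)$distinct, expected)
  }
})

test_that("exact Mann-Whitney p matches enumeration and known values", {
  expect_equal(mann_whitney_p(c(5, 6, 7), c(1, 2, 3), "exact")$p_value,
               2 / 20)
  expect_equal(mann_whitney_p(8:14, 1:7, "exact")$p_value, 2 / 3432)
  # identical multisets: cross-group ties, auto falls back to normal, p = 1
  expect_equal(mann_whitney_p(c(1, 2, 3), c(1, 2, 3), "auto")$p_value, 1)
  expect_error(mann_whitney_p(c(1, 2), c(2, 3), "exact"), "cross-group ties")

  set.seed(7)
  for (i in 1:40) {
    g <- random_groups(sample(2:7, 1), sample(2:7, 1))
    got <- mann_whitney_p(g$case, g$control, "exact")$p_value
    expect_equal(got, brute_mw_p(g$case, g$control), tolerance = 1e-12)
    # cross-check against the standard exact implementation
    expect_equal(got,
                 stats::wilcox.test(g$case, g$control, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("exact enumeration handles within-group ties via midranks", {
  cs <- c(2, 2, 5); ct <- c(1, 3, 4)  # tie within case only
  got <- mann_whitney_p(cs, ct, "exact")$p_value
  expect_equal(got, brute_mw_p(cs, ct), tolerance = 1e-12)
})

test_that("normal approximation is tie-corrected and close to exact", {
  g <- random_groups(8, 9)
  p_norm <- mann_whitney_p(g$case, g$control, "normal")$p_value
  p_ref <- suppressWarnings(
    stats::wilcox.test(g$case, g$control, exact = FALSE,
                       correct = TRUE)$p.value)
  expect_equal(p_norm, p_ref, tolerance = 1e-10)
})

test_that("p-value never increases as an already-higher case group moves up", {
  set.seed(21)
  for (rep in 1:20) {
    g <- random_groups(5, 6)
    span <- max(g$control) - min(g$case)
    shifts <- seq(0, span + 2, length.out = 12)
    stats <- t(vapply(shifts, function(s) {
      c(d = rank_sum_difference(g$case + s, g$control)$rank_sum_diff,
        p = mann_whitney_p(g$case + s, g$control, "exact")$p_value)
    }, numeric(2)))
    # once the case group sits at or above the control group in rank terms,
    # pushing it further up can only sharpen the evidence
    upper <- stats[stats[, "d"] >= 0, "p"]
    expect_true(all(diff(upper) <= 1e-12))
  }
})

test_that("signed fold change follows the ratio convention", {
  expect_equal(signed_fold_change(c(4, 4), c(2, 2))$fold_change_signed, 2)
  expect_equal(signed_fold_change(c(1, 1), c(4, 4))$fold_change_signed, -4)
  flat <- signed_fold_change(c(3, 3), c(3, 3))
  expect_equal(flat$fold_change_signed, 1)
  expect_equal(flat$direction, "flat")
  expect_error(signed_fold_change(c(0, 0), c(1, 1)), "positive")

  # antisymmetry for r != 1
  set.seed(3)
  for (i in 1:50) {
    a <- stats::rlnorm(5); b <- stats::rlnorm(5)
    if (mean(a) == mean(b)) next
    expect_equal(signed_fold_change(a, b)$fold_change_signed,
                 -signed_fold_change(b, a)$fold_change_signed,
                 tolerance = 1e-12)
  }

  # median aggregation is available
  expect_equal(signed_fold_change(c(2, 2, 100), c(1, 1, 1),
                                  agg = "median")$fold_change_signed, 2)
})

test_that("present-calling uses floor and per-group fraction", {
  m <- rbind(ALL_HIGH = rep(2^6, 4),
             ALL_LOW = rep(2^2, 4),
             CASE_ONLY = c(2^6, 2^6, 2^2, 2^2))
  colnames(m) <- paste0("S", 1:4)
  ds <- expression_dataset(m, data.frame(
    id = paste0("S", 1:4), group = rep(c("case", "control"), each = 2)))
  p <- call_present(ds, floor = 4, min_frac = 0.5)
  expect_true(p[["ALL_HIGH"]])
  expect_false(p[["ALL_LOW"]])
  expect_true(p[["CASE_ONLY"]])  # present in one group suffices
  expect_equal(sum(call_present(ds, floor = -Inf)), nrow(m))
})

test_that("run_de flags planted effects and reports summary counts", {
  cfg <- synthetic_config(n_mrna = 120, n_mirna = 20, n_de_mrna = 12,
                          n_de_mirna = 4, n_distinct = 4, n_true_pairs = 4,
                          noise_sd = 0, log_fc_mean = 1, log_fc_sd = 0,
                          seed = 5)
  ds <- generate_dataset(cfg)
  de <- run_de(ds$mrna)
  s <- attr(de, "summary")
  expect_named(s, c("present", "regulated", "up", "down", "distinct"))
  truth <- ds$truth
  got <- de[match(truth$de_mrna_ids, de$feature_id), ]
  # noiseless planted effects: all regulated, correct direction, distinct
  expect_true(all(got$regulated))
  expect_identical(unname(got$direction),
                   unname(truth$mrna_directions[got$feature_id]))
  expect_true(all(got$distinct))  # noiseless separation is complete
  expect_equal(s[["up"]] + s[["down"]], s[["regulated"]])
  # absent features carry NA statistics
  expect_true(all(is.na(de$p_value[!de$present])))
})

test_that("BH adjustment is available and governs regulation when chosen", {
  cfg <- synthetic_config(n_mrna = 80, n_mirna = 20, n_de_mrna = 8,
                          n_de_mirna = 2, n_distinct = 0, n_true_pairs = 2,
                          seed = 9)
  ds <- generate_dataset(cfg)
  de_raw <- run_de(ds$mrna, adjust = "none")
  de_bh <- run_de(ds$mrna, adjust = "BH")
  expect_true("p_adjusted" %in% names(de_bh))
  expect_true(all(de_bh$p_adjusted >= de_bh$p_value, na.rm = TRUE))
  expect_lte(sum(de_bh$regulated), sum(de_raw$regulated))
})
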