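# Synthetic study generator: determinism, planted structure, feasibility.

small_cfg <- function(...) {
  args <- list(n_mrna = 120, n_mirna = 24, n_de_mrna = 12, n_de_mirna = 4,
               n_distinct = 4, n_true_pairs = 6, seed = 42)
  override <- list(...)
  args[names(override)] <- override
  do.call(synthetic_config, args)
}

test_that("identical configurations give identical artifacts", {
  cfg <- small_cfg()
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(a, b)
  sa <- generate_sequences(cfg, a$truth)
  sb <- generate_sequences(cfg, b$truth)
  expect_identical(sa, sb)
  va <- generate_validation_table(sa$truth, a, noise_sd = 0.3, seed = 2)
  vb <- generate_validation_table(sb$truth, b, noise_sd = 0.3, seed = 2)
  expect_identical(va, vb)
  # generator does not disturb the session RNG stream
  set.seed(99); before <- stats::runif(3)
  set.seed(99); invisible(generate_dataset(cfg)); after <- stats::runif(3)
  expect_identical(before, after)
})

test_that("infeasible configurations are rejected up front", {
  expect_error(synthetic_config(n_distinct = 20, n_de_mrna = 10),
               "n_distinct")
  expect_error(synthetic_config(n_de_mirna = 2, max_targets = 2,
                                n_true_pairs = 5, n_de_mrna = 50),
               "n_true_pairs")
  expect_error(synthetic_config(frac_absent = 1), "frac_absent")
  expect_error(synthetic_config(n_mrna = 10, n_de_mrna = 50), "more DE")
  expect_error(small_cfg(utr_len = 10), NA)  # validated at sequence time
  expect_error(generate_sequences(small_cfg(utr_len = 10),
                                  generate_dataset(small_cfg())$truth),
               "utr_len too short")
})

test_that("noiseless planted effects are exact and distinct features separate", {
  cfg <- small_cfg(noise_sd = 0, log_fc_mean = 1, log_fc_sd = 0, gap = 1)
  ds <- generate_dataset(cfg)
  g <- split_groups(ds$mrna)
  truth <- ds$truth
  for (id in truth$de_mrna_ids) {
    fc <- signed_fold_change(g$case[id, ], g$control[id, ])$fold_change_signed
    expect_equal(abs(fc), 2, tolerance = 1e-12)
    expect_equal(unname(sign(fc) > 0),
                 unname(truth$mrna_directions[[id]] == "up"))
  }
  # planted distinct features: complete separation by construction
  for (id in truth$distinct_ids) {
    expect_true(overlap_distinct(g$case[id, ], g$control[id, ]))
    expect_true(rank_sum_difference(g$case[id, ], g$control[id, ])$distinct)
  }
})

test_that("distinct features separate at the default noise level too", {
  cfg <- small_cfg()
  g <- split_groups(generate_dataset(cfg)$mrna)
  for (id in generate_dataset(cfg)$truth$distinct_ids)
    expect_true(overlap_distinct(g$case[id, ], g$control[id, ]))
})

test_that("absent features stay below the present-call floor", {
  cfg <- small_cfg()
  ds <- generate_dataset(cfg)
  p <- call_present(ds$mrna, floor = cfg$floor, min_frac = 0.5)
  expect_false(any(p[ds$truth$absent_mrna_ids]))
  expect_true(all(log2(ds$mrna$values[ds$truth$absent_mrna_ids, ]) <
                    cfg$floor))
})

test_that("true pairs always have opposite planted directions", {
  for (seed in c(1, 7, 23)) {
    tp <- generate_dataset(small_cfg(seed = seed))$truth$true_pairs
    expect_true(all(tp$mirna_direction != tp$mrna_direction))
  }
})

test_that("planted seed sites are written at the recorded offsets", {
  cfg <- small_cfg()
  ds <- generate_dataset(cfg)
  sq <- generate_sequences(cfg, ds$truth)
  ps <- sq$truth$planted_sites
  expect_equal(nrow(ps), cfg$n_true_pairs)
  for (i in seq_len(nrow(ps))) {
    m <- chartr("U", "T", sq$mirna_seqs[[ps$mirna_id[i]]])
    rc <- function(s) paste(rev(strsplit(chartr("ACGT", "TGCA", s), "",
                                         fixed = TRUE)[[1]]), collapse = "")
    site <- paste0(rc(substr(m, 2, 8)), "A")  # default 8mer
    u <- sq$utr_seqs[[ps$mrna_id[i]]]
    expect_identical(substr(u, ps$utr_position[i] + 1,
                            ps$utr_position[i] + 8), site)
  }
  # no planted sites without true pairs
  cfg0 <- small_cfg(n_true_pairs = 0)
  sq0 <- generate_sequences(cfg0, generate_dataset(cfg0)$truth)
  expect_equal(nrow(sq0$truth$planted_sites), 0)
})

test_that("noiseless validation reproduces screening fold changes exactly", {
  cfg <- small_cfg()
  ds <- generate_dataset(cfg)
  qpcr <- generate_validation_table(ds$truth, ds, noise_sd = 0, seed = 1)
  curve <- attr(qpcr, "curve")
  rel <- qpcr_relative_expression(qpcr, curve, reference_id = "REF")
  groups <- ds$mrna$sample_meta$group[match(colnames(rel),
                                            ds$mrna$sample_meta$id)]
  feats <- rownames(rel)
  all_vals <- rbind(ds$mrna$values, ds$mirna$values)
  for (f in feats) {
    expect_equal(unname(rel[f, ]), unname(all_vals[f, colnames(rel)]),
                 tolerance = 1e-9)
  }
  val_fc <- vapply(feats, function(f)
    signed_fold_change(rel[f, groups == "case"],
                       rel[f, groups == "control"])$fold_change_signed,
    numeric(1))
  scr_fc <- vapply(feats, function(f)
    signed_fold_change(all_vals[f, colnames(rel)][groups == "case"],
                       all_vals[f, colnames(rel)][groups == "control"])$fold_change_signed,
    numeric(1))
  expect_equal(val_fc, scr_fc, tolerance = 1e-9)
  expect_equal(spearman_rho(scr_fc, val_fc), 1)
  # the reference feature is constant across samples by construction
  ct_ref <- qpcr[qpcr$feature_id == "REF", ]
  expect_equal(length(unique(ct_ref$ct)), 1)
  expect_error(generate_validation_table(ds$truth, ds,
                                         features = "NOPE"), "unknown")
})

test_that("moderate-noise validation is reproducible and mostly concordant", {
  cfg <- small_cfg()
  ds <- generate_dataset(cfg)
  q1 <- generate_validation_table(ds$truth, ds, noise_sd = 0.3, seed = 4)
  q2 <- generate_validation_table(ds$truth, ds, noise_sd = 0.3, seed = 4)
  expect_identical(q1, q2)
  rel <- qpcr_relative_expression(q1, attr(q1, "curve"), "REF")
  groups <- ds$mrna$sample_meta$group[match(colnames(rel),
                                            ds$mrna$sample_meta$id)]
  all_vals <- rbind(ds$mrna$values, ds$mirna$values)[, colnames(rel)]
  feats <- rownames(rel)
  val_fc <- vapply(feats, function(f)
    signed_fold_change(rel[f, groups == "case"],
                       rel[f, groups == "control"])$fold_change_signed,
    numeric(1))
  scr_fc <- vapply(feats, function(f)
    signed_fold_change(all_vals[f, groups == "case"],
                       all_vals[f, groups == "control"])$fold_change_signed,
    numeric(1))
  conc <- sign_concordance(scr_fc, val_fc)
  expect_gte(conc$n_same, round(0.8 * conc$n_total))
})

test_that("planted DE features are recoverable at the stated conditions", {
  cfg <- synthetic_config(n_mrna = 500, n_mirna = 50, n_de_mrna = 25,
                          n_de_mirna = 5, n_distinct = 5, n_true_pairs = 10,
                          log_fc_mean = 2, noise_sd = 0.5, seed = 8)
  ds <- generate_dataset(cfg)
  de <- run_de(ds$mrna)
  rec <- mean(de$regulated[match(ds$truth$de_mrna_ids, de$feature_id)])
  expect_gte(rec, 0.9)
})
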