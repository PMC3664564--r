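# Opposite-direction pair assembly, genomic map / hotspot scan,
# sign concordance.

mk_de <- function(ids, fc, p, distinct = rep(FALSE, length(ids))) {
  data.frame(feature_id = ids, fold_change_signed = fc, p_value = p,
             distinct = distinct, stringsAsFactors = FALSE)
}

test_that("pairs require opposite directions and joint significance", {
  de_mi <- mk_de("m1", 2.0, 0.01)
  de_up <- mk_de("t1", 1.8, 0.02)
  de_dn <- mk_de("t1", -1.8, 0.02)
  de_ns <- mk_de("t1", -1.8, 0.2)
  pred <- data.frame(mirna_id = "m1", transcript_id = "t1", score = 4)
  expect_equal(nrow(assemble_pairs(de_dn, de_mi, pred)), 1)
  expect_equal(nrow(assemble_pairs(de_up, de_mi, pred)), 0)  # both up
  expect_equal(nrow(assemble_pairs(de_ns, de_mi, pred)), 0)  # mRNA n.s.
  # flat features never pair
  expect_equal(nrow(assemble_pairs(mk_de("t1", 1, 0.01), de_mi, pred)), 0)
  pair <- assemble_pairs(de_dn, de_mi, pred)
  expect_equal(pair$mirna_fc_signed, 2.0)
  expect_equal(pair$mrna_fc_signed, -1.8)
  expect_equal(pair$prediction_score, 4)
})

test_that("pair assembly is canonical in order and prediction-row driven", {
  de_mi <- mk_de(c("m1", "m2"), c(2, -2), c(0.01, 0.01))
  de_mr <- mk_de(c("t1", "t2", "t3"), c(-2, 2, -3), c(0.01, 0.01, 0.01))
  pred <- data.frame(mirna_id = c("m2", "m1", "m1"),
                     transcript_id = c("t2", "t3", "t1"),
                     score = c(1, 2, 3))
  p1 <- assemble_pairs(de_mr, de_mi, pred)
  p2 <- assemble_pairs(de_mr, de_mi, pred[c(3, 1, 2), ])
  expect_identical(p1, p2)  # row-order invariant
  expect_equal(p1$mrna_id, sort(p1$mrna_id))
  # removing one prediction row removes exactly that pair
  p3 <- assemble_pairs(de_mr, de_mi, pred[-2, ])
  expect_equal(nrow(p3), nrow(p1) - 1)
  expect_false("t3" %in% p3$mrna_id)
  # duplicate prediction rows collapse to one pair with the best score
  p4 <- assemble_pairs(de_mr, de_mi,
                       rbind(pred, data.frame(mirna_id = "m1",
                                              transcript_id = "t1",
                                              score = 5)))
  expect_equal(nrow(p4), nrow(p1))
  expect_equal(p4$prediction_score[p4$mrna_id == "t1"], 5)
})

test_that("unknown prediction ids are skipped with a warning and counted", {
  de_mi <- mk_de("m1", 2, 0.01)
  de_mr <- mk_de("t1", -2, 0.01)
  pred <- data.frame(mirna_id = c("m1", "mX"), transcript_id = c("t1", "t1"))
  expect_warning(p <- assemble_pairs(de_mr, de_mi, pred), "skipped")
  expect_equal(nrow(p), 1)
  expect_equal(attr(p, "n_skipped"), 1)
})

test_that("restrict_to_distinct limits the mRNA side", {
  de_mi <- mk_de("m1", 2, 0.01)
  de_mr <- mk_de(c("t1", "t2"), c(-2, -2), c(0.01, 0.01),
                 distinct = c(TRUE, FALSE))
  pred <- data.frame(mirna_id = "m1", transcript_id = c("t1", "t2"))
  expect_equal(nrow(assemble_pairs(de_mr, de_mi, pred)), 2)
  expect_equal(assemble_pairs(de_mr, de_mi, pred,
                              restrict_to_distinct = TRUE)$mrna_id, "t1")
})

test_that("planted pairs are recovered on synthetic data", {
  cfg <- synthetic_config(n_mrna = 300, n_mirna = 40, n_de_mrna = 30,
                          n_de_mirna = 6, n_distinct = 5, n_true_pairs = 12,
                          seed = 3)
  ds <- generate_dataset(cfg)
  sq <- generate_sequences(cfg, ds$truth, record_chance = FALSE)
  de_mr <- run_de(ds$mrna)
  de_mi <- run_de(ds$mirna)
  pred <- predict_table(sq$mirna_seqs[ds$truth$de_mirna_ids], sq$utr_seqs)
  pairs <- assemble_pairs(de_mr, de_mi, pred)
  tp <- ds$truth$true_pairs
  key <- function(a, b) paste(a, b, sep = "/")
  recall <- mean(key(tp$mirna_id, tp$mrna_id) %in%
                   key(pairs$mirna_id, pairs$mrna_id))
  expect_gte(recall, 0.9)
  # every reported pair obeys the opposite-direction rule
  expect_true(all(sign(pairs$mirna_fc_signed) != sign(pairs$mrna_fc_signed)))
})

test_that("hotspot scan flags a loaded window and counts unmapped features", {
  # 100 tested features in 10 windows; all 10 regulated in window 0
  n <- 100
  de <- data.frame(feature_id = paste0("F", 1:n), present = TRUE,
                   p_value = c(rep(0.01, 10), rep(0.5, n - 10)),
                   fold_change_signed = c(rep(2, 10), rep(1.1, n - 10)),
                   regulated = c(rep(TRUE, 10), rep(FALSE, n - 10)))
  meta <- data.frame(id = paste0("F", 1:n), chrom = "chr1",
                     position = c(seq(0, 9) * 1e5,          # window 0
                                  seq(10, n - 1) * 1e6))    # spread out
  gm <- genomic_map(de, meta, window_size = 1e6)
  w0 <- gm$hotspots[gm$hotspots$window_start == 0, ]
  expect_equal(w0$n_regulated, 10)
  # binomial tail oracle
  expect_equal(w0$p_binomial,
               stats::pbinom(9, 10, 0.1, lower.tail = FALSE))
  expect_lt(w0$p_binomial, 1e-8)
  expect_equal(nrow(gm$map), 10)
  expect_equal(gm$map$neg_log10_p, rep(-log10(0.01), 10))

  # features without coordinates are excluded but counted
  meta$position[1] <- NA
  gm2 <- genomic_map(de, meta, window_size = 1e6)
  expect_equal(attr(gm2, "n_unmapped"), 1)
  expect_equal(nrow(gm2$map), 9)
})

test_that("uniformly scattered regulated features raise no hotspots", {
  set.seed(13)
  n_low <- 0; n_windows <- 0
  for (rep in 1:20) {
    n <- 200
    de <- data.frame(feature_id = paste0("F", 1:n), present = TRUE,
                     p_value = 0.5, fold_change_signed = 1.2,
                     regulated = sample(c(TRUE, FALSE), n, replace = TRUE,
                                        prob = c(0.1, 0.9)))
    meta <- data.frame(id = paste0("F", 1:n),
                       chrom = sample(paste0("chr", 1:5), n, replace = TRUE),
                       position = sample.int(5e7, n))
    gm <- genomic_map(de, meta, window_size = 1e7)
    n_low <- n_low + sum(gm$hotspots$p_binomial < 0.001)
    n_windows <- n_windows + nrow(gm$hotspots)
  }
  expect_lte(n_low / n_windows, 0.01)
})

test_that("sign concordance counts matches and rejects unmatched ids", {
  a <- c(f1 = 2, f2 = -3, f3 = 1.5, f4 = -2)
  expect_equal(sign_concordance(a, a), list(n_same = 4, n_total = 4))
  b <- a; b["f2"] <- 3
  expect_equal(sign_concordance(a, b)$n_same, 3)
  # flat counts as discordant unless both flat
  expect_equal(sign_concordance(c(f1 = 1, f2 = 2),
                                c(f1 = 1, f2 = 1))$n_same, 1)
  expect_error(sign_concordance(a, a[-1]), "f1")
})
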