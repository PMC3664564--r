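# Synthetic two-platform study generator with planted ground truth.
#
# Emulates a small case-control two-platform design (default 7 vs 7): log2
# baselines drawn per feature, a fraction of features kept below the
# present-call floor ("absent"), a planted set of differentially expressed
# features shifted in cases by a signed log2 effect, a subset constructed
# with a guaranteed between-group gap (complete separation), and planted
# miRNA-target pairs in which the miRNA and the target always move in
# opposite directions. Companion generators emit mature-miRNA/3'UTR
# sequences with seed sites planted at recorded offsets, a flat GO
# annotation, and qPCR-like triplicate Ct tables tied to the expression
# values through a standard curve.
#
# All randomness flows from the single `seed` in the configuration; small
# fixed offsets of that seed keep the sequence/annotation/validation
# streams independent of the expression stream.

#' Build a synthetic-study configuration
#'
#' Defaults describe the emulated study conditions at reduced feature
#' scale: 7 cases vs 7 controls, ~20% absent features, a minority of
#' features differentially expressed with log2 effects around 2 against a
#' within-group log2 noise sd of 0.5, a small complete-separation subset,
#' and 11 planted miRNA-target pairs.
#'
#' @param n_case,n_control samples per group.
#' @param n_mrna,n_mirna total features per platform.
#' @param frac_absent fraction of features generated below the
#'   present-call floor, in \[0, 1).
#' @param n_de_mrna,n_de_mirna planted differentially expressed features.
#' @param n_distinct planted complete-separation mRNA features
#'   (subset of the DE mRNAs).
#' @param n_true_pairs planted miRNA-target pairs
#'   (<= min(n_de_mrna, n_de_mirna * max_targets)).
#' @param max_targets maximum planted targets per DE miRNA.
#' @param log_fc_mean,log_fc_sd signed effect magnitude on the log2 scale.
#' @param noise_sd within-group log2 noise sd.
#' @param gap guaranteed log2 gap for planted distinct features.
#' @param baseline_mean,baseline_sd log2 baseline distribution
#'   (floored at 0).
#' @param floor present-call floor (log2) the absent features stay below.
#' @param utr_len 3'UTR length in bases.
#' @param mirna_len mature miRNA length in bases.
#' @param site_type seed-site type planted for true pairs.
#' @param seed integer RNG seed; fully determines all generated artifacts.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_case = 7, n_control = 7,
                             n_mrna = 2000, n_mirna = 150,
                             frac_absent = 0.2,
                             n_de_mrna = 100, n_de_mirna = 12,
                             n_distinct = 8, n_true_pairs = 11,
                             max_targets = 5,
                             log_fc_mean = 2, log_fc_sd = 0.25,
                             noise_sd = 0.5, gap = 1,
                             baseline_mean = 7, baseline_sd = 2,
                             floor = 4, utr_len = 500, mirna_len = 22,
                             site_type = "8mer", seed = 1) {
  cfg <- list(n_case = n_case, n_control = n_control, n_mrna = n_mrna,
              n_mirna = n_mirna, frac_absent = frac_absent,
              n_de_mrna = n_de_mrna, n_de_mirna = n_de_mirna,
              n_distinct = n_distinct, n_true_pairs = n_true_pairs,
              max_targets = max_targets, log_fc_mean = log_fc_mean,
              log_fc_sd = log_fc_sd, noise_sd = noise_sd, gap = gap,
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              floor = floor, utr_len = utr_len, mirna_len = mirna_len,
              site_type = site_type, seed = seed)
  counts <- c("n_case", "n_control", "n_mrna", "n_mirna", "n_de_mrna",
              "n_de_mirna", "n_distinct", "n_true_pairs", "max_targets",
              "utr_len", "mirna_len")
  for (nm in counts) if (cfg[[nm]] < 0 || cfg[[nm]] != round(cfg[[nm]]))
    stop("configuration error: ", nm, " must be a non-negative count")
  if (!(frac_absent >= 0 && frac_absent < 1))
    stop("configuration error: frac_absent must be in [0, 1)")
  n_present_mrna <- n_mrna - round(frac_absent * n_mrna)
  n_present_mirna <- n_mirna - round(frac_absent * n_mirna)
  if (n_de_mrna > n_present_mrna || n_de_mirna > n_present_mirna)
    stop("configuration error: more DE features than present features")
  if (n_distinct > n_de_mrna)
    stop("configuration error: n_distinct > n_de_mrna")
  if (n_true_pairs > min(n_de_mrna, n_de_mirna * max_targets))
    stop("configuration error: n_true_pairs exceeds ",
         "min(n_de_mrna, n_de_mirna * max_targets)")
  if (!site_type %in% names(site_type_rank))
    stop("configuration error: unknown site_type ", site_type)
  if (n_case < 1 || n_control < 1)
    stop("configuration error: need at least one sample per group")
  structure(cfg, class = "synthetic_config")
}

# one platform's worth of log2 values + truth bookkeeping
simulate_platform <- function(cfg, prefix, n_feat, n_de,
                              de_signs, distinct_in_de_idx) {
  n_samp <- cfg$n_case + cfg$n_control
  ids <- sprintf("%s%04d", prefix, seq_len(n_feat))
  n_absent <- round(cfg$frac_absent * n_feat)
  absent_idx <- if (n_absent > 0) sample(n_feat, n_absent) else integer(0)
  present_idx <- setdiff(seq_len(n_feat), absent_idx)
  de_idx <- if (n_de > 0) sample(present_idx, n_de) else integer(0)

  baseline <- pmax(stats::rnorm(n_feat, cfg$baseline_mean, cfg$baseline_sd), 0)
  effects <- abs(stats::rnorm(n_de, cfg$log_fc_mean, cfg$log_fc_sd))

  l2 <- matrix(baseline, n_feat, n_samp) +
    matrix(stats::rnorm(n_feat * n_samp, 0, cfg$noise_sd), n_feat, n_samp)
  case_cols <- seq_len(cfg$n_case)
  ctrl_cols <- cfg$n_case + seq_len(cfg$n_control)

  if (n_de > 0)
    l2[de_idx, case_cols] <- l2[de_idx, case_cols] + de_signs * effects

  # distinct features: rebuild with a guaranteed between-group gap
  distinct_idx <- de_idx[distinct_in_de_idx]
  for (j in seq_along(distinct_idx)) {
    i <- distinct_idx[j]
    s <- de_signs[distinct_in_de_idx[j]]
    ctrl <- baseline[i] + stats::rnorm(cfg$n_control, 0, cfg$noise_sd)
    off <- abs(stats::rnorm(cfg$n_case, 0, cfg$noise_sd))
    cs <- if (s > 0) max(ctrl) + cfg$gap + off else min(ctrl) - cfg$gap - off
    l2[i, case_cols] <- cs
    l2[i, ctrl_cols] <- ctrl
  }

  # absent features: below the present-call floor in every sample
  if (n_absent > 0) {
    ab_base <- stats::runif(n_absent, 0, cfg$floor - 1)
    ab <- matrix(ab_base, n_absent, n_samp) +
      matrix(stats::rnorm(n_absent * n_samp, 0, 0.5), n_absent, n_samp)
    l2[absent_idx, ] <- pmin(ab, cfg$floor - 0.05)
  }

  l2 <- pmax(l2, -10)  # keep linear values positive but tiny-capped
  list(ids = ids, log2 = l2, absent_idx = absent_idx, de_idx = de_idx,
       distinct_idx = distinct_idx)
}

#' Generate a synthetic two-platform dataset with ground truth
#'
#' @param config a [synthetic_config()].
#' @return list with `mrna` and `mirna` ([expression_dataset]s, linear
#'   scale) and `truth`: a list recording `de_mrna_ids`, `de_mirna_ids`,
#'   `distinct_ids`, `mrna_directions` / `mirna_directions` (named
#'   `"up"`/`"down"`), `absent_mrna_ids`, `absent_mirna_ids`,
#'   `true_pairs` (data.frame `mirna_id`, `mrna_id`, `mirna_direction`,
#'   `mrna_direction`), all feature ids, and (after
#'   [generate_sequences()]) `planted_sites`.
#' @export
generate_dataset <- function(config) {
  cfg <- config
  if (!inherits(cfg, "synthetic_config")) stop("config must be a synthetic_config")
  with_seed(cfg$seed, {
    n_samp <- cfg$n_case + cfg$n_control
    sample_ids <- c(sprintf("L%d", seq_len(cfg$n_case)),
                    sprintf("H%d", seq_len(cfg$n_control)))
    groups <- c(rep("case", cfg$n_case), rep("control", cfg$n_control))

    # miRNA directions drawn first; paired targets get the opposite sign
    mirna_signs <- sample(c(-1, 1), cfg$n_de_mirna, replace = TRUE)
    pair_mirna_slot <- if (cfg$n_true_pairs > 0)
      rep(seq_len(max(cfg$n_de_mirna, 1)),
          length.out = cfg$n_true_pairs) else integer(0)
    mrna_signs <- sample(c(-1, 1), cfg$n_de_mrna, replace = TRUE)
    if (cfg$n_true_pairs > 0)
      mrna_signs[seq_len(cfg$n_true_pairs)] <-
        -mirna_signs[pair_mirna_slot]

    distinct_slots <- if (cfg$n_distinct > 0)
      seq_len(cfg$n_distinct) else integer(0)  # first DE mRNAs, incl. pairs

    mr <- simulate_platform(cfg, "MRNA", cfg$n_mrna, cfg$n_de_mrna,
                            mrna_signs, distinct_slots)
    mi <- simulate_platform(cfg, "MIR", cfg$n_mirna, cfg$n_de_mirna,
                            mirna_signs, integer(0))

    chrom_mr <- sample(paste0("chr", 1:22), cfg$n_mrna, replace = TRUE)
    pos_mr <- sample.int(2.4e8, cfg$n_mrna, replace = TRUE) - 1L
    chrom_mi <- sample(paste0("chr", 1:22), cfg$n_mirna, replace = TRUE)
    pos_mi <- sample.int(2.4e8, cfg$n_mirna, replace = TRUE) - 1L

    mk_ds <- function(p, kind, chrom, pos, symprefix) {
      vals <- 2^p$log2
      dimnames(vals) <- list(p$ids, sample_ids)
      fm <- data.frame(id = p$ids,
                       symbol = sub("^MRNA", symprefix,
                                    sub("^MIR", symprefix, p$ids)),
                       kind = kind, chrom = chrom, position = pos,
                       stringsAsFactors = FALSE)
      expression_dataset(vals, data.frame(id = sample_ids, group = groups,
                                          stringsAsFactors = FALSE),
                         feature_meta = fm, kind = kind)
    }
    mrna_ds <- mk_ds(mr, "mRNA", chrom_mr, pos_mr, "GENE")
    mirna_ds <- mk_ds(mi, "miRNA", chrom_mi, pos_mi, "MIRN")

    dir_of <- function(s) ifelse(s > 0, "up", "down")
    mrna_dirs <- stats::setNames(dir_of(mrna_signs), mr$ids[mr$de_idx])
    mirna_dirs <- stats::setNames(dir_of(mirna_signs), mi$ids[mi$de_idx])

    true_pairs <- if (cfg$n_true_pairs > 0) {
      data.frame(mirna_id = mi$ids[mi$de_idx][pair_mirna_slot],
                 mrna_id = mr$ids[mr$de_idx][seq_len(cfg$n_true_pairs)],
                 mirna_direction = dir_of(mirna_signs[pair_mirna_slot]),
                 mrna_direction = dir_of(mrna_signs[seq_len(cfg$n_true_pairs)]),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(mirna_id = character(), mrna_id = character(),
                 mirna_direction = character(), mrna_direction = character(),
                 stringsAsFactors = FALSE)
    }

    truth <- list(mrna_ids = mr$ids, mirna_ids = mi$ids,
                  de_mrna_ids = mr$ids[mr$de_idx],
                  de_mirna_ids = mi$ids[mi$de_idx],
                  distinct_ids = mr$ids[mr$distinct_idx],
                  absent_mrna_ids = mr$ids[mr$absent_idx],
                  absent_mirna_ids = mi$ids[mi$absent_idx],
                  mrna_directions = mrna_dirs,
                  mirna_directions = mirna_dirs,
                  true_pairs = true_pairs,
                  planted_sites = NULL)
    list(mrna = mrna_ds, mirna = mirna_ds, truth = truth)
  })
}

# site string planted in a UTR for a given miRNA and site type (DNA, 5'->3')
planted_site_string <- function(mirna_dna, site_type) {
  switch(site_type,
         "8mer" = paste0(dna_revcomp(substr(mirna_dna, 2, 8)), "A"),
         "7mer-m8" = dna_revcomp(substr(mirna_dna, 2, 8)),
         "7mer-A1" = paste0(dna_revcomp(substr(mirna_dna, 2, 7)), "A"),
         "6mer" = dna_revcomp(substr(mirna_dna, 2, 7)),
         stop("unknown site type ", site_type))
}

#' Generate miRNA and 3'UTR sequences with planted seed sites
#'
#' Random-composition sequences for every miRNA (RNA alphabet) and every
#' mRNA 3'UTR (DNA alphabet); for each planted true pair, a seed-match
#' site of the configured type is written into the target's UTR at a
#' recorded 0-based offset, with flanking bases adjusted so the site
#' scans back as exactly the planted type. No sites are planted for
#' non-pairs; chance seed matches elsewhere are detected by scanning and
#' recorded in `truth$chance_sites`.
#'
#' @param config a [synthetic_config()].
#' @param truth ground truth from [generate_dataset()].
#' @param record_chance scan all sequences for accidental seed matches and
#'   record them (can be disabled to skip the genome-wide scan).
#' @return list with `mirna_seqs` (named, RNA), `utr_seqs` (named, DNA)
#'   and updated `truth` carrying `planted_sites` and `chance_sites`.
#' @export
generate_sequences <- function(config, truth, record_chance = TRUE) {
  cfg <- config
  site_len <- nchar(planted_site_string(paste(rep("A", 22), collapse = ""),
                                        cfg$site_type))
  # margin so flank fixes and the 3'-supplementary region stay in range
  if (cfg$utr_len < site_len + 12)
    stop("configuration error: utr_len too short for a ", cfg$site_type,
         " site")
  with_seed(cfg$seed + 104729L, {
    mirna_seqs <- vapply(truth$mirna_ids, function(id)
      paste(sample(c("A", "C", "G", "U"), cfg$mirna_len, replace = TRUE),
            collapse = ""), character(1))
    utr_seqs <- vapply(truth$mrna_ids, function(id)
      paste(sample(c("A", "C", "G", "T"), cfg$utr_len, replace = TRUE),
            collapse = ""), character(1))

    planted <- NULL
    tp <- truth$true_pairs
    used <- lapply(truth$mrna_ids, function(id) integer(0))
    names(used) <- truth$mrna_ids
    if (nrow(tp) > 0) {
      for (j in seq_len(nrow(tp))) {
        mid <- tp$mirna_id[j]; tid <- tp$mrna_id[j]
        m_dna <- as_dna(mirna_seqs[[mid]])
        site <- planted_site_string(m_dna, cfg$site_type)
        # keep one spare base on each side for flank disambiguation
        lo <- 10L  # room for the 3'-supplementary region 5' of the site
        hi <- cfg$utr_len - nchar(site) - 1L
        repeat {
          start0 <- sample(lo:hi, 1)  # 0-based
          span <- (start0 - 1):(start0 + nchar(site))
          if (!any(span %in% used[[tid]])) break
        }
        used[[tid]] <- c(used[[tid]], span)
        u <- utr_seqs[[tid]]
        substr(u, start0 + 1, start0 + nchar(site)) <- site
        # flank fixes so the scanner reports exactly the planted type
        if (cfg$site_type %in% c("7mer-m8", "6mer")) {
          a1_pos <- start0 + nchar(site) + 1  # 1-based base after the site
          if (substr(u, a1_pos, a1_pos) == "A")
            substr(u, a1_pos, a1_pos) <- "C"
        }
        if (cfg$site_type %in% c("7mer-A1", "6mer")) {
          m8_comp <- dna_complement(substr(m_dna, 8, 8))
          if (start0 >= 1 && substr(u, start0, start0) == m8_comp)
            substr(u, start0, start0) <-
              setdiff(c("A", "C", "G", "T"), m8_comp)[1]
        }
        utr_seqs[[tid]] <- u
        planted <- rbind(planted,
                         data.frame(mirna_id = mid, mrna_id = tid,
                                    site_type = cfg$site_type,
                                    utr_position = start0,
                                    stringsAsFactors = FALSE))
      }
    }
    truth$planted_sites <- planted %||%
      data.frame(mirna_id = character(), mrna_id = character(),
                 site_type = character(), utr_position = integer(),
                 stringsAsFactors = FALSE)

    # record chance seed matches (sites not planted)
    if (record_chance) {
      all_pred <- predict_table(mirna_seqs, utr_seqs, min_site_type = "6mer")
      sites <- attr(all_pred, "sites")
      pk <- paste(truth$planted_sites$mirna_id, truth$planted_sites$mrna_id,
                  truth$planted_sites$utr_position, sep = "\r")
      sk <- paste(sites$mirna_id, sites$transcript_id, sites$utr_start,
                  sep = "\r")
      truth$chance_sites <- sites[!sk %in% pk, , drop = FALSE]
    } else {
      truth$chance_sites <- NULL
    }

    list(mirna_seqs = mirna_seqs, utr_seqs = utr_seqs, truth = truth)
  })
}

#' Generate a flat GO annotation for the synthetic genes
#'
#' Random term assignments over the mRNA features, with one term made
#' more frequent among the planted DE genes so the enrichment stage has
#' signal to find, a small set of broad level-1 terms, and a category for
#' every term.
#'
#' @param config a [synthetic_config()].
#' @param truth ground truth from [generate_dataset()].
#' @param n_terms number of GO-like terms.
#' @return `go_mapping` list (`gene2term`, `terms`).
#' @export
generate_go_annotation <- function(config, truth, n_terms = 30) {
  cfg <- config
  categories <- c("proliferation", "apoptosis", "ion transport",
                  "immune process", "adhesion", "metabolism")
  with_seed(cfg$seed + 15485863L, {
    term_ids <- sprintf("T%04d", seq_len(n_terms))
    terms <- data.frame(term_id = term_ids,
                        name = paste("process", seq_len(n_terms)),
                        category = sample(categories, n_terms, replace = TRUE),
                        level = sample(c(1, 2, 3, 4), n_terms,
                                       replace = TRUE,
                                       prob = c(0.1, 0.3, 0.3, 0.3)),
                        stringsAsFactors = FALSE)
    genes <- truth$mrna_ids
    n_per_gene <- stats::rpois(length(genes), 2)
    g2t <- data.frame(
      gene_id = rep(genes, n_per_gene),
      term_id = sample(term_ids, sum(n_per_gene), replace = TRUE),
      stringsAsFactors = FALSE)
    # plant enrichment: first term preferentially on DE genes
    de <- truth$de_mrna_ids
    extra <- de[stats::runif(length(de)) < 0.5]
    if (length(extra))
      g2t <- rbind(g2t, data.frame(gene_id = extra, term_id = term_ids[1],
                                   stringsAsFactors = FALSE))
    g2t <- unique(g2t)
    g2t <- g2t[order(g2t$gene_id, g2t$term_id), , drop = FALSE]
    rownames(g2t) <- NULL
    structure(list(gene2term = g2t, terms = terms), class = "go_mapping")
  })
}

#' Generate a qPCR-like validation table tied to the expression data
#'
#' For each selected feature and sample, triplicate Ct values are derived
#' from the feature's linear expression through a standard curve
#' (`Ct = intercept + slope * log10(expression)`) plus Gaussian noise. A
#' constant reference feature (`REF`, relative quantity 1 in every
#' sample) is appended so the table round-trips through
#' [qpcr_relative_expression()]. At `noise_sd = 0` the recovered relative
#' expression equals the screening expression exactly.
#'
#' @param truth ground truth from [generate_dataset()].
#' @param datasets list with `mrna` and `mirna` [expression_dataset]s.
#' @param features feature ids to validate (default: all members of the
#'   planted true pairs).
#' @param noise_sd Ct noise sd.
#' @param seed RNG seed for the Ct noise.
#' @param slope,intercept standard-curve parameters (default slope
#'   -1/log10(2): one Ct per 2-fold, efficiency 1).
#' @param reference_id id given to the constant reference feature.
#' @return data.frame with columns `feature_id`, `sample_id`, `replicate`,
#'   `ct`; attribute `curve` holds the generating `standard_curve`.
#' @export
generate_validation_table <- function(truth, datasets, features = NULL,
                                      noise_sd = 0, seed = 1,
                                      slope = -1 / log10(2), intercept = 35,
                                      reference_id = "REF") {
  if (is.null(features))
    features <- unique(c(truth$true_pairs$mirna_id, truth$true_pairs$mrna_id))
  all_vals <- rbind(datasets$mrna$values, datasets$mirna$values)
  unknown <- setdiff(features, rownames(all_vals))
  if (length(unknown))
    stop("unknown feature id(s): ", paste(unknown, collapse = ", "))
  samples <- datasets$mrna$sample_meta$id
  feats <- c(features, reference_id)
  expr <- rbind(all_vals[features, , drop = FALSE],
                matrix(1, 1, length(samples),
                       dimnames = list(reference_id, samples)))
  grid <- expand.grid(replicate = 1:3, sample_id = samples,
                      feature_id = feats, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  base_ct <- intercept +
    slope * log10(expr[cbind(grid$feature_id, grid$sample_id)])
  ct <- with_seed(seed, base_ct + stats::rnorm(nrow(grid), 0, noise_sd))
  out <- data.frame(feature_id = grid$feature_id,
                    sample_id = grid$sample_id,
                    replicate = grid$replicate, ct = ct,
                    stringsAsFactors = FALSE)
  curve_q <- c(1, 10, 100)
  attr(out, "curve") <- fit_standard_curve(curve_q,
                                           intercept + slope * log10(curve_q))
  out
}
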