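# End-to-end orchestration: synthesize (or ingest) -> present-call/DE ->
# target prediction -> pairing -> genomic map -> GO -> structure ->
# validation. Every stage writes its outputs to the run directory; the
# intermediate files are the only inter-stage contract, and a manifest
# records the seed, configuration, summary counts and content digests so
# reruns can be verified byte for byte.

#' Build a pipeline configuration
#'
#' @param outdir output directory (created if needed).
#' @param synthetic a [synthetic_config()] describing the simulated study
#'   (the bundled mode of operation; pass pre-made inputs through the
#'   `inputs` argument instead to analyze real files).
#' @param inputs optional named list of paths
#'   (`mrna_matrix`, `mrna_sheet`, `mirna_matrix`, `mirna_sheet`,
#'   `mirna_fasta`, `utr_fasta`, `gene2term`, `term_table`, `predictions`,
#'   `qpcr`). When given, those stages read the files instead of
#'   simulating.
#' @param alpha regulation threshold.
#' @param floor,min_frac present-call parameters.
#' @param min_site_type weakest qualifying seed-site type.
#' @param restrict_to_distinct limit pairing to distinct mRNAs.
#' @param k_perm permutations for the concordance test.
#' @param validation_noise_sd Ct noise for the simulated validation table.
#' @param seed run seed (also the synthetic seed unless `synthetic` sets
#'   its own).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir, synthetic = synthetic_config(),
                            inputs = NULL, alpha = 0.05, floor = 4,
                            min_frac = 0.5, min_site_type = "6mer",
                            restrict_to_distinct = FALSE, k_perm = 10000,
                            validation_noise_sd = 0.25, seed = 1) {
  if (!is.null(inputs)) {
    missing_files <- unlist(inputs)[!file.exists(unlist(inputs))]
    if (length(missing_files))
      stop("input file(s) not found: ", paste(missing_files, collapse = ", "))
  }
  structure(list(outdir = outdir, synthetic = synthetic, inputs = inputs,
                 alpha = alpha, floor = floor, min_frac = min_frac,
                 min_site_type = min_site_type,
                 restrict_to_distinct = restrict_to_distinct,
                 k_perm = k_perm, validation_noise_sd = validation_noise_sd,
                 seed = seed),
            class = "pipeline_config")
}

#' Small demonstration configuration
#'
#' A reduced-scale synthetic study sized so the whole pipeline completes
#' in seconds: 7 vs 7 samples, 400 mRNAs / 60 miRNAs, 40 DE mRNAs, 8 DE
#' miRNAs, 8 planted pairs.
#'
#' @param outdir output directory.
#' @param seed run seed.
#' @return a `pipeline_config`.
#' @export
demo_pipeline_config <- function(outdir, seed = 1) {
  pipeline_config(
    outdir,
    synthetic = synthetic_config(n_mrna = 400, n_mirna = 60,
                                 n_de_mrna = 40, n_de_mirna = 8,
                                 n_distinct = 5, n_true_pairs = 8,
                                 seed = seed),
    k_perm = 2000, seed = seed)
}

stage_msg <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the full pipeline
#'
#' Executes every stage in order, writing all tables under
#' `config$outdir` and returning (and writing) a manifest with the seed,
#' summary counts and md5 digests of every output file. For a fixed
#' configuration and seed the outputs are byte-identical across reruns.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, the manifest list (also written as
#'   `manifest.json`).
#' @export
run_all <- function(config) {
  cfg <- config
  out <- cfg$outdir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  wr <- function(df, name) {
    p <- file.path(out, name)
    write_result_table(df, p)
    paths[[name]] <<- p
    p
  }

  # -- stage: data (simulate or ingest) ---------------------------------
  if (is.null(cfg$inputs)) {
    stage_msg("simulate", "generating synthetic study (seed ",
              cfg$synthetic$seed, ")")
    ds <- generate_dataset(cfg$synthetic)
    seqs <- generate_sequences(cfg$synthetic, ds$truth,
                               record_chance = FALSE)
    ds$truth <- seqs$truth
    go <- generate_go_annotation(cfg$synthetic, ds$truth)
    qpcr <- generate_validation_table(ds$truth, ds,
                                      noise_sd = cfg$validation_noise_sd,
                                      seed = cfg$synthetic$seed + 7L)
    curve <- attr(qpcr, "curve")
    write_expression(ds$mrna, file.path(out, "mrna_matrix.tsv"),
                     file.path(out, "samples.tsv"),
                     file.path(out, "mrna_features.tsv"))
    write_expression(ds$mirna, file.path(out, "mirna_matrix.tsv"),
                     file.path(out, "samples.tsv"),
                     file.path(out, "mirna_features.tsv"))
    write_fasta(seqs$mirna_seqs, file.path(out, "mirna.fa"))
    write_fasta(seqs$utr_seqs, file.path(out, "utr.fa"))
    wr(qpcr, "qpcr.tsv")
    for (nm in c("mrna_matrix.tsv", "samples.tsv", "mrna_features.tsv",
                 "mirna_matrix.tsv", "mirna_features.tsv", "mirna.fa",
                 "utr.fa"))
      paths[[nm]] <- file.path(out, nm)
    mirna_seqs <- seqs$mirna_seqs
    utr_seqs <- seqs$utr_seqs
    predictions_ext <- NULL
  } else {
    stage_msg("ingest", "reading provided input files")
    inp <- cfg$inputs
    mrna_ds <- read_expression(inp$mrna_matrix, inp$mrna_sheet,
                               kind = "mRNA")
    mirna_ds <- read_expression(inp$mirna_matrix, inp$mirna_sheet,
                                kind = "miRNA")
    ds <- list(mrna = mrna_ds, mirna = mirna_ds, truth = NULL)
    mirna_seqs <- if (!is.null(inp$mirna_fasta))
      read_fasta(inp$mirna_fasta, "RNA") else NULL
    utr_seqs <- if (!is.null(inp$utr_fasta))
      read_fasta(inp$utr_fasta, "DNA") else NULL
    go <- if (!is.null(inp$gene2term))
      read_go_mapping(inp$gene2term, inp$term_table) else NULL
    qpcr <- if (!is.null(inp$qpcr))
      utils::read.delim(inp$qpcr, stringsAsFactors = FALSE) else NULL
    curve <- fit_standard_curve(c(1, 10, 100),
                                35 - 1 / log10(2) * log10(c(1, 10, 100)))
    predictions_ext <- if (!is.null(inp$predictions))
      read_predictions(inp$predictions) else NULL
  }

  # -- stage: differential expression -----------------------------------
  stage_msg("de", "rank-based differential expression")
  de_mrna <- run_de(ds$mrna, alpha = cfg$alpha, floor = cfg$floor,
                    min_frac = cfg$min_frac)
  de_mirna <- run_de(ds$mirna, alpha = cfg$alpha, floor = cfg$floor,
                     min_frac = cfg$min_frac)
  wr(de_mrna, "de_mrna.tsv")
  wr(de_mirna, "de_mirna.tsv")
  s_mrna <- attr(de_mrna, "summary")
  s_mirna <- attr(de_mirna, "summary")

  # -- stage: target prediction -----------------------------------------
  if (!is.null(predictions_ext)) {
    stage_msg("predict", "using external prediction table")
    predictions <- predictions_ext
  } else if (!is.null(mirna_seqs) && !is.null(utr_seqs)) {
    reg_mirna <- de_mirna$feature_id[de_mirna$regulated %in% TRUE]
    reg_mirna <- intersect(reg_mirna, names(mirna_seqs))
    stage_msg("predict", "scanning UTRs for seed sites of ",
              length(reg_mirna), " regulated miRNAs")
    predictions <- predict_table(mirna_seqs[reg_mirna], utr_seqs,
                                 min_site_type = cfg$min_site_type)
  } else {
    stop("pairs stage requires either sequences or a prediction table")
  }
  wr(predictions, "predictions.tsv")

  # -- stage: pairing ----------------------------------------------------
  stage_msg("pairs", "assembling opposite-direction candidate pairs")
  pairs <- assemble_pairs(de_mrna, de_mirna, predictions,
                          alpha = cfg$alpha,
                          restrict_to_distinct = cfg$restrict_to_distinct)
  wr(pairs, "pairs.tsv")

  # -- stage: genomic map ------------------------------------------------
  stage_msg("map", "genomic map and hotspot scan")
  fm <- rbind(ds$mrna$feature_meta[c("id", "chrom", "position", "kind")],
              ds$mirna$feature_meta[c("id", "chrom", "position", "kind")])
  de_all <- rbind(de_mrna, de_mirna)
  gm <- genomic_map(de_all, fm)
  wr(gm$map, "genomic_map.tsv")
  wr(gm$hotspots, "hotspots.tsv")

  # -- stage: GO ---------------------------------------------------------
  if (!is.null(go)) {
    stage_msg("go", "GO term counting and enrichment")
    sel <- de_mrna$feature_id[de_mrna$regulated %in% TRUE]
    bg <- de_mrna$feature_id[de_mrna$present]
    enr <- test_enrichment(sel, bg, go, min_level = 2, alpha = cfg$alpha)
    wr(enr, "enrichment.tsv")
    cats <- categorize(count_terms(sel, go, min_level = 2),
                       go$terms[c("term_id", "category")])
    wr(data.frame(category = names(cats), count = as.integer(cats)),
       "categories.tsv")
  }

  # -- stage: structure --------------------------------------------------
  stage_msg("structure", "clustering and PCA on regulated features")
  struct <- list()
  for (platform in c("mrna", "mirna")) {
    de <- if (platform == "mrna") de_mrna else de_mirna
    dset <- ds[[platform]]
    feats <- de$feature_id[de$distinct %in% TRUE]
    if (length(feats) < 2) feats <- de$feature_id[de$regulated %in% TRUE]
    if (length(feats) < 2) next
    hc <- cluster_samples(dset, feats)
    pca <- pca_samples(dset, feats)
    labels <- dset$sample_meta$group[match(rownames(pca$scores),
                                           dset$sample_meta$id)]
    struct[[platform]] <- list(
      newick = dendrogram_newick(hc),
      cluster_misassigned =
        separation_score(dset$sample_meta$group[
          match(names(cut_two(hc)), dset$sample_meta$id)], cut_two(hc)),
      pca1_misassigned = separation_score(labels, pca$scores[, 1]),
      explained_variance = pca$explained_variance[1:min(2,
        length(pca$explained_variance))])
    writeLines(struct[[platform]]$newick,
               file.path(out, paste0("dendrogram_", platform, ".nwk")))
    paths[[paste0("dendrogram_", platform, ".nwk")]] <-
      file.path(out, paste0("dendrogram_", platform, ".nwk"))
    wr(data.frame(sample_id = rownames(pca$scores), group = labels,
                  PC1 = pca$scores[, 1],
                  PC2 = if (ncol(pca$scores) > 1) pca$scores[, 2] else NA_real_),
       paste0("pca_", platform, ".tsv"))
  }

  # -- stage: validation -------------------------------------------------
  concordance <- NULL
  if (!is.null(qpcr)) {
    stage_msg("validate", "qPCR quantification and permutation concordance")
    rel <- qpcr_relative_expression(qpcr, curve, reference_id = "REF")
    groups <- ds$mrna$sample_meta$group[match(colnames(rel),
                                              ds$mrna$sample_meta$id)]
    val_fc <- apply(rel, 1, function(v) {
      signed_fold_change(v[groups == "case"],
                         v[groups == "control"])$fold_change_signed
    })
    de_all2 <- rbind(de_mrna, de_mirna)
    scr_fc <- de_all2$fold_change_signed[match(names(val_fc),
                                               de_all2$feature_id)]
    names(scr_fc) <- names(val_fc)
    keep <- !is.na(scr_fc)
    comp <- data.frame(feature_id = names(val_fc)[keep],
                       screening_fc = scr_fc[keep],
                       validation_fc = val_fc[keep])
    wr(comp, "validation_comparison.tsv")
    conc <- sign_concordance(scr_fc[keep], val_fc[keep])
    perm <- permutation_concordance(comp$screening_fc, comp$validation_fc,
                                    k = cfg$k_perm, seed = cfg$seed)
    concordance <- list(n_same = conc$n_same, n_total = conc$n_total,
                        rho_observed = perm$rho_observed, k = perm$k,
                        p_empirical = perm$p_empirical,
                        p_two_sided = perm$p_two_sided,
                        p_greater = perm$p_greater)
    p <- file.path(out, "concordance.json")
    jsonlite::write_json(concordance, p, auto_unbox = TRUE, digits = NA)
    paths[["concordance.json"]] <- p
  }

  # -- manifest ----------------------------------------------------------
  digests <- vapply(paths, function(p) unname(tools::md5sum(p)), character(1))
  manifest <- list(
    package = "mirlink",
    version = as.character(utils::packageVersion("mirlink")),
    seed = cfg$seed,
    alpha = cfg$alpha,
    summary = list(
      mrna = as.list(s_mrna), mirna = as.list(s_mirna),
      n_predictions = nrow(predictions), n_pairs = nrow(pairs),
      n_hotspot_windows = nrow(gm$hotspots),
      structure = lapply(struct, function(s)
        s[c("cluster_misassigned", "pca1_misassigned")]),
      concordance = concordance),
    outputs = as.list(digests))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
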