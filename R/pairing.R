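# Candidate miRNA-mRNA pair assembly under the opposite-direction rule,
# the genomic map with a windowed hotspot scan, and screening-vs-validation
# sign concordance.

#' Assemble candidate miRNA-mRNA pairs
#'
#' A candidate pair is a predicted (miRNA, transcript) interaction in which
#' both members are regulated at `alpha` and the mRNA's signed fold change
#' has the opposite sign to the miRNA's (an up-regulated miRNA paired with
#' a down-regulated target, or vice versa). Flat features (fold change
#' exactly 1) never pair.
#'
#' @param de_mrna,de_mirna differential-expression tables from [run_de()]
#'   (or equivalent tables with columns `feature_id`, `p_value`,
#'   `fold_change_signed`, and optionally `distinct`).
#' @param predictions prediction table ([predict_table()] or
#'   [read_predictions()]).
#' @param alpha regulation threshold (inclusive), applied to both tables.
#' @param restrict_to_distinct if TRUE, the mRNA side is limited to
#'   distinctly expressed (complete-separation) transcripts.
#' @return data.frame ordered by (`mrna_id`, `mirna_id`) with columns
#'   `mirna_id`, `mrna_id`, `mirna_fc_signed`, `mrna_fc_signed`, `mirna_p`,
#'   `mrna_p`, `prediction_score`, `source`. Attribute `n_skipped` counts
#'   prediction rows whose ids are absent from the DE tables.
#' @export
assemble_pairs <- function(de_mrna, de_mirna, predictions, alpha = 0.05,
                           restrict_to_distinct = FALSE) {
  need <- c("feature_id", "p_value", "fold_change_signed")
  for (nm in c("de_mrna", "de_mirna")) {
    tab <- get(nm)
    miss <- setdiff(need, names(tab))
    if (length(miss))
      stop(nm, " is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (!all(c("mirna_id", "transcript_id") %in% names(predictions)))
    stop("predictions need columns mirna_id and transcript_id")
  src <- attr(predictions, "source") %||% "external"

  known <- predictions$mirna_id %in% de_mirna$feature_id &
    predictions$transcript_id %in% de_mrna$feature_id
  n_skipped <- sum(!known)
  if (n_skipped > 0)
    warning(n_skipped, " prediction row(s) with ids absent from the DE ",
            "tables were skipped")
  pred <- predictions[known, , drop = FALSE]

  im <- match(pred$mirna_id, de_mirna$feature_id)
  it <- match(pred$transcript_id, de_mrna$feature_id)
  mirna_p <- de_mirna$p_value[im]
  mrna_p <- de_mrna$p_value[it]
  mirna_fc <- de_mirna$fold_change_signed[im]
  mrna_fc <- de_mrna$fold_change_signed[it]

  ok <- !is.na(mirna_p) & !is.na(mrna_p) &
    mirna_p <= alpha & mrna_p <= alpha &
    !is.na(mirna_fc) & !is.na(mrna_fc) &
    mirna_fc != 1 & mrna_fc != 1 &          # flat features never pair
    sign(mirna_fc) != sign(mrna_fc)
  if (restrict_to_distinct) {
    if (!"distinct" %in% names(de_mrna))
      stop("restrict_to_distinct requires a `distinct` column in de_mrna")
    ok <- ok & de_mrna$distinct[it] %in% TRUE
  }

  score <- if ("score" %in% names(pred)) pred$score else rep(NA_real_, nrow(pred))
  out <- data.frame(mirna_id = pred$mirna_id[ok],
                    mrna_id = pred$transcript_id[ok],
                    mirna_fc_signed = mirna_fc[ok],
                    mrna_fc_signed = mrna_fc[ok],
                    mirna_p = mirna_p[ok], mrna_p = mrna_p[ok],
                    prediction_score = score[ok],
                    source = rep(src, sum(ok)), stringsAsFactors = FALSE)
  # one pair per (miRNA, transcript), keeping the best prediction score
  if (nrow(out)) {
    key <- paste(out$mirna_id, out$mrna_id, sep = "\r")
    keep <- !duplicated(key)
    if (any(!keep)) {
      best <- tapply(out$prediction_score, key, function(s)
        if (all(is.na(s))) NA_real_ else max(s, na.rm = TRUE))
      out <- out[keep, , drop = FALSE]
      out$prediction_score <- unname(best[paste(out$mirna_id, out$mrna_id,
                                                sep = "\r")])
    }
    out <- out[order(out$mrna_id, out$mirna_id), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Genomic map of regulated features with a windowed hotspot scan
#'
#' Plots-ready table of regulated features on the genome (-log10 p against
#' position) plus counts of regulated features per fixed-size window and a
#' binomial enrichment p per window against the genome-wide regulated
#' fraction. The scan is descriptive: it reports every window rather than
#' thresholding a headline.
#'
#' @param de differential-expression table from [run_de()] covering all
#'   tested features (regulated and not).
#' @param feature_meta data.frame with `id`, `chrom`, `position` (0-based
#'   bp) and optionally `kind`.
#' @param window_size window width in bp (default 10 Mb).
#' @return list with `map` (one row per regulated mapped feature:
#'   `feature_id`, `chrom`, `position`, `neg_log10_p`, `fc_signed`, `kind`)
#'   and `hotspots` (per window: `chrom`, `window_start`, `n_features`,
#'   `n_regulated`, `expected`, `p_binomial`). Attribute `n_unmapped`
#'   counts regulated features without coordinates.
#' @export
genomic_map <- function(de, feature_meta, window_size = 1e7) {
  if (!all(c("id", "chrom", "position") %in% names(feature_meta)))
    stop("feature_meta needs columns id, chrom, position")
  i <- match(de$feature_id, feature_meta$id)
  chrom <- feature_meta$chrom[i]
  pos <- feature_meta$position[i]
  kind <- if ("kind" %in% names(feature_meta))
    feature_meta$kind[i] else NA_character_

  mapped <- !is.na(chrom) & !is.na(pos)
  tested <- de$present %in% TRUE
  reg <- de$regulated %in% TRUE
  n_unmapped <- sum(reg & !mapped)

  sel <- reg & mapped
  map <- data.frame(feature_id = de$feature_id[sel], chrom = chrom[sel],
                    position = pos[sel],
                    neg_log10_p = -log10(de$p_value[sel]),
                    fc_signed = de$fold_change_signed[sel],
                    kind = kind[sel], stringsAsFactors = FALSE)
  map <- map[order(map$chrom, map$position), , drop = FALSE]
  rownames(map) <- NULL

  # hotspot scan over all tested, mapped features
  base <- tested & mapped
  frac <- if (any(base)) sum(reg & mapped) / sum(base) else 0
  win <- floor(pos / window_size)
  key <- paste(chrom, win, sep = ":")
  keys <- unique(key[base])
  hot <- do.call(rbind, lapply(keys, function(k) {
    in_w <- base & key == k
    m <- sum(in_w)
    x <- sum(in_w & reg)
    data.frame(chrom = chrom[which(in_w)[1]],
               window_start = win[which(in_w)[1]] * window_size,
               n_features = m, n_regulated = x, expected = m * frac,
               p_binomial = stats::pbinom(x - 1, m, frac, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }))
  if (!is.null(hot)) {
    hot <- hot[order(hot$chrom, hot$window_start), , drop = FALSE]
    rownames(hot) <- NULL
  } else {
    hot <- data.frame(chrom = character(), window_start = numeric(),
                      n_features = integer(), n_regulated = integer(),
                      expected = numeric(), p_binomial = numeric())
  }
  structure(list(map = map, hotspots = hot), n_unmapped = n_unmapped)
}

#' Sign concordance between screening and validation fold changes
#'
#' Counts features whose validation fold-change sign matches the screening
#' sign. A flat fold change (exactly 1) is concordant only with another
#' flat value.
#'
#' @param screening_fc,validation_fc named numeric vectors of signed fold
#'   changes, matched by name.
#' @return list with `n_same` and `n_total`.
#' @export
sign_concordance <- function(screening_fc, validation_fc) {
  if (is.null(names(screening_fc)) || is.null(names(validation_fc)))
    stop("fold-change vectors must be named by feature id")
  miss <- c(setdiff(names(screening_fc), names(validation_fc)),
            setdiff(names(validation_fc), names(screening_fc)))
  if (length(miss))
    stop("unmatched feature id(s): ", paste(unique(miss), collapse = ", "))
  v <- validation_fc[names(screening_fc)]
  s_flat <- screening_fc == 1
  v_flat <- v == 1
  same <- (s_flat & v_flat) |
    (!s_flat & !v_flat & sign(screening_fc) == sign(v))
  list(n_same = sum(same), n_total = length(same))
}
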