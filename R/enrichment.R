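# GO biological-process term counting, exact hypergeometric
# enrichment/depletion tails, and categorical summarization.

#' Count GO term occurrences over a selection of genes
#'
#' Each selected gene contributes one occurrence to every term it is
#' annotated with. When the mapping carries term levels, terms below
#' `min_level` (e.g. the very broad level-1 terms) are omitted.
#'
#' @param selected_ids character vector of gene ids.
#' @param go a `go_mapping` (see [read_go_mapping()]) or a list with
#'   `gene2term` (and optionally `terms`).
#' @param min_level minimum term level to keep (0 keeps everything; only
#'   applied when the term table has a `level` column).
#' @return named integer vector of per-term counts (descending). Attribute
#'   `n_unannotated` counts selected ids with no annotation.
#' @export
count_terms <- function(selected_ids, go, min_level = 0) {
  g2t <- go$gene2term
  hit <- g2t[g2t$gene_id %in% selected_ids, , drop = FALSE]
  if (min_level > 0 && !is.null(go$terms) && "level" %in% names(go$terms)) {
    keep_terms <- go$terms$term_id[go$terms$level >= min_level]
    hit <- hit[hit$term_id %in% keep_terms, , drop = FALSE]
  }
  counts <- sort(table(hit$term_id), decreasing = TRUE)
  out <- as.integer(counts)
  names(out) <- names(counts)
  attr(out, "n_unannotated") <-
    sum(!selected_ids %in% g2t$gene_id)
  out
}

#' Exact hypergeometric enrichment and depletion tails
#'
#' For a selection of `n_sel` genes from a background of `n_bg`, of which
#' `n_bg_term` carry the term and `n_sel_term` of the selected do:
#' `p_enrich = P(X >= n_sel_term)` and `p_deplete = P(X <= n_sel_term)`
#' under the hypergeometric null. The two tails share the observed point
#' mass, so they sum to at least 1.
#'
#' @param n_sel_term,n_sel,n_bg_term,n_bg counts.
#' @return list with `p_enrich` and `p_deplete`.
#' @export
#' @examples
#' hypergeometric_test(3, 5, 4, 10)  # p_enrich = 66/252
hypergeometric_test <- function(n_sel_term, n_sel, n_bg_term, n_bg) {
  bad <- n_sel_term > min(n_sel, n_bg_term) || n_sel > n_bg ||
    n_bg_term > n_bg || any(c(n_sel_term, n_sel, n_bg_term, n_bg) < 0) ||
    n_sel_term < n_sel - (n_bg - n_bg_term)
  if (bad) stop("inconsistent hypergeometric counts")
  p_enrich <- stats::phyper(n_sel_term - 1, n_bg_term, n_bg - n_bg_term,
                            n_sel, lower.tail = FALSE)
  p_deplete <- stats::phyper(n_sel_term, n_bg_term, n_bg - n_bg_term, n_sel)
  list(p_enrich = p_enrich, p_deplete = p_deplete)
}

#' Term-by-term enrichment of a gene selection against a background
#'
#' @param selected_ids genes of interest (e.g. regulated transcripts).
#' @param background_ids background universe (e.g. all present transcripts).
#' @param go a `go_mapping`.
#' @param min_level minimum term level, see [count_terms()].
#' @param alpha significance threshold used only to label `direction`.
#' @param method `"hypergeometric"` (exact tails) or `"permutation"`
#'   (resampling selections of equal size from the background).
#' @param n_perm,seed permutation parameters (used by the permutation
#'   method only).
#' @param adjust `"none"` or `"BH"` (adds BH-adjusted columns).
#' @return data.frame with one row per term: `term_id`, `term_name`,
#'   `n_selected_with_term`, `n_selected`, `n_background_with_term`,
#'   `n_background`, `expected`, `p_enrich`, `p_deplete`, `direction`.
#' @export
test_enrichment <- function(selected_ids, background_ids, go, min_level = 0,
                            alpha = 0.05,
                            method = c("hypergeometric", "permutation"),
                            n_perm = 1000, seed = 1,
                            adjust = c("none", "BH")) {
  method <- match.arg(method); adjust <- match.arg(adjust)
  if (!all(selected_ids %in% background_ids))
    stop("selection must be a subset of the background")
  sel_counts <- count_terms(selected_ids, go, min_level = min_level)
  bg_counts <- count_terms(background_ids, go, min_level = min_level)
  terms <- names(bg_counts)
  n_sel <- length(unique(selected_ids))
  n_bg <- length(unique(background_ids))

  k_sel <- ifelse(terms %in% names(sel_counts), sel_counts[terms], 0L)
  k_bg <- as.integer(bg_counts[terms])

  if (method == "hypergeometric") {
    pe <- pd <- numeric(length(terms))
    for (i in seq_along(terms)) {
      h <- hypergeometric_test(k_sel[i], n_sel, k_bg[i], n_bg)
      pe[i] <- h$p_enrich; pd[i] <- h$p_deplete
    }
  } else {
    # resample selections of equal size; empirical tails with +1 correction
    g2t <- go$gene2term
    bg_unique <- unique(background_ids)
    perm_counts <- with_seed(seed, {
      vapply(seq_len(n_perm), function(b) {
        s <- sample(bg_unique, n_sel)
        cnt <- count_terms(s, go, min_level = min_level)
        ifelse(terms %in% names(cnt), cnt[terms], 0L)
      }, numeric(length(terms)))
    })
    perm_counts <- matrix(perm_counts, nrow = length(terms))
    pe <- (rowSums(perm_counts >= k_sel) + 1) / (n_perm + 1)
    pd <- (rowSums(perm_counts <= k_sel) + 1) / (n_perm + 1)
  }

  nm <- if (!is.null(go$terms))
    go$terms$name[match(terms, go$terms$term_id)] else NA_character_
  out <- data.frame(term_id = terms, term_name = nm,
                    n_selected_with_term = as.integer(k_sel),
                    n_selected = n_sel,
                    n_background_with_term = k_bg, n_background = n_bg,
                    expected = n_sel * k_bg / n_bg,
                    p_enrich = pe, p_deplete = pd,
                    stringsAsFactors = FALSE)
  if (adjust == "BH") {
    out$p_enrich_adj <- stats::p.adjust(out$p_enrich, method = "BH")
    out$p_deplete_adj <- stats::p.adjust(out$p_deplete, method = "BH")
  }
  p_e <- if (adjust == "BH") out$p_enrich_adj else out$p_enrich
  p_d <- if (adjust == "BH") out$p_deplete_adj else out$p_deplete
  out$direction <- ifelse(p_e <= alpha, "enriched",
                          ifelse(p_d <= alpha, "depleted", "neither"))
  out <- out[order(out$p_enrich, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize term counts into categories
#'
#' @param term_counts named integer vector (term id -> count), e.g. from
#'   [count_terms()].
#' @param term_category named character vector or data.frame
#'   (`term_id`, `category`) mapping terms to categories.
#' @return named integer vector of per-category counts; terms without a
#'   category are pooled under `"other"`. Counts are conserved: the
#'   category totals sum to the term-count total.
#' @export
categorize <- function(term_counts, term_category) {
  if (is.data.frame(term_category)) {
    tc <- term_category$category
    names(tc) <- term_category$term_id
    term_category <- tc
  }
  cats <- term_category[names(term_counts)]
  cats[is.na(cats) | cats == ""] <- "other"
  out <- tapply(as.integer(term_counts), cats, sum)
  res <- as.integer(out)
  names(res) <- names(out)
  sort(res, decreasing = TRUE)
}
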