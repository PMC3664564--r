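# Canonical seed-match miRNA target prediction over 3'UTR sequences.
#
# Site types follow the field-standard definitions on the UTR sense strand
# (5'->3'): with seed = miRNA positions 2..7 and m8 = position 8,
#   6mer     : reverse complement of positions 2..7
#   7mer-m8  : reverse complement of positions 2..8
#   7mer-A1  : 6mer plus an adenosine opposite miRNA position 1 (the base
#              immediately 3' of the 6mer match)
#   8mer     : 7mer-m8 plus the A1 adenosine
# Matching is strict Watson-Crick (no G:U wobble). Offsets are 0-based on
# the UTR sense strand and point at the site's 5'-most matched base.
# Scoring ranks site types 8mer=4 > 7mer-m8=3 > 7mer-A1=2 > 6mer=1, with a
# +1 3'-supplementary bonus when the four UTR bases opposite miRNA
# positions 13..16 all pair Watson-Crick.

site_type_rank <- c("6mer" = 1, "7mer-A1" = 2, "7mer-m8" = 3, "8mer" = 4)

#' Scan one 3'UTR for seed-match sites of one miRNA
#'
#' @param mirna_seq mature miRNA sequence (RNA or DNA alphabet), length >= 8.
#' @param utr_seq 3'UTR sequence (DNA or RNA alphabet), length >= 6.
#' @param mirna_id,transcript_id identifiers copied into the result.
#' @return data.frame with columns `mirna_id`, `transcript_id`, `site_type`,
#'   `utr_start` (0-based offset of the site's 5'-most base), and
#'   `pairing_score`. One row per seed-match locus, classified as the
#'   strongest applicable type; deterministic 5'->3' order.
#' @export
#' @examples
#' # let-7a seed GAGGUAG reverse-complements to CTACCTC; with the A1 base
#' # the 8mer site is CTACCTCA
#' seed_sites("UGAGGUAGUAGGUUGUAUAGUU", "GGGCTACCTCAGGG")
seed_sites <- function(mirna_seq, utr_seq, mirna_id = "miRNA",
                       transcript_id = "transcript") {
  m <- as_dna(mirna_seq)
  u <- as_dna(utr_seq)
  if (nchar(m) < 8) stop("miRNA sequence too short (< 8 nt)")
  if (nchar(u) < 6) stop("UTR sequence too short (< 6 nt)")

  core6 <- dna_revcomp(substr(m, 2, 7))       # matches miRNA 2..7
  m8_comp <- dna_complement(substr(m, 8, 8))  # UTR base pairing m8
  supp <- if (nchar(m) >= 16) dna_revcomp(substr(m, 13, 16)) else NULL

  hits <- Biostrings::matchPattern(core6, Biostrings::DNAString(u))
  starts <- BiocGenerics::start(hits)  # 1-based, includes overlapping hits
  if (length(starts) == 0) return(empty_sites())

  L <- nchar(u)
  out <- lapply(starts, function(i) {
    has_m8 <- i >= 2 && substr(u, i - 1, i - 1) == m8_comp
    has_a1 <- (i + 6) <= L && substr(u, i + 6, i + 6) == "A"
    if (has_m8 && has_a1) {
      type <- "8mer"; start0 <- i - 2
    } else if (has_m8) {
      type <- "7mer-m8"; start0 <- i - 2
    } else if (has_a1) {
      type <- "7mer-A1"; start0 <- i - 1
    } else {
      type <- "6mer"; start0 <- i - 1
    }
    score <- unname(site_type_rank[type])
    # 3'-supplementary pairing: UTR bases opposite miRNA 13..16 sit 5' of
    # the position pairing m8 (index i-1), at i-9 .. i-6 (1-based)
    if (!is.null(supp) && (i - 9) >= 1 &&
        substr(u, i - 9, i - 6) == supp) {
      score <- score + 1
    }
    data.frame(mirna_id = mirna_id, transcript_id = transcript_id,
               site_type = type, utr_start = start0, pairing_score = score,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res[order(res$utr_start), , drop = FALSE]
}

empty_sites <- function() {
  data.frame(mirna_id = character(), transcript_id = character(),
             site_type = character(), utr_start = integer(),
             pairing_score = numeric(), stringsAsFactors = FALSE)
}

#' Scan all miRNA / UTR combinations and summarize per pair
#'
#' @param mirna_seqs named character vector of mature miRNA sequences.
#' @param utr_seqs named character vector of 3'UTR sequences.
#' @param min_site_type weakest site type that qualifies a transcript as a
#'   predicted target (`"6mer"` < `"7mer-A1"` < `"7mer-m8"` < `"8mer"`).
#' @return data.frame with one row per (miRNA, transcript) pair having at
#'   least one qualifying site: `mirna_id`, `transcript_id`, `score` (best
#'   site score), `best_site_type`, `n_sites`. Attribute
#'   `source = "internal"`; attribute `sites` holds the full site table.
#' @export
predict_table <- function(mirna_seqs, utr_seqs,
                          min_site_type = c("6mer", "7mer-A1", "7mer-m8",
                                            "8mer")) {
  min_site_type <- match.arg(min_site_type)
  min_rank <- site_type_rank[min_site_type]
  if (length(mirna_seqs) == 0 || length(utr_seqs) == 0) {
    warning("empty sequence set; returning empty prediction table")
    tab <- data.frame(mirna_id = character(), transcript_id = character(),
                      score = numeric(), best_site_type = character(),
                      n_sites = integer(), stringsAsFactors = FALSE)
    attr(tab, "source") <- "internal"
    attr(tab, "sites") <- empty_sites()
    return(tab)
  }
  if (is.null(names(mirna_seqs)) || is.null(names(utr_seqs)))
    stop("sequence vectors must be named by feature id")

  utr_set <- Biostrings::DNAStringSet(as_dna(utr_seqs))
  all_sites <- list()
  for (mid in names(mirna_seqs)) {
    m <- as_dna(mirna_seqs[[mid]])
    if (nchar(m) < 8) stop("miRNA sequence too short (< 8 nt): ", mid)
    core6 <- dna_revcomp(substr(m, 2, 7))
    hit_list <- Biostrings::vmatchPattern(core6, utr_set)
    n_hits <- lengths(hit_list)
    for (tid in names(utr_seqs)[n_hits > 0]) {
      all_sites[[length(all_sites) + 1L]] <-
        seed_sites(m, utr_seqs[[tid]], mirna_id = mid, transcript_id = tid)
    }
  }
  sites <- if (length(all_sites)) do.call(rbind, all_sites) else empty_sites()
  keep <- site_type_rank[sites$site_type] >= min_rank
  sites_kept <- sites[keep, , drop = FALSE]

  if (nrow(sites_kept)) {
    key <- paste(sites_kept$mirna_id, sites_kept$transcript_id, sep = "\r")
    agg <- lapply(split(sites_kept, key), function(s) {
      best <- which.max(s$pairing_score +
                          site_type_rank[s$site_type] / 10)  # tie-break
      data.frame(mirna_id = s$mirna_id[1], transcript_id = s$transcript_id[1],
                 score = max(s$pairing_score),
                 best_site_type = s$site_type[best],
                 n_sites = nrow(s), stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, agg)
    tab <- tab[order(tab$mirna_id, tab$transcript_id), , drop = FALSE]
    rownames(tab) <- NULL
  } else {
    tab <- data.frame(mirna_id = character(), transcript_id = character(),
                      score = numeric(), best_site_type = character(),
                      n_sites = integer(), stringsAsFactors = FALSE)
  }
  attr(tab, "source") <- "internal"
  attr(tab, "sites") <- sites
  tab
}
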