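# Independent oracles used across tests. These deliberately re-derive the
# quantities with naive methods (exhaustive enumeration, plain loops) so
# they share no code with the implementation.

# Brute-force two-sided Mann-Whitney p over all rank assignments.
brute_mw_p <- function(case_values, control_values) {
  n1 <- length(case_values); n2 <- length(control_values)
  pooled <- c(case_values, control_values)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- utils::combn(n1 + n2, n1)
  us <- apply(idx, 2, function(ii) sum(r[ii]) - n1 * (n1 + 1) / 2)
  p_le <- mean(us <= u_obs + 1e-9)
  p_ge <- mean(us >= u_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Value-overlap definition of distinct expression.
overlap_distinct <- function(case_values, control_values) {
  max(case_values) < min(control_values) ||
    max(control_values) < min(case_values)
}

# Naive per-offset seed-site oracle: try each full site string at every
# position of the UTR, strongest type first; +1 bonus for a perfect
# 3'-supplementary match opposite miRNA 13-16.
oracle_sites <- function(mirna_seq, utr_seq) {
  m <- chartr("Uu", "Tt", toupper(mirna_seq))
  u <- toupper(utr_seq)
  rc <- function(s) paste(rev(strsplit(chartr("ACGT", "TGCA", s), "",
                                       fixed = TRUE)[[1]]), collapse = "")
  s6 <- rc(substr(m, 2, 7))
  s7m8 <- rc(substr(m, 2, 8))
  s8 <- paste0(s7m8, "A")
  s7a1 <- paste0(s6, "A")
  supp <- if (nchar(m) >= 16) rc(substr(m, 13, 16)) else NULL
  L <- nchar(u)
  rows <- list()
  for (j in seq_len(L - 5)) {           # j: 1-based core (positions 2-7) start
    if (substr(u, j, j + 5) != s6) next
    if (j >= 2 && substr(u, j - 1, j + 6) == s8) {
      type <- "8mer"; start0 <- j - 2; score <- 4
    } else if (j >= 2 && substr(u, j - 1, j + 5) == s7m8) {
      type <- "7mer-m8"; start0 <- j - 2; score <- 3
    } else if (substr(u, j, j + 6) == s7a1) {
      type <- "7mer-A1"; start0 <- j - 1; score <- 2
    } else {
      type <- "6mer"; start0 <- j - 1; score <- 1
    }
    if (!is.null(supp) && j - 9 >= 1 && substr(u, j - 9, j - 6) == supp)
      score <- score + 1
    rows[[length(rows) + 1]] <- data.frame(site_type = type,
                                           utr_start = start0,
                                           pairing_score = score,
                                           stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(site_type = character(), utr_start = integer(),
                      pairing_score = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(out$utr_start), , drop = FALSE]
}

# Naive O(n^3) unweighted average-linkage (UPGMA) merge heights.
naive_upgma_heights <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  members <- as.list(seq_len(n))
  active <- rep(TRUE, n)
  heights <- numeric(0)
  dm <- d
  for (step in seq_len(n - 1)) {
    best <- Inf; bi <- bj <- NA
    idx <- which(active)
    for (a in seq_along(idx)) for (b in seq_len(a - 1)) {
      i <- idx[a]; j <- idx[b]
      if (dm[i, j] < best) { best <- dm[i, j]; bi <- i; bj <- j }
    }
    heights <- c(heights, best)
    # merge bj into bi with unweighted (all-pairs mean) linkage
    new_members <- c(members[[bi]], members[[bj]])
    for (kk in which(active)) {
      if (kk %in% c(bi, bj)) next
      dm[bi, kk] <- dm[kk, bi] <-
        mean(d[new_members, members[[kk]], drop = FALSE])
    }
    members[[bi]] <- new_members
    active[bj] <- FALSE
  }
  heights
}

# random tie-free two-group sample
random_groups <- function(n1, n2) {
  v <- sample(seq_len(100 * (n1 + n2)), n1 + n2) + stats::runif(n1 + n2, 0, 0.4)
  list(case = v[seq_len(n1)], control = v[n1 + seq_len(n2)])
}

extdata <- function(name) system.file("extdata", name, package = "mirlink")
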