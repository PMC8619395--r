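# Independent brute-force oracles used to validate the production code
# paths. These deliberately share no code with the package internals:
# character-by-character scanning, naive set comparison, per-base
# interval membership, and a textbook two-pass correlation formula.

oracle_revcomp <- function(m) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(m, "")[[1]]]), collapse = "")
}

oracle_rotations <- function(m) {
  k <- nchar(m)
  vapply(seq_len(k), function(i) {
    paste0(substr(m, i, k), substr(m, 1, i - 1))
  }, character(1))
}

oracle_standardize <- function(m) {
  min(c(oracle_rotations(m), oracle_rotations(oracle_revcomp(m))))
}

oracle_is_primitive <- function(m) {
  k <- nchar(m)
  if (k == 1) return(TRUE)
  for (d in seq_len(k - 1)) {
    if (k %% d == 0) {
      unit <- substr(m, 1, d)
      if (paste(rep(unit, k / d), collapse = "") == m) return(FALSE)
    }
  }
  TRUE
}

# Brute-force maximal-run miner: for every position and motif length,
# test whether a maximal primitive-motif run meeting the policy starts
# there; then select left-to-right with ascending motif length taking
# precedence, never overlapping an accepted record.
oracle_find_ssrs <- function(seq_string, policy = c(`1` = 6, `2` = 3,
                                                    `3` = 3, `4` = 3,
                                                    `5` = 3, `6` = 3)) {
  s <- strsplit(toupper(seq_string), "")[[1]]
  n <- length(s)
  cand <- list()
  for (start in seq_len(n)) {
    for (k in 1:6) {
      if (start + k - 1 > n) next
      motif <- paste(s[start:(start + k - 1)], collapse = "")
      if (grepl("[^ACGT]", motif)) next
      if (!oracle_is_primitive(motif)) next
      # left-maximal: previous base must not extend the periodic run
      if (start > 1 && s[start - 1] != "N" &&
          s[start - 1] == s[start + k - 1]) next
      len <- k
      while (start + len <= n && s[start + len] != "N" &&
             s[start + len] == s[start + len - k]) {
        len <- len + 1
      }
      reps <- len %/% k
      if (reps >= policy[[as.character(k)]]) {
        cand[[length(cand) + 1]] <- c(start = start, k = k, reps = reps)
      }
    }
  }
  if (length(cand) == 0) {
    return(data.frame(start = integer(0), end = integer(0),
                      motif = character(0), motif_len = integer(0),
                      repeats = integer(0)))
  }
  cm <- do.call(rbind, cand)
  cm <- cm[order(cm[, "start"], cm[, "k"]), , drop = FALSE]
  rows <- list()
  last_end <- 0
  for (i in seq_len(nrow(cm))) {
    st <- cm[i, "start"]
    if (st > last_end) {
      k <- cm[i, "k"]; reps <- cm[i, "reps"]
      last_end <- st + k * reps - 1
      rows[[length(rows) + 1]] <- data.frame(
        start = as.integer(st), end = as.integer(last_end),
        motif = paste(s[st:(st + k - 1)], collapse = ""),
        motif_len = as.integer(k), repeats = as.integer(reps),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

oracle_unique_motifs <- function(per_genome) {
  out <- list()
  for (g in names(per_genome)) {
    others <- unlist(per_genome[setdiff(names(per_genome), g)],
                     use.names = FALSE)
    m <- unique(per_genome[[g]])
    out[[g]] <- m[!(m %in% others)]
  }
  out
}

# per-base membership check against a set of intervals
oracle_is_coding <- function(start, end, intervals) {
  if (nrow(intervals) == 0) return(FALSE)
  for (p in start:end) {
    if (any(p >= intervals$start & p <= intervals$end)) return(TRUE)
  }
  FALSE
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

random_seq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# SSR-table comparison that ignores row names
expect_same_records <- function(found, expected_cols) {
  rownames(found) <- NULL
  rownames(expected_cols) <- NULL
  testthat::expect_identical(found, expected_cols)
}
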