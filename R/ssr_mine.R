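#' Minimum repeat-count policy per motif length
#'
#' Defaults follow the common prokaryote survey settings: at least 6
#' repeats for mononucleotide runs and at least 3 for di- through
#' hexanucleotide motifs.
#'
#' @param mono,di,tri,tetra,penta,hexa minimum repeat counts (all >= 2).
#' @return named integer vector with names `"1"`..`"6"`.
#' @examples
#' min_repeat_policy()
#' min_repeat_policy(mono = 8)
#' @export
min_repeat_policy <- function(mono = 6L, di = 3L, tri = 3L, tetra = 3L,
                              penta = 3L, hexa = 3L) {
  p <- c(`1` = mono, `2` = di, `3` = tri, `4` = tetra, `5` = penta,
         `6` = hexa)
  p <- as.integer(p)
  names(p) <- as.character(1:6)
  if (anyNA(p) || any(p < 2L)) {
    stop("minimum repeat counts must all be integers >= 2")
  }
  p
}

.check_policy <- function(policy) {
  if (!is.numeric(policy) || length(policy) != 6L ||
      !identical(names(policy), as.character(1:6)) || any(policy < 2)) {
    stop("policy must be a vector as returned by min_repeat_policy()")
  }
  p <- as.integer(policy)
  names(p) <- names(policy)
  p
}

#' Normalize a nucleotide sequence to the {A,C,G,T,N} alphabet
#'
#' Uppercases the input (soft-masking is ignored) and maps IUPAC
#' ambiguity codes other than N to N with a warning, so that draft
#' assemblies do not abort a survey. Any other character is an error.
#'
#' @param x character vector of sequences.
#' @return character vector over A, C, G, T, N.
#' @export
normalize_sequence <- function(x) {
  if (!is.character(x)) x <- as.character(x)
  x <- toupper(x)
  amb <- "RYSWKMBDHV"
  n_amb <- sum(vapply(x, function(s) {
    sum(charToRaw(chartr(amb, strrep("\x01", nchar(amb)), s)) == 1L)
  }, integer(1)))
  if (n_amb > 0L) {
    warning(sprintf(
      "%d IUPAC ambiguity base(s) other than N replaced by N", n_amb))
    x <- chartr(amb, strrep("N", nchar(amb)), x)
  }
  if (any(grepl("[^ACGTN]", x))) {
    stop("sequence contains characters outside the DNA alphabet")
  }
  x
}

#' Read a genome assembly from FASTA
#'
#' Loads a (possibly multi-contig) nucleotide FASTA via
#' [Biostrings::readDNAStringSet()], truncates each record id at the first
#' whitespace, and normalizes residues with [normalize_sequence()].
#'
#' @param path path to a FASTA file.
#' @return named character vector, one element per contig.
#' @export
read_genome <- function(path) {
  dss <- Biostrings::readDNAStringSet(path)
  seqs <- as.character(dss)
  names(seqs) <- sub("\\s.*$", "", names(dss))
  normalize_sequence(seqs)
}

## Length of the run of consecutive TRUEs starting at each position.
.true_runlen <- function(b) {
  m <- length(b)
  if (m == 0L) return(integer(0))
  w <- which(!b)
  if (length(w) == 0L) return(rev(seq_len(m)))
  nxt <- w[findInterval(seq_len(m) - 1L, w) + 1L]
  nxt[is.na(nxt)] <- m + 1L
  nxt - seq_len(m)
}

.proper_divisors <- list(
  `1` = integer(0), `2` = 1L, `3` = 1L, `4` = c(1L, 2L), `5` = 1L,
  `6` = c(1L, 2L, 3L))

## Core scanner for a single contig held as a vector of single characters.
## Candidate maximal runs are enumerated per motif length with vectorized
## periodicity matches, then selected left-to-right with ascending motif
## length taking precedence at equal starts; accepted records never
## overlap and a partial trailing unit is never counted.
.mine_chars <- function(s, seq_id, policy) {
  n <- length(s)
  empty <- data.frame(
    seq_id = character(0), start = integer(0), end = integer(0),
    motif = character(0), standard_motif = character(0),
    motif_len = integer(0), repeats = integer(0), length = integer(0),
    stringsAsFactors = FALSE)
  if (n < 2L) return(empty)

  notN <- s != "N"
  eqs <- vector("list", 6L)
  runs <- vector("list", 6L)
  for (k in 1:6) {
    m <- n - k
    if (m < 1L) {
      eqs[[k]] <- logical(0)
      runs[[k]] <- integer(0)
      next
    }
    i <- seq_len(m)
    eqs[[k]] <- (s[i] == s[i + k]) & notN[i] & notN[i + k]
    runs[[k]] <- .true_runlen(eqs[[k]])
  }

  cand_p <- integer(0); cand_k <- integer(0); cand_r <- integer(0)
  for (k in 1:6) {
    m <- n - k
    if (m < 1L) next
    reps <- (k + runs[[k]]) %/% k
    ok <- reps >= policy[k]
    if (!any(ok)) next
    left_ok <- c(TRUE, !eqs[[k]][seq_len(m - 1L)])
    ok <- ok & left_ok
    for (d in .proper_divisors[[k]]) {
      ok <- ok & (runs[[d]][seq_len(m)] < (k - d))
    }
    p <- which(ok)
    cand_p <- c(cand_p, p)
    cand_k <- c(cand_k, rep.int(k, length(p)))
    cand_r <- c(cand_r, reps[p])
  }
  if (length(cand_p) == 0L) return(empty)

  ord <- order(cand_p, cand_k)
  keep <- integer(0)
  last_end <- 0L
  for (i in ord) {
    p <- cand_p[i]
    if (p > last_end) {
      keep <- c(keep, i)
      last_end <- p + cand_k[i] * cand_r[i] - 1L
    }
  }

  p <- cand_p[keep]; k <- cand_k[keep]; r <- cand_r[keep]
  motif <- vapply(seq_along(p), function(j) {
    paste(s[p[j]:(p[j] + k[j] - 1L)], collapse = "")
  }, character(1))
  data.frame(
    seq_id = rep.int(seq_id, length(p)),
    start = p,
    end = p + k * r - 1L,
    motif = motif,
    standard_motif = standardize_motif(motif),
    motif_len = k,
    repeats = r,
    length = k * r,
    stringsAsFactors = FALSE)
}

#' Find all perfect microsatellites in a sequence
#'
#' Scans each contig left to right for maximal perfect tandem repeats of
#' primitive motifs 1-6 bp long that meet the per-motif-length minimum
#' repeat counts of `policy`. At a given start position shorter motifs take
#' precedence (a run of six A is reported as (A)6, never (AA)3), accepted
#' records never overlap, partial trailing units are not counted, and N
#' breaks every run.
#'
#' @param x sequences: a named character vector, a
#'   [Biostrings::DNAStringSet], a single string, or a path handled
#'   upstream by [read_genome()].
#' @param policy minimum repeat counts, see [min_repeat_policy()].
#' @param seq_ids optional ids used when `x` is unnamed.
#' @return data.frame with one row per SSR and columns `seq_id`, `start`,
#'   `end` (1-based inclusive), `motif` (as it occurs at `start`),
#'   `standard_motif`, `motif_len`, `repeats`, `length`.
#' @examples
#' find_perfect_ssrs(c(chr = "TTAGAGAGTT"))
#' @export
find_perfect_ssrs <- function(x, policy = min_repeat_policy(),
                              seq_ids = NULL) {
  policy <- .check_policy(policy)
  if (methods::is(x, "DNAStringSet") || methods::is(x, "DNAString")) {
    x <- as.character(x)
  }
  if (!is.character(x)) stop("x must be sequences or a DNAStringSet")
  if (is.null(names(x))) {
    names(x) <- if (!is.null(seq_ids)) seq_ids else
      paste0("seq", seq_along(x))
  }
  x <- normalize_sequence(x)
  out <- lapply(names(x), function(id) {
    .mine_chars(strsplit(x[[id]], "", fixed = TRUE)[[1]], id, policy)
  })
  do.call(rbind, out)
}

#' Tally SSRs by motif length
#'
#' @param records SSR table from [find_perfect_ssrs()].
#' @return named integer vector of counts for motif lengths 1-6.
#' @export
count_by_motif_length <- function(records) {
  counts <- integer(6)
  names(counts) <- as.character(1:6)
  if (nrow(records) > 0L) {
    tab <- table(factor(records$motif_len, levels = 1:6))
    counts[] <- as.integer(tab)
  }
  counts
}

#' Write an SSR table as TSV
#'
#' @param records SSR table.
#' @param path output file.
#' @export
write_ssr_table <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
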