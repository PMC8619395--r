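#' Reverse complement of short motif strings
#'
#' Thin character-vector wrapper around [Biostrings::reverseComplement()].
#'
#' @param x character vector of ACGT strings.
#' @return character vector of reverse complements.
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

.check_motif_alphabet <- function(motif) {
  if (!is.character(motif) || anyNA(motif)) {
    stop("invalid motif: must be a character vector without NA")
  }
  k <- nchar(motif)
  if (any(k < 1L | k > 6L)) {
    stop("invalid motif: length must be between 1 and 6")
  }
  if (any(grepl("[^ACGT]", motif))) {
    stop("invalid motif: only A, C, G, T allowed")
  }
  invisible(motif)
}

#' Test whether a motif is primitive
#'
#' A repeat unit is primitive when it is not itself a whole-number
#' repetition of a shorter unit; `"ACAC"` is `"AC"` twice and therefore not
#' a valid dinucleotide-survey motif.
#'
#' @param motif character vector of candidate motifs (1-6 bp, ACGT only).
#' @return logical vector.
#' @examples
#' is_primitive(c("A", "ACAC", "ACG"))
#' @export
is_primitive <- function(motif) {
  .check_motif_alphabet(motif)
  vapply(motif, function(m) {
    k <- nchar(m)
    if (k == 1L) return(TRUE)
    for (d in seq_len(k - 1L)) {
      if (k %% d == 0L && strrep(substr(m, 1L, d), k %/% d) == m) {
        return(FALSE)
      }
    }
    TRUE
  }, logical(1), USE.NAMES = FALSE)
}

.rotations <- function(m) {
  k <- nchar(m)
  if (k == 1L) return(m)
  doubled <- paste0(m, m)
  vapply(seq_len(k), function(i) substr(doubled, i, i + k - 1L),
         character(1))
}

#' Canonical (standard) motif class
#'
#' Merges a motif with its cyclic rotations and the rotations of its
#' reverse complement, returning the lexicographically smallest member as
#' the class representative. Under this convention every mononucleotide
#' repeat is reported as `"A"` or `"C"`, and e.g. `"GA"`, `"TC"`, `"CT"`
#' all standardize to `"AG"`.
#'
#' @param motif character vector of primitive motifs (1-6 bp).
#' @return character vector of standard motifs, same length class as the
#'   input, invariant under rotation and reverse complementation.
#' @examples
#' standardize_motif(c("T", "GA", "CGG"))
#' @export
standardize_motif <- function(motif) {
  .check_motif_alphabet(motif)
  if (!all(is_primitive(motif))) {
    stop("invalid motif: non-primitive motifs have no standard class")
  }
  um <- unique(motif)
  std <- vapply(um, function(m) {
    hit <- .std_cache[[m]]
    if (!is.null(hit)) return(hit)
    val <- min(c(.rotations(m), .rotations(revcomp(m))))
    assign(m, val, envir = .std_cache)
    val
  }, character(1), USE.NAMES = FALSE)
  std[match(motif, um)]
}

## memo cache: at most 5460 primitive motifs exist for lengths 1-6
.std_cache <- new.env(parent = emptyenv())
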