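#' Chain adjacent SSRs into compound microsatellites
#'
#' Two or more SSRs whose pairwise interruptions are each at most `dmax`
#' bp form one compound microsatellite (CSSR). The interruption between
#' consecutive loci is `start(next) - end(prev) - 1` and the `dmax` test
#' is inclusive; chains are maximal and never span contigs.
#'
#' @param ssrs SSR table from [find_perfect_ssrs()], sorted by start and
#'   non-overlapping within each `seq_id`.
#' @param dmax maximum interruption in bp (default 10).
#' @param chain_same_motif if `FALSE`, neighbors whose standard motifs are
#'   identical are not chained (an interrupted homogeneous repeat is then
#'   left as two singletons instead of one compound locus).
#' @return data.frame with one row per CSSR: `seq_id`, `start`, `end`,
#'   `complexity` (number of member SSRs), `length` (span),
#'   `motif_string` (member standard motifs joined with "-"),
#'   `member_starts`, `member_ends`, `gaps` (comma-separated).
#' @examples
#' ssrs <- find_perfect_ssrs(c(c1 = "AAAAAACCTTTAGAGAGTT"))
#' build_cssrs(ssrs, dmax = 10)
#' @export
build_cssrs <- function(ssrs, dmax = 10L, chain_same_motif = TRUE) {
  if (length(dmax) != 1L || is.na(dmax) || dmax < 0) {
    stop("dmax must be a single non-negative number")
  }
  empty <- data.frame(
    seq_id = character(0), start = integer(0), end = integer(0),
    complexity = integer(0), length = integer(0),
    motif_string = character(0), member_starts = character(0),
    member_ends = character(0), gaps = character(0),
    stringsAsFactors = FALSE)
  if (nrow(ssrs) == 0L) return(empty)

  out <- lapply(split(ssrs, factor(ssrs$seq_id, unique(ssrs$seq_id))),
                function(g) {
    m <- nrow(g)
    if (is.unsorted(g$start, strictly = TRUE) ||
        (m > 1L && any(g$start[-1L] <= g$end[-m]))) {
      stop("ssrs must be sorted by start and non-overlapping per seq_id")
    }
    if (m < 2L) return(empty)
    gaps <- g$start[-1L] - g$end[-m] - 1L
    brk <- gaps > dmax
    if (!chain_same_motif) {
      brk <- brk | (g$standard_motif[-1L] == g$standard_motif[-m])
    }
    grp <- cumsum(c(0L, as.integer(brk)))
    chains <- split(seq_len(m), grp)
    chains <- chains[lengths(chains) >= 2L]
    if (length(chains) == 0L) return(empty)
    rows <- lapply(chains, function(idx) {
      data.frame(
        seq_id = g$seq_id[idx[1L]],
        start = g$start[idx[1L]],
        end = g$end[idx[length(idx)]],
        complexity = length(idx),
        length = g$end[idx[length(idx)]] - g$start[idx[1L]] + 1L,
        motif_string = paste(g$standard_motif[idx], collapse = "-"),
        member_starts = paste(g$start[idx], collapse = ","),
        member_ends = paste(g$end[idx], collapse = ","),
        gaps = paste(gaps[idx[-length(idx)]], collapse = ","),
        stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Complexity spectrum of a CSSR set
#'
#' @param cssrs CSSR table from [build_cssrs()].
#' @return named integer vector mapping complexity C to the number of
#'   CSSRs with that many members; the weighted sum over the spectrum
#'   equals ncSSR.
#' @export
complexity_spectrum <- function(cssrs) {
  if (nrow(cssrs) == 0L) {
    return(structure(integer(0), names = character(0)))
  }
  tab <- table(cssrs$complexity)
  structure(as.integer(tab), names = names(tab))
}

#' Compound motifs unique to a single genome
#'
#' A compound motif string (e.g. `"CCG-AG-A"`) is unique to a genome when
#' it occurs in that genome's set and in no other genome of the panel.
#'
#' @param per_genome named list (>= 2 genomes) of character vectors of
#'   compound motif strings.
#' @return named list mapping each genome to its unique motif strings.
#' @export
unique_motifs <- function(per_genome) {
  if (!is.list(per_genome) || length(per_genome) < 2L) {
    stop("uniqueness needs at least two genomes")
  }
  sets <- lapply(per_genome, unique)
  counts <- table(unlist(sets, use.names = FALSE))
  lapply(sets, function(s) s[counts[s] == 1L])
}
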