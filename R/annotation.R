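#' Load merged CDS intervals from GFF3
#'
#' Reads GFF3 content with a tolerant line parser (malformed lines are
#' skipped with a warning, anything after a `##FASTA` directive is
#' ignored), keeps features of type `CDS`, and merges overlapping or
#' duplicated intervals per contig with both strands pooled, via
#' [GenomicRanges::reduce()].
#'
#' @param gff path to a GFF3 file, or a character vector of GFF3 lines.
#' @param feature_type feature type to keep (default `"CDS"`).
#' @return a [GenomicRanges::GRanges] of sorted, disjoint coding
#'   intervals (1-based inclusive).
#' @export
load_cds_intervals <- function(gff, feature_type = "CDS") {
  lines <- if (length(gff) == 1L && !grepl("\n", gff) &&
               file.exists(gff)) readLines(gff, warn = FALSE)
          else unlist(strsplit(gff, "\n", fixed = TRUE))
  fasta_at <- match("##FASTA", lines)
  if (!is.na(fasta_at)) lines <- lines[seq_len(fasta_at - 1L)]
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]

  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(fields) == 9L
  if (any(ok)) {
    starts <- suppressWarnings(
      as.integer(vapply(fields[ok], `[[`, "", 4L)))
    ends <- suppressWarnings(
      as.integer(vapply(fields[ok], `[[`, "", 5L)))
    bad_coord <- is.na(starts) | is.na(ends) | starts < 1L | starts > ends
    ok[ok] <- !bad_coord
  }
  if (length(lines) > 0L && sum(!ok) > 0L) {
    warning(sprintf("skipped %d malformed GFF3 line(s)", sum(!ok)))
  }
  fields <- fields[ok]

  if (length(fields) > 0L) {
    type <- vapply(fields, `[[`, "", 3L)
    fields <- fields[type == feature_type]
  }
  if (length(fields) == 0L) {
    warning(sprintf("no %s features found; all loci will be non-coding",
                    feature_type))
    return(GenomicRanges::GRanges())
  }
  gr <- GenomicRanges::GRanges(
    seqnames = vapply(fields, `[[`, "", 1L),
    ranges = IRanges::IRanges(
      start = as.integer(vapply(fields, `[[`, "", 4L)),
      end = as.integer(vapply(fields, `[[`, "", 5L))))
  GenomicRanges::reduce(sort(gr), ignore.strand = TRUE)
}

#' Classify loci as coding or non-coding
#'
#' Under the default `"any"` rule a locus is coding when it overlaps a
#' CDS interval by at least 1 bp; under `"majority"` more than half of the
#' locus must be covered by coding intervals. Loci on contigs absent from
#' the annotation are classified non-coding with a warning.
#'
#' @param loci data.frame with columns `seq_id`, `start`, `end` (SSR or
#'   CSSR table).
#' @param cds coding intervals from [load_cds_intervals()].
#' @param rule `"any"` (default) or `"majority"`.
#' @return character vector, `"coding"` or `"non-coding"` per locus.
#' @export
classify_loci <- function(loci, cds, rule = c("any", "majority")) {
  rule <- match.arg(rule)
  if (nrow(loci) == 0L) return(character(0))
  if (length(cds) > 0L) {
    unknown <- setdiff(unique(loci$seq_id), .present_seqnames(cds))
    if (length(unknown) > 0L) {
      warning(sprintf(
        "contig(s) absent from annotation classified non-coding: %s",
        paste(unknown, collapse = ", ")))
    }
  }
  gr <- GenomicRanges::GRanges(
    seqnames = loci$seq_id,
    ranges = IRanges::IRanges(start = loci$start, end = loci$end))
  if (rule == "any") {
    hit <- IRanges::overlapsAny(gr, cds, ignore.strand = TRUE)
  } else {
    ov <- GenomicRanges::findOverlaps(gr, cds, ignore.strand = TRUE)
    inter <- GenomicRanges::pintersect(
      gr[S4Vectors::queryHits(ov)], cds[S4Vectors::subjectHits(ov)])
    covered <- tapply(GenomicRanges::width(inter),
                      S4Vectors::queryHits(ov), sum)
    bp <- integer(nrow(loci))
    bp[as.integer(names(covered))] <- as.integer(covered)
    hit <- bp * 2L > (loci$end - loci$start + 1L)
  }
  ifelse(hit, "coding", "non-coding")
}

.present_seqnames <- function(x) {
  unique(as.character(GenomicRanges::seqnames(x)))
}

#' Coding/non-coding percentage summary
#'
#' @param region character vector of `"coding"`/`"non-coding"` classes.
#' @param by optional grouping (e.g. CSSR complexity) to stratify the
#'   summary.
#' @return data.frame with counts and percentages per class (and group).
#' @export
region_summary <- function(region, by = NULL) {
  if (is.null(by)) by <- rep.int("all", length(region))
  groups <- split(region, by)
  rows <- lapply(names(groups), function(g) {
    r <- groups[[g]]
    n <- length(r)
    nc <- sum(r == "coding")
    data.frame(group = g, n = n, coding = nc, non_coding = n - nc,
               coding_pct = 100 * nc / n,
               non_coding_pct = 100 * (n - nc) / n,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
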