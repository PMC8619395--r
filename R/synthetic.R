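#' Specification for a synthetic survey genome
#'
#' Describes a small prokaryote-like assembly with planted perfect
#' repeats for ground-truth validation of the mining, chaining and
#' annotation stages. Defaults emulate the conditions of cyanobacterial
#' surveys: GC around 52% (observed panel range roughly 46-59%), an SSR
#' density near 2.9 loci/kb (panel range about 2.0-3.3), compound chains
#' of complexity 2-3, and CDS covering about three quarters of the
#' sequence.
#'
#' @param n_contigs number of contigs.
#' @param contig_length length of each contig in bp.
#' @param background_gc target GC percent of the non-repetitive
#'   background.
#' @param planted_ssrs data.frame with columns `motif`, `repeats`,
#'   `count`: singleton SSRs to plant (motifs used as written; must be
#'   primitive and meet `policy`).
#' @param planted_chains list of chains, each a list with `motifs`,
#'   `repeats` and `gaps` (length one less than the members; every gap
#'   must be <= `dmax` for the chain to survey as one CSSR).
#' @param cds_fraction target fraction of each contig covered by CDS.
#' @param cds_cover_repeat_fraction optional fraction of planted elements
#'   forced inside CDS intervals (for coding-percentage tests).
#' @param min_spacer guaranteed bp of repeat-free background between
#'   planted elements; keep it above `dmax` so planted singletons never
#'   chain with their neighbours.
#' @param policy minimum repeat policy the plants must satisfy.
#' @param dmax chaining distance the chains are designed for.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(
    n_contigs = 1L,
    contig_length = 50000L,
    background_gc = 52,
    planted_ssrs = data.frame(
      motif = c("A", "C", "AG", "AC", "AT", "ACG", "CCG", "AAG",
                "AAGT", "AACGT", "AACGTC"),
      repeats = c(6L, 7L, 3L, 4L, 3L, 3L, 3L, 4L, 3L, 3L, 3L),
      count = c(30L, 15L, 30L, 20L, 10L, 15L, 10L, 5L, 5L, 3L, 2L),
      stringsAsFactors = FALSE),
    planted_chains = list(
      list(motifs = c("AG", "A"), repeats = c(3L, 6L), gaps = 5L),
      list(motifs = c("AC", "CCG"), repeats = c(4L, 3L), gaps = 3L),
      list(motifs = c("A", "AG"), repeats = c(6L, 4L), gaps = 10L),
      list(motifs = c("ACG", "C"), repeats = c(3L, 7L), gaps = 1L),
      list(motifs = c("AT", "AAG"), repeats = c(3L, 4L), gaps = 6L),
      list(motifs = c("C", "AG", "ACG"), repeats = c(6L, 3L, 3L),
           gaps = c(2L, 7L)),
      list(motifs = c("AG", "AC"), repeats = c(4L, 3L), gaps = 4L),
      list(motifs = c("CCG", "A"), repeats = c(3L, 8L), gaps = 8L)),
    cds_fraction = 0.75,
    cds_cover_repeat_fraction = NULL,
    min_spacer = 20L,
    policy = min_repeat_policy(),
    dmax = 10L) {
  policy <- .check_policy(policy)
  planted_ssrs$repeats <- as.integer(planted_ssrs$repeats)
  planted_ssrs$count <- as.integer(planted_ssrs$count)
  planted_chains <- lapply(planted_chains, function(ch) {
    ch$repeats <- as.integer(ch$repeats)
    ch$gaps <- as.integer(ch$gaps)
    ch
  })
  .check_motif_alphabet(planted_ssrs$motif)
  if (!all(is_primitive(planted_ssrs$motif))) {
    stop("planted motifs must be primitive")
  }
  if (any(planted_ssrs$repeats < policy[as.character(
        nchar(planted_ssrs$motif))])) {
    stop("planted repeats below the minimum repeat policy")
  }
  for (ch in planted_chains) {
    .check_motif_alphabet(ch$motifs)
    if (length(ch$motifs) < 2L ||
        length(ch$repeats) != length(ch$motifs) ||
        length(ch$gaps) != length(ch$motifs) - 1L) {
      stop("each chain needs >= 2 members and one gap per junction")
    }
    if (any(ch$repeats < policy[as.character(nchar(ch$motifs))])) {
      stop("chain member repeats below the minimum repeat policy")
    }
    if (any(ch$gaps < 0L)) stop("chain gaps must be non-negative")
  }
  if (background_gc <= 0 || background_gc >= 100) {
    stop("background_gc must be strictly between 0 and 100")
  }
  if (cds_fraction < 0 || cds_fraction > 1) {
    stop("cds_fraction must be in [0, 1]")
  }
  structure(list(
    n_contigs = as.integer(n_contigs),
    contig_length = as.integer(contig_length),
    background_gc = background_gc,
    planted_ssrs = planted_ssrs,
    planted_chains = planted_chains,
    cds_fraction = cds_fraction,
    cds_cover_repeat_fraction = cds_cover_repeat_fraction,
    min_spacer = as.integer(min_spacer),
    policy = policy,
    dmax = as.integer(dmax)), class = "synthetic_spec")
}

.rand_bases <- function(n, prob) {
  if (n == 0L) return(character(0))
  sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob)
}

## Draw a spacer and locally resample any window that forms a
## qualifying run (or extends a flanking element) until none remains.
.draw_spacer <- function(len, left, right, prob, policy,
                         max_tries = 500L) {
  sp <- .rand_bases(len, prob)
  a <- length(left)
  for (i in seq_len(max_tries)) {
    found <- .mine_chars(c(left, sp, right), "w", policy)
    if (nrow(found) > 0L) {
      found <- found[found$end >= a + 1L & found$start <= a + len, ,
                     drop = FALSE]
    }
    if (nrow(found) == 0L) return(sp)
    for (j in seq_len(nrow(found))) {
      lo <- max(1L, found$start[j] - a)
      hi <- min(len, found$end[j] - a)
      sp[lo:hi] <- .rand_bases(hi - lo + 1L, prob)
    }
  }
  stop("could not sample a repeat-free spacer; background too repetitive")
}

## Assemble one chain as characters plus expected member offsets,
## rejection-sampling the gap strings until mining the chain in
## isolation recovers exactly the intended members.
.build_chain <- function(ch, prob, policy, max_tries = 200L) {
  mem <- lapply(strrep(ch$motifs, ch$repeats),
                function(s) strsplit(s, "")[[1]])
  mem_len <- lengths(mem)
  k <- length(mem)
  offs <- integer(k)
  for (try in seq_len(max_tries)) {
    pieces <- list(mem[[1L]])
    offs[1L] <- 1L
    pos <- mem_len[1L]
    ok <- TRUE
    for (j in seq_len(k - 1L)) {
      pieces[[2L * j]] <- .rand_bases(ch$gaps[j], prob)
      offs[j + 1L] <- pos + ch$gaps[j] + 1L
      pieces[[2L * j + 1L]] <- mem[[j + 1L]]
      pos <- pos + ch$gaps[j] + mem_len[j + 1L]
    }
    chain <- unlist(pieces)
    found <- .mine_chars(chain, "c", policy)
    ok <- nrow(found) == k &&
      identical(found$start, offs) &&
      identical(found$end, offs + mem_len - 1L) &&
      identical(found$motif, ch$motifs)
    if (ok) return(list(chars = chain, offsets = offs))
  }
  stop("infeasible chain specification: members merge or gaps form ",
       "repeats at every draw")
}

.place_cds <- function(contig_length, fraction, forced) {
  ir <- if (length(forced) > 0L) {
    IRanges::reduce(IRanges::IRanges(start = forced$start,
                                     end = forced$end))
  } else IRanges::IRanges()
  target <- fraction * contig_length
  tries <- 0L
  while (sum(IRanges::width(ir)) < target && tries < 10000L) {
    len <- sample(300:1500, 1L)
    if (len >= contig_length) len <- contig_length
    st <- sample.int(contig_length - len + 1L, 1L)
    ir <- IRanges::reduce(c(ir, IRanges::IRanges(st, st + len - 1L)))
    tries <- tries + 1L
  }
  ir
}

#' Generate a synthetic genome panel member with ground truth
#'
#' Deterministic for a fixed seed. Planted elements are separated by
#' rejection-sampled background spacers that contain no qualifying run
#' and cannot extend a neighbouring plant, so mining the output recovers
#' exactly the planted loci at the recorded coordinates; this is verified
#' internally before returning. CDS intervals are placed independently of
#' the plants unless `cds_cover_repeat_fraction` is set.
#'
#' @param spec a [synthetic_spec()].
#' @param seed RNG seed.
#' @return list with `sequences` (named character vector), `gff`
#'   (character vector of GFF3 lines), `truth` (data.frame of planted
#'   SSRs: `seq_id`, `start`, `end`, `motif`, `standard_motif`,
#'   `motif_len`, `repeats`, `length`, `chain_id`), `chains` (data.frame
#'   of planted CSSRs) and `cds` (data.frame of CDS intervals).
#' @export
generate_synthetic <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(seed)
  g <- spec$background_gc / 100
  prob <- c((1 - g) / 2, g / 2, g / 2, (1 - g) / 2)
  policy <- spec$policy

  singles <- spec$planted_ssrs[rep(seq_len(nrow(spec$planted_ssrs)),
                                   spec$planted_ssrs$count), c("motif",
                                                               "repeats")]
  elements <- c(
    lapply(seq_len(nrow(singles)), function(i) {
      list(type = "ssr", motif = singles$motif[i],
           repeats = singles$repeats[i])
    }),
    lapply(spec$planted_chains, function(ch) list(type = "chain",
                                                  chain = ch)))
  elements <- elements[sample.int(length(elements))]
  contig_of <- rep_len(seq_len(spec$n_contigs), length(elements))

  seqs <- character(spec$n_contigs)
  names(seqs) <- sprintf("synth_contig%02d", seq_len(spec$n_contigs))
  truth <- NULL; chains_truth <- NULL; cds_truth <- NULL
  gff <- "##gff-version 3"

  for (ci in seq_len(spec$n_contigs)) {
    id <- names(seqs)[ci]
    elems <- elements[contig_of == ci]
    built <- lapply(elems, function(e) {
      if (e$type == "ssr") {
        list(chars = strsplit(strrep(e$motif, e$repeats), "")[[1L]],
             e = e)
      } else {
        c(.build_chain(e$chain, prob, policy), list(e = e))
      }
    })
    elem_bp <- sum(vapply(built, function(b) length(b$chars), integer(1)))
    n_slots <- length(built) + 1L
    free_bp <- spec$contig_length - elem_bp - n_slots * spec$min_spacer
    if (free_bp < 0L) {
      stop("infeasible packing: planted elements exceed contig length")
    }
    extra <- as.vector(stats::rmultinom(1L, free_bp, rep(1, n_slots)))
    spacer_len <- spec$min_spacer + extra

    pieces <- vector("list", 2L * length(built) + 1L)
    pos <- 0L
    tail17 <- character(0)
    chain_no <- 0L
    for (j in seq_along(built)) {
      nxt <- built[[j]]$chars
      sp <- .draw_spacer(spacer_len[j], tail17,
                         nxt[seq_len(min(17L, length(nxt)))], prob,
                         policy)
      pieces[[2L * j - 1L]] <- sp
      pos <- pos + length(sp)
      st <- pos + 1L
      pieces[[2L * j]] <- nxt
      pos <- pos + length(nxt)
      tail17 <- {
        w <- c(sp, nxt)
        w[seq.int(max(1L, length(w) - 16L), length(w))]
      }
      e <- built[[j]]$e
      if (e$type == "ssr") {
        truth <- rbind(truth, data.frame(
          seq_id = id, start = st, end = pos, motif = e$motif,
          standard_motif = standardize_motif(e$motif),
          motif_len = nchar(e$motif), repeats = e$repeats,
          length = nchar(e$motif) * e$repeats, chain_id = NA_character_,
          stringsAsFactors = FALSE))
      } else {
        chain_no <- chain_no + 1L
        cid <- sprintf("%s_chain%02d", id, chain_no)
        ch <- e$chain
        m_st <- st + built[[j]]$offsets - 1L
        m_len <- nchar(ch$motifs) * ch$repeats
        truth <- rbind(truth, data.frame(
          seq_id = id, start = m_st, end = m_st + m_len - 1L,
          motif = ch$motifs,
          standard_motif = standardize_motif(ch$motifs),
          motif_len = nchar(ch$motifs), repeats = ch$repeats,
          length = m_len, chain_id = cid, stringsAsFactors = FALSE))
        chains_truth <- rbind(chains_truth, data.frame(
          seq_id = id, chain_id = cid, start = m_st[1L],
          end = m_st[length(m_st)] + m_len[length(m_len)] - 1L,
          complexity = length(ch$motifs),
          motif_string = paste(standardize_motif(ch$motifs),
                               collapse = "-"),
          stringsAsFactors = FALSE))
      }
    }
    sp <- .draw_spacer(spacer_len[n_slots], tail17, character(0), prob,
                       policy)
    pieces[[2L * length(built) + 1L]] <- sp
    seqs[ci] <- paste(unlist(pieces), collapse = "")

    forced <- NULL
    if (!is.null(spec$cds_cover_repeat_fraction)) {
      here <- truth[truth$seq_id == id, ]
      n_forced <- ceiling(spec$cds_cover_repeat_fraction * nrow(here))
      if (n_forced > 0L) {
        pick <- here[sample.int(nrow(here), n_forced), ]
        forced <- data.frame(
          start = pmax(1L, pick$start - sample(20:100, n_forced,
                                               replace = TRUE)),
          end = pmin(spec$contig_length,
                     pick$end + sample(20:100, n_forced, replace = TRUE)))
      }
    }
    if (spec$cds_fraction > 0 || !is.null(forced)) {
      ir <- .place_cds(spec$contig_length, spec$cds_fraction, forced)
      cds_truth <- rbind(cds_truth, data.frame(
        seq_id = id, start = IRanges::start(ir), end = IRanges::end(ir),
        stringsAsFactors = FALSE))
      gff <- c(gff, sprintf(
        "%s\tssrsurvey\tCDS\t%d\t%d\t.\t+\t0\tID=cds_%s_%04d",
        id, IRanges::start(ir), IRanges::end(ir), id,
        seq_along(ir)))
    }
  }

  if (is.null(truth)) {
    truth <- data.frame(
      seq_id = character(0), start = integer(0), end = integer(0),
      motif = character(0), standard_motif = character(0),
      motif_len = integer(0), repeats = integer(0), length = integer(0),
      chain_id = character(0), stringsAsFactors = FALSE)
  }
  truth <- truth[order(truth$seq_id, truth$start), ]
  rownames(truth) <- NULL

  mined <- find_perfect_ssrs(seqs, policy)
  cols <- c("seq_id", "start", "end", "motif", "repeats")
  strip <- function(d) {
    d <- d[, cols]
    rownames(d) <- NULL
    d
  }
  if (!identical(strip(mined), strip(truth))) {
    stop("internal error: mined loci differ from planted truth")
  }

  list(sequences = seqs, gff = gff, truth = truth,
       chains = chains_truth, cds = cds_truth)
}

#' Write a synthetic genome to FASTA / GFF3 / truth TSV files
#'
#' @param gen result of [generate_synthetic()].
#' @param dir output directory.
#' @param prefix file stem (default `"synthetic"`).
#' @return (invisibly) named vector of the written paths.
#' @export
write_synthetic <- function(gen, dir, prefix = "synthetic") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, paste0(prefix, ".fasta"))
  gf <- file.path(dir, paste0(prefix, ".gff3"))
  tr <- file.path(dir, paste0(prefix, "_truth.tsv"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(gen$sequences), fa)
  writeLines(gen$gff, gf)
  write.table(gen$truth, tr, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(fasta = fa, gff = gf, truth = tr))
}
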