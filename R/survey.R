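#' One genome's survey row
#'
#' Collapses a genome's SSR and CSSR tables into the per-genome summary
#' used in comparative surveys: counts, relative abundance/density of
#' both locus classes, the compound-member count ncSSR, and cSSR%.
#' The Z index needs the whole panel and is added by [add_panel_z()].
#'
#' @param genome genome identifier.
#' @param size_bp assembly size in bp used as the RA/RD denominator (by
#'   convention the full assembly length including N).
#' @param gc_pct assembly GC percentage, see [gc_content()].
#' @param ssrs SSR table from [find_perfect_ssrs()].
#' @param cssrs CSSR table from [build_cssrs()].
#' @return one-row data.frame.
#' @export
genome_survey_row <- function(genome, size_bp, gc_pct, ssrs, cssrs) {
  n_ssr <- nrow(ssrs)
  n_cssr <- nrow(cssrs)
  nc_ssr <- if (n_cssr > 0L) sum(cssrs$complexity) else 0L
  data.frame(
    genome = genome,
    size_bp = size_bp,
    gc_pct = gc_pct,
    n_ssr = n_ssr,
    ssr_ra = relative_abundance(n_ssr, size_bp),
    ssr_rd = relative_density(sum(ssrs$length), size_bp),
    n_cssr = n_cssr,
    cssr_ra = relative_abundance(n_cssr, size_bp),
    cssr_rd = relative_density(sum(cssrs$length), size_bp),
    nc_ssr = nc_ssr,
    cssr_pct = if (n_ssr > 0L) cssr_percent(nc_ssr, n_ssr) else NA_real_,
    stringsAsFactors = FALSE)
}

#' Add the panel mean complexity and Z column to a survey table
#'
#' @param survey data.frame of rows from [genome_survey_row()] (or the
#'   fixture path, [fixture_survey()]).
#' @return the survey with a `z` column; the panel C-bar is attached as
#'   attribute `"c_bar"`.
#' @export
add_panel_z <- function(survey) {
  c_bar <- mean_complexity(survey$nc_ssr, survey$n_cssr)
  survey$z <- ifelse(survey$n_cssr > 0,
                     z_score(survey$n_cssr, survey$nc_ssr, c_bar),
                     NA_real_)
  attr(survey, "c_bar") <- c_bar
  survey
}

#' Bundled survey fixture: 46 cyanobacterial genomes
#'
#' A transcription of the printed per-genome summary table of a published
#' 46-genome *Leptolyngbya* repeat survey: raw integer columns (assembly
#' size, GC, nSSR, nCSSR, ncSSR) plus the printed derived columns (RA,
#' RD, cSSR%, Z) retained for validation only. The raw columns are the
#' input of the statistics stage; the printed rounded columns are never
#' used as inputs.
#'
#' @return data.frame with 46 rows.
#' @export
table1_fixture <- function() {
  path <- system.file("extdata", "leptolyngbya_table1.tsv",
                      package = "ssrsurvey", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}

#' Recompute survey statistics from printed raw counts
#'
#' Fixture-driven statistics mode: takes a table of per-genome raw
#' integer columns (`size_bp`, `gc_pct`, `n_ssr`, `n_cssr`, `nc_ssr`) and
#' recomputes relative abundances, cSSR%, the panel mean complexity and
#' the Z index at full precision.
#'
#' @param counts data.frame with the raw columns; defaults to the bundled
#'   46-genome fixture.
#' @return survey data.frame with computed `ssr_ra`, `cssr_ra`,
#'   `cssr_pct`, `z` columns and attribute `"c_bar"`.
#' @export
fixture_survey <- function(counts = table1_fixture()) {
  need <- c("size_bp", "n_ssr", "n_cssr", "nc_ssr")
  if (!all(need %in% names(counts))) {
    stop("counts must contain columns: ", paste(need, collapse = ", "))
  }
  sv <- data.frame(
    genome = if ("genome" %in% names(counts)) counts$genome
             else as.character(seq_len(nrow(counts))),
    size_bp = counts$size_bp,
    gc_pct = if ("gc_pct" %in% names(counts)) counts$gc_pct else NA_real_,
    n_ssr = counts$n_ssr,
    ssr_ra = relative_abundance(counts$n_ssr, counts$size_bp),
    n_cssr = counts$n_cssr,
    cssr_ra = relative_abundance(counts$n_cssr, counts$size_bp),
    nc_ssr = counts$nc_ssr,
    cssr_pct = cssr_percent(counts$nc_ssr, counts$n_ssr),
    stringsAsFactors = FALSE)
  if ("no" %in% names(counts)) sv <- cbind(no = counts$no, sv)
  add_panel_z(sv)
}

#' Cross-genome Pearson correlations
#'
#' The standard survey pairs: nSSR and nCSSR each against genome size,
#' GC content, and each other, plus both against ncSSR.
#'
#' @param survey survey table with columns `size_bp`, `gc_pct`, `n_ssr`,
#'   `n_cssr`, `nc_ssr` and at least 3 rows.
#' @return data.frame with one row per variable pair (`var1`, `var2`,
#'   `rho`, `p_value`, `n`, `significance`).
#' @export
run_correlations <- function(survey) {
  if (nrow(survey) < 3L) stop("correlations need at least 3 genomes")
  cols <- c(size_bp = "genome size", gc_pct = "GC content",
            n_ssr = "nSSR", n_cssr = "nCSSR", nc_ssr = "ncSSR")
  pairs <- rbind(
    c("n_ssr", "size_bp"), c("n_ssr", "gc_pct"), c("n_ssr", "nc_ssr"),
    c("n_cssr", "size_bp"), c("n_cssr", "gc_pct"), c("n_cssr", "n_ssr"),
    c("n_cssr", "nc_ssr"))
  rows <- apply(pairs, 1L, function(p) {
    res <- pearson_cor(survey[[p[1L]]], survey[[p[2L]]])
    cbind(data.frame(var1 = cols[[p[1L]]], var2 = cols[[p[2L]]],
                     stringsAsFactors = FALSE), res)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

.pair_annotation <- function(fasta) {
  stem <- sub("\\.(fa|fasta|fna)(\\.gz)?$", "", fasta, ignore.case = TRUE)
  for (ext in c(".gff3", ".gff")) {
    if (file.exists(paste0(stem, ext))) return(paste0(stem, ext))
  }
  NA_character_
}

#' Run the full survey over a panel of genomes
#'
#' For each genome: read and normalize the FASTA, mine perfect SSRs,
#' chain CSSRs, optionally classify loci against CDS intervals from the
#' paired GFF3 (`<stem>.gff3` beside `<stem>.fasta`, or given
#' explicitly), and assemble the per-genome survey row. Panel-level
#' results (C-bar, Z, correlations when >= 3 genomes, unique compound
#' motifs when >= 2) are added on top. Fully deterministic; re-running on
#' identical inputs reproduces identical reports.
#'
#' @param fastas character vector of FASTA paths, or one directory
#'   containing them.
#' @param gffs optional character vector of GFF3 paths parallel to
#'   `fastas` (NA allowed); by default annotations are discovered beside
#'   each FASTA.
#' @param policy minimum repeat counts, see [min_repeat_policy()].
#' @param dmax maximum CSSR interruption in bp.
#' @param overlap_rule coding classification rule, see [classify_loci()].
#' @param include_n_in_size if `TRUE` (default) the RA/RD denominator is
#'   the full assembly length including N.
#' @param out_dir optional directory; when given, survey, correlation,
#'   complexity-spectrum, motif-abundance, region and unique-motif TSV
#'   reports are written there.
#' @return (invisibly) a list with elements `survey`, `correlations`,
#'   `ssrs`, `cssrs`, `spectra`, `motif_abundance`, `regions`,
#'   `unique_motifs`.
#' @export
run_survey <- function(fastas, gffs = NULL, policy = min_repeat_policy(),
                       dmax = 10L, overlap_rule = c("any", "majority"),
                       include_n_in_size = TRUE, out_dir = NULL) {
  overlap_rule <- match.arg(overlap_rule)
  if (length(fastas) == 1L && dir.exists(fastas)) {
    fastas <- sort(list.files(fastas, "\\.(fa|fasta|fna)$",
                              full.names = TRUE, ignore.case = TRUE))
  }
  if (length(fastas) == 0L) stop("no genome FASTA files to survey")
  if (is.null(gffs)) {
    gffs <- vapply(fastas, .pair_annotation, character(1))
  }
  ids <- sub("\\.(fa|fasta|fna)(\\.gz)?$", "", basename(fastas),
             ignore.case = TRUE)

  ssr_tables <- list(); cssr_tables <- list(); sizes <- numeric(0)
  survey <- NULL; spectra <- list(); regions <- NULL
  for (i in seq_along(fastas)) {
    id <- ids[i]
    seqs <- read_genome(fastas[i])
    size <- if (include_n_in_size) sum(nchar(seqs)) else
      sum(nchar(gsub("N", "", seqs, fixed = TRUE)))
    ssrs <- find_perfect_ssrs(seqs, policy)
    cssrs <- build_cssrs(ssrs, dmax)
    message(sprintf("%s: %d contigs, %d SSRs, %d CSSRs",
                    id, length(seqs), nrow(ssrs), nrow(cssrs)))
    row <- genome_survey_row(id, size, gc_content(seqs), ssrs, cssrs)

    if (!is.na(gffs[i])) {
      cds <- load_cds_intervals(gffs[i])
      ssrs$region <- classify_loci(ssrs, cds, overlap_rule)
      cssrs$region <- classify_loci(cssrs, cds, overlap_rule)
      reg <- rbind(
        cbind(genome = id, locus = "SSR",
              region_summary(ssrs$region)),
        if (nrow(cssrs) > 0L)
          cbind(genome = id, locus = "CSSR",
                region_summary(cssrs$region)),
        if (nrow(cssrs) > 0L)
          cbind(genome = id, locus = "CSSR_by_complexity",
                region_summary(cssrs$region, by = cssrs$complexity)))
      regions <- rbind(regions, reg)
    } else {
      ssrs$region <- NA_character_
      cssrs$region <- NA_character_
      warning(sprintf("no annotation for %s; region columns set to NA",
                      id))
    }
    ssr_tables[[id]] <- ssrs
    cssr_tables[[id]] <- cssrs
    sizes[id] <- size
    spectra[[id]] <- complexity_spectrum(cssrs)
    survey <- rbind(survey, row)
  }

  survey <- add_panel_z(survey)
  correlations <- if (nrow(survey) >= 3L) {
    tryCatch(run_correlations(survey), error = function(e) {
      warning("panel correlations skipped: ", conditionMessage(e))
      NULL
    })
  } else NULL
  uniq <- if (length(cssr_tables) >= 2L) {
    unique_motifs(lapply(cssr_tables, function(t) t$motif_string))
  } else NULL
  mam <- motif_abundance_matrix(ssr_tables, sizes)

  res <- list(survey = survey, correlations = correlations,
              ssrs = ssr_tables, cssrs = cssr_tables, spectra = spectra,
              motif_abundance = mam, regions = regions,
              unique_motifs = uniq)
  if (!is.null(out_dir)) write_reports(res, out_dir)
  invisible(res)
}

.round_cols <- function(df, cols, digits) {
  for (cl in intersect(cols, names(df))) df[[cl]] <- round(df[[cl]], digits)
  df
}

#' Write survey reports as TSV files
#'
#' Emits `survey.tsv` (RA/RD/cSSR%/Z rounded to 2 decimals, C-bar to 3 in
#' a comment header), `correlations.tsv`, `complexity_spectrum.tsv`,
#' `motif_abundance.tsv` (long format), `region_summary.tsv` and
#' `unique_motifs.tsv` as available.
#'
#' @param res result list from [run_survey()].
#' @param out_dir output directory (created if needed).
#' @return (invisibly) the output directory.
#' @export
write_reports <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name) {
    write.table(df, file.path(out_dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  sv <- .round_cols(res$survey,
                    c("gc_pct", "ssr_ra", "ssr_rd", "cssr_ra", "cssr_rd",
                      "cssr_pct", "z"), 2L)
  con <- file(file.path(out_dir, "survey.tsv"), "w")
  writeLines(sprintf("# C_bar\t%.3f", attr(res$survey, "c_bar")), con)
  write.table(sv, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  if (!is.null(res$correlations)) {
    tsv(.round_cols(res$correlations, "rho", 2L), "correlations.tsv")
  }
  spec <- do.call(rbind, lapply(names(res$spectra), function(g) {
    s <- res$spectra[[g]]
    if (length(s) == 0L) return(NULL)
    data.frame(genome = g, complexity = as.integer(names(s)),
               count = s, stringsAsFactors = FALSE)
  }))
  if (!is.null(spec)) tsv(spec, "complexity_spectrum.tsv")
  mam <- res$motif_abundance
  if (!is.null(mam) && nrow(mam) > 0L) {
    long <- data.frame(
      genome = rep(colnames(mam), each = nrow(mam)),
      standard_motif = rep(rownames(mam), ncol(mam)),
      ra = as.vector(mam), stringsAsFactors = FALSE)
    tsv(long, "motif_abundance.tsv")
  }
  if (!is.null(res$regions)) {
    tsv(.round_cols(res$regions, c("coding_pct", "non_coding_pct"), 2L),
        "region_summary.tsv")
  }
  if (!is.null(res$unique_motifs)) {
    um <- do.call(rbind, lapply(names(res$unique_motifs), function(g) {
      m <- res$unique_motifs[[g]]
      if (length(m) == 0L) return(NULL)
      data.frame(genome = g, motif_string = m, stringsAsFactors = FALSE)
    }))
    if (!is.null(um)) tsv(um, "unique_motifs.tsv")
  }
  invisible(out_dir)
}
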