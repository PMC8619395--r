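#' GC content of a sequence, in percent
#'
#' `100 * (G + C) / (A + C + G + T)`; N and other ambiguity bases are
#' excluded from both numerator and denominator.
#'
#' @param x character vector of sequences or a [Biostrings::DNAStringSet];
#'   multiple elements are pooled (assembly-wide GC).
#' @return percent, a single number.
#' @export
gc_content <- function(x) {
  if (!methods::is(x, "DNAStringSet")) {
    x <- Biostrings::DNAStringSet(as.character(x))
  }
  freq <- colSums(Biostrings::alphabetFrequency(x)[, c("A", "C", "G", "T"),
                                                   drop = FALSE])
  total <- sum(freq)
  if (total == 0) stop("GC content undefined: no unambiguous bases")
  100 * (freq[["G"]] + freq[["C"]]) / total
}

#' Relative abundance: loci per kb
#'
#' @param count number of loci (SSRs or CSSRs).
#' @param size_bp genome size in bp.
#' @return loci per kb.
#' @export
relative_abundance <- function(count, size_bp) {
  if (any(size_bp <= 0)) stop("genome size must be positive")
  count / (size_bp / 1000)
}

#' Relative density: repeat bp per kb
#'
#' @param total_repeat_bp summed locus length in bp.
#' @param size_bp genome size in bp.
#' @return bp of repeat per kb.
#' @export
relative_density <- function(total_repeat_bp, size_bp) {
  if (any(size_bp <= 0)) stop("genome size must be positive")
  total_repeat_bp / (size_bp / 1000)
}

#' Percentage of SSRs participating in compound structures
#'
#' `cSSR% = 100 * ncSSR / nSSR`.
#'
#' @param nc_ssr number of compound-member SSRs.
#' @param n_ssr total number of SSRs.
#' @return percent.
#' @export
cssr_percent <- function(nc_ssr, n_ssr) {
  if (any(n_ssr <= 0)) stop("nSSR must be positive")
  if (any(nc_ssr > n_ssr)) stop("ncSSR cannot exceed nSSR")
  100 * nc_ssr / n_ssr
}

#' Panel mean complexity
#'
#' The average over genomes of the per-genome ratio ncSSR / nCSSR.
#' Genomes without any CSSR are excluded with a warning.
#'
#' @param nc_ssr per-genome compound-member counts.
#' @param n_cssr per-genome CSSR counts.
#' @return mean complexity (>= 2 whenever every CSSR has >= 2 members).
#' @export
mean_complexity <- function(nc_ssr, n_cssr) {
  if (length(nc_ssr) != length(n_cssr)) stop("length mismatch")
  zero <- n_cssr == 0
  if (any(zero)) {
    warning(sprintf("%d genome(s) without CSSRs excluded from C-bar",
                    sum(zero)))
    nc_ssr <- nc_ssr[!zero]
    n_cssr <- n_cssr[!zero]
  }
  if (length(n_cssr) == 0L) stop("no genomes with CSSRs")
  mean(nc_ssr / n_cssr)
}

#' Z index of compound-microsatellite representation
#'
#' The expected CSSR count of a genome is its compound-member count
#' divided by the panel mean complexity, `nCSSR_exp = ncSSR / C-bar`; the
#' index is `Z = (nCSSR_obs - nCSSR_exp) / sqrt(nCSSR_exp)`. Positive Z
#' means the genome packs its compound-member SSRs into more CSSRs than
#' the panel average predicts.
#'
#' @param n_cssr_obs observed CSSR count(s).
#' @param nc_ssr compound-member SSR count(s).
#' @param c_bar panel mean complexity from [mean_complexity()].
#' @return dimensionless Z, vectorized over genomes.
#' @export
z_score <- function(n_cssr_obs, nc_ssr, c_bar) {
  if (length(c_bar) != 1L || c_bar <= 0) stop("c_bar must be positive")
  expected <- nc_ssr / c_bar
  if (any(expected == 0)) stop("expected CSSR count is zero")
  (n_cssr_obs - expected) / sqrt(expected)
}

#' Motif relative-abundance matrix
#'
#' Cross-genome matrix of standard-motif relative abundances: one row per
#' standard motif observed in at least one genome, one column per genome,
#' cell = SSR count of that class / (genome size in kb). Column sums
#' equal each genome's overall SSR relative abundance.
#'
#' @param ssr_tables named list of SSR tables (one per genome).
#' @param sizes_bp named numeric vector of genome sizes, names matching
#'   `ssr_tables`.
#' @return numeric matrix, motifs x genomes.
#' @export
motif_abundance_matrix <- function(ssr_tables, sizes_bp) {
  if (is.null(names(ssr_tables)) ||
      !all(names(ssr_tables) %in% names(sizes_bp))) {
    stop("ssr_tables and sizes_bp must share genome names")
  }
  motifs <- sort(unique(unlist(
    lapply(ssr_tables, function(t) t$standard_motif))))
  mat <- matrix(0, nrow = length(motifs), ncol = length(ssr_tables),
                dimnames = list(motifs, names(ssr_tables)))
  for (g in names(ssr_tables)) {
    tab <- table(ssr_tables[[g]]$standard_motif)
    mat[names(tab), g] <- as.numeric(tab) / (sizes_bp[[g]] / 1000)
  }
  mat
}

#' Pearson correlation with two-sided t-test
#'
#' Product-moment correlation via [stats::cor.test()], with the two-sided
#' p-value from the t distribution on n - 2 degrees of freedom and
#' significance flagged at the 0.05 and 0.01 levels.
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return data.frame with `rho`, `p_value`, `n`, `significance`
#'   (`"p<0.01"`, `"p<0.05"` or `"ns"`).
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop("x and y must have equal length >= 3")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined")
  }
  ct <- stats::cor.test(x, y, method = "pearson",
                        alternative = "two.sided")
  rho <- unname(ct$estimate)
  p <- ct$p.value
  data.frame(
    rho = rho, p_value = p, n = length(x),
    significance = if (p < 0.01) "p<0.01" else if (p < 0.05) "p<0.05"
                   else "ns",
    stringsAsFactors = FALSE)
}
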