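test_that("a survey row reproduces hand-computed statistics", {
  gen <- generate_synthetic(synthetic_spec(contig_length = 20000L),
                            seed = 51)
  ssrs <- find_perfect_ssrs(gen$sequences)
  cssrs <- build_cssrs(ssrs, 10)
  size <- sum(nchar(gen$sequences))
  row <- genome_survey_row("g", size, gc_content(gen$sequences), ssrs,
                           cssrs)
  expect_equal(row$n_ssr, nrow(gen$truth))
  expect_equal(row$ssr_ra, nrow(gen$truth) / (size / 1000))
  expect_equal(row$ssr_rd, sum(gen$truth$length) / (size / 1000))
  expect_equal(row$nc_ssr, sum(!is.na(gen$truth$chain_id)))
  expect_equal(row$cssr_pct, 100 * row$nc_ssr / row$n_ssr)
})

test_that("RA and RD are invariant under genome self-concatenation", {
  gen <- generate_synthetic(synthetic_spec(contig_length = 30000L),
                            seed = 53)
  s <- gen$sequences[[1]]
  doubled <- paste0(s, "N", s)
  one <- find_perfect_ssrs(c(g = s))
  two <- find_perfect_ssrs(c(g = doubled))
  ra1 <- relative_abundance(nrow(one), nchar(s))
  ra2 <- relative_abundance(nrow(two), nchar(doubled))
  expect_equal(ra2, ra1, tolerance = 1e-3)
  rd1 <- relative_density(sum(one$length), nchar(s))
  rd2 <- relative_density(sum(two$length), nchar(doubled))
  expect_equal(rd2, rd1, tolerance = 1e-3)
})

test_that("run_survey produces one row per genome and stable reports", {
  dir <- tempfile("panel")
  dir.create(dir)
  base <- synthetic_spec()
  for (i in 1:3) {
    gen <- generate_synthetic(
      synthetic_spec(contig_length = c(15000L, 18000L, 21000L)[i],
                     background_gc = c(47, 52, 57)[i],
                     planted_ssrs = transform(base$planted_ssrs,
                                              count = count + 3L * i),
                     planted_chains = base$planted_chains[seq_len(4 + i)]),
      seed = 60 + i)
    write_synthetic(gen, dir, prefix = sprintf("genome%02d", i))
  }
  out1 <- file.path(dir, "rep1"); out2 <- file.path(dir, "rep2")
  res <- suppressMessages(run_survey(dir, out_dir = out1))
  expect_equal(nrow(res$survey), 3L)
  expect_equal(res$survey$genome, sprintf("genome%02d", 1:3))
  expect_false(any(is.na(res$survey$z)))
  expect_s3_class(res$correlations, "data.frame")
  expect_true(all(c("coding", "non_coding") %in% names(res$regions)))
  expect_length(res$unique_motifs, 3L)
  # motif matrix marginal equals the survey RA column
  for (i in 1:3) {
    expect_equal(sum(res$motif_abundance[, i]), res$survey$ssr_ra[i])
  }
  # byte-identical reports on rerun
  suppressMessages(run_survey(dir, out_dir = out2))
  for (f in list.files(out1)) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
  }
  unlink(dir, recursive = TRUE)
})

test_that("missing annotation leaves region columns NA but keeps the genome", {
  dir <- tempfile("noann")
  dir.create(dir)
  gen <- generate_synthetic(synthetic_spec(contig_length = 12000L),
                            seed = 71)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(gen$sequences),
                              file.path(dir, "g1.fasta"))
  expect_warning(
    res <- suppressMessages(run_survey(dir)),
    "region columns set to NA")
  expect_equal(nrow(res$survey), 1L)
  expect_true(all(is.na(res$ssrs$g1$region)))
  unlink(dir, recursive = TRUE)
})

test_that("an empty input directory is an error", {
  dir <- tempfile("empty")
  dir.create(dir)
  expect_error(suppressMessages(run_survey(dir)), "no genome FASTA")
  unlink(dir, recursive = TRUE)
})

test_that("fixture statistics mode recomputes the derived columns", {
  fx <- table1_fixture()
  expect_equal(nrow(fx), 46L)
  sv <- fixture_survey(fx)
  expect_equal(nrow(sv), 46L)
  expect_equal(attr(sv, "c_bar"), mean(fx$nc_ssr / fx$n_cssr))
  expect_equal(sv$cssr_pct, 100 * fx$nc_ssr / fx$n_ssr)
  # correlations runnable straight off the fixture survey
  cors <- run_correlations(sv)
  expect_equal(nrow(cors), 7L)
  expect_true(all(abs(cors$rho) <= 1))
  expect_error(run_correlations(sv[1:2, ]), "at least 3")
  const <- sv[1:5, ]; const$gc_pct <- 50
  expect_error(run_correlations(const), "variance")
})
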