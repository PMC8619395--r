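make_ssrs <- function(starts, lens, motifs = NULL, seq_id = "c1") {
  k <- if (is.null(motifs)) rep("A", length(starts)) else motifs
  data.frame(
    seq_id = seq_id, start = starts, end = starts + lens - 1L,
    motif = k, standard_motif = standardize_motif(k),
    motif_len = nchar(k), repeats = lens %/% nchar(k), length = lens,
    stringsAsFactors = FALSE)
}

test_that("the dmax gap rule is inclusive at the boundary", {
  # gap = start(next) - end(prev) - 1
  two <- make_ssrs(c(1L, 18L), c(6L, 6L))          # gap 11
  expect_equal(nrow(build_cssrs(two, 10)), 0L)
  two <- make_ssrs(c(1L, 17L), c(6L, 6L))          # gap 10, boundary
  cc <- build_cssrs(two, 10)
  expect_equal(nrow(cc), 1L)
  expect_equal(cc$complexity, 2L)
  expect_equal(cc$gaps, "10")
  # dmax = 0 admits only directly abutting loci
  expect_equal(nrow(build_cssrs(two, 0)), 0L)
  abut <- make_ssrs(c(1L, 7L), c(6L, 6L), c("A", "AG"))
  expect_equal(build_cssrs(abut, 0)$complexity, 2L)
})

test_that("chains are maximal and spans are consistent", {
  three <- make_ssrs(c(1L, 7L, 16L), c(6L, 6L, 9L),
                     c("A", "AG", "ACG"))                # gaps 0, 3
  cc <- build_cssrs(three, 10)
  expect_equal(cc$complexity, 3L)
  expect_equal(cc$motif_string, "A-AG-ACG")
  expect_equal(sum(cc$complexity), 3L)                   # ncSSR
  # span = sum of member lengths + sum of gaps
  expect_equal(cc$end - cc$start + 1L, 6L + 6L + 9L + 0L + 3L)
  # a fourth SSR beyond dmax stays out and the chain is unchanged
  four <- rbind(three, make_ssrs(60L, 6L))
  cc2 <- build_cssrs(four, 10)
  expect_identical(cc2, cc)
})

test_that("unsorted or overlapping input is a contract violation", {
  bad <- make_ssrs(c(10L, 1L), c(6L, 6L))
  expect_error(build_cssrs(bad, 10), "sorted")
  ovl <- make_ssrs(c(1L, 4L), c(6L, 6L))
  expect_error(build_cssrs(ovl, 10), "non-overlapping")
})

test_that("same-motif neighbours chain by default but not with the switch", {
  two <- make_ssrs(c(1L, 10L), c(6L, 6L), c("A", "A"))   # gap 3
  expect_equal(nrow(build_cssrs(two, 10)), 1L)
  expect_equal(nrow(build_cssrs(two, 10, chain_same_motif = FALSE)), 0L)
})

test_that("complexity spectrum tallies members correctly", {
  expect_length(complexity_spectrum(build_cssrs(make_ssrs(1L, 6L)[0, ],
                                                10)), 0L)
  three <- make_ssrs(c(1L, 7L, 16L), c(6L, 6L, 9L), c("A", "AG", "ACG"))
  expect_equal(complexity_spectrum(build_cssrs(three, 10)), c(`3` = 1L))
  set.seed(7)
  sizes <- c(2L, 2L, 2L, 4L)
  starts <- 1L; rows <- NULL; pos <- 1L
  for (s in sizes) {
    for (j in seq_len(s)) {
      rows <- rbind(rows, make_ssrs(pos, 6L, sample(c("A", "AG"), 1)))
      pos <- pos + 6L + 2L                               # gap 2 inside
    }
    pos <- pos + 40L                                     # break chains
  }
  spec <- complexity_spectrum(build_cssrs(rows, 10))
  expect_equal(spec, c(`2` = 3L, `4` = 1L))
  expect_equal(sum(as.integer(names(spec)) * spec), sum(sizes))
})

test_that("increasing dmax never decreases ncSSR nor adds singletons", {
  set.seed(11)
  for (rep in 1:20) {
    n <- 30L
    gaps <- sample(0:25, n - 1, replace = TRUE)
    lens <- sample(c(6L, 9L, 12L), n, replace = TRUE)
    starts <- cumsum(c(1L, lens[-n] + gaps))
    ssrs <- make_ssrs(starts, lens,
                      sample(c("A", "AG", "ACG"), n, replace = TRUE))
    prev_nc <- -1L; prev_singletons <- n + 1L
    for (d in c(0L, 5L, 10L, 30L)) {
      cc <- build_cssrs(ssrs, d)
      nc <- sum(cc$complexity)
      expect_gte(nc, prev_nc)
      singles <- n - nc
      expect_lte(singles, prev_singletons)
      expect_lte(nrow(cc), nc / 2 + 1e-9)
      prev_nc <- nc; prev_singletons <- singles
    }
    # dmax below every gap yields no compound loci
    if (all(gaps > 0)) {
      expect_equal(nrow(build_cssrs(ssrs, min(gaps) - 1L)), 0L)
    }
  }
})

test_that("unique compound motifs match the naive pairwise comparison", {
  expect_error(unique_motifs(list(g1 = "A-AG")), "at least two")
  same <- list(g1 = c("A-AG"), g2 = c("A-AG"))
  expect_equal(lengths(unique_motifs(same)), c(g1 = 0L, g2 = 0L))
  two <- list(g1 = "A-AG", g2 = c("A-AG", "CCG-A"))
  expect_equal(unique_motifs(two)$g2, "CCG-A")
  expect_length(unique_motifs(two)$g1, 0L)
  set.seed(13)
  pool <- apply(expand.grid(c("A", "AG", "CCG", "AC"),
                            c("A", "AG", "CCG", "AC")), 1, paste,
                collapse = "-")
  panel <- lapply(setNames(1:6, paste0("g", 1:6)), function(i) {
    sample(pool, sample(3:10, 1))
  })
  expect_equal(unique_motifs(panel), oracle_unique_motifs(panel))
})
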