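gff_line <- function(seqid, type, start, end) {
  sprintf("%s\tsrc\t%s\t%d\t%d\t.\t+\t0\tID=x", seqid, type, start, end)
}

test_that("overlapping CDS features merge into disjoint intervals", {
  cds <- load_cds_intervals(c(gff_line("c1", "CDS", 101, 200),
                              gff_line("c1", "CDS", 151, 250)))
  expect_length(cds, 1L)
  expect_equal(GenomicRanges::start(cds), 101L)
  expect_equal(GenomicRanges::end(cds), 250L)
  # non-CDS features are ignored
  cds <- load_cds_intervals(c(gff_line("c1", "gene", 1, 500),
                              gff_line("c1", "CDS", 101, 200)))
  expect_equal(GenomicRanges::width(cds), 100L)
})

test_that("empty or malformed annotations degrade with warnings", {
  expect_warning(cds <- load_cds_intervals("##gff-version 3"),
                 "non-coding")
  expect_length(cds, 0L)
  loci <- data.frame(seq_id = "c1", start = 10L, end = 20L)
  expect_equal(classify_loci(loci, cds), "non-coding")
  expect_warning(
    cds <- load_cds_intervals(c("garbage line without tabs",
                                gff_line("c1", "CDS", 5, 50))),
    "malformed")
  expect_length(cds, 1L)
})

test_that("a single bp of overlap makes a locus coding under the any rule", {
  cds <- load_cds_intervals(gff_line("c1", "CDS", 21, 100))
  loci <- data.frame(seq_id = "c1", start = c(10L, 10L), end = c(20L, 21L))
  expect_equal(classify_loci(loci, cds), c("non-coding", "coding"))
  # majority rule needs strictly more than half the locus covered:
  # 16-25 overlaps 21-100 by exactly half (5/10 bp), 18-25 by 5/8
  loci <- data.frame(seq_id = "c1", start = c(10L, 16L, 18L),
                     end = c(25L, 25L, 25L))
  expect_equal(classify_loci(loci, cds, rule = "majority"),
               c("non-coding", "non-coding", "coding"))
})

test_that("loci on unannotated contigs fall back to non-coding with warning", {
  cds <- load_cds_intervals(gff_line("c1", "CDS", 1, 100))
  loci <- data.frame(seq_id = c("c1", "c9"), start = c(5L, 5L),
                     end = c(9L, 9L))
  expect_warning(cls <- classify_loci(loci, cds), "c9")
  expect_equal(cls, c("coding", "non-coding"))
})

test_that("classification matches a per-base membership oracle", {
  set.seed(31)
  for (rep in 1:10) {
    iv <- data.frame(start = sort(sample(1:900, 5)) )
    iv$end <- iv$start + sample(10:80, 5, replace = TRUE)
    gff <- vapply(seq_len(nrow(iv)), function(i) {
      gff_line("c1", "CDS", iv$start[i], iv$end[i])
    }, character(1))
    cds <- load_cds_intervals(gff)
    loci <- data.frame(seq_id = "c1", start = sample(1:950, 40))
    loci$end <- loci$start + sample(0:30, 40, replace = TRUE)
    got <- classify_loci(loci, cds)
    want <- vapply(seq_len(nrow(loci)), function(i) {
      if (oracle_is_coding(loci$start[i], loci$end[i], iv)) "coding"
      else "non-coding"
    }, character(1))
    expect_equal(got, want)
    # exactly two classes partition the loci
    expect_true(all(got %in% c("coding", "non-coding")))
  }
})

test_that("classification is invariant to line order and interval splitting", {
  lines <- c(gff_line("c1", "CDS", 50, 100), gff_line("c1", "CDS", 300, 400))
  split_lines <- c(gff_line("c1", "CDS", 300, 350),
                   gff_line("c1", "CDS", 351, 400),
                   gff_line("c1", "CDS", 50, 100))
  loci <- data.frame(seq_id = "c1", start = c(40L, 90L, 340L, 360L, 200L),
                     end = c(49L, 120L, 355L, 360L, 250L))
  expect_equal(classify_loci(loci, load_cds_intervals(lines)),
               classify_loci(loci, load_cds_intervals(split_lines)))
})

test_that("region summaries report complementary percentages", {
  region <- c("coding", "coding", "non-coding", "coding")
  rs <- region_summary(region)
  expect_equal(rs$coding_pct + rs$non_coding_pct, 100)
  expect_equal(rs$coding, 3L)
  by_c <- region_summary(region, by = c(2, 2, 3, 3))
  expect_equal(nrow(by_c), 2L)
  expect_equal(by_c$coding_pct, c(100, 50))
})
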