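test_that("read_bed parses records, empty files, and flags bad lines", {
  path <- withr::local_tempfile()
  writeLines("chr1\t100\t200\tp1", path)
  iv <- read_bed(path)
  expect_equal(iv$chrom, "chr1")
  expect_equal(iv$start, 100L)
  expect_equal(iv$end, 200L)
  expect_equal(iv$name, "p1")

  writeLines(character(), path)
  expect_equal(nrow(read_bed(path)), 0)

  writeLines("chr1\t200\t100", path)
  expect_error(read_bed(path), "line 1")
})

test_that("write/read round trip preserves coordinates, names and strands", {
  iv <- data.frame(chrom = c("chr2", "chr1"), start = c(5L, 0L),
                   end = c(50L, 10L), name = c("a", NA),
                   strand = c("-", NA), stringsAsFactors = FALSE)
  path <- withr::local_tempfile()
  write_bed(iv, path)
  back <- read_bed(path)
  expect_equal(back, iv)
})

test_that("merge_intervals follows the bookended-merge dialect", {
  m <- merge_intervals(make_intervals("chr1", c(100, 150), c(200, 250)))
  expect_equal(m$merged[, c("start", "end")],
               data.frame(start = 100L, end = 250L))
  # bookended intervals merge at max_gap = 0
  m <- merge_intervals(make_intervals("chr1", c(100, 200), c(200, 300)))
  expect_equal(nrow(m$merged), 1)
  expect_equal(m$merged$end, 300L)
  # different chromosomes never merge
  m <- merge_intervals(make_intervals(c("chr1", "chr2"), c(100, 100),
                                      c(200, 200)))
  expect_equal(nrow(m$merged), 2)
  # gap larger than max_gap stays split, equal gap merges
  iv <- make_intervals("chr1", c(100, 210), c(200, 300))
  expect_equal(nrow(merge_intervals(iv)$merged), 2)
  expect_equal(nrow(merge_intervals(iv, max_gap = 10)$merged), 1)
})

test_that("merging is idempotent and provenance is a total single-valued map", {
  withr::local_seed(7)
  for (rep in 1:5) {
    iv <- make_intervals(sample(c("chr1", "chr2"), 40, TRUE),
                         start <- sample(0:2000, 40),
                         start + sample(20:400, 40, TRUE))
    m1 <- merge_intervals(iv)
    m2 <- merge_intervals(m1$merged)
    expect_equal(m1$merged[, 1:3], m2$merged[, 1:3])
    # disjoint and sorted per chromosome
    for (ch in unique(m1$merged$chrom)) {
      sub <- m1$merged[m1$merged$chrom == ch, ]
      if (nrow(sub) > 1) expect_true(all(diff(sub$start) > 0) &&
                                       all(sub$start[-1] > sub$end[-nrow(sub)]))
    }
    expect_setequal(m1$provenance$input_name, iv$name)
    expect_false(anyDuplicated(m1$provenance$input_name) > 0)
  }
})

test_that("fragment counting matches the stated overlap semantics", {
  peaks <- make_intervals("chr1", c(100, 300), c(200, 400),
                          name = c("p1", "p2"))
  # 1 bp overlap counts; no overlap does not
  frags <- make_intervals("chr1", c(120, 500, 199), c(180, 600, 250))
  counts <- count_fragments(frags, peaks)
  expect_equal(as.numeric(counts), c(2, 0))
  # a fragment spanning two peaks is discarded by default, counted twice
  # with the flag
  span <- make_intervals("chr1", 150, 350)
  expect_equal(as.numeric(count_fragments(span, peaks)), c(0, 0))
  expect_equal(as.numeric(count_fragments(span, peaks,
                                          count_multi_overlap = TRUE)),
               c(1, 1))
})

test_that("counting agrees with a brute-force all-pairs oracle", {
  withr::local_seed(11)
  for (rep in 1:4) {
    n_f <- 400; n_p <- 60
    p_start <- sort(sample(seq(0, 30000, by = 350), n_p))
    peaks <- make_intervals("chr1", p_start, p_start + 300,
                            name = sprintf("p%02d", seq_len(n_p)))
    f_start <- sample(0:30000, n_f, TRUE)
    frags <- make_intervals("chr1", f_start, f_start + sample(50:500, n_f,
                                                              TRUE))
    counts <- count_fragments(frags, peaks)
    # oracle: count overlaps per fragment, drop multi-overlap fragments
    oracle <- integer(n_p)
    for (i in seq_len(n_f)) {
      hit <- which(frags$start[i] < peaks$end & peaks$start < frags$end[i])
      if (length(hit) == 1) oracle[hit] <- oracle[hit] + 1L
    }
    expect_equal(as.integer(counts), oracle)
    expect_lte(sum(counts), n_f)
  }
})

test_that("count matrices round-trip through TSV", {
  m <- matrix(0:5, 2, 3, dimnames = list(c("pk1", "pk2"),
                                         c("s1", "s2", "s3")))
  path <- withr::local_tempfile()
  write_counts(m, path)
  expect_identical(read_counts(path), m)
})
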