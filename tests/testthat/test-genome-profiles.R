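test_that("genome models validate their invariants", {
  g <- genome_model(c("chr1", "2"), c(100, 200))
  expect_identical(g$chrom, c("1", "2"))  # chr prefix stripped
  expect_equal(genome_length(g), 300)
  expect_error(genome_model(c("1", "1"), c(1, 2)), "duplicate")
  expect_error(genome_model("1", 0), "> 0")
  expect_error(genome_model(character(0), numeric(0)), "at least one")
})

test_that("read_seg applies the SEG coordinate convention", {
  g <- genome_model("1", 200)
  f <- withr::local_tempfile(fileext = ".seg")
  writeLines(c("ID\tchrom\tloc.start\tloc.end\tnum.mark\tseg.mean",
               "s1\tchr1\t1\t100\t10\t0.500000",
               "s1\tchr1\t101\t200\t10\t-0.250000"), f)
  ps <- read_seg(f, g)
  expect_named(ps, "s1")
  s <- ps$s1$segments
  expect_identical(s$chrom, c("1", "1"))   # chr prefix stripped
  expect_equal(s$start, c(0, 100))
  expect_equal(s$end, c(100, 200))
  expect_equal(s$log_ratio, c(0.5, -0.25))
  # a file already in canonical formatting round-trips byte-for-byte
  fc <- withr::local_tempfile(fileext = ".seg")
  writeLines(c("ID\tchrom\tloc.start\tloc.end\tnum.mark\tseg.mean",
               "s1\t1\t1\t100\t10\t0.500000",
               "s1\t1\t101\t200\t10\t-0.250000"), fc)
  f2 <- withr::local_tempfile(fileext = ".seg")
  write_seg(read_seg(fc, g), f2)
  expect_identical(readLines(f2), readLines(fc))
})

test_that("read_seg reports malformed and invalid input precisely", {
  g <- genome_model("1", 200)
  f <- withr::local_tempfile(fileext = ".seg")
  writeLines(c("ID\tchrom\tloc.start\tloc.end\tnum.mark\tseg.mean",
               "s1\t1\t1\t100\t10"), f)
  expect_error(read_seg(f, g), "line 2")
  writeLines(c("ID\tchrom\tloc.start\tloc.end\tnum.mark\tseg.mean",
               "s1\t1\t1\tx\t10\t0.1"), f)
  expect_error(read_seg(f, g), "line 2")
  # overlapping rows name sample and chromosome
  writeLines(c("ID\tchrom\tloc.start\tloc.end\tnum.mark\tseg.mean",
               "s1\t1\t1\t100\t10\t0.1",
               "s1\t1\t50\t150\t10\t0.2"), f)
  expect_error(read_seg(f, g), "'s1', chromosome 1")
  # unknown chromosome
  writeLines(c("ID\tchrom\tloc.start\tloc.end\tnum.mark\tseg.mean",
               "s1\t7\t1\t100\t10\t0.1"), f)
  expect_error(read_seg(f, g), "unknown chromosome")
})

test_that("write_seg handles empty and single-segment inputs", {
  f <- withr::local_tempfile(fileext = ".seg")
  write_seg(list(), f)
  expect_identical(readLines(f),
                   "ID\tchrom\tloc.start\tloc.end\tnum.mark\tseg.mean")
  p <- make_profile("one", genome_model("1", 100), "1", 0, 100, 0.25)
  write_seg(p, f)
  expect_length(readLines(f), 2L)
})

test_that("SEG round-trip is exact for canonical (6-decimal) profiles", {
  g <- tg(3, 1e6)
  for (seed in 1:5) {
    set.seed(seed)
    ps <- lapply(1:3, function(i) {
      n <- sample(2:5, 1)
      bp <- sort(sample(seq(0, 1e6, by = 1e4), n + 1))
      make_profile(sprintf("p%d", i), g,
                   chrom = rep(as.character(sample(3, 1)), n),
                   start = bp[-(n + 1)], end = bp[-1],
                   log_ratio = round(rnorm(n, 0, 0.4), 6),
                   num_mark = sample(10:99, n))
    })
    names(ps) <- vapply(ps, function(p) p$sample_id, character(1))
    f <- withr::local_tempfile(fileext = ".seg")
    write_seg(ps, f)
    back <- read_seg(f, g)
    expect_identical(names(back), names(ps))
    for (id in names(ps)) {
      expect_equal(back[[id]]$segments, ps[[id]]$segments)
    }
    f2 <- withr::local_tempfile(fileext = ".seg")
    write_seg(back, f2)
    expect_identical(readLines(f2), readLines(f))
  }
})

test_that("restrict_to_autosomes drops sex chromosomes", {
  g <- genome_model(c("1", "X"), c(1e5, 1e5))
  p <- make_profile("s", g, c("1", "X"), c(0, 0), c(1e5, 1e5), c(0.1, 0.2))
  r <- restrict_to_autosomes(p)
  expect_identical(r$segments$chrom, "1")
  auto <- make_profile("s", g, "1", 0, 1e5, 0.1)
  expect_equal(restrict_to_autosomes(auto), auto)
  xonly <- make_profile("s", g, "X", 0, 1e5, 0.2)
  expect_error(restrict_to_autosomes(xonly), "no autosomal segments")
})

test_that("harmonize_pair intersects segmentations with conserved weight", {
  g <- genome_model("1", 200)
  a <- make_profile("a", g, c("1", "1"), c(0, 100), c(100, 200), c(0.1, 0.2))
  b <- make_profile("b", g, c("1", "1"), c(0, 150), c(150, 200), c(-0.1, 0.3))
  h <- harmonize_pair(a, b)
  expect_equal(h$start, c(0, 100, 150))
  expect_equal(h$end, c(100, 150, 200))
  expect_equal(h$value_a, c(0.1, 0.2, 0.2))
  expect_equal(h$value_b, c(-0.1, -0.1, 0.3))
  expect_equal(h$weight, c(100, 50, 50))
  # identity: harmonizing a profile with itself keeps its segmentation
  hs <- harmonize_pair(a, a)
  expect_equal(hs$start, a$segments$start)
  expect_identical(hs$value_a, hs$value_b)
  # disjoint coverage errors
  g2 <- genome_model(c("1", "2"), c(200, 200))
  p1 <- make_profile("p1", g2, "1", 0, 200, 0.1)
  p2 <- make_profile("p2", g2, "2", 0, 200, 0.1)
  expect_error(harmonize_pair(p1, p2), "zero mutual coverage")
})

test_that("harmonization matches per-bp lookup and is symmetric", {
  g <- genome_model("1", 1000)
  for (seed in 1:5) {
    set.seed(seed)
    mk <- function(id) {
      # random segmentation guaranteed to overlap [400, 600)
      bp <- sort(unique(c(400, 600, sample(0:1000, sample(3:6, 1)))))
      n <- length(bp) - 1
      make_profile(id, g, rep("1", n), bp[-(n + 1)], bp[-1],
                   round(rnorm(n), 3))
    }
    a <- mk("a"); b <- mk("b")
    h <- harmonize_pair(a, b)
    va <- bp_values(a, "1", 1000); vb <- bp_values(b, "1", 1000)
    covered <- !is.na(va) & !is.na(vb)
    expect_equal(sum(h$weight), sum(covered))
    for (i in seq_len(nrow(h))) {
      idx <- (h$start[i] + 1):h$end[i]
      expect_true(all(va[idx] == h$value_a[i]))
      expect_true(all(vb[idx] == h$value_b[i]))
    }
    h2 <- harmonize_pair(b, a)
    expect_equal(h2$value_a, h$value_b)
    expect_equal(h2$value_b, h$value_a)
    expect_equal(h2$weight, h$weight)
  }
})

test_that("weighted_mean_std implements the population formulas", {
  res <- weighted_mean_std(c(2, 3, 2, 2), rep(1, 4))
  expect_equal(res$mean, 2.25)
  expect_equal(res$std, 0.4330127018922193)
  expect_equal(weighted_mean_std(rep(7, 5), 1:5)$std, 0)
  expect_equal(weighted_mean_std(3.2, 10), list(mean = 3.2, std = 0))
  expect_error(weighted_mean_std(numeric(0), numeric(0)), "empty")
  expect_error(weighted_mean_std(1:2, c(1, 0)), "> 0")
})

test_that("marker weighting is supported and validated", {
  g <- genome_model("1", 300)
  p <- make_profile("m", g, c("1", "1"), c(0, 100), c(100, 300),
                    c(0.1, 0.2), num_mark = c(30L, 10L))
  expect_equal(segment_weights(p, "bp"), c(100, 200))
  expect_equal(segment_weights(p, "markers"), c(30, 10))
  pna <- make_profile("m", g, "1", 0, 300, 0.1)
  expect_error(segment_weights(pna, "markers"), "num_mark")
})
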