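test_that("make_regions tiles chromosomes with a short terminal bin", {
  r <- make_regions(c(chr1 = 60000), 25000)
  expect_equal(r$chrom, rep("chr1", 3))
  expect_equal(r$start, c(0, 25000, 50000))
  expect_equal(r$end, c(25000, 50000, 60000))

  expect_equal(nrow(make_regions(c(chrA = 25000), 25000)), 1L)
  single_short <- make_regions(c(chrA = 24999), 25000)
  expect_equal(single_short$end, 24999)

  # count property over random sizes
  set.seed(11)
  for (i in 1:10) {
    sizes <- setNames(sample.int(3e5, 4), paste0("c", 1:4))
    bs <- sample(c(7, 1000, 25000), 1)
    r <- make_regions(sizes, bs)
    expect_equal(nrow(r), sum(ceiling(sizes / bs)))
    # tiling: no gaps/overlaps per chromosome
    for (cc in names(sizes)) {
      rc <- r[r$chrom == cc, ]
      expect_equal(rc$start, c(0, head(rc$end, -1)))
      expect_equal(max(rc$end), unname(sizes[cc]))
    }
  }
})

test_that("make_regions rejects degenerate input", {
  expect_error(make_regions(numeric(0)), "empty")
  expect_error(make_regions(c(chr1 = 0)), "positive")
  expect_error(make_regions(c(chr1 = 100), 0), "positive")
})

test_that("bin_signal sums interval mass with boundary splitting", {
  regions <- make_regions(c(chr1 = 60000), 25000)
  flat <- data.frame(chrom = "chr1", start = 0, end = 60000, value = 1.0)
  expect_equal(as.numeric(bin_signal(flat, regions)), c(25000, 25000, 10000))

  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), value = numeric(0))
  expect_equal(as.numeric(bin_signal(empty, regions)), c(0, 0, 0))

  # straddling interval splits proportionally
  tr <- data.frame(chrom = "chr1", start = 24000, end = 26000, value = 2.0)
  expect_equal(as.numeric(bin_signal(tr, regions)), c(2000, 2000, 0))
})

test_that("bin_signal matches a per-base brute-force oracle on random tracks", {
  regions <- make_regions(c(chr1 = 75000), 25000)
  for (seed in 1:25) {
    tr <- rand_track("chr1", 75000, 200, seed)
    expect_equal(as.numeric(bin_signal(tr, regions)),
                 per_base_bin_oracle(tr, regions), tolerance = 1e-9)
  }
})

test_that("binned mass is conserved", {
  regions <- make_regions(c(chr1 = 50000, chr2 = 30000), 10000)
  for (seed in 1:5) {
    tr <- rbind(rand_track("chr1", 50000, 40, seed),
                rand_track("chr2", 30000, 30, seed + 100))
    total <- sum(tr$value * (tr$end - tr$start))
    expect_equal(sum(bin_signal(tr, regions)), total, tolerance = 1e-9)
  }
})

test_that("bin_signal rejects malformed tracks", {
  regions <- make_regions(c(chr1 = 50000), 25000)
  beyond <- data.frame(chrom = "chr1", start = 49000, end = 51000, value = 1)
  expect_error(bin_signal(beyond, regions), "beyond chromosome length")
  other <- data.frame(chrom = "chrX", start = 0, end = 10, value = 1)
  expect_error(bin_signal(other, regions), "not in the region index")
  overlapping <- data.frame(chrom = "chr1", start = c(0, 500),
                            end = c(1000, 1500), value = 1)
  expect_error(bin_signal(overlapping, regions), "overlap")
})

test_that("manifest loading enforces one file per condition", {
  g <- full_grid()
  g$path <- sprintf("f%02d.bedGraph", seq_len(nrow(g)))
  dir <- withr::local_tempdir()
  good <- file.path(dir, "manifest.tsv")
  write.table(g[, c("path", "cell_line", "mark", "phase", "replicate")],
              good, sep = "\t", quote = FALSE, row.names = FALSE)
  m <- load_manifest(good)
  expect_s3_class(m, "track_manifest")
  expect_equal(nrow(m), 48L)

  dup <- g
  dup[2, c("cell_line", "mark", "phase", "replicate")] <-
    dup[1, c("cell_line", "mark", "phase", "replicate")]
  f <- file.path(dir, "dup.tsv")
  write.table(dup[, c("path", "cell_line", "mark", "phase", "replicate")],
              f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_manifest(f), "RPE1/H3K27ac/interphase/1")

  less <- g[-5, ]
  f2 <- file.path(dir, "less.tsv")
  write.table(less[, c("path", "cell_line", "mark", "phase", "replicate")],
              f2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_manifest(f2), "missing condition")

  bad <- g
  bad$mark[3] <- "H3K9me3"
  f3 <- file.path(dir, "bad.tsv")
  write.table(bad[, c("path", "cell_line", "mark", "phase", "replicate")],
              f3, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_manifest(f3), "unknown mark")
})
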