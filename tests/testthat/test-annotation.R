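test_that("gene-region overlap follows >= 1 bp semantics", {
  genes <- data.frame(symbol = c("A", "B", "C"),
                      chrom = "chr1",
                      start = c(30000, 24000, 60000),
                      end = c(31000, 26000, 70000))
  sel <- data.frame(chrom = "chr1", start = 25000, end = 50000)
  expect_equal(genes_in_regions(genes, sel), c("A", "B"))

  # straddling gene counted once even across two selected regions
  sel2 <- data.frame(chrom = "chr1", start = c(0, 25000),
                     end = c(25000, 50000))
  expect_equal(genes_in_regions(genes, sel2), c("A", "B"))

  bad <- data.frame(symbol = "A", chrom = "1", start = 1, end = 10)
  expect_error(genes_in_regions(bad, sel), "chromosome names")
})

test_that("gene-region overlap matches a quadratic all-pairs oracle", {
  set.seed(61)
  for (rep in 1:25) {
    ng <- sample(5:40, 1)
    genes <- data.frame(symbol = paste0("g", seq_len(ng)),
                        chrom = "toy",
                        start = sample.int(9000, ng))
    genes$end <- genes$start + sample.int(800, ng)
    nr <- sample(3:15, 1)
    regions <- rand_peaks(10000, nr, seed = 1000 + rep)
    regions$chrom <- "toy"
    got <- genes_in_regions(genes, regions)
    want <- character(0)
    for (i in seq_len(ng)) {
      hit <- FALSE
      for (j in seq_len(nrow(regions)))
        if (genes$start[i] < regions$end[j] &&
            regions$start[j] < genes$end[i]) hit <- TRUE
      if (hit) want <- c(want, genes$symbol[i])
    }
    expect_equal(got, unique(want))
  }
})

test_that("gene count grows monotonically with the selection", {
  set.seed(62)
  genes <- data.frame(symbol = paste0("g", 1:50), chrom = "toy",
                      start = sample.int(50000, 50))
  genes$end <- genes$start + 500
  regions <- make_regions(c(toy = 50500), 5000)
  n_prev <- 0
  for (k in c(2, 5, 8, 11)) {
    n_now <- length(genes_in_regions(genes, regions[1:k, ]))
    expect_gte(n_now, n_prev)
    n_prev <- n_now
  }
})

test_that("peak intersection and subtraction follow per-base semantics", {
  a <- data.frame(chrom = "toy", start = 0, end = 100)
  b <- data.frame(chrom = "toy", start = 50, end = 150)
  expect_equal(intersect_peaksets(a, b),
               data.frame(chrom = "toy", start = 50, end = 100))
  expect_equal(subtract_peaksets(a, b),
               data.frame(chrom = "toy", start = 0, end = 50))
  disjoint <- data.frame(chrom = "toy", start = 200, end = 300)
  expect_equal(nrow(intersect_peaksets(a, disjoint)), 0L)
  expect_equal(nrow(subtract_peaksets(a, a)), 0L)
  # subtract(a, empty) = a; intersect commutative/associative
  empty <- a[0, ]
  expect_equal(subtract_peaksets(a, empty), normalize_peaks(a),
               ignore_attr = TRUE)
  set.seed(63)
  x <- rand_peaks(5000, 8, 1)
  y <- rand_peaks(5000, 8, 2)
  z <- rand_peaks(5000, 8, 3)
  expect_equal(intersect_peaksets(x, y), intersect_peaksets(y, x))
  expect_equal(intersect_peaksets(intersect_peaksets(x, y), z),
               intersect_peaksets(x, intersect_peaksets(y, z)))
})

test_that("interval set operations match per-base boolean oracles", {
  len <- 10000
  for (rep in 1:25) {
    a <- rand_peaks(len, 12, seed = 2000 + rep)
    b <- rand_peaks(len, 12, seed = 3000 + rep)
    ma <- mask_from_peaks(a, len)
    mb <- mask_from_peaks(b, len)
    expect_equal(intersect_peaksets(a, b), mask_to_peaks(ma & mb),
                 ignore_attr = TRUE)
    expect_equal(subtract_peaksets(a, b), mask_to_peaks(ma & !mb),
                 ignore_attr = TRUE)
  }
})

test_that("the stepwise peak pipeline integrates 36 sets to 18, 6, 1", {
  lv <- condition_levels()
  labels <- expand.grid(replicate = lv$replicate, phase = lv$phase,
                        mark = c("H3K27ac", "H3K4me1", "H3K4me3"),
                        cell_line = lv$cell_line, stringsAsFactors = FALSE)
  same <- data.frame(chrom = "toy", start = c(100, 900), end = c(500, 1200))

  peaks <- replicate(36, same, simplify = FALSE)
  res <- stage_overlap_pipeline(peaks, labels)
  expect_equal(res$counts$n_sets, c(18L, 6L, 1L))
  # identical inputs: H3K27ac keeps nothing (present in prometaphase too),
  # so the final intersection is empty under the subtraction rule
  expect_equal(nrow(res$final), 0L)

  # with prometaphase H3K27ac empty, the final set is the common list
  peaks2 <- peaks
  k27_pro <- which(labels$mark == "H3K27ac" & labels$phase == "prometaphase")
  for (i in k27_pro) peaks2[[i]] <- same[0, ]
  res2 <- stage_overlap_pipeline(peaks2, labels)
  expect_equal(res2$final, normalize_peaks(same), ignore_attr = TRUE)

  # any one empty H3K4me set empties the final intersection
  peaks3 <- peaks2
  peaks3[[which(labels$mark == "H3K4me1")[1]]] <- same[0, ]
  expect_equal(nrow(stage_overlap_pipeline(peaks3, labels)$final), 0L)

  expect_error(stage_overlap_pipeline(peaks[-1], labels), "36")
})

test_that("the peak pipeline equals the composed per-base oracle", {
  lv <- condition_levels()
  labels <- expand.grid(replicate = lv$replicate, phase = lv$phase,
                        mark = c("H3K27ac", "H3K4me1", "H3K4me3"),
                        cell_line = lv$cell_line, stringsAsFactors = FALSE)
  len <- 5000
  for (rep in 1:5) {
    peaks <- lapply(1:36, function(i) rand_peaks(len, 10, 5000 + 40 * rep + i))
    res <- stage_overlap_pipeline(peaks, labels)
    masks <- lapply(peaks, mask_from_peaks, len = len)
    final_mask <- rep(TRUE, len)
    for (cl in lv$cell_line) for (mk in c("H3K27ac", "H3K4me1", "H3K4me3")) {
      phase_masks <- lapply(lv$phase, function(ph) {
        ii <- which(labels$cell_line == cl & labels$mark == mk &
                      labels$phase == ph)
        Reduce(`&`, masks[ii])
      })
      names(phase_masks) <- lv$phase
      mk_mask <- if (mk == "H3K27ac")
        phase_masks$interphase & phase_masks$anaphase_telophase &
          !phase_masks$prometaphase
      else Reduce(`&`, phase_masks)
      final_mask <- final_mask & mk_mask
    }
    expect_equal(res$final, mask_to_peaks(final_mask), ignore_attr = TRUE)
  }
})

test_that("gene lists are written deduplicated, one symbol per line", {
  f <- withr::local_tempfile()
  export_gene_list(c("TP53", "RUNX1", "GATA2"), f)
  expect_equal(readLines(f), c("TP53", "RUNX1", "GATA2"))
  export_gene_list(c("A", "B", "A"), f)
  expect_equal(readLines(f), c("A", "B"))
  expect_warning(export_gene_list(character(0), f), "empty")
  expect_equal(length(readLines(f)), 0L)
})

test_that("peak files are merged on load", {
  f <- withr::local_tempfile()
  writeLines(c("toy\t10\t50", "toy\t40\t80", "toy\t200\t300"), f)
  p <- read_peaks(f)
  expect_equal(p$start, c(10, 200))
  expect_equal(p$end, c(80, 300))
})
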