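test_that("the generator is deterministic and plants the configured regions", {
  cfg <- sim_config()
  sim <- simulate_tensor(cfg)
  expect_equal(dim(sim$tensor), c(2000L, 2L, 4L, 3L, 2L))
  expect_length(sim$planted, 100L)
  expect_true(all(sim$tensor > 0))
  sim2 <- simulate_tensor(cfg)
  expect_identical(unclass(sim$tensor), unclass(sim2$tensor))
  expect_identical(sim$planted, sim2$planted)
  expect_error(sim_config(n_regions = 50, n_planted = 50), "n_planted")
})

test_that("unit effects leave planted regions identical to background", {
  cfg <- sim_config(n_regions = 400, n_planted = 40, seed = 9)
  null_cfg <- sim_config(n_regions = 400, n_planted = 40, seed = 9,
                         k27_effect = 1, k27_dip = 1, me_effect = 1)
  a <- unclass(simulate_tensor(cfg)$tensor)
  b_sim <- simulate_tensor(null_cfg)
  b <- unclass(b_sim$tensor)
  # same seed: identical draws; with all multipliers 1 nothing distinguishes
  # planted rows, and the Input mark is untouched in both
  expect_identical(b[, , 4, , ], a[, , 4, , ])
  bg <- setdiff(seq_len(400), b_sim$planted)
  expect_identical(b[bg, , , , ], a[bg, , , , ])
  expect_false(identical(b[b_sim$planted, , 1, , ], a[b_sim$planted, , 1, , ]))
})

test_that("written coverage files round-trip to the simulated tensor", {
  cfg <- sim_config(n_regions = 300, n_planted = 25, seed = 2)
  dir <- withr::local_tempdir()
  out <- simulate_coverage(cfg, file.path(dir, "a"))
  files <- list.files(out$dir, pattern = "bedGraph$")
  expect_length(files, 48L)

  regions <- make_regions(read_chrom_sizes(out$chrom_sizes), cfg$bin_size)
  binned <- bin_manifest(load_manifest(out$manifest), regions)
  x <- assemble_tensor(binned$values, binned$labels)
  expect_equal(unclass(x), unclass(out$tensor), tolerance = 1e-9)

  # truth BED marks exactly the planted bins
  truth <- read.table(out$truth, sep = "\t")
  expect_equal(truth[[2]] / cfg$bin_size + 1, out$planted)

  # byte-identical re-run
  out2 <- simulate_coverage(cfg, file.path(dir, "b"))
  for (f in c(files, "manifest.tsv", "truth.bed", "genome.chrom.sizes"))
    expect_identical(readLines(file.path(out$dir, f)),
                     readLines(file.path(out2$dir, f)))

  expect_error(simulate_coverage(cfg, file.path(dir, "c"),
                                 chrom_sizes = c(chr1 = 10 * cfg$bin_size)),
               "regions requested")
})

test_that("the file-based pipeline selects the same regions as the in-memory fit", {
  cfg <- sim_config(n_regions = 300, n_planted = 25, seed = 2)
  dir <- withr::local_tempdir()
  out <- simulate_coverage(cfg, dir)
  res <- run_pipeline(out$manifest, out$chrom_sizes, bin_size = cfg$bin_size,
                      out_dir = file.path(dir, "run"))
  fit_mem <- tdfe(out$tensor)
  expect_equal(which(res$fit$selection$selected),
               which(fit_mem$selection$selected))
  expect_true(file.exists(file.path(dir, "run", "regions.tsv")))
  expect_true(file.exists(file.path(dir, "run", "selected.bed")))
  expect_true(file.exists(file.path(dir, "run", "validation.tsv")))
  sel_bed <- read.table(file.path(dir, "run", "selected.bed"), sep = "\t")
  expect_equal(nrow(sel_bed), res$fit$n_selected)
})

test_that("recovery improves with effect size over a small grid", {
  f1_at <- function(effect) {
    cfg <- sim_config(n_regions = 600, n_planted = 40, seed = 5,
                      k27_effect = effect, me_effect = effect)
    sim <- simulate_tensor(cfg)
    fit <- tryCatch(suppressWarnings(tdfe(sim$tensor)),
                    error = function(e) NULL)
    if (is.null(fit)) return(0)
    recovery_stats(which(fit$selection$selected), sim$planted)$f1
  }
  f1s <- vapply(c(1.3, 2.5, 5), f1_at, numeric(1))
  # monotone up to one grid inversion from sampling noise
  expect_true(sum(diff(f1s) < 0) <= 1)
  expect_gt(f1s[3], f1s[1])
})
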