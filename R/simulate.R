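# Synthetic coverage generator: log-normal background with a planted subset
# of regions carrying the reactivation/bookmark pattern, identical across
# cell lines and replicates.

#' Simulation configuration
#'
#' Defaults define the standard study conditions for desk-scale testing:
#' 2000 regions of which 100 carry the planted pattern — H3K27ac elevated
#' 4-fold in interphase and anaphase/telophase but halved in prometaphase,
#' H3K4me1/H3K4me3 elevated 4-fold in every phase, Input untouched — on a
#' log-normal background with 20% multiplicative measurement noise.
#'
#' @param n_regions Total region count N (default 2000).
#' @param n_planted Planted region count (default 100).
#' @param background_meanlog,background_sdlog Log-normal background
#'   parameters for the per-region bin sums (defaults log(100) and 0.5:
#'   positive, right-skewed signal of realistic magnitude).
#' @param k27_effect Multiplicative H3K27ac elevation in interphase and
#'   anaphase/telophase (default 4).
#' @param k27_dip Multiplicative H3K27ac depression in prometaphase
#'   (default 0.5).
#' @param me_effect Multiplicative H3K4me1/H3K4me3 elevation in all phases
#'   (default 4).
#' @param noise_cv Coefficient of variation of the multiplicative
#'   replicate/cell-line noise (default 0.2).
#' @param bin_size Region width in bp used when writing coverage files
#'   (default 25000).
#' @param seed Random seed fixing the full output (default 1).
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_regions = 2000L, n_planted = 100L,
                       background_meanlog = log(100), background_sdlog = 0.5,
                       k27_effect = 4, k27_dip = 0.5, me_effect = 4,
                       noise_cv = 0.2, bin_size = 25000L, seed = 1L) {
  cfg <- list(n_regions = as.integer(n_regions),
              n_planted = as.integer(n_planted),
              background_meanlog = background_meanlog,
              background_sdlog = background_sdlog,
              k27_effect = k27_effect, k27_dip = k27_dip,
              me_effect = me_effect, noise_cv = noise_cv,
              bin_size = as.integer(bin_size), seed = as.integer(seed))
  if (cfg$n_regions < 2L || cfg$n_planted < 1L ||
      cfg$n_planted >= cfg$n_regions)
    stop("need 0 < n_planted < n_regions", call. = FALSE)
  if (any(c(cfg$k27_effect, cfg$k27_dip, cfg$me_effect) <= 0))
    stop("effect multipliers must be positive", call. = FALSE)
  if (cfg$noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  if (cfg$background_sdlog <= 0) stop("background_sdlog must be positive",
                                      call. = FALSE)
  structure(cfg, class = "sim_config")
}

#' Simulate a modification tensor with planted bookmark regions
#'
#' Background values are independent log-normal draws per tensor cell.
#' A random subset of regions is planted with the reactivation/bookmark
#' pattern (see [sim_config()]); planting is identical across cell lines and
#' replicates because a universal bookmark should appear in both cell lines
#' and every replicate.  Finally every cell is multiplied by mean-1
#' log-normal noise with the configured coefficient of variation.
#'
#' @param cfg A `sim_config`.
#' @return List with `tensor` (unnormalized `mod_tensor`) and `planted`
#'   (sorted integer indices of the planted regions).
#' @export
simulate_tensor <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_regions
  planted <- sort(sample.int(n, cfg$n_planted))
  x <- array(stats::rlnorm(n * 48, cfg$background_meanlog,
                           cfg$background_sdlog),
             dim = c(n, 2, 4, 3, 2))
  x[planted, , 1, c(1, 3), ] <- x[planted, , 1, c(1, 3), ] * cfg$k27_effect
  x[planted, , 1, 2, ]       <- x[planted, , 1, 2, ] * cfg$k27_dip
  x[planted, , 2:3, , ]      <- x[planted, , 2:3, , ] * cfg$me_effect
  if (cfg$noise_cv > 0) {
    s2 <- log(1 + cfg$noise_cv^2)
    x <- x * stats::rlnorm(length(x), -s2 / 2, sqrt(s2))
  }
  list(tensor = mod_tensor(x, normalized = FALSE), planted = planted)
}

#' Write simulated data as coverage files on a toy genome
#'
#' Lays the simulated regions onto the given chromosomes (a single
#' chromosome of exactly N x bin_size bp by default) and writes one bedGraph
#' file per condition whose per-bin sums reproduce the simulated tensor
#' values exactly (each bin holds a constant per-base value of
#' tensor value / bin width).  Also writes the chrom.sizes table, a manifest
#' TSV consumable by [load_manifest()], and a truth BED of the planted
#' regions.  Output is byte-identical across runs with the same
#' configuration.
#'
#' @param cfg A `sim_config`.
#' @param dir Output directory (created if absent).
#' @param chrom_sizes Optional named vector of chromosome lengths; must tile
#'   into at least `n_regions` bins.
#' @return List with `dir`, `manifest`, `chrom_sizes`, `truth` (file paths),
#'   `tensor`, `planted` and `regions` (the `region_index` the tensor rows
#'   occupy).
#' @export
simulate_coverage <- function(cfg, dir, chrom_sizes = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(chrom_sizes))
    chrom_sizes <- c(chrSim = cfg$n_regions * cfg$bin_size)
  regions <- make_regions(chrom_sizes, cfg$bin_size)
  if (nrow(regions) < cfg$n_regions)
    stop(sprintf("chromosomes tile into %d bins; %d regions requested",
                 nrow(regions), cfg$n_regions), call. = FALSE)
  sim <- simulate_tensor(cfg)
  used <- regions[seq_len(cfg$n_regions), , drop = FALSE]
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  sizes_path <- file.path(dir, "genome.chrom.sizes")
  writeLines(sprintf("%s\t%d", names(chrom_sizes),
                     as.integer(chrom_sizes)), sizes_path)

  grid <- condition_grid()
  files <- sprintf("%s_%s_%s_rep%s.bedGraph", grid$cell_line, grid$mark,
                   grid$phase, grid$replicate)
  width <- used$end - used$start
  a <- unclass(sim$tensor)
  j <- match(grid$cell_line, .tdfe_axes$cell_line)
  k <- match(grid$mark, .tdfe_axes$mark)
  m <- match(grid$phase, .tdfe_axes$phase)
  s <- match(grid$replicate, .tdfe_axes$replicate)
  for (f in seq_len(nrow(grid))) {
    v <- a[, j[f], k[f], m[f], s[f]] / width
    writeLines(sprintf("%s\t%d\t%d\t%.17g", used$chrom, used$start,
                       used$end, v),
               file.path(dir, files[f]))
  }

  manifest_path <- file.path(dir, "manifest.tsv")
  utils::write.table(cbind(path = files, grid), manifest_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)

  truth_path <- file.path(dir, "truth.bed")
  tr <- used[sim$planted, , drop = FALSE]
  writeLines(sprintf("%s\t%d\t%d", tr$chrom, tr$start, tr$end), truth_path)

  regions_attr <- structure(used, bin_size = cfg$bin_size,
                            class = c("region_index", "data.frame"))
  list(dir = dir, manifest = manifest_path, chrom_sizes = sizes_path,
       truth = truth_path, tensor = sim$tensor, planted = sim$planted,
       regions = regions_attr)
}
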