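# Genome binning: fixed-width tiles and per-region signal sums.
# Coordinates throughout are 0-based, half-open (BED convention).

#' Tile a genome into fixed-width regions
#'
#' Divides every chromosome into consecutive `bin_size`-bp regions anchored
#' at position 0.  The last region of each chromosome may be shorter when the
#' chromosome length is not a multiple of `bin_size`; short terminal bins are
#' kept.
#'
#' @param chrom_sizes Named numeric vector (or 2-column data frame of
#'   chromosome, length) of chromosome lengths in bp.  Chromosome order is
#'   taken as given.
#' @param bin_size Region width in bp (default 25000).
#' @return A `region_index`: data frame with columns `chrom`, `start`, `end`
#'   (0-based half-open), `bin_size` attribute, sorted by (chromosome order
#'   given, start).
#' @examples
#' make_regions(c(chr1 = 60000), 25000)
#' @export
make_regions <- function(chrom_sizes, bin_size = 25000L) {
  if (is.data.frame(chrom_sizes)) {
    stopifnot(ncol(chrom_sizes) >= 2)
    cs <- as.numeric(chrom_sizes[[2]])
    names(cs) <- as.character(chrom_sizes[[1]])
    chrom_sizes <- cs
  }
  if (length(chrom_sizes) == 0)
    stop("empty chromosome sizes", call. = FALSE)
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes))))
    stop("chromosome sizes must be named", call. = FALSE)
  if (any(!is.finite(chrom_sizes)) || any(chrom_sizes <= 0))
    stop("chromosome lengths must be positive", call. = FALSE)
  if (!is.finite(bin_size) || bin_size <= 0)
    stop("bin_size must be positive", call. = FALSE)
  bin_size <- as.integer(bin_size)
  pieces <- lapply(seq_along(chrom_sizes), function(i) {
    len <- chrom_sizes[[i]]
    starts <- seq.int(0L, len - 1L, by = bin_size)
    data.frame(chrom = names(chrom_sizes)[i],
               start = starts,
               end   = pmin(starts + bin_size, len),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  structure(out, bin_size = bin_size,
            class = c("region_index", "data.frame"))
}

#' Read a UCSC-style chrom.sizes file
#'
#' @param path Two-column TSV: chromosome name, length in bp.
#' @return Named numeric vector of lengths, in file order.
#' @export
read_chrom_sizes <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "length"))
  stats::setNames(as.numeric(tab$length), tab$chrom)
}

# region_index -> GRanges (1-based closed, as GenomicRanges expects)
.regions_gr <- function(regions) {
  GenomicRanges::GRanges(regions$chrom,
                         IRanges::IRanges(regions$start + 1L, regions$end))
}

#' Read a coverage track (bedGraph or bigWig)
#'
#' @param path File path; format is guessed from the extension unless given.
#' @param format One of "auto", "bedGraph", "bigWig".
#' @param label Optional named list/vector with elements cell_line, mark,
#'   phase, replicate, attached as the track label.
#' @return Data frame with columns `chrom`, `start`, `end`, `value`
#'   (0-based half-open intervals), `label` attribute.
#' @export
read_coverage <- function(path, format = c("auto", "bedGraph", "bigWig"),
                          label = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("bw", "bigwig")) "bigWig" else "bedGraph"
  }
  gr <- if (format == "bigWig") rtracklayer::import(path, format = "BigWig")
        else rtracklayer::import(path, format = "bedGraph")
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end   = GenomicRanges::end(gr),
    value = as.numeric(gr$score),
    stringsAsFactors = FALSE)
  attr(out, "label") <- label
  out
}

#' Sum coverage signal over genome regions
#'
#' Each region's value is the total per-base mass of the track within it: an
#' interval contributes its value times the number of overlapping bases, so
#' an interval straddling a region boundary is split proportionally.  Regions
#' with no coverage get 0.
#'
#' @param track Coverage data frame (`chrom`, `start`, `end`, `value`;
#'   0-based half-open), e.g. from [read_coverage()].  Intervals within a
#'   chromosome must not overlap.
#' @param regions A `region_index` from [make_regions()].
#' @return Numeric vector of length `nrow(regions)`; `label` attribute is
#'   propagated from the track.
#' @export
bin_signal <- function(track, regions) {
  stopifnot(is.data.frame(regions))
  n <- nrow(regions)
  if (is.null(track) || nrow(track) == 0) {
    out <- numeric(n)
    attr(out, "label") <- attr(track, "label")
    return(out)
  }
  need <- c("chrom", "start", "end", "value")
  if (!all(need %in% names(track)))
    stop("track must have columns chrom, start, end, value", call. = FALSE)
  if (any(!is.finite(track$value)))
    stop("track values must be finite", call. = FALSE)
  if (any(track$start >= track$end))
    stop("track intervals must have start < end", call. = FALSE)
  extra <- setdiff(unique(track$chrom), unique(regions$chrom))
  if (length(extra))
    stop(sprintf("track chromosome(s) not in the region index: %s",
                 paste(extra, collapse = ", ")), call. = FALSE)
  chrom_len <- tapply(regions$end, regions$chrom, max)
  over <- track$end > chrom_len[track$chrom]
  if (any(over))
    stop(sprintf(
      "interval(s) extend beyond chromosome length, e.g. %s:%d-%d (length %d)",
      track$chrom[over][1], track$start[over][1], track$end[over][1],
      chrom_len[track$chrom[over][1]]), call. = FALSE)
  ord <- order(track$chrom, track$start)
  tr <- track[ord, ]
  same <- tr$chrom[-1] == tr$chrom[-nrow(tr)]
  if (any(same & tr$start[-1] < tr$end[-nrow(tr)]))
    stop("track intervals overlap within a chromosome", call. = FALSE)
  q <- GenomicRanges::GRanges(tr$chrom,
                              IRanges::IRanges(tr$start + 1L, tr$end))
  s <- .regions_gr(regions)
  hits <- GenomicRanges::findOverlaps(q, s)
  out <- numeric(n)
  if (length(hits)) {
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    w <- GenomicRanges::width(IRanges::pintersect(
      GenomicRanges::ranges(q)[qi], GenomicRanges::ranges(s)[si]))
    contrib <- tr$value[qi] * w
    agg <- rowsum(contrib, group = si)
    out[as.integer(rownames(agg))] <- agg[, 1]
  }
  attr(out, "label") <- attr(track, "label")
  out
}

#' Load and validate a track manifest
#'
#' The manifest is a TSV with header columns `path`, `cell_line`, `mark`,
#' `phase`, `replicate` assigning each coverage file to one experimental
#' condition.  Exactly one file per combination of the 2 x 4 x 3 x 2 levels
#' of [condition_levels()] is required (48 rows).
#'
#' @param path Manifest file path.  Relative `path` entries are resolved
#'   against the manifest's directory when the files are read.
#' @return Data frame of class `track_manifest` with a `dir` attribute.
#' @export
load_manifest <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("path", "cell_line", "mark", "phase", "replicate")
  miss <- setdiff(need, names(m))
  if (length(miss))
    stop(sprintf("manifest lacks column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  for (ax in need[-1]) {
    bad <- setdiff(unique(m[[ax]]), .tdfe_axes[[ax]])
    if (length(bad))
      stop(sprintf("unknown %s level(s) in manifest: %s", ax,
                   paste(bad, collapse = ", ")), call. = FALSE)
  }
  key <- paste(m$cell_line, m$mark, m$phase, m$replicate, sep = "/")
  dup <- unique(key[duplicated(key)])
  if (length(dup))
    stop(sprintf("duplicated manifest condition(s): %s",
                 paste(dup, collapse = "; ")), call. = FALSE)
  full <- condition_grid()
  full_key <- do.call(paste, c(full, sep = "/"))
  absent <- setdiff(full_key, key)
  if (length(absent))
    stop(sprintf("manifest is missing condition(s): %s",
                 paste(absent, collapse = "; ")), call. = FALSE)
  structure(m[, need], dir = dirname(path),
            class = c("track_manifest", "data.frame"))
}

#' Bin all tracks of a manifest
#'
#' Reads every coverage file listed in the manifest and sums its signal over
#' the region index.
#'
#' @param manifest A `track_manifest` from [load_manifest()].
#' @param regions A `region_index` from [make_regions()].
#' @return List with `values` (matrix, regions x 48) and `labels` (data frame
#'   of the condition labels per column), ready for [assemble_tensor()].
#' @export
bin_manifest <- function(manifest, regions) {
  stopifnot(inherits(manifest, "track_manifest"))
  base <- attr(manifest, "dir")
  vals <- matrix(NA_real_, nrow = nrow(regions), ncol = nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    p <- manifest$path[i]
    if (!file.exists(p) && !is.null(base)) p <- file.path(base, manifest$path[i])
    if (!file.exists(p))
      stop(sprintf("coverage file not found: %s", manifest$path[i]),
           call. = FALSE)
    vals[, i] <- bin_signal(read_coverage(p), regions)
  }
  list(values = vals,
       labels = manifest[, c("cell_line", "mark", "phase", "replicate")])
}

#' Write a binned track as TSV
#'
#' @param values Numeric vector aligned to `regions`.
#' @param regions A `region_index`.
#' @param path Output file.
#' @export
write_binned_track <- function(values, regions, path) {
  stopifnot(length(values) == nrow(regions))
  utils::write.table(
    data.frame(chrom = regions$chrom, start = regions$start,
               end = regions$end, value = values),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
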