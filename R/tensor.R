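# Five-mode tensor container and per-condition normalization.

.tdfe_axes <- list(
  cell_line = c("RPE1", "U2OS"),
  mark      = c("H3K27ac", "H3K4me1", "H3K4me3", "Input"),
  phase     = c("interphase", "prometaphase", "anaphase_telophase"),
  replicate = c("1", "2")
)

.tdfe_modes <- c("region", "cell_line", "mark", "phase", "replicate")

#' Experimental-condition axis levels
#'
#' The fixed level order of the four condition axes of the modification
#' tensor: cell line (RPE1, U2OS), mark (H3K27ac, H3K4me1, H3K4me3, Input),
#' cell-cycle phase (interphase, prometaphase, anaphase/telophase) and
#' replicate (1, 2).  The phase order matters downstream: prometaphase is the
#' middle level, so the reactivation pattern is "outer phases high, middle
#' low".
#'
#' @return Named list of character vectors, one per condition axis.
#' @export
condition_levels <- function() .tdfe_axes

# All 48 (cell_line, mark, phase, replicate) combinations, replicate fastest.
condition_grid <- function() {
  g <- expand.grid(replicate = .tdfe_axes$replicate,
                   phase     = .tdfe_axes$phase,
                   mark      = .tdfe_axes$mark,
                   cell_line = .tdfe_axes$cell_line,
                   stringsAsFactors = FALSE)
  g[, c("cell_line", "mark", "phase", "replicate")]
}

#' Construct a modification tensor
#'
#' Wraps a numeric array of dimension N x 2 x 4 x 3 x 2 (region, cell line,
#' mark, phase, replicate) as a `mod_tensor`, attaching axis labels, the
#' normalization flag and optionally the genomic region index the first axis
#' is aligned to.
#'
#' @param values Numeric 5-d array, regions on the first axis, condition axes
#'   in the order cell line, mark, phase, replicate with the level order of
#'   [condition_levels()].
#' @param normalized Logical; whether each condition slice is already centered
#'   to mean 0 and rescaled to sum of squares N.
#' @param regions Optional `region_index` (see [make_regions()]) of length N.
#' @return A `mod_tensor` object (a classed array).
#' @seealso [assemble_tensor()], [normalize_tensor()]
#' @export
mod_tensor <- function(values, normalized = FALSE, regions = NULL) {
  if (!is.array(values) || length(dim(values)) != 5L)
    stop("'values' must be a 5-dimensional array", call. = FALSE)
  d <- dim(values)
  want <- c(2L, 4L, 3L, 2L)
  if (!identical(d[-1], want))
    stop(sprintf("condition axes must have sizes 2x4x3x2, got %s",
                 paste(d[-1], collapse = "x")), call. = FALSE)
  if (!all(is.finite(values)))
    stop("tensor values must all be finite", call. = FALSE)
  if (!is.null(regions) && nrow(regions) != d[1])
    stop("'regions' length does not match the region axis", call. = FALSE)
  dimnames(values) <- c(list(NULL), unname(.tdfe_axes))
  structure(values,
            normalized = isTRUE(normalized),
            regions = regions,
            class = "mod_tensor")
}

#' @export
print.mod_tensor <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("Modification tensor: %d regions x %d cell lines x %d marks x %d phases x %d replicates\n",
              d[1], d[2], d[3], d[4], d[5]))
  cat(sprintf("  normalized: %s\n", attr(x, "normalized")))
  if (!is.null(attr(x, "regions")))
    cat(sprintf("  region index: %d bins of %d bp\n",
                nrow(attr(x, "regions")), attr(attr(x, "regions"), "bin_size")))
  invisible(x)
}

#' Assemble binned tracks into the modification tensor
#'
#' Places 48 binned signal vectors into the five-mode tensor by their
#' condition labels, so the result does not depend on input order.
#'
#' @param values Numeric matrix, one column per track (N regions x 48).
#' @param labels Data frame with one row per column of `values` and columns
#'   `cell_line`, `mark`, `phase`, `replicate` naming that track's condition.
#' @param regions Optional `region_index` the rows are aligned to.
#' @return Unnormalized `mod_tensor`.
#' @export
assemble_tensor <- function(values, labels, regions = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("'values' must be numeric", call. = FALSE)
  need <- c("cell_line", "mark", "phase", "replicate")
  if (!all(need %in% names(labels)))
    stop("'labels' must have columns cell_line, mark, phase, replicate",
         call. = FALSE)
  if (nrow(labels) != ncol(values))
    stop("one label row per track column is required", call. = FALSE)
  lab <- data.frame(lapply(labels[need], as.character),
                    stringsAsFactors = FALSE)
  for (ax in need) {
    bad <- setdiff(unique(lab[[ax]]), .tdfe_axes[[ax]])
    if (length(bad))
      stop(sprintf("unknown %s level(s): %s", ax, paste(bad, collapse = ", ")),
           call. = FALSE)
  }
  key <- do.call(paste, c(lab, sep = "/"))
  full <- condition_grid()
  full_key <- do.call(paste, c(full, sep = "/"))
  dup <- key[duplicated(key)]
  if (length(dup))
    stop(sprintf("duplicated condition label(s): %s",
                 paste(unique(dup), collapse = "; ")), call. = FALSE)
  missing <- setdiff(full_key, key)
  if (length(missing))
    stop(sprintf("missing condition combination(s): %s",
                 paste(missing, collapse = "; ")), call. = FALSE)
  n <- nrow(values)
  x <- array(NA_real_, dim = c(n, 2, 4, 3, 2))
  j <- match(lab$cell_line, .tdfe_axes$cell_line)
  k <- match(lab$mark,      .tdfe_axes$mark)
  m <- match(lab$phase,     .tdfe_axes$phase)
  s <- match(lab$replicate, .tdfe_axes$replicate)
  for (col in seq_len(ncol(values)))
    x[, j[col], k[col], m[col], s[col]] <- values[, col]
  mod_tensor(x, normalized = FALSE, regions = regions)
}

#' Center and scale each condition slice of the tensor
#'
#' For every (cell line, mark, phase, replicate) combination the region
#' vector is centered to mean 0 and rescaled so that its sum of squares
#' equals N, i.e. `x <- (x - mean(x)) * sqrt(N / sum((x - mean(x))^2))`.
#' This puts all 48 condition slices on a common scale before the
#' decomposition; it is idempotent and invariant to per-slice affine maps
#' with positive slope.
#'
#' @param x A `mod_tensor`.
#' @return The normalized `mod_tensor` (normalized flag set).
#' @export
normalize_tensor <- function(x) {
  stopifnot(inherits(x, "mod_tensor"))
  a <- unclass(x)
  d <- dim(a)
  n <- d[1]
  if (n < 2L) stop("need at least 2 regions to normalize", call. = FALSE)
  for (j in seq_len(d[2])) for (k in seq_len(d[3]))
    for (m in seq_len(d[4])) for (s in seq_len(d[5])) {
      v <- a[, j, k, m, s]
      v <- v - mean(v)
      ss <- sum(v^2)
      if (ss == 0)
        stop(sprintf(
          "constant signal for condition (%s, %s, %s, replicate %s); cannot normalize",
          .tdfe_axes$cell_line[j], .tdfe_axes$mark[k],
          .tdfe_axes$phase[m], .tdfe_axes$replicate[s]), call. = FALSE)
      a[, j, k, m, s] <- v * sqrt(n / ss)
    }
  mod_tensor(a, normalized = TRUE, regions = attr(x, "regions"))
}

#' Export a tensor in long format
#'
#' @param x A `mod_tensor`.
#' @return Data frame with columns region, cell_line, mark, phase, replicate,
#'   value (region as 1-based index).
#' @export
tensor_to_long <- function(x) {
  stopifnot(inherits(x, "mod_tensor"))
  d <- dim(x)
  g <- expand.grid(region = seq_len(d[1]),
                   cell_line = .tdfe_axes$cell_line,
                   mark = .tdfe_axes$mark,
                   phase = .tdfe_axes$phase,
                   replicate = .tdfe_axes$replicate,
                   stringsAsFactors = FALSE)
  g$value <- as.vector(unclass(x))
  g
}
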