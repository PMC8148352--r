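# Higher-order SVD: mode unfoldings, per-mode SVD, core tensor.

.mode_index <- function(mode) {
  if (is.character(mode)) {
    i <- match(mode, .tdfe_modes)
    if (is.na(i)) stop(sprintf("unknown mode '%s'; use one of %s", mode,
                               paste(.tdfe_modes, collapse = ", ")),
                       call. = FALSE)
    return(i)
  }
  i <- as.integer(mode)
  if (is.na(i) || i < 1L || i > 5L)
    stop("mode must be in 1..5 or a mode name", call. = FALSE)
  i
}

#' Unfold (matricize) the tensor along one mode
#'
#' Rows are the entries of the chosen mode; columns run over all level
#' combinations of the remaining modes, in tensor-axis order with the
#' earliest remaining axis varying fastest (column-major).  This ordering is
#' fixed and [refold()] inverts it exactly; any consistent choice yields the
#' same singular vectors.
#'
#' @param x 5-d array or `mod_tensor`.
#' @param mode Mode name ("region", "cell_line", "mark", "phase",
#'   "replicate") or index 1-5.
#' @return Matrix of size (mode length) x (product of the other mode
#'   lengths).
#' @export
unfold <- function(x, mode) {
  i <- .mode_index(mode)
  a <- unclass(x)
  attributes(a) <- list(dim = dim(a))
  d <- dim(a)
  others <- setdiff(seq_len(5L), i)
  m <- aperm(a, c(i, others))
  dim(m) <- c(d[i], prod(d[others]))
  m
}

#' Refold an unfolded matrix back into a tensor
#'
#' @param m Matrix produced with the [unfold()] column convention.
#' @param mode The mode it was unfolded along.
#' @param dims The full 5-vector of tensor dimensions (with `dims[mode] ==
#'   nrow(m)`).
#' @return 5-d array.
#' @export
refold <- function(m, mode, dims) {
  i <- .mode_index(mode)
  others <- setdiff(seq_len(5L), i)
  a <- array(m, dim = c(dims[i], dims[others]))
  aperm(a, order(c(i, others)))
}

# mode-i product: contract mode i of array a with t(u) (u: old_len x new_len)
.ttm <- function(a, u, i) {
  d <- dim(a)
  m <- crossprod(u, unfold(a, i))
  d[i] <- ncol(u)
  refold(m, i, d)
}

#' Higher-order singular value decomposition
#'
#' Computes, for each of the five modes, the left singular vectors of that
#' mode's unfolding, and the core tensor obtained by contracting the data
#' with all five factor matrices.  The condition modes keep all their
#' components (2, 4, 3, 2); the region mode keeps `r` components, by default
#' `min(N, 48)` — with 48 condition columns the unfolding has rank at most
#' 48, so nothing is lost (all core entries beyond component 48 are zero).
#'
#' @param x `mod_tensor` (normalization recommended but not enforced) or 5-d
#'   array.
#' @param r Number of region-mode components to retain (default
#'   `min(N, 48)`; may be set larger, up to N, to inspect the zero tail).
#' @return Object of class `hosvd`: list with `factors` (named list of
#'   orthonormal-column matrices `region` (N x r), `cell_line` (2 x 2),
#'   `mark` (4 x 4), `phase` (3 x 3), `replicate` (2 x 2); column l is
#'   component l), `core` (array 2 x 4 x 3 x 2 x r indexed by one component
#'   per condition mode plus the region component last), `sv` (per-mode
#'   singular values of the unfoldings), and `dims`.
#' @export
hosvd <- function(x, r = NULL) {
  a <- unclass(x)
  attributes(a) <- list(dim = dim(a))
  if (!all(is.finite(a))) stop("tensor has non-finite values", call. = FALSE)
  d <- dim(a)
  n <- d[1]
  rmax <- min(n, prod(d[-1]))
  if (is.null(r)) r <- rmax
  r <- as.integer(min(r, n))
  if (r < 1L) stop("r must be at least 1", call. = FALSE)

  factors <- vector("list", 5L)
  sv <- vector("list", 5L)
  names(factors) <- names(sv) <- .tdfe_modes
  for (i in seq_len(5L)) {
    m <- unfold(a, i)
    nu <- if (i == 1L) r else d[i]
    s <- svd(m, nu = nu, nv = 0)
    factors[[i]] <- s$u
    sv[[i]] <- s$d[seq_len(min(length(s$d), nu))]
  }

  core <- a
  for (i in seq_len(5L)) core <- .ttm(core, factors[[i]], i)
  # core axes now (region component, j, k, m, s); report condition modes
  # first and the region component last, matching G(l1, l2, l3, l4, l5)
  core <- aperm(core, c(2L, 3L, 4L, 5L, 1L))

  structure(list(factors = factors, core = core, sv = sv, dims = d, r = r),
            class = "hosvd")
}

#' Reconstruct the tensor from an HOSVD
#'
#' Contracts the core tensor with all five factor matrices; with the full
#' complement of components this reproduces the input to numerical
#' precision.
#'
#' @param h An `hosvd` object.
#' @return 5-d array of the original dimensions.
#' @export
reconstruct <- function(h) {
  stopifnot(inherits(h, "hosvd"))
  a <- aperm(h$core, c(5L, 1L, 2L, 3L, 4L))  # region component first
  d <- dim(a)
  for (i in seq_len(5L)) {
    u <- h$factors[[i]]
    m <- u %*% unfold(a, i)
    d[i] <- nrow(u)
    a <- refold(m, i, d)
  }
  a
}

# core axis corresponding to each factor
.core_axis <- c(region = 5L, cell_line = 1L, mark = 2L, phase = 3L,
                replicate = 4L)

#' Fix the sign indeterminacy of the factor columns
#'
#' SVD columns are determined only up to sign.  This flips every factor
#' column so that its maximum-magnitude entry (first such entry on ties) is
#' positive, applying the compensating flip to the matching core slice so
#' the reconstruction is unchanged.  Idempotent.
#'
#' @param h An `hosvd` object.
#' @return The canonicalized `hosvd` object.
#' @export
sign_canonicalize <- function(h) {
  stopifnot(inherits(h, "hosvd"))
  core <- h$core
  for (nm in .tdfe_modes) {
    u <- h$factors[[nm]]
    ax <- .core_axis[[nm]]
    for (l in seq_len(ncol(u))) {
      i0 <- which.max(abs(u[, l]))
      if (u[i0, l] < 0) {
        u[, l] <- -u[, l]
        sel <- slice.index(core, ax) == l
        core[sel] <- -core[sel]
      }
    }
    h$factors[[nm]] <- u
  }
  h$core <- core
  h
}

#' @export
print.hosvd <- function(x, ...) {
  cat(sprintf("HOSVD of a %s tensor\n", paste(x$dims, collapse = " x ")))
  cat(sprintf("  region components retained: %d\n", x$r))
  cat(sprintf("  core: %s\n", paste(dim(x$core), collapse = " x ")))
  invisible(x)
}

#' Export factor matrices and singular values as TSV
#'
#' Writes one `<mode>_factor.tsv` (entries x components) and one
#' `<mode>_singular_values.tsv` per mode into `dir`.
#'
#' @param h An `hosvd` object.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the directory.
#' @export
export_hosvd <- function(h, dir) {
  stopifnot(inherits(h, "hosvd"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in .tdfe_modes) {
    u <- h$factors[[nm]]
    colnames(u) <- paste0("component_", seq_len(ncol(u)))
    utils::write.table(u, file.path(dir, paste0(nm, "_factor.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(component = seq_along(h$sv[[nm]]), lambda = h$sv[[nm]]),
      file.path(dir, paste0(nm, "_singular_values.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
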