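# Interpretation of the condition-mode factor columns and scoring of the
# region-mode components against the core tensor.
#
# All pattern tests are sign-robust: a column and its negation are treated
# identically, so the SVD sign indeterminacy cannot change a selection.

# Sign-robust "constant" test for one column: after flipping so the mean is
# positive, all entries share one sign and the maximum relative deviation
# from the column mean is at most tol.
.is_constant_column <- function(v, tol) {
  if (mean(v) < 0) v <- -v
  m <- mean(v)
  if (m <= 0) return(FALSE)
  if (any(v <= 0)) return(FALSE)
  max(abs(v - m)) / m <= tol
}

#' Find the component that is constant across a mode's levels
#'
#' Scans the factor columns in order and returns the first whose entries are
#' all of one sign with maximum relative deviation from the column mean at
#' most `tol` (evaluated after a global sign flip if needed).  Used to find
#' the cell-line and replicate components carrying no dependence on those
#' axes.
#'
#' @param factor Factor matrix (levels x components, orthonormal columns).
#' @param tol Relative-deviation tolerance (default 0.1).
#' @return 1-based component index.
#' @export
find_constant_component <- function(factor, tol = 0.1) {
  stopifnot(is.matrix(factor), tol > 0)
  for (l in seq_len(ncol(factor)))
    if (.is_constant_column(factor[, l], tol)) return(l)
  stop(paste0(
    "no factor column is constant across levels within tolerance ", tol,
    "; inspect the factor matrix and supply the component index manually ",
    "(components = list(...))"), call. = FALSE)
}

#' Find the phase component with a reactivation profile
#'
#' A reactivation profile is high in interphase and anaphase/telophase but
#' low in prometaphase: the interphase and anaphase/telophase entries share
#' one sign and the prometaphase entry takes the opposite sign (tested
#' sign-robustly).  Among matching columns the one with the largest contrast
#' `|u[prometaphase] - (u[interphase] + u[ana/telophase]) / 2|` is returned
#' (first on ties).
#'
#' @param factor 3 x 3 phase factor matrix, rows ordered (interphase,
#'   prometaphase, anaphase/telophase).
#' @return 1-based component index.
#' @export
find_reactivation_component <- function(factor) {
  stopifnot(is.matrix(factor), nrow(factor) == 3L)
  best <- NA_integer_
  best_contrast <- -Inf
  for (l in seq_len(ncol(factor))) {
    v <- factor[, l]
    s <- sign(v)
    if (s[1] != 0 && s[1] == s[3] && s[2] == -s[1]) {
      contrast <- abs(v[2] - (v[1] + v[3]) / 2)
      if (contrast > best_contrast) {
        best <- l
        best_contrast <- contrast
      }
    }
  }
  if (is.na(best))
    stop(paste0(
      "no phase component matches the reactivation pattern (interphase and ",
      "anaphase/telophase opposite in sign to prometaphase); supply the ",
      "component index manually (components = list(l3 = ...))"),
      call. = FALSE)
  best
}

#' Find the mark components that distinguish modifications from Input
#'
#' Excludes every factor column that is constant across the four marks
#' (same sign-robust test as [find_constant_component()]): such a column
#' cannot separate the histone modifications from the no-antibody Input
#' control.  The remaining component indices are returned.
#'
#' @param factor 4 x 4 mark factor matrix.
#' @param tol Relative-deviation tolerance for "constant" (default 0.1).
#' @return Integer vector of retained 1-based component indices.
#' @export
find_mark_components <- function(factor, tol = 0.1) {
  stopifnot(is.matrix(factor))
  const <- vapply(seq_len(ncol(factor)),
                  function(l) .is_constant_column(factor[, l], tol),
                  logical(1))
  keep <- which(!const)
  if (!length(keep))
    stop("every mark component is constant across marks; cannot proceed",
         call. = FALSE)
  keep
}

#' Score region components against the chosen condition components
#'
#' For each region component l5, the score is the sum over the retained mark
#' components of `|G(l1, l2, l3, l4, l5)|^alpha`, where G is the core
#' tensor.  Region components with large scores co-vary with the chosen
#' cell-line-invariant, replicate-invariant, reactivation-patterned
#' combination.
#'
#' @param core Core tensor from [hosvd()] (2 x 4 x 3 x 2 x r).
#' @param l1,l3,l4 Chosen cell-line, phase and replicate component indices.
#' @param l2_set Retained mark component indices (non-empty).
#' @param alpha Exponent (>= 1; default 2).
#' @return Numeric score vector over region components.
#' @export
score_l5 <- function(core, l1, l2_set, l3, l4, alpha = 2) {
  stopifnot(length(dim(core)) == 5L, alpha >= 1)
  if (!length(l2_set)) stop("l2_set must be non-empty", call. = FALSE)
  d <- dim(core)
  if (l1 > d[1] || any(l2_set > d[2]) || l3 > d[3] || l4 > d[4])
    stop("component index out of core bounds", call. = FALSE)
  g <- core[l1, l2_set, l3, l4, , drop = FALSE]
  g <- matrix(g, nrow = length(l2_set), ncol = d[5])
  colSums(abs(g)^alpha)
}

#' Select the region component with the largest score
#'
#' @param scores Numeric score vector from [score_l5()].
#' @return 1-based index of the maximum (smallest index on ties).
#' @export
select_l5 <- function(scores) {
  if (!length(scores)) stop("empty score vector", call. = FALSE)
  which.max(scores)
}
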