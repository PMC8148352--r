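# Region significance under a Gaussian null: chi-squared P-values on the
# region-mode singular vector, Benjamini-Hochberg correction, selection.

#' Chi-squared P-values for the region component
#'
#' Under the null that the region-component entries u_i are Gaussian noise,
#' `(u_i / sigma)^2` follows a chi-squared distribution with 1 degree of
#' freedom, where `sigma = sqrt(mean(u^2))` is the root-mean-square of the
#' component (its mean is essentially zero by construction, so RMS and
#' standard deviation coincide up to O(1/N)).  The P-value is the upper tail
#' at `(u_i / sigma)^2`, equivalently the two-sided normal tail of
#' `|u_i| / sigma`.
#'
#' @param u Region component vector (length >= 2, not all zero).
#' @return List with `sigma` and `p` (raw P-values, same length as `u`).
#' @export
region_pvalues <- function(u) {
  u <- as.numeric(u)
  if (length(u) < 2L) stop("u must have at least 2 entries", call. = FALSE)
  if (all(u == 0)) stop("u is identically zero", call. = FALSE)
  sigma <- sqrt(mean(u^2))
  p <- stats::pchisq((u / sigma)^2, df = 1, lower.tail = FALSE)
  list(sigma = sigma, p = p)
}

#' Benjamini-Hochberg adjusted P-values
#'
#' Standard step-up adjustment: with raw P-values sorted ascending,
#' `q_(i) = min_{k >= i} (p_(k) * m / k)` capped at 1, mapped back to the
#' original order.
#'
#' @param p Numeric vector of raw P-values in `[0, 1]`.
#' @return Adjusted P-values, same length and order.
#' @export
bh_adjust <- function(p) {
  p <- as.numeric(p)
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("P-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Select regions below an adjusted-P threshold
#'
#' @param p_adj Adjusted P-values aligned to the region index.
#' @param threshold Selection threshold (default 0.01); strictly less-than.
#' @return Logical selection mask.
#' @export
select_regions <- function(p_adj, threshold = 0.01) {
  stopifnot(is.numeric(p_adj), threshold > 0)
  p_adj < threshold
}
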