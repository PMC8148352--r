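# The fitting function: tensor -> HOSVD -> component interpretation ->
# region P-values -> selection, returned as one classed object.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Tensor-decomposition-based unsupervised feature extraction
#'
#' Fits the full region-selection procedure to a modification tensor: the
#' tensor is normalized per condition slice (if not already), decomposed by
#' HOSVD with sign-canonicalized factors, and the condition-mode components
#' are interpreted — the cell-line and replicate components constant across
#' their levels (no dependence on either), the phase component with the
#' reactivation profile (interphase and anaphase/telophase opposite in sign
#' to prometaphase), and the mark components that distinguish the histone
#' modifications from the Input control.  Region components are then scored
#' by the magnitude of the core-tensor entries coupling them to that
#' combination, the top-scoring region component u is taken as the per-region
#' association score, and each region receives a chi-squared P-value for
#' `(u_i / sigma)^2` under a Gaussian null, Benjamini-Hochberg corrected;
#' regions with adjusted P below `threshold` are selected.
#'
#' Scores are computed for exponents alpha = 1, 2, 3; if their maximizing
#' region components disagree a warning is issued and the `alpha` argument's
#' choice is used.
#'
#' @param x A `mod_tensor` (see [assemble_tensor()], [simulate_tensor()]).
#' @param constant_tol Relative-deviation tolerance for the "constant across
#'   levels" component tests (default 0.1).
#' @param alpha Exponent used for the core score (default 2).
#' @param threshold Adjusted-P selection threshold (default 0.01, strict).
#' @param components Optional named list of manual overrides `l1` (cell
#'   line), `l2` (mark component set), `l3` (phase), `l4` (replicate), `l5`
#'   (region component); any supplied entry bypasses the corresponding
#'   automatic test.
#' @param r Region-mode components to retain in the HOSVD (default
#'   `min(N, 48)`).
#' @return Object of class `tdfe` with elements `hosvd` (the canonicalized
#'   decomposition), `components` (chosen indices, the alpha sweep score
#'   matrix), `selection` (data frame: region, u, p, p_adj, selected — plus
#'   coordinates when the tensor carries a region index), `sigma`,
#'   `threshold`, `n_selected` and the matched call.
#' @examples
#' sim <- simulate_tensor(sim_config(n_regions = 300, n_planted = 20, seed = 1))
#' fit <- tdfe(sim$tensor)
#' fit
#' @export
tdfe <- function(x, constant_tol = 0.1, alpha = 2, threshold = 0.01,
                 components = list(), r = NULL) {
  stopifnot(inherits(x, "mod_tensor"))
  if (!isTRUE(attr(x, "normalized"))) x <- normalize_tensor(x)
  h <- sign_canonicalize(hosvd(x, r = r))

  l1 <- components$l1 %||% find_constant_component(h$factors$cell_line,
                                                   constant_tol)
  l4 <- components$l4 %||% find_constant_component(h$factors$replicate,
                                                   constant_tol)
  l3 <- components$l3 %||% find_reactivation_component(h$factors$phase)
  l2 <- components$l2 %||% find_mark_components(h$factors$mark, constant_tol)

  alphas <- sort(unique(c(1, 2, 3, alpha)))
  scores <- vapply(alphas, function(a) score_l5(h$core, l1, l2, l3, l4, a),
                   numeric(dim(h$core)[5]))
  colnames(scores) <- paste0("alpha_", alphas)
  argmax <- apply(scores, 2L, select_l5)
  if (!is.null(components$l5)) {
    l5 <- as.integer(components$l5)
  } else {
    if (length(unique(argmax)) > 1L)
      warning(sprintf(
        "score maximizer differs across alpha (%s); using alpha = %g",
        paste(sprintf("alpha %g -> %d", alphas, argmax), collapse = ", "),
        alpha), call. = FALSE)
    l5 <- unname(argmax[match(alpha, alphas)])
  }

  u <- h$factors$region[, l5]
  pv <- region_pvalues(u)
  p_adj <- bh_adjust(pv$p)
  selected <- select_regions(p_adj, threshold)

  sel <- data.frame(region = seq_along(u), u = u, p = pv$p, p_adj = p_adj,
                    selected = selected)
  regions <- attr(x, "regions")
  if (!is.null(regions))
    sel <- cbind(regions[, c("chrom", "start", "end")], sel)

  structure(list(
    hosvd = h,
    components = list(l1 = l1, l2 = l2, l3 = l3, l4 = l4, l5 = l5,
                      alpha = alpha, alphas = alphas, scores = scores,
                      argmax = argmax),
    selection = sel,
    sigma = pv$sigma,
    threshold = threshold,
    constant_tol = constant_tol,
    n = length(u),
    n_selected = sum(selected),
    regions = regions,
    call = match.call()),
    class = "tdfe")
}

#' @export
print.tdfe <- function(x, ...) {
  cat("Tensor-decomposition-based unsupervised feature extraction\n\n")
  cat("Call: ", deparse(x$call), "\n", sep = "")
  cmp <- x$components
  cat(sprintf("Components: cell line l1 = %d, marks l2 = {%s}, phase l3 = %d, replicate l4 = %d, region l5 = %d\n",
              cmp$l1, paste(cmp$l2, collapse = ","), cmp$l3, cmp$l4, cmp$l5))
  cat(sprintf("Regions: %d total, %d selected at adjusted P < %g\n",
              x$n, x$n_selected, x$threshold))
  invisible(x)
}

#' @export
summary.tdfe <- function(object, ...) {
  structure(list(fit = object), class = "summary.tdfe")
}

#' @export
print.summary.tdfe <- function(x, ...) {
  f <- x$fit
  print(f)
  cmp <- f$components
  cat(sprintf("\nsigma(u_l5) = %.4g\n", f$sigma))
  cat("\nScore maximizers over the alpha sweep:\n")
  print(stats::setNames(cmp$argmax, colnames(cmp$scores)))
  cat("\nPhase component (interphase, prometaphase, anaphase/telophase):\n")
  print(round(f$hosvd$factors$phase[, cmp$l3], 4))
  top <- f$selection[order(f$selection$p_adj), , drop = FALSE]
  cat("\nTop regions by adjusted P:\n")
  print(utils::head(top, 5), row.names = FALSE)
  invisible(x)
}

#' @export
coef.tdfe <- function(object, ...) {
  stats::setNames(object$selection$u, object$selection$region)
}

#' Diagnostic plots for a tdfe fit
#'
#' Four panels: the chosen phase component (reactivation profile), the
#' retained mark components, the region-component score profile on a log
#' scale, and the per-region scores with selected regions highlighted.
#'
#' @param x A `tdfe` object.
#' @param ... Passed to nothing; present for the generic.
#' @export
plot.tdfe <- function(x, ...) {
  cmp <- x$components
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2.5, 1))
  on.exit(graphics::par(op))
  ph <- x$hosvd$factors$phase[, cmp$l3]
  graphics::barplot(ph, names.arg = c("inter", "prometa", "ana/telo"),
                    main = sprintf("Phase component l3 = %d", cmp$l3),
                    ylab = "loading")
  mk <- x$hosvd$factors$mark[, cmp$l2, drop = FALSE]
  graphics::matplot(mk, type = "b", pch = 19, lty = 1, xaxt = "n",
                    xlab = "", ylab = "loading",
                    main = sprintf("Mark components {%s}",
                                   paste(cmp$l2, collapse = ",")))
  graphics::axis(1, at = 1:4, labels = .tdfe_axes$mark, las = 2, cex.axis = 0.8)
  sc <- cmp$scores[, match(cmp$alpha, cmp$alphas)]
  graphics::plot(seq_along(sc), sc, log = "y", type = "h",
                 xlab = "region component l5", ylab = "score",
                 main = sprintf("Core score (alpha = %g)", cmp$alpha))
  graphics::points(cmp$l5, sc[cmp$l5], col = 2, pch = 19)
  graphics::plot(x$selection$region, x$selection$u,
                 col = ifelse(x$selection$selected, 2, "grey50"),
                 pch = ".", cex = 2, xlab = "region", ylab = "u (l5)",
                 main = sprintf("%d selected regions", x$n_selected))
  invisible(x)
}

#' Write the region selection to disk
#'
#' Writes a TSV of all regions (coordinates when available, u, raw and
#' adjusted P, selection flag) and a BED file of the selected regions.
#'
#' @param fit A `tdfe` object fitted on a tensor carrying a region index
#'   (the BED is skipped, with a message, otherwise).
#' @param dir Output directory (created if absent).
#' @return Invisibly, the directory.
#' @export
export_selection <- function(fit, dir) {
  stopifnot(inherits(fit, "tdfe"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(fit$selection, file.path(dir, "regions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(fit$regions)) {
    sel <- fit$selection[fit$selection$selected, , drop = FALSE]
    utils::write.table(sel[, c("chrom", "start", "end")],
                       file.path(dir, "selected.bed"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  } else {
    message("no region index attached; selected.bed not written")
  }
  sc <- fit$components$scores
  utils::write.table(cbind(l5 = seq_len(nrow(sc)), sc),
                     file.path(dir, "scores.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
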