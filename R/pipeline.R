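# End-to-end convenience wrapper: coverage files -> selection on disk.

#' Run the full pipeline from coverage files
#'
#' Bins the 48 manifest tracks over fixed-width regions, assembles and
#' normalizes the tensor, fits [tdfe()], runs the six validation t-tests,
#' and (optionally) maps selected regions to gene symbols.  Artifacts are
#' written under `out_dir` when given: `regions.tsv`, `selected.bed`,
#' `scores.tsv`, `validation.tsv`, `gene_list.txt`.
#'
#' @param manifest_path Manifest TSV (see [load_manifest()]).
#' @param chrom_sizes_path chrom.sizes TSV.
#' @param bin_size Region width in bp (default 25000).
#' @param genes_path Optional gene annotation (BED/GTF) for symbol mapping.
#' @param out_dir Optional output directory.
#' @param ... Passed to [tdfe()] (e.g. `alpha`, `threshold`, `components`).
#' @return List with `fit` (the `tdfe` object), `validation` (the
#'   [reactivation_tests()] report), `genes` (symbols or NULL) and
#'   `regions`.
#' @export
run_pipeline <- function(manifest_path, chrom_sizes_path, bin_size = 25000L,
                         genes_path = NULL, out_dir = NULL, ...) {
  regions <- make_regions(read_chrom_sizes(chrom_sizes_path), bin_size)
  manifest <- load_manifest(manifest_path)
  binned <- bin_manifest(manifest, regions)
  x <- assemble_tensor(binned$values, binned$labels, regions = regions)
  x <- normalize_tensor(x)
  fit <- tdfe(x, ...)
  validation <- reactivation_tests(x, fit$selection$selected)
  genes <- NULL
  if (!is.null(genes_path)) {
    sel <- fit$selection[fit$selection$selected, c("chrom", "start", "end")]
    genes <- genes_in_regions(read_genes(genes_path), sel)
  }
  if (!is.null(out_dir)) {
    export_selection(fit, out_dir)
    write_reactivation_report(validation, file.path(out_dir, "validation.tsv"))
    if (!is.null(genes))
      export_gene_list(genes, file.path(out_dir, "gene_list.txt"))
  }
  list(fit = fit, validation = validation, genes = genes, regions = regions)
}
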