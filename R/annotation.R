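# Gene annotation of selected regions and the stepwise peak-overlap
# procedure.  All coordinates are 0-based half-open externally; conversion
# to the 1-based closed GenomicRanges convention happens at the boundary.

.df_gr <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(df$start + 1L, df$end))
}

.gr_df <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end   = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Read a gene annotation (BED or GTF)
#'
#' BED input must carry the gene symbol in the name (4th) column; GTF input
#' uses `gene` features (or all features if none are typed `gene`) and the
#' `gene_name` attribute.
#'
#' @param path Annotation file (.bed, .gtf or .gff).
#' @return Data frame with columns `symbol`, `chrom`, `start`, `end`,
#'   `strand` (0-based half-open).
#' @export
read_genes <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gtf", "gff", "gff3")) {
    gr <- rtracklayer::import(path)
    if ("type" %in% names(S4Vectors::mcols(gr)) &&
        any(gr$type == "gene")) gr <- gr[gr$type == "gene"]
    sym <- if ("gene_name" %in% names(S4Vectors::mcols(gr))) gr$gene_name
           else gr$gene_id
  } else {
    gr <- rtracklayer::import(path, format = "BED")
    sym <- gr$name
  }
  if (is.null(sym) || any(is.na(sym) | !nzchar(sym)))
    stop("annotation lacks gene symbols (BED name column / GTF gene_name)",
         call. = FALSE)
  out <- .gr_df(gr)
  out$symbol <- as.character(sym)
  out$strand <- as.character(GenomicRanges::strand(gr))
  out[, c("symbol", "chrom", "start", "end", "strand")]
}

#' Gene symbols overlapping the selected regions
#'
#' A symbol is reported iff its gene span overlaps any selected region by at
#' least 1 bp (strand ignored).  Symbols are deduplicated, keeping the order
#' of first appearance in the gene list.
#'
#' @param genes Gene data frame from [read_genes()] (columns `symbol`,
#'   `chrom`, `start`, `end`).
#' @param regions Data frame of the selected regions (`chrom`, `start`,
#'   `end`, 0-based half-open), e.g. the selected rows of a [tdfe()]
#'   selection.
#' @return Character vector of unique symbols.
#' @export
genes_in_regions <- function(genes, regions) {
  stopifnot(all(c("symbol", "chrom", "start", "end") %in% names(genes)))
  if (nrow(regions) == 0) return(character(0))
  shared <- intersect(unique(genes$chrom), unique(regions$chrom))
  if (!length(shared))
    stop(sprintf(
      "no chromosome names shared between annotation (e.g. %s) and regions (e.g. %s)",
      paste(utils::head(unique(genes$chrom), 3), collapse = ","),
      paste(utils::head(unique(regions$chrom), 3), collapse = ",")),
      call. = FALSE)
  hits <- GenomicRanges::findOverlaps(.df_gr(genes), .df_gr(regions))
  unique(genes$symbol[sort(unique(S4Vectors::queryHits(hits)))])
}

#' Read a peak-call interval file (BED 3+)
#'
#' Overlapping input intervals are merged so the returned set is sorted and
#' non-overlapping.
#'
#' @param path BED-like file (first three columns chrom, start, end).
#' @param label Optional condition label attached to the set.
#' @return Peak set: data frame `chrom`, `start`, `end` with a `label`
#'   attribute.
#' @export
read_peaks <- function(path, label = NULL) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  df <- data.frame(chrom = as.character(tab[[1]]),
                   start = as.integer(tab[[2]]),
                   end = as.integer(tab[[3]]), stringsAsFactors = FALSE)
  normalize_peaks(df, label = label)
}

#' Merge a peak set into sorted, non-overlapping intervals
#'
#' @param peaks Data frame `chrom`, `start`, `end` (0-based half-open).
#' @param label Optional label attribute.
#' @return Normalized peak set.
#' @export
normalize_peaks <- function(peaks, label = NULL) {
  stopifnot(all(c("chrom", "start", "end") %in% names(peaks)))
  if (nrow(peaks) == 0) {
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE)
  } else {
    if (any(peaks$start >= peaks$end))
      stop("peak intervals must have start < end", call. = FALSE)
    out <- .gr_df(GenomicRanges::reduce(.df_gr(peaks)))
  }
  attr(out, "label") <- label
  out
}

#' Base-pair intersection of two peak sets
#'
#' @param a,b Peak sets (data frames `chrom`, `start`, `end`).
#' @return Peak set covering exactly the bases present in both.
#' @export
intersect_peaksets <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0)
    return(normalize_peaks(a[0, , drop = FALSE]))
  .gr_df(GenomicRanges::intersect(.df_gr(a), .df_gr(b)))
}

#' Base-pair subtraction of two peak sets
#'
#' @param a,b Peak sets; bases of `b` are removed from `a`.
#' @return Peak set covering the bases of `a` not in `b`.
#' @export
subtract_peaksets <- function(a, b) {
  if (nrow(a) == 0) return(normalize_peaks(a))
  if (nrow(b) == 0) return(normalize_peaks(a))
  .gr_df(GenomicRanges::setdiff(.df_gr(a), .df_gr(b)))
}

#' Stepwise peak-overlap integration across replicates, phases and marks
#'
#' Given 36 peak sets (2 cell lines x 3 marks x 3 phases x 2 replicates —
#' no Input), integrates them in three steps:
#' \itemize{
#'   \item replicate consistency: intersect the two replicates of each
#'     (cell line, mark, phase), giving 18 sets;
#'   \item phase logic, per cell line: H3K4me1 and H3K4me3 are intersected
#'     across all three phases (a bookmark persists throughout), while
#'     H3K27ac keeps the bases present in interphase and
#'     anaphase/telophase but absent in prometaphase (reactivation),
#'     giving 6 sets;
#'   \item final intersection of all 6 sets.
#' }
#'
#' @param peaks List of 36 peak sets (data frames `chrom`, `start`, `end`).
#' @param labels Data frame with one row per peak set and columns
#'   `cell_line`, `mark` (H3K27ac/H3K4me1/H3K4me3), `phase`, `replicate`.
#' @param k27_absent How "absent in prometaphase" is applied to H3K27ac:
#'   `"subtract"` removes the prometaphase bases (default); `"reject"` drops
#'   every interval that overlaps a prometaphase peak at all.
#' @return List with `final` (peak set), `step1` and `step2` (named lists of
#'   the intermediate sets), and `counts` (data frame of set counts per
#'   stage: 18, 6, 1).
#' @export
stage_overlap_pipeline <- function(peaks, labels,
                                   k27_absent = c("subtract", "reject")) {
  k27_absent <- match.arg(k27_absent)
  marks3 <- c("H3K27ac", "H3K4me1", "H3K4me3")
  if (length(peaks) != 36L || nrow(labels) != 36L)
    stop("exactly 36 peak sets (2 cell lines x 3 marks x 3 phases x 2 replicates) are required",
         call. = FALSE)
  need <- c("cell_line", "mark", "phase", "replicate")
  stopifnot(all(need %in% names(labels)))
  lab <- data.frame(lapply(labels[need], as.character),
                    stringsAsFactors = FALSE)
  key <- do.call(paste, c(lab, sep = "/"))
  want <- expand.grid(replicate = .tdfe_axes$replicate,
                      phase = .tdfe_axes$phase, mark = marks3,
                      cell_line = .tdfe_axes$cell_line,
                      stringsAsFactors = FALSE)
  want_key <- paste(want$cell_line, want$mark, want$phase, want$replicate,
                    sep = "/")
  if (!setequal(key, want_key) || anyDuplicated(key))
    stop(sprintf("peak set labels must cover each combination once; missing: %s",
                 paste(setdiff(want_key, key), collapse = "; ")),
         call. = FALSE)
  get <- function(cl, mk, ph, rep = NULL) {
    if (is.null(rep)) stop("internal")
    peaks[[which(lab$cell_line == cl & lab$mark == mk &
                   lab$phase == ph & lab$replicate == rep)]]
  }

  step1 <- list()
  for (cl in .tdfe_axes$cell_line) for (mk in marks3)
    for (ph in .tdfe_axes$phase)
      step1[[paste(cl, mk, ph, sep = "/")]] <-
        intersect_peaksets(normalize_peaks(get(cl, mk, ph, "1")),
                           normalize_peaks(get(cl, mk, ph, "2")))

  step2 <- list()
  for (cl in .tdfe_axes$cell_line) {
    for (mk in c("H3K4me1", "H3K4me3")) {
      s <- Reduce(intersect_peaksets,
                  lapply(.tdfe_axes$phase,
                         function(ph) step1[[paste(cl, mk, ph, sep = "/")]]))
      step2[[paste(cl, mk, sep = "/")]] <- s
    }
    inter_ana <- intersect_peaksets(
      step1[[paste(cl, "H3K27ac", "interphase", sep = "/")]],
      step1[[paste(cl, "H3K27ac", "anaphase_telophase", sep = "/")]])
    pro <- step1[[paste(cl, "H3K27ac", "prometaphase", sep = "/")]]
    step2[[paste(cl, "H3K27ac", sep = "/")]] <-
      if (k27_absent == "subtract") subtract_peaksets(inter_ana, pro)
      else {
        if (nrow(inter_ana) == 0 || nrow(pro) == 0) inter_ana
        else {
          hits <- GenomicRanges::findOverlaps(.df_gr(inter_ana), .df_gr(pro))
          inter_ana[setdiff(seq_len(nrow(inter_ana)),
                            unique(S4Vectors::queryHits(hits))), ,
                    drop = FALSE]
        }
      }
  }

  final <- Reduce(intersect_peaksets, step2)
  counts <- data.frame(stage = c("replicate_consistent", "phase_logic",
                                 "final"),
                       n_sets = c(length(step1), length(step2), 1L),
                       n_intervals = c(sum(vapply(step1, nrow, integer(1))),
                                       sum(vapply(step2, nrow, integer(1))),
                                       nrow(final)))
  list(final = final, step1 = step1, step2 = step2, counts = counts)
}

#' Write a gene list, one symbol per line
#'
#' Symbols are deduplicated keeping first appearance; an empty list writes
#' an empty file with a warning.  The output is the upload format expected
#' by gene-set enrichment services.
#'
#' @param symbols Character vector.
#' @param path Output file.
#' @export
export_gene_list <- function(symbols, path) {
  symbols <- unique(as.character(symbols))
  if (!length(symbols))
    warning("empty gene list written to ", path, call. = FALSE)
  writeLines(symbols, path)
  invisible(path)
}
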