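#' Load gene models from a GTF annotation
#'
#' Reads exon features from a GTF file (1-based inclusive coordinates, per the
#' standard), merges overlapping exons per gene and derives the summed exon
#' length and the summed intron length (gene span minus merged exon length).
#' Intervals are stored 0-based half-open internally. The summed intron length
#' is the length-normalization factor used for intronic RPKM in the
#' genome-activation analysis.
#'
#' @param path path to a GTF file with `exon` features carrying `gene_id`
#'   attributes.
#' @return A data.frame of class `mzt_genemodels` with columns `gene_id`,
#'   `scaffold`, `strand`, `n_exons`, `start0`, `end0` (0-based half-open gene
#'   span), `exon_length_nt` and `intron_length_nt`; the merged exon intervals
#'   are kept in the `exons` attribute as a named list of two-column matrices
#'   (`start0`, `end0`).
#' @export
load_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (!length(gr)) stop("no exon features in ", path)
  if (is.null(gr$gene_id) || anyNA(gr$gene_id))
    stop("exon features must carry gene_id attributes")
  # rtracklayer/IRanges reject end < start at parse time; re-check explicitly
  if (any(BiocGenerics::end(gr) < BiocGenerics::start(gr)))
    stop("exon with end < start")
  by_gene <- S4Vectors::split(gr, gr$gene_id)
  n_scaf <- vapply(by_gene, function(g)
    length(unique(as.character(GenomicRanges::seqnames(g)))), integer(1))
  if (any(n_scaf > 1))
    stop("gene(s) on multiple scaffolds: ",
         paste(names(by_gene)[n_scaf > 1], collapse = ", "))
  merged <- GenomicRanges::reduce(by_gene)
  gene_ids <- names(merged)
  exon_len <- sum(BiocGenerics::width(merged))
  span_start <- vapply(seq_along(merged), function(i)
    min(BiocGenerics::start(merged[[i]])), numeric(1))
  span_end <- vapply(seq_along(merged), function(i)
    max(BiocGenerics::end(merged[[i]])), numeric(1))
  intron_len <- (span_end - span_start + 1) - exon_len
  strand <- vapply(by_gene, function(g)
    as.character(BiocGenerics::strand(g))[1], character(1))
  strand[!strand %in% c("+", "-")] <- "+"
  scaffold <- vapply(by_gene, function(g)
    as.character(GenomicRanges::seqnames(g))[1], character(1))
  exons <- lapply(seq_along(merged), function(i) {
    m <- cbind(start0 = BiocGenerics::start(merged[[i]]) - 1,
               end0 = BiocGenerics::end(merged[[i]]))
    m[order(m[, 1]), , drop = FALSE]
  })
  names(exons) <- gene_ids
  out <- data.frame(gene_id = gene_ids, scaffold = scaffold, strand = strand,
                    n_exons = lengths(merged),
                    start0 = span_start - 1, end0 = span_end,
                    exon_length_nt = as.numeric(exon_len),
                    intron_length_nt = as.numeric(intron_len),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "exons") <- exons
  class(out) <- c("mzt_genemodels", "data.frame")
  out
}

#' Gene and intron lengths from a model table
#'
#' @param models an `mzt_genemodels` data.frame.
#' @param genes gene ids to look up (all must be present).
#' @param what `"exon"` or `"intron"` summed length.
#' @return Named numeric vector of lengths in nucleotides.
#' @export
gene_lengths <- function(models, genes = models$gene_id, what = "exon") {
  what <- match.arg(what, c("exon", "intron"))
  idx <- match(genes, models$gene_id)
  if (anyNA(idx))
    stop("no gene model for: ",
         paste(utils::head(genes[is.na(idx)], 10), collapse = ", "))
  col <- if (what == "exon") "exon_length_nt" else "intron_length_nt"
  stats::setNames(models[[col]][idx], genes)
}

#' Compute TPM and RPKM abundances
#'
#' TPM for gene g in a sample is `1e6 * (count_g/len_g) / sum_j(count_j/len_j)`
#' and RPKM is `count_g / (len_kb * libsize_millions)`, with the summed merged
#' exon length as the effective length. A sample with zero total counts yields
#' all-zero abundances with a warning, so degenerate inputs pass through.
#'
#' @param cm an `mzt_counts` object.
#' @param models an `mzt_genemodels` data.frame covering every gene in `cm`.
#' @return A list of class `mzt_abundance` with matrices `tpm` and `rpkm`
#'   (same dimnames as the counts) and the `samples` data.frame.
#' @export
compute_abundance <- function(cm, models) {
  stopifnot(inherits(cm, "mzt_counts"))
  len <- gene_lengths(models, rownames(cm$counts), "exon")
  if (any(len <= 0)) stop("gene model(s) with non-positive exon length")
  rate <- cm$counts / len
  denom <- colSums(rate)
  zero <- denom == 0
  if (any(zero)) {
    warning("sample(s) with zero counts yield all-zero abundances: ",
            paste(colnames(cm$counts)[zero], collapse = ", "))
    denom[zero] <- 1
  }
  tpm <- sweep(rate, 2, denom, "/") * 1e6
  lib <- colSums(cm$counts) / 1e6
  lib[lib == 0] <- 1
  rpkm <- sweep(cm$counts / (len / 1e3), 2, lib, "/")
  structure(list(tpm = tpm, rpkm = rpkm, samples = cm$samples),
            class = "mzt_abundance")
}

#' Per-timepoint mean abundance
#'
#' Averages TPM across replicates of each timepoint for one library type and
#' condition.
#'
#' @param ab an `mzt_abundance` object.
#' @param library_type `"polyA"` or `"ribodep"`.
#' @param condition condition to keep (default `"untreated"`).
#' @return Matrix genes x timepoints (columns named by timepoint_h).
#' @export
mean_tpm_by_timepoint <- function(ab, library_type,
                                  condition = "untreated") {
  stopifnot(inherits(ab, "mzt_abundance"))
  keep <- ab$samples$library_type == library_type &
    ab$samples$condition %in% condition
  if (!any(keep)) stop("no samples for ", library_type, "/",
                       paste(condition, collapse = "+"))
  sm <- ab$samples[keep, , drop = FALSE]
  tps <- sort(unique(sm$timepoint_h))
  out <- vapply(tps, function(t) {
    ids <- sm$sample_id[sm$timepoint_h == t]
    rowMeans(ab$tpm[, ids, drop = FALSE])
  }, numeric(nrow(ab$tpm)))
  colnames(out) <- as.character(tps)
  out
}
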