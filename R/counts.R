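#' Construct a tagged count matrix
#'
#' Bundles an integer gene-by-sample count matrix with its sample metadata.
#' Every sample is tagged with its collection time (hours post fertilization),
#' library type (`polyA` for poly(A)-selected, `ribodep` for rRNA-depleted),
#' treatment condition and replicate number, so that downstream contrasts
#' (timepoint vs egg, Triptolide vs DMSO) can be formed by metadata alone.
#'
#' @param counts integer matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids). No negative entries.
#' @param samples data.frame with columns `sample_id`, `timepoint_h`,
#'   `library_type` (`"polyA"` or `"ribodep"`), `condition` (`"untreated"`,
#'   `"DMSO"` or `"triptolide"`) and `replicate` (positive integer). Rows must
#'   match the columns of `counts` in order or by `sample_id`.
#' @return An object of class `mzt_counts`: a list with elements `counts`
#'   (integer matrix) and `samples` (data.frame).
#' @export
count_matrix <- function(counts, samples) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts)))
    stop("counts must have gene ids as rownames and sample ids as colnames")
  if (is.null(rownames(counts))) {
    if (nrow(counts) > 0)
      stop("counts must have gene ids as rownames and sample ids as colnames")
    rownames(counts) <- character(0)  # empty matrices are legal
  }
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene ids in counts")
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids in counts")
  storage.mode(counts) <- "double"
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative")
  if (any(counts != round(counts)))
    stop("counts must be integers")
  samples <- validate_sample_sheet(samples)
  if (!setequal(samples$sample_id, colnames(counts)))
    stop("sample sheet and count matrix columns disagree")
  counts <- counts[, samples$sample_id, drop = FALSE]
  structure(list(counts = counts, samples = samples), class = "mzt_counts")
}

validate_sample_sheet <- function(samples) {
  required <- c("sample_id", "timepoint_h", "library_type", "condition",
                "replicate")
  missing <- setdiff(required, names(samples))
  if (length(missing))
    stop("sample sheet lacks columns: ", paste(missing, collapse = ", "))
  samples <- as.data.frame(samples)[, required]
  samples$sample_id <- as.character(samples$sample_id)
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id in sample sheet")
  samples$timepoint_h <- as.numeric(samples$timepoint_h)
  if (any(!is.finite(samples$timepoint_h)) || any(samples$timepoint_h < 0))
    stop("timepoint_h must be finite and non-negative")
  bad <- setdiff(unique(samples$library_type), c("polyA", "ribodep"))
  if (length(bad))
    stop("unknown library_type: ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(samples$condition),
                 c("untreated", "DMSO", "triptolide"))
  if (length(bad))
    stop("unknown condition: ", paste(bad, collapse = ", "))
  samples$replicate <- as.integer(samples$replicate)
  if (any(is.na(samples$replicate)) || any(samples$replicate < 1))
    stop("replicate must be a positive integer")
  rownames(samples) <- NULL
  samples
}

#' @export
print.mzt_counts <- function(x, ...) {
  cat(sprintf("mzt_counts: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat("library types:",
      paste(sprintf("%s=%d", names(table(x$samples$library_type)),
                    table(x$samples$library_type)), collapse = ", "), "\n")
  cat("timepoints (h):",
      paste(sort(unique(x$samples$timepoint_h)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.mzt_counts <- function(x) dim(x$counts)

#' Subset a count matrix by sample metadata
#'
#' @param cm an `mzt_counts` object.
#' @param library_type,condition,timepoint_h optional filters; `NULL` keeps all.
#' @param genes optional character vector of gene ids to keep.
#' @return The filtered `mzt_counts`.
#' @export
subset_counts <- function(cm, library_type = NULL, condition = NULL,
                          timepoint_h = NULL, genes = NULL) {
  stopifnot(inherits(cm, "mzt_counts"))
  keep <- rep(TRUE, nrow(cm$samples))
  if (!is.null(library_type))
    keep <- keep & cm$samples$library_type %in% library_type
  if (!is.null(condition))
    keep <- keep & cm$samples$condition %in% condition
  if (!is.null(timepoint_h))
    keep <- keep & cm$samples$timepoint_h %in% timepoint_h
  if (!any(keep)) stop("no samples left after filtering")
  counts <- cm$counts[, cm$samples$sample_id[keep], drop = FALSE]
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(counts))
    if (length(missing))
      stop("genes absent from matrix: ", paste(utils::head(missing, 5),
                                               collapse = ", "))
    counts <- counts[genes, , drop = FALSE]
  }
  count_matrix(counts, cm$samples[keep, , drop = FALSE])
}

#' Read a count matrix and its sample sheet from TSV
#'
#' The counts file is tab-separated with a `gene_id` first column and one
#' column per sample; the sample sheet carries the metadata columns described
#' in [count_matrix()]. Count columns must match the sheet exactly: a column
#' with no metadata row (or vice versa) is a hard error naming the offender.
#'
#' @param path path to the counts TSV.
#' @param meta path to the sample sheet TSV, or a data.frame.
#' @return An `mzt_counts` object with samples ordered as in the sheet.
#' @export
load_counts <- function(path, meta) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (names(tab)[1] != "gene_id")
    stop("counts TSV must have 'gene_id' as its first column")
  if (anyDuplicated(tab$gene_id))
    stop("duplicate gene_id in ", path)
  if (!is.data.frame(meta))
    meta <- utils::read.delim(meta, check.names = FALSE,
                              stringsAsFactors = FALSE)
  meta <- validate_sample_sheet(meta)
  cols <- names(tab)[-1]
  extra <- setdiff(cols, meta$sample_id)
  if (length(extra))
    stop("count column(s) missing from sample sheet: ",
         paste(extra, collapse = ", "))
  absent <- setdiff(meta$sample_id, cols)
  if (length(absent))
    stop("sample sheet entries missing from counts: ",
         paste(absent, collapse = ", "))
  mat <- matrix(NA_real_, nrow(tab), length(meta$sample_id),
                dimnames = list(tab$gene_id, meta$sample_id))
  for (s in meta$sample_id) {
    v <- suppressWarnings(as.numeric(tab[[s]]))
    bad <- which(is.na(v) | v != round(v))
    if (length(bad))
      stop(sprintf("non-integer count at row '%s', column '%s'",
                   tab$gene_id[bad[1]], s))
    mat[, s] <- v
  }
  count_matrix(mat, meta)
}

#' Write a count matrix (and optionally its sample sheet) to TSV
#'
#' @param cm an `mzt_counts` object.
#' @param path output path for the counts TSV.
#' @param meta_path optional output path for the sample sheet TSV.
#' @return Invisibly, `path`.
#' @export
write_counts <- function(cm, path, meta_path = NULL) {
  stopifnot(inherits(cm, "mzt_counts"))
  out <- data.frame(gene_id = rownames(cm$counts), cm$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(meta_path))
    utils::write.table(cm$samples, meta_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}
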