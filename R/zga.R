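#' Build an intron count table from pre-mRNA and exon counts
#'
#' Intron counts are pre-mRNA counts minus exon counts, clamped at zero with a
#' warning (exon counts can exceed pre-mRNA counts through counting noise).
#' Genes without introns are excluded, as are genes whose intronic RPKM --
#' computed with the summed intron length as the length factor and the summed
#' pre-mRNA counts as the library factor -- stays below `min_rpkm` in every
#' sample.
#'
#' @param premrna an `mzt_counts` of pre-mRNA (gene-span) counts,
#'   rRNA-depleted samples.
#' @param exon an `mzt_counts` of exon counts over the same genes and samples.
#' @param models an `mzt_genemodels`.
#' @param min_rpkm intronic RPKM retention threshold (default 0.5).
#' @return A list of class `mzt_intron_table`: `counts` (`mzt_counts` of
#'   intron counts for retained genes), `rpkm` (matrix), `excluded_no_intron`
#'   and `excluded_low_rpkm` (gene id vectors).
#' @export
build_intron_table <- function(premrna, exon, models, min_rpkm = 0.5) {
  stopifnot(inherits(premrna, "mzt_counts"), inherits(exon, "mzt_counts"))
  if (!setequal(rownames(premrna$counts), rownames(exon$counts)) ||
      !setequal(colnames(premrna$counts), colnames(exon$counts)))
    stop("pre-mRNA and exon tables must cover the same genes and samples")
  ex <- exon$counts[rownames(premrna$counts), colnames(premrna$counts)]
  intron <- premrna$counts - ex
  if (any(intron < 0)) {
    warning(sum(intron < 0),
            " negative intron count(s) clamped to zero (exon > pre-mRNA)")
    intron[intron < 0] <- 0
  }
  ilen <- gene_lengths(models, rownames(intron), "intron")
  no_intron <- names(ilen)[ilen == 0]
  keep <- ilen > 0
  intron <- intron[keep, , drop = FALSE]
  lib <- colSums(premrna$counts) / 1e6
  lib[lib == 0] <- 1
  rpkm <- sweep(intron / (ilen[keep] / 1e3), 2, lib, "/")
  low <- apply(rpkm, 1, max) < min_rpkm
  excluded_low <- rownames(intron)[low]
  intron <- intron[!low, , drop = FALSE]
  rpkm <- rpkm[!low, , drop = FALSE]
  structure(list(counts = count_matrix(intron, premrna$samples),
                 rpkm = rpkm,
                 excluded_no_intron = no_intron,
                 excluded_low_rpkm = excluded_low),
            class = "mzt_intron_table")
}

#' Combined exon + intron differential expression
#'
#' Stacks exon and intron counts into one table in which each gene can have up
#' to two entries (`gene::exon`, `gene::intron`), then runs the timecourse
#' differential expression so that exon and intron entries share size factors
#' and enter Benjamini-Hochberg adjustment jointly within each contrast. A
#' gene is "activated by intron signal" when its intron entry is
#' significantly up.
#'
#' @param exon an `mzt_counts` of exon counts (rRNA-depleted samples).
#' @param intron_table an `mzt_intron_table` from [build_intron_table()].
#' @param condition condition analysed (default `"untreated"`).
#' @param min_total low-count filter threshold.
#' @return data.frame as [de_timecourse()] plus an `entry` column
#'   (`"exon"`/`"intron"`).
#' @export
combined_de <- function(exon, intron_table, condition = "untreated",
                        min_total = 10) {
  stopifnot(inherits(exon, "mzt_counts"),
            inherits(intron_table, "mzt_intron_table"))
  intron <- intron_table$counts
  common <- intersect(colnames(exon$counts), colnames(intron$counts))
  if (!length(common)) stop("no shared samples between exon and intron")
  ex <- exon$counts[, common, drop = FALSE]
  intr <- intron$counts[, common, drop = FALSE]
  comb <- rbind(ex, intr)
  rownames(comb) <- c(paste0(rownames(ex), "::exon"),
                      paste0(rownames(intr), "::intron"))
  sm <- exon$samples[match(common, exon$samples$sample_id), , drop = FALSE]
  cm <- count_matrix(comb, sm)
  res <- de_timecourse(cm, library_type = sm$library_type[1],
                       condition = condition, min_total = min_total)
  parts <- strsplit(res$gene_id, "::", fixed = TRUE)
  res$entry <- vapply(parts, `[`, character(1), 2)
  res$gene_id <- vapply(parts, `[`, character(1), 1)
  res
}

#' Classify genes by maternal contribution and activation route
#'
#' Maternal genes have egg TPM >= `maternal_tpm` (rRNA-depleted); pure
#' zygotic candidates require egg TPM < `zygotic_tpm`; the band in between is
#' reported as `ambiguous` rather than forced into either class. A gene is
#' activated when any exon or intron entry is significantly up
#' (padj < alpha, log2fc > 0) at any timepoint, with `first_activation` the
#' earliest such timepoint and `evidence` recording whether exonic, intronic
#' or both signals support it.
#'
#' @param de combined DE results from [combined_de()] (rRNA-depleted).
#' @param abundance an `mzt_abundance` (for egg TPM, ribodep samples).
#' @param maternal_tpm,zygotic_tpm TPM thresholds (defaults 1 and 0.5).
#' @param alpha significance level on adjusted p (default 0.05).
#' @return data.frame with `gene_id`, `egg_tpm`, `maternal_status`
#'   (`maternal`/`ambiguous`/`none`), `activated`, `evidence`
#'   (`exon`/`intron`/`both`/`none`), `first_activation_timepoint_h`, and
#'   `route` (`maternal_only`, `maternal_zygotic`, `zygotic_only`,
#'   `ambiguous`, `silent`).
#' @export
classify_activation <- function(de, abundance, maternal_tpm = 1,
                                zygotic_tpm = 0.5, alpha = 0.05) {
  stopifnot(inherits(abundance, "mzt_abundance"))
  sm <- abundance$samples
  egg_ids <- sm$sample_id[sm$timepoint_h == 0 &
                            sm$library_type == "ribodep" &
                            sm$condition %in% c("untreated", "DMSO")]
  if (!length(egg_ids)) stop("no egg rRNA-depleted samples in abundance")
  egg_tpm <- rowMeans(abundance$tpm[, egg_ids, drop = FALSE])
  genes <- names(egg_tpm)
  up <- de[de$padj < alpha & de$log2fc > 0, , drop = FALSE]
  first_t <- tapply(up$timepoint_h, up$gene_id, min)
  ev_exon <- unique(up$gene_id[up$entry == "exon"])
  ev_intron <- unique(up$gene_id[up$entry == "intron"])
  evidence <- ifelse(genes %in% ev_exon & genes %in% ev_intron, "both",
              ifelse(genes %in% ev_exon, "exon",
              ifelse(genes %in% ev_intron, "intron", "none")))
  activated <- evidence != "none"
  maternal_status <- ifelse(egg_tpm >= maternal_tpm, "maternal",
                     ifelse(egg_tpm < zygotic_tpm, "none", "ambiguous"))
  route <- ifelse(maternal_status == "maternal" & !activated, "maternal_only",
           ifelse(maternal_status == "maternal" & activated, "maternal_zygotic",
           ifelse(maternal_status == "none" & activated, "zygotic_only",
           ifelse(maternal_status == "ambiguous", "ambiguous", "silent"))))
  data.frame(gene_id = genes, egg_tpm = as.numeric(egg_tpm),
             maternal_status = maternal_status, activated = activated,
             evidence = evidence,
             first_activation_timepoint_h =
               as.numeric(first_t[genes]),
             route = route, row.names = NULL, stringsAsFactors = FALSE)
}

#' Transcriptome-fraction trajectories per gene class
#'
#' For each class in a gene -> class map, the fraction of the transcriptome it
#' occupies at each timepoint (`sum of class TPM / 1e6`, replicate-averaged)
#' and the net-activation curve relative to the egg stage.
#'
#' @param abundance an `mzt_abundance`.
#' @param gene_classes named character vector (names = gene ids) or data.frame
#'   with columns `gene_id`, `class`; every gene must be in the abundance.
#' @param library_type library to trace (default `"ribodep"`, which also sees
#'   non-adenylated transcripts such as histone mRNA).
#' @return data.frame with `class`, `timepoint_h`, `fraction`,
#'   `net_activation` (fraction / egg fraction).
#' @export
class_fraction_trajectory <- function(abundance, gene_classes,
                                      library_type = "ribodep") {
  if (is.data.frame(gene_classes))
    gene_classes <- stats::setNames(gene_classes$class,
                                    gene_classes$gene_id)
  missing <- setdiff(names(gene_classes), rownames(abundance$tpm))
  if (length(missing))
    stop("unknown gene(s) in class map: ",
         paste(utils::head(missing, 5), collapse = ", "))
  tpm <- mean_tpm_by_timepoint(abundance, library_type)
  tps <- as.numeric(colnames(tpm))
  out <- lapply(unique(gene_classes), function(cl) {
    ids <- names(gene_classes)[gene_classes == cl]
    frac <- colSums(tpm[ids, , drop = FALSE]) / 1e6
    egg <- frac[which(tps == 0)]
    data.frame(class = cl, timepoint_h = tps, fraction = as.numeric(frac),
               net_activation = if (length(egg) && egg > 0)
                 as.numeric(frac / egg) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Windowed genome-activation scan
#'
#' Depth-normalizes two per-window count tables (e.g. 10-kb genome windows at
#' two timepoints), computes `log2((a + eps) / (b + eps))` and flags windows
#' whose fold increase exceeds `fold_threshold`.
#'
#' @param windows_t1,windows_t2 data.frames with columns `scaffold`, `start`,
#'   `end`, `count` over identical window sets; `t2` is the later timepoint.
#' @param eps pseudocount after normalization (default 1).
#' @param fold_threshold flagging threshold on the fold increase (default 3).
#' @return data.frame `scaffold`, `start`, `end`, `log2fc`, `flag`.
#' @export
windowed_activation <- function(windows_t1, windows_t2, eps = 1,
                                fold_threshold = 3) {
  key <- function(w) paste(w$scaffold, w$start, w$end)
  if (!identical(key(windows_t1), key(windows_t2)))
    stop("window sets differ between the two tables")
  if (any(windows_t1$count < 0) || any(windows_t2$count < 0) ||
      any(windows_t1$count != round(windows_t1$count)) ||
      any(windows_t2$count != round(windows_t2$count)))
    stop("window counts must be non-negative integers")
  norm <- function(x) {
    tot <- sum(x)
    if (tot == 0) x else x / tot * mean(c(sum(windows_t1$count),
                                          sum(windows_t2$count)))
  }
  a <- norm(windows_t2$count)
  b <- norm(windows_t1$count)
  lfc <- log2((a + eps) / (b + eps))
  data.frame(scaffold = windows_t1$scaffold, start = windows_t1$start,
             end = windows_t1$end, log2fc = lfc,
             flag = (a + eps) / (b + eps) > fold_threshold,
             stringsAsFactors = FALSE)
}
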