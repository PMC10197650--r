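#' First significant expression decrease versus the egg stage
#'
#' A gene's decrease time is the earliest timepoint with adjusted p below
#' `alpha` and a fold decrease of at least `fold` (log2fc <= -log2(fold)).
#' Genes whose size-factor-normalized mean trajectory shows any stage-to-stage
#' increase above `oscillation` are disqualified outright: an oscillation
#' filter that keeps only monotone-looking clearance profiles.
#' The trajectory is reconstructed from the per-contrast group means carried
#' by the DE table (egg mean from `mean_ref`, per-timepoint means from
#' `mean_treat`).
#'
#' @param de timecourse DE table from [de_timecourse()] for one library type.
#' @param alpha significance threshold on `padj` (default 0.05).
#' @param fold minimum fold decrease (default 2).
#' @param oscillation maximum tolerated stage-to-stage mean increase
#'   (default 1.5).
#' @return data.frame with `gene_id`, `t_down` (timepoint or `NA`),
#'   `oscillating` (disqualified flag).
#' @export
first_decrease <- function(de, alpha = 0.05, fold = 2, oscillation = 1.5) {
  if (length(unique(de$library_type)) > 1)
    stop("DE table mixes library types; pass one at a time")
  genes <- unique(de$gene_id)
  tps <- sort(unique(de$timepoint_h))
  idx <- cbind(match(de$gene_id, genes), match(de$timepoint_h, tps))
  means <- matrix(NA_real_, length(genes), length(tps) + 1,
                  dimnames = list(genes, c("0", as.character(tps))))
  means[cbind(idx[, 1], idx[, 2] + 1)] <- de$mean_treat
  egg <- tapply(de$mean_ref, de$gene_id, function(x) x[1])
  means[, 1] <- as.numeric(egg[genes])
  ratios <- means[, -1, drop = FALSE] / pmax(means[, -ncol(means),
                                                   drop = FALSE], 1e-9)
  oscillating <- apply(ratios, 1, function(r)
    any(r > oscillation, na.rm = TRUE))
  sig <- de[de$padj < alpha & de$log2fc <= -log2(fold), , drop = FALSE]
  t_first <- tapply(sig$timepoint_h, sig$gene_id, min)
  t_down <- as.numeric(t_first[genes])
  t_down[oscillating[genes]] <- NA_real_
  data.frame(gene_id = genes, t_down = t_down,
             oscillating = as.logical(oscillating[genes]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify maternal mRNA tail dynamics versus degradation
#'
#' Combines decrease times from the two library types with poly(A)+ up-calls:
#' `readenylated` genes rise significantly in poly(A)+ libraries (>= `fold`,
#' padj < alpha) with no matching rRNA-depleted rise at the same timepoint
#' (a poly(A)-tail lengthening signature); `deadenylated_only` genes fall in
#' poly(A)+ but never in rRNA-depleted libraries (tail shortening without
#' transcript loss); `deadenylate_then_degrade` genes fall in poly(A)+ first
#' and in rRNA-depleted later (`lead_h > 0`); `degraded_without_lead`
#' genes fall in both with no lead; everything else is `stable`.
#'
#' @param fd_polyA,fd_ribodep outputs of [first_decrease()] for the poly(A)+
#'   and rRNA-depleted timecourses.
#' @param de_polyA poly(A)+ timecourse DE table (for up-calls).
#' @param de_ribodep rRNA-depleted timecourse DE table (for matching
#'   up-calls).
#' @param alpha,fold significance and fold thresholds (defaults 0.05, 2).
#' @return data.frame with `gene_id`, `t_down_polyA`, `t_down_total`,
#'   `lead_h`, `tail_class`.
#' @export
classify_tail_dynamics <- function(fd_polyA, fd_ribodep, de_polyA,
                                   de_ribodep, alpha = 0.05, fold = 2) {
  genes <- union(fd_polyA$gene_id, fd_ribodep$gene_id)
  t_pa <- fd_polyA$t_down[match(genes, fd_polyA$gene_id)]
  t_rd <- fd_ribodep$t_down[match(genes, fd_ribodep$gene_id)]
  up_pa <- de_polyA[de_polyA$padj < alpha &
                      de_polyA$log2fc >= log2(fold), c("gene_id",
                                                       "timepoint_h")]
  up_rd <- de_ribodep[de_ribodep$padj < alpha &
                        de_ribodep$log2fc >= log2(fold), c("gene_id",
                                                           "timepoint_h")]
  key <- function(d) paste(d$gene_id, d$timepoint_h)
  readen <- unique(up_pa$gene_id[!(key(up_pa) %in% key(up_rd))])
  lead <- ifelse(!is.na(t_pa) & !is.na(t_rd), t_rd - t_pa, NA_real_)
  cls <- ifelse(genes %in% readen, "readenylated",
         ifelse(!is.na(t_pa) & is.na(t_rd), "deadenylated_only",
         ifelse(!is.na(t_pa) & !is.na(t_rd) & lead > 0,
                "deadenylate_then_degrade",
         ifelse(!is.na(t_pa) & !is.na(t_rd), "degraded_without_lead",
                "stable"))))
  data.frame(gene_id = genes, t_down_polyA = t_pa, t_down_total = t_rd,
             lead_h = lead, tail_class = cls, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Bubble-chart summary of clearance timing
#'
#' Gene counts over observed (poly(A)+ decrease time, rRNA-depleted decrease
#' time) pairs, with a `never` margin on each axis; the total equals the
#' number of genes with at least one non-null decrease time.
#'
#' @param calls output of [classify_tail_dynamics()].
#' @return matrix of counts, rows = poly(A)+ decrease times (+ `never`),
#'   columns = rRNA-depleted decrease times (+ `never`).
#' @export
bubble_summary <- function(calls) {
  has <- !is.na(calls$t_down_polyA) | !is.na(calls$t_down_total)
  sub <- calls[has, , drop = FALSE]
  if (!nrow(sub))
    return(matrix(integer(0), 0, 0))
  x <- ifelse(is.na(sub$t_down_polyA), "never",
              as.character(sub$t_down_polyA))
  y <- ifelse(is.na(sub$t_down_total), "never",
              as.character(sub$t_down_total))
  lev <- function(v) {
    nums <- suppressWarnings(sort(unique(as.numeric(v[v != "never"]))))
    c(as.character(nums), if ("never" %in% v) "never")
  }
  table(factor(x, levels = lev(x)), factor(y, levels = lev(y)))
}

#' Stable maternal reference gene set
#'
#' Genes whose poly(A)+ abundance stays within `fold` of the egg level at
#' every one of the probed timepoints and that are not significantly changed
#' by Triptolide versus mock: the reference set used as background for motif
#' and codon analyses.
#'
#' @param abundance an `mzt_abundance` (poly(A)+ samples used).
#' @param de_trip Triptolide-vs-mock DE table (any library); genes with
#'   `padj < alpha` there are excluded.
#' @param timepoints_h probed timepoints (default 4:7).
#' @param fold maximum fold difference vs egg (default 1.25).
#' @param alpha significance threshold for the Triptolide exclusion.
#' @return Character vector of gene ids.
#' @export
stable_reference_set <- function(abundance, de_trip,
                                 timepoints_h = c(4, 5, 6, 7), fold = 1.25,
                                 alpha = 0.05) {
  tpm <- mean_tpm_by_timepoint(abundance, "polyA")
  need <- as.character(c(0, timepoints_h))
  missing <- setdiff(need, colnames(tpm))
  if (length(missing))
    stop("abundance lacks poly(A)+ timepoints: ",
         paste(missing, collapse = ", "))
  egg <- tpm[, "0"]
  ok <- rep(TRUE, nrow(tpm))
  for (t in as.character(timepoints_h)) {
    ratio <- (tpm[, t] + 1e-9) / (egg + 1e-9)
    ok <- ok & ratio < fold & ratio > 1 / fold
  }
  trip_sig <- unique(de_trip$gene_id[de_trip$padj < alpha])
  ids <- rownames(tpm)[ok & egg > 0]
  setdiff(ids, trip_sig)
}

#' Wilcoxon signed-rank comparison of clearance under transcription
#' inhibition
#'
#' Pairs each gene's log2 fold change versus egg under Triptolide with the
#' matching mock (DMSO) value and tests the differences by Wilcoxon
#' signed-rank: exact distribution for n <= 25 without ties in the absolute
#' differences, normal approximation with continuity correction otherwise;
#' zero differences are dropped (Wilcoxon's convention). Direction
#' `stabilized` means Triptolide fold changes sit above mock, i.e. clearance
#' was inhibited.
#'
#' @param lfc_trip,lfc_dmso named numeric vectors of per-gene log2 fold
#'   changes vs egg (names = gene ids; the intersection is used).
#' @param group label for the report (e.g. `"early"`, `"late"`).
#' @return One-row data.frame: `group`, `n` (pairs after zero-dropping),
#'   `median_diff`, `direction` (`stabilized`/`destabilized`/`none`), `p`
#'   (`NA` with a note when fewer than 5 usable pairs).
#' @export
inhibition_comparison <- function(lfc_trip, lfc_dmso, group = "all") {
  common <- intersect(names(lfc_trip), names(lfc_dmso))
  d <- lfc_trip[common] - lfc_dmso[common]
  d <- d[is.finite(d)]
  if (length(d) && all(d == 0))
    return(data.frame(group = group, n = 0L, median_diff = 0,
                      direction = "none", p = 1, note = "all ties",
                      stringsAsFactors = FALSE))
  d <- d[d != 0]
  if (length(d) < 5)
    return(data.frame(group = group, n = length(d),
                      median_diff = if (length(d)) stats::median(d) else
                        NA_real_,
                      direction = "none", p = NA_real_,
                      note = "insufficient pairs", stringsAsFactors = FALSE))
  exact <- length(d) <= 25 && !any(duplicated(abs(d)))
  ht <- suppressWarnings(stats::wilcox.test(d, exact = exact,
                                            correct = TRUE))
  med <- stats::median(d)
  data.frame(group = group, n = length(d), median_diff = med,
             direction = if (med > 0) "stabilized" else if (med < 0)
               "destabilized" else "none",
             p = ht$p.value, note = "", stringsAsFactors = FALSE)
}
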