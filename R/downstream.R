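#' Stage-specific expression clusters
#'
#' Stage means are replicate- and timepoint-averaged TPM within named stages
#' (default: egg, gastrula = 4-7 h, then each larval timepoint). A gene is
#' stage-specific when some stage mean falls below `low` TPM, another exceeds
#' `high` TPM, and the gene is significantly different from egg at some
#' timepoint; its peak stage is the argmax (ties resolved to the earliest
#' stage and logged via a message).
#'
#' @param abundance an `mzt_abundance` (poly(A)+ samples used).
#' @param de poly(A)+ timecourse DE table.
#' @param stage_map named list mapping stage name -> timepoints (hours); the
#'   list order defines stage order. `NULL` builds the default from the
#'   timepoints present.
#' @param low,high TPM thresholds (defaults 1 and 5).
#' @param alpha significance threshold on `padj`.
#' @return data.frame `gene_id`, per-stage mean columns, `peak_stage`,
#'   `is_stage_specific`.
#' @export
stage_specific_clusters <- function(abundance, de, stage_map = NULL,
                                    low = 1, high = 5, alpha = 0.05) {
  tpm <- mean_tpm_by_timepoint(abundance, "polyA")
  tps <- as.numeric(colnames(tpm))
  if (is.null(stage_map)) {
    stage_map <- list(egg = 0, gastrula = tps[tps >= 4 & tps <= 7])
    for (t in tps[tps > 7]) stage_map[[as.character(t)]] <- t
  }
  stage_means <- vapply(names(stage_map), function(s) {
    cols <- as.character(stage_map[[s]])
    cols <- intersect(cols, colnames(tpm))
    if (!length(cols)) stop("stage '", s, "' has no samples")
    rowMeans(tpm[, cols, drop = FALSE])
  }, numeric(nrow(tpm)))
  sig <- unique(de$gene_id[de$padj < alpha])
  specific <- apply(stage_means, 1, min) < low &
    apply(stage_means, 1, max) > high &
    rownames(stage_means) %in% sig
  peak_i <- apply(stage_means, 1, which.max)  # which.max takes the first tie
  ties <- apply(stage_means, 1, function(x) sum(x == max(x)) > 1)
  if (any(ties & specific))
    message(sum(ties & specific),
            " stage-specific gene(s) with tied peaks assigned to the",
            " earliest stage")
  out <- data.frame(gene_id = rownames(stage_means), stage_means,
                    peak_stage = colnames(stage_means)[peak_i],
                    is_stage_specific = as.logical(specific),
                    row.names = NULL, check.names = FALSE,
                    stringsAsFactors = FALSE)
  attr(out, "stages") <- names(stage_map)
  out
}

#' Chi-squared GO enrichment across stage clusters
#'
#' For every GO term, a 2 x G contingency table (genes annotated with the
#' term vs not, across the G stage clusters of stage-specific genes) is
#' tested with Pearson's chi-squared statistic on G - 1 degrees of freedom
#' (no continuity correction), upper tail; p-values are Benjamini-Hochberg
#' adjusted over all tested terms. Terms whose table has any expected cell
#' below 1 are flagged. With the default five stages the test has 4 degrees
#' of freedom; other stage counts adjust df and are logged.
#'
#' @param clusters output of [stage_specific_clusters()]; only
#'   stage-specific genes enter the tables.
#' @param go_map data.frame `gene_id`, `term`.
#' @param min_genes skip terms annotating fewer genes (default 2).
#' @return data.frame `term`, per-stage annotated counts, `statistic`, `df`,
#'   `p`, `padj`, `low_expected` flag.
#' @export
go_chi2_enrichment <- function(clusters, go_map, min_genes = 2) {
  sub <- clusters[clusters$is_stage_specific, , drop = FALSE]
  if (nrow(sub) < 2) stop("fewer than two stage-specific genes")
  stages <- attr(clusters, "stages")
  if (is.null(stages)) stages <- sort(unique(sub$peak_stage))
  stage <- factor(sub$peak_stage, levels = stages)
  used <- table(stage) > 0
  if (sum(used) < 2) stop("need genes in at least two stages")
  stage <- droplevels(stage)
  G <- nlevels(stage)
  if (G != 5)
    message("chi-squared over ", G, " stage groups: df = ", G - 1)
  totals <- table(stage)
  go_map <- go_map[go_map$gene_id %in% sub$gene_id, , drop = FALSE]
  terms <- names(which(table(go_map$term) >= min_genes))
  if (!length(terms))
    return(data.frame(term = character(0)))
  gene_stage <- stats::setNames(as.character(stage), sub$gene_id)
  rows <- lapply(terms, function(tm) {
    ann <- unique(go_map$gene_id[go_map$term == tm])
    with_term <- table(factor(gene_stage[ann], levels = levels(stage)))
    tab <- rbind(annotated = as.numeric(with_term),
                 not_annotated = as.numeric(totals - with_term))
    ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    cnt <- as.list(as.numeric(with_term))
    names(cnt) <- paste0("n_", levels(stage))
    cbind(data.frame(term = tm, stringsAsFactors = FALSE),
          as.data.frame(cnt, check.names = FALSE),
          data.frame(statistic = unname(ht$statistic),
                     df = unname(ht$parameter),
                     p = ht$p.value,
                     low_expected = any(ht$expected < 1)))
  })
  out <- do.call(rbind, rows)
  out$p[is.na(out$p)] <- 1
  out$padj <- bh_adjust(out$p)
  out[order(out$p), ]
}

codon_families <- function() {
  gc <- Biostrings::GENETIC_CODE
  aa <- gc[gc != "*"]
  split(names(aa), aa)
}

#' Codon adaptation index against a highly expressed reference set
#'
#' Relative adaptiveness `w_c = f_c / max f` within each synonymous family is
#' estimated from the codon counts of a reference gene set (canonically the
#' most highly expressed uncleared maternal mRNA); zero counts receive a 0.5
#' pseudocount before computing `w`. A gene's CAI is the geometric mean of
#' `w` over its codons, excluding single-codon families (Met, Trp) and stop
#' codons. Genes whose CDS length is not a multiple of 3 are skipped with a
#' warning; internal stops are excluded from the product with a warning.
#'
#' @param cds named character vector (or `DNAStringSet`) of CDS sequences.
#' @param reference_ids gene ids defining the reference codon usage.
#' @param pseudocount added to unseen reference codons (default 0.5).
#' @return Named numeric vector of CAI values, with the `w` table in the
#'   `w` attribute.
#' @export
codon_adaptation_index <- function(cds, reference_ids, pseudocount = 0.5) {
  if (methods::is(cds, "DNAStringSet")) {
    nm <- names(cds)
    cds <- as.character(cds)
    names(cds) <- nm
  }
  cds <- toupper(chartr("U", "T", cds))
  missing <- setdiff(reference_ids, names(cds))
  if (length(missing))
    stop("reference gene(s) without CDS: ",
         paste(utils::head(missing, 5), collapse = ", "))
  split_codons <- function(s) {
    if (nchar(s) %% 3 != 0) return(NULL)
    substring(s, seq(1, nchar(s) - 2, 3), seq(3, nchar(s), 3))
  }
  fams <- codon_families()
  all_codons <- unlist(fams, use.names = FALSE)
  ref_codons <- unlist(lapply(cds[reference_ids], split_codons))
  f <- table(factor(ref_codons, levels = all_codons))
  f <- as.numeric(f)
  names(f) <- all_codons
  f[f == 0] <- pseudocount
  w <- f
  for (fam in fams) w[fam] <- f[fam] / max(f[fam])
  multi <- unlist(fams[lengths(fams) > 1], use.names = FALSE)
  cai <- stats::setNames(rep(NA_real_, length(cds)), names(cds))
  skipped <- character(0)
  stops <- c("TAA", "TAG", "TGA")
  internal_stop <- character(0)
  for (g in names(cds)) {
    cod <- split_codons(cds[[g]])
    if (is.null(cod)) {
      skipped <- c(skipped, g)
      next
    }
    if (any(cod[-length(cod)] %in% stops))
      internal_stop <- c(internal_stop, g)
    cod <- cod[cod %in% multi]
    if (!length(cod)) next
    cai[g] <- exp(mean(log(w[cod])))
  }
  if (length(skipped))
    warning(length(skipped), " gene(s) skipped: CDS length not a multiple",
            " of 3 (", paste(utils::head(skipped, 3), collapse = ", "), ")")
  if (length(internal_stop))
    warning(length(internal_stop), " gene(s) with internal stop codons")
  attr(cai, "w") <- w
  cai
}

#' Compare CAI between cleared and stable gene groups
#'
#' Two-sided Mann-Whitney U test (rank-based, distribution-free) on the CAI
#' values of the two groups.
#'
#' @param cai named CAI vector from [codon_adaptation_index()].
#' @param cleared_ids,stable_ids gene id vectors.
#' @return list with `n_cleared`, `n_stable`, medians, `p`.
#' @export
cai_compare <- function(cai, cleared_ids, stable_ids) {
  a <- cai[intersect(cleared_ids, names(cai))]
  b <- cai[intersect(stable_ids, names(cai))]
  a <- a[is.finite(a)]
  b <- b[is.finite(b)]
  if (!length(a) || !length(b)) stop("empty CAI group")
  ht <- suppressWarnings(stats::wilcox.test(a, b))
  list(n_cleared = length(a), n_stable = length(b),
       median_cleared = stats::median(a), median_stable = stats::median(b),
       p = ht$p.value)
}

#' Discriminative k-mer enrichment in 3'UTRs
#'
#' A transparent stand-in for EM-based discriminative motif discovery: for
#' each k in `k_range`, every k-mer observed in the sequences is scored by the
#' number of foreground versus background UTRs containing it, with a
#' one-sided Fisher exact test (hypergeometric tail) and Benjamini-Hochberg
#' adjustment within each k. UTRs of `min_len` or fewer nucleotides are
#' discarded. Sequences are reported in the RNA alphabet.
#'
#' @param fg_utrs,bg_utrs named character vectors of 3'UTR sequences
#'   (foreground = cleared genes, background = stable genes).
#' @param k_range k-mer sizes (default 5:8).
#' @param min_len minimum UTR length retained (default 20, exclusive).
#' @param max_kmers per k, keep only this many most foreground-frequent
#'   k-mers for testing (default 5000) to bound the multiple-testing burden.
#' @return data.frame `k`, `kmer` (RNA alphabet), `fg_with`, `fg_total`,
#'   `bg_with`, `bg_total`, `p`, `padj`, ordered by `p` within `k`.
#' @export
kmer_enrichment <- function(fg_utrs, bg_utrs, k_range = 5:8, min_len = 20,
                            max_kmers = 5000) {
  clean <- function(x) {
    x <- toupper(chartr("U", "T", x))
    x[nchar(x) > min_len]
  }
  fg <- clean(fg_utrs)
  bg <- clean(bg_utrs)
  if (!length(fg)) stop("empty foreground after length filtering")
  if (!length(bg)) stop("empty background after length filtering")
  presence <- function(seqs, k) {
    sets <- lapply(seqs, function(s) {
      n <- nchar(s)
      if (n < k) return(character(0))
      unique(substring(s, 1:(n - k + 1), k:n))
    })
    table(unlist(sets, use.names = FALSE))
  }
  out <- lapply(k_range, function(k) {
    fg_tab <- presence(fg, k)
    bg_tab <- presence(bg, k)
    kmers <- names(fg_tab)
    if (length(kmers) > max_kmers)
      kmers <- names(sort(fg_tab, decreasing = TRUE))[seq_len(max_kmers)]
    a <- as.numeric(fg_tab[kmers])
    b <- as.numeric(bg_tab[kmers])
    b[is.na(b)] <- 0
    nf <- length(fg)
    nb <- length(bg)
    # one-sided Fisher = hypergeometric upper tail
    p <- stats::phyper(a - 1, a + b, (nf - a) + (nb - b), nf,
                       lower.tail = FALSE)
    data.frame(k = k, kmer = chartr("T", "U", kmers), fg_with = a,
               fg_total = nf, bg_with = b, bg_total = nb, p = p,
               padj = bh_adjust(p), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out[order(out$k, out$p), ]
}
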