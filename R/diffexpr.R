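#' Median-of-ratios size factors
#'
#' The per-sample factor is the median, over genes with positive counts in all
#' samples, of the ratio between the sample's count and the gene's geometric
#' mean across samples. Factors are returned unnormalized.
#'
#' @param cm an `mzt_counts` object or a count matrix.
#' @param pseudo_reference fall back to a pseudo-reference built from nonzero
#'   counts when no gene is positive in every sample.
#' @return Named numeric vector of positive size factors, one per sample.
#' @export
size_factors <- function(cm, pseudo_reference = FALSE) {
  counts <- if (inherits(cm, "mzt_counts")) cm$counts else as.matrix(cm)
  allpos <- rowSums(counts > 0) == ncol(counts)
  if (!any(allpos)) {
    if (!pseudo_reference)
      stop("no gene has positive counts in all samples; ",
           "set pseudo_reference = TRUE to use a nonzero-count reference")
    use <- rowSums(counts > 0) >= ncol(counts) / 2
    if (!any(use)) stop("counts too sparse even for pseudo-reference")
    logg <- apply(counts[use, , drop = FALSE], 1, function(x)
      mean(log(x[x > 0])))
    ratios <- counts[use, , drop = FALSE] / exp(logg)
    sf <- apply(ratios, 2, function(r) stats::median(r[r > 0]))
  } else {
    sub <- counts[allpos, , drop = FALSE]
    geo <- exp(rowMeans(log(sub)))
    sf <- apply(sub / geo, 2, stats::median)
  }
  if (any(!is.finite(sf)) || any(sf <= 0))
    stop("degenerate size factor; check for empty samples")
  stats::setNames(sf, colnames(counts))
}

#' Drop genes with fewer than `min_total` reads across all samples
#'
#' @param cm an `mzt_counts` object.
#' @param min_total minimum row sum to retain a gene (default 10).
#' @return The filtered `mzt_counts`, with the removed gene ids recorded in
#'   the `removed` attribute.
#' @export
filter_low_counts <- function(cm, min_total = 10) {
  stopifnot(inherits(cm, "mzt_counts"))
  keep <- rowSums(cm$counts) >= min_total
  out <- cm
  out$counts <- cm$counts[keep, , drop = FALSE]
  attr(out, "removed") <- rownames(cm$counts)[!keep]
  out
}

#' Gene-wise negative-binomial dispersion with a mean trend
#'
#' The gene-wise estimate is the method-of-moments quantity
#' `max(0, (s^2 - mu) / mu^2)` computed within each replicate group on
#' size-factor-normalized counts and pooled across groups with
#' degrees-of-freedom weights. A mean trend `phi(mu) = a0 + a1/mu` is fit by
#' least squares to genes with positive gene-wise estimates, and the final
#' per-gene dispersion is the geometric mean of the gene-wise estimate
#' (floored at 1e-8) and the trend value. Groups with fewer than two
#' replicates contribute nothing; if no group has replicates, the trend alone
#' is returned with a warning.
#'
#' @param norm_counts matrix of normalized counts (genes x samples).
#' @param groups factor/vector assigning samples to replicate groups.
#' @return Named numeric vector of per-gene dispersions, with the gene-wise
#'   and trend components in attributes `genewise` and `trend`.
#' @export
estimate_dispersion <- function(norm_counts, groups) {
  norm_counts <- as.matrix(norm_counts)
  groups <- as.factor(groups)
  stopifnot(length(groups) == ncol(norm_counts))
  num <- matrix(0, nrow(norm_counts), 0)
  wts <- numeric(0)
  est <- matrix(NA_real_, nrow(norm_counts), 0)
  for (g in levels(groups)) {
    idx <- which(groups == g)
    if (length(idx) < 2) next
    m <- rowMeans(norm_counts[, idx, drop = FALSE])
    v <- apply(norm_counts[, idx, drop = FALSE], 1, stats::var)
    phi_g <- pmax(0, (v - m) / pmax(m, 1e-9)^2)
    est <- cbind(est, phi_g)
    wts <- c(wts, length(idx) - 1)
  }
  mu <- rowMeans(norm_counts)
  if (ncol(est) == 0) {
    warning("no replicate group with >= 2 samples; dispersion is trend-only ",
            "and the trend cannot be estimated -- returning zeros")
    out <- stats::setNames(rep(1e-8, nrow(norm_counts)),
                           rownames(norm_counts))
    return(out)
  }
  genewise <- as.numeric(est %*% wts / sum(wts))
  pos <- genewise > 0 & mu > 0
  if (sum(pos) >= 10) {
    fit <- stats::lm.fit(cbind(1, 1 / mu[pos]), genewise[pos])
    trend <- pmax(fit$coefficients[1] + fit$coefficients[2] / pmax(mu, 1e-9),
                  1e-8)
  } else {
    trend <- rep(max(mean(genewise), 1e-8), length(genewise))
  }
  phi <- sqrt(pmax(genewise, 1e-8) * trend)
  attr(phi, "genewise") <- genewise
  attr(phi, "trend") <- trend
  stats::setNames(phi, rownames(norm_counts))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment `padj_(i) = min_{j >= i} min(1, m * p_(j) / j)` with the
#' original order restored; values outside `[0, 1]` are a hard error.
#'
#' @param p numeric vector of p-values.
#' @return Vector of adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Negative-binomial Wald test of one group versus a reference
#'
#' A deliberately transparent two-group test: the fold change is
#' `log2((m_t + eps) / (m_0 + eps))` of size-factor-normalized group means
#' (`eps = 0.5`), its standard error comes from the delta method with NB
#' variance `mu + phi * mu^2`, and `z = log2fc / se` is referred to the
#' standard normal, two-sided. Genes failing [filter_low_counts()] over the
#' samples involved are excluded. This is an explicit simplified analogue of a
#' DESeq2-style analysis; exact concordance with DESeq2 is a non-goal.
#'
#' @param cm an `mzt_counts` object containing treatment and reference
#'   samples.
#' @param treat,ref character vectors of sample ids.
#' @param phi optional per-gene dispersion (named); estimated from the two
#'   groups when `NULL`.
#' @param sf optional named size factors covering all samples; computed from
#'   the two groups when `NULL`.
#' @param eps pseudocount on normalized group means (default 0.5).
#' @param min_total low-count filter threshold (default 10).
#' @return data.frame with columns `gene_id`, `base_mean`, `mean_treat`,
#'   `mean_ref`, `log2fc`, `se`, `p`, `padj` (BH within this contrast).
#' @export
nb_wald_test <- function(cm, treat, ref, phi = NULL, sf = NULL, eps = 0.5,
                         min_total = 10) {
  stopifnot(inherits(cm, "mzt_counts"))
  ids <- c(treat, ref)
  missing <- setdiff(ids, colnames(cm$counts))
  if (length(missing))
    stop("sample(s) absent from matrix: ", paste(missing, collapse = ", "))
  if (!length(ref)) stop("reference samples missing")
  counts <- cm$counts[, ids, drop = FALSE]
  keep <- rowSums(counts) >= min_total
  counts <- counts[keep, , drop = FALSE]
  if (is.null(sf)) sf <- size_factors(counts)
  norm <- sweep(counts, 2, sf[ids], "/")
  if (is.null(phi)) {
    grp <- rep(c("treat", "ref"), c(length(treat), length(ref)))
    phi <- estimate_dispersion(norm, grp)
  }
  phi <- phi[rownames(counts)]
  phi[is.na(phi)] <- 1e-8
  m_t <- rowMeans(norm[, treat, drop = FALSE])
  m_0 <- rowMeans(norm[, ref, drop = FALSE])
  n_t <- length(treat)
  n_0 <- length(ref)
  log2fc <- log2((m_t + eps) / (m_0 + eps))
  var_t <- (m_t + phi * m_t^2) / (n_t * (m_t + eps)^2)
  var_0 <- (m_0 + phi * m_0^2) / (n_0 * (m_0 + eps)^2)
  se <- sqrt((var_t + var_0)) / log(2)
  se <- pmax(se, 1e-12)
  z <- log2fc / se
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(gene_id = rownames(counts),
             base_mean = (m_t * n_t + m_0 * n_0) / (n_t + n_0),
             mean_treat = m_t, mean_ref = m_0,
             log2fc = log2fc, se = se, p = p, padj = bh_adjust(p),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Timecourse differential expression versus the egg stage
#'
#' Runs [nb_wald_test()] for every post-egg timepoint against the egg (0 h)
#' reference within one library type and condition, with a single low-count
#' filter, one set of size factors and one dispersion fit (replicate groups =
#' timepoints) shared across contrasts, mirroring a per-library DESeq2-style
#' analysis.
#'
#' @param cm an `mzt_counts` object.
#' @param library_type `"polyA"` or `"ribodep"`.
#' @param condition condition of the test samples (default `"untreated"`).
#' @param ref_condition condition of the egg reference samples (default same).
#' @param min_total low-count filter threshold.
#' @return data.frame of per-contrast results with added columns
#'   `timepoint_h`, `library_type`, `condition`; `padj` is BH within each
#'   contrast.
#' @export
de_timecourse <- function(cm, library_type, condition = "untreated",
                          ref_condition = condition, min_total = 10) {
  sub <- subset_counts(cm, library_type = library_type,
                       condition = unique(c(condition, ref_condition)))
  sm <- sub$samples
  egg <- sm$sample_id[sm$timepoint_h == 0 & sm$condition %in% ref_condition]
  if (!length(egg)) stop("no egg (0 h) reference samples for ", library_type)
  sub <- filter_low_counts(sub, min_total)
  sf <- size_factors(sub$counts)
  norm <- sweep(sub$counts, 2, sf, "/")
  grp <- interaction(sm$timepoint_h, sm$condition, drop = TRUE)
  if (max(table(grp)) < 2)
    warning("single-replicate groups: dispersion is trend-limited")
  phi <- estimate_dispersion(norm, grp)
  tps <- sort(setdiff(unique(sm$timepoint_h[sm$condition %in% condition]), 0))
  out <- lapply(tps, function(t) {
    treat <- sm$sample_id[sm$timepoint_h == t & sm$condition %in% condition]
    res <- nb_wald_test(sub, treat, egg, phi = phi, sf = sf,
                        min_total = min_total)
    res$timepoint_h <- t
    res
  })
  out <- do.call(rbind, out)
  out$library_type <- library_type
  out$condition <- paste(condition, collapse = "+")
  out
}

#' Condition contrast at one timepoint
#'
#' Tests one condition against another at a fixed timepoint within a library
#' type (e.g. Triptolide versus DMSO at 7 h.p.f.).
#'
#' @inheritParams de_timecourse
#' @param timepoint_h collection time of the compared samples.
#' @param treat_condition,ref_condition the contrasted conditions.
#' @return data.frame as in [nb_wald_test()] plus the contrast columns.
#' @export
de_condition <- function(cm, library_type, timepoint_h, treat_condition,
                         ref_condition, min_total = 10) {
  sub <- subset_counts(cm, library_type = library_type,
                       condition = c(treat_condition, ref_condition),
                       timepoint_h = timepoint_h)
  sm <- sub$samples
  treat <- sm$sample_id[sm$condition == treat_condition]
  ref <- sm$sample_id[sm$condition == ref_condition]
  if (!length(treat) || !length(ref))
    stop("missing samples for contrast ", treat_condition, " vs ",
         ref_condition)
  res <- nb_wald_test(sub, treat, ref, min_total = min_total)
  res$timepoint_h <- timepoint_h
  res$library_type <- library_type
  res$condition <- paste0(treat_condition, "_vs_", ref_condition)
  res
}
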