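#' Configuration for the synthetic MZT study
#'
#' Defines the simulated study: paired poly(A)+ and rRNA-depleted libraries
#' for every sample over an egg/0.5/1-7 h.p.f. timecourse, a Triptolide
#' transcription-inhibition arm collected at the final timepoint (with a DMSO
#' mock equivalent to untreated), optional later poly(A)+-only larval
#' timepoints, and per-gene ground-truth trajectories of transcript abundance
#' `M(t)`, poly(A)-capture efficiency `A(t)` in `[0, 1]` and transcription
#' rate `Z(t)`. Counts are negative binomial with variance `mu + phi * mu^2`.
#'
#' @param n_genes number of genes (default 2000).
#' @param timepoints_h ordered collection times in hours post fertilization.
#' @param replicates biological replicates per timepoint and library.
#' @param depth expected reads per library (default 2e6).
#' @param nb_dispersion shared NB dispersion phi (default 0.05).
#' @param premrna_fraction fraction kappa of ribodep library mass available to
#'   unspliced pre-mRNA at full transcription (default 0.05).
#' @param class_mixture named proportions over the truth classes
#'   `maternal_stable`, `readenylated`, `deadenylated_only`, `cleared_early`,
#'   `cleared_late`, `zygotic_only`, `maternal_zygotic`, `histone_like`;
#'   must sum to 1.
#' @param seed integer seed; all randomness derives from it.
#' @param include_larval add poly(A)+-only larval timepoints (24/48/72 h,
#'   single libraries, as later-development references).
#' @param n_mirna number of planted zygotic miRNA precursors.
#' @param n_target_sites number of cleared_late genes receiving a planted
#'   22-nt antisense miRNA target site in their 3'UTR.
#' @param utr_motif RNA motif planted in a fraction of cleared-gene 3'UTRs
#'   (DNA alphabet).
#' @param motif_fraction fraction of cleared genes carrying `utr_motif`.
#' @return A validated list of class `mzt_simconfig`.
#' @export
sim_config <- function(n_genes = 2000,
                       timepoints_h = c(0, 0.5, 1, 2, 3, 4, 5, 6, 7),
                       replicates = 2,
                       depth = 2e6,
                       nb_dispersion = 0.05,
                       premrna_fraction = 0.05,
                       class_mixture = c(maternal_stable = 0.35,
                                         readenylated = 0.10,
                                         deadenylated_only = 0.10,
                                         cleared_early = 0.10,
                                         cleared_late = 0.10,
                                         zygotic_only = 0.10,
                                         maternal_zygotic = 0.10,
                                         histone_like = 0.05),
                       seed = 1,
                       include_larval = TRUE,
                       n_mirna = 2,
                       n_target_sites = 5,
                       utr_motif = "TATTTATT",
                       motif_fraction = 0.5) {
  known <- c("maternal_stable", "readenylated", "deadenylated_only",
             "cleared_early", "cleared_late", "zygotic_only",
             "maternal_zygotic", "histone_like")
  bad <- setdiff(names(class_mixture), known)
  if (length(bad))
    stop("unknown class label in mixture: ", paste(bad, collapse = ", "))
  if (abs(sum(class_mixture) - 1) > 1e-9)
    stop("class_mixture proportions must sum to 1")
  if (n_genes < 1 || depth < 1) stop("n_genes and depth must be >= 1")
  if (nb_dispersion <= 0) stop("nb_dispersion must be positive")
  if (premrna_fraction <= 0 || premrna_fraction >= 1)
    stop("premrna_fraction must lie in (0, 1)")
  if (any(!is.finite(timepoints_h)) || is.unsorted(timepoints_h))
    stop("timepoints_h must be finite and ordered")
  if (!0 %in% timepoints_h) stop("timepoints_h must include the egg (0 h)")
  cfg <- list(n_genes = as.integer(n_genes), timepoints_h = timepoints_h,
              replicates = as.integer(replicates), depth = depth,
              nb_dispersion = nb_dispersion,
              premrna_fraction = premrna_fraction,
              class_mixture = class_mixture[names(class_mixture)],
              seed = as.integer(seed), include_larval = include_larval,
              larval_timepoints_h = if (include_larval) c(24, 48, 72)
                                    else numeric(0),
              n_mirna = as.integer(n_mirna),
              n_target_sites = as.integer(n_target_sites),
              utr_motif = utr_motif, motif_fraction = motif_fraction)
  class(cfg) <- "mzt_simconfig"
  cfg
}

# piecewise-linear ramp from 0 at t0 to 1 at t1
ramp01 <- function(t, t0, t1) pmin(1, pmax(0, (t - t0) / (t1 - t0)))

#' Draw per-gene ground truth for the simulated study
#'
#' Gene classes are drawn from the configured mixture and each class carries a
#' deterministic trajectory family: `maternal_stable` (constant abundance,
#' capture 0.7), `readenylated` (capture 0.2 rising to 0.9 by 2 h),
#' `deadenylated_only` (capture 0.7 falling to 0.15 from an onset in
#' \{2,3,4\} h), `cleared_early` (deadenylation plus a 4-fold abundance drop
#' from 6-7 h), `cleared_late` (capture falls from 5 h, abundance drops
#' 4-fold at 7 h, transcription-dependent), `zygotic_only` (near-zero
#' maternal level, activating at \{2,3,4\} h and ramping over 3 h, capture
#' 0.9), `maternal_zygotic` (maternal baseline plus a zygotic increment of
#' 10-30% of baseline after activation), and `histone_like` (poly(A)-capture
#' 0.02, low maternal level, abundance doubling by 3 h and 18-fold by 4 h,
#' like non-adenylated replication-dependent histone mRNA).
#'
#' @param cfg an `mzt_simconfig`.
#' @return A list of class `mzt_truth`: `genes` (data.frame with `gene_id`,
#'   `class`, `baseline`, `t_deA`, `t_deg`, `t_act`,
#'   `transcription_dependent_clearance`), matrices `M`, `A`, `Z` and
#'   `M_trip`/`Z_trip` (genes x timepoints, Triptolide counterparts), and
#'   `timepoints_h` (including larval points when configured).
#' @export
simulate_truth <- function(cfg) {
  stopifnot(inherits(cfg, "mzt_simconfig"))
  set.seed(cfg$seed)
  n <- cfg$n_genes
  classes <- sample(names(cfg$class_mixture), n, replace = TRUE,
                    prob = cfg$class_mixture)
  gene_id <- sprintf("g%05d", seq_len(n))
  baseline <- exp(stats::rnorm(n, 0, 1))
  t_deA <- rep(NA_real_, n)
  t_deg <- rep(NA_real_, n)
  t_act <- rep(NA_real_, n)
  tdc <- rep(FALSE, n)
  inc <- stats::runif(n, 0.1, 0.3)   # zygotic increment, maternal_zygotic
  # transcription output at genome activation is independent of the maternal
  # pool size: re-activated genes transcribe at their own (lognormal) rate,
  # while their net exon-level increment stays capped by `inc`
  tscale <- exp(stats::rnorm(n, 0, 1))
  larv <- matrix(stats::runif(n * 3, 0.1, 1.5), n, 3)  # larval variety
  t_deA[classes %in% c("deadenylated_only", "cleared_early")] <-
    sample(c(2, 3, 4), sum(classes %in% c("deadenylated_only",
                                          "cleared_early")), replace = TRUE)
  t_deA[classes == "cleared_late"] <- 5
  t_deg[classes == "cleared_early"] <-
    sample(c(6, 7), sum(classes == "cleared_early"), replace = TRUE)
  t_deg[classes == "cleared_late"] <- 7
  t_act[classes %in% c("zygotic_only", "maternal_zygotic")] <-
    sample(c(2, 3, 4), sum(classes %in% c("zygotic_only",
                                          "maternal_zygotic")),
           replace = TRUE)
  tdc[classes == "cleared_late"] <- TRUE
  baseline[classes == "histone_like"] <-
    0.1 * baseline[classes == "histone_like"]
  tps <- c(cfg$timepoints_h, cfg$larval_timepoints_h)
  M <- A <- Z <- M_trip <- Z_trip <- matrix(
    0, n, length(tps), dimnames = list(gene_id, as.character(tps)))
  zygotic_floor <- 5e-4
  for (i in seq_len(n)) {
    b <- baseline[i]
    traj <- switch(classes[i],
      maternal_stable = {
        list(M = rep(b, length(tps)), A = rep(0.7, length(tps)),
             Z = rep(0, length(tps)), Mt = rep(b, length(tps)))
      },
      readenylated = {
        list(M = rep(b, length(tps)),
             A = 0.2 + 0.7 * ramp01(tps, 0, 2),
             Z = rep(0, length(tps)), Mt = rep(b, length(tps)))
      },
      deadenylated_only = {
        a <- ifelse(tps < t_deA[i], 0.7,
                    ifelse(tps < t_deA[i] + 1, 0.25, 0.15))
        list(M = rep(b, length(tps)), A = a, Z = rep(0, length(tps)),
             Mt = rep(b, length(tps)))
      },
      cleared_early = {
        a <- ifelse(tps < t_deA[i], 0.7,
                    ifelse(tps < t_deA[i] + 1, 0.25, 0.15))
        m <- ifelse(tps < t_deg[i], b, b / 4)
        # degradation is maternally catalysed: unchanged under Triptolide
        list(M = m, A = a, Z = rep(0, length(tps)), Mt = m)
      },
      cleared_late = {
        a <- ifelse(tps < 5, 0.7, ifelse(tps < 6, 0.25, 0.15))
        m <- ifelse(tps < 7, b, b / 4)
        # zygotically triggered degradation: M held at its 5 h value
        list(M = m, A = a, Z = rep(0, length(tps)), Mt = rep(b, length(tps)))
      },
      zygotic_only = {
        zy <- b * ramp01(tps, t_act[i], t_act[i] + 3)
        if (any(tps >= 24))
          zy[tps >= 24] <- b * larv[i, match(tps[tps >= 24], c(24, 48, 72))]
        m <- zygotic_floor * b + zy
        list(M = m, A = rep(0.9, length(tps)), Z = zy,
             Mt = rep(zygotic_floor * b, length(tps)))
      },
      maternal_zygotic = {
        zy <- inc[i] * b * ramp01(tps, t_act[i], t_act[i] + 3)
        list(M = b + zy, A = rep(0.7, length(tps)),
             Z = tscale[i] * ramp01(tps, t_act[i], t_act[i] + 3),
             Mt = rep(b, length(tps)))
      },
      histone_like = {
        mult <- stats::approx(x = c(0, 2, 3, 4),
                              y = c(1, 1, 2, 18), xout = pmin(tps, 4),
                              rule = 2)$y
        m <- b * mult
        list(M = m, A = rep(0.02, length(tps)), Z = pmax(m - b, 0),
             Mt = rep(b, length(tps)))
      })
    M[i, ] <- traj$M
    A[i, ] <- traj$A
    Z[i, ] <- traj$Z
    M_trip[i, ] <- traj$Mt
  }
  # larval decline of the maternal pool (single later-reference libraries)
  if (length(cfg$larval_timepoints_h)) {
    lar <- tps >= 24
    shrink <- classes %in% c("maternal_stable", "readenylated",
                             "deadenylated_only", "maternal_zygotic")
    M[shrink, lar] <- M[shrink, lar] * 0.5
    M[classes %in% c("cleared_early", "cleared_late"), lar] <-
      baseline[classes %in% c("cleared_early", "cleared_late")] / 8
  }
  genes <- data.frame(gene_id = gene_id, class = classes,
                      baseline = baseline, t_deA = t_deA, t_deg = t_deg,
                      t_act = t_act,
                      transcription_dependent_clearance = tdc,
                      zygotic_increment = ifelse(classes == "maternal_zygotic",
                                                 inc, NA_real_),
                      stringsAsFactors = FALSE)
  structure(list(genes = genes, M = M, A = A, Z = Z, M_trip = M_trip,
                 Z_trip = Z_trip, timepoints_h = tps, cfg = cfg),
            class = "mzt_truth")
}

# expected per-sample counts for one library. Returns list(exon, intron);
# intron is NULL for polyA. Pre-mRNA competes with mRNA for ribodep reads so
# that expected exon + intron counts sum to the library depth.
expected_counts <- function(truth, t_idx, library_type, condition,
                            exon_len, intron_len) {
  cfg <- truth$cfg
  trip <- condition == "triptolide"
  M <- if (trip) truth$M_trip[, t_idx] else truth$M[, t_idx]
  Z <- if (trip) truth$Z_trip[, t_idx] else truth$Z[, t_idx]
  if (library_type == "polyA") {
    mass <- M * truth$A[, t_idx] * exon_len
    return(list(exon = cfg$depth * mass / sum(mass), intron = NULL))
  }
  mass_ex <- M * exon_len
  mass_in <- cfg$premrna_fraction * Z * intron_len
  tot <- sum(mass_ex) + sum(mass_in)
  list(exon = cfg$depth * mass_ex / tot,
       intron = cfg$depth * mass_in / tot)
}

#' Draw negative-binomial counts for the whole study design
#'
#' Expected poly(A)+ counts are proportional to `M(t) * A(t) * exon_length`
#' and rRNA-depleted counts to `M(t) * exon_length`, renormalized to the
#' library depth per sample; in rRNA-depleted libraries unspliced pre-mRNA
#' additionally contributes intron-mapping reads proportional to
#' `kappa * Z(t) * intron_length`, competing for the same depth (nascent
#' transcripts are unadenylated, so poly(A)+ libraries see none). The
#' Triptolide arm at the final timepoint forces `Z = 0` everywhere, holds
#' transcription-dependent clearance at its pre-degradation level and leaves
#' deadenylation untouched; its DMSO mock re-uses untreated trajectories.
#' Counts are `rnbinom(mu, size = 1/phi)` and bit-reproducible for a fixed
#' configuration seed.
#'
#' @param truth an `mzt_truth` from [simulate_truth()].
#' @param cfg the same `mzt_simconfig` used to generate `truth`.
#' @return A list of class `mzt_sim`: `exon` (`mzt_counts`, both library
#'   types, untreated + DMSO + triptolide), `premrna` (`mzt_counts`, ribodep
#'   samples, exon + intron reads), `models` (`mzt_genemodels`), `truth`,
#'   and sequence/annotation tables filled in by [write_fixture()].
#' @export
simulate_counts <- function(truth, cfg) {
  stopifnot(inherits(truth, "mzt_truth"), inherits(cfg, "mzt_simconfig"))
  if (!identical(truth$cfg, cfg))
    stop("truth was generated from a different configuration")
  set.seed(cfg$seed + 1L)
  models <- simulate_gene_models(truth)
  exon_len <- gene_lengths(models, truth$genes$gene_id, "exon")
  intron_len <- gene_lengths(models, truth$genes$gene_id, "intron")
  phi <- cfg$nb_dispersion
  draw <- function(mu) stats::rnbinom(length(mu), mu = mu, size = 1 / phi)

  sheet <- list()
  exon_cols <- list()
  pre_cols <- list()
  add_sample <- function(id, t, lib, cond, rep_i, t_idx) {
    ex <- expected_counts(truth, t_idx, lib, cond, exon_len, intron_len)
    exon_cols[[id]] <<- draw(ex$exon)
    if (lib == "ribodep") {
      intr <- draw(ex$intron)
      pre_cols[[id]] <<- exon_cols[[id]] + intr
    }
    sheet[[id]] <<- data.frame(sample_id = id, timepoint_h = t,
                               library_type = lib, condition = cond,
                               replicate = rep_i, stringsAsFactors = FALSE)
  }
  tps <- truth$timepoints_h
  early <- cfg$timepoints_h
  for (t in early) {
    t_idx <- match(t, tps)
    for (lib in c("ribodep", "polyA")) {
      for (r in seq_len(cfg$replicates)) {
        id <- sprintf("%s_t%s_r%d", lib, format(t, trim = TRUE), r)
        add_sample(id, t, lib, "untreated", r, t_idx)
      }
    }
  }
  t_final <- max(early)
  t_idx <- match(t_final, tps)
  for (lib in c("ribodep", "polyA")) {
    for (r in seq_len(cfg$replicates)) {
      add_sample(sprintf("%s_t%s_DMSO_r%d", lib, t_final, r),
                 t_final, lib, "DMSO", r, t_idx)
      add_sample(sprintf("%s_t%s_trip_r%d", lib, t_final, r),
                 t_final, lib, "triptolide", r, t_idx)
    }
  }
  for (t in cfg$larval_timepoints_h) {
    add_sample(sprintf("polyA_t%s_r1", t), t, "polyA", "untreated", 1,
               match(t, tps))
  }
  sheet <- do.call(rbind, sheet)
  exon <- do.call(cbind, exon_cols)
  rownames(exon) <- truth$genes$gene_id
  exon_cm <- count_matrix(exon, sheet)
  pre <- do.call(cbind, pre_cols)
  rownames(pre) <- truth$genes$gene_id
  pre_cm <- count_matrix(pre, sheet[sheet$sample_id %in% colnames(pre), ])
  structure(list(exon = exon_cm, premrna = pre_cm, models = models,
                 truth = truth, cfg = cfg),
            class = "mzt_sim")
}

# gene models: histone-like genes are intronless single-exon genes (like
# replication-dependent histones); others carry 1-3 introns. A handful of
# genes per scaffold. Coordinates are 1-based inclusive as in a GTF.
simulate_gene_models <- function(truth) {
  n <- nrow(truth$genes)
  histone <- truth$genes$class == "histone_like"
  n_exons <- ifelse(histone, 1L, sample(2:4, n, replace = TRUE))
  mrna_len <- ifelse(histone,
                     3 * sample(120:180, n, replace = TRUE) + 150,
                     3 * sample(200:700, n, replace = TRUE) + 150)
  rows <- vector("list", n)
  per_scaffold <- 10
  pos <- 1
  scaf_i <- 1
  on_scaf <- 0
  for (i in seq_len(n)) {
    k <- n_exons[i]
    cuts <- if (k > 1) sort(sample(seq(50, mrna_len[i] - 50, by = 10),
                                   k - 1)) else integer(0)
    ex_len <- diff(c(0, cuts, mrna_len[i]))
    in_len <- if (k > 1) sample(200:2000, k - 1, replace = TRUE) else integer(0)
    start <- pos
    exon_rows <- list()
    for (e in seq_len(k)) {
      exon_rows[[e]] <- c(start, start + ex_len[e] - 1)
      start <- start + ex_len[e] + if (e < k) in_len[e] else 0
    }
    rows[[i]] <- data.frame(
      scaffold = sprintf("scaf%04d", scaf_i),
      start = vapply(exon_rows, `[`, numeric(1), 1),
      end = vapply(exon_rows, `[`, numeric(1), 2),
      strand = sample(c("+", "-"), 1),
      gene_id = truth$genes$gene_id[i], stringsAsFactors = FALSE)
    pos <- start + 5000
    on_scaf <- on_scaf + 1
    if (on_scaf == per_scaffold) {
      scaf_i <- scaf_i + 1
      on_scaf <- 0
      pos <- 1
    }
  }
  gtf <- do.call(rbind, rows)
  tmp <- tempfile(fileext = ".gtf")
  on.exit(unlink(tmp))
  write_gtf(gtf, tmp)
  load_gene_models(tmp)
}

write_gtf <- function(df, path) {
  lines <- sprintf(
    '%s\tmztseq_sim\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s.t1";',
    df$scaffold, as.integer(df$start), as.integer(df$end), df$strand,
    df$gene_id, df$gene_id)
  writeLines(lines, path)
  invisible(path)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp_chr <- function(x) {
  chartr("ACGTU", "TGCAA",
         vapply(x, function(s) paste(rev(strsplit(s, "")[[1]]),
                                     collapse = ""), character(1),
                USE.NAMES = FALSE))
}

all_sense_codons <- function() {
  codons <- as.vector(outer(as.vector(outer(c("A", "C", "G", "T"),
                                            c("A", "C", "G", "T"), paste0)),
                            c("A", "C", "G", "T"), paste0))
  setdiff(codons, c("TAA", "TAG", "TGA"))
}

# CDS from non-stop codons, opened with ATG and closed with TAA. Codon usage
# is biased (shared across genes), as in real transcriptomes: a codon
# adaptation index against an unbiased reference would be meaningless.
random_cds <- function(n_codons, codon_weights) {
  codons <- all_sense_codons()
  paste0("ATG", paste(sample(codons, n_codons - 2, replace = TRUE,
                             prob = codon_weights),
                      collapse = ""), "TAA")
}

#' Write the simulated study to disk as a loadable fixture
#'
#' Emits everything the pipeline consumes: exon counts for all samples
#' (`counts.tsv`), pre-mRNA counts for the rRNA-depleted samples
#' (`premrna_counts.tsv`), the sample sheet (`samples.tsv`), the gene
#' annotation (`genes.gtf`), mRNA/CDS/3'UTR FASTA files, a reference
#' mature-miRNA FASTA (`H. echinata`-style homologs of the planted miRNAs,
#' each with one mismatch, plus unrelated decoys), a synthetic GO map, a
#' histone annotation table, and the ground-truth table (`truth.tsv`, columns
#' `gene_id`, `class`, `t_deA`, `t_deg`, `t_act`,
#' `transcription_dependent_clearance` plus planting records).
#'
#' Planted sequence elements: each simulated miRNA precursor (mature + 8-nt
#' loop + reverse complement, a perfect hairpin) is embedded in the 3'UTR of
#' a zygotically activated host gene; a 22-nt antisense target site of each
#' miRNA is planted in the 3'UTRs of a configurable number of cleared_late
#' genes; an AU-rich motif is planted in a fraction of cleared-gene 3'UTRs.
#'
#' @param sim an `mzt_sim` from [simulate_counts()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a named list of the written paths.
#' @export
write_fixture <- function(sim, out_dir) {
  stopifnot(inherits(sim, "mzt_sim"))
  cfg <- sim$cfg
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory ", out_dir)
  set.seed(cfg$seed + 2L)
  truth <- sim$truth
  genes <- truth$genes
  models <- sim$models
  exon_len <- gene_lengths(models, genes$gene_id, "exon")

  # --- sequences -----------------------------------------------------------
  utr_len <- pmax(60, pmin(300, round(exon_len * 0.15)))
  cds_codons <- pmax(50, floor((exon_len - utr_len) / 3))
  codon_weights <- exp(stats::rnorm(length(all_sense_codons()), 0, 0.7))
  cds <- vapply(cds_codons, random_cds, character(1),
                codon_weights = codon_weights)
  utr <- vapply(utr_len, random_dna, character(1))
  names(cds) <- names(utr) <- genes$gene_id

  # miRNA precursors in zygotic hosts
  zyg <- genes$gene_id[genes$class == "zygotic_only"]
  n_mir <- min(cfg$n_mirna, length(zyg))
  hosts <- if (n_mir) sample(zyg, n_mir) else character(0)
  mature <- vapply(seq_len(n_mir), function(i) random_dna(22), character(1))
  if (n_mir) names(mature) <- sprintf("sim-miR-%d", seq_len(n_mir))
  for (i in seq_len(n_mir)) {
    hairpin <- paste0(mature[i], "GCAAAAGC", revcomp_chr(mature[i]))
    u <- utr[hosts[i]]
    mid <- max(1, nchar(u) %/% 2)
    utr[hosts[i]] <- paste0(substr(u, 1, mid), hairpin,
                            substr(u, mid + 1, nchar(u)))
  }
  # reference miRNAs: homolog with 1 mismatch per planted mature + decoys
  mutate1 <- function(s) {
    p <- sample(nchar(s), 1)
    old <- substr(s, p, p)
    substr(s, p, p) <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
    s
  }
  ref_mirnas <- c(
    if (n_mir) stats::setNames(vapply(mature, mutate1, character(1)),
                               sprintf("ref-miR-%d", seq_len(n_mir))),
    stats::setNames(vapply(1:3, function(i) random_dna(22), character(1)),
                    sprintf("decoy-miR-%d", 1:3)))

  # planted antisense target sites in cleared_late 3'UTRs
  late <- genes$gene_id[genes$class == "cleared_late"]
  target_of <- stats::setNames(rep(NA_character_, nrow(genes)),
                               genes$gene_id)
  if (n_mir && cfg$n_target_sites > 0 && length(late)) {
    tg <- sample(late, min(cfg$n_target_sites, length(late)))
    for (j in seq_along(tg)) {
      mir <- names(mature)[1 + (j - 1) %% n_mir]
      site <- revcomp_chr(mature[[mir]])
      u <- utr[tg[j]]
      at <- max(1, nchar(u) %/% 3)
      utr[tg[j]] <- paste0(substr(u, 1, at), site,
                           substr(u, at + 1, nchar(u)))
      target_of[tg[j]] <- mir
    }
  }
  # AU-rich motif in a fraction of cleared-gene UTRs
  cleared <- genes$gene_id[genes$class %in% c("cleared_early",
                                              "cleared_late")]
  motif_in <- sample(cleared, round(cfg$motif_fraction * length(cleared)))
  for (g in motif_in)
    utr[g] <- paste0(cfg$utr_motif, substr(utr[g], nchar(cfg$utr_motif) + 1,
                                           nchar(utr[g])))
  mrna <- paste0(cds, utr)
  names(mrna) <- genes$gene_id

  # --- GO map and histone annotation --------------------------------------
  terms <- sprintf("GO:%07d", seq_len(40))
  go <- do.call(rbind, lapply(genes$gene_id, function(g) {
    k <- stats::rpois(1, 1.5)
    if (!k) return(NULL)
    data.frame(gene_id = g, term = sample(terms, min(k, 10)),
               stringsAsFactors = FALSE)
  }))
  hist_genes <- genes$gene_id[genes$class == "histone_like"]
  nuc <- data.frame(gene_id = hist_genes[stats::runif(length(hist_genes)) < 0.9],
                    term = "GO:0000786", stringsAsFactors = FALSE)
  go <- rbind(go, nuc)
  go <- go[order(go$gene_id, go$term), ]
  annot <- data.frame(gene_id = genes$gene_id,
                      annot_class = ifelse(genes$class == "histone_like",
                                           "histone", "other"),
                      stringsAsFactors = FALSE)

  # --- write ---------------------------------------------------------------
  paths <- list(
    counts = file.path(out_dir, "counts.tsv"),
    premrna = file.path(out_dir, "premrna_counts.tsv"),
    samples = file.path(out_dir, "samples.tsv"),
    gtf = file.path(out_dir, "genes.gtf"),
    mrna = file.path(out_dir, "mrna.fa"),
    cds = file.path(out_dir, "cds.fa"),
    utr3 = file.path(out_dir, "utr3.fa"),
    mirna_ref = file.path(out_dir, "mirna_ref.fa"),
    go = file.path(out_dir, "go_terms.tsv"),
    annot = file.path(out_dir, "annotations.tsv"),
    truth = file.path(out_dir, "truth.tsv"))
  write_counts(sim$exon, paths$counts, paths$samples)
  write_counts(sim$premrna, paths$premrna)
  gtf_rows <- do.call(rbind, lapply(genes$gene_id, function(g) {
    ex <- attr(models, "exons")[[g]]
    i <- match(g, models$gene_id)
    data.frame(scaffold = models$scaffold[i], start = ex[, 1] + 1,
               end = ex[, 2], strand = models$strand[i], gene_id = g,
               stringsAsFactors = FALSE)
  }))
  write_gtf(gtf_rows, paths$gtf)
  write_fasta <- function(x, path) {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(x), path,
                                width = 70)
  }
  write_fasta(mrna, paths$mrna)
  write_fasta(cds, paths$cds)
  write_fasta(utr, paths$utr3)
  write_fasta(ref_mirnas, paths$mirna_ref)
  utils::write.table(go, paths$go, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(annot, paths$annot, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth_out <- genes[, c("gene_id", "class", "t_deA", "t_deg", "t_act",
                         "transcription_dependent_clearance")]
  truth_out$mirna_host <- ifelse(genes$gene_id %in% hosts,
                                 names(mature)[match(genes$gene_id, hosts)],
                                 NA_character_)
  truth_out$mirna_mature <- ifelse(genes$gene_id %in% hosts,
                                   mature[match(genes$gene_id, hosts)],
                                   NA_character_)
  truth_out$planted_target_of <- target_of
  truth_out$utr_motif_planted <- genes$gene_id %in% motif_in
  utils::write.table(truth_out, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Simulate and write the default synthetic study in one call
#'
#' @param out_dir output directory.
#' @param cfg an `mzt_simconfig` (default [sim_config()]).
#' @return The `mzt_sim` object, invisibly, with the written paths in the
#'   `paths` attribute.
#' @export
simulate_study <- function(out_dir, cfg = sim_config()) {
  truth <- simulate_truth(cfg)
  sim <- simulate_counts(truth, cfg)
  attr(sim, "paths") <- write_fixture(sim, out_dir)
  invisible(sim)
}
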