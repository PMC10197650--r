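#' Pipeline configuration with every analysis threshold
#'
#' One flat configuration object whose keys carry the study's canonical
#' thresholds as defaults: maternal contribution at `maternal_tpm = 1` TPM
#' (egg, rRNA-depleted), pure-zygotic band below `zygotic_tpm = 0.5` TPM,
#' low-count filter at `low_count = 10` reads, intronic retention at
#' `intron_rpkm = 0.5`, clearance fold `clear_fold = 2`, oscillation cap
#' `oscillation = 1.5`, stable-reference band `stable_fold = 1.25`,
#' stage-specificity bounds `stage_low = 1` / `stage_high = 5` TPM,
#' significance `alpha = 0.05`, window flagging `window_fold = 3`, and the
#' miRNA thresholds (homology mismatches, stem fraction, G:U weight, target
#' score slack).
#'
#' @param ... overrides of the defaults listed above (also: `kmer_range`,
#'   `mirna_max_mismatch`, `stem_fraction`, `gu_weight`, `target_score_slack`,
#'   `cai_reference_n`, `seed`).
#' @return Validated list of class `mzt_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(maternal_tpm = 1.0, zygotic_tpm = 0.5, low_count = 10,
              intron_rpkm = 0.5, clear_fold = 2.0, oscillation = 1.5,
              stable_fold = 1.25, stage_low = 1.0, stage_high = 5.0,
              alpha = 0.05, window_fold = 3.0, mirna_max_mismatch = 2,
              stem_fraction = 0.6, gu_weight = 0.5, target_score_slack = 4,
              kmer_range = 5:8, cai_reference_n = 100, seed = 1)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop_config("unknown configuration key(s): ",
                paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  scalars <- setdiff(names(cfg), "kmer_range")
  for (k in scalars) {
    v <- cfg[[k]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0)
      stop_config("configuration key '", k,
                  "' must be a single finite positive number")
  }
  if (cfg$alpha >= 1) stop_config("alpha must be below 1")
  if (any(cfg$kmer_range < 1)) stop_config("kmer_range must be positive")
  class(cfg) <- "mzt_config"
  cfg
}

stop_config <- function(...) {
  stop(structure(class = c("mzt_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_input <- function(...) {
  stop(structure(class = c("mzt_input_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

read_fasta_named <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full MZT analysis pipeline on a fixture directory
#'
#' Executes the stages in order -- differential expression (both library
#' types, timecourse vs egg plus Triptolide-vs-mock), intron-signal genome
#' activation, clearance classification and inhibition testing, stage/GO/CAI/
#' k-mer downstream analyses, and miRNA discovery with target prediction --
#' reading only the files written by [write_fixture()] (the ground-truth
#' table is never read) and writing one TSV per result plus a deterministic
#' `log.txt` echoing package version, seed and parameters. Re-running with
#' the same inputs and configuration reproduces every output byte for byte.
#'
#' @param fixture_dir directory holding the input files (`counts.tsv`,
#'   `premrna_counts.tsv`, `samples.tsv`, `genes.gtf`, `mrna.fa`, `cds.fa`,
#'   `utr3.fa`, `mirna_ref.fa`, `go_terms.tsv`, `annotations.tsv`).
#' @param out_dir output directory (created if needed).
#' @param config an `mzt_config` (default [pipeline_config()]).
#' @return Invisibly, a named list with every stage's in-memory result and
#'   the output paths under `$paths`.
#' @export
run_pipeline <- function(fixture_dir, out_dir,
                         config = pipeline_config()) {
  if (!inherits(config, "mzt_config"))
    stop_config("config must come from pipeline_config()")
  need <- c("counts.tsv", "premrna_counts.tsv", "samples.tsv", "genes.gtf",
            "mrna.fa", "cds.fa", "utr3.fa", "mirna_ref.fa", "go_terms.tsv",
            "annotations.tsv")
  missing <- need[!file.exists(file.path(fixture_dir, need))]
  if (length(missing))
    stop_input("fixture lacks: ", paste(missing, collapse = ", "))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop_input("cannot create output directory ", out_dir)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (inherits(e, "mzt_config_error") || inherits(e, "mzt_input_error"))
        stop(e)
      stop(structure(class = c("mzt_stage_error", "error", "condition"),
                     list(message = paste0("stage '", name, "' failed: ",
                                           conditionMessage(e)),
                          call = NULL)))
    })
  }
  res <- list(paths = list())
  emit <- function(df, file) {
    p <- file.path(out_dir, file)
    write_tsv(df, p)
    res$paths[[file]] <<- p
  }

  ## -- load ----------------------------------------------------------------
  inputs <- stage("load", {
    cm <- load_counts(file.path(fixture_dir, "counts.tsv"),
                      file.path(fixture_dir, "samples.tsv"))
    sheet_pre <- cm$samples[cm$samples$library_type == "ribodep", ]
    pre <- load_counts(file.path(fixture_dir, "premrna_counts.tsv"),
                       sheet_pre)
    models <- load_gene_models(file.path(fixture_dir, "genes.gtf"))
    list(cm = cm, pre = pre, models = models,
         mrna = read_fasta_named(file.path(fixture_dir, "mrna.fa")),
         cds = read_fasta_named(file.path(fixture_dir, "cds.fa")),
         utr3 = read_fasta_named(file.path(fixture_dir, "utr3.fa")),
         mirna_ref = read_fasta_named(file.path(fixture_dir, "mirna_ref.fa")),
         go = utils::read.delim(file.path(fixture_dir, "go_terms.tsv"),
                                stringsAsFactors = FALSE),
         annot = utils::read.delim(file.path(fixture_dir, "annotations.tsv"),
                                   stringsAsFactors = FALSE))
  })
  cm <- inputs$cm
  ab <- stage("abundance", compute_abundance(cm, inputs$models))
  mock <- if ("DMSO" %in% cm$samples$condition) "DMSO" else "untreated"
  has_trip <- "triptolide" %in% cm$samples$condition
  # the paired-library timecourse spans the timepoints with ribodep samples;
  # later poly(A)+-only samples are later-development references
  early_tps <- sort(unique(
    cm$samples$timepoint_h[cm$samples$library_type == "ribodep"]))
  t_final <- if (has_trip)
    max(cm$samples$timepoint_h[cm$samples$condition == "triptolide"])
  else max(early_tps)

  ## -- diffexp -------------------------------------------------------------
  de <- stage("diffexp", {
    de_pa <- de_timecourse(subset_counts(cm, library_type = "polyA",
                                         timepoint_h = early_tps),
                           "polyA", min_total = config$low_count)
    de_rd <- de_timecourse(subset_counts(cm, library_type = "ribodep"),
                           "ribodep", min_total = config$low_count)
    larval_tps <- setdiff(unique(cm$samples$timepoint_h), early_tps)
    de_pa_all <- if (length(larval_tps))
      suppressWarnings(de_timecourse(subset_counts(cm,
                                                   library_type = "polyA"),
                                     "polyA",
                                     min_total = config$low_count))
    else de_pa
    de_trip_pa <- if (has_trip)
      de_condition(cm, "polyA", t_final, "triptolide", mock,
                   min_total = config$low_count)
    de_trip_rd <- if (has_trip)
      de_condition(cm, "ribodep", t_final, "triptolide", mock,
                   min_total = config$low_count)
    # fold changes vs egg under inhibition, for the clearance comparison
    de_tripegg_pa <- if (has_trip)
      de_timecourse(subset_counts(cm, library_type = "polyA",
                                  timepoint_h = c(0, t_final)),
                    "polyA", condition = "triptolide",
                    ref_condition = "untreated",
                    min_total = config$low_count)
    de_tripegg_rd <- if (has_trip)
      de_timecourse(subset_counts(cm, library_type = "ribodep",
                                  timepoint_h = c(0, t_final)),
                    "ribodep", condition = "triptolide",
                    ref_condition = "untreated",
                    min_total = config$low_count)
    list(polyA = de_pa, polyA_all = de_pa_all, ribodep = de_rd,
         trip_polyA = de_trip_pa, trip_ribodep = de_trip_rd,
         tripegg_polyA = de_tripegg_pa, tripegg_ribodep = de_tripegg_rd)
  })
  emit(de$polyA, "de_polyA.tsv")
  emit(de$ribodep, "de_ribodep.tsv")
  if (!is.null(de$trip_polyA)) {
    emit(de$trip_polyA, "de_triptolide_polyA.tsv")
    emit(de$trip_ribodep, "de_triptolide_ribodep.tsv")
  }

  ## -- zga -----------------------------------------------------------------
  zga <- stage("zga", {
    rd_untreated <- subset_counts(cm, library_type = "ribodep",
                                  condition = "untreated")
    pre_untreated <- subset_counts(inputs$pre, condition = "untreated")
    itab <- build_intron_table(pre_untreated, rd_untreated, inputs$models,
                               min_rpkm = config$intron_rpkm)
    cde <- combined_de(rd_untreated, itab, min_total = config$low_count)
    calls <- classify_activation(cde, ab,
                                 maternal_tpm = config$maternal_tpm,
                                 zygotic_tpm = config$zygotic_tpm,
                                 alpha = config$alpha)
    frac <- class_fraction_trajectory(ab, stats::setNames(
      inputs$annot$annot_class, inputs$annot$gene_id))
    list(intron_table = itab, combined_de = cde, calls = calls,
         fractions = frac)
  })
  emit(data.frame(gene_id = rownames(zga$intron_table$counts$counts),
                  zga$intron_table$counts$counts, check.names = FALSE),
       "intron_counts.tsv")
  emit(zga$combined_de, "de_combined_intron.tsv")
  emit(zga$calls, "activation_calls.tsv")
  emit(zga$fractions, "class_fractions.tsv")

  ## -- clearance -----------------------------------------------------------
  clr <- stage("clearance", {
    fd_pa <- first_decrease(de$polyA, alpha = config$alpha,
                            fold = config$clear_fold,
                            oscillation = config$oscillation)
    fd_rd <- first_decrease(de$ribodep, alpha = config$alpha,
                            fold = config$clear_fold,
                            oscillation = config$oscillation)
    calls <- classify_tail_dynamics(fd_pa, fd_rd, de$polyA, de$ribodep,
                                    alpha = config$alpha,
                                    fold = config$clear_fold)
    bubble <- bubble_summary(calls)
    no_trip <- data.frame(gene_id = character(0), padj = numeric(0))
    stable <- stable_reference_set(ab,
                                   if (is.null(de$trip_polyA)) no_trip
                                   else de$trip_polyA,
                                   fold = config$stable_fold,
                                   alpha = config$alpha)
    inhib <- NULL
    if (!is.null(de$tripegg_polyA)) {
      early_genes <- calls$gene_id[!is.na(calls$t_down_polyA) &
                                     calls$t_down_polyA >= 2 &
                                     calls$t_down_polyA <= 4]
      late_genes <- calls$gene_id[!is.na(calls$t_down_polyA) &
                                    calls$t_down_polyA >= 5]
      lfc_of <- function(d) stats::setNames(d$log2fc, d$gene_id)
      dmso_pa <- lfc_of(de$polyA[de$polyA$timepoint_h == t_final, ])
      dmso_rd <- lfc_of(de$ribodep[de$ribodep$timepoint_h == t_final, ])
      trip_pa <- lfc_of(de$tripegg_polyA)
      trip_rd <- lfc_of(de$tripegg_ribodep)
      inhib <- rbind(
        inhibition_comparison(trip_pa[early_genes], dmso_pa[early_genes],
                              "early_polyA"),
        inhibition_comparison(trip_rd[early_genes], dmso_rd[early_genes],
                              "early_ribodep"),
        inhibition_comparison(trip_pa[late_genes], dmso_pa[late_genes],
                              "late_polyA"),
        inhibition_comparison(trip_rd[late_genes], dmso_rd[late_genes],
                              "late_ribodep"))
    }
    list(fd_polyA = fd_pa, fd_ribodep = fd_rd, calls = calls,
         bubble = bubble, stable = stable, inhibition = inhib)
  })
  emit(clr$calls, "clearance_calls.tsv")
  emit(as.data.frame.matrix(clr$bubble), "bubble_matrix.tsv")
  emit(data.frame(gene_id = clr$stable), "stable_reference_set.tsv")
  if (!is.null(clr$inhibition)) emit(clr$inhibition, "inhibition_tests.tsv")

  ## -- downstream ----------------------------------------------------------
  dwn <- stage("downstream", {
    clusters <- stage_specific_clusters(ab, de$polyA_all,
                                        low = config$stage_low,
                                        high = config$stage_high,
                                        alpha = config$alpha)
    go <- tryCatch(go_chi2_enrichment(clusters, inputs$go),
                   error = function(e) NULL)
    cleared <- clr$calls$gene_id[!is.na(clr$calls$t_down_polyA)]
    egg_tpm <- rowMeans(ab$tpm[, ab$samples$sample_id[
      ab$samples$timepoint_h == 0 & ab$samples$library_type == "ribodep"],
      drop = FALSE])
    maternal <- names(egg_tpm)[egg_tpm >= config$maternal_tpm]
    ref_pool <- intersect(clr$stable, maternal)
    ref <- ref_pool[order(egg_tpm[ref_pool],
                          decreasing = TRUE)][
                            seq_len(min(config$cai_reference_n,
                                        length(ref_pool)))]
    cai <- codon_adaptation_index(inputs$cds, ref)
    caicmp <- cai_compare(cai, cleared, clr$stable)
    km <- kmer_enrichment(inputs$utr3[intersect(cleared,
                                                names(inputs$utr3))],
                          inputs$utr3[intersect(clr$stable,
                                                names(inputs$utr3))],
                          k_range = config$kmer_range)
    list(clusters = clusters, go = go, cai = cai, cai_compare = caicmp,
         kmers = km, cai_reference = ref, cleared = cleared)
  })
  emit(dwn$clusters, "stage_clusters.tsv")
  if (!is.null(dwn$go)) emit(dwn$go, "go_enrichment.tsv")
  emit(data.frame(gene_id = names(dwn$cai), cai = as.numeric(dwn$cai)),
       "cai.tsv")
  emit(utils::head(dwn$kmers[order(dwn$kmers$p), ], 200),
       "kmer_enrichment.tsv")

  ## -- mirna ---------------------------------------------------------------
  mir <- stage("mirna", {
    hits <- match_mirna_homology(inputs$mirna_ref, inputs$mrna,
                                 max_mismatch = config$mirna_max_mismatch)
    inhib_de <- if (is.null(de$trip_ribodep))
      data.frame(gene_id = character(0), padj = numeric(0),
                 log2fc = numeric(0))
    else de$trip_ribodep
    cand <- candidate_filter(hits, de$ribodep, inhib_de, inputs$mrna,
                             min_stem_fraction = config$stem_fraction,
                             alpha = config$alpha)
    passing <- cand[cand$candidate, , drop = FALSE]
    targets <- predict_targets(passing, inputs$mrna,
                               cleared_set = dwn$cleared,
                               stable_set = clr$stable,
                               gu_weight = config$gu_weight,
                               score_slack = config$target_score_slack)
    diagrams <- if (nrow(targets))
      vapply(seq_len(nrow(targets)), function(i)
        render_duplex(targets[i, , drop = FALSE]), character(1))
    else character(0)
    list(hits = hits, candidates = cand, targets = targets,
         diagrams = diagrams)
  })
  emit(mir$candidates, "mirna_candidates.tsv")
  emit(as.data.frame(mir$targets), "mirna_targets.tsv")
  writeLines(paste(mir$diagrams, collapse = "\n\n"),
             file.path(out_dir, "mirna_duplexes.txt"))
  res$paths[["mirna_duplexes.txt"]] <- file.path(out_dir,
                                                 "mirna_duplexes.txt")

  ## -- log -----------------------------------------------------------------
  cfg_flat <- vapply(config, function(v) paste(v, collapse = ","),
                     character(1))
  log_lines <- c(
    paste0("mztseq version: ",
           as.character(utils::packageVersion("mztseq"))),
    paste0("seed: ", config$seed),
    paste0("samples: ", nrow(cm$samples)),
    paste0("genes: ", nrow(cm$counts)),
    sprintf("param %s = %s", names(cfg_flat), cfg_flat))
  writeLines(log_lines, file.path(out_dir, "log.txt"))
  res$paths[["log.txt"]] <- file.path(out_dir, "log.txt")

  res$inputs <- inputs
  res$abundance <- ab
  res$de <- de
  res$zga <- zga
  res$clearance <- clr
  res$downstream <- dwn
  res$mirna <- mir
  invisible(res)
}
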