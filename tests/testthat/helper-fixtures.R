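# Shared fixtures. The default-scale study is expensive, so it is generated
# once per test run and cached; small builders are cheap and rebuilt freely.

.fixture_cache <- new.env(parent = emptyenv())

# a small paired-library study for smoke tests
small_study <- function() {
  if (!is.null(.fixture_cache$small)) return(.fixture_cache$small)
  fx <- file.path(tempdir(), "mztseq_small_fixture")
  cfg <- sim_config(n_genes = 300, seed = 11)
  sim <- simulate_study(fx, cfg)
  .fixture_cache$small <- list(dir = fx, sim = sim, cfg = cfg)
  .fixture_cache$small
}

# the full default-configuration study plus its pipeline run (shared by the
# acceptance tests)
default_study <- function() {
  if (!is.null(.fixture_cache$default)) return(.fixture_cache$default)
  fx <- file.path(tempdir(), "mztseq_default_fixture")
  out <- file.path(tempdir(), "mztseq_default_out")
  cfg <- sim_config(seed = 1)
  sim <- simulate_study(fx, cfg)
  res <- suppressWarnings(suppressMessages(run_pipeline(fx, out)))
  .fixture_cache$default <- list(dir = fx, out = out, sim = sim, cfg = cfg,
                                 res = res)
  .fixture_cache$default
}

# hand-built count matrix
make_cm <- function(counts, timepoint_h, library_type = "ribodep",
                    condition = "untreated", replicate = NULL) {
  n <- ncol(counts)
  if (is.null(replicate)) {
    key <- paste(timepoint_h, library_type, condition)
    replicate <- stats::ave(seq_len(n), key, FUN = seq_along)
  }
  ids <- sprintf("s%02d", seq_len(n))
  colnames(counts) <- ids
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("g%03d", seq_len(nrow(counts)))
  count_matrix(counts, data.frame(
    sample_id = ids, timepoint_h = timepoint_h,
    library_type = library_type, condition = condition,
    replicate = replicate, stringsAsFactors = FALSE))
}

# gene models from an in-memory exon table (1-based inclusive, GTF-style)
make_models <- function(df) {
  tmp <- tempfile(fileext = ".gtf")
  on.exit(unlink(tmp))
  lines <- sprintf(
    '%s\ttest\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s.t";',
    df$scaffold, df$start, df$end,
    if (is.null(df$strand)) "+" else df$strand, df$gene_id, df$gene_id)
  writeLines(lines, tmp)
  load_gene_models(tmp)
}

# NB counts for a two-group design, used in DE unit tests
nb_two_group <- function(n_genes, mu1, mu2, phi, n_per_group, seed = 1) {
  set.seed(seed)
  k1 <- matrix(stats::rnbinom(n_genes * n_per_group, mu = rep(mu1, n_per_group),
                              size = 1 / phi), n_genes)
  k2 <- matrix(stats::rnbinom(n_genes * n_per_group, mu = rep(mu2, n_per_group),
                              size = 1 / phi), n_genes)
  cbind(k1, k2)
}
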