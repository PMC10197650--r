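stage_ab <- function(tpm, tps) {
  structure(list(
    tpm = tpm, rpkm = tpm,
    samples = data.frame(sample_id = colnames(tpm), timepoint_h = tps,
                         library_type = "polyA", condition = "untreated",
                         replicate = 1)), class = "mzt_abundance")
}

test_that("stage specificity needs a low stage, a high stage and
          significance", {
  tpm <- rbind(spec = c(0.5, 10, 0.2, 0.1, 0.1),
               min_too_high = c(2, 10, 2, 2, 2),
               max_too_low = c(0.5, 4, 0.2, 0.1, 0.1),
               not_sig = c(0.5, 10, 0.2, 0.1, 0.1))
  colnames(tpm) <- sprintf("s%02d", 1:5)
  ab <- stage_ab(tpm, c(0, 5, 24, 48, 72))
  de <- data.frame(gene_id = c("spec", "min_too_high", "max_too_low"),
                   padj = 0.001)
  cl <- stage_specific_clusters(ab, de)
  flag <- setNames(cl$is_stage_specific, cl$gene_id)
  expect_true(flag[["spec"]])
  expect_equal(cl$peak_stage[cl$gene_id == "spec"], "gastrula")
  expect_false(flag[["min_too_high"]])
  expect_false(flag[["max_too_low"]])
  expect_false(flag[["not_sig"]])
})

test_that("the chi-squared enrichment matches the textbook formula", {
  # 100 stage-specific genes evenly over five stages
  genes <- sprintf("g%03d", 1:100)
  cl <- data.frame(gene_id = genes,
                   peak_stage = rep(c("egg", "gastrula", "24", "48", "72"),
                                    each = 20),
                   is_stage_specific = TRUE, stringsAsFactors = FALSE)
  attr(cl, "stages") <- c("egg", "gastrula", "24", "48", "72")
  # uniformly spread term: statistic 0, p 1
  uni <- data.frame(gene_id = genes[c(1, 21, 41, 61, 81)], term = "T:uni")
  # concentrated term: all 10 in the egg stage
  conc <- data.frame(gene_id = genes[1:10], term = "T:conc")
  res <- go_chi2_enrichment(cl, rbind(uni, conc))
  expect_equal(res$statistic[res$term == "T:uni"], 0, tolerance = 1e-12)
  expect_equal(res$p[res$term == "T:uni"], 1)
  expect_equal(res$df, rep(4, 2))
  tab <- rbind(c(10, 0, 0, 0, 0), c(10, 20, 20, 20, 20))
  expect_equal(res$statistic[res$term == "T:conc"], chi2_oracle(tab),
               tolerance = 1e-9)
  # column permutation leaves the statistic unchanged
  cl2 <- cl
  cl2$peak_stage <- rep(c("48", "egg", "72", "gastrula", "24"), each = 20)
  res2 <- go_chi2_enrichment(cl2, conc)
  expect_equal(res2$statistic, res$statistic[res$term == "T:conc"],
               tolerance = 1e-9)
})

test_that("CAI follows the geometric-mean definition and is monotone under
          optimal recoding", {
  # reference fixing w(TTT) = 1, w(TTC) = 0.25 in the Phe family
  ref <- c(ref1 = paste0(strrep("TTT", 4), "TTC"))
  genes <- c(ref1 = ref[["ref1"]],
             allmax = strrep("TTT", 6),
             half = "TTTTTC")
  cai <- codon_adaptation_index(genes, "ref1")
  expect_equal(unname(cai["allmax"]), 1.0)
  expect_equal(unname(cai["half"]), sqrt(1 * 0.25))

  # recoding any codon to its family-maximal synonym never lowers CAI
  set.seed(21)
  fams <- mztseq:::codon_families()
  ref_big <- c(r = paste(sample(unlist(fams), 3000, replace = TRUE,
                                prob = rep(seq_len(4), length.out = 61)),
                         collapse = ""))
  w <- attr(codon_adaptation_index(ref_big, "r"), "w")
  for (i in 1:10) {
    gene <- paste(sample(unlist(fams), 60, replace = TRUE), collapse = "")
    cai0 <- codon_adaptation_index(c(ref_big, g = gene), "r")["g"]
    cod <- substring(gene, seq(1, 178, 3), seq(3, 180, 3))
    j <- sample(60, 1)
    fam <- fams[[which(vapply(fams, function(f) cod[j] %in% f,
                              logical(1)))]]
    cod[j] <- fam[which.max(w[fam])]
    cai1 <- codon_adaptation_index(c(ref_big,
                                     g = paste(cod, collapse = "")), "r")["g"]
    expect_gte(cai1 + 1e-12, cai0)
  }

  # CDS not a multiple of 3 is skipped with a warning
  expect_warning(out <- codon_adaptation_index(
    c(ref1 = ref[["ref1"]], bad = "TTTT"), "ref1"), "multiple")
  expect_true(is.na(out["bad"]))
})

test_that("cleared/stable CAI comparison is null when codon usage is
          shared", {
  set.seed(33)
  fams <- mztseq:::codon_families()
  codons <- unlist(fams)
  wts <- exp(rnorm(length(codons), 0, 0.7))
  mkgene <- function() paste(sample(codons, 150, replace = TRUE,
                                    prob = wts), collapse = "")
  nonsig <- 0
  reps <- 30
  for (r in 1:reps) {
    pool <- setNames(replicate(150, mkgene()), sprintf("g%03d", 1:150))
    ref <- sprintf("g%03d", 1:50)
    cleared <- sprintf("g%03d", 51:100)
    stable <- sprintf("g%03d", 101:150)
    cai <- codon_adaptation_index(pool, ref)
    p <- cai_compare(cai, cleared, stable)$p
    nonsig <- nonsig + (p > 0.05)
  }
  expect_gte(nonsig / reps, 0.9)
})

test_that("k-mer enrichment finds planted motifs and nothing under the
          null", {
  set.seed(14)
  mkutr <- function(n) replicate(n, paste(
    sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = ""))
  # every fg UTR carries AUUUA, no bg UTR does
  fg <- paste0("ATTTA", gsub("ATTTA", "CCCCC", mkutr(12)))
  bg <- gsub("ATTTA", "CCCCC", mkutr(12))
  res <- kmer_enrichment(fg, bg, k_range = 5)
  expect_equal(res$kmer[1], "AUUUA")
  expect_equal(res$fg_with[1], 12)
  expect_lt(res$p[1], res$p[2])

  # identical fg and bg: nothing significant
  null_res <- kmer_enrichment(bg, bg, k_range = 5:6)
  expect_false(any(null_res$padj < 0.05))

  # Fisher p agrees with fisher.test on the 8/10 vs 1/10 table
  fg2 <- c(paste0("GATTACA", mkutr(8)), mkutr(2))
  bg2 <- c(paste0("GATTACA", mkutr(1)), mkutr(9))
  fg2 <- gsub("GGGGG", "ACACA", fg2)  # avoid accidental duplicates
  res2 <- kmer_enrichment(fg2, bg2, k_range = 7)
  row <- res2[res2$kmer == "GAUUACA", ]
  ft <- fisher.test(matrix(c(row$fg_with, 10 - row$fg_with,
                             row$bg_with, 10 - row$bg_with), 2,
                           byrow = TRUE), alternative = "greater")
  expect_equal(row$p, ft$p.value, tolerance = 1e-9)

  # a motif planted in 80% of fg UTRs is recovered at padj < 0.05
  fg3 <- mkutr(50)
  fg3[1:40] <- paste0(substr(fg3[1:40], 1, 20), "TATTTATT",
                      substr(fg3[1:40], 29, 60))
  bg3 <- mkutr(50)
  res3 <- kmer_enrichment(fg3, bg3, k_range = 8)
  hit <- res3[res3$kmer == "UAUUUAUU", ]
  expect_lt(hit$padj, 0.05)
  expect_equal(hit$kmer, res3$kmer[1])

  expect_error(kmer_enrichment(character(0), bg), "foreground")
})
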