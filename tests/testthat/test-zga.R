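zga_models <- function() {
  # gene "gi" with a 1 kb intron, gene "gn" intronless
  make_models(data.frame(gene_id = c("gi", "gi", "gn"),
                         scaffold = "s1",
                         start = c(1, 1501, 10001),
                         end = c(500, 2000, 11000)))
}

test_that("intron counts are pre-mRNA minus exon, clamped and filtered", {
  models <- zga_models()
  pre <- make_cm(matrix(c(100, 100, 60, 60,
                          50, 50, 50, 50), 2, byrow = TRUE,
                        dimnames = list(c("gi", "gn"), NULL)),
                 timepoint_h = c(0, 0, 4, 4))
  exon <- make_cm(matrix(c(70, 70, 70, 70,
                           50, 50, 50, 50), 2, byrow = TRUE,
                         dimnames = list(c("gi", "gn"), NULL)),
                  timepoint_h = c(0, 0, 4, 4))
  expect_warning(itab <- build_intron_table(pre, exon, models),
                 "clamped")
  # pre 100, exon 70 -> intron 30; pre 60, exon 70 -> clamped to 0
  expect_equal(unname(itab$counts$counts["gi", ]), c(30, 30, 0, 0))
  # the intronless gene is excluded
  expect_identical(itab$excluded_no_intron, "gn")

  # monotonicity: more pre-mRNA never means less intron signal
  pre2 <- pre
  pre2$counts["gi", ] <- pre2$counts["gi", ] + 25
  itab2 <- suppressWarnings(build_intron_table(pre2, exon, models))
  expect_true(all(itab2$counts$counts["gi", ] >=
                    itab$counts$counts["gi", ]))

  # RPKM below 0.5 in every sample excludes the gene: 1 intron read over a
  # 1 kb intron in a 10M-read pre-mRNA library is RPKM 0.1
  pre3 <- make_cm(rbind(gi = c(71, 71), gn = c(9999929, 9999929)),
                  timepoint_h = c(0, 0))
  exon3 <- make_cm(rbind(gi = c(70, 70), gn = c(9999929, 9999929)),
                   timepoint_h = c(0, 0))
  itab3 <- build_intron_table(pre3, exon3, models)
  expect_identical(itab3$excluded_low_rpkm, "gi")

  # mismatched gene sets are a hard error
  expect_error(build_intron_table(pre3, exon, models), "same genes")
})

test_that("combined exon/intron DE finds intron-only activation", {
  set.seed(9)
  # 40 background genes + one flat-exon gene with a 10x intron rise + one
  # pure zygotic gene + one gene with zero intron counts throughout
  n_bg <- 40
  tps <- rep(c(0, 2, 4), each = 2)
  mk <- function(mu) rnbinom(length(tps), mu = mu, size = 1 / 0.02)
  exon <- rbind(
    t(replicate(n_bg, mk(rep(300, 6)))),
    flat_exon = mk(rep(200, 6)),
    zygotic = rnbinom(6, mu = c(0, 0, 0, 0, 300, 300), size = 50),
    no_intron = mk(rep(250, 6)))
  rownames(exon)[1:n_bg] <- sprintf("bg%02d", 1:n_bg)
  intron <- matrix(0L, nrow(exon), 6, dimnames = list(rownames(exon)))
  intron["flat_exon", ] <- rnbinom(6, mu = c(20, 20, 200, 200, 200, 200),
                                   size = 50)
  intron["zygotic", ] <- rnbinom(6, mu = c(0, 0, 0, 0, 60, 60), size = 50)
  pre <- intron + exon
  models <- make_models(data.frame(
    gene_id = rep(c(sprintf("bg%02d", 1:n_bg), "flat_exon", "zygotic",
                    "no_intron"), each = 2),
    scaffold = "s1",
    start = rep(seq(1, by = 10000, length.out = n_bg + 3), each = 2) +
      c(0, 3000),
    end = rep(seq(1, by = 10000, length.out = n_bg + 3), each = 2) +
      c(999, 3999)))
  exon_cm <- make_cm(exon, timepoint_h = tps)
  pre_cm <- make_cm(pre, timepoint_h = tps)
  itab <- suppressWarnings(build_intron_table(pre_cm, exon_cm, models))
  # zero intron counts throughout -> filtered out, no intron entry
  expect_false("no_intron" %in% rownames(itab$counts$counts))
  de <- suppressWarnings(combined_de(exon_cm, itab))
  flat <- de[de$gene_id == "flat_exon", ]
  expect_true(any(flat$padj[flat$entry == "intron"] < 0.05 &
                    flat$log2fc[flat$entry == "intron"] > 0))
  expect_false(any(flat$padj[flat$entry == "exon"] < 0.05 &
                     flat$log2fc[flat$entry == "exon"] > 0))
  zyg <- de[de$gene_id == "zygotic" & de$timepoint_h == 4, ]
  expect_true(all(zyg$padj < 0.05 & zyg$log2fc > 0))
  expect_setequal(zyg$entry, c("exon", "intron"))
})

test_that("activation calls follow the TPM and significance rules", {
  de <- data.frame(
    gene_id = c("mat", "zyg", "mz", "mz"),
    entry = c("exon", "exon", "intron", "exon"),
    timepoint_h = c(4, 4, 4, 6),
    log2fc = c(0.1, 3, 2, 0.2),
    padj = c(0.9, 0.001, 0.01, 0.4))
  tpm <- cbind(s01 = c(mat = 5, zyg = 0.2, mz = 10, amb = 0.7),
               s02 = c(5, 0.2, 10, 0.7))
  ab <- structure(list(
    tpm = tpm, rpkm = tpm,
    samples = data.frame(sample_id = c("s01", "s02"), timepoint_h = 0,
                         library_type = "ribodep", condition = "untreated",
                         replicate = 1:2)), class = "mzt_abundance")
  calls <- classify_activation(de, ab)
  expect_equal(calls$route[calls$gene_id == "mat"], "maternal_only")
  expect_equal(calls$route[calls$gene_id == "zyg"], "zygotic_only")
  expect_equal(calls$first_activation_timepoint_h[calls$gene_id == "zyg"], 4)
  mz <- calls[calls$gene_id == "mz", ]
  expect_equal(mz$route, "maternal_zygotic")
  expect_equal(mz$evidence, "intron")
  expect_equal(calls$route[calls$gene_id == "amb"], "ambiguous")
})

test_that("class fractions and net activation behave at the boundaries", {
  st <- small_study()
  ab <- compute_abundance(st$sim$exon, st$sim$models)
  all_one <- setNames(rep("everything", st$cfg$n_genes),
                      st$sim$truth$genes$gene_id)
  fr <- class_fraction_trajectory(ab, all_one)
  expect_true(all(abs(fr$fraction - 1) < 1e-9))
  expect_error(class_fraction_trajectory(ab, c(bogus_gene = "x")),
               "unknown gene")
})

test_that("the windowed scan flags strong fold increases only", {
  n <- 20
  w <- data.frame(scaffold = "s1", start = seq(0, by = 1e4,
                                               length.out = n),
                  end = seq(1e4, by = 1e4, length.out = n),
                  count = c(rep(100, n - 1), 0))
  same <- windowed_activation(w, w)
  expect_true(all(same$log2fc == 0))
  expect_false(any(same$flag))
  # one window strongly up (8x raw; ~6x after depth normalization, still
  # above the 3-fold flag); zero counts ride on the pseudocount
  w2 <- w
  w2$count[1] <- 800
  up <- windowed_activation(w, w2)
  expect_true(up$flag[1])
  expect_false(any(up$flag[-1]))
  expect_equal(same$log2fc[n], 0)
  expect_error(windowed_activation(w, w2[-1, ]), "differ")
})
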