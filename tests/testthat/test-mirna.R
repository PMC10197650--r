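test_that("antisense matching finds planted sites and rejects excess
          mismatches", {
  set.seed(31)
  q <- random_rna(22)
  site <- mztseq:::revcomp_rna(q)
  subject <- paste0(random_rna(40), site, random_rna(40))
  hits <- antisense_match(q, subject, max_mismatch = 0)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 41)
  expect_equal(hits$mismatches, 0)

  # three mismatches with max_mismatch = 2: no match
  site3 <- site
  substr(site3, 3, 3) <- if (substr(site3, 3, 3) == "A") "C" else "A"
  substr(site3, 9, 9) <- if (substr(site3, 9, 9) == "G") "U" else "G"
  substr(site3, 15, 15) <- if (substr(site3, 15, 15) == "C") "A" else "C"
  subject3 <- paste0(random_rna(30), site3, random_rna(30))
  expect_equal(nrow(antisense_match(q, subject3, max_mismatch = 2)), 0)
  expect_equal(nrow(antisense_match(q, subject3, max_mismatch = 3)), 1)

  expect_error(antisense_match("ACGUN", subject), "non-ACGU")
  expect_error(antisense_match(random_rna(10), subject), "18-30")
})

test_that("antisense matching agrees with a naive scan and is
          strand-consistent", {
  set.seed(32)
  for (i in 1:200) {
    q <- random_rna(sample(18:26, 1))
    s <- random_rna(sample(40:120, 1))
    # plant a corrupted site half the time so hits actually occur
    if (i %% 2 == 0) {
      site <- mztseq:::revcomp_rna(q)
      pos <- sample(nchar(q), 2)
      for (p in pos)
        substr(site, p, p) <- sample(c("A", "C", "G", "U"), 1)
      at <- sample(nchar(s) - nchar(site), 1)
      s <- paste0(substr(s, 1, at), site,
                  substr(s, at + nchar(site) + 1, nchar(s)))
    }
    mm <- sample(0:3, 1)
    ours <- antisense_match(q, s, mm)
    oracle <- antisense_naive_oracle(q, s, mm)
    expect_equal(ours$start, oracle$start)
    expect_equal(ours$mismatches, oracle$mismatches)
    # matching q antisense equals matching revcomp(q) in sense orientation
    sense <- antisense_match(mztseq:::revcomp_rna(q), s, mm, sense = TRUE)
    expect_equal(ours$start, sense$start)
    expect_equal(ours$mismatches, sense$mismatches)
  }
})

test_that("hairpin folding maximizes base pairs", {
  expect_equal(fold_hairpin("GGGGAAAACCCC")$n_pairs, 4)
  expect_equal(fold_hairpin("AAAA")$n_pairs, 0)
  expect_equal(fold_hairpin("GGGGAAAAUUUU", allow_GU = TRUE)$n_pairs, 4)
  # without wobble only the A:U pairs remain; agree with enumeration
  expect_equal(fold_hairpin("GGGGAAAAUUUU", allow_GU = FALSE)$n_pairs,
               nussinov_oracle("GGGGAAAAUUUU", allow_GU = FALSE))

  # the reported structure is always valid: non-crossing, admissible pairs,
  # loop constraint respected
  set.seed(41)
  for (i in 1:40) {
    s <- random_rna(sample(8:30, 1))
    hp <- fold_hairpin(s)
    if (nrow(hp$pairs)) {
      expect_true(all(hp$pairs[, 2] - hp$pairs[, 1] > 3))
      b <- strsplit(hp$sequence, "")[[1]]
      expect_true(all(paste0(b[hp$pairs[, 1]], b[hp$pairs[, 2]]) %in%
                        c("AU", "UA", "GC", "CG", "GU", "UG")))
      # non-crossing: for any two pairs, nested or disjoint
      if (nrow(hp$pairs) > 1) {
        for (a in 1:(nrow(hp$pairs) - 1)) for (b2 in (a + 1):nrow(hp$pairs)) {
          i1 <- hp$pairs[a, 1]; j1 <- hp$pairs[a, 2]
          i2 <- hp$pairs[b2, 1]; j2 <- hp$pairs[b2, 2]
          crossing <- (i1 < i2 & i2 < j1 & j1 < j2) |
            (i2 < i1 & i1 < j2 & j2 < j1)
          expect_false(crossing)
        }
      }
    }
  }

  # equals brute-force enumeration on short random sequences
  set.seed(42)
  for (i in 1:150) {
    s <- random_rna(sample(6:12, 1))
    expect_equal(fold_hairpin(s)$n_pairs, nussinov_oracle(s),
                 label = paste("sequence", s))
  }

  # a planted perfect hairpin folds into its stem
  set.seed(43)
  mature <- random_rna(22)
  pre <- paste0(mature, "GCAAAAGC", mztseq:::revcomp_rna(mature))
  hp <- fold_hairpin(pre)
  expect_gte(stem_paired_fraction(hp, c(1, 22)), 0.9)
})

test_that("candidate filtering applies all four criteria with reasons", {
  st <- small_study()
  res <- st$sim
  truth <- read.delim(attr(res, "paths")$truth, stringsAsFactors = FALSE)
  hosts <- truth$gene_id[!is.na(truth$mirna_host)]
  mrna <- Biostrings::readDNAStringSet(attr(res, "paths")$mrna)
  mrna <- setNames(as.character(mrna), sub("\\s.*", "", names(mrna)))
  ref <- Biostrings::readDNAStringSet(attr(res, "paths")$mirna_ref)
  ref <- setNames(as.character(ref), sub("\\s.*", "", names(ref)))
  hits <- match_mirna_homology(ref, mrna, max_mismatch = 2)
  expect_true(all(hosts %in% hits$transcript_id))

  # synthetic DE tables: hosts activated and Triptolide-suppressed
  de <- data.frame(gene_id = hosts, padj = 1e-4, log2fc = 4)
  trip <- data.frame(gene_id = hosts, padj = 1e-4, log2fc = -4)
  cand <- candidate_filter(hits, de, trip, mrna)
  expect_true(all(cand$candidate[cand$transcript_id %in% hosts]))
  expect_gte(min(cand$stem_fraction[cand$transcript_id %in% hosts]), 0.6)

  # not activated -> rejected with reason
  de0 <- data.frame(gene_id = character(0), padj = numeric(0),
                    log2fc = numeric(0))
  cand2 <- candidate_filter(hits, de0, trip, mrna)
  expect_true(all(cand2$reason[cand2$transcript_id %in% hosts] ==
                    "not_activated"))
  expect_false(any(cand2$candidate))

  # an unstructured mature region fails the hairpin criterion: scan a
  # transcript that contains the mature but no complementary arm
  mat <- truth$mirna_mature[!is.na(truth$mirna_mature)][1]
  loose <- c(loose_tx = paste0(strrep("A", 60), chartr("U", "T", mat),
                               strrep("A", 60)))
  hits3 <- match_mirna_homology(setNames(mat, "m"), loose, 0)
  de3 <- data.frame(gene_id = "loose_tx", padj = 1e-4, log2fc = 4)
  trip3 <- data.frame(gene_id = "loose_tx", padj = 1e-4, log2fc = -4)
  cand3 <- candidate_filter(hits3, de3, trip3, loose)
  expect_equal(cand3$reason, "no_hairpin")
})

test_that("duplex scoring, shuffled-target null and diagram round trip", {
  set.seed(51)
  mature <- random_rna(22)
  site <- mztseq:::revcomp_rna(mature)
  target <- paste0(random_rna(50), site, random_rna(50))
  hits <- predict_targets(setNames(mature, "m"), c(tx = target),
                          cleared_set = "tx")
  expect_equal(nrow(hits), 1)
  expect_equal(hits$score, 22)
  expect_equal(hits$offset0, 50)
  expect_true(all(strsplit(hits$states, ",")[[1]] == "WC"))
  expect_equal(hits$group, "cleared")

  # two G:U wobbles score 20 * 1 + 2 * 0.5 = 21: U->C flips in the target
  # turn A:U pairs into G:U when read with the wobble rule reversed, so
  # instead mutate target positions pairing A->G (A:U -> G:U)
  site2 <- site
  apos <- which(strsplit(site2, "")[[1]] == "A")[1:2]
  skip_if(anyNA(apos), "site lacks two A positions")
  for (p in apos) substr(site2, p, p) <- "G"
  target2 <- paste0(random_rna(20), site2, random_rna(20))
  hits2 <- predict_targets(setNames(mature, "m"), c(tx = target2))
  expect_equal(nrow(hits2), 1)
  expect_equal(hits2$score, 21)
  expect_equal(hits2$n_gu, 2)
  st <- strsplit(hits2$states, ",")[[1]]
  expect_equal(sum(st == "GU"), 2)

  # render/parse round trip preserves the states
  txt <- render_duplex(hits2)
  expect_identical(parse_duplex(txt), st)
  txt_perfect <- render_duplex(hits)
  expect_false(grepl(":", strsplit(txt_perfect, "\n")[[1]][3]))

  # dinucleotide-shuffled targets yield no hits at the default threshold
  shuffle_dinuc <- function(s) {
    ch <- strsplit(s, "")[[1]]
    n <- length(ch) - length(ch) %% 2
    pairs <- vapply(seq(1, n, 2), function(i)
      paste0(ch[i], ch[i + 1]), character(1))
    paste(c(sample(pairs), ch[setdiff(seq_along(ch), 1:n)]), collapse = "")
  }
  set.seed(52)
  zero_hits <- 0
  for (i in 1:60) {
    sh <- shuffle_dinuc(target)
    h <- predict_targets(setNames(mature, "m"), c(tx = sh))
    zero_hits <- zero_hits + (nrow(h) == 0)
  }
  expect_gte(zero_hits / 60, 0.95)
})
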