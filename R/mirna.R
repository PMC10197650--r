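rna_upper <- function(x) toupper(chartr("T", "U", x))

check_rna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGU]", rna_upper(x))
  if (any(bad))
    stop("non-ACGU(T) characters in ", what)
  invisible(TRUE)
}

revcomp_rna <- function(s) {
  paste(rev(strsplit(chartr("ACGU", "UGCA", s), "")[[1]]), collapse = "")
}

seq_to_int <- function(s) {
  match(strsplit(s, "")[[1]], c("A", "C", "G", "U"))
}

# all ungapped alignments of query within subject (sense), <= max_mismatch
# mismatches over the full query. Vectorized over offsets: one pass per query
# position, exact by construction.
ungapped_scan <- function(query, subject, max_mismatch) {
  q <- seq_to_int(query)
  s <- seq_to_int(subject)
  nq <- length(q)
  ns <- length(s)
  if (ns < nq) return(integer(0))
  n_off <- ns - nq + 1
  mm <- integer(n_off)
  for (j in seq_len(nq))
    mm <- mm + (s[j:(n_off + j - 1)] != q[j])
  found <- which(mm <= max_mismatch)
  stats::setNames(mm[found], found)   # names: 1-based start in subject
}

#' Ungapped antisense matches of a mature miRNA in a transcript
#'
#' Finds every ungapped alignment of the query against the reverse complement
#' of the subject with at most `max_mismatch` mismatches over the full query
#' length -- the explicit-threshold replacement for an E-value-driven
#' antisense BLAST search. T is read as U.
#'
#' @param query mature miRNA sequence, 18-30 nt.
#' @param subject transcript sequence.
#' @param max_mismatch maximum mismatches (default 2).
#' @param sense match against the subject itself instead of its reverse
#'   complement (used for homology searches of miRNAs encoded in
#'   transcripts).
#' @return data.frame with `start` (1-based position of the matched window on
#'   the subject, forward coordinates), `end`, `mismatches`, `strand`.
#' @export
antisense_match <- function(query, subject, max_mismatch = 2,
                            sense = FALSE) {
  check_rna(query, "query")
  check_rna(subject, "subject")
  query <- rna_upper(query)
  subject <- rna_upper(subject)
  if (nchar(query) < 18 || nchar(query) > 30)
    stop("query length must be 18-30 nt")
  target <- if (sense) subject else revcomp_rna(subject)
  hits <- ungapped_scan(query, target, max_mismatch)
  if (!length(hits))
    return(data.frame(start = integer(0), end = integer(0),
                      mismatches = integer(0), strand = character(0)))
  pos <- as.integer(names(hits))
  nq <- nchar(query)
  ns <- nchar(subject)
  if (sense) {
    start <- pos
  } else {
    start <- ns - (pos + nq - 1) + 1
  }
  out <- data.frame(start = start, end = start + nq - 1,
                    mismatches = as.integer(hits),
                    strand = if (sense) "+" else "-",
                    stringsAsFactors = FALSE)
  out[order(out$start), , drop = FALSE]
}

#' Homology matches of reference mature miRNAs in transcripts
#'
#' Sense-strand ungapped scan of each reference mature miRNA against each
#' transcript, keeping matches with at most `max_mismatch` mismatches.
#'
#' @param ref_mirnas named character vector of mature miRNA sequences.
#' @param transcripts named character vector (or `DNAStringSet`) of
#'   transcript sequences.
#' @param max_mismatch maximum mismatches (default 2).
#' @return data.frame `mirna_id`, `transcript_id`, `start`, `end`,
#'   `mismatches`, `mature_seq` (the transcript-encoded sequence, RNA).
#' @export
match_mirna_homology <- function(ref_mirnas, transcripts, max_mismatch = 2) {
  if (methods::is(transcripts, "DNAStringSet")) {
    nm <- names(transcripts)
    transcripts <- as.character(transcripts)
    names(transcripts) <- nm
  }
  rows <- list()
  for (m in names(ref_mirnas)) {
    for (tx in names(transcripts)) {
      h <- antisense_match(ref_mirnas[[m]], transcripts[[tx]],
                           max_mismatch, sense = TRUE)
      if (nrow(h)) {
        h$mirna_id <- m
        h$transcript_id <- tx
        h$mature_seq <- vapply(seq_len(nrow(h)), function(i)
          rna_upper(substr(transcripts[[tx]], h$start[i], h$end[i])),
          character(1))
        rows[[length(rows) + 1]] <- h
      }
    }
  }
  if (!length(rows))
    return(data.frame(mirna_id = character(0), transcript_id = character(0),
                      start = integer(0), end = integer(0),
                      mismatches = integer(0), mature_seq = character(0)))
  out <- do.call(rbind, rows)
  out[, c("mirna_id", "transcript_id", "start", "end", "mismatches",
          "mature_seq")]
}

pairable <- function(a, b, allow_GU = TRUE) {
  # integer codes: A=1 C=2 G=3 U=4
  wc <- (a + b == 5)
  if (allow_GU) wc | (a + b == 7) else wc
}

#' Maximum base-pair hairpin folding (Nussinov dynamic program)
#'
#' Folds a sequence into the nested secondary structure with the maximum
#' number of base pairs (Watson-Crick, plus G:U wobble when `allow_GU`),
#' subject to a minimum hairpin loop of `min_loop` unpaired bases. A
#' pair-count criterion stands in for free-energy folding: it is sufficient
#' to recognize the long, near-perfectly paired stem-loops characteristic of
#' miRNA precursors. Traceback reports one optimal structure, preferring to
#' pair the leftmost base with its rightmost admissible partner over leaving
#' it unpaired.
#'
#' @param sequence RNA or DNA string (T read as U), length <= 400.
#' @param min_loop minimum loop size (default 3).
#' @param allow_GU admit G:U wobble pairs (default TRUE).
#' @return A list of class `mzt_hairpin`: `sequence`, `n_pairs`, `pairs`
#'   (two-column matrix of 1-based partners, i < j), `dotbracket`.
#' @export
fold_hairpin <- function(sequence, min_loop = 3, allow_GU = TRUE) {
  check_rna(sequence, "sequence")
  s <- rna_upper(sequence)
  n <- nchar(s)
  if (n > 400) stop("sequence longer than 400 nt; fold windows instead")
  empty <- structure(list(sequence = s, n_pairs = 0L,
                          pairs = matrix(integer(0), 0, 2,
                                         dimnames = list(NULL, c("i", "j"))),
                          dotbracket = strrep(".", n)),
                     class = "mzt_hairpin")
  if (n < min_loop + 2) return(empty)
  x <- seq_to_int(s)
  # dp[i, j]: max pairs in x[i..j]; recurrence over the fate of base i.
  # Padded one row/column so empty boundary segments read as zero.
  dp <- matrix(0L, n + 1, n + 1)
  for (span in seq(min_loop + 1, n - 1)) {
    for (i in seq_len(n - span)) {
      j <- i + span
      best <- dp[i + 1, j]                       # i unpaired
      ks <- seq(i + min_loop + 1, j)             # i paired with k
      ks <- ks[pairable(x[i], x[ks], allow_GU)]
      if (length(ks))
        best <- max(best, max(1L + dp[i + 1, ks - 1] + dp[ks + 1, j]))
      dp[i, j] <- best
    }
  }
  pairs <- matrix(integer(0), 0, 2)
  stack <- list(c(1L, n))
  while (length(stack)) {
    seg <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- seg[1]; j <- seg[2]
    while (i < j && j - i > min_loop) {
      target <- dp[i, j]
      if (target == 0L) break
      ks <- seq(i + min_loop + 1, j)
      ks <- ks[pairable(x[i], x[ks], allow_GU)]
      paired <- FALSE
      for (k in rev(ks)) {   # prefer the rightmost partner for base i
        left <- if (k - 1 >= i + 1) dp[i + 1, k - 1] else 0L
        right <- if (k + 1 <= j) dp[k + 1, j] else 0L
        if (1L + left + right == target) {
          pairs <- rbind(pairs, c(i, k))
          if (k + 1 <= j && right > 0L)
            stack[[length(stack) + 1]] <- c(k + 1L, j)
          j <- k - 1L
          i <- i + 1L
          paired <- TRUE
          break
        }
      }
      if (!paired) i <- i + 1L
    }
  }
  if (!nrow(pairs)) return(empty)
  colnames(pairs) <- c("i", "j")
  pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  db <- rep(".", n)
  db[pairs[, 1]] <- "("
  db[pairs[, 2]] <- ")"
  structure(list(sequence = s, n_pairs = nrow(pairs), pairs = pairs,
                 dotbracket = paste(db, collapse = "")),
            class = "mzt_hairpin")
}

#' Fraction of an interval's bases that are paired in a hairpin
#'
#' @param hairpin an `mzt_hairpin`.
#' @param interval integer vector `c(start, end)` (1-based, inclusive) on the
#'   folded sequence, e.g. the mature miRNA span.
#' @return Numeric in `[0, 1]`.
#' @export
stem_paired_fraction <- function(hairpin, interval) {
  stopifnot(inherits(hairpin, "mzt_hairpin"), length(interval) == 2)
  span <- seq(interval[1], interval[2])
  paired <- unique(as.vector(hairpin$pairs))
  mean(span %in% paired)
}

#' Filter homology matches into credible miRNA candidates
#'
#' A candidate must (a) match a reference mature miRNA with at most
#' `max_mismatch` mismatches, (b) sit in a host transcript that is
#' significantly activated over the timecourse, (c) fall inside a predicted
#' hairpin with a paired fraction of at least `min_stem_fraction` over the
#' mature positions (folding a window of `flank` nt around the match), and
#' (d) have its host transcript significantly down under transcription
#' inhibition (Triptolide vs mock), i.e. be zygotically encoded.
#'
#' @param matches output of [match_mirna_homology()].
#' @param de host-transcript timecourse DE (gene ids = transcript ids).
#' @param inhibition_de Triptolide-vs-mock DE for the same transcripts.
#' @param transcripts named character vector of transcript sequences.
#' @param min_stem_fraction minimum paired fraction (default 0.6).
#' @param flank folding window half-width around the mature match
#'   (default 60).
#' @param alpha significance level (default 0.05).
#' @param min_loop,allow_GU folding parameters, see [fold_hairpin()].
#' @return data.frame of all matches with `activated`, `stem_fraction`,
#'   `trip_down`, `candidate` and `reason` (first failing check or
#'   `"candidate"`).
#' @export
candidate_filter <- function(matches, de, inhibition_de, transcripts,
                             min_stem_fraction = 0.6, flank = 60,
                             alpha = 0.05, min_loop = 3, allow_GU = TRUE) {
  if (methods::is(transcripts, "DNAStringSet")) {
    nm <- names(transcripts)
    transcripts <- as.character(transcripts)
    names(transcripts) <- nm
  }
  if (!nrow(matches)) {
    matches$activated <- logical(0)
    matches$stem_fraction <- numeric(0)
    matches$trip_down <- logical(0)
    matches$candidate <- logical(0)
    matches$reason <- character(0)
    return(matches)
  }
  act <- unique(de$gene_id[de$padj < alpha & de$log2fc > 0])
  down <- unique(inhibition_de$gene_id[inhibition_de$padj < alpha &
                                         inhibition_de$log2fc < 0])
  out <- matches
  out$activated <- out$transcript_id %in% act
  out$trip_down <- out$transcript_id %in% down
  out$stem_fraction <- NA_real_
  for (i in seq_len(nrow(out))) {
    tx <- transcripts[[out$transcript_id[i]]]
    w0 <- max(1, out$start[i] - flank)
    w1 <- min(nchar(tx), out$end[i] + flank)
    hp <- fold_hairpin(substr(tx, w0, w1), min_loop = min_loop,
                       allow_GU = allow_GU)
    out$stem_fraction[i] <-
      stem_paired_fraction(hp, c(out$start[i] - w0 + 1,
                                 out$end[i] - w0 + 1))
  }
  out$reason <- ifelse(out$mismatches > 2, "homology",
                ifelse(!out$activated, "not_activated",
                ifelse(out$stem_fraction < min_stem_fraction, "no_hairpin",
                ifelse(!out$trip_down, "not_inhibited", "candidate"))))
  out$candidate <- out$reason == "candidate"
  out
}

duplex_states <- function(mature, window) {
  # mature 5'->3'; window is the target site 5'->3'; mature base i pairs
  # window base (L - i + 1). States reported along the target (left to
  # right), i.e. along the mature read 3'->5'.
  m <- seq_to_int(mature)
  w <- seq_to_int(window)
  L <- length(m)
  mi <- rev(m)                       # mature 3'->5' aligned to window 5'->3'
  sums <- mi + w
  ifelse(sums == 5, "WC", ifelse(sums == 7, "GU", "MM"))
}

#' Predict miRNA targets by near-full antisense complementarity
#'
#' Scans each mature miRNA against every ungapped antisense window of each
#' mRNA, scoring Watson-Crick pairs 1, G:U wobbles `gu_weight` and
#' mismatches 0, and reports duplexes scoring at least
#' `mature length - score_slack` -- the extensive-complementarity regime of
#' cnidarian miRNA targeting rather than bilaterian seed matching. Hits are
#' labelled by membership in the cleared and stable gene sets.
#'
#' @param candidates data.frame with `mirna_id` and `mature_seq` (e.g. the
#'   candidate rows of [candidate_filter()]), or a named character vector of
#'   mature sequences.
#' @param mrna_seqs named character vector (or `DNAStringSet`) of mRNA (or
#'   3'UTR) sequences to scan.
#' @param cleared_set,stable_set gene id vectors used for labelling.
#' @param gu_weight score of a G:U pair (default 0.5).
#' @param score_slack allowed score shortfall from perfect (default 4).
#' @return data.frame of class `mzt_duplexes`: `mirna_id`, `target_id`,
#'   `offset0` (0-based window start on the target), `score`, `n_wc`,
#'   `n_gu`, `n_mm`, `states` (target-oriented string like `"WC,GU,..."`),
#'   `group` (`cleared`/`stable`/`other`), plus the sequences.
#' @export
predict_targets <- function(candidates, mrna_seqs, cleared_set = character(0),
                            stable_set = character(0), gu_weight = 0.5,
                            score_slack = 4) {
  if (is.data.frame(candidates)) {
    mat <- stats::setNames(candidates$mature_seq, candidates$mirna_id)
    mat <- mat[!duplicated(names(mat))]
  } else mat <- candidates
  if (methods::is(mrna_seqs, "DNAStringSet")) {
    nm <- names(mrna_seqs)
    mrna_seqs <- as.character(mrna_seqs)
    names(mrna_seqs) <- nm
  }
  rows <- list()
  for (m in names(mat)) {
    mature <- rna_upper(mat[[m]])
    check_rna(mature, "mature sequence")
    L <- nchar(mature)
    if (L < 18 || L > 30) stop("mature sequences must be 18-30 nt")
    mi <- rev(seq_to_int(mature))
    thr <- L - score_slack
    for (tx in names(mrna_seqs)) {
      s <- seq_to_int(rna_upper(mrna_seqs[[tx]]))
      ns <- length(s)
      if (ns < L) next
      n_off <- ns - L + 1
      wc <- integer(n_off)
      gu <- integer(n_off)
      for (j in seq_len(L)) {
        sums <- mi[j] + s[j:(n_off + j - 1)]
        wc <- wc + (sums == 5)
        gu <- gu + (sums == 7)
      }
      score <- wc + gu_weight * gu
      hit <- which(score >= thr)
      for (h in hit) {
        window <- substr(rna_upper(mrna_seqs[[tx]]), h, h + L - 1)
        st <- duplex_states(mature, window)
        rows[[length(rows) + 1]] <- data.frame(
          mirna_id = m, target_id = tx, offset0 = h - 1,
          score = score[h], n_wc = wc[h], n_gu = gu[h],
          n_mm = L - wc[h] - gu[h],
          states = paste(st, collapse = ","),
          group = if (tx %in% cleared_set) "cleared"
                  else if (tx %in% stable_set) "stable" else "other",
          mature_seq = mature, target_window = window,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mirna_id = character(0), target_id = character(0),
               offset0 = integer(0), score = numeric(0), n_wc = integer(0),
               n_gu = integer(0), n_mm = integer(0), states = character(0),
               group = character(0), mature_seq = character(0),
               target_window = character(0), stringsAsFactors = FALSE)
  class(out) <- c("mzt_duplexes", "data.frame")
  out
}

#' Render a miRNA:target duplex as a text diagram
#'
#' Three lines: target 5'->3' with 0-based coordinates, pairing bars
#' (`|` Watson-Crick, `:` G:U wobble, space for mismatch), and the miRNA
#' written 3'->5'.
#'
#' @param duplex one row of a [predict_targets()] result.
#' @return Character scalar (lines separated by newline).
#' @export
render_duplex <- function(duplex) {
  stopifnot(nrow(duplex) == 1)
  st <- strsplit(duplex$states, ",", fixed = TRUE)[[1]]
  bars <- paste(ifelse(st == "WC", "|", ifelse(st == "GU", ":", " ")),
                collapse = "")
  mature35 <- paste(rev(strsplit(duplex$mature_seq, "")[[1]]), collapse = "")
  paste0(sprintf("target %s %d-%d\n", duplex$target_id, duplex$offset0,
                 duplex$offset0 + nchar(duplex$target_window) - 1),
         sprintf("5'-%s-3'\n", duplex$target_window),
         sprintf("   %s\n", bars),
         sprintf("3'-%s-5' %s", mature35, duplex$mirna_id))
}

#' Parse a rendered duplex diagram back into pairing states
#'
#' @param text output of [render_duplex()].
#' @return Character vector of per-position states (`WC`/`GU`/`MM`), target
#'   orientation.
#' @export
parse_duplex <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  target <- sub("-3'$", "", sub("^5'-", "", lines[2]))
  bars <- substr(lines[3], 4, 3 + nchar(target))
  st <- strsplit(bars, "")[[1]]
  if (length(st) < nchar(target))
    st <- c(st, rep(" ", nchar(target) - length(st)))
  ifelse(st == "|", "WC", ifelse(st == ":", "GU", "MM"))
}
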