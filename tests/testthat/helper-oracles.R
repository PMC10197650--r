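# Independent reference implementations used to cross-check the package.
# These deliberately re-derive each quantity from its textbook definition
# rather than sharing code with the implementation under test.

# Benjamini-Hochberg by the literal step-up definition
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m))
    adj[i] <- min(1, min(m * ps[i:m] / (i:m)))
  out <- numeric(m)
  out[o] <- adj
  out
}

# maximum nested base pairs by direct definitional recursion (no memo table)
can_pair_oracle <- function(a, b, allow_GU = TRUE) {
  pairs <- c("AU", "UA", "GC", "CG")
  if (allow_GU) pairs <- c(pairs, "GU", "UG")
  paste0(a, b) %in% pairs
}

nussinov_oracle <- function(seq, min_loop = 3, allow_GU = TRUE) {
  s <- strsplit(toupper(chartr("T", "U", seq)), "")[[1]]
  rec <- function(i, j) {
    if (j - i <= min_loop) return(0L)
    best <- rec(i + 1L, j)
    for (k in seq(i + min_loop + 1L, j)) {
      if (can_pair_oracle(s[i], s[k], allow_GU)) {
        left <- if (k - 1L >= i + 1L) rec(i + 1L, k - 1L) else 0L
        right <- if (k + 1L <= j) rec(k + 1L, j) else 0L
        best <- max(best, 1L + left + right)
      }
    }
    best
  }
  if (length(s) < 2) 0L else rec(1L, length(s))
}

# two-sided exact Wilcoxon signed-rank by full enumeration of sign vectors
wilcoxon_enum_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  p_low <- mean(v_all <= v_obs)
  p_high <- mean(v_all >= v_obs)
  min(1, 2 * min(p_low, p_high))
}

# Pearson chi-squared from the definition
chi2_oracle <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# naive antisense scan: substring-by-substring comparison against the
# Biostrings reverse complement
antisense_naive_oracle <- function(query, subject, max_mismatch) {
  q <- toupper(chartr("T", "U", query))
  rc <- chartr("T", "U", as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(
      chartr("U", "T", toupper(subject))))))
  nq <- nchar(q)
  hits <- data.frame(start = integer(0), mismatches = integer(0))
  qs <- strsplit(q, "")[[1]]
  for (off in seq_len(max(0, nchar(rc) - nq + 1))) {
    win <- strsplit(substr(rc, off, off + nq - 1), "")[[1]]
    mm <- sum(win != qs)
    if (mm <= max_mismatch) {
      start_fwd <- nchar(subject) - (off + nq - 1) + 1
      hits <- rbind(hits, data.frame(start = start_fwd, mismatches = mm))
    }
  }
  hits[order(hits$start), , drop = FALSE]
}

random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}
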