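# Independent oracles used across the suite.  These deliberately avoid
# the package's own code paths.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Brute-force junction-anchored open-run oracle: translate the
# 3'-anchored frame with Biostrings and take the run after the last
# stop.  Returns list(length_aa, aa_seq).
oracle_fusion_run <- function(insert, frame_offset = 0) {
  L <- nchar(insert)
  p0 <- (L - frame_offset) %% 3
  n_cod <- (L - p0) %/% 3
  if (n_cod == 0) return(list(length_aa = 0L, aa_seq = ""))
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(insert, p0 + 1, p0 + 3 * n_cod)),
    genetic.code = Biostrings::getGeneticCode("11"),
    no.init.codon = TRUE, if.fuzzy.codon = "error"))
  parts <- strsplit(aa, "*", fixed = TRUE)[[1]]
  last <- if (endsWith(aa, "*")) "" else parts[length(parts)]
  if (length(parts) == 0) last <- ""
  list(length_aa = nchar(last), aa_seq = last)
}

# Exact conditional two-proportion test by direct hypergeometric
# enumeration (sums P(X = k) over all tables as or less probable).
oracle_exact_prop_test <- function(a, ta, b, tb) {
  m <- a + b
  k <- seq(max(0, m - tb), min(ta, m))
  probs <- stats::dhyper(k, ta, tb, m)
  p_obs <- stats::dhyper(a, ta, tb, m)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Brute-force 100%-identity containment clustering: connected
# components of the identical-or-substring relation.
oracle_containment_clusters <- function(seqs) {
  n <- length(seqs)
  if (n == 0) return(integer(0))
  adj <- outer(seq_len(n), seq_len(n), Vectorize(function(i, j) {
    grepl(seqs[i], seqs[j], fixed = TRUE) ||
      grepl(seqs[j], seqs[i], fixed = TRUE)
  }))
  comp <- rep(0L, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] > 0) next
    cur <- cur + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (comp[v] > 0) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & comp == 0))
    }
  }
  comp
}

# Sliding-window hydropathy oracle (direct double loop).
oracle_tmh_windows <- function(aa, window = 19, threshold = 1.6) {
  kd <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
          E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
          M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
          Y = -1.3, V = 4.2)
  v <- kd[strsplit(aa, "")[[1]]]
  n <- length(v)
  hits <- logical(n)
  if (n >= window) {
    for (s in 1:(n - window + 1)) {
      if (mean(v[s:(s + window - 1)]) > threshold) {
        hits[s:(s + window - 1)] <- TRUE
      }
    }
  }
  hits
}

expected_category <- function(truth) {
  ifelse(truth == "NONE", "BACKGROUND", truth)
}
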