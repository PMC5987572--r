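# Independent oracles, deliberately naive: brute-force enumeration, direct
# tail summation, step-up by hand. They never share code with the package
# paths they check.

# survival function of PWM window scores by exhaustive k-mer enumeration,
# on the same per-position quantized score grid the calibration defines
sf_by_enumeration <- function(model, scores_at, granularity = 1e-3) {
  L <- nrow(model$pwm)
  qm <- round(model$pwm / granularity)
  kmers <- as.matrix(expand.grid(rep(list(1:4), L)))
  q <- apply(kmers, 1, function(k) sum(qm[cbind(seq_len(L), k)]))
  w <- apply(kmers, 1, function(k) prod(model$background[k]))
  vapply(scores_at, function(s) sum(w[q >= round(s / granularity)]), numeric(1))
}

# pure-R reference scanner (given-strand only), threshold in bits
scan_by_loop <- function(model, sequence, min_score, granularity = 1e-3) {
  enc <- match(strsplit(toupper(sequence), "")[[1]], c("A", "C", "G", "T"))
  L <- nrow(model$pwm)
  q <- round(model$pwm / granularity)
  hits <- integer(0)
  if (length(enc) >= L) {
    for (p in seq_len(length(enc) - L + 1)) {
      win <- enc[p:(p + L - 1)]
      if (anyNA(win)) next
      if (sum(q[cbind(seq_len(L), win)]) * granularity >= min_score - 1e-12)
        hits <- c(hits, p)
    }
  }
  hits
}

# Benjamini-Hochberg step-up, spelled out
bh_by_hand <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  prev <- 1
  for (i in n:1) {
    prev <- min(prev, p[o[i]] * n / i)
    q[o[i]] <- prev
  }
  q
}

# one-sided Fisher p by direct hypergeometric tail summation
fisher_tail_by_hand <- function(shared, size_a, size_b, n_universe) {
  kmax <- min(size_a, size_b)
  if (shared > kmax) return(0)
  sum(vapply(shared:kmax, function(k)
    stats::dhyper(k, size_a, n_universe - size_a, size_b), numeric(1)))
}

random_pfm <- function(L, max_count = 30) {
  matrix(sample.int(max_count, 4 * L, replace = TRUE), ncol = 4)
}

rc_string <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")
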