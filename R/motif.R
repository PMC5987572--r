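#' @useDynLib ocregnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# integer encoding A=1 C=2 G=3 T=4, anything else (N) = 0
encode_dna <- function(sequence) {
  lut <- integer(256L)
  lut[utf8ToInt("A")] <- 1L; lut[utf8ToInt("a")] <- 1L
  lut[utf8ToInt("C")] <- 2L; lut[utf8ToInt("c")] <- 2L
  lut[utf8ToInt("G")] <- 3L; lut[utf8ToInt("g")] <- 3L
  lut[utf8ToInt("T")] <- 4L; lut[utf8ToInt("t")] <- 4L
  lut[utf8ToInt(sequence)]
}

decode_dna <- function(codes) {
  paste(c("N", DNA_BASES)[codes + 1L], collapse = "")
}

revcomp <- function(sequence) {
  chartr("ACGTacgtN", "TGCAtgcaN", paste(rev(strsplit(sequence, "")[[1]]), collapse = ""))
}

#' Build a position weight matrix from a position frequency matrix
#'
#' Converts an L x 4 matrix of base counts (columns A, C, G, T) into a
#' log2-odds position weight matrix against a background base composition,
#' with a pseudocount distributed proportionally to the background:
#' \deqn{pwm_{i,b} = \log_2\frac{(pfm_{i,b} + c\,\pi_b) / (n_i + c)}{\pi_b}}
#' where \eqn{n_i} is the count total of motif position \eqn{i}, \eqn{c} the
#' pseudocount and \eqn{\pi} the background.
#'
#' @param pfm numeric L x 4 matrix of non-negative counts, columns in
#'   A, C, G, T order.
#' @param pseudocount non-negative scalar, split across bases by background
#'   composition. Default 0.1.
#' @param background length-4 base probabilities (A, C, G, T), all positive,
#'   summing to 1. Default uniform.
#' @param tf_id identifier of the TF the motif belongs to.
#' @return an object of class `motif_model` with elements `tf_id`, `pfm`,
#'   `pwm` (log2-odds, bits), `background`, `pseudocount`.
#' @export
build_pwm <- function(pfm, pseudocount = 0.1, background = rep(0.25, 4),
                      tf_id = "motif") {
  pfm <- as.matrix(pfm)
  if (ncol(pfm) != 4L) stop("pfm must have 4 columns (A, C, G, T)")
  if (nrow(pfm) < 1L) stop("pfm must have at least one row")
  if (any(pfm < 0)) stop("pfm counts must be non-negative")
  if (length(background) != 4L || any(background <= 0))
    stop("background must be 4 positive probabilities")
  if (abs(sum(background) - 1) > 1e-9) stop("background must sum to 1")
  if (pseudocount < 0) stop("pseudocount must be non-negative")
  rowsum <- rowSums(pfm)
  if (any(rowsum <= 0) && pseudocount == 0) stop("degenerate column")
  pwm <- log2(sweep(pfm, 2, background * pseudocount, "+") / (rowsum + pseudocount))
  pwm <- sweep(pwm, 2, log2(background), "-")
  colnames(pfm) <- colnames(pwm) <- DNA_BASES
  structure(list(tf_id = tf_id, pfm = pfm, pwm = pwm,
                 background = background, pseudocount = pseudocount),
            class = "motif_model")
}

#' @export
print.motif_model <- function(x, ...) {
  cat("<motif_model> ", x$tf_id, ": ", nrow(x$pwm), " positions, ",
      sprintf("%.2f", max_pwm_score(x)), " bits max score\n", sep = "")
  invisible(x)
}

max_pwm_score <- function(model) sum(apply(model$pwm, 1, max))

# reverse-complement a motif model (reverse row order, swap A<->T, C<->G)
revcomp_model <- function(model) {
  flip <- function(m) m[rev(seq_len(nrow(m))), c(4, 3, 2, 1), drop = FALSE]
  out <- model
  out$pfm <- flip(model$pfm)
  out$pwm <- flip(model$pwm)
  colnames(out$pfm) <- colnames(out$pwm) <- DNA_BASES
  out
}

quantize_pwm <- function(model, granularity) {
  q <- round(model$pwm / granularity)
  storage.mode(q) <- "integer"
  q
}

#' Exact null distribution of PWM window scores
#'
#' Computes, by position-wise convolution over the quantized score grid, the
#' exact distribution of the total window score when each base is drawn
#' independently from the background. This is the calibration that turns
#' scan scores into p-values; it never enumerates the 4^L k-mer space.
#'
#' @param model a [build_pwm()] `motif_model`.
#' @param granularity score quantization step in bits (default 1/1000 bit);
#'   scores are rounded to this grid before convolution and scanning.
#' @return object of class `score_distribution`: `granularity`, `scores`
#'   (quantized scores in bits, ascending), `pmf`, and `sf`, the survival
#'   function `S(s) = P(score >= s)`.
#' @export
null_score_distribution <- function(model, granularity = 1e-3) {
  if (granularity <= 0) stop("granularity must be positive")
  q <- quantize_pwm(model, granularity)
  L <- nrow(q)
  lo <- sum(apply(q, 1, min))
  hi <- sum(apply(q, 1, max))
  # pmf over integer scores lo..hi, convolved one motif position at a time
  pmf <- numeric(hi - lo + 1L)
  cur_lo <- 0L
  pmf[1L] <- 1
  cur_len <- 1L
  bg <- model$background
  for (i in seq_len(L)) {
    row <- q[i, ]
    new_lo <- cur_lo + min(row)
    new_len <- cur_len + (max(row) - min(row))
    new <- numeric(new_len)
    for (b in 1:4) {
      off <- row[b] - min(row)
      idx <- seq_len(cur_len) + off
      new[idx] <- new[idx] + pmf[seq_len(cur_len)] * bg[b]
    }
    pmf[seq_len(new_len)] <- new
    cur_lo <- new_lo
    cur_len <- new_len
  }
  pmf <- pmf[seq_len(cur_len)]
  structure(list(granularity = granularity,
                 int_scores = seq(cur_lo, by = 1L, length.out = cur_len),
                 scores = seq(cur_lo, by = 1L, length.out = cur_len) * granularity,
                 pmf = pmf,
                 sf = rev(cumsum(rev(pmf)))),
            class = "score_distribution")
}

# survival probability at integer score s (P(score >= s))
sf_at <- function(dist, int_score) {
  i <- findInterval(int_score - 1L, dist$int_scores) + 1L
  ifelse(i > length(dist$sf), 0, dist$sf[pmax(i, 1L)])
}

#' Score threshold attaining a p-value
#'
#' Smallest quantized score whose survival probability under the background
#' model is at or below `p_threshold`. Returns `Inf` when even the maximal
#' score is more probable than the threshold (no site can pass).
#'
#' @param dist a [null_score_distribution()] result.
#' @param p_threshold p-value threshold in (0, 1].
#' @return score in bits (on the quantized grid), or `Inf`.
#' @export
pvalue_threshold_score <- function(dist, p_threshold) {
  if (p_threshold <= 0 || p_threshold > 1) stop("p_threshold must be in (0, 1]")
  ok <- which(dist$sf <= p_threshold)
  if (!length(ok)) return(Inf)
  dist$scores[ok[1L]]
}

#' Construct a promoter record
#'
#' @param gene_id gene identifier.
#' @param sequence DNA string over A/C/G/T/N, stored in gene-strand
#'   orientation (position increases downstream).
#' @param tss_index 0-based index of the TSS base within `sequence`.
#' @param gene_strand "+" or "-" (annotation only; offsets are always
#'   gene-strand oriented).
#' @return object of class `promoter_record`.
#' @export
promoter_record <- function(gene_id, sequence, tss_index, gene_strand = "+") {
  if (tss_index < 0 || tss_index >= nchar(sequence))
    stop("tss_index must lie within the sequence")
  if (!gene_strand %in% c("+", "-")) stop("gene_strand must be '+' or '-'")
  structure(list(gene_id = gene_id, sequence = sequence,
                 tss_index = as.integer(tss_index), gene_strand = gene_strand),
            class = "promoter_record")
}

#' Scan a promoter for motif matches
#'
#' Scores every window of the promoter sequence and of its reverse
#' complement, keeping windows whose exact background p-value is at or below
#' `p_threshold`. Windows containing N are skipped. Offsets are TSS-relative
#' and gene-strand oriented (negative = upstream); for hits on either strand
#' the offset is that of the window's 5'-most base in gene orientation.
#'
#' @param model a `motif_model`.
#' @param promoter a [promoter_record()].
#' @param p_threshold scan p-value threshold, default 1e-4.
#' @param dist optional precomputed [null_score_distribution()]; computed on
#'   the fly when `NULL`.
#' @param granularity score quantization step, see [null_score_distribution()].
#' @return data.frame with columns `tf_id`, `gene_id`, `offset`,
#'   `match_strand` ("+" = given sequence, "-" = reverse complement),
#'   `score` (bits) and `pvalue`.
#' @export
scan_promoter <- function(model, promoter, p_threshold = 1e-4, dist = NULL,
                          granularity = 1e-3) {
  if (is.null(dist)) dist <- null_score_distribution(model, granularity)
  thr <- pvalue_threshold_score(dist, p_threshold)
  empty <- data.frame(tf_id = character(), gene_id = character(),
                      offset = integer(), match_strand = character(),
                      score = numeric(), pvalue = numeric())
  L <- nrow(model$pwm)
  if (is.infinite(thr) || nchar(promoter$sequence) < L) return(empty)
  thr_int <- as.integer(round(thr / dist$granularity))
  seq_int <- encode_dna(promoter$sequence)
  qf <- quantize_pwm(model, dist$granularity)
  qr <- quantize_pwm(revcomp_model(model), dist$granularity)
  fwd <- scan_quantized(seq_int, qf, thr_int)
  rev_ <- scan_quantized(seq_int, qr, thr_int)
  pos <- c(fwd$pos, rev_$pos)
  if (!length(pos)) return(empty)
  int_scores <- c(fwd$score, rev_$score)
  data.frame(tf_id = model$tf_id,
             gene_id = promoter$gene_id,
             offset = pos - 1L - promoter$tss_index,
             match_strand = rep(c("+", "-"), c(length(fwd$pos), length(rev_$pos))),
             score = int_scores * dist$granularity,
             pvalue = sf_at(dist, int_scores))
}

# disjoint annuli on the TSS-relative offset; offset 0 counts as downstream
offset_bin <- function(offset) {
  breaks <- c(-10000, -2000, -500, 0, 500, 2000, 10001)
  labs <- c("up10k", "up2k", "up500", "down500", "down2k", "down10k")
  labs[findInterval(offset, breaks)]
}

#' Bin motif hits into strand x distance-window counts
#'
#' Each hit falls in exactly one of 12 disjoint bins: strand (+/-) crossed
#' with distance annuli upstream `[-10000,-2000) [-2000,-500) [-500,0)` and
#' downstream `[0,500) [500,2000) [2000,10000]` of the TSS.
#'
#' @param hits data.frame as returned by [scan_promoter()] (columns `offset`
#'   and `match_strand` are used).
#' @return named integer vector of length 12 (strand "plus" bins first, then
#'   "minus", each ordered up10k, up2k, up500, down500, down2k, down10k).
#' @export
bin_hits <- function(hits) {
  counts <- setNames(integer(12L), MOTIF_BIN_NAMES)
  if (!nrow(hits)) return(counts)
  if (any(hits$offset < -10000 | hits$offset > 10000))
    stop("hit outside promoter")
  strand <- ifelse(hits$match_strand == "+", "plus", "minus")
  key <- paste(strand, offset_bin(hits$offset), sep = "_")
  tab <- table(factor(key, levels = MOTIF_BIN_NAMES))
  counts[] <- as.integer(tab)
  counts
}

#' Promoter motif feature table for a motif collection
#'
#' Scans every promoter with every motif and returns the genes x (TF x 12)
#' matrix of binned hit counts that supplies the motif half of the pair
#' feature vector.
#'
#' @param models list of `motif_model` objects.
#' @param promoters list of [promoter_record()] objects.
#' @inheritParams scan_promoter
#' @return integer matrix, one row per gene, 12 columns per TF named
#'   `<tf_id>.<strand>_<bin>`.
#' @export
motif_feature_table <- function(models, promoters, p_threshold = 1e-4,
                                granularity = 1e-3) {
  genes <- vapply(promoters, function(p) p$gene_id, "")
  tf_ids <- vapply(models, function(m) m$tf_id, "")
  out <- matrix(0L, nrow = length(promoters), ncol = 12L * length(models),
                dimnames = list(genes, as.vector(vapply(tf_ids, function(tf)
                  paste(tf, MOTIF_BIN_NAMES, sep = "."), character(12L)))))
  enc <- lapply(promoters, function(p) encode_dna(p$sequence))
  for (m in seq_along(models)) {
    model <- models[[m]]
    dist <- null_score_distribution(model, granularity)
    thr <- pvalue_threshold_score(dist, p_threshold)
    if (is.infinite(thr)) next
    thr_int <- as.integer(round(thr / dist$granularity))
    qf <- quantize_pwm(model, dist$granularity)
    qr <- quantize_pwm(revcomp_model(model), dist$granularity)
    cols <- (m - 1L) * 12L + seq_len(12L)
    for (g in seq_along(promoters)) {
      tss <- promoters[[g]]$tss_index
      fwd <- scan_quantized(enc[[g]], qf, thr_int)
      rev_ <- scan_quantized(enc[[g]], qr, thr_int)
      offs <- c(fwd$pos, rev_$pos) - 1L - tss
      if (!length(offs)) next
      idx <- rep(c(0L, 6L), c(length(fwd$pos), length(rev_$pos))) +
        findInterval(offs, c(-10000, -2000, -500, 0, 500, 2000, 10001))
      out[g, cols] <- out[g, cols] + tabulate(idx, nbins = 12L)
    }
  }
  out
}
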