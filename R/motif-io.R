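#' Read JASPAR-format position frequency matrices
#'
#' Parses the JASPAR text dialect: a `>ID NAME` header followed by four rows
#' `A [ 1 2 3 ... ]` (brackets optional) giving per-position counts for
#' A, C, G, T. The TF identifier is the motif NAME when present, else the ID.
#' When a file carries several motifs for one TF id, the first is kept and a
#' warning emitted.
#'
#' @param path file path.
#' @inheritParams build_pwm
#' @return named list of `motif_model` objects (one per TF).
#' @export
read_jaspar_pfm <- function(path, pseudocount = 0.1, background = rep(0.25, 4)) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  headers <- grep("^>", lines)
  if (!length(headers)) stop("no JASPAR '>' header found in ", path)
  models <- list()
  for (h in seq_along(headers)) {
    from <- headers[h] + 1L
    to <- if (h < length(headers)) headers[h + 1L] - 1L else length(lines)
    block <- lines[from:to]
    toks <- strsplit(sub("^>\\s*", "", lines[headers[h]]), "\\s+")[[1]]
    tf <- if (length(toks) >= 2) toks[2] else toks[1]
    rows <- lapply(c("A", "C", "G", "T"), function(b) {
      ln <- block[grepl(paste0("^", b, "\\b"), block)]
      if (length(ln) != 1L) stop("motif ", tf, ": missing or duplicated ", b, " row")
      nums <- gsub("[][]", " ", sub(paste0("^", b, "\\s*"), "", ln))
      as.numeric(strsplit(trimws(nums), "\\s+")[[1]])
    })
    if (length(unique(lengths(rows))) != 1L)
      stop("motif ", tf, ": rows of unequal length")
    pfm <- do.call(cbind, rows)
    if (tf %in% names(models)) {
      warning("multiple motifs for TF '", tf, "'; keeping the first")
      next
    }
    models[[tf]] <- build_pwm(pfm, pseudocount = pseudocount,
                              background = background, tf_id = tf)
  }
  models
}

#' Read motifs from minimal MEME text format
#'
#' Supports the minimal MEME dialect: a `MEME version` line, an optional
#' `ALPHABET` line, and for each motif a `MOTIF <id> [name]` line followed by
#' a `letter-probability matrix:` block (`w=` positions, optional `nsites=`).
#' Probabilities are converted to counts by multiplying with `nsites`
#' (default 20 when absent).
#'
#' @inheritParams read_jaspar_pfm
#' @return named list of `motif_model` objects.
#' @export
read_meme_motifs <- function(path, pseudocount = 0.1, background = rep(0.25, 4)) {
  lines <- trimws(readLines(path))
  starts <- grep("^MOTIF\\b", lines)
  if (!length(starts)) stop("no MOTIF block found in ", path)
  models <- list()
  for (s in starts) {
    toks <- strsplit(lines[s], "\\s+")[[1]]
    tf <- if (length(toks) >= 3) toks[3] else toks[2]
    lp <- s + grep("^letter-probability matrix", lines[(s + 1):length(lines)])[1]
    if (is.na(lp)) stop("motif ", tf, ": no letter-probability matrix block")
    w <- suppressWarnings(as.integer(sub(".*\\bw=\\s*(\\d+).*", "\\1", lines[lp])))
    nsites <- suppressWarnings(as.numeric(sub(".*\\bnsites=\\s*([0-9.]+).*", "\\1", lines[lp])))
    if (is.na(nsites) || !grepl("nsites=", lines[lp])) nsites <- 20
    if (is.na(w)) stop("motif ", tf, ": missing w= in matrix header")
    rows <- lines[(lp + 1):(lp + w)]
    probs <- t(vapply(strsplit(rows, "\\s+"),
                      function(x) as.numeric(x[nzchar(x)])[1:4], numeric(4)))
    if (anyNA(probs)) stop("motif ", tf, ": malformed probability row")
    if (tf %in% names(models)) {
      warning("multiple motifs for TF '", tf, "'; keeping the first")
      next
    }
    models[[tf]] <- build_pwm(probs * nsites, pseudocount = pseudocount,
                              background = background, tf_id = tf)
  }
  models
}

#' Estimate a 0-order background from promoter sequences
#'
#' Base composition (A, C, G, T) pooled over the given sequences, ignoring N.
#'
#' @param promoters list of [promoter_record()] objects.
#' @return length-4 probability vector.
#' @export
estimate_background <- function(promoters) {
  counts <- integer(4L)
  for (p in promoters) {
    enc <- encode_dna(p$sequence)
    tab <- tabulate(enc[enc > 0L], nbins = 4L)
    counts <- counts + tab
  }
  if (sum(counts) == 0) stop("no A/C/G/T bases in promoters")
  setNames(counts / sum(counts), DNA_BASES)
}
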