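pkg_header <- function() {
  paste0("# ocregnet ", as.character(utils::packageVersion("ocregnet")),
         " | ", format(Sys.time(), "%Y-%m-%d"))
}

write_tsv <- function(df, path, header = TRUE) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(pkg_header(), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = header)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE, ...)
}

#' Read promoters from FASTA plus a TSS table
#'
#' Joins a FASTA of promoter sequences (keyed by gene id) with a TSV giving
#' `gene_id`, `tss_index` (0-based index of the TSS base within the
#' sequence) and `gene_strand`. Genes missing a TSS row are dropped with a
#' warning.
#'
#' @param fasta_path FASTA file path.
#' @param tss_path TSS table path (tab-separated, header).
#' @return named list of [promoter_record()] objects.
#' @export
read_promoters <- function(fasta_path, tss_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (!length(seqs)) {
    warning("empty FASTA: ", fasta_path)
    return(list())
  }
  ids <- sub("\\s.*$", "", names(seqs))
  tss <- read_tsv(tss_path)
  need <- c("gene_id", "tss_index", "gene_strand")
  if (!all(need %in% names(tss)))
    stop("TSS table must have columns: ", paste(need, collapse = ", "))
  if (any(is.na(suppressWarnings(as.integer(tss$tss_index)))))
    stop("non-integer tss_index in ", tss_path)
  keep <- ids %in% tss$gene_id
  if (any(!keep))
    warning(sum(!keep), " sequence(s) without a TSS row dropped")
  out <- lapply(which(keep), function(i) {
    row <- tss[match(ids[i], tss$gene_id), ]
    promoter_record(ids[i], as.character(seqs[[i]]),
                    as.integer(row$tss_index), row$gene_strand)
  })
  stats::setNames(out, ids[keep])
}

#' Write promoters to FASTA plus a TSS table
#'
#' @param promoters list of [promoter_record()] objects.
#' @param fasta_path,tss_path output paths.
#' @export
write_promoters <- function(promoters, fasta_path, tss_path) {
  seqs <- Biostrings::DNAStringSet(
    stats::setNames(vapply(promoters, function(p) p$sequence, ""),
                    vapply(promoters, function(p) p$gene_id, "")))
  Biostrings::writeXStringSet(seqs, fasta_path)
  write_tsv(data.frame(
    gene_id = vapply(promoters, function(p) p$gene_id, ""),
    tss_index = vapply(promoters, function(p) p$tss_index, 1L),
    gene_strand = vapply(promoters, function(p) p$gene_strand, "")), tss_path)
}

#' Read a genes x samples expression table
#'
#' First column gene ids, remaining columns numeric sample values.
#'
#' @param path TSV path.
#' @return numeric matrix with gene rownames.
#' @export
read_expression_tsv <- function(path) {
  df <- read_tsv(path, check.names = FALSE)
  genes <- df[[1]]
  if (anyDuplicated(genes))
    stop("duplicate gene row(s): ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- suppressWarnings(as.numeric(vals[[j]]))
    if (anyNA(v) && !anyNA(vals[[j]]))
      stop("non-numeric value in column '", names(vals)[j], "', row ",
           which(is.na(v))[1], " of ", path)
    vals[[j]] <- v
  }
  m <- as.matrix(vals)
  rownames(m) <- genes
  m
}

#' @rdname read_expression_tsv
#' @param expr matrix to write.
#' @export
write_expression_tsv <- function(expr, path) {
  write_tsv(data.frame(gene_id = rownames(expr), expr, check.names = FALSE),
            path)
}

#' Read a sample sheet
#'
#' Columns `sample_id`, `group` (tumor/normal), `pair_id`; every sample
#' must be present in the expression matrix when one is given.
#'
#' @param path TSV path.
#' @param expr optional expression matrix to validate against.
#' @return data.frame.
#' @export
read_sample_sheet <- function(path, expr = NULL) {
  df <- read_tsv(path)
  need <- c("sample_id", "group")
  if (!all(need %in% names(df)))
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  if (!is.null(expr)) {
    missing <- setdiff(df$sample_id, colnames(expr))
    if (length(missing))
      stop("sample(s) absent from expression matrix: ",
           paste(missing, collapse = ", "))
  }
  df
}

#' Read a two-column PPI edge list
#'
#' @param path TSV path (first two columns are the interacting gene ids).
#' @return data.frame with columns `a`, `b`.
#' @export
read_ppi_tsv <- function(path) {
  df <- read_tsv(path)
  if (ncol(df) < 2) stop("PPI table needs two columns")
  out <- unique(data.frame(a = as.character(df[[1]]), b = as.character(df[[2]])))
  rownames(out) <- NULL
  out
}

#' Read TRRUST-style curated TF-target relations
#'
#' Four tab-separated columns: TF, target, mode, reference. Relations are
#' deduplicated on (TF, target); duplicates with differing modes are merged
#' with a warning.
#'
#' @param path TSV path.
#' @return data.frame (`tf_id`, `gene_id`, `mode`, `source`).
#' @export
read_curated_tsv <- function(path) {
  df <- read_tsv(path, header = FALSE)
  if (ncol(df) < 2) stop("curated table needs at least TF and target columns")
  names(df)[1:2] <- c("tf_id", "gene_id")
  df$mode <- if (ncol(df) >= 3) as.character(df[[3]]) else NA_character_
  df$source <- if (ncol(df) >= 4) as.character(df[[4]]) else NA_character_
  key <- paste(df$tf_id, df$gene_id)
  if (anyDuplicated(key)) {
    dups <- key[duplicated(key)]
    modes <- tapply(df$mode, key, function(m) paste(unique(m), collapse = ";"))
    df <- df[!duplicated(key), , drop = FALSE]
    df$mode <- as.character(modes[paste(df$tf_id, df$gene_id)])
    warning(length(unique(dups)), " duplicated (TF, target) relation(s) merged")
  }
  df[, c("tf_id", "gene_id", "mode", "source")]
}

#' Read gene-to-term annotations
#'
#' @param path two-column TSV (`gene_id`, `term_id`).
#' @return data.frame.
#' @export
read_annotations_tsv <- function(path) {
  df <- read_tsv(path)
  if (ncol(df) < 2) stop("annotation table needs two columns")
  stats::setNames(df[, 1:2], c("gene_id", "term_id"))
}

#' Write a predicted network with its degree-summary sidecar
#'
#' One `tf_id`/`gene_id` edge per line, plus a JSON sidecar
#' (`<path>.summary.json`) with per-TF/per-gene degree summaries.
#'
#' @param network a `regulatory_network`.
#' @param path output TSV path.
#' @export
write_network_tsv <- function(network, path) {
  edges <- network$edges[order(network$edges$tf_id, network$edges$gene_id), ]
  write_tsv(edges, path)
  deg <- network_degree_summary(network)
  jsonlite::write_json(list(n_edges = nrow(edges),
                            n_tfs = length(network$tfs),
                            n_genes = length(network$genes),
                            tf_degree = as.list(deg$tf_summary),
                            gene_degree = as.list(deg$gene_summary)),
                       paste0(path, ".summary.json"), auto_unbox = TRUE)
}

#' @rdname write_network_tsv
#' @export
read_network_tsv <- function(path) {
  edges <- read_tsv(path)
  structure(list(edges = edges, tfs = unique(edges$tf_id),
                 genes = unique(edges$gene_id)),
            class = "regulatory_network")
}

#' Write the core-TF table
#'
#' Columns DS (dataset), DIR (direction), TF, lfc, p, ntargs and targs
#' (comma-separated deregulated targets), sorted by DS, DIR, TF.
#'
#' @param core_tfs a [identify_core_tfs()] result.
#' @param path output path.
#' @param dataset dataset label for the DS column.
#' @export
write_core_tf_table <- function(core_tfs, path, dataset = "DS1") {
  df <- data.frame(DS = dataset,
                   DIR = core_tfs$direction,
                   TF = core_tfs$tf_id,
                   lfc = sprintf("%.4f", core_tfs$tf_log2fc),
                   p = sprintf("%.4g", core_tfs$tf_p),
                   ntargs = lengths(core_tfs$targets),
                   targs = vapply(core_tfs$targets, paste, "", collapse = ","))
  df <- df[order(df$DS, df$DIR, df$TF), ]
  write_tsv(df, path)
}

#' Write the GO enrichment table
#'
#' Columns DS, DIR, TF, GO, Term, Annotated, GOI, Hits, OR, pFisher, Genes.
#'
#' @param records a [term_enrichment()] result.
#' @param onto the [ontology] (for term names).
#' @param path output path.
#' @param dataset,direction,tf labels for the leading columns.
#' @export
write_enrichment_table <- function(records, onto, path, dataset = "DS1",
                                   direction = "up", tf = "") {
  nm <- stats::setNames(onto$terms$name, onto$terms$id)
  df <- data.frame(DS = dataset, DIR = direction, TF = tf,
                   GO = records$term_id,
                   Term = as.character(nm[records$term_id]),
                   Annotated = records$annotated, GOI = records$goi,
                   Hits = records$hits,
                   OR = sprintf("%.4f", records$odds_ratio),
                   pFisher = sprintf("%.4g", records$p),
                   Genes = vapply(records$gene_hits, paste, "", collapse = ","))
  write_tsv(df[order(df$DS, df$DIR, df$TF, as.numeric(df$pFisher)), ], path)
}

#' Write all synthetic-study artifacts to a directory
#'
#' Emits promoters.fa, tss.tsv, ref_expr.tsv, dataset_expr.tsv,
#' samples.tsv, ppi.tsv, curated.tsv and truth.json.
#'
#' @param sim a [simulate_regnet()] result.
#' @param out_dir output directory (created if needed).
#' @export
write_simulation <- function(sim, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_promoters(sim$promoters, p("promoters.fa"), p("tss.tsv"))
  write_expression_tsv(sim$ref_raw, p("ref_expr.tsv"))
  write_expression_tsv(sim$dataset_raw, p("dataset_expr.tsv"))
  write_tsv(sim$samples, p("samples.tsv"))
  write_tsv(sim$ppi, p("ppi.tsv"))
  con <- file(p("curated.tsv"), "w")
  writeLines(pkg_header(), con)
  utils::write.table(sim$curated, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  close(con)
  jsonlite::write_json(
    list(tfs = sim$truth$tfs,
         tf_targets = sim$truth$tf_targets,
         deregulated = sim$truth$deregulated,
         config = unclass(sim$truth$config)),
    p("truth.json"), auto_unbox = TRUE)
  invisible(out_dir)
}
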