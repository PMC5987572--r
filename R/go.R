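#' Read a minimal OBO ontology
#'
#' Parses `[Term]` stanzas for `id`, `name`, `namespace` and `is_a` parent
#' links (obsolete terms skipped). The parent graph must be acyclic and
#' every referenced parent must exist.
#'
#' @param path OBO file path.
#' @return object of class `ontology`: `terms` data.frame (`id`, `name`,
#'   `namespace`) and `parents`, a named list of parent term ids.
#' @export
read_obo <- function(path) {
  lines <- trimws(readLines(path))
  starts <- which(lines == "[Term]")
  if (!length(starts)) stop("no [Term] stanza found in ", path)
  bounds <- c(starts, length(lines) + 1L)
  ids <- names <- namespaces <- character(length(starts))
  parents <- vector("list", length(starts))
  keep <- logical(length(starts))
  for (k in seq_along(starts)) {
    block <- lines[(bounds[k] + 1L):(bounds[k + 1L] - 1L)]
    block <- block[!grepl("^\\[", block)]
    get1 <- function(key) {
      v <- sub(paste0("^", key, ":\\s*"), "", block[startsWith(block, paste0(key, ":"))])
      if (length(v)) v[1] else NA_character_
    }
    if (isTRUE(get1("is_obsolete") == "true")) next
    ids[k] <- get1("id")
    if (is.na(ids[k])) next
    names[k] <- get1("name")
    namespaces[k] <- get1("namespace")
    isa <- block[startsWith(block, "is_a:")]
    parents[[k]] <- trimws(sub("!.*$", "", sub("^is_a:\\s*", "", isa)))
    keep[k] <- TRUE
  }
  ids <- ids[keep]; names <- names[keep]; namespaces <- namespaces[keep]
  parents <- stats::setNames(parents[keep], ids)
  missing_parents <- setdiff(unlist(parents), ids)
  if (length(missing_parents))
    warning("parent term(s) not defined: ", paste(missing_parents, collapse = ", "))
  onto <- structure(list(terms = data.frame(id = ids, name = names,
                                            namespace = namespaces),
                         parents = parents),
                    class = "ontology")
  # acyclicity check by exhaustive ancestor closure
  anc <- ontology_ancestors(onto)
  cyc <- vapply(ids, function(i) i %in% anc[[i]], logical(1))
  if (any(cyc)) stop("ontology contains a cycle through: ",
                     paste(ids[cyc], collapse = ", "))
  onto
}

#' Construct an ontology from term and parent vectors (for simulated data)
#'
#' @param id,name,namespace character vectors of equal length.
#' @param parents named list mapping term id to parent ids.
#' @return an `ontology` object.
#' @export
ontology <- function(id, name = id, namespace = "biological_process",
                     parents = stats::setNames(rep(list(character(0)), length(id)), id)) {
  structure(list(terms = data.frame(id = id, name = name,
                                    namespace = rep_len(namespace, length(id))),
                 parents = parents[id]),
            class = "ontology")
}

# full ancestor sets (excluding the term itself, unless cyclic) per term
ontology_ancestors <- function(onto) {
  ids <- onto$terms$id
  anc <- stats::setNames(vector("list", length(ids)), ids)
  visiting <- character(0)
  walk <- function(id) {
    if (!is.null(anc[[id]])) return(anc[[id]])
    if (id %in% visiting) return(character(0))  # cycle guard; flagged upstream
    visiting <<- c(visiting, id)
    ps <- intersect(onto$parents[[id]], ids)
    out <- unique(c(ps, unlist(lapply(ps, walk))))
    visiting <<- setdiff(visiting, id)
    anc[[id]] <<- out
    out
  }
  for (id in ids) walk(id)
  anc
}

#' Propagate annotations up the ontology (true-path rule)
#'
#' Every gene annotated to a term is also annotated to all of the term's
#' ancestors; the operation is idempotent and annotations to unknown terms
#' are skipped with a warning.
#'
#' @param annotations data.frame with columns `gene_id`, `term_id` (direct
#'   annotations).
#' @param onto an [ontology].
#' @return data.frame (`gene_id`, `term_id`) of propagated annotations,
#'   without duplicates.
#' @export
propagate_annotations <- function(annotations, onto) {
  annotations <- as.data.frame(annotations)
  known <- annotations$term_id %in% onto$terms$id
  if (any(!known)) {
    warning(sum(!known), " annotation(s) to unknown term(s) skipped: ",
            paste(unique(annotations$term_id[!known]), collapse = ", "))
    annotations <- annotations[known, , drop = FALSE]
  }
  anc <- ontology_ancestors(onto)
  expanded <- lapply(seq_len(nrow(annotations)), function(i) {
    terms <- unique(c(annotations$term_id[i], anc[[annotations$term_id[i]]]))
    data.frame(gene_id = annotations$gene_id[i], term_id = terms)
  })
  out <- unique(do.call(rbind, c(expanded, list(annotations[0, c("gene_id", "term_id")]))))
  rownames(out) <- NULL
  out
}

#' GO term enrichment of a query gene set
#'
#' One-sided Fisher's exact test per term on the 2x2 table of query
#' membership versus (propagated) term annotation over the universe. A term
#' is flagged significant at `p < min_p` and odds ratio `> min_or`.
#'
#' @param query_genes character vector, subset of `universe`.
#' @param universe character vector of background genes.
#' @param annotations propagated annotations ([propagate_annotations()]).
#' @param onto optional [ontology]; when given, testing is restricted to
#'   `namespace`.
#' @param namespace namespace filter (default `"biological_process"`).
#' @param min_p,min_or significance thresholds (defaults 0.05 and 2).
#' @return data.frame sorted by p: `term_id`, `annotated`, `goi`, `hits`,
#'   `odds_ratio`, `p`, `significant`, `gene_hits` (list-column).
#' @export
term_enrichment <- function(query_genes, universe, annotations, onto = NULL,
                            namespace = "biological_process",
                            min_p = 0.05, min_or = 2) {
  query_genes <- unique(query_genes)
  universe <- unique(universe)
  if (length(setdiff(query_genes, universe)))
    stop("query genes must be a subset of the universe")
  out <- data.frame(term_id = character(), annotated = integer(),
                    goi = integer(), hits = integer(),
                    odds_ratio = numeric(), p = numeric(),
                    significant = logical())
  out$gene_hits <- list()
  if (!length(query_genes)) return(out)
  ann <- annotations[annotations$gene_id %in% universe, , drop = FALSE]
  if (!is.null(onto)) {
    keep <- onto$terms$id[onto$terms$namespace == namespace]
    ann <- ann[ann$term_id %in% keep, , drop = FALSE]
  }
  N <- length(universe)
  goi <- length(query_genes)
  by_term <- split(ann$gene_id, ann$term_id)
  rows <- lapply(names(by_term), function(term) {
    genes <- unique(by_term[[term]])
    annotated <- length(genes)
    hit_genes <- intersect(genes, query_genes)
    hits <- length(hit_genes)
    p <- stats::phyper(hits - 1, annotated, N - annotated, goi,
                       lower.tail = FALSE)
    d1 <- goi - hits
    d2 <- annotated - hits
    rest <- N - annotated - d1
    or <- if (d1 == 0 || d2 == 0)
      ((hits + 0.5) * (rest + 0.5)) / ((d1 + 0.5) * (d2 + 0.5))
    else (hits * rest) / (d1 * d2)
    row <- data.frame(term_id = term, annotated = annotated, goi = goi,
                      hits = hits, odds_ratio = or, p = p,
                      significant = (p < min_p && or > min_or && hits > 0))
    row$gene_hits <- list(hit_genes)
    row
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Prune significant terms toward the most specific
#'
#' Drops every significant term that has a significant descendant in the
#' record set, so the result carries no ancestor-descendant pair (priority
#' to more specific terms).
#'
#' @param records significant rows of a [term_enrichment()] result.
#' @param onto the [ontology].
#' @return the retained records.
#' @export
hierarchy_prune <- function(records, onto) {
  if (!nrow(records)) return(records)
  anc <- ontology_ancestors(onto)
  terms <- records$term_id
  # a term is dropped when it is an ancestor of another significant term
  ancestors_in_set <- unique(unlist(anc[terms]))
  keep <- !(terms %in% ancestors_in_set)
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
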