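# Minimal OBO ontology parsing: [Term] stanzas with is_a and part_of
# edges, obsolete-term filtering, ancestor closure with cycle detection.

#' Read a GO ontology from an OBO file
#'
#' Parses `[Term]` stanzas, keeping `id`, `name`, `namespace`, `is_a`
#' parents and `relationship: part_of` parents; obsolete terms are
#' dropped. Both edge types are treated as parent edges for annotation
#' propagation.
#'
#' @param path OBO file.
#' @return object of class `go_ontology`: `terms` (data.frame `id`,
#'   `name`, `namespace`), `parents` (named list of parent id vectors) and
#'   `roots` (ids without parents).
#' @export
read_obo <- function(path) {
  lines <- readLines(path)
  starts <- which(lines == "[Term]")
  terms <- list()
  for (s in starts) {
    end <- s
    repeat {
      end <- end + 1L
      if (end > length(lines) || startsWith(lines[end], "[")) break
    }
    block <- lines[(s + 1L):(end - 1L)]
    field <- function(key) {
      hit <- block[startsWith(block, paste0(key, ": "))]
      sub("\\s*!.*$", "", substring(hit, nchar(key) + 3L))
    }
    if (length(field("is_obsolete")) && field("is_obsolete")[1] == "true")
      next
    id <- field("id")[1]
    if (is.na(id)) next
    rel <- field("relationship")
    part_of <- sub("^part_of\\s+", "",
                   rel[startsWith(rel, "part_of")])
    terms[[id]] <- list(id = id,
                        name = if (length(field("name"))) field("name")[1]
                               else id,
                        namespace = if (length(field("namespace")))
                          field("namespace")[1] else NA_character_,
                        parents = unique(c(field("is_a"), part_of)))
  }
  ids <- names(terms)
  parents <- lapply(terms, function(t) intersect(t$parents, ids))
  structure(list(
    terms = data.frame(
      id = ids,
      name = vapply(terms, `[[`, character(1), "name"),
      namespace = vapply(terms, `[[`, character(1), "namespace"),
      stringsAsFactors = FALSE, row.names = NULL),
    parents = parents,
    roots = ids[lengths(parents) == 0L]), class = "go_ontology")
}

#' @export
print.go_ontology <- function(x, ...) {
  cat("go_ontology:", nrow(x$terms), "terms,", length(x$roots),
      "root(s):", paste(x$roots, collapse = ", "), "\n")
  invisible(x)
}

#' Ancestors of every term (transitive closure of parent edges)
#'
#' @param ontology a `go_ontology`.
#' @return named list: for each term id, the character vector of all its
#'   ancestors (self excluded). A cycle raises an error naming the terms
#'   involved.
#' @export
term_ancestors <- function(ontology) {
  parents <- ontology$parents
  anc <- setNames(vector("list", length(parents)), names(parents))
  state <- setNames(rep(0L, length(parents)), names(parents)) # 0 new, 1 open, 2 done
  visit <- function(id, path) {
    if (state[[id]] == 1L)
      stop("cycle detected in ontology: ",
           paste(c(path[which(path == id):length(path)], id),
                 collapse = " -> "))
    if (state[[id]] == 2L) return(anc[[id]])
    state[[id]] <<- 1L
    out <- character(0)
    for (p in parents[[id]])
      out <- union(out, c(p, visit(p, c(path, id))))
    state[[id]] <<- 2L
    anc[[id]] <<- out
    out
  }
  for (id in names(parents)) visit(id, character(0))
  anc
}

#' Propagate gene annotations up the ontology
#'
#' Annotates each gene to every ancestor (is_a / part_of) of its direct
#' terms. Terms absent from the ontology are kept as-is (flat
#' annotations). The operation is idempotent.
#'
#' @param annotations data.frame with `gene`, `term`.
#' @param ontology a `go_ontology`.
#' @return data.frame `gene`, `term`, closed upward and deduplicated.
#' @export
propagate_annotations <- function(annotations, ontology) {
  anc <- term_ancestors(ontology)
  by_term <- split(annotations$gene, annotations$term)
  expanded <- lapply(names(by_term), function(t) {
    terms <- c(t, anc[[t]])
    genes <- by_term[[t]]
    data.frame(gene = rep(genes, times = length(terms)),
               term = rep(terms, each = length(genes)),
               stringsAsFactors = FALSE)
  })
  out <- unique(do.call(rbind, expanded))
  out <- out[order(out$gene, out$term), ]
  rownames(out) <- NULL
  out
}
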