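# GO over-representation analysis of paralog groups: the WGD and tandem
# groups plus the six Ks ranges A-F, hypergeometric tests with a minimum
# background set size and Benjamini-Hochberg correction.

KS_GROUP_BOUNDS <- list(A = c(0, 0.5), B = c(0.5, 1), C = c(1, 1.5),
                        D = c(1.5, 2), E = c(0, 1), F = c(1, 2))

#' Build the eight paralog groups from representative pairs
#'
#' `WGD` and `tandem` groups collect the genes of pairs with those
#' mechanism labels; groups `A`-`F` collect genes of pairs in the Ks
#' ranges (A) 0 < Ks <= 0.5, (B) 0.5 < Ks <= 1, (C) 1 < Ks <= 1.5,
#' (D) 1.5 < Ks <= 2, (E) 0 < Ks <= 1 and (F) 1 < Ks <= 2, regardless of
#' mechanism (undefined pairs included). Gene sets are unions of both pair
#' members, deduplicated.
#'
#' @param rep_pairs data.frame with `gene_a`, `gene_b`, `label`, `ks`.
#' @return named list of unique gene-id vectors (`WGD`, `tandem`,
#'   `A`..`F`).
#' @export
build_groups <- function(rep_pairs) {
  genes_of <- function(rows)
    sort(unique(c(rep_pairs$gene_a[rows], rep_pairs$gene_b[rows])))
  out <- list(WGD = genes_of(rep_pairs$label == "WGD"),
              tandem = genes_of(rep_pairs$label == "tandem"))
  for (g in names(KS_GROUP_BOUNDS)) {
    b <- KS_GROUP_BOUNDS[[g]]
    out[[g]] <- genes_of(rep_pairs$ks > b[1] & rep_pairs$ks <= b[2])
  }
  out
}

#' Hypergeometric over-representation test for one paralog group
#'
#' For every GO term annotated to at least `min_set` background genes, the
#' upper-tail hypergeometric p-value for over-representation (P[X >= k]
#' when drawing n group genes from the N background genes of which K carry
#' the term) and the lower tail for under-representation; the reported
#' direction is the smaller side. Benjamini-Hochberg correction is applied
#' across the tested terms within the group. Genes are deduplicated before
#' counting.
#'
#' @param group character vector of group gene ids (subset of
#'   `background`).
#' @param background character vector of universe gene ids.
#' @param annotations data.frame `gene`, `term` (propagated; see
#'   [propagate_annotations()]).
#' @param min_set minimum background annotation count K for a term to be
#'   tested (default 10). Set `min_set_on = "group"` to apply it to the
#'   group count k instead.
#' @param min_set_on `"background"` (default) or `"group"`.
#' @param exclude_terms terms never tested (e.g. ontology roots).
#' @param group_name label recorded in the output.
#' @return data.frame: `term`, `group`, `k`, `n`, `K`, `N`, `raw_p`,
#'   `corrected_p`, `direction`, ordered by `raw_p`.
#' @export
ora_test <- function(group, background, annotations, min_set = 10,
                     min_set_on = c("background", "group"),
                     exclude_terms = character(0), group_name = "group") {
  min_set_on <- match.arg(min_set_on)
  empty <- data.frame(term = character(0), group = character(0),
                      k = integer(0), n = integer(0), K = integer(0),
                      N = integer(0), raw_p = numeric(0),
                      corrected_p = numeric(0), direction = character(0),
                      stringsAsFactors = FALSE)
  group <- unique(group)
  background <- unique(background)
  if (!all(group %in% background))
    stop("group contains genes absent from the background")
  if (!length(group)) return(empty)
  ann <- unique(annotations[annotations$gene %in% background, ,
                            drop = FALSE])
  ann <- ann[!ann$term %in% exclude_terms, , drop = FALSE]
  if (!nrow(ann)) return(empty)
  N <- length(background)
  n <- length(group)
  K_tab <- table(ann$term)
  k_tab <- table(ann$term[ann$gene %in% group])
  terms <- names(K_tab)
  K <- as.integer(K_tab)
  k <- as.integer(k_tab[terms]); k[is.na(k)] <- 0L
  tested <- if (min_set_on == "background") K >= min_set else k >= min_set
  if (!any(tested)) return(empty)
  terms <- terms[tested]; K <- K[tested]; k <- k[tested]
  p_over <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  p_under <- phyper(k, K, N - K, n)
  direction <- ifelse(p_over <= p_under, "over", "under")
  raw_p <- pmin(p_over, p_under)
  out <- data.frame(term = terms, group = group_name, k = k, n = n, K = K,
                    N = N, raw_p = raw_p,
                    corrected_p = p.adjust(raw_p, method = "BH"),
                    direction = direction, stringsAsFactors = FALSE)
  out <- out[order(out$raw_p, out$term), ]
  rownames(out) <- NULL
  out
}

#' Run the ORA over all paralog groups
#'
#' @param groups named list of gene sets from [build_groups()].
#' @param background universe gene ids (default: union of all group
#'   genes; the studied universe is the duplicate genes themselves, a
#'   whole-genome background can be passed explicitly).
#' @inheritParams ora_test
#' @return combined data.frame over groups (see [ora_test()]).
#' @export
ora_all_groups <- function(groups, background = NULL, annotations,
                           min_set = 10, exclude_terms = character(0)) {
  if (is.null(background)) background <- sort(unique(unlist(groups)))
  out <- do.call(rbind, lapply(names(groups), function(g)
    ora_test(groups[[g]], background, annotations, min_set = min_set,
             exclude_terms = exclude_terms, group_name = g)))
  rownames(out) <- NULL
  out
}

#' Term-by-group matrix of corrected p-values
#'
#' The tabular twin of a cross-group enrichment heat map: one row per
#' term, one column of corrected p-values per paralog group (NA where the
#' term was not tested in that group).
#'
#' @param results combined results from [ora_all_groups()].
#' @return data.frame with `term` plus one column per group.
#' @export
enrichment_heatmap_table <- function(results) {
  terms <- sort(unique(results$term))
  groups <- unique(results$group)
  out <- data.frame(term = terms, stringsAsFactors = FALSE)
  for (g in groups) {
    sub <- results[results$group == g, ]
    out[[g]] <- sub$corrected_p[match(terms, sub$term)]
  }
  out
}
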