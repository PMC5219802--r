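# Reduce the many-to-many paralog-pair universe to each gene's
# representative pair using the three precedence rules: per gene, a
# WGD-labelled pair beats tandem beats undefined, and within the winning
# class the lowest-Ks pair is kept.

#' Select representative paralog pairs (rules I-III)
#'
#' For each gene: if it participates in at least one WGD-labelled pair,
#' its lowest-Ks WGD pair is emitted (rule I); otherwise its lowest-Ks
#' tandem pair (rule II); otherwise its lowest-Ks undefined pair
#' (rule III). A pair is never blocked because the partner gene was
#' claimed under a different rule, and pairs selected from both endpoints
#' appear once. Ks ties break to the lexicographically smaller partner id.
#'
#' @param pairs data.frame with `gene_a`, `gene_b`, `label`
#'   (WGD/tandem/undefined) and `ks`; only Ks-filtered pairs should be
#'   passed (see [filter_estimates()]).
#' @return data.frame `gene_a`, `gene_b`, `label`, `ks`,
#'   `selected_by_rule` (I/II/III), deduplicated and sorted.
#' @export
select_pairs <- function(pairs) {
  empty <- data.frame(gene_a = character(0), gene_b = character(0),
                      label = character(0), ks = numeric(0),
                      selected_by_rule = character(0),
                      stringsAsFactors = FALSE)
  if (!nrow(pairs)) return(empty)
  stopifnot(all(pairs$label %in% c("WGD", "tandem", "undefined")),
            !any(is.na(pairs$ks)))
  # long form: one row per (gene, pair)
  long <- rbind(
    data.frame(gene = pairs$gene_a, partner = pairs$gene_b,
               row = seq_len(nrow(pairs)), stringsAsFactors = FALSE),
    data.frame(gene = pairs$gene_b, partner = pairs$gene_a,
               row = seq_len(nrow(pairs)), stringsAsFactors = FALSE))
  long$label <- pairs$label[long$row]
  long$ks <- pairs$ks[long$row]
  rule_rank <- c(WGD = 1L, tandem = 2L, undefined = 3L)
  long$rank <- rule_rank[long$label]
  # order so that the first row per gene is its winner:
  # best rule class, then lowest Ks, then smaller partner id
  long <- long[order(long$gene, long$rank, long$ks, long$partner), ]
  winners <- long[!duplicated(long$gene), ]
  rows <- sort(unique(winners$row))
  out <- data.frame(gene_a = pairs$gene_a[rows], gene_b = pairs$gene_b[rows],
                    label = pairs$label[rows], ks = pairs$ks[rows],
                    selected_by_rule = c(WGD = "I", tandem = "II",
                                         undefined = "III")[pairs$label[rows]],
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_a, out$gene_b), ]
  rownames(out) <- NULL
  out
}
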