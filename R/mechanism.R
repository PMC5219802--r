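# Duplication-mechanism classification: DAGchainer-style collinear
# chaining in gene-order coordinates for WGD calls, an intervening-gene
# rule for tandem calls, undefined otherwise.

#' Default chaining parameters
#'
#' Reconstruction of DAGchainer-style defaults restated in gene-index
#' space: anchor match score min(50, -log10(evalue)) with floor 1, gap
#' penalty 1 per skipped gene per axis, maximum gap 20 genes per axis,
#' minimum 5 anchors per chain, and a tandem exclusion window of 11 gene
#' ranks for within-chromosome self comparisons (anchors closer than that
#' are ignored by the chainer, mirroring the tandem rule of at most 10
#' intervening genes).
#'
#' @return named list of parameters accepted by [chain_anchors()] and
#'   [label_mechanisms()].
#' @export
chain_params <- function() {
  list(score_cap = 50, score_floor = 1, gap_penalty = 1,
       max_gap = 20, min_anchors = 5, tandem_window = 11)
}

#' Anchors from candidate pairs and gene-order coordinates
#'
#' Places each candidate pair in gene-order space: chromosome ids and
#' 1-based ordinal gene ranks, oriented so that `chrom_a <= chrom_b` (and
#' `idx_a < idx_b` within a chromosome). The match score is
#' `min(score_cap, -log10(evalue))`, floored at `score_floor`.
#'
#' @param pairs data.frame with `gene_a`, `gene_b`, `evalue`.
#' @param coords data.frame with `gene`, `chromosome`, `ordinal_index`.
#' @param params see [chain_params()].
#' @return data.frame of anchors: `pair_id` (row index into `pairs`),
#'   `chrom_a`, `chrom_b`, `idx_a`, `idx_b`, `score`. Pairs with missing
#'   coordinates are omitted (their ids are in attribute `"missing"`).
#' @export
make_anchors <- function(pairs, coords, params = chain_params()) {
  at <- match(pairs$gene_a, coords$gene)
  bt <- match(pairs$gene_b, coords$gene)
  missing <- which(is.na(at) | is.na(bt))
  ok <- setdiff(seq_len(nrow(pairs)), missing)
  ca <- as.character(coords$chromosome[at[ok]])
  cb <- as.character(coords$chromosome[bt[ok]])
  ia <- coords$ordinal_index[at[ok]]
  ib <- coords$ordinal_index[bt[ok]]
  swap <- ca > cb | (ca == cb & ia > ib)
  tmp <- ca[swap]; ca[swap] <- cb[swap]; cb[swap] <- tmp
  tmp <- ia[swap]; ia[swap] <- ib[swap]; ib[swap] <- tmp
  score <- pmax(params$score_floor,
                pmin(params$score_cap,
                     -log10(pmax(pairs$evalue[ok], 1e-300))))
  out <- data.frame(pair_id = ok, chrom_a = ca, chrom_b = cb,
                    idx_a = ia, idx_b = ib, score = score,
                    stringsAsFactors = FALSE)
  attr(out, "missing") <- missing
  out
}

#' Chain collinear anchors on one chromosome pair
#'
#' Highest-scoring-chain dynamic programming over anchors sorted by
#' `idx_a`: a predecessor is chainable if both indices strictly advance
#' (forward pass; a mirrored pass with `idx_b` negated finds reverse
#' chains), the gap cost is `gap_penalty * (delta_idx_a + delta_idx_b - 2)`
#' and links with either delta exceeding `max_gap` are forbidden. Chains
#' are extracted greedily best-first with used anchors removed; chains
#' shorter than `min_anchors` are discarded at the end. For
#' within-chromosome self comparisons (`chrom_a == chrom_b`) anchors with
#' `|idx_a - idx_b| <= tandem_window` are excluded, so tandem arrays do not
#' masquerade as collinear segments.
#'
#' @param anchors data.frame from [make_anchors()], all sharing one
#'   (`chrom_a`, `chrom_b`) combination.
#' @param params see [chain_params()].
#' @return list of chains; each chain is a list with `anchors` (the rows,
#'   in chain order), `orientation` (`"forward"`/`"reverse"`) and
#'   `total_score`.
#' @export
chain_anchors <- function(anchors, params = chain_params()) {
  stopifnot(nrow(unique(anchors[, c("chrom_a", "chrom_b")])) <= 1L)
  if (nrow(anchors) && anchors$chrom_a[1] == anchors$chrom_b[1])
    anchors <- anchors[abs(anchors$idx_a - anchors$idx_b) >
                         params$tandem_window, , drop = FALSE]
  chains <- list()
  remaining <- anchors
  while (nrow(remaining) > 0) {
    fwd <- best_chain_dp(remaining$idx_a, remaining$idx_b,
                         remaining$score, params)
    rev <- best_chain_dp(remaining$idx_a, -remaining$idx_b,
                         remaining$score, params)
    use_fwd <- fwd$score >= rev$score
    best <- if (use_fwd) fwd else rev
    if (!length(best$members)) break
    chain_rows <- remaining[best$members, , drop = FALSE]
    if (length(best$members) >= params$min_anchors)
      chains[[length(chains) + 1L]] <- list(
        anchors = chain_rows,
        orientation = if (use_fwd) "forward" else "reverse",
        total_score = best$score)
    remaining <- remaining[-best$members, , drop = FALSE]
  }
  # deterministic order: score desc, then length desc, then first idx_a
  if (length(chains) > 1L) {
    ord <- order(-vapply(chains, `[[`, numeric(1), "total_score"),
                 -vapply(chains, function(ch) nrow(ch$anchors), numeric(1)),
                 vapply(chains, function(ch) ch$anchors$idx_a[1], numeric(1)))
    chains <- chains[ord]
  }
  chains
}

# single highest-scoring chain by DP; y may be negated for reverse chains
best_chain_dp <- function(x, y, score, params) {
  n <- length(x)
  if (!n) return(list(members = integer(0), score = -Inf))
  ord <- order(x, y)
  x <- x[ord]; y <- y[ord]; s <- score[ord]
  best <- s
  prev <- rep(NA_integer_, n)
  for (j in seq_len(n)) {
    if (j == 1L) next
    i <- seq_len(j - 1L)
    da <- x[j] - x[i]
    db <- y[j] - y[i]
    okp <- da >= 1 & db >= 1 & da <= params$max_gap & db <= params$max_gap
    if (any(okp)) {
      cand <- best[i][okp] - params$gap_penalty * (da[okp] + db[okp] - 2)
      k <- which.max(cand)
      if (cand[k] > 0) {
        best[j] <- s[j] + cand[k]
        prev[j] <- i[okp][k]
      }
    }
  }
  end <- which.max(best)
  members <- integer(0)
  at <- end
  while (!is.na(at)) {
    members <- c(at, members)
    at <- prev[at]
  }
  list(members = ord[members], score = best[end])
}

#' Classify the duplication mechanism of candidate pairs
#'
#' A pair belonging to any collinear chain is WGD-derived; otherwise a
#' same-chromosome pair with at most `max_intervening` genes between the
#' copies is tandem-derived; everything else is undefined. Chain membership
#' is tested first, so a pair that is both chain member and within the
#' tandem window is WGD. Pairs with missing coordinates are labelled
#' undefined with a warning.
#'
#' @param pairs candidate pairs (`gene_a`, `gene_b`, `evalue`).
#' @param coords gene coordinates (`gene`, `chromosome`, `ordinal_index`).
#' @param max_intervening maximum intervening genes for a tandem call
#'   (default 10, inclusive).
#' @param params chaining parameters, see [chain_params()].
#' @return list with `labels` (data.frame `gene_a`, `gene_b`, `label`,
#'   `chain_id`) and `chains` (data.frame of chain anchors: `chain_id`,
#'   `chrom_a`, `chrom_b`, `orientation`, `idx_a`, `idx_b`, `gene_a`,
#'   `gene_b`, `total_score`).
#' @export
label_mechanisms <- function(pairs, coords, max_intervening = 10,
                             params = chain_params()) {
  anchors <- make_anchors(pairs, coords, params)
  missing <- attr(anchors, "missing")
  if (length(missing))
    warning(length(missing), " pairs lack coordinates; labelled undefined")
  groups <- split(seq_len(nrow(anchors)),
                  paste(anchors$chrom_a, anchors$chrom_b, sep = "\r"))
  # deterministic group order
  groups <- groups[order(names(groups))]
  chain_tab <- list()
  in_chain <- rep(NA_integer_, nrow(pairs))
  chain_id <- 0L
  for (g in groups) {
    chains <- chain_anchors(anchors[g, , drop = FALSE], params)
    for (ch in chains) {
      chain_id <- chain_id + 1L
      in_chain[ch$anchors$pair_id] <- chain_id
      chain_tab[[chain_id]] <- data.frame(
        chain_id = chain_id, chrom_a = ch$anchors$chrom_a,
        chrom_b = ch$anchors$chrom_b, orientation = ch$orientation,
        idx_a = ch$anchors$idx_a, idx_b = ch$anchors$idx_b,
        gene_a = pairs$gene_a[ch$anchors$pair_id],
        gene_b = pairs$gene_b[ch$anchors$pair_id],
        total_score = ch$total_score, stringsAsFactors = FALSE)
    }
  }
  idx <- setNames(coords$ordinal_index, coords$gene)
  chr <- setNames(as.character(coords$chromosome), coords$gene)
  label <- rep("undefined", nrow(pairs))
  same_chrom <- !is.na(chr[pairs$gene_a]) & !is.na(chr[pairs$gene_b]) &
    chr[pairs$gene_a] == chr[pairs$gene_b]
  intervening <- abs(idx[pairs$gene_a] - idx[pairs$gene_b]) - 1
  label[same_chrom & !is.na(intervening) & intervening <= max_intervening] <-
    "tandem"
  label[!is.na(in_chain)] <- "WGD"
  label[missing] <- "undefined"
  labels <- data.frame(gene_a = pairs$gene_a, gene_b = pairs$gene_b,
                       label = label, chain_id = in_chain,
                       stringsAsFactors = FALSE)
  chains <- if (length(chain_tab)) do.call(rbind, chain_tab) else
    data.frame(chain_id = integer(0), chrom_a = character(0),
               chrom_b = character(0), orientation = character(0),
               idx_a = integer(0), idx_b = integer(0),
               gene_a = character(0), gene_b = character(0),
               total_score = numeric(0), stringsAsFactors = FALSE)
  list(labels = labels, chains = chains)
}

#' @rdname label_mechanisms
#' @param chains chain table from a previous [label_mechanisms()] run (used
#'   by the lower-level interface; most callers want [label_mechanisms()]).
#' @export
classify_mechanism <- function(pairs, chains, coords, max_intervening = 10) {
  key <- paste(pairs$gene_a, pairs$gene_b, sep = "\r")
  ckey <- paste(chains$gene_a, chains$gene_b, sep = "\r")
  in_chain <- chains$chain_id[match(key, ckey)]
  idx <- setNames(coords$ordinal_index, coords$gene)
  chr <- setNames(as.character(coords$chromosome), coords$gene)
  missing <- is.na(chr[pairs$gene_a]) | is.na(chr[pairs$gene_b])
  if (any(missing))
    warning(sum(missing), " pairs lack coordinates; labelled undefined")
  label <- rep("undefined", nrow(pairs))
  same_chrom <- !missing & chr[pairs$gene_a] == chr[pairs$gene_b]
  intervening <- abs(idx[pairs$gene_a] - idx[pairs$gene_b]) - 1
  label[same_chrom & !is.na(intervening) & intervening <= max_intervening] <-
    "tandem"
  label[!is.na(in_chain)] <- "WGD"
  label[missing] <- "undefined"
  data.frame(gene_a = pairs$gene_a, gene_b = pairs$gene_b, label = label,
             chain_id = in_chain, stringsAsFactors = FALSE)
}
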