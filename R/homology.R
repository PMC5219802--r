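# Candidate paralog-pair universe: ingest or compute all-vs-all protein
# similarity hits, apply the five retention filters, drop self hits and
# enforce the same-family constraint.

HIT_COLUMNS <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                 "gapopen", "qstart", "qend", "sstart", "send",
                 "evalue", "bitscore")

#' Parse tabular similarity-search hits (12-column outfmt 6)
#'
#' @param path path to a tab-separated file with the standard 12 columns
#'   (qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#'   evalue bitscore), or a character vector of lines.
#' @return data.frame with the 12 standard columns, one row per hit.
#'   Malformed lines (wrong column count) raise an error naming the first
#'   offending line.
#' @export
parse_hits <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path)
           else as.character(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    out <- as.data.frame(setNames(
      lapply(HIT_COLUMNS, function(x) character(0)), HIT_COLUMNS))
    return(retype_hits(out))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != 12L)
  if (length(bad))
    stop("line ", bad[1L], ": expected 12 tab-separated columns, found ",
         nf[bad[1L]])
  out <- as.data.frame(do.call(rbind, fields), stringsAsFactors = FALSE)
  names(out) <- HIT_COLUMNS
  retype_hits(out)
}

retype_hits <- function(df) {
  num <- c("pident", "evalue", "bitscore")
  int <- c("length", "mismatch", "gapopen", "qstart", "qend", "sstart", "send")
  for (cl in num) df[[cl]] <- as.numeric(df[[cl]])
  for (cl in int) df[[cl]] <- as.integer(df[[cl]])
  df
}

#' Filter similarity hits with the five retention thresholds
#'
#' Defaults are e-value <= 1e-20, identity >= 50 percent, alignment
#' length > 300 bp, mismatches < 550 and gap opens < 30; self hits are
#' always removed. For protein-level hits (`units = "protein"`) the
#' reported alignment length is in aligned residues and is multiplied by 3
#' for the bp threshold; nucleotide-level hits (`units = "nucleotide"`)
#' are compared directly.
#'
#' @param hits data.frame from [parse_hits()] or [align_all_vs_all()].
#' @param max_evalue inclusive e-value ceiling.
#' @param min_identity inclusive minimum percent identity.
#' @param min_aln_bp exclusive minimum alignment length in bp.
#' @param max_mismatch exclusive maximum number of mismatches.
#' @param max_gapopen exclusive maximum number of gap opens.
#' @param units `"protein"` (default) or `"nucleotide"`.
#' @return the retained hits.
#' @export
filter_hits <- function(hits, max_evalue = 1e-20, min_identity = 50,
                        min_aln_bp = 300, max_mismatch = 550,
                        max_gapopen = 30,
                        units = c("protein", "nucleotide")) {
  units <- match.arg(units)
  aln_bp <- if (units == "protein") hits$length * 3L else hits$length
  keep <- hits$evalue <= max_evalue &
    hits$pident >= min_identity &
    aln_bp > min_aln_bp &
    hits$mismatch < max_mismatch &
    hits$gapopen < max_gapopen &
    hits$qseqid != hits$sseqid
  hits[keep, , drop = FALSE]
}

#' Build the unordered-unique candidate paralog pair set
#'
#' Keeps only pairs whose two genes share a gene family; genes without a
#' family assignment are dropped (count reported). When reciprocal hits
#' exist for a pair, the hit with the lower e-value is kept as the source
#' (ties: higher bitscore, then lexicographic query id).
#'
#' @param hits filtered hits (see [filter_hits()]).
#' @param families named character vector mapping gene id to family id, or
#'   a data.frame with columns `gene` and `family`.
#' @param quiet suppress the dropped-gene message.
#' @return data.frame with one row per unordered pair: `gene_a`, `gene_b`
#'   (lexicographically ordered), `family` and the source-hit columns
#'   `pident`, `length`, `mismatch`, `gapopen`, `evalue`, `bitscore`.
#' @export
build_candidate_pairs <- function(hits, families, quiet = FALSE) {
  fam <- as_family_map(families)
  fam_q <- fam[hits$qseqid]
  fam_s <- fam[hits$sseqid]
  no_family <- is.na(fam_q) | is.na(fam_s)
  if (!quiet && any(no_family))
    message("build_candidate_pairs: dropped ", sum(no_family),
            " hits with unassigned gene family")
  keep <- !no_family & fam_q == fam_s & hits$qseqid != hits$sseqid
  h <- hits[keep, , drop = FALSE]
  if (!nrow(h))
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      family = character(0), pident = numeric(0),
                      length = integer(0), mismatch = integer(0),
                      gapopen = integer(0), evalue = numeric(0),
                      bitscore = numeric(0), stringsAsFactors = FALSE))
  gene_a <- pmin(h$qseqid, h$sseqid)
  gene_b <- pmax(h$qseqid, h$sseqid)
  key <- paste(gene_a, gene_b, sep = "\r")
  ord <- order(key, h$evalue, -h$bitscore, h$qseqid)
  h <- h[ord, , drop = FALSE]
  gene_a <- gene_a[ord]; gene_b <- gene_b[ord]; key <- key[ord]
  first <- !duplicated(key)
  out <- data.frame(gene_a = gene_a[first], gene_b = gene_b[first],
                    family = unname(fam[gene_a[first]]),
                    pident = h$pident[first], length = h$length[first],
                    mismatch = h$mismatch[first], gapopen = h$gapopen[first],
                    evalue = h$evalue[first], bitscore = h$bitscore[first],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$gene_a, out$gene_b), , drop = FALSE]
}

as_family_map <- function(families) {
  if (is.data.frame(families)) {
    stopifnot(all(c("gene", "family") %in% names(families)))
    return(setNames(as.character(families$family),
                    as.character(families$gene)))
  }
  stopifnot(!is.null(names(families)))
  families
}

# Karlin-Altschul parameters for gapped BLOSUM62 (gap open 11, extend 1),
# as published for BLASTp.
KA_LAMBDA <- 0.267
KA_K <- 0.041

#' All-vs-all protein similarity with an internal aligner
#'
#' A built-in substitute for an external BLASTp run, so synthetic genomes
#' need no external binary: every pair of proteins is globally aligned
#' (BLOSUM62, affine gaps) and summarised into the standard 12 tabular-hit
#' columns. The e-value surrogate is computed from the raw score with the
#' Karlin-Altschul form (published gapped BLOSUM62 constants), using query
#' length times total database residues as the search space. Real BLAST
#' tabular output can be used instead via [parse_hits()].
#'
#' When `families` is supplied, only intra-family comparisons are aligned
#' (hits between families are discarded downstream anyway); this keeps
#' genome-scale runs tractable.
#'
#' @param proteins named character vector or `AAStringSet`.
#' @param families optional gene-to-family map (see
#'   [build_candidate_pairs()]); restricts comparisons to within-family.
#' @param gap_opening,gap_extension affine gap penalties.
#' @return data.frame of hits in the 12 standard columns (both hit
#'   orientations plus self hits, as BLAST would report).
#' @export
align_all_vs_all <- function(proteins, families = NULL,
                             gap_opening = 11, gap_extension = 1) {
  prot <- if (is(proteins, "AAStringSet")) {
    setNames(as.character(proteins), names(proteins))
  } else unlist(as.list(proteins))
  ids <- names(prot)
  if (!length(prot)) return(retype_hits(as.data.frame(
    setNames(lapply(HIT_COLUMNS, function(x) character(0)), HIT_COLUMNS))))
  stopifnot(!is.null(ids), !anyDuplicated(ids))
  db_residues <- sum(nchar(prot))

  if (is.null(families)) {
    cmb <- if (length(ids) >= 2) t(combn(ids, 2L)) else
      matrix(character(0), 0, 2)
  } else {
    fam <- as_family_map(families)
    cmb <- do.call(rbind, lapply(split(ids, fam[ids]), function(members) {
      if (length(members) < 2) return(NULL)
      t(combn(sort(members), 2L))
    }))
    if (is.null(cmb)) cmb <- matrix(character(0), 0, 2)
  }

  rows <- vector("list", nrow(cmb) + length(ids))
  if (nrow(cmb)) {
    pat <- Biostrings::AAStringSet(prot[cmb[, 1]])
    sub <- Biostrings::AAStringSet(prot[cmb[, 2]])
    aln <- Biostrings::pairwiseAlignment(
      pat, sub, substitutionMatrix = blosum62(), type = "global",
      gapOpening = gap_opening, gapExtension = gap_extension)
    ap <- as.character(Biostrings::alignedPattern(aln))
    as_ <- as.character(Biostrings::alignedSubject(aln))
    sc <- Biostrings::score(aln)
    for (i in seq_len(nrow(cmb))) {
      st <- alignment_stats(ap[i], as_[i])
      bit <- (KA_LAMBDA * sc[i] - log(KA_K)) / log(2)
      ev <- nchar(prot[cmb[i, 1]]) * db_residues * 2^(-bit)
      la <- nchar(prot[cmb[i, 1]]); lb <- nchar(prot[cmb[i, 2]])
      rows[[2L * i - 1L]] <- data.frame(
        qseqid = cmb[i, 1], sseqid = cmb[i, 2], pident = st$pident,
        length = st$length, mismatch = st$mismatch, gapopen = st$gapopen,
        qstart = 1L, qend = la, sstart = 1L, send = lb,
        evalue = ev, bitscore = round(bit, 1), stringsAsFactors = FALSE)
      rows[[2L * i]] <- data.frame(
        qseqid = cmb[i, 2], sseqid = cmb[i, 1], pident = st$pident,
        length = st$length, mismatch = st$mismatch, gapopen = st$gapopen,
        qstart = 1L, qend = lb, sstart = 1L, send = la,
        evalue = nchar(prot[cmb[i, 2]]) * db_residues * 2^(-bit),
        bitscore = round(bit, 1), stringsAsFactors = FALSE)
    }
  }
  # self hits, scored along the diagonal without alignment
  b62 <- blosum62()
  for (k in seq_along(ids)) {
    chars <- strsplit(prot[[k]], "")[[1]]
    chars[!chars %in% rownames(b62)] <- "X"
    sc <- sum(b62[cbind(chars, chars)])
    bit <- (KA_LAMBDA * sc - log(KA_K)) / log(2)
    n <- length(chars)
    rows[[2L * nrow(cmb) + k]] <- data.frame(
      qseqid = ids[k], sseqid = ids[k], pident = 100, length = n,
      mismatch = 0L, gapopen = 0L, qstart = 1L, qend = n, sstart = 1L,
      send = n, evalue = n * db_residues * 2^(-bit),
      bitscore = round(bit, 1), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# identity/mismatch/gap summaries of one aligned string pair
alignment_stats <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  gap_a <- ca == "-"; gap_b <- cb == "-"
  both <- !gap_a & !gap_b
  nident <- sum(both & ca == cb)
  runs <- function(g) sum(diff(c(FALSE, g)) == 1L)
  list(length = length(ca),
       pident = round(100 * nident / length(ca), 2),
       mismatch = sum(both & ca != cb),
       gapopen = runs(gap_a) + runs(gap_b))
}
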