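# Synthetic plant-like genomes with a known duplication history: one or
# more WGDs at chosen Ks depths with optionally GO-biased retention,
# ongoing tandem duplication, codon sequences diverged to target Ks, and
# ground-truth mechanism/age labels for every surviving duplicate pair.

#' Describe one whole-genome duplication event
#'
#' @param target_ks synonymous-divergence depth of the event (> 0).
#' @param retention_baseline probability that the duplicated copy of an
#'   unbiased gene is retained.
#' @param retention_biased retention probability for genes carrying
#'   `biased_go`.
#' @param biased_go GO id whose carriers are retained with
#'   `retention_biased` (NA for unbiased retention).
#' @return list describing the event, for [sim_config()].
#' @export
wgd_event <- function(target_ks, retention_baseline,
                      retention_biased = retention_baseline,
                      biased_go = NA_character_) {
  stopifnot(target_ks > 0,
            retention_baseline >= 0, retention_baseline <= 1,
            retention_biased >= 0, retention_biased <= 1)
  list(target_ks = target_ks, retention_baseline = retention_baseline,
       retention_biased = retention_biased, biased_go = biased_go)
}

default_go_terms <- function() {
  data.frame(
    term = c("GO:0003700", "GO:0016301", "GO:0003677", "GO:0005215",
             "GO:0006355", "GO:0008152", "GO:0005634"),
    fraction = c(0.10, 0.12, 0.15, 0.08, 0.10, 0.20, 0.15),
    stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Defaults describe a compact plant-like genome: 5 chromosomes, 2000
#' ancestral protein-coding genes of 150-400 codons, one WGD at Ks 1.0
#' with 30 percent unbiased retention, ongoing tandem duplication at 0.1
#' expected events per gene lineage with ages uniform on (0, 2], kappa 2,
#' and omega 0.1 (strong purifying selection typical of retained
#' duplicates, which also keeps even the oldest pairs above 50 percent
#' protein identity so the homology filters see them).
#'
#' @param n_chromosomes number of ancestral chromosomes.
#' @param n_ancestral_genes number of ancestral genes (split evenly across
#'   chromosomes).
#' @param codon_length_range integer pair: gene lengths in codons
#'   (minimum must be >= 100 so alignments can exceed the 300 bp filter).
#' @param wgd_events list of [wgd_event()]s; target Ks values must be
#'   distinct.
#' @param tandem_rate expected tandem duplications per gene lineage
#'   (Poisson).
#' @param tandem_ks_max tandem ages are uniform on (0, `tandem_ks_max`].
#' @param kappa transition/transversion rate ratio of the codon model.
#' @param omega dN/dS of the codon model.
#' @param go_terms data.frame with `term`, `fraction`: flat annotation
#'   probabilities for ancestral genes.
#' @param ks_jitter_sd lognormal sd of the per-pair WGD age jitter.
#' @param min_chain_len reference minimum chain length used by the
#'   config validity check.
#' @param seed integer seed; the whole simulation is deterministic given
#'   the config.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 5,
                       n_ancestral_genes = 2000,
                       codon_length_range = c(150, 400),
                       wgd_events = list(wgd_event(1.0, 0.3)),
                       tandem_rate = 0.1,
                       tandem_ks_max = 2,
                       kappa = 2,
                       omega = 0.1,
                       go_terms = default_go_terms(),
                       ks_jitter_sd = 0.1,
                       min_chain_len = 5,
                       seed = 1L) {
  stopifnot(n_chromosomes >= 1, n_ancestral_genes >= n_chromosomes,
            length(codon_length_range) == 2,
            codon_length_range[1] >= 100,
            codon_length_range[1] <= codon_length_range[2],
            tandem_rate >= 0, tandem_ks_max > 0, kappa > 0, omega > 0,
            all(go_terms$fraction >= 0 & go_terms$fraction <= 1))
  ks_depths <- vapply(wgd_events, `[[`, numeric(1), "target_ks")
  if (anyDuplicated(ks_depths))
    stop("WGD target_ks values must be distinct")
  for (ev in wgd_events) {
    expected_retained <- n_ancestral_genes * min(ev$retention_baseline,
                                                 ev$retention_biased)
    if (expected_retained < 2 * min_chain_len)
      stop("expected retained gene count (", expected_retained,
           ") below 2 x minimum chain length (", 2 * min_chain_len,
           "); chains would be undetectable")
  }
  structure(list(n_chromosomes = n_chromosomes,
                 n_ancestral_genes = n_ancestral_genes,
                 codon_length_range = as.integer(codon_length_range),
                 wgd_events = wgd_events[order(-ks_depths)],
                 tandem_rate = tandem_rate, tandem_ks_max = tandem_ks_max,
                 kappa = kappa, omega = omega, go_terms = go_terms,
                 ks_jitter_sd = ks_jitter_sd,
                 min_chain_len = min_chain_len, seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_ancestral_genes, "ancestral genes on",
      x$n_chromosomes, "chromosomes;", length(x$wgd_events),
      "WGD event(s) at Ks",
      paste(vapply(x$wgd_events, `[[`, numeric(1), "target_ks"),
            collapse = ", "),
      "; tandem rate", x$tandem_rate, "\n")
  invisible(x)
}

#' Simulate a genome with known duplication history
#'
#' Builds an ancestral multi-chromosome gene order with random codon
#' sequences, applies the configured WGD events oldest-first (each
#' duplicates every chromosome; the copy of each gene survives with the
#' baseline or GO-biased retention probability and keeps its ancestral
#' order on the duplicated chromosome, so collinear chains exist), then
#' applies tandem duplications (copies inserted 0-2 genes downstream of
#' their source). Sequences evolve along the resulting duplication
#' genealogy under a GY-style codon model; a per-gene divergence-depth
#' ledger makes each truth record's `true_ks` the realized expected
#' pairwise divergence on that genealogy (WGD ages get a lognormal jitter,
#' so Ks peaks have realistic width).
#'
#' @param config a [sim_config()].
#' @param sequences set `FALSE` to skip sequence evolution (coordinates,
#'   families, GO and truth only; much faster, used for calibration
#'   studies that do not need FASTA output).
#' @return list with `bundle` (class `genome_bundle`: `cds`, `proteins`
#'   (named character vectors), `coords`, `families`, `go` data.frames and
#'   the `config`) and `truth` (data.frame `gene_a`, `gene_b`,
#'   `true_mechanism`, `true_ks`, `wgd_index`).
#' @export
simulate_genome <- function(config, sequences = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nc <- config$n_chromosomes
  ng <- config$n_ancestral_genes

  gene_ids <- sprintf("G%05d", seq_len(ng))
  chrom_of <- sprintf("chr%d", rep(seq_len(nc), length.out = ng))
  chrom_order <- split(gene_ids, chrom_of)
  chrom_order <- chrom_order[order(as.integer(sub("chr", "", names(chrom_order))))]

  lens <- sample(seq(config$codon_length_range[1],
                     config$codon_length_range[2]), ng, replace = TRUE)
  uni <- codon_universe()
  atg <- match("ATG", uni$codons)
  seqs <- if (sequences) {
    setNames(lapply(lens, function(L)
      c(atg, sample.int(uni$n, L - 1L, replace = TRUE))), gene_ids)
  } else NULL

  # flat GO annotation of ancestral genes; duplicates inherit
  anno <- setNames(vector("list", ng), gene_ids)
  for (r in seq_len(nrow(config$go_terms))) {
    hit <- runif(ng) < config$go_terms$fraction[r]
    for (g in gene_ids[hit])
      anno[[g]] <- c(anno[[g]], config$go_terms$term[r])
  }

  family_of <- setNames(paste0("FAM", sprintf("%05d", seq_len(ng))), gene_ids)
  depth <- setNames(rep(0, ng), gene_ids)  # divergence depth from family root
  truth <- list()

  # WGD events, oldest first
  for (k in seq_along(config$wgd_events)) {
    ev <- config$wgd_events[[k]]
    for (chrom in names(chrom_order)) {
      members <- chrom_order[[chrom]]
      new_chrom <- paste0(chrom, "_w", k)
      retained <- character(0)
      for (g in members) {
        biased <- !is.na(ev$biased_go) && ev$biased_go %in% anno[[g]]
        p <- if (biased) ev$retention_biased else ev$retention_baseline
        if (runif(1) >= p) next
        copy <- paste0(g, ".w", k)
        total_ks <- ev$target_ks * rlnorm(1, 0, config$ks_jitter_sd)
        split_depth <- depth[[g]]
        if (sequences) {
          pair <- evolve_codon_pair(seqs[[g]], total_ks,
                                    kappa = config$kappa,
                                    omega = config$omega)
          seqs[[g]] <- pair$codons_a
          seqs[[copy]] <- pair$codons_b
        }
        depth[[g]] <- split_depth + total_ks / 2
        depth[[copy]] <- split_depth + total_ks / 2
        anno[[copy]] <- anno[[g]]
        family_of[[copy]] <- family_of[[g]]
        retained <- c(retained, copy)
        truth[[length(truth) + 1L]] <- list(
          gene_a = g, gene_b = copy, true_mechanism = "WGD",
          split_depth = split_depth, wgd_index = k)
      }
      if (length(retained)) chrom_order[[new_chrom]] <- retained
    }
  }

  # tandem duplications on all post-WGD gene lineages
  if (config$tandem_rate > 0) {
    for (chrom in names(chrom_order)) {
      members <- chrom_order[[chrom]]
      n_events <- rpois(length(members), config$tandem_rate)
      for (i in seq_along(members)) {
        g <- members[i]
        for (tcount in seq_len(n_events[i])) {
          copy <- paste0(g, ".t", tcount)
          age <- runif(1, 0, config$tandem_ks_max)
          split_depth <- depth[[g]]
          if (sequences) {
            pair <- evolve_codon_pair(seqs[[g]], age,
                                      kappa = config$kappa,
                                      omega = config$omega)
            seqs[[g]] <- pair$codons_a
            seqs[[copy]] <- pair$codons_b
          }
          depth[[g]] <- split_depth + age / 2
          depth[[copy]] <- split_depth + age / 2
          anno[[copy]] <- anno[[g]]
          family_of[[copy]] <- family_of[[g]]
          truth[[length(truth) + 1L]] <- list(
            gene_a = g, gene_b = copy, true_mechanism = "tandem",
            split_depth = split_depth, wgd_index = NA_integer_)
          # insert 0-2 genes downstream of the source
          cur <- chrom_order[[chrom]]
          at <- match(g, cur)
          offset <- sample(0:2, 1)
          at_ins <- min(at + offset, length(cur))
          chrom_order[[chrom]] <- append(cur, copy, after = at_ins)
        }
      }
    }
  }

  # realized pairwise divergence from the depth ledger
  truth_df <- do.call(rbind, lapply(truth, function(tr) {
    data.frame(gene_a = tr$gene_a, gene_b = tr$gene_b,
               true_mechanism = tr$true_mechanism,
               true_ks = depth[[tr$gene_a]] + depth[[tr$gene_b]] -
                 2 * tr$split_depth,
               wgd_index = tr$wgd_index, stringsAsFactors = FALSE)
  }))
  if (is.null(truth_df))
    truth_df <- data.frame(gene_a = character(0), gene_b = character(0),
                           true_mechanism = character(0),
                           true_ks = numeric(0), wgd_index = integer(0),
                           stringsAsFactors = FALSE)

  all_genes <- unlist(chrom_order, use.names = FALSE)
  coords <- do.call(rbind, lapply(names(chrom_order), function(chrom) {
    members <- chrom_order[[chrom]]
    data.frame(gene = members, chromosome = chrom,
               ordinal_index = seq_along(members),
               start_bp = (seq_along(members) - 1L) * 3000L + 1L,
               strand = sample(c("+", "-"), length(members), replace = TRUE),
               stringsAsFactors = FALSE)
  }))
  rownames(coords) <- NULL

  go <- do.call(rbind, lapply(all_genes, function(g) {
    terms <- anno[[g]]
    if (is.null(terms)) return(NULL)
    data.frame(gene = g, term = terms, stringsAsFactors = FALSE)
  }))
  if (is.null(go))
    go <- data.frame(gene = character(0), term = character(0),
                     stringsAsFactors = FALSE)

  bundle <- structure(list(
    cds = if (sequences)
      setNames(vapply(all_genes, function(g) codons_to_cds(seqs[[g]]),
                      character(1)), all_genes) else NULL,
    proteins = if (sequences)
      setNames(vapply(all_genes, function(g)
        paste(uni$aa[seqs[[g]]], collapse = ""), character(1)),
        all_genes) else NULL,
    coords = coords,
    families = data.frame(gene = all_genes,
                          family = unname(family_of[all_genes]),
                          stringsAsFactors = FALSE),
    go = go,
    config = config), class = "genome_bundle")
  list(bundle = bundle, truth = truth_df)
}

#' @export
print.genome_bundle <- function(x, ...) {
  cat("genome_bundle:", nrow(x$coords), "genes on",
      length(unique(x$coords$chromosome)), "chromosomes",
      if (is.null(x$cds)) "(no sequences)" else "", "\n")
  invisible(x)
}

#' Write a genome bundle to disk in standard formats
#'
#' Emits `cds.fna`, `proteins.faa` (FASTA), `genes.gff3` and `genes.tsv`
#' (coordinates), `families.tsv`, `go.tsv`, and (when supplied) the truth
#' table `truth.tsv`.
#'
#' @param bundle a `genome_bundle` from [simulate_genome()].
#' @param dir output directory (created if needed).
#' @param truth optional truth data.frame to write alongside.
#' @return `dir`, invisibly.
#' @export
write_genome_bundle <- function(bundle, dir, truth = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(bundle$cds)) {
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(bundle$cds), file.path(dir, "cds.fna"))
    Biostrings::writeXStringSet(
      Biostrings::AAStringSet(bundle$proteins),
      file.path(dir, "proteins.faa"))
  }
  write_tsv(bundle$coords, file.path(dir, "genes.tsv"))
  write_gff3(bundle, file.path(dir, "genes.gff3"))
  write_tsv(bundle$families, file.path(dir, "families.tsv"))
  write_tsv(bundle$go, file.path(dir, "go.tsv"))
  if (!is.null(truth)) write_tsv(truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}

write_gff3 <- function(bundle, path) {
  co <- bundle$coords
  gene_len <- if (!is.null(bundle$cds))
    nchar(bundle$cds[co$gene]) else rep(999L, nrow(co))
  lines <- c("##gff-version 3",
             paste(co$chromosome, "paleodup", "gene", co$start_bp,
                   co$start_bp + gene_len - 1L, ".", co$strand, ".",
                   paste0("ID=", co$gene), sep = "\t"))
  writeLines(lines, path)
}
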