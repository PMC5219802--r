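# End-to-end orchestration: homology -> mechanism -> divergence ->
# pairing -> age statistics -> enrichment, with plain-file handoffs
# between stages, a per-genome summary, and a run manifest.

#' Default pipeline thresholds
#'
#' All stage thresholds with their standard defaults: e-value <= 1e-20,
#' identity >= 50, alignment length > 300 bp, mismatches < 550, gap
#' opens < 30, at most 10 intervening genes for tandem calls, Ks <= 2,
#' SE < 0.5, minimum GO set size 10, SiZer bandwidths in [0.05, 5].
#'
#' @return named list of parameters for [run_pipeline()].
#' @export
pipeline_params <- function() {
  list(max_evalue = 1e-20, min_identity = 50, min_aln_bp = 300,
       max_mismatch = 550, max_gapopen = 30, units = "protein",
       max_intervening = 10, max_ks = 2, max_se = 0.5,
       ks_method = "YN00", min_set = 10, h_range = c(0.05, 5),
       bin_width = 0.05, n_boot = 200)
}

#' Core paralog analysis on in-memory inputs
#'
#' Runs homology (internal aligner or precomputed hits), mechanism
#' labelling, Ks estimation with the retention filters, and
#' representative-pair selection. [run_pipeline()] wraps this with file
#' input/output; tests and interactive use can call it directly.
#'
#' @param proteins named character vector of protein sequences.
#' @param cds named character vector of coding sequences.
#' @param coords gene coordinate data.frame (see [read_gene_coords()]).
#' @param families gene-to-family map (named vector or data.frame).
#' @param hits optional precomputed tabular hits (data.frame from
#'   [parse_hits()]); when NULL the internal aligner is used.
#' @param params threshold list, see [pipeline_params()].
#' @return list with `hits`, `pairs`, `labels`, `chains`, `ks`,
#'   `ks_filtered`, `rep_pairs`.
#' @export
paralog_pipeline_core <- function(proteins, cds, coords, families,
                                  hits = NULL, params = pipeline_params()) {
  if (is.null(hits))
    hits <- align_all_vs_all(proteins, families = families)
  filtered <- filter_hits(hits, max_evalue = params$max_evalue,
                          min_identity = params$min_identity,
                          min_aln_bp = params$min_aln_bp,
                          max_mismatch = params$max_mismatch,
                          max_gapopen = params$max_gapopen,
                          units = params$units)
  pairs <- build_candidate_pairs(filtered, families, quiet = TRUE)
  mech <- label_mechanisms(pairs, coords,
                           max_intervening = params$max_intervening)
  ks <- ks_for_pairs(cds, pairs, method = params$ks_method)
  ks$label <- mech$labels$label
  ks$chain_id <- mech$labels$chain_id
  ks_filtered <- filter_estimates(ks, max_ks = params$max_ks,
                                  max_se = params$max_se, quiet = TRUE)
  rep_pairs <- select_pairs(ks_filtered)
  list(hits = filtered, pairs = pairs, labels = mech$labels,
       chains = mech$chains, ks = ks, ks_filtered = ks_filtered,
       rep_pairs = rep_pairs)
}

#' Per-genome summary in the style of a genome-survey table row
#'
#' @param core result of [paralog_pipeline_core()].
#' @param n_genes initial protein-coding gene count.
#' @return list: `initial_genes`, `duplicate_pairs`, `mechanism` (counts
#'   by WGD/tandem/undefined over all candidate pairs), `ks_ranges`
#'   (counts of pre-filter estimates by (0,0.5], (0.5,1], (1,1.5],
#'   (1.5,2], >2) and `failed_estimates`.
#' @export
genome_summary <- function(core, n_genes) {
  mech <- table(factor(core$labels$label,
                       levels = c("WGD", "tandem", "undefined")))
  est <- core$ks$ks[!core$ks$saturated & !is.na(core$ks$ks)]
  ranges <- c("(0,0.5]" = sum(est > 0 & est <= 0.5),
              "(0.5,1]" = sum(est > 0.5 & est <= 1),
              "(1,1.5]" = sum(est > 1 & est <= 1.5),
              "(1.5,2]" = sum(est > 1.5 & est <= 2),
              ">2" = sum(est > 2))
  list(initial_genes = n_genes,
       duplicate_pairs = nrow(core$pairs),
       mechanism = as.list(mech),
       ks_ranges = as.list(ranges),
       failed_estimates = sum(core$ks$saturated | is.na(core$ks$ks)))
}

#' Run the full pipeline from files
#'
#' Stages execute in order homology, mechanism, divergence, pairing, age
#' statistics, enrichment; every stage writes its output as a plain file
#' under `out_dir`, enabling inspection and restart (`resume = TRUE`
#' reuses stage outputs already on disk). A manifest recording the
#' configuration is written alongside.
#'
#' @param config named list (or path to a YAML/JSON file) with input
#'   paths `proteins`, `cds`, `coords`, `families`, `go`, optional `obo`
#'   and `hits`, an output directory `out_dir`, optional `seed` (default
#'   1), `resume` (default FALSE) and any of the thresholds of
#'   [pipeline_params()].
#' @return the [genome_summary()] list (also written as `summary.json`),
#'   invisibly with attribute `"out_dir"`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  params <- utils::modifyList(pipeline_params(),
                              config[intersect(names(config),
                                               names(pipeline_params()))])
  out_dir <- config$out_dir
  stopifnot(!is.null(out_dir))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  resume <- isTRUE(config$resume)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  set.seed(seed)

  need <- function(what) {
    path <- config[[what]]
    if (is.null(path)) stop("stage ", what, ": missing input path '",
                            what, "' in config")
    if (!file.exists(path)) stop("stage ", what, ": input file not found: ",
                                 path)
    path
  }
  stage_file <- function(name) file.path(out_dir, name)
  run_stage <- function(name, reader, compute, writer) {
    path <- stage_file(name)
    if (resume && file.exists(path)) return(reader(path))
    res <- tryCatch(compute(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    writer(res, path)
    res
  }

  proteins <- read_fasta(need("proteins"), "protein")
  cds <- read_fasta(need("cds"), "dna")
  coords <- read_gene_coords(need("coords"))
  families <- read_family_tsv(need("families"))

  hits <- run_stage("hits.tsv", parse_hits_file, function() {
    if (!is.null(config$hits)) parse_hits(config$hits)
    else align_all_vs_all(proteins, families = families)
  }, function(res, path) write_hits(res, path))

  filtered <- filter_hits(hits, max_evalue = params$max_evalue,
                          min_identity = params$min_identity,
                          min_aln_bp = params$min_aln_bp,
                          max_mismatch = params$max_mismatch,
                          max_gapopen = params$max_gapopen,
                          units = params$units)
  pairs <- run_stage("pairs.tsv", read_tsv,
                     function() build_candidate_pairs(filtered, families),
                     write_tsv)

  mech <- NULL
  labels <- run_stage("labels.tsv", read_tsv, function() {
    mech <<- label_mechanisms(pairs, coords,
                              max_intervening = params$max_intervening)
    mech$labels
  }, write_tsv)
  if (!is.null(mech)) write_tsv(mech$chains, stage_file("chains.tsv"))

  ks <- run_stage("ks.tsv", read_tsv, function() {
    est <- ks_for_pairs(cds, pairs, method = params$ks_method)
    est$label <- labels$label
    est$chain_id <- labels$chain_id
    est
  }, write_tsv)

  ks_filtered <- run_stage("ks_filtered.tsv", read_tsv, function()
    filter_estimates(ks, max_ks = params$max_ks, max_se = params$max_se,
                     quiet = TRUE), write_tsv)

  rep_pairs <- run_stage("rep_pairs.tsv", read_tsv,
                         function() select_pairs(ks_filtered), write_tsv)

  # age statistics on the filtered Ks values; Ks = 0 pairs carry no age
  # information and fall outside the (0, max_ks] domain
  positive <- ks_filtered[ks_filtered$ks > 0, , drop = FALSE]
  subsets <- list(all = positive$ks,
                  wgd = positive$ks[positive$label == "WGD"],
                  tandem = positive$ks[positive$label == "tandem"])
  for (tag in names(subsets)) {
    vals <- subsets[[tag]]
    if (length(vals)) {
      hist <- build_histogram(vals, bin_width = params$bin_width,
                              subset = tag, max_ks = params$max_ks)
      write_tsv(data.frame(bin_lo = hist$bin_edges[-length(hist$bin_edges)],
                           bin_hi = hist$bin_edges[-1],
                           count = hist$counts),
                stage_file(paste0("histogram_", tag, ".tsv")))
    }
    if (length(vals) >= 50) {
      map <- sizer_map(vals, h_range = params$h_range,
                       bin_width = params$bin_width, max_ks = params$max_ks)
      write_tsv(sizer_as_table(map),
                stage_file(paste0("sizer_", tag, ".tsv")))
    }
  }
  if (length(subsets$all) >= 30) {
    gof <- ks_gof_test(subsets$all, n_boot = params$n_boot,
                       max_ks = params$max_ks)
    jsonlite::write_json(list(D = gof$D, p_value = gof$p_value,
                              rate = gof$rate, n = gof$n),
                         stage_file("gof.json"), auto_unbox = TRUE,
                         digits = NA)
  }

  # enrichment
  if (!is.null(config$go) && nrow(rep_pairs)) {
    anno <- read_go_tsv(need("go"))
    exclude <- character(0)
    if (!is.null(config$obo)) {
      onto <- read_obo(need("obo"))
      anno <- propagate_annotations(anno, onto)
      exclude <- onto$roots
    }
    groups <- build_groups(rep_pairs)
    background <- if (identical(config$background, "genome"))
      unique(coords$gene) else NULL
    enr <- ora_all_groups(groups, background = background,
                          annotations = anno, min_set = params$min_set,
                          exclude_terms = exclude)
    write_tsv(enr, stage_file("enrichment.tsv"))
    if (nrow(enr))
      write_tsv(enrichment_heatmap_table(enr), stage_file("heatmap.tsv"))
  }

  core <- list(hits = filtered, pairs = pairs, labels = labels,
               chains = if (is.null(mech)) NULL else mech$chains,
               ks = ks, ks_filtered = ks_filtered, rep_pairs = rep_pairs)
  summary <- genome_summary(core, n_genes = length(proteins))
  jsonlite::write_json(summary, stage_file("summary.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- c(config[setdiff(names(config), names(pipeline_params()))],
                params, list(seed = seed))
  jsonlite::write_json(manifest, stage_file("manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  attr(summary, "out_dir") <- out_dir
  invisible(summary)
}

read_run_config <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
}

parse_hits_file <- function(path) {
  df <- read_tsv(path)
  names(df) <- HIT_COLUMNS
  df
}

write_hits <- function(hits, path) {
  write_tsv(hits, path)
}
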