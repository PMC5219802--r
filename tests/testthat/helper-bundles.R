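# Lazily built, cached synthetic bundles shared across test files.
# The "acceptance" bundle is the stated world of the recovery checks:
# 5 chromosomes, 2000 ancestral genes, one WGD at Ks 1.0 with 30%
# retention, tandem rate 0.1.

.bundle_cache <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (is.null(.bundle_cache[[key]])) .bundle_cache[[key]] <- build()
  .bundle_cache[[key]]
}

small_bundle <- function() {
  cached("small", function() {
    cfg <- sim_config(n_chromosomes = 2, n_ancestral_genes = 200, seed = 5)
    simulate_genome(cfg)
  })
}

small_core <- function() {
  cached("small_core", function() {
    b <- small_bundle()$bundle
    paralog_pipeline_core(b$proteins, b$cds, b$coords, b$families)
  })
}

acceptance_bundle <- function() {
  cached("acceptance", function() {
    cfg <- sim_config(n_chromosomes = 5, n_ancestral_genes = 2000,
                      wgd_events = list(wgd_event(1.0, 0.3)),
                      tandem_rate = 0.1, seed = 20160301)
    simulate_genome(cfg)
  })
}

acceptance_core <- function() {
  cached("acceptance_core", function() {
    b <- acceptance_bundle()$bundle
    paralog_pipeline_core(b$proteins, b$cds, b$coords, b$families)
  })
}

biased_bundle <- function() {
  cached("biased", function() {
    cfg <- sim_config(n_chromosomes = 5, n_ancestral_genes = 2000,
                      wgd_events = list(wgd_event(1.0, 0.3, 0.9,
                                                  "GO:0003700")),
                      tandem_rate = 0.1, seed = 20160302)
    simulate_genome(cfg)
  })
}

mini_obo_path <- function() {
  system.file("extdata", "mini_go.obo", package = "paleodup")
}
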