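test_that("evolve_codon_pair honours target_Ks = 0 and never emits stops", {
  anc <- strrep("ATGGCTCGT", 50)
  pair <- evolve_codon_pair(anc, target_ks = 0)
  expect_identical(pair$cds_a, toupper(anc))
  expect_identical(pair$cds_b, toupper(anc))

  set.seed(11)
  pair <- evolve_codon_pair(anc, target_ks = 1.2, kappa = 2, omega = 0.2)
  for (cds in c(pair$cds_a, pair$cds_b)) {
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
    expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1)))
    expect_identical(nchar(cds) %% 3L, 0L)
  }
  expect_error(evolve_codon_pair("ATGGC", 0.5), "divisible by 3")
})

test_that("NG86 counting recovers the simulated synonymous divergence", {
  set.seed(23)
  anc <- sample.int(61, 10000, replace = TRUE)
  pair <- evolve_codon_pair(anc, target_ks = 0.5, kappa = 1, omega = 0.2)
  est <- estimate_ks(list(codons_a = pair$codons_a,
                          codons_b = pair$codons_b), method = "NG86")
  expect_lt(abs(est$ks / 0.5 - 1), 0.10)
})

test_that("simulation is byte-identical under a fixed seed", {
  cfg <- sim_config(n_chromosomes = 2, n_ancestral_genes = 60,
                    codon_length_range = c(100, 150), seed = 99,
                    tandem_rate = 0.2)
  sim1 <- simulate_genome(cfg)
  sim2 <- simulate_genome(cfg)
  expect_identical(sim1, sim2)

  d1 <- file.path(tempdir(), "sim1"); d2 <- file.path(tempdir(), "sim2")
  write_genome_bundle(sim1$bundle, d1, truth = sim1$truth)
  write_genome_bundle(sim2$bundle, d2, truth = sim2$truth)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
})

test_that("a single jitter-free WGD yields only WGD truth at one depth", {
  cfg <- sim_config(n_chromosomes = 2, n_ancestral_genes = 80,
                    codon_length_range = c(100, 120),
                    wgd_events = list(wgd_event(0.8, 0.5)),
                    tandem_rate = 0, ks_jitter_sd = 0, seed = 3)
  sim <- simulate_genome(cfg)
  expect_true(all(sim$truth$true_mechanism == "WGD"))
  expect_true(all(abs(sim$truth$true_ks - 0.8) < 1e-12))
})

test_that("gene order is a gapless permutation and WGD copies stay collinear", {
  sim <- small_bundle()
  co <- sim$bundle$coords
  for (chrom in unique(co$chromosome)) {
    idx <- sort(co$ordinal_index[co$chromosome == chrom])
    expect_identical(idx, seq_along(idx))
  }
  # copies on each duplicated chromosome preserve the ancestral order
  wgd <- sim$truth[sim$truth$true_mechanism == "WGD", ]
  pos <- setNames(co$ordinal_index, co$gene)
  chrom_of <- setNames(co$chromosome, co$gene)
  for (chrom in grep("_w", unique(co$chromosome), value = TRUE)) {
    members <- wgd[chrom_of[wgd$gene_b] == chrom, ]
    ord <- order(pos[members$gene_b])
    expect_identical(order(pos[members$gene_a][ord]),
                     seq_len(nrow(members)))
  }
  # duplicates share the ancestral family
  fam <- setNames(sim$bundle$families$family, sim$bundle$families$gene)
  expect_true(all(fam[sim$truth$gene_a] == fam[sim$truth$gene_b]))
})

test_that("unbiased retention leaves the biased term at background frequency", {
  cfg <- sim_config(n_chromosomes = 2, n_ancestral_genes = 600,
                    codon_length_range = c(100, 120),
                    wgd_events = list(wgd_event(1.0, 0.4, 0.4,
                                                "GO:0003700")),
                    tandem_rate = 0, seed = 17)
  sim <- simulate_genome(cfg, sequences = FALSE)
  go <- sim$bundle$go
  carriers <- unique(go$gene[go$term == "GO:0003700"])
  ancestral <- sprintf("G%05d", seq_len(600))
  p0 <- mean(ancestral %in% carriers)
  retained <- sim$truth$gene_b
  p_ret <- mean(retained %in% carriers)
  n <- length(retained)
  expect_lt(abs(p_ret - p0), 3 * sqrt(p0 * (1 - p0) / n))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_ancestral_genes = 20,
                          wgd_events = list(wgd_event(1, 0.3))),
               "chains would be undetectable")
  expect_error(sim_config(codon_length_range = c(50, 80)))
  expect_error(sim_config(wgd_events = list(wgd_event(1, 0.5),
                                            wgd_event(1, 0.5))),
               "distinct")
})
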