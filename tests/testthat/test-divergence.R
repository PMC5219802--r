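random_cds <- function(n_codons, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  codons_to_cds(sample.int(61, n_codons, replace = TRUE))
}

test_that("codon_align keeps all columns for identical or cleanly deleted CDS", {
  cds <- random_cds(100, seed = 1)
  aln <- codon_align(cds, cds)
  expect_identical(aln$n_codons_used, 100L)
  expect_identical(aln$codons_a, aln$codons_b)

  # clean 5-codon internal deletion
  codons <- cds_to_codons(cds)
  short <- codons_to_cds(codons[-(40:44)])
  aln2 <- codon_align(cds, short)
  expect_identical(aln2$n_codons_used, 95L)
})

test_that("codon_align reproduces a hand-constructed alignment", {
  # 12 codons; partner lacks codons 5-7 and differs at codons 2 and 10.
  # The hand alignment pairs columns 1:4 -> 1:4 and 8:12 -> 5:9.
  uni <- codon_universe()
  a_cod <- cds_to_codons(paste0("ATG", "AAA", "TGG", "GAA", "CCC", "GGG",
                                "TTT", "CAT", "ATC", "GAG", "AAG", "TAC"))
  b_cod <- a_cod[-(5:7)]
  b_cod[2] <- match("CGT", uni$codons)   # K -> R
  b_cod[7] <- match("GAT", uni$codons)   # position 10 in a: E -> D
  aln <- codon_align(codons_to_cds(a_cod), codons_to_cds(b_cod))
  expect_identical(aln$codons_a, a_cod[c(1:4, 8:12)])
  expect_identical(aln$codons_b, b_cod)
})

test_that("internal stops are rejected with sequence and codon index", {
  good <- random_cds(50, seed = 2)
  bad <- paste0(substr(good, 1, 30), "TAA", substr(good, 34, nchar(good)))
  expect_error(codon_align(bad, good, ids = c("mut", "wt")),
               "mut.*codon 11")
})

test_that("identical rows give Ks = Ka = 0 and estimates are symmetric", {
  cds <- random_cds(200, seed = 3)
  aln <- codon_align(cds, cds)
  est <- estimate_ks(aln)
  expect_identical(c(est$ks, est$ka, est$se), c(0, 0, 0))

  set.seed(4)
  pair <- evolve_codon_pair(random_cds(500, seed = 5), 0.6)
  for (method in c("YN00", "NG86")) {
    ab <- estimate_ks(list(codons_a = pair$codons_a,
                           codons_b = pair$codons_b), method = method)
    ba <- estimate_ks(list(codons_a = pair$codons_b,
                           codons_b = pair$codons_a), method = method)
    expect_equal(ab$ks, ba$ks, tolerance = 1e-12)
    expect_equal(ab$ka, ba$ka, tolerance = 1e-12)
  }
})

test_that("NG86 equals the hand site-counting oracle on fourfold transversions", {
  uni <- codon_universe()
  # 300 codons from fourfold families (third position freely exchangeable)
  set.seed(6)
  fourfold <- c("GCT", "GGT", "CCT", "ACT", "GTT", "CGT", "CTT", "TCT")
  a_str <- sample(fourfold, 300, replace = TRUE)
  b_str <- a_str
  # 10 third-position transversions (T -> G), all synonymous
  at <- sample(300, 10)
  substr(b_str[at], 3, 3) <- "G"
  ca <- match(a_str, uni$codons)
  cb <- match(b_str, uni$codons)
  est <- estimate_ks(list(codons_a = ca, codons_b = cb), method = "NG86")
  expect_equal(est$ks, oracle_ng86_fourfold(a_str, b_str, 10),
               tolerance = 1e-9)
  expect_identical(est$ka, 0)
})

test_that("NG86 and YN00 agree within 15 percent when kappa = omega = 1", {
  set.seed(8)
  anc <- sample.int(61, 4000, replace = TRUE)
  for (ks in c(0.3, 0.8)) {
    pair <- evolve_codon_pair(anc, target_ks = ks, kappa = 1, omega = 1)
    aln <- list(codons_a = pair$codons_a, codons_b = pair$codons_b)
    yn <- estimate_ks(aln, method = "YN00")
    ng <- estimate_ks(aln, method = "NG86")
    expect_lt(abs(yn$ks / ng$ks - 1), 0.15)
  }
})

test_that("the Ks and SE retention filters use the printed inclusivity", {
  est <- data.frame(ks = c(2.0, 1.0, 2.3, 0.5), ka = 0.1,
                    se = c(0.1, 0.5, 0.1, 0.49),
                    saturated = c(FALSE, FALSE, FALSE, FALSE))
  kept <- filter_estimates(est, quiet = TRUE)
  expect_identical(kept$ks, c(2.0, 0.5))  # Ks <= 2 inclusive, SE < 0.5 strict
  expect_identical(unname(attr(kept, "excluded")["ks_above_max"]), 1L)

  est$saturated[4] <- TRUE
  kept2 <- filter_estimates(est, quiet = TRUE)
  expect_identical(kept2$ks, 2.0)
})

test_that("estimates require a minimum number of codon columns", {
  cds <- random_cds(20, seed = 10)
  aln <- codon_align(cds, cds)
  expect_error(estimate_ks(aln), "need >= 30")
})
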