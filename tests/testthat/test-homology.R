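hit_line <- function(q = "g1", s = "g2", pident = 98.5, len = 200,
                     mm = 3, go = 0, ev = 1e-50, bit = 400) {
  paste(q, s, pident, len, mm, go, 1, len, 1, len,
        format(ev, scientific = TRUE), bit, sep = "\t")
}

make_hit <- function(...) parse_hits(hit_line(...))

test_that("parse_hits reads 12-column records and reports malformed lines", {
  h <- parse_hits(hit_line(pident = "98.50"))
  expect_equal(h$pident, 98.5)
  expect_identical(h$length, 200L)
  expect_identical(nrow(parse_hits(character(0))), 0L)
  bad <- c(hit_line(), paste(rep("x", 11), collapse = "\t"))
  expect_error(parse_hits(bad), "line 2")
})

test_that("filter thresholds pin the printed boundary semantics", {
  expect_identical(nrow(filter_hits(make_hit(pident = 49.9))), 0L)
  expect_identical(nrow(filter_hits(make_hit(pident = 50))), 1L)
  # 100 aligned residues = 300 bp is not > 300
  expect_identical(nrow(filter_hits(make_hit(len = 100))), 0L)
  expect_identical(nrow(filter_hits(make_hit(len = 101))), 1L)
  expect_identical(nrow(filter_hits(make_hit(mm = 550))), 0L)
  expect_identical(nrow(filter_hits(make_hit(mm = 549))), 1L)
  expect_identical(nrow(filter_hits(make_hit(go = 30))), 0L)
  expect_identical(nrow(filter_hits(make_hit(go = 29))), 1L)
  expect_identical(nrow(filter_hits(make_hit(ev = 1e-20))), 1L)  # inclusive
  expect_identical(nrow(filter_hits(make_hit(ev = 2e-20))), 0L)
  expect_identical(nrow(filter_hits(make_hit(q = "g1", s = "g1"))), 0L)
  # nucleotide-level hits compare alignment length directly
  expect_identical(nrow(filter_hits(make_hit(len = 301),
                                    units = "nucleotide")), 1L)
  expect_identical(nrow(filter_hits(make_hit(len = 301))), 1L)
})

test_that("filtering is idempotent and order-independent", {
  set.seed(1)
  hits <- do.call(rbind, lapply(1:40, function(i)
    make_hit(q = sample(letters, 1), s = sample(letters, 1),
             pident = runif(1, 30, 100), len = sample(50:400, 1),
             ev = 10^-runif(1, 5, 60))))
  once <- filter_hits(hits)
  expect_identical(filter_hits(once), once)
  shuffled <- hits[sample(nrow(hits)), ]
  reord <- filter_hits(shuffled)
  expect_identical(reord[order(reord$qseqid, reord$sseqid, reord$evalue), ],
                   once[order(once$qseqid, once$sseqid, once$evalue), ],
                   ignore_attr = TRUE)
})

test_that("candidate pairs honour the same-family constraint", {
  fams <- c(g1 = "F1", g2 = "F2", g3 = "F1")
  hits <- rbind(make_hit("g1", "g2"), make_hit("g1", "g3"))
  pairs <- build_candidate_pairs(hits, fams, quiet = TRUE)
  expect_identical(nrow(pairs), 1L)
  expect_identical(pairs$gene_a, "g1")
  expect_identical(pairs$gene_b, "g3")
  expect_identical(pairs$family, "F1")
})

test_that("reciprocal hits resolve deterministically to the lower e-value", {
  fams <- c(a = "F", b = "F")
  hits <- rbind(make_hit("a", "b", ev = 1e-30, bit = 100),
                make_hit("b", "a", ev = 1e-50, bit = 200))
  pairs <- build_candidate_pairs(hits, fams, quiet = TRUE)
  expect_identical(nrow(pairs), 1L)
  expect_equal(pairs$evalue, 1e-50)
  # permutation invariance of the pair set and chosen source hits
  pairs2 <- build_candidate_pairs(hits[2:1, ], fams, quiet = TRUE)
  expect_identical(pairs, pairs2)
})

test_that("an all-vs-all family yields n(n-1)/2 pairs", {
  n <- 6L
  genes <- paste0("g", seq_len(n))
  fams <- setNames(rep("F", n), genes)
  grid <- expand.grid(q = genes, s = genes, stringsAsFactors = FALSE)
  grid <- grid[grid$q != grid$s, ]
  hits <- do.call(rbind, Map(function(q, s) make_hit(q, s), grid$q, grid$s))
  pairs <- build_candidate_pairs(hits, fams, quiet = TRUE)
  expect_identical(nrow(pairs), (n * (n - 1L)) %/% 2L)
  expect_false(anyDuplicated(pair_key(pairs$gene_a, pairs$gene_b)) > 0)
})

test_that("the internal aligner matches a quadratic-time reference", {
  set.seed(42)
  aas <- c("A","R","N","D","C","Q","E","G","H","I",
           "L","K","M","F","P","S","T","W","Y","V")
  base <- paste(sample(aas, 130, replace = TRUE), collapse = "")
  mutate <- function(s, n_sub, del_at = NULL, del_len = 0) {
    v <- strsplit(s, "")[[1]]
    at <- sample(seq_along(v), n_sub)
    v[at] <- sample(aas, n_sub, replace = TRUE)
    if (!is.null(del_at)) v <- v[-(del_at:(del_at + del_len - 1))]
    paste(v, collapse = "")
  }
  prot <- c(p1 = base, p2 = mutate(base, 8),
            p3 = mutate(base, 12, del_at = 60, del_len = 7))
  hits <- align_all_vs_all(prot)
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  b62 <- as.matrix(e$BLOSUM62)
  combos <- list(c("p1", "p2"), c("p1", "p3"), c("p2", "p3"))
  for (cmb in combos) {
    ref <- oracle_global_align(prot[[cmb[1]]], prot[[cmb[2]]], b62)
    hit <- hits[hits$qseqid == cmb[1] & hits$sseqid == cmb[2], ]
    score_back <- (hit$bitscore * log(2) + log(0.041)) / 0.267
    expect_equal(score_back, ref$score, tolerance = 0.005)
    expect_equal(hit$length, ref$length)
    expect_equal(hit$pident, ref$pident, tolerance = 0.02)
    expect_equal(hit$mismatch, ref$mismatch)
    expect_equal(hit$gapopen, ref$gapopen)
  }
})

test_that("identical proteins score 100 percent and unrelated ones fail filters", {
  set.seed(9)
  aas <- c("A","R","N","D","C","Q","E","G","H","I",
           "L","K","M","F","P","S","T","W","Y","V")
  same <- paste(sample(aas, 400, replace = TRUE), collapse = "")
  unrelated <- paste(sample(aas, 400, replace = TRUE), collapse = "")
  hits <- align_all_vs_all(c(x = same, y = same, z = unrelated))
  xy <- hits[hits$qseqid == "x" & hits$sseqid == "y", ]
  expect_equal(xy$pident, 100)
  expect_identical(xy$mismatch, 0L)
  xz <- hits[hits$qseqid == "x" & hits$sseqid == "z", ]
  expect_identical(nrow(filter_hits(xz)), 0L)
  expect_identical(nrow(align_all_vs_all(character(0))), 0L)
})
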