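test_that("the packaged mini ontology parses with three roots", {
  onto <- read_obo(mini_obo_path())
  expect_s3_class(onto, "go_ontology")
  expect_setequal(onto$roots, c("GO:0003674", "GO:0008150", "GO:0005575"))
  expect_false("GO:0000000" %in% onto$terms$id)  # obsolete dropped
  # part_of edge present
  expect_true("GO:0008152" %in% onto$parents[["GO:0006355"]])
})

test_that("annotation propagation closes upward and is idempotent", {
  onto <- read_obo(mini_obo_path())
  anno <- data.frame(gene = "g1", term = "GO:0003700",
                     stringsAsFactors = FALSE)
  prop <- propagate_annotations(anno, onto)
  # leaf with 2 ancestors -> 3 terms
  expect_identical(nrow(prop), 3L)
  expect_setequal(prop$term,
                  c("GO:0003700", "GO:0140110", "GO:0003674"))
  expect_identical(propagate_annotations(prop, onto), prop)
})

test_that("closure equals brute force on a random DAG", {
  set.seed(41)
  n <- 20
  ids <- sprintf("T%02d", seq_len(n))
  # random DAG: edges only from higher to lower index
  parents <- setNames(lapply(seq_len(n), function(i) {
    if (i == 1) return(character(0))
    k <- sample(0:min(3, i - 1), 1)
    if (k == 0) character(0) else sample(ids[seq_len(i - 1)], k)
  }), ids)
  onto <- structure(list(
    terms = data.frame(id = ids, name = ids, namespace = "x",
                       stringsAsFactors = FALSE),
    parents = parents,
    roots = ids[lengths(parents) == 0]), class = "go_ontology")
  anc <- term_ancestors(onto)
  expect_identical(lapply(anc, sort), oracle_closure(parents))
})

test_that("a cyclic ontology is rejected naming the cycle", {
  onto <- structure(list(
    terms = data.frame(id = c("a", "b"), name = c("a", "b"),
                       namespace = "x", stringsAsFactors = FALSE),
    parents = list(a = "b", b = "a"), roots = character(0)),
    class = "go_ontology")
  expect_error(term_ancestors(onto), "cycle.*a.*b|cycle.*b.*a")
})

test_that("ora respects the minimum background set size of 10", {
  genes <- sprintf("g%02d", 1:40)
  anno <- rbind(data.frame(gene = genes[1:9], term = "GO:small"),
                data.frame(gene = genes[1:12], term = "GO:big"))
  res <- ora_test(genes[1:10], genes, anno, group_name = "grp")
  expect_false("GO:small" %in% res$term)  # K = 9 not tested
  expect_true("GO:big" %in% res$term)
})

test_that("group equal to background has over-representation p of 1", {
  genes <- sprintf("g%02d", 1:30)
  anno <- data.frame(gene = genes[1:15], term = "GO:t")
  res <- ora_test(genes, genes, anno, group_name = "grp")
  expect_equal(res$raw_p, 1)
})

test_that("hypergeometric tails equal exhaustive enumeration", {
  # the spec's pinned configuration
  res <- ora_test(group = sprintf("g%02d", 1:10),
                  background = sprintf("g%02d", 1:20),
                  annotations = data.frame(gene = sprintf("g%02d", c(1:9, 11)),
                                           term = "GO:t"),
                  group_name = "grp")
  expect_equal(res$raw_p, oracle_hyper_upper_tail(9, 10, 20, 10),
               tolerance = 1e-12)
  expect_identical(res$direction, "over")
})

test_that("BH correction preserves the raw p-value order", {
  set.seed(43)
  genes <- sprintf("g%03d", 1:200)
  group <- sample(genes, 60)
  anno <- do.call(rbind, lapply(1:8, function(i)
    data.frame(gene = sample(genes, sample(12:80, 1)),
               term = paste0("GO:", i))))
  res <- ora_test(group, genes, anno, group_name = "grp")
  expect_identical(order(res$raw_p), order(res$corrected_p))
  expect_true(all(res$corrected_p >= res$raw_p))
  expect_true(all(res$k <= pmin(res$n, res$K)))
})

test_that("paralog groups follow the Ks range bounds", {
  pairs <- data.frame(
    gene_a = c("a1", "b1", "c1"), gene_b = c("a2", "b2", "c2"),
    label = c("WGD", "undefined", "tandem"),
    ks = c(0.5, 1.2, 1.0), stringsAsFactors = FALSE)
  groups <- build_groups(pairs)
  expect_setequal(groups$A, c("a1", "a2"))        # Ks 0.5 in A
  expect_setequal(groups$E, c("a1", "a2", "c1", "c2"))
  expect_false(any(c("a1", "a2") %in% groups$B))
  expect_setequal(groups$C, c("b1", "b2"))        # undefined included
  expect_setequal(groups$F, c("b1", "b2"))
  expect_false(any(c("b1", "b2") %in% c(groups$WGD, groups$tandem)))
  for (g in names(groups))
    expect_lte(length(groups[[g]]), 2 * nrow(pairs))
})
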