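test_that("true-path propagation adds all ancestors, idempotently", {
  go <- tiny_go()
  ann <- go_annotation(list(gA = "GO:LEAF", gB = "GO:MID1"),
                       go$parents, go$term_names)
  prop <- propagate_annotations(ann)
  expect_setequal(prop$gene2terms$gA,
                  c("GO:LEAF", "GO:MID1", "GO:MID2", "GO:ROOT"))
  expect_setequal(prop$gene2terms$gB, c("GO:MID1", "GO:ROOT"))
  # idempotent, and diamond ancestors counted once (set semantics)
  expect_identical(propagate_annotations(prop)$gene2terms, prop$gene2terms)
  expect_identical(anyDuplicated(prop$gene2terms$gA), 0L)
})

test_that("cycles in the term DAG are reported with a member", {
  parents <- list(a = "b", b = "c", c = "a")
  ann <- go_annotation(list(g = "a"), parents)
  expect_error(propagate_annotations(ann), "cycle.*'(a|b|c)'")
})

test_that("study == population forces p = 1 everywhere", {
  go <- tiny_go()
  genes <- paste0("g", 1:6)
  g2t <- setNames(lapply(1:6, function(i)
    if (i <= 3) "GO:LEAF" else "GO:MID1"), genes)
  ann <- propagate_annotations(go_annotation(g2t, go$parents, go$term_names))
  res <- go_enrichment(genes, genes, ann, namespace = "BP")
  expect_true(nrow(res) > 0)
  expect_true(all(res$p_value == 1))
})

test_that("enrichment p equals the hypergeometric tail (worked example)", {
  # study of 10 with 5 in the term; population of 100 with 10 in the term
  p_expected <- brute_hyper_tail(5, 10, 10, 100)
  expect_equal(seednet:::.hyper_tail(5, 10, 10, 100), p_expected,
               tolerance = 1e-12)
  # and through the full pipeline
  pop <- paste0("g", 1:100)
  g2t <- setNames(rep(list("GO:LEAF"), 10), pop[1:10])
  go <- tiny_go()
  ann <- propagate_annotations(go_annotation(g2t, go$parents, go$term_names))
  study <- c(pop[1:5], pop[11:15]) # 5 in-term, 5 out
  res <- go_enrichment(study, pop, ann, namespace = "BP")
  leaf <- res[res$term == "GO:LEAF", ]
  expect_equal(leaf$p_value, p_expected, tolerance = 1e-12)
  expect_identical(leaf$study_count, 5L)
  expect_identical(leaf$pop_count, 10L)
  expect_equal(leaf$expected, 10 * 10 / 100)
})

test_that("Fisher tail matches brute-force enumeration on all small tables", {
  got <- numeric(); want <- numeric()
  for (N in 1:30) {
    for (K in 0:N) {
      for (n in seq_len(N)) {
        for (k in max(0L, n - (N - K)):min(n, K)) {
          got[length(got) + 1L] <- seednet:::.hyper_tail(k, K, n, N)
          want[length(want) + 1L] <- brute_hyper_tail(k, K, n, N)
        }
      }
    }
  }
  expect_gt(length(got), 40000)
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("the pipeline tail agrees with fisher.test on sampled tables", {
  set.seed(77)
  for (rep in 1:20) {
    N <- sample(10:30, 1); K <- sample(1:N, 1); n <- sample(1:N, 1)
    k_min <- max(0L, n - (N - K)); k_max <- min(n, K)
    k <- sample(k_min:k_max, 1)
    if (k == 0) next
    tab <- matrix(c(k, K - k, n - k, N - K - (n - k)), 2)
    expect_equal(seednet:::.hyper_tail(k, K, n, N),
                 fisher.test(tab, alternative = "greater")$p.value,
                 tolerance = 1e-9)
  }
})

test_that("terms with no study genes are excluded and rows are ranked by p", {
  go <- tiny_go()
  pop <- paste0("g", 1:20)
  g2t <- c(setNames(rep(list("GO:LEAF"), 4), pop[1:4]),
           setNames(rep(list("GO:MF1"), 4), pop[5:8]))
  ann <- propagate_annotations(go_annotation(g2t, go$parents, go$term_names))
  res <- go_enrichment(pop[1:4], pop, ann, namespace = "BP")
  expect_false("GO:MF1" %in% res$term) # MF term filtered by namespace
  expect_false(is.unsorted(res$p_value))
  res_mf <- go_enrichment(pop[1:4], pop, ann, namespace = "MF")
  expect_identical(nrow(res_mf), 0L)
  # BH adjustment preserves the p ordering
  expect_false(is.unsorted(res$p_adjusted[order(res$p_value)]))
  expect_error(go_enrichment(c(pop[1], "absent"), pop, ann), "absent")
})

test_that("enrichment is invariant to gene relabeling", {
  go <- tiny_go()
  pop <- paste0("g", 1:30)
  g2t <- setNames(rep(list("GO:LEAF"), 8), pop[1:8])
  ann <- propagate_annotations(go_annotation(g2t, go$parents, go$term_names))
  res1 <- go_enrichment(pop[c(1:4, 21:24)], pop, ann, namespace = "BP")
  relabel <- setNames(paste0("X", 1:30), pop)
  g2t2 <- setNames(g2t, relabel[names(g2t)])
  ann2 <- propagate_annotations(go_annotation(g2t2, go$parents, go$term_names))
  res2 <- go_enrichment(relabel[c(1:4, 21:24)], unname(relabel), ann2,
                        namespace = "BP")
  expect_equal(res1$p_value, res2$p_value)
  expect_equal(res1$study_count, res2$study_count)
})

test_that("OBO subset parser extracts ids, namespaces and both parent kinds", {
  obo <- tempfile(fileext = ".obo")
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:0000001", "name: child",
    "namespace: biological_process",
    "is_a: GO:0000002 ! parent one",
    "relationship: part_of GO:0000003 ! parent two", "",
    "[Term]", "id: GO:0000002", "name: parent one",
    "namespace: biological_process", "",
    "[Term]", "id: GO:0000003", "name: parent two",
    "namespace: molecular_function", "",
    "[Term]", "id: GO:0000009", "name: gone",
    "namespace: biological_process", "is_obsolete: true", "",
    "[Typedef]", "id: part_of"
  ), obo)
  parsed <- read_obo(obo)
  expect_setequal(parsed$term_parents[["GO:0000001"]],
                  c("GO:0000002", "GO:0000003"))
  expect_identical(parsed$term_names$namespace[parsed$term_names$term == "GO:0000003"],
                   "MF")
  expect_false("GO:0000009" %in% parsed$term_names$term)
})
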