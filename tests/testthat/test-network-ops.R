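test_that("trimming keeps records at or above the threshold, in order", {
  l <- make_list("s", c("a", "b", "c"), c(0.9, 0.6, 0.4))
  expect_identical(trim_list(l, 0)$records$gene, l$records$gene)
  t5 <- trim_list(l, 0.5)
  expect_identical(t5$records$f_rel, c(0.9, 0.6))
  expect_identical(t5$records$rank, 1:2)
  l2 <- make_list("s", c("a", "b"), c(1, 0.99), runs = 100L)
  expect_identical(trim_list(l2, 1)$records$gene, "a")
})

test_that("weight classes split the displayed band into equal thirds", {
  expect_identical(weight_class(1.0), "solid")
  expect_identical(weight_class(0.85), "solid")
  expect_identical(weight_class(0.75), "dashed")
  expect_identical(weight_class(0.55), "dotted")
  expect_identical(weight_class(0.5), "dotted")
  # band rescales with the trimming threshold
  expect_identical(weight_class(0.25, f_min = 0.2), "dotted")
  expect_identical(weight_class(0.9, f_min = 0.2), "solid")
  expect_error(weight_class(0.3), "band")
})

test_that("create_network applies the mutual-presence rule with mean weights", {
  lists <- list(
    make_list("A", c("B", "X"), c(0.8, 0.3), pearson = c(0.9, 0.1)),
    make_list("B", c("A", "X"), c(0.6, 0.2), pearson = c(0.88, 0.1))
  )
  net <- create_network(lists, f_min = 0.5)
  expect_identical(nrow(net$edges), 1L)
  expect_equal(net$edges$weight, 0.7)
  expect_identical(net$edges$sign, "+")
  expect_identical(net$edges$weight_class, "dashed")
  expect_identical(net$nodes$gene, c("A", "B"))

  # trimming at 0.7 removes the 0.6 direction -> no edge, nodes remain
  net2 <- create_network(lists, f_min = 0.7)
  expect_identical(nrow(net2$edges), 0L)
  expect_identical(net2$nodes$gene, c("A", "B"))

  # one-sided presence yields no edge under the mutual rule ...
  lists3 <- list(make_list("A", c("B"), 0.9),
                 make_list("B", c("Z"), 0.9))
  expect_identical(nrow(create_network(lists3, f_min = 0.5)$edges), 0L)
  # ... unless the relaxed rule is requested
  net3 <- create_network(lists3, f_min = 0.5, one_sided = TRUE)
  expect_identical(nrow(net3$edges), 1L)
  expect_equal(net3$edges$weight, 0.9)
})

test_that("edge sign is negative when either direction anticorrelates", {
  lists <- list(
    make_list("A", "B", 0.8, pearson = -0.7),
    make_list("B", "A", 0.8, pearson = -0.65)
  )
  expect_identical(create_network(lists, f_min = 0.5)$edges$sign, "-")
  lists2 <- list(
    make_list("A", "B", 0.8, pearson = 0.7),
    make_list("B", "A", 0.8, pearson = -0.65)
  )
  expect_message(net <- create_network(lists2, f_min = 0.5), "discordance")
  expect_identical(net$edges$sign, "-")
})

test_that("network is invariant to input list order and monotone in trimming", {
  set.seed(31)
  seeds <- paste0("S", 1:5)
  lists <- lapply(seeds, function(s) {
    others <- setdiff(seeds, s)
    make_list(s, others, round(runif(length(others)), 2),
              pearson = runif(length(others), -1, 1), runs = 100L)
  })
  net <- create_network(lists, f_min = 0.4)
  net_perm <- create_network(rev(lists), f_min = 0.4)
  expect_identical(net, net_perm)
  edges_lo <- create_network(lists, f_min = 0.4)$edges
  edges_hi <- create_network(lists, f_min = 0.6)$edges
  key <- function(e) paste(e$source, e$target)
  expect_true(all(key(edges_hi) %in% key(edges_lo)))
})

test_that("create_network in the single-full-tile limit matches the skeleton", {
  truth <- fixture_truth("dag-20")
  m <- sample_expression(truth, 500, rng_seed = 11)
  seeds <- c("g001", "g002", "g005", "g010")
  lists <- lapply(seeds, function(s)
    expand_gene(m, s, n_iterations = 1, tile_size = 20, rng_seed = 3))
  net <- create_network(lists, f_min = 0.5)
  full <- estimate_skeleton(m, alpha = 0.05)
  for (a in seeds) for (b in seeds) {
    if (a < b) {
      has_edge <- any(net$edges$source == a & net$edges$target == b)
      expect_identical(has_edge, unname(full$adjacency[a, b]))
    }
  }
})

test_that("expand_network honors all four aggregation criteria", {
  ann_tsv <- tempfile(fileext = ".tsv")
  writeLines(c("v1_id\tvcost_id\tsymbol\tcategory",
               "g1\tV1\tTF1\tvv60.1",
               "g2\tV2\tENZ\tvv30.2",
               "g3\tV3\tTF2\tvv60.9"), ann_tsv)
  ann <- read_annotation(ann_tsv)
  lists <- list(
    make_list("A", c("g1", "g2", "g3"), c(0.9, 0.7, 0.2)),
    make_list("B", c("g1", "g4"), c(0.5, 0.4)),
    make_list("C", c("g4", "g2"), c(0.95, 0.1))
  )
  # frel on one list reproduces the trimmed list exactly
  single <- expand_network(lists[1], criterion = "frel", value = 0.5)
  expect_identical(single$gene, trim_list(lists[[1]], 0.5)$records$gene)

  # shared: g1 is in 2 of 3 lists
  shared2 <- expand_network(lists, criterion = "shared", value = 2)
  expect_true(all(c("g1", "g2", "g4") %in% shared2$gene))
  shared3 <- expand_network(lists, criterion = "shared", value = 3)
  expect_identical(nrow(shared3), 0L)

  # rank
  rank1 <- expand_network(lists, criterion = "rank", value = 1)
  expect_identical(sort(rank1$gene), c("g1", "g4"))

  # pattern: only vv60-prefixed categories survive
  pat <- expand_network(lists, criterion = "pattern", value = "vv60",
                        annotation = ann)
  expect_identical(sort(pat$gene), c("g1", "g3"))
  expect_error(expand_network(lists, criterion = "pattern", value = "vv60"),
               "annotation")
  expect_error(expand_network(lists, criterion = "nope", value = 1))
})

test_that("frel aggregation equals brute-force union of trimmed lists", {
  set.seed(57)
  seeds <- paste0("S", 1:4)
  pool <- paste0("g", 1:15)
  lists <- lapply(seeds, function(s) {
    genes <- sample(pool, 8)
    make_list(s, genes, round(runif(8), 2), runs = 100L)
  })
  for (thr in c(0.2, 0.5, 0.8)) {
    agg <- expand_network(lists, criterion = "frel", value = thr)
    brute <- sort(unique(unlist(lapply(lists, function(l)
      trim_list(l, thr)$records$gene))))
    expect_identical(sort(agg$gene), brute)
    expect_true(all(agg$max_f_rel >= thr))
    expect_false(is.unsorted(-agg$max_f_rel))
  }
})

test_that("aggregated statistics are computed across source lists", {
  lists <- list(
    make_list("A", c("x", "y"), c(0.8, 0.6)),
    make_list("B", c("x"), c(0.4))
  )
  agg <- expand_network(lists, criterion = "frel", value = 0)
  x <- agg[agg$gene == "x", ]
  expect_identical(x$n_seeds, 2L)
  expect_identical(x$source_seeds, "A,B")
  expect_equal(x$max_f_rel, 0.8)
  expect_equal(x$mean_f_rel, 0.6)
  expect_identical(x$best_rank, 1L)
})

test_that("network tables and JSON round-trip byte-identically", {
  lists <- list(
    make_list("A", c("B", "C"), c(0.8, 0.55), pearson = c(-0.9, 0.5)),
    make_list("B", c("A", "C"), c(0.6, 0.9), pearson = c(-0.85, 0.4)),
    make_list("C", c("A", "B"), c(0.52, 0.88))
  )
  net <- create_network(lists, f_min = 0.5)
  pre1 <- file.path(tempdir(), "net1")
  write_network_tables(net, pre1)
  back <- read_network_tables(pre1)
  expect_equal(back$edges, net$edges, tolerance = 0)
  expect_identical(back$nodes$gene, net$nodes$gene)
  pre2 <- file.path(tempdir(), "net2")
  write_network_tables(back, pre2)
  for (suf in c("_nodes.tsv", "_edges.tsv")) {
    f1 <- paste0(pre1, suf); f2 <- paste0(pre2, suf)
    expect_identical(readBin(f1, "raw", file.size(f1)),
                     readBin(f2, "raw", file.size(f2)))
  }
  j1 <- tempfile(fileext = ".json"); j2 <- tempfile(fileext = ".json")
  export_graph_json(net, j1)
  export_graph_json(read_graph_json(j1, f_min = net$f_min), j2)
  expect_identical(readBin(j1, "raw", file.size(j1)),
                   readBin(j2, "raw", file.size(j2)))
})

test_that("static image rendering produces a PNG file", {
  lists <- list(make_list("A", "B", 0.8), make_list("B", "A", 0.7))
  net <- create_network(lists, f_min = 0.5)
  p <- tempfile(fileext = ".png")
  plot_network_png(net, p, width = 300, height = 300)
  expect_true(file.size(p) > 0)
  expect_identical(readBin(p, "raw", 4L)[2:4], charToRaw("PNG"))
})
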