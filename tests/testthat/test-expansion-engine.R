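test_that("tile arithmetic follows the ceiling partition rule", {
  expect_identical(num_tiles(1000, 1000), 1L)
  expect_identical(num_tiles(1001, 1000), 2L)
  expect_identical(num_tiles(10, 4), 3L)
  expect_error(num_tiles(5, 6), "n_genes >= tile_size")
  expect_error(num_tiles(10, 1), "tile_size >= 2")
  expect_identical(total_runs(1, 1, 1), 1)
  expect_identical(total_runs(10, 2, 5), 100)
})

test_that("tile plans partition the non-seed genes and are deterministic", {
  genes <- paste0("g", 1:10)
  plan <- make_tile_plan(genes, "g1", 4, iter_seed = 99)
  expect_length(plan, 3L)
  # 9 non-seed genes in chunks of at most 3: three tiles of 4 (seed included)
  expect_identical(lengths(plan), c(4L, 4L, 4L))
  # uneven case: 11 genes, tile 4 -> chunks 3,3,3,1 -> sizes 4,4,4,2
  plan11 <- make_tile_plan(paste0("h", 1:11), "h1", 4, iter_seed = 1)
  expect_identical(lengths(plan11), c(4L, 4L, 4L, 2L))
  expect_true(all(vapply(plan, function(t) t[1] == "g1", TRUE)))
  non_seed <- unlist(lapply(plan, `[`, -1L))
  expect_identical(sort(non_seed), sort(setdiff(genes, "g1")))
  expect_identical(anyDuplicated(non_seed), 0L)
  # same seed -> identical plan; plan depends only on the ID set
  expect_identical(make_tile_plan(genes, "g1", 4, 99), plan)
  expect_identical(make_tile_plan(rev(genes), "g1", 4, 99), plan)
  expect_error(make_tile_plan(genes, "zz", 4, 1), "not in gene universe")
  expect_error(make_tile_plan(genes, "g1", 11, 1), "exceeds gene count")
})

test_that("single full-tile expansion reduces to the full-skeleton adjacency", {
  truth <- fixture_truth("dag-20")
  m <- sample_expression(truth, 500, rng_seed = 11)
  el <- expand_gene(m, "g005", n_iterations = 1, tile_size = 20, rng_seed = 3)
  expect_true(all(el$records$f_rel %in% c(0, 1)))
  full <- estimate_skeleton(m, alpha = 0.05)
  adj <- full$adjacency["g005", el$records$gene]
  expect_identical(el$records$f_rel, as.numeric(adj))
  expect_true(all(el$records$input_count == 1L))
})

test_that("relative frequency equals output over input counts with full coverage", {
  truth <- fixture_truth("dag-20")
  m <- sample_expression(truth, 300, rng_seed = 17)
  el <- expand_gene(m, "g002", n_iterations = 8, tile_size = 7, rng_seed = 21)
  r <- el$records
  # tiles partition the universe, so every gene enters once per iteration
  expect_true(all(r$input_count == 8L))
  expect_equal(r$f_rel, r$output_count / r$input_count, tolerance = 0)
  expect_true(all(r$f_rel >= 0 & r$f_rel <= 1))
  expect_identical(r$rank, seq_len(nrow(r)))
  expect_false(is.unsorted(-r$f_rel))
  expect_false("g002" %in% r$gene)
  # stored correlation matches the full-sample Pearson correlation
  expect_equal(r$pearson_r[r$gene == "g001"],
               cor(m["g002", ], m["g001", ]), tolerance = 1e-12)
})

test_that("expansion is deterministic and invariant to gene row order", {
  truth <- fixture_truth("dag-20")
  m <- sample_expression(truth, 300, rng_seed = 11)
  el1 <- expand_gene(m, "g005", n_iterations = 15, tile_size = 8, rng_seed = 5)
  el2 <- expand_gene(m, "g005", n_iterations = 15, tile_size = 8, rng_seed = 5)
  expect_identical(el1, el2)
  set.seed(1)
  el3 <- expand_gene(m[sample(nrow(m)), ], "g005", n_iterations = 15,
                     tile_size = 8, rng_seed = 5)
  expect_identical(el1, el3)
  # different root seed gives a different (but valid) list
  el4 <- expand_gene(m, "g005", n_iterations = 15, tile_size = 8, rng_seed = 6)
  expect_false(identical(el1$records, el4$records))
})

test_that("true neighbors of a 4-neighbor seed rank in the top 6 (dag-20)", {
  truth <- fixture_truth("dag-20")
  sk <- dag_skeleton(truth$amat)
  seed <- "g010"
  expect_identical(sum(sk[seed, ]), 4L)
  m <- sample_expression(truth, 1000, rng_seed = 11)
  el <- expand_gene(m, seed, n_iterations = 200, tile_size = 10, rng_seed = 7)
  top6 <- el$records$gene[1:6]
  expect_true(all(truth$gene_ids[sk[seed, ]] %in% top6))
})

test_that("neighbor recovery does not degrade with sample size", {
  truth <- fixture_truth("dag-20")
  sk <- dag_skeleton(truth$amat)
  nb <- truth$gene_ids[sk["g010", ]]
  mean_frel <- vapply(c(100, 500, 2000), function(n) {
    m <- sample_expression(truth, n, rng_seed = 13)
    el <- expand_gene(m, "g010", n_iterations = 50, tile_size = 10, rng_seed = 7)
    mean(el$records$f_rel[match(nb, el$records$gene)])
  }, 0)
  # non-decreasing up to one re-draw of tolerance
  expect_true(all(diff(mean_frel) >= -0.05))
})

test_that("zero-variance genes are excluded with a warning; bad seeds error", {
  truth <- fixture_truth("chain-5")
  m <- sample_expression(truth, 200, rng_seed = 3)
  m <- rbind(m, flat = rep(1, ncol(m)))
  expect_warning(el <- expand_gene(m, "g001", n_iterations = 2, tile_size = 5,
                                   rng_seed = 1), "zero-variance")
  expect_false("flat" %in% el$records$gene)
  expect_error(expand_gene(m, "nope", n_iterations = 1, tile_size = 3),
               "not in matrix")
  expect_error(suppressWarnings(expand_gene(m, "flat", n_iterations = 1, tile_size = 3)),
               "zero variance")
})

test_that("parallel execution reproduces the sequential result", {
  truth <- fixture_truth("dag-20")
  m <- sample_expression(truth, 200, rng_seed = 23)
  el1 <- expand_gene(m, "g001", n_iterations = 6, tile_size = 10, rng_seed = 9)
  el2 <- expand_gene(m, "g001", n_iterations = 6, tile_size = 10, rng_seed = 9,
                     cores = 2L)
  expect_identical(el1, el2)
})

test_that("fixed tiling variant reuses the first iteration's plan", {
  truth <- fixture_truth("dag-20")
  m <- sample_expression(truth, 200, rng_seed = 29)
  el <- expand_gene(m, "g003", n_iterations = 5, tile_size = 10, rng_seed = 2,
                    resample_tiles = FALSE)
  # under a fixed plan, a gene is either always or never in the seed's tile,
  # so input counts are all equal to n_iterations (partition covers everyone)
  expect_true(all(el$records$input_count == 5L))
  expect_true(all(el$records$f_rel >= 0 & el$records$f_rel <= 1))
})
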