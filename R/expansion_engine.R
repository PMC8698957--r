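#' Number of seed-containing tiles needed to cover the gene universe
#'
#' Every tile holds the seed plus up to `tile_size - 1` other genes, and
#' within one iteration the non-seed genes are partitioned across tiles, so
#' the minimal tile count is `ceiling((n_genes - 1) / (tile_size - 1))`. With
#' a 28,013-gene universe and tiles of 1000 this gives the 29 subsets each
#' expansion iteration schedules.
#'
#' @param n_genes Total number of genes in the universe (including the seed).
#' @param tile_size Genes per tile (seed included), at least 2.
#' @return Integer tile count.
#' @export
num_tiles <- function(n_genes, tile_size) {
  n_genes <- as.numeric(n_genes)
  tile_size <- as.numeric(tile_size)
  if (tile_size < 2 || n_genes < tile_size) {
    stop("need n_genes >= tile_size >= 2", call. = FALSE)
  }
  as.integer(ceiling((n_genes - 1) / (tile_size - 1)))
}

#' Total skeleton runs for a full-genome expansion campaign
#'
#' When every gene in the universe is expanded, the scheduler executes
#' `n_genes * n_tiles * n_iterations` independent skeleton estimations
#' (e.g. `28013 * 29 * 2000 = 1,624,754,000`).
#'
#' @param n_genes Number of genes expanded.
#' @param n_tiles Tiles per iteration (see [num_tiles()]).
#' @param n_iterations Iterations per expansion.
#' @return The product, as a double (counts exceed 32-bit integers).
#' @export
total_runs <- function(n_genes, n_tiles, n_iterations) {
  stopifnot(n_genes > 0, n_tiles > 0, n_iterations > 0)
  as.numeric(n_genes) * as.numeric(n_tiles) * as.numeric(n_iterations)
}

# deterministic per-iteration RNG stream: seeds stay below 2^31 - 1 and
# depend only on the root seed and the iteration counter, so iterations can
# be computed independently (and concurrently) with identical results
.iteration_seed <- function(rng_seed, iteration) {
  as.integer((as.numeric(rng_seed) + 11400714 * as.numeric(iteration)) %% 2147483647)
}

#' Build one iteration's tile plan
#'
#' Shuffles the non-seed genes (canonically sorted first, so the plan depends
#' only on the ID set, never on input row order), partitions them into chunks
#' of at most `tile_size - 1`, and prepends the seed to each chunk. The last
#' tile may be smaller; tiles within an iteration are disjoint apart from the
#' seed and jointly cover every non-seed gene exactly once.
#'
#' @param gene_ids Character vector of gene IDs (the universe).
#' @param seed Seed gene ID, must be in `gene_ids`.
#' @param tile_size Genes per tile including the seed.
#' @param iter_seed Integer seed for this iteration's shuffle.
#' @return A list of character vectors, each starting with the seed.
#' @export
make_tile_plan <- function(gene_ids, seed, tile_size, iter_seed) {
  if (!seed %in% gene_ids) stop("seed '", seed, "' not in gene universe", call. = FALSE)
  if (tile_size > length(gene_ids)) stop("tile_size exceeds gene count", call. = FALSE)
  if (tile_size < 2L) stop("tile_size must be at least 2", call. = FALSE)
  others <- sort(setdiff(gene_ids, seed))
  shuffled <- .with_seed(iter_seed, sample(others))
  k <- num_tiles(length(gene_ids), tile_size)
  chunk <- ceiling(seq_along(shuffled) / (tile_size - 1L))
  unname(lapply(split(shuffled, chunk), function(g) c(seed, g)))
}

# evaluate expr under a local RNG state seeded with `seed`
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Expand a single seed gene
#'
#' The core procedure: for each of `n_iterations` iterations the gene
#' universe is tiled into random seed-containing subsets
#' (see [make_tile_plan()]), the PC skeleton is estimated on each tile, and
#' for every gene two counters accumulate: how often it shared a tile with
#' the seed (`input_count`) and how often it remained adjacent to the seed in
#' that tile's skeleton (`output_count`). The relative frequency
#' `f_rel = output_count / input_count` scores candidate direct interactions;
#' the result is ranked by descending `f_rel` (ties broken by larger
#' `|pearson_r|`, then lexicographic gene ID). The Pearson correlation of
#' each gene with the seed over all samples is recorded alongside, so the
#' correlation sign can color network edges downstream.
#'
#' @param mat Expression matrix, genes in rows (see
#'   [read_expression_matrix()]). Zero-variance genes are excluded with a
#'   warning before tiling.
#' @param seed_gene Gene ID to expand.
#' @param n_iterations Number of tiling iterations (production-scale runs use
#'   2000; small studies proportionally fewer).
#' @param tile_size Genes per tile including the seed (production scale:
#'   1000, i.e. seed + 999 sampled without replacement).
#' @param alpha Significance level of the Fisher-z test (default 0.05).
#' @param rng_seed Root RNG seed; per-iteration streams are derived
#'   deterministically from it.
#' @param resample_tiles If `TRUE` (default) a fresh random tiling is drawn
#'   every iteration; if `FALSE` the first iteration's tiling is reused
#'   throughout.
#' @param max_order Optional cap on the conditioning-set size passed to
#'   [estimate_skeleton()].
#' @param cores Number of worker processes for iteration-level parallelism
#'   (results are identical to sequential execution).
#' @return An [expansion_list()].
#' @export
expand_gene <- function(mat, seed_gene, n_iterations = 2000L, tile_size = 1000L,
                        alpha = 0.05, rng_seed = 1L, resample_tiles = TRUE,
                        max_order = Inf, cores = 1L) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)))
  if (!seed_gene %in% rownames(mat)) {
    stop("seed gene '", seed_gene, "' not in matrix", call. = FALSE)
  }
  n_iterations <- as.integer(n_iterations)
  tile_size <- as.integer(tile_size)
  stopifnot(n_iterations >= 1L, tile_size >= 2L)
  v <- apply(mat, 1L, stats::var)
  if (v[seed_gene] == 0) stop("seed gene has zero variance", call. = FALSE)
  if (any(v == 0)) {
    warning("excluding ", sum(v == 0), " zero-variance gene(s): ",
            paste(utils::head(rownames(mat)[v == 0], 5L), collapse = ", "),
            call. = FALSE)
    mat <- mat[v > 0, , drop = FALSE]
  }
  genes <- rownames(mat)
  if (tile_size > length(genes)) stop("tile_size exceeds usable gene count", call. = FALSE)

  others <- sort(setdiff(genes, seed_gene))
  # Pearson correlation with the seed over all samples, computed once
  pearson <- as.vector(stats::cor(mat[seed_gene, ], t(mat[others, , drop = FALSE])))
  names(pearson) <- others

  fixed_plan <- if (!resample_tiles) {
    make_tile_plan(genes, seed_gene, tile_size, .iteration_seed(rng_seed, 1L))
  } else NULL

  run_iteration <- function(it) {
    plan <- if (resample_tiles) {
      make_tile_plan(genes, seed_gene, tile_size, .iteration_seed(rng_seed, it))
    } else fixed_plan
    inp <- integer(length(others)); names(inp) <- others
    outp <- integer(length(others)); names(outp) <- others
    for (tile in plan) {
      sub <- mat[tile, , drop = FALSE]
      skel <- estimate_skeleton(sub, alpha = alpha, max_order = max_order)
      nbr <- tile[skel$adjacency[seed_gene, tile]]
      members <- setdiff(tile, seed_gene)
      inp[members] <- inp[members] + 1L
      outp[nbr] <- outp[nbr] + 1L
    }
    list(inp = inp, outp = outp)
  }

  results <- if (cores > 1L) {
    parallel::mclapply(seq_len(n_iterations), run_iteration, mc.cores = cores)
  } else {
    lapply(seq_len(n_iterations), run_iteration)
  }
  input_count <- Reduce(`+`, lapply(results, `[[`, "inp"))
  output_count <- Reduce(`+`, lapply(results, `[[`, "outp"))
  f_rel <- ifelse(input_count > 0, output_count / input_count, 0)

  ord <- order(-f_rel, -abs(pearson), others, method = "radix")
  records <- data.frame(
    gene = others[ord],
    input_count = as.integer(input_count[ord]),
    output_count = as.integer(output_count[ord]),
    f_rel = as.numeric(f_rel[ord]),
    pearson_r = as.numeric(pearson[ord]),
    rank = seq_along(ord),
    stringsAsFactors = FALSE
  )
  expansion_list(seed_gene, records,
                 list(n_iterations = n_iterations, tile_size = tile_size,
                      alpha = alpha, rng_seed = rng_seed))
}
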