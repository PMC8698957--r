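#' Generate a random DAG (ground truth for benchmarking)
#'
#' Draws a random topological order and includes each forward edge
#' independently with probability `edge_prob` (Erdos-Renyi over the upper
#' triangle of the ordered adjacency), so the graph is acyclic by
#' construction. Edge coefficients are drawn uniformly from
#' `[-hi, -lo] U [lo, hi]`; the magnitude floor keeps the linear model away
#' from near-unfaithful cancellations.
#'
#' @param n Number of genes (nodes), at least 2.
#' @param edge_prob Edge inclusion probability in `[0, 1]`.
#' @param rng_seed Integer seed; fixed seed gives an identical DAG.
#' @param weight_range Magnitude range `c(lo, hi)` for edge coefficients.
#' @param noise_sd Per-gene noise standard deviation (recycled to `n`).
#' @return An object of class `synthetic_truth`: `gene_ids`, logical `amat`
#'   (`amat[i, j]` means gene i -> gene j), numeric `weights` (zero off the
#'   edges), `noise_sd`, `topo_order`, `rng_seed`.
#' @export
random_dag <- function(n, edge_prob, rng_seed = 1L,
                       weight_range = c(0.5, 1.5), noise_sd = 1) {
  stopifnot(n >= 2L, edge_prob >= 0, edge_prob <= 1)
  gene_ids <- sprintf("g%03d", seq_len(n))
  .with_seed(rng_seed, {
    topo <- sample.int(n)
    amat <- matrix(FALSE, n, n, dimnames = list(gene_ids, gene_ids))
    weights <- matrix(0, n, n, dimnames = list(gene_ids, gene_ids))
    for (a in seq_len(n - 1L)) {
      for (b in seq.int(a + 1L, n)) {
        if (stats::runif(1L) < edge_prob) {
          i <- topo[a]; j <- topo[b]
          amat[i, j] <- TRUE
          w <- stats::runif(1L, weight_range[1L], weight_range[2L])
          if (stats::runif(1L) < 0.5) w <- -w
          weights[i, j] <- w
        }
      }
    }
    structure(list(gene_ids = gene_ids, amat = amat, weights = weights,
                   noise_sd = rep_len(noise_sd, n), topo_order = topo,
                   rng_seed = as.integer(rng_seed)),
              class = "synthetic_truth")
  })
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("Synthetic truth: %d genes, %d directed edges (seed %d)\n",
              length(x$gene_ids), sum(x$amat), x$rng_seed))
  invisible(x)
}

# topological order via Kahn's algorithm; errors on a cycle
.topo_sort <- function(amat) {
  n <- nrow(amat)
  indeg <- colSums(amat)
  order_out <- integer(0)
  avail <- which(indeg == 0)
  indeg[avail] <- NA
  while (length(avail) > 0L) {
    v <- avail[1L]; avail <- avail[-1L]
    order_out <- c(order_out, v)
    for (w in which(amat[v, ])) {
      if (!is.na(indeg[w])) {
        indeg[w] <- indeg[w] - 1L
        if (indeg[w] == 0L) { avail <- c(avail, w); indeg[w] <- NA }
      }
    }
  }
  if (length(order_out) < n) stop("cyclic adjacency: not a DAG", call. = FALSE)
  order_out
}

#' Sample expression data from a linear-Gaussian structural model
#'
#' Genes are visited in topological order and each is the weighted sum of its
#' parents plus independent Gaussian noise:
#' `X_j = sum_{i in pa(j)} w_ij X_i + eps_j`. The Fisher-z test is exactly
#' calibrated for this model, so it exercises the skeleton search under its
#' own assumptions.
#'
#' @param truth A `synthetic_truth` from [random_dag()].
#' @param n_samples Number of samples (columns).
#' @param rng_seed Integer seed (defaults to a stream derived from the
#'   truth's own seed).
#' @return Numeric matrix, genes x samples, rownames = gene IDs.
#' @export
sample_expression <- function(truth, n_samples, rng_seed = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"), n_samples >= 1L)
  if (is.null(rng_seed)) rng_seed <- .iteration_seed(truth$rng_seed, 1L)
  n <- length(truth$gene_ids)
  topo <- .topo_sort(truth$amat)
  .with_seed(rng_seed, {
    X <- matrix(0, n, n_samples, dimnames = list(truth$gene_ids, NULL))
    for (j in topo) {
      eps <- stats::rnorm(n_samples, 0, truth$noise_sd[j])
      parents <- which(truth$amat[, j])
      X[j, ] <- eps
      if (length(parents) > 0L) {
        X[j, ] <- X[j, ] + as.vector(truth$weights[parents, j] %*%
                                       X[parents, , drop = FALSE])
      }
    }
    colnames(X) <- sprintf("s%04d", seq_len(n_samples))
    X
  })
}

#' Analytic covariance of the linear-Gaussian model
#'
#' `Cov(X) = (I - W)^{-T} D (I - W)^{-1}` with `W` the weighted adjacency
#' (`W[i, j]` = effect of i on j) and `D = diag(noise_sd^2)`. Sample
#' covariance converges to this entrywise as samples grow.
#'
#' @param truth A `synthetic_truth`.
#' @return Covariance matrix (genes x genes).
#' @export
analytic_covariance <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  n <- length(truth$gene_ids)
  A <- solve(diag(n) - t(truth$weights))
  V <- A %*% diag(truth$noise_sd^2) %*% t(A)
  dimnames(V) <- list(truth$gene_ids, truth$gene_ids)
  V
}

#' Recovery metrics for an expansion list against ground truth
#'
#' Treats the seed's true skeleton neighbours (parents and children in the
#' generating DAG) as positives and `f_rel` as the score. AUROC is the
#' Mann-Whitney rank statistic (ties share average ranks); AUPR is the
#' step-interpolated area under the precision-recall curve.
#'
#' @param x An [expansion_list()] produced from data sampled from `truth`.
#' @param truth The generating `synthetic_truth`.
#' @param seed_gene Seed gene ID (defaults to the list's seed).
#' @return A list: `auroc`, `aupr`, `neighbor_mean_frel`,
#'   `non_neighbor_mean_frel`, `n_neighbors`.
#' @export
recovery_metrics <- function(x, truth, seed_gene = x$seed) {
  stopifnot(inherits(x, "expansion_list"), inherits(truth, "synthetic_truth"))
  sk <- dag_skeleton(truth$amat)
  if (!seed_gene %in% truth$gene_ids) stop("seed not in truth", call. = FALSE)
  neighbors <- truth$gene_ids[sk[seed_gene, ]]
  if (length(neighbors) == 0L) {
    stop("seed gene has no true neighbours: AUROC undefined", call. = FALSE)
  }
  r <- x$records
  labels <- r$gene %in% neighbors
  scores <- r$f_rel
  npos <- sum(labels); nneg <- sum(!labels)
  if (nneg == 0L) stop("no negatives among scored genes", call. = FALSE)
  rk <- rank(scores) # average ranks under ties
  auroc <- (sum(rk[labels]) - npos * (npos + 1) / 2) / (npos * nneg)

  ord <- order(-scores, r$gene, method = "radix")
  lab <- labels[ord]
  tp <- cumsum(lab)
  fp <- cumsum(!lab)
  precision <- tp / (tp + fp)
  recall <- tp / npos
  # area via recall increments (average-precision form)
  aupr <- sum(diff(c(0, recall)) * precision)

  list(auroc = auroc, aupr = aupr,
       neighbor_mean_frel = mean(scores[labels]),
       non_neighbor_mean_frel = mean(scores[!labels]),
       n_neighbors = npos)
}

#' Named benchmark fixtures
#'
#' A small registry of ground-truth graphs with hard-coded seeds, used
#' throughout the tests and examples:
#' \describe{
#'   \item{tiny-collider}{3 genes, `g001 -> g003 <- g002` with unit weights:
#'     the classic v-structure whose endpoints are marginally independent.}
#'   \item{chain-5}{5 genes in a directed chain with coefficient 0.9.}
#'   \item{dag-20}{20-gene random DAG, edge probability 0.12.}
#'   \item{dag-50}{50-gene random DAG, edge probability 0.08.}
#' }
#'
#' @param name Fixture name.
#' @return A `synthetic_truth`.
#' @export
fixture_truth <- function(name = c("tiny-collider", "chain-5", "dag-20", "dag-50")) {
  name <- match.arg(name)
  switch(name,
    "tiny-collider" = {
      t0 <- random_dag(3L, 0, rng_seed = 3L)
      t0$amat["g001", "g003"] <- TRUE
      t0$amat["g002", "g003"] <- TRUE
      t0$weights["g001", "g003"] <- 1
      t0$weights["g002", "g003"] <- 1
      t0$topo_order <- 1:3
      t0
    },
    "chain-5" = {
      t0 <- random_dag(5L, 0, rng_seed = 5L)
      for (k in 1:4) {
        t0$amat[k, k + 1L] <- TRUE
        t0$weights[k, k + 1L] <- 0.9
      }
      t0$topo_order <- 1:5
      t0
    },
    "dag-20" = random_dag(20L, 0.12, rng_seed = 20L),
    "dag-50" = random_dag(50L, 0.08, rng_seed = 50L)
  )
}

#' Serialize ground truth as a JSON edge list
#'
#' @param truth A `synthetic_truth`.
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  idx <- which(truth$amat, arr.ind = TRUE)
  edges <- lapply(seq_len(nrow(idx)), function(k) {
    list(from = truth$gene_ids[idx[k, 1L]],
         to = truth$gene_ids[idx[k, 2L]],
         weight = truth$weights[idx[k, 1L], idx[k, 2L]])
  })
  obj <- list(genes = truth$gene_ids, noise_sd = truth$noise_sd,
              rng_seed = truth$rng_seed, edges = edges)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE),
             path)
  invisible(path)
}

#' Read ground truth back from its JSON edge list
#'
#' @param path Path written by [write_truth_json()].
#' @return A `synthetic_truth`.
#' @export
read_truth_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  genes <- unlist(obj$genes)
  n <- length(genes)
  amat <- matrix(FALSE, n, n, dimnames = list(genes, genes))
  weights <- matrix(0, n, n, dimnames = list(genes, genes))
  for (e in obj$edges) {
    amat[e$from, e$to] <- TRUE
    weights[e$from, e$to] <- e$weight
  }
  truth <- structure(list(gene_ids = genes, amat = amat, weights = weights,
                          noise_sd = unlist(obj$noise_sd),
                          topo_order = NULL, rng_seed = as.integer(obj$rng_seed)),
                     class = "synthetic_truth")
  truth$topo_order <- .topo_sort(amat)
  truth
}
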