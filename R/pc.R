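#' Partial correlation from a correlation matrix
#'
#' Computes `rho(i, j | S)`, the correlation of variables `i` and `j` after
#' removing the linear effect of the conditioning set `S`. Two algebraically
#' equivalent routes are provided: inversion of the `(i, j, S)` submatrix
#' (the precision-matrix formula) and the classical first-order recursion;
#' they agree to numerical precision on any well-conditioned input and serve
#' as mutual checks.
#'
#' @param corr Symmetric correlation matrix.
#' @param i,j Variable indices (1-based), distinct, not in `S`.
#' @param S Integer vector of conditioning indices (possibly empty).
#' @param method `"inversion"` (default) or `"recursive"`.
#' @return The partial correlation, a number in `[-1, 1]`.
#' @export
partial_correlation <- function(corr, i, j, S = integer(), method = c("inversion", "recursive")) {
  method <- match.arg(method)
  stopifnot(is.matrix(corr), nrow(corr) == ncol(corr))
  i <- as.integer(i); j <- as.integer(j); S <- as.integer(S)
  if (i == j) stop("i and j must differ", call. = FALSE)
  if (i %in% S || j %in% S) stop("i and j must not be in S", call. = FALSE)
  if (length(S) == 0L) return(corr[i, j])
  if (method == "inversion") {
    idx <- c(i, j, S)
    P <- tryCatch(solve(corr[idx, idx, drop = FALSE]),
                  error = function(e) stop("degenerate input: singular submatrix for (",
                                           i, ",", j, " | ", paste(S, collapse = ","), ")",
                                           call. = FALSE))
    den <- sqrt(P[1L, 1L] * P[2L, 2L])
    if (!is.finite(den) || den <= 0) {
      stop("degenerate input: singular submatrix", call. = FALSE)
    }
    -P[1L, 2L] / den
  } else {
    k <- S[length(S)]
    S2 <- S[-length(S)]
    r_ij <- partial_correlation(corr, i, j, S2, method = "recursive")
    r_ik <- partial_correlation(corr, i, k, S2, method = "recursive")
    r_jk <- partial_correlation(corr, j, k, S2, method = "recursive")
    den <- sqrt((1 - r_ik^2) * (1 - r_jk^2))
    if (!is.finite(den) || den <= 0) {
      stop("degenerate input: unit marginal correlation in recursion", call. = FALSE)
    }
    (r_ij - r_ik * r_jk) / den
  }
}

#' Fisher-z conditional independence test
#'
#' Tests whether a (partial) correlation is compatible with conditional
#' independence: `z = sqrt(n - |S| - 3) * atanh(rho)` is compared against the
#' two-sided normal quantile at level `alpha`. `rho` is clamped to
#' `+/-(1 - 1e-12)` before the transform.
#'
#' @param rho Partial correlation.
#' @param n_samples Number of samples the correlation was estimated from.
#' @param cond_size Size of the conditioning set `|S|`.
#' @param alpha Significance level in (0, 1).
#' @return `"independent"` or `"dependent"`; `NA` when the test is
#'   unavailable (`n_samples - cond_size - 3 <= 0`), in which case callers
#'   must retain the edge.
#' @export
fisher_z_test <- function(rho, n_samples, cond_size, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  if (n_samples - cond_size - 3 <= 0) return(NA_character_)
  cap <- 1 - 1e-12
  rho <- max(min(rho, cap), -cap)
  z <- sqrt(n_samples - cond_size - 3) * 0.5 * log((1 + rho) / (1 - rho))
  if (abs(z) <= stats::qnorm(1 - alpha / 2)) "independent" else "dependent"
}

.skeleton_new <- function(variables, adjacency, sepsets, max_level) {
  dimnames(adjacency) <- list(variables, variables)
  structure(list(variables = variables, adjacency = adjacency,
                 sepsets = sepsets, max_level = max_level),
            class = "skeleton")
}

#' @export
print.skeleton <- function(x, ...) {
  ne <- sum(x$adjacency) / 2
  cat(sprintf("PC skeleton: %d variables, %d edges (max conditioning order %d)\n",
              length(x$variables), ne, x$max_level))
  invisible(x)
}

.sepset_key <- function(a, b) paste(sort(c(a, b)), collapse = "|")

# R-level PC-stable loop over an arbitrary CI-test closure. ci_test(i, j, S)
# returns TRUE (independent), FALSE (dependent) or NA (test unavailable at
# this conditioning size; the edge is retained for that subset).
.pc_skeleton_generic <- function(variables, ci_test, max_order = Inf) {
  p <- length(variables)
  adj <- matrix(TRUE, p, p)
  diag(adj) <- FALSE
  sepsets <- list()
  l <- 0L
  reached <- -1L
  repeat {
    if (l > max_order) break
    degs <- rowSums(adj)
    if (l > 0L && !any(adj & (degs - 1 >= l))) break
    reached <- l
    snap <- adj
    for (i in seq_len(p - 1L)) {
      for (j in seq.int(i + 1L, p)) {
        if (!adj[i, j]) next
        removed <- FALSE
        for (side in 1:2) {
          a <- if (side == 1L) i else j
          b <- if (side == 1L) j else i
          pool <- which(snap[a, ])
          pool <- pool[pool != b]
          if (length(pool) < l) next
          if (l == 0L && side == 2L) next
          subsets <- if (l == 0L) {
            list(integer())
          } else if (length(pool) == 1L) {
            list(pool) # combn(scalar, l) would enumerate seq_len(scalar)
          } else {
            utils::combn(pool, l, simplify = FALSE)
          }
          for (S in subsets) {
            verdict <- ci_test(i, j, S)
            if (isTRUE(verdict)) {
              adj[i, j] <- adj[j, i] <- FALSE
              sepsets[[.sepset_key(variables[i], variables[j])]] <- variables[S]
              removed <- TRUE
              break
            }
          }
          if (removed) break
        }
      }
    }
    l <- l + 1L
  }
  .skeleton_new(variables, adj, sepsets, reached)
}

#' Estimate the undirected skeleton of a causal graph
#'
#' Runs the order-independent ("stable") variant of the PC algorithm's
#' skeleton phase: starting from the complete undirected graph, edges `(i, j)`
#' are removed whenever some conditioning set `S` of growing size, drawn from
#' the level-start neighbourhood of `i` or of `j`, makes the pair
#' conditionally independent. With expression data the test is the Fisher-z
#' partial-correlation test; alternatively an arbitrary conditional
#' independence oracle can be supplied (e.g. exact d-separation on a known
#' DAG, see [dsep_oracle()]), which is how the implementation is validated.
#'
#' Because neighbourhoods are snapshotted at the start of each level, the
#' resulting skeleton does not depend on the order of the variables.
#'
#' @param data Numeric matrix with variables (genes) in rows and samples in
#'   columns. Ignored when `ci_test` is given.
#' @param alpha Significance level of the Fisher-z test.
#' @param max_order Optional cap on the conditioning-set size; `Inf` (default)
#'   lets the structural stopping rule decide.
#' @param ci_test Optional closure `function(i, j, S)` returning `TRUE`
#'   (independent), `FALSE` (dependent) or `NA` (unavailable).
#' @param variables Variable names; required with `ci_test`, defaults to
#'   `rownames(data)` otherwise.
#' @return An object of class `skeleton`: `variables`, a symmetric logical
#'   `adjacency` matrix, `sepsets` (a named list mapping removed pairs
#'   `"a|b"` to the separating variable set), and `max_level`, the largest
#'   conditioning order actually examined.
#' @export
estimate_skeleton <- function(data = NULL, alpha = 0.05, max_order = Inf,
                              ci_test = NULL, variables = NULL) {
  if (!is.null(ci_test)) {
    stopifnot(is.function(ci_test), !is.null(variables), length(variables) >= 2L)
    return(.pc_skeleton_generic(variables, ci_test, max_order))
  }
  stopifnot(is.matrix(data), nrow(data) >= 2L)
  if (ncol(data) < 4L) stop("need at least 4 samples", call. = FALSE)
  if (is.null(variables)) variables <- rownames(data)
  if (is.null(variables)) variables <- paste0("V", seq_len(nrow(data)))
  v <- apply(data, 1L, stats::var)
  if (any(v == 0)) {
    stop("degenerate input: zero-variance variable(s): ",
         paste(variables[v == 0], collapse = ", "), call. = FALSE)
  }
  C <- stats::cor(t(data))
  mo <- if (is.finite(max_order)) as.integer(max_order) else -1L
  res <- .pc_skeleton_cpp(C, ncol(data), alpha, mo)
  sepsets <- list()
  if (length(res$sep_i) > 0L) {
    for (k in seq_along(res$sep_i)) {
      key <- .sepset_key(variables[res$sep_i[k]], variables[res$sep_j[k]])
      sepsets[[key]] <- variables[res$sep_sets[[k]]]
    }
  }
  .skeleton_new(variables, res$adjacency, sepsets, res$max_level)
}

#' Extract a skeleton's edges as a table
#'
#' @param skel A `skeleton` object.
#' @return A data.frame with columns `from`, `to` (each undirected edge once,
#'   endpoints sorted).
#' @export
skeleton_edges <- function(skel) {
  stopifnot(inherits(skel, "skeleton"))
  idx <- which(skel$adjacency & upper.tri(skel$adjacency), arr.ind = TRUE)
  data.frame(from = skel$variables[idx[, 1L]],
             to = skel$variables[idx[, 2L]],
             stringsAsFactors = FALSE)
}

#' Dump a skeleton as an edge-list TSV
#'
#' @param skel A `skeleton` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_skeleton_tsv <- function(skel, path) {
  utils::write.table(skeleton_edges(skel), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
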