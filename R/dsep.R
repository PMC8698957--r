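# Exact conditional-independence oracle on a known DAG via d-separation.
# Used to validate the skeleton search: under faithfulness, PC run with this
# oracle must return exactly the DAG's skeleton.

# ancestors (reflexive) of a node set in a DAG given as a logical adjacency
# matrix with amat[i, j] == TRUE meaning i -> j
.ancestors_of <- function(amat, nodes) {
  anc <- rep(FALSE, nrow(amat))
  anc[nodes] <- TRUE
  repeat {
    # parents of any current member
    newly <- which(!anc & (amat %*% anc > 0))
    if (length(newly) == 0L) break
    anc[newly] <- TRUE
  }
  which(anc)
}

#' d-separation in a DAG
#'
#' Decides whether nodes `i` and `j` are d-separated given the set `S`, using
#' the moral-graph criterion: restrict the DAG to the ancestors of
#' `{i, j} union S`, moralize (join parents of a common child, drop
#' directions), delete `S`, and test graph separation of `i` and `j`.
#'
#' @param amat Logical (or 0/1) adjacency matrix of the DAG; `amat[i, j]`
#'   nonzero means an edge `i -> j`.
#' @param i,j Node indices (1-based).
#' @param S Integer vector of conditioning node indices (possibly empty).
#' @return `TRUE` if `i` and `j` are d-separated given `S`.
#' @export
dsep <- function(amat, i, j, S = integer()) {
  amat <- matrix(as.logical(amat), nrow(amat))
  i <- as.integer(i); j <- as.integer(j); S <- as.integer(S)
  stopifnot(i != j, !(i %in% S), !(j %in% S))
  keep <- .ancestors_of(amat, c(i, j, S))
  sub <- amat[keep, keep, drop = FALSE]
  m <- nrow(sub)
  undirected <- sub | t(sub)
  # moralization: parents sharing a child become adjacent
  for (child in seq_len(m)) {
    parents <- which(sub[, child])
    if (length(parents) > 1L) undirected[parents, parents] <- TRUE
  }
  diag(undirected) <- FALSE
  # delete conditioning nodes, then BFS from i
  drop <- match(S, keep)
  ii <- match(i, keep); jj <- match(j, keep)
  alive <- setdiff(seq_len(m), drop)
  reach <- rep(FALSE, m)
  reach[ii] <- TRUE
  frontier <- ii
  while (length(frontier) > 0L) {
    nxt <- unique(unlist(lapply(frontier, function(v) which(undirected[v, ])), use.names = FALSE))
    nxt <- nxt[nxt %in% alive & !reach[nxt]]
    reach[nxt] <- TRUE
    frontier <- nxt
  }
  !reach[jj]
}

#' Conditional-independence oracle from a known DAG
#'
#' Wraps [dsep()] as a CI-test closure suitable for
#' [estimate_skeleton()]'s `ci_test` argument: independence holds exactly
#' when the pair is d-separated.
#'
#' @param amat DAG adjacency matrix (`amat[i, j]` nonzero means `i -> j`).
#' @return A function `(i, j, S) -> logical`.
#' @export
dsep_oracle <- function(amat) {
  amat <- matrix(as.logical(amat), nrow(amat))
  function(i, j, S) dsep(amat, i, j, S)
}

#' Skeleton (undirected adjacency) of a DAG
#'
#' @param amat DAG adjacency matrix.
#' @return Symmetric logical matrix with an edge wherever the DAG has one in
#'   either direction.
#' @export
dag_skeleton <- function(amat) {
  a <- matrix(as.logical(amat), nrow(amat), dimnames = dimnames(amat))
  sk <- a | t(a)
  diag(sk) <- FALSE
  sk
}
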