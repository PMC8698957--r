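# Shared fixtures and independent oracles, all built in code at test time.

# hand-built expansion list (records supplied as f_rel out of a fixed number
# of runs so counts stay consistent with the f_rel formula)
make_list <- function(seed, genes, f_rel, pearson = NULL, runs = 100L,
                      params = list(n_iterations = runs, tile_size = 5L,
                                    alpha = 0.05, rng_seed = 1L)) {
  if (is.null(pearson)) pearson <- rep(0.5, length(genes))
  ord <- order(-f_rel, -abs(pearson), genes, method = "radix")
  records <- data.frame(
    gene = genes[ord],
    input_count = rep(runs, length(genes)),
    output_count = as.integer(round(f_rel[ord] * runs)),
    f_rel = f_rel[ord],
    pearson_r = pearson[ord],
    rank = seq_along(genes),
    stringsAsFactors = FALSE
  )
  expansion_list(seed, records, params)
}

# enumerate every labeled DAG on n nodes (upper-triangular masks pushed
# through all label permutations, deduplicated)
all_labeled_dags <- function(n) {
  if (n == 1L) return(list(matrix(FALSE, 1L, 1L)))
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  perms <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
  perms <- perms[apply(perms, 1L, function(x) length(unique(x)) == n), , drop = FALSE]
  seen <- new.env(parent = emptyenv())
  out <- list()
  for (mask in 0:(2^nrow(pairs) - 1L)) {
    bits <- bitwAnd(bitwShiftR(mask, seq_len(nrow(pairs)) - 1L), 1L) == 1L
    for (r in seq_len(nrow(perms))) {
      p <- perms[r, ]
      amat <- matrix(FALSE, n, n)
      amat[p[pairs[bits, 1L]] + n * (p[pairs[bits, 2L]] - 1L)] <- TRUE
      key <- paste0("k", paste(which(amat), collapse = ","))
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        out[[length(out) + 1L]] <- amat
      }
    }
  }
  out
}

# brute-force hypergeometric upper tail P(X >= k) by direct pmf summation
brute_hyper_tail <- function(k, K, n, N) {
  ks <- max(0L, n - (N - K)):min(n, K)
  pmf <- choose(K, ks) * choose(N - K, n - ks) / choose(N, n)
  sum(pmf[ks >= k])
}

# random correlation matrix (SPD with unit diagonal) of size p
random_corr <- function(p, seed) {
  set.seed(seed)
  A <- matrix(rnorm(p * p), p)
  S <- crossprod(A) + diag(p) * 0.5
  stats::cov2cor(S)
}

# tiny GO universe: a diamond-shaped BP branch and one MF term
#   bp_root <- bp_mid1 / bp_mid2 <- bp_leaf   (leaf has two paths to root)
tiny_go <- function() {
  parents <- list(
    "GO:LEAF" = c("GO:MID1", "GO:MID2"),
    "GO:MID1" = "GO:ROOT",
    "GO:MID2" = "GO:ROOT",
    "GO:MF1"  = "GO:MFROOT"
  )
  term_names <- data.frame(
    term = c("GO:LEAF", "GO:MID1", "GO:MID2", "GO:ROOT", "GO:MF1", "GO:MFROOT"),
    name = c("leaf process", "mid one", "mid two", "root process",
             "mf leaf", "mf root"),
    namespace = c("BP", "BP", "BP", "BP", "MF", "MF"),
    stringsAsFactors = FALSE
  )
  list(parents = parents, term_names = term_names)
}

# write a tiny genome FASTA + GFF3 pair; returns paths and the raw sequences
tiny_genome <- function(dir = tempfile("genome")) {
  dir.create(dir)
  set.seed(42)
  chr1 <- paste(sample(c("A", "C", "G", "T"), 6000, replace = TRUE), collapse = "")
  # lowercase block to verify case preservation
  substr(chr1, 4001, 4100) <- tolower(substr(chr1, 4001, 4100))
  chr2 <- paste(sample(c("A", "C", "G", "T"), 1500, replace = TRUE), collapse = "")
  fa <- file.path(dir, "genome.fa")
  writeLines(c(">chr1", substring(chr1, seq(1, 6000, 80), pmin(seq(1, 6000, 80) + 79, 6000)),
               ">chr2", substring(chr2, seq(1, 1500, 80), pmin(seq(1, 1500, 80) + 79, 1500))), fa)
  gff <- file.path(dir, "ann.gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\ttest\tgene\t5001\t5600\t.\t+\t.\tID=geneA",
    "chr1\ttest\tgene\t3000\t5000\t.\t-\t.\tID=geneB",
    "chr1\ttest\tgene\t500\t900\t.\t+\t.\tID=geneC",
    "chr2\ttest\tgene\t1000\t1400\t.\t-\t.\tID=geneD"
  ), gff)
  list(fa = fa, gff = gff, chr1 = chr1, chr2 = chr2)
}
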