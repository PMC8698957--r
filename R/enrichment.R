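#' Read a gene-to-GO-term annotation table
#'
#' A two-column TSV (`gene`, `term`) of direct annotations; one row per
#' gene/term pair.
#'
#' @param path Path to the TSV file.
#' @return A named list of character vectors: gene -> set of term IDs.
#' @export
read_gene2go <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, header = TRUE, colClasses = "character",
                           check.names = FALSE, comment.char = "#")
  if (!all(c("gene", "term") %in% names(tab))) {
    stop("gene2go table must have columns 'gene' and 'term'", call. = FALSE)
  }
  lapply(split(tab$term, tab$gene), unique)
}

#' Read a minimal OBO subset (term id, name, namespace, is_a/part_of parents)
#'
#' Parses only the stanza fields needed for true-path propagation and
#' namespace filtering; everything else in the file is ignored. Obsolete
#' terms are skipped.
#'
#' @param path Path to an OBO file.
#' @return A list with `term_parents` (named list term -> parent terms) and
#'   `term_names` (data.frame `term`, `name`, `namespace` with namespaces
#'   mapped to `"BP"`, `"MF"`, `"CC"`).
#' @export
read_obo <- function(path) {
  if (!file.exists(path)) stop("OBO file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  ns_map <- c(biological_process = "BP", molecular_function = "MF",
              cellular_component = "CC")
  terms <- list(); parents <- list()
  cur <- NULL; cur_name <- NA_character_; cur_ns <- NA_character_
  cur_parents <- character(); in_term <- FALSE; obsolete <- FALSE
  flush <- function() {
    if (!is.null(cur) && in_term && !obsolete) {
      terms[[cur]] <<- c(name = cur_name, namespace = cur_ns)
      parents[[cur]] <<- unique(cur_parents)
    }
  }
  for (ln in lines) {
    if (startsWith(ln, "[")) {
      flush()
      in_term <- identical(ln, "[Term]")
      cur <- NULL; cur_name <- NA_character_; cur_ns <- NA_character_
      cur_parents <- character(); obsolete <- FALSE
    } else if (in_term) {
      if (startsWith(ln, "id: ")) cur <- sub("^id: ", "", ln)
      else if (startsWith(ln, "name: ")) cur_name <- sub("^name: ", "", ln)
      else if (startsWith(ln, "namespace: ")) {
        ns <- sub("^namespace: ", "", ln)
        cur_ns <- if (ns %in% names(ns_map)) ns_map[[ns]] else ns
      }
      else if (startsWith(ln, "is_a: ")) {
        cur_parents <- c(cur_parents, sub("\\s*!.*$", "", sub("^is_a: ", "", ln)))
      }
      else if (startsWith(ln, "relationship: part_of ")) {
        cur_parents <- c(cur_parents,
                         sub("\\s*!.*$", "", sub("^relationship: part_of ", "", ln)))
      }
      else if (startsWith(ln, "is_obsolete: true")) obsolete <- TRUE
    }
  }
  flush()
  term_names <- data.frame(
    term = names(terms),
    name = vapply(terms, `[[`, "", "name"),
    namespace = vapply(terms, `[[`, "", "namespace"),
    stringsAsFactors = FALSE, row.names = NULL)
  list(term_parents = parents, term_names = term_names)
}

#' Assemble a GO annotation object
#'
#' @param gene2terms Named list gene -> direct term IDs
#'   (see [read_gene2go()]).
#' @param term_parents Named list term -> parent term IDs (is_a/part_of).
#' @param term_names Optional data.frame `term`, `name`, `namespace`.
#' @return An object of class `go_annotation`.
#' @export
go_annotation <- function(gene2terms, term_parents, term_names = NULL) {
  if (is.null(term_names)) {
    all_terms <- unique(c(names(term_parents), unlist(term_parents, use.names = FALSE),
                          unlist(gene2terms, use.names = FALSE)))
    term_names <- data.frame(term = all_terms, name = NA_character_,
                             namespace = NA_character_, stringsAsFactors = FALSE)
  }
  structure(list(gene2terms = gene2terms, term_parents = term_parents,
                 term_names = term_names, propagated = FALSE),
            class = "go_annotation")
}

# all ancestors (excluding the term itself) under the parent relation;
# errors on a cycle, naming a member
.term_ancestors <- function(term_parents) {
  memo <- new.env(parent = emptyenv())
  visiting <- new.env(parent = emptyenv())
  walk <- function(term) {
    if (!is.null(memo[[term]])) return(memo[[term]])
    if (isTRUE(visiting[[term]])) {
      stop("cycle detected in term DAG at '", term, "'", call. = FALSE)
    }
    visiting[[term]] <- TRUE
    ps <- term_parents[[term]]
    anc <- if (is.null(ps) || length(ps) == 0L) character() else {
      unique(c(ps, unlist(lapply(ps, walk), use.names = FALSE)))
    }
    visiting[[term]] <- FALSE
    memo[[term]] <- anc
    anc
  }
  all_terms <- unique(c(names(term_parents),
                        unlist(term_parents, use.names = FALSE)))
  stats::setNames(lapply(all_terms, walk), all_terms)
}

#' Propagate annotations up the term DAG (true-path rule)
#'
#' Every gene annotated to a term becomes annotated to all of the term's
#' ancestors (is_a/part_of closure). Idempotent; a diamond-shaped DAG counts
#' each ancestor once per gene (set semantics).
#'
#' @param ann A `go_annotation`.
#' @return The propagated `go_annotation`.
#' @export
propagate_annotations <- function(ann) {
  stopifnot(inherits(ann, "go_annotation"))
  anc <- .term_ancestors(ann$term_parents)
  ann$gene2terms <- lapply(ann$gene2terms, function(terms) {
    extra <- unlist(anc[intersect(terms, names(anc))], use.names = FALSE)
    sort(unique(c(terms, extra)))
  })
  ann$propagated <- TRUE
  ann
}

# one-sided over-representation tail P(X >= k) for X ~ Hypergeom(K, N - K, n)
.hyper_tail <- function(k, K, n, N) {
  stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
}

#' GO over-representation analysis
#'
#' Classic per-term one-sided Fisher test: for every term annotated to at
#' least one study gene, the hypergeometric upper tail
#' `P(X >= study_count)` is computed from the 2x2 table of
#' study/population x in-term/not-in-term, and a Benjamini-Hochberg adjusted
#' column is added. Rows are ranked by ascending raw p-value.
#'
#' @param study Character vector of study gene IDs (subset of `population`).
#' @param population Character vector of population (universe) gene IDs.
#' @param ann A propagated `go_annotation` (propagation is applied on the
#'   fly if it has not been).
#' @param namespace `"BP"`, `"MF"` (or `"CC"`); terms without a recorded
#'   namespace are kept only when `namespace = NULL`.
#' @return A data.frame with columns `term`, `name`, `study_count`,
#'   `study_size`, `pop_count`, `pop_size`, `expected`, `p_value`,
#'   `p_adjusted`.
#' @export
go_enrichment <- function(study, population, ann, namespace = c("BP", "MF", "CC")) {
  stopifnot(inherits(ann, "go_annotation"))
  study <- unique(study); population <- unique(population)
  missing_genes <- setdiff(study, population)
  if (length(missing_genes) > 0L) {
    stop("study gene(s) absent from population: ",
         paste(utils::head(missing_genes, 5L), collapse = ", "), call. = FALSE)
  }
  if (!is.null(namespace)) namespace <- match.arg(namespace)
  if (!isTRUE(ann$propagated)) ann <- propagate_annotations(ann)

  g2t <- ann$gene2terms[intersect(population, names(ann$gene2terms))]
  term_genes <- split(rep(names(g2t), lengths(g2t)),
                      unlist(g2t, use.names = FALSE))
  if (!is.null(namespace)) {
    ok_terms <- ann$term_names$term[!is.na(ann$term_names$namespace) &
                                      ann$term_names$namespace == namespace]
    term_genes <- term_genes[names(term_genes) %in% ok_terms]
  }
  pop_size <- length(population)
  study_size <- length(study)
  rows <- lapply(names(term_genes), function(term) {
    genes <- term_genes[[term]]
    k <- sum(study %in% genes)
    if (k == 0L) return(NULL)
    K <- length(genes)
    p <- .hyper_tail(k, K, study_size, pop_size)
    data.frame(term = term, study_count = k, study_size = study_size,
               pop_count = K, pop_size = pop_size,
               expected = study_size * K / pop_size,
               p_value = p, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L) {
    return(data.frame(term = character(), name = character(),
                      study_count = integer(), study_size = integer(),
                      pop_count = integer(), pop_size = integer(),
                      expected = numeric(), p_value = numeric(),
                      p_adjusted = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out$name <- ann$term_names$name[match(out$term, ann$term_names$term)]
  out <- out[order(out$p_value, out$term, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("term", "name", "study_count", "study_size", "pop_count",
          "pop_size", "expected", "p_value", "p_adjusted")]
}
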