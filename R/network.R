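#' Trim an expansion list at a relative-frequency threshold
#'
#' Keeps the records with `f_rel >= f_min`, preserving order. Trimming
#' chooses how many candidate genes enter network construction.
#'
#' @param x An [expansion_list()].
#' @param f_min Threshold in `[0, 1]`.
#' @return A trimmed [expansion_list()] (ranks renumbered 1..N).
#' @export
trim_list <- function(x, f_min) {
  stopifnot(inherits(x, "expansion_list"), f_min >= 0, f_min <= 1)
  keep <- x$records$f_rel >= f_min
  records <- x$records[keep, , drop = FALSE]
  records$rank <- seq_len(nrow(records))
  expansion_list(x$seed, records, x$params)
}

#' Edge line-type class from mean relative frequency
#'
#' Edge weights in the displayed band are binned into equal thirds:
#' `solid` for the top third, `dashed` for the middle, `dotted` for the
#' bottom. With the default band `[0.5, 1]` the cut points are 0.8333 and
#' 0.6667; for other trimming thresholds the band rescales to `[f_min, 1]`.
#'
#' @param weight Numeric vector of edge weights in `[f_min, 1]`.
#' @param f_min Lower end of the displayed band (the trimming threshold).
#' @return Character vector: `"solid"`, `"dashed"` or `"dotted"`.
#' @export
weight_class <- function(weight, f_min = 0.5) {
  stopifnot(f_min >= 0, f_min < 1)
  if (any(weight < f_min - 1e-12 | weight > 1 + 1e-12)) {
    stop("edge weight outside the displayed band [", f_min, ", 1]", call. = FALSE)
  }
  step <- (1 - f_min) / 3
  ifelse(weight >= f_min + 2 * step, "solid",
         ifelse(weight >= f_min + step, "dashed", "dotted"))
}

.empty_edges <- function() {
  data.frame(source = character(), target = character(), weight = numeric(),
             sign = character(), weight_class = character(),
             stringsAsFactors = FALSE)
}

.gene_network_new <- function(nodes, edges, f_min) {
  structure(list(nodes = nodes, edges = edges, f_min = f_min),
            class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("Gene network: %d nodes, %d edges (f_min = %g)\n",
              nrow(x$nodes), nrow(x$edges), x$f_min))
  invisible(x)
}

.annotate_nodes <- function(gene_ids, annotation) {
  nodes <- data.frame(gene = gene_ids, vcost_id = NA_character_,
                      symbol = NA_character_, category = NA_character_,
                      stringsAsFactors = FALSE)
  if (!is.null(annotation)) {
    m <- match(gene_ids, annotation$v1_id)
    hit <- !is.na(m)
    nodes$vcost_id[hit] <- annotation$vcost_id[m[hit]]
    nodes$symbol[hit] <- annotation$symbol[m[hit]]
    nodes$category[hit] <- annotation$category[m[hit]]
  }
  nodes
}

#' Build a gene network from expansion lists by mutual presence
#'
#' The input genes (the seeds of the supplied lists) become the nodes. For
#' each pair, both trimmed lists are inspected: an edge is drawn when each
#' gene appears in the other's trimmed list (mutual presence), its weight is
#' the mean of the two relative frequencies, and its sign is negative when
#' either stored Pearson correlation with the partner is negative (sign
#' discordances between the two directions are reported via a message). With
#' `one_sided = TRUE` a pair with only one qualifying direction also gets an
#' edge, weighted by the single available `f_rel`.
#'
#' @param lists A list of [expansion_list()] objects (distinct seeds, at
#'   least two).
#' @param f_min Relative-frequency trimming threshold.
#' @param annotation Optional annotation table from [read_annotation()].
#' @param one_sided Relax the mutual-presence rule (default `FALSE`).
#' @return A `gene_network`: node table, edge table (endpoints sorted
#'   lexicographically, `weight`, `sign`, `weight_class`), and the trimming
#'   threshold used.
#' @export
create_network <- function(lists, f_min, annotation = NULL, one_sided = FALSE) {
  if (inherits(lists, "expansion_list")) lists <- list(lists)
  stopifnot(length(lists) >= 2L)
  seeds <- vapply(lists, function(x) x$seed, "")
  if (anyDuplicated(seeds)) stop("duplicate seeds among input lists", call. = FALSE)
  names(lists) <- seeds
  trimmed <- lapply(lists, trim_list, f_min = f_min)

  lookup <- function(seed, gene) {
    r <- trimmed[[seed]]$records
    k <- match(gene, r$gene)
    if (is.na(k)) NULL else r[k, ]
  }

  seeds_sorted <- sort(seeds)
  rows <- list()
  for (a_i in seq_along(seeds_sorted)) {
    for (b_i in seq_len(a_i - 1L)) {
      a <- seeds_sorted[b_i]; b <- seeds_sorted[a_i] # a < b
      ab <- lookup(a, b) # b in a's list
      ba <- lookup(b, a)
      if (!is.null(ab) && !is.null(ba)) {
        if (sign(ab$pearson_r) != sign(ba$pearson_r)) {
          message("sign discordance for pair ", a, " - ", b,
                  "; flagged as anticorrelated")
        }
        rows[[length(rows) + 1L]] <- data.frame(
          source = a, target = b, weight = mean(c(ab$f_rel, ba$f_rel)),
          sign = if (ab$pearson_r < 0 || ba$pearson_r < 0) "-" else "+",
          stringsAsFactors = FALSE)
      } else if (one_sided && (!is.null(ab) || !is.null(ba))) {
        rec <- if (!is.null(ab)) ab else ba
        rows[[length(rows) + 1L]] <- data.frame(
          source = a, target = b, weight = rec$f_rel,
          sign = if (rec$pearson_r < 0) "-" else "+",
          stringsAsFactors = FALSE)
      }
    }
  }
  edges <- if (length(rows) > 0L) do.call(rbind, rows) else .empty_edges()
  if (nrow(edges) > 0L) {
    edges <- edges[order(edges$source, edges$target, method = "radix"), , drop = FALSE]
    edges$weight_class <- weight_class(edges$weight, f_min)
    rownames(edges) <- NULL
  } else {
    edges$weight_class <- character()
  }
  .gene_network_new(.annotate_nodes(seeds_sorted, annotation), edges, f_min)
}

#' Aggregate expansion lists into a candidate table
#'
#' Unions the records of all input lists into one candidate per gene (with
#' the set of source seeds whose list contains it, its best and mean relative
#' frequency, and its best rank) and then filters by one of four criteria:
#' \describe{
#'   \item{frel}{keep candidates with `max_f_rel >= value`}
#'   \item{rank}{keep candidates with `best_rank <= value`}
#'   \item{pattern}{keep candidates whose annotation category code starts
#'     with `value` (e.g. a transcription-factor category prefix); requires
#'     `annotation`}
#'   \item{shared}{keep candidates contained in at least `value` input lists}
#' }
#' Output is sorted by descending `max_f_rel`, ties broken by larger
#' `|pearson_r|` (of the best-scoring source record), then gene ID.
#'
#' @param lists A list of [expansion_list()] objects (at least one).
#' @param criterion One of `"frel"`, `"rank"`, `"pattern"`, `"shared"`.
#' @param value Threshold: numeric for `frel`, integer for `rank`/`shared`,
#'   category-code prefix string for `pattern`.
#' @param annotation Annotation table ([read_annotation()]); required for
#'   `pattern`, otherwise used only to decorate the output.
#' @return A data.frame of aggregated candidates.
#' @export
expand_network <- function(lists, criterion, value, annotation = NULL) {
  if (inherits(lists, "expansion_list")) lists <- list(lists)
  stopifnot(length(lists) >= 1L)
  criterion <- match.arg(criterion, c("frel", "rank", "pattern", "shared"))
  seeds <- vapply(lists, function(x) x$seed, "")
  if (anyDuplicated(seeds)) stop("duplicate seeds among input lists", call. = FALSE)

  all_rec <- do.call(rbind, lapply(lists, function(x) {
    cbind(x$records, source_seed = x$seed, stringsAsFactors = FALSE)
  }))
  split_rec <- split(all_rec, all_rec$gene)
  agg <- do.call(rbind, lapply(split_rec, function(r) {
    best <- order(-r$f_rel, -abs(r$pearson_r), r$source_seed, method = "radix")[1L]
    data.frame(gene = r$gene[1L],
               n_seeds = length(unique(r$source_seed)),
               source_seeds = paste(sort(unique(r$source_seed)), collapse = ","),
               max_f_rel = max(r$f_rel),
               mean_f_rel = mean(r$f_rel),
               best_rank = min(r$rank),
               pearson_r = r$pearson_r[best],
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL

  keep <- switch(criterion,
    frel = agg$max_f_rel >= as.numeric(value),
    rank = agg$best_rank <= as.numeric(value),
    shared = agg$n_seeds >= as.numeric(value),
    pattern = {
      if (is.null(annotation)) {
        stop("criterion 'pattern' requires an annotation table", call. = FALSE)
      }
      cat_code <- annotation$category[match(agg$gene, annotation$v1_id)]
      !is.na(cat_code) & startsWith(cat_code, as.character(value))
    })
  out <- agg[keep, , drop = FALSE]
  out <- out[order(-out$max_f_rel, -abs(out$pearson_r), out$gene, method = "radix"), ,
             drop = FALSE]
  if (!is.null(annotation)) {
    m <- match(out$gene, annotation$v1_id)
    out$vcost_id <- annotation$vcost_id[m]
    out$symbol <- annotation$symbol[m]
    out$category <- annotation$category[m]
  }
  rownames(out) <- NULL
  out
}

#' Write a network as node and edge TSV tables
#'
#' Emits `<prefix>_nodes.tsv` and `<prefix>_edges.tsv`. Weights are written
#' at full precision so [read_network_tables()] restores the network exactly.
#'
#' @param net A `gene_network`.
#' @param prefix Output path prefix.
#' @return The two paths, invisibly.
#' @export
write_network_tables <- function(net, prefix) {
  stopifnot(inherits(net, "gene_network"))
  node_path <- paste0(prefix, "_nodes.tsv")
  edge_path <- paste0(prefix, "_edges.tsv")
  con <- file(node_path, "wb")
  writeLines(paste(c("gene", "vcost_id", "symbol", "category"), collapse = "\t"), con)
  if (nrow(net$nodes) > 0L) {
    writeLines(sprintf("%s\t%s\t%s\t%s", net$nodes$gene,
                       ifelse(is.na(net$nodes$vcost_id), "", net$nodes$vcost_id),
                       ifelse(is.na(net$nodes$symbol), "", net$nodes$symbol),
                       ifelse(is.na(net$nodes$category), "", net$nodes$category)), con)
  }
  close(con)
  con <- file(edge_path, "wb")
  writeLines(sprintf("#f_min=%.17g", net$f_min), con)
  writeLines(paste(c("source", "target", "weight", "sign", "weight_class"),
                   collapse = "\t"), con)
  if (nrow(net$edges) > 0L) {
    writeLines(sprintf("%s\t%s\t%.17g\t%s\t%s", net$edges$source,
                       net$edges$target, net$edges$weight, net$edges$sign,
                       net$edges$weight_class), con)
  }
  close(con)
  invisible(c(nodes = node_path, edges = edge_path))
}

#' Read a network back from its node and edge tables
#'
#' @param prefix Path prefix used by [write_network_tables()].
#' @return A `gene_network`.
#' @export
read_network_tables <- function(prefix) {
  node_path <- paste0(prefix, "_nodes.tsv")
  edge_path <- paste0(prefix, "_edges.tsv")
  for (p in c(node_path, edge_path)) {
    if (!file.exists(p)) stop("network table not found: ", p, call. = FALSE)
  }
  nodes <- utils::read.delim(node_path, colClasses = "character", check.names = FALSE)
  for (col in c("vcost_id", "symbol", "category")) nodes[[col]][nodes[[col]] == ""] <- NA_character_
  lines <- readLines(edge_path)
  f_min <- as.numeric(sub("^#f_min=", "", lines[1L]))
  body <- lines[-(1:2)]
  edges <- if (length(body) > 0L) {
    fields <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
    data.frame(source = fields[, 1L], target = fields[, 2L],
               weight = as.numeric(fields[, 3L]), sign = fields[, 4L],
               weight_class = fields[, 5L], stringsAsFactors = FALSE)
  } else .empty_edges()
  .gene_network_new(nodes, edges, f_min)
}

#' Export a network as Cytoscape.js JSON
#'
#' Writes the `{"elements": {"nodes": [...], "edges": [...]}}` dialect that
#' graph viewers accept directly; node data carry the gene IDs and
#' annotation, edge data the weight, sign and line-type class.
#'
#' @param net A `gene_network`.
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
export_graph_json <- function(net, path) {
  stopifnot(inherits(net, "gene_network"))
  nodes <- lapply(seq_len(nrow(net$nodes)), function(k) {
    n <- net$nodes[k, ]
    list(data = list(id = n$gene, v1_id = n$gene,
                     vcost_id = if (is.na(n$vcost_id)) "" else n$vcost_id,
                     symbol = if (is.na(n$symbol)) "" else n$symbol,
                     category = if (is.na(n$category)) "" else n$category))
  })
  edges <- lapply(seq_len(nrow(net$edges)), function(k) {
    e <- net$edges[k, ]
    list(data = list(id = paste0("e", k), source = e$source, target = e$target,
                     weight = e$weight, sign = e$sign,
                     weight_class = e$weight_class))
  })
  json <- jsonlite::toJSON(list(elements = list(nodes = nodes, edges = edges)),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' Read a Cytoscape.js JSON export back into a network
#'
#' @param path Path written by [export_graph_json()].
#' @param f_min Trimming threshold to record on the restored object (not part
#'   of the JSON dialect); defaults to the smallest edge weight or 0.5.
#' @return A `gene_network`.
#' @export
read_graph_json <- function(path, f_min = NULL) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  nd <- x$elements$nodes
  ed <- x$elements$edges
  blank_na <- function(s) if (is.null(s) || !nzchar(s)) NA_character_ else s
  nodes <- if (length(nd) > 0L) {
    data.frame(gene = vapply(nd, function(n) n$data$id, ""),
               vcost_id = vapply(nd, function(n) blank_na(n$data$vcost_id), ""),
               symbol = vapply(nd, function(n) blank_na(n$data$symbol), ""),
               category = vapply(nd, function(n) blank_na(n$data$category), ""),
               stringsAsFactors = FALSE)
  } else {
    data.frame(gene = character(), vcost_id = character(), symbol = character(),
               category = character(), stringsAsFactors = FALSE)
  }
  edges <- if (length(ed) > 0L) {
    data.frame(source = vapply(ed, function(e) e$data$source, ""),
               target = vapply(ed, function(e) e$data$target, ""),
               weight = vapply(ed, function(e) as.numeric(e$data$weight), 0),
               sign = vapply(ed, function(e) e$data$sign, ""),
               weight_class = vapply(ed, function(e) e$data$weight_class, ""),
               stringsAsFactors = FALSE)
  } else .empty_edges()
  if (is.null(f_min)) f_min <- if (nrow(edges) > 0L) min(edges$weight) else 0.5
  .gene_network_new(nodes, edges, f_min)
}

#' Convert a network to an igraph object
#'
#' @param net A `gene_network`.
#' @return An undirected [igraph::graph] with `weight`, `sign` and
#'   `weight_class` edge attributes.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "gene_network"))
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = net$nodes)
  g
}

#' Render a static image of a network
#'
#' Line type encodes the weight class (solid/dashed/dotted), red edges mark
#' anticorrelated pairs (negative Pearson sign).
#'
#' @param net A `gene_network`.
#' @param path Output PNG path.
#' @param width,height Image size in pixels.
#' @return `path`, invisibly.
#' @export
plot_network_png <- function(net, path, width = 1200, height = 1200) {
  stopifnot(inherits(net, "gene_network"))
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  if (nrow(net$nodes) == 0L) {
    plot.new()
    return(invisible(path))
  }
  g <- as_igraph(net)
  lty <- c(solid = 1, dashed = 2, dotted = 3)
  ecol <- ifelse(igraph::E(g)$sign == "-", "red", "grey30")
  elty <- if (igraph::ecount(g) > 0) lty[igraph::E(g)$weight_class] else NULL
  set.seed(1L) # deterministic layout
  igraph::plot.igraph(g, edge.color = ecol, edge.lty = elty,
                      edge.width = if (igraph::ecount(g) > 0) 1 + 3 * igraph::E(g)$weight else 1,
                      vertex.color = "lightsteelblue", vertex.label.color = "black")
  invisible(path)
}
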