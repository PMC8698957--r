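#' Construct an expansion list
#'
#' An expansion list is the ranked result of expanding one seed gene: for
#' every other gene, the number of skeleton runs whose input tile contained
#' it (`input_count`), the number of runs where it remained adjacent to the
#' seed (`output_count`), their ratio `f_rel` (the relative frequency, the
#' edge-strength score), and the Pearson correlation of the gene with the
#' seed across all samples (`pearson_r`, whose sign travels to network edges).
#'
#' @param seed Seed gene identifier.
#' @param records A data.frame with columns `gene`, `input_count`,
#'   `output_count`, `f_rel`, `pearson_r` and optionally `rank` (recomputed
#'   if missing); must already be sorted by descending `f_rel`.
#' @param params Named list with `n_iterations`, `tile_size`, `alpha`,
#'   `rng_seed`.
#' @return An object of class `expansion_list`.
#' @export
expansion_list <- function(seed, records, params) {
  stopifnot(is.character(seed), length(seed) == 1L, is.data.frame(records))
  needed <- c("gene", "input_count", "output_count", "f_rel", "pearson_r")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0L) {
    stop("records lack columns: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (seed %in% records$gene) stop("seed must not appear among its own records", call. = FALSE)
  if (anyDuplicated(records$gene)) stop("duplicate gene in records", call. = FALSE)
  if (any(records$output_count > records$input_count)) {
    stop("output_count exceeds input_count", call. = FALSE)
  }
  pos <- records$input_count > 0
  if (any(abs(records$f_rel[pos] -
              records$output_count[pos] / records$input_count[pos]) > 1e-12)) {
    stop("f_rel inconsistent with output_count / input_count", call. = FALSE)
  }
  if (is.unsorted(-records$f_rel)) stop("records must be ordered by descending f_rel", call. = FALSE)
  if (is.null(records$rank)) records$rank <- seq_len(nrow(records))
  if (!identical(as.integer(records$rank), seq_len(nrow(records)))) {
    stop("ranks must be 1..N without gaps", call. = FALSE)
  }
  p <- list(n_iterations = as.integer(params$n_iterations),
            tile_size = as.integer(params$tile_size),
            alpha = as.numeric(params$alpha),
            rng_seed = as.integer(params$rng_seed))
  rownames(records) <- NULL
  structure(list(seed = seed, records = records, params = p),
            class = "expansion_list")
}

#' @export
print.expansion_list <- function(x, ...) {
  cat(sprintf("Expansion list for seed '%s': %d genes (%d iterations, tile %d, alpha %g)\n",
              x$seed, nrow(x$records), x$params$n_iterations,
              x$params$tile_size, x$params$alpha))
  print(utils::head(x$records, 10L))
  if (nrow(x$records) > 10L) cat("...\n")
  invisible(x)
}

#' @export
format.expansion_list <- function(x, ...) {
  sprintf("<expansion_list seed=%s n=%d>", x$seed, nrow(x$records))
}

# serialize one list to the TSV member format used inside archives
.expansion_member_text <- function(x) {
  hdr <- c(
    sprintf("#seed=%s", x$seed),
    sprintf("#n_iterations=%d\ttile_size=%d\talpha=%.17g\trng_seed=%d",
            x$params$n_iterations, x$params$tile_size,
            x$params$alpha, x$params$rng_seed),
    paste(c("gene", "input_count", "output_count", "f_rel", "pearson_r", "rank"),
          collapse = "\t")
  )
  r <- x$records
  body <- sprintf("%s\t%d\t%d\t%.17g\t%.17g\t%d",
                  r$gene, as.integer(r$input_count), as.integer(r$output_count),
                  r$f_rel, r$pearson_r, as.integer(r$rank))
  paste0(paste(c(hdr, body), collapse = "\n"), "\n")
}

.expansion_member_parse <- function(text, member_name) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  if (length(lines) < 3L || !startsWith(lines[1L], "#seed=") ||
      !startsWith(lines[2L], "#n_iterations=")) {
    stop("archive member '", member_name,
         "' lacks the seed/params header", call. = FALSE)
  }
  seed <- sub("^#seed=", "", lines[1L])
  kv <- strsplit(sub("^#", "", lines[2L]), "\t", fixed = TRUE)[[1L]]
  kv <- strsplit(kv, "=", fixed = TRUE)
  params <- stats::setNames(lapply(kv, `[`, 2L), vapply(kv, `[`, "", 1L))
  body <- lines[-(1:3)]
  if (length(body) > 0L) {
    fields <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
    records <- data.frame(
      gene = fields[, 1L],
      input_count = as.integer(fields[, 2L]),
      output_count = as.integer(fields[, 3L]),
      f_rel = as.numeric(fields[, 4L]),
      pearson_r = as.numeric(fields[, 5L]),
      rank = as.integer(fields[, 6L]),
      stringsAsFactors = FALSE
    )
  } else {
    records <- data.frame(gene = character(), input_count = integer(),
                          output_count = integer(), f_rel = numeric(),
                          pearson_r = numeric(), rank = integer(),
                          stringsAsFactors = FALSE)
  }
  expansion_list(seed, records,
                 list(n_iterations = as.integer(params[["n_iterations"]]),
                      tile_size = as.integer(params[["tile_size"]]),
                      alpha = as.numeric(params[["alpha"]]),
                      rng_seed = as.integer(params[["rng_seed"]])))
}

#' Write expansion lists to a ZIP archive
#'
#' Each list becomes one TSV member named `<seed>.tsv` with two header lines
#' carrying the seed and the run parameters; rows keep the descending-`f_rel`
#' order. Numeric fields are written at full precision so the archive
#' round-trips exactly.
#'
#' @param lists A list of [expansion_list()] objects (or a single one).
#' @param path Output `.zip` path.
#' @return `path`, invisibly.
#' @export
write_expansion_archive <- function(lists, path) {
  if (inherits(lists, "expansion_list")) lists <- list(lists)
  if (length(lists) == 0L) stop("cannot write an empty archive", call. = FALSE)
  ok <- vapply(lists, inherits, TRUE, "expansion_list")
  if (!all(ok)) stop("all elements must be expansion_list objects", call. = FALSE)
  seeds <- vapply(lists, function(x) x$seed, "")
  if (anyDuplicated(seeds)) stop("duplicate seeds in archive", call. = FALSE)
  members <- lapply(lists, .expansion_member_text)
  names(members) <- paste0(seeds, ".tsv")
  zip_write(path, members)
  invisible(path)
}

#' Read expansion lists from a ZIP archive
#'
#' @param path Path to an archive written by [write_expansion_archive()] (or
#'   any ZIP holding members in the same TSV dialect).
#' @return A named list of [expansion_list()] objects (names are seeds).
#' @export
read_expansion_archive <- function(path) {
  members <- zip_read(path)
  members <- members[grepl("\\.tsv$", names(members))]
  if (length(members) == 0L) stop("archive contains no expansion-list members", call. = FALSE)
  out <- mapply(.expansion_member_parse, members, names(members), SIMPLIFY = FALSE)
  names(out) <- vapply(out, function(x) x$seed, "")
  out
}
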