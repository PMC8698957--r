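# case-preserving reverse complement (IUPAC letters)
.revcomp <- function(s) {
  comp <- chartr("ACGTRYSWKMBDHVNacgtryswkmbdhvn",
                 "TGCAYRSWMKVHDBNtgcayrswmkvhdbn", s)
  vapply(comp, function(x) {
    paste(rev(strsplit(x, "", fixed = TRUE)[[1L]]), collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Extract upstream promoter sequences
#'
#' For each requested gene the region immediately upstream of the annotated
#' gene start is cut from the genome: on the plus strand the `length` bases
#' before the feature start (GFF 1-based inclusive coordinates), on the minus
#' strand the reverse complement of the `length` bases after the feature end.
#' Regions are clipped at chromosome boundaries, so promoters near a contig
#' edge may be shorter than requested. Soft-masked lowercase in the genome is
#' preserved.
#'
#' @param genome_fa Path to the genome FASTA (or a named character vector of
#'   chromosome sequences).
#' @param gff Path to a GFF3 annotation (or a data.frame with columns
#'   `gene`, `chrom`, `start`, `end`, `strand`). Gene features are matched by
#'   their `ID` (falling back to `Name`) attribute.
#' @param genes Character vector of gene IDs to extract.
#' @param length Promoter length in bases (default 1000, i.e. 1-kb
#'   promoters suitable for motif discovery).
#' @return A named character vector of promoter sequences (names are gene
#'   IDs), with attribute `"coords"` describing the extracted regions.
#' @export
extract_promoters <- function(genome_fa, gff, genes, length = 1000L) {
  length <- as.integer(length)
  stopifnot(length >= 1L)
  chroms <- if (is.character(genome_fa) && !is.null(names(genome_fa)) &&
                all(nzchar(names(genome_fa)))) {
    genome_fa
  } else {
    if (!file.exists(genome_fa)) stop("genome FASTA not found: ", genome_fa, call. = FALSE)
    # BString preserves soft-masked lowercase, unlike DNAString
    ss <- Biostrings::readBStringSet(genome_fa)
    names(ss) <- sub("\\s.*$", "", names(ss))
    stats::setNames(as.character(ss), names(ss))
  }

  feats <- if (is.data.frame(gff)) gff else {
    if (!file.exists(gff)) stop("GFF file not found: ", gff, call. = FALSE)
    gr <- rtracklayer::import(gff)
    ids <- if (!is.null(gr$ID)) as.character(gr$ID) else rep(NA_character_, base::length(gr))
    nm <- if (!is.null(gr$Name)) as.character(gr$Name) else rep(NA_character_, base::length(gr))
    ids[is.na(ids)] <- nm[is.na(ids)]
    data.frame(gene = ids,
               chrom = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr),
               end = GenomicRanges::end(gr),
               strand = as.character(GenomicRanges::strand(gr)),
               stringsAsFactors = FALSE)
  }
  feats <- feats[!is.na(feats$gene), , drop = FALSE]
  feats <- feats[!duplicated(feats$gene), , drop = FALSE]

  missing_genes <- setdiff(genes, feats$gene)
  if (base::length(missing_genes) > 0L) {
    stop("gene(s) without an annotated feature: ",
         paste(missing_genes, collapse = ", "), call. = FALSE)
  }
  idx <- match(genes, feats$gene)
  out <- character(base::length(genes))
  coords <- data.frame(gene = genes, chrom = feats$chrom[idx],
                       from = NA_integer_, to = NA_integer_,
                       strand = feats$strand[idx], stringsAsFactors = FALSE)
  for (k in seq_along(genes)) {
    f <- feats[idx[k], ]
    if (!f$chrom %in% names(chroms)) {
      stop("chromosome '", f$chrom, "' absent from genome FASTA", call. = FALSE)
    }
    chrom_seq <- chroms[[f$chrom]]
    chrom_len <- nchar(chrom_seq)
    if (f$strand == "-") {
      from <- f$end + 1L
      to <- min(f$end + length, chrom_len)
      seqtxt <- if (from > to) "" else .revcomp(substr(chrom_seq, from, to))
    } else {
      from <- max(1L, f$start - length)
      to <- f$start - 1L
      seqtxt <- if (from > to) "" else substr(chrom_seq, from, to)
    }
    coords$from[k] <- from; coords$to[k] <- to
    out[k] <- seqtxt
  }
  names(out) <- genes
  attr(out, "coords") <- coords
  out
}

#' Write promoter sequences as FASTA
#'
#' One record per gene, record ID = gene ID, sequence wrapped at 60 columns.
#'
#' @param promoters Named character vector from [extract_promoters()].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_promoters_fasta <- function(promoters, path) {
  stopifnot(!is.null(names(promoters)))
  con <- file(path, "wb")
  on.exit(close(con))
  for (k in seq_along(promoters)) {
    writeLines(paste0(">", names(promoters)[k]), con)
    s <- promoters[[k]]
    if (nzchar(s)) {
      starts <- seq(1L, nchar(s), by = 60L)
      writeLines(substring(s, starts, pmin(starts + 59L, nchar(s))), con)
    }
  }
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' Thin wrapper over [Biostrings::readBStringSet()] (case preserved).
#'
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  names(ss) <- sub("\\s.*$", "", names(ss))
  stats::setNames(as.character(ss), names(ss))
}
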