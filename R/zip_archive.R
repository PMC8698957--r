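# Minimal ZIP container support for expansion-list archives.
#
# Members are written with the STORE method (no compression): the archives are
# small TSV files and storing keeps the writer dependency-free and the output
# deterministic byte-for-byte. Reading goes through utils::unzip()'s built-in
# engine, so archives produced elsewhere (deflated members included) can be
# read back.

# CRC-32 (reflected, poly 0xEDB88320) lookup table, built once at load time.
.crc32_table <- local({
  poly <- -306674912L # 0xEDB88320 as a signed 32-bit integer
  tab <- integer(256L)
  for (n in 0:255) {
    c <- n
    for (k in 1:8) {
      c <- if (bitwAnd(c, 1L) == 1L) {
        bitwXor(bitwShiftR(c, 1L), poly)
      } else {
        bitwShiftR(c, 1L)
      }
    }
    tab[n + 1L] <- c
  }
  tab
})

.crc32 <- function(bytes) {
  crc <- -1L # 0xFFFFFFFF
  b <- as.integer(bytes)
  for (i in seq_along(b)) {
    idx <- bitwAnd(bitwXor(crc, b[i]), 255L)
    crc <- bitwXor(bitwShiftR(crc, 8L), .crc32_table[idx + 1L])
  }
  bitwXor(crc, -1L)
}

# little-endian raw encoding of a nonnegative number (crc may arrive signed)
.le_bytes <- function(x, width) {
  x <- as.numeric(x)
  if (x < 0) x <- x + 2^32
  out <- raw(width)
  for (i in seq_len(width)) {
    out[i] <- as.raw(x %% 256)
    x <- x %/% 256
  }
  out
}

# Fixed DOS timestamp (1980-01-01 00:00) keeps archives byte-identical across
# runs; provenance lives in the member headers, not in file mtimes.
.dos_date <- .le_bytes(33L, 2L)
.dos_time <- .le_bytes(0L, 2L)

#' @noRd
zip_write <- function(path, members) {
  stopifnot(is.list(members), length(members) > 0L,
            !is.null(names(members)), all(nzchar(names(members))))
  con <- file(path, "wb")
  on.exit(close(con))
  offsets <- integer(length(members))
  crcs <- integer(length(members))
  sizes <- integer(length(members))
  pos <- 0L
  for (k in seq_along(members)) {
    name_raw <- charToRaw(names(members)[k])
    data <- if (is.raw(members[[k]])) members[[k]] else charToRaw(members[[k]])
    crcs[k] <- .crc32(data)
    sizes[k] <- length(data)
    offsets[k] <- pos
    header <- c(
      as.raw(c(0x50, 0x4b, 0x03, 0x04)),
      .le_bytes(20L, 2L),            # version needed
      .le_bytes(0L, 2L),             # flags
      .le_bytes(0L, 2L),             # method: store
      .dos_time, .dos_date,
      .le_bytes(crcs[k], 4L),
      .le_bytes(sizes[k], 4L),       # compressed == uncompressed
      .le_bytes(sizes[k], 4L),
      .le_bytes(length(name_raw), 2L),
      .le_bytes(0L, 2L)              # extra length
    )
    writeBin(header, con)
    writeBin(name_raw, con)
    writeBin(data, con)
    pos <- pos + length(header) + length(name_raw) + length(data)
  }
  cd_start <- pos
  cd_size <- 0L
  for (k in seq_along(members)) {
    name_raw <- charToRaw(names(members)[k])
    entry <- c(
      as.raw(c(0x50, 0x4b, 0x01, 0x02)),
      .le_bytes(20L, 2L),            # version made by
      .le_bytes(20L, 2L),            # version needed
      .le_bytes(0L, 2L),
      .le_bytes(0L, 2L),
      .dos_time, .dos_date,
      .le_bytes(crcs[k], 4L),
      .le_bytes(sizes[k], 4L),
      .le_bytes(sizes[k], 4L),
      .le_bytes(length(name_raw), 2L),
      .le_bytes(0L, 2L),             # extra
      .le_bytes(0L, 2L),             # comment
      .le_bytes(0L, 2L),             # disk number
      .le_bytes(0L, 2L),             # internal attrs
      .le_bytes(0L, 4L),             # external attrs
      .le_bytes(offsets[k], 4L)
    )
    writeBin(entry, con)
    writeBin(name_raw, con)
    cd_size <- cd_size + length(entry) + length(name_raw)
  }
  eocd <- c(
    as.raw(c(0x50, 0x4b, 0x05, 0x06)),
    .le_bytes(0L, 2L), .le_bytes(0L, 2L),
    .le_bytes(length(members), 2L), .le_bytes(length(members), 2L),
    .le_bytes(cd_size, 4L),
    .le_bytes(cd_start, 4L),
    .le_bytes(0L, 2L)
  )
  writeBin(eocd, con)
  invisible(path)
}

#' @noRd
zip_read <- function(path) {
  if (!file.exists(path)) stop("archive not found: ", path, call. = FALSE)
  exdir <- tempfile("zipread")
  dir.create(exdir)
  on.exit(unlink(exdir, recursive = TRUE))
  files <- utils::unzip(path, exdir = exdir, unzip = "internal")
  out <- lapply(files, function(f) {
    readChar(f, file.size(f), useBytes = TRUE)
  })
  names(out) <- substring(files, nchar(exdir) + 2L)
  out
}
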