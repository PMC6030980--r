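# CRC-32 (IEEE 802.3, polynomial 0xEDB88320), table-driven.
.crc32_table <- local({
  tab <- integer(256)
  for (n in 0:255) {
    c <- n
    for (k in 1:8) {
      c <- if (bitwAnd(c, 1L) != 0L) {
        bitwXor(bitwShiftR(c, 1L), -306674912L) # 0xEDB88320 as signed int
      } else bitwShiftR(c, 1L)
    }
    tab[n + 1L] <- c
  }
  tab
})

.crc32 <- function(bytes) {
  c <- -1L # 0xFFFFFFFF
  for (b in as.integer(bytes)) {
    c <- bitwXor(bitwShiftR(c, 8L),
                 .crc32_table[bitwAnd(bitwXor(c, b), 255L) + 1L])
  }
  bitwXor(c, -1L)
}

.le_bytes <- function(x, n) {
  # little-endian unsigned encoding of x (given as signed 32-bit ok)
  out <- raw(n)
  v <- x
  for (i in seq_len(n)) {
    out[i] <- as.raw(bitwAnd(v, 255L))
    v <- bitwShiftR(v, 8L)
  }
  out
}

#' Write files into a ZIP archive (stored, uncompressed)
#'
#' Minimal ZIP writer used to build compressed-input fixtures: entries are
#' stored without compression, with correct CRC-32 checksums, readable by
#' any standard unzip implementation (including [utils::unzip()]).
#'
#' @param files paths of files to archive (stored under their base names).
#' @param zipfile output archive path.
#' @return `zipfile`, invisibly.
#' @export
write_zip <- function(files, zipfile) {
  con <- file(zipfile, "wb")
  on.exit(close(con))
  central <- list()
  offset <- 0L
  for (f in files) {
    data <- readBin(f, "raw", file.size(f))
    name <- charToRaw(basename(f))
    crc <- .crc32(data)
    local_header <- c(
      as.raw(c(0x50, 0x4b, 0x03, 0x04)), # local file header signature
      .le_bytes(20L, 2), .le_bytes(0L, 2), .le_bytes(0L, 2),
      .le_bytes(0L, 2), .le_bytes(0L, 2), # version, flags, method=0, time, date
      .le_bytes(crc, 4),
      .le_bytes(length(data), 4), .le_bytes(length(data), 4),
      .le_bytes(length(name), 2), .le_bytes(0L, 2)
    )
    writeBin(c(local_header, name, data), con)
    central[[length(central) + 1L]] <- list(
      name = name, crc = crc, size = length(data), offset = offset)
    offset <- offset + length(local_header) + length(name) + length(data)
  }
  cd_start <- offset
  cd_size <- 0L
  for (e in central) {
    rec <- c(
      as.raw(c(0x50, 0x4b, 0x01, 0x02)), # central directory signature
      .le_bytes(20L, 2), .le_bytes(20L, 2), .le_bytes(0L, 2),
      .le_bytes(0L, 2), .le_bytes(0L, 2), .le_bytes(0L, 2),
      .le_bytes(e$crc, 4), .le_bytes(e$size, 4), .le_bytes(e$size, 4),
      .le_bytes(length(e$name), 2), .le_bytes(0L, 2), .le_bytes(0L, 2),
      .le_bytes(0L, 2), .le_bytes(0L, 2), .le_bytes(0L, 4),
      .le_bytes(e$offset, 4)
    )
    writeBin(c(rec, e$name), con)
    cd_size <- cd_size + length(rec) + length(e$name)
  }
  eocd <- c(
    as.raw(c(0x50, 0x4b, 0x05, 0x06)), # end of central directory
    .le_bytes(0L, 2), .le_bytes(0L, 2),
    .le_bytes(length(central), 2), .le_bytes(length(central), 2),
    .le_bytes(cd_size, 4), .le_bytes(cd_start, 4), .le_bytes(0L, 2)
  )
  writeBin(eocd, con)
  invisible(zipfile)
}
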