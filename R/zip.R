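# Minimal zip container support. Reading goes through utils::unzip; writing
# assembles a single-entry archive (deflate, method 8) with CRC32 and raw
# deflate stream provided by zlib through the compiled helpers. Timestamps
# are fixed so identical content yields byte-identical archives.

le_bytes <- function(x, width) {
  out <- raw(width)
  for (i in seq_len(width)) {
    out[i] <- as.raw(x %% 256)
    x <- x %/% 256
  }
  out
}

zip_write_single <- function(path, filename, content) {
  if (is.character(content)) content <- charToRaw(paste(content, collapse = "\n"))
  stopifnot(is.raw(content))
  crc <- .Call(C_crc32, content)
  deflated <- .Call(C_deflate_raw, content, 6L)
  fname <- charToRaw(filename)
  usize <- length(content)
  csize <- length(deflated)

  local_header <- c(
    charToRaw("PK\x03\x04"),
    le_bytes(20, 2),          # version needed
    le_bytes(0, 2),           # flags
    le_bytes(8, 2),           # method: deflate
    le_bytes(0, 2), le_bytes(0x21, 2),   # fixed mod time/date
    le_bytes(crc, 4),
    le_bytes(csize, 4), le_bytes(usize, 4),
    le_bytes(length(fname), 2), le_bytes(0, 2),
    fname)
  central <- c(
    charToRaw("PK\x01\x02"),
    le_bytes(20, 2), le_bytes(20, 2),
    le_bytes(0, 2), le_bytes(8, 2),
    le_bytes(0, 2), le_bytes(0x21, 2),
    le_bytes(crc, 4),
    le_bytes(csize, 4), le_bytes(usize, 4),
    le_bytes(length(fname), 2), le_bytes(0, 2), le_bytes(0, 2),
    le_bytes(0, 2), le_bytes(0, 2), le_bytes(0, 4),
    le_bytes(0, 4),           # local header offset
    fname)
  eocd <- c(
    charToRaw("PK\x05\x06"),
    le_bytes(0, 2), le_bytes(0, 2),
    le_bytes(1, 2), le_bytes(1, 2),
    le_bytes(length(central), 4),
    le_bytes(length(local_header) + csize, 4),
    le_bytes(0, 2))

  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop("I/O error: cannot write '", path,
                                           "': ", conditionMessage(e)))
  on.exit(close(con))
  writeBin(c(local_header, deflated, central, eocd), con)
  invisible(path)
}

# Extract one file from a zip archive into a temporary directory and return
# its path. Raises a format error when `path` is not a zip archive.
zip_read_entry <- function(path, pattern = "\\.xml$") {
  if (!file.exists(path)) stop("I/O error: file not found: ", path)
  magic <- readBin(path, "raw", n = 4)
  if (length(magic) < 4 || !identical(magic[1:2], charToRaw("PK")))
    stop("format error: '", path, "' is not a zip archive")
  listing <- tryCatch(unzip(path, list = TRUE),
                      error = function(e) stop("format error: cannot read zip ",
                                               "archive '", path, "'"))
  entry <- listing$Name[grepl(pattern, listing$Name)]
  if (!length(entry))
    stop("structural error: archive contains no XML document")
  exdir <- tempfile("rdml")
  dir.create(exdir)
  unzip(path, files = entry[1], exdir = exdir)
  file.path(exdir, entry[1])
}
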