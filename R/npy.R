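# Minimal NumPy .npy / .npz codec.
#
# NPZ is a ZIP container of .npy members.  Reading goes through
# utils::unzip (internal method, no external binary needed).  Writing
# emits a ZIP with deflate-compressed members; both the deflate stream
# and the CRC32 checksum ZIP requires are obtained from memCompress()'s
# gzip wrapping (gzip = 10-byte header + raw deflate + CRC32 + size).

npyDescr <- function(arr) {
  if (is.integer(attr(arr, "npyUint8"))) return("|u1")
  "<f8"
}

# serialize an R array to .npy bytes; uint8 = TRUE writes |u1
npySerialize <- function(arr, uint8 = FALSE) {
  shape <- dim(arr)
  if (is.null(shape)) shape <- length(arr)
  descr <- if (uint8) "|u1" else "<f8"
  header <- sprintf("{'descr': '%s', 'fortran_order': False, 'shape': (%s), }",
                    descr,
                    if (length(shape) == 1L) sprintf("%d,", shape)
                    else paste(shape, collapse = ", "))
  # pad so that magic(6)+ver(2)+hlen(2)+header is a multiple of 64
  base <- 10L + nchar(header) + 1L
  pad <- (64L - base %% 64L) %% 64L
  header <- paste0(header, strrep(" ", pad), "\n")
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x93, 0x4e, 0x55, 0x4d, 0x50, 0x59, 0x01, 0x00)), con)
  writeBin(as.integer(nchar(header)), con, size = 2, endian = "little")
  writeChar(header, con, eos = NULL)
  # C order: last axis fastest; R arrays are column-major, so reverse axes
  vals <- if (length(shape) > 1L) as.vector(aperm(arr, rev(seq_along(shape))))
          else as.vector(arr)
  if (uint8) writeBin(as.raw(as.integer(round(vals))), con)
  else writeBin(as.numeric(vals), con, size = 8, endian = "little")
  rawConnectionValue(con)
}

npyParse <- function(bytes) {
  if (length(bytes) < 10L ||
      !identical(bytes[1:6], as.raw(c(0x93, 0x4e, 0x55, 0x4d, 0x50, 0x59))))
    stop("not an NPY file (bad magic)")
  major <- as.integer(bytes[7])
  if (major == 1L) {
    hlen <- as.integer(bytes[9]) + 256L * as.integer(bytes[10])
    off <- 10L
  } else {
    hlen <- sum(as.integer(bytes[9:12]) * 256^(0:3))
    off <- 12L
  }
  header <- rawToChar(bytes[(off + 1L):(off + hlen)])
  descr <- sub(".*'descr':\\s*'([^']+)'.*", "\\1", header)
  fortran <- grepl("'fortran_order':\\s*True", header)
  shapeStr <- sub(".*'shape':\\s*\\(([^)]*)\\).*", "\\1", header)
  shape <- as.integer(strsplit(gsub("\\s|,$", "", shapeStr), ",")[[1]])
  data <- bytes[(off + hlen + 1L):length(bytes)]
  n <- prod(shape)
  vals <- switch(descr,
    "|u1" = as.numeric(as.integer(data[seq_len(n)])),
    "<f8" = readBin(data, "double", n, size = 8, endian = "little"),
    "<f4" = readBin(data, "double", n, size = 4, endian = "little"),
    "<i8" = readBin(data, "integer", n, size = 8, endian = "little"),
    "<i4" = readBin(data, "integer", n, size = 4, endian = "little"),
    "<i2" = readBin(data, "integer", n, size = 2, endian = "little"),
    "|i1" = readBin(data, "integer", n, size = 1, signed = TRUE),
    stop("unsupported NPY dtype: ", descr)
  )
  if (length(shape) > 1L) {
    arr <- if (fortran) array(vals, shape)
           else aperm(array(vals, rev(shape)), rev(seq_along(shape)))
  } else arr <- vals
  attr(arr, "npyDescr") <- descr
  arr
}

# raw deflate stream (zlib stream minus 2-byte header and 4-byte
# Adler32 trailer) plus the CRC32 checksum ZIP headers require
deflateWithCrc <- function(bytes) {
  zs <- memCompress(bytes, type = "gzip")  # R emits a zlib stream
  n <- length(zs)
  stopifnot(n > 6L, zs[1] == as.raw(0x78))
  crc <- .Call(ada3d_crc32, bytes)
  list(deflate = zs[3:(n - 4L)], crc = u32le(crc),
       size = length(bytes))
}

u16le <- function(x) as.raw(c(x %% 256L, x %/% 256L %% 256L))
u32le <- function(x) as.raw(c(x %% 256, floor(x / 256) %% 256,
                              floor(x / 65536) %% 256,
                              floor(x / 16777216) %% 256))

# write a ZIP archive of raw members (deflate, fixed timestamp so
# reruns are byte-identical)
zipWrite <- function(path, members) {
  locals <- list(); centrals <- list(); offset <- 0
  for (name in names(members)) {
    d <- deflateWithCrc(members[[name]])
    nm <- charToRaw(name)
    local <- c(u32le(0x04034b50), u16le(20L), u16le(0L), u16le(8L),
               u16le(0L), u16le(0x21L),      # fixed time/date
               d$crc, u32le(length(d$deflate)), u32le(d$size),
               u16le(length(nm)), u16le(0L), nm, d$deflate)
    central <- c(u32le(0x02014b50), u16le(20L), u16le(20L), u16le(0L),
                 u16le(8L), u16le(0L), u16le(0x21L),
                 d$crc, u32le(length(d$deflate)), u32le(d$size),
                 u16le(length(nm)), u16le(0L), u16le(0L), u16le(0L),
                 u16le(0L), u32le(0L), u32le(offset), nm)
    locals[[name]] <- local
    centrals[[name]] <- central
    offset <- offset + length(local)
  }
  cd <- unlist(centrals, use.names = FALSE)
  eocd <- c(u32le(0x06054b50), u16le(0L), u16le(0L),
            u16le(length(members)), u16le(length(members)),
            u32le(length(cd)), u32le(offset), u16le(0L))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(unlist(locals, use.names = FALSE), cd, eocd), con)
  invisible(path)
}

zipReadMembers <- function(path) {
  exdir <- tempfile("npz")
  dir.create(exdir)
  on.exit(unlink(exdir, recursive = TRUE))
  files <- utils::unzip(path, exdir = exdir)
  out <- lapply(files, function(f) readBin(f, "raw", file.info(f)$size))
  names(out) <- basename(files)
  out
}
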