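## Plain-file interfaces: 16-bit grayscale TIFF frames, 8-bit grayscale
## PNG masks, a restricted YAML subset for configs, and uncompressed AVI
## for monitoring videos. Writers emit a fixed, minimal form of each
## format; the bundled readers support exactly that form (sufficient for
## round-tripping everything this package writes).

u16le <- function(v) as.raw(rbind(v %% 256, (v %/% 256) %% 256))
u32le <- function(v) as.raw(rbind(v %% 256, (v %/% 256) %% 256,
                                  (v %/% 65536) %% 256,
                                  (v %/% 16777216) %% 256))
u32be <- function(v) rev(u32le(v))
rd_u32le <- function(raw, off) sum(as.integer(raw[off + 0:3]) * 256^(0:3))
rd_u16le <- function(raw, off) sum(as.integer(raw[off + 0:1]) * 256^(0:1))

#' Write / read a 16-bit grayscale TIFF
#'
#' Intensities in `[0, 1]` are quantised to 16 bits. The writer emits a
#' single-strip, uncompressed, little-endian baseline TIFF; the reader
#' accepts that layout.
#'
#' @param img numeric matrix with values in `[0, 1]` (or a
#'   [new_frame()]).
#' @param path file path.
#' @return `read_tiff_gray16` returns a numeric matrix in `[0, 1]`.
#' @export
write_tiff_gray16 <- function(img, path) {
  img <- frame_pixels(img)
  v <- as.integer(round(pmin(pmax(img, 0), 1) * 65535))
  nr <- nrow(img); nc <- ncol(img)
  data <- u16le(as.vector(t(matrix(v, nr, nc))))  # row-major sample order
  data_off <- 8L
  ifd_off <- data_off + length(data)
  tag <- function(id, type, count, value)
    c(u16le(id), u16le(type), u32le(count), u32le(value))
  tags <- c(
    tag(256, 3, 1, nc),                 # ImageWidth
    tag(257, 3, 1, nr),                 # ImageLength
    tag(258, 3, 1, 16),                 # BitsPerSample
    tag(259, 3, 1, 1),                  # Compression = none
    tag(262, 3, 1, 1),                  # Photometric = BlackIsZero
    tag(273, 4, 1, data_off),           # StripOffsets
    tag(277, 3, 1, 1),                  # SamplesPerPixel
    tag(278, 3, 1, nr),                 # RowsPerStrip
    tag(279, 4, 1, length(data)))       # StripByteCounts
  ifd <- c(u16le(9), tags, u32le(0))
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(c(as.raw(c(0x49, 0x49)), u16le(42), u32le(ifd_off), data, ifd),
           con)
  invisible(path)
}

#' @rdname write_tiff_gray16
#' @export
read_tiff_gray16 <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (!identical(as.integer(raw[1:2]), c(0x49L, 0x49L)))
    stop("not a little-endian TIFF")
  ifd <- rd_u32le(raw, 5L)
  n <- rd_u16le(raw, ifd + 1L)
  tags <- list()
  for (i in seq_len(n)) {
    off <- ifd + 2L + (i - 1L) * 12L
    tags[[as.character(rd_u16le(raw, off + 1L))]] <- rd_u32le(raw, off + 9L)
  }
  need <- function(k) tags[[as.character(k)]] %||%
    stop("missing TIFF tag ", k)
  if ((tags[["259"]] %||% 1) != 1) stop("unsupported TIFF compression")
  if ((tags[["258"]] %||% 0) != 16) stop("expected 16-bit samples")
  nc <- need(256); nr <- need(257)
  off <- need(273)
  bytes <- raw[off + seq_len(2L * nr * nc)]
  lo <- as.integer(bytes[c(TRUE, FALSE)])
  hi <- as.integer(bytes[c(FALSE, TRUE)])
  matrix((lo + 256 * hi) / 65535, nr, nc, byrow = TRUE)
}

png_chunk <- function(type, payload) {
  body <- c(charToRaw(type), payload)
  c(u32be(length(payload)), body, u32be(.crc32(body, 0)))
}

#' Write / read an 8-bit grayscale PNG
#'
#' Used for binary spheroid masks (0/255) and other small 8-bit images.
#' The writer emits a non-interlaced grayscale PNG with filter type 0 on
#' every scanline; the reader accepts exactly that layout.
#'
#' @param img logical or numeric matrix; logical is written as 0/255,
#'   numeric in `[0, 1]` is quantised to 8 bits.
#' @param path file path.
#' @return `read_png_gray8` returns a numeric matrix in `[0, 1]` (use
#'   `> 0.5` to recover a mask).
#' @export
write_png_gray8 <- function(img, path) {
  if (inherits(img, "spheromon_mask")) img <- img$pixels
  if (is.logical(img)) img <- img * 1
  v <- as.integer(round(pmin(pmax(img, 0), 1) * 255))
  nr <- nrow(img); nc <- ncol(img)
  rows <- matrix(v, nr, nc)
  scan <- as.raw(rbind(0L, t(rows)))  # filter byte 0 before each row
  ihdr <- c(u32be(nc), u32be(nr), as.raw(c(8, 0, 0, 0, 0)))
  out <- c(as.raw(c(0x89, 0x50, 0x4E, 0x47, 0x0D, 0x0A, 0x1A, 0x0A)),
           png_chunk("IHDR", ihdr),
           png_chunk("IDAT", memCompress(scan, "gzip")),
           png_chunk("IEND", raw(0)))
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(out, con)
  invisible(path)
}

#' @rdname write_png_gray8
#' @export
read_png_gray8 <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (!identical(as.integer(raw[1:4]), c(0x89L, 0x50L, 0x4EL, 0x47L)))
    stop("not a PNG")
  pos <- 9L
  nc <- nr <- NULL
  idat <- raw(0)
  while (pos + 7L <= length(raw)) {
    len <- sum(as.integer(raw[pos + 0:3]) * 256^(3:0))
    type <- rawToChar(raw[pos + 4:7])
    data <- if (len > 0) raw[pos + 7L + seq_len(len)] else raw(0)
    if (type == "IHDR") {
      nc <- sum(as.integer(data[1:4]) * 256^(3:0))
      nr <- sum(as.integer(data[5:8]) * 256^(3:0))
      if (as.integer(data[9]) != 8L || as.integer(data[10]) != 0L)
        stop("unsupported PNG layout (need 8-bit grayscale)")
    } else if (type == "IDAT") idat <- c(idat, data)
    else if (type == "IEND") break
    pos <- pos + 12L + len
  }
  scan <- memDecompress(idat, "gzip")
  m <- matrix(as.integer(scan), nc + 1L, nr)  # each column = one scanline
  if (any(m[1, ] != 0L)) stop("unsupported PNG filter")
  t(m[-1, , drop = FALSE]) / 255
}

## ---- restricted YAML subset -----------------------------------------

#' Write / read a configuration file (YAML subset)
#'
#' Serialises nested named lists of scalars and flat vectors using a
#' restricted YAML subset: two-space-indented block maps, flow sequences
#' (`[a, b, c]`) for vectors, and plain scalars (numbers, `true`/`false`,
#' strings). Round-trips every configuration object this package produces.
#'
#' @param x named list (possibly nested).
#' @param path file path.
#' @return `read_yaml_config` returns the parsed list.
#' @export
write_yaml_config <- function(x, path) {
  lines <- yaml_emit(x, 0L)
  writeLines(lines, path)
  invisible(path)
}

yaml_scalar <- function(v) {
  if (is.logical(v)) return(ifelse(v, "true", "false"))
  if (is.numeric(v)) return(format(v, digits = 15, scientific = FALSE,
                                   trim = TRUE))
  as.character(v)
}

yaml_emit <- function(x, depth) {
  pad <- strrep("  ", depth)
  out <- character(0)
  for (k in names(x)) {
    v <- x[[k]]
    if (is.list(v)) {
      out <- c(out, paste0(pad, k, ":"), yaml_emit(v, depth + 1L))
    } else if (length(v) > 1L) {
      out <- c(out, paste0(pad, k, ": [",
                           paste(vapply(v, yaml_scalar, ""), collapse = ", "),
                           "]"))
    } else {
      out <- c(out, paste0(pad, k, ": ", yaml_scalar(v)))
    }
  }
  out
}

#' @rdname write_yaml_config
#' @export
read_yaml_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parse_block <- function(idx, depth) {
    out <- list()
    i <- idx
    while (i <= length(lines)) {
      ln <- lines[i]
      ind <- nchar(sub("\\S.*$", "", ln)) %/% 2L
      if (ind < depth) break
      if (ind > depth) stop("bad indentation at line ", i)
      m <- regmatches(ln, regexec("^\\s*([^:]+):\\s*(.*)$", ln))[[1]]
      if (length(m) != 3L) stop("cannot parse line: ", ln)
      key <- m[2]; val <- m[3]
      if (val == "") {
        sub <- parse_block(i + 1L, depth + 1L)
        out[[key]] <- sub$value
        i <- sub$next_index
      } else {
        out[[key]] <- yaml_parse_scalar(val)
        i <- i + 1L
      }
    }
    list(value = out, next_index = i)
  }
  parse_block(1L, 0L)$value
}

yaml_parse_scalar <- function(s) {
  s <- trimws(s)
  if (grepl("^\\[.*\\]$", s)) {
    parts <- trimws(strsplit(substr(s, 2, nchar(s) - 1L), ",")[[1]])
    vals <- lapply(parts, yaml_parse_scalar)
    return(unlist(vals, use.names = FALSE))
  }
  if (s %in% c("true", "false")) return(s == "true")
  if (grepl("^-?(\\d+\\.?\\d*|\\.\\d+)([eE][+-]?\\d+)?$", s))
    return(as.numeric(s))
  if (s == "inf" || s == ".inf") return(Inf)
  s
}
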