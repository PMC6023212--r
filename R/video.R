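## Monitoring-video export: uncompressed 24-bit AVI (RIFF 'DIB ' frames)
## with per-spheroid feature annotations stamped from a small digit font.

# 3x5 bitmaps for digits, '.', '-' and space; rows top to bottom
.font3x5 <- list(
  "0" = c(7,5,5,5,7), "1" = c(2,6,2,2,7), "2" = c(7,1,7,4,7),
  "3" = c(7,1,7,1,7), "4" = c(5,5,7,1,1), "5" = c(7,4,7,1,7),
  "6" = c(7,4,7,5,7), "7" = c(7,1,2,2,2), "8" = c(7,5,7,5,7),
  "9" = c(7,5,7,1,7), "." = c(0,0,0,0,2), "-" = c(0,0,7,0,0),
  " " = c(0,0,0,0,0))

#' Stamp a text label into an image
#'
#' Draws digits (plus `.`, `-`, space) with a 3x5 bitmap font at integer
#' scale; used to annotate overlay frames with feature values.
#'
#' @param img numeric matrix or `rows x cols x 3` array.
#' @param text label text (characters outside the font map to space).
#' @param x,y top-left position, 1-based pixels.
#' @param scale integer magnification of the 3x5 glyphs.
#' @param value intensity (or RGB triple) of the glyph pixels.
#' @return The annotated image.
#' @export
draw_label <- function(img, text, x, y, scale = 2L, value = 0) {
  chars <- strsplit(text, "")[[1]]
  is3d <- length(dim(img)) == 3L
  nr <- dim(img)[1]; nc <- dim(img)[2]
  if (is3d && length(value) == 1L) value <- rep(value, 3)
  cx <- x
  for (ch in chars) {
    glyph <- .font3x5[[ch]] %||% .font3x5[[" "]]
    for (gr in 1:5) for (gc in 1:3) {
      if (bitwAnd(glyph[gr], bitwShiftL(1L, 3L - gc)) == 0L) next
      rs <- y + (gr - 1L) * scale + seq_len(scale) - 1L
      cs <- cx + (gc - 1L) * scale + seq_len(scale) - 1L
      rs <- rs[rs >= 1 & rs <= nr]; cs <- cs[cs >= 1 & cs <= nc]
      if (!length(rs) || !length(cs)) next
      if (is3d) for (k in 1:3) img[rs, cs, k] <- value[k]
      else img[rs, cs] <- value[1]
    }
    cx <- cx + 4L * scale
  }
  img
}

#' Export frames as an uncompressed AVI video
#'
#' Writes the given frames (grayscale matrices or RGB arrays with values
#' in `[0, 1]`) as a bottom-up, 24-bit uncompressed AVI at the requested
#' frame rate (the monitoring-video convention is 5 frames per second).
#'
#' @param frames list of numeric matrices or `rows x cols x 3` arrays, all
#'   of identical size.
#' @param path output file path (`.avi`).
#' @param fps frames per second.
#' @return The path, invisibly.
#' @export
write_avi <- function(frames, path, fps = 5) {
  if (!length(frames)) stop("no frames to export")
  d1 <- dim(frames[[1]])
  nr <- d1[1]; nc <- d1[2]
  stride <- ceiling(nc * 3 / 4) * 4
  frame_bytes <- stride * nr
  enc <- function(img) {
    if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
    v <- array(as.integer(round(pmin(pmax(img, 0), 1) * 255)), dim(img))
    # bottom-up rows, BGR sample order, rows padded to 4 bytes
    out <- raw(frame_bytes)
    row_raw <- vapply(seq_len(nr), function(r) {
      rr <- nr - r + 1L
      px <- rbind(v[rr, , 3], v[rr, , 2], v[rr, , 1])
      row <- raw(stride)
      row[seq_len(3L * nc)] <- as.raw(px)
      row
    }, raw(stride))
    as.raw(row_raw)
  }
  n <- length(frames)
  strf <- c(u32le(40), u32le(nc), u32le(nr), u16le(1), u16le(24),
            u32le(0), u32le(frame_bytes), u32le(0), u32le(0), u32le(0),
            u32le(0))
  strh <- c(charToRaw("vids"), charToRaw("DIB "), u32le(0), u16le(0),
            u16le(0), u32le(0), u32le(1), u32le(fps), u32le(0), u32le(n),
            u32le(frame_bytes), u32le(0), u32le(0),
            u16le(0), u16le(0), u16le(nc), u16le(nr))
  avih <- c(u32le(round(1e6 / fps)), u32le(frame_bytes * fps), u32le(0),
            u32le(16), u32le(n), u32le(0), u32le(1), u32le(frame_bytes),
            u32le(nc), u32le(nr), u32le(0), u32le(0), u32le(0), u32le(0))
  chunk <- function(id, payload) c(charToRaw(id), u32le(length(payload)),
                                   payload,
                                   if (length(payload) %% 2) raw(1))
  lst <- function(type, payload) chunk("LIST", c(charToRaw(type), payload))
  strl <- lst("strl", c(chunk("strh", strh), chunk("strf", strf)))
  hdrl <- lst("hdrl", c(chunk("avih", avih), strl))
  movi_frames <- lapply(frames, function(f) chunk("00db", enc(f)))
  movi <- lst("movi", do.call(c, movi_frames))
  # idx1: one entry per frame
  offs <- cumsum(c(4, head(vapply(movi_frames, length, 0L), -1L)))
  idx <- do.call(c, lapply(seq_len(n), function(i)
    c(charToRaw("00db"), u32le(16), u32le(offs[i]), u32le(frame_bytes))))
  riff <- chunk("RIFF", c(charToRaw("AVI "), hdrl, movi,
                          chunk("idx1", idx)))
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(riff, con)
  invisible(path)
}

#' Read back an AVI written by [write_avi()]
#'
#' Minimal parser for the writer's fixed layout; used to verify exports.
#'
#' @param path file path.
#' @return A list with `fps`, `n_frames`, `width`, `height` and `frames`
#'   (list of RGB arrays in `[0, 1]`).
#' @export
read_avi <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  find4 <- function(tag, from = 1L) {
    t <- charToRaw(tag)
    for (i in from:(length(raw) - 3L))
      if (raw[i] == t[1] && raw[i + 1L] == t[2] && raw[i + 2L] == t[3] &&
          raw[i + 3L] == t[4]) return(i)
    stop("tag not found: ", tag)
  }
  av <- find4("avih") + 8L
  usec <- rd_u32le(raw, av)
  n <- rd_u32le(raw, av + 16L)
  w <- rd_u32le(raw, av + 32L)
  h <- rd_u32le(raw, av + 36L)
  stride <- ceiling(w * 3 / 4) * 4
  frames <- list()
  pos <- find4("movi") + 4L
  for (i in seq_len(n)) {
    pos <- find4("00db", pos)
    len <- rd_u32le(raw, pos + 4L)
    data <- raw[pos + 7L + seq_len(len)]
    arr <- array(0, c(h, w, 3))
    for (r in seq_len(h)) {
      row <- as.integer(data[(r - 1L) * stride + seq_len(3L * w)])
      rr <- h - r + 1L
      arr[rr, , 3] <- row[c(TRUE, FALSE, FALSE)]
      arr[rr, , 2] <- row[c(FALSE, TRUE, FALSE)]
      arr[rr, , 1] <- row[c(FALSE, FALSE, TRUE)]
    }
    frames[[i]] <- arr / 255
    pos <- pos + 8L + len
  }
  list(fps = 1e6 / usec, n_frames = n, width = w, height = h,
       frames = frames)
}
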