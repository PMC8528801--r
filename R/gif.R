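# Minimal animated GIF89a writer.
#
# Frames are quantized to a fixed 6x6x6 colour cube (216 colours) and the
# pixel stream is emitted as fixed-width 9-bit LZW literal codes with a
# clear code every 254 literals, so the decoder's string table never
# forces a width change. Larger files than a true LZW compressor, but
# fully self-contained and deterministic.

u16 <- function(x) as.raw(c(bitwAnd(x, 255L), bitwShiftR(x, 8L)))

gif_palette <- function() {
  lv <- as.integer(round(seq(0, 255, length.out = 6)))
  cube <- expand.grid(b = lv, g = lv, r = lv)  # index = r*36 + g*6 + b
  pal <- rbind(cube$r, cube$g, cube$b)
  pal <- cbind(pal, matrix(0L, 3, 256 - ncol(pal)))
  as.raw(as.vector(pal))
}

# map an h x w x 3 array in [0,1] to cube indices (row-major pixel order)
quantize_frame <- function(img) {
  if (length(dim(img)) == 3 && dim(img)[3] >= 3) {
    r <- img[, , 1]; g <- img[, , 2]; b <- img[, , 3]
  } else {
    r <- g <- b <- img[, , 1]
  }
  idx <- round(r * 5) * 36L + round(g * 5) * 6L + round(b * 5)
  # GIF wants row-major (scanline) order; R matrices are column-major
  as.integer(t(idx))
}

# pack 9-bit codes LSB-first into bytes
pack_codes <- function(codes) {
  n <- length(codes)
  bits <- matrix(0L, nrow = 9, ncol = n)
  for (k in 0:8) bits[k + 1, ] <- bitwAnd(bitwShiftR(codes, k), 1L)
  v <- as.vector(bits)
  pad <- (8 - length(v) %% 8) %% 8
  if (pad) v <- c(v, integer(pad))
  m <- matrix(v, nrow = 8)
  as.raw(colSums(m * 2L^(0:7)))
}

CLEAR_CODE <- 256L
EOI_CODE <- 257L

frame_code_stream <- function(idx) {
  groups <- split(idx, ceiling(seq_along(idx) / 254))
  codes <- integer(length(idx) + length(groups) + 2L)
  pos <- 1L
  codes[pos] <- CLEAR_CODE; pos <- pos + 1L
  for (g in groups) {
    codes[pos:(pos + length(g) - 1L)] <- g
    pos <- pos + length(g)
    codes[pos] <- CLEAR_CODE; pos <- pos + 1L
  }
  codes[pos] <- EOI_CODE
  pack_codes(codes[1:pos])
}

sub_blocks <- function(bytes) {
  n <- length(bytes)
  starts <- seq(1L, n, by = 255L)
  out <- vector("list", length(starts) + 1L)
  for (i in seq_along(starts)) {
    chunk <- bytes[starts[i]:min(starts[i] + 254L, n)]
    out[[i]] <- c(as.raw(length(chunk)), chunk)
  }
  out[[length(out)]] <- as.raw(0L)
  do.call(c, out)
}

#' Write an animated GIF
#'
#' @param frames A list of image frames: file paths to PNGs, or numeric
#'   arrays (height x width x channels, values in `[0, 1]`). All frames
#'   must share the same dimensions.
#' @param path Output `.gif` path.
#' @param fps Frames per second (stored as a centisecond frame delay).
#' @param loop Number of animation loops, 0 = forever.
#' @return Invisibly, a list with `path`, `n_frames`, `width`, `height`.
#' @export
write_gif <- function(frames, path, fps = 1, loop = 0) {
  if (!length(frames)) rlang::abort("write_gif: need at least one frame")
  imgs <- purrr::map(frames, function(f) {
    if (is.character(f)) png::readPNG(f) else f
  })
  dims <- purrr::map(imgs, ~ dim(.x)[1:2])
  if (length(unique(purrr::map_chr(dims, paste, collapse = "x"))) != 1) {
    rlang::abort("write_gif: all frames must have identical dimensions")
  }
  h <- dims[[1]][1]; w <- dims[[1]][2]
  delay <- max(1L, as.integer(round(100 / fps)))

  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(charToRaw("GIF89a"), con)
  writeBin(c(u16(w), u16(h), as.raw(0xF7), as.raw(0), as.raw(0)), con)
  writeBin(gif_palette(), con)
  # looping application extension
  writeBin(c(as.raw(c(0x21, 0xFF, 0x0B)), charToRaw("NETSCAPE2.0"),
             as.raw(c(0x03, 0x01)), u16(loop), as.raw(0)), con)
  for (img in imgs) {
    writeBin(c(as.raw(c(0x21, 0xF9, 0x04, 0x00)), u16(delay),
               as.raw(c(0x00, 0x00))), con)
    writeBin(c(as.raw(0x2C), u16(0), u16(0), u16(w), u16(h), as.raw(0)), con)
    writeBin(as.raw(8), con)  # LZW minimum code size
    writeBin(sub_blocks(frame_code_stream(quantize_frame(img))), con)
  }
  writeBin(as.raw(0x3B), con)
  invisible(list(path = path, n_frames = length(imgs), width = w, height = h))
}

#' Count the frames of a GIF file
#'
#' Walks the GIF block structure and counts image descriptors; used to
#' verify encoded movies without a decoder dependency.
#'
#' @param path A `.gif` file.
#' @return Integer frame count.
#' @export
gif_frame_count <- function(path) {
  bytes <- readBin(path, "raw", file.info(path)$size)
  if (rawToChar(bytes[1:6]) != "GIF89a") rlang::abort("not a GIF89a file")
  packed <- as.integer(bytes[11])
  pos <- 14L
  if (bitwAnd(packed, 0x80) > 0) pos <- pos + 3L * 2L^(bitwAnd(packed, 7L) + 1L)
  n <- 0L
  skip_blocks <- function(p) {
    repeat {
      len <- as.integer(bytes[p])
      p <- p + 1L
      if (len == 0L) return(p)
      p <- p + len
    }
  }
  while (pos <= length(bytes)) {
    marker <- as.integer(bytes[pos])
    if (marker == 0x3B) break
    if (marker == 0x21) {          # extension
      pos <- skip_blocks(pos + 2L)
    } else if (marker == 0x2C) {   # image descriptor
      n <- n + 1L
      lpacked <- as.integer(bytes[pos + 9L])
      pos <- pos + 10L
      if (bitwAnd(lpacked, 0x80) > 0) pos <- pos + 3L * 2L^(bitwAnd(lpacked, 7L) + 1L)
      pos <- skip_blocks(pos + 1L)  # skip LZW min code size, then data
    } else {
      rlang::abort(glue::glue("unexpected GIF block marker 0x{as.character(bytes[pos])}"))
    }
  }
  n
}
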