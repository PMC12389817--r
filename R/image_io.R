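# Raster input/output.
#
# PNG and JPEG are handled by the png/jpeg packages.  PNM (PGM/PPM, ASCII or
# binary) is read and written natively so that fixtures can be stored as
# plain text.  Images are numeric arrays in [0, 1], either H x W (grayscale)
# or H x W x 3 (RGB).

#' Read a raster image
#'
#' @param path Path to a `.png`, `.jpg`/`.jpeg`, `.pgm`, `.ppm` or `.pnm`
#'   file.
#' @return Numeric array in `[0, 1]`: `H x W` for grayscale input, `H x W x 3`
#'   for color.  Alpha channels are dropped.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop_invalid("no such image file: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = jpeg::readJPEG(path),
    pgm = ,
    ppm = ,
    pnm = read_pnm(path),
    stop_invalid("unsupported image format: .", ext)
  )
  if (length(dim(img)) == 3L && dim(img)[3] >= 3L)
    img <- img[, , 1:3, drop = FALSE]
  if (length(dim(img)) == 3L && dim(img)[3] == 1L) dim(img) <- dim(img)[1:2]
  img
}

#' Write a raster image
#'
#' @param img Numeric array in `[0, 1]`, `H x W` or `H x W x 3`.
#' @param path Output path; format chosen by extension (`.png`, `.pgm`,
#'   `.ppm`).
#' @export
write_image <- function(img, path) {
  img <- clamp(img, 0, 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(img, path),
    pgm = ,
    ppm = ,
    pnm = write_pnm(img, path),
    stop_invalid("unsupported output format: .", ext)
  )
  invisible(path)
}

read_pnm <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  magic <- rawToChar(raw[1:2])
  if (!magic %in% c("P2", "P3", "P5", "P6"))
    stop_invalid("unsupported PNM magic: ", magic)
  ws <- as.raw(c(0x20, 0x09, 0x0a, 0x0d))
  # Walk the header byte-wise: three integer tokens, '#' comments allowed.
  tokens <- integer(0)
  buf <- character(0)
  i <- 3L
  while (length(tokens) < 3L && i <= length(raw)) {
    ch <- raw[i]
    if (ch == as.raw(0x23)) {                     # '#'
      while (i <= length(raw) && raw[i] != as.raw(0x0a)) i <- i + 1L
    } else if (ch %in% ws) {
      if (length(buf)) {
        tokens <- c(tokens, as.integer(paste(buf, collapse = "")))
        buf <- character(0)
      }
    } else {
      buf <- c(buf, rawToChar(ch))
    }
    i <- i + 1L
  }
  if (length(tokens) < 3L) stop_invalid("truncated PNM header")
  w <- tokens[1]; h <- tokens[2]; maxval <- tokens[3]
  nch <- if (magic %in% c("P3", "P6")) 3L else 1L
  n <- w * h * nch
  vals <- if (magic %in% c("P2", "P3")) {
    as.integer(scan(text = rawToChar(raw[i:length(raw)]), what = integer(),
                    n = n, quiet = TRUE))
  } else {
    # i currently points just past the single whitespace after maxval
    as.integer(raw[i:(i + n - 1L)])
  }
  if (length(vals) != n) stop_invalid("truncated PNM payload")
  a <- array(vals / maxval, c(nch, w, h))       # file order: row-major
  a <- aperm(a, c(3, 2, 1))
  if (nch == 1L) dim(a) <- c(h, w)
  a
}

write_pnm <- function(img, path, ascii = TRUE) {
  v <- round(clamp(img, 0, 1) * 255)
  gray <- length(dim(v)) < 3L
  magic <- if (gray) (if (ascii) "P2" else "P5") else (if (ascii) "P3" else "P6")
  h <- dim(v)[1]; w <- dim(v)[2]
  flat <- if (gray) as.integer(t(v)) else {
    as.integer(aperm(v, c(3, 2, 1)))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("%s\n%d %d\n255\n", magic, w, h), con, eos = NULL)
  if (ascii) {
    writeChar(paste(flat, collapse = " "), con, eos = NULL)
    writeChar("\n", con, eos = NULL)
  } else {
    writeBin(as.raw(flat), con)
  }
  invisible(path)
}

#' Convert an RGB array to HSV
#'
#' Vectorised hexcone conversion; all channels in `[0, 1]`, hue scaled so a
#' full turn is 1.
#'
#' @param img `H x W x 3` numeric array in `[0, 1]`.
#' @return `H x W x 3` array with channels hue, saturation, value.
#' @export
rgb_to_hsv_array <- function(img) {
  if (length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop_invalid("rgb_to_hsv_array expects an H x W x 3 array")
  r <- img[, , 1]; g <- img[, , 2]; b <- img[, , 3]
  mx <- pmax(r, g, b)
  mn <- pmin(r, g, b)
  d <- mx - mn
  h <- matrix(0, nrow(r), ncol(r))
  nz <- d > 0
  i_r <- nz & (mx == r)
  i_g <- nz & (mx == g) & !i_r
  i_b <- nz & !i_r & !i_g
  h[i_r] <- (((g - b)[i_r] / d[i_r]) %% 6) / 6
  h[i_g] <- (((b - r)[i_g] / d[i_g]) + 2) / 6
  h[i_b] <- (((r - g)[i_b] / d[i_b]) + 4) / 6
  s <- ifelse(mx > 0, d / mx, 0)
  out <- array(0, dim(img))
  out[, , 1] <- h; out[, , 2] <- s; out[, , 3] <- mx
  out
}

#' Resize an image
#'
#' @param img `H x W` or `H x W x C` numeric array.
#' @param out_h,out_w Target size in pixels.
#' @param method `"bilinear"` (half-pixel-center convention) or
#'   `"nearest"`.
#' @return Resized array of the same rank.
#' @export
resize_image <- function(img, out_h, out_w, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  gray <- length(dim(img)) < 3L
  if (gray) dim(img) <- c(dim(img), 1L)
  d <- dim(img)
  if (method == "bilinear") {
    Mh <- bilinear_map(out_h, d[1])
    Mw <- bilinear_map(out_w, d[2])
    out <- array(0, c(out_h, out_w, d[3]))
    for (c in seq_len(d[3]))
      out[, , c] <- Mh %*% img[, , c] %*% t(Mw)
  } else {
    ri <- pmin(pmax(ceiling((seq_len(out_h) - 0.5) * d[1] / out_h), 1L), d[1])
    ci <- pmin(pmax(ceiling((seq_len(out_w) - 0.5) * d[2] / out_w), 1L), d[2])
    out <- img[ri, ci, , drop = FALSE]
  }
  if (gray) dim(out) <- dim(out)[1:2]
  out
}
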