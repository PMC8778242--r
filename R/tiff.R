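# Minimal baseline TIFF support for 16-bit grayscale micrographs.
# No TIFF package ships with the analysis environment, and only the plain
# uncompressed single-sample baseline dialect is needed, so the format is
# read and written directly. Writer emits little-endian, single-strip,
# uncompressed; reader additionally accepts big-endian and multi-strip
# files, but not compressed or tiled ones.

tiff_u16 <- function(bytes, i, big) {
  b <- as.integer(bytes[i + 0:1])
  if (big) b[1] * 256 + b[2] else b[2] * 256 + b[1]
}

tiff_u32 <- function(bytes, i, big) {
  b <- as.integer(bytes[i + 0:3])
  if (big) ((b[1] * 256 + b[2]) * 256 + b[3]) * 256 + b[4]
  else ((b[4] * 256 + b[3]) * 256 + b[2]) * 256 + b[1]
}

# value of an IFD entry (SHORT or LONG, possibly count > 1 via offset)
tiff_entry_values <- function(bytes, entry_at, big) {
  type <- tiff_u16(bytes, entry_at + 2, big)
  count <- tiff_u32(bytes, entry_at + 4, big)
  size <- c(1L, 1L, 2L, 4L)[type] # BYTE, ASCII, SHORT, LONG
  if (is.na(size)) return(NULL)
  total <- size * count
  at <- if (total <= 4) entry_at + 8 else tiff_u32(bytes, entry_at + 8, big) + 1
  reader <- if (size == 2L) tiff_u16 else if (size == 4L) tiff_u32 else {
    function(b, i, bg) as.integer(b[i])
  }
  vapply(seq_len(count), function(k) reader(bytes, at + (k - 1) * size, big), 0)
}

#' Read a 16-bit grayscale TIFF
#'
#' Supports uncompressed baseline grayscale TIFF (8- or 16-bit, either byte
#' order, one or many strips) -- the dialect the synthetic micrograph writer
#' produces and confocal exports commonly use.
#'
#' @param path TIFF file path.
#' @return integer matrix (rows = image rows).
#' @export
read_tiff16 <- function(path) {
  bytes <- readBin(path, "raw", file.info(path)$size)
  magic <- rawToChar(bytes[1:2])
  if (!magic %in% c("II", "MM")) stop("not a TIFF file: ", path)
  big <- magic == "MM"
  ifd <- tiff_u32(bytes, 5, big) + 1
  n <- tiff_u16(bytes, ifd, big)
  tags <- list()
  for (k in seq_len(n)) {
    at <- ifd + 2 + (k - 1) * 12
    tags[[as.character(tiff_u16(bytes, at, big))]] <- tiff_entry_values(bytes, at, big)
  }
  need <- function(tag, default = NULL) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) {
      if (is.null(default)) stop("TIFF missing required tag ", tag)
      default
    } else v
  }
  width <- need(256); height <- need(257)
  bits <- need(258, 8)[1]
  if (!bits %in% c(8, 16)) stop("unsupported BitsPerSample: ", bits)
  if (need(259, 1)[1] != 1) stop("compressed TIFF not supported")
  if (need(277, 1)[1] != 1) stop("multi-sample TIFF not supported")
  offsets <- need(273)
  counts <- need(279, width * height * bits / 8)
  px <- unlist(lapply(seq_along(offsets), function(s) {
    raw_s <- bytes[offsets[s] + seq_len(counts[s])]
    if (bits == 16) {
      readBin(raw_s, "integer", n = counts[s] / 2, size = 2, signed = FALSE,
              endian = if (big) "big" else "little")
    } else as.integer(raw_s)
  }))
  matrix(px, nrow = height, ncol = width, byrow = TRUE)
}

#' Write a matrix as 16-bit grayscale TIFF
#'
#' Single-strip, uncompressed, little-endian baseline TIFF. Values are
#' clamped to the 16-bit range and rounded.
#'
#' @param img numeric matrix (rows = image rows).
#' @param path output path.
#' @export
write_tiff16 <- function(img, path) {
  stopifnot(is.matrix(img))
  v <- pmin(pmax(round(img), 0), 65535)
  height <- nrow(img); width <- ncol(img)
  u16 <- function(x) as.raw(c(x %% 256, x %/% 256))
  u32 <- function(x) as.raw(c(x %% 256, (x %/% 256) %% 256,
                              (x %/% 65536) %% 256, (x %/% 16777216) %% 256))
  entry <- function(tag, type, count, value) {
    c(u16(tag), u16(type), u32(count),
      if (type == 3L) c(u16(value), u16(0L)) else u32(value))
  }
  n_entries <- 10L
  ifd_offset <- 8L
  data_offset <- ifd_offset + 2L + n_entries * 12L + 4L
  SHORT <- 3L; LONG <- 4L
  header <- c(charToRaw("II"), u16(42L), u32(ifd_offset))
  entries <- c(
    entry(256L, SHORT, 1L, width),
    entry(257L, SHORT, 1L, height),
    entry(258L, SHORT, 1L, 16L),
    entry(259L, SHORT, 1L, 1L),   # no compression
    entry(262L, SHORT, 1L, 1L),   # BlackIsZero
    entry(273L, LONG, 1L, data_offset),
    entry(277L, SHORT, 1L, 1L),
    entry(278L, SHORT, 1L, height),
    entry(279L, LONG, 1L, width * height * 2L),
    entry(339L, SHORT, 1L, 1L)    # unsigned integer samples
  )
  ifd <- c(u16(n_entries), entries, u32(0L))
  px <- as.integer(t(v))          # row-major
  pix_raw <- as.raw(rbind(px %% 256L, px %/% 256L))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(c(header, ifd, pix_raw), con)
  invisible(path)
}
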