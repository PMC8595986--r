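# Minimal EXIF APP1 reader/writer for the UserComment tag.
#
# Captures store their metadata document as a JSON string in the EXIF
# UserComment field (tag 0x9286), with the standard 8-byte "UNICODE\0"
# character-set prefix, inside an APP1 "Exif" segment inserted directly
# after the JPEG SOI marker. Only this one tag is written; the reader walks
# IFD0 -> Exif IFD and understands both byte orders. No R package in this
# stack writes EXIF, so the segment is constructed here by hand.

u16le <- function(x) as.raw(c(bitwAnd(x, 255L), bitwShiftR(x, 8L)))
u32le <- function(x) as.raw(c(bitwAnd(x, 255L), bitwAnd(bitwShiftR(x, 8L), 255L),
                              bitwAnd(bitwShiftR(x, 16L), 255L),
                              bitwAnd(bitwShiftR(x, 24L), 255L)))
u16be <- function(x) as.raw(c(bitwShiftR(x, 8L), bitwAnd(x, 255L)))

rd16 <- function(b, i, le) {
  a <- as.integer(b[i]); d <- as.integer(b[i + 1])
  if (le) a + 256L * d else 256L * a + d
}
rd32 <- function(b, i, le) {
  v <- as.numeric(as.integer(b[i:(i + 3)]))
  if (le) sum(v * 256^(0:3)) else sum(v * 256^(3:0))
}

#' Embed a metadata string in a JPEG's EXIF UserComment
#'
#' Inserts (or replaces) an APP1 Exif segment holding the string in the
#' UserComment tag. The string round-trips losslessly through
#' [exif_extract()].
#'
#' @param jpeg_bytes Raw vector: a baseline JPEG stream.
#' @param comment Character scalar (typically a JSON document).
#' @return Raw vector: the JPEG with the EXIF segment.
#' @export
exif_embed <- function(jpeg_bytes, comment) {
  stopifnot(is.raw(jpeg_bytes), length(jpeg_bytes) > 4,
            jpeg_bytes[1] == as.raw(0xFF), jpeg_bytes[2] == as.raw(0xD8))
  payload <- charToRaw(enc2utf8(comment))
  uc <- c(charToRaw("UNICODE"), as.raw(0), payload)

  # TIFF body, little-endian, offsets relative to the TIFF header
  ifd0_off <- 8L
  exif_ifd_off <- ifd0_off + 2L + 12L + 4L          # 26
  data_off <- exif_ifd_off + 2L + 12L + 4L          # 44
  tiff <- c(charToRaw("II"), u16le(42L), u32le(ifd0_off),
            # IFD0: one entry -> Exif IFD pointer (0x8769, LONG)
            u16le(1L),
            u16le(0x8769L), u16le(4L), u32le(1L), u32le(exif_ifd_off),
            u32le(0L),
            # Exif IFD: one entry -> UserComment (0x9286, UNDEFINED)
            u16le(1L),
            u16le(0x9286L), u16le(7L), u32le(length(uc)), u32le(data_off),
            u32le(0L),
            uc)
  seg_body <- c(charToRaw("Exif"), as.raw(c(0, 0)), tiff)
  seg <- c(as.raw(c(0xFF, 0xE1)), u16be(length(seg_body) + 2L), seg_body)

  rest <- jpeg_bytes[-(1:2)]
  # drop any existing Exif APP1 so embedding is idempotent
  if (length(rest) > 10 && rest[1] == as.raw(0xFF) && rest[2] == as.raw(0xE1) &&
      identical(rawToChar(rest[5:8]), "Exif")) {
    len <- rd16(rest, 3L, le = FALSE)
    rest <- rest[-(1:(2L + len))]
  }
  c(as.raw(c(0xFF, 0xD8)), seg, rest)
}

#' @rdname exif_embed
#' @return `exif_extract`: the UserComment string, or `NULL` when the JPEG
#'   has no Exif APP1 segment or no UserComment tag.
#' @export
exif_extract <- function(jpeg_bytes) {
  b <- jpeg_bytes
  if (length(b) < 4 || b[1] != as.raw(0xFF) || b[2] != as.raw(0xD8)) return(NULL)
  i <- 3L
  while (i + 3 <= length(b)) {
    if (b[i] != as.raw(0xFF)) return(NULL)
    marker <- as.integer(b[i + 1])
    if (marker == 0xDA || marker == 0xD9) return(NULL)   # image data / EOI
    len <- rd16(b, i + 2L, le = FALSE)
    if (marker == 0xE1 && i + 9 <= length(b) &&
        identical(rawToChar(b[(i + 4):(i + 7)]), "Exif")) {
      return(parse_exif_usercomment(b[(i + 10):(i + 1L + len)]))
    }
    i <- i + 2L + len
  }
  NULL
}

parse_exif_usercomment <- function(tiff) {
  if (length(tiff) < 8) return(NULL)
  le <- identical(rawToChar(tiff[1:2]), "II")
  ifd0 <- rd32(tiff, 5L, le) + 1L
  find_tag <- function(ifd_pos, tag) {
    if (ifd_pos + 1 > length(tiff)) return(NULL)
    n <- rd16(tiff, ifd_pos, le)
    for (k in seq_len(n)) {
      e <- ifd_pos + 2L + (k - 1L) * 12L
      if (rd16(tiff, e, le) == tag) {
        return(list(count = rd32(tiff, e + 4L, le),
                    value = rd32(tiff, e + 8L, le)))
      }
    }
    NULL
  }
  ptr <- find_tag(ifd0, 0x8769L)
  if (is.null(ptr)) return(NULL)
  uc <- find_tag(ptr$value + 1L, 0x9286L)
  if (is.null(uc) || uc$count <= 8) return(NULL)
  start <- uc$value + 1L
  bytes <- tiff[(start + 8L):(start + uc$count - 1L)]
  out <- rawToChar(bytes[bytes != as.raw(0)])
  Encoding(out) <- "UTF-8"
  out
}
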