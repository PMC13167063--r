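# Compression-based text representation.
#
# All quantities derive from one primitive: the byte length of the
# RFC 1952 (gzip) compression of the UTF-8 encoded text at zlib's default
# level 6, with empty header metadata (mtime zero, unknown OS), so lengths
# are identical across calls and platforms. R's memCompress() emits a zlib
# stream; gzip framing is reconstructed around its raw DEFLATE payload.

gzip_bytes <- function(text) {
  raw <- charToRaw(enc2utf8(as.character(text)))
  z <- memCompress(raw, type = "gzip")   # zlib: 2-byte header + deflate + adler32
  deflate <- z[seq.int(3L, length(z) - 4L)]
  crc <- digest::digest(raw, algo = "crc32", serialize = FALSE, raw = FALSE)
  crc <- formatC(crc, width = 8, flag = "0")
  crc_raw <- rev(as.raw(strtoi(substring(crc, c(1, 3, 5, 7), c(2, 4, 6, 8)),
                               base = 16L)))
  isize <- packBits(intToBits(length(raw) %% 2^32), "raw")  # little-endian
  header <- as.raw(c(0x1f, 0x8b, 0x08, 0x00, 0x00, 0x00, 0x00, 0x00, 0x00, 0xff))
  c(header, deflate, crc_raw, isize)
}

#' Compressed length of a text
#'
#' Byte length of the gzip-format compression of the UTF-8 encoding of
#' `text`, at fixed compression level 6 with zeroed header metadata. This is
#' the `C(x)` of the normalized compression distance and the single feature
#' of the compression representation.
#'
#' @param text character vector.
#' @return integer vector of byte counts.
#' @export
compressed_length <- function(text) {
  vapply(as.character(text), function(t) length(gzip_bytes(t)), integer(1),
         USE.NAMES = FALSE)
}

#' Compression features
#'
#' One row per document. By default a single column, `compressed_length`;
#' with `extra = TRUE` adds the raw UTF-8 byte length and the compression
#' ratio (compressed / max(raw, 1)).
#'
#' @param docs character vector of texts.
#' @param extra include `raw_byte_length` and `compression_ratio` columns.
#' @param doc_ids optional row ids.
#' @return a `notesieve_features` with tag `"COMP"` (dense matrix).
#' @export
compression_features <- function(docs, extra = FALSE, doc_ids = NULL) {
  n <- length(docs)
  ids <- doc_ids %||% names(docs) %||% sprintf("doc%d", seq_len(n))
  cl <- compressed_length(docs)
  if (extra) {
    rawlen <- vapply(as.character(docs),
                     function(t) length(charToRaw(enc2utf8(t))), integer(1),
                     USE.NAMES = FALSE)
    m <- cbind(compressed_length = cl, raw_byte_length = rawlen,
               compression_ratio = cl / pmax(rawlen, 1))
  } else {
    m <- cbind(compressed_length = cl)
  }
  rownames(m) <- ids
  vocab <- data.frame(token = colnames(m), index = seq_len(ncol(m)),
                      df = NA_integer_, stringsAsFactors = FALSE)
  new_features(m, vocab, "COMP")
}

#' Normalized compression distance
#'
#' `NCD(x, y) = (C(xy) - min(C(x), C(y))) / max(C(x), C(y))` where `C` is
#' [compressed_length()] and `xy` is byte concatenation with no separator.
#' A parameter-free dissimilarity: near 0 for near-identical texts, around 1
#' (occasionally slightly above) for unrelated ones. Both inputs empty is
#' defined as distance 0.
#'
#' @param x,y single strings.
#' @param cx,cy optional precomputed compressed lengths of `x` and `y`.
#' @return non-negative numeric distance.
#' @export
ncd <- function(x, y, cx = NULL, cy = NULL) {
  cx <- cx %||% compressed_length(x)
  cy <- cy %||% compressed_length(y)
  if (!nzchar(x) && !nzchar(y)) return(0)
  cxy <- compressed_length(paste0(x, y))
  (cxy - min(cx, cy)) / max(cx, cy)
}

#' Pairwise NCD matrix between query and reference texts
#'
#' Reference (and query) compressed lengths are computed once and reused,
#' which is what makes NCD-kNN classification of many queries affordable.
#'
#' @param queries,references character vectors.
#' @param ref_lengths optional precomputed `compressed_length(references)`.
#' @return numeric matrix, `length(queries)` x `length(references)`.
#' @export
ncd_distance_matrix <- function(queries, references, ref_lengths = NULL) {
  cq <- compressed_length(queries)
  cr <- ref_lengths %||% compressed_length(references)
  out <- matrix(0, nrow = length(queries), ncol = length(references))
  for (i in seq_along(queries)) {
    for (j in seq_along(references)) {
      out[i, j] <- ncd(queries[i], references[j], cx = cq[i], cy = cr[j])
    }
  }
  rownames(out) <- names(queries)
  colnames(out) <- names(references)
  out
}
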