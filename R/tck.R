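# Track-file (.tck) input/output. The format is a short ASCII header
# ("mrtrix tracks" magic, key: value lines, END) followed by little-endian
# float32 triplets; streamlines are separated by a NaN triplet and the
# stream is terminated by an Inf triplet.

#' Write a tractogram to a .tck track file
#'
#' @param tractogram list of n x 3 numeric matrices (world mm), e.g. from
#'   [make_tractogram()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tck <- function(tractogram, path) {
  streams <- lapply(tractogram, function(m) {
    m <- as.matrix(m)
    stopifnot(ncol(m) == 3)
    m
  })
  header_for <- function(offset)
    paste0("mrtrix tracks\n",
           "datatype: Float32LE\n",
           "count: ", length(streams), "\n",
           "file: . ", offset, "\nEND\n")
  # header length depends on the printed offset; iterate to a fixed point
  off <- nchar(header_for(0), type = "bytes")
  off <- nchar(header_for(off), type = "bytes")
  header <- header_for(off)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  for (m in streams) {
    writeBin(as.vector(t(m)), con, size = 4, endian = "little")
    writeBin(rep(NaN, 3), con, size = 4, endian = "little")
  }
  writeBin(rep(Inf, 3), con, size = 4, endian = "little")
  invisible(path)
}

#' Read a .tck track file
#'
#' @param path file path.
#' @return list of n x 3 matrices (world mm), class `cc_tractogram`.
#' @export
read_tck <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  # locate "END\n" by raw byte matching (the payload is binary)
  pat <- charToRaw("END\n")
  limit <- min(2048L, length(raw)) - 3L
  end_tag <- -1L
  for (i in seq_len(max(limit, 0))) {
    if (raw[i] == pat[1] && raw[i + 1] == pat[2] &&
        raw[i + 2] == pat[3] && raw[i + 3] == pat[4]) { end_tag <- i; break }
  }
  if (end_tag < 0) stop("not a track file: END tag not found in header")
  header <- rawToChar(raw[1:(end_tag + 3)])
  if (!grepl("^mrtrix tracks", header)) stop("not a track file")
  off_line <- regmatches(header, regexpr("file: \\. [0-9]+", header))
  offset <- as.integer(sub("file: \\. ", "", off_line))
  dat <- readBin(raw[(offset + 1):length(raw)], "numeric", size = 4,
                 n = (length(raw) - offset) / 4, endian = "little")
  pts <- matrix(dat, ncol = 3, byrow = TRUE)
  is_sep <- is.nan(pts[, 1])
  is_end <- is.infinite(pts[, 1])
  stream_id <- cumsum(is_sep) + 1
  keep <- !is_sep & !is_end
  ids <- stream_id[keep]
  pts <- pts[keep, , drop = FALSE]
  out <- lapply(split(seq_len(nrow(pts)), ids), function(i)
    pts[i, , drop = FALSE])
  names(out) <- NULL
  structure(out, class = "cc_tractogram")
}
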