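# Minimal MAT v5 (Level 5 MAT-file) reader/writer.
#
# Covers exactly what the deposited PDB-identifier lists need: top-level
# variables that are cell arrays of character vectors, character matrices
# (one id per row), or numeric arrays; zlib-compressed elements are
# supported. This is not a general MAT implementation.

MI_INT8 <- 1L; MI_UINT8 <- 2L; MI_INT16 <- 3L; MI_UINT16 <- 4L
MI_INT32 <- 5L; MI_UINT32 <- 6L; MI_SINGLE <- 7L; MI_DOUBLE <- 9L
MI_MATRIX <- 14L; MI_COMPRESSED <- 15L; MI_UTF8 <- 16L; MI_UTF16 <- 17L
MX_CELL <- 1L; MX_CHAR <- 4L; MX_DOUBLE <- 6L

#' Read variables from a MAT v5 file
#'
#' Supports the subset of the format used by deposited identifier lists:
#' cell arrays of strings, character matrices and numeric arrays, stored
#' uncompressed or zlib-compressed.
#'
#' @param path path to a `.mat` file.
#' @return named list of variables; cell-of-string and char-matrix
#'   variables become character vectors, numeric arrays become matrices.
#' @export
read_mat <- function(path) {
  if (!file.exists(path)) stop("MAT file not found: ", path)
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 128L) stop("not a MAT v5 file (short header): ", path)
  magic <- rawToChar(raw[1:4])
  endian <- rawToChar(raw[127:128])
  if (!identical(substr(magic, 1, 4), "MATL") || !endian %in% c("IM", "MI"))
    stop("not a MAT v5 file: ", path)
  if (endian == "MI")
    stop("big-endian MAT files are not supported")
  pos <- 128L
  vars <- list()
  while (pos < length(raw)) {
    tag <- parse_tag(raw, pos)
    payload <- raw[(pos + tag$hdr + 1L):(pos + tag$hdr + tag$nbytes)]
    if (tag$type == MI_COMPRESSED) {
      payload <- memDecompress(payload, type = "gzip")
      inner <- parse_tag(payload, 0L)
      el <- parse_matrix(payload[(inner$hdr + 1L):length(payload)])
    } else if (tag$type == MI_MATRIX) {
      el <- parse_matrix(payload)
    } else {
      el <- NULL
    }
    if (!is.null(el)) vars[[el$name]] <- el$value
    # compressed elements are not 8-byte padded (zlib stream length is
    # arbitrary); everything else is
    pad <- if (tag$type == MI_COMPRESSED) 0L
           else pad8(tag$nbytes, tag$small)
    pos <- pos + tag$hdr + tag$nbytes + pad
  }
  vars
}

pad8 <- function(nbytes, small) {
  if (small) 0L else (8L - nbytes %% 8L) %% 8L
}

# Parse an element tag at 0-based offset `pos`; handles the small-element
# format (type and size packed into the first 4 bytes).
parse_tag <- function(raw, pos) {
  b <- raw[(pos + 1L):(pos + 8L)]
  type32 <- readBin(b[1:4], "integer", 1L, size = 4L, endian = "little")
  upper <- bitwAnd(bitwShiftR(type32, 16L), 0xFFFFL)
  if (upper != 0L) {
    list(type = bitwAnd(type32, 0xFFFFL), nbytes = upper, hdr = 4L,
         small = TRUE)
  } else {
    nbytes <- readBin(b[5:8], "integer", 1L, size = 4L, endian = "little")
    list(type = type32, nbytes = nbytes, hdr = 8L, small = FALSE)
  }
}

# Walk the sub-elements of a miMATRIX payload.
parse_subelements <- function(payload) {
  pos <- 0L
  out <- list()
  while (pos < length(payload)) {
    tag <- parse_tag(payload, pos)
    data <- if (tag$nbytes > 0L)
      payload[(pos + tag$hdr + 1L):(pos + tag$hdr + tag$nbytes)]
    else raw(0)
    out[[length(out) + 1L]] <- list(type = tag$type, data = data)
    pos <- pos + tag$hdr + tag$nbytes + pad8(tag$nbytes, tag$small)
  }
  out
}

decode_numeric <- function(type, data) {
  switch(as.character(type),
    "1" = readBin(data, "integer", length(data), size = 1L, signed = TRUE),
    "2" = as.integer(data),
    "3" = readBin(data, "integer", length(data) %/% 2L, size = 2L,
                  signed = TRUE, endian = "little"),
    "4" = readBin(data, "integer", length(data) %/% 2L, size = 2L,
                  signed = FALSE, endian = "little"),
    "5" = readBin(data, "integer", length(data) %/% 4L, size = 4L,
                  endian = "little"),
    "6" = readBin(data, "integer", length(data) %/% 4L, size = 4L,
                  endian = "little"),
    "7" = readBin(data, "double", length(data) %/% 4L, size = 4L,
                  endian = "little"),
    "9" = readBin(data, "double", length(data) %/% 8L, size = 8L,
                  endian = "little"),
    stop("unsupported MAT data type: ", type)
  )
}

decode_char <- function(type, data, dims) {
  codes <- switch(as.character(type),
    "2" = , "1" = , "16" = {
      # single-byte / UTF-8 text
      ch <- rawToChar(data)
      strsplit(ch, "", fixed = TRUE)[[1]]
    },
    "4" = , "17" = {
      u <- readBin(data, "integer", length(data) %/% 2L, size = 2L,
                   signed = FALSE, endian = "little")
      vapply(u, function(x) intToUtf8(x), character(1))
    },
    stop("unsupported MAT char encoding: ", type)
  )
  n <- dims[1]; m <- prod(dims) %/% n
  if (length(codes) != n * m)
    stop("char data length does not match dimensions")
  mat <- matrix(codes, nrow = n, ncol = m)  # column-major, as stored
  trimws(apply(mat, 1L, paste, collapse = ""))
}

# Parse one miMATRIX payload into list(name=, value=).
parse_matrix <- function(payload) {
  subs <- parse_subelements(payload)
  if (length(subs) < 3L) stop("malformed MAT matrix element")
  flags <- decode_numeric(MI_UINT32, subs[[1]]$data)
  cls <- bitwAnd(flags[1], 0xFFL)
  dims <- decode_numeric(subs[[2]]$type, subs[[2]]$data)
  name <- rawToChar(subs[[3]]$data)
  value <- if (cls == MX_CELL) {
    cells <- subs[-(1:3)]
    unlist(lapply(cells, function(el) {
      if (el$type != MI_MATRIX) stop("cell entry is not a matrix element")
      parse_matrix(el$data)$value
    }), use.names = FALSE)
  } else if (cls == MX_CHAR) {
    if (length(subs) < 4L) stop("char array without data")
    decode_char(subs[[4]]$type, subs[[4]]$data, dims)
  } else {
    vals <- decode_numeric(subs[[4]]$type, subs[[4]]$data)
    if (length(dims) == 2L) matrix(as.numeric(vals), dims[1], dims[2])
    else as.numeric(vals)
  }
  list(name = name, value = value)
}

# --- writer ----------------------------------------------------------------

uint32_raw <- function(x) writeBin(as.integer(x), raw(), size = 4L,
                                   endian = "little")

element_raw <- function(type, data) {
  n <- length(data)
  pad <- as.integer((8L - n %% 8L) %% 8L)
  c(uint32_raw(type), uint32_raw(n), data, raw(pad))
}

char_matrix_raw <- function(s, name) {
  # one string as a 1 x nchar char array (miUINT16 text, MATLAB style)
  codes <- utf8ToInt(s)
  data <- writeBin(as.integer(codes), raw(), size = 2L, endian = "little")
  body <- c(
    element_raw(MI_UINT32, uint32_raw(c(MX_CHAR, 0L))),
    element_raw(MI_INT32, uint32_raw(c(1L, length(codes)))),
    element_raw(MI_INT8, charToRaw(name)),
    element_raw(MI_UINT16, data)
  )
  c(uint32_raw(MI_MATRIX), uint32_raw(length(body)), body)
}

cell_of_strings_raw <- function(strings, name) {
  cells <- unlist(lapply(strings, char_matrix_raw, name = ""),
                  use.names = FALSE)
  body <- c(
    element_raw(MI_UINT32, uint32_raw(c(MX_CELL, 0L))),
    element_raw(MI_INT32, uint32_raw(c(1L, length(strings)))),
    element_raw(MI_INT8, charToRaw(name)),
    cells
  )
  c(uint32_raw(MI_MATRIX), uint32_raw(length(body)), body)
}

#' Write character vectors as a MAT v5 file of cell arrays
#'
#' Each element of `vars` (a named list of character vectors) becomes a
#' 1 x n cell array of strings, the layout used by deposited PDB-identifier
#' lists. Intended for building synthetic stand-in files and round-trip
#' tests; uncompressed output.
#'
#' @param vars named list of character vectors.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mat_cellstr <- function(vars, path) {
  if (is.null(names(vars)) || any(names(vars) == ""))
    stop("all variables must be named")
  header <- charToRaw(sprintf("%-116s", "MATLAB 5.0 MAT-file, written by pfnet"))
  header <- c(header, raw(8L),            # subsystem offset
              as.raw(c(0x00, 0x01)),      # version 0x0100, little-endian
              charToRaw("IM"))
  header <- header[1:128]
  body <- unlist(lapply(names(vars), function(nm)
    cell_of_strings_raw(as.character(vars[[nm]]), nm)), use.names = FALSE)
  writeBin(c(header, body), path)
  invisible(path)
}

#' Load per-class PDB identifier lists from a MAT file
#'
#' The deposited identifier lists store the PDB ids of each structural
#' class in variables named `PID_A`, `PID_B`, `PID_M` (three-class data)
#' or `PID_1` .. `PID_4` (four-class data). No sequence retrieval is
#' performed; only the id lists and counts are returned.
#'
#' @param path path to the MAT file.
#' @return a list with `ids` (named list, one character vector per class
#'   variable), `counts` (named integer vector) and `total`.
#' @export
load_pdb_id_lists <- function(path) {
  vars <- read_mat(path)
  pid <- vars[grep("^PID_", names(vars))]
  if (length(pid) == 0L)
    stop("no PID_* variables found in ", path,
         " (expected PID_A/PID_B/PID_M or PID_1..PID_4)")
  pid <- lapply(pid, as.character)
  counts <- vapply(pid, length, integer(1))
  list(ids = pid, counts = counts, total = sum(counts))
}
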