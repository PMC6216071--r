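# Minimal MAT-file (Level 5) reader/writer.
#
# Covers what the trial-epoch containers need: double/integer/single numeric
# arrays (any dimensionality), character vectors, and scalar (1x1) structs,
# at the top level of the file.  Compressed (miCOMPRESSED) elements as
# written by MATLAB v7 / scipy are inflated transparently on read; this
# writer always emits uncompressed Level-5 elements, which every MAT reader
# accepts.  v7.3 files are HDF5 containers and are rejected with a clear
# error.

.mi <- list(INT8 = 1L, UINT8 = 2L, INT16 = 3L, UINT16 = 4L, INT32 = 5L,
            UINT32 = 6L, SINGLE = 7L, DOUBLE = 9L, INT64 = 12L,
            UINT64 = 13L, MATRIX = 14L, COMPRESSED = 15L, UTF8 = 16L,
            UTF16 = 17L)
.mx <- list(STRUCT = 2L, CHAR = 4L, DOUBLE = 6L)

pad8 <- function(r) {
  extra <- (8 - length(r) %% 8) %% 8
  c(r, raw(extra))
}

mat_tag <- function(type, nbytes) {
  c(writeBin(as.integer(type), raw(), size = 4, endian = "little"),
    writeBin(as.integer(nbytes), raw(), size = 4, endian = "little"))
}

mat_element <- function(type, data_raw) {
  pad8(c(mat_tag(type, length(data_raw)), data_raw))
}

mat_numeric_subelt <- function(x) {
  mat_element(.mi$DOUBLE, writeBin(as.double(x), raw(), size = 8,
                                   endian = "little"))
}

mat_int32_subelt <- function(x) {
  mat_element(.mi$INT32, writeBin(as.integer(x), raw(), size = 4,
                                  endian = "little"))
}

mat_name_subelt <- function(name) {
  mat_element(.mi$INT8, charToRaw(name))
}

mat_array_flags <- function(class_id) {
  mat_element(.mi$UINT32,
              writeBin(as.integer(c(class_id, 0L)), raw(), size = 4,
                       endian = "little"))
}

# serialize one variable (numeric array, character scalar, or named list
# as a 1x1 struct) into a complete miMATRIX element
mat_variable <- function(name, value) {
  if (is.character(value)) {
    stopifnot(length(value) == 1L)
    codes <- utf8ToInt(value)
    body <- c(mat_array_flags(.mx$CHAR),
              mat_int32_subelt(c(1L, length(codes))),
              mat_name_subelt(name),
              mat_element(.mi$UINT16,
                          writeBin(as.integer(codes), raw(), size = 2,
                                   endian = "little")))
  } else if (is.numeric(value) || is.array(value)) {
    dims <- if (is.null(dim(value))) c(1L, length(value)) else dim(value)
    if (length(dims) == 1L) dims <- c(1L, dims)
    body <- c(mat_array_flags(.mx$DOUBLE),
              mat_int32_subelt(dims),
              mat_name_subelt(name),
              mat_numeric_subelt(as.vector(value)))
  } else if (is.list(value)) {
    fn <- names(value)
    if (is.null(fn) || any(!nzchar(fn)))
      stop_trggc("struct fields must be named")
    maxlen <- 32L
    if (any(nchar(fn) >= maxlen)) stop_trggc("field name too long")
    names_raw <- unlist(lapply(fn, function(f) {
      r <- charToRaw(f); c(r, raw(maxlen - length(r)))
    }))
    fields_raw <- unlist(lapply(fn, function(f) mat_variable("", value[[f]])))
    body <- c(mat_array_flags(.mx$STRUCT),
              mat_int32_subelt(c(1L, 1L)),
              mat_name_subelt(name),
              mat_int32_subelt(maxlen),
              mat_element(.mi$INT8, names_raw),
              fields_raw)
  } else stop_trggc("unsupported value type for MAT serialization")
  mat_element(.mi$MATRIX, body)
}

#' Write variables to a Level-5 MAT-file
#'
#' @param vars named list of variables (numeric arrays, single strings, or
#'   named lists which become 1x1 structs).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mat <- function(vars, path) {
  stopifnot(is.list(vars), !is.null(names(vars)), all(nzchar(names(vars))))
  desc <- sprintf("MATLAB 5.0 MAT-file, Created by: trggc on %s",
                  format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  hdr <- charToRaw(desc)
  if (length(hdr) > 116) hdr <- hdr[1:116]
  hdr <- c(hdr, charToRaw(strrep(" ", 116 - length(hdr))))
  hdr <- c(hdr, raw(8))                                 # subsystem offset
  hdr <- c(hdr, writeBin(256L, raw(), size = 2, endian = "little"))
  hdr <- c(hdr, charToRaw("IM"))                        # endian indicator
  body <- unlist(lapply(names(vars), function(nm) mat_variable(nm, vars[[nm]])))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(hdr, body), con)
  invisible(path)
}

# --- reader ---------------------------------------------------------------

mat_read_int <- function(raw, pos, size, endian, signed = TRUE) {
  readBin(raw[pos:(pos + size - 1)], "integer", n = 1, size = size,
          endian = endian, signed = signed)
}

# read the 8-byte (or small-format 4-byte) tag at pos; returns
# list(type, nbytes, data_start, next_pos_of_data_end_unpadded)
mat_read_tag <- function(raw, pos, endian) {
  word <- readBin(raw[pos:(pos + 3)], "integer", n = 1, size = 4,
                  endian = endian)
  small_len <- bitwAnd(bitwShiftR(word, 16), 0xFFFFL)
  if (small_len != 0L) {
    list(type = bitwAnd(word, 0xFFFFL), nbytes = small_len,
         data_start = pos + 4L, hdr = 4L, small = TRUE)
  } else {
    nb <- readBin(raw[(pos + 4):(pos + 7)], "integer", n = 1, size = 4,
                  endian = endian)
    list(type = word, nbytes = nb, data_start = pos + 8L, hdr = 8L,
         small = FALSE)
  }
}

mat_elem_total <- function(tag) {
  if (tag$small) 8L else tag$hdr + tag$nbytes +
    (8L - tag$nbytes %% 8L) %% 8L
}

mat_read_numeric_payload <- function(raw, tag, endian) {
  b <- raw[tag$data_start:(tag$data_start + tag$nbytes - 1)]
  t <- tag$type
  if (t == .mi$DOUBLE) readBin(b, "double", n = tag$nbytes / 8, size = 8,
                               endian = endian)
  else if (t == .mi$SINGLE) readBin(b, "double", n = tag$nbytes / 4,
                                    size = 4, endian = endian)
  else if (t == .mi$INT8) readBin(b, "integer", n = tag$nbytes, size = 1,
                                  endian = endian, signed = TRUE)
  else if (t == .mi$UINT8) as.integer(b)
  else if (t == .mi$INT16) readBin(b, "integer", n = tag$nbytes / 2,
                                   size = 2, endian = endian, signed = TRUE)
  else if (t == .mi$UINT16) readBin(b, "integer", n = tag$nbytes / 2,
                                    size = 2, endian = endian,
                                    signed = FALSE)
  else if (t == .mi$INT32) readBin(b, "integer", n = tag$nbytes / 4,
                                   size = 4, endian = endian)
  else if (t == .mi$UINT32) {
    v <- readBin(b, "integer", n = tag$nbytes / 4, size = 4, endian = endian)
    ifelse(v < 0, v + 2^32, v)
  } else stop_trggc(sprintf("unsupported MAT data type %d", t))
}

# parse a miMATRIX payload (raw slice); returns list(name, value)
mat_parse_matrix <- function(body, endian) {
  pos <- 1L
  tg <- mat_read_tag(body, pos, endian)             # array flags
  flags <- readBin(body[tg$data_start:(tg$data_start + 3)], "integer",
                   n = 1, size = 4, endian = endian)
  class_id <- bitwAnd(flags, 0xFFL)
  pos <- pos + mat_elem_total(tg)
  tg <- mat_read_tag(body, pos, endian)             # dimensions
  dims <- readBin(body[tg$data_start:(tg$data_start + tg$nbytes - 1)],
                  "integer", n = tg$nbytes / 4, size = 4, endian = endian)
  pos <- pos + mat_elem_total(tg)
  tg <- mat_read_tag(body, pos, endian)             # name
  name <- if (tg$nbytes > 0)
    rawToChar(body[tg$data_start:(tg$data_start + tg$nbytes - 1)]) else ""
  pos <- pos + mat_elem_total(tg)

  if (class_id == .mx$STRUCT) {
    tg <- mat_read_tag(body, pos, endian)           # field name length
    flen <- readBin(body[tg$data_start:(tg$data_start + 3)], "integer",
                    n = 1, size = 4, endian = endian)
    pos <- pos + mat_elem_total(tg)
    tg <- mat_read_tag(body, pos, endian)           # field names
    nfields <- tg$nbytes / flen
    fnames <- vapply(seq_len(nfields), function(k) {
      r <- body[(tg$data_start + (k - 1) * flen):
                  (tg$data_start + k * flen - 1)]
      rawToChar(r[r != as.raw(0)])
    }, character(1))
    pos <- pos + mat_elem_total(tg)
    if (prod(dims) != 1L)
      stop_trggc("only scalar (1x1) structs are supported")
    value <- vector("list", nfields)
    names(value) <- fnames
    for (k in seq_len(nfields)) {
      tg <- mat_read_tag(body, pos, endian)
      if (tg$type != .mi$MATRIX) stop_trggc("malformed struct field")
      sub <- mat_parse_matrix(
        body[tg$data_start:(tg$data_start + tg$nbytes - 1)], endian)
      value[[k]] <- sub$value
      pos <- pos + mat_elem_total(tg)
    }
  } else if (class_id == .mx$CHAR) {
    tg <- mat_read_tag(body, pos, endian)
    if (tg$type %in% c(.mi$UINT16, .mi$UTF16)) {
      codes <- readBin(body[tg$data_start:(tg$data_start + tg$nbytes - 1)],
                       "integer", n = tg$nbytes / 2, size = 2,
                       endian = endian, signed = FALSE)
      value <- intToUtf8(codes)
    } else {
      value <- rawToChar(body[tg$data_start:(tg$data_start + tg$nbytes - 1)])
    }
  } else {
    # numeric array of any class: convert to double, honor dimensions
    tg <- mat_read_tag(body, pos, endian)
    v <- as.double(mat_read_numeric_payload(body, tg, endian))
    value <- if (length(dims) > 1L && !(length(dims) == 2L &&
                                        dims[1] == 1L && dims[2] == 1L))
      array(v, dim = dims) else v
    if (length(dims) == 2L && dims[1] == 1L && dims[2] == 1L)
      value <- v[1]
  }
  list(name = name, value = value)
}

#' Read a Level-5 MAT-file
#'
#' Reads the top-level variables of a MAT-file (v5/v6/v7 dialects, including
#' zlib-compressed elements).  Supports numeric arrays, character data and
#' scalar structs; complex, sparse, cell and object arrays are not.
#'
#' @param path file path.
#' @return named list of variables.
#' @export
read_mat <- function(path) {
  if (!file.exists(path)) stop_trggc("file not found: ", path)
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  rw <- readBin(con, "raw", sz)
  if (length(rw) < 132) stop_trggc("not a MAT-file (too short)")
  desc <- rawToChar(rw[1:20])
  if (grepl("MATLAB 7.3", desc))
    stop_trggc("MATLAB v7.3 files are HDF5 containers, not supported; ",
               "re-save with '-v7'")
  if (!grepl("^MATLAB 5", desc))
    stop_trggc("not a Level-5 MAT-file (header: '",
               trimws(rawToChar(rw[1:40])), "')")
  endian <- if (rawToChar(rw[127:128]) == "IM") "little" else "big"
  pos <- 129L
  out <- list()
  while (pos + 7L <= length(rw)) {
    tg <- mat_read_tag(rw, pos, endian)
    if (tg$type == .mi$COMPRESSED) {
      z <- rw[tg$data_start:(tg$data_start + tg$nbytes - 1)]
      inner <- memDecompress(z, type = "gzip")
      itg <- mat_read_tag(inner, 1L, endian)
      if (itg$type != .mi$MATRIX)
        stop_trggc("unexpected element inside compressed block")
      pv <- mat_parse_matrix(
        inner[itg$data_start:(itg$data_start + itg$nbytes - 1)], endian)
      out[[pv$name]] <- pv$value
    } else if (tg$type == .mi$MATRIX) {
      pv <- mat_parse_matrix(
        rw[tg$data_start:(tg$data_start + tg$nbytes - 1)], endian)
      out[[pv$name]] <- pv$value
    }
    pos <- pos + mat_elem_total(tg)
  }
  out
}
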