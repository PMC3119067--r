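#' In-memory cytometry dataset
#'
#' The basic container for list-mode cytometry data: a numeric matrix with one
#' row per event and one column per channel, the channel (parameter) names,
#' and any keyword metadata carried over from an FCS TEXT segment. Datasets
#' loaded from CSV have empty keywords.
#'
#' @param events numeric matrix, rows = events, columns = channels.
#' @param channels character vector of channel names, one per column.
#' @param keywords named character vector of FCS keywords (may be empty).
#' @return An object of class `fcs_dataset`.
#' @export
fcs_dataset <- function(events, channels, keywords = character()) {
  events <- as.matrix(events)
  if (!is.numeric(events)) cyto_value_error("event matrix must be numeric")
  channels <- as.character(channels)
  if (length(channels) != ncol(events))
    cyto_value_error("number of channel names must equal number of columns")
  if (anyDuplicated(channels))
    cyto_value_error("channel names must be unique")
  if (any(!nzchar(channels)))
    cyto_value_error("channel names must be non-empty")
  colnames(events) <- channels
  structure(
    list(events = events, channels = channels, keywords = keywords),
    class = "fcs_dataset"
  )
}

#' @export
print.fcs_dataset <- function(x, ...) {
  cat(sprintf(
    "<fcs_dataset> %d events x %d channels (%s)%s\n",
    nrow(x$events), length(x$channels),
    paste(x$channels, collapse = ", "),
    if (length(x$keywords)) sprintf(" [%d keywords]", length(x$keywords)) else ""
  ))
  invisible(x)
}

#' @export
dim.fcs_dataset <- function(x) dim(x$events)

# Case-insensitive keyword lookup ($-keywords are case-insensitive in FCS).
kw_get <- function(keywords, key) {
  hit <- which(toupper(names(keywords)) == toupper(key))
  if (!length(hit)) return(NA_character_)
  keywords[[hit[1]]]
}

kw_int <- function(keywords, key) {
  v <- suppressWarnings(as.integer(kw_get(keywords, key)))
  v
}

# ---------------------------------------------------------------------------
# TEXT segment

#' Parse an FCS TEXT segment
#'
#' The TEXT segment is a delimiter-framed sequence of keyword/value pairs.
#' The first byte defines the delimiter; a delimiter appearing inside a value
#' is escaped by doubling and is unescaped to a single literal character here.
#'
#' @param bytes raw vector covering the TEXT segment, delimiter-framed.
#' @return Named character vector of keyword values, in file order, with the
#'   delimiter attached as attribute `"delimiter"`.
#' @export
parse_text_segment <- function(bytes) {
  if (!is.raw(bytes)) bytes <- charToRaw(paste(bytes, collapse = ""))
  if (length(bytes) < 2)
    cyto_malformed_text_error("TEXT segment shorter than two bytes")
  delim <- rawToChar(bytes[1])
  if (rawToChar(bytes[length(bytes)]) != delim)
    cyto_malformed_text_error("TEXT segment does not end with its delimiter")
  content <- rawToChar(bytes[seq(2, length(bytes) - 1)])
  # a doubled delimiter is a literal delimiter inside a value
  sentinel <- "\x1e"
  esc <- gsub(paste0(delim, delim), sentinel, content, fixed = TRUE)
  tokens <- strsplit(esc, delim, fixed = TRUE)[[1]]
  tokens <- gsub(sentinel, delim, tokens, fixed = TRUE)
  if (length(tokens) == 0)
    cyto_malformed_text_error("TEXT segment contains no keyword/value pairs")
  if (length(tokens) %% 2 != 0)
    cyto_malformed_text_error(sprintf(
      "TEXT segment has an odd number of tokens (%d)", length(tokens)))
  keys <- tokens[seq(1, length(tokens), by = 2)]
  vals <- tokens[seq(2, length(tokens), by = 2)]
  if (any(!nzchar(keys)))
    cyto_malformed_text_error("TEXT segment contains an empty keyword")
  names(vals) <- keys
  attr(vals, "delimiter") <- delim
  vals
}

required_fcs_keys <- function(n_par) {
  c("$PAR", "$TOT", "$MODE", "$DATATYPE", "$BYTEORD",
    paste0("$P", seq_len(n_par), "B"),
    paste0("$P", seq_len(n_par), "E"),
    paste0("$P", seq_len(n_par), "R"),
    paste0("$P", seq_len(n_par), "N"))
}

# ---------------------------------------------------------------------------
# Reading

header_offset <- function(raw, from, to) {
  txt <- trimws(rawToChar(raw[from:to]))
  if (!nzchar(txt)) return(NA_integer_)
  suppressWarnings(as.integer(txt))
}

byteord_endian <- function(byteord) {
  switch(byteord,
    "1,2,3,4" = "little",
    "4,3,2,1" = "big",
    cyto_value_error(sprintf("unsupported $BYTEORD '%s' (mixed byte orders are not supported)", byteord))
  )
}

#' Read an FCS 3.0 list-mode file
#'
#' Parses the HEADER and TEXT segments and decodes the DATA segment according
#' to `$DATATYPE` (`I` with a uniform `$PnB` of 8/16/32 bits, `F` float32, or
#' `D` float64) and `$BYTEORD` (`1,2,3,4` or `4,3,2,1`). Only list mode
#' (`$MODE L`) is supported. When the HEADER data offsets are zero the
#' `$BEGINDATA`/`$ENDDATA` keywords are used instead (the FCS 3.0 large-file
#' convention). No amplification (`$PnE`) scaling is applied: stored values
#' are surfaced as written, keeping I/O lossless; scaling belongs to the
#' transform layer.
#'
#' @param path path to an FCS 3.0 file.
#' @return An [fcs_dataset] with keywords preserved verbatim.
#' @export
read_fcs <- function(path) {
  if (!file.exists(path)) cyto_io_error(sprintf("file not found: %s", path))
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 58) cyto_corrupt_error("file too short for an FCS header")
  version <- rawToChar(raw[1:6])
  if (version != "FCS3.0")
    cyto_version_error(sprintf("unsupported FCS version '%s' (only FCS3.0 is supported)", version))

  text_begin <- header_offset(raw, 11, 18)
  text_end <- header_offset(raw, 19, 26)
  if (is.na(text_begin) || is.na(text_end) ||
      text_begin < 1 || text_end > length(raw) || text_end <= text_begin)
    cyto_corrupt_error("invalid TEXT segment offsets in header")
  # offsets are 0-based byte positions; R indexing is 1-based
  kw <- parse_text_segment(raw[(text_begin + 1):(text_end + 1)])

  n_par <- kw_int(kw, "$PAR")
  n_tot <- kw_int(kw, "$TOT")
  if (is.na(n_par) || is.na(n_tot))
    cyto_corrupt_error("missing or non-numeric $PAR/$TOT")
  missing_keys <- setdiff(required_fcs_keys(n_par), toupper(names(kw)))
  if (length(missing_keys))
    cyto_corrupt_error(sprintf("required keywords missing: %s",
                               paste(missing_keys, collapse = ", ")))

  mode <- kw_get(kw, "$MODE")
  if (toupper(mode) != "L")
    cyto_mode_error(sprintf("unsupported $MODE '%s' (only list mode is supported)", mode))

  data_begin <- header_offset(raw, 27, 34)
  data_end <- header_offset(raw, 35, 42)
  if (is.na(data_begin) || is.na(data_end) || data_begin == 0 || data_end == 0) {
    data_begin <- kw_int(kw, "$BEGINDATA")
    data_end <- kw_int(kw, "$ENDDATA")
  }
  if (is.na(data_begin) || is.na(data_end) ||
      data_begin < 1 || data_end > length(raw) - 1 || data_end < data_begin)
    cyto_corrupt_error("invalid DATA segment offsets")

  datatype <- toupper(kw_get(kw, "$DATATYPE"))
  endian <- byteord_endian(kw_get(kw, "$BYTEORD"))
  bits <- vapply(seq_len(n_par),
                 function(i) kw_int(kw, sprintf("$P%dB", i)), integer(1))
  n_values <- n_par * n_tot

  if (datatype %in% c("F", "D")) {
    size <- if (datatype == "F") 4L else 8L
    if (any(bits != size * 8L))
      cyto_corrupt_error(sprintf("$PnB must be %d for $DATATYPE %s", size * 8L, datatype))
  } else if (datatype == "I") {
    if (length(unique(bits)) != 1L)
      cyto_value_error("mixed per-parameter $PnB widths are not supported for $DATATYPE I")
    if (!bits[1] %in% c(8L, 16L, 32L))
      cyto_value_error(sprintf("unsupported $PnB %d for $DATATYPE I", bits[1]))
    size <- bits[1] %/% 8L
  } else {
    cyto_value_error(sprintf("unsupported $DATATYPE '%s'", datatype))
  }

  n_bytes <- n_values * size
  avail <- data_end - data_begin + 1L
  if (avail < n_bytes)
    cyto_corrupt_error(sprintf(
      "DATA segment truncated: %d bytes available, %d required", avail, n_bytes))
  data_raw <- raw[(data_begin + 1):(data_begin + n_bytes)]

  values <- if (datatype %in% c("F", "D")) {
    readBin(data_raw, "double", n = n_values, size = size, endian = endian)
  } else if (size < 4L) {
    as.double(readBin(data_raw, "integer", n = n_values, size = size,
                      signed = FALSE, endian = endian))
  } else {
    v <- as.double(readBin(data_raw, "integer", n = n_values, size = 4L,
                           endian = endian))
    ifelse(v < 0, v + 2^32, v)  # reinterpret as unsigned 32-bit
  }
  if (anyNA(values) || any(is.nan(values)))
    cyto_corrupt_error("DATA segment decodes to NaN values")

  # list mode: each event's channel values are stored consecutively
  events <- matrix(values, nrow = n_tot, ncol = n_par, byrow = TRUE)
  channels <- vapply(seq_len(n_par),
                     function(i) kw_get(kw, sprintf("$P%dN", i)), character(1))
  fcs_dataset(events, channels, keywords = kw)
}

# ---------------------------------------------------------------------------
# Writing

fcs_pad_offset <- function(x) {
  s <- sprintf("%d", x)
  if (nchar(s) > 8) s <- "0"  # does not fit the 8-char header field
  formatC(s, width = 8, flag = " ")
}

#' Write an FCS 3.0 list-mode file
#'
#' Regenerates all size/offset and shape keywords (`$PAR`, `$TOT`, `$PnB`,
#' `$PnN`, `$BEGINDATA`, ...) from the dataset, preserves every other keyword
#' verbatim, and writes the DATA segment in the requested encoding. The
#' default encoding is the dataset's own `$DATATYPE` when present, float64
#' otherwise, so that a write/read cycle is numerically lossless.
#'
#' @param ds an [fcs_dataset]; must be non-empty with unique channel names.
#' @param path output path.
#' @param datatype `"F"` (float32), `"D"` (float64) or `"I"` (unsigned
#'   integer); `NULL` keeps the dataset's `$DATATYPE`, falling back to `"D"`.
#' @param byteord `"1,2,3,4"` (little-endian) or `"4,3,2,1"` (big-endian).
#' @param int_bits bits per value for `datatype = "I"` (8, 16 or 32).
#' @return `path`, invisibly.
#' @export
write_fcs <- function(ds, path, datatype = NULL, byteord = "1,2,3,4",
                      int_bits = 32L) {
  stopifnot(inherits(ds, "fcs_dataset"))
  if (nrow(ds$events) == 0) cyto_value_error("cannot write an empty dataset")
  if (is.null(datatype)) {
    datatype <- kw_get(ds$keywords, "$DATATYPE")
    if (is.na(datatype)) datatype <- "D"
  }
  datatype <- toupper(datatype)
  endian <- byteord_endian(byteord)
  n_tot <- nrow(ds$events)
  n_par <- ncol(ds$events)
  values <- as.vector(t(ds$events))  # list mode: event-major

  if (datatype == "F") {
    size <- 4L; bits <- 32L
  } else if (datatype == "D") {
    size <- 8L; bits <- 64L
  } else if (datatype == "I") {
    if (!int_bits %in% c(8L, 16L, 32L))
      cyto_value_error("int_bits must be 8, 16 or 32")
    if (any(values != round(values)) || any(values < 0) ||
        any(values > 2^int_bits - 1))
      cyto_value_error(sprintf(
        "values are not representable as unsigned %d-bit integers", int_bits))
    size <- int_bits %/% 8L; bits <- as.integer(int_bits)
  } else {
    cyto_value_error(sprintf("unsupported datatype '%s'", datatype))
  }

  rng <- if (datatype == "I") 2^bits else 262144
  kw <- ds$keywords
  drop <- c("$PAR", "$TOT", "$MODE", "$DATATYPE", "$BYTEORD", "$NEXTDATA",
            "$BEGINDATA", "$ENDDATA", "$BEGINANALYSIS", "$ENDANALYSIS",
            "$BEGINSTEXT", "$ENDSTEXT",
            unlist(lapply(c("B", "E", "R", "N"),
                          function(s) sprintf("$P%d%s", seq_len(max(n_par, 99)), s))))
  keep <- kw[!(toupper(names(kw)) %in% toupper(drop))]

  entries <- c(
    "$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
    "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0",
    "$BEGINDATA" = "%BD%", "$ENDDATA" = "%ED%",
    "$NEXTDATA" = "0",
    "$MODE" = "L", "$DATATYPE" = datatype, "$BYTEORD" = byteord,
    "$PAR" = as.character(n_par), "$TOT" = as.character(n_tot)
  )
  pn <- character(0)
  for (i in seq_len(n_par)) {
    p <- c(as.character(bits), "0,0", as.character(rng), ds$channels[i])
    names(p) <- sprintf("$P%d%s", i, c("B", "E", "R", "N"))
    pn <- c(pn, p)
  }
  entries <- c(entries, pn, keep)

  delim <- "/"
  esc <- function(s) gsub(delim, paste0(delim, delim), s, fixed = TRUE)
  build_text <- function(e) {
    paste0(delim,
           paste0(vapply(names(e), esc, character(1)), delim,
                  vapply(unname(e), esc, character(1)), delim,
                  collapse = ""))
  }
  # offsets depend on the TEXT length; fixed-width offset values break the cycle
  entries[["$BEGINDATA"]] <- sprintf("%012d", 0)
  entries[["$ENDDATA"]] <- sprintf("%012d", 0)
  text_len <- nchar(build_text(entries), type = "bytes")
  header_len <- 58L
  text_begin <- header_len
  text_end <- text_begin + text_len - 1L
  data_begin <- text_end + 1L
  data_end <- data_begin + length(values) * size - 1L
  entries[["$BEGINDATA"]] <- sprintf("%012d", data_begin)
  entries[["$ENDDATA"]] <- sprintf("%012d", data_end)
  text <- build_text(entries)
  stopifnot(nchar(text, type = "bytes") == text_len)

  header <- paste0(
    "FCS3.0    ",
    fcs_pad_offset(text_begin), fcs_pad_offset(text_end),
    if (data_end <= 99999999) paste0(fcs_pad_offset(data_begin), fcs_pad_offset(data_end))
    else paste0(fcs_pad_offset(0), fcs_pad_offset(0)),
    fcs_pad_offset(0), fcs_pad_offset(0)
  )
  stopifnot(nchar(header, type = "bytes") == header_len)

  con <- tryCatch(file(path, "wb"),
                  error = function(e) cyto_io_error(conditionMessage(e)),
                  warning = function(w) cyto_io_error(conditionMessage(w)))
  on.exit(close(con), add = TRUE)
  writeBin(charToRaw(header), con)
  writeBin(charToRaw(text), con)
  if (datatype %in% c("F", "D")) {
    writeBin(values, con, size = size, endian = endian)
  } else {
    ints <- values
    if (bits == 32L) ints <- ifelse(ints >= 2^31, ints - 2^32, ints)
    writeBin(as.integer(ints), con, size = size, endian = endian)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# CSV event tables

#' Read a CSV event table
#'
#' Expects a header row of unique channel names followed by numeric rows,
#' comma-separated with `.` as the decimal mark.
#'
#' @param path path to the CSV file.
#' @return An [fcs_dataset] with empty keywords.
#' @export
read_events_csv <- function(path) {
  if (!file.exists(path)) cyto_io_error(sprintf("file not found: %s", path))
  df <- tryCatch(
    utils::read.csv(path, check.names = FALSE, colClasses = "character"),
    error = function(e) cyto_parse_error(conditionMessage(e))
  )
  channels <- names(df)
  if (anyDuplicated(channels))
    cyto_parse_error(sprintf(
      "duplicate channel names in header: %s",
      paste(unique(channels[duplicated(channels)]), collapse = ", ")))
  mat <- matrix(NA_real_, nrow = nrow(df), ncol = length(channels))
  for (j in seq_along(channels)) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(is.na(v))
    if (length(bad))
      cyto_parse_error(sprintf(
        "non-numeric value '%s' at row %d, column %d (%s)",
        df[[j]][bad[1]], bad[1], j, channels[j]))
    mat[, j] <- v
  }
  fcs_dataset(mat, channels)
}

#' Write a CSV event table
#'
#' Values are printed with 17 significant digits so that a write/read cycle
#' reproduces doubles exactly.
#'
#' @param ds an [fcs_dataset].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(ds, path) {
  stopifnot(inherits(ds, "fcs_dataset"))
  header <- paste(ds$channels, collapse = ",")
  body <- apply(ds$events, 1, function(row)
    paste(sprintf("%.17g", row), collapse = ","))
  ok <- tryCatch({
    writeLines(c(header, body), path)
    TRUE
  }, error = function(e) cyto_io_error(conditionMessage(e)),
     warning = function(w) cyto_io_error(conditionMessage(w)))
  invisible(path)
}
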