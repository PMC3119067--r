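test_that("FCS write/read round trip is lossless for float data", {
  set.seed(101)
  for (case in 1:5) {
    n <- sample(1:80, 1); c <- sample(1:6, 1)
    ds <- random_dataset(n, c)
    path <- withr::local_tempfile(fileext = ".fcs")
    write_fcs(ds, path)  # default float64
    back <- read_fcs(path)
    expect_identical(unname(back$events), unname(ds$events))
    expect_identical(back$channels, ds$channels)
    expect_equal(kw_int(back$keywords, "$TOT"), n)
    expect_equal(kw_int(back$keywords, "$PAR"), c)
  }
})

test_that("degenerate 1-event 1-channel dataset writes a valid file", {
  ds <- fcs_dataset(matrix(3.5), "FSC")
  path <- withr::local_tempfile(fileext = ".fcs")
  write_fcs(ds, path)
  back <- read_fcs(path)
  expect_equal(unname(back$events), matrix(3.5))
  expect_identical(kw_get(back$keywords, "$TOT"), "1")
  expect_identical(kw_get(back$keywords, "$PAR"), "1")
})

test_that("both byte orders decode to identical matrices", {
  ds <- random_dataset(25, 4, seed = 7)
  little <- withr::local_tempfile(fileext = ".fcs")
  big <- withr::local_tempfile(fileext = ".fcs")
  write_fcs(ds, little, byteord = "1,2,3,4")
  write_fcs(ds, big, byteord = "4,3,2,1")
  expect_false(identical(readBin(little, "raw", file.size(little)),
                         readBin(big, "raw", file.size(big))))
  expect_identical(read_fcs(little)$events, read_fcs(big)$events)
})

test_that("float32 files round trip bitwise once values are float32", {
  set.seed(5)
  raw_vals <- matrix(runif(40, 0, 1e4), 10, 4)
  ds <- fcs_dataset(raw_vals, paste0("CH", 1:4))
  path <- withr::local_tempfile(fileext = ".fcs")
  write_fcs(ds, path, datatype = "F")
  once <- read_fcs(path)
  # the first write quantizes doubles to float32; from then on it is exact
  path2 <- withr::local_tempfile(fileext = ".fcs")
  write_fcs(once, path2)  # keeps $DATATYPE F from the keywords
  expect_identical(read_fcs(path2)$events, once$events)
  expect_identical(kw_get(read_fcs(path2)$keywords, "$DATATYPE"), "F")
})

test_that("integer data decodes exactly against hand-packed bytes", {
  # file assembled by hand: 3 events x 2 params, $DATATYPE I, $PnB 16, LE
  values <- c(1L, 2L, 3L, 40000L, 5L, 65535L)  # event-major
  text <- paste0(
    "/$PAR/2/$TOT/3/$MODE/L/$DATATYPE/I/$BYTEORD/1,2,3,4",
    "/$BEGINDATA/0/$ENDDATA/0",
    "/$P1B/16/$P1E/0,0/$P1R/65536/$P1N/A",
    "/$P2B/16/$P2E/0,0/$P2R/65536/$P2N/B/")
  text_begin <- 58L
  text_end <- text_begin + nchar(text) - 1L
  data_begin <- text_end + 1L
  data_end <- data_begin + length(values) * 2L - 1L
  pad8 <- function(x) formatC(x, width = 8, flag = " ")
  header <- paste0("FCS3.0    ", pad8(text_begin), pad8(text_end),
                   pad8(data_begin), pad8(data_end), pad8(0), pad8(0))
  path <- withr::local_tempfile(fileext = ".fcs")
  con <- file(path, "wb")
  writeBin(charToRaw(paste0(header, text)), con)
  # pack 16-bit little-endian by hand
  lo <- values %% 256L; hi <- values %/% 256L
  writeBin(as.raw(as.vector(rbind(lo, hi))), con)
  close(con)
  back <- read_fcs(path)
  expect_equal(unname(back$events),
               matrix(as.double(values), 3, 2, byrow = TRUE))
})

test_that("integer write path round trips 8/16/32-bit values", {
  for (bits in c(8L, 16L, 32L)) {
    set.seed(bits)
    vals <- matrix(sample(0:(2^min(bits, 31) - 1), 24, replace = TRUE), 8, 3)
    ds <- fcs_dataset(vals, paste0("CH", 1:3))
    path <- withr::local_tempfile(fileext = ".fcs")
    write_fcs(ds, path, datatype = "I", int_bits = bits)
    expect_equal(unname(read_fcs(path)$events), unname(ds$events) * 1.0)
  }
})

test_that("renamed channels propagate to $PnN on write", {
  ds <- random_dataset(5, 2, seed = 1)
  ws <- cyto_workspace()
  id <- ws_add_dataset(ws, ds)
  rename_channel(ws, id, 1, "FSC-H")
  path <- withr::local_tempfile(fileext = ".fcs")
  write_fcs(ws_node(ws, id)$data, path)
  kw <- read_fcs(path)$keywords
  expect_identical(kw_get(kw, "$P1N"), "FSC-H")
})

test_that("non-size keywords survive a write/read cycle", {
  ds <- random_dataset(6, 2, seed = 2)
  ds$keywords <- c("$CYT" = "SimCytometer", "EXPERIMENT" = "run 1")
  path <- withr::local_tempfile(fileext = ".fcs")
  write_fcs(ds, path)
  kw <- read_fcs(path)$keywords
  expect_identical(kw_get(kw, "$CYT"), "SimCytometer")
  expect_identical(kw_get(kw, "EXPERIMENT"), "run 1")
})

test_that("version, mode and truncation errors are classed", {
  path <- withr::local_tempfile(fileext = ".fcs")
  ds <- random_dataset(4, 2, seed = 3)
  write_fcs(ds, path)
  raw <- readBin(path, "raw", file.size(path))

  bad_version <- raw; bad_version[4] <- charToRaw("2")
  vp <- withr::local_tempfile(); writeBin(bad_version, vp)
  expect_error(read_fcs(vp), class = "cytopop_version_error")

  truncated <- raw[1:(length(raw) - 8)]
  tp <- withr::local_tempfile(); writeBin(truncated, tp)
  expect_error(read_fcs(tp), class = "cytopop_corrupt_file_error")

  # rewrite with $MODE C (correlated histograms) at identical text length
  mode_c <- raw
  mode_pos <- grepRaw("/\\$MODE/L/", raw)
  mode_c[mode_pos + 7] <- charToRaw("C")
  mp <- withr::local_tempfile(); writeBin(mode_c, mp)
  expect_error(read_fcs(mp), class = "cytopop_unsupported_mode_error")
})

test_that("TEXT segment parsing handles escapes and malformed input", {
  kw <- parse_text_segment(charToRaw("/$PAR/2/$TOT/3/"))
  expect_identical(kw[["$PAR"]], "2")
  expect_identical(kw[["$TOT"]], "3")
  expect_identical(attr(kw, "delimiter"), "/")

  # doubled delimiter inside a value unescapes to one literal delimiter
  kw2 <- parse_text_segment(charToRaw("/$FIL/a//b.fcs/$TOT/1/"))
  expect_identical(kw2[["$FIL"]], "a/b.fcs")

  expect_error(parse_text_segment(charToRaw("//")),
               class = "cytopop_malformed_text_error")
  expect_error(parse_text_segment(charToRaw("/$PAR/2/$TOT/")),
               class = "cytopop_malformed_text_error")
})

test_that("CSV round trip preserves doubles exactly and flags bad cells", {
  set.seed(9)
  ds <- fcs_dataset(matrix(rnorm(50) * 1e3, 10, 5), paste0("CH", 1:5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_events_csv(ds, path)
  back <- read_events_csv(path)
  expect_identical(unname(back$events), unname(ds$events))
  expect_identical(back$channels, ds$channels)
  expect_length(back$keywords, 0)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("FSC,SSC", "1,2", "3,oops"), bad)
  err <- tryCatch(read_events_csv(bad), condition = identity)
  expect_s3_class(err, "cytopop_parse_error")
  expect_match(conditionMessage(err), "row 2, column 2")

  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("FSC,FSC", "1,2"), dup)
  expect_error(read_events_csv(dup), class = "cytopop_parse_error")
})

test_that("small CSV loads with expected shape", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("FSC,SSC", "1,2", "3,4", "5,6"), path)
  ds <- read_events_csv(path)
  expect_equal(dim(ds$events), c(3L, 2L))
  expect_identical(ds$channels, c("FSC", "SSC"))
})
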