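# Minimal FCS 3.0/3.1 support: a reader covering list-mode float/double
# files and a fixture writer used by the simulator and the tests. No R FCS
# parser is available in this stack, so the segment handling lives here.
# Reference: ISAC FCS3.1 file standard (header + delimited TEXT + DATA).

FCS_HEADER_LEN <- 58L

#' Write a cell matrix as an FCS 3.1 file (fixture writer)
#'
#' List mode, 64-bit float, little-endian, linear scaling (doubles keep
#' the round trip exact). Marker names go
#' into $PnS (stain) and channel ids into $PnN, which is how the reader
#' matches the panel.
#'
#' @param m a raw-transform [cell_matrix()].
#' @param path output path.
#' @param panel optional `panel_definition` supplying channel ids for the
#'   markers; synthetic ids are used otherwise.
#' @return `path`, invisibly.
#' @export
write_fcs <- function(m, path, panel = NULL) {
  stopifnot(inherits(m, "cell_matrix"))
  if (m$transform != "raw") stop("fixture writer expects raw intensities")
  n <- nrow(m$values); p <- ncol(m$values)
  chan <- if (!is.null(panel)) {
    idx <- match(m$marker_names, panel$entries$marker)
    if (anyNA(idx)) stop("panel lacks channel for: ",
                         paste(m$marker_names[is.na(idx)], collapse = ", "))
    panel$entries$channel_id[idx]
  } else sprintf("ch%02d", seq_len(p))

  kw <- c("$DATATYPE" = "D", "$MODE" = "L", "$BYTEORD" = "1,2,3,4",
          "$PAR" = as.character(p), "$TOT" = as.character(n),
          "$NEXTDATA" = "0")
  for (j in seq_len(p)) {
    kw[sprintf("$P%dB", j)] <- "64"
    kw[sprintf("$P%dE", j)] <- "0,0"
    kw[sprintf("$P%dR", j)] <- "262144"
    kw[sprintf("$P%dN", j)] <- chan[j]
    kw[sprintf("$P%dS", j)] <- m$marker_names[j]
  }
  # BEGINDATA/ENDDATA written zero-padded so the TEXT length is fixed
  # before the offsets are known.
  data_len <- 8L * n * p
  make_text <- function(db, de) {
    body <- paste0("/", paste(rbind(names(kw), unname(kw)), collapse = "/"),
                   "/$BEGINDATA/", sprintf("%010d", db),
                   "/$ENDDATA/", sprintf("%010d", de), "/")
    body
  }
  text_len <- nchar(make_text(0, 0), type = "bytes")
  data_begin <- FCS_HEADER_LEN + text_len
  data_end <- data_begin + data_len - 1L
  text <- make_text(data_begin, data_end)

  hdr_num <- function(x) {
    if (x > 99999999) "       0" else sprintf("%8d", x)
  }
  header <- paste0(sprintf("%-10s", "FCS3.1"),
                   hdr_num(FCS_HEADER_LEN),
                   hdr_num(FCS_HEADER_LEN + text_len - 1L),
                   hdr_num(data_begin), hdr_num(data_end),
                   hdr_num(0), hdr_num(0))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(text, con, eos = NULL)
  writeBin(as.vector(t(m$values)), con, size = 8L, endian = "little")
  invisible(path)
}

parse_fcs_text <- function(raw_text) {
  delim <- rawToChar(raw_text[1L])
  body <- rawToChar(raw_text[-1L])
  parts <- strsplit(body, delim, fixed = TRUE)[[1L]]
  # trailing delimiter produces a final "" which strsplit drops; an odd
  # count means a stray element, tolerated as an empty value
  if (length(parts) %% 2L == 1L) parts <- c(parts, "")
  keys <- parts[seq(1L, length(parts), by = 2L)]
  vals <- parts[seq(2L, length(parts), by = 2L)]
  stats::setNames(as.list(trimws(vals)), toupper(trimws(keys)))
}

#' Read an FCS 3.0/3.1 file against a panel
#'
#' Channels are matched to panel markers via the $PnS (stain) field first,
#' falling back to $PnN, case-insensitively; $PnN may also carry the
#' panel's channel id. The result is restricted to the panel's non-ignore
#' channels in panel order, with `transform = "raw"`.
#'
#' @param path an FCS file.
#' @param panel a [panel_definition()] covering the file's channels.
#' @param sample_id sample id to attach (default: file name sans extension).
#' @return A raw [cell_matrix()].
#' @export
read_fcs <- function(path, panel, sample_id = NULL) {
  stopifnot(inherits(panel, "panel_definition"))
  sz <- file.info(path)$size
  if (is.na(sz) || sz < FCS_HEADER_LEN) stop("not an FCS file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readChar(con, FCS_HEADER_LEN, useBytes = TRUE)
  version <- substr(header, 1L, 6L)
  if (!version %in% c("FCS3.0", "FCS3.1")) {
    stop("unsupported FCS version or not an FCS file: '", version, "'")
  }
  off <- suppressWarnings(as.integer(substring(
    header, 10L + 8L * (0:5) + 1L, 10L + 8L * (1:6))))
  if (anyNA(off[1:2])) stop("malformed FCS header in ", path)
  seek(con, off[1L])
  kw <- parse_fcs_text(readBin(con, "raw", off[2L] - off[1L] + 1L))

  dtype <- toupper(kw[["$DATATYPE"]] %||% "")
  if (!dtype %in% c("F", "D")) stop("unsupported $DATATYPE '", dtype, "'")
  if (toupper(kw[["$MODE"]] %||% "L") != "L") stop("only list mode supported")
  endian <- if (grepl("^4", kw[["$BYTEORD"]] %||% "1,2,3,4")) "big" else "little"
  p <- as.integer(kw[["$PAR"]]); n <- as.integer(kw[["$TOT"]])
  data_begin <- off[3L]; data_end <- off[4L]
  if (is.na(data_begin) || data_begin == 0L) {
    data_begin <- as.integer(kw[["$BEGINDATA"]])
    data_end <- as.integer(kw[["$ENDDATA"]])
  }
  word <- if (dtype == "F") 4L else 8L
  seek(con, data_begin)
  vals <- readBin(con, "numeric", n * p, size = word, endian = endian)
  mat <- matrix(vals, nrow = n, ncol = p, byrow = TRUE)

  pnn <- vapply(seq_len(p), function(j) kw[[sprintf("$P%dN", j)]] %||% "",
                character(1))
  pns <- vapply(seq_len(p), function(j) kw[[sprintf("$P%dS", j)]] %||% "",
                character(1))
  live <- panel$entries[panel$entries$category != "ignore", , drop = FALSE]
  col_idx <- integer(nrow(live))
  for (i in seq_len(nrow(live))) {
    mk <- tolower(live$marker[i]); ch <- tolower(live$channel_id[i])
    hit <- which(tolower(pns) == mk)
    if (!length(hit)) hit <- which(tolower(pnn) %in% c(mk, ch))
    if (!length(hit)) {
      stop("channel for marker '", live$marker[i], "' not found in ", path)
    }
    col_idx[i] <- hit[1L]
  }
  if (is.null(sample_id)) sample_id <- sub("\\.[^.]*$", "", basename(path))
  cell_matrix(mat[, col_idx, drop = FALSE], sample_id, live$marker,
              transform = "raw")
}
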