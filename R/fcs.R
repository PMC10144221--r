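# Minimal FCS 3.0 list-mode I/O.  Covers the subset this package needs
# (and writes): one dataset, linear values, float32 or integer data,
# little- or big-endian.  No installed package reads FCS, so the format
# is handled here directly against the FCS 3.0 layout: a 58-byte ASCII
# header with segment offsets, a delimited TEXT segment of keyword
# pairs, and a binary DATA segment.

.fcs_delim <- "/"

#' Write an event table as an FCS 3.0 file
#'
#' List mode, float32 little-endian, linear amplification.
#'
#' @param events An [event_table()].
#' @param path Output path (`.fcs`).
#' @return `path`, invisibly.
#' @export
write_fcs <- function(events, path) {
  stopifnot(inherits(events, "event_table"))
  chans <- c("fsc", "ssc", "green", "red")
  n <- nrow(events); p <- length(chans)
  kw <- c("$DATATYPE", "F", "$MODE", "L", "$BYTEORD", "1,2,3,4",
          "$PAR", p, "$TOT", n, "$NEXTDATA", "0")
  for (i in seq_len(p))
    kw <- c(kw,
            sprintf("$P%dN", i), chans[i],
            sprintf("$P%dB", i), "32",
            sprintf("$P%dE", i), "0,0",
            sprintf("$P%dR", i), format(ceiling(max(events[[chans[i]]], 1)),
                                        scientific = FALSE))
  d <- .fcs_delim
  text <- paste0(d, paste(kw, collapse = d), d)
  # header: 6-byte version, 4 spaces, six 8-byte right-justified offsets
  text_start <- 58
  text_end <- text_start + nchar(text) - 1
  data_start <- text_end + 1
  data_end <- data_start + 4 * n * p - 1
  hdr <- sprintf("FCS3.0    %8d%8d%8d%8d%8d%8d",
                 text_start, text_end, data_start, data_end, 0, 0)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(hdr, con, eos = NULL)
  writeChar(text, con, eos = NULL)
  m <- t(as.matrix(as.data.frame(events)[chans]))
  writeBin(as.numeric(m), con, size = 4, endian = "little")
  invisible(path)
}

#' Read an FCS 3.0/3.1 list-mode file
#'
#' Supports linear list-mode data of type `F` (float32), `D` (float64)
#' or `I` (integer, byte widths 8/16/32), in either byte order.
#'
#' @param path Path to the FCS file.
#' @param channel_map Optional channel-name mapping applied to the
#'   `$PnN` names, see [event_table()].
#' @return An [event_table()].
#' @export
read_fcs <- function(path, channel_map = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- rawToChar(readBin(con, "raw", 58))
  version <- substr(hdr, 1, 6)
  if (!version %in% c("FCS3.0", "FCS3.1"))
    stop("parse error: unsupported FCS version '", trimws(version), "'")
  off <- suppressWarnings(as.numeric(c(
    substr(hdr, 11, 18), substr(hdr, 19, 26),
    substr(hdr, 27, 34), substr(hdr, 35, 42))))
  if (anyNA(off)) stop("parse error: malformed FCS header")
  seek(con, off[1])
  text <- rawToChar(readBin(con, "raw", off[2] - off[1] + 1))
  d <- substr(text, 1, 1)
  parts <- strsplit(substring(text, 2), d, fixed = TRUE)[[1]]
  if (length(parts) %% 2 == 1) parts <- parts[-length(parts)]
  keys <- parts[seq(1, length(parts), 2)]
  vals <- parts[seq(2, length(parts), 2)]
  kv <- stats::setNames(vals, toupper(trimws(keys)))
  need <- c("$DATATYPE", "$PAR", "$TOT", "$BYTEORD")
  if (!all(need %in% names(kv))) stop("parse error: missing FCS keywords")
  p <- as.integer(kv["$PAR"]); n <- as.integer(kv["$TOT"])
  endian <- if (startsWith(kv["$BYTEORD"], "1")) "little" else "big"
  data_start <- off[3]
  if (data_start == 0) data_start <- as.numeric(kv["$BEGINDATA"])
  seek(con, data_start)
  type <- toupper(kv["$DATATYPE"])
  vals <- switch(type,
    F = readBin(con, "numeric", n * p, size = 4, endian = endian),
    D = readBin(con, "numeric", n * p, size = 8, endian = endian),
    I = {
      bits <- as.integer(kv["$P1B"])
      readBin(con, "integer", n * p, size = bits / 8, endian = endian,
              signed = bits > 16)
    },
    stop("parse error: unsupported $DATATYPE ", type))
  if (length(vals) < n * p) stop("parse error: truncated DATA segment")
  m <- matrix(vals, nrow = p)
  names_p <- vapply(seq_len(p), function(i) {
    nm <- kv[sprintf("$P%dN", i)]
    if (is.na(nm)) sprintf("P%d", i) else unname(nm)
  }, character(1))
  df <- as.data.frame(t(m))
  names(df) <- names_p
  event_table(df, channel_map)
}
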