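# The Recording container and its readers/writers.

#' Multichannel biopotential recording
#'
#' @param data Numeric matrix or data frame, samples x channels, in mV.
#'   Column names are the channel names.
#' @param fs Sampling rate in Hz.
#' @param annotations Optional numeric vector of true R times in seconds
#'   (carried from synthesis).
#' @return An object of class `recording`: list with `data`, `fs`,
#'   `channels`, `annotations`.
#' @export
recording <- function(data, fs, annotations = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("`data` must be numeric", call. = FALSE)
  if (is.null(colnames(data)) || anyDuplicated(colnames(data))) {
    stop("`data` must have unique channel (column) names", call. = FALSE)
  }
  if (ncol(data) < 1L) stop("recording needs at least one channel", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a positive scalar", call. = FALSE)
  }
  structure(list(data = data, fs = fs, channels = colnames(data),
                 annotations = annotations),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              ncol(x$data), nrow(x$data), x$fs, nrow(x$data) / x$fs))
  cat("  channels:", paste(x$channels, collapse = ", "), "\n")
  if (!is.null(x$annotations)) {
    cat(sprintf("  annotations: %d true R times\n", length(x$annotations)))
  }
  invisible(x)
}

#' Extract one channel trace
#'
#' @param rec A [recording()].
#' @param channel Channel name.
#' @return Numeric vector in mV.
#' @export
get_channel <- function(rec, channel) {
  stopifnot(inherits(rec, "recording"))
  if (!channel %in% rec$channels) {
    stop("unknown channel '", channel, "'", call. = FALSE)
  }
  rec$data[, channel]
}

#' Write a recording to disk
#'
#' Two formats are supported:
#' \describe{
#'   \item{csv}{One header row `time_s,<ch1>,<ch2>,...`, comma separated,
#'     `.` decimal, full (round-trippable) precision. Sampling rate and any
#'     annotations are stored in leading `#` comment lines.}
#'   \item{wfdb}{A minimal WFDB-style record: text header `<path>.hea` plus
#'     interleaved 16-bit little-endian samples in `<path>.dat`, one
#'     ADC gain per channel. Round-trips within 1/gain per channel.}
#' }
#'
#' @param rec A [recording()].
#' @param path Output path. For `wfdb`, the record base name (a `.hea`/`.dat`
#'   pair is written next to it).
#' @param format `"csv"` or `"wfdb"`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("csv", "wfdb")) {
  stopifnot(inherits(rec, "recording"))
  format <- match.arg(format)
  if (format == "csv") {
    header <- c(sprintf("# earbeat recording"),
                sprintf("# fs=%.10g", rec$fs))
    if (!is.null(rec$annotations) && length(rec$annotations) > 0) {
      header <- c(header, paste0("# annotations_s=",
                                 paste(format(rec$annotations, digits = 15),
                                       collapse = ",")))
    }
    writeLines(header, path)
    # %.17g guarantees doubles survive the text round trip bit-exactly
    cols <- c(list(time_s = sprintf("%.17g", (seq_len(nrow(rec$data)) - 1) / rec$fs)),
              lapply(seq_along(rec$channels), function(j) {
                sprintf("%.17g", rec$data[, j])
              }))
    names(cols) <- c("time_s", rec$channels)
    data.table::fwrite(data.table::as.data.table(cols), path, append = TRUE,
                       col.names = TRUE, quote = FALSE)
  } else {
    write_wfdb(rec, path)
  }
  invisible(path)
}

#' Read a recording from disk
#'
#' @param path File path (for `wfdb`, the record base name or the `.hea`
#'   file).
#' @param format `"csv"` or `"wfdb"`.
#' @return A [recording()].
#' @export
read_recording <- function(path, format = c("csv", "wfdb")) {
  format <- match.arg(format)
  if (format == "wfdb") return(read_wfdb(path))
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, n = 10L)
  comments <- lines[startsWith(lines, "#")]
  fs_line <- grep("^# fs=", comments, value = TRUE)
  if (length(fs_line) != 1L) {
    stop("CSV recording is missing its '# fs=' header line", call. = FALSE)
  }
  fs <- as.numeric(sub("^# fs=", "", fs_line))
  ann <- NULL
  ann_line <- grep("^# annotations_s=", comments, value = TRUE)
  if (length(ann_line) == 1L) {
    ann <- as.numeric(strsplit(sub("^# annotations_s=", "", ann_line), ",")[[1]])
  }
  nf <- utils::count.fields(path, sep = ",", comment.char = "#")
  if (length(unique(nf)) > 1) {
    stop("ragged rows in CSV recording", call. = FALSE)
  }
  dt <- data.table::fread(path, skip = length(comments), header = TRUE)
  if (!"time_s" %in% names(dt)) {
    stop("CSV recording must have a 'time_s' first column", call. = FALSE)
  }
  data <- as.matrix(dt[, setdiff(names(dt), "time_s"), with = FALSE])
  if (!is.numeric(data) || anyNA(data)) {
    stop("ragged or non-numeric channel data", call. = FALSE)
  }
  recording(data, fs = fs, annotations = ann)
}

# --- minimal WFDB-style (.hea + 16-bit .dat) support --------------------

write_wfdb <- function(rec, path) {
  base <- sub("\\.hea$", "", path)
  recname <- basename(base)
  n <- nrow(rec$data)
  nsig <- ncol(rec$data)
  gains <- vapply(seq_len(nsig), function(j) {
    m <- max(abs(rec$data[, j]))
    if (m == 0) 200 else 32000 / m
  }, numeric(1))
  adc <- matrix(0L, nrow = n, ncol = nsig)
  for (j in seq_len(nsig)) {
    adc[, j] <- as.integer(pmax(-32767, pmin(32767, round(rec$data[, j] * gains[j]))))
  }
  hdr <- c(sprintf("%s %d %.10g %d", recname, nsig, rec$fs, n),
           vapply(seq_len(nsig), function(j) {
             sprintf("%s.dat 16 %.10g(0)/mV 16 0 %d 0 0 %s",
                     recname, gains[j], adc[1, j], rec$channels[j])
           }, character(1)))
  writeLines(hdr, paste0(base, ".hea"))
  con <- file(paste0(base, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.integer(t(adc)), con, size = 2L, endian = "little")
  invisible(base)
}

read_wfdb <- function(path) {
  base <- sub("\\.hea$", "", path)
  hea <- paste0(base, ".hea")
  if (!file.exists(hea)) stop("header not found: ", hea, call. = FALSE)
  lines <- readLines(hea)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  rl <- strsplit(lines[1], "\\s+")[[1]]
  nsig <- as.integer(rl[2])
  fs <- as.numeric(rl[3])
  n <- as.integer(rl[4])
  if (is.na(fs)) stop("missing sampling rate in header", call. = FALSE)
  gains <- numeric(nsig)
  chans <- character(nsig)
  for (j in seq_len(nsig)) {
    sl <- strsplit(lines[1 + j], "\\s+")[[1]]
    gspec <- sl[3]
    gains[j] <- as.numeric(sub("\\(.*$", "", sub("/.*$", "", gspec)))
    chans[j] <- paste(sl[9:length(sl)], collapse = " ")
  }
  con <- file(paste0(base, ".dat"), "rb")
  on.exit(close(con))
  raw <- readBin(con, integer(), n = n * nsig, size = 2L, endian = "little",
                 signed = TRUE)
  adc <- matrix(raw, nrow = n, ncol = nsig, byrow = TRUE)
  data <- sweep(adc, 2L, gains, "/")
  colnames(data) <- chans
  recording(data, fs = fs)
}
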