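sidecar_path <- function(path) paste0(sub("\\.[^.]+$", "", path), ".json")

#' Read a delimited time-series matrix
#'
#' Reads a CSV/TSV numeric matrix with a header row of channel labels.
#' Orientation `"long"` means one row per sample (columns are channels);
#' `"wide"` means one row per channel.  `"auto"` picks `"long"` when the
#' table has more rows than columns.  The sampling rate comes from the
#' `fs` argument or, failing that, from a JSON sidecar (`<stem>.json`
#' next to the file, containing at least `{"fs": ...}`).
#'
#' @param path path to a CSV or TSV file.
#' @param fs sampling rate in Hz; overrides any sidecar.
#' @param orientation `"auto"`, `"long"` or `"wide"`.
#' @return A [multichannel()] object (possibly with a single channel).
#' @export
read_timeseries <- function(path, fs = NULL,
                            orientation = c("auto", "long", "wide")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(fs)) {
    sc <- sidecar_path(path)
    if (file.exists(sc)) {
      meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
      fs <- meta$fs
    }
  }
  if (is.null(fs))
    stop("sampling rate unknown: pass 'fs' or provide a JSON sidecar ",
         "with an \"fs\" field next to ", path)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- read.csv(path, sep = sep, check.names = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("non-numeric values in ", path)
  if (orientation == "auto")
    orientation <- if (nrow(m) >= ncol(m)) "long" else "wide"
  if (orientation == "long") {
    multichannel(t(m), fs, labels = colnames(df))
  } else {
    multichannel(m, fs)  # header holds sample labels, not channels
  }
}

#' Write a time series (or multichannel recording) as CSV + JSON sidecar
#'
#' One column per channel, one row per sample, header row of labels; the
#' sampling rate (and any extra metadata) goes into a JSON sidecar next to
#' the file so that [read_timeseries()] can round-trip it.
#'
#' @param x a `timeseries` or `multichannel` object.
#' @param path output CSV path.
#' @param meta optional named list of extra metadata (seed, parameters...)
#'   merged into the sidecar.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(x, path, meta = list()) {
  if (inherits(x, "timeseries"))
    x <- multichannel(matrix(x$values, nrow = 1), x$fs, labels = "ch1")
  stopifnot(inherits(x, "multichannel"))
  df <- as.data.frame(t(x$values))
  colnames(df) <- x$labels
  write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(c(list(fs = x$fs), meta), sidecar_path(path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export a channel map as CSV
#'
#' Two columns: `channel`, `value` (seconds).
#'
#' @param map a `channel_map` object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_channel_map <- function(map, path) {
  stopifnot(inherits(map, "channel_map"))
  write.csv(data.frame(channel = map$labels, value = map$values),
            path, row.names = FALSE)
  invisible(path)
}
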