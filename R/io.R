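# Output conventions: .gdat (whitespace-delimited observable time courses
# with a "#"-prefixed header) and .info (key: value run metadata).

#' Write an observable time course as a .gdat file
#'
#' Whitespace-delimited text: first line `# time <name1> <name2> ...`,
#' then one row per report time, numbers in scientific notation with 8+
#' significant digits (re-readable to representation precision).
#'
#' @param times Numeric vector of report times.
#' @param values Numeric matrix (or data.frame) with one row per time and
#'   one column per observable; may have zero columns.
#' @param names Character vector of observable names (one per column).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_gdat <- function(times, values, names, path) {
  values <- as.matrix(values)
  if (length(times) != nrow(values) && !(ncol(values) == 0L))
    stop("length mismatch between times and values", call. = FALSE)
  if (ncol(values) != length(names))
    stop("one name per observable column required", call. = FALSE)
  header <- paste(c("# time", names), collapse = " ")
  rows <- vapply(seq_along(times), function(r)
    paste(sprintf("% .8e", c(times[r], if (ncol(values)) values[r, ])),
          collapse = " "), "")
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a .gdat file
#'
#' @param path Path to a file written by [write_gdat()] (or any
#'   BNGL-style .gdat).
#' @return A data.frame with column `time` and one column per observable.
#' @export
read_gdat <- function(path) {
  header <- readLines(path, n = 1L)
  cols <- strsplit(sub("^#\\s*", "", header), "\\s+")[[1L]]
  dat <- utils::read.table(path, header = FALSE, skip = 1L,
                           col.names = cols,
                           colClasses = "numeric")
  if (nrow(dat) == 0L)
    dat <- as.data.frame(stats::setNames(rep(list(numeric()), length(cols)),
                                         cols))
  dat
}

# fixed documented key order for .info files
.info_keys <- c("model", "seed", "t_end", "n_report", "events", "wall_time",
                "species_final", "molecules")

#' Write run metadata as a .info file
#'
#' `key: value` lines, keys in a fixed documented order
#' (model, seed, t_end, n_report, events, wall_time, species_final,
#' molecules), then any remaining keys in given order.  Missing keys are
#' omitted.
#'
#' @param meta Named list of metadata values.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_info <- function(meta, path) {
  keys <- c(intersect(.info_keys, names(meta)),
            setdiff(names(meta), .info_keys))
  lines <- vapply(keys, function(k)
    paste0(k, ": ", format(meta[[k]], scientific = FALSE, trim = TRUE)), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a .info file back into a named list
#'
#' @param path Path to a file written by [write_info()].
#' @return Named list of character values.
#' @export
read_info <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([^:]+):\\s*(.*)$", ln))[[1L]]
    if (length(m)) out[[m[2L]]] <- m[3L]
  }
  out
}
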