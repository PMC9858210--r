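#' Read and write kernels
#'
#' Two plain-text formats are supported. CSV: header row holds the column
#' labels, the first column holds the row labels. JSON: an object
#' `{"rows": [...], "cols": [...], "matrix": [[...], ...]}`. JSON round-trips
#' are exact (full double precision via 17 significant digits); CSV
#' round-trips to at least `1e-12`.
#'
#' @param path File path.
#' @param format `"csv"` or `"json"`; inferred from the file extension when
#'   missing.
#' @param tol_row Row-sum tolerance applied on read.
#' @return `read_kernel()` returns a `markov_kernel`; `write_kernel()`
#'   returns `path` invisibly.
#' @export
read_kernel <- function(path, format = NULL, tol_row = 1e-9) {
  format <- infer_format(path, format)
  if (format == "csv") {
    df <- tryCatch(
      utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE),
      error = function(e) stop(sprintf("cannot parse %s: %s", path,
                                       conditionMessage(e))))
    if (ncol(df) < 2L)
      stop(sprintf("cannot parse %s: need a label column plus data columns", path))
    m <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(m)) {
      bad <- which(is.na(suppressWarnings(as.numeric(m))))[1L]
      stop(sprintf("cannot parse %s: non-numeric entry near data line %d",
                   path, ((bad - 1L) %% nrow(m)) + 2L))
    }
    kernel(m, row_labels = as.character(df[[1L]]),
           col_labels = colnames(df)[-1L], tol_row = tol_row)
  } else {
    obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                    error = function(e) stop(sprintf("cannot parse %s: %s",
                                                     path, conditionMessage(e))))
    if (!all(c("rows", "cols", "matrix") %in% names(obj)))
      stop(sprintf("cannot parse %s: need fields rows, cols, matrix", path))
    kernel(matrix(as.numeric(t(obj$matrix)), nrow = length(obj$rows),
                  byrow = TRUE),
           row_labels = obj$rows, col_labels = obj$cols, tol_row = tol_row)
  }
}

#' @rdname read_kernel
#' @param k A `markov_kernel`.
#' @export
write_kernel <- function(k, path, format = NULL) {
  if (!is_kernel(k)) k <- kernel(k)
  format <- infer_format(path, format)
  if (format == "csv") {
    df <- data.frame(state = rownames(k), unclass(k), check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    obj <- list(rows = rownames(k), cols = colnames(k),
                matrix = unname(unclass(k)))
    # I(17) significant digits makes double round-trips bit-exact
    jsonlite::write_json(obj, path, digits = I(17), auto_unbox = FALSE)
  }
  invisible(path)
}

infer_format <- function(path, format) {
  if (!is.null(format)) return(match.arg(format, c("csv", "json")))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("csv", "json")) ext
  else stop("cannot infer format from extension; pass format = \"csv\" or \"json\"")
}

#' Read a directed graph from an edge-list TSV
#'
#' One `src<TAB>dst` pair per line, 1-based node labels; blank lines and
#' lines starting with `#` are skipped.
#'
#' @param path File path.
#' @param n Number of nodes (defaults to the largest endpoint).
#' @return Two-column integer matrix of edges, with attribute `n`.
#' @export
read_edge_list <- function(path, n = NULL) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lines <- lines[keep]
  rows <- lapply(seq_along(lines), function(i) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    v <- suppressWarnings(as.integer(parts))
    if (length(v) != 2L || anyNA(v))
      stop(sprintf("cannot parse %s: bad edge on line %d", path,
                   which(keep)[i]))
    v
  })
  em <- do.call(rbind, rows)
  if (is.null(em)) em <- matrix(integer(), 0L, 2L)
  attr(em, "n") <- if (is.null(n)) {
    if (nrow(em) == 0L) 0L else max(em)
  } else as.integer(n)
  em
}
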