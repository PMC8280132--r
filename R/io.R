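#' Read a tab-separated table, skipping comment lines
#'
#' All flat files in this package are plain TSV with a header row; lines
#' starting with `#` are comments.
#'
#' @param path File path.
#' @param col_types Passed to [readr::read_tsv()].
#' @return A tibble.
#' @keywords internal
read_flat_tsv <- function(path, col_types = readr::cols()) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "ppiclust_io_error")
  }
  readr::read_tsv(path, comment = "#", col_types = col_types,
                  progress = FALSE, show_col_types = FALSE)
}

#' Write a table as TSV with deterministic formatting
#'
#' Numeric columns are rendered with `format_num()` so that re-running a
#' pipeline with the same inputs reproduces byte-identical files.
#'
#' @param x Data frame.
#' @param path Output path.
#' @param digits Significant digits for numeric columns.
#' @return `path`, invisibly.
#' @export
write_flat_tsv <- function(x, path, digits = 10) {
  x <- as.data.frame(x)
  for (j in seq_along(x)) {
    if (is.double(x[[j]])) x[[j]] <- format_num(x[[j]], digits)
  }
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

format_num <- function(x, digits = 10) {
  out <- formatC(signif(x, digits), format = "g", digits = digits)
  out[is.na(x)] <- "NA"
  out
}

#' Read gene sets in GMT format
#'
#' Standard tab-separated GMT: set name, description, then member genes.
#'
#' @param path Path to a `.gmt` file.
#' @return Named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "ppiclust_io_error")
  }
  fgsea::gmtPathways(path)
}

#' Write gene sets in GMT format
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of descriptions (defaults to
#'   the set names).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (length(sets) == 0 || is.null(names(sets))) {
    abort("`sets` must be a non-empty named list", class = "ppiclust_value_error")
  }
  descriptions <- descriptions %||% names(sets)
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Path to a packaged example data file
#'
#' @param file File name under `extdata/`; with no argument, lists the
#'   available files.
#' @return A file path (or a vector of file names).
#' @export
ppiclust_example <- function(file = NULL) {
  if (is.null(file)) {
    dir(system.file("extdata", package = "ppiclust"))
  } else {
    system.file("extdata", file, package = "ppiclust", mustWork = TRUE)
  }
}
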