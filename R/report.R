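#' Measure reports
#'
#' A `measure_report` bundles one or more result tables with the metadata
#' (analysis name, window, containment policy, conventions) needed to
#' recompute them. Every mean, median and range in a report is recomputable
#' from the inputs it cites.
#'
#' @param tables Named list of `data.table`s.
#' @param meta Named list of metadata scalars.
#' @return An object of class `measure_report`.
#' @export
measure_report <- function(tables, meta = list()) {
  stopifnot(is.list(tables), length(names(tables)) == length(tables))
  structure(list(tables = tables, meta = meta), class = "measure_report")
}

#' @export
print.measure_report <- function(x, ...) {
  cat(sprintf("<measure_report: %s>\n",
              paste(names(x$tables), collapse = ", ")))
  for (nm in names(x$tables)) {
    cat("--", nm, "--\n")
    print(x$tables[[nm]])
  }
  invisible(x)
}

#' Write a measure report to TSV
#'
#' Each table of the report is written as `<stem>_<table>.tsv`. The file
#' opens with machine-readable comment lines (`# key\tvalue`) recording the
#' report metadata, followed by a standard TSV header and body.
#'
#' @param report A `measure_report`.
#' @param stem Output path stem (directory + file prefix).
#' @return Character vector of paths written, invisibly.
#' @export
write_measure_report <- function(report, stem) {
  stopifnot(inherits(report, "measure_report"))
  paths <- character()
  for (nm in names(report$tables)) {
    path <- paste0(stem, "_", nm, ".tsv")
    con <- file(path, "w")
    for (key in names(report$meta)) {
      writeLines(sprintf("# %s\t%s", key, format(report$meta[[key]])), con)
    }
    close(con)
    data.table::fwrite(report$tables[[nm]], path, sep = "\t", append = TRUE,
                       col.names = TRUE)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read one table of a measure report
#'
#' @param path Path written by [write_measure_report()].
#' @return A list with `meta` (named character) and `table` (`data.table`).
#' @export
read_measure_table <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^# ", lines)
  meta <- list()
  for (ln in lines[meta_lines]) {
    kv <- strsplit(sub("^# ", "", ln), "\t", fixed = TRUE)[[1]]
    meta[[kv[1]]] <- if (length(kv) > 1) kv[2] else ""
  }
  body <- lines[setdiff(seq_along(lines), meta_lines)]
  tab <- data.table::fread(text = paste(body, collapse = "\n"), sep = "\t")
  list(meta = meta, table = tab)
}
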