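#' Read an interaction edge list from TSV
#'
#' Expects three tab-separated columns `source`, `target`, `kind`
#' (`kind` in `ppi`/`regulatory`), no header required, `#`-prefixed
#' comment lines ignored. Malformed rows are reported with their line
#' numbers.
#'
#' @param path file path.
#' @param col_names logical: does the file carry a header row?
#' @return A tibble with columns `source`, `target`, `kind`.
#' @export
read_interactions <- function(path, col_names = FALSE) {
  raw <- readr::read_tsv(
    path,
    col_names = if (isTRUE(col_names)) TRUE else c("source", "target", "kind"),
    col_types = readr::cols(.default = readr::col_character()),
    comment = "#", progress = FALSE
  )
  if (ncol(raw) != 3L) {
    stop("expected 3 tab-separated columns in ", path, ", found ", ncol(raw))
  }
  names(raw) <- c("source", "target", "kind")
  bad <- which(!raw$kind %in% c("ppi", "regulatory"))
  if (length(bad) > 0L) {
    stop("unknown interaction kind in ", path, " at data line(s) ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  raw
}

#' Read a response-gene list
#'
#' Accepts either one gene symbol per line or two tab-separated columns
#' `gene` and `log_fc`. `#` comments are ignored.
#'
#' @param path file path.
#' @return A tibble with column `gene` and, when present, `log_fc`.
#' @export
read_responses <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no response genes found in ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) >= 2L)) {
    tibble::tibble(
      gene = vapply(parts, `[`, character(1), 1L),
      log_fc = as.numeric(vapply(parts, function(p) {
        if (length(p) >= 2L) p[2L] else NA_character_
      }, character(1)))
    )
  } else {
    tibble::tibble(gene = trimws(lines))
  }
}

#' Read a compound assay table from TSV
#'
#' Columns: `compound`, `targets` (`;`-separated symbols), `score`
#' (% of vehicle control). A header row is detected if the third
#' field of the first line is not numeric.
#'
#' @param path file path.
#' @return A tibble with columns `compound`, `targets`, `score`.
#' @export
read_assay <- function(path) {
  first <- readr::read_lines(path, n_max = 1L, progress = FALSE)
  has_header <- is.na(suppressWarnings(
    as.numeric(strsplit(first, "\t", fixed = TRUE)[[1L]][3L])
  ))
  raw <- readr::read_tsv(
    path,
    col_names = if (has_header) TRUE else c("compound", "targets", "score"),
    col_types = "ccd", comment = "#", progress = FALSE
  )
  if (ncol(raw) != 3L) {
    stop("expected 3 tab-separated columns in ", path, ", found ", ncol(raw))
  }
  names(raw) <- c("compound", "targets", "score")
  raw
}

#' Write a table as TSV with a `#`-prefixed comment header
#'
#' @param x data frame.
#' @param path output path.
#' @param comments character vector of header comment lines (written
#'   with a leading `# `).
#' @return `path`, invisibly.
#' @export
write_tsv_commented <- function(x, path, comments = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (cm in comments) writeLines(paste0("# ", cm), con)
  writeLines(paste(names(x), collapse = "\t"), con)
  body <- do.call(paste, c(lapply(x, format_tsv_field), sep = "\t"))
  if (length(body) > 0) writeLines(body, con)
  invisible(path)
}

format_tsv_field <- function(v) {
  if (is.numeric(v)) {
    out <- sprintf("%.15g", v)
    out[is.na(v)] <- "NA"
    out
  } else {
    as.character(v)
  }
}

#' Write an interaction edge list as TSV
#'
#' @param interactions tibble with `source`, `target`, `kind`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_interactions <- function(interactions, path) {
  interactions <- validate_interactions(interactions)
  readr::write_tsv(interactions, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
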