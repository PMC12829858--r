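# Reading, writing and validating concentration tables.

#' Validate a concentration sample table
#'
#' A sample table is a data frame with one row per sample: a unique
#' `sample_id`, a `group` label, optional `species`, `sex`, `age` and
#' `education_years` columns, and one numeric column per analyte
#' (concentrations in ug/mL, non-negative, `NA` allowed).
#'
#' @param x data frame to validate.
#' @return the validated data frame (invisibly classed
#'   `ffa_sample_table`).
#' @export
as_sample_table <- function(x) {
  if (!is.data.frame(x)) stop("sample table must be a data frame")
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(x)) stop("missing required column 'sample_id'")
  if (!"group" %in% names(x)) stop("missing required column 'group'")
  x$sample_id <- as.character(x$sample_id)
  if (anyDuplicated(x$sample_id))
    stop("duplicate sample_id: ",
         paste(unique(x$sample_id[duplicated(x$sample_id)]), collapse = ", "))
  if (any(is.na(x$group) | !nzchar(as.character(x$group))))
    stop("every sample must have a group label")
  ana <- setdiff(names(x), .meta_cols)
  if (length(ana) == 0L) stop("no analyte columns found")
  for (a in ana) {
    v <- x[[a]]
    if (!is.numeric(v)) stop("analyte column '", a, "' is not numeric")
    if (any(v < 0, na.rm = TRUE))
      stop("negative concentration in analyte '", a, "'")
  }
  class(x) <- unique(c("ffa_sample_table", class(x)))
  x
}

#' Read a concentration table from CSV/TSV
#'
#' Supports two dialects. `wide`: one row per sample with columns
#' `sample_id`, `group`, optional `species`/`sex`/`age`/`education_years`,
#' then one column per analyte. `long`: columns `sample_id`, `analyte_id`,
#' `value` plus optional per-sample metadata columns, pivoted to wide.
#' Non-numeric concentration cells (e.g. `"n.d."`) become missing with a
#' warning; group labels are preserved verbatim.
#'
#' @param path file path; the separator is inferred from the extension
#'   (`.tsv`/`.txt` = tab) unless `sep` is given.
#' @param dialect `"wide"` or `"long"`.
#' @param sep field separator override.
#' @return a validated sample table.
#' @export
read_concentration_table <- function(path, dialect = c("wide", "long"),
                                     sep = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character", comment.char = "")
  if (dialect == "long") {
    need <- c("sample_id", "analyte_id", "value")
    if (!all(need %in% names(raw)))
      stop("long dialect requires columns: ", paste(need, collapse = ", "))
    meta <- intersect(.meta_cols, names(raw))
    ids <- unique(raw$sample_id)
    analytes <- unique(raw$analyte_id)
    wide <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
    for (mcol in setdiff(meta, "sample_id"))
      wide[[mcol]] <- raw[[mcol]][match(ids, raw$sample_id)]
    for (a in analytes)
      wide[[a]] <- raw$value[match(paste(ids, a),
                                   paste(raw$sample_id, raw$analyte_id))]
    raw <- wide
  }
  ana <- setdiff(names(raw), .meta_cols)
  n_bad <- 0L
  for (a in ana) {
    v <- suppressWarnings(as.numeric(raw[[a]]))
    bad <- is.na(v) & !is.na(raw[[a]]) & nzchar(trimws(raw[[a]])) &
      !(tolower(trimws(raw[[a]])) %in% c("na", "nan"))
    n_bad <- n_bad + sum(bad)
    raw[[a]] <- v
  }
  if (n_bad > 0L)
    warning(n_bad, " non-numeric concentration cell(s) set to missing")
  for (mcol in intersect(c("age", "education_years"), names(raw)))
    raw[[mcol]] <- suppressWarnings(as.numeric(raw[[mcol]]))
  as_sample_table(raw)
}

#' Write a sample table to CSV
#'
#' UTF-8 CSV with a header row; round-trips bit-exactly through
#' [read_concentration_table()] for finite inputs.
#'
#' @param tab sample table.
#' @param path output path.
#' @export
write_concentration_table <- function(tab, path) {
  tab <- as_sample_table(tab)
  utils::write.csv(tab, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Drop analytes with excessive missingness
#'
#' Removes analytes missing in more than `max_missing` of the samples of any
#' group (a message names them); remaining missing values are handled
#' pairwise per analyte downstream.
#'
#' @param tab sample table.
#' @param max_missing maximum tolerated per-group missing fraction.
#' @return the table without the dropped analytes.
#' @export
drop_sparse_analytes <- function(tab, max_missing = 0.2) {
  tab <- as_sample_table(tab)
  ana <- analyte_names(tab)
  drop <- character(0)
  for (a in ana) {
    frac <- tapply(is.na(tab[[a]]), tab$group, mean)
    if (any(frac > max_missing)) drop <- c(drop, a)
  }
  if (length(drop)) {
    message("dropping analytes missing in > ", max_missing * 100,
            "% of a group: ", paste(drop, collapse = ", "))
    tab <- tab[, setdiff(names(tab), drop), drop = FALSE]
    if (length(analyte_names(tab)) == 0L)
      stop("all analytes dropped by missing-data policy")
  }
  tab
}
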