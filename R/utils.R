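#' @keywords internal
"_PACKAGE"

# Meta columns recognised in a sample table; everything else is an analyte.
.meta_cols <- c("sample_id", "species", "group", "sex", "age", "education_years")

#' Analyte columns of a sample table
#'
#' @param tab a sample table (see [as_sample_table()]).
#' @return character vector of analyte column names, in table order.
#' @export
analyte_names <- function(tab) setdiff(names(tab), .meta_cols)

#' Standard error of the mean
#'
#' SD/sqrt(n) with the sample (n - 1) standard deviation; `NA` values are
#' dropped.
#'
#' @param x numeric vector.
#' @return scalar SEM.
#' @export
sem <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

# Derive a reproducible sub-seed for a named random stream from one global
# integer seed. Keeps results independent across streams and < 2^31.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(seed) * 1009L + h * 7919L) %% 2147483629)
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

star_label <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}
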