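# Analyte nomenclature: canonical lipid shorthand "C<carbons>:<double
# bonds>[suffix]" plus a synonym dictionary for free-text fatty acid names.

# Synonym dictionary, lower-case free-text name -> canonical shorthand.
# "trans-9-octadecenoic acid" is keyed to C18:2n6c because the source tables
# this package targets label it that way; chemically that shorthand is
# linoleic acid. Both names are kept as display synonyms rather than
# resolving the chemistry.
.analyte_synonyms <- c(
  "hexanoic acid"              = "C6:0",
  "caproic acid"               = "C6:0",
  "caprylic acid"              = "C8:0",
  "octanoic acid"              = "C8:0",
  "nonanoic acid"              = "C9:0",
  "pelargonic acid"            = "C9:0",
  "capric acid"                = "C10:0",
  "decanoic acid"              = "C10:0",
  "undecanoic acid"            = "C11:0",
  "lauric acid"                = "C12:0",
  "dodecanoic acid"            = "C12:0",
  "tridecanoic acid"           = "C13:0",
  "myristic acid"              = "C14:0",
  "tetradecanoic acid"         = "C14:0",
  "myristoleic acid"           = "C14:1",
  "pentadecanoic acid"         = "C15:0",
  "palmitic acid"              = "C16:0",
  "hexadecanoic acid"          = "C16:0",
  "palmitoleic acid"           = "C16:1",
  "cis-9-palmitoleic acid"     = "C16:1",
  "heptadecanoic acid"         = "C17:0",
  "margaric acid"              = "C17:0",
  "heptadecenoic acid"         = "C17:1",
  "stearic acid"               = "C18:0",
  "octadecanoic acid"          = "C18:0",
  "oleic acid"                 = "C18:1n9c",
  "linoleic acid"              = "C18:2n6c",
  "trans-9-octadecenoic acid"  = "C18:2n6c",
  "linolenic acid"             = "C18:3n3",
  "alpha-linolenic acid"       = "C18:3n3",
  "nonadecylic acid"           = "C19:0",
  "nonadecanoic acid"          = "C19:0",
  "arachidic acid"             = "C20:0",
  "eicosanoic acid"            = "C20:0",
  "dihomo-gamma-linolenic acid" = "C20:3n6",
  "arachidonic acid"           = "C20:4n6",
  "eicosapentaenoic acid"      = "C20:5n3",
  "epa"                        = "C20:5n3",
  "heneicosanoic acid"         = "C21:0",
  "behenic acid"               = "C22:0",
  "docosanoic acid"            = "C22:0",
  "docosahexaenoic acid"       = "C22:6n3",
  "dha"                        = "C22:6n3"
)

.canonical_re <- "^C([0-9]+):([0-9]+)(.*)$"

#' Normalize fatty acid names to canonical shorthand
#'
#' Maps free-text fatty acid names ("nonanoic acid", "cis-9-palmitoleic
#' acid", ...) to the canonical carbon:double-bond shorthand ("C9:0",
#' "C16:1") via a built-in synonym dictionary. Inputs already in canonical
#' form are returned unchanged; unknown names pass through unchanged with a
#' warning. The mapping is idempotent.
#'
#' @param raw character vector of analyte names; empty strings are an error.
#' @return character vector of the same length with canonical ids where
#'   known.
#' @examples
#' normalize_analyte_name(c("nonanoic acid", "C16:1"))
#' @export
normalize_analyte_name <- function(raw) {
  if (!is.character(raw) || length(raw) == 0L)
    stop("'raw' must be a non-empty character vector")
  raw <- trimws(raw)
  if (any(!nzchar(raw))) stop("empty analyte name")
  out <- raw
  canonical <- grepl(.canonical_re, raw)
  key <- tolower(raw)
  hit <- !canonical & key %in% names(.analyte_synonyms)
  out[hit] <- unname(.analyte_synonyms[key[hit]])
  unknown <- !canonical & !hit
  if (any(unknown))
    warning("unrecognised analyte name(s) passed through unchanged: ",
            paste(unique(raw[unknown]), collapse = ", "))
  out
}

# Parse canonical shorthand into (carbons, double_bonds, suffix); NA rows for
# non-canonical ids.
parse_analyte_id <- function(ids) {
  m <- regmatches(ids, regexec(.canonical_re, ids))
  carbons <- vapply(m, function(x) if (length(x)) as.numeric(x[2]) else NA_real_, 0)
  dbonds  <- vapply(m, function(x) if (length(x)) as.numeric(x[3]) else NA_real_, 0)
  suffix  <- vapply(m, function(x) if (length(x)) x[4] else NA_character_, "")
  data.frame(analyte_id = ids, carbons = carbons, double_bonds = dbonds,
             suffix = suffix, stringsAsFactors = FALSE)
}

#' Canonical analyte panel ordering
#'
#' Orders shorthand ids by ascending carbon count, then ascending double-bond
#' count, then lexicographic suffix; ids that do not parse as shorthand sort
#' last, lexicographically. This ordering defines the default radar axis
#' order, so it is deterministic and always reported with area results.
#'
#' @param ids character vector of analyte ids.
#' @return `ids` reordered canonically.
#' @export
order_panel <- function(ids) {
  p <- parse_analyte_id(ids)
  key_bad <- is.na(p$carbons)
  ord <- order(key_bad, p$carbons, p$double_bonds, p$suffix, p$analyte_id)
  ids[ord]
}

#' Restrict two sample tables to their shared analyte panel
#'
#' Canonicalises analyte names in both tables, intersects the panels, and
#' returns both tables restricted to the shared panel in canonical order.
#' Needed before any cross-species comparison. Harmonization is idempotent.
#'
#' @param a,b sample tables (see [as_sample_table()]).
#' @return list with elements `panel` (ordered shared analyte ids), `a` and
#'   `b` (restricted copies).
#' @export
harmonize_panels <- function(a, b) {
  a <- as_sample_table(a); b <- as_sample_table(b)
  names(a)[!(names(a) %in% .meta_cols)] <-
    normalize_analyte_name(analyte_names(a))
  names(b)[!(names(b) %in% .meta_cols)] <-
    normalize_analyte_name(analyte_names(b))
  shared <- intersect(analyte_names(a), analyte_names(b))
  if (length(shared) == 0L)
    stop("analyte panels are disjoint: no shared analytes after harmonization")
  shared <- order_panel(shared)
  keep <- function(t) t[, c(intersect(.meta_cols, names(t)), shared), drop = FALSE]
  list(panel = shared, a = keep(a), b = keep(b))
}
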