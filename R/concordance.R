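# Core concordance layer: control-referenced z-scores, the S-score
# model-fidelity statistic, radar-polygon areas (AERC) and model ranking.

#' Z-score standardization against a reference population
#'
#' Every sample (reference and non-reference) is standardized per analyte by
#' subtracting the reference group's mean concentration and dividing by the
#' reference group's sample standard deviation (n - 1 denominator). By
#' construction the reference group's z-scores have mean 0 and SD 1 per
#' analyte. Analytes whose reference SD is zero (or not computable) are
#' dropped with a warning.
#'
#' @param tab sample table.
#' @param reference_group group label of the reference (control) population;
#'   needs at least 2 samples.
#' @return an `ffa_zscore` object: a data frame with the table's meta
#'   columns and one z column per retained analyte, with attributes
#'   `reference_group` and `reference_stats` (per-analyte mean and SD).
#' @export
zscore_reference <- function(tab, reference_group) {
  tab <- as_sample_table(tab)
  ref <- tab$group == reference_group
  if (sum(ref) < 2L)
    stop("reference group '", reference_group,
         "' absent or has fewer than 2 samples")
  ana <- analyte_names(tab)
  mu <- vapply(ana, function(a) mean(tab[[a]][ref], na.rm = TRUE), 0)
  sdv <- vapply(ana, function(a) stats::sd(tab[[a]][ref], na.rm = TRUE), 0)
  bad <- !is.finite(sdv) | sdv == 0
  if (any(bad)) {
    warning("dropping analyte(s) with zero or undefined reference SD: ",
            paste(ana[bad], collapse = ", "))
    ana <- ana[!bad]; mu <- mu[!bad]; sdv <- sdv[!bad]
    if (length(ana) == 0L) stop("no analytes left after dropping zero-SD ones")
  }
  z <- tab[, intersect(.meta_cols, names(tab)), drop = FALSE]
  for (i in seq_along(ana)) z[[ana[i]]] <- (tab[[ana[i]]] - mu[i]) / sdv[i]
  structure(z, reference_group = reference_group,
            reference_stats = data.frame(analyte_id = ana, mean = mu,
                                         sd = sdv, row.names = NULL),
            class = c("ffa_zscore", "data.frame"))
}

#' S-score: deviation of an animal from the patient cohort's z-scores
#'
#' For each animal and analyte, s = (z_animal - mean z_patient) /
#' SD z_patient, where the patient statistics are taken over the patient
#' cohort's z-scores (standardized against the human control group). An
#' s-score of 0 means the animal's standardized level coincides with the
#' patient cohort mean; larger |s| means greater divergence from the
#' patient profile.
#'
#' By default (`input = "zscore"`) the animal's value is its own z-score,
#' standardized against its own species' control group, so that the two
#' species are compared on a common dimensionless scale and the statistic is
#' invariant to within-species affine unit changes. `input = "raw"` applies
#' the formula to the animal's raw concentration instead (the literal
#' raw-value reading), provided for auditability.
#'
#' @param animal an `ffa_zscore` of the mouse cohort (or a raw sample table
#'   when `input = "raw"`).
#' @param patient_z an `ffa_zscore` of the human cohort.
#' @param patient_group label of the patient group within `patient_z`.
#' @param input `"zscore"` (default) or `"raw"`.
#' @return an `ffa_sscore` object: meta columns plus one s column per shared
#'   analyte, with attribute `patient_stats` (per-analyte mean and SD of the
#'   patient z-scores) and `input`.
#' @export
sscore <- function(animal, patient_z, patient_group,
                   input = c("zscore", "raw")) {
  input <- match.arg(input)
  if (!inherits(patient_z, "ffa_zscore"))
    stop("patient_z must come from zscore_reference()")
  if (input == "zscore" && !inherits(animal, "ffa_zscore"))
    stop("animal must come from zscore_reference() when input = 'zscore'")
  pat <- patient_z[patient_z$group == patient_group, , drop = FALSE]
  if (nrow(pat) < 2L)
    stop("patient group '", patient_group, "' absent or n < 2")
  shared <- intersect(analyte_names(animal), analyte_names(patient_z))
  if (length(shared) == 0L) stop("no shared analytes between cohorts")
  shared <- order_panel(shared)
  mu <- vapply(shared, function(a) mean(pat[[a]], na.rm = TRUE), 0)
  sdv <- vapply(shared, function(a) stats::sd(pat[[a]], na.rm = TRUE), 0)
  bad <- !is.finite(sdv) | sdv == 0
  if (any(bad)) {
    warning("dropping analyte(s) with zero patient z-score SD: ",
            paste(shared[bad], collapse = ", "))
    shared <- shared[!bad]; mu <- mu[!bad]; sdv <- sdv[!bad]
    if (length(shared) == 0L) stop("no analytes left")
  }
  s <- animal[, intersect(.meta_cols, names(animal)), drop = FALSE]
  for (i in seq_along(shared))
    s[[shared[i]]] <- (animal[[shared[i]]] - mu[i]) / sdv[i]
  structure(as.data.frame(s),
            patient_stats = data.frame(analyte_id = shared, mean = mu,
                                       sd = sdv, row.names = NULL),
            input = input, patient_group = patient_group,
            class = c("ffa_sscore", "data.frame"))
}

#' Area of an equiangular radar polygon
#'
#' With k radii at equal angular spacing theta = 2 pi / k, the enclosed
#' area is 0.5 * sum_i r_i r_(i+1) sin(theta), indices cyclic. Radii must
#' be non-negative; k >= 3.
#'
#' @param r numeric vector of radii in axis order.
#' @return scalar area (dimensionless).
#' @export
radar_polygon_area <- function(r) {
  k <- length(r)
  if (k < 3L) stop("a radar polygon needs at least 3 axes")
  if (any(is.na(r))) stop("radii contain NA")
  if (any(r < 0)) stop("internal error: negative radius")
  0.5 * sum(r * c(r[-1], r[1])) * sin(2 * pi / k)
}

#' Radar-polygon area (AERC) per animal over the analyte panel
#'
#' Places each animal's transformed s-scores on equally spaced radar axes in
#' the given panel order and computes the enclosed polygon area. S-scores
#' can be negative while radii cannot, so a transform is applied first:
#' `"abs"` (default; |s|, the distance-from-patient-mean reading),
#' `"shift_min"` (s minus the animal's own minimum) or `"clip_zero"`
#' (negative s set to 0). The area depends on the axis order, so the order
#' and transform used are always part of the result.
#'
#' @param s_table an `ffa_sscore` object.
#' @param panel_order analyte ids defining the axis order; defaults to the
#'   canonical ordering of the table's panel.
#' @param radius_transform `"abs"`, `"shift_min"` or `"clip_zero"`.
#' @return an `ffa_aerc` object: data frame with `sample_id`, `group`,
#'   `area`; attributes `panel_order`, `radius_transform`, `group_summary`
#'   (mean, SEM, n per group) and `radii` (the transformed radius matrix).
#' @export
aerc <- function(s_table, panel_order = NULL,
                 radius_transform = c("abs", "shift_min", "clip_zero")) {
  radius_transform <- match.arg(radius_transform)
  if (!inherits(s_table, "ffa_sscore"))
    stop("s_table must come from sscore()")
  ana <- analyte_names(s_table)
  if (is.null(panel_order)) panel_order <- order_panel(ana)
  if (!all(panel_order %in% ana))
    stop("panel_order contains analytes absent from the s-score table")
  if (length(panel_order) < 3L)
    stop("a radar polygon needs at least 3 analytes")
  smat <- as.matrix(s_table[, panel_order, drop = FALSE])
  rmat <- switch(radius_transform,
                 abs = abs(smat),
                 shift_min = smat - apply(smat, 1L, min),
                 clip_zero = pmax(smat, 0))
  areas <- apply(rmat, 1L, radar_polygon_area)
  out <- data.frame(sample_id = s_table$sample_id, group = s_table$group,
                    area = as.numeric(areas), stringsAsFactors = FALSE)
  gs <- do.call(rbind, lapply(split(out$area, out$group), function(a)
    data.frame(mean_area = mean(a), sem_area = sem(a), n = length(a))))
  gs <- data.frame(group = rownames(gs), gs, row.names = NULL)
  structure(out, panel_order = panel_order,
            radius_transform = radius_transform, group_summary = gs,
            radii = rmat, class = c("ffa_aerc", "data.frame"))
}

#' Per-analyte comparison of s-scores between two models
#'
#' For each shared analyte, a two-sided two-sample t-test on the animals'
#' s-scores between the two models, plus the mean |s| of each model; the
#' model with the smaller mean |s| is flagged as closer to the patient
#' profile per analyte and overall.
#'
#' @param s_a,s_b `ffa_sscore` objects for the two models (>= 2 animals
#'   each).
#' @param names_ab length-2 character naming the two models.
#' @param alpha significance level for the stars.
#' @return list with `per_analyte` (data frame) and `overall` (mean |s| per
#'   model and the overall winner, or `NA` on an exact tie).
#' @export
compare_model_sscores <- function(s_a, s_b, names_ab = c("A", "B"),
                                  alpha = 0.05) {
  shared <- intersect(analyte_names(s_a), analyte_names(s_b))
  if (length(shared) == 0L) stop("no shared analytes")
  shared <- order_panel(shared)
  if (nrow(s_a) < 2L || nrow(s_b) < 2L)
    stop("each model needs at least 2 animals")
  rows <- lapply(shared, function(a) {
    va <- s_a[[a]]; vb <- s_b[[a]]
    tt <- tryCatch(stats::t.test(va, vb), error = function(e) NULL)
    if (is.null(tt)) { stat <- NA_real_; p <- 1 }  # degenerate: constant data
    else { stat <- unname(tt$statistic); p <- tt$p.value }
    ma <- mean(abs(va)); mb <- mean(abs(vb))
    data.frame(analyte_id = a, statistic = stat, p_value = p,
               mean_abs_s_a = ma, mean_abs_s_b = mb,
               closer = if (ma < mb) names_ab[1]
                        else if (mb < ma) names_ab[2] else NA_character_,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  per$stars <- star_label(per$p_value)
  oa <- mean(abs(as.matrix(s_a[, shared]))); ob <- mean(abs(as.matrix(s_b[, shared])))
  winner <- if (oa < ob) names_ab[1] else if (ob < oa) names_ab[2]
            else NA_character_
  list(per_analyte = per,
       overall = stats::setNames(c(oa, ob), names_ab), winner = winner)
}

#' Rank animal models by concordance with the patient profile
#'
#' Orders models by mean AERC or mean |s| of the model-group animals
#' (smaller = more concordant with the patient cohort); ties are broken by
#' the other summary, then by model name. Both summaries are always
#' reported.
#'
#' @param aerc_by_model named list of `ffa_aerc` objects (or named numeric
#'   mean areas), model animals only.
#' @param s_by_model named list of `ffa_sscore` objects (or named numeric
#'   mean |s|).
#' @param policy `"mean_aerc"` or `"mean_abs_s"`.
#' @return data frame with one row per model in rank order: `model`,
#'   `mean_aerc`, `mean_abs_s`, `rank`.
#' @export
rank_models <- function(aerc_by_model, s_by_model,
                        policy = c("mean_aerc", "mean_abs_s")) {
  policy <- match.arg(policy)
  if (length(aerc_by_model) == 0L) stop("no models to rank")
  if (!setequal(names(aerc_by_model), names(s_by_model)))
    stop("model names differ between AERC and s-score inputs")
  models <- sort(names(aerc_by_model))
  ma <- vapply(models, function(m) {
    x <- aerc_by_model[[m]]
    if (inherits(x, "ffa_aerc")) mean(x$area) else as.numeric(x)
  }, 0)
  ms <- vapply(models, function(m) {
    x <- s_by_model[[m]]
    if (inherits(x, "ffa_sscore"))
      mean(abs(as.matrix(x[, analyte_names(x), drop = FALSE])))
    else as.numeric(x)
  }, 0)
  key1 <- if (policy == "mean_aerc") ma else ms
  key2 <- if (policy == "mean_aerc") ms else ma
  ord <- order(key1, key2, models)
  data.frame(model = models[ord], mean_aerc = unname(ma[ord]),
             mean_abs_s = unname(ms[ord]), rank = seq_along(ord),
             stringsAsFactors = FALSE)
}

#' Radar vertex coordinates for external plotting
#'
#' Angle (radians, starting at 12 o'clock, clockwise), radius and analyte id
#' of every vertex of each animal's radar polygon.
#'
#' @param aerc_result an `ffa_aerc` object.
#' @return data frame with `sample_id`, `group`, `analyte_id`, `angle`,
#'   `radius`.
#' @export
radar_vertices <- function(aerc_result) {
  stopifnot(inherits(aerc_result, "ffa_aerc"))
  rmat <- attr(aerc_result, "radii")
  panel <- attr(aerc_result, "panel_order")
  k <- length(panel)
  ang <- pi / 2 - (seq_len(k) - 1L) * 2 * pi / k
  do.call(rbind, lapply(seq_len(nrow(aerc_result)), function(i)
    data.frame(sample_id = aerc_result$sample_id[i],
               group = aerc_result$group[i], analyte_id = panel,
               angle = ang, radius = as.numeric(rmat[i, ]),
               stringsAsFactors = FALSE)))
}
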