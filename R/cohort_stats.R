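# Group-comparison layer: normality screening, normality-gated test
# selection, contingency and rank tests, covariate adjustment and the
# sucrose-preference endpoint.

#' Shapiro-Wilk normality screen with Q-Q coordinates
#'
#' Each group is screened with a Shapiro-Wilk test; the verdict is
#' `"normal"` only if every group's p-value exceeds `alpha`. Groups with
#' fewer than 3 non-missing values or constant values are untestable and
#' route the comparison to the nonparametric branch. Q-Q plot coordinates
#' (theoretical vs sample quantiles) are returned per group for inspection.
#'
#' @param values_by_group named list of numeric vectors.
#' @param alpha per-group significance threshold of the screen.
#' @return list with `verdict` (`"normal"`, `"non-normal"` or
#'   `"untestable"`), per-group `tests` (W, p, n) and `qq` coordinates.
#' @export
assess_normality <- function(values_by_group, alpha = 0.05) {
  stopifnot(is.list(values_by_group), length(values_by_group) >= 1L)
  tests <- list(); qq <- list(); untestable <- FALSE
  for (g in names(values_by_group)) {
    v <- values_by_group[[g]]; v <- v[!is.na(v)]
    if (length(v) < 3L || length(unique(v)) == 1L) {
      tests[[g]] <- list(W = NA_real_, p = NA_real_, n = length(v))
      untestable <- TRUE
    } else {
      sw <- stats::shapiro.test(v)
      tests[[g]] <- list(W = unname(sw$statistic), p = sw$p.value,
                         n = length(v))
    }
    if (length(v) >= 2L) {
      s <- sort(v)
      qq[[g]] <- data.frame(
        theoretical = stats::qnorm(stats::ppoints(length(s))), sample = s)
    }
  }
  verdict <- if (untestable) "untestable"
  else if (all(vapply(tests, function(t) t$p > alpha, TRUE))) "normal"
  else "non-normal"
  list(verdict = verdict, tests = tests, qq = qq, alpha = alpha)
}

#' Two-group comparison with normality-gated test selection
#'
#' With `test = "auto"`, both groups are screened with Shapiro-Wilk at
#' `normal_alpha`; if both pass, a two-sided unpaired t-test is used (Welch
#' by default), otherwise a two-sided Mann-Whitney U test. The Mann-Whitney
#' branch uses exact enumeration when both groups have at most 8
#' observations and there are no ties, and the tie-corrected normal
#' approximation otherwise. Direction is the sign of
#' mean(case) - mean(control).
#'
#' @param case,control numeric vectors, each with at least 2 non-missing
#'   values.
#' @param test `"auto"`, `"t"` or `"mann_whitney"`.
#' @param alpha significance level for the `significant` flag.
#' @param normal_alpha per-group threshold of the normality gate.
#' @param var_equal use the pooled-variance (Student) t-test instead of
#'   Welch.
#' @return list with `test_used`, `statistic`, `p_value`, `direction`
#'   (`"up"`, `"down"` or `"none"`), `significant`, and the normality
#'   verdict when the gate ran.
#' @export
compare_two_groups <- function(case, control,
                               test = c("auto", "t", "mann_whitney"),
                               alpha = 0.05, normal_alpha = 0.05,
                               var_equal = FALSE) {
  test <- match.arg(test)
  case <- case[!is.na(case)]; control <- control[!is.na(control)]
  if (length(case) < 2L || length(control) < 2L)
    stop("each group needs at least 2 non-missing values")
  d <- mean(case) - mean(control)
  direction <- if (d > 0) "up" else if (d < 0) "down" else "none"
  if (length(unique(c(case, control))) == 1L)
    return(list(test_used = "none", statistic = NA_real_, p_value = 1,
                direction = "none", significant = FALSE,
                normality = "untestable"))
  normality <- NA_character_
  if (test == "auto") {
    scr <- assess_normality(list(case = case, control = control),
                            alpha = normal_alpha)
    normality <- scr$verdict
    test <- if (identical(scr$verdict, "normal")) "t" else "mann_whitney"
  }
  if (test == "t") {
    tt <- stats::t.test(case, control, var.equal = var_equal)
    res <- list(test_used = "t_test", statistic = unname(tt$statistic),
                p_value = tt$p.value)
  } else {
    no_ties <- !anyDuplicated(c(case, control))
    exact <- no_ties && length(case) <= 8L && length(control) <= 8L
    wt <- suppressWarnings(
      stats::wilcox.test(case, control, exact = exact, correct = FALSE))
    res <- list(test_used = "mann_whitney",
                statistic = unname(wt$statistic), p_value = wt$p.value)
  }
  c(res, list(direction = direction, significant = res$p_value < alpha,
              normality = normality))
}

#' Per-analyte case-control comparisons over a sample table
#'
#' Runs [compare_two_groups()] for every analyte and returns a tidy result
#' table with significance stars (* p < 0.05, ** p < 0.01). No
#' multiple-testing correction is applied by default; Benjamini-Hochberg
#' adjusted p-values are reported alongside when `adjust = "BH"` (the
#' `significant` flag then uses them).
#'
#' @param tab sample table.
#' @param case_group,control_group group labels.
#' @param adjust `"none"` or `"BH"`.
#' @inheritParams compare_two_groups
#' @return data frame, one row per analyte: `analyte_id`, `test_used`,
#'   `statistic`, `p_value`, `p_adjusted`, `direction`, `significant`,
#'   `stars`, group means and SEMs.
#' @export
compare_analytes <- function(tab, case_group, control_group,
                             test = "auto", alpha = 0.05,
                             normal_alpha = 0.05, var_equal = FALSE,
                             adjust = c("none", "BH")) {
  tab <- as_sample_table(tab); adjust <- match.arg(adjust)
  for (g in c(case_group, control_group))
    if (!g %in% tab$group) stop("group not found in table: ", g)
  rows <- lapply(analyte_names(tab), function(a) {
    ca <- tab[[a]][tab$group == case_group]
    co <- tab[[a]][tab$group == control_group]
    r <- compare_two_groups(ca, co, test = test, alpha = alpha,
                            normal_alpha = normal_alpha,
                            var_equal = var_equal)
    data.frame(analyte_id = a, test_used = r$test_used,
               statistic = r$statistic, p_value = r$p_value,
               direction = r$direction,
               mean_case = mean(ca, na.rm = TRUE),
               sem_case = sem(ca),
               mean_control = mean(co, na.rm = TRUE),
               sem_control = sem(co), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- if (adjust == "BH")
    stats::p.adjust(out$p_value, "BH") else out$p_value
  out$significant <- out$p_adjusted < alpha
  out$stars <- star_label(out$p_adjusted)
  out
}

#' Pearson chi-square test on a contingency table
#'
#' No continuity correction by default (set `correct = TRUE` for Yates).
#' All row and column sums must be positive.
#'
#' @param counts r x c matrix of non-negative counts.
#' @param correct apply Yates continuity correction.
#' @return list with `statistic`, `df`, `p_value`, `expected`.
#' @export
chi_square_contingency <- function(counts, correct = FALSE) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero row or column marginal")
  ct <- suppressWarnings(stats::chisq.test(counts, correct = correct))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value, expected = ct$expected)
}

#' Kruskal-Wallis rank sum test
#'
#' Tie-corrected H statistic with the chi-square approximation. If all
#' values are identical, H = 0 and p = 1.
#'
#' @param groups list of numeric vectors (>= 2 groups, total n >= 3).
#' @return list with `statistic` (H), `df`, `p_value`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  groups <- lapply(groups, function(v) v[!is.na(v)])
  if (any(lengths(groups) == 0L)) stop("each group needs >= 1 value")
  if (sum(lengths(groups)) < 3L) stop("total n must be >= 3")
  if (length(unique(unlist(groups))) == 1L)
    return(list(statistic = 0, df = length(groups) - 1L, p_value = 1))
  kt <- stats::kruskal.test(groups)
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value)
}

#' One-way ANOVA across groups
#'
#' Provided for completeness of the test battery; the reference concordance
#' pipeline itself does not attach it to any result.
#'
#' @param groups list of numeric vectors.
#' @return list with `statistic` (F), `df`, `p_value`.
#' @export
one_way_anova <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  v <- unlist(groups)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  fit <- stats::aov(v ~ g)
  s <- summary(fit)[[1]]
  list(statistic = s[["F value"]][1], df = s[["Df"]],
       p_value = s[["Pr(>F)"]][1])
}

#' Covariate adjustment of analyte concentrations by linear model
#'
#' Fits an ordinary linear model of the analyte concentration on the listed
#' covariates over the pooled sample and returns the residuals re-centred at
#' the pooled mean (the adjusted values), plus the fitted coefficients.
#' Group comparisons can then be run on the adjusted values. The adjustment
#' is invariant to affine rescaling of the covariates.
#'
#' @param tab sample table.
#' @param covariates character vector of covariate column names (e.g.
#'   `c("sex", "age", "education_years")`).
#' @param analyte_id analyte to adjust.
#' @return list with `adjusted` (named numeric, by sample_id),
#'   `coefficients`, `n_used`.
#' @export
adjust_for_covariates <- function(tab, covariates, analyte_id) {
  tab <- as_sample_table(tab)
  if (!analyte_id %in% analyte_names(tab))
    stop("analyte not in table: ", analyte_id)
  if (!all(covariates %in% names(tab)))
    stop("covariate column(s) missing: ",
         paste(setdiff(covariates, names(tab)), collapse = ", "))
  df <- tab[, c("sample_id", covariates, analyte_id)]
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (nrow(df) < length(covariates) + 2L)
    stop("too few complete cases for adjustment")
  for (cv in covariates)
    if (is.character(df[[cv]])) df[[cv]] <- factor(df[[cv]])
  df$.y <- df[[analyte_id]]
  fml <- stats::reformulate(covariates, response = ".y")
  mm <- stats::model.matrix(stats::reformulate(covariates), data = df)
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    bad <- colnames(mm)[setdiff(seq_len(ncol(mm)),
                                qr_mm$pivot[seq_len(qr_mm$rank)])]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  fit <- stats::lm(fml, data = df)
  adj <- stats::residuals(fit) + mean(df[[analyte_id]])
  list(adjusted = stats::setNames(as.numeric(adj), df$sample_id),
       coefficients = stats::coef(fit), n_used = nrow(df))
}

#' Sucrose preference percentage
#'
#' sucrose intake / (sucrose + water intake) x 100; the standard anhedonia
#' readout of the sucrose preference test.
#'
#' @param sucrose_intake,water_intake non-negative intakes (same units),
#'   vectorized; their sum must be positive.
#' @return preference in percent, in \[0, 100\].
#' @export
sucrose_preference <- function(sucrose_intake, water_intake) {
  if (any(sucrose_intake < 0, na.rm = TRUE) ||
      any(water_intake < 0, na.rm = TRUE))
    stop("intakes must be non-negative")
  tot <- sucrose_intake + water_intake
  if (any(tot == 0, na.rm = TRUE)) stop("total intake is zero")
  sucrose_intake / tot * 100
}

#' Check contingency-table cells against published marginal totals
#'
#' Demographic tables sometimes print cell counts that contradict their own
#' group totals (e.g. a sex split of 55/32 against a stated group n of 88).
#' This checks each row of `counts` against `row_totals` and warns, naming
#' the offending rows, instead of silently fixing anything.
#'
#' @param counts r x c matrix of cell counts (rows = groups).
#' @param row_totals published per-group totals, length r.
#' @return logical: `TRUE` if every row sums to its published total
#'   (invisibly), `FALSE` with a warning otherwise.
#' @export
check_count_consistency <- function(counts, row_totals) {
  counts <- as.matrix(counts)
  stopifnot(length(row_totals) == nrow(counts))
  rs <- rowSums(counts)
  ok <- rs == row_totals
  if (!all(ok)) {
    lab <- if (!is.null(rownames(counts))) rownames(counts)[!ok]
           else which(!ok)
    warning("cell counts inconsistent with published totals in row(s) ",
            paste(lab, collapse = ", "), ": cells sum to ",
            paste(rs[!ok], collapse = ", "), " but totals say ",
            paste(row_totals[!ok], collapse = ", "))
    return(invisible(FALSE))
  }
  invisible(TRUE)
}
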