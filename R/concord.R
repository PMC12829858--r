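# The central user-facing entry point: one call that takes a human cohort
# and one or more mouse-model cohorts and returns a classed result holding
# z-scores, s-scores, per-analyte comparisons, AERC and the model ranking.

#' Cross-species FFA-profile concordance analysis
#'
#' Runs the full concordance pipeline. All panels are harmonized to their
#' shared analytes first. Human samples are z-scored against the human
#' control group and each mouse cohort against its own control group; the
#' patient cohort's z-score distribution then defines the S-score of every
#' model animal, the radar-polygon area (AERC) summarizes each animal's
#' whole-panel deviation, and models are ranked by mean AERC (smaller =
#' closer to the patient profile). Per-analyte case-control comparisons
#' (normality-gated test selection) are run within every cohort.
#'
#' @param human sample table of the human cohort.
#' @param models named list of mouse sample tables, one per model.
#' @param human_groups length-2 character `c(control, case)` naming the
#'   human control and patient groups.
#' @param model_controls control-group label(s) of the mouse cohorts; a
#'   single string recycled, or a named vector per model. The non-control
#'   group of each table is its model group.
#' @param alpha significance level for per-analyte comparisons.
#' @param radius_transform radar radius transform, see [aerc()].
#' @param panel_order optional explicit radar axis order (analyte ids);
#'   defaults to canonical panel ordering.
#' @param ranking_policy `"mean_aerc"` or `"mean_abs_s"`.
#' @param sscore_input `"zscore"` (default) or `"raw"`, see [sscore()].
#' @param max_missing missing-data policy, see [drop_sparse_analytes()].
#' @return an object of class `ffa_concord` with components `panel`,
#'   `human` (z-scores and comparisons), `models` (per model: z-scores,
#'   comparisons, s-scores, AERC), `ranking`, `pairwise` (s-score t-tests
#'   between the first two models, when >= 2), and `settings`.
#' @seealso [zscore_reference()], [sscore()], [aerc()], [rank_models()]
#' @examples
#' demo <- make_demo(tempfile("demo"), seed = 1)
#' fit <- ffa_concord(demo$human, demo$models,
#'                    human_groups = c("HC", "alMDD"))
#' fit
#' @export
ffa_concord <- function(human, models,
                        human_groups = c("HC", "alMDD"),
                        model_controls = "control",
                        alpha = 0.05,
                        radius_transform = c("abs", "shift_min", "clip_zero"),
                        panel_order = NULL,
                        ranking_policy = c("mean_aerc", "mean_abs_s"),
                        sscore_input = c("zscore", "raw"),
                        max_missing = 0.2) {
  radius_transform <- match.arg(radius_transform)
  ranking_policy <- match.arg(ranking_policy)
  sscore_input <- match.arg(sscore_input)
  stopifnot(is.list(models), length(models) >= 1L, !is.null(names(models)))
  if (length(model_controls) == 1L && is.null(names(model_controls)))
    model_controls <- stats::setNames(rep(model_controls, length(models)),
                                      names(models))
  human <- drop_sparse_analytes(as_sample_table(human), max_missing)
  models <- lapply(models, function(m)
    drop_sparse_analytes(as_sample_table(m), max_missing))

  # harmonize everything to the common shared panel
  for (m in names(models)) {
    h <- harmonize_panels(human, models[[m]])
    human <- h$a; models[[m]] <- h$b
  }
  for (m in names(models)) {
    h <- harmonize_panels(human, models[[m]])
    models[[m]] <- h$b
  }
  panel <- order_panel(analyte_names(human))

  human_z <- zscore_reference(human, human_groups[1])
  # analytes dropped for zero reference SD anywhere are dropped everywhere
  # so the polygons stay comparable
  panel <- intersect(panel, analyte_names(human_z))
  human_cmp <- compare_analytes(human, human_groups[2], human_groups[1],
                                alpha = alpha)
  model_res <- list()
  for (m in names(models)) {
    tabm <- models[[m]]
    ctrl <- model_controls[[m]]
    mgrp <- setdiff(unique(tabm$group), ctrl)
    if (length(mgrp) != 1L)
      stop("model '", m, "': expected exactly one non-control group, got: ",
           paste(mgrp, collapse = ", "))
    zm <- zscore_reference(tabm, ctrl)
    panel <- intersect(panel, analyte_names(zm))
    model_res[[m]] <- list(group = mgrp, control = ctrl, z = zm,
                           comparisons = compare_analytes(
                             tabm, mgrp, ctrl, alpha = alpha))
  }
  if (length(panel) < 3L)
    stop("fewer than 3 analytes survive harmonization; cannot build radar polygons")
  if (is.null(panel_order)) panel_order <- panel
  else if (!all(panel %in% panel_order))
    stop("panel_order must cover the shared panel")
  else panel_order <- panel_order[panel_order %in% panel]

  aerc_by_model <- list(); s_by_model <- list()
  for (m in names(model_res)) {
    r <- model_res[[m]]
    animal_input <- if (sscore_input == "zscore") r$z else models[[m]]
    s_all <- sscore(animal_input, human_z, human_groups[2],
                    input = sscore_input)
    s_model <- s_all[s_all$group == r$group, , drop = FALSE]
    keep <- intersect(panel_order, analyte_names(s_model))
    a <- aerc(s_model, panel_order = keep,
              radius_transform = radius_transform)
    model_res[[m]]$s <- s_model
    model_res[[m]]$aerc <- a
    aerc_by_model[[m]] <- a
    s_by_model[[m]] <- s_model
  }
  ranking <- rank_models(aerc_by_model, s_by_model, policy = ranking_policy)
  pairwise <- NULL
  if (length(model_res) >= 2L) {
    nm <- names(model_res)[1:2]
    pairwise <- compare_model_sscores(s_by_model[[nm[1]]],
                                      s_by_model[[nm[2]]],
                                      names_ab = nm, alpha = alpha)
  }
  structure(list(panel = panel_order,
                 human = list(groups = human_groups, z = human_z,
                              comparisons = human_cmp),
                 models = model_res, ranking = ranking, pairwise = pairwise,
                 settings = list(alpha = alpha,
                                 radius_transform = radius_transform,
                                 ranking_policy = ranking_policy,
                                 sscore_input = sscore_input,
                                 max_missing = max_missing)),
            class = "ffa_concord")
}

#' @export
print.ffa_concord <- function(x, ...) {
  cat("Cross-species FFA concordance analysis\n")
  cat("  shared panel: ", length(x$panel), " analytes\n", sep = "")
  cat("  human cohort: ", x$human$groups[2], " vs ", x$human$groups[1],
      " (", sum(x$human$comparisons$significant),
      " significant analytes at alpha = ", x$settings$alpha, ")\n", sep = "")
  cat("  models ranked by ", x$settings$ranking_policy,
      " (radius transform: ", x$settings$radius_transform, "):\n", sep = "")
  r <- x$ranking
  for (i in seq_len(nrow(r)))
    cat(sprintf("    %d. %-12s mean AERC %.3f   mean |s| %.3f\n",
                r$rank[i], r$model[i], r$mean_aerc[i], r$mean_abs_s[i]))
  invisible(x)
}

#' @export
summary.ffa_concord <- function(object, ...) {
  tabs <- lapply(names(object$models), function(m) {
    r <- object$models[[m]]
    gs <- attr(r$aerc, "group_summary")
    data.frame(model = m, group = r$group,
               n_animals = nrow(r$s),
               n_significant = sum(r$comparisons$significant),
               n_down = sum(r$comparisons$significant &
                              r$comparisons$direction == "down"),
               mean_aerc = gs$mean_area[gs$group == r$group],
               sem_aerc = gs$sem_area[gs$group == r$group],
               stringsAsFactors = FALSE)
  })
  out <- list(models = do.call(rbind, tabs), ranking = object$ranking,
              human_significant = sum(object$human$comparisons$significant),
              human_down = sum(object$human$comparisons$significant &
                                 object$human$comparisons$direction == "down"),
              settings = object$settings)
  class(out) <- "summary.ffa_concord"
  out
}

#' @export
print.summary.ffa_concord <- function(x, ...) {
  cat("Human cohort: ", x$human_significant, " significant analytes (",
      x$human_down, " down)\n\n", sep = "")
  cat("Per-model summary (model-group animals):\n")
  print(x$models, row.names = FALSE)
  cat("\nRanking (smaller = closer to patient profile):\n")
  print(x$ranking, row.names = FALSE)
  invisible(x)
}

#' Radar plot of mean transformed s-scores per model
#'
#' Base-graphics radar chart of each model's mean radius per analyte, on
#' the axis order used for AERC.
#'
#' @param x an `ffa_concord` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.ffa_concord <- function(x, ...) {
  panel <- x$panel; k <- length(panel)
  ang <- pi / 2 - (seq_len(k) - 1L) * 2 * pi / k
  rmax <- 0
  mean_r <- lapply(x$models, function(r)
    colMeans(attr(r$aerc, "radii")))
  rmax <- max(unlist(mean_r), 1e-9)
  graphics::plot(NA, xlim = c(-1.3, 1.3) * rmax, ylim = c(-1.3, 1.3) * rmax,
                 asp = 1, axes = FALSE, xlab = "", ylab = "",
                 main = "Mean |s| radar by model", ...)
  for (f in c(0.5, 1))
    graphics::polygon(f * rmax * cos(ang), f * rmax * sin(ang),
                      border = "grey80")
  graphics::text(1.22 * rmax * cos(ang), 1.22 * rmax * sin(ang), panel,
                 cex = 0.6)
  cols <- grDevices::hcl.colors(max(length(mean_r), 2L), "Dark 3")
  for (i in seq_along(mean_r)) {
    r <- mean_r[[i]][panel]
    graphics::polygon(r * cos(ang), r * sin(ang), border = cols[i], lwd = 2)
  }
  graphics::legend("topright", legend = names(mean_r), col = cols,
                   lwd = 2, bty = "n", cex = 0.8)
  invisible(x)
}
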