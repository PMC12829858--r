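# Synthetic cohort generator. Concentrations are log-normal per analyte:
# positive, spanning orders of magnitude, with a multiplicative case effect
# (additive on the log scale) and optional additive log-scale covariate
# effects. This is the generative model the whole test-bench rests on; real
# GC-MS panels are read in through data_io instead.

#' Default 26-analyte free fatty acid effect panel
#'
#' One row per analyte: canonical id, natural-log mean and SD of the control
#' concentration (log ug/mL), and the multiplicative case fold change
#' (mostly < 1: a general down-regulation of circulating FFAs in the case
#' group, strongest for C16:1, C18:2n6c, C19:0, C15:0, C17:0 and C9:0).
#' Control medians span roughly exp(-2) to exp(5.8) ug/mL, about three
#' orders of magnitude.
#'
#' @return data frame with columns `analyte_id`, `log_mean`, `log_sd`,
#'   `case_fold_change`.
#' @export
ffa_panel <- function() {
  data.frame(
    analyte_id = c("C6:0", "C8:0", "C9:0", "C10:0", "C11:0", "C12:0",
                   "C13:0", "C14:0", "C14:1", "C15:0", "C16:0", "C16:1",
                   "C17:0", "C17:1", "C18:0", "C18:1n9c", "C18:2n6c",
                   "C18:3n3", "C19:0", "C20:0", "C20:3n6", "C20:4n6",
                   "C20:5n3", "C21:0", "C22:0", "C22:6n3"),
    log_mean = c(0.0, -0.7, -1.2, -0.5, -2.0, 0.7, -1.6, 2.3, -0.9, 0.6,
                 5.6, 2.8, 1.1, 0.1, 5.2, 5.5, 5.8, 2.1, -0.4, 0.9, 1.6,
                 4.3, 2.0, -1.5, 0.5, 3.6),
    log_sd = c(0.45, 0.5, 0.5, 0.55, 0.5, 0.6, 0.5, 0.5, 0.55, 0.45, 0.35,
               0.5, 0.4, 0.5, 0.3, 0.4, 0.35, 0.5, 0.45, 0.4, 0.45, 0.35,
               0.55, 0.5, 0.45, 0.4),
    case_fold_change = c(0.85, 0.9, 0.75, 0.9, 1.0, 0.9, 0.95, 0.8, 0.9,
                         0.75, 0.9, 0.65, 0.75, 0.9, 0.95, 0.9, 0.7, 0.85,
                         0.7, 0.95, 0.9, 0.85, 0.85, 1.0, 0.95, 0.85),
    stringsAsFactors = FALSE
  )
}

.default_covariate_model <- function() {
  list(sex = list(p_female = 0.5),
       age = list(mean = 14.7, sd = 1.9),
       education_years = list(mean = 8.9, sd = 1.8))
}

#' Build and validate a simulation configuration
#'
#' @param panel effect panel as from [ffa_panel()] (columns `analyte_id`,
#'   `log_mean`, `log_sd`, `case_fold_change`).
#' @param n_control,n_case group sizes, both at least 2 (standard deviations
#'   must be computable).
#' @param covariate_model per-covariate distributions: `sex` as
#'   Bernoulli(`p_female`), `age` and `education_years` as normals. `NULL`
#'   disables covariates (mouse cohorts).
#' @param covariate_effects optional numeric matrix, one row per analyte,
#'   columns among `sex`, `age`, `education_years`: additive log-scale
#'   coefficients applied to the female indicator and to mean-centred age
#'   and education.
#' @param seed integer seed for this cohort's random stream.
#' @return validated `ffa_sim_config` list.
#' @export
sim_config <- function(panel = ffa_panel(), n_control, n_case,
                       covariate_model = NULL, covariate_effects = NULL,
                       seed = 1L) {
  stopifnot(is.data.frame(panel),
            all(c("analyte_id", "log_mean", "log_sd", "case_fold_change")
                %in% names(panel)))
  if (nrow(panel) == 0L) stop("panel is empty")
  if (anyDuplicated(panel$analyte_id)) stop("duplicate analyte_id in panel")
  if (any(panel$log_sd <= 0)) stop("log_sd must be > 0 for every analyte")
  if (any(panel$case_fold_change <= 0))
    stop("case_fold_change must be > 0 for every analyte")
  if (n_control < 2 || n_case < 2)
    stop("n_control and n_case must both be >= 2")
  if (!is.null(covariate_effects)) {
    covariate_effects <- as.matrix(covariate_effects)
    if (nrow(covariate_effects) != nrow(panel))
      stop("covariate_effects must have one row per panel analyte")
    if (is.null(colnames(covariate_effects)) ||
        !all(colnames(covariate_effects) %in%
             c("sex", "age", "education_years")))
      stop("covariate_effects columns must be named among sex, age, education_years")
  }
  structure(list(panel = panel, n_control = as.integer(n_control),
                 n_case = as.integer(n_case),
                 covariate_model = covariate_model,
                 covariate_effects = covariate_effects,
                 seed = as.integer(seed)),
            class = "ffa_sim_config")
}

#' Simulate one case-control cohort
#'
#' Concentration of analyte a in subject i is
#' `exp(log_mean_a + covariate terms + eps)`, `eps ~ N(0, log_sd_a)`,
#' multiplied by `case_fold_change_a` if the subject is a case. All
#' concentrations are strictly positive; the same config and seed give a
#' bit-identical table.
#'
#' @param config an `ffa_sim_config`.
#' @param group_labels length-2 character: control label, case label.
#' @param species `"human"` or `"mouse"` tag for the output table.
#' @param id_prefix prefix for generated sample ids.
#' @return a sample table; the generating fold-change vector is attached as
#'   attribute `"true_fold_change"` (named by analyte).
#' @export
simulate_cohort <- function(config, group_labels = c("HC", "case"),
                            species = "human", id_prefix = species) {
  if (!inherits(config, "ffa_sim_config")) config <- do.call(sim_config, config)
  stopifnot(length(group_labels) == 2L)
  panel <- config$panel
  k <- nrow(panel)
  n <- config$n_control + config$n_case
  is_case <- rep(c(FALSE, TRUE), c(config$n_control, config$n_case))
  with_seed(config$seed, {
    cm <- config$covariate_model
    if (!is.null(cm)) {
      sex <- ifelse(stats::rbinom(n, 1L, cm$sex$p_female) == 1L,
                    "female", "male")
      age <- stats::rnorm(n, cm$age$mean, cm$age$sd)
      edu <- stats::rnorm(n, cm$education_years$mean, cm$education_years$sd)
    } else {
      sex <- rep("male", n); age <- rep(NA_real_, n); edu <- rep(NA_real_, n)
    }
    cov_term <- matrix(0, n, k)
    ce <- config$covariate_effects
    if (!is.null(ce) && !is.null(cm)) {
      design <- cbind(sex = as.numeric(sex == "female"),
                      age = age - cm$age$mean,
                      education_years = edu - cm$education_years$mean)
      cov_term <- design[, colnames(ce), drop = FALSE] %*% t(ce)
    }
    eps <- matrix(stats::rnorm(n * k), n, k) %*% diag(panel$log_sd, k)
    logc <- matrix(panel$log_mean, n, k, byrow = TRUE) + cov_term + eps +
      outer(is_case, log(panel$case_fold_change))
    conc <- exp(logc)
  })
  out <- data.frame(
    sample_id = sprintf("%s_%s_%02d", id_prefix,
                        ifelse(is_case, group_labels[2], group_labels[1]),
                        c(seq_len(config$n_control), seq_len(config$n_case))),
    species = species,
    group = ifelse(is_case, group_labels[2], group_labels[1]),
    sex = sex, age = age, education_years = edu,
    stringsAsFactors = FALSE)
  conc <- as.data.frame(conc)
  names(conc) <- panel$analyte_id
  out <- as_sample_table(cbind(out, conc))
  attr(out, "true_fold_change") <-
    stats::setNames(panel$case_fold_change, panel$analyte_id)
  out
}

#' Simulate a cross-species concordance scenario
#'
#' Generates a human case-control cohort plus one mouse cohort per model.
#' For each model a fraction `fidelity` of the analytes inherit the human
#' case fold change (a seeded random subset); the remainder get fold change
#' 1 (no effect). Ground-truth fold-change vectors and the inherited analyte
#' sets are returned for parameter-recovery tests.
#'
#' @param human_config `ffa_sim_config` for the human cohort.
#' @param model_configs named list of `ffa_sim_config`, one per mouse model;
#'   panels must share the human panel's analyte ids.
#' @param fidelity named numeric in \[0, 1\], one entry per model.
#' @param human_labels,model_control_label group labels.
#' @param seed integer seed governing both the subset draws and all cohort
#'   streams (per-stream sub-seeds are derived from it).
#' @return list with `human` (sample table), `models` (named list of sample
#'   tables) and `truth` (per model: inherited analyte ids and the full
#'   generating fold-change vector).
#' @export
simulate_concordance_scenario <- function(human_config, model_configs,
                                          fidelity,
                                          human_labels = c("HC", "alMDD"),
                                          model_control_label = "control",
                                          seed = 1L) {
  stopifnot(is.list(model_configs), length(model_configs) >= 1L,
            !is.null(names(model_configs)))
  if (is.null(names(fidelity)) ||
      !setequal(names(fidelity), names(model_configs)))
    stop("fidelity must be named to match model_configs")
  if (any(fidelity < 0 | fidelity > 1)) stop("fidelity values must be in [0, 1]")
  hp <- human_config$panel
  if (nrow(hp) == 0L) stop("human panel is empty")
  human_config$seed <- derive_seed(seed, "human")
  human <- simulate_cohort(human_config, human_labels, species = "human",
                           id_prefix = "hum")
  models <- list(); truth <- list()
  for (m in names(model_configs)) {
    cfg <- model_configs[[m]]
    if (!setequal(cfg$panel$analyte_id, hp$analyte_id))
      stop("panel of model '", m, "' does not match the human panel")
    cfg$panel <- cfg$panel[match(hp$analyte_id, cfg$panel$analyte_id), ]
    k <- nrow(hp)
    n_inherit <- round(fidelity[[m]] * k)
    inherit <- with_seed(derive_seed(seed, paste0("subset_", m)),
                         sort(sample.int(k, n_inherit)))
    fc <- rep(1, k)
    fc[inherit] <- hp$case_fold_change[inherit]
    cfg$panel$case_fold_change <- fc
    cfg$seed <- derive_seed(seed, paste0("model_", m))
    models[[m]] <- simulate_cohort(cfg, c(model_control_label, m),
                                   species = "mouse", id_prefix = m)
    truth[[m]] <- list(inherited = hp$analyte_id[inherit],
                       fold_change = stats::setNames(fc, hp$analyte_id))
  }
  list(human = human, models = models, truth = truth)
}

#' Simulate behavioral endpoints for a mouse depression model
#'
#' Immobility time in the forced swim test (seconds within a 240 s scoring
#' window), sucrose and water intakes (grams, strictly positive, log-normal)
#' and social-interaction-zone time (seconds). The case group is shifted by
#' `effect` standard deviations in the depressive direction: longer
#' immobility, lower sucrose intake, shorter interaction-zone time.
#'
#' @param n_per_group animals per group, at least 2.
#' @param effect standardized effect size (Cohen's d).
#' @param seed integer seed.
#' @return data frame with columns `sample_id`, `group`, `immobility_s`,
#'   `sucrose_g`, `water_g`, `interaction_zone_s`, `sucrose_preference_pct`.
#' @export
simulate_behavior <- function(n_per_group, effect = 0, seed = 1L) {
  if (n_per_group < 2) stop("n_per_group must be >= 2")
  n <- 2L * n_per_group
  is_case <- rep(c(FALSE, TRUE), each = n_per_group)
  with_seed(derive_seed(seed, "behavior"), {
    immob <- stats::rnorm(n, 100 + 30 * effect * is_case, 30)
    immob <- pmin(pmax(immob, 0), 240)
    sucrose <- exp(stats::rnorm(n, log(3) - 0.25 * effect * is_case, 0.25))
    water <- exp(stats::rnorm(n, log(1), 0.25))
    izone <- pmax(stats::rnorm(n, 80 - 20 * effect * is_case, 20), 0)
  })
  data.frame(
    sample_id = sprintf("m_%s_%02d", ifelse(is_case, "case", "control"),
                        c(seq_len(n_per_group), seq_len(n_per_group))),
    group = ifelse(is_case, "case", "control"),
    immobility_s = immob, sucrose_g = sucrose, water_g = water,
    interaction_zone_s = izone,
    sucrose_preference_pct = sucrose_preference(sucrose, water),
    stringsAsFactors = FALSE)
}
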