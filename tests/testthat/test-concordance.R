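test_that("z-scores follow the reference-population definition", {
  tab <- tiny_table(matrix(c(2, 4, 6, 6), 4), c("HC", "HC", "HC", "MDD"),
                    analytes = "C16:1")
  z <- zscore_reference(tab, "HC")
  expect_equal(z[["C16:1"]][4], 1)  # mean 4, sample SD 2
  tab2 <- tiny_table(matrix(c(2, 4, 6, 4), 4), c("HC", "HC", "HC", "MDD"),
                     analytes = "C16:1")
  expect_equal(zscore_reference(tab2, "HC")[["C16:1"]][4], 0)
})

test_that("reference cohort z-scores have mean 0 and SD 1 per analyte", {
  set.seed(13)
  tab <- tiny_table(matrix(rlnorm(200, 1, 0.6), 50, 4),
                    rep(c("HC", "MDD"), 25))
  z <- zscore_reference(tab, "HC")
  for (a in analyte_names(z)) {
    zr <- z[[a]][z$group == "HC"]
    expect_equal(mean(zr), 0, tolerance = 1e-12)
    expect_equal(sd(zr), 1, tolerance = 1e-12)
  }
  expect_identical(attr(z, "reference_group"), "HC")
})

test_that("zero-SD analytes are dropped with a warning, absent groups error", {
  tab <- tiny_table(cbind(c(3, 3, 3, 5), c(1, 2, 3, 4)),
                    c("HC", "HC", "HC", "MDD"),
                    analytes = c("C6:0", "C9:0"))
  expect_warning(z <- zscore_reference(tab, "HC"), "C6:0")
  expect_identical(analyte_names(z), "C9:0")
  expect_error(zscore_reference(tab, "nope"), "reference group")
  one <- tiny_table(matrix(1:2, 2), c("HC", "MDD"))
  expect_error(zscore_reference(one, "HC"), "fewer than 2")
})

# crafted cohorts whose z-scores are exactly the hand-computed values:
# human reference [10,11,12] (mean 11, sd 1), patients 11 + z for
# z = (-1, -0.5, -1.5); mouse controls [5,6,7] (mean 6, sd 1)
crafted_pair <- function(animal_raw) {
  human <- tiny_table(matrix(c(10, 11, 12, 10, 10.5, 9.5), 6),
                      c(rep("HC", 3), rep("alMDD", 3)), analytes = "C16:1")
  mouse <- tiny_table(matrix(c(5, 6, 7, animal_raw), 4),
                      c(rep("ctl", 3), "LPS"), species = "mouse",
                      analytes = "C16:1")
  list(hz = zscore_reference(human, "HC"),
       mz = zscore_reference(mouse, "ctl"))
}

test_that("s-scores match hand computation against the patient z moments", {
  # patient z-scores are (-1, -0.5, -1.5): mean -1, SD 0.5
  p <- crafted_pair(animal_raw = 6)  # animal z = 0
  s <- sscore(p$mz, p$hz, "alMDD")
  expect_equal(s[["C16:1"]][s$group == "LPS"], 2)
  p2 <- crafted_pair(animal_raw = 4.5)  # animal z = -1.5
  s2 <- sscore(p2$mz, p2$hz, "alMDD")
  expect_equal(s2[["C16:1"]][s2$group == "LPS"], -1)
  p3 <- crafted_pair(animal_raw = 5)  # animal z = -1 = patient mean z
  s3 <- sscore(p3$mz, p3$hz, "alMDD")
  expect_equal(s3[["C16:1"]][s3$group == "LPS"], 0)
})

test_that("s-scores are invariant to within-species unit rescaling", {
  set.seed(19)
  human <- tiny_table(matrix(rlnorm(120, 2, 0.5), 30, 4),
                      rep(c("HC", "alMDD"), 15))
  mouse <- tiny_table(matrix(rlnorm(48, 1, 0.5), 12, 4),
                      rep(c("ctl", "LPS"), 6), species = "mouse")
  s1 <- sscore(zscore_reference(mouse, "ctl"),
               zscore_reference(human, "HC"), "alMDD")
  human2 <- human; mouse2 <- mouse
  for (a in analyte_names(human)) human2[[a]] <- 7 * human2[[a]]
  for (a in analyte_names(mouse)) mouse2[[a]] <- 1000 * mouse2[[a]]
  s2 <- sscore(zscore_reference(mouse2, "ctl"),
               zscore_reference(human2, "HC"), "alMDD")
  for (a in analyte_names(s1)) expect_equal(s1[[a]], s2[[a]], tolerance = 1e-10)
})

test_that("radar polygon area follows the closed forms", {
  expect_equal(radar_polygon_area(rep(1, 4)), 2)
  expect_equal(radar_polygon_area(rep(1, 26)), 13 * sin(2 * pi / 26))
  expect_identical(radar_polygon_area(rep(0, 5)), 0)
  expect_error(radar_polygon_area(c(1, 2)), "at least 3")
  expect_error(radar_polygon_area(c(1, -1, 2)), "negative")
})

test_that("polar area equals the Cartesian shoelace oracle", {
  set.seed(37)
  for (i in 1:200) {
    k <- sample(3:8, 1)
    r <- runif(k, 0, 5)
    expect_equal(radar_polygon_area(r), shoelace_area(r), tolerance = 1e-10)
  }
})

test_that("scaling all radii by c scales the area by c^2", {
  set.seed(43)
  r <- runif(7, 0.1, 2)
  for (cc in c(1.5, 3, 10))
    expect_equal(radar_polygon_area(cc * r), cc^2 * radar_polygon_area(r),
                 tolerance = 1e-10)
})

test_that("AERC summarizes per-animal areas with mean and SEM by group", {
  set.seed(47)
  human <- tiny_table(matrix(rlnorm(240, 2, 0.5), 40, 6),
                      rep(c("HC", "alMDD"), 20))
  mouse <- tiny_table(matrix(rlnorm(72, 1, 0.5), 12, 6),
                      rep(c("ctl", "LPS"), each = 6), species = "mouse")
  s <- sscore(zscore_reference(mouse, "ctl"),
              zscore_reference(human, "HC"), "alMDD")
  a <- aerc(s)
  expect_true(all(a$area >= 0))
  gs <- attr(a, "group_summary")
  lps <- a$area[a$group == "LPS"]
  expect_equal(gs$mean_area[gs$group == "LPS"], mean(lps))
  expect_equal(gs$sem_area[gs$group == "LPS"], sd(lps) / sqrt(length(lps)))
  expect_identical(attr(a, "panel_order"), order_panel(analyte_names(s)))
  # transform semantics
  a_shift <- aerc(s, radius_transform = "shift_min")
  expect_true(all(apply(attr(a_shift, "radii"), 1, min) == 0))
  a_clip <- aerc(s, radius_transform = "clip_zero")
  expect_true(all(attr(a_clip, "radii") >= 0))
  # vertex export covers every animal x analyte pair
  v <- radar_vertices(a)
  expect_equal(nrow(v), nrow(s) * length(analyte_names(s)))
})

test_that("AERC area depends on axis order as a polygon area must", {
  s_vals <- c(3, 0.1, 2.5, 0.2, 1.5, 0.3)
  expect_false(isTRUE(all.equal(
    radar_polygon_area(s_vals), radar_polygon_area(sort(s_vals)))))
})

test_that("model s-score comparison flags the closer model", {
  meta <- data.frame(sample_id = paste0("m", 1:4), species = "mouse",
                     group = "g", stringsAsFactors = FALSE)
  mk <- function(vals) {
    df <- cbind(meta, data.frame(`C6:0` = vals[, 1], `C9:0` = vals[, 2],
                                 `C14:0` = vals[, 3], check.names = FALSE))
    structure(df, class = c("ffa_sscore", "data.frame"))
  }
  a <- mk(matrix(c(0, 0.1, -0.1, 0), 4, 3))
  b <- mk(matrix(3 + c(0, 0.1, -0.1, 0), 4, 3))
  cmp <- compare_model_sscores(a, b, names_ab = c("A", "B"))
  expect_true(all(cmp$per_analyte$closer == "A"))
  expect_identical(cmp$winner, "A")
  same <- compare_model_sscores(a, a, names_ab = c("A", "B"))
  expect_true(all(same$per_analyte$p_value == 1))
  expect_true(is.na(same$winner))
})

test_that("model ranking orders by policy with documented tie-breaks", {
  r <- rank_models(list(A = 1, B = 2), list(A = 0.5, B = 0.6))
  expect_identical(r$model, c("A", "B"))
  # tie on AERC broken by mean |s|
  r2 <- rank_models(list(A = 1, B = 1), list(A = 0.7, B = 0.5))
  expect_identical(r2$model, c("B", "A"))
  # full tie broken by name
  r3 <- rank_models(list(B = 1, A = 1), list(B = 0.5, A = 0.5))
  expect_identical(r3$model, c("A", "B"))
  r4 <- rank_models(list(only = 2), list(only = 1))
  expect_identical(nrow(r4), 1L)
  expect_error(rank_models(list(), list()), "no models")
})
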