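test_that("evaluate_year satisfies its boundary identities", {
  reg <- default_registry()
  w <- fixture_weights()
  ones <- stats::setNames(rep(1, 17), reg$id)
  res <- evaluate_year(ones, w, reg)
  expect_equal(res$comprehensive_value, 1, tolerance = 1e-9)
  # group values equal each group's weight mass
  mass <- tapply(as.numeric(w), reg$group, sum)
  expect_equal(res$group_values, mass[names(res$group_values)],
               tolerance = 1e-9, ignore_attr = TRUE)
  # one-hot weight on S31 with S31 = 1
  onehot <- weight_vector(as.numeric(reg$id == "S31"), labels = reg$id)
  expect_equal(evaluate_year(ones, onehot, reg)$comprehensive_value, 1,
               tolerance = 1e-12)
  expect_error(evaluate_year(unname(ones), w, reg),
               class = "les_schema_error")
})

test_that("comprehensive value always equals the sum of group values", {
  reg <- default_registry()
  for (mode in c("scalar", "fuzzy")) {
    cfg <- pipeline_config(score_mode = mode)
    for (s in 1:25) {
      x <- stats::setNames(landsec:::with_seed(s, stats::runif(17)), reg$id)
      w <- rand_weights(17, seed = 500 + s)
      names(w) <- reg$id
      res <- evaluate_year(x, w, reg, cfg)
      expect_equal(res$comprehensive_value, sum(res$group_values),
                   tolerance = 1e-9)
      expect_equal(sum(res$membership$comprehensive), 1, tolerance = 1e-9)
      expect_true(res$comprehensive_value >= 0 &&
                    res$comprehensive_value <= 1 + 1e-12)
    }
  }
})

test_that("evaluate_panel yields one ordered result per year", {
  t1 <- load_fixture("table1_normalized")
  res <- evaluate_panel(t1)
  expect_s3_class(res, "les_results")
  expect_equal(res$year, 2004:2017)
  expect_equal(res$comprehensive, res$S1 + res$S2 + res$S3,
               tolerance = 1e-9)
  # rising security through 2016, mirroring the published trend
  expect_true(all(diff(res$comprehensive[1:13]) >= 0))
  # an all-ones panel scores exactly 1 every year
  ones <- indicator_panel(2004:2006, matrix(1, 3, 17,
                                            dimnames = list(NULL,
                                                            colnames(t1))),
                          normalized = TRUE)
  expect_equal(evaluate_panel(ones)$comprehensive, rep(1, 3),
               tolerance = 1e-9)
})

test_that("permuting indicators together with weights changes nothing", {
  reg <- default_registry()
  t1 <- load_fixture("table1_normalized")
  w <- fixture_weights()
  res <- evaluate_panel(t1, w, reg)
  p <- landsec:::with_seed(4, sample(17))
  preg <- indicator_registry(reg$id[p], reg$name[p], reg$unit[p],
                             reg$polarity[p], reg$group[p],
                             attr(reg, "group_labels"))
  ppan <- indicator_panel(panel_years(t1), unclass(t1)[, p],
                          normalized = TRUE)
  pres <- evaluate_panel(ppan, weight_vector(as.numeric(w)[p],
                                             labels = reg$id[p]), preg)
  expect_equal(pres$comprehensive, res$comprehensive, tolerance = 1e-12)
  expect_equal(pres[c("S1", "S2", "S3")], res[c("S1", "S2", "S3")],
               tolerance = 1e-12)
})

test_that("land_use_change_report reports sorted signed changes", {
  t1 <- load_fixture("table1_normalized")
  rep <- land_use_change_report(t1, c("S15", "S21", "S16"), 2004, 2017)
  expect_equal(rep$id, c("S21", "S15", "S16"))  # by |change| descending
  expect_equal(rep$percent_change[rep$id == "S21"], 25.20, tolerance = 1e-2)
  expect_equal(land_use_change_report(t1, "S12", 2010,
                                      2010)$percent_change, 0)
  expect_error(land_use_change_report(t1, c("S21", "S99"), 2004, 2017),
               "S99", class = "les_lookup_error")
  # identical on a raw panel proportional to the normalized one
  raw <- indicator_panel(panel_years(t1),
                         sweep(unclass(t1), 2L, seq(2, 34, 2), "*"))
  expect_equal(land_use_change_report(raw, c("S15", "S21", "S16"),
                                      2004, 2017)$percent_change,
               rep$percent_change, tolerance = 1e-9)
})

test_that("trend_report decomposes series into monotone segments", {
  up <- data.frame(year = 2004:2010, comprehensive = seq(0.1, 0.7, 0.1))
  class(up) <- c("les_results", "data.frame")
  tr <- trend_report(up)$comprehensive
  expect_equal(nrow(tr$segments), 1L)
  expect_equal(tr$segments$direction, "rising")
  expect_equal(tr$peak_year, 2010)
  expect_false(tr$falls_after_peak)

  hump <- data.frame(year = 2004:2010,
                     comprehensive = c(0.1, 0.2, 0.3, 0.6, 0.5, 0.4, 0.3))
  class(hump) <- c("les_results", "data.frame")
  tr2 <- trend_report(hump)$comprehensive
  expect_equal(tr2$peak_year, 2007)
  expect_equal(nrow(tr2$segments), 2L)
  expect_true(tr2$falls_after_peak)

  one <- up[1, , drop = FALSE]
  class(one) <- c("les_results", "data.frame")
  expect_error(trend_report(one), class = "les_value_error")
})

test_that("the published natural-coordination series peaks in 2009", {
  t3 <- load_fixture("table3_results")
  tr <- trend_report(t3)
  expect_equal(tr$S1$peak_year, 2009)
  expect_equal(tr$S1$peak_value, 0.1091)
  expect_true(tr$S1$falls_after_peak)
  expect_false(tr$S2$falls_after_peak)
})

test_that("scalar thresholds classify levels as configured", {
  cfg <- pipeline_config()
  set <- cfg$assessment
  expect_equal(landsec:::classify_scalar(0.80, cfg$scalar_thresholds, set), "S")
  expect_equal(landsec:::classify_scalar(0.60, cfg$scalar_thresholds, set), "RS")
  expect_equal(landsec:::classify_scalar(0.50, cfg$scalar_thresholds, set), "RU")
  expect_equal(landsec:::classify_scalar(0.347, cfg$scalar_thresholds, set), "U")
  expect_error(pipeline_config(scalar_thresholds = c(S = 0.5, RS = 0.6,
                                                     RU = 0.4)),
               class = "les_value_error")
})

test_that("pipeline configuration round-trips through YAML", {
  cfg <- pipeline_config(
    normalization = normalization_config(negative_mode = "inverse_min_over_x"),
    score_mode = "fuzzy",
    scalar_thresholds = c(S = 0.8, RS = 0.6, RU = 0.4))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, path)
  back <- read_config(path)
  expect_equal(back$normalization$negative_mode, "inverse_min_over_x")
  expect_equal(back$score_mode, "fuzzy")
  expect_equal(back$scalar_thresholds, cfg$scalar_thresholds)
  expect_equal(back$assessment$anchors, cfg$assessment$anchors)
})
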