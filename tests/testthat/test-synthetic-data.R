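test_that("generation is reproducible and obeys its configuration", {
  cfg <- generator_config(n_samples = 30, seed = 99)
  g1 <- generate_survey(cfg)
  g2 <- generate_survey(cfg)
  expect_identical(survey_matrix(g1$survey), survey_matrix(g2$survey))
  expect_identical(g1$truth$precensor, g2$truth$precensor)
  expect_equal(nrow(g1$survey), 30)
  expect_setequal(survey_analytes(g1$survey), cfg$analytes)

  # zero detection limits: no non-detect flags
  g0 <- generate_survey(generator_config(n_samples = 20, detection_limits = 0,
                                         seed = 5))
  expect_false(any(attr(g0$survey, "nondetect")))
})

test_that("an infeasible correlation matrix is rejected", {
  cfg <- generator_config(
    cluster_spec = list(list(members = c("Cd", "Cr"), within_cor = 0.5)))
  expect_no_error(generate_survey(cfg))
  expect_error(generator_config(
    cluster_spec = list(list(members = c("Cd", "Cr"), within_cor = 1.2))))
  expect_error(generator_config(
    cluster_spec = list(list(members = c("Cd", "Xx"), within_cor = 0.5))))
  expect_error(generator_config(hotspot_spec = list(analyte = "Pb",
                                                    n_hotspots = 1,
                                                    multiplier = 0.5)))
})

test_that("hotspot samples are multiplied on the configured analyte", {
  cfg <- generator_config(n_samples = 25, detection_limits = 0,
                          hotspot_spec = list(analyte = "Pb", n_hotspots = 2,
                                              multiplier = 50), seed = 7)
  g <- generate_survey(cfg)
  hs <- g$truth$hotspot_samples
  expect_length(hs, 2)
  pb <- survey_matrix(g$survey)[, "Pb"]
  # hotspot rows carry the two largest Pb values
  expect_setequal(order(pb, decreasing = TRUE)[1:2], hs)
})

test_that("detection-limit censoring hits the analytic rate at the median", {
  n <- 5000
  dl <- exp(-4)   # the median of lognormal(meanlog = -4)
  cfg <- generator_config(n_samples = n, analytes = c("Cd", "Pb"),
                          cluster_spec = NULL, meanlog = -4, sdlog = 1,
                          hotspot_spec = NULL, detection_limits = dl,
                          seed = 13)
  g <- generate_survey(cfg)
  nd_frac <- mean(attr(g$survey, "nondetect")[, "Cd"])
  expect_lt(abs(nd_frac - 0.5), 3 * sqrt(0.25 / n))
})

test_that("raising a detection limit never decreases the non-detect count", {
  base <- generator_config(n_samples = 200, analytes = c("Cd", "Pb"),
                           cluster_spec = NULL, hotspot_spec = NULL,
                           meanlog = -4, sdlog = 1,
                           detection_limits = 0.01, seed = 3)
  high <- generator_config(n_samples = 200, analytes = c("Cd", "Pb"),
                           cluster_spec = NULL, hotspot_spec = NULL,
                           meanlog = -4, sdlog = 1,
                           detection_limits = 0.05, seed = 3)
  n_low <- sum(attr(generate_survey(base)$survey, "nondetect"))
  n_high <- sum(attr(generate_survey(high)$survey, "nondetect"))
  expect_gte(n_high, n_low)
})

test_that("log-moments converge to the configured values (3 SE at n = 5000)", {
  n <- 5000
  cfg <- generator_config(n_samples = n, analytes = c("Cd", "Pb"),
                          cluster_spec = NULL, hotspot_spec = NULL,
                          meanlog = c(Cd = -5, Pb = -2),
                          sdlog = c(Cd = 1, Pb = 0.5),
                          detection_limits = 0, seed = 21)
  x <- log(generate_survey(cfg)$truth$precensor)
  expect_lt(abs(mean(x[, "Cd"]) - (-5)), 3 * 1 / sqrt(n))
  expect_lt(abs(mean(x[, "Pb"]) - (-2)), 3 * 0.5 / sqrt(n))
  expect_lt(abs(sd(x[, "Cd"]) - 1), 3 * 1 / sqrt(2 * n))
  # planted correlation is realised on the log scale
  cfg2 <- generator_config(n_samples = n, analytes = c("Cd", "Cr", "Pb"),
                           cluster_spec = list(list(members = c("Cd", "Cr"),
                                                    within_cor = 0.7)),
                           hotspot_spec = NULL, detection_limits = 0, seed = 22)
  y <- log(generate_survey(cfg2)$truth$precensor)
  expect_equal(cor(y[, "Cd"], y[, "Cr"]), 0.7, tolerance = 0.05)
  expect_lt(abs(cor(y[, "Cd"], y[, "Pb"])), 0.05)
})

test_that("re-censoring the ground truth reproduces the emitted survey exactly", {
  cfg <- generator_config(n_samples = 60, seed = 31)
  g <- generate_survey(cfg)
  pre <- g$truth$precensor
  nd <- sweep(pre, 2, cfg$detection_limits, "<")
  expect_identical(unname(nd), unname(attr(g$survey, "nondetect")))
  redone <- pre; redone[nd] <- NA_real_
  expect_identical(unname(redone), unname(survey_matrix(g$survey)))
})

test_that("the planted variable partition is recovered at default separation", {
  cfg <- generator_config(n_samples = 200, detection_limits = 0, seed = 11)
  g <- generate_survey(cfg)
  expect_equal(planted_partition_check(g$survey, g$truth), 1)

  # null structure: no planted correlation leaves recovery near chance
  set.seed(55)
  aris <- vapply(1:10, function(s) {
    cfg0 <- generator_config(n_samples = 60, detection_limits = 0,
                             cluster_spec = NULL, hotspot_spec = NULL, seed = s)
    g0 <- generate_survey(cfg0)
    truth <- g0$truth
    truth$cluster_labels[] <- rep(1:3, length.out = 8)   # arbitrary 3-group truth
    planted_partition_check(g0$survey, truth)
  }, numeric(1))
  expect_lt(abs(mean(aris)), 0.25)

  # a single planted group is rejected
  g1 <- generate_survey(generator_config(
    n_samples = 30, detection_limits = 0,
    cluster_spec = list(list(members = c("Cd", "Cr", "Cu", "Fe", "Mn", "Ni",
                                         "Pb", "Zn"), within_cor = 0.5))))
  expect_error(planted_partition_check(g1$survey, g1$truth), "at least 2")
  # k disagreeing with the truth is rejected
  g2 <- generate_survey(generator_config(n_samples = 30, detection_limits = 0))
  expect_error(planted_partition_check(g2$survey, g2$truth, k = 2), "match")
})
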