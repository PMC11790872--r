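point_exposure <- function(receptor) {
  s <- exposure_scenario(receptor)
  list(ir = point_mass(s$ir), ef = point_mass(s$ef), ed = point_mass(s$ed),
       bw = point_mass(s$bw), sa = point_mass(s$sa), et = point_mass(s$et),
       cf = point_mass(s$cf))
}

test_that("distribution specs validate their parameters and draw reproducibly", {
  expect_error(dist_spec("normal", mean = 0, sd = -1), "negative sd")
  expect_error(dist_spec("uniform", min = 2, max = 1), "min > max")
  expect_error(dist_spec("triangular", min = 0, mode = 3, max = 2))

  expect_equal(sample_draws(point_mass(3.5), 4, seed = 1), rep(3.5, 4))
  expect_equal(sample_draws(dist_spec("uniform", 2, 2), 5, seed = 1), rep(2, 5))

  spec <- dist_spec("lognormal", meanlog = -1, sdlog = 0.7)
  a <- sample_draws(spec, 1000, seed = 9)
  b <- sample_draws(spec, 1000, seed = 9)
  expect_identical(a, b)
  expect_false(identical(a, sample_draws(spec, 1000, seed = 10)))
})

test_that("lognormal draws have the configured log-moments (CLT bound)", {
  spec <- dist_spec("lognormal", meanlog = -2, sdlog = 0.8)
  n <- 10000
  x <- sample_draws(spec, n, seed = 4)
  expect_lt(abs(mean(log(x)) - (-2)), 4 * 0.8 / sqrt(n))
  expect_true(all(x > 0))
})

test_that("truncation bounds every draw and renormalises the mass", {
  spec <- dist_spec("normal", mean = 0, sd = 1, truncation = c(-1, 2))
  x <- sample_draws(spec, 5000, seed = 2)
  expect_true(all(x >= -1 & x <= 2))
  # renormalised mean of a [-1, 2]-truncated standard normal
  expected <- (dnorm(-1) - dnorm(2)) / (pnorm(2) - pnorm(-1))
  expect_equal(mean(x), expected, tolerance = 0.05)
  expect_error(sample_draws(dist_spec("uniform", 0, 1, truncation = c(5, 6)), 10, 1),
               "zero probability")
})

test_that("a degenerate simulation equals the deterministic chain exactly", {
  reg <- load_reference_registry()
  conc <- list(Cd = point_mass(0.02), Pb = point_mass(0.1))
  exps <- list(adult = point_exposure("adult"), child = point_exposure("child"))
  res <- mc_survey_risk(conc, exps, reg, n = 50, seed = 3)
  for (m in names(conc)) {
    ref <- reg$metals[m, ]
    for (receptor in names(exps)) {
      s <- exposure_scenario(receptor)
      c_w <- if (m == "Cd") 0.02 else 0.1
      det_oral <- hq(cdi_oral(c_w, s), ref$rfd_oral)
      row <- res[res$metal == m & res$receptor == receptor & res$route == "oral", ]
      expect_identical(row$hq_p5, det_oral)
      expect_identical(row$hq_mean, det_oral)
      expect_identical(row$hq_p95, det_oral)
      expect_identical(row$cr_mean, cr(cdi_oral(c_w, s), ref$csf_oral)$value)
      det_derm <- hq(cdi_dermal(c_w, ref$kp, s), ref$rfd_oral, ref$abs_gi, "dermal")
      drow <- res[res$metal == m & res$receptor == receptor & res$route == "dermal", ]
      expect_identical(drow$hq_mean, det_derm)
    }
  }
})

test_that("lognormal-concentration CR 95th percentile matches the closed form", {
  reg <- load_reference_registry()
  mu <- log(0.05); sigma <- 0.5
  conc <- list(Pb = dist_spec("lognormal", meanlog = mu, sdlog = sigma))
  exps <- list(adult = point_exposure("adult"))
  n <- 10000
  res <- mc_survey_risk(conc, exps, reg, n = n, seed = 6)
  s <- exposure_scenario("adult")
  k <- s$ir * s$ef * s$ed / (s$bw * s$at) * reg$metals["Pb", "csf_oral"]
  closed <- k * exp(mu + qnorm(0.95) * sigma)
  # Monte Carlo standard error of the 95th percentile of the CR distribution
  q_c <- exp(mu + qnorm(0.95) * sigma)
  dens <- dlnorm(q_c, mu, sigma) / k
  se <- sqrt(0.95 * 0.05 / n) / dens
  got <- res[res$route == "oral", "cr_p95"]
  expect_lt(abs(got - closed), 3 * se)
})

test_that("identical seeds reproduce summaries bitwise; point masses ignore the seed", {
  reg <- load_reference_registry()
  conc <- list(Cd = dist_spec("lognormal", meanlog = -4, sdlog = 1),
               Pb = point_mass(0.1))
  exps <- list(adult = point_exposure("adult"))
  r1 <- mc_survey_risk(conc, exps, reg, n = 2000, seed = 17)
  r2 <- mc_survey_risk(conc, exps, reg, n = 2000, seed = 17)
  expect_identical(r1, r2)
  r3 <- mc_survey_risk(conc, exps, reg, n = 2000, seed = 18)
  expect_false(identical(r1$hq_p95[r1$metal == "Cd"],
                         r3$hq_p95[r3$metal == "Cd"]))
  expect_identical(r1[r1$metal == "Pb", c("hq_p5", "hq_mean", "hq_p95")],
                   r3[r3$metal == "Pb", c("hq_p5", "hq_mean", "hq_p95")])
})

test_that("per-metal substreams are unaffected by adding another metal", {
  reg <- load_reference_registry()
  exps <- list(adult = point_exposure("adult"))
  solo <- mc_survey_risk(list(Cd = dist_spec("lognormal", -4, 1)), exps, reg,
                         n = 1000, seed = 5)
  both <- mc_survey_risk(list(Cd = dist_spec("lognormal", -4, 1),
                              Pb = dist_spec("lognormal", -3, 1)), exps, reg,
                         n = 1000, seed = 5)
  expect_identical(solo[solo$metal == "Cd", "hq_p95"],
                   both[both$metal == "Cd", "hq_p95"])
})

test_that("widening the concentration scale cannot decrease the CR 95th percentile", {
  reg <- load_reference_registry()
  exps <- list(adult = point_exposure("adult"))
  p95 <- vapply(c(0.3, 0.6, 1.2), function(sdl) {
    res <- mc_survey_risk(list(Pb = dist_spec("lognormal", log(0.05), sdl)),
                          exps, reg, n = 4000, seed = 8)
    res[res$route == "oral", "cr_p95"]
  }, numeric(1))
  expect_true(all(diff(p95) > 0))
})

test_that("quantile half-widths shrink about twofold from n to 4n", {
  reg <- load_reference_registry()
  conc <- list(Pb = dist_spec("lognormal", log(0.05), 0.8))
  exps <- list(adult = point_exposure("adult"))
  rep_ <- convergence_report(conc, exps, reg, n_small = 2500, n_large = 10000,
                             reps = 200, seed = 14)
  expect_gt(rep_$mean_ratio, 0.4)
  expect_lt(rep_$mean_ratio, 0.6)

  # point-mass specs have zero half-width at any n
  rep0 <- convergence_report(list(Pb = point_mass(0.1)), exps, reg,
                             n_small = 100, n_large = 400, reps = 5, seed = 1)
  expect_equal(rep0$mean_ratio, 0)
  expect_error(convergence_report(list(), exps, reg, reps = 2, seed = 1))
})

test_that("the default template reduces to point masses for degenerate surveys", {
  reg <- load_reference_registry()
  met <- load_metals()
  tmpl <- default_mc_template(met, reg)
  expect_setequal(names(tmpl$concentration), reg$metals$symbol)
  expect_true(all(vapply(tmpl$concentration, function(s)
    s$family %in% c("lognormal", "point"), logical(1))))
  bw <- tmpl$exposure$adult$bw
  x <- sample_draws(bw, 2000, seed = 3)
  expect_true(all(x >= bw$truncation[1] & x <= bw$truncation[2]))
})
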