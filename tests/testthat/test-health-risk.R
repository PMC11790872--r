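test_that("intake equations match direct arithmetic", {
  s <- exposure_scenario("adult", ir = 2, ef = 365, ed = 30, bw = 70,
                         at = 10950)
  expect_equal(cdi_oral(0, s), 0)
  expect_equal(cdi_oral(1, s), 2 * 365 * 30 / (70 * 10950), tolerance = 1e-14)
  expect_equal(cdi_oral(2, s), 2 * cdi_oral(1, s))         # linearity

  sd_ <- exposure_scenario("adult", ef = 365, ed = 30, bw = 70, at = 10950,
                           et = 0.58, sa = 18000, cf = 0.001)
  expect_equal(cdi_dermal(1, 0.001, sd_),
               0.58 * 365 * 0.001 * 18000 * 0.001 * 30 / (70 * 10950),
               tolerance = 1e-12)
  expect_equal(cdi_dermal(1, 0.001, sd_), 1.4914e-4, tolerance = 1e-3)
  s0 <- exposure_scenario("adult", et = 1e-12)
  expect_equal(cdi_dermal(1, 0.001, s0), 1e-12 * 365 * 0.001 * 18000 * 0.001 *
                 30 / (70 * s0$at), tolerance = 1e-12)

  # formula congruence: dermal equals oral when kp*sa*cf*et = ir
  kp <- 0.5
  s_eq <- exposure_scenario("adult", ir = kp * 18000 * 0.001 * 0.58)
  expect_equal(cdi_dermal(3, kp, s_eq), cdi_oral(3, s_eq), tolerance = 1e-12)
})

test_that("hazard quotient handles routes and the ABS identity", {
  expect_equal(hq(0.003, 0.003, route = "oral"), 1)
  expect_equal(hq(0.1, 0.02, abs_gi = 1, route = "dermal"),
               hq(0.1, 0.02, route = "oral"))
  expect_equal(hq(0.1, 0.02, abs_gi = 0.5, route = "dermal"),
               2 * hq(0.1, 0.02, route = "oral"))
  expect_error(hq(1, 0), "rfd")
})

test_that("hazard index is a commutative sum with the > 1 flag", {
  expect_equal(hi(numeric(0))$value, 0)
  h <- hi(c(0.5, 0.5, 0.1))
  expect_equal(h$value, 1.1)
  expect_true(h$high_risk)
  expect_equal(hi(c(0.1, 0.5, 0.5))$value, h$value)
  set.seed(21)
  x <- runif(20)
  acc <- 0; for (v in x) acc <- acc + v
  expect_equal(hi(x)$value, acc)
})

test_that("carcinogenic risk is the slope-factor product with monotone classes", {
  expect_equal(cr(0.5, 0)$value, 0)
  got <- cr(0.02857, 0.0085)
  expect_equal(got$value, 2.43e-4, tolerance = 0.01)
  expect_identical(got$class_label, "high")
  expect_identical(cr(1e-4, 0.0085)$class_label, "negligible")
  expect_true(cr(0.2, 0.0085)$value >= cr(0.1, 0.0085)$value)
})

test_that("survey-level risk matches a brute-force per-sample loop", {
  reg <- load_reference_registry()
  set.seed(31)
  n <- 6
  records <- data.frame(sample_id = paste0("r", 1:n), site_name = "x",
                        matrix(runif(n * 8, 0, 0.3), n, 8,
                               dimnames = list(NULL, reg$metals$symbol)),
                        check.names = FALSE)
  sv <- survey_table(records, "metals")
  scen <- list(adult = exposure_scenario("adult"),
               child = exposure_scenario("child"))
  risk <- survey_risk(sv, reg, scen)

  for (receptor in names(scen)) {
    s <- scen[[receptor]]
    for (m in reg$metals$symbol) {
      ref <- reg$metals[m, ]
      for (i in 1:n) {
        c_w <- records[i, m]
        cdi_o <- c_w * s$ir * s$ef * s$ed / (s$bw * s$at)
        row <- risk$per_metal[risk$per_metal$sample_id == records$sample_id[i] &
                              risk$per_metal$metal == m &
                              risk$per_metal$receptor == receptor &
                              risk$per_metal$route == "oral", ]
        expect_equal(row$cdi, cdi_o, tolerance = 1e-12)
        expect_equal(row$hq, cdi_o / ref$rfd_oral, tolerance = 1e-12)
      }
    }
    # HI is the sum of that route's HQs per sample
    for (i in 1:n) {
      sub <- risk$per_metal[risk$per_metal$sample_id == records$sample_id[i] &
                            risk$per_metal$receptor == receptor &
                            risk$per_metal$route == "oral", ]
      hival <- risk$hi[risk$hi$sample_id == records$sample_id[i] &
                       risk$hi$receptor == receptor &
                       risk$hi$route == "oral", "hi"]
      expect_equal(hival, sum(sub$hq), tolerance = 1e-12)
      expect_true(hival >= max(sub$hq))
    }
  }
  # exceedance fractions equal a direct count
  oral_cd <- risk$per_metal[risk$per_metal$metal == "Cd" &
                            risk$per_metal$receptor == "child" &
                            risk$per_metal$route == "oral", "hq"]
  frac <- risk$exceedance$hq
  expect_equal(frac[frac$metal == "Cd" & frac$receptor == "child" &
                    frac$route == "oral", "frac_hq_gt_1"],
               mean(oral_cd > 1))
})

test_that("an all-zero survey produces zero exceedance everywhere", {
  reg <- load_reference_registry()
  records <- data.frame(sample_id = c("a", "b"), site_name = "x",
                        matrix(0, 2, 8,
                               dimnames = list(NULL, reg$metals$symbol)),
                        check.names = FALSE)
  risk <- survey_risk(survey_table(records, "metals"), reg)
  expect_true(all(risk$exceedance$hq$frac_hq_gt_1 == 0))
  expect_true(all(risk$exceedance$cr$frac_cr_gt_1e4 == 0))
  expect_true(all(risk$exceedance$hi$frac_hi_gt_1 == 0))
})

test_that("HQ and CR are linear in concentration through the whole chain", {
  reg <- load_reference_registry()
  s <- exposure_scenario("child")
  for (m in c("Cd", "Pb")) {
    ref <- reg$metals[m, ]
    h1 <- hq(cdi_oral(0.05, s), ref$rfd_oral)
    h2 <- hq(cdi_oral(0.10, s), ref$rfd_oral)
    expect_equal(h2, 2 * h1, tolerance = 1e-12)
    c1 <- cr(cdi_dermal(0.05, ref$kp, s), ref$csf_dermal)$value
    c2 <- cr(cdi_dermal(0.10, ref$kp, s), ref$csf_dermal)$value
    expect_equal(c2, 2 * c1, tolerance = 1e-12)
  }
})

test_that("on the study fixture children exceed adults and Cd/Cr/Pb drive risk", {
  risk <- survey_risk(load_metals())
  pm <- risk$per_metal
  for (m in unique(pm$metal)) {
    for (route in c("oral", "dermal")) {
      a <- pm[pm$metal == m & pm$route == route & pm$receptor == "adult", ]
      c_ <- pm[pm$metal == m & pm$route == route & pm$receptor == "child", ]
      expect_true(all(c_$hq >= a$hq))
      if (!all(is.na(a$cr))) expect_true(all(c_$cr >= a$cr))
    }
  }
  # CR output exists only for the metals with a slope factor
  expect_setequal(unique(pm$metal[!is.na(pm$cr)]), c("Cd", "Cr", "Pb"))
  # oral HI exceeds dermal HI for every sample and receptor
  hi_w <- reshape(risk$hi[, c("sample_id", "receptor", "route", "hi")],
                  direction = "wide", idvar = c("sample_id", "receptor"),
                  timevar = "route")
  expect_true(all(hi_w$hi.oral > hi_w$hi.dermal))
})
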