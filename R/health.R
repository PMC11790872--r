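#' Chronic daily intake by ingestion
#'
#' `CDI_oral = C * IR * EF * ED / (BW * AT)` with the water concentration `C`
#' in mg/L; the result is a dose in mg/kg/day.
#'
#' @param c_w water concentration (mg/L), vectorised.
#' @param scenario an [exposure_scenario()].
#' @return dose (mg/kg/day).
#' @examples
#' s <- exposure_scenario("adult", ir = 2, ed = 30, at = 10950)
#' cdi_oral(1, s)  # 0.02857...
#' @export
cdi_oral <- function(c_w, scenario) {
  stopifnot(all(c_w >= 0))
  if (scenario$bw <= 0 || scenario$at <= 0)
    stop("body weight and averaging time must be positive")
  c_w * scenario$ir * scenario$ef * scenario$ed / (scenario$bw * scenario$at)
}

#' Chronic daily intake by dermal contact
#'
#' `CDI_dermal = C * ET * EF * Kp * SA * CF * ED / (BW * AT)` with the
#' dermal permeability coefficient `Kp` in cm/h, skin area `SA` in cm^2,
#' exposure time `ET` in h/day and the volume conversion `CF` in L/cm^3.
#'
#' @param c_w water concentration (mg/L), vectorised.
#' @param kp dermal permeability coefficient (cm/h).
#' @param scenario an [exposure_scenario()].
#' @return dose (mg/kg/day).
#' @export
cdi_dermal <- function(c_w, kp, scenario) {
  stopifnot(all(c_w >= 0), all(kp >= 0))
  if (scenario$bw <= 0 || scenario$at <= 0)
    stop("body weight and averaging time must be positive")
  c_w * scenario$et * scenario$ef * kp * scenario$sa * scenario$cf *
    scenario$ed / (scenario$bw * scenario$at)
}

#' Hazard quotient
#'
#' `HQ = CDI / RfD` with the route-appropriate reference dose; the dermal
#' reference dose is derived from the oral one through the gastrointestinal
#' absorption fraction, `RfD_dermal = RfD_oral * ABS`.
#'
#' @param cdi dose (mg/kg/day), vectorised.
#' @param rfd_oral oral reference dose (mg/kg/day), > 0.
#' @param abs_gi gastrointestinal absorption fraction in (0, 1].
#' @param route `"oral"` or `"dermal"`.
#' @return dimensionless hazard quotient.
#' @export
hq <- function(cdi, rfd_oral, abs_gi = 1, route = c("oral", "dermal")) {
  route <- match.arg(route)
  if (is.na(rfd_oral) || rfd_oral <= 0) stop("rfd_oral must be positive")
  if (abs_gi <= 0 || abs_gi > 1) stop("abs_gi must lie in (0, 1]")
  rfd <- if (route == "oral") rfd_oral else rfd_oral * abs_gi
  cdi / rfd
}

#' Hazard index
#'
#' Sum of per-metal hazard quotients for one route and receptor; flagged as
#' high risk when the sum exceeds 1.
#'
#' @param hqs numeric vector (possibly named by metal) of hazard quotients.
#' @return list with `value` and logical `high_risk`.
#' @export
hi <- function(hqs) {
  value <- sum(hqs)
  list(value = value, high_risk = value > 1)
}

#' Carcinogenic risk
#'
#' `CR = CDI * CSF` with the cancer slope factor in (mg/kg/day)^-1; the
#' result is an incremental lifetime cancer probability. Classified `high`
#' when above 1e-4, `negligible` below 1e-6, `acceptable` in between.
#'
#' @param cdi dose (mg/kg/day), vectorised.
#' @param csf cancer slope factor ((mg/kg/day)^-1), >= 0.
#' @return list with `value` and `class_label` (vectorised alongside `cdi`).
#' @export
cr <- function(cdi, csf) {
  if (is.na(csf) || csf < 0) stop("csf must be nonnegative")
  value <- cdi * csf
  label <- ifelse(value > 1e-4, "high",
                  ifelse(value < 1e-6, "negligible", "acceptable"))
  list(value = value, class_label = label)
}

#' Deterministic health-risk assessment of a metals survey
#'
#' Runs the full USEPA chain for every sample, metal, receptor and route:
#' chronic daily intake, hazard quotient, per-sample hazard index, and
#' carcinogenic risk for the metals with a configured cancer slope factor
#' (Cd, Cr and Pb by default). Metals lacking a reference dose or slope
#' factor are skipped for the corresponding output with a recorded warning.
#'
#' @param survey a metals `survey_table` (mg/L) with non-detects substituted.
#' @param registry reference registry supplying `rfd_oral`, `abs_gi`, `kp`
#'   and the slope factors.
#' @param scenarios named list of [exposure_scenario()]s; defaults to the
#'   shipped adult and child sets.
#' @return list with
#'   `per_metal` (data frame keyed by sample, metal, receptor, route with
#'   `cdi`, `hq`, `cr`), `hi` (data frame keyed by sample, receptor, route),
#'   `exceedance` (fractions of samples with HQ > 1 per metal/receptor/route,
#'   with HI > 1, and with CR > 1e-4), `skipped` (character log) and the
#'   registry `version_tag`.
#' @export
survey_risk <- function(survey, registry = load_reference_registry(),
                        scenarios = list(adult = exposure_scenario("adult"),
                                         child = exposure_scenario("child"))) {
  metals <- intersect(registry$metals$symbol, survey_analytes(survey))
  conc <- survey_matrix(survey)[, metals, drop = FALSE]
  skipped <- character(0)
  rows <- list()
  for (receptor in names(scenarios)) {
    s <- scenarios[[receptor]]
    for (metal in metals) {
      ref <- registry$metals[metal, ]
      for (route in c("oral", "dermal")) {
        cdi <- if (route == "oral") cdi_oral(conc[, metal], s)
               else cdi_dermal(conc[, metal], ref$kp, s)
        hq_val <- if (!is.na(ref$rfd_oral) && ref$rfd_oral > 0) {
          hq(cdi, ref$rfd_oral, ref$abs_gi, route)
        } else {
          skipped <- c(skipped, paste0(metal, ": no RfD, HQ skipped"))
          rep(NA_real_, length(cdi))
        }
        csf <- if (route == "oral") ref$csf_oral else ref$csf_dermal
        cr_val <- if (!is.na(csf)) cr(cdi, csf)$value else rep(NA_real_, length(cdi))
        rows[[length(rows) + 1]] <- data.frame(
          sample_id = survey$sample_id, metal = metal,
          receptor = receptor, route = route,
          cdi = unname(cdi), hq = unname(hq_val), cr = unname(cr_val),
          stringsAsFactors = FALSE)
      }
    }
  }
  per_metal <- do.call(rbind, rows)

  hi_tab <- stats::aggregate(hq ~ sample_id + receptor + route,
                             data = per_metal, FUN = sum, na.rm = TRUE)
  names(hi_tab)[names(hi_tab) == "hq"] <- "hi"
  hi_tab$high_risk <- hi_tab$hi > 1

  frac_over <- function(x, cut) mean(x > cut, na.rm = TRUE)
  exc_hq <- stats::aggregate(hq ~ metal + receptor + route, data = per_metal,
                             FUN = frac_over, cut = 1)
  names(exc_hq)[names(exc_hq) == "hq"] <- "frac_hq_gt_1"
  exc_cr <- stats::aggregate(cr ~ metal + receptor + route,
                             data = per_metal[!is.na(per_metal$cr), ],
                             FUN = frac_over, cut = 1e-4)
  names(exc_cr)[names(exc_cr) == "cr"] <- "frac_cr_gt_1e4"
  exc_hi <- stats::aggregate(hi ~ receptor + route, data = hi_tab,
                             FUN = frac_over, cut = 1)
  names(exc_hi)[names(exc_hi) == "hi"] <- "frac_hi_gt_1"

  list(per_metal = per_metal, hi = hi_tab,
       exceedance = list(hq = exc_hq, hi = exc_hi, cr = exc_cr),
       skipped = unique(skipped),
       registry_version = registry$version_tag)
}
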