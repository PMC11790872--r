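#' Reference registry of per-analyte constants
#'
#' Builds the registry of reference constants the pipeline needs: for each of
#' the eight study metals a standard limit `standard_limit_S` (mg/L, the
#' weighting denominator of the heavy-metal pollution index), an upper
#' allowable limit `ual` (mg/L, the metal-index denominator), a toxic-response
#' factor `tr` (dimensionless, Hakanson-style; `NA` for Fe, which is excluded
#' from the ecological risk index by default), an optional background
#' concentration `background` (mg/L), an oral reference dose `rfd_oral`
#' (mg/kg/day), a gastrointestinal absorption fraction `abs_gi`, a dermal
#' permeability coefficient `kp` (cm/h) and oral/dermal cancer slope factors
#' `csf_oral` / `csf_dermal` ((mg/kg/day)^-1, `NA` for non-carcinogens); and
#' for each of the sixteen study PAHs its ring count, weight class (LPAH for
#' 2-3 rings, HPAH for 4-6), carcinogenic-subgroup membership and the
#' negligible (`nc`) and maximum permissible (`mpc`) quality concentrations in
#' ng/L. The site-total risk quotient uses its own quality pair, stored as
#' `total_nc` / `total_mpc`.
#'
#' All defaults are data, not code: any field can be overridden through
#' `overrides`, a nested list such as
#' `list(metals = list(Cd = list(rfd_oral = 1e-3)), pahs = list(Naph = list(nc = 2)))`.
#' The `car_set` argument switches the carcinogenic-PAH subgroup; the default
#' (`"table"`) is the set consistent with the printed per-site carcinogenic
#' totals, `"prose"` selects the alternative USEPA/WHO listing.
#'
#' @param overrides nested list of per-analyte field overrides, or `NULL`.
#' @param car_set `"table"` (default) or `"prose"` carcinogenic-PAH subgroup.
#' @param version_tag text tag recorded in downstream results.
#' @return an object of class `reference_registry`: a list with data frames
#'   `metals` and `pahs`, scalars `total_nc` and `total_mpc` (ng/L) and the
#'   `version_tag`.
#' @examples
#' reg <- load_reference_registry()
#' reg$metals["Pb", "ual"]    # 0.01 mg/L
#' @export
load_reference_registry <- function(overrides = NULL,
                                    car_set = c("table", "prose"),
                                    version_tag = "coastrisk-defaults-1") {
  car_set <- match.arg(car_set)

  metals <- data.frame(
    symbol           = c("Cd", "Cr", "Cu", "Fe", "Mn", "Ni", "Pb", "Zn"),
    standard_limit_S = c(0.003, 0.05, 2.0, 0.3, 0.1, 0.07, 0.01, 3.0),
    ual              = c(0.003, 0.05, 2.0, 0.3, 0.1, 0.07, 0.01, 3.0),
    tr               = c(30, 2, 5, NA, 1, 5, 5, 1),
    background       = NA_real_,
    rfd_oral         = c(0.0005, 0.003, 0.04, 0.7, 0.14, 0.02, 0.0014, 0.3),
    abs_gi           = c(0.05, 0.025, 1, 1, 1, 1, 1, 1),
    kp               = c(0.001, 0.002, 0.001, 0.001, 0.001, 0.0002, 0.0001, 0.0006),
    csf_oral         = c(6.1, 0.5, NA, NA, NA, NA, 0.0085, NA),
    stringsAsFactors = FALSE
  )
  metals$csf_dermal <- metals$csf_oral / metals$abs_gi
  rownames(metals) <- metals$symbol

  pah_abbrev <- c("Naph", "Acthy", "Ace", "Fl", "Phe", "Ant", "Flu", "Pyr",
                  "BaA", "Chry", "BbF", "BkF", "BaP", "DBA", "BghiP", "InP")
  pahs <- data.frame(
    abbreviation = pah_abbrev,
    n_rings      = c(2, 3, 3, 3, 3, 3, 4, 4, 4, 4, 5, 5, 5, 5, 6, 6),
    nc           = c(1.2, 0.7, 0.7, 0.7, 3, 0.7, 3, 0.7, 0.1, 3.4, 0.1, 0.4,
                     0.5, 0.5, 0.3, 0.4),
    mpc          = c(1200, 70, 70, 70, 300, 70, 300, 70, 10, 340, 10, 40,
                     50, 50, 30, 40),
    stringsAsFactors = FALSE
  )
  pahs$weight_class <- ifelse(pahs$n_rings <= 3, "LPAH", "HPAH")
  car_members <- switch(car_set,
    table = c("BaA", "Chry", "BbF", "BkF", "BaP", "DBA", "BghiP", "InP"),
    prose = c("Naph", "Acthy", "Fl", "Phe", "Ant", "Pyr", "Flu", "BaP"))
  pahs$carcinogenic <- pahs$abbreviation %in% car_members
  rownames(pahs) <- pahs$abbreviation

  reg <- structure(
    list(metals = metals, pahs = pahs,
         total_nc = 27.2, total_mpc = 2720,
         version_tag = version_tag),
    class = "reference_registry")

  if (!is.null(overrides)) reg <- apply_registry_overrides(reg, overrides)
  validate_registry(reg)
  reg
}

apply_registry_overrides <- function(reg, overrides) {
  stopifnot(is.list(overrides))
  for (class_name in names(overrides)) {
    if (!class_name %in% c("metals", "pahs", "total_nc", "total_mpc"))
      stop("unknown override section: ", class_name)
    if (class_name %in% c("total_nc", "total_mpc")) {
      reg[[class_name]] <- as.numeric(overrides[[class_name]])
      next
    }
    tab <- reg[[class_name]]
    for (analyte in names(overrides[[class_name]])) {
      if (!analyte %in% rownames(tab))
        stop("override for unknown analyte: ", analyte)
      for (field in names(overrides[[class_name]][[analyte]])) {
        if (!field %in% colnames(tab))
          stop("override for unknown field: ", field)
        old <- tab[analyte, field]
        new <- overrides[[class_name]][[analyte]][[field]]
        tab[analyte, field] <- new
        message(sprintf("registry override: %s.%s %s -> %s",
                        analyte, field, format(old), format(new)))
      }
    }
    reg[[class_name]] <- tab
  }
  reg
}

validate_registry <- function(reg) {
  m <- reg$metals
  if (any(m$standard_limit_S <= 0) || any(m$ual <= 0))
    stop("standard limits and upper allowable limits must be positive")
  if (any(m$abs_gi <= 0 | m$abs_gi > 1))
    stop("abs_gi must lie in (0, 1]")
  if (any(m$rfd_oral < 0, na.rm = TRUE) || any(m$kp < 0, na.rm = TRUE) ||
      any(m$csf_oral < 0, na.rm = TRUE))
    stop("dose factors must be nonnegative")
  p <- reg$pahs
  if (any(p$nc <= 0) || any(p$mpc < p$nc))
    stop("quality values must satisfy mpc >= nc > 0")
  if (!identical(p$weight_class, ifelse(p$n_rings <= 3, "LPAH", "HPAH")))
    stop("weight_class must be determined by ring count")
  invisible(reg)
}

#' @export
print.reference_registry <- function(x, ...) {
  cat("<reference_registry> version", x$version_tag, "\n")
  cat("  metals:", paste(x$metals$symbol, collapse = " "), "\n")
  cat("  pahs:  ", paste(x$pahs$abbreviation, collapse = " "), "\n")
  cat("  site-total NC/MPC:", x$total_nc, "/", x$total_mpc, "ng/L\n")
  invisible(x)
}

#' Default exposure scenarios for the health-risk chain
#'
#' Receptor-specific exposure parameter sets for the oral and dermal chronic
#' daily intake equations: ingestion rate `ir` (L/day), exposure frequency
#' `ef` (days/year), exposure duration `ed` (years), body weight `bw` (kg),
#' averaging time `at` (days), exposed skin area `sa` (cm^2), water exposure
#' time `et` (h/day) and volume conversion factor `cf` (L/cm^3). The default
#' averaging time is `ed * 365` for both routes and receptors, which keeps the
#' intake equations on an exposure-duration basis; pass `at` explicitly for
#' lifetime averaging.
#'
#' @param receptor `"adult"` or `"child"`.
#' @param ... named overrides of any scenario field.
#' @return an object of class `exposure_scenario` (a named list).
#' @examples
#' exposure_scenario("child", bw = 16)
#' @export
exposure_scenario <- function(receptor = c("adult", "child"), ...) {
  receptor <- match.arg(receptor)
  s <- switch(receptor,
    adult = list(receptor = "adult", ir = 2.2, ef = 365, ed = 30, bw = 70,
                 sa = 18000, et = 0.58, cf = 0.001),
    child = list(receptor = "child", ir = 1.0, ef = 365, ed = 6, bw = 15,
                 sa = 6600, et = 1.0, cf = 0.001))
  s$at <- s$ed * 365
  dots <- list(...)
  bad <- setdiff(names(dots), names(s))
  if (length(bad)) stop("unknown exposure field(s): ", paste(bad, collapse = ", "))
  s[names(dots)] <- dots
  num <- s[setdiff(names(s), "receptor")]
  if (any(unlist(num) <= 0)) stop("all exposure parameters must be positive")
  if (s$at < s$ed * 365)
    warning("averaging time shorter than exposure duration (at < ed * 365)")
  structure(s, class = "exposure_scenario")
}
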