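#' Total PAH concentration of a sample
#'
#' Arithmetic sum over the sixteen registered PAH compounds, in the survey's
#' unit (canonically ug/L). Non-detects must have been substituted first.
#'
#' @param sample one-row slice of a PAH `survey_table`, or a named numeric
#'   vector of compound concentrations.
#' @param registry reference registry naming the compounds to sum.
#' @return total concentration (ug/L).
#' @examples
#' f <- system.file("extdata", "table2_pahs.csv", package = "coastrisk")
#' pahs <- substitute_nondetects(read_survey(f, "pahs"), "zero")
#' total_pahs(pahs[1, ])   # Suez: 479.02
#' @export
total_pahs <- function(sample, registry = load_reference_registry()) {
  v <- sample_values(sample)
  compounds <- registry$pahs$abbreviation
  missing <- setdiff(compounds, names(v))
  if (length(missing))
    stop("missing PAH compound column(s): ", paste(missing, collapse = ", "))
  sum(v[compounds])
}

sample_values <- function(sample) {
  if (is.data.frame(sample)) {
    stopifnot(nrow(sample) == 1)
    analytes <- setdiff(names(sample), c("sample_id", "site_name"))
    v <- as.numeric(sample[1, analytes])
    names(v) <- analytes
    v
  } else {
    stopifnot(is.numeric(sample), !is.null(names(sample)))
    sample
  }
}

#' Group totals of a PAH sample
#'
#' Splits the total PAH burden into the carcinogenic subgroup (`car_total`)
#' and the molecular-weight classes: LPAH (2-3 rings) and HPAH (4-6 rings).
#' `lpah_total + hpah_total` equals `total` by construction.
#'
#' @inheritParams total_pahs
#' @return list with `total`, `car_total`, `lpah_total`, `hpah_total` (ug/L).
#' @export
group_totals <- function(sample, registry = load_reference_registry()) {
  v <- sample_values(sample)
  p <- registry$pahs
  missing <- setdiff(p$abbreviation, names(v))
  if (length(missing))
    stop("missing PAH compound column(s): ", paste(missing, collapse = ", "))
  v <- v[p$abbreviation]
  list(total = sum(v),
       car_total = sum(v[p$carcinogenic]),
       lpah_total = sum(v[p$weight_class == "LPAH"]),
       hpah_total = sum(v[p$weight_class == "HPAH"]))
}

#' Diagnostic source ratios of a PAH sample
#'
#' The five standard source-apportionment ratios: LMW/HMW, Phe/Ant, Flu/Pyr,
#' Flu/(Flu+Pyr) and BaA/(BaA+Chry). A ratio whose denominator is zero is
#' `NA` ("undefined"), never 0 or infinity.
#'
#' @inheritParams total_pahs
#' @return named list of ratios (`NA` where undefined).
#' @export
diagnostic_ratios <- function(sample, registry = load_reference_registry()) {
  v <- sample_values(sample)
  g <- group_totals(sample, registry)
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  list(
    lmw_hmw = safe_div(g$lpah_total, g$hpah_total),
    phe_ant = safe_div(v[["Phe"]], v[["Ant"]]),
    flu_pyr = safe_div(v[["Flu"]], v[["Pyr"]]),
    flu_flupyr = safe_div(v[["Flu"]], v[["Flu"]] + v[["Pyr"]]),
    baa_baachry = safe_div(v[["BaA"]], v[["BaA"]] + v[["Chry"]])
  )
}

#' Default rule table for source classification
#'
#' Thresholds are half-open: a value exactly at a boundary belongs to the
#' upper class. For each ratio the table gives the cut points and the labels
#' of the resulting intervals, lowest first.
#'
#' @return nested list of per-ratio rules.
#' @export
default_source_rules <- function() {
  list(
    lmw_hmw     = list(cuts = 1,            labels = c("pyrogenic", "petrogenic")),
    phe_ant     = list(cuts = c(10, 15),    labels = c("pyrogenic", "mixed", "petrogenic")),
    flu_pyr     = list(cuts = 1,            labels = c("petrogenic", "pyrogenic")),
    flu_flupyr  = list(cuts = c(0.4, 0.5),  labels = c("petrogenic", "mixed", "pyrogenic")),
    baa_baachry = list(cuts = c(0.2, 0.35), labels = c("petrogenic", "mixed", "pyrogenic"))
  )
}

#' Classify the pollution source of a sample from its diagnostic ratios
#'
#' Each defined ratio is mapped to `petrogenic`, `pyrogenic` or `mixed` by the
#' rule table; the consensus label is the majority vote over defined ratios,
#' with ties (including a `mixed` plurality) resolved to `mixed`.
#'
#' @param ratios output of [diagnostic_ratios()].
#' @param rules rule table, by default [default_source_rules()].
#' @return list with `per_ratio` (named character, `NA` where the ratio is
#'   undefined) and `consensus`.
#' @export
classify_source <- function(ratios, rules = default_source_rules()) {
  labels <- vapply(names(rules), function(rn) {
    x <- ratios[[rn]]
    if (is.null(x) || is.na(x)) return(NA_character_)
    rule <- rules[[rn]]
    # boundary belongs to the upper class
    idx <- sum(x >= rule$cuts) + 1
    rule$labels[idx]
  }, character(1))
  defined <- labels[!is.na(labels)]
  consensus <- if (length(defined) == 0) {
    NA_character_
  } else {
    tab <- table(factor(defined, levels = c("petrogenic", "pyrogenic", "mixed")))
    top <- names(tab)[tab == max(tab)]
    if (length(top) > 1 || identical(top, "mixed")) "mixed" else top
  }
  list(per_ratio = labels, consensus = consensus)
}

#' Risk quotients of a PAH sample
#'
#' Per-compound risk quotients against the negligible concentration
#' (`rq_nc = C * 1000 / NC`) and the maximum permissible concentration
#' (`rq_mpc = C * 1000 / MPC`), with concentrations in ug/L and quality
#' values in ng/L, plus a site-total quotient computed from the total PAH
#' concentration and the dedicated total-row quality pair (27.2 / 2720 ng/L
#' by default). Each row carries its risk grade from [grade_rq()].
#'
#' @inheritParams total_pahs
#' @return data frame with columns `compound`, `concentration_ug_L`, `rq_nc`,
#'   `rq_mpc`, `grade`; the last row (`compound == "TOTAL"`) is the
#'   site-total quotient.
#' @examples
#' f <- system.file("extdata", "table2_pahs.csv", package = "coastrisk")
#' pahs <- substitute_nondetects(read_survey(f, "pahs"), "zero")
#' rq(pahs[1, ])  # Suez site-total rq_nc ~ 17611
#' @export
rq <- function(sample, registry = load_reference_registry()) {
  v <- sample_values(sample)
  p <- registry$pahs
  missing <- setdiff(p$abbreviation, names(v))
  if (length(missing))
    stop("missing NC/MPC or concentration for: ",
         paste(missing, collapse = ", "))
  if (any(is.na(p$nc)) || any(is.na(p$mpc)))
    stop("registry is missing NC or MPC values")
  conc <- v[p$abbreviation]
  out <- data.frame(
    compound = p$abbreviation,
    concentration_ug_L = unname(conc),
    rq_nc = unname(conc * 1000 / p$nc),
    rq_mpc = unname(conc * 1000 / p$mpc),
    stringsAsFactors = FALSE
  )
  total <- sum(conc)
  out <- rbind(out, data.frame(
    compound = "TOTAL",
    concentration_ug_L = total,
    rq_nc = total * 1000 / registry$total_nc,
    rq_mpc = total * 1000 / registry$total_mpc,
    stringsAsFactors = FALSE
  ))
  out$grade <- mapply(grade_rq, out$rq_nc, out$rq_mpc)
  out
}

#' Grade a risk quotient pair
#'
#' Risk grades follow the quotient rule table: `high` when `rq_nc >= 800` and
#' `rq_mpc >= 1`; `moderate` when `rq_nc < 800` and `rq_mpc >= 1`; `low` when
#' `rq_mpc < 1` and `rq_nc >= 1`; `negligible` when `rq_nc < 1`.
#'
#' @param rq_nc risk quotient against the negligible concentration.
#' @param rq_mpc risk quotient against the maximum permissible concentration.
#' @return one of `"negligible"`, `"low"`, `"moderate"`, `"high"`.
#' @export
grade_rq <- function(rq_nc, rq_mpc) {
  stopifnot(length(rq_nc) == 1, length(rq_mpc) == 1)
  if (rq_nc < 1) return("negligible")
  if (rq_mpc < 1) return("low")
  if (rq_nc >= 800) return("high")
  "moderate"
}

#' Summarise a total organic carbon survey
#'
#' @param survey a TOC `survey_table` (single `TOC` analyte, mg/L).
#' @return list with `mean`, `min`, `max` (mg/L) and `n`.
#' @export
toc_summary <- function(survey) {
  if (nrow(survey) == 0) stop("empty TOC survey")
  x <- survey_matrix(survey)[, "TOC"]
  list(mean = mean(x), min = min(x), max = max(x), n = length(x))
}

#' Per-site PAH report for a survey
#'
#' Applies [group_totals()], [diagnostic_ratios()], [classify_source()] and
#' the site-total [rq()] to every sample of a PAH survey.
#'
#' @param survey a PAH `survey_table` with non-detects substituted.
#' @param registry reference registry.
#' @param rules source-classification rule table.
#' @return data frame, one row per sample, with totals, ratios, source labels
#'   and the site-total risk-quotient grade.
#' @export
pah_site_report <- function(survey, registry = load_reference_registry(),
                            rules = default_source_rules()) {
  rows <- lapply(seq_len(nrow(survey)), function(i) {
    smp <- survey[i, ]
    g <- group_totals(smp, registry)
    r <- diagnostic_ratios(smp, registry)
    cls <- classify_source(r, rules)
    q <- rq(smp, registry)
    tot <- q[q$compound == "TOTAL", ]
    data.frame(
      sample_id = survey$sample_id[i],
      site_name = survey$site_name[i],
      total_pahs = g$total, car_total = g$car_total,
      lpah_total = g$lpah_total, hpah_total = g$hpah_total,
      lmw_hmw = r$lmw_hmw, phe_ant = r$phe_ant, flu_pyr = r$flu_pyr,
      flu_flupyr = r$flu_flupyr, baa_baachry = r$baa_baachry,
      source_consensus = cls$consensus,
      rq_nc_total = tot$rq_nc, rq_mpc_total = tot$rq_mpc,
      rq_grade = tot$grade,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
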