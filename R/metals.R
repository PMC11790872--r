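#' Classification scales for the pollution indices
#'
#' Named scales used by [classify_index()]. Every scale is stored as a set of
#' half-open intervals: the printed class tables leave gaps between classes
#' (e.g. 25 / 26), which are closed here by assigning every boundary to the
#' upper class.
#'
#' @return nested list of scales, each with `cuts` and `labels`.
#' @export
index_scales <- function() {
  list(
    hpi = list(cuts = c(25, 50, 75, 100),
               labels = c("very low", "low", "medium", "high", "unsuitable")),
    mi = list(cuts = c(0.3, 1, 2, 4, 6),
              labels = c("very clean", "clean", "partly affected",
                         "moderately affected", "heavily affected",
                         "severely affected")),
    ri = list(cuts = c(30, 60, 120),
              labels = c("low", "moderate", "considerable", "high"))
  )
}

#' Classify an index value on a named scale
#'
#' Half-open interval lookup; a value exactly at a cut belongs to the upper
#' class (so HPI 100 is "unsuitable" and MI 6 is "severely affected").
#'
#' @param value index value (dimensionless, >= 0).
#' @param scale scale name registered in [index_scales()].
#' @return class label.
#' @export
classify_index <- function(value, scale) {
  scales <- index_scales()
  if (!scale %in% names(scales)) stop("unknown scale name: ", scale)
  s <- scales[[scale]]
  s$labels[sum(value >= s$cuts) + 1]
}

#' Heavy-metal pollution index (HPI) of a sample
#'
#' Weighted arithmetic mean of the sub-indices `Qi = 100 * Ci / Si` with
#' weights `Wi = 1 / Si`, where `Si` is the standard limit of metal i (mg/L):
#' `HPI = sum(Wi * Qi) / sum(Wi)`. Concentrations and limits share the mg/L
#' unit, so the index is unit-invariant as long as both are converted
#' together.
#'
#' @param sample one-row slice of a metals `survey_table` (mg/L), or a named
#'   numeric vector of metal concentrations.
#' @param registry reference registry supplying the standard limits.
#' @return list with `value`, `class_label` and `per_metal_terms` (the
#'   `Wi * Qi` contributions).
#' @examples
#' reg <- load_reference_registry()
#' hpi(c(Cd = 0.003, Cr = 0.05, Cu = 2, Fe = 0.3,
#'       Mn = 0.1, Ni = 0.07, Pb = 0.01, Zn = 3), reg)$value  # 100
#' @export
hpi <- function(sample, registry = load_reference_registry()) {
  v <- sample_values(sample)
  m <- registry$metals[intersect(registry$metals$symbol, names(v)), ]
  if (nrow(m) == 0) stop("no registered metal found in sample")
  if (any(m$standard_limit_S <= 0)) stop("standard limit S must be positive")
  ci <- v[m$symbol]
  qi <- 100 * ci / m$standard_limit_S
  wi <- 1 / m$standard_limit_S
  terms <- wi * qi
  value <- sum(terms) / sum(wi)
  list(value = value,
       class_label = classify_index(value, "hpi"),
       per_metal_terms = stats::setNames(terms, m$symbol))
}

#' Metal index (MI) of a sample
#'
#' Sum of concentration-to-limit ratios `MI = sum(Ci / UALi)` with the upper
#' allowable limit `UALi` in mg/L. The index is additive: the MI of a
#' componentwise sum of two samples is the sum of their MIs.
#'
#' @inheritParams hpi
#' @return list with `value`, `class_label` and `per_metal_terms` (the
#'   `Ci / UALi` ratios).
#' @export
mi <- function(sample, registry = load_reference_registry()) {
  v <- sample_values(sample)
  m <- registry$metals[intersect(registry$metals$symbol, names(v)), ]
  if (nrow(m) == 0) stop("no registered metal found in sample")
  if (any(m$ual <= 0)) stop("upper allowable limit must be positive")
  terms <- v[m$symbol] / m$ual
  value <- sum(terms)
  list(value = value,
       class_label = classify_index(value, "mi"),
       per_metal_terms = stats::setNames(terms, m$symbol))
}

#' Potential ecological risk index (RI) of a survey
#'
#' Hakanson-style index: for each included metal the contamination factor is
#' the ratio of its concentration to its background value,
#' `cf = C / C_bg`, the per-metal risk factor is `Er = Tr * cf` with the
#' toxic-response factor `Tr`, and `RI = sum(Er)`. Fe carries no `Tr` and is
#' excluded by default. Background concentrations are a required input (via
#' the registry `background` column or `backgrounds`); the package ships an
#' illustrative example file only.
#'
#' @param samples a metals `survey_table` (mg/L) or a named numeric vector
#'   for a single sample.
#' @param registry reference registry supplying `tr` and, optionally,
#'   `background`.
#' @param included_metals metals to include; defaults to every registered
#'   metal with a toxic-response factor.
#' @param backgrounds optional named numeric vector of background
#'   concentrations (mg/L) overriding the registry column.
#' @return data frame with one row per sample: `ri`, `class_label`, and
#'   per-metal `er_*` and `cf_*` columns.
#' @export
ri <- function(samples, registry = load_reference_registry(),
               included_metals = NULL, backgrounds = NULL) {
  if (!is.data.frame(samples)) {
    samples <- data.frame(sample_id = "sample", site_name = "",
                          as.list(samples), check.names = FALSE)
  }
  m <- registry$metals
  if (!is.null(backgrounds)) m[names(backgrounds), "background"] <- backgrounds
  if (is.null(included_metals)) included_metals <- m$symbol[!is.na(m$tr)]
  unknown <- setdiff(included_metals, m$symbol)
  if (length(unknown)) stop("unknown metal(s): ", paste(unknown, collapse = ", "))
  m <- m[included_metals, ]
  if (any(is.na(m$tr)))
    stop("no toxic-response factor for: ",
         paste(m$symbol[is.na(m$tr)], collapse = ", "))
  if (any(is.na(m$background) | m$background <= 0))
    stop("missing background concentration for: ",
         paste(m$symbol[is.na(m$background) | m$background <= 0],
               collapse = ", "))
  conc <- as.matrix(samples[m$symbol])
  cf <- sweep(conc, 2, m$background, "/")
  er <- sweep(cf, 2, m$tr, "*")
  ri_val <- rowSums(er)
  out <- data.frame(sample_id = samples$sample_id,
                    ri = ri_val,
                    class_label = vapply(ri_val, classify_index, character(1),
                                         scale = "ri"),
                    stringsAsFactors = FALSE)
  colnames(er) <- paste0("er_", m$symbol)
  colnames(cf) <- paste0("cf_", m$symbol)
  cbind(out, er, cf)
}

#' Pollution-index report for a metals survey
#'
#' Computes [hpi()] and [mi()] for every sample, with class labels and
#' survey-level summaries (mean, min, max, and the class-fraction table).
#'
#' @param survey a metals `survey_table` (mg/L).
#' @param registry reference registry.
#' @return list with `per_sample` (data frame of values and labels) and
#'   `summary` (named list of summaries and class fractions).
#' @export
metal_index_report <- function(survey, registry = load_reference_registry()) {
  per_sample <- do.call(rbind, lapply(seq_len(nrow(survey)), function(i) {
    h <- hpi(survey[i, ], registry)
    m <- mi(survey[i, ], registry)
    data.frame(sample_id = survey$sample_id[i],
               hpi = h$value, hpi_class = h$class_label,
               mi = m$value, mi_class = m$class_label,
               stringsAsFactors = FALSE)
  }))
  frac <- function(x, lv) as.vector(table(factor(x, levels = lv))) / length(x)
  scales <- index_scales()
  list(
    per_sample = per_sample,
    summary = list(
      hpi_mean = mean(per_sample$hpi), hpi_min = min(per_sample$hpi),
      hpi_max = max(per_sample$hpi),
      mi_mean = mean(per_sample$mi), mi_min = min(per_sample$mi),
      mi_max = max(per_sample$mi),
      hpi_class_fractions = stats::setNames(
        frac(per_sample$hpi_class, scales$hpi$labels), scales$hpi$labels),
      mi_class_fractions = stats::setNames(
        frac(per_sample$mi_class, scales$mi$labels), scales$mi$labels)
    )
  )
}
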