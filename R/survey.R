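canonical_units <- c(metals = "mg/L", pahs = "ug/L", toc = "mg/L")
nd_tokens <- c("nd", "<dl")

#' Construct a survey table
#'
#' A survey table is a data frame with a `sample_id` column, a `site_name`
#' column and one numeric column per analyte, carrying as attributes the
#' analyte class (`metals`, `pahs` or `toc`), the declared concentration unit
#' for that class, a logical non-detect matrix aligned with the analyte
#' columns, optional per-analyte detection limits, and free-text provenance.
#' Non-detect cells hold `NA` until a substitution policy is applied with
#' [substitute_nondetects()].
#'
#' @param records data frame with `sample_id`, `site_name` and analyte columns.
#' @param analyte_class one of `"metals"`, `"pahs"`, `"toc"`.
#' @param units concentration unit; defaults to the canonical unit of the class
#'   (`mg/L` for metals and TOC, `ug/L` for PAHs).
#' @param nondetect logical matrix (samples x analytes) of non-detect flags.
#' @param detection_limits named numeric vector of per-analyte detection
#'   limits, in the survey's unit, or `NULL`.
#' @param provenance free text recorded with the table.
#' @return an object of class `survey_table`.
#' @export
survey_table <- function(records, analyte_class = c("metals", "pahs", "toc"),
                         units = NULL, nondetect = NULL,
                         detection_limits = NULL, provenance = "") {
  analyte_class <- match.arg(analyte_class)
  stopifnot(is.data.frame(records))
  if (!all(c("sample_id", "site_name") %in% names(records)))
    stop("records must have sample_id and site_name columns")
  analytes <- setdiff(names(records), c("sample_id", "site_name"))
  if (anyDuplicated(records$sample_id))
    stop("sample_id values must be unique within a survey")
  if (is.null(units)) units <- canonical_units[[analyte_class]]
  if (!units %in% c("mg/L", "ug/L"))
    stop("unit must be mg/L or ug/L, got: ", units)
  if (is.null(nondetect)) {
    nondetect <- matrix(FALSE, nrow(records), length(analytes),
                        dimnames = list(records$sample_id, analytes))
  }
  vals <- as.matrix(records[analytes])
  neg <- which(!is.na(vals) & vals < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop("negative concentration for sample ",
         records$sample_id[neg[1, 1]], ", analyte ", analytes[neg[1, 2]])
  structure(records,
            class = c("survey_table", "data.frame"),
            analyte_class = analyte_class,
            units = units,
            nondetect = nondetect,
            detection_limits = detection_limits,
            provenance = provenance)
}

#' List the analyte columns of a survey
#' @param survey a `survey_table`.
#' @return character vector of analyte names.
#' @export
survey_analytes <- function(survey) {
  setdiff(names(survey), c("sample_id", "site_name"))
}

#' Extract the concentration matrix of a survey
#' @param survey a `survey_table`.
#' @return numeric matrix, samples in rows, analytes in columns.
#' @export
survey_matrix <- function(survey) {
  m <- as.matrix(as.data.frame(survey)[survey_analytes(survey)])
  rownames(m) <- survey$sample_id
  m
}

#' Read a delimited survey file
#'
#' Reads a comma-separated survey with columns `sample_id`, `site_name` and
#' one column per analyte. Cells are numbers or a non-detect token (`ND` or
#' `<DL`, case-insensitive). Analyte columns are validated against the active
#' reference registry (metals and PAHs) or against the single `TOC` column.
#'
#' @param path file path.
#' @param analyte_class one of `"metals"`, `"pahs"`, `"toc"`.
#' @param registry a [load_reference_registry()] registry used for column
#'   validation.
#' @param units declared unit; defaults to the canonical unit of the class.
#' @return a [survey_table()]; non-detect cells are `NA` with their flag set.
#' @examples
#' f <- system.file("extdata", "table2_pahs.csv", package = "coastrisk")
#' pahs <- read_survey(f, "pahs")
#' @export
read_survey <- function(path, analyte_class = c("metals", "pahs", "toc"),
                        registry = load_reference_registry(), units = NULL) {
  analyte_class <- match.arg(analyte_class)
  if (!file.exists(path)) stop("survey file does not exist: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  if (!all(c("sample_id", "site_name") %in% names(raw)))
    stop("survey header must start with sample_id, site_name")
  analytes <- setdiff(names(raw), c("sample_id", "site_name"))
  known <- switch(analyte_class,
                  metals = registry$metals$symbol,
                  pahs   = registry$pahs$abbreviation,
                  toc    = "TOC")
  unknown <- setdiff(analytes, known)
  if (length(unknown))
    stop("unknown analyte column(s) for class '", analyte_class, "': ",
         paste(unknown, collapse = ", "))

  nd <- matrix(FALSE, nrow(raw), length(analytes),
               dimnames = list(raw$sample_id, analytes))
  records <- raw[c("sample_id", "site_name")]
  for (a in analytes) {
    cell <- raw[[a]]
    is_nd <- tolower(cell) %in% nd_tokens
    val <- suppressWarnings(as.numeric(cell))
    bad <- !is_nd & is.na(val) & nzchar(cell)
    if (any(bad))
      stop("non-numeric cell for sample ", raw$sample_id[which(bad)[1]],
           ", analyte ", a, ": '", cell[which(bad)[1]], "'")
    val[is_nd] <- NA_real_
    nd[, a] <- is_nd
    records[[a]] <- val
  }
  dl <- detection_limit_defaults(analyte_class, analytes)
  survey_table(records, analyte_class, units = units, nondetect = nd,
               detection_limits = dl, provenance = paste("read from", path))
}

# Instrument detection limits of the study's ICP-OES / HPLC methods, in the
# canonical unit of each analyte class.
detection_limit_defaults <- function(analyte_class, analytes) {
  dl <- switch(analyte_class,
    metals = c(Cd = 0.0001, Cr = 0.001, Cu = 0.001, Fe = 0.001, Mn = 0.0005,
               Ni = 0.001, Pb = 0.001, Zn = 0.0005),
    pahs = c(Naph = 0.05, Acthy = 0.10, Ace = 0.10, Fl = 0.05, Phe = 0.05,
             Ant = 0.05, Flu = 0.05, Pyr = 0.05, BaA = 0.05, Chry = 0.05,
             BbF = 0.10, BkF = 0.10, BaP = 0.05, DBA = 0.10, BghiP = 0.10,
             InP = 0.10),
    toc = c(TOC = NA_real_))
  dl[analytes]
}

#' Write a survey table to a delimited file
#'
#' Inverse of [read_survey()]: non-detect cells are written as the `ND` token
#' regardless of any substituted value, so a read/write round trip preserves
#' both values and flags.
#'
#' @param survey a `survey_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_survey <- function(survey, path) {
  out <- as.data.frame(survey)
  nd <- attr(survey, "nondetect")
  for (a in survey_analytes(survey)) {
    col <- as.character(out[[a]])
    col[nd[, a]] <- "ND"
    out[[a]] <- col
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Substitute non-detect measurements
#'
#' Applies a substitution policy to every flagged non-detect: `"zero"` maps
#' them to 0 (the default throughout the pipeline, consistent with per-site
#' totals that sum detected compounds only), `"half_dl"` maps them to half the
#' analyte's detection limit.
#'
#' @param survey a `survey_table`.
#' @param policy `"zero"` or `"half_dl"`.
#' @return a `survey_table` with no remaining non-detect flags; the applied
#'   policy is recorded in the `nd_policy` attribute.
#' @export
substitute_nondetects <- function(survey, policy = c("zero", "half_dl")) {
  policy <- match.arg(policy)
  nd <- attr(survey, "nondetect")
  dl <- attr(survey, "detection_limits")
  analytes <- survey_analytes(survey)
  if (policy == "half_dl") {
    have_dl <- if (is.null(dl)) rep(FALSE, length(analytes)) else
      !is.na(dl[analytes])
    missing_dl <- analytes[colSums(nd[, analytes, drop = FALSE]) > 0 & !have_dl]
    if (length(missing_dl))
      stop("half_dl substitution needs detection limits for: ",
           paste(missing_dl, collapse = ", "))
  }
  for (a in analytes) {
    hit <- nd[, a]
    if (!any(hit)) next
    survey[[a]][hit] <- if (policy == "zero") 0 else dl[[a]] / 2
  }
  attr(survey, "nondetect") <- nd & FALSE
  attr(survey, "nd_policy") <- policy
  survey
}

#' Convert the concentration unit of a survey
#'
#' Explicit conversion between mg/L and ug/L (factor 1000); all other
#' attributes, including detection limits, are converted consistently.
#'
#' @param survey a `survey_table`.
#' @param to `"mg/L"` or `"ug/L"`.
#' @return the converted `survey_table`.
#' @export
convert_survey_units <- function(survey, to = c("mg/L", "ug/L")) {
  to <- match.arg(to)
  from <- attr(survey, "units")
  if (from == to) return(survey)
  # scale by multiplying up / dividing down: dividing by the exact integer
  # 1000 round-trips doubles exactly, multiplying by 0.001 does not
  conv <- if (from == "mg/L" && to == "ug/L") function(x) x * 1000
          else function(x) x / 1000
  for (a in survey_analytes(survey)) survey[[a]] <- conv(survey[[a]])
  dl <- attr(survey, "detection_limits")
  if (!is.null(dl)) attr(survey, "detection_limits") <- conv(dl)
  attr(survey, "units") <- to
  survey
}

#' @export
print.survey_table <- function(x, ...) {
  cat(sprintf("<survey_table> %d samples x %d analytes (%s, %s)\n",
              nrow(x), length(survey_analytes(x)),
              attr(x, "analyte_class"), attr(x, "units")))
  nd <- attr(x, "nondetect")
  if (any(nd)) cat("  non-detects:", sum(nd), "cells\n")
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Read a flat sectioned configuration file
#'
#' Minimal reader for the package's configuration dialect: `[section]`
#' headers followed by `key = value` lines, where a value is a number, a
#' quoted string or a `[a, b, c]` numeric list. Blank lines and `#` comments
#' are ignored.
#'
#' @param path file path.
#' @return nested named list, one element per section.
#' @export
read_risk_config <- function(path) {
  if (!file.exists(path)) stop("config file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- list()
  section <- NULL
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- sub("^\\[(.*)\\]$", "\\1", ln)
      next
    }
    if (!grepl("=", ln, fixed = TRUE))
      stop("malformed config line: ", ln)
    key <- trimws(sub("=.*$", "", ln))
    raw <- trimws(sub("^[^=]*=", "", ln))
    value <- parse_config_value(raw)
    if (is.null(section)) cfg[[key]] <- value
    else {
      parts <- strsplit(section, ".", fixed = TRUE)[[1]]
      cfg <- assign_nested(cfg, c(parts, key), value)
    }
  }
  cfg
}

parse_config_value <- function(raw) {
  if (grepl("^\\[.*\\]$", raw)) {
    items <- strsplit(sub("^\\[(.*)\\]$", "\\1", raw), ",")[[1]]
    return(vapply(trimws(items), function(v) as.numeric(v), numeric(1),
                  USE.NAMES = FALSE))
  }
  if (grepl('^".*"$', raw)) return(sub('^"(.*)"$', "\\1", raw))
  num <- suppressWarnings(as.numeric(raw))
  if (!is.na(num)) return(num)
  raw
}

assign_nested <- function(lst, keys, value) {
  if (length(keys) == 1) {
    lst[[keys]] <- value
    return(lst)
  }
  head_key <- keys[[1]]
  if (is.null(lst[[head_key]])) lst[[head_key]] <- list()
  lst[[head_key]] <- assign_nested(lst[[head_key]], keys[-1], value)
  lst
}
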