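#' Run a pipeline subcommand
#'
#' Thin orchestration layer over the package's analysis functions, suitable
#' for driving from a shell wrapper (see `inst/scripts/coastrisk`). Each run
#' writes its outputs plus a manifest JSON (subcommand, inputs, registry
#' version, seed, timestamp, package version) into the output directory.
#'
#' Subcommands: `pah` (per-site totals, ratios, source labels, RQ grades),
#' `metals` (HPI/MI report), `health` (deterministic HQ/HI/CR), `mc`
#' (Monte Carlo risk summary), `stats` (clustering + PCA), `simulate`
#' (synthetic survey), `report` (pah + metals + health + stats on the
#' packaged fixtures or the given inputs).
#'
#' @param args character vector of command-line style arguments, e.g.
#'   `c("pah", "--in", "table2_pahs.csv", "--out", "out_dir")`. Supported
#'   flags: `--in`, `--out`, `--seed`, `--nd-policy` (`zero` or `half_dl`),
#'   `--receptor` (`adult`, `child`, `both`), `--format` (`csv`, `json`),
#'   `--n` (Monte Carlo iterations), `--quiet`.
#' @return exit status, invisibly: 0 success, 2 bad paths/arguments,
#'   3 validation failure.
#' @export
run_workbench <- function(args) {
  status <- tryCatch({
    run_workbench_inner(args)
    0L
  },
  workbench_usage_error = function(e) {
    message("error: ", conditionMessage(e))
    2L
  },
  error = function(e) {
    message("validation error: ", conditionMessage(e))
    3L
  })
  invisible(status)
}

usage_stop <- function(...) {
  stop(structure(class = c("workbench_usage_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

parse_workbench_args <- function(args) {
  if (length(args) < 1) usage_stop("no subcommand given")
  sub <- args[[1]]
  known <- c("pah", "metals", "health", "mc", "stats", "simulate", "report")
  if (!sub %in% known)
    usage_stop("unknown subcommand '", sub, "'; expected one of: ",
               paste(known, collapse = ", "))
  opts <- list(subcommand = sub, seed = 1L, nd_policy = "zero",
               receptor = "both", format = "csv", n = 10000L,
               quiet = FALSE, input = NULL, out = "coastrisk_out")
  i <- 2
  while (i <= length(args)) {
    flag <- args[[i]]
    take <- function() {
      if (i + 1 > length(args)) usage_stop("missing value for ", flag)
      args[[i + 1]]
    }
    switch(flag,
      "--in" = { opts$input <- take(); i <- i + 2 },
      "--out" = { opts$out <- take(); i <- i + 2 },
      "--seed" = { opts$seed <- as.integer(take()); i <- i + 2 },
      "--n" = { opts$n <- as.integer(take()); i <- i + 2 },
      "--nd-policy" = { opts$nd_policy <- take(); i <- i + 2 },
      "--receptor" = { opts$receptor <- take(); i <- i + 2 },
      "--format" = { opts$format <- take(); i <- i + 2 },
      "--quiet" = { opts$quiet <- TRUE; i <- i + 1 },
      usage_stop("unknown flag: ", flag))
  }
  if (!opts$nd_policy %in% c("zero", "half_dl"))
    usage_stop("--nd-policy must be zero or half_dl")
  if (!opts$receptor %in% c("adult", "child", "both"))
    usage_stop("--receptor must be adult, child or both")
  if (!opts$format %in% c("csv", "json"))
    usage_stop("--format must be csv or json")
  opts
}

fixture_path <- function(name) {
  system.file("extdata", name, package = "coastrisk", mustWork = TRUE)
}

workbench_log <- function(opts, stage, ...) {
  if (!opts$quiet)
    message(sprintf("[%s] %s: %s", opts$subcommand, stage, paste0(...)))
}

write_output <- function(obj, opts, name) {
  path <- file.path(opts$out, paste0(name, ".", opts$format))
  if (opts$format == "csv" && is.data.frame(obj)) {
    utils::write.csv(obj, path, row.names = FALSE)
  } else {
    path <- file.path(opts$out, paste0(name, ".json"))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", force = TRUE)
  }
  path
}

write_manifest <- function(opts, inputs, registry) {
  manifest <- list(
    subcommand = opts$subcommand,
    inputs = inputs,
    registry_version = registry$version_tag,
    nd_policy = opts$nd_policy,
    seed = opts$seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    software = paste0("coastrisk ",
                      as.character(utils::packageVersion("coastrisk"))))
  jsonlite::write_json(manifest, file.path(opts$out, "manifest.json"),
                       auto_unbox = TRUE)
}

load_input_survey <- function(opts, analyte_class, default_fixture, registry) {
  path <- opts$input
  if (is.null(path)) path <- fixture_path(default_fixture)
  if (!file.exists(path)) usage_stop("input file does not exist: ", path)
  substitute_nondetects(read_survey(path, analyte_class, registry),
                        opts$nd_policy)
}

run_workbench_inner <- function(args) {
  opts <- parse_workbench_args(args)
  registry <- load_reference_registry()
  dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
  inputs <- opts$input

  if (opts$subcommand %in% c("pah", "report")) {
    pah_survey <- load_input_survey(
      opts_for(opts, "pah"), "pahs", "table2_pahs.csv", registry)
    workbench_log(opts, "pah", nrow(pah_survey), " sites")
    rep_pah <- pah_site_report(pah_survey, registry)
    write_output(rep_pah, opts, "pah_report")
    percomp <- do.call(rbind, lapply(seq_len(nrow(pah_survey)), function(i) {
      q <- rq(pah_survey[i, ], registry)
      cbind(sample_id = pah_survey$sample_id[i], q)
    }))
    write_output(percomp, opts, "pah_rq")
  }
  if (opts$subcommand %in% c("metals", "report")) {
    metal_survey <- load_input_survey(
      opts_for(opts, "metals"), "metals", "table1_metals.csv", registry)
    workbench_log(opts, "metals", nrow(metal_survey), " samples")
    rep_m <- metal_index_report(metal_survey, registry)
    write_output(rep_m$per_sample, opts, "metal_indices")
  }
  if (opts$subcommand %in% c("health", "report")) {
    metal_survey <- load_input_survey(
      opts_for(opts, "health"), "metals", "table1_metals.csv", registry)
    scen <- workbench_scenarios(opts$receptor)
    risk <- survey_risk(metal_survey, registry, scen)
    workbench_log(opts, "health", nrow(risk$per_metal), " risk rows")
    write_output(risk$per_metal, opts, "health_per_metal")
    write_output(risk$hi, opts, "health_hi")
  }
  if (opts$subcommand == "mc") {
    metal_survey <- load_input_survey(
      opts_for(opts, "mc"), "metals", "table1_metals.csv", registry)
    template <- default_mc_template(metal_survey, registry)
    exposure <- template$exposure[workbench_receptors(opts$receptor)]
    res <- mc_survey_risk(template$concentration, exposure, registry,
                          n = opts$n, seed = opts$seed)
    workbench_log(opts, "mc", opts$n, " iterations, seed ", opts$seed)
    write_output(as.data.frame(res), opts, "mc_report")
  }
  if (opts$subcommand %in% c("stats", "report")) {
    metal_survey <- load_input_survey(
      opts_for(opts, "stats"), "metals", "table1_metals.csv", registry)
    tree <- ward_cluster(metal_survey, "variables")
    linkage <- data.frame(step = seq_along(tree$height),
                          left = tree$merge[, 1], right = tree$merge[, 2],
                          height = tree$height)
    write_output(linkage, opts, "cluster_linkage")
    pc <- pca(metal_survey)
    load_tab <- data.frame(variable = rownames(pc$loadings),
                           pc$loadings, check.names = FALSE)
    write_output(load_tab, opts, "pca_loadings")
    eig_tab <- data.frame(component = seq_along(pc$eigenvalues),
                          eigenvalue = pc$eigenvalues,
                          variance_pct = pc$variance_explained,
                          cumulative_pct = pc$cumulative_variance)
    write_output(eig_tab, opts, "pca_eigenvalues")
    workbench_log(opts, "stats",
                  sprintf("KMO %.3f, %d PCs retained", pc$kmo,
                          length(pc$retained)))
  }
  if (opts$subcommand == "simulate") {
    gen <- generate_survey(generator_config(seed = opts$seed))
    out_csv <- file.path(opts$out, "synthetic_survey.csv")
    write_survey(gen$survey, out_csv)
    truth <- data.frame(analyte = names(gen$truth$cluster_labels),
                        cluster = gen$truth$cluster_labels)
    write_output(truth, opts, "synthetic_truth")
    workbench_log(opts, "simulate", nrow(gen$survey), " samples -> ", out_csv)
  }
  write_manifest(opts, inputs, registry)
  invisible(opts)
}

# `report` runs several stages; the --in override only applies to the stage
# matching the subcommand the user named, fixtures are used elsewhere.
opts_for <- function(opts, stage) {
  if (opts$subcommand == "report" && !is.null(opts$input)) {
    opts$input <- NULL
  }
  opts
}

workbench_receptors <- function(receptor) {
  if (receptor == "both") c("adult", "child") else receptor
}

workbench_scenarios <- function(receptor) {
  r <- workbench_receptors(receptor)
  stats::setNames(lapply(r, exposure_scenario), r)
}
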