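.rate_units <- c(per_s = 3600, per_h = 1,
                 AA_per_s = 3600, AA_per_h = 1,
                 NT_per_s = 3600, NT_per_h = 1)

.convert_rate <- function(entry, field) {
  if (is.numeric(entry) && length(entry) == 1L) return(entry) # per hour
  if (is.list(entry) && !is.null(entry$value)) {
    unit <- if (is.null(entry$unit)) "per_h" else entry$unit
    fac <- unname(.rate_units[unit])
    if (is.na(fac))
      stop("load_parameters: unknown unit '", unit, "' for rate '", field, "'")
    return(unname(entry$value) * fac)
  }
  stop("load_parameters: malformed rate entry for '", field, "'")
}

#' Load a parameter set from a JSON or TSV file
#'
#' JSON files carry sections `masses`, `lengths`, `rates`, `fractions`,
#' `degradation`, and optionally `variant` and `condition_label`. Rates may
#' be bare numbers (interpreted per hour) or `{value, unit}` objects with
#' unit `per_s`/`per_h` (also `AA_`/`NT_` prefixed); per-second values are
#' converted to per-hour on load. TSV files have columns `name`, `value`,
#' `unit` with dotted names for nested fields (e.g. `degradation.K`).
#' Partially specified sets are rejected with an error naming the missing
#' field.
#'
#' @param path file path (extension `.json` or `.tsv`).
#' @param schema_version expected schema version (checked if the file
#'   declares one).
#' @return a validated `rba_params` object.
#' @seealso [write_parameters()]
#' @export
load_parameters <- function(path, schema_version = "1.0") {
  if (!file.exists(path)) stop("load_parameters: file not found: ", path)
  if (grepl("\\.tsv$", path, ignore.case = TRUE)) {
    obj <- .tsv_to_param_list(path)
  } else {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(obj$schema_version) &&
      !identical(as.character(obj$schema_version), schema_version))
    stop("load_parameters: schema version '", obj$schema_version,
         "' does not match expected '", schema_version, "'")
  args <- list()
  for (f in .rba_mass_fields) args[[f]] <- obj$masses[[f]]
  for (f in setdiff(.rba_length_fields, c("n_AA", "n_NT")))
    args[[f]] <- obj$lengths[[f]]
  args$n_AA <- obj$lengths$n_AA
  args$n_NT <- obj$lengths$n_NT
  for (f in .rba_rate_fields) {
    if (is.null(obj$rates[[f]]))
      stop("load_parameters: missing field '", f, "'")
    args[[f]] <- .convert_rate(obj$rates[[f]], f)
  }
  for (f in .rba_fraction_fields) args[[f]] <- obj$fractions[[f]]
  miss <- c(.rba_mass_fields,
            setdiff(.rba_length_fields, c("n_AA", "n_NT")),
            .rba_fraction_fields)
  for (f in miss) {
    if (is.null(args[[f]])) stop("load_parameters: missing field '", f, "'")
  }
  d <- obj$degradation
  if (is.null(d) || is.null(d$scenario))
    stop("load_parameters: missing field 'degradation'")
  if (!d$scenario %in% c("none", "constant", "hill"))
    stop("load_parameters: unknown scenario '", d$scenario,
         "' in field 'degradation'")
  args$degradation <- degradation_model(
    d$scenario,
    kdeg_max = if (is.null(d$kdeg_max)) 0 else .convert_rate(d$kdeg_max,
                                                             "kdeg_max"),
    K = if (is.null(d$K)) 0.2 else d$K,
    n_hill = if (is.null(d$n_hill)) 1 else d$n_hill
  )
  if (!is.null(obj$variant$rp_import_fraction))
    args$rp_import_fraction <- obj$variant$rp_import_fraction
  if (!is.null(obj$condition_label)) args$condition_label <- obj$condition_label
  args$meta <- list(source = path, schema_version = schema_version)
  do.call(parameter_set, args)
}

.tsv_to_param_list <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("name", "value", "unit") %in% names(df)))
    stop("load_parameters: TSV must have columns name, value, unit")
  obj <- list(masses = list(), lengths = list(), rates = list(),
              fractions = list(), degradation = list(), variant = list())
  for (i in seq_len(nrow(df))) {
    nm <- df$name[i]
    val <- df$value[i]
    unit <- df$unit[i]
    if (nm == "condition_label") {
      obj$condition_label <- as.character(val)
    } else if (nm == "schema_version") {
      obj$schema_version <- as.character(val)
    } else if (startsWith(nm, "degradation.")) {
      key <- sub("^degradation\\.", "", nm)
      obj$degradation[[key]] <-
        if (key %in% c("kdeg_max")) list(value = as.numeric(val), unit = unit)
        else if (key == "scenario") as.character(val)
        else as.numeric(val)
    } else if (nm == "rp_import_fraction") {
      obj$variant$rp_import_fraction <- as.numeric(val)
    } else if (nm %in% .rba_mass_fields) {
      obj$masses[[nm]] <- as.numeric(val)
    } else if (nm %in% .rba_length_fields) {
      obj$lengths[[nm]] <- as.numeric(val)
    } else if (nm %in% .rba_rate_fields) {
      obj$rates[[nm]] <- list(value = as.numeric(val),
                              unit = if (nzchar(unit)) unit else "per_h")
    } else if (nm %in% .rba_fraction_fields) {
      obj$fractions[[nm]] <- as.numeric(val)
    } else {
      stop("load_parameters: unknown field '", nm, "' in TSV")
    }
  }
  obj
}

#' Write a parameter set to a JSON file
#'
#' Serializes with all rates per hour (unit tags included), full precision.
#' `load_parameters()` of the written file reproduces the numeric content
#' exactly.
#'
#' @param p an `rba_params` object.
#' @param path output path (`.json`).
#' @return `path`, invisibly.
#' @export
write_parameters <- function(p, path) {
  stopifnot(inherits(p, "rba_params"))
  rate_obj <- function(v) list(value = v, unit = "per_h")
  obj <- list(
    schema_version = "1.0",
    condition_label = p$condition_label,
    masses = p[.rba_mass_fields],
    lengths = p[.rba_length_fields],
    rates = lapply(p[.rba_rate_fields], rate_obj),
    fractions = p[.rba_fraction_fields],
    degradation = list(
      scenario = p$degradation$scenario,
      kdeg_max = rate_obj(p$degradation$kdeg_max),
      K = p$degradation$K, n_hill = p$degradation$n_hill
    ),
    variant = list(rp_import_fraction = p$rp_import_fraction)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Run a scenario pipeline and write its tables
#'
#' Orchestrates the standard analyses as pure functions of a configuration:
#' every run writes tidy CSV tables plus a JSON manifest (inputs, seeds,
#' output checksums) into `out_dir/<name>/`. Supported types:
#' \describe{
#'   \item{`ratio`}{per-condition optima at fixed composition with
#'     RNA/protein ratios (growth-law validation).}
#'   \item{`branches`}{extreme-solution RNAP fluxes across a growth-rate
#'     grid for one condition.}
#'   \item{`sweep`}{composition sweeps per condition under a degradation
#'     scenario (`none`, `constant`, or `hill` with `n_hill`).}
#'   \item{`calibrate`}{degradation-rate calibration to a target optimal
#'     composition.}
#'   \item{`import_sweep`}{sweeps under increasing free rP import
#'     (mitochondrial scenario).}
#' }
#'
#' @param config named list (or path to a YAML/JSON file) with `name`,
#'   `type`, and type-specific fields: `conditions`, `x_rP`, `grid_step`,
#'   `mu_points`, `degradation` (list: scenario, kdeg_max, K, n_hill),
#'   `deg_factor`, `import_fractions`, `target_x`, `tol`, `seed`.
#' @param out_dir output directory (created if needed).
#' @return list with `tables` (named list of data frames), `manifest`, and
#'   the output `dir`, invisibly.
#' @export
run_scenario <- function(config, out_dir = ".") {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config, ignore.case = TRUE)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("run_scenario: the 'yaml' package is required for YAML configs")
      yaml::read_yaml(config)
    } else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config), !is.null(config$name), !is.null(config$type))
  cfg <- utils::modifyList(
    list(conditions = ecoli_conditions(), x_rP = 0.36, grid_step = 0.01,
         tol = 1e-6, seed = 1L, condition = "glc",
         degradation = list(scenario = "hill", kdeg_max = NULL, K = 0.2,
                            n_hill = 6),
         deg_factor = 1, import_fractions = c(0, 1 / 3, 2 / 3),
         target_x = 0.36, mu_points = 8),
    config)
  set.seed(as.integer(cfg$seed))
  grid <- seq(0, 1, by = cfg$grid_step)
  pf <- function(cond) {
    p <- ecoli_fixture(cond)
    d <- cfg$degradation
    scen <- d$scenario %||% "hill"
    p$degradation <- if (scen == "none") degradation_model("none")
      else degradation_model(
        scen,
        kdeg_max = d$kdeg_max %||% p$degradation$kdeg_max,
        K = d$K %||% p$degradation$K,
        n_hill = d$n_hill %||% if (scen == "hill") 6 else 1)
    if (cfg$deg_factor != 1 && scen != "none")
      p <- variant_archaea(p, cfg$deg_factor)
    p
  }
  tables <- switch(
    cfg$type,
    ratio = {
      panel <- condition_panel(cfg$conditions, cfg$x_rP, "base",
                               tol = cfg$tol)
      list(ratio = panel$summary)
    },
    branches = {
      p <- ecoli_fixture(cfg$condition)
      mu_max <- maximize_growth(p, cfg$x_rP, "base", cfg$tol)$mu
      mu_grid <- seq(mu_max / cfg$mu_points, mu_max - cfg$tol,
                     length.out = cfg$mu_points)
      list(branches = rnap_flux_branches(p, cfg$x_rP, mu_grid, "base"))
    },
    sweep = {
      variant <- if ((cfg$degradation$scenario %||% "hill") == "none")
        "base" else "extended"
      rows <- lapply(cfg$conditions, function(cond) {
        sw <- sweep_composition(pf(cond), grid, variant, cfg$tol,
                                keep_solutions = FALSE)
        cbind(condition = cond, sw$table,
              argmax = sw$argmax, interior = sw$interior)
      })
      list(sweep = do.call(rbind, rows))
    },
    calibrate = {
      cal <- calibrate_kdeg_max(pf(cfg$condition), cfg$target_x, grid,
                                tol = cfg$tol)
      list(calibration = data.frame(
        condition = cfg$condition, target_x = cfg$target_x,
        kdeg_max = cal$kdeg_max, argmax = cal$sweep$argmax,
        iterations = cal$iterations))
    },
    import_sweep = {
      rows <- lapply(cfg$import_fractions, function(f) {
        p <- variant_mitochondria(pf(cfg$condition), f)
        sw <- sweep_composition(p, grid, "extended", cfg$tol,
                                keep_solutions = FALSE)
        cbind(import_fraction = f, sw$table,
              argmax = sw$argmax, interior = sw$interior)
      })
      list(import_sweep = do.call(rbind, rows))
    },
    stop("run_scenario: unknown type '", cfg$type, "'")
  )
  dir <- file.path(out_dir, cfg$name)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  for (nm in names(tables)) {
    fp <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], fp, row.names = FALSE)
    files[nm] <- fp
  }
  manifest <- list(
    tool = paste0("ribocomp ",
                  as.character(utils::packageVersion("ribocomp"))),
    config = cfg[setdiff(names(cfg), "name")],
    name = cfg$name,
    seed = cfg$seed,
    outputs = lapply(files, function(f)
      list(path = f, md5 = unname(tools::md5sum(f)))),
    r_version = R.version.string
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(tables = tables, manifest = manifest, dir = dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
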