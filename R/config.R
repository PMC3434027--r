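# Configuration: a single human-readable YAML file with sections
# lineage / morphogen / geometry / numerics / scenario. Unspecified fields
# fall back to the documented package defaults; every value is validated
# by the parameter constructors, which name the offending field.

scenario_names <- c("formation", "dW_scan", "dB_scan", "d1_scan",
                    "regeneration_partial", "regeneration_full",
                    "bmp_knockout", "phase_diagram", "localized_seed",
                    "exogenous_wnt")

#' Load and validate a configuration file
#'
#' @param path YAML file; missing sections/fields are filled from package
#'   defaults.
#' @return validated parameter list (see [default_params()]).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  params_from_list(raw)
}

#' Build a validated parameter list from a plain nested list
#' @param raw nested list with any of the sections `lineage`, `morphogen`,
#'   `geometry`, `numerics`, `scenario`.
#' @export
params_from_list <- function(raw) {
  raw <- raw %||% list()
  build <- function(ctor, section) {
    given <- raw[[section]] %||% list()
    given <- given[!vapply(given, is.null, logical(1))]
    # YAML 1.1 readers coerce the bare key "n" (Hill exponent) to the
    # boolean FALSE; restore the only schema name it can have come from
    nm <- names(given)
    if (!"n" %in% nm) nm[nm %in% c("FALSE", "no")] <- "n"
    names(given) <- nm
    # mixed int/double YAML sequences arrive as lists; flatten to vectors
    given <- lapply(given, function(v)
      if (is.list(v) && length(v) &&
          all(vapply(v, is.numeric, logical(1)))) unlist(v) else v)
    known <- names(formals(ctor))
    bad <- setdiff(names(given), known)
    if (length(bad))
      stop("unknown field(s) in section '", section, "': ",
           paste(bad, collapse = ", "), call. = FALSE)
    do.call(ctor, given)
  }
  params <- list(lineage = build(lineage_params, "lineage"),
                 morphogen = build(morphogen_params, "morphogen"),
                 geometry = build(geometry_params, "geometry"),
                 numerics = build(numerics_params, "numerics"),
                 scenario = raw$scenario %||% default_params()$scenario)
  if (!is.null(params$scenario$name) &&
      !params$scenario$name %in% scenario_names)
    stop("unknown scenario name '", params$scenario$name, "'; known: ",
         paste(scenario_names, collapse = ", "), call. = FALSE)
  params
}

#' Write the effective configuration
#'
#' @param params parameter list.
#' @param path output YAML path.
#' @export
save_config <- function(params, path) {
  plain <- lapply(params[c("lineage", "morphogen", "geometry", "numerics")],
                  function(p) lapply(unclass(p), identity))
  plain$scenario <- params$scenario
  writeLines(yaml::as.yaml(plain, precision = 15L), path)
  invisible(path)
}

#' Apply `key=value` overrides to a parameter list
#'
#' Keys are dotted paths into the config, e.g.
#' `"morphogen.d_W=0.02"` or `"numerics.n_points=128"`. Values are parsed
#' as YAML scalars. The touched section is re-validated.
#'
#' @param params parameter list.
#' @param overrides character vector of `section.field=value` strings.
#' @export
apply_overrides <- function(params, overrides) {
  if (length(overrides) == 0) return(params)
  plain <- lapply(params[c("lineage", "morphogen", "geometry", "numerics")],
                  unclass)
  plain$scenario <- params$scenario
  for (ov in overrides) {
    kv <- strsplit(ov, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("override must look like section.field=value: ", ov)
    keys <- strsplit(kv[1], ".", fixed = TRUE)[[1]]
    value <- yaml::yaml.load(kv[2])
    plain <- modify_path(plain, keys, value)
  }
  params_from_list(plain)
}

modify_path <- function(lst, keys, value) {
  if (length(keys) == 1) {
    lst[[keys]] <- value
    return(lst)
  }
  node <- lst[[keys[1]]] %||% list()
  lst[[keys[1]]] <- modify_path(node, keys[-1], value)
  lst
}

#' Export a run to flat files
#'
#' Writes per-field CSV profiles (xi, s, C0, C1, Wnt, inhibitor, BMP,
#' curve x/y), the time-series table, the effective config and an RDS
#' snapshot container into a directory.
#'
#' @param run `crypt_run` object.
#' @param dir output directory (created).
#' @export
export_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  st <- run$state
  g <- st$grid
  prof <- data.frame(xi = g$xi, s = grid_s(g), C0 = st$cells$C0,
                     C1 = st$cells$C1, wnt = st$morphogens$wnt,
                     inhibitor = st$morphogens$inhibitor,
                     bmp = st$morphogens$bmp)
  utils::write.csv(prof, file.path(dir, "profiles.csv"), row.names = FALSE)
  cvd <- data.frame(xi = (0:st$curve$n) / st$curve$n,
                    x = st$curve$x, y = st$curve$y)
  utils::write.csv(cvd, file.path(dir, "curve.csv"), row.names = FALSE)
  utils::write.csv(run$timeseries, file.path(dir, "timeseries.csv"),
                   row.names = FALSE)
  save_config(run$params, file.path(dir, "config.yaml"))
  saveRDS(run$state, file.path(dir, "state.rds"))
  invisible(dir)
}
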