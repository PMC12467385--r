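#' Read a boundary measurement series from CSV
#'
#' Expects a header with column `t_s` plus `u_m_s` and/or `area_m2`
#' (optional passthrough columns `vessel_id`, `end`, `x_m` are kept).
#' Time must be strictly increasing and all values finite; each violation
#' raises a distinct error.
#'
#' @param path CSV file path.
#' @return A tibble.
#' @export
read_boundary_csv <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  d <- as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  if (!"t_s" %in% names(d))
    abort(paste0("missing column `t_s` in ", path))
  if (!any(c("u_m_s", "area_m2") %in% names(d)))
    abort(paste0("missing data columns (`u_m_s` and/or `area_m2`) in ", path))
  split_keys <- intersect(c("vessel_id", "end"), names(d))
  groups <- if (length(split_keys))
    split(d, d[split_keys], drop = TRUE) else list(d)
  for (g in groups) {
    if (any(diff(g$t_s) <= 0))
      abort(paste0("`t_s` must be strictly increasing in ", path))
  }
  num <- intersect(c("t_s", "u_m_s", "area_m2", "x_m"), names(d))
  if (any(!vapply(d[num], function(x) all(is.finite(x)), TRUE)))
    abort(paste0("non-finite values in ", path))
  d
}

#' Write a boundary measurement series to CSV
#'
#' Locale-independent (C locale decimal points), fixed column order.
#'
#' @param series Tibble with `t_s` and `u_m_s` and/or `area_m2` (plus
#'   optional `vessel_id`, `end`, `x_m`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_boundary_csv <- function(series, path) {
  ord <- intersect(c("vessel_id", "end", "x_m", "t_s", "u_m_s", "area_m2"),
                   names(series))
  utils::write.csv(as.data.frame(series)[ord], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read and write field-state CSVs
#'
#' The on-disk field format has columns `vessel_id, x_m, t_s, area_m2,
#' velocity_m_s, pressure_pa` (SI units; pressure in Pa).
#'
#' @param path CSV file path.
#' @return [read_field_csv()]: a tibble of fields.
#' @export
read_field_csv <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  d <- as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  need <- c("vessel_id", "x_m", "t_s", "area_m2", "velocity_m_s",
            "pressure_pa")
  miss <- setdiff(need, names(d))
  if (length(miss))
    abort(paste0("missing columns in ", path, ": ",
                 paste(miss, collapse = ", ")))
  if (any(d$area_m2 <= 0)) abort("non-positive areas in field file.")
  d[need]
}

#' @rdname read_field_csv
#' @param fields Tibble in the field-state layout.
#' @export
write_field_csv <- function(fields, path) {
  need <- c("vessel_id", "x_m", "t_s", "area_m2", "velocity_m_s",
            "pressure_pa")
  miss <- setdiff(need, names(fields))
  if (length(miss))
    abort(paste0("fields are missing columns: ", paste(miss, collapse = ", ")))
  utils::write.csv(as.data.frame(fields)[need], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

config_defaults <- list(
  fluid = list(rho = 1060, alpha = 1, KR = 0),
  cycle_duration = 0.89,
  pext_mmhg = 16,
  mechanics = list(thickness_ratio = 0.1, nu = 0.5),
  network = list(hidden_layers = 7, hidden_width = 100, init_seed = 1),
  training = list(epochs = 50000, learning_rate = 0.001,
                  n_collocation = 2000, n_boundary = 101,
                  ic_zero_velocity = TRUE, log_every = 100, seed = 1)
)

check_known_keys <- function(x, known, where) {
  bad <- setdiff(names(x), known)
  if (length(bad))
    abort(paste0("unknown key(s) at ", where, ": ", paste(bad, collapse = ", ")))
}

#' Read a full problem configuration (YAML)
#'
#' A structured plain-text configuration resolves to a
#' [bifurcation_problem()], a [network_spec()] and a [training_control()]
#' with all defaults filled (flat velocity profile `alpha = 1`, no
#' friction, `pext` 16 mmHg, `nu = 0.5`, `h0/R0 = 0.1`, learning rate
#' 0.001, 50,000 epochs, 2000 collocation points, 101 boundary samples).
#' Per vessel, either `beta` or wall mechanics (`E`, optional `h0`,
#' `nu`) must be given -- both at once is an explicit conflict error --
#' and `measurements` may point to boundary CSV files (paths relative to
#' the configuration file). Unknown keys are rejected with the path to
#' the offending key.
#'
#' @param path YAML configuration file.
#' @return List with elements `problem`, `network`, `control`.
#' @export
read_problem_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config not found: ", path))
  cfg <- yaml::read_yaml(path)
  check_known_keys(cfg, c("fluid", "cycle_duration", "pext_mmhg", "vessels",
                          "mechanics", "network", "training"), "top level")
  if (is.null(cfg$vessels) || length(cfg$vessels) != 3L)
    abort("config needs a `vessels` block with exactly parent, daughter1, daughter2.")
  check_known_keys(cfg$vessels, c("parent", "daughter1", "daughter2"),
                   "vessels")
  for (blk in c("fluid", "mechanics", "network", "training"))
    if (!is.null(cfg[[blk]]))
      check_known_keys(cfg[[blk]], names(config_defaults[[blk]]),
                       blk)
  merged <- utils::modifyList(config_defaults, cfg[setdiff(names(cfg),
                                                           "vessels")])
  pext <- mmhg_to_pa(merged$pext_mmhg)
  mech <- merged$mechanics

  base <- dirname(normalizePath(path))
  meas <- list()
  vs <- lapply(c("parent", "daughter1", "daughter2"), function(role) {
    v <- cfg$vessels[[role]]
    if (is.null(v)) abort(paste0("vessels$", role, " is missing."))
    check_known_keys(v, c("id", "length", "A0", "beta", "E", "h0", "nu",
                          "measurements"), paste0("vessels$", role))
    if (is.null(v$length) || is.null(v$A0))
      abort(paste0("vessels$", role, " needs `length` and `A0`."))
    if (!is.null(v$beta) && !is.null(v$E))
      abort(paste0("vessels$", role,
                   ": `beta` and mechanics (`E`) are both given; supply only one."))
    id <- v$id %||% role
    seg <- vessel_segment(
      id, length = v$length, A0 = v$A0, beta = v$beta, pext = pext,
      E = v$E,
      h0 = v$h0 %||% (if (is.null(v$beta)) mech$thickness_ratio *
                        sqrt(v$A0 / pi)),
      nu = v$nu %||% mech$nu)
    if (!is.null(v$measurements)) {
      check_known_keys(v$measurements, c("inlet", "outlet"),
                       paste0("vessels$", role, "$measurements"))
      for (e in names(v$measurements)) {
        f <- v$measurements[[e]]
        if (!file.exists(f)) f <- file.path(base, v$measurements[[e]])
        d <- read_boundary_csv(f)
        d$vessel_id <- id; d$end <- e
        meas[[length(meas) + 1L]] <<- d
      }
    }
    seg
  })
  measurements <- if (length(meas)) dplyr::bind_rows(meas)
  problem <- bifurcation_problem(
    vs[[1]], vs[[2]], vs[[3]],
    fluid = fluid_model(merged$fluid$rho, merged$fluid$alpha,
                        merged$fluid$KR),
    measurements = measurements,
    cycle_duration = merged$cycle_duration)
  net <- network_spec(merged$network$hidden_layers,
                      merged$network$hidden_width,
                      merged$network$init_seed)
  tr <- merged$training
  control <- training_control(
    epochs = tr$epochs, learning_rate = tr$learning_rate,
    n_collocation = tr$n_collocation, n_boundary = tr$n_boundary,
    ic_zero_velocity = tr$ic_zero_velocity, log_every = tr$log_every,
    seed = tr$seed)
  list(problem = problem, network = net, control = control)
}

#' Serialize a problem to a configuration fragment
#'
#' Writes the vessel geometry/mechanics and fluid constants of a
#' [bifurcation_problem()] (or the `beta` table of a
#' [estimate_wall_mechanics()] result) as YAML consumable by
#' [read_problem_config()].
#'
#' @param x A `bifurcation_problem` or `wall_mechanics` object.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_config_fragment <- function(x, path) {
  if (inherits(x, "wall_mechanics")) {
    roles <- c("parent", "daughter1", "daughter2")
    vessels <- stats::setNames(lapply(seq_len(nrow(x$beta)), function(i)
      list(id = x$beta$vessel_id[i], A0 = x$beta$A0_m2[i],
           beta = x$beta$beta_pa_m[i])),
      roles[seq_len(min(nrow(x$beta), 3L))])
    out <- list(mechanics = list(thickness_ratio = x$thickness_ratio,
                                 nu = x$nu),
                vessels = vessels)
  } else if (inherits(x, "bifurcation_problem")) {
    roles <- c("parent", "daughter1", "daughter2")
    vessels <- stats::setNames(lapply(1:3, function(i) {
      v <- x$vessels[[i]]
      list(id = v$id, length = v$length, A0 = v$A0, beta = v$beta)
    }), roles)
    out <- list(fluid = list(rho = x$fluid$rho, alpha = x$fluid$alpha,
                             KR = x$fluid$KR),
                cycle_duration = x$cycle_duration,
                pext_mmhg = pa_to_mmhg(x$vessels[[1]]$pext),
                vessels = vessels)
  } else {
    abort("`x` must be a bifurcation_problem or wall_mechanics object.")
  }
  yaml::write_yaml(out, path, precision = 12L)
  invisible(path)
}

#' Build a run manifest
#'
#' Snapshot from which a stochastic run can be reconstructed: resolved
#' configuration values, seeds, package version, MD5 digests of input
#' files, and a timestamp.
#'
#' @param control A [training_control()].
#' @param network A [network_spec()].
#' @param input_files Character vector of input file paths to digest.
#' @param extra Named list of extra fields to record.
#' @return A list of class `run_manifest`.
#' @export
run_manifest <- function(control, network, input_files = character(),
                         extra = list()) {
  digests <- if (length(input_files))
    as.list(tools::md5sum(input_files)) else list()
  structure(c(list(
    package = "pulsepinn",
    version = as.character(utils::packageVersion("pulsepinn")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = control$seed,
    network = unclass(network),
    training = unclass(control),
    input_digests = digests), extra),
    class = "run_manifest")
}

#' Write the full output set of a trained model
#'
#' Writes predicted field CSVs (one per vessel on a regular grid), the
#' loss-history CSV, a pressure-summary report (Pa and mmHg), and the run
#' manifest (JSON).
#'
#' @param model A [train_pinn()] result.
#' @param outdir Output directory (created if missing).
#' @param n_x,n_t Prediction grid resolution.
#' @param overwrite Overwrite existing files (default `TRUE`; `FALSE`
#'   errors if any target exists).
#' @param manifest Optional [run_manifest()]; one is built if omitted.
#' @return Invisibly, the named vector of written paths.
#' @export
write_outputs <- function(model, outdir, n_x = 21, n_t = 101,
                          overwrite = TRUE, manifest = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  T <- model$problem$cycle_duration
  fields <- purrr::map_dfr(model$problem$vessels, function(s)
    predict_fields(model, s$id, seq(0, s$length, length.out = n_x),
                   seq(0, T, length.out = n_t)))
  paths <- c(fields = file.path(outdir, "fields.csv"),
             history = file.path(outdir, "loss_history.csv"),
             summary = file.path(outdir, "pressure_summary.csv"),
             manifest = file.path(outdir, "manifest.json"))
  if (!overwrite && any(file.exists(paths)))
    abort("output files exist and `overwrite = FALSE`.")
  write_field_csv(fields[names(fields) != "extrapolated"], paths[["fields"]])
  utils::write.csv(as.data.frame(model$history), paths[["history"]],
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(as.data.frame(pressure_summary(model, n_x, n_t)),
                   paths[["summary"]], row.names = FALSE, quote = FALSE)
  mf <- manifest %||% run_manifest(model$control, model$network)
  jsonlite::write_json(unclass(mf), paths[["manifest"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
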