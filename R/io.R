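# Configuration files, state/trajectory I/O, and the run/analyze entry
# points behind the command-line wrapper.

.scenario_registry <- function() {
  list(
    gliding_assay = scenario_gliding_assay,
    nematic_tube = scenario_nematic_tube,
    bulk_isotropic = scenario_bulk_isotropic,
    spherical_shell = scenario_spherical_shell,
    confined_cylinder = scenario_confined_cylinder
  )
}

#' Read and validate a run configuration
#'
#' Configurations are YAML with three blocks: `scenario` (generator `name`
#' and its `args`), `step` (arguments of [step_config()]), and `run`
#' (`duration`, `record_every`, `record_motors`, `record_events`,
#' `seed`), plus an optional `output` block (`trajectory`, `frames_tsv`,
#' `log_tsv`, `state_tsv` file paths). Unknown keys fail with the offending
#' key named. All physical quantities use the package units (um, s, pN).
#'
#' @param path YAML file path.
#' @return A validated `fm_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  raw <- yaml::read_yaml(path)
  validate_run_config(raw, context = path)
}

#' @rdname read_run_config
#' @param config A raw configuration list.
#' @param context Label used in error messages.
#' @export
validate_run_config <- function(config, context = "config") {
  fail <- function(...) abort(paste0(context, ": ", ...))
  check_keys <- function(block, allowed, where) {
    extra <- setdiff(names(block), allowed)
    if (length(extra) > 0) {
      fail("unknown key(s) in ", where, ": ", paste(extra, collapse = ", "),
           " (allowed: ", paste(allowed, collapse = ", "), ")")
    }
  }
  check_keys(config, c("scenario", "step", "run", "output"), "top level")
  sc <- config$scenario
  if (is.null(sc$name)) fail("scenario$name is required")
  reg <- .scenario_registry()
  if (!sc$name %in% names(reg)) {
    fail("unknown scenario '", sc$name, "'; available: ",
         paste(names(reg), collapse = ", "))
  }
  check_keys(sc, c("name", "args"), "scenario")
  gen <- reg[[sc$name]]
  if (any(names(sc$args) %in% c("TRUE", "FALSE", "NA"))) {
    fail("a scenario argument key was parsed as a YAML boolean; quote ",
         "keys like 'n' or 'y' in the config file (e.g. \"n\": 100)")
  }
  bad <- setdiff(names(sc$args), names(formals(gen)))
  if (length(bad) > 0) {
    fail("scenario '", sc$name, "' has no argument(s): ",
         paste(bad, collapse = ", "))
  }
  check_keys(config$step %||% list(), names(formals(step_config)), "step")
  check_keys(config$run %||% list(),
             c("duration", "record_every", "record_motors", "record_events",
               "seed"), "run")
  if (is.null(config$run$duration) || config$run$duration <= 0) {
    fail("run$duration (s) must be positive")
  }
  check_keys(config$output %||% list(),
             c("trajectory", "frames_tsv", "log_tsv", "state_tsv"), "output")
  structure(config, class = "fm_config")
}

#' Run a configured simulation
#'
#' Generates the scenario, integrates for the configured duration, and
#' writes any requested outputs. `seed` overrides both the scenario seed
#' and the dynamics RNG stream, so one integer reproduces the whole run.
#'
#' @param config An `fm_config` (or path to a YAML file).
#' @param seed Optional integer overriding `run$seed`.
#' @return Invisibly, a list with `state` and `trajectory`.
#' @export
run_simulation <- function(config, seed = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "fm_config")) {
    config <- validate_run_config(config)
  }
  seed <- seed %||% config$run$seed %||% 1
  gen <- .scenario_registry()[[config$scenario$name]]
  args <- config$scenario$args %||% list()
  args$seed <- seed
  state <- do.call(gen, args)
  cfg <- do.call(step_config, config$step %||% list())
  run <- config$run
  res <- simulate_run(
    state, cfg, duration = run$duration,
    record_every = run$record_every %||% (run$duration / 50),
    record_motors = run$record_motors %||% TRUE,
    record_events = run$record_events %||% FALSE)
  out <- config$output
  if (!is.null(out$trajectory)) write_trajectory(res$trajectory,
                                                 out$trajectory)
  if (!is.null(out$frames_tsv)) {
    utils::write.table(tidy(res$trajectory), out$frames_tsv, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  if (!is.null(out$log_tsv)) {
    utils::write.table(res$trajectory$log, out$log_tsv, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  if (!is.null(out$state_tsv)) write_state_table(res$state, out$state_tsv)
  invisible(res)
}

#' Compute observables from a recorded trajectory
#'
#' Dispatch layer used by the command line: maps observable names to the
#' corresponding functions and returns one tidy table per request.
#'
#' @param trajectory An `fm_trajectory` or path to a saved one.
#' @param which Character vector among `"transport_velocity"`, `"rdf"`,
#'   `"rdf_peaks"`, `"stress"`, `"straining_velocity"`, `"log"`.
#' @param ... Passed on to the underlying observable functions.
#' @return Named list of tibbles.
#' @export
analyze_trajectory <- function(trajectory, which = "log", ...) {
  if (is.character(trajectory)) trajectory <- read_trajectory(trajectory)
  known <- c("transport_velocity", "rdf", "rdf_peaks", "stress",
             "straining_velocity", "log")
  bad <- setdiff(which, known)
  if (length(bad) > 0) {
    abort(paste0("unknown observable(s): ", paste(bad, collapse = ", "),
                 "; available: ", paste(known, collapse = ", ")))
  }
  dots <- list(...)
  res <- list()
  for (w in which) {
    res[[w]] <- switch(w,
      transport_velocity = fit_transport_velocity(trajectory),
      rdf = .traj_rdf(trajectory, dots),
      rdf_peaks = rdf_peaks(.traj_rdf(trajectory, dots)),
      stress = stress_series(trajectory,
                             dots$volume %||% .traj_volume(trajectory)),
      straining_velocity = do.call(plane_straining_velocity,
                                   c(list(trajectory),
                                     dots[intersect(names(dots),
                                       names(formals(
                                         plane_straining_velocity)))])),
      log = trajectory$log
    )
  }
  res
}

.traj_volume <- function(trajectory) {
  b <- trajectory$boundary
  switch(b$kind,
    periodic_box = b$lx * b$ly * b$lz,
    cylinder_x = pi * b$radius^2 * b$period,
    sphere = 4 / 3 * pi * b$radius^3,
    spherical_shell = 4 / 3 * pi * (b$r_out^3 - b$r_in^3),
    abort("volume undefined for a free boundary; pass `volume`"))
}

.traj_rdf <- function(trajectory, dots) {
  fr <- trajectory$frames[nrow(trajectory$frames), ]
  fil <- fr$filaments[[1]]
  fil$length <- trajectory$filaments$length
  fil$diameter <- trajectory$filaments$diameter
  ends <- filament_ends(fil, "minus")
  args <- list(ends, boundary = trajectory$boundary)
  if (trajectory$boundary$kind != "periodic_box") {
    args$volume <- .traj_volume(trajectory)
  }
  do.call(rdf_minus_ends,
          c(args, dots[intersect(names(dots), c("bin_width", "r_max"))]))
}

#' Write / read a filament state as a plain-text table
#'
#' Tab-separated, one row per filament, full double precision (17
#' significant digits), so a write-read round trip reproduces the state
#' exactly. Motor and species tables are written alongside when present
#' (suffixes `_motors`, `_species`).
#'
#' @param state A [system_state()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_state_table <- function(state, path) {
  fmt <- function(df) {
    out <- df
    for (c_ in names(out)) {
      if (is.double(out[[c_]])) out[[c_]] <- sprintf("%.17g", out[[c_]])
    }
    out
  }
  utils::write.table(fmt(state$filaments), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  side <- function(suffix) sub("(\\.[^.]*)?$", paste0("_", suffix, "\\1"),
                               path)
  if (nrow(state$motors) > 0) {
    utils::write.table(fmt(state$motors), side("motors"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    utils::write.table(fmt(state$species), side("species"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_state_table
#' @param boundary,eta,time,step,seed State fields not stored in the table.
#' @export
read_state_table <- function(path, boundary = boundary_free(), eta = 0.01,
                             time = 0, step = 0, seed = 1) {
  read_tsv_full <- function(p) {
    tibble::as_tibble(utils::read.table(p, header = TRUE, sep = "\t",
                                        stringsAsFactors = FALSE))
  }
  fil <- read_tsv_full(path)
  fil$id <- as.integer(fil$id)
  for (c_ in c("ix", "iy", "iz")) fil[[c_]] <- as.integer(fil[[c_]])
  side <- function(suffix) sub("(\\.[^.]*)?$", paste0("_", suffix, "\\1"),
                               path)
  motors <- NULL
  species <- NULL
  if (file.exists(side("motors"))) {
    motors <- read_tsv_full(side("motors"))
    for (c_ in c("id", "species", "fil_a", "fil_b")) {
      motors[[c_]] <- as.integer(motors[[c_]])
    }
    for (c_ in c("s_a", "s_b")) motors[[c_]] <- as.numeric(motors[[c_]])
    species <- read_tsv_full(side("species"))
    for (c_ in c("dir_a", "dir_b")) species[[c_]] <- as.integer(species[[c_]])
  }
  system_state(fil, motors, species, boundary = boundary, eta = eta,
               time = time, step = step, seed = seed)
}

#' Save / load a trajectory container
#'
#' Trajectories are structured binary containers (R serialization, version
#' 3) holding the frame list, the per-step solver log, and the static
#' filament/species/boundary tables. Use the `frames_tsv` output option or
#' [tidy()] for a plain-text view.
#'
#' @param trajectory An `fm_trajectory`.
#' @param path File path (conventionally `.rds`).
#' @export
write_trajectory <- function(trajectory, path) {
  saveRDS(trajectory, path)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  x <- readRDS(path)
  if (!inherits(x, "fm_trajectory")) abort("file does not hold a trajectory")
  x
}
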