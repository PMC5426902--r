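#' Solver settings
#'
#' Numerical controls for the operator-split integrator.  Each splitting
#' interval `dt_diff` the local chemistry of every reactive compartment is
#' advanced by adaptive Runge-Kutta-Fehlberg integration (relative tolerance
#' `rtol`, absolute tolerance `atol`), then one implicit backward-Euler
#' diffusion step is taken (Lie splitting; Strang splitting via
#' `method = "strang"`).  Snapshots are recorded every `dt_rec`.
#'
#' @param t_end End time of the run (s).
#' @param dt_diff Splitting / diffusion time step (s, default 0.005).
#' @param dt_rec Recording interval (s, default 0.1); rounded to a multiple
#'   of `dt_diff`.
#' @param rtol,atol Reaction-step tolerances.
#' @param method `"lie"` (default) or `"strang"` splitting.
#' @return An object of class `solver_settings`.
#' @export
solver_settings <- function(t_end, dt_diff = 0.005, dt_rec = 0.1,
                            rtol = 1e-6, atol = 1e-8,
                            method = c("lie", "strang")) {
  method <- match.arg(method)
  stopifnot(t_end > 0, dt_diff > 0, rtol > 0, atol > 0)
  rec_every <- max(1L, as.integer(round(dt_rec / dt_diff)))
  dt_rec <- rec_every * dt_diff
  structure(list(t_end = t_end, dt_diff = dt_diff, dt_rec = dt_rec,
                 rtol = rtol, atol = atol, method = method),
            class = "solver_settings")
}

# assemble the compiled-core chemistry descriptor for an abstract model
abstract_chem <- function(model) {
  list(family = FAMILY_CODES[[model$family]],
       par = unname(model$params),
       ca_decay = model$ca_decay,
       ca_species = 2L)  # 0-based index of Ca
}

abstract_state0 <- function(model, n) {
  rbind(A = rep(model$rest[["A"]], n),
        B = rep(model$rest[["B"]], n),
        Ca = rep(0, n))
}

stim_list <- function(stimulus) {
  if (is.null(stimulus)) return(list())
  lapply(seq_along(stimulus$sites), function(i) list(
    site = as.integer(stimulus$sites[i] - 1L),
    species = 2L,
    phase = stimulus$phases[i],
    width = stimulus$width,
    amp = stimulus$amplitude,
    krelax = stimulus$krelax,
    kind = 0L))
}

#' Run a reaction-diffusion simulation
#'
#' Integrates an abstract chemistry model (or a mass-action model built with
#' [build_spiny_model()]) under a sequence stimulus, alternating adaptive
#' local reaction integration with implicit diffusion.  Ca input is injected
#' at the stimulus sites as a fast relaxation toward the commanded Gaussian
#' profile, and decays and diffuses everywhere.  The run is deterministic:
#' identical inputs give identical outputs.
#'
#' @param model A `chem_model` from [abstract_model()] or a `spiny_model`
#'   from [build_spiny_model()].
#' @param stimulus A `seq_stimulus` from [build_protocol()] (abstract
#'   models), or a list of stimulus events from [psd_ca_stimulus()] (spiny
#'   models); `NULL` for an unstimulated run.
#' @param grid A [grid1d()]; defaults to the stimulus' grid (abstract
#'   models).  Ignored for spiny models, which carry their own geometry.
#' @param settings A [solver_settings()]; defaults to
#'   `solver_settings(t_end = last phase + 10)` for abstract models.
#' @return An object of class `rd_trajectory`: `times` (s), `data` (array
#'   `[snapshot, species, compartment]`), `species`, `final`, `n_clamped`
#'   (count of negativity clamps), plus the inputs as metadata.
#' @examples
#' m <- abstract_model("switch")
#' stim <- build_protocol(0:4, spacing = 4, interval = 2, amplitude = 1)
#' traj <- simulate(m, stim, settings = solver_settings(t_end = 12))
#' dim(traj$data)
#' @export
simulate <- function(model, stimulus = NULL, grid = NULL, settings = NULL) {
  if (inherits(model, "spiny_model"))
    return(simulate_spiny(model, stimulus, settings))
  stopifnot(inherits(model, "chem_model"))
  if (is.null(grid)) {
    if (!is.null(stimulus)) grid <- attr(stimulus, "grid")
    if (is.null(grid)) grid <- grid1d()
  }
  if (is.null(settings)) {
    t_end <- if (is.null(stimulus)) 10 else max(stimulus$phases) + 10
    settings <- solver_settings(t_end = t_end)
  }
  if (!is.null(stimulus) &&
      any(stimulus$sites < 1 | stimulus$sites > grid$n_compartments))
    stop("stimulus sites lie outside the grid")
  tree <- chain_tree(grid)
  state0 <- abstract_state0(model, grid$n_compartments)
  res <- cpp_run(state0, abstract_chem(model),
                 c(model$D_A, model$D_B, model$D_Ca),
                 as.integer(tree$parent), tree$gfac, tree$vol,
                 grid$reactive_mask, c(FALSE, FALSE, TRUE),
                 stim_list(stimulus),
                 settings$dt_diff, settings$dt_rec, settings$t_end,
                 settings$rtol, settings$atol,
                 settings$method == "strang")
  new_trajectory(res, species = c("A", "B", "Ca"), model = model,
                 stimulus = stimulus, grid = grid, settings = settings)
}

#' Point-model (well-mixed) response to impulse or step input
#'
#' Runs a single-compartment, non-spatial version of an abstract model under
#' either a Gaussian impulse or a sustained step of Ca input.  This is the
#' protocol used to characterise the temporal signature of each chemistry:
#' all four families give a large impulse response; under a step, FHN
#' oscillates, the feedforward-inhibition and switch models respond only
#' transiently, and the negative-feedback model shows a strong transient
#' followed by a shallow sustained plateau.
#'
#' @param model A `chem_model`.
#' @param input `"impulse"` (Gaussian pulse) or `"step"` (held input).
#' @param amplitude Input amplitude; defaults to the model's point-protocol
#'   reference amplitude.
#' @param width Gaussian sigma (s) for the impulse (default 1 s).
#' @param onset Input onset/centre time (s).
#' @param t_end Run end time (s).
#' @param settings Optional [solver_settings()] override.
#' @return An `rd_trajectory` with a single compartment.
#' @export
point_response <- function(model, input = c("impulse", "step"),
                           amplitude = NULL, width = 1, onset = 2,
                           t_end = 40, settings = NULL) {
  input <- match.arg(input)
  stopifnot(inherits(model, "chem_model"))
  if (is.null(amplitude)) amplitude <- model$point_amplitude
  if (is.null(settings)) settings <- solver_settings(t_end = t_end)
  g <- grid1d(1, 1)
  ev <- list(site = 0L, species = 2L, phase = onset,
             width = if (input == "impulse") width else settings$t_end,
             amp = amplitude, krelax = 50,
             kind = if (input == "impulse") 0L else 1L)
  res <- cpp_run(abstract_state0(model, 1L), abstract_chem(model),
                 c(0, 0, 0), -1L, 0, 1, TRUE, c(FALSE, FALSE, TRUE),
                 list(ev), settings$dt_diff, settings$dt_rec, settings$t_end,
                 settings$rtol, settings$atol, settings$method == "strang")
  new_trajectory(res, species = c("A", "B", "Ca"), model = model,
                 stimulus = NULL, grid = g, settings = settings)
}

new_trajectory <- function(res, species, model, stimulus, grid, settings) {
  n_rec <- length(res$times)
  data <- array(res$traj, dim = c(n_rec, length(species),
                                  length(res$traj) / (n_rec * length(species))),
                dimnames = list(NULL, species, NULL))
  structure(list(times = res$times, data = data, species = species,
                 final = res$final, n_clamped = res$n_clamped,
                 model = model, stimulus = stimulus, grid = grid,
                 settings = settings),
            class = "rd_trajectory")
}

#' @export
print.rd_trajectory <- function(x, ...) {
  cat(sprintf("<rd_trajectory> %d snapshots x %d species x %d compartments; t in [0, %g] s\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              max(x$times)))
  if (x$n_clamped > 0)
    cat(sprintf("  note: %d negativity clamps during integration\n",
                x$n_clamped))
  invisible(x)
}

#' Single implicit diffusion step
#'
#' Advances a state matrix by one backward-Euler diffusion step with
#' zero-flux boundaries.  Species with zero diffusion constant are unchanged;
#' the total amount of each species is conserved.
#'
#' @param state Matrix `[species, compartment]`.
#' @param D Diffusion constant per species (um^2/s).
#' @param dt Time step (s).
#' @param grid A [grid1d()].
#' @return The advanced state matrix.
#' @export
diffuse_step <- function(state, D, dt, grid) {
  stopifnot(is.matrix(state), dt > 0, all(D >= 0),
            ncol(state) == grid$n_compartments, length(D) == nrow(state))
  tree <- chain_tree(grid)
  cpp_diffuse_step(state, D, dt, as.integer(tree$parent), tree$gfac, tree$vol)
}

#' Single adaptive reaction step
#'
#' Advances each reactive compartment independently by adaptive local
#' integration of the model chemistry over `dt`.  Compartments outside the
#' reactive mask are unchanged, except that Ca input deposition and decay
#' still apply.
#'
#' @inheritParams diffuse_step
#' @param model A `chem_model`.
#' @param t Start time of the step (s, default 0); the stimulus profile is
#'   evaluated at absolute time.
#' @param stimulus Optional `seq_stimulus`.
#' @param rtol,atol Tolerances.
#' @return The advanced state matrix.
#' @export
react_step <- function(state, model, dt, grid, t = 0, stimulus = NULL,
                       rtol = 1e-6, atol = 1e-8) {
  stopifnot(is.matrix(state), dt > 0, inherits(model, "chem_model"),
            ncol(state) == grid$n_compartments)
  tree <- chain_tree(grid)
  res <- cpp_react_step(state, abstract_chem(model),
                        c(model$D_A, model$D_B, model$D_Ca),
                        as.integer(tree$parent), tree$gfac, tree$vol,
                        grid$reactive_mask, c(FALSE, FALSE, TRUE),
                        stim_list(stimulus), t, dt, rtol, atol)
  res$state
}

#' Write a trajectory to CSV with a JSON metadata sidecar
#'
#' Long format: `time, compartment, species, value`.  The run configuration
#' (model, grid, stimulus, solver settings, package version) is written next
#' to it as `<path>.json`.  If the `arrow` package is available a
#' column-compressed Parquet container can be written instead
#' (`format = "parquet"`) for large sweeps.
#'
#' @param trajectory An `rd_trajectory`.
#' @param path Output file path.
#' @param format `"csv"` (default) or `"parquet"`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path, format = c("csv", "parquet")) {
  format <- match.arg(format)
  x <- trajectory
  d <- dim(x$data)
  df <- data.frame(
    time = rep(x$times, times = d[2] * d[3]),
    species = rep(rep(x$species, each = d[1]), times = d[3]),
    compartment = rep(seq_len(d[3]), each = d[1] * d[2]),
    value = as.vector(x$data))
  if (format == "parquet") {
    if (!requireNamespace("arrow", quietly = TRUE))
      stop("the 'arrow' package is required for parquet output")
    arrow::write_parquet(df, path)
  } else {
    utils::write.csv(df, path, row.names = FALSE)
  }
  meta <- list(
    package_version = as.character(utils::packageVersion("dendroseq")),
    species = x$species, n_clamped = x$n_clamped,
    model = trajectory_model_meta(x$model),
    stimulus = if (!is.null(x$stimulus) && inherits(x$stimulus, "seq_stimulus"))
      x$stimulus[c("order", "spacing", "interval", "width", "amplitude",
                   "onset")] else NULL,
    grid = if (!is.null(x$grid)) x$grid[c("n_compartments", "dx",
                                          "total_length")] else NULL,
    settings = unclass(x$settings))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

trajectory_model_meta <- function(model) {
  if (inherits(model, "chem_model"))
    list(family = model$family, params = as.list(model$params),
         D_A = model$D_A, D_B = model$D_B, D_Ca = model$D_Ca,
         registry_version = model$registry_version)
  else if (inherits(model, "spiny_model"))
    list(family = "massaction", n_species = length(model$network$species),
         n_compartments = nrow(model$geometry$nodes))
  else NULL
}
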