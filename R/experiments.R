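#' Default sweep grids
#'
#' Interval and spacing grids bracketing the selective ranges of the
#' calibrated models (0.5-4 s between stimuli, 2-6 um between stimuli), plus
#' a coarser 6 x 6 grid used for scaled-down structural tests.
#'
#' @name sweep_grids
#' @return Numeric vectors of intervals (s) or spacings (um).
#' @export
default_intervals <- function() c(0.5, 1, 1.5, 2, 2.5, 3, 4, 5)

#' @rdname sweep_grids
#' @export
default_spacings <- function() c(1, 2, 3, 4, 5, 6, 8, 10)

#' @rdname sweep_grids
#' @export
coarse_intervals <- function() c(1, 1.5, 2, 2.5, 3, 4)

#' @rdname sweep_grids
#' @export
coarse_spacings <- function() c(2, 3, 4, 5, 6, 8)

run_one_order <- function(model, order, spacing, interval, amplitude, width,
                          grid, settings, readout = "A", krelax = 20,
                          onset = 1, tail = 10, dt_diff = 0.005) {
  stim <- build_protocol(order, spacing, interval, width = width,
                         amplitude = amplitude, grid = grid, krelax = krelax,
                         onset = onset)
  if (is.null(settings))
    settings <- solver_settings(t_end = max(stim$phases) + tail,
                                dt_diff = dt_diff,
                                dt_rec = max(0.1, dt_diff))
  traj <- simulate(model, stim, settings = settings)
  a_total(traj, stim, readout = readout)
}

#' Q-vs-Atot scatter experiment
#'
#' Runs one simulation per stimulus order in the chosen permutation protocol
#' at a fixed (interval, spacing) operating point, and tabulates the
#' sequence-order metric Q and the total activity Atot for each order.  The
#' sequential order and the reference scrambled order `[2,1,4,3,0]` are
#' flagged.
#'
#' @param model A `chem_model`.
#' @param spacing Site spacing (um); default: the model's tuned spacing.
#' @param interval Stimulus interval (s); default: the model's tuned
#'   interval.
#' @param protocol `"subsample"` (12 orders, default) or `"full"` (120).
#' @param amplitude,width Stimulus amplitude and Gaussian sigma; default:
#'   the model's calibrated values.
#' @param grid Simulation grid (default 100 x 1 um).
#' @param settings Optional [solver_settings()]; default ends 10 s after the
#'   last pulse.
#' @param krelax Stimulus relaxation rate (1/s) passed to
#'   [build_protocol()]; co-scaled with the chemistry in
#'   [rate_scaling_experiment()].
#' @param onset First pulse time (s, default 1).
#' @param tail Recording continues `tail` seconds past the last pulse
#'   (default 10 s); together with `onset` and `dt_diff` this is part of
#'   the measurement protocol and co-scales with the chemistry under rate
#'   scaling.
#' @param dt_diff Splitting time step (s) when `settings` is `NULL`.
#' @return A data.frame with columns `order`, `Q`, `Atot`, `is_sequential`,
#'   `is_reference_scrambled`, plus the operating point as attributes.
#' @export
scatter_experiment <- function(model, spacing = NULL, interval = NULL,
                               protocol = c("subsample", "full"),
                               amplitude = NULL, width = NULL,
                               grid = grid1d(), settings = NULL,
                               krelax = 20, onset = 1, tail = 10,
                               dt_diff = 0.005) {
  protocol <- match.arg(protocol)
  stopifnot(inherits(model, "chem_model"))
  if (is.null(spacing)) spacing <- model$tuned[["spacing"]]
  if (is.null(interval)) interval <- model$tuned[["interval"]]
  if (is.null(amplitude)) amplitude <- model$amplitude
  if (is.null(width)) width <- model$sequence_width
  orders <- if (protocol == "full") all_permutations(5)
            else permutation_subsample(5, 10)
  atot <- vapply(orders, function(o) {
    v <- try(run_one_order(model, o, spacing, interval, amplitude, width,
                           grid, settings, krelax = krelax, onset = onset,
                           tail = tail, dt_diff = dt_diff), silent = TRUE)
    if (inherits(v, "try-error"))
      stop(sprintf("simulation failed for order [%s]: %s",
                   paste(o, collapse = ","), attr(v, "condition")$message))
    v
  }, numeric(1))
  keys <- vapply(orders, order_key, character(1))
  out <- data.frame(
    order = keys,
    Q = vapply(orders, function(o) q_score(o)$Q, numeric(1)),
    Atot = atot,
    is_sequential = keys == "0-1-2-3-4",
    is_reference_scrambled = keys == "2-1-4-3-0")
  attr(out, "spacing") <- spacing
  attr(out, "interval") <- interval
  attr(out, "model") <- model$family
  attr(out, "protocol") <- protocol
  out
}

#' Space-by-time selectivity matrix
#'
#' Computes the selectivity statistic on a grid of stimulus intervals and
#' spacings: each cell runs a [scatter_experiment()] and evaluates
#' selectivity over its per-order Atot values.  Cells whose selectivity is
#' undefined (all responses zero) are recorded as `NA`, not 0.
#'
#' @inheritParams scatter_experiment
#' @param intervals Interval grid (s), strictly increasing.
#' @param spacings Spacing grid (um), strictly increasing.
#' @return An object of class `selectivity_matrix`: a numeric matrix
#'   (rows = intervals, columns = spacings) with the grids, the model id,
#'   and the total stimulus-zone lengths (`4 * spacing + 1` um patch width)
#'   as attributes.
#' @export
selectivity_matrix <- function(model, intervals = default_intervals(),
                               spacings = default_spacings(),
                               protocol = c("subsample", "full"),
                               amplitude = NULL, width = NULL,
                               grid = grid1d(), settings = NULL,
                               krelax = 20, onset = 1, tail = 10,
                               dt_diff = 0.005) {
  protocol <- match.arg(protocol)
  check_grid_axis(intervals); check_grid_axis(spacings)
  M <- matrix(NA_real_, length(intervals), length(spacings),
              dimnames = list(interval = intervals, spacing = spacings))
  for (i in seq_along(intervals)) {
    for (j in seq_along(spacings)) {
      tab <- scatter_experiment(model, spacings[j], intervals[i], protocol,
                                amplitude, width, grid, settings, krelax,
                                onset, tail, dt_diff)
      s <- withCallingHandlers(
        selectivity(stats::setNames(tab$Atot, tab$order)),
        warning = function(w) invokeRestart("muffleWarning"))
      M[i, j] <- s$selectivity
    }
  }
  structure(M, class = c("selectivity_matrix", "matrix"),
            intervals = intervals, spacings = spacings,
            zone_length = 4 * spacings + 1,
            model = model$family, protocol = protocol)
}

check_grid_axis <- function(x) {
  if (length(x) == 0 || any(x <= 0) || any(diff(x) <= 0))
    stop(sprintf("%s must be non-empty, positive, strictly increasing",
                 deparse(substitute(x))))
}

#' @export
print.selectivity_matrix <- function(x, ...) {
  cat(sprintf("<selectivity_matrix> %s model, %s protocol (rows: interval s, cols: spacing um)\n",
              attr(x, "model"), attr(x, "protocol")))
  print(round(unclass(x), 3))
  invisible(x)
}

#' Argmax cell of a selectivity matrix
#'
#' Ties are broken toward the smaller interval, then the smaller spacing.
#'
#' @param M A `selectivity_matrix`.
#' @return Named vector `c(interval, spacing, selectivity)`.
#' @export
preferred_cell <- function(M) {
  iv <- attr(M, "intervals"); sp <- attr(M, "spacings")
  best <- max(M, na.rm = TRUE)
  hits <- which(M >= best - 1e-12, arr.ind = TRUE)
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  c(interval = iv[hits[1, 1]], spacing = sp[hits[1, 2]], selectivity = best)
}

#' High-selectivity zone of a matrix
#'
#' Cells with selectivity at least `frac` of the matrix maximum.
#'
#' @param M A `selectivity_matrix`.
#' @param frac Fraction of the maximum (default 0.6).
#' @return Data frame with columns `interval`, `spacing`, `selectivity`.
#' @export
selectivity_zone <- function(M, frac = 0.6) {
  iv <- attr(M, "intervals"); sp <- attr(M, "spacings")
  hits <- which(M >= frac * max(M, na.rm = TRUE), arr.ind = TRUE)
  data.frame(interval = iv[hits[, 1]], spacing = sp[hits[, 2]],
             selectivity = M[hits])
}

#' Rate/diffusion scaling experiment
#'
#' Scales all rate and diffusion constants of the model by each factor,
#' divides the stimulus width by the same factor, and co-scales the rest of
#' the stimulus machinery (input relaxation rate, onset, recording tail,
#' splitting step) so the transformation approximates an exact rescaling of
#' time; it then recomputes the selectivity matrix and reports the preferred
#' (argmax) cell and the
#' preferred sequence speed (spacing / interval).  Faster chemistries tune
#' to shorter time intervals at roughly the same spatial intervals, so the
#' preferred speed grows with the factor.
#'
#' @inheritParams selectivity_matrix
#' @param factors Positive scale factors (default `1:4`).
#' @return A data.frame with, per factor: the argmax cell (`interval`,
#'   `spacing`, `selectivity`; ties broken toward the smaller interval then
#'   spacing), the selectivity-weighted centroid of the high-selectivity
#'   zone (`interval_zone`, `spacing_zone`; cells above 70% of the matrix
#'   maximum -- a more stable location summary than the raw argmax when
#'   several cells are nearly tied), and the preferred sequence speed
#'   `speed = spacing_zone / interval_zone`.  The per-factor matrices are
#'   attached as attribute `matrices`.
#' @export
rate_scaling_experiment <- function(model, factors = 1:4,
                                    intervals = default_intervals(),
                                    spacings = default_spacings(),
                                    protocol = "subsample",
                                    grid = grid1d(), settings = NULL) {
  stopifnot(all(factors > 0))
  mats <- list()
  rows <- lapply(factors, function(f) {
    mf <- scale_model(model, f)
    M <- selectivity_matrix(mf, intervals, spacings, protocol,
                            width = model$sequence_width / f,
                            grid = grid, settings = settings,
                            krelax = 20 * f, onset = 1 / f, tail = 10 / f,
                            dt_diff = max(0.005 / f, 0.00125))
    mats[[as.character(f)]] <<- M
    pc <- preferred_cell(M)
    zn <- selectivity_zone(M, frac = 0.7)
    iv_z <- stats::weighted.mean(zn$interval, zn$selectivity)
    sp_z <- stats::weighted.mean(zn$spacing, zn$selectivity)
    data.frame(factor = f, interval = pc[["interval"]],
               spacing = pc[["spacing"]],
               interval_zone = iv_z, spacing_zone = sp_z,
               speed = sp_z / iv_z,
               selectivity = pc[["selectivity"]])
  })
  out <- do.call(rbind, rows)
  attr(out, "matrices") <- mats
  out
}

#' Stimulus-amplitude experiment
#'
#' Recomputes the selectivity matrix at several stimulus amplitudes
#' (specified relative to the model's calibrated basal amplitude) and
#' reports how the preferred cell shifts.  Selectivity needs the stimulus
#' strong enough to trigger the pathway but not so strong that it overrides
#' the inhibitory reactions and produces indiscriminate activation.
#'
#' @inheritParams selectivity_matrix
#' @param rel_amplitudes Amplitudes as fractions of basal (default
#'   `c(0.9, 1, 1.1)`).
#' @return A data.frame with one row per amplitude (`rel_amplitude`,
#'   `interval`, `spacing`, `selectivity`); matrices in attribute
#'   `matrices`.
#' @export
amplitude_experiment <- function(model, rel_amplitudes = c(0.9, 1, 1.1),
                                 intervals = default_intervals(),
                                 spacings = default_spacings(),
                                 protocol = "subsample",
                                 grid = grid1d(), settings = NULL) {
  stopifnot(all(rel_amplitudes > 0))
  mats <- list()
  rows <- lapply(rel_amplitudes, function(ra) {
    M <- selectivity_matrix(model, intervals, spacings, protocol,
                            amplitude = ra * model$amplitude,
                            grid = grid, settings = settings)
    mats[[as.character(ra)]] <<- M
    pc <- preferred_cell(M)
    data.frame(rel_amplitude = ra, interval = pc[["interval"]],
               spacing = pc[["spacing"]], selectivity = pc[["selectivity"]])
  })
  out <- do.call(rbind, rows)
  attr(out, "matrices") <- mats
  out
}

#' One-dimensional parameter-sensitivity sweep
#'
#' Varies a single model or stimulus parameter by multiplicative factors and
#' reports, for each factor, Asequential (the sequential-stimulus Atot),
#' mean(Atot) over the 12-order subsample protocol, and the selectivity.
#'
#' @inheritParams scatter_experiment
#' @param parameter Name of a rate constant of the model, or one of
#'   `"amplitude"`, `"width"`, `"D_A"`, `"D_B"`.
#' @param factors Multiplicative factors (default
#'   `c(0.8, 0.9, 0.95, 1, 1.05, 1.1, 1.2)`).
#' @return A data.frame with columns `factor`, `Asequential`, `mean_Atot`,
#'   `selectivity`.
#' @export
parameter_sensitivity <- function(model, parameter,
                                  factors = c(0.8, 0.9, 0.95, 1, 1.05, 1.1, 1.2),
                                  spacing = NULL, interval = NULL,
                                  grid = grid1d(), settings = NULL) {
  stopifnot(inherits(model, "chem_model"))
  valid <- c(names(model$params), "amplitude", "width", "D_A", "D_B")
  if (!parameter %in% valid)
    stop(sprintf("unknown parameter '%s'; valid: %s", parameter,
                 paste(valid, collapse = ", ")))
  if (is.null(spacing)) spacing <- model$tuned[["spacing"]]
  if (is.null(interval)) interval <- model$tuned[["interval"]]
  rows <- lapply(factors, function(f) {
    m <- model; amp <- model$amplitude; wid <- model$sequence_width
    if (parameter == "amplitude") amp <- amp * f
    else if (parameter == "width") wid <- wid * f
    else if (parameter == "D_A") m$D_A <- m$D_A * f
    else if (parameter == "D_B") m$D_B <- m$D_B * f
    else m$params[[parameter]] <- m$params[[parameter]] * f
    tab <- scatter_experiment(m, spacing, interval, "subsample",
                              amplitude = amp, width = wid, grid = grid,
                              settings = settings)
    s <- withCallingHandlers(
      selectivity(stats::setNames(tab$Atot, tab$order)),
      warning = function(w) invokeRestart("muffleWarning"))
    data.frame(factor = f, Asequential = s$Asequential,
               mean_Atot = s$mean_Atot, selectivity = s$selectivity)
  })
  out <- do.call(rbind, rows)
  attr(out, "parameter") <- parameter
  attr(out, "model") <- model$family
  out
}

#' Write a selectivity matrix as CSV with a JSON sidecar
#'
#' @param M A `selectivity_matrix`.
#' @param path Output CSV path; axis values are written as row/column
#'   labels and the metadata (model, protocol, zone lengths) as
#'   `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_selectivity_matrix <- function(M, path) {
  df <- as.data.frame(unclass(M))
  names(df) <- paste0("spacing_", attr(M, "spacings"))
  df <- cbind(interval = attr(M, "intervals"), df)
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    list(model = attr(M, "model"), protocol = attr(M, "protocol"),
         intervals_s = attr(M, "intervals"),
         spacings_um = attr(M, "spacings"),
         zone_length_um = attr(M, "zone_length"),
         package_version = as.character(utils::packageVersion("dendroseq"))),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
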