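## The four abstract two-species chemistries.  A is the readout ("activator"),
## B the inhibitory variable, Ca the input.  In every family B inhibits A.
## Rest (A0, B0) is a stationary point of the rates at Ca = 0; for FHN the
## resting values are non-zero (the classic excitable fixed point), for the
## other families they are zero.
##
## Parameter vectors are stored in a fixed order matching the compiled core:
##   negFB : k_act, k_deg, k_inh, k_ab, k_db
##   negFF : k_act, k_deg, k_inh, k_b,  k_db
##   FHN   : k_a, k_t, a, b, offset_A, offset_B
##   switch: k1a, k2a, k2b, k4a, k4b, k3a, k3b

FAMILY_CODES <- c(negFB = 1L, negFF = 2L, FHN = 3L, switch = 4L,
                  massaction = 5L)

# FHN resting point for a = 1, b = 0.8, offset_B = 0.7 (cubic root of
# v - v^3/3 = (v + 0.7)/0.8), computed once to full precision in .onLoad.
fhn_rest <- function(a = 1, b = 0.8, offset_B = 0.7, offset_A = 0) {
  f <- function(v) v - v^3 / 3 - (a * v + offset_B) / b + offset_A
  v0 <- stats::uniroot(f, c(-3, -1e-9), tol = 1e-14)$root
  c(A = v0, B = (a * v0 + offset_B) / b)
}

# Frozen calibrated defaults (registry version 1).  Amplitudes follow the
# point-model reference inputs (1, 10, 0.4, 1); sequence_amplitude and
# sequence_width are the calibrated defaults for the five-pulse protocols.
abstract_defaults <- function() {
  fr <- fhn_rest()
  list(
    negFB = list(
      params = c(k_act = 1, k_deg = 0.5, k_inh = 0.5, k_ab = 0.2, k_db = 0.1),
      D_A = 2, D_B = 2, rest = c(A = 0, B = 0),
      amplitude = 1, sequence_amplitude = 1, sequence_width = 0.3,
      tuned = c(interval = 3, spacing = 4)
    ),
    negFF = list(
      params = c(k_act = 10, k_deg = 1, k_inh = 40, k_b = 4, k_db = 0.02),
      D_A = 0.5, D_B = 0.5, rest = c(A = 0, B = 0),
      amplitude = 10, sequence_amplitude = 10, sequence_width = 0.3,
      tuned = c(interval = 2.5, spacing = 4)
    ),
    FHN = list(
      params = c(k_a = 10, k_t = 0.67, a = 1, b = 0.8,
                 offset_A = 0, offset_B = 0.7),
      D_A = 1, D_B = 1, rest = fr,
      amplitude = 0.4, sequence_amplitude = 0.4, sequence_width = 0.3,
      tuned = c(interval = 2, spacing = 2)
    ),
    switch = list(
      params = c(k1a = 0.9, k2a = 9, k2b = 0.36, k4a = 6, k4b = 0.8,
                 k3a = 0.23, k3b = 0.03),
      D_A = 5, D_B = 5, rest = c(A = 0, B = 0),
      amplitude = 1, sequence_amplitude = 1, sequence_width = 0.3,
      tuned = c(interval = 2, spacing = 4)
    )
  )
}

#' Construct an abstract chemistry model
#'
#' Returns one of the four calibrated two-species reaction schemes: negative
#' feedback (`negFB`: Ca excites A, A excites B, B inhibits A), feedforward
#' inhibition (`negFF`: Ca excites both A and a slower B, B inhibits A),
#' FitzHugh-Nagumo (`FHN`: cubic fast activator, linear slow recovery), and
#' the bistable switch with delayed inhibition (`switch`: Hill-type
#' self-activation of A, B slowly accumulates with A and multiplicatively
#' strengthens A's self-inhibition).  Concentrations are in arbitrary units.
#'
#' @param family One of `"negFB"`, `"negFF"`, `"FHN"`, `"switch"`.
#' @param params Optional named vector of rate-constant overrides.
#' @param D_A,D_B Diffusion constants of A and B (um^2/s).
#' @param D_Ca Diffusion constant of the Ca input species (um^2/s).
#' @param ca_decay First-order removal rate of the Ca input (1/s).
#' @param amplitude Default stimulus amplitude for this model.
#' @param sequence_width Default Gaussian sigma (s) for sequence pulses.
#' @return An object of class `chem_model`.
#' @examples
#' m <- abstract_model("switch")
#' switch_rates(0, 0, 0, m$params)   # resting stationarity
#' @export
abstract_model <- function(family = c("negFB", "negFF", "FHN", "switch"),
                           params = NULL, D_A = NULL, D_B = NULL, D_Ca = 5,
                           ca_decay = 4, amplitude = NULL,
                           sequence_width = NULL) {
  family <- match.arg(family)
  def <- abstract_defaults()[[family]]
  p <- def$params
  if (!is.null(params)) {
    bad <- setdiff(names(params), names(p))
    if (length(bad))
      stop(sprintf("unknown parameter(s) %s for family %s; valid: %s",
                   paste(bad, collapse = ", "), family,
                   paste(names(p), collapse = ", ")))
    p[names(params)] <- params
  }
  stopifnot(all(is.finite(p)))
  m <- structure(list(
    family = family,
    params = p,
    D_A = if (is.null(D_A)) def$D_A else D_A,
    D_B = if (is.null(D_B)) def$D_B else D_B,
    D_Ca = D_Ca,
    ca_decay = ca_decay,
    rest = def$rest,
    amplitude = if (is.null(amplitude)) def$sequence_amplitude else amplitude,
    point_amplitude = def$amplitude,
    sequence_width = if (is.null(sequence_width)) def$sequence_width
                     else sequence_width,
    tuned = def$tuned,
    registry_version = "1"
  ), class = "chem_model")
  if (m$D_A < 0 || m$D_B < 0) stop("diffusion constants must be >= 0")
  r <- chem_rates(m, m$rest[["A"]], m$rest[["B"]], 0)
  if (max(abs(r)) > 1e-8)
    stop(sprintf("(A0, B0) is not a stationary point for %s (rates %g, %g)",
                 family, r[1], r[2]))
  m
}

#' @export
print.chem_model <- function(x, ...) {
  cat(sprintf("<chem_model> %s (registry v%s)\n", x$family,
              x$registry_version))
  cat("  params:", paste(sprintf("%s=%g", names(x$params), x$params),
                         collapse = ", "), "\n")
  cat(sprintf("  D_A = %g, D_B = %g, D_Ca = %g um^2/s; rest (%g, %g); amp %g\n",
              x$D_A, x$D_B, x$D_Ca, x$rest[["A"]], x$rest[["B"]],
              x$amplitude))
  invisible(x)
}

#' Rate functions of the abstract chemistries
#'
#' Each returns `c(dA = ..., dB = ...)` (units: concentration/s) for scalar
#' `A`, `B`, `Ca` and the family's named parameter vector.  These are the
#' reference R implementations of the compiled rate laws.
#'
#' `negfb_rates`: `dA = k_act*Ca - k_deg*A - k_inh*A*B`,
#' `dB = k_ab*A - k_db*B` (A drives B; B multiplicatively inhibits A).
#'
#' @param A,B,Ca Species values (arbitrary concentration units).
#' @param params Named parameter vector (see [abstract_model()]).
#' @return Numeric `c(dA, dB)`.
#' @export
negfb_rates <- function(A, B, Ca, params) {
  p <- params
  c(dA = p[["k_act"]] * Ca - p[["k_deg"]] * A - p[["k_inh"]] * A * B,
    dB = p[["k_ab"]] * A - p[["k_db"]] * B)
}

#' @rdname negfb_rates
#' @details `negff_rates`: as `negfb_rates` but B is driven by Ca
#'   (`dB = k_b*Ca - k_db*B`), with B calibrated slower than A, giving
#'   near-perfect adaptation to sustained input.
#' @export
negff_rates <- function(A, B, Ca, params) {
  p <- params
  c(dA = p[["k_act"]] * Ca - p[["k_deg"]] * A - p[["k_inh"]] * A * B,
    dB = p[["k_b"]] * Ca - p[["k_db"]] * B)
}

#' @rdname negfb_rates
#' @details `fhn_rates`: `dA = k_a*(A - A^3/3 - B + offset_A + Ca)`,
#'   `dB = k_t*(a*A - b*B + offset_B)`.  The resting point is the classic
#'   excitable fixed point on the left branch of the cubic nullcline.
#' @export
fhn_rates <- function(A, B, Ca, params) {
  p <- params
  c(dA = p[["k_a"]] * (A - A^3 / 3 - B + p[["offset_A"]] + Ca),
    dB = p[["k_t"]] * (p[["a"]] * A - p[["b"]] * B + p[["offset_B"]]))
}

#' @rdname negfb_rates
#' @details `switch_rates`:
#'   `dA = k1a*Ca + k2a*A^2/(k2b^2 + A^2) - k4a*A*(1 + k4b*B)`,
#'   `dB = k3a*A - k3b*B`.  With B frozen at 0 the A kinetics are bistable
#'   (three nullcline roots, outer two stable); B accumulates slowly while A
#'   is high and multiplicatively strengthens A's self-inhibition, returning
#'   the switch to baseline after several seconds.
#' @export
switch_rates <- function(A, B, Ca, params) {
  p <- params
  c(dA = p[["k1a"]] * Ca + p[["k2a"]] * A^2 / (p[["k2b"]]^2 + A^2) -
         p[["k4a"]] * A * (1 + p[["k4b"]] * B),
    dB = p[["k3a"]] * A - p[["k3b"]] * B)
}

chem_rates <- function(model, A, B, Ca) {
  fn <- switch(model$family, negFB = negfb_rates, negFF = negff_rates,
               FHN = fhn_rates, switch = switch_rates)
  fn(A, B, Ca, model$params)
}

#' Scale all rates and diffusion constants of a model
#'
#' Multiplies every rate constant and both diffusion constants by `factor`,
#' leaving the resting state unchanged.  This rescales the model's intrinsic
#' timescale: the tuned stimulus interval shrinks by roughly the same factor.
#' The matching stimulus-width divisor (equal to `factor`) is attached as
#' attribute `width_divisor`: the stimulus width should be divided by it.
#'
#' Only true rate constants (units containing 1/s) are scaled; dimensionless
#' shape constants and concentration-valued constants (FHN's `a`, `b` and
#' offsets; the switch's Hill constant `k2b` and inhibition gain `k4b`) are
#' left alone.  The phase portrait -- and the resting state -- are therefore
#' unchanged and the transformation is an exact rescaling of time.
#'
#' @param model A `chem_model`.
#' @param factor Positive scale factor.
#' @return The scaled `chem_model`.
#' @export
scale_model <- function(model, factor) {
  stopifnot(inherits(model, "chem_model"))
  if (!is.numeric(factor) || length(factor) != 1 || factor <= 0)
    stop("factor must be a positive scalar")
  scaled <- switch(model$family,
    negFB = c("k_act", "k_deg", "k_inh", "k_ab", "k_db"),
    negFF = c("k_act", "k_deg", "k_inh", "k_b", "k_db"),
    FHN = c("k_a", "k_t"),
    switch = c("k1a", "k2a", "k4a", "k3a", "k3b"))
  model$params[scaled] <- model$params[scaled] * factor
  model$D_A <- model$D_A * factor
  model$D_B <- model$D_B * factor
  model$D_Ca <- model$D_Ca * factor
  model$ca_decay <- model$ca_decay * factor
  attr(model, "width_divisor") <- factor
  model
}

#' Count roots of the frozen-B A-nullcline of the switch model
#'
#' Bistability certificate: with B held at its resting value and Ca = 0, the
#' scalar A-rate of the switch model must have exactly three roots, the outer
#' two stable.  Roots are located by a dense sign scan plus bisection.
#'
#' @param model A `chem_model` of family `"switch"`.
#' @param A_max Upper end of the scanned A range.
#' @param n_scan Number of scan points.
#' @return List with `roots` (sorted) and `stable` (logical per root).
#' @export
switch_nullcline_roots <- function(model, A_max = 10, n_scan = 4000) {
  stopifnot(inherits(model, "chem_model"), model$family == "switch")
  B0 <- model$rest[["B"]]
  f <- function(A) switch_rates(A, B0, 0, model$params)[["dA"]]
  grid <- seq(0, A_max, length.out = n_scan)
  fv <- vapply(grid, f, numeric(1))
  roots <- numeric(0)
  if (abs(fv[1]) < 1e-12) roots <- c(roots, grid[1])
  for (i in seq_len(n_scan - 1)) {
    if (fv[i] == 0 && grid[i] > 0) roots <- c(roots, grid[i])
    if (fv[i] * fv[i + 1] < 0)
      roots <- c(roots, stats::uniroot(f, c(grid[i], grid[i + 1]),
                                       tol = 1e-12)$root)
  }
  roots <- sort(unique(round(roots, 10)))
  eps <- 1e-6
  stable <- vapply(roots, function(r) f(r + eps) < 0 && f(r - eps) > 0 ||
                     (r == 0 && f(r + eps) < 0), logical(1))
  list(roots = roots, stable = stable)
}
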