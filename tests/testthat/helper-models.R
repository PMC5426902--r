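# short solver settings for fast unit runs
quick_settings <- function(t_end, dt_diff = 0.02)
  solver_settings(t_end = t_end, dt_diff = dt_diff)

# a minimal synthetic trajectory for metric tests: constant readout `value`
# at every compartment, `n_rec` snapshots at dt_rec spacing
fake_trajectory <- function(value, n_rec, dt_rec = 0.1, n_comp = 10,
                            species = "A") {
  data <- array(value, dim = c(n_rec, length(species), n_comp),
                dimnames = list(NULL, species, NULL))
  structure(list(
    times = (seq_len(n_rec) - 1) * dt_rec,
    data = data, species = species, final = NULL, n_clamped = 0,
    model = NULL, stimulus = NULL, grid = NULL,
    settings = list(dt_rec = dt_rec)), class = "rd_trajectory")
}

run_atot_for <- function(model, order, spacing, interval, ...) {
  stim <- build_protocol(order, spacing, interval,
                         width = model$sequence_width,
                         amplitude = model$amplitude, ...)
  traj <- simulate(model, stim,
                   settings = solver_settings(t_end = max(stim$phases) + 10))
  a_total(traj, stim)
}

atot_subsample <- function(model, spacing, interval) {
  orders <- permutation_subsample(5, 10)
  at <- vapply(orders, function(o) run_atot_for(model, o, spacing, interval),
               numeric(1))
  names(at) <- vapply(orders, function(o) paste(o, collapse = "-"),
                      character(1))
  at
}

chem_rates_for <- function(fam, m, A, B, Ca) {
  fn <- switch(fam, negFB = negfb_rates, negFF = negff_rates,
               FHN = fhn_rates, switch = switch_rates)
  fn(A, B, Ca, m$params)
}
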