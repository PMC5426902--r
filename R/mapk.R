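## Schematic mass-action MAPK switch on a spiny cylinder.
##
## The network is a minimal reconstruction of a bistable MAPK cascade with
## delayed negative feedback: Ca (buffered by CaM) activates Raf; Raf drives
## MEK phosphorylation and MEK-P doubly phosphorylates MAPK; active MAPK
## feeds back positively through PKC onto Raf, making the cascade switch-like;
## a MAPK-induced phosphatase provides slow negative feedback that returns
## the switch to baseline and suppresses closely following inputs.  Active
## PKC and Raf are non-diffusible; everything else diffuses.  Units: uM, s,
## um.  Rate constants are a frozen calibration (registry v1) against the
## qualitative pulse/step/sequence behaviours; absolute concentrations are
## not matched to any published table.

#' Spiny cylinder geometry
#'
#' A dendritic cylinder (default 60 um x 1 um) carrying spines placed by a
#' Poisson process along its length (uniform positions conditional on the
#' spine count, with a fixed default seed so the bundled geometry is
#' deterministic).  Each spine is a PSD subvolume on a cylindrical head
#' (0.5 um length and diameter) on a cylindrical shaft (1 um x 0.2 um)
#' attached to one dendrite compartment.  Five spines, spaced approximately
#' `stim_spacing` apart around the cylinder midpoint, are flagged as the
#' stimulated spines.
#'
#' @param dend_length,dend_diam Dendrite dimensions (um).
#' @param dx Dendrite compartment length (um).
#' @param n_spines Number of spines (default 49).
#' @param n_stim Number of stimulated spines (default 5).
#' @param stim_spacing Target spacing of stimulated spines (um, default 3).
#' @param seed Seed for spine placement (model constant; default 20170419).
#' @return An object of class `spiny_cylinder`: `nodes` (data.frame with
#'   type, spine id, position, volume, coupling factor, parent), stimulated
#'   spine ids, their PSD node and dendrite compartment indices, and the
#'   realised spine spacing.
#' @export
spiny_cylinder <- function(dend_length = 60, dend_diam = 1, dx = 1,
                           n_spines = 49, n_stim = 5, stim_spacing = 3,
                           seed = 20170419L) {
  stopifnot(dend_length > 0, dx > 0, n_spines >= n_stim)
  n_dend <- as.integer(round(dend_length / dx))
  pos <- withr_seed(seed, function() sort(stats::runif(n_spines, 0, dend_length)))
  dend_of_spine <- pmin(pmax(1L, ceiling(pos / dx)), n_dend)

  # node order: (psd, head, shaft) per spine, then the dendrite chain; this
  # guarantees children precede parents for the tree solver
  n_spine_nodes <- 3L * n_spines
  n_nodes <- n_spine_nodes + n_dend
  type <- c(rep(c("psd", "head", "shaft"), n_spines), rep("dendrite", n_dend))
  spine <- c(rep(seq_len(n_spines), each = 3), rep(NA_integer_, n_dend))
  node_pos <- c(rep(pos, each = 3), (seq_len(n_dend) - 0.5) * dx)

  a_dend <- pi / 4 * dend_diam^2
  a_shaft <- pi / 4 * 0.2^2
  a_head <- pi / 4 * 0.5^2
  vol <- c(rep(c(0.1 * a_head,            # psd: 0.1 um slab of the head
                 0.5 * a_head,            # head: 0.5 um x 0.5 um cylinder
                 1.0 * a_shaft),          # shaft: 1 um x 0.2 um cylinder
               n_spines),
           rep(dx * a_dend, n_dend))

  parent <- integer(n_nodes)
  gfac <- numeric(n_nodes)
  for (k in seq_len(n_spines)) {
    i_psd <- 3L * (k - 1L) + 1L
    parent[i_psd] <- i_psd + 1L;  gfac[i_psd] <- a_head / 0.3
    parent[i_psd + 1L] <- i_psd + 2L;  gfac[i_psd + 1L] <- a_shaft / 0.75
    parent[i_psd + 2L] <- n_spine_nodes + dend_of_spine[k]
    gfac[i_psd + 2L] <- a_shaft / 1.0
  }
  for (j in seq_len(n_dend - 1L)) {
    parent[n_spine_nodes + j] <- n_spine_nodes + j + 1L
    gfac[n_spine_nodes + j] <- a_dend / dx
  }
  parent[n_nodes] <- 0L  # root (stored 1-based; 0 = none)

  # stimulated spines: nearest spine to each target position, targets centred
  targets <- dend_length / 2 + (seq_len(n_stim) - (n_stim + 1) / 2) * stim_spacing
  stim <- integer(n_stim)
  avail <- seq_len(n_spines)
  for (i in seq_len(n_stim)) {
    j <- avail[which.min(abs(pos[avail] - targets[i]))]
    stim[i] <- j
    avail <- setdiff(avail, j)
  }
  stim <- sort(stim)

  structure(list(
    nodes = data.frame(type = type, spine = spine, pos = node_pos,
                       vol = vol, gfac = gfac, parent = parent),
    n_dend = n_dend, dx = dx, dend_length = dend_length,
    n_spines = n_spines, spine_pos = pos,
    mean_spacing = dend_length / n_spines,
    stim_spines = stim,
    psd_nodes = 3L * (stim - 1L) + 1L,
    dend_sites = n_spine_nodes + dend_of_spine[stim],
    seed = seed
  ), class = "spiny_cylinder")
}

withr_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' @export
print.spiny_cylinder <- function(x, ...) {
  cat(sprintf("<spiny_cylinder> %g um x dendrite, %d compartments, %d spines (mean spacing %.2f um)\n",
              x$dend_length, x$n_dend, x$n_spines, x$mean_spacing))
  cat("  stimulated spines:", paste(x$stim_spines, collapse = ", "),
      "at", paste(round(x$spine_pos[x$stim_spines], 1), collapse = ", "), "um\n")
  invisible(x)
}

#' Schematic MAPK switch reaction network
#'
#' Species (uM) and reactions of the mass-action MAPK switch with delayed
#' phosphatase feedback.  Reaction types: reversible mass-action (`kf`,
#' `kb`; empty reactant side = zero-order source) and irreversible
#' Michaelis-Menten enzyme steps (`kcat`, `Km`; the enzyme is a modifier and
#' is not consumed).  Active PKC and Raf (both forms) have zero diffusion
#' constants; all other species are diffusible.
#'
#' @param params Optional named overrides of the frozen rate constants (see
#'   [mapk_default_rates()] for names and values).
#' @return An object of class `mapk_network` with `species` (data.frame:
#'   name, nominal resting value, D, non-negativity flag), `reactions`
#'   (list of reaction descriptors), and the rate-constant set in `params`.
#' @export
mapk_network <- function(params = NULL) {
  p <- mapk_default_rates()
  if (!is.null(params)) {
    bad <- setdiff(names(params), names(p))
    if (length(bad))
      stop(sprintf("unknown rate constant(s): %s; valid: %s",
                   paste(bad, collapse = ", "),
                   paste(names(p), collapse = ", ")))
    p[names(params)] <- params
  }
  species <- data.frame(
    name = c("Ca", "CaM", "CaMCa", "Raf", "Raf_a", "MEK", "MEK_p",
             "MAPK", "MAPK_p", "MAPK_pp", "PKC", "PKC_a", "Phos", "Phos_a",
             "MKP", "PP2A"),
    rest = c(0.08, 10, 0, 0.5, 0, 0.8, 0, 1.2, 0, 0, 0.5, 0, 0.5, 0, 1, 1),
    D    = c(20, 4, 4, 0, 0, 1, 1, 1, 1, 1, 1, 0, 3, 3, 1, 1),
    stringsAsFactors = FALSE)
  km <- p[["Km"]]
  rx <- list(
    list(kind = "ma", name = "ca_turnover", sub = character(0), prod = "Ca",
         kf = 0.08 * p[["k_ca_pump"]], kb = p[["k_ca_pump"]]),
    list(kind = "ma", name = "cam_buffer", sub = c("CaM", "Ca"),
         prod = "CaMCa", kf = p[["cam_kf"]], kb = p[["cam_kb"]]),
    list(kind = "ma", name = "raf_act_ca", sub = c("Raf", "Ca"),
         prod = c("Raf_a", "Ca"), kf = p[["kf_raf"]], kb = 0),
    list(kind = "ma", name = "raf_inact", sub = "Raf_a", prod = "Raf",
         kf = p[["k_raf_off"]], kb = 0),
    list(kind = "enz", name = "raf_act_pkc", enz = "PKC_a", sub = "Raf",
         prod = "Raf_a", kcat = p[["kcat_pkc_raf"]], km = km),
    list(kind = "enz", name = "mek_phos", enz = "Raf_a", sub = "MEK",
         prod = "MEK_p", kcat = p[["kcat_mek"]], km = km),
    list(kind = "enz", name = "mek_dephos", enz = "PP2A", sub = "MEK_p",
         prod = "MEK", kcat = p[["kcat_pp2a"]], km = km),
    list(kind = "enz", name = "mapk_phos1", enz = "MEK_p", sub = "MAPK",
         prod = "MAPK_p", kcat = p[["kcat_mapk"]], km = km),
    list(kind = "enz", name = "mapk_phos2", enz = "MEK_p", sub = "MAPK_p",
         prod = "MAPK_pp", kcat = p[["kcat_mapk"]], km = km),
    list(kind = "enz", name = "mapk_dephos2_basal", enz = "MKP",
         sub = "MAPK_pp", prod = "MAPK_p", kcat = p[["kcat_mkp"]], km = km),
    list(kind = "enz", name = "mapk_dephos1_basal", enz = "MKP",
         sub = "MAPK_p", prod = "MAPK", kcat = p[["kcat_mkp"]], km = km),
    list(kind = "enz", name = "pkc_act", enz = "MAPK_pp", sub = "PKC",
         prod = "PKC_a", kcat = p[["kcat_pkc"]], km = km),
    list(kind = "ma", name = "pkc_inact", sub = "PKC_a", prod = "PKC",
         kf = p[["k_pkc_off"]], kb = 0),
    list(kind = "enz", name = "phos_induction", enz = "MAPK_pp",
         sub = "Phos", prod = "Phos_a", kcat = p[["kcat_phos"]], km = km),
    list(kind = "ma", name = "phos_recovery", sub = "Phos_a", prod = "Phos",
         kf = p[["k_phos_off"]], kb = 0),
    list(kind = "enz", name = "mek_dephos_fb", enz = "Phos_a",
         sub = "MEK_p", prod = "MEK", kcat = p[["kcat_fbm"]], km = km),
    list(kind = "enz", name = "mapk_dephos2_fb", enz = "Phos_a",
         sub = "MAPK_pp", prod = "MAPK_p", kcat = p[["kcat_fb"]], km = km),
    list(kind = "enz", name = "mapk_dephos1_fb", enz = "Phos_a",
         sub = "MAPK_p", prod = "MAPK", kcat = p[["kcat_fb"]], km = km)
  )
  structure(list(species = species, reactions = rx, params = p,
                 registry_version = "1"),
            class = "mapk_network")
}

#' Frozen rate constants of the MAPK switch (registry v1)
#'
#' Units: 1/s for first-order constants, 1/(uM s) for second-order, uM for
#' `Km`.  Values are a frozen behavioural calibration (see the package
#' vignette); they are not taken from any published rate table.
#'
#' @return Named numeric vector.
#' @export
mapk_default_rates <- function() {
  c(k_ca_pump = 7,      # dendritic Ca clearance
    cam_kf = 1, cam_kb = 2,     # CaM buffering (Kd 2 uM)
    kf_raf = 0.15,      # Ca activation of Raf (the pathway input)
    k_raf_off = 0.4,
    kcat_pkc_raf = 0.5, # positive-feedback arm PKC* -> Raf
    kcat_mek = 6, kcat_pp2a = 0.8,
    kcat_mapk = 6, kcat_mkp = 0.9,
    kcat_pkc = 2, k_pkc_off = 1,
    kcat_phos = 0.1, k_phos_off = 0.004,   # slow induction / recovery
    kcat_fbm = 5,       # induced-phosphatase activity on MEK-P
    kcat_fb = 5,        # induced-phosphatase activity on MAPK
    Km = 0.1)
}

#' @export
print.mapk_network <- function(x, ...) {
  cat(sprintf("<mapk_network> %d species, %d reactions (registry v%s)\n",
              nrow(x$species), length(x$reactions), x$registry_version))
  invisible(x)
}

# flatten the network to the 0-based index form used by the compiled core
flatten_network <- function(network) {
  sp <- network$species$name
  idx <- function(nm) {
    i <- match(nm, sp)
    if (anyNA(i)) stop("unknown species: ", paste(nm[is.na(i)], collapse = ", "))
    i - 1L
  }
  ma <- Filter(function(r) r$kind == "ma", network$reactions)
  en <- Filter(function(r) r$kind == "enz", network$reactions)
  sub <- integer(0); prod <- integer(0)
  sub_ptr <- 0L; prod_ptr <- 0L
  for (r in ma) {
    sub <- c(sub, idx(r$sub)); prod <- c(prod, idx(r$prod))
    sub_ptr <- c(sub_ptr, length(sub)); prod_ptr <- c(prod_ptr, length(prod))
  }
  list(sub = as.integer(sub), prod = as.integer(prod),
       sub_ptr = as.integer(sub_ptr), prod_ptr = as.integer(prod_ptr),
       kf = vapply(ma, `[[`, numeric(1), "kf"),
       kb = vapply(ma, `[[`, numeric(1), "kb"),
       enz_e = as.integer(vapply(en, function(r) idx(r$enz), integer(1))),
       enz_s = as.integer(vapply(en, function(r) idx(r$sub), integer(1))),
       enz_p = as.integer(vapply(en, function(r) idx(r$prod), integer(1))),
       kcat = vapply(en, `[[`, numeric(1), "kcat"),
       km = vapply(en, `[[`, numeric(1), "km"))
}

#' Net stoichiometry matrix of a reaction network
#'
#' Rows are species, columns reactions; enzymes appear with net
#' stoichiometry zero in their catalytic steps.
#'
#' @param network A [mapk_network()].
#' @return Integer matrix `species x reactions` with dimnames.
#' @export
stoichiometry_matrix <- function(network) {
  sp <- network$species$name
  S <- matrix(0L, nrow = length(sp), ncol = length(network$reactions),
              dimnames = list(sp, vapply(network$reactions, `[[`,
                                         character(1), "name")))
  for (j in seq_along(network$reactions)) {
    r <- network$reactions[[j]]
    for (s in r$sub) S[s, j] <- S[s, j] - 1L
    for (s in r$prod) S[s, j] <- S[s, j] + 1L
  }
  S
}

#' Conserved-moiety audit
#'
#' Verifies that the declared conserved moieties of the MAPK network (total
#' Raf, MEK, MAPK, PKC, phosphatase, CaM) lie in the left null space of the
#' stoichiometry matrix, i.e. no reaction leaks any of them.
#'
#' @param network A [mapk_network()].
#' @return A list of moiety definitions (named species-weight vectors), with
#'   attribute `max_leak`: the largest absolute entry of `w' S` over all
#'   moieties (0 for a leak-free network).
#' @export
moiety_audit <- function(network) {
  S <- stoichiometry_matrix(network)
  sp <- network$species$name
  moieties <- list(
    Raf_total = c(Raf = 1, Raf_a = 1),
    MEK_total = c(MEK = 1, MEK_p = 1),
    MAPK_total = c(MAPK = 1, MAPK_p = 1, MAPK_pp = 1),
    PKC_total = c(PKC = 1, PKC_a = 1),
    Phos_total = c(Phos = 1, Phos_a = 1),
    CaM_total = c(CaM = 1, CaMCa = 1))
  leak <- 0
  for (m in moieties) {
    w <- stats::setNames(numeric(length(sp)), sp)
    w[names(m)] <- m
    leak <- max(leak, max(abs(w %*% S)))
  }
  attr(moieties, "max_leak") <- leak
  moieties
}

#' Assemble a runnable spiny-cylinder MAPK model
#'
#' Combines a geometry and a network into a model usable by [simulate()].
#' The chemistry runs in every compartment; the chemical resting state is
#' found by relaxing the full spatial model for `settle` seconds with no
#' stimulus, so an unstimulated run stays at rest.
#'
#' @param geometry A [spiny_cylinder()].
#' @param network A [mapk_network()].
#' @param settle Settling time (s) for the resting-state computation.
#' @return An object of class `spiny_model`.
#' @export
build_spiny_model <- function(geometry = spiny_cylinder(),
                              network = mapk_network(), settle = 400) {
  stopifnot(inherits(geometry, "spiny_cylinder"),
            inherits(network, "mapk_network"))
  aud <- moiety_audit(network)
  if (attr(aud, "max_leak") != 0)
    stop("network fails the moiety-conservation audit")
  p <- geometry$nodes$parent
  if (sum(p == 0L) != 1L || any(p[p != 0L] <= seq_along(p)[p != 0L]))
    stop("geometry is not a rooted tree with children before parents")
  net <- flatten_network(network)
  ns <- nrow(network$species)
  chem <- list(family = FAMILY_CODES[["massaction"]], network = net,
               ca_decay = 0, ca_species = match("Ca", network$species$name) - 1L)
  n <- nrow(geometry$nodes)
  state0 <- matrix(network$species$rest, nrow = ns, ncol = n)
  res <- cpp_run(state0, chem, network$species$D,
                 as.integer(geometry$nodes$parent - 1L), geometry$nodes$gfac,
                 geometry$nodes$vol, rep(TRUE, n), rep(TRUE, ns),
                 list(), 0.1, settle, settle, 1e-8, 1e-10, FALSE)
  rest_state <- res$final
  rownames(rest_state) <- network$species$name
  structure(list(
    geometry = geometry, network = network, chem = chem,
    rest_state = rest_state,
    rest = stats::setNames(rowMeans(rest_state[, geometry$nodes$type == "dendrite",
                                               drop = FALSE]),
                           network$species$name),
    D = network$species$D,
    readout = "MAPK_pp",
    registry_version = network$registry_version
  ), class = "spiny_model")
}

#' @export
print.spiny_model <- function(x, ...) {
  cat(sprintf("<spiny_model> %d species on %d compartments; readout %s\n",
              length(x$rest), nrow(x$geometry$nodes), x$readout))
  cat("  resting MAPK_pp:", signif(x$rest[["MAPK_pp"]], 3), "uM\n")
  invisible(x)
}

#' PSD calcium stimulus event
#'
#' Clamps Ca in the PSD subvolume of one stimulated spine toward
#' `amplitude` for `duration` seconds (fast first-order relaxation, rate
#' `krelax`), from which it diffuses into the spine head and dendrite and
#' is buffered by CaM.
#'
#' @param model A `spiny_model`.
#' @param spine Index into the model's stimulated spines (1..5).
#' @param amplitude Clamp level (uM, default 160).
#' @param duration Clamp duration (s, default 2.9).
#' @param onset Clamp start time (s).
#' @param krelax Relaxation rate (1/s).
#' @return A stimulus event (class `stim_event`) for [simulate()].
#' @export
psd_ca_stimulus <- function(model, spine, amplitude = 160, duration = 2.9,
                            onset = 1, krelax = 200) {
  stopifnot(inherits(model, "spiny_model"))
  g <- model$geometry
  if (!(spine %in% seq_along(g$stim_spines)))
    stop(sprintf("unknown stimulated spine %s (have 1..%d)",
                 toString(spine), length(g$stim_spines)))
  structure(list(
    site = g$psd_nodes[spine] - 1L,
    species = model$chem$ca_species,
    phase = onset, width = duration, amp = amplitude,
    krelax = krelax, kind = 1L), class = "stim_event")
}

simulate_spiny <- function(model, stimuli = NULL, settings = NULL) {
  if (is.null(settings)) settings <- solver_settings(t_end = 60)
  if (!is.null(stimuli)) {
    if (inherits(stimuli, "stim_event")) stimuli <- list(stimuli)
    stopifnot(all(vapply(stimuli, inherits, logical(1), "stim_event")))
  } else stimuli <- list()
  g <- model$geometry
  n <- nrow(g$nodes)
  state0 <- model$rest_state
  res <- cpp_run(state0, model$chem, model$D,
                 as.integer(g$nodes$parent - 1L), g$nodes$gfac, g$nodes$vol,
                 rep(TRUE, n), rep(TRUE, length(model$rest)),
                 lapply(stimuli, unclass),
                 settings$dt_diff, settings$dt_rec, settings$t_end,
                 settings$rtol, settings$atol, settings$method == "strang")
  new_trajectory(res, species = model$network$species$name, model = model,
                 stimulus = stimuli, grid = NULL, settings = settings)
}

#' Paired-pulse and step protocol on the spiny MAPK model
#'
#' Reference characterisation of the switch: two Ca pulses (1 s, 160 uM at
#' the PSD) separated by 50 s, then after a further delay a 50 s step.  The
#' first pulse triggers a full switch-like MAPK-P excursion; the second is
#' strongly suppressed by the induced phosphatase; during the sustained step
#' the response peaks and then declines.  Readout: doubly phosphorylated
#' MAPK in the dendrite compartment under the central stimulated spine.
#'
#' @param model A `spiny_model` (default: the bundled calibration).
#' @param gap Pulse separation (s, default 50).
#' @param step_delay Delay from second pulse to the step (s, default 100).
#' @param step_duration Step length (s, default 50).
#' @param pulse_duration Duration of the two pulses (s, default 1).
#' @param amplitude PSD clamp level (uM, default 800).  The
#'   characterisation protocol uses a deliberately suprathreshold pulse:
#'   in the frozen calibration an isolated 1 s, 160 uM input is below the
#'   dendritic switching threshold (that subthreshold margin of the
#'   sequence-grade input is what makes the model order-selective), so the
#'   switch demonstration drives the PSD harder.
#' @param settings Optional [solver_settings()].
#' @return List with the trajectory, the dendritic MAPK-P time course, and a
#'   summary (first/second pulse peaks, their ratio, step peak, MAPK-P at
#'   step end).
#' @export
pulse_protocol_demo <- function(model = build_spiny_model(), gap = 50,
                                step_delay = 100, step_duration = 50,
                                pulse_duration = 1, amplitude = 800,
                                settings = NULL) {
  spine <- ceiling(length(model$geometry$stim_spines) / 2)
  t1 <- 1; t2 <- t1 + gap; t3 <- t2 + step_delay
  t_end <- t3 + step_duration + 20
  if (is.null(settings))
    settings <- solver_settings(t_end = t_end, dt_diff = 0.05, dt_rec = 0.25)
  stims <- list(
    psd_ca_stimulus(model, spine, amplitude = amplitude,
                    duration = pulse_duration, onset = t1),
    psd_ca_stimulus(model, spine, amplitude = amplitude,
                    duration = pulse_duration, onset = t2),
    psd_ca_stimulus(model, spine, amplitude = amplitude,
                    duration = step_duration, onset = t3))
  traj <- simulate(model, stims, settings = settings)
  site <- model$geometry$dend_sites[spine]
  mp <- traj$data[, "MAPK_pp", site]
  tt <- traj$times
  win <- function(a, b) mp[tt >= a & tt < b]
  pk1 <- max(win(t1, t2)); pk2 <- max(win(t2, t3))
  pk3 <- max(win(t3, t3 + step_duration))
  end3 <- mp[which.min(abs(tt - (t3 + step_duration)))]
  list(trajectory = traj, times = tt, mapk_p = mp,
       summary = list(first_peak = pk1, second_peak = pk2,
                      suppression_ratio = pk1 / pk2,
                      step_peak = pk3, step_end = end3,
                      pulse_times = c(t1, t2), step_time = t3))
}

#' Sequential-stimulus demonstration on the spiny MAPK model
#'
#' Delivers the PSD Ca stimulus train (default 160 uM for 2.9 s per spine,
#' 3 s intervals) to the five stimulated spines in the given order and
#' computes the total dendritic MAPK-P response (Atot) under the stimulated
#' spines, plus peak and duration summaries.
#'
#' @param model A `spiny_model`.
#' @param order Permutation of `0:4` (spatial spine order).
#' @param interval Inter-stimulus interval (s, default 3).
#' @param amplitude,duration PSD clamp parameters.
#' @param tail Extra simulated time after the last stimulus (s).
#' @param settings Optional [solver_settings()].
#' @return List with `Atot`, `peak` (max dendritic MAPK-P), `dur_half`
#'   (total time the spatial-mean readout exceeds half its peak), the
#'   per-site readout matrix, and the trajectory.
#' @export
sequence_demo <- function(model, order = 0:4, interval = 3, amplitude = 160,
                          duration = 2.9, tail = 30, settings = NULL) {
  stopifnot(inherits(model, "spiny_model"))
  order <- check_permutation(order, 5)
  onset <- 1
  ranks <- match(0:4, order) - 1
  phases <- onset + interval * ranks
  if (is.null(settings))
    settings <- solver_settings(t_end = max(phases) + duration + tail,
                                dt_diff = 0.05, dt_rec = 0.25)
  stims <- lapply(1:5, function(k)
    psd_ca_stimulus(model, k, amplitude = amplitude, duration = duration,
                    onset = phases[k]))
  traj <- simulate(model, stims, settings = settings)
  sites <- model$geometry$dend_sites
  rest <- model$rest_state["MAPK_pp", sites]
  vals <- sweep(traj$data[, "MAPK_pp", sites], 2, rest)
  keep <- traj$times >= min(phases)
  atot <- sum(vals[keep, ]) * settings$dt_rec
  mean_tc <- rowMeans(vals)
  pk <- max(mean_tc)
  dur <- sum(mean_tc > pk / 2) * settings$dt_rec
  list(Atot = atot, peak = max(vals), dur_half = dur,
       readout = vals, times = traj$times, trajectory = traj,
       order = order, interval = interval)
}

#' 12-order sequence selectivity of the spiny MAPK model
#'
#' Runs the subsampled permutation protocol (12 orders) through
#' [sequence_demo()] and evaluates the selectivity statistic on the
#' resulting Atot values.
#'
#' @inheritParams sequence_demo
#' @return A `selectivity_result`.
#' @export
mapk_selectivity <- function(model, interval = 3, amplitude = 160,
                             duration = 2.9, tail = 30, settings = NULL) {
  orders <- permutation_subsample(5, 10)
  atot <- vapply(orders, function(o)
    sequence_demo(model, o, interval, amplitude, duration, tail,
                  settings)$Atot, numeric(1))
  names(atot) <- vapply(orders, order_key, character(1))
  selectivity(atot)
}

#' Export the MAPK network
#'
#' `reaction_table()` returns a human-readable table (reactants, products,
#' rate constants); `write_sbml()` writes a minimal SBML Level 3 document
#' (species with initial concentrations, reactions with kinetic-law
#' parameters; enzyme steps carry the enzyme as a modifier).
#'
#' @param network A [mapk_network()].
#' @return `reaction_table`: a data.frame.
#' @export
reaction_table <- function(network) {
  rows <- lapply(network$reactions, function(r) {
    if (r$kind == "ma")
      data.frame(name = r$name, type = "mass_action",
                 reactants = paste(r$sub, collapse = " + "),
                 products = paste(r$prod, collapse = " + "),
                 enzyme = "", kf = r$kf, kb = r$kb, kcat = NA, Km = NA)
    else
      data.frame(name = r$name, type = "michaelis_menten",
                 reactants = r$sub, products = r$prod, enzyme = r$enz,
                 kf = NA, kb = NA, kcat = r$kcat, Km = r$km)
  })
  do.call(rbind, rows)
}

#' @rdname reaction_table
#' @param path Output file path for the SBML document.
#' @export
write_sbml <- function(network, path) {
  xq <- function(s) gsub("&", "&amp;", s, fixed = TRUE)
  con <- file(path, "w"); on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w('<?xml version="1.0" encoding="UTF-8"?>')
  w('<sbml xmlns="http://www.sbml.org/sbml/level3/version2/core" level="3" version="2">')
  w('  <model id="mapk_switch_spiny" substanceUnits="micromole" timeUnits="second">')
  w('    <listOfCompartments><compartment id="cell" constant="true"/></listOfCompartments>')
  w('    <listOfSpecies>')
  for (i in seq_len(nrow(network$species)))
    w('      <species id="%s" compartment="cell" initialConcentration="%g" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>',
      xq(network$species$name[i]), network$species$rest[i])
  w('    </listOfSpecies>')
  w('    <listOfReactions>')
  for (r in network$reactions) {
    rev <- if (r$kind == "ma" && r$kb > 0) "true" else "false"
    w('      <reaction id="%s" reversible="%s">', xq(r$name), rev)
    if (length(r$sub)) {
      w('        <listOfReactants>')
      for (s in unique(r$sub))
        w('          <speciesReference species="%s" stoichiometry="%d" constant="true"/>',
          xq(s), sum(r$sub == s))
      w('        </listOfReactants>')
    }
    w('        <listOfProducts>')
    for (s in unique(r$prod))
      w('          <speciesReference species="%s" stoichiometry="%d" constant="true"/>',
        xq(s), sum(r$prod == s))
    w('        </listOfProducts>')
    if (r$kind == "enz") {
      w('        <listOfModifiers><modifierSpeciesReference species="%s"/></listOfModifiers>',
        xq(r$enz))
      w('        <kineticLaw><listOfLocalParameters><localParameter id="kcat" value="%g"/><localParameter id="Km" value="%g"/></listOfLocalParameters></kineticLaw>',
        r$kcat, r$km)
    } else {
      w('        <kineticLaw><listOfLocalParameters><localParameter id="kf" value="%g"/><localParameter id="kb" value="%g"/></listOfLocalParameters></kineticLaw>',
        r$kf, r$kb)
    }
    w('      </reaction>')
  }
  w('    </listOfReactions>')
  w('  </model>')
  w('</sbml>')
  invisible(path)
}
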