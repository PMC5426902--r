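#' Sequence-order metric Q
#'
#' Quantifies how ordered a stimulus sequence is.  The ordinal arrival-time
#' rank of each site is regressed (ordinary least squares) against its
#' ordinal spatial position, and Q = m * R^2 where m is the slope and R the
#' regression coefficient.  Q is +1 for the perfect forward sequence, -1 for
#' the perfect reverse, and near 0 for scrambled orders.
#'
#' @param order Integer permutation of `0:(n-1)`; `order[1]` fires first.
#' @return An object of class `q_score` with fields `order`, `m`, `R2`, `Q`.
#' @examples
#' q_score(c(0, 1, 2, 3, 4))$Q   # 1
#' q_score(c(4, 0, 2, 1, 3))$Q   # -0.001
#' @export
q_score <- function(order) {
  n <- length(order)
  if (n < 2) stop("order must have length >= 2")
  order <- check_permutation(order, n)
  pos <- seq_len(n) - 1                        # ordinal position of each site
  arrival <- match(pos, order) - 1             # ordinal arrival-time rank
  m <- stats::cov(pos, arrival) / stats::var(pos)
  r2 <- stats::cov(pos, arrival)^2 / (stats::var(pos) * stats::var(arrival))
  structure(list(order = order, m = m, R2 = r2, Q = m * r2),
            class = "q_score")
}

#' @export
print.q_score <- function(x, ...) {
  cat(sprintf("<q_score> order [%s]: m = %.3f, R2 = %.3f, Q = %.3f\n",
              paste(x$order, collapse = ","), x$m, x$R2, x$Q))
  invisible(x)
}

#' Total readout activity Atot
#'
#' Sums the readout species over the five stimulus-site compartments and over
#' all recorded snapshots from the time of the first pulse to the end of the
#' run, multiplied by the recording interval so the value is invariant to the
#' recording rate (a Riemann sum of the spatially summed time course).  The
#' resting value of the readout is subtracted so that Atot measures activity
#' above baseline (for models resting at zero this equals the raw sum).
#'
#' @param trajectory An `rd_trajectory` from [simulate()].
#' @param stimulus The `seq_stimulus` used for the run (supplies the site
#'   compartments and the first-pulse time); may be omitted if `sites` and
#'   `t_start` are given.
#' @param readout Species name to sum (default `"A"`).
#' @param sites Compartment indices to sum over (default: stimulus sites).
#' @param t_start Start of the integration window (s; default: first phase).
#' @param baseline Resting value to subtract (default: the readout's value in
#'   the first snapshot of the trajectory at the first site).
#' @return Atot (readout units x s).
#' @export
a_total <- function(trajectory, stimulus = NULL, readout = "A",
                    sites = NULL, t_start = NULL, baseline = NULL) {
  stopifnot(inherits(trajectory, "rd_trajectory"))
  if (is.null(sites)) {
    if (is.null(stimulus)) stop("supply either a stimulus or explicit sites")
    sites <- stimulus$sites
  }
  if (is.null(t_start))
    t_start <- if (!is.null(stimulus)) min(stimulus$phases) else 0
  sp <- match(readout, trajectory$species)
  if (is.na(sp))
    stop(sprintf("readout species '%s' not in trajectory (have: %s)",
                 readout, paste(trajectory$species, collapse = ", ")))
  keep <- trajectory$times >= t_start - 1e-9
  if (!any(keep)) stop("trajectory does not cover the stimulus window")
  vals <- trajectory$data[keep, sp, sites, drop = FALSE]
  if (is.null(baseline)) baseline <- trajectory$data[1, sp, sites[1]]
  dt_rec <- trajectory$settings$dt_rec
  sum(vals - baseline) * dt_rec
}

#' Sequence selectivity
#'
#' Selectivity = (Asequential - mean(Atot)) / max(Atot), where the mean and
#' max are taken over the supplied set of stimulus orders.  Provided the
#' system responds most strongly to the sequential order, selectivity lies in
#' \[0, 1\]: 0 = unselective, near 1 = highly selective.
#'
#' @param atot_by_order Named numeric vector of Atot values; names are
#'   dash-joined orders (e.g. `"0-1-2-3-4"`), or a data.frame with columns
#'   `order` and `Atot`.
#' @param sequential_order The sequential order (default `0:4`).
#' @return An object of class `selectivity_result` with the selectivity
#'   scalar and its ingredients.  If `max(Atot) <= 0` the selectivity is
#'   undefined and reported as `NA` (with a warning), never as 0.
#' @examples
#' a <- c("0-1-2-3-4" = 2, "1-0-2-3-4" = 1, "2-1-0-3-4" = 1)
#' selectivity(a)
#' @export
selectivity <- function(atot_by_order, sequential_order = 0:4) {
  atot <- as_atot_vector(atot_by_order)
  key <- order_key(check_permutation(sequential_order,
                                     length(sequential_order)))
  if (!key %in% names(atot))
    stop("atot_by_order must include the sequential order")
  a_seq <- unname(atot[key])
  sel_core(a_seq, atot, meta = list(n_orders = length(atot)))
}

#' Selectivity with replicate-averaged sequential response
#'
#' Variant used with stochastic or replicated runs: Asequential is the mean
#' of several sequential-stimulus replicates, and that mean joins the set of
#' per-order Atot values over which mean(Atot) and max(Atot) are computed.
#'
#' @param runs_sequential Numeric vector of Atot values from sequential
#'   replicates (length >= 1).
#' @param atot_by_order Atot for the non-sequential orders (named vector or
#'   data.frame as in [selectivity()]; any entry named for the sequential
#'   order is ignored).
#' @inheritParams selectivity
#' @return A `selectivity_result`.
#' @export
selectivity_averaged_sequential <- function(runs_sequential, atot_by_order,
                                            sequential_order = 0:4) {
  if (length(runs_sequential) < 1) stop("need at least one sequential replicate")
  atot <- as_atot_vector(atot_by_order)
  key <- order_key(check_permutation(sequential_order,
                                     length(sequential_order)))
  atot <- atot[setdiff(names(atot), key)]
  a_seq <- mean(runs_sequential)
  pool <- c(stats::setNames(a_seq, key), atot)
  sel_core(a_seq, pool,
           meta = list(n_orders = length(pool),
                       n_replicates = length(runs_sequential)))
}

sel_core <- function(a_seq, pool, meta = list()) {
  a_mean <- mean(pool)
  a_max <- max(pool)
  if (a_max <= 0) {
    warning("max(Atot) <= 0: selectivity is undefined; reporting NA")
    sel <- NA_real_
  } else {
    sel <- (a_seq - a_mean) / a_max
  }
  structure(c(list(selectivity = sel, Asequential = a_seq, mean_Atot = a_mean,
                   max_Atot = a_max, atot = pool), meta),
            class = "selectivity_result")
}

#' @export
print.selectivity_result <- function(x, ...) {
  cat(sprintf("<selectivity> %.4f  (Aseq = %.4g, mean = %.4g, max = %.4g, %d orders)\n",
              x$selectivity, x$Asequential, x$mean_Atot, x$max_Atot,
              x$n_orders))
  invisible(x)
}

as_atot_vector <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("order", "Atot") %in% names(x)))
    x <- stats::setNames(x$Atot, x$order)
  }
  if (is.null(names(x)) || any(names(x) == ""))
    stop("Atot values must be named by their stimulus order (e.g. '0-1-2-3-4')")
  if (length(x) == 0) stop("atot_by_order is empty")
  x
}
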