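#' Gaussian calcium pulse profile
#'
#' The commanded Ca input at a stimulus site follows a Gaussian time profile
#' `amplitude * exp(-(phase - t)^2 / (2 * width^2))`, where `phase` is the
#' pulse centre and `width` its Gaussian sigma (s).  The pulse is truncated to
#' zero beyond `phase +/- 4 * width` to bound simulation windows.
#'
#' @param t Time (s); vectorised.
#' @param phase Pulse centre (s).
#' @param width Gaussian sigma (s); must be positive.
#' @param amplitude Peak value (input units, default 1).
#' @return The commanded input value at `t`.
#' @examples
#' ca_profile(2, phase = 2, width = 0.5)          # peak
#' ca_profile(2.5, phase = 2, width = 0.5)        # exp(-1/2)
#' @export
ca_profile <- function(t, phase, width, amplitude = 1) {
  if (!is.numeric(width) || any(width <= 0))
    stop("width must be positive")
  v <- amplitude * exp(-((phase - t)^2) / (2 * width^2))
  v[abs(t - phase) > 4 * width] <- 0
  v
}

#' Build a five-site sequence stimulus protocol
#'
#' Constructs the full stimulus description for one run: five Gaussian Ca
#' pulses delivered at the five reactive-patch centres, in the order given by
#' a permutation of `0:4`.  Site `k` (spatial position `k`) receives its pulse
#' at `onset + interval * rank(k)`, where `rank(k)` is the position of `k` in
#' `order`.
#'
#' @param order Integer permutation of `0:4`; `order[1]` is the site that
#'   fires first.
#' @param spacing Centre-to-centre site distance (um).
#' @param interval Time between successive pulses (s).
#' @param width Gaussian sigma of each pulse (s).
#' @param amplitude Pulse amplitude (input units).
#' @param grid A [grid1d()]; its reactive patches are (re)placed at `spacing`.
#' @param onset Time of the first pulse centre (s); default 1 s so the model
#'   settles first.
#' @param krelax Relaxation rate (1/s) with which local Ca is driven toward
#'   the commanded profile (the input acts as a fast clamp-like source, so Ca
#'   still diffuses and decays).
#' @return An object of class `seq_stimulus`: sites (compartment indices in
#'   spatial order), per-site phases, and the pulse parameters.  The grid with
#'   its reactive mask is attached as attribute `grid`.
#' @export
build_protocol <- function(order, spacing, interval, width = 0.3,
                           amplitude = 1, grid = grid1d(), onset = 1,
                           krelax = 20) {
  order <- check_permutation(order, n = 5)
  stopifnot(spacing > 0, interval >= 0, width > 0, amplitude >= 0)
  grid <- reactive_patches(grid, spacing, n_patches = 5, patch_width = 1)
  sites <- attr(grid, "sites")
  ranks <- match(0:4, order) - 1          # firing rank of each spatial site
  phases <- onset + interval * ranks
  structure(list(
    sites = sites, order = order, spacing = spacing, interval = interval,
    width = width, amplitude = amplitude, onset = onset, krelax = krelax,
    phases = phases
  ), class = "seq_stimulus", grid = grid)
}

#' @export
print.seq_stimulus <- function(x, ...) {
  cat(sprintf("<seq_stimulus> order [%s]; spacing %g um; interval %g s; width %g s; amp %g\n",
              paste(x$order, collapse = ","), x$spacing, x$interval,
              x$width, x$amplitude))
  invisible(x)
}

check_permutation <- function(order, n = length(order)) {
  order <- as.integer(order)
  if (length(order) != n || anyNA(order) || !setequal(order, seq_len(n) - 1L))
    stop(sprintf("order must be a permutation of 0..%d", n - 1L))
  order
}

#' All permutations in lexicographic order
#'
#' Enumerates every permutation of `0:(n-1)` in lexicographic order (the
#' order produced by standard library permutation generators).  For n = 5
#' this yields the 120 stimulus orders of the exhaustive protocol.
#'
#' @param n Sequence length (default 5).
#' @return A list of integer vectors.
#' @export
all_permutations <- function(n = 5) {
  stopifnot(n >= 1)
  rec <- function(items) {
    if (length(items) == 1) return(list(items))
    out <- list()
    for (i in seq_along(items))
      out <- c(out, lapply(rec(items[-i]), function(p) c(items[i], p)))
    out
  }
  rec(seq_len(n) - 1L)
}

#' Subsampled permutation protocol
#'
#' Takes every `stride`-th permutation from the lexicographic enumeration,
#' starting with the first (the sequential order).  With the defaults
#' (n = 5, stride = 10) this gives the 12-order protocol used for the
#' selectivity matrices and sensitivity sweeps.
#'
#' @param n Sequence length (default 5).
#' @param stride Subsampling stride (default 10).
#' @return A list of integer vectors (a sublist of [all_permutations()]).
#' @export
permutation_subsample <- function(n = 5, stride = 10) {
  if (!is.numeric(stride) || stride < 1)
    stop("stride must be a positive integer")
  perms <- all_permutations(n)
  perms[seq(1, length(perms), by = as.integer(stride))]
}

order_key <- function(order) paste(order, collapse = "-")
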