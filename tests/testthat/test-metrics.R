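test_that("Q reproduces the reference values for the printed orders", {
  expect_equal(q_score(0:4)$Q, 1)
  expect_equal(q_score(4:0)$Q, -1)
  expect_equal(q_score(c(4, 0, 2, 1, 3))$Q, -0.001)
  expect_equal(q_score(c(0, 1, 3, 2, 4))$Q, 0.729)
  expect_error(q_score(c(0, 0, 1, 2, 3)), "permutation")
  expect_error(q_score(3L), "length")
})

test_that("Q is antisymmetric under reversal and bounded, over all 120 orders", {
  for (o in all_permutations(5)) {
    q <- q_score(o)
    expect_lte(abs(q$Q), 1)
    expect_lte(abs(q$m), 1)
    expect_gte(q$R2, 0); expect_lte(q$R2, 1)
    expect_equal(q_score(rev(o))$Q, -q$Q)
  }
})

test_that("Atot is the time-normalised site sum above baseline", {
  tr0 <- fake_trajectory(0, n_rec = 21)
  expect_equal(a_total(tr0, sites = 1:5, t_start = 0, baseline = 0), 0)
  # constant readout c over 5 sites and window T gives 5 c T (Riemann sum)
  tr <- fake_trajectory(2, n_rec = 21, dt_rec = 0.1)
  expect_equal(a_total(tr, sites = 1:5, t_start = 0, baseline = 0),
               5 * 2 * 2.1)
  expect_error(a_total(tr, sites = 1:5, t_start = 0, readout = "Z"),
               "readout species")
})

test_that("Atot of a smooth stored response is stable under recording-rate refinement", {
  m <- abstract_model("negFB")
  stim <- build_protocol(0:4, 4, 1, width = 0.3, amplitude = 1)
  s1 <- solver_settings(t_end = 10, dt_rec = 0.1)
  s2 <- solver_settings(t_end = 10, dt_rec = 0.2)
  a1 <- a_total(simulate(m, stim, settings = s1), stim)
  a2 <- a_total(simulate(m, stim, settings = s2), stim)
  expect_lt(abs(a2 - a1) / abs(a1), 0.01)
})

test_that("selectivity follows the direct-evaluation algebra", {
  keys120 <- sapply(all_permutations(5), paste, collapse = "-")
  all_equal <- setNames(rep(3, 120), keys120)
  expect_equal(selectivity(all_equal)$selectivity, 0)

  one_hot <- setNames(c(5, rep(0, 119)), keys120)
  expect_equal(selectivity(one_hot)$selectivity, 119 / 120, tolerance = 1e-12)

  keys12 <- sapply(permutation_subsample(5, 10), paste, collapse = "-")
  one_hot12 <- setNames(c(7, rep(0, 11)), keys12)
  expect_equal(selectivity(one_hot12)$selectivity, 11 / 12, tolerance = 1e-12)

  expect_error(selectivity(setNames(1, "1-0-2-3-4")), "sequential")
  und <- setNames(rep(0, 12), keys12)
  expect_warning(s <- selectivity(und), "undefined")
  expect_true(is.na(s$selectivity))
})

test_that("selectivity is invariant to uniform rescaling of Atot", {
  keys <- sapply(permutation_subsample(5, 10), paste, collapse = "-")
  set.seed(7)
  at <- setNames(runif(12, 0.5, 2), keys)
  s1 <- selectivity(at)$selectivity
  s2 <- selectivity(at * 37.5)$selectivity
  expect_equal(s1, s2)
})

test_that("replicate-averaged sequential selectivity pools the mean into the order set", {
  keys12 <- sapply(permutation_subsample(5, 10), paste, collapse = "-")
  others <- setNames(rep(1, 11), keys12[-1])
  s <- selectivity_averaged_sequential(rep(2, 5), others)
  expect_equal(s$selectivity, 11 / 24, tolerance = 1e-12)

  # zero-variance replicates with a one-hot pattern reduce to the plain form
  others0 <- setNames(rep(0, 11), keys12[-1])
  s0 <- selectivity_averaged_sequential(c(4, 4, 4), others0)
  expect_equal(s0$selectivity, 11 / 12, tolerance = 1e-12)

  # replicates equal to the single-run value reproduce plain selectivity
  at <- setNames(c(2, rep(1, 11)), keys12)
  expect_equal(selectivity_averaged_sequential(rep(2, 3), at[-1])$selectivity,
               selectivity(at)$selectivity)
})
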