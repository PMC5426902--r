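families <- c("negFB", "negFF", "FHN", "switch")

test_that("every family is stationary at its resting state", {
  for (fam in families) {
    m <- abstract_model(fam)
    r <- switch(fam,
      negFB = negfb_rates(m$rest[["A"]], m$rest[["B"]], 0, m$params),
      negFF = negff_rates(m$rest[["A"]], m$rest[["B"]], 0, m$params),
      FHN = fhn_rates(m$rest[["A"]], m$rest[["B"]], 0, m$params),
      switch = switch_rates(m$rest[["A"]], m$rest[["B"]], 0, m$params))
    expect_lt(max(abs(r)), 1e-8)
  }
  expect_error(abstract_model("negFB", params = c(bogus = 1)), "unknown")
})

test_that("Ca excites A at rest in the inhibition motifs", {
  for (fn in list(negfb_rates, negff_rates)) {
    m <- abstract_model(if (identical(fn, negfb_rates)) "negFB" else "negFF")
    r <- fn(0, 0, 1, m$params)
    expect_gt(r[["dA"]], 0)
  }
  # negFB: A drives B; B inhibits A
  m <- abstract_model("negFB")
  expect_gt(negfb_rates(1, 0, 0, m$params)[["dB"]], 0)
  expect_lt(negfb_rates(1, 1, 0, m$params)[["dA"]],
            negfb_rates(1, 0, 0, m$params)[["dA"]])
  # negFF: Ca drives B directly
  m <- abstract_model("negFF")
  expect_gt(negff_rates(0, 0, 1, m$params)[["dB"]], 0)
})

test_that("the switch's frozen-B nullcline has three roots, outer two stable", {
  roots <- switch_nullcline_roots(abstract_model("switch"))
  expect_length(roots$roots, 3)
  expect_true(roots$stable[1])
  expect_false(roots$stable[2])
  expect_true(roots$stable[3])
})

test_that("rate scaling is an exact rescaling of time", {
  for (fam in families) {
    m <- abstract_model(fam)
    expect_equal(scale_model(m, 1)$params, m$params)
    expect_equal(scale_model(scale_model(m, 2), 2)$params,
                 scale_model(m, 4)$params)
    expect_equal(attr(scale_model(m, 3), "width_divisor"), 3)
    # resting state unchanged
    m2 <- scale_model(m, 2.5)
    r <- chem_rates_for(fam, m2, m2$rest[["A"]], m2$rest[["B"]], 0)
    expect_lt(max(abs(r)), 1e-8)
  }
  expect_error(scale_model(abstract_model("FHN"), -1), "positive")

  # point-model trajectory at factor 2 is the basal trajectory compressed 2x
  # (with the input onset and clamp rate co-scaled)
  m <- abstract_model("switch")
  m2 <- scale_model(m, 2)
  t1 <- point_response(m, "step", amplitude = 1, onset = 2, t_end = 20)
  t2 <- point_response(m2, "step", amplitude = 1, onset = 1, t_end = 10,
                       settings = solver_settings(t_end = 10,
                                                  dt_diff = 0.0025,
                                                  dt_rec = 0.05))
  pick1 <- match(seq(6, 18, by = 2), round(t1$times, 6))
  pick2 <- match(seq(3, 9, by = 1), round(t2$times, 6))
  expect_equal(t2$data[pick2, "A", 1], t1$data[pick1, "A", 1],
               tolerance = 0.05)
})

test_that("all four point models give a large impulse response", {
  for (fam in families) {
    m <- abstract_model(fam)
    tr <- point_response(m, "impulse", t_end = 30)
    excursion <- max(tr$data[, "A", 1]) - m$rest[["A"]]
    expect_gt(excursion, 0.5)
  }
})

test_that("point-model step responses have the family-specific signatures", {
  # negFB: strong transient then a shallower sustained plateau
  m <- abstract_model("negFB")
  tr <- point_response(m, "step", t_end = 60)
  A <- tr$data[, "A", 1]
  peak <- max(A); plateau <- mean(A[tr$times > 50])
  expect_gt(peak, 1.3 * plateau)
  expect_gt(plateau, 0.1 * peak)

  # negFF and switch: transient only, returning near baseline
  for (fam in c("negFF", "switch")) {
    m <- abstract_model(fam)
    tr <- point_response(m, "step", t_end = 60)
    A <- tr$data[, "A", 1] - m$rest[["A"]]
    expect_lt(mean(A[tr$times > 50]), 0.3 * max(A))
  }

  # FHN: sustained limit-cycle oscillation (many sign changes about the mid
  # level in the second half of the run)
  m <- abstract_model("FHN")
  tr <- point_response(m, "step", t_end = 60)
  A <- tr$data[tr$times > 20, "A", 1]
  mid <- (max(A) + min(A)) / 2
  expect_gte(sum(diff(sign(A - mid)) != 0), 6)
  expect_gt(max(A) - min(A), 1)
})

test_that("the switch point model turns on and autonomously returns to rest", {
  m <- abstract_model("switch")
  tr <- point_response(m, "impulse", t_end = 40)
  A <- tr$data[, "A", 1]
  pk <- max(A)
  dur <- sum(A > pk / 2) * tr$settings$dt_rec
  expect_gt(pk, 1)
  expect_gt(dur, 2)                 # sustained for seconds
  expect_lt(dur, 25)                # ... but not indefinitely
  expect_lt(abs(A[length(A)]), 0.05 * pk)
})

test_that("FHN excitation relays along the patches at a finite positive speed", {
  m <- abstract_model("FHN")
  stim <- build_protocol(0:4, spacing = 3, interval = 2,
                         width = m$sequence_width, amplitude = m$amplitude)
  tr <- simulate(m, stim,
                 settings = solver_settings(t_end = max(stim$phases) + 6))
  thr <- m$rest[["A"]] + 1          # excitation threshold above rest
  cross <- sapply(stim$sites, function(s) {
    i <- which(tr$data[, "A", s] > thr)[1]
    if (is.na(i)) NA_real_ else tr$times[i]
  })
  expect_false(anyNA(cross))
  expect_true(all(diff(cross) > 0))
  speed <- 3 / mean(diff(cross))
  expect_gt(speed, 0.1); expect_lt(speed, 20)
})
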