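test_that("diffusion of a uniform field is a no-op and D = 0 freezes a species", {
  g <- grid1d(50, 1)
  state <- rbind(rep(2.5, 50), seq(0, 1, length.out = 50))
  out <- diffuse_step(state, D = c(3, 0), dt = 0.5, g)
  expect_equal(out[1, ], rep(2.5, 50))
  expect_equal(out[2, ], state[2, ])
})

test_that("implicit diffusion conserves mass to 1e-10 for random fields", {
  g <- grid1d(100, 1)
  set.seed(42)
  for (i in 1:5) {
    state <- matrix(runif(100, 0, 10), 1)
    s <- state
    for (k in 1:20) s <- diffuse_step(s, D = 2, dt = 0.05, g)
    expect_lt(abs(sum(s) - sum(state)) / sum(state), 1e-10)
  }
})

test_that("implicit diffusion matches the analytic heat kernel within 1%", {
  g <- grid1d(20, 0.1)
  M <- 10
  state <- matrix(0, 1, g$n_compartments)
  state[1, 100] <- M / g$dx
  D <- 1; dt <- 0.001
  s <- state
  for (k in 1:1000) s <- diffuse_step(s, D, dt, g)
  x <- g$x - g$x[100]
  analytic <- M / sqrt(4 * pi * D * 1) * exp(-x^2 / (4 * D * 1))
  interior <- 20:180
  expect_lt(max(abs(s[1, interior] - analytic[interior])) / max(analytic),
            0.01)
})

test_that("a zero-rate chemistry leaves the state unchanged", {
  m <- abstract_model("negFB",
                      params = c(k_act = 0, k_deg = 0, k_inh = 0,
                                 k_ab = 0, k_db = 0))
  g <- reactive_patches(grid1d(), 4)
  state <- rbind(A = runif(100), B = runif(100), Ca = rep(0, 100))
  out <- react_step(state, m, dt = 1, grid = g)
  expect_equal(out[1:2, ], state[1:2, ], tolerance = 1e-12)
})

test_that("adaptive reaction integration matches exponential decay to 1e-6", {
  m <- abstract_model("negFB",
                      params = c(k_act = 0, k_deg = 1, k_inh = 0,
                                 k_ab = 0, k_db = 0))
  g <- grid1d(1, 1)
  state <- matrix(c(1, 0, 0), 3, 1)
  out <- react_step(state, m, dt = 1, grid = g)
  expect_lt(abs(out[1, 1] - exp(-1)), 1e-6)
})

test_that("compartments outside the reactive mask are untouched by reactions", {
  m <- abstract_model("switch")
  g <- reactive_patches(grid1d(), 4)
  state <- rbind(A = rep(1.5, 100), B = rep(0, 100), Ca = rep(0, 100))
  out <- react_step(state, m, dt = 0.5, grid = g)
  expect_equal(out[1, !g$reactive_mask], state[1, !g$reactive_mask])
  # reactive compartments did evolve (A = 1.5 is not a fixed point)
  expect_false(any(out[1, g$reactive_mask] == 1.5))
})

test_that("a resting model under zero-amplitude stimulus stays at rest", {
  for (fam in c("negFB", "FHN", "switch")) {
    m <- abstract_model(fam)
    stim <- build_protocol(0:4, 4, 2, amplitude = 0)
    tr <- simulate(m, stim, settings = quick_settings(5))
    expect_lt(max(abs(tr$data[, "A", ] - m$rest[["A"]])), 1e-6)
    expect_lt(max(abs(tr$data[, "B", ] - m$rest[["B"]])), 1e-6)
  }
})

test_that("operator splitting self-converges monotonically on the switch run", {
  m <- abstract_model("switch")
  run_final <- function(dt) {
    stim <- build_protocol(0:4, 4, 2)
    simulate(m, stim,
             settings = solver_settings(t_end = 8, dt_diff = dt,
                                        dt_rec = 0.4))$final
  }
  ref <- run_final(0.00125)
  errs <- sapply(c(0.04, 0.02, 0.01), function(dt)
    max(abs(run_final(dt) - ref)))
  expect_true(all(diff(errs) < 0))
  # the ignition phenomenology is step-size robust: the ordered response
  # stays switched on (and far above the scrambled one) at every dt
  atot_at <- function(dt, order) {
    stim <- build_protocol(order, 4, 2)
    a_total(simulate(m, stim,
                     settings = solver_settings(t_end = max(stim$phases) + 10,
                                                dt_diff = dt)), stim)
  }
  for (dt in c(0.01, 0.005)) {
    expect_gt(atot_at(dt, 0:4), 10 * atot_at(dt, c(2, 1, 4, 3, 0)))
  }
})

test_that("runs are deterministic: identical inputs give identical output", {
  m <- abstract_model("FHN")
  stim <- build_protocol(c(2, 1, 4, 3, 0), 3, 1.5)
  t1 <- simulate(m, stim, settings = quick_settings(6))
  t2 <- simulate(m, stim, settings = quick_settings(6))
  expect_identical(t1$data, t2$data)
})

test_that("strang splitting is available and close to lie splitting", {
  m <- abstract_model("switch")
  stim <- build_protocol(0:4, 4, 2)
  a <- simulate(m, stim, settings = solver_settings(t_end = 6))$final
  b <- simulate(m, stim,
                settings = solver_settings(t_end = 6,
                                           method = "strang"))$final
  expect_lt(max(abs(a - b)), 0.05 * max(abs(a)))
  expect_false(identical(a, b))
})

test_that("non-finite states trigger an integration-failure error", {
  m <- abstract_model("switch")
  g <- reactive_patches(grid1d(), 4)
  state <- rbind(A = rep(0, 100), B = rep(0, 100), Ca = rep(0, 100))
  state[1, which(g$reactive_mask)[1]] <- NaN
  expect_error(react_step(state, m, dt = 0.1, grid = g),
               "integration failure")
  expect_error(diffuse_step(state, c(1, 1, 1), 0.1, g),
               "integration failure")
})

test_that("trajectories round-trip through the CSV writer with metadata", {
  m <- abstract_model("negFB")
  stim <- build_protocol(0:4, 4, 1)
  tr <- simulate(m, stim, settings = quick_settings(3))
  path <- file.path(tempdir(), "traj.csv")
  write_trajectory(tr, path)
  df <- read.csv(path)
  expect_equal(nrow(df), prod(dim(tr$data)))
  expect_setequal(unique(df$species), c("A", "B", "Ca"))
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(meta$model$family, "negFB")
  expect_equal(meta$stimulus$interval, 1)
  unlink(c(path, paste0(path, ".json")))
})
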