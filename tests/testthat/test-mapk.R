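spiny <- build_spiny_model()

test_that("the default spiny cylinder has the reference geometry", {
  g <- spiny$geometry
  expect_equal(g$n_spines, 49)
  expect_equal(g$dend_length, 60)
  expect_length(g$stim_spines, 5)
  # stimulated spines around the midpoint, roughly 3 um apart
  pos <- g$spine_pos[g$stim_spines]
  expect_true(all(diff(pos) > 1 & diff(pos) < 5))
  expect_lt(abs(mean(diff(pos)) - 3), 0.7)
  # head volume from the stated cylinder dimensions
  head_vol <- g$nodes$vol[g$nodes$type == "head"][1]
  expect_equal(head_vol, pi * 0.25^2 * 0.5)
  # rooted tree, children before parents
  p <- g$nodes$parent
  expect_equal(sum(p == 0), 1)
  expect_true(all(p[p != 0] > seq_along(p)[p != 0]))
  # regeneration with another seed is supported and differs
  g2 <- spiny_cylinder(seed = 7L)
  expect_false(identical(g2$spine_pos, g$spine_pos))
  expect_equal(g2$n_spines, 49)
})

test_that("the reaction network passes the moiety-conservation audit", {
  net <- spiny$network
  aud <- moiety_audit(net)
  expect_equal(attr(aud, "max_leak"), 0)
  S <- stoichiometry_matrix(net)
  # independent check: the MAPK-moiety row sums of S vanish columnwise
  w <- as.numeric(rownames(S) %in% c("MAPK", "MAPK_p", "MAPK_pp"))
  expect_equal(unname(as.vector(w %*% S)), rep(0, ncol(S)))
})

test_that("moieties are conserved to 1e-6 along a stimulated run", {
  sq <- sequence_demo(spiny, c(2, 0, 4, 1, 3), tail = 10)
  tr <- sq$trajectory
  vols <- spiny$geometry$nodes$vol
  for (moiety in list(c("MAPK", "MAPK_p", "MAPK_pp"),
                      c("MEK", "MEK_p"), c("Raf", "Raf_a"),
                      c("PKC", "PKC_a"), c("Phos", "Phos_a"),
                      c("CaM", "CaMCa"))) {
    tot <- sapply(seq_along(tr$times), function(i)
      sum(tr$data[i, moiety, , drop = FALSE] *
            rep(vols, each = length(moiety))))
    expect_lt(max(abs(tot - tot[1])) / tot[1], 1e-6)
  }
  # non-negativity of all species
  expect_gte(min(tr$data), 0)
})

test_that("an unstimulated or zero-amplitude run stays at the resting state", {
  tr <- simulate(spiny, NULL,
                 settings = solver_settings(t_end = 50, dt_diff = 0.05,
                                            dt_rec = 5))
  drift <- max(abs(sweep(tr$data[length(tr$times), , ], c(1, 2),
                         spiny$rest_state)))
  expect_lt(drift, 1e-3)
  tr0 <- simulate(spiny, psd_ca_stimulus(spiny, 3, amplitude = 0),
                  settings = solver_settings(t_end = 20, dt_diff = 0.05,
                                             dt_rec = 5))
  expect_lt(max(abs(tr0$data[, "MAPK_pp", ] -
                      mean(spiny$rest_state["MAPK_pp", ]))), 1e-3)
})

test_that("PSD Ca input is diluted and buffered on its way to the dendrite", {
  tr <- simulate(spiny, psd_ca_stimulus(spiny, 3),
                 settings = solver_settings(t_end = 10, dt_diff = 0.05,
                                            dt_rec = 0.5))
  psd <- spiny$geometry$psd_nodes[3]
  dend <- spiny$geometry$dend_sites[3]
  expect_gt(max(tr$data[, "Ca", psd]), 30)
  expect_lt(max(tr$data[, "Ca", dend]), 0.2 * max(tr$data[, "Ca", psd]))
  expect_error(psd_ca_stimulus(spiny, 9), "unknown stimulated spine")
})

test_that("sub-threshold inputs relax while supra-threshold inputs switch fully", {
  site <- spiny$geometry$dend_sites[3]
  peak_at <- function(amp) {
    tr <- simulate(spiny, psd_ca_stimulus(spiny, 3, amplitude = amp),
                   settings = solver_settings(t_end = 30, dt_diff = 0.05,
                                              dt_rec = 1))
    max(tr$data[, "MAPK_pp", site])
  }
  lo <- peak_at(160); hi <- peak_at(500)
  expect_lt(lo, 0.1)
  expect_gt(hi, 0.9)          # sharp input-output relation
})

test_that("the paired-pulse / step protocol shows suppression and decline", {
  pd <- pulse_protocol_demo(spiny)
  s <- pd$summary
  expect_gt(s$first_peak, 0.5)
  expect_gt(s$suppression_ratio, 3)
  expect_lt(s$step_end, s$step_peak / 2)
  # baseline holds between episodes
  mid <- pd$mapk_p[pd$times > 120 & pd$times < 150]
  expect_lt(max(mid), 0.05)
})

test_that("ordered input outperforms the scrambled reference in size and duration", {
  sq <- sequence_demo(spiny, 0:4)
  sc <- sequence_demo(spiny, c(4, 0, 3, 1, 2))
  expect_gt(sq$Atot, sc$Atot)
  expect_gt(sq$peak, sc$peak)
  expect_gt(sq$dur_half, sc$dur_half)
})

test_that("the network exports to a reaction table and SBML", {
  net <- spiny$network
  tab <- reaction_table(net)
  expect_equal(nrow(tab), length(net$reactions))
  expect_true(all(tab$type %in% c("mass_action", "michaelis_menten")))
  path <- file.path(tempdir(), "mapk.sbml")
  write_sbml(net, path)
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns(doc)
  expect_equal(length(xml2::xml_find_all(doc, "//d1:species", ns)),
               nrow(net$species))
  expect_equal(length(xml2::xml_find_all(doc, "//d1:reaction", ns)),
               length(net$reactions))
  unlink(path)
})

test_that("the bundled registry matches the in-code frozen defaults", {
  reg <- model_registry()
  expect_equal(reg$version, "1")
  expect_equal(unlist(reg$mapk_rates), mapk_default_rates())
  for (fam in c("negFB", "negFF", "FHN", "switch")) {
    m <- abstract_model(fam)
    expect_equal(unlist(reg$abstract[[fam]]$params), m$params)
    expect_equal(reg$abstract[[fam]]$D_A, m$D_A)
    expect_equal(unlist(reg$abstract[[fam]]$tuned), m$tuned)
  }
})
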