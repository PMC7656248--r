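# The synthetic-data module: state-path chain, coordinate emission,
# thermogram and series-table generators.

test_that("a zero-rate chain stays frozen in its start state", {
  spec <- traj_spec(n_frames = 50, water_count = 0,
                    state_rates = c("i->ii" = 0),
                    chelation_rates = list(D3 = c(0, 0)), seed = 3)
  gt <- sample_state_path(spec)
  expect_true(all(gt$complex_state == "i"))
  expect_true(all(gt$n5_state == "bound"))
  expect_true(all(gt$n_waters == 0L))
})

test_that("transitions only ever use allowed edges", {
  # forced single-edge chain: the first event out of i must be i->ii
  spec <- traj_spec(n_frames = 500, dt = 50, water_count = 0,
                    state_rates = c("i->ii" = 5, "ii->i" = 5), seed = 11)
  ev <- attr(sample_state_path(spec), "events")$complex
  expect_gt(length(ev$states), 2)
  expect_identical(ev$states[2], "ii")
  expect_true(all(ev$states %in% c("i", "ii")))

  # with every edge active, consecutive event states always form an
  # allowed unordered pair
  spec2 <- traj_spec(n_frames = 2000, dt = 100, water_count = 0,
                     state_rates = default_state_rates() * 20, seed = 5)
  ev2 <- attr(sample_state_path(spec2), "events")$complex
  key <- paste(pmin(ev2$states[-1], ev2$states[-length(ev2$states)]),
               pmax(ev2$states[-1], ev2$states[-length(ev2$states)]))
  allowed <- paste(pmin(allowed_edges()[, 1], allowed_edges()[, 2]),
                   pmax(allowed_edges()[, 1], allowed_edges()[, 2]))
  expect_true(all(key %in% allowed))
  # disallowed rate names are rejected up front
  expect_error(traj_spec(state_rates = c("i->iii" = 1)), "disallowed")
})

test_that("long-run occupancy matches the analytic stationary distribution", {
  rates <- stats::setNames(rep(1, 10), names(default_state_rates()))
  spec <- traj_spec(n_frames = 20000, dt = 100, water_count = 0,
                    state_rates = rates, seed = 42)
  gt <- sample_state_path(spec)
  pi_hat <- as.numeric(table(factor(gt$complex_state, complex_states()))) /
    length(gt$complex_state)
  pi_oracle <- ctmc_stationary_oracle(as.list(rates), complex_states())
  n_events <- length(attr(gt, "events")$complex$states)
  se <- 3 * sqrt(pi_oracle * (1 - pi_oracle) / n_events)
  expect_true(all(abs(pi_hat - pi_oracle) < pmax(se, 0.02)))
})

test_that("dwell-time means match the reciprocal exit rates", {
  rates <- stats::setNames(rep(1, 10), names(default_state_rates()))
  spec <- traj_spec(n_frames = 1200, dt = 5000, water_count = 0,
                    state_rates = rates, seed = 9)
  ev <- attr(sample_state_path(spec), "events")$complex
  expect_gt(length(ev$times), 1e4)
  dwell <- diff(ev$times)
  st <- ev$states[-length(ev$states)]
  exit <- vapply(complex_states(), function(s) {
    sum(rates[startsWith(names(rates), paste0(s, "->"))])
  }, numeric(1))
  for (s in complex_states()) {
    d <- dwell[st == s]
    se <- stats::sd(d) / sqrt(length(d))
    expect_lt(abs(mean(d) - 1 / exit[[s]]), 3 * se)
  }
})

test_that("the emission model is reproducible bitwise from the seed", {
  spec <- traj_spec(n_frames = 40, water_count = 25, seed = 77)
  g1 <- generate_complex_trajectory(spec)
  g2 <- generate_complex_trajectory(traj_spec(n_frames = 40,
                                              water_count = 25, seed = 77))
  expect_identical(g1$traj$coords, g2$traj$coords)
  expect_identical(g1$truth$complex_state, g2$truth$complex_state)
  g3 <- generate_complex_trajectory(traj_spec(n_frames = 40,
                                              water_count = 25, seed = 78))
  expect_false(identical(g1$traj$coords, g3$traj$coords))
})

test_that("an all-bound frozen path keeps every donor in the restraint window", {
  spec <- traj_spec(n_frames = 400, water_count = 5,
                    state_rates = c("i->ii" = 0),
                    chelation_rates = list(D3 = c(0, 0), D7 = c(0, 0),
                                           E11 = c(0, 0), E14 = c(0, 0)),
                    seed = 2)
  gen <- generate_complex_trajectory(spec)
  ion <- select_atoms(gen$top, sprintf("resname %s", toupper(spec$ion)))
  donors <- with(gen$top, which(class == "peptide" & element == "O"))
  d <- lncoord:::atom_set_distances(gen$traj, as.integer(ion), donors)
  expect_true(all(d >= 0.21 - 1e-9 & d <= 0.30 + 1e-9))
})

test_that("water-free specs emit only peptide and ion atoms", {
  spec <- traj_spec(n_frames = 10, water_count = 0, seed = 1,
                    state_rates = c("i->ii" = 0))
  gen <- generate_complex_trajectory(spec)
  expect_true(all(gen$top$class %in% c("peptide", "ion")))
  expect_equal(sum(gen$top$class == "ion"), 1L)
})

test_that("bound donor distances honour the truncation of the emission model", {
  spec <- traj_spec(n_frames = 2000, water_count = 0,
                    state_rates = c("i->ii" = 0), seed = 13)
  gen <- generate_complex_trajectory(spec)
  ds <- distance_series(gen$traj, gen$top, "resname LA",
                        "resid 5 and name OD1")
  dm <- spec$distance_model
  frac_out <- mean(abs(ds$values - dm$bound_mean) > 3 * dm$bound_sd)
  expect_lt(frac_out, 0.005)
})

test_that("synthetic thermograms reduce to the forward model", {
  proto <- itc_protocol()
  expect_equal(generate_itc_thermogram(1, 1e6, 0, proto)$heats,
               rep(0, 20))
  exp0 <- generate_itc_thermogram(1, 1e6, 3.83, proto, noise_sd = 0)
  expect_equal(exp0$heats, one_site_heats(1, 1e6, 3.83, proto))
  # endothermic, decaying toward the dilution baseline
  q <- exp0$heats[-1]
  expect_true(all(q > 0))
  expect_true(all(diff(q) < 0))
})

test_that("the default series table carries the observed branch structure", {
  tab <- generate_ln_series_table()
  expect_identical(detect_branch_points(tab$dH, tab$ion), c("Sm", "Yb"))
  expect_identical(detect_branch_points(tab$mTdS, tab$ion), c("Sm", "Yb"))
  # flat pattern: constant columns, no branches
  flat <- generate_ln_series_table(pattern = list(
    dH_nodes = c(La = 2, Lu = 2), mTdS_nodes = c(La = -9, Lu = -9)))
  expect_true(all(flat$dH == 2))
  expect_length(detect_branch_points(flat$dH, flat$ion), 0)
  # jitter preserves the constructed dG identity to machine precision
  jit <- generate_ln_series_table(jitter_sd = 0.03, seed = 4)
  expect_equal(jit$dG, jit$dH + jit$mTdS, tolerance = 1e-12)
})
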