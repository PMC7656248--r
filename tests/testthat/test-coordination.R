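# Coordination calling, chelation modes, water counting, complex-state
# classification and transition statistics.

test_that("distance series use minimum-image distances in nm", {
  fx <- make_fixed_traj(rbind(c(0, 0, 0), c(0.25, 0, 0)), box = 5)
  d <- distance_series(fx$traj, fx$top, "resname LA", "resname HOH")
  expect_equal(d$values, 0.25)
  fx2 <- make_fixed_traj(rbind(c(0.1, 0, 0), c(4.9, 0, 0)), box = 5)
  d2 <- distance_series(fx2$traj, fx2$top, "resname LA", "resname HOH")
  expect_equal(d2$values, 0.2)
})

test_that("multi-atom selections are rejected for pair distances", {
  fx <- make_fixed_traj(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)), box = 5)
  expect_error(distance_series(fx$traj, fx$top, "resname LA", "resname HOH"),
               "one atom")
})

test_that("hysteresis calling binds below r_on, releases above r_off, remembers between", {
  expect_identical(as.character(hysteresis_states(c(0.24, 0.25, 0.24))),
                   rep("bound", 3))
  expect_identical(
    as.character(hysteresis_states(c(0.24, 0.35, 0.45, 0.35, 0.24))),
    c("bound", "bound", "unbound", "unbound", "bound"))
  # first frame in the gap: nearer threshold, tie to unbound
  expect_identical(as.character(hysteresis_states(c(0.32, 0.32)))[1], "bound")
  expect_identical(as.character(hysteresis_states(c(0.38, 0.38)))[1], "unbound")
  expect_identical(as.character(hysteresis_states(c(0.35)))[1], "unbound")
  expect_error(hysteresis_states(0.25, coordination_params(r_on = 0.4,
                                                           r_off = 0.3)))
})

test_that("labels are invariant to distance values inside the retention band", {
  set.seed(1)
  for (rep in 1:20) {
    r <- c(0.25, runif(30, 0.15, 0.55))
    base <- as.character(hysteresis_states(r))
    gap <- which(r > 0.30 & r < 0.40)
    if (length(gap) == 0) next
    r2 <- r
    r2[gap] <- runif(length(gap), 0.301, 0.399)
    expect_identical(as.character(hysteresis_states(r2)), base)
  }
})

test_that("hysteresis recovers the generated N5 ground truth", {
  spec <- traj_spec(n_frames = 4000, water_count = 0, seed = 31)
  gen <- generate_complex_trajectory(spec)
  ds <- distance_series(gen$traj, gen$top, "resname LA",
                        "resid 5 and name OD1")
  lab <- as.character(hysteresis_states(ds))
  mask <- away_from_transitions(gen$truth$n5_state)
  expect_gte(mean(lab[mask] == gen$truth$n5_state[mask]), 0.99)
})

test_that("chelation mode distinguishes bidentate, monodentate and dissociated", {
  mk <- function(d1, d2) {
    fx <- make_fixed_traj(rbind(c(0, 0, 0), c(d1, 0, 0), c(0, d2, 0)),
                          box = 5,
                          names = c("LA", "OD1", "OD2"),
                          resnames = c("LA", "ASP", "ASP"),
                          resids = c(1, 3, 3))
    as.character(chelation_mode(fx$traj, fx$top, "resname LA",
                                "name OD1", "name OD2"))
  }
  expect_identical(mk(0.24, 0.26), "bidentate")
  expect_identical(mk(0.24, 0.41), "monodentate_O1")
  expect_identical(mk(0.41, 0.24), "monodentate_O2")
  expect_identical(mk(0.45, 0.41), "dissociated")
})

test_that("chelation classification recovers the generated D3 mode path", {
  spec <- traj_spec(n_frames = 3000, water_count = 0,
                    state_rates = c("i->ii" = 0),
                    chelation_rates = list(D3 = c(bi_to_mono = 0.3,
                                                  mono_to_bi = 0.3)),
                    seed = 17)
  gen <- generate_complex_trajectory(spec)
  mode <- as.character(chelation_mode(gen$traj, gen$top, "resname LA",
                                      "resid 3 and name OD1",
                                      "resid 3 and name OD2"))
  truth <- gen$truth$chelation_mode[, "D3"]
  mask <- away_from_transitions(truth)
  expect_gte(mean(mode[mask] == truth[mask]), 0.99)
  expect_gt(length(unique(truth)), 1)  # the path actually switches
})

test_that("water coordination counting matches placement", {
  fx0 <- make_fixed_traj(rbind(c(1, 1, 1)), box = 5,
                         names = "LA", resnames = "LA", resids = 1)
  wc0 <- water_coordination_count(fx0$traj, fx0$top, "resname LA")
  expect_identical(wc0$counts, 0L)
  fx1 <- make_fixed_traj(rbind(c(1, 1, 1), c(1.25, 1, 1), c(3, 3, 3)),
                         box = 5)
  wc1 <- water_coordination_count(fx1$traj, fx1$top, "resname LA")
  expect_identical(wc1$counts, 1L)
  expect_identical(wc1$ids[[1]], 2L)
})

test_that("generated state-iv segments carry two first-shell waters", {
  spec <- traj_spec(n_frames = 3000, water_count = 8,
                    state_rates = c("i->ii" = 2, "ii->i" = 0.5,
                                    "ii->iii" = 2, "iii->ii" = 0.5,
                                    "iii->iv" = 2, "iv->iii" = 0.5),
                    seed = 23)
  gen <- generate_complex_trajectory(spec)
  wc <- water_coordination_count(gen$traj, gen$top, "resname LA")
  iv <- gen$truth$complex_state == "iv"
  expect_gt(sum(iv), 50)
  expect_gte(mean(wc$counts[iv] == 2L), 0.95)
  # and the state-iii water hydrogen-bonds to the dissociated N5 oxygen
  iii <- which(gen$truth$complex_state == "iii")
  n5 <- lncoord:::resolve_single(gen$top, "resid 5 and name OD1", "n5")
  w1 <- as.integer(select_atoms(gen$top, "resname HOH and name O"))[1]
  d <- lncoord:::atom_set_distances(gen$traj, n5, w1)[iii]
  expect_true(all(d <= 0.35))
})

test_that("complex-state classification follows the five-state rules", {
  five_ok <- matrix("bound", 5, 5)
  lab <- classify_complex_state(
    n5 = c("bound", "bound", "unbound", "unbound", "unbound"),
    waters = c(0, 1, 1, 2, 0),
    five_site_states = five_ok)
  expect_identical(as.character(lab), c("i", "ii", "iii", "iv", "v"))
  # broken beats everything; surplus waters are 'other'
  five_bad <- five_ok
  five_bad[3, 2] <- "unbound"
  lab2 <- classify_complex_state(c("bound", "bound", "bound", "unbound",
                                   "unbound"),
                                 c(0, 3, 1, 2, 5), five_bad)
  expect_identical(as.character(lab2), c("i", "other", "broken", "iv",
                                         "other"))
  expect_error(classify_complex_state("bound", c(0, 1)), "length")
})

test_that("the classifier is a pure per-frame function", {
  set.seed(4)
  n <- 200
  n5 <- sample(c("bound", "unbound"), n, replace = TRUE)
  w <- sample(0:3, n, replace = TRUE)
  perm <- sample(n)
  lab <- as.character(classify_complex_state(n5, w))
  lab_perm <- as.character(classify_complex_state(n5[perm], w[perm]))
  expect_identical(lab_perm, lab[perm])
})

test_that("transition statistics count edges and flag off-path changes", {
  tr0 <- transition_stats(rep("i", 10))
  expect_equal(tr0$n_transitions, 0)
  expect_equal(nrow(tr0$off_path), 0)
  expect_equal(unname(tr0$occupancy), 1)

  tr1 <- transition_stats(c("i", "ii", "iii", "iv"))
  expect_equal(tr1$n_transitions, 3)
  expect_equal(nrow(tr1$off_path), 0)

  tr2 <- transition_stats(c("i", "iii"))
  expect_equal(nrow(tr2$off_path), 1)
  expect_identical(tr2$off_path$from, "i")
  expect_identical(tr2$off_path$to, "iii")

  set.seed(2)
  lab <- sample(c(complex_states(), "other"), 500, replace = TRUE)
  expect_lt(abs(sum(transition_stats(lab)$occupancy) - 1), 1e-12)
})

test_that("per-ion mean distances follow the lanthanide contraction", {
  series <- lapply(stats::setNames(LN_SYMBOLS, LN_SYMBOLS), function(ion) {
    spec <- traj_spec(n_frames = 600, water_count = 0, ion = ion,
                      state_rates = c("i->ii" = 0),
                      chelation_rates = list(D3 = c(0, 0), D7 = c(0, 0)),
                      seed = 100 + match(ion, LN_SYMBOLS))
    gen <- generate_complex_trajectory(spec)
    distance_series(gen$traj, gen$top,
                    sprintf("resname %s", toupper(ion)),
                    "resid 5 and name OD1")
  })
  tab <- mean_distance_by_ion(series)
  expect_identical(tab$ion, LN_SYMBOLS)
  # monotone contraction within sampling jitter; clear overall decrease
  expect_true(all(diff(tab$mean_nm) < 6e-4))
  expect_gt(tab$mean_nm[1] - tab$mean_nm[15], 0.012)

  # constant and duplicated series behave exactly
  tab2 <- mean_distance_by_ion(list(La = rep(0.25, 10), Lu = rep(0.25, 10)))
  expect_equal(tab2$mean_nm, c(0.25, 0.25))
  expect_equal(tab2$sd_nm, c(0, 0))
  expect_equal(tab2[1, -1], tab2[2, -1], ignore_attr = TRUE)
})

test_that("conditional proximity stratifies probe-water distances by chelation", {
  spec <- traj_spec(n_frames = 2500, water_count = 6,
                    state_rates = c("i->ii" = 0),
                    chelation_rates = list(D3 = c(bi_to_mono = 0.3,
                                                  mono_to_bi = 0.3)),
                    seed = 19)
  gen <- generate_complex_trajectory(spec)
  cond <- chelation_mode(gen$traj, gen$top, "resname LA",
                         "resid 3 and name OD1", "resid 3 and name OD2")
  cp <- conditional_proximity(gen$traj, gen$top, "resid 8 and name HN",
                              condition = cond)
  s <- cp$summary
  expect_true(all(c("bidentate", "monodentate_O1") %in% s$label))
  expect_lt(s$mean[s$label == "bidentate"],
            s$mean[s$label == "monodentate_O1"])

  # single stratum equals the unstratified summary
  cp_all <- conditional_proximity(gen$traj, gen$top, "resid 8 and name HN")
  cp_one <- conditional_proximity(gen$traj, gen$top, "resid 8 and name HN",
                                  condition = rep("x", 2500))
  expect_equal(cp_one$summary$mean, cp_all$summary$mean)

  # a single frame yields a one-entry histogram
  one <- make_fixed_traj(rbind(c(1, 1, 1), c(1.3, 1, 1)), box = 5)
  cp1 <- conditional_proximity(one$traj, one$top, "resname LA")
  expect_equal(sum(cp1$histograms[[1]]$counts), 1)
})
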