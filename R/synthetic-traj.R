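# Synthetic labelled trajectories.
#
# The generator is an explicit emission model around the known coordination
# geometry of the LBT3-Ln complex, not a molecular-dynamics surrogate: a
# continuous-time Markov chain over the five complex states drives which
# donors are bound and how many waters sit in the first shell, and
# coordinates are emitted i.i.d. per frame given the state. Every frame
# carries ground-truth labels so the downstream classifiers can be scored.

#' Complex-state labels and their allowed interconversions
#'
#' The five coordination states of the peptide-Ln3+ complex:
#' (i) ion bound to all six donor sites, no inner-shell water;
#' (ii) six sites plus one water; (iii) five sites (N5 side-chain oxygen
#' dissociated) plus one water; (iv) five sites plus two waters;
#' (v) five sites, no water. Interconversion is restricted to the edges
#' i-ii, ii-iii, iii-iv (large-ion path) and i-v, v-iii (small-ion path).
#'
#' @return `complex_states()`: character vector of the five labels.
#' @export
complex_states <- function() c("i", "ii", "iii", "iv", "v")

#' @rdname complex_states
#' @return `allowed_edges()`: two-column matrix of unordered allowed state
#'   pairs.
#' @export
allowed_edges <- function() {
  matrix(c("i", "ii",
           "ii", "iii",
           "iii", "iv",
           "i", "v",
           "v", "iii"), ncol = 2, byrow = TRUE,
         dimnames = list(NULL, c("from", "to")))
}

# N5 binding and first-shell water count implied by each complex state.
state_n5_bound <- c(i = TRUE, ii = TRUE, iii = FALSE, iv = FALSE, v = FALSE)
state_n_waters <- c(i = 0L, ii = 1L, iii = 1L, iv = 2L, v = 0L)

#' Default complex-state transition rates
#'
#' Per-ns rates for each directed allowed edge. The defaults give mean
#' state dwell times of a few ns so that, at the default 10 ps frame
#' spacing, dwells span hundreds of frames and two transitions almost
#' never fall inside one frame interval. Which states are visited is
#' controlled by which edges get nonzero rates; residence times
#' themselves are a free choice of the generator.
#'
#' @param k_off,k_on N5 dissociation/rebinding rates (per ns) applied to
#'   the ii->iii and iii->ii (and v->i) edges.
#' @return Named numeric vector of directed rates per ns.
#' @export
default_state_rates <- function(k_off = 0.08, k_on = 0.12) {
  c("i->ii" = 0.12, "ii->i" = 0.15,
    "ii->iii" = k_off, "iii->ii" = k_on,
    "iii->iv" = 0.06, "iv->iii" = 0.20,
    "i->v" = 0.05, "v->i" = k_on,
    "v->iii" = 0.08, "iii->v" = 0.05)
}

default_donor_set <- function() {
  data.frame(
    resid = c(3L, 3L, 5L, 7L, 7L, 9L, 11L, 11L, 14L, 14L),
    resname = c("ASP", "ASP", "ASN", "ASP", "ASP", "TRP",
                "GLU", "GLU", "GLU", "GLU"),
    name = c("OD1", "OD2", "OD1", "OD1", "OD2", "O",
             "OE1", "OE2", "OE1", "OE2"),
    site = c("D3", "D3", "N5", "D7", "D7", "W9",
             "E11", "E11", "E14", "E14"),
    stringsAsFactors = FALSE
  )
}

#' Specification of a synthetic complex trajectory
#'
#' Collects every knob of the generator: chain length, frame spacing, box,
#' ion identity (which sets the bound donor-ion distance through the ionic
#' radius), transition rates of the complex-state chain and of the
#' carboxylate mono/bidentate chains, water count and the per-state
#' distance emission model.
#'
#' Defaults mirror the simulated study conditions the analyses were
#' designed for: a cubic box holding 2589 waters (edge 4.3 nm), 100 ns of
#' sampling at 10 ps per frame, and a bound donor-oxygen distance of
#' (ionic radius + 1.40 Angstrom)/10 nm with 0.01 nm spread, clipped to
#' the 0.21-0.30 nm coordination-restraint window.
#'
#' @param n_frames Number of frames (>= 2).
#' @param dt Frame spacing in ps.
#' @param box_edge Cubic box edge in nm.
#' @param ion Lanthanide symbol, La through Lu.
#' @param ionic_radius Ionic radius in Angstrom; defaults to the packaged
#'   eight-coordinate value for `ion`.
#' @param state_rates Directed complex-state rates per ns
#'   (see [default_state_rates()]); only allowed edges may be named.
#' @param n5_rates Convenience pair `c(k_off, k_on)` per ns used to build
#'   `state_rates` when that argument is missing.
#' @param chelation_rates Named list per carboxylate site (`D3`, `D7`,
#'   `E11`, `E14`) of `c(bi_to_mono, mono_to_bi)` per ns.
#' @param water_count Total number of water molecules.
#' @param distance_model List with `bound_sd`, `unbound_mean`,
#'   `unbound_sd`, `angular_jitter` (all nm except the dimensionless
#'   jitter) and optional `bound_mean` override.
#' @param start_state Initial complex state.
#' @param seed Integer seed; the whole generator is reproducible from it.
#' @return An object of class `ln_traj_spec`.
#' @export
traj_spec <- function(n_frames = 10000, dt = 10, box_edge = 4.3,
                      ion = "La", ionic_radius = ln_radius(ion),
                      state_rates = NULL,
                      n5_rates = c(k_off = 0.08, k_on = 0.12),
                      chelation_rates = list(
                        D3 = c(bi_to_mono = 0.10, mono_to_bi = 0.30),
                        D7 = c(bi_to_mono = 0.10, mono_to_bi = 0.30),
                        E11 = c(bi_to_mono = 0, mono_to_bi = 0),
                        E14 = c(bi_to_mono = 0, mono_to_bi = 0)),
                      water_count = 2589,
                      distance_model = list(),
                      start_state = "i",
                      seed = 1L) {
  if (is.null(state_rates)) {
    state_rates <- default_state_rates(n5_rates[[1]], n5_rates[[2]])
  }
  chelation_rates <- utils::modifyList(list(
    D3 = c(bi_to_mono = 0.10, mono_to_bi = 0.30),
    D7 = c(bi_to_mono = 0.10, mono_to_bi = 0.30),
    E11 = c(bi_to_mono = 0, mono_to_bi = 0),
    E14 = c(bi_to_mono = 0, mono_to_bi = 0)), as.list(chelation_rates))
  dm <- utils::modifyList(list(
    bound_mean = ionic_radius / 10 + 0.14,
    bound_sd = 0.01,
    unbound_mean = 0.50,
    unbound_sd = 0.04,
    angular_jitter = 0.06,
    restraint_window = c(0.21, 0.30)
  ), distance_model)
  spec <- structure(list(
    n_frames = as.integer(n_frames), dt = dt, box_edge = box_edge,
    ion = ion, ionic_radius = ionic_radius,
    state_rates = state_rates, chelation_rates = chelation_rates,
    water_count = as.integer(water_count), distance_model = dm,
    donor_set = default_donor_set(),
    start_state = match.arg(start_state, complex_states()),
    seed = as.integer(seed)
  ), class = "ln_traj_spec")
  validate_traj_spec(spec)
  spec
}

validate_traj_spec <- function(spec) {
  dm <- spec$distance_model
  if (spec$n_frames < 2) stop("n_frames must be >= 2")
  if (any(spec$state_rates < 0) ||
      any(unlist(spec$chelation_rates) < 0)) stop("rates must be >= 0")
  edge_names <- c(paste0(allowed_edges()[, 1], "->", allowed_edges()[, 2]),
                  paste0(allowed_edges()[, 2], "->", allowed_edges()[, 1]))
  bad <- setdiff(names(spec$state_rates), edge_names)
  if (length(bad) > 0) stop("rates on disallowed edges: ",
                            paste(bad, collapse = ", "))
  if (dm$bound_sd <= 0 || dm$unbound_sd <= 0) stop("sigma must be > 0")
  if (spec$water_count < 0) stop("water_count must be >= 0")
  if (spec$box_edge <= 2 * (dm$unbound_mean + 3 * dm$unbound_sd)) {
    stop("box_edge must exceed twice the largest donor excursion")
  }
  invisible(spec)
}

#' @export
print.ln_traj_spec <- function(x, ...) {
  cat(sprintf("Synthetic trajectory spec: %s3+ (r = %.3f A), %d frames x %g ps, box %g nm, %d waters\n",
              x$ion, x$ionic_radius, x$n_frames, x$dt, x$box_edge,
              x$water_count))
  invisible(x)
}

# Exact continuous-time Markov chain simulation (Gillespie): event times and
# states, then discretisation at the frame times. Transitions shorter than
# dt are invisible in the frame-sampled path, as in real saved MD output.
simulate_ctmc <- function(rates, states, start, t_end_ns) {
  rate_list <- lapply(states, function(s) {
    pref <- paste0(s, "->")
    r <- rates[startsWith(names(rates), pref)]
    list(to = sub(pref, "", names(r), fixed = TRUE), rate = as.numeric(r))
  })
  names(rate_list) <- states
  t <- 0
  s <- start
  ev_t <- 0
  ev_s <- start
  repeat {
    out <- rate_list[[s]]
    lambda <- sum(out$rate)
    if (lambda == 0) break
    t <- t + stats::rexp(1, lambda)
    if (t >= t_end_ns) break
    s <- sample(out$to, 1, prob = out$rate)
    ev_t <- c(ev_t, t)
    ev_s <- c(ev_s, s)
  }
  list(times = ev_t, states = ev_s)
}

#' Sample the ground-truth state path
#'
#' Simulates the complex-state chain (exact event-time simulation on the
#' allowed edge set, then discretisation at frame times) and the
#' per-carboxylate mono/bidentate chains, and derives the N5 binding state
#' and first-shell water count deterministically from the complex state
#' (i, ii: N5 bound; waters i = 0, ii = 1, iii = 1, iv = 2, v = 0).
#'
#' @param spec An `ln_traj_spec`.
#' @return An object of class `ln_ground_truth`: list with per-frame
#'   `complex_state`, `n5_state` (`"bound"`/`"unbound"`), `n_waters`,
#'   `chelation_mode` (frame x carboxylate matrix of
#'   `"bidentate"`/`"monodentate_O1"`), and the raw event lists in
#'   attribute `"events"`.
#' @export
sample_state_path <- function(spec) {
  validate_traj_spec(spec)
  set.seed(spec$seed)
  t_end <- spec$n_frames * spec$dt / 1000  # ns
  frame_t <- (seq_len(spec$n_frames) - 1) * spec$dt / 1000
  ev <- simulate_ctmc(spec$state_rates, complex_states(), spec$start_state,
                      t_end)
  cs <- ev$states[findInterval(frame_t, ev$times)]
  chel_ev <- list()
  chel <- matrix("bidentate", spec$n_frames, length(spec$chelation_rates),
                 dimnames = list(NULL, names(spec$chelation_rates)))
  for (site in names(spec$chelation_rates)) {
    r <- spec$chelation_rates[[site]]
    rr <- c("bidentate->monodentate_O1" = as.numeric(r[[1]]),
            "monodentate_O1->bidentate" = as.numeric(r[[2]]))
    e <- simulate_ctmc(rr, c("bidentate", "monodentate_O1"), "bidentate",
                       t_end)
    chel[, site] <- e$states[findInterval(frame_t, e$times)]
    chel_ev[[site]] <- e
  }
  structure(list(
    complex_state = cs,
    n5_state = ifelse(state_n5_bound[cs], "bound", "unbound"),
    n_waters = as.integer(state_n_waters[cs]),
    chelation_mode = chel
  ), events = c(list(complex = ev), chel_ev), class = "ln_ground_truth")
}

#' @export
print.ln_ground_truth <- function(x, ...) {
  occ <- table(x$complex_state) / length(x$complex_state)
  cat("Ground truth:", length(x$complex_state), "frames; occupancy:",
      paste(names(occ), sprintf("%.3f", occ), collapse = ", "), "\n")
  invisible(x)
}

# truncated normal on [lo, hi] via inverse-CDF sampling
rtnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

unit_rows <- function(m) m / sqrt(rowSums(m * m))

# per-frame jittered copies of a fixed direction
jitter_dirs <- function(u, n, sd) {
  if (sd <= 0) return(matrix(u, n, 3, byrow = TRUE))
  unit_rows(matrix(u, n, 3, byrow = TRUE) +
              matrix(stats::rnorm(3 * n, 0, sd), n, 3))
}

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# site directions: donors spread over the sphere, probes off-axis
site_directions <- function() {
  s3 <- 1 / sqrt(3)
  list(D3 = c(1, 0, 0), N5 = c(0, 1, 0), D7 = c(-1, 0, 0),
       W9 = c(0, -1, 0), E11 = c(0, 0, 1), E14 = c(0, 0, -1),
       G8 = c(s3, s3, -s3), W2 = unname(c(s3, s3, s3)))
}

#' Generate a labelled synthetic complex trajectory
#'
#' Emits coordinates for the ion (box centre), the ten donor oxygens, the
#' N5/G8 amide probe protons and `water_count` waters, frame by frame,
#' conditioned on the sampled ground-truth state path:
#' \itemize{
#' \item bound donors sit at a distance drawn from a truncated normal
#'   around the ionic-radius-tied mean, inside the 0.21-0.30 nm
#'   coordination-restraint window; the dissociated N5 oxygen at
#'   0.50 +/- 0.04 nm;
#' \item carboxylate oxygen pairs keep an exact 0.22 nm O-O separation;
#'   bidentate places both oxygens on the coordination sphere, monodentate
#'   points the second oxygen radially outward;
#' \item first-shell waters are placed within 0.30 nm of the ion next to
#'   the N5 site, so the state-(iii) water sits within hydrogen-bond
#'   distance (<= 0.35 nm) of the dissociated N5 oxygen;
#' \item one designated probe water tracks the D3 chelation mode: near
#'   G8-HN (0.25 nm) under bidentate chelation, far (0.45 nm) under
#'   monodentate;
#' \item remaining waters are uniform in the periodic box outside a
#'   0.35 nm exclusion radius around all solute atoms.
#' }
#'
#' @param spec An `ln_traj_spec`.
#' @param ground_truth Optional pre-sampled `ln_ground_truth`; sampled
#'   from `spec` when missing.
#' @return List with elements `traj` (`ln_traj`), `top` (`ln_topology`)
#'   and `truth` (`ln_ground_truth`, with per-frame `bound_water_ids`).
#' @export
generate_complex_trajectory <- function(spec, ground_truth = NULL) {
  validate_traj_spec(spec)
  if (is.null(ground_truth)) ground_truth <- sample_state_path(spec)
  gt <- ground_truth
  nf <- spec$n_frames
  dm <- spec$distance_model
  dirs <- site_directions()
  centre <- rep(spec$box_edge / 2, 3)

  donors <- spec$donor_set
  nw <- spec$water_count
  top <- topology(
    name = c(spec$ion, donors$name, "HN", "HN", rep("O", nw)),
    resname = c(toupper(spec$ion), donors$resname, "ASN", "GLY",
                rep("HOH", nw)),
    resid = c(1L, donors$resid, 5L, 8L,
              if (nw > 0) 100L + seq_len(nw) else integer(0))
  )
  ion_i <- 1L
  donor_i <- 1L + seq_len(nrow(donors))
  n5hn_i <- donor_i[length(donor_i)] + 1L
  g8hn_i <- n5hn_i + 1L
  water_i <- if (nw > 0) g8hn_i + seq_len(nw) else integer(0)

  coords <- array(NA_real_, c(nf, nrow(top), 3))
  coords[, ion_i, ] <- matrix(centre, nf, 3, byrow = TRUE)

  bound_lo <- max(dm$restraint_window[1], dm$bound_mean - 3 * dm$bound_sd)
  bound_hi <- min(dm$restraint_window[2], dm$bound_mean + 3 * dm$bound_sd)
  r_bound <- function(n) rtnorm(n, dm$bound_mean, dm$bound_sd, bound_lo,
                                bound_hi)
  aj <- dm$angular_jitter

  place <- function(dirmat, r) {
    matrix(centre, nf, 3, byrow = TRUE) + dirmat * r
  }

  # N5 side-chain oxygen: state-dependent
  n5_bound <- gt$n5_state == "bound"
  u_n5 <- jitter_dirs(dirs$N5, nf, aj)
  r_n5 <- numeric(nf)
  r_n5[n5_bound] <- r_bound(sum(n5_bound))
  r_n5[!n5_bound] <- rtnorm(sum(!n5_bound), dm$unbound_mean, dm$unbound_sd,
                            dm$unbound_mean - 3 * dm$unbound_sd,
                            dm$unbound_mean + 3 * dm$unbound_sd)
  n5_row <- donor_i[donors$site == "N5"]
  coords[, n5_row, ] <- place(u_n5, r_n5)

  # carboxylates (exact 0.22 nm O-O) and the W9 backbone oxygen
  oo_sep <- 0.22
  for (site in c("D3", "D7", "E11", "E14")) {
    rows <- donor_i[donors$site == site]
    u <- jitter_dirs(dirs[[site]], nf, aj)
    v <- unit_rows(cross3(u, matrix(if (site %in% c("E11", "E14"))
      c(1, 0, 0) else c(0, 0, 1), nf, 3, byrow = TRUE)))
    r <- r_bound(nf)
    mode <- gt$chelation_mode[, site]
    bi <- mode == "bidentate"
    sinp <- (oo_sep / 2) / r
    cosp <- sqrt(1 - sinp^2)
    o1 <- place(u * cosp + v * sinp, r)
    o2 <- place(u * cosp - v * sinp, r)
    # monodentate: O1 on-sphere along the site axis, O2 radially outward
    o1[!bi, ] <- place(u, r)[!bi, ]
    o2[!bi, ] <- place(u, r + oo_sep)[!bi, ]
    coords[, rows[1], ] <- o1
    coords[, rows[2], ] <- o2
  }
  w9_row <- donor_i[donors$site == "W9"]
  coords[, w9_row, ] <- place(jitter_dirs(dirs$W9, nf, aj), r_bound(nf))

  # probe protons: N5-HN rides outside the N5 oxygen, G8-HN on its own axis
  coords[, n5hn_i, ] <- place(u_n5, r_n5 + 0.25)
  u_g8 <- jitter_dirs(dirs$G8, nf, aj)
  coords[, g8hn_i, ] <- place(u_g8, rtnorm(nf, 0.45, 0.01, 0.42, 0.48))

  bound_ids <- rep(list(integer(0)), nf)
  if (nw > 0) {
    # shell waters (molecule ids 1 and 2) near the N5 site when present
    w1 <- gt$n_waters >= 1L
    w2 <- gt$n_waters >= 2L
    if (nw < 2 && any(w2)) stop("water_count too small for state iv")
    if (nw < 1 && any(w1)) stop("water_count too small for bound waters")
    # state-ii water sits beside the bound N5 oxygen on its own axis;
    # when N5 is dissociated (iii, iv) the water rides the N5 axis at a
    # radius that keeps it within hydrogen-bond reach (<= 0.35 nm) of the
    # dissociated N5 oxygen while staying inside the first shell
    u_wii <- jitter_dirs(dirs$W2, nf, aj)
    r_w1 <- rtnorm(nf, 0.26, 0.008, 0.236, 0.284)
    r_w1[!n5_bound] <- pmin(pmax(r_n5[!n5_bound] - 0.27, 0.236), 0.284)
    shell1 <- place(u_wii, r_w1)
    shell1[!n5_bound, ] <- place(u_n5, r_w1)[!n5_bound, ]
    u_w2 <- jitter_dirs(dirs$W2, nf, aj)
    shell2 <- place(u_w2, rtnorm(nf, 0.27, 0.008, 0.246, 0.294))
    for (f in which(w1)) bound_ids[[f]] <- 1L
    for (f in which(w2)) bound_ids[[f]] <- c(1L, 2L)

    # probe water (id 3) coupled to the D3 chelation mode
    has_probe <- nw >= 3
    if (has_probe) {
      bi3 <- gt$chelation_mode[, "D3"] == "bidentate"
      d_probe <- ifelse(bi3, rtnorm(nf, 0.25, 0.02, 0.19, 0.31),
                        rtnorm(nf, 0.45, 0.04, 0.33, 0.57))
      probe <- coords[, g8hn_i, ] + u_g8 * d_probe
    }

    solute_rows <- c(ion_i, donor_i, n5hn_i, g8hn_i)
    excl <- 0.35
    box <- rep(spec$box_edge, 3)
    sphere_vol <- 4 / 3 * pi * excl^3 * length(solute_rows)
    if (sphere_vol > 0.5 * prod(box)) stop("packing error: box too small ",
                                           "for the exclusion constraints")
    for (f in seq_len(nf)) {
      ids_bulk <- seq_len(nw)
      if (w1[f]) coords[f, water_i[1], ] <- shell1[f, ]
      if (w2[f]) coords[f, water_i[2], ] <- shell2[f, ]
      if (has_probe) coords[f, water_i[3], ] <- probe[f, ]
      placed <- c(if (w1[f]) 1L, if (w2[f]) 2L, if (has_probe) 3L)
      ids_bulk <- setdiff(ids_bulk, placed)
      if (length(ids_bulk) > 0) {
        sol <- matrix(coords[f, solute_rows, ], length(solute_rows), 3)
        pos <- sample_excluded(length(ids_bulk), box, sol, excl)
        coords[f, water_i[ids_bulk], ] <- pos
      }
    }
  }
  gt$bound_water_ids <- bound_ids
  list(traj = trajectory(coords, rep(spec$box_edge, 3),
                         times = (seq_len(nf) - 1) * spec$dt),
       top = top, truth = gt)
}

# uniform positions in an orthorhombic box outside `excl` of any solute
# atom (minimum image)
sample_excluded <- function(n, box, solute, excl) {
  out <- matrix(NA_real_, n, 3)
  need <- seq_len(n)
  for (attempt in 1:200) {
    m <- length(need)
    cand <- cbind(stats::runif(m, 0, box[1]), stats::runif(m, 0, box[2]),
                  stats::runif(m, 0, box[3]))
    ok <- rep(TRUE, m)
    for (s in seq_len(nrow(solute))) {
      d2 <- 0
      for (k in 1:3) {
        dx <- cand[, k] - solute[s, k]
        dx <- dx - box[k] * round(dx / box[k])
        d2 <- d2 + dx * dx
      }
      ok <- ok & d2 > excl^2
    }
    out[need[ok], ] <- cand[ok, , drop = FALSE]
    need <- need[!ok]
    if (length(need) == 0) return(out)
  }
  stop("packing error: could not place waters outside the exclusion zones")
}

#' Write the generator outputs to disk
#'
#' Trajectory as multi-model PDB or XYZ (+ box sidecar), ground truth as
#' CSV (frame, complex_state, n5_state, n_bound_waters) and JSON.
#'
#' @param gen Result of [generate_complex_trajectory()].
#' @param dir Output directory (created if needed).
#' @param format Trajectory format.
#' @return The directory, invisibly.
#' @export
write_synthetic_trajectory <- function(gen, dir, format = c("pdb", "xyz")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (format == "pdb") "pdb" else "xyz"
  write_trajectory(gen$traj, gen$top, file.path(dir, paste0("traj.", ext)),
                   format)
  gt <- data.frame(frame = seq_along(gen$truth$complex_state),
                   complex_state = gen$truth$complex_state,
                   n5_state = gen$truth$n5_state,
                   n_bound_waters = gen$truth$n_waters)
  write_result_csv(gt, file.path(dir, "ground_truth.csv"))
  write_result_json(list(complex_state = gen$truth$complex_state,
                         n5_state = gen$truth$n5_state,
                         n_bound_waters = gen$truth$n_waters,
                         bound_water_ids = gen$truth$bound_water_ids),
                    file.path(dir, "ground_truth.json"))
  invisible(dir)
}
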