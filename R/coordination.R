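# Coordination-state analysis: donor-ion distance series, hysteresis
# bound/unbound calling, carboxylate chelation modes, first-shell water
# counting, the five-state complex classifier and its transition
# statistics, and the per-ion mean-distance tables.

#' Coordination-calling parameters
#'
#' Distance cutoffs in nm. `r_on`/`r_off` are the hysteresis thresholds
#' for donor binding (bound below 0.30 nm, dissociated above 0.40 nm,
#' memory in the gap); `r_water` is the first-shell cutoff for direct
#' water coordination; `r_chel` the carboxylate-oxygen binding cutoff.
#'
#' @param r_on Binding threshold (default 0.30).
#' @param r_off Release threshold (default 0.40, must exceed `r_on`).
#' @param r_water First-shell water cutoff (default 0.30; cross-check
#'   against the first minimum of the water-ion RDF).
#' @param r_chel Carboxylate binding cutoff (default 0.30).
#' @return An object of class `ln_coord_params`.
#' @export
coordination_params <- function(r_on = 0.30, r_off = 0.40, r_water = 0.30,
                                r_chel = 0.30) {
  if (!(r_on > 0 && r_on < r_off)) stop("need 0 < r_on < r_off")
  stopifnot(r_water > 0, r_chel > 0)
  structure(list(r_on = r_on, r_off = r_off, r_water = r_water,
                 r_chel = r_chel), class = "ln_coord_params")
}

#' Donor-ion distance series
#'
#' Per-frame minimum-image distance between two single atoms, in nm.
#'
#' @param traj An `ln_traj`.
#' @param top The matching `ln_topology`.
#' @param sel_a,sel_b Selections (see [select_atoms()]) or expressions,
#'   each resolving to exactly one atom.
#' @return An object of class `ln_distance_series`: list with `times`
#'   (ps), `values` (nm) and the atom-pair descriptors.
#' @export
distance_series <- function(traj, top, sel_a, sel_b) {
  check_traj_topology(traj, top)
  a <- resolve_single(top, sel_a, "sel_a")
  b <- resolve_single(top, sel_b, "sel_b")
  structure(list(times = traj$times,
                 values = atom_pair_distance(traj, a, b),
                 pair = c(atom_label(top, a), atom_label(top, b))),
            class = "ln_distance_series")
}

resolve_selection <- function(top, sel) {
  if (inherits(sel, "ln_selection")) return(as.integer(sel))
  if (is.character(sel)) return(as.integer(select_atoms(top, sel)))
  as.integer(sel)
}

resolve_single <- function(top, sel, what) {
  idx <- resolve_selection(top, sel)
  if (length(idx) != 1) {
    stop(what, " must resolve to one atom (got ", length(idx),
         "); use conditional_proximity() for atom sets")
  }
  idx
}

atom_label <- function(top, i) {
  sprintf("%s%d-%s", top$resname[i], top$resid[i], top$name[i])
}

#' @export
print.ln_distance_series <- function(x, ...) {
  cat(sprintf("Distance series %s ... %s: %d frames, %.3f-%.3f nm\n",
              x$pair[1], x$pair[2], length(x$values), min(x$values),
              max(x$values)))
  invisible(x)
}

#' Hysteresis (dual-threshold) bound/unbound calling
#'
#' A frame is `bound` when the distance is below `r_on`, `unbound` when
#' above `r_off`, and inherits the previous frame's label inside the
#' gap -- the memory suppresses chattering around a single cutoff. A
#' first frame falling in the gap takes the label of the nearer
#' threshold; an exact tie goes to `unbound`.
#'
#' @param series An `ln_distance_series` or numeric vector (nm).
#' @param params An `ln_coord_params`.
#' @return An object of class `ln_binary_states`: character vector of
#'   `"bound"`/`"unbound"` with the thresholds as attributes.
#' @export
hysteresis_states <- function(series, params = coordination_params()) {
  r <- if (inherits(series, "ln_distance_series")) series$values else series
  if (length(r) == 0) stop("empty distance series")
  lab <- character(length(r))
  mid <- (params$r_on + params$r_off) / 2
  first <- if (r[1] < params$r_on) "bound"
  else if (r[1] > params$r_off) "unbound"
  else if (r[1] < mid - 1e-12) "bound"  # nearer threshold; tie -> unbound
  else "unbound"
  lab[1] <- first
  if (length(r) > 1) {
    for (k in 2:length(r)) {
      lab[k] <- if (r[k] < params$r_on) "bound"
      else if (r[k] > params$r_off) "unbound"
      else lab[k - 1]
    }
  }
  structure(lab, r_on = params$r_on, r_off = params$r_off,
            class = "ln_binary_states")
}

#' Carboxylate chelation mode
#'
#' Classifies each frame of a carboxylate-ion pair as `bidentate` (both
#' oxygens within `r_chel`), `monodentate_O1`/`monodentate_O2` (only one
#' within), or `dissociated`.
#'
#' @param traj,top Trajectory and topology.
#' @param ion_sel,o1_sel,o2_sel Single-atom selections for the ion and
#'   the two carboxylate oxygens.
#' @param params An `ln_coord_params`.
#' @return An object of class `ln_chelation_series`: character labels
#'   with the two distance series as attributes.
#' @export
chelation_mode <- function(traj, top, ion_sel, o1_sel, o2_sel,
                           params = coordination_params()) {
  d1 <- distance_series(traj, top, ion_sel, o1_sel)$values
  d2 <- distance_series(traj, top, ion_sel, o2_sel)$values
  in1 <- d1 <= params$r_chel
  in2 <- d2 <= params$r_chel
  lab <- ifelse(in1 & in2, "bidentate",
                ifelse(in1, "monodentate_O1",
                       ifelse(in2, "monodentate_O2", "dissociated")))
  structure(lab, d1 = d1, d2 = d2, r_chel = params$r_chel,
            class = "ln_chelation_series")
}

#' First-shell water count
#'
#' Number (and identities) of water oxygens within `r_water` of the ion,
#' per frame, with minimum-image distances.
#'
#' @param traj,top Trajectory and topology.
#' @param ion_sel Single-atom ion selection.
#' @param water_sel Selection of water oxygens (may be empty: all counts
#'   zero).
#' @param params An `ln_coord_params`.
#' @return List with `counts` (integer per frame) and `ids` (list of
#'   water-oxygen atom indices per frame).
#' @export
water_coordination_count <- function(traj, top, ion_sel,
                                     water_sel = "resname HOH and name O",
                                     params = coordination_params()) {
  check_traj_topology(traj, top)
  ion <- resolve_single(top, ion_sel, "ion_sel")
  wat <- resolve_selection(top, water_sel)
  nf <- n_frames(traj)
  if (length(wat) == 0) {
    return(list(counts = integer(nf), ids = rep(list(integer(0)), nf)))
  }
  d <- atom_set_distances(traj, ion, wat)
  within <- d <= params$r_water
  list(counts = as.integer(rowSums(within)),
       ids = lapply(seq_len(nf), function(f) wat[within[f, ]]))
}

#' Classify the complex state (i)-(v)
#'
#' Combines the N5 binding state, the first-shell water count and the
#' integrity of the five other donor sites into the five complex states:
#' any broken non-N5 site gives `broken`; otherwise (N5 bound, 0 waters)
#' is `i`, (bound, 1) `ii`, (unbound, 1) `iii`, (unbound, 2) `iv`,
#' (unbound, 0) `v`; any other combination (e.g. bound with two or more
#' waters) is `other`. The classifier is a pure per-frame function.
#'
#' @param n5 An `ln_binary_states` (or character vector) for N5.
#' @param waters Integer water counts per frame.
#' @param five_site_states List of five `ln_binary_states` (or a
#'   character matrix with five columns) for the non-N5 sites; `NULL`
#'   asserts all five intact.
#' @return An object of class `ln_complex_states`: character labels with
#'   `waters` and `n5` attributes.
#' @export
classify_complex_state <- function(n5, waters, five_site_states = NULL) {
  n5 <- as.character(n5)
  waters <- as.integer(waters)
  nf <- length(n5)
  if (length(waters) != nf) stop("length mismatch between n5 and waters")
  if (is.null(five_site_states)) {
    intact <- rep(TRUE, nf)
  } else {
    if (is.list(five_site_states)) {
      five_site_states <- do.call(cbind, lapply(five_site_states,
                                                as.character))
    }
    if (nrow(five_site_states) != nf) {
      stop("length mismatch between n5 and five_site_states")
    }
    intact <- rowSums(five_site_states != "bound") == 0
  }
  bound <- n5 == "bound"
  lab <- rep("other", nf)
  lab[bound & waters == 0L] <- "i"
  lab[bound & waters == 1L] <- "ii"
  lab[!bound & waters == 1L] <- "iii"
  lab[!bound & waters == 2L] <- "iv"
  lab[!bound & waters == 0L] <- "v"
  lab[!intact] <- "broken"
  structure(lab, waters = waters, n5 = n5, class = "ln_complex_states")
}

#' Transition statistics of a complex-state series
#'
#' Counts adjacent-frame label changes, reports occupancy fractions
#' (summing to 1) and lists transitions outside the allowed edge set.
#' Off-path transitions are flagged, not errors: frame sampling can hide
#' short-lived intermediates.
#'
#' @param states An `ln_complex_states` (or character vector).
#' @param edges Allowed unordered state pairs (two-column matrix);
#'   default [allowed_edges()].
#' @return An object of class `ln_transition_report`: list with `counts`
#'   (transition count matrix), `occupancy` (named fractions),
#'   `off_path` (data.frame of flagged transitions with frame indices)
#'   and `n_transitions`.
#' @export
transition_stats <- function(states, edges = allowed_edges()) {
  lab <- as.character(states)
  if (length(lab) == 0) stop("empty state series")
  lev <- sort(unique(lab))
  occ <- as.numeric(table(factor(lab, lev))) / length(lab)
  names(occ) <- lev
  chg <- which(lab[-1] != lab[-length(lab)])
  from <- lab[chg]
  to <- lab[chg + 1]
  counts <- table(factor(from, lev), factor(to, lev))
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  allowed_keys <- key(edges[, 1], edges[, 2])
  off <- !(key(from, to) %in% allowed_keys)
  structure(list(
    counts = unclass(counts),
    occupancy = occ,
    off_path = data.frame(frame = chg, from = from, to = to,
                          stringsAsFactors = FALSE)[off, , drop = FALSE],
    n_transitions = length(chg)
  ), class = "ln_transition_report")
}

#' @export
print.ln_transition_report <- function(x, ...) {
  cat("Transitions:", x$n_transitions, "(", nrow(x$off_path), "off-path )\n")
  cat("Occupancy:", paste(names(x$occupancy),
                          sprintf("%.3f", x$occupancy), collapse = ", "), "\n")
  invisible(x)
}

#' Mean donor-ion distance per ion
#'
#' Population mean and standard deviation of one or more distance series
#' per ion, in series order -- the per-ion distance table behind the
#' lanthanide-contraction trend of the bound donor distances.
#'
#' @param series_by_ion Named list (ion symbol -> `ln_distance_series`,
#'   numeric vector, or list of either).
#' @return Data frame with `ion`, `mean_nm`, `sd_nm`, `n_frames`, ordered
#'   by atomic number.
#' @export
mean_distance_by_ion <- function(series_by_ion) {
  ions <- names(series_by_ion)
  if (is.null(ions) || anyNA(match(ions, LN_SYMBOLS))) {
    stop("series_by_ion must be named by lanthanide symbols")
  }
  rows <- lapply(ions, function(ion) {
    s <- series_by_ion[[ion]]
    if (inherits(s, "ln_distance_series")) s <- list(s)
    if (is.numeric(s)) s <- list(s)
    v <- unlist(lapply(s, function(x) {
      if (inherits(x, "ln_distance_series")) x$values else as.numeric(x)
    }))
    if (length(v) == 0) stop("empty distance series for ", ion)
    data.frame(ion = ion, mean_nm = mean(v),
               sd_nm = sqrt(mean((v - mean(v))^2)), n_frames = length(v),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(match(out$ion, LN_SYMBOLS)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Probe-water proximity stratified by a condition
#'
#' Per frame, the minimum-image minimum distance from a probe atom (e.g.
#' the G8 amide proton) to any water oxygen, summarised separately for
#' each label of a per-frame condition (e.g. the D3 chelation mode).
#'
#' @param traj,top Trajectory and topology.
#' @param probe_sel Single-atom probe selection.
#' @param water_sel Water-oxygen selection (empty gives empty summaries).
#' @param condition Per-frame labels (e.g. an `ln_chelation_series`);
#'   `NULL` puts every frame in one stratum `"all"`.
#' @return List with `per_frame` (data.frame frame/min_dist_nm/label) and
#'   `summary` (per-label mean, median, n) plus per-label histograms.
#' @export
conditional_proximity <- function(traj, top, probe_sel,
                                  water_sel = "resname HOH and name O",
                                  condition = NULL) {
  check_traj_topology(traj, top)
  probe <- resolve_single(top, probe_sel, "probe_sel")
  wat <- resolve_selection(top, water_sel)
  nf <- n_frames(traj)
  lab <- if (is.null(condition)) rep("all", nf) else as.character(condition)
  if (length(lab) != nf) stop("condition length must equal n_frames")
  if (length(wat) == 0) {
    return(list(per_frame = data.frame(frame = integer(0),
                                       min_dist_nm = numeric(0),
                                       label = character(0)),
                summary = data.frame(label = character(0), mean = numeric(0),
                                     median = numeric(0), n = integer(0)),
                histograms = list()))
  }
  d <- atom_set_distances(traj, probe, wat)
  mind <- apply(d, 1, min)
  per_frame <- data.frame(frame = seq_len(nf), min_dist_nm = mind,
                          label = lab, stringsAsFactors = FALSE)
  labs <- sort(unique(lab))
  summ <- do.call(rbind, lapply(labs, function(l) {
    v <- mind[lab == l]
    data.frame(label = l, mean = mean(v), median = stats::median(v),
               n = length(v), stringsAsFactors = FALSE)
  }))
  hists <- lapply(stats::setNames(labs, labs), function(l) {
    graphics::hist(mind[lab == l], breaks = "Sturges", plot = FALSE)
  })
  list(per_frame = per_frame, summary = summ, histograms = hists)
}
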