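# Radial distribution functions around a single reference atom, running
# coordination numbers, and first-shell boundary detection.

#' Radial distribution function
#'
#' g(r) between one reference atom (e.g. the ion, or the G8 amide proton)
#' and a set of target atoms (e.g. all water oxygens), averaged over
#' frames with minimum-image distances. Shell normalisation uses the
#' ideal 4 pi r^2 dr form with the mean target number density
#' rho = N_target / <V_box>; the bias against the exact bin-sphere
#' intersection is negligible at the default 0.002 nm bin width.
#'
#' @param traj,top Trajectory and topology.
#' @param ref_sel Single-atom reference selection.
#' @param target_sel Target-atom selection.
#' @param r_max Histogram range in nm; must not exceed half the smallest
#'   box edge.
#' @param dr Bin width in nm.
#' @return An object of class `ln_rdf`: list with bin centres `r`, `g`,
#'   running coordination number `n`, density `rho` (nm^-3), `dr` and
#'   `n_frames`.
#' @export
rdf <- function(traj, top, ref_sel, target_sel, r_max = 1.0, dr = 0.002) {
  check_traj_topology(traj, top)
  stopifnot(dr > 0)
  half_box <- min(traj$box) / 2
  if (r_max > half_box + 1e-12) {
    stop(sprintf("r_max = %g nm exceeds half the smallest box edge (%g nm)",
                 r_max, half_box))
  }
  ref <- resolve_single(top, ref_sel, "ref_sel")
  targets <- setdiff(resolve_selection(top, target_sel), ref)
  breaks <- seq(0, r_max, by = dr)
  nb <- length(breaks) - 1L
  centres <- breaks[-1] - dr / 2
  nf <- n_frames(traj)
  if (length(targets) == 0) {
    warning("no target atoms: rho = 0, g set to 0")
    return(structure(list(r = centres, g = numeric(nb), n = numeric(nb),
                          rho = 0, dr = dr, n_frames = nf),
                     class = "ln_rdf"))
  }
  d <- atom_set_distances(traj, ref, targets)
  idx <- .bincode(d, breaks, right = FALSE)
  counts <- tabulate(idx[!is.na(idx)], nbins = nb)
  mean_counts <- counts / nf
  rho <- length(targets) / mean(apply(traj$box, 1, prod))
  g <- mean_counts / (4 * pi * centres^2 * dr * rho)
  structure(list(r = centres, g = g, n = cumsum(mean_counts), rho = rho,
                 dr = dr, n_frames = nf), class = "ln_rdf")
}

#' @export
print.ln_rdf <- function(x, ...) {
  cat(sprintf("RDF: %d bins to %.3f nm (dr = %g), rho = %.3f nm^-3, %d frames\n",
              length(x$r), max(x$r) + x$dr / 2, x$dr, x$rho, x$n_frames))
  invisible(x)
}

#' Running coordination number at a cutoff
#'
#' n(r_cut) = 4 pi rho sum g(r_k) r_k^2 dr over bins below the cutoff;
#' equals the direct mean count of targets within `r_cut` up to binning
#' error.
#'
#' @param rdfres An `ln_rdf`.
#' @param r_cut Cutoff in nm (<= r_max).
#' @return Mean number of targets within `r_cut`.
#' @export
coordination_number <- function(rdfres, r_cut) {
  if (r_cut > max(rdfres$r) + rdfres$dr / 2 + 1e-12) {
    stop("r_cut exceeds the RDF range")
  }
  use <- rdfres$r + rdfres$dr / 2 <= r_cut + 1e-12
  if (!any(use)) return(0)
  4 * pi * rdfres$rho * sum(rdfres$g[use] * rdfres$r[use]^2 * rdfres$dr)
}

#' First minimum of an RDF
#'
#' Location of the first local minimum after the first maximum of the
#' 3-bin moving-average-smoothed g(r) -- the outer boundary of the first
#' solvation shell, used to calibrate the first-shell water cutoff.
#'
#' @param rdfres An `ln_rdf`.
#' @param window Optional search window `c(lo, hi)` in nm.
#' @return The r value of the first minimum (nm).
#' @export
first_minimum <- function(rdfres, window = NULL) {
  r <- rdfres$r
  g <- rdfres$g
  if (!is.null(window)) {
    keep <- r >= window[1] & r <= window[2]
    r <- r[keep]
    g <- g[keep]
  }
  if (length(g) < 5) stop("too few bins in the search window")
  gs <- stats::filter(g, rep(1 / 3, 3), sides = 2)
  gs[1] <- g[1]
  gs[length(g)] <- g[length(g)]
  gs <- as.numeric(gs)
  n <- length(gs)
  imax <- NA_integer_
  for (k in 2:(n - 1)) {
    if (gs[k] > gs[k - 1] && gs[k] >= gs[k + 1]) {
      imax <- k
      break
    }
  }
  if (is.na(imax)) stop("no maximum found: g(r) is monotone or flat")
  for (k in (imax + 1):(n - 1)) {
    if (gs[k] < gs[k - 1] && gs[k] <= gs[k + 1]) return(r[k])
  }
  stop("no minimum found after the first maximum")
}
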