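# Independent oracles and small fixtures used across the test files.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stationary distribution of a CTMC from the eigen-decomposition of the
# transposed rate matrix (null vector of Q^T), independent of the
# Gillespie sampler.
ctmc_stationary_oracle <- function(rates, states) {
  n <- length(states)
  Q <- matrix(0, n, n, dimnames = list(states, states))
  for (nm in names(rates)) {
    ft <- strsplit(nm, "->", fixed = TRUE)[[1]]
    Q[ft[1], ft[2]] <- Q[ft[1], ft[2]] + rates[[nm]]
  }
  diag(Q) <- -rowSums(Q)
  e <- eigen(t(Q))
  v <- Re(e$vectors[, which.min(abs(e$values))])
  v / sum(v)
}

# Naive direction-scan oracle for branch detection: fill in the carried
# direction first, then report ions where consecutive directions differ.
branch_scan_oracle <- function(values, ions, tol = 0.05) {
  d <- diff(values)
  s <- sign(d)
  s[abs(d) <= tol] <- NA
  # carry the previous direction over "no change" steps
  for (i in seq_along(s)) {
    if (is.na(s[i]) && i > 1) s[i] <- s[i - 1]
  }
  out <- character(0)
  for (i in seq_along(s)[-1]) {
    if (!is.na(s[i]) && !is.na(s[i - 1]) && s[i] != s[i - 1]) {
      out <- c(out, ions[i])
    }
  }
  out
}

# An "ideal gas" fixture: one central reference atom plus nt uniformly
# random water oxygens per frame in a cubic periodic box.
make_uniform_traj <- function(nf, nt, box, seed = 1) {
  set.seed(seed)
  coords <- array(NA_real_, c(nf, nt + 1, 3))
  coords[, 1, ] <- matrix(box / 2, nf, 3)
  coords[, -1, ] <- stats::runif(nf * nt * 3, 0, box)
  top <- topology(c("LA", rep("O", nt)), c("LA", rep("HOH", nt)),
                  c(1L, 100L + seq_len(nt)))
  list(traj = trajectory(coords, rep(box, 3)), top = top)
}

# A tiny hand-placed trajectory: atoms at fixed positions every frame.
make_fixed_traj <- function(positions, box, nf = 1,
                            names = NULL, resnames = NULL, resids = NULL) {
  na <- nrow(positions)
  coords <- array(NA_real_, c(nf, na, 3))
  for (f in seq_len(nf)) coords[f, , ] <- positions
  if (is.null(names)) names <- c("LA", rep("O", na - 1))
  if (is.null(resnames)) resnames <- c("LA", rep("HOH", na - 1))
  if (is.null(resids)) resids <- c(1L, 100L + seq_len(na - 1))
  list(traj = trajectory(coords, box),
       top = topology(names, resnames, resids))
}

# Direct (histogram-free) mean count of targets within r_cut of the
# reference atom, minimum image - the cross-check for the running
# coordination number.
direct_mean_count <- function(traj, ref, targets, r_cut) {
  nf <- dim(traj$coords)[1]
  cnt <- numeric(nf)
  for (f in seq_len(nf)) {
    d2 <- 0
    for (k in 1:3) {
      dx <- traj$coords[f, targets, k] - traj$coords[f, ref, k]
      dx <- dx - traj$box[f, k] * round(dx / traj$box[f, k])
      d2 <- d2 + dx^2
    }
    cnt[f] <- sum(d2 <= r_cut^2)
  }
  mean(cnt)
}

# Mask of frames at least `pad` frames away from any ground-truth state
# change.
away_from_transitions <- function(truth_states, pad = 1) {
  chg <- which(truth_states[-1] != truth_states[-length(truth_states)])
  mask <- rep(TRUE, length(truth_states))
  for (k in chg) {
    lo <- max(1, k - pad + 1)
    hi <- min(length(truth_states), k + pad)
    mask[lo:hi] <- FALSE
  }
  mask
}
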