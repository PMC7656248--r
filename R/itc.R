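# One-site isothermal titration calorimetry.
#
# Forward model, blank subtraction, nonlinear least-squares fitting with a
# fixed-stoichiometry fallback for non-sigmoidal (low c = N*K*M0)
# thermograms, and the derived DG / -TDS decomposition.

#' ITC injection protocol
#'
#' @param T Temperature in kelvin (default 283.15 K, i.e. 10 C).
#' @param V0 Cell volume in mL.
#' @param M0 Cell macromolecule (peptide) concentration in uM.
#' @param X0 Syringe ligand (Ln3+) concentration in uM.
#' @param injection_volumes Injection volumes in uL; the default is the
#'   standard 20-injection schedule with an initial 2 uL pre-injection
#'   followed by 19 x 10 uL.
#' @return An object of class `ln_itc_protocol`.
#' @export
itc_protocol <- function(T = 283.15, V0 = 1.4, M0 = 15, X0 = 300,
                         injection_volumes = c(2, rep(10, 19))) {
  stopifnot(T > 0, V0 > 0, M0 > 0, X0 > 0, all(injection_volumes > 0))
  structure(list(T = T, V0 = V0, M0 = M0, X0 = X0,
                 injection_volumes = as.numeric(injection_volumes)),
            class = "ln_itc_protocol")
}

#' @export
print.ln_itc_protocol <- function(x, ...) {
  cat(sprintf("ITC protocol: %d injections, cell %g mL @ %g uM, syringe %g uM, T = %g K\n",
              length(x$injection_volumes), x$V0, x$M0, x$X0, x$T))
  invisible(x)
}

#' One-site binding isotherm: heats per injection
#'
#' The Wiseman one-site model with the half-displacement volume
#' correction used by the instrument analysis software. With cumulative
#' injected volume \eqn{dV_i}, cell concentrations are
#' \eqn{M_i = M_0 (1 - dV_i/2V_0)/(1 + dV_i/2V_0)} and
#' \eqn{X_i = X_0 (dV_i/V_0)/(1 + dV_i/2V_0)}; the bound fraction
#' \eqn{\Theta_i} is the physical root of
#' \eqn{\Theta^2 - \Theta(1 + X_i/NM_i + 1/NKM_i) + X_i/NM_i = 0};
#' the cumulative heat is \eqn{Q_i = N \Theta_i M_i \Delta H V_0} and the
#' per-injection heat
#' \eqn{q_i = Q_i - Q_{i-1} + (v_i/V_0)(Q_i + Q_{i-1})/2}.
#'
#' @param N Stoichiometry (dimensionless).
#' @param K Association constant in 1/M.
#' @param dH Binding enthalpy in kcal/mol.
#' @param protocol An `ln_itc_protocol`.
#' @param displacement If `FALSE`, the half-volume displacement correction
#'   is dropped (testing aid).
#' @return Heats per injection in ucal.
#' @export
one_site_heats <- function(N, K, dH, protocol, displacement = TRUE) {
  stopifnot(K > 0, N > 0)
  V0 <- protocol$V0 * 1e-3                 # L
  M0 <- protocol$M0 * 1e-6                 # M
  X0 <- protocol$X0 * 1e-6                 # M
  v <- protocol$injection_volumes * 1e-6   # L
  dV <- cumsum(v)
  if (displacement) {
    M <- M0 * (1 - dV / (2 * V0)) / (1 + dV / (2 * V0))
    X <- X0 * (dV / V0) / (1 + dV / (2 * V0))
  } else {
    M <- rep(M0, length(dV))
    X <- X0 * dV / V0
  }
  b <- 1 + X / (N * M) + 1 / (N * K * M)
  disc <- b^2 - 4 * X / (N * M)
  if (any(disc < 0)) stop("numerical guard: negative discriminant in the ",
                          "one-site isotherm")
  theta <- (b - sqrt(disc)) / 2
  Q <- N * theta * M * (dH * 1000) * V0 * 1e6  # ucal
  Qprev <- c(0, Q[-length(Q)])
  if (displacement) {
    q <- Q - Qprev + (v / V0) * (Q + Qprev) / 2
  } else {
    q <- Q - Qprev
  }
  q
}

#' An ITC experiment (thermogram)
#'
#' @param protocol An `ln_itc_protocol`.
#' @param heats Per-injection heats in ucal.
#' @param blank Optional per-injection blank (ligand-into-buffer) heats.
#' @param true_params Optional named list `(N, K, dH)` when the thermogram
#'   is synthetic (kept for recovery tests).
#' @return An object of class `ln_itc_experiment`.
#' @export
itc_experiment <- function(protocol, heats, blank = NULL,
                           true_params = NULL) {
  n <- length(protocol$injection_volumes)
  if (length(heats) != n) stop("heats length must equal injection count")
  if (!is.null(blank) && length(blank) != n) {
    stop("blank length must equal injection count")
  }
  structure(list(protocol = protocol, heats = as.numeric(heats),
                 blank = blank, true_params = true_params),
            class = "ln_itc_experiment")
}

#' @export
print.ln_itc_experiment <- function(x, ...) {
  cat(sprintf("ITC experiment: %d injections, heats %.2f .. %.2f ucal%s\n",
              length(x$heats), max(x$heats), min(x$heats),
              if (is.null(x$blank)) "" else " (blank attached)"))
  invisible(x)
}

#' Generate a synthetic thermogram
#'
#' Forward-model heats plus i.i.d. Gaussian noise.
#'
#' @inheritParams one_site_heats
#' @param noise_sd Noise standard deviation in ucal (>= 0).
#' @param seed Integer seed.
#' @return An `ln_itc_experiment` carrying the true parameters.
#' @export
generate_itc_thermogram <- function(N, K, dH, protocol = itc_protocol(),
                                    noise_sd = 0, seed = 1L) {
  stopifnot(noise_sd >= 0)
  set.seed(seed)
  q <- one_site_heats(N, K, dH, protocol)
  q <- q + stats::rnorm(length(q), 0, noise_sd)
  itc_experiment(protocol, q, true_params = list(N = N, K = K, dH = dH))
}

#' Subtract a blank titration
#'
#' Removes the ligand-dilution heats measured by titrating ligand into
#' buffer. Element-wise subtraction; the blank is cleared on the output.
#'
#' @param exp An `ln_itc_experiment` with a blank attached.
#' @return The corrected `ln_itc_experiment`.
#' @export
subtract_blank <- function(exp) {
  if (is.null(exp$blank)) stop("no blank heats attached")
  if (length(exp$blank) != length(exp$heats)) stop("blank length mismatch")
  itc_experiment(exp$protocol, exp$heats - exp$blank,
                 true_params = exp$true_params)
}

#' Derive the free-energy decomposition from K and dH
#'
#' \eqn{\Delta G = -RT \ln K} and \eqn{-T\Delta S = \Delta G - \Delta H}.
#'
#' @param K Association constant in 1/M (> 0).
#' @param dH Binding enthalpy in kcal/mol.
#' @param T Temperature in kelvin.
#' @return List with `dG` and `mTdS` in kcal/mol.
#' @export
derive_thermo <- function(K, dH, T) {
  stopifnot(K > 0, T > 0)
  dG <- -R_KCAL * T * log(K)
  list(dG = dG, mTdS = dG - dH)
}

#' Fit the one-site model to a thermogram
#'
#' Levenberg-Marquardt least squares of (N, K, dH) -- or (K, dH) with the
#' stoichiometry fixed -- against blank-corrected heats, with a multistart
#' grid over log10 K to avoid local minima. The initial small
#' pre-injection is excluded from the residuals by default (its volume
#' still enters the concentration bookkeeping). A warning is emitted when
#' the fitted c value (N K M0) is below 1, where the isotherm is no longer
#' sigmoidal and fixing N = 1 is the recommended fallback.
#'
#' @param exp An `ln_itc_experiment`; a blank, if attached, is subtracted
#'   first.
#' @param fix_N Optional fixed stoichiometry (e.g. `1.0`).
#' @param exclude_first Drop the first injection from the fit (default
#'   `TRUE`).
#' @return An object of class `ln_itc_fit` with elements `N`, `K`, `dH`,
#'   `dG`, `mTdS`, `T`, `N_fixed`, `rss`, `c_value`.
#' @export
fit_one_site <- function(exp, fix_N = NULL, exclude_first = TRUE) {
  if (!is.null(exp$blank)) exp <- subtract_blank(exp)
  proto <- exp$protocol
  heats <- exp$heats
  use <- seq_along(heats)
  if (exclude_first) use <- use[-1]
  if (length(use) < 3) stop("need at least 3 usable injections")

  resid_fun <- function(par) {
    N <- if (is.null(fix_N)) par[["N"]] else fix_N
    q <- tryCatch(one_site_heats(N, 10^par[["logK"]], par[["dH"]], proto),
                  error = function(e) rep(1e6, length(heats)))
    q[use] - heats[use]
  }
  dH0 <- sum(heats[use]) /
    (proto$M0 * 1e-6 * proto$V0 * 1e-3 * 1e9)  # rough scale, kcal/mol
  if (!is.finite(dH0) || dH0 == 0) dH0 <- 1
  best <- NULL
  for (logK0 in c(3, 4, 5, 6, 7, 8)) {
    start <- c(logK = logK0, dH = dH0)
    if (is.null(fix_N)) start <- c(N = 1, start)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = start, fn = resid_fun,
                         lower = if (is.null(fix_N))
                           c(N = 1e-3, logK = 0, dH = -Inf)
                         else c(logK = 0, dH = -Inf),
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss - 1e-12 * abs(best$rss)) {
      best <- list(par = fit$par, rss = rss)
    }
  }
  if (is.null(best)) stop("one-site fit failed to converge from any start")
  N_hat <- if (is.null(fix_N)) best$par[["N"]] else fix_N
  K_hat <- 10^best$par[["logK"]]
  dH_hat <- best$par[["dH"]]
  thermo <- derive_thermo(K_hat, dH_hat, proto$T)
  c_value <- N_hat * K_hat * proto$M0 * 1e-6
  if (c_value < 1 && is.null(fix_N)) {
    warning(sprintf(paste0("non-sigmoidal thermogram (c = %.3g < 1); ",
                           "parameters are poorly determined - consider ",
                           "refitting with fix_N = 1.0"), c_value))
  }
  structure(list(N = N_hat, K = K_hat, dH = dH_hat,
                 dG = thermo$dG, mTdS = thermo$mTdS, T = proto$T,
                 N_fixed = !is.null(fix_N), rss = best$rss,
                 c_value = c_value),
            class = "ln_itc_fit")
}

#' @export
print.ln_itc_fit <- function(x, ...) {
  cat(sprintf("One-site ITC fit%s: N = %.3f, K = %.4g 1/M (c = %.3g)\n",
              if (x$N_fixed) " (N fixed)" else "", x$N, x$K, x$c_value))
  cat(sprintf("  dG = %.3f, dH = %.3f, -TdS = %.3f kcal/mol at %g K\n",
              x$dG, x$dH, x$mTdS, x$T))
  invisible(x)
}

#' Read/write thermogram CSV
#'
#' Columns `injection`, `volume_uL`, `heat_ucal` (plus `blank_ucal` when a
#' blank is attached); the protocol is stored in a JSON header file next
#' to the CSV (`<path>.json`).
#'
#' @param exp An `ln_itc_experiment`.
#' @param path CSV path.
#' @return `path` (writer); an `ln_itc_experiment` (reader).
#' @export
write_itc_csv <- function(exp, path) {
  df <- data.frame(injection = seq_along(exp$heats),
                   volume_uL = exp$protocol$injection_volumes,
                   heat_ucal = exp$heats)
  if (!is.null(exp$blank)) df$blank_ucal <- exp$blank
  write_result_csv(df, path)
  write_result_json(exp$protocol[c("T", "V0", "M0", "X0")],
                    paste0(path, ".json"))
  invisible(path)
}

#' @rdname write_itc_csv
#' @export
read_itc_csv <- function(path) {
  df <- read_result_csv(path)
  hdr_path <- paste0(path, ".json")
  hdr <- if (file.exists(hdr_path)) {
    jsonlite::read_json(hdr_path, simplifyVector = TRUE)
  } else {
    stop("missing protocol header ", hdr_path)
  }
  proto <- itc_protocol(T = hdr$T, V0 = hdr$V0, M0 = hdr$M0, X0 = hdr$X0,
                        injection_volumes = df$volume_uL)
  itc_experiment(proto, df$heat_ucal,
                 blank = if ("blank_ucal" %in% names(df)) df$blank_ucal)
}
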