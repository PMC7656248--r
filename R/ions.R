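#' Gas constant in kcal/(mol K)
#'
#' Used throughout for free-energy conversions (\eqn{\Delta G = -RT \ln K},
#' Boltzmann inversion of distance histograms).
#' @export
R_KCAL <- 1.987204e-3

#' The trivalent lanthanide series
#'
#' Per-ion reference table for the 15 lanthanides La through Lu: element
#' symbol, atomic number and the Shannon effective ionic radius of the
#' +3 cation in eight-fold coordination. The radii contract monotonically
#' with atomic number (the lanthanide contraction); the total spread across
#' the series is below 0.26 Angstrom, which is what makes discriminating
#' individual Ln3+ a hard recognition problem.
#'
#' @return A data.frame with columns `ion` (symbol), `atomic_number`, and
#'   `radius_A` (Angstrom), ordered La to Lu.
#' @examples
#' tab <- ln_ions()
#' stopifnot(all(diff(tab$radius_A) < 0))
#' @export
ln_ions <- function() {
  data.frame(
    ion = c("La", "Ce", "Pr", "Nd", "Pm", "Sm", "Eu", "Gd",
            "Tb", "Dy", "Ho", "Er", "Tm", "Yb", "Lu"),
    atomic_number = 57:71,
    radius_A = c(1.160, 1.143, 1.126, 1.109, 1.093, 1.079, 1.066, 1.053,
                 1.040, 1.027, 1.015, 1.004, 0.994, 0.985, 0.977),
    stringsAsFactors = FALSE
  )
}

#' @rdname ln_ions
#' @format NULL
#' @usage NULL
#' @export
LN_SYMBOLS <- c("La", "Ce", "Pr", "Nd", "Pm", "Sm", "Eu", "Gd",
                "Tb", "Dy", "Ho", "Er", "Tm", "Yb", "Lu")

#' Ionic radius lookup
#'
#' @param ion Element symbol, e.g. `"La"`.
#' @return Radius in Angstrom.
#' @export
ln_radius <- function(ion) {
  tab <- ln_ions()
  i <- match(ion, tab$ion)
  if (anyNA(i)) {
    stop("unknown lanthanide symbol: ", paste(ion[is.na(i)], collapse = ", "))
  }
  tab$radius_A[i]
}
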