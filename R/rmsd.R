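# Optimal-superposition RMSD (Kabsch). Used for comparing structure
# ensembles, e.g. mean backbone structures of two complexes.

#' RMSD after optimal rigid superposition
#'
#' Centres both coordinate sets, finds the optimal rotation by the Kabsch
#' singular-value-decomposition construction (with the determinant
#' correction that excludes reflections) and returns the root mean square
#' deviation of the superposed atoms.
#'
#' @param a,b Matched n x 3 coordinate matrices (same unit).
#' @return RMSD in the input unit.
#' @export
kabsch_rmsd <- function(a, b) {
  a <- as.matrix(a)
  b <- as.matrix(b)
  stopifnot(ncol(a) == 3, ncol(b) == 3, nrow(a) == nrow(b), nrow(a) >= 3)
  ac <- sweep(a, 2, colMeans(a))
  bc <- sweep(b, 2, colMeans(b))
  s <- svd(crossprod(bc, ac))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  diff <- ac %*% R - bc
  sqrt(mean(rowSums(diff^2)))
}

#' Mean pairwise RMSD between two structure ensembles
#'
#' @param ens_a,ens_b Lists of matched n x 3 coordinate matrices.
#' @return Mean of [kabsch_rmsd()] over all cross pairs.
#' @export
ensemble_rmsd <- function(ens_a, ens_b) {
  vals <- unlist(lapply(ens_a, function(x) {
    vapply(ens_b, function(y) kabsch_rmsd(x, y), numeric(1))
  }))
  mean(vals)
}
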