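# Rigid-body least-squares superposition (Kabsch), the primitive beneath
# RMSD, RMSF and the delta-RMSD progress variable.  SVD-based, with the
# standard sign correction of the smallest singular vector so that only
# proper rotations (det = +1) are returned: protein chirality is preserved
# even when the mirror image would fit better.

#' Optimal rigid superposition of two coordinate sets
#'
#' Finds the proper rotation `R` and translation `t` minimising the RMSD
#' between `mobile` and `reference` over `fit_indices`, and applies the
#' transform to *all* mobile atoms.  The fit is unweighted.
#'
#' @param mobile `n x 3` coordinate matrix (Angstrom).
#' @param reference `n x 3` coordinate matrix with the same atom order.
#' @param fit_indices indices of the atoms used for the fit (default: all).
#'   At least 3 non-collinear points are required.
#' @param allow_degenerate if `TRUE`, 2-point and collinear fit sets are
#'   accepted: the SVD still returns a proper rotation minimising the
#'   objective, and the post-fit RMSD is unique, but the transform itself is
#'   not (any rotation about the common axis fits equally well).  Default
#'   `FALSE`: such sets raise a degeneracy error.
#' @return a list with elements `rotation` (3x3, `det = +1`), `translation`
#'   (length-3), and `coords` (the transformed mobile coordinates,
#'   `x' = R x + t`).
#' @examples
#' ref <- matrix(rnorm(15), 5, 3)
#' mob <- ref %*% matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3) # 90 deg about z
#' fit <- kabsch_superpose(mob, ref)
#' max(abs(fit$coords - ref)) < 1e-8
#' @export
kabsch_superpose <- function(mobile, reference, fit_indices = NULL,
                             allow_degenerate = FALSE) {
  mobile <- coords_of(mobile)
  reference <- coords_of(reference)
  if (!identical(dim(mobile), dim(reference)))
    abort_shape("mobile and reference must have the same dimensions")
  if (is.null(fit_indices)) fit_indices <- seq_len(nrow(mobile))
  if (length(fit_indices) < 3L && !allow_degenerate)
    abort_degenerate("superposition needs at least 3 fit points")
  if (length(fit_indices) < 2L)
    abort_degenerate("superposition needs at least 2 fit points")
  A <- mobile[fit_indices, , drop = FALSE]
  B <- reference[fit_indices, , drop = FALSE]
  mc <- colMeans(A)
  rc <- colMeans(B)
  A <- sweep(A, 2L, mc)
  B <- sweep(B, 2L, rc)
  if (!allow_degenerate) {
    for (M in list(A, B)) {
      sv <- svd(M, nu = 0, nv = 0)$d
      if (sv[2] <= 1e-8 * max(sv[1], 1))
        abort_degenerate("fit points are collinear or coincident")
    }
  }
  s <- svd(crossprod(A, B)) # H = t(A) %*% B; R = V S U^T
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  trans <- rc - as.vector(R %*% mc)
  tf <- list(rotation = R, translation = trans)
  tf$coords <- apply_transform(tf, mobile)
  tf
}

#' Apply a rigid transform to coordinates
#'
#' @param tf a list with `rotation` (3x3) and `translation` (length-3), as
#'   returned by [kabsch_superpose()].
#' @param coords `n x 3` coordinate matrix.
#' @return the transformed `n x 3` matrix, `x' = R x + t`.
#' @export
apply_transform <- function(tf, coords) {
  coords <- coords_of(coords)
  if (!all(is.finite(coords))) abort_param("coordinates must be finite")
  sweep(coords %*% t(tf$rotation), 2L, tf$translation, "+")
}

# plain RMSD between two equal-shape coordinate sets (no fitting)
rmsd_value <- function(a, b) {
  sqrt(mean(rowSums((a - b)^2)))
}

#' RMSD after optimal superposition
#'
#' Convenience wrapper: superposes `mobile` onto `reference` over
#' `fit_indices` and returns the RMSD over `measure_indices`.
#'
#' @inheritParams kabsch_superpose
#' @param measure_indices indices over which the deviation is measured
#'   (default: the fit indices).
#' @return RMSD in Angstrom.
#' @export
fit_rmsd <- function(mobile, reference, fit_indices = NULL, measure_indices = NULL,
                     allow_degenerate = FALSE) {
  mobile <- coords_of(mobile)
  reference <- coords_of(reference)
  if (is.null(fit_indices)) fit_indices <- seq_len(nrow(mobile))
  if (is.null(measure_indices)) measure_indices <- fit_indices
  ft <- kabsch_superpose(mobile, reference, fit_indices, allow_degenerate)
  rmsd_value(ft$coords[measure_indices, , drop = FALSE],
             reference[measure_indices, , drop = FALSE])
}
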