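# Domain-motion geometry: radius of gyration, per-domain centers,
# inter-domain centre-of-mass distances and the I-II-III hinge angle.
# All observables here are rigid-invariant, so no superposition is needed.

#' Mass-weighted radius of gyration per frame
#'
#' `Rg(t) = sqrt( (1/M) sum_i m_i |r_i(t) - R(t)|^2 )` with `R(t)` the
#' mass-weighted centre of the selection.
#'
#' @param traj an `mdh_traj`.
#' @param indices atom indices (default: all atoms).
#' @return an [metric_series()] in Angstrom.
#' @export
radius_of_gyration <- function(traj, indices = NULL) {
  if (is.null(indices)) indices <- seq_len(nrow(traj$atoms))
  if (length(indices) == 0L) abort_empty("empty selection for Rg")
  m <- traj$atoms$mass[indices]
  M <- sum(m)
  if (M <= 0) abort_param("total mass of the selection is zero")
  vals <- vapply(seq_len(n_frames(traj)), function(f) {
    x <- coords_of(traj, f)[indices, , drop = FALSE]
    com <- colSums(x * m) / M
    sqrt(sum(m * rowSums(sweep(x, 2L, com)^2)) / M)
  }, numeric(1))
  metric_series("rg", vals, traj$times, "angstrom",
                sprintf("%d atoms, mass-weighted", length(indices)))
}

#' Per-frame domain centers over C-alpha atoms
#'
#' Two flavors are provided, matching the two conventions in use: the
#' mass-weighted centre of mass (used for inter-domain distances) and the
#' unweighted centre of geometry (used for hinge angles).  Both are computed
#' over C-alpha atoms only.
#'
#' @param traj an `mdh_traj`.
#' @param domains an [domain_set()].
#' @param flavor `"com"` (mass-weighted, default) or `"cog"` (unweighted).
#' @return an object of class `mdh_centers`: list with `centers` (array
#'   `n_frames x n_domains x 3`, dimnames on domains), `flavor`, `times`.
#' @export
domain_centers <- function(traj, domains, flavor = c("com", "cog")) {
  flavor <- match.arg(flavor)
  dn <- names(domains$domains)
  ctr <- array(NA_real_, dim = c(n_frames(traj), length(dn), 3L),
               dimnames = list(NULL, dn, NULL))
  for (d in dn) {
    idx <- select_atoms(traj, paste0("CA and domain ", d), domains)
    m <- if (flavor == "com") traj$atoms$mass[idx] else rep(1, length(idx))
    M <- sum(m)
    for (f in seq_len(n_frames(traj))) {
      x <- coords_of(traj, f)[idx, , drop = FALSE]
      ctr[f, d, ] <- colSums(x * m) / M
    }
  }
  structure(list(centers = ctr, flavor = flavor, times = traj$times),
            class = "mdh_centers")
}

center_of <- function(centers, name) {
  if (!name %in% dimnames(centers$centers)[[2]])
    abort_config(sprintf("unknown domain '%s' in centers", name))
  matrix(centers$centers[, name, ], ncol = 3L)
}

#' Distance between two domain centers, per frame
#'
#' @param centers an [domain_centers()] result (conventionally the
#'   mass-weighted `"com"` flavor).
#' @param a,b domain names.
#' @return an [metric_series()] in Angstrom.
#' @export
interdomain_distance <- function(centers, a, b) {
  pa <- center_of(centers, a)
  pb <- center_of(centers, b)
  metric_series("distance", sqrt(rowSums((pa - pb)^2)), centers$times,
                "angstrom", sprintf("%s center to %s center (%s)", a, b,
                                    centers$flavor))
}

#' Hinge angle at a vertex domain, per frame
#'
#' `theta = arccos( BA . BC / (|BA| |BC|) )` where `B` is the vertex domain
#' centre and `A`, `C` the flanking domain centres (conventionally the
#' unweighted `"cog"` flavor).
#'
#' @param centers an [domain_centers()] result.
#' @param a,c flanking domain names (the angle is symmetric in `a` and `c`).
#' @param vertex vertex domain name.
#' @return an [metric_series()] in degrees, range \[0, 180\].
#' @export
hinge_angle <- function(centers, a, vertex, c) {
  ba <- center_of(centers, a) - center_of(centers, vertex)
  bc <- center_of(centers, c) - center_of(centers, vertex)
  na_ <- sqrt(rowSums(ba^2))
  nc_ <- sqrt(rowSums(bc^2))
  if (any(na_ < 1e-9) || any(nc_ < 1e-9))
    abort_degenerate("coincident domain centers: hinge angle undefined")
  cosv <- pmin(1, pmax(-1, rowSums(ba * bc) / (na_ * nc_)))
  metric_series("angle", acos(cosv) * 180 / pi, centers$times, "degree",
                sprintf("%s-%s-%s (%s centers)", a, vertex, c, centers$flavor))
}
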