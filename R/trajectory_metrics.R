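# Stability metrics: per-frame RMSD (whole protein and per domain),
# per-residue RMSF about the trajectory-average structure, and a
# sliding-window estimate of the equilibration point that separates the
# equilibration transient from the production run.

#' Per-frame RMSD against a reference structure
#'
#' Each frame is rigid-body superposed onto the reference over
#' `fit_indices`, then the root-mean-square deviation is taken over
#' `measure_indices`.
#'
#' @param traj an `mdh_traj`.
#' @param reference reference coordinates: an `mdh_structure`, an `n x 3`
#'   matrix, or a frame index into `traj` (default 1, the first frame).
#' @param fit_indices atom indices used for the superposition; default all
#'   C-alpha atoms.
#' @param measure_indices atom indices over which the deviation is measured;
#'   default the fit indices.
#' @return an [metric_series()] in Angstrom.
#' @export
rmsd_series <- function(traj, reference = 1L, fit_indices = NULL,
                        measure_indices = NULL) {
  if (is.null(fit_indices)) fit_indices <- select_atoms(traj, "CA")
  if (is.null(measure_indices)) measure_indices <- fit_indices
  ref <- if (is.numeric(reference) && length(reference) == 1L)
    coords_of(traj, reference) else coords_of(reference)
  if (nrow(ref) != nrow(traj$atoms))
    abort_shape("reference atom count differs from trajectory topology")
  vals <- vapply(seq_len(n_frames(traj)), function(f) {
    fit_rmsd(coords_of(traj, f), ref, fit_indices, measure_indices)
  }, numeric(1))
  metric_series("rmsd", vals, traj$times, "angstrom",
                sprintf("fit %d atoms / measure %d atoms",
                        length(fit_indices), length(measure_indices)))
}

#' Per-domain RMSD with independent per-domain superposition
#'
#' For each named domain, both the fit and the measurement use that domain's
#' C-alpha atoms only, so the series tracks internal domain stability and is
#' blind to rigid-body inter-domain motion.
#'
#' @param traj an `mdh_traj`.
#' @param reference as in [rmsd_series()].
#' @param domains an [domain_set()]; every domain must resolve to at least 3
#'   C-alpha atoms.
#' @return a named list of [metric_series()], one per domain.
#' @export
per_domain_rmsd <- function(traj, reference = 1L, domains) {
  ref <- if (is.numeric(reference) && length(reference) == 1L)
    coords_of(traj, reference) else coords_of(reference)
  out <- list()
  for (dn in names(domains$domains)) {
    idx <- select_atoms(traj, paste0("CA and domain ", dn), domains)
    if (length(idx) < 3L)
      abort_degenerate(sprintf("domain '%s' has fewer than 3 C-alpha atoms", dn))
    vals <- vapply(seq_len(n_frames(traj)), function(f) {
      fit_rmsd(coords_of(traj, f), ref, idx, idx)
    }, numeric(1))
    out[[dn]] <- metric_series("rmsd", vals, traj$times, "angstrom",
                               sprintf("CA of domain %s (per-domain fit)", dn))
  }
  out
}

#' Per-residue RMSF about the trajectory-average structure
#'
#' The trajectory is first aligned to its first frame over the measured
#' atoms, the average structure is computed, the original frames are then
#' re-aligned to that average (one iteration, which is standard and
#' deterministic), and the RMSF of each measured atom is taken about the
#' average structure.
#'
#' @param traj an `mdh_traj` with at least 2 frames.
#' @param measure_indices atom indices (default: all C-alpha atoms).
#' @param fit_indices atom indices used for the alignments (default: the
#'   measured atoms); a separate fit selection lets fluctuations of mobile
#'   atoms be measured relative to a stable scaffold.
#' @param offset numbering offset subtracted from file residue numbers so the
#'   profile is reported in sequence numbering (default 0).
#' @param error_on_single if `TRUE`, a single-frame trajectory is an error;
#'   otherwise (default) it yields an all-zero profile with a warning.
#' @return a list of class `mdh_profile` with `residues` (sequence
#'   numbering), `values` (Angstrom) and `units`.
#' @export
rmsf_profile <- function(traj, measure_indices = NULL, fit_indices = NULL,
                         offset = 0L, error_on_single = FALSE) {
  if (is.null(measure_indices)) measure_indices <- select_atoms(traj, "CA")
  if (is.null(fit_indices)) fit_indices <- measure_indices
  res <- traj$atoms$resno[measure_indices] - offset
  nf <- n_frames(traj)
  if (nf < 2L) {
    if (error_on_single) abort_param("RMSF requires at least 2 frames")
    warning("single-frame trajectory: RMSF is identically zero")
    return(structure(list(residues = res,
                          values = numeric(length(measure_indices)),
                          units = "angstrom"), class = "mdh_profile"))
  }
  use <- sort(unique(c(fit_indices, measure_indices)))
  fit_in_use <- match(fit_indices, use)
  measure_in_use <- match(measure_indices, use)
  sub <- function(f) coords_of(traj, f)[use, , drop = FALSE]
  ref1 <- sub(1L)
  aligned <- lapply(seq_len(nf), function(f)
    kabsch_superpose(sub(f), ref1, fit_in_use)$coords)
  avg <- Reduce(`+`, aligned) / nf
  dev2 <- matrix(0, nf, length(measure_indices))
  for (f in seq_len(nf)) {
    x <- kabsch_superpose(sub(f), avg, fit_in_use)$coords
    dev2[f, ] <- rowSums((x[measure_in_use, , drop = FALSE] -
                          avg[measure_in_use, , drop = FALSE])^2)
  }
  structure(list(residues = res, values = sqrt(colMeans(dev2)),
                 units = "angstrom"), class = "mdh_profile")
}

#' @export
print.mdh_profile <- function(x, ...) {
  cat(sprintf("<mdh_profile> %d residues, RMSF %.3g-%.3g %s\n",
              length(x$residues), min(x$values), max(x$values), x$units))
  invisible(x)
}

#' Estimate the equilibration point of a metric series
#'
#' Scans candidate start frames at window boundaries and accepts the
#' earliest start such that, over every subsequent full window of the
#' series, (i) the least-squares slope satisfies `|slope| <= slope_tol` and
#' (ii) window means differ from each other by at most twice the pooled
#' within-window standard deviation.  Frames at and after the accepted start
#' constitute the production run.  A drifting series that never satisfies
#' the test returns `NA` (the "not equilibrated" sentinel).
#'
#' @param series an [metric_series()].
#' @param window window length in frames; default 10% of the series (at
#'   least 5 frames).
#' @param slope_tol slope tolerance in series-units per ns (default 0.02).
#' @return the equilibration time in ns, with attribute `frame` (the first
#'   production frame index), or `NA_real_` if no start qualifies.
#' @export
estimate_equilibration <- function(series, window = NULL, slope_tol = 0.02) {
  v <- series$values
  tt <- series$times
  n <- length(v)
  if (is.null(window)) window <- max(5L, floor(0.1 * n))
  window <- as.integer(window)
  if (n < 2L * window)
    abort_param("series must span at least two windows")
  starts <- seq(1L, n - 2L * window + 1L, by = window)
  for (s in starts) {
    nw <- (n - s + 1L) %/% window
    ok <- TRUE
    means <- numeric(nw)
    vars <- numeric(nw)
    for (w in seq_len(nw)) {
      i <- s + (w - 1L) * window
      j <- i + window - 1L
      slope <- coef(lm(v[i:j] ~ tt[i:j]))[2]
      if (!is.finite(slope) || abs(slope) > slope_tol) { ok <- FALSE; break }
      means[w] <- mean(v[i:j])
      vars[w] <- var(v[i:j])
    }
    if (!ok) next
    pooled <- sqrt(mean(vars))
    if (max(means) - min(means) > 2 * pooled && pooled > 0) next
    out <- tt[s]
    attr(out, "frame") <- s
    return(out)
  }
  NA_real_
}
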