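# The delta-RMSD open/closed progress variable: for each frame, the RMSD to
# a closed reference and to an open reference are computed with independent
# superpositions, and their difference locates the frame between the two
# conformations.  Negative values are closed-like, positive open-like, and
# values near zero are intermediate.

#' Delta-RMSD progress variable between two reference conformations
#'
#' For each frame, `sigma_closed` and `sigma_open` are superposition-fit
#' RMSDs to the two references, each with its own independent fit over
#' `indices`; `delta = sigma_closed - sigma_open`.
#'
#' @param traj an `mdh_traj`.
#' @param ref_closed,ref_open reference coordinates (`mdh_structure` or
#'   `n x 3` matrix), atom-compatible with the trajectory topology.
#' @param indices atom indices used for fit and measurement (default: all
#'   C-alpha atoms).
#' @return an object of class `mdh_delta`: list with `delta`,
#'   `sigma_closed`, `sigma_open`, `times` (ns) and `D`, the inter-reference
#'   RMSD (after superposition over the same indices).
#' @export
delta_rmsd <- function(traj, ref_closed, ref_open, indices = NULL) {
  if (is.null(indices)) indices <- select_atoms(traj, "CA")
  rc <- coords_of(ref_closed)
  ro <- coords_of(ref_open)
  if (nrow(rc) != nrow(traj$atoms) || nrow(ro) != nrow(traj$atoms))
    abort_shape("reference atom count differs from trajectory topology")
  nf <- n_frames(traj)
  sc <- numeric(nf)
  so <- numeric(nf)
  for (f in seq_len(nf)) {
    x <- coords_of(traj, f)
    sc[f] <- fit_rmsd(x, rc, indices)
    so[f] <- fit_rmsd(x, ro, indices)
  }
  structure(list(delta = sc - so, sigma_closed = sc, sigma_open = so,
                 times = traj$times,
                 D = fit_rmsd(rc, ro, indices)),
            class = "mdh_delta")
}

#' @export
print.mdh_delta <- function(x, ...) {
  cat(sprintf("<mdh_delta> %d frames, D = %.3g A, mean delta = %.3g A\n",
              length(x$delta), x$D, mean(x$delta)))
  invisible(x)
}

#' Classify frames and systems as closed-like, open-like or intermediate
#'
#' A frame is `closed` if `delta < -threshold_frac * D`, `open` if
#' `delta > +threshold_frac * D`, and `intermediate` otherwise, where `D` is
#' the inter-reference RMSD.  The per-system call is the majority label over
#' the production run.
#'
#' @param dser an [delta_rmsd()] result.
#' @param threshold_frac fraction of `D` defining the intermediate band
#'   (default 0.2).
#' @param production_start first production frame index (default 1).
#' @return a list with `frame_labels` (factor per frame), `system_label`,
#'   `fractions` (named, over production frames) and `threshold_frac`.
#' @export
classify_state <- function(dser, threshold_frac = 0.2, production_start = 1L) {
  if (dser$D <= 1e-12)
    abort_degenerate("identical references: state classification undefined")
  thr <- threshold_frac * dser$D
  lab <- ifelse(dser$delta < -thr, "closed",
                ifelse(dser$delta > thr, "open", "intermediate"))
  lab <- factor(lab, levels = c("closed", "intermediate", "open"))
  prod <- lab[production_start:length(lab)]
  frac <- table(prod) / length(prod)
  list(frame_labels = lab,
       system_label = names(frac)[which.max(frac)],
       fractions = c(frac),
       threshold_frac = threshold_frac)
}

#' Detect the onset of a conformational transition in a scalar series
#'
#' Establishes a baseline over the initial fraction of the series and
#' reports the first frame at which the value departs from the baseline mean
#' by more than `n_sd` baseline standard deviations for at least `min_run`
#' consecutive frames.
#'
#' @param x an [delta_rmsd()] result (the `delta` component is used), an
#'   [metric_series()], or a numeric vector.
#' @param baseline_frac initial fraction of frames taken as baseline
#'   (default 0.25).
#' @param n_sd detection threshold in baseline standard deviations
#'   (default 6).
#' @param min_run consecutive frames required beyond threshold (default 3).
#' @return the first transition frame index (integer), or `NA_integer_` if
#'   no departure is found.
#' @export
detect_transition <- function(x, baseline_frac = 0.25, n_sd = 6, min_run = 3L) {
  v <- if (inherits(x, "mdh_delta")) x$delta
       else if (inherits(x, "mdh_series")) x$values
       else as.numeric(x)
  n <- length(v)
  nb <- max(5L, floor(baseline_frac * n))
  if (n <= nb) abort_param("series too short for baseline estimation")
  mu <- mean(v[1:nb])
  s <- sd(v[1:nb])
  if (s == 0) s <- .Machine$double.eps
  out <- abs(v - mu) > n_sd * s
  run <- 0L
  for (i in seq_len(n)) {
    run <- if (out[i]) run + 1L else 0L
    if (run >= min_run) return(i - min_run + 1L)
  }
  NA_integer_
}
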