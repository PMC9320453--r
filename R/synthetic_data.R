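# Coarse-grained synthetic hinge-protein generator.
#
# Emulates a three-domain protein in which two flanking domains (I and III)
# swing about a central domain (II): rigid spherical shells of pseudo
# C-alpha beads joined by straight linkers, a programmable hinge angle
# theta(t) with an optional closed->open transition, isotropic Gaussian
# thermal noise, and designed domain I - domain III contacts that exist
# only while the hinge is closed.  Every observable the analysis modules
# compute has an exact noise-free ground truth here.

#' Parameters of the synthetic hinge model
#'
#' Domain I and III centres sit at `arm_length` from the domain II centre;
#' the angle between the two arms is the hinge angle.  Domains are rigid
#' shells of `atoms_per_domain` beads of radius `domain_radius`; linkers are
#' straight chains of `linker_length` beads re-anchored every frame.
#'
#' The hinge path is: closed (`theta_closed`) until `transition_frame`, a
#' linear ramp over 10% of the frames to
#' `theta_closed + park_fraction * (theta_open - theta_closed)`, then parked
#' there.  `transition_frame = NULL` keeps the hinge closed throughout;
#' `transition_frame = 0` parks it from the first frame (an "open-start"
#' run when `park_fraction = 1`).
#'
#' @param atoms_per_domain beads per domain (>= 4).
#' @param domain_radius shell radius, Angstrom.
#' @param linker_length beads per linker.
#' @param theta_closed,theta_open hinge angles in degrees,
#'   `0 < theta_closed < theta_open <= 180`.
#' @param arm_length domain II centre to flanking-domain centres, Angstrom.
#' @param noise_sigma Gaussian noise per coordinate, Angstrom.
#' @param n_frames number of frames.
#' @param transition_frame frame at which the closed->open ramp starts
#'   (`NULL` = never, `0` = parked from the start).
#' @param park_fraction where the hinge parks on the closed->open path
#'   (0 = stays closed, 0.5 = intermediate, 1 = fully open).
#' @param designed_contacts list of `c(residue_in_I, residue_in_III)` pairs
#'   (sequence numbering) enforced at salt-bridge range while the hinge is
#'   closed; the pairs are assigned ASP/LYS identities.
#' @param theta_contact hinge angle (degrees) below which designed contacts
#'   are active; default `theta_closed + 5`.
#' @param offset file-numbering offset for the emitted topology (default 0).
#' @param dt frame spacing, ns (default 0.1).
#' @param seed integer seed; all stochasticity flows from it.
#' @return a validated list of class `mdh_hinge_params`.
#' @export
hinge_params <- function(atoms_per_domain = 40L, domain_radius = 8,
                         linker_length = 6L, theta_closed = 60,
                         theta_open = 110, arm_length = 25,
                         noise_sigma = 0.3, n_frames = 400L,
                         transition_frame = NULL, park_fraction = 1,
                         designed_contacts = NULL, theta_contact = NULL,
                         offset = 0L, dt = 0.1, seed = 42L) {
  if (atoms_per_domain < 4L) abort_param("atoms_per_domain must be >= 4")
  if (!(theta_closed > 0 && theta_closed < theta_open && theta_open <= 180))
    abort_param("need 0 < theta_closed < theta_open <= 180")
  if (noise_sigma < 0) abort_param("noise_sigma must be >= 0")
  if (park_fraction < 0 || park_fraction > 1)
    abort_param("park_fraction must lie in [0, 1]")
  if (!is.null(transition_frame) && transition_frame >= n_frames)
    abort_param("transition_frame must be < n_frames")
  if (is.null(theta_contact)) theta_contact <- theta_closed + 5
  p <- list(atoms_per_domain = as.integer(atoms_per_domain),
            domain_radius = domain_radius,
            linker_length = as.integer(linker_length),
            theta_closed = theta_closed, theta_open = theta_open,
            arm_length = arm_length, noise_sigma = noise_sigma,
            n_frames = as.integer(n_frames),
            transition_frame = transition_frame,
            park_fraction = park_fraction,
            designed_contacts = designed_contacts,
            theta_contact = theta_contact,
            offset = as.integer(offset), dt = dt, seed = as.integer(seed))
  structure(p, class = "mdh_hinge_params")
}

# deterministic quasi-uniform points on a sphere (Fibonacci lattice)
fibonacci_sphere <- function(n, radius) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  radius * cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# residue layout: domain I | linker | domain II | linker | domain III
hinge_layout <- function(p) {
  n <- p$atoms_per_domain
  L <- p$linker_length
  dom1 <- 1:n
  link1 <- (n + 1):(n + L)
  dom2 <- (n + L + 1):(2 * n + L)
  link2 <- (2 * n + L + 1):(2 * n + 2 * L)
  dom3 <- (2 * n + 2 * L + 1):(3 * n + 2 * L)
  list(dom1 = dom1, link1 = link1, dom2 = dom2, link2 = link2, dom3 = dom3,
       n_res = 3L * n + 2L * L)
}

#' Domain definitions matching the synthetic topology
#' @param params an [hinge_params()].
#' @return an [domain_set()] with domains `I`, `II`, `III` (linker residues
#'   belong to no domain).
#' @export
hinge_domain_set <- function(params) {
  lay <- hinge_layout(params)
  domain_set(list(I = list(range(lay$dom1)),
                  II = list(range(lay$dom2)),
                  III = list(range(lay$dom3))),
             offset = params$offset)
}

# residue names: LEU/SER alternating inside domains (hydrophobic scaffold
# for the HC graph), GLY linkers, ASP/LYS on designed contact residues
hinge_resnames <- function(p) {
  lay <- hinge_layout(p)
  resid <- rep("GLY", lay$n_res)
  for (dom in list(lay$dom1, lay$dom2, lay$dom3)) {
    resid[dom] <- ifelse(seq_along(dom) %% 2L == 1L, "LEU", "SER")
  }
  for (ct in p$designed_contacts) {
    resid[ct[1]] <- "ASP"
    resid[ct[2]] <- "LYS"
  }
  resid
}

# noise-free coordinates at hinge angle theta (degrees);
# contacts enforced when active
hinge_frame_coords <- function(p, theta, contacts_active) {
  lay <- hinge_layout(p)
  shell <- fibonacci_sphere(p$atoms_per_domain, p$domain_radius)
  th2 <- theta * pi / 360 # theta/2 in radians
  cB <- c(0, 0, 0)
  cA <- p$arm_length * c(cos(th2), sin(th2), 0)
  cC <- p$arm_length * c(cos(th2), -sin(th2), 0)
  x <- matrix(NA_real_, lay$n_res, 3L)
  x[lay$dom1, ] <- sweep(shell, 2L, cA, "+")
  x[lay$dom2, ] <- sweep(shell, 2L, cB, "+")
  x[lay$dom3, ] <- sweep(shell, 2L, cC, "+")
  lin <- function(from, to, k) {
    s <- seq_len(k) / (k + 1)
    cbind(from[1] + s * (to[1] - from[1]),
          from[2] + s * (to[2] - from[2]),
          from[3] + s * (to[3] - from[3]))
  }
  x[lay$link1, ] <- lin(cA, cB, p$linker_length)
  x[lay$link2, ] <- lin(cB, cC, p$linker_length)
  if (length(p$designed_contacts)) {
    # contact beads live on the domain surfaces facing the partner domain;
    # while active they are pulled symmetrically to salt-bridge range
    u <- cC - cA
    u <- u / sqrt(sum(u^2))
    m <- (cA + cC) / 2
    for (ct in p$designed_contacts) {
      if (contacts_active) {
        x[ct[1], ] <- m - 1.75 * u
        x[ct[2], ] <- m + 1.75 * u
      } else {
        x[ct[1], ] <- cA + p$domain_radius * u
        x[ct[2], ] <- cC - p$domain_radius * u
      }
    }
  }
  x
}

# programmed hinge angle per frame
hinge_theta_path <- function(p) {
  park <- p$theta_closed + p$park_fraction * (p$theta_open - p$theta_closed)
  if (is.null(p$transition_frame)) return(rep(p$theta_closed, p$n_frames))
  if (p$transition_frame == 0L) return(rep(park, p$n_frames))
  n_ramp <- max(1L, round(0.1 * p$n_frames))
  theta <- rep(p$theta_closed, p$n_frames)
  ramp <- seq_len(n_ramp)
  idx <- p$transition_frame + ramp - 1L
  idx <- idx[idx <= p$n_frames]
  theta[idx] <- p$theta_closed + (park - p$theta_closed) *
    (ramp[seq_along(idx)] / n_ramp)
  if (p$transition_frame + n_ramp <= p$n_frames)
    theta[(p$transition_frame + n_ramp):p$n_frames] <- park
  theta
}

hinge_topology <- function(p) {
  lay <- hinge_layout(p)
  data.frame(serial = seq_len(lay$n_res), elety = "CA",
             resno = seq_len(lay$n_res) + p$offset,
             resid = hinge_resnames(p), chain = "A", element = "C",
             mass = element_mass("C"), stringsAsFactors = FALSE)
}

#' Noise-free closed and open reference structures
#'
#' @param params an [hinge_params()].
#' @return list with `closed` and `open` (`mdh_structure`s sharing one
#'   topology); designed contacts are enforced in the closed reference
#'   (where the hinge angle is below `theta_contact`) and absent from the
#'   open one.
#' @export
generate_references <- function(params) {
  atoms <- hinge_topology(params)
  mk <- function(theta, id) {
    structure(list(atoms = atoms,
                   coords = hinge_frame_coords(params, theta,
                                               theta <= params$theta_contact),
                   model_id = id),
              class = "mdh_structure")
  }
  list(closed = mk(params$theta_closed, 1L), open = mk(params$theta_open, 2L))
}

#' Generate a synthetic hinge trajectory with ground truth
#'
#' Frames follow the noise-free hinge path plus i.i.d. Gaussian noise of
#' `noise_sigma` per coordinate; all randomness flows from `params$seed`
#' through one stream, so equal parameters give bit-identical output.
#'
#' @param params an [hinge_params()].
#' @return list with `trajectory` (an [mdh_trajectory()]) and
#'   `ground_truth`: list of per-frame noise-free observables `theta_t`
#'   (degrees), `rg_t` (Angstrom, all beads), `com_distance_t` (matrix,
#'   columns `I-II`, `I-III`, `II-III`), `contact_active_t` (logical matrix,
#'   one column per designed contact) and `state_label_t`.
#' @export
generate_trajectory <- function(params) {
  p <- params
  theta <- hinge_theta_path(p)
  atoms <- hinge_topology(p)
  lay <- hinge_layout(p)
  nf <- p$n_frames
  xyz <- array(NA_real_, dim = c(nf, lay$n_res, 3L))
  rg_t <- numeric(nf)
  com_d <- matrix(NA_real_, nf, 3L, dimnames = list(NULL, c("I-II", "I-III", "II-III")))
  n_ct <- length(p$designed_contacts)
  active <- matrix(FALSE, nf, max(1L, n_ct))[, seq_len(n_ct), drop = FALSE]
  m <- atoms$mass
  M <- sum(m)
  doms <- list(I = lay$dom1, II = lay$dom2, III = lay$dom3)
  for (f in seq_len(nf)) {
    act <- theta[f] <= p$theta_contact
    x <- hinge_frame_coords(p, theta[f], act)
    xyz[f, , ] <- x
    com <- colSums(x * m) / M
    rg_t[f] <- sqrt(sum(m * rowSums(sweep(x, 2L, com)^2)) / M)
    ctr <- lapply(doms, function(ii) colSums(x[ii, , drop = FALSE] * m[ii]) / sum(m[ii]))
    com_d[f, ] <- c(sqrt(sum((ctr$I - ctr$II)^2)),
                    sqrt(sum((ctr$I - ctr$III)^2)),
                    sqrt(sum((ctr$II - ctr$III)^2)))
    if (n_ct) active[f, ] <- act
  }
  frac <- (theta - p$theta_closed) / (p$theta_open - p$theta_closed)
  state <- ifelse(frac < 0.2, "closed", ifelse(frac > 0.8, "open", "intermediate"))
  if (p$noise_sigma > 0) {
    set.seed(p$seed)
    xyz <- xyz + array(rnorm(length(xyz), sd = p$noise_sigma), dim = dim(xyz))
  }
  list(trajectory = mdh_trajectory(atoms, xyz, times = seq_len(nf) * p$dt - p$dt),
       ground_truth = list(theta_t = theta, rg_t = rg_t, com_distance_t = com_d,
                           contact_active_t = active, state_label_t = state))
}

#' Write the canonical synthetic fixture set
#'
#' Emits, under `out_dir`: `closed.pdb` and `open.pdb` (references),
#' `traj_closed.pdb` (hinge parked closed), `traj_open.pdb` (parked open
#' from the first frame), `traj_mutantlike.pdb` (closed->intermediate
#' transition at mid-run, `park_fraction = 0.5`), `domains.yaml` and
#' `ground_truth.json`.
#'
#' @param out_dir output directory (created if missing).
#' @param params base [hinge_params()]; per-trajectory seeds are derived
#'   from `params$seed`.
#' @return named character vector of the 7 file paths, invisibly.
#' @export
write_fixture_set <- function(out_dir, params = hinge_params(
                                designed_contacts = list(c(3L, 95L)))) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  refs <- generate_references(params)
  variants <- list(
    traj_closed = modifyList(unclass(params), list(transition_frame = NULL), keep.null = FALSE),
    traj_open = modifyList(unclass(params),
                           list(transition_frame = 0L, park_fraction = 1)),
    traj_mutantlike = modifyList(unclass(params),
                                 list(transition_frame = params$n_frames %/% 2L,
                                      park_fraction = 0.5))
  )
  variants$traj_closed["transition_frame"] <- list(NULL)
  paths <- c(closed = file.path(out_dir, "closed.pdb"),
             open = file.path(out_dir, "open.pdb"))
  write_multimodel_pdb(refs$closed, paths[["closed"]])
  write_multimodel_pdb(refs$open, paths[["open"]])
  gt <- list()
  for (i in seq_along(variants)) {
    nm <- names(variants)[i]
    v <- variants[[i]]
    v$seed <- params$seed + i
    class(v) <- "mdh_hinge_params"
    gen <- generate_trajectory(v)
    path <- file.path(out_dir, paste0(nm, ".pdb"))
    write_multimodel_pdb(gen$trajectory, path)
    paths[[nm]] <- path
    g <- gen$ground_truth
    g$com_distance_t <- as.data.frame(g$com_distance_t, check.names = FALSE)
    gt[[nm]] <- g
  }
  paths[["domains"]] <- file.path(out_dir, "domains.yaml")
  write_domains_yaml(hinge_domain_set(params), paths[["domains"]])
  paths[["ground_truth"]] <- file.path(out_dir, "ground_truth.json")
  jsonlite::write_json(gt, paths[["ground_truth"]], digits = NA, pretty = TRUE)
  invisible(paths)
}
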