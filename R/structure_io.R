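# Containers and I/O: trajectories as multi-model PDB, atom selections,
# domain definitions with a sequence<->file numbering offset, and CSV
# output for per-frame metric series.
#
# Residue numbering convention: everything user-facing is *sequence*
# numbering; `offset` is added to a sequence position to obtain the number
# stored in the PDB file (some reference PDBs number the construct with a
# leading tag, shifting every residue).

# ---------------------------------------------------------------------------
# constructors

#' Build a trajectory object
#'
#' A trajectory is an ordered set of frames sharing one topology.  Coordinates
#' are stored as an `n_frames x n_atoms x 3` array in Angstrom; `times` are
#' frame times in nanoseconds and must be strictly increasing.
#'
#' @param atoms data frame with columns `serial`, `elety` (atom name),
#'   `resno` (file-numbering residue id), `resid` (3-letter residue name),
#'   `chain`, `element`, `mass` (amu).
#' @param xyz numeric array `n_frames x n_atoms x 3` (Angstrom).
#' @param times numeric vector of frame times (ns).
#' @return an object of class `mdh_traj`.
#' @export
mdh_trajectory <- function(atoms, xyz, times = NULL) {
  if (length(dim(xyz)) != 3L || dim(xyz)[3] != 3L)
    abort_shape("xyz must be an n_frames x n_atoms x 3 array")
  n_frames <- dim(xyz)[1]
  n_atoms <- dim(xyz)[2]
  if (n_atoms != nrow(atoms))
    abort_shape(sprintf("topology has %d atoms but frames have %d", nrow(atoms), n_atoms))
  if (n_atoms == 0L) abort_empty("trajectory has no atoms")
  if (n_frames == 0L) abort_empty("trajectory has no frames")
  if (is.null(times)) times <- seq_len(n_frames) * 0.1 - 0.1
  if (length(times) != n_frames)
    abort_shape("length(times) must equal the number of frames")
  if (n_frames > 1 && any(diff(times) <= 0))
    abort_param("frame times must be strictly increasing")
  if (!all(is.finite(xyz))) abort_param("coordinates must be finite")
  if (any(atoms$mass <= 0)) abort_param("atom masses must be positive")
  structure(list(atoms = atoms, xyz = xyz, times = as.numeric(times)),
            class = "mdh_traj")
}

#' Extract one frame of a trajectory as a structure
#'
#' @param traj an `mdh_traj`.
#' @param i frame index (1-based).
#' @return an object of class `mdh_structure` with fields `atoms`,
#'   `coords` (`n_atoms x 3` matrix) and `model_id`.
#' @export
traj_frame <- function(traj, i = 1L) {
  if (i < 1L || i > n_frames(traj)) abort_param("frame index out of range")
  structure(list(atoms = traj$atoms,
                 coords = matrix(traj$xyz[i, , ], ncol = 3L),
                 model_id = as.integer(i)),
            class = "mdh_structure")
}

#' @export
print.mdh_traj <- function(x, ...) {
  cat(sprintf("<mdh_traj> %d frames, %d atoms, %.4g-%.4g ns\n",
              n_frames(x), nrow(x$atoms), x$times[1], x$times[length(x$times)]))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj an `mdh_traj`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) dim(traj$xyz)[1]

# coordinates of a structure or of a trajectory frame as an n x 3 matrix
coords_of <- function(x, frame = 1L) {
  if (inherits(x, "mdh_structure")) return(x$coords)
  if (inherits(x, "mdh_traj")) return(matrix(x$xyz[frame, , ], ncol = 3L))
  if (is.matrix(x) && ncol(x) == 3L) return(x)
  abort_shape("expected an mdh_structure, mdh_traj or n x 3 matrix")
}

# ---------------------------------------------------------------------------
# PDB I/O (multi-model)

# standard atomic masses (amu) for the elements found in protein structures;
# unknown elements fall back to carbon (the C-alpha coarse-model convention)
ELEMENT_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
                  P = 30.974, SE = 78.971, FE = 55.845, ZN = 65.38, MG = 24.305)

element_mass <- function(element) {
  m <- ELEMENT_MASS[toupper(trimws(element))]
  m[is.na(m)] <- ELEMENT_MASS[["C"]]
  unname(m)
}

# Scan raw PDB text and report the number of coordinate records per model,
# so that malformed files produce an error naming the offending model.
scan_model_counts <- function(lines) {
  rec <- substr(lines, 1, 6)
  is_atom <- rec == "ATOM  " | rec == "HETATM"
  is_model <- startsWith(lines, "MODEL")
  is_end <- startsWith(lines, "ENDMDL")
  if (!any(is_model)) {
    return(if (any(is_atom)) sum(is_atom) else integer(0))
  }
  model_id <- cumsum(is_model)
  in_model <- model_id > 0 & cumsum(is_end) < model_id
  tab <- table(factor(model_id[is_atom & in_model], levels = seq_len(max(model_id))))
  as.integer(tab)
}

#' Read a multi-model PDB file as a trajectory
#'
#' Each `MODEL`/`ENDMDL` block becomes one frame; the topology is taken from
#' the first model and the atom count of every subsequent model is validated
#' against it.  A file without `MODEL` records yields a one-frame trajectory.
#' Masses are assigned per element from a standard atomic-mass table; a
#' C-alpha-only coarse model therefore carries the carbon mass (12.011 amu).
#'
#' @param path path to a PDB file.
#' @param dt time spacing between frames in ns (PDB carries no time axis);
#'   default 0.1 ns.
#' @return an [mdh_trajectory()].
#' @export
read_multimodel_pdb <- function(path, dt = 0.1) {
  if (!file.exists(path)) abort_config(sprintf("file not found: %s", path))
  counts <- scan_model_counts(readLines(path, warn = FALSE))
  if (length(counts) == 0L || sum(counts) == 0L)
    abort_empty(sprintf("no models / coordinate records in %s", path))
  if (length(counts) > 1L && any(counts != counts[1])) {
    bad <- which(counts != counts[1])[1]
    abort_format(sprintf(
      "model %d of %s has %d atoms; model 1 has %d", bad, path, counts[bad], counts[1]))
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  nf <- nrow(xyz)
  na <- ncol(xyz) / 3L
  arr <- array(NA_real_, dim = c(nf, na, 3L))
  for (k in 1:3) arr[, , k] <- xyz[, seq(k, by = 3L, length.out = na), drop = FALSE]
  elem <- pdb$atom$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == "")) {
    elem <- substr(trimws(pdb$atom$elety), 1, 1)
  }
  mass <- element_mass(elem)
  atoms <- data.frame(
    serial = pdb$atom$eleno,
    elety = trimws(pdb$atom$elety),
    resno = pdb$atom$resno,
    resid = trimws(pdb$atom$resid),
    chain = ifelse(is.na(pdb$atom$chain), "A", pdb$atom$chain),
    element = elem,
    mass = mass,
    stringsAsFactors = FALSE
  )
  mdh_trajectory(atoms, arr, times = seq_len(nf) * dt - dt)
}

#' Write a trajectory (or structure) as a multi-model PDB file
#'
#' @param traj an `mdh_traj` or `mdh_structure`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_multimodel_pdb <- function(traj, path) {
  if (inherits(traj, "mdh_structure")) {
    traj <- mdh_trajectory(traj$atoms, array(traj$coords, dim = c(1L, nrow(traj$coords), 3L)),
                           times = 0)
  }
  nf <- n_frames(traj)
  na <- nrow(traj$atoms)
  xyz <- matrix(NA_real_, nf, 3L * na)
  for (k in 1:3) xyz[, seq(k, by = 3L, length.out = na)] <- traj$xyz[, , k]
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = traj$atoms$resno, resid = traj$atoms$resid,
                   eleno = traj$atoms$serial, elety = traj$atoms$elety,
                   chain = traj$atoms$chain)
  invisible(path)
}

# ---------------------------------------------------------------------------
# domain definitions

#' Define named domains with a residue-numbering offset
#'
#' @param domains named list; each element is a two-column matrix or a list
#'   of `c(start, end)` inclusive ranges in *sequence* numbering.
#' @param offset integer added to a sequence position to obtain the residue
#'   number used in the structure file (default 0).
#' @return an object of class `mdh_domains`.
#' @export
domain_set <- function(domains, offset = 0L) {
  if (is.null(names(domains)) || any(names(domains) == ""))
    abort_config("every domain must be named")
  norm <- lapply(domains, function(d) {
    m <- if (is.matrix(d)) d else do.call(rbind, lapply(d, function(r) as.integer(r)))
    if (is.null(dim(m))) m <- matrix(as.integer(m), ncol = 2L)
    if (ncol(m) != 2L || any(m[, 1] > m[, 2]))
      abort_config("domain ranges must be [start, end] with start <= end")
    m
  })
  all_res <- unlist(lapply(norm, function(m)
    unlist(apply(m, 1L, function(r) r[1]:r[2], simplify = FALSE))))
  if (anyDuplicated(all_res))
    abort_config("domain residue ranges overlap")
  structure(list(domains = norm, offset = as.integer(offset)), class = "mdh_domains")
}

#' Residues belonging to a domain
#'
#' @param dset an `mdh_domains`.
#' @param name domain name.
#' @param numbering `"sequence"` (default) or `"file"` (offset applied).
#' @return integer vector of residue numbers.
#' @export
domain_residues <- function(dset, name, numbering = c("sequence", "file")) {
  numbering <- match.arg(numbering)
  if (!name %in% names(dset$domains))
    abort_config(sprintf("unknown domain '%s' (have: %s)", name,
                         paste(names(dset$domains), collapse = ", ")))
  m <- dset$domains[[name]]
  res <- unlist(apply(m, 1L, function(r) r[1]:r[2], simplify = FALSE))
  if (numbering == "file") res + dset$offset else res
}

#' Read a domain definition from a YAML file
#'
#' Expected schema: a top-level optional integer `offset`, plus one entry per
#' domain mapping the name to a list of `[start, end]` ranges in sequence
#' numbering.
#'
#' @param path YAML file path.
#' @return an [domain_set()].
#' @export
read_domains_yaml <- function(path) {
  if (!file.exists(path)) abort_config(sprintf("file not found: %s", path))
  y <- yaml::read_yaml(path)
  offset <- if (!is.null(y$offset)) as.integer(y$offset) else 0L
  y$offset <- NULL
  domain_set(y, offset = offset)
}

#' Write a domain definition to a YAML file
#' @param dset an `mdh_domains`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_domains_yaml <- function(dset, path) {
  out <- lapply(dset$domains, function(m)
    lapply(seq_len(nrow(m)), function(i) as.integer(m[i, ])))
  out$offset <- dset$offset
  yaml::write_yaml(out, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# atom selection

#' Select atoms by name, domain and residue range
#'
#' The selection expression is a conjunction of clauses joined by `" and "`.
#' Supported clauses: `"all"`; `"backbone"` (N, CA, C, O); an atom name such
#' as `"CA"` (optionally written `"name CA"`); `"domain <name>"` (requires
#' `domains`); `"residues a-b"` or `"residues a,b,c"` in sequence numbering
#' (`"residue"` also accepted).  The domain-set offset is applied when
#' translating sequence residue numbers to file numbers.
#'
#' @param traj an `mdh_traj` (or `mdh_structure`).
#' @param spec selection expression string.
#' @param domains optional [domain_set()]; required for `domain` clauses and
#'   for the numbering offset (otherwise offset 0).
#' @return integer vector of atom indices in topology order.
#' @export
select_atoms <- function(traj, spec, domains = NULL) {
  atoms <- traj$atoms
  offset <- if (!is.null(domains)) domains$offset else 0L
  keep <- rep(TRUE, nrow(atoms))
  clauses <- trimws(strsplit(spec, "\\band\\b")[[1]])
  clauses <- clauses[clauses != ""]
  if (length(clauses) == 0L) abort_config("empty selection expression")
  for (cl in clauses) {
    if (identical(cl, "all")) next
    if (identical(cl, "backbone")) {
      keep <- keep & atoms$elety %in% c("N", "CA", "C", "O")
    } else if (grepl("^domain\\s+", cl)) {
      dn <- sub("^domain\\s+", "", cl)
      if (is.null(domains)) abort_config("selection uses a domain but no domain set given")
      keep <- keep & atoms$resno %in% domain_residues(domains, dn, "file")
    } else if (grepl("^residues?\\s+", cl)) {
      txt <- sub("^residues?\\s+", "", cl)
      res <- integer(0)
      for (piece in strsplit(txt, ",")[[1]]) {
        piece <- trimws(piece)
        if (grepl("-", piece)) {
          ab <- as.integer(strsplit(piece, "-")[[1]])
          res <- c(res, ab[1]:ab[2])
        } else res <- c(res, as.integer(piece))
      }
      keep <- keep & atoms$resno %in% (res + offset)
    } else {
      nm <- sub("^name\\s+", "", cl)
      keep <- keep & atoms$elety == nm
    }
  }
  idx <- which(keep)
  if (length(idx) == 0L) abort_empty(sprintf("selection '%s' matches no atoms", spec))
  idx
}

# ---------------------------------------------------------------------------
# metric series

#' Construct a per-frame metric series
#'
#' @param metric short metric name (e.g. `"rmsd"`).
#' @param values per-frame scalar values.
#' @param times frame times (ns).
#' @param units unit string (e.g. `"angstrom"`, `"degree"`).
#' @param selection free-text description of the atom selection used.
#' @return an object of class `mdh_series`.
#' @export
metric_series <- function(metric, values, times, units, selection = "") {
  if (length(values) != length(times))
    abort_shape("values and times must have equal length")
  if (!all(is.finite(values))) abort_param("metric values must be finite")
  structure(list(metric = metric, values = as.numeric(values),
                 times = as.numeric(times), units = units,
                 selection = selection),
            class = "mdh_series")
}

#' @export
print.mdh_series <- function(x, ...) {
  cat(sprintf("<mdh_series> %s [%s], %d frames, mean %.4g\n",
              x$metric, x$units, length(x$values), mean(x$values)))
  invisible(x)
}

#' Write a metric series to CSV
#'
#' Produces a two-column file (`time_ns`, `value`) preceded by one comment
#' line carrying the metric name, units and selection.  Values round-trip
#' through [read_metric_series()] to better than 1e-6 relative.
#'
#' @param series an [metric_series()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metric_series <- function(series, path) {
  if (!inherits(series, "mdh_series")) abort_shape("expected an mdh_series")
  if (length(series$values) == 0L) abort_empty("refusing to write an empty series")
  con <- tryCatch(file(path, "w"), error = function(e)
    abort_config(sprintf("cannot open '%s' for writing", path)))
  on.exit(close(con))
  writeLines(sprintf("# metric: %s; units: %s; selection: %s",
                     series$metric, series$units, series$selection), con)
  writeLines("time_ns,value", con)
  writeLines(paste(format(series$times, digits = 12, trim = TRUE, scientific = FALSE),
                   format(series$values, digits = 12, trim = TRUE, scientific = FALSE),
                   sep = ","), con)
  invisible(path)
}

#' Read a metric series written by [write_metric_series()]
#' @param path CSV path.
#' @return an [metric_series()].
#' @export
read_metric_series <- function(path) {
  if (!file.exists(path)) abort_config(sprintf("file not found: %s", path))
  header <- readLines(path, n = 1L)
  meta <- regmatches(header,
                     regexec("# metric: (.*); units: (.*); selection: (.*)", header))[[1]]
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  metric_series(metric = meta[2], values = df$value, times = df$time_ns,
                units = meta[3], selection = meta[4])
}
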