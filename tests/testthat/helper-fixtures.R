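# Shared fixtures and independent oracles, built in code.

# minimal C-alpha topology for n residues
ca_atoms <- function(n, resid = "ALA", offset = 0L) {
  data.frame(serial = seq_len(n), elety = "CA", resno = seq_len(n) + offset,
             resid = rep_len(resid, n), chain = "A", element = "C",
             mass = 12.011, stringsAsFactors = FALSE)
}

# trajectory from a list of n x 3 coordinate matrices
traj_from_coords <- function(coord_list, atoms = NULL, dt = 0.1) {
  n <- nrow(coord_list[[1]])
  if (is.null(atoms)) atoms <- ca_atoms(n)
  xyz <- array(NA_real_, dim = c(length(coord_list), n, 3L))
  for (f in seq_along(coord_list)) xyz[f, , ] <- coord_list[[f]]
  mdh_trajectory(atoms, xyz, times = seq_along(coord_list) * dt - dt)
}

# random proper rotation via normalised quaternion
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2),
         3L, 3L, byrow = TRUE)
}

# independent brute-force superposition oracle: centroid alignment plus the
# best of n_rot random proper rotations (never calls the package's Kabsch)
brute_force_rmsd <- function(mobile, reference, n_rot = 10000L) {
  A <- sweep(mobile, 2L, colMeans(mobile))
  B <- sweep(reference, 2L, colMeans(reference))
  Rs <- replicate(n_rot, random_rotation(), simplify = FALSE)
  Rstack <- do.call(cbind, lapply(Rs, t)) # columns 3k-2..3k hold t(R_k)
  AR <- A %*% Rstack                      # n x (3 n_rot)
  sq <- (AR - B[, rep(1:3, n_rot)])^2
  msd <- colSums(matrix(colSums(sq), nrow = 3L)) / nrow(A)
  sqrt(min(msd))
}

# star-shaped salt-bridge records: `center` bonded to each of `leaves`
star_records <- function(center, leaves) {
  data.frame(residue_a = pmin(center, leaves), residue_b = pmax(center, leaves),
             class = "SB", persistence = 1.0)
}

# write a small multi-model PDB by hand (independent of the package writer)
write_raw_pdb <- function(path, models) {
  lines <- character(0)
  for (m in seq_along(models)) {
    x <- models[[m]]
    lines <- c(lines, sprintf("MODEL     %4d", m))
    for (i in seq_len(nrow(x))) {
      lines <- c(lines, sprintf(
        "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        i, i, x[i, 1], x[i, 2], x[i, 3]))
    }
    lines <- c(lines, "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  path
}
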