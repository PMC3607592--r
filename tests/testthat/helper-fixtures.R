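# shared fixtures and independent oracles; everything is built in code

# a hand-written PDB: n residues of glycine backbone, coordinates in Angstrom
make_pdb_text <- function(coords_ang, resid = NULL, names = NULL,
                          het = FALSE) {
  n <- nrow(coords_ang)
  if (is.null(resid)) resid <- seq_len(n)
  if (is.null(names)) names <- rep("CA", n)
  rec <- if (het) "HETATM" else "ATOM  "
  vapply(seq_len(n), function(i)
    sprintf("%s%5d  %-3s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            rec, i, names[i], if (het) "LIG" else "GLY", resid[i],
            coords_ang[i, 1], coords_ang[i, 2], coords_ang[i, 3]),
    ""
  )
}

# toy structure with one CA atom per residue at given nm coordinates
toy_structure <- function(xyz, resid = seq_len(nrow(xyz)),
                          name = rep("CA", nrow(xyz)), label = "toy") {
  atoms <- data.frame(serial = seq_len(nrow(xyz)), name = name,
                      resid = resid, resname = "GLY", chain = "A",
                      element = "C", het = FALSE,
                      stringsAsFactors = FALSE)
  new_structure(atoms, xyz, label)
}

toy_trajectory <- function(frames, dt = 1) {
  nat <- nrow(frames[[1]])
  coords <- array(NA_real_, c(length(frames), nat, 3))
  for (k in seq_along(frames)) coords[k, , ] <- frames[[k]]
  new_trajectory(coords, (seq_along(frames) - 1) * dt,
                 toy_structure(frames[[1]]))
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b),
           a^2 - b^2 - c^2 + d^2),
         3, 3, byrow = TRUE)
}

# Horn's quaternion method: independent oracle for the optimal rigid fit
quaternion_superpose <- function(mobile, reference) {
  cm <- colMeans(mobile); cr <- colMeans(reference)
  a <- sweep(mobile, 2, cm); b <- sweep(reference, 2, cr)
  s <- crossprod(a, b)  # S_xy = sum a_x b_y
  key <- matrix(0, 4, 4)
  key[1, 1] <- s[1, 1] + s[2, 2] + s[3, 3]
  key[1, 2] <- key[2, 1] <- s[2, 3] - s[3, 2]
  key[1, 3] <- key[3, 1] <- s[3, 1] - s[1, 3]
  key[1, 4] <- key[4, 1] <- s[1, 2] - s[2, 1]
  key[2, 2] <- s[1, 1] - s[2, 2] - s[3, 3]
  key[2, 3] <- key[3, 2] <- s[1, 2] + s[2, 1]
  key[2, 4] <- key[4, 2] <- s[1, 3] + s[3, 1]
  key[3, 3] <- -s[1, 1] + s[2, 2] - s[3, 3]
  key[3, 4] <- key[4, 3] <- s[2, 3] + s[3, 2]
  key[4, 4] <- -s[1, 1] - s[2, 2] + s[3, 3]
  q <- eigen(key, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rot <- matrix(c(
    w^2 + x^2 - y^2 - z^2, 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), w^2 - x^2 + y^2 - z^2, 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), w^2 - x^2 - y^2 + z^2),
    3, 3, byrow = TRUE)
  fitted <- sweep(a %*% t(rot), 2, cr, "+")
  list(rotation = rot, coords = fitted,
       rmsd = sqrt(mean(rowSums((fitted - reference)^2))))
}

# textbook dihedral via plane normals + sign from the axis triple product;
# independent of the atan2 route used by the implementation
dihedral_oracle <- function(p1, p2, p3, p4) {
  xp <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- xp(b1, b2); n2 <- xp(b2, b3)
  ct <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  ang <- acos(min(1, max(-1, ct))) * 180 / pi
  if (sum(xp(n1, n2) * b2) < 0) ang <- -ang
  if (ang <= -180) ang <- ang + 360
  ang
}

# standard double-well world used by the acceptance suite (criteria 3/4);
# barrier high enough that unbiased runs of the metadynamics length do not
# cross spontaneously
acceptance_double_well <- function() {
  double_well_potential(wells = c(0.53, 1.12), barrier = 9,
                        delta = 1.19, width = 0.1)
}
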