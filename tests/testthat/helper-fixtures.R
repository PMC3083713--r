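# Fixture builders shared across the suite. Everything is generated in
# code; no binary data.

# direct access to the S4 constructors (not exported)
.Structure <- IDPAnchor:::Structure
.Ensemble <- IDPAnchor:::Ensemble

# a bare structure from an atom spec matrix: list(name, resname, chain,
# resno, element) columns + xyz
toyStructure <- function(names, xyz, resname = "DUM", chain = "Z",
                         resno = NULL, element = NULL) {
  n <- length(names)
  atoms <- data.frame(
    name = names,
    resname = rep_len(resname, n),
    chain = rep_len(chain, n),
    resno = if (is.null(resno)) seq_len(n) else resno,
    element = if (is.null(element)) substr(names, 1L, 1L) else element,
    stringsAsFactors = FALSE)
  .Structure(atoms, matrix(xyz, ncol = 3L, byrow = TRUE))
}

# ensemble of rigid-body copies of one structure
rigidCopies <- function(structure, nframes, rotate = FALSE, seed = 1) {
  set.seed(seed)
  natoms <- nAtoms(structure)
  coords <- array(NA_real_, dim = c(nframes, natoms, 3L))
  for (f in seq_len(nframes)) {
    xyz <- getCoords(structure)
    if (rotate) {
      R <- randomRotation()
      xyz <- xyz %*% t(R) + matrix(rnorm(3, sd = 5), natoms, 3L,
                                   byrow = TRUE)
    }
    coords[f, , ] <- xyz
  }
  .Ensemble(atomData(structure), coords, dt = 0.1)
}

# uniform random proper rotation from a random quaternion
randomRotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3L, 3L, byrow = TRUE)
}

# independent quaternion-based RMSD oracle (Horn's closed form): minimum
# RMSD over proper rotations via the largest eigenvalue of the 4x4 key
# matrix. Used only to cross-check superpose().
quaternionRMSD <- function(mobile, ref) {
  M <- scale(mobile, scale = FALSE); Rf <- scale(ref, scale = FALSE)
  S <- t(M) %*% Rf
  K <- matrix(0, 4, 4)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[1, 3] + S[3, 1]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  lmax <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(M^2) + sum(Rf^2) - 2 * lmax) / nrow(M)
  sqrt(max(0, msd))
}

# Monte-Carlo SASA oracle: random points on each expanded sphere,
# occlusion tested against all other atoms. Returns value and MC se.
mcSASA <- function(xyz, radii, probe = 1.4, npts = 2000, seed = 1) {
  set.seed(seed)
  R <- radii + probe
  m <- nrow(xyz)
  val <- numeric(m); se <- numeric(m)
  for (i in seq_len(m)) {
    z <- runif(npts, -1, 1); th <- runif(npts, 0, 2 * pi)
    r <- sqrt(1 - z^2)
    P <- cbind(r * cos(th), r * sin(th), z) * R[i]
    P <- sweep(P, 2L, xyz[i, ], "+")
    exposed <- rep(TRUE, npts)
    for (j in seq_len(m)[-i]) {
      d2 <- (P[, 1] - xyz[j, 1])^2 + (P[, 2] - xyz[j, 2])^2 +
        (P[, 3] - xyz[j, 3])^2
      exposed <- exposed & d2 >= R[j]^2
    }
    p <- mean(exposed)
    val[i] <- p * 4 * pi * R[i]^2
    se[i] <- sqrt(p * (1 - p) / npts) * 4 * pi * R[i]^2
  }
  list(sasa = val, se = se)
}

p53nHelix <- function(chi = list()) buildPeptide(backbone = "helix", chi = chi)
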