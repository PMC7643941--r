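# shared fixtures, built in code

# minimal three-residue PDB text (ALA-ASN-GLY backbone + side chains)
write_toy_pdb <- function(path) {
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
    "ATOM      4  O   ALA A   1       1.251   2.390   0.000  1.00  0.00           O",
    "ATOM      5  CB  ALA A   1       1.988  -0.773  -1.199  1.00  0.00           C",
    "ATOM      6  N   ASN A   2       3.332   1.536   0.000  1.00  0.00           N",
    "ATOM      7  CA  ASN A   2       3.988   2.839   0.000  1.00  0.00           C",
    "ATOM      8  C   ASN A   2       5.504   2.693   0.000  1.00  0.00           C",
    "ATOM      9  O   ASN A   2       6.052   1.590   0.000  1.00  0.00           O",
    "ATOM     10  CB  ASN A   2       3.560   3.668   1.218  1.00  0.00           C",
    "ATOM     11  CG  ASN A   2       4.124   5.078   1.198  1.00  0.00           C",
    "ATOM     12  OD1 ASN A   2       5.197   5.320   0.650  1.00  0.00           O",
    "ATOM     13  ND2 ASN A   2       3.402   6.021   1.793  1.00  0.00           N",
    "ATOM     14  N   GLY A   3       6.186   3.837   0.000  1.00  0.00           N",
    "ATOM     15  CA  GLY A   3       7.637   3.856   0.000  1.00  0.00           C",
    "ATOM     16  C   GLY A   3       8.226   5.257   0.000  1.00  0.00           C",
    "ATOM     17  O   GLY A   3       7.503   6.255   0.000  1.00  0.00           O",
    "END")
  writeLines(lines, path)
  path
}

# n-bead structure with given coordinates, one CA bead per residue
bead_structure <- function(xyz, resno = seq_len(nrow(xyz))) {
  sbm_structure(
    data.frame(elety = "CA", elesy = "C", resid = "GLY", resno = resno,
               chain = "A", stringsAsFactors = FALSE),
    xyz)
}

# trajectory from a list of n x 3 frames
frames_trajectory <- function(frames, topology = NULL) {
  xyz <- do.call(rbind, lapply(frames, function(f) as.numeric(t(f))))
  sbm_trajectory(xyz, step_index = seq_along(frames), topology = topology)
}

# brute-force contact enumeration oracle
brute_contacts <- function(s, cutoff, exclusion, min_dist = 2.5) {
  n <- nrow(s$xyz)
  out <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (abs(s$atoms$resno[i] - s$atoms$resno[j]) < exclusion) next
    d <- sqrt(sum((s$xyz[i, ] - s$xyz[j, ])^2))
    if (d <= cutoff && d >= min_dist)
      out[[length(out) + 1]] <- data.frame(i = i, j = j, r = d)
  }
  if (!length(out)) return(data.frame(i = integer(), j = integer(),
                                      r = numeric()))
  do.call(rbind, out)
}

# finite-difference gradient oracle
fd_gradient <- function(topology, x, h = 1e-6) {
  g <- x * 0
  for (a in seq_len(nrow(x))) for (d in 1:3) {
    xp <- x; xp[a, d] <- xp[a, d] + h
    xm <- x; xm[a, d] <- xm[a, d] - h
    g[a, d] <- (evaluate_potential(topology, xp)$energy[["total"]] -
                  evaluate_potential(topology, xm)$energy[["total"]]) / (2 * h)
  }
  g
}

# five-bead topology exercising every energy term type
all_terms_topology <- function() {
  sbm_topology(
    masses = rep(1, 5),
    bonds = data.frame(i = 1:4, j = 2:5, r0 = c(3, 3, 2.8, 2.9), eps = 50),
    angles = data.frame(i = 1:3, j = 2:4, k = 3:5,
                        theta0 = c(1.9, 2.1, 2.0), eps = 40),
    impropers = data.frame(i = 1, j = 2, k = 3, l = 4, chi0 = 0.4,
                           eps = 10),
    planars = data.frame(i = 2, j = 3, k = 4, l = 5, chi0 = -0.3,
                         eps = 40),
    propers = data.frame(i = 1, j = 2, k = 3, l = 5, phi0 = 0.7, eps = 2),
    contacts = data.frame(i = 1, j = 5, r_alpha = 6, r_beta = 9,
                          weight = 1, category = "shared-dual",
                          stringsAsFactors = FALSE))
}

all_terms_coords <- function() {
  matrix(c(0, 0, 0, 3, 0.5, 0.2, 5.5, 2, 1, 7, 4.5, 0.5, 9, 5, 2.5),
         5, 3, byrow = TRUE)
}
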