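#' Dual-basin topology container
#'
#' An `sbm_topology` holds the complete force-field description used by the
#' Langevin engine: harmonic bonds and angles, harmonic improper/planar
#' dihedrals, proper dihedrals with the (1 - cos) + 1/2 (1 - cos 3) form,
#' contacts (single- or dual-basin Gaussian wells), and r^-12 excluded
#' volume for all remaining pairs. Energies are in reduced units of the
#' native contact energy (epsilon_0 = 1); the default term strengths are
#' eps_r = 50, eps_theta = 40, eps_chi_improper = 10, eps_chi_planar = 40,
#' eps_NC = 0.1 with sigma_NC = 2.5 A.
#'
#' @param masses per-atom masses (reduced; unit mass by default).
#' @param bonds data.frame `i, j, r0, eps`.
#' @param angles data.frame `i, j, k, theta0, eps` (radians).
#' @param impropers,planars data.frames `i, j, k, l, chi0, eps` (radians).
#' @param propers data.frame `i, j, k, l, phi0, eps`.
#' @param contacts data.frame `i, j, r_alpha, r_beta, weight, category`;
#'   `NA` in `r_alpha`/`r_beta` marks a single-basin record.
#' @param gauss_A Gaussian well amplitude; 1 gives each well depth -1.
#' @param gauss_sigma Gaussian well width (A).
#' @param eps_nc,sigma_nc excluded-volume strength and size.
#' @param atoms optional atom bookkeeping data.frame carried along.
#' @return An object of class `sbm_topology`.
#' @export
sbm_topology <- function(masses,
                         bonds = empty_bonds(), angles = empty_angles(),
                         impropers = empty_dihedrals(),
                         planars = empty_dihedrals(),
                         propers = empty_dihedrals("phi0"),
                         contacts = empty_contacts(),
                         gauss_A = 1, gauss_sigma = 0.5,
                         eps_nc = 0.1, sigma_nc = 2.5,
                         atoms = NULL) {
  validate_contacts(contacts)
  structure(list(masses = as.numeric(masses), bonds = bonds, angles = angles,
                 impropers = impropers, planars = planars, propers = propers,
                 contacts = contacts, gauss_A = gauss_A,
                 gauss_sigma = gauss_sigma, eps_nc = eps_nc,
                 sigma_nc = sigma_nc, atoms = atoms),
            class = "sbm_topology")
}

empty_bonds <- function()
  data.frame(i = integer(), j = integer(), r0 = numeric(), eps = numeric())
empty_angles <- function()
  data.frame(i = integer(), j = integer(), k = integer(),
             theta0 = numeric(), eps = numeric())
empty_dihedrals <- function(ref = "chi0") {
  d <- data.frame(i = integer(), j = integer(), k = integer(), l = integer(),
                  x0 = numeric(), eps = numeric())
  names(d)[5] <- ref
  d
}
empty_contacts <- function()
  data.frame(i = integer(), j = integer(), r_alpha = numeric(),
             r_beta = numeric(), weight = numeric(),
             category = character(), stringsAsFactors = FALSE)

validate_contacts <- function(contacts) {
  if (!nrow(contacts)) return(invisible(TRUE))
  if (any(contacts$i == contacts$j))
    stop("contact with i == j")
  both_na <- is.na(contacts$r_alpha) & is.na(contacts$r_beta)
  if (any(both_na))
    stop("contact records need at least one native distance")
  dists <- c(contacts$r_alpha, contacts$r_beta)
  if (any(dists <= 0, na.rm = TRUE)) stop("native distances must be > 0")
  if (any(contacts$weight <= 0)) stop("contact weights must be > 0")
  invisible(TRUE)
}

#' @export
print.sbm_topology <- function(x, ...) {
  cc <- table(factor(x$contacts$category,
                     levels = c("shared-dual", "alpha-only", "beta-only",
                                "dye-linker")))
  cat("sbm_topology:", length(x$masses), "atoms |",
      nrow(x$bonds), "bonds,", nrow(x$angles), "angles,",
      nrow(x$impropers) + nrow(x$planars) + nrow(x$propers), "dihedrals\n")
  cat("  contacts:", paste(names(cc), cc, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Compute a native contact map from one conformation
#'
#' All heavy-atom pairs from residues at least `exclusion` apart in
#' sequence whose distance is at most `cutoff` become contact records
#' carrying their native distance. This is a plain distance-cutoff contact
#' definition (not a shadow map); cutoff and exclusion are configurable.
#'
#' @param s an [sbm_structure].
#' @param cutoff distance cutoff in Angstrom (default 4.5).
#' @param exclusion minimum sequence separation in residues (default 3).
#' @param weight contact weight assigned to every record (default 1).
#' @param min_dist pairs closer than this are not contacts (default the
#'   excluded-volume size 2.5 A; a Gaussian well below the r^-12 wall is
#'   unphysically stiff).
#' @return data.frame of contact records ordered by (i, j), with the native
#'   distance in `r_alpha`.
#' @export
compute_contact_map <- function(s, cutoff = 4.5, exclusion = 3, weight = 1,
                                min_dist = 2.5) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  xyz <- s$xyz
  n <- nrow(xyz)
  resno <- s$atoms$resno
  # block over i to bound memory on large structures
  out_i <- integer(); out_j <- integer(); out_r <- numeric()
  block <- 512L
  for (start in seq(1L, n, by = block)) {
    rows <- start:min(start + block - 1L, n)
    d2 <- outer(rowSums(xyz[rows, , drop = FALSE]^2), rowSums(xyz^2), "+") -
      2 * xyz[rows, , drop = FALSE] %*% t(xyz)
    d2[d2 < 0] <- 0
    sep_ok <- abs(outer(resno[rows], resno, "-")) >= exclusion
    upper <- outer(rows, seq_len(n), "<")
    hit <- which(sep_ok & upper & d2 <= cutoff^2 & d2 >= min_dist^2,
                 arr.ind = TRUE)
    if (nrow(hit)) {
      out_i <- c(out_i, rows[hit[, 1]])
      out_j <- c(out_j, hit[, 2])
      out_r <- c(out_r, sqrt(d2[hit]))
    }
  }
  ord <- order(out_i, out_j)
  data.frame(i = out_i[ord], j = out_j[ord], r_alpha = out_r[ord],
             r_beta = rep(NA_real_, length(ord)),
             weight = rep(weight, length(ord)),
             category = rep("alpha-only", length(ord)),
             stringsAsFactors = FALSE)
}

#' Build a dual-basin topology from two conformations
#'
#' The two structures must share an identical atom ordering. Contacts found
#' in both conformations become shared-dual records with both native
#' distances; contacts unique to one conformation become single-basin
#' records. Bonded terms (bonds, angles, proper dihedrals) are taken from a
#' designated reference conformation. The Gaussian amplitude defaults to 1
#' so that each well has depth -1 (times the contact weight).
#'
#' @param open,closed [sbm_structure] objects for the alpha (open) and beta
#'   (closed) conformations.
#' @param options list of build options:
#'   \describe{
#'     \item{cutoff, exclusion}{contact-map parameters (4.5 A, 3 residues).}
#'     \item{reference}{"open" or "closed": source of bonded terms.}
#'     \item{bond_pairs}{optional two-column matrix of atom-index bonds;
#'       when absent, bonds are detected by covalent distance (< 1.9 A,
#'       2.2 A when sulfur is involved).}
#'     \item{beta_only_weight}{weight applied to closed-state-specific
#'       contacts (default 0.33, the midpoint of the 0.2-0.46 calibration
#'       range; see [scan_contact_weight]).}
#'     \item{unit_masses}{logical, use unit masses (default TRUE; reduced
#'       units).}
#'     \item{gauss_sigma}{Gaussian well width (default 0.5 A).}
#'     \item{dihedrals}{logical, enumerate proper dihedrals from the bond
#'       graph (default TRUE).}
#'     \item{dihedral_contact_ratio}{total dihedral strength as a fraction
#'       of total contact strength (default 0.5), split 2:1 between
#'       backbone and side-chain dihedrals.}
#'   }
#' @return An [sbm_topology].
#' @export
build_dual_basin_topology <- function(open, closed, options = list()) {
  opt <- modifyList(list(cutoff = 4.5, exclusion = 3, reference = "open",
                         bond_pairs = NULL, beta_only_weight = 0.33,
                         unit_masses = TRUE, gauss_sigma = 0.5,
                         dihedrals = TRUE, dihedral_contact_ratio = 0.5),
                    options)
  same <- open$atoms$elety == closed$atoms$elety &
    open$atoms$resno == closed$atoms$resno
  if (nrow(open$atoms) != nrow(closed$atoms) || !all(same)) {
    first <- if (nrow(open$atoms) != nrow(closed$atoms))
      min(nrow(open$atoms), nrow(closed$atoms)) + 1L else which(!same)[1]
    stop("atom-ordering mismatch between conformations at atom ", first)
  }
  ref <- if (opt$reference == "open") open else closed
  n <- nrow(ref$atoms)

  map_a <- compute_contact_map(open, opt$cutoff, opt$exclusion)
  map_b <- compute_contact_map(closed, opt$cutoff, opt$exclusion)
  key_a <- paste(map_a$i, map_a$j)
  key_b <- paste(map_b$i, map_b$j)
  shared <- intersect(key_a, key_b)
  ia <- match(shared, key_a); ib <- match(shared, key_b)
  contacts <- rbind(
    if (length(shared))
      data.frame(i = map_a$i[ia], j = map_a$j[ia],
                 r_alpha = map_a$r_alpha[ia], r_beta = map_b$r_alpha[ib],
                 weight = 1, category = "shared-dual",
                 stringsAsFactors = FALSE),
    {
      aa <- map_a[!(key_a %in% key_b), , drop = FALSE]
      aa$category <- rep("alpha-only", nrow(aa))
      aa
    },
    {
      only_b <- !(key_b %in% key_a)
      bb <- map_b[only_b, , drop = FALSE]
      data.frame(i = bb$i, j = bb$j, r_alpha = rep(NA_real_, nrow(bb)),
                 r_beta = bb$r_alpha,
                 weight = rep(opt$beta_only_weight, nrow(bb)),
                 category = rep("beta-only", nrow(bb)),
                 stringsAsFactors = FALSE)
    })
  contacts <- contacts[order(contacts$i, contacts$j), , drop = FALSE]
  rownames(contacts) <- NULL

  bp <- opt$bond_pairs
  if (is.null(bp)) bp <- detect_covalent_bonds(ref)
  bp <- as.matrix(bp)
  if (nrow(bp) && nrow(contacts)) { # a bonded pair is never also a contact
    bond_key <- paste(pmin(bp[, 1], bp[, 2]), pmax(bp[, 1], bp[, 2]))
    ckey <- paste(pmin(contacts$i, contacts$j), pmax(contacts$i, contacts$j))
    contacts <- contacts[!(ckey %in% bond_key), , drop = FALSE]
  }
  bonds <- if (nrow(bp)) data.frame(
    i = bp[, 1], j = bp[, 2],
    r0 = sqrt(rowSums((ref$xyz[bp[, 1], , drop = FALSE] -
                         ref$xyz[bp[, 2], , drop = FALSE])^2)),
    eps = 50) else empty_bonds()

  adj <- vector("list", n)
  for (r in seq_len(nrow(bonds))) {
    adj[[bonds$i[r]]] <- c(adj[[bonds$i[r]]], bonds$j[r])
    adj[[bonds$j[r]]] <- c(adj[[bonds$j[r]]], bonds$i[r])
  }
  angles <- enumerate_angles(adj, ref$xyz)
  propers <- if (opt$dihedrals) enumerate_propers(adj, ref, opt) else
    empty_dihedrals("phi0")
  # normalize total dihedral strength to a fixed fraction of total contact
  # strength, preserving the backbone : side-chain 2 : 1 split
  if (nrow(propers) && nrow(contacts) && opt$dihedral_contact_ratio > 0) {
    target <- opt$dihedral_contact_ratio * sum(contacts$weight)
    propers$eps <- propers$eps * target / sum(propers$eps)
  }

  masses <- if (opt$unit_masses) rep(1, n) else
    .element_mass(ref$atoms$elesy)
  sbm_topology(masses = masses, bonds = bonds, angles = angles,
               propers = propers, contacts = contacts,
               gauss_A = 1, gauss_sigma = opt$gauss_sigma,
               atoms = ref$atoms)
}

detect_covalent_bonds <- function(s) {
  xyz <- s$xyz
  n <- nrow(xyz)
  is_s <- toupper(s$atoms$elesy) == "S"
  out <- matrix(integer(), 0, 2)
  block <- 512L
  for (start in seq(1L, n, by = block)) {
    rows <- start:min(start + block - 1L, n)
    d2 <- outer(rowSums(xyz[rows, , drop = FALSE]^2), rowSums(xyz^2), "+") -
      2 * xyz[rows, , drop = FALSE] %*% t(xyz)
    lim <- matrix(1.9, length(rows), n)
    lim[is_s[rows], ] <- 2.2
    lim[, is_s] <- 2.2
    hit <- which(outer(rows, seq_len(n), "<") & d2 <= lim^2, arr.ind = TRUE)
    if (nrow(hit)) out <- rbind(out, cbind(rows[hit[, 1]], hit[, 2]))
  }
  out[order(out[, 1], out[, 2]), , drop = FALSE]
}

enumerate_angles <- function(adj, xyz) {
  res <- list()
  for (j in seq_along(adj)) {
    nb <- sort(unique(adj[[j]]))
    if (length(nb) < 2) next
    cmb <- utils::combn(nb, 2)
    for (c_ in seq_len(ncol(cmb))) {
      i <- cmb[1, c_]; k <- cmb[2, c_]
      res[[length(res) + 1]] <- c(i, j, k)
    }
  }
  if (!length(res)) return(empty_angles())
  m <- do.call(rbind, res)
  th <- vapply(seq_len(nrow(m)), function(r) {
    v1 <- xyz[m[r, 1], ] - xyz[m[r, 2], ]
    v2 <- xyz[m[r, 3], ] - xyz[m[r, 2], ]
    acos(pmin(1, pmax(-1, sum(v1 * v2) /
                        sqrt(sum(v1^2) * sum(v2^2)))))
  }, numeric(1))
  # near-collinear reference angles make the bending force singular
  # (1/sin theta); such triples stay held by their bonds and contacts
  ok <- th > 0.3 & th < pi - 0.3
  data.frame(i = m[ok, 1], j = m[ok, 2], k = m[ok, 3], theta0 = th[ok],
             eps = 40)
}

enumerate_propers <- function(adj, ref, opt) {
  res <- list()
  for (j in seq_along(adj)) for (k in adj[[j]]) {
    if (k <= j) next
    for (i in adj[[j]]) for (l in adj[[k]]) {
      if (i == k || l == j || i == l) next
      res[[length(res) + 1]] <- c(i, j, k, l)
    }
  }
  if (!length(res)) return(empty_dihedrals("phi0"))
  m <- unique(do.call(rbind, res))
  # drop torsions whose reference internal angles are near-collinear:
  # the dihedral is ill-conditioned (1/|b1 x b2|^2) around such triples
  bend <- function(a, b, c) {
    v1 <- ref$xyz[a, ] - ref$xyz[b, ]; v2 <- ref$xyz[c, ] - ref$xyz[b, ]
    acos(pmin(1, pmax(-1, sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)))))
  }
  ok <- vapply(seq_len(nrow(m)), function(r) {
    a1 <- bend(m[r, 1], m[r, 2], m[r, 3])
    a2 <- bend(m[r, 2], m[r, 3], m[r, 4])
    all(c(a1, a2) > 0.25 & c(a1, a2) < pi - 0.25)
  }, logical(1))
  m <- m[ok, , drop = FALSE]
  if (!nrow(m)) return(empty_dihedrals("phi0"))
  phi <- vapply(seq_len(nrow(m)), function(r)
    dihedral_angle(ref$xyz[m[r, 1], ], ref$xyz[m[r, 2], ],
                   ref$xyz[m[r, 3], ], ref$xyz[m[r, 4], ]), numeric(1))
  bb_names <- c("N", "CA", "C", "O")
  is_bb <- matrix(ref$atoms$elety[m] %in% bb_names, nrow(m))
  raw <- ifelse(rowSums(is_bb) == 4, 2, 1) # backbone : side-chain = 2 : 1
  data.frame(i = m[, 1], j = m[, 2], k = m[, 3], l = m[, 4],
             phi0 = phi, eps = raw)
}

dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1])
  atan2(sum(m1 * n2) / sqrt(sum(b2^2)), sum(n1 * n2))
}

#' Append scaled dye-linker contacts to a topology
#'
#' @param topology an [sbm_topology].
#' @param contacts contact records (as from [extract_proximity_contacts]).
#' @param scale weight scaling in (0, 1]; 0.5 reproduces experimental FRET
#'   levels in the reference system.
#' @param overwrite replace an existing record for the same pair instead of
#'   raising a merge-policy error.
#' @return The topology with the dye-linker records appended.
#' @export
inject_dye_linker_contacts <- function(topology, contacts, scale = 0.5,
                                       overwrite = FALSE) {
  stopifnot(scale > 0, scale <= 1)
  if (!nrow(contacts)) return(topology)
  key_old <- paste(pmin(topology$contacts$i, topology$contacts$j),
                   pmax(topology$contacts$i, topology$contacts$j))
  key_new <- paste(pmin(contacts$i, contacts$j),
                   pmax(contacts$i, contacts$j))
  dup <- key_new %in% key_old
  if (any(dup) && !overwrite)
    stop("merge policy error: ", sum(dup),
         " pair(s) already present; set overwrite = TRUE to replace")
  if (any(dup))
    topology$contacts <- topology$contacts[!(key_old %in% key_new), ,
                                           drop = FALSE]
  add <- contacts
  add$weight <- add$weight * scale
  add$category <- "dye-linker"
  topology$contacts <- rbind(topology$contacts,
                             add[, names(topology$contacts)])
  rownames(topology$contacts) <- NULL
  validate_contacts(topology$contacts)
  topology
}

#' Extract persistent proximity contacts from a trajectory
#'
#' Pairs (a in group_a, b in group_b) whose distance is at most `cutoff` in
#' at least a `persistence` fraction of frames become contact records; the
#' native distance is the median observed distance.
#'
#' @param trajectory an [sbm_trajectory].
#' @param group_a,group_b disjoint atom index sets.
#' @param cutoff distance cutoff in Angstrom (default 3).
#' @param persistence minimum fraction of frames (default 0.5).
#' @return data.frame of contact records (category "dye-linker" candidates,
#'   stored as `alpha-only` with the median distance until injected).
#' @export
extract_proximity_contacts <- function(trajectory, group_a, group_b,
                                       cutoff = 3, persistence = 0.5) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  if (length(intersect(group_a, group_b))) stop("groups must be disjoint")
  nf <- n_frames(trajectory)
  if (nf == 0) stop("no-data error: empty trajectory")
  pairs <- expand.grid(a = group_a, b = group_b)
  dmat <- matrix(0, nf, nrow(pairs))
  for (f in seq_len(nf)) {
    fr <- traj_frame(trajectory, f)
    d <- fr[pairs$a, , drop = FALSE] - fr[pairs$b, , drop = FALSE]
    dmat[f, ] <- sqrt(rowSums(d * d))
  }
  frac <- colMeans(dmat <= cutoff)
  keep <- which(frac >= persistence)
  if (!length(keep)) return(empty_contacts())
  i <- pmin(pairs$a[keep], pairs$b[keep])
  j <- pmax(pairs$a[keep], pairs$b[keep])
  med <- apply(dmat[, keep, drop = FALSE], 2, median)
  ord <- order(i, j)
  data.frame(i = i[ord], j = j[ord], r_alpha = med[ord], r_beta = NA_real_,
             weight = 1, category = "alpha-only", stringsAsFactors = FALSE)
}
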