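#' Protein structures for dual-basin model building
#'
#' An `sbm_structure` is a light container around an ordered heavy-atom list
#' (name, element, residue name, author residue number, chain) plus an
#' n x 3 coordinate matrix in Angstrom, an optional residue -> domain
#' assignment, and bookkeeping for attached fluorophores.
#'
#' @param atoms data.frame with columns `elety` (atom name), `elesy`
#'   (element), `resid` (residue name), `resno` (author residue number),
#'   `chain`.
#' @param xyz numeric matrix, one row per atom, columns x/y/z in Angstrom.
#' @param domains optional data.frame with columns `resno`, `domain`
#'   (1, 2 or NA).
#' @return An object of class `sbm_structure`.
#' @export
sbm_structure <- function(atoms, xyz, domains = NULL) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  xyz <- as.matrix(xyz)
  stopifnot(nrow(atoms) == nrow(xyz), ncol(xyz) == 3)
  if (!all(is.finite(xyz))) stop("coordinates must be finite")
  if (anyNA(atoms$resno)) stop("every atom needs a residue number")
  key <- paste(atoms$chain, atoms$resno, atoms$elety)
  if (anyDuplicated(key))
    stop("duplicate (chain, residue number, atom name) triple: ",
         key[anyDuplicated(key)])
  if (!is.null(domains)) {
    d1 <- domains$resno[domains$domain %in% 1]
    d2 <- domains$resno[domains$domain %in% 2]
    if (length(intersect(d1, d2)))
      stop("domains 1 and 2 must be disjoint")
  }
  structure(list(atoms = atoms, xyz = xyz, domains = domains,
                 dyes = list()),
            class = "sbm_structure")
}

#' @export
print.sbm_structure <- function(x, ...) {
  cat("sbm_structure:", nrow(x$atoms), "heavy atoms,",
      length(unique(paste(x$atoms$chain, x$atoms$resno))), "residues")
  if (length(x$dyes)) cat(",", length(x$dyes), "dye(s) attached")
  cat("\n")
  invisible(x)
}

n_atoms <- function(s) nrow(s$atoms)

# side-chain atoms kept when mutating towards each supported target;
# atoms beyond CB are rebuilt geometrically (one terminal heavy atom)
.mutation_table <- list(
  ALA = list(keep = "CB", add = NULL),
  GLY = list(keep = character(), add = NULL),
  SER = list(keep = "CB", add = c(name = "OG", element = "O", bond = 1.41)),
  CYS = list(keep = "CB", add = c(name = "SG", element = "S", bond = 1.81))
)

#' Load a PDB structure and apply point mutations
#'
#' Parses a PDB file (first chain and altloc A only, hydrogens removed) and
#' applies simple point mutations: the residue is renamed, side-chain atoms
#' beyond C-beta are pruned and the mutated residue's single distal heavy
#' atom (OG for Ser, SG for Cys) is rebuilt along the CA->CB direction.
#'
#' @param pdb_source path to a PDB file, or a `bio3d` pdb object.
#' @param mutations list of `c(position, target)` pairs (or two-column
#'   data.frame), e.g. `list(c(53, "SER"), c(78, "SER"))`. Supported
#'   targets: ALA, GLY, SER, CYS.
#' @param chain chain identifier to keep (default: first chain present).
#' @return An [sbm_structure].
#' @export
load_and_prepare_structure <- function(pdb_source, mutations = list(),
                                       chain = NULL) {
  pdb <- if (inherits(pdb_source, "pdb")) pdb_source else
    bio3d::read.pdb(pdb_source, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (is.null(chain)) chain <- at$chain[1]
  at <- at[at$chain %in% chain, , drop = FALSE]
  if (!is.null(at$alt)) at <- at[is.na(at$alt) | at$alt %in% c("", "A"), , drop = FALSE]
  hyd <- at$elesy %in% c("H", "D") |
    (is.na(at$elesy) & grepl("^[0-9]*H", at$elety))
  at <- at[!hyd, , drop = FALSE]
  atoms <- data.frame(elety = at$elety, elesy = at$elesy, resid = at$resid,
                      resno = at$resno, chain = at$chain,
                      stringsAsFactors = FALSE)
  xyz <- cbind(at$x, at$y, at$z)
  s <- sbm_structure(atoms, xyz)
  for (m in mutations) {
    pos <- as.integer(m[[1]])
    target <- toupper(as.character(m[[2]]))
    s <- mutate_residue(s, pos, target)
  }
  s
}

#' Mutate one residue of a structure
#'
#' @param s an [sbm_structure].
#' @param position author residue number to mutate.
#' @param target three-letter code of the target residue (ALA, GLY, SER, CYS).
#' @return The mutated [sbm_structure].
#' @export
mutate_residue <- function(s, position, target) {
  target <- toupper(target)
  idx <- which(s$atoms$resno == position)
  if (!length(idx))
    stop("position not found: residue ", position, " is absent")
  rule <- .mutation_table[[target]]
  if (is.null(rule))
    stop("unsupported mutation target: ", target)
  backbone <- c("N", "CA", "C", "O", "OXT")
  keep_names <- c(backbone, rule$keep)
  drop <- idx[!(s$atoms$elety[idx] %in% keep_names)]
  if (length(drop)) {
    s$atoms <- s$atoms[-drop, , drop = FALSE]
    s$xyz <- s$xyz[-drop, , drop = FALSE]
    idx <- which(s$atoms$resno == position)
  }
  s$atoms$resid[idx] <- target
  if (!is.null(rule$add) && !(rule$add[["name"]] %in% s$atoms$elety[idx])) {
    ica <- idx[s$atoms$elety[idx] == "CA"]
    icb <- idx[s$atoms$elety[idx] == "CB"]
    if (length(ica) == 1 && length(icb) == 1) {
      u <- s$xyz[icb, ] - s$xyz[ica, ]
      u <- u / sqrt(sum(u^2))
      new_xyz <- s$xyz[icb, ] + as.numeric(rule$add[["bond"]]) * u
      row <- s$atoms[icb, , drop = FALSE]
      row$elety <- rule$add[["name"]]
      row$elesy <- rule$add[["element"]]
      ins <- max(idx)
      s$atoms <- rbind(s$atoms[seq_len(ins), ], row,
                       if (ins < nrow(s$atoms)) s$atoms[(ins + 1):nrow(s$atoms), ])
      s$xyz <- rbind(s$xyz[seq_len(ins), , drop = FALSE], new_xyz,
                     if (ins < nrow(s$xyz)) s$xyz[(ins + 1):nrow(s$xyz), , drop = FALSE])
      rownames(s$atoms) <- NULL
      rownames(s$xyz) <- NULL
    }
  }
  s
}

#' Assign residues to the two clamshell domains
#'
#' @param s an [sbm_structure].
#' @param domain1,domain2 integer vectors of residue numbers.
#' @return The structure with its `domains` table set.
#' @export
assign_domains <- function(s, domain1, domain2) {
  if (length(intersect(domain1, domain2)))
    stop("domains 1 and 2 must be disjoint")
  res <- sort(unique(s$atoms$resno))
  dom <- rep(NA_integer_, length(res))
  dom[res %in% domain1] <- 1L
  dom[res %in% domain2] <- 2L
  s$domains <- data.frame(resno = res, domain = dom)
  s
}

#' Attach a fluorophore template to a cysteine
#'
#' Appends the dye atoms as a new residue bonded to the cysteine sulfur
#' (thiol-maleimide junction). The template's local frame has its attachment
#' atom at the origin and its long axis along +x; that axis is aligned with
#' the outward CB->SG direction and the template placed at a 1.8 A S-C bond.
#' If a placed heavy atom falls within 1.5 A of an existing one, the
#' template is spun about the attachment axis and placement retried.
#'
#' @param s an [sbm_structure].
#' @param template a [dye_template].
#' @param attachment_residue residue number of the labeling cysteine.
#' @param max_retries rotational retries before giving up on a clash.
#' @return The structure with dye atoms appended and a `dyes` bookkeeping
#'   entry recording chromophore, linker and dipole atom indices.
#' @export
attach_dye <- function(s, template, attachment_residue, max_retries = 12L) {
  idx <- which(s$atoms$resno == attachment_residue)
  if (!length(idx)) stop("position not found: residue ", attachment_residue)
  if (!all(s$atoms$resid[idx] == "CYS"))
    stop("chemistry error: attachment residue ", attachment_residue,
         " is ", s$atoms$resid[idx][1], ", not CYS")
  isg <- idx[s$atoms$elety[idx] == "SG"]
  icb <- idx[s$atoms$elety[idx] == "CB"]
  if (length(isg) != 1) stop("attachment cysteine has no SG atom")
  u <- s$xyz[isg, ] - s$xyz[if (length(icb) == 1) icb else idx[1], ]
  u <- u / sqrt(sum(u^2))
  base <- s$xyz[isg, ] + 1.8 * u
  R0 <- .rotation_to(c(1, 0, 0), u)
  local <- as.matrix(template$atoms[, c("x", "y", "z")])

  placed <- NULL
  retries <- 0L
  for (k in seq_len(max_retries)) {
    ang <- 2 * pi * (k - 1) / max_retries
    Rspin <- .rotation_about(u, ang)
    cand <- t(Rspin %*% R0 %*% t(local)) +
      matrix(base, nrow(local), 3, byrow = TRUE)
    dmin <- min(.cross_dist(cand, s$xyz[-isg, , drop = FALSE]))
    if (dmin >= 1.5) { placed <- cand; retries <- k - 1L; break }
  }
  if (is.null(placed))
    stop("placement error: steric clash after ", max_retries, " retries")

  n0 <- nrow(s$atoms)
  new_resno <- max(s$atoms$resno) + 1L
  add <- data.frame(elety = template$atoms$name,
                    elesy = template$atoms$element,
                    resid = template$name, resno = new_resno,
                    chain = s$atoms$chain[isg], stringsAsFactors = FALSE)
  s$atoms <- rbind(s$atoms, add)
  s$xyz <- rbind(s$xyz, placed)
  rownames(s$atoms) <- NULL
  rownames(s$xyz) <- NULL

  loc <- function(names) n0 + match(names, template$atoms$name)
  s$dyes[[template$name]] <- list(
    template = template$name,
    attachment_residue = attachment_residue,
    sg_index = isg,
    attachment_index = loc(template$attachment_atom),
    atom_indices = n0 + seq_len(nrow(template$atoms)),
    chromophore = loc(template$chromophore_atoms),
    linker = loc(template$linker_atoms),
    dipole = loc(template$dipole_axis),
    retries = retries)
  s
}

# rotation matrix taking unit vector a onto unit vector b
.rotation_to <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  cth <- sum(a * b)
  if (cth < -1 + 1e-12) { # antiparallel: rotate pi about any perpendicular
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- p - sum(p * a) * a
    return(.rotation_about(v / sqrt(sum(v^2)), pi))
  }
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) + vx + vx %*% vx / (1 + cth)
}

.rotation_about <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  c <- cos(angle); s <- sin(angle); C <- 1 - c
  x <- axis[1]; y <- axis[2]; z <- axis[3]
  matrix(c(x * x * C + c, x * y * C - z * s, x * z * C + y * s,
           y * x * C + z * s, y * y * C + c, y * z * C - x * s,
           z * x * C - y * s, z * y * C + x * s, z * z * C + c),
         3, 3, byrow = TRUE)
}

# minimum pairwise distances between two coordinate sets
.cross_dist <- function(a, b) {
  out <- numeric(nrow(a))
  for (i in seq_len(nrow(a))) {
    d <- sweep(b, 2, a[i, ])
    out[i] <- sqrt(min(rowSums(d * d)))
  }
  out
}

# approximate atomic masses (amu) by element; reduced-unit topologies may
# override these with unit masses
.element_mass <- function(elesy) {
  tab <- c(C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
           H = 1.008)
  m <- tab[toupper(elesy)]
  m[is.na(m)] <- 12.011
  unname(m)
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
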