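test_that("PDB loading applies mutations and prunes side chains", {
  pdb <- write_toy_pdb(tempfile(fileext = ".pdb"))
  s0 <- load_and_prepare_structure(pdb)
  expect_s3_class(s0, "sbm_structure")
  expect_equal(nrow(s0$atoms), 17)

  # identity: empty mutation list leaves the structure untouched
  expect_equal(load_and_prepare_structure(pdb, list())$atoms, s0$atoms)

  # ASN2 -> ALA: side chain truncated to CB, residue renamed
  s1 <- load_and_prepare_structure(pdb, list(c(2, "ALA")))
  idx <- which(s1$atoms$resno == 2)
  expect_equal(sort(s1$atoms$elety[idx]), sort(c("N", "CA", "C", "O", "CB")))
  expect_true(all(s1$atoms$resid[idx] == "ALA"))

  # ASN2 -> CYS: SG rebuilt along CA->CB at 1.81 A
  s2 <- load_and_prepare_structure(pdb, list(c(2, "CYS")))
  idx <- which(s2$atoms$resno == 2)
  expect_true("SG" %in% s2$atoms$elety[idx])
  icb <- idx[s2$atoms$elety[idx] == "CB"]
  isg <- idx[s2$atoms$elety[idx] == "SG"]
  expect_equal(sqrt(sum((s2$xyz[isg, ] - s2$xyz[icb, ])^2)), 1.81,
               tolerance = 1e-6)

  expect_error(load_and_prepare_structure(pdb, list(c(99, "SER"))),
               "position not found")
  expect_error(load_and_prepare_structure(pdb, list(c(2, "TRP"))),
               "unsupported mutation")
})

test_that("dye attachment bonds to the cysteine sulfur and bookkeeps", {
  pdb <- write_toy_pdb(tempfile(fileext = ".pdb"))
  s <- load_and_prepare_structure(pdb, list(c(2, "CYS")))
  tpl <- dye_template("mock")
  n0 <- nrow(s$atoms)
  s2 <- attach_dye(s, tpl, 2)
  expect_equal(nrow(s2$atoms), n0 + 3)
  info <- s2$dyes[["mock"]]
  expect_length(info$chromophore, 2)
  expect_length(info$atom_indices, 3)
  # junction carbon sits 1.8 A from SG
  d <- sqrt(sum((s2$xyz[info$attachment_index, ] -
                   s2$xyz[info$sg_index, ])^2))
  expect_equal(d, 1.8, tolerance = 1e-6)
  # attaching to a non-Cys residue is a chemistry error
  expect_error(attach_dye(s, tpl, 1), "chemistry error")
})

test_that("shipped dye templates satisfy their own invariants", {
  for (nm in c("LD555", "LD655")) {
    tpl <- dye_template(nm)
    expect_true(all(tpl$chromophore_atoms %in% tpl$atoms$name))
    expect_true(all(tpl$linker_atoms %in% tpl$atoms$name))
    expect_true(all(tpl$dipole_axis %in% tpl$chromophore_atoms))
    expect_false(tpl$dipole_axis[1] == tpl$dipole_axis[2])
  }
  # Cy5-like core is longer than Cy3-like
  expect_gt(nrow(dye_template("LD655")$atoms),
            nrow(dye_template("LD555")$atoms))
})

test_that("contact map equals brute-force enumeration", {
  # two atoms at 4.0 A: present at cutoff 4.5, absent at 3.5
  s <- bead_structure(rbind(c(0, 0, 0), c(4, 0, 0)), resno = c(1, 10))
  expect_equal(nrow(compute_contact_map(s, cutoff = 4.5)), 1)
  expect_equal(compute_contact_map(s, cutoff = 4.5)$r_alpha, 4.0)
  expect_equal(nrow(compute_contact_map(s, cutoff = 3.5)), 0)

  set.seed(7)
  s5 <- bead_structure(matrix(runif(15 * 3, 0, 12), 15, 3))
  for (cutoff in c(4.5, 6, 8)) {
    got <- compute_contact_map(s5, cutoff = cutoff, exclusion = 3)
    want <- brute_contacts(s5, cutoff, 3)
    expect_equal(got$i, want$i)
    expect_equal(got$j, want$j)
    expect_equal(got$r_alpha, want$r, tolerance = 1e-12)
  }
})

test_that("dual-basin build decomposes contacts as set algebra predicts", {
  set.seed(11)
  xyz_a <- matrix(runif(36, 0, 14), 12, 3)
  xyz_b <- xyz_a + matrix(rnorm(36, 0, 1.5), 12, 3)
  sa <- bead_structure(xyz_a); sb <- bead_structure(xyz_b)
  bonds <- cbind(1:11, 2:12)
  topo <- build_dual_basin_topology(sa, sb,
                                    options = list(cutoff = 7,
                                                   bond_pairs = bonds,
                                                   dihedrals = FALSE))
  key <- function(df) paste(df$i, df$j)
  bond_key <- paste(bonds[, 1], bonds[, 2])
  drop_bonded <- function(df) df[!(key(df) %in% bond_key), , drop = FALSE]
  ka <- key(drop_bonded(compute_contact_map(sa, 7)))
  kb <- key(drop_bonded(compute_contact_map(sb, 7)))
  tab <- table(topo$contacts$category)
  expect_equal(unname(tab["shared-dual"]), length(intersect(ka, kb)))
  expect_equal(unname(tab["alpha-only"]), length(setdiff(ka, kb)))
  expect_equal(unname(tab["beta-only"]), length(setdiff(kb, ka)))
  # shared records carry both native distances
  sh <- topo$contacts[topo$contacts$category == "shared-dual", ]
  expect_true(all(is.finite(sh$r_alpha) & is.finite(sh$r_beta)))

  # identical conformations: everything shared with r_alpha == r_beta,
  # and the dual-basin potential equals the single-basin one pointwise
  topo_id <- build_dual_basin_topology(sa, sa,
                                       options = list(cutoff = 7,
                                                      bond_pairs = bonds,
                                                      dihedrals = FALSE))
  expect_true(all(topo_id$contacts$category == "shared-dual"))
  expect_equal(topo_id$contacts$r_alpha, topo_id$contacts$r_beta)
  single <- topo_id
  single$contacts$r_beta <- NA_real_
  set.seed(3)
  for (rep in 1:3) {
    x <- xyz_a + matrix(rnorm(36, 0, 0.3), 12, 3)
    expect_equal(evaluate_potential(topo_id, x)$energy,
                 evaluate_potential(single, x)$energy, tolerance = 1e-12)
  }
})

test_that("atom-ordering mismatch is reported with the first divergence", {
  s1 <- bead_structure(matrix(runif(9), 3, 3))
  s2 <- bead_structure(matrix(runif(9), 3, 3), resno = c(1, 5, 3))
  expect_error(build_dual_basin_topology(s1, s2), "atom-ordering mismatch")
})

test_that("dye-linker contact injection scales weights and appends", {
  toy <- generate_toy_dual_basin()
  topo <- toy$topology
  add <- data.frame(i = 1, j = 2 + 0, r_alpha = 3.5, r_beta = NA_real_,
                    weight = 1, category = "alpha-only",
                    stringsAsFactors = FALSE)
  # duplicate of the existing pair: merge policy error unless overwrite
  expect_error(inject_dye_linker_contacts(topo, add, 0.5), "merge policy")
  topo2 <- inject_dye_linker_contacts(topo, add, 0.5, overwrite = TRUE)
  expect_equal(nrow(topo2$contacts), 1)
  expect_equal(topo2$contacts$weight, 0.5)
  expect_equal(topo2$contacts$category, "dye-linker")
  # empty list: unchanged; scale 1: weights preserved
  expect_identical(inject_dye_linker_contacts(topo, empty_contacts()),
                   topo)
  add2 <- data.frame(i = c(1, 1, 2), j = c(3, 4, 4),
                     r_alpha = c(3, 4, 5), r_beta = NA_real_, weight = 2,
                     category = "alpha-only", stringsAsFactors = FALSE)
  topo3 <- sbm_topology(masses = rep(1, 4))
  topo3 <- inject_dye_linker_contacts(topo3, add2, 1.0)
  expect_equal(topo3$contacts$weight, rep(2, 3))
})

test_that("proximity contacts honor cutoff and persistence", {
  # single frame, pair at 2.9 A -> contact; at 3.1 A -> none
  f1 <- rbind(c(0, 0, 0), c(2.9, 0, 0))
  tr <- frames_trajectory(list(f1))
  expect_equal(nrow(extract_proximity_contacts(tr, 1, 2, cutoff = 3)), 1)
  f2 <- rbind(c(0, 0, 0), c(3.1, 0, 0))
  expect_equal(nrow(extract_proximity_contacts(frames_trajectory(list(f2)),
                                               1, 2, cutoff = 3)), 0)
  # 10 frames, under cutoff in 4: persistence 0.5 excludes, 0.3 includes
  frames <- lapply(1:10, function(k) {
    d <- if (k <= 4) 2.5 else 4.5
    rbind(c(0, 0, 0), c(d, 0, 0))
  })
  tr10 <- frames_trajectory(frames)
  expect_equal(nrow(extract_proximity_contacts(tr10, 1, 2, 3, 0.5)), 0)
  got <- extract_proximity_contacts(tr10, 1, 2, 3, 0.3)
  expect_equal(nrow(got), 1)
  expect_equal(got$r_alpha, median(c(rep(2.5, 4), rep(4.5, 6))))
  expect_error(extract_proximity_contacts(tr10, 1, 1, 3), "disjoint")
})

test_that("topology round-trips through the text format", {
  topo <- all_terms_topology()
  topo$contacts <- rbind(topo$contacts,
                         data.frame(i = 2, j = 4, r_alpha = NA_real_,
                                    r_beta = 7.25, weight = 0.33,
                                    category = "beta-only",
                                    stringsAsFactors = FALSE))
  path <- tempfile(fileext = ".top")
  write_topology(topo, path)
  back <- read_topology(path)
  for (f in c("masses", "gauss_A", "gauss_sigma", "eps_nc", "sigma_nc"))
    expect_equal(back[[f]], topo[[f]])
  for (f in c("bonds", "angles", "impropers", "planars", "propers",
              "contacts"))
    expect_equal(back[[f]], topo[[f]], ignore_attr = TRUE)
  # and the round-tripped topology evaluates identically
  x <- all_terms_coords()
  expect_identical(evaluate_potential(back, x)$energy,
                   evaluate_potential(topo, x)$energy)
})
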