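#' Idealized fluorophore templates
#'
#' Ship-with-the-package dye geometries for the LD555 (donor, Cy3-like core)
#' and LD655 (acceptor, Cy5-like core) self-healing fluorophores. These are
#' synthetic idealized templates, not quantum-mechanically optimized
#' coordinates: a maleimide junction carbon, a flexible alkyl linker, and a
#' planar polymethine chromophore whose long axis carries the transition
#' dipole. The local frame places the attachment atom at the origin with the
#' molecular long axis along +x.
#'
#' @param name "LD555", "LD655", or "mock" (a 3-atom test dye).
#' @return A `dye_template`: list with `name`, `atoms` (name, element,
#'   local x/y/z), `chromophore_atoms`, `dipole_axis` (ordered atom pair),
#'   `linker_atoms`, `attachment_atom`.
#' @export
dye_template <- function(name = c("LD555", "LD655", "mock")) {
  name <- match.arg(name)
  if (name == "mock") {
    atoms <- data.frame(
      name = c("CM", "CC1", "CC2"),
      element = c("C", "C", "C"),
      x = c(0, 1.5, 3.0), y = c(0, 0.4, -0.4), z = 0,
      stringsAsFactors = FALSE)
    return(new_dye_template(name, atoms,
                            chromophore = c("CC1", "CC2"),
                            dipole = c("CC1", "CC2"),
                            linker = character(),
                            attachment = "CM"))
  }
  # number of methine carbons in the polymethine bridge: Cy3-like cores
  # have three, Cy5-like cores five (longer conjugated axis)
  n_bridge <- if (name == "LD555") 3L else 5L
  zig <- function(i) 0.45 * (-1)^(i)
  # maleimide junction + 4-carbon alkyl linker
  linker <- data.frame(
    name = c("CM", "L1", "L2", "L3", "L4"),
    element = "C",
    x = c(0, 1.45, 2.90, 4.35, 5.80),
    y = c(0, zig(1), zig(2), zig(3), zig(4)),
    z = 0, stringsAsFactors = FALSE)
  # chromophore: indolenine-like nitrogen caps flanking the bridge, with
  # two ring carbons on each cap to give the core some bulk
  xs <- 7.3
  bridge <- data.frame(
    name = paste0("CB", seq_len(n_bridge)),
    element = "C",
    x = xs + 1.35 * (1 + seq_len(n_bridge)),
    y = zig(seq_len(n_bridge)),
    z = 0, stringsAsFactors = FALSE)
  caps <- data.frame(
    name = c("N1", "CR1", "CR2", "N2", "CR3", "CR4"),
    element = c("N", "C", "C", "N", "C", "C"),
    x = c(xs + 1.35, xs + 0.8, xs + 0.8,
          xs + 1.35 * (n_bridge + 2), xs + 1.35 * (n_bridge + 2) + 0.55,
          xs + 1.35 * (n_bridge + 2) + 0.55),
    y = c(0, 1.15, -1.15, 0, 1.15, -1.15),
    z = 0, stringsAsFactors = FALSE)
  atoms <- rbind(linker, caps[1:3, ], bridge, caps[4:6, ])
  new_dye_template(name, atoms,
                   chromophore = c("N1", "CR1", "CR2", bridge$name,
                                   "N2", "CR3", "CR4"),
                   dipole = c("N1", "N2"),
                   linker = c("CM", "L1", "L2", "L3", "L4"),
                   attachment = "CM")
}

#' Construct a dye template from components
#'
#' @param name template name.
#' @param atoms data.frame with columns name, element, x, y, z (local frame).
#' @param chromophore atom names used for the chromophore center of mass.
#' @param dipole ordered pair of distinct chromophore atom names defining
#'   the transition-dipole direction.
#' @param linker atom names of the flexible linker.
#' @param attachment name of the thiol-maleimide junction atom.
#' @return A `dye_template` object.
#' @export
new_dye_template <- function(name, atoms, chromophore, dipole, linker,
                             attachment) {
  stopifnot(all(c("name", "element", "x", "y", "z") %in% names(atoms)))
  if (!all(chromophore %in% atoms$name))
    stop("chromophore_atoms must be a subset of the atom list")
  if (!all(linker %in% atoms$name))
    stop("linker_atoms must be a subset of the atom list")
  if (length(dipole) != 2 || dipole[1] == dipole[2] ||
      !all(dipole %in% chromophore))
    stop("dipole_axis must be two distinct chromophore atoms")
  if (!attachment %in% atoms$name)
    stop("attachment_atom not in atom list")
  structure(list(name = name, atoms = atoms,
                 chromophore_atoms = chromophore,
                 dipole_axis = dipole, linker_atoms = linker,
                 attachment_atom = attachment),
            class = "dye_template")
}

#' @export
print.dye_template <- function(x, ...) {
  cat("dye_template", x$name, "-", nrow(x$atoms), "atoms,",
      length(x$chromophore_atoms), "chromophore,",
      length(x$linker_atoms), "linker\n")
  invisible(x)
}
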