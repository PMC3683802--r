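BEAD_KINDS <- c(attractor = 0L, top = 1L, bottom = 2L, excluder = 3L,
                arm = 4L, polymer = 5L, inert = 6L)

#' Bead system container
#'
#' The full particle state used by the energy, dynamics and analysis code:
#' positions, bead kinds, charges, rigid-body membership, bonds, angles and
#' the (cubic, periodic) box. Rigid bodies are sets of beads sharing a
#' positive `body` id; `body = 0` marks free beads. Bonded pairs are
#' excluded from the nonbonded terms.
#'
#' @param pos N x 3 matrix of coordinates, nm
#' @param kind character vector: one of `attractor`, `top`, `bottom`,
#'   `excluder`, `arm`, `polymer`, `inert`
#' @param charge integer valences (e); must be 0 except on arm/polymer beads
#' @param body rigid-body id per bead (0 = free)
#' @param bonds B x 2 integer matrix of 1-based bead indices
#' @param bond_r0,bond_k per-bond rest length (nm) and constant (kBT/nm^2)
#' @param angles A x 3 integer matrix of bonded triples
#' @param angle_k per-angle bending constant (kBT/rad^2)
#' @param box cubic box edge, nm; 0 means open (non-periodic) boundaries
#' @param diameter bead diameters for export/volume computations (defaults
#'   by kind from the standard force field)
#' @return an object of class `bead_system`
#' @export
bead_system <- function(pos, kind, charge = 0, body = 0L, bonds = NULL,
                        bond_r0 = numeric(0), bond_k = numeric(0),
                        angles = NULL, angle_k = numeric(0), box = 0,
                        diameter = NULL) {
  pos <- as.matrix(pos)
  if (ncol(pos) != 3) stop("pos must be an N x 3 matrix", call. = FALSE)
  n <- nrow(pos)
  if (is.character(kind)) {
    if (!all(kind %in% names(BEAD_KINDS)))
      stop("unknown bead kind(s): ",
           paste(setdiff(unique(kind), names(BEAD_KINDS)), collapse = ", "),
           call. = FALSE)
    type <- unname(BEAD_KINDS[kind])
  } else type <- as.integer(kind)
  type <- rep_len(type, n)
  charge <- rep_len(as.numeric(charge), n)
  body <- rep_len(as.integer(body), n)
  if (any(charge != 0 & !(type %in% c(4L, 5L))))
    stop("only arm and polymer beads may carry charge", call. = FALSE)
  if (is.null(bonds)) bonds <- matrix(0L, 0, 2)
  bonds <- matrix(as.integer(bonds), ncol = 2)
  if (nrow(bonds) != length(bond_r0) || nrow(bonds) != length(bond_k))
    stop("bond_r0/bond_k must match the number of bonds", call. = FALSE)
  if (is.null(angles)) angles <- matrix(0L, 0, 3)
  angles <- matrix(as.integer(angles), ncol = 3)
  if (nrow(angles) != length(angle_k))
    stop("angle_k must match the number of angles", call. = FALSE)
  if (is.null(diameter)) {
    dflt <- c(0.5, 0.5, 0.5, 3.0, 0.5, 0.5, 0.5)
    diameter <- dflt[type + 1L]
  }
  structure(list(pos = pos, type = type, charge = charge, body = body,
                 bonds = bonds, bond_r0 = as.numeric(bond_r0),
                 bond_k = as.numeric(bond_k), angles = angles,
                 angle_k = as.numeric(angle_k), box = box,
                 diameter = rep_len(diameter, n),
                 permeable_bodies = integer(0)),
            class = "bead_system")
}

#' @export
print.bead_system <- function(x, ...) {
  kn <- names(BEAD_KINDS)[x$type + 1L]
  cat(sprintf("<bead_system> %d beads, %d bonds, %d angles, %d rigid bodies",
              nrow(x$pos), nrow(x$bonds), nrow(x$angles),
              length(unique(x$body[x$body > 0]))))
  if (x$box > 0) cat(sprintf(", box %g nm", x$box))
  cat("\n  kinds: ", paste(sprintf("%s=%d", names(table(kn)), table(kn)),
                           collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Number of beads in a system
#' @param system a `bead_system`
#' @export
n_beads <- function(system) nrow(system$pos)

bead_kind <- function(system) names(BEAD_KINDS)[system$type + 1L]

as_cpp_system <- function(system) {
  list(pos = system$pos, type = as.integer(system$type),
       charge = as.numeric(system$charge), body = as.integer(system$body),
       bonds = system$bonds, bond_r0 = system$bond_r0,
       bond_k = system$bond_k, angles = system$angles,
       angle_k = system$angle_k, box = as.numeric(system$box),
       permeable_bodies = as.integer(system$permeable_bodies))
}

#' Concatenate bead systems
#'
#' Combines systems, offsetting bead indices in bonds/angles and rigid-body
#' ids so they stay distinct. The box of the first system wins.
#'
#' @param ... `bead_system` objects
#' @return a single `bead_system`
#' @export
combine_systems <- function(...) {
  parts <- list(...)
  parts <- parts[!vapply(parts, is.null, TRUE)]
  stopifnot(length(parts) >= 1)
  off_i <- 0L; off_b <- 0L
  acc <- NULL
  for (p in parts) {
    b <- p$body
    b[b > 0] <- b[b > 0] + off_b
    perm <- p$permeable_bodies + off_b
    if (is.null(acc)) {
      acc <- p; acc$body <- b; acc$permeable_bodies <- perm
    } else {
      acc$pos <- rbind(acc$pos, p$pos)
      acc$type <- c(acc$type, p$type)
      acc$charge <- c(acc$charge, p$charge)
      acc$body <- c(acc$body, b)
      acc$diameter <- c(acc$diameter, p$diameter)
      acc$bonds <- rbind(acc$bonds, p$bonds + off_i)
      acc$bond_r0 <- c(acc$bond_r0, p$bond_r0)
      acc$bond_k <- c(acc$bond_k, p$bond_k)
      acc$angles <- rbind(acc$angles, p$angles + off_i)
      acc$angle_k <- c(acc$angle_k, p$angle_k)
      acc$permeable_bodies <- c(acc$permeable_bodies, perm)
    }
    off_i <- nrow(acc$pos)
    off_b <- max(0L, acc$body)
  }
  acc
}

#' Make one assembled subunit permeable to the polymer
#'
#' Disables the excluder-polymer repulsion for the given rigid body, leaving
#' all its other interactions unchanged; the polymer can then thread through
#' that face so the packaged length equilibrates.
#'
#' @param system a `bead_system` containing the subunit
#' @param subunit_id rigid-body id of the subunit
#' @return the modified system
#' @export
set_permeable <- function(system, subunit_id) {
  if (!subunit_id %in% system$body)
    stop("no rigid body with id ", subunit_id, " in the system",
         call. = FALSE)
  system$permeable_bodies <- unique(c(system$permeable_bodies,
                                      as.integer(subunit_id)))
  system
}
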