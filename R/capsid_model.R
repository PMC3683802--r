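## Geometry of the rigid pentameric subunit and the assembled dodecahedral
## shell. The capsid is 12 pentagonal subunits; subunit-subunit attraction
## acts through attractor ('A') pseudoatoms at the pentagon vertices, the
## preferred dihedral is enforced by repulsive Top ('T') / Bottom ('B')
## pseudoatoms on the face axis, and a layer of excluder beads makes the
## face impassable to the polymer. Flexible ARM tails (one bead per residue,
## first bead rigid) carry the positive charges.

GOLDEN <- (1 + sqrt(5)) / 2
# half the angle between adjacent dodecahedral face normals
DODECA_HALF_NORMAL_ANGLE <- 0.5 * acos(1 / sqrt(5))
# ideal dodecahedral dihedral angle, rad (~116.565 deg)
DODECA_DIHEDRAL <- pi - acos(1 / sqrt(5))
# inradius / face circumradius for a closed regular dodecahedron
DODECA_INRADIUS_PER_R5 <- {
  a <- 2 * sin(pi / 5)  # edge for unit face circumradius
  (a / 2) * sqrt(5 / 2 + 11 / (2 * sqrt(5)))
}

#' Pseudoatom record
#'
#' One coarse-grained site of a subunit in its body frame. Attractor, Top,
#' Bottom and excluder pseudoatoms are neutral; only ARM beads carry charge
#' (-1, 0 or +1 e).
#'
#' @param kind one of `attractor`, `top`, `bottom`, `excluder`, `arm`,
#'   `inert`
#' @param position 3-vector, nm, body frame
#' @param charge integer valence (e)
#' @param diameter nm
#' @return a one-row data.frame
#' @export
pseudo_atom <- function(kind, position, charge = 0, diameter = 0.5) {
  kind <- match.arg(kind, c("attractor", "top", "bottom", "excluder",
                            "arm", "inert"))
  if (diameter <= 0) stop("diameter must be positive", call. = FALSE)
  if (kind != "arm" && charge != 0)
    stop(kind, " pseudoatoms must be neutral", call. = FALSE)
  if (kind == "arm" && !charge %in% c(-1, 0, 1))
    stop("arm bead charge must be -1, 0 or +1", call. = FALSE)
  data.frame(kind = kind, x = position[1], y = position[2], z = position[3],
             charge = charge, diameter = diameter)
}

#' Capsid parameterization
#'
#' Structural parameters of one capsid model: the inradius (distance from
#' the capsid center to a face center), triangulation number, ARM length and
#' net charge, optional fixed inner-surface charges, and the reference
#' genome length. Use [virus_preset()] for the shipped virus table.
#'
#' @param name label
#' @param inradius nm, > 0
#' @param t_number 1 or 3
#' @param arm_length residues per ARM
#' @param arm_net_charge net charge per ARM, e
#' @param surface_charges count of fixed +1 charges on the inner face per
#'   subunit (satellite viruses)
#' @param genome_length reference genome length, nt (NA if none)
#' @param arm_sequence optional explicit charge sequence (length
#'   `arm_length`, values in -1/0/+1); default built by
#'   [default_arm_sequence()]
#' @return an object of class `capsid_params`
#' @export
capsid_params <- function(name = "custom", inradius = 7.3, t_number = 1,
                          arm_length = 5, arm_net_charge = arm_length,
                          surface_charges = 0, genome_length = NA,
                          arm_sequence = NULL) {
  if (inradius <= 0) stop("inradius must be positive", call. = FALSE)
  if (!t_number %in% c(1, 3)) stop("t_number must be 1 or 3", call. = FALSE)
  if (arm_length < 0) stop("arm_length must be >= 0", call. = FALSE)
  if (is.null(arm_sequence))
    arm_sequence <- default_arm_sequence(arm_length, arm_net_charge, name)
  if (length(arm_sequence) != arm_length)
    stop("arm_sequence length must equal arm_length", call. = FALSE)
  if (arm_length > 0 && sum(arm_sequence) != arm_net_charge)
    stop("arm_sequence net charge (", sum(arm_sequence),
         ") does not match arm_net_charge (", arm_net_charge, ")",
         call. = FALSE)
  structure(list(name = name, inradius = inradius, t_number = t_number,
                 arm_length = arm_length, arm_net_charge = arm_net_charge,
                 surface_charges = surface_charges,
                 genome_length = genome_length,
                 arm_sequence = as.numeric(arm_sequence),
                 arms_per_subunit = if (t_number == 3) 15L else 5L),
            class = "capsid_params")
}

#' @export
print.capsid_params <- function(x, ...) {
  cat(sprintf(paste0("<capsid_params> %s: T=%d, Rin=%.1f nm, ARM %d/%+d e,",
                     " surface %+d e, genome %s nt\n"),
              x$name, x$t_number, x$inradius, x$arm_length,
              x$arm_net_charge, x$surface_charges,
              ifelse(is.na(x$genome_length), "-", x$genome_length)))
  invisible(x)
}

#' The simplest capsid model
#'
#' T=1 shell with inradius 7.3 nm and five-residue, fully charged ARMs:
#' 60 ARMs of 5 positive residues each, net capsid charge +300 e.
#' @return a `capsid_params` object
#' @export
simple_capsid_params <- function() {
  capsid_params(name = "simple", inradius = 7.3, t_number = 1,
                arm_length = 5, arm_net_charge = 5)
}

#' Synthetic ARM charge sequence
#'
#' The per-residue charge sequences of the preset viruses are not part of
#' the shipped table (only length and net charge are); this builds a
#' deterministic synthetic stand-in: `net` positive charges at evenly
#' spaced positions (for CCMV, the documented 11 positive / 1 negative
#' split, with most positives clustered as in its radial charge profile).
#'
#' @param arm_length residues
#' @param net_charge net charge, e
#' @param name preset name (CCMV gets its documented split)
#' @return numeric vector of -1/0/+1 of length `arm_length`
#' @export
default_arm_sequence <- function(arm_length, net_charge, name = "") {
  if (arm_length == 0) return(numeric(0))
  s <- numeric(arm_length)
  if (identical(toupper(name), "CCMV") && arm_length >= 40) {
    s[seq(2, 32, by = 3)] <- 1   # 11 positive residues
    s[40] <- -1                  # 1 negative residue
    return(s)
  }
  if (net_charge < 0) stop("negative net ARM charge not supported",
                           call. = FALSE)
  if (net_charge > arm_length)
    stop("net charge exceeds ARM length", call. = FALSE)
  s[unique(round(seq(1, arm_length, length.out = net_charge)))] <- 1
  # rounding collisions: fill remaining charge onto the first neutral slots
  short <- net_charge - sum(s)
  if (short > 0) s[which(s == 0)[seq_len(short)]] <- 1
  s
}

subunit_t_height <- function(params, ff = forcefield_params()) {
  h <- ff$sigma_t / (2 * sin(DODECA_HALF_NORMAL_ANGLE)) - params$inradius
  if (h <= 0)
    stop("sigma_t = ", ff$sigma_t, " nm is too small to place Top atoms ",
         "for inradius ", params$inradius, " nm", call. = FALSE)
  h
}

hex_excluder_layout <- function(circumradius, spacing) {
  # hexagonal lattice clipped to the pentagon (small margin so the face is
  # covered out to its edges); spacing chosen so no polymer bead can pass
  vx <- cbind(cos(2 * pi * (0:4) / 5),
              sin(2 * pi * (0:4) / 5)) * circumradius
  nmax <- ceiling(circumradius / spacing) + 1
  pts <- expand.grid(i = -nmax:nmax, j = -nmax:nmax)
  xy <- cbind(pts$i * spacing + pts$j * spacing / 2,
              pts$j * spacing * sqrt(3) / 2)
  # signed distance to pentagon: inside if within all edge half-planes
  inside <- rep(TRUE, nrow(xy))
  margin <- 0.45 * spacing
  for (k in 1:5) {
    a <- vx[k, ]; b <- vx[k %% 5 + 1, ]
    e <- b - a
    nrm <- c(e[2], -e[1]) / sqrt(sum(e^2))
    if (sum(nrm * a) < 0) nrm <- -nrm   # outward normal
    inside <- inside & (xy %*% nrm - sum(nrm * a)) <= margin
  }
  xy[inside, , drop = FALSE]
}

arm_anchor_layout <- function(params, circumradius) {
  if (params$arms_per_subunit == 5L) {
    r <- 0.5 * circumradius
    ang <- 2 * pi * (0:4) / 5
    cbind(r * cos(ang), r * sin(ang))
  } else {
    # 15 ARMs per T=3 subunit, spread uniformly (sunflower layout)
    k <- seq_len(15)
    r <- 0.85 * circumradius * sqrt(k / 15)
    ang <- 2 * pi * k * (1 - 1 / GOLDEN)
    cbind(r * cos(ang), r * sin(ang))
  }
}

#' Build a rigid subunit template
#'
#' Constructs the body-frame pseudoatom layout of one pentameric subunit:
#' five attractors at the vertices of a regular pentagon (circumradius
#' 1 Du = 5 nm for the standard model), one Top atom above and one Bottom
#' atom below the face center at the height that makes the Top-Top contact
#' enforce the dodecahedral dihedral, a hexagonally packed excluder layer
#' spanning the face, and one rigid anchor bead per ARM midway along the
#' pentagonal radius (on the inner side of the excluder layer). The
#' remaining ARM beads are flexible and are instantiated by
#' [subunit_beads()].
#'
#' @param params a [capsid_params()] object
#' @param arm_sequence charge sequence per ARM (default from `params`)
#' @param pentagon_circumradius nm (default 5)
#' @param ff force-field parameters (diameters, sigma_t)
#' @param active_attractors indices (1-5) of attractors that keep the
#'   attractive type; the rest become inert (used to restrict binding to a
#'   single edge in dimerization runs)
#' @return an object of class `subunit_template`
#' @export
build_subunit <- function(params, arm_sequence = params$arm_sequence,
                          pentagon_circumradius = 5,
                          ff = forcefield_params(t_number = params$t_number),
                          active_attractors = 1:5) {
  if (pentagon_circumradius <= 0)
    stop("pentagon circumradius must be positive", call. = FALSE)
  if (params$arm_length > 0 && length(arm_sequence) == 0)
    stop("ARM length is ", params$arm_length,
         " but the arm sequence is empty", call. = FALSE)
  if (length(arm_sequence) != params$arm_length)
    stop("arm_sequence must have length ", params$arm_length, call. = FALSE)
  R5 <- pentagon_circumradius
  h <- subunit_t_height(params, ff)
  ang <- 2 * pi * (0:4) / 5
  atoms <- list()
  for (k in 1:5) {
    kind <- if (k %in% active_attractors) "attractor" else "inert"
    atoms[[length(atoms) + 1]] <-
      pseudo_atom(kind, c(R5 * cos(ang[k]), R5 * sin(ang[k]), 0),
                  diameter = ff$r0)
  }
  atoms[[length(atoms) + 1]] <- pseudo_atom("top", c(0, 0, h),
                                            diameter = ff$sigma_t)
  atoms[[length(atoms) + 1]] <- pseudo_atom("bottom", c(0, 0, -h),
                                            diameter = ff$sigma_b)
  ex <- hex_excluder_layout(R5, spacing = ff$sigma_x / 2)
  for (k in seq_len(nrow(ex)))
    atoms[[length(atoms) + 1]] <- pseudo_atom("excluder",
                                              c(ex[k, 1], ex[k, 2], 0),
                                              diameter = ff$sigma_x)
  anchors <- arm_anchor_layout(params, R5)
  z_anchor <- -ff$sigma_xa
  n_arms <- nrow(anchors)
  anchor_rows <- integer(n_arms)
  if (params$arm_length > 0) {
    for (k in seq_len(n_arms)) {
      atoms[[length(atoms) + 1]] <-
        pseudo_atom("arm", c(anchors[k, 1], anchors[k, 2], z_anchor),
                    charge = arm_sequence[1], diameter = ff$sigma_a)
      anchor_rows[k] <- length(atoms)
    }
  }
  if (params$surface_charges > 0) {
    # fixed synthetic layout of inner-surface charges (sunflower spiral)
    for (k in seq_len(params$surface_charges)) {
      rr <- 0.8 * R5 * sqrt(k / params$surface_charges)
      aa <- 2 * pi * k * (1 - 1 / GOLDEN) + pi / 5
      atoms[[length(atoms) + 1]] <-
        pseudo_atom("arm", c(rr * cos(aa), rr * sin(aa), z_anchor),
                    charge = 1, diameter = ff$sigma_a)
    }
  }
  rigid <- do.call(rbind, atoms)
  structure(list(rigid_atoms = rigid,
                 arm_sequences = rep(list(as.numeric(arm_sequence)), n_arms),
                 arm_anchor_rows = if (params$arm_length > 0) anchor_rows
                                   else integer(0),
                 pentagon_circumradius = R5, t_height = h,
                 params = params, ff = ff),
            class = "subunit_template")
}

#' @export
print.subunit_template <- function(x, ...) {
  cat(sprintf("<subunit_template> %s: %d rigid atoms, %d ARMs x %d beads, R5=%g nm\n",
              x$params$name, nrow(x$rigid_atoms),
              length(x$arm_sequences), x$params$arm_length,
              x$pentagon_circumradius))
  invisible(x)
}

rotation_to_face <- function(normal, first_vertex_dir) {
  zb <- normal / sqrt(sum(normal^2))
  xb <- first_vertex_dir - sum(first_vertex_dir * zb) * zb
  xb <- xb / sqrt(sum(xb^2))
  yb <- c(zb[2] * xb[3] - zb[3] * xb[2],
          zb[3] * xb[1] - zb[1] * xb[3],
          zb[1] * xb[2] - zb[2] * xb[1])
  cbind(xb, yb, zb)
}

#' Bead table for one posed subunit
#'
#' Instantiates a template at a pose: rigid atoms transformed by the
#' rotation and center, plus the flexible ARM beads laid out from each
#' anchor (inward along -z of the body frame, optionally folding onto a
#' sphere around `fold_center` so long ARMs stay inside the shell).
#'
#' @param template a [build_subunit()] template
#' @param center 3-vector, nm
#' @param rotation 3 x 3 rotation matrix (body to lab)
#' @param body_id rigid-body id for the rigid atoms
#' @param fold_center optional capsid center for ARM folding
#' @return a `bead_system`
#' @export
subunit_beads <- function(template, center = c(0, 0, 0), rotation = diag(3),
                          body_id = 1L, fold_center = NULL) {
  ra <- template$rigid_atoms
  pos <- t(rotation %*% t(as.matrix(ra[, c("x", "y", "z")]))) +
    matrix(center, nrow(ra), 3, byrow = TRUE)
  kind <- ra$kind
  charge <- ra$charge
  body <- rep(as.integer(body_id), nrow(ra))
  diameter <- ra$diameter
  bonds <- matrix(0L, 0, 2); bond_r0 <- bond_k <- numeric(0)
  angles <- matrix(0L, 0, 3); angle_k <- numeric(0)
  ff <- template$ff
  L <- template$params$arm_length
  step <- ff$sigma_a
  inward <- as.numeric(rotation %*% c(0, 0, -1))
  for (a in seq_along(template$arm_anchor_rows)) {
    if (L <= 1) break
    anchor_row <- template$arm_anchor_rows[a]
    seqs <- template$arm_sequences[[a]]
    prev <- pos[anchor_row, ]
    dirv <- inward
    idx_prev <- anchor_row
    for (m in 2:L) {
      nxt <- prev + step * dirv
      if (!is.null(fold_center)) {
        r_rel <- nxt - fold_center
        r_len <- sqrt(sum(r_rel^2))
        r_min <- 0.35 * template$params$inradius
        if (r_len < r_min) {
          # walk a geodesic on the sphere of radius r_min instead
          tang <- pracma_cross(r_rel / r_len, inward)
          if (sum(tang^2) < 1e-8) tang <- pracma_cross(r_rel / r_len, c(1, 0, 0))
          tang <- tang / sqrt(sum(tang^2))
          nxt <- prev + step * tang
          nxt <- fold_center + (nxt - fold_center) *
            (r_min / sqrt(sum((nxt - fold_center)^2)))
          dirv <- (nxt - prev) / sqrt(sum((nxt - prev)^2))
        }
      }
      pos <- rbind(pos, nxt)
      kind <- c(kind, "arm")
      charge <- c(charge, seqs[m])
      body <- c(body, 0L)
      diameter <- c(diameter, ff$sigma_a)
      bonds <- rbind(bonds, c(idx_prev, nrow(pos)))
      bond_r0 <- c(bond_r0, ff$sigma_a)
      bond_k <- c(bond_k, ff$kbond)
      if (m >= 3 && ff$kangle_ss > 0) {
        angles <- rbind(angles, c(nrow(pos) - 2L, nrow(pos) - 1L, nrow(pos)))
        angle_k <- c(angle_k, ff$kangle_ss)
      }
      prev <- nxt
      idx_prev <- nrow(pos)
    }
  }
  bead_system(pos, kind, charge, body, bonds, bond_r0, bond_k,
              angles, angle_k, box = 0, diameter = diameter)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

dodecahedron_geometry <- function() {
  phi <- GOLDEN
  V <- rbind(expand.grid(x = c(-1, 1), y = c(-1, 1), z = c(-1, 1)))
  V <- as.matrix(V)
  dimnames(V) <- NULL
  V <- rbind(V,
             cbind(0, c(-1, -1, 1, 1) / phi, c(-phi, phi, -phi, phi)),
             cbind(c(-1, -1, 1, 1) / phi, c(-phi, phi, -phi, phi), 0),
             cbind(c(-phi, phi, -phi, phi), 0, c(-1, -1, 1, 1) / phi))
  # face planes: the 12 outward unit normals whose supporting plane holds
  # exactly 5 vertices (found from vertex triples on the hull)
  N <- matrix(0, 0, 3)
  faces <- list()
  for (i in 1:18) {
    for (j in (i + 1):19) {
      for (k in (j + 1):20) {
        n <- pracma_cross(V[j, ] - V[i, ], V[k, ] - V[i, ])
        nn <- sqrt(sum(n^2))
        if (nn < 1e-9) next
        n <- n / nn
        d <- drop(V %*% n)
        dmax <- max(abs(d))
        if (abs(abs(sum(n * V[i, ])) - dmax) > 1e-9) next
        if (sum(n * V[i, ]) < 0) { n <- -n; d <- -d }
        on_face <- abs(d - dmax) < 1e-9
        if (sum(on_face) != 5) next
        if (nrow(N) && any(rowSums(abs(sweep(N, 2, n))) < 1e-6)) next
        idx <- which(on_face)
        ctr <- colMeans(V[idx, ])
        e1 <- V[idx[1], ] - sum(V[idx[1], ] * n) * n
        e1 <- e1 / sqrt(sum(e1^2))
        e2 <- pracma_cross(n, e1)
        rel <- sweep(V[idx, ], 2, ctr)
        angv <- atan2(rel %*% e2, rel %*% e1)
        N <- rbind(N, n)
        faces[[nrow(N)]] <- idx[order(angv)]
        if (nrow(N) == 12) break
      }
      if (nrow(N) == 12) break
    }
    if (nrow(N) == 12) break
  }
  if (nrow(N) != 12) stop("internal error: dodecahedron construction failed")
  list(vertices = V, normals = N, faces = faces)
}

#' Assemble the complete dodecahedral capsid
#'
#' Places 12 copies of a subunit template on the faces of a regular
#' dodecahedron, outward normals along the face axes and vertices aligned
#' so that attractors of neighboring subunits pair across the shared edges,
#' with the face centers at exactly `target_inradius` from the capsid
#' center. The gap between paired attractors is reported; at the standard
#' inradius it sits inside the Morse well (minimum at `r0`).
#'
#' @param template a [build_subunit()] template
#' @param target_inradius nm; defaults to the template's `params$inradius`
#' @param center capsid center
#' @param box periodic box edge for the returned system (0 = open)
#' @param fold_arms lay long ARMs on an inner sphere instead of straight
#'   lines (recommended; see [subunit_beads()])
#' @return list with `layout` (centers, normals, rotations, measured
#'   inradius, attractor gap, dihedral angle) and `system` (a
#'   [bead_system()] of all 12 subunits)
#' @export
build_assembled_capsid <- function(template,
                                   target_inradius = template$params$inradius,
                                   center = c(0, 0, 0), box = 0,
                                   fold_arms = TRUE) {
  R5 <- template$pentagon_circumradius
  touch <- R5 * DODECA_INRADIUS_PER_R5
  if (target_inradius < touch)
    stop("target inradius ", target_inradius, " nm is smaller than the ",
         "closed-shell inradius ", signif(touch, 4), " nm for pentagon ",
         "circumradius ", R5, " nm: subunits would interpenetrate",
         call. = FALSE)
  geo <- dodecahedron_geometry()
  sys <- NULL
  centers <- matrix(0, 12, 3)
  rotations <- vector("list", 12)
  for (f in 1:12) {
    n <- geo$normals[f, ]
    v1 <- geo$vertices[geo$faces[[f]][1], ]
    Rm <- rotation_to_face(n, v1)
    ctr <- center + target_inradius * n
    centers[f, ] <- ctr
    rotations[[f]] <- Rm
    part <- subunit_beads(template, ctr, Rm, body_id = 1L,
                          fold_center = if (fold_arms) center else NULL)
    sys <- if (is.null(sys)) part else combine_systems(sys, part)
  }
  sys$box <- box
  # measured geometry
  attr_idx <- which(sys$type == BEAD_KINDS[["attractor"]])
  gap <- min_cross_body_distance(sys$pos[attr_idx, , drop = FALSE],
                                 sys$body[attr_idx])
  if (gap > template$ff$rcut_morse)
    stop("attractor gap ", signif(gap, 3), " nm exceeds the Morse cutoff: ",
         "r0/inradius combination leaves subunits out of contact",
         call. = FALSE)
  meas_in <- mean(sqrt(rowSums(sweep(centers, 2, center)^2)))
  ndot <- geo$normals %*% t(geo$normals)
  diag(ndot) <- -Inf
  dihedral <- acos(max(ndot))  # angle between adjacent face normals
  layout <- list(centers = centers, normals = geo$normals,
                 rotations = rotations, center = center,
                 inradius = meas_in, attractor_gap = gap,
                 dihedral_deg = 180 - dihedral * 180 / pi)
  list(layout = layout, system = sys)
}

min_cross_body_distance <- function(pos, body) {
  best <- Inf
  n <- nrow(pos)
  for (i in seq_len(n - 1)) {
    d <- sqrt(rowSums(sweep(pos[(i + 1):n, , drop = FALSE], 2, pos[i, ])^2))
    d[body[(i + 1):n] == body[i]] <- Inf
    best <- min(best, d)
  }
  best
}

#' Virus parameter presets
#'
#' Returns the capsid parameterization for one of the modeled viruses; the
#' table (inradius, ARM length and net charge, genome length) is shipped at
#' `system.file("extdata", "virus_presets.tsv", package = "capsidsim")`.
#'
#' @param name one of PaV, CCMV, BMV, PC2, STNV, BBT, STMV, SPMV
#' @return a [capsid_params()] object (with `leq_reference` and
#'   `occupied_volume_reference` attributes from the table)
#' @export
virus_preset <- function(name) {
  tab <- virus_preset_table()
  hit <- match(toupper(name), toupper(tab$name))
  if (is.na(hit))
    stop("unknown virus preset '", name, "'; available: ",
         paste(tab$name, collapse = ", "), call. = FALSE)
  row <- tab[hit, ]
  p <- capsid_params(name = row$name, inradius = row$inradius_nm,
                     t_number = row$t_number, arm_length = row$arm_length,
                     arm_net_charge = row$arm_net_charge,
                     genome_length = row$genome_nt)
  attr(p, "leq_reference") <- row$leq_bp_model
  attr(p, "occupied_volume_reference") <- row$occupied_volume_fraction
  p
}

#' @rdname virus_preset
#' @export
virus_preset_table <- function() {
  f <- system.file("extdata", "virus_presets.tsv", package = "capsidsim")
  utils::read.delim(f, stringsAsFactors = FALSE)
}

#' Net charge of a complete capsid
#'
#' Sum over all ARM bead charges plus fixed inner-surface charges of the
#' assembled shell (12 subunits; 5 ARMs each for T=1, 15 for T=3).
#'
#' @param params a [capsid_params()] object
#' @return integer charge in e
#' @export
total_capsid_charge <- function(params) {
  per_subunit <- params$arms_per_subunit * sum(params$arm_sequence) +
    params$surface_charges
  12 * per_subunit
}

#' Interior volume of the model capsid
#'
#' Volume of a regular dodecahedron with the given inradius (the defined
#' interior of the shell).
#'
#' @param params a [capsid_params()] object or a numeric inradius in nm
#' @return volume in nm^3
#' @export
capsid_interior_volume <- function(params) {
  rin <- if (inherits(params, "capsid_params")) params$inradius else params
  a <- 2 * rin / sqrt(5 / 2 + 11 / (2 * sqrt(5)))  # edge length
  (15 + 7 * sqrt(5)) / 4 * a^3
}
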