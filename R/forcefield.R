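#' Force-field parameter set
#'
#' Collects every interaction constant of the coarse-grained capsid/NA model
#' in reduced units (energies in kBT, lengths in nm). Defaults follow the
#' standard parameterization: subunit attraction scale `epsilon` = 5 kBT,
#' Top-Top and Bottom-Top diameters 10.5 and 9.0 nm, Morse minimum at
#' `r0` = 1 nm with width `rho` = 2.5 and cutoff 10 nm, bead diameters
#' `sigma_p` = `sigma_a` = 0.5 nm and excluder diameter `sigma_x` = 3 nm
#' (5.25 nm for T=3 shells), Debye length 1 nm (physiological salt) and
#' Bjerrum length 0.714 nm. Cross diameters use the arithmetic mixing rule
#' `sigma_xy = (sigma_x + sigma_y) / 2`.
#'
#' The bonded constants are not dictated by the pair potentials and are
#' exposed here: `kbond` = 200 kBT/nm^2 keeps bond-length fluctuations well
#' below a bead diameter; `kangle_ss` (single-stranded / ARM backbone
#' bending) defaults to 0, i.e. fully flexible chains whose stiffness comes
#' from electrostatics and excluded volume alone; `kangle_ds` is calibrated
#' so that an isolated model duplex has a persistence length of about 50 nm.
#' `bp_rest` is the rest length of the harmonic bond joining paired
#' nucleotides (approximately the helix diameter at this resolution).
#'
#' @param epsilon subunit-subunit attraction scale, kBT
#' @param sigma_t,sigma_b Top-Top and Bottom-Top interaction diameters, nm
#' @param r0,rho,rcut_morse Morse minimum (nm), width parameter, cutoff (nm)
#' @param sigma_p,sigma_x,sigma_a polymer, excluder and ARM bead diameters, nm
#' @param kbond harmonic bond constant, kBT/nm^2
#' @param kangle_ss,kangle_ds bending constants for single- and
#'   double-stranded triples, kBT/rad^2
#' @param lambda_D Debye screening length, nm
#' @param l_b Bjerrum length, nm
#' @param css standard-state concentration, M
#' @param bp_rest base-pair bond rest length, nm
#' @param cap_frac onset of the repulsive-force cap, as a fraction of the
#'   interaction diameter (numerical safeguard; unreachable in equilibrium)
#' @param t_number 1 or 3; selects the excluder diameter when `sigma_x` is
#'   not given explicitly
#' @return an object of class `forcefield_params` (a named list)
#' @examples
#' ff <- forcefield_params()
#' ff$epsilon
#' @export
forcefield_params <- function(epsilon = 5, sigma_t = 10.5, sigma_b = 9.0,
                              r0 = 1.0, rho = 2.5, rcut_morse = 10.0,
                              sigma_p = 0.5, sigma_x = NULL, sigma_a = 0.5,
                              kbond = 200, kangle_ss = 0, kangle_ds = 34,
                              lambda_D = 1.0, l_b = 0.714, css = 1.0,
                              bp_rest = 1.0, cap_frac = 0.2, t_number = 1) {
  if (is.null(sigma_x)) sigma_x <- if (t_number == 3) 5.25 else 3.0
  p <- list(epsilon = epsilon, sigma_t = sigma_t, sigma_b = sigma_b, r0 = r0,
            rho = rho, rcut_morse = rcut_morse, sigma_p = sigma_p,
            sigma_x = sigma_x, sigma_a = sigma_a, kbond = kbond,
            kangle_ss = kangle_ss, kangle_ds = kangle_ds,
            lambda_D = lambda_D, l_b = l_b, css = css, bp_rest = bp_rest,
            cap_frac = cap_frac, t_number = t_number)
  lens <- c("sigma_t", "sigma_b", "r0", "rcut_morse", "sigma_p", "sigma_x",
            "sigma_a", "lambda_D", "l_b", "bp_rest")
  for (nm in lens)
    if (!is.numeric(p[[nm]]) || p[[nm]] <= 0)
      stop("force-field length '", nm, "' must be positive", call. = FALSE)
  p$sigma_xp <- 0.5 * (p$sigma_x + p$sigma_p)
  p$sigma_xa <- 0.5 * (p$sigma_x + p$sigma_a)
  p$sigma_ap <- 0.5 * (p$sigma_a + p$sigma_p)
  structure(p, class = "forcefield_params")
}

#' @export
print.forcefield_params <- function(x, ...) {
  cat("<forcefield_params>\n")
  for (nm in names(x)) cat(sprintf("  %-10s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Repulsive Lennard-Jones potential shifted to zero at the diameter
#'
#' `(sigma/x)^12 - 1` for `x < sigma`, zero beyond; continuous at the
#' interaction diameter.
#'
#' @param x separation, nm (must be positive)
#' @param sigma interaction diameter, nm
#' @return energy in kBT (before any `epsilon` scaling)
#' @export
u_repulsive_lj <- function(x, sigma) {
  if (any(x <= 0)) stop("separation must be positive", call. = FALSE)
  ifelse(x < sigma, (sigma / x)^12 - 1, 0)
}

#' Morse potential of the attractor-attractor interaction
#'
#' `(exp(rho (1 - x/r0)) - 2) exp(rho (1 - x/r0))` for `x < rcut`, zero
#' beyond; the minimum value is -1 at `x = r0` (scaled by `epsilon` when
#' used in the capsomer-capsomer term).
#'
#' @param x separation, nm
#' @param r0 minimum-energy distance, nm
#' @param rho width parameter (dimensionless)
#' @param rcut cutoff, nm
#' @return dimensionless well depth (scale by epsilon)
#' @export
u_morse <- function(x, r0 = 1.0, rho = 2.5, rcut = 10.0) {
  m <- exp(rho * (1 - x / r0))
  ifelse(x < rcut, (m - 2) * m, 0)
}

#' Screened (Debye-Hueckel) electrostatic pair potential
#'
#' Finite-ion-size screened Coulomb interaction
#' `q1 q2 l_b exp(sigma/lambda_D) / (1 + sigma/lambda_D) exp(-r/lambda_D)/r`,
#' smoothly switched to zero between `2 lambda_D` and `3 lambda_D` with the
#' XPLOR switching polynomial, so that both the energy and its first
#' derivative are continuous at the switching radius and at the cutoff.
#'
#' @param r separation, nm
#' @param q1,q2 charge valences (e)
#' @param sigma contact diameter of the interacting beads, nm
#' @param lambda_D Debye length, nm
#' @param l_b Bjerrum length, nm
#' @return energy, kBT
#' @export
u_debye_huckel <- function(r, q1, q2, sigma, lambda_D = 1.0, l_b = 0.714) {
  if (any(r <= 0)) stop("separation must be positive", call. = FALSE)
  ron <- 2 * lambda_D
  rc <- 3 * lambda_D
  pref <- q1 * q2 * l_b * exp(sigma / lambda_D) / (1 + sigma / lambda_D)
  core <- pref * exp(-r / lambda_D) / r
  s <- rep(1, length(core))
  mid <- r > ron & r < rc
  if (any(mid)) {
    rc2 <- rc^2; ron2 <- ron^2; r2 <- r[mid]^2
    s[mid] <- (rc2 - r2)^2 * (rc2 + 2 * r2 - 3 * ron2) / (rc2 - ron2)^3
  }
  out <- core * s
  out[r >= rc] <- 0
  out
}

#' Harmonic bond and angle potentials
#'
#' `u_bond` is `kbond/2 (r - sigma)^2`; `u_angle` is `kangle/2 theta^2`
#' where `theta` is the deviation of a bonded triple from a straight line.
#'
#' @param r bond length, nm
#' @param sigma rest length, nm
#' @param kbond spring constant, kBT/nm^2
#' @return energy, kBT
#' @export
u_bond <- function(r, sigma, kbond) {
  if (any(r <= 0)) stop("bond length must be positive", call. = FALSE)
  0.5 * kbond * (r - sigma)^2
}

#' @rdname u_bond
#' @param theta deviation angle from a straight triple, rad
#' @param kangle bending constant, kBT/rad^2
#' @export
u_angle <- function(theta, kangle) 0.5 * kangle * theta^2

#' Bare Coulomb interaction (explicit-ion electrostatics)
#'
#' The explicit-ion Coulomb treatment (primitive-model ions with Ewald
#' long-range electrostatics) is not supported by this package; all
#' electrostatics use the screened [u_debye_huckel()] form.
#'
#' @param ... ignored
#' @export
u_coulomb <- function(...) {
  stop("explicit-ion Coulomb electrostatics are not supported; ",
       "use u_debye_huckel()", call. = FALSE)
}

#' Separation at which the Morse attraction is half its depth
#'
#' Used as the default contact criterion for subunit-subunit bonds (cluster
#' detection, dimer classification): the outer distance where the Morse term
#' equals -epsilon/2.
#'
#' @param params a [forcefield_params()] object
#' @return distance in nm
#' @export
morse_halfdepth_distance <- function(params = forcefield_params()) {
  # (m - 2) m = -1/2  =>  m = 1 - 1/sqrt(2) on the outer branch
  params$r0 * (1 - log(1 - 1 / sqrt(2)) / params$rho)
}

#' Capsomer-capsomer pair energy
#'
#' Sum of the geometry-guiding repulsions (Top-Top at `sigma_t`, Bottom-Top
#' at `sigma_b`) and the attractive Morse term between attractors, all
#' scaled by `epsilon`; intra-body pairs are excluded by construction.
#'
#' @param sub_i,sub_j subunit bead tables as returned by [subunit_beads()]
#' @param params a [forcefield_params()] object
#' @return energy in kBT
#' @export
capsomer_pair_energy <- function(sub_i, sub_j, params = forcefield_params()) {
  pos <- rbind(as.matrix(sub_i[, c("x", "y", "z")]),
               as.matrix(sub_j[, c("x", "y", "z")]))
  kinds <- c(sub_i$kind, sub_j$kind)
  keep <- kinds %in% c("attractor", "top", "bottom", "inert")
  sys <- bead_system(pos[keep, , drop = FALSE], kinds[keep],
                     body = rep(c(1L, 2L), c(sum(keep[seq_len(nrow(sub_i))]),
                                             sum(keep) - sum(keep[seq_len(nrow(sub_i))]))))
  total_energy(sys, params)$u_cc
}

#' Total energy of a bead system, decomposed
#'
#' Evaluates the full potential and returns the six-term decomposition:
#' capsomer-capsomer (`u_cc`), capsomer-polymer (`u_cp`), capsomer-ARM
#' (`u_ca`), polymer-polymer (`u_pp`), polymer-ARM (`u_pa`) and ARM-ARM
#' (`u_aa`), with bonded (bond/angle) contributions folded into the bucket
#' of the species they join. `total` is the sum of the six terms.
#'
#' @param system a [bead_system()]
#' @param params a [forcefield_params()] object
#' @param naive if TRUE use the all-pairs reference path instead of the
#'   linked-cell neighbor search (identical result; used for validation)
#' @return an object of class `energy_report`
#' @export
total_energy <- function(system, params = forcefield_params(), naive = FALSE) {
  rep <- cs_energy(as_cpp_system(system), unclass(params), naive)
  structure(rep, class = "energy_report")
}

#' @export
print.energy_report <- function(x, ...) {
  cat("<energy_report> (kBT)\n")
  for (nm in c("u_cc", "u_cp", "u_ca", "u_pp", "u_pa", "u_aa", "total"))
    cat(sprintf("  %-6s %.6g\n", nm, x[[nm]]))
  invisible(x)
}

#' Forces and rigid-body torques
#'
#' Analytic forces `-grad U` on every bead, plus the net force and torque
#' (about the body centroid) for each rigid body.
#'
#' @inheritParams total_energy
#' @return list with `forces` (N x 3), `energy` (an `energy_report`),
#'   `body_force` and `body_torque` (one row per rigid body)
#' @export
forces <- function(system, params = forcefield_params(), naive = FALSE) {
  out <- cs_forces(as_cpp_system(system), unclass(params), naive)
  F <- out$forces
  bodies <- sort(unique(system$body[system$body > 0]))
  bf <- bt <- matrix(0, length(bodies), 3)
  if (length(bodies)) {
    for (k in seq_along(bodies)) {
      m <- which(system$body == bodies[k])
      bf[k, ] <- colSums(F[m, , drop = FALSE])
      ctr <- colMeans(system$pos[m, , drop = FALSE])
      rel <- sweep(system$pos[m, , drop = FALSE], 2, ctr)
      bt[k, ] <- colSums(cbind(
        rel[, 2] * F[m, 3] - rel[, 3] * F[m, 2],
        rel[, 3] * F[m, 1] - rel[, 1] * F[m, 3],
        rel[, 1] * F[m, 2] - rel[, 2] * F[m, 1]))
    }
  }
  list(forces = F, energy = structure(out$energy, class = "energy_report"),
       body_ids = bodies, body_force = bf, body_torque = bt)
}

#' Read and write force-field configuration files
#'
#' Flat `key = value` text files holding every [forcefield_params()] field.
#'
#' @param params a `forcefield_params` object
#' @param file path
#' @export
write_forcefield <- function(params, file) {
  keep <- setdiff(names(params), c("sigma_xp", "sigma_xa", "sigma_ap"))
  writeLines(sprintf("%s = %.17g", keep, vapply(params[keep], as.numeric, 0)),
             file)
  invisible(file)
}

#' @rdname write_forcefield
#' @export
read_forcefield <- function(file) {
  ln <- readLines(file)
  ln <- ln[nzchar(trimws(ln)) & !startsWith(trimws(ln), "#")]
  kv <- strsplit(ln, "=", fixed = TRUE)
  vals <- lapply(kv, function(p) as.numeric(trimws(p[2])))
  names(vals) <- trimws(vapply(kv, `[`, "", 1))
  do.call(forcefield_params, vals)
}
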