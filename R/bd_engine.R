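#' Simulation configuration
#'
#' Settings of a Brownian dynamics run, in reduced units (kBT, nm, tu). The
#' default time step `dt = 1e-4` tu and 200 nm periodic box match the
#' standard assembly protocol; `gamma` is the translational friction per
#' bead (rigid bodies get the summed friction and a rotational friction
#' from their radius of gyration). Only equilibrium observables are
#' compared across runs, so `gamma` sets the time scale, not the sampled
#' distribution.
#'
#' @param dt time step, tu
#' @param n_steps number of steps
#' @param temperature kBT
#' @param box cubic box edge, nm (0 = open boundaries)
#' @param seed RNG seed
#' @param gamma friction per bead, kBT tu / nm^2
#' @param skin neighbor skin, nm (also the per-step displacement guard)
#' @param out_stride steps between stored frames (0 = final frame only)
#' @param permeable_subunit optional rigid-body id made permeable to the
#'   polymer before the run
#' @return an object of class `sim_config`
#' @export
sim_config <- function(dt = 1e-4, n_steps = 1e5, temperature = 1, box = 200,
                       seed = 1, gamma = 1, skin = 1, out_stride = 0,
                       permeable_subunit = NULL) {
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  structure(list(dt = dt, n_steps = n_steps, temperature = temperature,
                 box = box, seed = seed, gamma = gamma, skin = skin,
                 out_stride = out_stride,
                 permeable_subunit = permeable_subunit),
            class = "sim_config")
}

check_box <- function(system, params, config) {
  if (config$box > 0) {
    rc <- max(params$rcut_morse, params$sigma_t, params$sigma_b,
              3 * params$lambda_D)
    if (config$box <= 2 * rc)
      stop("box (", config$box, " nm) must exceed twice the largest ",
           "interaction cutoff (", rc, " nm)", call. = FALSE)
  }
}

#' Run Brownian dynamics
#'
#' Overdamped Langevin integration of a [bead_system()]: free beads follow
#' Euler-Maruyama updates, rigid bodies translate under their net force and
#' rotate under their net torque (small-angle quaternion updates with
#' isotropic mobilities). Identical seeds give bit-identical trajectories.
#'
#' @param system a `bead_system`
#' @param params a [forcefield_params()]
#' @param config a [sim_config()]
#' @param fixed_bodies rigid-body ids held immobile
#' @return an object of class `cs_trajectory`: stored `frames` (positions),
#'   `frame_steps`, `frame_energies` (six-term decomposition per frame),
#'   the final `system`, and the integrator `status`
#' @export
run_bd <- function(system, params = forcefield_params(),
                   config = sim_config(), fixed_bodies = integer(0)) {
  check_box(system, params, config)
  sys <- system
  sys$box <- config$box
  if (!is.null(config$permeable_subunit))
    sys <- set_permeable(sys, config$permeable_subunit)
  out <- cs_bd_run(as_cpp_system(sys), unclass(params), config$dt,
                   config$n_steps, config$temperature, config$gamma,
                   as.integer(config$seed), config$out_stride, config$skin,
                   as.integer(fixed_bodies))
  if (out$status == "displacement_overflow")
    stop("single-step displacement exceeded skin/2 = ", config$skin / 2,
         " nm; reduce dt (last good step kept)", call. = FALSE)
  final <- sys
  final$pos <- out$pos
  fe <- if (length(out$frame_energies))
    do.call(rbind, out$frame_energies) else matrix(0, 0, 6)
  colnames(fe) <- c("u_cc", "u_cp", "u_ca", "u_pp", "u_pa", "u_aa")
  structure(list(frames = out$frames, frame_steps = out$frame_steps,
                 frame_energies = fe, system = final, status = out$status,
                 n_capped = out$n_capped, config = config),
            class = "cs_trajectory")
}

#' @export
print.cs_trajectory <- function(x, ...) {
  cat(sprintf("<cs_trajectory> %d frames over %g steps (status: %s)\n",
              length(x$frames), max(c(0, x$frame_steps)), x$status))
  invisible(x)
}

#' Advance a system by one (or a few) BD steps
#'
#' @inheritParams run_bd
#' @param n_steps steps to take (default 1)
#' @return the advanced `bead_system`
#' @export
bd_step <- function(system, params = forcefield_params(),
                    config = sim_config(), n_steps = 1) {
  config$n_steps <- n_steps
  config$out_stride <- 0
  run_bd(system, params, config)$system
}

#' Extract one frame of a trajectory as a bead system
#' @param traj a `cs_trajectory`
#' @param i frame index (default last)
#' @export
frame_system <- function(traj, i = length(traj$frames)) {
  sys <- traj$system
  sys$pos <- traj$frames[[i]]
  sys
}

random_rotation <- function() {
  # uniform random rotation via normalized quaternion
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Set up and run a dynamical assembly simulation
#'
#' Places `n_subunits` free subunits at random non-overlapping poses around
#' a polymer (random-walk initialized at the box center), relaxes residual
#' overlaps with a capped push-off, and runs Brownian dynamics. The
#' standard protocol (12 subunits in a 200 nm box, i.e. 12 uM, Debye length
#' 1 nm) is the default; production-scale runs (2e8 steps) are exposed via
#' the shipped configuration files rather than run here.
#'
#' @param template a [build_subunit()] template
#' @param topology polymer topology from [build_topology()] (NULL for
#'   subunits only)
#' @param params force field
#' @param config simulation configuration
#' @param n_subunits free subunits to place
#' @return a `cs_trajectory`
#' @export
run_assembly <- function(template, topology = NULL,
                         params = forcefield_params(),
                         config = sim_config(), n_subunits = 12) {
  set.seed(config$seed)
  box <- config$box
  parts <- list()
  if (!is.null(topology)) {
    pos <- na_initial_coords(topology, params)
    pos <- sweep(pos, 2, colMeans(pos))
    pos <- sweep(pos, 2, rep(box / 2, 3), `+`)
    parts[[1]] <- topology_system(topology, pos, params, box = box)
  }
  # random subunit poses, resampled on overlap with previous content
  placed <- matrix(NA_real_, 0, 3)
  min_sep <- 2.2 * template$pentagon_circumradius
  for (s in seq_len(n_subunits)) {
    repeat {
      ctr <- stats::runif(3, 0, box)
      if (nrow(placed) == 0) break
      d <- sqrt(rowSums(sweep(placed, 2, ctr)^2))
      if (min(d) > min_sep) break
    }
    placed <- rbind(placed, ctr)
    parts[[length(parts) + 1]] <-
      subunit_beads(template, ctr, random_rotation(), body_id = 1L)
  }
  sys <- do.call(combine_systems, parts)
  sys$box <- box
  po <- cs_pushoff(as_cpp_system(sys), unclass(params), 100, 0.05)
  sys$pos <- po$pos
  run_bd(sys, params, config)
}

#' Replica-exchange Brownian dynamics
#'
#' Runs `n_replicas` copies of the system at temperatures distributed
#' geometrically between `T_min` and `T_max`; every `swap_stride` steps
#' neighboring temperature slots attempt a configuration exchange under the
#' Metropolis criterion on `(beta_i - beta_j)(U_j - U_i)`.
#'
#' @param system a `bead_system`
#' @param params force field
#' @param config base [sim_config()] (its `temperature` is ignored)
#' @param n_replicas number of replicas (>= 2)
#' @param T_min,T_max temperature ladder endpoints, kBT
#' @param swap_stride steps between swap attempts
#' @param n_swaps number of swap rounds
#' @return list with per-replica final systems, the temperature ladder,
#'   the overall swap `acceptance` fraction, and per-replica observable
#'   traces (total energy per round)
#' @export
run_rex <- function(system, params = forcefield_params(),
                    config = sim_config(), n_replicas = 12,
                    T_min = 1.0, T_max = 1.5, swap_stride = 1000,
                    n_swaps = 20) {
  if (n_replicas < 2) stop("need at least two replicas", call. = FALSE)
  temps <- T_min * (T_max / T_min)^((seq_len(n_replicas) - 1) /
                                      max(1, n_replicas - 1))
  reps <- replicate(n_replicas, system, simplify = FALSE)
  set.seed(config$seed)
  n_acc <- 0; n_try <- 0
  energies <- matrix(NA_real_, n_swaps, n_replicas)
  for (round in seq_len(n_swaps)) {
    for (r in seq_len(n_replicas)) {
      cfg <- config
      cfg$temperature <- temps[r]
      cfg$n_steps <- swap_stride
      cfg$seed <- config$seed + 7919L * round + r
      reps[[r]] <- run_bd(reps[[r]], params, cfg)$system
    }
    U <- vapply(reps, function(s) total_energy(s, params)$total, 0)
    energies[round, ] <- U
    first <- if (round %% 2 == 1) 1 else 2
    for (r in seq(first, n_replicas - 1, by = 2)) {
      n_try <- n_try + 1
      dlt <- (1 / temps[r] - 1 / temps[r + 1]) * (U[r + 1] - U[r])
      if (dlt <= 0 || stats::runif(1) < exp(-dlt)) {
        tmp <- reps[[r]]; reps[[r]] <- reps[[r + 1]]; reps[[r + 1]] <- tmp
        tmpU <- U[r]; U[r] <- U[r + 1]; U[r + 1] <- tmpU
        n_acc <- n_acc + 1
      }
    }
  }
  list(replicas = reps, temperatures = temps,
       acceptance = if (n_try > 0) n_acc / n_try else NA_real_,
       energies = energies)
}

#' Export coordinates as XYZ text (VMD-compatible)
#'
#' One line per bead with the bead kind as the element field; trajectories
#' write one XYZ block per frame.
#'
#' @param x a `bead_system` or `cs_trajectory`
#' @param file path
#' @export
write_xyz <- function(x, file) {
  con <- file(file, "w")
  on.exit(close(con))
  blocks <- if (inherits(x, "cs_trajectory"))
    lapply(seq_along(x$frames), function(i) frame_system(x, i)) else list(x)
  for (sys in blocks) {
    kn <- toupper(substr(bead_kind(sys), 1, 1))
    writeLines(as.character(nrow(sys$pos)), con)
    writeLines("capsidsim frame", con)
    writeLines(sprintf("%s %.4f %.4f %.4f", kn, sys$pos[, 1], sys$pos[, 2],
                       sys$pos[, 3]), con)
  }
  invisible(file)
}

#' Export a bead system as a PDB-style coordinate file
#'
#' Uses bio3d when available; one HETATM record per pseudoatom with the
#' bead kind in the atom-name field.
#'
#' @param system a `bead_system`
#' @param file path
#' @export
write_pdb <- function(system, file) {
  kn <- toupper(substr(bead_kind(system), 1, 2))
  if (requireNamespace("bio3d", quietly = TRUE)) {
    bio3d::write.pdb(file = file, xyz = as.numeric(t(system$pos)),
                     type = rep("HETATM", nrow(system$pos)),
                     elety = kn, resid = rep("CGB", nrow(system$pos)),
                     chain = rep("A", nrow(system$pos)))
  } else {
    lines <- sprintf(
      "HETATM%5d %-4s CGB A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
      seq_len(nrow(system$pos)) %% 100000, kn,
      seq_len(nrow(system$pos)) %% 10000,
      system$pos[, 1], system$pos[, 2], system$pos[, 3])
    writeLines(c(lines, "END"), file)
  }
  invisible(file)
}
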