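## Equilibrium estimators: Widom chain-increment chemical potentials,
## optimal packaged length via the semipermeable-subunit method, the
## encapsidation free energy, and subunit dimerization free energies.

#' Monte Carlo sampling of an unconfined polymer
#'
#' Metropolis sampling of a (possibly base-paired) polymer in open space
#' under the model force field, mixing local bead displacements, crankshaft
#' rotations of base-pair-closed backbone intervals about their anchor
#' axis, and end pivots. Nested pairings guarantee a rich supply of closed
#' intervals, so branched structures equilibrate as well as linear chains.
#' The run starts from [na_initial_coords()] (or `init`), relaxes overlaps
#' with a capped push-off, and discards `warmup_frac` of the samples.
#'
#' If move acceptance drops below 1% the move amplitudes are halved and the
#' run is repeated once (with a warning).
#'
#' @param topology an [build_topology()] object
#' @param params force field
#' @param n_moves MC move attempts
#' @param seed RNG seed
#' @param init optional N x 3 starting coordinates
#' @param sample_stride moves between radius-of-gyration samples
#' @param frame_stride moves between stored frames (0 = none)
#' @param warmup_frac fraction of samples discarded as warm-up
#' @param local_disp local-move half-width, nm
#' @param max_angle maximum rotation of interval moves, rad
#' @return list with `rg` (post-warmup samples), `rg_mean`, `rg_se`
#'   (block-averaged), acceptance rates, stored `frames`, final `pos`
#' @export
mc_polymer_sampler <- function(topology, params = forcefield_params(),
                               n_moves = 2e4, seed = 1, init = NULL,
                               sample_stride = 50, frame_stride = 0,
                               warmup_frac = 0.3, local_disp = 0.3,
                               max_angle = pi) {
  set.seed(seed)
  if (is.null(init)) init <- na_initial_coords(topology, params)
  sys <- topology_system(topology, init, params)
  po <- cs_pushoff(as_cpp_system(sys), unclass(params), 150, 0.05)
  run1 <- function(ld, ma) {
    cs_mc_polymer(po$pos, topology$charge, as.integer(topology$partner),
                  topology$bonds, topology$bond_r0, topology$bond_k,
                  topology$angles, topology$angle_k, unclass(params),
                  beta = 1, n_moves = n_moves, seed = as.integer(seed),
                  sample_stride = sample_stride, frame_stride = frame_stride,
                  local_disp = ld, max_angle = ma)
  }
  out <- run1(local_disp, max_angle)
  acc <- c(out$accept_local, out$accept_interval)
  if (any(acc < 0.01, na.rm = TRUE)) {
    warning("MC acceptance below 1%; halving move amplitudes and rerunning",
            call. = FALSE)
    out <- run1(local_disp / 2, max_angle / 2)
  }
  rg <- out$rg
  keep <- rg[-seq_len(floor(length(rg) * warmup_frac))]
  se <- block_se(keep)
  list(rg = keep, rg_mean = mean(keep), rg_se = se,
       accept_local = out$accept_local,
       accept_interval = out$accept_interval,
       frames = out$frames, pos = out$pos, energy = out$energy)
}

block_se <- function(x, n_blocks = 10) {
  n <- length(x)
  if (n < 2 * n_blocks) return(stats::sd(x) / sqrt(max(1, n)))
  bl <- split(x, cut(seq_len(n), n_blocks, labels = FALSE))
  m <- vapply(bl, mean, 0)
  stats::sd(m) / sqrt(length(m))
}

#' Solution radius of gyration of a model NA
#'
#' Equilibrium RG of an unconfined chain, averaged over independent seeds
#' of the Monte Carlo sampler.
#'
#' @param topology an [build_topology()] object (or a function(seed) that
#'   returns one, to average over structures as well)
#' @param params force field
#' @param n_seeds independent replicates (>= 3 recommended)
#' @param n_moves MC moves per replicate
#' @param seed base seed
#' @param ... passed to [mc_polymer_sampler()]
#' @return list with `rg` (grand mean), `se` (between-seed), per-seed means
#' @export
solution_rg <- function(topology, params = forcefield_params(), n_seeds = 3,
                        n_moves = 2e4, seed = 1, ...) {
  means <- vapply(seq_len(n_seeds), function(s) {
    topo <- if (is.function(topology)) topology(seed + s) else topology
    mc_polymer_sampler(topo, params, n_moves = n_moves, seed = seed + s,
                       ...)$rg_mean
  }, 0)
  list(rg = mean(means), se = stats::sd(means) / sqrt(n_seeds),
       per_seed = means)
}

truncnorm_sample <- function(n, mean, sd, k = 3) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2 * n, mean, sd)
    x <- x[abs(x - mean) <= k * sd & x > 0]
    out <- c(out, x)
  }
  out[seq_len(n)]
}

#' Residual chemical potential by Widom chain-increment insertion
#'
#' Inserts a test polymer segment at a chain end of each supplied
#' configuration, with the bond length drawn from a normal distribution
#' matched to the equilibrium bond distribution and truncated at +-3
#' standard deviations; the bias of the proposal is removed a posteriori by
#' importance reweighting against the Boltzmann bond distribution
#' (restricted to the same truncation window, so a non-interacting chain
#' gives exactly zero). The estimator is
#' `-beta mu_r = log( sum_t w_t exp(-beta UI_t) / I )` with
#' `w = l^2 exp(-beta U_bond(l)) / g(l)` and `I` the corresponding
#' single-bond integral.
#'
#' @param configs list of `bead_system` snapshots of the equilibrated chain
#'   (chain beads must be of kind `polymer`; any capsid content may be
#'   present)
#' @param chain_idx indices of the chain beads in order along the backbone
#' @param params force field
#' @param n_insertions insertions per configuration per end
#' @param end `head`, `tail` or `both`
#' @param seed RNG seed
#' @param kangle bending constant applied to the inserted triple
#' @return list with `mu_r` (kBT), `se` (jackknife over configurations),
#'   and the per-configuration estimates; `mu_r = Inf` flags all-overlap
#'   insertions
#' @export
widom_mu_r <- function(configs, chain_idx, params = forcefield_params(),
                       n_insertions = 1000, end = c("both", "head", "tail"),
                       seed = 1, kangle = params$kangle_ss) {
  end <- match.arg(end)
  if (inherits(configs, "bead_system")) configs <- list(configs)
  beta <- 1
  sd_b <- sqrt(1 / (beta * params$kbond))
  r0 <- params$sigma_p
  # single-bond normalization over the truncation window
  lo <- max(1e-9, r0 - 3 * sd_b); hi <- r0 + 3 * sd_b
  I <- stats::integrate(function(l) l^2 * exp(-beta * 0.5 * params$kbond *
                                                (l - r0)^2), lo, hi)$value
  g_norm <- stats::pnorm(hi, r0, sd_b) - stats::pnorm(lo, r0, sd_b)
  ends <- switch(end, head = 1L, tail = 2L, both = c(1L, 2L))
  per_cfg <- numeric(0)
  all_num <- all_den <- 0
  k <- 0
  for (cfg in configs) {
    k <- k + 1
    num <- den <- 0
    for (e in ends) {
      ei <- if (e == 1L) chain_idx[1] else chain_idx[length(chain_idx)]
      pi_ <- if (e == 1L) {
        if (length(chain_idx) > 1) chain_idx[2] else -1L
      } else {
        if (length(chain_idx) > 1) chain_idx[length(chain_idx) - 1] else -1L
      }
      w <- cs_widom(as_cpp_system(cfg), unclass(params), as.integer(ei),
                    as.integer(pi_), r0, params$kbond, kangle, beta,
                    as.integer(n_insertions),
                    as.integer(seed + 131L * k + e), 3)
      l <- w$l
      gl <- stats::dnorm(l, r0, sd_b) / g_norm
      wt <- l^2 * exp(-beta * 0.5 * params$kbond * (l - r0)^2) / gl
      num <- num + sum(wt * exp(-beta * w$ui))
      den <- den + length(l)
    }
    per_cfg <- c(per_cfg, -log((num / den) / I) / beta)
    all_num <- all_num + num
    all_den <- all_den + den
  }
  if (all_num == 0)
    return(list(mu_r = Inf, se = NA_real_, per_config = per_cfg,
                note = "all insertions overlapped"))
  mu <- -log((all_num / all_den) / I) / beta
  se <- if (length(per_cfg) > 1)
    stats::sd(per_cfg[is.finite(per_cfg)]) /
      sqrt(sum(is.finite(per_cfg))) else NA_real_
  list(mu_r = mu, se = se, per_config = per_cfg)
}

#' Residual chemical potential curve for a growing chain
#'
#' Replicates the chain-increment protocol: starting from a short chain,
#' alternate relaxation dynamics, Widom insertions at the chain ends, and
#' chain growth by one segment (placed at an insertion position sampled
#' with probability proportional to its Boltzmann weight). Works for a
#' chain free in solution or inside an `environment` (e.g. an assembled
#' capsid with fixed subunits).
#'
#' @param np_grid segment counts at which mu_r is recorded
#' @param params force field
#' @param environment optional `bead_system` merged with the chain (its
#'   rigid bodies are held fixed during relaxation)
#' @param n_relax BD steps between increments
#' @param n_insertions insertions per recorded point
#' @param config base [sim_config()] for the relaxation dynamics
#' @param context label stored with the curve (`free` or `encapsidated`)
#' @param start optional starting position of the first bead
#' @return a data.frame of class `chemical_potential_curve` with columns
#'   `np`, `mu_r`, `se`, `context`
#' @export
chemical_potential_curve <- function(np_grid, params = forcefield_params(),
                                     environment = NULL, n_relax = 2000,
                                     n_insertions = 500,
                                     config = sim_config(box = 0),
                                     context = if (is.null(environment))
                                       "free" else "encapsidated",
                                     start = c(0, 0, 0)) {
  np_grid <- sort(unique(as.integer(np_grid)))
  np_max <- max(np_grid)
  set.seed(config$seed)
  chain_pos <- matrix(start, 1, 3)
  fixed <- integer(0)
  if (!is.null(environment))
    fixed <- unique(environment$body[environment$body > 0])
  build_sys <- function() {
    chain <- bead_system(chain_pos, "polymer", charge = -1,
                         bonds = if (nrow(chain_pos) > 1)
                           cbind(seq_len(nrow(chain_pos) - 1),
                                 2:nrow(chain_pos)) else NULL,
                         bond_r0 = rep(params$sigma_p,
                                       max(0, nrow(chain_pos) - 1)),
                         bond_k = rep(params$kbond,
                                      max(0, nrow(chain_pos) - 1)),
                         box = config$box)
    if (is.null(environment)) chain else
      combine_systems(environment, chain)
  }
  rows <- list()
  for (np in 2:np_max) {
    # grow by one bead: sample an insertion position by Boltzmann weight
    sys <- build_sys()
    n_env <- if (is.null(environment)) 0L else nrow(environment$pos)
    ei <- n_env + nrow(chain_pos)
    prev <- if (nrow(chain_pos) > 1) ei - 1L else -1L
    sd_b <- sqrt(1 / params$kbond)
    ntry <- 200
    w <- cs_widom(as_cpp_system(sys), unclass(params), as.integer(ei),
                  as.integer(prev), params$sigma_p, params$kbond,
                  params$kangle_ss, 1, ntry,
                  as.integer(config$seed + np), 3)
    lw <- exp(-w$ui)
    pick <- sample.int(ntry, 1, prob = pmax(lw, 1e-300))
    chain_pos <- rbind(chain_pos, w$xyz[pick, ])
    # relax
    sys <- build_sys()
    cfg <- config
    cfg$n_steps <- n_relax
    cfg$seed <- config$seed + 10007L * np
    traj <- run_bd(sys, params, cfg, fixed_bodies = fixed)
    pos <- traj$system$pos
    chain_pos <- pos[(n_env + 1):nrow(pos), , drop = FALSE]
    if (np %in% np_grid) {
      sys <- build_sys()
      sys$pos <- pos
      idx <- (n_env + 1):nrow(pos)
      est <- widom_mu_r(list(sys), idx, params, n_insertions,
                        seed = config$seed + np)
      rows[[length(rows) + 1]] <-
        data.frame(np = np, mu_r = est$mu_r,
                   se = ifelse(is.na(est$se), abs(est$mu_r) * 0.1 + 0.05,
                               est$se),
                   context = context)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("chemical_potential_curve", class(out))
  out
}

#' Encapsidation free energy from chemical-potential curves
#'
#' Trapezoidal integral of the difference between the encapsidated and free
#' residual chemical potentials from 0 to `L`, with propagated standard
#' error. By convention `mu_r(np) = 0` at np = 0.
#'
#' @param free_curve,encaps_curve `chemical_potential_curve` data frames
#' @param L upper integration limit (segments)
#' @return list with `dG` (kBT) and `se`
#' @export
encapsidation_free_energy <- function(free_curve, encaps_curve, L) {
  np <- intersect(free_curve$np, encaps_curve$np)
  np <- sort(np[np <= L])
  if (length(np) < 2)
    stop("curves share fewer than two grid points below L = ", L,
         call. = FALSE)
  d <- encaps_curve$mu_r[match(np, encaps_curve$np)] -
    free_curve$mu_r[match(np, free_curve$np)]
  se2 <- encaps_curve$se[match(np, encaps_curve$np)]^2 +
    free_curve$se[match(np, free_curve$np)]^2
  x <- c(0, np)
  y <- c(0, d)
  v <- c(0, se2)
  wgt <- numeric(length(x))
  for (i in seq_along(x)) {
    if (i > 1) wgt[i] <- wgt[i] + (x[i] - x[i - 1]) / 2
    if (i < length(x)) wgt[i] <- wgt[i] + (x[i + 1] - x[i]) / 2
  }
  list(dG = sum(wgt * y), se = sqrt(sum(wgt^2 * v)))
}

#' Intersection of free and encapsidated chemical-potential curves
#'
#' Fits local linear models to each curve around the sign change of their
#' difference and intersects the fits; the confidence interval comes from a
#' parametric bootstrap over the per-point standard errors.
#'
#' @param free_curve,encaps_curve `chemical_potential_curve` data frames
#' @param n_boot bootstrap draws
#' @return list with `np_star`, `ci` (2.5/97.5%)
#' @export
curve_intersection <- function(free_curve, encaps_curve, n_boot = 500) {
  np <- sort(intersect(free_curve$np, encaps_curve$np))
  if (length(np) < 2) stop("curves do not overlap", call. = FALSE)
  d <- encaps_curve$mu_r[match(np, encaps_curve$np)] -
    free_curve$mu_r[match(np, free_curve$np)]
  se <- sqrt(encaps_curve$se[match(np, encaps_curve$np)]^2 +
               free_curve$se[match(np, free_curve$np)]^2)
  cross1 <- function(dd) {
    sg <- which(diff(sign(dd)) != 0)
    if (!length(sg)) return(NA_real_)
    i <- sg[1]
    lo <- max(1, i - 2); hi <- min(length(np), i + 3)
    x <- np[lo:hi]
    fit <- stats::lm(dd[lo:hi] ~ x)
    unname(-stats::coef(fit)[1] / stats::coef(fit)[2])
  }
  est <- cross1(d)
  boots <- vapply(seq_len(n_boot), function(b)
    cross1(d + stats::rnorm(length(d), 0, se)), 0)
  list(np_star = est,
       ci = stats::quantile(boots, c(0.025, 0.975), na.rm = TRUE))
}

#' Optimal packaged length via the semipermeable subunit
#'
#' Brownian dynamics of a preassembled capsid with one subunit permeable to
#' the polymer and a long chain threaded through it; the number of
#' encapsidated segments (bead centers inside the excluder shell's
#' inscribed sphere plus half a bead-diameter margin) is averaged after
#' convergence, over independent seeds.
#'
#' @param capsid result of [build_assembled_capsid()]
#' @param topology polymer topology (length well above the expected
#'   optimum)
#' @param params force field
#' @param config base [sim_config()]; `permeable_subunit` defaults to 1
#' @param n_seeds independent replicates (>= 3)
#' @param margin counting margin, nm (default `0.5 * sigma_p`)
#' @param fixed_capsid hold the capsid rigid bodies in place
#' @return list with `leq` (mean), `se`, per-seed values, convergence info
#'   and the margin sensitivity (`leq` recomputed at margin +- 0.25 nm)
#' @export
equilibrium_length <- function(capsid, topology,
                               params = forcefield_params(),
                               config = sim_config(box = 0, out_stride = 2000),
                               n_seeds = 3, margin = 0.5 * params$sigma_p,
                               fixed_capsid = TRUE) {
  rin <- capsid$layout$inradius
  r_enc <- rin - params$sigma_x / 2 + margin
  center <- capsid$layout$center
  if (is.null(config$permeable_subunit)) config$permeable_subunit <- 1L
  perm <- config$permeable_subunit
  count_inside <- function(pos, idx, rr) {
    d <- sqrt(rowSums(sweep(pos[idx, , drop = FALSE], 2, center)^2))
    sum(d < rr)
  }
  res <- lapply(seq_len(n_seeds), function(s) {
    # thread the chain start through the permeable face: a short stretch
    # inside along the face axis, a straight exit through the face, and a
    # self-avoiding-ish walk kept outside the shell for the remainder
    face_n <- capsid$layout$normals[perm, ]
    set.seed(config$seed + s)
    npol <- topology$n
    a <- params$sigma_p
    pos <- matrix(NA_real_, npol, 3)
    inside_len <- min(10L, npol)
    for (i in seq_len(inside_len))
      pos[i, ] <- center + face_n * (rin - 1 - a * (inside_len - i))
    exit_len <- min(inside_len + 8L, npol)
    if (npol > inside_len)
      for (i in (inside_len + 1):exit_len)
        pos[i, ] <- center + face_n * (rin - 1 + a * (i - inside_len))
    if (npol > exit_len) {
      dirv <- face_n
      for (i in (exit_len + 1):npol) {
        for (try in 1:20) {
          stp <- dirv + 0.4 * stats::rnorm(3)
          stp <- stp / sqrt(sum(stp^2))
          cand <- pos[i - 1, ] + a * stp
          if (sqrt(sum((cand - center)^2)) > rin + 2) break
          dirv <- (pos[i - 1, ] - center)
          dirv <- dirv / sqrt(sum(dirv^2))
        }
        pos[i, ] <- cand
        dirv <- stp
      }
    }
    pol <- topology_system(topology, pos, params)
    sys <- combine_systems(capsid$system, pol)
    sys <- set_permeable(sys, perm)
    fixed <- if (fixed_capsid)
      sort(unique(sys$body[sys$body > 0])) else integer(0)
    # relax ARM/polymer overlaps with the shell held in place, then a
    # gentle pre-relaxation run before production
    po <- cs_pushoff(as_cpp_system(sys), unclass(params), 300, 0.05, FALSE)
    sys$pos <- po$pos
    pre <- config
    pre$dt <- config$dt / 10
    pre$n_steps <- 2000
    pre$out_stride <- 0
    pre$seed <- config$seed + 5000L + s
    sys <- run_bd(sys, params, pre, fixed_bodies = fixed)$system
    cfg <- config
    cfg$seed <- config$seed + s
    traj <- run_bd(sys, params, cfg, fixed_bodies = fixed)
    idx <- which(traj$system$type == BEAD_KINDS[["polymer"]])
    counts <- vapply(traj$frames, count_inside, 0, idx = idx, rr = r_enc)
    nfr <- length(counts)
    tail_counts <- counts[max(1, floor(nfr / 2)):nfr]
    if (max(tail_counts) >= npol - 2)
      stop("polymer fully packaged: supply a longer polymer", call. = FALSE)
    final_pos <- traj$system$pos
    c(mean(tail_counts),
      count_inside(final_pos, idx, r_enc - 0.25),
      count_inside(final_pos, idx, r_enc + 0.25))
  })
  m <- vapply(res, `[`, 0, 1)
  list(leq = mean(m), se = stats::sd(m) / sqrt(n_seeds), per_seed = m,
       margin = margin,
       margin_sensitivity = c(lo = mean(vapply(res, `[`, 0, 2)),
                              hi = mean(vapply(res, `[`, 0, 3))))
}

#' Subunit dimerization free energy
#'
#' Two subunits with a single attractive edge (the other attractors inert)
#' in a periodic box; the dimer fraction over a long trajectory gives
#' `Kd = 4 (1 - p)^2 / (p V N_A)` in molar units and
#' `gcc = -kBT ln(css / Kd)` with standard state `css = 1 M`. A
#' configuration counts as a dimer when any active attractor pair is closer
#' than the Morse half-depth distance. The multiplicity correction
#' `-T dsc = ln(25/2)` for distinguishable pentagon edges is reported
#' alongside.
#'
#' @param epsilon attraction strength, kBT
#' @param params force field (epsilon is overridden)
#' @param config [sim_config()]; a small box samples association faster
#' @param template_params capsid parameters for the subunits (ARM-free by
#'   default to speed sampling; pass e.g. `simple_capsid_params()` for the
#'   ARM effect)
#' @return an object of class `binding_free_energy`
#' @export
dimer_binding <- function(epsilon, params = forcefield_params(),
                          config = sim_config(box = 40, n_steps = 2e5,
                                              out_stride = 200),
                          template_params = capsid_params(name = "armfree",
                                                          arm_length = 0,
                                                          arm_net_charge = 0)) {
  params$epsilon <- epsilon
  tpl <- build_subunit(template_params, ff = params,
                       active_attractors = 1:2)
  set.seed(config$seed)
  s1 <- subunit_beads(tpl, c(config$box / 2 - 4, config$box / 2,
                             config$box / 2), diag(3))
  s2 <- subunit_beads(tpl, c(config$box / 2 + 4, config$box / 2,
                             config$box / 2),
                      random_rotation())
  sys <- combine_systems(s1, s2)
  sys$box <- config$box
  traj <- run_bd(sys, params, config)
  rcut <- morse_halfdepth_distance(params)
  att <- which(traj$system$type == BEAD_KINDS[["attractor"]])
  body <- traj$system$body[att]
  is_dimer <- vapply(traj$frames, function(P) {
    p <- P[att, , drop = FALSE]
    for (i in which(body == 1)) {
      d <- p[body == 2, , drop = FALSE]
      dd <- sweep(d, 2, p[i, ])
      dd <- dd - config$box * round(dd / config$box)
      if (min(sqrt(rowSums(dd^2))) < rcut) return(TRUE)
    }
    FALSE
  }, TRUE)
  p_d <- mean(is_dimer)
  v_l <- config$box^3 * 1e-24  # nm^3 to liters
  n_av <- 6.02214076e23
  kd <- if (p_d <= 0) Inf else if (p_d >= 1) 0 else
    4 * (1 - p_d)^2 / (p_d * v_l * n_av)
  gcc <- if (is.finite(kd) && kd > 0) -log(1 / kd) else
    if (kd == 0) -Inf else Inf
  structure(list(epsilon = epsilon, Kd = kd, gcc = gcc,
                 p_dimer = p_d, n_frames = length(is_dimer),
                 delta_sc = log(25 / 2),
                 note = if (!any(is_dimer)) "no dimer events: Kd is a lower bound"
                        else NULL),
            class = "binding_free_energy")
}

#' @export
print.binding_free_energy <- function(x, ...) {
  cat(sprintf("<binding_free_energy> eps=%.2f kBT: Kd=%.3g M, gcc=%.3g kBT (p_dimer=%.3f)\n",
              x$epsilon, x$Kd, x$gcc, x$p_dimer))
  invisible(x)
}

#' Persistence length from bond-vector correlations
#'
#' Fits the segmental autocorrelation `<u_i . u_{i+k}>` to an exponential
#' decay in contour separation; the decay constant is the persistence
#' length.
#'
#' @param frames list of N x 3 coordinate matrices
#' @param idx bead indices of the chain (in backbone order)
#' @param bond_length contour step per bond, nm
#' @param max_sep largest separation (bonds) used in the fit
#' @return persistence length, nm
#' @export
persistence_length <- function(frames, idx = NULL, bond_length = 0.5,
                               max_sep = 20) {
  acc <- numeric(max_sep); cnt <- numeric(max_sep)
  for (P in frames) {
    p <- if (is.null(idx)) P else P[idx, , drop = FALSE]
    u <- diff(p)
    u <- u / sqrt(rowSums(u^2))
    nb <- nrow(u)
    for (k in seq_len(min(max_sep, nb - 1))) {
      acc[k] <- acc[k] + sum(rowSums(u[1:(nb - k), , drop = FALSE] *
                                       u[(1 + k):nb, , drop = FALSE]))
      cnt[k] <- cnt[k] + (nb - k)
    }
  }
  cor_k <- acc / pmax(cnt, 1)
  k <- seq_len(max_sep)
  ok <- cor_k > 0.01
  fit <- stats::lm(log(cor_k[ok]) ~ 0 + k[ok])
  -bond_length / stats::coef(fit)[[1]]
}
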