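# Independent reference implementations used as oracles; these deliberately
# re-derive the physics in plain R, independent of the compiled kernels.

# all-pairs reference energy, including the linear force cap below
# cap_frac * sigma that the kernels apply for integrator stability
oracle_rep_lj <- function(x, sigma, cap_frac = 0.2) {
  xc <- cap_frac * sigma
  if (x >= sigma) return(0)
  if (x >= xc) return((sigma / x)^12 - 1)
  uc <- (sigma / xc)^12 - 1
  fc <- 12 * sigma^12 / xc^13
  uc + fc * (xc - x)
}

oracle_pair_energy <- function(ti, tj, qi, qj, r, p) {
  ts <- sort(c(ti, tj))
  if (ts[1] == "arm" && ts[2] == "polymer")
    return(oracle_rep_lj(r, p$sigma_ap) +
             u_debye_huckel(r, qi, qj, p$sigma_ap, p$lambda_D, p$l_b))
  if (ti == "attractor" && tj == "attractor")
    return(p$epsilon * u_morse(r, p$r0, p$rho, p$rcut_morse))
  if (ti == "top" && tj == "top")
    return(p$epsilon * oracle_rep_lj(r, p$sigma_t))
  if (ts[1] == "bottom" && ts[2] == "top")
    return(p$epsilon * oracle_rep_lj(r, p$sigma_b))
  if (ts[1] == "excluder" && ts[2] == "polymer")
    return(oracle_rep_lj(r, p$sigma_xp))
  if (ts[1] == "arm" && ts[2] == "excluder")
    return(oracle_rep_lj(r, p$sigma_xa))
  if (ti == "polymer" && tj == "polymer")
    return(oracle_rep_lj(r, p$sigma_p) +
             u_debye_huckel(r, qi, qj, p$sigma_p, p$lambda_D, p$l_b))
  if (ti == "arm" && tj == "arm")
    return(oracle_rep_lj(r, p$sigma_a) +
             u_debye_huckel(r, qi, qj, p$sigma_a, p$lambda_D, p$l_b))
  0
}

oracle_total_energy <- function(sys, p) {
  n <- nrow(sys$pos)
  kinds <- names(c(attractor = 0, top = 1, bottom = 2, excluder = 3,
                   arm = 4, polymer = 5, inert = 6))[sys$type + 1]
  bonded <- matrix(FALSE, n, n)
  if (nrow(sys$bonds)) bonded[sys$bonds] <- TRUE
  bonded <- bonded | t(bonded)
  tot <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (sys$body[i] > 0 && sys$body[i] == sys$body[j]) next
      if (bonded[i, j]) next
      if (kinds[i] == "inert" || kinds[j] == "inert") next
      d <- sys$pos[i, ] - sys$pos[j, ]
      if (sys$box > 0) d <- d - sys$box * round(d / sys$box)
      tot <- tot + oracle_pair_energy(kinds[i], kinds[j], sys$charge[i],
                                      sys$charge[j], sqrt(sum(d^2)), p)
    }
  }
  for (b in seq_len(nrow(sys$bonds))) {
    r <- sqrt(sum((sys$pos[sys$bonds[b, 1], ] - sys$pos[sys$bonds[b, 2], ])^2))
    tot <- tot + 0.5 * sys$bond_k[b] * (r - sys$bond_r0[b])^2
  }
  for (a in seq_len(nrow(sys$angles))) {
    v1 <- sys$pos[sys$angles[a, 1], ] - sys$pos[sys$angles[a, 2], ]
    v2 <- sys$pos[sys$angles[a, 3], ] - sys$pos[sys$angles[a, 2], ]
    cq <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
    tot <- tot + 0.5 * sys$angle_k[a] * (pi - acos(max(-1, min(1, cq))))^2
  }
  tot
}

# random mixed bead system on a jittered grid (no unphysical deep overlaps,
# so forces stay moderate and floating-point cancellation is benign)
random_mixed_system <- function(n = 80, seed = 1, box = 0, spacing = 0.9) {
  set.seed(seed)
  m <- ceiling(n^(1 / 3))
  grid <- as.matrix(expand.grid(x = 1:m, y = 1:m, z = 1:m))
  # boustrophedon (snake) order: consecutive points are grid neighbors, so
  # the bonded chain below has sane bond lengths and angles
  gx <- grid[, 1]; gy <- grid[, 2]; gz <- grid[, 3]
  gx <- ifelse(gy %% 2 == 0, m + 1 - gx, gx)
  gy <- ifelse(gz %% 2 == 0, m + 1 - gy, gy)
  ord <- order(gz, gy, gx)
  grid <- grid[ord, ][seq_len(n), ]
  pos <- grid * spacing + matrix(runif(n * 3, -0.15, 0.15), n, 3)
  kind <- sample(c("polymer", "arm"), n, replace = TRUE)
  charge <- ifelse(kind == "polymer", -1, sample(c(0, 1), n, replace = TRUE))
  bonds <- cbind(seq_len(n - 1), 2:n)
  bead_system(pos, kind, charge, bonds = bonds,
              bond_r0 = rep(0.5, n - 1), bond_k = rep(200, n - 1),
              angles = cbind(seq_len(n - 2), 2:(n - 1), 3:n),
              angle_k = rep(1.5, n - 2), box = box)
}

# exhaustive-path MLD oracle: enumerate all simple paths in the
# secondary-structure tree and take the maximum total stem weight
oracle_mld <- function(bp) {
  g <- ss_graph(bp)
  if (igraph::ecount(g) == 0) return(0)
  vs <- igraph::V(g)
  best <- 0
  for (i in seq_along(vs)) {
    paths <- igraph::all_simple_paths(g, from = vs[i])
    for (p in paths) {
      ids <- igraph::get_edge_ids(g, rep(as.integer(p), each = 2)[
        -c(1, 2 * length(p))])
      best <- max(best, sum(igraph::E(g)$weight[ids]))
    }
  }
  best
}

duplex_topology <- function(nbp, ff) {
  spec <- structure_spec(LC = 2 * nbp, fbp = 1, Lbp = nbp, mode = "hairpin",
                         seed = 1)
  segs <- data.frame(start = c(1L, nbp + 1L), length = c(nbp, nbp))
  bp <- capsidsim:::new_base_pairing(segs, cbind(1L, 2L), spec)
  build_topology(bp, ff)
}

bead_kind_of <- function(sys) {
  c("attractor", "top", "bottom", "excluder", "arm", "polymer",
    "inert")[sys$type + 1]
}

simple_capsid <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- build_assembled_capsid(build_subunit(simple_capsid_params()))
    cache
  }
})
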