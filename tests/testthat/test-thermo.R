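test_that("Widom insertion on a non-interacting chain gives zero mu_r", {
  ff <- forcefield_params()
  # inert beads: no nonbonded terms act on the probe
  chain <- bead_system(cbind(0.5 * (1:10), 0, 0), "inert")
  est <- widom_mu_r(replicate(4, chain, simplify = FALSE), 1:10, ff,
                    n_insertions = 4000, seed = 3)
  expect_lt(abs(est$mu_r), 0.02)
})

test_that("Widom estimate matches a quadrature oracle for one obstacle", {
  ff <- forcefield_params()
  d <- 0.8  # obstacle distance from the insertion end
  sys <- bead_system(rbind(c(0, 0, 0), c(d, 0, 0)), "polymer", charge = 0)
  # probe bonded to bead 1; the only interaction is the repulsive LJ with
  # bead 2 (charges zero)
  est <- widom_mu_r(replicate(6, sys, simplify = FALSE), chain_idx = 1, ff,
                    n_insertions = 20000, seed = 5, end = "head")
  sd_b <- sqrt(1 / ff$kbond); r0 <- ff$sigma_p
  lo <- r0 - 3 * sd_b; hi <- r0 + 3 * sd_b
  inner <- function(l) vapply(l, function(li) {
    integrate(function(u) {
      r <- sqrt(li^2 + d^2 - 2 * li * d * u)
      exp(-vapply(r, oracle_rep_lj, 0, sigma = ff$sigma_p)) / 2
    }, -1, 1)$value
  }, 0)
  num <- integrate(function(l)
    l^2 * exp(-0.5 * ff$kbond * (l - r0)^2) * inner(l), lo, hi)$value
  den <- integrate(function(l)
    l^2 * exp(-0.5 * ff$kbond * (l - r0)^2), lo, hi)$value
  oracle <- -log(num / den)
  expect_equal(est$mu_r, oracle, tolerance = 0.1)
  expect_gt(oracle, 0)
})

test_that("Widom estimates are insertion-end invariant within error", {
  ff <- forcefield_params()
  set.seed(2)
  topo <- linear_topology(30, ff)
  out <- mc_polymer_sampler(topo, ff, n_moves = 1e4, seed = 2,
                            frame_stride = 1000)
  cfgs <- lapply(out$frames[-(1:3)], function(P)
    topology_system(topo, P, ff))
  eh <- widom_mu_r(cfgs, 1:30, ff, n_insertions = 3000, seed = 7,
                   end = "head")
  et <- widom_mu_r(cfgs, 1:30, ff, n_insertions = 3000, seed = 8,
                   end = "tail")
  joint <- sqrt(eh$se^2 + et$se^2) + 0.05
  expect_lt(abs(eh$mu_r - et$mu_r), 4 * joint)
})

test_that("encapsidation free energy integrates chemical-potential curves", {
  mk <- function(np, mu) {
    out <- data.frame(np = np, mu_r = mu, se = 0.1, context = "x")
    class(out) <- c("chemical_potential_curve", class(out))
    out
  }
  np <- seq(10, 100, by = 10)
  free <- mk(np, rep(1, 10))
  enc <- mk(np, rep(1, 10))
  expect_equal(encapsidation_free_energy(free, enc, 100)$dG, 0)
  enc2 <- mk(np, rep(0, 10))   # constant difference of -1 beyond np = 10
  dg <- encapsidation_free_energy(free, enc2, 100)
  # trapezoid: ramp 0 to -1 over [0, 10], then flat -1 up to 100
  expect_equal(dg$dG, -(0.5 * 10 + 90))
  # additivity over subintervals: [0, 50] plus the flat piece [50, 100]
  d1 <- encapsidation_free_energy(free, enc2, 50)$dG
  expect_equal(dg$dG - d1, -50, tolerance = 1e-9)
  expect_error(encapsidation_free_energy(free, mk(np + 1000, rep(0, 10)),
                                         100), "grid")
})

test_that("curve intersection finds the crossing of two linear curves", {
  np <- seq(100, 200, by = 10)
  mk <- function(np, mu) {
    out <- data.frame(np = np, mu_r = mu, se = 0.02, context = "x")
    class(out) <- c("chemical_potential_curve", class(out))
    out
  }
  free <- mk(np, 0.01 * np)           # crosses at np = 150
  enc <- mk(np, 3 - 0.01 * np)
  ci <- curve_intersection(free, enc, n_boot = 200)
  expect_equal(ci$np_star, 150, tolerance = 0.02)
  expect_true(ci$ci[1] < 150 && ci$ci[2] > 150)
})

test_that("a neutral capsid and neutral polymer have no packaged optimum", {
  ff <- forcefield_params()
  p0 <- capsid_params(arm_length = 0, arm_net_charge = 0)
  cap <- build_assembled_capsid(build_subunit(p0))
  topo <- linear_topology(80, ff)
  topo$charge <- rep(0, 80)
  el <- equilibrium_length(cap, topo, ff,
                           config = sim_config(box = 0, n_steps = 1.5e4,
                                               out_stride = 1000, seed = 2),
                           n_seeds = 2)
  # the threaded stub drifts out; nothing pulls the chain inside
  expect_lt(el$leq, 25)
  expect_equal(length(el$per_seed), 2)
  expect_true(all(is.finite(c(el$margin_sensitivity))))
})

test_that("a fully packaged polymer is flagged as too short", {
  ff <- forcefield_params()
  cap <- simple_capsid()
  topo <- linear_topology(12, ff)   # fits entirely inside
  expect_error(
    equilibrium_length(cap, topo, ff,
                       config = sim_config(box = 0, n_steps = 4000,
                                           out_stride = 500, seed = 3),
                       n_seeds = 1),
    "longer polymer")
})

test_that("dimer binding strengthens with epsilon and reports Kd in molar", {
  ff <- forcefield_params()
  strong <- dimer_binding(12, ff, sim_config(box = 40, n_steps = 4e4,
                                             out_stride = 400, seed = 2,
                                             dt = 2e-4))
  expect_gt(strong$p_dimer, 0.2)
  expect_lt(strong$gcc, 0)
  expect_equal(strong$gcc, -log(1 / strong$Kd))
  expect_equal(strong$delta_sc, log(25 / 2))
  weak <- dimer_binding(0.5, ff, sim_config(box = 40, n_steps = 4e4,
                                            out_stride = 400, seed = 2,
                                            dt = 2e-4))
  expect_gt(weak$Kd, strong$Kd)
})

test_that("the MC sampler reaches the rigid-rod limit and autotunes", {
  ff <- forcefield_params()
  topo <- linear_topology(20, ff)
  topo$angles <- cbind(1:18, 2:19, 3:20)
  topo$angle_k <- rep(1e5, 18)
  topo$charge <- rep(0, 20)
  expect_warning(
    out <- mc_polymer_sampler(topo, ff, n_moves = 2e4, seed = 1,
                              init = cbind(0.5 * (1:20), 0, 0)),
    "acceptance")
  rod <- sqrt(0.5^2 * (20^2 - 1) / 12)
  expect_equal(out$rg_mean, rod, tolerance = 0.02)
})

test_that("MC and BD sampling agree on the coil size of a neutral chain", {
  ff <- forcefield_params()
  topo <- linear_topology(30, ff)
  topo$charge <- rep(0, 30)
  mcr <- solution_rg(topo, ff, n_seeds = 3, n_moves = 3e4)
  sysb <- topology_system(topo, cbind(0.5 * (1:30), 0, 0), ff)
  rgs <- vapply(1:3, function(s) {
    tr <- run_bd(sysb, ff, sim_config(dt = 1e-4, n_steps = 3e5, box = 0,
                                      out_stride = 2000, seed = s))
    mean(vapply(tr$frames[-(1:50)], function(P) {
      p <- sweep(P, 2, colMeans(P)); sqrt(mean(rowSums(p^2)))
    }, 0))
  }, 0)
  joint <- sqrt(mcr$se^2 + var(rgs) / 3)
  expect_lt(abs(mcr$rg - mean(rgs)), 4 * joint + 0.05)
})

test_that("chemical-potential curves grow a chain and report finite mu_r", {
  ff <- forcefield_params()
  curve <- chemical_potential_curve(np_grid = c(5, 10), params = ff,
                                    n_relax = 500, n_insertions = 300,
                                    config = sim_config(box = 0, seed = 4))
  expect_equal(curve$np, c(5, 10))
  expect_true(all(is.finite(curve$mu_r)))
  expect_true(all(curve$se > 0))
  # a charged chain resists growth: positive residual chemical potential
  expect_true(all(curve$mu_r > 0))
})
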