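test_that("zero forces at zero temperature leave the system unchanged", {
  ff <- forcefield_params()
  sys <- bead_system(matrix(rnorm(30), 10, 3) * 10, "inert")
  cfg <- sim_config(dt = 1e-3, n_steps = 100, temperature = 0, box = 0)
  out <- run_bd(sys, ff, cfg)
  expect_equal(out$system$pos, sys$pos)
})

test_that("free-bead diffusion satisfies the Einstein relation", {
  ff <- forcefield_params()
  nb <- 1000
  sys <- bead_system(matrix(0, nb, 3), "inert")
  cfg <- sim_config(dt = 1e-3, n_steps = 1e4, box = 0, seed = 21,
                    out_stride = 500)
  tr <- run_bd(sys, ff, cfg)
  t <- tr$frame_steps * cfg$dt
  msd <- vapply(tr$frames, function(P) mean(rowSums(P^2)), 0)
  slope <- coef(lm(msd ~ 0 + t))[[1]]
  expect_equal(slope, 6, tolerance = 0.05)  # D = kBT/gamma = 1
})

test_that("a bonded pair samples the Boltzmann bond-length distribution", {
  ff <- forcefield_params()
  sys <- bead_system(rbind(c(0, 0, 0), c(0.5, 0, 0)), "polymer", charge = 0,
                     bonds = matrix(c(1, 2), 1), bond_r0 = 0.5, bond_k = 200)
  cfg <- sim_config(dt = 1e-4, n_steps = 3e5, box = 0, seed = 8,
                    out_stride = 150)
  tr <- run_bd(sys, ff, cfg)
  r <- vapply(tr$frames, function(P) sqrt(sum((P[1, ] - P[2, ])^2)), 0)
  r <- r[-seq_len(100)]
  dens <- function(s) s^2 * exp(-0.5 * 200 * (s - 0.5)^2)
  z <- integrate(dens, 0, 2)$value
  cdf <- function(s) vapply(s, function(si)
    integrate(dens, 0, si)$value / z, 0)
  ks <- suppressWarnings(ks.test(r, cdf))
  expect_gt(ks$p.value, 0.01)
})

test_that("trajectories are bit-identical for identical seeds", {
  ff <- forcefield_params()
  sys <- random_mixed_system(n = 40, seed = 2)
  cfg <- sim_config(dt = 1e-4, n_steps = 3000, box = 0, seed = 33,
                    out_stride = 1000)
  t1 <- run_bd(sys, ff, cfg)
  t2 <- run_bd(sys, ff, cfg)
  expect_identical(t1$system$pos, t2$system$pos)
  expect_identical(t1$frames, t2$frames)
  t3 <- run_bd(sys, ff, sim_config(dt = 1e-4, n_steps = 3000, box = 0,
                                   seed = 34, out_stride = 1000))
  expect_false(identical(t1$system$pos, t3$system$pos))
})

test_that("rigid bodies stay exactly rigid over a run", {
  ff <- forcefield_params()
  tpl <- build_subunit(simple_capsid_params())
  s1 <- subunit_beads(tpl, c(0, 0, 0), diag(3))
  d0 <- dist(s1$pos[s1$body == 1, ])
  tr <- run_bd(s1, ff, sim_config(dt = 1e-4, n_steps = 3000, box = 0,
                                  seed = 4))
  d1 <- dist(tr$system$pos[s1$body == 1, ])
  expect_lt(max(abs(d0 - d1)), 1e-10)
})

test_that("neighbor-list frame energies match the all-pairs reference", {
  ff <- forcefield_params()
  sys <- random_mixed_system(n = 100, seed = 5)
  cfg <- sim_config(dt = 1e-4, n_steps = 2000, box = 0, seed = 12,
                    out_stride = 500)
  tr <- run_bd(sys, ff, cfg)
  for (k in seq_along(tr$frames)) {
    s2 <- sys
    s2$pos <- tr$frames[[k]]
    ref <- total_energy(s2, ff, naive = TRUE)
    expect_lt(abs(sum(tr$frame_energies[k, ]) - ref$total), 1e-8)
  }
})

test_that("oversized single-step displacements abort with a diagnostic", {
  ff <- forcefield_params()
  # two polymer beads deeply overlapped and unbonded: enormous repulsion
  sys <- bead_system(rbind(c(0, 0, 0), c(0.12, 0, 0)), "polymer",
                     charge = -1)
  expect_error(run_bd(sys, ff, sim_config(dt = 1, n_steps = 10, box = 0)),
               "displacement")
})

test_that("box size must exceed twice the largest cutoff", {
  ff <- forcefield_params()
  sys <- bead_system(matrix(0, 1, 3), "polymer", charge = -1)
  expect_error(run_bd(sys, ff, sim_config(box = 15)), "cutoff")
})

test_that("replica exchange accepts every swap at equal temperatures", {
  ff <- forcefield_params()
  sys <- bead_system(rbind(c(0, 0, 0), c(0.5, 0, 0), c(1, 0, 0)), "polymer",
                     charge = -1, bonds = rbind(c(1, 2), c(2, 3)),
                     bond_r0 = rep(0.5, 2), bond_k = rep(200, 2))
  rx <- run_rex(sys, ff, sim_config(dt = 1e-4, box = 0, seed = 5),
                n_replicas = 4, T_min = 1, T_max = 1, swap_stride = 200,
                n_swaps = 8)
  expect_equal(rx$acceptance, 1)
  expect_error(run_rex(sys, ff, n_replicas = 1), "two replicas")
})

test_that("a replica-exchange ladder reproduces the single-T bond energy", {
  ff <- forcefield_params()
  sys <- bead_system(rbind(c(0, 0, 0), c(0.5, 0, 0)), "polymer", charge = 0,
                     bonds = matrix(c(1, 2), 1), bond_r0 = 0.5, bond_k = 200)
  rx <- run_rex(sys, ff, sim_config(dt = 1e-4, box = 0, seed = 6),
                n_replicas = 4, T_min = 1, T_max = 1.5, swap_stride = 1000,
                n_swaps = 100)
  expect_gt(rx$acceptance, 0.2)
  # cold-slot mean energy matches a direct T = 1 run within sampling error
  cold <- mean(rx$energies[-(1:10), 1])
  tr <- run_bd(sys, ff, sim_config(dt = 1e-4, n_steps = 5e4, box = 0,
                                   seed = 7, out_stride = 100))
  direct <- mean(vapply(seq_along(tr$frames), function(k)
    sum(tr$frame_energies[k, ]), 0)[-(1:50)])
  se_cold <- sd(rx$energies[-(1:10), 1]) / sqrt(90)
  expect_lt(abs(cold - direct), 4 * se_cold + 0.05)
  # hot slot is measurably hotter than the cold slot on average
  expect_gt(mean(rx$energies[-(1:10), 4]) + 0.1, cold)
})

test_that("assembly runs produce trajectories with transient clusters only", {
  ff <- forcefield_params()   # epsilon = 5: too weak without cargo
  p0 <- capsid_params(arm_length = 0, arm_net_charge = 0)
  tpl <- build_subunit(p0)
  cfg <- sim_config(dt = 2e-4, n_steps = 1e4, box = 60, seed = 11,
                    out_stride = 2000)
  tr <- run_assembly(tpl, topology = NULL, params = ff, config = cfg,
                     n_subunits = 6)
  expect_equal(tr$status, "ok")
  sizes <- vapply(seq_along(tr$frames), function(k)
    max(detect_clusters(frame_system(tr, k), ff)$sizes), 0L)
  expect_lt(max(sizes), 4)
})
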