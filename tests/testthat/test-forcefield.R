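test_that("shifted repulsive LJ has its zero at the diameter and known values", {
  expect_equal(u_repulsive_lj(1.0, 1.0), 0)
  expect_equal(u_repulsive_lj(2.0, 1.0), 0)
  expect_equal(u_repulsive_lj(0.5, 1.0), 2^12 - 1)
  expect_error(u_repulsive_lj(-1, 1), "positive")
  # continuity at the diameter
  expect_lt(abs(u_repulsive_lj(1 - 1e-9, 1)), 1e-6)
})

test_that("Morse potential has depth -1 at r0 and vanishes beyond the cutoff", {
  expect_equal(u_morse(1.0), -1)
  expect_equal(u_morse(10.0), 0)
  expect_equal(u_morse(12), 0)
  # two-exponential form evaluated at the half-width point
  x <- 1 * (1 + log(2) / 2.5)
  m <- exp(2.5 * (1 - x))
  expect_equal(u_morse(x), (m - 2) * m)
  expect_equal(u_morse(x), -0.75)  # m = 1/2 there
  # continuity at the cutoff (the residual well depth there is ~1e-10)
  expect_lt(abs(u_morse(10 - 1e-9)), 1e-8)
})

test_that("Debye-Hueckel term switches smoothly to zero at 3 lambda_D", {
  lD <- 1; lb <- 0.714
  expect_equal(u_debye_huckel(3.0, -1, -1, 0.5, lD, lb), 0)
  expect_equal(u_debye_huckel(5.0, -1, -1, 0.5, lD, lb), 0)
  # hand evaluation of the unswitched core at r = 1 nm
  core <- 0.714 * exp(0.5) / (1 + 0.5) * exp(-1) / 1
  expect_equal(u_debye_huckel(1.0, -1, -1, 0.5, lD, lb), core)
  # sign: like charges repel, opposite attract, at all r inside the cutoff
  r <- seq(0.2, 2.9, by = 0.1)
  expect_true(all(u_debye_huckel(r, -1, -1, 0.5) > 0))
  expect_true(all(u_debye_huckel(r, -1, 1, 0.5) < 0))
  # value and first-derivative continuity at r_on = 2 lD and r_cut = 3 lD
  for (r0 in c(2, 3)) {
    h <- 1e-7
    u <- function(r) u_debye_huckel(r, -1, -1, 0.5, lD, lb)
    expect_lt(abs(u(r0 + h) - u(r0 - h)), 1e-6)
    dplus <- (u(r0 + 2 * h) - u(r0 + h)) / h
    dminus <- (u(r0 - h) - u(r0 - 2 * h)) / h
    expect_lt(abs(dplus - dminus), 1e-3)
  }
  # the -0.5 kBT threshold distance for a unit charge pair is ~0.74 nm
  thr <- uniroot(function(r) u_debye_huckel(r, -1, 1, 0.5) + 0.5,
                 c(0.3, 2))$root
  expect_equal(thr, 0.74, tolerance = 0.01)
})

test_that("bond and angle potentials are harmonic with zero at rest", {
  expect_equal(u_bond(0.5, 0.5, 200), 0)
  expect_equal(u_bond(1.5, 0.5, 7), 3.5)
  expect_equal(u_angle(0, 10), 0)
  expect_equal(u_angle(0.3, 10), 0.45)
  expect_error(u_bond(-0.1, 0.5, 200), "positive")
})

test_that("explicit-ion Coulomb electrostatics are a documented stub", {
  expect_error(u_coulomb(1, 1, -1), "not supported")
})

test_that("force-field params validate and round-trip through config files", {
  expect_error(forcefield_params(sigma_p = -1), "positive")
  ff <- forcefield_params(epsilon = 7, lambda_D = 2)
  expect_equal(ff$sigma_xp, 0.5 * (ff$sigma_x + ff$sigma_p))
  f <- tempfile(fileext = ".cfg")
  write_forcefield(ff, f)
  ff2 <- read_forcefield(f)
  for (nm in names(ff)) expect_equal(ff2[[nm]], ff[[nm]], label = nm)
  # T=3 selects the larger excluder
  expect_equal(forcefield_params(t_number = 3)$sigma_x, 5.25)
})

test_that("capsomer pair energy matches an independent sum and is symmetric", {
  p <- simple_capsid_params()
  tpl <- build_subunit(p)
  cap <- simple_capsid()
  s1 <- subunit_beads(tpl, cap$layout$centers[1, ], cap$layout$rotations[[1]])
  s2 <- subunit_beads(tpl, cap$layout$centers[2, ], cap$layout$rotations[[2]])
  ff <- forcefield_params()
  b1 <- cbind(as.data.frame(s1$pos), kind = bead_kind_of(s1))
  b2 <- cbind(as.data.frame(s2$pos), kind = bead_kind_of(s2))
  names(b1)[1:3] <- names(b2)[1:3] <- c("x", "y", "z")
  e12 <- capsomer_pair_energy(b1, b2, ff)
  e21 <- capsomer_pair_energy(b2, b1, ff)
  expect_equal(e12, e21)
  # independent R-side sum over the capsomer-capsomer channels
  ref_cc <- 0
  for (i in seq_len(nrow(b1))) {
    for (j in seq_len(nrow(b2))) {
      ki <- b1$kind[i]; kj <- b2$kind[j]
      if (!(ki %in% c("attractor", "top", "bottom")) ||
          !(kj %in% c("attractor", "top", "bottom"))) next
      r <- sqrt(sum((as.numeric(b1[i, 1:3]) - as.numeric(b2[j, 1:3]))^2))
      ref_cc <- ref_cc + oracle_pair_energy(ki, kj, 0, 0, r, ff)
    }
  }
  expect_equal(e12, ref_cc, tolerance = 1e-12)
  # far-apart subunits do not interact
  s3 <- subunit_beads(tpl, c(500, 0, 0), diag(3))
  b3 <- cbind(as.data.frame(s3$pos), kind = bead_kind_of(s3))
  names(b3)[1:3] <- c("x", "y", "z")
  expect_equal(capsomer_pair_energy(b1, b3, ff), 0)
})
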