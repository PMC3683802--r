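test_that("cluster detection separates singletons, shells and half-shells", {
  ff <- forcefield_params()
  tpl <- build_subunit(simple_capsid_params())
  # 12 dispersed subunits
  parts <- lapply(1:12, function(k)
    subunit_beads(tpl, c(40 * k, 0, 0), diag(3)))
  far <- do.call(combine_systems, parts)
  cl <- detect_clusters(far, ff)
  expect_equal(cl$sizes, rep(1L, 12))
  # assembled shell: one 12-cluster, every subunit with 5 contacts
  cap <- simple_capsid()
  cl2 <- detect_clusters(cap$system, ff)
  expect_equal(cl2$sizes, 12L)
  expect_true(all(cl2$degrees == 5))
  # two half-shells far apart
  half <- cap$system
  mv <- half$body %in% 7:12
  half$pos[mv, ] <- half$pos[mv, ] + 200
  cl3 <- detect_clusters(half, ff)
  expect_equal(sort(cl3$sizes), c(6L, 6L))
})

test_that("outcome classification follows the 12/5-neighbor/encapsulation rule", {
  ff <- forcefield_params()
  cap <- simple_capsid()
  # no cargo: never complete
  expect_false(classify_outcome(cap$system, ff)$complete)
  # small coil fully inside
  set.seed(3)
  coil <- matrix(rnorm(150, sd = 1.2), 50, 3)
  pol <- bead_system(coil, "polymer", charge = -1)
  full <- combine_systems(cap$system, pol)
  oc <- classify_outcome(full, ff)
  expect_true(oc$polymer_fully_encapsulated)
  expect_true(oc$complete)
  expect_equal(oc$n_capsids_on_polymer, 1L)
  # a tail sticking out breaks completeness
  coil2 <- coil
  coil2[1:5, 1] <- coil2[1:5, 1] + 12
  oc2 <- classify_outcome(combine_systems(cap$system,
                                          bead_system(coil2, "polymer",
                                                      charge = -1)), ff)
  expect_false(oc2$polymer_fully_encapsulated)
  expect_false(oc2$complete)
})

test_that("outcome classification is invariant to rigid transforms", {
  ff <- forcefield_params()
  cap <- simple_capsid()
  set.seed(4)
  coil <- matrix(rnorm(120, sd = 1.2), 40, 3)
  sys <- combine_systems(cap$system, bead_system(coil, "polymer",
                                                 charge = -1))
  oc0 <- classify_outcome(sys, ff)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  s2 <- sys
  s2$pos <- sys$pos %*% t(R) + matrix(c(11, -4, 7), nrow(sys$pos), 3,
                                      byrow = TRUE)
  oc1 <- classify_outcome(s2, ff)
  expect_equal(oc1$complete, oc0$complete)
  expect_equal(oc1$n_subunits_in_largest_cluster,
               oc0$n_subunits_in_largest_cluster)
})

test_that("yield curves distinguish missing lengths from failed assembly", {
  mk <- function(complete) structure(list(complete = complete),
                                     class = "assembly_outcome")
  oc <- list(mk(TRUE), mk(TRUE), mk(FALSE), mk(FALSE))
  yc <- yield_curve(oc, c(500, 500, 500, 700))
  expect_equal(yc$yield[yc$length == 500], 2 / 3)
  expect_equal(yc$yield[yc$length == 700], 0)
  yc2 <- yield_curve(oc[1:2], c(500, 500))
  expect_false(600 %in% yc2$length)   # absent, not reported as zero
})

test_that("the critical nucleus is the smallest majority-committed size", {
  # synthetic committor data: everything reaching 5 completes; cluster
  # sizes that only reach 4 mostly dissolve
  grow <- function(peak, complete) {
    s <- c(1:peak)
    if (complete) c(s, peak:12) else c(s, rev(seq_len(peak)), 1, 1)
  }
  trajs <- c(replicate(6, grow(12, TRUE), simplify = FALSE),
             replicate(8, grow(4, FALSE), simplify = FALSE))
  cn <- critical_nucleus(trajs)
  expect_equal(cn$n_nuc, 5)
  expect_lt(cn$committor[4], 0.5)
  expect_error(critical_nucleus(list(c(1, 1, 1))), "resolved")
})

test_that("trajectories that complete from size 4 bound the nucleus at 4", {
  grow <- function() c(1, 2, 3, 4, 6, 8, 10, 12)
  cn <- critical_nucleus(replicate(5, grow(), simplify = FALSE))
  expect_lte(cn$n_nuc, 4)
})

test_that("bridging classification is exhaustive, exclusive and threshold-consistent", {
  ff <- forcefield_params()
  # one NA bead 0.5 nm from a +1 ARM charge: screened energy below -0.5 kBT
  sys <- bead_system(rbind(c(0, 0, 0), c(0.5, 0, 0)),
                     c("arm", "polymer"), charge = c(1, -1))
  br <- bridging_report(sys, ff, mode = "energy")
  expect_equal(br$n_interacting, 1L)
  expect_equal(br$n_bridging, 0L)
  expect_lt(u_debye_huckel(0.5, -1, 1, ff$sigma_ap), -0.5)
  # beads beyond the electrostatic cutoff are all bridging
  sys2 <- bead_system(rbind(c(0, 0, 0), c(4, 0, 0), c(5, 0, 0)),
                      c("arm", "polymer", "polymer"), charge = c(1, -1, -1))
  br2 <- bridging_report(sys2, ff, mode = "energy")
  expect_equal(br2$n_interacting, 0L)
  expect_equal(br2$n_bridging, 2L)
  # sum rule and mode agreement on a random packaged configuration
  set.seed(9)
  npol <- 200
  pol <- matrix(rnorm(3 * npol, sd = 2), npol, 3)
  arm <- matrix(rnorm(90, sd = 2), 30, 3)
  sys3 <- bead_system(rbind(arm, pol),
                      rep(c("arm", "polymer"), c(30, npol)),
                      charge = rep(c(1, -1), c(30, npol)))
  be <- bridging_report(sys3, ff, mode = "energy")
  bd <- bridging_report(sys3, ff, mode = "distance")
  expect_equal(be$n_interacting + be$n_bridging, npol)
  agree <- 1 - abs(be$n_interacting - bd$n_interacting) / npol
  expect_gt(agree, 0.95)
})

test_that("densities integrate to bead counts and stay flat for uniform beads", {
  ff <- forcefield_params()
  set.seed(12)
  n <- 4000
  # uniform beads in a sphere of radius 6
  u <- matrix(rnorm(3 * n), n, 3)
  u <- u / sqrt(rowSums(u^2)) * 6 * runif(n)^(1 / 3)
  sys <- bead_system(u, "polymer", charge = 0)
  rd <- radial_density(sys, center = c(0, 0, 0),
                       breaks = seq(0, 6, by = 0.5))
  expect_equal(sum(rd$count), sum(sqrt(rowSums(u^2)) <= 6))
  # number density roughly constant away from the tiny-volume core bins
  core <- rd$density[rd$r > 2]
  expect_lt(max(abs(core - mean(core))) / mean(core), 0.25)
  am <- angular_density(sys, r_range = c(3, 6), center = c(0, 0, 0),
                        n_theta = 6, n_phi = 8)
  expect_equal(sum(am), sum(sqrt(rowSums(u^2)) >= 3 &
                              sqrt(rowSums(u^2)) <= 6))
  # flat within counting noise: compare to Poisson expectation per bin
  w <- sum(am)
  # solid-angle weights of theta bins
  th <- seq(0, pi, length.out = 7)
  wth <- diff(-cos(th)) / 2
  expected <- outer(wth, rep(1 / 8, 8)) * w
  chi2 <- sum((am - expected)^2 / expected)
  expect_lt(chi2, 2 * length(am))
})

test_that("scalar observables report the documented charge ratio", {
  ff <- forcefield_params()
  cap <- simple_capsid()
  set.seed(5)
  coil <- matrix(rnorm(3 * 575, sd = 1.5), 575, 3)
  sys <- combine_systems(cap$system, bead_system(coil, "polymer",
                                                 charge = -1))
  so <- scalar_observables(sys, ff, inradius = 7.3)
  expect_equal(so$charge_ratio, 575 / 300)
  expect_gt(so$occupied_volume_fraction, 0)
  so0 <- scalar_observables(cap$system, ff, inradius = 7.3)
  expect_equal(so0$occupied_volume_fraction, 0)
  expect_true(is.na(so0$rg))
})
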