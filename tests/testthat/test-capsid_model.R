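test_that("subunit template has a regular attractor pentagon and valid ARMs", {
  p <- simple_capsid_params()
  tpl <- build_subunit(p)
  att <- tpl$rigid_atoms[tpl$rigid_atoms$kind == "attractor", ]
  expect_equal(nrow(att), 5)
  r <- sqrt(att$x^2 + att$y^2 + att$z^2)
  expect_lt(max(abs(r - tpl$pentagon_circumradius)), 1e-9)
  # consecutive vertex separations equal (regular pentagon)
  side <- 2 * tpl$pentagon_circumradius * sin(pi / 5)
  d <- sqrt(diff(att$x)^2 + diff(att$y)^2 + diff(att$z)^2)
  expect_lt(max(abs(d - side)), 1e-9)
  expect_equal(length(tpl$arm_sequences), 5)
  expect_equal(lengths(tpl$arm_sequences), rep(5L, 5))
  # simple model: 25 e per subunit
  beads <- subunit_beads(tpl)
  expect_equal(sum(beads$charge), 25)
  # one top above, one bottom below the face plane
  expect_equal(sum(tpl$rigid_atoms$kind == "top"), 1)
  expect_equal(sum(tpl$rigid_atoms$kind == "bottom"), 1)
  expect_gt(tpl$rigid_atoms$z[tpl$rigid_atoms$kind == "top"], 0)
  expect_lt(tpl$rigid_atoms$z[tpl$rigid_atoms$kind == "bottom"], 0)
})

test_that("degenerate subunit parameters are rejected", {
  expect_error(capsid_params(inradius = -1), "positive")
  p <- simple_capsid_params()
  expect_error(build_subunit(p, arm_sequence = numeric(0)), "empty|length")
  expect_error(build_subunit(p, pentagon_circumradius = -2), "positive")
  # ARM-free template is fine and neutral
  p0 <- capsid_params(arm_length = 0, arm_net_charge = 0)
  tpl0 <- build_subunit(p0)
  expect_equal(sum(subunit_beads(tpl0)$charge), 0)
  expect_equal(total_capsid_charge(p0), 0)
})

test_that("assembled capsid hits the target inradius with dodecahedral geometry", {
  cap <- simple_capsid()
  expect_equal(cap$layout$inradius, 7.3, tolerance = 1e-9)
  # neighboring-subunit dihedral angle ~116 degrees
  expect_equal(cap$layout$dihedral_deg, 116.565, tolerance = 1e-2)
  # face normals have icosahedral symmetry: dot products take exactly the
  # ideal values {1, +-1/sqrt(5), -1}
  nd <- cap$layout$normals %*% t(cap$layout$normals)
  expect_lt(max(abs(nd[abs(nd) < 0.9] ) - 1 / sqrt(5)), 1e-9)
  # 12 equal center-to-face distances
  d <- sqrt(rowSums(cap$layout$centers^2))
  expect_lt(max(abs(d - 7.3)), 1e-6)
  # attractor pairs across edges sit inside the Morse well
  expect_gt(cap$layout$attractor_gap, 0.5)
  expect_lt(cap$layout$attractor_gap, 1.2)
})

test_that("scaling all subunit dimensions scales the measured inradius", {
  p <- simple_capsid_params()
  p2 <- p; p2$inradius <- 2 * p$inradius
  ff2 <- forcefield_params(sigma_t = 2 * 10.5, sigma_b = 2 * 9.0,
                           sigma_x = 2 * 3.0)
  tpl2 <- build_subunit(p2, pentagon_circumradius = 10, ff = ff2)
  cap2 <- build_assembled_capsid(tpl2)
  expect_equal(cap2$layout$inradius, 14.6, tolerance = 1e-9)
})

test_that("overlapping or out-of-contact geometries are rejected by name", {
  tpl <- build_subunit(simple_capsid_params())
  expect_error(build_assembled_capsid(tpl, target_inradius = 5),
               "interpenetrate")
  expect_error(build_assembled_capsid(tpl, target_inradius = 40),
               "Morse cutoff")
})

test_that("virus presets return the shipped table rows exactly", {
  tab <- virus_preset_table()
  expect_equal(nrow(tab), 8)
  stnv <- virus_preset("STNV")
  expect_equal(stnv$inradius, 7.7)
  expect_equal(stnv$arm_length, 28)
  expect_equal(stnv$arm_net_charge, 16)
  expect_equal(stnv$genome_length, 1239)
  spmv <- virus_preset("SPMV")
  expect_equal(spmv$inradius, 6.8)
  expect_equal(spmv$arm_length, 20)
  expect_equal(spmv$arm_net_charge, 13)
  expect_equal(spmv$genome_length, 826)
  expect_error(virus_preset("TMV"), "available")
  # every row round-trips through the constructor
  for (k in seq_len(nrow(tab))) {
    p <- virus_preset(tab$name[k])
    expect_equal(p$inradius, tab$inradius_nm[k])
    expect_equal(p$t_number, tab$t_number[k])
    expect_equal(p$arm_length, tab$arm_length[k])
    expect_equal(sum(p$arm_sequence), tab$arm_net_charge[k])
    expect_equal(p$genome_length, tab$genome_nt[k])
  }
  # CCMV: 48-residue ARM, net +10 from 11 positive and 1 negative residue
  ccmv <- virus_preset("CCMV")
  expect_equal(length(ccmv$arm_sequence), 48)
  expect_equal(sum(ccmv$arm_sequence == 1), 11)
  expect_equal(sum(ccmv$arm_sequence == -1), 1)
})

test_that("total capsid charge equals the brute-force sum over beads", {
  p <- simple_capsid_params()
  expect_equal(total_capsid_charge(p), 300)
  cap <- simple_capsid()
  expect_equal(sum(cap$system$charge), 300)
  # 10 fully charged residues per ARM on a T=1 shell
  p10 <- capsid_params(arm_length = 10, arm_net_charge = 10)
  expect_equal(total_capsid_charge(p10), 600)
  # T=3: 15 ARMs per subunit
  p3 <- capsid_params(t_number = 3, arm_length = 5, arm_net_charge = 5,
                      inradius = 11.5)
  expect_equal(total_capsid_charge(p3), 12 * 15 * 5)
})

test_that("interior volume matches the dodecahedron closed form within 1%", {
  # independent route: V = (1/3) * total face area * inradius
  rin <- 7.3
  a <- 2 * rin / sqrt(5 / 2 + 11 / (2 * sqrt(5)))
  face_area <- (1 / 4) * sqrt(5 * (5 + 2 * sqrt(5))) * a^2
  v_ref <- 12 * face_area * rin / 3
  expect_equal(capsid_interior_volume(rin), v_ref, tolerance = 0.01)
})

test_that("coordinate exports write readable text files", {
  cap <- simple_capsid()
  fx <- tempfile(fileext = ".xyz")
  write_xyz(cap$system, fx)
  ln <- readLines(fx)
  expect_equal(as.integer(ln[1]), n_beads(cap$system))
  fp <- tempfile(fileext = ".pdb")
  write_pdb(cap$system, fp)
  expect_true(any(grepl("^HETATM", readLines(fp))))
})
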