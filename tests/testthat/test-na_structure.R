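test_that("segment assignment yields the prescribed counts without overlap", {
  set.seed(1)
  spec <- structure_spec(LC = 1000, fbp = 0.5, Lbp = 5)
  segs <- assign_ds_segments(spec)
  expect_equal(nrow(segs), 100)
  expect_equal(sum(segs$length), 500)
  expect_true(all(diff(segs$start) >= 5))            # non-overlapping
  expect_true(all(segs$start >= 1 & segs$start + 4 <= 1000))
  expect_equal(nrow(assign_ds_segments(structure_spec(fbp = 0,
                                                      mode = "linear"))), 0)
  segs20 <- assign_ds_segments(structure_spec(LC = 20, fbp = 0.5, Lbp = 5))
  expect_equal(nrow(segs20), 2)
  expect_error(assign_ds_segments(structure_spec(LC = 12, fbp = 0.5,
                                                 Lbp = 5)), "base pair")
})

test_that("hairpin pairing pairs consecutive segments and drops odd tails", {
  spec <- structure_spec(LC = 100, fbp = 0.4, Lbp = 5, mode = "hairpin")
  segs <- data.frame(start = c(1, 11, 31, 51), length = 5)
  bp <- pair_hairpin(segs, spec)
  expect_equal(bp$pairs, cbind(c(1L, 3L), c(2L, 4L)))
  expect_equal(nrow(pair_hairpin(segs[0, ], spec)$pairs), 0)
  segs5 <- data.frame(start = c(1, 11, 31, 51, 71), length = 5)
  expect_message(bp5 <- pair_hairpin(segs5, spec), "single-stranded")
  expect_equal(nrow(bp5$pairs), 2)
})

test_that("general pairing never creates pseudoknots", {
  spec <- structure_spec(LC = 500, fbp = 0.5, Lbp = 5, mode = "general")
  for (lam in c(0.05, 1, 20)) {
    for (s in 1:40) {
      sp <- spec; sp$lambda <- lam; sp$seed <- 37 * s
      expect_true(is_pseudoknot_free(generate_structure(sp)))
    }
  }
})

test_that("the large-lambda limit is fully nested with maximal MLD", {
  sp <- structure_spec(LC = 600, fbp = 0.5, Lbp = 5, mode = "general",
                       lambda = 1e6, seed = 3)
  bp <- generate_structure(sp)
  m <- compute_mld(bp)
  expect_equal(m$normalized, 1)
  expect_equal(m$mld, m$max_mld)
  # all junctions order <= 2 (a single nested stack)
  h <- junction_histogram(bp)
  expect_true(all(as.integer(names(h)) <= 2))
})

test_that("mean normalized MLD increases with lambda", {
  spec <- structure_spec(LC = 500, fbp = 0.5, Lbp = 5, mode = "general")
  grid <- c(0.01, 0.3, 10)
  means <- sapply(grid, function(lam) {
    mean(sapply(1:200, function(s) {
      sp <- spec; sp$lambda <- lam; sp$seed <- 1000 + s
      compute_mld(generate_structure(sp))$normalized
    }))
  })
  expect_true(all(diff(means) > 0))
  # clear separation of the endpoints, not a statistical accident
  expect_gt(means[3] - means[1], 0.2)
})

test_that("MLD equals the exhaustive-path oracle on small structures", {
  for (s in 1:12) {
    sp <- structure_spec(LC = 20 * 5, fbp = 0.5, Lbp = 5, mode = "general",
                         lambda = ifelse(s %% 2, 0.2, 5), seed = 500 + s)
    bp <- generate_structure(sp)
    expect_lte(nrow(bp$segments), 20)
    expect_equal(compute_mld(bp)$mld, oracle_mld(bp))
  }
  # unpaired chain
  lin <- structure_spec(LC = 50, fbp = 0, mode = "linear")
  expect_equal(compute_mld(generate_structure(lin))$mld, 0)
})

test_that("two-hairpin structures have tip-to-tip MLD through both stems", {
  spec <- structure_spec(LC = 100, fbp = 0.2, Lbp = 5, mode = "hairpin")
  segs <- data.frame(start = c(1, 21, 51, 71), length = 5)
  bp <- pair_hairpin(segs, spec)
  m <- compute_mld(bp)
  expect_equal(m$mld, 10)
  expect_equal(m$max_mld, 10)
  # junctions: two hairpin loops of order 1, exterior of order 2
  h <- junction_histogram(bp)
  expect_equal(unname(h[["1"]]), 2 / 3)
  expect_equal(unname(h[["2"]]), 1 / 3)
})

test_that("fitting lambda to a junction histogram recovers a known value", {
  spec <- structure_spec(LC = 1000, fbp = 0.5, Lbp = 5, mode = "general")
  tg_acc <- NULL
  for (s in 1:80) {
    sp <- spec; sp$lambda <- 1; sp$seed <- 2000 + s
    h <- junction_histogram(generate_structure(sp))
    orders <- union(names(tg_acc), names(h))
    a <- stats::setNames(numeric(length(orders)), orders)
    a[names(tg_acc)] <- tg_acc
    a[names(h)] <- a[names(h)] + h
    tg_acc <- a
  }
  fit <- fit_lambda(tg_acc / sum(tg_acc), spec, n_seeds = 60)
  expect_gt(fit$lambda, 0.8 * 1.0 / 1.2)
  expect_lt(fit$lambda, 1.2 / 0.8)
  expect_error(fit_lambda(c(`2` = NaN), spec), "histogram")
  # degenerate all-order-2 target pushes lambda to the search bound
  expect_warning(fit2 <- fit_lambda(c(`2` = 1), spec, n_seeds = 10,
                                    interval = c(1e-3, 5)), "upper bound")
  expect_gt(fit2$lambda, 4)
})

test_that("topologies have per-nucleotide beads, bonds and calibrated angles", {
  ff <- forcefield_params()
  lin <- linear_topology(200, ff)
  expect_equal(lin$n, 200)
  expect_equal(nrow(lin$bonds), 199)
  expect_equal(lin$n_bp_bonds, 0)
  expect_true(all(lin$charge == -1))
  sp <- structure_spec(LC = 1000, fbp = 0.5, Lbp = 5, mode = "general",
                       lambda = 1, seed = 9)
  bp <- generate_structure(sp)
  topo <- build_topology(bp, ff)
  expect_equal(topo$n_bp_bonds, 250)
  expect_equal(nrow(topo$bonds), 999 + 250)
  # paired fraction within one segment of the requested fbp
  expect_lte(abs(sum(topo$partner > 0) / 1000 - 0.5), 5 / 1000 + 1e-9)
  # partner map is an involution and pairing is antiparallel within stems
  prt <- topo$partner
  expect_true(all(prt[prt[prt > 0]] == which(prt > 0)))
  # ds angles use the duplex constant, ss angles are absent at kangle_ss = 0
  expect_true(all(topo$angle_k == ff$kangle_ds))
})

test_that("dot-bracket and pair-list exports round-trip", {
  sp <- structure_spec(LC = 300, fbp = 0.4, Lbp = 5, mode = "general",
                       lambda = 2, seed = 4)
  bp <- generate_structure(sp)
  db <- pairing_to_dotbracket(bp)
  expect_equal(nchar(db), 300)
  prs <- dotbracket_to_pairs(db)
  topo <- build_topology(bp)
  ref <- cbind(which(topo$partner > seq_len(300)),
               topo$partner[topo$partner > seq_len(300)])
  expect_equal(prs[order(prs[, 1]), ], ref[order(ref[, 1]), ],
               ignore_attr = TRUE)
  expect_error(dotbracket_to_pairs("(()"), "unbalanced")
  f <- tempfile(fileext = ".tsv")
  write_pair_list(bp, f)
  tab <- read.delim(f)
  expect_equal(nrow(tab), n_base_pairs(bp))
})

test_that("an isolated duplex has a ~50 nm fitted persistence length", {
  ff <- forcefield_params()
  topo <- duplex_topology(100, ff)
  lps <- sapply(1:6, function(s) {
    out <- mc_polymer_sampler(topo, ff, n_moves = 2e6, seed = s,
                              sample_stride = 10000, frame_stride = 2000,
                              local_disp = 0.1, max_angle = 0.25)
    persistence_length(out$frames[-(1:300)], idx = 1:100, max_sep = 40)
  })
  expect_gt(mean(lps), 40)
  expect_lt(mean(lps), 60)
})
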