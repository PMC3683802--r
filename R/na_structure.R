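## Generation and analysis of pseudoknot-free base-pairing patterns with
## tunable maximum ladder distance (MLD) and junction statistics, and
## conversion to bead/bond/angle topologies (one bead per nucleotide,
## charge -1 e; double-stranded regions are two adjoined semiflexible
## strands joined by harmonic base-pair bonds).

#' Specification of a model NA structure
#'
#' @param LC contour length, nt
#' @param fbp fraction of nucleotides that are base-paired, in [0, 1]
#' @param Lbp nucleotides per double-stranded segment
#' @param mode `linear` (no pairing), `hairpin` (each segment pairs with
#'   the next) or `general` (stochastic pairing controlled by `lambda`)
#' @param lambda rate parameter of the exponential separation draw in the
#'   general pairing model; the draw has density `lambda exp(-lambda l)`
#'   (mean `1/lambda`), and larger `lambda` gives more extended structures
#'   (larger MLD)
#' @param seed optional RNG seed applied by [generate_structure()]
#' @return an object of class `structure_spec`
#' @export
structure_spec <- function(LC = 1000, fbp = 0.5, Lbp = 5,
                           mode = c("general", "hairpin", "linear"),
                           lambda = 1, seed = NULL) {
  mode <- match.arg(mode)
  if (LC < 1 || Lbp < 1) stop("LC and Lbp must be >= 1", call. = FALSE)
  if (fbp < 0 || fbp > 1) stop("fbp must lie in [0, 1]", call. = FALSE)
  if (lambda <= 0) stop("lambda must be positive", call. = FALSE)
  structure(list(LC = as.integer(LC), fbp = fbp, Lbp = as.integer(Lbp),
                 mode = mode, lambda = lambda, seed = seed),
            class = "structure_spec")
}

#' Randomly assign double-stranded segments along the chain
#'
#' Chooses `floor(fbp * LC / Lbp)` non-overlapping segments of `Lbp`
#' consecutive nucleotides uniformly at random along the chain, numbered
#' sequentially (adjacent segments without a single-stranded spacer are
#' allowed).
#'
#' @param spec a [structure_spec()]
#' @return data.frame with columns `start`, `length` (1-based nt indices)
#' @export
assign_ds_segments <- function(spec) {
  n_seg <- floor(spec$fbp * spec$LC / spec$Lbp)
  if (spec$fbp == 0 || spec$mode == "linear")
    return(data.frame(start = integer(0), length = integer(0)))
  if (n_seg < 2)
    stop("fbp * LC = ", spec$fbp * spec$LC, " accommodates fewer than two ",
         "segments of ", spec$Lbp, " nt: cannot form a base pair",
         call. = FALSE)
  free <- spec$LC - n_seg * spec$Lbp
  # uniform non-overlapping placement via the stars-and-bars bijection
  at <- sort(sample.int(free + n_seg, n_seg))
  starts <- at + (seq_len(n_seg) - 1L) * (spec$Lbp - 1L)
  data.frame(start = starts, length = rep(spec$Lbp, n_seg))
}

new_base_pairing <- function(segments, pairs, spec) {
  pairs <- matrix(as.integer(pairs), ncol = 2)
  structure(list(segments = segments, pairs = pairs, LC = spec$LC,
                 Lbp = spec$Lbp, spec = spec),
            class = "base_pairing")
}

#' @export
print.base_pairing <- function(x, ...) {
  cat(sprintf("<base_pairing> LC=%d nt, %d ds segments, %d pairs (%d bp)\n",
              x$LC, nrow(x$segments), nrow(x$pairs), n_base_pairs(x)))
  invisible(x)
}

#' Number of base pairs in a pairing
#' @param bp a `base_pairing`
#' @export
n_base_pairs <- function(bp) {
  if (nrow(bp$pairs) == 0) return(0L)
  as.integer(sum(bp$segments$length[bp$pairs[, 1]]))
}

#' Hairpin-only pairing
#'
#' Pairs each double-stranded segment with the next one in the sequence:
#' (1,2), (3,4), ... For an odd segment count the final segment cannot pair
#' and reverts to single-stranded (a message reports the adjusted fbp).
#'
#' @param segments data.frame from [assign_ds_segments()]
#' @param spec the originating [structure_spec()]
#' @return a `base_pairing`
#' @export
pair_hairpin <- function(segments, spec) {
  n <- nrow(segments)
  if (n %% 2 == 1) {
    message("odd segment count (", n, "): last segment reverts to ",
            "single-stranded; realized fbp = ",
            signif((n - 1) * spec$Lbp / spec$LC, 3))
  }
  k <- n %/% 2
  pairs <- if (k > 0) cbind(2 * seq_len(k) - 1L, 2 * seq_len(k)) else
    matrix(0L, 0, 2)
  new_base_pairing(segments, pairs, spec)
}

#' General stochastic pairing with tunable extension
#'
#' Iterates over unpaired segments in order. For the current segment the
#' admissible partners are the later, still-unpaired segments whose pairing
#' keeps every existing pair nested (no pseudoknots); with `lmax` of them
#' available, a separation `lrandom ~ Exp(rate = lambda)` is drawn and the
#' partner sits `lpair = round(lmax - lrandom)` positions away (clamped to
#' the admissible range; `lpair <= 1` pairs the nearest admissible
#' segment). Large `lambda` therefore gives maximal separations, fully
#' nested structures and maximal MLD; small `lambda` gives hairpins and
#' high-order junctions.
#'
#' @param segments data.frame from [assign_ds_segments()]
#' @param lambda rate parameter (> 0)
#' @param spec the originating [structure_spec()]
#' @return a `base_pairing` (pseudoknot-free by construction)
#' @export
pair_general <- function(segments, lambda, spec) {
  n <- nrow(segments)
  partner <- integer(n)  # 0 = unpaired
  pairs <- matrix(0L, 0, 2)
  for (s in seq_len(n)) {
    if (partner[s] != 0) next
    # tightest enclosing pair bounds the admissible partners
    bound <- n + 1L
    if (nrow(pairs) > 0) {
      enc <- pairs[pairs[, 1] < s & pairs[, 2] > s, 2]
      if (length(enc)) bound <- min(enc)
    }
    cand <- which(partner == 0)
    cand <- cand[cand > s & cand < bound]
    lmax <- length(cand)
    if (lmax == 0) next  # unpairable; reverts to single-stranded
    lrandom <- stats::rexp(1, rate = lambda)
    lpair <- min(max(round(lmax - lrandom), 0), lmax)
    idx <- max(1L, lpair)
    # keep the number of segments enclosed by the new pair even, so that
    # they can all pair among themselves (no segment is stranded and the
    # realized fbp stays within one segment of the requested value)
    if ((idx - 1L) %% 2L == 1L) idx <- if (idx > 1L) idx - 1L else idx + 1L
    idx <- min(idx, lmax)
    partner_idx <- cand[idx]
    partner[s] <- partner_idx
    partner[partner_idx] <- s
    pairs <- rbind(pairs, c(s, partner_idx))
  }
  bpg <- new_base_pairing(segments, pairs, spec)
  if (any(partner == 0) && n > 0)
    attr(bpg, "unpaired_segments") <- which(partner == 0)
  bpg
}

#' Generate a base-paired structure from a spec
#'
#' Convenience wrapper: assigns segments and pairs them according to the
#' spec's mode, applying `spec$seed` locally when given.
#'
#' @param spec a [structure_spec()]
#' @return a `base_pairing`
#' @export
generate_structure <- function(spec) {
  run <- function() {
    segs <- assign_ds_segments(spec)
    switch(spec$mode,
           linear = new_base_pairing(segs, matrix(0L, 0, 2), spec),
           hairpin = pair_hairpin(segs, spec),
           general = pair_general(segs, spec$lambda, spec))
  }
  if (is.null(spec$seed)) return(run())
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec$seed)
  run()
}

segment_nt_intervals <- function(bp) {
  if (nrow(bp$pairs) == 0) return(matrix(0L, 0, 2))
  lo <- bp$segments$start[bp$pairs[, 1]]
  hi <- bp$segments$start[bp$pairs[, 2]] + bp$segments$length[bp$pairs[, 2]] - 1L
  cbind(lo, hi)
}

#' Check that a pairing is pseudoknot-free
#'
#' For every two pairs the paired nucleotide intervals must be nested or
#' disjoint.
#'
#' @param bp a `base_pairing`
#' @return TRUE/FALSE
#' @export
is_pseudoknot_free <- function(bp) {
  iv <- segment_nt_intervals(bp)
  np <- nrow(iv)
  if (np < 2) return(TRUE)
  for (i in seq_len(np - 1)) {
    for (j in (i + 1):np) {
      a <- iv[i, ]; b <- iv[j, ]
      disjoint <- a[2] < b[1] || b[2] < a[1]
      nested <- (a[1] < b[1] && b[2] < a[2]) || (b[1] < a[1] && a[2] < b[2])
      if (!disjoint && !nested) return(FALSE)
    }
  }
  TRUE
}

#' Secondary-structure graph
#'
#' Tree with one node per loop (single-stranded region, including the
#' exterior) and one edge per stem, weighted by the stem's base-pair count.
#' Pseudoknot-freedom guarantees acyclicity.
#'
#' @param bp a `base_pairing`
#' @return an igraph graph with edge attribute `weight`
#' @export
ss_graph <- function(bp) {
  if (!is_pseudoknot_free(bp))
    stop("pairing contains a pseudoknot; the secondary-structure graph is ",
         "only defined for nested pairings", call. = FALSE)
  iv <- segment_nt_intervals(bp)
  np <- nrow(iv)
  if (np == 0)
    return(igraph::make_empty_graph(n = 1, directed = FALSE))
  ord <- order(iv[, 1])
  iv <- iv[ord, , drop = FALSE]
  # parent = tightest enclosing pair; node k+1 = loop closed by pair k,
  # node 1 = exterior loop
  parent <- integer(np)
  for (k in seq_len(np)) {
    enc <- which(iv[, 1] < iv[k, 1] & iv[, 2] > iv[k, 2])
    parent[k] <- if (length(enc)) enc[which.max(iv[enc, 1])] + 1L else 1L
  }
  w <- bp$segments$length[bp$pairs[ord, 1]]
  igraph::graph_from_data_frame(
    data.frame(from = parent, to = seq_len(np) + 1L, weight = w),
    directed = FALSE,
    vertices = data.frame(name = seq_len(np + 1L)))
}

#' Maximum ladder distance
#'
#' The largest number of base pairs along any single path across the
#' molecule's secondary structure (the weighted diameter of [ss_graph()]),
#' together with the maximum attainable value (the total base-pair count,
#' reached when all pairs lie on one path).
#'
#' @param bp a `base_pairing`
#' @return list with `mld`, `max_mld` and `normalized` (= mld / max_mld;
#'   0 for an unpaired chain)
#' @export
compute_mld <- function(bp) {
  total <- n_base_pairs(bp)
  if (total == 0) return(list(mld = 0, max_mld = 0, normalized = 0))
  g <- ss_graph(bp)
  mld <- igraph::diameter(g, weights = igraph::E(g)$weight)
  list(mld = as.numeric(mld), max_mld = as.numeric(total),
       normalized = as.numeric(mld) / total)
}

#' Junction-order histogram
#'
#' For every loop of the secondary-structure graph the junction order is
#' the number of stems meeting it (hairpin loops have order 1, continuing
#' duplex interruptions order 2, branched junctions 3+). Returns relative
#' frequencies normalized to 1.
#'
#' @param bp a `base_pairing`
#' @return named numeric vector (names = junction order)
#' @export
junction_histogram <- function(bp) {
  if (nrow(bp$pairs) == 0) return(stats::setNames(numeric(0), character(0)))
  g <- ss_graph(bp)
  deg <- igraph::degree(g)
  tb <- table(deg)
  out <- as.numeric(tb) / sum(tb)
  stats::setNames(out, names(tb))
}

#' Fit lambda to a target junction-order distribution
#'
#' Finds the pairing parameter `lambda` whose ensemble-averaged junction
#' histogram (over `n_seeds` generated structures) best matches a target
#' distribution, by 1-D minimization of the summed squared difference on a
#' log scale.
#'
#' @param target named numeric vector of relative junction-order
#'   frequencies (names = order)
#' @param spec a [structure_spec()] defining LC, fbp, Lbp
#' @param n_seeds structures per lambda evaluation
#' @param interval search interval for lambda
#' @return list with `lambda`, `objective`, and the fitted histogram
#' @export
fit_lambda <- function(target, spec = structure_spec(), n_seeds = 100,
                       interval = c(1e-3, 50)) {
  if (any(!is.finite(target)) || sum(target) <= 0)
    stop("target histogram must be non-negative with positive sum",
         call. = FALSE)
  target <- target / sum(target)
  mean_hist <- function(lambda) {
    acc <- numeric(0)
    for (s in seq_len(n_seeds)) {
      sp <- spec; sp$lambda <- lambda; sp$seed <- s
      h <- junction_histogram(generate_structure(sp))
      orders <- union(names(acc), names(h))
      a2 <- stats::setNames(numeric(length(orders)), orders)
      a2[names(acc)] <- acc
      a2[names(h)] <- a2[names(h)] + h
      acc <- a2
    }
    acc / n_seeds
  }
  obj <- function(loglam) {
    h <- mean_hist(10^loglam)
    orders <- union(names(h), names(target))
    hv <- tv <- stats::setNames(numeric(length(orders)), orders)
    hv[names(h)] <- h; tv[names(target)] <- target
    sum((hv - tv)^2)
  }
  opt <- stats::optimize(obj, log10(interval), tol = 0.02)
  lam <- 10^opt$minimum
  if (lam > 0.9 * interval[2])
    warning("fitted lambda is at the search upper bound (degenerate, ",
            "fully nested target?)", call. = FALSE)
  list(lambda = lam, objective = opt$objective, histogram = mean_hist(lam))
}

#' Tune lambda to a target normalized MLD
#'
#' The ensemble-mean normalized MLD is monotone in `lambda`; this finds the
#' `lambda` whose mean normalized MLD (over `n_seeds` structures with
#' common random seeds) matches `target_nmld` by root bracketing.
#'
#' @param spec a [structure_spec()]
#' @param target_nmld target normalized MLD in (0, 1)
#' @param n_seeds structures per evaluation
#' @param interval lambda search interval
#' @param seed_base base RNG seed for the common structure seeds
#' @return the fitted lambda
#' @export
lambda_for_mld <- function(spec = structure_spec(), target_nmld,
                           n_seeds = 40, interval = c(1e-3, 100),
                           seed_base = 1000) {
  mean_nmld <- function(lambda) {
    v <- vapply(seq_len(n_seeds), function(s) {
      sp <- spec; sp$lambda <- lambda; sp$seed <- seed_base + s
      compute_mld(generate_structure(sp))$normalized
    }, 0)
    mean(v)
  }
  f <- function(loglam) mean_nmld(10^loglam) - target_nmld
  lo <- log10(interval[1]); hi <- log10(interval[2])
  if (f(lo) > 0) return(interval[1])
  if (f(hi) < 0) return(interval[2])
  10^stats::uniroot(f, c(lo, hi), tol = 0.01)$root
}

#' Bead/bond/angle topology of a model NA
#'
#' One bead per nucleotide (charge -1 e, diameter `sigma_p`), harmonic
#' backbone bonds at rest length `sigma_p`, harmonic base-pair bonds (rest
#' length `bp_rest`) between paired nucleotides (antiparallel within each
#' stem), and bending potentials on consecutive triples: `kangle_ds` for
#' triples fully inside a double-stranded segment (calibrated against the
#' ~50 nm duplex persistence length), `kangle_ss` elsewhere.
#'
#' @param bp a `base_pairing` (use mode `linear` spec for an unstructured
#'   chain)
#' @param params a [forcefield_params()] object
#' @return an object of class `na_topology`
#' @export
build_topology <- function(bp, params = forcefield_params()) {
  LC <- bp$LC
  partner <- integer(LC)
  seg_id <- integer(LC)
  segs <- bp$segments
  for (k in seq_len(nrow(segs)))
    seg_id[segs$start[k] + 0:(segs$length[k] - 1L)] <- k
  if (nrow(bp$pairs) > 0) {
    for (p in seq_len(nrow(bp$pairs))) {
      i <- bp$pairs[p, 1]; j <- bp$pairs[p, 2]
      si <- segs$start[i]; sj <- segs$start[j]; L <- segs$length[i]
      for (k in 0:(L - 1)) {
        a <- si + k; b <- sj + L - 1L - k
        partner[a] <- b; partner[b] <- a
      }
    }
  }
  bonds <- cbind(seq_len(LC - 1L), 2:LC)
  bond_r0 <- rep(params$sigma_p, LC - 1L)
  bond_k <- rep(params$kbond, LC - 1L)
  bp_i <- which(partner > seq_len(LC))
  if (length(bp_i)) {
    bonds <- rbind(bonds, cbind(bp_i, partner[bp_i]))
    bond_r0 <- c(bond_r0, rep(params$bp_rest, length(bp_i)))
    bond_k <- c(bond_k, rep(params$kbond, length(bp_i)))
  }
  ctr <- 2:(LC - 1L)
  in_ds <- partner > 0
  same_seg <- seg_id[ctr - 1L] == seg_id[ctr] & seg_id[ctr] == seg_id[ctr + 1L]
  ds_triple <- in_ds[ctr - 1L] & in_ds[ctr] & in_ds[ctr + 1L] & same_seg
  kang <- ifelse(ds_triple, params$kangle_ds, params$kangle_ss)
  keep <- kang > 0
  angles <- cbind(ctr - 1L, ctr, ctr + 1L)[keep, , drop = FALSE]
  angle_k <- kang[keep]
  structure(list(n = LC, charge = rep(-1, LC), partner = partner,
                 bonds = bonds, bond_r0 = bond_r0, bond_k = bond_k,
                 angles = angles, angle_k = angle_k,
                 n_bp_bonds = length(bp_i), pairing = bp),
            class = "na_topology")
}

#' @export
print.na_topology <- function(x, ...) {
  cat(sprintf("<na_topology> %d beads, %d bonds (%d base-pair), %d angles\n",
              x$n, nrow(x$bonds), x$n_bp_bonds, nrow(x$angles)))
  invisible(x)
}

#' Linear polyelectrolyte topology
#'
#' Shortcut for an unstructured chain of `n` beads.
#' @param n bead count
#' @param params a [forcefield_params()] object
#' @export
linear_topology <- function(n, params = forcefield_params()) {
  spec <- structure_spec(LC = n, fbp = 0, mode = "linear")
  build_topology(new_base_pairing(data.frame(start = integer(0),
                                             length = integer(0)),
                                  matrix(0L, 0, 2), spec), params)
}

#' Initial 3-D embedding of a NA topology
#'
#' Recursive layout: stems are straight ladders (strand separation
#' `bp_rest`) perpendicular to the local path, loops and the exterior are
#' laid on circular arcs joining their backbone anchors; random stem
#' azimuths and arc orientations give distinct starting structures.
#' Residual overlaps are expected and should be relaxed with a push-off
#' before sampling (see [mc_polymer_sampler()]).
#'
#' @param topology an [build_topology()] object
#' @param params force-field parameters (bond rest lengths)
#' @param seed optional RNG seed
#' @return N x 3 coordinate matrix
#' @export
na_initial_coords <- function(topology, params = forcefield_params(),
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- topology$n
  partner <- topology$partner
  a <- params$sigma_p      # backbone step
  w <- params$bp_rest      # strand separation in a stem
  pos <- matrix(NA_real_, n, 3)

  rand_perp <- function(t) {
    v <- stats::rnorm(3)
    v <- v - sum(v * t) * t
    nv <- sqrt(sum(v^2))
    if (nv < 1e-8) return(rand_perp(t))
    v / nv
  }
  arc_points <- function(A, B, arclen, npts) {
    # npts points along an arc from A to B with total length ~arclen
    chord <- sqrt(sum((B - A)^2))
    if (npts == 0) return(matrix(0, 0, 3))
    if (arclen <= chord * 1.001 || chord < 1e-9) {
      tt <- seq_len(npts) / (npts + 1)
      return(outer(tt, B - A) + matrix(A, npts, 3, byrow = TRUE))
    }
    th <- tryCatch(stats::uniroot(function(q) 2 * sin(q / 2) / q - chord / arclen,
                                  c(1e-6, 2 * pi - 1e-6))$root,
                   error = function(e) pi)
    R <- arclen / th
    tdir <- (B - A) / chord
    ndir <- rand_perp(tdir)
    ctr <- (A + B) / 2 - ndir * R * cos(th / 2)
    # parametrize from A to B
    u <- (A - ctr); u <- u / sqrt(sum(u^2))
    vperp <- tdir - sum(tdir * u) * u
    vperp <- vperp / sqrt(sum(vperp^2))
    angs <- th * seq_len(npts) / (npts + 1)
    t(vapply(angs, function(q) ctr + R * (cos(q) * u + sin(q) * vperp),
             numeric(3)))
  }

  # returns nothing; fills pos[lo..hi] given anchor points A (before lo) and
  # B (after hi); at top level B is free and chosen from the path length
  place <- function(lo, hi, A, B) {
    if (lo > hi) return(invisible())
    # break range into items: runs of ss nt, and stems
    items <- list()
    c0 <- lo
    while (c0 <= hi) {
      if (partner[c0] == 0) {
        c1 <- c0
        while (c1 < hi && partner[c1 + 1] == 0) c1 <- c1 + 1
        items[[length(items) + 1]] <- list(kind = "ss", lo = c0, hi = c1)
        c0 <- c1 + 1
      } else {
        # stem starting here: strand1 = c0..e1 (ascending partners nested)
        e1 <- c0
        while (e1 < hi && partner[e1 + 1] == partner[e1] - 1 &&
               partner[e1 + 1] > e1 + 1) e1 <- e1 + 1
        items[[length(items) + 1]] <- list(kind = "stem", lo = c0, hi = e1,
                                           plo = partner[e1], phi = partner[c0])
        c0 <- partner[c0] + 1
      }
    }
    lens <- vapply(items, function(it)
      if (it$kind == "ss") a * (it$hi - it$lo + 1) else w + a, 0)
    D <- sum(lens) + a
    if (is.null(B)) {
      tdir <- c(0, 0, 1)
      B <- A + tdir * min(0.7 * D, 0.5 * sqrt(D / a) * a * 3)
    }
    # anchor positions of each item boundary along the arc from A to B
    nslots <- length(items)
    bounds <- cumsum(c(0, lens)) / D
    # sample points: we need the entry/exit points for each item; lay a
    # fine arc with one point per boundary
    bpts <- arc_points(A, B, D, 2 * nslots)
    # simpler: arc points at item boundaries
    allb <- arc_points(A, B, D, nslots + 1)
    entry <- rbind(A, allb)
    for (k in seq_len(nslots)) {
      it <- items[[k]]
      Ak <- entry[k + 1, ]   # start anchor of this item
      Bk <- if (k < nslots) entry[k + 2, ] else B
      if (it$kind == "ss") {
        nn <- it$hi - it$lo + 1
        pts <- arc_points(Ak, Bk, a * (nn + 1), nn)
        pos[it$lo:it$hi, ] <<- pts
      } else {
        L <- it$hi - it$lo + 1
        tdir <- Bk - Ak
        ntd <- sqrt(sum(tdir^2))
        tdir <- if (ntd > 1e-9) tdir / ntd else c(1, 0, 0)
        sdir <- rand_perp(tdir)
        for (q in 0:(L - 1)) {
          p1 <- Ak + (q + 1) * a * sdir
          pos[it$lo + q, ] <<- p1
          pos[partner[it$lo + q], ] <<- p1 + w * tdir
        }
        # interior between strand1 end and strand2 top
        top1 <- pos[it$hi, ]
        top2 <- pos[partner[it$hi], ]
        place(it$hi + 1, partner[it$hi] - 1, top1, top2)
      }
    }
    invisible()
  }
  place(1, n, c(0, 0, 0), NULL)
  pos
}

#' Dot-bracket export and import
#'
#' Pseudoknot-free pairings round-trip through dot-bracket strings (one
#' character per nucleotide). `pairing_to_dotbracket` returns the string;
#' `dotbracket_to_pairs` returns a two-column matrix of paired nt indices.
#'
#' @param bp a `base_pairing`
#' @export
pairing_to_dotbracket <- function(bp) {
  s <- rep(".", bp$LC)
  segs <- bp$segments
  for (p in seq_len(nrow(bp$pairs))) {
    i <- bp$pairs[p, 1]; j <- bp$pairs[p, 2]; L <- segs$length[i]
    s[segs$start[i] + 0:(L - 1)] <- "("
    s[segs$start[j] + 0:(L - 1)] <- ")"
  }
  paste(s, collapse = "")
}

#' @rdname pairing_to_dotbracket
#' @param db dot-bracket string
#' @export
dotbracket_to_pairs <- function(db) {
  ch <- strsplit(db, "")[[1]]
  stack <- integer(0)
  out <- matrix(0L, 0, 2)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") stack <- c(stack, i)
    else if (ch[i] == ")") {
      if (!length(stack)) stop("unbalanced dot-bracket string", call. = FALSE)
      out <- rbind(out, c(stack[length(stack)], i))
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack)) stop("unbalanced dot-bracket string", call. = FALSE)
  out
}

#' Write a pairing as a two-column TSV of paired nucleotide indices
#' @param bp a `base_pairing`
#' @param file path
#' @export
write_pair_list <- function(bp, file) {
  topo <- build_topology(bp)
  i <- which(topo$partner > seq_len(bp$LC))
  utils::write.table(data.frame(nt_i = i, nt_j = topo$partner[i]),
                     file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Convert a topology to a bead system
#'
#' @param topology an [build_topology()] result
#' @param pos N x 3 coordinates (default from [na_initial_coords()])
#' @param params force-field parameters
#' @param box box edge (0 = open)
#' @return a [bead_system()]
#' @export
topology_system <- function(topology, pos = NULL,
                            params = forcefield_params(), box = 0) {
  if (is.null(pos)) pos <- na_initial_coords(topology, params)
  bead_system(pos, "polymer", charge = topology$charge, body = 0L,
              bonds = topology$bonds, bond_r0 = topology$bond_r0,
              bond_k = topology$bond_k, angles = topology$angles,
              angle_k = topology$angle_k, box = box,
              diameter = params$sigma_p)
}
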