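## Assembly outcome classification, bridging analysis and densities.

subunit_contact_graph <- function(system, params = forcefield_params(),
                                  cutoff = morse_halfdepth_distance(params)) {
  att <- which(system$type == BEAD_KINDS[["attractor"]])
  bodies <- sort(unique(system$body[system$body > 0]))
  if (!length(bodies))
    return(list(graph = igraph::make_empty_graph(0, directed = FALSE),
                bodies = bodies))
  p <- system$pos[att, , drop = FALSE]
  b <- system$body[att]
  edges <- matrix(0L, 0, 2)
  box <- system$box
  for (i in seq_along(bodies)) {
    for (j in seq_along(bodies)) {
      if (j <= i) next
      pi_ <- p[b == bodies[i], , drop = FALSE]
      pj <- p[b == bodies[j], , drop = FALSE]
      hit <- FALSE
      for (k in seq_len(nrow(pi_))) {
        dd <- sweep(pj, 2, pi_[k, ])
        if (box > 0) dd <- dd - box * round(dd / box)
        if (min(sqrt(rowSums(dd^2))) < cutoff) { hit <- TRUE; break }
      }
      if (hit) edges <- rbind(edges, c(i, j))
    }
  }
  g <- igraph::make_empty_graph(length(bodies), directed = FALSE)
  if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
  list(graph = g, bodies = bodies)
}

#' Detect subunit clusters
#'
#' Connected components of the subunit contact graph, where two subunits
#' are in contact when any attractor pair sits within the Morse half-depth
#' distance (the dimer criterion).
#'
#' @param system a `bead_system` frame
#' @param params force field
#' @return list with `clusters` (list of body-id vectors, largest first),
#'   `sizes` and `degrees` (contacts per subunit)
#' @export
detect_clusters <- function(system, params = forcefield_params()) {
  cg <- subunit_contact_graph(system, params)
  if (!length(cg$bodies))
    return(list(clusters = list(), sizes = integer(0), degrees = integer(0)))
  comp <- igraph::components(cg$graph)
  clusters <- lapply(seq_len(comp$no),
                     function(k) cg$bodies[comp$membership == k])
  ord <- order(-vapply(clusters, length, 0L))
  clusters <- clusters[ord]
  list(clusters = clusters,
       sizes = vapply(clusters, length, 0L),
       degrees = stats::setNames(igraph::degree(cg$graph), cg$bodies))
}

capsid_center_of <- function(system, body_ids) {
  ex <- which(system$type == BEAD_KINDS[["excluder"]] &
                system$body %in% body_ids)
  colMeans(system$pos[ex, , drop = FALSE])
}

#' Classify an assembly outcome
#'
#' A well-formed nucleocapsid is a cluster of 12 subunits, each in contact
#' with five neighbors, that completely encapsulates the polymer (every
#' polymer bead inside the shell sphere of its cluster, radius
#' `inradius - sigma_x/2 + margin`). Without cargo the outcome is never
#' `complete` (the rule classifies nucleocapsids).
#'
#' @param x a `bead_system` frame or `cs_trajectory` (final frame used)
#' @param params force field
#' @param inradius shell inradius used for the encapsulation test, nm
#' @param margin encapsulation margin, nm
#' @return an object of class `assembly_outcome`
#' @export
classify_outcome <- function(x, params = forcefield_params(),
                             inradius = 7.3, margin = 0.5 * params$sigma_p) {
  system <- if (inherits(x, "cs_trajectory")) frame_system(x) else x
  cl <- detect_clusters(system, params)
  largest <- if (length(cl$sizes)) max(cl$sizes) else 0L
  pol <- which(system$type == BEAD_KINDS[["polymer"]])
  r_enc <- inradius - params$sigma_x / 2 + margin
  shells <- Filter(function(cc) length(cc) >= 10, cl$clusters)
  covered <- rep(FALSE, length(pol))
  n_caps_on_polymer <- 0L
  for (cc in shells) {
    ctr <- capsid_center_of(system, cc)
    d <- sqrt(rowSums(sweep(system$pos[pol, , drop = FALSE], 2, ctr)^2))
    inside <- d < r_enc
    covered <- covered | inside
    # a capsid "on the polymer" holds a run of >= 20 consecutive beads
    if (length(inside) >= 20) {
      r <- rle(inside)
      if (any(r$values & r$lengths >= 20))
        n_caps_on_polymer <- n_caps_on_polymer + 1L
    }
  }
  full_encaps <- length(pol) > 0 && all(covered)
  twelve <- which(cl$sizes == 12)
  all_deg5 <- FALSE
  if (length(twelve)) {
    members <- cl$clusters[[twelve[1]]]
    all_deg5 <- all(cl$degrees[as.character(members)] == 5)
  }
  complete <- length(pol) > 0 && largest == 12 && all_deg5 && full_encaps
  structure(list(n_subunits_in_largest_cluster = largest,
                 complete = complete,
                 polymer_fully_encapsulated = full_encaps,
                 n_capsids_on_polymer = n_caps_on_polymer,
                 cluster_sizes = cl$sizes),
            class = "assembly_outcome")
}

#' @export
print.assembly_outcome <- function(x, ...) {
  cat(sprintf("<assembly_outcome> largest cluster %d, complete: %s, cargo encapsulated: %s, capsids on polymer: %d\n",
              x$n_subunits_in_largest_cluster, x$complete,
              x$polymer_fully_encapsulated, x$n_capsids_on_polymer))
  invisible(x)
}

#' Assembly yield versus polymer length
#'
#' Fraction of trajectories classified complete at each polymer length.
#' Lengths with no trajectories are reported as NA (missing, not failed).
#'
#' @param outcomes list of `assembly_outcome` objects
#' @param lengths polymer length per outcome
#' @return data.frame with `length`, `n`, `yield`
#' @export
yield_curve <- function(outcomes, lengths) {
  stopifnot(length(outcomes) == length(lengths))
  ul <- sort(unique(lengths))
  data.frame(length = ul,
             n = vapply(ul, function(L) sum(lengths == L), 0L),
             yield = vapply(ul, function(L) {
               sel <- lengths == L
               if (!any(sel)) return(NA_real_)
               mean(vapply(outcomes[sel], function(o) o$complete, TRUE))
             }, 0))
}

#' Critical nucleus size from committor statistics
#'
#' The smallest cluster size n for which more than half of the trajectories
#' that reach n go on to complete assembly (cluster of 12) before complete
#' disassembly (cluster size < 3).
#'
#' @param size_series list of integer vectors: largest-cluster size per
#'   logged frame, one vector per trajectory
#' @return list with `n_nuc` and the per-size committor estimates
#' @export
critical_nucleus <- function(size_series) {
  resolve <- vapply(size_series, function(s) {
    if (any(s >= 12)) return(TRUE)
    t3 <- which(s >= 3)[1]
    !is.na(t3) && any(s[-seq_len(t3)] < 3)
  }, TRUE)
  if (!any(resolve))
    stop("no trajectory resolved to assembly or disassembly", call. = FALSE)
  probs <- rep(NA_real_, 12)
  for (n in 3:12) {
    hit <- vapply(size_series, function(s) {
      t0 <- which(s >= n)[1]
      if (is.na(t0)) return(NA)
      rest <- s[t0:length(s)]
      t_up <- which(rest >= 12)[1]
      t_dn <- which(rest < 3)[1]
      if (is.na(t_up) && is.na(t_dn)) return(NA)
      if (is.na(t_dn)) return(TRUE)
      if (is.na(t_up)) return(FALSE)
      t_up < t_dn
    }, NA)
    if (any(!is.na(hit))) probs[n] <- mean(hit, na.rm = TRUE)
  }
  n_nuc <- which(probs > 0.5)[1]
  list(n_nuc = n_nuc, committor = probs)
}

#' Bridging-segment classification
#'
#' Splits the packaged polymer segments into those directly interacting
#' with positive ARM charges and bridging segments. In `energy` mode a
#' segment interacts when its screened electrostatic energy with the
#' nearest positive charge is at most -0.5 kBT; in `distance` mode when
#' the nearest positive charge is within 0.74 nm (the distance at which
#' that energy equals -0.5 kBT at physiological screening).
#'
#' @param system a `bead_system` frame containing a packaged polymer
#' @param params force field
#' @param mode `energy` or `distance`
#' @param threshold_energy kBT (energy mode)
#' @param threshold_distance nm (distance mode)
#' @param packaged_only restrict to beads inside the shell (needs
#'   `inradius`); FALSE classifies every polymer bead
#' @param inradius shell inradius, nm
#' @return an object of class `bridging_report`
#' @export
bridging_report <- function(system, params = forcefield_params(),
                            mode = c("energy", "distance"),
                            threshold_energy = -0.5,
                            threshold_distance = 0.74,
                            packaged_only = FALSE, inradius = 7.3) {
  mode <- match.arg(mode)
  pol <- which(system$type == BEAD_KINDS[["polymer"]])
  pls <- which(system$type == BEAD_KINDS[["arm"]] & system$charge > 0)
  if (packaged_only) {
    ctr <- capsid_center_of(system, unique(system$body[system$body > 0]))
    d <- sqrt(rowSums(sweep(system$pos[pol, , drop = FALSE], 2, ctr)^2))
    pol <- pol[d < inradius - params$sigma_x / 2 + 0.5 * params$sigma_p]
  }
  if (!length(pol))
    return(structure(list(n_interacting = 0L, n_bridging = 0L,
                          threshold_energy = threshold_energy,
                          threshold_distance = threshold_distance,
                          mode = mode), class = "bridging_report"))
  mind <- vapply(pol, function(i) {
    dd <- sweep(system$pos[pls, , drop = FALSE], 2, system$pos[i, ])
    if (system$box > 0) dd <- dd - system$box * round(dd / system$box)
    min(sqrt(rowSums(dd^2)))
  }, 0)
  if (mode == "distance") {
    interacting <- mind <= threshold_distance
  } else {
    emin <- u_debye_huckel(pmax(mind, 1e-6), -1, 1, params$sigma_ap,
                           params$lambda_D, params$l_b)
    interacting <- emin <= threshold_energy
  }
  structure(list(n_interacting = sum(interacting),
                 n_bridging = sum(!interacting),
                 threshold_energy = threshold_energy,
                 threshold_distance = threshold_distance, mode = mode),
            class = "bridging_report")
}

#' @export
print.bridging_report <- function(x, ...) {
  cat(sprintf("<bridging_report> interacting %d, bridging %d (mode %s)\n",
              x$n_interacting, x$n_bridging, x$mode))
  invisible(x)
}

#' Radial density of selected beads from the capsid center
#'
#' @param system a `bead_system`
#' @param kind bead kind to bin (default polymer)
#' @param center capsid center (default: mean of excluder beads)
#' @param breaks radial bin edges, nm
#' @return data.frame with bin mid, count and number density; counts sum to
#'   the bead count inside the outermost edge
#' @export
radial_density <- function(system, kind = "polymer", center = NULL,
                           breaks = seq(0, 10, by = 0.25)) {
  idx <- which(system$type == BEAD_KINDS[[kind]])
  if (is.null(center))
    center <- capsid_center_of(system, unique(system$body[system$body > 0]))
  r <- sqrt(rowSums(sweep(system$pos[idx, , drop = FALSE], 2, center)^2))
  h <- graphics::hist(r[r <= max(breaks)], breaks = breaks, plot = FALSE)
  vol <- 4 / 3 * pi * diff(breaks^3)
  data.frame(r = h$mids, count = h$counts, density = h$counts / vol)
}

#' Angular density heat map of packaged beads
#'
#' Counts beads with radius in `r_range` on a grid of spherical angles
#' (no angular averaging). Supply `rotation` to align the capsid symmetry
#' axes across frames.
#'
#' @param system a `bead_system`
#' @param r_range radial window, nm
#' @param kind bead kind
#' @param center capsid center
#' @param n_theta,n_phi grid resolution
#' @param rotation optional 3 x 3 alignment rotation
#' @return matrix of counts (rows = theta bins, cols = phi bins); total
#'   equals the bead count in the window
#' @export
angular_density <- function(system, r_range = c(5, 6.25), kind = "polymer",
                            center = NULL, n_theta = 18, n_phi = 36,
                            rotation = diag(3)) {
  idx <- which(system$type == BEAD_KINDS[[kind]])
  if (is.null(center))
    center <- capsid_center_of(system, unique(system$body[system$body > 0]))
  rel <- sweep(system$pos[idx, , drop = FALSE], 2, center) %*% t(rotation)
  r <- sqrt(rowSums(rel^2))
  sel <- r >= r_range[1] & r <= r_range[2]
  rel <- rel[sel, , drop = FALSE]; r <- r[sel]
  theta <- acos(pmin(1, pmax(-1, rel[, 3] / r)))
  phi <- atan2(rel[, 2], rel[, 1]) + pi
  ti <- pmin(n_theta, 1 + floor(theta / pi * n_theta))
  pj <- pmin(n_phi, 1 + floor(phi / (2 * pi) * n_phi))
  m <- matrix(0L, n_theta, n_phi)
  for (k in seq_along(ti)) m[ti[k], pj[k]] <- m[ti[k], pj[k]] + 1L
  m
}

#' Scalar observables of a frame
#'
#' Radius of gyration of the polymer, the charge ratio (|polymer charge| /
#' positive capsid charge) and the occupied volume fraction (sum of bead
#' volumes of the interior contents over the interior volume of a
#' dodecahedron with the given inradius).
#'
#' @param system a `bead_system`
#' @param params force field
#' @param inradius capsid inradius, nm
#' @param center capsid center (default from the excluder beads; pass
#'   explicitly for polymer-only systems)
#' @return list with `rg`, `charge_ratio`, `occupied_volume_fraction`
#' @export
scalar_observables <- function(system, params = forcefield_params(),
                               inradius = 7.3, center = NULL) {
  pol <- which(system$type == BEAD_KINDS[["polymer"]])
  rg <- NA_real_
  if (length(pol)) {
    p <- system$pos[pol, , drop = FALSE]
    rg <- sqrt(mean(rowSums(sweep(p, 2, colMeans(p))^2)))
  }
  pos_charge <- sum(system$charge[system$charge > 0 &
                                    system$type == BEAD_KINDS[["arm"]]])
  pol_charge <- abs(sum(system$charge[pol]))
  charge_ratio <- if (pos_charge > 0) pol_charge / pos_charge else NA_real_
  occ <- NA_real_
  if (is.null(center) && any(system$body > 0))
    center <- capsid_center_of(system, unique(system$body[system$body > 0]))
  if (!is.null(center)) {
    # contents only: cargo beads inside the shell (ARMs are capsid material)
    interior <- which(system$type == BEAD_KINDS[["polymer"]] &
                        sqrt(rowSums(sweep(system$pos, 2, center)^2)) <
                          inradius - params$sigma_x / 2)
    occ <- sum(4 / 3 * pi * (system$diameter[interior] / 2)^3) /
      capsid_interior_volume(inradius)
  }
  list(rg = rg, charge_ratio = charge_ratio,
       occupied_volume_fraction = if (is.na(occ)) 0 else occ)
}
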