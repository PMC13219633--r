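# Ground-truth synthetic fixtures: ideal helices and bundles with analytic
# heights, core+belt antenna scenes with constrained macrocycle placements,
# and pairs of LHC-like subfamily analogs for Q-score discrimination tests.
#
# All randomness is confined to unconstrained placements and governed by a
# single integer seed; constrained quantities (heights, edge-to-edge
# distances) are exact by construction and recorded as machine-readable
# ground truth next to every generated model.

CA_RADIUS <- 2.3      # A, CA distance from the helical axis
CA_TWIST <- 100       # degrees per residue
DEFAULT_RISE <- 1.5   # A per residue

# orthonormal basis perpendicular to d
perp_basis <- function(d) {
  ref <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- unit(ref - sum(ref * d) * d)
  v <- c(d[2] * u[3] - d[3] * u[2],
         d[3] * u[1] - d[1] * u[3],
         d[1] * u[2] - d[2] * u[1])
  list(u = u, v = v)
}

#' Generate an ideal helix with known axis geometry
#'
#' Builds a CA spiral (radius 2.3 A, 100 degrees per residue) wound about an
#' axis that is either a straight line tilted from the z axis or a circular
#' arc of given radius. The true height is the analytic axis arc length,
#' `(length - 1) * rise`; the axis is centred on z = 0 (the membrane
#' midplane) at the given anchor.
#'
#' @param length number of residues (>= 8).
#' @param rise axis rise per residue, Angstrom (in \[1, 2\]).
#' @param tilt axis tilt from the membrane normal, degrees (< 60).
#' @param curvature arc radius of the axis in Angstrom (>= 10), or `NULL`
#'   for a straight axis.
#' @param anchor in-membrane (x, y) position of the axis midpoint.
#' @param chain_id chain identifier.
#' @param azimuth direction of the tilt/curvature in the membrane plane,
#'   degrees.
#' @param start_resno first residue number.
#' @return list with `atoms` (CA atom table rows) and `truth` (chain,
#'   residue range, exact height, axis endpoints).
#' @export
make_helix <- function(length, rise = DEFAULT_RISE, tilt = 0, curvature = NULL,
                       anchor = c(0, 0), chain_id = "A", azimuth = 0,
                       start_resno = 1L) {
  stopifnot(length >= 8, rise >= 1.0, rise <= 2.0, tilt >= 0, tilt < 60)
  if (!is.null(curvature) && curvature < 10) {
    stop("infeasible curvature: arc radius must be >= 10 A")
  }
  n <- as.integer(length)
  L <- (n - 1) * rise
  az <- azimuth * pi / 180
  th <- tilt * pi / 180
  d <- c(sin(th) * cos(az), sin(th) * sin(az), cos(th))  # start tangent
  s <- (seq_len(n) - 1) * rise
  phase <- (seq_len(n) - 1) * CA_TWIST * pi / 180
  if (is.null(curvature)) {
    pb <- perp_basis(d)
    axis_pts <- outer(s, d)
    ca <- axis_pts + CA_RADIUS * (cos(phase) %o% pb$u + sin(phase) %o% pb$v)
    axis_ends <- rbind(axis_pts[1, ], axis_pts[n, ])
    mid <- (axis_ends[1, ] + axis_ends[2, ]) / 2
  } else {
    R <- curvature
    pb <- perp_basis(d)
    e <- pb$u                      # curvature direction
    C <- R * e                     # arc centre relative to axis start
    phi <- s / R
    axis_pts <- t(vapply(phi, function(p) C - R * cos(p) * e + R * sin(p) * d,
                         numeric(3)))
    ca <- t(vapply(seq_len(n), function(i) {
      p <- phi[i]
      Nv <- cos(p) * e - sin(p) * d  # toward the arc centre
      b <- c(d[2] * e[3] - d[3] * e[2],
             d[3] * e[1] - d[1] * e[3],
             d[1] * e[2] - d[2] * e[1])
      axis_pts[i, ] + CA_RADIUS * (cos(phase[i]) * Nv + sin(phase[i]) * b)
    }, numeric(3)))
    axis_ends <- rbind(axis_pts[1, ], axis_pts[n, ])
    mid <- axis_pts[ceiling(n / 2), ]
  }
  shift <- c(anchor[1], anchor[2], 0) - mid
  ca <- sweep(ca, 2, shift, `+`)
  axis_ends <- sweep(axis_ends, 2, shift, `+`)
  resno <- start_resno + seq_len(n) - 1L
  atoms <- data.frame(
    chain_id = chain_id, residue_name = "ALA", residue_seq = resno,
    insertion_code = "", atom_name = "CA", element = "C",
    x = ca[, 1], y = ca[, 2], z = ca[, 3],
    occupancy = 1, b_factor = 20, is_hetero = FALSE,
    stringsAsFactors = FALSE
  )
  stromal_end <- axis_ends[which.max(axis_ends[, 3]), ]
  list(atoms = atoms,
       truth = list(chain_id = chain_id, residue_start = resno[1],
                    residue_end = resno[n], height = L,
                    tilt = tilt, curvature = curvature,
                    axis_start = axis_ends[1, ], axis_end = axis_ends[2, ],
                    stromal_end = stromal_end))
}

# residue count and rise reproducing an exact target height
height_to_residues <- function(height, rise = DEFAULT_RISE) {
  n <- max(8L, as.integer(round(height / rise)) + 1L)
  list(n = n, rise = height / (n - 1))
}

#' Generate a helical bundle with prescribed per-helix heights
#'
#' @param heights per-helix target heights, Angstrom (exact by construction).
#' @param tilts per-helix tilts, degrees.
#' @param curvatures per-helix arc radii (NA for straight).
#' @param anchors matrix of (x, y) anchor positions, one row per helix;
#'   defaults to a ring of radius `bundle_radius`.
#' @param azimuths per-helix tilt directions, degrees.
#' @param chain_id single chain for the whole bundle (helices separated by
#'   residue-number gaps).
#' @param bundle_radius default anchor ring radius, Angstrom.
#' @return list with `atoms` and `truth` (list per helix).
#' @export
make_bundle <- function(heights, tilts = rep(0, length(heights)),
                        curvatures = rep(NA_real_, length(heights)),
                        anchors = NULL, azimuths = NULL, chain_id = "A",
                        bundle_radius = 5) {
  k <- length(heights)
  if (is.null(anchors)) {
    ang <- 2 * pi * (seq_len(k) - 1) / max(k, 1)
    anchors <- cbind(bundle_radius * cos(ang), bundle_radius * sin(ang))
  }
  anchors <- matrix(anchors, ncol = 2)
  if (is.null(azimuths)) azimuths <- (seq_len(k) - 1) * 360 / max(k, 1)
  atoms <- NULL
  truth <- list()
  resno <- 1L
  for (i in seq_len(k)) {
    hp <- height_to_residues(heights[i])
    h <- make_helix(hp$n, rise = hp$rise, tilt = tilts[i],
                    curvature = if (is.na(curvatures[i])) NULL else curvatures[i],
                    anchor = anchors[i, ], chain_id = chain_id,
                    azimuth = azimuths[i], start_resno = resno)
    atoms <- rbind(atoms, h$atoms)
    truth[[i]] <- h$truth
    resno <- resno + hp$n + 10L  # numbering gap so helices stay separate runs
  }
  list(atoms = atoms, truth = truth)
}

# idealized flat tetrapyrrole: 24 ring atoms + central Mg, in the plane
# spanned by (u, v) at `center` with plane normal `normal`.
macrocycle_template <- function() {
  ring_letter <- c("A", "B", "C", "D")
  names <- "MG"; radius <- 0; angle <- 0
  # pyrrole nitrogens
  names <- c(names, paste0("N", ring_letter))
  radius <- c(radius, rep(2.05, 4)); angle <- c(angle, c(45, 135, 225, 315))
  # pyrrole ring carbons (4 per ring)
  for (i in 1:4) {
    names <- c(names, paste0("C", 1:4, ring_letter[i]))
    base <- c(45, 135, 225, 315)[i]
    radius <- c(radius, c(3.0, 3.4, 3.4, 3.0))
    angle <- c(angle, base + c(-25, -9, 9, 25))
  }
  # meso carbons
  names <- c(names, paste0("CH", ring_letter))
  radius <- c(radius, rep(3.45, 4)); angle <- c(angle, c(0, 90, 180, 270))
  a <- angle * pi / 180
  list(names = names,
       xy = cbind(radius * cos(a), radius * sin(a)),
       element = ifelse(grepl("^N", names), "N",
                        ifelse(names == "MG", "MG", "C")))
}

#' Generate an idealized chlorophyll macrocycle
#'
#' A flat 24-atom tetrapyrrole ring plus central Mg, adequate for
#' edge-to-edge / Mg-Mg distance and sidedness logic (no phytol tail).
#'
#' @param center ring centre (Mg position), Angstrom.
#' @param normal ring plane normal.
#' @param kind `"chl_a"` (residue CLA) or `"chl_c"` (residue KC2).
#' @param chain_id,resno identity of the hetero residue.
#' @return atom table rows for the ring.
#' @export
make_macrocycle <- function(center, normal = c(0, 0, 1), kind = "chl_a",
                            chain_id = "P", resno = 401L) {
  tpl <- macrocycle_template()
  pb <- perp_basis(unit(normal))
  xyz <- sweep(tpl$xy[, 1] %o% pb$u + tpl$xy[, 2] %o% pb$v, 2, center, `+`)
  data.frame(
    chain_id = chain_id,
    residue_name = if (kind == "chl_c") "KC2" else "CLA",
    residue_seq = as.integer(resno), insertion_code = "",
    atom_name = tpl$names, element = tpl$element,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occupancy = 1, b_factor = 30, is_hetero = TRUE,
    stringsAsFactors = FALSE
  )
}

min_cross_dist <- function(a, b) cpp_min_set_dist(as.matrix(a), as.matrix(b))

#' Generate a core + belt antenna scene with placed macrocycles
#'
#' A tall central bundle ("core") is surrounded by a ring of shorter
#' single-helix "belt" bundles, emulating a photosystem core wrapped by an
#' antenna belt. Chlorophyll-like macrocycles can be placed either freely or
#' at an exact edge-to-edge distance from a previously placed ring (solved by
#' translating along the inter-ring axis to within 1e-3 A).
#'
#' @param core_heights heights of the core helices, Angstrom.
#' @param belt_heights heights of the belt helices, Angstrom.
#' @param belt_radius radius of the belt ring, Angstrom.
#' @param core_radius anchor radius of the core helices, Angstrom.
#' @param rings optional list of macrocycle specs; each element is a list
#'   with `kind`, and either `center` (free placement) or `partner` (index of
#'   an earlier ring) + `distance` (target edge-to-edge, Angstrom) +
#'   optional `direction`; optional `chain_id`, `resno`, `normal`.
#' @param n_random_rings additionally scatter this many unconstrained rings
#'   at seeded random positions on the stromal side.
#' @param seed integer seed for unconstrained placements.
#' @return list with `model` ([molecular_model()]), `truth` (helix truths,
#'   ring truths, frame, groups) and `annotation` (a `subunit_annotation`).
#' @export
make_scene <- function(core_heights = rep(48, 3), belt_heights = rep(31, 6),
                       belt_radius = 14, core_radius = 4, rings = list(),
                       n_random_rings = 0, seed = 1) {
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  core <- make_bundle(core_heights, chain_id = "A", bundle_radius = core_radius)
  atoms <- core$atoms
  helix_truth <- lapply(core$truth, function(t) c(t, list(group = "core")))
  belt_chains <- LETTERS[1 + seq_along(belt_heights)]
  for (i in seq_along(belt_heights)) {
    ang <- 2 * pi * (i - 1) / length(belt_heights)
    anchor <- belt_radius * c(cos(ang), sin(ang))
    b <- make_bundle(belt_heights[i], anchors = matrix(anchor, 1),
                     chain_id = belt_chains[i])
    atoms <- rbind(atoms, b$atoms)
    helix_truth <- c(helix_truth,
                     lapply(b$truth, function(t) c(t, list(group = "belt"))))
  }
  # macrocycles
  ring_truth <- list()
  ring_atoms_list <- list()
  next_resno <- 401L
  place_ring <- function(spec, placed) {
    kind <- spec$kind %||% "chl_a"
    normal <- spec$normal %||% c(0, 0, 1)
    chain <- spec$chain_id %||% "P"
    resno <- spec$resno %||% next_resno
    if (!is.null(spec$partner)) {
      partner <- placed[[spec$partner]]
      dir <- unit(spec$direction %||% c(1, 0, 0))
      pxyz <- as.matrix(partner[, c("x", "y", "z")])
      pcen <- colMeans(pxyz[partner$atom_name != "MG", , drop = FALSE])
      ring_at <- function(t) make_macrocycle(pcen + t * dir, normal, kind,
                                             chain, resno)
      f <- function(t) {
        r <- ring_at(t)
        min_cross_dist(r[, c("x", "y", "z")], pxyz) - spec$distance
      }
      t_hi <- spec$distance + 2 * 3.45 + 2
      sol <- uniroot(f, c(0.05, t_hi), tol = 1e-9)
      ring <- ring_at(sol$root)
      achieved <- min_cross_dist(ring[, c("x", "y", "z")], pxyz)
      if (abs(achieved - spec$distance) > 1e-3) {
        stop("constrained ring placement failed: achieved ", achieved,
             " A vs target ", spec$distance)
      }
      list(ring = ring, target = spec$distance, partner = spec$partner)
    } else {
      list(ring = make_macrocycle(spec$center, normal, kind, chain, resno),
           target = NA_real_, partner = NA_integer_)
    }
  }
  placed <- list()
  for (i in seq_along(rings)) {
    res <- place_ring(rings[[i]], placed)
    placed[[i]] <- res$ring
    ring_atoms_list[[i]] <- res$ring
    ring_truth[[i]] <- list(chain_id = res$ring$chain_id[1],
                            resno = res$ring$residue_seq[1],
                            kind = rings[[i]]$kind %||% "chl_a",
                            center = colMeans(as.matrix(
                              res$ring[res$ring$atom_name == "MG",
                                       c("x", "y", "z")])),
                            target_distance = res$target,
                            partner = res$partner)
    next_resno <- next_resno + 1L
  }
  if (n_random_rings > 0) {
    existing <- if (length(placed)) do.call(rbind, placed) else NULL
    tries <- 0
    while (n_random_rings > 0) {
      tries <- tries + 1
      if (tries > 1000) stop("could not place random rings without clashes")
      cen <- c(runif(1, -belt_radius, belt_radius),
               runif(1, -belt_radius, belt_radius),
               runif(1, 8, 14))
      ring <- make_macrocycle(cen, c(0, 0, 1), "chl_a", "P", next_resno)
      ok <- TRUE
      if (!is.null(existing)) {
        ok <- min_cross_dist(ring[, c("x", "y", "z")],
                             existing[, c("x", "y", "z")]) >= 1.5
      }
      if (ok) {
        placed[[length(placed) + 1L]] <- ring
        ring_atoms_list[[length(ring_atoms_list) + 1L]] <- ring
        ring_truth[[length(ring_truth) + 1L]] <- list(
          chain_id = "P", resno = next_resno, kind = "chl_a", center = cen,
          target_distance = NA_real_, partner = NA_integer_)
        existing <- rbind(existing, ring)
        next_resno <- next_resno + 1L
        n_random_rings <- n_random_rings - 1
      }
    }
  }
  if (length(ring_atoms_list)) atoms <- rbind(atoms, do.call(rbind, ring_atoms_list))
  model <- molecular_model("synthetic_scene", atoms)
  frame <- membrane_frame(c(0, 0, 1), c(0, 0, 0), 1)
  annotation <- data.frame(
    chain_id = c("A", belt_chains),
    subunit_label = c("core", paste0("belt", seq_along(belt_chains))),
    role = c("core", rep("belt1", length(belt_chains))),
    subfamily = c(NA, rep("Lhcf", length(belt_chains))),
    stringsAsFactors = FALSE)
  class(annotation) <- c("subunit_annotation", "data.frame")
  list(model = model,
       truth = list(helices = helix_truth, rings = ring_truth, frame = frame,
                    groups = list(core = "A", belt = belt_chains)),
       annotation = annotation)
}

#' Write a scene and its ground truth to disk
#' @param scene a [make_scene()] result.
#' @param dir output directory (created if needed).
#' @param format structure format, `"pdb"` or `"mmcif"`.
#' @return named vector of paths written.
#' @export
write_scene <- function(scene, dir, format = "pdb") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (format == "pdb") "pdb" else "cif"
  spath <- file.path(dir, paste0("scene.", ext))
  write_structure(scene$model, spath, format = format)
  tpath <- file.path(dir, "truth.json")
  jsonlite::write_json(scene$truth, tpath, digits = NA, auto_unbox = TRUE,
                       na = "null", null = "null", force = TRUE)
  apath <- file.path(dir, "annotation.csv")
  write.csv(as.data.frame(scene$annotation), apath, row.names = FALSE)
  c(structure = spath, truth = tpath, annotation = apath)
}

#' Generate two LHC-like subfamily analogs and their simulated maps
#'
#' Two three-helix bundles identical in helices A and B (and in shared
#' chlorophyll placement) but differing in helix C: one short and straight,
#' one longer and curved — the geometric signature that separates Lhcf-like
#' from Lhcr/Lhcq-like antenna proteins. Maps are simulated at the requested
#' resolutions for cross-fit discrimination experiments.
#'
#' @param short_helixC_len,long_helixC_len helix C residue counts
#'   (differing by >= 4).
#' @param n_chlorophylls chlorophylls shared by both models.
#' @param resolutions map resolutions to simulate, Angstrom.
#' @param helixC_curvature arc radius of the long helix C, Angstrom.
#' @param voxel map voxel size, Angstrom.
#' @return list with `models` (named list short/long) and `maps` (list by
#'   resolution, each a named list short/long).
#' @export
make_subfamily_analogs <- function(short_helixC_len = 10L,
                                   long_helixC_len = 18L,
                                   n_chlorophylls = 4L,
                                   resolutions = c(5, 15),
                                   helixC_curvature = 40,
                                   voxel = 1.0) {
  if (long_helixC_len - short_helixC_len < 4) {
    stop("helix C lengths must differ by >= 4 residues")
  }
  build <- function(c_len, curved) {
    hA <- make_helix(20, anchor = c(-5, 0), chain_id = "A", azimuth = 0)
    hB <- make_helix(20, tilt = 10, anchor = c(5, 0), chain_id = "A",
                     azimuth = 180, start_resno = 40L)
    hC <- make_helix(c_len, tilt = if (curved) 5 else 0,
                     curvature = if (curved) helixC_curvature else NULL,
                     anchor = c(0, 8), chain_id = "A", azimuth = 90,
                     start_resno = 80L)
    atoms <- rbind(hA$atoms, hB$atoms, hC$atoms)
    ring_centers <- cbind(x = c(-9, 9, 0, 0, -9, 9)[seq_len(n_chlorophylls)],
                          y = c(-5, -5, -6, -6, 5, 5)[seq_len(n_chlorophylls)],
                          z = c(8, 8, -8, 8, -8, -8)[seq_len(n_chlorophylls)])
    for (i in seq_len(n_chlorophylls)) {
      atoms <- rbind(atoms, make_macrocycle(ring_centers[i, ],
                                            normal = c(0, 0, 1),
                                            chain_id = "A",
                                            resno = 400L + i))
    }
    molecular_model(if (curved) "analog_long" else "analog_short", atoms)
  }
  models <- list(short = build(short_helixC_len, FALSE),
                 long = build(long_helixC_len, TRUE))
  maps <- lapply(resolutions, function(r) {
    lapply(models, simulate_map, resolution = r, voxel = voxel)
  })
  names(maps) <- as.character(resolutions)
  list(models = models, maps = maps)
}
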