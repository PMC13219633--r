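# Map-model Q-scores, density simulation, low-pass filtering and the
# cross-fit matrix used to discriminate antenna subfamilies in
# medium-resolution focused maps.
#
# Per atom, the map is sampled at the atom centre and on spherical shells of
# increasing radius (a fixed Fibonacci point layout, so results are
# deterministic); points that fall nearer to another atom are rejected. The
# Q-score is the Pearson correlation between the sampled values and a
# reference Gaussian profile g(r) = A exp(-r^2 / (2 sigma_ref^2)) + B whose
# amplitude and offset are anchored at the map's high/low reference values.
# A perfectly resolved atom approaches q = 1; atoms in featureless density
# score near 0.

ELEMENT_Z <- c(H = 1, D = 1, C = 6, N = 7, O = 8, F = 9, NA_ = 11, MG = 12,
               P = 15, S = 16, CL = 17, K = 19, CA = 20, MN = 25, FE = 26,
               CO = 27, NI = 28, CU = 29, ZN = 30)

atomic_number <- function(element) {
  z <- ELEMENT_Z[ifelse(element == "NA", "NA_", element)]
  z[is.na(z)] <- 6  # unknown elements score as carbon
  unname(z)
}

# Gaussian width convention tying a nominal resolution to the per-atom
# width used in simulation: sigma = 0.225 * resolution.
SIGMA_PER_RESOLUTION <- 0.225

#' Simulate a density map from a model
#'
#' Each heavy atom contributes an isotropic Gaussian of width
#' `0.225 * resolution` with amplitude proportional to its atomic number.
#'
#' @param model a [molecular_model()].
#' @param resolution nominal resolution, Angstrom (>= 2 * voxel).
#' @param voxel voxel edge, Angstrom.
#' @param padding grid margin beyond the model bounding box, Angstrom;
#'   defaults to `max(5, 4.5 * sigma_atom)` so each atom's full Gaussian
#'   footprint fits inside the box.
#' @return a [density_grid()] with `resolution` set.
#' @export
simulate_map <- function(model, resolution, voxel = 1.0, padding = NULL) {
  stopifnot_scalar_number(resolution, "resolution")
  if (resolution < 2 * voxel) {
    stop("resolution must be >= 2 * voxel (grid would undersample the density)")
  }
  xyz <- model_xyz(model)
  sigma <- SIGMA_PER_RESOLUTION * resolution
  # the box must contain each atom's full Gaussian footprint (4.5 sigma),
  # otherwise low-resolution maps get edge-truncated density
  if (is.null(padding)) padding <- max(5, 4.5 * sigma)
  stopifnot_scalar_number(padding, "padding")
  lo <- apply(xyz, 2, min) - padding
  hi <- apply(xyz, 2, max) + padding
  dims <- pmax(2L, as.integer(ceiling((hi - lo) / voxel)) + 1L)
  w <- atomic_number(model$atoms$element)
  vals <- cpp_simulate_density(xyz, w, sigma, lo, rep(voxel, 3), dims,
                               rcut = 4.5 * sigma)
  density_grid(array(vals, dim = dims), origin = lo, voxel_size = voxel,
               resolution = resolution)
}

#' Low-pass filter a density grid
#'
#' Applies a Gaussian filter in the frequency domain whose amplitude falls
#' to 0.5 at spatial frequency `1 / target_resolution`. Sharpening (a target
#' finer than the declared resolution) is refused.
#'
#' @param grid a [density_grid()].
#' @param target_resolution target resolution, Angstrom.
#' @return filtered [density_grid()] with updated `resolution`.
#' @export
lowpass <- function(grid, target_resolution) {
  stopifnot(inherits(grid, "density_grid"))
  stopifnot_scalar_number(target_resolution, "target_resolution")
  if (is.finite(grid$resolution) && target_resolution < grid$resolution) {
    stop("cannot sharpen: target resolution ", target_resolution,
         " A is finer than the declared ", grid$resolution, " A")
  }
  d <- grid$dims
  freq_axis <- function(n, v) {
    k <- 0:(n - 1)
    ifelse(k <= n / 2, k, k - n) / (n * v)
  }
  f0 <- 1 / target_resolution
  sigma_f <- f0 / sqrt(2 * log(2))
  fx2 <- freq_axis(d[1], grid$voxel_size[1])^2
  fy2 <- freq_axis(d[2], grid$voxel_size[2])^2
  fz2 <- freq_axis(d[3], grid$voxel_size[3])^2
  f2 <- outer(outer(fx2, fy2, `+`), fz2, `+`)
  H <- exp(-f2 / (2 * sigma_f^2))
  filtered <- Re(fft(fft(grid$values) * H, inverse = TRUE)) / prod(d)
  density_grid(array(filtered, dim = d), origin = grid$origin,
               voxel_size = grid$voxel_size, resolution = target_resolution)
}

# Deterministic quasi-uniform points on the unit sphere (Fibonacci layout).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  cbind(r * cos(phi), r * sin(phi), z)
}

grid_contains <- function(grid, xyz) {
  lo <- grid$origin
  hi <- grid$origin + (grid$dims - 1) * grid$voxel_size
  all(sweep(xyz, 2, lo, `>=`)) && all(sweep(xyz, 2, hi, `<=`))
}

#' Map-model Q-score
#'
#' @param model a [molecular_model()] positioned in the map.
#' @param grid a [density_grid()].
#' @param sigma_ref width of the reference Gaussian profile, Angstrom.
#' @param max_radius outermost sampling shell radius, Angstrom.
#' @param shells number of radial shells.
#' @param points_per_shell points per shell (fixed Fibonacci layout).
#' @return object of class `qscore_result`: `atom_q` (per-atom table with a
#'   `flagged` column marking zero-variance atoms scored 0), `residue_q`,
#'   `mean_q`, and the sampling `parameters`.
#' @export
qscore <- function(model, grid, sigma_ref = 0.6, max_radius = 2.0,
                   shells = 8L, points_per_shell = 8L) {
  stopifnot(inherits(model, "molecular_model"), inherits(grid, "density_grid"))
  xyz <- model_xyz(model)
  if (!grid_contains(grid, xyz)) {
    stop("model does not lie within the grid bounds")
  }
  n_atoms <- nrow(xyz)
  radii <- max_radius * seq_len(shells) / shells
  sphere <- fibonacci_sphere(points_per_shell)
  # all sample points: per atom, center + shells * points_per_shell
  offsets <- rbind(c(0, 0, 0),
                   do.call(rbind, lapply(radii, function(r) sphere * r)))
  point_r <- c(0, rep(radii, each = points_per_shell))
  npp <- nrow(offsets)
  pts <- xyz[rep(seq_len(n_atoms), each = npp), , drop = FALSE] +
    offsets[rep(seq_len(npp), n_atoms), , drop = FALSE]
  owner <- rep(seq_len(n_atoms), each = npp)
  nearest <- cpp_nearest_atom(pts, xyz)
  keep <- nearest == owner | point_r[rep(seq_len(npp), n_atoms)] == 0
  vals <- cpp_trilinear(as.numeric(grid$values), grid$dims, grid$origin,
                        grid$voxel_size, pts)
  v <- grid$values
  map_hi <- max(v); map_lo <- min(v)
  A <- map_hi - map_lo; B <- map_lo
  ref_all <- A * exp(-point_r^2 / (2 * sigma_ref^2)) + B
  ref <- rep(ref_all, n_atoms)
  q <- numeric(n_atoms)
  flagged <- logical(n_atoms)
  for (a in seq_len(n_atoms)) {
    sel <- owner == a & keep
    va <- vals[sel]; ra <- ref[sel]
    if (length(va) < 4 || sd(va) < 1e-12 || sd(ra) < 1e-12) {
      q[a] <- 0
      flagged[a] <- TRUE
    } else {
      q[a] <- cor(va, ra)
    }
  }
  atoms <- model$atoms
  atom_q <- data.frame(chain_id = atoms$chain_id,
                       residue_seq = atoms$residue_seq,
                       atom_name = atoms$atom_name, q = q, flagged = flagged,
                       stringsAsFactors = FALSE)
  res_key <- paste(atom_q$chain_id, atom_q$residue_seq)
  residue_q <- aggregate(q ~ chain_id + residue_seq, data = atom_q, FUN = mean)
  structure(list(atom_q = atom_q, residue_q = residue_q, mean_q = mean(q),
                 parameters = list(sigma_ref = sigma_ref,
                                   max_radius = max_radius, shells = shells,
                                   points_per_shell = points_per_shell)),
            class = "qscore_result")
}

#' @export
print.qscore_result <- function(x, ...) {
  cat(sprintf("<qscore_result> mean Q %.3f over %d atoms (%d flagged)\n",
              x$mean_q, nrow(x$atom_q), sum(x$atom_q$flagged)))
  invisible(x)
}

#' Identity rigid transform
#'
#' @return a `rigid_transform` that leaves coordinates unchanged; useful as
#'   an explicit initial placement for [rigid_fit()].
#' @export
identity_transform <- function() {
  structure(list(rotation = diag(3), translation = c(0, 0, 0),
                 rmsd = 0, n_atoms = NA_integer_), class = "rigid_transform")
}

#' Rotation matrix from Euler angles
#'
#' @param rx,ry,rz rotations about the x, y and z axes, radians, applied in
#'   that order.
#' @return 3x3 rotation matrix.
#' @export
rotation_xyz <- function(rx, ry, rz) {
  cx <- cos(rx); sx <- sin(rx)
  cy <- cos(ry); sy <- sin(ry)
  cz <- cos(rz); sz <- sin(rz)
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3)
  Rz %*% Ry %*% Rx
}

# Local model-map correlation: Pearson correlation between the map sampled
# at the (posed) atom centres and the density the model itself predicts
# there. The prediction is pose-invariant, so it is computed once; the
# correlation is maximal when the model sits in its own density.
expected_self_density <- function(xyz, z, sigma) {
  d2 <- as.matrix(dist(xyz))^2
  drop(exp(-d2 / (2 * sigma^2)) %*% z)
}

fit_score <- function(xyz, w, grid) {
  m <- cpp_trilinear(as.numeric(grid$values), grid$dims, grid$origin,
                     grid$voxel_size, xyz)
  if (sd(m) < 1e-12 || sd(w) < 1e-12) return(0)
  cor(w, m)
}

#' Local rigid-body refinement of a model into a map
#'
#' Deterministic bounded local search around a supplied initial placement:
#' a coarse translation grid, a rotation grid about the model centroid, and
#' a fine translation grid, keeping the pose maximising the local model-map
#' correlation (Pearson correlation between the density the model predicts
#' at its atom centres and the map interpolated there). The identity
#' perturbation is always
#' a candidate, so the refined correlation never drops below the initial one.
#'
#' @param model a [molecular_model()].
#' @param grid a [density_grid()].
#' @param initial_placement a `rigid_transform` pre-positioning the model
#'   (identity by default: the model is already placed).
#' @param max_shift translation search bound, Angstrom.
#' @param max_rot rotation search bound, degrees.
#' @param min_gain minimum correlation improvement for accepting a move.
#'   Sub-voxel trilinear-interpolation bias produces spurious gains of order
#'   1e-4, while a genuinely misplaced model loses order 1e-1; the default
#'   sits between the two so a model already at its optimum stays put.
#' @return list with `transform` (composed placement), `correlation`,
#'   `correlation_initial`, `shift` (Angstrom) and `rotation_deg` applied.
#' @export
rigid_fit <- function(model, grid, initial_placement = identity_transform(),
                      max_shift = 3, max_rot = 10, min_gain = 1e-3) {
  stopifnot_scalar_number(min_gain, "min_gain")
  placed <- apply_transform(model, initial_placement)
  xyz0 <- model_xyz(placed)
  if (!grid_contains(grid, xyz0)) {
    stop("initial placement puts the model outside the grid")
  }
  sigma <- SIGMA_PER_RESOLUTION *
    (if (is.finite(grid$resolution)) grid$resolution else 3 * max(grid$voxel_size))
  w <- expected_self_density(xyz0, atomic_number(placed$atoms$element), sigma)
  centroid <- colMeans(xyz0)
  score0 <- fit_score(xyz0, w, grid)

  best <- list(shift = c(0, 0, 0), rot = c(0, 0, 0), score = score0)
  try_pose <- function(shift, rot) {
    R <- rotation_xyz(rot[1] * pi / 180, rot[2] * pi / 180, rot[3] * pi / 180)
    xyz <- sweep(sweep(xyz0, 2, centroid) %*% t(R), 2, centroid + shift, `+`)
    fit_score(xyz, w, grid)
  }
  ladder <- function(step, bound) {
    g <- seq(-bound, bound, by = step)
    g[order(abs(g), g)]  # zero first, so ties keep the smallest move
  }
  # stage 1: coarse translations
  for (dx in ladder(1, max_shift)) for (dy in ladder(1, max_shift))
    for (dz in ladder(1, max_shift)) {
      s <- try_pose(c(dx, dy, dz), c(0, 0, 0))
      if (s > best$score + min_gain) best <- list(shift = c(dx, dy, dz),
                                               rot = c(0, 0, 0), score = s)
    }
  # stage 2: rotations about the centroid at the best translation
  rg <- ladder(5, max_rot)
  for (rx in rg) for (ry in rg) for (rz in rg) {
    s <- try_pose(best$shift, c(rx, ry, rz))
    if (s > best$score + min_gain) best <- list(shift = best$shift,
                                             rot = c(rx, ry, rz), score = s)
  }
  # stage 3: fine translations around the best pose; the 0.2 A step keeps
  # any interpolation-bias move at the true pose within the 0.2 A contract
  fg <- ladder(0.2, 0.6)
  base_shift <- best$shift
  for (dx in fg) for (dy in fg) for (dz in fg) {
    s <- try_pose(base_shift + c(dx, dy, dz), best$rot)
    if (s > best$score + min_gain) best <- list(shift = base_shift + c(dx, dy, dz),
                                             rot = best$rot, score = s)
  }
  R <- rotation_xyz(best$rot[1] * pi / 180, best$rot[2] * pi / 180,
                    best$rot[3] * pi / 180)
  # refinement acts on the pre-placed model: x -> R (x - c) + c + shift
  refine <- structure(list(rotation = R,
                           translation = centroid + best$shift -
                             drop(R %*% centroid),
                           rmsd = NA_real_, n_atoms = NA_integer_),
                      class = "rigid_transform")
  composed <- structure(list(
    rotation = refine$rotation %*% initial_placement$rotation,
    translation = drop(refine$rotation %*% initial_placement$translation) +
      refine$translation,
    rmsd = NA_real_, n_atoms = NA_integer_), class = "rigid_transform")
  list(transform = composed, correlation = best$score,
       correlation_initial = score0, shift = best$shift,
       rotation_deg = best$rot)
}

#' Cross-fit matrix of candidate models against maps
#'
#' Each candidate is locally refined into each map (from its supplied
#' placement) and scored by its per-model mean Q.
#'
#' @param candidates named list of [molecular_model()] objects.
#' @param maps named list of [density_grid()] objects.
#' @param placements optional list (by candidate, then map) of
#'   `rigid_transform` initial placements; identity by default.
#' @param refine run [rigid_fit()] before scoring.
#' @param ... Q-score parameters passed to [qscore()].
#' @return object of class `crossfit_matrix`: a candidates x maps numeric
#'   matrix with a `parameters` attribute.
#' @export
crossfit_matrix <- function(candidates, maps, placements = NULL,
                            refine = TRUE, ...) {
  stopifnot(length(candidates) >= 1, length(maps) >= 1)
  cn <- names(candidates) %||% paste0("model", seq_along(candidates))
  mn <- names(maps) %||% paste0("map", seq_along(maps))
  M <- matrix(NA_real_, length(candidates), length(maps),
              dimnames = list(cn, mn))
  for (i in seq_along(candidates)) {
    for (j in seq_along(maps)) {
      placement <- if (!is.null(placements)) placements[[i]][[j]]
                   else identity_transform()
      mod <- candidates[[i]]
      if (refine) {
        fit <- rigid_fit(mod, maps[[j]], initial_placement = placement)
        mod <- apply_transform(mod, fit$transform)
      } else {
        mod <- apply_transform(mod, placement)
      }
      M[i, j] <- qscore(mod, maps[[j]], ...)$mean_q
    }
  }
  structure(M, class = c("crossfit_matrix", "matrix"),
            parameters = c(list(refine = refine), list(...)))
}

#' @export
print.crossfit_matrix <- function(x, ...) {
  cat("<crossfit_matrix> mean Q, candidates x maps:\n")
  print(round(unclass(x), 4))
  invisible(x)
}

#' Subfamily assignment from a cross-fit matrix
#'
#' For every map, the candidate with the highest mean Q is proposed; the
#' assignment is flagged ambiguous when the margin over the runner-up falls
#' below `margin_threshold` (poorly discriminating fits).
#'
#' @param matrix a [crossfit_matrix()].
#' @param margin_threshold minimum Q margin for a confident assignment.
#' @return data.frame of class `discrimination_report` with one row per map:
#'   `map`, `best`, `best_q`, `margin`, `ambiguous`.
#' @export
discriminate <- function(matrix, margin_threshold = 0.02) {
  if (nrow(matrix) < 2) stop("need >= 2 candidate models to discriminate")
  out <- do.call(rbind, lapply(seq_len(ncol(matrix)), function(j) {
    col <- matrix[, j]
    ord <- order(col, decreasing = TRUE)
    margin <- col[ord[1]] - col[ord[2]]
    data.frame(map = colnames(matrix)[j], best = rownames(matrix)[ord[1]],
               best_q = col[ord[1]], margin = margin,
               ambiguous = margin < margin_threshold,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("discrimination_report", "data.frame")
  out
}

#' Radially averaged power spectrum of a grid
#'
#' Diagnostic used to verify low-pass behaviour: mean squared Fourier
#' amplitude in shells of spatial frequency.
#'
#' @param grid a [density_grid()].
#' @param n_bins number of frequency bins up to Nyquist.
#' @return data.frame with `freq` (1/Angstrom) and `power`.
#' @export
radial_power <- function(grid, n_bins = 20) {
  d <- grid$dims
  F2 <- Mod(fft(grid$values))^2
  freq_axis <- function(n, v) {
    k <- 0:(n - 1)
    ifelse(k <= n / 2, k, k - n) / (n * v)
  }
  f <- sqrt(outer(outer(freq_axis(d[1], grid$voxel_size[1])^2,
                        freq_axis(d[2], grid$voxel_size[2])^2, `+`),
                  freq_axis(d[3], grid$voxel_size[3])^2, `+`))
  nyq <- 0.5 / max(grid$voxel_size)
  bin <- pmin(n_bins, 1L + as.integer(f / nyq * n_bins))
  data.frame(freq = as.numeric(tapply(as.numeric(f), bin, mean)),
             power = as.numeric(tapply(as.numeric(F2), bin, mean)))
}
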