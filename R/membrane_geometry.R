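# Transmembrane helix detection and height measurement.
#
# Helix detection is purely C-alpha geometric so results are deterministic
# and dependency-free: a residue window is helical when the i -> i+4 CA
# distance and the local rise along the smoothed axis both sit in alpha
# helical ranges. Heights are measured on the smoothed axis polyline as a
# piecewise (curvature-aware) arc length over k >= 3 sub-segments, with the
# span projected on the membrane normal reported alongside.

HELIX_I_IP4_RANGE <- c(4.8, 6.6)  # A, CA(i)-CA(i+4) distance in alpha helices
HELIX_RISE_RANGE <- c(1.1, 1.9)   # A per residue along the local axis
HELIX_MIN_LEN <- 8L               # residues
HELIX_KINK_ANGLE <- 40            # degrees; split axis at sharper direction changes

#' Construct a helix segment
#' @param chain_id chain identifier.
#' @param residue_start,residue_end first and last residue number (inclusive).
#' @param axis numeric matrix (>= 2 rows) of axis polyline points in Angstrom.
#' @return an object of class `helix_segment`.
#' @export
helix_segment <- function(chain_id, residue_start, residue_end, axis) {
  axis <- as.matrix(axis)
  stopifnot(ncol(axis) == 3L, nrow(axis) >= 2L, all(is.finite(axis)))
  structure(list(chain_id = as.character(chain_id),
                 residue_start = as.integer(residue_start),
                 residue_end = as.integer(residue_end),
                 axis = axis),
            class = "helix_segment")
}

#' @export
print.helix_segment <- function(x, ...) {
  cat(sprintf("<helix_segment> chain %s, residues %d-%d (%d axis points)\n",
              x$chain_id, x$residue_start, x$residue_end, nrow(x$axis)))
  invisible(x)
}

# CA trace of one chain: residue numbers + coordinates, ordered by residue.
chain_ca_trace <- function(model, chain) {
  a <- model$atoms
  sel <- a$chain_id == chain & a$atom_name == "CA" & !a$is_hetero
  a <- a[sel, , drop = FALSE]
  a <- a[order(a$residue_seq), , drop = FALSE]
  a <- a[!duplicated(a$residue_seq), , drop = FALSE]
  list(resno = a$residue_seq, xyz = as.matrix(a[, c("x", "y", "z")]))
}

# Sliding-window (window 4) CA centroids: for an ideal alpha helix these lie
# on the helical axis. Extended at both ends by projecting the terminal CA
# onto the local axis direction so the polyline spans the full helix.
helix_axis_polyline <- function(xyz) {
  n <- nrow(xyz)
  m <- n - 3L
  cen <- (xyz[1:m, , drop = FALSE] + xyz[2:(m + 1), , drop = FALSE] +
          xyz[3:(m + 2), , drop = FALSE] + xyz[4:(m + 3), , drop = FALSE]) / 4
  if (m >= 2) {
    d0 <- unit(cen[2, ] - cen[1, ])
    p0 <- cen[1, ] + sum((xyz[1, ] - cen[1, ]) * d0) * d0
    d1 <- unit(cen[m, ] - cen[m - 1, ])
    p1 <- cen[m, ] + sum((xyz[n, ] - cen[m, ]) * d1) * d1
    cen <- rbind(p0, cen, p1)
  }
  unname(cen)
}

# Split a helix at interior kinks where the axis direction (averaged over
# 4-point lookback/lookahead) turns by more than HELIX_KINK_ANGLE degrees.
split_at_kinks <- function(resno_run, xyz_run, chain) {
  n <- length(resno_run)
  axis <- helix_axis_polyline(xyz_run)
  step <- 4L
  kinks <- integer(0)
  if (nrow(axis) > 2 * step) {
    for (i in seq(step + 1L, nrow(axis) - step)) {
      v1 <- axis[i, ] - axis[i - step, ]
      v2 <- axis[i + step, ] - axis[i, ]
      ang <- acos(pmin(1, pmax(-1, sum(unit(v1) * unit(v2))))) * 180 / pi
      if (ang > HELIX_KINK_ANGLE) kinks <- c(kinks, i)
    }
  }
  if (!length(kinks)) {
    return(list(helix_segment(chain, resno_run[1], resno_run[n], axis)))
  }
  # merge adjacent kink points, keep the middle one of each run
  grp <- cumsum(c(TRUE, diff(kinks) > 2))
  cutpts <- vapply(split(kinks, grp), function(k) k[ceiling(length(k) / 2)], 0L)
  # axis point i corresponds roughly to residue index i (after end extension)
  bounds <- c(1L, cutpts, n)
  out <- list()
  for (s in seq_len(length(bounds) - 1L)) {
    lo <- bounds[s]; hi <- bounds[s + 1L]
    if (hi - lo + 1L < HELIX_MIN_LEN) next
    out[[length(out) + 1L]] <- helix_segment(
      chain, resno_run[lo], resno_run[hi],
      helix_axis_polyline(xyz_run[lo:hi, , drop = FALSE]))
  }
  out
}

#' Detect helices from C-alpha geometry
#'
#' A residue window starting at i is flagged helical when the CA(i)-CA(i+4)
#' distance lies in \[4.8, 6.6\] A and the local per-residue rise along the
#' smoothed axis lies in \[1.1, 1.9\] A. Flagged windows are merged into runs
#' (a window covers residues i..i+4); runs shorter than 8 residues are
#' discarded, and runs with an interior axis kink sharper than 40 degrees are
#' split into separate helices.
#'
#' @param model a [molecular_model()].
#' @param min_length minimum helix length in residues.
#' @return list of [helix_segment()] objects.
#' @export
assign_helices <- function(model, min_length = HELIX_MIN_LEN) {
  out <- list()
  for (chain in model_chains(model)) {
    full <- chain_ca_trace(model, chain)
    if (length(full$resno) == 0L) next
    if (length(full$resno) < min_length) {
      warning("chain ", chain, " has fewer than ", min_length,
              " CA atoms; skipped")
      next
    }
    # chain breaks (non-consecutive numbering) split the trace outright
    seg_id <- cumsum(c(1L, diff(full$resno) != 1L))
    for (seg in split(seq_along(full$resno), seg_id)) {
      tr <- list(resno = full$resno[seg],
                 xyz = full$xyz[seg, , drop = FALSE])
      n <- length(tr$resno)
      if (n < min_length) next
      d_ip4 <- sqrt(rowSums((tr$xyz[5:n, , drop = FALSE] -
                             tr$xyz[1:(n - 4), , drop = FALSE])^2))
      # local rise: distance between successive window-4 centroids
      m <- n - 3L
      cen <- (tr$xyz[1:m, , drop = FALSE] + tr$xyz[2:(m + 1), , drop = FALSE] +
              tr$xyz[3:(m + 2), , drop = FALSE] +
              tr$xyz[4:(m + 3), , drop = FALSE]) / 4
      rise <- sqrt(rowSums((cen[-1, , drop = FALSE] - cen[-m, , drop = FALSE])^2))
      ok <- d_ip4 >= HELIX_I_IP4_RANGE[1] & d_ip4 <= HELIX_I_IP4_RANGE[2] &
        rise >= HELIX_RISE_RANGE[1] & rise <= HELIX_RISE_RANGE[2]
      if (!any(ok)) next
      # expand window flags to residue flags (window i covers residues i..i+4)
      helical <- logical(n)
      for (i in which(ok)) helical[i:min(n, i + 4L)] <- TRUE
      runs <- rle(helical)
      stops <- cumsum(runs$lengths)
      starts <- stops - runs$lengths + 1L
      for (r in which(runs$values & runs$lengths >= min_length)) {
        idx <- starts[r]:stops[r]
        out <- c(out, split_at_kinks(tr$resno[idx],
                                     tr$xyz[idx, , drop = FALSE], chain))
      }
    }
  }
  out
}

#' Construct a membrane frame
#' @param normal membrane normal (normalised internally).
#' @param midplane_point a point on the membrane midplane, Angstrom.
#' @param stromal_sign +1 if the stromal side is along `normal`, -1 otherwise.
#' @return an object of class `membrane_frame`.
#' @export
membrane_frame <- function(normal, midplane_point = c(0, 0, 0), stromal_sign = 1) {
  stopifnot(stromal_sign %in% c(-1, 1))
  structure(list(normal = unit(as.numeric(normal)),
                 midplane_point = as.numeric(midplane_point),
                 stromal_sign = as.numeric(stromal_sign)),
            class = "membrane_frame")
}

#' @export
print.membrane_frame <- function(x, ...) {
  cat(sprintf("<membrane_frame> normal (%.3f, %.3f, %.3f), midplane (%.1f, %.1f, %.1f), stromal side %+d\n",
              x$normal[1], x$normal[2], x$normal[3],
              x$midplane_point[1], x$midplane_point[2], x$midplane_point[3],
              as.integer(x$stromal_sign)))
  invisible(x)
}

# signed height of points above the midplane, stromal side positive
stromal_coord <- function(frame, pts) {
  pts <- matrix(pts, ncol = 3)
  drop(as.matrix(sweep(pts, 2, frame$midplane_point)) %*% frame$normal) *
    frame$stromal_sign
}

#' Estimate the membrane frame from transmembrane-scale helices
#'
#' The normal is the first principal axis of the helix end-to-end unit
#' vectors (sign-aligned by majority vote); the midplane passes through the
#' centroid of helix axis midpoints. The stromal side is set so that the
#' reference (a chain id, e.g. the PsaC chain, or an explicit point) lies on
#' the positive side. An explicit `normal` override skips estimation and is
#' honoured verbatim after normalisation.
#'
#' @param model a [molecular_model()].
#' @param helices list of [helix_segment()] from [assign_helices()].
#' @param stromal_reference chain id of a stromal subunit, or a 3-vector
#'   point on the stromal side; `NULL` leaves the stromal side along the
#'   estimated/supplied normal.
#' @param normal optional explicit membrane normal.
#' @return a [membrane_frame()].
#' @export
estimate_frame <- function(model, helices, stromal_reference = NULL,
                           normal = NULL) {
  mids <- t(vapply(helices, function(h) colMeans(h$axis[c(1, nrow(h$axis)), ]),
                   numeric(3)))
  if (is.null(normal)) {
    if (length(helices) < 3L) stop("need >= 3 helices to estimate a frame")
    u <- t(vapply(helices, function(h) unit(h$axis[nrow(h$axis), ] - h$axis[1, ]),
                  numeric(3)))
    # first eigenvector of sum(u u^T): sign-free principal direction
    ev <- eigen(crossprod(u), symmetric = TRUE)
    if (ev$values[1] < 1.5 * ev$values[2]) {
      stop("degenerate helix direction distribution; supply an explicit normal")
    }
    n <- ev$vectors[, 1]
    # majority vote orients n along the dominant helix direction
    if (sum(sign(drop(u %*% n))) < 0) n <- -n
  } else {
    n <- unit(as.numeric(normal))
  }
  mid <- colMeans(mids)
  frame <- membrane_frame(n, mid, 1)
  if (!is.null(stromal_reference)) {
    ref_pt <- if (is.character(stromal_reference)) {
      sel <- model$atoms$chain_id == stromal_reference
      if (!any(sel)) stop("stromal reference chain not in model: ",
                          stromal_reference)
      colMeans(model_xyz(model, sel))
    } else {
      as.numeric(stromal_reference)
    }
    if (stromal_coord(frame, ref_pt) < 0) frame$stromal_sign <- -1
  }
  frame
}

#' Keep helices that actually span the membrane
#'
#' Retains helices whose axis spans at least `min_span` along the membrane
#' normal and whose axis crosses the midplane.
#'
#' @param helices list of [helix_segment()].
#' @param frame a [membrane_frame()].
#' @param min_span minimum span along the normal, Angstrom.
#' @return filtered list of [helix_segment()].
#' @export
filter_transmembrane <- function(helices, frame, min_span = 15) {
  keep <- vapply(helices, function(h) {
    s <- stromal_coord(frame, h$axis)
    (max(s) - min(s)) >= min_span && min(s) < 0 && max(s) > 0
  }, logical(1))
  helices[keep]
}

#' Measure the height of one transmembrane helix
#'
#' The axis polyline is divided into `k` sub-segments of equal residue
#' count; the height is the summed chord length over the sub-segments
#' (a curvature-aware arc length). The projected height is the span of the
#' axis endpoints along the membrane normal. The stromal end is the axis
#' terminus on the stromal side.
#'
#' @param helix a [helix_segment()].
#' @param frame a [membrane_frame()].
#' @param k number of sub-segments (>= 3).
#' @param subunit_label optional subunit name carried into the result.
#' @return an object of class `tm_helix_measure` with fields `helix`,
#'   `subunit_label`, `stromal_end`, `lumenal_end`, `height`,
#'   `height_projected`, `n_subsegments`.
#' @export
measure_height <- function(helix, frame, k = 3L, subunit_label = NA_character_) {
  if (k < 3L) stop("k must be >= 3: curvature-aware heights need at least three sub-segments")
  axis <- helix$axis
  np <- nrow(axis)
  # k+1 division points at equal fractions of the polyline's residue index
  idx <- seq(1, np, length.out = k + 1L)
  pts <- t(vapply(idx, function(i) {
    lo <- floor(i); hi <- ceiling(i); w <- i - lo
    axis[lo, ] * (1 - w) + axis[hi, ] * w
  }, numeric(3)))
  height <- sum(sqrt(rowSums((pts[-1, , drop = FALSE] -
                              pts[-(k + 1L), , drop = FALSE])^2)))
  ends <- axis[c(1, np), , drop = FALSE]
  s <- stromal_coord(frame, ends)
  height_projected <- abs(diff(drop(as.matrix(sweep(ends, 2, frame$midplane_point)) %*%
                                      frame$normal)))
  stromal_end <- ends[which.max(s), ]
  lumenal_end <- ends[which.min(s), ]
  structure(list(helix = helix, subunit_label = as.character(subunit_label),
                 stromal_end = stromal_end, lumenal_end = lumenal_end,
                 height = height, height_projected = height_projected,
                 n_subsegments = as.integer(k)),
            class = "tm_helix_measure")
}

#' Measure all transmembrane helices of a model
#'
#' Convenience wrapper: detects helices, filters to transmembrane ones and
#' measures each.
#'
#' @param model a [molecular_model()].
#' @param frame optional [membrane_frame()]; estimated when `NULL`.
#' @param annotation optional `subunit_annotation` used to label measures.
#' @param k sub-segments per helix (>= 3).
#' @param min_span minimum transmembrane span, Angstrom.
#' @param stromal_reference passed to [estimate_frame()].
#' @return list with `measures` (list of `tm_helix_measure`) and `frame`.
#' @export
measure_heights <- function(model, frame = NULL, annotation = NULL, k = 3L,
                            min_span = 15, stromal_reference = NULL) {
  helices <- assign_helices(model)
  if (is.null(frame)) {
    frame <- estimate_frame(model, helices, stromal_reference = stromal_reference)
  }
  tm <- filter_transmembrane(helices, frame, min_span = min_span)
  labels <- rep(NA_character_, length(tm))
  if (!is.null(annotation)) {
    m <- match(vapply(tm, `[[`, "", "chain_id"), annotation$chain_id)
    labels <- annotation$subunit_label[m]
  }
  measures <- Map(function(h, lab) measure_height(h, frame, k = k,
                                                  subunit_label = lab),
                  tm, labels)
  list(measures = measures, frame = frame)
}

#' Tabulate helix measures
#' @param measures list of `tm_helix_measure`.
#' @param structure_id optional id recorded per row.
#' @return data.frame, one row per helix.
#' @export
measures_table <- function(measures, structure_id = NA_character_) {
  if (!length(measures)) {
    return(data.frame(structure_id = character(), chain_id = character(),
                      subunit_label = character(), helix_index = integer(),
                      residue_start = integer(), residue_end = integer(),
                      height_A = numeric(), height_projected_A = numeric(),
                      stromal_x = numeric(), stromal_y = numeric(),
                      stromal_z = numeric()))
  }
  do.call(rbind, lapply(seq_along(measures), function(i) {
    m <- measures[[i]]
    data.frame(structure_id = structure_id, chain_id = m$helix$chain_id,
               subunit_label = m$subunit_label, helix_index = i,
               residue_start = m$helix$residue_start,
               residue_end = m$helix$residue_end,
               height_A = m$height, height_projected_A = m$height_projected,
               stromal_x = m$stromal_end[1], stromal_y = m$stromal_end[2],
               stromal_z = m$stromal_end[3], stringsAsFactors = FALSE)
  }))
}

#' Aggregate helix heights per subunit and per subfamily
#'
#' Chains whose CA superposition RMSD is below `equivalence_rmsd` are treated
#' as copies of the same subunit and pooled into a single entry. Subfamily
#' means are flagged under-sampled when based on fewer than
#' `min_representatives` helices.
#'
#' @param measures list of `tm_helix_measure` (labelled).
#' @param annotation `subunit_annotation` table.
#' @param model the measured [molecular_model()] (needed for RMSD pooling);
#'   `NULL` disables pooling.
#' @param equivalence_rmsd pooling threshold, Angstrom.
#' @param min_representatives minimum helices per subfamily mean.
#' @return list with data.frames `per_subunit` and `per_subfamily`.
#' @export
aggregate_heights <- function(measures, annotation, model = NULL,
                              equivalence_rmsd = 0.55, min_representatives = 5L) {
  tab <- measures_table(measures)
  tab$subfamily <- annotation$subfamily[match(tab$chain_id, annotation$chain_id)]
  tab$role <- annotation$role[match(tab$chain_id, annotation$chain_id)]
  # pool equivalent chains (same fold copies) via pairwise CA RMSD
  pool_label <- tab$subunit_label
  if (!is.null(model)) {
    chains <- unique(tab$chain_id)
    group <- seq_along(chains)
    if (length(chains) > 1) {
      for (i in seq_len(length(chains) - 1)) {
        for (j in seq(i + 1, length(chains))) {
          r <- tryCatch(superpose_chains_rmsd(model, chains[i], chains[j]),
                        error = function(e) NA_real_)
          if (is.finite(r) && r < equivalence_rmsd) {
            group[group == group[j]] <- group[i]
          }
        }
      }
    }
    pooled_name <- vapply(group, function(g) {
      labs <- unique(tab$subunit_label[tab$chain_id %in% chains[group == g]])
      paste(sort(labs), collapse = "/")
    }, "")
    pool_label <- pooled_name[match(tab$chain_id, chains)]
  }
  tab$pooled_subunit <- pool_label
  per_subunit <- aggregate(height_A ~ pooled_subunit, data = tab, FUN = mean)
  names(per_subunit) <- c("subunit", "mean_height_A")
  per_subunit$n_helices <- aggregate(height_A ~ pooled_subunit, data = tab,
                                     FUN = length)$height_A
  sf <- tab[!is.na(tab$subfamily), , drop = FALSE]
  if (nrow(sf)) {
    per_subfamily <- aggregate(height_A ~ subfamily, data = sf, FUN = mean)
    names(per_subfamily) <- c("subfamily", "mean_height_A")
    per_subfamily$n_helices <- aggregate(height_A ~ subfamily, data = sf,
                                         FUN = length)$height_A
    per_subfamily$under_sampled <- per_subfamily$n_helices < min_representatives
  } else {
    per_subfamily <- data.frame(subfamily = character(),
                                mean_height_A = numeric(),
                                n_helices = integer(),
                                under_sampled = logical())
  }
  list(per_subunit = per_subunit, per_subfamily = per_subfamily, table = tab)
}

# CA RMSD of two chains after optimal superposition; residues paired by
# shared residue numbers, falling back to an ungapped best offset.
superpose_chains_rmsd <- function(model, chain_a, chain_b) {
  ta <- chain_ca_trace(model, chain_a)
  tb <- chain_ca_trace(model, chain_b)
  common <- intersect(ta$resno, tb$resno)
  if (length(common) >= 20) {
    xa <- ta$xyz[match(common, ta$resno), , drop = FALSE]
    xb <- tb$xyz[match(common, tb$resno), , drop = FALSE]
  } else {
    n <- min(length(ta$resno), length(tb$resno))
    if (n < 20) stop("fewer than 20 CA atoms to pair")
    xa <- ta$xyz[seq_len(n), , drop = FALSE]
    xb <- tb$xyz[seq_len(n), , drop = FALSE]
  }
  kabsch(xb, xa)$rmsd
}
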