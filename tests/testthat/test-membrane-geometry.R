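# membrane_geometry: helix detection, frame estimation, transmembrane
# filtering, height measurement and aggregation.

test_that("an ideal 20-residue helix is detected as exactly one helix", {
  m <- ideal_helix_model()$model
  hx <- assign_helices(m)
  expect_length(hx, 1L)
  expect_equal(hx[[1]]$residue_start, 1L)
  expect_equal(hx[[1]]$residue_end, 20L)
})

test_that("an extended strand yields zero helices", {
  n <- 20
  tab <- data.frame(
    chain_id = "A", residue_name = "ALA", residue_seq = seq_len(n),
    insertion_code = "", atom_name = "CA", element = "C",
    x = 3.8 * seq_len(n), y = 0, z = 0,
    occupancy = 1, b_factor = 20, is_hetero = FALSE,
    stringsAsFactors = FALSE
  )
  expect_length(assign_helices(molecular_model("strand", tab)), 0L)
})

test_that("a 3-helix bundle is recovered at the truth residue ranges", {
  b <- make_bundle(c(30, 36, 42), tilts = c(0, 10, 5))
  m <- molecular_model("bundle3", b$atoms)
  hx <- assign_helices(m)
  expect_length(hx, 3L)
  for (i in seq_along(hx)) {
    expect_lte(abs(hx[[i]]$residue_start - b$truth[[i]]$residue_start), 1L)
    expect_lte(abs(hx[[i]]$residue_end - b$truth[[i]]$residue_end), 1L)
  }
})

test_that("chains with fewer than 8 CA atoms are skipped with a warning", {
  tab <- data.frame(
    chain_id = "A", residue_name = "ALA", residue_seq = 1:4,
    insertion_code = "", atom_name = "CA", element = "C",
    x = c(0, 1, 2, 3), y = 0, z = 0,
    occupancy = 1, b_factor = 20, is_hetero = FALSE,
    stringsAsFactors = FALSE
  )
  expect_warning(hx <- assign_helices(molecular_model("tiny", tab)),
                 "fewer than")
  expect_length(hx, 0L)
})

test_that("frame estimation recovers the construction normal within 2 deg", {
  scene <- default_scene()
  hx <- assign_helices(scene$model)
  fr <- estimate_frame(scene$model, hx, stromal_reference = c(0, 0, 50))
  ang <- acos(min(1, abs(sum(fr$normal * c(0, 0, 1))))) * 180 / pi
  expect_lt(ang, 2)
  expect_equal(fr$stromal_sign * sign(fr$normal[3]), 1)
})

test_that("an explicit normal override is honoured verbatim (normalised)", {
  scene <- default_scene()
  fr <- estimate_frame(scene$model, assign_helices(scene$model),
                       normal = c(0, 0, 2))
  expect_equal(fr$normal, c(0, 0, 1))
})

test_that("degenerate helix direction distributions are refused", {
  # four helices lying in the xy plane along two orthogonal directions
  flat <- function(dir, off, chain) {
    n <- 20
    s <- (seq_len(n) - 1) * 1.5
    phase <- (seq_len(n) - 1) * 100 * pi / 180
    pb <- if (dir[1] == 1) list(u = c(0, 1, 0), v = c(0, 0, 1)) else
      list(u = c(1, 0, 0), v = c(0, 0, 1))
    xyz <- outer(s, dir) + 2.3 * (cos(phase) %o% pb$u + sin(phase) %o% pb$v)
    xyz <- sweep(xyz, 2, off, `+`)
    data.frame(chain_id = chain, residue_name = "ALA",
               residue_seq = seq_len(n), insertion_code = "",
               atom_name = "CA", element = "C",
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
               occupancy = 1, b_factor = 20, is_hetero = FALSE,
               stringsAsFactors = FALSE)
  }
  tab <- rbind(flat(c(1, 0, 0), c(0, 0, 0), "A"),
               flat(c(0, 1, 0), c(40, 0, 0), "B"),
               flat(c(1, 0, 0), c(0, 40, 0), "C"),
               flat(c(0, 1, 0), c(40, 40, 0), "D"))
  m <- molecular_model("flat", tab)
  hx <- assign_helices(m)
  expect_gte(length(hx), 3L)
  expect_error(estimate_frame(m, hx), "degenerate")
  # explicit override still works
  fr <- estimate_frame(m, hx, normal = c(0, 0, 1))
  expect_equal(fr$normal, c(0, 0, 1))
})

test_that("filter_transmembrane keeps spanning helices only", {
  fr <- z_frame()
  vertical <- helix_segment("A", 1, 21, rbind(c(0, 0, -15), c(0, 0, 15)))
  surface <- helix_segment("B", 1, 21, rbind(c(-15, 0, 5), c(15, 0, 5)))
  short <- helix_segment("C", 1, 9, rbind(c(0, 0, -5), c(0, 0, 5)))
  kept <- filter_transmembrane(list(vertical, surface, short), fr)
  expect_length(kept, 1L)
  expect_equal(kept[[1]]$chain_id, "A")
})

test_that("measure_height matches analytic truth for straight helices", {
  fx <- ideal_helix_model()
  hx <- assign_helices(fx$model)
  meas <- measure_height(hx[[1]], z_frame())
  expect_lt(abs(meas$height - 28.5), 0.5)
  # the axis polyline keeps a slight residual wobble from the terminal CA
  # projections, so arc and projected span differ by ~0.1 A even when straight
  expect_lt(abs(meas$height - meas$height_projected), 0.3)
  expect_gte(meas$height, meas$height_projected - 1e-6)
  expect_equal(meas$stromal_end[3] > meas$lumenal_end[3], TRUE)
})

test_that("measure_height recovers curved arc length within 2 percent", {
  h <- make_helix(24, curvature = 100, tilt = 5)
  m <- molecular_model("curved", h$atoms)
  hx <- assign_helices(m)
  expect_length(hx, 1L)
  meas <- measure_height(hx[[1]], z_frame(), k = 5)
  expect_lt(abs(meas$height - h$truth$height) / h$truth$height, 0.02)
  expect_gte(meas$height, meas$height_projected - 1e-6)
})

test_that("k < 3 is refused and k beyond 3 converges on ideal helices", {
  hx <- assign_helices(ideal_helix_model()$model)
  expect_error(measure_height(hx[[1]], z_frame(), k = 2), "k must be >= 3")
  h3 <- measure_height(hx[[1]], z_frame(), k = 3)$height
  h8 <- measure_height(hx[[1]], z_frame(), k = 8)$height
  expect_lt(abs(h8 - h3), 0.5)
})

test_that("aggregate_heights pools identical chains and averages subfamilies", {
  b1 <- make_bundle(30, chain_id = "X")
  b2 <- b1$atoms
  b2$chain_id <- "Y"
  b2[, c("x", "y")] <- b2[, c("x", "y")] + 40  # translated copy, RMSD 0
  b3 <- make_bundle(26, chain_id = "Z", anchors = matrix(c(80, 0), 1))
  m <- molecular_model("pool", rbind(b1$atoms, b2, b3$atoms))
  ann <- data.frame(chain_id = c("X", "Y", "Z"),
                    subunit_label = c("FCP1", "FCP2", "FCP3"),
                    role = "belt1", subfamily = "Lhcf",
                    stringsAsFactors = FALSE)
  class(ann) <- c("subunit_annotation", "data.frame")
  mh <- measure_heights(m, frame = z_frame(), annotation = ann)
  agg <- aggregate_heights(mh$measures, ann, model = m)
  # X and Y pool into one subunit entry; Z stays separate
  expect_equal(nrow(agg$per_subunit), 2L)
  expect_true("FCP1/FCP2" %in% agg$per_subunit$subunit)
  # subfamily mean over heights {30, 30, 26} = 28.667 (to measurement error)
  expect_equal(agg$per_subfamily$subfamily, "Lhcf")
  expect_lt(abs(agg$per_subfamily$mean_height_A - mean(c(30, 30, 26))), 0.5)
  expect_true(agg$per_subfamily$under_sampled)  # 3 < 5 representatives
})

test_that("heights are rigid-motion invariant", {
  scene <- default_scene()
  base <- measure_heights(scene$model, stromal_reference = c(0, 0, 50))
  h0 <- sort(vapply(base$measures, `[[`, 0, "height"))
  p0 <- sort(vapply(base$measures, `[[`, 0, "height_projected"))
  set.seed(11)
  tr <- random_rigid()
  moved <- apply_transform(scene$model, tr)
  ref <- drop(tr$rotation %*% c(0, 0, 50)) + tr$translation
  mh <- measure_heights(moved, stromal_reference = ref)
  expect_equal(sort(vapply(mh$measures, `[[`, 0, "height")), h0,
               tolerance = 1e-9)
  expect_equal(sort(vapply(mh$measures, `[[`, 0, "height_projected")), p0,
               tolerance = 1e-9)
})

test_that("measures_table has the documented schema", {
  scene <- default_scene()
  mh <- scene_measures(scene)
  tab <- measures_table(mh$measures, structure_id = "scene")
  expect_equal(nrow(tab), 9L)  # 3 core + 6 belt helices
  expect_true(all(c("structure_id", "chain_id", "subunit_label",
                    "helix_index", "residue_start", "residue_end",
                    "height_A", "height_projected_A",
                    "stromal_x", "stromal_y", "stromal_z") %in% names(tab)))
  expect_true(all(tab$height_A >= tab$height_projected_A - 1e-6))
})
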