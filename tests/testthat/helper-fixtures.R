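# Shared fixtures, built once per test run. Everything is generated at
# runtime from the synthetic-data module; no binary fixtures are shipped.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# default core(3 x 48 A) + belt(6 x 31 A) scene with two constrained rings
default_scene <- function() {
  fixture("default_scene", function() {
    make_scene(rings = list(
      list(kind = "chl_a", center = c(0, 8, 9)),
      list(kind = "chl_c", partner = 1, distance = 6.0,
           direction = c(1, 0, 0))
    ), n_random_rings = 3, seed = 42)
  })
}

# subfamily analog models + maps at 5 and 15 A
analogs <- function() {
  fixture("analogs", function() make_subfamily_analogs(10L, 18L))
}

# an ideal vertical 20-residue helix model
ideal_helix_model <- function() {
  fixture("ideal_helix", function() {
    h <- make_helix(20)
    list(model = molecular_model("ideal20", h$atoms), truth = h$truth)
  })
}

# z-up frame through the origin
z_frame <- function() membrane_frame(c(0, 0, 1), c(0, 0, 0), 1)

# random rigid transform (uniform rotation via QR, bounded translation)
random_rigid <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  structure(list(rotation = q, translation = runif(3, -30, 30),
                 rmsd = NA_real_, n_atoms = NA_integer_),
            class = "rigid_transform")
}

# measures + frame for a model, with the frame estimated from the model
scene_measures <- function(scene) {
  measure_heights(scene$model, frame = scene$truth$frame,
                  annotation = scene$annotation)
}

# ripple measures built from generator truth (exact analytic heights)
truth_measures <- function(scene) {
  lapply(scene$truth$helices, function(t) {
    h <- helix_segment(t$chain_id, t$residue_start, t$residue_end,
                       rbind(t$axis_start, t$axis_end))
    measure_height(h, scene$truth$frame, k = 3, subunit_label = t$group)
  })
}
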