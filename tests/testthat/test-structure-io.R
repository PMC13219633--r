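# structure_io: model construction, PDB/mmCIF round-trips, MRC maps,
# annotation tables.

three_atom_table <- function() {
  data.frame(
    chain_id = "A", residue_name = "ALA", residue_seq = 1:3,
    insertion_code = "", atom_name = c("N", "CA", "C"),
    element = c("N", "C", "C"),
    x = c(0, 1.4, 2.5), y = c(0, 0.2, 1.1), z = c(0, 0.1, 0.3),
    occupancy = 1, b_factor = 20, is_hetero = FALSE,
    stringsAsFactors = FALSE
  )
}

test_that("molecular_model wraps a minimal well-formed atom table", {
  m <- molecular_model("mini", three_atom_table())
  expect_s3_class(m, "molecular_model")
  expect_equal(nrow(m$atoms), 3L)
  expect_equal(model_chains(m), "A")
})

test_that("empty and malformed models are rejected", {
  tab <- three_atom_table()
  expect_error(molecular_model("empty", tab[0, ]), "empty model")
  bad <- tab; bad$x[2] <- NA_real_
  expect_error(molecular_model("nan", bad), "finite")
  noel <- tab; noel$element[1] <- ""
  expect_error(molecular_model("noel", noel), "element")
  expect_error(molecular_model("cols", tab[, -1]), "missing columns")
})

test_that("occupancy is clamped into [0, 1]", {
  tab <- three_atom_table()
  tab$occupancy <- c(-0.5, 0.5, 1.7)
  m <- molecular_model("occ", tab)
  expect_equal(m$atoms$occupancy, c(0, 0.5, 1))
})

test_that("PDB round-trip preserves coordinates and identities", {
  scene <- default_scene()
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(scene$model, path)
  back <- read_structure(path)
  expect_equal(nrow(back$atoms), nrow(scene$model$atoms))
  expect_lt(max(abs(model_xyz(back) - model_xyz(scene$model))), 1e-3)
  expect_equal(back$atoms$chain_id, scene$model$atoms$chain_id)
  expect_equal(back$atoms$residue_seq, scene$model$atoms$residue_seq)
  expect_equal(back$atoms$residue_name, scene$model$atoms$residue_name)
  expect_equal(back$atoms$atom_name, scene$model$atoms$atom_name)
  expect_equal(back$atoms$is_hetero, scene$model$atoms$is_hetero)
})

test_that("mmCIF round-trip preserves coordinates and identities", {
  scene <- default_scene()
  path <- withr::local_tempfile(fileext = ".cif")
  write_structure(scene$model, path)
  back <- read_structure(path)
  expect_equal(nrow(back$atoms), nrow(scene$model$atoms))
  expect_lt(max(abs(model_xyz(back) - model_xyz(scene$model))), 1e-3)
  expect_equal(back$atoms$chain_id, scene$model$atoms$chain_id)
  expect_equal(back$atoms$residue_seq, scene$model$atoms$residue_seq)
})

test_that("round-trip holds across randomized small models", {
  set.seed(7)
  for (i in 1:10) {
    n <- sample(5:40, 1)
    tab <- data.frame(
      chain_id = sample(LETTERS[1:3], n, replace = TRUE),
      residue_name = "GLY", residue_seq = seq_len(n), insertion_code = "",
      atom_name = "CA", element = "C",
      x = round(runif(n, -90, 90), 3), y = round(runif(n, -90, 90), 3),
      z = round(runif(n, -90, 90), 3),
      occupancy = 1, b_factor = 10, is_hetero = FALSE,
      stringsAsFactors = FALSE
    )
    tab <- tab[order(tab$chain_id, tab$residue_seq), ]
    m <- molecular_model(paste0("r", i), tab)
    p <- withr::local_tempfile(fileext = ".pdb")
    write_structure(m, p)
    back <- read_structure(p)
    expect_equal(nrow(back$atoms), n)
    expect_lt(max(abs(model_xyz(back) - model_xyz(m))), 1e-3)
    expect_equal(sort(unique(back$atoms$chain_id)),
                 sort(unique(m$atoms$chain_id)))
  }
})

test_that("alternate-location collapse keeps the top-occupancy conformer", {
  tab <- three_atom_table()
  dup <- tab[2, ]
  dup$x <- 9; dup$occupancy <- 0.4
  tab$occupancy[2] <- 0.6
  collapsed <- lhctools:::collapse_altloc(rbind(tab, dup))
  expect_equal(nrow(collapsed), 3L)  # never increases the count
  expect_equal(collapsed$x[collapsed$atom_name == "CA"], 1.4)
})

test_that("hydrogens are dropped on read", {
  tab <- three_atom_table()
  h <- tab[1, ]; h$atom_name <- "H"; h$element <- "H"
  m <- molecular_model("withH", rbind(tab, h))
  p <- withr::local_tempfile(fileext = ".pdb")
  write_structure(m, p)
  expect_equal(nrow(read_structure(p)$atoms), 3L)
})

test_that("unreadable structure input errors clearly", {
  expect_error(read_structure("no/such/file.pdb"), "no such file")
  p <- withr::local_tempfile(fileext = ".xyz")
  writeLines("hello", p)
  expect_error(read_structure(p), "format")
})

test_that("MRC zero-grid round-trip is exact", {
  g <- density_grid(array(0, dim = c(8, 8, 8)), origin = c(1, 2, 3),
                    voxel_size = 1.25)
  p <- withr::local_tempfile(fileext = ".mrc")
  write_map(g, p)
  back <- read_map(p)
  expect_equal(back$dims, c(8L, 8L, 8L))
  expect_equal(back$values, g$values)
  expect_equal(back$origin, g$origin, tolerance = 1e-6)
  expect_equal(back$voxel_size, g$voxel_size, tolerance = 1e-6)
})

test_that("simulated-map round-trip deviates < 1e-5 of the value range", {
  m <- ideal_helix_model()$model
  g <- simulate_map(m, resolution = 4)
  p <- withr::local_tempfile(fileext = ".mrc")
  write_map(g, p)
  back <- read_map(p)
  rng <- diff(range(g$values))
  expect_lt(max(abs(back$values - g$values)) / rng, 1e-5)
})

test_that("permuted axis order in the header is normalised", {
  # write a z,y,x-ordered file by hand and check real-space positions match
  vals <- array(seq_len(3 * 4 * 5), dim = c(3, 4, 5))  # x fastest
  ref <- density_grid(vals, origin = c(0, 0, 0), voxel_size = 2)
  p <- withr::local_tempfile(fileext = ".mrc")
  perm <- aperm(vals, c(3, 2, 1))  # store sections of x, rows y, columns z
  con <- file(p, "wb")
  d <- dim(perm)
  writeBin(as.integer(c(d, 2L, 0L, 0L, 0L, d)), con, size = 4, endian = "little")
  writeBin(as.numeric(c(d * 2, 90, 90, 90)), con, size = 4, endian = "little")
  writeBin(c(3L, 2L, 1L), con, size = 4, endian = "little")  # mapc=z mapr=y maps=x
  writeBin(as.numeric(c(min(perm), max(perm), mean(perm))), con, size = 4,
           endian = "little")
  writeBin(c(1L, 0L), con, size = 4, endian = "little")
  writeBin(integer(24), con, size = 4, endian = "little")
  writeBin(as.numeric(c(0, 0, 0)), con, size = 4, endian = "little")
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0, 0)), con)
  writeBin(as.numeric(sd(perm)), con, size = 4, endian = "little")
  writeBin(0L, con, size = 4, endian = "little")
  writeBin(raw(800), con)
  writeBin(as.numeric(perm), con, size = 4, endian = "little")
  close(con)
  back <- read_map(p)
  expect_equal(back$dims, ref$dims)
  # oracle: sample 10 random voxels by header math
  set.seed(3)
  for (r in 1:10) {
    ix <- sample(3, 1); iy <- sample(4, 1); iz <- sample(5, 1)
    expect_equal(back$values[ix, iy, iz], ref$values[ix, iy, iz])
  }
})

test_that("corrupt MRC headers error naming the field", {
  g <- density_grid(array(0, dim = c(4, 4, 4)))
  p <- withr::local_tempfile(fileext = ".mrc")
  write_map(g, p)
  raw <- readBin(p, "raw", n = file.size(p))
  bad <- raw
  bad[205:208] <- as.raw(c(0, 0, 0, 0))  # clobber the MAP tag (word 52)
  pb <- withr::local_tempfile(fileext = ".mrc")
  writeBin(bad, pb)
  expect_error(read_map(pb), "MAP")
  bad2 <- raw
  bad2[13:16] <- writeBin(9L, raw(), size = 4, endian = "little")  # mode 9
  pb2 <- withr::local_tempfile(fileext = ".mrc")
  writeBin(bad2, pb2)
  expect_error(read_map(pb2), "mode")
})

test_that("annotation tables load, validate and warn", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("chain_id,subunit_label,role,subfamily",
               "A,PsaA,core,",
               "B,FCP1,belt1,Lhcf"), p)
  ann <- load_annotation(p)
  expect_s3_class(ann, "subunit_annotation")
  expect_equal(nrow(ann), 2L)
  expect_true(is.na(ann$subfamily[1]))

  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("chain_id,subunit_label,role,subfamily",
               "A,PsaA,core,", "A,PsaB,core,"), dup)
  expect_error(load_annotation(dup), "duplicate chain_id")

  badrole <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("chain_id,subunit_label,role,subfamily",
               "A,PsaA,nucleus,"), badrole)
  expect_error(load_annotation(badrole), "unknown role")

  coresf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("chain_id,subunit_label,role,subfamily",
               "A,PsaA,core,Lhcf"), coresf)
  expect_error(load_annotation(coresf), "antenna roles")

  m <- molecular_model("mini", three_atom_table())
  extra <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("chain_id,subunit_label,role,subfamily",
               "A,PsaA,core,", "Z,FCP9,belt2,Lhcr"), extra)
  expect_warning(load_annotation(extra, model = m), "absent from model")
})

test_that("tab-separated annotations are accepted", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chain_id\tsubunit_label\trole\tsubfamily",
               "A\tPsaA\tcore\t", "B\tFCP1\tbelt1\tLhcq"), p)
  expect_equal(nrow(load_annotation(p)), 2L)
})
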