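# Atomic-model and density-map I/O, plus subunit annotation tables.
#
# Models are held as a flat atom table (one row per heavy atom) wrapped in a
# light S3 class; all downstream geometry works on this table. PDB and mmCIF
# parsing is delegated to bio3d; density maps use the MRC2014 format.

MODEL_COLUMNS <- c("chain_id", "residue_name", "residue_seq", "insertion_code",
                   "atom_name", "element", "x", "y", "z",
                   "occupancy", "b_factor", "is_hetero")

#' Construct a molecular model from an atom table
#'
#' @param id structure identifier (e.g. a PDB code or fixture name).
#' @param atoms data.frame with columns `chain_id`, `residue_name`,
#'   `residue_seq`, `insertion_code`, `atom_name`, `element`, `x`, `y`, `z`,
#'   `occupancy`, `b_factor`, `is_hetero`.
#' @return an object of class `molecular_model`.
#' @export
molecular_model <- function(id, atoms) {
  stopifnot(is.data.frame(atoms))
  missing_cols <- setdiff(MODEL_COLUMNS, names(atoms))
  if (length(missing_cols)) {
    stop("atom table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  atoms <- atoms[, MODEL_COLUMNS]
  if (nrow(atoms) == 0L) stop("empty model: no atoms")
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite atom coordinates")
  occ <- atoms$occupancy
  occ[!is.finite(occ)] <- 1
  atoms$occupancy <- pmin(pmax(occ, 0), 1)
  if (any(!nzchar(atoms$element) | is.na(atoms$element))) {
    stop("every atom must carry a non-empty element symbol")
  }
  atoms$chain_id <- as.character(atoms$chain_id)
  rownames(atoms) <- NULL
  structure(list(id = as.character(id), atoms = atoms), class = "molecular_model")
}

#' @export
print.molecular_model <- function(x, ...) {
  cat(sprintf("<molecular_model> %s: %d atoms, %d chains (%s)\n",
              x$id, nrow(x$atoms), length(model_chains(x)),
              paste(head(model_chains(x), 10), collapse = ",")))
  invisible(x)
}

#' Chain identifiers of a model
#' @param model a `molecular_model`.
#' @return character vector of chain ids in order of first appearance.
#' @export
model_chains <- function(model) unique(model$atoms$chain_id)

#' Coordinate matrix of (a subset of) a model
#' @param model a `molecular_model`.
#' @param sel optional logical or integer row selector into the atom table.
#' @return numeric matrix with columns x, y, z.
#' @export
model_xyz <- function(model, sel = NULL) {
  a <- model$atoms
  if (!is.null(sel)) a <- a[sel, , drop = FALSE]
  as.matrix(a[, c("x", "y", "z")])
}

# Collapse alternate locations: keep the highest-occupancy conformer of each
# (chain, residue, insertion, atom name) site; ties resolved by file order.
collapse_altloc <- function(atoms) {
  key <- paste(atoms$chain_id, atoms$residue_seq, atoms$insertion_code,
               atoms$residue_name, atoms$atom_name, sep = "\r")
  ord <- order(key, -atoms$occupancy, seq_len(nrow(atoms)))
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(key[ord]), , drop = FALSE]
  atoms[order(as.integer(rownames(atoms))), , drop = FALSE]
}

bio3d_to_atoms <- function(pdb) {
  a <- pdb$atom
  elesy <- a$elesy
  guess <- toupper(substr(gsub("[^A-Za-z].*$", "", a$elety), 1, 1))
  elesy[is.na(elesy) | !nzchar(elesy)] <- guess[is.na(elesy) | !nzchar(elesy)]
  data.frame(
    chain_id = ifelse(is.na(a$chain), " ", as.character(a$chain)),
    residue_name = as.character(a$resid),
    residue_seq = as.integer(a$resno),
    insertion_code = ifelse(is.na(a$insert), "", as.character(a$insert)),
    atom_name = as.character(a$elety),
    element = toupper(elesy),
    x = a$x, y = a$y, z = a$z,
    occupancy = ifelse(is.na(a$o), 1, a$o),
    b_factor = ifelse(is.na(a$b), 0, a$b),
    is_hetero = a$type == "HETATM",
    stringsAsFactors = FALSE
  )
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("cif", "mmcif")) "mmcif" else if (ext %in% c("pdb", "ent")) "pdb"
  else stop("cannot guess structure format from extension '", ext,
            "'; pass format explicitly")
}

#' Read an atomic model from PDB or mmCIF
#'
#' Hydrogens are dropped and, where alternate locations are modelled, the
#' highest-occupancy conformer of each atom site is kept (ties broken by file
#' order), so all downstream geometry sees a single heavy-atom conformer.
#'
#' @param path path to a `.pdb` or `.cif` file.
#' @param format `"auto"` (by extension), `"pdb"` or `"mmcif"`.
#' @param naming `"auth"` uses author-assigned chain identifiers (the naming
#'   that subunit annotations and published figures use); `"label"` switches
#'   mmCIF models to `label_asym_id` chains.
#' @param id structure identifier; defaults to the file base name.
#' @return a [molecular_model()].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           naming = c("auth", "label"), id = NULL) {
  format <- match.arg(format)
  naming <- match.arg(naming)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") format <- guess_format(path)
  pdb <- tryCatch(
    if (format == "pdb") {
      bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
    } else {
      suppressWarnings(bio3d::read.cif(path, verbose = FALSE))
    },
    error = function(e) stop("failed to parse ", format, " file '", path,
                             "': ", conditionMessage(e))
  )
  atoms <- bio3d_to_atoms(pdb)
  if (naming == "label" && format == "mmcif") {
    atoms$chain_id <- cif_label_chains(path)
  }
  atoms <- atoms[!(atoms$element %in% c("H", "D")), , drop = FALSE]
  atoms <- collapse_altloc(atoms)
  if (nrow(atoms) == 0L) stop("empty model in '", path, "'")
  molecular_model(id %||% tools::file_path_sans_ext(basename(path)), atoms)
}

# Extract label_asym_id per atom row from an mmCIF atom_site loop, in file
# order, so author chain ids can be swapped for label ids.
cif_label_chains <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^_atom_site\\.", lines)
  if (!length(hdr)) stop("mmCIF file has no atom_site loop: ", path)
  fields <- sub("^_atom_site\\.", "", trimws(lines[hdr]))
  col <- match("label_asym_id", fields)
  if (is.na(col)) stop("atom_site loop lacks label_asym_id: ", path)
  body <- lines[(max(hdr) + 1):length(lines)]
  rows <- grep("^(ATOM|HETATM)\\s", body, value = TRUE)
  vapply(strsplit(rows, "\\s+"), function(tok) tok[col], character(1))
}

#' Write an atomic model to PDB or mmCIF
#'
#' @param model a [molecular_model()].
#' @param path output file path.
#' @param format `"pdb"` or `"mmcif"` (default taken from the extension).
#' @return the path, invisibly.
#' @export
write_structure <- function(model, path, format = c("auto", "pdb", "mmcif")) {
  stopifnot(inherits(model, "molecular_model"))
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  a <- model$atoms
  if (nrow(a) == 0L) stop("refusing to write an empty model")
  if (format == "pdb") {
    bio3d::write.pdb(
      file = path,
      xyz = as.vector(t(as.matrix(a[, c("x", "y", "z")]))),
      type = ifelse(a$is_hetero, "HETATM", "ATOM"),
      resno = a$residue_seq, resid = a$residue_name,
      eleno = seq_len(nrow(a)), elety = a$atom_name,
      chain = a$chain_id,
      insert = ifelse(nzchar(a$insertion_code), a$insertion_code, NA),
      o = a$occupancy, b = a$b_factor, elesy = a$element,
      verbose = FALSE
    )
  } else {
    write_mmcif(model, path)
  }
  invisible(path)
}

write_mmcif <- function(model, path) {
  a <- model$atoms
  ins <- ifelse(nzchar(a$insertion_code), a$insertion_code, "?")
  rows <- sprintf(
    "%s %d %s %s . %s %s 1 %d %s %.3f %.3f %.3f %.2f %.2f %d %s %s %s 1",
    ifelse(a$is_hetero, "HETATM", "ATOM"), seq_len(nrow(a)), a$element,
    a$atom_name, a$residue_name, a$chain_id, a$residue_seq, ins,
    a$x, a$y, a$z, a$occupancy, a$b_factor,
    a$residue_seq, a$residue_name, a$chain_id, a$atom_name
  )
  header <- c(
    paste0("data_", gsub("[^A-Za-z0-9_-]", "_", model$id)),
    "#", "loop_",
    paste0("_atom_site.", c(
      "group_PDB", "id", "type_symbol", "label_atom_id", "label_alt_id",
      "label_comp_id", "label_asym_id", "label_entity_id", "label_seq_id",
      "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
      "B_iso_or_equiv", "auth_seq_id", "auth_comp_id", "auth_asym_id",
      "auth_atom_id", "pdbx_PDB_model_num"))
  )
  writeLines(c(header, rows, "#"), path)
}

# ---------------------------------------------------------------------------
# Density grids (MRC2014)

#' Construct a density grid
#'
#' @param values 3-D numeric array, x fastest.
#' @param origin position of voxel (1,1,1) in Angstrom.
#' @param voxel_size voxel edge lengths in Angstrom (length 1 or 3).
#' @param resolution optional declared resolution in Angstrom.
#' @return an object of class `density_grid`.
#' @export
density_grid <- function(values, origin = c(0, 0, 0), voxel_size = 1,
                         resolution = NA_real_) {
  stopifnot(is.array(values), length(dim(values)) == 3L)
  if (!all(is.finite(values))) stop("grid values must be finite")
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  if (any(voxel_size <= 0)) stop("voxel_size must be positive")
  if (any(dim(values) < 1L)) stop("grid dims must be positive")
  structure(list(origin = as.numeric(origin), voxel_size = voxel_size,
                 dims = dim(values), values = values,
                 resolution = as.numeric(resolution)),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf("<density_grid> %d x %d x %d voxels @ %.3f A, origin (%.1f, %.1f, %.1f)%s\n",
              x$dims[1], x$dims[2], x$dims[3], x$voxel_size[1],
              x$origin[1], x$origin[2], x$origin[3],
              if (is.finite(x$resolution)) sprintf(", %.1f A", x$resolution) else ""))
  invisible(x)
}

#' Read an MRC2014 density map
#'
#' Axis order is normalised to x,y,z regardless of the `mapc/mapr/maps`
#' permutation in the header; the origin honours the MRC2014 origin record,
#' falling back to `n*start` offsets when the origin words are zero.
#'
#' MRC headers carry no nominal resolution; supply `resolution` (e.g. the
#' reported FSC resolution) so downstream fitting can pick a matching
#' Gaussian width.
#'
#' @param path path to an `.mrc`/`.map` file.
#' @param resolution optional nominal resolution of the map, Angstrom.
#' @return a [density_grid()].
#' @export
read_map <- function(path, resolution = NA_real_) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  ints1 <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  cella <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  readBin(con, "numeric", n = 3, size = 4, endian = "little") # cell angles
  mapcrs <- readBin(con, "integer", n = 3, size = 4, endian = "little")
  readBin(con, "numeric", n = 3, size = 4, endian = "little") # dmin/dmax/dmean
  readBin(con, "integer", n = 1, size = 4, endian = "little") # ispg
  nsymbt <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  readBin(con, "integer", n = 24, size = 4, endian = "little") # extra
  orig <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  maptag <- rawToChar(readBin(con, "raw", n = 4))
  readBin(con, "raw", n = 4) # machine stamp
  readBin(con, "numeric", n = 1, size = 4, endian = "little") # rms
  readBin(con, "raw", n = 804) # nlabl + labels
  mode <- ints1[4]
  if (!identical(substr(maptag, 1, 3), "MAP")) {
    stop("corrupt MRC header: missing 'MAP ' tag in '", path, "'")
  }
  if (!all(mapcrs %in% 1:3) || anyDuplicated(mapcrs)) {
    stop("corrupt MRC header: invalid axis fields mapc/mapr/maps")
  }
  ncrs <- ints1[1:3]
  nstart <- ints1[5:7]
  m <- ints1[8:10]
  if (any(ncrs <= 0) || any(m <= 0)) stop("corrupt MRC header: non-positive nx/ny/nz or mx/my/mz")
  if (nsymbt > 0) readBin(con, "raw", n = nsymbt)
  nvox <- prod(ncrs)
  values <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", n = nvox, size = 1, signed = TRUE)),
    "1" = as.numeric(readBin(con, "integer", n = nvox, size = 2, endian = "little")),
    "2" = readBin(con, "numeric", n = nvox, size = 4, endian = "little"),
    stop("corrupt or unsupported MRC header: mode ", mode))
  if (length(values) < nvox) stop("truncated MRC data section in '", path, "'")
  arr <- array(values, dim = ncrs)
  # reorder stored column/row/section axes onto x,y,z
  perm <- match(1:3, mapcrs)
  arr <- aperm(arr, perm)
  nstart_xyz <- nstart[perm]
  voxel <- cella / m
  origin <- if (any(abs(orig) > 1e-6)) orig else nstart_xyz * voxel
  density_grid(arr, origin = origin, voxel_size = voxel,
               resolution = resolution)
}

#' Write a density grid as MRC2014
#'
#' @param grid a [density_grid()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_map <- function(grid, path) {
  stopifnot(inherits(grid, "density_grid"))
  con <- file(path, "wb")
  on.exit(close(con))
  d <- grid$dims
  v <- as.numeric(grid$values)
  writeBin(as.integer(c(d, 2L, 0L, 0L, 0L, d)), con, size = 4, endian = "little")
  writeBin(as.numeric(c(d * grid$voxel_size, 90, 90, 90)), con, size = 4,
           endian = "little")
  writeBin(1:3, con, size = 4, endian = "little")
  writeBin(as.numeric(c(min(v), max(v), mean(v))), con, size = 4, endian = "little")
  writeBin(c(1L, 0L), con, size = 4, endian = "little")     # ispg, nsymbt
  writeBin(integer(24), con, size = 4, endian = "little")   # extra
  writeBin(as.numeric(grid$origin), con, size = 4, endian = "little")
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)          # little-endian stamp
  writeBin(as.numeric(sd(v)), con, size = 4, endian = "little")
  writeBin(0L, con, size = 4, endian = "little")            # nlabl
  writeBin(raw(800), con)                                   # labels
  writeBin(v, con, size = 4, endian = "little")
  invisible(path)
}

# ---------------------------------------------------------------------------
# Subunit annotations

ANNOTATION_ROLES <- c("core", "belt1", "belt2", "outer")
ANNOTATION_SUBFAMILIES <- c("Lhcr", "Lhcf", "Lhcq", "Lhcx", "Lhcz",
                            "CgLhcr9-like", "RedCAP", "unknown")

#' Load a chain-to-subunit annotation table
#'
#' The table binds model chains to subunit names (e.g. PsaA, FCP11), their
#' architectural role (PSI core, first/second antenna belt, outer) and, for
#' antenna subunits, an LHC subfamily.
#'
#' @param path comma- or tab-separated file with a header row and columns
#'   `chain_id`, `subunit_label`, `role`, `subfamily`.
#' @param model optional [molecular_model()]; chains present in only one of
#'   table/model are reported as warnings.
#' @return data.frame of class `subunit_annotation`.
#' @export
load_annotation <- function(path, model = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  sep <- if (grepl("\t", first)) "\t" else ","
  tab <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                  strip.white = TRUE, comment.char = "#")
  need <- c("chain_id", "subunit_label", "role", "subfamily")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    stop("annotation table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  tab <- tab[, need]
  tab$chain_id <- as.character(tab$chain_id)
  if (anyDuplicated(tab$chain_id)) {
    stop("duplicate chain_id in annotation table: ",
         paste(unique(tab$chain_id[duplicated(tab$chain_id)]), collapse = ", "))
  }
  bad_role <- setdiff(unique(tab$role), ANNOTATION_ROLES)
  if (length(bad_role)) {
    stop("unknown role(s): ", paste(bad_role, collapse = ", "),
         " (expected ", paste(ANNOTATION_ROLES, collapse = "/"), ")")
  }
  tab$subfamily[is.na(tab$subfamily) | !nzchar(tab$subfamily)] <- NA_character_
  bad_sf <- setdiff(unique(tab$subfamily[!is.na(tab$subfamily)]),
                    ANNOTATION_SUBFAMILIES)
  if (length(bad_sf)) {
    stop("unknown subfamily value(s): ", paste(bad_sf, collapse = ", "))
  }
  core_sf <- tab$role == "core" & !is.na(tab$subfamily)
  if (any(core_sf)) {
    stop("subfamily may only be set for antenna roles, offending chains: ",
         paste(tab$chain_id[core_sf], collapse = ", "))
  }
  if (!is.null(model)) {
    only_tab <- setdiff(tab$chain_id, model_chains(model))
    # pure-ligand chains (e.g. pigments) need no subunit annotation
    poly_chains <- unique(model$atoms$chain_id[!model$atoms$is_hetero])
    only_mod <- setdiff(poly_chains, tab$chain_id)
    if (length(only_tab)) {
      warning("annotation chains absent from model: ",
              paste(only_tab, collapse = ", "))
    }
    if (length(only_mod)) {
      warning("model chains without annotation: ",
              paste(only_mod, collapse = ", "))
    }
  }
  class(tab) <- c("subunit_annotation", "data.frame")
  tab
}
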