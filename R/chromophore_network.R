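# Chromophore extraction and distance networks.
#
# Chlorophylls are reduced to their tetrapyrrole macrocycle (ring heavy
# atoms, meso carbons, first-shell substituents and the central metal; the
# phytol tail is excluded) so that minimum heavy-atom "edge-to-edge"
# distances reflect the porphyrin rings, the quantity that excitation energy
# transfer efficiency tracks. Carotenoids are carried through extraction but
# excluded from EET networks by default.

# Tetrapyrrole macrocycle atom names (PDB chemical-component conventions).
MACROCYCLE_ATOMS <- c(
  "MG",
  "NA", "NB", "NC", "ND",
  paste0("C", rep(1:4, 4), rep(c("A", "B", "C", "D"), each = 4)),
  "CHA", "CHB", "CHC", "CHD",
  "CMA", "CMB", "CMC", "CMD",
  "CAA", "CAB", "CAC", "CAD",
  "CBA", "CBB", "CBC", "CBD",
  "CGA", "CGD"
)

#' Default chromophore residue catalogue
#'
#' Maps hetero residue names to chromophore kinds. Covers chlorophyll a
#' (CLA), chlorophylls c1/c2/c3 (KC1/KC2/KC3), chlorophyll b (CHL) and the
#' common photosynthetic carotenoids (beta-carotene, fucoxanthin,
#' diadinoxanthin/diatoxanthin, violaxanthin, lutein, zeaxanthin).
#'
#' @return named character vector: residue name -> kind
#'   (`chl_a`, `chl_c`, `carotenoid`, `other`).
#' @export
default_chromophore_catalog <- function() {
  c(CLA = "chl_a", CHL = "other",
    KC1 = "chl_c", KC2 = "chl_c", KC3 = "chl_c",
    BCR = "carotenoid", BCA = "carotenoid", FXA = "carotenoid",
    A86 = "carotenoid", DD6 = "carotenoid", DTX = "carotenoid",
    XAT = "carotenoid", LUT = "carotenoid", ZEX = "carotenoid")
}

chromophore_id <- function(ch) paste0(ch$chain_id, ":", ch$residue_seq)

new_chromophore <- function(chain_id, residue_seq, residue_name, kind,
                            macrocycle, atom_names, metal, side) {
  structure(list(chain_id = chain_id, residue_seq = as.integer(residue_seq),
                 residue_name = residue_name, kind = kind,
                 macrocycle = macrocycle, atom_names = atom_names,
                 metal = metal, side = side),
            class = "chromophore")
}

#' @export
print.chromophore <- function(x, ...) {
  cat(sprintf("<chromophore> %s %s %s (%d ring atoms, side %s)\n",
              x$kind, x$residue_name, chromophore_id(x), nrow(x$macrocycle),
              x$side))
  invisible(x)
}

#' Extract chromophores from a model
#'
#' One chromophore per catalogued hetero residue. Chlorophylls keep only
#' their macrocycle heavy atoms and central metal; carotenoids keep all heavy
#' atoms. Membrane side is assigned from the metal position (macrocycle
#' centroid when the metal is missing) relative to the membrane midplane;
#' chromophores within `side_margin` of the midplane are left `unassigned`.
#'
#' @param model a [molecular_model()].
#' @param frame optional [membrane_frame()]; without it all sides are
#'   `unassigned`.
#' @param catalog residue-name-to-kind map, see
#'   [default_chromophore_catalog()].
#' @param side_margin half-width of the unassigned band around the midplane,
#'   Angstrom.
#' @return list of `chromophore` objects; uncatalogued hetero residue names
#'   are attached as attribute `uncatalogued`.
#' @export
extract_chromophores <- function(model, frame = NULL,
                                 catalog = default_chromophore_catalog(),
                                 side_margin = 2) {
  a <- model$atoms
  het <- a[a$is_hetero, , drop = FALSE]
  skip <- c("HOH", "WAT", "DOD", "NA", "CL", "K", "MG", "CA", "ZN", "MN", "FE")
  out <- list()
  uncat <- character(0)
  if (nrow(het)) {
    key <- paste(het$chain_id, het$residue_seq, het$residue_name, sep = "\r")
    for (grp in split(seq_len(nrow(het)), factor(key, levels = unique(key)))) {
      res <- het[grp, , drop = FALSE]
      rname <- res$residue_name[1]
      if (rname %in% skip) next
      kind <- unname(catalog[rname])
      if (is.na(kind)) {
        uncat <- c(uncat, rname)
        next
      }
      is_chl <- kind %in% c("chl_a", "chl_c")
      ring <- if (is_chl) {
        res[res$atom_name %in% MACROCYCLE_ATOMS, , drop = FALSE]
      } else {
        res
      }
      if (!nrow(ring)) next
      xyz <- as.matrix(ring[, c("x", "y", "z")])
      metal_row <- which(ring$element == "MG" | ring$atom_name == "MG")
      metal <- if (length(metal_row)) xyz[metal_row[1], ] else NULL
      if (is_chl && is.null(metal)) {
        warning("chlorophyll ", res$chain_id[1], ":", res$residue_seq[1],
                " lacks its Mg; using the macrocycle centroid for sidedness")
      }
      side <- "unassigned"
      if (!is.null(frame)) {
        s <- stromal_coord(frame, metal %||% colMeans(xyz))
        if (abs(s) > side_margin) side <- if (s > 0) "stromal" else "lumenal"
      }
      out[[length(out) + 1L]] <- new_chromophore(
        res$chain_id[1], res$residue_seq[1], rname, kind,
        xyz, ring$atom_name, metal, side)
    }
  }
  # deterministic order: chain, then residue number
  if (length(out)) {
    ord <- order(vapply(out, `[[`, "", "chain_id"),
                 vapply(out, `[[`, 0L, "residue_seq"))
    out <- out[ord]
  }
  attr(out, "uncatalogued") <- unique(uncat)
  out
}

#' Subset a chromophore collection
#' @param chromophores list of `chromophore`.
#' @param chains keep only these chain ids.
#' @param side keep only `"stromal"`/`"lumenal"`/`"unassigned"` chromophores.
#' @param kinds keep only these kinds.
#' @param exclude drop chromophores with these ids (`"chain:resno"`).
#' @return filtered list.
#' @export
filter_chromophores <- function(chromophores, chains = NULL, side = NULL,
                                kinds = NULL, exclude = NULL) {
  keep <- rep(TRUE, length(chromophores))
  if (!is.null(chains)) {
    keep <- keep & vapply(chromophores, `[[`, "", "chain_id") %in% chains
  }
  if (!is.null(side)) {
    keep <- keep & vapply(chromophores, `[[`, "", "side") %in% side
  }
  if (!is.null(kinds)) {
    keep <- keep & vapply(chromophores, `[[`, "", "kind") %in% kinds
  }
  if (!is.null(exclude)) {
    keep <- keep & !(vapply(chromophores, chromophore_id, "") %in% exclude)
  }
  chromophores[keep]
}

#' Tabulate chromophores
#' @param chromophores list of `chromophore`.
#' @param structure_id optional id per row.
#' @return data.frame, one row per chromophore.
#' @export
chromophore_table <- function(chromophores, structure_id = NA_character_) {
  if (!length(chromophores)) {
    return(data.frame(structure_id = character(), chain_id = character(),
                      residue_seq = integer(), residue_name = character(),
                      kind = character(), side = character(),
                      metal_x = numeric(), metal_y = numeric(),
                      metal_z = numeric()))
  }
  do.call(rbind, lapply(chromophores, function(ch) {
    m <- ch$metal %||% rep(NA_real_, 3)
    data.frame(structure_id = structure_id, chain_id = ch$chain_id,
               residue_seq = ch$residue_seq, residue_name = ch$residue_name,
               kind = ch$kind, side = ch$side,
               metal_x = m[1], metal_y = m[2], metal_z = m[3],
               stringsAsFactors = FALSE)
  }))
}

#' Porphyrin edge-to-edge distance
#'
#' Minimum heavy-atom distance between the macrocycle atom sets of two
#' chromophores.
#'
#' @param c1,c2 `chromophore` objects (distinct).
#' @return distance in Angstrom.
#' @export
edge_to_edge <- function(c1, c2) {
  if (identical(chromophore_id(c1), chromophore_id(c2))) {
    stop("self distance is undefined: ", chromophore_id(c1))
  }
  cpp_min_set_dist(c1$macrocycle, c2$macrocycle)
}

#' Mg-Mg distance between two chlorophylls
#' @param c1,c2 `chromophore` objects carrying central metals.
#' @return distance in Angstrom.
#' @export
mg_mg <- function(c1, c2) {
  if (is.null(c1$metal) || is.null(c2$metal)) {
    stop("Mg-Mg distance requires central metals on both chromophores")
  }
  vnorm(c1$metal - c2$metal)
}

#' Build an EET candidate network
#'
#' Edges join chromophore pairs whose porphyrin edge-to-edge distance is
#' within `cutoff` (strictly below it when `strict = TRUE`, matching a
#' "closer than" reading). Carotenoids are excluded by default.
#'
#' @param chromophores list of `chromophore` (>= 2 after kind filtering).
#' @param cutoff edge-to-edge cutoff, Angstrom.
#' @param side_filter optional: `"stromal"` or `"lumenal"` restricts nodes to
#'   one membrane side.
#' @param strict use `<` instead of `<=` at the cutoff.
#' @param kinds chromophore kinds admitted as nodes.
#' @param brute_force evaluate every pair without spatial pruning; slower but
#'   useful as an oracle / sensitivity check.
#' @return object of class `eet_network` with data.frames `nodes`, `edges`.
#' @export
build_eet_network <- function(chromophores, cutoff = 15, side_filter = NULL,
                              strict = FALSE, kinds = c("chl_a", "chl_c"),
                              brute_force = FALSE) {
  ch <- filter_chromophores(chromophores, side = side_filter, kinds = kinds)
  if (length(ch) < 2L) stop("need >= 2 chromophores after filtering")
  sizes <- vapply(ch, function(c) nrow(c$macrocycle), 0L)
  coords <- do.call(rbind, lapply(ch, `[[`, "macrocycle"))
  end <- cumsum(sizes)
  start <- end - sizes + 1L
  e <- if (brute_force) cpp_set_edges_brute(coords, start, end, cutoff, strict)
       else cpp_set_edges(coords, start, end, cutoff, strict)
  nodes <- chromophore_table(ch)
  nodes$id <- seq_along(ch)
  edges <- data.frame(source = e$i, target = e$j, edge_to_edge = e$dist)
  if (nrow(edges)) {
    edges$same_side <- nodes$side[edges$source] == nodes$side[edges$target]
    edges$cross_subunit <- nodes$chain_id[edges$source] !=
      nodes$chain_id[edges$target]
    edges$mg_mg <- mapply(function(i, j) {
      if (!is.null(ch[[i]]$metal) && !is.null(ch[[j]]$metal)) {
        vnorm(ch[[i]]$metal - ch[[j]]$metal)
      } else NA_real_
    }, edges$source, edges$target)
    edges <- edges[order(edges$source, edges$target), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges$same_side <- logical(0)
    edges$cross_subunit <- logical(0)
    edges$mg_mg <- numeric(0)
  }
  structure(list(nodes = nodes, edges = edges, cutoff = cutoff,
                 strict = strict, chromophores = ch),
            class = "eet_network")
}

#' @export
print.eet_network <- function(x, ...) {
  cat(sprintf("<eet_network> %d chromophores, %d edges (edge-to-edge %s %.1f A)\n",
              nrow(x$nodes), nrow(x$edges), if (x$strict) "<" else "<=",
              x$cutoff))
  invisible(x)
}

#' Closest cross-group chromophore pair
#'
#' @param group_a,group_b lists of `chromophore` (non-overlapping sets).
#' @param side optional side filter applied to both groups.
#' @param exclude chromophore ids (`"chain:resno"`) removed before the search.
#' @return list with `a`, `b` (the chromophores), `edge_to_edge`, `mg_mg`.
#' @export
closest_pair <- function(group_a, group_b, side = NULL, exclude = NULL) {
  ga <- filter_chromophores(group_a, side = side, exclude = exclude)
  gb <- filter_chromophores(group_b, side = side, exclude = exclude)
  if (!length(ga) || !length(gb)) {
    stop("empty chromophore group after filtering")
  }
  best <- Inf
  arg <- c(NA_integer_, NA_integer_)
  for (i in seq_along(ga)) {
    for (j in seq_along(gb)) {
      d <- cpp_min_set_dist(ga[[i]]$macrocycle, gb[[j]]$macrocycle)
      if (d < best - 1e-12) {
        best <- d
        arg <- c(i, j)
      }
    }
  }
  a <- ga[[arg[1]]]; b <- gb[[arg[2]]]
  list(a = a, b = b, edge_to_edge = best,
       mg_mg = if (!is.null(a$metal) && !is.null(b$metal)) {
         vnorm(a$metal - b$metal)
       } else NA_real_)
}

# ---------------------------------------------------------------------------
# Rigid superposition

# Least-squares rotation + translation (Kabsch, via SVD) taking `mobile`
# onto `reference` (rows are points): y = R x + t.
kabsch <- function(mobile, reference) {
  stopifnot(nrow(mobile) == nrow(reference), ncol(mobile) == 3)
  ca <- colMeans(mobile); cb <- colMeans(reference)
  A <- sweep(mobile, 2, ca); B <- sweep(reference, 2, cb)
  H <- crossprod(A, B)   # sum a_c b_c^T
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t <- cb - drop(R %*% ca)
  moved <- sweep(mobile %*% t(R), 2, t, `+`)
  list(rotation = R, translation = t,
       rmsd = sqrt(mean(rowSums((moved - reference)^2))))
}

#' Superpose one model onto another
#'
#' Kabsch least-squares superposition on CA atoms of paired chains. Residues
#' are paired by shared residue numbers; when fewer than 20 match, an
#' ungapped pairing at the offset with maximal overlap is used.
#'
#' @param mobile,reference [molecular_model()] objects.
#' @param chain_pairing named character vector: names are mobile chains,
#'   values the corresponding reference chains.
#' @param atom_selection currently `"ca"`.
#' @return object of class `rigid_transform`: fields `rotation` (3x3),
#'   `translation`, `rmsd`, `n_atoms`.
#' @export
superpose <- function(mobile, reference, chain_pairing,
                      atom_selection = "ca") {
  stopifnot(atom_selection == "ca", length(chain_pairing) >= 1)
  xm <- NULL; xr <- NULL
  for (mc in names(chain_pairing)) {
    tm <- chain_ca_trace(mobile, mc)
    tr <- chain_ca_trace(reference, chain_pairing[[mc]])
    common <- intersect(tm$resno, tr$resno)
    if (length(common) >= 20) {
      xm <- rbind(xm, tm$xyz[match(common, tm$resno), , drop = FALSE])
      xr <- rbind(xr, tr$xyz[match(common, tr$resno), , drop = FALSE])
    } else {
      # ungapped pairing: slide one numbering over the other, keep the
      # offset with the largest overlap
      offs <- range(tr$resno) - rev(range(tm$resno))
      best_o <- NULL; best_n <- 0
      for (o in seq(offs[1], offs[2])) {
        n <- length(intersect(tm$resno + o, tr$resno))
        if (n > best_n) { best_n <- n; best_o <- o }
      }
      if (best_n > 0) {
        common <- intersect(tm$resno + best_o, tr$resno)
        xm <- rbind(xm, tm$xyz[match(common - best_o, tm$resno), , drop = FALSE])
        xr <- rbind(xr, tr$xyz[match(common, tr$resno), , drop = FALSE])
      }
    }
  }
  if (is.null(xm) || nrow(xm) < 20) {
    stop("fewer than 20 matched CA atoms across the chain pairing")
  }
  k <- kabsch(xm, xr)
  structure(list(rotation = k$rotation, translation = k$translation,
                 rmsd = k$rmsd, n_atoms = nrow(xm)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> RMSD %.3f A over %d atoms\n", x$rmsd, x$n_atoms))
  invisible(x)
}

#' Apply a rigid transform
#' @param x a coordinate matrix, [molecular_model()] or chromophore list.
#' @param transform a `rigid_transform` (or list with `rotation`,
#'   `translation`).
#' @return transformed object of the same type.
#' @export
apply_transform <- function(x, transform) {
  R <- transform$rotation; t <- transform$translation
  move <- function(m) sweep(m %*% t(R), 2, t, `+`)
  if (is.matrix(x)) return(move(x))
  if (inherits(x, "molecular_model")) {
    xyz <- move(model_xyz(x))
    x$atoms$x <- xyz[, 1]; x$atoms$y <- xyz[, 2]; x$atoms$z <- xyz[, 3]
    return(x)
  }
  if (inherits(x, "chromophore")) {
    x$macrocycle <- move(x$macrocycle)
    if (!is.null(x$metal)) x$metal <- drop(move(matrix(x$metal, 1)))
    return(x)
  }
  if (is.list(x)) return(lapply(x, apply_transform, transform = transform))
  stop("cannot transform object of class ", paste(class(x), collapse = "/"))
}

#' Chromophore gain/loss accounting between two structures
#'
#' Greedy nearest-metal matching in ascending distance order: each reference
#' chromophore is matched to at most one query chromophore within
#' `match_cutoff` (Mg-Mg, macrocycle centroid when a metal is missing).
#' Unmatched reference chromophores are reported lost, unmatched query
#' chromophores gained. Structures must already be superposed.
#'
#' @param reference,query lists of `chromophore` (already transformed into a
#'   common frame, restricted to the region of interest).
#' @param match_cutoff maximum match distance, Angstrom.
#' @param kinds chromophore kinds considered.
#' @return object of class `gain_loss_report` with data.frames `matched`,
#'   `lost`, `gained`.
#' @export
compare_chromophores <- function(reference, query, match_cutoff = 5,
                                 kinds = c("chl_a", "chl_c")) {
  ref <- filter_chromophores(reference, kinds = kinds)
  qry <- filter_chromophores(query, kinds = kinds)
  if (!length(ref) || !length(qry)) {
    stop("empty chromophore region on ", if (!length(ref)) "reference" else "query")
  }
  anchor <- function(ch) ch$metal %||% colMeans(ch$macrocycle)
  pr <- t(vapply(ref, anchor, numeric(3)))
  pq <- t(vapply(qry, anchor, numeric(3)))
  d <- sqrt(outer(rowSums(pr^2), rep(1, nrow(pq))) +
            outer(rep(1, nrow(pr)), rowSums(pq^2)) - 2 * pr %*% t(pq))
  d[d < 0 | is.nan(d)] <- 0
  cand <- which(d <= match_cutoff, arr.ind = TRUE)
  matched <- data.frame(ref_id = character(), query_id = character(),
                        distance = numeric(), stringsAsFactors = FALSE)
  used_r <- logical(length(ref)); used_q <- logical(length(qry))
  if (nrow(cand)) {
    cand <- cand[order(d[cand]), , drop = FALSE]
    for (r in seq_len(nrow(cand))) {
      i <- cand[r, 1]; j <- cand[r, 2]
      if (used_r[i] || used_q[j]) next
      used_r[i] <- TRUE; used_q[j] <- TRUE
      matched <- rbind(matched, data.frame(
        ref_id = chromophore_id(ref[[i]]), query_id = chromophore_id(qry[[j]]),
        distance = d[i, j], stringsAsFactors = FALSE))
    }
  }
  lost <- chromophore_table(ref[!used_r])
  gained <- chromophore_table(qry[!used_q])
  structure(list(matched = matched, lost = lost, gained = gained,
                 match_cutoff = match_cutoff,
                 n_reference = length(ref), n_query = length(qry)),
            class = "gain_loss_report")
}

#' @export
print.gain_loss_report <- function(x, ...) {
  cat(sprintf("<gain_loss_report> %d matched, %d lost, %d gained (cutoff %.1f A)\n",
              nrow(x$matched), nrow(x$lost), nrow(x$gained), x$match_cutoff))
  invisible(x)
}

#' Gain/loss sensitivity to the match cutoff
#' @param reference,query as in [compare_chromophores()].
#' @param cutoffs cutoffs to sweep, Angstrom.
#' @param kinds chromophore kinds considered.
#' @return data.frame of matched/lost/gained counts per cutoff.
#' @export
gain_loss_sweep <- function(reference, query, cutoffs = 3:7,
                            kinds = c("chl_a", "chl_c")) {
  do.call(rbind, lapply(cutoffs, function(cu) {
    r <- compare_chromophores(reference, query, match_cutoff = cu, kinds = kinds)
    data.frame(match_cutoff = cu, matched = nrow(r$matched),
               lost = nrow(r$lost), gained = nrow(r$gained))
  }))
}

#' Export an EET network
#' @param network an `eet_network`.
#' @param path output path (prefix for `"csv"`).
#' @param format `"json"`, `"graphml"` or `"csv"`.
#' @return path(s) written, invisibly.
#' @export
export_network <- function(network, path, format = c("json", "graphml", "csv")) {
  format <- tryCatch(match.arg(format),
                     error = function(e) stop("unknown network format: ",
                                              format[1]))
  if (format == "json") {
    jsonlite::write_json(list(nodes = network$nodes, edges = network$edges,
                              cutoff = network$cutoff, strict = network$strict),
                         path, digits = NA, auto_unbox = TRUE,
                         dataframe = "columns", na = "null")
    return(invisible(path))
  }
  if (format == "graphml") {
    nodes <- network$nodes
    nodes$id <- seq_len(nrow(nodes))
    return(invisible(write_graphml(nodes, network$edges, path)))
  }
  paths <- paste0(path, c("_nodes.csv", "_edges.csv"))
  write.csv(network$nodes, paths[1], row.names = FALSE)
  write.csv(network$edges, paths[2], row.names = FALSE)
  invisible(paths)
}
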