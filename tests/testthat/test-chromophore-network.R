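# chromophore_network: extraction, distances, EET networks, superposition,
# gain/loss accounting.

single_chl_model <- function(z = 8, kind = "chl_a") {
  ring <- make_macrocycle(c(0, 0, z), kind = kind, chain_id = "P", resno = 401)
  molecular_model("one_chl", ring)
}

test_that("a chlorophyll with Mg at +8 A is extracted as stromal chl_a", {
  ch <- extract_chromophores(single_chl_model(), z_frame())
  expect_length(ch, 1L)
  expect_equal(ch[[1]]$kind, "chl_a")
  expect_equal(ch[[1]]$side, "stromal")
  expect_equal(unname(ch[[1]]$metal), c(0, 0, 8))
})

test_that("models without hetero residues give an empty collection", {
  ch <- extract_chromophores(ideal_helix_model()$model, z_frame())
  expect_length(ch, 0L)
})

test_that("uncatalogued hetero residues are reported, skip list honoured", {
  ring <- make_macrocycle(c(0, 0, 8))
  odd <- ring[1, ]
  odd$residue_name <- "XYZ"; odd$residue_seq <- 900L
  wat <- ring[1, ]
  wat$residue_name <- "HOH"; wat$residue_seq <- 901L; wat$element <- "O"
  m <- molecular_model("mix", rbind(ring, odd, wat))
  ch <- extract_chromophores(m, z_frame())
  expect_length(ch, 1L)
  expect_equal(attr(ch, "uncatalogued"), "XYZ")
})

test_that("a chlorophyll missing its Mg warns and uses the centroid", {
  ring <- make_macrocycle(c(0, 0, 8))
  ring <- ring[ring$atom_name != "MG", ]
  m <- molecular_model("nomg", ring)
  expect_warning(ch <- extract_chromophores(m, z_frame()), "lacks its Mg")
  expect_equal(ch[[1]]$side, "stromal")
  expect_null(ch[[1]]$metal)
})

test_that("the unassigned band around the midplane is respected", {
  ch <- extract_chromophores(single_chl_model(z = 1), z_frame())
  expect_equal(ch[[1]]$side, "unassigned")
  ch2 <- extract_chromophores(single_chl_model(z = -3), z_frame())
  expect_equal(ch2[[1]]$side, "lumenal")
})

test_that("edge_to_edge matches generator placement and refuses self pairs", {
  scene <- default_scene()
  ch <- extract_chromophores(scene$model, scene$truth$frame)
  ids <- vapply(ch, function(c) paste0(c$chain_id, ":", c$residue_seq), "")
  c1 <- ch[[which(ids == "P:401")]]
  c2 <- ch[[which(ids == "P:402")]]
  expect_equal(edge_to_edge(c1, c2), 6.0, tolerance = 1e-3)
  expect_equal(edge_to_edge(c1, c2), edge_to_edge(c2, c1))
  expect_error(edge_to_edge(c1, c1), "self distance")
  # brute-force oracle in plain R
  brute <- min(as.matrix(stats::dist(rbind(c1$macrocycle, c2$macrocycle)))[
    seq_len(nrow(c1$macrocycle)),
    nrow(c1$macrocycle) + seq_len(nrow(c2$macrocycle))])
  expect_equal(edge_to_edge(c1, c2), brute, tolerance = 1e-9)
})

test_that("rings sharing an atom position have edge_to_edge 0", {
  r1 <- make_macrocycle(c(0, 0, 8), resno = 401)
  r2 <- make_macrocycle(c(0, 0, 8), resno = 402)
  m <- molecular_model("coincident", rbind(r1, r2))
  ch <- extract_chromophores(m)
  expect_equal(edge_to_edge(ch[[1]], ch[[2]]), 0)
})

test_that("mg_mg is exact, requires metals, and bounds edge_to_edge", {
  r1 <- make_macrocycle(c(0, 0, 8), resno = 401)
  r2 <- make_macrocycle(c(12, 0, 8), resno = 402)
  m <- molecular_model("pair", rbind(r1, r2))
  ch <- extract_chromophores(m)
  expect_equal(mg_mg(ch[[1]], ch[[2]]), 12, tolerance = 1e-6)
  expect_gte(mg_mg(ch[[1]], ch[[2]]), edge_to_edge(ch[[1]], ch[[2]]))
  nometal <- ch[[1]]
  nometal$metal <- NULL
  expect_error(mg_mg(nometal, ch[[2]]), "requires central metals")
})

test_that("EET networks respect the cutoff and the strict flag", {
  r1 <- make_macrocycle(c(0, 0, 8), resno = 401)
  r2 <- make_macrocycle(c(20 + 2 * 3.45, 0, 8), resno = 402)  # edge-to-edge 20
  m <- molecular_model("far", rbind(r1, r2))
  ch <- extract_chromophores(m, z_frame())
  net <- build_eet_network(ch, cutoff = 15)
  expect_equal(nrow(net$edges), 0L)
  # a pair exactly at the cutoff: included inclusively, dropped strictly
  d <- edge_to_edge(ch[[1]], ch[[2]])
  at_cut <- build_eet_network(ch, cutoff = d)
  expect_equal(nrow(at_cut$edges), 1L)
  strict <- build_eet_network(ch, cutoff = d, strict = TRUE)
  expect_equal(nrow(strict$edges), 0L)
})

test_that("EET network edges equal the brute-force oracle on a scene", {
  scene <- default_scene()
  ch <- extract_chromophores(scene$model, scene$truth$frame)
  net <- build_eet_network(ch, cutoff = 15)
  oracle <- build_eet_network(ch, cutoff = 15, brute_force = TRUE)
  expect_equal(net$edges, oracle$edges)
  # independent R oracle on every pair
  for (i in seq_len(length(ch) - 1)) {
    for (j in seq(i + 1, length(ch))) {
      d <- edge_to_edge(ch[[i]], ch[[j]])
      in_net <- any(net$edges$source == i & net$edges$target == j)
      expect_equal(in_net, d <= 15)
    }
  }
  expect_true(all(net$edges$edge_to_edge <= 15))
  expect_true(all(net$edges$mg_mg >= net$edges$edge_to_edge))
})

test_that("carotenoids are excluded from EET networks by default", {
  r1 <- make_macrocycle(c(0, 0, 8), resno = 401)
  r2 <- make_macrocycle(c(10, 0, 8), resno = 402)
  caro <- make_macrocycle(c(5, 5, 8), resno = 403)
  caro$residue_name <- "BCR"
  m <- molecular_model("withcaro", rbind(r1, r2, caro))
  ch <- extract_chromophores(m, z_frame())
  expect_equal(vapply(ch, `[[`, "", "kind"),
               c("chl_a", "chl_a", "carotenoid"))
  net <- build_eet_network(ch)
  expect_equal(nrow(net$nodes), 2L)
})

test_that("closest_pair finds the minimal cross pair with exclusions", {
  ra <- make_macrocycle(c(0, 0, 8), resno = 401)
  rb1 <- make_macrocycle(c(10, 0, 8), resno = 402)
  rb2 <- make_macrocycle(c(14, 0, 8), resno = 403)
  m <- molecular_model("groups", rbind(ra, rb1, rb2))
  ch <- extract_chromophores(m, z_frame())
  cp <- closest_pair(ch[1], ch[2:3])
  expect_equal(cp$b$residue_seq, 402L)
  expect_equal(cp$edge_to_edge, edge_to_edge(ch[[1]], ch[[2]]))
  cp2 <- closest_pair(ch[1], ch[2:3], exclude = "P:402")
  expect_equal(cp2$b$residue_seq, 403L)
  expect_error(closest_pair(ch[1], ch[2:3], exclude = c("P:402", "P:403")),
               "empty chromophore group")
})

test_that("superpose recovers identity and inverts random rotations", {
  scene <- default_scene()
  pairing <- setNames(model_chains(scene$model), model_chains(scene$model))
  pairing <- pairing[names(pairing) != "P"]
  tr <- superpose(scene$model, scene$model, pairing)
  expect_lt(tr$rmsd, 1e-9)
  expect_equal(tr$rotation, diag(3), tolerance = 1e-9)
  set.seed(17)
  rt <- random_rigid()
  moved <- apply_transform(scene$model, rt)
  back <- superpose(moved, scene$model, pairing)
  expect_lt(back$rmsd, 1e-6)
  restored <- apply_transform(moved, back)
  expect_lt(max(abs(model_xyz(restored) - model_xyz(scene$model))), 1e-6)
})

test_that("superpose needs at least 20 matched CA atoms", {
  tab <- make_helix(10)$atoms
  m <- molecular_model("short", tab)
  expect_error(superpose(m, m, c(A = "A")), "fewer than 20")
})

test_that("superpose pairs renumbered chains by ungapped offset", {
  scene <- default_scene()
  shifted <- scene$model
  shifted$atoms$residue_seq <- shifted$atoms$residue_seq + 500L
  tr <- superpose(shifted, scene$model, c(A = "A"))
  expect_lt(tr$rmsd, 1e-9)
  expect_gte(tr$n_atoms, 20L)
})

test_that("compare_chromophores matches identical regions completely", {
  scene <- default_scene()
  ch <- extract_chromophores(scene$model, scene$truth$frame)
  chl <- filter_chromophores(ch, kinds = c("chl_a", "chl_c"))
  rep <- compare_chromophores(chl, chl)
  expect_equal(nrow(rep$matched), length(chl))
  expect_equal(nrow(rep$lost), 0L)
  expect_equal(nrow(rep$gained), 0L)
})

test_that("deletions and additions are counted exactly", {
  scene <- default_scene()
  ch <- filter_chromophores(extract_chromophores(scene$model,
                                                 scene$truth$frame),
                            kinds = c("chl_a", "chl_c"))
  query <- ch[-(1:2)]  # delete two
  extra_ring <- make_macrocycle(c(30, 30, 10), resno = 990)
  extra <- extract_chromophores(molecular_model("x", extra_ring),
                                scene$truth$frame)
  query <- c(query, extra)
  rep <- compare_chromophores(ch, query)
  expect_equal(nrow(rep$lost), 2L)
  expect_equal(nrow(rep$gained), 1L)
  # conservation: reference = matched + lost; query = matched + gained
  expect_equal(rep$n_reference, nrow(rep$matched) + nrow(rep$lost))
  expect_equal(rep$n_query, nrow(rep$matched) + nrow(rep$gained))
  # partial injection: no chromophore appears twice
  expect_false(anyDuplicated(rep$matched$ref_id) > 0)
  expect_false(anyDuplicated(rep$matched$query_id) > 0)
})

test_that("gain_loss_sweep is monotone in the cutoff", {
  scene <- default_scene()
  ch <- filter_chromophores(extract_chromophores(scene$model,
                                                 scene$truth$frame),
                            kinds = c("chl_a", "chl_c"))
  query <- lapply(ch, function(c) {
    apply_transform(c, list(rotation = diag(3), translation = c(2, 0, 0)))
  })
  sweep_tab <- gain_loss_sweep(ch, query, cutoffs = 3:7)
  expect_equal(sweep_tab$match_cutoff, 3:7)
  expect_true(all(diff(sweep_tab$matched) >= 0))
  expect_equal(sweep_tab$matched + sweep_tab$lost,
               rep(length(ch), 5))
})

test_that("distances are rigid-motion invariant", {
  scene <- default_scene()
  ch <- filter_chromophores(extract_chromophores(scene$model,
                                                 scene$truth$frame),
                            kinds = c("chl_a", "chl_c"))
  d0 <- edge_to_edge(ch[[1]], ch[[2]])
  m0 <- mg_mg(ch[[1]], ch[[2]])
  set.seed(23)
  tr <- random_rigid()
  moved <- apply_transform(ch, tr)
  expect_equal(edge_to_edge(moved[[1]], moved[[2]]), d0, tolerance = 1e-9)
  expect_equal(mg_mg(moved[[1]], moved[[2]]), m0, tolerance = 1e-9)
})

test_that("networks export to JSON, GraphML and CSV", {
  scene <- default_scene()
  ch <- extract_chromophores(scene$model, scene$truth$frame)
  net <- build_eet_network(ch)
  jp <- withr::local_tempfile(fileext = ".json")
  export_network(net, jp, "json")
  payload <- jsonlite::read_json(jp, simplifyVector = TRUE)
  expect_equal(length(payload$edges$source), nrow(net$edges))
  expect_equal(payload$cutoff, 15)
  gp <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, gp, "graphml")
  doc <- xml2::read_xml(gp)
  expect_equal(length(xml2::xml_find_all(doc, "//*[local-name()='edge']")),
               nrow(net$edges))
  cp <- withr::local_tempfile()
  paths <- export_network(net, cp, "csv")
  expect_equal(nrow(read.csv(paths[2])), nrow(net$edges))
  expect_error(export_network(net, jp, "dot"), "unknown network format")
})
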