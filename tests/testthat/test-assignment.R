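# Small helper: run edges + clustering and return the single network.
one_network <- function(tab, residue_set = default_residue_set(),
                        mass_tol = 0.02) {
  cl <- cluster_subgraphs(tab, detect_edges(tab, residue_set, mass_tol))
  expect_length(cl$networks, 1L)
  cl$networks[[1L]]
}

test_that("the reference at 2486.981 matches EEQYNSTYR + N4H3 first", {
  db <- build_candidate_db(c("EEQYNSTYR", "EEQFNSTFR"))
  nw <- list(network_id = 1L, reference_mass = 2486.981)
  m <- match_reference(nw, db)
  expect_gt(nrow(m), 0L)
  expect_equal(m$peptide[1L], "EEQYNSTYR")
  expect_equal(m$composition[1L], "N4H3")
  expect_lt(abs(m$mass_error_da[1L]), 0.001)
})

test_that("a reference with no candidate within tolerance matches nothing", {
  db <- build_candidate_db(c("EEQYNSTYR", "EEQFNSTFR"))
  m <- match_reference(list(network_id = 1L, reference_mass = 1500.0), db)
  expect_equal(nrow(m), 0L)
})

test_that("an equidistant tie is broken toward the smaller composition", {
  db <- data.frame(peptide = "EEQYNSTYR",
                   composition = c("N4H3", "N3H3"),
                   mono_mass = c(2000.00, 2000.04),
                   stringsAsFactors = FALSE)
  m <- match_reference(list(network_id = 1L, reference_mass = 2000.02), db,
                       match_tol = 0.05)
  expect_equal(nrow(m), 2L)
  expect_equal(m$composition[1L], "N3H3")  # 6 residues < 7
})

test_that("a single fucose edge propagates the composition one step", {
  tab <- ladder_table("EEQYNSTYR", c("N4H3", "N4H3F1"))
  nw <- one_network(tab)
  db <- build_candidate_db("EEQYNSTYR")
  acc <- match_reference(nw, db)[1L, ]
  acc$network_id <- nw$network_id
  out <- propagate(tab, nw, acc)
  expect_equal(out$composition, c("N4H3", "N4H3F1"))
  expect_equal(out$status, rep("assigned", 2L))
})

test_that("two agreeing paths across a diamond are not ambiguous", {
  tab <- ladder_table("EEQYNSTYR", c("N4H3", "N4H4", "N4H3F1", "N4H4F1"))
  nw <- one_network(tab)
  acc <- match_reference(nw, build_candidate_db("EEQYNSTYR"))[1L, ]
  out <- propagate(tab, nw, acc)
  expect_equal(sort(out$composition), sort(c("N4H3", "N4H4", "N4H3F1",
                                             "N4H4F1")))
  expect_true(all(out$status == "assigned"))
})

test_that("conflicting path compositions flag the node as ambiguous", {
  # custom residue algebra: delta 200 is one Hex-like unit, but 2 x 100
  # (HexNAc-like) reaches the same node with a different composition
  rs <- data.frame(name = c("R1", "R2"), delta_mass = c(100, 200),
                   rt_window = c(100, 100),
                   hexnac = c(1L, 0L), hex = c(0L, 1L), fuc = 0L,
                   neuac = 0L, neugc = 0L, stringsAsFactors = FALSE)
  tab <- feature_table(neutral_mass = c(1000, 1100, 1200),
                       rt = c(10, 12, 14), intensity = c(1, 1, 1))
  nw <- one_network(tab, residue_set = rs)
  acc <- data.frame(network_id = nw$network_id, peptide = "PEP",
                    composition = "", candidate_mass = 1000,
                    mass_error_da = 0, stringsAsFactors = FALSE)
  out <- propagate(tab, nw, acc, residue_set = rs)
  expect_equal(out$status[out$feature_id == 3L], "ambiguous")
  # node 2 is unambiguous but its nominal residue masses do not explain
  # the observed 100 Da step, so verification flags it
  expect_equal(out$status[out$feature_id == 2L], "mass_inconsistent")
})

test_that("subtraction below zero prunes the path instead of going negative", {
  # reference N2H3 with a downward Fuc edge candidate cannot exist; build
  # an upward chain and check no negative counts ever appear
  sim <- generate_features(fig_fixture_serum_igg(seed = 2))
  fit <- glyconet(sim$features, c("EEQYNSTYR", "EEQFNSTFR"))
  counts <- parse_composition(
    fit$result$assignments$composition[fit$result$assignments$status == "assigned"])
  expect_true(all(counts >= 0L))
})

test_that("accumulated within-tolerance edge errors trip mass verification", {
  base <- glycopeptide_mass("EEQYNSTYR", "N4H3")
  hex <- composition_mass("H1")
  tab <- feature_table(
    neutral_mass = c(base, base + hex + 0.018, base + 2 * hex + 0.036,
                     base + 3 * hex + 0.054),
    rt = c(700, 702, 704, 706), intensity = rep(1, 4))
  nw <- one_network(tab)
  acc <- match_reference(nw, build_candidate_db("EEQYNSTYR"))[1L, ]
  out <- propagate(tab, nw, acc)
  expect_equal(out$status, c("assigned", "assigned", "mass_inconsistent",
                             "mass_inconsistent"))
})

test_that("a match from another network is rejected", {
  tab <- ladder_table("EEQYNSTYR", c("N4H3", "N4H4"))
  nw <- one_network(tab)
  acc <- match_reference(nw, build_candidate_db("EEQYNSTYR"))[1L, ]
  acc$network_id <- 99L
  expect_error(propagate(tab, nw, acc), "does not belong")
})

test_that("auto mode assigns exactly the two planted peptide networks", {
  sim <- generate_features(fig_fixture_serum_igg(seed = 1))
  fit <- glyconet(sim$features, c("EEQYNSTYR", "EEQFNSTFR"))
  expect_equal(fit$counts[["networks"]], 18L)
  expect_equal(nrow(fit$result$accepted), 2L)
  expect_setequal(fit$result$accepted$peptide, c("EEQYNSTYR", "EEQFNSTFR"))
  expect_equal(length(fit$result$unassigned_networks), 16L)
})

test_that("every assigned node satisfies the mass-verification inequality", {
  for (seed in c(1, 6)) {
    sim <- generate_features(fig_fixture_serum_igg(seed = seed))
    fit <- glyconet(sim$features, c("EEQYNSTYR", "EEQFNSTFR"))
    a <- fit$result$assignments
    a <- a[a$status == "assigned", ]
    expected <- glycopeptide_mass(a$peptide, a$composition)
    expect_true(all(abs(a$neutral_mass - expected) <= 0.03))
    expect_equal(unname(residuals(fit)), a$neutral_mass - expected,
                 tolerance = 1e-9)
  }
})

test_that("from-file decisions reproduce auto mode and support rejection", {
  sim <- generate_features(fig_fixture_serum_igg(seed = 1))
  tab <- mass_floor_filter(sim$features,
                           default_mass_floor(c("EEQYNSTYR", "EEQFNSTFR")))
  cl <- cluster_subgraphs(tab, detect_edges(tab))
  db <- build_candidate_db(c("EEQYNSTYR", "EEQFNSTFR"))
  auto <- assign_all(tab, cl, db, mode = "auto")
  dec <- data.frame(network_id = auto$accepted$network_id,
                    accept = paste(auto$accepted$peptide,
                                   auto$accepted$composition, sep = "|"))
  from_file <- assign_all(tab, cl, db, mode = "from-file", decisions = dec)
  expect_equal(from_file$assignments, auto$assignments)
  # rejecting everything yields zero assignments
  dec$accept <- "reject"
  rej <- assign_all(tab, cl, db, mode = "from-file", decisions = dec)
  expect_equal(nrow(rej$assignments), 0L)
  expect_length(rej$unassigned_networks, 18L)
  # a missing decision is an error
  expect_error(assign_all(tab, cl, db, mode = "from-file",
                          decisions = dec[-1L, ]), "no decision")
})

test_that("propagation is independent of node and edge visit order", {
  sim <- generate_features(fig_fixture_serum_igg(seed = 8))
  tab <- mass_floor_filter(sim$features,
                           default_mass_floor(c("EEQYNSTYR", "EEQFNSTFR")))
  db <- build_candidate_db(c("EEQYNSTYR", "EEQFNSTFR"))
  ref <- assign_all(tab, cluster_subgraphs(tab, detect_edges(tab)), db)
  set.seed(99)
  for (k in 1:3) {
    perm <- sample(nrow(tab))
    tab2 <- tab[perm, ]
    out <- assign_all(tab2, cluster_subgraphs(tab2, detect_edges(tab2)), db)
    expect_equal(out$assignments[order(out$assignments$feature_id),
                                 c("feature_id", "peptide", "composition",
                                   "status")],
                 ref$assignments[order(ref$assignments$feature_id),
                                 c("feature_id", "peptide", "composition",
                                   "status")],
                 ignore_attr = TRUE)
  }
})

test_that("assignments agree with a brute-force database search at zero noise", {
  sim <- generate_features(random_spec(17, mass_error_sd = 0))
  fit <- glyconet(sim$features, unique(sim$spec$peptides$sequence))
  got <- fit$result$assignments
  got <- got[got$status == "assigned", c("feature_id", "peptide",
                                         "composition")]
  got <- got[order(got$feature_id), ]
  tab <- mass_floor_filter(sim$features,
                           default_mass_floor(sim$spec$peptides$sequence))
  oracle <- bf_assign(tab, fit$candidate_db)
  expect_equal(got$feature_id, oracle$feature_id)
  expect_equal(got$composition, oracle$composition)
  expect_equal(got$peptide, oracle$peptide)
})
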