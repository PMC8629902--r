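test_that("PDB reading partitions protein and DNA, drops water, reports errors", {
  s0 <- synth_structure_pair(contact_plan(1, "hydrogen_bond"))$reference
  path <- write_structure_pdb(s0, tempfile(fileext = ".pdb"))
  s <- read_structure(path)
  expect_equal(sum(s$atoms$role == "protein"), 1L)
  expect_equal(sum(s$atoms$role == "dna"), 1L)

  lines <- readLines(path)
  water <- "HETATM   99  O   HOH A  50      50.000  50.000  50.000  1.00  0.00           O"
  writeLines(c(lines[-length(lines)], water, "END"), path)
  expect_message(s2 <- read_structure(path), "water")
  expect_equal(nrow(s2$atoms), 2L)

  prot_only <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "END"), prot_only)
  expect_error(read_structure(prot_only), "DNA")
})

test_that("hydrogen bonds respect the distance cutoff", {
  mk <- function(d) {
    s <- synth_structure_pair(contact_plan(1, "hydrogen_bond"))$reference
    s$atoms$z[s$atoms$role == "protein"] <- d
    s
  }
  inside <- detect_contacts(mk(2.9))
  expect_equal(nrow(inside), 1L)
  expect_equal(inside$category, "hydrogen_bond")
  expect_equal(inside$distance, 2.9, tolerance = 1e-9)
  expect_equal(nrow(detect_contacts(mk(3.8))), 0L)
})

test_that("category precedence and planted categories are honoured", {
  plan <- contact_plan(zf = c(1, 2, 3, 5),
                       category = c("hydrogen_bond", "electrostatic",
                                    "hydrophobic", "cation_pi"))
  cc <- detect_contacts(synth_structure_pair(plan)$reference)
  expect_equal(sort(cc$category),
               sort(c("hydrogen_bond", "electrostatic", "hydrophobic",
                      "cation_pi")))
  # a cationic N at H-bond range is classified hydrogen_bond, not electrostatic
  s <- synth_structure_pair(contact_plan(1, "electrostatic"))$reference
  s$atoms$z[s$atoms$role == "protein"] <- 3.2
  cc2 <- detect_contacts(s)
  expect_equal(cc2$category, "hydrogen_bond")
})

test_that("contact sets are invariant under rigid transforms", {
  plan <- contact_plan(zf = c(1, 2, 4, 6),
                       category = c("hydrogen_bond", "electrostatic",
                                    "hydrophobic", "cation_pi"))
  s <- synth_structure_pair(plan)$reference
  a <- detect_contacts(s)
  b <- detect_contacts(transform_structure(s))
  expect_identical(contact_keys(a), contact_keys(b))
  expect_equal(a$distance, b$distance, tolerance = 1e-9)
})

test_that("cell-list search equals the naive all-pairs oracle on random clouds", {
  set.seed(101)
  for (i in 1:20) {
    s <- random_cloud_structure(n_protein = 25, n_dna = 25)
    a <- detect_contacts(s, method = "cell")
    b <- detect_contacts(s, method = "naive")
    expect_identical(contact_keys(a), contact_keys(b))
    expect_equal(a$distance, b$distance, tolerance = 1e-9)
  }
})

test_that("bond tallies keep their accounting invariants", {
  arch <- ctcf_architecture(with_sequence = FALSE)
  empty <- detect_contacts(synth_structure_pair(
    contact_plan(1, "hydrogen_bond"))$reference)[0, ]
  t0 <- per_zf_bond_tally(empty, arch)
  expect_equal(sum(t0$total), 0L)

  plan <- contact_plan(zf = c(2, 2, 2, 5),
                       category = rep("hydrogen_bond", 4))
  cc <- detect_contacts(synth_structure_pair(plan)$reference)
  tal <- per_zf_bond_tally(cc, arch)
  expect_equal(tal$total[2], 3L)
  expect_equal(tal$total[5], 1L)
  expect_equal(sum(tal$total), attr(tal, "grand_total"))
  expect_equal(attr(tal, "grand_total"), nrow(cc))
  # net change against itself is zero everywhere
  nc <- tally_net_change(tal, tal)
  expect_true(all(nc$net_change == 0L))
})

test_that("WT/mutant synthetic pairs reproduce planted bond differences", {
  arch <- ctcf_architecture(with_sequence = FALSE)
  plan <- contact_plan(zf = c(3, 3, 6), category = c("hydrogen_bond",
                                                     "electrostatic",
                                                     "hydrophobic"))
  sp <- synth_structure_pair(plan, lose = c(1, 2),
                             gain = contact_plan(6, "hydrogen_bond"))
  ref <- detect_contacts(sp$reference)
  var <- detect_contacts(sp$variant)
  d <- bond_diff(ref, var)
  expect_equal(nrow(d$lost), 2L)
  expect_equal(nrow(d$gained), 1L)
  expect_length(intersect(contact_keys(d$lost), contact_keys(d$gained)), 0L)
  # losing 2 contacts from ZF3 shows up as net change -2
  nc <- tally_net_change(per_zf_bond_tally(var, arch),
                         per_zf_bond_tally(ref, arch))
  expect_equal(nc$net_change[3], -2L)
  expect_equal(nc$net_change[6], 1L)
})

test_that("bond_diff is antisymmetric and respects set algebra", {
  plan <- contact_plan(zf = c(1, 2, 3), category = rep("hydrogen_bond", 3))
  sp <- synth_structure_pair(plan, gain = contact_plan(c(4, 5),
                                                       rep("hydrophobic", 2)))
  a <- detect_contacts(sp$reference)  # subset of b
  b <- detect_contacts(sp$variant)
  d <- bond_diff(a, b)
  expect_equal(nrow(d$lost), 0L)
  expect_equal(nrow(d$gained), 2L)
  rev <- bond_diff(b, a)
  expect_identical(contact_keys(rev$lost), contact_keys(d$gained))
  expect_identical(contact_keys(rev$gained), contact_keys(d$lost))
  ident <- bond_diff(a, a)
  expect_equal(nrow(ident$lost) + nrow(ident$gained), 0L)
})

test_that("centroid distances are rigid-invariant and net shifts are signed", {
  # two unit point masses 10 A apart
  atoms <- data.frame(eleno = 1:2, elety = c("CA", "P"),
                      element = c("C", "P"), resid = c("ALA", "DT"),
                      resno = c(1L, 1L), chain = c("A", "B"),
                      x = c(0, 10), y = 0, z = 0,
                      role = c("protein", "dna"), stringsAsFactors = FALSE)
  s <- structure(list(atoms = atoms, path = NA), class = "zf_structure")
  expect_equal(centroid_distance(s), 10)
  moved <- transform_structure(s)
  expect_equal(centroid_distance(moved), 10, tolerance = 1e-9)
  # pull the protein 2 A along the inter-centroid axis
  away <- s; away$atoms$x[1] <- -2
  expect_equal(net_shift(away, s), 2.0, tolerance = 1e-12)
  toward <- s; toward$atoms$x[1] <- 2
  expect_equal(net_shift(toward, s), -2.0, tolerance = 1e-12)
  expect_error(centroid_distance(s, protein_resno = 99), "empty selection")
})

test_that("free-energy classification follows the 0.5 kcal/mol thresholds", {
  table1 <- c(12.05, 6.87, 5.00, 5.64, 1.91)
  out <- classify_stability(table1)
  expect_true(all(out$label == "destabilising"))
  expect_equal(classify_stability(0)$label, "neutral")
  expect_equal(classify_stability(0.5)$label, "neutral")
  expect_equal(classify_stability(-0.5)$label, "neutral")
  expect_equal(classify_stability(0.51)$label, "destabilising")
  expect_equal(classify_stability(-0.7)$label, "stabilising")
  expect_error(classify_stability(NaN), "finite")
})
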