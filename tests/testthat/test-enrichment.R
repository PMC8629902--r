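test_that("expected counts are length-proportional and chi-square matches the hand oracle", {
  # two domains of length 50 each, observed 60/40
  doms <- data.frame(name = c("N", "Z"), start = c(1L, 51L),
                     end = c(50L, 100L))
  zf <- zinc_finger(1L, 55L, 58L, 71L, 76L)
  arch <- zf_architecture(100L, doms, list(zf))
  rec <- make_records(c(sprintf("A%dV", sample(1:50, 60, TRUE)),
                        sprintf("A%dV", sample(51:100, 40, TRUE))))
  out <- domain_enrichment(rec, arch)
  expect_equal(out$expected, c(50, 50))
  expect_equal(sum(out$expected), sum(out$observed))
  # 2-cell goodness of fit: (60 vs 50, 40 vs 50)
  expect_equal(out$chi_square[1], chisq_oracle(c(60, 40), c(50, 50)),
               tolerance = 1e-12)
  expect_equal(out$chi_square[1], 4.0, tolerance = 1e-12)
  expect_equal(out$oe_ratio, c(1.2, 0.8))
})

test_that("uniform catalogues give near-unit O/E and record order never matters", {
  arch <- ctcf_architecture()
  set.seed(123)
  rec <- make_records(sprintf("A%dV", sample(arch$protein_length, 10000,
                                             replace = TRUE)))
  out <- domain_enrichment(rec, arch)
  expect_true(all(out$oe_ratio > 0.9 & out$oe_ratio < 1.1))
  # weighted mean of O/E with expected-share weights is exactly 1
  expect_equal(sum(out$oe_ratio * out$expected) / sum(out$expected), 1,
               tolerance = 1e-12)
  shuf <- rec[sample(nrow(rec)), ]
  expect_equal(domain_enrichment(shuf, arch), out)
})

test_that("chi-square equals the sum((O-E)^2/E) oracle on random 2-cell tables", {
  arch <- ctcf_architecture()
  lens <- domain_lengths(arch)
  set.seed(77)
  for (i in 1:25) {
    n <- sample(20:200, 1)
    rec <- make_records(sprintf("A%dV",
                                sample(arch$protein_length, n, TRUE)))
    out <- domain_enrichment(rec, arch)
    for (d in seq_len(nrow(out))) {
      o <- c(out$observed[d], n - out$observed[d])
      e <- c(out$expected[d], n - out$expected[d])
      expect_equal(out$chi_square[d], chisq_oracle(o, e), tolerance = 1e-9)
    }
  }
})

test_that("adding Z-domain mutations raises Z's O/E and lowers the others", {
  arch <- ctcf_architecture()
  base <- make_records(sprintf("A%dV", c(seq(10, 250, by = 16),
                                         seq(270, 570, by = 16),
                                         seq(590, 720, by = 16))))
  more_z <- rbind(base, make_records(sprintf("A%dV", seq(280, 560, by = 8))))
  e1 <- domain_enrichment(base, arch)
  e2 <- domain_enrichment(more_z, arch)
  expect_gt(e2$oe_ratio[e2$domain == "Z"], e1$oe_ratio[e1$domain == "Z"])
  expect_lt(e2$oe_ratio[e2$domain == "N"], e1$oe_ratio[e1$domain == "N"])
  expect_lt(e2$oe_ratio[e2$domain == "C"], e1$oe_ratio[e1$domain == "C"])
})

test_that("per-finger frequencies recover planted placements", {
  arch <- ctcf_architecture()
  # all mutations planted in ZF1 (non-anchor residues)
  zf1 <- arch$zfs[[1]]
  inside <- setdiff(zf1$start:zf1$end, c(zf1$c1, zf1$c2, zf1$h1, zf1$h2))
  rec <- make_records(sprintf("A%dV", rep(inside[1:5], 4)))
  out <- per_zf_frequency(rec, arch)
  expect_equal(out$pct[1], 100)
  expect_equal(sum(out$pct[-1]), 0)
  # 10 per finger -> 1/11 each
  per_zf <- unlist(lapply(arch$zfs, function(z) {
    ok <- setdiff(z$start:z$end, c(z$c1, z$c2, z$h1, z$h2))
    rep(ok[1:5], 2)
  }))
  rec2 <- make_records(sprintf("A%dV", per_zf))
  out2 <- per_zf_frequency(rec2, arch)
  expect_equal(out2$pct, rep(100 / 11, 11), tolerance = 1e-9)
  expect_equal(attr(out2, "mean_pct"), 100 / 11, tolerance = 1e-9)
})

test_that("positional class shares sum to 100 and match an architecture census", {
  arch <- ctcf_architecture()
  # uniform over all Z-domain residues: shares equal residue-class shares
  z <- arch$domains[arch$domains$name == "Z", ]
  rec <- make_records(sprintf("A%dV", z$start:z$end))
  out <- per_position_frequency(rec, arch)
  expect_equal(sum(out$by_class$pct), 100, tolerance = 1e-9)
  census <- table(map_residue(arch, z$start:z$end)$class)
  for (k in out$by_class$class)
    expect_equal(out$by_class$pct[out$by_class$class == k],
                 100 * unname(census[k]) / sum(census), tolerance = 1e-9)
  # a single +6 mutation is 100% key-DNA
  one <- make_records("R339Q")
  expect_equal(per_position_frequency(one, arch)$by_class$pct[
    per_position_frequency(one, arch)$by_class$class == "key_dna"], 100)
})

test_that("planted enrichment multipliers fall inside bootstrap CIs", {
  # a 95% CI misses its target in ~1 replicate of 20, so assert coverage
  # over replicates rather than on a single draw
  arch <- ctcf_architecture()
  cover_z <- 0L; cover_c <- 0L
  for (r in 1:10) {
    rec <- synth_catalog(catalog_spec(arch, n = 2000L,
                                      multipliers = c(N = 1, Z = 1.47, C = 1),
                                      seed = 31L + r))
    ci <- recover_enrichment(rec, arch, n_boot = 100L)
    z <- ci[ci$domain == "Z", ]
    c_ <- ci[ci$domain == "C", ]
    cover_z <- cover_z + (z$lower <= 1.47 && 1.47 <= z$upper)
    cover_c <- cover_c + (c_$lower <= 1.0 && 1.0 <= c_$upper)
  }
  expect_gte(cover_z, 8L)
  expect_gte(cover_c, 8L)
})
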