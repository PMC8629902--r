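test_that("catalogue reading preserves counts and honours strict/permissive modes", {
  df <- data.frame(protein_change = c("R339Q", "T204fs*26", "R457*"),
                   cdna_change = c("c.1016G>A", "c.610del", "c.1369C>T"),
                   tissue = "blood", origin = "somatic")
  path <- write_catalog_tsv(df, tempfile(fileext = ".tsv"))
  rec <- read_catalog(path)
  expect_equal(nrow(rec), 3L)
  expect_equal(attr(rec, "n_read"), 3L)
  expect_equal(rec$variant_class, c("missense", "frameshift", "nonsense"))

  df$protein_change[2] <- "p.Xx204"
  path2 <- write_catalog_tsv(df, tempfile(fileext = ".tsv"))
  expect_error(read_catalog(path2), "row 2")
  rec2 <- suppressMessages(read_catalog(path2, strict = FALSE))
  expect_equal(nrow(rec2), 2L)
  expect_equal(attr(rec2, "rejected")$row, 2L)
})

test_that("column mapping works and a missing required column errors", {
  df <- data.frame(aa_change = c("R339Q", "L309P"), tumour = "ALL")
  path <- write_catalog_tsv(df, tempfile(fileext = ".tsv"))
  rec <- read_catalog(path, mapping = list(protein_change = "aa_change",
                                           tissue = "tumour"))
  expect_equal(rec$tissue, c("ALL", "ALL"))
  expect_error(read_catalog(path), "protein_change")
})

test_that("catalogue round trips through write_catalog/read_catalog", {
  arch <- ctcf_architecture()
  cat_ <- synth_catalog(catalog_spec(arch, n = 40L,
                                     class_mix = c(missense = 0.6,
                                                   nonsense = 0.4),
                                     seed = 3L))
  path <- write_catalog(cat_, tempfile(fileext = ".tsv"))
  back <- read_catalog(path)
  expect_equal(back$protein_change, cat_$protein_change)
  expect_equal(back$variant_class, cat_$variant_class)
})

test_that("recurrence grouping distinguishes residue and allele level", {
  rec <- make_records(c(rep("R339Q", 12), "L309P"))
  out <- recurrence_table(rec, threshold = 10)
  expect_equal(out$site, "R339")
  expect_equal(out$count, 12L)
  expect_equal(nrow(recurrence_table(rec, threshold = 13)), 0L)

  mixed <- make_records(c(rep("R339Q", 6), rep("R339W", 6)))
  expect_equal(recurrence_table(mixed, 10, "residue")$count, 12L)
  expect_equal(nrow(recurrence_table(mixed, 10, "allele")), 0L)
  expect_error(recurrence_table(mixed, threshold = 0), "threshold")
})

test_that("composition proportions sum to one and match direct counts", {
  rec <- make_records(c("R339Q", "G420D", "R457*", "T204fs*26"))
  out <- composition(rec, "variant_class")
  expect_equal(sum(out$proportion), 1, tolerance = 1e-12)
  expect_equal(attr(out, "n"), 4L)
  expect_equal(out$proportion[out$level == "missense"], 0.5)
  expect_equal(out$proportion[out$level == "nonsense"], 0.25)
  expect_equal(out$proportion[out$level == "frameshift"], 0.25)
  expect_error(composition(rec[0, ], "variant_class"), "empty")
})

test_that("20/20 fraction uses strict inequality and is order invariant", {
  rec40 <- make_records(c(rep("R457*", 40), rep("R339Q", 60)))
  out <- twenty_twenty(rec40)
  expect_equal(out$fraction, 0.40)
  expect_true(out$exceeds_rule)
  expect_equal(twenty_twenty(make_records(rep("R339Q", 10)))$fraction, 0)
  boundary <- twenty_twenty(make_records(c(rep("R457*", 20),
                                           rep("R339Q", 80))))
  expect_equal(boundary$fraction, 0.20)
  expect_false(boundary$exceeds_rule)
  shuffled <- rec40[sample(nrow(rec40)), ]
  expect_equal(twenty_twenty(shuffled)$fraction, out$fraction)
})

test_that("Ts/Tv counts exclude non-substitutions and flag the undefined ratio", {
  rec <- make_records(c("R339Q", "R339Q", "R339Q", "T204fs*26"),
                      cdna = c("c.1G>A", "c.2C>T", "c.3G>T", "c.4del"))
  out <- tstv_ratio(rec)
  expect_equal(out$n_transition, 2L)
  expect_equal(out$n_transversion, 1L)
  expect_equal(out$n_excluded, 1L)
  expect_equal(out$ratio, 2.0)
  only_ts <- make_records("R339Q", cdna = "c.1G>A")
  expect_warning(res <- tstv_ratio(only_ts), "undefined")
  expect_true(is.na(res$ratio))
  expect_equal(res$n_transition, 1L)
})

test_that("Ts/Tv chi-square equals the hand oracle and is null on identical mixes", {
  a <- make_records(rep("R339Q", 4), cdna = c("c.1G>A", "c.2G>A",
                                              "c.3G>T", "c.4G>T"))
  b <- make_records(rep("R339Q", 4), cdna = c("c.1C>T", "c.2C>T",
                                              "c.3C>A", "c.4C>A"),
                    origin = "snp")
  out <- compare_tstv(a, b)
  expect_equal(out$chi_square, 0, tolerance = 1e-12)
  expect_equal(out$p_value, 1, tolerance = 1e-12)

  # [[30,10],[20,20]] via planted substitution lists
  a2 <- make_records(rep("R339Q", 40),
                     cdna = c(sprintf("c.%dG>A", 1:30), sprintf("c.%dG>T", 1:10)))
  b2 <- make_records(rep("R339Q", 40),
                     cdna = c(sprintf("c.%dG>A", 1:20), sprintf("c.%dG>T", 1:20)),
                     origin = "snp")
  out2 <- compare_tstv(a2, b2)
  tab <- rbind(c(30, 10), c(20, 20))
  expect_equal(unname(out2$table), tab)
  expect_equal(out2$chi_square, chisq_oracle(tab, contingency_expected(tab)),
               tolerance = 1e-12)
  expect_error(compare_tstv(a2[0, ], b2), "substitution")
})

test_that("Mann-Whitney U equals the pairwise-win enumeration", {
  a <- c(0.9, 0.95, 1.0); b <- c(0.1, 0.15, 0.2)
  out <- compare_impact_scores(a, b)
  expect_equal(out$U, u_oracle(a, b))
  expect_true(out$exact)
  set.seed(11)
  for (i in 1:5) {
    x <- round(runif(6), 3); y <- round(runif(5), 3)
    expect_equal(compare_impact_scores(x, y)$U, u_oracle(x, y))
  }
  same <- compare_impact_scores(c(0.2, 0.5, 0.8), c(0.2, 0.5, 0.8))
  expect_gte(same$p_value, 0.99)
  expect_error(compare_impact_scores(c(0.5, 1.2), c(0.1)), "\\[0, 1\\]")
})
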