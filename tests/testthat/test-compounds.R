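test_that("packaged reference set loads as 31 validated big molecules", {
  p <- fixture_properties
  expect_s3_class(p, "compound_table")
  expect_equal(nrow(p), 31)
  expect_true(all(p$size_class == "big"))
  expect_true(all(p$mw >= 800))
  sp <- big_small_split(p)
  expect_equal(nrow(sp$big), 31)
  expect_equal(nrow(sp$small), 0)
})

test_that("reader enforces schema and flags bad cells and rows", {
  tmp <- tempfile(fileext = ".csv")

  # header-only file: empty table, no error
  writeLines("id,log_s0,mp,clogp,mw", tmp)
  empty <- read_compound_table(tmp)
  expect_equal(nrow(empty), 0)

  # missing required column
  writeLines(c("id,log_s0,mp,clogp", "a,-3,100,2"), tmp)
  expect_error(read_compound_table(tmp), "missing required column.*mw")

  # non-numeric cell names row and column
  writeLines(c("id,log_s0,mp,clogp,mw", "a,-3,oops,2,500"), tmp)
  expect_error(read_compound_table(tmp), "non-numeric.*'oops'.*'mp'.*row 1")

  # invariant-violating row rejected with diagnostic, others kept
  writeLines(c("id,log_s0,mp,clogp,mw",
               "a,-3,100,2,500", "b,-4,120,1,-5"), tmp)
  expect_warning(kept <- read_compound_table(tmp), "rejected 1 row")
  expect_equal(kept$id, "a")
  expect_equal(attr(kept, "rejected")$id, "b")
  expect_match(attr(kept, "rejected")$reason, "mw")

  # schema mapping renames non-canonical headers
  writeLines(c("cmpd,logS,melting,logp,weight", "a,-3,100,2,500"), tmp)
  mapped <- read_compound_table(tmp, schema = c(
    id = "cmpd", log_s0 = "logS", mp = "melting",
    clogp = "logp", mw = "weight"))
  expect_equal(mapped$mw, 500)
})

test_that("count, ionization and descriptor invariants reject rows", {
  base <- data.frame(id = "x", log_s0 = -3, mp = 100, clogp = 2, mw = 500,
                     stringsAsFactors = FALSE)
  expect_warning(as_compound_table(transform(base, nha = -1)), "nha")
  expect_warning(as_compound_table(transform(base, nrot = 2.5)), "nrot")
  expect_warning(as_compound_table(transform(base, ionization = "salt")),
                 "ionization")
  expect_warning(as_compound_table(transform(base, A = -0.1)), "Abraham A")
  expect_warning(as_compound_table(transform(base, V = 0)), "Abraham V")
  ok <- as_compound_table(transform(base, ionization = "ampholyte",
                                    nha = 3, A = 0, V = 1.2))
  expect_equal(nrow(ok), 1)
})

test_that("write/read round-trip preserves every field", {
  tmp <- tempfile(fileext = ".csv")
  write_compound_table(fixture_properties, tmp)
  back <- read_compound_table(tmp)
  orig <- as.data.frame(fixture_properties)
  expect_equal(as.data.frame(back), orig)
})

test_that("big/small partition is exhaustive, disjoint, order-preserving", {
  mix <- toy_compounds(mw = c(799, 800, 1200, 250, 800))
  sp <- big_small_split(mix)
  expect_equal(nrow(sp$big) + nrow(sp$small), nrow(mix))
  expect_length(intersect(sp$big$id, sp$small$id), 0)
  expect_equal(sp$small$mw, c(799, 250))
  expect_equal(sp$big$mw, c(800, 1200, 800))
  none <- big_small_split(mix[0, ])
  expect_equal(nrow(none$big), 0)
  expect_equal(nrow(none$small), 0)
})

test_that("property summaries reproduce the big-set profile", {
  s <- summarize_properties(fixture_properties)
  expect_equal(s$mean_log_s0, -4.52, tolerance = 0.01)
  expect_equal(s$mean_clogp, 3.17, tolerance = 0.01)
  expect_equal(s$mean_mw, 1034, tolerance = 1e-3)
  expect_equal(sum(s$nha_counts), 31)

  # arithmetic oracle: drop the clogP outlier
  no_ubi <- fixture_properties[fixture_properties$id != "ubiquinone", ]
  expect_equal(summarize_properties(no_ubi)$mean_clogp,
               (98.21 - 17.85) / 30, tolerance = 1e-10)

  one <- summarize_properties(fixture_properties[1, ])
  expect_equal(one$mean_clogp, fixture_properties$clogp[1])
  expect_error(summarize_properties(fixture_properties[0, ]), "empty")
})
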