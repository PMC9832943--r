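test_that("parsing a generated design reproduces the manifest ground truth", {
  spec <- fixture_spec(n_assemblies = 4, fragments_per_assembly = 4,
                       seed = 7, strategy = "golden_gate")
  fx <- generate_design(spec, dir = withr::local_tempdir())
  bundle <- parse_design(fx$path, strategy = "golden_gate")

  expect_equal(nrow(bundle$combinations), 4)
  expect_true(all(lengths(bundle$combinations$piece_ids) == 4))
  m <- fx$manifest
  expect_equal(bundle$pcrs$ta_opt, m$pcrs$ta_opt)
  expect_equal(bundle$pcrs$product_length, m$pcrs$product_length)
  expect_equal(bundle$pcrs$template_name, m$pcrs$template_name)
  expect_equal(bundle$oligos$name, m$oligos$name)
  expect_equal(bundle$oligos$anneal_tm, m$oligos$anneal_tm)
  expect_equal(bundle$combinations$piece_ids, m$piece_order)
})

test_that("single-file and split-table round trips are the identity", {
  spec <- fixture_spec(n_assemblies = 3, fragments_per_assembly = 3,
                       seed = 11, delta_policy = "mixed")
  bundle <- parsed_fixture(spec)

  f <- withr::local_tempfile(fileext = ".csv")
  write_design(bundle, f)
  reparsed <- parse_design(f, strategy = bundle$strategy)
  expect_equal(reparsed, bundle)

  d <- withr::local_tempdir()
  write_section_tables(bundle, d)
  reread <- read_section_tables(d, strategy = bundle$strategy)
  expect_equal(reread, bundle)
})

test_that("split tables use the canonical file names and row counts", {
  bundle <- parsed_fixture(fixture_spec(n_assemblies = 2, seed = 3))
  d <- withr::local_tempdir()
  paths <- write_section_tables(bundle, d)
  expect_setequal(basename(unname(paths)),
                  c("oligo.csv", "pcr.csv", "assembly.csv",
                    "combinations.csv"))
  pcr <- readr::read_csv(file.path(d, "pcr.csv"), show_col_types = FALSE)
  expect_equal(nrow(pcr), nrow(bundle$pcrs))
  oligo <- readr::read_csv(file.path(d, "oligo.csv"), show_col_types = FALSE)
  expect_gt(nrow(oligo), 0)
})

test_that("malformed design files raise classed parse errors", {
  bundle <- parsed_fixture(fixture_spec(n_assemblies = 1, seed = 5))
  f <- withr::local_tempfile(fileext = ".csv")
  write_design(bundle, f)
  lines <- readLines(f)

  # drop a whole section
  no_combo <- lines[seq_len(which(trimws(lines) ==
                                    "Combinations of Assembly Pieces") - 1)]
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(no_combo, f2)
  err <- expect_error(parse_design(f2), class = "buildplanr_parse_error")
  expect_match(conditionMessage(err), "Combinations of Assembly Pieces")

  # keep the PCR header row but remove all its data rows
  pcr_at <- which(trimws(lines) == "PCR Reactions")
  piece_at <- which(trimws(lines) == "Assembly Pieces")
  no_pcr_rows <- c(lines[seq_len(pcr_at + 1)], lines[piece_at:length(lines)])
  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(no_pcr_rows, f3)
  err <- expect_error(parse_design(f3), class = "buildplanr_parse_error")
  expect_match(conditionMessage(err), "PCR Reactions")

  # semicolon-delimited headers are rejected
  semi <- gsub(",", ";", lines, fixed = TRUE)
  f4 <- withr::local_tempfile(fileext = ".csv")
  writeLines(semi, f4)
  expect_error(parse_design(f4), class = "buildplanr_parse_error")
})

test_that("unresolvable references raise an error naming the identifier", {
  bundle <- parsed_fixture(fixture_spec(n_assemblies = 1, seed = 9))
  broken <- bundle
  broken$pcrs$fwd_oligo[1] <- "oligo_missing"
  err <- expect_error(
    design_bundle(broken$oligos, broken$pcrs, broken$pieces,
                  broken$combinations, strategy = broken$strategy),
    class = "buildplanr_reference_error")
  expect_match(conditionMessage(err), "oligo_missing")
})

test_that("a blank mean annealing optimum is filled from the two primers", {
  bundle <- parsed_fixture(fixture_spec(n_assemblies = 1, seed = 13))
  tweaked <- bundle$pcrs
  tweaked$ta_opt <- NA_real_
  rebuilt <- design_bundle(bundle$oligos, tweaked, bundle$pieces,
                           bundle$combinations, strategy = bundle$strategy)
  tm <- setNames(bundle$oligos$anneal_tm, bundle$oligos$name)
  expected <- (tm[bundle$pcrs$fwd_oligo] + tm[bundle$pcrs$rev_oligo]) / 2
  expect_equal(rebuilt$pcrs$ta_opt, unname(expected))
})

test_that("validation reports capacity exactly at the 96 boundary", {
  expect_true(validate_design(bundle_with_capacity(96L))$ok)
  rep97 <- validate_design(bundle_with_capacity(97L))
  expect_false(rep97$ok)
  expect_true("capacity" %in% rep97$violations$rule)
  # boundary is exact for another primer/template mix
  expect_true(validate_design(bundle_with_capacity(90L))$ok)
})

test_that("validation reports broken references, lengths and deltas", {
  bundle <- parsed_fixture(fixture_spec(n_assemblies = 2, seed = 21))

  b1 <- bundle
  b1$pieces$source_pcr[1] <- 999L
  rep <- validate_design(b1)
  expect_false(rep$ok)
  expect_true("reference" %in% rep$violations$rule)

  b2 <- bundle
  b2$pcrs$delta[1] <- -0.5
  expect_true("delta" %in% validate_design(b2)$violations$rule)

  b3 <- bundle
  b3$pcrs$product_length[1] <- 0L
  expect_true("length" %in% validate_design(b3)$violations$rule)

  b4 <- bundle
  b4$combinations <- b4$combinations[1, ]
  expect_true("unused_piece" %in% validate_design(b4)$violations$rule)

  # a clean bundle is accepted by every workflow without reference errors
  expect_true(validate_design(bundle)$ok)
  expect_s3_class(build_aqua_workflow(bundle), "run_bundle")
})

test_that("bundle tidiers summarise tables and capacity", {
  bundle <- parsed_fixture(fixture_spec(n_assemblies = 2, seed = 2))
  g <- glance(bundle)
  expect_equal(g$n_pcrs, 8)
  expect_equal(g$primers_plus_templates, 24)
  expect_true(g$valid)
  td <- tidy(bundle)
  expect_equal(sum(td$table == "pcr"), 8)
})
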