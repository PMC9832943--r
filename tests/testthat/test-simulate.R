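small_pcr_run <- function(seed = 41, n_frag = 2, config = run_config()) {
  bundle <- parsed_fixture(fixture_spec(n_assemblies = 1,
                                        fragments_per_assembly = n_frag,
                                        seed = seed, strategy = "pcr_only"))
  build_pcr_workflow(bundle, config)
}

test_that("executing no steps leaves exactly the initial stocks", {
  run <- small_pcr_run()
  empty <- run
  empty$steps <- empty$steps[0, ]
  state <- execute_run(empty)
  expect_equal(length(state$wells), nrow(run$initial_stocks))
  for (i in seq_len(nrow(run$initial_stocks))) {
    s <- run$initial_stocks[i, ]
    w <- state$wells[[paste0(s$slot, ":", s$well)]]
    expect_equal(w$volume_ul, s$volume_ul)
  }
  expect_equal(nrow(state$violations), 0)
})

test_that("a transfer moves volume and proportional amounts", {
  run <- small_pcr_run()
  # first dilution transfer draws primer stock into a working well
  tr <- run$steps[run$steps$type == "transfer" &
                    run$steps$phase == "dilution" &
                    grepl("^oligo_", run$steps$source_item), ][1, ]
  one <- run
  one$steps <- dplyr::mutate(tr, ordinal = 1L)
  state <- execute_run(one)
  dest <- state$wells[[paste0(tr$dest_slot, ":", tr$dest_well)]]
  # 0.5 uL of a 100 uM stock carries 50 pmol
  expect_equal(dest$volume_ul, 0.5)
  expect_equal(unname(dest$amounts[tr$source_item]), 50)
})

test_that("the assembled PCR well matches the printed recipe exactly", {
  run <- small_pcr_run()
  state <- execute_run(run)
  rxn <- run$design$pcrs[1, ]
  comp <- well_composition(state, item = "pcr_1", stage = "pcr_mix")
  expect_equal(comp$volume_ul, 25, tolerance = 1e-12)
  primers <- comp$composition[comp$composition$kind == "primer", ]
  expect_equal(nrow(primers), 2)
  expect_equal(primers$conc, c(0.1, 0.1), tolerance = 1e-9)
  template <- comp$composition[comp$composition$kind == "template", ]
  expect_equal(template$amount, 0.5, tolerance = 1e-9)

  # after digestion the well is 50 uL and the template is destroyed
  post <- well_composition(state, item = "pcr_1")
  expect_equal(post$volume_ul, 50, tolerance = 1e-9)
  tmpl_post <- post$composition[post$composition$kind == "template", ]
  expect_equal(tmpl_post$amount, 0)
})

test_that("full Golden Gate and AQUA runs execute without violations", {
  for (strategy in c("golden_gate", "aqua")) {
    fx <- chromoprotein_like_fixture(dir = withr::local_tempdir(),
                                     strategy = strategy)
    bundle <- parse_design(fx$path, strategy)
    run <- if (strategy == "golden_gate") build_goldengate_workflow(bundle)
      else build_aqua_workflow(bundle)
    state <- execute_run(run)
    expect_equal(nrow(state$violations), 0)
    cons <- check_conservation(state, run$initial_stocks)
    expect_true(cons$ok)
    expect_true(cons$volume_ok)
  }
})

test_that("pooled assembly wells are equimolar within 1 percent", {
  for (strategy in c("golden_gate", "aqua")) {
    fx <- chromoprotein_like_fixture(dir = withr::local_tempdir(),
                                     strategy = strategy)
    bundle <- parse_design(fx$path, strategy)
    run <- if (strategy == "golden_gate") build_goldengate_workflow(bundle)
      else build_aqua_workflow(bundle)
    state <- execute_run(run)
    for (cn in bundle$combinations$construct_name) {
      comp <- well_composition(state, item = paste0("pool_", cn))
      frags <- comp$composition[comp$composition$kind == "fragment", ]
      expect_equal(nrow(frags), 4)
      ratio <- max(frags$pmol) / min(frags$pmol)
      expect_lt(ratio, 1.01)
    }
  }
})

test_that("conservation accounting survives digestion and amplification", {
  run <- small_pcr_run()
  state <- execute_run(run)
  cons <- check_conservation(state, run$initial_stocks)
  expect_true(cons$ok)
  rep <- cons$report
  # digestion destroys the template in the reaction wells; what is left
  # lives only outside the thermocycler (working plate leftovers)
  tmpl <- rep[rep$species == run$design$pcrs$template_name[1], ]
  expect_gt(tmpl$destroyed, 0)
  expect_false(any(startsWith(strsplit(tmpl$wells, ",")[[1]], "7:")))
  # amplified fragments: created during the run, still on deck
  frag <- rep[startsWith(rep$species, "frag_pcr_"), ]
  expect_true(all(frag$created > 0))
})

test_that("a corrupted state is reported with the species named", {
  run <- small_pcr_run()
  state <- execute_run(run)
  victim <- run$design$pcrs$fwd_oligo[1]
  for (k in names(state$wells)) {
    a <- state$wells[[k]]$amounts
    if (victim %in% names(a) && a[[victim]] > 0) {
      state$wells[[k]]$amounts[[victim]] <- a[[victim]] * 2
      break
    }
  }
  cons <- check_conservation(state, run$initial_stocks)
  expect_false(cons$ok)
  bad <- cons$report[!cons$report$ok, ]
  expect_true(victim %in% bad$species)
  expect_true(nzchar(bad$wells[bad$species == victim]))
})

test_that("overdrawing a well records a violation instead of going negative", {
  run <- small_pcr_run()
  i <- which(run$steps$type == "transfer" &
               grepl("^template_", run$steps$source_item))[1]
  run$steps$volume_ul[i] <- run$steps$volume_ul[i] + 1e6
  state <- execute_run(run)
  expect_true("overdraw" %in% state$violations$rule)
  vols <- vapply(state$wells, function(w) w$volume_ul, numeric(1))
  expect_true(all(vols >= -1e-9))
})

test_that("execution is deterministic", {
  run <- small_pcr_run()
  s1 <- execute_run(run)
  s2 <- execute_run(run)
  expect_identical(s1$wells, s2$wells)
  expect_identical(tidy(s1), tidy(s2))
})

test_that("unknown wells raise a classed lookup error", {
  run <- small_pcr_run()
  state <- execute_run(run)
  expect_error(well_composition(state, slot = 3, well = "H12"),
               class = "buildplanr_key_error")
})
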