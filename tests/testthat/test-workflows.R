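chromo_run <- function(strategy = "golden_gate", config = run_config()) {
  fx <- chromoprotein_like_fixture(dir = withr::local_tempdir(),
                                   strategy = strategy)
  bundle <- parse_design(fx$path, strategy = strategy)
  switch(strategy,
         golden_gate = build_goldengate_workflow(bundle, config),
         aqua = build_aqua_workflow(bundle, config))
}

test_that("the PCR workflow mixes five components per reaction well", {
  bundle <- parsed_fixture(fixture_spec(n_assemblies = 1,
                                        fragments_per_assembly = 5,
                                        seed = 23, strategy = "pcr_only"))
  run <- build_pcr_workflow(bundle)
  mixes <- run$steps[run$steps$phase == "pcr_mix", ]
  expect_equal(nrow(mixes), 25)  # 5 wells x 5 components
  per_well <- table(mixes$dest_item)
  expect_equal(unname(as.integer(per_well)), rep(5L, 5))
  expect_equal(sum(mixes$volume_ul[mixes$dest_item == "pcr_1"]), 25,
               tolerance = 1e-12)

  # the external amplification is immediately preceded by a pause
  amp <- which(run$steps$type == "thermocycle" &
                 run$steps$location == "external")
  expect_true(length(amp) >= 1)
  expect_equal(run$steps$type[amp[1] - 1], "pause")

  # digestion can be disabled
  no_dpn <- build_pcr_workflow(bundle, run_config(dpn1 = FALSE))
  expect_false(any(no_dpn$steps$phase == "digestion"))
  expect_true(any(run$steps$phase == "digestion"))
})

test_that("step ordinals increase strictly and sources precede first use", {
  for (run in list(chromo_run("golden_gate"), chromo_run("aqua"))) {
    expect_equal(run$steps$ordinal, seq_len(nrow(run$steps)))
    # executing on the virtual deck proves every source is filled in time
    expect_s3_class(execute_run(run), "sim_state")
  }
})

test_that("the Golden Gate workflow pools, adds enzymes and cycles", {
  run <- chromo_run("golden_gate")
  msgs <- run$steps$message[run$steps$type == "pause"]
  expect_true(any(grepl("clean and concentrate", msgs)))

  pooling <- run$steps[run$steps$phase == "pooling", ]
  frag_adds <- pooling[grepl("^pool_", pooling$dest_item), ]
  expect_equal(nrow(frag_adds), 16)  # 4 pools x 4 fragments
  per_pool <- table(frag_adds$dest_item)
  expect_equal(unname(as.integer(per_pool)), rep(4L, 4))

  mix <- run$steps[run$steps$phase == "assembly_mix", ]
  expect_equal(nrow(mix), 16)  # 4 pools x (buffer, enzyme, ligase, water)
  expect_setequal(unique(mix$source_item),
                  c("ligase_buffer", "bsai", "ligase", "water"))

  gg <- run$steps[run$steps$phase == "assembly" &
                    run$steps$type == "thermocycle", ]
  expect_equal(nrow(gg), 1)
  expect_equal(gg$location, "on_deck")

  ext <- chromo_run("golden_gate", run_config(gg_external_cycler = TRUE))
  gg_ext <- which(ext$steps$phase == "assembly" &
                    ext$steps$type == "thermocycle")
  expect_equal(ext$steps$location[gg_ext], "external")
  expect_equal(ext$steps$type[gg_ext - 1], "pause")
})

test_that("destination-plasmid mode skips backbone amplification", {
  fx <- chromoprotein_like_fixture(dir = withr::local_tempdir())
  bundle <- parse_design(fx$path, "golden_gate")
  backbone <- fx$manifest$backbone_pieces
  cfg <- run_config(destination_piece_ids = backbone)
  run <- build_goldengate_workflow(bundle, cfg)

  # only the four reporter reactions are amplified
  rx <- run$layout$placements[run$layout$placements$kind == "reaction", ]
  expect_equal(nrow(rx), 4)
  backbone_pcrs <- paste0("pcr_", bundle$pieces$source_pcr[
    match(backbone, bundle$pieces$id)])
  expect_false(any(run$steps$dest_item %in% backbone_pcrs))

  # pools draw the backbone from the intact destination stocks
  pooling <- run$steps[run$steps$phase == "pooling", ]
  expect_true(any(grepl("^dest_piece_", pooling$source_item)))
  state <- execute_run(run)
  expect_equal(nrow(state$violations), 0)
})

test_that("one-pot IVA builds a single well per two-fragment combination", {
  bundle <- parsed_fixture(fixture_spec(n_assemblies = 2,
                                        fragments_per_assembly = 2,
                                        seed = 29, strategy = "iva_onepot"))
  run <- build_onepot_iva_workflow(bundle)
  mixes <- run$steps[run$steps$phase == "pcr_mix", ]
  wells <- unique(mixes$dest_item)
  expect_equal(length(wells), 2)
  for (w in wells) {
    sub <- mixes[mixes$dest_item == w, ]
    expect_equal(sum(grepl("_working$", sub$source_item) &
                       grepl("^oligo_", sub$source_item)), 4)
    expect_equal(sum(sub$volume_ul), 25, tolerance = 1e-12)
  }
  expect_true(any(run$steps$type == "message" &
                    grepl("transform", run$steps$message)))
})

test_that("one-pot IVA rejects multi-fragment combinations unless overridden", {
  bundle <- parsed_fixture(fixture_spec(n_assemblies = 1,
                                        fragments_per_assembly = 4,
                                        seed = 31, strategy = "iva_onepot"))
  expect_error(build_onepot_iva_workflow(bundle),
               class = "buildplanr_strategy_error")
  forced <- build_onepot_iva_workflow(
    bundle, run_config(iva_multi_fragment_override = TRUE))
  expect_true(any(forced$steps$type == "message" &
                    grepl("warning", forced$steps$message)))
})

test_that("AQUA pools length-proportional volumes with no enzymes", {
  run <- chromo_run("aqua")
  expect_false(any(run$steps$phase == "assembly_mix"))
  expect_false(any(run$steps$source_item %in%
                     c("ligase", "bsai", "ligase_buffer"), na.rm = TRUE))
  progs <- purrr::map_chr(
    run$steps$program[run$steps$type == "thermocycle"], "label")
  expect_false("golden_gate" %in% progs)
  expect_true(any(run$steps$type == "message" &
                    grepl("transform fragment mixture", run$steps$message)))

  # pooled volumes proportional to piece lengths
  bundle <- run$design
  pooling <- run$steps[run$steps$phase == "pooling" &
                         grepl("^pool_", run$steps$dest_item), ]
  combo <- bundle$combinations[1, ]
  ids <- combo$piece_ids[[1]]
  lens <- bundle$pieces$length[match(ids, bundle$pieces$id)]
  dest <- paste0("pool_", combo$construct_name)
  vols <- pooling$volume_ul[pooling$dest_item == dest]
  ev <- equimolar_volumes(tibble::tibble(id = ids, length = lens))
  expect_equal(vols, ev$volume_ul)

  single <- parsed_fixture(fixture_spec(n_assemblies = 1, seed = 37,
                                        strategy = "aqua"))
  one <- build_aqua_workflow(single)
  expect_equal(sum(one$layout$placements$kind == "pool"), 1)
})

test_that("Golden Gate and AQUA share an identical amplification prefix", {
  dir <- withr::local_tempdir()
  fx <- chromoprotein_like_fixture(dir = dir)
  gg_bundle <- parse_design(fx$path, "golden_gate")
  aq_bundle <- parse_design(fx$path, "aqua")
  gg <- build_goldengate_workflow(gg_bundle)
  aq <- build_aqua_workflow(aq_bundle)
  upto <- function(run) {
    last <- max(which(run$steps$phase %in%
                        c("dilution", "pcr_mix", "amplification",
                          "digestion")))
    tidy(run)[seq_len(last),
              c("type", "phase", "source_item", "dest_item", "volume_ul")]
  }
  expect_equal(upto(gg), upto(aq))
})

test_that("the config snapshot reproduces byte-identical artifacts", {
  run <- chromo_run("golden_gate", run_config(pcr_cycles = 36))
  d1 <- withr::local_tempdir()
  write_run_artifacts(run, d1)

  snap <- jsonlite::read_json(file.path(d1, "runbundle.json"),
                              simplifyVector = TRUE)
  cfg2 <- do.call(run_config, as.list(snap$config_snapshot))
  expect_equal(cfg2$pcr_cycles, 36L)
  run2 <- chromo_run("golden_gate", cfg2)
  d2 <- withr::local_tempdir()
  write_run_artifacts(run2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f), warn = FALSE),
                     readLines(file.path(d2, f), warn = FALSE),
                     label = f)
  }
})

test_that("workflows refuse designs that fail validation", {
  bad <- bundle_with_capacity(97L)
  expect_error(build_aqua_workflow(bad),
               class = "buildplanr_validation_error")
})
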