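chromo_bundle <- function(strategy = "golden_gate") {
  fx <- chromoprotein_like_fixture(dir = withr::local_tempdir(),
                                   strategy = strategy)
  parse_design(fx$path, strategy = strategy)
}

test_that("reaction placements match the gradient tube assignment", {
  bundle <- chromo_bundle()
  cfg <- run_config()
  plan <- plan_gradient(bundle$pcrs)
  layout <- layout_deck(bundle, cfg, plan)
  rx <- layout$placements[layout$placements$kind == "reaction", ]
  expect_equal(nrow(rx), 7)
  expect_true(all(rx$slot == 7L))
  expect_setequal(rx$well, plan$assignments$position)
  for (i in seq_len(nrow(plan$assignments))) {
    item <- paste0("pcr_", plan$assignments$pcr_id[i])
    expect_equal(rx$well[rx$item == item], plan$assignments$position[i])
  }
})

test_that("no two items share a well and pools avoid reaction tubes", {
  bundle <- chromo_bundle()
  layout <- layout_deck(bundle, run_config(), plan_gradient(bundle$pcrs))
  expect_equal(anyDuplicated(layout$placements[c("slot", "well")]), 0)
  pools <- layout$placements[layout$placements$kind == "pool", ]
  expect_equal(nrow(pools), 4)
})

test_that("stocks overflow onto a second tube rack past 24 items", {
  small <- bundle_with_capacity(20L)   # 19 oligos + 1 template
  one_rack <- layout_deck(small, run_config())
  expect_equal(sum(grepl("source stocks", one_rack$slots$label)), 1)

  big <- bundle_with_capacity(26L)     # 25 oligos + 1 template
  two_racks <- layout_deck(big, run_config())
  expect_equal(sum(grepl("source stocks", two_racks$slots$label)), 2)
})

test_that("reagent setup lists every placement once, deterministically", {
  bundle <- chromo_bundle()
  layout <- layout_deck(bundle, run_config(), plan_gradient(bundle$pcrs))
  l1 <- render_reagent_setup(layout)
  l2 <- render_reagent_setup(layout)
  expect_identical(l1, l2)
  body <- l1[!startsWith(l1, "#")]
  expect_equal(length(body), nrow(layout$placements))
  items <- trimws(vapply(strsplit(body, "|", fixed = TRUE), `[`, "", 1))
  expect_setequal(items, layout$placements$item)
  expect_equal(sum(grepl("| template_stock |", body, fixed = TRUE)), 7)
})

test_that("reactions setup lists positions with the hottest at the hot end", {
  rx <- tibble::tibble(id = 1:5, ta_opt = c(58, 58.4, 59.1, 60.2, 64.5),
                       delta = NA_real_)
  plan <- plan_gradient(rx)
  prog <- build_pcr_program(plan, ext_s = 60)
  lines <- render_reactions_setup(plan, prog)
  pos_lines <- grep("^reaction ", lines, value = TRUE)
  expect_equal(length(pos_lines), 5)
  # positions appear in zone order, so the last one is the hottest reaction
  expect_match(pos_lines[5], "pcr_5")
  expect_match(lines[2], "gradient")

  flat <- plan_gradient(tibble::tibble(id = 1:2, ta_opt = c(60, 60),
                                       delta = NA_real_))
  flat_lines <- render_reactions_setup(flat,
                                       build_pcr_program(flat, ext_s = 30))
  expect_match(flat_lines[2], "no gradient")
})

test_that("tracking tables partition items by lifecycle stage", {
  bundle <- chromo_bundle()
  run <- build_goldengate_workflow(bundle)
  rows <- tracking_rows(run)
  d <- withr::local_tempdir()
  paths <- write_tracking_tables(rows, d)
  expect_setequal(names(paths), c("initial", "post_dilution", "post_pcr",
                                  "post_digest", "post_assembly"))
  post_dil <- readr::read_csv(paths[["post_dilution"]],
                              show_col_types = FALSE)
  # working-primer wells carry the derived 2.5 uM working concentration
  primer_rows <- post_dil[grepl("^oligo_.*_working$", post_dil$item), ]
  expect_equal(nrow(primer_rows), 14)
  expect_equal(unique(primer_rows$conc_value),
               plan_primer_dilution()$working_conc, tolerance = 1e-9)
  template_rows <- post_dil[grepl("^template_.*_working$", post_dil$item), ]
  expect_equal(unique(template_rows$conc_value), 0.5, tolerance = 1e-9)

  post_pcr <- readr::read_csv(paths[["post_pcr"]], show_col_types = FALSE)
  expect_equal(nrow(post_pcr), 7)
  expect_equal(unique(post_pcr$volume_ul), 25, tolerance = 1e-9)
  post_digest <- readr::read_csv(paths[["post_digest"]],
                                 show_col_types = FALSE)
  expect_equal(unique(post_digest$volume_ul), 50, tolerance = 1e-9)

  # determinism: rebuilding the run writes byte-identical tables
  d2 <- withr::local_tempdir()
  write_tracking_tables(tracking_rows(build_goldengate_workflow(bundle)), d2)
  for (st in names(paths)) {
    expect_identical(readLines(paths[[st]]),
                     readLines(file.path(d2, basename(paths[[st]]))))
  }
})
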