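# Deck and labware model: deterministic placement of stocks, working
# dilutions, reactions and assembly pools, plus rendering of the
# operator instruction files and item-tracking tables.

LABWARE_DIMS <- list(
  tube_rack_24 = c(rows = 4L, cols = 6L),
  plate_96 = c(rows = 8L, cols = 12L),
  thermocycler = c(rows = 8L, cols = 12L),
  tip_rack = c(rows = 8L, cols = 12L)
)

THERMOCYCLER_SLOT <- 7L
# remaining addressable deck slots, allocated in this order
FREE_SLOTS <- c(1L, 2L, 3L, 4L, 5L, 6L, 9L, 10L, 11L)

labware_capacity <- function(type) {
  d <- LABWARE_DIMS[[type]]
  unname(d["rows"] * d["cols"])
}

labware_wells <- function(type) {
  d <- LABWARE_DIMS[[type]]
  wells_column_major(d[["rows"]], d[["cols"]])
}

# which PCR reactions actually run (destination-plasmid pieces are
# supplied intact, so reactions used only by those pieces are skipped)
active_pcr_ids <- function(bundle, config) {
  dest <- config$destination_piece_ids
  live_pieces <- bundle$pieces[!bundle$pieces$id %in% dest, ]
  if (bundle$strategy == "pcr_only") return(bundle$pcrs$id)
  sort(unique(live_pieces$source_pcr))
}

#' Lay out the deck for a design
#'
#' Produces a deterministic placement of every physical item: template
#' and primer stocks fill 24-tube racks in bundle order (wells A1-D6,
#' column-major, extra racks allocated as needed), working dilutions
#' fill a 96-well plate in the same order, reagents (master mix, water,
#' digestion and assembly enzymes as the strategy requires) occupy their
#' own tube rack, and reactions sit in thermocycler wells at the
#' gradient plan's tube positions. Golden Gate and AQUA strategies also
#' reserve one pool well per combination (first free thermocycler wells)
#' and predilution wells on the working plate for fragments whose
#' equimolar addition would fall below the minimum pipettable volume.
#'
#' @param bundle a validated `design_bundle`.
#' @param config a [run_config()].
#' @param plan a `gradient_plan` giving reaction tube positions; when
#'   `NULL`, reactions are not placed.
#' @return a `deck_layout`: list with `slots` (tibble: `slot`, `type`,
#'   `label`) and `placements` (tibble: `item`, `kind`, `slot`, `well`).
#' @export
layout_deck <- function(bundle, config = run_config(), plan = NULL) {
  slots <- tibble::tibble(slot = THERMOCYCLER_SLOT, type = "thermocycler",
                          label = "thermocycler module")
  free <- FREE_SLOTS
  placements <- list()
  add_place <- function(item, kind, slot, well) {
    placements[[length(placements) + 1]] <<-
      tibble::tibble(item = item, kind = kind, slot = slot, well = well)
  }
  take_slot <- function(type, label) {
    if (length(free) == 0) {
      stop_buildplanr("buildplanr_layout_error", "no free deck slots left")
    }
    s <- free[1]; free <<- free[-1]
    slots <<- dplyr::bind_rows(slots,
                               tibble::tibble(slot = s, type = type,
                                              label = label))
    s
  }

  active <- active_pcr_ids(bundle, config)
  pcrs <- bundle$pcrs[bundle$pcrs$id %in% active, ]
  templates <- unique(pcrs$template_name)
  primers <- unique(c(rbind(pcrs$fwd_oligo, pcrs$rev_oligo)))

  # source stocks on 24-tube racks, templates first then primers
  stock_items <- c(templates, primers)
  stock_kinds <- c(rep("template_stock", length(templates)),
                   rep("primer_stock", length(primers)))
  rack_wells <- labware_wells("tube_rack_24")
  n_racks <- ceiling(length(stock_items) / labware_capacity("tube_rack_24"))
  rack_slots <- vapply(seq_len(n_racks), function(i) {
    take_slot("tube_rack_24", sprintf("source stocks rack %d", i))
  }, integer(1))
  for (i in seq_along(stock_items)) {
    r <- ((i - 1L) %/% 24L) + 1L
    add_place(stock_items[i], stock_kinds[i], rack_slots[r],
              rack_wells[((i - 1L) %% 24L) + 1L])
  }

  # reagent rack
  reagents <- c("master_mix", "water")
  if (isTRUE(config$dpn1)) reagents <- c(reagents, "rcutsmart_buffer", "dpn1")
  if (bundle$strategy == "golden_gate") {
    reagents <- c(reagents, "ligase_buffer", "bsai", "ligase")
  }
  dest <- config$destination_piece_ids
  dest_items <- if (length(dest) > 0) sprintf("dest_piece_%d", dest)
    else character(0)
  reagent_items <- c(reagents, dest_items)
  reagent_kinds <- c(rep("reagent", length(reagents)),
                     rep("destination_stock", length(dest_items)))
  rs <- take_slot("tube_rack_24", "reagents rack")
  for (i in seq_along(reagent_items)) {
    add_place(reagent_items[i], reagent_kinds[i], rs, rack_wells[i])
  }

  # working dilution plate, same order as the stock tubes
  plate_wells <- labware_wells("plate_96")
  ps <- take_slot("plate_96", "working dilution plate")
  working_items <- paste0(stock_items, "_working")
  if (length(working_items) > 96) {
    stop_buildplanr("buildplanr_layout_error",
                    "more than 96 working dilutions")
  }
  for (i in seq_along(working_items)) {
    add_place(working_items[i], "working_dilution", ps, plate_wells[i])
  }
  next_plate_well <- length(working_items) + 1L

  # reactions at the gradient plan's tube positions
  if (!is.null(plan)) {
    a <- plan$assignments
    items <- if (bundle$strategy == "iva_onepot") {
      paste0("onepot_", bundle$combinations$construct_name[a$pcr_id])
    } else {
      paste0("pcr_", a$pcr_id)
    }
    for (i in seq_len(nrow(a))) {
      add_place(items[i], "reaction", THERMOCYCLER_SLOT, a$position[i])
    }
  }

  # pool wells and fragment predilution wells
  if (bundle$strategy %in% c("golden_gate", "aqua")) {
    used <- if (!is.null(plan)) plan$assignments$position else character(0)
    tc_free <- setdiff(labware_wells("thermocycler"), used)
    if (nrow(bundle$combinations) > length(tc_free)) {
      stop_buildplanr("buildplanr_layout_error",
                      "not enough thermocycler wells for assembly pools")
    }
    for (i in seq_len(nrow(bundle$combinations))) {
      add_place(paste0("pool_", bundle$combinations$construct_name[i]),
                "pool", THERMOCYCLER_SLOT, tc_free[i])
    }
    # predilution wells for any fragment pooled below the minimum volume
    predil <- character(0)
    for (i in seq_len(nrow(bundle$combinations))) {
      ids <- bundle$combinations$piece_ids[[i]]
      lens <- bundle$pieces$length[match(ids, bundle$pieces$id)]
      ev <- equimolar_volumes(tibble::tibble(id = ids, length = lens),
                              ref_volume = config$ref_pool_volume_ul,
                              min_pipette = config$min_pipette_ul)
      predil <- c(predil, sprintf("frag_%d_predil", ev$id[ev$prediluted]))
    }
    for (p in unique(predil)) {
      if (next_plate_well > 96) {
        stop_buildplanr("buildplanr_layout_error",
                        "working plate full: no well for predilution")
      }
      add_place(p, "predilution", ps, plate_wells[next_plate_well])
      next_plate_well <- next_plate_well + 1L
    }
  }

  placements <- dplyr::bind_rows(placements)
  if (anyDuplicated(placements[c("slot", "well")]) > 0) {
    stop_buildplanr("buildplanr_layout_error", "well double-booked")
  }
  structure(list(slots = slots, placements = placements,
                 free_slots = free),
            class = "deck_layout")
}

#' Append tip racks to a layout
#'
#' One 96-tip rack is allocated per 96 transfers, on the remaining free
#' slots.
#'
#' @param layout a `deck_layout`.
#' @param n_transfers number of pipetting steps in the run.
#' @return the layout with tip-rack slots added.
#' @export
allocate_tip_racks <- function(layout, n_transfers) {
  n <- max(1L, ceiling(n_transfers / 96))
  free <- layout$free_slots
  for (i in seq_len(n)) {
    if (length(free) == 0) {
      stop_buildplanr("buildplanr_layout_error",
                      "no free deck slots left for tip racks")
    }
    layout$slots <- dplyr::bind_rows(
      layout$slots,
      tibble::tibble(slot = free[1], type = "tip_rack",
                     label = sprintf("tip rack %d", i)))
    free <- free[-1]
  }
  layout$free_slots <- free
  layout
}

#' @export
print.deck_layout <- function(x, ...) {
  cat(sprintf("<deck_layout> %d labware, %d placements\n",
              nrow(x$slots), nrow(x$placements)))
  print(x$slots, ...)
  invisible(x)
}

lookup_place <- function(layout, item) {
  i <- match(item, layout$placements$item)
  if (is.na(i)) {
    stop_buildplanr("buildplanr_layout_error",
                    sprintf("item not placed: %s", item))
  }
  list(slot = layout$placements$slot[i], well = layout$placements$well[i])
}

order_placements <- function(placements) {
  rc <- purrr::map(placements$well, split_well)
  ord <- order(placements$slot,
               purrr::map_int(rc, "col"), purrr::map_int(rc, "row"))
  placements[ord, ]
}

#' Render the reagent-setup instruction file
#'
#' One line per placed item, `item | kind | slot | well | required
#' volume`, ordered by slot then well (column-major), so repeated runs
#' on the same input are byte-identical.
#'
#' @param layout a `deck_layout`.
#' @param required named numeric vector or tibble (`item`, `volume_ul`)
#'   of volumes the operator must provide; items without an entry print
#'   `"-"`.
#' @param file output path; `NULL` returns the lines invisibly without
#'   writing.
#' @return invisibly, the rendered lines.
#' @export
render_reagent_setup <- function(layout, required = NULL, file = NULL) {
  req <- numeric(0)
  if (is.data.frame(required)) {
    req <- stats::setNames(required$volume_ul, required$item)
  } else if (!is.null(required)) {
    req <- required
  }
  pl <- order_placements(layout$placements)
  vol <- ifelse(pl$item %in% names(req),
                paste0(fmt_num(unname(req[pl$item])), " uL"), "-")
  lines <- c(
    "# reagent_setup: place each item at the listed deck position",
    sprintf("# labware: %s",
            paste(sprintf("slot %d = %s", layout$slots$slot,
                          layout$slots$label), collapse = "; ")),
    sprintf("%s | %s | %d | %s | %s", pl$item, pl$kind, pl$slot, pl$well, vol)
  )
  if (!is.null(file)) readr::write_lines(lines, file)
  invisible(lines)
}

#' Render the reactions-setup instruction file
#'
#' Lists each reaction's tube position and zone temperature in the
#' gradient block, then the full thermocycler program (endpoints and
#' step table) for the operator to key into the external gradient
#' cycler.
#'
#' @param plan a `gradient_plan` with tube positions assigned.
#' @param program the amplification `thermo_program`.
#' @param file output path; `NULL` returns lines invisibly.
#' @return invisibly, the rendered lines.
#' @export
render_reactions_setup <- function(plan, program, file = NULL) {
  a <- plan$assignments[order(plan$assignments$zone,
                              plan$assignments$pcr_id), ]
  flat <- plan$t_high == plan$t_low
  header <- if (flat) {
    sprintf("# annealing temperature %s degC (no gradient needed)",
            fmt_num(plan$t_low, 1))
  } else {
    sprintf("# gradient %s-%s degC across %d columns (cold left, hot right)",
            fmt_num(plan$t_low, 1), fmt_num(plan$t_high, 1),
            plan$geometry$n_zones)
  }
  pos_lines <- sprintf(
    "reaction pcr_%d | tube %s | zone %d at %s degC | optimum %s degC | deviation %s degC",
    a$pcr_id, a$position, a$zone, fmt_num(round_tenth(a$zone_temp), 1),
    fmt_num(a$ta_opt, 1), fmt_num(a$deviation, 3))
  prog_lines <- c(sprintf("# program: %s", program$label))
  for (i in seq_len(nrow(program$steps))) {
    s <- program$steps[i, ]
    temp <- if (s$temp_low_c == s$temp_high_c) {
      sprintf("%s degC", fmt_num(s$temp_low_c, 1))
    } else {
      sprintf("gradient %s-%s degC", fmt_num(s$temp_low_c, 1),
              fmt_num(s$temp_high_c, 1))
    }
    tag <- if (!is.null(program$cycled) && i >= program$cycled[1] &&
               i <= program$cycled[2]) {
      sprintf(" | cycled x%d", program$cycled[3])
    } else ""
    prog_lines <- c(prog_lines,
                    sprintf("step %d | %s | %s s%s", i, temp,
                            fmt_num(s$duration_s, 0), tag))
  }
  lines <- c("# reactions_setup: arrange PCR tubes in the gradient block",
             header, pos_lines, prog_lines)
  if (!is.null(file)) readr::write_lines(lines, file)
  invisible(lines)
}

#' Write per-stage item tracking tables
#'
#' One CSV per lifecycle stage (`tracking_<stage>.csv`), each holding
#' the items alive at that stage with their location, concentration and
#' volume, in deterministic (slot, well column-major, item) order.
#'
#' @param rows tibble with columns `item`, `kind`, `slot`, `well`,
#'   `conc_value`, `conc_unit`, `volume_ul`, `stage`.
#' @param out_dir output directory.
#' @return invisibly, a named character vector of file paths.
#' @export
write_tracking_tables <- function(rows, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) {
    stop_buildplanr("buildplanr_io_error",
                    sprintf("cannot create directory: %s", out_dir))
  }
  paths <- character(0)
  for (st in unique(rows$stage)) {
    sub <- rows[rows$stage == st, ]
    rc <- purrr::map(sub$well, split_well)
    sub <- sub[order(sub$slot, purrr::map_int(rc, "col"),
                     purrr::map_int(rc, "row"), sub$item), ]
    sub$stage <- NULL
    p <- file.path(out_dir, sprintf("tracking_%s.csv", st))
    readr::write_csv(sub, p, na = "", progress = FALSE)
    paths[st] <- p
  }
  invisible(paths)
}
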