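# End-to-end builders: compose the gradient planner, stoichiometry and
# deck layout into an ordered, machine-checkable run bundle per assembly
# strategy. A run bundle is a flat table of steps (liquid transfers,
# operator pauses, thermocycler runs, messages) plus everything needed
# to execute it on the virtual deck or render operator artifacts.

empty_steps <- function() {
  tibble::tibble(
    ordinal = integer(0), type = character(0), phase = character(0),
    source_item = character(0), source_slot = integer(0),
    source_well = character(0), dest_item = character(0),
    dest_slot = integer(0), dest_well = character(0),
    volume_ul = numeric(0), mix_reps = integer(0), mix_vol_ul = numeric(0),
    below_min = logical(0), message = character(0), location = character(0),
    program = list(), wells = list(), spawn = list()
  )
}

new_builder <- function(layout, config) {
  env <- new.env(parent = emptyenv())
  env$rows <- list()
  env$layout <- layout
  env$config <- config
  env
}

b_add <- function(b, type, phase, source_item = NA_character_,
                  dest_item = NA_character_, volume_ul = NA_real_,
                  mix_reps = NA_integer_, mix_vol_ul = NA_real_,
                  message = NA_character_, location = NA_character_,
                  program = NULL, wells = NULL, spawn = NULL,
                  flag_min = TRUE) {
  src <- if (!is.na(source_item)) lookup_place(b$layout, source_item) else
    list(slot = NA_integer_, well = NA_character_)
  dst <- if (!is.na(dest_item)) lookup_place(b$layout, dest_item) else
    list(slot = NA_integer_, well = NA_character_)
  below <- type == "transfer" && flag_min && !is.na(volume_ul) &&
    volume_ul < b$config$min_pipette_ul - 1e-12
  b$rows[[length(b$rows) + 1]] <- tibble::tibble(
    ordinal = length(b$rows) + 1L, type = type, phase = phase,
    source_item = source_item, source_slot = src$slot,
    source_well = src$well, dest_item = dest_item, dest_slot = dst$slot,
    dest_well = dst$well, volume_ul = volume_ul,
    mix_reps = mix_reps, mix_vol_ul = mix_vol_ul,
    below_min = below, message = message, location = location,
    program = list(program), wells = list(wells), spawn = list(spawn)
  )
  invisible(b)
}

b_transfer <- function(b, phase, from, to, volume, mix_reps = NA_integer_,
                       mix_vol = NA_real_, flag_min = TRUE) {
  if (volume <= 1e-12) return(invisible(b))  # zero fillers are dropped
  b_add(b, "transfer", phase, source_item = from, dest_item = to,
        volume_ul = volume, mix_reps = mix_reps, mix_vol_ul = mix_vol,
        flag_min = flag_min)
}

b_pause <- function(b, phase, message) {
  b_add(b, "pause", phase, message = message)
}

b_message <- function(b, phase, message) {
  b_add(b, "message", phase, message = message)
}

b_thermocycle <- function(b, phase, program, location, wells,
                          spawn = NULL) {
  b_add(b, "thermocycle", phase, location = location, program = program,
        wells = wells, spawn = spawn)
}

ensure_valid <- function(bundle) {
  rep <- validate_design(bundle)
  if (!rep$ok) {
    v <- rep$violations[1, ]
    stop_buildplanr(
      "buildplanr_validation_error",
      sprintf("design fails validation (%d violation(s)); first: [%s] %s: %s",
              nrow(rep$violations), v$rule, v$item, v$detail),
      report = rep
    )
  }
  invisible(bundle)
}

species_registry <- function(bundle, config) {
  active <- active_pcr_ids(bundle, config)
  pcrs <- bundle$pcrs[bundle$pcrs$id %in% active, ]
  primers <- unique(c(rbind(pcrs$fwd_oligo, pcrs$rev_oligo)))
  templates <- unique(pcrs$template_name)
  frag <- tibble::tibble(
    species = paste0("frag_pcr_", pcrs$id), kind = "fragment",
    length_bp = pcrs$product_length, unit = "ng"
  )
  dest <- config$destination_piece_ids
  dest_tbl <- if (length(dest) > 0) {
    tibble::tibble(
      species = sprintf("dest_piece_%d", dest), kind = "fragment",
      length_bp = bundle$pieces$length[match(dest, bundle$pieces$id)],
      unit = "ng")
  } else NULL
  dplyr::bind_rows(
    tibble::tibble(species = primers, kind = "primer",
                   length_bp = NA_integer_, unit = "pmol"),
    tibble::tibble(species = templates, kind = "template",
                   length_bp = NA_integer_, unit = "ng"),
    frag, dest_tbl,
    tibble::tibble(
      species = c("master_mix", "water", "rcutsmart_buffer", "dpn1",
                  "ligase_buffer", "bsai", "ligase"),
      kind = "reagent", length_bp = NA_integer_, unit = "uL")
  )
}

# fragment species for a piece id (destination pieces keep their own stock)
piece_species <- function(bundle, config, piece_id) {
  if (piece_id %in% config$destination_piece_ids) {
    sprintf("dest_piece_%d", piece_id)
  } else {
    paste0("frag_pcr_",
           bundle$pieces$source_pcr[match(piece_id, bundle$pieces$id)])
  }
}

# well item holding a piece's DNA at pooling time
piece_source_item <- function(bundle, config, piece_id, predil_items) {
  sp <- sprintf("frag_%d_predil", piece_id)
  if (sp %in% predil_items) return(sp)
  if (piece_id %in% config$destination_piece_ids) {
    return(sprintf("dest_piece_%d", piece_id))
  }
  paste0("pcr_", bundle$pieces$source_pcr[match(piece_id, bundle$pieces$id)])
}

# Shared amplification prefix: working dilutions, reaction mixes, pause,
# external gradient amplification, optional template-removal digestion.
# Used verbatim by the separate-PCR strategies so their step prefixes are
# identical by construction.
build_pcr_prefix <- function(b, bundle, config, plan) {
  layout <- b$layout
  active <- active_pcr_ids(bundle, config)
  pcrs <- bundle$pcrs[bundle$pcrs$id %in% active, ]
  templates <- unique(pcrs$template_name)
  primers <- unique(c(rbind(pcrs$fwd_oligo, pcrs$rev_oligo)))

  primer_dil <- plan_primer_dilution(
    stock_conc = config$primer_stock_um,
    final_conc = config$primer_final_um, rxn_volume = 25,
    add_volume = config$primer_add_ul,
    working_volume = config$working_volume_ul)
  template_dil <- plan_template_dilution(
    stock_conc = config$template_stock_ng_ul,
    target_mass = config$template_target_ng,
    add_volume = config$template_add_ul,
    working_volume = config$working_volume_ul,
    rxn_volume = 25)

  # working dilutions, templates first then primers (stock-tube order)
  for (tm in templates) {
    if (!template_dil$pass_through) {
      b_transfer(b, "dilution", tm, paste0(tm, "_working"),
                 template_dil$source_volume_ul)
      b_transfer(b, "dilution", "water", paste0(tm, "_working"),
                 template_dil$diluent_volume_ul,
                 mix_reps = 3L, mix_vol = 10, flag_min = FALSE)
    }
  }
  for (pr in primers) {
    b_transfer(b, "dilution", pr, paste0(pr, "_working"),
               primer_dil$source_volume_ul)
    b_transfer(b, "dilution", "water", paste0(pr, "_working"),
               primer_dil$diluent_volume_ul,
               mix_reps = 3L, mix_vol = 10, flag_min = FALSE)
  }

  # reaction mixes at the gradient tube positions
  scale <- config$rxn_volume_ul / 25
  for (i in seq_len(nrow(pcrs))) {
    rxn <- pcrs[i, ]
    dest <- paste0("pcr_", rxn$id)
    mix <- build_pcr_mix(rxn, config)
    sources <- c(
      "master_mix",
      paste0(rxn$fwd_oligo, "_working"),
      paste0(rxn$rev_oligo, "_working"),
      if (template_dil$pass_through) rxn$template_name
        else paste0(rxn$template_name, "_working"),
      "water")
    vols <- mix$volume_ul
    if (template_dil$pass_through) {
      # stock used directly: adjusted add volume, water absorbs the rest
      vols[4] <- template_dil$add_volume_ul * scale
      vols[5] <- config$rxn_volume_ul - sum(vols[1:4])
      if (vols[5] < -1e-9) {
        stop_buildplanr("buildplanr_mix_error",
                        "overfull: components exceed the reaction volume")
      }
    }
    for (k in seq_along(sources)) {
      b_transfer(b, "pcr_mix", sources[k], dest, vols[k],
                 mix_reps = if (k == length(sources)) 3L else NA_integer_,
                 mix_vol = if (k == length(sources)) 10 else NA_real_)
    }
  }

  ext_s <- extension_time(pcrs$product_length,
                          rate_s_per_kb = config$ext_rate_s_per_kb,
                          rounding = config$ext_round_s,
                          floor = config$ext_floor_s)
  program <- build_pcr_program(plan, ext_s, n_cycles = config$pcr_cycles,
                               final_ext_s = config$final_ext_s)
  rxn_items <- paste0("pcr_", pcrs$id)
  rxn_wells <- purrr::map(rxn_items, ~ lookup_place(layout, .x))
  spawn <- tibble::tibble(
    item = rxn_items,
    species = paste0("frag_pcr_", pcrs$id),
    conc_ng_ul = config$frag_yield_ng_ul
  )
  b_pause(b, "amplification",
          "transfer reactions to the gradient thermocycler")
  b_thermocycle(b, "amplification", program, "external",
                wells = rxn_items, spawn = spawn)

  if (isTRUE(config$dpn1)) {
    dmix <- build_dpn1_mix(config$rxn_volume_ul, config)
    for (i in seq_len(nrow(pcrs))) {
      dest <- paste0("pcr_", pcrs$id[i])
      for (k in seq_len(nrow(dmix))) {
        b_transfer(b, "digestion", dmix$source_item[k], dest,
                   dmix$volume_ul[k],
                   mix_reps = if (k == nrow(dmix)) 3L else NA_integer_,
                   mix_vol = if (k == nrow(dmix)) 10 else NA_real_)
      }
    }
    b_thermocycle(b, "digestion", build_dpn1_program(), "on_deck",
                  wells = rxn_items)
  }
  list(ext_s = ext_s, program = program, rxn_items = rxn_items)
}

finish_run <- function(b, bundle, config, plan) {
  steps <- if (length(b$rows) > 0) dplyr::bind_rows(b$rows) else
    empty_steps()
  n_transfers <- sum(steps$type == "transfer")
  layout <- allocate_tip_racks(b$layout, n_transfers)
  stocks <- initial_stocks(bundle, config, layout, steps)
  run <- structure(
    list(steps = steps, layout = layout, plan = plan, design = bundle,
         config = config, initial_stocks = stocks,
         species = species_registry(bundle, config),
         mix_report = steps[steps$type == "transfer" & steps$below_min,
                            c("ordinal", "phase", "source_item",
                              "dest_item", "volume_ul")]),
    class = "run_bundle"
  )
  run
}

# Initial stock table: every source that is not filled by an earlier
# step, with the exact volume the run draws from it (plus dead volume).
initial_stocks <- function(bundle, config, layout, steps) {
  transfers <- steps[steps$type == "transfer", ]
  drawn <- dplyr::summarise(
    dplyr::group_by(transfers, .data$source_item),
    volume_ul = sum(.data$volume_ul), .groups = "drop")
  filled <- unique(transfers$dest_item)
  src <- drawn[!drawn$source_item %in% filled, ]
  pl <- layout$placements
  info <- purrr::map_dfr(seq_len(nrow(src)), function(i) {
    item <- src$source_item[i]
    j <- match(item, pl$item)
    kind <- pl$kind[j]
    conc <- switch(kind,
      primer_stock = c(config$primer_stock_um, "uM"),
      template_stock = c(config$template_stock_ng_ul, "ng/uL"),
      destination_stock = c(dest_stock_conc(config), "ng/uL"),
      reagent = c(NA, "")
    )
    tibble::tibble(
      item = item, kind = kind, slot = pl$slot[j], well = pl$well[j],
      conc_value = as.numeric(conc[1]), conc_unit = conc[2],
      volume_ul = src$volume_ul[i] + config$dead_volume_ul
    )
  })
  info
}

# destination plasmid stocks are supplied at the same mass concentration
# the amplified fragments have when pooled (post-digestion dilution)
dest_stock_conc <- function(config) {
  if (isTRUE(config$dpn1)) {
    post <- config$rxn_volume_ul +
      (config$dpn1_water_ul + config$dpn1_buffer_ul +
         config$dpn1_enzyme_ul) * config$rxn_volume_ul / 25
    config$frag_yield_ng_ul * config$rxn_volume_ul / post
  } else {
    config$frag_yield_ng_ul
  }
}

#' Build a gradient-optimized PCR run
#'
#' Plans working dilutions for every primer and template, mixes each
#' reaction at its gradient tube position, pauses for the operator to
#' move tubes to the external gradient thermocycler, runs the
#' amplification program, and (unless disabled) performs the
#' template-removal digestion.
#'
#' @param bundle a `design_bundle` (validated; a failing design raises a
#'   classed validation error).
#' @param config a [run_config()].
#' @return a `run_bundle`: ordered steps plus layout, gradient plan,
#'   initial stock table and species registry. Execute it with
#'   [execute_run()], render artifacts with [write_run_artifacts()].
#' @export
#' @examples
#' fx <- generate_design(fixture_spec(n_assemblies = 1, seed = 3,
#'                                    strategy = "pcr_only"),
#'                       dir = tempfile())
#' run <- build_pcr_workflow(parse_design(fx$path, "pcr_only"))
#' run
build_pcr_workflow <- function(bundle, config = run_config()) {
  ensure_valid(bundle)
  active <- active_pcr_ids(bundle, config)
  pcrs <- bundle$pcrs[bundle$pcrs$id %in% active, ]
  geometry <- gradient_geometry(config$n_zones, config$rows_per_zone,
                                config$max_span_c)
  plan <- plan_gradient(pcrs, geometry, default_tol = config$default_tol_c,
                        endpoint_window_c = config$endpoint_window_c,
                        endpoint_step_c = config$endpoint_step_c)
  layout <- layout_deck(bundle, config, plan)
  b <- new_builder(layout, config)
  build_pcr_prefix(b, bundle, config, plan)
  finish_run(b, bundle, config, plan)
}

#' Build a Golden Gate assembly run
#'
#' The full amplification prefix (dilutions, gradient PCR, digestion),
#' then a pause for manual fragment clean-up, equimolar pooling of each
#' combination's fragments into a fresh well, enzyme/buffer/water
#' additions, and the restriction-ligation cycling program on the deck
#' thermocycler (or externally with `gg_external_cycler = TRUE`).
#' Pieces listed in `config$destination_piece_ids` are supplied as an
#' intact destination plasmid stock and skip amplification.
#'
#' @inheritParams build_pcr_workflow
#' @return a `run_bundle`.
#' @export
build_goldengate_workflow <- function(bundle, config = run_config()) {
  ensure_valid(bundle)
  active <- active_pcr_ids(bundle, config)
  pcrs <- bundle$pcrs[bundle$pcrs$id %in% active, ]
  geometry <- gradient_geometry(config$n_zones, config$rows_per_zone,
                                config$max_span_c)
  plan <- plan_gradient(pcrs, geometry, default_tol = config$default_tol_c,
                        endpoint_window_c = config$endpoint_window_c,
                        endpoint_step_c = config$endpoint_step_c)
  layout <- layout_deck(bundle, config, plan)
  b <- new_builder(layout, config)
  build_pcr_prefix(b, bundle, config, plan)

  b_pause(b, "cleanup",
          "clean and concentrate fragments, return to positions")
  pool_fragments(b, bundle, config)

  # assembly reagents and cycling
  pools <- paste0("pool_", bundle$combinations$construct_name)
  for (i in seq_along(pools)) {
    pooled <- pool_volume(bundle, config, i)
    water <- config$gg_total_ul - pooled - config$gg_buffer_ul -
      config$gg_enzyme_ul - config$gg_ligase_ul
    if (water < -1e-9) {
      stop_buildplanr(
        "buildplanr_mix_error",
        sprintf("overfull: pooled fragments (%.2f uL) leave no room in the %g uL assembly reaction",
                pooled, config$gg_total_ul))
    }
    b_transfer(b, "assembly_mix", "ligase_buffer", pools[i],
               config$gg_buffer_ul)
    b_transfer(b, "assembly_mix", "bsai", pools[i], config$gg_enzyme_ul)
    b_transfer(b, "assembly_mix", "ligase", pools[i], config$gg_ligase_ul)
    b_transfer(b, "assembly_mix", "water", pools[i], water,
               mix_reps = 3L, mix_vol = 5, flag_min = FALSE)
  }
  program <- build_goldengate_program(
    n_cycles = config$gg_cycles, digest_c = config$gg_digest_c,
    ligate_c = config$gg_ligate_c, hold_s = config$gg_hold_s,
    final_c = config$gg_final_c, final_s = config$gg_final_s,
    kill_c = config$gg_kill_c, kill_s = config$gg_kill_s)
  if (isTRUE(config$gg_external_cycler)) {
    b_pause(b, "assembly", "transfer assembly reactions to the thermocycler")
    b_thermocycle(b, "assembly", program, "external", wells = pools)
  } else {
    b_thermocycle(b, "assembly", program, "on_deck", wells = pools)
  }
  finish_run(b, bundle, config, plan)
}

# total undiluted-equivalent volume pooled into combination i's well
pool_volume <- function(bundle, config, i) {
  ids <- bundle$combinations$piece_ids[[i]]
  lens <- bundle$pieces$length[match(ids, bundle$pieces$id)]
  ev <- equimolar_volumes(tibble::tibble(id = ids, length = lens),
                          ref_volume = config$ref_pool_volume_ul,
                          min_pipette = config$min_pipette_ul)
  sum(ev$volume_ul)
}

# predilutions (shared across combinations) plus per-combination
# equimolar pooling transfers
pool_fragments <- function(b, bundle, config) {
  combos <- bundle$combinations
  # predilution requirements: smallest factor reaching min_pipette
  predil <- list()
  uses <- integer(0)
  for (i in seq_len(nrow(combos))) {
    ids <- combos$piece_ids[[i]]
    lens <- bundle$pieces$length[match(ids, bundle$pieces$id)]
    ev <- equimolar_volumes(tibble::tibble(id = ids, length = lens),
                            ref_volume = config$ref_pool_volume_ul,
                            min_pipette = config$min_pipette_ul)
    for (k in which(ev$prediluted)) {
      key <- as.character(ev$id[k])
      predil[[key]] <- ev$dilution_factor[k]
      uses[key] <- (if (key %in% names(uses)) uses[[key]] else 0L) + 1L
    }
  }
  predil_items <- sprintf("frag_%s_predil", names(predil))
  for (k in seq_along(predil)) {
    id <- as.integer(names(predil)[k])
    f <- predil[[k]]
    src_vol <- config$min_pipette_ul * uses[[names(predil)[k]]]
    src <- piece_source_item(bundle, config, id, character(0))
    b_transfer(b, "pooling", src, predil_items[k], src_vol)
    b_transfer(b, "pooling", "water", predil_items[k], src_vol * (f - 1),
               mix_reps = 3L, mix_vol = 2, flag_min = FALSE)
  }
  for (i in seq_len(nrow(combos))) {
    ids <- combos$piece_ids[[i]]
    lens <- bundle$pieces$length[match(ids, bundle$pieces$id)]
    ev <- equimolar_volumes(tibble::tibble(id = ids, length = lens),
                            ref_volume = config$ref_pool_volume_ul,
                            min_pipette = config$min_pipette_ul)
    dest <- paste0("pool_", combos$construct_name[i])
    for (k in seq_along(ids)) {
      src <- piece_source_item(bundle, config, ids[k], predil_items)
      b_transfer(b, "pooling", src, dest, ev$volume_ul[k])
    }
  }
  invisible(b)
}

#' Build a one-pot in vivo assembly (IVA) run
#'
#' Each combination becomes a single PCR well containing all of its
#' pieces' primers and template(s); amplification produces overlapping
#' linear fragments in the same tube, which after digestion are
#' transformed directly — homologous recombination in the host cell
#' completes the assembly. Combinations with more than two pieces are
#' rejected (one-pot amplification of three or more fragments fails in
#' practice) unless `config$iva_multi_fragment_override` is set, in
#' which case the plan is emitted with a warning message step.
#'
#' @inheritParams build_pcr_workflow
#' @return a `run_bundle`.
#' @export
build_onepot_iva_workflow <- function(bundle, config = run_config()) {
  ensure_valid(bundle)
  combos <- bundle$combinations
  sizes <- purrr::map_int(combos$piece_ids, length)
  if (any(sizes > 2) && !isTRUE(config$iva_multi_fragment_override)) {
    stop_buildplanr(
      "buildplanr_strategy_error",
      sprintf("combination %s has %d pieces: one-pot amplification is only reliable for two fragments (set iva_multi_fragment_override to force)",
              combos$construct_name[which(sizes > 2)[1]],
              max(sizes)),
      reason = "multi_fragment"
    )
  }

  # one pooled reaction per combination: annealing optimum is the mean
  # of the member reactions' optima, tolerance the most rigid delta
  pcr_of <- function(ids) bundle$pcrs[match(
    bundle$pieces$source_pcr[match(ids, bundle$pieces$id)],
    bundle$pcrs$id), ]
  rx <- purrr::map_dfr(seq_len(nrow(combos)), function(i) {
    member <- pcr_of(combos$piece_ids[[i]])
    tibble::tibble(
      id = i, ta_opt = mean(member$ta_opt),
      delta = if (all(is.na(member$delta))) NA_real_
        else min(member$delta, na.rm = TRUE))
  })
  geometry <- gradient_geometry(config$n_zones, config$rows_per_zone,
                                config$max_span_c)
  plan <- plan_gradient(rx, geometry, default_tol = config$default_tol_c,
                        endpoint_window_c = config$endpoint_window_c,
                        endpoint_step_c = config$endpoint_step_c)
  layout <- layout_deck(bundle, config, plan)
  b <- new_builder(layout, config)
  if (any(sizes > 2)) {
    b_message(b, "setup",
              "warning: one-pot amplification of >2 fragments is unreliable")
  }

  pcrs <- bundle$pcrs
  templates <- unique(pcrs$template_name)
  primers <- unique(c(rbind(pcrs$fwd_oligo, pcrs$rev_oligo)))
  primer_dil <- plan_primer_dilution(
    stock_conc = config$primer_stock_um,
    final_conc = config$primer_final_um, rxn_volume = 25,
    add_volume = config$primer_add_ul,
    working_volume = config$working_volume_ul)
  template_dil <- plan_template_dilution(
    stock_conc = config$template_stock_ng_ul,
    target_mass = config$template_target_ng,
    add_volume = config$template_add_ul,
    working_volume = config$working_volume_ul, rxn_volume = 25)
  for (tm in templates) {
    if (!template_dil$pass_through) {
      b_transfer(b, "dilution", tm, paste0(tm, "_working"),
                 template_dil$source_volume_ul)
      b_transfer(b, "dilution", "water", paste0(tm, "_working"),
                 template_dil$diluent_volume_ul,
                 mix_reps = 3L, mix_vol = 10, flag_min = FALSE)
    }
  }
  for (pr in primers) {
    b_transfer(b, "dilution", pr, paste0(pr, "_working"),
               primer_dil$source_volume_ul)
    b_transfer(b, "dilution", "water", paste0(pr, "_working"),
               primer_dil$diluent_volume_ul,
               mix_reps = 3L, mix_vol = 10, flag_min = FALSE)
  }

  scale <- config$rxn_volume_ul / 25
  rxn_items <- paste0("onepot_", combos$construct_name)
  spawn <- list()
  for (i in seq_len(nrow(combos))) {
    member <- pcr_of(combos$piece_ids[[i]])
    dest <- rxn_items[i]
    mm <- config$rxn_volume_ul / 2
    b_transfer(b, "pcr_mix", "master_mix", dest, mm)
    total <- mm
    for (j in seq_len(nrow(member))) {
      for (p in c(member$fwd_oligo[j], member$rev_oligo[j])) {
        v <- config$primer_add_ul * scale
        b_transfer(b, "pcr_mix", paste0(p, "_working"), dest, v)
        total <- total + v
      }
    }
    for (tm in unique(member$template_name)) {
      src <- if (template_dil$pass_through) tm else paste0(tm, "_working")
      v <- (if (template_dil$pass_through) template_dil$add_volume_ul
            else config$template_add_ul) * scale
      b_transfer(b, "pcr_mix", src, dest, v)
      total <- total + v
    }
    water <- config$rxn_volume_ul - total
    if (water < -1e-9) {
      stop_buildplanr("buildplanr_mix_error",
                      "overfull: components exceed the reaction volume")
    }
    b_transfer(b, "pcr_mix", "water", dest, water,
               mix_reps = 3L, mix_vol = 10, flag_min = FALSE)
    spawn[[i]] <- tibble::tibble(
      item = dest, species = paste0("frag_pcr_", member$id),
      conc_ng_ul = config$frag_yield_ng_ul / nrow(member))
  }

  ext_s <- extension_time(pcrs$product_length,
                          rate_s_per_kb = config$ext_rate_s_per_kb,
                          rounding = config$ext_round_s,
                          floor = config$ext_floor_s)
  program <- build_pcr_program(plan, ext_s, n_cycles = config$pcr_cycles,
                               final_ext_s = config$final_ext_s)
  b_pause(b, "amplification",
          "transfer reactions to the gradient thermocycler")
  b_thermocycle(b, "amplification", program, "external",
                wells = rxn_items, spawn = dplyr::bind_rows(spawn))
  if (isTRUE(config$dpn1)) {
    dmix <- build_dpn1_mix(config$rxn_volume_ul, config)
    for (i in seq_along(rxn_items)) {
      for (k in seq_len(nrow(dmix))) {
        b_transfer(b, "digestion", dmix$source_item[k], rxn_items[i],
                   dmix$volume_ul[k],
                   mix_reps = if (k == nrow(dmix)) 3L else NA_integer_,
                   mix_vol = if (k == nrow(dmix)) 10 else NA_real_)
      }
    }
    b_thermocycle(b, "digestion", build_dpn1_program(), "on_deck",
                  wells = rxn_items)
  }
  b_message(b, "handoff", "transform fragment mixture")
  finish_run(b, bundle, config, plan)
}

#' Build a separate-PCR homology assembly (AQUA) run
#'
#' Amplifies every fragment in its own gradient-optimized reaction,
#' digests residual template, then pools each combination's fragments
#' in length-proportional (equimolar) volumes. No ligation enzymes are
#' added and no assembly cycling is run: the pooled mixture is
#' transformed directly and assembled by the host's own recombination
#' machinery.
#'
#' @inheritParams build_pcr_workflow
#' @return a `run_bundle`.
#' @export
build_aqua_workflow <- function(bundle, config = run_config()) {
  ensure_valid(bundle)
  active <- active_pcr_ids(bundle, config)
  pcrs <- bundle$pcrs[bundle$pcrs$id %in% active, ]
  geometry <- gradient_geometry(config$n_zones, config$rows_per_zone,
                                config$max_span_c)
  plan <- plan_gradient(pcrs, geometry, default_tol = config$default_tol_c,
                        endpoint_window_c = config$endpoint_window_c,
                        endpoint_step_c = config$endpoint_step_c)
  layout <- layout_deck(bundle, config, plan)
  b <- new_builder(layout, config)
  build_pcr_prefix(b, bundle, config, plan)
  pool_fragments(b, bundle, config)
  b_message(b, "handoff", "transform fragment mixture")
  finish_run(b, bundle, config, plan)
}

#' @export
print.run_bundle <- function(x, ...) {
  counts <- table(x$steps$type)
  cat(sprintf(
    "<run_bundle> %s strategy: %d steps (%s)\n",
    x$design$strategy, nrow(x$steps),
    paste(sprintf("%d %s", as.integer(counts), names(counts)),
          collapse = ", ")))
  if (nrow(x$mix_report) > 0) {
    cat(sprintf("  %d transfer(s) below the minimum pipettable volume\n",
                nrow(x$mix_report)))
  }
  invisible(x)
}
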