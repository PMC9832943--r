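# Virtual execution of a run bundle with exact volume and amount
# bookkeeping. The simulator is the package's principal verification
# surface: every workflow is checked here for conservation, capacity,
# overdraw and final well composition before it is trusted.

WELL_CAPACITY_UL <- c(tube_rack_24 = 2000, plate_96 = 200,
                      thermocycler = 100, tip_rack = Inf)

well_key <- function(slot, well) paste0(slot, ":", well)

#' Execute a run bundle on the virtual deck
#'
#' Applies steps in ordinal order. A transfer moves volume and
#' proportional per-species amounts from source to destination; a
#' digestion thermocycle zeroes template species in its wells (modelling
#' template removal); an amplification thermocycle deposits each
#' reaction's product species at the configured nominal equal-yield mass
#' concentration; pauses and messages are logged no-ops. Aspirating more
#' than a well holds or overfilling a well past its labware capacity is
#' recorded as a violation, never silently dropped.
#'
#' @param run a `run_bundle`.
#' @param initial_stocks stock table to load before the first step;
#'   defaults to `run$initial_stocks`.
#' @return a `sim_state`: list with `wells` (named list of
#'   `list(volume_ul, amounts)` keyed `"slot:well"`), `violations`
#'   (tibble), `log` (character), `snapshots` (per-phase well states),
#'   `created`/`destroyed` (named per-species totals), `species`
#'   (registry) and `layout`.
#' @export
#' @examples
#' fx <- generate_design(fixture_spec(n_assemblies = 1, seed = 3,
#'                                    strategy = "pcr_only"),
#'                       dir = tempfile())
#' run <- build_pcr_workflow(parse_design(fx$path, "pcr_only"))
#' state <- execute_run(run)
#' nrow(state$violations)
execute_run <- function(run, initial_stocks = run$initial_stocks) {
  stopifnot(inherits(run, "run_bundle"))
  layout <- run$layout
  kind_of <- stats::setNames(run$species$kind, run$species$species)
  slot_type <- stats::setNames(layout$slots$type, layout$slots$slot)

  wells <- list()
  for (i in seq_len(nrow(initial_stocks))) {
    s <- initial_stocks[i, ]
    amount <- switch(s$kind,
      primer_stock = ,
      template_stock = ,
      destination_stock = s$conc_value * s$volume_ul,
      s$volume_ul  # reagents tracked by volume
    )
    wells[[well_key(s$slot, s$well)]] <- list(
      volume_ul = s$volume_ul,
      amounts = stats::setNames(amount, s$item)
    )
  }

  violations <- list()
  note_violation <- function(rule, step, detail) {
    violations[[length(violations) + 1]] <<- tibble::tibble(
      rule = rule, ordinal = step, detail = detail)
  }
  created <- numeric(0)
  destroyed <- numeric(0)
  log <- character(0)
  snapshots <- list()

  capacity_of <- function(slot) {
    unname(WELL_CAPACITY_UL[slot_type[[as.character(slot)]]])
  }

  steps <- run$steps
  prev_phase <- NA_character_
  for (i in seq_len(nrow(steps))) {
    st <- steps[i, ]
    if (!is.na(prev_phase) && !identical(st$phase, prev_phase)) {
      snapshots[[prev_phase]] <- wells
    }
    prev_phase <- st$phase

    if (st$type == "transfer") {
      sk <- well_key(st$source_slot, st$source_well)
      if (is.null(wells[[sk]])) {
        stop_buildplanr(
          "buildplanr_sim_error",
          sprintf("step %d: transfer from empty/unplaced source %s (%s)",
                  st$ordinal, st$source_item, sk))
      }
      src <- wells[[sk]]
      v <- st$volume_ul
      if (v > src$volume_ul + 1e-9) {
        note_violation("overdraw", st$ordinal, sprintf(
          "%s: requested %.3f uL, %.3f uL available",
          st$source_item, v, src$volume_ul))
        v <- src$volume_ul
      }
      frac <- if (src$volume_ul > 0) v / src$volume_ul else 0
      moved <- src$amounts * frac
      src$volume_ul <- src$volume_ul - v
      src$amounts <- src$amounts - moved
      wells[[sk]] <- src

      dk <- well_key(st$dest_slot, st$dest_well)
      dst <- wells[[dk]] %||% list(volume_ul = 0, amounts = numeric(0))
      dst$volume_ul <- dst$volume_ul + v
      for (sp in names(moved)) {
        dst$amounts[sp] <- (if (sp %in% names(dst$amounts))
          dst$amounts[[sp]] else 0) + moved[[sp]]
      }
      cap <- capacity_of(st$dest_slot)
      if (dst$volume_ul > cap + 1e-9) {
        note_violation("capacity", st$ordinal, sprintf(
          "well %s at %.1f uL exceeds %.0f uL capacity",
          dk, dst$volume_ul, cap))
      }
      wells[[dk]] <- dst
      log <- c(log, sprintf("transfer %d: %s -> %s %.3f uL",
                            st$ordinal, sk, dk, v))
    } else if (st$type == "thermocycle") {
      prog <- st$program[[1]]
      items <- st$wells[[1]]
      keys <- vapply(items, function(it) {
        p <- lookup_place(layout, it); well_key(p$slot, p$well)
      }, character(1))
      if (identical(prog$label, "dpn1")) {
        for (k in keys) {
          w <- wells[[k]]
          if (is.null(w)) next
          tmpl <- names(w$amounts)[kind_of[names(w$amounts)] == "template"]
          for (sp in tmpl) {
            destroyed[sp] <- (if (sp %in% names(destroyed))
              destroyed[[sp]] else 0) + w$amounts[[sp]]
            w$amounts[[sp]] <- 0
          }
          wells[[k]] <- w
        }
      }
      spawn <- st$spawn[[1]]
      if (!is.null(spawn) && nrow(spawn) > 0) {
        for (j in seq_len(nrow(spawn))) {
          p <- lookup_place(layout, spawn$item[j])
          k <- well_key(p$slot, p$well)
          w <- wells[[k]] %||% list(volume_ul = 0, amounts = numeric(0))
          amt <- spawn$conc_ng_ul[j] * w$volume_ul
          prev <- if (spawn$species[j] %in% names(w$amounts))
            w$amounts[[spawn$species[j]]] else 0
          w$amounts[[spawn$species[j]]] <- amt
          created[spawn$species[j]] <-
            (if (spawn$species[j] %in% names(created))
              created[[spawn$species[j]]] else 0) + amt - prev
          wells[[k]] <- w
        }
      }
      log <- c(log, sprintf("thermocycle %d: %s (%s, %d wells)",
                            st$ordinal, prog$label, st$location,
                            length(items)))
    } else {
      log <- c(log, sprintf("%s %d: %s", st$type, st$ordinal, st$message))
    }
  }
  if (!is.na(prev_phase)) snapshots[[prev_phase]] <- wells

  structure(
    list(
      wells = wells,
      violations = if (length(violations) > 0) dplyr::bind_rows(violations)
        else tibble::tibble(rule = character(0), ordinal = integer(0),
                            detail = character(0)),
      log = log, snapshots = snapshots, created = created,
      destroyed = destroyed, species = run$species, layout = layout
    ),
    class = "sim_state"
  )
}

#' @export
print.sim_state <- function(x, ...) {
  cat(sprintf("<sim_state> %d occupied wells, %d violation(s)\n",
              sum(vapply(x$wells, function(w) w$volume_ul > 1e-12,
                         logical(1))),
              nrow(x$violations)))
  invisible(x)
}

#' Check volume and amount conservation of an executed state
#'
#' For every species the final total across all wells, plus what modelled
#' digestion destroyed, minus what modelled amplification created, must
#' equal the initial stock total to a relative error of 1e-9; total
#' liquid volume must equal the initially loaded volume.
#'
#' @param state a `sim_state` from [execute_run()].
#' @param initial_stocks the stock table the state was initialized with.
#' @return list with `ok`, `volume_ok`, and `report` — a tibble with one
#'   row per species (`species`, `initial`, `final`, `created`,
#'   `destroyed`, `rel_err`, `ok`, `wells`).
#' @export
check_conservation <- function(state, initial_stocks) {
  init <- numeric(0)
  for (i in seq_len(nrow(initial_stocks))) {
    s <- initial_stocks[i, ]
    amount <- switch(s$kind,
      primer_stock = , template_stock = ,
      destination_stock = s$conc_value * s$volume_ul,
      s$volume_ul)
    init[s$item] <- (if (s$item %in% names(init)) init[[s$item]] else 0) +
      amount
  }
  all_species <- unique(c(names(init), names(state$created),
                          unlist(lapply(state$wells,
                                        function(w) names(w$amounts)))))
  rows <- purrr::map_dfr(all_species, function(sp) {
    fin <- 0; where <- character(0)
    for (k in names(state$wells)) {
      a <- state$wells[[k]]$amounts
      if (sp %in% names(a) && a[[sp]] > 0) {
        fin <- fin + a[[sp]]
        if (a[[sp]] > 1e-12) where <- c(where, k)
      } else if (sp %in% names(a)) {
        fin <- fin + a[[sp]]
      }
    }
    i0 <- if (sp %in% names(init)) init[[sp]] else 0
    cr <- if (sp %in% names(state$created)) state$created[[sp]] else 0
    de <- if (sp %in% names(state$destroyed)) state$destroyed[[sp]] else 0
    expected <- i0 + cr - de
    scale <- max(abs(expected), abs(fin), 1e-12)
    rel <- abs(fin - expected) / scale
    tibble::tibble(species = sp, initial = i0, final = fin, created = cr,
                   destroyed = de, rel_err = rel, ok = rel <= 1e-9,
                   wells = paste(where, collapse = ","))
  })
  vol_init <- sum(initial_stocks$volume_ul)
  vol_fin <- sum(vapply(state$wells, function(w) w$volume_ul, numeric(1)))
  vol_ok <- abs(vol_fin - vol_init) <= 1e-9 * max(vol_init, 1)
  list(ok = all(rows$ok) && vol_ok, volume_ok = vol_ok, report = rows)
}

#' Composition of one well after execution
#'
#' @param state a `sim_state`.
#' @param slot,well deck location; alternatively pass `item` to resolve
#'   a placed item's location from the layout.
#' @param item placed item name (overrides `slot`/`well`).
#' @param stage optional phase name: query the per-phase snapshot taken
#'   just after that phase completed (e.g. `"pcr_mix"` for the assembled
#'   reaction before thermocycling) instead of the final state.
#' @return list with `volume_ul` and `composition`, a tibble of
#'   `species`, `kind`, `amount`, `unit`, `conc`, `conc_unit` (uM for
#'   mole-tracked species, ng/uL for mass-tracked, volume fraction for
#'   reagents).
#' @export
#' @examples
#' # see execute_run(); then:
#' # well_composition(state, item = "pcr_1")
well_composition <- function(state, slot = NULL, well = NULL, item = NULL,
                             stage = NULL) {
  if (!is.null(item)) {
    p <- lookup_place(state$layout, item)
    slot <- p$slot; well <- p$well
  }
  k <- well_key(slot, well)
  wells <- if (is.null(stage)) state$wells else {
    if (!stage %in% names(state$snapshots)) {
      stop_buildplanr("buildplanr_key_error",
                      sprintf("no snapshot for stage: %s", stage))
    }
    state$snapshots[[stage]]
  }
  w <- wells[[k]]
  if (is.null(w)) {
    stop_buildplanr("buildplanr_key_error",
                    sprintf("unknown or empty well: %s", k))
  }
  unit_of <- stats::setNames(state$species$unit, state$species$species)
  kind_of <- stats::setNames(state$species$kind, state$species$species)
  len_of <- stats::setNames(state$species$length_bp, state$species$species)
  sp <- names(w$amounts)
  comp <- tibble::tibble(
    species = sp,
    kind = unname(kind_of[sp]),
    amount = unname(w$amounts),
    unit = unname(unit_of[sp]),
    conc = unname(w$amounts) / w$volume_ul,
    conc_unit = dplyr::case_when(
      unname(unit_of[sp]) == "pmol" ~ "uM",
      unname(unit_of[sp]) == "ng" ~ "ng/uL",
      TRUE ~ "vol_frac"
    ),
    length_bp = unname(len_of[sp]),
    # mole amounts for mass-tracked DNA (650 g/mol per bp)
    pmol = dplyr::if_else(
      unname(unit_of[sp]) == "ng" & !is.na(unname(len_of[sp])),
      unname(w$amounts) * 1000 / (650 * unname(len_of[sp])),
      NA_real_)
  )
  list(volume_ul = w$volume_ul, composition = comp)
}
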