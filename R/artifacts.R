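# Rendering of the complete artifact set for a run: split design
# tables, operator instruction files, per-stage tracking tables, the
# machine-readable run bundle, and the transfer picklist.

# principal concentration shown in a tracking row
principal_conc <- function(wellstate, item, species_tbl) {
  if (is.null(wellstate) || wellstate$volume_ul <= 0) {
    return(list(value = NA_real_, unit = ""))
  }
  unit_of <- stats::setNames(species_tbl$unit, species_tbl$species)
  amounts <- wellstate$amounts
  # working dilution wells: the eponymous species
  base <- sub("_working$", "", item)
  if (base %in% names(amounts)) {
    u <- unit_of[[base]]
    return(list(value = amounts[[base]] / wellstate$volume_ul,
                unit = if (u == "pmol") "uM" else
                  if (u == "ng") "ng/uL" else "vol_frac"))
  }
  # reaction/pool wells: total DNA fragment mass concentration
  frag <- names(amounts)[names(amounts) %in%
                           species_tbl$species[species_tbl$kind == "fragment"]]
  if (length(frag) > 0) {
    return(list(value = sum(unlist(amounts[frag])) / wellstate$volume_ul,
                unit = "ng/uL"))
  }
  list(value = NA_real_, unit = "")
}

#' Item-tracking rows for a run
#'
#' Executes the run on the virtual deck and derives one tracking row per
#' surviving item per lifecycle stage: `initial` (declared stocks),
#' `post_dilution` (working plate), `post_pcr` and `post_digest`
#' (reaction wells) and `post_assembly` (pool wells), each with
#' location, concentration and volume.
#'
#' @param run a `run_bundle`.
#' @param state optional pre-computed [execute_run()] result.
#' @return tibble with columns `item`, `kind`, `slot`, `well`,
#'   `conc_value`, `conc_unit`, `volume_ul`, `stage`.
#' @export
tracking_rows <- function(run, state = execute_run(run)) {
  rows <- list()
  add <- function(df) rows[[length(rows) + 1]] <<- df

  add(dplyr::mutate(run$initial_stocks, stage = "initial"))

  pl <- run$layout$placements
  stage_rows <- function(snapshot, kinds, stage) {
    sub <- pl[pl$kind %in% kinds, ]
    out <- purrr::map_dfr(seq_len(nrow(sub)), function(i) {
      k <- well_key(sub$slot[i], sub$well[i])
      w <- snapshot[[k]]
      if (is.null(w) || w$volume_ul <= 1e-12) return(NULL)
      pc <- principal_conc(w, sub$item[i], run$species)
      tibble::tibble(
        item = sub$item[i], kind = sub$kind[i], slot = sub$slot[i],
        well = sub$well[i], conc_value = pc$value, conc_unit = pc$unit,
        volume_ul = w$volume_ul, stage = stage)
    })
    out
  }

  snaps <- state$snapshots
  if ("dilution" %in% names(snaps)) {
    add(stage_rows(snaps[["dilution"]], "working_dilution", "post_dilution"))
  }
  if ("amplification" %in% names(snaps)) {
    add(stage_rows(snaps[["amplification"]], "reaction", "post_pcr"))
  }
  if ("digestion" %in% names(snaps)) {
    add(stage_rows(snaps[["digestion"]], "reaction", "post_digest"))
  }
  if (any(pl$kind == "pool")) {
    add(stage_rows(state$wells, "pool", "post_assembly"))
  }
  dplyr::bind_rows(rows)
}

#' Transfer picklist of a run
#'
#' @param run a `run_bundle`.
#' @return tibble with columns `ordinal`, `source_slot`, `source_well`,
#'   `dest_slot`, `dest_well`, `volume_ul`, `mix_reps`, `mix_vol_ul`
#'   (transfers only, in execution order).
#' @export
picklist <- function(run) {
  tr <- run$steps[run$steps$type == "transfer", ]
  tibble::tibble(
    ordinal = tr$ordinal, source_slot = tr$source_slot,
    source_well = tr$source_well, dest_slot = tr$dest_slot,
    dest_well = tr$dest_well, volume_ul = tr$volume_ul,
    mix_reps = tr$mix_reps, mix_vol_ul = tr$mix_vol_ul
  )
}

run_bundle_json <- function(run) {
  steps <- run$steps
  serial <- purrr::map(seq_len(nrow(steps)), function(i) {
    st <- steps[i, ]
    base <- list(ordinal = st$ordinal, type = st$type, phase = st$phase)
    if (st$type == "transfer") {
      c(base, list(
        source_item = st$source_item, source_slot = st$source_slot,
        source_well = st$source_well, dest_item = st$dest_item,
        dest_slot = st$dest_slot, dest_well = st$dest_well,
        volume_ul = st$volume_ul,
        mix_reps = if (is.na(st$mix_reps)) NULL else st$mix_reps,
        mix_vol_ul = if (is.na(st$mix_vol_ul)) NULL else st$mix_vol_ul))
    } else if (st$type == "thermocycle") {
      prog <- st$program[[1]]
      c(base, list(
        location = st$location,
        program = list(label = prog$label,
                       steps = prog$steps,
                       cycled = prog$cycled),
        wells = st$wells[[1]]))
    } else {
      c(base, list(message = st$message))
    }
  })
  list(
    strategy = run$design$strategy,
    config_snapshot = unclass(run$config),
    gradient = list(
      t_low = run$plan$t_low, t_high = run$plan$t_high,
      zone_temps = run$plan$zone_temps,
      assignments = run$plan$assignments
    ),
    initial_stocks = run$initial_stocks,
    steps = serial
  )
}

#' Write the full artifact set of a run
#'
#' Writes, into `out_dir`: the four split design tables (`oligo.csv`,
#' `pcr.csv`, `assembly.csv`, `combinations.csv`), the operator
#' instruction files `reagent_setup.txt` and `reactions_setup.txt`, the
#' per-stage tracking tables (`tracking_<stage>.csv`), the
#' machine-readable `runbundle.json` (steps, gradient, initial stocks
#' and the full configuration snapshot) and the transfer
#' `picklist.csv`. All output is deterministic: the same run yields
#' byte-identical files.
#'
#' @param run a `run_bundle`.
#' @param out_dir output directory (created if absent).
#' @return invisibly, a named character vector of artifact paths.
#' @export
write_run_artifacts <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- write_section_tables(run$design, out_dir)

  req <- run$initial_stocks[c("item", "volume_ul")]
  p <- file.path(out_dir, "reagent_setup.txt")
  render_reagent_setup(run$layout, required = req, file = p)
  paths["reagent_setup"] <- p

  amp_idx <- which(run$steps$type == "thermocycle" &
                     purrr::map_lgl(run$steps$program,
                                    ~ !is.null(.x) &&
                                      .x$label == "amplification"))
  if (length(amp_idx) > 0) {
    p <- file.path(out_dir, "reactions_setup.txt")
    render_reactions_setup(run$plan, run$steps$program[[amp_idx[1]]],
                           file = p)
    paths["reactions_setup"] <- p
  }

  state <- execute_run(run)
  paths <- c(paths, write_tracking_tables(tracking_rows(run, state),
                                          out_dir))

  p <- file.path(out_dir, "runbundle.json")
  jsonlite::write_json(run_bundle_json(run), p, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  paths["runbundle"] <- p

  p <- file.path(out_dir, "picklist.csv")
  readr::write_csv(picklist(run), p, na = "", progress = FALSE)
  paths["picklist"] <- p
  invisible(paths)
}
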