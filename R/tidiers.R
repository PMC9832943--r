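# broom-style tidiers so planner objects drop straight into pipelines.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a gradient plan into its assignment table
#'
#' @param x a `gradient_plan`.
#' @param ... unused.
#' @return tibble with one row per reaction: `pcr_id`, `ta_opt`, `zone`,
#'   `position`, `zone_temp`, `deviation`, `tolerance`.
#' @export
tidy.gradient_plan <- function(x, ...) {
  x$assignments
}

#' One-row summary of a gradient plan
#'
#' @param x a `gradient_plan`.
#' @param ... unused.
#' @return one-row tibble: `n_reactions`, `n_zones`, `t_low`, `t_high`,
#'   `span`, `max_deviation`, `within_tolerance`.
#' @export
glance.gradient_plan <- function(x, ...) {
  tibble::tibble(
    n_reactions = nrow(x$assignments),
    n_zones = x$geometry$n_zones,
    t_low = x$t_low, t_high = x$t_high, span = x$t_high - x$t_low,
    max_deviation = max(x$assignments$deviation),
    within_tolerance = all(x$assignments$deviation <=
                             x$assignments$tolerance + 1e-12)
  )
}

#' Tidy a design bundle into one long item table
#'
#' @param x a `design_bundle`.
#' @param ... unused.
#' @return tibble with columns `table`, `item`, `detail`.
#' @export
tidy.design_bundle <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(table = "oligo", item = x$oligos$name,
                   detail = sprintf("Tm %.1f degC", x$oligos$anneal_tm)),
    tibble::tibble(table = "pcr", item = paste0("pcr_", x$pcrs$id),
                   detail = sprintf("%s + %s on %s, %d bp",
                                    x$pcrs$fwd_oligo, x$pcrs$rev_oligo,
                                    x$pcrs$template_name,
                                    x$pcrs$product_length)),
    tibble::tibble(table = "piece", item = paste0("piece_", x$pieces$id),
                   detail = sprintf("%d bp (%s)", x$pieces$length,
                                    x$pieces$piece_kind)),
    tibble::tibble(table = "combination", item = x$combinations$construct_name,
                   detail = purrr::map_chr(x$combinations$piece_ids,
                                           ~ paste(.x, collapse = ";")))
  )
}

#' One-row summary of a design bundle
#'
#' @param x a `design_bundle`.
#' @param ... unused.
#' @return one-row tibble with table sizes, the combined distinct
#'   primer+template count and whether validation passes.
#' @export
glance.design_bundle <- function(x, ...) {
  tibble::tibble(
    strategy = x$strategy,
    n_oligos = nrow(x$oligos), n_pcrs = nrow(x$pcrs),
    n_pieces = nrow(x$pieces), n_combinations = nrow(x$combinations),
    primers_plus_templates = design_capacity(x),
    valid = validate_design(x)$ok
  )
}

#' Tidy a run bundle into its flat step table
#'
#' @param x a `run_bundle`.
#' @param ... unused.
#' @return the step tibble without list-columns (`program`, `wells`,
#'   `spawn` are summarised as labels/counts).
#' @export
tidy.run_bundle <- function(x, ...) {
  st <- x$steps
  st$program_label <- purrr::map_chr(st$program,
                                     ~ if (is.null(.x)) NA_character_
                                       else .x$label)
  st$n_wells <- purrr::map_int(st$wells,
                               ~ if (is.null(.x)) NA_integer_
                                 else length(.x))
  st[setdiff(names(st), c("program", "wells", "spawn"))]
}

#' One-row summary of a run bundle
#'
#' @param x a `run_bundle`.
#' @param ... unused.
#' @return one-row tibble: step counts by type, total transferred
#'   volume, and the number of below-minimum transfers flagged.
#' @export
glance.run_bundle <- function(x, ...) {
  tr <- x$steps[x$steps$type == "transfer", ]
  tibble::tibble(
    strategy = x$design$strategy,
    n_steps = nrow(x$steps),
    n_transfers = nrow(tr),
    n_pauses = sum(x$steps$type == "pause"),
    n_thermocycles = sum(x$steps$type == "thermocycle"),
    total_volume_ul = sum(tr$volume_ul),
    n_below_min = nrow(x$mix_report)
  )
}

#' Tidy an executed deck state into a well/species table
#'
#' @param x a `sim_state`.
#' @param ... unused.
#' @return tibble with one row per (well, species): `slot`, `well`,
#'   `volume_ul`, `species`, `kind`, `amount`, `unit`, `conc`.
#' @export
tidy.sim_state <- function(x, ...) {
  unit_of <- stats::setNames(x$species$unit, x$species$species)
  kind_of <- stats::setNames(x$species$kind, x$species$species)
  purrr::map_dfr(names(x$wells), function(k) {
    w <- x$wells[[k]]
    if (length(w$amounts) == 0) return(NULL)
    parts <- strsplit(k, ":", fixed = TRUE)[[1]]
    sp <- names(w$amounts)
    tibble::tibble(
      slot = as.integer(parts[1]), well = parts[2],
      volume_ul = w$volume_ul, species = sp,
      kind = unname(kind_of[sp]), amount = unname(w$amounts),
      unit = unname(unit_of[sp]),
      conc = if (w$volume_ul > 0) unname(w$amounts) / w$volume_ul
        else NA_real_)
  })
}

#' One-row summary of an executed deck state
#'
#' @param x a `sim_state`.
#' @param ... unused.
#' @return one-row tibble: occupied well count, total volume, violation
#'   count.
#' @export
glance.sim_state <- function(x, ...) {
  tibble::tibble(
    n_wells = sum(vapply(x$wells, function(w) w$volume_ul > 1e-12,
                         logical(1))),
    total_volume_ul = sum(vapply(x$wells, function(w) w$volume_ul,
                                 numeric(1))),
    n_violations = nrow(x$violations)
  )
}

#' Tidy a validation report
#'
#' @param x a `validation_report`.
#' @param ... unused.
#' @return the violations tibble (`rule`, `item`, `detail`).
#' @export
tidy.validation_report <- function(x, ...) x$violations

#' One-row summary of a validation report
#'
#' @param x a `validation_report`.
#' @param ... unused.
#' @return one-row tibble: `ok`, `n_violations`.
#' @export
glance.validation_report <- function(x, ...) {
  tibble::tibble(ok = x$ok, n_violations = nrow(x$violations))
}
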