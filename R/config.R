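#' Run configuration for build planning
#'
#' Collects every tunable used by the planners into a single named list.
#' Values not overridden keep their defaults, which reproduce the published
#' bench protocol: 25 uL PCRs at 0.1 uM per primer and 0.5 ng template,
#' DpnI digestion by adding 19 uL water + 5 uL buffer + 1 uL enzyme, a
#' 0.4 degC annealing-temperature accommodation bound, and a 12-zone
#' gradient block.
#'
#' @param ... overrides, e.g. `run_config(rxn_volume_ul = 50)`. Unknown
#'   keys raise an error so typos cannot silently fall back to defaults.
#' @param file optional YAML or JSON file of overrides applied before `...`.
#'
#' @return a named list with class `"run_config"`.
#' @details Key groups:
#' \describe{
#'   \item{gradient}{`n_zones` (12), `rows_per_zone` (8), `max_span_c` (24),
#'     `default_tol_c` (0.4), `endpoint_window_c` (2.0), `endpoint_step_c`
#'     (0.1): geometry of the gradient block and the endpoint re-optimizer.}
#'   \item{thermal}{`pcr_cycles` (34), `ext_rate_s_per_kb` (30),
#'     `ext_round_s` (5), `ext_floor_s` (10), `final_ext_s` (300), Golden
#'     Gate cycling `gg_cycles` (30), `gg_digest_c`/`gg_ligate_c` (37/16),
#'     `gg_hold_s` (300), `gg_final_c` (50), `gg_final_s` (300),
#'     `gg_kill_c` (80), `gg_kill_s` (600).}
#'   \item{stoichiometry}{`rxn_volume_ul` (25), `primer_stock_um` (100),
#'     `primer_final_um` (0.1), `primer_add_ul` (1), `template_stock_ng_ul`
#'     (50), `template_target_ng` (0.5), `template_add_ul` (1),
#'     `working_volume_ul` (20), `min_pipette_ul` (1), `ref_pool_volume_ul`
#'     (4), `dpn1_water_ul`/`dpn1_buffer_ul`/`dpn1_enzyme_ul` (19/5/1 at a
#'     25 uL reaction, scaled proportionally), Golden Gate body
#'     `gg_total_ul` (20), `gg_buffer_ul` (2), `gg_enzyme_ul` (1),
#'     `gg_ligase_ul` (1).}
#'   \item{flags}{`dpn1` (TRUE), `gg_external_cycler` (FALSE),
#'     `iva_multi_fragment_override` (FALSE), `destination_piece_ids`
#'     (integer(0); pieces supplied as an intact destination plasmid
#'     rather than amplified), `frag_yield_ng_ul` (25; nominal equal-yield
#'     post-PCR fragment mass concentration), `dead_volume_ul` (0).}
#' }
#' @export
#' @examples
#' cfg <- run_config(rxn_volume_ul = 50)
#' cfg$rxn_volume_ul
run_config <- function(..., file = NULL) {
  defaults <- list(
    # gradient geometry and endpoint search
    n_zones = 12L,
    rows_per_zone = 8L,
    max_span_c = 24,
    default_tol_c = 0.4,
    endpoint_window_c = 2.0,
    endpoint_step_c = 0.1,
    # thermal programs
    pcr_cycles = 34L,
    ext_rate_s_per_kb = 30,
    ext_round_s = 5,
    ext_floor_s = 10,
    final_ext_s = 300,
    gg_cycles = 30L,
    gg_digest_c = 37,
    gg_ligate_c = 16,
    gg_hold_s = 300,
    gg_final_c = 50,
    gg_final_s = 300,
    gg_kill_c = 80,
    gg_kill_s = 600,
    # volumes and concentrations
    rxn_volume_ul = 25,
    primer_stock_um = 100,
    primer_final_um = 0.1,
    primer_add_ul = 1,
    template_stock_ng_ul = 50,
    template_target_ng = 0.5,
    template_add_ul = 1,
    working_volume_ul = 20,
    min_pipette_ul = 1,
    ref_pool_volume_ul = 4,
    dpn1_water_ul = 19,
    dpn1_buffer_ul = 5,
    dpn1_enzyme_ul = 1,
    gg_total_ul = 20,
    gg_buffer_ul = 2,
    gg_enzyme_ul = 1,
    gg_ligase_ul = 1,
    # behaviour flags
    dpn1 = TRUE,
    gg_external_cycler = FALSE,
    iva_multi_fragment_override = FALSE,
    destination_piece_ids = integer(0),
    frag_yield_ng_ul = 25,
    dead_volume_ul = 0
  )
  overrides <- list(...)
  if (!is.null(file)) {
    ext <- tolower(tools::file_ext(file))
    from_file <- if (ext %in% c("yml", "yaml")) {
      yaml::read_yaml(file)
    } else {
      jsonlite::read_json(file, simplifyVector = TRUE)
    }
    overrides <- c(from_file[!names(from_file) %in% names(overrides)], overrides)
  }
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0) {
    stop_buildplanr(
      "buildplanr_config_error",
      sprintf("unknown config key(s): %s", paste(unknown, collapse = ", "))
    )
  }
  cfg <- utils::modifyList(defaults, overrides)
  # canonicalize types so a config restored from JSON/YAML behaves
  # identically to one built in R
  cfg$destination_piece_ids <- as.integer(unlist(cfg$destination_piece_ids))
  for (k in c("n_zones", "rows_per_zone", "pcr_cycles", "gg_cycles")) {
    cfg[[k]] <- as.integer(cfg[[k]])
  }
  structure(cfg, class = c("run_config", "list"))
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  keys <- names(x)
  for (k in keys) {
    cat(sprintf("  %-28s %s\n", k, paste(format(x[[k]]), collapse = ", ")))
  }
  invisible(x)
}
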