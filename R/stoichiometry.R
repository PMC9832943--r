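# Concentration and volume bookkeeping: dilution planning, reaction mix
# construction, and equimolar fragment pooling. All plans are exact
# C1V1 = C2V2 arithmetic; nothing is rounded until rendering.

#' Plan the working dilution of a primer stock
#'
#' Primers arrive as concentrated synthesis stocks (typically 100 uM)
#' and are diluted into a working plate so that adding `add_volume` to a
#' `rxn_volume` reaction yields `final_conc` in the well. The working
#' concentration is therefore `final_conc * rxn_volume / add_volume`
#' (2.5 uM at the defaults), prepared at `working_volume`.
#'
#' @param stock_conc stock concentration, uM.
#' @param final_conc target in-reaction concentration, uM.
#' @param rxn_volume reaction volume, uL.
#' @param add_volume volume of working stock added per reaction, uL.
#' @param working_volume working-stock volume prepared, uL.
#' @return a `dilution`: list with `source_volume_ul`,
#'   `diluent_volume_ul`, `working_conc`, `working_volume_ul`,
#'   `add_volume_ul`, `conc_unit`, `pass_through`.
#' @export
#' @examples
#' plan_primer_dilution()  # 0.5 uL stock + 19.5 uL water -> 2.5 uM
plan_primer_dilution <- function(stock_conc = 100, final_conc = 0.1,
                                 rxn_volume = 25, add_volume = 1.0,
                                 working_volume = 20) {
  working_conc <- final_conc * rxn_volume / add_volume
  if (stock_conc <= working_conc) {
    stop_buildplanr(
      "buildplanr_dilution_error",
      sprintf("primer stock (%g uM) is not above the working target (%g uM); use the stock directly with an adjusted add volume",
              stock_conc, working_conc)
    )
  }
  source_volume <- working_conc * working_volume / stock_conc
  new_dilution(
    source_conc = stock_conc, conc_unit = "uM",
    source_volume_ul = source_volume,
    diluent_volume_ul = working_volume - source_volume,
    working_conc = working_conc, working_volume_ul = working_volume,
    add_volume_ul = add_volume, pass_through = FALSE
  )
}

#' Plan the working dilution of a template stock
#'
#' Templates are delivered by mass: `add_volume` of the working stock
#' must carry `target_mass` (0.5 ng by default) into each reaction, so
#' the working concentration is `target_mass / add_volume`. A stock
#' already at or below the working concentration is passed through
#' undiluted with the add volume raised to `target_mass / stock_conc`;
#' a stock too dilute to deliver the target mass within 10% of the
#' reaction volume is rejected.
#'
#' @param stock_conc stock concentration, ng/uL.
#' @param target_mass template mass per reaction, ng.
#' @param add_volume volume added per reaction, uL.
#' @param working_volume working-stock volume prepared, uL.
#' @param rxn_volume reaction volume, uL (caps the pass-through add
#'   volume at 10%).
#' @return a `dilution` (see [plan_primer_dilution()]).
#' @export
#' @examples
#' plan_template_dilution(50)   # 0.2 uL stock + 19.8 uL water -> 0.5 ng/uL
#' plan_template_dilution(0.5)  # pass-through, add 1 uL
plan_template_dilution <- function(stock_conc, target_mass = 0.5,
                                   add_volume = 1.0, working_volume = 20,
                                   rxn_volume = 25) {
  if (stock_conc <= 0) {
    stop_buildplanr("buildplanr_value_error",
                    "template stock concentration must be > 0")
  }
  working_conc <- target_mass / add_volume
  if (stock_conc > working_conc) {
    source_volume <- working_conc * working_volume / stock_conc
    return(new_dilution(
      source_conc = stock_conc, conc_unit = "ng/uL",
      source_volume_ul = source_volume,
      diluent_volume_ul = working_volume - source_volume,
      working_conc = working_conc, working_volume_ul = working_volume,
      add_volume_ul = add_volume, pass_through = FALSE
    ))
  }
  # stock at or below the working concentration: use it directly,
  # adding enough volume to deliver the target mass
  add <- target_mass / stock_conc
  if (add > 0.1 * rxn_volume + 1e-12) {
    stop_buildplanr(
      "buildplanr_dilution_error",
      sprintf("template too dilute: delivering %g ng needs %.2f uL (> %.2f uL, 10%% of the reaction)",
              target_mass, add, 0.1 * rxn_volume)
    )
  }
  new_dilution(
    source_conc = stock_conc, conc_unit = "ng/uL",
    source_volume_ul = 0, diluent_volume_ul = 0,
    working_conc = stock_conc, working_volume_ul = working_volume,
    add_volume_ul = add, pass_through = TRUE
  )
}

new_dilution <- function(...) {
  structure(list(...), class = "dilution")
}

#' @export
print.dilution <- function(x, ...) {
  if (x$pass_through) {
    cat(sprintf("<dilution> pass-through: add %.2f uL of stock (%g %s)\n",
                x$add_volume_ul, x$source_conc, x$conc_unit))
  } else {
    cat(sprintf(
      "<dilution> %.2f uL stock (%g %s) + %.2f uL water -> %.2f uL at %g %s; add %.2f uL per reaction\n",
      x$source_volume_ul, x$source_conc, x$conc_unit,
      x$diluent_volume_ul, x$working_volume_ul, x$working_conc,
      x$conc_unit, x$add_volume_ul))
  }
  invisible(x)
}

#' Component volumes of one PCR mix
#'
#' Per reaction: half the volume as 2x polymerase master mix, one add of
#' each working primer, one add of working template, and water to
#' volume. At the 25 uL defaults that is 12.5 uL master mix, 1 uL of
#' each 2.5 uM primer (0.1 uM final), 1 uL of 0.5 ng/uL template
#' (0.5 ng) and 9.5 uL water. All component volumes scale linearly with
#' `rxn_volume`, so final concentrations are invariant to reaction size.
#'
#' @param rxn one row of a `design_bundle$pcrs` table (or any list with
#'   `id`, `fwd_oligo`, `rev_oligo`, `template_name`).
#' @param config a [run_config()].
#' @return tibble with columns `component`, `source_item`, `volume_ul`,
#'   `below_min` (flag: volume under the minimum pipettable volume and
#'   not a water filler).
#' @export
build_pcr_mix <- function(rxn, config = run_config()) {
  scale <- config$rxn_volume_ul / 25
  mm <- config$rxn_volume_ul / 2
  primer_add <- config$primer_add_ul * scale
  template_add <- config$template_add_ul * scale
  water <- config$rxn_volume_ul - mm - 2 * primer_add - template_add
  if (water < -1e-9) {
    stop_buildplanr("buildplanr_mix_error",
                    "overfull: components exceed the reaction volume")
  }
  steps <- tibble::tibble(
    component = c("master_mix", "fwd_primer", "rev_primer", "template",
                  "water"),
    source_item = c("master_mix", rxn$fwd_oligo, rxn$rev_oligo,
                    rxn$template_name, "water"),
    volume_ul = c(mm, primer_add, primer_add, template_add, water)
  )
  steps$below_min <- steps$volume_ul < config$min_pipette_ul - 1e-12 &
    steps$component != "water"
  steps
}

#' Component volumes of a template-removal digestion addition
#'
#' Adds water, reaction buffer and DpnI enzyme to a completed PCR:
#' 19 uL / 5 uL / 1 uL at a 25 uL reaction, scaled proportionally for
#' other reaction volumes (bringing a default reaction to 50 uL).
#'
#' @param rxn_volume completed reaction volume, uL.
#' @param config a [run_config()].
#' @return tibble as in [build_pcr_mix()].
#' @export
build_dpn1_mix <- function(rxn_volume = 25, config = run_config()) {
  scale <- rxn_volume / 25
  steps <- tibble::tibble(
    component = c("water", "buffer", "dpn1"),
    source_item = c("water", "rcutsmart_buffer", "dpn1"),
    volume_ul = c(config$dpn1_water_ul, config$dpn1_buffer_ul,
                  config$dpn1_enzyme_ul) * scale
  )
  steps$below_min <- steps$volume_ul < config$min_pipette_ul - 1e-12 &
    steps$component != "water"
  steps
}

#' Equimolar pooling volumes for a set of fragments
#'
#' Under the equal-yield assumption (every PCR produces the same mass
#' concentration of product), equal moles of each fragment are delivered
#' by volumes proportional to fragment length: the longest fragment
#' contributes `ref_volume` and fragment i contributes
#' `ref_volume * length_i / max(length)`. Any volume that falls below
#' the minimum pipettable volume is replaced by a predilution: the
#' fragment is diluted by the smallest factor (`min_pipette / v_i`) that
#' brings the addition up to exactly `min_pipette`, leaving the moles
#' delivered unchanged.
#'
#' @param fragments tibble with columns `id` and `length` (bp).
#' @param ref_volume volume of the longest fragment, uL.
#' @param min_pipette minimum pipettable volume, uL.
#' @return tibble with columns `id`, `length`, `volume_ul` (volume drawn
#'   from the — possibly prediluted — fragment well), `prediluted`,
#'   `dilution_factor` (1 when not prediluted), `relative_moles`
#'   (delivered moles relative to the longest fragment; 1 for all rows
#'   by construction).
#' @export
#' @examples
#' equimolar_volumes(tibble::tibble(id = 1:3, length = c(1000, 2000, 4000)))
equimolar_volumes <- function(fragments, ref_volume = 4.0,
                              min_pipette = 1.0) {
  fragments <- tibble::as_tibble(fragments)
  stopifnot(all(fragments$length > 0), ref_volume >= min_pipette)
  v <- ref_volume * fragments$length / max(fragments$length)
  predilute <- v < min_pipette - 1e-12
  factor <- ifelse(predilute, min_pipette / v, 1)
  volume <- ifelse(predilute, min_pipette, v)
  # moles drawn from a stock diluted by `factor`: volume / factor is the
  # equivalent undiluted volume, proportional to length
  rel <- (volume / factor) / ref_volume * max(fragments$length) /
    fragments$length
  tibble::tibble(
    id = fragments$id, length = fragments$length,
    volume_ul = volume, prediluted = predilute,
    dilution_factor = factor, relative_moles = rel
  )
}
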