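# Annealing-gradient planning and thermocycler program construction.
#
# A gradient block is modelled as `n_zones` columns at linearly spaced
# temperatures, `rows_per_zone` tube positions per column, running cold
# (left, column 1) to hot (right). Each PCR is assigned to the column
# whose temperature is closest to its optimal annealing temperature; if
# any reaction then deviates by more than its tolerance, the two gradient
# endpoints are re-optimized by grid search.

#' Gradient block geometry
#'
#' @param n_zones number of temperature zones (columns) in the block.
#' @param rows_per_zone tube positions per zone.
#' @param max_span_c maximum low-to-high temperature span the instrument
#'   supports, degC.
#' @return a `gradient_geometry` list.
#' @export
gradient_geometry <- function(n_zones = 12L, rows_per_zone = 8L,
                              max_span_c = 24) {
  stopifnot(n_zones >= 1, rows_per_zone >= 1, max_span_c > 0)
  structure(
    list(n_zones = as.integer(n_zones),
         rows_per_zone = as.integer(rows_per_zone),
         orientation = "columns_cold_to_hot",
         max_span_c = as.numeric(max_span_c)),
    class = "gradient_geometry"
  )
}

#' Per-reaction annealing-temperature tolerance
#'
#' The planner accommodates every reaction's annealing optimum to within
#' 0.4 degC by default. A design file may carry a per-reaction `delta`
#' (the tolerable variance from the optimum): a delta below the default
#' tightens the tolerance for that reaction; a larger delta never loosens
#' it beyond the default.
#'
#' @param delta per-reaction delta in degC; `NA` means unspecified.
#' @param default_tol default accommodation bound in degC.
#' @return `pmin(delta, default_tol)`, with `NA` deltas mapped to
#'   `default_tol`. Vectorized over `delta`.
#' @export
#' @examples
#' reaction_tolerance(c(0.2, 1.0, NA))
reaction_tolerance <- function(delta, default_tol = 0.4) {
  if (any(!is.na(delta) & delta < 0)) {
    stop_buildplanr("buildplanr_value_error", "delta must be >= 0")
  }
  out <- pmin(delta, default_tol)
  out[is.na(delta)] <- default_tol
  out
}

zone_temperatures <- function(t_low, t_high, n_zones) {
  if (n_zones == 1L || t_high == t_low) return(rep(t_low, n_zones))
  t_low + (seq_len(n_zones) - 1) * (t_high - t_low) / (n_zones - 1)
}

# nearest-zone assignment; ties go to the coldest qualifying zone
nearest_zones <- function(ta, zone_temps) {
  vapply(ta, function(t) which.min(abs(t - zone_temps)), integer(1))
}

score_endpoints <- function(ta, tol, t_low, t_high, n_zones) {
  zt <- zone_temperatures(t_low, t_high, n_zones)
  zone <- nearest_zones(ta, zt)
  dev <- abs(ta - zt[zone])
  list(
    zone = zone, dev = dev,
    excess = max(pmax(dev - tol, 0)),
    max_dev = max(dev)
  )
}

#' Plan an optimal annealing-temperature gradient
#'
#' Chooses gradient endpoints and a zone for every PCR so that each
#' reaction's assigned zone temperature sits within its tolerance of its
#' optimal annealing temperature, letting all reactions run in a single
#' gradient cycle. Endpoints default to the range of the annealing
#' optima; if any reaction then exceeds its tolerance (for example a
#' rigid sub-default delta), the endpoints are re-optimized by an
#' exhaustive grid search (+/- `endpoint_window_c` around the defaults in
#' `endpoint_step_c` steps), minimizing first the worst clamped excess
#' over tolerance, then the worst deviation, breaking ties toward the
#' lowest low endpoint and then the smallest span.
#'
#' @param reactions tibble with columns `id`, `ta_opt` and optionally
#'   `delta` (a `design_bundle$pcrs` table works directly).
#' @param geometry a [gradient_geometry()].
#' @param default_tol default accommodation bound, degC.
#' @param endpoint_window_c,endpoint_step_c grid-search window half-width
#'   and step for endpoint re-optimization, degC.
#' @return a `gradient_plan`: list with `t_low`, `t_high`, `zone_temps`
#'   (exact, equally spaced), `geometry`, and `assignments` — a tibble
#'   with one row per reaction (`pcr_id`, `ta_opt`, `zone` (1-based
#'   column), `position` (e.g. `"A6"`), `zone_temp`, `deviation`,
#'   `tolerance`). Tube positions are filled via [assign_tubes()].
#' @export
#' @examples
#' rx <- tibble::tibble(id = 1:5, ta_opt = c(58, 58.4, 59.1, 60.2, 64.5),
#'                      delta = NA_real_)
#' plan <- plan_gradient(rx)
#' glance(plan)
plan_gradient <- function(reactions, geometry = gradient_geometry(),
                          default_tol = 0.4, endpoint_window_c = 2.0,
                          endpoint_step_c = 0.1) {
  reactions <- tibble::as_tibble(reactions)
  if (!"delta" %in% names(reactions)) reactions$delta <- NA_real_
  n <- nrow(reactions)
  if (n < 1) {
    stop_buildplanr("buildplanr_value_error", "no reactions to plan")
  }
  capacity <- geometry$n_zones * geometry$rows_per_zone
  if (n > capacity) {
    stop_buildplanr(
      "buildplanr_layout_error",
      sprintf("%d reactions exceed the %d tube positions of the block",
              n, capacity)
    )
  }
  ta <- reactions$ta_opt
  if (any(is.na(ta))) {
    stop_buildplanr("buildplanr_value_error",
                    "every reaction needs an annealing optimum")
  }
  tol <- reaction_tolerance(reactions$delta, default_tol)

  spread <- max(ta) - min(ta)
  if (spread > geometry$max_span_c + 1e-9) {
    stop_buildplanr(
      "buildplanr_gradient_infeasible",
      sprintf(paste0("annealing optima span %.1f degC exceeds the %.1f degC",
                     " block span: split run required"),
              spread, geometry$max_span_c),
      reason = "split run"
    )
  }

  t_low <- min(ta); t_high <- max(ta)
  sc <- score_endpoints(ta, tol, t_low, t_high, geometry$n_zones)

  if (sc$excess > 1e-12) {
    # re-optimize endpoints on a 0.1 degC grid around the defaults
    ks <- seq(-round(endpoint_window_c / endpoint_step_c),
              round(endpoint_window_c / endpoint_step_c))
    best <- NULL
    for (ki in ks) {
      cand_low <- t_low + ki * endpoint_step_c
      for (kj in ks) {
        cand_high <- t_high + kj * endpoint_step_c
        if (cand_high < cand_low - 1e-12) next
        if (cand_high - cand_low > geometry$max_span_c + 1e-9) next
        s <- score_endpoints(ta, tol, cand_low, cand_high, geometry$n_zones)
        key <- c(round(s$excess, 9), round(s$max_dev, 9),
                 round(cand_low, 9), round(cand_high - cand_low, 9))
        if (is.null(best) || lex_less(key, best$key)) {
          best <- list(key = key, t_low = cand_low, t_high = cand_high, s = s)
        }
      }
    }
    t_low <- best$t_low; t_high <- best$t_high; sc <- best$s
    if (sc$excess > 1e-12) {
      stop_buildplanr(
        "buildplanr_gradient_infeasible",
        "no gradient endpoints satisfy every reaction's tolerance",
        reason = "tolerance"
      )
    }
  }

  zt <- zone_temperatures(t_low, t_high, geometry$n_zones)
  zone <- sc$zone
  # degenerate flat gradient: every zone has the same temperature, so
  # spread reactions across zones instead of stacking them in column 1
  if (t_high == t_low && n > geometry$rows_per_zone) {
    zone <- ((seq_len(n) - 1L) %/% geometry$rows_per_zone) + 1L
  }
  assignments <- tibble::tibble(
    pcr_id = reactions$id,
    ta_opt = ta,
    zone = as.integer(zone),
    position = NA_character_,
    zone_temp = zt[zone],
    deviation = abs(ta - zt[zone]),
    tolerance = tol
  )
  plan <- structure(
    list(t_low = t_low, t_high = t_high, zone_temps = zt,
         geometry = geometry, assignments = assignments),
    class = "gradient_plan"
  )
  assign_tubes(plan, geometry)
}

# lexicographic strict less-than on equal-length numeric keys
lex_less <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  FALSE
}

#' Assign tube positions within gradient zones
#'
#' Within each zone (block column), tubes fill rows A downwards in
#' ascending reaction id; the position string is row letter plus 1-based
#' column number, e.g. `"A6"` for the first tube in zone 6.
#'
#' @param plan a `gradient_plan` with zones assigned.
#' @param geometry a [gradient_geometry()].
#' @return the plan with `assignments$position` filled.
#' @export
assign_tubes <- function(plan, geometry = plan$geometry) {
  a <- plan$assignments
  a <- a[order(a$zone, a$pcr_id), ]
  pos <- character(nrow(a))
  for (z in unique(a$zone)) {
    idx <- which(a$zone == z)
    if (length(idx) > geometry$rows_per_zone) {
      stop_buildplanr(
        "buildplanr_layout_error",
        sprintf("zone %d holds %d reactions but has only %d rows",
                z, length(idx), geometry$rows_per_zone)
      )
    }
    pos[idx] <- well_name(seq_along(idx), z)
  }
  a$position <- pos
  plan$assignments <- a[order(a$pcr_id), ]
  plan
}

#' @export
print.gradient_plan <- function(x, ...) {
  cat(sprintf(
    "<gradient_plan> %d reactions, %d zones, %.1f-%.1f degC (span %.1f)\n",
    nrow(x$assignments), x$geometry$n_zones, x$t_low, x$t_high,
    x$t_high - x$t_low
  ))
  cat(sprintf("  max deviation %.3f degC (worst tolerance %.1f degC)\n",
              max(x$assignments$deviation), min(x$assignments$tolerance)))
  invisible(x)
}

#' Shared extension time for a set of reactions
#'
#' One extension time is used for the whole run, long enough for the
#' largest product: the longest length at `rate_s_per_kb`, rounded up to
#' the nearest `rounding` seconds, never below `floor`.
#'
#' @param product_lengths product lengths in bp.
#' @param rate_s_per_kb polymerase extension rate, seconds per kb.
#' @param rounding round up to this many seconds.
#' @param floor minimum extension time, seconds.
#' @return extension time in seconds.
#' @export
#' @examples
#' extension_time(c(800, 2400, 3200))  # 100 s
extension_time <- function(product_lengths, rate_s_per_kb = 30,
                           rounding = 5, floor = 10) {
  if (length(product_lengths) == 0) {
    stop_buildplanr("buildplanr_value_error", "no product lengths given")
  }
  if (any(product_lengths <= 0)) {
    stop_buildplanr("buildplanr_value_error", "product lengths must be > 0")
  }
  raw <- max(product_lengths) / 1000 * rate_s_per_kb
  max(floor, ceiling(raw / rounding) * rounding)
}

#' Thermocycler program container
#'
#' @param label short program name.
#' @param steps tibble with columns `temp_low_c`, `temp_high_c`
#'   (equal for constant-temperature steps) and `duration_s`.
#' @param cycled optional `c(start, end, n_cycles)`: the (1-based,
#'   inclusive) step range repeated `n_cycles` times.
#' @return a `thermo_program`.
#' @export
thermo_program <- function(label, steps, cycled = NULL) {
  steps <- tibble::as_tibble(steps)
  stopifnot(all(c("temp_low_c", "temp_high_c", "duration_s") %in% names(steps)),
            all(steps$duration_s > 0))
  if (!is.null(cycled)) {
    stopifnot(length(cycled) == 3, cycled[1] >= 1, cycled[2] <= nrow(steps),
              cycled[1] <= cycled[2], cycled[3] >= 1)
    cycled <- as.integer(cycled)
  }
  structure(list(label = label, steps = steps, cycled = cycled),
            class = "thermo_program")
}

#' Total run time of a thermocycler program
#'
#' Non-cycled steps count once; cycled steps count `n_cycles` times.
#'
#' @param program a [thermo_program()].
#' @return duration in seconds.
#' @export
program_duration <- function(program) {
  d <- program$steps$duration_s
  if (is.null(program$cycled)) return(sum(d))
  idx <- seq.int(program$cycled[1], program$cycled[2])
  sum(d[-idx]) + program$cycled[3] * sum(d[idx])
}

#' Gradient amplification program
#'
#' Initial denaturation 30 s at 98 degC; `n_cycles` of 10 s at 98 degC,
#' 30 s annealing across the plan's gradient, extension at 72 degC; then
#' a final 5 min extension at 72 degC. A flat plan renders the annealing
#' step as a single temperature.
#'
#' @param plan a `gradient_plan`.
#' @param ext_s extension time in seconds (see [extension_time()]).
#' @param n_cycles number of amplification cycles.
#' @param final_ext_s final extension, seconds.
#' @return a `thermo_program` labelled `"amplification"`.
#' @export
build_pcr_program <- function(plan, ext_s, n_cycles = 34L,
                              final_ext_s = 300) {
  steps <- tibble::tibble(
    temp_low_c = c(98, 98, plan$t_low, 72, 72),
    temp_high_c = c(98, 98, plan$t_high, 72, 72),
    duration_s = c(30, 10, 30, ext_s, final_ext_s)
  )
  thermo_program("amplification", steps, cycled = c(2L, 4L, n_cycles))
}

#' Template-removal digestion program
#'
#' 30 min at 37 degC, then heat inactivation for 20 min at 65 degC.
#'
#' @return a `thermo_program` labelled `"dpn1"`.
#' @export
build_dpn1_program <- function() {
  thermo_program(
    "dpn1",
    tibble::tibble(temp_low_c = c(37, 65), temp_high_c = c(37, 65),
                   duration_s = c(1800, 1200))
  )
}

#' Golden Gate restriction-ligation cycling program
#'
#' Alternates type-IIS digestion and ligation temperatures, then a final
#' digestion hold and heat inactivation. All temperatures and durations
#' are configurable; the defaults follow standard one-pot
#' restriction-ligation practice.
#'
#' @param n_cycles digestion/ligation cycles.
#' @param digest_c,ligate_c cycle temperatures, degC.
#' @param hold_s per-step duration within the cycle, seconds.
#' @param final_c,final_s final digestion hold.
#' @param kill_c,kill_s heat-inactivation step.
#' @return a `thermo_program` labelled `"golden_gate"`.
#' @export
build_goldengate_program <- function(n_cycles = 30L, digest_c = 37,
                                     ligate_c = 16, hold_s = 300,
                                     final_c = 50, final_s = 300,
                                     kill_c = 80, kill_s = 600) {
  steps <- tibble::tibble(
    temp_low_c = c(digest_c, ligate_c, final_c, kill_c),
    temp_high_c = c(digest_c, ligate_c, final_c, kill_c),
    duration_s = c(hold_s, hold_s, final_s, kill_s)
  )
  cycled <- if (n_cycles > 1) c(1L, 2L, as.integer(n_cycles)) else NULL
  thermo_program("golden_gate", steps, cycled = cycled)
}

#' @export
print.thermo_program <- function(x, ...) {
  cat(sprintf("<thermo_program> %s (%d steps, %.0f s total)\n",
              x$label, nrow(x$steps), program_duration(x)))
  for (i in seq_len(nrow(x$steps))) {
    s <- x$steps[i, ]
    temp <- if (s$temp_low_c == s$temp_high_c) {
      sprintf("%.1f degC", s$temp_low_c)
    } else {
      sprintf("gradient %.1f-%.1f degC", s$temp_low_c, s$temp_high_c)
    }
    tag <- if (!is.null(x$cycled) && i >= x$cycled[1] && i <= x$cycled[2]) {
      sprintf("  [x%d]", x$cycled[3])
    } else ""
    cat(sprintf("  %d. %s for %.0f s%s\n", i, temp, s$duration_s, tag))
  }
  invisible(x)
}
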