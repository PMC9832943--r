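# ggplot2 views of planner objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a gradient plan as the physical block layout
#'
#' Draws the gradient block (columns cold to hot, rows A down), one tile
#' per zone column coloured by zone temperature, with each reaction's
#' tube position marked and labelled by reaction id.
#'
#' @param object a `gradient_plan`.
#' @param ... unused.
#' @return a ggplot.
#' @export
#' @examples
#' rx <- tibble::tibble(id = 1:5, ta_opt = c(58, 58.4, 59.1, 60.2, 64.5))
#' autoplot(plan_gradient(rx))
autoplot.gradient_plan <- function(object, ...) {
  geom <- object$geometry
  block <- tidyr::expand_grid(
    col = seq_len(geom$n_zones), row = seq_len(geom$rows_per_zone))
  block$zone_temp <- object$zone_temps[block$col]
  a <- object$assignments
  rc <- purrr::map(a$position, split_well)
  tubes <- tibble::tibble(
    col = purrr::map_int(rc, "col"), row = purrr::map_int(rc, "row"),
    label = as.character(a$pcr_id), ta_opt = a$ta_opt)
  ggplot2::ggplot(block, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$zone_temp),
                       colour = "grey80") +
    ggplot2::geom_point(data = tubes, size = 7, shape = 21,
                        fill = "white", colour = "black") +
    ggplot2::geom_text(data = tubes, ggplot2::aes(label = .data$label),
                       size = 3) +
    ggplot2::scale_y_reverse(
      breaks = seq_len(geom$rows_per_zone),
      labels = LETTERS[seq_len(geom$rows_per_zone)]) +
    ggplot2::scale_x_continuous(breaks = seq_len(geom$n_zones)) +
    ggplot2::scale_fill_viridis_c(option = "plasma") +
    ggplot2::labs(
      x = "block column (cold to hot)", y = "row",
      fill = "zone temp (degC)",
      title = sprintf("Annealing gradient %.1f-%.1f degC",
                      object$t_low, object$t_high)) +
    ggplot2::theme_minimal()
}

#' Plot a thermocycler program as a temperature profile
#'
#' One cycle of any cycled block is shown, annotated with its repeat
#' count; gradient steps are drawn as a ribbon between the low and high
#' endpoint temperatures.
#'
#' @param object a `thermo_program`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.thermo_program <- function(object, ...) {
  s <- object$steps
  n <- nrow(s)
  t_end <- cumsum(s$duration_s)
  t_start <- t_end - s$duration_s
  seg <- tibble::tibble(
    xmin = t_start / 60, xmax = t_end / 60,
    lo = s$temp_low_c, hi = s$temp_high_c,
    cycled = if (is.null(object$cycled)) rep(FALSE, n) else
      seq_len(n) >= object$cycled[1] & seq_len(n) <= object$cycled[2]
  )
  p <- ggplot2::ggplot(seg) +
    ggplot2::geom_rect(
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = .data$lo, ymax = .data$hi + 0.8,
                   fill = .data$cycled), colour = "grey30") +
    ggplot2::scale_fill_manual(
      values = c(`FALSE` = "grey85", `TRUE` = "steelblue"),
      labels = c(`FALSE` = "once", `TRUE` = if (is.null(object$cycled))
        "cycled" else sprintf("x%d cycles", object$cycled[3]))) +
    ggplot2::labs(x = "time within one pass (min)",
                  y = "temperature (degC)", fill = NULL,
                  title = sprintf("Program: %s", object$label)) +
    ggplot2::theme_minimal()
  p
}
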