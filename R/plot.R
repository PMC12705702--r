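#' Plot a filament side view
#'
#' Protomer centroids in the unrolled cylindrical frame (azimuth vs axial
#' coordinate), which makes the helical strands and the base layer visible
#' at a glance.
#'
#' @param object A [filament()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.filament <- function(object, ...) {
  td <- tidy(object)
  td$azimuth <- azimuth_deg(object, cbind(td$x, td$y, td$z))
  ggplot2::ggplot(td, ggplot2::aes(x = .data$azimuth, y = .data$axial)) +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$index %% 6)),
                        size = 3, show.legend = FALSE) +
    ggplot2::geom_text(ggplot2::aes(label = .data$index), vjust = -1,
                       size = 3) +
    ggplot2::labs(x = "azimuth (deg)", y = "axial coordinate (Å)",
                  title = "Filament lattice (unrolled)") +
    ggplot2::theme_minimal()
}

honeycomb_layout <- function(shell) {
  shell |>
    group_by(.data$half) |>
    arrange(.data$offset, .by_group = TRUE) |>
    mutate(xpos = row_number() - (n() + 1) / 2,
           ypos = ifelse(.data$half == "top", 1, -1)) |>
    ungroup()
}

#' Honeycomb diagram of a classified neighborhood
#'
#' Schematic center-plus-shell diagram: one tile per shell contact, placed
#' on its axial half, labeled with its interface surface and contact count.
#'
#' @param object A `honeycomb` (see [extract_honeycomb()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.honeycomb <- function(object, ...) {
  sh <- honeycomb_layout(tidy(object))
  lab <- if ("surface" %in% names(sh) && !all(is.na(sh$surface)))
    paste0(sh$surface, "\n", sh$n_contacts) else as.character(sh$n_contacts)
  sh$label <- lab
  ggplot2::ggplot(sh, ggplot2::aes(x = .data$xpos, y = .data$ypos)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$half), width = 0.9,
                       height = 0.9, alpha = 0.5) +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 3) +
    ggplot2::annotate("tile", x = 0, y = 0, width = 0.9, height = 0.9,
                      fill = "steelblue", alpha = 0.6) +
    ggplot2::annotate("text", x = 0, y = 0, label = "center") +
    ggplot2::labs(x = NULL, y = NULL, title = "Honeycomb neighborhood") +
    ggplot2::theme_void() +
    ggplot2::theme(legend.position = "none")
}

#' Honeycomb score diagram for a compatibility report
#'
#' Mirrors the honeycomb layout with per-interface scores and the
#' top-/bottom-half sums.
#'
#' @param object A `compat_report` (see [score_shell()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.compat_report <- function(object, ...) {
  sh <- honeycomb_layout(object$per_interface)
  sh$label <- paste0(ifelse(is.na(sh$surface), "", paste0(sh$surface, "\n")),
                     "score ", sh$score,
                     ifelse(sh$clash_count > 0,
                            paste0("\n", sh$clash_count, " clash"), ""))
  subtitle <- sprintf("%s in %s shell: top %g, bottom %g, total %g",
                      object$threaded_monomer, object$template,
                      object$half_sums[["top"]], object$half_sums[["bottom"]],
                      object$total)
  ggplot2::ggplot(sh, ggplot2::aes(x = .data$xpos, y = .data$ypos)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$clash_count > 0),
                       width = 0.9, height = 0.9, alpha = 0.6) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70",
                                          `TRUE` = "indianred")) +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 3) +
    ggplot2::annotate("tile", x = 0, y = 0, width = 0.9, height = 0.9,
                      fill = "steelblue", alpha = 0.6) +
    ggplot2::annotate("text", x = 0, y = 0,
                      label = object$threaded_monomer) +
    ggplot2::labs(title = "Cross-threading compatibility",
                  subtitle = subtitle, x = NULL, y = NULL) +
    ggplot2::theme_void() +
    ggplot2::theme(legend.position = "none")
}
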