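#' Plot a modification census
#'
#' Bar chart of modified-position counts per class, faceted by chain.
#'
#' @param object A `ribo_census`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ribo_census
#' @export
autoplot.ribo_census <- function(object, ...) {
  object$class_counts |>
    ggplot2::ggplot(ggplot2::aes(x = .data$class, y = .data$n,
                                 fill = .data$class)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_wrap(ggplot2::vars(.data$chain)) +
    ggplot2::labs(x = NULL, y = "modified positions",
                  title = "Modification census") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot ion classification results
#'
#' Mean ligand distance against octahedral geometry score, coloured by the
#' assigned label, with the Mg and K distance windows shaded.
#'
#' @param sites Tibble from [classify_ions()].
#' @param thresholds See [ribomod_thresholds()].
#' @return A ggplot object.
#' @export
plot_ion_sites <- function(sites, thresholds = ribomod_thresholds()) {
  th <- thresholds
  sites |>
    filter(!is.na(.data$mean_distance)) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$mean_distance,
                                 y = .data$geometry_score_oct,
                                 colour = .data$label)) +
    ggplot2::annotate("rect", xmin = th$mg_window[1], xmax = th$mg_window[2],
                      ymin = -Inf, ymax = Inf, alpha = 0.08, fill = "green") +
    ggplot2::annotate("rect", xmin = th$k_window[1], xmax = th$k_window[2],
                      ymin = -Inf, ymax = Inf, alpha = 0.08, fill = "purple") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "mean ligand distance (Å)",
                  y = "octahedral deviation (°)",
                  title = "Coordination-site classification") +
    ggplot2::theme_minimal()
}

#' Plot pseudouridine assessments
#'
#' Acceptor distance against out-of-plane offset, coloured by verdict, with
#' the distance cutoff and coplanarity tolerance drawn as decision lines.
#'
#' @param assessments Tibble from [validate_modeled_psu()] or
#'   [screen_uridines()].
#' @param cutoff,coplanarity_tol The thresholds used for the assessments.
#' @return A ggplot object.
#' @export
plot_psu_assessments <- function(assessments, cutoff = 3.2,
                                 coplanarity_tol = 1.0) {
  assessments |>
    filter(!is.na(.data$distance)) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$distance, y = .data$out_of_plane,
                                 colour = .data$verdict)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_vline(xintercept = cutoff, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = coplanarity_tol, linetype = "dashed") +
    ggplot2::labs(x = "acceptor distance (Å)",
                  y = "out-of-plane offset (Å)",
                  title = "Pseudouridine binding-pattern screen") +
    ggplot2::theme_minimal()
}

#' Plot a hydrogen-bond network
#'
#' 2D projection (x/y) of nodes and edges; waters and metals are
#' distinguished by shape, seeds are enlarged.
#'
#' @param object A `ribo_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ribo_network
#' @export
autoplot.ribo_network <- function(object, ...) {
  nodes <- object$nodes |>
    mutate(
      role = case_when(
        .data$serial %in% object$seeds ~ "seed",
        .data$comp_id == "HOH" ~ "water",
        .data$element %in% metal_elements ~ "metal",
        TRUE ~ "polymer"
      )
    )
  segs <- object$edges |>
    left_join(nodes |> select("serial", x0 = "x", y0 = "y"),
              by = c(from = "serial")) |>
    left_join(nodes |> select("serial", x1 = "x", y1 = "y"),
              by = c(to = "serial"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = segs,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1,
                   yend = .data$y1, linetype = .data$kind),
      colour = "grey50") +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, colour = .data$role,
                   size = .data$role == "seed")) +
    ggplot2::scale_size_manual(values = c(`TRUE` = 3, `FALSE` = 1.5),
                               guide = "none") +
    ggplot2::labs(x = "x (Å)", y = "y (Å)",
                  title = "Hydrogen-bond network") +
    ggplot2::theme_minimal()
}
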