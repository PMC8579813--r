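# ggplot2 views of the package's result objects.

#' Sequence-logo-style view of a PWM
#'
#' Stacked per-column base contributions scaled by column information
#' content (bits); unmodeled spacer columns appear empty.
#'
#' @param object A `pwm_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pwm_model <- function(object, ...) {
  dat <- logo_data(object) |>
    mutate(height = .data$prob * .data$ic * .data$modeled)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$position, y = .data$height,
                                    fill = .data$base)) +
    ggplot2::geom_col(width = 0.9) +
    ggplot2::scale_fill_manual(values = c(A = "#109648", C = "#255C99",
                                          G = "#F7B32B", T = "#D62839")) +
    ggplot2::labs(x = "position (bp)", y = "information content (bits)",
                  title = sprintf("%s  %s", object$tf_id,
                                  consensus_string(object))) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.pwm_model
#' @export
autoplot.motif_discovery <- function(object, ...) autoplot(object$motif, ...)

#' Conservation profile of a regulon
#'
#' Member operons ranked by the number of species in which the site is
#' conserved, against the per-operon quorum.
#'
#' @param object A `regulon`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.regulon <- function(object, ...) {
  dat <- object$members |>
    mutate(group_id = stats::reorder(.data$group_id, .data$n_species_hit))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$group_id,
                                    y = .data$n_species_hit)) +
    ggplot2::geom_col(fill = "#255C99") +
    ggplot2::geom_point(ggplot2::aes(y = .data$quorum), shape = 95, size = 8,
                        colour = "#D62839") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "species with a conserved site",
                  title = sprintf("%s regulon (quorum marked)", object$tf_id)) +
    ggplot2::theme_minimal()
}

#' Heatmap of the DE cross-tabulation
#'
#' @param object A `de_table`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.de_table <- function(object, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(x = .data$cond_down, y = .data$cond_up,
                               fill = .data$n_de)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%d (%d)", .data$n_de, .data$n_de_members)),
      colour = "white") +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "relative to", y = "up-regulated on",
                  fill = sprintf("genes >%.1f", object$threshold)) +
    ggplot2::theme_minimal()
}
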