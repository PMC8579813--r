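# broom-style tidiers for the package's fitted objects.

#' Tidy a PWM into one row per column and base
#'
#' @param x A `pwm_model`.
#' @param ... Unused.
#' @return Tibble: `position` (1-based over the span), `base`, `count`,
#'   `prob`, `weight` (log2-odds), `modeled`.
#' @export
tidy.pwm_model <- function(x, ...) {
  m <- length(x$layout$offsets)
  tibble(position = rep(x$layout$offsets + 1L, each = 4),
         base = rep(DNA_BASES, m),
         count = as.vector(x$counts),
         prob = as.vector(sweep(x$counts + x$alpha * x$background, 2,
                                colSums(x$counts) + x$alpha, "/")),
         weight = as.vector(x$weights),
         modeled = TRUE) |>
    tidyr::complete(position = seq_len(x$layout$span), base = DNA_BASES,
                    fill = list(modeled = FALSE)) |>
    arrange(.data$position, .data$base)
}

#' @export
glance.pwm_model <- function(x, ...) {
  bg <- x$background
  probs <- sweep(x$counts + x$alpha * bg, 2, colSums(x$counts) + x$alpha, "/")
  tibble(tf_id = x$tf_id, mode = x$mode, span = x$layout$span,
         n_modeled = length(x$layout$offsets), n_sites = x$n_sites,
         threshold = x$threshold, mean_ic = mean_column_ic(probs, bg),
         consensus = consensus_string(x))
}

#' Tidy a discovery result into its training sites
#'
#' @param x A `motif_discovery`.
#' @param ... Unused.
#' @return The per-region best-site tibble.
#' @export
tidy.motif_discovery <- function(x, ...) x$sites

#' @export
glance.motif_discovery <- function(x, ...) {
  tibble(geometry = geometry_label(x$geometry), span = x$span,
         n_sites = nrow(x$sites), gamma = x$gamma, loglik = x$loglik,
         mean_ic = x$mean_ic, consensus = consensus_string(x),
         low_confidence = x$low_confidence)
}

#' Tidy a regulon into one row per member operon
#'
#' @param x A `regulon`.
#' @param ... Unused.
#' @return The member tibble with conservation counts.
#' @export
tidy.regulon <- function(x, ...) x$members

#' @export
glance.regulon <- function(x, ...) {
  tibble(tf_id = x$tf_id, n_members = nrow(x$members),
         n_species = length(x$species), mode = x$mode,
         quorum_fraction = x$quorum_fraction, quorum_min = x$quorum_min,
         unverified = x$unverified)
}

#' Tidy a DE cross-tabulation into one row per condition pair
#'
#' @param x A `de_table`.
#' @param ... Unused.
#' @return The per-pair count tibble.
#' @export
tidy.de_table <- function(x, ...) x$table

#' @export
glance.de_table <- function(x, ...) {
  tibble(n_conditions = length(x$conditions), threshold = x$threshold,
         moderate_lo = x$moderate[1], moderate_hi = x$moderate[2],
         n_union = x$n_union, n_members = length(x$regulon_members))
}
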