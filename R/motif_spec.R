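# Motif geometry.  Three intrinsic symmetry modes are supported:
#   * palindrome: a single self-reverse-complementary element of width w
#     (search grid 20-24 bp by default);
#   * direct_repeat: two identical boxes of `unit` bp at a start-to-start
#     periodicity of 21 or 32 bp (two or three DNA helical turns), the linker
#     unmodeled;
#   * inverted_repeat_spaced: two reverse-complementary half-sites of `unit`
#     bp separated by an unmodeled spacer (the "GGGAC-(27)-GTCCC" layout).

#' Specify a motif search space
#'
#' @param mode One of `"palindrome"`, `"direct_repeat"`,
#'   `"inverted_repeat_spaced"`.
#' @param width_range Palindrome width range in bp (default `c(20, 24)`).
#' @param unit_range Repeated-unit width range in bp for the repeat modes
#'   (default `c(7, 11)`).
#' @param periods Candidate start-to-start periodicities in bp for
#'   `direct_repeat` (default `c(21, 32)`).
#' @param spacer_range Spacer range in bp for `inverted_repeat_spaced`
#'   (default `c(20, 30)`).
#' @return A `motif_spec` list.
#' @export
motif_spec <- function(mode = c("palindrome", "direct_repeat",
                                "inverted_repeat_spaced"),
                       width_range = c(20, 24), unit_range = c(7, 11),
                       periods = c(21, 32), spacer_range = c(20, 30)) {
  mode <- match.arg(mode)
  spec <- list(mode = mode, width_range = as.integer(width_range),
               unit_range = as.integer(unit_range),
               periods = as.integer(periods),
               spacer_range = as.integer(spacer_range))
  if (mode == "palindrome" && width_range[1] > width_range[2])
    abort("empty width range")
  if (mode == "direct_repeat" && !any(spec$periods > spec$unit_range[1]))
    abort("no period exceeds the smallest unit width")
  structure(spec, class = "motif_spec")
}

# enumerate candidate geometries (one row each), ordered by increasing span
geometry_grid <- function(spec) {
  grid <- switch(spec$mode,
    palindrome = tibble(
      mode = "palindrome",
      width = seq(spec$width_range[1], spec$width_range[2]),
      unit = NA_integer_, period = NA_integer_, spacer = NA_integer_),
    direct_repeat = tidyr::expand_grid(
      unit = seq(spec$unit_range[1], spec$unit_range[2]),
      period = spec$periods) |>
      filter(.data$period > .data$unit) |>
      mutate(mode = "direct_repeat", width = NA_integer_,
             spacer = NA_integer_) |>
      select("mode", "width", "unit", "period", "spacer"),
    inverted_repeat_spaced = tidyr::expand_grid(
      unit = seq(spec$unit_range[1], spec$unit_range[2]),
      spacer = seq(spec$spacer_range[1], spec$spacer_range[2])) |>
      mutate(mode = "inverted_repeat_spaced", width = NA_integer_,
             period = NA_integer_) |>
      select("mode", "width", "unit", "period", "spacer"))
  grid$span <- purrr::pmap_int(grid, function(mode, width, unit, period, spacer, ...)
    geometry_layout(list(mode = mode, width = width, unit = unit,
                         period = period, spacer = spacer))$span)
  arrange(grid, .data$span)
}

# modeled-column offsets (0-based within the span) and the symmetry pairing
geometry_layout <- function(g) {
  if (g$mode == "palindrome") {
    w <- g$width
    list(offsets = 0:(w - 1L), span = as.integer(w),
         partner = (w - 1L):0L, comp = rep(TRUE, w))
  } else if (g$mode == "direct_repeat") {
    u <- g$unit; p <- g$period
    list(offsets = c(0:(u - 1L), p + 0:(u - 1L)), span = as.integer(p + u),
         partner = c(u + 0:(u - 1L), 0:(u - 1L)), comp = rep(FALSE, 2L * u))
  } else if (g$mode == "inverted_repeat_spaced") {
    u <- g$unit; s <- g$spacer
    list(offsets = c(0:(u - 1L), u + s + 0:(u - 1L)),
         span = as.integer(2L * u + s),
         partner = (2L * u - 1L):0L, comp = rep(TRUE, 2L * u))
  } else abort(sprintf("unknown motif mode '%s'", g$mode))
}

# is a motif element its own reverse complement (strand-degenerate)?
geometry_self_revcomp <- function(g) {
  g$mode %in% c("palindrome", "inverted_repeat_spaced")
}

geometry_label <- function(g) {
  switch(g$mode,
    palindrome = sprintf("palindrome_w%d", g$width),
    direct_repeat = sprintf("direct_u%d_p%d", g$unit, g$period),
    inverted_repeat_spaced = sprintf("spacedIR_u%d_s%d", g$unit, g$spacer))
}

parse_geometry_label <- function(label) {
  if (grepl("^palindrome_w(\\d+)$", label)) {
    list(mode = "palindrome",
         width = as.integer(sub("^palindrome_w", "", label)),
         unit = NA_integer_, period = NA_integer_, spacer = NA_integer_)
  } else if (grepl("^direct_u(\\d+)_p(\\d+)$", label)) {
    m <- as.integer(strsplit(sub("^direct_u", "", label), "_p")[[1]])
    list(mode = "direct_repeat", width = NA_integer_, unit = m[1],
         period = m[2], spacer = NA_integer_)
  } else if (grepl("^spacedIR_u(\\d+)_s(\\d+)$", label)) {
    m <- as.integer(strsplit(sub("^spacedIR_u", "", label), "_s")[[1]])
    list(mode = "inverted_repeat_spaced", width = NA_integer_, unit = m[1],
         period = NA_integer_, spacer = m[2])
  } else abort(sprintf("cannot parse geometry label '%s'", label))
}
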