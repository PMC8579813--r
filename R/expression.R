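# Differential-expression overlay.  Input is a replicate-averaged gene x
# condition matrix of log2 expression values (tibble: `gene` column plus one
# column per condition); fold changes are differences of stored log2 values.

#' Read an expression matrix
#'
#' @param path TSV with a `gene` column and one numeric column per condition.
#' @return Wide tibble.
#' @export
read_expression <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"gene" %in% names(tab)) abort("expression table needs a 'gene' column")
  if (anyDuplicated(tab$gene)) abort("duplicate gene ids in expression table")
  vals <- as.matrix(tab[, setdiff(names(tab), "gene")])
  if (any(!is.finite(vals))) abort("expression values must be finite")
  as_tibble(tab)
}

#' Per-gene log2 fold change between two conditions
#'
#' Values are already log2, so the fold change is the difference of stored
#' values.
#'
#' @param expr Wide expression tibble (`gene` + condition columns).
#' @param cond_a,cond_b Condition names (`a` over `b`).
#' @return Tibble with `gene`, `log2fc`.
#' @export
log2fc <- function(expr, cond_a, cond_b) {
  for (cond in c(cond_a, cond_b)) {
    if (!cond %in% names(expr))
      abort(sprintf("unknown condition '%s'", cond))
  }
  tibble(gene = expr$gene, log2fc = expr[[cond_a]] - expr[[cond_b]])
}

#' Differential-expression cross-tabulation
#'
#' For every ordered condition pair, counts genes up in the row condition
#' relative to the column condition (strictly above `threshold` log2 units),
#' with a parenthetical sub-count of regulon members, plus a separately
#' annotated moderate band (fold change within `moderate`, boundaries
#' included).  The number of genes up in at least one pair is reported as
#' `n_union`.
#'
#' @param expr Wide expression tibble.
#' @param threshold Strict log2 fold-change cutoff for DE (default 2).
#' @param moderate Closed moderate band (default `c(1.5, 2)`); genes at
#'   exactly `threshold` fall in the moderate band, not the DE set.
#' @param regulon_members Optional character vector of regulon member genes
#'   for the parenthetical sub-counts.
#' @return A `de_table` object: `$table` of per-pair counts, `$fc` of
#'   per-gene per-pair fold changes, and summary fields.
#' @export
de_crosstab <- function(expr, threshold = 2, moderate = c(1.5, 2),
                        regulon_members = NULL) {
  conds <- setdiff(names(expr), "gene")
  if (length(conds) < 2) abort("need at least 2 conditions")
  members <- regulon_members %||% character(0)
  pairs <- tidyr::expand_grid(cond_up = conds, cond_down = conds) |>
    filter(.data$cond_up != .data$cond_down)
  fc <- purrr::pmap(pairs, function(cond_up, cond_down) {
    mutate(log2fc(expr, cond_up, cond_down),
           cond_up = cond_up, cond_down = cond_down)
  }) |> bind_rows()
  fc <- fc |>
    mutate(de = .data$log2fc > threshold,
           moderate = .data$log2fc >= moderate[1] & .data$log2fc <= moderate[2],
           member = .data$gene %in% members)
  table <- fc |>
    group_by(.data$cond_up, .data$cond_down) |>
    summarise(n_de = sum(.data$de), n_de_members = sum(.data$de & .data$member),
              n_moderate = sum(.data$moderate),
              n_moderate_members = sum(.data$moderate & .data$member),
              .groups = "drop")
  structure(list(
    table = table, fc = fc, conditions = conds,
    threshold = threshold, moderate = moderate,
    regulon_members = members,
    n_union = dplyr::n_distinct(fc$gene[fc$de])
  ), class = "de_table")
}

#' @export
print.de_table <- function(x, ...) {
  cat(sprintf("<de_table> %d condition(s); %d gene(s) up >%.1f log2 units in >=1 pair\n",
              length(x$conditions), x$n_union, x$threshold))
  wide <- x$table |>
    mutate(cell = sprintf("%d (%d)", .data$n_de, .data$n_de_members)) |>
    select("cond_up", "cond_down", "cell") |>
    tidyr::pivot_wider(names_from = "cond_down", values_from = "cell",
                       values_fill = "-")
  print(wide)
  invisible(x)
}

#' Write a DE cross-tabulation as TSV
#'
#' Square layout with `count (member-subcount)` cells, rows = up-condition.
#'
#' @param de A `de_table`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_de_crosstab <- function(de, path) {
  wide <- de$table |>
    mutate(cell = sprintf("%d (%d)", .data$n_de, .data$n_de_members)) |>
    select("cond_up", "cond_down", "cell") |>
    tidyr::pivot_wider(names_from = "cond_down", values_from = "cell",
                       values_fill = "-")
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}

#' Concordance between regulon membership and substrate induction
#'
#' For each regulon, checks that its members are up-regulated (above the DE
#' threshold) on the regulon's expected inducing conditions against every
#' non-inducing condition.  Members failing any expected pair are flagged
#' discordant; members whose weakest expected fold change falls in the
#' moderate band are annotated.
#'
#' @param de A `de_table` from [de_crosstab()].
#' @param regulons Named list of member-gene character vectors (or a single
#'   `regulon`-like vector).
#' @param induction_map Named list (or tibble `regulon`/`condition`) of
#'   expected inducing conditions per regulon.
#' @return Tibble with one row per regulon: `n_members`, `n_assessed`,
#'   `concordance`, `discordant` (list column), `n_moderate`,
#'   `assessable`.
#' @export
regulon_concordance <- function(de, regulons, induction_map) {
  if (is.character(regulons)) regulons <- list(regulon = regulons)
  if (is.data.frame(induction_map)) {
    induction_map <- split(induction_map$condition, induction_map$regulon)
  }
  purrr::imap(regulons, function(members, name) {
    inducing <- intersect(induction_map[[name]], de$conditions)
    other <- setdiff(de$conditions, inducing)
    present <- intersect(members, unique(de$fc$gene))
    if (length(present) == 0 || length(inducing) == 0 || length(other) == 0) {
      return(tibble(regulon = name, n_members = length(members),
                    n_assessed = 0L, concordance = NA_real_,
                    discordant = list(character(0)), n_moderate = 0L,
                    assessable = FALSE))
    }
    sub <- de$fc |>
      filter(.data$gene %in% present, .data$cond_up %in% inducing,
             .data$cond_down %in% other) |>
      group_by(.data$gene) |>
      summarise(min_fc = min(.data$log2fc), all_de = all(.data$de))
    tibble(regulon = name, n_members = length(members),
           n_assessed = nrow(sub),
           concordance = mean(sub$all_de),
           discordant = list(sub$gene[!sub$all_de]),
           n_moderate = sum(sub$min_fc >= de$moderate[1] &
                              sub$min_fc <= de$moderate[2]),
           assessable = TRUE)
  }) |> bind_rows()
}
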