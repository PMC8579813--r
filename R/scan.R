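# Whole-genome PWM scanning and cross-genome consistency filtering.

#' Scan genomes' upstream regions with a motif
#'
#' Scores the upstream window (up to `window` bp before the translation
#' start) of every first-in-operon gene of every genome, keeping hits at or
#' above the motif's minimum-training-score threshold.  Genomes lacking an
#' ortholog of the transcription factor are skipped, mirroring the practice
#' of scanning only genomes that encode the regulator.
#'
#' @param motif A `pwm_model`.
#' @param genomes Named list of [genome_record()]s.
#' @param window Scan window in bp upstream of the translation start
#'   (default 300).
#' @param tf_species Optional character vector of species that carry the TF
#'   ortholog; others are skipped with a message.  Default: scan all.
#' @param stop_at_coding Truncate windows at upstream genes (default TRUE).
#' @param operon_max_gap Same-strand gap rule for operon grouping in bp
#'   (default 100); scanning anchors at first-in-operon genes.
#' @return Tibble of hits (`species_id`, `locus_tag`, `offset`, `strand`,
#'   `score`, `site_seq`).
#' @export
scan_genomes <- function(motif, genomes, window = 300, tf_species = NULL,
                         stop_at_coding = TRUE, operon_max_gap = 100) {
  if (window <= 0) {
    return(tibble(species_id = character(0), locus_tag = character(0),
                  offset = integer(0), strand = character(0),
                  score = numeric(0), site_seq = character(0)))
  }
  species <- names(genomes)
  if (!is.null(tf_species)) {
    skipped <- setdiff(species, tf_species)
    if (length(skipped) > 0)
      inform(sprintf("scan_genomes: skipping %d genome(s) without a TF ortholog: %s",
                     length(skipped), paste(skipped, collapse = ", ")))
    species <- intersect(species, tf_species)
  }
  purrr::map(species, function(sp) {
    gnm <- genomes[[sp]]
    anchors <- assign_operons(gnm$genes, max_gap = operon_max_gap) |>
      filter(.data$first_in_operon)
    purrr::map(anchors$locus_tag, function(lt) {
      reg <- extract_upstream(gnm, lt, max_len = window,
                              stop_at_coding = stop_at_coding)
      if (nchar(reg$seq) < motif$layout$span) return(NULL)
      score_region(motif, reg)
    }) |> bind_rows()
  }) |> bind_rows()
}

#' Cross-genome consistency filter
#'
#' Retains a candidate target operon only when hits recur upstream of its
#' orthologs in enough genomes: at least
#' `max(quorum_min, ceiling(quorum_fraction * n_eligible))` species, where a
#' species is eligible when it carries both the TF ortholog and the operon
#' ortholog.  This is the false-positive removal step of phylogenetic
#' footprinting.
#'
#' @param hits Hit tibble from [scan_genomes()].
#' @param groups Ortholog tibble (`group_id`, `species_id`, `locus_tag`).
#' @param quorum_fraction Fraction of eligible species required (default 0.5).
#' @param quorum_min Absolute minimum number of species (default 2).
#' @param species Species that were scanned (carry the TF); default: all
#'   species present in `groups`.
#' @param tf_id Identifier recorded on the regulon.
#' @return A `regulon` object; its `members` tibble has one row per retained
#'   operon with conservation counts and the best hit per species in
#'   `$hits`.  A single-species scan returns all hit operons flagged
#'   unverified.
#' @export
consistency_filter <- function(hits, groups, quorum_fraction = 0.5,
                               quorum_min = 2, species = NULL,
                               tf_id = "TF") {
  groups <- as_tibble(groups)
  species <- species %||% unique(groups$species_id)
  hits_g <- inner_join(hits, groups, by = c("species_id", "locus_tag"))

  eligible <- groups |>
    filter(.data$species_id %in% species) |>
    group_by(.data$group_id) |>
    summarise(n_eligible = dplyr::n_distinct(.data$species_id))

  per_group <- hits_g |>
    group_by(.data$group_id) |>
    summarise(n_species_hit = dplyr::n_distinct(.data$species_id),
              best_score = max(.data$score)) |>
    left_join(eligible, by = "group_id")

  unverified <- length(species) < 2
  if (unverified) {
    warn("consistency filter over a single species: regulon is unverified")
    members <- per_group |> mutate(quorum = NA_integer_, retained = TRUE)
  } else {
    members <- per_group |>
      mutate(quorum = pmax(quorum_min,
                           as.integer(ceiling(quorum_fraction * .data$n_eligible))),
             retained = .data$n_species_hit >= .data$quorum)
  }
  members <- members |> filter(.data$retained) |> select(-"retained")
  member_hits <- hits_g |>
    filter(.data$group_id %in% members$group_id) |>
    group_by(.data$group_id, .data$species_id) |>
    dplyr::slice_max(.data$score, n = 1, with_ties = FALSE) |>
    ungroup()

  structure(list(tf_id = tf_id, members = members, hits = member_hits,
                 all_hits = hits_g, species = species,
                 quorum_fraction = quorum_fraction, quorum_min = quorum_min,
                 unverified = unverified, mode = "unknown"),
            class = "regulon")
}

#' @export
print.regulon <- function(x, ...) {
  cat(sprintf("<regulon> %s: %d member operon(s) over %d species (mode: %s)%s\n",
              x$tf_id, nrow(x$members), length(x$species), x$mode,
              if (x$unverified) " [unverified: single species]" else ""))
  if (nrow(x$members) > 0) print(x$members, n = 10)
  invisible(x)
}

#' Export scan hits as GFF3 intervals
#'
#' Converts upstream-relative hit offsets back to genomic coordinates and
#' writes a GFF3 file with the score carried in the attributes.
#'
#' @param hits Hit tibble from [scan_genomes()].
#' @param genomes Named list of [genome_record()]s.
#' @param path Output path.
#' @param span Site length in bp (the motif span).
#' @return Invisibly, `path`.
#' @export
write_hits_gff <- function(hits, genomes, path, span) {
  rows <- purrr::pmap(hits, function(species_id, locus_tag, offset, strand,
                                     score, site_seq, ...) {
    gnm <- genomes[[species_id]]
    g <- gnm$genes[gnm$genes$locus_tag == locus_tag, ]
    if (g$strand == "+") {
      gstart <- g$start + offset            # 0-based genomic site start
      gstrand <- strand
    } else {
      gstart <- g$end - offset - span
      gstrand <- if (strand == "+") "-" else "+"
    }
    tibble(seqnames = g$contig, start = gstart + 1L, end = gstart + span,
           strand = gstrand, score = score,
           locus_tag = locus_tag, species_id = species_id, site_seq = site_seq)
  }) |> bind_rows()
  gr <- GenomicRanges::GRanges(
    seqnames = rows$seqnames,
    ranges = IRanges::IRanges(start = rows$start, end = rows$end),
    strand = rows$strand)
  gr$score <- rows$score
  gr$locus_tag <- rows$locus_tag
  gr$species_id <- rows$species_id
  gr$site_seq <- rows$site_seq
  gr$type <- "TF_binding_site"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
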