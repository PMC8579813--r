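# Upstream-region extraction.  A region is the coding-strand sequence of the
# window immediately 5' of a gene's translation start; offsets are relative
# to the translation start (negative = upstream, half-open), so offset 0 is
# the first coding base and the window is [offset_start, 0).

#' Extract the upstream region of a gene
#'
#' Returns the coding-strand sequence of the window `[-L, 0)` relative to the
#' translation start, where `L` is `max_len` shortened by the nearest
#' upstream coding interval (when `stop_at_coding` is `TRUE`) and by the
#' contig edge.  Minus-strand genes are handled by reverse complementation so
#' offsets are always relative to the translation start.
#'
#' @param genome A [genome_record()].
#' @param locus_tag Gene identifier.
#' @param max_len Maximum window length in bp (default 300).
#' @param stop_at_coding Truncate at the nearest upstream gene (default TRUE).
#' @return A one-row tibble: `species_id`, `locus_tag`, `seq`, `offset_start`,
#'   `offset_end`, `truncated_by` (`"none"`, `"upstream_gene"`, or
#'   `"contig_edge"`).
#' @export
extract_upstream <- function(genome, locus_tag, max_len = 300,
                             stop_at_coding = TRUE) {
  stopifnot(max_len > 0)
  genes <- genome$genes
  i <- match(locus_tag, genes$locus_tag)
  if (is.na(i)) abort(sprintf("no gene '%s' in genome '%s'",
                              locus_tag, genome$species_id))
  g <- genes[i, ]
  contig <- genome$contigs[[g$contig]]
  clen <- nchar(contig)
  others <- genes[-i, , drop = FALSE]
  others <- others[others$contig == g$contig, , drop = FALSE]

  if (g$strand == "+") {
    # nearest coding base left of the translation start
    block <- 0L
    if (stop_at_coding && nrow(others) > 0) {
      cand <- others[others$start < g$start, , drop = FALSE]
      if (nrow(cand) > 0) block <- max(pmin(cand$end, g$start))
    }
    lo <- max(g$start - max_len, block, 0L)
    len <- g$start - lo
    seq <- if (len > 0) substr(contig, lo + 1, g$start) else ""
    truncated_by <- if (len == max_len) "none"
      else if (lo == block && block > 0L) "upstream_gene" else "contig_edge"
  } else {
    block <- clen
    if (stop_at_coding && nrow(others) > 0) {
      cand <- others[others$end > g$end, , drop = FALSE]
      if (nrow(cand) > 0) block <- min(pmax(cand$start, g$end))
    }
    hi <- min(g$end + max_len, block, clen)
    len <- hi - g$end
    seq <- if (len > 0) reverse_complement(substr(contig, g$end + 1, hi)) else ""
    truncated_by <- if (len == max_len) "none"
      else if (hi == block && block < clen) "upstream_gene" else "contig_edge"
  }

  tibble(species_id = genome$species_id, locus_tag = locus_tag,
         seq = seq, offset_start = -len, offset_end = 0L,
         truncated_by = truncated_by)
}

#' Assemble a cross-genome training set of upstream regions
#'
#' For every member of every ortholog group, extracts the upstream region and
#' keeps those longer than `min_len` (intergenic regions of more than 50 bp
#' by default).  The number of dropped regions is reported via a message and
#' the `"n_dropped"` attribute.
#'
#' @param groups Ortholog tibble (`group_id`, `species_id`, `locus_tag`).
#' @param genomes Named list of [genome_record()]s keyed by species.
#' @param min_len Keep regions strictly longer than this (default 50 bp).
#' @param max_len,stop_at_coding Passed to [extract_upstream()].
#' @return Tibble of regions with a `group_id` column, invariant to the
#'   ordering of `groups`.
#' @export
training_regions <- function(groups, genomes, min_len = 50, max_len = 300,
                             stop_at_coding = TRUE) {
  groups <- arrange(as_tibble(groups), .data$group_id, .data$species_id)
  resolvable <- groups$species_id %in% names(genomes)
  if (!any(resolvable)) abort("no ortholog group member resolves in any genome")
  rows <- purrr::pmap(groups[resolvable, ], function(group_id, species_id, locus_tag, ...) {
    gnm <- genomes[[species_id]]
    if (!locus_tag %in% gnm$genes$locus_tag) return(NULL)
    reg <- extract_upstream(gnm, locus_tag, max_len = max_len,
                            stop_at_coding = stop_at_coding)
    reg$group_id <- group_id
    reg
  })
  regions <- bind_rows(rows)
  if (nrow(regions) == 0) abort("training set empty: no member resolved")
  keep <- nchar(regions$seq) > min_len
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    inform(sprintf("training_regions: dropped %d region(s) of length <= %d bp",
                   n_dropped, min_len))
  regions <- regions[keep, , drop = FALSE]
  if (nrow(regions) == 0) abort("training set empty: all regions filtered out")
  attr(regions, "n_dropped") <- n_dropped
  regions
}
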