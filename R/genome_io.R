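# Genome input/output.  Coordinates are 0-based half-open internally; files
# are read and written 1-based inclusive (GFF convention).

#' Construct a genome record
#'
#' Bundles a set of contig sequences with a validated gene feature table.
#' Users normally obtain one from [read_genome()] or the synthetic generator.
#'
#' @param species_id Identifier for the genome.
#' @param contigs Named character vector of uppercase `{A,C,G,T,N}` sequences.
#' @param genes Data frame with columns `locus_tag`, `contig`, `start`, `end`
#'   (0-based half-open), `strand` (`"+"`/`"-"`), and optionally `product`.
#' @return An object of class `genome_record`.
#' @export
genome_record <- function(species_id, contigs, genes) {
  contigs <- toupper(unlist(contigs))
  if (is.null(names(contigs)) || anyNA(names(contigs)))
    abort("contigs must be a named character vector")
  validate_dna(contigs, "contig sequence")
  genes <- as_tibble(genes)
  if (!"product" %in% names(genes)) genes$product <- NA_character_
  genes <- genes[, c("locus_tag", "contig", "start", "end", "strand", "product")]
  if (nrow(genes) > 0) {
    if (anyDuplicated(genes$locus_tag))
      abort(sprintf("duplicated locus_tag in genome '%s'", species_id))
    bad_contig <- which(!genes$contig %in% names(contigs))
    if (length(bad_contig) > 0) {
      abort(sprintf(
        "feature row %d (locus_tag '%s') refers to unknown contig '%s'",
        bad_contig[1], genes$locus_tag[bad_contig[1]], genes$contig[bad_contig[1]]))
    }
    if (!all(genes$strand %in% c("+", "-")))
      abort("gene strand must be '+' or '-'")
    clen <- nchar(contigs)[genes$contig]
    bad <- which(!(genes$start >= 0 & genes$start < genes$end & genes$end <= clen))
    if (length(bad) > 0) {
      abort(sprintf(
        "feature row %d (locus_tag '%s'): invalid coordinates [%d, %d) on contig of length %d",
        bad[1], genes$locus_tag[bad[1]], genes$start[bad[1]], genes$end[bad[1]],
        clen[bad[1]]))
    }
  }
  structure(list(species_id = species_id, contigs = contigs, genes = genes),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %d contig(s), %d gene(s), %s bp\n",
              x$species_id, length(x$contigs), nrow(x$genes),
              format(sum(nchar(x$contigs)), big.mark = ",")))
  invisible(x)
}

#' Read an annotated genome
#'
#' Reads a nucleotide FASTA plus a gene feature table (GFF3 or tab-separated).
#' File coordinates are 1-based inclusive and are converted to the package's
#' internal 0-based half-open convention on read.  A TSV feature table must
#' have a header with columns `contig`, `start`, `end`, `strand`, `locus_tag`
#' (extra columns such as `product` are kept).
#'
#' @param fasta_path Path to the genome FASTA.
#' @param features_path Path to a GFF3 (`.gff`/`.gff3`) or TSV feature table.
#' @param species_id Genome identifier; defaults to the FASTA file stem.
#' @return A [genome_record()].
#' @export
read_genome <- function(fasta_path, features_path, species_id = NULL) {
  species_id <- species_id %||%
    sub("\\.(fa|fna|fasta)$", "", basename(fasta_path))
  dna <- Biostrings::readDNAStringSet(fasta_path)
  contigs <- stats::setNames(toupper(as.character(dna)),
                             sub("\\s.*$", "", names(dna)))
  is_gff <- grepl("\\.gff3?$", features_path, ignore.case = TRUE)
  feats <- if (is_gff) read_features_gff(features_path)
           else read_features_tsv(features_path)
  if (nrow(feats) == 0) {
    warn(sprintf("feature file '%s' contains no gene rows", features_path))
  }
  # 1-based inclusive -> 0-based half-open
  feats$start <- feats$start - 1L
  genome_record(species_id, contigs, feats)
}

read_features_tsv <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("contig", "start", "end", "strand", "locus_tag")
  if (!all(need %in% names(tab)))
    abort(sprintf("feature TSV must have header columns: %s",
                  paste(need, collapse = ", ")))
  tab <- tab[, c(need, intersect("product", names(tab)))]
  tab$start <- as.integer(tab$start)
  tab$end <- as.integer(tab$end)
  as_tibble(tab)
}

read_features_gff <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  keep <- as.character(gr$type) %in% c("gene", "CDS")
  if (any(keep)) gr <- gr[keep]
  lt <- if (!is.null(gr$locus_tag)) as.character(gr$locus_tag)
        else as.character(gr$ID)
  tibble(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    locus_tag = lt,
    product = if (!is.null(gr$product)) as.character(gr$product) else NA_character_
  )
}

#' Write a genome record to FASTA + feature TSV
#'
#' The inverse of [read_genome()]; feature coordinates are written 1-based
#' inclusive.
#'
#' @param genome A [genome_record()].
#' @param fasta_path,features_path Output paths.
#' @return Invisibly, the genome.
#' @export
write_genome <- function(genome, fasta_path, features_path) {
  dna <- Biostrings::DNAStringSet(genome$contigs)
  Biostrings::writeXStringSet(dna, fasta_path)
  out <- genome$genes
  out$start <- out$start + 1L
  readr::write_tsv(out, features_path, progress = FALSE)
  invisible(genome)
}

#' Read an ortholog table
#'
#' Tab-separated with header `group_id`, `species_id`, `locus_tag`; at most
#' one member per species within a group.
#'
#' @param path Path to the TSV.
#' @return A tibble in long format (one row per group member).
#' @export
read_ortholog_groups <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("group_id", "species_id", "locus_tag")
  if (!all(need %in% names(tab)))
    abort("ortholog table must have header columns group_id, species_id, locus_tag")
  tab <- as_tibble(tab[, need])
  dup <- dplyr::count(tab, .data$group_id, .data$species_id)
  if (any(dup$n > 1))
    abort("ortholog group has more than one member in a species")
  tab
}

#' Group adjacent same-strand genes into operons
#'
#' Approximates operon structure by the standard distance rule: adjacent
#' genes on the same strand and contig whose intergenic gap is below
#' `max_gap` are merged into one operon.  The first (most 5') gene of each
#' operon is flagged; upstream-region scans anchor there.
#'
#' @param genes Gene tibble from a [genome_record()].
#' @param max_gap Maximum intergenic gap in bp (default 100).
#' @return The gene tibble with `operon_id` and `first_in_operon` columns.
#' @export
assign_operons <- function(genes, max_gap = 100) {
  genes <- as_tibble(genes)
  if (nrow(genes) == 0) {
    genes$operon_id <- character(0)
    genes$first_in_operon <- logical(0)
    return(genes)
  }
  genes <- arrange(genes, .data$contig, .data$start)
  gap <- genes$start - dplyr::lag(genes$end)
  new_op <- genes$contig != dplyr::lag(genes$contig) |
    genes$strand != dplyr::lag(genes$strand) |
    gap >= max_gap
  new_op[1] <- TRUE
  op <- cumsum(new_op)
  genes$operon_id <- sprintf("op%04d", op)
  # first-in-operon is the 5'-most gene: smallest start on '+', largest end on '-'
  genes <- genes |>
    group_by(.data$operon_id) |>
    mutate(first_in_operon = ifelse(.data$strand == "+",
                                    row_number() == 1L,
                                    row_number() == n())) |>
    ungroup()
  genes
}
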