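# Positional weight matrices.  Columns carry log2-odds weights
# w(b,i) = log2((n(b,i) + a*q(b)) / ((N_i + a) * q(b))) with a Laplace-style
# pseudocount distributed by the background q.  A motif's score threshold is
# the lowest score observed among its own training sites, so scanning the
# training regions always recovers the full training set.

#' Build a positional weight matrix from aligned sites
#'
#' @param sites Character vector of aligned, equal-length site sequences
#'   spanning the full motif (including any unmodeled spacer bases).
#' @param geometry Optional geometry list (`mode` plus
#'   width/unit/period/spacer) as selected by [discover_motif()]; when absent
#'   every column is modeled with no symmetry constraint.  For palindrome and
#'   spaced-inverted-repeat geometries the counts are pooled with their
#'   reverse-complement partner columns, which makes plus- and minus-strand
#'   scores of any window exactly equal.
#' @param background Length-4 base frequencies (A,C,G,T); default uniform.
#' @param alpha Pseudocount mass (default 1), spread as `alpha * q(b)`.
#' @param tf_id Identifier stored with the motif.
#' @param training_sites Optional tibble of site metadata to carry along.
#' @return A `pwm_model` object with counts, log2-odds `weights`, and the
#'   minimum-training-score `threshold`.
#' @export
build_pwm <- function(sites, geometry = NULL, background = NULL, alpha = 1,
                      tf_id = "motif", training_sites = NULL) {
  sites <- toupper(as.character(sites))
  if (length(sites) < 2) abort("need at least 2 training sites")
  if (length(unique(nchar(sites))) != 1)
    abort("training sites have unequal lengths")
  validate_dna(sites, "site sequence")
  span <- nchar(sites[1])
  if (is.null(geometry)) {
    geometry <- list(mode = "plain", width = span, unit = NA_integer_,
                     period = NA_integer_, spacer = NA_integer_)
    lay <- list(offsets = 0:(span - 1L), span = span,
                partner = 0:(span - 1L), comp = rep(FALSE, span))
  } else {
    lay <- geometry_layout(geometry)
    if (lay$span != span)
      abort(sprintf("sites are %d bp but the geometry spans %d bp", span, lay$span))
  }
  q <- background %||% rep(0.25, 4)
  q <- as.numeric(q) / sum(q)
  m <- length(lay$offsets)

  counts <- matrix(0, 4, m, dimnames = list(DNA_BASES, NULL))
  enc <- lapply(sites, encode_dna)
  for (s in enc) {
    b <- s[lay$offsets + 1L]
    for (j in seq_len(m)) {
      if (b[j] <= 4) counts[b[j], j] <- counts[b[j], j] + 1
      else counts[, j] <- counts[, j] + q  # N spread as background
    }
  }
  symmetric <- !all(lay$partner == seq_len(m) - 1L)
  if (symmetric) {
    pooled <- counts
    for (j in seq_len(m)) {
      pj <- lay$partner[j] + 1L
      other <- if (lay$comp[j]) rev(counts[, pj]) else counts[, pj]
      pooled[, j] <- counts[, j] + other
    }
    counts <- pooled
  }
  ntot <- colSums(counts)
  weights <- log2(sweep(counts + alpha * q, 2, (ntot + alpha), "/") / q)

  motif <- structure(list(
    tf_id = tf_id, geometry = geometry, layout = lay, mode = geometry$mode,
    n_sites = length(sites), counts = counts, weights = weights,
    background = q, alpha = alpha, threshold = NA_real_,
    training_sites = NULL
  ), class = "pwm_model")

  scores <- vapply(sites, function(s) score_site(motif, s), numeric(1))
  motif$threshold <- min(scores)
  ts <- training_sites %||% tibble(site_seq = sites)
  ts$score <- unname(scores)
  motif$training_sites <- ts
  motif
}

#' @export
print.pwm_model <- function(x, ...) {
  cat(sprintf("<pwm_model> %s (%s), span %d bp, %d modeled column(s), %d site(s)\n",
              x$tf_id, geometry_label_or_plain(x$geometry), x$layout$span,
              length(x$layout$offsets), x$n_sites))
  cat(sprintf("  consensus: %s\n  threshold: %.3f bits (minimum training-site score)\n",
              consensus_string(x), x$threshold))
  invisible(x)
}

geometry_label_or_plain <- function(g) {
  if (g$mode == "plain") sprintf("plain_w%d", g$width) else geometry_label(g)
}

# score one full-span sequence: sum of column weights over modeled columns.
# Goes through the same compiled kernel as region scanning so that the
# minimum-training-score threshold is bit-identical to scan scores.
score_site <- function(motif, seq) {
  w5 <- rbind(motif$weights, 0)
  score_positions_cpp(encode_dna(seq) - 1L, w5, motif$layout$offsets)[1]
}

#' Consensus string of a motif
#'
#' Majority base per modeled column; unmodeled linkers are shown as
#' `-(n)-`.
#'
#' @param motif A `pwm_model` or `motif_discovery`.
#' @return A character scalar such as `"GGGAC-(27)-GTCCC"`.
#' @export
consensus_string <- function(motif) {
  if (inherits(motif, "motif_discovery")) motif <- motif$motif
  top <- DNA_BASES[apply(motif$counts, 2, which.max)]
  g <- motif$geometry
  if (g$mode %in% c("palindrome", "plain")) return(paste(top, collapse = ""))
  u <- g$unit
  gap <- motif$layout$offsets[u + 1L] - u
  paste0(paste(top[1:u], collapse = ""), "-(", gap, ")-",
         paste(top[(u + 1):(2 * u)], collapse = ""))
}

#' Scan one upstream region with a PWM
#'
#' Reports every start position and strand whose score reaches the motif's
#' threshold, sorted by offset.  For strand-degenerate motifs (palindromes
#' and spaced inverted repeats, whose pooled columns make the two strands
#' score identically) only the canonical plus-strand hit is reported.
#'
#' @param motif A `pwm_model`.
#' @param region One-row region tibble (see [extract_upstream()]) or a plain
#'   sequence string.
#' @param both_strands Scan the minus strand too (default TRUE; ignored for
#'   strand-degenerate motifs).
#' @param threshold Score cutoff; defaults to the motif's training-set
#'   minimum.
#' @return Tibble of hits: `species_id`, `locus_tag`, `offset` (site start
#'   relative to the translation start), `strand`, `score`, `site_seq`.
#' @export
score_region <- function(motif, region, both_strands = TRUE,
                         threshold = NULL) {
  region <- as_region_tbl(if (is.character(region)) region else as_tibble(region))
  stopifnot(nrow(region) == 1)
  theta <- threshold %||% motif$threshold
  span <- motif$layout$span
  L <- nchar(region$seq)
  empty <- tibble(species_id = character(0), locus_tag = character(0),
                  offset = integer(0), strand = character(0),
                  score = numeric(0), site_seq = character(0))
  if (L < span) return(empty)

  w5 <- rbind(motif$weights, 0)
  enc <- encode_dna(region$seq) - 1L
  sc_f <- score_positions_cpp(enc, w5, motif$layout$offsets)
  hits <- tibble(p = which(sc_f >= theta) - 1L, strand = "+",
                 score = sc_f[sc_f >= theta])
  if (both_strands && !geometry_self_revcomp(motif$geometry)) {
    enc_r <- encode_dna(reverse_complement(region$seq)) - 1L
    sc_r <- score_positions_cpp(enc_r, w5, motif$layout$offsets)
    keep <- which(sc_r >= theta)
    if (length(keep) > 0) {
      hits <- bind_rows(hits, tibble(p = L - span - (keep - 1L), strand = "-",
                                     score = sc_r[keep]))
    }
  }
  if (nrow(hits) == 0) return(empty)
  hits |>
    mutate(species_id = region$species_id, locus_tag = region$locus_tag,
           offset = region$offset_start + .data$p,
           site_seq = {
             s <- substr(rep(region$seq, n()), .data$p + 1L, .data$p + span)
             ifelse(.data$strand == "-", reverse_complement(s), s)
           }) |>
    select("species_id", "locus_tag", "offset", "strand", "score", "site_seq") |>
    arrange(.data$offset, .data$strand)
}

# ---- MEME minimal motif format ---------------------------------------------

#' Write a motif in MEME minimal format
#'
#' Standard MEME minimal motif text with the letter-probability matrix over
#' the full span (unmodeled linker columns carry the background).  Package-
#' specific state needed for an exact round-trip (geometry, pseudocount,
#' threshold, per-column count totals) travels in comment lines that other
#' MEME readers ignore.
#'
#' @param motif A `pwm_model`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_meme <- function(motif, path) {
  q <- motif$background
  m <- length(motif$layout$offsets)
  ntot <- colSums(motif$counts)
  probs <- sweep(motif$counts + motif$alpha * q, 2, ntot + motif$alpha, "/")
  span <- motif$layout$span
  full <- matrix(rep(q, span), nrow = 4)
  full[, motif$layout$offsets + 1L] <- probs
  num <- function(x) sprintf("%.17g", x)
  lines <- c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "strands: + -", "",
    "Background letter frequencies",
    paste(rbind(DNA_BASES, vapply(q, num, "")), collapse = " "), "",
    sprintf("# regufoot geometry= %s alpha= %s threshold= %s nsites= %d",
            geometry_label_or_plain(motif$geometry), num(motif$alpha),
            num(motif$threshold), motif$n_sites),
    sprintf("# regufoot column_totals= %s", paste(num(ntot), collapse = " ")),
    sprintf("MOTIF %s %s", motif$tf_id, geometry_label_or_plain(motif$geometry)),
    sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
            span, motif$n_sites),
    apply(full, 2, function(col) paste(" ", paste(vapply(col, num, ""), collapse = "  ")))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a motif written by [write_meme()]
#'
#' @param path Path to the MEME minimal file.
#' @return A `pwm_model` (without training-site sequences; the stored
#'   threshold and weights round-trip to within 1e-9).
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  bg_i <- grep("^Background letter frequencies", lines)
  q <- as.numeric(strsplit(trimws(lines[bg_i + 1]), "\\s+")[[1]][c(2, 4, 6, 8)])
  meta <- lines[grep("^# regufoot geometry=", lines)]
  toks <- strsplit(trimws(sub("^# regufoot ", "", meta)), "\\s+")[[1]]
  gl <- toks[which(toks == "geometry=") + 1]
  alpha <- as.numeric(toks[which(toks == "alpha=") + 1])
  threshold <- as.numeric(toks[which(toks == "threshold=") + 1])
  nsites <- as.integer(toks[which(toks == "nsites=") + 1])
  ct_line <- sub("^# regufoot column_totals= ", "",
                 lines[grep("^# regufoot column_totals=", lines)])
  ntot <- as.numeric(strsplit(trimws(ct_line), "\\s+")[[1]])
  motif_i <- grep("^MOTIF ", lines)
  tf_id <- strsplit(lines[motif_i], "\\s+")[[1]][2]
  hdr_i <- grep("^letter-probability matrix:", lines)
  w <- as.integer(sub(".*w= *(\\d+).*", "\\1", lines[hdr_i]))
  mat <- do.call(rbind, lapply(lines[hdr_i + seq_len(w)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  full <- t(mat)  # 4 x span

  geometry <- if (grepl("^plain_w", gl)) {
    list(mode = "plain", width = as.integer(sub("^plain_w", "", gl)),
         unit = NA_integer_, period = NA_integer_, spacer = NA_integer_)
  } else parse_geometry_label(gl)
  lay <- if (geometry$mode == "plain") {
    list(offsets = 0:(w - 1L), span = w, partner = 0:(w - 1L),
         comp = rep(FALSE, w))
  } else geometry_layout(geometry)
  probs <- full[, lay$offsets + 1L, drop = FALSE]
  counts <- sweep(probs, 2, ntot + alpha, "*") - alpha * q
  counts[counts < 0] <- 0
  weights <- log2(sweep(counts + alpha * q, 2, (colSums(counts) + alpha), "/") / q)
  dimnames(counts) <- dimnames(weights) <- list(DNA_BASES, NULL)
  structure(list(tf_id = tf_id, geometry = geometry, layout = lay,
                 mode = geometry$mode, n_sites = nsites, counts = counts,
                 weights = weights, background = q, alpha = alpha,
                 threshold = threshold, training_sites = NULL),
            class = "pwm_model")
}

#' Per-position base probabilities for logo plotting
#'
#' @param motif A `pwm_model`.
#' @return Tibble with `position` (1-based over the full span), `base`,
#'   `prob`, `ic` (column information content in bits), and `modeled`.
#' @export
logo_data <- function(motif) {
  q <- motif$background
  ntot <- colSums(motif$counts)
  probs <- sweep(motif$counts + motif$alpha * q, 2, ntot + motif$alpha, "/")
  span <- motif$layout$span
  full <- matrix(rep(q, span), nrow = 4, dimnames = list(DNA_BASES, NULL))
  full[, motif$layout$offsets + 1L] <- probs
  ic <- colSums(ifelse(full > 0, full * log2(full / q), 0))
  tibble(position = rep(seq_len(span), each = 4),
         base = rep(DNA_BASES, span),
         prob = as.vector(full),
         ic = rep(ic, each = 4),
         modeled = rep(seq_len(span) %in% (motif$layout$offsets + 1L), each = 4))
}
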