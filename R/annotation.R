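# TSS/promoter annotation and repressor-vs-activator classification.  All
# coordinates are offsets relative to the translation start (negative =
# upstream, half-open intervals), matching upstream regions and site hits.

#' Read a TSS table
#'
#' Tab-separated with header `locus_tag` and either `tss_offset` (negative,
#' relative to the translation start) or `utr_len` (non-negative).
#'
#' @param path Path to the TSV.
#' @return Tibble with `locus_tag`, `tss_offset`, `utr_len`.
#' @export
read_tss <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"locus_tag" %in% names(tab)) abort("TSS table needs a locus_tag column")
  if ("tss_offset" %in% names(tab)) {
    tab$utr_len <- -as.integer(tab$tss_offset)
  } else if ("utr_len" %in% names(tab)) {
    tab$tss_offset <- -as.integer(tab$utr_len)
  } else abort("TSS table needs a tss_offset or utr_len column")
  if (any(tab$utr_len < 0)) abort("utr_len must be non-negative")
  as_tibble(tab[, c("locus_tag", "tss_offset", "utr_len")])
}

#' Locate sigma-A -35/-10 promoter elements upstream of a TSS
#'
#' Searches the region's coding strand for the hexamer pair closest to the
#' consensus `TTGACA` (-35) and `TATAAT` (-10) under canonical sigma-A
#' geometry: the -10 element separated from the TSS by a 4-9 bp gap and the
#' two hexamers by a 15-19 bp spacer.  The call with the fewest total
#' mismatches wins; ties are broken toward the canonical layout (-10 gap of
#' 7 bp, then 17 bp spacer).  Calls worse than `max_total_mm` (or with
#' either hexamer worse than `max_mm`) are rejected as background.
#'
#' @param region One-row region tibble from [extract_upstream()].
#' @param tss One-row of a TSS tibble (needs `tss_offset`), or a scalar
#'   offset.
#' @param spacer_range Allowed -35/-10 spacer in bp (default `c(15, 19)`).
#' @param max_mm Maximum mismatches per hexamer (default 2).
#' @param max_total_mm Maximum total mismatches for an acceptable call
#'   (default 4, the null-calibrated cut; see [calibrate_promoter_mm()]).
#' @return One-row tibble (`minus35_offset`, `minus35_seq`, `minus35_mm`,
#'   `minus10_offset`, `minus10_seq`, `minus10_mm`, `spacer`, `gap10`,
#'   `total_mm`, `partial`) or `NULL` when no acceptable call exists.
#' @export
find_promoter <- function(region, tss, spacer_range = c(15, 19), max_mm = 2,
                          max_total_mm = 4) {
  t_off <- if (is.numeric(tss)) as.integer(tss) else as.integer(tss$tss_offset)
  region <- as_tibble(region)
  off0 <- region$offset_start[1]
  seqc <- region$seq[1]
  L <- nchar(seqc)
  hex_at <- function(o) {
    i <- o - off0  # 0-based index into seq
    if (i < 0 || i + 6 > L) return(NA_character_)
    substr(seqc, i + 1, i + 6)
  }
  partial <- FALSE
  cand <- tidyr::expand_grid(gap10 = 4:9, spacer = spacer_range[1]:spacer_range[2]) |>
    mutate(minus10_offset = t_off - 6L - .data$gap10,
           minus35_offset = .data$minus10_offset - .data$spacer - 6L)
  rows <- purrr::pmap(cand, function(gap10, spacer, minus10_offset, minus35_offset) {
    h10 <- hex_at(minus10_offset)
    h35 <- hex_at(minus35_offset)
    if (is.na(h10) || is.na(h35)) return(NULL)
    mm10 <- hexamer_mismatches(h10, "TATAAT")
    mm35 <- hexamer_mismatches(h35, "TTGACA")
    tibble(gap10 = gap10, spacer = spacer,
           minus10_offset = minus10_offset, minus35_offset = minus35_offset,
           minus10_seq = h10, minus35_seq = h35,
           minus10_mm = mm10, minus35_mm = mm35, total_mm = mm10 + mm35)
  })
  out <- bind_rows(rows)
  if (nrow(out) < nrow(cand)) partial <- TRUE
  if (nrow(out) == 0) {
    warn("promoter search window truncated: no candidate layout fits the region")
    return(NULL)
  }
  out <- out |>
    filter(.data$minus10_mm <= max_mm, .data$minus35_mm <= max_mm,
           .data$total_mm <= max_total_mm) |>
    arrange(.data$total_mm, abs(.data$gap10 - 7L) + abs(.data$spacer - 17L),
            .data$gap10, .data$spacer)
  if (nrow(out) == 0) return(NULL)
  best <- out[1, ]
  best$partial <- partial
  best |>
    select("minus35_offset", "minus35_seq", "minus35_mm",
           "minus10_offset", "minus10_seq", "minus10_mm",
           "spacer", "gap10", "total_mm", "partial")
}

hexamer_mismatches <- function(hex, consensus) {
  sum(strsplit(hex, "")[[1]] != strsplit(consensus, "")[[1]])
}

#' Null calibration of the promoter mismatch cut
#'
#' Simulates background regions, records the best achievable total mismatch
#' count under the sigma-A layout constraints, and returns the lower quantile
#' minus one as the acceptance cut: calls at least this good arise in less
#' than `1 - quantile` of background windows.
#'
#' @param n_sims Number of null regions (default 200).
#' @param region_len Region length (default 80 bp, covering the search
#'   layouts).
#' @param gc Background GC fraction (default 0.35).
#' @param quantile Quantile of the null best-mismatch distribution
#'   (default 0.05: the cut rejects all but the best 5 percent of nulls).
#' @param seed Integer seed.
#' @return Integer mismatch cut with the simulated null minima attached as
#'   the `"null_mm"` attribute.
#' @export
calibrate_promoter_mm <- function(n_sims = 200, region_len = 80, gc = 0.35,
                                  quantile = 0.05, seed = 1) {
  seeds <- derive_seeds(seed, n_sims)
  mins <- purrr::map_int(seeds, function(s) {
    seqc <- gen_background(region_len, gc, seed = s)
    reg <- tibble(species_id = "null", locus_tag = "null", seq = seqc,
                  offset_start = -region_len, offset_end = 0L)
    best <- find_promoter(reg, tss = -10L, max_mm = 6, max_total_mm = 12)
    if (is.null(best)) 12L else as.integer(best$total_mm)
  })
  structure(as.integer(stats::quantile(mins, quantile, type = 1)) - 1L,
            null_mm = mins)
}

#' Classify a TF as repressor or activator from site position
#'
#' Positional rule: a binding site overlapping the 5' UTR (`[tss, 0)`) or
#' either promoter hexamer indicates a repressor (it occludes RNA polymerase
#' or the transcript start); a site lying entirely upstream of the -35
#' element (or, with no promoter call, entirely upstream of `tss - 35`)
#' indicates an activator; anything else is ambiguous.  The call is a pure
#' function of the supplied intervals.
#'
#' @param site One-row hit tibble (needs `offset`) or scalar site start
#'   offset.
#' @param span Site length in bp (taken from `site$span` or required).
#' @param tss Scalar TSS offset or one-row TSS tibble; `NA`/`NULL` gives
#'   `"unknown"`.
#' @param promoter Optional promoter call from [find_promoter()].
#' @return One-row tibble with `call` (`repressor`/`activator`/`ambiguous`/
#'   `unknown`) and `evidence`.
#' @export
classify_mode <- function(site, span, tss = NULL, promoter = NULL) {
  s0 <- if (is.numeric(site)) as.integer(site) else as.integer(site$offset)
  s1 <- s0 + as.integer(span)
  t_off <- if (is.null(tss)) NA_integer_
           else if (is.numeric(tss)) as.integer(tss)
           else as.integer(tss$tss_offset)
  if (is.na(t_off)) {
    return(tibble(call = "unknown", evidence = "no TSS mapped"))
  }
  overlaps <- function(a0, a1) s1 > a0 && s0 < a1
  if (overlaps(t_off, 0L)) {
    return(tibble(call = "repressor", evidence = "site overlaps 5' UTR"))
  }
  if (!is.null(promoter)) {
    if (overlaps(promoter$minus10_offset, promoter$minus10_offset + 6L)) {
      return(tibble(call = "repressor", evidence = "site overlaps -10 element"))
    }
    if (overlaps(promoter$minus35_offset, promoter$minus35_offset + 6L)) {
      return(tibble(call = "repressor", evidence = "site overlaps -35 element"))
    }
    if (s1 <= promoter$minus35_offset) {
      return(tibble(call = "activator", evidence = "site entirely upstream of -35 element"))
    }
  } else if (s1 <= t_off - 35L) {
    return(tibble(call = "activator", evidence = "site entirely upstream of TSS - 35"))
  }
  tibble(call = "ambiguous", evidence = "site between promoter landmarks")
}

#' Summary statistics of 5' UTR lengths
#'
#' @param tss TSS tibble with `utr_len` (or `tss_offset`).
#' @param cutoff Report the fraction of UTRs at or below this length
#'   (default 180 bp).
#' @return One-row tibble: `n`, `median_utr`, `frac_within`.
#' @export
utr_stats <- function(tss, cutoff = 180) {
  tss <- as_tibble(tss)
  if (!"utr_len" %in% names(tss)) tss$utr_len <- -tss$tss_offset
  if (nrow(tss) == 0) abort("no TSS records")
  tibble(n = nrow(tss), median_utr = stats::median(tss$utr_len),
         frac_within = mean(tss$utr_len <= cutoff))
}

#' Phylogenetic footprint report for one ortholog group
#'
#' Renders the orthologous upstream regions of a group as text lines
#' right-anchored at the translation start (offset 0), with binding sites
#' upper-cased and marked, and TSS/promoter positions flagged on a markup
#' line.  No gapped alignment is attempted: the anchor alignment reflects
#' the no-indel divergence model of the footprint display.
#'
#' @param group_id Ortholog group to render.
#' @param regions Region tibble with `group_id` (see [training_regions()]).
#' @param hits Hit tibble (optional).
#' @param tss TSS tibble (optional; applied to matching locus tags).
#' @param promoters Named list of promoter calls keyed by locus tag
#'   (optional).
#' @param span Site length used for markup when `hits` are given.
#' @return A `footprint_report` character vector (one element per line).
#' @export
footprint_report <- function(group_id, regions, hits = NULL, tss = NULL,
                             promoters = NULL, span = NULL) {
  regs <- regions[regions$group_id == group_id, , drop = FALSE]
  if (nrow(regs) == 0) abort(sprintf("no regions for group '%s'", group_id))
  if (nrow(regs) == 1)
    warn("footprint report over a single species")
  width <- max(-regs$offset_start)
  lines <- character(0)
  for (i in seq_len(nrow(regs))) {
    r <- regs[i, ]
    seq_disp <- tolower(r$seq)
    mark <- strrep(" ", nchar(r$seq))
    if (!is.null(hits)) {
      h <- hits[hits$locus_tag == r$locus_tag &
                  (is.na(r$species_id) | hits$species_id == r$species_id), ,
                drop = FALSE]
      for (k in seq_len(nrow(h))) {
        a <- h$offset[k] - r$offset_start
        b <- a + (span %||% nchar(h$site_seq[k]))
        if (a >= 0 && b <= nchar(seq_disp)) {
          substr(seq_disp, a + 1, b) <- toupper(substr(r$seq, a + 1, b))
          substr(mark, a + 1, b) <- strrep("*", b - a)
        }
      }
    }
    if (!is.null(tss)) {
      tr <- tss[tss$locus_tag == r$locus_tag, , drop = FALSE]
      if (nrow(tr) == 1) {
        a <- tr$tss_offset[1] - r$offset_start
        if (a >= 0 && a < nchar(mark)) substr(mark, a + 1, a + 1) <- ">"
      }
    }
    pr <- promoters[[r$locus_tag]]
    if (!is.null(pr)) {
      for (o in c(pr$minus35_offset, pr$minus10_offset)) {
        a <- o - r$offset_start
        if (a >= 0 && a + 6 <= nchar(mark))
          substr(mark, a + 1, a + 6) <- strrep("=", 6)
      }
    }
    pad <- strrep(" ", width - nchar(seq_disp))
    tag <- sprintf("%-14s", paste0(r$species_id, "/", r$locus_tag))
    lines <- c(lines, paste0(tag, pad, seq_disp),
               if (grepl("[^ ]", mark)) paste0(strrep(" ", 14), pad, mark))
  }
  structure(c(sprintf("footprint %s (anchored at translation start; * site, > TSS, = promoter)",
                      group_id), lines),
            class = "footprint_report")
}

#' @export
print.footprint_report <- function(x, ...) {
  cat(paste(unclass(x), collapse = "\n"), "\n")
  invisible(x)
}

#' Write a footprint report as HTML
#'
#' @param report A `footprint_report`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_footprint_html <- function(report, path) {
  body <- paste(vapply(unclass(report), function(l)
    gsub("<", "&lt;", gsub(">", "&gt;", gsub("&", "&amp;", l))), ""),
    collapse = "\n")
  writeLines(c("<html><body><pre style=\"font-family:monospace\">",
               body, "</pre></body></html>"), path)
  invisible(path)
}
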