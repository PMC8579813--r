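region_from <- function(seq) {
  tibble::tibble(species_id = "sp", locus_tag = "g", seq = seq,
                 offset_start = -nchar(seq), offset_end = 0L)
}

test_that("a consensus promoter at canonical spacing is called exactly", {
  # ...TTGACA (17 bp) TATAAT (7 bp) TSS (utr 20)...
  tss_offset <- -20L
  utr <- gen_background(20, 0.5, seed = 1)
  up <- gen_background(30, 0.5, seed = 2)
  seq <- paste0(up, "TTGACA", gen_background(17, 0.5, seed = 3), "TATAAT",
                gen_background(7, 0.5, seed = 4), utr)
  pc <- find_promoter(region_from(seq), tss_offset)
  expect_equal(pc$total_mm, 0L)
  expect_equal(pc$spacer, 17L)
  expect_equal(pc$gap10, 7L)
  expect_equal(pc$minus10_seq, "TATAAT")
  expect_equal(pc$minus35_seq, "TTGACA")
  expect_equal(pc$minus10_offset, tss_offset - 13L)
})

test_that("background without recognizable hexamers yields no call", {
  # poly-C scores 6 mismatches per hexamer: over both per-hexamer and total cuts
  seq <- strrep("C", 80)
  expect_null(find_promoter(region_from(seq), -10L))
})

test_that("ties are broken toward the canonical -10 placement", {
  # poly-T makes every candidate layout score identically (3 + 4 mismatches),
  # so the tie-break alone decides: gap 7, spacer 17
  seq <- strrep("T", 80)
  pc <- find_promoter(region_from(seq), -10L, max_mm = 6, max_total_mm = 12)
  expect_equal(pc$gap10, 7L)
  expect_equal(pc$spacer, 17L)
})

test_that("truncated search windows degrade to a partial search", {
  # a 40 bp region with the TSS at -4 leaves room for most but not all
  # -35 placements: the call succeeds but is flagged partial
  pc <- find_promoter(region_from(strrep("T", 40)), -4L,
                      max_mm = 6, max_total_mm = 12)
  expect_true(pc$partial)
  # no layout fits at all: warning and no call
  expect_warning(
    none <- find_promoter(region_from(strrep("T", 18)), -12L,
                          max_mm = 6, max_total_mm = 12),
    "truncated")
  expect_null(none)
})

test_that("the null mismatch calibration returns a usable cut", {
  cut <- calibrate_promoter_mm(n_sims = 40, seed = 3)
  expect_true(is.numeric(cut) && length(cut) == 1)
  expect_true(cut >= 0 && cut <= 12)
  expect_length(attr(cut, "null_mm"), 40)
})

test_that("mode classification is total and matches the positional rules exhaustively", {
  span <- 10L
  tss <- -30L
  prom <- tibble::tibble(minus35_offset = -66L, minus10_offset = -43L)
  # sweep every site placement across the landmarks
  for (s0 in seq(-90L, -10L)) {
    s1 <- s0 + span
    got <- classify_mode(s0, span, tss = tss, promoter = prom)$call
    expected <- if (s1 > tss && s0 < 0) "repressor"
      else if (s1 > -43L && s0 < -37L) "repressor"
      else if (s1 > -66L && s0 < -60L) "repressor"
      else if (s1 <= -66L) "activator"
      else "ambiguous"
    expect_equal(got, expected, info = sprintf("s0 = %d", s0))
  }
  # without a promoter call, the activator boundary falls back to TSS - 35
  for (s0 in seq(-90L, -10L)) {
    s1 <- s0 + span
    got <- classify_mode(s0, span, tss = tss, promoter = NULL)$call
    expected <- if (s1 > tss && s0 < 0) "repressor"
      else if (s1 <= tss - 35L) "activator"
      else "ambiguous"
    expect_equal(got, expected)
  }
  expect_equal(classify_mode(-50L, span, tss = NULL)$call, "unknown")
})

test_that("a site 45 bp upstream of the TSS with a canonical promoter is an activator", {
  span <- 20L
  tss <- -60L
  prom <- tibble::tibble(minus35_offset = tss - 36L, minus10_offset = tss - 13L)
  site_start <- tss - 45L - span
  expect_equal(classify_mode(site_start, span, tss = tss, promoter = prom)$call,
               "activator")
})

test_that("UTR summaries report median and within-cutoff fraction", {
  tss <- tibble::tibble(locus_tag = c("a", "b", "c"),
                        tss_offset = c(-10L, -50L, -300L),
                        utr_len = c(10L, 50L, 300L))
  s <- utr_stats(tss)
  expect_equal(s$median_utr, 50)
  expect_equal(s$frac_within, 2 / 3)
  one <- utr_stats(tibble::tibble(locus_tag = "fucI", tss_offset = -329L,
                                  utr_len = 329L))
  expect_equal(one$median_utr, 329)
  zero <- utr_stats(tibble::tibble(locus_tag = c("x", "y"),
                                   tss_offset = c(0L, 0L), utr_len = c(0L, 0L)))
  expect_equal(zero$median_utr, 0)
  expect_equal(zero$frac_within, 1)
  expect_error(utr_stats(tibble::tibble(locus_tag = character(0),
                                        tss_offset = integer(0),
                                        utr_len = integer(0))), "no TSS")
  # permutation invariance of the median
  set.seed(2)
  utr <- sample(0:300, 21)
  t1 <- tibble::tibble(locus_tag = as.character(1:21), utr_len = utr)
  t2 <- t1[sample(21), ]
  expect_equal(utr_stats(t1)$median_utr, utr_stats(t2)$median_utr)
})

test_that("footprint reports align conserved sites in one column band", {
  sim <- gen_ortholog_regions(generator_config(
    n_species = 3, n_target_operons = 2, n_decoy_genes = 0,
    site_mutation_rate = 0, seed = 91))
  gid <- sim$truth$target_groups[1]
  hits <- sim$truth$sites |>
    dplyr::filter(group_id == gid) |>
    dplyr::mutate(score = 10, site_seq = strrep("A", sim$truth$span))
  rep <- footprint_report(gid, sim$regions, hits = hits, span = sim$truth$span)
  body <- unclass(rep)[-1]  # drop the legend line
  mark_lines <- grep("\\*", body, value = TRUE)
  expect_length(mark_lines, 3L)
  stars <- vapply(mark_lines, function(l) regexpr("\\*", l), 1L,
                  USE.NAMES = FALSE)
  expect_equal(length(unique(stars)), 1L)  # same column in every species
  # a species without a hit gets a sequence line but no marker
  rep2 <- footprint_report(gid, sim$regions, hits = hits[-1, ],
                           span = sim$truth$span)
  expect_length(grep("\\*", unclass(rep2)[-1]), 2L)
  # single species downgraded to a warning
  expect_warning(
    footprint_report(gid, sim$regions[sim$regions$species_id == "sp01", ],
                     hits = hits, span = sim$truth$span),
    "single species")
})
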