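test_that("planted sites are found across genomes with no extras", {
  sim <- gen_toy_genomes(generator_config(
    n_species = 3, n_target_operons = 5, n_decoy_genes = 20,
    site_mutation_rate = 0, seed = 55))
  # train on the truth: build the PWM from the planted site sequences
  regs <- training_regions(sim$groups |>
                             dplyr::filter(group_id %in% sim$truth$target_groups),
                           sim$genomes)
  st <- dplyr::inner_join(regs, sim$truth$sites,
                          by = c("species_id", "locus_tag"))
  sites <- substr(st$seq, st$position + 1, st$position + sim$truth$span)
  sites <- ifelse(st$strand == "-", reverse_complement(sites), sites)
  motif <- build_pwm(sites, geometry = sim$truth$geometry,
                     background = regufoot:::estimate_background(regs$seq))
  hits <- scan_genomes(motif, sim$genomes)
  planted <- dplyr::semi_join(hits, sim$truth$sites,
                              by = c("species_id", "locus_tag", "offset"))
  expect_equal(nrow(planted), 15L)      # all 5 operons x 3 species
  # no extra hits beyond the planted positions at planted-signal strength
  extras <- dplyr::anti_join(hits, sim$truth$sites,
                             by = c("species_id", "locus_tag", "offset"))
  expect_equal(nrow(extras), 0L)
})

test_that("genomes without the TF ortholog are skipped; window 0 is empty", {
  sim <- gen_toy_genomes(generator_config(
    n_species = 3, n_target_operons = 3, n_decoy_genes = 5,
    site_mutation_rate = 0, seed = 56))
  motif <- build_pwm(c("ACGTACGTAC", "ACGTACGTAC"))
  expect_message(
    h <- scan_genomes(motif, sim$genomes, tf_species = c("sp01", "sp02")),
    "skipping")
  expect_false("sp03" %in% h$species_id)
  expect_equal(nrow(scan_genomes(motif, sim$genomes, window = 0)), 0L)
})

test_that("the consistency quorum follows max(quorum_min, ceil(fraction * eligible))", {
  species <- sprintf("s%d", 1:8)
  groups <- tidyr::expand_grid(group_id = c("opA", "opB"), species_id = species) |>
    dplyr::mutate(locus_tag = paste0(species_id, "_", group_id))
  mk_hits <- function(group, n) tibble::tibble(
    species_id = species[seq_len(n)],
    locus_tag = paste0(species[seq_len(n)], "_", group),
    offset = -50L, strand = "+", score = 5, site_seq = "ACGT")
  # opA in 5 of 8 eligible: retained (5 >= max(2, 4)); opB in 1 of 8: removed
  hits <- dplyr::bind_rows(mk_hits("opA", 5), mk_hits("opB", 1))
  reg <- consistency_filter(hits, groups)
  expect_equal(reg$members$group_id, "opA")
  expect_equal(reg$members$n_species_hit, 5L)
  expect_equal(reg$members$quorum, 4L)
  # full-consensus quorum: 7 of 8 is not enough at fraction 1.0
  reg2 <- consistency_filter(mk_hits("opA", 7), groups, quorum_fraction = 1)
  expect_equal(nrow(reg2$members), 0L)
  reg3 <- consistency_filter(mk_hits("opA", 8), groups, quorum_fraction = 1)
  expect_equal(nrow(reg3$members), 1L)
})

test_that("single-species scans return all hits but are flagged unverified", {
  groups <- tibble::tibble(group_id = "opA", species_id = "s1",
                           locus_tag = "s1_opA")
  hits <- tibble::tibble(species_id = "s1", locus_tag = "s1_opA",
                         offset = -40L, strand = "+", score = 3,
                         site_seq = "ACGT")
  expect_warning(reg <- consistency_filter(hits, groups), "unverified")
  expect_true(reg$unverified)
  expect_equal(nrow(reg$members), 1L)
})

test_that("lowering the quorum never removes regulon members", {
  set.seed(77)
  species <- sprintf("s%d", 1:6)
  groups <- tidyr::expand_grid(group_id = sprintf("op%d", 1:10),
                               species_id = species) |>
    dplyr::mutate(locus_tag = paste0(species_id, "_", group_id))
  hits <- groups |>
    dplyr::slice_sample(prop = 0.5) |>
    dplyr::mutate(offset = -30L, strand = "+", score = 4, site_seq = "ACGT") |>
    dplyr::select(species_id, locus_tag, offset, strand, score, site_seq)
  for (f in c(0.9, 0.7, 0.5, 0.3)) {
    hi <- consistency_filter(hits, groups, quorum_fraction = f)$members$group_id
    lo <- consistency_filter(hits, groups, quorum_fraction = f - 0.2)$members$group_id
    expect_true(all(hi %in% lo))
  }
})

test_that("hits exported as GFF3 point back at the genomic site sequence", {
  sim <- gen_toy_genomes(generator_config(
    n_species = 2, n_target_operons = 3, n_decoy_genes = 2,
    site_mutation_rate = 0, seed = 57))
  regs <- training_regions(sim$groups |>
                             dplyr::filter(group_id %in% sim$truth$target_groups),
                           sim$genomes)
  st <- dplyr::inner_join(regs, sim$truth$sites, by = c("species_id", "locus_tag"))
  sites <- substr(st$seq, st$position + 1, st$position + sim$truth$span)
  sites <- ifelse(st$strand == "-", reverse_complement(sites), sites)
  motif <- build_pwm(sites, geometry = sim$truth$geometry)
  hits <- scan_genomes(motif, sim$genomes)
  path <- withr::local_tempfile(fileext = ".gff3")
  write_hits_gff(hits, sim$genomes, path, span = sim$truth$span)
  gr <- rtracklayer::import(path)
  expect_equal(length(gr), nrow(hits))
  for (i in seq_len(length(gr))) {
    gnm <- sim$genomes[[gr$species_id[i]]]
    raw <- substr(gnm$contigs[["c1"]], GenomicRanges::start(gr)[i],
                  GenomicRanges::end(gr)[i])
    oriented <- if (as.character(GenomicRanges::strand(gr))[i] == "-")
      reverse_complement(raw) else raw
    expect_equal(oriented, gr$site_seq[i])
  }
})
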