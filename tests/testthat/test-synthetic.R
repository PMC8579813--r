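test_that("background sequences hit the requested GC content and are seeded", {
  s <- gen_background(1e5, gc = 0.35, seed = 2)
  gc_obs <- mean(strsplit(s, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc_obs - 0.35), 0.01)
  expect_equal(gen_background(0, 0.5), "")
  expect_identical(gen_background(500, 0.4, seed = 9),
                   gen_background(500, 0.4, seed = 9))
  expect_error(gen_background(10, gc = 1.5), "gc")
})

test_that("ortholog regions carry conserved planted sites in diverged background", {
  cf <- generator_config(n_species = 5, n_target_operons = 6,
                         n_decoy_genes = 10, seed = 31)
  sim <- gen_ortholog_regions(cf)
  expect_equal(nrow(sim$regions), (6 + 10) * 5)
  lay <- regufoot:::geometry_layout(sim$truth$geometry)

  st <- dplyr::inner_join(sim$regions, sim$truth$sites,
                          by = c("species_id", "locus_tag", "group_id"))
  site_seq <- substr(st$seq, st$position + 1, st$position + sim$truth$span)
  site_seq <- ifelse(st$strand == "-", reverse_complement(site_seq), site_seq)
  ident <- vapply(site_seq, function(s)
    mean(strsplit(s, "")[[1]][lay$offsets + 1] ==
           strsplit(sim$truth$consensus, "")[[1]]), numeric(1))
  # expected per-base identity >= 1 - mutation_rate (mutation always changes
  # the base, so identity ~ 1 - 0.1 with binomial noise)
  expect_gte(mean(ident), 1 - cf$site_mutation_rate - 0.05)

  # site columns are more conserved than background columns across species
  by_group <- split(st, st$group_id)
  pid <- function(a, b) mean(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  site_div <- bg_div <- numeric(0)
  for (g in by_group) {
    ref <- g$seq[g$species_id == "sp01"]
    for (other in g$seq[g$species_id != "sp01"]) {
      cols <- g$position[1] + lay$offsets + 1
      a <- strsplit(ref, "")[[1]]; b <- strsplit(other, "")[[1]]
      site_div <- c(site_div, mean(a[cols] != b[cols]))
      bg_div <- c(bg_div, mean(a[-cols] != b[-cols]))
    }
  }
  expect_lt(mean(site_div), mean(bg_div))
})

test_that("mutation-free sites are exact and decoys can be disabled", {
  cf <- generator_config(n_species = 3, n_target_operons = 4,
                         n_decoy_genes = 0, site_mutation_rate = 0, seed = 8)
  sim <- gen_ortholog_regions(cf)
  expect_equal(nrow(sim$regions), 12L)
  lay <- regufoot:::geometry_layout(sim$truth$geometry)
  st <- dplyr::inner_join(sim$regions, sim$truth$sites,
                          by = c("species_id", "locus_tag", "group_id"))
  site_seq <- substr(st$seq, st$position + 1, st$position + sim$truth$span)
  site_seq <- ifelse(st$strand == "-", reverse_complement(site_seq), site_seq)
  cons_cols <- strsplit(sim$truth$consensus, "")[[1]]
  for (s in site_seq) {
    expect_identical(strsplit(s, "")[[1]][lay$offsets + 1], cons_cols)
  }
})

test_that("toy genomes round-trip through FASTA/TSV and preserve coordinates", {
  cf <- generator_config(n_species = 2, n_target_operons = 3,
                         n_decoy_genes = 3, seed = 5)
  sim <- gen_toy_genomes(cf)
  dir <- withr::local_tempdir()
  write_sim_dataset(sim, dir)
  for (sp in names(sim$genomes)) {
    back <- read_genome(file.path(dir, paste0(sp, ".fna")),
                        file.path(dir, paste0(sp, ".features.tsv")),
                        species_id = sp)
    expect_identical(back$contigs, sim$genomes[[sp]]$contigs)
    expect_equal(back$genes$start, sim$genomes[[sp]]$genes$start)
    expect_equal(back$genes$end, sim$genomes[[sp]]$genes$end)
    expect_equal(back$genes$strand, sim$genomes[[sp]]$genes$strand)
  }
  groups_back <- read_ortholog_groups(file.path(dir, "orthologs.tsv"))
  expect_equal(nrow(groups_back), nrow(sim$groups))
  tss_back <- read_tss(file.path(dir, "tss.tsv"))
  expect_equal(tss_back$tss_offset, sim$tss$tss_offset)

  # extraction recovers the planted upstream regions exactly, both strands
  for (sp in names(sim$genomes)) {
    gnm <- sim$genomes[[sp]]
    for (lt in gnm$genes$locus_tag) {
      reg <- extract_upstream(gnm, lt, max_len = cf$region_len)
      expect_equal(nchar(reg$seq), cf$region_len)
    }
  }
  st <- sim$truth$sites[sim$truth$sites$species_id == "sp01", ]
  for (i in seq_len(nrow(st))) {
    reg <- extract_upstream(sim$genomes$sp01, st$locus_tag[i])
    site <- substr(reg$seq, st$position[i] + 1, st$position[i] + sim$truth$span)
    if (st$strand[i] == "-") site <- reverse_complement(site)
    lay <- regufoot:::geometry_layout(sim$truth$geometry)
    expect_identical(strsplit(site, "")[[1]][lay$offsets + 1],
                     strsplit(sim$truth$consensus, "")[[1]])
  }
})

test_that("planted TSS geometries classify as planted modes on the reference", {
  cf <- generator_config(n_species = 2, n_target_operons = 8,
                         n_decoy_genes = 0, repressor_fraction = 1, seed = 19)
  sim <- gen_toy_genomes(cf)
  ops <- sim$truth$operons
  expect_true(all(ops$mode == "repressor"))
  for (i in seq_len(nrow(ops))) {
    lt <- paste0("sp01_", ops$group_id[i])
    reg <- extract_upstream(sim$genomes$sp01, lt)
    prom <- find_promoter(reg, ops$tss_offset[i])
    call <- classify_mode(ops$site_offset[i], sim$truth$span,
                          tss = ops$tss_offset[i], promoter = prom)
    expect_equal(call$call, "repressor")
  }
  cf_act <- generator_config(n_species = 2, n_target_operons = 8,
                             n_decoy_genes = 0, repressor_fraction = 0,
                             seed = 20)
  sim_act <- gen_toy_genomes(cf_act)
  ops_act <- sim_act$truth$operons
  for (i in seq_len(nrow(ops_act))) {
    lt <- paste0("sp01_", ops_act$group_id[i])
    reg <- extract_upstream(sim_act$genomes$sp01, lt)
    prom <- find_promoter(reg, ops_act$tss_offset[i])
    call <- classify_mode(ops_act$site_offset[i], sim_act$truth$span,
                          tss = ops_act$tss_offset[i], promoter = prom)
    expect_equal(call$call, "activator")
  }
})

test_that("UTR lengths track the configured median", {
  sim <- gen_toy_genomes(generator_config(n_decoy_genes = 150, seed = 23))
  s <- utr_stats(sim$tss)
  expect_gt(s$n, 100)
  expect_lt(abs(s$median_utr - 50), 15)
})

test_that("expression truth: members exceed the DE threshold on inducing pairs", {
  cf <- generator_config(seed = 29)
  genes <- sprintf("g%03d", 1:210)
  members <- genes[1:10]
  ge <- gen_expression(cf, members, genes)
  fc <- log2fc(ge$expr, "xylan", "glucose")
  expect_gte(mean(fc$log2fc[fc$gene %in% members] > 2), 0.95)
  expect_identical(gen_expression(cf, members, genes)$expr, ge$expr)
})

test_that("all generator outputs are deterministic under a fixed seed", {
  cf <- generator_config(n_species = 3, n_target_operons = 3,
                         n_decoy_genes = 5, seed = 101)
  s1 <- gen_toy_genomes(cf)
  s2 <- gen_toy_genomes(cf)
  expect_identical(s1$genomes$sp02$contigs, s2$genomes$sp02$contigs)
  expect_identical(s1$truth$sites, s2$truth$sites)
  o1 <- gen_ortholog_regions(cf)
  o2 <- gen_ortholog_regions(cf)
  expect_identical(o1$regions$seq, o2$regions$seq)
})
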