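# Fixtures are built in code; nothing is read from disk except files the
# tests themselves write to tempdir().

# A small genome with genes at chosen coordinates over a random contig.
make_test_genome <- function(genes, contig_len = 1000, species_id = "spT",
                             gc = 0.5, seed = 42) {
  contig <- gen_background(contig_len, gc, seed = seed)
  genome_record(species_id, c(c1 = contig), genes)
}

gene_row <- function(locus_tag, start, end, strand = "+", contig = "c1") {
  tibble::tibble(locus_tag = locus_tag, contig = contig, start = start,
                 end = end, strand = strand, product = NA_character_)
}

# Independent brute-force PWM scorer: explicit loops over positions, strands
# and columns, its own complement table, no shared code with score_region.
brute_force_scores <- function(motif, seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  span <- motif$layout$span
  offs <- motif$layout$offsets
  w <- motif$weights
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  npos <- L - span + 1
  out <- list(plus = numeric(0), minus = numeric(0))
  if (npos < 1) return(out)
  score_chars <- function(site_chars) {
    s <- 0
    for (j in seq_along(offs)) {
      b <- site_chars[offs[j] + 1]
      if (b != "N") s <- s + unname(w[b, j])
    }
    s
  }
  for (p in 0:(npos - 1)) {
    window <- chars[(p + 1):(p + span)]
    out$plus <- c(out$plus, score_chars(window))
    rc <- rev(unname(comp[window]))
    out$minus <- c(out$minus, score_chars(rc))
  }
  out
}

# a random plain motif built from random sites
random_motif <- function(width = 8, n_sites = 6, gc = 0.5) {
  sites <- replicate(n_sites, gen_background(width, gc))
  build_pwm(sites, background = gc_bg4(gc))
}

gc_bg4 <- function(gc) c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
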