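# Ground-truthed synthetic data.  The generator emulates the statistical
# structure of a multi-genome regulon study: orthologous upstream regions
# (<= 300 bp) across k pseudo-species carrying conserved planted motif
# instances in diverged background, toy genomes with TSS geometries realizing
# repressor/activator layouts, and regulon-structured expression matrices
# over five substrate conditions.

#' Generator configuration
#'
#' Defaults are the benchmark study conditions: 8 species, 10 target operons,
#' 200 decoy genes per genome, 300 bp upstream regions at thermophile-like
#' GC 0.35, per-base site mutation rate 0.1 against a background divergence
#' of 0.3, a 20 bp palindromic motif, and an expression effect of +3 log2
#' units (noise sd 0.3) on the inducing substrate.
#'
#' @param n_species Number of pseudo-species (default 8).
#' @param n_target_operons Regulon member operons (default 10).
#' @param n_decoy_genes Unregulated genes per genome (default 200).
#' @param region_len Upstream region length in bp (default 300).
#' @param gc Background GC fraction (default 0.35).
#' @param divergence Per-base background resampling rate per species
#'   (default 0.3).
#' @param site_mutation_rate Per-base substitution rate at motif site columns
#'   (default 0.1); sites are more conserved than background, which is the
#'   footprinting signal.
#' @param motif Planted motif geometry: a list with `mode` and `width`
#'   (palindrome), `unit`/`period` (direct repeat), or `unit`/`spacer`
#'   (spaced inverted repeat); an explicit `consensus` string may be given.
#' @param n_training_operons Target operons whose genomic context is assumed
#'   known a priori, used as the discovery training set (default 4).
#' @param repressor_fraction Fraction of target operons realizing repressor
#'   site/TSS geometry; the rest realize activator geometry (default 0.5).
#' @param tss_median Median 5' UTR length in bp (default 50).
#' @param tss_fraction Probability that a decoy operon has a mapped TSS
#'   (default 0.8); target operons always do.
#' @param orf_len Placeholder ORF length in bp (default 150).
#' @param conditions Expression conditions (default: the five study
#'   substrates).
#' @param inducing Condition(s) on which regulon members are induced
#'   (default `"xylan"`).
#' @param effect Induction effect size in log2 units (default 3).
#' @param noise_sd Expression noise sd (default 0.3).
#' @param baseline_mean,baseline_sd Per-gene baseline distribution
#'   (default Normal(8, 1)).
#' @param seed Master seed (default 1).
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_species = 8, n_target_operons = 10,
                             n_decoy_genes = 200, region_len = 300,
                             gc = 0.35, divergence = 0.3,
                             site_mutation_rate = 0.1,
                             motif = list(mode = "palindrome", width = 20),
                             n_training_operons = 4,
                             repressor_fraction = 0.5, tss_median = 50,
                             tss_fraction = 0.8, orf_len = 150,
                             conditions = c("cellulose", "cellobiose",
                                            "glucose", "xylan", "xylose"),
                             inducing = "xylan", effect = 3, noise_sd = 0.3,
                             baseline_mean = 8, baseline_sd = 1, seed = 1) {
  stopifnot(n_species >= 2, gc >= 0, gc <= 1,
            site_mutation_rate >= 0, site_mutation_rate <= 1,
            divergence >= 0, divergence <= 1)
  structure(as.list(environment()), class = "generator_config")
}

#' Generate an i.i.d. background sequence
#'
#' @param length Sequence length (>= 0).
#' @param gc GC fraction: `P(G) = P(C) = gc / 2`.
#' @param seed Optional seed; by default the current RNG stream is used.
#' @return A character scalar.
#' @export
gen_background <- function(length, gc = 0.35, seed = NULL) {
  if (gc < 0 || gc > 1) abort("gc must be in [0, 1]")
  stopifnot(length >= 0)
  draw <- function() {
    if (length == 0) return("")
    paste(sample(DNA_BASES, length, replace = TRUE, prob = gc_background(gc)),
          collapse = "")
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

# planted-motif helpers ------------------------------------------------------

# draw a consensus for a geometry; returns list(geometry, consensus_units)
draw_consensus <- function(motif, gc) {
  g <- list(mode = motif$mode,
            width = motif$width %||% NA_integer_,
            unit = motif$unit %||% NA_integer_,
            period = motif$period %||% NA_integer_,
            spacer = motif$spacer %||% NA_integer_)
  if (!is.null(motif$consensus)) {
    if (g$mode == "palindrome") {
      g$width <- nchar(motif$consensus)
      return(list(geometry = g, units = motif$consensus))
    }
    abort("an explicit consensus string is supported for palindromes only; use 'unit'")
  }
  if (g$mode == "palindrome") {
    w <- g$width
    half <- gen_background(ceiling(w / 2), gc)
    cons <- if (w %% 2 == 0) {
      paste0(half, reverse_complement(half))
    } else {
      paste0(half, reverse_complement(substr(half, 1, w %/% 2)))
    }
    list(geometry = g, units = cons)
  } else {
    unit <- if (is.character(motif$unit)) motif$unit
            else gen_background(g$unit, gc)
    g$unit <- nchar(unit)
    list(geometry = g, units = unit)
  }
}

# realize one planted instance (full span string); linkers are fresh draws
realize_instance <- function(cons, gc) {
  g <- cons$geometry
  switch(g$mode,
    palindrome = cons$units,
    direct_repeat = paste0(cons$units,
                           gen_background(g$period - g$unit, gc), cons$units),
    inverted_repeat_spaced = paste0(cons$units, gen_background(g$spacer, gc),
                                    reverse_complement(cons$units)))
}

# substitute bases at `idx` (1-based) with a different base, w.p. rate each
mutate_positions <- function(chars, idx, rate) {
  if (rate <= 0 || length(idx) == 0) return(chars)
  hit <- idx[runif(length(idx)) < rate]
  for (i in hit) {
    chars[i] <- sample(setdiff(DNA_BASES, chars[i]), 1)
  }
  chars
}

# resample bases at `idx` from the background, w.p. rate each
diverge_positions <- function(chars, idx, rate, gc) {
  if (rate <= 0 || length(idx) == 0) return(chars)
  hit <- idx[runif(length(idx)) < rate]
  if (length(hit) > 0)
    chars[hit] <- sample(DNA_BASES, length(hit), replace = TRUE,
                         prob = gc_background(gc))
  chars
}

#' Generate a single-species training set with planted sites
#'
#' `n_regions` background regions, each carrying one planted instance of a
#' fixed consensus at a random position and strand, with optional per-base
#' substitution at the modeled site columns.
#'
#' @param n_regions,region_len Training-set shape.
#' @param motif Planted geometry as in [generator_config()].
#' @param gc Background GC fraction.
#' @param mutation_rate Per-base substitution rate at modeled site columns
#'   (default 0).
#' @param seed Integer seed.
#' @return List with `regions` (tibble), `truth` (site tibble with
#'   0-based `position`, `offset`, `strand`), `consensus`, `geometry`.
#' @export
gen_training_set <- function(n_regions, region_len = 300,
                             motif = list(mode = "palindrome", width = 20),
                             gc = 0.5, mutation_rate = 0, seed = 1) {
  with_seed(seed, {
    cons <- draw_consensus(motif, gc)
    lay <- geometry_layout(cons$geometry)
    if (lay$span > region_len) abort("motif span exceeds region length")
    rows <- purrr::map(seq_len(n_regions), function(i) {
      inst <- realize_instance(cons, gc)
      chars <- strsplit(gen_background(region_len, gc), "")[[1]]
      p <- sample.int(region_len - lay$span + 1L, 1) - 1L
      strand <- sample(c("+", "-"), 1)
      planted <- if (strand == "+") inst else reverse_complement(inst)
      pchars <- strsplit(planted, "")[[1]]
      site_cols <- if (strand == "+") lay$offsets + 1L
                   else lay$span - lay$offsets
      pchars <- mutate_positions(pchars, site_cols, mutation_rate)
      chars[(p + 1):(p + lay$span)] <- pchars
      list(seq = paste(chars, collapse = ""), position = p, strand = strand)
    })
    regions <- tibble(
      species_id = "sim", locus_tag = sprintf("r%03d", seq_len(n_regions)),
      seq = purrr::map_chr(rows, "seq"),
      offset_start = -region_len, offset_end = 0L, truncated_by = "none")
    truth <- tibble(
      locus_tag = regions$locus_tag,
      position = purrr::map_int(rows, "position"),
      offset = purrr::map_int(rows, "position") - region_len,
      strand = purrr::map_chr(rows, "strand"))
    list(regions = regions, truth = truth, consensus = cons$units,
         geometry = cons$geometry, span = lay$span)
  })
}

#' Generate orthologous upstream regions across pseudo-species
#'
#' One ancestral region per target operon carries a planted consensus
#' instance; per-species copies resample background bases at the divergence
#' rate and substitute site bases at the (lower) site mutation rate, so
#' sites are conserved islands.  Decoy groups get independent background in
#' every species.
#'
#' @param config A [generator_config()].
#' @return List with `regions`, `groups`, `truth` (`$sites`, `$consensus`,
#'   `$geometry`, `$target_groups`, `$training_groups`).
#' @export
gen_ortholog_regions <- function(config) {
  cf <- config
  with_seed(cf$seed, {
    cons <- draw_consensus(cf$motif, cf$gc)
    lay <- geometry_layout(cons$geometry)
    if (lay$span > cf$region_len) abort("motif span exceeds region length")
    species <- sprintf("sp%02d", seq_len(cf$n_species))
    target_groups <- sprintf("tg%02d", seq_len(cf$n_target_operons))
    decoy_groups <- sprintf("dc%03d", seq_len(cf$n_decoy_genes))

    target <- purrr::map(seq_len(cf$n_target_operons), function(j) {
      anc <- strsplit(gen_background(cf$region_len, cf$gc), "")[[1]]
      inst <- realize_instance(cons, cf$gc)
      p <- sample.int(cf$region_len - lay$span + 1L, 1) - 1L
      strand <- sample(c("+", "-"), 1)
      planted <- if (strand == "+") inst else reverse_complement(inst)
      anc[(p + 1):(p + lay$span)] <- strsplit(planted, "")[[1]]
      site_cols <- p + if (strand == "+") lay$offsets + 1L
                       else lay$span - lay$offsets
      bg_cols <- setdiff(seq_len(cf$region_len), site_cols)
      per_sp <- purrr::map(seq_len(cf$n_species), function(s) {
        chars <- anc
        if (s > 1) {  # species 1 is the reference/anchor genome
          chars <- diverge_positions(chars, bg_cols, cf$divergence, cf$gc)
          chars <- mutate_positions(chars, site_cols, cf$site_mutation_rate)
        }
        paste(chars, collapse = "")
      })
      list(seqs = per_sp, position = p, strand = strand)
    })
    decoys <- purrr::map(seq_len(cf$n_decoy_genes), function(j) {
      purrr::map(seq_len(cf$n_species), function(s)
        gen_background(cf$region_len, cf$gc))
    })

    regions <- bind_rows(
      tidyr::expand_grid(g = seq_len(cf$n_target_operons),
                         s = seq_len(cf$n_species)) |>
        mutate(group_id = target_groups[.data$g], species_id = species[.data$s],
               locus_tag = paste0(species[.data$s], "_", target_groups[.data$g]),
               seq = purrr::map2_chr(.data$g, .data$s, ~ target[[.x]]$seqs[[.y]])),
      tidyr::expand_grid(g = seq_len(cf$n_decoy_genes),
                         s = seq_len(cf$n_species)) |>
        mutate(group_id = decoy_groups[.data$g], species_id = species[.data$s],
               locus_tag = paste0(species[.data$s], "_", decoy_groups[.data$g]),
               seq = purrr::map2_chr(.data$g, .data$s, ~ decoys[[.x]][[.y]]))
    ) |>
      mutate(offset_start = -cf$region_len, offset_end = 0L,
             truncated_by = "none") |>
      select("species_id", "locus_tag", "group_id", "seq",
             "offset_start", "offset_end", "truncated_by")

    groups <- regions |> select("group_id", "species_id", "locus_tag")
    sites <- tidyr::expand_grid(g = seq_len(cf$n_target_operons),
                                s = seq_len(cf$n_species)) |>
      mutate(group_id = target_groups[.data$g], species_id = species[.data$s],
             locus_tag = paste0(species[.data$s], "_", target_groups[.data$g]),
             position = purrr::map_int(.data$g, ~ target[[.x]]$position),
             offset = .data$position - cf$region_len,
             strand = purrr::map_chr(.data$g, ~ target[[.x]]$strand)) |>
      select(-"g", -"s")
    truth <- list(sites = sites, consensus = cons$units,
                  geometry = cons$geometry, span = lay$span,
                  target_groups = target_groups,
                  training_groups = target_groups[seq_len(min(cf$n_training_operons,
                                                              cf$n_target_operons))],
                  decoy_groups = decoy_groups)
    list(regions = regions, groups = groups, truth = truth)
  })
}

#' Generate toy genomes with TSS-anchored site geometries
#'
#' Assembles, for every pseudo-species, a contig that concatenates
#' `[upstream region][placeholder ORF]` blocks (strand alternating) for each
#' target operon and decoy gene, so that [extract_upstream()] with the
#' default 300 bp window recovers exactly the planted regions.  Target
#' operons realize a prescribed repressor or activator geometry: repressor
#' sites lie within (or straddle the start of) the 5' UTR, activator sites
#' end 45 bp upstream of the TSS, and consensus `TTGACA`/`TATAAT` hexamers
#' are planted at canonical spacing (17 bp spacer, 7 bp gap to the TSS).
#' 5' UTR lengths are drawn with median `tss_median`.  Species 1 is the
#' unmutated reference (where TSS are mapped); the others diverge.
#'
#' @param config A [generator_config()].
#' @return A `regufoot_sim` list: `genomes` (named [genome_record()]s),
#'   `groups`, `tss` (reference species), `truth`, and `config`.
#' @export
gen_toy_genomes <- function(config) {
  cf <- config
  with_seed(cf$seed, {
    cons <- draw_consensus(cf$motif, cf$gc)
    lay <- geometry_layout(cons$geometry)
    S <- lay$span
    if (S > cf$region_len) abort("motif span exceeds region length")
    species <- sprintf("sp%02d", seq_len(cf$n_species))
    target_groups <- sprintf("tg%02d", seq_len(cf$n_target_operons))
    decoy_groups <- sprintf("dc%03d", seq_len(cf$n_decoy_genes))
    n_rep <- round(cf$repressor_fraction * cf$n_target_operons)

    draw_utr <- function(lo) {
      med <- max(cf$tss_median - lo, 1)
      lo + stats::rgeom(1, prob = 1 - 0.5^(1 / med))
    }

    targets <- purrr::map(seq_len(cf$n_target_operons), function(j) {
      mode <- if (j <= n_rep) "repressor" else "activator"
      if (mode == "repressor") {
        utr <- min(draw_utr(ceiling(S / 2) + 2L), cf$region_len - 20L)
        t_off <- -utr
        s0 <- if (utr >= S + 4L) {
          sample(seq(t_off, -S), 1)           # site wholly inside the UTR
        } else t_off - S %/% 2L               # site straddles the TSS
      } else {
        utr <- min(draw_utr(15L), cf$region_len - 45L - S - 5L)
        t_off <- -utr
        s0 <- t_off - 45L - S                 # site ends 45 bp upstream of TSS
      }
      inst <- realize_instance(cons, cf$gc)
      strand <- sample(c("+", "-"), 1)
      anc <- strsplit(gen_background(cf$region_len, cf$gc), "")[[1]]
      at <- function(off) off + cf$region_len + 1L  # offset -> 1-based index
      # canonical sigma-A promoter anchored at the TSS
      o10 <- t_off - 6L - 7L
      o35 <- o10 - 17L - 6L
      anc[at(o10) + 0:5] <- strsplit("TATAAT", "")[[1]]
      anc[at(o35) + 0:5] <- strsplit("TTGACA", "")[[1]]
      planted <- if (strand == "+") inst else reverse_complement(inst)
      p <- at(s0) - 1L  # 0-based site start within the region
      anc[(p + 1):(p + S)] <- strsplit(planted, "")[[1]]
      site_cols <- p + if (strand == "+") lay$offsets + 1L else S - lay$offsets
      bg_cols <- setdiff(seq_len(cf$region_len), site_cols)
      seqs <- purrr::map_chr(seq_len(cf$n_species), function(s) {
        chars <- anc
        if (s > 1) {
          chars <- diverge_positions(chars, bg_cols, cf$divergence, cf$gc)
          chars <- mutate_positions(chars, site_cols, cf$site_mutation_rate)
        }
        paste(chars, collapse = "")
      })
      list(mode = mode, tss_offset = t_off, site_offset = s0,
           site_strand = strand, minus10_offset = o10, minus35_offset = o35,
           seqs = seqs)
    })
    decoy_seqs <- purrr::map(seq_len(cf$n_decoy_genes), function(j)
      purrr::map_chr(seq_len(cf$n_species), function(s)
        gen_background(cf$region_len, cf$gc)))
    decoy_tss <- purrr::map(seq_len(cf$n_decoy_genes), function(j) {
      if (runif(1) < cf$tss_fraction) -draw_utr(15L) else NA_integer_
    })

    all_groups <- c(target_groups, decoy_groups)
    n_genes <- length(all_groups)
    genomes <- purrr::map(seq_len(cf$n_species), function(s) {
      chunks <- character(0)
      rows <- vector("list", n_genes)
      cursor <- 0L
      for (i in seq_len(n_genes)) {
        up <- if (i <= cf$n_target_operons) targets[[i]]$seqs[s]
              else decoy_seqs[[i - cf$n_target_operons]][s]
        orf <- paste0("ATG", gen_background(cf$orf_len - 6L, cf$gc), "TAA")
        strand <- if (i %% 2 == 1) "+" else "-"
        lt <- paste0(species[s], "_", all_groups[i])
        if (strand == "+") {
          chunks <- c(chunks, up, orf)
          rows[[i]] <- tibble(locus_tag = lt, contig = "c1",
                              start = cursor + cf$region_len,
                              end = cursor + cf$region_len + cf$orf_len,
                              strand = "+", product = NA_character_)
        } else {
          chunks <- c(chunks, reverse_complement(orf), reverse_complement(up))
          rows[[i]] <- tibble(locus_tag = lt, contig = "c1",
                              start = cursor, end = cursor + cf$orf_len,
                              strand = "-", product = NA_character_)
        }
        cursor <- cursor + cf$region_len + cf$orf_len
      }
      genome_record(species[s], c(c1 = paste(chunks, collapse = "")),
                    bind_rows(rows))
    })
    names(genomes) <- species

    groups <- tidyr::expand_grid(group_id = all_groups, species_id = species) |>
      mutate(locus_tag = paste0(.data$species_id, "_", .data$group_id))
    ref <- species[1]
    tss <- bind_rows(
      tibble(locus_tag = paste0(ref, "_", target_groups),
             tss_offset = purrr::map_int(targets, "tss_offset")),
      tibble(locus_tag = paste0(ref, "_", decoy_groups),
             tss_offset = purrr::map_int(decoy_tss, ~ .x))) |>
      filter(!is.na(.data$tss_offset)) |>
      mutate(utr_len = -.data$tss_offset)

    operons <- tibble(
      group_id = target_groups,
      mode = purrr::map_chr(targets, "mode"),
      tss_offset = purrr::map_int(targets, "tss_offset"),
      site_offset = purrr::map_int(targets, "site_offset"),
      site_strand = purrr::map_chr(targets, "site_strand"),
      minus10_offset = purrr::map_int(targets, "minus10_offset"),
      minus35_offset = purrr::map_int(targets, "minus35_offset"))
    sites <- tidyr::expand_grid(group_id = target_groups,
                                species_id = species) |>
      left_join(operons |> select("group_id", "site_offset", "site_strand"),
                by = "group_id") |>
      mutate(locus_tag = paste0(.data$species_id, "_", .data$group_id),
             offset = .data$site_offset,
             position = .data$site_offset + cf$region_len,
             strand = .data$site_strand) |>
      select("group_id", "species_id", "locus_tag", "position", "offset",
             "strand")

    truth <- list(sites = sites, operons = operons, consensus = cons$units,
                  geometry = cons$geometry, span = S,
                  target_groups = target_groups,
                  training_groups = target_groups[seq_len(min(cf$n_training_operons,
                                                              cf$n_target_operons))],
                  decoy_groups = decoy_groups, reference = ref)
    structure(list(genomes = genomes, groups = groups, tss = tss,
                   truth = truth, config = cf),
              class = "regufoot_sim")
  })
}

#' @export
print.regufoot_sim <- function(x, ...) {
  cf <- x$config
  cat(sprintf("<regufoot_sim> %d species x (%d target + %d decoy) genes; motif %s (%s)\n",
              cf$n_species, cf$n_target_operons, cf$n_decoy_genes,
              x$truth$consensus, geometry_label(x$truth$geometry)))
  invisible(x)
}

#' Generate a regulon-structured expression matrix
#'
#' Per-gene baseline `Normal(baseline_mean, baseline_sd)`, plus `effect`
#' log2 units for regulon members on the inducing condition(s), plus
#' `Normal(0, noise_sd)` noise everywhere.
#'
#' @param config A [generator_config()].
#' @param members Character vector of member gene ids.
#' @param genes All gene ids (members must be a subset).
#' @return List with `expr` (wide tibble) and `truth` (members, inducing
#'   conditions, and the expected DE gene set per inducing/non-inducing
#'   pair).
#' @export
gen_expression <- function(config, members, genes) {
  cf <- config
  seed <- derive_seeds(cf$seed, 2)[2]
  with_seed(seed, {
    baseline <- rnorm(length(genes), cf$baseline_mean, cf$baseline_sd)
    vals <- purrr::map(cf$conditions, function(cond) {
      mu <- baseline + cf$effect * ((genes %in% members) &
                                      (cond %in% cf$inducing))
      mu + rnorm(length(genes), 0, cf$noise_sd)
    })
    expr <- bind_cols(tibble(gene = genes),
                      stats::setNames(as_tibble(vals, .name_repair = "minimal"),
                                      cf$conditions))
    pairs <- tidyr::expand_grid(cond_up = cf$inducing,
                                cond_down = setdiff(cf$conditions, cf$inducing))
    list(expr = expr,
         truth = list(members = members, inducing = cf$inducing,
                      expected_pairs = pairs))
  })
}

#' Write a synthetic dataset to disk in the package's input formats
#'
#' Per-species FASTA + feature TSV, ortholog table, TSS table, optional
#' expression matrix, and truth TSVs sufficient to score any pipeline stage
#' without re-running the generator.
#'
#' @param sim A `regufoot_sim` from [gen_toy_genomes()].
#' @param dir Output directory (created if needed).
#' @param expr Optional expression tibble from [gen_expression()].
#' @return Invisibly, `dir`.
#' @export
write_sim_dataset <- function(sim, dir, expr = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sp in names(sim$genomes)) {
    write_genome(sim$genomes[[sp]],
                 file.path(dir, paste0(sp, ".fna")),
                 file.path(dir, paste0(sp, ".features.tsv")))
  }
  readr::write_tsv(sim$groups, file.path(dir, "orthologs.tsv"), progress = FALSE)
  readr::write_tsv(sim$tss, file.path(dir, "tss.tsv"), progress = FALSE)
  if (!is.null(expr))
    readr::write_tsv(expr, file.path(dir, "expression.tsv"), progress = FALSE)
  readr::write_tsv(sim$truth$sites, file.path(dir, "truth_sites.tsv"),
                   progress = FALSE)
  readr::write_tsv(sim$truth$operons, file.path(dir, "truth_operons.tsv"),
                   progress = FALSE)
  yaml::write_yaml(list(consensus = sim$truth$consensus,
                        geometry = sim$truth$geometry[!is.na(sim$truth$geometry)],
                        target_groups = sim$truth$target_groups,
                        training_groups = sim$truth$training_groups,
                        reference = sim$truth$reference,
                        seed = sim$config$seed),
                   file.path(dir, "truth.yaml"))
  invisible(dir)
}
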