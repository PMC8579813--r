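# End-to-end orchestration: simulate (or load) -> discover -> scan -> filter
# -> annotate -> overlay.  The configuration is a plain list (or a YAML file
# with the same structure); every stage is a pure function of (inputs,
# config, seed), so reruns with the same config are byte-identical.

#' Run the full regulon-reconstruction pipeline
#'
#' Stages: assemble the training set from ortholog groups with known genomic
#' context, discover the binding-site motif, build the PWM with the
#' minimum-training-score threshold, scan every genome's first-in-operon
#' upstream regions, apply the cross-genome consistency filter, classify the
#' TF's mode from TSS/promoter geometry in the reference genome, and overlay
#' differential expression.  With a `simulate` block the inputs come from the
#' synthetic generator and the summary additionally scores the run against
#' the planted truth.
#'
#' @param config A list or path to a YAML file.  Recognized blocks:
#'   `seed`; `simulate` (arguments of [generator_config()]); or `inputs`
#'   (paths: `genomes` = named list of `fasta`/`features`, `orthologs`,
#'   `tss`, `expression`, `training_groups`); `motif_spec` (arguments of
#'   [motif_spec()]); `discovery` (`restarts`); `scan` (`window`,
#'   `min_intergenic`); `quorum` (`fraction`, `min`); `expression`
#'   (`threshold`, `moderate`, `induction`).
#' @param outdir Optional output directory; when given, motifs (MEME),
#'   sites, hits, regulon, mode calls, DE tables, footprint reports and a
#'   JSON summary are written there.
#' @return A `regufoot_run` list with every stage's result and a `summary`
#'   list.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- config$seed %||% 1L
  log_msg <- function(fmt, ...) inform(sprintf(paste0("[regufoot] ", fmt), ...))

  # ---- inputs ---------------------------------------------------------------
  expr <- NULL
  if (!is.null(config$simulate)) {
    cf <- do.call(generator_config, c(config$simulate, list(seed = seed)))
    log_msg("simulating %d genomes (%d target + %d decoy genes)",
            cf$n_species, cf$n_target_operons, cf$n_decoy_genes)
    sim <- gen_toy_genomes(cf)
    genomes <- sim$genomes
    groups <- sim$groups
    tss <- sim$tss
    truth <- sim$truth
    training_groups <- truth$training_groups
    ref_members <- paste0(truth$reference, "_", truth$target_groups)
    ref_genes <- c(ref_members, paste0(truth$reference, "_", truth$decoy_groups))
    expr <- gen_expression(cf, ref_members, ref_genes)$expr
    reference <- truth$reference
    sim_inducing <- cf$inducing
  } else {
    sim_inducing <- NULL
    inp <- config$inputs %||% abort("config needs a 'simulate' or 'inputs' block")
    genomes <- purrr::imap(inp$genomes, function(g, sp)
      read_genome(g$fasta, g$features, species_id = sp))
    groups <- read_ortholog_groups(inp$orthologs)
    tss <- if (!is.null(inp$tss)) read_tss(inp$tss) else NULL
    expr <- if (!is.null(inp$expression)) read_expression(inp$expression) else NULL
    truth <- NULL
    training_groups <- inp$training_groups %||%
      abort("config$inputs needs 'training_groups' (ortholog groups with known TF context)")
    reference <- inp$reference %||% names(genomes)[1]
  }

  spec <- do.call(motif_spec, config$motif_spec %||% list())
  window <- config$scan$window %||% 300
  min_intergenic <- config$scan$min_intergenic %||% 50
  restarts <- config$discovery$restarts %||% 20
  qf <- config$quorum$fraction %||% 0.5
  qm <- config$quorum$min %||% 2
  de_threshold <- config$expression$threshold %||% 2
  de_moderate <- unlist(config$expression$moderate %||% c(1.5, 2))

  # ---- discovery ------------------------------------------------------------
  train <- training_regions(groups |> filter(.data$group_id %in% training_groups),
                            genomes, min_len = min_intergenic, max_len = window)
  log_msg("training set: %d regions from %d groups", nrow(train),
          length(training_groups))
  disc <- discover_motif(train, spec, restarts = restarts, seed = seed)
  log_msg("selected %s, %.2f bits/column, consensus %s",
          geometry_label(disc$geometry), disc$mean_ic, consensus_string(disc))

  # ---- scan + consistency filter -------------------------------------------
  hits <- scan_genomes(disc$motif, genomes, window = window)
  regulon <- consistency_filter(hits, groups, quorum_fraction = qf,
                                quorum_min = qm, species = names(genomes),
                                tf_id = disc$motif$tf_id)
  log_msg("scan: %d hits; regulon: %d member operons", nrow(hits),
          nrow(regulon$members))

  # ---- mode classification (reference genome) ------------------------------
  mode_calls <- NULL
  if (!is.null(tss)) {
    ref_hits <- regulon$hits |> filter(.data$species_id == reference)
    mode_calls <- purrr::pmap(ref_hits, function(locus_tag, offset, ...) {
      tr <- tss[tss$locus_tag == locus_tag, ]
      if (nrow(tr) == 0) {
        return(bind_cols(tibble(locus_tag = locus_tag, offset = offset),
                         classify_mode(offset, disc$span, tss = NULL)))
      }
      reg <- extract_upstream(genomes[[reference]], locus_tag, max_len = window)
      prom <- find_promoter(reg, tr)
      bind_cols(tibble(locus_tag = locus_tag, offset = offset),
                classify_mode(offset, disc$span, tss = tr, promoter = prom))
    }) |> bind_rows()
    calls <- mode_calls$call[mode_calls$call %in% c("repressor", "activator")]
    regulon$mode <- if (length(calls) == 0) "unknown"
      else if (mean(calls == "repressor") >= 0.8) "repressor"
      else if (mean(calls == "activator") >= 0.8) "activator"
      else "ambiguous"
  }

  # ---- expression overlay ---------------------------------------------------
  de <- NULL
  concordance <- NULL
  if (!is.null(expr)) {
    member_genes <- regulon$hits |>
      filter(.data$species_id == reference) |> pull(.data$locus_tag)
    de <- de_crosstab(expr, threshold = de_threshold, moderate = de_moderate,
                      regulon_members = member_genes)
    induction <- config$expression$induction %||%
      (if (!is.null(sim_inducing))
        stats::setNames(list(sim_inducing), disc$motif$tf_id))
    if (!is.null(induction)) {
      concordance <- regulon_concordance(
        de, stats::setNames(list(member_genes), disc$motif$tf_id), induction)
    }
  } else {
    log_msg("no expression matrix: differential-expression stage skipped")
  }

  # ---- summary --------------------------------------------------------------
  summary <- list(
    seed = seed,
    geometry = geometry_label(disc$geometry),
    consensus = consensus_string(disc),
    mean_ic = disc$mean_ic,
    n_training_regions = nrow(train),
    n_training_sites = nrow(disc$sites),
    threshold = disc$motif$threshold,
    n_hits = nrow(hits),
    n_regulon_members = nrow(regulon$members),
    regulon_mode = regulon$mode,
    n_de_union = if (!is.null(de)) de$n_union else NA_integer_,
    concordance = if (!is.null(concordance)) concordance$concordance[1] else NA_real_
  )
  if (!is.null(truth)) {
    pred <- regulon$members$group_id
    pos <- truth$target_groups
    tp <- length(intersect(pred, pos))
    summary$precision <- if (length(pred) > 0) tp / length(pred) else NA_real_
    summary$recall <- tp / length(pos)
    recovered <- disc$sites |>
      inner_join(truth$sites, by = c("species_id", "locus_tag"),
                 suffix = c("", ".true"))
    summary$site_recovery <- if (nrow(recovered) > 0)
      mean(recovered$offset == recovered$offset.true) else NA_real_
  }

  run <- structure(list(
    config = config, genomes = genomes, groups = groups, tss = tss,
    expr = expr, truth = truth, training = train, discovery = disc,
    hits = hits, regulon = regulon, mode_calls = mode_calls, de = de,
    concordance = concordance, summary = summary
  ), class = "regufoot_run")
  if (!is.null(outdir)) write_run(run, outdir)
  run
}

#' @export
print.regufoot_run <- function(x, ...) {
  s <- x$summary
  cat("<regufoot_run>\n")
  cat(sprintf("  motif: %s  consensus %s  (%.2f bits/col, threshold %.2f)\n",
              s$geometry, s$consensus, s$mean_ic, s$threshold))
  cat(sprintf("  regulon: %d member operon(s) from %d scan hits; mode %s\n",
              s$n_regulon_members, s$n_hits, s$regulon_mode))
  if (!is.null(s$precision))
    cat(sprintf("  vs truth: precision %.3f, recall %.3f, site recovery %.3f\n",
                s$precision, s$recall, s$site_recovery))
  if (!is.na(s$concordance %||% NA))
    cat(sprintf("  expression concordance: %.3f\n", s$concordance))
  invisible(x)
}

# write all stage outputs under `outdir`
write_run <- function(run, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_meme(run$discovery$motif, file.path(outdir, "motif.meme"))
  readr::write_tsv(run$discovery$sites, file.path(outdir, "training_sites.tsv"),
                   progress = FALSE)
  readr::write_tsv(logo_data(run$discovery$motif), file.path(outdir, "logo.tsv"),
                   progress = FALSE)
  readr::write_tsv(run$hits, file.path(outdir, "hits.tsv"), progress = FALSE)
  readr::write_tsv(run$regulon$members, file.path(outdir, "regulon.tsv"),
                   progress = FALSE)
  if (!is.null(run$mode_calls))
    readr::write_tsv(run$mode_calls, file.path(outdir, "mode_calls.tsv"),
                     progress = FALSE)
  if (!is.null(run$de)) write_de_crosstab(run$de, file.path(outdir, "de_crosstab.tsv"))
  if (!is.null(run$concordance))
    readr::write_tsv(run$concordance |> mutate(discordant = purrr::map_chr(
      .data$discordant, paste, collapse = ",")),
      file.path(outdir, "concordance.tsv"), progress = FALSE)
  for (gid in head(run$regulon$members$group_id, 5)) {
    regs <- run$training |> filter(.data$group_id == gid)
    if (nrow(regs) >= 2) {
      rep <- footprint_report(gid, regs, hits = run$hits,
                              span = run$discovery$span)
      writeLines(unclass(rep), file.path(outdir, paste0("footprint_", gid, ".txt")))
    }
  }
  jsonlite::write_json(run$summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
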