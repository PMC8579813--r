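# De novo motif discovery: ZOOPS expectation-maximization with the symmetry
# constraint imposed in the M-step, restarted from data-seeded
# initializations over a grid of candidate geometries.  Geometries compete on
# the mean per-column information content of their modeled columns; ties go
# to the smaller span.

#' Discover a symmetric motif in a set of upstream regions
#'
#' Runs seeded EM restarts for every candidate geometry in `spec` and returns
#' the geometry/run with the best model-selection score.  The sequence model
#' is ZOOPS (zero or one site per region, both strands); the symmetry
#' constraint (palindrome, tandem repeat, or spaced inverted repeat) is
#' enforced exactly after every M-step.  Linker/spacer columns are not
#' modeled and score as background.
#'
#' @param regions Tibble of regions (needs a `seq` column; see
#'   [training_regions()]) or a plain character vector of sequences.
#' @param spec A [motif_spec()].
#' @param restarts EM restarts per geometry (default 20).
#' @param seed Integer seed; the run is bit-reproducible given the seed.
#' @param tol Relative log-likelihood convergence tolerance (default 1e-6).
#' @param max_iter Maximum EM iterations per run (default 500).
#' @param gamma0 Initial ZOOPS site prior (default 0.8).
#' @param background Optional length-4 base frequency vector (A,C,G,T);
#'   default is estimated from the regions themselves.
#' @param ic_threshold Optional low-confidence cutoff in bits/column (see
#'   [calibrate_null_ic()]); when supplied, results whose mean information
#'   content falls below it are flagged `low_confidence`.
#' @return A `motif_discovery` object: the fitted [build_pwm()] motif, the
#'   selected geometry, per-region best sites, and per-geometry scores.
#' @export
discover_motif <- function(regions, spec, restarts = 20, seed = 1,
                           tol = 1e-6, max_iter = 500, gamma0 = 0.8,
                           background = NULL, ic_threshold = NULL) {
  regions <- as_region_tbl(regions)
  if (nrow(regions) < 3) abort("need at least 3 regions for motif discovery")
  bg <- background %||% estimate_background(regions$seq)
  bg <- as.numeric(bg) / sum(bg)
  grid <- geometry_grid(spec)
  if (nrow(grid) == 0) abort("motif spec yields no candidate geometry")
  max_span <- max(grid$span)
  short <- nchar(regions$seq) < max_span
  if (any(short)) {
    warn(sprintf("excluding %d region(s) shorter than the maximal motif span (%d bp)",
                 sum(short), max_span))
    regions <- regions[!short, , drop = FALSE]
  }
  if (nrow(regions) < 3) abort("fewer than 3 regions remain after span filtering")

  enc_f <- lapply(regions$seq, function(s) encode_dna(s) - 1L)
  enc_r <- lapply(reverse_complement(regions$seq), function(s) encode_dna(s) - 1L)
  geom_seeds <- derive_seeds(seed, nrow(grid))

  fits <- purrr::pmap(cbind(grid, .seed = geom_seeds), function(mode, width, unit,
                                                                period, spacer, span,
                                                                .seed, ...) {
    g <- list(mode = mode, width = width, unit = unit, period = period,
              spacer = spacer)
    lay <- geometry_layout(g)
    best <- NULL
    run_seeds <- derive_seeds(.seed, restarts)
    for (k in seq_len(restarts)) {
      # screen a handful of data-seeded starts by one-step likelihood, then
      # run the best to convergence (cheap insurance against restarts that
      # never land near a site)
      cand_seeds <- derive_seeds(run_seeds[k], 5L)
      pwm0 <- NULL
      best_screen <- -Inf
      for (cs in cand_seeds) {
        cand <- init_pwm(enc_f, lay, bg, cs)
        probe <- em_zoops_cpp(enc_f, enc_r, lay$offsets, lay$partner, lay$comp,
                              cand, bg, gamma0, tol, 1L)
        if (probe$loglik > best_screen) {
          best_screen <- probe$loglik
          pwm0 <- cand
        }
      }
      fit <- em_zoops_cpp(enc_f, enc_r, lay$offsets, lay$partner, lay$comp,
                          pwm0, bg, gamma0, tol, max_iter)
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
    best$geometry <- g
    best$layout <- lay
    best$mean_ic <- mean_column_ic(best$pwm, bg)
    best
  })

  scores <- purrr::map_dbl(fits, "mean_ic")
  # grid is span-ordered; which.max takes the first (= smallest span) on ties
  sel <- which.max(scores)
  fit <- fits[[sel]]
  g <- fit$geometry
  lay <- fit$layout

  sites <- extract_em_sites(fit, regions, lay)
  motif <- build_pwm(sites$site_seq, geometry = g, background = bg,
                     training_sites = sites)
  geometry_scores <- grid |>
    mutate(mean_ic = scores, loglik = purrr::map_dbl(fits, "loglik"),
           n_iter = purrr::map_int(fits, "n_iter"),
           converged = purrr::map_lgl(fits, "converged"),
           selected = dplyr::row_number() == sel)

  structure(list(
    motif = motif, geometry = g, span = lay$span,
    sites = sites, gamma = fit$gamma, loglik = fit$loglik,
    loglik_trace = fit$loglik_trace, mean_ic = fit$mean_ic,
    geometry_scores = geometry_scores, background = bg,
    restarts = restarts, seed = seed,
    low_confidence = if (is.null(ic_threshold)) NA else fit$mean_ic < ic_threshold,
    ic_threshold = ic_threshold %||% NA_real_
  ), class = "motif_discovery")
}

#' @export
print.motif_discovery <- function(x, ...) {
  cat(sprintf("<motif_discovery> %s, span %d bp, %d site(s), %.2f bits/column\n",
              geometry_label(x$geometry), x$span, nrow(x$sites), x$mean_ic))
  cat("  consensus:", consensus_string(x$motif), "\n")
  if (isTRUE(x$low_confidence))
    cat(sprintf("  flagged low-confidence (below %.2f bits/column)\n",
                x$ic_threshold))
  invisible(x)
}

#' One EM iteration (E-step + symmetry-constrained M-step)
#'
#' Mainly for inspection and testing: advances a ZOOPS EM state by exactly
#' one iteration and reports the data log-likelihood at the *incoming*
#' parameters.  The incoming PWM is first projected onto the geometry's
#' symmetry manifold (the constrained EM's guarantees hold for in-family
#' states).
#'
#' @param state List with `pwm` (4 x m column-probability matrix), `gamma`.
#' @param regions Region tibble or character vector.
#' @param geometry List with `mode` and the relevant width/unit/period/spacer.
#' @param background Length-4 base frequencies (default: estimated).
#' @return Updated state (`pwm`, `gamma`, `loglik`, `posterior` tibble).
#' @export
em_step <- function(state, regions, geometry, background = NULL) {
  regions <- as_region_tbl(regions)
  bg <- background %||% estimate_background(regions$seq)
  bg <- as.numeric(bg) / sum(bg)
  lay <- geometry_layout(geometry)
  enc_f <- lapply(regions$seq, function(s) encode_dna(s) - 1L)
  enc_r <- lapply(reverse_complement(regions$seq), function(s) encode_dna(s) - 1L)
  fit <- em_zoops_cpp(enc_f, enc_r, lay$offsets, lay$partner, lay$comp,
                      state$pwm, bg, state$gamma, tol = 0, max_iter = 1L)
  list(pwm = fit$pwm, gamma = fit$gamma, loglik = fit$loglik,
       posterior = tibble(region = seq_along(enc_f), site_prob = fit$Q,
                          best_pos = fit$best_pos,
                          best_strand = ifelse(fit$best_strand == 1, "-", "+"),
                          best_z = fit$best_z))
}

#' Calibrate the no-motif information-content threshold
#'
#' Runs discovery on `n_sims` training sets of pure i.i.d. background and
#' returns the upper quantile of the best-motif mean information content.
#' Discovery results scoring below this value are indistinguishable from
#' background overfitting and should be flagged low-confidence.
#'
#' @param spec A [motif_spec()].
#' @param n_regions,region_len Shape of each null training set.
#' @param gc Background GC fraction.
#' @param n_sims Number of null simulations (default 200).
#' @param quantile Quantile reported (default 0.95).
#' @param restarts,seed Passed to [discover_motif()].
#' @return The calibrated threshold in bits per modeled column, with the
#'   simulated null scores in the `"null_scores"` attribute.
#' @export
calibrate_null_ic <- function(spec, n_regions = 20, region_len = 300,
                              gc = 0.35, n_sims = 200, quantile = 0.95,
                              restarts = 5, seed = 1) {
  seeds <- derive_seeds(seed, n_sims)
  scores <- purrr::map_dbl(seeds, function(s) {
    regs <- with_seed(s, replicate(n_regions, gen_background(region_len, gc)))
    discover_motif(regs, spec, restarts = restarts, seed = s)$mean_ic
  })
  structure(stats::quantile(scores, quantile, names = FALSE),
            null_scores = scores)
}

# ---- internals --------------------------------------------------------------

as_region_tbl <- function(regions) {
  if (is.character(regions)) {
    regions <- tibble(species_id = NA_character_,
                      locus_tag = sprintf("region%03d", seq_along(regions)),
                      seq = unname(regions),
                      offset_start = -nchar(regions), offset_end = 0L)
  }
  regions <- as_tibble(regions)
  if (!"seq" %in% names(regions)) abort("regions need a 'seq' column")
  validate_dna(regions$seq, "region sequence")
  if (!"offset_start" %in% names(regions)) {
    regions$offset_start <- -nchar(regions$seq)
    regions$offset_end <- 0L
  }
  regions
}

# seed a PWM from a random span-window of the data (70/10/10/10 smoothing),
# then symmetrize with the same pooling the M-step uses
init_pwm <- function(enc_f, lay, bg, seed) {
  m <- length(lay$offsets)
  with_seed(seed, {
    lens <- vapply(enc_f, length, 1L)
    ok <- which(lens >= lay$span)
    r <- ok[sample.int(length(ok), 1)]
    p <- sample.int(lens[r] - lay$span + 1L, 1)
    window <- enc_f[[r]][p + lay$offsets]  # 0-based bases at modeled columns
    pwm <- matrix(rep(bg, m), nrow = 4)
    for (j in seq_len(m)) {
      if (window[j] < 4) {
        pwm[, j] <- 0.1
        pwm[window[j] + 1L, j] <- 0.7
      }
    }
    # symmetry projection: pool with (complemented) partner and renormalize
    pooled <- pwm
    for (j in seq_len(m)) {
      pj <- lay$partner[j] + 1L
      other <- if (lay$comp[j]) rev(pwm[, pj]) else pwm[, pj]
      pooled[, j] <- pwm[, j] + other
    }
    sweep(pooled, 2, colSums(pooled), "/")
  })
}

# mean per-column information content (bits) relative to the background
mean_column_ic <- function(pwm, bg) {
  ic <- colSums(ifelse(pwm > 0, pwm * log2(pwm / bg), 0))
  mean(ic)
}

# per-region best sites from a converged EM fit (ZOOPS: site called when the
# posterior site probability exceeds 1/2)
extract_em_sites <- function(fit, regions, lay) {
  span <- lay$span
  rows <- purrr::map(seq_len(nrow(regions)), function(r) {
    if (fit$Q[r] < 0.5) return(NULL)
    L <- nchar(regions$seq[r])
    strand <- if (fit$best_strand[r] == 1) "-" else "+"
    p_scan <- fit$best_pos[r]  # 0-based on the scanned strand
    p_fwd <- if (strand == "+") p_scan else L - span - p_scan
    site_seq <- substr(regions$seq[r], p_fwd + 1, p_fwd + span)
    if (strand == "-") site_seq <- reverse_complement(site_seq)
    tibble(species_id = regions$species_id[r], locus_tag = regions$locus_tag[r],
           region = r, position = p_fwd,
           offset = regions$offset_start[r] + p_fwd,
           strand = strand, site_prob = fit$Q[r], site_seq = site_seq)
  })
  bind_rows(rows)
}
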