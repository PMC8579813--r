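test_that("planted palindromes are recovered at exact positions", {
  ts <- gen_training_set(20, 300, motif = list(mode = "palindrome", width = 20),
                         gc = 0.5, mutation_rate = 0, seed = 7)
  d <- discover_motif(ts$regions, motif_spec("palindrome"), restarts = 20,
                      seed = 3)
  expect_equal(d$geometry$width, 20L)
  expect_equal(consensus_string(d), ts$consensus)
  cmp <- dplyr::inner_join(d$sites, ts$truth, by = "locus_tag",
                           suffix = c("", ".true"))
  expect_equal(nrow(cmp), 20L)
  expect_true(all(cmp$position == cmp$position.true))
})

test_that("spaced inverted-repeat discovery recovers the printed spacer", {
  # half-sites GGGAC / GTCCC with a 27 bp nonconserved linker
  ts <- gen_training_set(20, 300,
                         motif = list(mode = "inverted_repeat_spaced",
                                      unit = "GGGAC", spacer = 27),
                         gc = 0.5, seed = 11)
  d <- discover_motif(ts$regions,
                      motif_spec("inverted_repeat_spaced",
                                 unit_range = c(5, 5), spacer_range = c(20, 30)),
                      restarts = 20, seed = 5)
  expect_equal(d$geometry$spacer, 27L)
  expect_equal(consensus_string(d), "GGGAC-(27)-GTCCC")
})

test_that("direct-repeat discovery selects the planted periodicity", {
  ts <- gen_training_set(20, 300,
                         motif = list(mode = "direct_repeat", unit = 8,
                                      period = 21),
                         gc = 0.5, seed = 13)
  d <- discover_motif(ts$regions, motif_spec("direct_repeat"), restarts = 20,
                      seed = 5)
  expect_equal(d$geometry$period, 21L)
})

test_that("EM log-likelihood is monotone and the symmetry projection is exact", {
  set.seed(4)
  regions <- replicate(8, gen_background(120, 0.4))
  g <- list(mode = "palindrome", width = 10)
  state <- list(pwm = matrix(0.25, 4, 10), gamma = 0.8)
  # perturb the start away from uniform
  state$pwm[, 1] <- c(0.4, 0.2, 0.2, 0.2)
  lls <- numeric(0)
  for (i in 1:15) {
    state <- em_step(state, regions, g)
    lls <- c(lls, state$loglik)
    # palindrome symmetry: p(b, i) = p(comp(b), w + 1 - i) exactly
    expect_identical(state$pwm, state$pwm[4:1, 10:1])
    expect_true(all(abs(colSums(state$pwm) - 1) < 1e-12))
  }
  expect_true(all(diff(lls) >= -1e-9 * (abs(lls[-1]) + 1)))
})

test_that("EM is near a fixed point at the planted parameters", {
  ts <- gen_training_set(15, 200, motif = list(mode = "palindrome", width = 12),
                         gc = 0.5, mutation_rate = 0.05, seed = 31)
  # build the true PWM from the planted site sequences
  sites <- substr(ts$regions$seq, ts$truth$position + 1, ts$truth$position + 12)
  sites <- ifelse(ts$truth$strand == "-", reverse_complement(sites), sites)
  pwm_true <- build_pwm(sites, geometry = list(mode = "palindrome", width = 12))
  q <- regufoot:::estimate_background(ts$regions$seq)
  probs <- sweep(pwm_true$counts + q, 2, colSums(pwm_true$counts) + 1, "/")
  s1 <- em_step(list(pwm = probs, gamma = 1 - 1e-6), ts$regions,
                list(mode = "palindrome", width = 12))
  s2 <- em_step(s1, ts$regions, list(mode = "palindrome", width = 12))
  rel <- abs(s2$loglik - s1$loglik) / (abs(s1$loglik) + 1)
  expect_lt(rel, 1e-3)
})

test_that("discovery is strand invariant and seed reproducible", {
  ts <- gen_training_set(12, 200, motif = list(mode = "palindrome", width = 14),
                         gc = 0.5, mutation_rate = 0.05, seed = 17)
  spec <- motif_spec("palindrome", width_range = c(14, 14))
  d1 <- discover_motif(ts$regions, spec, restarts = 10, seed = 9)
  d2 <- discover_motif(ts$regions, spec, restarts = 10, seed = 9)
  expect_identical(d1$motif$weights, d2$motif$weights)
  expect_identical(d1$sites, d2$sites)

  rc <- dplyr::mutate(ts$regions, seq = reverse_complement(seq))
  d3 <- discover_motif(rc, spec, restarts = 10, seed = 9)
  expect_equal(consensus_string(d3), consensus_string(d1))  # palindrome
  expect_lt(abs(d3$loglik - d1$loglik), 1e-6 * (abs(d1$loglik) + 1))
})

test_that("pure background is flagged low-confidence at a calibrated cut", {
  spec <- motif_spec("palindrome", width_range = c(12, 12))
  thr <- calibrate_null_ic(spec, n_regions = 12, region_len = 150, gc = 0.5,
                           n_sims = 30, restarts = 3, seed = 5)
  nulls <- vapply(1:10, function(k) {
    regs <- withr::with_seed(1000 + k,
                             replicate(12, gen_background(150, 0.5)))
    d <- discover_motif(regs, spec, restarts = 3, seed = k,
                        ic_threshold = thr)
    d$low_confidence
  }, logical(1))
  expect_gte(mean(nulls), 0.9)
  ts <- gen_training_set(12, 150, motif = list(mode = "palindrome", width = 12),
                         gc = 0.5, mutation_rate = 0.1, seed = 77)
  d <- discover_motif(ts$regions, spec, restarts = 5, seed = 2,
                      ic_threshold = thr)
  expect_false(d$low_confidence)
})

test_that("regions shorter than the motif span are excluded with a warning", {
  ts <- gen_training_set(10, 150, motif = list(mode = "palindrome", width = 12),
                         gc = 0.5, seed = 3)
  regs <- ts$regions
  regs$seq[1] <- substr(regs$seq[1], 1, 8)
  expect_warning(d <- discover_motif(regs, motif_spec("palindrome",
                                                      width_range = c(12, 12)),
                                     restarts = 5, seed = 1),
                 "shorter than")
  expect_false(regs$locus_tag[1] %in% d$sites$locus_tag)
  expect_error(suppressWarnings(
    discover_motif(substr(ts$regions$seq[1:3], 1, 8),
                   motif_spec("palindrome", width_range = c(12, 12)),
                   restarts = 2, seed = 1)))
})
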