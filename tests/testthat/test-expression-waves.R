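make_tables <- function(values, detected = NULL) {
  # values: named list sample -> named numeric gene vector
  lapply(values, function(v) {
    det <- if (is.null(detected)) v >= 10 else detected
    structure(data.frame(gene_id = names(v), raw_count = v, normalized = v,
                         detected = det),
              class = c("gene_count_table", "data.frame"))
  })
}

test_that("log ratios against a reference follow the display rules", {
  v <- c(gA = 100, gB = 400, gC = 5, gD = 50)
  tabs <- make_tables(list(t0 = v,
                           t1 = c(gA = 100, gB = 1600, gC = 50, gD = 4)))
  course <- log_ratio_to_reference(tabs, "t0", time_points = c(0, 1))
  m <- course$log2_ratio
  expect_equal(unname(m["gA", ]), c(0, 0))       # sample = reference
  expect_equal(unname(m["gB", "1"]), 2)           # 4x the reference
  expect_true(all(is.na(m["gC", ])))              # masked in the reference
  expect_true(is.na(m["gD", "1"]))                # masked in that sample
  expect_false(is.na(m["gD", "0"]))
  expect_error(log_ratio_to_reference(tabs, "missing", c(0, 1)),
               "not found")
})

test_that("time-point correlations match the direct Pearson formula", {
  set.seed(2)
  m <- matrix(rnorm(12), 4, 3, dimnames = list(paste0("g", 1:4), NULL))
  course <- expression_course(m, c(1, 2, 3))
  cc <- timepoint_correlation(course)
  for (i in 1:3) for (j in 1:3)
    expect_equal(cc[i, j], pearson_direct(m[, i], m[, j]),
                 tolerance = 1e-12)
  expect_true(isSymmetric(cc))
  expect_equal(unname(diag(cc)), rep(1, 3))
  # duplicated column: off-diagonal 1; negated column: -1
  m2 <- cbind(m, m[, 3], -m[, 3])
  cc2 <- timepoint_correlation(expression_course(m2, 1:5))
  expect_equal(cc2[3, 4], 1)
  expect_equal(cc2[3, 5], -1)
  # cells with < 3 complete pairs are masked
  m3 <- m
  m3[1:2, 1] <- NA
  cc3 <- timepoint_correlation(expression_course(m3, 1:3))
  expect_true(is.na(cc3[1, 2]))
})

test_that("wave detection equals the exhaustive optimal bipartition", {
  # block matrix: {t1..t4} vs {t5..t8}
  blk <- matrix(0.2, 8, 8)
  blk[1:4, 1:4] <- 0.95
  blk[5:8, 5:8] <- 0.95
  diag(blk) <- 1
  wp <- detect_waves(blk, time_points = 1:8, seed = 1)
  expect_identical(wp$labels, rep(c(1L, 2L), each = 4))
  expect_identical(wp$wave2_first_onset, 5)
  oracle <- exhaustive_bipartition(blk)
  expect_identical(wp$labels, oracle$labels)

  # random correlation matrices: k-means with restarts attains the optimum
  set.seed(10)
  for (i in 1:60) {
    t_n <- sample(4:9, 1)
    x <- matrix(rnorm(12 * t_n), 12, t_n)
    cc <- cor(x)
    wp <- detect_waves(cc, time_points = seq_len(t_n), seed = i)
    if (!wp$has_second_wave) next
    oracle <- exhaustive_bipartition(cc)
    expect_equal(partition_objective(cc, wp$labels), oracle$objective,
                 tolerance = 1e-9)
  }
})

test_that("degenerate correlation matrices yield a no-second-wave outcome", {
  ones <- matrix(1, 6, 6)
  wp <- detect_waves(ones, time_points = 1:6, seed = 1)
  expect_false(wp$has_second_wave)
  expect_warning(d <- wave_delay(wp), "undefined")
  expect_true(is.na(d))
})

test_that("transient re-induction: first versus stable onset", {
  # wave-2-like correlation profile at 3.5-4.5 h, back to wave-1 at 5.5 h,
  # then stable wave-2 from 7 h (the 0.06 mM pattern)
  tp <- c(1, 2, 3.5, 4.5, 5.5, 7, 8.5, 10)
  lab <- c(1, 1, 2, 2, 1, 2, 2, 2)
  cc <- outer(lab, lab, function(a, b) ifelse(a == b, 0.92, 0.15))
  diag(cc) <- 1
  wp <- detect_waves(cc, time_points = tp, seed = 1)
  expect_true(wp$has_second_wave)
  expect_identical(wp$wave2_first_onset, 3.5)
  expect_identical(wp$wave2_stable_onset, 7)
  expect_identical(wave_delay(wp), 3.5)
})

test_that("synthetic default courses reproduce the printed wave delays", {
  panel <- pho_gene_panel()
  targets <- c(panel$wave1, panel$wave2)
  onset <- function(pi0, seed) {
    sim <- simulate_culture(pi0, seed = seed)
    cc <- timepoint_correlation(sim$expression, gene_subset = targets)
    detect_waves(cc, sim$expression$time_points, seed = seed)$wave2_first_onset
  }
  expect_equal(onset(0, 1), 2)      # ~2 h delay in medium lacking Pi
  expect_equal(onset(0.2, 1), 9.5)  # ~9.5 h delay at 0.2 mM Pi
  # parameter recovery: the detected onset equals the generating onset
  # (first grid point after the wave-2 trigger) in >= 18 of 20 seeded runs
  hits <- 0L
  for (sd in 1:10) {
    for (pi0 in c(0, 0.2)) {
      sim <- simulate_culture(pi0, seed = sd)
      grid <- sim$expression$time_points
      gen_onset <- grid[grid > sim$truth$t_wave2][1]
      cc <- timepoint_correlation(sim$expression, gene_subset = targets)
      det <- detect_waves(cc, grid, seed = sd)$wave2_first_onset
      hits <- hits + as.integer(isTRUE(all.equal(det, gen_onset)))
    }
  }
  expect_gte(hits, 18L)
})

test_that("gene ordering by early induction matches a direct sort", {
  m <- rbind(fast = c(3, 3, 1), slow = c(1, 1, 5),
             masked = c(NA, NA, 2))
  course <- expression_course(m, c(0.5, 1.5, 6))
  expect_identical(order_genes_by_early_induction(course, window_h = 2),
                   c("fast", "slow", "masked"))
  set.seed(4)
  m2 <- matrix(rnorm(20 * 4), 20, 4,
               dimnames = list(sprintf("g%02d", 1:20), NULL))
  course2 <- expression_course(m2, c(0.5, 1, 1.5, 8))
  means <- rowMeans(m2[, 1:3])
  expect_identical(order_genes_by_early_induction(course2, 2),
                   names(sort(means, decreasing = TRUE)))
})

test_that("activation threshold is consistent across declining conditions", {
  mk_cond <- function(onset_h, reporter_rate) {
    tt <- seq(0, 12, 0.5)
    # reporter rises linearly; it crosses 1000 au exactly at onset_h
    rep_df <- data.frame(time_h = tt,
                         reporter_au = 1000 / onset_h * tt)
    rate_df <- data.frame(time_h = tt,
                          normalized_rate = ifelse(tt >= onset_h, -0.3, 0))
    list(reporter = rep_df, rates = rate_df)
  }
  conds <- list(fast = mk_cond(3), mid = mk_cond(6), slow = mk_cond(9))
  out <- activation_threshold(lapply(conds, `[[`, "reporter"),
                              lapply(conds, `[[`, "rates"))
  expect_true(out$has_threshold)
  expect_equal(out$mean, 1000, tolerance = 0.05)
  expect_lt(out$cv, 0.10)
  # a never-declining (rich) condition is excluded from the estimate
  rich <- list(reporter = data.frame(time_h = seq(0, 12, 0.5),
                                     reporter_au = 100),
               rates = data.frame(time_h = seq(0, 12, 0.5),
                                  normalized_rate = 0))
  out2 <- activation_threshold(
    c(lapply(conds, `[[`, "reporter"), list(rich = rich$reporter)),
    c(lapply(conds, `[[`, "rates"), list(rich = rich$rates)))
  expect_identical(nrow(out2$per_condition), 3L)
  # a single declining condition returns a threshold with undefined CV
  out3 <- activation_threshold(list(fast = conds$fast$reporter),
                               list(fast = conds$fast$rates))
  expect_true(out3$has_threshold)
  expect_true(is.na(out3$cv))
  # no declining condition at all: undefined-threshold outcome
  out4 <- activation_threshold(list(rich = rich$reporter),
                               list(rich = rich$rates))
  expect_false(out4$has_threshold)
})
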