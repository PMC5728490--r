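# Seeded synthetic phosphate-starvation cultures.
#
# The mean model is a deliberately simple stand-in: Monod-style uptake from
# external Pi plus a single internal store that sustains a fixed number of
# doublings once external Pi is exhausted. Cells grow exponentially at
# max_rate until the combined budget (external Pi * yield, then the store) or
# a Pi-independent carrying capacity is exhausted, then arrest. Two facets of
# the internal pool drive the transcription response:
#   * the uptake-replete fraction u = m*P/(K + m*P) -- the first wave fires
#     when external Pi can no longer keep the pool replete (u < wave1
#     threshold);
#   * the store fraction sigma -- intact while external Pi remains, halving
#     with every store-funded doubling afterwards; the second wave fires at
#     deeper depletion (sigma < wave2 threshold < wave1 threshold).
# Defaults are calibrated so that, on the standard sampling grid, cultures
# reproduce ~3.5 generations at 0 mM Pi, ~8 at 0.5 mM, a second-wave onset of
# ~2 h at 0 mM and ~9.5 h at 0.2 mM.

#' Simulation parameters for synthetic cultures
#'
#' @param pi_levels_mM external Pi concentrations (mM) the generator is
#'   calibrated for.
#' @param od_initial inoculation OD600.
#' @param max_rate maximal growth rate, doublings/hour.
#' @param internal_store_generations doublings sustainable on the internal
#'   store alone (0 mM Pi yields exactly this many generations).
#' @param yield_od_per_mM biomass yield, OD600 per mM external Pi (default
#'   calibrated so 0.5 mM yields ~8 generations).
#' @param stationary_od_cap Pi-independent carrying capacity (OD600); keeps
#'   rich cultures Pi-replete at stationary phase.
#' @param uptake_K_mM Monod half-saturation of the uptake-replete signal (mM).
#' @param wave1_threshold uptake-replete fraction below which the first
#'   (moderate) induction wave fires.
#' @param wave2_threshold internal-store fraction below which the second
#'   (strong) wave fires; must be `< wave1_threshold`.
#' @param reporter_delay_h reporter maturation lag (first-order time
#'   constant, hours; default 20 min).
#' @param induction_timescale_h mRNA induction time constant (hours).
#' @param noise_sd_od multiplicative OD measurement noise (sd of log OD).
#' @param noise_sd_expr expression measurement noise (sd, log2 units).
#' @param seed default integer seed for stochastic draws.
#' @return A validated list of class `sim_params`.
#' @examples
#' p <- sim_params()
#' p$wave2_threshold < p$wave1_threshold
#' @export
sim_params <- function(pi_levels_mM = c(0, 0.06, 0.2, 0.5, 7.3, 20),
                       od_initial = 0.05,
                       max_rate = 0.45,
                       internal_store_generations = 3.5,
                       yield_od_per_mM = 2.16274,
                       stationary_od_cap = 12.8,
                       uptake_K_mM = 0.1,
                       wave1_threshold = 0.75,
                       wave2_threshold = 0.6,
                       reporter_delay_h = 1 / 3,
                       induction_timescale_h = 0.2,
                       noise_sd_od = 0.01,
                       noise_sd_expr = 0.25,
                       seed = 1L) {
  if (!is.numeric(pi_levels_mM) || any(!is.finite(pi_levels_mM)) ||
      any(pi_levels_mM < 0))
    stop_param("pi_levels_mM must be non-negative and finite")
  for (nm in c("od_initial", "max_rate", "internal_store_generations",
               "yield_od_per_mM", "stationary_od_cap", "uptake_K_mM",
               "reporter_delay_h", "induction_timescale_h"))
    check_scalar(get(nm), nm, lower = 1e-12)
  check_scalar(wave1_threshold, "wave1_threshold", 0, 1)
  check_scalar(wave2_threshold, "wave2_threshold", 0, 1)
  check_scalar(noise_sd_od, "noise_sd_od", 0)
  check_scalar(noise_sd_expr, "noise_sd_expr", 0)
  check_scalar(seed, "seed")
  if (wave2_threshold >= wave1_threshold)
    stop_param("wave2_threshold must be < wave1_threshold ",
               "(the second wave fires at deeper depletion)")
  structure(list(
    pi_levels_mM = pi_levels_mM, od_initial = od_initial,
    max_rate = max_rate,
    internal_store_generations = internal_store_generations,
    yield_od_per_mM = yield_od_per_mM,
    stationary_od_cap = stationary_od_cap,
    uptake_K_mM = uptake_K_mM,
    wave1_threshold = wave1_threshold, wave2_threshold = wave2_threshold,
    reporter_delay_h = reporter_delay_h,
    induction_timescale_h = induction_timescale_h,
    noise_sd_od = noise_sd_od, noise_sd_expr = noise_sd_expr,
    seed = as.integer(seed)), class = "sim_params")
}

#' Genotype specification for synthetic cultures
#'
#' @param induction_enabled if `FALSE`, Pho4-target induction is absent
#'   (models pho4/pho81 deletions); the store is only partially mobilized,
#'   giving earlier arrest under limitation.
#' @param constitutive_transporter if `TRUE`, models constitutive
#'   high-affinity transporter expression; the default uptake multiplier
#'   rises to 5, delaying the first wave.
#' @param uptake_multiplier multiplier on external Pi in the uptake signal
#'   (> 0); overrides the constitutive default if given.
#' @param store_access fraction of the internal store accessible without an
#'   intact starvation program.
#' @return A list of class `genotype_spec`.
#' @examples
#' genotype_spec()                          # wild type
#' genotype_spec(induction_enabled = FALSE) # pho4-null-like
#' @export
genotype_spec <- function(induction_enabled = TRUE,
                          constitutive_transporter = FALSE,
                          uptake_multiplier = NULL,
                          store_access = 0.6) {
  stopifnot(is.logical(induction_enabled), length(induction_enabled) == 1L,
            is.logical(constitutive_transporter),
            length(constitutive_transporter) == 1L)
  m <- uptake_multiplier %||% (if (constitutive_transporter) 5 else 1)
  check_scalar(m, "uptake_multiplier", lower = 1e-12)
  check_scalar(store_access, "store_access", 0, 1)
  structure(list(induction_enabled = induction_enabled,
                 constitutive_transporter = constitutive_transporter,
                 uptake_multiplier = m, store_access = store_access),
            class = "genotype_spec")
}

#' Noiseless mean model of one phosphate-limited culture
#'
#' Closed-form landmark times and evaluator functions for the deterministic
#' mean model underlying [simulate_culture()]: exponential growth on
#' external Pi, then on the internal store, arresting when the combined
#' budget (or the carrying capacity) is exhausted.
#'
#' @inheritParams simulate_culture
#' @return A list with landmark scalars (`t_dep`, `t_arrest`, `t_wave1`,
#'   `t_wave2`, `od_max`, `generations`) and vectorized functions of time
#'   (`od_mean`, `pi_external`, `uptake_fraction`, `store_fraction`).
#' @examples
#' culture_mean_model(0)$generations    # ~3.5 on the internal store alone
#' @export
culture_mean_model <- function(pi0, genotype = genotype_spec(),
                               params = sim_params()) {
  check_scalar(pi0, "pi0", lower = 0)
  stopifnot(inherits(params, "sim_params"), inherits(genotype, "genotype_spec"))
  r <- params$max_rate
  od0 <- params$od_initial
  y <- params$yield_od_per_mM
  gs <- params$internal_store_generations *
    (if (genotype$induction_enabled) 1 else genotype$store_access)
  m <- genotype$uptake_multiplier
  k <- params$uptake_K_mM
  w1 <- params$wave1_threshold
  w2 <- params$wave2_threshold

  od_dep <- od0 + y * pi0                    # OD at external-Pi exhaustion
  od_max <- min(od_dep * 2^gs, params$stationary_od_cap)
  t_arrest <- log2(od_max / od0) / r
  t_dep <- if (od_dep < od_max) log2(od_dep / od0) / r else Inf

  od_mean <- function(t) pmin(od0 * 2^(r * t), od_max)
  pi_external <- function(t) pmax(0, pi0 - pmin(od_mean(t) - od0, y * pi0) / y)
  uptake_fraction <- function(t) {
    p <- m * pi_external(t)
    ifelse(p <= 0, 0, p / (k + p))
  }
  store_fraction <- function(t) {
    tt <- pmin(t, t_arrest)
    ifelse(tt <= t_dep, 1, 2^(-r * (tt - t_dep)))
  }

  # first-wave onset: earliest crossing of w1 by either facet of the pool
  u0 <- if (pi0 > 0) m * pi0 / (k + m * pi0) else 0
  t_w1_u <- if (u0 < w1) 0 else {
    p_w1 <- w1 * k / (m * (1 - w1))          # P at which u = w1
    od_cross <- od0 + y * (pi0 - p_w1)
    if (od_cross < od_max) log2(od_cross / od0) / r else Inf
  }
  t_w1_s <- if (is.finite(t_dep)) t_dep + log2(1 / w1) / r else Inf
  t_wave1 <- min(t_w1_u, t_w1_s)
  if (t_wave1 > t_arrest) t_wave1 <- Inf
  t_wave2 <- if (is.finite(t_dep)) t_dep + log2(1 / w2) / r else Inf
  if (t_wave2 > t_arrest) t_wave2 <- Inf

  list(pi0 = pi0, genotype = genotype, params = params,
       od_max = od_max, t_dep = t_dep, t_arrest = t_arrest,
       t_wave1 = t_wave1, t_wave2 = t_wave2,
       generations = log2(od_max / od0),
       od_mean = od_mean, pi_external = pi_external,
       uptake_fraction = uptake_fraction, store_fraction = store_fraction)
}

#' Default gene panel of the synthetic expression courses
#'
#' Wave-1 Pho4 targets induce moderately at the first threshold and
#' strongly at the second; a disjoint wave-2 target set induces only at the
#' second, concomitant with stress-gene induction and ribosomal-protein
#' repression; background genes stay flat.
#'
#' @return A named list of gene-id vectors: `wave1`, `wave2`, `stress`,
#'   `ribosomal`, `background`.
#' @export
pho_gene_panel <- function() {
  list(
    wave1 = c("PHO84", "SPL2", "PHO5", "PHM3", "PHO89", "PHM1", "PHM2",
              "PHM4", "VTC3", "GIT1"),
    wave2 = c("PHO8", "PHO11", "PHO12", "DDP1", "PPN1", "HOR2"),
    stress = c("HSP12", "CTT1", "HSP26", "TPS1", "GRE1", "DDR2", "SIP18",
               "HSP104"),
    ribosomal = c("RPL28", "RPS3", "RPL3", "RPS6A", "RPL4A", "RPS8B",
                  "RPL15A", "RPS11A"),
    background = c("ACT1", "TEF1", "TDH3", "PGK1", "ENO2", "CDC19", "ADH1",
                   "PDA1", "UBC6", "TFC1", "ALG9", "TAF10", "KRE11", "SEC13",
                   "RPN2", "VMA6", "SNF2", "SWI3"))
}

# Saturating induction ramp: 0 before onset, amp * (1 - exp(-(t-onset)/tau)).
ramp <- function(t, onset, amp, tau) {
  if (!is.finite(onset)) return(rep(0, length(t)))
  ifelse(t > onset, amp * (1 - exp(-(t - onset) / tau)), 0)
}

# Fixed per-gene log2 induction amplitudes. Heterogeneity matters: the
# moderate (wave-1) and strong (wave-2) patterns must not be proportional
# across genes, otherwise the time-point correlation cannot tell the waves
# apart. Values are arbitrary but frozen.
gene_amplitudes <- function() {
  list(
    wave1_moderate = c(2.0, 3.2, 1.6, 2.8, 3.5, 1.8, 2.4, 3.0, 1.5, 2.6),
    wave1_extra    = c(3.5, 1.0, 4.0, 1.5, 0.8, 3.8, 2.0, 1.2, 4.2, 2.2),
    wave2          = c(4.5, 2.5, 5.0, 3.0, 5.5, 2.0),
    stress         = c(2.5, 3.5, 2.0, 4.0, 3.0, 2.2, 3.8, 2.8),
    ribosomal      = -c(1.5, 2.5, 2.0, 1.8, 2.8, 2.2, 1.6, 2.4))
}

# Mean log2 expression ratios (vs the pre-transfer reference) for the panel.
expression_mean_matrix <- function(times, model) {
  panel <- pho_gene_panel()
  amps <- gene_amplitudes()
  tau <- model$params$induction_timescale_h
  ind <- model$genotype$induction_enabled
  t1 <- model$t_wave1
  t2 <- model$t_wave2
  stress_scale <- if (ind) 1 else 0.6  # stress response weaker without Pho4
  zero <- rep(0, length(times))
  rows <- list()
  for (i in seq_along(panel$wave1))
    rows[[panel$wave1[i]]] <- if (ind)
      ramp(times, t1, amps$wave1_moderate[i], tau) +
        ramp(times, t2, amps$wave1_extra[i], tau) else zero
  for (i in seq_along(panel$wave2))
    rows[[panel$wave2[i]]] <- if (ind) ramp(times, t2, amps$wave2[i], tau)
                              else zero
  for (i in seq_along(panel$stress))
    rows[[panel$stress[i]]] <- ramp(times, t2, stress_scale * amps$stress[i],
                                    tau)
  for (i in seq_along(panel$ribosomal))
    rows[[panel$ribosomal[i]]] <- ramp(times, t2, amps$ribosomal[i], tau)
  for (g in panel$background) rows[[g]] <- zero
  mat <- do.call(rbind, rows)
  dimnames(mat) <- list(names(rows), format(times, trim = TRUE))
  mat
}

# First-order lagged reporter: dR/dt = (A(t) - R)/tau_rep with promoter
# activity A stepping at the wave onsets. Piecewise-exponential solution.
reporter_mean <- function(times, model) {
  if (!model$genotype$induction_enabled) return(rep(100, length(times)))
  tau <- model$params$reporter_delay_h
  base <- 100; a1 <- 1200; a2 <- 4000
  bks <- c(0, model$t_wave1, model$t_wave2, Inf)
  lvl <- c(base, a1, a2)
  vapply(times, function(t) {
    r <- base
    for (s in 1:3) {
      t_lo <- bks[s]; t_hi <- min(t, bks[s + 1])
      if (!is.finite(t_lo) || t_hi <= t_lo) next
      r <- lvl[s] + (r - lvl[s]) * exp(-(t_hi - t_lo) / tau)
    }
    r
  }, 0)
}

#' Simulate one phosphate-limited culture
#'
#' Generates, for one external Pi level and genotype, a noisy OD600 time
#' series, a gene-by-time log2 expression course relative to the pre-transfer
#' rich-medium reference, and a starvation-reporter course, together with the
#' noiseless ground truth (wave onsets, depletion and arrest times, total
#' generations).
#'
#' @param pi0 external Pi concentration (mM, >= 0).
#' @param genotype a [genotype_spec()].
#' @param params a [sim_params()].
#' @param seed integer seed (defaults to `params$seed`).
#' @param expr_times expression sampling times (hours after transfer);
#'   default is the standard RNA-seq grid 1, 2, 3.5, 5, 6.5, 8, 9.5, 24.7 h.
#' @param od_times OD/flow sampling times; default every 30 min for 12 h
#'   plus a final stationary point at 26 h.
#' @return A list of class `culture_sim` with elements `od` ([od_series()]),
#'   `expression` ([expression_course()]), `reporter` (data.frame with
#'   `time_h`, `reporter_au`) and `truth` (landmark times and generations).
#' @examples
#' sim <- simulate_culture(0.2, seed = 1)
#' sim$truth$t_wave2   # second-wave trigger time (h)
#' @export
simulate_culture <- function(pi0, genotype = genotype_spec(),
                             params = sim_params(), seed = params$seed,
                             expr_times = c(1, 2, 3.5, 5, 6.5, 8, 9.5, 24.7),
                             od_times = c(seq(0, 12, by = 0.5), 26)) {
  model <- culture_mean_model(pi0, genotype, params)
  if (!is.numeric(expr_times) || any(expr_times < 0) ||
      any(diff(expr_times) <= 0))
    stop_param("expr_times must be non-negative and strictly increasing")
  mean_expr <- expression_mean_matrix(expr_times, model)
  with_seed(seed, {
    od_noisy <- model$od_mean(od_times) *
      exp(stats::rnorm(length(od_times), 0, params$noise_sd_od))
    expr <- mean_expr + stats::rnorm(length(mean_expr), 0,
                                     params$noise_sd_expr)
    reporter <- reporter_mean(od_times, model) *
      exp(stats::rnorm(length(od_times), 0, params$noise_sd_od))
    cond <- paste0(format(pi0, trim = TRUE), " mM Pi")
    list(
      od = od_series(od_times, od_noisy, condition = cond),
      expression = expression_course(expr, expr_times,
                                     reference = "t0 (7.3 mM Pi)"),
      reporter = data.frame(time_h = od_times, reporter_au = reporter),
      truth = list(pi0 = pi0, t_dep = model$t_dep, t_arrest = model$t_arrest,
                   t_wave1 = model$t_wave1, t_wave2 = model$t_wave2,
                   od_max = model$od_max, generations = model$generations,
                   gene_sets = pho_gene_panel()))
  }) -> out
  structure(out, class = "culture_sim")
}

#' @export
print.culture_sim <- function(x, ...) {
  tr <- x$truth
  cat(sprintf("<culture_sim> %g mM Pi: %.2f generations, arrest %.2f h\n",
              tr$pi0, tr$generations, tr$t_arrest))
  cat(sprintf("  wave 1 at %.2f h, wave 2 at %.2f h\n",
              tr$t_wave1, tr$t_wave2))
  invisible(x)
}

#' Simulate normalized expression tables for regulon classification
#'
#' Builds the matched table set the two-criterion PHO-regulon classifier
#' expects: constitutively-ON cells (strong constitutive Pho4) and OFF cells
#' (pho4 null) across 25 samples (3 low-Pi levels x 8 time points plus one
#' pre-transfer high-Pi sample), a wild-type no-Pi course over the standard
#' 8-point grid, and the high-Pi reference vector. Values are normalized
#' expression units (library sum 1e6 scale); entries below the detection
#' level are `NA`. The true regulon is the generator's wave-1 plus wave-2
#' gene sets; one wave-2 gene is fully Pho4-dependent and silenced below
#' detection in OFF cells, so the classifier's rescue clause is exercised.
#'
#' @param params a [sim_params()].
#' @param seed integer seed.
#' @param detection_level normalized detection floor (default 10).
#' @return A list with matrices `on`, `off` (genes x 25), `wt_no_pi`
#'   (genes x 8), vector `high_pi_ref`, and `truth_genes`.
#' @export
simulate_regulon_dataset <- function(params = sim_params(),
                                     seed = params$seed,
                                     detection_level = 10) {
  panel <- pho_gene_panel()
  genes <- unlist(panel, use.names = FALSE)
  targets <- c(panel$wave1, panel$wave2)
  rescue_gene <- panel$wave2[1]  # below detection in OFF cells
  expr_times <- c(1, 2, 3.5, 5, 6.5, 8, 9.5, 24.7)
  n_genes <- length(genes)

  with_seed(seed, {
    # per-gene basal normalized expression, log-uniform over ~30-3000 units
    basal <- stats::setNames(10^stats::runif(n_genes, 1.5, 3.5), genes)
    basal[rescue_gene] <- 40
    noise <- function(n) exp(stats::rnorm(n, 0, 0.2))
    sample_names <- c(t(outer(c("0.06", "0.2", "0.5"), expr_times,
                              function(p, t) paste0(p, "mM_", t, "h"))),
                      "highPi_t0")
    n_s <- length(sample_names)

    mk <- function(fold_fun) {
      m <- matrix(NA_real_, n_genes, n_s, dimnames = list(genes, sample_names))
      for (j in seq_len(n_s))
        m[, j] <- basal * fold_fun(genes, sample_names[j]) * noise(n_genes)
      m
    }
    on_fold <- function(g, s) ifelse(g %in% targets, 12, 1)
    # the rescue gene is fully Pho4-dependent: silent in pho4-null cells
    off_fold <- function(g, s) ifelse(g == rescue_gene, 0.05, 1)
    on <- mk(on_fold)
    off <- mk(off_fold)

    # wild-type course at 0 mM: targets follow the two-wave mean kinetics
    model <- culture_mean_model(0, genotype_spec(), params)
    fold_mat <- 2^expression_mean_matrix(expr_times, model)
    wt <- matrix(NA_real_, n_genes, length(expr_times),
                 dimnames = list(genes, paste0("noPi_", expr_times, "h")))
    for (j in seq_along(expr_times))
      wt[, j] <- basal * fold_mat[genes, j] * noise(n_genes)
    high_pi_ref <- basal * noise(n_genes)
    names(high_pi_ref) <- genes
  })

  mask <- function(m) { m[m < detection_level] <- NA_real_; m }
  list(on = mask(on), off = mask(off), wt_no_pi = mask(wt),
       high_pi_ref = { v <- high_pi_ref; v[v < detection_level] <- NA; v },
       truth_genes = sort(targets))
}
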