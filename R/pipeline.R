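# End-to-end pipeline orchestration: simulate -> growth -> count -> waves ->
# classify -> fitness, from one configuration, with per-stage derived seeds
# and a reproducibility manifest.

default_config <- function() {
  list(
    seed = 1L,
    simulate = list(pi_levels_mM = c(0, 0.2), reference_pi_mM = 7.3),
    growth = list(smoothing = 0.4),
    count = list(n_genes = 30, depth = 50000, shared_frac = 0.05),
    waves = list(restarts = 50),
    classify = list(),
    fitness = list(duration_depletion_h = 24, duration_recovery_h = 24,
                   pi_mM = 0.2, n_events = 20000, bootstrap = 200))
}

validate_config <- function(config) {
  known <- names(default_config())
  bad <- setdiff(names(config), known)
  if (length(bad))
    stop("configuration error: unknown key(s): ", paste(bad, collapse = ", "))
  base <- default_config()
  for (k in known) {
    if (is.null(config[[k]])) next
    if (k == "seed") { base$seed <- config$seed; next }
    if (!is.list(config[[k]]))
      stop("configuration error: key '", k, "' must be a block (list)")
    bad2 <- setdiff(names(config[[k]]), names(base[[k]]))
    if (length(bad2))
      stop("configuration error: unknown key(s) in '", k, "': ",
           paste(bad2, collapse = ", "))
    base[[k]][names(config[[k]])] <- config[[k]]
  }
  check_scalar(base$seed, "seed")
  base
}

#' Read a pipeline run configuration
#'
#' Configurations are JSON objects mirroring the blocks of the default
#' configuration (`seed`, `simulate`, `growth`, `count`, `waves`,
#' `classify`, `fitness`); unknown keys are rejected by name.
#'
#' @param path path to a JSON configuration file.
#' @return A validated configuration list.
#' @export
read_run_config <- function(path) {
  validate_config(jsonlite::fromJSON(path, simplifyVector = TRUE))
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes every stage from one configuration: simulates cultures at the
#' configured Pi levels plus a rich-medium reference, fits growth profiles
#' and density-normalizes them, simulates and counts UMI alignments,
#' detects the transcription waves per condition, classifies the regulon on
#' a simulated ON/OFF design, and estimates competition fitness. All stage
#' outputs are written as plain tables under `out_dir` together with a
#' manifest (file, stage, seed, md5). Identical configuration and seed
#' reproduce byte-identical tables.
#'
#' @param config configuration list (see [read_run_config()]); missing
#'   blocks take defaults.
#' @param out_dir output directory (created if needed).
#' @return The manifest data.frame, invisibly; also written as
#'   `manifest.tsv`.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("phowaves_run")) {
  cfg <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  params <- sim_params(seed = cfg$seed)
  manifest <- list()
  note <- function(file, stage, seed) {
    manifest[[length(manifest) + 1L]] <<- data.frame(
      file = basename(file), stage = stage, seed = seed,
      md5 = unname(tools::md5sum(file)))
  }

  # --- simulate: cultures per condition plus the rich reference ----------
  seed_sim <- derive_seed(cfg$seed, "simulate")
  levels <- unique(c(cfg$simulate$pi_levels_mM, cfg$simulate$reference_pi_mM))
  sims <- lapply(levels, function(p)
    simulate_culture(p, params = params,
                     seed = derive_seed(seed_sim, paste0("pi", p))))
  names(sims) <- paste0("pi_", levels)
  od_all <- do.call(rbind, lapply(sims, `[[`, "od"))
  f <- file.path(out_dir, "od_series.tsv")
  write_od_series(od_all, f); note(f, "simulate", seed_sim)
  for (nm in names(sims)) {
    f <- file.path(out_dir, paste0("expression_", nm, ".tsv"))
    write_expression_course(sims[[nm]]$expression, f)
    note(f, "simulate", seed_sim)
  }

  # --- growth: profiles and density-matched normalization ----------------
  ref_name <- paste0("pi_", cfg$simulate$reference_pi_mM)
  ref_prof <- fit_log_od(sims[[ref_name]]$od, cfg$growth$smoothing)
  rate_rows <- lapply(names(sims), function(nm) {
    prof <- fit_log_od(sims[[nm]]$od, cfg$growth$smoothing)
    prof <- suppressWarnings(normalize_by_reference_density(prof, ref_prof))
    data.frame(condition = sims[[nm]]$od$condition[1], time_h = prof$times,
               rate = prof$rates, normalized_rate = prof$normalized_rates)
  })
  f <- file.path(out_dir, "growth_rates.tsv")
  write_tsv_plain(do.call(rbind, rate_rows), f)
  note(f, "growth", cfg$seed)

  # --- count: synthetic alignments through the UMI pipeline --------------
  seed_cnt <- derive_seed(cfg$seed, "count")
  ann <- toy_annotation(cfg$count$n_genes)
  truth <- data.frame(gene_id = ann$gene_id,
                      count = with_seed(seed_cnt,
                                        stats::rgamma(cfg$count$n_genes,
                                                      shape = 0.8, rate = 1e-3)))
  recs <- simulate_alignments(truth, ann, depth = cfg$count$depth,
                              shared_frac = cfg$count$shared_frac,
                              seed = derive_seed(seed_cnt, "reads"))
  counts <- count_pipeline(recs, ann, depth = cfg$count$depth,
                           seed = derive_seed(seed_cnt, "downsample"))
  f <- file.path(out_dir, "gene_counts.tsv")
  write_tsv_plain(counts, f); note(f, "count", seed_cnt)

  # --- waves: correlation clustering per low-Pi condition ----------------
  seed_wav <- derive_seed(cfg$seed, "waves")
  panel <- pho_gene_panel()
  wave_rows <- lapply(names(sims), function(nm) {
    sim <- sims[[nm]]
    if (sim$truth$pi0 >= cfg$simulate$reference_pi_mM) return(NULL)
    corr <- timepoint_correlation(sim$expression,
                                  gene_subset = c(panel$wave1, panel$wave2))
    wp <- detect_waves(corr, sim$expression$time_points,
                       restarts = cfg$waves$restarts, seed = seed_wav)
    data.frame(condition = sim$od$condition[1],
               has_second_wave = wp$has_second_wave,
               wave2_first_onset_h = wp$wave2_first_onset,
               wave2_stable_onset_h = wp$wave2_stable_onset,
               delay_h = wp$delay)
  })
  f <- file.path(out_dir, "wave_partition.tsv")
  write_tsv_plain(do.call(rbind, wave_rows), f)
  note(f, "waves", seed_wav)

  # --- classify: two-criterion rule on a simulated ON/OFF design ---------
  seed_cls <- derive_seed(cfg$seed, "classify")
  ds <- simulate_regulon_dataset(params, seed = seed_cls)
  cls <- classify_pho_regulon(ds$on, ds$off, ds$wt_no_pi, ds$high_pi_ref)
  f <- file.path(out_dir, "regulon.tsv")
  write_tsv_plain(data.frame(gene_id = cls$regulon), f)
  note(f, "classify", seed_cls)
  f <- file.path(out_dir, "regulon_venn.tsv")
  write_tsv_plain(data.frame(set = names(cls$venn), count = cls$venn), f)
  note(f, "classify", seed_cls)

  # --- fitness: simulated competition, filtered, gated, fitted -----------
  seed_fit <- derive_seed(cfg$seed, "fitness")
  comp <- simulate_competition(
    list(genotype_spec(), genotype_spec(induction_enabled = FALSE)),
    data.frame(phase = c("depletion", "recovery"),
               pi_mM = c(cfg$fitness$pi_mM, 20),
               duration_h = c(cfg$fitness$duration_depletion_h,
                              cfg$fitness$duration_recovery_h)),
    params = params, seed = seed_fit, n_events = cfg$fitness$n_events)
  traj <- comp$trajectory
  if (!is.null(comp$streams)) {
    # gate automatically on the 1:1 starting sample, then reuse that fixed
    # threshold for the whole course (late samples can be too unbalanced
    # for density-based mode finding)
    first <- filter_acquisition_artifacts(comp$streams[[1]])$stream
    cut <- gate_marker_populations(first)$threshold
    traj$mutant_fraction <- vapply(comp$streams, function(s) {
      kept <- filter_acquisition_artifacts(s)$stream
      gate_marker_populations(kept, threshold = cut)$fraction
    }, 0)
  }
  traj <- relative_abundance(traj)
  fits <- lapply(unique(traj$phase), function(ph)
    relative_fitness(traj, phase = ph, bootstrap = cfg$fitness$bootstrap,
                     seed = derive_seed(seed_fit, ph)))
  f <- file.path(out_dir, "competition_trajectory.tsv")
  write_tsv_plain(traj, f); note(f, "fitness", seed_fit)
  f <- file.path(out_dir, "fitness.tsv")
  write_tsv_plain(data.frame(
    phase = vapply(fits, `[[`, "", "phase"),
    s_per_generation = vapply(fits, `[[`, 0, "s"),
    ci_lower = vapply(fits, function(x) x$ci[1] %||% NA_real_, 0),
    ci_upper = vapply(fits, function(x) x$ci[2] %||% NA_real_, 0)), f)
  note(f, "fitness", seed_fit)

  manifest <- do.call(rbind, manifest)
  write_tsv_plain(manifest, file.path(out_dir, "manifest.tsv"))
  invisible(manifest)
}
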