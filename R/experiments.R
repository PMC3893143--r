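#' Write / read a delimited numeric matrix
#'
#' Plain tab-separated text with a `#`-prefixed header line carrying
#' free-form metadata; the standard on-disk form for weight matrices and
#' snapshots.
#'
#' @param m numeric matrix
#' @param path file path
#' @param comment metadata string for the header line
#' @export
write_matrix_txt <- function(m, path, comment = "") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", comment), con)
  write.table(m, con, sep = "\t", row.names = FALSE, col.names = FALSE)
}

#' @rdname write_matrix_txt
#' @return `read_matrix_txt`: the matrix
#' @export
read_matrix_txt <- function(path) {
  as.matrix(read.table(path, sep = "\t", comment.char = "#"))
}

#' Write a spike record as two-column delimited text
#'
#' @param sim a [simulate_network()] result
#' @param path file path
#' @export
write_spikes_txt <- function(sim, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# duration_ms=%g dt_ms=%g seed=%d", sim$duration,
                     sim$dt, sim$seed), con)
  writeLines("time_ms\tneuron_id", con)
  write.table(sim$spikes, con, sep = "\t", row.names = FALSE,
              col.names = FALSE)
}

experiment_names <- c("fig1_toy", "fig2_stats", "fig3_controls",
                      "fig5_rules", "fig6_large", "fig7_meanfield_hetero",
                      "fig8_mixed_sweep")

#' Default configuration for a named experiment
#'
#' @param experiment one of the experiment names (see [run_experiment()])
#' @param seed master seed
#' @param scale scale factor in `(0, 1]`: shrinks network size and
#'   duration of the large experiments for constrained runs
#' @param outdir output directory
#' @return nested configuration list
#' @export
default_config <- function(experiment, seed = 1, scale = 1,
                           outdir = tempfile("motifnet_run_")) {
  if (!experiment %in% experiment_names)
    stop("unknown experiment name: ", experiment)
  protocol <- list(baseline = 0.2, pulse_amplitude = 1.0, dwell_time = 20,
                   sigma = 0.5, noise_mean = 100, noise_std = 150,
                   noise_tau = 5, drive_current = 1100, n_driven = 5)
  if (experiment == "fig3_controls") {
    # strong-drive control: zero-mean jitter so undriven units stay slow
    protocol$noise_mean <- 0
    protocol$noise_std <- 100
    protocol$drive_current <- 800
  }
  list(
    experiment = experiment, seed = seed, scale = scale, outdir = outdir,
    n_repeats = 20,
    network = list(N = 10, prune_fraction = 0.2, A = NA),
    large_network = list(N = 1000, duration = 100000, A_homog = NA,
                         noise_mean_homog = 250),
    protocol = protocol,
    run = list(duration = 30000, dt = 0.1, snapshot_every = 5000),
    rule = list(A2_plus = 0, A2_minus = 7.1e-3, A3_plus = 6.5e-3,
                A3_minus = 0, tau_plus = 16.8, tau_minus = 33.7,
                tau_x = 101, tau_y = 114, lambda = 1, w_max = 1,
                variant = "triplet", pair_match_rate = 1),
    motifs = list(strong_fraction = 0.5, n_draws = 2000),
    protocol_stdp = list(n_pairs = 60, delta_t = 10,
                         rates = c(1, 2, 5, 10, 15, 20, 25, 30, 35, 40,
                                   45, 50),
                         window = seq(-100, 100, by = 5)),
    meanfield = list(duration = 15000, dt = 0.5, h = 5,
                     p_grid = seq(0, 1, by = 0.1)))
}

#' Validate and normalise an experiment configuration
#'
#' Accepts a configuration list or the path of a JSON file; unknown keys
#' are rejected, missing ones filled with defaults, and cross-field
#' consistency enforced (in particular a `pair` rule variant with nonzero
#' triplet amplitudes is inconsistent).
#'
#' @param config list or JSON file path; must name the `experiment`
#' @return the normalised configuration list
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("no such config file: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (is.null(config$experiment))
    stop("config must name an 'experiment'")
  base <- default_config(config$experiment)
  bad <- setdiff(names(config), names(base))
  if (length(bad) > 0)
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  for (blk in names(config)) {
    if (is.list(base[[blk]])) {
      extra <- setdiff(names(config[[blk]]), names(base[[blk]]))
      if (length(extra) > 0)
        stop("unknown keys in '", blk, "': ", paste(extra, collapse = ", "))
    }
  }
  # an explicitly pair-based rule must not also set triplet amplitudes
  # (checked on the raw config: defaults legitimately carry the triplet
  # base from which the pair control is derived)
  if (!is.null(config$rule$variant) && config$rule$variant == "pair") {
    a3p <- config$rule$A3_plus %||% 0
    a3m <- config$rule$A3_minus %||% 0
    if (a3p != 0 || a3m != 0)
      stop("rule variant 'pair' is inconsistent with nonzero triplet ",
           "amplitudes (A3_plus / A3_minus)")
  }
  cfg <- modifyList(base, config)
  if (cfg$scale <= 0 || cfg$scale > 1) stop("scale must be in (0, 1]")
  for (key in c("dwell_time", "noise_tau"))
    if (cfg$protocol[[key]] <= 0)
      stop("protocol key '", key, "' must be strictly positive")
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_rule <- function(cfg) {
  args <- cfg$rule
  variant <- args$variant %||% "triplet"
  args$variant <- NULL
  # the config block always describes the triplet base; control variants
  # are derived from it
  base <- do.call(triplet_params, args)
  configure_rule(variant, base)
}

config_protocol <- function(cfg, mode, drive_units = integer()) {
  p <- cfg$protocol
  stimulus_protocol(mode = mode, baseline = p$baseline,
                    pulse_amplitude = p$pulse_amplitude,
                    dwell_time = p$dwell_time, sigma = p$sigma,
                    noise_mean = p$noise_mean, noise_std = p$noise_std,
                    noise_tau = p$noise_tau, drive_units = drive_units,
                    drive_current = p$drive_current)
}

# tiny djb2 hash over the deparsed config, enough to fingerprint runs
config_hash <- function(cfg) {
  bytes <- utf8ToInt(paste(deparse(cfg), collapse = ""))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

run_and_score <- function(cfg, kind, seed, mode = "toy_wave",
                          drive_units = integer()) {
  A <- cfg$network$A
  if (length(A) == 1 && is.na(A)) A <- NULL # auto: size-scaled default
  wir <- build_wiring(cfg$network$N, cfg$network$prune_fraction, seed = seed,
                      kind = kind, A = A)
  sim <- simulate_network(wir, config_protocol(cfg, mode, drive_units),
                          duration = cfg$run$duration, dt = cfg$run$dt,
                          seed = seed + 1, rule = config_rule(cfg),
                          snapshot_every = cfg$run$snapshot_every)
  wt <- normalize_clip(sim$w_final, config_rule(cfg)$w_max,
                       cfg$motifs$strong_fraction)
  sres <- symmetry_index(wt)
  p <- if (is.na(sres$s)) NA_real_ else
    symmetry_null_pvalue(sres$s, wir$N, cfg$network$prune_fraction,
                         cfg$motifs$strong_fraction,
                         n_draws = cfg$motifs$n_draws, seed = seed + 2,
                         tail = if (kind == "facilitating") "upper"
                                else "lower")
  rs <- rate_summary(sim, window = min(cfg$run$duration, 10000))
  list(sim = sim, wt = wt, s = sres$s, p = p,
       mean_rate = mean(rs$rates), rates = rs$rates)
}

#' Run a named experiment end to end
#'
#' Executes one of the stock protocols, writing spike records, weight
#' snapshots, motif tables and summary statistics (all delimited text)
#' plus a JSON manifest into the configured output directory.
#'
#' Experiments: `fig1_toy` (one facilitating and one depressing toy run),
#' `fig2_stats` (repeated toy runs, symmetry-index distributions),
#' `fig3_controls` (depressing network with a strongly driven subset),
#' `fig5_rules` (timing windows and frequency sweeps for the triplet,
#' pair and anti variants), `fig6_large` (large homogeneous and
#' heterogeneous networks with motif tallies and rate histograms),
#' `fig7_meanfield_hetero` (two-population mean-field trajectory) and
#' `fig8_mixed_sweep` (mixed-kind equilibrium curves).
#'
#' @param config configuration list or JSON path; see [validate_config()]
#' @return the run manifest (invisibly): config hash, seed, file list
#' @export
run_experiment <- function(config) {
  cfg <- validate_config(config)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  put <- function(name) {
    files <<- c(files, name)
    file.path(cfg$outdir, name)
  }
  emit_table <- function(df, name, comment = "") {
    path <- put(name)
    con <- file(path, "w")
    writeLines(paste0("# ", comment), con)
    suppressWarnings(write.table(df, con, sep = "\t", row.names = FALSE,
                                 quote = FALSE))
    close(con)
  }
  seed <- cfg$seed
  switch(cfg$experiment,
    fig1_toy = {
      for (kind in c("depressing", "facilitating")) {
        r <- run_and_score(cfg, kind, seed)
        tag <- substr(kind, 1, 1)
        write_spikes_txt(r$sim, put(sprintf("spikes_%s.tsv", tag)))
        write_matrix_txt(r$sim$w_final, put(sprintf("w_final_%s.tsv", tag)),
                         sprintf("final scaling factors, %s toy net", kind))
        for (si in seq_along(r$sim$snapshots)) {
          tms <- r$sim$snapshot_times[si]
          write_matrix_txt(
            r$sim$snapshots[[si]],
            put(sprintf("w_snapshot_%s_t%07d.tsv", tag, round(tms))),
            sprintf("scaling factors at t=%g ms, %s toy net", tms, kind))
        }
        emit_table(data.frame(kind = kind, s = r$s, p = r$p,
                              mean_rate = r$mean_rate),
                   sprintf("summary_%s.tsv", tag), "toy-run summary")
      }
    },
    fig2_stats = {
      for (kind in c("depressing", "facilitating")) {
        rows <- lapply(seq_len(cfg$n_repeats), function(k) {
          r <- run_and_score(cfg, kind, seed + 13 * k)
          data.frame(repeat_id = k, s = r$s, p = r$p,
                     mean_rate = r$mean_rate)
        })
        emit_table(do.call(rbind, rows),
                   sprintf("stats_%s.tsv", substr(kind, 1, 1)),
                   sprintf("symmetry statistics over %d %s toy runs",
                           cfg$n_repeats, kind))
      }
    },
    fig3_controls = {
      driven <- seq_len(cfg$protocol$n_driven)
      r <- run_and_score(cfg, "depressing", seed,
                         mode = "strong_drive_subset",
                         drive_units = driven)
      s_sub <- symmetry_index(r$wt, subset = driven)$s
      write_matrix_txt(r$sim$w_final, put("w_final.tsv"),
                       "depressing net, strongly driven subset")
      emit_table(data.frame(s_whole = r$s, s_driven_submatrix = s_sub,
                            p_whole = r$p,
                            driven = paste(driven, collapse = ",")),
                 "summary.tsv", "strong-drive control")
    },
    fig5_rules = {
      base <- config_rule(cfg)
      ps <- cfg$protocol_stdp
      for (v in c("triplet", "pair", "anti")) {
        rule <- configure_rule(v, base)
        win <- vapply(ps$window, function(d) {
          run_timing_protocol(d, ps$n_pairs, 1, rule)
        }, numeric(1))
        emit_table(data.frame(delta_t = ps$window, dw = win),
                   sprintf("window_%s.tsv", v),
                   sprintf("timing window, %s rule, 1 Hz pairing", v))
        dtf <- if (v == "anti") ps$delta_t else -ps$delta_t
        sweep <- run_frequency_protocol(dtf, rule, ps$rates, ps$n_pairs)
        cross <- ltd_ltp_crossover(rule, dtf, n_pairs = ps$n_pairs)
        emit_table(data.frame(rate = ps$rates, dw = sweep,
                              crossover = as.numeric(cross)),
                   sprintf("frequency_%s.tsv", v),
                   sprintf("frequency sweep, %s rule, delta_t = %g ms",
                           v, dtf))
      }
    },
    fig6_large = {
      N <- max(10, round(cfg$large_network$N * cfg$scale))
      duration <- max(5000, round(cfg$large_network$duration * cfg$scale))
      for (kind in c("depressing", "facilitating", "mixed_populations")) {
        # homogeneous nets run in a weaker-coupling / stronger-noise regime
        # than the heterogeneous one (see the methods vignette)
        hom <- kind != "mixed_populations"
        wir <- build_wiring(N, cfg$network$prune_fraction, seed = seed,
                            kind = kind,
                            A = if (!hom) NULL
                            else if (is.na(cfg$large_network$A_homog))
                              50000 / (N - 1)
                            else cfg$large_network$A_homog)
        prot <- config_protocol(cfg, "wave_plus_noise")
        if (hom) prot$noise_mean <- cfg$large_network$noise_mean_homog
        sim <- simulate_network(
          wir, prot, duration = duration,
          dt = cfg$run$dt, seed = seed + 1, rule = config_rule(cfg),
          w_cross_scale = if (kind == "mixed_populations") 0.3 else 1,
          snapshot_every = 0)
        wt <- normalize_clip(sim$w_final, config_rule(cfg)$w_max,
                             cfg$motifs$strong_fraction)
        tally <- count_pair_motifs(wt, wir$kind)
        emit_table(motif_tally_table(tally),
                   sprintf("tally_%s.tsv", kind),
                   sprintf("motif tally vs Bernoulli null, %s, N=%d", kind,
                           N))
        rs <- rate_summary(sim, window = min(duration, 10000))
        emit_table(data.frame(neuron = seq_len(N), label = wir$labels,
                              rate = rs$rates),
                   sprintf("rates_%s.tsv", kind), "steady-state rates")
      }
    },
    fig7_meanfield_hetero = {
      cfgmf <- mf_config(h = cfg$meanfield$h)
      tr <- integrate_meanfield(cfgmf, duration = cfg$meanfield$duration,
                                dt = cfg$meanfield$dt)
      emit_table(data.frame(time = tr$time, nu_D = tr$nu[, 1],
                            nu_F = tr$nu[, 2], w_DD = tr$w[, 1],
                            w_DF = tr$w[, 3], w_FD = tr$w[, 2],
                            w_FF = tr$w[, 4]),
                 "trajectory.tsv",
                 "heterogeneous mean-field trajectory")
    },
    fig8_mixed_sweep = {
      rows <- lapply(c(0, cfg$meanfield$h), function(h) {
        eq <- mixed_equilibria(cfg$meanfield$p_grid,
                               mf_config(populations = "F", h = h))
        eq$h <- h
        eq
      })
      emit_table(do.call(rbind, rows), "mixed_equilibria.tsv",
                 "stable and unstable equilibria vs depressing probability")
    })
  manifest <- list(experiment = cfg$experiment, seed = cfg$seed,
                   scale = cfg$scale, scaled_down = cfg$scale < 1,
                   config_hash = config_hash(cfg),
                   version = as.character(utils::packageVersion("motifnet")),
                   files = files, written = format(Sys.time()))
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest$outdir <- cfg$outdir
  invisible(manifest)
}

#' Write deterministic wiring fixtures to disk
#'
#' Emits, for each requested size (always including 3 and 10), the binary
#' wiring matrix, the kind labels and uniform initial scaling factors as
#' delimited text. Byte-identical for identical seeds.
#'
#' @param N additional network size
#' @param seed RNG seed
#' @param outdir output directory
#' @param w_max upper bound for the initial scaling factors
#' @return character vector of written file paths (invisibly)
#' @export
generate_fixtures <- function(N = 10, seed = 1, outdir = ".", w_max = 1) {
  if (N < 2) stop("N must be >= 2")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (n in unique(c(3, 10, N))) {
    wir <- build_wiring(n, seed = seed, kind = "mixed_populations")
    set.seed(seed + n)
    w0 <- matrix(runif(n * n, 0, w_max), n, n) * wir$C
    base <- file.path(outdir, sprintf("fixture_N%d", n))
    write_matrix_txt(wir$C, paste0(base, "_C.tsv"),
                     sprintf("wiring, N=%d, seed=%d", n, seed))
    write_matrix_txt(w0, paste0(base, "_w0.tsv"),
                     sprintf("initial scaling factors, N=%d, seed=%d", n,
                             seed))
    kf <- wir$kind
    kf[is.na(kf)] <- "-"
    con <- file(paste0(base, "_kind.tsv"), "w")
    writeLines(paste0("# SD kinds, N=", n), con)
    write.table(kf, con, sep = "\t", row.names = FALSE, col.names = FALSE,
                quote = FALSE)
    close(con)
    paths <- c(paths, paste0(base, c("_C.tsv", "_w0.tsv", "_kind.tsv")))
  }
  invisible(paths)
}

#' Summarise a finished experiment run
#'
#' @param manifest a [run_experiment()] manifest (or the path of a run
#'   directory containing `manifest.json`)
#' @return data frame with one row per output table, reporting basic
#'   integrity (rows, existence) and any summary columns found
#' @export
summarize_run <- function(manifest) {
  if (is.character(manifest)) {
    manifest <- jsonlite::read_json(file.path(manifest, "manifest.json"),
                                    simplifyVector = TRUE)
    manifest$outdir <- dirname(file.path(manifest$files[1]))
  }
  outdir <- manifest$outdir
  rows <- lapply(manifest$files, function(f) {
    path <- file.path(outdir, f)
    ok <- file.exists(path) && file.size(path) > 0
    n <- if (ok && grepl("\\.tsv$", f))
      nrow(read.table(path, sep = "\t", header = TRUE, comment.char = "#"))
    else NA_integer_
    data.frame(file = f, exists = ok, rows = n)
  })
  cbind(experiment = manifest$experiment, seed = manifest$seed,
        do.call(rbind, rows))
}
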