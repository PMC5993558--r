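# Experiment presets binding model, stimulus, integrator and spectra into
# reproducible figure-level runs, plus configuration serialization.

#' Default study conditions for the parkinsonian experiments
#'
#' Returns the run settings shared by the experiment presets: integration
#' step, seeded white-noise excitation of the external drive channel (the
#' nominal operating state is a marginally stable focus, so its resonances
#' are revealed by small stochastic forcing), and the equilibrium-breaking
#' seed offset.
#'
#' @param seed integer; seeds the noise stream.
#' @param noise_psd one-sided spectral density of the rate noise on the
#'   external channel (s^-2 Hz^-1).
#' @return List with `dt`, `noise`, `seed_offset`.
#' @export
study_conditions <- function(seed = 1, noise_psd = 0.1) {
  list(dt = 1e-4,
       noise = list(psd = noise_psd, seed = as.integer(seed)),
       seed_offset = 1e-6)
}

#' Key loop definitions of the CTBG network
#'
#' Closed gain paths used by the gain-versus-stimulation analyses: the
#' STN-GPe loop, the hyperdirect pathway (cortex -> STN -> GPi -> thalamic
#' relay -> cortex), and the direct and indirect pathways through the
#' striatum.
#'
#' @return Named list of population-label paths for [loop_gain()].
#' @export
ctbg_loops <- function() {
  list(
    stn_gpe = c("z", "p2", "z"),
    hyperdirect = c("e", "z", "p1", "s", "e"),
    direct = c("e", "d1", "p1", "s", "e"),
    indirect = c("e", "d2", "p2", "z", "p1", "s", "e")
  )
}

#' Loop gains as a function of DBS pulse frequency
#'
#' For each stimulus frequency the stimulated system is simulated, the
#' operating point is taken as the time-averaged soma potentials over the
#' analysis window, the sigmoid slopes are evaluated there, and the
#' configured loop-gain products are reported.  A baseline row gives the
#' unstimulated gains.
#'
#' @param model a [ctbg_model()].
#' @param protocol a [stim_protocol()] with a numeric amplitude.
#' @param f_list stimulus frequencies (Hz).
#' @param loops named list of closed paths (default [ctbg_loops()]).
#' @param duration,window,dt,noise,init,seed_offset run settings as in
#'   [suppression_curve()].
#' @return Data frame: `f_stim` (NA for baseline) and one column per loop.
#' @export
gain_vs_fstim <- function(model, protocol, f_list, loops = ctbg_loops(),
                          duration = 20, window = c(10, 20), dt = 1e-4,
                          noise = NULL, init = NULL, seed_offset = 1e-6) {
  if (is.null(init))
    init <- select_operating_state(solve_steady_states(model))
  gains_at <- function(proto) {
    sim <- simulate_ctbg(model, protocol = proto, duration = duration,
                         dt = dt, init = init, noise = noise,
                         seed_offset = seed_offset)
    i0 <- which(sim$time >= window[1] & sim$time <= window[2])
    phi0 <- vapply(CTBG_STATE_POPS, function(a)
      firing_rate(mean(sim$V[i0, a]), a, model), numeric(1))
    phi0 <- c(phi0, i = unname(phi0[["e"]]))[CTBG_ALL_POPS]
    op <- structure(list(phi0 = phi0), class = "ctbg_steady")
    g <- gains(op, model)
    vapply(loops, function(p) loop_gain(g, p), numeric(1))
  }
  base <- gains_at(NULL)
  rows <- lapply(f_list, function(f) {
    proto <- protocol
    proto$f_stim <- f
    c(f_stim = f, gains_at(proto))
  })
  out <- as.data.frame(rbind(c(f_stim = NA_real_, base),
                             do.call(rbind, rows)))
  out
}

preset_names <- function() {
  c("beta-generation-a", "beta-generation-b", "dbs-onset-150Hz",
    "suppression-sweep", "gain-vs-fstim", "direct-vs-indirect",
    "fstim-spectrogram", "entrainment-scan")
}

resolve_preset_config <- function(name, overrides, seed) {
  base <- list(
    preset = name, seed = seed,
    model = list(nu = NULL),
    protocol = list(f_stim = 150, t_width = 7e-4, amp = NA_real_, onset = 0,
                    couplings = c(zx = -1.2, p1x = 1.2, p2x = 1.2),
                    calibrate_share = 0.06),
    run = list(duration = 40, window = c(10, 30), dt = 1e-4,
               noise_psd = 0.1, seed_offset = 1e-6),
    f_list = NULL, band = c(20, 30), dV_list = NULL
  )
  defaults <- switch(
    name,
    "beta-generation-a" = list(model = list(nu = c(p2z = 1.8))),
    "beta-generation-b" = list(),
    "dbs-onset-150Hz" = list(
      run = list(duration = 50, window = c(10, 30), dt = 1e-4,
                 noise_psd = 0.1, seed_offset = 1e-6),
      protocol = utils::modifyList(base$protocol, list(onset = 30)),
      window_during = c(30, 50)),
    "suppression-sweep" = list(
      f_list = seq(100, 200, 10),
      run = list(duration = 20, window = c(10, 20), dt = 1e-4,
                 noise_psd = 0.1, seed_offset = 1e-6)),
    "gain-vs-fstim" = list(
      f_list = seq(20, 200, 20),
      run = list(duration = 20, window = c(10, 20), dt = 1e-4,
                 noise_psd = 0.1, seed_offset = 1e-6)),
    "direct-vs-indirect" = list(
      dV_list = c(0.1, 0.2, 0.4, 0.8, 1.2),
      run = list(duration = 20, window = c(10, 20), dt = 1e-4,
                 noise_psd = 0.1, seed_offset = 1e-6)),
    "fstim-spectrogram" = list(
      f_list = seq(20, 200, 10),
      run = list(duration = 20, window = c(10, 20), dt = 1e-4,
                 noise_psd = 0.1, seed_offset = 1e-6)),
    "entrainment-scan" = list(
      f_list = seq(24, 28, 0.2),
      run = list(duration = 20, window = c(10, 20), dt = 1e-4,
                 noise_psd = 0.1, seed_offset = 1e-6)),
    stop("unknown preset: ", name, " (available: ",
         paste(preset_names(), collapse = ", "), ")")
  )
  cfg <- utils::modifyList(base, defaults)
  if (length(overrides)) {
    for (nm in intersect(names(overrides), c("f_list", "band", "dV_list",
                                             "window_during")))
      overrides[[nm]] <- unlist(overrides[[nm]])
    if (!is.null(overrides$run)) overrides$run <- lapply(overrides$run, unlist)
    if (!is.null(overrides$protocol))
      overrides$protocol <- lapply(overrides$protocol, unlist)
    bad <- setdiff(names(overrides), c(names(cfg), "amp"))
    if (length(bad)) stop("unknown override key(s): ",
                          paste(bad, collapse = ", "))
    if (!is.null(overrides$amp)) {
      cfg$protocol$amp <- overrides$amp
      overrides$amp <- NULL
    }
    cfg <- utils::modifyList(cfg, overrides)
  }
  for (nm in c("f_list", "band", "dV_list", "window_during"))
    if (!is.null(cfg[[nm]])) cfg[[nm]] <- unlist(cfg[[nm]])
  cfg$run <- lapply(cfg$run, unlist)
  cfg
}

# yaml drops the names of nested named atomic vectors; convert them to
# named lists before writing and collapse back after reading
config_namedvec_to_list <- function(x) {
  if (is.list(x)) return(lapply(x, config_namedvec_to_list))
  if (is.atomic(x) && !is.null(names(x))) return(as.list(x))
  x
}

as_named_num <- function(x) {
  if (is.null(x)) return(NULL)
  stats::setNames(vapply(x, as.numeric, numeric(1)), names(x))
}

config_hash <- function(cfg) {
  path <- tempfile(fileext = ".yaml")
  on.exit(unlink(path))
  yaml::write_yaml(config_namedvec_to_list(cfg), path, precision = 12)
  unname(tools::md5sum(path))
}

preset_model <- function(cfg) {
  args <- cfg$model[!vapply(cfg$model, is.null, logical(1))]
  for (nm in intersect(names(args), c("nu", "tau", "Qmax", "theta")))
    args[[nm]] <- as_named_num(args[[nm]])
  do.call(ctbg_model, args)
}

preset_protocol <- function(cfg, model, init) {
  pr <- stim_protocol(f_stim = cfg$protocol$f_stim,
                      t_width = cfg$protocol$t_width,
                      amp = cfg$protocol$amp,
                      onset = cfg$protocol$onset,
                      couplings = as_named_num(cfg$protocol$couplings))
  if (is.na(pr$amp)) {
    cal <- pr
    cal$onset <- 0
    cal$f_stim <- 150  # calibration reference frequency
    cal <- calibrate_amplitude(model, cal,
                               target_share = cfg$protocol$calibrate_share,
                               dt = cfg$run$dt, init = init)
    pr$amp <- cal$amp
    attr(pr, "calibration") <- attr(cal, "calibration")
  }
  pr
}

#' Run an experiment preset
#'
#' Executes one of the packaged figure-level experiment pipelines
#' (steady state -> simulation(s) -> spectra or derived tables) under fully
#' resolved, hashed settings.  Available presets:
#' `beta-generation-a` / `beta-generation-b` (unstimulated parkinsonian
#' spectra at STN -> GPe coupling 1.8 / 2.4 mV s), `dbs-onset-150Hz`
#' (stimulation switched on mid-run, spectra before and during),
#' `suppression-sweep` (beta-band peak power versus pulse frequency),
#' `gain-vs-fstim` (loop gains versus pulse frequency),
#' `direct-vs-indirect` (constant-potential versus pulse-train
#' perturbation), `fstim-spectrogram` (full spectra versus pulse frequency),
#' and `entrainment-scan` (locking and intermodulation near the beta peak).
#'
#' Durations and scan grids are scaled-down defaults that run in seconds to
#' minutes; full-scale settings are one override away (e.g.
#' `overrides = list(run = list(duration = 40, window = c(20, 40)))`).
#'
#' @param name preset identifier.
#' @param overrides named list of config overrides (unknown keys rejected).
#' @param outdir optional directory; when given, all tables, the resolved
#'   configuration and a log are written there.
#' @param seed integer seed for the noise stream.
#' @return A list with the preset outputs (tables / spectra), the resolved
#'   `config`, and its `hash`.
#' @export
run_preset <- function(name, overrides = list(), outdir = NULL, seed = 1) {
  cfg <- resolve_preset_config(name, overrides, seed)
  hash <- config_hash(cfg)
  model <- preset_model(cfg)
  init <- select_operating_state(solve_steady_states(model))
  noise <- list(psd = cfg$run$noise_psd, seed = cfg$seed)
  rn <- cfg$run
  out <- list(config = cfg, hash = hash)

  needs_stim <- !(name %in% c("beta-generation-a", "beta-generation-b"))
  protocol <- if (needs_stim) preset_protocol(cfg, model, init) else NULL
  if (needs_stim) out$protocol <- protocol

  if (name %in% c("beta-generation-a", "beta-generation-b")) {
    sim <- simulate_ctbg(model, duration = rn$duration, dt = rn$dt,
                         init = init, noise = noise,
                         seed_offset = rn$seed_offset)
    sp <- power_spectrum(sim, "z", rn$window[1], rn$window[2])
    out$sim <- sim
    out$spectrum <- sp
    out$dominant <- dominant_peak(sp, 1, 60)
  } else if (name == "dbs-onset-150Hz") {
    sim <- simulate_ctbg(model, protocol = protocol, duration = rn$duration,
                         dt = rn$dt, init = init, noise = noise,
                         seed_offset = rn$seed_offset)
    out$sim <- sim
    out$spectrum_pre <- power_spectrum(sim, "z", rn$window[1], rn$window[2])
    wd <- cfg$window_during
    out$spectrum_during <- power_spectrum(sim, "z", wd[1], wd[2])
    out$beta_pre <- band_peak_power(out$spectrum_pre, cfg$band[1], cfg$band[2])
    out$beta_during <- band_peak_power(out$spectrum_during, cfg$band[1],
                                       cfg$band[2],
                                       exclude_harmonics_of = protocol$f_stim)
  } else if (name == "suppression-sweep") {
    out$table <- suppression_curve(model, protocol, cfg$f_list,
                                   band = cfg$band, duration = rn$duration,
                                   window = rn$window, dt = rn$dt,
                                   noise = noise, init = init,
                                   seed_offset = rn$seed_offset)
  } else if (name == "gain-vs-fstim") {
    out$table <- gain_vs_fstim(model, protocol, cfg$f_list,
                               duration = rn$duration, window = rn$window,
                               dt = rn$dt, noise = noise, init = init,
                               seed_offset = rn$seed_offset)
  } else if (name == "direct-vs-indirect") {
    out$table <- direct_vs_indirect(model, protocol, cfg$dV_list,
                                    band = cfg$band, duration = rn$duration,
                                    window = rn$window, dt = rn$dt,
                                    noise = noise, init = init,
                                    seed_offset = rn$seed_offset)
  } else if (name == "fstim-spectrogram") {
    specs <- lapply(cfg$f_list, function(f) {
      proto <- protocol
      proto$f_stim <- f
      sim <- simulate_ctbg(model, protocol = proto, duration = rn$duration,
                           dt = rn$dt, init = init, noise = noise,
                           seed_offset = rn$seed_offset)
      power_spectrum(sim, "z", rn$window[1], rn$window[2])
    })
    keep <- specs[[1]]$freq <= 300
    out$freq <- specs[[1]]$freq[keep]
    out$power <- do.call(cbind, lapply(specs, function(s) s$power[keep]))
    colnames(out$power) <- paste0("f", cfg$f_list)
  } else if (name == "entrainment-scan") {
    out$table <- entrainment_scan(model, protocol, cfg$f_list,
                                  duration = rn$duration, window = rn$window,
                                  dt = rn$dt, noise = noise, init = init,
                                  seed_offset = rn$seed_offset)
  }

  if (!is.null(outdir)) write_preset_outputs(out, name, outdir)
  out
}

#' Direct constant perturbation versus equivalent pulse-train stimulation
#'
#' For each perturbation magnitude, measures the beta-band peak power of the
#' STN rate under (a) a direct constant soma perturbation (STN inhibited,
#' pallidum excited) and (b) the pulse train whose time-averaged evoked
#' potential equals the same magnitude.
#'
#' @param model a [ctbg_model()].
#' @param protocol pulse-train template (frequency, width, couplings).
#' @param dV_list perturbation magnitudes (mV).
#' @param band,duration,window,dt,noise,init,seed_offset as in
#'   [suppression_curve()].
#' @return Data frame: `dV`, `amp_equivalent`, `power_direct`,
#'   `power_indirect`, `rel_difference`.
#' @export
direct_vs_indirect <- function(model, protocol, dV_list, band = c(20, 30),
                               duration = 20, window = c(10, 20), dt = 1e-4,
                               noise = NULL, init = NULL,
                               seed_offset = 1e-6) {
  if (is.null(init))
    init <- select_operating_state(solve_steady_states(model))
  nu_zx <- abs(protocol$couplings[["zx"]])
  pk <- function(sim, f_stim = NULL) {
    sp <- power_spectrum(sim, "z", window[1], window[2])
    band_peak_power(sp, band[1], band[2], exclude_harmonics_of = f_stim)
  }
  rows <- lapply(dV_list, function(dV) {
    sd <- apply_direct_perturbation(model, init, dV, duration, dt,
                                    noise = noise, seed_offset = seed_offset)
    amp <- dV / (nu_zx * protocol$t_width * protocol$f_stim)
    proto <- protocol
    proto$amp <- amp
    si <- simulate_ctbg(model, protocol = proto, duration = duration,
                        dt = dt, init = init, noise = noise,
                        seed_offset = seed_offset)
    pd <- pk(sd)
    pi_ <- pk(si, proto$f_stim)
    data.frame(dV = dV, amp_equivalent = amp, power_direct = pd,
               power_indirect = pi_,
               rel_difference = abs(pd - pi_) / max(pd, pi_))
  })
  do.call(rbind, rows)
}

write_preset_outputs <- function(out, name, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(config_namedvec_to_list(c(out$config,
                                              list(hash = out$hash))),
                   file.path(outdir, "config.yaml"), precision = 12)
  log <- c(sprintf("preset: %s", name),
           sprintf("hash: %s", out$hash),
           sprintf("time: %s", format(Sys.time())),
           sprintf("ctbgsim version: %s",
                   as.character(utils::packageVersion("ctbgsim"))))
  if (!is.null(out$table))
    utils::write.table(out$table, file.path(outdir, "table.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  for (el in c("spectrum", "spectrum_pre", "spectrum_during")) {
    if (!is.null(out[[el]]))
      utils::write.table(
        data.frame(freq = out[[el]]$freq, power = out[[el]]$power),
        file.path(outdir, paste0(el, ".tsv")),
        sep = "\t", row.names = FALSE, quote = FALSE)
  }
  if (!is.null(out$power))
    utils::write.table(cbind(freq = out$freq, out$power),
                       file.path(outdir, "spectrogram.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(out$sim))
    export_trajectory(out$sim, file.path(outdir, "trajectory.tsv"))
  writeLines(log, file.path(outdir, "log.txt"))
  invisible(outdir)
}

#' Re-run a preset from its saved configuration and compare outputs
#'
#' Reads `config.yaml` from an output directory written by [run_preset()],
#' re-executes the preset into a temporary directory, and compares the
#' regenerated tables file-by-file.
#'
#' @param dir directory containing `config.yaml` and the preset outputs.
#' @return TRUE invisibly if all regenerated files match; otherwise an error
#'   listing the mismatches.
#' @export
verify_preset <- function(dir) {
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  name <- cfg$preset
  seed <- cfg$seed
  cfg$hash <- NULL
  tmp <- tempfile("ctbg_verify_")
  # re-resolve from the stored full config: pass it through as overrides
  ov <- cfg[setdiff(names(cfg), c("preset", "seed"))]
  run_preset(name, overrides = ov, outdir = tmp, seed = seed)
  files <- setdiff(list.files(dir), c("log.txt"))
  bad <- character()
  for (f in files) {
    a <- file.path(dir, f)
    b <- file.path(tmp, f)
    if (!file.exists(b)) { bad <- c(bad, paste(f, "(missing)")); next }
    if (f == "config.yaml") next
    if (!isTRUE(unname(tools::md5sum(a)) == unname(tools::md5sum(b))))
      bad <- c(bad, f)
  }
  unlink(tmp, recursive = TRUE)
  if (length(bad)) stop("regenerated outputs differ: ",
                        paste(bad, collapse = ", "))
  invisible(TRUE)
}
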