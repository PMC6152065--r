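# Synthetic chromatograms and gel lanes with the statistical structure the
# caller assumes: Gaussian peaks centered at per-subunit reference RTs
# (optionally jittered by the reference SDs), a doubled amplitude for the
# overexpressed Bx7 variant, optional LMW-region clutter after 42 min, and
# optional white baseline noise.

#' Simulation configuration
#'
#' @param peak_sigma Gaussian peak width in minutes (default 0.15, chosen
#'   so the closest reference means remain resolvable at zero jitter).
#' @param amplitude peak amplitude in AU (default 100); the Bx7OE peak is
#'   simulated at twice this, reflecting its overexpression.
#' @param rt_jitter_scale multiplier on the per-subunit reference SDs for
#'   run-to-run retention-time jitter; 0 (default) is noise-free.
#' @param baseline_noise_sd SD of white noise added per sample (AU;
#'   default 0).
#' @param grid_step sampling interval in minutes (default 0.01).
#' @param time_range acquisition window in minutes (default 20-60).
#' @param lmw_clutter add a cluster of nuisance peaks confined to 43-54
#'   min, emulating LMW glutenins and gliadin carryover (default `FALSE`).
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(peak_sigma = 0.15, amplitude = 100,
                       rt_jitter_scale = 0, baseline_noise_sd = 0,
                       grid_step = 0.01, time_range = c(20, 60),
                       lmw_clutter = FALSE, seed = NULL) {
  stopifnot(peak_sigma > 0, grid_step > 0, rt_jitter_scale >= 0,
            baseline_noise_sd >= 0, amplitude > 0,
            length(time_range) == 2, time_range[1] < time_range[2])
  structure(list(peak_sigma = peak_sigma, amplitude = amplitude,
                 rt_jitter_scale = rt_jitter_scale,
                 baseline_noise_sd = baseline_noise_sd,
                 grid_step = grid_step, time_range = time_range,
                 lmw_clutter = lmw_clutter, seed = seed),
            class = "sim_config")
}

#' Simulate an RP-HPLC chromatogram for a cultivar
#'
#' Sums one Gaussian per expressed subunit, centered at the subunit's
#' reference mean RT plus (optionally) jitter drawn from
#' `N(0, rt_jitter_scale^2 * sd_rt^2)`; the Bx7OE peak gets double
#' amplitude. Clutter, when enabled, is 15 Gaussians with random centers
#' in 43-54 min. Reproducible under a fixed `cfg$seed`.
#'
#' @param profile a [cultivar_profile()].
#' @param table reference table from [load_reference()].
#' @param cfg a [sim_config()].
#' @return a [chromatogram()] named after the cultivar.
#' @examples
#' cs <- load_fixtures()$standards[[4]]  # Chinese Spring
#' tr <- simulate_chromatogram(cs, load_reference(), sim_config())
#' nrow(detect_peaks(tr))
#' @export
simulate_chromatogram <- function(profile, table, cfg = sim_config()) {
  subs <- profile_subunits(profile)
  i <- match(subs, table$subunit)
  if (anyNA(i)) {
    hmwgs_stop(paste0("subunit(s) not in reference table: ",
                      paste(subs[is.na(i)], collapse = ", ")),
               "hmwgs_lookup_error")
  }
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  t <- seq(cfg$time_range[1], cfg$time_range[2], by = cfg$grid_step)
  y <- numeric(length(t))
  for (j in seq_along(subs)) {
    center <- table$mean_rt[i[j]] +
      cfg$rt_jitter_scale * stats::rnorm(1, 0, table$sd_rt[i[j]])
    amp <- cfg$amplitude * if (subs[j] == "Bx7OE") 2 else 1
    y <- y + amp * exp(-(t - center)^2 / (2 * cfg$peak_sigma^2))
  }
  if (isTRUE(cfg$lmw_clutter)) {
    centers <- stats::runif(15, 43, 54)
    amps <- stats::runif(15, 10, 80)
    for (j in seq_len(15)) {
      y <- y + amps[j] * exp(-(t - centers[j])^2 / (2 * cfg$peak_sigma^2))
    }
  }
  if (cfg$baseline_noise_sd > 0) {
    y <- y + stats::rnorm(length(t), 0, cfg$baseline_noise_sd)
  }
  chromatogram(t, y, profile$name)
}

#' Simulate an SDS-PAGE lane for a cultivar
#'
#' One band per expressed subunit at its mobility rank; co-migrating
#' subunits collapse to a single band.
#'
#' @param profile a [cultivar_profile()].
#' @param mobility mobility table from [load_mobility()].
#' @return a [gel_lane()].
#' @examples
#' fx <- load_fixtures()
#' simulate_gel(fx$standards[[3]], load_mobility())  # Cheyenne: 5 bands
#' @export
simulate_gel <- function(profile, mobility) {
  gel_lane(profile$name, band_rank(mobility, profile_subunits(profile)))
}

#' Simulate replicate retention times for every reference subunit
#'
#' Draws `n_analyses` independent retention times per subunit from
#' `N(mean_rt, (scale * sd_rt)^2)`, emulating the replicate runs behind the
#' reference statistics.
#'
#' @param table reference table.
#' @param scale multiplier on the reference SDs (default 1).
#' @param seed optional integer seed.
#' @return named list of numeric vectors, one per subunit.
#' @export
simulate_replicate_rts <- function(table, scale = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(seq_len(nrow(table)), function(i) {
    stats::rnorm(table$n_analyses[i], table$mean_rt[i],
                 scale * table$sd_rt[i])
  })
  stats::setNames(out, table$subunit)
}
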