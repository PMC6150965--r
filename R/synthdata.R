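#' Population simulation parameters
#'
#' Parameters for generating per-metaphase chromosome measurements of one
#' population: a mean and SD of total length for every chromosome of the
#' diploid set (ranked, TL non-increasing), a uniform arm-ratio range
#' (default [1, 1.3], comfortably metacentric) and the number of
#' metaphases (default 10).
#'
#' @param population_id identifier.
#' @param mean_tl_um numeric vector of per-rank mean total lengths (um),
#'   length 2n, non-increasing.
#' @param sd_tl_um per-rank SDs (um), positive, recycled if scalar.
#' @param arm_ratio_range interval from which arm ratios are drawn
#'   uniformly.
#' @param n_metaphases metaphases to simulate.
#' @return object of class `population_params`.
#' @export
population_params <- function(population_id, mean_tl_um, sd_tl_um,
                              arm_ratio_range = c(1, 1.3),
                              n_metaphases = 10) {
  sd_tl_um <- rep_len(sd_tl_um, length(mean_tl_um))
  if (any(mean_tl_um <= 0) || any(sd_tl_um < 0))
    stop_domain("means must be positive and SDs non-negative")
  if (is.unsorted(rev(mean_tl_um)))
    stop_domain("mean lengths must be non-increasing with rank")
  if (length(mean_tl_um) %% 2L != 0L)
    stop_domain("need an even number of chromosomes (2n)")
  if (length(arm_ratio_range) != 2 || arm_ratio_range[1] < 1 ||
      diff(arm_ratio_range) < 0)
    stop_domain("arm_ratio_range must be an interval with lower bound >= 1")
  structure(list(population_id = population_id,
                 mean_tl_um = as.numeric(mean_tl_um),
                 sd_tl_um = as.numeric(sd_tl_um),
                 arm_ratio_range = as.numeric(arm_ratio_range),
                 n_metaphases = as.integer(n_metaphases)),
            class = "population_params")
}

#' Packaged karyomorphometric summary parameters (five ant populations)
#'
#' Returns the packaged per-homologue mean and SD total chromosome lengths
#' for the five Trachymyrmex holmgreni populations (CI, TO, BG, MC, CC;
#' 2n = 20, all metacentric), as simulation parameters.  At
#' `level = "homologue"` (default) each of the 20 ranked homologues keeps
#' its own printed mean +/- SD; `level = "pair"` averages the two
#' homologues of each pair.
#'
#' @param level `"homologue"` or `"pair"`.
#' @param n_metaphases metaphases per population (default 10, the number
#'   of measured spreads per population in the source study design).
#' @return named list of five [population_params()] objects, each also
#'   carrying a `printed_kl_um` element (the published karyotype length).
#' @export
table1_params <- function(level = c("homologue", "pair"),
                          n_metaphases = 10) {
  level <- match.arg(level)
  path <- system.file("extdata", "table1_trachymyrmex.csv",
                      package = "karyomorph", mustWork = TRUE)
  x <- read.csv(path)
  pops <- c("CI", "TO", "BG", "MC", "CC")
  out <- lapply(pops, function(p) {
    sub <- x[x$population_id == p, ]
    sub <- sub[order(sub$pair_rank, sub$homologue), ]
    if (level == "pair") {
      m <- tapply(sub$mean_tl_um, sub$pair_rank, mean)
      s <- tapply(sub$sd_tl_um, sub$pair_rank, mean)
      m <- rep(as.numeric(m), each = 2); s <- rep(as.numeric(s), each = 2)
    } else {
      m <- sub$mean_tl_um; s <- sub$sd_tl_um
    }
    # printed means can tie across adjacent ranks; enforce sortedness
    pp <- population_params(p, cummin(m), s, n_metaphases = n_metaphases)
    pp$printed_kl_um <- sub$printed_kl_um[1]
    pp
  })
  names(out) <- pops
  out
}

#' Simulate per-metaphase chromosome measurements
#'
#' For each metaphase and ranked homologue, draws a total length from a
#' Normal with the rank's mean and SD (truncated below at 0.1 um to keep
#' lengths physical) and an arm ratio uniformly from the parameter range;
#' arms are then L = TL r/(1+r) and S = TL/(1+r).  Chromosomes are
#' re-ranked by descending TL within each metaphase (as a measured
#' karyotype would be), so homologue lengths are drawn independently with
#' no within-pair correlation.  Deterministic given the seed.
#'
#' @param params a [population_params()].
#' @param seed integer seed.
#' @return a [measurement_dataset()].
#' @export
simulate_measurements <- function(params, seed) {
  stopifnot(inherits(params, "population_params"))
  with_seed(seed, {
    n2 <- length(params$mean_tl_um)
    rows <- lapply(seq_len(params$n_metaphases), function(mi) {
      tl <- rnorm(n2, params$mean_tl_um, params$sd_tl_um)
      tl <- pmax(tl, 0.1)
      r <- runif(n2, params$arm_ratio_range[1], params$arm_ratio_range[2])
      data.frame(population_id = params$population_id,
                 colony_id = params$population_id,
                 specimen_id = sprintf("%s_m%02d", params$population_id, mi),
                 long_arm_um = tl * r / (1 + r),
                 short_arm_um = tl / (1 + r),
                 total_length_um = tl, stringsAsFactors = FALSE)
    })
    measurement_dataset(do.call(rbind, rows))
  })
}

#' Simulate a multi-population measurement study
#'
#' Applies [simulate_measurements()] to each parameter set with a seed
#' derived deterministically from `seed` and the population's position,
#' and combines the results into one dataset.
#'
#' @param params_list list of [population_params()] (e.g.
#'   [table1_params()]).
#' @param seed integer seed.
#' @return a [measurement_dataset()] covering all populations.
#' @export
simulate_study <- function(params_list, seed) {
  sets <- lapply(seq_along(params_list), function(i)
    simulate_measurements(params_list[[i]], seed = (seed * 131 + i) %% 2^31))
  d <- do.call(rbind, lapply(sets, as.data.frame))
  measurement_dataset(d)
}

#' Flow-cytometry simulation parameters
#'
#' @param true_1c_pg true 1C value of the simulated sample (pg).
#' @param standard_1c_pg 1C of the internal standard (pg; default 0.18).
#' @param standard_channel mean fluorescence channel of the standard's
#'   G0/G1 peak (default 200 on a 1024-channel axis).
#' @param peak_cv coefficient of variation of each peak (default 0.02).
#' @param n_events total nuclei acquired (default 10,000, split evenly
#'   between sample and standard).
#' @param background_fraction fraction of events drawn uniformly across
#'   the axis as debris/background (default 0).
#' @param n_channels,channel_max binning grid (default 1024 channels over
#'   [0, 1023], mimicking a conventional cytometer ADC).
#' @return object of class `flow_sim_params`.
#' @export
flow_sim_params <- function(true_1c_pg, standard_1c_pg = 0.18,
                            standard_channel = 200, peak_cv = 0.02,
                            n_events = 10000, background_fraction = 0,
                            n_channels = 1024, channel_max = 1023) {
  stopifnot(true_1c_pg > 0, standard_1c_pg > 0, standard_channel > 0,
            peak_cv > 0, peak_cv < 0.2, n_events > 0,
            background_fraction >= 0, background_fraction < 1)
  structure(list(true_1c_pg = true_1c_pg, standard_1c_pg = standard_1c_pg,
                 standard_channel = standard_channel, peak_cv = peak_cv,
                 n_events = as.integer(n_events),
                 background_fraction = background_fraction,
                 n_channels = as.integer(n_channels),
                 channel_max = channel_max),
            class = "flow_sim_params")
}

#' Simulate a two-peak fluorescence histogram
#'
#' Events are split between the internal standard's G0/G1 peak at
#' `standard_channel` and the sample's peak at
#' `standard_channel * true_1c / standard_1c` (fluorescence proportional
#' to DNA content), each Gaussian with the given CV, plus optional uniform
#' background, binned onto the fixed channel grid.  Deterministic given
#' the seed.  If the two peak centers lie within 3 combined SDs a warning
#' is raised (the peaks will not be resolvable).
#'
#' @param params a [flow_sim_params()].
#' @param seed integer seed.
#' @return a [fluorescence_histogram()].
#' @export
simulate_histogram <- function(params, seed) {
  stopifnot(inherits(params, "flow_sim_params"))
  ch_std <- params$standard_channel
  ch_smp <- ch_std * params$true_1c_pg / params$standard_1c_pg
  sd_std <- ch_std * params$peak_cv
  sd_smp <- ch_smp * params$peak_cv
  if (abs(ch_smp - ch_std) < 3 * (sd_std + sd_smp))
    warning("sample and standard peaks closer than 3 combined SDs; ",
            "histogram is unresolvable", call. = FALSE)
  with_seed(seed, {
    n_bg <- round(params$n_events * params$background_fraction)
    n_sig <- params$n_events - n_bg
    n_std <- floor(n_sig / 2); n_smp <- n_sig - n_std
    ev <- c(rnorm(n_std, ch_std, sd_std), rnorm(n_smp, ch_smp, sd_smp),
            runif(n_bg, 0, params$channel_max))
    grid <- seq(0, params$channel_max, length.out = params$n_channels)
    step <- grid[2] - grid[1]
    idx <- pmin(pmax(round(ev / step), 0), params$n_channels - 1L) + 1L
    counts <- tabulate(idx, nbins = params$n_channels)
    fluorescence_histogram(grid, counts)
  })
}
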