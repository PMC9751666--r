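# Synthetic cohort and excretion generators.  The defaults encode the study
# design being emulated: four groups (external-beam arm and internal-emitter
# arm, each with its control), shortened lifespans in the exposed arms, a
# transient white-blood-cell dip after acute external exposure versus a
# sustained deficit under chronic internal exposure, and the qualitative
# bone-turnover / inflammation marker trends of such studies.

#' Cohort simulation configuration
#'
#' @param groups Data frame with one row per group: `group`, `arm`
#'   (`"HDR"` external or `"LDR"` internal), `exposed` (logical),
#'   `n_male`, `n_female`.  Defaults reproduce the reference design
#'   (control 18 = 10M/8F and exposed 20 = 9M/11F in the external arm;
#'   control 8 = 4M/4F and exposed 9 = 5M/4F in the internal arm).
#' @param gompertz_shape Gompertz shape (per week) of the lifespan
#'   distribution; mouse mortality accelerates with age.
#' @param gompertz_rate Baseline Gompertz rate (per week); the default pair
#'   puts the control median lifespan near 110 weeks.
#' @param hazard_multiplier Proportional-hazards multiplier applied to
#'   exposed groups (default 4; irradiated arms in lifespan studies of this
#'   design show survival differences significant at group sizes below 20,
#'   which corresponds to a hazard ratio of this magnitude).
#' @param wbc_baseline Mean white-blood-cell count, 10^3/uL.
#' @param wbc_hdr_dip Fractional WBC suppression at 2 weeks after acute
#'   exposure (recovers linearly by `wbc_recovery_week`).
#' @param wbc_recovery_week Week post-exposure at which the acute dip has
#'   recovered.
#' @param wbc_ldr_deficit Sustained fractional WBC deficit under chronic
#'   exposure (persists through `wbc_deficit_through_week`).
#' @param wbc_deficit_through_week Last week of the sustained deficit.
#' @param wbc_cv Coefficient of variation of WBC measurements (lognormal).
#' @param wbc_weeks Measurement weeks (post-exposure) for blood counts.
#' @param marker_means Named list `marker -> group -> c(early, late)` mean
#'   concentrations; defaults encode the qualitative trend pattern:
#'   formation marker P1NP up everywhere; OPG down over time in the
#'   external arm but up in the internal arm; resorption marker CTX-I up
#'   everywhere except the internally exposed group (flat); inflammation
#'   markers CCL2/CXCL1 flat except a late rise in the internally exposed
#'   group.
#' @param marker_sdlog Lognormal log-SD of marker concentrations.
#' @param marker_weeks Named list with `early` and `late` measurement
#'   weeks.
#' @return An object of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(
    groups = data.frame(
      group = c("Ctrl_X", "X-ray", "Ctrl_Ca", "Ca-45"),
      arm = c("HDR", "HDR", "LDR", "LDR"),
      exposed = c(FALSE, TRUE, FALSE, TRUE),
      n_male = c(10, 9, 4, 5),
      n_female = c(8, 11, 4, 4)),
    gompertz_shape = 0.05,
    gompertz_rate = 1.42e-4,
    hazard_multiplier = 4,
    wbc_baseline = 8,
    wbc_hdr_dip = 0.6,
    wbc_recovery_week = 10,
    wbc_ldr_deficit = 0.3,
    wbc_deficit_through_week = 29,
    wbc_cv = 0.12,
    wbc_weeks = c(2, 5, 10, 16, 22, 29),
    marker_means = list(
      "P1NP" = list("Ctrl_X" = c(20, 30), "X-ray" = c(20, 30),
                    "Ctrl_Ca" = c(20, 30), "Ca-45" = c(20, 32)),
      "OPG" = list("Ctrl_X" = c(2000, 1800), "X-ray" = c(2000, 1600),
                   "Ctrl_Ca" = c(2000, 2300), "Ca-45" = c(2000, 2800)),
      "CTX-I" = list("Ctrl_X" = c(10, 15), "X-ray" = c(10, 16),
                     "Ctrl_Ca" = c(10, 14), "Ca-45" = c(10, 10)),
      "CCL2" = list("Ctrl_X" = c(80, 80), "X-ray" = c(80, 82),
                    "Ctrl_Ca" = c(80, 82), "Ca-45" = c(80, 130)),
      "CXCL1" = list("Ctrl_X" = c(60, 60), "X-ray" = c(60, 62),
                     "Ctrl_Ca" = c(60, 62), "Ca-45" = c(60, 100))),
    marker_sdlog = 0.2,
    marker_weeks = list(early = c(2, 8), late = c(26, 32))) {
  stopifnot(is.data.frame(groups),
            all(c("group", "arm", "exposed", "n_male", "n_female") %in%
                  names(groups)),
            all(groups$n_male + groups$n_female > 0),
            gompertz_shape > 0, gompertz_rate > 0, hazard_multiplier > 0,
            marker_sdlog > 0, wbc_cv > 0)
  structure(list(groups = groups, gompertz_shape = gompertz_shape,
                 gompertz_rate = gompertz_rate,
                 hazard_multiplier = hazard_multiplier,
                 wbc_baseline = wbc_baseline, wbc_hdr_dip = wbc_hdr_dip,
                 wbc_recovery_week = wbc_recovery_week,
                 wbc_ldr_deficit = wbc_ldr_deficit,
                 wbc_deficit_through_week = wbc_deficit_through_week,
                 wbc_cv = wbc_cv, wbc_weeks = wbc_weeks,
                 marker_means = marker_means,
                 marker_sdlog = marker_sdlog,
                 marker_weeks = marker_weeks),
            class = "cohort_sim_config")
}

#' Simulate a cohort table
#'
#' Draws per-animal lifespans (Gompertz with a proportional-hazards
#' multiplier for exposed groups) and longitudinal measurements (WBC
#' counts and serum markers, lognormal noise) according to a
#' [cohort_sim_config()].  All randomness flows from `seed`, which is
#' recorded in the output.
#'
#' @param config A [cohort_sim_config()].
#' @param seed Integer seed.
#' @return A long-format data frame (the cohort table) with columns
#'   `animal_id`, `group`, `arm`, `exposed`, `sex`, `lifespan_weeks`,
#'   `event`, `measurement`, `week`, `value`; the seed is attached as
#'   attribute `"seed"`.  Survival rows carry `measurement = "lifespan"`.
#' @export
#' @examples
#' coh <- simulate_cohort(cohort_sim_config(), seed = 17)
#' table(unique(coh[c("animal_id", "group")])$group)
simulate_cohort <- function(config = cohort_sim_config(), seed = 1) {
  stopifnot(inherits(config, "cohort_sim_config"))
  set.seed(seed)
  g <- config$groups
  animals <- do.call(rbind, lapply(seq_len(nrow(g)), function(i) {
    n <- g$n_male[i] + g$n_female[i]
    data.frame(group = g$group[i], arm = g$arm[i], exposed = g$exposed[i],
               sex = rep(c("M", "F"), c(g$n_male[i], g$n_female[i])),
               stringsAsFactors = FALSE)
  }))
  animals$animal_id <- sprintf("m%03d", seq_len(nrow(animals)))
  rate <- ifelse(animals$exposed,
                 config$gompertz_rate * config$hazard_multiplier,
                 config$gompertz_rate)
  animals$lifespan_weeks <- flexsurv::rgompertz(
    nrow(animals), shape = config$gompertz_shape, rate = rate)
  animals$event <- 1L

  rows <- list()
  rows[[1]] <- data.frame(animals[c("animal_id", "group", "arm", "exposed",
                                    "sex", "lifespan_weeks", "event")],
                          measurement = "lifespan",
                          week = animals$lifespan_weeks,
                          value = animals$lifespan_weeks)

  # WBC counts: acute dip with recovery in the exposed external-beam group,
  # sustained deficit in the exposed internal-emitter group
  wbc_factor <- function(arm, exposed, w) {
    if (!exposed) return(1)
    if (arm == "HDR") {
      if (w <= config$wbc_recovery_week)
        1 - config$wbc_hdr_dip *
          (config$wbc_recovery_week - w) / (config$wbc_recovery_week - 2)
      else 1
    } else {
      if (w <= config$wbc_deficit_through_week)
        1 - config$wbc_ldr_deficit
      else 1
    }
  }
  sdl <- sqrt(log(1 + config$wbc_cv ^ 2))
  wbc <- do.call(rbind, lapply(seq_len(nrow(animals)), function(i) {
    w <- config$wbc_weeks
    mu <- config$wbc_baseline *
      vapply(w, function(wk) wbc_factor(animals$arm[i],
                                        animals$exposed[i], wk),
             numeric(1))
    data.frame(animals[i, c("animal_id", "group", "arm", "exposed", "sex",
                            "lifespan_weeks", "event")],
               measurement = "WBC", week = w,
               value = stats::rlnorm(length(w), log(mu) - sdl ^ 2 / 2, sdl),
               row.names = NULL)
  }))
  rows[[2]] <- wbc

  # serum markers at the early and late windows
  mk_weeks <- c(config$marker_weeks$early, config$marker_weeks$late)
  is_late <- mk_weeks >= min(config$marker_weeks$late)
  sdm <- config$marker_sdlog
  markers <- do.call(rbind, lapply(names(config$marker_means), function(mk) {
    per_group <- config$marker_means[[mk]]
    do.call(rbind, lapply(seq_len(nrow(animals)), function(i) {
      means <- per_group[[animals$group[i]]]
      if (is.null(means)) return(NULL)   # no marker model for this group
      mu <- means[1 + is_late]
      data.frame(animals[i, c("animal_id", "group", "arm", "exposed", "sex",
                              "lifespan_weeks", "event")],
                 measurement = mk, week = mk_weeks,
                 value = stats::rlnorm(length(mk_weeks),
                                       log(mu) - sdm ^ 2 / 2, sdm),
                 row.names = NULL)
    }))
  }))
  rows[[3]] <- markers

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "seed") <- seed
  out
}

#' Excretion simulation configuration
#'
#' @param days Measurement days post-injection.
#' @param effective_half_life_days True effective half-life driving the
#'   residual decay; the physical half-life of Ca-45 (163 d) corresponds
#'   to biological elimination switched off.
#' @param initial_residual_pct Skeletal retention extrapolated to day 0;
#'   the default is chosen so pure physical decay reproduces a day-3
#'   residual mean of 89.7%.
#' @param uptake_sd Between-animal SD of the retained fraction (persists
#'   across days within an animal), percent points.
#' @param measurement_sd Per-measurement counting noise SD, percent points.
#' @param excreted_mean,excreted_sd Per-day excreted-fraction means and
#'   SDs, percent (defaults: 12.9 (4.7) at day 3, 2.3 (0.7) at day 10).
#' @param replicates Animals per time point (default 3).
#' @return An object of class `excretion_sim_config`.
#' @export
excretion_sim_config <- function(days = c(3, 10),
                                 effective_half_life_days = 163,
                                 initial_residual_pct =
                                   89.7 * 2 ^ (3 / 163),
                                 uptake_sd = 1.4,
                                 measurement_sd = 0.2,
                                 excreted_mean = c(12.9, 2.3),
                                 excreted_sd = c(4.7, 0.7),
                                 replicates = 3) {
  stopifnot(length(days) >= 1, all(diff(days) > 0),
            effective_half_life_days > 0, replicates >= 1,
            length(excreted_mean) == length(days),
            length(excreted_sd) == length(days))
  structure(list(days = days,
                 effective_half_life_days = effective_half_life_days,
                 initial_residual_pct = initial_residual_pct,
                 uptake_sd = uptake_sd, measurement_sd = measurement_sd,
                 excreted_mean = excreted_mean, excreted_sd = excreted_sd,
                 replicates = replicates),
            class = "excretion_sim_config")
}

#' Simulate excretion/retention measurements
#'
#' Generates replicate-level excreted and residual percentages.  Each
#' animal carries a persistent uptake offset (so residual measurements are
#' correlated across days within an animal) plus small per-measurement
#' counting noise; residuals decay with the configured effective
#' half-life.
#'
#' @param config An [excretion_sim_config()].
#' @param seed Integer seed.
#' @return A [retention_data()] whose `excreted`/`residual` components hold
#'   the per-day means and SDs over replicates; replicate-level draws are
#'   attached as attribute `"replicates"`, the seed as `"seed"`.
#' @export
simulate_excretion <- function(config = excretion_sim_config(), seed = 1) {
  stopifnot(inherits(config, "excretion_sim_config"))
  set.seed(seed)
  nd <- length(config$days)
  nr <- config$replicates
  uptake <- stats::rnorm(nr, 0, config$uptake_sd)
  res <- sapply(seq_len(nd), function(j) {
    decay <- 2 ^ (-config$days[j] / config$effective_half_life_days)
    pmin(100, pmax(0, (config$initial_residual_pct + uptake) * decay +
                     stats::rnorm(nr, 0, config$measurement_sd)))
  })
  exc <- sapply(seq_len(nd), function(j)
    pmin(100, pmax(0, stats::rnorm(nr, config$excreted_mean[j],
                                   config$excreted_sd[j]))))
  res <- matrix(res, nrow = nr)
  exc <- matrix(exc, nrow = nr)
  sd0 <- function(x) if (length(x) > 1) stats::sd(x) else 0
  out <- retention_data(
    excreted = data.frame(day = config$days,
                          percent = colMeans(exc),
                          sd = apply(exc, 2, sd0)),
    residual = data.frame(day = config$days,
                          percent = colMeans(res),
                          sd = apply(res, 2, sd0)))
  attr(out, "replicates") <- data.frame(
    animal = rep(seq_len(nr), nd * 2),
    day = rep(rep(config$days, each = nr), 2),
    quantity = rep(c("excreted", "residual"), each = nr * nd),
    percent = c(as.vector(exc), as.vector(res)))
  attr(out, "seed") <- seed
  out
}
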