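#' Excretion/retention measurement set
#'
#' Whole-excreta measurements after a radionuclide injection: per-day mean
#' (and SD) of the percent excreted and the percent remaining in the animal.
#'
#' @param excreted Data frame with columns `day`, `percent`, `sd`
#'   (cumulative percent excreted at each day post-injection), or `NULL`.
#' @param residual Data frame with the same columns for the percent of the
#'   injected activity remaining.
#' @return An object of class `retention_data`.
#' @export
#' @examples
#' ca45_reference_retention()
retention_data <- function(excreted = NULL, residual = NULL) {
  check <- function(df, what) {
    if (is.null(df)) return(NULL)
    stopifnot(is.data.frame(df),
              all(c("day", "percent", "sd") %in% names(df)))
    if (any(df$percent < 0 | df$percent > 100))
      stop(what, " percents must lie in [0, 100]", call. = FALSE)
    if (is.unsorted(df$day, strictly = TRUE))
      stop(what, " days must be strictly increasing", call. = FALSE)
    df
  }
  structure(list(excreted = check(excreted, "excreted"),
                 residual = check(residual, "residual")),
            class = "retention_data")
}

#' Measured Ca-45 excretion/retention reference values
#'
#' Whole-excreta means (SD) from three mice per time point after a Ca-45
#' injection: 12.9% (4.7) excreted by day 3 and a further 2.3% (0.7) by day
#' 10; 89.7% (1.4) residual at day 3 and 87.9% (1.6) at day 10.
#'
#' @return A [retention_data()] object.
#' @export
ca45_reference_retention <- function() {
  retention_data(
    excreted = data.frame(day = c(3, 10), percent = c(12.9, 2.3),
                          sd = c(4.7, 0.7)),
    residual = data.frame(day = c(3, 10), percent = c(89.7, 87.9),
                          sd = c(1.4, 1.6)))
}

#' Is physical decay consistent with the measured retention?
#'
#' Tests whether the decline of the measured residual activity is explained
#' by physical decay alone, i.e. whether biological elimination can be
#' neglected when integrating the internal dose.  Each residual mean after
#' the first is predicted from the first measurement by pure physical decay,
#' `R(t_j) = R(t_1) * 2^(-(t_j - t_1)/T)`; if every prediction lies within
#' one SD of the corresponding measured mean the physical half-life is
#' declared adequate.  An effective half-life is also fitted from the
#' residual means (log-linear regression on day).
#'
#' @param data A [retention_data()] with at least the `residual` component.
#' @param nuclide A [beta_nuclide()] supplying the physical half-life.
#' @return A list with `predictions` (data frame: `day`, `measured`, `sd`,
#'   `predicted`, `within_1sd`), `effective_half_life_days` (NA when fewer
#'   than two residual points), and `decision` (`"use physical half-life"`
#'   or `"biological elimination suspected"`).
#' @export
#' @examples
#' retention_consistency(ca45_reference_retention(), nuclide_ca45())
retention_consistency <- function(data, nuclide) {
  stopifnot(inherits(data, "retention_data"),
            inherits(nuclide, "beta_nuclide"))
  res <- data$residual
  if (is.null(res) || nrow(res) < 1)
    stop("retention data contain no residual measurements", call. = FALSE)
  hl <- nuclide$half_life_days
  if (nrow(res) < 2) {
    warning("single residual point: cannot fit or test; ",
            "returning predictions only")
    return(list(predictions = data.frame(day = res$day,
                                         measured = res$percent,
                                         sd = res$sd,
                                         predicted = res$percent,
                                         within_1sd = NA),
                effective_half_life_days = NA_real_,
                decision = NA_character_))
  }
  pred <- res$percent[1] * 2 ^ (-(res$day - res$day[1]) / hl)
  within <- abs(pred - res$percent) <= res$sd
  # log-linear fit of the residual means -> effective half-life
  fit <- stats::lm(log(percent) ~ day, data = res)
  slope <- stats::coef(fit)[["day"]]
  eff_hl <- if (is.na(slope) || slope >= 0) Inf else -log(2) / slope
  list(predictions = data.frame(day = res$day, measured = res$percent,
                                sd = res$sd, predicted = pred,
                                within_1sd = within),
       effective_half_life_days = eff_hl,
       decision = if (all(within[-1])) "use physical half-life"
                  else "biological elimination suspected")
}
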