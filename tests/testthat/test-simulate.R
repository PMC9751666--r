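test_that("cohort simulation honors group sizes, sex splits and the seed", {
  cfg <- cohort_sim_config()
  coh <- simulate_cohort(cfg, seed = 17)
  an <- unique(coh[c("animal_id", "group", "sex")])
  counts <- table(an$group, an$sex)
  expect_equal(unname(counts["Ctrl_X", c("M", "F")]), c(10, 8))
  expect_equal(unname(counts["X-ray", c("M", "F")]), c(9, 11))
  expect_equal(unname(counts["Ctrl_Ca", c("M", "F")]), c(4, 4))
  expect_equal(unname(counts["Ca-45", c("M", "F")]), c(5, 4))
  expect_identical(attr(coh, "seed"), 17)
  coh2 <- simulate_cohort(cfg, seed = 17)
  expect_identical(coh, coh2)
  expect_false(identical(coh, simulate_cohort(cfg, seed = 18)))
})

test_that("exposed arms live shorter; WBC patterns are transient vs sustained", {
  # average over replicate cohorts so the pattern, not one draw, is tested
  agg <- function(field, seeds = 1:10) {
    res <- lapply(seeds, function(s) {
      coh <- simulate_cohort(cohort_sim_config(), seed = s)
      field(coh)
    })
    Reduce(`+`, res) / length(res)
  }
  med_life <- agg(function(coh) {
    lt <- coh[coh$measurement == "lifespan", ]
    tapply(lt$lifespan_weeks, lt$group, median)
  })
  expect_lt(med_life[["X-ray"]], med_life[["Ctrl_X"]] - 10)
  expect_lt(med_life[["Ca-45"]], med_life[["Ctrl_Ca"]] - 10)
  wbc <- agg(function(coh) {
    w <- coh[coh$measurement == "WBC", ]
    tapply(w$value, list(w$group, w$week), mean)
  })
  # acute-arm dip at week 2 with recovery by week 10
  expect_lt(wbc["X-ray", "2"], 0.6 * wbc["Ctrl_X", "2"])
  expect_gt(wbc["X-ray", "10"], 0.9 * wbc["Ctrl_X", "10"])
  # chronic-arm deficit sustained through week 29
  for (wk in c("2", "10", "22", "29"))
    expect_lt(wbc["Ca-45", wk], 0.85 * wbc["Ctrl_Ca", wk])
})

test_that("null lifespans keep the GBW rejection rate near 5%", {
  cfg <- cohort_sim_config(groups = data.frame(
    group = c("C", "E"), arm = c("LDR", "LDR"),
    exposed = c(FALSE, TRUE), n_male = c(10, 10), n_female = c(10, 10)),
    hazard_multiplier = 1)
  rej <- sapply(1:200, function(s) {
    coh <- simulate_cohort(cfg, seed = s)
    lt <- coh[coh$measurement == "lifespan", ]
    a <- lt[lt$group == "E", ]; b <- lt[lt$group == "C", ]
    gehan_breslow_wilcoxon(a$lifespan_weeks, a$event,
                           b$lifespan_weeks, b$event)$p_value < 0.05
  })
  expect_lt(abs(mean(rej) - 0.05), 0.045)
})

test_that("excretion simulation reproduces the measured calibration envelope", {
  cfg <- excretion_sim_config()
  ex <- simulate_excretion(cfg, seed = 1)
  expect_s3_class(ex, "retention_data")
  # replicate-averaged day-3/day-10 means stay inside 1 SD of the
  # reference values (12.9 (4.7) / 2.3 (0.7) excreted; 89.7 / 87.9 residual)
  means <- Reduce(`+`, lapply(1:20, function(s) {
    d <- simulate_excretion(cfg, seed = s)
    c(d$excreted$percent, d$residual$percent)
  })) / 20
  expect_lt(abs(means[1] - 12.9), 4.7)
  expect_lt(abs(means[2] - 2.3), 0.7)
  expect_lt(abs(means[3] - 89.7), 1.4)
  expect_lt(abs(means[4] - 87.9), 1.6)
  expect_identical(simulate_excretion(cfg, seed = 4),
                   simulate_excretion(cfg, seed = 4))
})

test_that("noise-free excretion follows pure physical decay", {
  cfg <- excretion_sim_config(uptake_sd = 1e-12, measurement_sd = 1e-12)
  ex <- simulate_excretion(cfg, seed = 2)
  expect_equal(ex$residual$percent[2],
               ex$residual$percent[1] * 2 ^ (-7 / 163), tolerance = 1e-9)
})

test_that("physical-decay decision is recovered in almost all simulations", {
  ok <- sapply(1:120, function(s) {
    ex <- simulate_excretion(excretion_sim_config(), seed = s)
    retention_consistency(ex, nuclide_ca45())$decision ==
      "use physical half-life"
  })
  expect_gt(mean(ok), 0.95)
})

test_that("marker trends encode the designed group patterns", {
  # replicate-averaged late/early ratios per group and marker
  cfg <- cohort_sim_config()
  ratios <- Reduce(`+`, lapply(1:10, function(s) {
    coh <- simulate_cohort(cfg, seed = s)
    sapply(c("P1NP", "OPG", "CTX-I", "CCL2", "CXCL1"), function(mk) {
      fc <- fold_change_over_time(coh, mk)
      stats::setNames(fc$ratio, fc$group)[c("Ctrl_X", "X-ray",
                                            "Ctrl_Ca", "Ca-45")]
    })
  })) / 10
  expect_true(all(ratios[, "P1NP"] > 1.05))          # formation up everywhere
  expect_lt(ratios["X-ray", "OPG"], 0.95)            # down in the acute arm
  expect_gt(ratios["Ca-45", "OPG"], 1.05)            # up in the chronic arm
  expect_gt(ratios["X-ray", "CTX-I"], 1.05)          # resorption up...
  expect_lt(abs(ratios["Ca-45", "CTX-I"] - 1), 0.05) # ...except chronic arm
  for (mk in c("CCL2", "CXCL1")) {
    expect_lt(abs(ratios["X-ray", mk] - 1), 0.06)    # inflammation flat (acute)
    expect_gt(ratios["Ca-45", mk], 1.2)              # but rises (chronic)
  }
})

test_that("fold-change summaries report ratio, direction and gate p", {
  cohort <- data.frame(
    group = rep("g", 8), measurement = "M",
    week = c(2, 2, 8, 8, 26, 26, 32, 32),
    value = c(2, 2, 2, 2, 5, 5, 5, 5))
  fc <- fold_change_over_time(cohort, "M")
  expect_equal(fc$ratio, 2.5)
  expect_identical(fc$direction, "up")
  flat <- within(cohort, value <- 3)
  expect_identical(fold_change_over_time(flat, "M")$direction, "flat")
  expect_equal(fold_change_over_time(flat, "M")$ratio, 1.0)
  expect_error(fold_change_over_time(cohort, "missing"), "no measurements")
  expect_error(fold_change_over_time(cohort, "M", late = c(90, 99)),
               "empty late window")
})
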