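# one shared grid run keeps this file inside a few seconds
td_grid <- run_trial_design_grid(ref_victim, ref_phys)
td_metrics <- td_grid$recommendation

test_that("virtual inhibitors hit their potency and half-life classes", {
  scn <- virtual_inhibitor("moderate", "short")
  expect_equal(half_life(scn$params), 4, tolerance = 0.01)
  expect_equal(half_life(virtual_inhibitor("weak", "long")$params), 30,
               tolerance = 0.01)
  # realized steady-state inlet Iu,max / Ki matches the class ratio
  t_end <- scn$regimen$interval * scn$regimen$n_doses
  prof <- simulate_inhibitor_pk(scn$params, scn$regimen, t_end, ref_phys)
  ss <- prof[prof$time_h >= t_end - 24, ]
  expect_equal(max(ss$conc_inlet_unbound_uM) / scn$params$ki[["OATP1B1"]],
               3, tolerance = 0.02)
})

test_that("Cmax ratio dominates AUC ratio, most strongly for short half-lives", {
  expect_true(all(td_metrics$cmax_ratio >= td_metrics$auc_ratio))
  expect_true(all(td_metrics$cmax_ratio > 1 & td_metrics$auc_ratio > 1))
  gap <- function(pot, th) {
    r <- td_metrics[td_metrics$potency_class == pot &
                      td_metrics$t_half_class == th, ]
    r$cmax_ratio - r$auc_ratio
  }
  expect_gt(gap("strong", "short"), gap("strong", "long"))
  # strong/short: the peak markedly exceeds the day-average interaction
  strong_short <- td_metrics[td_metrics$potency_class == "strong" &
                               td_metrics$t_half_class == "short", ]
  expect_gt(strong_short$cmax_ratio / strong_short$auc_ratio, 1.2)
})

test_that("zero-dose scenario is a null interaction", {
  scn <- virtual_inhibitor("weak", "short")
  scn$regimen$dose <- 0
  res <- simulate_scenario(scn, ref_victim, ref_phys)
  expect_equal(res$metrics$cmax_ratio, 1, tolerance = 5e-3)
  expect_equal(res$metrics$auc_ratio, 1, tolerance = 5e-3)
})

test_that("steady-state certification is idempotent under regimen extension", {
  scn <- virtual_inhibitor("moderate", "short")
  res <- simulate_scenario(scn, ref_victim, ref_phys)
  longer <- scn
  longer$regimen$n_doses <- scn$regimen$n_doses + 3
  res2 <- simulate_scenario(longer, ref_victim, ref_phys)
  expect_equal(res2$metrics$cmax_ratio, res$metrics$cmax_ratio,
               tolerance = 5e-3)
  expect_equal(res2$metrics$auc_ratio, res$metrics$auc_ratio,
               tolerance = 5e-3)

  short_reg <- virtual_inhibitor("strong", "long")
  short_reg$regimen$n_doses <- 2
  expect_error(simulate_scenario(short_reg, ref_victim, ref_phys),
               class = "coprokin_invalid_parameter")
})

test_that("sparse sampling is exact at Tmax and degrades away from it", {
  res <- td_grid$results[[which(td_metrics$potency_class == "strong" &
                                  td_metrics$t_half_class == "short")]]
  tmax <- res$metrics$tmax_h
  at_tmax <- sparse_sampling_cmaxr(res, tmax)
  expect_lt(abs(at_tmax$deviation_pct), 1e-4)

  before <- sparse_sampling_cmaxr(res, sort(pmax(tmax - c(2, 1, 0.5), 0.05)))
  expect_true(all(diff(before$deviation_pct) <= 0)) # closer -> smaller error
  after <- sparse_sampling_cmaxr(res, tmax + c(2, 4, 8))
  expect_true(all(diff(after$deviation_pct) >= 0)) # further -> larger error
  expect_true(all(c(before$deviation_pct, after$deviation_pct) >= 0))

  expect_error(sparse_sampling_cmaxr(res, -1),
               class = "coprokin_invalid_parameter")
})

test_that("metric recommendation encodes the design rule set", {
  rec <- td_grid$recommendation
  row <- function(pot, th) rec[rec$potency_class == pot &
                                 rec$t_half_class == th, ]
  ss <- row("strong", "short")
  expect_equal(ss$required_dosing, "single dose")
  expect_equal(ss$recommended_metric, "CmaxR")
  expect_true(ss$tmax_sensitive)

  ws <- row("weak", "short")
  expect_equal(ws$required_dosing, "single dose")
  expect_equal(ws$recommended_metric, "CmaxR and AUCR")
  expect_false(ws$tmax_sensitive)

  sl <- row("strong", "long")
  expect_equal(sl$required_dosing, "multiple dose")
  expect_equal(sl$recommended_metric, "CmaxR and AUCR")

  expect_error(recommend_metric(rec[rec$t_half_class == "short", ]),
               class = "coprokin_invalid_parameter")
})
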