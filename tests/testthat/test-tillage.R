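test_that("effect classification follows the sign truth table exhaustively", {
  cases <- tidyr::expand_grid(
    variable = c("yield", "ghg", "ghgi"),
    d = c(0.1, -0.1)
  )
  want <- c(yield.pos = "PE", yield.neg = "NE",
            ghg.pos = "NE", ghg.neg = "PE",
            ghgi.pos = "NE", ghgi.neg = "PE")
  got <- purrr::pmap_chr(cases, effect_classify)
  expect_equal(got, unname(want[paste0(cases$variable,
                                       ifelse(cases$d > 0, ".pos", ".neg"))]))
  # zero difference is neutral for every variable
  expect_true(all(is.na(sapply(c("yield", "ghg", "ghgi"), function(v)
    effect_classify(0, v)))))
  expect_equal(effect_classify(0.1, "eghg"), "NE") # alias of ghg
})

test_that("positive-effect frequency excludes neutral windows", {
  expect_equal(positive_effect_frequency(rep("PE", 10)), 1)
  expect_equal(positive_effect_frequency(c(rep("PE", 30), rep("NE", 10))), 0.75)
  # neutral windows leave both numerator and denominator
  expect_equal(positive_effect_frequency(c("PE", "PE", NA, NA, "NE")), 2 / 3)
  expect_true(is.na(positive_effect_frequency(c(NA_character_, NA))))
})

test_that("recommendation decision table is exact at the strict boundary", {
  expect_equal(recommend_tillage(0.80, 0.60), "NT")
  expect_equal(recommend_tillage(0.60, 0.80), "CT")
  expect_equal(recommend_tillage(0.75, 0.75), "none") # strict >
  expect_equal(recommend_tillage(0.90, 0.80), "NT")
  expect_equal(recommend_tillage(0.80, 0.90), "CT")
  expect_equal(recommend_tillage(0.80, 0.80), "NT") # tie toward NT
  expect_equal(recommend_tillage(0.80, 0.80, tie = "CT"), "CT")
  expect_equal(recommend_tillage(0.5, NA), "none")
  expect_equal(recommend_tillage(NA, 0.9), "CT")
  # monotone: raising the qualifying frequency never flips away from it
  grid <- seq(0.76, 1, by = 0.02)
  expect_true(all(recommend_tillage(grid, 0.7) == "NT"))
  expect_true(all(recommend_tillage(pmax(grid, 0.9), 0.76) == "NT"))
})

# Shared fixture: sensitivity fields for actual/NT/CT on the tiny grid.
tiny_tillage_fields <- function(cfg = tiny_config()) {
  edh <- compute_edh_field(generate_daily_climate(cfg))
  lapply(c(actual = "S2", nt = "S12", ct = "S13"), function(s) {
    edh_sensitivity(edh, ghg_intensity(generate_scenario_outputs(edh, cfg, s)),
                    window = 20)
  })
}

test_that("tillage effects difference the aligned fields with labels", {
  f <- tiny_tillage_fields()
  eff <- tillage_effects(f$actual, f$nt, "NT")
  joined <- dplyr::inner_join(
    f$actual, dplyr::rename(f$nt, r_nt = r),
    by = c("cell", "lat", "lon", "window_end_year", "edh_index", "response",
           "method", "dataset_variant")
  )
  expect_equal(eff$d, joined$r_nt - joined$r)
  # the NT counterfactual only touches the CO2 flux, so yield sensitivity is
  # untouched: every yield window is neutral
  yield_rows <- eff$response == "yield"
  expect_true(all(eff$d[yield_rows] == 0))
  expect_true(all(is.na(eff$label[yield_rows])))
  for (resp in c("eghg", "ghgi")) {
    rows <- eff$response == resp & !is.na(eff$d) & eff$d != 0
    expect_gt(sum(rows), 0)
    expect_equal(eff$label[rows], ifelse(eff$d[rows] > 0, "NE", "PE"))
  }
  expect_error(tillage_effects(f$actual, f$nt[-(1:5), ], "NT"),
               class = "edhwheat_input_error")
})

test_that("recommendation map aggregates frequencies cell by cell", {
  f <- tiny_tillage_fields()
  map <- recommendation_map(f$actual, f$nt, f$ct, threshold = 0.75)
  expect_s3_class(map, "edh_recommendation")
  expect_setequal(unique(map$edh_index), c("hc", "dc", "cdhc", "consensus"))
  # brute-force one cell/index against the primitives
  eff_nt <- tillage_effects(f$actual, f$nt, "NT")
  one <- eff_nt[eff_nt$cell == 3 & eff_nt$edh_index == "hc" &
                  eff_nt$response == "ghgi", ]
  want_freq <- positive_effect_frequency(one$label)
  row <- map[map$cell == 3 & map$edh_index == "hc", ]
  expect_equal(row$freq_nt, want_freq)
  expect_equal(row$recommendation,
               recommend_tillage(row$freq_nt, row$freq_ct, 0.75))
  # invariants: a recommendation implies a qualifying frequency;
  # full mitigation implies frequency one
  per <- map[map$edh_index != "consensus", ]
  rec <- per[per$recommendation != "none", ]
  expect_true(all(pmax(rec$freq_nt, rec$freq_ct, na.rm = TRUE) > 0.75))
  full <- per[per$full_mitigation, ]
  expect_true(all(ifelse(full$recommendation == "NT",
                         full$freq_nt, full$freq_ct) == 1))
})

test_that("applying a recommendation map is cellwise and idempotent", {
  f <- tiny_tillage_fields()
  map <- recommendation_map(f$actual, f$nt, f$ct)
  # degenerate maps
  none_map <- dplyr::mutate(map, recommendation = "none")
  expect_equal(apply_recommendation(f$actual, f$nt, f$ct, none_map)$r,
               f$actual$r)
  nt_map <- dplyr::mutate(map, recommendation = "NT")
  got_nt <- apply_recommendation(f$actual, f$nt, f$ct, nt_map)
  joined <- dplyr::inner_join(
    got_nt, dplyr::rename(f$nt, r_nt = r),
    by = c("cell", "lat", "lon", "window_end_year", "edh_index", "response",
           "method", "dataset_variant")
  )
  expect_equal(joined$r, joined$r_nt)
  # mixed map: cellwise oracle
  opt <- apply_recommendation(f$actual, f$nt, f$ct, map)
  rec <- map[map$edh_index != "consensus", ]
  for (i in sample(nrow(rec), 10)) {
    pickf <- switch(rec$recommendation[i], NT = f$nt, CT = f$ct, f$actual)
    sel <- opt$cell == rec$cell[i] & opt$edh_index == rec$edh_index[i]
    expect_equal(opt$r[sel], pickf$r[sel])
  }
  # idempotence
  opt2 <- apply_recommendation(opt, f$nt, f$ct, map)
  expect_equal(opt2$r, opt$r)
})

test_that("sensitivity reduction arithmetic matches the stated formula", {
  f <- tiny_tillage_fields()
  map <- recommendation_map(f$actual, f$nt, f$ct)
  # no change: zero reduction
  zero <- sensitivity_reduction(f$actual, f$actual, map)
  expect_true(all(zero$reduction_pct[!is.na(zero$reduction_pct)] == 0))
  # constant 10% drop of the median in every window
  rec_cells <- unique(map$cell[map$recommendation != "none" &
                                 map$edh_index != "consensus"])
  expect_gt(length(rec_cells), 0) # injected benefits must surface even here
  shrunk <- dplyr::mutate(f$actual, r = r * 0.9)
  red <- sensitivity_reduction(f$actual, shrunk, map)
  med_sign <- f$actual |>
    dplyr::filter(response == "ghgi") |>
    dplyr::semi_join(map[map$recommendation != "none" &
                           map$edh_index != "consensus", c("cell", "edh_index")],
                     by = c("cell", "edh_index")) |>
    dplyr::group_by(edh_index, window_end_year) |>
    dplyr::summarise(m = median(r, na.rm = TRUE), .groups = "drop") |>
    dplyr::group_by(edh_index) |>
    dplyr::summarise(mean_sign = mean(sign(m)))
  # when every window median is positive the scaling is exactly +10%
  pos <- med_sign$edh_index[med_sign$mean_sign == 1]
  expect_equal(red$reduction_pct[red$edh_index %in% pos],
               rep(10, length(pos)), tolerance = 1e-10)
  expect_named(glance(red),
               c("mean_reduction_pct", "min_reduction_pct",
                 "max_reduction_pct", "n_indices"))
})

test_that("effect trajectories recover injected drift in the differences", {
  # longer record: six moving windows, enough for a trend
  f <- tiny_tillage_fields(synthetic_config(n_lat = 2, n_lon = 2,
                                            years = c(1994, 2018), seed = 42L))
  eff <- tillage_effects(f$actual, f$nt, "NT")
  # constant difference: zero slope
  const <- dplyr::mutate(eff, d = 0.1, label = "PE")
  traj <- effect_trajectory(const)
  expect_true(all(abs(traj$slope) < 1e-12))
  expect_true(all(traj$status == "PE"))
  # injected linear drift is recovered
  drift <- eff |>
    dplyr::group_by(cell, edh_index, response) |>
    dplyr::mutate(d = 0.01 * (window_end_year - min(window_end_year)),
                  label = "NE") |>
    dplyr::ungroup()
  traj2 <- effect_trajectory(drift)
  expect_equal(traj2$slope, rep(0.01, nrow(traj2)), tolerance = 1e-10)
})
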