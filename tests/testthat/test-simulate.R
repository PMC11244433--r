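test_that("generator reproduces the field design scale and is seed-deterministic", {
  d <- generate_dataset(scenario_presets("paper-like", seed = 11))
  expect_equal(nrow(d$plots), 20)  # 5 treatments x 4 replicates
  expect_equal(unique(d$plots$treatment),
               c("CK", "N2.5", "N5", "N10", "N20"))
  expect_setequal(d$trait_cols, c("H", "LA", "LDMC", "SLA"))
  # ~6 species x ~8 individuals x 20 plots, minus species lost at high N
  expect_gt(nrow(d$traits), 800)
  expect_lte(nrow(d$traits), 960)
  expect_true(all(d$traits$H > 0 & d$traits$SLA > 0))
  expect_true(validate_dataset(d$traits, d$composition, d$plots)$is_valid)

  d2 <- generate_dataset(scenario_presets("paper-like", seed = 11))
  expect_identical(d, d2)
  d3 <- generate_dataset(scenario_presets("paper-like", seed = 12))
  expect_false(identical(d3$traits$H, d$traits$H))

  # byte-identical CSVs from the same seed
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  write_tables(d, dir1); write_tables(d2, dir2)
  for (f in c("traits.csv", "composition.csv", "plots.csv")) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
  }
})

test_that("species loss removes species from both composition and traits", {
  d <- generate_dataset(scenario_presets("paper-like", seed = 4))
  n_sp <- tapply(d$composition$species_id, d$composition$plot_id, length)
  expect_lt(min(n_sp), 6)  # the rare species drops out at high N
  expect_equal(max(n_sp), 6)
  ck <- paste(d$composition$plot_id, d$composition$species_id)
  tk <- unique(paste(d$traits$plot_id, d$traits$species_id))
  expect_setequal(ck, tk)
  sums <- tapply(d$composition$relative_biomass, d$composition$plot_id, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("noise-free, shift-free generation zeroes every intraspecific signal", {
  cfg <- synthetic_config(noise_sd = c(H = 0, LA = 0, LDMC = 0, SLA = 0),
                          seed = 1, scenario = "null")
  d <- generate_dataset(cfg)
  w <- within_community_indices(d$traits, d$composition, d$plots)
  expect_true(all(w$witv_intra == 0))
  cm <- community_means(d$traits, d$composition, d$plots)
  expect_true(all(abs(cm$intra) < 1e-12))
})

test_that("plasticity-only design keeps the fixed component constant across plots", {
  cfg <- scenario_presets("plasticity-only", seed = 8)
  d <- generate_dataset(cfg)
  cm <- community_means(d$traits, d$composition, d$plots)
  cwm_fixed <- cm$fixed[cm$scheme == "cwm"]
  by_trait <- split(cwm_fixed, cm$trait[cm$scheme == "cwm"])
  for (v in by_trait) expect_lt(diff(range(v)), 1e-9)
})

test_that("hierarchical seeding isolates species streams", {
  cfg <- scenario_presets("composition-only", seed = 21)
  d <- generate_dataset(cfg)
  # removing the rarest species from the pool leaves the others' draws intact
  cfg2 <- cfg
  cfg2$species <- cfg$species[1:5, ]
  cfg2$abundance_multipliers <- cfg$abundance_multipliers[1:5, ]
  cfg2$trait_shifts <- lapply(cfg$trait_shifts, function(m) m[1:5, ])
  d2 <- generate_dataset(cfg2)
  a <- d$traits[d$traits$species_id != "sp6", ]
  expect_equal(d2$traits$H, a$H)
  expect_equal(d2$traits$SLA, a$SLA)
})

test_that("ANPP regression recovers the configured coefficients at zero noise", {
  cfg <- scenario_presets("composition-only", seed = 13)
  cfg$anpp$noise_sd <- 0
  cfg$dirichlet_jitter <- 100  # per-plot composition spread -> full-rank design
  d <- generate_dataset(cfg)
  truth <- tidyr::pivot_wider(d$ground_truth$true_cwm,
                              id_cols = "plot_id", names_from = "trait",
                              values_from = "true_cwm_specific")
  df <- dplyr::left_join(d$plots, truth, by = "plot_id")
  fit <- stats::lm(anpp ~ H + LA + LDMC + SLA, data = df)
  expect_equal(unname(coef(fit)["(Intercept)"]), cfg$anpp$intercept,
               tolerance = 1e-8)
  expect_equal(unname(coef(fit)[c("H", "LA", "LDMC", "SLA")]),
               unname(cfg$anpp$coefficients[c("H", "LA", "LDMC", "SLA")]),
               tolerance = 1e-8)
})

test_that("dirichlet jitter adds replicate-level composition noise only when asked", {
  cfg <- scenario_presets("composition-only", seed = 17)
  d <- generate_dataset(cfg)
  # deterministic default: replicates of a treatment share abundances
  ab <- d$ground_truth$abundances
  ck <- ab[ab$treatment == "CK", ]
  expect_equal(ck$relative_abundance[ck$plot_id == "CK-1"],
               ck$relative_abundance[ck$plot_id == "CK-2"])
  cfg$dirichlet_jitter <- 200
  dj <- generate_dataset(cfg)
  abj <- dj$ground_truth$abundances
  ckj <- abj[abj$treatment == "CK", ]
  expect_false(isTRUE(all.equal(
    ckj$relative_abundance[ckj$plot_id == "CK-1"],
    ckj$relative_abundance[ckj$plot_id == "CK-2"]
  )))
})

test_that("config validation rejects impossible settings", {
  expect_error(scenario_presets("no-such-preset"), "arg")
  expect_error(synthetic_config(noise_sd = c(H = -1, LA = 1, LDMC = 1,
                                             SLA = 1)))
  cfg <- scenario_presets("paper-like", seed = 1)
  cfg$loss_threshold <- 0.9
  expect_error(generate_dataset(cfg), "empty")
})
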