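test_that("baseline width curve hits its landmarks, stays positive, and is symmetric when configured so", {
  b <- generator_config()$baseline
  expect_equal(baseline_width_curve(0.5), b$body, tolerance = 1e-3)
  tt <- seq(0, 1, by = 1e-4)
  expect_true(all(baseline_width_curve(tt) > 0))
  bs <- b; bs$splenium <- bs$genu; bs$splenium_center <- 1 - bs$genu_center
  expect_equal(baseline_width_curve(tt, bs), baseline_width_curve(1 - tt, bs),
               tolerance = 1e-9)
  # thick genu / thin body / thick splenium ordering
  expect_gt(baseline_width_curve(0.1), baseline_width_curve(0.5))
  expect_gt(baseline_width_curve(0.9), baseline_width_curve(0.5))
})

test_that("effect profile peaks at 1.47 mm at centile 63 and is zero off-range", {
  d <- effect_profile(generator_config())
  expect_equal(max(abs(d)), 1.47)
  expect_equal(which.max(abs(d)), 63L)
  expect_true(all(d <= 0))                       # thinning
  expect_true(all(d[30:50] == 0))
  expect_true(all(d[c(1:7, 16:60, 71:99)] == 0))
  # halving the peak halves the profile
  cfg <- generator_config()
  cfg$effect[[2]]$peak <- cfg$effect[[2]]$peak / 2
  expect_equal(min(effect_profile(cfg)[61:70]), -1.47 / 2)
  bad <- generator_config()
  bad$effect[[1]]$at <- 20L
  expect_error(effect_profile(bad), class = "ccmorph_bad_effect")
})

test_that("cohort generation is seed-deterministic and respects the degenerate limit", {
  cfg <- generator_config(seed = 11)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$widths, c2$widths)
  expect_identical(c1$age, c2$age)

  quiet <- generator_config(regional_sd = 0, end_factor_sd = 0,
                            global_scale_sd = 0, noise_sd = 0,
                            effect = list(), seed = 1)
  co <- generate_cohort(quiet)
  base <- baseline_width_curve((1:99) / 100)
  expect_equal(unname(co$widths[1, ]), base, tolerance = 1e-12)
  expect_equal(unname(co$widths[26, ]), base, tolerance = 1e-12)
})

test_that("the empirical mean group difference converges to the effect profile", {
  cfg <- generator_config(n_case = 2000L, n_control = 2000L, seed = 5)
  co <- suppressWarnings(generate_cohort(cfg))
  diff <- colMeans(co$widths[co$group == "case", ]) -
          colMeans(co$widths[co$group == "control", ])
  expect_lt(max(abs(diff - effect_profile(cfg))), 0.1)
})

test_that("excessive noise triggers the clipping guard", {
  cfg <- generator_config(noise_sd = 6, seed = 2)
  expect_error(generate_cohort(cfg), class = "ccmorph_noise_too_large")
})

test_that("ages are matched within half a year across pairs", {
  co <- generate_cohort(generator_config(seed = 3))
  a_case <- co$age[co$group == "case"][order(co$pairing[co$group == "case"])]
  a_ctrl <- co$age[co$group == "control"][order(co$pairing[co$group == "control"])]
  expect_true(all(abs(a_case - a_ctrl) <= 0.5))
  expect_true(all(a_case >= 1 & a_case <= 15))
})

test_that("rendered masks round-trip through the geometry module", {
  prof <- extract_widths(render_mask(rep(10, 99)))
  expect_true(all(abs(prof$widths[5:95] - 10) <= 0.5))

  wb <- baseline_width_curve((1:99) / 100)
  back <- extract_widths(render_mask(wb))
  expect_true(all(abs(back$widths[5:95] - wb[5:95]) <= 0.5))
})

test_that("straight-axis render of a constant profile is a rectangle up to the tip wedges", {
  prof <- extract_widths(render_mask(rep(10, 99), radius_mm = Inf, length_mm = 80))
  expect_equal(prof$area, 800, tolerance = 0.02)
  expect_true(all(abs(prof$widths[5:95] - 10) <= 0.5))
})

test_that("a sweep that would fold over is rejected", {
  expect_error(render_mask(rep(70, 99), radius_mm = 30),
               class = "ccmorph_sweep_fold")
})

test_that("per-subject rendered cohort masks are reproducible from the seed", {
  cfg <- generator_config(seed = 21)
  w1 <- generate_cohort(cfg)$widths[1, ]
  m1 <- render_mask(w1)
  m2 <- render_mask(generate_cohort(cfg)$widths[1, ])
  expect_identical(m1$grid, m2$grid)
})
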