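# Stage counts, V1 bounds, rounding convention and ratios.

test_that("point-mode surface is area times magnification and linear in area", {
  stim <- stimulus_spec(1, 3)
  expect_equal(cortical_surface(stim), ORACLE$M3, tolerance = 1e-12)
  expect_identical(cortical_surface(stimulus_spec(0, 3)), 0)
  for (k in c(0.25, 2, 4, 7.5))
    expect_equal(cortical_surface(stimulus_spec(k, 3)),
                 k * cortical_surface(stim), tolerance = 1e-12)
})

test_that("integrated-mode surface matches a Riemann-sum oracle and converges to point mode", {
  model <- default_models()$v1_magnification
  s11 <- cortical_surface(stimulus_spec(1, 3, 1, 1), mode = "integrated")
  expect_equal(s11, riemann_surface(model, 3, 1, 1), tolerance = 1e-8)
  # a 1x1 deg^2 band stays within 5% of the point evaluation
  expect_lt(abs(s11 - ORACLE$M3) / ORACLE$M3, 0.05)
  # shrinking extent converges to point mode
  h <- 1e-4
  tiny <- cortical_surface(stimulus_spec(h^2, 3, h, h), mode = "integrated")
  expect_equal(tiny, h^2 * ORACLE$M3, tolerance = 1e-6)
  expect_error(cortical_surface(stimulus_spec(1, 3), mode = "banana"), "mode")
  # band extending below the fovea is refused
  expect_error(cortical_surface(stimulus_spec(4, 0.5, 2, 2), mode = "integrated"),
               "below 0")
})

test_that("effective depth is laminar depth times excitatory fraction", {
  expect_equal(effective_depth(anatomy_params()), 0.6, tolerance = 1e-12)
  expect_equal(effective_depth(anatomy_params(excitatory_fraction = 1)), 0.75)
  expect_equal(effective_depth(anatomy_params(laminar_depth = 1,
                                              excitatory_fraction = 0.5)), 0.5)
})

test_that("half-up rounding matches the integer-arithmetic oracle and is idempotent", {
  cases <- data.frame(
    value = c(148500, 9195.062, 6666.667, 4.8499, 2.90994, 155000, 144042,
              9500, 250, 0, 123456.78),
    grain = c(10000, 1000, 500, 1, 1, 10000, 10000, 1000, 500, 1000, 1)
  )
  for (i in seq_len(nrow(cases))) {
    got <- round_paper_style(cases$value[i], cases$grain[i])
    expect_equal(got, round_half_up_oracle(cases$value[i], cases$grain[i]))
    expect_equal(round_paper_style(got, cases$grain[i]), got)  # idempotence
  }
  # frozen reference points
  expect_identical(round_paper_style(148500, 10000), 150000)
  expect_identical(round_paper_style(9195, 1000), 9000)
  # ties go up
  expect_identical(round_paper_style(5000, 10000), 10000)
  expect_error(round_paper_style(100, -1), "grain")
  expect_error(round_paper_style(-5, 10), "nonnegative")
})

test_that("V1 bounds reproduce both the raw chain and the rounded-intermediate chain", {
  stim <- stimulus_spec(1, 3)
  expect_equal(v1_upper(stim), ORACLE$V1_RAW, tolerance = 1e-12)
  expect_identical(v1_upper(stim, rounded = TRUE), 360000)
  expect_identical(v1_lower_tuned(stim, rounded = TRUE), 270000)
  expect_identical(v1_lower_loose(stim, rounded = TRUE), 150000)
  expect_equal(v1_lower_tuned(stim), 0.75 * ORACLE$V1_RAW, tolerance = 1e-12)
  expect_equal(v1_lower_loose(stim), 0.75 * 0.55 * ORACLE$V1_RAW, tolerance = 1e-12)
  # degenerate fractions collapse the bounds
  p1 <- anatomy_params(tuned_fraction = 1, responsive_fraction = 1)
  expect_equal(v1_lower_tuned(stim, params = p1), v1_upper(stim, params = p1))
  expect_equal(v1_lower_loose(stim, params = p1), v1_upper(stim, params = p1))
  p0 <- anatomy_params(tuned_fraction = 0)
  expect_identical(v1_lower_tuned(stim, params = p0), 0)
})

test_that("bound ordering holds across sampled fractions", {
  stim <- stimulus_spec(1.7, 2.6)
  set.seed(42)
  for (i in 1:50) {
    p <- anatomy_params(tuned_fraction = runif(1), responsive_fraction = runif(1))
    up <- v1_upper(stim, params = p)
    lt <- v1_lower_tuned(stim, params = p)
    ll <- v1_lower_loose(stim, params = p)
    expect_true(ll <= lt && lt <= up)
    expect_true(ll >= 0)
  }
})

test_that("LGN and RGC counts follow area times density", {
  stim <- stimulus_spec(1, 3)
  lgn <- lgn_count(stim)
  expect_equal(lgn[["parvo"]], ORACLE$NP3, tolerance = 1e-12)
  expect_equal(lgn[["magno"]], ORACLE$NM3, tolerance = 1e-12)
  expect_equal(lgn[["total"]], lgn[["parvo"]] + lgn[["magno"]])
  expect_equal(round_paper_style(lgn[["total"]], 1000), 9000)
  expect_identical(lgn_count(stimulus_spec(0, 3)),
                   c(parvo = 0, magno = 0, total = 0))
  expect_equal(rgc_count(stim), ORACLE$RGC3, tolerance = 1e-12)
  expect_equal(round_paper_style(rgc_count(stim), 500), 6500)
  expect_identical(rgc_count(stimulus_spec(1, 2)), 8500)
  expect_error(rgc_count(stimulus_spec(1, 10)), "anchor range")
  # linearity in area
  expect_equal(rgc_count(stimulus_spec(3, 3)), 3 * ORACLE$RGC3, tolerance = 1e-12)
  expect_equal(lgn_count(stimulus_spec(2, 3))[["total"]], 2 * ORACLE$LGN_RAW,
               tolerance = 1e-12)
})

test_that("estimate_pathway populates raw and rounded fields consistently", {
  est <- estimate_pathway()
  expect_s3_class(est, "pathway_estimate")
  expect_named(est$raw, c("v1_surface", "v1_effective_depth", "v1_volume",
                          "v1_upper", "v1_lower_tuned", "v1_lower_loose",
                          "lgn_parvo", "lgn_magno", "lgn_total", "rgc"))
  expect_named(est$rounded, names(est$raw))
  expect_true(all(est$raw >= 0))
  expect_equal(est$raw[["lgn_total"]], est$raw[["lgn_parvo"]] + est$raw[["lgn_magno"]])
  # fields not subject to the rounded-intermediate chain round directly from raw
  g <- est$config$rounding
  expect_equal(est$rounded[["v1_surface"]], round_paper_style(est$raw[["v1_surface"]], g$surface))
  expect_equal(est$rounded[["lgn_parvo"]], round_paper_style(est$raw[["lgn_parvo"]], g$lgn))
  expect_equal(est$rounded[["lgn_magno"]], round_paper_style(est$raw[["lgn_magno"]], g$lgn))
  expect_equal(est$rounded[["lgn_total"]], round_paper_style(est$raw[["lgn_total"]], g$lgn))
  expect_equal(est$rounded[["rgc"]], round_paper_style(est$raw[["rgc"]], g$rgc))
  # the V1 chain instead propagates rounded intermediates
  expect_equal(est$rounded[["v1_volume"]],
               round_paper_style(est$rounded[["v1_surface"]] * est$raw[["v1_effective_depth"]], g$volume))
  expect_equal(est$rounded[["v1_upper"]],
               round_paper_style(est$rounded[["v1_volume"]] * est$config$v1$density, g$v1))
})

test_that("estimate_pathway is deterministic and linear in stimulus scalars", {
  a <- estimate_pathway()
  b <- estimate_pathway()
  expect_identical(a$raw, b$raw)
  expect_identical(a$rounded, b$rounded)
  expect_identical(unclass(a$ratios), unclass(b$ratios))
  # doubling cortical density doubles the raw V1 counts only
  cfg2 <- config_set(default_config(), "v1.density", 240000)
  est2 <- estimate_pathway(cfg2)
  for (k in c("v1_upper", "v1_lower_tuned", "v1_lower_loose"))
    expect_equal(est2$raw[[k]], 2 * a$raw[[k]], tolerance = 1e-12)
  expect_equal(est2$raw[["lgn_total"]], a$raw[["lgn_total"]])
  expect_equal(est2$raw[["rgc"]], a$raw[["rgc"]])
  # doubling area doubles every raw stage count in point mode
  cfga <- config_set(default_config(), "stimulus.area", 2)
  esta <- estimate_pathway(cfga)
  for (k in c("v1_surface", "v1_volume", "v1_upper", "v1_lower_tuned",
              "v1_lower_loose", "lgn_parvo", "lgn_magno", "lgn_total", "rgc"))
    expect_equal(esta$raw[[k]], 2 * a$raw[[k]], tolerance = 1e-12)
})

test_that("expansion ratios divide rounded counts and error on zero stages", {
  est <- estimate_pathway()
  r <- expansion_ratios(est)
  expect_identical(unclass(r), unclass(est$ratios))
  expect_equal(r[["lgn_v1_high"]],
               round_paper_style(est$rounded[["v1_upper"]] / est$rounded[["lgn_total"]], 1))
  expect_equal(r[["rgc_v1_low"]],
               round_paper_style(est$rounded[["v1_lower_loose"]] / est$rounded[["rgc"]], 1))
  expect_true(r[["lgn_v1_low"]] <= r[["lgn_v1_high"]])
  expect_true(r[["rgc_v1_low"]] <= r[["rgc_v1_high"]])
  # stage counts equal to the V1 counts give ratio 1
  fake <- est
  fake$rounded[c("lgn_total", "rgc")] <- fake$rounded[["v1_upper"]]
  fake$rounded[["v1_lower_loose"]] <- fake$rounded[["v1_upper"]]
  r1 <- expansion_ratios(fake)
  expect_true(all(unclass(r1) == 1))
  # zero stage count is an error
  zero <- est
  zero$rounded[["lgn_total"]] <- 0
  expect_error(expansion_ratios(zero), "undefined")
})

test_that("zero-area stimulus yields zero counts and undefined ratios", {
  cfg <- config_set(default_config(), "stimulus.area", 0)
  expect_warning(est <- estimate_pathway(cfg), "undefined")
  counts <- est$raw[setdiff(names(est$raw), "v1_effective_depth")]
  expect_true(all(counts == 0))
  expect_null(est$ratios)
})

test_that("partial mode reports V1 and LGN when the RGC stage is out of range", {
  cfg <- config_set(default_config(), "stimulus.eccentricity", 10)
  expect_error(estimate_pathway(cfg), "anchor range")
  warns <- character()
  est <- withCallingHandlers(
    estimate_pathway(cfg, partial = TRUE),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  expect_match(warns, "RGC stage", all = FALSE)
  expect_true(is.na(est$raw[["rgc"]]))
  expect_true(est$raw[["v1_upper"]] > 0 && est$raw[["lgn_total"]] > 0)
  expect_true(is.na(est$ratios[["rgc_v1_high"]]))
  expect_false(is.na(est$ratios[["lgn_v1_high"]]))
})

test_that("stimulus and anatomy constructors enforce their invariants", {
  expect_error(stimulus_spec(-1, 3), "area")
  expect_error(stimulus_spec(1, -3), ">= 0")
  expect_error(stimulus_spec(1, 3, width = 2), "both")
  expect_error(stimulus_spec(1, 3, width = 2, height = 2), "equal area")
  expect_silent(stimulus_spec(4, 3, width = 2, height = 2))
  expect_error(anatomy_params(tuned_fraction = 1.2), "fraction")
  expect_error(anatomy_params(laminar_depth = 0), "laminar_depth")
})
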