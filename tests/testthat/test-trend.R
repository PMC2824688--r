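test_that("fit_linear_trend recovers collinear and constant inputs exactly", {
  tr <- fit_linear_trend(1998:2000, c(0.10, 0.09, 0.08))
  expect_equal(tr$slope, -0.01, tolerance = 1e-12)
  expect_equal(tr$level, 0.08, tolerance = 1e-12)
  expect_identical(tr$reference_year, 2000L)

  flat <- fit_linear_trend(1998:2000, c(0.05, 0.05, 0.05))
  expect_equal(flat$slope, 0, tolerance = 1e-15)
  expect_equal(flat$level, 0.05, tolerance = 1e-15)

  # any collinear triple is reproduced with zero residuals
  set.seed(11)
  for (i in 1:20) {
    a <- runif(1, 0.2, 0.5)
    b <- runif(1, -0.05, 0.05)
    y <- a + b * (0:2)
    tr_i <- fit_linear_trend(1998:2000, y)
    expect_equal(tr_i$slope, b, tolerance = 1e-12)
    expect_equal(tr_i$level, y[3], tolerance = 1e-12)
  }
})

test_that("fit_linear_trend matches the lm() least-squares fit on noisy points", {
  y <- c(0.10, 0.10, 0.07)
  tr <- fit_linear_trend(1998:2000, y)
  expect_equal(tr$slope, -0.015, tolerance = 1e-12)
  fit <- lm(y ~ x, data = data.frame(x = 1998:2000, y = y))
  expect_equal(tr$slope, unname(coef(fit)[2]), tolerance = 1e-12)
  expect_equal(tr$level,
               unname(predict(fit, data.frame(x = 2000))), tolerance = 1e-12)

  set.seed(7)
  for (i in 1:10) {
    yy <- runif(3, 0.01, 0.4)
    tr_i <- fit_linear_trend(1998:2000, yy)
    fit_i <- lm(yy ~ x, data = data.frame(x = 1998:2000))
    expect_equal(tr_i$slope, unname(coef(fit_i)[2]), tolerance = 1e-10)
    expect_equal(tr_i$level,
                 unname(predict(fit_i, data.frame(x = 2000))),
                 tolerance = 1e-10)
  }

  expect_error(fit_linear_trend(1998:2000, c(0.1, 0.2)), "equal length")
  expect_error(fit_linear_trend(c(1998, 1998, 1998), c(0.1, 0.1, 0.1)),
               "two distinct years")
  expect_error(fit_linear_trend(1998:2000, c(0.1, 1.2, 0.1)), "\\[0, 1\\]")
})

test_that("fit_trends fits every cell and demands complete fit years", {
  cfg <- synthetic_config(noise_sd = 0)
  hist <- generate_risk_history(cfg, 1998:2000)
  tr <- fit_trends(hist)
  expect_identical(nrow(tr), 2L * 9L * 4L * 5L)
  # spot-check one cell against the scalar primitive
  cell <- hist[hist$sex == "male" & hist$age_band == "55-59" &
                 hist$state == "NO_HISTORY" & hist$event == "PCI", ]
  cell <- cell[order(cell$year), ]
  ref <- fit_linear_trend(cell$year, cell$probability)
  row <- tr[tr$sex == "male" & tr$age_band == "55-59" &
              tr$state == "NO_HISTORY" & tr$event == "PCI", ]
  expect_equal(row$level, ref$level, tolerance = 1e-12)
  expect_equal(row$slope, ref$slope, tolerance = 1e-12)

  expect_error(fit_trends(generate_risk_history(cfg, 1999:2000)),
               "does not cover fit year")
})

test_that("project_risks extrapolates the fitted line and clamps at the floor", {
  trends <- structure(
    data.frame(sex = "male", age_band = "55-59", state = "NO_HISTORY",
               event = "PCI", reference_year = 2000L, level = 0.08,
               slope = -0.01),
    class = c("trend_table", "data.frame"))
  proj <- project_risks(trends, years = 2001:2010)
  val <- function(y) proj$probability[proj$year == y]
  expect_equal(val(2005), 0.03, tolerance = 1e-12)
  expect_equal(val(2010), 0) # raw -0.02 clamped at the floor
  clamp <- attr(proj, "clamping")
  expect_true(all(c(2009, 2010) %in% clamp$year))
  expect_true(all(proj$probability >= 0 & proj$probability <= 1))

  flat <- trends
  flat$slope <- 0
  proj_flat <- project_risks(flat, years = 2001:2010)
  expect_true(all(proj_flat$probability == 0.08))
})

test_that("project_risks rejects projections whose event sums pass 1", {
  trends <- do.call(rbind, lapply(event_types(), function(e) {
    data.frame(sex = "male", age_band = "55-59", state = "NO_HISTORY",
               event = e, reference_year = 2000L, level = 0.15, slope = 0.02)
  }))
  expect_error(project_risks(trends, years = 2001:2010),
               "sum above 1.*55-59")
})

test_that("apply_scenario implements scale and level_off and is identity for Base", {
  trends <- structure(
    data.frame(sex = rep(c("male", "female"), each = 2),
               age_band = "55-59", state = "NO_HISTORY",
               event = rep(c("PCI", "CABG"), 2), reference_year = 2000L,
               level = c(0.05, 0.08, 0.05, 0.08),
               slope = c(0, -0.01, 0, -0.01)),
    class = c("trend_table", "data.frame"))
  proj <- project_risks(trends, years = 2001:2005)

  base <- apply_scenario(proj, trends, scenario_spec("base"))
  expect_identical(base$probability, proj$probability)

  scaled <- apply_scenario(proj, trends, scenario_spec("up", list(
    modification("PCI", kind = "scale", factor = 1.2))))
  pci <- scaled$event == "PCI"
  expect_equal(scaled$probability[pci], proj$probability[pci] * 1.2,
               tolerance = 1e-15)
  expect_equal(scaled$probability[pci][scaled$year[pci] == 2001], rep(0.06, 2))
  # untargeted cells bit-identical
  expect_identical(scaled$probability[!pci], proj$probability[!pci])

  level <- apply_scenario(proj, trends, scenario_spec("lvl", list(
    modification("CABG", kind = "level_off"))))
  cabg <- level$event == "CABG"
  expect_true(all(level$probability[cabg] == 0.08))
  # level-off of a declining risk never falls below the trend projection
  expect_true(all(level$probability[cabg] >= proj$probability[cabg]))
  expect_identical(level$probability[!cabg], proj$probability[!cabg])
})

test_that("scaling by f >= 1 never decreases the targeted event's projection", {
  cfg <- synthetic_config()
  hist <- generate_risk_history(cfg, 1998:2000, seed = 3)
  trends <- fit_trends(hist)
  proj <- project_risks(trends)
  for (f in c(1, 1.05, 1.2)) {
    for (ev in event_types()) {
      mod <- apply_scenario(proj, trends, scenario_spec("s", list(
        modification(ev, states = history_states(), kind = "scale",
                     factor = f))))
      tgt <- mod$event == ev
      expect_true(all(mod$probability[tgt] >= proj$probability[tgt]))
      expect_identical(mod$probability[!tgt], proj$probability[!tgt])
    }
  }
})

test_that("built-in scenarios match their definitions", {
  sc <- builtin_scenarios()
  expect_named(sc, c("base", "incidence1", "incidence2", "incidence3",
                     "incidence4"))
  expect_length(sc$base$modifications, 0)

  m1 <- sc$incidence1$modifications[[1]]
  expect_identical(m1$kind, "level_off")
  expect_identical(m1$events, "CHD_ADMISSION_NO_CARP")
  expect_identical(m1$states, "NO_HISTORY")

  expect_equal(sc$incidence2$modifications[[1]]$factor, 1.10)
  m3 <- sc$incidence3$modifications
  expect_length(m3, 1)
  expect_identical(m3[[1]]$kind, "scale")
  expect_equal(m3[[1]]$factor, 1.20)

  m4 <- sc$incidence4$modifications
  expect_length(m4, 4)
  kinds <- vapply(m4, `[[`, "", "kind")
  evs <- vapply(m4, function(m) m$events[1], "")
  expect_identical(kinds[match("CHD_ADMISSION_NO_CARP", evs)], "scale")
  expect_equal(m4[[match("CHD_ADMISSION_NO_CARP", evs)]]$factor, 1.20)
  expect_equal(m4[[match("PCI", evs)]]$factor, 1.05)
  expect_identical(kinds[match("CABG", evs)], "level_off")
  expect_identical(kinds[match("CHD_DEATH", evs)], "level_off")
  expect_true(all(vapply(m4, function(m) identical(m$states, "NO_HISTORY"),
                         TRUE)))
})

test_that("scenario JSON round-trips", {
  sc <- builtin_scenarios()
  path <- withr::local_tempfile(fileext = ".json")
  write_scenario_json(sc, path)
  back <- read_scenario_json(path)
  expect_named(back, names(sc))
  for (nm in names(sc)) {
    expect_length(back[[nm]]$modifications, length(sc[[nm]]$modifications))
    for (j in seq_along(sc[[nm]]$modifications)) {
      a <- sc[[nm]]$modifications[[j]]
      b <- back[[nm]]$modifications[[j]]
      expect_identical(b$events, a$events)
      expect_identical(b$kind, a$kind)
      expect_equal(b$factor, a$factor)
    }
  }
})
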