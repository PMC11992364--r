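# Synthetic single-cell generator: determinism, spatial statistics,
# noiseless exactness, noise structure and table round-tripping.

test_that("generation is deterministic and respects configured counts", {
  pop <- population_config(n_receivers = 300, n_emitters = 100)
  a <- generate_cells(pop, seed = 42)
  b <- generate_cells(pop, seed = 42)
  expect_identical(a, b)
  expect_equal(sum(a$identity == "receiver"), 300)
  expect_equal(sum(a$identity == "emitter"), 100)
  d <- generate_cells(pop, seed = 43)
  expect_false(identical(a$x_um, d$x_um))
  none <- generate_cells(population_config(n_receivers = 0, n_emitters = 10), 1)
  expect_equal(sum(none$identity == "receiver"), 0)
  expect_error(population_config(x_range = c(5, 5)), "max > min")
  # full simulated tables are byte-identical for identical seeds
  t1 <- simulate_experiment(seed = 9, pop = small_pop(200))
  t2 <- simulate_experiment(seed = 9, pop = small_pop(200))
  f1 <- tempfile(); f2 <- tempfile()
  write_cell_table(t1, f1); write_cell_table(t2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("positions are uniform over the stripe at the assay density", {
  pop <- population_config()   # 6,686 receivers over 5,400 um
  tab <- generate_cells(pop, seed = 5)
  dens <- nrow(tab[tab$identity == "receiver", ]) / diff(pop$x_range)
  expect_equal(dens, 6686 / 5400, tolerance = 1e-12)
  # KS against uniform: non-significant at alpha = .01 in >= 95% of seeds
  pvals <- vapply(1:20, function(s) {
    x <- generate_cells(small_pop(800), seed = 100 + s)$x_um
    suppressWarnings(ks.test(x, "punif", -2700, 2700)$p.value)
  }, numeric(1))
  expect_gte(mean(pvals > 0.01), 0.95)
})

test_that("noiseless readouts equal the model means exactly", {
  noise0 <- noise_config(gfp_cv = 0, length_sd = 0)
  tab <- simulate_experiment(seed = 3, pop = small_pop(400), noise = noise0)
  rec <- tab[tab$identity == "receiver", ]
  sh <- fixture_shape()
  expect_equal(rec$gfp_au,
               observed_response(rec$x_um, sh, fixture_resp_g()),
               tolerance = 1e-12)
  expect_equal(rec$length_um,
               observed_response(rec$x_um, sh, fixture_resp_m()),
               tolerance = 1e-12)
  # far-dark cells sit at the baselines, far-light at the plateaus
  farpop <- population_config(x_range = c(40000, 50000), n_receivers = 300,
                              n_emitters = 0)
  fd <- simulate_experiment(seed = 4, pop = farpop, noise = noise0)
  expect_equal(unique(round(fd$length_um[fd$identity == "receiver"], 4)), 5)
  litpop <- population_config(x_range = c(-50000, -40000), n_receivers = 300,
                              n_emitters = 0)
  fl <- simulate_experiment(seed = 4, pop = litpop, noise = noise0)
  flr <- fl[fl$identity == "receiver", ]
  expect_equal(flr$gfp_au, observed_response(flr$x_um, sh, fixture_resp_g()),
               tolerance = 1e-12)
  # within ~1% of the plateau value this deep into the light domain
  expect_equal(mean(flr$gfp_au), 1 * 1.45 / 2.45 + 0.1, tolerance = 0.01)
})

test_that("multiplicative GFP noise has unit mean and the configured CV", {
  pop <- population_config(x_range = c(-60000, -50000), n_receivers = 20000,
                           n_emitters = 0)
  tab <- simulate_experiment(seed = 8, pop = pop,
                             noise = noise_config(gfp_cv = 0.3, length_sd = 0))
  g <- tab$gfp_au[tab$identity == "receiver"]
  mu <- 1 * hill_response(1.45 * source_profile(mean(tab$x_um), 735), 1) + 0.1
  expect_equal(mean(g) / mu, 1, tolerance = 0.02)
  expect_equal(sd(g) / mean(g), 0.3, tolerance = 0.03)
})

test_that("bimodal morphology mode matches the Hill elongation probability", {
  pop <- population_config(x_range = c(-9000, -7000), n_receivers = 5000,
                           n_emitters = 0)
  tab <- simulate_experiment(seed = 12, pop = pop,
                             noise = noise_config(length_sd = 0.3,
                                                  morphology_mode = "bimodal"))
  rec <- tab[tab$identity == "receiver", ]
  frac <- mean(rec$length_um > 15)    # halfway between round (5) and elongated (30)
  theory <- mean(hill_response(concentration(rec$x_um, fixture_shape(), "source"), 3))
  expect_equal(frac, theory, tolerance = 0.03)
  # bin means still follow the graded model
  mp <- bin_cells(tab, "length", width = 500)
  expect_equal(mp$mean,
               observed_response(mp$bin_center, fixture_shape(), fixture_resp_m()),
               tolerance = 0.05)
})

test_that("orientations are uniform on (0, 180] with no gradient alignment", {
  tab <- simulate_experiment(seed = 21, pop = small_pop(3000))
  ang <- tab$orientation_deg[tab$identity == "receiver"]
  expect_true(all(ang > 0 & ang <= 180))
  expect_equal(mean(ang), 90, tolerance = 90 * 3 / sqrt(3000))
  pvals <- vapply(1:20, function(s) {
    t2 <- simulate_experiment(seed = 300 + s, pop = small_pop(500))
    a <- t2$orientation_deg[t2$identity == "receiver"]
    suppressWarnings(ks.test(a, "punif", 0, 180)$p.value)
  }, numeric(1))
  expect_gte(mean(pvals > 0.01), 0.95)
})

test_that("cell tables round-trip through CSV with metadata preserved", {
  tab <- simulate_experiment(seed = 6, pop = small_pop(150))
  path <- tempfile(fileext = ".csv")
  write_cell_table(tab, path)
  expect_true(any(grepl("^# seed: 6", readLines(path, n = 8))))
  back <- read_cell_table(path)
  expect_equal(as.data.frame(back),
               as.data.frame(tab)[, names(back)], tolerance = 1e-9)
})

test_that("the four-column segmentation schema is accepted, bad files rejected", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("identity,x_um,area_px,gfp_au",
               "receiver,-120.5,210,0.61",
               "emitter,300.2,180,NA"), path)
  tab <- read_cell_table(path)
  expect_equal(nrow(tab), 2)
  expect_true(all(is.na(tab$length_um)))
  expect_equal(tab$x_um, c(-120.5, 300.2))

  bad <- tempfile(fileext = ".csv")
  writeLines(c("identity,x_um,area_px,gfp_au",
               "receiver,oops,210,0.61"), bad)
  expect_error(read_cell_table(bad), "row 1")

  miss <- tempfile(fileext = ".csv")
  writeLines(c("identity,area_px", "receiver,210"), miss)
  expect_error(read_cell_table(miss), "schema")
  expect_error(read_cell_table(tempfile()), "not found")
  expect_error(write_cell_table(data.frame(a = 1), tempfile()), "missing required")
})
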