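test_that("tidal channel generator honours its geometry and defaults", {
  ch <- make_tidal_channel(10000, 500, 10, 100)
  expect_equal(dim(ch$grid$bed_depth), c(100, 5))
  expect_true(all(ch$grid$landtype == "riverbed"))
  expect_equal(ch$tide$amplitude, 2.7)
  expect_equal(nrow(ch$grid$open_boundary), 5) # one tidal end
  closed <- make_tidal_channel(5000, 300, 8, 100, west = "closed", east = "closed")
  expect_equal(nrow(closed$grid$open_boundary), 0)
  expect_error(make_tidal_channel(10000, 500, 10, 300), "divide")
  expect_error(make_tidal_channel(-1, 500, 10, 100), "degenerate")
})

test_that("toy catchment carries the default source table and geometry", {
  tc <- make_toy_catchment()
  expect_equal(dim(tc$grid$bed_depth), c(20, 100))
  rates <- vapply(tc$sources, function(s) s$rate, numeric(1))
  names(rates) <- vapply(tc$sources, function(s) s$name, character(1))
  expect_equal(rates[c("A2", "A1", "Cai_Mep", "Phu_My", "Go_Dau")],
               c(A2 = 0.5, A1 = 1, Cai_Mep = 1, Phu_My = 0.2, Go_Dau = 2))
  # west bank mangrove, east bank bare, channel riverbed
  expect_true(all(tc$grid$landtype[1:8, ] == "mangrove_floodplain"))
  expect_true(all(tc$grid$landtype[9:12, ] == "riverbed"))
  expect_true(all(tc$grid$landtype[13:20, ] == "bare"))
  # stations sit in the wet channel at mean tide
  for (r in seq_len(nrow(tc$stations))) {
    i <- tc$stations$i[r]; j <- tc$stations$j[r]
    expect_equal(tc$grid$landtype[i, j], "riverbed")
    expect_gt(tc$grid$bed_depth[i, j], 1)
  }
  # sources discharge into wet channel cells
  for (s in tc$sources) expect_equal(tc$grid$landtype[s$i, s$j], "riverbed")
  # generator is pure: identical calls give identical objects
  expect_identical(make_toy_catchment(), tc)
})

test_that("scenario templates edit the land classification as designed", {
  tc <- make_toy_catchment()
  sc1 <- build_scenario("SC1", tc)
  expect_identical(sc1$grid$landtype, tc$grid$landtype)

  sc2 <- build_scenario("SC2", tc)
  expect_equal(sum(sc2$grid$landtype == "mangrove_floodplain"), 0)
  expect_lt(sum(sc2$grid$landtype == "mangrove_floodplain"),
            sum(tc$grid$landtype == "mangrove_floodplain"))
  expect_true(all(sc2$k13 == 0)) # no plant uptake anywhere

  sc3 <- build_scenario("SC3", tc)
  wl_cells <- do.call(rbind, lapply(tc$wetland_template, function(w) w$cells))
  expect_true(all(sc3$grid$landtype[wl_cells] == "constructed_wetland"))
  k <- kinetic_params()
  expect_true(all(sc3$k13[wl_cells] == k$k13_young))
  expect_true(all(vapply(sc3$sources, function(s) s$routing, character(1)) ==
                    "through_wetland"))
  expect_error(build_scenario("SC9", tc))
})

test_that("greenhouse datasets are reproducible and noiseless at sd = 0", {
  k <- kinetic_params()
  ds0 <- make_greenhouse_dataset(k, c0 = 500, noise_sd = 0)
  traj <- analytic_compartments(k, 500, ds0$times)
  expect_equal(ds0$observations$value,
               c(traj$Sl, traj$Ss, traj$Pl)) # exact, no noise
  a <- make_greenhouse_dataset(k, noise_sd = 0.1, seed = 99)
  b <- make_greenhouse_dataset(k, noise_sd = 0.1, seed = 99)
  expect_identical(a$observations, b$observations)
  c2 <- make_greenhouse_dataset(k, noise_sd = 0.1, seed = 100)
  expect_false(identical(a$observations$value, c2$observations$value))
  expect_error(make_greenhouse_dataset(k, noise_sd = -0.1), "noise_sd")
})

test_that("multiplicative noise has the configured relative spread", {
  k <- kinetic_params()
  rel <- unlist(lapply(1:300, function(s) {
    ds <- make_greenhouse_dataset(k, c0 = 500, noise_sd = 0.1, seed = s)
    truthv <- make_greenhouse_dataset(k, c0 = 500, noise_sd = 0)$observations$value
    keep <- truthv > 0
    (ds$observations$value[keep] - truthv[keep]) / truthv[keep]
  }))
  expect_gt(sd(rel), 0.09)
  expect_lt(sd(rel), 0.11)
})

test_that("the dataset generator leaves the global RNG stream untouched", {
  set.seed(123); before <- .Random.seed
  invisible(make_greenhouse_dataset(kinetic_params(), noise_sd = 0.2, seed = 7))
  expect_identical(.Random.seed, before)
})
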