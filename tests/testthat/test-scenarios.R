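test_that("reference parameterisation reproduces the canonical table", {
  base <- baseline_parameters()
  p <- base$params
  expect_equal(unlist(p[c("r10", "r20", "d1", "d2", "d3", "a1", "a2",
                          "g1", "g2", "S1", "S2", "k", "CE")]),
               c(r10 = 4.1, r20 = 4.0, d1 = 0.1, d2 = 0.002, d3 = 0.002,
                 a1 = 0.052, a2 = 0.052, g1 = 1.2, g2 = 1.3,
                 S1 = 0.042, S2 = 0.039, k = 2.0, CE = 30))
  expect_equal(base$init, c(x1 = 100, x2 = 10, C1 = 0, C2 = 0))
  expect_identical(nrow(validate_params(p)), 0L)
})

test_that("conditions encode the intensity-ratio design", {
  a <- make_condition("a")
  expect_true(a$freeze_toxin)
  expect_identical(c(a$r11, a$r21), c(0, 0))
  expect_true(is.na(a$delta))

  b <- make_condition("b", 0.1, 0.1)
  expect_equal(b$delta, 1)
  cc <- make_condition("c", 1.0, 10.0)
  expect_equal(cc$delta, 0.1)
  dd <- make_condition("d", 10.0, 1.0)
  expect_equal(dd$delta, 10)
  expect_error(make_condition("b", 1.0, 10.0), "r11/r21")
  expect_error(make_condition("c", 0.3, 3.0), "level set")
})

test_that("feeding-decline variant overrides only the decline rates", {
  v <- feeding_decline_variant(mp_params(r11 = 1, r21 = 1))
  expect_equal(unlist(v[c("d1", "d2", "d3")]),
               c(d1 = 0.6, d2 = 0.012, d3 = 0.012))
  expect_equal(unlist(v[c("r10", "r11", "a1", "CE")]),
               c(r10 = 4.1, r11 = 1, a1 = 0.052, CE = 30))
  expect_identical(nrow(validate_params(v)), 0L)
  expect_equal(feeding_decline_variant(v), v)
  # the once-reported larger d3 would flip the predation sign: rejected
  alt <- mp_params(d1 = 0.6, d2 = 0.012, d3 = 0.12)
  expect_true(any(grepl("a1 - d3", validate_params(alt)$constraint)))
})

test_that("the registry holds all eleven design points, once each", {
  reg <- campaign_scenarios()
  expect_identical(nrow(reg), 11L)
  expect_identical(anyDuplicated(reg$name), 0L)
  expect_identical(sum(reg$r11 == 0 & reg$r21 == 0), 1L)
  expect_identical(sum(reg$feeding_decline), 3L)
  expect_true(any(reg$r11 == 1 & reg$r21 == 10))
  for (i in seq_len(nrow(reg))) {
    expect_identical(nrow(validate_params(reg$params[[i]])), 0L)
  }
  fd <- reg[reg$feeding_decline, ]
  expect_true(all(vapply(fd$params, function(p) p$d1 == 0.6, TRUE)))
})

test_that("seeded ensembles are reproducible and valid", {
  e1 <- random_ensemble(5, seed = 42)
  e2 <- random_ensemble(5, seed = 42)
  expect_identical(as.data.frame(e1[c("name", "r11", "r21", "delta")]),
                   as.data.frame(e2[c("name", "r11", "r21", "delta")]))
  expect_identical(map(e1$params, as.data.frame),
                   map(e2$params, as.data.frame))
  e3 <- random_ensemble(5, seed = 43)
  expect_false(identical(e1$r11, e3$r11))
  big <- random_ensemble(50, seed = 1)
  expect_true(all(big$delta > 0))
  for (i in seq_len(nrow(big))) {
    expect_identical(nrow(validate_params(big$params[[i]])), 0L)
  }
  expect_error(random_ensemble(0, seed = 1), "at least 1")
  expect_error(random_ensemble(3, seed = 1, jitter = 0.5), "jitter")
})

test_that("ensemble draws leave the global RNG stream untouched", {
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(random_ensemble(3, seed = 7))
  expect_identical(runif(1), before)
})

test_that("campaign runs summarise each scenario deterministically", {
  sc <- dplyr::bind_rows(make_condition("a"),
                         make_condition("b", 10, 10))
  sw <- run_campaign(sc, settings = coarse_settings())
  expect_s3_class(sw, "mp_sweep")
  expect_identical(sw$outcome, c("coexistence", "both_extinct"))
  expect_true(is.na(sw$extinction_x2[1]) && !is.na(sw$extinction_x2[2]))
  sw2 <- run_campaign(sc, settings = coarse_settings())
  expect_equal(tidy(sw), tidy(sw2))
  g <- glance(sw)
  expect_identical(g$n_scenarios, 2L)
  expect_identical(g$n_both_extinct, 1L)
})

test_that("the symmetric toxin-free system mirrors under species swap", {
  s <- solver_settings(dt_out = 0.005)
  fwd <- simulate_mp(mp_params(), init = c(x1 = 100, x2 = 10, C1 = 0, C2 = 0),
                     t_end = 10, settings = s, freeze_toxin = TRUE)
  swp <- simulate_mp(mp_params(), init = c(x1 = 10, x2 = 100, C1 = 0, C2 = 0),
                     t_end = 10, settings = s, freeze_toxin = TRUE)
  expect_equal(max(swp$x2), max(fwd$x1), tolerance = 1e-4)
  expect_equal(min(swp$x2), min(fwd$x1), tolerance = 1e-4)
  expect_equal(max(swp$x1), max(fwd$x2), tolerance = 1e-4)
})

test_that("a heavier predator burden accelerates its decline", {
  # time for the predator to drop below one individual per m^3, at severe
  # prey response: should come earlier the larger r21
  drop_time <- vapply(c(1, 2, 10), function(r21) {
    tr <- simulate_mp(mp_params(r11 = 10, r21 = r21), t_end = 10,
                      settings = solver_settings(dt_out = 0.005))
    extinction_time(tr$t, tr$x2, threshold = 1)
  }, 0)
  expect_true(all(diff(drop_time) < 0))
})
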