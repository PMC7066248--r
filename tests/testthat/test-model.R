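test_that("raw derivatives match hand-computed rates at the reference state", {
  d <- mp_derivatives(c(x1 = 100, x2 = 10, C1 = 0, C2 = 0), mp_params())
  # dx1 = 100*(4 - 0.05*10), dx2 = 10*(-4 + 0.05*100),
  # dC1 = 0.042*30 - 1.2, dC2 = 0.039*30 - 1.3 (raw, before clamping)
  expect_equal(unlist(d), c(dx1 = 350, dx2 = 10, dC1 = 0.06, dC2 = -0.13),
               tolerance = 1e-12)
})

test_that("population rates vanish multiplicatively at zero density", {
  for (p in list(mp_params(), mp_params(r11 = 3, r21 = 0.5),
                 feeding_decline_variant(mp_params()))) {
    d <- mp_derivatives(c(x1 = 0, x2 = 0, C1 = 2, C2 = 5), p)
    expect_identical(unname(unlist(d[c("dx1", "dx2")])), c(0, 0))
  }
})

test_that("toxin-free equilibrium zeroes the population field", {
  eq <- lv_equilibrium(mp_params())
  expect_equal(unlist(eq), c(x1 = 80, x2 = 80), tolerance = 1e-12)
  d <- mp_derivatives(c(x1 = eq$x1, x2 = eq$x2, C1 = 0, C2 = 0), mp_params())
  expect_equal(unname(unlist(d[c("dx1", "dx2")])), c(0, 0), tolerance = 1e-10)
})

test_that("equilibrium obeys the ratio identities", {
  # r20 equal to the effective feeding gain gives x1* = 1
  expect_equal(lv_equilibrium(mp_params(r20 = 0.05))$x1, 1, tolerance = 1e-12)
  # r10-d1 = 2(a1-d3), r20 = 3(a2-d2) gives (3, 2)
  p <- mp_params(r10 = 0.2, d1 = 0.1, r20 = 0.15)
  expect_equal(unlist(lv_equilibrium(p)), c(x1 = 3, x2 = 2),
               tolerance = 1e-12)
  expect_error(lv_equilibrium(mp_params(d2 = 0.052)), "a2 - d2")
})

test_that("first integral: frozen values, symmetry, minimum at equilibrium", {
  p <- mp_params()
  # 0.05*100 - 4 log 100 + 0.05*10 - 4 log 10 and 8 - 8 log 80
  expect_equal(lv_invariant(100, 10, p), -22.13102, tolerance = 1e-6)
  expect_equal(lv_invariant(80, 80, p), -27.05621, tolerance = 1e-6)
  # the reference rates are symmetric (r10-d1 = r20, a1-d3 = a2-d2)
  u <- c(3, 40, 100, 250); v <- c(17, 80, 9, 120)
  expect_equal(lv_invariant(u, v, p), lv_invariant(v, u, p))
  # grid search around the fixed point never goes below H(80, 80)
  g <- expand.grid(x1 = seq(10, 300, by = 5), x2 = seq(10, 300, by = 5))
  expect_true(all(lv_invariant(g$x1, g$x2, p) >= lv_invariant(80, 80, p)))
  expect_error(lv_invariant(-1, 10, p), "positive")
})

test_that("toxin closed form follows the clamped branches", {
  p <- mp_params()
  cf <- toxin_closed_form(c(0, 1, 2), p)
  expect_equal(cf$C1, c(0, 0.06, 0.12), tolerance = 1e-12)
  # predator burden held at zero until its net rate turns positive at
  # t = 13/12, then the quadratic branch 0.06 t^2 - 0.13 t + 0.0704167
  expect_equal(cf$C2, c(0, 0, 0.0504167), tolerance = 1e-5)
  raw <- toxin_closed_form(c(1, 2), p, clamped = FALSE)
  expect_equal(raw$C2, c(0.039 * 30 - 1.3 + 0.06,
                         (0.039 * 30 - 1.3) * 2 + 0.24), tolerance = 1e-12)
  expect_error(toxin_closed_form(-0.5, p), "nonnegative")
})

test_that("toxin closed form handles degenerate uptake balances", {
  # prey egests faster than it ingests: burden clamped at zero throughout
  p1 <- mp_params(S1 = 0.01)                 # S1*CE - g1 = -0.9
  cf1 <- toxin_closed_form(c(0, 1, 5), p1)
  expect_equal(cf1$C1, c(0, 0, 0))
  # with no trophic transfer either, the predator burden stays clamped too
  p2 <- mp_params(S1 = 0.01, k = 0)
  expect_equal(toxin_closed_form(c(1, 10), p2)$C2, c(0, 0))
  # net-positive predator uptake: no clamped interval at all
  p3 <- mp_params(g2 = 1.0)                  # S2*CE - g2 = 0.17
  cf3 <- toxin_closed_form(2, p3)
  expect_equal(cf3$C2, 0.17 * 2 + 2 * 0.06 * 4 / 2, tolerance = 1e-12)
})

test_that("validate_params reports violated constraints by name", {
  expect_identical(nrow(validate_params(mp_params())), 0L)
  v <- validate_params(mp_params(d3 = 0.12))
  expect_true(any(grepl("a1 - d3 must be positive", v$constraint)))
  v2 <- validate_params(mp_params(r20 = -1))
  expect_true(any(grepl("r20 must be positive", v2$constraint)))
  v3 <- validate_params(mp_params(S1 = -0.1, k = -2))
  expect_setequal(v3$field, c("S1", "k"))
})

test_that("population rates are affine in the internal burdens", {
  p <- mp_params(r11 = 1.7, r21 = 4.2)
  at <- function(C1, C2) {
    unlist(mp_derivatives(c(x1 = 50, x2 = 30, C1 = C1, C2 = C2), p))
  }
  d0 <- at(0, 0); d1 <- at(1, 1); d2 <- at(2, 2)
  # zero second difference in each burden
  expect_equal(d2["dx1"] - 2 * d1["dx1"] + d0["dx1"], c(dx1 = 0),
               tolerance = 1e-9)
  expect_equal(d2["dx2"] - 2 * d1["dx2"] + d0["dx2"], c(dx2 = 0),
               tolerance = 1e-9)
  # and the slopes are the response intensities times density
  expect_equal(unname(d1["dx1"] - d0["dx1"]), -1.7 * 50, tolerance = 1e-9)
  expect_equal(unname(d1["dx2"] - d0["dx2"]), -4.2 * 30, tolerance = 1e-9)
})

test_that("toxin rates are independent of the population densities", {
  p <- mp_params(r11 = 1, r21 = 10)
  a <- mp_derivatives(c(x1 = 1, x2 = 1, C1 = 0.3, C2 = 0.7), p)
  b <- mp_derivatives(c(x1 = 4000, x2 = 0, C1 = 0.3, C2 = 0.7), p)
  expect_identical(a[c("dC1", "dC2")], b[c("dC1", "dC2")])
})
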