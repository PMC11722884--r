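test_that("wf_vector validates components and derives the total", {
  v <- wf_vector(10, 5, 5)
  expect_s3_class(v, "wf_vector")
  expect_equal(wf_total(v), 20)
  expect_error(wf_vector(-1, 0, 0), "non-negative")
  expect_error(wf_vector(NA, 0, 0), "finite")
})

test_that("scaling is componentwise and conserves the total", {
  v <- wf_vector(10, 5, 5)
  expect_equal(unclass(wf_scale(v, 0)), c(green = 0, blue = 0, grey = 0))
  expect_equal(wf_scale(v, 1), v)
  # red meat: 113 g/week at (9661, 505, 537) L/kg
  r <- wf_scale(wf_vector(9661, 505, 537), 0.113)
  expect_equal(unclass(r), c(green = 1091.693, blue = 57.065, grey = 60.681),
               tolerance = 1e-9)
  expect_equal(wf_total(r), 1209.439, tolerance = 1e-9)
  expect_error(wf_scale(v, -0.1), "non-negative")
})

test_that("addition is componentwise and total-conserving", {
  a <- wf_vector(1, 2, 3)
  expect_equal(wf_add(a, wf_vector(0, 0, 0)), a)
  expect_equal(unclass(wf_add(a, wf_vector(4, 5, 6))),
               c(green = 5, blue = 7, grey = 9))
  set.seed(42)
  for (i in 1:25) {
    x <- wf_vector(runif(1, 0, 5000), runif(1, 0, 1000), runif(1, 0, 1000))
    y <- wf_vector(runif(1, 0, 5000), runif(1, 0, 1000), runif(1, 0, 1000))
    k <- runif(1, 0, 10)
    expect_equal(wf_total(wf_add(x, y)), wf_total(x) + wf_total(y))
    expect_equal(wf_total(wf_scale(x, k)), k * wf_total(x))
  }
})

test_that("arithmetic operators mirror wf_add / wf_scale", {
  a <- wf_vector(1, 2, 3)
  expect_equal(a + a, wf_add(a, a))
  expect_equal(a * 2, wf_scale(a, 2))
  expect_equal(2 * a, wf_scale(a, 2))
  expect_equal(unname((a + a) - a), c(1, 2, 3))  # differences drop the class
})

test_that("jam is a fixed-composition fruit/sugar composite, linear in both", {
  zero <- wf_vector(0, 0, 0)
  expect_equal(jam_wf(zero, zero), zero)
  # totals forced by the 0.35/0.40 fractions
  expect_equal(wf_total(jam_wf(wf_vector(1000, 0, 0), wf_vector(1000, 0, 0))),
               750)
  j <- jam_wf(wf_vector(540, 171, 108), wf_vector(860, 327, 137))
  expect_equal(unclass(j), c(green = 533, blue = 190.65, grey = 92.6),
               tolerance = 1e-12)
  # linearity in each argument
  f <- wf_vector(540, 171, 108); s <- wf_vector(860, 327, 137)
  expect_equal(jam_wf(wf_scale(f, 2), s),
               wf_add(jam_wf(f, s), wf_scale(f, 0.35)))
  expect_equal(jam_wf(f, wf_scale(s, 2)),
               wf_add(jam_wf(f, s), wf_scale(s, 0.40)))
})

test_that("cooked-to-dry conversion round-trips through the factor", {
  expect_equal(cooked_to_dry_mass(0), 0)
  expect_equal(cooked_to_dry_mass(250), 100)
  expect_equal(cooked_to_dry_mass(185), 74)
  set.seed(1)
  m <- runif(20, 0, 500)
  expect_equal(cooked_to_dry_mass(m) * 2.5, m, tolerance = 1e-9)
  expect_equal(cooked_to_dry_mass(m, factor = 3) * 3, m, tolerance = 1e-9)
  expect_error(cooked_to_dry_mass(-1), "non-negative")
})

test_that("only the farmed share of seafood mass is charged", {
  expect_equal(effective_seafood_mass(640, 0.5), 320)
  expect_equal(effective_seafood_mass(123, 0), 0)
  expect_equal(effective_seafood_mass(123, 1), 123)
  expect_error(effective_seafood_mass(100, 1.5), "\\[0, 1\\]")
})

test_that("constants default to the pattern-construction values", {
  k <- wf_constants()
  expect_equal(k$cooked_to_dry, 2.5)
  expect_equal(k$aquaculture_fraction, 0.5)
  expect_equal(k$jam_fruit_fraction, 0.35)
  expect_equal(k$jam_sugar_fraction, 0.40)
})
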