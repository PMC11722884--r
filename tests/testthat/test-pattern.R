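make_entry <- function(category = "x", serving = 100, servings = 7,
                       wf = wf_vector(1000, 100, 50), kcal = 250,
                       protein = 10, fraction = 1, class = "plant") {
  diet_entry(category, serving, servings, wf, classification = class,
             edible_fraction = fraction, kcal_per_100g = kcal,
             protein_per_100g = protein)
}

test_that("edible mass converts to production weight by the edible fraction", {
  expect_equal(edible_to_production(100, 1), 100)
  expect_equal(edible_to_production(150, 0.5), 300)
  # fresh fruit: 3150 g edible at the fraction implied by 3150/4074
  expect_equal(edible_to_production(3150, 3150 / 4074), 4074, tolerance = 1e-9)
  expect_error(edible_to_production(100, 0), "\\(0, 1\\]")
  expect_error(edible_to_production(100, 1.2), "\\(0, 1\\]")
})

test_that("patterns validate entries, categories, and mass consistency", {
  e1 <- make_entry("a"); e2 <- make_entry("b")
  p <- dietary_pattern("test", list(e1, e2), target_kcal_per_day = 2000)
  expect_s3_class(p, "dietary_pattern")
  expect_equal(nrow(p$entries), 2)
  expect_error(dietary_pattern("test", list(e1, e1)), "duplicate")
  expect_error(dietary_pattern("test", list()), "at least one entry")
  # production mass below edible mass implies an edible fraction > 1
  bad <- e1
  bad$g_per_week_production <- 0.5 * bad$serving_size_g_edible *
    bad$servings_per_week
  expect_error(dietary_pattern("test", list(bad)), "edible fraction")
  # ... unless within the declared rounding slack
  near <- e1
  near$g_per_week_production <- 0.97 * near$serving_size_g_edible *
    near$servings_per_week
  expect_s3_class(dietary_pattern("test", list(near), mass_tol = 0.05),
                  "dietary_pattern")
})

test_that("min/max averaging is the categorywise mean and is symmetric", {
  lo <- dietary_pattern("sdg", list(make_entry("dairy", 125, 14),
                                    make_entry("veg", 200, 0)))
  hi <- dietary_pattern("sdg", list(make_entry("dairy", 125, 21),
                                    make_entry("veg", 200, 2)))
  avg <- average_min_max(lo, hi)
  expect_equal(avg$entries$servings_per_week, c(17.5, 1))
  expect_equal(average_min_max(hi, lo)$entries$servings_per_week,
               avg$entries$servings_per_week)
  # idempotent on identical specs
  same <- average_min_max(lo, lo)
  expect_equal(same$entries$servings_per_week, lo$entries$servings_per_week)
  expect_equal(same$entries$g_per_week_production,
               lo$entries$g_per_week_production)
  expect_error(average_min_max(lo, dietary_pattern("sdg",
    list(make_entry("dairy", 125, 21)))), "same categories")
})

test_that("pattern energy matches an independent spreadsheet-style sum", {
  expect_equal(pattern_energy(dietary_pattern("z",
    list(make_entry("water", 100, 14, kcal = 0)))), 0)
  expect_equal(pattern_energy(dietary_pattern("one",
    list(make_entry("a", 100, 7, kcal = 250)))), 250)
  g <- gen_pattern(synth_config(n_categories = 12, seed = 11))
  p <- g$pattern
  # oracle: accumulate row by row with scalar arithmetic
  oracle <- 0
  for (i in seq_len(nrow(p$entries))) {
    row <- p$entries[i, ]
    oracle <- oracle +
      row$serving_size_g_edible * row$servings_per_week *
        row$kcal_per_100g / 100 / 7
  }
  expect_equal(pattern_energy(p), oracle, tolerance = 1e-9)
  # named error for a missing composition record
  p$entries$kcal_per_100g[3] <- NA
  expect_error(pattern_energy(p), p$entries$category[3], fixed = TRUE)
  # external composition table takes precedence over entry values
  comp <- data.frame(category = "a", kcal_per_100g = 500)
  expect_equal(pattern_energy(dietary_pattern("one",
    list(make_entry("a", 100, 7, kcal = 250))), comp), 500)
})

test_that("energy rescaling hits the target, preserves ratios, idempotent", {
  g <- gen_pattern(synth_config(n_categories = 8, seed = 3))
  p <- g$pattern
  q <- rescale_to_energy(p, 2000)
  expect_equal(pattern_energy(q), 2000, tolerance = 1e-6)
  ratios <- function(x) x$entries$servings_per_week /
    x$entries$servings_per_week[1]
  expect_equal(ratios(q), ratios(p), tolerance = 1e-12)
  expect_equal(rescale_to_energy(q, 2000)$entries$servings_per_week,
               q$entries$servings_per_week, tolerance = 1e-12)
  # masses rescale consistently with servings
  f <- 2000 / pattern_energy(p)
  expect_equal(q$entries$g_per_week_production,
               p$entries$g_per_week_production * f, tolerance = 1e-12)
  # fixed point when already on target
  expect_equal(rescale_to_energy(p, pattern_energy(p))$entries, p$entries,
               tolerance = 1e-12)
  zero <- dietary_pattern("z", list(make_entry("water", 100, 14, kcal = 0)))
  expect_error(rescale_to_energy(zero, 2000), "zero-energy")
})

test_that("classification is explicit: animal, plant (incl. fats), other", {
  tax <- c(Seafood = "animal", Dairy = "animal", Sugar = "other",
           Butter = "plant", Bread = "plant")
  expect_equal(classify_entry("Seafood", tax), "animal")
  expect_equal(classify_entry("Sugar", tax), "other")
  expect_equal(classify_entry("Butter", tax), "plant")
  expect_equal(classify_entry(c("Bread", "Dairy"), tax), c("plant", "animal"))
  expect_error(classify_entry("Tofu", tax), "Tofu")
  expect_error(classify_entry("Bread", c(Bread = "mineral")), "invalid")
})
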