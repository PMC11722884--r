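test_that("equal-mass deltas: self-swap zero, antisymmetric, linear in mass", {
  a <- wf_vector(7248, 392, 492)
  b <- wf_vector(987, 90, 83)
  expect_equal(unname(delta_equal_mass(a, a, 400)), rep(0, 4))
  expect_equal(delta_equal_mass(a, b, 125), -delta_equal_mass(b, a, 125))
  expect_equal(delta_equal_mass(a, b, 250), 2 * delta_equal_mass(a, b, 125))
  # food_record and entry inputs resolve to their WF/kg
  fr <- food_record("meat", a)
  expect_equal(delta_equal_mass(fr, b, 100), delta_equal_mass(a, b, 100))
  expect_error(delta_equal_mass(a, b, -5), "non-negative")
})

test_that("equal-protein swaps balance protein mass", {
  pulses <- food_record("dry pulses", wf_vector(3174, 218, 879),
                        protein_per_100g = 22)
  meat <- food_record("meat mix", wf_vector(6365, 392, 492),
                      protein_per_100g = 20)
  d <- delta_equal_protein(meat, pulses, mass_add_g = 50)
  # oracle, by hand: removed meat mass = 50 * 22 / 20 = 55 g
  mass_remove <- 50 * 22 / 20
  hand <- (c(6365, 392, 492) * mass_remove - c(3174, 218, 879) * 50) / 1000
  expect_equal(unname(d), c(hand, sum(hand)), tolerance = 1e-12)
  # equal protein densities reduce to the equal-mass delta
  p1 <- food_record("a", wf_vector(1000, 100, 10), protein_per_100g = 15)
  p2 <- food_record("b", wf_vector(400, 40, 4), protein_per_100g = 15)
  expect_equal(delta_equal_protein(p1, p2, 80),
               delta_equal_mass(p1, p2, 80))
  # remove with 2x the protein density: half the removed mass
  rich <- food_record("rich", wf_vector(1000, 0, 0), protein_per_100g = 30)
  lean <- food_record("lean", wf_vector(0, 0, 0), protein_per_100g = 15)
  expect_equal(delta_equal_protein(rich, lean, 100)[["green"]],
               1000 * 0.05)   # 50 g of 'rich' removed
  expect_error(delta_equal_protein(food_record("x", wf_vector(1, 1, 1)),
                                   pulses, 50), "protein")
})

test_that("applying a swap matches a full recomputation and is local", {
  p <- gen_pattern(synth_config(n_categories = 10, seed = 5))$pattern
  r0 <- diet_wf(p)
  cats <- p$entries$category
  res <- apply_swap(p, cats[2], cats[5], mass_remove_g = 40, mass_add_g = 70)
  r1 <- diet_wf(res$pattern)
  expect_equal(wf_total(r1$weekly_total),
               wf_total(r0$weekly_total) - res$delta[["total"]],
               tolerance = 1e-6)
  # untouched entries are bit-identical
  untouched <- !cats %in% cats[c(2, 5)]
  expect_identical(res$pattern$entries[untouched, ], p$entries[untouched, ])
  # null swap
  null <- apply_swap(p, cats[1], cats[1], 0)
  expect_equal(null$pattern$entries, p$entries)
  expect_equal(unname(null$delta), rep(0, 4))
  # swap then inverse swap restores the totals
  back <- apply_swap(res$pattern, cats[5], cats[2],
                     mass_remove_g = 70, mass_add_g = 40)
  expect_equal(wf_total(diet_wf(back$pattern)$weekly_total),
               wf_total(r0$weekly_total), tolerance = 1e-9)
  expect_error(apply_swap(p, cats[1], cats[2],
                          p$entries$g_per_week_production[1] + 1),
               "cannot remove")
  expect_error(apply_swap(p, "nope", cats[2], 1), "nope")
})
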