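#' Water saved by replacing one food with another, equal mass
#'
#' `(mass/1000) * (wf_a - wf_b)`, componentwise. Positive total = water
#' saved by the swap. Seafood substitutions should charge only the farmed
#' share of the added mass (see [effective_seafood_mass()]).
#'
#' @param wf_remove,wf_add [wf_vector()]s in L/kg (or [food_record()]s /
#'   one-row `diet_entry`s, whose WF/kg is used).
#' @param mass_g Swapped mass in g/week.
#' @return Named numeric delta (green, blue, grey) in L/week; may be
#'   negative componentwise.
#' @export
delta_equal_mass <- function(wf_remove, wf_add, mass_g) {
  a <- resolve_wf_per_kg(wf_remove)
  b <- resolve_wf_per_kg(wf_add)
  if (mass_g < 0) stop("mass must be non-negative", call. = FALSE)
  d <- (unclass(a) - unclass(b)) * mass_g / 1000
  c(d, total = sum(d))
}

resolve_wf_per_kg <- function(x) {
  if (inherits(x, "food_record")) return(x$wf_per_kg)
  if (inherits(x, "diet_entry") || (is.data.frame(x) && nrow(x) == 1L &&
                                    "wf_green_per_kg" %in% names(x)))
    return(wf_vector(x$wf_green_per_kg, x$wf_blue_per_kg, x$wf_grey_per_kg))
  as_wf_vector(x)
}

#' Water saved by an equal-protein substitution
#'
#' The removed mass is chosen so that it supplies the same protein as the
#' added mass: `mass_remove = mass_add * protein(add) / protein(remove)`;
#' the delta is `(mass_remove * wf_remove - mass_add * wf_add) / 1000`.
#'
#' @param remove,add [food_record()]s with `protein_per_100g` set.
#' @param mass_add_g Added mass in g/week.
#' @return Named numeric delta (green, blue, grey, total) in L/week,
#'   positive total = water saved.
#' @export
delta_equal_protein <- function(remove, add, mass_add_g) {
  for (f in list(remove, add))
    if (!inherits(f, "food_record") || is.na(f$protein_per_100g) ||
        f$protein_per_100g <= 0)
      stop("equal-protein swaps need food_records with positive protein_per_100g",
           call. = FALSE)
  mass_remove_g <- mass_add_g * add$protein_per_100g / remove$protein_per_100g
  d <- (unclass(remove$wf_per_kg) * mass_remove_g -
          unclass(add$wf_per_kg) * mass_add_g) / 1000
  c(d, total = sum(d))
}

#' Apply a mass swap between two categories of a pattern
#'
#' Moves `mass_remove_g` per week out of one category and adds `mass_add_g`
#' (default: the same) to another, returning the modified pattern and the
#' footprint delta. The delta equals the difference of full reports:
#' `diet_wf(old)` total minus `diet_wf(new)` total. Entries not named are
#' untouched.
#'
#' @param pattern A resolved [dietary_pattern()].
#' @param remove,add Category labels present in the pattern.
#' @param mass_remove_g Production mass removed, g/week; must not exceed the
#'   category's current mass.
#' @param mass_add_g Production mass added, g/week (default `mass_remove_g`).
#' @return A list with `pattern` (modified) and `delta` (green, blue, grey,
#'   total in L/week; positive total = water saved).
#' @export
apply_swap <- function(pattern, remove, add, mass_remove_g,
                       mass_add_g = mass_remove_g) {
  e <- pattern$entries
  i <- match(remove, e$category)
  j <- match(add, e$category)
  if (is.na(i) || is.na(j))
    stop(sprintf("category not in pattern: %s",
                 paste(c(remove, add)[is.na(c(i, j))], collapse = ", ")),
         call. = FALSE)
  if (mass_remove_g < 0 || mass_add_g < 0)
    stop("swap masses must be non-negative", call. = FALSE)
  if (mass_remove_g > e$g_per_week_production[i] + 1e-9)
    stop(sprintf("cannot remove %.1f g from '%s' (only %.1f g present)",
                 mass_remove_g, remove, e$g_per_week_production[i]),
         call. = FALSE)
  wf_i <- entry_wf_per_kg(e, i)
  wf_j <- entry_wf_per_kg(e, j)
  d <- (unclass(wf_i) * mass_remove_g - unclass(wf_j) * mass_add_g) / 1000
  scale_entry <- function(e, k, new_mass) {
    old <- e$g_per_week_production[k]
    e$g_per_week_production[k] <- new_mass
    if (old > 0) e$servings_per_week[k] <- e$servings_per_week[k] * new_mass / old
    e
  }
  e <- scale_entry(e, i, e$g_per_week_production[i] - mass_remove_g)
  e <- scale_entry(e, j, e$g_per_week_production[j] + mass_add_g)
  out <- pattern
  out$entries <- e
  list(pattern = out, delta = c(d, total = sum(d)))
}
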