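#' Edible-portion mass to production weight
#'
#' Guideline serving sizes are edible weights while WF databases price
#' production weight; dividing by the edible fraction converts between the
#' two (e.g. fruit with peel and stone).
#'
#' @param mass_edible_g Edible mass in g.
#' @param edible_fraction Edible share of production weight, in (0, 1].
#' @return Production mass in g; identity when `edible_fraction` is 1.
#' @export
edible_to_production <- function(mass_edible_g, edible_fraction) {
  if (any(edible_fraction <= 0) || any(edible_fraction > 1))
    stop("edible_fraction must be in (0, 1]", call. = FALSE)
  if (any(mass_edible_g < 0)) stop("mass must be non-negative", call. = FALSE)
  mass_edible_g / edible_fraction
}

#' One resolved food category of a dietary pattern
#'
#' @param category Category label, unique within a pattern.
#' @param serving_size_g_edible Serving size in g of edible portion.
#' @param servings_per_week Suggested servings per week (fractional allowed).
#' @param wf_per_kg [wf_vector()] in L per kg of production weight.
#' @param classification One of `"animal"`, `"plant"`, `"other"`.
#' @param edible_fraction Edible share used to derive the production mass
#'   when `g_per_week_production` is not given.
#' @param g_per_week_production Production mass consumed per week in g;
#'   default `serving_size_g_edible * servings_per_week / edible_fraction`.
#' @param food_group Optional coarser group label used for contribution
#'   analyses (e.g. `"dairy"`, `"cereals"`).
#' @param kcal_per_100g,protein_per_100g Optional composition per 100 g
#'   edible weight.
#' @return A one-row data frame of class `diet_entry`.
#' @export
diet_entry <- function(category, serving_size_g_edible, servings_per_week,
                       wf_per_kg, classification = c("plant", "animal", "other"),
                       edible_fraction = 1, g_per_week_production = NULL,
                       food_group = NA_character_,
                       kcal_per_100g = NA_real_, protein_per_100g = NA_real_) {
  classification <- match.arg(classification)
  wf_per_kg <- as_wf_vector(wf_per_kg)
  if (servings_per_week < 0) stop("servings_per_week must be >= 0", call. = FALSE)
  if (serving_size_g_edible < 0) stop("serving size must be >= 0", call. = FALSE)
  if (is.null(g_per_week_production))
    g_per_week_production <- edible_to_production(
      serving_size_g_edible * servings_per_week, edible_fraction)
  out <- data.frame(
    category = category, food_group = food_group,
    classification = classification,
    serving_size_g_edible = serving_size_g_edible,
    servings_per_week = servings_per_week,
    g_per_week_production = g_per_week_production,
    edible_fraction = edible_fraction,
    wf_green_per_kg = wf_per_kg[["green"]],
    wf_blue_per_kg = wf_per_kg[["blue"]],
    wf_grey_per_kg = wf_per_kg[["grey"]],
    kcal_per_100g = kcal_per_100g, protein_per_100g = protein_per_100g,
    stringsAsFactors = FALSE)
  class(out) <- c("diet_entry", "data.frame")
  out
}

#' A named dietary pattern: the unit the pipeline aggregates
#'
#' @param name Pattern label (e.g. `"italy"`).
#' @param entries A list of [diet_entry()]s or a data frame with their
#'   columns.
#' @param target_kcal_per_day Target energy of the pattern, kcal/day.
#' @param mass_tol Relative slack allowed in the consistency check
#'   `g_per_week_production >= serving * servings` (edible fraction cannot
#'   exceed 1). Published tables round serving counts after energy
#'   rescaling, so their implied edible mass can exceed the printed
#'   production mass by a few percent; default 0 (strict).
#' @return An object of class `dietary_pattern`.
#' @export
dietary_pattern <- function(name, entries, target_kcal_per_day = NA_real_,
                            mass_tol = 0) {
  if (is.data.frame(entries)) df <- as.data.frame(entries)
  else df <- do.call(rbind, lapply(entries, as.data.frame))
  if (is.null(df) || nrow(df) == 0L)
    stop("a pattern needs at least one entry", call. = FALSE)
  if (anyDuplicated(df$category))
    stop(sprintf("duplicate categories: %s",
                 paste(unique(df$category[duplicated(df$category)]),
                       collapse = ", ")), call. = FALSE)
  needed <- c("category", "classification", "serving_size_g_edible",
              "servings_per_week", "g_per_week_production",
              "wf_green_per_kg", "wf_blue_per_kg", "wf_grey_per_kg")
  miss <- setdiff(needed, names(df))
  if (length(miss))
    stop(sprintf("entries lack columns: %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  if (!"food_group" %in% names(df)) df$food_group <- NA_character_
  if (!"edible_fraction" %in% names(df)) df$edible_fraction <- NA_real_
  if (!"kcal_per_100g" %in% names(df)) df$kcal_per_100g <- NA_real_
  if (!"protein_per_100g" %in% names(df)) df$protein_per_100g <- NA_real_
  bad <- !df$classification %in% c("animal", "plant", "other")
  if (any(bad))
    stop(sprintf("invalid classification for: %s",
                 paste(df$category[bad], collapse = ", ")), call. = FALSE)
  wf <- as.matrix(df[, c("wf_green_per_kg", "wf_blue_per_kg", "wf_grey_per_kg")])
  if (any(wf < 0) || anyNA(wf))
    stop("WF/kg components must be non-negative and known", call. = FALSE)
  edible <- df$serving_size_g_edible * df$servings_per_week
  short <- df$g_per_week_production < edible * (1 - mass_tol) - 1e-9
  if (any(short))
    stop(sprintf(
      "production mass below edible mass (edible fraction > 1) for: %s",
      paste(df$category[short], collapse = ", ")), call. = FALSE)
  rownames(df) <- NULL
  structure(list(name = name, entries = df,
                 target_kcal_per_day = target_kcal_per_day),
            class = "dietary_pattern")
}

#' @export
print.dietary_pattern <- function(x, ...) {
  cat(sprintf("<dietary_pattern> %s: %d categories, target %s kcal/day\n",
              x$name, nrow(x$entries),
              ifelse(is.na(x$target_kcal_per_day), "?",
                     format(x$target_kcal_per_day))))
  print(utils::head(x$entries[, c("category", "classification",
                                  "serving_size_g_edible",
                                  "servings_per_week",
                                  "g_per_week_production")], 10))
  if (nrow(x$entries) > 10) cat("...\n")
  invisible(x)
}

# per-kg wf_vector of one entry row
entry_wf_per_kg <- function(entries, i) {
  wf_vector(entries$wf_green_per_kg[i], entries$wf_blue_per_kg[i],
            entries$wf_grey_per_kg[i])
}

#' Average a minimum and a maximum serving pattern
#'
#' Guidelines that state serving ranges (e.g. 2--3 servings/day) are turned
#' into two patterns, one at the minimum and one at the maximum; their
#' category-wise mean of servings/week gives the working pattern, which is
#' then rescaled to the target energy.
#'
#' @param spec_min,spec_max [dietary_pattern()]s over the same categories.
#' @return A `dietary_pattern` with averaged `servings_per_week` (and
#'   production masses rescaled in proportion per category).
#' @export
average_min_max <- function(spec_min, spec_max) {
  a <- spec_min$entries; b <- spec_max$entries
  if (!setequal(a$category, b$category))
    stop("min and max patterns must cover the same categories", call. = FALSE)
  b <- b[match(a$category, b$category), ]
  out <- a
  mean_serv <- (a$servings_per_week + b$servings_per_week) / 2
  # carry production mass in proportion to servings (same per-serving mass)
  per_serv_a <- ifelse(a$servings_per_week > 0,
                       a$g_per_week_production / a$servings_per_week,
                       a$serving_size_g_edible / pmin(a$edible_fraction, 1,
                                                     na.rm = TRUE))
  out$servings_per_week <- mean_serv
  out$g_per_week_production <- per_serv_a * mean_serv
  dietary_pattern(spec_min$name, out,
                  target_kcal_per_day = spec_min$target_kcal_per_day)
}

#' Daily energy of a pattern from a composition table
#'
#' @param p A [dietary_pattern()].
#' @param composition Optional data frame with columns `category` and
#'   `kcal_per_100g` (per 100 g edible weight); when absent, the entries'
#'   own `kcal_per_100g` are used.
#' @return Energy in kcal per day:
#'   `sum(serving_g_edible * servings_week * kcal_per_100g / 100) / 7`.
#' @export
pattern_energy <- function(p, composition = NULL) {
  e <- p$entries
  kcal <- lookup_composition(e, composition, "kcal_per_100g")
  sum(e$serving_size_g_edible * e$servings_per_week * kcal / 100) / 7
}

lookup_composition <- function(entries, composition, col) {
  if (is.null(composition)) {
    vals <- entries[[col]]
  } else {
    idx <- match(entries$category, composition$category)
    vals <- composition[[col]][idx]
  }
  if (anyNA(vals))
    stop(sprintf("no %s for: %s", col,
                 paste(entries$category[is.na(vals)], collapse = ", ")),
         call. = FALSE)
  vals
}

#' Proportionally rescale a pattern to a target daily energy
#'
#' Every entry's servings/week (and with it the weekly production mass) is
#' multiplied by `target / pattern_energy(p)`, so serving ratios between
#' categories are preserved exactly; indulgence entries rescale like all
#' others.
#'
#' @inheritParams pattern_energy
#' @param target_kcal_per_day Target energy, kcal/day (default 2000).
#' @return The rescaled `dietary_pattern`, whose energy equals the target.
#' @export
rescale_to_energy <- function(p, target_kcal_per_day = 2000,
                              composition = NULL) {
  cur <- pattern_energy(p, composition)
  if (cur <= 0) stop("cannot rescale a zero-energy pattern", call. = FALSE)
  f <- target_kcal_per_day / cur
  e <- p$entries
  e$servings_per_week <- e$servings_per_week * f
  e$g_per_week_production <- e$g_per_week_production * f
  out <- p
  out$entries <- e
  out$target_kcal_per_day <- target_kcal_per_day
  out
}

#' Classify a food category as animal, plant, or other
#'
#' Animal covers the meat, poultry, egg, seafood, and dairy groups; "other"
#' covers discretionary (indulgence) items such as sugar, jam, and alcohol;
#' everything else is plant, including the whole fats group (butter rides
#' with the oils on the plant side of the animal/plant split used in
#' contribution analyses).
#'
#' @param category Category label(s).
#' @param taxonomy Named character vector mapping category to one of
#'   `"animal"`, `"plant"`, `"other"`.
#' @return Classification label(s); unmapped categories are an error, never
#'   silently defaulted.
#' @export
classify_entry <- function(category, taxonomy) {
  out <- unname(taxonomy[category])
  if (anyNA(out))
    stop(sprintf("unmapped categories: %s",
                 paste(category[is.na(out)], collapse = ", ")), call. = FALSE)
  bad <- !out %in% c("animal", "plant", "other")
  if (any(bad))
    stop(sprintf("taxonomy assigns invalid classes: %s",
                 paste(unique(out[bad]), collapse = ", ")), call. = FALSE)
  out
}
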