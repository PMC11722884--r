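#' Read a food water-footprint database from CSV
#'
#' Expected columns: `name`, `green_l_per_kg`, `blue_l_per_kg`,
#' `grey_l_per_kg`, `edible_fraction`, and optionally `kcal_per_100g`,
#' `protein_per_100g` (empty = unknown). Malformed rows are reported with
#' their line number in the file.
#'
#' @param path CSV file path.
#' @return A data frame of class `wf_food_db`.
#' @export
read_food_db <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  db <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("name", "green_l_per_kg", "blue_l_per_kg", "grey_l_per_kg",
                "edible_fraction")
  miss <- setdiff(required, names(db))
  if (length(miss))
    stop(sprintf("%s: missing columns: %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  if (!"kcal_per_100g" %in% names(db))
    db$kcal_per_100g <- rep(NA_real_, nrow(db))
  if (!"protein_per_100g" %in% names(db))
    db$protein_per_100g <- rep(NA_real_, nrow(db))
  db$edible_fraction[is.na(db$edible_fraction)] <- 1
  problems <- character()
  for (i in seq_len(nrow(db))) {
    line <- i + 1L                       # header is line 1
    wf <- c(db$green_l_per_kg[i], db$blue_l_per_kg[i], db$grey_l_per_kg[i])
    if (anyNA(wf) || any(wf < 0))
      problems <- c(problems, sprintf(
        "line %d (%s): WF components must be non-negative numbers",
        line, db$name[i]))
    if (db$edible_fraction[i] <= 0 || db$edible_fraction[i] > 1)
      problems <- c(problems, sprintf(
        "line %d (%s): edible_fraction must be in (0, 1]", line, db$name[i]))
    for (col in c("kcal_per_100g", "protein_per_100g"))
      if (!is.na(db[[col]][i]) && db[[col]][i] < 0)
        problems <- c(problems, sprintf(
          "line %d (%s): %s must be >= 0", line, db$name[i], col))
  }
  if (length(problems))
    stop(paste(c(sprintf("invalid food database %s:", path), problems),
               collapse = "\n  "), call. = FALSE)
  structure(db, class = c("wf_food_db", "data.frame"))
}

#' @rdname read_food_db
#' @param db A `wf_food_db` data frame.
#' @export
write_food_db <- function(db, path) {
  utils::write.csv(as.data.frame(db), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Look up one food of a database as a food_record
#'
#' @param db A `wf_food_db` data frame.
#' @param name Food name present in `db`.
#' @export
db_food <- function(db, name) {
  i <- match(name, db$name)
  if (is.na(i)) stop(sprintf("unknown food: %s", name), call. = FALSE)
  food_record(db$name[i],
              wf_vector(db$green_l_per_kg[i], db$blue_l_per_kg[i],
                        db$grey_l_per_kg[i]),
              edible_fraction = db$edible_fraction[i],
              kcal_per_100g = db$kcal_per_100g[i],
              protein_per_100g = db$protein_per_100g[i])
}

#' Read a dietary-pattern specification (YAML or JSON)
#'
#' A spec names the pattern and lists categories; each category gives a
#' serving size in g edible weight, either `servings_week` or a
#' `servings_day_min`/`servings_day_max` range, a classification, and its
#' footprint source: explicit `wf_green_per_kg`/`wf_blue_per_kg`/
#' `wf_grey_per_kg`, a single `food` from the database, or `members` (a
#' list of database foods averaged with `weighting`, optionally
#' `member_serving_g` for serving-weighted averages). Optional fields:
#' `food_group`, `edible_fraction`, `kcal_per_100g`, `protein_per_100g`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return The parsed spec (a list); resolve it with [resolve_pattern()].
#' @export
read_pattern_spec <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  spec <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
          else if (ext == "json") jsonlite::read_json(path, simplifyVector = FALSE)
          else stop("pattern specs must be YAML or JSON", call. = FALSE)
  if (is.null(spec$categories) || !length(spec$categories))
    stop(sprintf("%s: spec has no categories", path), call. = FALSE)
  cats <- vapply(spec$categories, function(x) x$category %||% "", "")
  if (any(!nzchar(cats)))
    stop(sprintf("%s: every category needs a name", path), call. = FALSE)
  if (anyDuplicated(cats))
    stop(sprintf("%s: duplicate categories: %s", path,
                 paste(unique(cats[duplicated(cats)]), collapse = ", ")),
         call. = FALSE)
  spec
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Resolve a pattern specification against a food database
#'
#' Categories with a `servings_day_min`/`servings_day_max` range are built
#' as a minimum and a maximum pattern, averaged with [average_min_max()],
#' and — when the spec carries a `target_kcal_per_day` and composition data
#' are available — rescaled with [rescale_to_energy()].
#'
#' @param spec A spec from [read_pattern_spec()] (or an equivalent list).
#' @param db Optional `wf_food_db`, needed when categories reference foods.
#' @param rescale Rescale to `spec$target_kcal_per_day` when a range spec is
#'   given (default TRUE when energy data allow it).
#' @return A resolved [dietary_pattern()].
#' @export
resolve_pattern <- function(spec, db = NULL, rescale = TRUE) {
  resolve_cat <- function(x, servings_week) {
    wf <- if (!is.null(x$wf_green_per_kg)) {
      wf_vector(x$wf_green_per_kg, x$wf_blue_per_kg %||% 0,
                x$wf_grey_per_kg %||% 0)
    } else if (!is.null(x$food)) {
      db_food(need_db(db), x$food)$wf_per_kg
    } else if (!is.null(x$members)) {
      members <- lapply(unlist(x$members), function(m) db_food(need_db(db), m))
      wgt <- if (!is.null(x$member_serving_g))
        group_weighting("serving_weighted", unlist(x$member_serving_g))
      else group_weighting(x$weighting %||% "simple_mean")
      group_wf(members, wgt)
    } else {
      stop(sprintf("category '%s': no WF source (wf_*_per_kg, food, or members)",
                   x$category), call. = FALSE)
    }
    if (is.null(x$serving_g_edible))
      stop(sprintf("category '%s': missing serving_g_edible", x$category),
           call. = FALSE)
    diet_entry(
      category = x$category,
      serving_size_g_edible = x$serving_g_edible,
      servings_per_week = servings_week,
      wf_per_kg = wf,
      classification = x$classification %||% "plant",
      edible_fraction = x$edible_fraction %||% 1,
      food_group = x$food_group %||% NA_character_,
      kcal_per_100g = x$kcal_per_100g %||% NA_real_,
      protein_per_100g = x$protein_per_100g %||% NA_real_)
  }
  need_db <- function(db) {
    if (is.null(db)) stop("spec references foods but no database was given",
                          call. = FALSE)
    db
  }
  has_range <- vapply(spec$categories, function(x)
    !is.null(x$servings_day_min) || !is.null(x$servings_day_max), TRUE)
  week_of <- function(x, which) {
    if (!is.null(x$servings_week)) return(x$servings_week)
    lo <- x$servings_day_min; hi <- x$servings_day_max
    if (is.null(lo) && is.null(hi))
      stop(sprintf("category '%s': missing serving frequency", x$category),
           call. = FALSE)
    7 * (if (which == "min") (lo %||% hi) else (hi %||% lo))
  }
  name <- spec$name %||% "pattern"
  target <- spec$target_kcal_per_day %||% NA_real_
  if (!any(has_range)) {
    entries <- lapply(spec$categories, function(x)
      resolve_cat(x, week_of(x, "min")))
    return(dietary_pattern(name, entries, target_kcal_per_day = target))
  }
  p_min <- dietary_pattern(name, lapply(spec$categories, function(x)
    resolve_cat(x, week_of(x, "min"))), target_kcal_per_day = target)
  p_max <- dietary_pattern(name, lapply(spec$categories, function(x)
    resolve_cat(x, week_of(x, "max"))), target_kcal_per_day = target)
  p <- average_min_max(p_min, p_max)
  if (rescale && !is.na(target) && !anyNA(p$entries$kcal_per_100g))
    p <- rescale_to_energy(p, target)
  p
}

#' Write / read a report table as CSV
#'
#' `write_report_csv()` writes the rendered guideline-layout table;
#' `read_report_table()` reads such a file back and rebuilds a resolvable
#' pattern from its full-precision g/week and WF/kg columns (the `Total`
#' row is dropped).
#'
#' @param r A `wf_report`.
#' @param pattern The pattern the report was computed from.
#' @param path Output/input CSV path.
#' @export
write_report_csv <- function(r, pattern, path) {
  utils::write.csv(render_table(r, pattern), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_report_csv
#' @export
read_report_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab <- tab[tab$category != "Total", ]
  entries <- data.frame(
    category = tab$category,
    classification = "plant",
    serving_size_g_edible = tab$serving_size_g_edible,
    servings_per_week = tab$servings_per_week,
    g_per_week_production = tab$g_per_week,
    wf_green_per_kg = tab$wf_green_per_kg,
    wf_blue_per_kg = tab$wf_blue_per_kg,
    wf_grey_per_kg = tab$wf_grey_per_kg,
    stringsAsFactors = FALSE)
  dietary_pattern(basename(path), entries, mass_tol = 0.06)
}

#' Write a full-precision JSON report
#'
#' @param r A `wf_report`.
#' @param path Output path.
#' @export
write_report_json <- function(r, path) {
  out <- list(
    pattern = r$pattern,
    per_entry = r$per_entry,
    weekly_total = as.list(unclass(r$weekly_total)),
    weekly_total_l = wf_total(r$weekly_total),
    per_capita_day = as.list(unclass(r$per_capita_day)),
    per_capita_day_l = wf_total(r$per_capita_day),
    component_shares = as.list(r$component_shares),
    class_contributions = as.list(r$class_contributions),
    group_contributions = as.list(r$group_contributions))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
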