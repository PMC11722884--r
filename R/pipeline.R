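#' Weekly water footprint of one resolved entry
#'
#' `(g_per_week_production / 1000) * wf_per_kg`, componentwise.
#'
#' @param entry A [diet_entry()] (or one-row subset of a pattern's entries).
#' @return A [wf_vector()] in L/week.
#' @export
entry_weekly_wf <- function(entry) {
  wf_scale(wf_vector(entry$wf_green_per_kg, entry$wf_blue_per_kg,
                     entry$wf_grey_per_kg),
           entry$g_per_week_production / 1000)
}

#' Aggregate a dietary pattern into a water-footprint report
#'
#' The central computation: per-category weekly WFs (mass in kg times WF/kg,
#' componentwise), their sum as the pattern's weekly WF, the per-capita
#' daily WF (weekly / 7), the green/blue/grey component shares, and the
#' contribution of each classification (animal/plant/other) and, where
#' present, each food group to the weekly total.
#'
#' @param pattern A resolved [dietary_pattern()].
#' @return An object of class `wf_report` with elements `pattern` (name),
#'   `per_entry` (data frame with weekly `green`, `blue`, `grey`, `total`
#'   in L/week per category), `weekly_total` and `per_capita_day`
#'   ([wf_vector()]s), `component_shares` (fractions summing to 1),
#'   `class_contributions` and `group_contributions` (fractions summing
#'   to 1 over each partition).
#' @examples
#' p <- load_fixture("italy")
#' r <- diet_wf(p)
#' r$per_capita_day
#' @export
diet_wf <- function(pattern) {
  stopifnot(inherits(pattern, "dietary_pattern"))
  e <- pattern$entries
  kg <- e$g_per_week_production / 1000
  per <- data.frame(
    category = e$category,
    food_group = e$food_group,
    classification = e$classification,
    green = kg * e$wf_green_per_kg,
    blue = kg * e$wf_blue_per_kg,
    grey = kg * e$wf_grey_per_kg,
    stringsAsFactors = FALSE)
  per$total <- per$green + per$blue + per$grey
  weekly <- wf_vector(sum(per$green), sum(per$blue), sum(per$grey))
  tot <- wf_total(weekly)
  shares <- if (tot > 0) unclass(weekly) / tot else
    c(green = NA_real_, blue = NA_real_, grey = NA_real_)
  out <- list(
    pattern = pattern$name,
    per_entry = per,
    weekly_total = weekly,
    per_capita_day = per_capita_day(weekly),
    component_shares = shares,
    class_contributions = contribution_fractions(per, per$classification),
    group_contributions =
      if (all(!is.na(per$food_group)))
        contribution_fractions(per, per$food_group) else NULL)
  class(out) <- "wf_report"
  out
}

contribution_fractions <- function(per, groups) {
  s <- tapply(per$total, groups, sum)
  frac <- as.numeric(s) / sum(per$total)
  names(frac) <- names(s)
  frac
}

#' Per-capita daily water footprint
#'
#' @param weekly A [wf_vector()] in L/week.
#' @return A `wf_vector` in L per capita per day (weekly / 7).
#' @export
per_capita_day <- function(weekly) wf_scale(weekly, 1 / 7)

#' Green/blue/grey shares of a report's weekly total
#'
#' @param r A `wf_report` from [diet_wf()].
#' @return Named fractions summing to 1.
#' @export
component_shares <- function(r) {
  if (anyNA(r$component_shares))
    stop("zero-footprint pattern has no component shares", call. = FALSE)
  r$component_shares
}

#' Contribution of groups of entries to the weekly total
#'
#' @param r A `wf_report` from [diet_wf()].
#' @param by Either the name of a per-entry column (`"classification"` or
#'   `"food_group"`) or a named character vector mapping every category to a
#'   group (a taxonomy); the partition must cover all entries.
#' @return Named fractions of the weekly total, summing to 1.
#' @export
group_contribution <- function(r, by = "classification") {
  per <- r$per_entry
  if (is.character(by) && length(by) == 1L && by %in% names(per)) {
    g <- per[[by]]
    if (anyNA(g)) stop(sprintf("'%s' does not cover all entries", by),
                       call. = FALSE)
  } else {
    g <- unname(by[per$category])
    if (anyNA(g))
      stop(sprintf("unmapped categories: %s",
                   paste(per$category[is.na(g)], collapse = ", ")),
           call. = FALSE)
  }
  contribution_fractions(per, g)
}

#' @export
print.wf_report <- function(x, ...) {
  wt <- x$weekly_total
  cat(sprintf("<wf_report> %s (%d categories)\n", x$pattern,
              nrow(x$per_entry)))
  cat(sprintf("  weekly WF:  %7.0f green  %6.0f blue  %6.0f grey  = %7.0f L/week\n",
              wt[["green"]], wt[["blue"]], wt[["grey"]], wf_total(wt)))
  pd <- x$per_capita_day
  cat(sprintf("  per capita: %7.0f green  %6.0f blue  %6.0f grey  = %7.0f L/day\n",
              pd[["green"]], pd[["blue"]], pd[["grey"]], wf_total(pd)))
  cat(sprintf("  shares:     green %.0f%%, blue %.0f%%, grey %.0f%%\n",
              100 * x$component_shares[["green"]],
              100 * x$component_shares[["blue"]],
              100 * x$component_shares[["grey"]]))
  invisible(x)
}

#' @export
summary.wf_report <- function(object, ...) {
  print(object)
  cat("  contributions by classification:\n")
  for (n in names(object$class_contributions))
    cat(sprintf("    %-8s %5.1f%%\n", n,
                100 * object$class_contributions[[n]]))
  if (!is.null(object$group_contributions)) {
    cat("  contributions by food group:\n")
    for (n in names(object$group_contributions))
      cat(sprintf("    %-18s %5.1f%%\n", n,
                  100 * object$group_contributions[[n]]))
  }
  invisible(object)
}

#' @export
as.data.frame.wf_report <- function(x, ...) x$per_entry

#' Render a report in the guideline-table column layout
#'
#' One row per category with serving size, servings/week, g/week, WF/kg
#' (green, blue, grey, total) and weekly WF (green, blue, grey, total), plus
#' a `Total` row; weekly cells are rounded half away from zero to whole
#' litres, the convention of published WF tables. Full-precision values stay
#' in the report; rounding happens only here.
#'
#' @param r A `wf_report` from [diet_wf()].
#' @param pattern The `dietary_pattern` the report was computed from.
#' @param digits Decimal places for the weekly WF cells (default 0).
#' @return A data frame in the table layout.
#' @export
render_table <- function(r, pattern, digits = 0) {
  e <- pattern$entries
  per <- r$per_entry
  stopifnot(identical(e$category, per$category))
  out <- data.frame(
    category = e$category,
    serving_size_g_edible = e$serving_size_g_edible,
    servings_per_week = e$servings_per_week,
    g_per_week = round_half_up(e$g_per_week_production, 2),
    wf_green_per_kg = e$wf_green_per_kg,
    wf_blue_per_kg = e$wf_blue_per_kg,
    wf_grey_per_kg = e$wf_grey_per_kg,
    wf_total_per_kg = e$wf_green_per_kg + e$wf_blue_per_kg + e$wf_grey_per_kg,
    week_green = round_half_up(per$green, digits),
    week_blue = round_half_up(per$blue, digits),
    week_grey = round_half_up(per$grey, digits),
    week_total = round_half_up(per$total, digits),
    stringsAsFactors = FALSE)
  wt <- r$weekly_total
  total_row <- data.frame(
    category = "Total", serving_size_g_edible = NA, servings_per_week = NA,
    g_per_week = NA, wf_green_per_kg = NA, wf_blue_per_kg = NA,
    wf_grey_per_kg = NA, wf_total_per_kg = NA,
    week_green = round_half_up(wt[["green"]], digits),
    week_blue = round_half_up(wt[["blue"]], digits),
    week_grey = round_half_up(wt[["grey"]], digits),
    week_total = round_half_up(wf_total(wt), digits),
    stringsAsFactors = FALSE)
  rbind(out, total_row)
}
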