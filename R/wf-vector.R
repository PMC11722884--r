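#' Green/blue/grey water footprint triple
#'
#' A `wf_vector` holds the three components of a water footprint (WF) in a
#' common unit, typically L per kg of production weight or L per week for a
#' resolved diet entry. The green component is rainwater evapotranspired
#' during production, the blue component surface and groundwater consumed,
#' and the grey component the freshwater volume needed to assimilate
#' pollutant loads. The total WF is always derived as their sum and never
#' stored independently.
#'
#' @param green,blue,grey Non-negative scalars, all in the same unit.
#' @return An object of class `wf_vector`: a named numeric vector with
#'   elements `green`, `blue`, `grey`.
#' @examples
#' v <- wf_vector(9661, 505, 537)   # red meat, L/kg
#' wf_total(v)
#' @export
wf_vector <- function(green, blue, grey) {
  comp <- c(green = as.numeric(green), blue = as.numeric(blue),
            grey = as.numeric(grey))
  if (length(comp) != 3L || anyNA(comp) || any(!is.finite(comp)))
    stop("wf_vector components must be three finite scalars", call. = FALSE)
  if (any(comp < 0))
    stop("wf_vector components must be non-negative", call. = FALSE)
  structure(comp, class = "wf_vector")
}

#' @rdname wf_vector
#' @param x Object to test or coerce.
#' @export
is_wf_vector <- function(x) inherits(x, "wf_vector")

#' @rdname wf_vector
#' @export
as_wf_vector <- function(x) {
  if (is_wf_vector(x)) return(x)
  if (is.numeric(x) && length(x) == 3L) return(wf_vector(x[[1]], x[[2]], x[[3]]))
  if (is.list(x) && all(c("green", "blue", "grey") %in% names(x)))
    return(wf_vector(x$green, x$blue, x$grey))
  stop("cannot coerce to wf_vector", call. = FALSE)
}

#' Total water footprint of a component triple
#'
#' @param v A [wf_vector()].
#' @return `green + blue + grey`, a scalar in the unit of `v`.
#' @export
wf_total <- function(v) {
  v <- as_wf_vector(v)
  sum(unclass(v))
}

#' Scale a water footprint by a non-negative factor
#'
#' Componentwise multiplication; the total scales by the same factor. Used to
#' convert L/kg to L/week (multiply by kg consumed per week) and for the
#' proportional adjustments of pattern construction.
#'
#' @param v A [wf_vector()].
#' @param k Non-negative scalar.
#' @export
wf_scale <- function(v, k) {
  v <- as_wf_vector(v)
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 0)
    stop("scale factor must be a single non-negative number", call. = FALSE)
  structure(unclass(v) * k, class = "wf_vector")
}

#' Add two water footprints of the same unit
#'
#' @param a,b [wf_vector()]s in the same unit.
#' @export
wf_add <- function(a, b) {
  a <- as_wf_vector(a); b <- as_wf_vector(b)
  structure(unclass(a) + unclass(b), class = "wf_vector")
}

#' @export
Ops.wf_vector <- function(e1, e2) {
  if (.Generic == "+") return(wf_add(e1, e2))
  if (.Generic == "-") {
    a <- if (is_wf_vector(e1)) unclass(e1) else e1
    b <- if (is_wf_vector(e2)) unclass(e2) else e2
    # a difference may be negative (scenario deltas); plain named numeric
    return(a - b)
  }
  if (.Generic == "*") {
    if (is.numeric(e2) && length(e2) == 1L) return(wf_scale(e1, e2))
    if (is.numeric(e1) && length(e1) == 1L) return(wf_scale(e2, e1))
  }
  stop(sprintf("'%s' not defined for wf_vector", .Generic), call. = FALSE)
}

#' @export
print.wf_vector <- function(x, digits = 1, ...) {
  cat(sprintf("WF (green/blue/grey): %s / %s / %s  total %s\n",
              format(round(x[["green"]], digits)),
              format(round(x[["blue"]], digits)),
              format(round(x[["grey"]], digits)),
              format(round(wf_total(x), digits))))
  invisible(x)
}

#' Conversion constants for pattern construction
#'
#' Single place for the constants used when resolving guideline patterns:
#' the cooked-to-dry legume mass factor, the assumed aquaculture share of
#' consumed seafood (wild-caught fish carries 0 L/kg), and the fruit and
#' sugar content fractions of jam.
#'
#' @param cooked_to_dry Factor dividing cooked legume mass to get dry mass.
#' @param aquaculture_fraction Share of seafood consumption assumed farmed.
#' @param jam_fruit_fraction,jam_sugar_fraction Mass fractions of fruit and
#'   sugar in jam.
#' @return A named list of the four constants.
#' @export
wf_constants <- function(cooked_to_dry = 2.5,
                         aquaculture_fraction = 0.5,
                         jam_fruit_fraction = 0.35,
                         jam_sugar_fraction = 0.40) {
  stopifnot(cooked_to_dry > 0, aquaculture_fraction >= 0,
            aquaculture_fraction <= 1, jam_fruit_fraction > 0,
            jam_sugar_fraction > 0)
  list(cooked_to_dry = cooked_to_dry,
       aquaculture_fraction = aquaculture_fraction,
       jam_fruit_fraction = jam_fruit_fraction,
       jam_sugar_fraction = jam_sugar_fraction)
}

#' Composite water footprint of jam
#'
#' Jam is modelled as a fixed-composition composite of fruit and sugar:
#' `fruit_fraction * fruit + sugar_fraction * sugar`, componentwise, with the
#' remaining mass (water) carrying no footprint.
#'
#' @param fruit,sugar [wf_vector()]s in L/kg.
#' @param fruit_fraction,sugar_fraction Mass fractions; defaults 0.35 / 0.40.
#' @return A `wf_vector` in L/kg.
#' @export
jam_wf <- function(fruit, sugar, fruit_fraction = 0.35, sugar_fraction = 0.40) {
  wf_add(wf_scale(fruit, fruit_fraction), wf_scale(sugar, sugar_fraction))
}

#' Cooked to dry legume mass
#'
#' WF databases report dried legumes while serving sizes may be given as
#' cooked mass; dividing by the swelling factor recovers the dry mass the
#' footprint applies to.
#'
#' @param mass_cooked_g Cooked mass in grams, `>= 0`.
#' @param factor Swelling factor, default 2.5.
#' @export
cooked_to_dry_mass <- function(mass_cooked_g, factor = 2.5) {
  if (any(mass_cooked_g < 0)) stop("mass must be non-negative", call. = FALSE)
  if (factor <= 0) stop("factor must be positive", call. = FALSE)
  mass_cooked_g / factor
}

#' Seafood mass charged against the aquaculture footprint
#'
#' Wild-caught fish is assigned 0 L/kg, so only the farmed share of suggested
#' seafood consumption carries the aquaculture WF. The discount applies to
#' the MASS charged, not to the WF per kg, matching how resolved patterns
#' keep the full aquaculture WF/kg alongside a halved g/week.
#'
#' @param mass_suggested_g Suggested consumption in g.
#' @param aquaculture_fraction Share assumed farmed, in \[0, 1\]; default 0.5.
#' @return Mass in g to which the aquaculture WF/kg applies.
#' @export
effective_seafood_mass <- function(mass_suggested_g, aquaculture_fraction = 0.5) {
  if (any(mass_suggested_g < 0)) stop("mass must be non-negative", call. = FALSE)
  if (aquaculture_fraction < 0 || aquaculture_fraction > 1)
    stop("aquaculture_fraction must be in [0, 1]", call. = FALSE)
  mass_suggested_g * aquaculture_fraction
}

# round half away from zero, the convention of the printed tables
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
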