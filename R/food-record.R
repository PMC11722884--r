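#' A single food with its water footprint and conversion data
#'
#' @param name Food identifier.
#' @param wf_per_kg A [wf_vector()] in L per kg of production weight.
#' @param edible_fraction Edible share of production weight, in (0, 1].
#' @param kcal_per_100g,protein_per_100g Optional composition values per
#'   100 g edible weight (`NA` = unknown).
#' @return An object of class `food_record`.
#' @export
food_record <- function(name, wf_per_kg, edible_fraction = 1,
                        kcal_per_100g = NA_real_, protein_per_100g = NA_real_) {
  wf_per_kg <- as_wf_vector(wf_per_kg)
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("food name must be a non-empty string", call. = FALSE)
  if (edible_fraction <= 0 || edible_fraction > 1)
    stop(sprintf("edible_fraction of '%s' must be in (0, 1]", name),
         call. = FALSE)
  for (v in c(kcal_per_100g, protein_per_100g))
    if (!is.na(v) && v < 0)
      stop(sprintf("composition values of '%s' must be >= 0", name),
           call. = FALSE)
  structure(list(name = name, wf_per_kg = wf_per_kg,
                 edible_fraction = as.numeric(edible_fraction),
                 kcal_per_100g = as.numeric(kcal_per_100g),
                 protein_per_100g = as.numeric(protein_per_100g)),
            class = "food_record")
}

#' @export
print.food_record <- function(x, ...) {
  cat(sprintf("<food_record> %s  edible %.2f  kcal/100g %s  protein/100g %s\n",
              x$name, x$edible_fraction,
              ifelse(is.na(x$kcal_per_100g), "?", x$kcal_per_100g),
              ifelse(is.na(x$protein_per_100g), "?", x$protein_per_100g)))
  print(x$wf_per_kg)
  invisible(x)
}

#' Group-averaging scheme for a guideline food group
#'
#' Guidelines list member foods for a group without individual frequencies;
#' the group WF/kg is then an average over members. Three schemes are
#' supported: `simple_mean` (unweighted componentwise mean), `serving_weighted`
#' (each member contributes its per-serving WF; the group WF/kg is the mean
#' per-serving WF divided by the mean serving mass, as with cup-equivalent
#' dairy servings), and `consumption_weighted` (shares summing to 1).
#'
#' @param mode One of `"simple_mean"`, `"serving_weighted"`,
#'   `"consumption_weighted"`.
#' @param weights For `serving_weighted`, positive per-member serving masses
#'   in g; for `consumption_weighted`, shares summing to 1; ignored for
#'   `simple_mean`.
#' @export
group_weighting <- function(mode = c("simple_mean", "serving_weighted",
                                     "consumption_weighted"),
                            weights = NULL) {
  mode <- match.arg(mode)
  if (mode == "serving_weighted") {
    if (is.null(weights) || any(weights <= 0))
      stop("serving_weighted needs a positive serving mass per member",
           call. = FALSE)
  }
  if (mode == "consumption_weighted") {
    if (is.null(weights) || abs(sum(weights) - 1) > 1e-9 || any(weights < 0))
      stop("consumption_weighted needs non-negative shares summing to 1",
           call. = FALSE)
  }
  structure(list(mode = mode, weights = weights), class = "group_weighting")
}

#' Average the water footprints of a food group's members
#'
#' @param members A list of [food_record()]s (or `wf_vector`s in L/kg).
#' @param weighting A [group_weighting()]; default simple mean.
#' @return A [wf_vector()] in L/kg for the group.
#' @examples
#' a <- wf_vector(1000, 0, 0); b <- wf_vector(3000, 0, 0)
#' group_wf(list(a, b))                                   # (2000, 0, 0)
#' group_wf(list(a, b), group_weighting("serving_weighted",
#'                                      weights = c(244, 43)))
#' @export
group_wf <- function(members, weighting = group_weighting("simple_mean")) {
  if (length(members) == 0L) stop("empty member list", call. = FALSE)
  wf <- lapply(members, function(m) {
    if (inherits(m, "food_record")) m$wf_per_kg else as_wf_vector(m)
  })
  mat <- do.call(rbind, lapply(wf, unclass))
  w <- weighting$weights
  if (!is.null(w) && length(w) != length(members))
    stop("one weight per member required", call. = FALSE)
  comp <- switch(weighting$mode,
    simple_mean = colMeans(mat),
    consumption_weighted = colSums(mat * w),
    serving_weighted = {
      kg <- w / 1000                       # serving masses in kg
      per_serving <- mat * kg              # L per serving, componentwise
      colMeans(per_serving) / mean(kg)     # back to L/kg
    })
  wf_vector(comp[[1]], comp[[2]], comp[[3]])
}
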