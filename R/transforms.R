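#' Age transforms for clock regression
#'
#' An epigenetic clock regresses a transform of chronological age on CpG
#' beta values. Three transforms are supported:
#'
#' * `identity`: age in years, unchanged. Used for single-species clocks
#'   over a limited age range.
#' * `loglinear`: a piecewise map, logarithmic before an adult-age knot and
#'   linear after it, continuous with matching first derivative at the knot.
#'   This lets a single linear model cover the fast methylation drift of
#'   development and the slower drift of adulthood, and is the standard
#'   transform for dual-species chronological clocks.
#' * `relative`: age divided by the species' maximum recorded lifespan, so
#'   that species of very different longevity share a common regression
#'   scale in \[0, 1\]. A marmoset and a human land on the same value
#'   exactly when their age/maxLifespan ratios agree.
#'
#' Parameters (`max_lifespan`, `adult_age`) are named numeric vectors keyed
#' by species label, or a single unnamed value applied to every species.
#' The latter is how a dual-species *chronological* clock is built: one
#' common formula maps ages in years for both species (e.g.
#' `age_transform("loglinear", adult_age = 15)`), which is precisely what
#' introduces the skew between short- and long-lived species that the
#' relative-age transform removes. Defaults are the marmoset/human
#' constants used throughout: maximum lifespans 22.8 and 122.5 years,
#' adult-age knots 2 and 15 years, knot offset 1 year.
#'
#' @param kind one of `"identity"`, `"loglinear"`, `"relative"`.
#' @param max_lifespan named numeric vector of maximum lifespans in years
#'   (used by `kind = "relative"`).
#' @param adult_age named numeric vector of adult-age knots in years
#'   (used by `kind = "loglinear"`).
#' @param offset positive offset in years added inside the logarithm of the
#'   log-linear map (used by `kind = "loglinear"`).
#' @return an object of class `age_transform`.
#' @examples
#' tr <- age_transform("relative")
#' transform_age(tr, 11.4, species = "marmoset")  # 0.5
#' @export
age_transform <- function(kind = c("identity", "loglinear", "relative"),
                          max_lifespan = c(marmoset = 22.8, human = 122.5),
                          adult_age = c(marmoset = 2, human = 15),
                          offset = 1) {
  kind <- match.arg(kind)
  if (kind == "relative") {
    if (any(!is.finite(max_lifespan)) || any(max_lifespan <= 0))
      stop("all maximum lifespans must be positive and finite")
  }
  if (kind == "loglinear") {
    if (any(!is.finite(adult_age)) || any(adult_age <= 0))
      stop("all adult ages must be positive and finite")
    if (!is.finite(offset) || offset <= 0)
      stop("'offset' must be positive")
  }
  structure(
    list(kind = kind,
         max_lifespan = max_lifespan,
         adult_age = adult_age,
         offset = offset),
    class = "age_transform"
  )
}

#' @export
print.age_transform <- function(x, ...) {
  cat("Age transform:", x$kind, "\n")
  if (x$kind == "relative") {
    cat("  max lifespan (y):",
        paste(names(x$max_lifespan), x$max_lifespan, sep = " = ",
              collapse = ", "), "\n")
  }
  if (x$kind == "loglinear") {
    cat("  adult age (y):",
        paste(names(x$adult_age), x$adult_age, sep = " = ",
              collapse = ", "), "\n")
    cat("  offset (y):", x$offset, "\n")
  }
  invisible(x)
}

## a single unnamed value is a species-independent ("single formula")
## parameter; a named vector is looked up per species
.species_param <- function(param, species, what, n) {
  if (is.null(names(param)) && length(param) == 1L)
    return(rep(param, n))
  if (is.null(species))
    stop("'species' is required when ", what, " is per-species")
  species <- rep_len(as.character(species), n)
  miss <- setdiff(unique(species), names(param))
  if (length(miss))
    stop("no ", what, " for species: ", paste(miss, collapse = ", "))
  unname(param[species])
}

#' Map chronological age onto the regression scale
#'
#' @param transform an [age_transform()] object.
#' @param age_years numeric vector of ages in years, all `>= 0`.
#' @param species character vector of species labels, recycled to the
#'   length of `age_years`; required for the `relative` and `loglinear`
#'   kinds, ignored by `identity`.
#' @return numeric vector on the regression scale.
#' @export
transform_age <- function(transform, age_years, species = NULL) {
  stopifnot(inherits(transform, "age_transform"))
  if (any(!is.finite(age_years)) || any(age_years < 0))
    stop("ages must be finite and non-negative")
  switch(transform$kind,
    identity = age_years,
    relative = {
      ml <- .species_param(transform$max_lifespan, species, "max lifespan",
                           length(age_years))
      to_relative_age(age_years, ml)
    },
    loglinear = {
      aa <- .species_param(transform$adult_age, species, "adult age",
                           length(age_years))
      loglinear_forward(age_years, aa, transform$offset)
    })
}

#' Map a regression-scale value back to age in years
#'
#' Exact inverse of [transform_age()] over the valid domain; the relative
#' kind is deliberately not clipped to \[0, 1\], so a prediction may exceed
#' the species' recorded maximum lifespan.
#'
#' @inheritParams transform_age
#' @param value numeric vector on the regression scale.
#' @return ages in years.
#' @export
inverse_age <- function(transform, value, species = NULL) {
  stopifnot(inherits(transform, "age_transform"))
  switch(transform$kind,
    identity = value,
    relative = {
      ml <- .species_param(transform$max_lifespan, species, "max lifespan",
                           length(value))
      from_relative_age(value, ml)
    },
    loglinear = {
      aa <- .species_param(transform$adult_age, species, "adult age",
                           length(value))
      loglinear_inverse(value, aa, transform$offset)
    })
}

#' Relative age: age divided by maximum lifespan
#'
#' `Relative age = Age / maxLifespan` puts species with very different
#' longevity on a shared \[0, 1\] aging scale. The result is not clipped at
#' 1: an individual may exceed its species' recorded maximum.
#'
#' @param age_years ages in years, `>= 0`.
#' @param max_lifespan_years maximum lifespan(s) in years, `> 0`.
#' @return `age_years / max_lifespan_years`.
#' @export
to_relative_age <- function(age_years, max_lifespan_years) {
  if (any(!is.finite(age_years)) || any(age_years < 0))
    stop("ages must be finite and non-negative")
  if (any(!is.finite(max_lifespan_years)) || any(max_lifespan_years <= 0))
    stop("maximum lifespan must be positive")
  age_years / max_lifespan_years
}

#' @rdname to_relative_age
#' @param relative_age fraction(s) of maximum lifespan.
#' @export
from_relative_age <- function(relative_age, max_lifespan_years) {
  if (any(!is.finite(max_lifespan_years)) || any(max_lifespan_years <= 0))
    stop("maximum lifespan must be positive")
  relative_age * max_lifespan_years
}

#' Log-linear age map
#'
#' `F(a) = log((a + offset) / (adult + offset))` for `a <= adult`, and
#' `F(a) = (a - adult) / (adult + offset)` for `a > adult`. Both branches
#' vanish at the knot `a = adult` and share the derivative
#' `1 / (adult + offset)` there, so the map is continuously differentiable
#' and strictly increasing. `loglinear_inverse` is its exact inverse.
#'
#' @param age_years ages in years, `>= 0`.
#' @param adult_age_years knot position(s) in years, `> 0`.
#' @param offset_years positive offset in years.
#' @return transformed value(s).
#' @export
loglinear_forward <- function(age_years, adult_age_years, offset_years = 1) {
  if (any(!is.finite(age_years)) || any(age_years < 0))
    stop("ages must be finite and non-negative")
  if (any(adult_age_years <= 0) || any(offset_years <= 0))
    stop("'adult_age_years' and 'offset_years' must be positive")
  adult <- rep_len(adult_age_years, length(age_years))
  k <- adult + offset_years
  ifelse(age_years <= adult,
         log((age_years + offset_years) / k),
         (age_years - adult) / k)
}

#' @rdname loglinear_forward
#' @param value transformed value(s).
#' @export
loglinear_inverse <- function(value, adult_age_years, offset_years = 1) {
  if (any(adult_age_years <= 0) || any(offset_years <= 0))
    stop("'adult_age_years' and 'offset_years' must be positive")
  adult <- rep_len(adult_age_years, length(value))
  k <- adult + offset_years
  ifelse(value <= 0,
         k * exp(value) - offset_years,
         adult + value * k)
}
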