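# Allometric scaling of embryonic developmental period (EDP) on egg
# mass, and the residuals used as the response of the comparative
# regression.
#
# The reference relationship is the Charadriiform power law
#   expected EDP (days) = a * egg mass (g) ^ b,  a = 17.18, b = 0.119.

#' Predicted EDP from egg mass
#'
#' Evaluates the Charadriiform allometric power law
#' \eqn{a \cdot m^{b}} giving the expected embryonic developmental
#' period (days) for a fresh egg of mass \eqn{m} grams.
#'
#' @param egg_mass Egg mass in grams (vectorized); must be positive.
#' @param a Allometric coefficient in days (default 17.18).
#' @param b Allometric exponent, dimensionless (default 0.119).
#' @return Predicted EDP in days.
#' @export
#' @examples
#' predicted_edp(95.7) # razorbill egg
predicted_edp <- function(egg_mass, a = 17.18, b = 0.119) {
  stopifnot(is.numeric(egg_mass), is.numeric(a), length(a) == 1L, a > 0,
            is.numeric(b), length(b) == 1L, is.finite(b))
  if (any(!is.na(egg_mass) & egg_mass <= 0)) {
    stop("egg mass must be positive", call. = FALSE)
  }
  a * egg_mass^b
}

#' EDP residual from the egg-mass allometry
#'
#' Observed minus allometrically predicted EDP. Positive values mean
#' slower-than-predicted embryonic development, negative values faster.
#'
#' @param edp_observed Observed EDP in days (vectorized).
#' @param egg_mass Egg mass in grams.
#' @inheritParams predicted_edp
#' @return Residual EDP in days.
#' @export
edp_residual <- function(edp_observed, egg_mass, a = 17.18, b = 0.119) {
  edp_observed - predicted_edp(egg_mass, a = a, b = b)
}

#' Per-species allometric residual table
#'
#' Computes predicted EDP and the allometric residual for every species
#' of a trait table, preserving input order. Residuals are carried at
#' full floating-point precision; any rounding (the published table
#' prints 2 decimals) is left to the caller.
#'
#' @param traits A data frame with at least columns \code{species},
#'   \code{edp_days} and \code{egg_mass_g} (as produced by
#'   [load_trait_table()]).
#' @inheritParams predicted_edp
#' @return A data frame with columns \code{species},
#'   \code{edp_observed}, \code{egg_mass}, \code{edp_predicted} and
#'   \code{edp_residual}.
#' @export
residual_table <- function(traits, a = 17.18, b = 0.119) {
  need <- c("species", "edp_days", "egg_mass_g")
  miss <- setdiff(need, names(traits))
  if (length(miss)) {
    stop("trait table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(traits) == 0L) {
    return(data.frame(species = character(0), edp_observed = numeric(0),
                      egg_mass = numeric(0), edp_predicted = numeric(0),
                      edp_residual = numeric(0), stringsAsFactors = FALSE))
  }
  bad <- is.na(traits$edp_days) | is.na(traits$egg_mass_g) |
    traits$edp_days <= 0 | traits$egg_mass_g <= 0
  if (any(bad)) {
    stop("missing or non-positive EDP/egg mass for: ",
         paste(traits$species[bad], collapse = ", "), call. = FALSE)
  }
  pred <- predicted_edp(traits$egg_mass_g, a = a, b = b)
  data.frame(
    species = traits$species,
    edp_observed = traits$edp_days,
    egg_mass = traits$egg_mass_g,
    edp_predicted = pred,
    edp_residual = traits$edp_days - pred,
    stringsAsFactors = FALSE
  )
}
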