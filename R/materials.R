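# Tissue-mixture material model for callus elements, plus the base material
# table for bone, implant and pure tissue phases (N-mm-MPa unit system).

#' Base material properties
#'
#' Young's modulus (MPa) and Poisson's ratio of the constituent materials.
#' Cortical bone is treated as isotropic with the compressive modulus; the
#' transverse tensile modulus is kept for the optional transversely
#' isotropic variant.  The fibrocartilage row lists the standalone tissue
#' modulus (200 MPa); note that the callus mixture rule deliberately uses
#' its own cartilage coefficient of 40 MPa and a Poisson ratio of 0.45 (see
#' [mixture_properties()]) -- the two values are not reconciled, and the
#' mixture coefficients can be overridden via the `coefficients` argument.
#'
#' @return data.frame with columns `material`, `E` (MPa), `nu`.
#' @export
base_materials <- function() {
  data.frame(
    material = c("cancellous", "cortical", "cortical_transverse", "woven_bone",
                 "fibrocartilage", "connective", "steel"),
    E  = c(155, 16700, 10000, 4000, 200, 3, 193000),
    nu = c(0.3, 0.3, 0.3, 0.3, 0.45, 0.3, 0.3),
    stringsAsFactors = FALSE
  )
}

#' Mixture rule for callus element properties
#'
#' Computes the effective Young's modulus and Poisson's ratio of a callus
#' element from its tissue composition by a weighted sum over the three
#' phases:
#' \deqn{E = 4000\,c_{bone} + 40\,c_{cartilage} + 3\,c_{conn} \;\mathrm{MPa}}
#' \deqn{\nu = 0.3\,c_{bone} + 0.45\,c_{cartilage} + 0.3\,c_{conn}}
#' where the concentrations (given in percent) are converted to weights in
#' `[0, 1]` before the sum.
#'
#' @param c_bone,c_cartilage,c_connective Tissue concentrations in percent;
#'   vectors of equal length.  Each element-wise triple must lie in
#'   `[0, 100]` and sum to 100 (tolerance 1e-9).
#' @param coefficients Optional override list with numeric vectors `E` and
#'   `nu`, each length 3 ordered (bone, cartilage, connective).
#' @return A list with numeric vectors `E` (MPa) and `nu`.
#' @examples
#' mixture_properties(100, 0, 0)   # woven bone: E = 4000, nu = 0.3
#' mixture_properties(0, 100, 0)   # cartilage:  E = 40,   nu = 0.45
#' @export
mixture_properties <- function(c_bone, c_cartilage, c_connective,
                               coefficients = NULL) {
  n <- length(c_bone)
  if (length(c_cartilage) != n || length(c_connective) != n) {
    stop("concentration vectors must have equal length")
  }
  vals <- c(c_bone, c_cartilage, c_connective)
  if (anyNA(vals) || any(vals < -1e-9) || any(vals > 100 + 1e-9)) {
    stop("tissue concentrations must lie in [0, 100] percent")
  }
  s <- c_bone + c_cartilage + c_connective
  if (any(abs(s - 100) > 1e-9)) {
    stop(sprintf("tissue concentrations must sum to 100%% (worst deviation %.3g)",
                 max(abs(s - 100))))
  }
  co <- list(E = c(4000, 40, 3), nu = c(0.3, 0.45, 0.3))
  if (!is.null(coefficients)) {
    co[names(coefficients)] <- coefficients
    stopifnot(length(co$E) == 3L, length(co$nu) == 3L)
  }
  wb <- c_bone / 100; wc <- c_cartilage / 100; wt <- c_connective / 100
  list(E  = co$E[1] * wb + co$E[2] * wc + co$E[3] * wt,
       nu = co$nu[1] * wb + co$nu[2] * wc + co$nu[3] * wt)
}
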