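#' Relative membrane O2 diffusivity
#'
#' The membrane O2 permeability, expressed as diffusivity relative to
#' seawater. In `"fixed"` mode it is the constant `eps_fixed`. In
#' `"dynamic"` mode it is regulated by intracellular O2 through a
#' Michaelis-Menten response,
#' `eps = eps_max * O2 / (O2 + k_O2_diff)`,
#' so the membrane opens when the cell is O2-loaded (venting photosynthetic
#' O2) and closes as intracellular O2 falls (shielding nitrogenase from
#' ambient O2).
#'
#' @param O2 intracellular O2 (mol m^-3), vectorized.
#' @param params a [tricho_params()] registry (fields `eps_max`, `k_O2_diff`,
#'   `eps_fixed`).
#' @param mode `"dynamic"` or `"fixed"`.
#' @return Relative diffusivity in `[0, eps_max]` (dimensionless).
#' @examples
#' p <- tricho_params()
#' relative_permeability(0.213, p, "dynamic")  # half of eps_max = 1e-4
#' @export
relative_permeability <- function(O2, params, mode = c("dynamic", "fixed")) {
  mode <- match.arg(mode)
  if (any(!is.finite(O2)) || any(O2 < 0)) {
    stop("O2 must be non-negative and finite", call. = FALSE)
  }
  if (mode == "fixed") {
    rep_len(params$eps_fixed, length(O2))
  } else {
    params$eps_max * O2 / (O2 + params$k_O2_diff)
  }
}

## Conductance g (s^-1) such that T_O2 = g * (O2_ext - O2): the series
## resistance of membrane (scaled by 1/eps) and boundary layer around a
## cylinder. Internal; assumes eps > 0 and valid geometry.
o2_conductance <- function(eps, geom, d_O2) {
  r_mem <- (1 / eps) * log((geom$R + geom$Lg) / geom$R)
  r_bl  <- log((geom$R + geom$Lg + geom$Lb) / (geom$R + geom$Lg))
  2 * pi * d_O2 * (geom$L / geom$V) / (r_mem + r_bl)
}

#' Physical O2 exchange across the trichome envelope
#'
#' Diffusive O2 flux between cytoplasm and far field for a cylindrical cell,
#' through the series resistance of the membrane (relative diffusivity `eps`)
#' and the boundary layer:
#' `T_O2 = -2 pi d_O2 (L/V) * { (1/eps) ln(R/(R+Lg)) - ln((R+Lg+Lb)/(R+Lg)) }^-1 * (O2_ext - O2)`.
#' Positive flux is into the cell; the flux is linear in the gradient
#' `O2_ext - O2` at fixed `eps`.
#'
#' @param O2 intracellular O2 (mol m^-3).
#' @param O2_ext far-field O2 (mol m^-3).
#' @param eps relative membrane diffusivity (dimensionless, > 0).
#' @param geom a [tricho_geometry()].
#' @param d_O2 O2 diffusion coefficient in seawater (m^2 s^-1).
#' @return Volumetric exchange rate (mol O2 m^-3 s^-1), positive into the
#'   cell.
#' @examples
#' g <- tricho_geometry()
#' o2_exchange_flux(0.1, 0.213, 1e-4, g, 2.1e-9) > 0  # influx down-gradient
#' @export
o2_exchange_flux <- function(O2, O2_ext, eps, geom, d_O2 = 2.1e-9) {
  if (!inherits(geom, "tricho_geometry")) {
    stop("geom must be a tricho_geometry object", call. = FALSE)
  }
  if (any(!is.finite(eps))) stop("eps must be finite", call. = FALSE)
  if (any(eps == 0)) {
    stop("eps = 0 makes the membrane resistance singular; use a small ",
         "positive value (e.g. 1e-12) for a near-sealed membrane",
         call. = FALSE)
  }
  if (any(eps < 0)) stop("eps must be positive", call. = FALSE)
  if (d_O2 <= 0) stop("d_O2 must be positive", call. = FALSE)
  o2_conductance(eps, geom, d_O2) * (O2_ext - O2)
}
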