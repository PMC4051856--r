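#' Geometry and transport constants of the 1D gel region
#'
#' The microfluidic device holds a hydrogel strip of length `l` (default
#' 5 mm) between a source channel at `x = 0` and a sink-free far wall at
#' `x = l`. A `gel_domain` bundles the length, the cue diffusion coefficient
#' `Dc` within the gel, and a uniform computational grid on `[0, l]`.
#'
#' @param length_um gel length `l` in micrometres (> 0; default 5000).
#' @param Dc_um2_s cue diffusion coefficient in um^2/s (> 0).
#' @param Dc_m2_s alternatively, the diffusion coefficient in m^2/s
#'   (converted internally; supply exactly one of the two).
#' @param n_grid number of evenly spaced grid nodes on `[0, l]` (>= 3).
#' @return an object of class `gel_domain` with fields `length_um`,
#'   `Dc_um2_s`, `n_grid`, `dx_um` (spacing `l/(n_grid - 1)`) and `x_um`
#'   (the node coordinates).
#' @examples
#' dom <- gel_domain(Dc_m2_s = 8e-12)       # IGF-1 in 2 mg/mL collagen
#' dom$Dc_um2_s                             # 8 um^2/s
#' seconds_to_hours(diffusion_time(dom))    # ~22 h
#' @seealso [diffusion_time()], [exact_concentration()]
#' @export
gel_domain <- function(length_um = 5000, Dc_um2_s = NULL, Dc_m2_s = NULL,
                       n_grid = 1001) {
  if (is.null(Dc_um2_s) && is.null(Dc_m2_s)) {
    stop("supply the diffusion coefficient as `Dc_um2_s` or `Dc_m2_s`",
         call. = FALSE)
  }
  if (!is.null(Dc_um2_s) && !is.null(Dc_m2_s)) {
    stop("supply only one of `Dc_um2_s` and `Dc_m2_s`", call. = FALSE)
  }
  Dc <- if (is.null(Dc_um2_s)) m2s_to_um2s(Dc_m2_s) else Dc_um2_s
  .check_number(length_um, "length_um", min = 0, allow_min = FALSE)
  .check_number(Dc, "Dc_um2_s", min = 0, allow_min = FALSE)
  .check_number(n_grid, "n_grid", min = 3)
  n_grid <- as.integer(n_grid)
  structure(
    list(
      length_um = length_um,
      Dc_um2_s = Dc,
      n_grid = n_grid,
      dx_um = length_um / (n_grid - 1L),
      x_um = seq(0, length_um, length.out = n_grid)
    ),
    class = "gel_domain"
  )
}

#' @export
print.gel_domain <- function(x, ...) {
  cat(sprintf(
    "<gel_domain> l = %g um, Dc = %g um^2/s, %d nodes (dx = %g um)\n",
    x$length_um, x$Dc_um2_s, x$n_grid, x$dx_um))
  invisible(x)
}

#' Receptor-saturating chemotaxis law chi(c) = k / (1 + m c)^2
#'
#' The chemotactic sensitivity of a growth cone decreases as the local cue
#' concentration rises and surface receptors saturate. Following the
#' receptor-law form, `chi(c) = k / (1 + m c)^2`, so that `chi(0) = k`
#' (sensitivity at vanishing cue) and `chi(1/m) = k/4`; `m` plays the role of
#' an inverse dissociation constant.
#'
#' @param k chemotaxis magnitude in um^2 mL / (ug s) (>= 0).
#' @param m receptor-saturation parameter in mL/ug (>= 0; `m = 0` gives a
#'   constant, non-saturating sensitivity).
#' @return an object of class `chemotaxis_law`.
#' @examples
#' law <- chemotaxis_law(k = 9, m = 15)
#' chi(0, law)        # k
#' chi(1 / 15, law)   # k / 4
#' @export
chemotaxis_law <- function(k, m) {
  .check_number(k, "k", min = 0)
  .check_number(m, "m", min = 0)
  structure(list(k = k, m = m), class = "chemotaxis_law")
}

#' @export
print.chemotaxis_law <- function(x, ...) {
  cat(sprintf("<chemotaxis_law> chi(c) = k/(1 + m c)^2, k = %g, m = %g\n",
              x$k, x$m))
  if (x$m > 0) {
    cat(sprintf("  quarter-sensitivity at c = 1/m = %g ug/mL\n", 1 / x$m))
  }
  invisible(x)
}

#' Evaluate the chemotaxis coefficient
#'
#' @param c cue concentration(s) in ug/mL (>= 0).
#' @param law a [chemotaxis_law()].
#' @return `chi(c) = k / (1 + m c)^2`, vectorised over `c`, in
#'   um^2 mL / (ug s).
#' @examples
#' chi(c(0, 1, 10), chemotaxis_law(9, 15))
#' @export
chi <- function(c, law) {
  stopifnot(inherits(law, "chemotaxis_law"))
  .check_finite_vec(c, "c")
  if (any(c < 0)) stop("concentration `c` must be non-negative", call. = FALSE)
  law$k / (1 + law$m * c)^2
}

#' Initial growth-cone density profile
#'
#' The growth-cone population is represented by a density `g(x, t)` whose
#' initial condition is a Gaussian centred at `x0` (the soma position,
#' default mid-domain) with width `sigma` chosen so the full width at half
#' maximum is much smaller than the domain. The density is normalised to
#' unit mass internally; displacement of its peak is invariant to the scale
#' `g0`, which is kept as metadata.
#'
#' @param domain a [gel_domain()].
#' @param g0 nominal peak value (metadata only; the PDE is linear in `g`).
#' @param sigma_um Gaussian width parameter in um (default 25, FWHM ~ 59 um).
#' @param x0_um initial peak location in um (default `l/2`).
#' @param Dg_um2_s growth-cone diffusion coefficient in um^2/s
#'   (default 7e-3).
#' @return an object of class `growth_cone_density` with the normalised
#'   `values` on the domain grid.
#' @examples
#' dom <- gel_domain(Dc_um2_s = 8, n_grid = 501)
#' gc <- growth_cone_density(dom)
#' @export
growth_cone_density <- function(domain, g0 = 1, sigma_um = 25, x0_um = NULL,
                                Dg_um2_s = 7e-3) {
  stopifnot(inherits(domain, "gel_domain"))
  if (is.null(x0_um)) x0_um <- domain$length_um / 2
  .check_number(g0, "g0", min = 0, allow_min = FALSE)
  .check_number(sigma_um, "sigma_um", min = 0, allow_min = FALSE)
  .check_number(x0_um, "x0_um", min = 0, max = domain$length_um)
  .check_number(Dg_um2_s, "Dg_um2_s", min = 0, allow_min = FALSE)
  fwhm <- 2 * sqrt(2 * log(2)) * sigma_um
  if (fwhm > 0.2 * domain$length_um) {
    warning(sprintf(
      "initial FWHM (%.0f um) is not small relative to l (%.0f um)",
      fwhm, domain$length_um))
  }
  vals <- exp(-(domain$x_um - x0_um)^2 / (2 * sigma_um^2))
  w <- .trap_weights(domain)
  vals <- vals / sum(w * vals)  # unit mass under the trapezoid rule
  structure(
    list(domain = domain, values = vals, g0 = g0, sigma_um = sigma_um,
         x0_um = x0_um, Dg_um2_s = Dg_um2_s),
    class = "growth_cone_density"
  )
}

#' @export
print.growth_cone_density <- function(x, ...) {
  cat(sprintf(
    "<growth_cone_density> Gaussian IC at x0 = %g um, sigma = %g um, Dg = %g um^2/s\n",
    x$x0_um, x$sigma_um, x$Dg_um2_s))
  invisible(x)
}

# trapezoid quadrature weights on the domain grid (finite-volume cells)
.trap_weights <- function(domain) {
  n <- domain$n_grid
  c(domain$dx_um / 2, rep(domain$dx_um, n - 2L), domain$dx_um / 2)
}
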