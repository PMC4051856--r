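#' Parameter sweeps of the chemotaxis displacement
#'
#' Runs [simulate_growth_cones()] over a grid of one model parameter
#' crossed with a set of source concentrations, reproducing the standard
#' sensitivity curves: displacement vs `Dc`, domain length `l`, chemotaxis
#' magnitude `k`, saturation `m`, or `c0` itself.
#'
#' When sweeping `l` the grid spacing `dx` of the base domain is kept and
#' the node count adjusted; when sweeping `c0` the `c0` argument is ignored
#' and `values` are the concentrations.
#'
#' @param param one of `"Dc"`, `"l"`, `"k"`, `"m"`, `"c0"` or `"Dg"`.
#' @param values positive parameter values to sweep.
#' @param c0 source concentrations in ug/mL crossed with `values`
#'   (default `c(0.01, 0.1, 1, 10)`).
#' @param domain base [gel_domain()].
#' @param law base [chemotaxis_law()].
#' @param sigma_um,x0_um,Dg_um2_s base initial-density configuration
#'   (see [growth_cone_density()]).
#' @param t_end_s time horizon in seconds (default 48 h).
#' @return a tidy data frame with columns `param`, `value`, `c0_ug_ml`,
#'   `d_um` and `error` (NA, or the solver error message for that row).
#' @examples
#' parameter_sweep("k", c(3, 9), c0 = 0.1,
#'                 domain = gel_domain(Dc_um2_s = 8, n_grid = 251),
#'                 t_end_s = hours_to_seconds(6))
#' @export
parameter_sweep <- function(param, values, c0 = c(0.01, 0.1, 1, 10),
                            domain = gel_domain(Dc_um2_s = 8),
                            law = chemotaxis_law(9, 15),
                            sigma_um = 25, x0_um = NULL, Dg_um2_s = 7e-3,
                            t_end_s = 172800) {
  param <- match.arg(param, c("Dc", "l", "k", "m", "c0", "Dg"))
  .check_finite_vec(values, "values")
  if (any(values < 0) || (param %in% c("Dc", "l") && any(values <= 0))) {
    stop("`values` must be positive for this parameter", call. = FALSE)
  }
  if (param == "c0") c0 <- NA_real_
  grid <- expand.grid(value = values, c0_ug_ml = c0)
  out <- data.frame(param = param, grid, d_um = NA_real_,
                    error = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(out))) {
    v <- out$value[i]
    ci <- if (param == "c0") v else out$c0_ug_ml[i]
    dom <- domain
    lw <- law
    Dg <- Dg_um2_s
    if (param == "Dc") dom <- gel_domain(domain$length_um, Dc_um2_s = v,
                                         n_grid = domain$n_grid)
    if (param == "l") dom <- gel_domain(v, Dc_um2_s = domain$Dc_um2_s,
                                        n_grid = max(3L, round(v / domain$dx_um) + 1L))
    if (param == "k") lw <- chemotaxis_law(v, law$m)
    if (param == "m") lw <- chemotaxis_law(law$k, v)
    if (param == "Dg") Dg <- v
    gc <- growth_cone_density(dom, sigma_um = sigma_um,
                              x0_um = if (is.null(x0_um)) NULL else x0_um,
                              Dg_um2_s = Dg)
    res <- tryCatch(
      simulate_growth_cones(dom, lw, ci, gc = gc, t_end_s = t_end_s),
      error = function(e) e)
    if (inherits(res, "error")) {
      out$error[i] <- conditionMessage(res)
    } else {
      out$d_um[i] <- res$d_final
    }
    if (param == "c0") out$c0_ug_ml[i] <- ci
  }
  out
}

#' Predicted displacement dose-response over source concentration
#'
#' Forward-simulates the fitted (or specified) chemotaxis law over a grid
#' of source concentrations spanning several orders of magnitude. With
#' `m > 0` the response saturates: displacement is bounded as `c0` grows.
#'
#' @param law a [chemotaxis_law()].
#' @param c0_grid source concentrations in ug/mL (default half-decade steps
#'   over 0.01-100).
#' @param domain a [gel_domain()].
#' @param sigma_um,x0_um,Dg_um2_s initial-density configuration.
#' @param t_end_s time horizon in seconds.
#' @return a data frame with columns `c0_ug_ml` and `d_um`, with the
#'   maximising concentration in attribute `"c0_at_max"`.
#' @examples
#' predict_dose_response(chemotaxis_law(9, 15), c0_grid = c(0.1, 1),
#'                       domain = gel_domain(Dc_um2_s = 8, n_grid = 251),
#'                       t_end_s = hours_to_seconds(6))
#' @export
predict_dose_response <- function(law, c0_grid = 10^seq(-2, 2, by = 0.5),
                                  domain = gel_domain(Dc_um2_s = 8),
                                  sigma_um = 25, x0_um = NULL,
                                  Dg_um2_s = 7e-3, t_end_s = 172800) {
  .check_finite_vec(c0_grid, "c0_grid", min = 0)
  gc <- growth_cone_density(domain, sigma_um = sigma_um, x0_um = x0_um,
                            Dg_um2_s = Dg_um2_s)
  d <- vapply(c0_grid, function(ci) {
    simulate_growth_cones(domain, law, ci, gc = gc, t_end_s = t_end_s)$d_final
  }, 0)
  out <- data.frame(c0_ug_ml = c0_grid, d_um = d)
  attr(out, "c0_at_max") <- c0_grid[which.max(d)]
  out
}
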