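# Staged estimation of the chemotaxis parameters (k, m) from displacement
# observations. The forward model is simulate_growth_cones(); displacement
# is monotone increasing in k (fixed m) and monotone decreasing in m
# (fixed k), so each stage is a bracketed 1D root-find.

# forward displacement for a (k, m, c0) triple under a shared
# configuration; large-displacement warnings are expected while a
# root-finder explores its bracket and are muffled here
.displacement <- function(k, m, c0, config, stop_at_d_um = NULL) {
  sim <- withCallingHandlers(
    simulate_growth_cones(
      config$domain, chemotaxis_law(k, m), c0, gc = config$gc,
      t_end_s = config$t_end_s, stop_at_d_um = stop_at_d_um),
    warning = function(w) {
      if (grepl("not small relative|captured at the source wall",
                conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  sim$d_final
}

#' Simulation configuration shared by the fitting routines
#'
#' Bundles the forward-model configuration (domain, initial density, time
#' horizon) so that fits and forward simulations use identical numerics.
#'
#' @param domain a [gel_domain()].
#' @param sigma_um,x0_um,Dg_um2_s initial-density configuration
#'   (see [growth_cone_density()]).
#' @param t_end_s time horizon in seconds (default 48 h).
#' @return a list with elements `domain`, `gc`, `t_end_s`.
#' @export
fit_config <- function(domain = gel_domain(Dc_um2_s = 8),
                       sigma_um = 25, x0_um = NULL, Dg_um2_s = 7e-3,
                       t_end_s = 172800) {
  list(domain = domain,
       gc = growth_cone_density(domain, sigma_um = sigma_um, x0_um = x0_um,
                                Dg_um2_s = Dg_um2_s),
       t_end_s = t_end_s)
}

#' Fit the chemotaxis magnitude k from one displacement observation
#'
#' Solves `d_model(c0; k, m) = d_obs` for `k` with `m` held fixed, by
#' Brent's method on a bracket grown from `k_init`, exploiting the
#' monotonicity of displacement in `k`. The calibration concentration is
#' `c0 = 0.1` ug/mL by convention (where `chi ~ k` because `m c` is small).
#'
#' @param d_obs_um observed displacement in um (mean treated-minus-control
#'   outgrowth; >= 0).
#' @param m fixed saturation parameter in mL/ug.
#' @param c0 calibration concentration in ug/mL (default 0.1).
#' @param config a [fit_config()].
#' @param k_max upper bracket in um^2 mL/(ug s) (default 1e4).
#' @param k_init initial bracket guess (default 20).
#' @param tol_um residual tolerance in um (default 0.01).
#' @return the fitted `k`, with attributes `residual_um` and `n_evals`.
#' @examples
#' cfg <- fit_config(gel_domain(Dc_um2_s = 8, n_grid = 251),
#'                   t_end_s = hours_to_seconds(6))
#' d <- simulate_growth_cones(cfg$domain, chemotaxis_law(9, 15), 0.1,
#'                            gc = cfg$gc, t_end_s = cfg$t_end_s)$d_final
#' fit_k(d, m = 15, config = cfg)
#' @export
fit_k <- function(d_obs_um, m, c0 = 0.1, config = fit_config(),
                  k_max = 1e4, k_init = 20, tol_um = 0.01) {
  .check_number(d_obs_um, "d_obs_um", min = 0)
  .check_number(m, "m", min = 0)
  if (d_obs_um == 0) {
    return(structure(0, residual_um = 0, n_evals = 0L))
  }
  if (d_obs_um >= config$domain$length_um) {
    stop("`d_obs_um` exceeds the domain length; infeasible", call. = FALSE)
  }
  evals <- 0L
  cap <- 2 * d_obs_um + 10 * config$domain$dx_um
  f <- function(k) {
    evals <<- evals + 1L
    .displacement(k, m, c0, config, stop_at_d_um = cap) - d_obs_um
  }
  # two-sided bracket grown geometrically from the initial guess
  # (warm-started by callers iterating the staged scheme)
  a <- min(max(k_init, 1e-3), k_max)
  fa <- f(a)
  if (fa >= 0) {
    hi <- a; fhi <- fa; lo <- a / 4; flo <- f(lo)
    while (flo > 0 && lo > 1e-9) {
      hi <- lo; fhi <- flo
      lo <- lo / 4; flo <- f(lo)
    }
    if (flo > 0) { lo <- 0; flo <- -d_obs_um }
  } else {
    lo <- a; flo <- fa; hi <- min(a * 4, k_max); fhi <- f(hi)
    while (fhi < 0 && hi < k_max) {
      lo <- hi; flo <- fhi
      hi <- min(hi * 4, k_max); fhi <- f(hi)
    }
    if (fhi < 0) {
      stop(sprintf(
        "d_obs = %.3g um is unreachable: d_model(k_max = %g) = %.3g um",
        d_obs_um, k_max, fhi + d_obs_um), call. = FALSE)
    }
  }
  root <- uniroot(f, c(lo, hi), f.lower = flo, f.upper = fhi,
                  tol = max(hi * 1e-4, 1e-8))
  structure(root$root, residual_um = root$f.root, n_evals = evals)
}

#' Fit the receptor-saturation parameter m from one displacement observation
#'
#' Solves `d_model(c0; k, m) = d_obs` for `m` with `k` held fixed, at the
#' high calibration concentration (`c0 = 1` ug/mL by convention) where
#' saturation is informative. Displacement is monotone decreasing in `m`, so
#' `d_obs` must not exceed the `m = 0` prediction (saturation can only
#' reduce displacement).
#'
#' @inheritParams fit_k
#' @param k fixed chemotaxis magnitude.
#' @param m_max upper bracket in mL/ug (default 1e5).
#' @param m_init initial bracket guess (default 10).
#' @return the fitted `m`, with attributes `residual_um` and `n_evals`.
#' @export
fit_m <- function(d_obs_um, k, c0 = 1, config = fit_config(),
                  m_max = 1e5, m_init = 10, tol_um = 0.01) {
  .check_number(d_obs_um, "d_obs_um", min = 0)
  .check_number(k, "k", min = 0)
  evals <- 0L
  cap <- 2 * d_obs_um + 10 * config$domain$dx_um
  f <- function(m) {
    evals <<- evals + 1L
    .displacement(k, m, c0, config, stop_at_d_um = cap) - d_obs_um
  }
  f0 <- f(0)
  if (f0 < -tol_um) {
    stop(sprintf(
      "d_obs = %.3g um exceeds the m = 0 prediction (%.3g um); saturation can only reduce displacement",
      d_obs_um, f0 + d_obs_um), call. = FALSE)
  }
  if (abs(f0) <= tol_um) {
    return(structure(0, residual_um = f0, n_evals = evals))
  }
  # two-sided bracket around the initial guess; f is decreasing in m
  a <- min(max(m_init, 1e-3), m_max)
  fa <- f(a)
  if (fa <= 0) {
    hi <- a; fhi <- fa; lo <- a / 4; flo <- f(lo)
    while (flo < 0 && lo > 1e-9) {
      hi <- lo; fhi <- flo
      lo <- lo / 4; flo <- f(lo)
    }
    if (flo < 0) { lo <- 0; flo <- f0 }
  } else {
    lo <- a; flo <- fa; hi <- min(a * 4, m_max); fhi <- f(hi)
    while (fhi > 0 && hi < m_max) {
      lo <- hi; flo <- fhi
      hi <- min(hi * 4, m_max); fhi <- f(hi)
    }
    if (fhi > 0) {
      stop(sprintf(
        "d_obs = %.3g um is below d_model(m_max = %g) = %.3g um; m out of bracket",
        d_obs_um, m_max, fhi + d_obs_um), call. = FALSE)
    }
  }
  root <- uniroot(f, c(lo, hi), f.lower = flo, f.upper = fhi,
                  tol = max(hi * 1e-4, 1e-8))
  structure(root$root, residual_um = root$f.root, n_evals = evals)
}

#' Staged estimation of (k, m) from a low/high concentration pair
#'
#' Implements the two-stage calibration scheme: `k` is determined from the
#' displacement observed at the low concentration (0.1 ug/mL, where
#' saturation is negligible), then `m` from the displacement at the high
#' concentration (1 ug/mL). The two stages are alternated until both model
#' residuals fall below `tol_um`, so the procedure exactly inverts the
#' forward model: displacements simulated from a known `(k, m)` are
#' recovered.
#'
#' @param d_low_um observed displacement at `c0_low` in um.
#' @param d_high_um observed displacement at `c0_high` in um.
#' @param c0_low,c0_high calibration concentrations in ug/mL
#'   (defaults 0.1 and 1).
#' @param config a [fit_config()].
#' @param m_init starting value for `m` in the first `k` stage (default 0,
#'   i.e. `chi ~ k`; the fixed point is independent of this for feasible
#'   data).
#' @param tol_um residual tolerance in um (default 0.02).
#' @param max_iter maximum number of stage alternations (default 50).
#' @param k_max,m_max root-finding brackets.
#' @return an object of class `ks_fit`: list with `law`
#'   (a [chemotaxis_law()]), `residuals_um` (named, per observation),
#'   `iterations`, `converged`, `m_identifiable` and the residual `trace`.
#' @examples
#' cfg <- fit_config(gel_domain(Dc_um2_s = 8, n_grid = 126),
#'                   t_end_s = hours_to_seconds(6))
#' truth <- chemotaxis_law(9, 15)
#' d1 <- simulate_growth_cones(cfg$domain, truth, 0.1, gc = cfg$gc,
#'                             t_end_s = cfg$t_end_s)$d_final
#' d2 <- simulate_growth_cones(cfg$domain, truth, 1, gc = cfg$gc,
#'                             t_end_s = cfg$t_end_s)$d_final
#' fit_staged(d1, d2, config = cfg)
#' @export
fit_staged <- function(d_low_um, d_high_um, c0_low = 0.1, c0_high = 1,
                       config = fit_config(), m_init = 0, tol_um = 0.02,
                       max_iter = 50, k_max = 1e4, m_max = 1e5,
                       verbose = FALSE) {
  .check_number(d_low_um, "d_low_um", min = 0)
  .check_number(d_high_um, "d_high_um", min = 0)
  if (d_low_um == 0 && d_high_um == 0) {
    return(structure(
      list(law = chemotaxis_law(0, 0),
           residuals_um = c(low = 0, high = 0), iterations = 0L,
           converged = TRUE, m_identifiable = FALSE,
           trace = data.frame(iter = integer(), k = numeric(),
                              m = numeric(), r_low = numeric(),
                              r_high = numeric())),
      class = "ks_fit"))
  }
  if (d_low_um == 0 && d_high_um > 0) {
    stop("d = 0 at the low concentration but d > 0 at the high one is infeasible under this model (k would be 0)",
         call. = FALSE)
  }
  m_cur <- m_init
  k_cur <- NA_real_
  trace <- vector("list", max_iter)
  converged <- FALSE
  it <- 0L
  hist_k <- numeric(0)  # consecutive plain-alternation iterates for
  hist_m <- numeric(0)  # Aitken extrapolation of the linear tail
  for (it in seq_len(max_iter)) {
    k_fit <- fit_k(
      d_low_um, m = m_cur, c0 = c0_low, config = config, k_max = k_max,
      k_init = if (is.na(k_cur)) 20 else k_cur, tol_um = tol_um)
    k_cur <- as.numeric(k_fit)
    m_fit <- fit_m(
      d_high_um, k = k_cur, c0 = c0_high, config = config, m_max = m_max,
      m_init = max(m_cur, 1), tol_um = tol_um)
    r_high <- attr(m_fit, "residual_um")
    m_cur <- as.numeric(m_fit)
    r_low <- .displacement(k_cur, m_cur, c0_low, config) - d_low_um
    trace[[it]] <- data.frame(iter = it, k = k_cur, m = m_cur,
                              r_low = r_low, r_high = r_high)
    if (verbose) {
      message(sprintf(
        "iter %2d: k = %.5g (%d evals), m = %.5g (%d evals), residuals (%.3g, %.3g) um",
        it, k_cur, attr(k_fit, "n_evals"), m_cur,
        attr(m_fit, "n_evals"), r_low, r_high))
    }
    if (abs(r_low) < tol_um && abs(r_high) < tol_um) {
      converged <- TRUE
      break
    }
    # the alternation converges linearly when the two stages are strongly
    # coupled (large m c0); Aitken's delta-squared step on three plain
    # iterates jumps to the fixed point's extrapolated limit
    hist_k <- c(hist_k, k_cur)
    hist_m <- c(hist_m, m_cur)
    if (length(hist_m) >= 3L) {
      aitken <- function(h) {
        n <- length(h)
        d1 <- h[n] - h[n - 1L]
        d2 <- d1 - (h[n - 1L] - h[n - 2L])
        if (abs(d2) < 1e-300) return(NA_real_)
        h[n] - d1^2 / d2
      }
      k_acc <- aitken(hist_k)
      m_acc <- aitken(hist_m)
      if (is.finite(k_acc) && is.finite(m_acc) &&
          k_acc > 0 && m_acc > 0 && k_acc < k_max && m_acc < m_max) {
        k_cur <- k_acc
        m_cur <- m_acc
        if (verbose) {
          message(sprintf("        Aitken step -> k = %.5g, m = %.5g",
                          k_cur, m_cur))
        }
      }
      hist_k <- numeric(0)
      hist_m <- numeric(0)
    }
  }
  trace <- do.call(rbind, trace[seq_len(it)])
  if (!converged) {
    warning(sprintf(
      "staged fit did not converge in %d iterations (residuals %.3g / %.3g um); see $trace",
      max_iter, trace$r_low[it], trace$r_high[it]))
  }
  structure(
    list(law = chemotaxis_law(k_cur, m_cur),
         residuals_um = c(low = trace$r_low[it], high = trace$r_high[it]),
         iterations = it, converged = converged, m_identifiable = TRUE,
         trace = trace),
    class = "ks_fit")
}

#' @export
print.ks_fit <- function(x, ...) {
  cat(sprintf("<ks_fit> k = %.4g um^2 mL/(ug s), m = %.4g mL/ug\n",
              x$law$k, x$law$m))
  cat(sprintf("  %d iteration(s), %s; residuals (low, high) = (%.3g, %.3g) um\n",
              x$iterations,
              if (x$converged) "converged" else "NOT converged",
              x$residuals_um[["low"]], x$residuals_um[["high"]]))
  if (!x$m_identifiable) cat("  note: m not identifiable (both d = 0)\n")
  invisible(x)
}

#' Read displacement observations from CSV
#'
#' Expects columns `condition`, `c0_ug_ml`, `d_obs_um` (one row per
#' condition mean), the input schema for [fit_staged()] and
#' [fit_wls()].
#'
#' @param path path to the CSV file.
#' @return a validated data frame.
#' @export
read_displacement_obs <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("condition", "c0_ug_ml", "d_obs_um")
  missing <- setdiff(req, names(df))
  if (length(missing)) {
    stop("observation CSV is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  .check_finite_vec(df$c0_ug_ml, "c0_ug_ml", min = 0)
  .check_finite_vec(df$d_obs_um, "d_obs_um", min = 0)
  df[req]
}

#' Weighted least-squares fit of (k, m) over several observations
#'
#' Extension of the exactly determined two-observation scheme of
#' [fit_staged()]: minimises the weighted sum of squared displacement
#' residuals over any number of `(c0, d_obs)` pairs, by Nelder-Mead on
#' `(log k, log m)` initialised from a staged fit of the observations
#' closest to the two standard calibration concentrations.
#'
#' @param obs data frame with columns `c0_ug_ml` and `d_obs_um` (>= 2
#'   rows), e.g. from [read_displacement_obs()].
#' @param config a [fit_config()].
#' @param weights optional per-observation weights (default equal).
#' @param init optional [chemotaxis_law()] starting point (skips the
#'   staged initialisation).
#' @param maxit Nelder-Mead iteration cap (default 200).
#' @return an object of class `ks_fit` with the additional fields `rss`
#'   and `fitted_d_um`.
#' @export
fit_wls <- function(obs, config = fit_config(), weights = NULL,
                    init = NULL, maxit = 200) {
  req <- c("c0_ug_ml", "d_obs_um")
  if (!is.data.frame(obs) || !all(req %in% names(obs)) || nrow(obs) < 2L) {
    stop("`obs` needs >= 2 rows with columns c0_ug_ml and d_obs_um",
         call. = FALSE)
  }
  if (is.null(weights)) weights <- rep(1, nrow(obs))
  stopifnot(length(weights) == nrow(obs), all(weights >= 0))
  if (is.null(init)) {
    i_lo <- which.min(abs(log(obs$c0_ug_ml) - log(0.1)))
    i_hi <- which.min(abs(log(obs$c0_ug_ml) - log(1)))
    if (i_lo == i_hi) i_hi <- if (i_lo < nrow(obs)) i_lo + 1L else i_lo - 1L
    st <- fit_staged(obs$d_obs_um[i_lo], obs$d_obs_um[i_hi],
                     c0_low = obs$c0_ug_ml[i_lo],
                     c0_high = obs$c0_ug_ml[i_hi], config = config)
    init <- st$law
  }
  obj <- function(p) {
    d <- vapply(seq_len(nrow(obs)), function(i) {
      .displacement(exp(p[1]), exp(p[2]), obs$c0_ug_ml[i], config)
    }, 0)
    sum(weights * (d - obs$d_obs_um)^2)
  }
  p0 <- log(c(max(init$k, 1e-6), max(init$m, 1e-6)))
  opt <- stats::optim(p0, obj, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-10))
  law <- chemotaxis_law(exp(opt$par[1]), exp(opt$par[2]))
  fitted <- vapply(seq_len(nrow(obs)), function(i) {
    .displacement(law$k, law$m, obs$c0_ug_ml[i], config)
  }, 0)
  structure(
    list(law = law,
         residuals_um = fitted - obs$d_obs_um,
         iterations = opt$counts[["function"]],
         converged = opt$convergence == 0, m_identifiable = TRUE,
         rss = opt$value, fitted_d_um = fitted,
         trace = NULL),
    class = "ks_fit")
}
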