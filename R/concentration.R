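#' Exact series solution of the cue diffusion problem
#'
#' The guidance cue diffuses into the gel from the source channel held at a
#' constant concentration `c0` at `x = 0`, with zero flux at the far wall
#' `x = l` and an initially cue-free gel. The solution of
#' `dc/dt = Dc d2c/dx2` under these conditions is the eigenfunction series
#'
#' \deqn{c(x,t) = c_0\Big[1 - \sum_{n\ge 1} \frac{4}{(2n-1)\pi}
#'   \sin\frac{(2n-1)\pi x}{2l}
#'   \exp\Big(-\frac{(2n-1)^2\pi^2 D_c t}{4 l^2}\Big)\Big].}
#'
#' The series is truncated adaptively: terms are added until the magnitude
#' bound of the next term falls below `tol * c0` (at least 50 terms are used
#' at small `t`, where convergence is slowest). At `t = 0` the initial
#' condition is returned directly.
#'
#' @param domain a [gel_domain()].
#' @param c0 boundary concentration at `x = 0` in ug/mL (>= 0).
#' @param x position(s) in um, each within `[0, l]`.
#' @param t time in seconds (>= 0, scalar).
#' @param n_terms optional fixed number of series terms (>= 1). If too small
#'   to reach `tol` at the requested `t`, a warning reports the achieved
#'   error bound.
#' @param tol relative truncation tolerance (default 1e-8).
#' @return concentration(s) in ug/mL, vectorised over `x`.
#' @examples
#' dom <- gel_domain(Dc_um2_s = 8)
#' exact_concentration(dom, c0 = 1, x = 2500, t = hours_to_seconds(48))
#' @export
exact_concentration <- function(domain, c0, x, t, n_terms = NULL,
                                tol = 1e-8) {
  stopifnot(inherits(domain, "gel_domain"))
  .check_number(c0, "c0", min = 0)
  .check_number(t, "t", min = 0)
  .check_finite_vec(x, "x", min = 0)
  if (any(x > domain$length_um)) {
    stop("`x` must lie within [0, l]", call. = FALSE)
  }
  if (t == 0) return(ifelse(x == 0, c0, 0))
  if (c0 == 0) return(rep(0, length(x)))
  N <- .series_n_terms(t, domain$length_um, domain$Dc_um2_s, tol = tol,
                       n_terms = n_terms)
  c0 * (1 - .series_sum(x, t, domain$length_um, domain$Dc_um2_s, N))
}

# number of terms so that the first neglected term's bound
# (4/((2n-1) pi)) exp(-lambda_n t) < tol; minimum 50 terms.
.series_n_terms <- function(t, l, Dc, tol = 1e-8, n_terms = NULL,
                            n_min = 50L) {
  lam1 <- pi^2 * Dc / (4 * l^2)  # decay rate of mode n is (2n-1)^2 * lam1
  need <- function(n) (4 / ((2 * n - 1) * pi)) * exp(-(2 * n - 1)^2 * lam1 * t)
  # solve (2n-1)^2 lam1 t > log(4/((2n-1) pi tol)) conservatively
  q <- sqrt(max(log(4 / (pi * tol)), 0) / max(lam1 * t, 1e-300))
  N <- max(n_min, ceiling((q + 1) / 2) + 5L)
  if (!is.null(n_terms)) {
    .check_number(n_terms, "n_terms", min = 1)
    n_terms <- as.integer(n_terms)
    if (n_terms < N && need(n_terms + 1L) > tol) {
      warning(sprintf(
        "n_terms = %d truncates the series with error bound ~%.2e (requested tol %.1e)",
        n_terms, need(n_terms + 1L), tol))
    }
    return(n_terms)
  }
  as.integer(N)
}

# sum_{n=1..N} (4/((2n-1)pi)) sin((2n-1)pi x/(2l)) exp(-lambda_n t); 0..1
.series_sum <- function(x, t, l, Dc, N) {
  n <- seq_len(N)
  mu <- (2 * n - 1) * pi / (2 * l)           # wavenumbers
  a <- (4 / ((2 * n - 1) * pi)) * exp(-mu^2 * Dc * t)
  drop(sin(outer(x, mu)) %*% a)
}

# spatial gradient dc/dx of the series solution at positions x (t > 0)
.series_grad <- function(x, t, l, Dc, c0, N) {
  n <- seq_len(N)
  mu <- (2 * n - 1) * pi / (2 * l)
  a <- (2 / l) * exp(-mu^2 * Dc * t)
  -c0 * drop(cos(outer(x, mu)) %*% a)
}

#' Snapshot of the cue concentration field on the domain grid
#'
#' @param domain a [gel_domain()].
#' @param c0 boundary concentration in ug/mL.
#' @param t time in seconds.
#' @inheritParams exact_concentration
#' @return an object of class `concentration_field` holding the grid
#'   `values` together with `domain`, `c0` and `t`.
#' @examples
#' fld <- concentration_field(gel_domain(Dc_um2_s = 8), c0 = 1,
#'                            t = hours_to_seconds(21))
#' steepness(fld, x = 2500)
#' @export
concentration_field <- function(domain, c0, t, n_terms = NULL) {
  vals <- exact_concentration(domain, c0, domain$x_um, t, n_terms = n_terms)
  structure(
    list(domain = domain, c0 = c0, t = t, values = vals),
    class = "concentration_field"
  )
}

#' @export
print.concentration_field <- function(x, ...) {
  cat(sprintf(
    "<concentration_field> c0 = %g ug/mL at t = %.3g h; range [%.3g, %.3g] ug/mL\n",
    x$c0, seconds_to_hours(x$t), min(x$values), max(x$values)))
  invisible(x)
}

#' Characteristic gradient-establishment time
#'
#' Heuristic time for significant diffusion to establish across a gel of
#' length `l`: `tau = l^2 / (4 pi^2 Dc)`.
#'
#' @param domain a [gel_domain()].
#' @return `tau` in seconds.
#' @examples
#' # IGF-1 (Dc = 8e-12 m^2/s) across 5 mm of 2 mg/mL collagen: ~22 h
#' seconds_to_hours(diffusion_time(gel_domain(5000, Dc_m2_s = 8e-12)))
#' @export
diffusion_time <- function(domain) {
  stopifnot(inherits(domain, "gel_domain"))
  domain$length_um^2 / (4 * pi^2 * domain$Dc_um2_s)
}

#' Local gradient steepness across a growth-cone width
#'
#' Growth cones are ~10 um wide; the fractional concentration drop across
#' that width is the standard measure of how strong a gradient they sense.
#' Steepness at `x` is `100 * (c(x) - c(x + w)) / c(x)` with `w = 10` um.
#'
#' @param field a [concentration_field()], or a function `c(x)` giving the
#'   concentration profile directly.
#' @param x position in um; the window `[x, x + window_um]` must lie in
#'   `[0, l]` for a `concentration_field`.
#' @param window_um sensing width in um (default 10).
#' @return steepness in percent per `window_um`.
#' @examples
#' # a linear profile c = c0 (1 - x/l) has steepness 100 * w / l at x = 0
#' steepness(function(x) 1 - x / 5000, x = 0)  # 0.2 %
#' @export
steepness <- function(field, x, window_um = 10) {
  .check_number(x, "x", min = 0)
  .check_number(window_um, "window_um", min = 0, allow_min = FALSE)
  if (is.function(field)) {
    cx <- field(x)
    cw <- field(x + window_um)
  } else if (inherits(field, "concentration_field")) {
    if (x + window_um > field$domain$length_um) {
      stop("the sensing window must lie inside [0, l]", call. = FALSE)
    }
    cc <- exact_concentration(field$domain, field$c0, c(x, x + window_um),
                              field$t)
    cx <- cc[1]
    cw <- cc[2]
  } else {
    stop("`field` must be a concentration_field or a function of x",
         call. = FALSE)
  }
  if (!is.finite(cx) || cx <= 0) {
    stop("steepness is undefined where c(x) <= 0", call. = FALSE)
  }
  100 * (cx - cw) / cx
}

#' Scale a diffusion coefficient by molecular mass
#'
#' Stokes-Einstein scaling through the hydrodynamic radius: for globular
#' molecules the radius grows as the cube root of the molecular mass, so
#' `D = D_ref * (M_ref / M)^(1/3)`. Going from a 17 kDa to a 27 kDa cue
#' this predicts ~14% slower diffusion (reported rounded as 15%).
#'
#' @param D_ref reference diffusion coefficient (any units; > 0).
#' @param M_ref reference molecular mass in kDa (> 0).
#' @param M target molecular mass in kDa (> 0).
#' @param exponent mass exponent (default 1/3, radius ~ M^(1/3)).
#' @return the scaled diffusion coefficient, in the units of `D_ref`.
#' @examples
#' scale_dc_by_mass(8, 17, 27)   # ~6.85 um^2/s, 14.3% slower
#' @export
scale_dc_by_mass <- function(D_ref, M_ref, M, exponent = 1 / 3) {
  .check_number(D_ref, "D_ref", min = 0, allow_min = FALSE)
  .check_number(M_ref, "M_ref", min = 0, allow_min = FALSE)
  .check_number(M, "M", min = 0, allow_min = FALSE)
  D_ref * (M_ref / M)^exponent
}

#' Estimate the cue diffusion coefficient from intensity profiles
#'
#' Time-stamped 1D fluorescence intensity profiles (assumed proportional to
#' concentration, with one unknown gain shared across time points) are fit
#' against the exact series solution by least squares. For each candidate
#' `Dc` the optimal gain has a closed form, leaving a 1D minimisation over
#' `log10(Dc)`.
#'
#' @param profiles a data frame with columns `time_s`, `x_um`, `intensity`
#'   (one row per time/position), e.g. from
#'   [generate_intensity_profiles()] or [read_intensity_profiles()].
#' @param length_um gel length `l` in um (default 5000).
#' @param dc_bounds search interval for `Dc` in um^2/s.
#' @return an object of class `dc_fit`: list with `Dc_um2_s`, `gain`,
#'   `rss` (residual sum of squares), `residual_norm` and `n_obs`.
#' @examples
#' dom <- gel_domain(Dc_um2_s = 8, n_grid = 101)
#' prof <- generate_intensity_profiles(dom, c0 = 1,
#'   times_s = hours_to_seconds(c(6, 12, 24, 48)), noise_cv = 0, seed = 1)
#' estimate_dc_from_profiles(prof)$Dc_um2_s
#' @export
estimate_dc_from_profiles <- function(profiles, length_um = 5000,
                                      dc_bounds = c(0.01, 100)) {
  req <- c("time_s", "x_um", "intensity")
  if (!is.data.frame(profiles) || !all(req %in% names(profiles))) {
    stop("`profiles` needs columns time_s, x_um, intensity", call. = FALSE)
  }
  .check_finite_vec(profiles$time_s, "time_s", min = 0)
  .check_finite_vec(profiles$x_um, "x_um", min = 0)
  .check_finite_vec(profiles$intensity, "intensity", min = 0)
  times <- sort(unique(profiles$time_s))
  if (length(times) < 2L) {
    stop("need profiles at >= 2 distinct times to identify Dc",
         call. = FALSE)
  }
  if (max(times) <= 0) {
    stop("Dc is not identifiable from t = 0 profiles alone (field is flat)",
         call. = FALSE)
  }
  model_vals <- function(Dc) {
    dom <- gel_domain(length_um, Dc_um2_s = Dc, n_grid = 3L)
    out <- numeric(nrow(profiles))
    for (tt in times) {
      idx <- profiles$time_s == tt
      out[idx] <- exact_concentration(dom, 1, profiles$x_um[idx], tt)
    }
    out
  }
  obj <- function(logDc) {
    m <- model_vals(10^logDc)
    ss <- sum(m^2)
    if (ss < 1e-12) return(sum(profiles$intensity^2) + 1)
    gain <- sum(profiles$intensity * m) / ss
    sum((profiles$intensity - gain * m)^2)
  }
  opt <- optimize(obj, log10(dc_bounds), tol = 1e-7)
  Dc <- 10^opt$minimum
  m <- model_vals(Dc)
  ss <- sum(m^2)
  if (ss < 1e-12) {
    stop("Dc is not identifiable: the fitted field is flat over the data",
         call. = FALSE)
  }
  gain <- sum(profiles$intensity * m) / ss
  rss <- sum((profiles$intensity - gain * m)^2)
  structure(
    list(Dc_um2_s = Dc, gain = gain, rss = rss,
         residual_norm = sqrt(rss), n_obs = nrow(profiles)),
    class = "dc_fit"
  )
}

#' @export
print.dc_fit <- function(x, ...) {
  cat(sprintf(
    "<dc_fit> Dc = %.4g um^2/s (gain %.4g, residual norm %.4g, n = %d)\n",
    x$Dc_um2_s, x$gain, x$residual_norm, x$n_obs))
  invisible(x)
}

#' Read intensity profiles from CSV
#'
#' Expects the schema `time_s, x_um, intensity` with a header row, one row
#' per (time, position) sample.
#'
#' @param path path to the CSV file.
#' @return a validated data frame suitable for
#'   [estimate_dc_from_profiles()].
#' @export
read_intensity_profiles <- function(path) {
  df <- read.csv(path)
  req <- c("time_s", "x_um", "intensity")
  missing <- setdiff(req, names(df))
  if (length(missing)) {
    stop("profile CSV is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  .check_finite_vec(df$intensity, "intensity", min = 0)
  ord <- order(df$time_s, df$x_um)
  df[ord, req]
}
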