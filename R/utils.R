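# internal helpers: argument checks, unit conversions, seeded evaluation

.check_number <- function(x, name, min = -Inf, max = Inf,
                          allow_min = TRUE, allow_max = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  lo_ok <- if (allow_min) x >= min else x > min
  hi_ok <- if (allow_max) x <= max else x < max
  if (!lo_ok || !hi_ok) {
    stop(sprintf("`%s` = %g is outside its allowed range", name, x),
         call. = FALSE)
  }
  invisible(x)
}

.check_finite_vec <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) == 0L || any(!is.finite(x))) {
    stop(sprintf("`%s` must be finite and non-empty", name), call. = FALSE)
  }
  if (any(x < min)) {
    stop(sprintf("`%s` has values below %g", name, min), call. = FALSE)
  }
  invisible(x)
}

#' Unit conversions used throughout the package
#'
#' Internal canonical units are micrometres, seconds and ug/mL. These helpers
#' convert the SI values in which hydrogel diffusion coefficients are usually
#' reported (m^2/s) and culture times (hours).
#'
#' @param Dc_m2_s diffusion coefficient in m^2/s.
#' @param hours time in hours.
#' @param seconds time in seconds.
#' @return the converted value (um^2/s, seconds, or hours).
#' @examples
#' m2s_to_um2s(8e-12)  # 8 um^2/s
#' hours_to_seconds(48)
#' @export
m2s_to_um2s <- function(Dc_m2_s) Dc_m2_s * 1e12

#' @rdname m2s_to_um2s
#' @export
hours_to_seconds <- function(hours) hours * 3600

#' @rdname m2s_to_um2s
#' @export
seconds_to_hours <- function(seconds) seconds / 3600

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, code) {
  .check_number(seed, "seed")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Derive a child seed from a master seed
#'
#' Synthetic experiments derive one independent sub-stream per component
#' (lengths, angles, device effects, time point) from a single master seed by
#' the counter scheme `(seed * 1009 + index) mod (2^31 - 1)`. The scheme is
#' deterministic and documented so that generated datasets are reproducible
#' bit-for-bit from the master seed alone.
#'
#' @param seed master seed (integer-valued scalar).
#' @param index non-negative counter identifying the sub-stream.
#' @return an integer seed.
#' @export
child_seed <- function(seed, index) {
  .check_number(seed, "seed")
  .check_number(index, "index", min = 0)
  as.integer((abs(seed) * 1009 + index) %% 2147483647)
}
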