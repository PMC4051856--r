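# Neurite morphometry at the trace-table level: outgrowth summaries,
# quadrant turning analysis and group comparisons.
#
# Angle convention: angles are planar orientations of the soma-to-tip
# vector in degrees on [0, 360), with the gradient source channel on the
# left so that 180 degrees points toward the source. The toward-gradient
# quadrant Q1 is 135 < angle < 225; the away quadrant Q3 is angle < 45 or
# angle > 315; boundary angles fall in "other".

#' Read neurite traces from CSV or SWC
#'
#' Trace CSVs carry one neuron per row with columns `neuron_id`,
#' `condition`, `length_um` (soma-to-growth-cone path length) and
#' `angle_deg` (orientation on `[0, 360)`, 180 = toward the source).
#' Malformed rows (non-finite or negative length, angle out of range) are
#' not dropped silently: they are collected, with reasons, in the
#' `"rejected"` attribute of the result.
#'
#' SWC morphology files (standard 7 columns: id, type, x, y, z, radius,
#' parent) are accepted for single neurons: length is the cumulative
#' parent-child segment distance along the longest soma-to-tip path, and
#' the angle is the planar orientation of the soma-to-tip vector.
#'
#' @param path path to a `.csv` trace table or a `.swc` morphology file,
#'   or a data frame already holding the CSV columns.
#' @param condition condition label for SWC input (default `"unknown"`).
#' @return a `neurite_traces` data frame with attribute `rejected` (a data
#'   frame of dropped rows and a `reason` column).
#' @examples
#' df <- data.frame(neuron_id = 1:3, condition = "CTRL",
#'                  length_um = c(12, 15, 18), angle_deg = c(10, 180, 200))
#' read_traces(df)
#' @export
read_traces <- function(path, condition = "unknown") {
  if (is.data.frame(path)) {
    return(.validate_traces(path))
  }
  stopifnot(is.character(path), length(path) == 1L)
  if (grepl("\\.swc$", path, ignore.case = TRUE)) {
    return(.validate_traces(read_swc_trace(path, condition = condition)))
  }
  df <- read.csv(path, stringsAsFactors = FALSE)
  .validate_traces(df)
}

.validate_traces <- function(df) {
  req <- c("neuron_id", "condition", "length_um", "angle_deg")
  missing <- setdiff(req, names(df))
  if (length(missing)) {
    stop("trace table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df <- df[req]
  len <- suppressWarnings(as.numeric(df$length_um))
  ang <- suppressWarnings(as.numeric(df$angle_deg))
  reason <- rep(NA_character_, nrow(df))
  reason[!is.finite(len)] <- "non-finite length"
  reason[is.finite(len) & len < 0] <- "negative length"
  bad_ang <- !is.finite(ang) | ang < 0 | ang >= 360
  reason[is.na(reason) & bad_ang] <- "angle outside [0, 360)"
  keep <- is.na(reason)
  rejected <- df[!keep, , drop = FALSE]
  if (nrow(rejected)) rejected$reason <- reason[!keep]
  out <- df[keep, , drop = FALSE]
  out$length_um <- len[keep]
  out$angle_deg <- ang[keep]
  rownames(out) <- NULL
  structure(out, rejected = rejected,
            class = c("neurite_traces", "data.frame"))
}

#' @rdname read_traces
#' @export
read_swc_trace <- function(path, condition = "unknown") {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines)) stop("SWC file has no data rows", call. = FALSE)
  m <- read.table(text = lines,
                  col.names = c("id", "type", "x", "y", "z", "radius",
                                "parent"))
  soma <- m$id[m$type == 1L]
  if (!length(soma)) stop("SWC file has no soma node (type 1)",
                          call. = FALSE)
  root <- soma[1]
  # cumulative path length from the soma, following parent links
  idx <- match(m$parent, m$id)
  plen <- rep(NA_real_, nrow(m))
  plen[m$id == root] <- 0
  # iterate until all reachable nodes are assigned (tree depth passes)
  for (pass in seq_len(nrow(m))) {
    todo <- which(is.na(plen) & !is.na(idx) & !is.na(plen[idx]))
    if (!length(todo)) break
    seg <- sqrt((m$x[todo] - m$x[idx[todo]])^2 +
                (m$y[todo] - m$y[idx[todo]])^2 +
                (m$z[todo] - m$z[idx[todo]])^2)
    plen[todo] <- plen[idx[todo]] + seg
  }
  tips <- which(!(m$id %in% m$parent) & !is.na(plen))
  if (!length(tips)) stop("SWC file has no reachable tip", call. = FALSE)
  far <- tips[which.max(plen[tips])]
  s <- which(m$id == root)
  ang <- atan2(m$y[far] - m$y[s], m$x[far] - m$x[s]) * 180 / pi
  data.frame(
    neuron_id = basename(path),
    condition = condition,
    length_um = plen[far],
    angle_deg = ang %% 360,
    stringsAsFactors = FALSE
  )
}

#' Summarise neurite outgrowth for one condition
#'
#' Computes the per-condition outgrowth statistics: sample size, mean and
#' sd of length, fold change versus a control sample (with first-order
#' propagated sd), and the length histogram over the standard bins
#' `[1, 10], (10, 20], (20, 30], ...` (neurites shorter than 1 um are
#' excluded from the histogram, not from the mean).
#'
#' @param traces a `neurite_traces` data frame (or any data frame with a
#'   `length_um` column), or a numeric vector of lengths in um.
#' @param control optional control sample in the same form; enables the
#'   fold-change fields.
#' @param binwidth_um histogram bin width in um (default 10; the first bin
#'   always starts at 1 um).
#' @return an object of class `outgrowth_summary`: list with `n`,
#'   `mean_um`, `sd_um`, `fold`, `fold_sd`, `histogram` (data frame
#'   `bin_lo`, `bin_hi`, `count`, `fraction`) and `n_below_1um`.
#' @examples
#' summarize_outgrowth(c(10, 20, 30), control = c(10, 20, 30))$fold  # 1
#' @export
summarize_outgrowth <- function(traces, control = NULL, binwidth_um = 10) {
  len <- .as_lengths(traces)
  if (!length(len)) stop("`traces` is empty", call. = FALSE)
  out <- list(
    n = length(len),
    mean_um = mean(len),
    sd_um = if (length(len) > 1L) sd(len) else 0,
    fold = NA_real_,
    fold_sd = NA_real_,
    histogram = .length_histogram(len, binwidth_um),
    n_below_1um = sum(len < 1)
  )
  if (!is.null(control)) {
    lc <- .as_lengths(control)
    if (!length(lc) || mean(lc) <= 0) {
      warning("fold change undefined: control sample empty or zero-mean")
    } else {
      mc <- mean(lc)
      sc <- if (length(lc) > 1L) sd(lc) else 0
      out$fold <- out$mean_um / mc
      # first-order propagation of the two sds through the ratio
      if (out$mean_um > 0) {
        out$fold_sd <- out$fold *
          sqrt((out$sd_um / out$mean_um)^2 + (sc / mc)^2)
      }
      out$control_mean_um <- mc
      out$control_n <- length(lc)
    }
  }
  structure(out, class = "outgrowth_summary")
}

.as_lengths <- function(x) {
  if (is.numeric(x)) {
    .check_finite_vec(x, "lengths", min = 0)
    return(x)
  }
  if (is.data.frame(x) && "length_um" %in% names(x)) {
    return(.as_lengths(x$length_um))
  }
  stop("expected a numeric vector of lengths or a trace data frame",
       call. = FALSE)
}

# histogram over [1, bw], (bw, 2 bw], ... ; fractions over neurites >= 1 um
.length_histogram <- function(len, binwidth_um = 10) {
  .check_number(binwidth_um, "binwidth_um", min = 0, allow_min = FALSE)
  len <- len[len >= 1]
  if (!length(len)) {
    return(data.frame(bin_lo = numeric(), bin_hi = numeric(),
                      count = integer(), fraction = numeric()))
  }
  top <- max(binwidth_um, ceiling(max(len) / binwidth_um) * binwidth_um)
  breaks <- unique(c(1, seq(binwidth_um, top, by = binwidth_um)))
  cnt <- as.integer(table(cut(len, breaks, include.lowest = TRUE,
                              right = TRUE)))
  data.frame(
    bin_lo = breaks[-length(breaks)],
    bin_hi = breaks[-1],
    count = cnt,
    fraction = cnt / sum(cnt)
  )
}

#' @export
print.outgrowth_summary <- function(x, ...) {
  cat(sprintf("<outgrowth_summary> n = %d, length %.2f +/- %.2f um\n",
              x$n, x$mean_um, x$sd_um))
  if (!is.na(x$fold)) {
    cat(sprintf("  fold vs control: %.2f +/- %.2f\n", x$fold, x$fold_sd))
  }
  if (x$n_below_1um > 0) {
    cat(sprintf("  %d neurite(s) < 1 um excluded from the histogram\n",
                x$n_below_1um))
  }
  invisible(x)
}

#' Classify a turning angle into quadrants
#'
#' Q1 (toward the gradient source): `135 < angle < 225`. Q3 (away):
#' `angle < 45` or `angle > 315`. The boundary angles 45, 135, 225 and 315
#' are classified as `"other"` (strict inequalities). Each quadrant covers
#' 90 degrees of angular measure, so uniformly oriented neurites fall in
#' each with probability 1/4.
#'
#' @param angle_deg angle(s) in degrees, each in `[0, 360)`.
#' @return a factor with levels `Q1`, `Q3`, `other`.
#' @examples
#' classify_turning(c(180, 0, 135))  # Q1, Q3, other
#' @export
classify_turning <- function(angle_deg) {
  .check_finite_vec(angle_deg, "angle_deg")
  if (any(angle_deg < 0 | angle_deg >= 360)) {
    stop("angles must lie in [0, 360)", call. = FALSE)
  }
  out <- rep("other", length(angle_deg))
  out[angle_deg > 135 & angle_deg < 225] <- "Q1"
  out[angle_deg < 45 | angle_deg > 315] <- "Q3"
  factor(out, levels = c("Q1", "Q3", "other"))
}

#' Summarise neurite turning for one condition
#'
#' Quadrant fractions per [classify_turning()] plus a 24-sector (15 degree)
#' wind-rose count table.
#'
#' @param traces a `neurite_traces` data frame (or any data frame with an
#'   `angle_deg` column), or a numeric vector of angles in degrees.
#' @return an object of class `turning_summary`: list with `n`,
#'   `q1_fraction`, `q3_fraction`, `other_fraction` and `windrose`
#'   (data frame `sector_lo`, `sector_hi`, `count`).
#' @examples
#' turning_summary(rep(180, 5))$q1_fraction  # 1
#' @export
turning_summary <- function(traces) {
  ang <- if (is.numeric(traces)) traces
         else if (is.data.frame(traces) && "angle_deg" %in% names(traces))
           traces$angle_deg
         else stop("expected angles or a trace data frame", call. = FALSE)
  if (!length(ang)) stop("`traces` is empty", call. = FALSE)
  cls <- classify_turning(ang)
  tab <- table(cls) / length(ang)
  edges <- seq(0, 360, by = 15)
  cnt <- as.integer(table(cut(ang, edges, include.lowest = TRUE,
                              right = FALSE)))
  structure(
    list(n = length(ang),
         q1_fraction = as.numeric(tab[["Q1"]]),
         q3_fraction = as.numeric(tab[["Q3"]]),
         other_fraction = as.numeric(tab[["other"]]),
         windrose = data.frame(sector_lo = edges[-25], sector_hi = edges[-1],
                               count = cnt)),
    class = "turning_summary")
}

#' @export
print.turning_summary <- function(x, ...) {
  cat(sprintf(
    "<turning_summary> n = %d: Q1 (toward) %.1f%%, Q3 (away) %.1f%%, other %.1f%%\n",
    x$n, 100 * x$q1_fraction, 100 * x$q3_fraction, 100 * x$other_fraction))
  invisible(x)
}

#' Two-sample comparison of outgrowth (or any per-neuron measure)
#'
#' Compares two samples with Welch's t test or the Mann-Whitney (Wilcoxon
#' rank-sum) test. `method = "auto"` screens both samples for normality
#' (Shapiro-Wilk at alpha = 0.05) and picks Welch when both pass, the
#' rank-sum test otherwise. Degenerate zero-variance samples under Welch
#' fall back to the rank-sum test with a warning. Two-sided p values.
#'
#' @param sample_a,sample_b numeric vectors (each n >= 3).
#' @param method `"auto"`, `"welch_t"` or `"mann_whitney"`.
#' @return an object of class `group_comparison`: list with `method`,
#'   `statistic`, `p_value`, `n_a`, `n_b`.
#' @examples
#' compare_groups(c(1, 2, 3), c(101, 102, 103), method = "welch_t")
#' @export
compare_groups <- function(sample_a, sample_b,
                           method = c("auto", "welch_t", "mann_whitney")) {
  method <- match.arg(method)
  .check_finite_vec(sample_a, "sample_a")
  .check_finite_vec(sample_b, "sample_b")
  if (length(sample_a) < 3L || length(sample_b) < 3L) {
    stop("each sample needs n >= 3", call. = FALSE)
  }
  normal_enough <- function(x) {
    if (sd(x) == 0) return(FALSE)
    if (length(x) > 5000L) x <- x[round(seq(1, length(x), length.out = 5000L))]
    tryCatch(shapiro.test(x)$p.value > 0.05, error = function(e) FALSE)
  }
  if (method == "auto") {
    method <- if (normal_enough(sample_a) && normal_enough(sample_b)) {
      "welch_t"
    } else {
      "mann_whitney"
    }
  }
  if (method == "welch_t" && (sd(sample_a) == 0 && sd(sample_b) == 0)) {
    warning("zero variance in both samples; falling back to Mann-Whitney")
    method <- "mann_whitney"
  }
  ht <- if (method == "welch_t") {
    t.test(sample_a, sample_b, var.equal = FALSE)
  } else {
    suppressWarnings(wilcox.test(sample_a, sample_b, exact = NULL))
  }
  structure(
    list(method = method,
         statistic = unname(ht$statistic),
         p_value = ht$p.value,
         n_a = length(sample_a), n_b = length(sample_b)),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: statistic = %.4g, p = %.4g (n = %d, %d)\n",
              x$method, x$statistic, x$p_value, x$n_a, x$n_b))
  invisible(x)
}
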