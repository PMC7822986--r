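# The three neural-health estimates: multipulse integration (MPI), polarity
# effect (PE) and the interphase-gap (IPG) offset between two ECAP amplitude
# growth functions.

#' ECAP amplitude growth function at one interphase gap
#'
#' An AGF is a set of (level, amplitude) points in log-log coordinates:
#' stimulus level in dB re 1 uA, ECAP amplitude in dB re 1 uV. Points can
#' be flagged as excluded (noise floor or saturation) without being
#' removed, so the measured support is preserved.
#'
#' @param levels_db Strictly increasing stimulus levels, dB re 1 uA.
#' @param amplitudes_db Amplitudes, dB re 1 uV.
#' @param ipg_us Interphase gap tag, microseconds.
#' @param floor_db Optional recording noise floor, dB re 1 uV.
#' @param excluded Optional logical flags per point.
#' @return An `agf` data frame.
#' @export
agf <- function(levels_db, amplitudes_db, ipg_us, floor_db = NULL,
                excluded = NULL) {
  stopifnot(length(levels_db) == length(amplitudes_db))
  if (is.unsorted(levels_db, strictly = TRUE))
    stop("AGF levels must be strictly increasing", call. = FALSE)
  if (is.null(excluded)) excluded <- rep(FALSE, length(levels_db))
  out <- data.frame(level_db = levels_db, amplitude_db = amplitudes_db,
                    excluded = excluded)
  attr(out, "ipg_us") <- ipg_us
  attr(out, "floor_db") <- floor_db
  class(out) <- c("agf", "data.frame")
  out
}

#' Trim an AGF to its linear growth region
#'
#' Reproducible substitute for the manual selection of the linear portion
#' of an amplitude growth function. Three rules are applied in order:
#' points within `floor_margin_db` of the noise floor are excluded; trailing
#' points whose local slope falls below `slope_ratio` of the maximum local
#' slope are excluded as saturation; then, while the linear fit of the
#' remaining points has R-squared below `r2_min`, the endpoint whose removal
#' improves the fit most is dropped (never below 2 points).
#'
#' @param x An [agf()].
#' @param floor_margin_db Margin above the noise floor, dB.
#' @param slope_ratio Saturation rule: fraction of the maximum local slope.
#' @param r2_min Minimum R-squared of the retained points' linear fit.
#' @return The AGF with its `excluded` flags updated.
#' @export
trim_to_linear_region <- function(x, floor_margin_db = 1, slope_ratio = 0.5,
                                  r2_min = 0.95) {
  stopifnot(inherits(x, "agf"))
  keep <- !x$excluded
  floor_db <- attr(x, "floor_db")
  if (!is.null(floor_db))
    keep <- keep & (x$amplitude_db >= floor_db + floor_margin_db)
  idx <- which(keep)
  if (length(idx) >= 3) {
    lv <- x$level_db[idx]
    am <- x$amplitude_db[idx]
    sl <- diff(am) / diff(lv)             # local slopes between kept points
    max_sl <- max(sl)
    if (max_sl > 0) {
      # drop trailing saturated points
      n <- length(idx)
      while (n >= 3 && sl[n - 1] < slope_ratio * max_sl) n <- n - 1
      idx <- idx[seq_len(n)]
    }
  }
  # endpoint trimming until the linear fit is acceptable
  r2 <- function(i) {
    if (length(i) < 3) return(1)
    f <- stats::lm.fit(cbind(1, x$level_db[i]), x$amplitude_db[i])
    1 - sum(f$residuals^2) / sum((x$amplitude_db[i] -
                                    mean(x$amplitude_db[i]))^2)
  }
  while (length(idx) > 2 && r2(idx) < r2_min) {
    drop_first <- r2(idx[-1])
    drop_last <- r2(idx[-length(idx)])
    idx <- if (drop_first >= drop_last) idx[-1] else idx[-length(idx)]
  }
  if (length(idx) < 2)
    stop("degenerate AGF: fewer than 2 points survive trimming",
         call. = FALSE)
  x$excluded <- !(seq_len(nrow(x)) %in% idx)
  x
}

.agf_included <- function(x) x[!x$excluded, , drop = FALSE]

#' IPG offset between two amplitude growth functions
#'
#' The offset is the average difference (in dB) between the overlapping
#' linear portions of the two AGFs: both curves are evaluated on a common
#' level grid in steps of `grid_db` spanning the overlap of their included
#' ranges, using linear interpolation between the two nearest measured
#' points, and the mean of (long minus short) amplitude is returned. No
#' extrapolation outside the measured support is performed.
#'
#' `mode = "horizontal"` instead averages the level difference (short minus
#' long) at equal amplitudes over the overlapping amplitude range — the
#' equal-output current-shift reading used in some animal studies; it
#' requires both trimmed AGFs to grow monotonically.
#'
#' @param agf_short,agf_long Trimmed [agf()] objects at the short and long
#'   interphase gap.
#' @param grid_db Evaluation grid step, dB.
#' @param mode `"vertical"` (default) or `"horizontal"`.
#' @return Offset in dB; positive when the long-IPG response is larger
#'   (vertical) or reached at lower current (horizontal).
#' @export
ipg_offset <- function(agf_short, agf_long, grid_db = 0.1,
                       mode = c("vertical", "horizontal")) {
  mode <- match.arg(mode)
  stopifnot(inherits(agf_short, "agf"), inherits(agf_long, "agf"))
  s <- .agf_included(agf_short)
  l <- .agf_included(agf_long)
  if (nrow(s) < 2 || nrow(l) < 2)
    stop("need >= 2 included points per AGF", call. = FALSE)
  if (mode == "vertical") {
    lo <- max(min(s$level_db), min(l$level_db))
    hi <- min(max(s$level_db), max(l$level_db))
    if (hi - lo < 0.2)
      stop("no overlap between the linear portions of the AGFs",
           call. = FALSE)
    grid <- seq(lo, hi, by = grid_db)
    as_ <- stats::approx(s$level_db, s$amplitude_db, xout = grid)$y
    al <- stats::approx(l$level_db, l$amplitude_db, xout = grid)$y
    mean(al - as_)
  } else {
    if (is.unsorted(s$amplitude_db, strictly = TRUE) ||
        is.unsorted(l$amplitude_db, strictly = TRUE))
      stop("horizontal mode requires monotonically growing AGFs",
           call. = FALSE)
    lo <- max(min(s$amplitude_db), min(l$amplitude_db))
    hi <- min(max(s$amplitude_db), max(l$amplitude_db))
    if (hi - lo < 0.2)
      stop("no overlap between the linear portions of the AGFs",
           call. = FALSE)
    grid <- seq(lo, hi, by = grid_db)
    ls_ <- stats::approx(s$amplitude_db, s$level_db, xout = grid)$y
    ll <- stats::approx(l$amplitude_db, l$level_db, xout = grid)$y
    mean(ls_ - ll)
  }
}

#' Multipulse integration from a pair of thresholds
#'
#' MPI is the detection threshold at 80 pps minus the threshold at
#' 1000 pps; positive values mean an integration benefit at the high rate.
#'
#' @param threshold_80pps,threshold_1000pps Thresholds, dB re 1 uA (or any
#'   common dB scale). Missing inputs give `NA`.
#' @return MPI in dB.
#' @export
compute_mpi <- function(threshold_80pps, threshold_1000pps) {
  ifelse(is.na(threshold_80pps) | is.na(threshold_1000pps), NA_real_,
         threshold_80pps - threshold_1000pps)
}

#' Polarity effect from a pair of quadraphasic thresholds
#'
#' PE is the cathodic-centred threshold minus the anodic-centred threshold;
#' negative values (cathodic advantage) are the conventional signature of
#' surviving peripheral processes.
#'
#' @param threshold_cathodic,threshold_anodic Thresholds, dB. Missing
#'   inputs give `NA`.
#' @return PE in dB.
#' @export
compute_pe <- function(threshold_cathodic, threshold_anodic) {
  ifelse(is.na(threshold_cathodic) | is.na(threshold_anodic), NA_real_,
         threshold_cathodic - threshold_anodic)
}
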