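#' Kaplan-Meier survival estimate for one treatment arm
#'
#' Product-limit estimator with right censoring (via the survival
#' package). The median is the smallest time t with S(t) <= 0.5 and is
#' reported as NA when the curve never reaches 0.5. Arms below `min_worms`
#' tracked worms are rejected unless the gate is waived, mirroring the
#' quality rule for reportable lifespan curves.
#'
#' @param table survival data.frame (`worm`, `arm`, `day`, `censored`).
#' @param arm arm label to estimate (default: all rows).
#' @param min_worms minimum worms per reportable curve.
#' @param waive_min_n set TRUE to analyse smaller arms anyway.
#' @return object of class `km_curve`: `curve` data.frame (`time`,
#'   `n_risk`, `n_event`, `surv`), `median`, `n`, `arm`.
#' @export
km_estimate <- function(table, arm = NULL, min_worms = 50,
                        waive_min_n = FALSE) {
  if (!is.null(arm)) table <- table[table$arm == arm, , drop = FALSE]
  if (nrow(table) == 0L) stop("no worms in the requested arm")
  if (nrow(table) < min_worms && !waive_min_n) {
    stop(sprintf("arm has %d worms (< %d); set waive_min_n = TRUE to analyse",
                 nrow(table), min_worms))
  }
  fit <- survival::survfit(
    survival::Surv(table$day, 1 - table$censored) ~ 1
  )
  # median convention: smallest t with S(t) <= 0.5 (right-continuous steps)
  at_half <- which(fit$surv <= 0.5 + 1e-12)
  med <- if (length(at_half)) fit$time[at_half[1L]] else NA_real_
  structure(list(
    curve = data.frame(time = fit$time, n_risk = fit$n.risk,
                       n_event = fit$n.event, surv = fit$surv),
    median = med,
    n = nrow(table),
    arm = if (is.null(arm)) "all" else arm
  ), class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve, arm '%s': n = %d, median = %s days\n",
              x$arm, x$n,
              if (is.na(x$median)) "not reached" else format(x$median)))
  invisible(x)
}

#' Two-group log-rank test
#'
#' Standard (unweighted) log-rank comparison of two arms; p from the
#' chi-square distribution with 1 df. Symmetric in the arm labels.
#'
#' @param table survival data.frame (`worm`, `arm`, `day`, `censored`).
#' @param arm_a,arm_b the two arm labels.
#' @return list: `chisq`, `p`, `n` (per-arm worm counts).
#' @export
logrank_test <- function(table, arm_a, arm_b) {
  sub <- table[table$arm %in% c(arm_a, arm_b), , drop = FALSE]
  if (!all(c(arm_a, arm_b) %in% sub$arm)) stop("both arms must be nonempty")
  if (all(sub$censored == 1)) stop("no events in either arm")
  sd <- survival::survdiff(
    survival::Surv(day, 1 - censored) ~ arm, data = sub
  )
  chisq <- unname(sd$chisq)
  list(chisq = chisq,
       p = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
       n = table(sub$arm))
}

#' Percent change in median lifespan
#'
#' @param treated,control median lifespans in days; both must be defined
#'   and the control positive.
#' @return `100 * (treated - control) / control`.
#' @export
median_lifespan_change <- function(treated, control) {
  if (is.na(treated) || is.na(control)) {
    stop("median lifespan undefined for one of the arms")
  }
  if (control <= 0) stop("control median must be positive")
  100 * (treated - control) / control
}

#' Reconstruct binary occupancy grids from a position log
#'
#' One binary matrix per timepoint: cell (x, y) is 1 iff a worm object was
#' recorded there (idempotent for coincident objects), 0 elsewhere.
#'
#' @param positions data.frame with columns `plate`, `timepoint`, `x`, `y`
#'   (integer pixel coordinates).
#' @param plate plate id to reconstruct.
#' @param dims grid dimensions `c(width, height)`.
#' @param timepoints optional explicit timepoint grid; timepoints with no
#'   recorded objects yield all-zero grids. Default: the timepoints present
#'   in the log.
#' @return object of class `occupancy_series`: `timepoints` (strictly
#'   increasing) and `grids` (list of 0/1 matrices).
#' @export
occupancy_series <- function(positions, plate, dims, timepoints = NULL) {
  sub <- positions[positions$plate == plate, , drop = FALSE]
  if (nrow(sub) == 0L && is.null(timepoints)) {
    stop("no positions recorded for plate ", plate)
  }
  oob <- sub$x < 1 | sub$x > dims[1] | sub$y < 1 | sub$y > dims[2]
  if (any(oob)) {
    i <- which(oob)[1L]
    stop(sprintf("out-of-bounds coordinate on plate %s at timepoint %s",
                 plate, format(sub$timepoint[i])))
  }
  tps <- if (is.null(timepoints)) sort(unique(sub$timepoint))
         else sort(unique(timepoints))
  grids <- lapply(tps, function(t) {
    g <- matrix(0L, dims[1], dims[2])
    at <- sub[sub$timepoint == t, , drop = FALSE]
    g[cbind(at$x, at$y)] <- 1L
    g
  })
  structure(list(timepoints = tps, grids = grids, plate = plate),
            class = "occupancy_series")
}

#' Pearson correlations between adjacent occupancy frames
#'
#' Flattens each binary grid to a vector and correlates every timepoint n
#' with its direct successor n + 1. Higher correlation means less
#' population movement. Pairs where either frame has zero variance (e.g.
#' empty late frames) are recorded as NA. Timepoints beyond
#' `death_time` are omitted.
#'
#' @param series an `occupancy_series`.
#' @param death_time last timepoint to use (default: all).
#' @return data.frame (`time` = the earlier timepoint of the pair, `r`).
#' @export
activity_correlations <- function(series, death_time = Inf) {
  stopifnot(inherits(series, "occupancy_series"))
  keep <- series$timepoints <= death_time
  tps <- series$timepoints[keep]
  grids <- series$grids[keep]
  if (length(tps) < 2L) stop("need at least 2 usable timepoints")
  r <- vapply(seq_len(length(tps) - 1L), function(i) {
    a <- as.numeric(grids[[i]]); b <- as.numeric(grids[[i + 1L]])
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }, numeric(1))
  data.frame(time = tps[-length(tps)], r = r)
}

#' Derive a normalized population activity curve
#'
#' Pools adjacent-frame correlation sequences from one or more plates,
#' smooths them with a smoothing spline (smoothing chosen by generalized
#' cross-validation), then mirrors and affinely normalizes the smoothed
#' curve so the minimum correlation maps to activity 1 ("most active") and
#' the maximum to 0 ("least active"). Values before the time of maximum
#' activity are clamped to 1 (population optimum) and values after the
#' time of minimum activity are clamped to 0 (end of movement). The curve
#' is invariant to a global shift of all correlation values.
#'
#' @param corrs data.frame (`time`, `r`) or list of such data.frames from
#'   [activity_correlations()]; NAs dropped.
#' @param death_time correlations beyond this time are omitted.
#' @param grid_n evaluation grid size over the observed time range.
#' @param smooth set FALSE to skip spline smoothing (mirror/normalize the
#'   raw sequence instead).
#' @return object of class `activity_curve`: `curve` data.frame (`time`,
#'   `activity` in \[0, 1\]), `t_peak` (peak-activity time), `t_end`
#'   (end-of-movement time).
#' @export
activity_curve <- function(corrs, death_time = Inf, grid_n = 200,
                           smooth = TRUE) {
  if (is.data.frame(corrs)) corrs <- list(corrs)
  pooled <- do.call(rbind, corrs)
  pooled <- pooled[!is.na(pooled$r) & pooled$time <= death_time, ,
                   drop = FALSE]
  if (nrow(pooled) < 2L) stop("need at least 2 usable correlations")

  tgrid <- seq(min(pooled$time), max(pooled$time), length.out = grid_n)
  if (diff(range(pooled$r)) < 1e-12) {
    warning("constant correlation sequence; returning a degenerate flat curve")
    act <- ifelse(tgrid <= death_time, 1, 0)
    return(structure(list(
      curve = data.frame(time = tgrid, activity = act),
      t_peak = tgrid[1L], t_end = max(tgrid), degenerate = TRUE
    ), class = "activity_curve"))
  }

  if (smooth && length(unique(pooled$time)) >= 4L) {
    sm <- stats::smooth.spline(pooled$time, pooled$r)   # GCV by default
    rhat <- stats::predict(sm, tgrid)$y
  } else {
    rhat <- stats::approx(pooled$time, pooled$r, xout = tgrid, rule = 2,
                          ties = mean)$y
  }

  lo <- min(rhat); hi <- max(rhat)
  if (hi - lo < 1e-12) {
    act <- rep(1, length(tgrid))
    t_peak <- tgrid[1L]; t_end <- max(tgrid)
  } else {
    act <- (hi - rhat) / (hi - lo)       # mirror + normalize to [0, 1]
    t_peak <- tgrid[which.max(act)]      # lowest correlation = most active
    t_end <- tgrid[which.min(act)]       # highest correlation = least active
    act[tgrid < t_peak] <- 1
    act[tgrid > t_end] <- 0
  }
  structure(list(
    curve = data.frame(time = tgrid, activity = pmin(pmax(act, 0), 1)),
    t_peak = t_peak, t_end = t_end, degenerate = FALSE
  ), class = "activity_curve")
}

#' @export
print.activity_curve <- function(x, ...) {
  cat(sprintf("activity curve over [%.1f, %.1f] d; peak activity to %.1f d, movement ends %.1f d\n",
              min(x$curve$time), max(x$curve$time), x$t_peak, x$t_end))
  h <- half_activity_time(x)
  cat(sprintf("  half-activity time: %s d\n",
              if (is.na(h)) "not reached" else sprintf("%.2f", h)))
  invisible(x)
}

#' Time at which population activity first drops to 0.5
#'
#' @param curve an `activity_curve`.
#' @return time of the first crossing (linear interpolation), or NA if the
#'   curve never reaches 0.5.
#' @export
half_activity_time <- function(curve) {
  stopifnot(inherits(curve, "activity_curve"))
  tt <- curve$curve$time
  a <- curve$curve$activity
  below <- which(a <= 0.5)
  if (length(below) == 0L) return(NA_real_)
  i <- below[1L]
  if (i == 1L) return(tt[1L])
  # linear interpolation between the bracketing grid points
  t0 <- tt[i - 1L]; t1 <- tt[i]; a0 <- a[i - 1L]; a1 <- a[i]
  if (a0 == a1) return(t1)
  t0 + (a0 - 0.5) / (a0 - a1) * (t1 - t0)
}

#' Full activity analysis for one treatment arm
#'
#' Convenience wrapper: builds occupancy grids per plate, computes
#' adjacent-frame correlations (cut at the arm's last event time), pools
#' the plates and fits the activity curve.
#'
#' @param positions position log (`plate`, `timepoint`, `x`, `y`).
#' @param survival survival table (`worm`, `arm`, `plate`, `day`,
#'   `censored`) used to find the arm's plates and death time.
#' @param arm arm label.
#' @param dims occupancy grid dimensions.
#' @return an `activity_curve`.
#' @export
arm_activity_curve <- function(positions, survival, arm, dims) {
  plates <- unique(survival$plate[survival$arm == arm])
  if (length(plates) == 0L) stop("no plates recorded for arm ", arm)
  events <- survival$day[survival$arm == arm & survival$censored == 0]
  death_time <- if (length(events)) max(events) else Inf
  corrs <- lapply(plates, function(p) {
    activity_correlations(occupancy_series(positions, p, dims), death_time)
  })
  activity_curve(corrs, death_time = death_time)
}
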