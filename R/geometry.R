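# Time-dependent domain geometry: measured hindbrain dimensions, smooth
# interpolants, the three L-R convergence schedules, and the affine growth
# velocity field shared by all other modules.

#' Measured hindbrain dimensions, 11-14 hpf
#'
#' Returns the packaged table of hindbrain dimensions used to drive the
#' time-dependent rectangular domains. L-R widths at 11, 12 and 14 hpf are the
#' measured values (283, 162 and 104 um at the A-P level of r4). The A-P
#' lengths (`L1_um`, posterior MHB edge to posterior end of the RA production
#' region), the anterior edge of the RA production region (`p_um`) and the
#' 13-hpf width are fixture assumptions chosen to be consistent with slow A-P
#' elongation and rapid-then-slow narrowing; they are not measured values.
#'
#' @return A data.frame with columns `time_hpf`, `L1_um`, `L2_um`, `p_um`.
#' @export
#' @examples
#' hindbrain_dimensions()
hindbrain_dimensions <- function() {
  data.frame(
    time_hpf = c(11, 12, 13, 14),
    L1_um    = c(300, 310, 320, 330),
    L2_um    = c(283, 162, 120, 104),
    p_um     = c(240, 248, 256, 265)
  )
}

#' Validate a dimension table
#'
#' @param table data.frame with columns `time_hpf`, `L1_um`, `L2_um`, `p_um`.
#' @return The table, invisibly, after checking invariants.
#' @keywords internal
validate_dimension_table <- function(table) {
  req <- c("time_hpf", "L1_um", "L2_um", "p_um")
  if (!all(req %in% names(table)))
    stop("dimension table must have columns ", paste(req, collapse = ", "))
  if (nrow(table) < 3)
    stop("cubic interpolation needs at least 3 time points")
  if (any(diff(table$time_hpf) <= 0))
    stop("times must be strictly increasing")
  if (any(table$L1_um <= 0) || any(table$L2_um <= 0) || any(table$p_um <= 0))
    stop("all lengths must be positive")
  if (any(table$p_um > table$L1_um))
    stop("RA-production onset p must not exceed the A-P length L1")
  invisible(table)
}

#' Read or write a dimension table as CSV
#'
#' @param path file path of a CSV with header `time_hpf,L1_um,L2_um,p_um`.
#' @return `read_dimension_table` returns the validated data.frame.
#' @export
read_dimension_table <- function(path) {
  tab <- utils::read.csv(path)
  validate_dimension_table(tab)
  tab
}

#' @rdname read_dimension_table
#' @param table a valid dimension table.
#' @export
write_dimension_table <- function(table, path) {
  validate_dimension_table(table)
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Fit smooth dimension curves
#'
#' Fits monotone cubic (Hyman-filtered) interpolants through the measured
#' times, returning functions with continuous first derivatives that pass
#' exactly through the tabulated values.
#'
#' @param table a dimension table (see [hindbrain_dimensions()]).
#' @return An object of class `dimension_curves`: a list of functions
#'   `L1(t)`, `L2(t)`, `p(t)` and derivatives `dL1(t)`, `dL2(t)`, `dp(t)`,
#'   plus the time range.
#' @export
fit_dimension_curves <- function(table = hindbrain_dimensions()) {
  validate_dimension_table(table)
  t <- table$time_hpf
  mk <- function(y) {
    f <- stats::splinefun(t, y, method = "hyman")
    list(val = function(tt) f(tt), der = function(tt) f(tt, deriv = 1))
  }
  fL1 <- mk(table$L1_um); fL2 <- mk(table$L2_um); fp <- mk(table$p_um)
  structure(list(
    L1 = fL1$val, dL1 = fL1$der,
    L2 = fL2$val, dL2 = fL2$der,
    p  = fp$val,  dp  = fp$der,
    t_range = range(t)
  ), class = "dimension_curves")
}

#' Build a convergence schedule
#'
#' The `rapid` schedule is the measured width curve. `medium` is the straight
#' line between the endpoint widths. `slow` is the reflection of the rapid
#' graph across that straight line: in coordinates normalized so the chord runs
#' from (0,1) to (1,0), the mirror across the chord maps (u,v) to (1-v,1-u),
#' i.e. the slow curve is the flipped inverse of the rapid one. This is
#' single-valued, monotone non-increasing by construction and an exact
#' involution. The alternative pointwise reflection `2*linear - rapid` is kept
#' behind `slow_mode = "pointwise"` (it overshoots the initial width near the
#' start and is clipped to be monotone).
#'
#' @param kind one of `"rapid"`, `"medium"`, `"slow"`.
#' @param curves a `dimension_curves` object (the rapid width lives in `$L2`).
#' @param slow_mode `"reflect"` (default) or `"pointwise"`.
#' @return An object of class `convergence_schedule` with elements `kind`,
#'   `width_fn(t)`, `dwidth_fn(t)` and the underlying `curves`.
#' @export
make_schedule <- function(kind = c("rapid", "medium", "slow"),
                          curves = fit_dimension_curves(),
                          slow_mode = c("reflect", "pointwise")) {
  kind <- match.arg(kind)
  slow_mode <- match.arg(slow_mode)
  t0 <- curves$t_range[1]; t1 <- curves$t_range[2]
  w0 <- curves$L2(t0); w1 <- curves$L2(t1)
  if (kind == "rapid") {
    width_fn <- curves$L2; dwidth_fn <- curves$dL2
  } else if (kind == "medium") {
    slope <- (w1 - w0) / (t1 - t0)
    width_fn <- function(tt) w0 + slope * (tt - t0)
    dwidth_fn <- function(tt) rep(slope, length(tt))
  } else if (slow_mode == "reflect") {
    # normalized rapid graph v = Rn(u), u,v in [0,1], decreasing
    ugrid <- seq(0, 1, length.out = 2001)
    vgrid <- (curves$L2(t0 + (t1 - t0) * ugrid) - w1) / (w0 - w1)
    # inverse sampled on the (decreasing) v grid
    inv <- stats::splinefun(rev(vgrid), rev(ugrid), method = "hyman")
    slow_n <- 1 - inv(1 - ugrid)               # mirrored graph, still 1 -> 0
    slow_n <- cummin(pmin(pmax(slow_n, 0), 1)) # guard clip (no-op in practice)
    slow_n[1] <- 1; slow_n[length(slow_n)] <- 0
    f <- stats::splinefun(t0 + (t1 - t0) * ugrid, w1 + (w0 - w1) * slow_n,
                          method = "hyman")
    width_fn <- function(tt) f(tt)
    dwidth_fn <- function(tt) f(tt, deriv = 1)
  } else {
    slope <- (w1 - w0) / (t1 - t0)
    lin <- function(tt) w0 + slope * (tt - t0)
    tgrid <- seq(t0, t1, length.out = 2001)
    w <- cummin(pmin(2 * lin(tgrid) - curves$L2(tgrid), w0))
    f <- stats::splinefun(tgrid, w, method = "hyman")
    width_fn <- function(tt) f(tt)
    dwidth_fn <- function(tt) f(tt, deriv = 1)
  }
  structure(list(kind = kind, width_fn = width_fn, dwidth_fn = dwidth_fn,
                 curves = curves),
            class = "convergence_schedule")
}

#' Tissue-domain fractions
#'
#' Defaults for the dimensionless A-P fractions `r1`, `r2` placing the modeled
#' tissue domain (r2-r6) inside the morphogen domain. Chosen so the tissue
#' spans about five rhombomeres (about 190 um at 14 hpf).
#' @return named numeric vector with elements `r1`, `r2`.
#' @export
tissue_fractions <- function() c(r1 = 0.115, r2 = 0.691)

#' Domain state at a time point
#'
#' Evaluates the rectangular morphogen domain `M(t) = [0, L1] x [-L2/2, L2/2]`,
#' the RA production region `P(t) = [p, L1] x full width` and the tissue domain
#' `T(t) = [r1*L1, r2*L1] x full width` at time `t`.
#'
#' @param t time in hpf, inside the fitted range.
#' @param schedule a `convergence_schedule`.
#' @param r1,r2 tissue-domain fractions (defaults from [tissue_fractions()]).
#' @return A `domain_state` list: `t`, `L1`, `L2`, `p`, `dL1dt`, `dL2dt`,
#'   `r1`, `r2`.
#' @export
domain_at <- function(t, schedule, r1 = tissue_fractions()[["r1"]],
                      r2 = tissue_fractions()[["r2"]]) {
  rng <- schedule$curves$t_range
  if (t < rng[1] - 1e-9 || t > rng[2] + 1e-9)
    stop("t = ", t, " outside the fitted range [", rng[1], ", ", rng[2], "]")
  t <- min(max(t, rng[1]), rng[2])
  structure(list(
    t = t,
    L1 = schedule$curves$L1(t),
    L2 = schedule$width_fn(t),
    p  = schedule$curves$p(t),
    dL1dt = schedule$curves$dL1(t),
    dL2dt = schedule$dwidth_fn(t),
    r1 = r1, r2 = r2
  ), class = "domain_state")
}

#' Growth velocity field
#'
#' Affine convergent-extension velocity
#' `V(x) = (L1' x1 / L1, L2' x2 / L2)` in um/h.
#'
#' @param x numeric length-2 vector or n x 2 matrix of positions (um), with
#'   `x1` the A-P and `x2` the L-R coordinate (origin on the midline at the
#'   MHB).
#' @param state a `domain_state`.
#' @return velocity with the same shape as `x` (um/h).
#' @export
growth_velocity <- function(x, state) {
  if (is.null(dim(x))) {
    c(state$dL1dt * x[1] / state$L1, state$dL2dt * x[2] / state$L2)
  } else {
    cbind(state$dL1dt * x[, 1] / state$L1, state$dL2dt * x[, 2] / state$L2)
  }
}
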