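# Stochastic convection-reaction-diffusion dynamics of RA ([RA]out, [RA]in)
# and FGF ([Fgf]free, [Fgf]signal) on the moving morphogen domain, plus
# grid <-> cell interpolation and the deterministic RA steady-state solver.

#' RA morphogen parameters
#'
#' @param ... overrides. Units: `Dr` um^2/h; `vr` a.u./h; `kr`, `kmax`, `k0`
#'   1/h; `beta_r` dimensionless; `mu_r1`, `mu_r2` noise amplitudes
#'   (a.u. um / sqrt(h)).
#' @return an `ra_params` list.
#' @export
ra_params <- function(...) {
  p <- list(Dr = 15000, vr = 55, kr = 3, beta_r = 1.2, kmax = 10, k0 = 0.15,
            mu_r1 = 0.1, mu_r2 = 0.1)
  ov <- list(...)
  stopifnot(all(names(ov) %in% names(p)))
  p[names(ov)] <- ov
  stopifnot(p$kmax >= p$k0, all(unlist(p) >= 0))
  p
}

#' FGF morphogen parameters
#'
#' @param ... overrides. Units: `Df` um^2/h; `vf` a.u./h; `ahf` dimensionless;
#'   `kf`, `krf`, `df1`, `df2` 1/h; `mu_f1`, `mu_f2` noise amplitudes.
#' @return an `fgf_params` list.
#' @export
fgf_params <- function(...) {
  p <- list(Df = 5000, vf = 30, ahf = 1, kf = 10, krf = 2.5, df1 = 5, df2 = 10,
            mu_f1 = 0.05, mu_f2 = 0.05)
  ov <- list(...)
  stopifnot(all(names(ov) %in% names(p)))
  p[names(ov)] <- ov
  stopifnot(all(unlist(p) >= 0))
  p
}

#' RA production rate at an A-P position
#'
#' A steep Hill function of A-P position confining production to the region
#' posterior of `p`: `A = vr / (1 + (x1/p)^-20)`; the anterior limit is 0.
#'
#' @param x1 A-P position (um), vectorized.
#' @param p anterior edge of the RA production region (um).
#' @param vr maximal production rate (a.u./h).
#' @export
ra_production_rate <- function(x1, p, vr) {
  stopifnot(p > 0, all(x1 >= 0))
  ifelse(x1 <= 0, 0, vr / (1 + (x1 / p)^(-20)))
}

#' Intracellular RA degradation rate
#'
#' Piecewise: `kmax` inside the production region (`x1 > p`, where the
#' degrading enzyme cyp26a1 is expressed), `k0` otherwise.
#'
#' @param x1 A-P position (um), vectorized.
#' @param p anterior edge of the production region (um).
#' @param kmax,k0 degradation rates (1/h).
#' @export
ra_degradation_rate <- function(x1, p, kmax, k0) ifelse(x1 > p, kmax, k0)

#' FGF production rate from a hoxb1a level
#'
#' Saturating Hill function `Af = vf H^2 / (1 + ahf H^2)`.
#'
#' @param H hoxb1a level (a.u.), vectorized.
#' @param vf maximal gain (a.u./h); `ahf` saturation coefficient.
#' @param ahf dimensionless saturation coefficient.
#' @export
fgf_production_rate <- function(H, vf, ahf) vf * H^2 / (1 + ahf * H^2)

#' Create an empty morphogen grid
#'
#' Fields live on a cell-centered uniform grid on the computational unit
#' rectangle mapped onto the moving morphogen domain.
#'
#' @param nx,ny grid resolution along A-P and L-R.
#' @return a `morphogen_grid` list of four zero fields plus the hoxb1a grid
#'   field `Hfield`.
#' @export
morphogen_grid <- function(nx = 64, ny = 16) {
  z <- matrix(0, nx, ny)
  structure(list(nx = nx, ny = ny, RAout = z, RAin = z, FGFfree = z,
                 FGFsignal = z, Hfield = z),
            class = "morphogen_grid")
}

#' Physical coordinates of grid nodes
#' @param grid a `morphogen_grid`; `state` a `domain_state`.
#' @param state a `domain_state`.
#' @return list `x1` (length nx), `x2` (length ny) in um.
#' @export
grid_coords <- function(grid, state) {
  list(x1 = (seq_len(grid$nx) - 0.5) / grid$nx * state$L1,
       x2 = ((seq_len(grid$ny) - 0.5) / grid$ny - 0.5) * state$L2)
}

#' Bilinear interpolation of a grid field at points
#'
#' Interpolates in computational coordinates; exact for fields linear in
#' position. Points outside the domain are clamped to the boundary (with a
#' warning).
#'
#' @param field nx x ny matrix.
#' @param points n x 2 matrix of physical positions (um).
#' @param state a `domain_state`.
#' @return numeric vector of length n.
#' @export
interpolate_grid_to_points <- function(field, points, state) {
  nx <- nrow(field); ny <- ncol(field)
  xi <- points[, 1] / state$L1
  eta <- points[, 2] / state$L2 + 0.5
  if (any(xi < -1e-9 | xi > 1 + 1e-9 | eta < -1e-9 | eta > 1 + 1e-9))
    warning("points outside the morphogen domain were clamped to the boundary")
  # fractional index on the cell-centered grid, clamped so the stencil exists
  fi <- pmin(pmax(xi * nx - 0.5, 0), nx - 1)
  fj <- pmin(pmax(eta * ny - 0.5, 0), ny - 1)
  i0 <- pmin(floor(fi), nx - 2) + 1
  j0 <- pmin(floor(fj), ny - 2) + 1
  wx <- fi - (i0 - 1); wy <- fj - (j0 - 1)
  idx <- cbind(i0, j0)
  f00 <- field[idx]
  f10 <- field[cbind(i0 + 1, j0)]
  f01 <- field[cbind(i0, j0 + 1)]
  f11 <- field[cbind(i0 + 1, j0 + 1)]
  (1 - wx) * (1 - wy) * f00 + wx * (1 - wy) * f10 +
    (1 - wx) * wy * f01 + wx * wy * f11
}

#' Scattered interpolation of per-cell values onto the grid
#'
#' Inverse-distance-weighted average of cell values within `radius` of each
#' grid node (exact for constant fields); nodes with no cell within `radius`
#' get 0, so the field vanishes away from the tissue (no hoxb1a source outside
#' the cell-populated region).
#'
#' @param values numeric vector, one value per cell.
#' @param points n x 2 matrix of cell centroid positions (um).
#' @param grid a `morphogen_grid`.
#' @param state a `domain_state`.
#' @param radius support radius (um); default 1.5 lattice spacings at 11 hpf.
#' @return nx x ny matrix.
#' @export
interpolate_points_to_grid <- function(values, points, grid, state,
                                       radius = 12) {
  out <- matrix(0, grid$nx, grid$ny)
  if (length(values) == 0) return(out)
  co <- grid_coords(grid, state)
  # restrict to grid nodes near the tissue bounding box to keep this cheap
  xr <- range(points[, 1]); yr <- range(points[, 2])
  isel <- which(co$x1 >= xr[1] - radius & co$x1 <= xr[2] + radius)
  jsel <- which(co$x2 >= yr[1] - radius & co$x2 <= yr[2] + radius)
  if (!length(isel) || !length(jsel)) return(out)
  gx <- rep(co$x1[isel], times = length(jsel))
  gy <- rep(co$x2[jsel], each = length(isel))
  d2 <- outer(gx, points[, 1], function(a, b) (a - b)^2) +
        outer(gy, points[, 2], function(a, b) (a - b)^2)
  w <- 1 / (d2 + 1e-6)
  w[d2 > radius^2] <- 0
  sw <- rowSums(w)
  vals <- as.vector(w %*% values)
  vals <- ifelse(sw > 0, vals / sw, 0)
  out[isel, jsel] <- matrix(vals, length(isel), length(jsel))
  out
}

#' Deterministic RA steady state on a frozen domain
#'
#' Solves the elliptic steady state of the RA pair with zero noise and zero
#' growth: `[RA]in = kr [RA]out / (kr + dr(x1))` pointwise, substituted into
#' the `[RA]out` balance, giving a linear system solved sparsely. Absorbing at
#' the anterior limit, no-flux elsewhere.
#'
#' @param state a `domain_state`.
#' @param params an `ra_params` list.
#' @param nx,ny grid resolution.
#' @return list `RAout`, `RAin` (nx x ny matrices), `residual` (max norm of
#'   the discrete steady-state equations).
#' @export
solve_ra_steady_state <- function(state, params = ra_params(),
                                  nx = 64, ny = 16) {
  p <- params
  dx <- 1 / nx; dy <- 1 / ny
  ax <- p$Dr / (state$L1^2 * dx^2); ay <- p$Dr / (state$L2^2 * dy^2)
  x1 <- (seq_len(nx) - 0.5) * dx * state$L1
  dr <- ra_degradation_rate(x1, state$p, p$kmax, p$k0)
  cc <- (1 + p$beta_r) * p$kr - p$kr^2 / (p$kr + dr)  # effective loss per row
  A <- ra_production_rate(x1, state$p, p$vr)
  N <- nx * ny
  idx <- function(i, j) (j - 1L) * nx + i
  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  add <- function(a, b, v) {
    ii <<- c(ii, a); jj <<- c(jj, b); vv <<- c(vv, v)
  }
  ig <- rep(seq_len(nx), times = ny)
  jg <- rep(seq_len(ny), each = nx)
  diagv <- rep(0, N)
  # x-direction fluxes
  west_interior <- ig > 1
  add(idx(ig[west_interior], jg[west_interior]),
      idx(ig[west_interior] - 1L, jg[west_interior]), rep(ax, sum(west_interior)))
  diagv <- diagv - ax * ifelse(ig > 1, 1, 2)  # Dirichlet ghost doubles the loss
  east_interior <- ig < nx
  add(idx(ig[east_interior], jg[east_interior]),
      idx(ig[east_interior] + 1L, jg[east_interior]), rep(ax, sum(east_interior)))
  diagv <- diagv - ax * ifelse(ig < nx, 1, 0)
  # y-direction fluxes (no-flux both sides)
  s_int <- jg > 1
  add(idx(ig[s_int], jg[s_int]), idx(ig[s_int], jg[s_int] - 1L),
      rep(ay, sum(s_int)))
  diagv <- diagv - ay * ifelse(jg > 1, 1, 0)
  n_int <- jg < ny
  add(idx(ig[n_int], jg[n_int]), idx(ig[n_int], jg[n_int] + 1L),
      rep(ay, sum(n_int)))
  diagv <- diagv - ay * ifelse(jg < ny, 1, 0)
  diagv <- diagv - cc[ig]
  add(seq_len(N), seq_len(N), diagv)
  M <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(N, N))
  rhs <- -A[ig]
  sol <- as.numeric(Matrix::solve(M, rhs))
  RAout <- matrix(sol, nx, ny)
  RAin <- RAout * p$kr / (p$kr + dr)  # dr varies by row; recycled down columns
  residual <- max(abs(M %*% sol - rhs))
  list(RAout = pmax(RAout, 0), RAin = pmax(RAin, 0), residual = residual)
}

#' Diffusion-stability time step
#'
#' Largest explicit Euler step for the diffusion terms on the mapped grid,
#' with a safety factor.
#'
#' @param state a `domain_state`; `nx`, `ny` grid resolution.
#' @param nx,ny grid resolution.
#' @param Dmax largest diffusion coefficient (um^2/h).
#' @param safety CFL safety factor (default 0.4).
#' @export
cfl_dt <- function(state, nx, ny, Dmax = max(ra_params()$Dr, fgf_params()$Df),
                   safety = 0.4) {
  dx <- 1 / nx; dy <- 1 / ny
  ax <- Dmax / (state$L1^2 * dx^2); ay <- Dmax / (state$L2^2 * dy^2)
  safety / (2 * (ax + ay))
}

#' One stochastic step of the morphogen fields
#'
#' Euler-Maruyama update of the four fields on the moving domain mapped to the
#' fixed computational rectangle. RA is absorbed at the anterior limit and
#' no-flux on the other three sides; FGF is no-flux on all four. With
#' `advect_intracellular = FALSE` the convection terms are dropped for
#' `[RA]in` and `[Fgf]signal` only (an upwinded counter-advection undoes the
#' mesh motion). With `multiplicative_noise = TRUE` the noise amplitude scales
#' with the local field value. Fields are clipped at zero. Uses R's RNG.
#'
#' @param grid a `morphogen_grid` (its `Hfield` provides the FGF source).
#' @param state a `domain_state`.
#' @param dt time step (h); must satisfy the diffusion CFL bound.
#' @param ra,fgf parameter lists.
#' @param advect_intracellular,multiplicative_noise,noise logical flags.
#' @return the updated `morphogen_grid`.
#' @export
step_morphogens <- function(grid, state, dt, ra = ra_params(),
                            fgf = fgf_params(), advect_intracellular = TRUE,
                            multiplicative_noise = FALSE, noise = TRUE) {
  lim <- cfl_dt(state, grid$nx, grid$ny, Dmax = max(ra$Dr, fgf$Df))
  if (dt > lim)
    stop(sprintf("dt = %g exceeds the diffusion stability limit %g", dt, lim))
  out <- morphogen_steps_cpp(grid$RAout, grid$RAin, grid$FGFfree,
                             grid$FGFsignal, grid$Hfield,
                             state$L1, state$L2, state$dL1dt, state$dL2dt,
                             state$p, dt, ra, fgf, advect_intracellular,
                             multiplicative_noise, noise)
  grid$RAout <- out$RAout; grid$RAin <- out$RAin
  grid$FGFfree <- out$FGFfree; grid$FGFsignal <- out$FGFsignal
  grid
}

#' Total field mass on the physical domain
#' @param field nx x ny matrix; `state` a `domain_state`.
#' @param state a `domain_state`.
#' @return the integral of the field over the domain (a.u. um^2).
#' @export
field_mass <- function(field, state) {
  sum(field) * (state$L1 / nrow(field)) * (state$L2 / ncol(field))
}
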