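test_that("RA production is a steep Hill switch at the production edge", {
  expect_equal(ra_production_rate(100, p = 100, vr = 2), 1)   # midpoint vr/2
  expect_equal(ra_production_rate(0, p = 100, vr = 2), 0)     # anterior limit
  expect_equal(ra_production_rate(120, p = 100, vr = 1),
               1 / (1 + 1.2^(-20)), tolerance = 1e-12)
  expect_equal(ra_production_rate(120, p = 100, vr = 1), 0.9746,
               tolerance = 1e-3)
})

test_that("intracellular RA degradation is piecewise at the production edge", {
  expect_equal(ra_degradation_rate(150, 100, kmax = 8, k0 = 0.2), 8)
  expect_equal(ra_degradation_rate(50, 100, kmax = 8, k0 = 0.2), 0.2)
  expect_equal(ra_degradation_rate(100, 100, kmax = 8, k0 = 0.2), 0.2)
})

test_that("FGF production saturates in hoxb1a", {
  expect_equal(fgf_production_rate(0, 5, 1), 0)
  expect_equal(fgf_production_rate(1e6, 5, 2), 2.5, tolerance = 1e-9)
  expect_equal(fgf_production_rate(1, 1, 1), 0.5)
})

test_that("bilinear interpolation is exact for constant and linear fields", {
  st <- static_state()
  g <- morphogen_grid(32, 8)
  co <- grid_coords(g, st)
  pts <- cbind(stats::runif(50, 5, st$L1 - 5),
               stats::runif(50, -st$L2 / 2 + 5, st$L2 / 2 - 5))
  # constant field
  expect_equal(interpolate_grid_to_points(matrix(7, 32, 8), pts, st),
               rep(7, 50))
  # node coincidence
  fld <- matrix(stats::runif(32 * 8), 32, 8)
  expect_equal(interpolate_grid_to_points(fld, cbind(co$x1[5], co$x2[3]), st),
               fld[5, 3])
  # linear field f(x) = x1 is reproduced exactly
  fld1 <- matrix(co$x1, 32, 8)
  expect_equal(interpolate_grid_to_points(fld1, pts, st), pts[, 1],
               tolerance = 1e-9)
  expect_warning(
    interpolate_grid_to_points(fld1, cbind(st$L1 + 10, 0), st), "clamped")
})

test_that("scattered cell values extend to the grid as expected", {
  st <- static_state()
  g <- morphogen_grid(64, 16)
  pts <- cbind(stats::runif(200, 50, 200), stats::runif(200, -40, 40))
  # constant values reproduce the constant over the tissue
  fld <- interpolate_points_to_grid(rep(3, 200), pts, g, st, radius = 12)
  co <- grid_coords(g, st)
  inside <- outer(co$x1 >= 60 & co$x1 <= 190, abs(co$x2) <= 30, "&")
  expect_true(all(abs(fld[inside] - 3) < 1e-6))
  # far outside the tissue the field is zero
  far <- outer(co$x1 > 260, rep(TRUE, 16), "&")
  expect_true(all(fld[far] == 0))
  # a hoxb1a-high stripe peaks inside the stripe
  H <- ifelse(pts[, 1] > 100 & pts[, 1] < 140, 2, 0)
  fld2 <- interpolate_points_to_grid(H, pts, g, st, radius = 12)
  peak_at <- co$x1[which(fld2 == max(fld2), arr.ind = TRUE)[1]]
  expect_true(peak_at > 100 && peak_at < 140)
  # no cells: zero field
  expect_true(all(interpolate_points_to_grid(numeric(0),
    matrix(0, 0, 2), g, st) == 0))
})

test_that("RA steady state: zero production and L-R symmetry", {
  st <- static_state()
  z <- solve_ra_steady_state(st, ra_params(vr = 0), nx = 32, ny = 8)
  expect_true(all(abs(z$RAout) < 1e-12) && all(abs(z$RAin) < 1e-12))
  ss <- solve_ra_steady_state(st, nx = 32, ny = 8)
  expect_lt(ss$residual, 1e-8)
  expect_equal(ss$RAout, ss$RAout[, 8:1])  # symmetric in x2
  # monotone non-increasing from the production region toward the anterior
  prof <- rowMeans(ss$RAin)
  ant <- prof[which((seq_len(32) - 0.5) / 32 * st$L1 < st$p)]
  expect_true(all(diff(ant) > 0))
})

test_that("well-mixed fixed point matches the closed form (no diffusion)", {
  # with Dr = 0 every node is an independent two-variable ODE whose fixed
  # point is RAin* = kr RAout* / (kr + dr) and
  # RAout* = a / (kr ((1 + br) - kr / (kr + dr)))
  st <- static_state()
  ra <- ra_params(Dr = 0, vr = 8, kr = 2, beta_r = 0.5, kmax = 10, k0 = 0.1)
  fgf0 <- fgf_params(Df = 0)
  g <- morphogen_grid(16, 4)
  stepped <- g
  for (i in 1:4000)
    stepped <- step_morphogens(stepped, st, 0.01, ra = ra, fgf = fgf0,
                               noise = FALSE)
  x1 <- grid_coords(g, st)$x1
  a <- ra_production_rate(x1, st$p, ra$vr)
  dr <- ra_degradation_rate(x1, st$p, ra$kmax, ra$k0)
  out_star <- a / (ra$kr * ((1 + ra$beta_r) - ra$kr / (ra$kr + dr)))
  in_star <- ra$kr * out_star / (ra$kr + dr)
  expect_equal(stepped$RAout[, 2], out_star, tolerance = 1e-4)
  expect_equal(stepped$RAin[, 2], in_star, tolerance = 1e-4)
})

test_that("total mass is conserved without reactions on the moving domain", {
  # no production, no degradation, no noise, no-flux everywhere for FGFfree;
  # the non-diffusing species are pure advection-dilution
  sch <- make_schedule("rapid")
  ra <- ra_params(Dr = 0, vr = 0, kr = 0, k0 = 0, kmax = 0, beta_r = 0)
  fgf <- fgf_params(vf = 0, kf = 0, krf = 0, df1 = 0, df2 = 0)
  g <- morphogen_grid(32, 8)
  set.seed(1)
  g$FGFfree <- matrix(stats::runif(256, 0.5, 2), 32, 8)
  g$FGFsignal <- matrix(stats::runif(256, 0.5, 2), 32, 8)
  st0 <- domain_at(11, sch)
  m0_free <- field_mass(g$FGFfree, st0)
  m0_sig <- field_mass(g$FGFsignal, st0)
  t <- 11
  for (i in 1:600) {
    st <- domain_at(t, sch)
    dt <- min(cfl_dt(st, 32, 8, Dmax = fgf$Df), 0.002)
    g <- step_morphogens(g, st, dt, ra = ra, fgf = fgf, noise = FALSE)
    t <- t + dt
  }
  st1 <- domain_at(t, sch)
  expect_equal(field_mass(g$FGFfree, st1), m0_free, tolerance = 5e-3)
  expect_equal(field_mass(g$FGFsignal, st1), m0_sig, tolerance = 5e-3)
})

test_that("explicit stepping reproduces the elliptic steady state", {
  st <- static_state()
  ss <- solve_ra_steady_state(st, nx = 32, ny = 8)
  g <- morphogen_grid(32, 8)
  g$RAout <- ss$RAout; g$RAin <- ss$RAin
  dt <- cfl_dt(st, 32, 8)
  for (i in 1:400) g <- step_morphogens(g, st, dt, noise = FALSE)
  expect_equal(g$RAout, ss$RAout, tolerance = 1e-6)
  expect_equal(g$RAin, ss$RAin, tolerance = 1e-6)
})

test_that("a time step above the diffusion stability limit is rejected", {
  st <- static_state()
  g <- morphogen_grid(32, 8)
  expect_error(step_morphogens(g, st, 1, noise = FALSE), "stability")
})

test_that("1D steady profile matches the analytic two-species solution", {
  # constant coefficients, absorbing left boundary, production far to the
  # right: in the source-free region RAout solves Dr u'' = c_eff u, giving
  # u(x) proportional to sinh(x / lambda)
  ra <- ra_params(Dr = 6000, vr = 10, kr = 2, beta_r = 0.8, k0 = 0.3,
                  kmax = 0.3)
  st <- static_state(L1 = 300, L2 = 1, p = 260)
  ss <- solve_ra_steady_state(st, ra, nx = 512, ny = 1)
  c_eff <- (1 + ra$beta_r) * ra$kr - ra$kr^2 / (ra$kr + ra$k0)
  lambda <- sqrt(ra$Dr / c_eff)
  x <- (seq_len(512) - 0.5) / 512 * st$L1
  sel <- x > 30 & x < 180   # well away from source and boundary
  u <- ss$RAout[sel, 1]
  ratio <- u / sinh(x[sel] / lambda)
  expect_lt(stats::sd(ratio) / mean(ratio), 0.02)
})

test_that("the deterministic field converges under grid refinement", {
  st <- static_state()
  coarse <- solve_ra_steady_state(st, nx = 64, ny = 16)
  fine <- solve_ra_steady_state(st, nx = 128, ny = 32)
  # compare on the coarse nodes (fine 2x2 block means are the coarse cells),
  # over the cell-populated tissue region (the production region has a
  # discontinuous degradation coefficient whose jump cell dominates any
  # global norm without being scientifically relevant)
  block <- function(m) {
     0.25 * (m[seq(1, 127, 2), seq(1, 31, 2)] + m[seq(2, 128, 2), seq(1, 31, 2)] +
             m[seq(1, 127, 2), seq(2, 32, 2)] + m[seq(2, 128, 2), seq(2, 32, 2)])
  }
  x1 <- (seq_len(64) - 0.5) / 64 * st$L1
  sel <- x1 >= st$r1 * st$L1 & x1 <= st$r2 * st$L1
  num <- sum((coarse$RAin[sel, ] - block(fine$RAin)[sel, ])^2)
  den <- sum(block(fine$RAin)[sel, ]^2)
  expect_lt(sqrt(num / den), 0.02)
})

test_that("the ensemble mean approaches the deterministic field as noise shrinks", {
  st <- static_state()
  ss <- solve_ra_steady_state(st, nx = 32, ny = 8)
  dt <- cfl_dt(st, 32, 8)
  dev <- vapply(c(0.05, 0.2, 0.8), function(mu) {
    set.seed(7)
    acc <- matrix(0, 32, 8)
    nrep <- 8
    for (r in 1:nrep) {
      g <- morphogen_grid(32, 8)
      g$RAout <- ss$RAout; g$RAin <- ss$RAin
      for (i in 1:80)
        g <- step_morphogens(g, st, dt, ra = ra_params(mu_r1 = mu, mu_r2 = mu))
      acc <- acc + g$RAin / nrep
    }
    sqrt(mean((acc - ss$RAin)^2))
  }, numeric(1))
  expect_true(all(diff(dev) > 0))        # deviation grows with noise
  expect_lt(dev[1], 0.05 * max(ss$RAin)) # and is small at small noise
})

test_that("fields remain non-negative under strong noise", {
  st <- static_state()
  g <- morphogen_grid(16, 4)
  dt <- cfl_dt(st, 16, 4)
  set.seed(2)
  for (i in 1:50)
    g <- step_morphogens(g, st, dt,
                         ra = ra_params(mu_r1 = 2, mu_r2 = 2),
                         fgf = fgf_params(mu_f1 = 2, mu_f2 = 2))
  expect_true(all(g$RAout >= 0) && all(g$RAin >= 0) &&
              all(g$FGFfree >= 0) && all(g$FGFsignal >= 0))
})
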