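# Reduced models: the 1D steady-state gene-expression model (two-morphogen
# vs one-morphogen variants), initial-condition sweeps / phase diagrams, and
# the sorting-only model with Gaussian-mixture identity initialization.

#' Steady RA profile on a fixed 1D domain
#' @keywords internal
ra_steady_1d <- function(L1, p, ra = ra_params(), n_nodes = 256) {
  st <- structure(list(t = NA, L1 = L1, L2 = 1, p = p, dL1dt = 0, dL2dt = 0,
                       r1 = 0, r2 = 1), class = "domain_state")
  ss <- solve_ra_steady_state(st, ra, nx = n_nodes, ny = 1)
  list(x = (seq_len(n_nodes) - 0.5) / n_nodes * L1, RAin = ss$RAin[, 1],
       RAout = ss$RAout[, 1])
}

#' Equilibrium vhnf1/irx3 profiles given RA
#'
#' Damped fixed-point iteration of the V/I mutual-inhibition pair starting
#' from the irx3-first history (I at its unrepressed level), matching the
#' staged initialization in which irx3 rises before vhnf1.
#' @keywords internal
vi_equilibrium <- function(RAin, gp = gene_params(), iters = 400,
                           damp = 0.3) {
  V <- rep(0, length(RAin)); I <- rep(gp$vi / gp$di, length(RAin))
  R2 <- RAin^2
  for (it in seq_len(iters)) {
    Vn <- (gp$vv / gp$dv) * gp$arv * R2 / (1 + gp$arv * R2 + gp$biv * I^2)
    In <- (gp$vi / gp$di) / (1 + gp$bvi * V^2)
    V <- (1 - damp) * V + damp * Vn
    I <- (1 - damp) * I + damp * In
  }
  list(V = V, I = I)
}

#' Boundary positions from 1D profiles by threshold crossing
#'
#' r3/r4 and r4/r5 are the anterior and posterior edges of the hoxb1a-high
#' band; r2/r3 is the anterior up-crossing of krox20 and r5/r6 its last
#' down-crossing posterior of the hoxb1a band. Crossings are linearly
#' interpolated; missing bands give NA.
#'
#' @param x node positions (um); `H`, `K` profiles.
#' @param H,K hoxb1a and krox20 profiles at `x`.
#' @param threshold classification threshold (default 1.2).
#' @return named numeric vector `m_r2r3`, `m_r3r4`, `m_r4r5`, `m_r5r6`,
#'   `len_r3`, `len_r4`, `len_r5`.
#' @export
boundaries_1d <- function(x, H, K, threshold = 1.2) {
  cross <- function(y, i, up) {
    # linear interpolation of the threshold crossing between i and i+1
    x[i] + (threshold - y[i]) * (x[i + 1] - x[i]) / (y[i + 1] - y[i])
  }
  hi_h <- H >= threshold
  m34 <- m45 <- m23 <- m56 <- NA_real_
  if (any(hi_h)) {
    i1 <- which(hi_h)[1]; i2 <- which(hi_h)[sum(hi_h)]
    m34 <- if (i1 > 1) cross(H, i1 - 1, TRUE) else x[1]
    m45 <- if (i2 < length(x)) cross(H, i2, FALSE) else x[length(x)]
  }
  hi_k <- K >= threshold
  if (any(hi_k)) {
    j1 <- which(hi_k)[1]
    m23 <- if (j1 > 1) cross(K, j1 - 1, TRUE) else x[1]
    post <- if (!is.na(m45)) which(hi_k & x > m45) else which(hi_k)
    if (length(post)) {
      j2 <- post[length(post)]
      m56 <- if (j2 < length(x) && K[j2 + 1] < threshold)
        cross(K, j2, FALSE) else NA_real_
    }
  }
  c(m_r2r3 = m23, m_r3r4 = m34, m_r4r5 = m45, m_r5r6 = m56,
    len_r3 = m34 - m23, len_r4 = m45 - m34, len_r5 = m56 - m45)
}

#' Run the 1D reduced gene-expression model
#'
#' Integrates the one-dimensional analogue of the full gene/morphogen system
#' on a fixed A-P domain to steady state. RA is held at its quasi-static
#' equilibrium profile; vhnf1/irx3 start from their RA-conditioned
#' equilibrium; krox20 and FGF start at zero; hoxb1a starts from
#' `initial_H_spec`. In the `one_morphogen` variant the krox20 activator is
#' `ark * RAin^2` instead of `afk * FGF^2` and the FGF equations are dropped.
#'
#' @param variant `"two_morphogen"` or `"one_morphogen"`.
#' @param initial_H_spec a constant, or a length-2 range `c(lo, hi)` from
#'   which per-node levels are drawn uniformly (requires a seeded RNG).
#' @param noise logical; add the gene SDE noise terms during integration.
#' @param n_nodes spatial resolution (default 256 on the 14-hpf domain).
#' @param gene,ra,fgf parameter lists.
#' @param ark one-morphogen krox20 activation gain (a.u.^-2).
#' @param t_max,tol integration horizon (h) and steady-state tolerance
#'   (max |dC/dt| / max(level, 1)).
#' @param dt integration step override (h); defaults to the diffusion
#'   stability limit capped at 0.002.
#' @param ra_scale factor on RA production. The fixed 1D domain never
#'   experiences convergence, which in the full model concentrates RA by
#'   about 1.7-fold by the commitment stage; the default matches the 1D
#'   profile to that signaling environment.
#' @param dims dimension curves (domain length and production edge at 14 hpf).
#' @return list with `x`, `profiles` (data.frame x, RA, H, K, V, I, FGF),
#'   `boundaries` (from [boundaries_1d()]), `converged`.
#' @export
run_1d_model <- function(variant = c("two_morphogen", "one_morphogen"),
                         initial_H_spec = gene_params()$initial_H,
                         noise = FALSE, n_nodes = 256,
                         gene = gene_params(), ra = ra_params(),
                         fgf = fgf_params(), ark = one_morphogen_gain(),
                         t_max = 24, tol = 1e-6, ra_scale = 1.7,
                         dt = NULL, dims = fit_dimension_curves()) {
  variant <- match.arg(variant)
  L1 <- dims$L1(dims$t_range[2]); p <- dims$p(dims$t_range[2])
  ra$vr <- ra$vr * ra_scale
  rss <- ra_steady_1d(L1, p, ra, n_nodes)
  vi <- vi_equilibrium(rss$RAin, gene)
  H0 <- if (length(initial_H_spec) == 2)
    stats::runif(n_nodes, initial_H_spec[1], initial_H_spec[2])
  else rep(initial_H_spec, n_nodes)
  fr <- tissue_fractions()
  active <- rss$x >= fr[["r1"]] * L1 & rss$x <= fr[["r2"]] * L1
  genes <- cbind(H0, rep(0, n_nodes), vi$V, vi$I)
  genes[!active, ] <- 0
  dx <- L1 / n_nodes
  dt_f <- if (variant == "two_morphogen") 0.4 * dx^2 / (2 * fgf$Df) else Inf
  dt <- if (is.null(dt)) min(0.002, dt_f) else min(dt, dt_f)
  out <- run_1d_core_cpp(rss$RAin, genes, active, dx, dt, t_max, tol, gene,
                         fgf, variant == "two_morphogen", ark, noise)
  profiles <- data.frame(x = rss$x, RA = rss$RAin, H = out$genes[, 1],
                         K = out$genes[, 2], V = out$genes[, 3],
                         I = out$genes[, 4], FGF = out$FGFsignal)
  list(x = rss$x, profiles = profiles,
       boundaries = boundaries_1d(rss$x, out$genes[, 1], out$genes[, 2],
                                  gene$classify_threshold),
       converged = out$converged, variant = variant)
}

#' Default one-morphogen krox20 activation gain
#'
#' Gain of the `ark * RAin^2` activator replacing the FGF input in the
#' one-morphogen variant, calibrated so the r2/r3 boundary matches the
#' two-morphogen baseline.
#' @return numeric gain (a.u.^-2).
#' @export
one_morphogen_gain <- function() 0.54

#' Phase diagram over initial hoxb1a levels
#'
#' @param variant model variant (see [run_1d_model()]).
#' @param initial_H_grid numeric vector of constant initial hoxb1a levels.
#' @param ... passed to [run_1d_model()].
#' @return tidy data.frame: `initial_H`, `boundary`, `position_um`, plus
#'   segment-length rows (`boundary` = "len_r3" etc., value in um).
#' @export
phase_diagram <- function(variant, initial_H_grid, ...) {
  rows <- lapply(initial_H_grid, function(h0) {
    b <- run_1d_model(variant, initial_H_spec = h0, ...)$boundaries
    data.frame(initial_H = h0, boundary = names(b), value = unname(b))
  })
  do.call(rbind, rows)
}

#' Ensemble of 1D runs with random initial hoxb1a fields
#'
#' @param variant model variant.
#' @param range length-2 uniform range for the per-node initial hoxb1a level.
#' @param n ensemble size (>= 2).
#' @param ... passed to [run_1d_model()].
#' @return list with `mean_H`, `sd_H`, `mean_K`, `sd_K` profiles, `x`, and
#'   `boundary_sd` (SD of each boundary position across runs).
#' @export
noisy_ic_ensemble <- function(variant, range, n, ...) {
  stopifnot(n >= 2, length(range) == 2)
  runs <- lapply(seq_len(n), function(i)
    run_1d_model(variant, initial_H_spec = range, ...))
  Hm <- sapply(runs, function(r) r$profiles$H)
  Km <- sapply(runs, function(r) r$profiles$K)
  B <- t(sapply(runs, function(r) r$boundaries[1:4]))
  list(x = runs[[1]]$x,
       mean_H = rowMeans(Hm), sd_H = apply(Hm, 1, stats::sd),
       mean_K = rowMeans(Km), sd_K = apply(Km, 1, stats::sd),
       boundaries = B,
       boundary_sd = apply(B, 2, stats::sd, na.rm = TRUE))
}

#' Default identity mixture for the sorting-only model
#'
#' Five Gaussian components, one per segment identity (r2-r6), centered at the
#' equal-fifths segment centers of the tissue domain with spread equal to half
#' a segment length.
#'
#' @param state a `domain_state` (normally at 11 hpf).
#' @return list `labels`, `means`, `sds` (um), `weights` (component priors).
#' @export
identity_mixture <- function(state) {
  a <- state$r1 * state$L1; b <- state$r2 * state$L1
  seg <- (b - a) / 5
  list(labels = c("r2", "r3", "r4", "r5", "r6"),
       means = a + (seq_len(5) - 0.5) * seg,
       sds = rep(seg / 2, 5),
       weights = rep(0.2, 5))
}

#' Sample salt-and-pepper identities from a position-conditional mixture
#'
#' Each cell's identity is drawn from the categorical distribution whose
#' weights are the (prior-weighted) Gaussian component densities at the cell's
#' A-P position, normalized.
#'
#' @param positions numeric vector of A-P centroid positions (um).
#' @param mixture an identity mixture (see [identity_mixture()]).
#' @return character vector of segment labels (`"r2"` ... `"r6"`).
#' @export
sample_identities_gmm <- function(positions, mixture) {
  dens <- sapply(seq_along(mixture$labels), function(k)
    mixture$weights[k] * stats::dnorm(positions, mixture$means[k],
                                      max(mixture$sds[k], 1e-9)))
  if (is.null(dim(dens))) dens <- matrix(dens, nrow = 1)
  idx <- vapply(seq_along(positions), function(i) {
    w <- dens[i, ]
    if (sum(w) <= 0) {
      # degenerate spreads: all densities underflow; nearest component wins
      which.min(abs(positions[i] - mixture$means))
    } else {
      sample.int(length(w), 1, prob = w / sum(w))
    }
  }, integer(1))
  mixture$labels[idx]
}

#' Position-conditional mixture weights (analytic)
#' @param positions A-P positions (um); `mixture` an identity mixture.
#' @param mixture an identity mixture (see [identity_mixture()]).
#' @return matrix n x 5 of identity probabilities at each position.
#' @export
identity_mixture_weights <- function(positions, mixture) {
  dens <- sapply(seq_along(mixture$labels), function(k)
    mixture$weights[k] * stats::dnorm(positions, mixture$means[k],
                                      max(mixture$sds[k], 1e-9)))
  if (is.null(dim(dens))) dens <- matrix(dens, nrow = 1)
  sw <- rowSums(dens)
  dens / ifelse(sw > 0, sw, 1)
}

# segment label -> metric identity and synthetic krox20/hoxb1a levels
segment_identity <- function(labels) {
  c(r2 = "none", r3 = "krox20", r4 = "hoxb1a", r5 = "krox20",
    r6 = "none")[labels]
}
segment_levels <- function(labels) {
  K <- ifelse(labels %in% c("r3", "r5"), 2, 0)
  H <- ifelse(labels == "r4", 2, 0)
  cbind(H = H, K = K)
}

#' Run the sorting-only model
#'
#' Mechanics-only simulation: cell identities are pre-assigned from the
#' position-conditional Gaussian mixture at 11 hpf and frozen; cells sort by
#' krox20-selective adhesion while the domain converges and extends; pattern
#' metrics are computed on the frozen identities at the snapshot cadence.
#'
#' @param schedule a `convergence_schedule` or a kind string.
#' @param seed integer RNG seed.
#' @param t_start,t_end simulated interval (hpf).
#' @param macro_dt mechanics step (h); `snapshot_dt` metric cadence (h).
#' @param snapshot_dt metric snapshot cadence (h).
#' @param mech a `mechanics_params` list.
#' @param mixture identity mixture; default from the 11-hpf tissue domain.
#' @return list with `metrics` (time series data.frame), `cells` (final
#'   snapshot data.frame), `identities`, `initial_identities`.
#' @export
run_sorting_only <- function(schedule = "rapid", seed = 1,
                             t_start = 11, t_end = 14,
                             macro_dt = 0.0025, snapshot_dt = 0.1,
                             mech = mechanics_params(), mixture = NULL) {
  if (is.character(schedule)) schedule <- make_schedule(schedule)
  set.seed(seed)
  st <- domain_at(t_start, schedule)
  lat <- init_lattice(st, mech)
  if (is.null(mixture)) mixture <- identity_mixture(st)
  labels <- sample_identities_gmm(lat$centers[, 1], mixture)
  ids <- segment_identity(labels)
  K <- segment_levels(labels)[, "K"]
  nodes <- lat$nodes
  nsteps <- ceiling((t_end - t_start) / macro_dt)
  snap_every <- max(1L, round(snapshot_dt / macro_dt))
  metrics <- list()
  snap <- function(t) {
    cen <- cell_centroids(nodes)
    rep_ <- quantify_pattern(cen[, 1], ids, domain_at(t, schedule),
                             r = mech$R_out)
    report_row(rep_, t)
  }
  metrics[[1]] <- snap(t_start)
  for (s in seq_len(nsteps)) {
    t <- t_start + (s - 1) * macro_dt
    stt <- domain_at(min(t, t_end), schedule)
    nodes <- step_mechanics(nodes, K, stt, macro_dt, mech)
    if (s %% snap_every == 0 || s == nsteps)
      metrics[[length(metrics) + 1]] <- snap(min(t + macro_dt, t_end))
  }
  cen <- cell_centroids(nodes)
  cells <- data.frame(time_hpf = t_end, cell_id = seq_len(lat$n_cell),
                      centroid_x_um = cen[, 1], centroid_y_um = cen[, 2],
                      identity = ids, label = labels)
  list(metrics = do.call(rbind, metrics), cells = cells, identities = ids,
       initial_identities = ids, labels = labels, seed = seed,
       schedule = schedule$kind)
}
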