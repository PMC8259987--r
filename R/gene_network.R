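# Per-cell stochastic gene regulation: hoxb1a (H), krox20 (K), vhnf1 (V),
# irx3 (I) driven by interpolated intracellular RA and FGF signal levels.
#
# Drift structure (per cell, a.u./h):
#   dH = vh (ahh H^2 + arh RA^2) / (1 + ahh H^2 + arh RA^2 + bkh K^2 + bvh V^2) - dh H
#   dK = vk (akk K^2 + afk F^2)  / (1 + akk K^2 + afk F^2 + bhk H^2)            - dk K
#   dV = vv (arv RA^2)           / (1 + arv RA^2 + biv I^2)                     - dv V
#   dI = vi                      / (1 + bvi V^2)                                - di I
# H and K are self-activating and mutually repressing (toggle switch); V is a
# pure RA readout repressed by I (no self-activation); I is constitutive and
# repressed by V.

#' Gene-network parameters
#'
#' Hill gains, repression coefficients, degradation rates and noise amplitudes
#' of the four-gene network. Defaults are calibrated so that (i) the H/K
#' subsystem is a bistable toggle with high states above the classification
#' threshold 1.2, (ii) the unstable H branch sits near 0.2 at r4-level RA so
#' that the pre-pattern hoxb1a level 0.21 ignites r4, and (iii) the
#' steady-state boundaries land at the measured rhombomere positions (see the
#' methods vignette).
#'
#' @param ... overrides for any listed element.
#' @return a `gene_params` list.
#' @export
gene_params <- function(...) {
  p <- list(
    # hoxb1a
    vh = 20, ahh = 1.5, arh = 0.12, bkh = 4.0, bvh = 2.0, dh = 10,
    # krox20
    vk = 20, akk = 1.5, afk = 6.8, bhk = 24.0, dk = 10,
    # vhnf1
    vv = 15, arv = 1.0, biv = 5.0, dv = 7.5,
    # irx3
    vi = 10, bvi = 4.0, di = 5,
    # noise amplitudes (a.u. / sqrt(h))
    mu_h = 0.1, mu_k = 0.1, mu_v = 0.02, mu_i = 0.02,
    # identity classification threshold (a.u.) and pre-pattern hoxb1a level
    classify_threshold = 1.2, initial_H = 0.21
  )
  ov <- list(...)
  stopifnot(all(names(ov) %in% names(p)))
  p[names(ov)] <- ov
  p
}

#' Deterministic drift of the gene network
#'
#' @param s numeric matrix (n_cells x 4, columns H, K, V, I) or length-4
#'   vector of expression levels.
#' @param RAin,FGFsig intracellular RA and FGF signal levels at each cell
#'   (recycled to n_cells).
#' @param params a `gene_params` list.
#' @return drift with the same shape as `s` (a.u./h).
#' @export
gene_rhs <- function(s, RAin, FGFsig, params = gene_params()) {
  vec <- is.null(dim(s))
  if (vec) s <- matrix(s, nrow = 1)
  H <- s[, 1]; K <- s[, 2]; V <- s[, 3]; I <- s[, 4]
  p <- params
  R2 <- RAin^2; F2 <- FGFsig^2
  dH <- p$vh * (p$ahh * H^2 + p$arh * R2) /
    (1 + p$ahh * H^2 + p$arh * R2 + p$bkh * K^2 + p$bvh * V^2) - p$dh * H
  dK <- p$vk * (p$akk * K^2 + p$afk * F2) /
    (1 + p$akk * K^2 + p$afk * F2 + p$bhk * H^2) - p$dk * K
  dV <- p$vv * (p$arv * R2) / (1 + p$arv * R2 + p$biv * I^2) - p$dv * V
  dI <- p$vi / (1 + p$bvi * V^2) - p$di * I
  out <- cbind(dH, dK, dV, dI)
  if (vec) drop(out) else out
}

#' One Euler-Maruyama step of the per-cell gene SDEs
#'
#' Additive noise by default; with `noise_mode = "multiplicative"` each
#' species' noise amplitude is scaled by its current level. Values are clipped
#' at zero after the step. Uses R's global RNG stream.
#'
#' @param states n_cells x 4 matrix (H, K, V, I).
#' @param RAin,FGFsig signal levels per cell.
#' @param dt step (h).
#' @param params a `gene_params` list.
#' @param noise_mode `"additive"` or `"multiplicative"`.
#' @param species_mask logical length-4; FALSE freezes a species (used by the
#'   two-stage pre-pattern protocol).
#' @return updated states matrix.
#' @export
step_genes <- function(states, RAin, FGFsig, dt, params = gene_params(),
                       noise_mode = c("additive", "multiplicative"),
                       species_mask = rep(TRUE, 4)) {
  noise_mode <- match.arg(noise_mode)
  n <- nrow(states)
  drift <- gene_rhs(states, RAin, FGFsig, params)
  mu <- c(params$mu_h, params$mu_k, params$mu_v, params$mu_i)
  noise <- matrix(stats::rnorm(n * 4), n, 4)
  amp <- matrix(mu, n, 4, byrow = TRUE)
  if (noise_mode == "multiplicative") amp <- amp * states
  upd <- states + dt * drift + sqrt(dt) * amp * noise
  upd[upd < 0] <- 0
  keep <- !species_mask
  if (any(keep)) upd[, keep] <- states[, keep]
  upd
}

#' Classify cell identity from hoxb1a and krox20 levels
#'
#' hoxb1a identity if `H >= threshold` and `K < threshold`; krox20 identity if
#' `K >= threshold` and `H < threshold`; if both exceed the threshold the
#' larger level wins (ties go to krox20); otherwise non-expressing.
#'
#' @param H,K numeric vectors of expression levels.
#' @param threshold classification threshold (a.u.), default 1.2.
#' @return character vector in `c("hoxb1a", "krox20", "none")`.
#' @export
classify_cell <- function(H, K, threshold = 1.2) {
  out <- rep("none", length(H))
  out[H >= threshold & K < threshold] <- "hoxb1a"
  out[K >= threshold & H < threshold] <- "krox20"
  both <- H >= threshold & K >= threshold
  out[both] <- ifelse(H[both] > K[both], "hoxb1a", "krox20")
  out
}
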