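# Subcellular element method (SCEM) cell mechanics: each cell is 12 nodes in
# two hexagonal layers; overdamped node dynamics combine intra-cell shape
# springs, identity-selective inter-cell forces and the convergent-extension
# velocity field.

#' Mechanics parameters
#'
#' Geometry of the two-hexagon cell (outer radius `R_out`, inner radius
#' `R_in`, rest lengths `l_out`, `l_in`, `l_inter` for outer-ring, inner-ring
#' and same-angle cross-layer springs), intra-cell spring stiffness, the
#' inter-cell Morse-type pair forces (short-range exponential repulsion
#' `A_rep`/`rho_rep`, longer-range exponential attraction `A_att`/`rho_att`
#' scaled by `2F - 1` with the similarity weight `F`), interaction cutoffs and
#' the mechanics time step.
#'
#' @param ... overrides. Lengths um, rates 1/h, force amplitudes um/h.
#' @return a `mechanics_params` list.
#' @export
mechanics_params <- function(...) {
  p <- list(
    R_out = 3.6, R_in = 1.8,
    l_out = 3.6, l_in = 1.8, l_inter = 1.8,
    k_intra = 150,
    A_rep = 80, rho_rep = 0.8,
    A_att = 20, rho_att = 2.5,
    node_cutoff = 5, pair_cutoff = 14,
    similarity_steepness = 4,
    n_substeps = 3
  )
  ov <- list(...)
  stopifnot(all(names(ov) %in% names(p)))
  p[names(ov)] <- ov
  stopifnot(p$R_in < p$R_out, p$rho_rep < p$rho_att)
  p
}

#' Rest-configuration nodes of one cell
#'
#' @param center length-2 centroid position (um).
#' @param params a `mechanics_params` list.
#' @return 12 x 2 matrix: rows 1-6 the outer hexagon, 7-12 the inner hexagon
#'   at the same angles.
#' @export
rest_cell_nodes <- function(center, params = mechanics_params()) {
  ang <- (0:5) * pi / 3
  rbind(cbind(center[1] + params$R_out * cos(ang),
              center[2] + params$R_out * sin(ang)),
        cbind(center[1] + params$R_in * cos(ang),
              center[2] + params$R_in * sin(ang)))
}

#' Initialize the 23 x 15 cell lattice
#'
#' Places 345 cells (23 rows along A-P, 15 columns along L-R) uniformly in the
#' tissue domain, each in its two-hexagon rest configuration.
#'
#' @param state a `domain_state` (normally at 11 hpf).
#' @param params a `mechanics_params` list.
#' @param n_ap,n_lr lattice dimensions (defaults 23 x 15).
#' @return list with `nodes` ((n_cell*12) x 2 matrix, cell c in rows
#'   `(c-1)*12 + 1:12`), `n_cell`, and `centers` (n_cell x 2).
#' @export
init_lattice <- function(state, params = mechanics_params(),
                         n_ap = 23, n_lr = 15) {
  a <- state$r1 * state$L1; b <- state$r2 * state$L1
  sx <- (b - a) / n_ap; sy <- state$L2 / n_lr
  cx <- a + (seq_len(n_ap) - 0.5) * sx
  cy <- -state$L2 / 2 + (seq_len(n_lr) - 0.5) * sy
  centers <- cbind(rep(cx, times = n_lr), rep(cy, each = n_ap))
  nodes <- do.call(rbind, lapply(seq_len(nrow(centers)), function(c)
    rest_cell_nodes(centers[c, ], params)))
  list(nodes = nodes, n_cell = nrow(centers), centers = centers)
}

#' Cell centroids from the node matrix
#' @param nodes (n_cell*12) x 2 node matrix.
#' @return n_cell x 2 matrix of centroids (arithmetic node means).
#' @export
cell_centroids <- function(nodes) {
  n_cell <- nrow(nodes) / 12
  g <- rep(seq_len(n_cell), each = 12)
  out <- cbind(rowsum(nodes[, 1], g) / 12, rowsum(nodes[, 2], g) / 12)
  dimnames(out) <- NULL
  out
}

# intra-cell spring pair list (1-based): outer ring, inner ring, cross-layer
intra_pairs <- function() {
  cbind(a = c(1:6, 7:12, 1:6),
        b = c(2:6, 1, 8:12, 7, 7:12))
}

#' Intra-cell restoring velocities
#'
#' Linear springs toward the rest lengths `l_out` (outer-ring neighbors),
#' `l_in` (inner-ring neighbors) and `l_inter` (same-angle cross-layer pairs);
#' zero at the rest configuration, and internal forces sum to zero.
#'
#' @param cell_nodes 12 x 2 matrix of one cell's nodes.
#' @param params a `mechanics_params` list.
#' @return 12 x 2 matrix of node velocity contributions (um/h).
#' @export
intra_velocity <- function(cell_nodes, params = mechanics_params()) {
  pr <- intra_pairs()
  l0 <- rep(c(params$l_out, params$l_in, params$l_inter), each = 6)
  v <- matrix(0, 12, 2)
  d <- cell_nodes[pr[, "a"], ] - cell_nodes[pr[, "b"], ]
  len <- sqrt(rowSums(d^2))
  f <- -params$k_intra * (len - l0) / pmax(len, 1e-12)
  fx <- f * d[, 1]; fy <- f * d[, 2]
  v[, 1] <- rowsum(c(fx, -fx), c(pr[, "a"], pr[, "b"]), reorder = TRUE)
  v[, 2] <- rowsum(c(fy, -fy), c(pr[, "a"], pr[, "b"]), reorder = TRUE)
  v
}

#' Pairwise similarity weight from krox20 levels
#'
#' `F = 1 - s_i (1 - s_j) - s_j (1 - s_i)` with `s = sigmoid(K)` centered at
#' the classification threshold: F ~ 1 when both cells are krox20-high or both
#' low (attraction), F ~ 0 when exactly one is high (repulsion), F = 0.5 at
#' indeterminate levels (neutral).
#'
#' @param K_i,K_j krox20 levels (vectorized).
#' @param threshold sigmoid center (a.u.), default the classification
#'   threshold 1.2.
#' @param steepness sigmoid steepness (1/a.u.).
#' @return similarity weights in `[0, 1]`.
#' @export
similarity_weight <- function(K_i, K_j, threshold = 1.2, steepness = 4) {
  si <- stats::plogis(steepness * (K_i - threshold))
  sj <- stats::plogis(steepness * (K_j - threshold))
  1 - si * (1 - sj) - sj * (1 - si)
}

#' Inter-cell node velocities for one cell pair
#'
#' Short-range exponential repulsion independent of identity plus a
#' longer-range exponential term whose sign and magnitude follow `2F - 1`:
#' attraction for similar cells (F > 1/2), repulsion for dissimilar ones
#' (F < 1/2), absent at F = 1/2. Forces act between the outer (membrane)
#' layers of the two cells -- the inner layers lie beyond the node cutoff
#' across any normal cell-cell contact -- and are antisymmetric between the
#' paired nodes.
#'
#' @param nodes_n,nodes_m 12 x 2 node matrices of the two cells.
#' @param F similarity weight in `[0, 1]`.
#' @param params a `mechanics_params` list.
#' @return list `v_n`, `v_m`: 12 x 2 velocity contributions on each cell.
#' @export
inter_velocity <- function(nodes_n, nodes_m, F, params = mechanics_params()) {
  v_n <- matrix(0, 12, 2); v_m <- matrix(0, 12, 2)
  att <- (2 * F - 1) * params$A_att
  for (i in 1:6) {
    d <- matrix(nodes_n[i, ], 6, 2, byrow = TRUE) - nodes_m[1:6, , drop = FALSE]
    len <- sqrt(rowSums(d^2))
    sel <- which(len < params$node_cutoff & len > 1e-12)
    if (!length(sel)) next
    f <- (params$A_rep * exp(-len[sel] / params$rho_rep) -
            att * exp(-len[sel] / params$rho_att)) / len[sel]
    fx <- f * d[sel, 1]; fy <- f * d[sel, 2]
    v_n[i, 1] <- v_n[i, 1] + sum(fx); v_n[i, 2] <- v_n[i, 2] + sum(fy)
    v_m[sel, 1] <- v_m[sel, 1] - fx; v_m[sel, 2] <- v_m[sel, 2] - fy
  }
  list(v_n = v_n, v_m = v_m)
}

#' Convergent-extension velocity of a cell
#'
#' The growth velocity evaluated at the cell centroid, applied identically to
#' all 12 nodes.
#'
#' @param cell_nodes 12 x 2 node matrix.
#' @param state a `domain_state`.
#' @return 12 x 2 matrix with identical rows (um/h).
#' @export
external_velocity <- function(cell_nodes, state) {
  v <- growth_velocity(colMeans(cell_nodes), state)
  matrix(v, 12, 2, byrow = TRUE)
}

#' One overdamped mechanics step for all cells
#'
#' First-order explicit update of every node by the sum of the
#' convergent-extension, inter-cell and intra-cell velocities. Neighbor search
#' prunes cell pairs by centroid distance at `pair_cutoff`.
#'
#' @param nodes (n_cell*12) x 2 node matrix.
#' @param K krox20 level per cell (length n_cell); drives selectivity.
#' @param state a `domain_state`.
#' @param dt time step (h).
#' @param params a `mechanics_params` list.
#' @param ce_on if FALSE the convergent-extension velocity is dropped.
#' @param selective if FALSE the similarity weight is forced to 0.5 for all
#'   pairs (random sorting).
#' @param classify_threshold sigmoid center for the similarity weight.
#' @return updated node matrix.
#' @export
step_mechanics <- function(nodes, K, state, dt, params = mechanics_params(),
                           ce_on = TRUE, selective = TRUE,
                           classify_threshold = 1.2) {
  sigma <- stats::plogis(params$similarity_steepness * (K - classify_threshold))
  nsub <- max(1L, as.integer(params$n_substeps))
  out <- nodes
  for (i in seq_len(nsub)) {
    new <- mechanics_step_cpp(out, sigma, state$L1, state$L2,
                              state$dL1dt, state$dL2dt, dt / nsub, params,
                              ce_on, selective)
    disp <- sqrt(rowSums((new - out)^2))
    if (max(disp) > params$R_out)
      stop(sprintf("node displacement %.2f um exceeds one cell radius; reduce dt",
                   max(disp)))
    out <- new
  }
  out
}

#' Radius of gyration of each cell
#' @param nodes (n_cell*12) x 2 node matrix.
#' @return numeric vector, RMS node distance from the centroid per cell (um).
#' @export
radius_of_gyration <- function(nodes) {
  cen <- cell_centroids(nodes)
  n_cell <- nrow(cen)
  g <- rep(seq_len(n_cell), each = 12)
  d2 <- (nodes[, 1] - cen[g, 1])^2 + (nodes[, 2] - cen[g, 2])^2
  sqrt(rowsum(d2, g) / 12)[, 1]
}
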