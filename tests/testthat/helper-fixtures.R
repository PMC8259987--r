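# shared fixtures: small domain states, synthetic cell patterns, and a cached
# default 1D run reused across tests

static_state <- function(L1 = 330, L2 = 104, p = 265, r1 = 0.115, r2 = 0.691) {
  structure(list(t = 14, L1 = L1, L2 = L2, p = p, dL1dt = 0, dL2dt = 0,
                 r1 = r1, r2 = r2), class = "domain_state")
}

# perfect five-stripe pattern: n_per cells per stripe, stripes of given width,
# returns centroids and identities on [a, a + 5*width]
perfect_stripes <- function(a = 38, width = 38, n_per = 30, jitter = 0,
                            seed = 1) {
  set.seed(seed)
  ids <- c("none", "krox20", "hoxb1a", "krox20", "none")
  r_inset <- 3.6  # keep cell edges clear of the nominal boundaries
  x <- unlist(lapply(0:4, function(k)
    a + k * width + r_inset +
      (seq_len(n_per) - 0.5) / n_per * (width - 2 * r_inset)))
  if (jitter > 0) x <- x + stats::runif(length(x), -jitter, jitter)
  list(x = x, ids = rep(ids, each = n_per),
       range = c(a, a + 5 * width),
       boundaries = a + width * 1:4)
}

# brute-force boundary oracle on a very fine candidate grid
brute_boundary <- function(cells_L, cells_R, interval, r, step = 0.01) {
  ks <- seq(interval[1], interval[2], by = step)
  obj <- vapply(ks, function(k) {
    dL <- cell_boundary_distance(cells_L, r, k, "L")
    dR <- cell_boundary_distance(cells_R, r, k, "R")
    d <- c(dL[dL <= 6 * r], dR[dR <= 6 * r])
    sqrt(sum(d^2))
  }, numeric(1))
  best <- which(obj <= min(obj) + 1e-12)
  list(m = (ks[best[1]] + ks[best[length(best)]]) / 2, SI = min(obj))
}

# cached default 1D two-morphogen run (computed once per test session)
default_1d_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- run_1d_model("two_morphogen", t_max = 12,
                                               tol = 1e-5)
    cache
  }
})
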