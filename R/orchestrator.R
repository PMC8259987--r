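# Full-model orchestration: configuration, the staged pre-pattern
# initialization, the coupled macro-step loop (morphogens -> genes ->
# mechanics), ensembles, random-parameter sweeps and commitment-time curves.

#' Simulation configuration
#'
#' Collects every knob of the full model: the convergence schedule, time
#' range, grid resolution, macro time step, parameter sets, ablation flags and
#' time windows, the RNG seed and output cadence.
#'
#' Flags: `gene_window` / `sorting_window` restrict gene regulation /
#' selective sorting to sub-intervals of the run (outside the sorting window
#' the similarity weight is held at 0.5 so cells sort randomly);
#' `disable_ce` switches off the convergent-extension velocity;
#' `advect_intracellular = FALSE` drops the convection terms of the
#' intracellular species only; `multiplicative_noise` scales noise amplitudes
#' with local levels; `mechanics`/`genes_on` switch whole sub-models off.
#'
#' @param ... overrides for any listed element.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(...) {
  cfg <- list(
    schedule = "rapid", slow_mode = "reflect",
    t_start = 11, t_end = 14,
    nx = 64, ny = 16,
    macro_dt = 0.0025,
    snapshot_dt = 0.1,
    burn_in_hours = c(1, 1),
    ra = ra_params(), fgf = fgf_params(), gene = gene_params(),
    mech = mechanics_params(),
    gene_window = c(11, 14), sorting_window = c(11, 14),
    disable_ce = FALSE, advect_intracellular = TRUE,
    multiplicative_noise = FALSE, noise = TRUE,
    mechanics = TRUE, genes_on = TRUE,
    h_support_radius = 12,
    h_update_every = 4,
    seed = 1
  )
  ov <- list(...)
  stopifnot(all(names(ov) %in% names(cfg)))
  cfg[names(ov)] <- ov
  stopifnot(cfg$t_end > cfg$t_start,
            cfg$gene_window[1] >= cfg$t_start - 1e-9,
            cfg$gene_window[2] <= cfg$t_end + 1e-9,
            cfg$sorting_window[1] >= cfg$t_start - 1e-9,
            cfg$sorting_window[2] <= cfg$t_end + 1e-9)
  class(cfg) <- "simulation_config"
  cfg
}

# frozen copy of a domain state (zero growth rates)
freeze_state <- function(state) {
  state$dL1dt <- 0; state$dL2dt <- 0
  state
}

# advance the morphogen grid over one macro step, sub-cycling at the
# diffusion CFL limit; geometry is evaluated at each substep start
advance_morphogens <- function(grid, schedule, t, macro_dt, cfg,
                               frozen_state = NULL) {
  state_at <- function(tt) {
    if (!is.null(frozen_state)) frozen_state else domain_at(tt, schedule)
  }
  st_end <- state_at(t + macro_dt)
  lim <- cfl_dt(st_end, grid$nx, grid$ny,
                Dmax = max(cfg$ra$Dr, cfg$fgf$Df))
  nsub <- max(1L, ceiling(macro_dt / lim))
  dt <- macro_dt / nsub
  ts <- t + (seq_len(nsub) - 1) * dt
  sts <- lapply(ts, state_at)
  g <- function(f) vapply(sts, function(s) s[[f]], numeric(1))
  out <- morphogen_steps_cpp(grid$RAout, grid$RAin, grid$FGFfree,
                             grid$FGFsignal, grid$Hfield,
                             g("L1"), g("L2"), g("dL1dt"), g("dL2dt"),
                             g("p"), dt, cfg$ra, cfg$fgf,
                             cfg$advect_intracellular,
                             cfg$multiplicative_noise, cfg$noise)
  grid$RAout <- out$RAout; grid$RAin <- out$RAin
  grid$FGFfree <- out$FGFfree; grid$FGFsignal <- out$FGFsignal
  grid
}

#' Staged pre-pattern initialization
#'
#' Builds the 11-hpf initial condition by simulating the two hours preceding
#' the main run on the geometry frozen at its start-time shape: RA starts from
#' its deterministic equilibrium; in the first stage only RA and the
#' vhnf1/irx3 pair evolve (from zero); in the second stage all species evolve,
#' with krox20 and FGF starting at zero and hoxb1a at its constant pre-pattern
#' level. Cells sit at their lattice positions throughout.
#'
#' @param cfg a `simulation_config`.
#' @param schedule a `convergence_schedule` (defaults to `cfg$schedule`).
#' @return list `grid`, `nodes`, `genes` (n_cell x 4), `state` (the frozen
#'   start-time domain state), `centers`.
#' @export
initialize_pre_pattern <- function(cfg = simulation_config(),
                                   schedule = NULL) {
  if (is.null(schedule))
    schedule <- make_schedule(cfg$schedule, slow_mode = cfg$slow_mode)
  st <- freeze_state(domain_at(cfg$t_start, schedule))
  lat <- init_lattice(st, cfg$mech)
  grid <- morphogen_grid(cfg$nx, cfg$ny)
  ss <- solve_ra_steady_state(st, cfg$ra, cfg$nx, cfg$ny)
  grid$RAout <- ss$RAout; grid$RAin <- ss$RAin
  genes <- matrix(0, lat$n_cell, 4)
  stage <- function(genes, hours, mask) {
    if (hours <= 0) return(genes)
    nsteps <- ceiling(hours / cfg$macro_dt)
    for (s in seq_len(nsteps)) {
      grid <<- advance_morphogens(grid, schedule, cfg$t_start, cfg$macro_dt,
                                  cfg, frozen_state = st)
      RAc <- interpolate_grid_to_points(grid$RAin, lat$centers, st)
      Fc <- interpolate_grid_to_points(grid$FGFsignal, lat$centers, st)
      if (cfg$noise) {
        genes <- step_genes(genes, RAc, Fc, cfg$macro_dt, cfg$gene,
                            if (cfg$multiplicative_noise) "multiplicative"
                            else "additive",
                            species_mask = mask)
      } else {
        upd <- genes + cfg$macro_dt * gene_rhs(genes, RAc, Fc, cfg$gene)
        upd[upd < 0] <- 0
        upd[, !mask] <- genes[, !mask]
        genes <- upd
      }
      if (mask[1] && (s %% cfg$h_update_every == 0)) {
        grid$Hfield <- interpolate_points_to_grid(
          genes[, 1], lat$centers, grid, st, cfg$h_support_radius)
      }
    }
    genes
  }
  # stage 1: RA + vhnf1/irx3 only (FGF fields stay zero: no hoxb1a source)
  genes <- stage(genes, cfg$burn_in_hours[1], c(FALSE, FALSE, TRUE, TRUE))
  # stage 2: all species; krox20/FGF from zero, hoxb1a from its pre-pattern
  genes[, 1] <- cfg$gene$initial_H
  genes[, 2] <- 0
  grid$FGFfree[] <- 0; grid$FGFsignal[] <- 0
  genes <- stage(genes, cfg$burn_in_hours[2], rep(TRUE, 4))
  list(grid = grid, nodes = lat$nodes, genes = genes, state = st,
       centers = lat$centers)
}

# noise-aware gene step respecting cfg$noise
step_genes_cfg <- function(genes, RAc, Fc, cfg) {
  if (cfg$noise) {
    step_genes(genes, RAc, Fc, cfg$macro_dt, cfg$gene,
               if (cfg$multiplicative_noise) "multiplicative" else "additive")
  } else {
    upd <- genes + cfg$macro_dt * gene_rhs(genes, RAc, Fc, cfg$gene)
    upd[upd < 0] <- 0
    upd
  }
}

#' Run the full coupled model
#'
#' Per macro step: (1) update the domain state from the schedule; (2) advance
#' the morphogen fields (sub-cycled at the diffusion stability limit);
#' (3) advance per-cell gene states using signals interpolated at centroids
#' (frozen outside the gene window); (4) advance cell mechanics (similarity
#' forced to 0.5 outside the sorting window; convergent extension dropped if
#' disabled). Snapshots of cells and pattern metrics are taken at the
#' configured cadence. Fully reproducible from (config, seed).
#'
#' @param cfg a `simulation_config`.
#' @return list with `metrics` (data.frame time series), `cells` (snapshot
#'   data.frame across cadence times), `final` (final `pattern_report`),
#'   `genes`, `nodes`, `grid`, `config`.
#' @export
run_full_model <- function(cfg = simulation_config()) {
  set.seed(cfg$seed)
  schedule <- make_schedule(cfg$schedule, slow_mode = cfg$slow_mode)
  init <- initialize_pre_pattern(cfg, schedule)
  grid <- init$grid; nodes <- init$nodes; genes <- init$genes
  n_cell <- nrow(genes)
  nsteps <- ceiling((cfg$t_end - cfg$t_start) / cfg$macro_dt)
  snap_every <- max(1L, round(cfg$snapshot_dt / cfg$macro_dt))
  thr <- cfg$gene$classify_threshold
  metrics <- list(); cells <- list(); k <- 0L
  take_snapshot <- function(t, cen, ids) {
    rep_ <- quantify_pattern(cen[, 1], ids, domain_at(t, schedule),
                             r = cfg$mech$R_out)
    k <<- k + 1L
    metrics[[k]] <<- report_row(rep_, t)
    cells[[k]] <<- data.frame(
      time_hpf = t, cell_id = seq_len(n_cell),
      centroid_x_um = cen[, 1], centroid_y_um = cen[, 2],
      H = genes[, 1], K = genes[, 2], V = genes[, 3], I = genes[, 4],
      identity = ids)
    rep_
  }
  cen <- cell_centroids(nodes)
  ids <- classify_cell(genes[, 1], genes[, 2], thr)
  final <- take_snapshot(cfg$t_start, cen, ids)
  for (s in seq_len(nsteps)) {
    t <- cfg$t_start + (s - 1) * cfg$macro_dt
    t_next <- min(t + cfg$macro_dt, cfg$t_end)
    st <- domain_at(t_next, schedule)
    # morphogens
    grid <- advance_morphogens(grid, schedule, t, cfg$macro_dt, cfg)
    # genes
    cen <- cell_centroids(nodes)
    if (cfg$genes_on && t >= cfg$gene_window[1] - 1e-9 &&
        t < cfg$gene_window[2] - 1e-9) {
      RAc <- interpolate_grid_to_points(grid$RAin, cen, st)
      Fc <- interpolate_grid_to_points(grid$FGFsignal, cen, st)
      genes <- step_genes_cfg(genes, RAc, Fc, cfg)
      # the FGF source field follows cell-level hoxb1a, which evolves on the
      # gene timescale; refreshing it every few macro steps is ample
      if (s %% cfg$h_update_every == 0 || s == nsteps)
        grid$Hfield <- interpolate_points_to_grid(genes[, 1], cen, grid, st,
                                                  cfg$h_support_radius)
    }
    # mechanics
    if (cfg$mechanics) {
      selective <- t >= cfg$sorting_window[1] - 1e-9 &&
        t < cfg$sorting_window[2] - 1e-9
      nodes <- step_mechanics(nodes, genes[, 2], st, cfg$macro_dt, cfg$mech,
                              ce_on = !cfg$disable_ce, selective = selective,
                              classify_threshold = thr)
    } else if (!cfg$disable_ce) {
      # pure material advection when the mechanical sub-model is off
      st_prev <- domain_at(t, schedule)
      nodes[, 1] <- nodes[, 1] * st$L1 / st_prev$L1
      nodes[, 2] <- nodes[, 2] * st$L2 / st_prev$L2
    }
    if (s %% snap_every == 0 || s == nsteps) {
      cen <- cell_centroids(nodes)
      ids <- classify_cell(genes[, 1], genes[, 2], thr)
      final <- take_snapshot(t_next, cen, ids)
    }
  }
  list(metrics = do.call(rbind, metrics), cells = do.call(rbind, cells),
       final = final, genes = genes, nodes = nodes, grid = grid, config = cfg)
}

#' Run an ensemble of independent full-model simulations
#'
#' @param cfg a `simulation_config` (its seed is ignored).
#' @param n number of runs.
#' @param seeds integer seeds (default `seq_len(n)` offset by `cfg$seed`).
#' @return list with `runs` (per-run metrics + final report), `summary`
#'   (data.frame of final lengths, SIs, DC per run), `mean`, `sd` of the
#'   summary columns, and `success` flags.
#' @export
run_ensemble <- function(cfg = simulation_config(), n = 3,
                         seeds = cfg$seed + seq_len(n) - 1) {
  stopifnot(n >= 1, length(seeds) == n)
  runs <- lapply(seeds, function(s) {
    ci <- cfg; ci$seed <- s
    r <- run_full_model(ci)
    list(metrics = r$metrics, final = r$final, seed = s)
  })
  summary <- do.call(rbind, lapply(runs, function(r) {
    row <- utils::tail(r$metrics, 1)
    row$seed <- r$seed
    row$success <- !row$failed && !any(is.na(row[, c("len_r3", "len_r4",
                                                     "len_r5")]))
    row
  }))
  num <- summary[, c("len_r3", "len_r4", "len_r5", "SI_r2r3", "SI_r3r4",
                     "SI_r4r5", "SI_r5r6", "DC")]
  list(runs = runs, summary = summary,
       mean = colMeans(num, na.rm = TRUE),
       sd = if (n >= 2) apply(num, 2, stats::sd, na.rm = TRUE)
            else stats::setNames(rep(NA_real_, ncol(num)), names(num)),
       success = summary$success)
}

#' Random-parameter sweep of the gene-regulation constants
#'
#' Perturbs the gene-network rate constants multiplicatively (independent
#' uniform factors in `1 +/- perturbation`), runs `n` simulations per listed
#' schedule, and summarizes success rates and the fraction `f(d)` of
#' successful runs whose r3/r4/r5 lengths all fall within `d%` of the measured
#' means (42, 34, 37 um). The default half-width of 10% keeps the perturbed
#' networks inside their operating regime (toggle high states above the
#' classification threshold); much larger perturbations mostly probe
#' pattern collapse rather than length accuracy.
#'
#' @param cfg base `simulation_config`.
#' @param n runs per schedule.
#' @param schedules character vector of schedule kinds.
#' @param perturbation relative half-width of the uniform factor (default 0.2).
#' @param d_grid percent deviations at which to evaluate `f(d)`.
#' @param target_lengths reference mean lengths (um) for r3, r4, r5.
#' @param seed base seed.
#' @return list with `results` (per-run data.frame), `f_curves` (data.frame
#'   schedule, d, fraction), `success_counts`.
#' @export
random_parameter_sweep <- function(cfg = simulation_config(), n = 50,
                                   schedules = c("rapid", "medium", "slow"),
                                   perturbation = 0.1,
                                   d_grid = seq(0, 50, by = 5),
                                   target_lengths = c(r3 = 42, r4 = 34,
                                                      r5 = 37),
                                   seed = cfg$seed) {
  perturb_names <- c("vh", "ahh", "arh", "bkh", "bvh", "dh",
                     "vk", "akk", "afk", "bhk", "dk",
                     "vv", "arv", "biv", "dv", "vi", "bvi", "di")
  rows <- list()
  for (sch in schedules) {
    for (i in seq_len(n)) {
      run_seed <- seed + 1000L * match(sch, schedules) + i
      set.seed(run_seed)
      gp <- cfg$gene
      fac <- stats::runif(length(perturb_names), 1 - perturbation,
                          1 + perturbation)
      gp[perturb_names] <- mapply(function(nm, f) gp[[nm]] * f,
                                  perturb_names, fac, SIMPLIFY = FALSE)
      ci <- cfg; ci$gene <- gp; ci$schedule <- sch; ci$seed <- run_seed
      r <- run_full_model(ci)
      row <- utils::tail(r$metrics, 1)
      rows[[length(rows) + 1]] <- data.frame(
        schedule = sch, run = i, seed = run_seed,
        len_r3 = row$len_r3, len_r4 = row$len_r4, len_r5 = row$len_r5,
        SI_r3r4 = row$SI_r3r4, SI_r4r5 = row$SI_r4r5, SI_r5r6 = row$SI_r5r6,
        DC = row$DC, failed = row$failed,
        success = !row$failed && !any(is.na(c(row$len_r3, row$len_r4,
                                              row$len_r5))))
    }
  }
  results <- do.call(rbind, rows)
  f_curves <- do.call(rbind, lapply(schedules, function(sch) {
    sub <- results[results$schedule == sch, ]
    data.frame(schedule = sch, d = d_grid, fraction = vapply(d_grid,
      function(d) {
        ok <- sub$success &
          abs(sub$len_r3 - target_lengths[1]) <= d / 100 * target_lengths[1] &
          abs(sub$len_r4 - target_lengths[2]) <= d / 100 * target_lengths[2] &
          abs(sub$len_r5 - target_lengths[3]) <= d / 100 * target_lengths[3]
        mean(ok, na.rm = TRUE)
      }, numeric(1)))
  }))
  list(results = results, f_curves = f_curves,
       success_counts = tapply(results$success, results$schedule, sum))
}

#' Per-rhombomere cell-commitment curves
#'
#' A cell is committed at the first snapshot after which its identity never
#' changes. Cells are grouped by their final segment (from the final boundary
#' positions), and the committed fraction is reported per snapshot time.
#'
#' @param run output of [run_full_model()].
#' @return data.frame `time_hpf`, `segment`, `fraction_committed`.
#' @export
cell_commitment_times <- function(run) {
  cells <- run$cells
  times <- sort(unique(cells$time_hpf))
  n_cell <- max(cells$cell_id)
  idm <- matrix(cells$identity[order(cells$time_hpf, cells$cell_id)],
                nrow = n_cell)
  # commitment index: first column c such that identity is constant from c on
  last_change <- apply(idm, 1, function(z) {
    ch <- which(z[-1] != z[-length(z)])
    if (length(ch)) ch[length(ch)] + 1L else 1L
  })
  commit_time <- times[last_change]
  final_row <- utils::tail(run$metrics, 1)
  bnd <- c(-Inf, final_row$m_r2r3, final_row$m_r3r4, final_row$m_r4r5,
           final_row$m_r5r6, Inf)
  finals <- cells[cells$time_hpf == times[length(times)], ]
  seg <- cut(finals$centroid_x_um[order(finals$cell_id)], breaks = bnd,
             labels = c("r2", "r3", "r4", "r5", "r6"))
  do.call(rbind, lapply(levels(seg), function(sg) {
    sel <- seg == sg
    if (!any(sel)) return(NULL)
    data.frame(time_hpf = times, segment = sg,
               fraction_committed = vapply(times, function(tt)
                 mean(commit_time[sel] <= tt + 1e-9), numeric(1)))
  }))
}

#' Write cell snapshots / metric time series / field snapshot as CSV
#'
#' @param x the data.frame (or `morphogen_grid` for fields).
#' @param path output path.
#' @param state a `domain_state` (fields only, for physical coordinates).
#' @return the path, invisibly.
#' @export
write_cells_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cells_csv
#' @export
write_metrics_csv <- write_cells_csv

#' @rdname write_cells_csv
#' @export
write_fields_csv <- function(x, path, state) {
  co <- grid_coords(x, state)
  df <- data.frame(x1_um = rep(co$x1, times = x$ny),
                   x2_um = rep(co$x2, each = x$nx),
                   RAout = as.vector(x$RAout), RAin = as.vector(x$RAin),
                   FGFfree = as.vector(x$FGFfree),
                   FGFsignal = as.vector(x$FGFsignal))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
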