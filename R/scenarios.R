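# Scenario orchestration: initial conditions (dermal rim of fibroblasts +
# ECM around a macrophage-seeded wound), the five repair classifications,
# replicate management, time-series sampling, the wound-closure metric and
# end-state outcome classification.

.scenario_names <- c("healthy", "chronic_high_psnc", "fibrotic_no_snc",
                     "fibrotic_delayed", "chronic_preexisting")

#' Scenario configuration
#'
#' The five canonical repair classifications differ ONLY in senescent-cell
#' dynamics: `chronic_high_psnc` raises the myofibroblast senescence
#' probability to 0.75; `fibrotic_no_snc` sets it to zero;
#' `fibrotic_delayed` delays the induction gate to day 15; and
#' `chronic_preexisting` seeds pre-existing inflammatory senescent cells at
#' t = 0. No other parameters are changed.
#'
#' @param name One of healthy, chronic_high_psnc, fibrotic_no_snc,
#'   fibrotic_delayed, chronic_preexisting.
#' @param params Base parameter set.
#' @param duration_days,replicates,sample_period_mcs Run control overrides.
#' @param seeds Integer seeds, one per replicate (default `seq_len(replicates)`).
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(name = .scenario_names, params = default_params(),
                            duration_days = NULL, replicates = NULL,
                            sample_period_mcs = NULL, seeds = NULL) {
  name <- match.arg(name)
  params <- validate_params(params)
  # pre-existing seeding scales with wound area (15 cells in the full
  # 120 x 120 wound)
  wa <- (params$init$width - 2 * params$init$wound_margin) *
    (params$init$height - 2 * params$init$wound_margin)
  ov <- switch(name,
    healthy = list(),
    chronic_high_psnc = list(rules = list(p_snc = 0.75)),
    fibrotic_no_snc = list(rules = list(p_snc = 0)),
    fibrotic_delayed = list(rules = list(t_sen = 15, t_sen_unit = "days")),
    chronic_preexisting = list(init = list(n_preexisting =
                                             max(1, round(15 * wa / 14400)))))
  params <- do.call(sim_params, c(ov, list(base = params)))
  if (!is.null(duration_days)) params$scenario$duration_days <- duration_days
  if (!is.null(replicates)) params$scenario$replicates <- replicates
  if (!is.null(sample_period_mcs)) params$scenario$sample_period_mcs <- sample_period_mcs
  if (is.null(seeds)) seeds <- seq_len(params$scenario$replicates)
  structure(list(name = name, params = params, seeds = as.integer(seeds)),
            class = "scenario_config")
}

#' Build the initial wounded-dermis state
#'
#' A width x height lattice whose dermal rim (width `init$wound_margin`) is
#' tiled with 8x8 fibroblasts interleaved with one-pixel ECM cells; the
#' central wound is populated by M2-polarised macrophages (and, for the
#' pre-existing classification, inflammatory senescent cells with an initial
#' inflammatory SASP bolus on their pixels). All fields start at zero
#' otherwise. The wound mask is fixed at t = 0 and used for the closure
#' metric and the differentiation rule.
#'
#' @param params Parameter list (its `init` block sets the geometry).
#' @param seed RNG seed for placement and the engine.
#' @return A `cpm_sim`.
#' @export
build_initial_state <- function(params = default_params(), seed = 1L) {
  params <- validate_params(params)
  ini <- params$init
  W <- ini$width; H <- ini$height
  mrg <- ini$wound_margin; blk <- ini$cell_block
  set.seed(seed)
  wound <- matrix(FALSE, W, H)
  wound[(mrg + 1):(W - mrg), (mrg + 1):(H - mrg)] <- TRUE

  grid <- matrix(0L, W, H)
  types <- integer(0)
  ct <- cell_types()
  new_cell <- function(type) { types[length(types) + 1L] <<- type; length(types) }

  # wound mask dilated by one pixel: dermal blocks touching it form the
  # wound-facing fibroblast ring (the invasion front)
  dil <- wound
  dil[-1, ] <- dil[-1, ] | wound[-W, ]
  dil[-W, ] <- dil[-W, ] | wound[-1, ]
  dil[, -1] <- dil[, -1] | wound[, -H]
  dil[, -H] <- dil[, -H] | wound[, -1]

  # dermal rim: the ring blocks are fibroblasts; deeper whole blocks become
  # fibroblasts with prob fib_fraction, the rest interstitial 1-pixel ECM
  bx <- ceiling(W / blk); by <- ceiling(H / blk)
  for (ix in seq_len(bx)) for (iy in seq_len(by)) {
    xs <- ((ix - 1) * blk + 1):min(ix * blk, W)
    ys <- ((iy - 1) * blk + 1):min(iy * blk, H)
    cells_px <- expand.grid(x = xs, y = ys)
    inw <- wound[cbind(cells_px$x, cells_px$y)]
    if (all(inw)) next
    ring <- !any(inw) && any(dil[cbind(cells_px$x, cells_px$y)])
    if (!any(inw) && length(xs) == blk && length(ys) == blk &&
        (ring || stats::runif(1) < ini$fib_fraction)) {
      id <- new_cell(ct[["Fibroblast"]])
      grid[xs, ys] <- id
    } else {
      out <- cells_px[!inw, , drop = FALSE]
      keep <- stats::runif(nrow(out)) < ini$ecm_fraction
      out <- out[keep, , drop = FALSE]
      for (r in seq_len(nrow(out))) {
        id <- new_cell(ct[["ECM"]])
        grid[out$x[r], out$y[r]] <- id
      }
    }
  }

  # wound interior: non-overlapping blocks for macrophages (+ pre-existing
  # senescent cells), placed at random block slots
  slot_x <- seq(mrg + 1, W - mrg - blk + 1, by = blk)
  slot_y <- seq(mrg + 1, H - mrg - blk + 1, by = blk)
  slots <- expand.grid(x = slot_x, y = slot_y)
  want <- ini$n_macrophages + ini$n_preexisting
  if (want > nrow(slots))
    stop("wound cannot fit ", want, " seeded cells (", nrow(slots), " slots)")
  pick <- slots[sample.int(nrow(slots), want), , drop = FALSE]
  kinds <- c(rep(ct[["Macrophage"]], ini$n_macrophages),
             rep(ct[["InflammatorySenescent"]], ini$n_preexisting))
  pre_px <- NULL
  for (r in seq_len(nrow(pick))) {
    xs <- pick$x[r]:(pick$x[r] + blk - 1)
    ys <- pick$y[r]:(pick$y[r] + blk - 1)
    id <- new_cell(kinds[r])
    grid[xs, ys] <- id
    if (kinds[r] == ct[["InflammatorySenescent"]])
      pre_px <- rbind(pre_px, expand.grid(x = xs, y = ys))
  }

  sim <- simulation_from_grid(grid, types, params, seed = seed,
                              wound_mask = wound)
  if (!is.null(pre_px)) {
    # initial inflammatory load carried by pre-existing senescent cells
    amt <- ini$pre_inf_bolus / (blk * blk)
    cpp_field_add_at(sim$ptr, .field_index("inf"), pre_px$x, pre_px$y, amt)
  }
  if (ini$csf1_init > 0)
    set_field_matrix(sim, "csf1", matrix(ini$csf1_init, W, H))
  .refresh_signaling(sim)
  sim
}

# Push secretion rates + chemotaxis from the current state without running
# any behaviour rules (used once at t = 0).
.refresh_signaling <- function(sim) {
  p <- sim$params
  ct <- cell_types()
  cen <- cpp_sweep_census(sim$ptr)
  fl <- sim$flags
  m <- match(cen$id, fl$id)
  pre <- !is.na(m) & fl$sen_mech[m] %in% "preexisting"
  roster <- data.frame(
    id = cen$id, type = cen$type, c_mac = cen$c_mac, c_ecm = cen$c_ecm,
    m1 = !is.na(m) & fl$m1[m],
    activated = !is.na(m) & fl$activated[m],
    fibrolytic = cen$type %in% ct[c("SenescentMyofibroblast", "InflammatorySenescent")] &
      update_sasp_phase(ifelse(is.na(m), Inf, fl$sen_clock[m]),
                        p$rules$t_nis_days, pre) == "fibrolytic")
  rates <- secretion_rates(roster, fl, p)
  cpp_set_secretion(sim$ptr, rates$id,
                    as.matrix(rates[, c("pdgf", "csf1", "mmp", "inf")]))
  .refresh_chemotaxis(sim, cen)
  invisible(sim)
}

#' Wound-closure fraction
#'
#' Fraction of the (t = 0) wound-mask pixels currently occupied by any cell.
#' The closure RATE reported in time series is the per-sample difference of
#' this fraction.
#'
#' @param grid Integer lattice matrix (or a `cpm_sim`).
#' @param wound_mask Logical matrix fixed at t = 0 (taken from the sim if a
#'   `cpm_sim` is given).
#' @return Fraction in \[0, 1\].
#' @export
wound_closure_fraction <- function(grid, wound_mask = NULL) {
  if (inherits(grid, "cpm_sim")) {
    wound_mask <- grid$wound_mask
    grid <- lattice_matrix(grid)
  }
  if (is.null(wound_mask) || !any(wound_mask)) stop("empty wound mask")
  mean(grid[wound_mask] != 0)
}

# One time-series sample row.
.sample_row <- function(sim) {
  p <- sim$params
  tab <- cpp_cells_table(sim$ptr)
  ct <- cell_types()
  cnt <- function(tt) sum(tab$type == ct[[tt]])
  grid <- lattice_matrix(sim)
  wids <- grid[sim$wound_mask]
  wids <- wids[wids > 0]
  ecm_wound <- sum(tab$type[match(unique(wids), tab$id)] == ct[["ECM"]],
                   na.rm = TRUE)
  data.frame(
    mcs = sim$mcs,
    day = mcs_to_days(sim$mcs, p),
    fibroblasts = cnt("Fibroblast"),
    myofibroblasts = cnt("Myofibroblast"),
    macrophages = cnt("Macrophage"),
    senescent = cnt("SenescentMyofibroblast"),
    preexisting_senescent = cnt("InflammatorySenescent"),
    ecm = cnt("ECM"),
    ecm_wound = ecm_wound,
    pdgf_total = total_field(field_matrix(sim, "pdgf")),
    csf1_total = total_field(field_matrix(sim, "csf1")),
    mmp_total = total_field(field_matrix(sim, "mmp")),
    inf_total = total_field(field_matrix(sim, "inf")),
    closure = wound_closure_fraction(sim),
    sen_primary = sim$counters$primary,
    sen_juxtacrine = sim$counters$juxtacrine,
    sen_paracrine = sim$counters$paracrine,
    sen_preexisting = sim$counters$preexisting,
    sen_cleared = sim$counters$cleared)
}

#' Run one simulation replicate
#'
#' Interleaves CPM Monte-Carlo steps, field integration (every MCS) and
#' behaviour sweeps (every `rules$sweep_period_mcs`), sampling the time
#' series every `scenario$sample_period_mcs` and keeping lattice snapshots at
#' the requested days.
#'
#' @param params Parameter list.
#' @param seed Replicate seed.
#' @param duration_days Simulated duration.
#' @param keep_snapshots Keep lattice grids at `scenario$snapshot_days`?
#' @param progress Print a line per simulated day?
#' @return List with `timeseries` (data.frame), `snapshots` (named list of
#'   grids or NULL), `final` (the `cpm_sim`), `seed`.
#' @export
run_replicate <- function(params, seed, duration_days = NULL,
                          keep_snapshots = FALSE, progress = FALSE) {
  params <- validate_params(params)
  if (is.null(duration_days)) duration_days <- params$scenario$duration_days
  sim <- build_initial_state(params, seed = seed)
  K <- params$rules$sweep_period_mcs
  sample_period <- params$scenario$sample_period_mcs
  total_mcs <- ceiling(days_to_mcs(duration_days, params))
  snaps <- NULL
  snap_at <- if (keep_snapshots)
    unique(round(days_to_mcs(params$scenario$snapshot_days, params))) else numeric(0)
  rows <- list(.sample_row(sim))
  if (keep_snapshots && 0 %in% snap_at)
    snaps[["day_0"]] <- lattice_matrix(sim)
  next_sample <- sample_period
  done <- 0
  while (done < total_mcs) {
    step <- min(K, total_mcs - done)
    run_mcs(sim, step, fields = TRUE)
    done <- done + step
    behaviour_sweep(sim)
    if (done >= next_sample) {
      rows[[length(rows) + 1L]] <- .sample_row(sim)
      next_sample <- next_sample + sample_period
    }
    hit <- snap_at[abs(snap_at - done) < K / 2]
    if (length(hit))
      snaps[[paste0("day_", round(mcs_to_days(hit[1], params), 2))]] <-
        lattice_matrix(sim)
    if (progress && done %% round(mcs_per_day(params)) < K)
      message(sprintf("day %.1f: %d cells", mcs_to_days(done, params),
                      nrow(sim$flags)))
  }
  ts <- do.call(rbind, rows)
  ts$closure_rate <- c(0, diff(ts$closure))
  list(timeseries = ts, snapshots = snaps, final = sim, seed = seed)
}

#' Run a scenario (all replicates)
#'
#' @param config A `scenario_config`.
#' @param keep_snapshots Keep lattice snapshots at the panel days?
#' @param progress Verbose per-day progress.
#' @return An object of class `scenario_result`: list with `name`,
#'   `replicates` (list of [run_replicate()] results) and `params`.
#' @export
run_scenario <- function(config, keep_snapshots = FALSE, progress = FALSE) {
  stopifnot(inherits(config, "scenario_config"))
  reps <- lapply(config$seeds, function(s)
    run_replicate(config$params, seed = s, keep_snapshots = keep_snapshots,
                  progress = progress))
  structure(list(name = config$name, replicates = reps,
                 params = config$params),
            class = "scenario_result")
}

#' Classify a repair outcome against a healthy baseline
#'
#' End-state (final sampled day) comparison: fibrotic when final ECM exceeds
#' the baseline by `fibrosis_factor`; chronic when final ECM falls below
#' `deficit_factor` times baseline OR the final inflammatory load
#' (inflammation total plus macrophage count, each relative to baseline)
#' exceeds `inflammation_factor`; otherwise healthy. Both series must be
#' sampled on the same day grid.
#'
#' @param ts Time series (data.frame from [run_replicate()]).
#' @param baseline_ts Healthy-baseline time series on the same day grid.
#' @param params Parameter list (for the classification factors).
#' @return One of "healthy", "chronic", "fibrotic".
#' @export
classify_outcome <- function(ts, baseline_ts, params = default_params()) {
  if (nrow(ts) != nrow(baseline_ts) ||
      max(abs(ts$day - baseline_ts$day)) > 1e-6)
    stop("time series are not sampled on the same day grid")
  cf <- params$classification
  last <- nrow(ts)
  ecol <- if ("ecm_wound" %in% names(ts) && "ecm_wound" %in% names(baseline_ts))
    "ecm_wound" else "ecm"   # new matrix laid down in the wound, if recorded
  ecm_ratio <- ts[[ecol]][last] / max(baseline_ts[[ecol]][last], 1)
  inf_ratio <- (ts$inf_total[last] + 1) / (baseline_ts$inf_total[last] + 1)
  mac_ratio <- (ts$macrophages[last] + 1) / (baseline_ts$macrophages[last] + 1)
  if (ecm_ratio < cf$deficit_factor) return("chronic")
  if (max(inf_ratio, mac_ratio) > cf$inflammation_factor) return("chronic")
  if (ecm_ratio > cf$fibrosis_factor) return("fibrotic")
  "healthy"
}
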