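# Multidimensional sensitivity sweep over the two senescence parameters:
# probability of myofibroblast senescence (P_SNC) and senescence induction
# time (T_SEN), with a "preexisting" pseudo-level standing for induction
# before the start of the simulated window (seeded inflammatory senescent
# cells). One simulation per grid point; 5 x 5 = 25 by default.

#' Sweep specification
#'
#' @param p_snc_levels Per-day senescence probabilities (default 0,
#'   baseline/2, baseline, 0.45, 0.75).
#' @param t_sen_levels List of induction-time levels: numbers are days;
#'   the string `"preexisting"` maps that column to the pre-existing
#'   inflammatory-senescence initial state.
#' @param params Base parameters.
#' @param duration_days,sample_period_mcs Run control.
#' @param scale Lattice scale factor (1 = the full 200 x 200 domain;
#'   0.3 gives the reduced 60 x 60 domain used for quick sweeps).
#' @param seed Master seed; each grid cell derives its own seed from its
#'   coordinates.
#' @return A `sweep_spec` list.
#' @export
sweep_spec <- function(p_snc_levels = NULL, t_sen_levels = NULL,
                       params = default_params(), duration_days = 6,
                       sample_period_mcs = 500, scale = 0.3, seed = 1L) {
  params <- validate_params(params)
  if (is.null(p_snc_levels)) {
    b <- params$rules$p_snc
    p_snc_levels <- c(0, b / 2, b, 0.45, 0.75)
  }
  if (is.null(t_sen_levels))
    t_sen_levels <- list("preexisting", t_sen_days(params), 7.5, 11, 15)
  structure(list(p_snc_levels = p_snc_levels, t_sen_levels = t_sen_levels,
                 params = params, duration_days = duration_days,
                 sample_period_mcs = sample_period_mcs, scale = scale,
                 seed = as.integer(seed)),
            class = "sweep_spec")
}

# Scale the lattice geometry (and seeded cell counts) by a linear factor.
.scale_params <- function(params, scale) {
  if (scale == 1) return(params)
  ini <- params$init
  blk <- ini$cell_block
  rnd <- function(v) max(blk, blk * round(v * scale / blk))
  params$init$width <- rnd(ini$width)
  params$init$height <- rnd(ini$height)
  params$init$wound_margin <- max(blk, blk * round(ini$wound_margin * scale / blk))
  params$init$n_macrophages <- max(1, round(ini$n_macrophages * scale^2))
  if (ini$n_preexisting > 0)
    params$init$n_preexisting <- max(1, round(ini$n_preexisting * scale^2))
  validate_params(params)
}

#' Run the parameter sweep
#'
#' Executes one simulation per (P_SNC, T_SEN) grid point and classifies each
#' end state against the baseline grid cell run at the same scale.
#'
#' @param spec A `sweep_spec`.
#' @param progress Print one line per completed run?
#' @return A `sweep_result`: list with `grid` (data.frame of one row per run
#'   with parameters, seed and classification), `timeseries` (list of
#'   data.frames, row order matching `grid`), and `spec`.
#' @export
run_sweep <- function(spec, progress = FALSE) {
  stopifnot(inherits(spec, "sweep_spec"))
  base <- .scale_params(spec$params, spec$scale)
  base$scenario$sample_period_mcs <- spec$sample_period_mcs
  cells <- expand.grid(i = seq_along(spec$p_snc_levels),
                       j = seq_along(spec$t_sen_levels))
  # healthy baseline at this scale, for classification
  base_run <- run_replicate(base, seed = spec$seed,
                            duration_days = spec$duration_days)
  ts_list <- vector("list", nrow(cells))
  grid <- data.frame(p_snc = numeric(nrow(cells)),
                     t_sen = character(nrow(cells)),
                     seed = integer(nrow(cells)),
                     classification = character(nrow(cells)))
  for (r in seq_len(nrow(cells))) {
    i <- cells$i[r]; j <- cells$j[r]
    p_snc <- spec$p_snc_levels[i]
    t_lvl <- spec$t_sen_levels[[j]]
    pr <- sim_params(rules = list(p_snc = p_snc), base = base)
    if (identical(t_lvl, "preexisting")) {
      # seed density matching 15 cells in the full 120x120 wound
      wa <- (pr$init$width - 2 * pr$init$wound_margin) *
        (pr$init$height - 2 * pr$init$wound_margin)
      pr <- sim_params(init = list(n_preexisting = max(1, round(15 * wa / 14400))),
                       base = pr)
    } else {
      pr <- sim_params(rules = list(t_sen = as.numeric(t_lvl),
                                    t_sen_unit = "days"), base = pr)
    }
    seed_r <- (spec$seed * 97L + i * 31L + j) %% .Machine$integer.max
    run <- run_replicate(pr, seed = seed_r,
                         duration_days = spec$duration_days)
    ts_list[[r]] <- run$timeseries
    grid$p_snc[r] <- p_snc
    grid$t_sen[r] <- if (identical(t_lvl, "preexisting")) "preexisting"
                     else as.character(t_lvl)
    grid$seed[r] <- seed_r
    grid$classification[r] <- classify_outcome(run$timeseries,
                                               base_run$timeseries, base)
    if (progress)
      message(sprintf("sweep %d/%d: p_snc=%.3g t_sen=%s -> %s",
                      r, nrow(cells), p_snc, grid$t_sen[r],
                      grid$classification[r]))
  }
  structure(list(grid = grid, timeseries = ts_list, spec = spec,
                 baseline = base_run$timeseries),
            class = "sweep_result")
}
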