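# Particle swarm optimisation of the six threshold parameters (PDGF_f,
# SNC_thr, MMP_thr, ECM_thr, INF_thr, CSF1_thr) against calibration curves,
# with the relative-error objective over the six observables: fibroblast,
# myofibroblast, senescent-myofibroblast and macrophage populations, ECM and
# wound-closure rate.

.pso_observables <- c("fibroblasts", "myofibroblasts", "senescent",
                      "macrophages", "ecm", "closure_rate")

#' Relative error between a simulation and target curves
#'
#' For each observable: the mean over sampled times of
#' `|sim - target| / max(|target|, eps)`, where the floor `eps` is 1% of the
#' curve's maximum (so exact zeros in a target do not blow up the error).
#' Targets are linearly interpolated onto the simulation's sample days; the
#' overall objective is the mean over the observables present in both.
#'
#' @param sim_ts Simulation time series ([run_replicate()] data.frame).
#' @param target_curves Named list of data.frames with columns `day`,
#'   `value` (one per observable), or a long data.frame with a column
#'   `observable`.
#' @param eps_frac Relative floor for the denominator (default 0.01).
#' @return Scalar mean relative error (>= 0).
#' @export
objective_relative_error <- function(sim_ts, target_curves, eps_frac = 0.01) {
  if (is.data.frame(target_curves))
    target_curves <- split(target_curves[c("day", "value")],
                           target_curves$observable)
  obs <- intersect(.pso_observables, names(target_curves))
  if (!length(obs)) stop("no usable target curves")
  errs <- vapply(obs, function(o) {
    tc <- target_curves[[o]]
    if (!nrow(tc)) stop("empty target curve for ", o)
    keep <- sim_ts$day >= min(tc$day) & sim_ts$day <= max(tc$day)
    d <- sim_ts$day[keep]
    tgt <- stats::approx(tc$day, tc$value, xout = d, rule = 2)$y
    eps <- max(abs(tc$value)) * eps_frac
    eps <- max(eps, .Machine$double.eps)
    mean(abs(sim_ts[[o]][keep] - tgt) / pmax(abs(tgt), eps))
  }, numeric(1))
  mean(errs)
}

#' Particle swarm optimisation
#'
#' Canonical global-best PSO: velocity update with inertia, cognitive and
#' social terms; positions clamped to the box bounds. The returned
#' best-value trace is non-increasing by construction.
#'
#' @param objective Function of a parameter vector, returning a scalar.
#' @param lower,upper Box bounds (named vectors name the parameters).
#' @param swarm Swarm size (>= 2).
#' @param iterations Iteration budget (exhausting it is normal termination).
#' @param inertia,cognitive,social PSO coefficients.
#' @param seed RNG seed.
#' @return List: `par` (best position), `value`, `trace` (best value per
#'   iteration), `evaluations`.
#' @export
pso_fit <- function(objective, lower, upper, swarm = 15, iterations = 50,
                    inertia = 0.7, cognitive = 1.5, social = 1.5, seed = 1L) {
  stopifnot(length(lower) == length(upper), all(is.finite(c(lower, upper))),
            all(upper >= lower), swarm >= 2)
  set.seed(seed)
  d <- length(lower)
  span <- upper - lower
  pos <- matrix(stats::runif(swarm * d), swarm, d)
  pos <- sweep(sweep(pos, 2, span, "*"), 2, lower, "+")
  vel <- matrix(stats::runif(swarm * d, -1, 1), swarm, d) *
    matrix(span, swarm, d, byrow = TRUE) * 0.1
  val <- apply(pos, 1, objective)
  pbest <- pos; pbest_val <- val
  g <- which.min(val)
  gbest <- pos[g, ]; gbest_val <- val[g]
  trace <- numeric(iterations)
  for (it in seq_len(iterations)) {
    r1 <- matrix(stats::runif(swarm * d), swarm, d)
    r2 <- matrix(stats::runif(swarm * d), swarm, d)
    vel <- inertia * vel +
      cognitive * r1 * (pbest - pos) +
      social * r2 * (matrix(gbest, swarm, d, byrow = TRUE) - pos)
    pos <- pos + vel
    for (k in seq_len(d)) pos[, k] <- pmin(pmax(pos[, k], lower[k]), upper[k])
    val <- apply(pos, 1, objective)
    improved <- val < pbest_val
    pbest[improved, ] <- pos[improved, , drop = FALSE]
    pbest_val[improved] <- val[improved]
    g <- which.min(pbest_val)
    if (pbest_val[g] < gbest_val) {
      gbest_val <- pbest_val[g]; gbest <- pbest[g, ]
    }
    trace[it] <- gbest_val
  }
  names(gbest) <- names(lower)
  list(par = gbest, value = gbest_val, trace = trace,
       evaluations = swarm * (iterations + 1))
}

#' Simulate the six calibration observables at given thresholds
#'
#' Helper used for threshold fitting: runs one (optionally reduced-scale)
#' replicate with the six threshold parameters replaced, and returns its
#' time series.
#'
#' @param thresholds Named vector with any of pdgf_f, snc_thr, mmp_thr,
#'   ecm_thr, inf_thr, csf1_thr.
#' @param params Base parameters.
#' @param scale Lattice scale factor (see [sweep_spec()]).
#' @param duration_days Simulated duration.
#' @param seed Seed (keep it fixed across objective evaluations so the
#'   objective is deterministic in the parameters).
#' @return Time-series data.frame.
#' @export
simulate_observables <- function(thresholds, params = default_params(),
                                 scale = 0.3, duration_days = 4, seed = 1L) {
  p <- .scale_params(validate_params(params), scale)
  th <- as.list(thresholds)
  bad <- setdiff(names(th), names(p$thresholds))
  if (length(bad)) stop("unknown threshold: ", bad[1])
  p <- sim_params(thresholds = th, base = p)
  run_replicate(p, seed = seed, duration_days = duration_days)$timeseries
}

#' Fit thresholds to calibration curves by PSO
#'
#' @param target_curves Target curves (see [objective_relative_error()]).
#' @param lower,upper Named bounds over a subset of the six thresholds.
#' @param params Base parameters.
#' @param scale,duration_days Reduced-scale simulation settings for each
#'   objective evaluation.
#' @param swarm,iterations,seed PSO controls.
#' @return [pso_fit()] result plus `objective` (the closed-over function).
#' @export
fit_thresholds <- function(target_curves, lower, upper,
                           params = default_params(), scale = 0.3,
                           duration_days = 4, swarm = 10, iterations = 12,
                           seed = 1L) {
  obj <- function(x) {
    names(x) <- names(lower)
    ts <- simulate_observables(x, params, scale, duration_days, seed = seed)
    objective_relative_error(ts, target_curves)
  }
  res <- pso_fit(obj, lower, upper, swarm = swarm, iterations = iterations,
                 seed = seed + 1L)
  res$objective <- obj
  res
}
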