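# Model parameters, configuration I/O and validation.
#
# All parameters live in one nested list (class "cpm_params") whose baseline
# values ship as inst/extdata/baseline_params.yaml. Field concentrations are
# in arbitrary model units (only ratios to thresholds matter); lengths are in
# pixels (3 um each) and times in MCS (27 s each) unless a key name says
# otherwise (_per_day, _days).

.pkg_env <- new.env(parent = emptyenv())

#' Cell type codes used on the lattice
#'
#' Integer codes shared with the C++ engine: 0 is Medium (no cell), then
#' fibroblast, myofibroblast, macrophage, senescent myofibroblast,
#' pre-existing inflammatory senescent cell and one-pixel ECM.
#'
#' @return Named integer vector of type codes.
#' @export
cell_types <- function() {
  c(Medium = 0L, Fibroblast = 1L, Myofibroblast = 2L, Macrophage = 3L,
    SenescentMyofibroblast = 4L, InflammatorySenescent = 5L, ECM = 6L)
}

#' Chemical field names
#'
#' Order matches the engine's internal field indices (0-based in C++).
#'
#' @return Character vector: pdgf, csf1, mmp, inf.
#' @export
field_names <- function() c("pdgf", "csf1", "mmp", "inf")

.field_index <- function(name) {
  i <- match(match.arg(name, field_names()), field_names())
  i - 1L
}

#' Baseline simulation parameters
#'
#' Loads the packaged baseline configuration (the healthy-healing
#' parameterisation). The result is cached per session.
#'
#' @return A `cpm_params` list.
#' @export
default_params <- function() {
  if (is.null(.pkg_env$defaults)) {
    path <- system.file("extdata", "baseline_params.yaml", package = "dermalCPM")
    if (!nzchar(path)) stop("packaged baseline_params.yaml not found")
    .pkg_env$defaults <- load_config(path)
  }
  .pkg_env$defaults
}

#' Build a parameter set with overrides
#'
#' @param ... Named overrides as nested lists, e.g.
#'   `sim_params(rules = list(p_snc = 0))`. Unknown keys are an error.
#' @param base Parameter set to start from (default: packaged baseline).
#' @return A validated `cpm_params` list.
#' @export
sim_params <- function(..., base = default_params()) {
  ov <- list(...)
  p <- .merge_params(base, ov, path = "")
  validate_params(p)
}

.merge_params <- function(base, ov, path) {
  if (length(ov) == 0) return(base)
  nm <- names(ov)
  if (is.null(nm) || any(!nzchar(nm))) stop("overrides must be named")
  for (i in seq_along(ov)) {
    k <- nm[i]
    full <- if (nzchar(path)) paste0(path, "$", k) else k
    if (!k %in% names(base)) stop("unknown parameter key: ", full)
    if (is.list(base[[k]]) && !is.null(names(base[[k]]))) {
      if (!is.list(ov[[i]])) stop("parameter ", full, " must be a named list")
      base[[k]] <- .merge_params(base[[k]], ov[[i]], full)
    } else {
      base[[k]] <- ov[[i]]
    }
  }
  base
}

#' Validate a parameter set
#'
#' Checks probability bounds, non-negativity of rates and thresholds, the
#' explicit-scheme stability bound for the diffusion solver and the fixed
#' unit identities. The ECM output doubling rule (myofibroblasts produce
#' twice the fibroblast amount) is a warning, not an error, so it can be
#' overridden deliberately.
#'
#' @param p Parameter list.
#' @return The validated list, invisibly classed as `cpm_params`.
#' @export
validate_params <- function(p) {
  chk <- function(ok, msg) if (!any(is.na(ok)) && all(ok)) TRUE else stop("invalid parameters: ", msg)
  u <- p$units
  chk(u$pixel_um > 0 && u$seconds_per_mcs > 0, "unit scales must be positive")
  chk(abs(u$seconds_per_mcs -
          u$reference_displacement_um * 3600 / u$reference_speed_um_h) < 1e-9,
      "seconds_per_mcs must equal reference_displacement_um * 3600 / reference_speed_um_h")
  chk(p$cpm$temperature > 0, "Metropolis temperature must be > 0")
  for (f in field_names()) {
    fp <- p$fields[[f]]
    chk(fp$diffusion >= 0 && fp$decay >= 0, paste0(f, " diffusion/decay must be >= 0"))
    chk(fp$decay <= 1, paste0(f, " decay per MCS must be <= 1"))
  }
  pr <- p$rules
  for (k in c("p_mf", "p_snc", "p_clear"))
    chk(pr[[k]] >= 0 && pr[[k]] <= 1, paste0(k, " must be a probability"))
  chk(pr$mu >= 0, "mu must be >= 0")
  chk(pr$t_nis_days > 0, "t_nis_days must be > 0")
  chk(pr$sweep_period_mcs >= 1, "sweep_period_mcs must be >= 1")
  chk(pr$t_sen >= 0, "t_sen must be >= 0")
  chk(pr$t_sen_unit %in% c("steps500", "steps1000", "days", "hours"), "t_sen_unit unknown")
  chk(pr$t_sen_gate %in% c("open_after", "closed_after"), "t_sen_gate unknown")
  th <- p$thresholds
  for (k in names(th)) chk(th[[k]] >= 0, paste0("threshold ", k, " must be >= 0"))
  g <- p$growth
  chk(all(c(g$gmax_fib, g$gmax_myo, g$gmax_mac) >= 0), "growth rates must be >= 0")
  chk(g$pdgf0 > 0 && g$csf0 > 0, "half-saturation constants must be > 0")
  chk(g$t_ci >= 0 && g$t_ci <= 1, "t_ci must be in [0,1]")
  if (abs(pr$ecm_myo_per_day - 2 * pr$ecm_fib_per_day) > 1e-9)
    warning("ecm_myo_per_day is not twice ecm_fib_per_day (override allowed)")
  cx <- p$chemotaxis
  chk(cx$lambda_pdgf_ecm >= cx$lambda_pdgf,
      "lambda_pdgf_ecm must be >= lambda_pdgf (chemotaxis strengthened on ECM)")
  ini <- p$init
  chk(ini$width >= 3 && ini$height >= 3, "lattice too small")
  chk(2 * ini$wound_margin < min(ini$width, ini$height),
      "wound margin leaves no wound interior")
  structure(p, class = "cpm_params")
}

#' Read a configuration file
#'
#' YAML configuration with the same nesting as [default_params()]. Unknown
#' keys are rejected with the offending key named.
#'
#' @param path File path.
#' @param base Optional base to merge a partial config over; if `NULL`
#'   (default) the file must be complete.
#' @return A validated `cpm_params` list.
#' @export
load_config <- function(path, base = NULL) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (!is.null(base)) return(validate_params(.merge_params(base, raw, "")))
  validate_params(.check_complete(raw))
}

.config_keys <- function() {
  list(
    units = c("pixel_um", "seconds_per_mcs", "reference_displacement_um",
              "reference_speed_um_h"),
    cpm = c("temperature", "contact_energy", "target_volume", "lambda_volume",
            "target_surface", "lambda_surface"),
    chemotaxis = c("lambda_pdgf", "lambda_pdgf_ecm", "lambda_inf"),
    fields = field_names(),
    secretion = c("pdgf_mac_m2", "mmp_mac_m1", "mmp_mac_ecm", "csf1_fib",
                  "pdgf_myo", "csf1_myo", "pdgf_snc", "csf1_snc", "inf_snc",
                  "mmp_snc"),
    growth = c("gmax_fib", "gmax_myo", "gmax_mac", "pdgf0", "csf0", "t_ci"),
    thresholds = c("pdgf_f", "snc_thr", "mmp_thr", "ecm_thr", "inf_thr",
                   "csf1_thr"),
    rules = c("sweep_period_mcs", "p_mf", "p_snc", "p_clear", "mu",
              "t_sen", "t_sen_unit", "t_sen_gate", "t_nis_days",
              "ecm_fib_per_day", "ecm_myo_per_day", "ecm_snc_per_day",
              "p_dediff"),
    init = c("width", "height", "wound_margin", "cell_block", "fib_fraction",
             "ecm_fraction", "n_macrophages", "n_preexisting", "pre_inf_bolus",
             "csf1_init"),
    scenario = c("duration_days", "replicates", "sample_period_mcs",
                 "snapshot_days"),
    classification = c("fibrosis_factor", "deficit_factor",
                       "inflammation_factor"))
}

.check_complete <- function(raw) {
  spec <- .config_keys()
  for (sec in names(spec)) {
    if (!sec %in% names(raw)) stop("config section missing: ", sec)
    extra <- setdiff(names(raw[[sec]]), spec[[sec]])
    if (length(extra))
      stop("unknown config key: ", sec, "$", extra[1])
    missing <- setdiff(spec[[sec]], names(raw[[sec]]))
    if (length(missing))
      stop("config key missing: ", sec, "$", missing[1])
  }
  extra <- setdiff(names(raw), names(spec))
  if (length(extra)) stop("unknown config section: ", extra[1])
  raw
}

#' Write a configuration file
#'
#' @param p A `cpm_params` list.
#' @param path Output path (YAML).
#' @return `path`, invisibly.
#' @export
save_config <- function(p, path) {
  yaml::write_yaml(unclass(p), path)
  invisible(path)
}

# Full symmetric contact-energy matrix over (Medium, F, MF, M, SNC, PRE, ECM)
# from the compact config block. Medium-Medium is 0 by definition.
build_contact_matrix <- function(p) {
  ce <- p$cpm$contact_energy
  tn <- names(cell_types())
  J <- matrix(ce$cell_cell, 7, 7, dimnames = list(tn, tn))
  J["Medium", ] <- J[, "Medium"] <- ce$cell_medium
  J["ECM", ] <- J[, "ECM"] <- ce$ecm_cell
  J["ECM", "Medium"] <- J["Medium", "ECM"] <- ce$ecm_medium
  J["ECM", "ECM"] <- ce$ecm_ecm
  J["Medium", "Medium"] <- 0
  J
}

# Per-type energy parameter lookup vectors (indexed by type code 1..6).
.type_param <- function(block) {
  nm <- c("fib", "myo", "mac", "snc", "pre", "ecm")
  vapply(nm, function(k) as.numeric(block[[k]]), numeric(1))
}

#' T_SEN gate time in days
#'
#' Converts the configured senescence-induction time constraint to days,
#' honouring its configurable unit (500-MCS model steps, hours or days).
#'
#' @param p Parameter list.
#' @return Gate time in simulated days.
#' @export
t_sen_days <- function(p) {
  v <- p$rules$t_sen
  switch(p$rules$t_sen_unit,
         steps500 = v * 500 / mcs_per_day(p),
         steps1000 = v * 1000 / mcs_per_day(p),
         hours = v / 24,
         days = v)
}

#' Is primary (CCN1) senescence permitted at time t?
#'
#' The default gate opens at `t >= T_SEN` (induction during mid-to-late
#' healing); the alternative reading (`closed_after`) permits induction only
#' before the gate time.
#'
#' @param t_day Simulated time in days.
#' @param p Parameter list.
#' @return Logical.
#' @export
senescence_gate_open <- function(t_day, p) {
  gate <- t_sen_days(p)
  if (identical(p$rules$t_sen_gate, "closed_after")) t_day < gate
  else t_day >= gate
}
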