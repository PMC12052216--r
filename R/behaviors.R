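# Cell behaviour rules, executed once per behaviour sweep (every
# `rules$sweep_period_mcs` MCS). All rules are computed from a consistent
# census snapshot taken at the start of the sweep and then applied together;
# threshold comparisons are strict (>) or (<) as stated per rule.
#
# The binomial-draw probabilities p_mf and p_snc are per 500-MCS model step
# (the cadence at which the model's state is reported) and are compounded to
# the sweep period as 1 - (1 - p)^(K/500); the removal rate mu is per day
# (1 - exp(-mu*dt)); p_clear is a per-sweep probability by definition.

#' Monod growth increment
#'
#' Saturating growth law `Gmax * c / (c + c0)` linking the target-volume
#' increment per MCS to the limiting factor's concentration (PDGF for
#' fibroblasts/myofibroblasts, CSF1 for macrophages).
#'
#' @param gmax Maximum growth rate (pixels/MCS).
#' @param conc Concentration at the cell's COM (>= 0).
#' @param half_sat Half-saturation concentration (> 0).
#' @return Target-volume increment per MCS (vectorised).
#' @export
monod_growth_increment <- function(gmax, conc, half_sat) {
  if (any(conc < 0)) stop("concentration must be >= 0")
  gmax * conc / (conc + half_sat)
}

#' Contact-inhibition gate
#'
#' A cell may grow only while the fraction of its surface facing Medium,
#' Rs, is at least the threshold `t_ci`; below it, growth is arrested and the
#' target volume is frozen at the current volume (the boundary case Rs ==
#' t_ci grows).
#'
#' @param rs Medium-surface ratio in \[0, 1\].
#' @param t_ci Contact-inhibition threshold.
#' @return Logical: may the cell grow? (vectorised)
#' @export
contact_inhibition_gate <- function(rs, t_ci) rs >= t_ci

#' Macrophage polarisation
#'
#' M1 (MMP-secreting) if the inflammatory SASP concentration at the COM
#' strictly exceeds `inf_thr`, else M2 (PDGF-secreting). Re-evaluated every
#' behaviour sweep.
#'
#' @param inf_at_com Inflammation at the macrophage COM.
#' @param inf_thr Polarisation threshold.
#' @return Character vector, "M1" or "M2".
#' @export
polarize_macrophage <- function(inf_at_com, inf_thr) {
  ifelse(inf_at_com > inf_thr, "M1", "M2")
}

#' Fibroblast activation
#'
#' A quiescent fibroblast activates when PDGF at its COM strictly exceeds
#' `pdgf_f`; activation is persistent (an activated cell never reverts).
#'
#' @param activated Current activation state (logical).
#' @param pdgf_at_com PDGF at the COM.
#' @param pdgf_f Activation threshold.
#' @return Updated activation state (vectorised).
#' @export
activate_fibroblast <- function(activated, pdgf_at_com, pdgf_f) {
  activated | (pdgf_at_com > pdgf_f)
}

#' Myofibroblast differentiation decision
#'
#' An activated fibroblast inside the (t = 0) wound region differentiates
#' when PDGF at its COM exceeds `pdgf_f` AND its shared surface with ECM
#' exceeds `ecm_thr`, with per-check probability `p_mf`.
#'
#' @param eligible Logical: both gates hold (activated, in wound, PDGF and
#'   ECM-contact gates).
#' @param p_mf Per-check differentiation probability.
#' @return Logical: differentiate this check (vectorised; draws from the
#'   session RNG).
#' @export
differentiate_myofibroblast <- function(eligible, p_mf) {
  eligible & stats::runif(length(eligible)) < p_mf
}

#' Myofibroblast fate decision
#'
#' Apoptosis when ECM contact is strictly below `ecm_thr` (release of
#' mechanical tension) OR inflammation at the COM strictly exceeds `inf_thr`;
#' otherwise, while the senescence time gate is open and ECM contact strictly
#' exceeds `ecm_thr`, primary (CCN1) senescence with per-check probability
#' `p_snc`; otherwise survival.
#'
#' @param ecm_contact Shared surface (pixel pairs) with ECM.
#' @param inf_at_com Inflammation at the COM.
#' @param gate_open Is primary senescence currently permitted?
#' @param p_snc Per-check senescence probability.
#' @param ecm_thr,inf_thr Thresholds.
#' @return Character vector: "survive", "apoptosis" or "senesce".
#' @export
myofibroblast_fate <- function(ecm_contact, inf_at_com, gate_open, p_snc,
                               ecm_thr, inf_thr) {
  n <- length(ecm_contact)
  out <- rep("survive", n)
  apo <- ecm_contact < ecm_thr | inf_at_com > inf_thr
  out[apo] <- "apoptosis"
  if (gate_open) {
    elig <- !apo & ecm_contact > ecm_thr
    sen <- elig & stats::runif(n) < p_snc
    out[sen] <- "senesce"
  }
  out
}

#' SASP phase of a senescent cell
#'
#' Fibrogenic (PDGF + ECM output) while the senescence clock is below
#' `t_nis_days`, fibrolytic (CSF1 + inflammation + MMP) from `t_nis_days`
#' onward; pre-existing inflammatory senescent cells are permanently
#' fibrolytic.
#'
#' @param sen_clock Days since induction.
#' @param t_nis_days Fibrogenic phase duration (days).
#' @param preexisting Logical: pre-existing inflammatory senescent cell?
#' @return Character vector, "fibrogenic" or "fibrolytic".
#' @export
update_sasp_phase <- function(sen_clock, t_nis_days, preexisting = FALSE) {
  ifelse(preexisting | sen_clock >= t_nis_days, "fibrolytic", "fibrogenic")
}

#' Senescent-cell clearance decision
#'
#' Two independent immune-surveillance triggers with the same per-sweep
#' probability `p_clear` ("equal chance"): macrophage contact (phagocytosis)
#' and inflammation at the COM strictly above `inf_thr`.
#'
#' @param mac_contact Shared surface with macrophages (pairs).
#' @param inf_at_com Inflammation at the COM.
#' @param inf_thr Threshold.
#' @param p_clear Per-sweep clearance probability per trigger.
#' @return Logical removal flag (vectorised; draws from the session RNG).
#' @export
clear_senescent <- function(mac_contact, inf_at_com, inf_thr, p_clear) {
  n <- length(mac_contact)
  by_contact <- mac_contact > 0 & stats::runif(n) < p_clear
  by_inf <- inf_at_com > inf_thr & stats::runif(n) < p_clear
  by_contact | by_inf
}

#' Per-sweep probability from a per-day rate or probability
#'
#' `rate_kind = "probability"` compounds a per-day probability
#' (`1 - (1-p)^dt`); `rate_kind = "rate"` converts a Poisson rate
#' (`1 - exp(-mu * dt)`).
#'
#' @param p_day Per-day probability or rate.
#' @param dt_days Sweep period in days.
#' @param rate_kind "probability" or "rate".
#' @return Per-sweep probability.
#' @export
per_sweep_probability <- function(p_day, dt_days, rate_kind = c("probability", "rate")) {
  switch(match.arg(rate_kind),
         probability = 1 - (1 - p_day)^dt_days,
         rate = 1 - exp(-p_day * dt_days))
}

# Integer ECM output for one sweep from a per-day deposition rate:
# deterministic floor plus a Bernoulli draw on the fractional remainder.
.ecm_count <- function(rate_per_day, dt_days, n) {
  expect <- rep(rate_per_day * dt_days, length.out = n)
  base <- floor(expect)
  frac <- expect - base
  as.integer(base + (stats::runif(n) < frac))
}

# Per-cell secretion rates (per MCS, to be split over pixels) from a roster
# of current states. `roster` needs: id, type, c_mac, c_ecm, m1, fibrolytic.
secretion_rates <- function(roster, flags, params) {
  ct <- cell_types()
  s <- params$secretion
  n <- nrow(roster)
  out <- data.frame(id = roster$id, pdgf = numeric(n), csf1 = numeric(n),
                    mmp = numeric(n), inf = numeric(n))
  if (!n) return(out)
  if (!"m1" %in% names(roster)) {
    m <- match(roster$id, flags$id)
    roster$m1 <- flags$m1[m]
    roster$fibrolytic <- with(flags[m, ], !is.na(sen_clock) &
      update_sasp_phase(sen_clock, params$rules$t_nis_days,
                        sen_mech %in% "preexisting") == "fibrolytic")
    roster$activated <- flags$activated[m]
  }
  mac <- roster$type == ct[["Macrophage"]]
  out$pdgf[mac & !roster$m1] <- s$pdgf_mac_m2
  out$mmp[mac & roster$m1] <- out$mmp[mac & roster$m1] + s$mmp_mac_m1
  ecm_touch <- mac & roster$c_ecm > 0
  out$mmp[ecm_touch] <- out$mmp[ecm_touch] + s$mmp_mac_ecm
  fib <- roster$type == ct[["Fibroblast"]]
  gated <- fib & roster$activated & roster$c_mac > 0
  out$csf1[gated] <- s$csf1_fib
  myo <- roster$type == ct[["Myofibroblast"]]
  out$pdgf[myo] <- s$pdgf_myo
  out$csf1[myo & roster$c_mac > 0] <- s$csf1_myo
  sen <- roster$type %in% ct[c("SenescentMyofibroblast", "InflammatorySenescent")]
  fibro_phase <- sen & !roster$fibrolytic
  lytic_phase <- sen & roster$fibrolytic
  out$pdgf[fibro_phase] <- s$pdgf_snc
  out$csf1[lytic_phase] <- s$csf1_snc
  out$inf[lytic_phase] <- s$inf_snc
  out$mmp[lytic_phase] <- s$mmp_snc
  out
}

#' Execute one behaviour sweep
#'
#' Applies the full per-sweep rule system in a fixed, documented order:
#' senescence clocks and SASP phases; macrophage polarisation; fibroblast
#' activation; TIMP inhibition of MMP at myofibroblast COMs; MMP-driven ECM
#' degradation; myofibroblast differentiation; ECM deposition; myofibroblast
#' fate (apoptosis / primary senescence); juxtacrine then paracrine secondary
#' senescence; senescent-cell clearance; background removal (rate mu and
#' CSF1 withdrawal); Monod growth under the contact-inhibition gate;
#' mitosis; fragment culling; then refreshed secretion and chemotaxis
#' settings. All decisions read the census snapshot taken at entry.
#'
#' @param sim A `cpm_sim`.
#' @return The simulation, invisibly (its counters record events).
#' @export
behaviour_sweep <- function(sim) {
  p <- sim$params
  ct <- cell_types()
  th <- p$thresholds
  K <- p$rules$sweep_period_mcs
  dt <- K / mcs_per_day(p)
  dt_step <- K / 500            # behaviour probabilities are per 500-MCS step
  t_day <- mcs_to_days(sim$mcs, p)
  cen <- cpp_sweep_census(sim$ptr)
  fl <- sim$flags

  # cells that vanished through pixel-copy attrition since the last sweep
  gone <- setdiff(fl$id, cen$id)
  if (length(gone)) {
    was_sen <- fl$id %in% gone & !is.na(fl$sen_clock)
    sim$counters$cleared <- sim$counters$cleared + sum(was_sen)
    fl <- fl[!fl$id %in% gone, , drop = FALSE]
  }
  m <- match(cen$id, fl$id)            # NA for ECM cells
  type <- cen$type
  is_sen_type <- type %in% ct[c("SenescentMyofibroblast", "InflammatorySenescent")]

  # 1. clocks and SASP phase
  fl$sen_clock[stats::na.omit(m[is_sen_type])] <-
    fl$sen_clock[stats::na.omit(m[is_sen_type])] + dt
  pre <- !is.na(m) & fl$sen_mech[m] %in% "preexisting"
  fibrolytic <- is_sen_type &
    update_sasp_phase(ifelse(is.na(m), NA_real_, fl$sen_clock[m]),
                      p$rules$t_nis_days, pre) == "fibrolytic"
  fibrolytic[is.na(fibrolytic)] <- FALSE

  # 2. macrophage polarisation
  mac <- type == ct[["Macrophage"]]
  fl$m1[m[mac]] <- polarize_macrophage(cen$f_inf[mac], th$inf_thr) == "M1"

  # 3. fibroblast activation (persistent)
  fib <- type == ct[["Fibroblast"]]
  fl$activated[m[fib]] <- activate_fibroblast(fl$activated[m[fib]],
                                              cen$f_pdgf[fib], th$pdgf_f)

  # 4. TIMP: myofibroblasts reduce MMP at their COM by mmp_thr
  myo <- type == ct[["Myofibroblast"]]
  if (any(myo)) {
    px <- floor(cen$com_x[myo] + 0.5)
    py <- floor(cen$com_y[myo] + 0.5)
    cpp_field_sub_at(sim$ptr, .field_index("mmp"), as.integer(px),
                     as.integer(py), th$mmp_thr)
  }

  # 5. ECM degradation by MMP
  ecm_rm <- cen$id[type == ct[["ECM"]] & cen$f_mmp > th$mmp_thr]
  sim$counters$ecm_degraded <- sim$counters$ecm_degraded + length(ecm_rm)

  # 6. myofibroblast differentiation (activated, in wound, PDGF + ECM gates)
  px_all <- pmin(pmax(floor(cen$com_x + 0.5), 1), nrow(sim$wound_mask))
  py_all <- pmin(pmax(floor(cen$com_y + 0.5), 1), ncol(sim$wound_mask))
  in_wound <- sim$wound_mask[cbind(px_all, py_all)]
  p_mf_sweep <- per_sweep_probability(p$rules$p_mf, dt_step)
  elig_mf <- fib & fl$activated[m] & in_wound &
    cen$f_pdgf > th$pdgf_f & cen$c_ecm > th$ecm_thr
  elig_mf[is.na(elig_mf)] <- FALSE
  to_myo <- cen$id[differentiate_myofibroblast(elig_mf, p_mf_sweep)]

  # 7. ECM deposition (PDGF-gated for fibroblasts/myofibroblasts;
  #    constitutive for fibrogenic-phase senescent cells)
  prod_fib <- fib & fl$activated[m] & cen$f_pdgf > th$pdgf_f & !cen$id %in% to_myo
  prod_fib[is.na(prod_fib)] <- FALSE
  prod_myo <- myo & cen$f_pdgf > th$pdgf_f
  prod_sen <- is_sen_type & !fibrolytic
  prod_ids <- c(cen$id[prod_fib], cen$id[prod_myo], cen$id[prod_sen])
  if (length(prod_ids)) {
    counts <- c(.ecm_count(p$rules$ecm_fib_per_day, dt, sum(prod_fib)),
                .ecm_count(p$rules$ecm_myo_per_day, dt, sum(prod_myo)),
                .ecm_count(p$rules$ecm_snc_per_day, dt, sum(prod_sen)))
    keep <- counts > 0
    if (any(keep)) {
      got <- cpp_spawn_ecm(sim$ptr, prod_ids[keep], counts[keep],
                           p$cpm$target_volume$ecm, p$cpm$lambda_volume$ecm,
                           p$cpm$target_surface$ecm, p$cpm$lambda_surface$ecm)
      sim$counters$ecm_spawned <- sim$counters$ecm_spawned + sum(got)
    }
  }

  # 8. myofibroblast fate: apoptosis or primary (CCN1) senescence
  p_snc_sweep <- per_sweep_probability(p$rules$p_snc, dt_step)
  gate <- senescence_gate_open(t_day, p)
  fate <- rep("survive", nrow(cen))
  fate[myo] <- myofibroblast_fate(cen$c_ecm[myo], cen$f_inf[myo], gate,
                                  p_snc_sweep, th$ecm_thr, th$inf_thr)
  apo_ids <- cen$id[fate == "apoptosis"]
  primary_ids <- cen$id[fate == "senesce"]

  # 9. secondary senescence (juxtacrine then paracrine) in surviving myofibs
  surviving_myo <- myo & fate == "survive"
  fibro_ids <- cen$id[is_sen_type & !fibrolytic]
  lytic_ids <- cen$id[is_sen_type & fibrolytic]
  jux_ids <- par_ids <- integer(0)
  if (any(surviving_myo)) {
    if (length(fibro_ids)) {
      touch <- cpp_contact_with_ids(sim$ptr, fibro_ids)[cen$id + 1L]
      jux <- surviving_myo & touch > 0 & cen$f_pdgf > th$snc_thr
      jux_ids <- cen$id[jux]
      surviving_myo <- surviving_myo & !jux
    }
    if (length(lytic_ids) && any(surviving_myo)) {
      touch <- cpp_contact_with_ids(sim$ptr, lytic_ids)[cen$id + 1L]
      par <- surviving_myo & touch > 0 & cen$f_inf > th$inf_thr
      par_ids <- cen$id[par]
      surviving_myo <- surviving_myo & !par
    }
  }

  # optional de-differentiation of surviving myofibroblasts (off by default)
  dediff_ids <- integer(0)
  if (p$rules$p_dediff > 0 && any(surviving_myo)) {
    p_dd <- per_sweep_probability(p$rules$p_dediff, dt_step)
    dd <- surviving_myo & stats::runif(nrow(cen)) < p_dd
    dediff_ids <- cen$id[dd]
  }

  # 10. senescent clearance (macrophage contact / inflammation, equal chance)
  clr <- is_sen_type & clear_senescent(cen$c_mac, cen$f_inf, th$inf_thr,
                                       p$rules$p_clear)
  clr_ids <- cen$id[clr]

  # 11. background removal: rate mu for activated fibroblasts + macrophages;
  #     CSF1 withdrawal for macrophages
  p_mu <- per_sweep_probability(p$rules$mu, dt, "rate")
  act_fib <- fib & fl$activated[m] & !cen$id %in% to_myo
  act_fib[is.na(act_fib)] <- FALSE
  bg <- (act_fib | mac) & stats::runif(nrow(cen)) < p_mu
  starve <- mac & cen$f_csf1 < th$csf1_thr
  bg_ids <- cen$id[bg | starve]

  removed <- unique(c(ecm_rm, apo_ids, clr_ids, bg_ids))
  sim$counters$apoptosis <- sim$counters$apoptosis +
    length(setdiff(apo_ids, c(clr_ids, bg_ids)))
  sim$counters$cleared <- sim$counters$cleared + length(setdiff(clr_ids, bg_ids))

  # 12. Monod growth under contact inhibition (skipping removed cells)
  grow_type <- type %in% ct[c("Fibroblast", "Myofibroblast", "Macrophage")]
  growers <- grow_type & !cen$id %in% removed & cen$surface > 0
  if (any(growers)) {
    rs <- cen$c_medium[growers] / cen$surface[growers]
    allow <- contact_inhibition_gate(rs, p$growth$t_ci)
    conc <- ifelse(type[growers] == ct[["Macrophage"]],
                   cen$f_csf1[growers], cen$f_pdgf[growers])
    gmax <- c(p$growth$gmax_fib, p$growth$gmax_myo,
              p$growth$gmax_mac)[match(type[growers], ct[c("Fibroblast",
                                                           "Myofibroblast",
                                                           "Macrophage")])]
    c0 <- ifelse(type[growers] == ct[["Macrophage"]], p$growth$csf0, p$growth$pdgf0)
    inc <- monod_growth_increment(gmax, conc, c0) * K
    tv_new <- ifelse(allow, cen$target_volume[growers] + inc, cen$volume[growers])
    cpp_set_target_volume(sim$ptr, cen$id[growers], tv_new)
    fl$frozen[m[which(growers)]] <- !allow
  }

  # apply type transitions
  if (length(to_myo)) cpp_set_type(sim$ptr, to_myo, ct[["Myofibroblast"]])
  new_sen <- c(primary_ids, jux_ids, par_ids)
  new_sen <- setdiff(new_sen, removed)
  if (length(new_sen)) {
    cpp_set_type(sim$ptr, new_sen, ct[["SenescentMyofibroblast"]])
    idx <- match(new_sen, fl$id)
    fl$sen_clock[idx] <- 0
    fl$sen_mech[idx] <- c(rep("primary", length(setdiff(primary_ids, removed))),
                          rep("juxtacrine", length(setdiff(jux_ids, removed))),
                          rep("paracrine", length(setdiff(par_ids, removed))))
    sim$counters$primary <- sim$counters$primary + sum(fl$sen_mech[idx] == "primary")
    sim$counters$juxtacrine <- sim$counters$juxtacrine + sum(fl$sen_mech[idx] == "juxtacrine")
    sim$counters$paracrine <- sim$counters$paracrine + sum(fl$sen_mech[idx] == "paracrine")
  }
  if (length(dediff_ids)) {
    keep_dd <- setdiff(dediff_ids, removed)
    if (length(keep_dd)) cpp_set_type(sim$ptr, keep_dd, ct[["Fibroblast"]])
  }
  if (length(removed)) {
    cpp_remove_cells(sim$ptr, removed)
    fl <- fl[!fl$id %in% removed, , drop = FALSE]
  }

  # 13. mitosis at doubling volume (post-removal state)
  tab <- cpp_cells_table(sim$ptr)
  m2 <- match(tab$id, fl$id)
  ready <- tab$type %in% ct[c("Fibroblast", "Myofibroblast", "Macrophage")] &
    !is.na(m2) & tab$volume >= 2 * fl$orig_tv[m2]
  if (any(ready)) {
    div <- cpp_divide_cells(sim$ptr, tab$id[ready])
    if (nrow(div)) {
      sim$counters$divisions <- sim$counters$divisions + nrow(div)
      pm <- match(div$parent, fl$id)
      kids <- fl[pm, , drop = FALSE]
      kids$id <- div$daughter
      fl <- rbind(fl, kids)
      both <- c(div$parent, div$daughter)
      cpp_set_target_volume(sim$ptr, both, fl$orig_tv[match(both, fl$id)])
      fl$frozen[match(both, fl$id)] <- FALSE
    }
  }

  # 14. fragment culling (lazy connectivity repair)
  culled <- cpp_cull_fragments(sim$ptr)
  if (length(culled)) {
    was_sen <- fl$id %in% culled & !is.na(fl$sen_clock)
    sim$counters$cleared <- sim$counters$cleared + sum(was_sen)
    sim$counters$fragments_culled <- sim$counters$fragments_culled + length(culled)
    fl <- fl[!fl$id %in% culled, , drop = FALSE]
  }
  sim$flags <- fl

  # 15. refresh secretion + chemotaxis from the post-sweep state
  cen2 <- cpp_sweep_census(sim$ptr)
  m3 <- match(cen2$id, fl$id)
  pre2 <- !is.na(m3) & fl$sen_mech[m3] %in% "preexisting"
  roster <- data.frame(
    id = cen2$id, type = cen2$type, c_mac = cen2$c_mac, c_ecm = cen2$c_ecm,
    m1 = !is.na(m3) & fl$m1[m3],
    activated = !is.na(m3) & fl$activated[m3],
    fibrolytic = cen2$type %in% ct[c("SenescentMyofibroblast", "InflammatorySenescent")] &
      update_sasp_phase(ifelse(is.na(m3), Inf, fl$sen_clock[m3]),
                        p$rules$t_nis_days, pre2) == "fibrolytic")
  rates <- secretion_rates(roster, fl, p)
  cpp_set_secretion(sim$ptr, rates$id,
                    as.matrix(rates[, c("pdgf", "csf1", "mmp", "inf")]))
  .refresh_chemotaxis(sim, cen2)
  invisible(sim)
}
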