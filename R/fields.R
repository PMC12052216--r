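# Reaction-diffusion layer: four non-negative scalar fields (PDGF, CSF1,
# MMP, inflammatory SASP) co-registered with the lattice, integrated by
# forward-Euler 5-point diffusion with reflecting (no-flux) boundaries,
# multiplicative decay and additive secretion.

#' Read a chemical field
#' @param sim A `cpm_sim`.
#' @param field One of `field_names()`.
#' @return Numeric matrix, same shape as the lattice.
#' @export
field_matrix <- function(sim, field) cpp_field(sim$ptr, .field_index(field))

#' Overwrite a chemical field
#' @param sim A `cpm_sim`.
#' @param field One of `field_names()`.
#' @param values Numeric matrix (negative entries are clamped to 0).
#' @return The simulation, invisibly.
#' @export
set_field_matrix <- function(sim, field, values) {
  cpp_set_field(sim$ptr, .field_index(field), values)
  invisible(sim)
}

#' Advance one field by one Monte-Carlo step
#'
#' Standalone integrator on plain matrices: adds the secretion map, then
#' applies `substeps` forward-Euler substeps of 5-point no-flux diffusion and
#' multiplicative decay `(1 - decay * dt)` (clamped at 0). The number of
#' substeps defaults to the smallest value satisfying the explicit-scheme
#' stability bound `D * dt <= 1/4`.
#'
#' @param field Numeric matrix.
#' @param diffusion Diffusion coefficient D (pixel^2/MCS).
#' @param decay Decay constant (1/MCS).
#' @param secretion Numeric matrix of per-pixel secretion for this MCS, or
#'   `NULL` for none.
#' @param substeps Number of substeps, or `NULL` for automatic.
#' @return The advanced field matrix (non-negative).
#' @export
step_fields <- function(field, diffusion, decay, secretion = NULL,
                        substeps = NULL) {
  if (diffusion < 0 || decay < 0) stop("diffusion and decay must be >= 0")
  # auto choice keeps D*dt <= 0.2; the hard bound below is the 1/4 limit
  if (is.null(substeps)) substeps <- max(1L, ceiling(diffusion / 0.2 - 1e-12))
  if (diffusion / substeps > 0.25 + 1e-12)
    stop("stability bound D/substeps <= 1/4 unsatisfiable with the configured substeps")
  if (is.null(secretion)) {
    secretion <- matrix(0, 0, 0)
  } else {
    if (any(secretion < 0)) stop("secretion map must be non-negative")
    if (!all(dim(secretion) == dim(field))) stop("secretion map shape mismatch")
  }
  cpp_diffuse_matrix(field, diffusion, decay, secretion, as.integer(substeps))
}

#' Per-pixel secretion maps implied by the current cell states
#'
#' Applies the secretion rules to the current lattice: M2 macrophages deposit
#' PDGF; M1 macrophages deposit MMP, as do macrophages touching ECM;
#' activated fibroblasts deposit CSF1 only while sharing surface with a
#' macrophage; myofibroblasts deposit PDGF plus (contact-gated) CSF1;
#' fibrogenic-phase senescent cells deposit PDGF; fibrolytic-phase and
#' pre-existing senescent cells deposit CSF1, inflammatory SASP and MMP.
#' Each per-cell rate is split uniformly over the cell's pixels, so cell size
#' does not multiply output.
#'
#' @param sim A `cpm_sim`.
#' @return Named list of four matrices (pdgf, csf1, mmp, inf), per-pixel
#'   amounts for one MCS.
#' @export
build_secretion_map <- function(sim) {
  census <- cpp_sweep_census(sim$ptr)
  rates <- secretion_rates(census, sim$flags, sim$params)
  grid <- lattice_matrix(sim)
  out <- lapply(field_names(), function(f) matrix(0, nrow(grid), ncol(grid)))
  names(out) <- field_names()
  if (!nrow(rates)) return(out)
  vol <- census$volume[match(rates$id, census$id)]
  idx_by_cell <- split(seq_along(grid), grid)
  for (r in seq_len(nrow(rates))) {
    px <- idx_by_cell[[as.character(rates$id[r])]]
    for (f in field_names()) {
      amt <- rates[[f]][r]
      if (amt > 0) out[[f]][px] <- out[[f]][px] + amt / vol[r]
    }
  }
  out
}

#' Field value at a centre of mass
#'
#' Nearest-pixel convention (round half up): the value of the pixel
#' containing the COM.
#'
#' @param field Numeric matrix.
#' @param com Length-2 coordinates (1-based).
#' @return Scalar concentration.
#' @export
field_at_com <- function(field, com) {
  px <- floor(com[1] + 0.5)
  py <- floor(com[2] + 0.5)
  if (px < 1 || px > nrow(field) || py < 1 || py > ncol(field))
    stop("COM out of bounds")
  field[px, py]
}

#' Total amount of a field
#' @param field Numeric matrix.
#' @return Sum over all pixels.
#' @export
total_field <- function(field) sum(field)
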