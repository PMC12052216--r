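# Simulation state: a reference object wrapping the C++ lattice engine plus
# the R-side behaviour bookkeeping (activation, polarisation, senescence
# clocks and mechanisms, event counters).
#
# A `cpm_sim` has reference semantics (like an external pointer or a
# data.table): engine calls mutate it in place.

#' Create a simulation from an explicit lattice
#'
#' Low-level constructor used by [build_initial_state()], the test fixtures
#' and anyone wanting full control of the initial configuration.
#'
#' @param grid Integer matrix of cell ids (0 = Medium). Every id in `1:n`
#'   must appear in `types`.
#' @param types Integer or character vector (length n) of cell types per id;
#'   see [cell_types()].
#' @param params Parameter list from [sim_params()].
#' @param seed Integer seed for the engine RNG and the rule RNG.
#' @param wound_mask Optional logical matrix marking the initial wound area
#'   (fixed for the whole run); defaults to all-`FALSE`.
#' @return A `cpm_sim` object.
#' @export
simulation_from_grid <- function(grid, types, params = default_params(),
                                 seed = 1L, wound_mask = NULL) {
  params <- validate_params(params)
  if (is.character(types)) types <- cell_types()[types]
  types <- as.integer(types)
  n <- length(types)
  if (n > 0 && max(grid) > n) stop("grid contains ids without a type entry")
  tv <- .type_param(params$cpm$target_volume)
  lv <- .type_param(params$cpm$lambda_volume)
  ts <- .type_param(params$cpm$target_surface)
  ls <- .type_param(params$cpm$lambda_surface)
  J <- build_contact_matrix(params)
  D <- vapply(field_names(), function(f) params$fields[[f]]$diffusion, 0)
  dec <- vapply(field_names(), function(f) params$fields[[f]]$decay, 0)
  ptr <- cpp_state_new(nrow(grid), ncol(grid), J, params$cpm$temperature, D, dec)
  cpp_set_seed(ptr, seed)
  if (n > 0) {
    cpp_load(ptr, grid, types, tv[types], lv[types], ts[types], ls[types])
  } else {
    cpp_load(ptr, grid, integer(0), numeric(0), numeric(0), numeric(0), numeric(0))
  }
  sim <- new.env(parent = emptyenv())
  sim$ptr <- ptr
  sim$params <- params
  sim$seed <- as.integer(seed)
  sim$mcs <- 0
  if (is.null(wound_mask)) wound_mask <- matrix(FALSE, nrow(grid), ncol(grid))
  sim$wound_mask <- wound_mask
  ct <- cell_types()
  non_ecm <- which(types != ct[["ECM"]])
  nne <- length(non_ecm)
  sim$flags <- data.frame(
    id = non_ecm,
    activated = rep(FALSE, nne),
    m1 = rep(FALSE, nne),
    sen_clock = ifelse(types[non_ecm] %in% ct[c("SenescentMyofibroblast",
                                               "InflammatorySenescent")], 0, NA_real_),
    sen_mech = ifelse(types[non_ecm] == ct[["InflammatorySenescent"]],
                      "preexisting",
                      ifelse(types[non_ecm] == ct[["SenescentMyofibroblast"]],
                             "primary", NA_character_)),
    frozen = rep(FALSE, nne),
    orig_tv = tv[types[non_ecm]])
  sim$counters <- list(primary = 0L, juxtacrine = 0L, paracrine = 0L,
                       preexisting = sum(types == ct[["InflammatorySenescent"]]),
                       cleared = 0L, divisions = 0L, apoptosis = 0L,
                       ecm_spawned = 0L, ecm_degraded = 0L,
                       fragments_culled = 0L)
  class(sim) <- "cpm_sim"
  .refresh_chemotaxis(sim)
  sim
}

#' @export
print.cpm_sim <- function(x, ...) {
  tab <- cell_table(x)
  cat("<cpm_sim> ", nrow(x$wound_mask), "x", ncol(x$wound_mask),
      " lattice, MCS ", x$mcs,
      " (day ", round(mcs_to_days(x$mcs, x$params), 2), ")\n", sep = "")
  if (nrow(tab)) print(table(tab$type_name)) else cat("  (no cells)\n")
  invisible(x)
}

#' Lattice cell-id grid
#' @param sim A `cpm_sim`.
#' @return Integer matrix (0 = Medium).
#' @export
lattice_matrix <- function(sim) cpp_grid(sim$ptr)

#' Per-cell table
#'
#' Geometry caches merged with the behaviour flags; one row per live cell
#' (including one-pixel ECM cells, which carry no behaviour flags).
#'
#' @param sim A `cpm_sim`.
#' @return data.frame with id, type code and name, volume, surface, centre
#'   of mass, target volume and behaviour columns.
#' @export
cell_table <- function(sim) {
  tab <- cpp_cells_table(sim$ptr)
  tab$type_name <- names(cell_types())[tab$type + 1L]
  fl <- sim$flags[match(tab$id, sim$flags$id),
                  c("activated", "m1", "sen_clock", "sen_mech", "frozen", "orig_tv")]
  cbind(tab, fl, row.names = NULL)
}

#' Centre of mass of one cell
#'
#' Cached sums; equals the arithmetic mean of the cell's pixel coordinates
#' (1-based lattice coordinates).
#'
#' @param sim A `cpm_sim`.
#' @param id Cell id.
#' @return Numeric length-2 vector (x, y).
#' @export
com <- function(sim, id) cpp_com(sim$ptr, id)

#' Contact surface with a cell type or Medium
#'
#' Number of Moore boundary pixel pairs between cell `id` and any cell of
#' the named type (or Medium).
#'
#' @param sim A `cpm_sim`.
#' @param id Cell id.
#' @param other Type name (one of `names(cell_types())`, including
#'   `"Medium"`).
#' @return Integer pair count.
#' @export
contact_surface <- function(sim, id, other) {
  tcode <- cell_types()[[match.arg(other, names(cell_types()))]]
  cpp_contact_surface(sim$ptr, id, tcode)
}

#' Fraction of a cell's surface facing Medium (Rs)
#'
#' The contact-inhibition ratio: boundary pairs shared with Medium divided by
#' total boundary pairs.
#'
#' @param sim A `cpm_sim`.
#' @param id Cell id.
#' @return Rs in \[0, 1\].
#' @export
medium_surface_ratio <- function(sim, id) {
  tab <- cpp_cells_table(sim$ptr)
  row <- which(tab$id == id)
  if (!length(row)) stop("unknown cell id ", id)
  s <- tab$surface[row]
  if (s == 0) stop("cell ", id, " has zero surface (degenerate)")
  cpp_contact_surface(sim$ptr, id, 0L) / s
}

#' Energy change of a candidate pixel copy
#'
#' The incremental effective-energy difference for copying the cell id at
#' `source` into the von-Neumann-neighbouring pixel `target`: contact +
#' volume-constraint + surface-constraint terms, plus the chemotaxis bias of
#' the extending cell (omitted when `chemotaxis = FALSE`).
#'
#' @param sim A `cpm_sim`.
#' @param source,target Length-2 integer pixel coordinates (1-based).
#' @param chemotaxis Include the chemotaxis term?
#' @return Scalar energy difference.
#' @export
delta_energy <- function(sim, source, target, chemotaxis = TRUE) {
  cpp_delta_energy(sim$ptr, source[1], source[2], target[1], target[2], chemotaxis)
}

#' One Metropolis pixel-copy attempt
#'
#' Picks a random target pixel and a random von Neumann neighbour as source;
#' accepts with probability 1 if the energy change is <= 0, else
#' `exp(-dH / T)`. Caches are updated incrementally on acceptance.
#'
#' @param sim A `cpm_sim`.
#' @return Logical: was the copy accepted? (Rejection is a normal outcome.)
#' @export
attempt_pixel_copy <- function(sim) cpp_attempt(sim$ptr)

#' Advance the lattice by whole Monte-Carlo steps
#'
#' One MCS is width x height pixel-copy attempts. With `fields = TRUE` each
#' MCS also deposits secretion and integrates the four chemical fields.
#' This advances only the CPM/PDE layer; scenario runs interleave it with
#' [behaviour_sweep()].
#'
#' @param sim A `cpm_sim`.
#' @param n Number of MCS.
#' @param fields Integrate chemical fields each step?
#' @return The simulation, invisibly.
#' @export
run_mcs <- function(sim, n = 1, fields = TRUE) {
  cpp_run_mcs(sim$ptr, as.integer(n), fields)
  sim$mcs <- sim$mcs + as.integer(n)
  invisible(sim)
}

# Push per-cell chemotaxis settings: fibroblasts/myofibroblasts follow PDGF
# (lambda strengthened while touching ECM), macrophages follow the
# inflammatory SASP field.
.refresh_chemotaxis <- function(sim, census = NULL) {
  p <- sim$params
  tab <- if (is.null(census)) cpp_sweep_census(sim$ptr) else census
  ct <- cell_types()
  fib <- tab$type %in% ct[c("Fibroblast", "Myofibroblast")]
  mac <- tab$type == ct[["Macrophage"]]
  ids <- c(tab$id[fib], tab$id[mac])
  if (!length(ids)) return(invisible(sim))
  fieldv <- c(rep(.field_index("pdgf"), sum(fib)), rep(.field_index("inf"), sum(mac)))
  lam <- c(rep(p$chemotaxis$lambda_pdgf, sum(fib)), rep(p$chemotaxis$lambda_inf, sum(mac)))
  lam_ecm <- c(rep(p$chemotaxis$lambda_pdgf_ecm, sum(fib)),
               rep(p$chemotaxis$lambda_inf, sum(mac)))
  on_ecm <- c(tab$c_ecm[fib] > 0, rep(FALSE, sum(mac)))
  cpp_set_chemotaxis(sim$ptr, ids, fieldv, lam, lam_ecm, on_ecm)
  invisible(sim)
}
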