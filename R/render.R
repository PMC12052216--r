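# Snapshot rendering and archiving.

#' Render a lattice snapshot to PNG
#'
#' Uses the standard palette: fibroblasts blue, myofibroblasts green,
#' macrophages brown, ECM yellow, senescent myofibroblasts pink,
#' pre-existing inflammatory senescent cells red, Medium white.
#'
#' @param grid Integer lattice (or a `cpm_sim`).
#' @param path Output PNG path.
#' @param types Integer type vector indexed by cell id (taken from the sim
#'   when a `cpm_sim` is given).
#' @return `path`, invisibly.
#' @export
render_snapshot <- function(grid, path, types = NULL) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is required for rendering")
  if (inherits(grid, "cpm_sim")) {
    tab <- cpp_cells_table(grid$ptr)
    types <- integer(max(tab$id, 1))
    types[tab$id] <- tab$type
    grid <- lattice_matrix(grid)
  }
  if (is.null(types)) stop("per-id types are required")
  pal <- grDevices::col2rgb(c(Medium = "white", Fibroblast = "#2c5aa0",
                              Myofibroblast = "#3aa655", Macrophage = "#8b5a2b",
                              SenescentMyofibroblast = "#f49ac2",
                              InflammatorySenescent = "#d62728",
                              ECM = "#e8c832")) / 255
  tcode <- matrix(0L, nrow(grid), ncol(grid))
  nz <- grid > 0
  tcode[nz] <- types[grid[nz]]
  img <- array(0, dim = c(ncol(grid), nrow(grid), 3))
  for (ch in 1:3)
    img[, , ch] <- t(matrix(pal[ch, tcode + 1L], nrow(grid), ncol(grid)))
  png::writePNG(img, path)
  invisible(path)
}

#' Write a snapshot archive
#'
#' Serialises the lattice, per-cell table and the four field matrices, with
#' a JSON sidecar recording the seed, MCS and a parameter digest.
#'
#' @param sim A `cpm_sim`.
#' @param dir Output directory (created if needed).
#' @param label Basename for the archive files.
#' @return The archive path, invisibly.
#' @export
write_snapshot <- function(sim, dir, label = sprintf("mcs_%d", sim$mcs)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  payload <- list(grid = lattice_matrix(sim),
                  cells = cell_table(sim),
                  fields = lapply(stats::setNames(field_names(), field_names()),
                                  function(f) field_matrix(sim, f)))
  path <- file.path(dir, paste0(label, ".rds"))
  saveRDS(payload, path, compress = "gzip")
  meta <- list(seed = sim$seed, mcs = sim$mcs,
               day = mcs_to_days(sim$mcs, sim$params),
               params_digest = sum(utils::object.size(sim$params)) +
                 length(unlist(sim$params)))
  jsonlite::write_json(meta, file.path(dir, paste0(label, ".json")),
                       auto_unbox = TRUE)
  invisible(path)
}
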