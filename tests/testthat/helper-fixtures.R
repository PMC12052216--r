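# Shared fixtures: tiny lattices built in code, plus independent brute-force
# oracles for the effective energy and the geometric caches. The oracles are
# deliberately written against the plain grid matrix, not the engine caches.

fixture_params <- function(...) {
  # small, fast default geometry for tests; energy parameters are baseline
  sim_params(init = list(width = 24, height = 24, wound_margin = 8,
                         n_macrophages = 1),
             ...)
}

# a sim with explicitly placed rectangular cells on an otherwise empty lattice
fixture_sim <- function(cells, width = 12, height = 12, params = NULL,
                        seed = 1) {
  if (is.null(params)) params <- fixture_params()
  g <- matrix(0L, width, height)
  types <- character(length(cells))
  for (i in seq_along(cells)) {
    c <- cells[[i]]
    g[c$x, c$y] <- i
    types[i] <- c$type
  }
  simulation_from_grid(g, types, params, seed = seed)
}

# Moore neighbourhood offsets (contact/surface convention)
.moore <- cbind(dx = c(1, -1, 0, 0, 1, 1, -1, -1),
                dy = c(0, 0, 1, -1, 1, -1, 1, -1))

# brute-force full-lattice effective energy: contact over all in-lattice
# Moore pairs + volume and surface constraints per cell
brute_energy <- function(grid, types, J, tv, lv, ts, ls) {
  W <- nrow(grid); H <- ncol(grid)
  tcode <- function(id) if (id == 0) 1L else types[id] + 1L
  contact <- 0
  surface <- numeric(length(tv))
  volume <- numeric(length(tv))
  for (x in seq_len(W)) for (y in seq_len(H)) {
    a <- grid[x, y]
    if (a > 0) volume[a] <- volume[a] + 1
    for (k in 1:8) {
      nx <- x + .moore[k, 1]; ny <- y + .moore[k, 2]
      if (nx < 1 || nx > W || ny < 1 || ny > H) next
      b <- grid[nx, ny]
      if (a != b) {
        contact <- contact + J[tcode(a), tcode(b)] / 2
        if (a > 0) surface[a] <- surface[a] + 1
      }
    }
  }
  # each unordered pair counted twice above, hence J/2
  vol_term <- sum(lv * (volume - tv)^2)
  surf_term <- sum(ls * (surface - ts)^2)
  contact + vol_term + surf_term
}

# all admissible copies (von Neumann neighbour pairs with different ids)
admissible_copies <- function(grid) {
  W <- nrow(grid); H <- ncol(grid)
  out <- NULL
  for (x in seq_len(W)) for (y in seq_len(H)) {
    for (k in 1:4) {
      nx <- x + .moore[k, 1]; ny <- y + .moore[k, 2]
      if (nx < 1 || nx > W || ny < 1 || ny > H) next
      if (grid[x, y] != grid[nx, ny])
        out <- rbind(out, c(sx = x, sy = y, tx = nx, ty = ny))
    }
  }
  out
}

# recompute volume / surface / COM for one id straight from the grid
recount_cell <- function(grid, id) {
  px <- which(grid == id, arr.ind = TRUE)
  surface <- 0
  W <- nrow(grid); H <- ncol(grid)
  for (r in seq_len(nrow(px))) {
    for (k in 1:8) {
      nx <- px[r, 1] + .moore[k, 1]; ny <- px[r, 2] + .moore[k, 2]
      if (nx < 1 || nx > W || ny < 1 || ny > H) next
      if (grid[nx, ny] != id) surface <- surface + 1
    }
  }
  list(volume = nrow(px), surface = surface, com = colMeans(px)[c(1, 2)])
}

energy_inputs <- function(sim) {
  p <- sim$params
  tab <- dermalCPM:::cpp_cells_table(sim$ptr)
  types <- integer(max(tab$id))
  types[tab$id] <- tab$type
  tv <- dermalCPM:::.type_param(p$cpm$target_volume)[pmax(types, 1)]
  lv <- dermalCPM:::.type_param(p$cpm$lambda_volume)[pmax(types, 1)]
  ts <- dermalCPM:::.type_param(p$cpm$target_surface)[pmax(types, 1)]
  ls <- dermalCPM:::.type_param(p$cpm$lambda_surface)[pmax(types, 1)]
  tv[tab$id] <- tab$target_volume   # behaviour sweeps may have changed it
  list(types = types, J = dermalCPM:::build_contact_matrix(p),
       tv = tv, lv = lv, ts = ts, ls = ls)
}
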