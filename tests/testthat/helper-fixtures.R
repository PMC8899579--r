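# Shared in-code fixtures: everything is generated at test time.

# a tiny hand-made MSI dataset: nx x ny full grid, given peak list
tiny_ds <- function(mz = c(300, 400, 500), nx = 4, ny = 3,
                    fill = function(n, p) matrix(runif(n * p, 1, 10), n, p),
                    pixel_size = c(50, 75)) {
  coords <- cbind(rep(seq_len(nx) - 1L, each = ny),
                  rep(seq_len(ny) - 1L, times = nx))
  msi_dataset(mz = mz, intensities = fill(nx * ny, length(mz)),
              coords = coords, nx = nx, ny = ny, pixel_size = pixel_size)
}

# a reduced-size generator configuration for fast unit tests
small_synth_config <- function(seed = 1, ...) {
  synth_config(grid_nx = 48, grid_ny = 48, n_tissue_regions = 12,
               cell_density_per_class = c(tumor = 400, connective = 300,
                                          necrosis = 40),
               seed = seed, ...)
}

# a cell table with explicit marker intensities; unspecified markers are 0.1
make_cells <- function(pattern_list) {
  mk <- msifuse:::panel_markers()
  n <- length(pattern_list)
  df <- data.frame(cell_id = seq_len(n), x_um = runif(n, 0, 1000),
                   y_um = runif(n, 0, 1000), area_um2 = rep(80, n))
  ints <- matrix(0.1, n, length(mk), dimnames = list(NULL, mk))
  for (i in seq_len(n)) {
    pos <- pattern_list[[i]]
    ints[i, pos] <- 10
  }
  cell_table(cbind(df, as.data.frame(ints)), markers = mk)
}

# independent re-statement of the six published gates, written as plain
# nested logic over positivity flags (the oracle for gating tests)
oracle_phenotype <- function(pos) {
  core <- pos[["CD45"]] && pos[["CD11b"]]
  f_or_68 <- pos[["F480"]] || pos[["CD68"]]
  labs <- character(0)
  if (core && f_or_68 && !pos[["CD11c"]] && !pos[["Ly6G"]]) labs <- c(labs, "macrophage")
  if (core && f_or_68 && pos[["MHCII"]]) labs <- c(labs, "M1_macrophage")
  if (core && f_or_68 && pos[["CD163"]] && pos[["CD206"]]) labs <- c(labs, "M2_macrophage")
  if (core && f_or_68 && pos[["Ly6G"]] && !pos[["CD11c"]]) labs <- c(labs, "immature_monocyte")
  if (core && f_or_68 && pos[["CD11c"]]) labs <- c(labs, "dendritic_cell")
  if (core && !pos[["F480"]] && !pos[["CD68"]] && pos[["Ly6G"]]) labs <- c(labs, "neutrophil")
  for (p in c("neutrophil", "dendritic_cell", "M2_macrophage",
              "M1_macrophage", "immature_monocyte", "macrophage")) {
    if (p %in% labs) return(p)
  }
  "none"
}

# exhaustive counting oracle for the strict majority-vote rule
oracle_vote <- function(ix, iy, cls, nx, ny) {
  labels <- matrix("unassigned", ny, nx)
  for (x in 0:(nx - 1)) for (y in 0:(ny - 1)) {
    here <- which(ix == x & iy == y)
    if (!length(here)) next
    for (cl in c("tumor", "connective", "necrosis")) {
      if (sum(cls[here] == cl) / length(here) > 0.5) labels[y + 1, x + 1] <- cl
    }
  }
  labels
}
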