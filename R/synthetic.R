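#' Canonical land-cover classes
#'
#' The fragmented urban mosaic the synthetic generator emulates: four
#' vegetated classes carrying carbon components, plus impervious surface and
#' water which carry none (nodata in the component rasters).
#'
#' @return Named character vector mapping class codes to class names.
#' @export
ugci_classes <- function() {
  c("1" = "forest", "2" = "park", "3" = "agricultural", "4" = "roadside",
    "5" = "impervious", "6" = "water")
}

#' Default per-class component means and standard deviations
#'
#' Class-level distributions used by [generate_components()]: rows are the
#' four vegetated classes, columns the four components (tC/ha, tC/ha,
#' tC/ha/yr, % silt+clay). Means are anchored to published zonal statistics
#' for a Korean metropolitan case (forest vegetation C ~86.6, roadside ~9.4
#' tC/ha; NEP forest 12.26, park 6.72, roadside 5.56 tC/ha/yr; silt+clay
#' means and sds per class), with the remaining cells set to field-typical
#' values.
#'
#' @return List with `mean` and `sd`, each a 4 x 4 matrix with class-name
#'   rows and component columns.
#' @export
default_class_components <- function() {
  comps <- ugci_components()
  classes <- c("forest", "park", "agricultural", "roadside")
  mean <- matrix(c(
    # vegetation_c, soil_c, net_uptake, soil_potential
    86.59, 48.0, 12.26, 33.15,   # forest
    35.00, 36.0,  6.72, 33.25,   # park
     5.00, 38.0,  4.00, 36.42,   # agricultural
     9.44, 28.0,  5.56, 31.85    # roadside
  ), nrow = 4, byrow = TRUE, dimnames = list(classes, comps))
  sd <- matrix(c(
    15.0, 6.0, 2.5, 3.58,
     8.0, 5.0, 1.5, 5.79,
     2.0, 5.0, 1.2, 4.93,
     3.0, 5.0, 1.5, 7.15
  ), nrow = 4, byrow = TRUE, dimnames = list(classes, comps))
  list(mean = mean, sd = sd)
}

#' Specify a synthetic landscape
#'
#' Bundles and validates everything the generator needs: grid dimensions and
#' cell size, target area fractions per class (any remainder is impervious),
#' per-class component means and sds, the multiplicative edge deficit, and
#' the RNG seed. The defaults emulate a fragmented mid-size city: a few
#' large forest tracts, scattered parks and agricultural land, thin roadside
#' vegetation, and an impervious matrix.
#'
#' @param nrow,ncol grid dimensions (default 200 x 200).
#' @param cell_size cell size in metres (default 30).
#' @param fractions named target area fractions for classes other than
#'   impervious; must sum to <= 1.
#' @param class_components list with `mean` and `sd` matrices as in
#'   [default_class_components()].
#' @param edge_deficit multiplicative factor applied to component values in
#'   edge cells, in (0, 1]; either a scalar (all components) or a length-4
#'   vector named by component. 1 disables the deficit.
#' @param n_seeds number of region-growing seed points (default 0.5% of
#'   cells, at least 24).
#' @param seed RNG seed (integer).
#' @return A validated `landscape_spec` list.
#' @export
landscape_spec <- function(nrow = 200, ncol = 200, cell_size = 30,
                           fractions = c(forest = 0.30, park = 0.10,
                                         agricultural = 0.15, roadside = 0.05,
                                         water = 0.05),
                           class_components = default_class_components(),
                           edge_deficit = 1,
                           n_seeds = max(24L, round(0.005 * nrow * ncol)),
                           seed = 1L) {
  if (nrow < 2 || ncol < 2) stop("landscape must be at least 2 x 2")
  if (any(fractions < 0)) stop("class fractions must be non-negative")
  if (sum(fractions) > 1 + 1e-9)
    stop(sprintf("class fractions sum to %.3f > 1", sum(fractions)))
  comps <- ugci_components()
  if (length(edge_deficit) == 1) {
    edge_deficit <- stats::setNames(rep(edge_deficit, 4), comps)
  } else {
    if (!all(comps %in% names(edge_deficit)))
      stop("per-component `edge_deficit` must be named by the four components")
    edge_deficit <- edge_deficit[comps]
  }
  if (any(edge_deficit <= 0 | edge_deficit > 1))
    stop("`edge_deficit` must lie in (0, 1]")
  stopifnot(is.list(class_components),
            all(c("mean", "sd") %in% names(class_components)),
            all(class_components$sd >= 0))
  structure(
    list(nrow = as.integer(nrow), ncol = as.integer(ncol),
         cell_size = cell_size, fractions = fractions,
         class_components = class_components, edge_deficit = edge_deficit,
         n_seeds = as.integer(n_seeds), seed = as.integer(seed)),
    class = "landscape_spec"
  )
}

# Largest-remainder apportionment of n_seeds among fractions (impervious
# takes the remainder); every class with fraction > 0 gets at least one seed.
apportion_seeds <- function(fractions, n_seeds) {
  f <- c(fractions, impervious = 1 - sum(fractions))
  f <- f[f > 0]
  quota <- f * n_seeds
  alloc <- floor(quota)
  alloc[alloc == 0] <- 1
  rem <- n_seeds - sum(alloc)
  if (rem > 0) {
    extra <- order(quota - floor(quota), decreasing = TRUE)
    alloc[extra[seq_len(rem)]] <- alloc[extra[seq_len(rem)]] + 1
  } else if (rem < 0) {
    shrink <- order(alloc, decreasing = TRUE)
    for (i in shrink) {
      if (rem == 0) break
      take <- min(alloc[i] - 1, -rem)
      alloc[i] <- alloc[i] - take
      rem <- rem + take
    }
  }
  alloc
}

#' Generate a synthetic land-cover mosaic
#'
#' Seeded-region mosaic: seed points are apportioned among classes by the
#' target fractions (largest remainder), scattered uniformly over the grid,
#' and every cell takes the class of its nearest seed (squared-integer
#' distances, ties to the lowest seed index), producing contiguous irregular
#' patches whose realized class fractions approximate the targets. Fully
#' deterministic under the spec's seed.
#'
#' @param spec a [landscape_spec()].
#' @return A categorical [grid_raster] of class codes (see [ugci_classes()]).
#' @export
generate_landcover <- function(spec) {
  stopifnot(inherits(spec, "landscape_spec"))
  set.seed(spec$seed)
  nr <- spec$nrow; nc <- spec$ncol
  ncell <- nr * nc
  alloc <- apportion_seeds(spec$fractions, spec$n_seeds)
  code_of <- stats::setNames(as.integer(names(ugci_classes())), ugci_classes())
  seed_codes <- sample(rep(unname(code_of[names(alloc)]), alloc))
  n_seeds <- length(seed_codes)
  seed_cells <- sample.int(ncell, n_seeds)
  seed_row <- (seed_cells - 1L) %% nr + 1L
  seed_col <- (seed_cells - 1L) %/% nr + 1L
  out <- integer(ncell)
  # nearest seed per cell, chunked to bound memory; integer distances make
  # ties exact and the first-minimum rule deterministic
  chunk <- 4000L
  cell_row <- rep(seq_len(nr), times = nc)
  cell_col <- rep(seq_len(nc), each = nr)
  for (start in seq(1L, ncell, by = chunk)) {
    ix <- start:min(start + chunk - 1L, ncell)
    d2 <- outer(cell_row[ix], seed_row, "-")^2 + outer(cell_col[ix], seed_col, "-")^2
    out[ix] <- seed_codes[max.col(-d2, ties.method = "first")]
  }
  grid_raster(matrix(out, nr, nc), cell_size = spec$cell_size,
              crs = "synthetic-local", categorical = TRUE)
}

#' Generate component rasters over a land-cover mosaic
#'
#' Draws per-cell component values from truncated Gaussians with the class
#' means and sds of the spec (truncation by clamping at 0, and at 100 for
#' the silt+clay percentage), multiplies edge-cell values by the spec's edge
#' deficit, and masks impervious and water cells as nodata. Edge cells are
#' found with the same 30 m centre-distance rule used by [detect_edges()].
#'
#' @param landcover categorical [grid_raster] from [generate_landcover()].
#' @param spec the [landscape_spec()] used to generate it.
#' @param seed RNG seed for the component noise; defaults to `spec$seed + 1`
#'   so land cover and components are independently reproducible.
#' @param edge_distance_m edge depth used for the deficit (default: one cell).
#' @return A `component_stack` (see [stack_components()]).
#' @export
generate_components <- function(landcover, spec, seed = spec$seed + 1L,
                                edge_distance_m = spec$cell_size) {
  stopifnot(inherits(spec, "landscape_spec"), is_grid_raster(landcover))
  set.seed(seed)
  cls <- landcover$values
  classes <- ugci_classes()
  veg_codes <- as.integer(names(classes)[classes %in% rownames(spec$class_components$mean)])
  edge <- edge_flags(cls, landcover$cell_size, edge_distance_m)
  comps <- ugci_components()
  rasters <- vector("list", length(comps))
  names(rasters) <- comps
  for (k in seq_along(comps)) {
    m <- matrix(NA_real_, nrow(cls), ncol(cls))
    for (code in veg_codes) {
      cname <- classes[[as.character(code)]]
      sel <- !is.na(cls) & cls == code
      nsel <- sum(sel)
      if (!nsel) next
      mu <- spec$class_components$mean[cname, comps[k]]
      sdv <- spec$class_components$sd[cname, comps[k]]
      m[sel] <- pmax(0, stats::rnorm(nsel, mu, sdv))
    }
    m[edge & !is.na(m)] <- m[edge & !is.na(m)] * spec$edge_deficit[comps[k]]
    if (comps[k] == "soil_potential") m <- pmin(m, 100)
    rasters[[k]] <- grid_raster(m, cell_size = landcover$cell_size,
                                xll = landcover$xll, yll = landcover$yll,
                                crs = landcover$crs, categorical = FALSE)
  }
  stack_components(rasters$vegetation_c, rasters$soil_c, rasters$net_uptake,
                   rasters$soil_potential)
}

#' Generate a synthetic tree inventory
#'
#' Reproducible per-tree records (species, DBH) for exercising the allometric
#' stock equation: species drawn from a categorical mix, DBH from a
#' log-normal (all positive).
#'
#' @param n_trees number of trees.
#' @param species_mix named probability vector over species.
#' @param dbh_meanlog,dbh_sdlog log-normal parameters of DBH in cm
#'   (defaults give a median of ~25 cm).
#' @param seed RNG seed.
#' @return Data frame with columns `species` and `dbh`.
#' @export
generate_tree_inventory <- function(n_trees,
                                    species_mix = c(ginkgo = 0.4, zelkova = 0.3,
                                                    cherry = 0.2, metasequoia = 0.1),
                                    dbh_meanlog = log(25), dbh_sdlog = 0.3,
                                    seed = 1L) {
  stopifnot(n_trees >= 0, all(species_mix > 0), dbh_sdlog >= 0)
  if (n_trees == 0)
    return(data.frame(species = character(0), dbh = numeric(0)))
  set.seed(seed)
  data.frame(
    species = sample(names(species_mix), n_trees, replace = TRUE,
                     prob = species_mix),
    dbh = stats::rlnorm(n_trees, dbh_meanlog, dbh_sdlog)
  )
}
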