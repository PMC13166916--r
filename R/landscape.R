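# Neighbourhood offsets for a given connectivity.
neighbor_offsets <- function(connectivity) {
  if (connectivity == 4) {
    cbind(di = c(-1L, 1L, 0L, 0L), dj = c(0L, 0L, -1L, 1L))
  } else if (connectivity == 8) {
    cbind(di = rep(-1:1, each = 3), dj = rep(-1:1, 3))[-5, , drop = FALSE]
  } else {
    stop("`connectivity` must be 4 or 8")
  }
}

# Shift a matrix by (di, dj), filling exposed cells with NA.
shift_matrix <- function(m, di, dj) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(m[0][NA], nr, nc)
  sr <- max(1, 1 - di):min(nr, nr - di)
  sc <- max(1, 1 - dj):min(nc, nc - dj)
  if (length(sr) > 0 && length(sc) > 0 && sr[1] <= sr[length(sr)] && sc[1] <= sc[length(sc)])
    out[sr, sc] <- m[sr + di, sc + dj]
  out
}

#' Label land-cover patches by connected components
#'
#' Identifies patches as connected components of same-class cells under 4- or
#' 8-connectivity (8 by default, the common raster-tooling default). Labels
#' are dense from 1 in reading (row-major) order of each patch's first cell,
#' so labeling is deterministic. Nodata cells belong to no patch.
#'
#' @param landcover categorical [grid_raster].
#' @param connectivity 4 (rook) or 8 (queen) neighbourhood.
#' @return A `patch_map`: list with the integer `labels` matrix, the source
#'   `landcover` raster, `connectivity`, and `patches`, a per-patch table of
#'   id, class code, cell count, and area (m2 and ha). Edge/adjacency slots
#'   are filled by [detect_edges()] and [classify_adjacency()].
#' @export
label_patches <- function(landcover, connectivity = 8) {
  stopifnot(is_grid_raster(landcover))
  if (!landcover$categorical) stop("label_patches() requires a categorical raster")
  cls <- landcover$values
  nr <- nrow(cls); nc <- ncol(cls)
  ncell <- nr * nc
  # cells numbered row-major so patch labels come out in reading order
  id <- matrix(seq_len(ncell), nr, nc, byrow = TRUE)
  offs <- neighbor_offsets(connectivity)
  # undirected edges suffice once per unordered pair: keep offsets pointing
  # "forward" in reading order
  offs <- offs[offs[, "di"] > 0 | (offs[, "di"] == 0 & offs[, "dj"] > 0), , drop = FALSE]
  edges <- vector("list", nrow(offs))
  for (k in seq_len(nrow(offs))) {
    sh <- shift_matrix(cls, offs[k, "di"], offs[k, "dj"])
    shid <- shift_matrix(id, offs[k, "di"], offs[k, "dj"])
    link <- !is.na(cls) & !is.na(sh) & cls == sh
    edges[[k]] <- cbind(id[link], shid[link])
  }
  edges <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = ncell, directed = FALSE)
  if (!is.null(edges) && nrow(edges))
    g <- igraph::add_edges(g, t(edges))
  memb <- igraph::components(g)$membership
  valid <- as.vector(t(!is.na(cls)))       # row-major validity
  membv <- memb[seq_len(ncell)]
  lab <- rep(NA_integer_, ncell)
  lab[valid] <- match(membv[valid], unique(membv[valid]))
  labels <- matrix(lab, nr, nc, byrow = TRUE)
  first <- !duplicated(lab[valid])
  patches <- data.frame(
    patch = lab[valid][first][order(lab[valid][first])],
    class = as.vector(t(cls))[valid][first][order(lab[valid][first])]
  )
  counts <- tabulate(lab[valid], nbins = nrow(patches))
  patches$n_cells <- counts
  patches$area_m2 <- counts * landcover$cell_size^2
  patches$area_ha <- patches$area_m2 / 1e4
  structure(
    list(labels = labels, landcover = landcover, connectivity = connectivity,
         patches = patches, edge = NULL, adjacency = NULL),
    class = "patch_map"
  )
}

#' @export
print.patch_map <- function(x, ...) {
  cat(sprintf("<patch_map> %d patches over %d classes (connectivity %d)%s\n",
              nrow(x$patches), length(unique(x$patches$class)), x$connectivity,
              if (is.null(x$edge)) "" else ", edges detected"))
  invisible(x)
}

# Logical matrix: cell centre within distance_m of a different-class or
# nodata cell centre (cells outside the raster count as nodata).
edge_flags <- function(cls, cell_size, distance_m) {
  nr <- nrow(cls); nc <- ncol(cls)
  r <- floor(distance_m / cell_size + 1e-9)
  edge <- matrix(FALSE, nr, nc)
  for (di in -r:r) for (dj in -r:r) {
    if (di == 0 && dj == 0) next
    if ((di^2 + dj^2) * cell_size^2 > distance_m^2 + 1e-6) next
    sh <- shift_matrix(cls, di, dj)
    edge <- edge | (!is.na(cls) & (is.na(sh) | sh != cls))
  }
  edge
}

#' Flag edge cells of every patch
#'
#' A cell is an edge cell when its centre lies within `distance_m` of the
#' centre of any cell of a different class or of nodata (cells beyond the
#' raster boundary count as nodata). At the native 30 m resolution and the
#' default 30 m edge distance this is exactly the outermost one-cell ring of
#' each patch; patch cells that are not edge are interior. Edge cells are
#' counted inside their own patch — the outside ring belongs to the
#' neighbouring class.
#'
#' @param patches a `patch_map` from [label_patches()].
#' @param distance_m edge depth in metres (default 30).
#' @return The `patch_map` with its `edge` logical matrix filled.
#' @export
detect_edges <- function(patches, distance_m = 30) {
  stopifnot(inherits(patches, "patch_map"))
  cs <- patches$landcover$cell_size
  if (distance_m < cs)
    warning(sprintf("edge distance %g m is below the cell size %g m: no cell centre can qualify",
                    distance_m, cs))
  patches$edge <- edge_flags(patches$landcover$values, cs, distance_m)
  patches$edge_distance_m <- distance_m
  patches
}

#' Classify edge cells by their out-of-class neighbourhood
#'
#' Labels each edge cell by what lies across the boundary: `impervious`
#' (touches impervious classes and no green ones), `green` (the converse),
#' `mixed` (both), or `other` (only nodata or unlisted classes, e.g. water).
#' Neighbourhood connectivity follows the patch map's.
#'
#' @param patches a `patch_map` with edges detected.
#' @param impervious_classes integer class codes counting as impervious
#'   (non-empty).
#' @param green_classes integer class codes counting as green/vegetated.
#' @return The `patch_map` with an `adjacency` character matrix filled
#'   (values only at edge cells).
#' @export
classify_adjacency <- function(patches, impervious_classes, green_classes) {
  stopifnot(inherits(patches, "patch_map"))
  if (is.null(patches$edge)) stop("run detect_edges() first")
  if (!length(impervious_classes)) stop("`impervious_classes` must be non-empty")
  cls <- patches$landcover$values
  offs <- neighbor_offsets(patches$connectivity)
  touches_imp <- matrix(FALSE, nrow(cls), ncol(cls))
  touches_green <- matrix(FALSE, nrow(cls), ncol(cls))
  for (k in seq_len(nrow(offs))) {
    sh <- shift_matrix(cls, offs[k, "di"], offs[k, "dj"])
    out_of_class <- !is.na(cls) & !is.na(sh) & sh != cls
    touches_imp <- touches_imp | (out_of_class & sh %in% impervious_classes)
    touches_green <- touches_green | (out_of_class & sh %in% green_classes)
  }
  adj <- matrix(NA_character_, nrow(cls), ncol(cls))
  e <- patches$edge
  adj[e & touches_imp & !touches_green] <- "impervious"
  adj[e & !touches_imp & touches_green] <- "green"
  adj[e & touches_imp & touches_green] <- "mixed"
  adj[e & !touches_imp & !touches_green] <- "other"
  patches$adjacency <- adj
  patches
}

#' Zonal statistics of a value raster over categorical zones
#'
#' Mean, sample standard deviation and cell count of the valid value cells
#' within each zone. Zones with no valid cells are omitted; single-cell zones
#' report sd 0 with `sd_defined = FALSE`.
#'
#' @param values continuous [grid_raster] (or numeric matrix).
#' @param zones categorical [grid_raster] (or integer matrix) of the same
#'   shape.
#' @return Data frame with columns `zone`, `mean`, `sd`, `n`, `sd_defined`.
#' @export
zonal_stats <- function(values, zones) {
  v <- if (is_grid_raster(values)) values$values else values
  z <- if (is_grid_raster(zones)) zones$values else zones
  if (!identical(dim(v), dim(z))) stop("`values` and `zones` shapes differ")
  ok <- !is.na(v) & !is.na(z)
  if (!any(ok))
    return(data.frame(zone = integer(0), mean = numeric(0), sd = numeric(0),
                      n = integer(0), sd_defined = logical(0)))
  zs <- sort(unique(z[ok]))
  out <- lapply(zs, function(zz) {
    x <- v[ok & z == zz]
    data.frame(zone = zz, mean = mean(x),
               sd = if (length(x) > 1) stats::sd(x) else 0,
               n = length(x), sd_defined = length(x) > 1)
  })
  do.call(rbind, out)
}

# Pull an aligned value matrix out of the accepted input types.
value_matrix <- function(values, patches) {
  v <- if (is_grid_raster(values)) values$values else values
  if (!identical(dim(v), dim(patches$labels)))
    stop("`values` does not match the patch map geometry")
  v
}

#' Compare edge and interior condition per land-cover class
#'
#' For each class, compares the value raster (typically the composite index,
#' or a raw component when the injected contrast is known) between the
#' class's edge cells and its interior cells: group means, the relative edge
#' deficit `100 * (interior - edge) / interior` (percent lower at the edge),
#' and a Welch two-sample t-test. Classes with fewer than 2 cells in either
#' group are skipped with a message.
#'
#' @param values continuous [grid_raster] or matrix aligned with `patches`.
#' @param patches a `patch_map` with edges detected.
#' @param classes class codes to compare (default: all classes with any valid
#'   value cells).
#' @param class_names optional named vector mapping codes to names.
#' @return Data frame with one row per compared class: `class`, `class_name`,
#'   `n_edge`, `n_interior`, `edge_mean`, `interior_mean`, `pct_lower`,
#'   `t`, `df`, `p_value`.
#' @export
compare_edge_interior <- function(values, patches, classes = NULL,
                                  class_names = NULL) {
  stopifnot(inherits(patches, "patch_map"))
  if (is.null(patches$edge)) stop("run detect_edges() first")
  v <- value_matrix(values, patches)
  cls <- patches$landcover$values
  ok <- !is.na(v) & !is.na(cls)
  if (is.null(classes)) classes <- sort(unique(cls[ok]))
  rows <- lapply(classes, function(cc) {
    edge_v <- v[ok & cls == cc & patches$edge]
    int_v <- v[ok & cls == cc & !patches$edge]
    if (length(edge_v) < 2 || length(int_v) < 2) {
      message(sprintf("class %s skipped: %d edge / %d interior valid cells",
                      cc, length(edge_v), length(int_v)))
      return(NULL)
    }
    tt <- stats::t.test(int_v, edge_v)   # Welch by default
    data.frame(
      class = cc,
      class_name = if (!is.null(class_names)) unname(class_names[as.character(cc)]) else NA_character_,
      n_edge = length(edge_v), n_interior = length(int_v),
      edge_mean = mean(edge_v), interior_mean = mean(int_v),
      pct_lower = 100 * (mean(int_v) - mean(edge_v)) / mean(int_v),
      t = unname(tt$statistic), df = unname(tt$parameter),
      p_value = tt$p.value
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(class = integer(0), class_name = character(0),
                      n_edge = integer(0), n_interior = integer(0),
                      edge_mean = numeric(0), interior_mean = numeric(0),
                      pct_lower = numeric(0), t = numeric(0), df = numeric(0),
                      p_value = numeric(0))
  out
}

#' Compare edge condition by adjacent cover type
#'
#' Among a class's edge cells, compares those adjacent to impervious surfaces
#' against those adjacent to green cover (Welch t-test), quantifying how
#' much harsher impervious-facing edges are.
#'
#' @inheritParams compare_edge_interior
#' @return Data frame with one row per compared class: group sizes and means,
#'   `pct_lower` (impervious-adjacent relative to green-adjacent), `t`, `df`,
#'   `p_value`.
#' @export
compare_adjacency <- function(values, patches, classes = NULL,
                              class_names = NULL) {
  stopifnot(inherits(patches, "patch_map"))
  if (is.null(patches$adjacency)) stop("run classify_adjacency() first")
  v <- value_matrix(values, patches)
  cls <- patches$landcover$values
  ok <- !is.na(v) & !is.na(cls)
  if (is.null(classes)) classes <- sort(unique(cls[ok]))
  rows <- lapply(classes, function(cc) {
    imp_v <- v[ok & cls == cc & !is.na(patches$adjacency) & patches$adjacency == "impervious"]
    grn_v <- v[ok & cls == cc & !is.na(patches$adjacency) & patches$adjacency == "green"]
    if (length(imp_v) < 2 || length(grn_v) < 2) {
      message(sprintf("class %s skipped: %d impervious-adjacent / %d green-adjacent cells",
                      cc, length(imp_v), length(grn_v)))
      return(NULL)
    }
    tt <- stats::t.test(grn_v, imp_v)
    data.frame(
      class = cc,
      class_name = if (!is.null(class_names)) unname(class_names[as.character(cc)]) else NA_character_,
      n_impervious = length(imp_v), n_green = length(grn_v),
      impervious_mean = mean(imp_v), green_mean = mean(grn_v),
      pct_lower = 100 * (mean(grn_v) - mean(imp_v)) / mean(grn_v),
      t = unname(tt$statistic), df = unname(tt$parameter),
      p_value = tt$p.value
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(class = integer(0), class_name = character(0),
                      n_impervious = integer(0), n_green = integer(0),
                      impervious_mean = numeric(0), green_mean = numeric(0),
                      pct_lower = numeric(0), t = numeric(0), df = numeric(0),
                      p_value = numeric(0))
  out
}

#' Correlate patch size with mean condition
#'
#' Pearson correlation between log patch area and the per-patch mean of the
#' value raster for one class (log base does not affect r). Requires at least
#' 3 patches of the class with valid values; a constant side yields an
#' undefined correlation, returned as NA with a warning.
#'
#' @param values continuous [grid_raster] or matrix aligned with `patches`.
#' @param patches a `patch_map`.
#' @param class class code to analyse.
#' @return List with `r`, `p_value`, `n_patches`, and the per-patch table.
#' @export
patch_size_correlation <- function(values, patches, class) {
  stopifnot(inherits(patches, "patch_map"))
  v <- value_matrix(values, patches)
  ptab <- patches$patches[patches$patches$class == class, , drop = FALSE]
  means <- vapply(ptab$patch, function(p) {
    x <- v[!is.na(v) & !is.na(patches$labels) & patches$labels == p]
    if (length(x)) mean(x) else NA_real_
  }, numeric(1))
  keep <- !is.na(means)
  ptab <- ptab[keep, , drop = FALSE]
  means <- means[keep]
  if (nrow(ptab) < 3)
    stop(sprintf("patch-size correlation needs >= 3 patches of class %s with values; found %d",
                 class, nrow(ptab)))
  la <- log(ptab$area_ha)
  if (stats::sd(la) == 0 || stats::sd(means) == 0) {
    warning("constant patch areas or values: correlation undefined")
    return(list(r = NA_real_, p_value = NA_real_, n_patches = nrow(ptab),
                patches = transform(ptab, mean_value = means)))
  }
  ct <- stats::cor.test(la, means, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n_patches = nrow(ptab),
       patches = transform(ptab, mean_value = means))
}
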