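#' Ternary coordinates of three component values
#'
#' Closes three normalized component values (a, b, c) to proportions on the
#' 2-simplex: \eqn{X = a/(a+b+c)}, \eqn{Y = b/(a+b+c)}, \eqn{Z = c/(a+b+c)}.
#' The coordinates are scale-invariant and sum to 1. A cell with
#' \eqn{a = b = c = 0} has no defined position — it is fully depleted in all
#' three components — and is returned as an `NA` row flagged in the
#' `undefined` column.
#'
#' @param a,b,c numeric vectors of normalized component values in \[0, 1\],
#'   recycled to a common length.
#' @return Data frame with columns `X`, `Y`, `Z`, `undefined`.
#' @export
ternary_coordinates <- function(a, b, c) {
  k <- max(length(a), length(b), length(c))
  a <- rep_len(a, k); b <- rep_len(b, k); c <- rep_len(c, k)
  if (any(c(a, b, c) < -1e-12 | c(a, b, c) > 1 + 1e-12, na.rm = TRUE))
    stop("ternary inputs must be normalized values in [0, 1]")
  s <- a + b + c
  undefined <- !is.na(s) & s == 0
  s[undefined | is.na(s)] <- NA
  data.frame(X = a / s, Y = b / s, Z = c / s, undefined = undefined)
}

#' Diagnose the limitation pattern of ternary positions
#'
#' Interprets each cell's position on the simplex of the three top-weight
#' components. A point near a vertex means that one component dominates and
#' the two opposite components are substantially weaker — those two are the
#' limited ones that management should target. A point near the centre means
#' all three components are uniformly (low) balanced — all are limited. The
#' numeric meaning of "near" is set by two tunable thresholds, as the source
#' framework leaves it qualitative.
#'
#' @param coords data frame from [ternary_coordinates()].
#' @param components character length-3: names of the components behind
#'   `X`, `Y`, `Z` (in that order).
#' @param vertex_threshold dominant-vertex cut-off on the maximum proportion
#'   (default 0.5): at or above it the cell is `vertex`-classed.
#' @param center_radius Euclidean distance from (1/3, 1/3, 1/3) in proportion
#'   space at or below which the cell is `center`-classed (default 0.15).
#' @return Data frame with columns `category` (`vertex`, `center`,
#'   `intermediate`, or `undefined`), `dominant` (component name or NA), and
#'   `limited` (canonical `+`-joined names of the limited components; `"all"`
#'   for centre and undefined cells; NA for intermediate ones).
#' @export
diagnose_limitation <- function(coords, components = ugci_components()[1:3],
                                vertex_threshold = 0.5, center_radius = 0.15) {
  stopifnot(is.data.frame(coords), all(c("X", "Y", "Z") %in% names(coords)),
            length(components) == 3)
  P <- as.matrix(coords[, c("X", "Y", "Z")])
  n <- nrow(P)
  category <- rep("intermediate", n)
  dominant <- rep(NA_character_, n)
  limited <- rep(NA_character_, n)
  undef <- if ("undefined" %in% names(coords)) coords$undefined else is.na(P[, 1])
  undef <- undef | is.na(P[, 1])
  maxp <- apply(P, 1, max)
  imax <- max.col(P, ties.method = "first")
  dist_center <- sqrt(rowSums((P - 1 / 3)^2))
  is_vertex <- !undef & maxp >= vertex_threshold
  is_center <- !undef & !is_vertex & dist_center <= center_radius
  category[is_vertex] <- "vertex"
  category[is_center] <- "center"
  category[undef] <- "undefined"
  dominant[is_vertex] <- components[imax[is_vertex]]
  limited[is_vertex] <- vapply(imax[is_vertex], function(i)
    paste(components[-i], collapse = "+"), character(1))
  limited[is_center | undef] <- "all"
  data.frame(category = category, dominant = dominant, limited = limited)
}

#' Default management-strategy table
#'
#' Reads the strategy lookup shipped with the package (or a user-localized
#' copy): one row per land-cover class and limitation pattern, mapping to a
#' management strategy text. The shipped table encodes the practice bundles
#' for forest edges (litter retention, shade-tolerant understory),
#' agricultural land (conservation agriculture: residue mulch, reduced
#' tillage, biochar/compost), urban parks (aeration, organic amendments,
#' multilayer planting) and roadside vegetation (multilayered drought-tolerant
#' plantings, decompaction, permeable surfaces). The table is data, not code:
#' practitioners can edit the CSV to localize wording.
#'
#' @param path CSV with columns `landcover`, `limited`, `strategy`; defaults
#'   to the packaged table.
#' @return Data frame with those three columns.
#' @export
ugci_strategies <- function(path = system.file("extdata", "strategies.csv",
                                               package = "ugci")) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("landcover", "limited", "strategy") %in% names(tab)))
  tab
}

#' Look up the management strategy for a diagnosed limitation
#'
#' Matches (land-cover class, limited components) against the strategy table.
#' Lookup falls back from the exact limitation pattern to the class's `all`
#' row and finally to its `any` row, so a partially filled table still
#' resolves every diagnosis.
#'
#' @param landcover_class class name (e.g. `"forest"`).
#' @param limited limitation key as produced by [diagnose_limitation()]
#'   (`"soil_c+net_uptake"`, `"all"`, ...), or NA for intermediate cells.
#' @param strategies strategy table, see [ugci_strategies()].
#' @return A one-row data frame (`landcover`, `limited`, `strategy`).
#' @export
recommend_strategy <- function(landcover_class, limited,
                               strategies = ugci_strategies()) {
  rows <- strategies[strategies$landcover == landcover_class, , drop = FALSE]
  if (nrow(rows) == 0)
    stop(sprintf("no management strategies configured for land-cover class '%s'",
                 landcover_class))
  for (key in c(if (!is.na(limited)) limited, "all", "any")) {
    hit <- rows[rows$limited == key, , drop = FALSE]
    if (nrow(hit)) return(hit[1, ])
  }
  data.frame(landcover = landcover_class, limited = limited,
             strategy = "no strategy configured")
}

#' Prescribe management for low-index grids
#'
#' The prescription step: restricted to cells classified `low` or
#' `extremely_low`, decomposes the index over the three highest-weight
#' components ([select_top_components()]), places each cell on the ternary
#' simplex, diagnoses its limitation pattern, and attaches the land-cover
#' specific strategy. Cells at `moderate` or `high` are excluded — they call
#' for conservation, not intervention.
#'
#' @param index an `index_result` aligned with `norm`'s valid cells.
#' @param norm the `normalized_matrix` (must be stack-derived so cells map to
#'   the grid).
#' @param w the `weight_vector`.
#' @param landcover categorical [grid_raster] aligned with the stack.
#' @param class_names named character vector mapping class codes to names,
#'   e.g. `c("1" = "forest", ...)`; see [ugci_classes()].
#' @param strategies strategy table, see [ugci_strategies()].
#' @param vertex_threshold,center_radius passed to [diagnose_limitation()].
#' @return Data frame with one row per low/extremely-low cell: `cell` (row-
#'   major index), `row`, `col`, `landcover`, `ugci`, `level`, the three
#'   component proportions, `category`, `limited`, `strategy`.
#' @export
prescribe <- function(index, norm, w, landcover,
                      class_names = ugci_classes(),
                      strategies = ugci_strategies(),
                      vertex_threshold = 0.5, center_radius = 0.15) {
  stopifnot(inherits(index, "index_result"), inherits(norm, "normalized_matrix"),
            inherits(w, "weight_vector"), is_grid_raster(landcover))
  if (is.null(norm$idx))
    stop("`norm` must be built from a component_stack to map cells to the grid")
  if (length(index$ugci) != nrow(norm$values))
    stop("`index` and `norm` cover different cell sets")
  top <- select_top_components(w, 3)
  low <- which(index$levels %in% c("extremely_low", "low"))
  cols <- c("cell", "row", "col", "landcover", "ugci", "level", "X", "Y", "Z",
            "category", "limited", "strategy")
  if (!length(low)) {
    out <- data.frame(cell = integer(0), row = integer(0), col = integer(0),
                      landcover = character(0), ugci = numeric(0),
                      level = character(0), X = numeric(0), Y = numeric(0),
                      Z = numeric(0), category = character(0),
                      limited = character(0), strategy = character(0))
    names(out) <- cols
    return(out)
  }
  dims <- norm$dims
  cell <- norm$idx[low]                      # row-major cell index
  rows <- (cell - 1L) %/% dims[2] + 1L
  colsix <- (cell - 1L) %% dims[2] + 1L
  lc_codes <- landcover$values[cbind(rows, colsix)]
  lc_names <- unname(class_names[as.character(lc_codes)])
  V <- norm$values[low, top, drop = FALSE]
  coords <- ternary_coordinates(V[, 1], V[, 2], V[, 3])
  diag <- diagnose_limitation(coords, components = top,
                              vertex_threshold = vertex_threshold,
                              center_radius = center_radius)
  strategy <- vapply(seq_along(low), function(i) {
    if (is.na(lc_names[i])) return(NA_character_)
    recommend_strategy(lc_names[i], diag$limited[i], strategies)$strategy
  }, character(1))
  out <- data.frame(
    cell = cell, row = rows, col = colsix, landcover = lc_names,
    ugci = index$ugci[low], level = as.character(index$levels[low]),
    X = coords$X, Y = coords$Y, Z = coords$Z,
    category = diag$category, limited = diag$limited, strategy = strategy
  )
  attr(out, "components") <- top
  out
}
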