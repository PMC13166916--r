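# Raised for malformed configuration: the CLI maps it to exit code 2.
config_error <- function(msg) {
  stop(structure(class = c("ugci_config_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Default run configuration
#'
#' The complete configuration the pipeline commands understand, with every
#' tunable at its default. User configs (YAML, see [read_config()]) override
#' these keys; unknown keys are rejected.
#'
#' @return Nested list of defaults.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    out_dir = "ugci_out",
    landscape = list(nrow = 200L, ncol = 200L, cell_size = 30,
                     fractions = c(forest = 0.30, park = 0.10,
                                   agricultural = 0.15, roadside = 0.05,
                                   water = 0.05),
                     edge_deficit = 1),
    inputs = NULL,               # named .asc paths; alternative to `landscape`
    impervious_classes = 5L,
    green_classes = 1:4,
    edge_distance_m = 30,
    quartiles = NULL,            # fixed (Q1, Q2, Q3) instead of estimating
    ternary = list(vertex_threshold = 0.5, center_radius = 0.15),
    strategies = NULL,           # path to a localized strategy CSV
    figures = FALSE
  )
}

#' Read and validate a YAML run configuration
#'
#' Loads a YAML file, overlays it on [default_config()], and validates the
#' result: exactly one input source (a synthetic landscape spec or a set of
#' raster paths), known keys only, fractions summing to at most 1, and
#' referenced files existing.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @param overrides named list applied after the file (CLI flags).
#' @return Validated configuration list.
#' @export
read_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  user <- if (!is.null(path)) {
    if (!file.exists(path)) config_error(sprintf("config file not found: '%s'", path))
    yaml::read_yaml(path)
  } else list()
  merge_into <- function(base, new) {
    for (nm in names(new)) {
      if (is.list(base[[nm]]) && is.list(new[[nm]]) && !is.null(names(new[[nm]])))
        base[[nm]] <- merge_into(base[[nm]], new[[nm]])
      else base[[nm]] <- new[[nm]]
    }
    base
  }
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    config_error(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  cfg <- merge_into(cfg, user)
  cfg <- merge_into(cfg, overrides)
  validate_config(cfg)
  cfg
}

#' @rdname read_config
#' @param cfg configuration list to validate in place.
#' @export
validate_config <- function(cfg) {
  if (!is.null(cfg$inputs)) {   # measured rasters take precedence over simulation
    need <- c("landcover", ugci_components())
    missing <- setdiff(need, names(cfg$inputs))
    if (length(missing))
      config_error(sprintf("`inputs` must name rasters: %s missing",
                           paste(missing, collapse = ", ")))
    for (nm in need) {
      if (!file.exists(cfg$inputs[[nm]]))
        config_error(sprintf("input raster '%s' not found: %s", nm, cfg$inputs[[nm]]))
    }
  }
  fr <- unlist(cfg$landscape$fractions)
  if (any(fr < 0) || sum(fr) > 1 + 1e-9)
    config_error(sprintf("landscape fractions must be >= 0 and sum to <= 1 (sum = %.3f)", sum(fr)))
  if (!is.null(cfg$quartiles) &&
      (length(cfg$quartiles) != 3 || any(diff(unlist(cfg$quartiles)) <= 0)))
    config_error("`quartiles` must be 3 strictly increasing thresholds")
  if (!length(cfg$impervious_classes))
    config_error("`impervious_classes` must be non-empty")
  if (!is.null(cfg$strategies) && !file.exists(cfg$strategies))
    config_error(sprintf("strategy table not found: %s", cfg$strategies))
  invisible(cfg)
}

cfg_spec <- function(cfg) {
  ls <- cfg$landscape
  landscape_spec(nrow = ls$nrow, ncol = ls$ncol, cell_size = ls$cell_size,
                 fractions = unlist(ls$fractions),
                 edge_deficit = if (length(ls$edge_deficit) > 1)
                   unlist(ls$edge_deficit) else ls$edge_deficit,
                 seed = cfg$seed)
}

component_paths <- function(out_dir) {
  stats::setNames(file.path(out_dir, paste0(ugci_components(), ".asc")),
                  ugci_components())
}

#' Simulate: write a synthetic landscape to disk
#'
#' Generates the land-cover mosaic and the four component rasters from the
#' config's landscape block and writes them as `.asc` grids into `out_dir`,
#' together with a small provenance record (`simulate_log.json`: package
#' version, seed, realized class fractions). Deterministic given config and
#' seed.
#'
#' @param cfg configuration list from [read_config()].
#' @return Invisibly, the list of written paths.
#' @export
run_simulate <- function(cfg) {
  validate_config(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  spec <- cfg_spec(cfg)
  lc <- generate_landcover(spec)
  stack <- generate_components(lc, spec, edge_distance_m = cfg$edge_distance_m)
  paths <- c(landcover = file.path(cfg$out_dir, "landcover.asc"),
             component_paths(cfg$out_dir))
  write_raster(lc, paths[["landcover"]])
  for (nm in ugci_components()) write_raster(stack$components[[nm]], paths[[nm]])
  realized <- table(factor(lc$values, levels = names(ugci_classes()),
                           labels = ugci_classes())) / length(lc$values)
  jsonlite::write_json(
    list(package_version = as.character(utils::packageVersion("ugci")),
         seed = cfg$seed, n_valid = stack$n,
         realized_fractions = as.list(round(unclass(realized), 4))),
    file.path(cfg$out_dir, "simulate_log.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}

load_stack <- function(cfg) {
  paths <- if (!is.null(cfg$inputs)) cfg$inputs
           else as.list(c(landcover = file.path(cfg$out_dir, "landcover.asc"),
                          component_paths(cfg$out_dir)))
  for (nm in c("landcover", ugci_components())) {
    if (!file.exists(paths[[nm]]))
      stop(sprintf("required raster missing: %s (run the simulate step or set `inputs`)",
                   paths[[nm]]))
  }
  lc <- read_raster(paths[["landcover"]], categorical = TRUE)
  comps <- lapply(ugci_components(), function(nm) read_raster(paths[[nm]]))
  names(comps) <- ugci_components()
  list(landcover = lc,
       stack = stack_components(comps$vegetation_c, comps$soil_c,
                                comps$net_uptake, comps$soil_potential))
}

#' Diagnose: compute the index surface and management levels
#'
#' Runs normalization, entropy weighting, index aggregation and quartile
#' classification on the configured rasters, writing `ugci.asc` (index
#' surface), `levels.asc` (level codes 1-4), and `weights.json` (weights,
#' entropies, per-component min/max, thresholds, n).
#'
#' @param cfg configuration list.
#' @return Invisibly, a list with the in-memory `norm`, `weights`, `index`.
#' @export
run_diagnose <- function(cfg) {
  validate_config(cfg)
  inp <- load_stack(cfg)
  norm <- normalize_minmax(inp$stack)
  w <- entropy_weights(norm)
  vals <- compute_ugci(norm, w)
  index <- classify_quartiles(vals, thresholds = unlist(cfg$quartiles))
  write_raster(values_to_raster(vals, norm), file.path(cfg$out_dir, "ugci.asc"))
  write_raster(values_to_raster(as.integer(index$levels), norm, categorical = TRUE),
               file.path(cfg$out_dir, "levels.asc"))
  jsonlite::write_json(
    list(components = w$components,
         weights = as.list(round(w$weights, 10)),
         entropy = as.list(round(w$entropy, 10)),
         component_min = as.list(norm$min), component_max = as.list(norm$max),
         thresholds = round(index$thresholds, 10),
         n = nrow(norm$values),
         level_counts = as.list(unclass(index$counts))),
    file.path(cfg$out_dir, "weights.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  message(sprintf("diagnose: n = %d; weights = %s; thresholds = %s",
                  nrow(norm$values),
                  paste(sprintf("%s %.3f", w$components, w$weights), collapse = ", "),
                  paste(signif(index$thresholds, 3), collapse = "/")))
  invisible(list(norm = norm, weights = w, index = index,
                 landcover = inp$landcover))
}

#' Prescribe: diagnose limitations of low-index grids
#'
#' Recomputes the diagnosis (deterministic given the same inputs), restricts
#' to `low`/`extremely_low` cells, and writes `prescriptions.csv` with the
#' ternary coordinates, limitation category and management strategy per cell.
#' With `figures: true` (and ggplot2 installed) also writes one ternary
#' scatter per land-cover class.
#'
#' @param cfg configuration list.
#' @return Invisibly, the prescription data frame.
#' @export
run_prescribe <- function(cfg) {
  validate_config(cfg)
  wj <- file.path(cfg$out_dir, "weights.json")
  if (!file.exists(wj))
    stop(sprintf("diagnosis artifacts missing (%s): run the diagnose step first", wj))
  stored <- jsonlite::read_json(wj, simplifyVector = TRUE)
  d <- run_diagnose_quiet(cfg, thresholds = stored$thresholds)
  strategies <- if (!is.null(cfg$strategies)) ugci_strategies(cfg$strategies)
                else ugci_strategies()
  pres <- prescribe(d$index, d$norm, d$weights, d$landcover,
                    strategies = strategies,
                    vertex_threshold = cfg$ternary$vertex_threshold,
                    center_radius = cfg$ternary$center_radius)
  out_csv <- file.path(cfg$out_dir, "prescriptions.csv")
  utils::write.csv(format_numeric(pres), out_csv, row.names = FALSE)
  if (isTRUE(cfg$figures) && nrow(pres) > 0 &&
      requireNamespace("ggplot2", quietly = TRUE)) {
    for (lc in unique(stats::na.omit(pres$landcover))) {
      p <- plot_ternary(pres[!is.na(pres$landcover) & pres$landcover == lc, ],
                        components = attr(pres, "components"),
                        title = lc)
      ggplot2::ggsave(file.path(cfg$out_dir, sprintf("ternary_%s.png", lc)),
                      p, width = 5, height = 4.6, dpi = 150)
    }
  }
  invisible(pres)
}

# diagnose without re-writing artifacts (prescribe/edges reuse)
run_diagnose_quiet <- function(cfg, thresholds = NULL) {
  inp <- load_stack(cfg)
  norm <- normalize_minmax(inp$stack)
  w <- entropy_weights(norm)
  vals <- compute_ugci(norm, w)
  index <- classify_quartiles(vals, thresholds = thresholds)
  list(norm = norm, weights = w, index = index, landcover = inp$landcover)
}

# round-trip-stable CSV formatting: full precision, plain notation
format_numeric <- function(df) {
  for (nm in names(df)) {
    if (is.numeric(df[[nm]]) && !is.integer(df[[nm]]))
      df[[nm]] <- sprintf("%.12g", df[[nm]])
  }
  df
}

#' Edge analysis: edge-versus-interior and adjacency contrasts
#'
#' Labels patches on the land-cover raster, detects 30 m edges, classifies
#' edge adjacency, and writes `edge_comparison.csv` (per-class edge vs
#' interior index contrast with Welch t-tests), `adjacency_comparison.csv`
#' (impervious- vs green-adjacent edges), and `patch_correlation.csv`
#' (log patch area vs mean index for the park class, where patch fragmentation
#' is most pronounced).
#'
#' @param cfg configuration list.
#' @return Invisibly, a list of the three tables.
#' @export
run_edges <- function(cfg) {
  validate_config(cfg)
  ugci_path <- file.path(cfg$out_dir, "ugci.asc")
  if (!file.exists(ugci_path))
    stop(sprintf("diagnosis artifacts missing (%s): run the diagnose step first", ugci_path))
  ug <- read_raster(ugci_path)
  inp <- load_stack(cfg)
  classes <- ugci_classes()
  pm <- label_patches(inp$landcover)
  pm <- detect_edges(pm, distance_m = cfg$edge_distance_m)
  pm <- classify_adjacency(pm, impervious_classes = unlist(cfg$impervious_classes),
                           green_classes = unlist(cfg$green_classes))
  green <- intersect(unlist(cfg$green_classes), unique(pm$patches$class))
  cmp <- compare_edge_interior(ug, pm, classes = green, class_names = classes)
  adj <- compare_adjacency(ug, pm, classes = green, class_names = classes)
  utils::write.csv(format_numeric(cmp), file.path(cfg$out_dir, "edge_comparison.csv"),
                   row.names = FALSE)
  utils::write.csv(format_numeric(adj), file.path(cfg$out_dir, "adjacency_comparison.csv"),
                   row.names = FALSE)
  park_code <- as.integer(names(classes)[classes == "park"])
  corr <- tryCatch(patch_size_correlation(ug, pm, park_code),
                   error = function(e) {
                     message("patch-size correlation skipped: ", conditionMessage(e))
                     NULL
                   })
  if (!is.null(corr)) {
    utils::write.csv(format_numeric(
      data.frame(class = "park", r = corr$r, p_value = corr$p_value,
                 n_patches = corr$n_patches)),
      file.path(cfg$out_dir, "patch_correlation.csv"), row.names = FALSE)
  }
  invisible(list(edge = cmp, adjacency = adj, patch_correlation = corr))
}

#' Report: bundle run artifacts into a Markdown summary
#'
#' Collects the weights, thresholds, level counts, prescription summary and
#' edge tables written by the other steps into `report.md`.
#'
#' @param cfg configuration list.
#' @return Invisibly, the report path.
#' @export
run_report <- function(cfg) {
  validate_config(cfg)
  wj <- file.path(cfg$out_dir, "weights.json")
  if (!file.exists(wj)) stop("diagnosis artifacts missing: run diagnose first")
  w <- jsonlite::read_json(wj, simplifyVector = TRUE)
  lines <- c("# Urban green carbon condition report", "",
             sprintf("Grids analysed: %d", w$n), "",
             "## Component weights", "",
             "| component | entropy | weight |", "|---|---|---|",
             sprintf("| %s | %.4f | %.4f |", w$components,
                     unlist(w$entropy), unlist(w$weights)), "",
             sprintf("Quartile thresholds: %s",
                     paste(signif(unlist(w$thresholds), 4), collapse = " / ")), "",
             "## Management levels", "",
             "| level | grids |", "|---|---|",
             sprintf("| %s | %d |", names(w$level_counts), unlist(w$level_counts)))
  pres_path <- file.path(cfg$out_dir, "prescriptions.csv")
  if (file.exists(pres_path)) {
    pres <- utils::read.csv(pres_path)
    lines <- c(lines, "", "## Prescriptions", "",
               sprintf("%d low / extremely-low grids diagnosed.", nrow(pres)))
    if (nrow(pres)) {
      tab <- table(pres$landcover, pres$category)
      lines <- c(lines, "", "Limitation categories by land cover:", "",
                 utils::capture.output(print(tab)))
    }
  }
  edge_path <- file.path(cfg$out_dir, "edge_comparison.csv")
  if (file.exists(edge_path)) {
    cmp <- utils::read.csv(edge_path)
    lines <- c(lines, "", "## Edge effects", "",
               "| class | edge mean | interior mean | % lower at edge | p |",
               "|---|---|---|---|---|",
               sprintf("| %s | %.3f | %.3f | %.1f | %.2g |", cmp$class_name,
                       cmp$edge_mean, cmp$interior_mean, cmp$pct_lower,
                       cmp$p_value))
  }
  path <- file.path(cfg$out_dir, "report.md")
  writeLines(lines, path)
  invisible(path)
}
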