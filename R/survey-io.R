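# Data model, file IO and validation shared by all analysis stages.

#' Names of the environmental covariates used by the analyses
#'
#' The vocabulary covers seabed depth, a binary trawl-fishing flag, four
#' sediment variables (percent carbonate, sand, gravel and mud; the last
#' three sum to 100) and the annual mean and standard deviation of five
#' oceanographic variables.
#'
#' @return Character vector of covariate names.
#' @export
covariate_vocabulary <- function() {
  c("depth", "fished", "carbonate", "sand", "gravel", "mud",
    "temperature_mean", "temperature_sd",
    "salinity_mean", "salinity_sd",
    "oxygen_mean", "oxygen_sd",
    "nitrate_mean", "nitrate_sd",
    "phosphate_mean", "phosphate_sd")
}

#' Construct and validate a survey dataset
#'
#' Bundles the per-sample metadata, the sites-by-species count matrix and
#' the species table into a validated object used by all downstream
#' analyses.
#'
#' @param samples Data frame with columns `site_id`, `lon`, `lat`,
#'   `depth_m`, `area_swept_m2` and `fished` (0/1).
#' @param abundance Integer matrix, sites in rows (rownames = `site_id`),
#'   species in columns (colnames = `species_id`); non-negative counts.
#' @param species Optional data frame with columns `species_id` and
#'   `countable` (logical). Taxa that cannot be identified to individuals
#'   (e.g. colonial corals) carry `countable = FALSE` and are excluded
#'   from abundance-based summaries. Defaults to all countable.
#' @return An object of class `survey_dataset`.
#' @export
survey_dataset <- function(samples, abundance, species = NULL) {
  req <- c("site_id", "lon", "lat", "depth_m", "area_swept_m2", "fished")
  missing_cols <- setdiff(req, names(samples))
  if (length(missing_cols) > 0)
    stop("samples table is missing columns: ", paste(missing_cols, collapse = ", "))
  samples$site_id <- as.character(samples$site_id)
  if (anyDuplicated(samples$site_id))
    stop("duplicate site_id in samples table")
  if (any(samples$area_swept_m2 <= 0))
    stop("area_swept_m2 must be positive for every sample")
  abundance <- as.matrix(abundance)
  if (is.null(rownames(abundance)) || is.null(colnames(abundance)))
    stop("abundance matrix must carry site_id rownames and species_id colnames")
  if (!setequal(rownames(abundance), samples$site_id))
    stop("abundance rows do not match samples: unknown site_id ",
         paste(setdiff(rownames(abundance), samples$site_id), collapse = ", "))
  abundance <- abundance[samples$site_id, , drop = FALSE]
  if (any(abundance < 0) || any(abundance != round(abundance)))
    stop("abundance counts must be non-negative integers")
  storage.mode(abundance) <- "integer"
  if (is.null(species)) {
    species <- data.frame(species_id = colnames(abundance),
                          countable = TRUE, stringsAsFactors = FALSE)
  }
  species$species_id <- as.character(species$species_id)
  if (!setequal(species$species_id, colnames(abundance)))
    stop("species table does not match abundance columns")
  species <- species[match(colnames(abundance), species$species_id), , drop = FALSE]
  if (is.null(species$countable)) species$countable <- TRUE
  species$countable <- as.logical(species$countable)
  rownames(samples) <- NULL
  rownames(species) <- NULL
  structure(list(samples = samples, abundance = abundance, species = species),
            class = "survey_dataset")
}

#' @export
print.survey_dataset <- function(x, ...) {
  cat("survey_dataset:", nrow(x$samples), "samples x",
      ncol(x$abundance), "species\n")
  cat("  total individuals:", sum(x$abundance), "\n")
  occ <- colSums(x$abundance > 0)
  observed <- sum(occ > 0)
  cat("  species observed:", observed,
      sprintf("(singletons: %d, %.1f%%)", sum(occ == 1),
              if (observed > 0) 100 * sum(occ == 1) / observed else 0), "\n")
  invisible(x)
}

#' Read a survey dataset from CSV files
#'
#' The canonical on-disk form is a long abundance table (sparse-friendly
#' given the high singleton fraction of deep-sea samples); a wide
#' sites-by-species table is also accepted and detected from the header.
#' Absent (site, species) pairs are zeros.
#'
#' @param samples_path CSV with sample metadata (see [survey_dataset()]).
#' @param abundance_path CSV, either long (`site_id`, `species_id`,
#'   `count`, optional `countable_flag`) or wide (`site_id` + one column
#'   per species).
#' @param species_path Optional CSV with `species_id`, `countable`.
#' @return A `survey_dataset`.
#' @export
load_survey <- function(samples_path, abundance_path, species_path = NULL) {
  samples <- read.csv(samples_path, stringsAsFactors = FALSE)
  ab <- read.csv(abundance_path, stringsAsFactors = FALSE, check.names = FALSE)
  species <- if (!is.null(species_path))
    read.csv(species_path, stringsAsFactors = FALSE) else NULL
  long <- all(c("site_id", "species_id", "count") %in% names(ab))
  if (long) {
    ab$site_id <- as.character(ab$site_id)
    ab$species_id <- as.character(ab$species_id)
    unknown <- setdiff(unique(ab$site_id), as.character(samples$site_id))
    if (length(unknown) > 0)
      stop("abundance refers to unknown site_id: ", paste(unknown, collapse = ", "))
    if (anyDuplicated(ab[c("site_id", "species_id")]))
      stop("duplicate (site_id, species_id) rows in abundance file")
    if (any(ab$count < 0) || any(ab$count != round(ab$count)))
      stop("abundance counts must be non-negative integers")
    mat <- pivot_abundance(ab, as.character(samples$site_id))
    if (is.null(species) && "countable_flag" %in% names(ab)) {
      flags <- tapply(as.logical(ab$countable_flag), ab$species_id, unique)
      if (any(lengths(flags) != 1))
        stop("inconsistent countable_flag within a species")
      species <- data.frame(species_id = colnames(mat),
                            countable = unlist(flags)[colnames(mat)],
                            stringsAsFactors = FALSE)
    }
  } else {
    if (!"site_id" %in% names(ab))
      stop("wide abundance file must contain a site_id column")
    mat <- as.matrix(ab[setdiff(names(ab), "site_id")])
    rownames(mat) <- as.character(ab$site_id)
  }
  if (!is.null(species)) {
    # species listed but never caught are all-zero columns
    extra <- setdiff(colnames(mat), species$species_id)
    if (length(extra) > 0)
      stop("abundance refers to unknown species_id: ",
           paste(extra, collapse = ", "))
    miss <- setdiff(species$species_id, colnames(mat))
    if (length(miss) > 0)
      mat <- cbind(mat, matrix(0L, nrow(mat), length(miss),
                               dimnames = list(rownames(mat), miss)))
    mat <- mat[, species$species_id, drop = FALSE]
  }
  survey_dataset(samples, mat, species)
}

# long (site_id, species_id, count) -> sites x species integer matrix
pivot_abundance <- function(long, site_ids) {
  sp_ids <- sort(unique(long$species_id))
  mat <- matrix(0L, nrow = length(site_ids), ncol = length(sp_ids),
                dimnames = list(site_ids, sp_ids))
  mat[cbind(match(long$site_id, site_ids), match(long$species_id, sp_ids))] <-
    as.integer(long$count)
  mat
}

#' Write a survey dataset to CSV files
#'
#' Writes `samples.csv`, `abundance.csv` (long format, zero counts
#' dropped) and `species.csv` under `dir`.
#'
#' @param dataset A `survey_dataset`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_survey <- function(dataset, dir) {
  stopifnot(inherits(dataset, "survey_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("samples.csv", "abundance.csv", "species.csv"))
  write.csv(dataset$samples, paths[1], row.names = FALSE)
  idx <- which(dataset$abundance > 0, arr.ind = TRUE)
  countable <- dataset$species$countable[idx[, 2]]
  long <- data.frame(
    site_id = rownames(dataset$abundance)[idx[, 1]],
    species_id = colnames(dataset$abundance)[idx[, 2]],
    count = dataset$abundance[idx],
    countable_flag = countable,
    stringsAsFactors = FALSE)
  long <- long[order(long$site_id, long$species_id), ]
  write.csv(long, paths[2], row.names = FALSE)
  write.csv(dataset$species, paths[3], row.names = FALSE)
  invisible(paths)
}

#' Presence/absence matrix of a survey dataset
#'
#' @param x A `survey_dataset` or a count matrix.
#' @return Binary matrix of the same shape: 1 where count > 0.
#' @export
presence_absence <- function(x) {
  mat <- if (inherits(x, "survey_dataset")) x$abundance else as.matrix(x)
  out <- (mat > 0) * 1L
  dimnames(out) <- dimnames(mat)
  out
}

#' Construct an environmental grid
#'
#' A regular lon/lat grid of covariate layers used for spatial
#' prediction. Layer names must come from [covariate_vocabulary()].
#'
#' @param cells Data frame with `cell_id`, `lon`, `lat` and one numeric
#'   column per covariate layer.
#' @param cell_size Grid resolution in decimal degrees.
#' @return An object of class `environmental_grid`.
#' @export
environmental_grid <- function(cells, cell_size) {
  stopifnot(all(c("cell_id", "lon", "lat") %in% names(cells)))
  if (anyDuplicated(cells$cell_id)) stop("duplicate cell_ids in grid")
  layers <- setdiff(names(cells), c("cell_id", "lon", "lat"))
  unknown <- setdiff(layers, covariate_vocabulary())
  if (length(unknown) > 0)
    stop("unknown covariate name: ", paste(unknown, collapse = ", "))
  structure(list(cells = cells, layers = layers, cell_size = cell_size),
            class = "environmental_grid")
}

#' @export
print.environmental_grid <- function(x, ...) {
  cat("environmental_grid:", nrow(x$cells), "cells,",
      length(x$layers), "layers at", x$cell_size, "deg resolution\n")
  cat("  layers:", paste(x$layers, collapse = ", "), "\n")
  invisible(x)
}

#' Read / write an environmental grid as CSV
#'
#' @param path CSV path (`cell_id`, `lon`, `lat`, one column per layer).
#' @param cell_size Grid resolution in degrees; inferred from the lon
#'   spacing when omitted on read.
#' @return `load_grid` returns an `environmental_grid`.
#' @export
load_grid <- function(path, cell_size = NULL) {
  cells <- read.csv(path, stringsAsFactors = FALSE)
  if (is.null(cell_size)) {
    lons <- sort(unique(cells$lon))
    cell_size <- if (length(lons) > 1) min(diff(lons)) else 1
  }
  environmental_grid(cells, cell_size)
}

#' @rdname load_grid
#' @param grid An `environmental_grid`.
#' @export
write_grid <- function(grid, path) {
  stopifnot(inherits(grid, "environmental_grid"))
  write.csv(grid$cells, path, row.names = FALSE)
  invisible(path)
}

#' Attach grid covariates to survey samples
#'
#' Each site receives the covariates of the nearest grid-cell centre
#' (Euclidean distance in degrees; ties broken towards the lower
#' `cell_id`). The measured sample depth `depth_m` overrides the grid
#' depth layer, since the sled depth is observed directly.
#'
#' @param dataset A `survey_dataset`.
#' @param grid An `environmental_grid`.
#' @return Data frame of covariates, one row per site (rownames =
#'   `site_id`).
#' @export
attach_covariates <- function(dataset, grid) {
  stopifnot(inherits(dataset, "survey_dataset"),
            inherits(grid, "environmental_grid"))
  s <- dataset$samples
  g <- grid$cells
  half <- grid$cell_size / 2
  outside <- s$lon < min(g$lon) - half | s$lon > max(g$lon) + half |
    s$lat < min(g$lat) - half | s$lat > max(g$lat) + half
  if (any(outside))
    stop("site outside grid extent: ", paste(s$site_id[outside], collapse = ", "))
  ord <- order(g$cell_id)
  g <- g[ord, , drop = FALSE]
  nearest <- vapply(seq_len(nrow(s)), function(i) {
    d2 <- (g$lon - s$lon[i])^2 + (g$lat - s$lat[i])^2
    which(d2 <= min(d2) + 1e-15)[1]  # ties -> lower cell_id (g is sorted)
  }, integer(1))
  out <- g[nearest, grid$layers, drop = FALSE]
  if ("depth" %in% names(out)) out$depth <- s$depth_m
  rownames(out) <- s$site_id
  out
}

#' Extract the covariate frame of a grid
#'
#' @param grid An `environmental_grid`.
#' @param covariates Optional subset of layer names.
#' @return Data frame of layer values, rownames = `cell_id`.
#' @export
grid_covariates <- function(grid, covariates = NULL) {
  stopifnot(inherits(grid, "environmental_grid"))
  covariates <- if (is.null(covariates)) grid$layers else covariates
  missing_layers <- setdiff(covariates, grid$layers)
  if (length(missing_layers) > 0)
    stop("missing covariate layer: ", paste(missing_layers, collapse = ", "))
  out <- grid$cells[, covariates, drop = FALSE]
  rownames(out) <- grid$cells$cell_id
  out
}
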