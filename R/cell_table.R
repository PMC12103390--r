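# Data model for segmented mIHC cell tables.
#
# A tissue sample is one stained section: a cell table (one row per
# segmented cell, coordinates in micrometres, binary positivity per panel
# marker, optional raw intensities, a region label) plus the region
# geometry (tumor polygons, exclusion polygons, analyzable window, and the
# region areas used as density denominators).  Densities are reported per
# mm^2 (1 mm^2 = 1e6 um^2); coordinates have their origin at the window's
# lower-left corner.

#' Marker panel
#'
#' The six-plex panel: PANCK (pan-cytokeratin, epithelial tumor cells),
#' CD4, CD8 (T-cell subsets), LAG3 (inhibitory checkpoint), KI67
#' (proliferation) and IFNG (interferon-gamma).
#' @export
marker_panel <- function() c("PANCK", "CD4", "CD8", "LAG3", "KI67", "IFNG")

region_levels <- function() c("tumor", "stroma", "excluded")

timepoint_levels <- function() c("baseline", "on_treatment", "post_treatment")

UM2_PER_MM2 <- 1e6

#' Region geometry of a section
#'
#' @param window bounding rectangle `c(xmin, ymin, xmax, ymax)` in
#'   micrometres of the analyzable section.
#' @param tumor_polygons list of simple polygon rings (matrices with x, y
#'   columns, micrometres) delimiting cancer nests.
#' @param exclusion_polygons list of rings for regions removed from analysis
#'   (necrosis, normal epithelium).
#' @param tumor_area_mm2,stroma_area_mm2,exclusion_area_mm2 optional
#'   precomputed areas; when `NULL` they are derived from the polygons
#'   clipped to the window, with exclusion taking precedence over tumor and
#'   stroma defined as the remainder of the window.
#' @return an object of class `region_geometry`.
#' @export
region_geometry <- function(window,
                            tumor_polygons = list(),
                            exclusion_polygons = list(),
                            tumor_area_mm2 = NULL,
                            stroma_area_mm2 = NULL,
                            exclusion_area_mm2 = NULL) {
  window <- as.numeric(window)
  if (length(window) != 4 || any(!is.finite(window)) ||
      window[3] <= window[1] || window[4] <= window[2]) {
    stop("window must be c(xmin, ymin, xmax, ymax) with positive extent")
  }
  tumor_polygons <- lapply(tumor_polygons, normalize_ring)
  exclusion_polygons <- lapply(exclusion_polygons, normalize_ring)
  win_area <- (window[3] - window[1]) * (window[4] - window[2]) / UM2_PER_MM2
  wr <- window_ring(window)
  if (is.null(exclusion_area_mm2)) {
    exclusion_area_mm2 <- union_area(exclusion_polygons, wr) / UM2_PER_MM2
  }
  if (is.null(tumor_area_mm2)) {
    # exclusion takes precedence: tumor area outside exclusions
    a_t <- union_area(tumor_polygons, wr) / UM2_PER_MM2
    if (length(exclusion_polygons) && length(tumor_polygons)) {
      a_te <- union_area(c(tumor_polygons, exclusion_polygons), wr) / UM2_PER_MM2
      a_t <- a_te - exclusion_area_mm2
    }
    tumor_area_mm2 <- a_t
  }
  if (is.null(stroma_area_mm2)) {
    stroma_area_mm2 <- win_area - tumor_area_mm2 - exclusion_area_mm2
  }
  if (tumor_area_mm2 + stroma_area_mm2 > win_area * (1 + 1e-9)) {
    stop("tumor + stroma area exceeds the window area")
  }
  structure(list(window = window,
                 tumor_polygons = tumor_polygons,
                 exclusion_polygons = exclusion_polygons,
                 window_area_mm2 = win_area,
                 tumor_area_mm2 = tumor_area_mm2,
                 stroma_area_mm2 = stroma_area_mm2,
                 exclusion_area_mm2 = exclusion_area_mm2),
            class = "region_geometry")
}

#' Construct and validate a tissue sample
#'
#' @param cells data frame with columns `cell_id`, `x_um`, `y_um`, one 0/1
#'   column per panel marker, optionally `<marker>_intensity` columns and a
#'   `region` column (`tumor`/`stroma`/`excluded`; defaults to `stroma`
#'   until segmentation assigns labels).
#' @param geometry a [region_geometry()]; when `NULL` a window snapped to
#'   the cell bounding box is used (all area counted as stroma).
#' @param patient_id,timepoint sample metadata; `timepoint` is one of
#'   `baseline`, `on_treatment`, `post_treatment`.
#' @param panel marker names expected in `cells`.
#' @return object of class `tissue_sample`.
#' @export
tissue_sample <- function(cells, geometry = NULL, patient_id = "P1",
                          timepoint = "baseline", panel = marker_panel()) {
  cells <- as.data.frame(cells, stringsAsFactors = FALSE)
  required <- c("cell_id", "x_um", "y_um", panel)
  missing_cols <- setdiff(required, names(cells))
  if (length(missing_cols)) {
    stop("cell table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  cells$cell_id <- as.character(cells$cell_id)
  if (anyDuplicated(cells$cell_id)) {
    stop("duplicate cell_id: ",
         paste(unique(cells$cell_id[duplicated(cells$cell_id)])[1:3], collapse = ", "))
  }
  for (col in c("x_um", "y_um")) {
    v <- suppressWarnings(as.numeric(cells[[col]]))
    bad <- !is.finite(v)
    if (any(bad)) {
      stop("non-finite ", col, " for cell_id: ",
           paste(utils::head(cells$cell_id[bad], 3), collapse = ", "))
    }
    cells[[col]] <- v
  }
  for (m in panel) {
    v <- suppressWarnings(as.numeric(cells[[m]]))
    if (any(!v %in% c(0, 1))) {
      stop("marker column ", m, " must be binary 0/1")
    }
    cells[[m]] <- as.integer(v)
  }
  int_cols <- grep("_intensity$", names(cells), value = TRUE)
  for (col in int_cols) {
    v <- suppressWarnings(as.numeric(cells[[col]]))
    if (any(!is.finite(v) | v < 0)) {
      stop("intensity column ", col, " must be finite and >= 0")
    }
    cells[[col]] <- v
  }
  if (is.null(cells$region)) {
    cells$region <- rep("stroma", nrow(cells))
  }
  cells$region <- as.character(cells$region)
  if (nrow(cells) && any(!cells$region %in% region_levels())) {
    stop("region must be one of ", paste(region_levels(), collapse = "/"))
  }
  if (is.null(geometry)) {
    if (nrow(cells)) {
      window <- c(0, 0,
                  max(cells$x_um, 1) * 1.000001,
                  max(cells$y_um, 1) * 1.000001)
      if (min(cells$x_um) < 0 || min(cells$y_um) < 0) {
        stop("coordinates must be >= 0 when no window is supplied")
      }
    } else {
      window <- c(0, 0, 1, 1)
    }
    geometry <- region_geometry(window)
  }
  if (!inherits(geometry, "region_geometry")) stop("geometry must be a region_geometry")
  w <- geometry$window
  if (nrow(cells)) {
    out <- cells$x_um < w[1] | cells$x_um > w[3] | cells$y_um < w[2] | cells$y_um > w[4]
    if (any(out)) {
      stop("cells outside the window: ",
           paste(utils::head(cells$cell_id[out], 3), collapse = ", "))
    }
  }
  timepoint <- match.arg(timepoint, timepoint_levels())
  structure(list(patient_id = as.character(patient_id),
                 timepoint = timepoint,
                 cells = cells,
                 geometry = geometry,
                 panel = panel),
            class = "tissue_sample")
}

#' @export
print.tissue_sample <- function(x, ...) {
  cat(sprintf("<tissue_sample> patient %s, %s: %d cells (%d tumor / %d stroma / %d excluded)\n",
              x$patient_id, x$timepoint, nrow(x$cells),
              sum(x$cells$region == "tumor"), sum(x$cells$region == "stroma"),
              sum(x$cells$region == "excluded")))
  g <- x$geometry
  cat(sprintf("  window %.0f x %.0f um; areas (mm^2): tumor %.4f, stroma %.4f, excluded %.4f\n",
              g$window[3] - g$window[1], g$window[4] - g$window[2],
              g$tumor_area_mm2, g$stroma_area_mm2, g$exclusion_area_mm2))
  invisible(x)
}

#' Read a cell table from CSV
#'
#' Expects a header with `cell_id`, `x_um`, `y_um`, one column per panel
#' marker (0/1 calls), and optionally `<marker>_intensity` columns and a
#' `region` column.
#'
#' @param path CSV file path.
#' @inheritParams tissue_sample
#' @param geometry optional [region_geometry()] for the section.
#' @return a validated [tissue_sample()].
#' @export
read_cell_table <- function(path, panel = marker_panel(), geometry = NULL,
                            patient_id = "P1", timepoint = "baseline") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(cell_id = "character"))
  required <- c("cell_id", "x_um", "y_um", panel)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("file ", path, " is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  tissue_sample(df, geometry = geometry, patient_id = patient_id,
                timepoint = timepoint, panel = panel)
}

#' Write a cell table to CSV
#'
#' Emits the dialect accepted by [read_cell_table()]; numeric coordinates
#' and intensities are written with 17 significant digits so that a
#' read-back reproduces them exactly.
#'
#' @param sample a [tissue_sample()].
#' @param path output CSV path.
#' @export
write_cell_table <- function(sample, path) {
  stopifnot(inherits(sample, "tissue_sample"))
  df <- sample$cells
  num_cols <- c("x_um", "y_um", grep("_intensity$", names(df), value = TRUE))
  for (col in num_cols) df[[col]] <- sprintf("%.17g", df[[col]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read polygon masks from GeoJSON
#'
#' Accepts Polygon / MultiPolygon geometries (bare, as Feature, or inside a
#' FeatureCollection), coordinates in micrometres.  Only outer rings are
#' used; each ring must be closed, have at least three distinct vertices
#' and be simple (non-self-intersecting).
#'
#' @param path GeoJSON file path.
#' @return list of polygon matrices (open rings).
#' @export
read_polygons <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  geoms <- collect_geometries(gj)
  rings <- list()
  for (g in geoms) {
    if (identical(g$type, "Polygon")) {
      rings <- c(rings, list(g$coordinates[[1]]))
    } else if (identical(g$type, "MultiPolygon")) {
      rings <- c(rings, lapply(g$coordinates, function(p) p[[1]]))
    } else {
      stop("unsupported geometry type: ", g$type)
    }
  }
  out <- vector("list", length(rings))
  for (i in seq_along(rings)) {
    m <- do.call(rbind, lapply(rings[[i]], function(v) c(v[[1]], v[[2]])))
    ring <- tryCatch(normalize_ring(m),
                     error = function(e) stop("ring ", i, ": ", conditionMessage(e)))
    if (!is_simple_ring(ring)) stop("ring ", i, " is self-intersecting")
    out[[i]] <- ring
  }
  out
}

collect_geometries <- function(node) {
  if (is.null(node$type)) stop("not a GeoJSON document")
  switch(node$type,
         FeatureCollection = do.call(c, lapply(node$features, collect_geometries)),
         Feature = collect_geometries(node$geometry),
         GeometryCollection = do.call(c, lapply(node$geometries, collect_geometries)),
         list(node))
}

#' Write polygon masks to GeoJSON
#'
#' @param polygons list of polygon matrices (micrometre coordinates).
#' @param path output path.
#' @export
write_polygons <- function(polygons, path) {
  feats <- lapply(polygons, function(p) {
    p <- normalize_ring(p)
    ring <- rbind(p, p[1, , drop = FALSE])
    list(type = "Feature", properties = NULL,
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(i) as.list(ring[i, ])))))
  })
  doc <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a clinical table
#'
#' CSV with columns `patient_id`, `os_months` (overall survival, months,
#' >= 0, finite) and `event` (1 = death observed, 0 = censored); an
#' optional `timepoint` column is preserved.
#'
#' @param path CSV file path.
#' @return validated data frame of survival records.
#' @export
read_clinical <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(patient_id = "character"))
  validate_survival_records(df)
}

validate_survival_records <- function(df) {
  need <- c("patient_id", "os_months", "event")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("clinical table missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  df$patient_id <- as.character(df$patient_id)
  df$os_months <- as.numeric(df$os_months)
  if (any(!is.finite(df$os_months) | df$os_months < 0)) {
    stop("os_months must be finite and >= 0")
  }
  if (any(!df$event %in% c(0, 1))) stop("event must be 0 or 1")
  df$event <- as.integer(df$event)
  df
}
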