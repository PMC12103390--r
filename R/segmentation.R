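# Tumor/stroma region segmentation from the PANCK+ point pattern.
#
# The tumor region is rebuilt algorithmically from the cell table: PANCK+
# cells are grouped into cancer nests by single-linkage clustering at a
# maximum neighbor spacing, each sufficiently large nest becomes a convex
# hull dilated by a small boundary buffer, and every cell is relabeled by
# point-in-polygon.  Manual masks, when available, override this.

#' Segmentation parameters
#'
#' @param nest_link_distance maximum spacing (um) between PANCK+ cells of
#'   the same nest (single-linkage threshold).
#' @param min_nest_cells minimum PANCK+ cells for a group to count as a
#'   nest (>= 3).
#' @param boundary_buffer dilation (um) of the nest hull forming the tumor
#'   region.
#' @return object of class `segmentation_params`.
#' @export
segmentation_params <- function(nest_link_distance = 30,
                                min_nest_cells = 10,
                                boundary_buffer = 10) {
  if (nest_link_distance < 0 || boundary_buffer < 0) {
    stop("distances must be >= 0")
  }
  if (min_nest_cells < 3) stop("min_nest_cells must be >= 3")
  structure(list(nest_link_distance = nest_link_distance,
                 min_nest_cells = as.integer(min_nest_cells),
                 boundary_buffer = boundary_buffer),
            class = "segmentation_params")
}

# Single-linkage components at distance threshold d, via grid bucketing and
# union-find.  Returns integer component labels.
cluster_single_linkage <- function(x, y, d) {
  n <- length(x)
  if (n == 0) return(integer(0))
  if (d <= 0) return(seq_len(n))
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  gx <- floor((x - min(x)) / d)
  gy <- floor((y - min(y)) / d)
  key <- paste(gx, gy)
  buckets <- split(seq_len(n), key)
  bucket_of <- function(ix, iy) buckets[[paste(ix, iy)]]
  d2 <- d * d
  for (b in names(buckets)) {
    ids <- buckets[[b]]
    ij <- as.integer(strsplit(b, " ", fixed = TRUE)[[1]])
    neigh <- ids
    for (ddx in -1:1) for (ddy in -1:1) {
      if (ddx == 0 && ddy == 0) next
      nb <- bucket_of(ij[1] + ddx, ij[2] + ddy)
      if (!is.null(nb)) neigh <- c(neigh, nb)
    }
    for (i in ids) {
      close_idx <- neigh[(x[neigh] - x[i])^2 + (y[neigh] - y[i])^2 <= d2]
      for (j in close_idx) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' Segment tumor and stroma regions from PANCK+ cells
#'
#' Cells already labeled `excluded` keep their label; all other cells are
#' relabeled tumor/stroma.  With zero PANCK+ cells every non-excluded cell
#' becomes stroma and the tumor area is 0.  Rerunning with the same
#' parameters is idempotent because the labels are derived solely from the
#' (unchanged) PANCK calls.
#'
#' @param sample a [tissue_sample()] with PANCK calls.
#' @param params a [segmentation_params()].
#' @return the sample with updated region labels and geometry (tumor
#'   polygons, tumor/stroma areas).
#' @export
segment_regions <- function(sample, params = segmentation_params()) {
  stopifnot(inherits(sample, "tissue_sample"),
            inherits(params, "segmentation_params"))
  cells <- sample$cells
  usable <- cells$region != "excluded"
  panck <- which(usable & cells$PANCK == 1L)
  polys <- list()
  if (length(panck) >= params$min_nest_cells) {
    comp <- cluster_single_linkage(cells$x_um[panck], cells$y_um[panck],
                                   params$nest_link_distance)
    for (k in unique(comp)) {
      idx <- panck[comp == k]
      if (length(idx) < params$min_nest_cells) next
      polys <- c(polys, list(buffered_hull(cells$x_um[idx], cells$y_um[idx],
                                           params$boundary_buffer)))
    }
  }
  relabel_with_polygons(sample, polys, sample$geometry$exclusion_polygons,
                        clip_warn = FALSE)
}

#' Assign regions from manual polygon masks
#'
#' Exclusion takes precedence over tumor; remaining cells become stroma.
#' Polygons reaching outside the window are clipped (with a warning) and
#' the region areas are recomputed from the clipped geometry.
#'
#' @param sample a [tissue_sample()].
#' @param tumor_polygons,exclusion_polygons lists of polygon rings (um).
#' @return the relabeled sample.
#' @export
assign_regions_from_masks <- function(sample, tumor_polygons = list(),
                                      exclusion_polygons = list()) {
  stopifnot(inherits(sample, "tissue_sample"))
  relabel_with_polygons(sample, lapply(tumor_polygons, normalize_ring),
                        lapply(exclusion_polygons, normalize_ring),
                        clip_warn = TRUE, reset_excluded = TRUE)
}

relabel_with_polygons <- function(sample, tumor_polygons, exclusion_polygons,
                                  clip_warn = FALSE, reset_excluded = FALSE) {
  w <- sample$geometry$window
  wr <- window_ring(w)
  outside <- function(p) min(p[, 1]) < w[1] - 1e-9 || max(p[, 1]) > w[3] + 1e-9 ||
    min(p[, 2]) < w[2] - 1e-9 || max(p[, 2]) > w[4] + 1e-9
  clip_list <- function(polys) {
    if (clip_warn && any(vapply(polys, outside, logical(1)))) {
      warning("polygon extends outside the window; clipped")
    }
    Filter(Negate(is.null), lapply(polys, clip_to_convex, clip = wr))
  }
  tumor_polygons <- clip_list(tumor_polygons)
  exclusion_polygons <- clip_list(exclusion_polygons)

  cells <- sample$cells
  n <- nrow(cells)
  in_any <- function(polys) {
    hit <- logical(n)
    for (p in polys) {
      todo <- which(!hit)
      if (!length(todo)) break
      bb_ok <- cells$x_um[todo] >= min(p[, 1]) & cells$x_um[todo] <= max(p[, 1]) &
        cells$y_um[todo] >= min(p[, 2]) & cells$y_um[todo] <= max(p[, 2])
      cand <- todo[bb_ok]
      if (length(cand)) {
        hit[cand] <- points_in_polygon(cells$x_um[cand], cells$y_um[cand], p)
      }
    }
    hit
  }
  in_excl <- in_any(exclusion_polygons)
  in_tum <- in_any(tumor_polygons)
  region <- rep("stroma", n)
  region[in_tum] <- "tumor"
  region[in_excl] <- "excluded"
  if (!reset_excluded) region[cells$region == "excluded"] <- "excluded"
  cells$region <- region
  sample$cells <- cells
  sample$geometry <- region_geometry(window = w,
                                     tumor_polygons = tumor_polygons,
                                     exclusion_polygons = exclusion_polygons)
  sample
}
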