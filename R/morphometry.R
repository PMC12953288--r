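#' Classify a lipid droplet by cross-sectional area
#'
#' The three morphometric droplet categories: tiny (microvesicular droplets
#' below 1 um^2), small (vacuoles of 1 to under 100 um^2, not displacing the
#' nucleus) and large (vacuoles of at least 100 um^2, the macrovesicular
#' droplets pathologists grade). The lower bound of each band is inclusive:
#' exactly 1 um^2 is small, exactly 100 um^2 is large.
#'
#' @param area_um2 Numeric vector of droplet areas in square micrometres,
#'   strictly positive.
#' @return Factor with levels \code{tiny}, \code{small}, \code{large}.
#' @examples
#' classify_droplet_area(c(0.5, 1, 99.9, 100))
#' @export
classify_droplet_area <- function(area_um2) {
  if (!is.numeric(area_um2) || anyNA(area_um2)) {
    stop("'area_um2' must be numeric without NA")
  }
  if (any(area_um2 <= 0)) stop("droplet area must be positive")
  cls <- ifelse(area_um2 < 1, "tiny", ifelse(area_um2 < 100, "small", "large"))
  factor(cls, levels = c("tiny", "small", "large"))
}

as_gray_matrix <- function(image) {
  if (inherits(image, "ld_image")) image <- image$image
  if (length(dim(image)) == 3) {
    image <- apply(image[, , 1:3, drop = FALSE], c(1, 2), mean)
  }
  if (!is.matrix(image)) stop("image must be a 2-D raster")
  img <- image
  storage.mode(img) <- "double"
  if (max(img) > 1) img <- img / 255
  img
}

#' Segment tissue on a calibrated raster
#'
#' Delineates the tissue region by global intensity thresholding with the
#' between-class-variance (Otsu) criterion, fills enclosed holes (droplet
#' rims and lumina belong to tissue) and removes connected components smaller
#' than a minimum area.
#'
#' @param image 2-D grayscale raster (matrix; integer 0--255 or numeric in
#'   \[0, 1\]) or an \code{ld_image}.
#' @param min_tissue_area_px Minimum component size (pixels) kept as tissue.
#' @return Logical tissue mask.
#' @export
segment_tissue <- function(image, min_tissue_area_px = 64L) {
  img <- as_gray_matrix(image)
  if (stats::sd(img) < 1e-6) stop("no tissue detected: image is uniform")
  thr <- EBImage::otsu(EBImage::Image(img))
  mask <- img > thr
  if (!any(mask)) stop("no tissue detected above the intensity threshold")
  mask <- fill_enclosed(mask)
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(lab), nrow(img), ncol(img))
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_tissue_area_px)
  mask <- matrix(lab %in% keep, nrow(img), ncol(img))
  if (!any(mask)) stop("no tissue detected: all components below minimum area")
  mask
}

# fill any background region not reachable from the raster border; unlike a
# per-object hole fill this also closes ring-shaped holes (stain rims) that
# enclose further bright components (droplet lumina)
fill_enclosed <- function(mask) {
  bg <- EBImage::bwlabel(!mask)
  bg <- matrix(as.integer(bg), nrow(mask), ncol(mask))
  border <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  border <- border[border > 0L]
  !(matrix(bg %in% border, nrow(mask), ncol(mask)))
}

# 8-connected labelling: EBImage's 4-connected bwlabel plus a union-find
# merge of diagonally adjacent labels
label_components <- function(mask, connectivity = 8L) {
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  if (connectivity == 4L || max(lab) < 2L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  parent <- seq_len(max(lab))
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (sh in list(c(1L, 1L), c(1L, -1L))) {
    a <- lab[seq_len(nr - 1), if (sh[2] == 1L) seq_len(nc - 1) else 2:nc]
    b <- lab[2:nr, if (sh[2] == 1L) 2:nc else seq_len(nc - 1)]
    hit <- which(a > 0L & b > 0L & a != b)
    for (k in hit) {
      ra <- find(a[k]); rb <- find(b[k])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_along(parent), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0L] <- relab[lab[lab > 0L]]
  out
}

#' Segment lipid droplets within tissue
#'
#' The droplet-extraction operator chain: threshold bright lumina within the
#' tissue mask, label connected components (8-connected by default), fill
#' per-component holes, optionally split touching droplets by a
#' distance-transform watershed, then measure each component and keep those
#' passing the size and shape filters. Area is pixel count times the pixel
#' area; perimeter is the boundary-pixel-count estimator of EBImage's shape
#' features; circularity is \code{4*pi*area/perimeter^2} clipped at 1, and
#' components below \code{circularity_min} are discarded as
#' non-ovoid/circular. Droplet ids follow deterministic raster-scan order
#' (top row first, then left to right).
#'
#' @param image Raster as in \code{\link{segment_tissue}}.
#' @param tissue_mask Logical tissue mask of the same dimensions.
#' @param pixel_size_um Pixel edge length in micrometres, positive.
#' @param intensity_threshold Lumen threshold on the \[0, 1\] intensity scale.
#' @param circularity_min Minimum circularity kept, in \[0, 1\].
#' @param min_area_px Minimum component size in pixels (default 2; at the
#'   default 0.25 um calibration this is 0.125 um^2, below the tiny-class
#'   ceiling, so tiny droplets remain countable).
#' @param watershed If \code{TRUE}, split touching droplets by a watershed on
#'   the distance transform.
#' @param connectivity 4 or 8 (default) connected-component connectivity.
#' @return A data.frame of segmented droplets: droplet_id, centroid_x,
#'   centroid_y, area_um2, perimeter_um, circularity, size_class.
#' @export
segment_droplets <- function(image, tissue_mask, pixel_size_um,
                             intensity_threshold = 0.75,
                             circularity_min = 0.6,
                             min_area_px = 2L,
                             watershed = FALSE,
                             connectivity = 8L) {
  img <- as_gray_matrix(image)
  if (!is.matrix(tissue_mask) || !all(dim(tissue_mask) == dim(img))) {
    stop("tissue_mask dimensions must match the image")
  }
  if (!any(tissue_mask)) stop("tissue mask is empty")
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0) {
    stop("pixel_size_um must be positive")
  }
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")

  empty <- data.frame(
    droplet_id = integer(), centroid_x = numeric(), centroid_y = numeric(),
    area_um2 = numeric(), perimeter_um = numeric(), circularity = numeric(),
    size_class = factor(character(), levels = c("tiny", "small", "large")),
    stringsAsFactors = FALSE
  )

  bright <- img >= intensity_threshold & tissue_mask
  if (!any(bright)) return(empty)

  lab <- label_components(bright, connectivity)
  lab <- EBImage::fillHull(lab)
  lab <- matrix(as.integer(lab), nrow(img), ncol(img))
  if (watershed) {
    filled <- lab > 0L
    dm <- EBImage::distmap(EBImage::Image(filled * 1))
    lab <- EBImage::watershed(dm)
    lab <- matrix(as.integer(lab), nrow(img), ncol(img))
  }
  if (max(lab) == 0L) return(empty)

  shp <- EBImage::computeFeatures.shape(lab)
  mom <- EBImage::computeFeatures.moment(lab)
  if (is.null(dim(shp))) { shp <- matrix(shp, nrow = 1, dimnames = list(NULL, names(shp))) }
  if (is.null(dim(mom))) { mom <- matrix(mom, nrow = 1, dimnames = list(NULL, names(mom))) }

  area_px <- shp[, "s.area"]
  perim_px <- pmax(shp[, "s.perimeter"], 1)
  circ <- pmin(1, 4 * pi * area_px / perim_px^2)
  keep <- which(area_px >= min_area_px & circ >= circularity_min)
  if (!length(keep)) return(empty)

  # raster-scan order: first pixel encountered scanning rows top-down
  nr <- nrow(lab); nc <- ncol(lab)
  idx <- which(lab > 0L)
  rows <- (idx - 1L) %% nr + 1L
  cols <- (idx - 1L) %/% nr + 1L
  scan_key <- (rows - 1) * nc + cols
  first_seen <- tapply(scan_key, lab[idx], min)
  keep <- keep[order(first_seen[as.character(keep)])]

  area_um2 <- area_px[keep] * pixel_size_um^2
  data.frame(
    droplet_id = seq_along(keep),
    centroid_x = unname(mom[keep, "m.cy"]),  # EBImage first dim = matrix row
    centroid_y = unname(mom[keep, "m.cx"]),
    area_um2 = unname(area_um2),
    perimeter_um = unname(perim_px[keep] * pixel_size_um),
    circularity = unname(circ[keep]),
    size_class = classify_droplet_area(unname(area_um2)),
    stringsAsFactors = FALSE
  )
}

#' Proportionate-area morphometry profile
#'
#' The digital-image-analysis steatosis metric: per-class lipid area as a
#' percentage of total tissue area, and total LD as the ratio of the sum of
#' tiny, small and large LD areas to the tissue area.
#'
#' @param droplets Data.frame from \code{\link{segment_droplets}} (needs
#'   \code{area_um2} and \code{size_class}).
#' @param tissue_area_um2 Total tissue area in square micrometres, positive.
#' @return A list of class \code{morphometry_profile}: tiny_pct, small_pct,
#'   large_pct, total_pct, tissue_area_um2, n_droplets_by_class.
#' @examples
#' d <- data.frame(area_um2 = 100, size_class = classify_droplet_area(100))
#' compute_profile(d, tissue_area_um2 = 1e4)$large_pct
#' @export
compute_profile <- function(droplets, tissue_area_um2) {
  if (!is.numeric(tissue_area_um2) || tissue_area_um2 <= 0) {
    stop("tissue_area_um2 must be positive")
  }
  lv <- c("tiny", "small", "large")
  if (nrow(droplets) > 0 && sum(droplets$area_um2) > tissue_area_um2) {
    stop("total droplet area exceeds tissue area: check pixel calibration")
  }
  cls <- factor(as.character(droplets$size_class), levels = lv)
  by_class <- vapply(lv, function(k) {
    sum(droplets$area_um2[cls == k])
  }, numeric(1))
  pct <- 100 * by_class / tissue_area_um2
  structure(list(
    tiny_pct = unname(pct["tiny"]),
    small_pct = unname(pct["small"]),
    large_pct = unname(pct["large"]),
    total_pct = unname(sum(pct)),
    tissue_area_um2 = tissue_area_um2,
    n_droplets_by_class = table(cls)
  ), class = "morphometry_profile")
}

#' @export
print.morphometry_profile <- function(x, ...) {
  cat("Morphometry profile (% of tissue area)\n")
  cat(sprintf("  tiny %.3f | small %.3f | large %.3f | total %.3f\n",
              x$tiny_pct, x$small_pct, x$large_pct, x$total_pct))
  cat(sprintf("  tissue area: %.0f um^2; droplets: %s\n", x$tissue_area_um2,
              paste(names(x$n_droplets_by_class), as.integer(x$n_droplets_by_class),
                    sep = "=", collapse = " ")))
  invisible(x)
}
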