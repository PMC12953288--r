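#' Specification for a synthetic adipophilin-style tissue image
#'
#' Describes a calibrated 2-D raster emulating a scanned
#' adipophilin-immunostained liver section: mid-intensity textured tissue on a
#' dark non-tissue background, with lipid-droplet lumina rendered as bright
#' ellipses carrying a one-pixel darker stain rim. Droplet areas are sampled
#' per size class (tiny < 1, small 1--100, large >= 100 square micrometres)
#' so that segmentation can be validated against exact ground truth.
#'
#' @param width_px,height_px Raster dimensions in pixels.
#' @param pixel_size_um Pixel edge length in micrometres. The default 0.25
#'   corresponds to a 40x scan, so a 1 um^2 droplet spans ~16 pixels and tiny
#'   droplets are resolvable objects.
#' @param n_tiny,n_small,n_large Number of droplets per size class.
#' @param area_dist_params Named list of \code{c(min, max)} area bounds (um^2)
#'   per class; areas are drawn log-uniformly within them. Bounds must respect
#'   the class limits and the 2-pixel minimum at the given calibration.
#' @param axis_ratio_range Range of the ellipse minor/major axis ratio,
#'   within (0, 1].
#' @param tissue_fraction Fraction of the raster covered by tissue, in (0, 1].
#' @param overlap_allowed If \code{FALSE} (default) droplets are placed with a
#'   guard margin so they never touch; placement failure after bounded
#'   rejection sampling is an error.
#' @param seed Integer seed; identical spec + seed give bit-identical rasters.
#' @return An object of class \code{image_spec}.
#' @seealso \code{\link{generate_image}}
#' @export
image_spec <- function(width_px = 512, height_px = 512,
                       pixel_size_um = 0.25,
                       n_tiny = 30, n_small = 10, n_large = 2,
                       area_dist_params = list(
                         tiny = c(0.2, 0.9),
                         small = c(2, 60),
                         large = c(120, 600)
                       ),
                       axis_ratio_range = c(0.7, 1),
                       tissue_fraction = 0.8,
                       overlap_allowed = FALSE,
                       seed = 1L) {
  spec <- list(
    width_px = as.integer(width_px), height_px = as.integer(height_px),
    pixel_size_um = pixel_size_um,
    n_tiny = as.integer(n_tiny), n_small = as.integer(n_small),
    n_large = as.integer(n_large),
    area_dist_params = area_dist_params,
    axis_ratio_range = axis_ratio_range,
    tissue_fraction = tissue_fraction,
    overlap_allowed = isTRUE(overlap_allowed),
    seed = as.integer(seed)
  )
  validate_image_spec(spec)
  structure(spec, class = "image_spec")
}

DROPLET_CLASS_BOUNDS <- list(tiny = c(0, 1), small = c(1, 100),
                             large = c(100, Inf))

validate_image_spec <- function(spec) {
  with(spec, {
    if (width_px < 8 || height_px < 8) stop("raster must be at least 8x8")
    if (pixel_size_um <= 0) stop("pixel_size_um must be positive")
    if (any(c(n_tiny, n_small, n_large) < 0)) stop("droplet counts must be >= 0")
    if (tissue_fraction <= 0 || tissue_fraction > 1) {
      stop("tissue_fraction must lie in (0, 1]")
    }
    if (length(axis_ratio_range) != 2 || axis_ratio_range[1] <= 0 ||
        axis_ratio_range[2] > 1 || diff(axis_ratio_range) < 0) {
      stop("axis_ratio_range must be an increasing pair within (0, 1]")
    }
    min_area <- 2 * pixel_size_um^2
    counts <- c(tiny = n_tiny, small = n_small, large = n_large)
    for (cls in names(counts)) {
      if (counts[[cls]] == 0) next
      b <- area_dist_params[[cls]]
      if (is.null(b) || length(b) != 2 || b[1] <= 0 || b[2] < b[1]) {
        stop("area_dist_params$", cls, " must be a positive c(min, max) pair")
      }
      lim <- DROPLET_CLASS_BOUNDS[[cls]]
      if (b[1] < lim[1] || b[2] > lim[2] || (cls != "large" && b[2] >= lim[2])) {
        stop("area_dist_params$", cls, " violates the ", cls, " class bounds")
      }
      if (b[1] < min_area) {
        stop("class '", cls, "': minimum area ", b[1],
             " um^2 is below the 2-pixel floor (", min_area,
             " um^2) at pixel_size_um = ", pixel_size_um)
      }
    }
  })
  invisible(spec)
}

# rasterize an ellipse of target pixel area at (cy, cx); returns pixel indices
rasterize_ellipse <- function(cy, cx, area_px, axis_ratio, theta, nrow_, ncol_) {
  a <- sqrt(area_px / (pi * axis_ratio))   # semi-major in px
  b <- axis_ratio * a
  r <- ceiling(a) + 1L
  rows <- max(1L, floor(cy - r)):min(nrow_, ceiling(cy + r))
  cols <- max(1L, floor(cx - r)):min(ncol_, ceiling(cx + r))
  dy <- rep(rows - cy, times = length(cols))
  dx <- rep(cols - cx, each = length(rows))
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  inside <- u^2 + v^2 <= 1
  cbind(row = rep(rows, times = length(cols))[inside],
        col = rep(cols, each = length(rows))[inside])
}

#' Generate a synthetic tissue image with droplet ground truth
#'
#' Renders an 8-bit grayscale raster: non-tissue background at low intensity,
#' tissue as a mid-intensity textured region covering \code{tissue_fraction}
#' of the raster, droplet lumina as bright ellipses with a one-pixel darker
#' stain rim. Each droplet's recorded ground-truth area is its rasterized
#' pixel count times the pixel area, and rendering is retried until that
#' realized area stays inside the intended size class.
#'
#' @param spec An \code{\link{image_spec}}.
#' @param max_attempts Rejection-sampling budget per droplet before a
#'   placement error is raised.
#' @return A list of class \code{ld_image} with elements \code{image}
#'   (integer matrix, 0--255, rows = y), \code{droplets} (data.frame:
#'   droplet_id, center_x, center_y, area_um2, axis_ratio, size_class),
#'   \code{tissue_mask} (logical matrix) and \code{spec}.
#' @examples
#' im <- generate_image(image_spec(n_tiny = 5, n_small = 2, n_large = 1, seed = 3))
#' table(im$droplets$size_class)
#' @export
generate_image <- function(spec = image_spec(), max_attempts = 200L) {
  if (!inherits(spec, "image_spec")) spec <- do.call(image_spec, spec)
  validate_image_spec(spec)
  set.seed(spec$seed)
  h <- spec$height_px; w <- spec$width_px
  px2 <- spec$pixel_size_um^2

  # tissue: centered rectangle with area ~ tissue_fraction * raster area
  th <- max(4L, round(h * sqrt(spec$tissue_fraction)))
  tw <- max(4L, round(w * sqrt(spec$tissue_fraction)))
  r0 <- floor((h - th) / 2) + 1L; r1 <- r0 + th - 1L
  c0 <- floor((w - tw) / 2) + 1L; c1 <- c0 + tw - 1L
  tissue_mask <- matrix(FALSE, h, w)
  tissue_mask[r0:r1, c0:c1] <- TRUE

  img <- matrix(30 + stats::rnorm(h * w, 0, 3), h, w)
  tex <- 120 + stats::rnorm(sum(tissue_mask), 0, 8)
  img[tissue_mask] <- tex

  occupied <- matrix(FALSE, h, w)   # droplets plus guard margin
  counts <- c(large = spec$n_large, small = spec$n_small, tiny = spec$n_tiny)
  gt <- list()
  did <- 0L
  for (cls in names(counts)) {       # place big ones first
    if (counts[[cls]] == 0) next
    bounds <- spec$area_dist_params[[cls]]
    lim <- DROPLET_CLASS_BOUNDS[[cls]]
    for (i in seq_len(counts[[cls]])) {
      placed <- FALSE
      for (att in seq_len(max_attempts)) {
        area_um2 <- exp(stats::runif(1, log(bounds[1]), log(bounds[2])))
        q <- stats::runif(1, spec$axis_ratio_range[1], spec$axis_ratio_range[2])
        theta <- stats::runif(1, 0, pi)
        a_px <- sqrt(area_um2 / px2 / (pi * q))
        pad <- ceiling(a_px) + 3
        if (r0 + pad > r1 - pad || c0 + pad > c1 - pad) next
        cy <- stats::runif(1, r0 + pad, r1 - pad)
        cx <- stats::runif(1, c0 + pad, c1 - pad)
        pix <- rasterize_ellipse(cy, cx, area_um2 / px2, q, theta, h, w)
        if (nrow(pix) < 2) {
          # sub-pixel ellipse: force the minimal 2-pixel droplet
          pr <- round(cy); pc <- round(cx)
          pix <- cbind(row = c(pr, pr), col = c(pc, pc + 1L))
        }
        realized <- nrow(pix) * px2
        if (realized < lim[1] || realized >= lim[2] || realized < 2 * px2) next
        idx <- (pix[, "col"] - 1L) * h + pix[, "row"]
        # guard zone: droplet dilated by 2 px must stay free of other droplets
        guard <- dilate_indices(idx, h, w, 2L)
        if (!spec$overlap_allowed && any(occupied[guard])) next
        occupied[guard] <- TRUE
        rim <- setdiff(dilate_indices(idx, h, w, 1L), idx)
        img[rim] <- 70 + stats::rnorm(length(rim), 0, 3)
        img[idx] <- 235 + stats::rnorm(length(idx), 0, 4)
        did <- did + 1L
        gt[[did]] <- data.frame(
          droplet_id = did,
          center_x = mean(pix[, "col"]), center_y = mean(pix[, "row"]),
          area_um2 = realized, axis_ratio = q, size_class = cls,
          stringsAsFactors = FALSE
        )
        placed <- TRUE
        break
      }
      if (!placed) {
        stop("could not place a ", cls, " droplet without overlap after ",
             max_attempts, " attempts")
      }
    }
  }
  droplets <- if (did > 0) do.call(rbind, gt) else data.frame(
    droplet_id = integer(), center_x = numeric(), center_y = numeric(),
    area_um2 = numeric(), axis_ratio = numeric(), size_class = character(),
    stringsAsFactors = FALSE
  )
  img <- matrix(as.integer(pmin(255, pmax(0, round(img)))), h, w)
  structure(list(image = img, droplets = droplets,
                 tissue_mask = tissue_mask, spec = spec),
            class = "ld_image")
}

# indices of the set dilated by a square structuring element of radius k
dilate_indices <- function(idx, nrow_, ncol_, k) {
  rows <- (idx - 1L) %% nrow_ + 1L
  cols <- (idx - 1L) %/% nrow_ + 1L
  off <- expand.grid(dr = -k:k, dc = -k:k)
  r <- rep(rows, each = nrow(off)) + off$dr
  c <- rep(cols, each = nrow(off)) + off$dc
  keep <- r >= 1 & r <= nrow_ & c >= 1 & c <= ncol_
  unique((c[keep] - 1L) * nrow_ + r[keep])
}

#' Write a synthetic image bundle to disk
#'
#' Writes the raster as a single-channel 8-bit PNG or TIFF, the ground-truth
#' droplet table as a sidecar CSV and a YAML metadata record carrying the
#' pixel calibration and seed.
#'
#' @param x An \code{ld_image} from \code{\link{generate_image}}.
#' @param path_prefix Output path without extension.
#' @param format "png" or "tiff".
#' @return Invisibly, the named vector of file paths written.
#' @export
write_image_bundle <- function(x, path_prefix, format = c("png", "tiff")) {
  stopifnot(inherits(x, "ld_image"))
  format <- match.arg(format)
  g <- x$image / 255
  img_path <- paste0(path_prefix, ".", if (format == "png") "png" else "tif")
  if (format == "png") png::writePNG(g, img_path)
  else tiff::writeTIFF(g, img_path, bits.per.sample = 8L)
  csv_path <- paste0(path_prefix, "_truth.csv")
  utils::write.csv(x$droplets, csv_path, row.names = FALSE)
  meta_path <- paste0(path_prefix, "_meta.yaml")
  yaml::write_yaml(list(pixel_size_um = x$spec$pixel_size_um,
                        seed = x$spec$seed,
                        width_px = x$spec$width_px,
                        height_px = x$spec$height_px), meta_path)
  invisible(c(image = img_path, truth = csv_path, meta = meta_path))
}

#' Read a raster image as an intensity matrix
#'
#' Reads a PNG or TIFF into a numeric matrix in \[0, 1\]; RGB images are
#' averaged to grayscale.
#'
#' @param path Image file path (.png, .tif/.tiff).
#' @return Numeric matrix, rows = y.
#' @export
read_raster <- function(path) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported raster format: .", ext)
  )
  if (length(dim(arr)) == 3) arr <- apply(arr[, , 1:3, drop = FALSE], c(1, 2), mean)
  arr
}
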