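validate_grid <- function(grid, what = "image") {
  if (!is.matrix(grid) || !is.numeric(grid)) {
    abort(sprintf("%s must be a numeric matrix", what))
  }
  if (nrow(grid) < 16 || ncol(grid) < 16) {
    abort(sprintf("%s must be at least 16x16 pixels", what))
  }
  if (any(!is.finite(grid))) abort(sprintf("%s has non-finite values", what))
  invisible(grid)
}

otsu_threshold <- function(grid) {
  r <- range(grid)
  if (diff(r) == 0) return(r[1])
  EBImage::otsu(EBImage::Image(grid), range = r, levels = 256)
}

disc_brush <- function(radius) {
  size <- 2 * radius + 1
  EBImage::makeBrush(size, shape = "disc")
}

# 8-connected components of a logical mask, via a pixel adjacency graph
label_components <- function(mask) {
  stopifnot(is.logical(mask) || all(mask %in% c(0, 1)))
  mask <- mask > 0
  nr <- nrow(mask); nc <- ncol(mask)
  fg <- which(mask)
  labels <- matrix(0L, nr, nc)
  if (length(fg) == 0) return(labels)
  row_i <- (fg - 1L) %% nr + 1L
  col_i <- (fg - 1L) %/% nr + 1L
  edges <- list()
  # neighbour offsets covering each unordered pair once: S, E, SE, NE
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- row_i + off[1]; c2 <- col_i + off[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    hit <- mask[nb]
    edges[[length(edges) + 1L]] <- cbind(fg[ok][hit], nb[hit])
  }
  em <- do.call(rbind, edges)
  ids <- match(seq_len(nr * nc), fg)    # pixel index -> vertex id
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (nrow(em) > 0) {
    g <- igraph::add_edges(g, rbind(ids[em[, 1]], ids[em[, 2]]))
  }
  comp <- igraph::components(g)$membership
  labels[fg] <- as.integer(comp)
  labels
}

#' Segment droplets in a fluorescence image
#'
#' Applies a lower-bound intensity threshold (Otsu-derived by default),
#' labels 8-connected components, discards components smaller than
#' `min_area`, and measures each droplet's area, equivalent diameter and
#' mean intensity. An image that is entirely background or entirely
#' foreground after thresholding yields zero droplets with a warning.
#'
#' @param grid Numeric intensity matrix (>= 16x16).
#' @param threshold `"otsu"` or a numeric lower-bound threshold; pixels
#'   with `grid >= threshold` are foreground.
#' @param min_area Minimum component area in px (default 4).
#' @param pixel_size Optional pixel size in um/px; adds `area_um2`.
#' @return A list of class `droplet_segmentation`: `labels` (integer
#'   matrix, 0 = background), `records` (tibble with `label`, `area`,
#'   `size`, `mean_intensity`, and `area_um2` if `pixel_size` given),
#'   `threshold`.
#' @export
segment_droplets <- function(grid, threshold = "otsu", min_area = 4,
                             pixel_size = NULL) {
  validate_grid(grid)
  thr <- if (identical(threshold, "otsu")) otsu_threshold(grid)
         else as.numeric(threshold)
  mask <- grid >= thr
  empty_records <- tibble(label = integer(), area = double(), size = double(),
                          mean_intensity = double())
  empty_result <- function() {
    structure(list(labels = matrix(0L, nrow(grid), ncol(grid)),
                   records = empty_records, threshold = thr),
              class = "droplet_segmentation")
  }
  if (all(mask) || !any(mask)) {
    warn("threshold left no droplet/background separation; zero droplets")
    return(empty_result())
  }
  if (identical(threshold, "otsu")) {
    # Otsu on a featureless (noise-only) frame splits the noise in half;
    # require real contrast: class means separated by > 3 pooled sds
    mu1 <- mean(grid[mask]); mu0 <- mean(grid[!mask])
    s_pool <- sqrt((sum((grid[mask] - mu1)^2) + sum((grid[!mask] - mu0)^2)) /
                     max(length(grid) - 2, 1))
    if (mu1 - mu0 <= 3 * s_pool) {
      warn("no droplet/background contrast above noise; zero droplets")
      return(empty_result())
    }
  }
  labels <- label_components(mask)
  areas <- tabulate(labels[labels > 0])
  keep <- which(areas >= min_area)
  if (length(keep) == 0) {
    warn("no component reached min_area; zero droplets")
    return(structure(list(labels = matrix(0L, nrow(grid), ncol(grid)),
                          records = empty_records, threshold = thr),
                     class = "droplet_segmentation"))
  }
  relabel <- integer(max(labels))
  relabel[keep] <- seq_along(keep)
  labels[labels > 0] <- relabel[labels[labels > 0]]
  mean_int <- as.numeric(tapply(grid[labels > 0], labels[labels > 0], mean))
  records <- tibble(label = seq_along(keep),
                    area = as.numeric(areas[keep]),
                    size = 2 * sqrt(areas[keep] / pi),
                    mean_intensity = mean_int)
  if (!is.null(pixel_size)) records$area_um2 <- records$area * pixel_size^2
  structure(list(labels = labels, records = records, threshold = thr),
            class = "droplet_segmentation")
}

#' Per-droplet enrichment scores
#'
#' Enrichment of each droplet is its mean intensity divided by the mean
#' background intensity, where the background excludes all droplets plus a
#' halo of `halo_px` pixels around them (so partial-volume pixels at
#' droplet rims do not inflate the background).
#'
#' @param grid Intensity matrix the labels were derived from (same shape).
#' @param labels Integer label matrix from [segment_droplets()] (or the
#'   `droplet_segmentation` object itself).
#' @param halo_px Halo width in px excluded from the background (default 2).
#' @return Tibble with `label`, `mean_inside`, `background_mean`,
#'   `enrichment`.
#' @export
enrichment_scores <- function(grid, labels, halo_px = 2) {
  if (inherits(labels, "droplet_segmentation")) labels <- labels$labels
  if (!all(dim(grid) == dim(labels))) abort("grid and labels shapes differ")
  fg <- labels > 0
  if (!any(fg)) {
    return(tibble(label = integer(), mean_inside = double(),
                  background_mean = double(), enrichment = double()))
  }
  # halo = every pixel within halo_px in either axis (Chebyshev), so the
  # whole rim ring including corners is excluded from the background
  dilated <- if (halo_px > 0) {
    EBImage::dilate(EBImage::Image(fg * 1),
                    EBImage::makeBrush(2 * halo_px + 1, shape = "box")) > 0
  } else fg
  bg <- !dilated
  if (!any(bg)) abort("no background pixels left after halo exclusion")
  bg_mean <- mean(grid[bg])
  ids <- sort(unique(labels[fg]))
  inside <- as.numeric(tapply(grid[fg], labels[fg], mean))
  tibble(label = ids, mean_inside = inside, background_mean = bg_mean,
         enrichment = inside / bg_mean)
}

#' Phase-diagram summary over conditions and time points
#'
#' Summarises per-droplet records into one cell per (condition, time):
#' mean droplet count per image and mean enrichment pooled over all
#' droplets in the cell. Supplying the full image inventory lets images
#' with zero droplets count toward the mean; otherwise only images that
#' produced droplets are known.
#'
#' @param droplets Tibble of per-droplet records with columns `condition`,
#'   `time`, `image` and `enrichment`.
#' @param images Optional tibble enumerating all images (`condition`,
#'   `time`, `image`), including droplet-free ones.
#' @return Tibble with `condition`, `time`, `n_images`, `mean_count`,
#'   `mean_enrichment` (`NA` for cells with no droplets).
#' @export
phase_diagram <- function(droplets, images = NULL) {
  droplets <- as_tibble(droplets)
  if (is.null(images)) {
    images <- dplyr::distinct(droplets, .data$condition, .data$time,
                              .data$image)
  }
  images <- as_tibble(images)
  per_image <- dplyr::summarise(
    dplyr::group_by(droplets, .data$condition, .data$time, .data$image),
    count = dplyr::n(), .groups = "drop")
  per_image <- dplyr::left_join(images, per_image,
                                by = c("condition", "time", "image"))
  per_image$count[is.na(per_image$count)] <- 0L
  counts <- dplyr::summarise(
    dplyr::group_by(per_image, .data$condition, .data$time),
    n_images = dplyr::n(), mean_count = mean(.data$count), .groups = "drop")
  enr <- dplyr::summarise(
    dplyr::group_by(droplets, .data$condition, .data$time),
    mean_enrichment = mean(.data$enrichment), .groups = "drop")
  dplyr::left_join(counts, enr, by = c("condition", "time"))
}

#' Speckle enhancement (white top-hat)
#'
#' Enhances bright features smaller than `feature_size` by subtracting a
#' grayscale morphological opening with a disc of that diameter (the
#' standard speckle-enhancement filter); flat background and broad
#' gradients are suppressed.
#'
#' @param grid Intensity matrix.
#' @param feature_size Disc diameter in px (default 20; >= 2). Even sizes
#'   are rounded up to the next odd brush size.
#' @return Matrix of enhanced intensities (nonnegative).
#' @export
enhance_speckles <- function(grid, feature_size = 20) {
  validate_grid(grid)
  if (feature_size < 2) abort("feature_size must be >= 2")
  size <- if (feature_size %% 2 == 0) feature_size + 1 else feature_size
  brush <- EBImage::makeBrush(size, shape = "disc")
  r <- range(grid)
  scaled <- if (diff(r) > 0) (grid - r[1]) / diff(r) else grid * 0
  th <- EBImage::whiteTopHat(EBImage::Image(scaled), brush)
  out <- as.matrix(EBImage::imageData(th)) * if (diff(r) > 0) diff(r) else 1
  out[out < 0] <- 0
  out
}

#' Mask of cytoplasmic foci
#'
#' Builds the mask used for stress-granule colocalization: foci are
#' speckle-enhanced and thresholded; nuclei are thresholded and shrunk
#' (eroded) by `shrink_px` pixels so peri-nuclear foci are not swallowed;
#' the shrunken nuclei are then inversely masked onto the foci, leaving
#' cytoplasmic foci only.
#'
#' @param foci_grid Fluorescence channel containing the foci.
#' @param nuclei_grid Nuclear (DAPI-like) channel, same shape.
#' @param shrink_px Nuclear erosion radius in px (default 5).
#' @param threshold `"otsu"` or numeric, applied to both the enhanced foci
#'   and the nuclei channel.
#' @param feature_size Speckle-enhancement feature size (default 20).
#' @return Logical matrix: cytoplasmic-foci pixels.
#' @export
cytoplasmic_foci_mask <- function(foci_grid, nuclei_grid, shrink_px = 5,
                                  threshold = "otsu", feature_size = 20) {
  if (!all(dim(foci_grid) == dim(nuclei_grid))) {
    abort("foci and nuclei channels must have the same shape")
  }
  enhanced <- enhance_speckles(foci_grid, feature_size)
  thr_f <- if (identical(threshold, "otsu")) otsu_threshold(enhanced)
           else as.numeric(threshold)
  foci <- enhanced >= thr_f & enhanced > 0
  thr_n <- if (identical(threshold, "otsu")) otsu_threshold(nuclei_grid)
           else as.numeric(threshold)
  # a featureless nuclear channel means no nuclei, not an all-nuclei frame
  nuclei <- if (diff(range(nuclei_grid)) == 0) {
    matrix(FALSE, nrow(nuclei_grid), ncol(nuclei_grid))
  } else {
    nuclei_grid >= thr_n
  }
  shrunk <- if (any(nuclei) && shrink_px > 0) {
    EBImage::erode(EBImage::Image(nuclei * 1), disc_brush(shrink_px)) > 0
  } else nuclei
  foci & !shrunk
}

#' Pearson colocalization of two channels within a mask
#'
#' Pearson correlation of the raw intensities of two channels over the
#' pixels of a mask (typically the union of the two channels' cytoplasmic
#' foci masks). Invariant under affine rescaling of either channel.
#'
#' @param grid_a,grid_b Intensity matrices, same shape.
#' @param mask Logical matrix with at least 10 `TRUE` pixels; both
#'   channels must have nonzero variance within it.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson_colocalization <- function(grid_a, grid_b, mask) {
  if (!all(dim(grid_a) == dim(grid_b)) || !all(dim(grid_a) == dim(mask))) {
    abort("grids and mask must share one shape")
  }
  sel <- mask > 0
  if (sum(sel) < 10) abort("mask must contain at least 10 pixels")
  a <- grid_a[sel]; b <- grid_b[sel]
  if (var(a) == 0 || var(b) == 0) {
    abort("zero intensity variance within the mask")
  }
  cor(a, b)
}

#' Cytoplasmic-foci colocalization pipeline for a two-channel cell image
#'
#' Convenience composition of [cytoplasmic_foci_mask()] for both channels
#' and [pearson_colocalization()] over the union of the two masks.
#'
#' @inheritParams cytoplasmic_foci_mask
#' @param grid_a,grid_b The two foci channels (e.g. FUS and TIAR).
#' @return List with `r`, `mask_a`, `mask_b`, `union_mask`.
#' @export
colocalize_cytoplasmic_foci <- function(grid_a, grid_b, nuclei_grid,
                                        shrink_px = 5, threshold = "otsu",
                                        feature_size = 20) {
  ma <- cytoplasmic_foci_mask(grid_a, nuclei_grid, shrink_px, threshold,
                              feature_size)
  mb <- cytoplasmic_foci_mask(grid_b, nuclei_grid, shrink_px, threshold,
                              feature_size)
  u <- ma | mb
  list(r = pearson_colocalization(grid_a, grid_b, u),
       mask_a = ma, mask_b = mb, union_mask = u)
}

#' Mean number of assemblies per image
#'
#' @param label_maps A list of integer label matrices (or
#'   `droplet_segmentation` objects); each image contributes its count of
#'   distinct nonzero labels.
#' @return Arithmetic mean count per image.
#' @export
count_assemblies <- function(label_maps) {
  if (length(label_maps) == 0) abort("need at least one image")
  counts <- vapply(label_maps, function(lm) {
    if (inherits(lm, "droplet_segmentation")) lm <- lm$labels
    length(unique(lm[lm > 0]))
  }, numeric(1))
  mean(counts)
}

#' @export
print.droplet_segmentation <- function(x, ...) {
  cat(sprintf("Droplet segmentation: %d droplets (threshold %.4g)\n",
              nrow(x$records), x$threshold))
  invisible(x)
}

#' @rdname segment_droplets
#' @param x,object A `droplet_segmentation` object.
#' @param ... Unused.
#' @method tidy droplet_segmentation
#' @export
tidy.droplet_segmentation <- function(x, ...) x$records

#' @rdname segment_droplets
#' @method autoplot droplet_segmentation
#' @export
autoplot.droplet_segmentation <- function(object, ...) {
  df <- tibble(row = as.vector(row(object$labels)),
               col = as.vector(col(object$labels)),
               label = as.vector(object$labels))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = factor(.data$label))) +
    ggplot2::geom_raster(show.legend = FALSE) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("%d droplets", nrow(object$records)))
}

#' Read a grayscale image as an intensity matrix
#'
#' @param path A `.tif`/`.tiff` or `.png` file; multi-channel images are
#'   averaged to grayscale.
#' @return Numeric matrix.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  arr <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    rlang::check_installed("tiff")
    tiff::readTIFF(path)
  } else if (grepl("\\.png$", path, ignore.case = TRUE)) {
    rlang::check_installed("png")
    png::readPNG(path)
  } else {
    abort("unsupported image format (use TIFF or PNG)")
  }
  if (length(dim(arr)) == 3) arr <- apply(arr, c(1, 2), mean)
  unclass(arr)
}

#' Write an intensity matrix as a 16-bit TIFF
#'
#' Intensities are rescaled to `[0, 1]` over the matrix range.
#'
#' @param grid Numeric matrix.
#' @param path Output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_image <- function(grid, path) {
  rlang::check_installed("tiff")
  r <- range(grid)
  scaled <- if (diff(r) > 0) (grid - r[1]) / diff(r) else grid * 0
  tiff::writeTIFF(scaled, path, bits.per.sample = 16)
  invisible(path)
}
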