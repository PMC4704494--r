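#' Render a synthetic two-channel well image
#'
#' Draws one DNA (nuclei) and one actin (cell body) channel for a well. Each
#' cell is an elliptical nucleus inside a larger, optionally elongated actin
#' body; cells are placed by rejection sampling so that cell bodies do not
#' overlap beyond the packing limit. Intensities live in [0, 1] as is usual
#' for floating-point microscopy containers; optional Gaussian speckle adds
#' texture.
#'
#' @param n_cells number of cells to place (0 gives background-only images).
#' @param image_size side length in pixels (square field), default 256.
#' @param nuclear_radius mean nuclear semi-major axis in pixels.
#' @param nuclear_radius_sd cell-to-cell spread of the nuclear radius.
#' @param nuclear_ecc nuclear eccentricity in [0, 1).
#' @param cell_scale actin body size as a multiple of the nuclear radius.
#' @param elongation cell-body axis ratio (1 = round, larger = elongated).
#' @param dna_level,actin_level,bg_level foreground/background intensities.
#' @param texture_sd speckle noise standard deviation (0 = flat).
#' @param max_tries rejection-sampling attempts before declaring the packing
#'   impossible.
#' @param tiles if > 1, the field is replicated into a \code{tiles x tiles}
#'   mosaic (acquisition-style tiling, used by the border-crop test).
#' @param seed integer seed.
#' @return list with matrices \code{dna} and \code{actin} (values in [0, 1]),
#'   \code{centers} (n x 2, x/y pixel coordinates), \code{nuclear_radii}, and
#'   the parameters used.
#' @export
gen_well_images <- function(n_cells, image_size = 256,
                            nuclear_radius = 6, nuclear_radius_sd = 0,
                            nuclear_ecc = 0, cell_scale = 2.2,
                            elongation = 1,
                            dna_level = 0.8, actin_level = 0.5,
                            bg_level = 0.05, texture_sd = 0,
                            max_tries = 2000, tiles = 1, seed = 1L) {
  stopifnot(n_cells >= 0, image_size >= 16, nuclear_radius > 0,
            cell_scale >= 1, elongation >= 1)
  set.seed(seed)
  cell_r <- nuclear_radius * cell_scale * sqrt(elongation)
  margin <- ceiling(cell_r) + 1
  if (n_cells > 0 && 2 * margin >= image_size)
    stop("cells do not fit: cell radius too large for image_size")

  centers <- matrix(numeric(0), 0, 2)
  tries <- 0
  while (nrow(centers) < n_cells) {
    if (tries >= max_tries)
      stop(sprintf("impossible packing: placed %d of %d cells after %d tries",
                   nrow(centers), n_cells, max_tries))
    p <- stats::runif(2, margin, image_size - margin)
    if (nrow(centers) == 0 ||
        min(sqrt(colSums((t(centers) - p)^2))) > 2 * cell_r) {
      centers <- rbind(centers, p)
    }
    tries <- tries + 1
  }

  dna <- matrix(bg_level, image_size, image_size)
  act <- matrix(bg_level, image_size, image_size)
  radii <- numeric(0)
  if (n_cells > 0) {
    radii <- pmax(1, stats::rnorm(n_cells, nuclear_radius, nuclear_radius_sd))
    X <- matrix(rep(seq_len(image_size), image_size), image_size)      # x index
    Y <- matrix(rep(seq_len(image_size), each = image_size), image_size)
    theta <- stats::runif(n_cells, 0, pi)
    b_ratio <- sqrt(1 - min(nuclear_ecc, 0.999)^2)
    for (i in seq_len(n_cells)) {
      dx <- X - centers[i, 1]; dy <- Y - centers[i, 2]
      u <- dx * cos(theta[i]) + dy * sin(theta[i])
      v <- -dx * sin(theta[i]) + dy * cos(theta[i])
      a_n <- radii[i]; b_n <- radii[i] * b_ratio
      dna[(u / a_n)^2 + (v / b_n)^2 <= 1] <- dna_level
      a_c <- radii[i] * cell_scale * sqrt(elongation)
      b_c <- radii[i] * cell_scale / sqrt(elongation)
      act[(u / a_c)^2 + (v / b_c)^2 <= 1] <- actin_level
    }
  }
  if (texture_sd > 0) {
    dna <- dna + matrix(stats::rnorm(length(dna), sd = texture_sd),
                        image_size)
    act <- act + matrix(stats::rnorm(length(act), sd = texture_sd),
                        image_size)
  }
  dna <- pmin(pmax(dna, 0), 1)
  act <- pmin(pmax(act, 0), 1)
  if (tiles > 1) {
    dna <- do.call(rbind, rep(list(do.call(cbind, rep(list(dna), tiles))), tiles))
    act <- do.call(rbind, rep(list(do.call(cbind, rep(list(act), tiles))), tiles))
  }
  colnames(centers) <- c("x", "y")
  list(dna = dna, actin = act, centers = centers, nuclear_radii = radii,
       params = list(n_cells = n_cells, image_size = image_size,
                     nuclear_radius = nuclear_radius, cell_scale = cell_scale,
                     elongation = elongation, tiles = tiles, seed = seed))
}

#' Write a two-channel well image as a multi-page 16-bit TIFF
#'
#' Page 1 is the DNA channel, page 2 the actin channel.
#' @param img list as returned by \code{\link{gen_well_images}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_well_tiff <- function(img, path) {
  stack <- EBImage::Image(
    array(c(img$dna, img$actin), dim = c(dim(img$dna), 2)))
  EBImage::writeImage(stack, path, type = "tiff", bits.per.sample = 16L)
  invisible(path)
}

#' Read a two-channel well TIFF written by \code{write_well_tiff}
#' @param path file path.
#' @return list with matrices \code{dna} and \code{actin}.
#' @export
read_well_tiff <- function(path) {
  x <- EBImage::imageData(EBImage::readImage(path))
  if (length(dim(x)) != 3 || dim(x)[3] < 2)
    stop("expected a multi-page two-channel TIFF")
  list(dna = x[, , 1], actin = x[, , 2])
}
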