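#' Larva shape specification
#'
#' A larva is rendered as a curved capsule: a quadratic Bezier centreline of
#' arc length `length`, thickened to `width`. The silhouette mimics an
#' elongated 1st/2nd-instar larva floated to the focal plane; in the
#' straight limit (`curvature = 0`) the mask is a stadium whose analytic
#' area `length * width + pi * width^2 / 4` serves as an exact oracle for
#' the renderer. The gut dye darkens the body, so larvae render darker than
#' the well background by the fraction `intensity_contrast`.
#'
#' @param length Centreline arc length in pixels; must exceed `width`.
#' @param width Body width in pixels; must be positive.
#' @param curvature Dimensionless bend: perpendicular offset of the Bezier
#'   control point as a fraction of `length`. 0 gives a straight capsule.
#' @param intensity_contrast Fractional darkening relative to the local
#'   background, in (0, 1).
#' @param position Optional centre `(row, col)` in image pixels.
#' @param orientation Orientation of the chord, radians.
#' @return A `larva_spec` list.
#' @export
larva_spec <- function(length, width, curvature = 0,
                       intensity_contrast = 0.45, position = NULL,
                       orientation = 0) {
  if (!is.numeric(length) || !is.numeric(width) ||
      length <= 0 || width <= 0 || length <= width)
    stop("invalid larva dimensions: need length > width > 0")
  stopifnot(intensity_contrast > 0, intensity_contrast < 1)
  structure(list(length = length, width = width, curvature = curvature,
                 intensity_contrast = intensity_contrast,
                 position = position, orientation = orientation),
            class = "larva_spec")
}

# Sampled Bezier centreline, rescaled so its arc length equals spec$length.
larva_centreline <- function(spec, n = 80L) {
  L <- spec$length
  u <- c(cos(spec$orientation), sin(spec$orientation))
  v <- c(-u[2], u[1])
  p0 <- -u * L / 2
  p2 <- u * L / 2
  p1 <- v * spec$curvature * L
  t <- seq(0, 1, length.out = n)
  pts <- outer((1 - t)^2, p0) + outer(2 * t * (1 - t), p1) + outer(t^2, p2)
  seg <- sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2)
  ctr <- colMeans(pts)
  sweep(pts, 2, ctr) * (L / sum(seg)) +
    matrix(ctr, n, 2, byrow = TRUE) * 0  # centred on the larva origin
}

#' Render a larva mask
#'
#' Rasterises a [larva_spec()] on a local pixel grid centred on the larva.
#' Each pixel is sampled on a 4 x 4 subpixel lattice; the binary mask keeps
#' pixels with coverage of at least one half, while the returned `area` is
#' the subpixel coverage sum — a discretisation-robust ground truth that
#' for a straight capsule agrees with the analytic stadium area
#' `length * width + pi * width^2 / 4` (by the tube formula the same
#' expression holds for any non-self-intersecting bend).
#'
#' @param spec A [larva_spec()].
#' @return A list with `mask` (logical matrix), `area` (subpixel coverage
#'   area), `mask_area` (binary pixel count), `ys`, `xs` (integer row/col
#'   offsets of the mask grid from the larva centre) and `extent` (max
#'   distance of any covered pixel from the centre, for placement).
#' @export
render_larva <- function(spec) {
  stopifnot(inherits(spec, "larva_spec"))
  pts <- larva_centreline(spec)
  w2 <- spec$width / 2
  ylim <- range(pts[, 1]); xlim <- range(pts[, 2])
  ys <- seq(floor(ylim[1] - w2) - 1L, ceiling(ylim[2] + w2) + 1L)
  xs <- seq(floor(xlim[1] - w2) - 1L, ceiling(xlim[2] + w2) + 1L)
  gy <- rep(ys, times = length(xs))
  gx <- rep(xs, each = length(ys))
  off <- as.matrix(expand.grid(oy = seq(-0.375, 0.375, by = 0.25),
                               ox = seq(-0.375, 0.375, by = 0.25)))
  npix <- length(gy)
  sgy <- rep(gy, times = nrow(off)) + rep(off[, 1], each = npix)
  sgx <- rep(gx, times = nrow(off)) + rep(off[, 2], each = npix)
  d2 <- rep(Inf, length(sgy))
  for (i in seq_len(nrow(pts)))
    d2 <- pmin(d2, (sgy - pts[i, 1])^2 + (sgx - pts[i, 2])^2)
  cover <- rowMeans(matrix(d2 <= w2^2, npix, nrow(off)))
  mask <- matrix(cover >= 0.5, length(ys), length(xs))
  if (!any(mask)) stop("degenerate larva: empty mask")
  covered <- cover > 0
  ext <- sqrt(max(gy[covered]^2 + gx[covered]^2)) + 1
  list(mask = mask, area = sum(cover), mask_area = sum(mask),
       ys = ys, xs = xs, extent = ext)
}

#' Plate imaging geometry
#'
#' Nominal geometry of the full-plate capture: an 8 x 12 grid of wells at a
#' fixed pitch, with `margin` pixels from the image border to the first
#' well centre. Image resolution is a free parameter of the imager; the
#' defaults keep a full plate around one megapixel.
#'
#' @param pitch Well-to-well spacing, pixels.
#' @param radius Well radius, pixels.
#' @param margin Border-to-first-centre distance, pixels.
#' @return A `grid_geometry` list including derived image dimensions and
#'   nominal well centres.
#' @export
grid_geometry <- function(pitch = 110, radius = 50, margin = 70) {
  stopifnot(pitch > 0, radius > 0, margin > radius)
  if (pitch < 2 * (radius + 2))
    stop("overlapping well geometry: pitch smaller than well diameter")
  g <- list(pitch = pitch, radius = radius, margin = margin,
            nrow_img = 2 * margin + 7 * pitch,
            ncol_img = 2 * margin + 11 * pitch)
  g$centers <- well_centers(g)
  structure(g, class = "grid_geometry")
}

# Nominal well centres, row-major A1..H12.
well_centers <- function(geom, dy = 0, dx = 0) {
  rows <- LETTERS[1:8]
  df <- expand.grid(col = 1:12, row = rows, stringsAsFactors = FALSE)
  df <- df[order(match(df$row, rows), df$col), ]
  data.frame(well = paste0(df$row, df$col), row = df$row, col = df$col,
             cy = geom$margin + (match(df$row, rows) - 1) * geom$pitch + dy,
             cx = geom$margin + (df$col - 1) * geom$pitch + dx,
             stringsAsFactors = FALSE)
}

#' Render a full synthetic plate image
#'
#' Composites well rims, an optional linear illumination gradient, larvae,
#' uneaten-food background blobs and sensor noise into one grayscale image
#' in [0, 1], and returns per-well ground truth. Larvae without a fixed
#' position are placed uniformly at random inside the well, rejecting
#' placements that overlap an already-placed larva (25 attempts, after
#' which overlap is accepted and the recorded truth is the union area).
#'
#' @param layout A data frame with columns `well`, `row`, `col` (a
#'   [plate_layout()] or compatible).
#' @param specs_by_well Named list (by well id) of lists of [larva_spec()];
#'   wells absent from the list are rendered empty. Placement rejection
#'   runs 50 attempts per larva before accepting an overlap.
#' @param artifacts An [artifact_model()]; high-background blobs are
#'   sampled per well with `p_high_background`.
#' @param geometry A [grid_geometry()].
#' @param seed Integer seed for placements, artifact sampling and noise.
#' @param flag_low_dmso Optional logical per layout row, recorded in the
#'   truth table (the size effect itself belongs to spec generation).
#' @param backdrop,interior,rim Intensity levels of plate plastic, well
#'   interior and well rim.
#' @param rim_halfwidth Rim ring half-width, pixels.
#' @param noise_sd Gaussian sensor noise SD.
#' @param gradient Length-2 numeric: total intensity change across the
#'   image rows and columns (linear ramp).
#' @return A list with `image` (matrix in [0, 1]), `truth` (per-well data
#'   frame: `well`, `row`, `col`, `cy`, `cx`, `n_larvae`, `true_area`,
#'   `flag_high_bg`, `flag_low_dmso`) and `geometry`.
#' @export
render_plate <- function(layout, specs_by_well = list(),
                         artifacts = no_artifacts(),
                         geometry = grid_geometry(), seed = 1L,
                         flag_low_dmso = NULL,
                         backdrop = 0.60, interior = 0.72, rim = 0.25,
                         rim_halfwidth = 1.5, noise_sd = 0.008,
                         gradient = c(0, 0)) {
  stopifnot(inherits(geometry, "grid_geometry"),
            all(c("well", "row", "col") %in% names(layout)))
  ctr <- geometry$centers
  r <- geometry$radius
  with_seed(seed, {
    img <- matrix(backdrop, geometry$nrow_img, geometry$ncol_img)
    if (any(gradient != 0)) {
      gy <- gradient[1] * (seq_len(nrow(img)) / nrow(img) - 0.5)
      gx <- gradient[2] * (seq_len(ncol(img)) / ncol(img) - 0.5)
      img <- img + outer(gy, rep(1, ncol(img))) + outer(rep(1, nrow(img)), gx)
    }
    half <- ceiling(r + rim_halfwidth + 1)
    loc <- seq(-half, half)
    dmat <- sqrt(outer(loc^2, rep(1, length(loc))) +
                   outer(rep(1, length(loc)), loc^2))
    in_band <- abs(dmat - r) <= rim_halfwidth
    in_disc <- dmat < r - rim_halfwidth
    flag_bg <- stats::runif(nrow(ctr)) < artifacts$p_high_background
    truth <- data.frame(well = ctr$well, row = ctr$row, col = ctr$col,
                        cy = ctr$cy, cx = ctr$cx, n_larvae = 0L,
                        true_area = 0, mask_area_sum = 0, overlap_px = 0,
                        flag_high_bg = flag_bg,
                        flag_low_dmso = FALSE, stringsAsFactors = FALSE)
    if (!is.null(flag_low_dmso))
      truth$flag_low_dmso <- flag_low_dmso[match(truth$well, layout$well)]
    for (i in seq_len(nrow(ctr))) {
      yy <- ctr$cy[i] + loc; xx <- ctr$cx[i] + loc
      patch <- img[yy, xx]
      patch[in_disc] <- patch[in_disc] - backdrop + interior
      patch[in_band] <- rim
      if (flag_bg[i]) {  # diffuse uneaten-food blob inside the well
        off <- stats::runif(2, -0.3 * r, 0.3 * r)
        db <- sqrt(outer((loc - off[1])^2, rep(1, length(loc))) +
                     outer(rep(1, length(loc)), (loc - off[2])^2))
        blob <- artifacts$food_blob_intensity *
          exp(-db^2 / (2 * (artifacts$food_blob_extent * r)^2))
        patch[in_disc] <- patch[in_disc] - blob[in_disc]
      }
      specs <- specs_by_well[[ctr$well[i]]]
      if (length(specs)) {
        occ <- matrix(FALSE, length(loc), length(loc))
        mask_sum <- 0
        for (sp in specs) {
          rl <- render_larva(sp)
          if (is.null(sp$position)) {
            maxoff <- 0.90 * r - rl$extent
            if (maxoff < 0)
              stop("larva too large for well disc (well ", ctr$well[i], ")")
            ok <- FALSE
            for (try in 1:50) {
              ang <- stats::runif(1, 0, 2 * pi)
              rad <- sqrt(stats::runif(1)) * maxoff
              cy0 <- round(rad * sin(ang)); cx0 <- round(rad * cos(ang))
              iy <- rl$ys + cy0 + half + 1; ix <- rl$xs + cx0 + half + 1
              if (!any(occ[iy, ix] & rl$mask)) { ok <- TRUE; break }
            }
          } else {
            cy0 <- round(sp$position[1]) - ctr$cy[i]
            cx0 <- round(sp$position[2]) - ctr$cx[i]
            iy <- rl$ys + cy0 + half + 1; ix <- rl$xs + cx0 + half + 1
            if (any(iy < 1) || any(ix < 1) ||
                any(iy > length(loc)) || any(ix > length(loc)))
              stop("positioned larva outside well patch")
          }
          if (sqrt(cy0^2 + cx0^2) + rl$extent > r)
            stop("larva mask does not fit inside the well disc")
          sub <- patch[iy, ix]
          sub[rl$mask] <- sub[rl$mask] * (1 - sp$intensity_contrast)
          patch[iy, ix] <- sub
          occ[iy, ix] <- occ[iy, ix] | rl$mask
          mask_sum <- mask_sum + rl$mask_area
        }
        truth$n_larvae[i] <- length(specs)
        truth$true_area[i] <- sum(occ)
        truth$mask_area_sum[i] <- mask_sum
        truth$overlap_px[i] <- mask_sum - sum(occ)
      }
      img[yy, xx] <- patch
    }
    img <- img + matrix(stats::rnorm(length(img), 0, noise_sd),
                        nrow(img), ncol(img))
    img <- pmin(pmax(img, 0), 1)
    list(image = img, truth = truth, geometry = geometry)
  })
}

# Build larva specs for one well given per-larva target areas.
# Aspect ratio ~4 gives L from the stadium area identity
# A = L^2 (1/a + pi/(4 a^2)).
specs_from_areas <- function(areas, contrast = 0.45, aspect = 4) {
  shape <- 1 / aspect + pi / (4 * aspect^2)
  lapply(areas, function(a) {
    L <- sqrt(a / shape)
    larva_spec(length = L, width = L / aspect,
               curvature = stats::runif(1, -0.22, 0.22),
               intensity_contrast = contrast,
               orientation = stats::runif(1, 0, 2 * pi))
  })
}

#' Simulate a complete plate image from the size model
#'
#' Draws per-larva areas from the [size_model()] according to each well's
#' genotype and DMSO dose (plus any true-hit rescue and the low-DMSO
#' artifact boost), converts them to curved-capsule specs, and renders the
#' plate. The returned truth table contains the rendered (mask-union) area
#' per well, which is the detection oracle.
#'
#' @param layout A [plate_layout()]-compatible data frame (needs `well`,
#'   `row`, `col`, `genotype`, `dmso_pct`; optional `compound_id`).
#' @param model A [size_model()].
#' @param artifacts An [artifact_model()].
#' @param geometry A [grid_geometry()].
#' @param seed Integer seed; fully determines the plate.
#' @param larvae_per_well Larvae per occupied well.
#' @param rescue_ids,rescues Optional true-hit compound ids and their
#'   rescue fractions.
#' @param contrast Larval intensity contrast.
#' @inheritParams render_plate
#' @return As [render_plate()].
#' @export
simulate_plate_image <- function(layout, model = size_model(),
                                 artifacts = no_artifacts(),
                                 geometry = grid_geometry(), seed = 1L,
                                 larvae_per_well = 3, rescue_ids = character(),
                                 rescues = NULL, contrast = 0.45, ...) {
  sub <- with_seed(seed, {
    flag_ld <- stats::runif(nrow(layout)) < artifacts$p_low_dmso &
      layout$dmso_pct > 0
    specs <- vector("list", nrow(layout))
    names(specs) <- layout$well
    for (i in seq_len(nrow(layout))) {
      nl <- if (!is.null(layout$n_larvae)) layout$n_larvae[i]
            else larvae_per_well
      if (nl == 0L) next
      resc <- 0
      if (!is.null(layout$compound_id) && !is.na(layout$compound_id[i])) {
        j <- match(layout$compound_id[i], rescue_ids)
        if (!is.na(j)) resc <- if (is.null(rescues)) model$hit_rescue
                               else rescues[j]
      }
      mu <- expected_larva_area(model, layout$genotype[i],
                                layout$dmso_pct[i], resc)
      if (flag_ld[i] && layout$genotype[i] == "hom")
        mu <- mu * artifacts$low_dmso_size_boost
      specs[[i]] <- specs_from_areas(
        rlarva_area(nl, mu, model$cv), contrast = contrast)
    }
    list(specs = specs, flag_ld = flag_ld)
  })
  render_plate(layout, sub$specs, artifacts = artifacts, geometry = geometry,
               seed = substream_seed(seed, 1L),
               flag_low_dmso = sub$flag_ld, ...)
}

#' Write / read a plate image
#'
#' Images are written as 16-bit grayscale TIFF; `write_plate_png` writes an
#' 8-bit preview.
#'
#' @param image Matrix in [0, 1].
#' @param path Output path.
#' @export
write_plate_tiff <- function(image, path) {
  tiff::writeTIFF(image, path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname write_plate_tiff
#' @export
write_plate_png <- function(image, path) {
  png::writePNG(image, path)
  invisible(path)
}

#' @rdname write_plate_tiff
#' @export
read_plate_image <- function(path) {
  img <- if (grepl("\\.tiff?$", path, ignore.case = TRUE))
    tiff::readTIFF(path) else png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img
}
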