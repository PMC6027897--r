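#' Locate the 96-well grid in a plate image
#'
#' The well grid is rigid (fixed pitch), so location reduces to finding the
#' global translation that best aligns a ring template with the dark well
#' rims. A rim-darkness map (intensity below the image median, clipped at
#' zero) is convolved with a one-ring kernel at the nominal well radius;
#' the translation maximising the summed ring response over all 96 nominal
#' centres is selected by exhaustive integer search within `search` pixels.
#'
#' @param image Grayscale matrix.
#' @param geometry A [grid_geometry()] giving nominal pitch, radius and
#'   margins.
#' @param search Half-width of the translation search window, pixels.
#' @param min_peak Minimum robust z-score (`(best - median) / mad` over all
#'   candidate translations) for the alignment peak; below this the image
#'   is declared rim-free.
#' @return A data frame of 96 well regions (`well`, `row`, `col`, `cy`,
#'   `cx`, `radius`), row-major A1..H12, with the fitted translation in
#'   attribute `"offset"`.
#' @export
locate_well_grid <- function(image, geometry = grid_geometry(),
                             search = 30L, min_peak = 8) {
  stopifnot(is.matrix(image), all(is.finite(image)))
  if (nrow(image) < geometry$nrow_img - 2 * search ||
      ncol(image) < geometry$ncol_img - 2 * search)
    stop("image smaller than the expected well grid")
  dark <- pmax(stats::median(image) - image, 0)
  r <- geometry$radius
  half <- ceiling(r + 2)
  loc <- seq(-half, half)
  dmat <- sqrt(outer(loc^2, rep(1, length(loc))) +
                 outer(rep(1, length(loc)), loc^2))
  ring <- (abs(dmat - r) <= 1.5) * 1
  ring <- ring / sum(ring)
  resp <- EBImage::filter2(dark, ring)
  ctr <- geometry$centers
  offs <- expand.grid(dy = -search:search, dx = -search:search)
  score <- numeric(nrow(offs))
  nr <- nrow(resp); nc <- ncol(resp)
  for (k in seq_len(nrow(offs))) {
    yy <- ctr$cy + offs$dy[k]; xx <- ctr$cx + offs$dx[k]
    keep <- yy >= 1 & yy <= nr & xx >= 1 & xx <= nc
    if (sum(keep) < 96L) { score[k] <- -Inf; next }
    score[k] <- sum(resp[cbind(yy, xx)])
  }
  fin <- is.finite(score)
  if (!any(fin)) stop("well grid does not fit inside the image")
  s_med <- stats::median(score[fin]); s_mad <- stats::mad(score[fin])
  best <- which.max(score)
  if (s_mad == 0 || (score[best] - s_med) / s_mad < min_peak)
    stop("no well rims detected: cannot locate the 96-well grid")
  regions <- well_centers(geometry, dy = offs$dy[best], dx = offs$dx[best])
  regions$radius <- r
  miss <- regions$cy - half < 1 | regions$cy + half > nrow(image) |
    regions$cx - half < 1 | regions$cx + half > ncol(image)
  if (any(miss))
    stop("wells not resolvable inside the image: ",
         paste(regions$well[miss], collapse = ", "))
  attr(regions, "offset") <- c(dy = offs$dy[best], dx = offs$dx[best])
  regions
}

#' Extract one well's sub-raster
#'
#' Returns the square patch around a well centre together with the disc
#' mask and the analysis mask (disc minus the outer 5% rim ring, which is
#' masked out; components touching walls are otherwise kept).
#'
#' @param image Plate image matrix.
#' @param region One row of the [locate_well_grid()] table.
#' @param rim_frac Fraction of the radius excluded as rim ring.
#' @return List with `pixels` (matrix), `disc`, `analysis` (logical
#'   matrices), `cy`, `cx`, `radius`.
#' @export
well_patch <- function(image, region, rim_frac = 0.05) {
  r <- region$radius
  half <- floor(r)
  yy <- region$cy + seq(-half, half); xx <- region$cx + seq(-half, half)
  stopifnot(min(yy) >= 1, min(xx) >= 1,
            max(yy) <= nrow(image), max(xx) <= ncol(image))
  loc <- seq(-half, half)
  dmat <- sqrt(outer(loc^2, rep(1, length(loc))) +
                 outer(rep(1, length(loc)), loc^2))
  list(pixels = image[yy, xx], disc = dmat < r,
       analysis = dmat < (1 - rim_frac) * r - 1.5,
       cy = region$cy, cx = region$cx, radius = r)
}
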