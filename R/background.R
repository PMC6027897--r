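#' Estimate what a well would look like when empty
#'
#' Reconstructs the empty-well background of one well: pixels near edges
#' are probably larvae, so they are excluded and the background is
#' interpolated across the gaps. "Near edges" is operationalised as local
#' gradient magnitude above a robust threshold (median + `grad_k` * MAD of
#' the gradient over the analysis region), dilated by `edge_margin` pixels
#' so that thin larval bodies are covered entirely. Interpolation is a
#' trimmed least-squares quadratic surface fit to the remaining pixels: a
#' first fit is refined once after dropping gross outliers (residuals
#' beyond `trim_k` * MAD), which keeps diffuse artifacts such as uneaten
#' food out of the background model. The surface reproduces constant and
#' linear-ramp backgrounds exactly and is idempotent.
#'
#' The residual metric is the 90th percentile of |observed - estimate| over
#' analysis pixels outside the exclusion mask (i.e. outside putative
#' detections): a robust upper-quantile scale that stays at the noise level
#' for clean wells but responds strongly to diffuse background artifacts,
#' which are too smooth to be excluded as larvae.
#'
#' @param well A [well_patch()] (or any list with `pixels` and `analysis`).
#' @param edge_margin Dilation radius for the exclusion mask, pixels.
#' @param grad_k Robustness constant of the gradient threshold.
#' @param trim_k Trimming constant of the refinement pass.
#' @return A `background_model` list: `estimate` (matrix over the full
#'   patch), `excluded_mask`, `residual_metric`, `analysis`.
#' @export
estimate_empty_background <- function(well, edge_margin = 3, grad_k = 5,
                                      trim_k = 4) {
  px <- well$pixels
  stopifnot(is.matrix(px), all(is.finite(px)))
  an <- if (!is.null(well$analysis)) well$analysis
        else matrix(TRUE, nrow(px), ncol(px))
  if (!any(an)) stop("empty analysis region")
  n <- nrow(px); m <- ncol(px)
  gy <- matrix(0, n, m); gx <- matrix(0, n, m)
  gy[2:(n - 1), ] <- (px[3:n, ] - px[1:(n - 2), ]) / 2
  gx[, 2:(m - 1)] <- (px[, 3:m] - px[, 1:(m - 2)]) / 2
  grad <- sqrt(gy^2 + gx^2)
  g <- grad[an]
  thr <- stats::median(g) + grad_k * stats::mad(g)
  excl <- grad > thr & an
  if (any(excl) && edge_margin > 0) {
    brush <- EBImage::makeBrush(2 * edge_margin + 1, shape = "disc")
    excl <- EBImage::dilate(EBImage::Image(excl * 1), brush) > 0.5
    excl <- matrix(as.logical(excl), n, m) & an
  }
  fitpix <- an & !excl
  if (sum(fitpix) < 12L)
    stop("exclusion covers the entire well: cannot interpolate background")
  yy <- (row(px) - (n + 1) / 2) / n
  xx <- (col(px) - (m + 1) / 2) / m
  X <- cbind(1, yy[fitpix], xx[fitpix], yy[fitpix]^2,
             yy[fitpix] * xx[fitpix], xx[fitpix]^2)
  z <- px[fitpix]
  beta <- stats::.lm.fit(X, z)$coefficients
  res <- z - X %*% beta
  s <- stats::mad(res)
  keep <- abs(res) <= max(trim_k * s, .Machine$double.eps)
  if (s > 0 && sum(keep) >= 12L)
    beta <- stats::.lm.fit(X[keep, , drop = FALSE], z[keep])$coefficients
  est <- matrix(cbind(1, c(yy), c(xx), c(yy)^2, c(yy) * c(xx), c(xx)^2) %*%
                  beta, n, m)
  resid_pix <- abs(px - est)[fitpix]
  structure(list(estimate = est, excluded_mask = excl,
                 residual_metric = unname(stats::quantile(resid_pix, 0.90)),
                 analysis = an),
            class = "background_model")
}
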