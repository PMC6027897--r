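#' Cumulative event fraction normalised to survivors
#'
#' Converts daily event counts into the cumulative fraction of surviving
#' animals that have undergone the event by each day — the standard
#' normalisation for eclosion/pupariation timecourses, under which every
#' curve for animals that complete development ends at 1.
#'
#' @param events A `dev_events` data frame (or any with `day`, `count`).
#' @param n_survivors Number of animals surviving to the event; defaults to
#'   the table's `n_survivors` attribute, falling back to `sum(count)`.
#' @return Data frame `day`, `count`, `cum_fraction`.
#' @export
#' @examples
#' ev <- data.frame(day = 9:11, count = c(5, 10, 5))
#' cumulative_fraction(ev, n_survivors = 20)$cum_fraction  # 0.25 0.75 1
cumulative_fraction <- function(events, n_survivors = NULL) {
  stopifnot(all(c("day", "count") %in% names(events)))
  if (is.null(n_survivors))
    n_survivors <- attr(events, "n_survivors") %||% sum(events$count)
  if (!is.numeric(n_survivors) || length(n_survivors) != 1L ||
      n_survivors <= 0)
    stop("n_survivors must be a single positive number")
  ev <- events[order(events$day), c("day", "count")]
  ev$cum_fraction <- cumsum(ev$count) / n_survivors
  if (any(ev$cum_fraction > 1 + 1e-9))
    stop("cumulative events exceed n_survivors")
  ev
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Median event day of a timecourse
#'
#' Day at which the cumulative survivor-normalised fraction first reaches
#' one half; used to quantify developmental delay between conditions.
#'
#' @inheritParams cumulative_fraction
#' @export
median_event_day <- function(events, n_survivors = NULL) {
  cf <- cumulative_fraction(events, n_survivors)
  cf$day[which(cf$cum_fraction >= 0.5)[1]]
}

#' Eclosion-fraction fold change between treatment arms
#'
#' Per-vial eclosed/total fractions are the replicate unit. The fold change
#' is the ratio of arm means (treated over control) and significance comes
#' from a two-sample Student's t-test on the per-vial fractions
#' (equal-variance classical test by default, matching the screen's
#' reporting; `welch = TRUE` for the unequal-variance variant).
#'
#' @param treated,control Numeric vectors of per-vial eclosion fractions
#'   (>= 2 vials per arm).
#' @param welch Use the Welch test instead of the classical equal-variance
#'   test.
#' @return List with `fold_change`, `p_value`, `t_statistic`, `df`,
#'   `mean_treated`, `mean_control`.
#' @export
eclosion_fold_change <- function(treated, control, welch = FALSE) {
  stopifnot(length(treated) >= 2L, length(control) >= 2L)
  mc <- mean(control)
  if (mc == 0) stop("control mean is zero: fold change undefined")
  if (stats::sd(treated) == 0 && stats::sd(control) == 0) {
    # zero within-arm variance: exact-equality fast path (p = 1 when the
    # arms coincide, p = 0 for perfect separation)
    eq <- mean(treated) == mc
    return(list(fold_change = mean(treated) / mc,
                p_value = if (eq) 1 else 0,
                t_statistic = if (eq) 0 else Inf * sign(mean(treated) - mc),
                df = length(treated) + length(control) - 2,
                mean_treated = mean(treated), mean_control = mc))
  }
  tt <- stats::t.test(treated, control, var.equal = !welch)
  list(fold_change = mean(treated) / mc, p_value = tt$p.value,
       t_statistic = unname(tt$statistic), df = unname(tt$parameter),
       mean_treated = mean(treated), mean_control = mc)
}

#' Compare larval sizes between two groups
#'
#' Ratio of group means with a two-sided Student's t-test (classical
#' equal-variance by default). Degenerate zero-variance inputs with equal
#' means are reported through an exact-equality fast path.
#'
#' @param group_a,group_b Numeric area vectors (>= 2 values each).
#' @param welch Use the Welch variant.
#' @return List with `ratio` (`mean(group_a)/mean(group_b)`), `p_value`,
#'   `t_statistic`, `df`, `mean_a`, `mean_b`.
#' @export
compare_sizes <- function(group_a, group_b, welch = FALSE) {
  stopifnot(length(group_a) >= 2L, length(group_b) >= 2L)
  ma <- mean(group_a); mb <- mean(group_b)
  if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0) {
    return(list(ratio = ma / mb, p_value = if (ma == mb) 1 else 0,
                t_statistic = if (ma == mb) 0 else Inf * sign(ma - mb),
                df = length(group_a) + length(group_b) - 2,
                mean_a = ma, mean_b = mb))
  }
  tt <- stats::t.test(group_a, group_b, var.equal = !welch)
  list(ratio = ma / mb, p_value = tt$p.value,
       t_statistic = unname(tt$statistic), df = unname(tt$parameter),
       mean_a = ma, mean_b = mb)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares 4PL fit `y = bottom + (top - bottom) / (1 + (x/ic50)^slope)`
#' via Levenberg-Marquardt, initialised from data quantiles (top and bottom
#' from the extreme-dose means, IC50 from the dose whose mean response is
#' nearest halfway, slope 1). The IC50 is flagged `extrapolated` when it
#' falls outside the positive tested dose range, and the whole fit is
#' flagged `unreliable` when the response is not monotone beyond tolerance
#' (Spearman rank correlation of per-dose means against dose weaker than
#' `monotone_tol`) or the optimiser fails.
#'
#' @param doses Dose vector (same length as `responses`); dose 0 is
#'   allowed and informs the top plateau.
#' @param responses Response vector (e.g. larval areas).
#' @param monotone_tol Minimum |Spearman rho| of per-dose means vs dose for
#'   a fit to be considered reliable.
#' @return A `dose_response_fit` list: `top`, `bottom`, `ic50`, `slope`,
#'   `fitted`, `residual_sd`, `unreliable`, `extrapolated`, `doses`,
#'   `dose_means`.
#' @export
fit_dose_response <- function(doses, responses, monotone_tol = 0.5) {
  stopifnot(length(doses) == length(responses))
  ok <- is.finite(doses) & is.finite(responses)
  doses <- doses[ok]; responses <- responses[ok]
  lev <- sort(unique(doses))
  if (length(lev) < 4L) stop("need at least 4 dose levels")
  means <- vapply(lev, function(d) mean(responses[doses == d]), numeric(1))
  rho <- suppressWarnings(stats::cor(lev, means, method = "spearman"))
  unreliable <- !is.finite(rho) || abs(rho) < monotone_tol
  top0 <- means[which.min(lev)]
  bot0 <- means[which.max(lev)]
  if (top0 < bot0) { tmp <- top0; top0 <- bot0; bot0 <- tmp }
  half <- (top0 + bot0) / 2
  pos <- lev[lev > 0]
  ic0 <- pos[which.min(abs(means[match(pos, lev)] - half))]
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ bottom + (top - bottom) / (1 + (x / ic50)^slope),
      data = data.frame(x = doses, y = responses),
      start = list(top = top0, bottom = bot0, ic50 = ic0, slope = 1),
      lower = c(top = -Inf, bottom = -Inf, ic50 = 1e-9, slope = 0.05),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    out <- list(top = top0, bottom = bot0, ic50 = NA_real_, slope = NA_real_,
                fitted = NULL, residual_sd = NA_real_, unreliable = TRUE,
                extrapolated = NA, doses = lev, dose_means = means)
    class(out) <- "dose_response_fit"
    return(out)
  }
  cf <- stats::coef(fit)
  if (cf["top"] < cf["bottom"]) {   # enforce top >= bottom orientation
    cf[c("top", "bottom")] <- cf[c("bottom", "top")]
    cf["slope"] <- -cf["slope"]
  }
  out <- list(top = unname(cf["top"]), bottom = unname(cf["bottom"]),
              ic50 = unname(cf["ic50"]), slope = unname(cf["slope"]),
              fitted = stats::fitted(fit),
              residual_sd = stats::sd(stats::residuals(fit)),
              unreliable = unreliable,
              extrapolated = cf["ic50"] < min(pos) || cf["ic50"] > max(lev),
              doses = lev, dose_means = means)
  class(out) <- "dose_response_fit"
  out
}

#' IC50 ratio between two fitted dose-response curves
#'
#' @param fit_a,fit_b `dose_response_fit` objects (e.g. mutant and
#'   control); the ratio `ic50_a / ic50_b` quantifies a sensitivity shift.
#' @export
ic50_ratio <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "dose_response_fit"),
            inherits(fit_b, "dose_response_fit"))
  fit_a$ic50 / fit_b$ic50
}

#' Plot survivor-normalised timecourses
#'
#' Simple base-graphics step plot of one or more cumulative timecourses.
#'
#' @param timecourses Named list of data frames from
#'   [cumulative_fraction()].
#' @param main Plot title.
#' @export
plot_timecourses <- function(timecourses, main = "Eclosion timecourse") {
  stopifnot(length(timecourses) >= 1L)
  days <- range(unlist(lapply(timecourses, `[[`, "day")))
  graphics::plot(NA, xlim = days, ylim = c(0, 1), xlab = "day",
                 ylab = "cumulative fraction", main = main)
  cols <- grDevices::hcl.colors(length(timecourses), "Dark 3")
  for (i in seq_along(timecourses))
    graphics::lines(timecourses[[i]]$day, timecourses[[i]]$cum_fraction,
                    type = "s", col = cols[i], lwd = 2)
  graphics::legend("bottomright", legend = names(timecourses), col = cols,
                   lwd = 2, bty = "n")
  invisible(NULL)
}
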