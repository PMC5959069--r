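#' Local-versus-regional richness regression
#'
#' Community-saturation test: ordinary least squares of mean local richness
#' on regional richness, one point per regional unit. For each unit at
#' \code{regional_level} the response is the mean richness of its member
#' sites and the predictor is the unit's pooled (regional) richness, so the
#' fit never treats sites within a unit as independent points
#' (pseudoreplication guard: the number of points equals the number of
#' regional units). A slope near 1 along the \code{local = regional}
#' diagonal indicates proportional (unsaturated) communities; a flat slope
#' indicates local richness capped independently of the regional pool.
#'
#' @param m an [incidence_matrix()]
#' @param h a [site_hierarchy()] covering the sites of \code{m}
#' @param regional_level level of \code{h} defining the regional units
#'   (needs at least 3 units)
#' @return list of class \code{local_regional_fit}: \code{slope},
#'   \code{intercept}, \code{r_squared}, \code{f_statistic}, \code{df_num}
#'   (1), \code{df_den} (units - 2), \code{p_value}, \code{points}
#'   (data.frame unit/regional/local_mean), \code{residuals}, and the
#'   underlying \code{lm} fit
#' @export
local_regional_regression <- function(m, h, regional_level) {
  stopifnot(inherits(m, "incidence_matrix"), inherits(h, "site_hierarchy"))
  lv <- attr(h, "levels")
  if (!regional_level %in% lv)
    stop("unknown level '", regional_level, "'")
  hh <- match_hierarchy(m, h)
  units <- unique(hh[[regional_level]])
  if (length(units) < 3L)
    stop("need at least 3 regional units, got ", length(units))
  regional <- rowSums(unclass(aggregate_incidence(m, h, regional_level)))
  site_rich <- rowSums(unclass(m))
  local_mean <- vapply(units, function(u) {
    mean(site_rich[hh[[regional_level]] == u])
  }, numeric(1))
  pts <- data.frame(unit = units, regional = unname(regional[units]),
                    local_mean = unname(local_mean))
  if (stats::var(pts$regional) == 0)
    stop("degenerate fit: all regional richnesses are equal")
  fit <- stats::lm(local_mean ~ regional, data = pts)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = sm$r.squared,
                 f_statistic = unname(fstat["value"]),
                 df_num = unname(fstat["numdf"]),
                 df_den = unname(fstat["dendf"]),
                 p_value = unname(stats::pf(fstat["value"], fstat["numdf"],
                                            fstat["dendf"],
                                            lower.tail = FALSE)),
                 points = pts,
                 residuals = unname(stats::residuals(fit)),
                 lm = fit),
            class = "local_regional_fit")
}

#' @export
print.local_regional_fit <- function(x, ...) {
  cat(sprintf("local ~ regional richness over %d units: slope = %.3f, R2 = %.2f, F(%d,%d) = %.2f, p = %.4g\n",
              nrow(x$points), x$slope, x$r_squared, x$df_num, x$df_den,
              x$f_statistic, x$p_value))
  invisible(x)
}

#' Scatter plot of the local-regional relationship
#'
#' Points, fitted line, and the theoretical boundary \code{local = regional}
#' (dashed diagonal) for visual comparison; the boundary is never fitted.
#'
#' @param x a [local_regional_regression()] fit
#' @param ... passed to [plot()]
#' @export
plot.local_regional_fit <- function(x, ...) {
  pts <- x$points
  lim <- c(0, max(pts$regional))
  plot(pts$regional, pts$local_mean, xlim = lim, ylim = lim,
       xlab = "regional richness", ylab = "mean local richness", pch = 17,
       ...)
  graphics::abline(x$intercept, x$slope)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
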