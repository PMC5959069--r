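#' Multiple-site Sorensen-family dissimilarity decomposition
#'
#' A single dissimilarity value for a whole set of sites — not an average of
#' pairwise values — split into turnover and nestedness-resultant components.
#' With \eqn{b_{ij}} the number of species at site i but not j,
#' \eqn{\Sigma_{min} = \sum_{i<j} \min(b_{ij}, b_{ji})},
#' \eqn{\Sigma_{max} = \sum_{i<j} \max(b_{ij}, b_{ji})}, and
#' \eqn{K = \sum_i S_i - S_T} (total of site richnesses minus regional
#' richness):
#' \deqn{\beta_{SIM} = \Sigma_{min} / (\Sigma_{min} + K)}
#' \deqn{\beta_{SOR} = (\Sigma_{min} + \Sigma_{max}) /
#'       (2K + \Sigma_{min} + \Sigma_{max})}
#' \deqn{\beta_{SNE} = \beta_{SOR} - \beta_{SIM}}
#'
#' A strict nested chain of sites forces \eqn{\beta_{SIM} = 0}; communities
#' where every pair has \eqn{b_{ij} = b_{ji}} (pure replacement) force
#' \eqn{\beta_{SNE} = 0}; identical sites give all three measures 0.
#'
#' @param m an [incidence_matrix()] with at least 2 non-empty sites
#' @param drop_empty discard empty sites instead of raising an error
#' @return list of class \code{multisite_beta}: \code{beta_sor},
#'   \code{beta_sim}, \code{beta_sne} in \code{[0, 1]} with
#'   \code{beta_sne = beta_sor - beta_sim}, plus \code{n_sites}
#' @export
multisite_beta <- function(m, drop_empty = FALSE) {
  stopifnot(inherits(m, "incidence_matrix"))
  m <- check_no_empty(m, drop_empty, "multiple-site dissimilarity")
  if (nrow(m) < 2L) stop("need at least 2 non-empty sites")
  x <- unclass(m)
  A <- tcrossprod(x)
  S <- rowSums(x)
  B <- S - A
  up <- upper.tri(B)
  smin <- sum(pmin(B, t(B))[up])
  smax <- sum(pmax(B, t(B))[up])
  K <- sum(S) - sum(colSums(x) > 0L)
  sim <- if (smin + K > 0) smin / (smin + K) else 0
  sor <- if (2 * K + smin + smax > 0) (smin + smax) / (2 * K + smin + smax) else 0
  structure(list(beta_sor = sor, beta_sim = sim, beta_sne = sor - sim,
                 n_sites = nrow(m)),
            class = "multisite_beta")
}

#' @export
print.multisite_beta <- function(x, ...) {
  cat(sprintf("multiple-site beta over %d sites: beta_sor = %.4f, beta_sim = %.4f (turnover), beta_sne = %.4f (nestedness)\n",
              x$n_sites, x$beta_sor, x$beta_sim, x$beta_sne))
  invisible(x)
}

#' Resampling distribution of multiple-site dissimilarity
#'
#' Multiple-site measures grow with the number of sites, so sets of different
#' sizes are compared via the distribution of the measure over random subsets
#' of a fixed size: \code{n_reps} subsets of \code{subset_size} sites are
#' drawn without replacement (independently per draw) and the decomposition
#' recomputed for each. The draw sequence is fully reproducible from
#' \code{seed}, which is recorded in the result.
#'
#' @param m an [incidence_matrix()]
#' @param subset_size sites per draw (default 10); at least 2 and at most the
#'   number of sites
#' @param n_reps number of draws (default 1000)
#' @param seed integer seed for the draw sequence
#' @param drop_empty discard empty sites before resampling
#' @return list of class \code{beta_sample_distribution}: \code{draws}
#'   (n_reps x 3 matrix, columns beta_sor/beta_sim/beta_sne), \code{summary}
#'   (mean and sd per component), \code{subset_size}, \code{n_reps},
#'   \code{seed}, \code{n_sites}
#' @export
beta_sample <- function(m, subset_size = 10, n_reps = 1000, seed = NULL,
                        drop_empty = FALSE) {
  stopifnot(inherits(m, "incidence_matrix"))
  m <- check_no_empty(m, drop_empty, "multiple-site dissimilarity")
  if (subset_size < 2L) stop("subset_size must be at least 2")
  if (subset_size > nrow(m))
    stop(sprintf("subset_size (%d) exceeds available sites (%d)",
                 subset_size, nrow(m)))
  if (!is.null(seed)) set.seed(seed)
  draws <- matrix(NA_real_, n_reps, 3L,
                  dimnames = list(NULL, c("beta_sor", "beta_sim", "beta_sne")))
  for (r in seq_len(n_reps)) {
    idx <- sample.int(nrow(m), subset_size)
    b <- multisite_beta(subset_sites(m, idx))
    draws[r, ] <- c(b$beta_sor, b$beta_sim, b$beta_sne)
  }
  structure(list(draws = draws,
                 summary = rbind(mean = colMeans(draws),
                                 sd = apply(draws, 2L, stats::sd)),
                 subset_size = subset_size, n_reps = n_reps,
                 seed = seed, n_sites = nrow(m)),
            class = "beta_sample_distribution")
}

#' @export
print.beta_sample_distribution <- function(x, ...) {
  cat(sprintf("beta resampling: %d draws of %d sites from %d (seed %s)\n",
              x$n_reps, x$subset_size, x$n_sites,
              x$seed %||% "unset"))
  print(round(x$summary, 4))
  invisible(x)
}

#' Density plot of resampled beta components
#'
#' Draws the distribution of total dissimilarity and its two components
#' across the resampling draws, one curve per component.
#'
#' @param x a [beta_sample()] result
#' @param ... passed to [plot()]
#' @export
plot.beta_sample_distribution <- function(x, ...) {
  dens <- apply(x$draws, 2L, stats::density, simplify = FALSE)
  xlim <- range(vapply(dens, function(d) range(d$x), numeric(2)))
  ylim <- c(0, max(vapply(dens, function(d) max(d$y), numeric(1))))
  plot(NA, xlim = xlim, ylim = ylim, xlab = "dissimilarity",
       ylab = "density", ...)
  lty <- c(beta_sor = 1, beta_sim = 2, beta_sne = 3)
  for (comp in names(lty)) lines(dens[[comp]], lty = lty[[comp]])
  legend("top", legend = names(lty), lty = lty, bty = "n")
  invisible(x)
}

#' Compare two resampling distributions of a beta component
#'
#' Summaries for judging whether two sets of sites differ in a dissimilarity
#' component: the probability that a random draw from the first exceeds a
#' random draw from the second (ties counted one half, so identical
#' distributions score exactly 0.5), each distribution's 2.5% and 97.5%
#' quantiles, and whether those 95% intervals overlap. No single verdict is
#' returned; the summaries are reported side by side.
#'
#' @param d1,d2 [beta_sample()] results
#' @param component \code{"beta_sor"}, \code{"beta_sim"} or \code{"beta_sne"}
#' @return list of class \code{beta_distribution_difference}:
#'   \code{p_greater} = P(X > Y) + 0.5 P(X = Y) over all cross pairs,
#'   \code{quantiles} (2 x 2 matrix), \code{overlap} (logical), and the
#'   component name
#' @export
distribution_difference <- function(d1, d2,
                                    component = c("beta_sim", "beta_sne",
                                                  "beta_sor")) {
  stopifnot(inherits(d1, "beta_sample_distribution"),
            inherits(d2, "beta_sample_distribution"))
  component <- match.arg(component)
  x <- d1$draws[, component]; y <- d2$draws[, component]
  if (!length(x) || !length(y)) stop("empty distribution")
  # P(X > Y) with ties split, via the rank-sum identity (avoids the full
  # n1 x n2 cross table)
  rk <- rank(c(x, y))
  p_greater <- (sum(rk[seq_along(x)]) - length(x) * (length(x) + 1) / 2) /
    (length(x) * length(y))
  q <- rbind(d1 = stats::quantile(x, c(0.025, 0.975)),
             d2 = stats::quantile(y, c(0.025, 0.975)))
  overlap <- q["d1", 1L] <= q["d2", 2L] && q["d2", 1L] <= q["d1", 2L]
  structure(list(component = component, p_greater = p_greater,
                 quantiles = q, overlap = overlap),
            class = "beta_distribution_difference")
}

#' @export
print.beta_distribution_difference <- function(x, ...) {
  cat(sprintf("%s: P(d1 > d2) = %.3f; 95%% intervals %s\n", x$component,
              x$p_greater, if (x$overlap) "overlap" else "do not overlap"))
  print(round(x$quantiles, 4))
  invisible(x)
}
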