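#' Additive partition of regional richness across nested spatial scales
#'
#' Decomposes regional (gamma) richness into within- and between-level
#' components that all share species units: with levels ordered lowest first
#' (e.g. plot < mountain < range), \eqn{\alpha_l} is the mean richness of the
#' units at level \eqn{l} (a unit's richness being that of its aggregated
#' incidence), \eqn{\beta_l = \alpha_{l+1} - \alpha_l} between consecutive
#' levels, and the top beta is \eqn{\gamma - \alpha_{top}}. The identity
#' \eqn{\alpha_1 + \sum_l \beta_l = \gamma} holds exactly, and every
#' component is also expressed as a percentage of gamma.
#'
#' @param m an [incidence_matrix()]
#' @param h a [site_hierarchy()] covering the sites of \code{m}
#' @return list of class \code{additive_partition}: \code{components}
#'   data.frame (component, level, species units, percent of gamma),
#'   \code{alpha} and \code{beta} named vectors, \code{gamma},
#'   \code{level_names}
#' @export
additive_partition <- function(m, h) {
  stopifnot(inherits(m, "incidence_matrix"), inherits(h, "site_hierarchy"))
  lv <- attr(h, "levels")
  alpha <- vapply(lv, function(l) {
    mean(rowSums(unclass(aggregate_incidence(m, h, l))))
  }, numeric(1))
  gamma <- ncol(m)
  beta <- c(diff(alpha), gamma - alpha[length(alpha)])
  names(alpha) <- paste0("alpha", seq_along(lv))
  names(beta) <- paste0("beta", seq_along(lv))
  comp <- c(alpha[1L], beta)
  components <- data.frame(
    component = names(comp),
    level = c(lv[1L], lv),
    species = unname(comp),
    percent = unname(100 * comp / gamma))
  structure(list(components = components, alpha = alpha, beta = beta,
                 gamma = gamma, level_names = lv),
            class = "additive_partition")
}

#' @export
print.additive_partition <- function(x, ...) {
  cat(sprintf("additive partition of gamma = %d across levels %s\n",
              x$gamma, paste(x$level_names, collapse = " < ")))
  df <- x$components
  df$species <- round(df$species, 2)
  df$percent <- round(df$percent, 2)
  if (!is.null(df$expected_percent))
    df$expected_percent <- round(df$expected_percent, 2)
  print(df, row.names = FALSE)
  invisible(x)
}

shuffle_hierarchy <- function(h) {
  lv <- attr(h, "levels")
  df <- as.data.frame(h)
  # permute member units among parent units, level by level, keeping the
  # number of children per parent fixed; each site keeps its species list
  for (k in seq_along(lv)[-length(lv)]) {
    units <- unique(df[[lv[k]]])
    parent <- df[[lv[k + 1L]]][match(units, df[[lv[k]]])]
    new_parent <- sample(parent)
    df[[lv[k + 1L]]] <- new_parent[match(df[[lv[k]]], units)]
    # reassignment at level k rewires all higher levels through the parent
    for (kk in seq_along(lv)[-seq_len(k + 1L)]) {
      anc <- h[[lv[kk]]][match(new_parent, h[[lv[k + 1L]]])]
      df[[lv[kk]]] <- anc[match(df[[lv[k]]], units)]
    }
  }
  site_hierarchy(df)
}

#' Randomization test for additive partition components
#'
#' Sample-based null model: at each level, member units are shuffled among
#' their parent units keeping the number of children per parent fixed, so
#' every unit keeps its own species list and only the spatial arrangement is
#' randomized. The lowest-level alpha is invariant under this null (its null
#' variance is 0). Two-tailed Monte-Carlo p-values use the add-one
#' correction: with \code{k} the smaller of the counts of null values at or
#' above / at or below the observed value,
#' \eqn{p = \min(1, 2(k + 1)/(n_{null} + 1))}.
#'
#' @inheritParams additive_partition
#' @param n_null number of null randomizations (default 999)
#' @param seed integer seed; recorded in the result
#' @return an [additive_partition()] whose \code{components} table gains
#'   \code{expected} (null mean, species units), \code{expected_percent} and
#'   \code{p_value} columns, plus fields \code{n_null}, \code{seed} and
#'   \code{null_draws} (matrix of component values per draw)
#' @export
partition_significance <- function(m, h, n_null = 999, seed = NULL) {
  obs <- additive_partition(m, h)
  lv <- attr(h, "levels")
  shuffleable <- length(lv) >= 2L &&
    any(vapply(seq_along(lv)[-1L],
               function(k) length(unique(h[[lv[k]]])) > 1L, logical(1)))
  if (!shuffleable)
    warning("hierarchy has nothing to shuffle; null model is degenerate, p-values reported as 1")
  if (!is.null(seed)) set.seed(seed)
  comp_names <- obs$components$component
  null_draws <- matrix(NA_real_, n_null, length(comp_names),
                       dimnames = list(NULL, comp_names))
  for (r in seq_len(n_null)) {
    p <- additive_partition(m, shuffle_hierarchy(h))
    null_draws[r, ] <- p$components$species
  }
  observed <- obs$components$species
  p_value <- vapply(seq_along(comp_names), function(j) {
    nv <- null_draws[, j]
    if (stats::sd(nv) == 0 && all(nv == observed[j])) return(1)
    k <- min(sum(nv >= observed[j]), sum(nv <= observed[j]))
    min(1, 2 * (k + 1) / (n_null + 1))
  }, numeric(1))
  obs$components$expected <- colMeans(null_draws)
  obs$components$expected_percent <- 100 * colMeans(null_draws) / obs$gamma
  obs$components$p_value <- p_value
  obs$n_null <- n_null
  obs$seed <- seed
  obs$null_draws <- null_draws
  obs
}

#' Write an additive-partition table
#'
#' Produces the stacked component table (component, species units, percent of
#' gamma, and — when a null model was run — expected percent and p-value) as
#' delimited text.
#'
#' @param x an [additive_partition()] result
#' @param path output file; extension picks the separator
#' @param sep field separator; defaults by file extension
#' @return \code{path}, invisibly
#' @export
write_partition <- function(x, path, sep = detect_sep(path)) {
  stopifnot(inherits(x, "additive_partition"))
  utils::write.table(x$components, path, sep = sep, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
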