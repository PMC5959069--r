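#' Shared and exclusive species counts for a pair of sites
#'
#' The matching components of the Sorensen family: \code{a} species shared,
#' \code{b} exclusive to the first site, \code{c} exclusive to the second.
#'
#' @param m an [incidence_matrix()]
#' @param i,j site labels or indices, distinct
#' @param drop_empty ignored here except for validation symmetry: empty sites
#'   are an error because 0/0 dissimilarities are undefined
#' @return list with integer components \code{a}, \code{b}, \code{c}
#' @export
pair_components <- function(m, i, j, drop_empty = FALSE) {
  stopifnot(inherits(m, "incidence_matrix"))
  if (is.character(i)) i <- match(i, rownames(m))
  if (is.character(j)) j <- match(j, rownames(m))
  if (is.na(i) || is.na(j)) stop("unknown site label")
  if (i == j) stop("i and j must name distinct sites")
  xi <- unclass(m)[i, ]; xj <- unclass(m)[j, ]
  if (sum(xi) == 0L || sum(xj) == 0L)
    stop("pair components are undefined for empty sites (",
         paste(c(i, j)[c(sum(xi), sum(xj)) == 0L], collapse = ", "), ")")
  a <- sum(xi & xj)
  list(a = a, b = sum(xi) - a, c = sum(xj) - a)
}

#' Pairwise Sorensen-family dissimilarity matrices
#'
#' For every pair of sites the total dissimilarity (Sorensen) is split into
#' spatial turnover (Simpson) and a nestedness-resultant remainder:
#' \deqn{\beta_{sor} = (b+c)/(2a+b+c)}
#' \deqn{\beta_{sim} = \min(b,c)/(a+\min(b,c))}
#' \deqn{\beta_{sne} = \beta_{sor} - \beta_{sim}}
#' where \code{a,b,c} are the [pair_components()]. The Simpson component is 0
#' whenever one site's species are a subset of the other's; the remainder
#' is 0 whenever the two sites are equally rich (\code{b = c}).
#'
#' @param m an [incidence_matrix()] with at least 2 non-empty sites
#' @param drop_empty discard empty sites instead of raising an error
#' @return list of class \code{pairwise_beta} with square symmetric
#'   zero-diagonal matrices \code{beta_sor}, \code{beta_sim}, \code{beta_sne},
#'   all in \code{[0, 1]} and satisfying
#'   \code{beta_sor = beta_sim + beta_sne} elementwise
#' @export
pairwise_beta_matrices <- function(m, drop_empty = FALSE) {
  stopifnot(inherits(m, "incidence_matrix"))
  m <- check_no_empty(m, drop_empty, "pairwise dissimilarity")
  if (nrow(m) < 2L) stop("need at least 2 non-empty sites")
  x <- unclass(m)
  A <- tcrossprod(x)                       # shared counts a_ij
  S <- rowSums(x)
  B <- S - A                               # b_ij: exclusive to row site
  Cc <- t(B)                               # c_ij: exclusive to column site
  minbc <- pmin(B, Cc)
  sor <- (B + Cc) / (2 * A + B + Cc)
  sim <- minbc / (A + minbc)
  # identical pairs have b = c = 0: all three measures exactly 0
  zero <- (B + Cc) == 0
  sor[zero] <- 0; sim[zero] <- 0
  diag(sor) <- 0; diag(sim) <- 0
  dimnames(sor) <- dimnames(sim) <- list(rownames(m), rownames(m))
  structure(list(beta_sor = sor, beta_sim = sim, beta_sne = sor - sim),
            class = "pairwise_beta")
}

#' @export
print.pairwise_beta <- function(x, ...) {
  n <- nrow(x$beta_sor)
  up <- upper.tri(x$beta_sor)
  cat(sprintf("pairwise beta over %d sites: mean beta_sor %.4f = beta_sim %.4f + beta_sne %.4f\n",
              n, mean(x$beta_sor[up]), mean(x$beta_sim[up]),
              mean(x$beta_sne[up])))
  invisible(x)
}

#' Write a square labelled dissimilarity matrix
#'
#' Site labels appear in the header row and first column, so the file is
#' self-describing and round-trips through [read_dissimilarity()].
#'
#' @param d square numeric matrix with dimnames
#' @param path output file; extension picks the separator
#' @param sep field separator; defaults by file extension
#' @return \code{path}, invisibly
#' @export
write_dissimilarity <- function(d, path, sep = detect_sep(path)) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  df <- data.frame(site = rownames(d), d, check.names = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a square labelled dissimilarity matrix
#'
#' @inheritParams read_incidence
#' @return a square numeric matrix with site dimnames
#' @export
read_dissimilarity <- function(path, sep = detect_sep(path)) {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  d <- as.matrix(df[, -1L, drop = FALSE])
  rownames(d) <- as.character(df[[1L]])
  d
}
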