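# Brute-force oracles, independent of the package's vectorized code paths:
# everything here works from raw species sets with explicit loops.

# plain 0/1 matrix without the class and flag attributes, for identical()
bare <- function(m) {
  x <- unclass(m)
  attr(x, "empty_sites") <- NULL
  x
}

random_incidence <- function(n_sites, n_species, p = 0.4) {
  repeat {
    x <- matrix(rbinom(n_sites * n_species, 1L, p), n_sites, n_species,
                dimnames = list(paste0("s", seq_len(n_sites)),
                                paste0("sp", seq_len(n_species))))
    if (all(rowSums(x) > 0L) && all(colSums(x) > 0L))
      return(incidence_matrix(x))
  }
}

site_sets <- function(m) {
  apply(unclass(m), 1L, function(r) colnames(m)[r == 1L], simplify = FALSE)
}

brute_pair <- function(m, i, j) {
  s <- site_sets(m)
  a <- length(intersect(s[[i]], s[[j]]))
  b <- length(setdiff(s[[i]], s[[j]]))
  cc <- length(setdiff(s[[j]], s[[i]]))
  sor <- if (b + cc == 0) 0 else (b + cc) / (2 * a + b + cc)
  sim <- if (min(b, cc) == 0) 0 else min(b, cc) / (a + min(b, cc))
  c(a = a, b = b, c = cc, sor = sor, sim = sim, sne = sor - sim)
}

brute_multisite <- function(m) {
  s <- site_sets(m)
  n <- length(s)
  smin <- smax <- 0
  for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n)) {
    bij <- length(setdiff(s[[i]], s[[j]]))
    bji <- length(setdiff(s[[j]], s[[i]]))
    smin <- smin + min(bij, bji)
    smax <- smax + max(bij, bji)
  }
  K <- sum(lengths(s)) - length(unique(unlist(s)))
  sim <- if (smin + K > 0) smin / (smin + K) else 0
  sor <- if (2 * K + smin + smax > 0)
    (smin + smax) / (2 * K + smin + smax) else 0
  c(beta_sor = sor, beta_sim = sim, beta_sne = sor - sim)
}

# step-by-step average-linkage agglomeration recomputing every
# cluster-to-cluster distance from the original matrix at each step
brute_upgma_heights <- function(d) {
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_len(length(clusters) - 1L))
      for (j in seq((i + 1L), length(clusters))) {
        dd <- mean(d[clusters[[i]], clusters[[j]]])
        if (dd < best_d) {best <- c(i, j); best_d <- dd}
      }
    heights <- c(heights, best_d)
    clusters[[best[1L]]] <- c(clusters[[best[1L]]], clusters[[best[2L]]])
    clusters[[best[2L]]] <- NULL
  }
  heights
}

# additive partition from first principles: mean richness of pooled unit
# species sets per level
brute_partition <- function(m, h) {
  s <- site_sets(m)
  names(s) <- rownames(m)
  lv <- attr(h, "levels")
  alpha <- vapply(lv, function(l) {
    units <- unique(h[[l]])
    mean(vapply(units, function(u) {
      length(unique(unlist(s[h$site[h[[l]] == u]])))
    }, numeric(1)))
  }, numeric(1))
  gamma <- length(unique(unlist(s)))
  c(alpha[1L], diff(alpha), gamma - alpha[length(alpha)])
}

toy_partition_fixture <- function() {
  m <- incidence_matrix(rbind(
    p1 = c(1, 1, 0, 0, 0, 0), p2 = c(0, 1, 1, 0, 0, 0),
    p3 = c(0, 0, 0, 1, 1, 0), p4 = c(0, 0, 0, 0, 1, 1)))
  h <- site_hierarchy(data.frame(site = paste0("p", 1:4),
                                 plot = paste0("p", 1:4),
                                 mountain = c("M1", "M1", "M2", "M2")))
  list(m = m, h = h)
}
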