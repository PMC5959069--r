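#' Run the full multi-scale diversity analysis
#'
#' Reproduces the complete analysis sequence for one or two communities
#' (e.g. host plants and their galls) sampled over the same hierarchy:
#' richness summaries; multiple-site beta decomposition, both for the full
#' site set and as the mean of subset-resampling draws; additive
#' partitioning across all hierarchy levels with randomization-based
#' significance; local-versus-regional richness regression; and UPGMA trees
#' of the pairwise turnover and nestedness-resultant matrices. When the
#' hierarchy has a top level with several units (e.g. two mountain ranges),
#' the same routine is applied to each top-level unit separately. All
#' randomness flows from one master seed, split deterministically per stage,
#' so a rerun with the same inputs and seed gives byte-identical output.
#'
#' @param plants an [incidence_matrix()] (the primary community)
#' @param galls optional second [incidence_matrix()] over the same sites;
#'   sites where it records nothing are dropped from its dissimilarity
#'   computations
#' @param hierarchy a [site_hierarchy()] covering the sites
#' @param subset_size,n_resamples passed to [beta_sample()]
#' @param n_null passed to [partition_significance()]
#' @param seed master seed
#' @param regional_level level used for the local-regional regression;
#'   default the second hierarchy level
#' @param per_range also analyse each top-level unit separately
#' @param out_dir if given, write the report bundle there: a JSON summary,
#'   partition and dissimilarity tables, Newick trees, and a log with seeds
#'   and input checksums
#' @return nested list of class \code{betascale_report}
#' @export
run_full_analysis <- function(plants, galls = NULL, hierarchy,
                              subset_size = 10, n_resamples = 1000,
                              n_null = 999, seed = 1L,
                              regional_level = NULL, per_range = TRUE,
                              out_dir = NULL) {
  stopifnot(inherits(plants, "incidence_matrix"),
            inherits(hierarchy, "site_hierarchy"))
  lv <- attr(hierarchy, "levels")
  if (is.null(regional_level))
    regional_level <- if (length(lv) >= 2L) lv[2L] else lv[1L]
  set.seed(seed)
  stage_seeds <- sample.int(.Machine$integer.max, 64L)
  next_seed <- local({i <- 0L; function() {i <<- i + 1L; stage_seeds[i]}})

  communities <- list(plants = plants)
  if (!is.null(galls)) communities$galls <- galls

  analyse_set <- function(m, h, label) {
    m <- check_no_empty(m, drop_empty = TRUE)
    res <- list(label = label, n_sites = nrow(m))
    res$richness <- richness_summary(m)
    res$multisite <- multisite_beta(m)
    res$resample <- tryCatch(
      beta_sample(m, subset_size = min(subset_size, nrow(m)),
                  n_reps = n_resamples, seed = next_seed()),
      error = function(e) {warning("resample stage (", label, "): ",
                                   conditionMessage(e)); NULL})
    res$partition <- tryCatch(
      partition_significance(m, h, n_null = n_null, seed = next_seed()),
      error = function(e) {warning("partition stage (", label, "): ",
                                   conditionMessage(e)); NULL})
    res$regression <- tryCatch(
      local_regional_regression(m, h, regional_level),
      error = function(e) {warning("regression stage (", label, "): ",
                                   conditionMessage(e)); NULL})
    pb <- pairwise_beta_matrices(m)
    res$pairwise <- pb
    res$tree_sim <- if (nrow(m) >= 2L) cluster_beta(pb, "beta_sim")
    res$tree_sne <- if (nrow(m) >= 2L) cluster_beta(pb, "beta_sne")
    res
  }

  report <- list(seed = seed, subset_size = subset_size,
                 n_resamples = n_resamples, n_null = n_null,
                 levels = lv, regional_level = regional_level)
  report$all <- lapply(names(communities), function(nm) {
    analyse_set(communities[[nm]], hierarchy, paste0(nm, "/all"))
  })
  names(report$all) <- names(communities)

  top <- lv[length(lv)]
  top_units <- unique(hierarchy[[top]])
  if (per_range && length(lv) >= 2L && length(top_units) > 1L) {
    report$per_range <- lapply(top_units, function(u) {
      keep <- hierarchy$site[hierarchy[[top]] == u]
      sub_h <- site_hierarchy(
        as.data.frame(hierarchy)[hierarchy[[top]] == u,
                                 c("site", lv[-length(lv)]), drop = FALSE])
      out <- lapply(names(communities), function(nm) {
        m <- communities[[nm]]
        m_keep <- intersect(keep, rownames(m))
        analyse_set(subset_sites(m, m_keep), sub_h, paste0(nm, "/", u))
      })
      names(out) <- names(communities)
      out
    })
    names(report$per_range) <- top_units
  }
  class(report) <- "betascale_report"
  if (!is.null(out_dir))
    write_report(report, communities, hierarchy, out_dir)
  report
}

#' @export
print.betascale_report <- function(x, ...) {
  cat(sprintf("multi-scale diversity report (seed %d)\n", x$seed))
  for (nm in names(x$all)) {
    a <- x$all[[nm]]
    cat(sprintf("\n== %s: %d sites, gamma = %d ==\n", nm, a$n_sites,
                a$richness$gamma))
    print(a$multisite)
    if (!is.null(a$resample))
      cat(sprintf("resample means (%d x %d sites): beta_sor %.4f, beta_sim %.4f, beta_sne %.4f\n",
                  a$resample$n_reps, a$resample$subset_size,
                  a$resample$summary["mean", "beta_sor"],
                  a$resample$summary["mean", "beta_sim"],
                  a$resample$summary["mean", "beta_sne"]))
    if (!is.null(a$partition)) print(a$partition)
    if (!is.null(a$regression)) print(a$regression)
  }
  invisible(x)
}

summarize_set <- function(a) {
  out <- list(
    n_sites = a$n_sites,
    gamma = a$richness$gamma,
    mean_alpha = a$richness$mean_alpha,
    multisite = a$multisite[c("beta_sor", "beta_sim", "beta_sne")])
  if (!is.null(a$resample))
    out$resample_mean <- as.list(a$resample$summary["mean", ])
  if (!is.null(a$partition))
    out$partition <- a$partition$components
  if (!is.null(a$regression))
    out$regression <- a$regression[c("slope", "intercept", "r_squared",
                                     "f_statistic", "df_num", "df_den",
                                     "p_value")]
  out
}

write_report <- function(report, communities, hierarchy, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  summary <- list(
    seed = report$seed, subset_size = report$subset_size,
    n_resamples = report$n_resamples, n_null = report$n_null,
    levels = report$levels,
    all = lapply(report$all, summarize_set))
  if (!is.null(report$per_range))
    summary$per_range <- lapply(report$per_range,
                                function(u) lapply(u, summarize_set))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (nm in names(report$all)) {
    a <- report$all[[nm]]
    if (!is.null(a$partition))
      write_partition(a$partition,
                      file.path(out_dir, paste0(nm, "_partition.tsv")))
    write_dissimilarity(a$pairwise$beta_sim,
                        file.path(out_dir, paste0(nm, "_beta_sim.tsv")))
    write_dissimilarity(a$pairwise$beta_sne,
                        file.path(out_dir, paste0(nm, "_beta_sne.tsv")))
    if (!is.null(a$tree_sim))
      writeLines(tree_to_newick(a$tree_sim),
                 file.path(out_dir, paste0(nm, "_upgma_beta_sim.nwk")))
    if (!is.null(a$tree_sne))
      writeLines(tree_to_newick(a$tree_sne),
                 file.path(out_dir, paste0(nm, "_upgma_beta_sne.nwk")))
  }
  checksum <- function(m) {
    f <- tempfile(fileext = ".tsv")
    on.exit(unlink(f))
    write_incidence(m, f, layout = "wide")
    unname(tools::md5sum(f))
  }
  log <- c(sprintf("betascale %s", as.character(utils::packageVersion("betascale"))),
           sprintf("R %s", as.character(getRversion())),
           sprintf("seed %d", report$seed),
           sprintf("subset_size %d n_resamples %d n_null %d",
                   report$subset_size, report$n_resamples, report$n_null),
           vapply(names(communities), function(nm) {
             sprintf("input %s: %d sites x %d species, md5 %s", nm,
                     nrow(communities[[nm]]), ncol(communities[[nm]]),
                     checksum(communities[[nm]]))
           }, character(1)))
  writeLines(log, file.path(out_dir, "run.log"))
  invisible(out_dir)
}
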