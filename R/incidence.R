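#' Construct a binary incidence matrix
#'
#' An incidence matrix is the substrate of every statistic in this package:
#' a sites-by-species 0/1 matrix where entry 1 means the species was recorded
#' at the site. Site richness is the row sum; regional (gamma) richness is the
#' number of species columns, every one of which must be occupied somewhere.
#'
#' @param x a numeric or logical matrix (or object coercible to one) with
#'   sites in rows and species in columns; dimnames are used as site and
#'   species labels. Labels are trimmed of surrounding whitespace and matched
#'   exactly (case-sensitive); no fuzzy taxon matching is attempted.
#' @param drop_absent drop species columns with no occurrences instead of
#'   raising an error. Useful when subsetting sites from a larger matrix.
#' @return an object of class \code{incidence_matrix}: an integer 0/1 matrix
#'   with site and species dimnames. Sites with zero recorded species are
#'   accepted but flagged (attribute \code{empty_sites}); dissimilarity
#'   functions reject them unless asked to drop them.
#' @seealso [read_incidence()], [aggregate_incidence()], [richness_summary()]
#' @export
incidence_matrix <- function(x, drop_absent = FALSE) {
  x <- as.matrix(x)
  if (length(x) == 0L) stop("incidence matrix is empty")
  if (is.logical(x)) storage.mode(x) <- "integer"
  if (!is.numeric(x)) stop("incidence matrix must be numeric or logical")
  bad <- which(!(x %in% c(0, 1)))
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% nrow(x)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(x)) + 1L
    stop(sprintf("non-binary cell %s at row %d ('%s'), column %d ('%s')",
                 format(x[bad[1L]]), i, rownames(x)[i] %||% i,
                 j, colnames(x)[j] %||% j))
  }
  storage.mode(x) <- "integer"
  if (is.null(rownames(x))) rownames(x) <- paste0("site", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("sp", seq_len(ncol(x)))
  rownames(x) <- trimws(rownames(x))
  colnames(x) <- trimws(colnames(x))
  if (anyDuplicated(rownames(x)))
    stop("duplicate site labels: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  if (anyDuplicated(colnames(x)))
    stop("duplicate species labels: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  absent <- colSums(x) == 0L
  if (any(absent)) {
    if (!drop_absent)
      stop("species never recorded at any site: ",
           paste(utils::head(colnames(x)[absent], 5L), collapse = ", "),
           if (sum(absent) > 5L) sprintf(" (and %d more)", sum(absent) - 5L))
    x <- x[, !absent, drop = FALSE]
    if (ncol(x) == 0L) stop("no occupied species columns remain")
  }
  empty <- rownames(x)[rowSums(x) == 0L]
  structure(x, empty_sites = empty,
            class = c("incidence_matrix", class(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.incidence_matrix <- function(x, ...) {
  cat(sprintf("incidence matrix: %d sites x %d species, gamma = %d\n",
              nrow(x), ncol(x), ncol(x)))
  empty <- attr(x, "empty_sites")
  if (length(empty))
    cat("empty sites (no species recorded):",
        paste(empty, collapse = ", "), "\n")
  invisible(x)
}

#' Subset sites of an incidence matrix
#'
#' Keeps the incidence-matrix class and revalidates, dropping species that no
#' longer occur in the retained sites.
#'
#' @param m an [incidence_matrix()]
#' @param sites site labels or indices to keep
#' @return an \code{incidence_matrix} over the retained sites
#' @export
subset_sites <- function(m, sites) {
  stopifnot(inherits(m, "incidence_matrix"))
  incidence_matrix(unclass(m)[sites, , drop = FALSE], drop_absent = TRUE)
}

drop_empty_sites <- function(m) {
  keep <- rowSums(m) > 0L
  if (all(keep)) return(m)
  incidence_matrix(unclass(m)[keep, , drop = FALSE], drop_absent = TRUE)
}

check_no_empty <- function(m, drop_empty = FALSE, caller = "this operation") {
  empty <- rownames(m)[rowSums(m) == 0L]
  if (!length(empty)) return(m)
  if (drop_empty) return(drop_empty_sites(m))
  stop(sprintf("%s is undefined for sites with no species (%s); %s",
               caller, paste(utils::head(empty, 5L), collapse = ", "),
               "set drop_empty = TRUE to discard them"))
}

detect_sep <- function(path) {
  if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
}

#' Read an incidence matrix from delimited text
#'
#' Two layouts are supported. \code{wide}: first column holds site labels, the
#' remaining columns are species with 0/1 cells. \code{long}: two columns
#' (site, species), one row per occurrence; duplicated occurrences are
#' deduplicated. Site and species order follow first appearance in the file,
#' so a given input always yields the same matrix.
#'
#' @param path a \code{.csv} (comma) or \code{.tsv}/\code{.txt} (tab) file;
#'   UTF-8.
#' @param layout \code{"wide"} or \code{"long"}
#' @param sep field separator; defaults by file extension
#' @inheritParams incidence_matrix
#' @return an [incidence_matrix()]
#' @export
read_incidence <- function(path, layout = c("wide", "long"),
                           sep = detect_sep(path), drop_absent = FALSE) {
  layout <- match.arg(layout)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = if (layout == "long") "character" else NA,
                          fileEncoding = "UTF-8")
  if (nrow(df) == 0L) stop("empty file: ", path)
  if (layout == "wide") {
    sites <- trimws(as.character(df[[1L]]))
    if (anyDuplicated(sites))
      stop("duplicate site row labels in ", path, ": ",
           paste(unique(sites[duplicated(sites)]), collapse = ", "))
    mat <- as.matrix(df[, -1L, drop = FALSE])
    rownames(mat) <- sites
    incidence_matrix(mat, drop_absent = drop_absent)
  } else {
    if (ncol(df) < 2L) stop("long layout needs two columns (site, species)")
    long_to_incidence(df[[1L]], df[[2L]], drop_absent = drop_absent)
  }
}

long_to_incidence <- function(site, species, drop_absent = FALSE) {
  site <- trimws(as.character(site)); species <- trimws(as.character(species))
  sites <- unique(site); spp <- unique(species)
  mat <- matrix(0L, length(sites), length(spp), dimnames = list(sites, spp))
  mat[cbind(match(site, sites), match(species, spp))] <- 1L
  incidence_matrix(mat, drop_absent = drop_absent)
}

#' Write an incidence matrix to delimited text
#'
#' The inverse of [read_incidence()]: reading back the written file in the
#' same layout reproduces the matrix exactly.
#'
#' @param m an [incidence_matrix()]
#' @param path output file; extension picks the separator
#' @param layout \code{"wide"} or \code{"long"}
#' @param sep field separator; defaults by file extension
#' @return \code{path}, invisibly
#' @export
write_incidence <- function(m, path, layout = c("wide", "long"),
                            sep = detect_sep(path)) {
  stopifnot(inherits(m, "incidence_matrix"))
  layout <- match.arg(layout)
  if (layout == "wide") {
    df <- data.frame(site = rownames(m), unclass(m), check.names = FALSE)
  } else {
    idx <- which(unclass(m) == 1L, arr.ind = TRUE)
    idx <- idx[order(idx[, "row"], idx[, "col"]), , drop = FALSE]
    df <- data.frame(site = rownames(m)[idx[, "row"]],
                     species = colnames(m)[idx[, "col"]])
  }
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Construct a site hierarchy
#'
#' Describes the nested spatial design: every site carries one unit label per
#' level, levels ordered lowest (the site itself, e.g. plot) to highest
#' (e.g. mountain range). Nesting must be consistent: two sites sharing a unit
#' at some level must share units at every higher level.
#'
#' @param df data.frame whose first column is the site label and remaining
#'   columns, lowest level first, give the unit label of each site at that
#'   level
#' @return object of class \code{site_hierarchy}: the validated data.frame
#'   with attribute \code{levels}
#' @export
site_hierarchy <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("hierarchy needs a site column and >= 1 level")
  df[] <- lapply(df, function(v) trimws(as.character(v)))
  names(df)[1L] <- "site"
  if (anyDuplicated(df$site))
    stop("duplicate sites in hierarchy: ",
         paste(unique(df$site[duplicated(df$site)]), collapse = ", "))
  lv <- names(df)[-1L]
  if (anyDuplicated(df[[lv[1L]]]))
    stop("lowest level must have one site per unit; duplicated: ",
         paste(unique(df[[lv[1L]]][duplicated(df[[lv[1L]]])]), collapse = ", "))
  for (k in seq_along(lv)[-length(lv)]) {
    parent_of <- tapply(df[[lv[k + 1L]]], df[[lv[k]]],
                        function(p) length(unique(p)))
    bad <- names(parent_of)[parent_of > 1L]
    if (length(bad))
      stop(sprintf("inconsistent nesting: unit(s) %s at level '%s' appear under multiple '%s' units",
                   paste(bad, collapse = ", "), lv[k], lv[k + 1L]))
  }
  structure(df, levels = lv, class = c("site_hierarchy", "data.frame"))
}

#' @export
print.site_hierarchy <- function(x, ...) {
  lv <- attr(x, "levels")
  counts <- vapply(lv, function(l) length(unique(x[[l]])), integer(1))
  cat(sprintf("site hierarchy: %d sites; levels: %s\n", nrow(x),
              paste(sprintf("%s (%d)", lv, counts), collapse = " < ")))
  invisible(x)
}

#' Read a site hierarchy from delimited text
#'
#' Columns: site label, then one column per level, lowest to highest.
#'
#' @inheritParams read_incidence
#' @return a [site_hierarchy()]
#' @export
read_hierarchy <- function(path, sep = detect_sep(path)) {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, colClasses = "character",
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (nrow(df) == 0L) stop("empty file: ", path)
  site_hierarchy(df)
}

match_hierarchy <- function(m, h) {
  miss <- setdiff(rownames(m), h$site)
  if (length(miss))
    stop("sites in incidence but absent from hierarchy: ",
         paste(utils::head(miss, 5L), collapse = ", "))
  h[match(rownames(m), h$site), , drop = FALSE]
}

#' Aggregate an incidence matrix to a hierarchy level
#'
#' One row per unit at the requested level; a species is present in a unit if
#' it is present in any member site (logical union). Gamma richness is
#' unchanged by aggregation, and no unit can be poorer than its member sites.
#'
#' @param m an [incidence_matrix()]
#' @param h a [site_hierarchy()] covering the sites of \code{m}
#' @param level a level name of \code{h}
#' @return an \code{incidence_matrix} over the units of \code{level}, in
#'   first-appearance order
#' @export
aggregate_incidence <- function(m, h, level) {
  stopifnot(inherits(m, "incidence_matrix"), inherits(h, "site_hierarchy"))
  lv <- attr(h, "levels")
  if (!level %in% lv)
    stop("unknown level '", level, "'; available: ", paste(lv, collapse = ", "))
  hh <- match_hierarchy(m, h)
  g <- factor(hh[[level]], levels = unique(hh[[level]]))
  agg <- rowsum(unclass(m), g, reorder = FALSE)
  incidence_matrix((agg > 0L) * 1L)
}

#' Richness summary of an incidence matrix
#'
#' Per-site richness, regional (gamma) richness, and mean alpha richness (the
#' arithmetic mean of site richnesses).
#'
#' @param m an [incidence_matrix()]
#' @return a list of class \code{richness_summary} with elements
#'   \code{per_site_richness} (named integer vector), \code{gamma} and
#'   \code{mean_alpha}
#' @export
richness_summary <- function(m) {
  stopifnot(inherits(m, "incidence_matrix"))
  s <- rowSums(unclass(m))
  structure(list(per_site_richness = s, gamma = ncol(m),
                 mean_alpha = mean(s)),
            class = "richness_summary")
}

#' @export
print.richness_summary <- function(x, ...) {
  cat(sprintf("gamma = %d, mean alpha = %.2f over %d sites (range %d-%d)\n",
              x$gamma, x$mean_alpha, length(x$per_site_richness),
              min(x$per_site_richness), max(x$per_site_richness)))
  invisible(x)
}

#' Read a spreadsheet occurrence table
#'
#' Convenience reader for workbook-deposited occurrence data (for example a
#' supplementary XLSX listing plants per sample point). Column mapping is
#' explicit because deposited sheets rarely share a layout: name the columns
#' holding the site and species labels; all other columns (coordinates,
#' richness tallies) are ignored.
#'
#' @param path an \code{.xlsx} file (requires the \pkg{readxl} package)
#' @param site_col,species_col names (or positions) of the site and species
#'   columns in the first sheet; a header row is expected
#' @param sheet sheet to read, default the first
#' @inheritParams incidence_matrix
#' @return an [incidence_matrix()]
#' @export
read_incidence_xlsx <- function(path, site_col, species_col, sheet = 1,
                                drop_absent = FALSE) {
  if (!requireNamespace("readxl", quietly = TRUE))
    stop("reading .xlsx requires the 'readxl' package")
  df <- as.data.frame(readxl::read_excel(path, sheet = sheet))
  long_to_incidence(df[[site_col]], df[[species_col]],
                    drop_absent = drop_absent)
}
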