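test_that("long-layout reading counts occurrences and deduplicates", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("site,species", "P1,sp1", "P1,sp2", "P2,sp2"), f)
  m <- read_incidence(f, layout = "long")
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(unname(rowSums(unclass(m))), c(2, 1))
  expect_equal(ncol(m), 2L)

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("site,species", "P1,sp1", "P1,sp2", "P2,sp2", "P1,sp2"), f2)
  expect_identical(unclass(read_incidence(f2, layout = "long")),
                   unclass(m))
})

test_that("wide-layout contract errors carry position information", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("site,sp1,sp2", "P1,1,2", "P2,0,1"), f)
  expect_error(read_incidence(f, layout = "wide"), "row 1.*column 2|sp2")

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("site,sp1", "P1,1", "P1,0"), f2)
  expect_error(read_incidence(f2, layout = "wide"), "duplicate site")

  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines("site,sp1", f3)
  expect_error(read_incidence(f3), "empty")
})

test_that("write then read round-trips both layouts exactly", {
  set.seed(42)
  m <- random_incidence(7, 13)
  for (layout in c("wide", "long")) {
    for (ext in c(".csv", ".tsv")) {
      f <- withr::local_tempfile(fileext = ext)
      write_incidence(m, f, layout = layout)
      m2 <- read_incidence(f, layout = layout)
      expect_identical(bare(m2)[rownames(m), colnames(m)], bare(m),
                       label = paste(layout, ext))
    }
  }
})

test_that("species labels are trimmed and matched exactly", {
  m <- incidence_matrix(matrix(c(1, 1), 2, 1,
                               dimnames = list(c(" A ", "B"), " sp1 ")))
  expect_identical(rownames(m), c("A", "B"))
  expect_identical(colnames(m), "sp1")
  expect_error(incidence_matrix(matrix(1, 2, 2,
                                       dimnames = list(c("A", "A "),
                                                       c("x", "y")))),
               "duplicate site")
})

test_that("all-zero species columns are rejected unless dropped", {
  x <- cbind(sp1 = c(1, 1), sp2 = c(0, 0))
  rownames(x) <- c("A", "B")
  expect_error(incidence_matrix(x), "never recorded")
  expect_equal(colnames(incidence_matrix(x, drop_absent = TRUE)), "sp1")
})

test_that("empty sites are flagged at construction and rejected downstream", {
  x <- rbind(A = c(1, 1), B = c(0, 0), C = c(1, 0))
  colnames(x) <- c("sp1", "sp2")
  m <- incidence_matrix(x)
  expect_identical(attr(m, "empty_sites"), "B")
  expect_error(multisite_beta(m), "empty|undefined")
  expect_error(pairwise_beta_matrices(m), "empty|undefined")
  ok <- multisite_beta(m, drop_empty = TRUE)
  expect_equal(ok$n_sites, 2L)
})

test_that("hierarchy validation enforces consistent nesting", {
  df <- data.frame(site = paste0("p", 1:4), plot = paste0("p", 1:4),
                   mountain = c("M1", "M1", "M2", "M2"),
                   range = "R1")
  h <- site_hierarchy(df)
  expect_identical(attr(h, "levels"), c("plot", "mountain", "range"))
  expect_equal(length(unique(h$mountain)), 2L)

  bad <- df
  bad$range <- c("R1", "R2", "R1", "R1")   # M1 under two ranges
  expect_error(site_hierarchy(bad), "inconsistent nesting")

  single <- site_hierarchy(df[, c("site", "plot")])
  expect_identical(attr(single, "levels"), "plot")
})

test_that("hierarchy and incidence must cover the same sites at join time", {
  fix <- toy_partition_fixture()
  m5 <- incidence_matrix(rbind(unclass(fix$m), p9 = c(1, 0, 0, 0, 0, 0)))
  expect_error(aggregate_incidence(m5, fix$h, "mountain"),
               "absent from hierarchy")
  expect_error(additive_partition(m5, fix$h), "absent from hierarchy")
})

test_that("aggregation takes unions, preserves gamma, is identity at base level", {
  fix <- toy_partition_fixture()
  mm <- aggregate_incidence(fix$m, fix$h, "mountain")
  expect_equal(nrow(mm), 2L)
  expect_equal(unname(unclass(mm)["M1", ]), c(1, 1, 1, 0, 0, 0))
  expect_identical(unclass(aggregate_incidence(fix$m, fix$h, "plot")),
                   unclass(fix$m))
  expect_error(aggregate_incidence(fix$m, fix$h, "continent"),
               "unknown level")

  set.seed(7)
  for (rep in 1:20) {
    m <- random_incidence(12, 15)
    h <- site_hierarchy(data.frame(site = rownames(m), plot = rownames(m),
                                   mountain = rep(c("M1", "M2", "M3"),
                                                  each = 4),
                                   range = rep(c("R1", "R2"), c(8, 4))))
    rich <- lapply(attr(h, "levels"), function(l) {
      a <- aggregate_incidence(m, h, l)
      list(gamma = ncol(a), max_unit = max(rowSums(unclass(a))),
           min_unit = min(rowSums(unclass(a))))
    })
    expect_true(all(vapply(rich, `[[`, numeric(1), "gamma") == ncol(m)))
    # higher-level units can never be poorer than any of their members
    mins <- vapply(rich, `[[`, numeric(1), "min_unit")
    expect_true(all(diff(mins) >= 0))
  }
})

test_that("richness summary reports per-site richness, gamma and mean alpha", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("site,species", "P1,sp1", "P1,sp2", "P2,sp2"), f)
  rs <- richness_summary(read_incidence(f, layout = "long"))
  expect_equal(unname(rs$per_site_richness), c(2, 1))
  expect_equal(rs$gamma, 2L)
  expect_equal(rs$mean_alpha, 1.5)

  same <- incidence_matrix(matrix(1, 4, 3,
                                  dimnames = list(paste0("s", 1:4),
                                                  paste0("sp", 1:3))))
  rs2 <- richness_summary(same)
  expect_equal(rs2$mean_alpha, rs2$gamma)

  set.seed(9)
  for (rep in 1:10) {
    rs3 <- richness_summary(random_incidence(8, 20))
    expect_lte(rs3$mean_alpha, rs3$gamma)
  }
})
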