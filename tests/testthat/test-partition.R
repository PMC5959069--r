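test_that("additive partition reproduces the worked four-plot example", {
  fix <- toy_partition_fixture()
  p <- additive_partition(fix$m, fix$h)
  expect_equal(p$gamma, 6)
  expect_equal(unname(p$alpha), c(2, 3))
  expect_equal(unname(p$beta), c(1, 3))
  expect_equal(round(p$components$percent, 2), c(33.33, 16.67, 50.00))
  expect_equal(sum(p$components$species), p$gamma)
})

test_that("degenerate hierarchies partition cleanly", {
  # all plots identical: every beta component 0, alpha1 = gamma
  m <- incidence_matrix(matrix(1, 4, 5,
                               dimnames = list(paste0("p", 1:4),
                                               paste0("sp", 1:5))))
  h <- site_hierarchy(data.frame(site = paste0("p", 1:4),
                                 plot = paste0("p", 1:4),
                                 mountain = c("M1", "M1", "M2", "M2")))
  p <- additive_partition(m, h)
  expect_equal(unname(p$beta), c(0, 0))
  expect_equal(unname(p$alpha[1L]), p$gamma)

  # one plot, one mountain: alpha1 = gamma, beta 0
  h1 <- site_hierarchy(data.frame(site = "p1", plot = "p1",
                                  mountain = "M1"))
  m1 <- subset_sites(m, "p1")
  p1 <- additive_partition(m1, h1)
  expect_equal(unname(p1$alpha[1L]), p1$gamma)
  expect_equal(unname(sum(p1$beta)), 0)
})

test_that("additive identity holds exactly on random and synthetic data", {
  set.seed(21)
  for (rep in 1:25) {
    m <- random_incidence(12, 18)
    h <- site_hierarchy(data.frame(site = rownames(m), plot = rownames(m),
                                   mountain = rep(paste0("M", 1:4),
                                                  each = 3),
                                   range = rep(c("R1", "R2"), each = 6)))
    p <- additive_partition(m, h)
    expect_equal(unname(p$alpha[1L] + sum(p$beta)), p$gamma)
    expect_equal(unname(diff(p$alpha)),
                 unname(p$beta[-length(p$beta)]))
    expect_equal(sum(p$components$percent), 100)
    expect_equal(brute_partition(m, h), p$components$species,
                 ignore_attr = TRUE)
  }
})

test_that("observed components agree with vegan's additive partition", {
  skip_if_not_installed("vegan")
  set.seed(31)
  m <- random_incidence(12, 30)
  h <- site_hierarchy(data.frame(site = rownames(m), plot = rownames(m),
                                 mountain = rep(paste0("M", 1:4), each = 3),
                                 range = rep(c("R1", "R2"), each = 6)))
  p <- additive_partition(m, h)
  hier <- data.frame(plot = factor(h$plot, levels = unique(h$plot)),
                     mountain = factor(h$mountain,
                                       levels = unique(h$mountain)),
                     range = factor(h$range, levels = unique(h$range)),
                     all = factor(1))
  v <- suppressWarnings(
    vegan::adipart(unclass(m), hier, index = "richness",
                   weights = "unif", relative = FALSE, nsimul = 2))
  vobs <- v$statistic
  expect_equal(unname(vobs[c("alpha.1", "alpha.2", "alpha.3")]),
               unname(p$alpha), tolerance = 1e-10)
  expect_equal(unname(vobs[c("beta.1", "beta.2", "beta.3")]),
               unname(p$beta), tolerance = 1e-10)
  expect_equal(unname(vobs["gamma"]), p$gamma)
})

test_that("null randomization keeps unit sizes, fixes alpha1, is seeded", {
  set.seed(41)
  m <- random_incidence(12, 18)
  h <- site_hierarchy(data.frame(site = rownames(m), plot = rownames(m),
                                 mountain = rep(paste0("M", 1:4), each = 3),
                                 range = rep(c("R1", "R2"), each = 6)))
  ps1 <- partition_significance(m, h, n_null = 99, seed = 7)
  ps2 <- partition_significance(m, h, n_null = 99, seed = 7)
  expect_identical(ps1$null_draws, ps2$null_draws)
  expect_identical(ps1$components, ps2$components)

  # alpha1 invariant under the sample-based null: null variance exactly 0
  expect_equal(unname(stats::sd(ps1$null_draws[, "alpha1"])), 0)
  expect_equal(unname(ps1$null_draws[1L, "alpha1"]),
               unname(ps1$alpha[1L]))
  # additive identity holds for every null draw
  sums <- ps1$null_draws[, "alpha1"] + ps1$null_draws[, "beta1"] +
    ps1$null_draws[, "beta2"] + ps1$null_draws[, "beta3"]
  expect_equal(unname(sums), rep(ps1$gamma, 99))
  expect_true(all(ps1$components$p_value > 0 &
                    ps1$components$p_value <= 1))
})

test_that("identical plots give flat nulls with p = 1", {
  m <- incidence_matrix(matrix(1, 6, 4,
                               dimnames = list(paste0("p", 1:6),
                                               paste0("sp", 1:4))))
  h <- site_hierarchy(data.frame(site = paste0("p", 1:6),
                                 plot = paste0("p", 1:6),
                                 mountain = rep(c("M1", "M2", "M3"),
                                                each = 2)))
  ps <- partition_significance(m, h, n_null = 49, seed = 2)
  expect_equal(unname(ps$beta), c(0, 0))
  expect_equal(ps$components$p_value, rep(1, 3))
})

test_that("strong turnover yields the minimum attainable two-tailed p", {
  sim <- simulate_metacommunity(synthetic_config(
    turnover_weight = 1, detection = "exhaustive", seed = 5))
  ps <- partition_significance(sim$plants, sim$hierarchy, n_null = 99,
                               seed = 13)
  obs_b2 <- ps$components$species[ps$components$component == "beta2"]
  expect_true(all(ps$null_draws[, "beta2"] < obs_b2))
  expect_equal(ps$components$p_value[ps$components$component == "beta2"],
               2 / (99 + 1))
})

test_that("partition tables serialize with expected and p-value columns", {
  fix <- toy_partition_fixture()
  ps <- partition_significance(fix$m, fix$h, n_null = 19, seed = 1)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_partition(ps, f)
  back <- read.delim(f)
  expect_identical(names(back),
                   c("component", "level", "species", "percent",
                     "expected", "expected_percent", "p_value"))
  expect_equal(back$species, ps$components$species)
})
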