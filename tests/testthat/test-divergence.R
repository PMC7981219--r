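# Natural-breaks classification and the signed divergent-sympatry
# statistic with its composition tests.

test_that("Fisher-Jenks finds the obvious three clusters", {
  v <- c(1, 2, 3, 10, 11, 12, 100, 101, 102)
  names(v) <- letters[1:9]
  cls <- classify_sizes(v, k = 3)
  expect_equal(unname(cls$counts), c(3L, 3L, 3L))
  expect_equal(as.character(cls$class[c("a", "d", "g")]),
               c("small", "medium", "large"))
  expect_equal(cls$breaks, c(3, 12))
})

test_that("k equal to the number of distinct values gives zero within-class SS", {
  v <- stats::setNames(c(5, 9, 14, 20), letters[1:4])
  cls <- classify_sizes(v, k = 4)
  expect_equal(cls$within_ss, 0)
  expect_equal(length(unique(cls$class)), 4)
  expect_error(classify_sizes(stats::setNames(rep(7, 5), letters[1:5]), k = 3),
               "distinct")
})

test_that("optimal breaks match exhaustive enumeration on random vectors", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(6:15, 1)
    v <- stats::setNames(round(runif(n, 40, 115), 1), paste0("s", seq_len(n)))
    if (length(unique(v)) < 4) next
    cls <- classify_sizes(v, k = 3)
    oracle <- jenks_exhaustive_3(v)
    expect_equal(cls$within_ss, oracle$ss, tolerance = 1e-9)
    expect_equal(cls$breaks, oracle$breaks)
  }
})

test_that("explicit breaks override the optimiser and ties go to the lower class", {
  v <- stats::setNames(c(50, 60, 61, 85, 86), paste0("s", 1:5))
  cls <- classify_sizes(v, breaks = c(60, 85))
  expect_equal(as.character(cls$class),
               c("small", "small", "medium", "medium", "large"))
})

test_that("divergent sympatry reproduces the uniform-pool hand cases", {
  # pool of 30 species (10 per class) around a small focal
  species <- c("focal", paste0("s", 1:10), paste0("m", 1:10), paste0("l", 1:10))
  classes <- c("small", rep(c("small", "medium", "large"), each = 10))
  names(classes) <- species
  cls <- fake_classes(classes)

  # O = (0, 5, 5), n = 10: chi2 = 5, own class under-represented -> +5
  r1 <- divergent_sympatry("focal",
                           fake_sympatry(species, "focal",
                                         c(paste0("m", 1:5), paste0("l", 1:5))),
                           cls)
  expect_equal(r1$observed, c(0, 5, 5))
  expect_equal(r1$expected, rep(10 / 3, 3))
  expect_equal(r1$chi2, 5, tolerance = 1e-12)
  expect_equal(r1$signed_score, 5, tolerance = 1e-12)

  # O = (10, 0, 0): chi2 = 20, own class over-represented -> -20
  r2 <- divergent_sympatry("focal",
                           fake_sympatry(species, "focal", paste0("s", 1:10)),
                           cls)
  expect_equal(r2$chi2, 20, tolerance = 1e-12)
  expect_equal(r2$sign, -1L)
  expect_equal(r2$signed_score, -20, tolerance = 1e-12)
})

test_that("zero sympatric congeners is flagged undefined, not scored", {
  species <- c("focal", "x", "y", "z")
  classes <- stats::setNames(c("small", "small", "medium", "large"), species)
  r <- divergent_sympatry("focal", fake_sympatry(species, "focal", character(0)),
                          fake_classes(classes))
  expect_false(r$defined)
  expect_true(is.na(r$signed_score))
})

test_that("observed and expected counts always sum to the sympatric count", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(10:25, 1)
    species <- c("focal", paste0("p", seq_len(n)))
    classes <- stats::setNames(
      c(sample(c("small", "medium", "large"), n + 1, replace = TRUE)), species)
    # ensure all three classes appear in the pool
    classes[2:4] <- c("small", "medium", "large")
    partners <- sample(species[-1], sample(1:n, 1))
    r <- divergent_sympatry("focal", fake_sympatry(species, "focal", partners),
                            fake_classes(classes))
    expect_equal(sum(r$observed), r$n_sympatric)
    expect_equal(sum(r$expected), r$n_sympatric, tolerance = 1e-9)
    expect_gte(r$chi2, 0)
    expect_equal(r$signed_score, r$sign * r$chi2)
  }
})

test_that("the genus pool can optionally include the focal species", {
  species <- c("focal", "a", "b", "c")
  classes <- stats::setNames(c("small", "small", "medium", "large"), species)
  symp <- fake_sympatry(species, "focal", c("a", "b", "c"))
  excl <- divergent_sympatry("focal", symp, fake_classes(classes))
  incl <- divergent_sympatry("focal", symp, fake_classes(classes),
                             include_focal = TRUE)
  expect_equal(excl$expected, rep(1, 3))
  expect_equal(incl$expected, 3 * c(2, 1, 1) / 4)
})

test_that("sign-category goodness of fit matches hand values", {
  mk <- function(scores) data.frame(
    focal = paste0("s", seq_along(scores)), class = "small",
    signed_score = scores, defined = TRUE)
  # exact uniformity
  t0 <- sign_category_test(mk(c(rep(2, 10), rep(0, 10), rep(-2, 10))),
                           "small", neutral_band = 1)
  expect_equal(t0$chi2, 0)
  expect_equal(t0$p_value, 1)
  # the 14:5:3 split against uniform 22/3
  t1 <- sign_category_test(mk(c(rep(2, 14), rep(0.5, 5), rep(-2, 3))),
                           "small", neutral_band = 1)
  expect_equal(unname(t1$counts), c(14L, 5L, 3L))
  expect_equal(t1$chi2, 9.3636, tolerance = 1e-4)
  expect_equal(t1$df, 2L)
  # (n, 0, 0) -> chi2 = 2n
  for (n in c(6, 12, 30)) {
    tn <- sign_category_test(mk(rep(2, n)), "small", neutral_band = 1)
    expect_equal(tn$chi2, 2 * n, tolerance = 1e-12)
  }
  expect_error(sign_category_test(mk(1)[0, ], "small"), "no defined")
})

test_that("bioregion size composition tests per-region class counts", {
  species <- paste0("s", 1:12)
  classes <- stats::setNames(rep(c("small", "medium", "large"), each = 4),
                             species)
  cls <- fake_classes(classes)
  asg <- structure(list(
    cell_region = c(c1 = 1L, c2 = 2L, c3 = 3L),
    region_species = list("1" = species,          # same proportions as genus
                          "2" = paste0("s", 1:4), # all small: O = (4,0,0)
                          "3" = "s1"),            # single species
    n_regions = 3L, seed = 1),
    class = "bioregion_assignment")
  res <- bioregion_size_composition(asg, cls)
  expect_equal(res[[1]]$chi2, 0, tolerance = 1e-12)
  # E = 4 * (1/3, 1/3, 1/3); chi2 = ((4 - 4/3)^2 + 2*(4/3)^2) / (4/3) = 8
  expect_equal(res[[2]]$chi2, 8, tolerance = 1e-9)
  expect_false(res[[3]]$tested)
})
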