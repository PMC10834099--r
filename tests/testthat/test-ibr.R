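test_that("standardization centers, scales, flips and shifts site means", {
  m <- matrix(rep(c(1, 2, 3), 3), nrow = 3,
              dimnames = list(c("S1", "S2", "S3"), c("cat", "gst", "ache")))
  std <- ibr_std(m, coefficient_table(c("cat", "gst", "ache"), c(1, 1, -1)))
  # sample SD of {1,2,3} is 1, so Y = {-1, 0, 1}
  expect_equal(unname(std$Y[, "cat"]), c(-1, 0, 1))
  expect_equal(unname(std$S[, "cat"]), c(0, 1, 2))   # shift by |-1|
  expect_equal(unname(std$Z[, "ache"]), c(1, 0, -1)) # coefficient -1 flips
  expect_equal(unname(std$S[, "ache"]), c(2, 1, 0))
  # per-biomarker invariants: mean(Y) = 0, sd(Y) = 1, min(S) = 0, S >= 0
  expect_equal(unname(colMeans(std$Y)), rep(0, 3))
  expect_equal(unname(apply(std$Y, 2, sd)), rep(1, 3))
  expect_equal(unname(apply(std$S, 2, min)), rep(0, 3))
  expect_true(all(std$S >= 0))
})

test_that("a biomarker with identical site means is rejected by name", {
  m <- matrix(c(1, 2, 3, 5, 5, 5, 2, 4, 6), nrow = 3,
              dimnames = list(paste0("S", 1:3), c("cat", "gst", "ache")))
  expect_error(ibr_std(m), "gst.*zero variance")
})

test_that("S-matrix invariants hold on random standardizations", {
  for (seed in 1:20) {
    tab <- make_table(n_sites = 3 + seed %% 4, k = 3 + seed %% 7,
                      reps = 3, seed = seed)
    coef <- coefficient_table(biomarker_names(tab),
                              ifelse(seq_along(biomarker_names(tab)) %% 2,
                                     1, -1))
    std <- ibr_std(tab, coef)
    expect_true(all(std$S >= 0))
    expect_equal(unname(apply(std$S, 2, min)),
                 rep(0, length(std$biomarkers)))
    expect_equal(unname(colMeans(std$Y)), rep(0, length(std$biomarkers)))
  }
})

test_that("circular arrangements are canonical and counted as (k-1)!/2", {
  for (k in 3:9) {
    arr <- enumerate_arrangements(k)
    expect_length(arr, factorial(k - 1) / 2)
    expect_true(all(vapply(arr, function(a) a[1L] == 1L, TRUE)))
    expect_true(all(vapply(arr, function(a) setequal(a, seq_len(k)), TRUE)))
    expect_equal(anyDuplicated(vapply(arr, paste, "", collapse = "-")), 0L)
    # canonical: lexicographically no larger than the reflected ordering
    expect_true(all(vapply(arr, function(a) {
      r <- c(1L, rev(a[-1L]))
      paste(a, collapse = ",") <= paste(r, collapse = ",")
    }, TRUE)))
  }
  expect_error(enumerate_arrangements(2), "between 3 and 9")
  expect_error(enumerate_arrangements(10), "between 3 and 9")
})

test_that("arrangements match brute-force necklace deduplication", {
  for (k in 3:6) {
    expect_equal(length(enumerate_arrangements(k)), brute_necklace_count(k))
    # every canonical arrangement maps to a distinct necklace class
    classes <- vapply(enumerate_arrangements(k), necklace_canon, "")
    expect_equal(anyDuplicated(classes), 0L)
  }
})

test_that("star area follows the triangle-fan formula and its edge cases", {
  expect_equal(star_area(c(0, 0, 0)), 0)
  expect_equal(star_area(c(1, 1, 1)), 3 * sqrt(3) / 4)
  expect_equal(star_area(c(1, 2, 1, 2)), 4)
  expect_equal(star_area(c(0, 5, 0)), 0)  # every adjacent product has a 0
  expect_error(star_area(c(-1, 1, 1)), "non-negative")
  expect_error(star_area(c(1, NA, 1)), "finite")
  expect_error(star_area(c(1, 1, 1), c(1, 1, 2)), "permutation")
})

test_that("star area is invariant under rotation and reversal of the arrangement", {
  set.seed(42)
  for (i in 1:25) {
    k <- sample(3:9, 1)
    s <- runif(k, 0, 10)
    a <- sample(k)
    rot <- c(a[-1L], a[1L])
    expect_equal(star_area(s, rot), star_area(s, a))
    expect_equal(star_area(s, rev(a)), star_area(s, a))
  }
})

test_that("the IBR index averages star areas over all arrangements", {
  # k = 4, one site with S = (1, 2, 1, 2); expected areas worked by hand
  # via the shoelace oracle: {4, 4.5, 4.5}
  std <- structure(list(sites = "S1", biomarkers = paste0("b", 1:4),
                        coefficients = rep(1, 4),
                        S = matrix(c(1, 2, 1, 2), nrow = 1,
                                   dimnames = list("S1", paste0("b", 1:4)))),
                   class = "ibr_std")
  res <- ibr_index(std)
  expect_equal(sort(unname(res$per_arrangement[, "S1"])), c(4, 4.5, 4.5))
  expect_equal(unname(res$mean["S1"]), 13 / 3)
  expect_equal(unname(res$sd["S1"]), sqrt(1 / 12))
  # mean and sd rows are consistent with the per-arrangement table
  expect_equal(unname(res$mean), unname(colMeans(res$per_arrangement)))
  expect_equal(unname(res$sd), unname(apply(res$per_arrangement, 2, sd)))
})

test_that("k = 3 and constant score rows give zero arrangement SD", {
  m <- matrix(c(1, 2, 3, 2, 6, 4, 9, 3, 6), nrow = 3,
              dimnames = list(paste0("S", 1:3), c("a", "b", "c")))
  res <- ibr_index(ibr_std(m))
  expect_equal(nrow(res$per_arrangement), 1)
  expect_equal(unname(res$sd), rep(0, 3))

  # a constant S row is a regular polygon: same area in every arrangement
  std <- structure(list(sites = "S1", biomarkers = paste0("b", 1:5),
                        coefficients = rep(1, 5),
                        S = matrix(rep(2, 5), nrow = 1,
                                   dimnames = list("S1", paste0("b", 1:5)))),
                   class = "ibr_std")
  res5 <- ibr_index(std)
  expect_equal(unname(res5$sd["S1"]), 0)
  expect_equal(unname(res5$mean["S1"]), star_area(rep(2, 5)))
})

test_that("IBR mean and SD are invariant to biomarker column order", {
  tab <- make_table(n_sites = 4, k = 5, reps = 3, seed = 3)
  coef <- coefficient_table(biomarker_names(tab), c(1, -1, 1, 1, -1))
  res1 <- ibr_index(ibr_std(tab, coef))
  set.seed(5)
  perm <- sample(5)
  tab2 <- biomarker_table(tab[, c(1L, 1L + perm)])
  res2 <- ibr_index(ibr_std(tab2, coef))
  expect_equal(res1$mean, res2$mean)
  expect_equal(res1$sd, res2$sd)
})

test_that("scaling one site's scores by lambda scales its areas by lambda^2", {
  tab <- make_table(n_sites = 4, k = 5, reps = 3, seed = 8)
  std <- ibr_std(tab)
  lambda <- 1.7
  std2 <- std
  std2$S["S2", ] <- lambda * std$S["S2", ]
  r1 <- ibr_index(std)
  r2 <- ibr_index(std2)
  expect_equal(r2$per_arrangement[, "S2"], lambda^2 * r1$per_arrangement[, "S2"])
  expect_equal(unname(r2$mean["S2"]), lambda^2 * unname(r1$mean["S2"]))
  expect_equal(unname(r2$sd["S2"]), lambda^2 * unname(r1$sd["S2"]))
  # other sites untouched
  expect_equal(r2$mean["S1"], r1$mean["S1"])
})
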