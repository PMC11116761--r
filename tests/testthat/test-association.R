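test_that("SRI matches hand-worked dyads", {
  s <- sightings_df(
    sighting("s1", "2020-01-01 08:00:00", c("A", "B")),
    sighting("s2", "2020-01-02 08:00:00", c("A", "B")))
  am <- compute_sri(s, "sighting")
  expect_equal(am$sri["A", "B"], 1)

  s2 <- sightings_df(
    sighting("s1", "2020-01-01 08:00:00", c("A", "B")),
    sighting("s2", "2020-01-02 08:00:00", "A"),
    sighting("s3", "2020-01-03 08:00:00", "B"),
    sighting("s4", "2020-01-04 08:00:00", c("A", "B")))
  am2 <- compute_sri(s2, "sighting")
  expect_equal(am2$x["A", "B"], 2)
  expect_equal(am2$d["A", "B"], 4)
  expect_equal(am2$sri["A", "B"], 0.5)

  s3 <- sightings_df(
    sighting("s1", "2020-01-01 08:00:00", c("A", "C")),
    sighting("s2", "2020-01-02 08:00:00", c("B", "C")))
  am3 <- compute_sri(s3, "sighting")
  expect_equal(am3$sri["A", "B"], 0)
})

test_that("day sampling counts same-day separate groups in the denominator", {
  # A and B sighted the same day in different groups: together 0 of 1 day,
  # but the day still enters the denominator (yAB)
  s <- sightings_df(
    sighting("s1", "2020-01-01 08:00:00", c("A", "C")),
    sighting("s2", "2020-01-01 14:00:00", c("B", "C")),
    sighting("s3", "2020-01-02 08:00:00", c("A", "B")))
  am <- compute_sri(s, "day")
  expect_equal(am$x["A", "B"], 1)
  expect_equal(am$d["A", "B"], 2)
  expect_equal(am$sri["A", "B"], 0.5)
  # C together with A on day 1 (shared sighting) and absent day 2
  expect_equal(am$sri["A", "C"], 0.5)
})

test_that("SRI agrees with a brute-force enumeration oracle", {
  for (seed in 1:4) {
    s <- simulate_null_groups(n_individuals = 8, n_days = 12,
                              groups_per_day = 2, group_size = 3,
                              seed = seed)
    for (period in c("sighting", "day")) {
      am <- compute_sri(s, period)
      oracle <- oracle_sri(s, period)
      expect_equal(am$sri[am$ids, am$ids], oracle$sri, info = period)
      expect_equal(am$x[am$ids, am$ids] * 1, oracle$x, info = period)
      expect_equal(am$d[am$ids, am$ids] * 1, oracle$d, info = period)
    }
  }
})

test_that("SRI matrices are symmetric with values in [0, 1]", {
  s <- simulate_null_groups(n_individuals = 12, n_days = 15, seed = 3)
  for (period in c("sighting", "day")) {
    am <- compute_sri(s, period)
    expect_equal(am$sri, t(am$sri))
    v <- am$sri[upper.tri(am$sri)]
    expect_true(all(v >= 0 & v <= 1))
    expect_true(all(is.na(diag(am$sri))))
    expect_true(all(am$d[upper.tri(am$d)] >= am$x[upper.tri(am$x)]))
  }
})

test_that("permutation chain preserves group sizes and daily frequencies", {
  s <- simulate_null_groups(n_individuals = 10, n_days = 10,
                            groups_per_day = 2, group_size = 4, seed = 2)
  sizes0 <- sort(lengths(s$individual_ids))
  # per-individual total record count
  freq0 <- sort(table(unlist(s$individual_ids)))
  pt <- permutation_test(s, "cv_sri", n_permutations = 50, seed = 1,
                         burn_in = 100,
                         inspect = function(groups) {
                           list(sizes = sort(lengths(groups)),
                                freq = sort(tabulate(unlist(groups), 10)))
                         })
  for (st in pt$inspections) {
    expect_equal(unname(st$sizes), unname(sizes0))
    expect_equal(unname(st$freq), unname(as.integer(freq0)))
  }
})

test_that("permutation test is reproducible and respects degenerate input", {
  s <- simulate_null_groups(n_individuals = 10, n_days = 12, seed = 5)
  a <- permutation_test(s, "cv_sri", n_permutations = 60, seed = 9)
  b <- permutation_test(s, "cv_sri", n_permutations = 60, seed = 9)
  expect_identical(a$permuted, b$permuted)

  # identical groups on every day: no informative swap exists, statistic
  # never moves
  s2 <- sightings_df(
    sighting("s1", "2020-01-01 08:00:00", c("A", "B", "C")),
    sighting("s2", "2020-01-01 12:00:00", c("A", "B", "C")),
    sighting("s3", "2020-01-02 08:00:00", c("A", "B", "C")),
    sighting("s4", "2020-01-02 12:00:00", c("A", "B", "C")))
  pt <- permutation_test(s2, "cv_sri", n_permutations = 30, seed = 1)
  expect_true(all(pt$permuted == pt$observed))

  # a single group per day cannot be permuted at all
  s3 <- sightings_df(
    sighting("s1", "2020-01-01 08:00:00", c("A", "B")),
    sighting("s2", "2020-01-02 08:00:00", c("C", "D")))
  expect_warning(pt3 <- permutation_test(s3, "cv_sri", n_permutations = 10),
                 "not permutable")
  expect_true(pt3$untestable)
  expect_equal(pt3$p_value, 1)
})

test_that("planted always-together cliques are detected as preferred", {
  s <- simulate_clique_groups(n_cliques = 2, group_size = 5, n_days = 40,
                              days_per_clique = 25, seed = 3)
  pt <- permutation_test(s, "cv_sri", n_permutations = 400, seed = 1)
  expect_lt(pt$p_value, 0.005)
  pt_sd <- permutation_test(s, "sd_sri", n_permutations = 400, seed = 1)
  expect_lt(pt_sd$p_value, 0.005)
})

test_that("Mantel test recovers identity and monotone transforms", {
  s <- simulate_null_groups(n_individuals = 12, n_days = 20, seed = 6)
  am <- compute_sri(s, "sighting")
  m <- mantel_test(am, am, n_permutations = 200, seed = 1)
  expect_equal(m$R, 1)
  # Spearman invariance under a rank-preserving monotone transform
  am2 <- am
  am2$sri <- am$sri^3 + 0.01 * am$sri
  m2 <- mantel_test(am, am2, n_permutations = 200, seed = 1)
  expect_equal(m2$R, 1)
  expect_error(mantel_test(am$sri[1:2, 1:2], am$sri[1:2, 1:2]),
               "3 common individuals")
})

test_that("Mantel p-values stay calibrated under independence", {
  set.seed(10)
  pv <- vapply(1:30, function(i) {
    ids <- sprintf("I%02d", 1:12)
    r1 <- matrix(runif(144), 12, dimnames = list(ids, ids))
    r2 <- matrix(runif(144), 12, dimnames = list(ids, ids))
    r1 <- (r1 + t(r1)) / 2; r2 <- (r2 + t(r2)) / 2
    mantel_test(r1, r2, n_permutations = 120, seed = i)$p_value
  }, 0)
  expect_gt(mean(pv), 0.3)
  expect_lte(mean(pv <= 0.05), 0.2)
})

test_that("social differentiation flags data with no detectable variation", {
  # every dyad observed together in exactly half of 10^4 periods
  n <- 20
  ids <- sprintf("I%02d", 1:n)
  dm <- matrix(10000, n, n, dimnames = list(ids, ids))
  xm <- dm / 2
  sri <- xm / dm
  diag(dm) <- diag(xm) <- diag(sri) <- NA
  am <- structure(list(ids = ids, x = xm, d = dm, sri = sri,
                       sampling_period = "sighting"), class = "sri_matrix")
  sd_fit <- social_differentiation(am, seed = 1, n_boot = 10)
  expect_lt(sd_fit$S, 0.05)
  expect_true(sd_fit$degenerate)
})

test_that("social differentiation recovers a planted Beta(2,2) truth", {
  am <- simulate_dyads(n_dyads = 500, shape1 = 2, shape2 = 2, d = 100,
                       seed = 7)
  sd_fit <- social_differentiation(am, seed = 1, n_boot = 40)
  true_cv <- 1 / sqrt(5)
  expect_lt(abs(sd_fit$S - true_cv) / true_cv, 0.10)
  expect_equal(sd_fit$power, sd_fit$S^2 * sd_fit$H)
  expect_equal(sd_fit$H, 100)  # mean denominator
  expect_gt(sd_fit$se_S, 0)
})

test_that("estimation power r increases with sampling effort per dyad", {
  r_at <- vapply(c(5, 50, 500), function(d) {
    am <- simulate_dyads(n_dyads = 300, shape1 = 2, shape2 = 2, d = d,
                         seed = 3)
    suppressWarnings(
      social_differentiation(am, seed = 1, n_boot = 5, n_sim_r = 50)$r)
  }, 0)
  expect_true(all(diff(r_at) > 0))
  expect_gt(r_at[3], 0.95)
})
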