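# minimal partition helper
make_partition <- function(memb) {
  structure(list(membership = memb, units = split(names(memb), memb),
                 gamma = 0.28, quality = 0, stability = 1, n_restarts = 1,
                 n_iterations = 1, seed = 1),
            class = "unit_partition")
}

test_that("12-h exclusion drops within-window repeats around one vessel", {
  memb <- setNames(c("UA", "UA", "UB"), c("A", "B", "C"))
  p <- make_partition(memb)
  base <- utc("2020-01-01 00:00:00")
  mk <- function(id, hours, inds, vessel = "V1") {
    sighting(id, format(base + hours * 3600, "%Y-%m-%d %H:%M:%S"),
             inds, vessel = vessel)
  }
  # same unit, same vessel, 6 h apart -> second dropped
  ds <- kw_dataset(sightings_df(mk("s1", 0, "A"), mk("s2", 6, "B")))
  expect_equal(dedup_12h(ds, p)$sighting_id, "s1")
  # different vessels -> both kept
  ds2 <- kw_dataset(sightings_df(mk("s1", 0, "A"),
                                 mk("s2", 6, "A", vessel = "V2")))
  expect_equal(nrow(dedup_12h(ds2, p)), 2)
  # 13 h apart -> both kept
  ds3 <- kw_dataset(sightings_df(mk("s1", 0, "A"), mk("s2", 13, "A")))
  expect_equal(nrow(dedup_12h(ds3, p)), 2)
  # window anchored at first sighting: 0 h, 8 h (dropped), 16 h kept
  # because 16 h is beyond 12 h from the 0 h anchor
  ds4 <- kw_dataset(sightings_df(mk("s1", 0, "A"), mk("s2", 8, "A"),
                                 mk("s3", 16, "A")))
  expect_equal(dedup_12h(ds4, p)$sighting_id, c("s1", "s3"))
  # a sighting with one fresh unit among repeats is retained
  ds5 <- kw_dataset(sightings_df(mk("s1", 0, "A"), mk("s2", 6, c("B", "C"))))
  expect_equal(nrow(dedup_12h(ds5, p)), 2)
})

test_that("12-h exclusion never drops sightings beyond the window", {
  sim <- simulate_dataset(sim_config(n_vessel_sightings = 400,
                                     n_shore_sightings = 0,
                                     unit_sizes = c(3, 4, 5),
                                     n_individuals = 12,
                                     n_vessels = 1, years = 2020,
                                     unit_prob_range = c(0.3, 0.6)),
                          seed = 8)
  p <- make_partition(sim$truth$membership)
  kept <- dedup_12h(sim$dataset, p)
  expect_gt(nrow(sim$dataset$sightings) - nrow(kept), 0)
  vs <- sim$dataset$sightings
  memb <- sim$truth$membership
  vs$units_present <- lapply(vs$individual_ids, function(g)
    unique(unname(memb[g])))
  dropped <- setdiff(vs$sighting_id, kept$sighting_id)
  for (id in dropped) {
    row <- vs[vs$sighting_id == id, ]
    prior <- vs[vs$vessel_id == row$vessel_id &
                  vs$start_time < row$start_time, ]
    # every unit in a dropped sighting has a same-vessel predecessor
    # containing it within 12 h
    for (u in row$units_present[[1]]) {
      has_u <- vapply(prior$units_present, function(x) u %in% x, TRUE)
      expect_true(any(has_u) && min(as.numeric(row$start_time) -
        as.numeric(prior$start_time[has_u])) / 3600 <= 12)
    }
  }
})

test_that("occurrence table has one record per retained sighting and unit", {
  sim <- simulate_dataset(sim_config(n_vessel_sightings = 150,
                                     n_shore_sightings = 10,
                                     unit_sizes = c(3, 4, 5),
                                     n_individuals = 12,
                                     unit_prob_range = c(0.3, 0.6)),
                          seed = 8)
  p <- make_partition(sim$truth$membership)
  rec <- occurrence_records(sim$dataset, p, dedup_hours = 12)
  n_units <- length(p$units)
  expect_equal(nrow(rec) %% n_units, 0)
  expect_false(any(duplicated(paste(rec$sighting_id, rec$unit))))
  # present matches membership lookups
  vs <- sim$dataset$sightings
  k <- sample(nrow(rec), 50)
  for (i in k) {
    g <- vs$individual_ids[[which(vs$sighting_id == rec$sighting_id[i])]]
    expect_equal(rec$present[i],
                 as.integer(any(sim$truth$membership[g] == rec$unit[i])))
  }
})

test_that("parameter bookkeeping reproduces the published model ladder", {
  # factor scaffolding with 18 years, 12 months, 17 units, 5 effort levels
  rec <- data.frame(year = factor(rep(2005:2022, length.out = 1000)),
                    month = factor(rep(1:12, length.out = 1000)),
                    unit = factor(rep(sprintf("U%02d", 1:17),
                                      length.out = 1000)),
                    effort = factor(rep(c("very_low", "low", "medium",
                                          "high", "very_high"),
                                        length.out = 1000)),
                    sighting_id = rep(sprintf("s%03d", 1:200), 5))
  expect_equal(count_parameters(rec, character(), "effort"), 2L)
  expect_equal(count_parameters(rec, "year", "effort"), 19L)
  expect_equal(count_parameters(rec, c("year", "month"), "effort"), 30L)
  expect_equal(count_parameters(rec, c("year", "month", "unit"), "effort"),
               46L)
  expect_equal(count_parameters(rec, c("year", "month", "unit"),
                                c("effort", "sighting_id/unit")), 48L)
})

test_that("AICc identity holds and reduces to AIC at large n", {
  expect_equal(aicc(-100, 5, 1e9), -2 * -100 + 2 * 5, tolerance = 1e-6)
  k <- 46; n <- 20604; ll <- -7453.54
  expect_equal(aicc(ll, k, n), -2 * ll + 2 * k + 2 * k * (k + 1) / (n - k - 1))
})


test_that("the mixed model collapses to plain logistic regression as s2 -> 0", {
  p_u <- plogis(seq(-2.5, -1, length.out = 6))
  rec <- sim_records(400, p_u, seed = 2)
  fit <- fit_glmm(rec, "unit", "effort")
  ref <- glm(present ~ unit, family = binomial, data = rec)
  expect_lt(fit$sigma2[["effort"]], 1e-4)
  expect_lt(abs(fit$loglik - as.numeric(logLik(ref))), 1e-4)
})

test_that("the marginal likelihood matches an independent implementation", {
  skip_if_not_installed("lme4")
  p_u <- plogis(seq(-2.5, -1, length.out = 6))
  rec <- sim_records(300, p_u, b_eff = c(-0.5, -0.2, 0, 0.3, 0.6), seed = 5)
  fit <- fit_glmm(rec, "unit", "effort")
  # same Laplace integral, independently implemented
  ref <- lme4::glmer(present ~ unit + (1 | effort), data = rec,
                     family = binomial)
  expect_lt(abs(fit$loglik - as.numeric(logLik(ref))), 1e-4)
  expect_equal(unname(fit$beta), unname(lme4::fixef(ref)), tolerance = 1e-3)
  # refining the integral with 15-node adaptive quadrature moves the
  # log-likelihood only marginally at this cluster size
  agq <- lme4::glmer(present ~ unit + (1 | effort), data = rec,
                     family = binomial, nAGQ = 15)
  expect_lt(abs(fit$loglik - as.numeric(logLik(agq))), 0.01)
})

test_that("forward AICc selection keeps real effects and drops absent ones", {
  p_u <- plogis(seq(qlogis(0.05), qlogis(0.3), length.out = 8))
  rec <- sim_records(400, p_u, seed = 3)
  rec$year <- factor(rep(sample(2011:2014, 400, TRUE), each = 8))
  rec$month <- factor(rep(sample(1:6, 400, TRUE), each = 8))
  lad <- select_model(rec, c("year", "month", "unit"), "effort")
  expect_equal(lad$best, 4L)  # unit effects are real
  expect_equal(lad$table$X2, c(NA, 2 * diff(lad$table$LL)))
  expect_equal(sum(lad$table$wAICc), 1)
  # the unit step is overwhelming, year/month steps are noise
  expect_gt(lad$table$X2[4], 100)
  expect_lt(lad$table$X2[2], 30)
  # AICc identity for every fitted model
  for (f in lad$fits) {
    expect_equal(f$aicc, aicc(f$loglik, f$K, f$n_records))
  }
})

test_that("null-effect data ranks the null model first", {
  rej <- vapply(1:8, function(i) {
    rec <- sim_records(120, rep(0.15, 5), seed = 40 + i)
    rec$year <- factor(rep(sample(2011:2013, 120, TRUE), each = 5))
    lad <- select_model(rec, "year", "effort")
    lad$best == 1L
  }, TRUE)
  expect_gte(mean(rej), 0.5)  # majority criterion
})

test_that("marginal means equal empirical frequencies for a saturated model", {
  p_u <- c(0.05, 0.1, 0.2, 0.3)
  rec <- sim_records(500, p_u, seed = 7)
  fit <- fit_glmm(rec, "unit", character())   # plain logistic regression
  em <- emmeans_units(fit)
  emp <- tapply(rec$present, rec$unit, mean)
  expect_equal(em$probabilities$prob, as.vector(emp), tolerance = 1e-6)
  expect_true(all(em$probabilities$lower < em$probabilities$prob))
  expect_true(all(em$probabilities$upper > em$probabilities$prob))
  expect_true(all(em$contrasts$p_holm >= em$contrasts$p - 1e-12))
  expect_equal(em$contrasts$p_holm, p.adjust(em$contrasts$p, "holm"))
  expect_error(emmeans_units(fit_glmm(rec, character(), "effort")),
               "no 'unit'")
})

test_that("identical units rarely yield familywise false positives", {
  any_sig <- vapply(1:6, function(i) {
    rec <- sim_records(250, rep(0.15, 5), seed = 70 + i)
    fit <- fit_glmm(rec, "unit", "effort")
    em <- emmeans_units(fit)
    any(em$contrasts$p_holm < 0.05)
  }, TRUE)
  expect_lte(sum(any_sig), 1)
})

test_that("residual diagnostics are calibrated on correctly specified fits", {
  p_u <- plogis(seq(-2.5, -1.2, length.out = 6))
  rec <- sim_records(350, p_u, b_eff = rnorm(5, 0, 0.3), seed = 11)
  fit <- fit_glmm(rec, "unit", "effort")
  dg <- diagnose(fit, rec, n_sim = 200, seed = 2)
  expect_gt(dg$ks_p, 0.01)
  expect_equal(dg$dispersion_ratio, 1, tolerance = 0.15)
  expect_equal(dg$zero_inflation_ratio, 1, tolerance = 0.05)
  expect_equal(dg$durbin_watson, 2, tolerance = 0.25)
  expect_true(all(dg$scaled_residuals >= 0 & dg$scaled_residuals <= 1))
  expect_true(all(dg$gvif$gvif >= 1 - 1e-6))
})

test_that("collinear fixed effects blow up the generalized VIF", {
  p_u <- c(0.1, 0.2, 0.3)
  rec <- sim_records(200, p_u, seed = 13)
  rec$unit_copy <- rec$unit
  fit <- fit_glmm(rec, "unit", "effort")
  fit$fixed_terms <- c("unit", "unit_copy")  # duplicated covariate
  dg <- diagnose(fit, rec, n_sim = 50, seed = 1)
  expect_true(any(!is.finite(dg$gvif$gvif) | dg$gvif$gvif > 100))
})
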