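#' Simple Ratio Index association matrix
#'
#' For each dyad the Simple Ratio Index is `x / (x + yAB + yA + yB)`: the
#' proportion of sampling periods in which the two individuals were
#' recorded together, out of all periods in which at least one was
#' recorded. Under `sampling_period = "sighting"` every sighting is one
#' period and two individuals are together when photographed in the same
#' sighting ("gambit of the group"). Under `"day"` every UTC calendar date
#' is one period: individuals are together when they share at least one
#' sighting that day, and a dyad both present on a day but never in the
#' same sighting contributes to the denominator only (`yAB`).
#'
#' @param ds a [kw_dataset()] (or a sighting data.frame).
#' @param sampling_period `"sighting"` or `"day"`.
#' @return An object of class `sri_matrix`: list with `ids`, symmetric
#'   matrices `x` (periods together), `d` (denominator), `sri`,
#'   and `sampling_period`. Diagonals are `NA`; `sri` is 0 where `d` is 0.
#' @export
compute_sri <- function(ds, sampling_period = c("sighting", "day")) {
  sampling_period <- match.arg(sampling_period)
  s <- if (inherits(ds, "kw_dataset")) ds$sightings else ds
  ids <- sort(unique(unlist(s$individual_ids)))
  n <- length(ids)
  if (n < 2) stopf("need at least 2 individuals to compute associations")
  groups <- lapply(s$individual_ids, function(g) match(g, ids))
  if (sampling_period == "sighting") {
    # incidence: periods x individuals
    M <- matrix(0L, nrow(s), n)
    for (k in seq_along(groups)) M[k, groups[[k]]] <- 1L
    x <- crossprod(M)            # periods with both (same group, one per period)
    np <- diag(x)
    both <- x
  } else {
    day <- utc_date(s$start_time)
    udays <- sort(unique(day))
    P <- matrix(0L, length(udays), n)   # day presence
    x <- matrix(0L, n, n)               # days with >= 1 shared sighting
    di <- match(day, udays)
    for (k in seq_along(groups)) P[di[k], groups[[k]]] <- 1L
    for (d in seq_along(udays)) {
      T_d <- day_together(groups[di == d], n)
      x <- x + T_d
    }
    both <- crossprod(P)
    np <- diag(both)
  }
  # d = periods where i or j (or both) present
  d <- outer(np, np, "+") - both
  sri <- ifelse(d > 0, x / d, 0)
  diag(x) <- diag(d) <- diag(sri) <- NA_real_
  dimnames(x) <- dimnames(d) <- dimnames(sri) <- list(ids, ids)
  structure(list(ids = ids, x = x, d = d, sri = sri,
                 sampling_period = sampling_period),
            class = "sri_matrix")
}

# 0/1 matrix marking dyads that share at least one group in `groups`
day_together <- function(groups, n) {
  T_d <- matrix(0L, n, n)
  for (g in groups) if (length(g) > 1) T_d[g, g] <- 1L
  diag(T_d) <- 0L
  T_d
}

#' @export
print.sri_matrix <- function(x, ...) {
  v <- x$sri[upper.tri(x$sri)]
  cat(sprintf("sri_matrix: %d individuals, sampling period = %s\n",
              length(x$ids), x$sampling_period))
  cat(sprintf("  mean SRI %.3f, nonzero dyads %d/%d\n",
              mean(v), sum(v > 0), length(v)))
  invisible(x)
}

#' Dyad table of an association matrix
#'
#' Long-format view (one row per unordered dyad) used for text export.
#'
#' @param am an [compute_sri()] result.
#' @return data.frame with columns `i`, `j`, `x`, `d`, `sri`.
#' @export
sri_dyads <- function(am) {
  ut <- which(upper.tri(am$sri), arr.ind = TRUE)
  data.frame(i = am$ids[ut[, 1]], j = am$ids[ut[, 2]],
             x = am$x[ut], d = am$d[ut], sri = am$sri[ut])
}

sri_statistic <- function(sri_ut, statistic) {
  switch(statistic,
         cv_sri = pop_cv(sri_ut),
         sd_sri = pop_sd(sri_ut),
         sd_nonzero_sri = {
           nz <- sri_ut[sri_ut > 0]
           if (length(nz) < 2) NA_real_ else pop_sd(nz)
         },
         stopf("unknown statistic '%s'", statistic))
}

#' Data-stream permutation test for preferred/avoided association
#'
#' Tests whether individuals associate non-randomly by comparing a network
#' statistic (CV of the SRI, SD of the SRI, or SD of the nonzero SRI,
#' computed on the day-level association matrix) against a null generated
#' by constrained swaps of the group-by-individual incidence data. Each
#' permutation step applies `trials_per_permutation` attempted 2x2
#' checkerboard swaps between two groups observed on the same calendar
#' day, which preserves every group's size and every individual's number
#' of records per day; after each step the statistic is recorded. Larger
#' observed variation than the permuted networks indicates preferred
#' associations, so the p-value is the proportion of permuted values at or
#' above the observed one (one-sided; `two_sided = TRUE` doubles the
#' smaller tail).
#'
#' Successive recorded networks along a swap chain are autocorrelated, so
#' the naive proportion-above-observed p-value of a chain started at the
#' observed data is anticonservative. The default `method = "serial"`
#' therefore uses the serial Monte Carlo construction for reversible
#' chains (Besag-Clifford): the observed network is planted at a
#' uniformly random position in a stationary trajectory by running the
#' chain independently backward and forward from the observed state
#' (the swap kernel is symmetric, so both directions use the same
#' sampler), and `p = (1 + #\{permuted >= observed\}) / (n_permutations
#' + 1)` is exactly valid under the null whatever the autocorrelation.
#' `method = "chain"` records a single forward chain and reports the
#' plain proportion at or above the observed value, optionally after a
#' `burn_in` discard. Reproducible given `seed`.
#'
#' @param ds a [kw_dataset()] (or sighting data.frame).
#' @param statistic one of `"cv_sri"`, `"sd_sri"`, `"sd_nonzero_sri"`.
#' @param n_permutations number of recorded permutation steps.
#' @param trials_per_permutation attempted swaps between recorded steps
#'   (failed attempts count).
#' @param seed integer seed.
#' @param method `"serial"` (exactly valid rank p-value) or `"chain"`
#'   (single forward chain).
#' @param burn_in swap attempts discarded before recording starts, for
#'   `method = "chain"` only; `NULL` uses ten times the number of
#'   individual records in the data.
#' @param two_sided if `TRUE`, report twice the smaller tail probability.
#' @param inspect optional function applied to the current list of groups
#'   (integer member indices) after every recorded step; its results are
#'   returned in `$inspections`. Intended for chain diagnostics such as
#'   checking that group sizes and individual daily frequencies are
#'   preserved.
#' @return Object of class `sri_permutation`: observed value, permuted
#'   values, mean permuted value and p-value.
#' @export
permutation_test <- function(ds, statistic = c("cv_sri", "sd_sri",
                                               "sd_nonzero_sri"),
                             n_permutations = 10000,
                             trials_per_permutation = 10,
                             seed = 1, method = c("serial", "chain"),
                             burn_in = NULL, two_sided = FALSE,
                             inspect = NULL) {
  method <- match.arg(method)
  statistic <- match.arg(statistic)
  s <- if (inherits(ds, "kw_dataset")) ds$sightings else ds
  ids <- sort(unique(unlist(s$individual_ids)))
  n <- length(ids)
  if (n < 2) stopf("need at least 2 individuals")
  groups <- lapply(s$individual_ids, function(g) match(g, ids))
  day <- as.integer(factor(utc_date(s$start_time)))
  n_days <- max(day)

  # fixed day-level denominator (union of presence days, invariant to swaps)
  P <- matrix(0L, n_days, n)
  for (k in seq_along(groups)) P[day[k], groups[[k]]] <- 1L
  npres <- colSums(P)
  d_mat <- outer(npres, npres, "+") - crossprod(P)

  day_groups <- split(seq_along(groups), day)
  multi_days <- which(lengths(day_groups) >= 2)
  x <- matrix(0L, n, n)
  T_days <- vector("list", n_days)
  for (dd in seq_len(n_days)) {
    T_days[[dd]] <- day_together(groups[day_groups[[dd]]], n)
    x <- x + T_days[[dd]]
  }
  ut <- upper.tri(x)
  sri_ut <- ifelse(d_mat[ut] > 0, x[ut] / d_mat[ut], 0)
  observed <- sri_statistic(sri_ut, statistic)

  if (!length(multi_days)) {
    warning("no day holds two or more groups; association data not permutable")
    return(structure(list(statistic = statistic, observed = observed,
                          permuted = rep(observed, 0), mean_permuted = NA_real_,
                          p_value = 1, n_permutations = 0L,
                          trials_per_permutation = trials_per_permutation,
                          seed = seed, untestable = TRUE),
                     class = "sri_permutation"))
  }

  if (is.null(burn_in)) burn_in <- 10L * sum(lengths(groups))
  groups0 <- groups
  x0 <- x
  T_days0 <- T_days

  one_swap <- function() {
    dd <- multi_days[sample.int(length(multi_days), 1)]
    gs <- day_groups[[dd]]
    pick <- sample.int(length(gs), 2)
    g1 <- groups[[gs[pick[1]]]]
    g2 <- groups[[gs[pick[2]]]]
    cand1 <- setdiff(g1, g2)
    cand2 <- setdiff(g2, g1)
    if (!length(cand1) || !length(cand2)) return(invisible())  # failed attempt
    i <- cand1[sample.int(length(cand1), 1)]
    j <- cand2[sample.int(length(cand2), 1)]
    groups[[gs[pick[1]]]] <<- c(setdiff(g1, i), j)
    groups[[gs[pick[2]]]] <<- c(setdiff(g2, j), i)
    T_new <- day_together(groups[day_groups[[dd]]], n)
    x <<- x + (T_new - T_days[[dd]])
    T_days[[dd]] <<- T_new
    invisible()
  }

  inspections <- if (is.null(inspect)) NULL else list()
  run_segment <- function(n_steps) {
    out <- numeric(n_steps)
    for (step in seq_len(n_steps)) {
      for (trial in seq_len(trials_per_permutation)) one_swap()
      sri_ut <- ifelse(d_mat[ut] > 0, x[ut] / d_mat[ut], 0)
      out[step] <- sri_statistic(sri_ut, statistic)
      if (!is.null(inspect)) {
        inspections[[length(inspections) + 1]] <<- inspect(groups)
      }
    }
    out
  }
  permuted <- with_seed(seed, {
    if (method == "serial") {
      # plant the observed state at a uniform position of a stationary
      # trajectory: backward and forward runs both start at the data
      n_back <- sample.int(n_permutations + 1, 1) - 1L
      back <- run_segment(n_back)
      groups <- groups0; x <- x0; T_days <- T_days0
      c(back, run_segment(n_permutations - n_back))
    } else {
      for (b in seq_len(burn_in)) one_swap()
      run_segment(n_permutations)
    }
  })

  p_high <- if (method == "serial") {
    (1 + sum(permuted >= observed)) / (n_permutations + 1)
  } else {
    mean(permuted >= observed)
  }
  p_low <- if (method == "serial") {
    (1 + sum(permuted <= observed)) / (n_permutations + 1)
  } else {
    mean(permuted <= observed)
  }
  p <- if (two_sided) min(1, 2 * min(p_high, p_low)) else p_high
  structure(list(statistic = statistic, observed = observed,
                 permuted = permuted, mean_permuted = mean(permuted),
                 p_value = p, n_permutations = as.integer(n_permutations),
                 trials_per_permutation = as.integer(trials_per_permutation),
                 seed = seed, untestable = FALSE, inspections = inspections),
            class = "sri_permutation")
}

#' @export
print.sri_permutation <- function(x, ...) {
  cat(sprintf("Data-stream permutation test (%s)\n", x$statistic))
  cat(sprintf("  observed %.4f, mean permuted %.4f, p = %.4g (%d permutations)\n",
              x$observed, x$mean_permuted, x$p_value, x$n_permutations))
  invisible(x)
}

#' Mantel test between two association matrices
#'
#' Spearman rank matrix correlation between two association matrices over
#' their common individuals, with significance from simultaneous random
#' relabelling of rows/columns of one matrix (one-sided, positive
#' association). Used here to compare associations measured from the two
#' observation platforms (shore vs. fishing vessels).
#'
#' @param m1,m2 [compute_sri()] results (or plain symmetric matrices with
#'   dimnames).
#' @param n_permutations number of permutations.
#' @param seed integer seed.
#' @return list with `R` (matrix correlation), `p_value`,
#'   `n_permutations`, `n_common`.
#' @export
mantel_test <- function(m1, m2, n_permutations = 10000, seed = 1) {
  a1 <- if (inherits(m1, "sri_matrix")) m1$sri else m1
  a2 <- if (inherits(m2, "sri_matrix")) m2$sri else m2
  common <- intersect(rownames(a1), rownames(a2))
  if (length(common) < 3) stopf("need at least 3 common individuals")
  a1 <- a1[common, common]
  a2 <- a2[common, common]
  diag(a1) <- diag(a2) <- 0
  res <- with_seed(seed,
    vegan::mantel(as.dist(a1), as.dist(a2), method = "spearman",
                  permutations = n_permutations))
  list(R = unname(res$statistic), p_value = res$signif,
       n_permutations = n_permutations, n_common = length(common))
}

# Negative log-likelihood of the beta-binomial model for observed
# (together-count, denominator) dyads with latent true index ~ Beta(a, b).
# Guarded: at extreme shapes lgamma cancellation can fabricate spuriously
# small values, so non-finite or out-of-range evaluations are rejected.
betabinom_nll <- function(par, x, d) {
  if (any(!is.finite(par)) || any(abs(par) > 15)) return(1e10)
  a <- exp(par[1]); b <- exp(par[2])
  v <- -sum(lchoose(d, x) + lbeta(a + x, b + d - x) - lbeta(a, b))
  if (!is.finite(v)) 1e10 else v
}

#' Social differentiation by maximum likelihood
#'
#' Estimates the spread of the *true* (latent) dyadic association indices
#' from the observed counts. The true index of each dyad is modelled as a
#' draw from a Beta(a, b) distribution and the observed together-count `x`
#' as Binomial(d, true index); `a`, `b` are estimated by maximising the
#' beta-binomial marginal likelihood over dyads. Social differentiation
#' `S` is the coefficient of variation of the fitted Beta; `r`, the
#' correlation between true and estimated indices (a measure of the power
#' of the sampled data to reveal the true structure), is computed by
#' simulation under the fitted model; standard errors come from a
#' nonparametric bootstrap over dyads. `H` summarises the amount of data
#' per dyad (default: mean denominator over dyads with `d > 0`;
#' alternative `"mean_x_per_individual"`: mean number of association
#' records per individual), and `S^2 x H` is the usual heuristic for power
#' to detect preferred association.
#'
#' @param am an [compute_sri()] result.
#' @param seed integer seed (posterior simulation and bootstrap).
#' @param n_boot bootstrap resamples for the standard errors.
#' @param n_sim_r simulated replicates of the dyad set used for `r`.
#' @param H one of `"mean_denominator"`, `"mean_x_per_individual"`.
#' @return Object of class `social_differentiation` with elements `S`,
#'   `se_S`, `r`, `se_r`, `H`, `power` (= S^2 H), `shape` (a, b),
#'   `loglik`, `degenerate`.
#' @export
social_differentiation <- function(am, seed = 1, n_boot = 200, n_sim_r = 20,
                                   H = c("mean_denominator",
                                         "mean_x_per_individual")) {
  H <- match.arg(H)
  ut <- upper.tri(am$sri)
  d <- am$d[ut]; x <- am$x[ut]
  keep <- !is.na(d) & d > 0
  d <- d[keep]; x <- x[keep]
  if (!length(d)) stopf("no dyads with positive denominator")

  fit_ab <- function(x, d) {
    p_hat <- x / d
    m <- mean(p_hat); v <- var(p_hat)
    # method-of-moments start, guarded against degeneracy
    if (!is.finite(v) || v <= 1e-10 || m <= 0 || m >= 1) {
      start <- c(0, 0)
    } else {
      k <- max(m * (1 - m) / v - 1, 0.1)
      start <- log(pmax(c(m * k, (1 - m) * k), 1e-3))
    }
    opt <- optim(start, betabinom_nll, x = x, d = d, method = "L-BFGS-B",
                 lower = -12, upper = 12, control = list(maxit = 500))
    opt2 <- optim(opt$par, betabinom_nll, x = x, d = d,
                  method = "Nelder-Mead", control = list(maxit = 2000))
    if (opt2$value <= opt$value) opt <- opt2
    if (opt$convergence != 0 || opt$value >= 1e10) {
      stopf("beta-binomial likelihood did not converge (code %d, nll %.3f)",
            opt$convergence, opt$value)
    }
    exp(opt$par)
  }
  beta_cv <- function(ab) {
    a <- ab[1]; b <- ab[2]
    sqrt(b / (a * (a + b + 1)))
  }

  ab <- fit_ab(x, d)
  S <- beta_cv(ab)
  H_val <- switch(H,
                  mean_denominator = mean(d),
                  mean_x_per_individual = sum(x) * 2 / length(am$ids))

  sim_r <- function(ab, d, nrep) {
    true_p <- rbeta(length(d) * nrep, ab[1], ab[2])
    dd <- rep(d, nrep)
    obs <- rbinom(length(dd), dd, true_p) / dd
    cor(true_p, obs)
  }

  res <- with_seed(seed, {
    r <- sim_r(ab, d, n_sim_r)
    boot <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(length(d), replace = TRUE)
      ab_b <- tryCatch(fit_ab(x[idx], d[idx]), error = function(e) c(NA, NA))
      if (anyNA(ab_b)) return(c(NA_real_, NA_real_))
      c(beta_cv(ab_b), sim_r(ab_b, d[idx], 5))
    }, numeric(2))
    list(r = r, se_S = sd(boot[1, ], na.rm = TRUE),
         se_r = sd(boot[2, ], na.rm = TRUE))
  })

  structure(list(S = S, se_S = res$se_S, r = res$r, se_r = res$se_r,
                 H = H_val, H_method = H, power = S^2 * H_val,
                 shape = c(a = ab[1], b = ab[2]),
                 loglik = -betabinom_nll(log(ab), x, d),
                 n_dyads = length(d),
                 degenerate = S < 0.05),
            class = "social_differentiation")
}

#' @export
print.social_differentiation <- function(x, ...) {
  cat(sprintf("Social differentiation: S = %.3f (SE %.3f), r = %.3f (SE %.3f)\n",
              x$S, x$se_S, x$r, x$se_r))
  cat(sprintf("  H = %.2f (%s), S^2 x H = %.2f; Beta(a = %.3f, b = %.3f), %d dyads\n",
              x$H, x$H_method, x$power, x$shape[1], x$shape[2], x$n_dyads))
  if (x$degenerate) cat("  note: S near zero - little detectable true variation\n")
  invisible(x)
}
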