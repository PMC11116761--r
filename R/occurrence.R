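#' Exclude within-window repeat sightings of the same units
#'
#' Killer whale social units often follow a vessel and depredate on
#' consecutive hauls, which would inflate their apparent occurrence
#' probability. Scanning each vessel's sightings in time order, a
#' sighting is dropped when every unit photographed in it had already
#' been photographed around that vessel within the preceding `hours`
#' (the window is anchored at each unit's first sighting inside it: a
#' unit's anchor only advances once more than `hours` have elapsed since
#' the anchor). Sightings observed from shore are ignored.
#'
#' @param ds a [kw_dataset()].
#' @param partition a [detect_units()] partition.
#' @param hours exclusion window in hours.
#' @return The vessel sighting data.frame restricted to retained
#'   sightings, with a list column `units_present`.
#' @export
dedup_12h <- function(ds, partition, hours = 12) {
  stopifnot(inherits(ds, "kw_dataset"), inherits(partition, "unit_partition"))
  vs <- ds$sightings[ds$sightings$platform == "vessel", , drop = FALSE]
  if (!nrow(vs)) stopf("no vessel sightings")
  memb <- partition$membership
  vs$units_present <- lapply(vs$individual_ids, function(g)
    sort(unique(unname(memb[g[g %in% names(memb)]]))))
  vs <- vs[lengths(vs$units_present) > 0, , drop = FALSE]
  vs <- vs[order(vs$vessel_id, vs$start_time), , drop = FALSE]
  keep <- logical(nrow(vs))
  anchors <- list()
  for (k in seq_len(nrow(vs))) {
    v <- vs$vessel_id[k]
    t <- as.numeric(vs$start_time[k])
    if (is.null(anchors[[v]])) anchors[[v]] <- numeric()
    a <- anchors[[v]]
    units <- vs$units_present[[k]]
    elapsed <- (t - a[units]) / 3600
    repeats <- !is.na(elapsed) & elapsed <= hours
    keep[k] <- !all(repeats)
    fresh <- units[is.na(elapsed) | elapsed > hours]
    a[fresh] <- t
    anchors[[v]] <- a
  }
  out <- vs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the unit-by-sighting occurrence table
#'
#' One record per retained vessel sighting and social unit, with the
#' binary response `present` (1 when at least one member of the unit was
#' photographed during the sighting), the sighting's calendar year and
#' month as categorical terms, and its five-level photographic-effort
#' category.
#'
#' @param ds a [kw_dataset()].
#' @param partition a [detect_units()] partition.
#' @param dedup_hours window for [dedup_12h()]; `NULL` disables the
#'   exclusion.
#' @return data.frame with columns `sighting_id`, `unit`, `present`,
#'   `year`, `month`, `effort`, `vessel_id`, `timestamp` (factors for the
#'   model terms).
#' @export
occurrence_records <- function(ds, partition, dedup_hours = 12) {
  vs <- if (is.null(dedup_hours)) {
    v <- ds$sightings[ds$sightings$platform == "vessel", , drop = FALSE]
    memb <- partition$membership
    v$units_present <- lapply(v$individual_ids, function(g)
      sort(unique(unname(memb[g[g %in% names(memb)]]))))
    v[lengths(v$units_present) > 0, , drop = FALSE]
  } else dedup_12h(ds, partition, hours = dedup_hours)
  units <- sort(names(partition$units))
  n_s <- nrow(vs)
  rec <- data.frame(
    sighting_id = rep(vs$sighting_id, each = length(units)),
    unit = factor(rep(units, times = n_s), levels = units),
    present = as.integer(unlist(lapply(vs$units_present, function(u)
      units %in% u))),
    year = factor(rep(utc_year(vs$start_time), each = length(units))),
    month = factor(rep(as.integer(format(vs$start_time, "%m", tz = "UTC")),
                       each = length(units)), levels = 1:12),
    effort = rep(effort_category(vs$n_photos), each = length(units)),
    vessel_id = rep(vs$vessel_id, each = length(units)),
    timestamp = rep(vs$start_time, each = length(units)))
  rec$month <- droplevels(rec$month)
  rec$effort <- factor(rec$effort, ordered = FALSE)
  rec$effort <- droplevels(rec$effort)
  rec
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 LL + 2K + 2K(K + 1) / (n - K - 1)`.
#'
#' @param loglik maximised log-likelihood.
#' @param k number of estimated parameters.
#' @param n number of records.
#' @return AICc value.
#' @export
aicc <- function(loglik, k, n) {
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Parameter count of a binomial mixed model
#'
#' `K = 1 (intercept) + sum(levels - 1)` over fixed categorical terms
#' `+ 1` per random-intercept variance.
#'
#' @param records occurrence table ([occurrence_records()]).
#' @param fixed_terms character vector of fixed factor names.
#' @param random_terms character vector of random-intercept terms (each
#'   contributes one variance parameter; nested terms like
#'   `"sighting_id/unit"` contribute two).
#' @return integer parameter count.
#' @export
count_parameters <- function(records, fixed_terms, random_terms) {
  k <- 1L
  for (f in fixed_terms) k <- k + nlevels(factor(records[[f]])) - 1L
  k + sum(vapply(random_terms, function(r)
    length(strsplit(r, "/", fixed = TRUE)[[1]]), 1L))
}

#' Fit a binomial mixed model of unit occurrence
#'
#' Maximum-likelihood fit (Laplace approximation, via glmmTMB) of
#' `logit P(present) = fixed factors + random intercepts`, with treatment
#' contrasts (first level as reference). Returns the log-likelihood, the
#' parameter count per [count_parameters()], AICc with `n` = number of
#' records, and Nakagawa-Schielzeth coefficients of determination:
#' `R2m = Vf / (Vf + sum(Vg) + pi^2/3)` (fixed effects alone) and
#' `R2c = (Vf + sum(Vg)) / (Vf + sum(Vg) + pi^2/3)` (fixed plus random),
#' with `Vf` the variance of the fixed-effect linear predictor over the
#' records.
#'
#' @param records occurrence table ([occurrence_records()]).
#' @param fixed_terms character vector of fixed factor names (possibly
#'   empty for the null model).
#' @param random_terms character vector of random-intercept grouping
#'   factors, e.g. `"effort"` or `c("effort", "sighting_id/unit")`.
#' @param optimizer passed to glmmTMB (`"nlminb"` default; `"optim"`
#'   uses L-BFGS-B).
#' @return Object of class `occurrence_fit`: the glmmTMB `model` plus
#'   `loglik`, `K`, `aicc`, `r2_marginal`, `r2_conditional`, `sigma2`
#'   (named random-intercept variances), `beta`, `vcov_beta`,
#'   `fixed_terms`, `random_terms`, `n_records`, `converged`.
#' @export
fit_glmm <- function(records, fixed_terms = c("year", "month", "unit"),
                     random_terms = "effort", optimizer = "nlminb") {
  for (f in c(fixed_terms, setdiff(unlist(strsplit(random_terms, "/")), ""))) {
    if (!f %in% names(records)) stopf("records lack term '%s'", f)
    if (nlevels(factor(records[[f]])) < 2) {
      stopf("term '%s' needs at least 2 levels", f)
    }
  }
  rhs <- c(if (length(fixed_terms)) fixed_terms else "1",
           if (length(random_terms)) sprintf("(1 | %s)", random_terms))
  form <- stats::as.formula(paste("present ~", paste(rhs, collapse = " + ")))
  ctrl <- if (optimizer == "optim") {
    glmmTMB::glmmTMBControl(optimizer = stats::optim,
                            optArgs = list(method = "L-BFGS-B"))
  } else glmmTMB::glmmTMBControl()
  model <- glmmTMB::glmmTMB(form, data = records, family = stats::binomial(),
                            control = ctrl)
  conv <- isTRUE(model$fit$convergence == 0) && !model$sdr$pdHess %in% FALSE
  if (!conv) {
    warning("model fit did not fully converge; inspect $model")
  }
  ll <- as.numeric(logLik(model))
  n <- nrow(records)
  K <- count_parameters(records, fixed_terms, random_terms)
  beta <- glmmTMB::fixef(model)$cond
  if (any(abs(beta) > 15)) warning("possible separation: |beta| > 15")
  vc <- glmmTMB::VarCorr(model)$cond
  sigma2 <- if (length(random_terms)) {
    vapply(vc, function(m) as.numeric(m[1, 1]), 0)
  } else numeric()
  X <- model.matrix(stats::as.formula(
    paste("~", paste(if (length(fixed_terms)) fixed_terms else "1",
                     collapse = " + "))), records)
  vf <- var(as.numeric(X %*% beta))
  vtot <- vf + sum(sigma2) + pi^2 / 3
  structure(list(model = model, formula = form, loglik = ll, K = K,
                 aicc = aicc(ll, K, n),
                 r2_marginal = vf / vtot,
                 r2_conditional = (vf + sum(sigma2)) / vtot,
                 sigma2 = sigma2, beta = beta,
                 vcov_beta = as.matrix(vcov(model)$cond),
                 fixed_terms = fixed_terms, random_terms = random_terms,
                 n_records = n, converged = conv),
            class = "occurrence_fit")
}

#' @export
print.occurrence_fit <- function(x, ...) {
  cat("Binomial mixed model: ", deparse(x$formula), "\n", sep = "")
  cat(sprintf("  LL = %.2f, K = %d, AICc = %.2f, R2m = %.2f%%, R2c = %.2f%%\n",
              x$loglik, x$K, x$aicc, 100 * x$r2_marginal,
              100 * x$r2_conditional))
  cat(sprintf("  random-intercept variance(s): %s\n",
              paste(sprintf("%s = %.3f", names(x$sigma2), x$sigma2),
                    collapse = ", ")))
  invisible(x)
}

#' Forward AICc selection over the occurrence-model ladder
#'
#' Fits the nested ladder of binomial mixed models obtained by adding the
#' fixed terms in `terms_order` one at a time (all with the same random
#' structure), compares them by AICc, and reports Akaike weights plus the
#' likelihood-ratio statistic `X2 = 2 (LL_k - LL_(k-1))` with its degrees
#' of freedom and p-value for each step. Optionally refits the final
#' model with an extra nested random structure to probe
#' pseudoreplication.
#'
#' @param records occurrence table ([occurrence_records()]).
#' @param terms_order fixed terms, in the order they are offered.
#' @param random_terms baseline random structure.
#' @param nested_random optional extra random term for the final model
#'   (e.g. `"sighting_id/unit"`).
#' @return Object of class `occurrence_ladder`: `fits` (list of
#'   [fit_glmm()] results) and `table` (model, K, LL, AICc, wAICc, R2m
#'   and R2c in percent, X2, df, p_value), plus `best` (index of the
#'   lowest-AICc model).
#' @export
select_model <- function(records, terms_order = c("year", "month", "unit"),
                         random_terms = "effort", nested_random = NULL) {
  fits <- list()
  labels <- character()
  fits[[1]] <- fit_glmm(records, character(), random_terms)
  labels[1] <- "null"
  for (i in seq_along(terms_order)) {
    fits[[i + 1]] <- fit_glmm(records, terms_order[seq_len(i)], random_terms)
    labels[i + 1] <- paste(terms_order[seq_len(i)], collapse = " + ")
  }
  if (!is.null(nested_random)) {
    fits[[length(fits) + 1]] <- fit_glmm(records, terms_order,
                                         c(random_terms, nested_random))
    labels[length(labels) + 1] <- paste(paste(terms_order, collapse = " + "),
                                        "+ nested", nested_random)
  }
  ll <- vapply(fits, function(f) f$loglik, 0)
  K <- vapply(fits, function(f) f$K, 1L)
  aic <- vapply(fits, function(f) f$aicc, 0)
  delta <- aic - min(aic)
  w <- exp(-delta / 2); w <- w / sum(w)
  x2 <- c(NA, 2 * diff(ll))
  df <- c(NA, diff(K))
  pv <- ifelse(is.na(x2) | df <= 0, NA,
               pchisq(pmax(x2, 0), pmax(df, 1), lower.tail = FALSE))
  tab <- data.frame(model = labels, K = K, LL = ll, AICc = aic, wAICc = w,
                    R2m = 100 * vapply(fits, function(f) f$r2_marginal, 0),
                    R2c = 100 * vapply(fits, function(f) f$r2_conditional, 0),
                    X2 = x2, df = df, p_value = pv)
  structure(list(fits = fits, table = tab, best = which.min(aic)),
            class = "occurrence_ladder")
}

#' @export
print.occurrence_ladder <- function(x, ...) {
  print(x$table, digits = 4)
  cat(sprintf("best model by AICc: %s\n", x$table$model[x$best]))
  invisible(x)
}

#' Simulation-based diagnostics of an occurrence-model fit
#'
#' Simulates `n_sim` response vectors from the fitted model and computes,
#' per record, the scaled residual: the rank position of the observed
#' response within its simulated values, with uniform randomisation of
#' ties, which is Uniform(0, 1) under a correctly specified model. By
#' default the simulation is conditional on the estimated random-effect
#' values, which keeps the per-record residuals independent;
#' `conditional = FALSE` re-draws the random effects each time, in which
#' case residuals of records sharing a random-effect level become
#' dependent and the uniformity test loses its nominal calibration when
#' the grouping factor has few levels. Reports a Kolmogorov-Smirnov
#' uniformity
#' test, a dispersion ratio (variance of observed Pearson residuals over
#' the mean simulated variance, with a two-sided simulation p-value), an
#' outlier test (fraction of residuals at the extremes against its
#' binomial expectation), a zero-inflation ratio (observed zero count
#' over the simulated mean), a Durbin-Watson statistic on time-ordered
#' scaled residuals (permutation p), and generalized variance-inflation
#' factors of the fixed-effect design.
#'
#' @param fit an [fit_glmm()] result.
#' @param records the table the model was fitted to.
#' @param n_sim number of simulated datasets.
#' @param seed integer seed (simulation and tie randomisation).
#' @param conditional simulate at the estimated random-effect values
#'   (default) or re-draw random effects each simulation.
#' @return Object of class `occurrence_diagnostics`.
#' @export
diagnose <- function(fit, records, n_sim = 1000, seed = 1,
                     conditional = TRUE) {
  stopifnot(inherits(fit, "occurrence_fit"))
  y <- records$present
  n <- length(y)
  res <- with_seed(seed, {
    S <- if (conditional) {
      mu_hat <- stats::predict(fit$model, type = "response")
      matrix(rbinom(n * n_sim, 1, mu_hat), n, n_sim)
    } else {
      as.matrix(simulate(fit$model, nsim = n_sim))
    }
    # scaled residuals: randomised PIT of y within its simulated values
    less <- rowSums(S < y)
    eq <- rowSums(S == y)
    u <- (less + runif(n) * (eq + 1)) / (n_sim + 1)
    mu <- rowMeans(S)
    vr <- pmax(mu * (1 - pmin(mu, 1)), 1e-12)
    var_obs <- var((y - mu) / sqrt(vr))
    var_sim <- apply(S, 2, function(s) var((s - mu) / sqrt(vr)))
    disp <- var_obs / mean(var_sim)
    p_disp <- min(1, 2 * min(mean(var_sim >= var_obs),
                             mean(var_sim <= var_obs)))
    zeros_obs <- sum(y == 0)
    zeros_sim <- apply(S, 2, function(s) sum(s == 0))
    zi <- zeros_obs / mean(zeros_sim)
    p_zi <- min(1, 2 * min(mean(zeros_sim >= zeros_obs),
                           mean(zeros_sim <= zeros_obs)))
    # outliers: residuals outside the simulated envelope
    out_obs <- mean(u < 1 / (n_sim + 1) | u > n_sim / (n_sim + 1))
    p_out <- stats::binom.test(round(out_obs * n), n,
                               p = 2 / (n_sim + 1))$p.value
    ord <- order(records$timestamp)
    uo <- u[ord]
    dw <- sum(diff(uo)^2) / sum((uo - mean(uo))^2)
    dw_null <- vapply(seq_len(500), function(i) {
      up <- uo[sample.int(n)]
      sum(diff(up)^2) / sum((up - mean(up))^2)
    }, 0)
    p_dw <- min(1, 2 * min(mean(dw_null >= dw), mean(dw_null <= dw)))
    list(u = u, disp = disp, p_disp = p_disp, zi = zi, p_zi = p_zi,
         out_obs = out_obs, p_out = p_out, dw = dw, p_dw = p_dw)
  })
  ks <- suppressWarnings(ks.test(res$u, "punif"))
  vif <- if (length(fit$fixed_terms)) gvif(records, fit$fixed_terms) else NULL
  structure(list(dispersion_ratio = res$disp, dispersion_p = res$p_disp,
                 ks_statistic = unname(ks$statistic), ks_p = ks$p.value,
                 outlier_fraction = res$out_obs, outlier_p = res$p_out,
                 zero_inflation_ratio = res$zi, zero_inflation_p = res$p_zi,
                 durbin_watson = res$dw, durbin_watson_p = res$p_dw,
                 gvif = vif, scaled_residuals = res$u,
                 n_simulations = n_sim),
            class = "occurrence_diagnostics")
}

# Generalized VIF per term, from determinant ratios of the correlation
# matrix of the non-intercept fixed-effect design columns.
gvif <- function(records, fixed_terms) {
  X <- model.matrix(stats::as.formula(
    paste("~", paste(fixed_terms, collapse = " + "))), records)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  assign_idx <- attr(model.matrix(stats::as.formula(
    paste("~", paste(fixed_terms, collapse = " + "))), records), "assign")
  assign_idx <- assign_idx[assign_idx != 0]
  R <- cor(X)
  detR <- det(R)
  out <- vapply(seq_along(fixed_terms), function(j) {
    own <- assign_idx == j
    if (det(R) < 1e-12) return(Inf)
    det(as.matrix(R[own, own])) * det(as.matrix(R[!own, !own])) / detR
  }, 0)
  df <- vapply(seq_along(fixed_terms), function(j) sum(assign_idx == j), 0)
  data.frame(term = fixed_terms, gvif = out, df = df,
             gvif_scaled = out^(1 / (2 * df)))
}

#' @export
print.occurrence_diagnostics <- function(x, ...) {
  cat("Simulation-based residual diagnostics\n")
  cat(sprintf("  dispersion ratio = %.2f (p = %.3f); KS = %.3f (p = %.3f)\n",
              x$dispersion_ratio, x$dispersion_p, x$ks_statistic, x$ks_p))
  cat(sprintf("  zero-inflation ratio = %.2f (p = %.3f); outliers p = %.3f\n",
              x$zero_inflation_ratio, x$zero_inflation_p, x$outlier_p))
  cat(sprintf("  Durbin-Watson = %.2f (p = %.3f); %d simulations\n",
              x$durbin_watson, x$durbin_watson_p, x$n_simulations))
  if (!is.null(x$gvif)) {
    cat(sprintf("  max generalized VIF = %.2f\n", max(x$gvif$gvif)))
  }
  invisible(x)
}

#' Per-unit marginal occurrence probabilities with Holm contrasts
#'
#' Estimated marginal means for the social-unit factor: the linear
#' predictor is averaged on the logit scale over a balanced
#' (equal-weight) reference grid of the other fixed factors with random
#' effects at zero, then back-transformed; 95% confidence intervals are
#' delta-method intervals built on the link scale. All pairwise unit
#' contrasts are tested with z statistics and Holm step-down adjustment.
#'
#' @param fit an [fit_glmm()] result whose fixed terms include `unit`.
#' @param level confidence level.
#' @return Object of class `unit_emm`: `probabilities` (unit, prob,
#'   lower, upper) and `contrasts` (pair, estimate (log-odds), z, p,
#'   p_holm).
#' @export
emmeans_units <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "occurrence_fit"))
  if (!"unit" %in% fit$fixed_terms) stopf("model has no 'unit' fixed term")
  em <- emmeans::emmeans(fit$model, "unit", level = level)
  s <- as.data.frame(stats::confint(em))
  lcl <- s[[grep("LCL|lower", names(s))[1]]]
  ucl <- s[[grep("UCL|upper", names(s))[1]]]
  probs <- data.frame(unit = as.character(s$unit),
                      prob = plogis(s$emmean),
                      lower = plogis(lcl), upper = plogis(ucl))
  pr <- as.data.frame(emmeans::test(graphics::pairs(em), adjust = "none"))
  contrasts <- data.frame(pair = as.character(pr$contrast),
                          estimate = pr$estimate, z = pr$z.ratio,
                          p = pr$p.value,
                          p_holm = stats::p.adjust(pr$p.value, "holm"))
  structure(list(probabilities = probs, contrasts = contrasts,
                 level = level),
            class = "unit_emm")
}

#' @export
print.unit_emm <- function(x, ...) {
  cat(sprintf("Marginal unit occurrence probabilities (%d units, %.0f%% CI)\n",
              nrow(x$probabilities), 100 * x$level))
  print(transform(x$probabilities, prob = round(100 * prob, 1),
                  lower = round(100 * lower, 1),
                  upper = round(100 * upper, 1)), row.names = FALSE)
  sig <- sum(x$contrasts$p_holm < 0.05)
  cat(sprintf("  %d of %d pairwise contrasts significant after Holm\n",
              sig, nrow(x$contrasts)))
  invisible(x)
}
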