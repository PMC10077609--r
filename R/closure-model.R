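#' Specification of the closure regression
#'
#' Names the binary outcome and the ordered covariate terms of the
#' multivariate logistic closure model. Categorical terms expand to
#' indicator columns against fixed reference levels: private ownership, no
#' pediatrics department, non-teaching, low population density. Fertility
#' enters as a continuous covariate.
#'
#' @param response name of the binary outcome column.
#' @param covariates ordered character vector of model terms (cohort column
#'   names). The order also breaks AIC ties during backward elimination
#'   (the later-listed term is dropped first).
#' @param alpha significance level for reported tests.
#' @param gvif_threshold multicollinearity cutoff on `GVIF^(1/(2*df))`;
#'   terms above it are removed by [screen_multicollinearity()].
#' @return object of class `regression_spec`.
#' @export
regression_spec <- function(response = "closed_by_followup",
                            covariates = c("ownership", "has_pediatrics",
                                           "teaching", "density_category",
                                           "fertility_rate", "live_births",
                                           "min_interfacility_time"),
                            alpha = 0.05,
                            gvif_threshold = sqrt(10)) {
  stopifnot(is.character(response), length(response) == 1L,
            is.character(covariates), length(covariates) >= 1L,
            alpha > 0, alpha < 1, gvif_threshold > 0)
  structure(list(response = response, covariates = covariates,
                 alpha = alpha, gvif_threshold = gvif_threshold),
            class = "regression_spec")
}

# Reference levels of the categorical covariates (rows printed as "--").
.reference_levels <- list(
  ownership = c("private", "nonprofit", "public"),
  has_pediatrics = c("no", "yes"),
  teaching = c("no", "yes"),
  density_category = c("low", "medium", "high"),
  fertility_category = c("low", "medium", "high")
)

# Model frame with outcome 0/1 and releveled factors; errors on NA.
prepare_model_frame <- function(cohort, spec) {
  used <- c(spec$response, spec$covariates)
  miss <- setdiff(used, names(cohort))
  if (length(miss)) stop("cohort is missing column(s): ", paste(miss, collapse = ", "))
  df <- as.data.frame(cohort)[, used, drop = FALSE]
  for (v in used) {
    if (anyNA(df[[v]])) stop("missing values in '", v, "'")
  }
  y <- df[[spec$response]]
  if (is.logical(y)) y <- as.integer(y)
  if (!all(y %in% c(0L, 1L))) stop("response must be binary (0/1 or logical)")
  df[[spec$response]] <- y
  for (v in spec$covariates) {
    lv <- .reference_levels[[v]]
    if (v == "has_pediatrics" && is.logical(df[[v]])) {
      df[[v]] <- factor(ifelse(df[[v]], "yes", "no"), levels = c("no", "yes"))
    } else if (!is.null(lv) && !is.numeric(df[[v]])) {
      seen <- unique(as.character(df[[v]]))
      extra <- setdiff(seen, lv)
      if (length(extra)) {
        stop("unexpected level(s) in '", v, "': ", paste(extra, collapse = ", "),
             " (exclude university hospitals before fitting)")
      }
      df[[v]] <- factor(as.character(df[[v]]), levels = intersect(lv, seen))
    }
  }
  df
}

#' Fit the multivariate logistic closure model
#'
#' Maximum-likelihood logistic regression of the closure outcome on the
#' specified covariates, with Wald standard errors from the observed
#' information. The fit is checked against the score equations (max-norm of
#' the log-likelihood gradient below 1e-8) and refuses perfectly separated
#' or rank-deficient designs with a diagnostic naming the offending
#' covariate(s). p-values of all non-intercept coefficients are adjusted by
#' Benjamini-Hochberg within the model.
#'
#' @param cohort regression cohort (after [apply_exclusions()]).
#' @param spec a [regression_spec()].
#' @return object of class `closure_fit`: list with `table` (per-column
#'   coefficient, SE, OR, 95% CI, GVIF, raw and adjusted p), `term_gvif`,
#'   `stats` (log-likelihood, deviances, AIC, BIC, McFadden adjusted R^2,
#'   n), `model` (the underlying glm) and `spec`.
#' @export
fit_logistic <- function(cohort, spec = regression_spec()) {
  stopifnot(inherits(spec, "regression_spec"))
  df <- prepare_model_frame(cohort, spec)
  fm <- stats::reformulate(spec$covariates, response = spec$response)
  fit <- do.call(stats::glm,
                 list(formula = fm, family = stats::binomial(),
                      data = df,
                      control = stats::glm.control(epsilon = 1e-12, maxit = 100)))
  co <- stats::coef(fit)
  if (anyNA(co)) {
    stop("rank-deficient design; aliased column(s): ",
         paste(names(co)[is.na(co)], collapse = ", "))
  }
  mu <- stats::fitted(fit)
  extreme <- any(mu < 1e-10) || any(mu > 1 - 1e-10)
  if (extreme && (fit$deviance < 1e-6 || max(abs(co[-1L])) > 15)) {
    worst <- names(co[-1L])[which.max(abs(co[-1L]))]
    stop("perfect (or quasi-perfect) separation; separating covariate: ", worst)
  }
  # score-equation contract: gradient of the log-likelihood ~ 0. glm stops
  # on relative deviance change, which for covariates spanning thousands of
  # births can leave the raw score above tolerance; polish with Newton steps
  # and restart glm from the polished estimate if needed.
  X <- stats::model.matrix(fit)
  yv <- fit$y
  score_of <- function(beta) drop(crossprod(X, yv - stats::plogis(drop(X %*% beta))))
  if (max(abs(score_of(stats::coef(fit)))) >= 1e-8) {
    beta <- stats::coef(fit)
    for (it in seq_len(50L)) {
      muv <- stats::plogis(drop(X %*% beta))
      s <- drop(crossprod(X, yv - muv))
      if (max(abs(s)) < 1e-10) break
      H <- crossprod(X * (muv * (1 - muv)), X)
      step <- solve(H, s)
      # damped Newton: halve the step until the score norm improves
      for (h in 0:20) {
        cand <- beta + step / 2^h
        s2 <- drop(crossprod(X, yv - stats::plogis(drop(X %*% cand))))
        if (max(abs(s2)) < max(abs(s))) break
      }
      beta <- cand
    }
    fit <- suppressWarnings(do.call(stats::glm,
      list(formula = fm, family = stats::binomial(), data = df, start = beta,
           control = stats::glm.control(epsilon = 1e-12, maxit = 100))))
    fit$call$start <- NULL  # keep the call re-usable by stats::step/update
    if (max(abs(score_of(stats::coef(fit)))) >= 1e-8) {
      stop("IRLS did not reach the score tolerance (max |score| = ",
           format(max(abs(score_of(stats::coef(fit))))), ")")
    }
  }
  new_closure_fit(fit, df, spec)
}

# Assemble the reporting object around a fitted glm.
new_closure_fit <- function(fit, df, spec) {
  sm <- summary(fit)
  est <- sm$coefficients[, "Estimate"]
  se <- sm$coefficients[, "Std. Error"]
  p <- sm$coefficients[, "Pr(>|z|)"]
  z <- stats::qnorm(0.975)
  nm <- rownames(sm$coefficients)

  tl <- attr(stats::terms(fit), "term.labels")
  asg <- attr(stats::model.matrix(fit), "assign")
  term_of <- c("(Intercept)", tl)[asg + 1L]
  level_of <- mapply(function(cn, tm) {
    if (tm == "(Intercept)" || identical(cn, tm)) "" else sub(tm, "", cn, fixed = TRUE)
  }, nm, term_of)

  gv <- gvif(fit)
  gv_col <- gv$gvif[match(term_of, gv$term)]

  nonint <- term_of != "(Intercept)"
  p_adj <- rep(NA_real_, length(p))
  p_adj[nonint] <- bh_adjust(p[nonint])

  tab <- data.frame(
    term = term_of, level = unname(level_of),
    estimate = unname(est), se = unname(se),
    or = exp(unname(est)),
    ci_low = exp(unname(est) - z * unname(se)),
    ci_high = exp(unname(est) + z * unname(se)),
    gvif = gv_col,
    p_raw = unname(p), p_adj = p_adj,
    stringsAsFactors = FALSE
  )

  ll <- as.numeric(stats::logLik(fit))
  k <- length(stats::coef(fit)) - 1L  # parameters excluding intercept
  ll0 <- -fit$null.deviance / 2
  stats <- list(
    loglik = ll,
    null_deviance = fit$null.deviance, null_df = fit$df.null,
    deviance = fit$deviance, residual_df = fit$df.residual,
    aic = stats::AIC(fit), bic = stats::BIC(fit),
    mcfadden_adj_r2 = 1 - (ll - k) / ll0,
    n = length(fit$y)
  )
  structure(list(table = tab, term_gvif = gv, stats = stats,
                 model = fit, data = df, spec = spec),
            class = "closure_fit")
}

#' @export
print.closure_fit <- function(x, digits = 3, ...) {
  cat("Logistic closure model (n =", x$stats$n, ")\n")
  tab <- x$table
  show <- tab[tab$term != "(Intercept)",
              c("term", "level", "or", "ci_low", "ci_high", "gvif", "p_raw", "p_adj")]
  print(format(show, digits = digits), row.names = FALSE)
  with(x$stats, cat(sprintf(
    "\nLog-likelihood = %.1f; Null deviance = %.0f (df %d); Deviance = %.0f (df %d)\nAIC = %.1f; BIC = %.1f; McFadden adjusted R2 = %.3f\n",
    loglik, null_deviance, null_df, deviance, residual_df, aic, bic, mcfadden_adj_r2)))
  invisible(x)
}

#' Generalized variance inflation factors
#'
#' Per-term GVIF of a fitted model (determinant-ratio definition over the
#' coefficient correlation matrix, via [car::vif()]); for a 1-df term the
#' GVIF equals the classical VIF. A single-term model has no collinearity by
#' construction and reports GVIF = 1.
#'
#' @param fit a `closure_fit` or a fitted [stats::glm] model.
#' @param term optional term name; if given, that term's GVIF is returned as
#'   a scalar.
#' @return data.frame with `term`, `gvif`, `df` and `gvif_adj`
#'   (`GVIF^(1/(2*df))`), or a scalar when `term` is given.
#' @export
gvif <- function(fit, term = NULL) {
  m <- if (inherits(fit, "closure_fit")) fit$model else fit
  tl <- attr(stats::terms(m), "term.labels")
  if (length(tl) < 2L) {
    out <- data.frame(term = tl, gvif = rep(1, length(tl)),
                      df = vapply(tl, function(t) term_df(m, t), 0L),
                      gvif_adj = rep(1, length(tl)))
  } else {
    v <- car::vif(m)
    if (is.matrix(v)) {
      out <- data.frame(term = rownames(v), gvif = v[, 1L], df = as.integer(v[, 2L]),
                        gvif_adj = v[, 3L])
    } else {
      out <- data.frame(term = names(v), gvif = as.numeric(v), df = 1L,
                        gvif_adj = sqrt(as.numeric(v)))
    }
  }
  rownames(out) <- NULL
  if (!is.null(term)) {
    i <- match(term, out$term)
    if (is.na(i)) stop("no term '", term, "' in the model")
    return(out$gvif[i])
  }
  out
}

term_df <- function(m, t) {
  asg <- attr(stats::model.matrix(m), "assign")
  tl <- attr(stats::terms(m), "term.labels")
  as.integer(sum(asg == match(t, tl)))
}

#' Remove collinear terms before model selection
#'
#' Iteratively drops the term with the largest `GVIF^(1/(2*df))` while any
#' term exceeds the configured threshold, then refits.
#'
#' @param cohort regression cohort.
#' @param spec a [regression_spec()].
#' @return list with `fit` (the screened [fit_logistic()] result) and
#'   `removed` (character vector of dropped terms).
#' @export
screen_multicollinearity <- function(cohort, spec = regression_spec()) {
  removed <- character(0)
  cur <- spec
  repeat {
    fit <- fit_logistic(cohort, cur)
    gv <- fit$term_gvif
    if (nrow(gv) < 2L || all(gv$gvif_adj <= cur$gvif_threshold)) {
      return(list(fit = fit, removed = removed))
    }
    drop <- gv$term[which.max(gv$gvif_adj)]
    removed <- c(removed, drop)
    cur$covariates <- setdiff(cur$covariates, drop)
    if (length(cur$covariates) == 0L) stop("all terms removed as collinear")
  }
}

#' Box-Tidwell check of linearity on the logit scale
#'
#' Augments a univariate logistic model of the outcome on `x` with the
#' `x * log(x)` interaction term; a significant interaction indicates a
#' departure from logit-linearity. Non-positive covariate values are shifted
#' to positivity and the shift is reported.
#'
#' @param cohort cohort data.frame.
#' @param continuous_term name of a continuous covariate (> 10 distinct
#'   values required).
#' @param response outcome column name.
#' @param alpha significance level.
#' @return list with `term`, `statistic` (Wald z of the interaction), `p_value`,
#'   `linear` (TRUE iff p > alpha) and `shift` applied.
#' @export
check_logit_linearity <- function(cohort, continuous_term,
                                  response = "closed_by_followup",
                                  alpha = 0.05) {
  x <- cohort[[continuous_term]]
  if (is.null(x)) stop("no column '", continuous_term, "'")
  if (anyNA(x)) stop("missing values in '", continuous_term, "'")
  if (length(unique(x)) <= 10L) {
    stop("'", continuous_term, "' has too few distinct values for a linearity check")
  }
  y <- cohort[[response]]
  if (is.logical(y)) y <- as.integer(y)
  shift <- if (min(x) <= 0) 1 - min(x) else 0
  xs <- x + shift
  df <- data.frame(y = y, xs = xs, xlx = xs * log(xs))
  fit <- stats::glm(y ~ xs + xlx, family = stats::binomial(), data = df)
  sm <- summary(fit)$coefficients
  list(term = continuous_term,
       statistic = sm["xlx", "z value"],
       p_value = sm["xlx", "Pr(>|z|)"],
       linear = sm["xlx", "Pr(>|z|)"] > alpha,
       shift = shift)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' False-discovery-rate adjusted p-values: monotone in the ranks, never
#' below the raw p, capped at 1, invariant to input order and idempotent.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values in the input order.
#' @export
bh_adjust <- function(p_values) {
  if (anyNA(p_values) || any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Fit statistics of a closure model
#'
#' @param fit a `closure_fit`.
#' @return list with `aic`, `bic`, `mcfadden_adj_r2` (`1 - (LL - k)/LL0`
#'   with `k` the number of non-intercept parameters), plus the
#'   log-likelihood, deviances and `n`.
#' @export
model_fit_stats <- function(fit) {
  stopifnot(inherits(fit, "closure_fit"))
  fit$stats
}

#' Backward stepwise model selection by AIC
#'
#' Starting from the full model, repeatedly removes the whole term (a
#' categorical term is dropped as a block of indicator columns) whose
#' removal lowers the AIC the most, stopping when no removal lowers it.
#' The final model is refit so that its coefficient table, GVIFs and
#' adjusted p-values are consistent with the retained terms.
#'
#' @param cohort regression cohort.
#' @param spec a [regression_spec()] describing the full model.
#' @return object of class `stepwise_result`: list with `fit` (final
#'   `closure_fit`), `trace` (data.frame: `step`, `dropped`, `aic`),
#'   `full_aic`, `final_aic` and `retained`.
#' @export
backward_stepwise_aic <- function(cohort, spec = regression_spec()) {
  full <- fit_logistic(cohort, spec)
  st <- stats::step(full$model, direction = "backward", trace = 0)
  an <- st$anova
  trace <- data.frame(
    step = seq_len(nrow(an)) - 1L,
    dropped = sub("^- ", "", trimws(as.character(an$Step))),
    aic = an$AIC,
    stringsAsFactors = FALSE
  )
  retained <- attr(stats::terms(st), "term.labels")
  final_spec <- spec
  final_spec$covariates <- spec$covariates[spec$covariates %in% retained]
  final <- if (length(final_spec$covariates)) {
    fit_logistic(cohort, final_spec)
  } else {
    stop("stepwise selection removed every term; no final model")
  }
  structure(list(fit = final, trace = trace,
                 full_aic = full$stats$aic, final_aic = final$stats$aic,
                 retained = final_spec$covariates,
                 dropped = setdiff(spec$covariates, final_spec$covariates)),
            class = "stepwise_result")
}

#' @export
print.stepwise_result <- function(x, ...) {
  cat("Backward stepwise selection by AIC\n")
  cat("  full-model AIC:", format(x$full_aic, digits = 6),
      "-> final AIC:", format(x$final_aic, digits = 6), "\n")
  cat("  dropped:", if (length(x$dropped)) paste(x$dropped, collapse = ", ") else "(none)", "\n\n")
  print(x$fit, ...)
  invisible(x)
}

#' LOWESS closure-probability curve over annual live births
#'
#' Locally weighted linear smooth of the binary closure indicator on the
#' annual number of live births, optionally stratified by the availability
#' of a pediatrics department. Strata below the minimum size are skipped
#' with a warning. The smooth is evaluated on an equispaced grid over the
#' stratum's observed birth range.
#'
#' @param cohort cohort data.frame with `live_births`, `closed_by_followup`
#'   and (for stratification) `has_pediatrics`.
#' @param stratify_by_pediatrics stratify into pediatrics / no-pediatrics?
#' @param span LOWESS smoother fraction (default 2/3).
#' @param grid_n number of grid points per stratum.
#' @param min_stratum minimum observations per stratum.
#' @return data.frame of class `smooth_curve` with columns `stratum`, `x`
#'   (live births) and `y` (smoothed closure probability).
#' @export
lowess_curve <- function(cohort, stratify_by_pediatrics = TRUE,
                         span = 2/3, grid_n = 100L, min_stratum = 20L) {
  y <- cohort$closed_by_followup
  if (is.logical(y)) y <- as.integer(y)
  strata <- if (stratify_by_pediatrics) {
    split(seq_len(nrow(cohort)),
          ifelse(cohort$has_pediatrics %in% c(TRUE, "yes"), "pediatrics", "no_pediatrics"))
  } else {
    list(all = seq_len(nrow(cohort)))
  }
  out <- list()
  for (nm in names(strata)) {
    idx <- strata[[nm]]
    if (length(idx) < min_stratum) {
      warning("stratum '", nm, "' has fewer than ", min_stratum,
              " observations; skipped")
      next
    }
    # iter = 0: robustness reweighting would treat the minority outcome of a
    # binary indicator as outliers and bias the smooth toward the majority
    lw <- stats::lowess(cohort$live_births[idx], y[idx], f = span, iter = 0L)
    grid <- seq(min(lw$x), max(lw$x), length.out = grid_n)
    yy <- stats::approx(lw$x, lw$y, xout = grid, rule = 2, ties = mean)$y
    out[[nm]] <- data.frame(stratum = nm, x = grid, y = yy)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(stratum = character(0), x = numeric(0), y = numeric(0))
  rownames(res) <- NULL
  attr(res, "span") <- span
  class(res) <- c("smooth_curve", "data.frame")
  res
}
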