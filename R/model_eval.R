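#' Forward-stepwise logistic regression at a Wald entry threshold
#'
#' Builds the CPSP prediction model the conventional clinical way: candidate
#' terms enter one at a time, each step adding the candidate with the
#' smallest Wald p-value in the augmented model provided it is below
#' `entry_p`; after each entry, retained terms whose p-value has risen to or
#' above `entry_p` are removed. Stops when no candidate qualifies. With no
#' qualifying candidate at all, the intercept-only model is returned.
#'
#' @param phenotypes Data frame containing the outcome and candidate columns
#'   (augment it with a `prs` column to fit the genetic model).
#' @param candidate_terms Character vector of candidate predictor columns.
#' @param entry_p Wald p-value threshold for entry/retention (strict `<`).
#' @param outcome Binary outcome column (0/1).
#' @return A list of class `cpsp_model`: `fit` (the `glm`), `terms` (data
#'   frame with coefficient, SE, OR, Wald 95% CI, p), `auc`, `auc_ci`,
#'   `roc` (a `pROC::roc`), `n`.
#' @export
fit_stepwise_logistic <- function(phenotypes, candidate_terms, entry_p = 0.05,
                                  outcome = "cpsp") {
  stopifnot(outcome %in% names(phenotypes))
  dat <- phenotypes[stats::complete.cases(phenotypes[, c(outcome, candidate_terms),
                                                     drop = FALSE]), , drop = FALSE]
  y <- dat[[outcome]]
  if (length(unique(y)) < 2) stop("binary outcome must have both classes")

  fit_formula <- function(terms) {
    f <- if (length(terms) == 0) stats::reformulate("1", response = outcome)
      else stats::reformulate(terms, response = outcome)
    sep_stop <- function() stop("perfect separation detected for terms: ",
                                paste(terms, collapse = ", "), call. = FALSE)
    fit <- withCallingHandlers(
      stats::glm(f, data = dat, family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
          sep_stop()
        invokeRestart("muffleWarning")
      })
    # separated fits can also converge silently to a ~zero-deviance solution
    if (length(terms) > 0 && fit$deviance < 1e-6) sep_stop()
    fit
  }
  wald_p <- function(fit, term) {
    sm <- summary(fit)$coefficients
    rows <- grep(paste0("^", term), rownames(sm))
    if (length(rows) == 0) return(NA_real_)
    min(sm[rows, 4])
  }

  current <- character(0)
  remaining <- candidate_terms
  repeat {
    best_term <- NULL; best_p <- Inf
    for (tm in remaining) {
      fit_try <- fit_formula(c(current, tm))
      p <- wald_p(fit_try, tm)
      if (is.finite(p) && p < best_p) { best_p <- p; best_term <- tm }
    }
    if (is.null(best_term) || best_p >= entry_p) break
    current <- c(current, best_term)
    remaining <- setdiff(remaining, best_term)
    # backward check: drop entered terms that no longer hold p < entry_p
    repeat {
      fit_cur <- fit_formula(current)
      ps <- vapply(current, function(tm) wald_p(fit_cur, tm), numeric(1))
      worst <- which.max(ps)
      if (length(ps) > 0 && ps[worst] >= entry_p) {
        remaining <- c(remaining, current[worst])
        current <- current[-worst]
      } else break
    }
    if (length(remaining) == 0) break
  }
  fit <- fit_formula(current)
  cpsp_model_from_glm(fit, y)
}

# Wrap a fitted binomial glm with OR table and ROC/AUC.
cpsp_model_from_glm <- function(fit, y = fit$y) {
  sm <- summary(fit)$coefficients
  terms_df <- data.frame(
    term = rownames(sm),
    estimate = sm[, 1], se = sm[, 2],
    or = exp(sm[, 1]),
    or_lower = exp(sm[, 1] - stats::qnorm(0.975) * sm[, 2]),
    or_upper = exp(sm[, 1] + stats::qnorm(0.975) * sm[, 2]),
    p_value = sm[, 4],
    stringsAsFactors = FALSE
  )
  rownames(terms_df) <- NULL
  scores <- stats::fitted(fit)
  ra <- roc_auc(scores, y)
  structure(list(fit = fit, terms = terms_df, auc = ra$auc, auc_ci = ra$ci,
                 roc = attr(ra, "roc"), n = length(y)),
            class = "cpsp_model")
}

#' @export
print.cpsp_model <- function(x, ...) {
  cat("Logistic CPSP model (n =", x$n, "), AUC =", round(x$auc, 3),
      sprintf("(95%% CI %.3f-%.3f)\n", x$auc_ci[1], x$auc_ci[2]))
  print(x$terms, row.names = FALSE)
  invisible(x)
}

#' Rank-based AUC with DeLong confidence interval
#'
#' Area under the ROC curve (Mann-Whitney equivalence: ties count one half)
#' with an asymptotic 95% confidence interval by DeLong's covariance method.
#'
#' @param scores Predicted probabilities or any monotone risk score; higher
#'   scores are treated as predicting the positive class.
#' @param outcomes Binary 0/1 outcomes; both classes must be present.
#' @return List with `auc` and `ci` (length 2); the underlying `pROC::roc`
#'   object is attached as an attribute.
#' @export
roc_auc <- function(scores, outcomes) {
  outcomes <- as.integer(outcomes)
  if (length(unique(outcomes)) < 2) stop("both outcome classes must be present")
  r <- pROC::roc(response = outcomes, predictor = as.numeric(scores),
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  ci <- suppressWarnings(as.numeric(pROC::ci.auc(r, method = "delong")))
  structure(list(auc = as.numeric(pROC::auc(r)),
                 ci = c(max(0, ci[1]), min(1, ci[3]))),
            roc = r)
}

#' Compare two correlated (or independent) AUCs
#'
#' DeLong's test for the difference between two areas under ROC curves, the
#' standard equivalent of comparing models on the same individuals. Identical
#' score vectors have zero difference and return p = 1.
#'
#' @param fit_a,fit_b `cpsp_model` objects, or lists with `roc` elements.
#' @param paired Same individuals in both models (the usual case).
#' @return List with `p_value`, `auc_a`, `auc_b`.
#' @export
compare_auc <- function(fit_a, fit_b, paired = TRUE) {
  ra <- fit_a$roc; rb <- fit_b$roc
  if (paired) {
    if (length(ra$response) != length(rb$response) ||
        any(ra$response != rb$response))
      stop("paired comparison requires the same individuals and outcomes")
    if (isTRUE(all.equal(as.numeric(ra$predictor), as.numeric(rb$predictor))))
      return(list(p_value = 1, auc_a = as.numeric(pROC::auc(ra)),
                  auc_b = as.numeric(pROC::auc(rb))))
  }
  tt <- pROC::roc.test(ra, rb, method = "delong", paired = paired)
  list(p_value = as.numeric(tt$p.value),
       auc_a = as.numeric(pROC::auc(ra)), auc_b = as.numeric(pROC::auc(rb)))
}

#' Predicted CPSP probability as a function of PRS
#'
#' Evaluates the fitted logistic model along a PRS grid at a fixed CASI
#' value, with pointwise Wald 95% confidence bands on the probability scale,
#' and reports the PRS at which the predicted probability crosses 50%
#' (closed form `-(b0 + b_casi * casi) / b_prs`).
#'
#' @param fit A `cpsp_model` whose glm contains `prs` and `casi` terms.
#' @param prs_grid Numeric grid of PRS values.
#' @param casi_fixed CASI value at which to evaluate (e.g. the cohort median).
#' @return Data frame `prs`, `probability`, `lower`, `upper`; the 50%
#'   crossing is in `attr(, "crossing_prs")` (`NA` when undefined).
#' @export
probability_curve <- function(fit, prs_grid, casi_fixed) {
  glmfit <- fit$fit
  cf <- stats::coef(glmfit)
  if (!all(c("prs", "casi") %in% names(cf)))
    stop("model must contain `prs` and `casi` terms")
  nd <- data.frame(prs = prs_grid, casi = casi_fixed)
  pr <- stats::predict(glmfit, newdata = nd, type = "link", se.fit = TRUE)
  inv <- stats::plogis
  out <- data.frame(prs = prs_grid,
                    probability = inv(pr$fit),
                    lower = inv(pr$fit - stats::qnorm(0.975) * pr$se.fit),
                    upper = inv(pr$fit + stats::qnorm(0.975) * pr$se.fit))
  crossing <- if (cf[["prs"]] == 0) NA_real_ else
    -(cf[["(Intercept)"]] + cf[["casi"]] * casi_fixed) / cf[["prs"]]
  attr(out, "crossing_prs") <- crossing
  out
}

#' Bootstrap internal validation of a logistic model
#'
#' Refits the final model on `n_boot` resamples of the original rows (same
#' size, with replacement; resamples missing an outcome class are redrawn so
#' `n_boot` stays fixed) and reports, per term: the original coefficient, the
#' bootstrap mean, the bootstrap bias (bootstrap mean minus original), the
#' bias-corrected coefficient (original minus bias), the percentile 95%
#' interval, and the odds-ratio equivalents.
#'
#' @param phenotypes Data frame with outcome and model terms.
#' @param model_terms Character vector of predictor columns (fixed; no
#'   re-selection inside the bootstrap).
#' @param n_boot Number of bootstrap resamples.
#' @param seed Integer seed.
#' @param outcome Binary outcome column.
#' @return A data frame of class `bootstrap_summary` with one row per
#'   coefficient; the redraw count is in `attr(, "n_redrawn")`.
#' @export
bootstrap_validate <- function(phenotypes, model_terms, n_boot = 1000,
                               seed = 1L, outcome = "cpsp") {
  dat <- phenotypes[stats::complete.cases(
    phenotypes[, c(outcome, model_terms), drop = FALSE]), , drop = FALSE]
  f <- stats::reformulate(model_terms, response = outcome)
  orig <- stats::glm(f, data = dat, family = stats::binomial())
  cf0 <- stats::coef(orig)
  n <- nrow(dat)
  set.seed(seed)
  boots <- matrix(NA_real_, n_boot, length(cf0),
                  dimnames = list(NULL, names(cf0)))
  n_redrawn <- 0L
  for (b in seq_len(n_boot)) {
    repeat {
      rows <- sample.int(n, n, replace = TRUE)
      if (length(unique(dat[[outcome]][rows])) == 2) break
      n_redrawn <- n_redrawn + 1L
    }
    fitb <- suppressWarnings(
      stats::glm(f, data = dat[rows, , drop = FALSE], family = stats::binomial()))
    boots[b, ] <- stats::coef(fitb)[names(cf0)]
  }
  if (n_redrawn > 0.1 * n_boot)
    warning("more than 10% of bootstrap resamples were redrawn (",
            n_redrawn, " redraws)")
  boot_mean <- colMeans(boots)
  bias <- boot_mean - cf0
  corrected <- cf0 - bias
  qs <- apply(boots, 2, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
  out <- data.frame(term = names(cf0),
                    original = as.numeric(cf0),
                    boot_mean = as.numeric(boot_mean),
                    bias = as.numeric(bias),
                    corrected = as.numeric(corrected),
                    ci_lower = qs[1, ], ci_upper = qs[2, ],
                    or_corrected = exp(as.numeric(corrected)),
                    or_ci_lower = exp(qs[1, ]), or_ci_upper = exp(qs[2, ]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_redrawn") <- n_redrawn
  attr(out, "n_boot") <- n_boot
  attr(out, "seed") <- seed
  class(out) <- c("bootstrap_summary", "data.frame")
  out
}
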