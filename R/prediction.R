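#' Cramér's V association between two categorical variables
#'
#' `V = sqrt(chi2 / (n * (min(r, c) - 1)))` from the contingency table,
#' using the uncorrected Pearson chi-squared statistic and no bias
#' correction.
#'
#' @param a,b categorical vectors of equal length with at least two levels
#'   each.
#' @return V in `[0, 1]`.
#' @export
cramers_v <- function(a, b) {
  tab <- table(a, b)
  if (any(dim(tab) < 2L)) stop("both variables need at least two levels")
  chi2 <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))$statistic
  unname(sqrt(chi2 / (sum(tab) * (min(dim(tab)) - 1))))
}

#' Pairwise Cramér's V matrix
#'
#' @param features data.frame of categorical variables.
#' @return symmetric matrix of pairwise V values (diagonal 1; `NA` for
#'   single-level variables).
#' @export
cramers_v_matrix <- function(features) {
  p <- ncol(features)
  out <- matrix(NA_real_, p, p, dimnames = list(names(features),
                                                names(features)))
  diag(out) <- 1
  for (i in seq_len(p - 1)) for (j in seq(i + 1, p)) {
    v <- tryCatch(cramers_v(features[[i]], features[[j]]),
                  error = function(e) NA_real_)
    out[i, j] <- out[j, i] <- v
  }
  out
}

#' Dummy-encoded design matrix with most-frequent reference levels
#'
#' Each categorical variable with L levels contributes L - 1 indicator
#' columns; the reference level of every variable is its most frequent
#' level. Logical columns are coerced to factors.
#'
#' @param features data.frame of categorical variables.
#' @return list with `x` (numeric matrix, no intercept column), `assign`
#'   (source variable name per column), `reference` (dropped level per
#'   variable) and `dropped` (variables with a single observed level, which
#'   carry no information and are removed).
#' @export
make_design_matrix <- function(features) {
  df <- as.data.frame(features)
  single <- vapply(df, function(v) length(unique(v)) < 2L, logical(1))
  dropped <- names(df)[single]
  df <- df[, !single, drop = FALSE]
  if (ncol(df) == 0L) stop("no feature has two or more observed levels")
  refs <- character(ncol(df))
  for (j in seq_len(ncol(df))) {
    f <- droplevels(as.factor(df[[j]]))
    ref <- names(which.max(table(f)))
    df[[j]] <- stats::relevel(f, ref = ref)
    refs[j] <- ref
  }
  names(refs) <- names(df)
  mm <- stats::model.matrix(~., data = df)
  asg <- attr(mm, "assign")
  x <- mm[, asg != 0, drop = FALSE]
  list(x = x, assign = names(df)[asg[asg != 0]], reference = refs,
       dropped = dropped)
}

#' Variance-inflation-factor screen for a design matrix
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` comes from regressing column j on
#' all other columns. Exactly collinear columns are reported as infinite.
#'
#' @param x numeric design matrix without intercept.
#' @param threshold flag columns whose VIF exceeds this (default 5).
#' @return data.frame with `column`, `vif`, `flagged`.
#' @export
vif_screen <- function(x, threshold = 5) {
  p <- ncol(x)
  vif <- numeric(p)
  for (j in seq_len(p)) {
    r2 <- suppressWarnings(   # exact collinearity warns of a perfect fit
      summary(stats::lm(x[, j] ~ x[, -j, drop = FALSE]))$r.squared)
    vif[j] <- if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  data.frame(column = colnames(x), vif = vif, flagged = vif > threshold,
             row.names = NULL)
}

# rank-based (Wilcoxon) AUC; midranks handle ties
auc_rank <- function(y, score) {
  y <- as.integer(y)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# stratified train indices: proportion `prop` within each outcome class
split_train_test <- function(y, prop = 0.7, seed = 1) {
  set.seed(seed)
  idx <- unlist(lapply(split(seq_along(y), y), function(ii) {
    sample(ii, floor(length(ii) * prop))
  }))
  sort(idx)
}

classification_metrics <- function(y, p, cutoff = 0.5) {
  pred <- p >= cutoff
  c(auc = auc_rank(y, p),
    sensitivity = if (sum(y == 1) > 0) mean(pred[y == 1]) else NA_real_,
    specificity = if (sum(y == 0) > 0) mean(!pred[y == 0]) else NA_real_,
    rmse = sqrt(mean((p - y)^2)),
    r_squared = 1 - sum((y - p)^2) / sum((y - mean(y))^2))
}

#' Cross-validated penalized logistic fit
#'
#' Stratified 70/30 train/test split, then 10-fold cross-validation on the
#' training part to choose the penalty weight lambda by CV binomial
#' deviance, a fit at the chosen lambda, and held-out evaluation:
#' AUC, sensitivity and specificity of the predicted probabilities, plus
#' RMSE and R-squared on the probability scale for the model-comparison
#' stage. Columns are standardised internally; coefficients are reported on
#' the original indicator scale.
#'
#' @param x design matrix (no intercept), e.g. from
#'   [make_design_matrix()].
#' @param y binary outcome (0/1 or logical).
#' @param penalty `"ridge"`, `"lasso"` or `"elastic_net"` (mixing 0.5).
#' @param seed governs the split and the fold assignment.
#' @param train_frac training fraction (default 0.7).
#' @param nfolds CV folds (default 10).
#' @param cutoff probability cutoff for sensitivity/specificity (0.5).
#' @param lambda_rule `"1se"` (default) chooses the largest lambda whose CV
#'   deviance is within one standard error of the minimum — the standard
#'   parsimonious rule, which keeps variable selection sparse; `"min"`
#'   chooses the deviance-minimising lambda.
#' @return object of class `penalized_fit`: penalty, `lambda_grid`,
#'   `chosen_lambda`, `coefficients` (named, incl. intercept), `train_idx`,
#'   `metrics` (test split), `cv_auc` (fold-level AUC at the chosen lambda).
#' @export
cv_penalized_fit <- function(x, y, penalty = c("lasso", "ridge",
                                               "elastic_net"),
                             seed = 1, train_frac = 0.7, nfolds = 10,
                             cutoff = 0.5, lambda_rule = c("1se", "min")) {
  penalty <- match.arg(penalty)
  lambda_rule <- match.arg(lambda_rule)
  s_lab <- paste0("lambda.", lambda_rule)
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("outcome must contain both classes")
  alpha <- c(lasso = 1, ridge = 0, elastic_net = 0.5)[[penalty]]
  tr <- split_train_test(y, train_frac, seed)
  if (length(unique(y[tr])) < 2L) stop("training split has one class only")
  set.seed(seed + 1L)
  foldid <- sample(rep(seq_len(nfolds), length.out = length(tr)))
  cv <- glmnet::cv.glmnet(x[tr, , drop = FALSE], y[tr], family = "binomial",
                          alpha = alpha, foldid = foldid,
                          type.measure = "deviance")
  co <- as.matrix(stats::coef(cv, s = s_lab))[, 1]
  p_test <- as.numeric(stats::predict(cv, x[-tr, , drop = FALSE],
                                      s = s_lab, type = "response"))
  # fold-level AUC at the chosen lambda (CV counterpart of the test AUC)
  cv_auc <- vapply(seq_len(nfolds), function(f) {
    hold <- tr[foldid == f]
    fit_f <- glmnet::glmnet(x[setdiff(tr, hold), , drop = FALSE],
                            y[setdiff(tr, hold)], family = "binomial",
                            alpha = alpha, lambda = cv$lambda)
    pf <- as.numeric(stats::predict(fit_f, x[hold, , drop = FALSE],
                                    s = cv[[s_lab]], type = "response"))
    auc_rank(y[hold], pf)
  }, numeric(1))
  structure(list(penalty = penalty, alpha = alpha, lambda_grid = cv$lambda,
                 chosen_lambda = cv[[s_lab]], lambda_rule = lambda_rule,
                 coefficients = co,
                 train_idx = tr, seed = seed, cv_fit = cv,
                 metrics = classification_metrics(y[-tr], p_test, cutoff),
                 cv_auc = cv_auc),
            class = "penalized_fit")
}

#' Compare ridge, LASSO and elastic-net fits
#'
#' The model with the lowest RMSE and the highest R-squared wins; if the two
#' metrics disagree the discordance is reported and no winner is flagged.
#' Exact ties are broken by the higher AUC.
#'
#' @param fits list of [cv_penalized_fit()] objects on identical splits.
#' @return data.frame of metrics per penalty with a logical `winner` column;
#'   attribute `discordant` signals metric disagreement.
#' @export
compare_penalties <- function(fits) {
  tab <- do.call(rbind, lapply(fits, function(f) {
    data.frame(penalty = f$penalty, rmse = f$metrics[["rmse"]],
               r_squared = f$metrics[["r_squared"]],
               auc = f$metrics[["auc"]])
  }))
  rownames(tab) <- NULL
  best_rmse <- tab$rmse == min(tab$rmse)
  if (sum(best_rmse) > 1L) {   # exact RMSE tie: higher AUC decides
    best_rmse <- best_rmse & tab$auc == max(tab$auc[best_rmse])
  }
  concordant <- tab$r_squared[which(best_rmse)[1]] == max(tab$r_squared)
  tab$winner <- if (concordant) best_rmse else rep(FALSE, nrow(tab))
  attr(tab, "discordant") <- !concordant
  tab
}

#' Final logistic model from LASSO group-survival selection
#'
#' A source variable is retained iff at least one of its dummy columns has a
#' nonzero LASSO coefficient at the chosen lambda; the whole variable (all
#' its levels) then enters an unpenalized logistic refit on the training
#' split. Reports odds ratios with 95% Wald confidence intervals, held-out
#' AUC/sensitivity/specificity, and the Hosmer-Lemeshow test and Nagelkerke
#' R-squared on the training fit.
#'
#' @param fit a [cv_penalized_fit()] LASSO fit.
#' @param features the categorical feature data.frame the design came from.
#' @param y binary outcome (same order as `features`).
#' @param design the [make_design_matrix()] object used for `fit`.
#' @param cutoff probability cutoff for sensitivity/specificity (0.5).
#' @return object of class `model_report`: `selected`, `coefficients`
#'   (term, estimate, odds ratio, CI, p), `metrics`, `hosmer_lemeshow`,
#'   `nagelkerke_r2`, and the `glm` fit.
#' @export
final_logistic_from_lasso <- function(fit, features, y, design,
                                      cutoff = 0.5) {
  stopifnot(inherits(fit, "penalized_fit"))
  co <- fit$coefficients[colnames(design$x)]
  selected <- unique(design$assign[co != 0])
  tr <- fit$train_idx
  y <- as.integer(y)
  dat <- as.data.frame(features)
  dat$.y <- y
  if (length(selected) == 0L) {
    warning("no variable survived LASSO selection; intercept-only model")
    form <- stats::as.formula(".y ~ 1")
  } else {
    form <- stats::as.formula(paste(".y ~",
                                    paste(selected, collapse = " + ")))
  }
  gm <- stats::glm(form, family = stats::binomial(), data = dat[tr, ])
  sm <- summary(gm)$coefficients
  ci <- stats::confint.default(gm)
  coefs <- data.frame(term = rownames(sm), estimate = sm[, 1],
                      odds_ratio = exp(sm[, 1]),
                      or_low = exp(ci[, 1]), or_high = exp(ci[, 2]),
                      p_value = sm[, 4], row.names = NULL)
  p_train <- stats::fitted(gm)
  p_test <- stats::predict(gm, newdata = dat[-tr, ], type = "response")
  ll1 <- as.numeric(stats::logLik(gm))
  ll0 <- as.numeric(stats::logLik(stats::glm(.y ~ 1, stats::binomial(),
                                             data = dat[tr, ])))
  structure(list(selected = selected, coefficients = coefs,
                 metrics = classification_metrics(y[-tr], p_test, cutoff),
                 hosmer_lemeshow = hosmer_lemeshow(y[tr], p_train),
                 nagelkerke_r2 = nagelkerke_r2(ll0, ll1, length(tr)),
                 fit = gm),
            class = "model_report")
}

#' Plain logistic model on all variables (sensitivity mode)
#'
#' Skips LASSO selection: every feature with at least two observed levels
#' enters an unpenalized logistic fit (single-level variables are dropped,
#' as they carry no information and break estimation).
#'
#' @inheritParams final_logistic_from_lasso
#' @param seed governs the stratified 70/30 split.
#' @param train_frac training fraction.
#' @return a `model_report`, as in [final_logistic_from_lasso()].
#' @export
plain_logistic <- function(features, y, seed = 1, train_frac = 0.7,
                           cutoff = 0.5) {
  y <- as.integer(y)
  keep <- vapply(features, function(v) length(unique(v)) > 1L, logical(1))
  dat <- as.data.frame(features[, keep, drop = FALSE])
  vars <- names(dat)
  dat$.y <- y
  tr <- split_train_test(y, train_frac, seed)
  form <- stats::as.formula(paste(".y ~", if (length(vars))
    paste(vars, collapse = " + ") else "1"))
  gm <- stats::glm(form, family = stats::binomial(), data = dat[tr, ])
  sm <- summary(gm)$coefficients
  ci <- stats::confint.default(gm)
  coefs <- data.frame(term = rownames(sm), estimate = sm[, 1],
                      odds_ratio = exp(sm[, 1]),
                      or_low = exp(ci[, 1]), or_high = exp(ci[, 2]),
                      p_value = sm[, 4], row.names = NULL)
  ll1 <- as.numeric(stats::logLik(gm))
  ll0 <- as.numeric(stats::logLik(stats::glm(.y ~ 1, stats::binomial(),
                                             data = dat[tr, ])))
  p_test <- stats::predict(gm, newdata = dat[-tr, ], type = "response")
  structure(list(selected = vars, coefficients = coefs,
                 metrics = classification_metrics(y[-tr], p_test, cutoff),
                 hosmer_lemeshow = hosmer_lemeshow(y[tr], stats::fitted(gm)),
                 nagelkerke_r2 = nagelkerke_r2(ll0, ll1, length(tr)),
                 fit = gm),
            class = "model_report")
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Groups observations into deciles of predicted risk (ties kept together;
#' groups whose expected count is zero are merged into their neighbour) and
#' compares observed and expected event counts:
#' `sum (O - E)^2 / (E (1 - E/n_g))`, referred to chi-squared with
#' `groups - 2` degrees of freedom.
#'
#' @param y binary outcomes.
#' @param p predicted probabilities.
#' @param groups number of risk groups (default 10).
#' @return list with `statistic`, `p_value`, `df`, `table` (per-group O, E,
#'   n).
#' @export
hosmer_lemeshow <- function(y, p, groups = 10) {
  y <- as.integer(y)
  stopifnot(length(y) == length(p), length(y) >= groups)
  br <- unique(stats::quantile(p, probs = seq(0, 1, length.out = groups + 1)))
  if (length(br) < 3L) br <- c(-Inf, mean(range(p)), Inf)
  g <- cut(p, br, include.lowest = TRUE)
  O <- tapply(y, g, sum); E <- tapply(p, g, sum); n_g <- tapply(y, g, length)
  keep <- !is.na(n_g)
  O <- O[keep]; E <- E[keep]; n_g <- n_g[keep]
  merged <- 0L
  while (length(E) > 2L && any(E < 1e-8 | n_g - E < 1e-8)) {
    i <- which(E < 1e-8 | n_g - E < 1e-8)[1]
    j <- if (i == 1L) 2L else i - 1L
    O[j] <- O[j] + O[i]; E[j] <- E[j] + E[i]; n_g[j] <- n_g[j] + n_g[i]
    O <- O[-i]; E <- E[-i]; n_g <- n_g[-i]
    merged <- merged + 1L
  }
  stat <- sum((O - E)^2 / (E * (1 - E / n_g)))
  df <- max(1L, length(O) - 2L)
  list(statistic = unname(stat),
       p_value = stats::pchisq(stat, df, lower.tail = FALSE), df = df,
       table = data.frame(observed = as.numeric(O), expected = as.numeric(E),
                          n = as.numeric(n_g)),
       merged_groups = merged)
}

#' Nagelkerke pseudo R-squared
#'
#' Cox-Snell `1 - exp(2 (ll0 - ll1) / n)` rescaled by its maximum
#' `1 - exp(2 ll0 / n)`.
#'
#' @param loglik_null log-likelihood of the intercept-only model.
#' @param loglik_model log-likelihood of the fitted model (>= null).
#' @param n number of observations (> 0).
#' @return R-squared in `[0, 1]`.
#' @export
nagelkerke_r2 <- function(loglik_null, loglik_model, n) {
  if (n <= 0) stop("n must be positive")
  cs <- 1 - exp(2 * (loglik_null - loglik_model) / n)
  cs_max <- 1 - exp(2 * loglik_null / n)
  if (cs_max <= 0) return(0)
  min(1, cs / cs_max)
}
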