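test_that("Cramer's V reproduces closed-form values", {
  a <- rep(c("u", "v"), each = 20)
  b <- rep(c("u", "v"), each = 20)
  expect_equal(cramers_v(a, b), 1.0)
  b2 <- rep(c("u", "v", "u", "v"), each = 10)
  expect_equal(cramers_v(a, b2), 0.0)
  # 2x2 table [[20,10],[10,20]]: chi2 = 20/3, V = 1/3
  a3 <- rep(c("x", "y"), c(30, 30))
  b3 <- c(rep("p", 20), rep("q", 10), rep("p", 10), rep("q", 20))
  expect_equal(cramers_v(a3, b3), 1 / 3, tolerance = 1e-12)
  expect_error(cramers_v(rep("x", 10), rep(c("p", "q"), 5)), "two levels")
})

test_that("design matrix drops the most frequent level of each variable", {
  f <- data.frame(cls = c("a", "a", "a", "b", "c"),
                  flag = c("yes", "no", "no", "no", "no"))
  dsg <- make_design_matrix(f)
  expect_equal(dsg$reference, c(cls = "a", flag = "no"))
  expect_equal(ncol(dsg$x), 3)     # (3-1) + (2-1)
  expect_equal(unname(dsg$assign), c("cls", "cls", "flag"))
})

test_that("VIF detects collinearity and closed-form two-variable case", {
  set.seed(1)
  n <- 500
  x1 <- rnorm(n); x2 <- rnorm(n); x3 <- rnorm(n)
  X <- cbind(a = x1, b = x2, c = x3)
  v <- vif_screen(X)
  expect_true(all(v$vif < 1.1))
  # duplicated column -> infinite VIF
  v2 <- vif_screen(cbind(a = x1, b = x1, c = x2))
  expect_true(any(is.infinite(v2$vif)))
  # pair with known correlation r: VIF = 1/(1-r^2)
  r <- 0.9
  x2c <- r * x1 + sqrt(1 - r^2) * x2
  v3 <- vif_screen(cbind(a = x1, b = x2c))
  r_emp <- cor(x1, x2c)
  expect_equal(v3$vif[1], 1 / (1 - r_emp^2), tolerance = 1e-8)
})

sim_logit_design <- function(n, beta, seed) {
  set.seed(seed)
  p <- length(beta)
  x <- matrix(rbinom(n * p, 1, 0.5), n, p,
              dimnames = list(NULL, paste0("v", seq_len(p))))
  y <- rbinom(n, 1, plogis(-0.3 + drop(x %*% beta)))
  list(x = x, y = y)
}

test_that("penalization limits: huge lambda zeroes, lambda ~ 0 matches ML", {
  d <- sim_logit_design(400, c(0.8, -0.6, 0.4), seed = 2)
  big <- glmnet::glmnet(d$x, d$y, family = "binomial", alpha = 1,
                        lambda = 5)
  co <- as.matrix(coef(big))[, 1]
  expect_true(all(co[-1] == 0))
  expect_equal(unname(co[1]), qlogis(mean(d$y)), tolerance = 1e-6)
  # unpenalized: agree with an independent Newton-Raphson optimizer
  small <- glmnet::glmnet(d$x, d$y, family = "binomial", alpha = 1,
                          lambda = 0, thresh = 1e-14)
  co2 <- as.matrix(coef(small))[, 1]
  # hand-rolled Newton-Raphson for logistic ML
  X <- cbind(1, d$x); b <- rep(0, ncol(X))
  for (it in 1:50) {
    mu <- plogis(drop(X %*% b))
    W <- mu * (1 - mu)
    b <- b + solve(t(X) %*% (X * W), t(X) %*% (d$y - mu))
  }
  expect_equal(unname(co2), unname(drop(b)), tolerance = 1e-4)
})

test_that("the group-survival rule selects true variables and refits them", {
  hits <- 0; null_ok <- 0; sign_ok <- TRUE
  n_seeds <- 10
  for (s in 1:n_seeds) {
    beta <- c(0.7, -0.7, 0.7, rep(0, 6))
    d <- sim_logit_design(5000, beta, seed = 100 + s)
    feats <- as.data.frame(lapply(as.data.frame(d$x), function(v)
      factor(ifelse(v == 1, "yes", "no"), levels = c("no", "yes"))))
    dsg <- make_design_matrix(feats)
    fit <- cv_penalized_fit(dsg$x, d$y, "lasso", seed = s)
    rep_ <- final_logistic_from_lasso(fit, feats, d$y, dsg)
    true_vars <- paste0("v", 1:3)
    if (all(true_vars %in% rep_$selected)) hits <- hits + 1
    if (sum(!rep_$selected %in% true_vars) <= 1) null_ok <- null_ok + 1
    co <- rep_$coefficients
    for (j in 1:3) {
      row <- co[co$term == paste0("v", j, "yes"), ]
      if (nrow(row) == 1 && sign(row$estimate) != sign(beta[j]))
        sign_ok <- FALSE
    }
  }
  expect_gte(hits / n_seeds, 0.9)
  expect_gte(null_ok / n_seeds, 0.9)
  expect_true(sign_ok)
})

test_that("lasso path is monotone and null data give chance-level AUC", {
  d <- sim_logit_design(800, rep(0.5, 4), seed = 9)
  fit <- glmnet::glmnet(d$x, d$y, family = "binomial", alpha = 1)
  nz <- colSums(as.matrix(fit$beta) != 0)
  # nonzero count non-increasing as lambda grows (reverse path order)
  expect_true(all(diff(rev(nz)) <= 0))
  # no planted effects: held-out AUC near 0.5
  d0 <- sim_logit_design(5000, rep(0, 6), seed = 10)
  feats <- as.data.frame(lapply(as.data.frame(d0$x), factor))
  dsg <- make_design_matrix(feats)
  f <- cv_penalized_fit(dsg$x, d0$y, "lasso", seed = 4)
  expect_gte(f$metrics[["auc"]], 0.45)
  expect_lte(f$metrics[["auc"]], 0.55)
})

test_that("penalty comparison applies the lowest-RMSE/highest-R2 rule", {
  fake <- function(p, rmse, r2, auc) {
    structure(list(penalty = p,
                   metrics = c(rmse = rmse, r_squared = r2, auc = auc)),
              class = "penalized_fit")
  }
  tab <- compare_penalties(list(fake("ridge", 0.40, 0.20, 0.7),
                                fake("lasso", 0.41, 0.19, 0.7),
                                fake("elastic_net", 0.42, 0.18, 0.7)))
  expect_equal(tab$penalty[tab$winner], "ridge")
  expect_false(attr(tab, "discordant"))
  # discordant metrics: no winner flagged
  tab2 <- compare_penalties(list(fake("ridge", 0.40, 0.10, 0.7),
                                 fake("lasso", 0.41, 0.30, 0.7)))
  expect_true(attr(tab2, "discordant"))
  expect_false(any(tab2$winner))
  # identical fits: AUC breaks the tie, first maximal flagged
  tab3 <- compare_penalties(list(fake("ridge", 0.4, 0.2, 0.6),
                                 fake("lasso", 0.4, 0.2, 0.8)))
  expect_equal(tab3$penalty[tab3$winner], "lasso")
})

test_that("rank AUC agrees with pROC", {
  skip_if_not_installed("pROC")
  set.seed(5)
  y <- rbinom(200, 1, 0.4)
  p <- plogis(rnorm(200) + y)
  expect_equal(rxadhere:::auc_rank(y, p),
               as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("Hosmer-Lemeshow is zero under perfect group calibration and calibrated overall", {
  # groups whose predicted probability equals the observed group rate
  p <- rep(c(0.2, 0.5, 0.8), each = 10)
  y <- c(rep(c(1, 0), c(2, 8)), rep(c(1, 0), c(5, 5)), rep(c(1, 0), c(8, 2)))
  hl <- hosmer_lemeshow(y, p, groups = 3)
  expect_equal(hl$statistic, 0)
  expect_equal(hl$p_value, 1)
  # calibration property: well-specified model passes, shifted model fails
  set.seed(11)
  pass <- 0; fail <- 0
  for (s in 1:20) {
    pr <- runif(2000, 0.05, 0.9)
    y2 <- rbinom(2000, 1, pr)
    if (hosmer_lemeshow(y2, pr)$p_value > 0.05) pass <- pass + 1
    bad <- pmin(pr + 0.2, 0.99)
    if (hosmer_lemeshow(y2, bad)$p_value < 0.05) fail <- fail + 1
  }
  expect_gte(pass / 20, 0.9)
  expect_gte(fail / 20, 0.9)
})

test_that("Nagelkerke R2 matches hand computation and limits", {
  expect_equal(nagelkerke_r2(-50, -50, 100), 0)
  # hand fixture: CS = 1-exp(-0.2) = 0.1813, max = 1-exp(-1.3862) = 0.75
  expect_equal(nagelkerke_r2(-69.31, -59.31, 100),
               (1 - exp(-0.2)) / (1 - exp(2 * -69.31 / 100)),
               tolerance = 1e-12)
  expect_equal(round(nagelkerke_r2(-69.31, -59.31, 100), 4), 0.2417)
  # perfect prediction limit
  expect_equal(nagelkerke_r2(-69.31, 0, 100), 1)
  expect_error(nagelkerke_r2(-1, 0, 0), "positive")
})

test_that("plain logistic sensitivity mode matches LASSO-selected signs", {
  beta <- c(0.7, -0.7, 0.7, 0, 0, 0)
  d <- sim_logit_design(4000, beta, seed = 77)
  feats <- as.data.frame(lapply(as.data.frame(d$x), function(v)
    factor(ifelse(v == 1, "yes", "no"), levels = c("no", "yes"))))
  dsg <- make_design_matrix(feats)
  lrep <- final_logistic_from_lasso(
    cv_penalized_fit(dsg$x, d$y, "lasso", seed = 3), feats, d$y, dsg)
  prep <- plain_logistic(feats, d$y, seed = 3)
  for (j in 1:3) {
    tm <- paste0("v", j, "yes")
    a <- lrep$coefficients[lrep$coefficients$term == tm, "estimate"]
    b <- prep$coefficients[prep$coefficients$term == tm, "estimate"]
    if (length(a) == 1) expect_equal(sign(a), sign(b))
    expect_equal(sign(b), sign(beta[j]))
  }
})
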