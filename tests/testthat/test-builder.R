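test_that("logistic fit matches closed forms", {
  # intercept only: logit of prevalence
  f0 <- fit_logistic(matrix(numeric(0), nrow = 8, ncol = 0),
                     rep(c("died", "survived"), c(2, 6)))
  expect_equal(f0$intercept, log(0.25 / 0.75), tolerance = 1e-8)

  # single binary item, 2x2 table (a,b,c,d) all > 0 -> log odds ratio
  tabs <- list(c(10, 20, 14, 56), c(5, 45, 20, 30), c(7, 3, 9, 81))
  for (tb in tabs) {
    x <- matrix(rep(c(1, 0), c(tb[1] + tb[2], tb[3] + tb[4])), ncol = 1)
    y <- c(rep(c(TRUE, FALSE), tb[1:2]), rep(c(TRUE, FALSE), tb[3:4]))
    f <- fit_logistic(x, y)
    expect_equal(unname(f$coefficients),
                 log(tb[1] * tb[4] / (tb[2] * tb[3])), tolerance = 1e-7)
  }
})

test_that("logistic fit agrees with a coarse grid search on tiny data", {
  set.seed(12)
  n <- 50
  x <- cbind(a = sample(0:2, n, TRUE), b = rbinom(n, 1, 0.5))
  y <- runif(n) < plogis(-1 + 0.7 * x[, 1] - 0.4 * x[, 2])
  if (length(unique(y)) < 2) y[1:2] <- c(TRUE, FALSE)
  fit <- fit_logistic(x, y)
  ll <- function(b) {
    eta <- b[1] + x %*% b[-1]
    sum(y * eta - log1p(exp(eta)))
  }
  grid <- seq(-3, 3, by = 0.05)
  best <- c(NA, NA, NA)
  best_ll <- -Inf
  for (b0 in grid) for (b1 in grid[grid >= -1 & grid <= 2]) {
    for (b2 in grid[grid >= -2 & grid <= 1]) {
      v <- ll(c(b0, b1, b2))
      if (v > best_ll) {
        best_ll <- v
        best <- c(b0, b1, b2)
      }
    }
  }
  est <- c(fit$intercept, unname(fit$coefficients))
  expect_true(all(abs(est - best) <= 0.051))
  expect_gte(fit$log_likelihood, best_ll)
})

test_that("degenerate logistic inputs are rejected", {
  expect_error(fit_logistic(matrix(c(0, 1), ncol = 1), c(TRUE, TRUE)),
               "constant")
  expect_error(fit_logistic(matrix(c(1, 1, 1), ncol = 1),
                            c(TRUE, FALSE, TRUE)), "constant")
  expect_error(
    fit_logistic(matrix(c(0, 0, 1, 1), ncol = 1),
                 c(FALSE, FALSE, TRUE, TRUE)),
    "separated")
})

test_that("integerize applies the x2-and-round rule", {
  sp <- bin_spec(list(
    sex = score_item_categorical(c(male = 1, female = 0)),
    cause = score_item_categorical(c(disease = 1, non_disease = 0)),
    hr = score_item_binned(upper = c(54, 87), scores = c(1, 0), above = 2)
  ))
  fit <- list(coefficients = c(sex = 0.455, cause = 0.786, hr = 0.110),
              converged = TRUE)
  tab <- integerize(fit, sp)
  expect_equal(unname(tab$items$sex$scores["male"]), 1)     # round(0.910)
  expect_equal(unname(tab$items$cause$scores["disease"]), 2)  # round(1.572)
  expect_equal(tab$items$hr$scores, c(0, 0))
  expect_equal(tab$items$hr$above, 0)  # round(0.44)

  # zero coefficient zeroes every bin
  fit0 <- list(coefficients = c(sex = 0, cause = 0, hr = 0),
               converged = TRUE)
  tab0 <- integerize(fit0, sp)
  expect_true(all(unlist(lapply(tab0$items, function(it) {
    if (it$kind == "categorical") it$scores else c(it$scores, it$above)
  })) == 0))

  # half-away-from-zero: 2*0.25*3 = 1.5 -> 2
  sph <- bin_spec(list(a = score_item_categorical(c(x = 3, y = 0))))
  fith <- list(coefficients = c(a = 0.25), converged = TRUE)
  expect_equal(unname(integerize(fith, sph)$items$a$scores["x"]), 2)

  # negative products floor at zero with a warning
  fitn <- list(coefficients = c(a = -0.5), converged = TRUE)
  expect_warning(tn <- integerize(fitn, sph), "floored")
  expect_equal(unname(tn$items$a$scores["x"]), 0)

  # missing coefficient is a mapping error
  expect_error(integerize(list(coefficients = c(sex = 1), converged = TRUE),
                          sp), "cause")
})

test_that("integerize is scale-consistent", {
  sp <- bin_spec(list(
    a = score_item_binned(upper = c(1, 2), scores = c(3, 1), above = 5),
    b = score_item_categorical(c(p = 2, q = 0))
  ))
  fit <- list(coefficients = c(a = 0.37, b = 0.81), converged = TRUE)
  doubled <- bin_spec(list(
    a = score_item_binned(upper = c(1, 2), scores = c(6, 2), above = 10),
    b = score_item_categorical(c(p = 4, q = 0))
  ))
  halved <- list(coefficients = c(a = 0.185, b = 0.405), converged = TRUE)
  t1 <- integerize(fit, sp)
  t2 <- integerize(halved, doubled)
  expect_equal(t1$items$a$scores, t2$items$a$scores)
  expect_equal(t1$items$b$scores, t2$items$b$scores)
})

test_that("auroc matches brute force and its invariances", {
  expect_equal(auroc(c(1, 2, 3, 4),
                     rep(c("survived", "died"), each = 2)), 1.0)
  expect_equal(auroc(c(1, 3, 2, 4),
                     rep(c("survived", "died"), each = 2)), 0.75)
  set.seed(31)
  for (i in 1:10) {
    n <- sample(6:20, 1)
    scores <- sample(0:8, n, replace = TRUE)  # ties likely
    outcomes <- rep("survived", n)
    outcomes[sample(n, sample(2:(n - 2), 1))] <- "died"
    a <- auroc(scores, outcomes)
    expect_equal(a, brute_auroc(scores, outcomes))
    # monotone transformation invariance
    expect_equal(auroc(exp(scores / 3), outcomes), a)
    # in the absence of ties, auc(x) + auc(-x) = 1
    jit <- scores + runif(n) / 10
    expect_equal(auroc(jit, outcomes) + auroc(-jit, outcomes), 1.0)
  }
  expect_error(auroc(1:3, rep("died", 3)), "both outcome classes")
})
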