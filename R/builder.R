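#' Maximum-likelihood logistic regression of mortality on item scores
#'
#' Fits the Bernoulli log-likelihood with logit link by damped Newton
#' iterations (step-halving on likelihood decrease); deterministic and
#' seedless. Convergence is declared when the largest absolute component of
#' the score equations (the log-likelihood gradient) falls below `1e-8`;
#' after 100 iterations without convergence the fit aborts with a
#' diagnostic, which is the typical signature of complete separation.
#'
#' @param x numeric matrix (or data frame) of per-record item scores, one
#'   column per item; column names become coefficient names.
#' @param y outcome per record: logical `TRUE` for died, or
#'   `"died"`/`"survived"`.
#' @return an object of class `edies_logistic_fit`: `intercept`,
#'   `coefficients` (named), `standard_errors` (named, from the inverse
#'   observed information), `converged`, `n_iterations`, `log_likelihood`.
#' @examples
#' fit <- fit_logistic(matrix(numeric(0), nrow = 4, ncol = 0),
#'                     c(TRUE, FALSE, FALSE, FALSE))
#' fit$intercept  # log(0.25/0.75)
#' @export
fit_logistic <- function(x, y) {
  y <- as_died(y)
  x <- as.matrix(x)
  if (is.null(colnames(x)) && ncol(x) > 0) {
    colnames(x) <- paste0("item", seq_len(ncol(x)))
  }
  stopifnot(nrow(x) == length(y))
  if (length(unique(y)) < 2) {
    stop("outcome is constant: both survivors and deaths are required")
  }
  const <- apply(x, 2, function(col) length(unique(col)) < 2)
  if (any(const)) {
    stop("item(s) constant across all records: ",
         paste(colnames(x)[const], collapse = ", "))
  }
  X <- cbind(`(intercept)` = 1, x)
  p_ <- ncol(X)
  beta <- numeric(p_)
  loglik <- function(b) {
    eta <- drop(X %*% b)
    # stable log(1 + exp(eta)) for large |eta|
    sum(y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta)))))
  }
  ll <- loglik(beta)
  iter <- 0L
  converged <- FALSE
  repeat {
    iter <- iter + 1L
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    grad <- drop(crossprod(X, y - mu))
    if (max(abs(beta)) > 30) {
      # the likelihood is still improving while estimates diverge: the
      # gradient only vanishes because fitted probabilities saturate
      stop("logistic estimates diverged (|coefficient| > 30): the data ",
           "appear completely separated")
    }
    if (max(abs(grad)) < 1e-8) {
      converged <- TRUE
      break
    }
    if (iter > 100L) break
    w <- mu * (1 - mu)
    H <- crossprod(X * w, X)
    step <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(step)) break
    # damping: halve the step until the likelihood does not decrease
    lambda <- 1
    repeat {
      cand <- beta + lambda * step
      ll_new <- loglik(cand)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      lambda <- lambda / 2
      if (lambda < 1e-10) break
    }
    beta <- beta + lambda * step
    ll <- loglik(beta)
  }
  if (!converged) {
    stop("logistic fit did not converge after 100 iterations ",
         "(max |gradient| = ", signif(max(abs(grad)), 3),
         "); the data may be completely separated")
  }
  mu <- stats::plogis(drop(X %*% beta))
  H <- crossprod(X * (mu * (1 - mu)), X)
  se <- sqrt(diag(solve(H)))
  structure(list(
    intercept = unname(beta[1]),
    coefficients = stats::setNames(beta[-1], colnames(x)),
    standard_errors = stats::setNames(se[-1], colnames(x)),
    intercept_se = unname(se[1]),
    converged = TRUE,
    n_iterations = iter,
    log_likelihood = ll
  ), class = "edies_logistic_fit")
}

#' @export
print.edies_logistic_fit <- function(x, ...) {
  cat("Logistic fit (", x$n_iterations, " iterations, logLik ",
      sprintf("%.3f", x$log_likelihood), ")\n", sep = "")
  tab <- data.frame(coefficient = c(x$intercept, x$coefficients),
                    std_error = c(x$intercept_se, x$standard_errors))
  rownames(tab) <- c("(intercept)", names(x$coefficients))
  print(tab)
  invisible(x)
}

#' Bin specifications with arbitrary (pre-regression) scores
#'
#' The score-construction procedure assigns arbitrary real-valued scores to
#' ranges of each variable (the original bin scores were chosen by
#' inspecting univariate mortality curves and are not published, so they are
#' a required user input here), regresses mortality on those item scores,
#' and converts each bin's arbitrary score to a final integer point score.
#' A bin spec has the same shape as a score table but its scores may be any
#' non-negative reals.
#'
#' @param items named list of [score_item_categorical()] /
#'   [score_item_binned()] items (real scores allowed).
#' @return an object of class `edies_bin_spec`.
#' @export
bin_spec <- function(items) {
  out <- score_table(items)
  class(out) <- c("edies_bin_spec", class(out))
  out
}

#' Convert a fitted model plus arbitrary bin scores to an integer score table
#'
#' Each bin's final point score is `round(2 * coefficient * arbitrary_score)`
#' with half-away-from-zero rounding, the published construction rule. A
#' negative product floors at 0 with a warning (final tables carry only
#' non-negative points).
#'
#' @param fit an `edies_logistic_fit` (or any list with a named
#'   `coefficients` element), one coefficient per bin-spec item.
#' @param spec an [bin_spec()] (or score table) with the arbitrary scores.
#' @return an `edies_score_table` with integer scores.
#' @examples
#' sp <- bin_spec(list(cause = score_item_categorical(
#'   c(disease = 1, non_disease = 0))))
#' fit <- list(coefficients = c(cause = 0.786), converged = TRUE)
#' integerize(fit, sp)$items$cause$scores  # disease -> 2
#' @export
integerize <- function(fit, spec) {
  if (!is.null(fit$converged) && !isTRUE(fit$converged)) {
    stop("refusing to integerize a non-converged fit")
  }
  coefs <- fit$coefficients
  absent <- setdiff(names(spec$items), names(coefs))
  if (length(absent)) {
    stop("no coefficient for item(s): ", paste(absent, collapse = ", "))
  }
  floored <- FALSE
  conv <- function(arb, beta) {
    s <- round_half_away(2 * beta * arb)
    if (any(s < 0)) {
      floored <<- TRUE
      s <- pmax(s, 0)
    }
    s
  }
  items <- lapply(names(spec$items), function(nm) {
    it <- spec$items[[nm]]
    b <- coefs[[nm]]
    if (it$kind == "categorical") {
      score_item_categorical(stats::setNames(conv(unname(it$scores), b),
                                             names(it$scores)))
    } else {
      score_item_binned(it$upper, conv(it$scores, b), conv(it$above, b),
                        gap = it$gap)
    }
  })
  names(items) <- names(spec$items)
  if (floored) warning("negative bin product(s) floored at 0")
  score_table(items)
}

#' Area under the ROC curve (Mann-Whitney estimator)
#'
#' The probability that a randomly chosen death has a higher score than a
#' randomly chosen survivor, with ties counted one half — computed from
#' ranks, equivalent to the trapezoidal area under the empirical ROC curve.
#'
#' @param scores numeric score per record.
#' @param outcomes `"died"`/`"survived"` or logical died.
#' @return a single number in [0, 1].
#' @examples
#' auroc(c(1, 3, 2, 4), c("survived", "survived", "died", "died"))  # 0.75
#' @export
auroc <- function(scores, outcomes) {
  died <- as_died(outcomes)
  nd <- as.numeric(sum(died))
  ns <- as.numeric(sum(!died))
  if (nd == 0 || ns == 0) {
    stop("both outcome classes are required to compute the AUROC")
  }
  r <- rank(scores)
  (sum(r[died]) - nd * (nd + 1) / 2) / (nd * ns)
}
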