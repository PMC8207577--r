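#' The W statistic: excess survivors per 100 patients
#'
#' `100 * (observed - expected) / n`: positive values mean more patients
#' survived than the severity model predicted. `observed` may be
#' real-valued so that analytic self-consistency (observed set exactly equal
#' to expected) can be expressed; cohort-level entry points always produce
#' integer observed counts.
#'
#' @param n number of patients (> 0).
#' @param observed observed survivors, in [0, n].
#' @param expected expected survivors (sum of predicted survival
#'   probabilities), in [0, n].
#' @return a single number.
#' @examples
#' w_statistic(200, 190, 180)  # 5
#' @export
w_statistic <- function(n, observed, expected) {
  stopifnot(length(n) == 1, length(observed) == 1, length(expected) == 1)
  if (n <= 0) stop("W statistic undefined for n = 0")
  if (observed < 0 || observed > n || expected < 0 || expected > n) {
    stop("observed and expected survivors must lie in [0, n]")
  }
  100 * (observed - expected) / n
}

#' Standardized W from per-stratum summaries
#'
#' Low-level entry point taking stratum summaries directly, so analytic
#' cohorts (real-valued observed survivor totals, e.g. observed set exactly
#' equal to expected) can be expressed without materializing records.
#' Strata with `n_j = 0` are dropped and the remaining reference fractions
#' renormalized, with a warning.
#'
#' @param labels stratum labels.
#' @param n_j patients per stratum.
#' @param O_j observed survivors per stratum (real-valued allowed).
#' @param E_j expected survivors per stratum.
#' @param varsum_j per-stratum sum of per-record survival variances
#'   `Ps_i (1 - Ps_i)`.
#' @param fractions reference stratum fractions `f_j`.
#' @return an `edies_ws` (see [ws_statistic()]).
#' @export
ws_from_strata <- function(labels, n_j, O_j, E_j, varsum_j, fractions) {
  k <- length(n_j)
  stopifnot(length(O_j) == k, length(E_j) == k, length(fractions) == k)
  if (all(n_j == 0)) stop("all strata are empty")
  nonempty <- n_j > 0
  f <- fractions
  renorm <- FALSE
  if (any(!nonempty)) {
    warning(sum(!nonempty), " empty stratum(s); reference fractions ",
            "renormalized over the populated strata")
    f[!nonempty] <- 0
    f <- f / sum(f)
    renorm <- TRUE
  }
  W_j <- ifelse(nonempty, 100 * (O_j - E_j) / pmax(n_j, 1), NA_real_)
  var_W_j <- ifelse(nonempty, (100 / pmax(n_j, 1))^2 * varsum_j, NA_real_)
  ws <- sum(f[nonempty] * W_j[nonempty])
  se <- sqrt(sum(f[nonempty]^2 * var_W_j[nonempty]))
  overall_w <- 100 * (sum(O_j) - sum(E_j)) / sum(n_j)
  structure(list(
    ws = ws, se = se,
    ci_low = ws - 1.96 * se, ci_high = ws + 1.96 * se,
    overall_w = overall_w, renormalized = renorm,
    strata = data.frame(stratum = labels, n_j = n_j, O_j = O_j, E_j = E_j,
                        f_j = f, W_j = W_j, var_W_j = var_W_j)
  ), class = "edies_ws")
}

#' Standardized W statistic of a scored cohort
#'
#' Computes, for each severity stratum j of the reference: the expected
#' survivors `E_j` (sum of predicted survival probabilities over the
#' stratum's records), the observed survivors `O_j`, the stratum W statistic
#' `W_j = 100 (O_j - E_j) / n_j` and its variance
#' `var_W_j = (100/n_j)^2 * sum Ps_i (1 - Ps_i)`. The standardized W is the
#' reference-fraction-weighted mean `ws = sum f_j W_j`, with standard error
#' `sqrt(sum f_j^2 var_W_j)` and fixed 95% interval `ws +/- 1.96 se`. Strata
#' with no cohort records are dropped and the remaining reference fractions
#' renormalized, with a warning.
#'
#' The default variance uses the reference's predicted probabilities
#' (null-model binomial variance); `variance = "observed"` substitutes the
#' observed stratum survival proportion, as a sensitivity analysis.
#'
#' @param scores integer score per record.
#' @param outcomes `"died"`/`"survived"` or logical died, one per record.
#' @param reference an `edies_reference`.
#' @param variance `"predicted"` (default) or `"observed"`.
#' @return an object of class `edies_ws`: `ws`, `se`, `ci_low`, `ci_high`,
#'   `overall_w`, `renormalized`, and a per-stratum data frame `strata`.
#' @examples
#' ref <- builtin_reference()
#' pop <- generate_population(generator_spec(n = 20000, seed = 1))
#' ws_statistic(pop$score, pop$outcome, ref)
#' @export
ws_statistic <- function(scores, outcomes, reference,
                         variance = c("predicted", "observed")) {
  variance <- match.arg(variance)
  stopifnot(length(scores) == length(outcomes), length(scores) > 0)
  died <- as_died(outcomes)
  ps <- ps_lookup(reference, scores)
  j <- stratum_lookup(reference, scores)
  k <- nrow(reference$strata)
  n_j <- tabulate(j, nbins = k)
  O_j <- tabulate(j[!died], nbins = k)
  E_j <- as.vector(rowsum_safe(ps, j, k))
  vs <- if (variance == "predicted") ps * (1 - ps) else {
    p_obs <- (O_j / pmax(n_j, 1))[j]
    p_obs * (1 - p_obs)
  }
  varsum_j <- as.vector(rowsum_safe(vs, j, k))
  ws_from_strata(reference$strata$label, n_j, O_j, E_j, varsum_j,
                 reference$strata$fraction)
}

# rowsum over groups 1..k, returning zeros for absent groups
rowsum_safe <- function(x, g, k) {
  out <- numeric(k)
  s <- rowsum(x, g)
  out[as.integer(rownames(s))] <- s
  out
}

#' @export
print.edies_ws <- function(x, ...) {
  cat(sprintf("Ws = %.3f (95%% CI: %.3f - %.3f), overall W = %.3f\n",
              x$ws, x$ci_low, x$ci_high, x$overall_w))
  if (x$renormalized) cat("note: empty strata; fractions renormalized\n")
  print(x$strata, digits = 4)
  invisible(x)
}

#' @rdname ws_statistic
#' @param x an `edies_ws` result.
#' @param path output file path.
#' @export
write_ws_result <- function(x, path) {
  jsonlite::write_json(
    list(ws = x$ws, se = x$se, ci_low = x$ci_low, ci_high = x$ci_high,
         overall_w = x$overall_w, renormalized = x$renormalized,
         strata = x$strata),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
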