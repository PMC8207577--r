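#' Sampling scenarios for the coverage experiment
#'
#' A scenario describes how replicates are drawn from a population:
#' `mode = "random"` takes simple random samples; `mode = "gamma"` reweights
#' the severity-score distribution to match a discretized gamma density
#' (shape/rate), the device used to manufacture hypothetically severe
#' (shape 9, rate 1) and non-severe (shape 3.4, rate 1.1) case mixes.
#'
#' @param mode `"random"` or `"gamma"`.
#' @param shape,rate gamma parameters (required when `mode = "gamma"`).
#' @param sample_size records per replicate (default 30000).
#' @param replicates number of replicates (default 1000).
#' @param seed master RNG seed; each replicate runs on an independent,
#'   individually reproducible substream derived from it.
#' @param with_replacement sample within strata with replacement (default
#'   FALSE; an undersized stratum falls back to with-replacement with a
#'   warning).
#' @return an object of class `edies_scenario`.
#' @export
sampling_scenario <- function(mode = c("random", "gamma"),
                              shape = NULL, rate = NULL,
                              sample_size = 30000L, replicates = 1000L,
                              seed = 1L, with_replacement = FALSE) {
  mode <- match.arg(mode)
  if (mode == "gamma") {
    if (is.null(shape) || is.null(rate) || shape <= 0 || rate <= 0) {
      stop("gamma mode requires shape > 0 and rate > 0")
    }
  }
  structure(list(mode = mode, shape = shape, rate = rate,
                 sample_size = as.integer(sample_size),
                 replicates = as.integer(replicates),
                 seed = as.integer(seed),
                 with_replacement = isTRUE(with_replacement)),
            class = "edies_scenario")
}

#' Target stratum fractions from a discretized gamma density
#'
#' The gamma(shape, rate) density is discretized by integrating over
#' `[s, s + 1)` for each member score s of each stratum (for an open-ended
#' final stratum the integral runs to infinity), then renormalized to sum
#' to one over the strata. Integration over unit intervals, rather than
#' point evaluation of the density, is exact for the implied continuous
#' severity model.
#'
#' @param shape,rate gamma parameters (> 0).
#' @param strata list of integer vectors of member scores; give the last
#'   stratum attribute `open = TRUE` (or use [score_strata()]) to integrate
#'   its tail to infinity.
#' @return numeric vector of fractions summing to 1.
#' @examples
#' gamma_target_distribution(9, 1, as.list(0:22))
#' @export
gamma_target_distribution <- function(shape, rate, strata) {
  stopifnot(shape > 0, rate > 0, length(strata) > 0)
  mass <- vapply(strata, function(g) {
    hi <- g + 1
    if (isTRUE(attr(g, "open"))) hi[which.max(g)] <- Inf
    sum(stats::pgamma(hi, shape = shape, rate = rate) -
          stats::pgamma(g, shape = shape, rate = rate))
  }, 1.0)
  mass / sum(mass)
}

#' Per-score strata for a population
#'
#' One stratum per distinct score present, the last marked open-ended.
#' Severity reweighting operates at individual-score resolution.
#'
#' @param scores integer score vector.
#' @return list of single-score strata suitable for
#'   [gamma_target_distribution()] and [stratified_resample()].
#' @export
score_strata <- function(scores) {
  vals <- sort(unique(scores))
  strata <- lapply(vals, identity)
  attr(strata[[length(strata)]], "open") <- TRUE
  strata
}

#' Stratified resampling toward a target severity distribution
#'
#' Per-stratum sample sizes are the largest-remainder apportionment of
#' `n * target`; within each stratum records are drawn uniformly without
#' replacement (falling back to with-replacement, with a warning, when a
#' stratum holds fewer records than its quota). A target that puts positive
#' mass on a stratum absent from the population is infeasible.
#'
#' @param scores population score vector.
#' @param target fractions per stratum (same order as `strata`).
#' @param strata list of integer vectors of member scores.
#' @param n total sample size.
#' @param seed RNG seed.
#' @param with_replacement force with-replacement sampling.
#' @return integer vector of selected population indices (length `n`).
#' @export
stratified_resample <- function(scores, target, strata, n, seed,
                                with_replacement = FALSE) {
  stopifnot(n > 0, length(scores) > 0, length(target) == length(strata))
  idx_by <- stratum_members(scores, strata)
  quota <- largest_remainder(n, target)
  empty <- quota > 0 & vapply(idx_by, length, 1L) == 0
  if (any(empty)) {
    stop("target puts positive mass on stratum(s) absent from the ",
         "population: ", paste(which(empty), collapse = ", "))
  }
  set.seed(seed)
  out <- vector("list", length(strata))
  short <- FALSE
  for (i in seq_along(strata)) {
    q <- quota[i]
    if (q == 0L) next
    pool <- idx_by[[i]]
    if (!with_replacement && q > length(pool)) {
      short <- TRUE
      out[[i]] <- pool[sample.int(length(pool), q, replace = TRUE)]
    } else {
      out[[i]] <- pool[sample.int(length(pool), q,
                                  replace = with_replacement)]
    }
  }
  if (short) {
    warning("stratum quota exceeded stratum size; sampled those strata ",
            "with replacement")
  }
  unlist(out, use.names = FALSE)
}

stratum_members <- function(scores, strata) {
  lapply(strata, function(g) which(scores %in% as.integer(g) |
                                     (isTRUE(attr(g, "open")) &
                                        scores >= max(g))))
}

#' Confidence-interval coverage experiment for the standardized W
#'
#' Computes the population Ws once, then draws `scenario$replicates`
#' independent samples of `scenario$sample_size` records (simple random
#' samples, or stratified samples matching a discretized-gamma severity
#' target), computes Ws and its 95% interval for each, and reports the
#' percentage of replicates whose interval contains the population Ws — the
#' empirical coverage, nominally 95%.
#'
#' @param scores,outcomes the population, as parallel vectors.
#' @param reference an `edies_reference`.
#' @param scenario an [sampling_scenario()].
#' @return an object of class `edies_coverage`: `population_ws`,
#'   `replicate_ws` (vector), `coverage_pct`, `mean_replicate_ws`,
#'   `scenario`.
#' @export
coverage_experiment <- function(scores, outcomes, reference, scenario) {
  stopifnot(inherits(scenario, "edies_scenario"))
  died <- as_died(outcomes)
  pop_ws <- ws_statistic(scores, outcomes, reference)$ws

  # precompute per-record Ps and stratum for the fast replicate path
  ps <- ps_lookup(reference, scores)
  j <- stratum_lookup(reference, scores)
  k <- nrow(reference$strata)
  fractions <- reference$strata$fraction
  vs <- ps * (1 - ps)

  npop <- length(scores)
  n <- scenario$sample_size
  if (scenario$mode == "gamma") {
    strata <- score_strata(scores)
    target <- gamma_target_distribution(scenario$shape, scenario$rate,
                                        strata)
    # membership pools and quotas are replicate-invariant: compute once
    idx_by <- stratum_members(scores, strata)
    quota <- largest_remainder(n, target)
    empty <- quota > 0 & vapply(idx_by, length, 1L) == 0
    if (any(empty)) {
      stop("target puts positive mass on stratum(s) absent from the ",
           "population")
    }
    short <- quota > vapply(idx_by, length, 1L)
    if (any(short) && !scenario$with_replacement) {
      warning("stratum quota exceeds stratum size for ", sum(short),
              " stratum(s); those strata are sampled with replacement")
    }
  }
  seeds <- spawn_seeds(scenario$seed, scenario$replicates)
  rep_ws <- rep_lo <- rep_hi <- numeric(scenario$replicates)
  for (r in seq_len(scenario$replicates)) {
    set.seed(seeds[r])
    idx <- if (scenario$mode == "random") {
      sample.int(npop, n, replace = scenario$with_replacement)
    } else {
      unlist(lapply(seq_along(idx_by), function(i) {
        if (quota[i] == 0L) return(integer(0))
        pool <- idx_by[[i]]
        repl <- scenario$with_replacement || quota[i] > length(pool)
        pool[sample.int(length(pool), quota[i], replace = repl)]
      }), use.names = FALSE)
    }
    jr <- j[idx]
    dr <- died[idx]
    n_j <- tabulate(jr, nbins = k)
    O_j <- tabulate(jr[!dr], nbins = k)
    E_j <- rowsum_safe(ps[idx], jr, k)
    varsum_j <- rowsum_safe(vs[idx], jr, k)
    res <- suppressWarnings(
      ws_from_strata(reference$strata$label, n_j, O_j, E_j, varsum_j,
                     fractions))
    rep_ws[r] <- res$ws
    rep_lo[r] <- res$ci_low
    rep_hi[r] <- res$ci_high
  }
  covered <- rep_lo <= pop_ws & pop_ws <= rep_hi
  structure(list(
    population_ws = pop_ws,
    replicate_ws = rep_ws,
    coverage_pct = 100 * mean(covered),
    mean_replicate_ws = mean(rep_ws),
    scenario = scenario
  ), class = "edies_coverage")
}

#' @export
print.edies_coverage <- function(x, ...) {
  sc <- x$scenario
  lab <- if (sc$mode == "gamma") {
    sprintf("gamma(shape %g, rate %g)", sc$shape, sc$rate)
  } else "simple random"
  cat(sprintf(
    "Coverage experiment (%s, %d x %d):\n  population Ws %.4f, mean replicate Ws %.4f, 95%% CI coverage %.1f%%\n",
    lab, sc$replicates, sc$sample_size, x$population_ws,
    x$mean_replicate_ws, x$coverage_pct))
  invisible(x)
}
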