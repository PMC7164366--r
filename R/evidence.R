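# Marginal-likelihood estimation by stepping-stone sampling and Bayesian
# clock-model selection.

#' Stepping-stone beta schedule
#'
#' `beta_k = (k/K)^(1/a)` for k = 0..K-1 (the k = 0 stone is the prior),
#' plus the endpoint 1 for bookkeeping. Small `a` front-loads stones near
#' the prior, where the power-posterior changes fastest.
#'
#' @param K Number of stones (>= 2).
#' @param a Schedule shape (> 0; default 0.3).
#' @return Increasing numeric vector of length K + 1 ending in 1.
#' @export
beta_schedule <- function(K = 8, a = 0.3) {
  stopifnot(K >= 2, a > 0)
  c(((seq_len(K) - 1) / K)^(1 / a), 1)
}

#' Stepping-stone log marginal likelihood
#'
#' Given log-likelihood samples drawn from the power posterior at each
#' stone, estimates
#' `log mL = sum_k log mean_i exp[(b_{k+1} - b_k) * (l_i - max l_i)] +
#' (b_{k+1} - b_k) * max l_i`,
#' with a per-stone delta-method standard error combined in quadrature.
#'
#' @param loglik_samples List of numeric vectors, one per stone (ordered as
#'   `schedule[1..K]`); each needs >= 10 samples.
#' @param schedule The beta schedule (length K + 1, see
#'   [beta_schedule()]).
#' @param model Optional model label carried in the result.
#' @return Object of class `logml_estimate`: `log_ml`, `se`, `n_stones`,
#'   `n_per_stone`, `schedule`, `model`.
#' @export
stepping_stone_logml <- function(loglik_samples, schedule, model = NA) {
  K <- length(schedule) - 1L
  if (length(loglik_samples) != K)
    stop("need one sample vector per stone (", K, ")")
  ns <- lengths(loglik_samples)
  if (any(ns < 10)) stop("every stone needs at least 10 samples")
  log_ml <- 0; se2 <- 0
  for (k in seq_len(K)) {
    db <- schedule[k + 1] - schedule[k]
    l <- loglik_samples[[k]]
    mx <- max(l)
    w <- exp(db * (l - mx))
    mw <- mean(w)
    log_ml <- log_ml + log(mw) + db * mx
    se2 <- se2 + stats::var(w) / (length(w) * mw^2)
  }
  structure(list(log_ml = log_ml, se = sqrt(se2), n_stones = K,
                 n_per_stone = ns, schedule = schedule, model = model),
            class = "logml_estimate")
}

#' @export
print.logml_estimate <- function(x, ...) {
  cat(sprintf("log mL = %.3f +/- %.3f (%s, %d stones)\n", x$log_ml, x$se,
              if (is.na(x$model)) "model ?" else x$model, x$n_stones))
  invisible(x)
}

#' Posterior model probabilities from log marginal likelihoods
#'
#' Assuming equal prior model probabilities. The plug-in mode is a softmax
#' of the log marginal likelihoods (with max subtraction); the SE-aware
#' mode averages the softmax over normal resamples of each estimate.
#'
#' @param estimates List of [stepping_stone_logml()] results, or a numeric
#'   vector of log marginal likelihoods (then `se` supplies errors).
#' @param use_se Average over estimate uncertainty?
#' @param se Standard errors when `estimates` is numeric.
#' @param n_resample Resamples for the SE-aware mode.
#' @return Named probability vector summing to 1.
#' @export
model_posterior_probs <- function(estimates, use_se = FALSE, se = NULL,
                                  n_resample = 1e4) {
  if (is.list(estimates) && inherits(estimates[[1]], "logml_estimate")) {
    lm <- vapply(estimates, `[[`, 0, "log_ml")
    se <- vapply(estimates, `[[`, 0, "se")
    labs <- vapply(estimates, function(e)
      if (is.na(e$model)) NA_character_ else as.character(e$model), "")
    if (!anyNA(labs)) names(lm) <- labs
  } else {
    lm <- estimates
    if (is.null(se)) se <- rep(0, length(lm))
  }
  if (length(lm) < 2) stop("need at least two models")
  if (any(!is.finite(lm))) stop("log marginal likelihoods must be finite")
  softmax <- function(x) { e <- exp(x - max(x)); e / sum(e) }
  if (!use_se) return(softmax(lm))
  acc <- rep(0, length(lm))
  for (r in seq_len(n_resample))
    acc <- acc + softmax(stats::rnorm(length(lm), lm, se))
  p <- acc / n_resample
  names(p) <- names(lm)
  p
}

#' Power-posterior sampling for one model
#'
#' Runs the dating sampler at each stone's beta (the beta = 0 stone samples
#' the prior, still recording log likelihoods) and collects post-burn-in
#' log-likelihood samples.
#'
#' @param model `"STR"`, `"IR"`, or `"AR"`.
#' @param data,topology,cals,bd As in [run_mcmc()].
#' @param schedule Beta schedule from [beta_schedule()].
#' @param settings An [mcmc_settings()]; one chain per stone.
#' @return List of log-likelihood sample vectors (one per stone).
#' @export
power_posterior_samples <- function(model, data, topology, cals,
                                    bd = bd_params(), schedule,
                                    settings = mcmc_settings()) {
  K <- length(schedule) - 1L
  lapply(seq_len(K), function(k) {
    st <- settings
    st$beta <- schedule[k]
    st$n_chains <- 1L
    st$seed <- derive_seed(settings$seed, paste0(model, ".stone", k))
    tr <- run_mcmc(model, data, topology, cals, bd, st)
    post_burnin(tr)$logL
  })
}

#' Bayesian clock-model selection by stepping-stone sampling
#'
#' Reproduces the selection protocol used for large dating studies: exact
#' likelihood on a small data subset, root age fixed by a narrow uniform
#' calibration (0.999-1.001 in internal time units by default), no other
#' calibrations, stepping-stone marginal likelihoods per model, and
#' posterior model probabilities under equal model priors.
#'
#' @param data Exact-likelihood data: `list(partitions = <alignments>,
#'   sub = <substitution_params>)`.
#' @param topology Rooted binary `phylo`.
#' @param models Models to compare (default STR, IR, AR).
#' @param settings An [mcmc_settings()] for the power-posterior chains.
#' @param K,a Stepping-stone schedule parameters.
#' @param bd Birth-death prior parameters.
#' @param root_window Narrow uniform root calibration, in internal 100-Myr
#'   units (default `c(0.999, 1.001)`).
#' @param max_cells Refusal guard: taxa x sites budget for exact
#'   likelihood.
#' @return Object of class `model_selection`: `estimates`, `probabilities`
#'   (plug-in), `table` (data frame ordered by probability).
#' @export
select_clock_model <- function(data, topology, models = c("STR", "IR", "AR"),
                               settings = mcmc_settings(), K = 8, a = 0.3,
                               bd = bd_params(),
                               root_window = c(0.999, 1.001),
                               max_cells = 2e5) {
  nsites <- sum(vapply(data$partitions, function(m) ncol(aln_matrix(m)), 0))
  cells <- ape::Ntip(topology) * nsites
  if (cells > max_cells)
    stop(sprintf(paste0("dataset too large for exact-likelihood model ",
                        "selection (%d taxa x %d sites = %g cells > budget %g); ",
                        "select on a smaller subset"),
                 ape::Ntip(topology), nsites, cells, max_cells))
  # root fixed by a narrow uniform calibration; no other calibrations
  rt_tips <- root_anchor_tips(topology)
  cals <- calibration_set(data.frame(
    tip_a = rt_tips[1], tip_b = rt_tips[2],
    t_min = root_window[1] * TIME_UNIT_MA,
    t_max = root_window[2] * TIME_UNIT_MA,
    min_type = "hard", max_type = "hard", p_lower = 0, p_upper = 0))
  schedule <- beta_schedule(K, a)
  estimates <- lapply(models, function(mdl) {
    ll <- power_posterior_samples(mdl, data, topology, cals, bd, schedule,
                                  settings)
    stepping_stone_logml(ll, schedule, model = mdl)
  })
  names(estimates) <- models
  probs <- model_posterior_probs(estimates)
  tab <- data.frame(model = models,
                    log_ml = vapply(estimates, `[[`, 0, "log_ml"),
                    se = vapply(estimates, `[[`, 0, "se"),
                    pr = probs, stringsAsFactors = FALSE)
  tab <- tab[order(-tab$pr), ]
  rownames(tab) <- NULL
  structure(list(estimates = estimates, probabilities = probs, table = tab),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  print(x$table, digits = 6)
  invisible(x)
}

root_anchor_tips <- function(phy) {
  n <- ape::Ntip(phy)
  kids <- phy$edge[phy$edge[, 1] == n + 1L, 2]
  tip_below <- function(v) {
    while (v > n) v <- phy$edge[phy$edge[, 1] == v, 2][1]
    phy$tip.label[v]
  }
  c(tip_below(kids[1]), tip_below(kids[2]))
}
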