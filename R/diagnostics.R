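# Infinite-sites diagnostics and complete-vs-reduced dataset comparison.

#' Infinite-sites regression of CI width on posterior mean age
#'
#' Ordinary least squares of the 95% credibility-interval width on the
#' posterior mean node age over all dated internal nodes. The slope
#' measures how much uncertainty each Ma of divergence adds to the CI; on
#' the infinite-data asymptote the points fall on a straight line and the
#' residual uncertainty is attributable to the fossil calibrations.
#'
#' @param summary A [summarize_posterior()] table (node rows are used).
#' @param include_root Include the root node? The root is often a
#'   high-leverage point; both variants are reported in practice.
#' @return Object of class `infinite_sites_fit`: `points` (data frame),
#'   `slope`, `intercept`, `r2`, `variant`.
#' @export
infinite_sites_fit <- function(summary, include_root = TRUE) {
  pts <- summary[!is.na(summary$node), c("node", "mean", "ci_width")]
  if (!include_root) pts <- pts[-which.max(pts$mean), , drop = FALSE]
  if (nrow(pts) < 3) stop("need at least 3 nodes for the regression")
  fit <- stats::lm(ci_width ~ mean, data = pts)
  sst <- sum((pts$ci_width - mean(pts$ci_width))^2)
  r2 <- if (sst == 0) 1 else max(0, 1 - sum(stats::resid(fit)^2) / sst)
  structure(list(points = pts, slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]), r2 = r2,
                 variant = if (include_root) "with_root" else "without_root"),
            class = "infinite_sites_fit")
}

#' @export
print.infinite_sites_fit <- function(x, ...) {
  cat(sprintf("infinite-sites fit (%s): width = %.3f + %.3f * age, r2 = %.3f\n",
              x$variant, x$intercept, x$slope, x$r2))
  invisible(x)
}

#' Compare divergence-time summaries of a full and a reduced dataset
#'
#' Pairs nodes by identity and reports per-node posterior-mean scatter
#' pairs, the regression of full on reduced means, per-node and mean
#' CI-width ratios (reduced / full), and both infinite-sites slopes.
#'
#' @param full,reduced [summarize_posterior()] tables over the same node
#'   set.
#' @param include_root Passed to [infinite_sites_fit()].
#' @return List: `pairs` (data frame), `mean_width_ratio`,
#'   `mean_regression` (`c(intercept, slope)` of full on reduced),
#'   `slope_full`, `slope_reduced`, `slope_difference`.
#' @export
compare_datasets <- function(full, reduced, include_root = TRUE) {
  fn <- full[!is.na(full$node), ]
  rn <- reduced[!is.na(reduced$node), ]
  if (!setequal(fn$node, rn$node))
    stop("node sets differ: ",
         paste(c(setdiff(fn$node, rn$node), setdiff(rn$node, fn$node)),
               collapse = ", "))
  rn <- rn[match(fn$node, rn$node), ]
  pairs <- data.frame(node = fn$node, mean_full = fn$mean,
                      mean_reduced = rn$mean, width_full = fn$ci_width,
                      width_reduced = rn$ci_width,
                      width_ratio = rn$ci_width / fn$ci_width)
  reg <- stats::lm(mean_full ~ mean_reduced, data = pairs)
  isf <- infinite_sites_fit(full, include_root)
  isr <- infinite_sites_fit(reduced, include_root)
  list(pairs = pairs, mean_width_ratio = mean(pairs$width_ratio),
       mean_regression = stats::setNames(coef(reg), c("intercept", "slope")),
       slope_full = isf$slope, slope_reduced = isr$slope,
       slope_difference = isr$slope - isf$slope)
}

#' Closed-form OLS (normal equations)
#'
#' Independent least-squares solve used to cross-check regression results.
#'
#' @param x,y Numeric vectors.
#' @return `c(intercept, slope)`.
#' @export
ols_normal_equations <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  stats::setNames(as.numeric(beta), c("intercept", "slope"))
}
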