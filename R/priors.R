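# Joint prior on node ages and branch rates: birth-death node-age kernel,
# hard/soft fossil-calibration densities, and relaxed-clock rate priors.

#' Birth-death parameters
#'
#' @param lambda Birth rate (>= 0).
#' @param mu_death Death rate (>= 0).
#' @param rho Sampling fraction in (0, 1].
#' @return Object of class `bd_params`.
#' @export
bd_params <- function(lambda = 1, mu_death = 1, rho = 0.1) {
  stopifnot(lambda >= 0, mu_death >= 0, rho > 0, rho <= 1)
  structure(list(lambda = lambda, mu_death = mu_death, rho = rho),
            class = "bd_params")
}

as_bd <- function(bd) {
  if (inherits(bd, "bd_params")) return(bd)
  bd_params(bd[1], bd[2], bd[3])
}

#' Birth-death node-age kernel log density
#'
#' Density of a non-root interior node age conditional on the root age under
#' a birth-death speciation process with species sampling fraction rho. For
#' lambda = mu the closed form
#' \deqn{g(t) = (1 + \rho\lambda t_1) / (t_1 (1 + \rho\lambda t)^2)}
#' is used; the general case uses the sampled-birth-death kernel. The
#' density integrates to 1 over (0, root_age).
#'
#' @param t Age(s), 0 < t < root_age.
#' @param root_age Root age.
#' @param bd `bd_params` (or numeric `c(lambda, mu_death, rho)`).
#' @return Log density (vectorized over `t`); `-Inf` outside (0, root_age).
#' @export
bd_kernel_logdensity <- function(t, root_age, bd = bd_params()) {
  bd <- as_bd(bd)
  lam <- bd$lambda; mud <- bd$mu_death; rho <- bd$rho
  out <- rep(-Inf, length(t))
  ok <- t > 0 & t < root_age
  if (!any(ok)) return(out)
  tt <- t[ok]
  if (abs(lam - mud) < 1e-12) {
    c0 <- rho * lam
    out[ok] <- log1p(c0 * root_age) - log(root_age) - 2 * log1p(c0 * tt)
  } else {
    d <- lam - mud
    p0 <- function(s) rho * d / (rho * lam + (lam * (1 - rho) - mud) * exp(-d * s))
    vt1 <- 1 - p0(root_age) * exp(-d * root_age) / rho
    out[ok] <- log(lam) + 2 * log(p0(tt)) - d * tt - log(rho) - log(vt1)
  }
  out
}

# CDF of the kernel (closed form; see the derivation in the methods vignette)
bd_kernel_cdf <- function(t, root_age, lambda, mu_death, rho) {
  if (abs(lambda - mu_death) < 1e-12) {
    c0 <- rho * lambda
    (1 + c0 * root_age) * t / (root_age * (1 + c0 * t))
  } else {
    d <- lambda - mu_death
    a <- rho * lambda
    b <- lambda * (1 - rho) - mu_death
    p0 <- function(s) rho * d / (a + b * exp(-d * s))
    vt1 <- 1 - p0(root_age) * exp(-d * root_age) / rho
    prim <- function(s) {
      x <- exp(-d * s)
      if (abs(b) < 1e-12) lambda * rho^2 * d * (1 - x) / a^2
      else lambda * rho^2 * d / b * (1 / (a + b * x) - 1 / (a + b))
    }
    vapply(t, prim, numeric(1)) / (rho * vt1)
  }
}

# Quantile function of the kernel (inverse CDF); exact for lambda = mu.
bd_kernel_quantile <- function(u, root_age, lambda, mu_death, rho) {
  if (abs(lambda - mu_death) < 1e-12) {
    c0 <- rho * lambda
    u * root_age / (1 + c0 * root_age * (1 - u))
  } else {
    vapply(u, function(ui) {
      stats::uniroot(function(t)
        bd_kernel_cdf(t, root_age, lambda, mu_death, rho) - ui,
        interval = c(1e-12 * root_age, root_age * (1 - 1e-12)),
        tol = 1e-10 * root_age)$root
    }, numeric(1))
  }
}

#' Fossil calibration set
#'
#' @param df Data frame with columns `tip_a`, `tip_b` (tip-pair anchors whose
#'   MRCA is calibrated; use the same tip twice or `node_label` conventions
#'   for the root), `t_min`, `min_type` (`"hard"` or `"soft"`), `t_max`,
#'   `max_type`, and optionally `p_lower`, `p_upper` (tail probabilities;
#'   default 0 for hard, 0.025 for soft).
#' @return Object of class `calibration_set` (validated data frame).
#' @export
calibration_set <- function(df) {
  need <- c("tip_a", "tip_b", "t_min", "min_type", "t_max", "max_type")
  if (!all(need %in% names(df))) stop("missing columns: ",
                                      paste(setdiff(need, names(df)), collapse = ", "))
  if (is.null(df$p_lower)) df$p_lower <- ifelse(df$min_type == "hard", 0, 0.025)
  if (is.null(df$p_upper)) df$p_upper <- ifelse(df$max_type == "hard", 0, 0.025)
  df$p_lower[df$min_type == "hard"] <- 0
  df$p_upper[df$max_type == "hard"] <- 0
  if (any(!is.finite(df$t_min)) || any(!is.finite(df$t_max)))
    stop("both bounds are required for every calibration")
  if (any(df$t_min >= df$t_max)) stop("t_min must be < t_max (zero-width calibrations are rejected)")
  if (any(df$p_lower < 0 | df$p_lower >= 0.5 | df$p_upper < 0 | df$p_upper >= 0.5))
    stop("tail probabilities must lie in [0, 0.5)")
  structure(df, class = c("calibration_set", "data.frame"))
}

#' Calibration log density
#'
#' Uniform density carrying mass `1 - pL - pU` on `[t_min, t_max]`. A soft
#' maximum decays exponentially above `t_max` (total tail mass `pU`), a soft
#' minimum decays as a power of `t` below `t_min` (mass `pL`); both tails
#' are matched to the interior density for continuity. Hard bounds have true
#' zero density outside.
#'
#' @param t Age(s) in Ma.
#' @param cal One row of a [calibration_set()].
#' @return Log density, vectorized over `t`.
#' @export
calibration_logdensity <- function(t, cal) {
  tL <- cal$t_min; tU <- cal$t_max; pL <- cal$p_lower; pU <- cal$p_upper
  h <- (1 - pL - pU) / (tU - tL)
  out <- rep(-Inf, length(t))
  inside <- t >= tL & t <= tU
  out[inside] <- log(h)
  above <- t > tU
  if (pU > 0) out[above] <- log(h) - (t[above] - tU) * h / pU
  below <- t < tL & t > 0
  if (pL > 0) {
    theta <- h * tL / pL - 1
    out[below] <- log(h) + theta * (log(t[below]) - log(tL))
  }
  out
}

#' Build calibrations bracketing true node ages of a timetree
#'
#' For each tip-pair anchor the MRCA's true age `a` receives bounds
#' `[a (1 - below), a (1 + above)]` with the requested tail probabilities,
#' so every generated calibration contains the generating age by
#' construction.
#'
#' @param tt A `timetree`.
#' @param anchors List of 2-vectors of tip labels (each anchors one node);
#'   the root is included automatically when `calibrate_root = TRUE`.
#' @param rel_offsets `c(below, above)` relative offsets (>= 0, not both 0).
#' @param tails `c(pL, pU)` tail probabilities (0 = hard bound).
#' @param calibrate_root Add a root calibration with the same offsets?
#' @return A [calibration_set()] with an extra `node` column (ape node ids)
#'   and `true_age` column.
#' @export
make_calibrations <- function(tt, anchors = list(), rel_offsets = c(0.1, 0.1),
                              tails = c(0, 0.025), calibrate_root = TRUE) {
  stopifnot(inherits(tt, "timetree"))
  if (any(rel_offsets < 0)) stop("offsets must be nonnegative")
  if (all(rel_offsets == 0)) stop("zero-width (point) calibrations are rejected")
  phy <- tt$phy
  rows <- list()
  if (calibrate_root) {
    rt <- ape::Ntip(phy) + 1L
    kid_tips <- vapply(phy$edge[phy$edge[, 1] == rt, 2], function(v) {
      if (v <= ape::Ntip(phy)) phy$tip.label[v]
      else phy$tip.label[ape::prop.part(phy)[[v - ape::Ntip(phy)]][1]]
    }, character(1))
    rows[[length(rows) + 1L]] <- list(tips = kid_tips, node = rt)
  }
  for (a in anchors) {
    rows[[length(rows) + 1L]] <- list(tips = a, node = mrca_node(phy, a[1], a[2]))
  }
  df <- do.call(rbind, lapply(rows, function(r) {
    age <- tt$ages[r$node]
    data.frame(tip_a = r$tips[1], tip_b = r$tips[2],
               t_min = age * (1 - rel_offsets[1]),
               min_type = if (tails[1] == 0) "hard" else "soft",
               t_max = age * (1 + rel_offsets[2]),
               max_type = if (tails[2] == 0) "hard" else "soft",
               p_lower = tails[1], p_upper = tails[2],
               node = r$node, true_age = age,
               stringsAsFactors = FALSE)
  }))
  calibration_set(df)
}

# Resolve the calibrated node ids of a calibration set on a given phylogeny.
calibration_nodes <- function(cals, phy) {
  vapply(seq_len(nrow(cals)), function(i) {
    mrca_node(phy, cals$tip_a[i], cals$tip_b[i])
  }, integer(1))
}

#' Joint log prior on node ages
#'
#' Calibrated nodes contribute their calibration density (replacing, not
#' multiplying, the birth-death term); uncalibrated non-root internal nodes
#' contribute the birth-death kernel conditional on the current root age.
#' Violations of parent > child ordering or of hard bounds give `-Inf`.
#'
#' @param tt A `timetree` (its ages are evaluated).
#' @param cals A [calibration_set()]; must calibrate the root.
#' @param bd `bd_params`.
#' @return Log prior density (one number).
#' @export
joint_time_logprior <- function(tt, cals, bd = bd_params()) {
  phy <- tt$phy
  n <- ape::Ntip(phy)
  ages <- tt$ages
  if (any(ages[phy$edge[, 1]] <= ages[phy$edge[, 2]])) return(-Inf)
  cal_nodes <- calibration_nodes(cals, phy)
  root <- n + 1L
  if (!(root %in% cal_nodes)) stop("a root calibration is required")
  lp <- 0
  for (v in (n + 1L):(n + phy$Nnode)) {
    i <- match(v, cal_nodes)
    lp <- lp + if (!is.na(i)) calibration_logdensity(ages[v], cals[i, ])
    else bd_kernel_logdensity(ages[v], ages[root], bd)
    if (!is.finite(lp)) return(-Inf)
  }
  lp
}

#' Relaxed-clock model specification
#'
#' @param model `"STR"` (strict), `"IR"` (independent lognormal), or `"AR"`
#'   (autocorrelated geometric Brownian motion).
#' @param mu Mean substitution rate (substitutions/site per time unit).
#' @param sigma2 Rate variance: log-rate variance (IR) or diffusion rate per
#'   time unit (AR); must be 0 for STR.
#' @return Object of class `clock_model_spec`.
#' @export
clock_model_spec <- function(model = c("STR", "IR", "AR"), mu = 0.1,
                             sigma2 = 0) {
  model <- match.arg(model)
  stopifnot(mu > 0, sigma2 >= 0)
  if (model == "STR" && sigma2 != 0) stop("STR implies sigma2 = 0")
  structure(list(model = model, mu = mu, sigma2 = sigma2,
                 priors = list(mu = c(shape = 2, rate = 20),
                               sigma2 = c(shape = 2, rate = 2))),
            class = "clock_model_spec")
}

#' Log prior of branch rates and clock hyperparameters
#'
#' STR contributes only the Gamma(2, 20) hyperprior on mu. IR adds i.i.d.
#' lognormal branch-rate terms with expectation mu and log-variance sigma2;
#' AR adds sequential conditional lognormals along the tree (geometric
#' Brownian motion between branch midpoints, mean-preserving drift). IR and
#' AR add the Gamma(2, 2) hyperprior on sigma2. With several partitions the
#' partition mean rates follow a gamma-Dirichlet prior: Gamma(2, 20) on
#' their average, Dirichlet (concentration `conc`) on the proportions.
#'
#' @param rates Numeric vector of branch rates (ordered as `tt$phy$edge`
#'   rows), or a list of such vectors (one per partition).
#' @param spec A [clock_model_spec()]; `mu`/`sigma2` may be vectors over
#'   partitions.
#' @param tt The `timetree` carrying branch durations (needed for AR).
#' @param conc Dirichlet concentration for multi-partition mean rates.
#' @return Log density.
#' @export
clock_logprior <- function(rates, spec, tt, conc = 1) {
  if (!is.list(rates)) rates <- list(rates)
  npart <- length(rates)
  mu <- rep_len(spec$mu, npart)
  s2 <- rep_len(spec$sigma2, npart)
  if (any(unlist(rates) <= 0)) stop("rates must be positive")
  # gamma-Dirichlet on partition mean rates
  s <- mean(mu)
  lp <- stats::dgamma(s, shape = 2, rate = 20, log = TRUE)
  if (npart > 1) {
    z <- mu / (npart * s)
    lp <- lp + lgamma(npart * conc) - npart * lgamma(conc) +
      sum((conc - 1) * log(z)) - npart * log(npart) - (npart - 1) * log(s)
  }
  if (spec$model != "STR")
    lp <- lp + sum(stats::dgamma(s2, shape = 2, rate = 2, log = TRUE))
  if (spec$model == "IR") {
    for (p in seq_len(npart)) {
      sdl <- sqrt(max(s2[p], 1e-12))
      lp <- lp + sum(stats::dlnorm(rates[[p]], log(mu[p]) - s2[p] / 2, sdl,
                                   log = TRUE))
    }
  } else if (spec$model == "AR") {
    phy <- tt$phy
    root <- ape::Ntip(phy) + 1L
    dur <- tt$ages[phy$edge[, 1]] - tt$ages[phy$edge[, 2]]
    parent_edge <- match(phy$edge[, 1], phy$edge[, 2])  # NA for root edges
    for (p in seq_len(npart)) {
      r <- rates[[p]]
      for (e in seq_along(r)) {
        if (is.na(parent_edge[e])) {
          dt <- dur[e] / 2
          ml <- log(mu[p]) - s2[p] * dt / 2
        } else {
          pe <- parent_edge[e]
          dt <- (dur[pe] + dur[e]) / 2
          ml <- log(r[pe]) - s2[p] * dt / 2
        }
        v <- max(s2[p] * dt, 1e-12)
        lp <- lp + stats::dlnorm(r[e], ml, sqrt(v), log = TRUE)
      }
    }
  }
  lp
}
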