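#' Dichotomisation rules for a latent continuous outcome
#'
#' A binary outcome D is generated from a latent continuous score Y either by
#' a deterministic threshold, `P(D = 1 | Y = y) = 1(y > c)`, or by a logistic
#' link, `P(D = 1 | Y = y) = plogis(alpha + beta * y)`. The threshold rule is
#' the large-slope limit of the logistic rule (`beta -> Inf` with
#' `alpha = -beta * c`).
#'
#' @param c threshold on the latent score (threshold rule).
#' @param alpha intercept of the logistic link.
#' @param beta slope of the logistic link; must be positive so that a higher
#'   score makes "case" more likely.
#' @return An object of class `dicho_rule`.
#' @examples
#' dicho_threshold(1.1)
#' dicho_logistic(-3, 3)
#' @export
dicho_threshold <- function(c) {
  stopifnot(is.numeric(c), length(c) == 1L, is.finite(c))
  structure(list(kind = "threshold", c = c), class = "dicho_rule")
}

#' @rdname dicho_threshold
#' @export
dicho_logistic <- function(alpha, beta) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha),
            is.numeric(beta), length(beta) == 1L, is.finite(beta))
  if (beta <= 0) stop("`beta` must be > 0 (higher score => more likely case)")
  structure(list(kind = "logistic", alpha = alpha, beta = beta),
            class = "dicho_rule")
}

#' @export
print.dicho_rule <- function(x, ...) {
  if (x$kind == "threshold") {
    cat(sprintf("Dichotomisation rule: threshold, D = 1(Y > %.4g)\n", x$c))
  } else {
    cat(sprintf(
      "Dichotomisation rule: logistic, P(D=1|Y=y) = expit(%.4g + %.4g y)\n",
      x$alpha, x$beta))
  }
  invisible(x)
}

# P(D = 1 | Y = y) under a rule (vectorised in y)
dicho_prob <- function(rule, y) {
  if (rule$kind == "threshold") as.numeric(y > rule$c)
  else stats::plogis(rule$alpha + rule$beta * y)
}

#' Latent-outcome population model
#'
#' The data-generating law for the analytic computations and the simulator:
#' a binary exposure X with prevalence `pi_x`; a latent continuous outcome
#' `Y | X = x ~ N(mu_x, 1)` (conditional standard deviation fixed at 1, so the
#' exposure effect `delta = mu1 - mu0` is in SD units); and a binary outcome D
#' generated from Y via a [dicho_threshold()] or [dicho_logistic()] rule,
#' never from X directly.
#'
#' @param pi_x exposure prevalence, in (0, 1).
#' @param dicho a `dicho_rule`.
#' @param delta exposure effect on the latent score (location shift, SD units);
#'   equivalently `mu1` with `mu0 = 0`.
#' @param mu0 mean of Y in the unexposed arm (default 0).
#' @return An object of class `population_model` with fields `pi_x`, `mu0`,
#'   `mu1`, `delta` and `dicho`.
#' @seealso [calibrate_dichotomisation()] to construct the model from target
#'   prevalence and odds ratio; [case_prob()], [full_log_or()].
#' @examples
#' pm <- population_model(0.25, dicho_threshold(1.1), delta = 0.22)
#' case_prob(pm, 0)
#' @export
population_model <- function(pi_x, dicho, delta, mu0 = 0) {
  stopifnot(is.numeric(pi_x), length(pi_x) == 1L, is.finite(pi_x),
            inherits(dicho, "dicho_rule"),
            is.numeric(delta), length(delta) == 1L, is.finite(delta),
            is.numeric(mu0), length(mu0) == 1L, is.finite(mu0))
  if (pi_x <= 0 || pi_x >= 1) stop("`pi_x` must lie strictly in (0, 1)")
  structure(list(pi_x = pi_x, mu0 = mu0, mu1 = mu0 + delta, delta = delta,
                 dicho = dicho),
            class = "population_model")
}

#' @export
print.population_model <- function(x, ...) {
  cat("Latent-outcome population model\n")
  cat(sprintf("  P(X = 1) = %.4g;  Y | X ~ N(%.4g + %.4g X, 1)\n",
              x$pi_x, x$mu0, x$delta))
  print(x$dicho)
  p0 <- case_prob(x, 0); p1 <- case_prob(x, 1)
  cat(sprintf("  P(D=1|X=0) = %.4f, P(D=1|X=1) = %.4f, marginal = %.4f\n",
              p0, p1, (1 - x$pi_x) * p0 + x$pi_x * p1))
  cat(sprintf("  full-population exposure log OR = %.4f\n", full_log_or(x)))
  invisible(x)
}

# adaptive quadrature of f(y) * dnorm(y - mu) with tight tolerances
.quad <- function(f, mu, lower = -Inf, upper = Inf) {
  stats::integrate(function(y) f(y) * stats::dnorm(y, mean = mu),
                   lower, upper,
                   rel.tol = 1e-10, abs.tol = 1e-10,
                   subdivisions = 500L)$value
}

#' Probability of being a case given exposure
#'
#' Computes `P(D = 1 | X = x)` by integrating the dichotomisation link over
#' the conditional normal law of the latent score. For the threshold rule
#' this is the closed form `1 - pnorm(c - mu_x)`; for the logistic rule it is
#' evaluated by adaptive quadrature (absolute tolerance 1e-10).
#'
#' @param model a [population_model()].
#' @param x exposure level, 0 or 1 (vectorised).
#' @return Probabilities in (0, 1).
#' @export
case_prob <- function(model, x) {
  stopifnot(inherits(model, "population_model"), all(x %in% c(0, 1)))
  mu <- ifelse(x == 1, model$mu1, model$mu0)
  rule <- model$dicho
  if (rule$kind == "threshold") {
    1 - stats::pnorm(rule$c - mu)
  } else {
    vapply(mu, function(m) .quad(function(y) dicho_prob(rule, y), m),
           numeric(1))
  }
}

#' Full-population exposure log odds ratio
#'
#' The log odds ratio comparing `P(D = 1 | X = 1)` with `P(D = 1 | X = 0)`
#' in the full population (no missingness).
#'
#' @inheritParams case_prob
#' @return A single numeric log odds ratio.
#' @export
full_log_or <- function(model) {
  p <- case_prob(model, c(0, 1))
  if (any(p <= 0 | p >= 1))
    stop("degenerate dichotomisation: P(D=1|X) is 0 or 1")
  stats::qlogis(p[2]) - stats::qlogis(p[1])
}

#' Calibrate the generator to a target prevalence and odds ratio
#'
#' Solves for the dichotomisation parameter (threshold `c`, or intercept
#' `alpha` at fixed slope `beta`) and the latent exposure effect `delta`
#' such that the marginal outcome prevalence and the full-population exposure
#' log odds ratio hit their targets. The defaults reproduce the reference
#' scenario: exposure prevalence 25%, outcome prevalence 15%, log OR 0.405
#' (OR 1.50).
#'
#' The system is triangular once the case probabilities are profiled out:
#' given the threshold (or intercept), `P(D=1|X=0)` is fixed, the target log
#' OR pins `P(D=1|X=1)`, and the marginal prevalence then depends on the
#' threshold alone; a bracketed root search (tolerance well below 1e-8)
#' recovers it, after which `delta` follows from a second one-dimensional
#' solve (closed-form normal quantiles for the threshold rule).
#'
#' @param target_prev marginal outcome prevalence `P(D = 1)`.
#' @param target_log_or full-population exposure log odds ratio.
#' @param pi_x exposure prevalence.
#' @param kind `"threshold"` or `"logistic"` dichotomisation.
#' @param beta logistic slope (only for `kind = "logistic"`).
#' @return A calibrated [population_model()] whose `dicho` rule and `delta`
#'   reproduce the targets to within 1e-8.
#' @examples
#' pm <- calibrate_dichotomisation()
#' full_log_or(pm)                      # 0.405
#' p <- case_prob(pm, c(0, 1))
#' 0.75 * p[1] + 0.25 * p[2]            # 0.15
#' @export
calibrate_dichotomisation <- function(target_prev = 0.15,
                                      target_log_or = 0.405,
                                      pi_x = 0.25,
                                      kind = c("threshold", "logistic"),
                                      beta = 3) {
  kind <- match.arg(kind)
  stopifnot(is.finite(target_log_or), is.finite(target_prev),
            target_prev > 0, target_prev < 1, pi_x > 0, pi_x < 1)
  # p1 implied by p0 and the target log OR
  p1_of <- function(p0) stats::plogis(stats::qlogis(p0) + target_log_or)

  if (kind == "threshold") {
    prev_of_c <- function(cc) {
      p0 <- 1 - stats::pnorm(cc)
      (1 - pi_x) * p0 + pi_x * p1_of(p0) - target_prev
    }
    sol <- stats::uniroot(prev_of_c, c(-8, 8), extendInt = "downX",
                          tol = 1e-12)
    cc <- sol$root
    p1 <- p1_of(1 - stats::pnorm(cc))
    delta <- cc - stats::qnorm(1 - p1)
    rule <- dicho_threshold(cc)
  } else {
    p0_of_alpha <- function(alpha) {
      .quad(function(y) stats::plogis(alpha + beta * y), 0)
    }
    prev_of_alpha <- function(alpha) {
      p0 <- p0_of_alpha(alpha)
      (1 - pi_x) * p0 + pi_x * p1_of(p0) - target_prev
    }
    sol <- stats::uniroot(prev_of_alpha, c(-20, 20), extendInt = "upX",
                          tol = 1e-12)
    alpha <- sol$root
    rule <- dicho_logistic(alpha, beta)
    p1 <- p1_of(p0_of_alpha(alpha))
    if (target_log_or == 0) {
      delta <- 0
    } else {
      pcase_of_delta <- function(d) {
        .quad(function(y) stats::plogis(alpha + beta * y), d) - p1
      }
      delta <- stats::uniroot(pcase_of_delta, c(-6, 6), extendInt = "upX",
                              tol = 1e-12)$root
    }
  }
  model <- population_model(pi_x, rule, delta)
  # round-trip guard: the calibration must reproduce its own targets
  p <- case_prob(model, c(0, 1))
  prev <- (1 - pi_x) * p[1] + pi_x * p[2]
  if (abs(prev - target_prev) > 1e-8 ||
      abs(full_log_or(model) - target_log_or) > 1e-8)
    stop("calibration failed to reach its targets to 1e-8")
  model
}

#' Selection (missingness) model for the outcome
#'
#' The probability that the outcome is observed for a subject with exposure
#' `x` and latent score `y` is `linkinv(g0 + gx*x + gy*y + gxy*x*y)`. With
#' `link = "logit"` the inverse link is the logistic function; with
#' `link = "log"` it is the exponential, capped at 1 (a cap is reported via
#' a warning wherever it binds, since the log link does not constrain
#' probabilities). Setting `gx = gy = gxy = 0` gives missingness completely
#' at random; `gy != 0` with `gxy = 0` is the "outcome-only" mechanism, and
#' `gxy != 0` adds an exposure-by-outcome interaction, the configuration
#' under which complete-case logistic regression is not robust.
#'
#' For closed-form robustness checks the selection can instead depend on the
#' *binary* outcome (`depends_on = "d"`), in which case `gy`/`gxy` multiply
#' `d` and `x*d`.
#'
#' @param g0 intercept (solve with [solve_missingness_intercept()] to hit a
#'   target observed fraction).
#' @param gx exposure coefficient.
#' @param gy coefficient on the continuous outcome, per 1 SD (or on the
#'   binary outcome when `depends_on = "d"`).
#' @param gxy exposure-by-outcome interaction coefficient.
#' @param link `"logit"` (default) or `"log"`.
#' @param depends_on `"y"` (latent continuous outcome, default) or `"d"`.
#' @return An object of class `missingness_model`.
#' @examples
#' # observation OR of 0.75 per SD of the latent outcome
#' missingness_model(g0 = 0.43, gy = log(0.75))
#' @export
missingness_model <- function(g0 = 0, gx = 0, gy = 0, gxy = 0,
                              link = c("logit", "log"),
                              depends_on = c("y", "d")) {
  link <- match.arg(link)
  depends_on <- match.arg(depends_on)
  stopifnot(is.finite(g0), is.finite(gx), is.finite(gy), is.finite(gxy))
  structure(list(link = link, g0 = g0, gx = gx, gy = gy, gxy = gxy,
                 depends_on = depends_on),
            class = "missingness_model")
}

#' @export
print.missingness_model <- function(x, ...) {
  v <- if (x$depends_on == "y") "y" else "d"
  cat(sprintf(
    "Missingness model (%s link): P(R=1) = linkinv(%.4g + %.4g x + %.4g %s + %.4g x.%s)\n",
    x$link, x$g0, x$gx, x$gy, v, x$gxy, v))
  invisible(x)
}

#' Probability of the outcome being observed
#'
#' Evaluates the selection model at given outcome and exposure values.
#' For the log link, values above 1 are capped at 1 with a warning.
#'
#' @param miss a [missingness_model()].
#' @param y latent score (or binary outcome when `depends_on = "d"`).
#' @param x exposure (0/1), recycled against `y`.
#' @param warn_cap warn when the log link is capped at 1 (default TRUE;
#'   internal solvers disable it).
#' @return Observation probabilities in \[0, 1\].
#' @export
obs_prob <- function(miss, y, x, warn_cap = TRUE) {
  stopifnot(inherits(miss, "missingness_model"))
  eta <- miss$g0 + miss$gx * x + miss$gy * y + miss$gxy * x * y
  if (miss$link == "logit") {
    stats::plogis(eta)
  } else {
    p <- exp(eta)
    if (any(p > 1)) {
      if (warn_cap)
        warning("log-link observation probability capped at 1 for ",
                sum(p > 1), " point(s)")
      p <- pmin(p, 1)
    }
    p
  }
}

#' Analytic complete-case exposure log odds ratio and its bias
#'
#' Computes the odds ratio targeted by a complete-case logistic regression of
#' the dichotomised outcome on the exposure, when the probability of being
#' observed follows a selection model on the latent continuous outcome.
#' Assuming the binary outcome and the observation indicator are independent
#' given (Y, X),
#' \deqn{P(D = 1 \mid X = x, R = 1) =
#'   \frac{\int P(D = 1 \mid y)\, \pi(y, x)\, \phi(y - \mu_x)\, dy}
#'        {\int \pi(y, x)\, \phi(y - \mu_x)\, dy},}
#' evaluated by adaptive quadrature (absolute tolerance 1e-10 per integral).
#' When the selection depends on the binary outcome instead
#' (`depends_on = "d"`), the integrals collapse to exact finite sums.
#'
#' @param model a [population_model()].
#' @param miss a [missingness_model()].
#' @return An object of class `bias_result`: a list with `log_or_full`,
#'   `log_or_cc`, `bias` (`log_or_cc - log_or_full`), `percent_bias`
#'   (on the log-OR scale; an error if the full-population log OR is 0) and
#'   `frac_observed` (marginal probability of being observed).
#' @examples
#' pm <- calibrate_dichotomisation()
#' ms <- missingness_model(gy = log(0.75))
#' ms$g0 <- solve_missingness_intercept(pm, ms, target_frac_observed = 0.6)
#' complete_case_log_or(pm, ms)
#' @export
complete_case_log_or <- function(model, miss) {
  stopifnot(inherits(model, "population_model"),
            inherits(miss, "missingness_model"))
  rule <- model$dicho
  mu <- c(model$mu0, model$mu1)
  q <- numeric(2)   # P(D=1 | X=x, R=1)
  den <- numeric(2) # P(R=1 | X=x)
  for (i in 1:2) {
    x <- i - 1
    if (miss$depends_on == "d") {
      p <- case_prob(model, x)
      pr1 <- obs_prob(miss, 1, x)
      pr0 <- obs_prob(miss, 0, x)
      den[i] <- p * pr1 + (1 - p) * pr0
      q[i] <- p * pr1 / den[i]
    } else {
      pi_yx <- function(y) obs_prob(miss, y, x, warn_cap = FALSE)
      den[i] <- .quad(pi_yx, mu[i])
      num <- if (rule$kind == "threshold") {
        stats::integrate(function(y) pi_yx(y) * stats::dnorm(y, mu[i]),
                         rule$c, Inf, rel.tol = 1e-10, abs.tol = 1e-10,
                         subdivisions = 500L)$value
      } else {
        .quad(function(y) dicho_prob(rule, y) * pi_yx(y), mu[i])
      }
      q[i] <- num / den[i]
    }
  }
  if (any(den < 1e-12))
    stop("practically no complete cases in one exposure arm")
  lf <- full_log_or(model)
  lcc <- stats::qlogis(q[2]) - stats::qlogis(q[1])
  frac <- (1 - model$pi_x) * den[1] + model$pi_x * den[2]
  structure(list(log_or_full = lf, log_or_cc = lcc, bias = lcc - lf,
                 percent_bias = if (lf != 0) 100 * (lcc - lf) / lf else NA_real_,
                 frac_observed = frac),
            class = "bias_result")
}

#' @export
print.bias_result <- function(x, ...) {
  cat("Complete-case bias (analytic)\n")
  cat(sprintf("  full-population log OR : %.6f\n", x$log_or_full))
  cat(sprintf("  complete-case  log OR : %.6f\n", x$log_or_cc))
  cat(sprintf("  bias                  : %.6f", x$bias))
  if (!is.na(x$percent_bias)) cat(sprintf("  (%.2f%%)", x$percent_bias))
  cat(sprintf("\n  fraction observed     : %.4f\n", x$frac_observed))
  invisible(x)
}

#' Percent bias of a bias_result
#'
#' Percent bias on the log-OR scale; errors when the full-population log OR
#' is zero (percent bias is undefined there).
#'
#' @param x a `bias_result`.
#' @return Percent bias (numeric).
#' @export
percent_bias <- function(x) {
  stopifnot(inherits(x, "bias_result"))
  if (x$log_or_full == 0)
    stop("percent bias undefined: full-population log OR is 0")
  100 * x$bias / x$log_or_full
}

#' Solve the selection-model intercept for a target observed fraction
#'
#' Finds `g0` such that the marginal probability of being observed,
#' `sum_x P(X = x) * E[pi(Y, x)]`, equals `target_frac_observed`, by
#' bracketed root search (tolerance below 1e-8) with each expectation
#' evaluated by quadrature (or exact sums when the selection depends on the
#' binary outcome).
#'
#' @inheritParams complete_case_log_or
#' @param target_frac_observed marginal observation probability in (0, 1);
#'   equals 1 minus the target fraction of missing outcomes.
#' @return The intercept `g0` (numeric scalar).
#' @examples
#' pm <- calibrate_dichotomisation()
#' solve_missingness_intercept(pm, missingness_model(), 0.8)  # logit(0.8)
#' @export
solve_missingness_intercept <- function(model, miss, target_frac_observed) {
  stopifnot(inherits(model, "population_model"),
            inherits(miss, "missingness_model"),
            target_frac_observed > 0, target_frac_observed < 1)
  frac_of <- function(g0) {
    m <- miss; m$g0 <- g0
    marginal_obs_frac(model, m) - target_frac_observed
  }
  upper <- if (miss$link == "log") 0 else 40
  sol <- tryCatch(
    stats::uniroot(frac_of, c(-40, upper), tol = 1e-12, extendInt = "upX"),
    error = function(e) stop("no intercept reaches the target observed ",
                             "fraction (", conditionMessage(e), ")"))
  sol$root
}

# marginal P(R = 1) under the selection model
marginal_obs_frac <- function(model, miss) {
  mu <- c(model$mu0, model$mu1)
  w <- c(1 - model$pi_x, model$pi_x)
  per_arm <- vapply(1:2, function(i) {
    x <- i - 1
    if (miss$depends_on == "d") {
      p <- case_prob(model, x)
      p * obs_prob(miss, 1, x, warn_cap = FALSE) +
        (1 - p) * obs_prob(miss, 0, x, warn_cap = FALSE)
    } else {
      .quad(function(y) obs_prob(miss, y, x, warn_cap = FALSE), mu[i])
    }
  }, numeric(1))
  sum(w * per_arm)
}

#' Analytic bias over a grid of missingness strengths and fractions
#'
#' Re-solves the selection intercept for every grid cell and evaluates the
#' complete-case bias there, reproducing the classic bias-vs-missingness
#' curves: one curve per observation odds ratio per SD of the latent outcome,
#' swept over the fraction of missing outcome data.
#'
#' @param model a [population_model()].
#' @param gy_or observation odds (or risk, for the log link) ratios per 1 SD
#'   of the latent outcome; one curve per value.
#' @param frac_missing fractions of missing outcome data in (0, 1).
#' @param link `"logit"` or `"log"` selection link.
#' @param gx,gxy optional exposure and interaction coefficients (log scale),
#'   fixed across the grid.
#' @return A data frame with columns `gy_or`, `frac_missing`, `log_or_full`,
#'   `log_or_cc`, `bias`, `percent_bias`, `frac_observed`.
#' @examples
#' pm <- calibrate_dichotomisation()
#' bias_curve(pm, gy_or = c(0.9, 0.75), frac_missing = c(0.2, 0.5, 0.8))
#' @export
bias_curve <- function(model, gy_or, frac_missing, link = "logit",
                       gx = 0, gxy = 0) {
  stopifnot(length(gy_or) >= 1, length(frac_missing) >= 1,
            all(gy_or > 0), all(frac_missing > 0 & frac_missing < 1))
  grid <- expand.grid(frac_missing = frac_missing, gy_or = gy_or,
                      KEEP.OUT.ATTRS = FALSE)[, c("gy_or", "frac_missing")]
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    m <- missingness_model(gx = gx, gy = log(grid$gy_or[i]), gxy = gxy,
                           link = link)
    m$g0 <- solve_missingness_intercept(model, m,
                                        1 - grid$frac_missing[i])
    b <- complete_case_log_or(model, m)
    data.frame(gy_or = grid$gy_or[i], frac_missing = grid$frac_missing[i],
               log_or_full = b$log_or_full, log_or_cc = b$log_or_cc,
               bias = b$bias, percent_bias = b$percent_bias,
               frac_observed = b$frac_observed)
  })
  do.call(rbind, rows)
}
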