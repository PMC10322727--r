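#' Maximum-likelihood logistic regression with Wald standard errors
#'
#' A thin wrapper around [stats::glm.fit()] (binomial family, IRLS) returning
#' the exposure log odds ratio with its observed-information Wald standard
#' error and an explicit convergence flag. Accepts case weights, so grouped
#' binary data (covariate-pattern counts) give exactly the record-level fit.
#' Separation or non-convergence is reported via `converged = FALSE` and a
#' diagnostic message, never silently.
#'
#' @param outcome binary 0/1 response vector.
#' @param design numeric design matrix including the intercept column; the
#'   coefficient reported as `estimate` is the one named `"x"` if present,
#'   otherwise the second column.
#' @param weights optional non-negative case weights (counts).
#' @return An object of class `logit_fit`: list with `coef`, `vcov`,
#'   `estimate`, `se`, `n_used`, `converged`, `message`.
#' @examples
#' # a balanced 2x2: exposure log OR is exactly 0
#' fit_logistic(c(0, 0, 1, 1), cbind(1, x = c(0, 1, 0, 1)))
#' @export
fit_logistic <- function(outcome, design, weights = NULL) {
  design <- as.matrix(design)
  stopifnot(length(outcome) == nrow(design),
            all(outcome %in% c(0, 1)))
  if (is.null(weights)) weights <- rep(1, length(outcome))
  stopifnot(all(weights >= 0))
  if (length(unique(outcome[weights > 0])) < 2L)
    stop("outcome needs both classes present")
  if (is.null(colnames(design)))
    colnames(design) <- c("(Intercept)",
                          paste0("b", seq_len(ncol(design) - 1L)))
  fit <- suppressWarnings(
    stats::glm.fit(design, outcome, weights = weights,
                   family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-10,
                                                maxit = 100L)))
  p <- fit$rank
  cf <- fit$coefficients
  piv <- fit$qr$pivot[seq_len(p)]
  vc <- matrix(NA_real_, ncol(design), ncol(design),
               dimnames = list(colnames(design), colnames(design)))
  vc[piv, piv] <- chol2inv(fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE])
  se_all <- sqrt(diag(vc))
  term <- if ("x" %in% colnames(design)) "x" else colnames(design)[2L]
  sep <- any(!is.finite(cf)) || max(abs(cf), na.rm = TRUE) > 15 ||
    any(!is.finite(se_all)) || max(se_all, na.rm = TRUE) > 100
  converged <- isTRUE(fit$converged) && p == ncol(design) && !sep
  msg <- if (converged) ""
         else if (p < ncol(design)) "rank-deficient design"
         else if (sep) "separation (diverging estimates)"
         else "IRLS did not converge"
  structure(list(coef = cf, vcov = vc,
                 estimate = unname(cf[term]), se = unname(se_all[term]),
                 n_used = sum(weights),  # records, counting case weights
                 converged = converged, message = msg),
            class = "logit_fit")
}

#' @export
print.logit_fit <- function(x, ...) {
  cat(sprintf("Logistic fit (n = %g): exposure log OR = %.4f (SE %.4f)%s\n",
              x$n_used, x$estimate, x$se,
              if (x$converged) "" else paste0("  [NOT CONVERGED: ",
                                              x$message, "]")))
  invisible(x)
}

#' @export
coef.logit_fit <- function(object, ...) object$coef

# reusable binomial family object (glm.fit instantiates closures otherwise)
.binom <- stats::binomial()

# the fixed 8-cell design for a conditional of one binary variable on two
# others: response pattern in column 1, covariates in 2:3
.cell_grid <- as.matrix(expand.grid(0:1, 0:1, 0:1, KEEP.OUT.ATTRS = FALSE))
.cell_X <- cbind(1, .cell_grid[, 2L], .cell_grid[, 3L])
.cell_y <- .cell_grid[, 1L]

# minimal-overhead weighted logistic fit on the fixed 8-cell design;
# glm.fit does the IRLS, we only pull out coef, Cholesky of the vcov and a
# convergence flag. Used in the chained-equations inner loop.
.cellfit <- function(cnt) {
  fit <- suppressWarnings(
    stats::glm.fit(.cell_X, .cell_y, weights = cnt, family = .binom,
                   control = stats::glm.control(epsilon = 1e-10,
                                                maxit = 100L)))
  cf <- fit$coefficients
  if (!isTRUE(fit$converged) || fit$rank < 3L || anyNA(cf) ||
      max(abs(cf)) > 15)
    return(NULL)
  p <- fit$rank
  vc <- chol2inv(fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE])
  list(coef = cf, cholv = chol(vc))
}

# proper draw from a .cellfit and the four pattern probabilities
# plogis(b1 + b2*u + b3*v) for (u, v) in {0,1}^2 (order: 00, 10, 01, 11)
.cell_draw_probs <- function(fit) {
  b <- fit$coef + drop(crossprod(fit$cholv, stats::rnorm(3L)))
  stats::plogis(b[1L] + b[2L] * c(0, 1, 0, 1) + b[3L] * c(0, 0, 1, 1))
}

# collapse binary data to covariate-pattern counts and fit; identical
# MLE/Wald SE to the record-level fit, orders of magnitude faster in the
# simulation loops
.fit_collapsed <- function(y, covs) {
  p <- length(covs)
  idx <- y + 1L
  mult <- 2L
  for (v in covs) {
    idx <- idx + v * mult
    mult <- mult * 2L
  }
  cnt <- tabulate(idx, mult)
  grid <- as.matrix(expand.grid(rep(list(0:1), p + 1L),
                                KEEP.OUT.ATTRS = FALSE))
  keep <- cnt > 0L
  X <- cbind(1, grid[keep, -1L, drop = FALSE])
  colnames(X) <- c("(Intercept)", names(covs))
  fit_logistic(grid[keep, 1L], X, weights = cnt[keep])
}

#' Complete-case exposure estimate
#'
#' Logistic regression of the binary outcome on the exposure restricted to
#' records with the outcome observed (`r = 1`).
#'
#' @param cohort a `cohort` (see [draw_cohort()]).
#' @return A [fit_logistic()] result with `n_used` the number of complete
#'   cases.
#' @export
complete_case_estimate <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  ok <- cohort$r == 1L & !is.na(cohort$d)
  if (!any(ok)) stop("no complete cases")
  .fit_collapsed(cohort$d[ok], list(x = cohort$x[ok]))
}

# proper posterior draw of logistic coefficients: N(MLE, observed-information
# covariance)
.draw_coef <- function(fit) {
  L <- chol(fit$vcov)
  fit$coef + drop(crossprod(L, stats::rnorm(length(fit$coef))))
}

#' Single proper imputation of the binary outcome
#'
#' Fits the imputation model -- logistic regression of the outcome on the
#' exposure and the auxiliary proxy among records with the outcome observed
#' -- draws a coefficient vector from its asymptotic normal posterior
#' (mean = MLE, covariance = inverse observed information), and imputes each
#' missing outcome as a Bernoulli draw of the drawn-parameter predicted
#' probability. Requires a fully observed auxiliary; use
#' [chained_imputation()] otherwise.
#'
#' @param cohort a `cohort` with missingness imposed.
#' @param seed optional seed for this call (otherwise the current RNG state
#'   is used, as inside [mi_estimate()]).
#' @param imp_fit optional precomputed imputation-model fit (the fit does not
#'   change between imputations, only the posterior draw does).
#' @return The completed binary outcome vector.
#' @export
impute_once <- function(cohort, seed = NULL, imp_fit = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  if (!is.null(seed)) set.seed(seed)
  d <- cohort$d
  mis <- is.na(d)
  if (!any(mis)) return(d)
  if (anyNA(cohort$a))
    stop("auxiliary has missing values: use chained_imputation()")
  if (is.null(imp_fit)) {
    obs <- !mis
    imp_fit <- .fit_collapsed(d[obs], list(x = cohort$x[obs],
                                           a = cohort$a[obs]))
  }
  if (!imp_fit$converged)
    stop("imputation model did not converge: ", imp_fit$message)
  b <- .draw_coef(imp_fit)
  eta <- b[1] + b[2] * cohort$x[mis] + b[3] * cohort$a[mis]
  d[mis] <- stats::rbinom(sum(mis), 1L, stats::plogis(eta))
  d
}

#' Chained-equations imputation of outcome and auxiliary
#'
#' Multiple imputation by chained equations for the case where both the
#' binary outcome and the auxiliary proxy are partially observed: missing
#' values are initialised by resampling the observed margins, then the two
#' conditionals -- auxiliary given (exposure, outcome) and outcome given
#' (exposure, auxiliary), each a proper logistic draw as in [impute_once()]
#' -- are alternated for `burn_in` cycles and the final completed pair is
#' returned. With a fully observed auxiliary the auxiliary step is a no-op
#' and the procedure reduces to a single-variable imputation.
#'
#' @param cohort a `cohort`.
#' @param burn_in number of cycles (default 20).
#' @param seed optional seed for this call.
#' @return A list with completed vectors `d` and `a`.
#' @export
chained_imputation <- function(cohort, burn_in = 20L, seed = NULL) {
  stopifnot(inherits(cohort, "cohort"), burn_in >= 1L)
  if (!is.null(seed)) set.seed(seed)
  d <- cohort$d; a <- cohort$a; x <- cohort$x
  mis_d <- is.na(d); mis_a <- is.na(a)
  if (!any(mis_d) && !any(mis_a)) return(list(d = d, a = a))
  # initialise from the observed margins
  if (any(mis_a)) a[mis_a] <- sample(a[!mis_a], sum(mis_a), replace = TRUE)
  if (any(mis_d)) d[mis_d] <- sample(d[!mis_d], sum(mis_d), replace = TRUE)
  # Binary data make each conditional a weighted logistic regression on the
  # fixed 8-cell design, and drawn predicted probabilities take only 4
  # values. Cell counts are updated incrementally: the rows where both
  # variables are observed contribute a fixed count vector; only the rows
  # whose partner value is re-imputed are re-tabulated each cycle.
  oa <- !mis_a; od <- !mis_d
  both <- oa & od
  fix_a <- tabulate(1L + a[both] + 2L * x[both] + 4L * d[both], 8L)
  fix_d <- tabulate(1L + d[both] + 2L * x[both] + 4L * a[both], 8L)
  va <- which(oa & mis_d)        # a-model rows with imputed outcome
  vd <- which(od & mis_a)        # d-model rows with imputed auxiliary
  base_a <- 1L + a[va] + 2L * x[va]
  base_d <- 1L + d[vd] + 2L * x[vd]
  wm_a <- which(mis_a); wm_d <- which(mis_d)
  pat_a <- 1L + x[wm_a]          # + 2*d at draw time
  pat_d <- 1L + x[wm_d]
  n_ma <- length(wm_a); n_md <- length(wm_d)
  for (cycle in seq_len(burn_in)) {
    if (n_ma > 0L) {
      cnt <- fix_a + tabulate(base_a + 4L * d[va], 8L)
      f <- .cellfit(cnt)
      if (is.null(f))
        stop("auxiliary conditional did not converge (separation)")
      pr <- .cell_draw_probs(f)
      a[wm_a] <- as.integer(stats::runif(n_ma) < pr[pat_a + 2L * d[wm_a]])
    }
    if (n_md > 0L) {
      cnt <- fix_d + tabulate(base_d + 4L * a[vd], 8L)
      f <- .cellfit(cnt)
      if (is.null(f))
        stop("outcome conditional did not converge (separation)")
      pr <- .cell_draw_probs(f)
      d[wm_d] <- as.integer(stats::runif(n_md) < pr[pat_d + 2L * a[wm_d]])
    }
    if (n_ma == 0L) break  # nothing iterates: one pass is the fixed point
  }
  list(d = d, a = a)
}

#' Rubin's-rules pooling
#'
#' Pools per-imputation estimates and squared standard errors:
#' `qbar = mean(estimates)`, within-variance `w = mean(variances)`,
#' between-variance `b = var(estimates)` (denominator m - 1), total
#' `t = w + (1 + 1/m) b`, small-sample degrees of freedom
#' `df = (m - 1) (1 + w / ((1 + 1/m) b))^2`, and the df-adjusted fraction of
#' missing information `fmi = (r + 2/(df + 3)) / (r + 1)` with
#' `r = (1 + 1/m) b / w`. The simple variant `(1 + 1/m) b / t` is also
#' returned as `fmi_simple`.
#'
#' @param estimates per-imputation point estimates (length m >= 2).
#' @param variances per-imputation squared standard errors.
#' @return An object of class `mi_pool` with fields `m, qbar, w, b, t, se,
#'   df, fmi, fmi_simple`.
#' @examples
#' pool_rubin(c(0.4, 0.6), c(0.01, 0.01))  # qbar 0.5, t 0.04, se 0.2
#' @export
pool_rubin <- function(estimates, variances) {
  m <- length(estimates)
  stopifnot(m >= 2L, length(variances) == m, all(variances > 0))
  qbar <- mean(estimates)
  w <- mean(variances)
  b <- stats::var(estimates)
  t <- w + (1 + 1 / m) * b
  if (b > 0) {
    r <- (1 + 1 / m) * b / w
    df <- (m - 1) * (1 + 1 / r)^2
    fmi <- (r + 2 / (df + 3)) / (r + 1)
  } else {
    r <- 0; df <- Inf; fmi <- 0
  }
  structure(list(m = m, qbar = qbar, w = w, b = b, t = t, se = sqrt(t),
                 df = df, fmi = fmi,
                 fmi_simple = (1 + 1 / m) * b / t),
            class = "mi_pool")
}

#' @export
print.mi_pool <- function(x, ...) {
  cat(sprintf(
    "Rubin's-rules pooled estimate (m = %d): %.4f (SE %.4f), FMI %.3f\n",
    x$m, x$qbar, x$se, x$fmi))
  invisible(x)
}

#' Multiple-imputation estimate of the exposure log odds ratio
#'
#' Generates `m` completed datasets -- by [impute_once()] when the auxiliary
#' is fully observed, by [chained_imputation()] otherwise -- fits the
#' analysis model (logistic regression of outcome on exposure) to each, and
#' pools with Rubin's rules. Imputations whose analysis fit does not
#' converge are dropped and counted (`n_dropped`); fewer than two usable
#' fits is an error.
#'
#' @param cohort a `cohort` with missingness imposed.
#' @param m number of imputations (default from the cohort's spec).
#' @param burn_in chained-equations burn-in (default from the spec).
#' @param seed optional seed; by default the imputation-stage substream of
#'   the cohort's (seed, scenario, replicate) is used, so results are
#'   reproducible without touching the global RNG contract.
#' @return An `mi_pool` with an extra field `n_dropped`.
#' @export
mi_estimate <- function(cohort, m = NULL, burn_in = NULL, seed = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  spec <- attr(cohort, "spec")
  if (is.null(m)) m <- spec$m
  if (is.null(burn_in)) burn_in <- spec$burn_in
  if (is.null(seed))
    seed <- substream_seed(spec$seed, 4L, attr(cohort, "replicate"),
                           spec$scenario_id)
  set.seed(seed)
  chained <- anyNA(cohort$a)
  imp_fit <- NULL
  if (!chained && anyNA(cohort$d)) {
    obs <- !is.na(cohort$d)
    imp_fit <- .fit_collapsed(cohort$d[obs],
                              list(x = cohort$x[obs], a = cohort$a[obs]))
    if (!imp_fit$converged)
      stop("imputation model did not converge: ", imp_fit$message)
  }
  est <- se2 <- numeric(m)
  keep <- logical(m)
  for (j in seq_len(m)) {
    dj <- if (chained) chained_imputation(cohort, burn_in)$d
          else impute_once(cohort, imp_fit = imp_fit)
    fj <- .fit_collapsed(dj, list(x = cohort$x))
    est[j] <- fj$estimate
    se2[j] <- fj$se^2
    keep[j] <- fj$converged
  }
  if (sum(keep) < 2L)
    stop("fewer than 2 converged per-imputation analysis fits")
  out <- pool_rubin(est[keep], se2[keep])
  out$n_dropped <- sum(!keep)
  out
}
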