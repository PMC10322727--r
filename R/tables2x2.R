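#' Exact 2x2 contingency table of an index test against a reference standard
#'
#' Counts are laid out with the reference standard on the columns and the
#' index test (the auxiliary proxy here) on the rows: `tn` reference-negative
#' test-negative, `fp` reference-negative test-positive, `fn`
#' reference-positive test-negative, `tp` reference-positive test-positive.
#'
#' @param tn,fp,fn,tp non-negative integer counts.
#' @return An object of class `twobytwo`.
#' @examples
#' two_by_two(tn = 3012, fp = 72, fn = 199, tp = 71)
#' @export
two_by_two <- function(tn, fp, fn, tp) {
  cts <- c(tn = tn, fp = fp, fn = fn, tp = tp)
  stopifnot(all(is.finite(cts)), all(cts >= 0))
  if (sum(cts) == 0) stop("empty table")
  structure(as.list(cts), class = "twobytwo")
}

#' @export
print.twobytwo <- function(x, ...) {
  m <- matrix(c(x$tn, x$fn, x$fp, x$tp), 2, 2,
              dimnames = list(test = c("negative", "positive"),
                              reference = c("negative", "positive")))
  print(m)
  cat(sprintf("sensitivity %s%%, specificity %s%%\n",
              format(percent1(sensitivity(x)), nsmall = 1),
              format(percent1(specificity(x)), nsmall = 1)))
  invisible(x)
}

#' Sensitivity and specificity of a 2x2 table
#'
#' `sensitivity` is `tp / (tp + fn)` (recovery of reference positives);
#' `specificity` is `tn / (tn + fp)`. Both are returned as raw proportions
#' at full precision; use [percent1()] for the 1-decimal percent rendering
#' used in reports.
#'
#' @param t a [two_by_two()] table.
#' @return A proportion in \[0, 1\].
#' @examples
#' t3 <- two_by_two(3012, 72, 199, 71)
#' percent1(sensitivity(t3))  # 26.3
#' percent1(specificity(t3))  # 97.7
#' @export
sensitivity <- function(t) {
  stopifnot(inherits(t, "twobytwo"))
  if (t$tp + t$fn == 0) stop("no reference positives: sensitivity undefined")
  t$tp / (t$tp + t$fn)
}

#' @rdname sensitivity
#' @export
specificity <- function(t) {
  stopifnot(inherits(t, "twobytwo"))
  if (t$tn + t$fp == 0) stop("no reference negatives: specificity undefined")
  t$tn / (t$tn + t$fp)
}

#' Render a proportion as a percent rounded half-up to 1 decimal
#'
#' Report parity: printed tables round half-up (so 0.26250 -> 26.3), whereas
#' base R `round()` rounds half to even.
#'
#' @param p proportion(s) in \[0, 1\].
#' @return Percent value(s) with 1 decimal.
#' @export
percent1 <- function(p) floor(p * 1000 + 0.5) / 10

#' Odds ratio of a 2x2 table with Woolf log-scale standard error
#'
#' Cross-product ratio `(tp * tn) / (fp * fn)` with
#' `SE(log OR) = sqrt(1/tp + 1/fp + 1/fn + 1/tn)`. A zero cell is an error
#' unless the opt-in continuity correction (add 0.5 to every cell) is
#' enabled, in which case the result is flagged `corrected`.
#'
#' @param t a [two_by_two()] table.
#' @param correct apply the 0.5 continuity correction to all cells?
#' @return List with `or`, `log_or`, `se_log_or`, `corrected`.
#' @examples
#' odds_ratio(two_by_two(3012, 72, 199, 71))$or  # ~14.93
#' @export
odds_ratio <- function(t, correct = FALSE) {
  stopifnot(inherits(t, "twobytwo"))
  cells <- c(t$tn, t$fp, t$fn, t$tp)
  corrected <- FALSE
  if (any(cells == 0)) {
    if (!correct)
      stop("zero cell: enable `correct = TRUE` for the 0.5 continuity ",
           "correction")
    cells <- cells + 0.5
    corrected <- TRUE
  }
  or <- (cells[4] * cells[1]) / (cells[2] * cells[3])
  list(or = or, log_or = log(or), se_log_or = sqrt(sum(1 / cells)),
       corrected = corrected)
}

#' Packaged reference 2x2 tables of proxy depression measures
#'
#' Reference cross-tabulations of three record-linkage proxy measures of
#' depression (current, future, historical) against a cohort study's binary
#' depression outcome, shipped as a plain-text fixture together with their
#' reported sensitivity/specificity percentages (rounded to one decimal).
#'
#' @return A data frame with columns `measure`, `tn`, `fp`, `fn`, `tp`,
#'   `sens_pct`, `spec_pct`.
#' @export
proxy_accuracy_tables <- function() {
  path <- system.file("extdata", "proxy_accuracy_tables.csv",
                      package = "dichobias", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Check the packaged tables against their printed accuracy figures
#'
#' Recomputes sensitivity and specificity from the packaged counts and
#' compares with the printed percentages at 1-decimal half-up rounding.
#'
#' @return A data frame with computed and expected percentages and a
#'   logical `ok` column; invisibly signals overall agreement via the
#'   `all_ok` attribute.
#' @export
check_proxy_accuracy <- function() {
  tab <- proxy_accuracy_tables()
  comp <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
    t <- two_by_two(tab$tn[i], tab$fp[i], tab$fn[i], tab$tp[i])
    data.frame(measure = tab$measure[i],
               sens_computed = percent1(sensitivity(t)),
               sens_expected = tab$sens_pct[i],
               spec_computed = percent1(specificity(t)),
               spec_expected = tab$spec_pct[i])
  }))
  comp$ok <- comp$sens_computed == comp$sens_expected &
    comp$spec_computed == comp$spec_expected
  attr(comp, "all_ok") <- all(comp$ok)
  comp
}
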