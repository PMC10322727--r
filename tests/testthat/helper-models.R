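# shared fixtures: the calibrated reference generator (cached in-package)
# and frozen oracle values computed independently by closed-form normal
# arithmetic plus high-precision quadrature before the implementation was
# written (see test comments for the defining formulas)
ref_pop <- function() default_population()

# threshold and latent shift solving prev 0.15 / log OR 0.405 / pi_x 0.25
ORACLE_C <- 1.0973426087
ORACLE_DELTA <- 0.2240893398

# mechanism (i), observation OR 0.75 per SD: intercept for 60% observed and
# the complete-case log OR at 40% and 80% missing
ORACLE_G0_60 <- 0.42977468
ORACLE_CC_LOR_40 <- 0.41348535
ORACLE_CC_LOR_80 <- 0.42728489

# a cohort wrapper for hand-built records (tests of accessors/estimators)
make_cohort <- function(x, y, d, a, r = rep(1L, length(x)),
                        spec = scenario_spec(n = length(x), seed = 1)) {
  out <- data.frame(x = x, y = y, d = d, a = a, r = r)
  class(out) <- c("cohort", "data.frame")
  attr(out, "spec") <- spec
  attr(out, "replicate") <- 1L
  out
}
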