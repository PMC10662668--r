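# Shared fixtures and independent oracles used across the suite.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Independent integer seeds for replicate simulations.
derive_seeds_for_test <- function(seed, n) {
  set.seed(seed)
  sample.int(2^31 - 3L, n)
}

# Fully deterministic child behavior: no guessing, no lapses, no timeouts,
# step-function psychometric (correct iff level >= threshold).
noiseless_behavior <- function() {
  psychometric_params(guess = 0, lapse = 0, slope = 0, timeout_prob = 0)
}

# A child with flat audiograms at the given per-ear levels.
flat_child <- function(id, right_dB, left_dB, behavior = psychometric_params()) {
  child_profile(id,
                ear_audiogram("right", rep(right_dB, 5)),
                ear_audiogram("left", rep(left_dB, 5)),
                behavior)
}

# Brute-force kappa: expand the 2x2 table into paired label vectors, then
# compute observed agreement by enumeration and expected agreement from the
# empirical label frequencies. Independent of the closed-form path.
kappa_oracle <- function(t) {
  test <- c(rep("pos", t$a), rep("pos", t$b), rep("neg", t$c), rep("neg", t$d))
  ref  <- c(rep("pos", t$a), rep("neg", t$b), rep("pos", t$c), rep("neg", t$d))
  po <- mean(test == ref)
  pe <- sum(vapply(c("pos", "neg"), function(lab) {
    mean(test == lab) * mean(ref == lab)
  }, numeric(1)))
  (po - pe) / (1 - pe)
}

# Brute-force Clopper-Pearson from the defining binomial tail equations,
# solved numerically on the cumulative sum (no beta quantiles involved).
cp_oracle <- function(x, n, conf = 0.95) {
  alpha <- (1 - conf) / 2
  upper_tail <- function(p) sum(dbinom(x:n, n, p))       # P(X >= x)
  lower_tail <- function(p) sum(dbinom(0:x, n, p))       # P(X <= x)
  lo <- if (x == 0) 0 else {
    uniroot(function(p) upper_tail(p) - alpha, c(1e-12, 1 - 1e-12),
            tol = 1e-12)$root
  }
  hi <- if (x == n) 1 else {
    uniroot(function(p) lower_tail(p) - alpha, c(1e-12, 1 - 1e-12),
            tol = 1e-12)$root
  }
  c(lo = 100 * lo, hi = 100 * hi)
}

# Direct evaluation of the descent decision tree for a deterministic child:
# a level is passed iff it is at or above the ear threshold; descent stops at
# the first failure; the category comes from the lowest passed level.
tree_oracle <- function(threshold, levels = c(40, 30, 20)) {
  lowest <- NA_real_
  for (lv in levels) {
    if (lv >= threshold) lowest <- lv else break
  }
  if (is.na(lowest)) return("moderate")
  if (lowest <= 20) "normal" else "mild"
}
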