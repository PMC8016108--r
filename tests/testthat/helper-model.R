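# Shared test helpers: small hand-assembled systems and parameter tweaks.

# Copy a follicle_params with some fields overridden (bypasses re-validation;
# only used with values known to be admissible).
tweak_params <- function(base, ...) {
  upd <- list(...)
  for (nm in names(upd)) base[[nm]] <- upd[[nm]]
  base
}

# A chain of two unit springs over DOFs 1-2-3.
two_spring_chain <- function(k = 1) {
  list(spring_element(k, c(1, 2)), spring_element(k, c(2, 3)))
}

# Independent zero-crossing count: plain consecutive-sign scan on samples
# above an absolute threshold, no interpolation, same domain convention as
# classify_profile (interior of the follicle minus the clamped entrance
# margin). Used as the dense-grid oracle for classify_profile.
count_crossings_brute <- function(x, r, L, eps, entrance_margin = 0.05) {
  keep <- x > 0 & x <= (1 - entrance_margin) * L & abs(r) >= eps
  s <- sign(r[keep])
  sum(diff(s) != 0)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected)) / max(abs(expected)), tol)
}
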