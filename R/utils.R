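# Internal numeric helpers shared across modules.

# Two-sided p-value from a z-score, safe in the far tail (works on the log
# scale internally; smallest representable two-sided p is ~1e-308).
p_from_z <- function(z) {
  lp <- pnorm(abs(z), lower.tail = FALSE, log.p = TRUE) + log(2)
  p <- exp(lp)
  # p-values are reported in (0, 1]; exact zeros only occur past double range
  pmin(p, 1)
}

# Upper-tail probit: gene z from p, overflow-safe. p below double precision is
# floored at 1e-300 (with a warning at the call site where it matters).
z_from_p_upper <- function(p) {
  p <- pmax(p, 1e-300)
  qnorm(p, lower.tail = FALSE)
}

# log(sum(exp(x))) without overflow; drives PIP normalization.
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Assign n items to k groups as evenly as possible (first groups get the
# remainder); used to lay variants and genes onto chromosomes.
split_counts <- function(n, k) {
  base <- n %/% k
  extra <- n %% k
  base + c(rep(1L, extra), rep(0L, k - extra))
}
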