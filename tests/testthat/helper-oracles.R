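# Independent oracle implementations used to cross-check the package's
# likelihood code.  These deliberately follow different algebraic routes
# (explicit per-interval loops over exponential log-densities) from the
# vectorised implementations in the package.

# Pure birth: sum of per-interval exponential log-densities.  While i
# lineages exist the waiting time to the next event is Exp(i * lambda);
# the final interval (n lineages) is censored at the present.
oracle_pb_lnl <- function(lambda, ages) {
  ages <- sort(ages, decreasing = TRUE)
  n <- length(ages) + 1L
  bounds <- c(ages, 0)
  lnl <- 0
  for (i in 2:n) {
    d <- bounds[i - 1L] - bounds[i]
    if (i < n) lnl <- lnl + log(i * lambda) - i * lambda * d
    else       lnl <- lnl - i * lambda * d
  }
  lnl
}

# Per-interval rates, same loop structure.
oracle_rpi_lnl <- function(rates, ages) {
  ages <- sort(ages, decreasing = TRUE)
  n <- length(ages) + 1L
  bounds <- c(ages, 0)
  lnl <- 0
  for (i in 2:n) {
    lam <- rates[i - 1L]
    d <- bounds[i - 1L] - bounds[i]
    if (i < n) lnl <- lnl + log(i * lam) - i * lam * d
    else       lnl <- lnl - i * lam * d
  }
  lnl
}

# Constant-rate birth-death, direct term-by-term evaluation of the
# reconstructed-process expression (safe without log-sum tricks at the
# small ages used in tests), plus the shared orderings constant.
oracle_bd_lnl <- function(r, a, ages) {
  ages <- sort(ages, decreasing = TRUE)
  n <- length(ages) + 1L
  lnl <- lgamma(n) + (n - 2) * log(r) + n * log(1 - a)
  for (x in ages[-1L]) lnl <- lnl + r * x
  for (x in ages) lnl <- lnl - 2 * log(exp(r * x) - a)
  lnl
}

# Two-rate shift: split every interval at the shift age and accumulate
# segment by segment; the event closing an interval takes the rate in
# force on the younger side of the interval, except that an event exactly
# at the shift age belongs to the older regime.
oracle_y2r_lnl <- function(r1, r2, st, ages) {
  ages <- sort(ages, decreasing = TRUE)
  n <- length(ages) + 1L
  bounds <- c(ages, 0)
  lnl <- lgamma(n)   # orderings constant, matching the package convention
  for (i in 2:n) {
    hi <- bounds[i - 1L]; lo <- bounds[i]
    above <- max(0, hi - max(lo, st))
    below <- max(0, min(hi, st) - lo)
    lnl <- lnl - i * (r1 * above + r2 * below)
    if (i < n) lnl <- lnl + log(r1 * (lo >= st) + r2 * (lo < st))
  }
  lnl
}

# Small fixed trees used across test files.
fixture_ages <- list(
  three = c(2, 1),
  four = c(3, 2, 1),
  tied = c(4, 2, 2, 0.5),
  six = c(9.3, 5.1, 4.4, 2.2, 0.7)
)

local_seeded <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}
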