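# Birth-death diversification likelihoods, ML fitting, and AIC comparison.
#
# All five models consume branching times x_2 >= x_3 >= ... >= x_n (ages
# before present; x_2 = crown age).  Writing d_i for the duration during
# which the reconstructed tree has exactly i lineages (d_n runs from x_n to
# the present), the shared pure-birth kernel is
#
#   lnL = sum_{i=2}^{n-1} ln(i * lambda_i)  -  sum_{i=2}^{n} i * lambda_i * d_i
#
# with lambda_i the per-lineage speciation rate while i lineages exist.  The
# constant-rate birth-death likelihood (Nee-style reconstructed process)
# omits the orderings constant sum_{i=2}^{n-1} ln i; we add that constant to
# it so all five models share one additive constant.  Absolute log-
# likelihoods may therefore differ from other software by this constant,
# which cancels in every AIC difference.

# Precomputed per-dataset quantities shared by the likelihoods.
.bt_env <- function(bt) {
  bt <- as_branching_times(bt)
  n <- bt$n_tips
  x <- bt$ages
  i <- 2:n                       # lineage count during interval i
  d <- c(x[-length(x)] - x[-1L], x[length(x)])  # durations d_2..d_n
  list(n = n, x = x, i = i, d = d,
       ev = 2:(n - 1L),          # lineage counts at which events occur
       S = sum(i * d),           # total weighted exposure = x_2 + sum(x)
       logC = lgamma(n))         # orderings constant sum_{i=2}^{n-1} ln i
}

.check_rate <- function(r, name = "rate") {
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r <= 0)
    stop("'", name, "' must be a single positive finite number")
}

#' Pure-birth (Yule) log-likelihood
#'
#' Constant-rate birth model with one parameter, the per-lineage speciation
#' rate `lambda`, and extinction set to zero.
#'
#' @param lambda Speciation rate (events per lineage per time unit), > 0.
#' @param bt Branching times ([as_branching_times()] or a tree).
#' @return Log-likelihood in nats.
#' @export
#' @examples
#' loglik_pure_birth(1, as_branching_times(c(2, 1)))  # log(2) - 5
loglik_pure_birth <- function(lambda, bt) {
  .check_rate(lambda, "lambda")
  b <- .bt_env(bt)
  b$logC + (b$n - 2) * log(lambda) - lambda * b$S
}

#' Per-interval-rate pure-birth log-likelihood
#'
#' Shared kernel for the lineage-dependent models (DDL, DDX) and the
#' two-rate shift model: a pure-birth process whose speciation rate is
#' constant within each inter-node interval but may differ between
#' intervals.
#'
#' @param rates Vector of per-lineage rates, one per interval i = 2..n
#'   (length `n_tips - 1`), all > 0.
#' @param bt Branching times.
#' @return Log-likelihood in nats.
#' @export
loglik_rate_per_interval <- function(rates, bt) {
  b <- .bt_env(bt)
  if (length(rates) != b$n - 1L)
    stop("need one rate per interval: expected ", b$n - 1L, ", got ", length(rates))
  if (anyNA(rates) || any(!is.finite(rates)) || any(rates <= 0))
    stop("all rates must be positive and finite")
  sum(log(b$ev * rates[seq_len(b$n - 2L)])) - sum(b$i * rates * b$d)
}

#' Constant-rate birth-death log-likelihood
#'
#' Reconstructed-process likelihood in the (r, a) parameterisation, where
#' r is the net diversification rate and a = mu/lambda the extinction
#' fraction.  The orderings constant is included so that at a = 0 this
#' equals [loglik_pure_birth()] exactly.
#'
#' @param r Net diversification rate, > 0.
#' @param a Extinction fraction in `[0, 1)`.
#' @param bt Branching times.
#' @return Log-likelihood in nats.
#' @export
loglik_birth_death <- function(r, a, bt) {
  .check_rate(r, "r")
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || a < 0 || a >= 1)
    stop("'a' must lie in [0, 1)")
  b <- .bt_env(bt)
  z <- r * b$x
  # ln(e^z - a) = z + log1p(-a e^{-z}), overflow-safe
  b$logC + (b$n - 2) * log(r) + r * sum(b$x[-1L]) + b$n * log1p(-a) -
    2 * sum(z + log1p(-a * exp(-z)))
}

#' Two-rate pure-birth (shift) log-likelihood
#'
#' Speciation proceeds at rate `r1` for ages older than the shift time `st`
#' and at `r2` for younger ages.  A branching event exactly at `st` is
#' attributed to the older regime.
#'
#' @param r1,r2 Per-lineage rates before (older than) and after the shift.
#' @param st Shift time, age before present, inside (0, crown age).
#' @param bt Branching times.
#' @return Log-likelihood in nats.
#' @export
loglik_yule2rate <- function(r1, r2, st, bt) {
  .check_rate(r1, "r1"); .check_rate(r2, "r2")
  b <- .bt_env(bt)
  if (!is.numeric(st) || length(st) != 1L || !is.finite(st) ||
      st <= 0 || st >= b$x[1L])
    stop("'st' must lie strictly inside (0, crown age)")
  sp <- .y2r_split(b, st)
  b$logC + sp$n1 * log(r1) + sp$n2 * log(r2) - r1 * sp$E1 - r2 * sp$E2
}

# Split exposures and event counts at shift age st.
# Events happen at ages x_3..x_n; event at exactly st counts as old.
.y2r_split <- function(b, st) {
  hi <- b$x
  lo <- c(b$x[-1L], 0)
  above <- pmax(0, hi - pmax(lo, st))
  below <- pmax(0, pmin(hi, st) - lo)
  e <- b$x[-1L]                      # event ages
  n1 <- sum(e >= st)
  list(n1 = n1, n2 = length(e) - n1,
       E1 = sum(b$i * above), E2 = sum(b$i * below))
}

#' Density-dependent logistic (DDL) log-likelihood
#'
#' Speciation rate declines linearly with standing diversity:
#' `lambda_i = r1 * (1 - i / k)`, with carrying capacity `k > n_tips`.
#' `k = Inf` is the pure-birth limit.
#'
#' @param r1 Initial speciation rate, > 0.
#' @param k Carrying capacity (lineages), `> n_tips` (may be `Inf`).
#' @param bt Branching times.
#' @return Log-likelihood in nats.
#' @export
loglik_ddl <- function(r1, k, bt) {
  .check_rate(r1, "r1")
  b <- .bt_env(bt)
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k <= b$n)
    stop("'k' must exceed the number of tips (", b$n, ")")
  if (is.infinite(k)) return(loglik_pure_birth(r1, bt))
  loglik_rate_per_interval(r1 * (1 - (2:b$n) / k), bt)
}

#' Density-dependent exponential (DDX) log-likelihood
#'
#' Speciation rate is a power law in standing diversity:
#' `lambda_i = r1 * i^(-x)`.  `x = 0` reduces to pure birth; negative `x`
#' means rates that increase with diversity.
#'
#' @param r1 Rate scale, > 0.
#' @param x Rate-change exponent.
#' @param bt Branching times.
#' @return Log-likelihood in nats.
#' @export
loglik_ddx <- function(r1, x, bt) {
  .check_rate(r1, "r1")
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop("'x' must be a finite number")
  b <- .bt_env(bt)
  loglik_rate_per_interval(r1 * (2:b$n)^(-x), bt)
}

#' Akaike information criterion under two conventions
#'
#' `standard` is the usual AIC = -2 lnL + 2 k.  `table5` is a compatibility
#' convention, AIC = -(2 lnL + 2 k), in which the parameter penalty enters
#' with inverted sign; it is provided because published model-comparison
#' tables in this analysis style print that quantity.  The two conventions
#' always satisfy `aic_standard - aic_table5 = 4 k`.
#'
#' @param lnL Log-likelihood.
#' @param n_params Number of free parameters, >= 1.
#' @param convention `"standard"` (default) or `"table5"`.
#' @return AIC score.
#' @export
#' @examples
#' aic(14.668, 3, "table5")  # -35.336
aic <- function(lnL, n_params, convention = c("standard", "table5")) {
  convention <- match.arg(convention)
  if (!is.numeric(n_params) || n_params < 1)
    stop("'n_params' must be >= 1")
  if (convention == "standard") -2 * lnL + 2 * n_params else -2 * lnL - 2 * n_params
}

.model_fit <- function(model, params, lnL, n_params, note = NULL) {
  structure(list(model = model, params = params, lnL = lnL,
                 n_params = n_params,
                 aic_standard = aic(lnL, n_params, "standard"),
                 aic_table5 = aic(lnL, n_params, "table5"),
                 delta_aic_vs_purebirth = NA_real_,
                 note = note),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("%s fit: lnL = %.4f, k = %d\n", x$model, x$lnL, x$n_params))
  cat("  params:", paste(names(x$params),
                         format(unlist(x$params), digits = 5),
                         sep = " = ", collapse = ", "), "\n")
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Maximum-likelihood pure-birth fit
#'
#' The speciation-rate MLE is available in closed form:
#' `lambda_hat = (n - 2) / sum_i i * d_i`.
#'
#' @param bt Branching times (>= 3 tips).
#' @return A `"model_fit"` object.
#' @export
mle_pure_birth <- function(bt) {
  b <- .bt_env(bt)
  if (b$n < 3L) stop("pure-birth MLE undefined for fewer than 3 tips")
  lam <- (b$n - 2) / b$S
  .model_fit("pureBirth", list(r1 = lam), loglik_pure_birth(lam, bt), 1L)
}

#' Maximum-likelihood constant-rate birth-death fit
#'
#' Bounded maximisation over net rate r > 0 and extinction fraction
#' a in `[0, 1)`, from `nrow(starts)` deterministic starting points plus an
#' explicit evaluation of the a = 0 boundary (where the model collapses to
#' pure birth).  Boundary solutions are reported as such: a fitted
#' `a = 0` with log-likelihood identical to the pure-birth fit is a
#' scientifically meaningful outcome, not a failure.
#'
#' @param bt Branching times.
#' @param starts Optional numeric matrix of starting values with columns
#'   `r` and `a`; defaults to five points spread over log-spaced r.
#' @return A `"model_fit"` object with parameters `r1` and `a`.
#' @export
fit_birth_death <- function(bt, starts = NULL) {
  b <- .bt_env(bt)
  pb <- mle_pure_birth(bt)
  lam <- pb$params$r1
  if (is.null(starts))
    starts <- cbind(r = lam * c(0.25, 0.5, 1, 2, 4),
                    a = c(0.05, 0.2, 0.4, 0.6, 0.8))
  nll <- function(p) {
    r <- exp(p[1L]); a <- p[2L]
    v <- loglik_birth_death(r, a, bt)
    if (!is.finite(v)) 1e10 else -v
  }
  best <- NULL
  fails <- character(0)
  for (j in seq_len(nrow(starts))) {
    res <- tryCatch(
      stats::nlminb(c(log(starts[j, 1L]), starts[j, 2L]), nll,
                    lower = c(-30, 0), upper = c(30, 1 - 1e-9),
                    control = list(rel.tol = 1e-12, iter.max = 500L)),
      error = function(e) conditionMessage(e))
    if (is.character(res)) { fails <- c(fails, res); next }
    if (is.null(best) || res$objective < best$objective) best <- res
  }
  if (is.null(best))
    stop("birth-death optimisation failed from every start: ",
         paste(unique(fails), collapse = "; "))
  lnl_int <- -best$objective
  # a = 0 boundary candidate: profile maximum there is the pure-birth MLE.
  if (pb$lnL >= lnl_int - 1e-9) {
    .model_fit("BD", list(r1 = lam, a = 0), pb$lnL, 2L,
               note = "extinction fraction at the a = 0 boundary; collapses to pure birth")
  } else {
    .model_fit("BD", list(r1 = exp(best$par[1L]), a = best$par[2L]), lnl_int, 2L)
  }
}

# Profile optimiser shared by DDL/DDX: coarse grid scan, then golden-section
# refinement on the bracketing interval.  The rate scale r1 is profiled out
# in closed form, leaving a one-dimensional smooth problem.
.profile_optimize <- function(f, lower, upper, n_grid = 41L) {
  grid <- seq(lower, upper, length.out = n_grid)
  vals <- vapply(grid, f, numeric(1))
  j <- which.max(vals)
  lo <- grid[max(1L, j - 1L)]
  hi <- grid[min(n_grid, j + 1L)]
  opt <- stats::optimize(f, c(lo, hi), maximum = TRUE, tol = 1e-12)
  if (vals[j] > opt$objective) list(par = grid[j], value = vals[j])
  else list(par = opt$maximum, value = opt$objective)
}

#' Maximum-likelihood density-dependent logistic (DDL) fit
#'
#' Maximises over r1 > 0 and carrying capacity k > n_tips.  The search is
#' parameterised in u = 1/k on `[0, 1/n_tips)`, with u = 0 the pure-birth
#' limit; r1 is profiled out in closed form.  When the optimum sits at
#' u = 0 the fit is reported as collapsed to pure birth with `k = Inf`,
#' the supremum of the model family -- the analogue of published fits with
#' astronomically large carrying capacities.
#'
#' @param bt Branching times.
#' @return A `"model_fit"` object with parameters `r1` and `k`.
#' @export
fit_ddl <- function(bt) {
  b <- .bt_env(bt)
  iseq <- 2:b$n
  ev <- seq_len(b$n - 2L)
  prof <- function(u) {
    ci <- 1 - iseq * u
    if (any(ci <= 0)) return(-Inf)
    w <- sum(iseq * ci * b$d)
    r1 <- (b$n - 2) / w
    b$logC + sum(log(ci[ev])) + (b$n - 2) * (log(r1) - 1)
  }
  opt <- .profile_optimize(prof, 0, (1 - 1e-9) / b$n)
  u <- opt$par
  pb <- mle_pure_birth(bt)
  if (u < 1e-10 || pb$lnL >= opt$value - 1e-12) {
    .model_fit("DDL", list(r1 = pb$params$r1, k = Inf), pb$lnL, 2L,
               note = "carrying capacity collapsed to the pure-birth limit (k -> Inf)")
  } else {
    k <- 1 / u
    r1 <- (b$n - 2) / sum(iseq * (1 - iseq / k) * b$d)
    .model_fit("DDL", list(r1 = r1, k = k), opt$value, 2L)
  }
}

#' Maximum-likelihood density-dependent exponential (DDX) fit
#'
#' Maximises over r1 > 0 and the rate-change exponent x in `[-5, 5]`
#' (negative x -- rates increasing with diversity -- is permitted); r1 is
#' profiled out in closed form.
#'
#' @param bt Branching times.
#' @return A `"model_fit"` object with parameters `r1` and `x`.
#' @export
fit_ddx <- function(bt) {
  b <- .bt_env(bt)
  iseq <- 2:b$n
  ev <- seq_len(b$n - 2L)
  sum_log_i_ev <- sum(log(iseq[ev]))
  prof <- function(x) {
    w <- sum(iseq^(1 - x) * b$d)
    if (!is.finite(w) || w <= 0) return(-Inf)
    r1 <- (b$n - 2) / w
    b$logC + (-x) * sum_log_i_ev + (b$n - 2) * (log(r1) - 1)
  }
  opt <- .profile_optimize(prof, -5, 5)
  x <- opt$par
  r1 <- (b$n - 2) / sum(iseq^(1 - x) * b$d)
  note <- if (abs(x) > 5 - 1e-6) "rate-change exponent at the search bound" else NULL
  .model_fit("DDX", list(r1 = r1, x = x), opt$value, 2L, note = note)
}

#' Maximum-likelihood two-rate pure-birth (yule2rate) fit
#'
#' The likelihood is piecewise in the shift time st, so within each piece
#' the optimum is attained by the closed-form segment MLEs of the two
#' rates.  Candidate shift times are the internal branching times together
#' with midpoints of adjacent branching intervals; candidates that leave no
#' event (or no exposure) on one side are skipped, and ties are broken
#' toward the older candidate.
#'
#' @param bt Branching times (>= 4 tips).
#' @return A `"model_fit"` object with parameters `r1`, `r2` and `st`.
#' @export
fit_yule2rate <- function(bt) {
  b <- .bt_env(bt)
  if (b$n < 4L)
    stop("yule2rate needs at least 4 tips (one event on each side of a shift)")
  knots <- c(b$x, 0)
  mids <- (knots[-1L] + knots[-length(knots)]) / 2
  cand <- sort(unique(c(b$x[-1L], mids)), decreasing = TRUE)
  cand <- cand[cand > 0 & cand < b$x[1L]]
  best <- NULL
  for (st in cand) {
    sp <- .y2r_split(b, st)
    if (sp$n1 < 1L || sp$n2 < 1L || sp$E1 <= 0 || sp$E2 <= 0) next
    r1 <- sp$n1 / sp$E1
    r2 <- sp$n2 / sp$E2
    lnl <- b$logC + sp$n1 * (log(r1) - 1) + sp$n2 * (log(r2) - 1)
    if (is.null(best) || lnl > best$lnL + 1e-12)
      best <- list(r1 = r1, r2 = r2, st = st, lnL = lnl)
  }
  if (is.null(best))
    stop("no admissible shift-time candidate; are all branching times tied?")
  .model_fit("yule2rate", list(r1 = best$r1, r2 = best$r2, st = best$st),
             best$lnL, 3L)
}

#' Fit all five diversification models and assemble a comparison table
#'
#' Fits pureBirth, BD, DDL, DDX and yule2rate (in that column order), fills
#' in both AIC conventions and the delta-AIC-versus-pureBirth column, and
#' identifies the best rate-constant model (among pureBirth, BD) and the
#' best rate-variable model (among DDL, DDX, yule2rate) by minimum AIC
#' under the chosen convention.
#'
#' Because the rate-variable models nest pure birth, each optimised
#' log-likelihood must be at least the pure-birth log-likelihood; a
#' violation beyond numerical tolerance signals an optimiser failure and
#' raises an error rather than returning a silently wrong table.
#'
#' @param bt Branching times (>= 4 tips).
#' @param clade_label Label carried through to reports.
#' @param convention AIC convention used for model selection and the
#'   delta-AIC column: `"standard"` (default) or `"table5"`.
#' @return An object of class `"model_comparison_table"`.
#' @export
fit_all_models <- function(bt, clade_label = "",
                           convention = c("standard", "table5")) {
  convention <- match.arg(convention)
  bt <- as_branching_times(bt)
  if (bt$n_tips < 4L) stop("need at least 4 tips to fit all five models")
  fits <- list(pureBirth = mle_pure_birth(bt),
               BD = fit_birth_death(bt),
               DDL = fit_ddl(bt),
               DDX = fit_ddx(bt),
               yule2rate = fit_yule2rate(bt))
  lnl_pb <- fits$pureBirth$lnL
  for (m in names(fits)) {
    if (fits[[m]]$lnL < lnl_pb - 1e-6)
      stop("optimiser failure: ", m, " log-likelihood ", fits[[m]]$lnL,
           " fell below the nested pure-birth value ", lnl_pb)
    fits[[m]]$delta_aic_vs_purebirth <-
      .aic_of(fits[[m]], convention) - .aic_of(fits$pureBirth, convention)
    fits[[m]]$delta_aic_table5 <- fits[[m]]$aic_table5 - fits$pureBirth$aic_table5
    fits[[m]]$delta_aic_standard <- fits[[m]]$aic_standard - fits$pureBirth$aic_standard
  }
  const <- c("pureBirth", "BD")
  variab <- c("DDL", "DDX", "yule2rate")
  aics <- vapply(fits, .aic_of, numeric(1), convention = convention)
  structure(list(clade_label = clade_label,
                 n_tips = bt$n_tips,
                 convention = convention,
                 fits = fits,
                 best_constant = const[which.min(aics[const])],
                 best_variable = variab[which.min(aics[variab])]),
            class = "model_comparison_table")
}

.aic_of <- function(fit, convention) {
  if (convention == "standard") fit$aic_standard else fit$aic_table5
}

#' @export
print.model_comparison_table <- function(x, ...) {
  cat("Diversification model comparison",
      if (nzchar(x$clade_label)) paste0("(", x$clade_label, ")"), "--",
      x$n_tips, "tips,", x$convention, "AIC convention\n")
  print(as.data.frame(x), ...)
  cat("best constant-rate:", x$best_constant,
      "| best rate-variable:", x$best_variable, "\n")
  invisible(x)
}

#' Tabulate a model comparison in the published row layout
#'
#' Rows Parameters / Ln(L) / AIC / dAIC; columns the five models in the
#' order pureBirth, BD, DDL, DDX, yule2rate.  Numeric cells are rounded to
#' 3 decimals; the AIC and dAIC rows follow the table's `convention`.
#'
#' @param x A `"model_comparison_table"`.
#' @param ... Unused.
#' @return A character data frame with row names Parameters, Ln(L), AIC, dAIC.
#' @export
as.data.frame.model_comparison_table <- function(x, ...) {
  models <- c("pureBirth", "BD", "DDL", "DDX", "yule2rate")
  fmt <- function(v) formatC(round(v, 3), format = "fg", digits = 15)
  cols <- lapply(models, function(m) {
    f <- x$fits[[m]]
    pars <- paste(names(f$params), vapply(unlist(f$params), fmt, ""),
                  sep = " = ", collapse = "; ")
    c(Parameters = pars,
      `Ln(L)` = fmt(f$lnL),
      AIC = fmt(.aic_of(f, x$convention)),
      dAIC = fmt(f$delta_aic_vs_purebirth))
  })
  out <- as.data.frame(cols, optional = TRUE)
  names(out) <- models
  out
}

#' Write a model comparison table as TSV
#'
#' @param x A `"model_comparison_table"`.
#' @param file Output path.
#' @export
write_model_table_tsv <- function(x, file) {
  df <- as.data.frame(x)
  df <- cbind(row = rownames(df), df)
  utils::write.table(df, file = file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Serialise a model comparison table to structured JSON
#'
#' Full-precision values plus metadata (AIC convention, optimiser notes).
#'
#' @param x A `"model_comparison_table"`.
#' @param file Optional output path; if `NULL` the JSON string is returned.
#' @return JSON string, invisibly when written to file.
#' @export
model_table_json <- function(x, file = NULL) {
  payload <- list(
    clade_label = x$clade_label,
    n_tips = x$n_tips,
    convention = x$convention,
    note = paste("table5 AIC convention is -(2 lnL + 2 k); standard is",
                 "-2 lnL + 2 k; log-likelihoods include the orderings",
                 "constant shared across all five models"),
    best_constant = x$best_constant,
    best_variable = x$best_variable,
    fits = lapply(x$fits, function(f)
      list(model = f$model, params = f$params, lnL = f$lnL,
           n_params = f$n_params, aic_standard = f$aic_standard,
           aic_table5 = f$aic_table5,
           delta_aic_vs_purebirth = f$delta_aic_vs_purebirth,
           note = f$note)))
  s <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(file)) return(s)
  writeLines(s, file)
  invisible(s)
}
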