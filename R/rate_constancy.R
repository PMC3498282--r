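# The rate-constancy test: contrast the best rate-constant model's AIC with
# the best rate-variable model's AIC, and calibrate the statistic against a
# simulated pure-birth null distribution matched on tip count and
# pure-birth rate estimate.

#' Rate-constancy statistic from a fitted model comparison
#'
#' The statistic is `aic_rc - aic_rv`, where `aic_rc` is the AIC of the
#' best-fitting rate-constant model (pureBirth or BD) and `aic_rv` that of
#' the best-fitting rate-variable model (DDL, DDX or yule2rate), both
#' selected by minimum AIC under the stated convention.  A positive value
#' indicates that a rate-variable model better approximates the data.
#'
#' @param table A complete `"model_comparison_table"` from [fit_all_models()].
#' @param convention AIC convention; defaults to the one stored in `table`.
#' @return An object of class `"rate_constancy"` holding the statistic and
#'   the provenance of the selected models (no null sample / p-value yet;
#'   see [test_rate_constancy()]).
#' @export
delta_aic_rc <- function(table, convention = NULL) {
  if (!inherits(table, "model_comparison_table"))
    stop("'table' must be a model_comparison_table from fit_all_models()")
  models <- c("pureBirth", "BD", "DDL", "DDX", "yule2rate")
  if (!identical(sort(names(table$fits)), sort(models)) ||
      any(vapply(table$fits, function(f) !is.finite(f$lnL), logical(1))))
    stop("incomplete model comparison table: need finite fits for all five models")
  if (is.null(convention)) convention <- table$convention
  convention <- match.arg(convention, c("standard", "table5"))
  aics <- vapply(table$fits[models], .aic_of, numeric(1), convention = convention)
  const <- c("pureBirth", "BD")
  variab <- c("DDL", "DDX", "yule2rate")
  bc <- const[which.min(aics[const])]
  bv <- variab[which.min(aics[variab])]
  structure(list(aic_rc = unname(aics[bc]),
                 aic_rv = unname(aics[bv]),
                 delta_aic_rc = unname(aics[bc] - aics[bv]),
                 best_constant = bc,
                 best_variable = bv,
                 convention = convention,
                 n_tips = table$n_tips,
                 clade_label = table$clade_label),
            class = "rate_constancy")
}

#' Simulated pure-birth null distribution of the rate-constancy statistic
#'
#' For each replicate, a pure-birth tree conditioned on `n_tips` is drawn at
#' rate `lambda_hat` (the pure-birth MLE of the observed data), all five
#' models are fitted, and the rate-constancy statistic is recorded.  A
#' replicate whose fits fail is rejected and resampled; more than 1% failed
#' replicates raises an error.
#'
#' The default number of replicates for a full analysis is 9000 (see
#' [test_rate_constancy()]); smaller values are appropriate for exploratory
#' runs.  The statistic is invariant to time rescaling, so conditioning the
#' null on tip count alone (crown ages vary across replicates) suffices.
#'
#' @param n_tips Number of tips (>= 4).
#' @param lambda_hat Pure-birth speciation rate for the simulations, > 0.
#' @param n_reps Number of null replicates, >= 1.
#' @param seed Optional integer seed (set once for the whole sample).
#' @param convention AIC convention for the statistic.
#' @return A list with `values` (numeric vector of length `n_reps`),
#'   `n_failures` (resampled replicates) and the simulation settings.
#' @export
simulate_null <- function(n_tips, lambda_hat, n_reps = 9000L, seed = NULL,
                          convention = c("standard", "table5")) {
  convention <- match.arg(convention)
  if (n_tips < 4L) stop("'n_tips' must be >= 4")
  .check_rate(lambda_hat, "lambda_hat")
  if (n_reps < 1L) stop("'n_reps' must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  values <- numeric(n_reps)
  n_fail <- 0L
  max_fail <- max(1L, ceiling(0.01 * n_reps))
  for (rep in seq_len(n_reps)) {
    repeat {
      bt <- as_branching_times(sim_yule_ages(n_tips, lambda_hat))
      stat <- tryCatch(
        delta_aic_rc(fit_all_models(bt, convention = convention))$delta_aic_rc,
        error = function(e) NULL)
      if (!is.null(stat)) break
      n_fail <- n_fail + 1L
      if (n_fail > max_fail)
        stop("more than 1% of null replicates failed to fit (",
             n_fail, " failures); aborting")
    }
    values[rep] <- stat
  }
  list(values = values, n_failures = n_fail, n_reps = n_reps,
       n_tips = n_tips, lambda_hat = lambda_hat, seed = seed,
       convention = convention)
}

#' Rate-constancy test against a simulated pure-birth null
#'
#' Combines [fit_all_models()], [delta_aic_rc()] and [simulate_null()] (with
#' the pure-birth MLE and tip count of the observed data) into a full test.
#' The p-value is the one-sided upper tail with the add-one estimator,
#' `(1 + #{null >= observed}) / (n_reps + 1)`, so it is never exactly zero
#' at finite replicates.
#'
#' @param bt Branching times (or tree) of the observed clade.
#' @param n_reps Null replicates; 9000 by default.
#' @param seed Optional integer seed for the null simulation.
#' @param convention AIC convention.
#' @return An object of class `"rate_constancy"` with the observed
#'   statistic, selected models, null sample, p-value, and settings.
#' @export
test_rate_constancy <- function(bt, n_reps = 9000L, seed = NULL,
                                convention = c("standard", "table5")) {
  convention <- match.arg(convention)
  bt <- branching_times(bt)
  tab <- fit_all_models(bt, convention = convention)
  obs <- delta_aic_rc(tab)
  lam <- tab$fits$pureBirth$params$r1
  null <- simulate_null(bt$n_tips, lam, n_reps = n_reps, seed = seed,
                        convention = convention)
  obs$lambda_hat <- lam
  obs$null_sample <- null$values
  obs$n_null_failures <- null$n_failures
  obs$n_reps <- n_reps
  obs$seed <- seed
  obs$p_value <- (1 + sum(null$values >= obs$delta_aic_rc)) / (n_reps + 1)
  obs$table <- tab
  obs
}

#' @export
print.rate_constancy <- function(x, ...) {
  cat("Rate-constancy test (", x$convention, " AIC convention)\n", sep = "")
  cat(sprintf("  best constant-rate:  %s (AIC %.4f)\n", x$best_constant, x$aic_rc))
  cat(sprintf("  best rate-variable:  %s (AIC %.4f)\n", x$best_variable, x$aic_rv))
  cat(sprintf("  delta AIC (RC - RV): %.4f\n", x$delta_aic_rc))
  if (!is.null(x$p_value))
    cat(sprintf("  p (upper tail, %d null reps): %.4g\n", x$n_reps, x$p_value))
  invisible(x)
}

#' Serialise a rate-constancy result to JSON
#'
#' The null sample itself is summarised (quantiles) unless
#' `include_null = TRUE`; use [write_null_tsv()] for a full dump.
#'
#' @param x A `"rate_constancy"` object.
#' @param file Optional output path.
#' @param include_null Include the full null sample in the JSON.
#' @return JSON string, invisibly when written to file.
#' @export
rate_constancy_json <- function(x, file = NULL, include_null = FALSE) {
  payload <- list(
    clade_label = x$clade_label,
    n_tips = x$n_tips,
    convention = x$convention,
    best_constant = x$best_constant,
    best_variable = x$best_variable,
    aic_rc = x$aic_rc,
    aic_rv = x$aic_rv,
    delta_aic_rc = x$delta_aic_rc,
    lambda_hat = x$lambda_hat,
    p_value = x$p_value,
    n_reps = x$n_reps,
    seed = x$seed,
    n_null_failures = x$n_null_failures,
    null_quantiles = if (!is.null(x$null_sample))
      as.list(stats::quantile(x$null_sample, c(0.5, 0.9, 0.95, 0.99))))
  if (include_null) payload$null_sample <- x$null_sample
  s <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(file)) return(s)
  writeLines(s, file)
  invisible(s)
}

#' Dump a null sample as a one-column TSV (for plotting)
#'
#' @param x A `"rate_constancy"` object with a null sample.
#' @param file Output path.
#' @export
write_null_tsv <- function(x, file) {
  if (is.null(x$null_sample)) stop("no null sample in this result")
  utils::write.table(data.frame(delta_aic_rc = x$null_sample), file,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
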