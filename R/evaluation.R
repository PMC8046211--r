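#' Mean squared prediction error on the original scale
#'
#' `MSE = (1/n) sum_ij (y_ij - yhat_ij)^2`.
#'
#' @param y observed original-scale responses.
#' @param yhat predictions (same length).
#' @return Scalar MSE.
#' @export
mse <- function(y, yhat) {
  if (length(y) == 0L) validation_error("empty response vector")
  if (length(y) != length(yhat)) {
    validation_error("y and yhat must have the same length")
  }
  mean((y - yhat)^2)
}

#' Replication study of original-scale prediction error
#'
#' For each scenario and replicate: generate a dataset, fit the log-scale
#' heteroscedastic random-intercept model (regardless of the generating
#' family), predict the original-scale response under every requested
#' correction method, and compute the MSE against the generated `y`.
#' Results are aggregated per scenario as the mean and standard deviation of
#' the per-replicate MSE. Replicates whose fit fails are dropped and
#' counted, never imputed. The whole study is reproducible from the master
#' seed: each scenario gets a derived seed, and each replicate within it a
#' further derived seed, so runs are independent of evaluation order.
#'
#' @param scenarios a [scenario_config()] or list of them.
#' @param methods subset of [correction_methods()].
#' @param reps number of replicates per scenario (>= 2).
#' @param seed master seed for the whole study.
#' @param fit_method `"REML"` (default) or `"ML"`, passed to [fit_rim()].
#' @return A data frame of class `mse_table`: one row per scenario with the
#'   scenario descriptors, `mse_mean_<method>` and `mse_sd_<method>` columns
#'   in canonical method order, the replicate count `reps`, and the number
#'   of dropped replicates `n_failed`. Attribute `seeds` records the
#'   per-scenario derived seeds; attribute `mse` keeps the per-replicate MSE
#'   matrices.
#' @export
run_study <- function(scenarios, methods = correction_methods(), reps = 100L,
                      seed = 1L, fit_method = "REML") {
  if (inherits(scenarios, "scenario_config")) scenarios <- list(scenarios)
  if (reps < 2) config_error("reps must be >= 2")
  methods <- intersect(correction_methods(), methods)
  if (length(methods) == 0L) config_error("no valid correction method requested")
  scen_seeds <- derive_seeds(seed, length(scenarios))
  rows <- vector("list", length(scenarios))
  per_rep <- vector("list", length(scenarios))
  for (s in seq_along(scenarios)) {
    cfg <- scenarios[[s]]
    stopifnot(inherits(cfg, "scenario_config"))
    cfg$seed <- scen_seeds[s]
    msem <- matrix(NA_real_, reps, length(methods),
                   dimnames = list(NULL, methods))
    failed <- 0L
    for (r in seq_len(reps)) {
      data <- generate_scenario(cfg, replicate = r)
      fit <- tryCatch(fit_rim(data, method = fit_method),
                      error = function(e) NULL)
      if (is.null(fit)) {
        failed <- failed + 1L
        next
      }
      for (mm in methods) {
        pred <- predict_rim(fit, data, method = mm)
        msem[r, mm] <- mse(data$y, pred$pred)
      }
    }
    row <- data.frame(scenario = cfg$label, family = cfg$family, m = cfg$m,
                      n = sum(cfg$n_i),
                      n_i = if (length(unique(cfg$n_i)) == 1L) {
                        as.character(cfg$n_i[1])
                      } else {
                        sprintf("%d..%d", min(cfg$n_i), max(cfg$n_i))
                      },
                      sigma2 = cfg$sigma2, sigma_gamma2 = cfg$sigma_gamma2,
                      alpha = if (cfg$family == "gamma") cfg$alpha else NA_real_,
                      stringsAsFactors = FALSE)
    ok <- stats::complete.cases(msem)
    for (mm in methods) {
      row[[paste0("mse_mean_", mm)]] <- if (any(ok)) mean(msem[ok, mm]) else NA_real_
      row[[paste0("mse_sd_", mm)]] <- if (sum(ok) > 1) stats::sd(msem[ok, mm]) else NA_real_
    }
    row$reps <- reps
    row$n_failed <- failed
    rows[[s]] <- row
    per_rep[[s]] <- msem
  }
  out <- do.call(rbind, rows)
  structure(out, seeds = scen_seeds, mse = per_rep, master_seed = seed,
            class = c("mse_table", "data.frame"))
}

#' @export
print.mse_table <- function(x, digits = 3, ...) {
  cat(sprintf("MSE study: %d scenario(s), %d replicate(s), master seed %s\n",
              nrow(x), x$reps[1], format(attr(x, "master_seed"))))
  methods <- sub("^mse_mean_", "", grep("^mse_mean_", names(x), value = TRUE))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %s%s\n", x$scenario[i],
                if (x$n_failed[i] > 0) sprintf("  [%d failed fit(s) dropped]", x$n_failed[i]) else ""))
    for (mm in methods) {
      cat(sprintf("    %-16s %s (%s)\n", mm,
                  format(x[[paste0("mse_mean_", mm)]][i], digits = digits),
                  format(x[[paste0("mse_sd_", mm)]][i], digits = digits)))
    }
  }
  invisible(x)
}

#' Write an MSE study table to CSV
#'
#' @param table an `mse_table` from [run_study()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_mse_table <- function(table, path) {
  stopifnot(inherits(table, "mse_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}
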