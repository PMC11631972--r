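#' Monte-Carlo simulation design
#'
#' Describes one simulation study: for each sample size and each
#' indeterminacy endpoint, `reps` samples are drawn from the NeS-BrIII
#' distribution at that endpoint's true parameters and refitted by maximum
#' likelihood.  Defaults mirror the published design (sample sizes 30, 50,
#' 100, 200, 300; 5000 replicates in the source study, 500 at desk scale).
#'
#' `lambda` and `theta` may be scalars (same truth at both endpoints) or
#' length-2 vectors `c(lower, upper)`.
#'
#' @param lambda,theta true shape parameters per endpoint.
#' @param indet [indet_interval()] whose endpoints define the two cells.
#' @param n_values vector of sample sizes.
#' @param reps replicates per cell (>= 1); the published study uses 5000.
#' @param seed integer seed for the counter-based per-replicate stream.
#' @return an object of class `sim_design`.
#' @export
sim_design <- function(lambda, theta, indet = indet_interval(0, 0.05),
                       n_values = c(30, 50, 100, 200, 300), reps = 500L,
                       seed = 20240511L) {
  stopifnot(length(n_values) >= 1L, reps >= 1L)
  lambda <- rep_len(as.numeric(lambda), 2L)
  theta <- rep_len(as.numeric(theta), 2L)
  I <- as_indet(indet)
  check_params(lambda, theta, unclass(I))
  structure(list(lambda = lambda, theta = theta, indet = I,
                 n_values = as.integer(n_values), reps = as.integer(reps),
                 seed = as.integer(seed)),
            class = "sim_design")
}

## per-replicate seed, derived from a counter so every cell/replicate is
## independently reproducible; kept below 2^31 - 1
replicate_seed <- function(seed, cell, rep)
  (abs(seed) + 104729 * cell + rep) %% 2147483629L + 1L

## internal aggregator: AE = mean(est), Bias = AE - truth,
## MSE = mean((est - truth)^2)  -- exactly the published estimator formulas
sim_aggregate <- function(est, truth) {
  c(ae = mean(est), bias = mean(est) - truth,
    mse = mean((est - truth)^2))
}

#' Run a Monte-Carlo simulation study
#'
#' For every cell (sample size x indeterminacy endpoint) draws `design$reps`
#' samples with [rnesbr3()], refits each with [fit_burr3()] at the same
#' fixed indeterminacy, and aggregates average estimates (AE), biases and
#' MSEs per parameter.  Failed fits are excluded from the aggregates and
#' counted in `n_fail`.  The run is fully reproducible from `design$seed`.
#'
#' @param design a [sim_design()].
#' @param keep_estimates if `TRUE`, attach the raw per-replicate estimates
#'   (used by the variance-decomposition identity check).
#' @return an object of class `sim_summary`: data.frame with one row per
#'   (n, endpoint, parameter) and columns `ae`, `bias`, `mse`, `n_fail`.
#' @export
run_simulation <- function(design, keep_estimates = FALSE) {
  stopifnot(inherits(design, "sim_design"))
  endpoints <- c("lower", "upper")
  rows <- list()
  est_store <- list()
  cell <- 0L
  opts <- fit_opts(starts = "light")
  for (ni in seq_along(design$n_values)) {
    n <- design$n_values[ni]
    for (ei in 1:2) {
      cell <- cell + 1L
      lam <- design$lambda[ei]; th <- design$theta[ei]
      I <- unclass(design$indet)[ei]
      est <- matrix(NA_real_, design$reps, 2L,
                    dimnames = list(NULL, c("lambda", "theta")))
      for (r in seq_len(design$reps)) {
        set.seed(replicate_seed(design$seed, cell, r))
        x <- rnesbr3(n, lam, th, I)
        f <- tryCatch(suppressWarnings(fit_burr3(x, indet = I, opts = opts)),
                      error = function(e) NULL)
        if (!is.null(f) && f$converged) est[r, ] <- f$estimates
      }
      ok <- stats::complete.cases(est)
      n_fail <- sum(!ok)
      if (!any(ok)) {
        rows[[length(rows) + 1L]] <-
          data.frame(n = n, endpoint = endpoints[ei],
                     parameter = c("lambda", "theta"), truth = c(lam, th),
                     ae = NA_real_, bias = NA_real_, mse = NA_real_,
                     n_fail = n_fail, all_failed = TRUE)
        next
      }
      agg_l <- sim_aggregate(est[ok, "lambda"], lam)
      agg_t <- sim_aggregate(est[ok, "theta"], th)
      rows[[length(rows) + 1L]] <-
        data.frame(n = n, endpoint = endpoints[ei],
                   parameter = c("lambda", "theta"), truth = c(lam, th),
                   ae = c(agg_l["ae"], agg_t["ae"]),
                   bias = c(agg_l["bias"], agg_t["bias"]),
                   mse = c(agg_l["mse"], agg_t["mse"]),
                   n_fail = n_fail, all_failed = FALSE)
      if (keep_estimates)
        est_store[[paste(n, endpoints[ei], sep = "_")]] <- est[ok, ,
                                                               drop = FALSE]
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("sim_summary", "data.frame")
  attr(out, "design") <- design
  if (keep_estimates) attr(out, "estimates") <- est_store
  out
}

#' Reshape a simulation summary into the published table layout
#'
#' One row per sample size; columns AE/Bias/MSE per parameter per endpoint
#' (2 parameters x 3 statistics x 2 endpoints = 12 value columns).
#'
#' @param summary a `sim_summary` from [run_simulation()].
#' @param path optional output file; written as CSV (or JSON if `format` is
#'   `"json"`).
#' @param format `"csv"` or `"json"` (used only when `path` is given).
#' @return the wide data.frame, invisibly if written to `path`.
#' @export
summarize_to_table <- function(summary, path = NULL,
                               format = c("csv", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(summary, "sim_summary") || is.data.frame(summary),
            nrow(summary) > 0L)
  wide <- NULL
  for (stat in c("ae", "bias", "mse")) {
    for (ep in c("lower", "upper")) {
      for (par in c("lambda", "theta")) {
        sub <- summary[summary$endpoint == ep & summary$parameter == par, ]
        col <- setNames(data.frame(sub$n, sub[[stat]]),
                        c("n", paste(stat, par, ep, sep = "_")))
        wide <- if (is.null(wide)) col else merge(wide, col, by = "n")
      }
    }
  }
  wide <- wide[order(wide$n), , drop = FALSE]
  rownames(wide) <- NULL
  if (!is.null(path)) {
    if (format == "csv") write.csv(wide, path, row.names = FALSE)
    else jsonlite::write_json(wide, path, dataframe = "rows", digits = NA)
    return(invisible(wide))
  }
  wide
}
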