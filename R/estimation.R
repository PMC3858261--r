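# Weighted least-squares parameter estimation with multistart local
# optimization. Parameters are optimized in log10 space (they are all
# strictly positive and span ten orders of magnitude); each start is a
# bound-constrained Levenberg-Marquardt run.

.gene_variables <- c("rex1", "fgf5", "dppa3")
.observable_variables <- c("x_v", "glc", "gln", "lac", "amm", .gene_variables)

.model_observables <- function(traj) {
  traj |>
    dplyr::mutate(x_v = .data$x_u + .data$x_d) |>
    as_tibble() |>
    dplyr::select("time_h", dplyr::all_of(.observable_variables))
}

# Per-observation residual scales: replicate SD when available, else 10%
# of the variable's range in the dataset. Gene fold changes are compared
# on the log scale; their SDs transfer by the delta method (sd/value).
.residual_table <- function(data) {
  stopifnot(nrow(data) > 0, all(c("time_h", "variable", "value") %in% names(data)))
  bad <- setdiff(unique(data$variable), .observable_variables)
  if (length(bad) > 0) {
    stop("variables with no model observable: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!"sd" %in% names(data)) data$sd <- NA_real_
  data |>
    dplyr::mutate(is_gene = .data$variable %in% .gene_variables,
                  obs = ifelse(.data$is_gene, log(pmax(.data$value, 1e-12)),
                               .data$value),
                  sd_t = ifelse(.data$is_gene, .data$sd / pmax(.data$value, 1e-12),
                                .data$sd)) |>
    dplyr::group_by(.data$variable) |>
    dplyr::mutate(
      range_scale = {
        r <- diff(range(.data$obs))
        0.1 * ifelse(r > 0, r, pmax(abs(.data$obs), 1))
      },
      scale = ifelse(is.finite(.data$sd_t) & .data$sd_t > 0,
                     .data$sd_t, .data$range_scale)
    ) |>
    dplyr::ungroup()
}

.residuals_for <- function(values, resid_tab, reactor, initial, rtol, atol) {
  times <- sort(unique(resid_tab$time_h))
  traj <- simulate_culture(initial, values, reactor,
                           horizon = max(times, 1), times = times,
                           rtol = rtol, atol = atol)
  obs <- .model_observables(traj)
  i <- match(resid_tab$time_h, obs$time_h)
  model <- as.numeric(as.matrix(obs[, -1])[cbind(
    i, match(resid_tab$variable, .observable_variables))])
  model_t <- ifelse(resid_tab$is_gene, log(pmax(model, 1e-12)), model)
  (model_t - resid_tab$obs) / resid_tab$scale
}

#' Weighted least-squares objective
#'
#' Sum over observations of squared scaled residuals between the model
#' trajectory and a tidy dataset. The scale of each residual is the
#' replicate SD where the dataset provides one, otherwise 10% of the
#' variable's observed range; gene fold changes are compared on the log
#' scale. The objective is invariant to observation order.
#'
#' @param params Parameter tibble or named vector.
#' @param data Tidy observations: columns `time_h`, `variable`, `value`,
#'   optionally `sd`, `replicate`, `assay`. Variables must map to model
#'   observables (`x_v`, `glc`, `gln`, `lac`, `amm`, `rex1`, `fgf5`,
#'   `dppa3`).
#' @param reactor A `reactor_config`.
#' @param initial Initial culture state.
#' @param rtol,atol Solver tolerances used inside the objective.
#' @return Scalar objective value.
#' @export
fit_objective <- function(params, data, reactor = reactor_batch(),
                          initial = initial_state(),
                          rtol = 1e-7, atol = 1e-9) {
  resid_tab <- .residual_table(data)
  sum(.residuals_for(param_values(params), resid_tab, reactor, initial,
                     rtol, atol)^2)
}

#' Fit model parameters to time-series data
#'
#' Bound-constrained weighted least squares on the free parameter subset,
#' in log10 space, with multistart: the supplied values plus `n_starts`
#' log-uniform draws within the bounds, each refined by
#' Levenberg-Marquardt ([minpack.lm::nls.lm()]). Deterministic given
#' `seed`.
#'
#' @param data Tidy observations (see [fit_objective()]).
#' @param reactor A `reactor_config`.
#' @param free Character vector of parameter names to estimate; the rest
#'   stay fixed at `start` values. Empty set returns `start` unchanged
#'   with its objective.
#' @param start Parameter tibble holding fixed values, starting values and
#'   bounds.
#' @param n_starts Number of random multistart draws (in addition to the
#'   supplied start).
#' @param seed RNG seed for the multistart draws.
#' @param initial Initial culture state.
#' @param rtol,atol Solver tolerances used inside the objective.
#' @param control Control list passed to [minpack.lm::nls.lm()]. The
#'   default sets `epsfcn` so that finite-difference Jacobian steps stay
#'   above the ODE solver's noise floor; with the machine-epsilon default
#'   the optimizer stalls on integration noise.
#' @return An object of class `mesc_fit`: fitted parameter table,
#'   objective, approximate standard errors, and the multistart table.
#' @examples
#' \donttest{
#' truth <- mesc_parameters()
#' quiet <- assay_noise_model(cell_count_cv = 0, nutrient_cv = 0,
#'                            nutrient_sd_floor = 0, qpcr_cv = 0,
#'                            replicates = 1)
#' data <- generate_dataset(truth, noise = quiet, seed = 1)
#' fit <- fit_parameters(data, free = c("Y_LACGLC", "Y_AMMGLN"),
#'                       n_starts = 2, seed = 1)
#' tidy(fit)
#' }
#' @export
fit_parameters <- function(data, reactor = reactor_batch(), free,
                           start = mesc_parameters(), n_starts = 25,
                           seed = 1, initial = initial_state(),
                           rtol = 1e-7, atol = 1e-9,
                           control = minpack.lm::nls.lm.control(
                             maxiter = 100, epsfcn = 1e-6)) {
  validate_parameters(start)
  stopifnot(is.character(free), all(free %in% start$name))
  resid_tab <- .residual_table(data)
  values <- param_values(start)

  if (length(free) == 0) {
    obj <- sum(.residuals_for(values, resid_tab, reactor, initial, rtol, atol)^2)
    return(new_mesc_fit(start, free, obj,
                        tibble(start_id = integer(), objective = numeric(),
                               converged = logical()),
                        std_errors = stats::setNames(numeric(0), character(0)),
                        n_obs = nrow(resid_tab)))
  }

  idx <- match(free, names(values))
  lower <- log10(start$lower[match(free, start$name)])
  upper <- log10(start$upper[match(free, start$name)])

  resid_fn <- function(theta) {
    v <- values
    v[idx] <- 10^theta
    tryCatch(
      .residuals_for(v, resid_tab, reactor, initial, rtol, atol),
      error = function(e) rep(1e6, nrow(resid_tab))
    )
  }

  starts <- matrix(log10(values[idx]), nrow = 1)
  if (n_starts > 0) {
    old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    draws <- matrix(stats::runif(n_starts * length(free), lower, upper),
                    ncol = length(free), byrow = TRUE)
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
    starts <- rbind(starts, draws)
  }

  runs <- purrr::map(seq_len(nrow(starts)), function(s) {
    res <- tryCatch(
      minpack.lm::nls.lm(par = starts[s, ], lower = lower, upper = upper,
                         fn = resid_fn, control = control),
      error = function(e) NULL
    )
    if (is.null(res)) {
      list(objective = Inf, theta = starts[s, ], converged = FALSE, fit = NULL)
    } else {
      list(objective = res$deviance, theta = res$par,
           converged = res$info %in% 1:4, fit = res)
    }
  })

  objectives <- purrr::map_dbl(runs, "objective")
  if (all(!is.finite(objectives))) {
    stop("all multistart optimizations failed", call. = FALSE)
  }
  best <- runs[[which.min(objectives)]]

  fitted <- start
  fi <- match(free, fitted$name)
  # log-scale round-trip can overshoot a bound by round-off
  fitted$value[fi] <- pmin(pmax(10^best$theta, fitted$lower[fi]),
                           fitted$upper[fi])
  fitted$free <- fitted$name %in% free

  se <- stats::setNames(rep(NA_real_, length(free)), free)
  if (!is.null(best$fit)) {
    se_log <- tryCatch(
      unname(summary(best$fit)$coefficients[, "Std. Error"]),
      error = function(e) rep(NA_real_, length(free))
    )
    # delta method from log10 scale to natural scale
    se <- stats::setNames(10^best$theta * log(10) * se_log, free)
  }

  multistart <- tibble(
    start_id = seq_along(runs),
    objective = objectives,
    converged = purrr::map_lgl(runs, "converged")
  )

  new_mesc_fit(fitted, free, min(objectives), multistart, se,
               n_obs = nrow(resid_tab))
}

new_mesc_fit <- function(parameters, free, objective, multistart,
                         std_errors, n_obs) {
  structure(
    list(parameters = parameters, free = free, objective = objective,
         multistart = multistart, std_errors = std_errors, n_obs = n_obs),
    class = "mesc_fit"
  )
}

#' Two-stage perfusion re-estimation
#'
#' Implements the partitioned workflow: parameters deemed insignificant by
#' the sensitivity analysis keep their batch estimates; only the
#' significant subset is re-estimated against perfusion data.
#'
#' @param batch_fit A `mesc_fit` from the batch stage (or a parameter
#'   tibble of batch estimates).
#' @param perfusion_data Tidy perfusion observations.
#' @param significant Names of the parameters to re-estimate (defaults to
#'   the shipped six-parameter subset).
#' @param reactor Perfusion `reactor_config`.
#' @param ... Passed to [fit_parameters()].
#' @return A `mesc_fit` for the perfusion stage.
#' @export
refit_significant <- function(batch_fit, perfusion_data,
                              significant = significant_parameters(),
                              reactor = reactor_perfusion(), ...) {
  start <- if (inherits(batch_fit, "mesc_fit")) batch_fit$parameters else batch_fit
  if (length(significant) == 0) {
    return(new_mesc_fit(start, character(0),
                        fit_objective(start, perfusion_data, reactor),
                        tibble(start_id = integer(), objective = numeric(),
                               converged = logical()),
                        stats::setNames(numeric(0), character(0)),
                        n_obs = nrow(perfusion_data)))
  }
  fit_parameters(perfusion_data, reactor, free = significant,
                 start = start, ...)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @export
tidy.mesc_fit <- function(x, ...) {
  out <- x$parameters |>
    dplyr::select("name", "value", "unit", "free") |>
    dplyr::rename(term = "name", estimate = "value")
  out$std.error <- unname(x$std_errors[out$term])
  out
}

#' @export
glance.mesc_fit <- function(x, ...) {
  tibble(
    objective = x$objective,
    n_obs = x$n_obs,
    n_free = length(x$free),
    n_starts = nrow(x$multistart),
    n_converged = sum(x$multistart$converged)
  )
}

#' @export
print.mesc_fit <- function(x, ...) {
  cat("<mesc_fit>", length(x$free), "free parameters,",
      x$n_obs, "observations\n")
  cat("  objective:", format(x$objective, digits = 6), "\n")
  if (length(x$free) > 0) {
    est <- x$parameters$value[match(x$free, x$parameters$name)]
    cat("  estimates:",
        paste(sprintf("%s=%.4g", x$free, est), collapse = ", "), "\n")
  }
  invisible(x)
}
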