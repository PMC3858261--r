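# Trajectory integration. The ODE system is stiff on the hourly time base
# of the shipped parameter tables and has one switching discontinuity (the
# transfer direction reverses where Rex1 crosses its reference; the flux
# itself vanishes there, so the right-hand side is continuous with a kink)
# and, in fed-batch mode, solute reset events at each medium exchange.
# Integration restarts at root-located switch times and at exchange times
# so the solver never steps across either.

.build_parms <- function(params, reactor, rex_reference) {
  v <- param_values(params)
  c(unname(v),
    reactor$n_bead, dilution_rate(reactor),
    unname(reactor$inlet[c("GLC", "GLN", "LAC", "AMM")]),
    rex_reference)
}

# Fast R closure mirroring the compiled derivatives, for engine = "r".
.make_r_rhs <- function(parms) {
  p <- stats::setNames(parms[seq_along(.param_names)], .param_names)
  n_bead <- parms[30]; dil <- parms[31]
  inlet <- parms[32:35]; ref <- parms[36]
  n_hill <- .stress_hill_n
  function(t, y, ...) {
    y <- pmax(y, 0)
    x_u <- y[1]; x_d <- y[2]; glc <- y[3]; gln <- y[4]
    lac <- y[5]; amm <- y[6]; rex <- y[7]; fgf <- y[8]; dppa <- y[9]
    x_v <- x_u + x_d
    r <- p[["K_Diff"]] * abs(ref - rex)
    flux <- if (rex < ref) r * x_u else -r * x_d
    s_glc <- max(glc - p[["GLC_MIN"]], 0)
    q_glc <- p[["K_GLC_MAX"]] * s_glc / (p[["Kx_GLC"]] + s_glc) * x_v * n_bead
    q_gln <- p[["K_GLN_MAX"]] * gln / (p[["Kx_GLN"]] + gln) * x_v * n_bead
    s_lac <- max(lac - p[["LAC_MIN"]], 0)
    s_amm <- max(amm - p[["AMM_MIN"]], 0)
    list(c(
      (p[["mu_max_U"]] * glc / (p[["Kglc_U"]] + glc) -
         p[["mud_max_U"]] * lac / (p[["Kdlac_U"]] + lac)) * x_u - flux,
      (p[["mu_max_D"]] * glc / (p[["Kglc_D"]] + glc) -
         p[["mud_max_D"]] * lac / (p[["Kdlac_D"]] + lac)) * x_d + flux,
      -q_glc + dil * (inlet[1] - glc),
      -q_gln - p[["K_D_GLN"]] * gln + dil * (inlet[2] - gln),
      p[["Y_LACGLC"]] * q_glc + dil * (inlet[3] - lac),
      p[["Y_AMMGLN"]] * q_gln + dil * (inlet[4] - amm),
      p[["b_REX1"]] / (1 + (s_lac / p[["K_LAC_REX"]])^n_hill) - p[["a_REX"]] * rex,
      p[["b_FGF"]] * (s_lac / (p[["K_LAC_FGF"]] + s_lac)) *
        (fgf / (p[["K_FGF"]] + fgf)) - p[["alpha_FGF"]] * fgf,
      p[["b_DPPA"]] / (1 + (s_amm / p[["K_AMM_DPPA"]])^n_hill) -
        p[["alpha_DPPA"]] * dppa
    ))
  }
}

# Integrate one exchange-free span [t0, t1], restarting at Rex1-reference
# roots. Returns rows at the requested output times plus switch times found.
.integrate_span <- function(y0, t0, t1, out_times, parms, rtol, atol,
                            engine, max_switches = 1000L) {
  ref <- parms[36]
  rows <- NULL
  switches <- numeric(0)
  r_rhs <- if (engine == "r") .make_r_rhs(parms) else NULL
  r_root <- function(t, y, ...) y[7] - ref
  for (k in seq_len(max_switches)) {
    # Starting exactly on the switching surface stalls root detection;
    # take a short plain step off it first.
    if (abs(y0[7] - ref) < 1e-12 && t1 - t0 > 1e-6) {
      t_off <- min(t0 + 1e-3, t1)
      sol0 <- if (engine == "compiled") {
        deSolve::ode(y0, c(t0, t_off), func = "mesc_derivs", parms = parms,
                     dllname = "mescsim", initfunc = "mesc_initmod",
                     method = "lsoda", rtol = rtol, atol = atol)
      } else {
        deSolve::ode(y0, c(t0, t_off), func = r_rhs, parms = NULL,
                     method = "lsoda", rtol = rtol, atol = atol)
      }
      y0 <- sol0[nrow(sol0), -1]
      t0 <- t_off
    }
    tt <- sort(unique(c(t0, out_times[out_times > t0 & out_times <= t1], t1)))
    sol <- if (engine == "compiled") {
      deSolve::ode(y0, tt, func = "mesc_derivs", parms = parms,
                   dllname = "mescsim", initfunc = "mesc_initmod",
                   rootfunc = "mesc_root", nroot = 1L,
                   method = "lsodar", rtol = rtol, atol = atol)
    } else {
      deSolve::ode(y0, tt, func = r_rhs, parms = NULL, rootfunc = r_root,
                   method = "lsodar", rtol = rtol, atol = atol)
    }
    istate <- attr(sol, "istate")
    if (!is.null(istate) && istate[1] < 0) {
      stop(sprintf(
        "solver failure (istate %d) at t = %.6g h; last state: %s",
        ds$istate[1], sol[nrow(sol), 1],
        paste(sprintf("%s=%.4g", .state_names, sol[nrow(sol), -1]),
              collapse = ", ")), call. = FALSE)
    }
    troot <- attr(sol, "troot")
    rows <- rbind(rows, sol[sol[, 1] %in% out_times, , drop = FALSE])
    t_end <- sol[nrow(sol), 1]
    if (is.null(troot) || length(troot) == 0 || t_end >= t1 - 1e-9) {
      if (!is.null(troot) && length(troot) > 0 && troot[1] < t1 - 1e-9) {
        switches <- c(switches, troot[1])
      }
      break
    }
    switches <- c(switches, troot[1])
    y0 <- sol[nrow(sol), -1]
    t0 <- t_end
  }
  list(rows = rows, switches = switches)
}

#' Simulate a bioreactor culture
#'
#' Integrates the nine-state culture model over a horizon under batch,
#' fed-batch or perfusion operation, producing a trajectory on the
#' requested output grid (hourly over eight days by default, the study's
#' batch horizon). The integration restarts at every Rex1 switching root
#' and at every fed-batch medium exchange.
#'
#' @param initial Initial culture state (see [initial_state()]).
#' @param params Parameter tibble or named vector.
#' @param reactor A `reactor_config`.
#' @param horizon Culture duration (h).
#' @param times Output times (h); defaults to hourly on `[0, horizon]`.
#'   Must lie within the horizon; 0 is prepended if absent.
#' @param rtol,atol Solver relative/absolute tolerances.
#' @param rex_reference Rex1 level at which the transfer direction flips.
#' @param engine `"compiled"` (default) uses the C right-hand side;
#'   `"r"` uses the pure-R mirror (slower, for cross-checking).
#' @return A tibble of class `mesc_trajectory` with columns `time_h` and
#'   the nine states. Attributes carry the parameters, reactor, solver
#'   settings and the root-located switch times (`attr(x, "switches")`).
#' @examples
#' traj <- simulate_culture(horizon = 48, times = seq(0, 48, 4))
#' summarize_trajectory(traj)
#' @export
simulate_culture <- function(initial = initial_state(),
                             params = mesc_parameters(),
                             reactor = reactor_batch(),
                             horizon = 192,
                             times = NULL,
                             rtol = 1e-8, atol = 1e-10,
                             rex_reference = 1,
                             engine = c("compiled", "r")) {
  engine <- match.arg(engine)
  validate_reactor(reactor)
  stopifnot(horizon > 0)
  if (is.null(times)) times <- seq(0, horizon, by = 1)
  times <- sort(unique(times))
  if (any(times < 0) || any(times > horizon + 1e-9)) {
    stop("output times must lie within [0, horizon]", call. = FALSE)
  }
  if (times[1] > 0) times <- c(0, times)

  y0 <- as_state_vector(initial)
  parms <- .build_parms(params, reactor, rex_reference)

  boundaries <- 0
  if (reactor$mode == "fed_batch") {
    ex <- seq(reactor$exchange_interval, horizon, by = reactor$exchange_interval)
    boundaries <- c(boundaries, ex[ex < horizon - 1e-9])
  }
  boundaries <- c(boundaries, horizon)

  rows <- matrix(c(0, y0), nrow = 1)
  switches <- numeric(0)
  y <- y0
  for (i in seq_len(length(boundaries) - 1)) {
    t0 <- boundaries[i]; t1 <- boundaries[i + 1]
    seg <- .integrate_span(y, t0, t1, times[times > t0 + 1e-12], parms,
                           rtol, atol, engine)
    if (!is.null(seg$rows)) {
      rows <- rbind(rows, unname(seg$rows[seg$rows[, 1] > t0 + 1e-12, ,
                                          drop = FALSE]))
      last <- seg$rows[nrow(seg$rows), -1]
    } else {
      last <- y
    }
    switches <- c(switches, seg$switches)
    y <- pmax(last, 0)
    if (reactor$mode == "fed_batch" && t1 < horizon - 1e-9) {
      st <- stats::setNames(as.numeric(y), .state_names)
      y <- as_state_vector(apply_medium_exchange(st, reactor))
      # the post-exchange state replaces the pre-exchange row at t1 for
      # the remainder of the integration; the stored row keeps the
      # pre-exchange value (the measurable supernatant)
    }
  }

  out <- as_tibble(as.data.frame(rows[!duplicated(rows[, 1]), , drop = FALSE]))
  names(out) <- c("time_h", .state_names)
  out <- out[out$time_h %in% times, ]
  structure(
    out,
    class = c("mesc_trajectory", class(out)),
    params = if (is.data.frame(params)) params else NULL,
    reactor = reactor,
    switches = switches,
    solver = list(rtol = rtol, atol = atol, engine = engine,
                  rex_reference = rex_reference)
  )
}

#' Full medium exchange
#'
#' Replaces the vessel medium with fresh inlet medium: the four solute
#' concentrations are reset to the inlet composition while cells (retained
#' in their beads) and their gene-expression states are unchanged.
#'
#' @param state Culture state (named vector or one-row tibble).
#' @param reactor A `reactor_config` in fed-batch mode.
#' @return State of the same shape as the input.
#' @export
apply_medium_exchange <- function(state, reactor) {
  validate_reactor(reactor)
  if (reactor$mode != "fed_batch") {
    stop("medium exchange applies to fed_batch mode only", call. = FALSE)
  }
  solutes <- c(glc = "GLC", gln = "GLN", lac = "LAC", amm = "AMM")
  if (is.data.frame(state)) {
    state[names(solutes)] <- as.list(unname(reactor$inlet[solutes]))
  } else {
    state[names(solutes)] <- unname(reactor$inlet[solutes])
  }
  state
}

#' Tidy long form of a trajectory
#'
#' Pivots a trajectory to the tidy schema `time_h, variable, value`,
#' adding the derived total viable density `x_v = x_u + x_d`.
#'
#' @param traj A `mesc_trajectory`.
#' @return A long tibble.
#' @export
trajectory_long <- function(traj) {
  traj |>
    dplyr::mutate(x_v = .data$x_u + .data$x_d) |>
    as_tibble() |>
    tidyr::pivot_longer(-"time_h", names_to = "variable", values_to = "value")
}

#' Write a trajectory to tidy CSV
#'
#' @param traj A `mesc_trajectory`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(trajectory_long(traj), path, row.names = FALSE)
  invisible(path)
}

.first_crossing <- function(time, value, threshold) {
  above <- value >= threshold
  if (above[1]) return(time[1])
  idx <- which(!above[-length(above)] & above[-1])
  if (length(idx) == 0) return(NA_real_)
  i <- idx[1]
  # linear interpolation between bracketing grid points
  time[i] + (threshold - value[i]) * (time[i + 1] - time[i]) /
    (value[i + 1] - value[i])
}

#' Summarize a trajectory
#'
#' Culture-level performance indicators: peak viable density and its time;
#' the realized maximum specific growth rate, estimated by log-linear
#' regression of total viable density over a sliding window (24 h by
#' default, matching how daily experimental counts are used) and the
#' corresponding doubling time; the final primed fraction; fold expansion
#' relative to inoculation; and the times at which lactate and ammonia
#' first cross their inhibitory levels (16 and 4 mM; `NA` if never).
#'
#' @param traj A `mesc_trajectory`.
#' @param growth_window Width of the sliding regression window (h).
#' @param lac_threshold,amm_threshold Inhibitory levels (mM).
#' @return A one-row tibble.
#' @export
summarize_trajectory <- function(traj, growth_window = 24,
                                 lac_threshold = 16, amm_threshold = 4) {
  stopifnot(nrow(traj) > 0)
  tt <- traj$time_h
  x_v <- traj$x_u + traj$x_d
  peak_i <- which.max(x_v)

  mu_max <- -Inf
  pos <- x_v > 0
  for (i in seq_along(tt)) {
    w <- which(tt >= tt[i] & tt <= tt[i] + growth_window & pos)
    if (length(w) >= 2) {
      slope <- stats::coef(stats::lm.fit(cbind(1, tt[w]), log(x_v[w])))[2]
      if (is.finite(slope)) mu_max <- max(mu_max, slope)
    }
  }
  if (!is.finite(mu_max)) mu_max <- NA_real_

  tibble(
    peak_x_v = x_v[peak_i],
    t_peak_h = tt[peak_i],
    mu_max_realized = mu_max,
    doubling_time_h = ifelse(!is.na(mu_max) && mu_max > 0,
                             doubling_time(mu_max), NA_real_),
    final_frac_d = traj$x_d[nrow(traj)] / x_v[nrow(traj)],
    fold_expansion = x_v[nrow(traj)] / x_v[1],
    t_lac_cross_h = .first_crossing(tt, traj$lac, lac_threshold),
    t_amm_cross_h = .first_crossing(tt, traj$amm, amm_threshold)
  )
}

#' Doubling time from a specific growth rate
#'
#' `ln(2) / mu`, in the inverse units of `mu` (e.g. 0.49/day gives 1.41
#' days; 1.15/day gives 0.60 days).
#'
#' @param mu Specific growth rate.
#' @return Doubling time.
#' @export
doubling_time <- function(mu) log(2) / mu

#' @importFrom generics glance
#' @export
generics::glance

#' @export
glance.mesc_trajectory <- function(x, ...) summarize_trajectory(x, ...)

#' Plot a trajectory
#'
#' Four-panel view of a simulated culture: cell densities (naive, primed,
#' total), nutrients, metabolites, and relative gene expression.
#'
#' @param object A `mesc_trajectory`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mesc_trajectory <- function(object, ...) {
  panels <- c(x_u = "cells", x_d = "cells", x_v = "cells",
              glc = "nutrients (mM)", gln = "nutrients (mM)",
              lac = "metabolites (mM)", amm = "metabolites (mM)",
              rex1 = "expression (fold)", fgf5 = "expression (fold)",
              dppa3 = "expression (fold)")
  df <- trajectory_long(object) |>
    dplyr::mutate(panel = panels[.data$variable])
  ggplot2::ggplot(df, ggplot2::aes(.data$time_h, .data$value,
                                   colour = .data$variable)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
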