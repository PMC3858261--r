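# Reactor operating configurations: batch (single feed at inoculation),
# fed-batch (periodic full medium exchange, beads retained), and perfusion
# (continuous medium supply, beads retained so only solutes are diluted).

.default_inlet <- c(GLC = 25, GLN = 4, LAC = 0, AMM = 0)

new_reactor_config <- function(mode, volume, n_bead, feed_rate = NA_real_,
                               inlet = .default_inlet,
                               exchange_interval = NA_real_) {
  inlet_full <- .default_inlet
  inlet_full[names(inlet)] <- inlet
  cfg <- structure(
    list(mode = mode, volume = volume, n_bead = n_bead,
         feed_rate = feed_rate, inlet = inlet_full,
         exchange_interval = exchange_interval),
    class = "reactor_config"
  )
  validate_reactor(cfg)
}

#' Reactor configurations
#'
#' Constructors for the three operating modes of the encapsulated-mESC
#' bioreactor model. Defaults mirror the study's vessels: a 55 ml
#' high-aspect-ratio batch vessel and a 60 ml perfusion vessel fed at
#' 2.29 ml/h, both holding approximately 500 hydrogel beads. Fed-batch is
#' batch operation with a full medium exchange every `exchange_interval`
#' hours (daily by default), retaining the beads.
#'
#' Fresh medium defaults to 25 mM glucose (high-glucose DMEM), 4 mM
#' glutamine and no lactate or ammonia.
#'
#' @param volume Working volume (ml).
#' @param n_bead Number of hydrogel beads in the vessel.
#' @param feed_rate Continuous medium feed (ml/h, perfusion only).
#' @param inlet Named fresh-medium concentrations (mM); any of `GLC`,
#'   `GLN`, `LAC`, `AMM`. Unnamed species keep their defaults.
#' @param exchange_interval Hours between full medium exchanges
#'   (fed-batch only).
#' @return A `reactor_config` object.
#' @examples
#' reactor_batch()
#' reactor_perfusion(feed_rate = 2.29)
#' @export
reactor_batch <- function(volume = 55, n_bead = 500, inlet = .default_inlet) {
  new_reactor_config("batch", volume, n_bead, inlet = inlet)
}

#' @rdname reactor_batch
#' @export
reactor_fed_batch <- function(volume = 55, n_bead = 500,
                              exchange_interval = 24,
                              inlet = .default_inlet) {
  new_reactor_config("fed_batch", volume, n_bead, inlet = inlet,
                     exchange_interval = exchange_interval)
}

#' @rdname reactor_batch
#' @export
reactor_perfusion <- function(volume = 60, n_bead = 500, feed_rate = 2.29,
                              inlet = .default_inlet) {
  new_reactor_config("perfusion", volume, n_bead, feed_rate = feed_rate,
                     inlet = inlet)
}

#' Validate a reactor configuration
#'
#' @param reactor A `reactor_config`.
#' @return The input, invisibly-checked (returned) if consistent.
#' @export
validate_reactor <- function(reactor) {
  if (!inherits(reactor, "reactor_config")) {
    stop("`reactor` must be a reactor_config (see reactor_batch())",
         call. = FALSE)
  }
  with(reactor, {
    if (!mode %in% c("batch", "fed_batch", "perfusion")) {
      stop("unknown reactor mode: ", mode, call. = FALSE)
    }
    if (!is.finite(volume) || volume <= 0) stop("volume must be > 0", call. = FALSE)
    if (!is.finite(n_bead) || n_bead <= 0) stop("n_bead must be > 0", call. = FALSE)
    if (mode == "perfusion" && (!is.finite(feed_rate) || feed_rate <= 0)) {
      stop("perfusion mode requires feed_rate > 0", call. = FALSE)
    }
    if (mode != "perfusion" && is.finite(feed_rate)) {
      stop("feed_rate only applies to perfusion mode", call. = FALSE)
    }
    if (mode == "fed_batch" &&
        (!is.finite(exchange_interval) || exchange_interval <= 0)) {
      stop("fed_batch mode requires exchange_interval > 0", call. = FALSE)
    }
    if (any(reactor$inlet < 0)) stop("inlet concentrations must be >= 0", call. = FALSE)
  })
  reactor
}

#' Dilution rate of a reactor
#'
#' Feed flow divided by working volume; the washout rate constant applied to
#' soluble species in perfusion mode. Zero for batch and fed-batch.
#'
#' @param reactor A `reactor_config`.
#' @return Dilution rate (1/h).
#' @export
dilution_rate <- function(reactor) {
  validate_reactor(reactor)
  if (reactor$mode == "perfusion") reactor$feed_rate / reactor$volume else 0
}

#' @export
print.reactor_config <- function(x, ...) {
  cat("<reactor_config> mode:", x$mode,
      sprintf("| volume %g ml | %g beads", x$volume, x$n_bead))
  if (x$mode == "perfusion") cat(sprintf(" | feed %g ml/h", x$feed_rate))
  if (x$mode == "fed_batch") cat(sprintf(" | exchange every %g h", x$exchange_interval))
  cat("\n  inlet (mM):", paste(names(x$inlet), x$inlet, sep = "=", collapse = " "), "\n")
  invisible(x)
}

.state_names <- c("x_u", "x_d", "glc", "gln", "lac", "amm",
                  "rex1", "fgf5", "dppa3")

#' Initial culture state
#'
#' One row per culture: naive (`x_u`) and primed (`x_d`) viable cell
#' densities (cells/bead), vessel concentrations of glucose, glutamine,
#' lactate and ammonia (mM), and day-0-normalized relative expression of
#' Rex1, Fgf5 and Dppa3 (fold, 1 at inoculation by construction of the
#' 2^-ddCt scale).
#'
#' Defaults encode the study's inoculum: 2e4 cells per bead split 85:15
#' naive:primed, fresh high-glucose DMEM.
#'
#' @param x_v Total viable cell density (cells/bead).
#' @param frac_u Naive fraction of the inoculum.
#' @param glc,gln,lac,amm Initial concentrations (mM).
#' @param rex1,fgf5,dppa3 Initial relative expression (fold).
#' @return A one-row tibble with the nine state variables.
#' @examples
#' initial_state()
#' @export
initial_state <- function(x_v = 2e4, frac_u = 0.85,
                          glc = 25, gln = 4, lac = 0, amm = 0,
                          rex1 = 1, fgf5 = 1, dppa3 = 1) {
  stopifnot(x_v >= 0, frac_u >= 0, frac_u <= 1,
            glc >= 0, gln >= 0, lac >= 0, amm >= 0,
            rex1 >= 0, fgf5 >= 0, dppa3 >= 0)
  tibble(
    x_u = x_v * frac_u, x_d = x_v * (1 - frac_u),
    glc = glc, gln = gln, lac = lac, amm = amm,
    rex1 = rex1, fgf5 = fgf5, dppa3 = dppa3
  )
}

as_state_vector <- function(state) {
  if (is.data.frame(state)) {
    stopifnot(nrow(state) == 1)
    state <- unlist(state[1, intersect(names(state), c("time_h", .state_names))])
  }
  state <- state[setdiff(names(state), "time_h")]
  missing <- setdiff(.state_names, names(state))
  if (length(missing) > 0) {
    stop("missing state variables: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  v <- state[.state_names]
  if (any(v < 0)) stop("state variables must be >= 0", call. = FALSE)
  v
}
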