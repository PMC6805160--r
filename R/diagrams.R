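#' Two-phase (piecewise-linear) flow function
#'
#' Flow rises linearly with density up to a breakpoint density `k_j` and then
#' stays constant: `q(k) = v * min(k, k_j)`.  Below the breakpoint ants move
#' freely and flow is proportional to density; above it the flow saturates at
#' the plateau `q_j = v * k_j` without decaying.
#'
#' @param k density in ants cm^-2 (vectorised).
#' @param v slope of the free phase, cm s^-1 per unit width.
#' @param k_j breakpoint (jam) density in ants cm^-2.
#' @return Flow in ants cm^-1 s^-1.
#' @examples
#' two_phase_flow(c(4, 8, 12), v = 1.25, k_j = 8)
#' @export
two_phase_flow <- function(k, v, k_j) {
  if (any(k < 0)) ant_config_error("two_phase_flow: density k must be >= 0")
  if (v <= 0 || k_j <= 0)
    ant_config_error("two_phase_flow: v and k_j must be positive")
  v * pmin(k, k_j)
}

#' Classical speed-density relations
#'
#' The three speed-density functions commonly used for vehicular, pedestrian
#' and fluid traffic.  `greenshields_speed` is linear in density,
#' `pipes_munjal_speed` generalises it with a power-law exponent `p`
#' (`p = 1` recovers Greenshields), and `underwood_speed` decays
#' exponentially.  All satisfy `v(0) = v_f` and are non-increasing in `k`;
#' the first two clamp at zero beyond the jam density `k_j`.
#'
#' @param k density in ants cm^-2 (vectorised).
#' @param v_f free-flow speed in cm s^-1.
#' @param k_j jam density (speed reaches zero there) for the Greenshields and
#'   Pipes-Munjal forms.
#' @param p power-law exponent of the Pipes-Munjal form.
#' @param k_m density scale of the Underwood form; `v(k_m) = v_f / e`.
#' @return Speed in cm s^-1.
#' @name classical_speeds
#' @examples
#' greenshields_speed(4, v_f = 2, k_j = 8)    # half the free speed
#' underwood_speed(6, v_f = 2, k_m = 6)       # v_f / e
NULL

#' @rdname classical_speeds
#' @export
greenshields_speed <- function(k, v_f, k_j) {
  if (any(k < 0)) ant_config_error("greenshields_speed: density k must be >= 0")
  if (v_f <= 0 || k_j <= 0)
    ant_config_error("greenshields_speed: parameters must be positive")
  v_f * pmax(1 - k / k_j, 0)
}

#' @rdname classical_speeds
#' @export
pipes_munjal_speed <- function(k, v_f, k_j, p) {
  if (any(k < 0)) ant_config_error("pipes_munjal_speed: density k must be >= 0")
  if (v_f <= 0 || k_j <= 0 || p <= 0)
    ant_config_error("pipes_munjal_speed: parameters must be positive")
  v_f * pmax(1 - (k / k_j)^p, 0)
}

#' @rdname classical_speeds
#' @export
underwood_speed <- function(k, v_f, k_m) {
  if (any(k < 0)) ant_config_error("underwood_speed: density k must be >= 0")
  if (v_f <= 0 || k_m <= 0)
    ant_config_error("underwood_speed: parameters must be positive")
  v_f * exp(-k / k_m)
}

#' Fundamental-diagram model definitions
#'
#' Returns the definition of one of the four flow-density models as a list
#' holding its parameter names and its flow function `q(k, par)`.  For the
#' three speed-based models the flow is `q = k * v(k)`; the two-phase model
#' is defined directly on the flow scale.
#'
#' @param name one of `"two_phase"`, `"greenshields"`, `"pipes_munjal"`,
#'   `"underwood"`.
#' @return An object of class `fd_model` with elements `name`, `par_names`,
#'   `flow` (function of `k` and a named parameter vector) and, for the
#'   speed-based models, `speed`.
#' @seealso [fit_diagram()]
#' @export
fd_model <- function(name = c("two_phase", "greenshields", "pipes_munjal",
                              "underwood")) {
  name <- match.arg(name)
  def <- switch(name,
    two_phase = list(
      par_names = c("v", "k_j"),
      flow  = function(k, par) two_phase_flow(k, par[["v"]], par[["k_j"]]),
      speed = NULL),
    greenshields = list(
      par_names = c("v_f", "k_j"),
      flow  = function(k, par) k * greenshields_speed(k, par[["v_f"]], par[["k_j"]]),
      speed = function(k, par) greenshields_speed(k, par[["v_f"]], par[["k_j"]])),
    pipes_munjal = list(
      par_names = c("v_f", "k_j", "p"),
      flow  = function(k, par)
        k * pipes_munjal_speed(k, par[["v_f"]], par[["k_j"]], par[["p"]]),
      speed = function(k, par)
        pipes_munjal_speed(k, par[["v_f"]], par[["k_j"]], par[["p"]])),
    underwood = list(
      par_names = c("v_f", "k_m"),
      flow  = function(k, par) k * underwood_speed(k, par[["v_f"]], par[["k_m"]]),
      speed = function(k, par) underwood_speed(k, par[["v_f"]], par[["k_m"]]))
  )
  structure(c(list(name = name), def), class = "fd_model")
}

#' @export
print.fd_model <- function(x, ...) {
  cat(sprintf("Fundamental-diagram model '%s' with parameters %s\n",
              x$name, paste(x$par_names, collapse = ", ")))
  invisible(x)
}
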