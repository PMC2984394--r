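#' Piecewise-constant oxygen protocol
#'
#' Oxygen schedules used in the simulations are step protocols: oxygen is
#' held constant within segments and switches instantaneously at segment
#' boundaries (the experimental hypoxia/reoxygenation paradigm). Ramps are
#' deliberately not supported.
#'
#' @param times numeric vector of segment start times, strictly increasing;
#'   the first element is the initial time of any simulation using the
#'   protocol.
#' @param oxygen numeric vector of oxygen values (>= 0), one per segment,
#'   in the convention of the model the protocol is applied to ("tilde" for
#'   Full/SKM1, "bar" for SKM2).
#' @return An object of class `"oxygen_protocol"`.
#' @examples
#' oxygen_protocol(0, 0.5)                    # constant normoxia
#' oxygen_protocol(c(0, 10), c(0.001, 0.5))   # reoxygenation at t = 10
#' @export
oxygen_protocol <- function(times, oxygen) {
  if (length(times) != length(oxygen) || length(times) == 0L)
    stop("times and oxygen must be nonempty vectors of equal length")
  if (any(diff(times) <= 0)) stop("segment start times must be strictly increasing")
  if (any(oxygen < 0)) stop("oxygen values must be >= 0")
  structure(list(times = as.numeric(times), oxygen = as.numeric(oxygen)),
            class = "oxygen_protocol")
}

#' @export
print.oxygen_protocol <- function(x, ...) {
  cat("Oxygen step protocol (", length(x$times), " segment(s)):\n", sep = "")
  for (i in seq_along(x$times))
    cat(sprintf("  t >= %g : O2 = %g\n", x$times[i], x$oxygen[i]))
  invisible(x)
}

#' Oxygen value of a protocol at given times
#'
#' @param protocol an [oxygen_protocol()].
#' @param t numeric vector of times (>= the protocol's initial time).
#' @return Oxygen values at `t` (right-continuous step function).
#' @export
protocol_oxygen_at <- function(protocol, t) {
  idx <- findInterval(t, protocol$times)
  if (any(idx == 0L)) stop("time precedes the protocol's initial time")
  protocol$oxygen[idx]
}

model_rhs <- function(model) {
  switch(model,
         full = function(s, o, p) rhs_full(s, o, p),
         skm1 = function(s, o, p) rhs_skm1(s, o, p),
         skm2 = function(s, o, p) rhs_skm2(s[["A"]], o, p),
         stop("unknown model tag '", model, "'"))
}

check_state <- function(model, state, params) {
  state <- as.numeric(state)
  need <- switch(model, full = 3L, skm1 = 2L, skm2 = 1L)
  if (length(state) != need)
    stop("model '", model, "' needs a state of length ", need)
  names(state) <- switch(model, full = c("H_tot", "H", "A"),
                         skm1 = c("H_tot", "H"), skm2 = "A")
  if (any(state < -1e-12)) stop("state values must be >= 0")
  if (model == "full" && state[["A"]] > params$A_tot + 1e-9)
    stop("A must not exceed A_tot")
  if (model == "skm2" && state[["A"]] > 1 + 1e-9)
    stop("SKM2 state is the unhydroxylated fraction and must be <= 1")
  if (model %in% c("full", "skm1") &&
      state[["H"]] > state[["H_tot"]] + 1e-9)
    stop("H must not exceed H_tot")
  state
}

default_init <- function(model, params) {
  # anoxic fixed point of each model
  switch(model,
         full = c(H_tot = 1, H = 1, A = params$A_tot),
         skm1 = c(H_tot = 1, H = 1),
         skm2 = c(A = 1))
}

#' Integrate a model under a piecewise-constant oxygen protocol
#'
#' Wraps the model right-hand sides in a stiff-capable adaptive integrator
#' (`deSolve::ode`, `lsoda`). Integration is restarted exactly at every
#' protocol breakpoint so oxygen steps are sharp rather than smoothed
#' through the step-size control.
#'
#' @param model one of `"full"`, `"skm1"`, `"skm2"`.
#' @param params a [full_params()] (full/skm1) or [skm2_params()] (skm2)
#'   object.
#' @param protocol an [oxygen_protocol()]; its first start time is the
#'   initial time.
#' @param init initial state (named or positional); defaults to the model's
#'   anoxic fixed point.
#' @param duration total simulated time (> 0).
#' @param step sampling interval for the returned trajectory.
#' @param rtol,atol relative and absolute integrator tolerances.
#' @return A `"fih_trajectory"`: a data frame with columns `time`, `oxygen`,
#'   the model species and derived observables (`H_OH`, `A_OH`, `F_free`,
#'   HRE occupancies where applicable), with the model tag, parameters and
#'   protocol attached as attributes.
#' @examples
#' q <- skm2_params(10, 50)
#' tr <- integrate_model("skm2", q, oxygen_protocol(0, 1), duration = 10)
#' tail(tr, 1)   # near the high-oxygen steady state
#' @export
integrate_model <- function(model = c("full", "skm1", "skm2"), params,
                            protocol, init = NULL, duration, step = 0.05,
                            rtol = 1e-8, atol = 1e-10) {
  model <- match.arg(model)
  if (!inherits(protocol, "oxygen_protocol"))
    stop("protocol must be an oxygen_protocol")
  if (duration <= 0) stop("duration must be > 0")
  init <- if (is.null(init)) default_init(model, params)
          else check_state(model, init, params)
  rhs <- model_rhs(model)

  t0 <- protocol$times[1]
  t_end <- t0 + duration
  breaks <- protocol$times[protocol$times > t0 & protocol$times < t_end]
  bounds <- c(t0, breaks, t_end)
  samples <- unique(sort(c(seq(t0, t_end, by = step), bounds)))

  out_t <- numeric(0)
  out_s <- NULL
  y <- init
  for (i in seq_len(length(bounds) - 1L)) {
    a <- bounds[i]; b <- bounds[i + 1L]
    o <- protocol_oxygen_at(protocol, a)
    tt <- samples[samples >= a & samples <= b]
    if (tt[1] > a) tt <- c(a, tt)
    if (tt[length(tt)] < b) tt <- c(tt, b)
    sol <- deSolve::ode(y = y, times = tt,
                        func = function(t, s, parms) list(rhs(s, o, parms)),
                        parms = params, method = "lsoda",
                        rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1] < 0)
      stop("integration failed at t = ", max(sol[, 1]),
           " (model '", model, "', oxygen ", o, ")")
    keep <- if (i > 1L) -1L else seq_len(nrow(sol))
    out_t <- c(out_t, sol[keep, 1])
    out_s <- rbind(out_s, sol[keep, -1, drop = FALSE])
    y <- sol[nrow(sol), -1]
  }

  traj <- data.frame(time = out_t,
                     oxygen = protocol_oxygen_at(protocol, out_t))
  traj <- cbind(traj, as.data.frame(out_s))
  names(traj)[-(1:2)] <- names(init)
  traj <- add_observables(model, traj, params)
  structure(traj, model = model, params = params, protocol = protocol,
            class = c("fih_trajectory", "data.frame"))
}

add_observables <- function(model, df, params) {
  if (model %in% c("full", "skm1")) {
    df$H_OH <- pmax(df$H_tot - df$H, 0)
    occ <- hre_occupancy(df$H, df$H_OH, df$H_tot, params$KD_HRE)
    df$HRE_CAD <- occ$cad
    df$HRE_CADOH <- occ$cadoh
    df$HRE_total <- occ$cad + occ$cadoh
  }
  if (model == "full") {
    df$A_OH <- pmax(params$A_tot - df$A, 0)
    df$F_free <- vapply(seq_len(nrow(df)), function(i)
      f_free_full(c(H_tot = df$H_tot[i], H = df$H[i], A = df$A[i]), params),
      numeric(1))
  }
  if (model == "skm2") {
    df$A_OH <- pmax(1 - df$A, 0)
    df$F_free <- 1 / (1 + params$kappa * pmax(df$A, 0))
  }
  df
}

#' Steady state by relaxation
#'
#' Integrates the model at constant oxygen until the largest right-hand-side
#' component falls below `residual_tol`, mirroring the original numerical
#' procedure of running time courses until a steady state is reached.
#' Integration proceeds in geometrically growing chunks with tight
#' tolerances; non-convergence within `t_cap` raises an error that reports
#' the residual.
#'
#' @inheritParams integrate_model
#' @param oxygen constant oxygen value (model convention).
#' @param residual_tol convergence threshold on `max |dX/dt|`.
#' @param t_cap maximum integrated time before giving up.
#' @return Named numeric state vector with attributes `residual` and
#'   `time` (integrated time used).
#' @examples
#' steady_state("skm2", skm2_params(10, 50), oxygen = 0)  # A = 1
#' @export
steady_state <- function(model = c("full", "skm1", "skm2"), params, oxygen,
                         init = NULL, residual_tol = 1e-9, t_cap = 1e4,
                         rtol = 1e-10, atol = 1e-12) {
  model <- match.arg(model)
  if (oxygen < 0) stop("oxygen must be >= 0")
  y <- if (is.null(init)) default_init(model, params)
       else check_state(model, init, params)
  rhs <- model_rhs(model)
  t_done <- 0
  chunk <- 10
  repeat {
    res <- max(abs(rhs(y, oxygen, params)))
    if (res < residual_tol) break
    if (t_done >= t_cap)
      stop("steady state not reached within t = ", t_cap,
           " (residual ", format(res, digits = 3), ")")
    tt <- c(0, min(chunk, t_cap - t_done))
    sol <- deSolve::ode(y = y, times = tt,
                        func = function(t, s, parms)
                          list(rhs(s, oxygen, parms)),
                        parms = params, method = "lsoda",
                        rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1] < 0)
      stop("integration failed during relaxation at oxygen = ", oxygen)
    y <- sol[nrow(sol), -1]
    t_done <- t_done + tt[2]
    chunk <- chunk * 4
  }
  structure(y, residual = max(abs(rhs(y, oxygen, params))), time = t_done)
}

#' Equilibrate at one oxygen level, then apply a step
#'
#' Reproduces the hypoxia/reoxygenation paradigm: the model is relaxed to
#' its steady state at `o_before`, which becomes the `t = 0` initial
#' condition of a time course at `o_after`.
#'
#' @inheritParams integrate_model
#' @param o_before,o_after oxygen before and after the step (>= 0, model
#'   convention).
#' @param duration length of the post-step time course.
#' @return A `"fih_trajectory"` over `[0, duration]` at `o_after`.
#' @export
equilibrate_then_step <- function(model = c("full", "skm1", "skm2"), params,
                                  o_before, o_after, duration, step = 0.05,
                                  ...) {
  model <- match.arg(model)
  y0 <- steady_state(model, params, o_before, ...)
  integrate_model(model, params, oxygen_protocol(0, o_after),
                  init = as.numeric(y0), duration = duration, step = step)
}
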