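#' Logarithmic oxygen grid
#'
#' Default steady-state scans use logarithmically spaced oxygen because the
#' biologically interesting behaviour spans several decades of hypoxia.
#'
#' @param from,to grid endpoints (> 0).
#' @param n number of points.
#' @return Strictly increasing numeric vector.
#' @export
oxygen_grid <- function(from = 1e-4, to = 1, n = 60) {
  if (from <= 0 || to <= from) stop("need 0 < from < to")
  exp(seq(log(from), log(to), length.out = n))
}

#' Steady-state signal/response scan
#'
#' Computes the relaxation steady state at every point of an oxygen grid,
#' warm-starting each solve from the neighbouring solution, and attaches the
#' derived observables (CAD-hydroxylated HIF-alpha, free FIH, HRE
#' occupancies).
#'
#' @inheritParams steady_state
#' @param oxygen strictly increasing oxygen grid (model convention).
#' @return A `"fih_response"`: a data frame with one row per grid point and
#'   the same columns as a trajectory (minus `time`), with model tag and
#'   parameters as attributes.
#' @examples
#' rc <- response_scan("skm2", skm2_params(10, 50), oxygen_grid(1e-3, 10, 25))
#' rc$F_free[1]    # close to the anoxic sequestration floor 1/11
#' @export
response_scan <- function(model = c("full", "skm1", "skm2"), params,
                          oxygen = oxygen_grid(), ...) {
  model <- match.arg(model)
  if (length(oxygen) == 0L || any(diff(oxygen) <= 0))
    stop("oxygen grid must be nonempty and strictly increasing")
  states <- matrix(NA_real_, nrow = length(oxygen),
                   ncol = length(default_init(model, params)))
  y <- NULL
  for (i in seq_along(oxygen)) {
    ss <- tryCatch(steady_state(model, params, oxygen[i], init = y, ...),
                   error = function(e)
                     stop("scan failed at oxygen = ", oxygen[i], ": ",
                          conditionMessage(e)))
    y <- as.numeric(ss)
    states[i, ] <- y
  }
  df <- data.frame(oxygen = oxygen)
  df <- cbind(df, as.data.frame(states))
  names(df)[-1] <- names(default_init(model, params))
  df <- add_observables(model, df, params)
  structure(df, model = model, params = params,
            class = c("fih_response", "data.frame"))
}

#' Fractional occupancy of hypoxia response elements
#'
#' Assuming fast DNA binding with equal affinity for all HIF-alpha forms,
#' the fractions of HREs occupied by non-CAD-hydroxylated and by
#' CAD-hydroxylated HIF-alpha are `H / (KD_HRE + H_tot)` and
#' `H_OH / (KD_HRE + H_tot)`; their sum is the fraction occupied by either
#' form.
#'
#' @param H non-CAD-hydroxylated HIF-alpha.
#' @param H_OH CAD-hydroxylated HIF-alpha.
#' @param H_tot total HIF-alpha; must equal `H + H_OH`.
#' @param KD_HRE HIF/HRE dissociation constant (> 0).
#' @return List with components `cad` and `cadoh` (fractions in `[0, 1]`).
#' @examples
#' hre_occupancy(1, 0, 1, 0.3)$cad    # 1/1.3
#' @export
hre_occupancy <- function(H, H_OH, H_tot, KD_HRE) {
  if (KD_HRE <= 0) stop("KD_HRE must be > 0")
  if (any(abs(H + H_OH - H_tot) > 1e-6 * pmax(1, H_tot)))
    stop("inconsistent inputs: H + H_OH must equal H_tot")
  list(cad = H / (KD_HRE + H_tot), cadoh = H_OH / (KD_HRE + H_tot))
}

#' Classify oxygen regimes of differential gene expression
#'
#' Given a scanned response curve with HRE occupancies, labels each oxygen
#' level by which classes of HIF target genes exceed an (arbitrary)
#' activation threshold: genes needing any DNA-bound HIF (NAD-dependent),
#' genes additionally needing non-CAD-hydroxylated HIF-alpha
#' (CAD-dependent), and the postulated class activated by CAD-hydroxylated
#' HIF-alpha.
#'
#' @param curve a `"fih_response"` from [response_scan()] for a model with
#'   HRE occupancies (full or skm1).
#' @param threshold activation threshold on HRE occupancy, in (0, 1);
#'   default 0.20.
#' @return Data frame with columns `oxygen`, `regime` (factor with levels
#'   `none`, `NAD`, `NAD+CAD`) and `cadoh` (logical: CADOH-driven occupancy
#'   above threshold).
#' @export
gene_regimes <- function(curve, threshold = 0.2) {
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must lie in (0, 1)")
  if (is.null(curve$HRE_total))
    stop("curve carries no HRE occupancies (scan a full or skm1 model)")
  regime <- ifelse(curve$HRE_total <= threshold, "none",
                   ifelse(curve$HRE_CAD > threshold, "NAD+CAD", "NAD"))
  data.frame(oxygen = curve$oxygen,
             regime = factor(regime, levels = c("none", "NAD", "NAD+CAD")),
             cadoh = curve$HRE_CADOH > threshold)
}

interp_crossing <- function(x, y, target) {
  # first bracketing interval where y crosses target; interpolate in log(x)
  # when x is positive (scans are log-spaced)
  dy <- y - target
  idx <- which(dy[-length(dy)] * dy[-1] <= 0 & dy[-length(dy)] != 0)
  if (any(dy == 0)) {
    hit <- which(dy == 0)[1]
    return(x[hit])
  }
  if (length(idx) == 0L) return(NA_real_)
  i <- idx[1]
  uselog <- all(x > 0)
  xi <- if (uselog) log(x[i + 0:1]) else x[i + 0:1]
  w <- (target - y[i]) / (y[i + 1] - y[i])
  xc <- xi[1] + w * (xi[2] - xi[1])
  if (uselog) exp(xc) else xc
}

#' Oxygen threshold of a monotone response
#'
#' Operationalises the "oxygen threshold" of a sigmoid response as the
#' oxygen at which the observable crosses a given fraction of its range
#' (`min + level * (max - min)`), located by interpolating between the
#' bracketing grid points (in log-oxygen for positive grids).
#'
#' @param oxygen strictly increasing oxygen grid.
#' @param observable response values at each grid point; approximately
#'   monotone over the grid.
#' @param level fractional response level defining the threshold, in
#'   (0, 1); default 0.5.
#' @return The threshold oxygen.
#' @examples
#' o <- oxygen_grid(1e-2, 1e2, 200)
#' find_threshold(o, o^2 / (0.25 + o^2))   # 0.5 for this Hill-2 curve
#' @export
find_threshold <- function(oxygen, observable, level = 0.5) {
  if (length(oxygen) != length(observable) || length(oxygen) < 2L)
    stop("oxygen and observable must be equal-length vectors (n >= 2)")
  if (any(diff(oxygen) <= 0)) stop("oxygen grid must be strictly increasing")
  if (level <= 0 || level >= 1) stop("level must lie in (0, 1)")
  rng <- range(observable)
  if (diff(rng) == 0) stop("observable is constant; no threshold exists")
  target <- rng[1] + level * diff(rng)
  xc <- interp_crossing(oxygen, observable, target)
  if (is.na(xc)) stop("observable does not cross the requested level")
  xc
}

#' Apparent Hill exponent of a monotone signal/response curve
#'
#' Quantifies ultrasensitivity by the classical 10-90% steepness measure:
#' `n_H = ln(81) / |ln(o_90 / o_10)|`, where `o_10` and `o_90` are the
#' oxygen values at 10% and 90% of the response amplitude (located by
#' interpolation). A Michaelis-Menten curve gives 1; steeper responses give
#' larger exponents.
#'
#' @inheritParams find_threshold
#' @return The apparent Hill exponent.
#' @examples
#' o <- oxygen_grid(1e-3, 1e3, 400)
#' hill_coefficient(o, o / (1 + o))   # ~1
#' @export
hill_coefficient <- function(oxygen, observable) {
  o10 <- find_threshold(oxygen, observable, 0.1)
  o90 <- find_threshold(oxygen, observable, 0.9)
  if (o10 == o90) stop("10% and 90% crossings are not resolved by the grid")
  log(81) / abs(log(o90 / o10))
}

#' Locate the peak of a response observable
#'
#' Finds the grid argmax and refines it by fitting a quadratic through the
#' three bracketing points (in log-oxygen for positive grids). Flags
#' whether the peak is interior to the grid, the signature of the
#' non-monotone (bell-shaped) accumulation of CAD-hydroxylated HIF-alpha at
#' intermediate oxygen.
#'
#' @inheritParams find_threshold
#' @return List with `oxygen` (peak location), `value` (peak height) and
#'   `interior` (logical).
#' @export
find_peak <- function(oxygen, observable) {
  if (length(oxygen) != length(observable) || length(oxygen) < 3L)
    stop("oxygen and observable must be equal-length vectors (n >= 3)")
  if (any(observable < 0)) stop("observable must be >= 0")
  if (all(observable == 0)) stop("observable is identically zero")
  i <- which.max(observable)
  if (i == 1L || i == length(oxygen))
    return(list(oxygen = oxygen[i], value = observable[i],
                interior = FALSE))
  uselog <- all(oxygen > 0)
  x <- if (uselog) log(oxygen[i + (-1:1)]) else oxygen[i + (-1:1)]
  y <- observable[i + (-1:1)]
  d21 <- (y[2] - y[1]) / (x[2] - x[1])
  d32 <- (y[3] - y[2]) / (x[3] - x[2])
  curv <- (d32 - d21) / (x[3] - x[1])
  if (curv >= 0) {                       # flat top; keep the grid argmax
    xp <- x[2]; yp <- y[2]
  } else {
    xp <- 0.5 * (x[1] + x[2] - d21 / curv)
    xp <- min(max(xp, x[1]), x[3])
    yp <- y[2] + curv * (xp - x[2])^2 +
      (d21 + curv * (x[2] - x[1])) * (xp - x[2])
  }
  list(oxygen = if (uselog) exp(xp) else xp,
       value = max(yp, y[2]), interior = TRUE)
}

#' Delay of the response to a reoxygenation step
#'
#' For a trajectory started at the moment of an oxygen step (as produced by
#' [equilibrate_then_step()]), returns the time at which an observable has
#' covered a given fraction of the way from its value at the step to its
#' final value. The delayed, switch-like release of FIH after reoxygenation
#' makes this delay a readout of the hydroxylation status of the ARD pool.
#'
#' @param trajectory a `"fih_trajectory"`.
#' @param observable name of a trajectory column (e.g. `"F_free"`).
#' @param level fractional response level, in (0, 1); default 0.5.
#' @return Delay time (>= 0), in the model's time units.
#' @export
reoxygenation_delay <- function(trajectory, observable, level = 0.5) {
  if (!observable %in% names(trajectory))
    stop("trajectory has no column '", observable, "'")
  if (level <= 0 || level >= 1) stop("level must lie in (0, 1)")
  tt <- trajectory$time - trajectory$time[1]
  y <- trajectory[[observable]]
  v0 <- y[1]; vf <- y[length(y)]
  if (vf == v0) return(0)
  target <- v0 + level * (vf - v0)
  dy <- y - target
  if (dy[1] == 0) return(0)
  idx <- which(dy[-length(dy)] * dy[-1] <= 0)
  if (length(idx) == 0L)
    stop("observable does not reach the requested level within the trajectory")
  i <- idx[1]
  if (dy[i + 1] == 0) return(tt[i + 1])
  w <- (target - y[i]) / (y[i + 1] - y[i])
  tt[i] + w * (tt[i + 1] - tt[i])
}

#' Memory map: reoxygenation delay versus hypoxia severity and duration
#'
#' For every combination of hypoxic oxygen level ("severity") and hypoxia
#' duration: equilibrate at normoxia, hold at the severity for the duration,
#' step back to normoxia, and record the delay until half-maximal recovery
#' of free FIH. The map quantifies how the hydroxylation status of the ARD
#' protein pool encodes the strength and duration of a hypoxic episode.
#'
#' @inheritParams steady_state
#' @param severities oxygen levels during hypoxia, all `< normoxia`.
#' @param durations hypoxia durations (> 0), model time units.
#' @param normoxia oxygen level before and after the episode; default 0.5.
#' @param level fractional recovery level for the delay; default 0.5.
#' @param post_cap longest post-reoxygenation time simulated.
#' @param step sampling interval of the post-step trajectories.
#' @return A `"fih_memory_map"`: matrix of delays with severities as rows
#'   and durations as columns.
#' @export
memory_map <- function(model = c("full", "skm2"), params, severities,
                       durations, normoxia = 0.5, level = 0.5,
                       post_cap = 500, step = 0.02, ...) {
  model <- match.arg(model)
  if (any(severities >= normoxia))
    stop("severities must all be below the normoxic oxygen level")
  if (any(durations <= 0)) stop("durations must be > 0")
  delays <- matrix(NA_real_, length(severities), length(durations),
                   dimnames = list(severity = as.character(severities),
                                   duration = as.character(durations)))
  y_norm <- steady_state(model, params, normoxia, ...)
  for (i in seq_along(severities)) {
    for (j in seq_along(durations)) {
      prot <- oxygen_protocol(c(0, durations[j]),
                              c(severities[i], normoxia))
      tr <- integrate_model(model, params, prot,
                            init = as.numeric(y_norm),
                            duration = durations[j] + post_cap, step = step)
      post <- tr[tr$time >= durations[j], , drop = FALSE]
      delays[i, j] <- reoxygenation_delay(post, "F_free", level)
    }
  }
  structure(delays, class = c("fih_memory_map", class(delays)),
            model = model, params = params, normoxia = normoxia)
}
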