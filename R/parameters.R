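#' Dimensionless parameter set for the Full Model and SKM1
#'
#' Constructs and validates the dimensionless parameters of the HIF-alpha
#' hydroxylation network. Concentrations are expressed relative to the
#' maximal HIF-alpha level reached in anoxia, first-order rates relative to
#' the basal HIF-alpha degradation rate constant, and oxygen relative to the
#' Michaelis constant of PHD for oxygen.
#'
#' Defaults are the published dimensionless values for the fixed parameters
#' (`P_tot = 0.2`, `KD_P = 1`, `kcat_P = 500`, `F_tot = 1`, `KD_FH = 1`,
#' `omega = 1`, `alpha = 0.33`, `KD_FA = 1`, `KD_HRE = 0.3`). The three
#' parameters that are scanned in the analyses default to the reference
#' time-course set `A_tot = 100`, `gamma = 0.02`, `epsilon = 5`.
#'
#' @param P_tot total PHD concentration (relative to maximal HIF-alpha).
#' @param KD_P dissociation constant of the PHD/HIF-alpha complex.
#' @param kcat_P turnover number for ODD hydroxylation over the basal
#'   HIF-alpha degradation rate constant.
#' @param F_tot total FIH concentration.
#' @param KD_FH dissociation constant of the FIH/HIF-alpha complex.
#' @param kcat_FH turnover number for CAD hydroxylation (same normalisation
#'   as `kcat_P`; set equal to it by default).
#' @param omega ratio of the CAD-hydroxylation turnover to the
#'   AR-hydroxylation turnover; `kcat_FA = kcat_FH / omega`.
#' @param alpha Michaelis constant of FIH for oxygen over that of PHD.
#' @param A_tot total concentration of FIH-target ankyrin repeats (may be 0).
#' @param KD_FA dissociation constant of FIH binding to unhydroxylated
#'   ankyrin repeats.
#' @param gamma FIH affinity for hydroxylated relative to unhydroxylated
#'   ankyrin repeats, in `[0, 1]`.
#' @param epsilon basal HIF-alpha degradation rate constant over the ARD
#'   protein degradation rate constant (ARD protein stability).
#' @param KD_HRE dissociation constant of HIF binding to hypoxia response
#'   elements.
#' @return An object of class `"full_params"`: a named list of the validated
#'   parameters plus the derived `kcat_FA`.
#' @seealso [skm2_params()], [nondimensionalize()]
#' @examples
#' p <- full_params()                  # reference parameter set
#' p0 <- full_params(A_tot = 0)        # no FIH/AR interaction
#' @export
full_params <- function(P_tot = 0.2, KD_P = 1, kcat_P = 500,
                        F_tot = 1, KD_FH = 1, kcat_FH = 500, omega = 1,
                        alpha = 0.33, A_tot = 100, KD_FA = 1,
                        gamma = 0.02, epsilon = 5, KD_HRE = 0.3) {
  p <- list(P_tot = P_tot, KD_P = KD_P, kcat_P = kcat_P,
            F_tot = F_tot, KD_FH = KD_FH, kcat_FH = kcat_FH, omega = omega,
            alpha = alpha, A_tot = A_tot, KD_FA = KD_FA,
            gamma = gamma, epsilon = epsilon, KD_HRE = KD_HRE)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite number")
  }
  pos <- setdiff(names(p), c("A_tot", "gamma"))
  for (nm in pos) if (p[[nm]] <= 0)
    stop("parameter '", nm, "' must be > 0, got ", p[[nm]])
  if (p$A_tot < 0) stop("A_tot must be >= 0")
  if (p$gamma < 0 || p$gamma > 1) stop("gamma must lie in [0, 1]")
  p$kcat_FA <- p$kcat_FH / p$omega
  structure(p, class = "full_params")
}

#' @export
print.full_params <- function(x, ...) {
  cat("Dimensionless Full Model / SKM1 parameters:\n")
  nm <- setdiff(names(x), "kcat_FA")
  cat(paste0("  ", format(nm, width = 8), " = ",
             vapply(x[nm], format, ""), collapse = "\n"), "\n")
  cat("  derived kcat_FA =", format(x$kcat_FA), "\n")
  invisible(x)
}

#' Parameters of the reduced FIH/ARD sequestration model (SKM2)
#'
#' The reduced model of FIH sequestration by ankyrin-repeat domain proteins
#' is governed by two dimensionless groups: the sequestration capacity
#' `kappa` (total FIH-target repeats over their FIH dissociation constant)
#' and the hydroxylation efficiency `beta` (maximal AR-hydroxylation rate
#' relative to ARD protein turnover).
#'
#' @param kappa sequestration capacity, > 0.
#' @param beta hydroxylation efficiency, >= 0.
#' @return An object of class `"skm2_params"`.
#' @examples
#' q <- skm2_params(kappa = 10, beta = 50)
#' @export
skm2_params <- function(kappa, beta) {
  if (!is.numeric(kappa) || length(kappa) != 1L || !is.finite(kappa) ||
      kappa <= 0)
    stop("kappa must be a single finite number > 0")
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) ||
      beta < 0)
    stop("beta must be a single finite number >= 0")
  structure(list(kappa = kappa, beta = beta), class = "skm2_params")
}

#' @export
print.skm2_params <- function(x, ...) {
  cat("SKM2 parameters: kappa =", format(x$kappa),
      " beta =", format(x$beta), "\n")
  invisible(x)
}

#' Convert dimensional rate constants to the model's dimensionless groups
#'
#' Applies the model's non-dimensionalisation conventions: concentrations
#' are scaled by the maximal HIF-alpha level `ks_H / kd_H` (the level
#' approached in the absence of oxygen-dependent degradation), first-order
#' rates by the basal HIF-alpha degradation rate constant `kd_H`, and oxygen
#' by the Michaelis constant of PHD for oxygen.
#'
#' @param ks_H,kd_H HIF-alpha synthesis rate and basal degradation rate
#'   constant (`kd_H > 0`).
#' @param kd_A ARD protein degradation rate constant (> 0).
#' @param P_tot,F_tot,A_tot total PHD, FIH and FIH-target repeat
#'   concentrations (same units as `ks_H / kd_H`).
#' @param kcat_P,kcat_FH,kcat_FA turnover numbers for ODD-, CAD- and
#'   AR-hydroxylation.
#' @param KD_P,KD_FH,KD_FA dissociation constants (concentration units).
#' @param KM_P_O2,KM_F_O2 Michaelis constants of PHD and FIH for oxygen.
#' @param KD_HRE HIF/HRE dissociation constant.
#' @param gamma relative FIH affinity for hydroxylated repeats.
#' @return A `"full_params"` object.
#' @examples
#' p <- nondimensionalize(ks_H = 1, kd_H = 0.1, kd_A = 0.02,
#'                        P_tot = 2, F_tot = 10, A_tot = 1000,
#'                        kcat_P = 50, kcat_FH = 50, kcat_FA = 50,
#'                        KD_P = 10, KD_FH = 10, KD_FA = 10,
#'                        KM_P_O2 = 250, KM_F_O2 = 82.5,
#'                        KD_HRE = 3, gamma = 0.02)
#' p$alpha    # 0.33
#' @export
nondimensionalize <- function(ks_H, kd_H, kd_A,
                              P_tot, F_tot, A_tot,
                              kcat_P, kcat_FH, kcat_FA,
                              KD_P, KD_FH, KD_FA,
                              KM_P_O2, KM_F_O2,
                              KD_HRE, gamma = 0) {
  if (kd_H <= 0 || kd_A <= 0)
    stop("degradation rate constants kd_H and kd_A must be > 0")
  if (ks_H <= 0) stop("ks_H must be > 0")
  H_max <- ks_H / kd_H
  full_params(P_tot = P_tot / H_max, KD_P = KD_P / H_max,
              kcat_P = kcat_P / kd_H,
              F_tot = F_tot / H_max, KD_FH = KD_FH / H_max,
              kcat_FH = kcat_FH / kd_H, omega = kcat_FH / kcat_FA,
              alpha = KM_F_O2 / KM_P_O2,
              A_tot = A_tot / H_max, KD_FA = KD_FA / H_max,
              gamma = gamma, epsilon = kd_H / kd_A,
              KD_HRE = KD_HRE / H_max)
}

#' SKM2 parameters from dimensional quantities
#'
#' `kappa = A_tot / KD_FA` and `beta = kcat_FA * F_tot / (kd_A * A_tot)`.
#' The reduced model normalises the repeat pool to `A_tot`, so `A_tot = 0`
#' leaves `beta` undefined and is rejected.
#'
#' @param A_tot total FIH-target repeat concentration (> 0).
#' @param KD_FA FIH/repeat dissociation constant (> 0).
#' @param kcat_FA AR-hydroxylation turnover number.
#' @param F_tot total FIH concentration.
#' @param kd_A ARD protein degradation rate constant (> 0).
#' @return An `"skm2_params"` object.
#' @export
skm2_from_dimensional <- function(A_tot, KD_FA, kcat_FA, F_tot, kd_A) {
  if (A_tot <= 0)
    stop("SKM2 is undefined for A_tot = 0 (beta has A_tot in its ",
         "denominator); use the Full Model with A_tot = 0 instead")
  if (kd_A <= 0) stop("kd_A must be > 0")
  skm2_params(kappa = A_tot / KD_FA,
              beta = kcat_FA * F_tot / (kd_A * A_tot))
}

#' Convert between the two oxygen conventions
#'
#' The Full Model and SKM1 express oxygen relative to the Michaelis constant
#' of PHD for oxygen ("tilde" convention); SKM2 expresses it relative to the
#' Michaelis constant of FIH for oxygen ("bar" convention). The two are
#' related through `alpha = KM_F / KM_P`: `o_bar = o_tilde / alpha`.
#'
#' @param o_tilde,o_bar oxygen in the respective convention (>= 0).
#' @param alpha ratio of the FIH to the PHD Michaelis constant for oxygen.
#' @return Oxygen in the other convention.
#' @export
oxygen_tilde_to_bar <- function(o_tilde, alpha) {
  stopifnot(all(o_tilde >= 0), alpha > 0)
  o_tilde / alpha
}

#' @rdname oxygen_tilde_to_bar
#' @export
oxygen_bar_to_tilde <- function(o_bar, alpha) {
  stopifnot(all(o_bar >= 0), alpha > 0)
  o_bar * alpha
}
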