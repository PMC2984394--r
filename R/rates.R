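#' Free (unbound) substrate under tight-binding equilibrium
#'
#' Solves the binding conservation relation
#' `s_free + e_tot * s_free / (kd + s_free) = s_tot` for the free substrate
#' concentration, i.e. the positive root of
#' `s^2 + (kd + e_tot - s_tot) * s - kd * s_tot = 0`. Unlike the
#' Michaelis-Menten approximation this remains valid when the enzyme is not
#' in trace amounts relative to its substrate, the typical situation in
#' protein-protein interaction networks.
#'
#' @param s_tot total substrate concentration (>= 0).
#' @param e_tot total enzyme concentration (>= 0).
#' @param kd dissociation constant of the enzyme-substrate complex (> 0).
#' @return Free substrate concentration, in
#'   `[max(0, s_tot - e_tot), s_tot]`. Vectorised over its arguments.
#' @examples
#' free_substrate(1, 0.2, 1)   # ~0.905
#' free_substrate(1, 0, 1)     # 1: nothing bound
#' @export
free_substrate <- function(s_tot, e_tot, kd) {
  if (any(s_tot < 0) || any(e_tot < 0)) stop("s_tot and e_tot must be >= 0")
  if (any(kd <= 0)) stop("kd must be > 0")
  b <- kd + e_tot - s_tot
  # discriminant clamped at 0: rounding can push it negative when
  # s_tot ~ e_tot and kd -> 0
  disc <- sqrt(pmax(b * b + 4 * kd * s_tot, 0))
  # pick the cancellation-free expression for the positive root
  ifelse(b > 0, 2 * kd * s_tot / (b + disc), 0.5 * (disc - b))
}

#' Ankyrin-inflated competitive inhibition constant for FIH/HIF-alpha binding
#'
#' Both unhydroxylated repeats (`a_hat`) and, with relative affinity
#' `gamma`, hydroxylated repeats (`a_oh_hat`) compete with HIF-alpha for
#' FIH. Competition inflates the apparent FIH/HIF-alpha dissociation
#' constant to
#' `KD_FH * (1 + a_hat / KD_FA + gamma * a_oh_hat / KD_FA)`.
#'
#' @param a_hat unhydroxylated FIH-target repeats (>= 0).
#' @param a_oh_hat hydroxylated FIH-target repeats (>= 0).
#' @param p a [full_params()] object.
#' @return The apparent inhibition constant (equals `KD_FH` when both repeat
#'   pools are zero).
#' @export
ki_fh <- function(a_hat, a_oh_hat, p) {
  if (any(a_hat < 0) || any(a_oh_hat < 0))
    stop("repeat pools must be >= 0")
  p$KD_FH * (1 + a_hat / p$KD_FA + p$gamma * a_oh_hat / p$KD_FA)
}

#' Hydroxylation rate functions of the Full Model
#'
#' `nu_p()` is the PHD-dependent ODD-hydroxylation rate, `nu_fh()` the
#' FIH-dependent CAD-hydroxylation rate in the presence of competing
#' ankyrin repeats, and `nu_fa()` the FIH-dependent AR-hydroxylation rate in
#' the presence of competing HIF-alpha. All three use tight-binding
#' (free-substrate) kinetics for HIF-alpha binding; AR-hydroxylation uses
#' the Michaelis-Menten approximation, justified by the expected excess of
#' ARD proteins over FIH. Rates are per unit of non-hydroxylated substrate
#' and saturate hyperbolically in oxygen (`o / (1 + o)` for PHD,
#' `o / (alpha + o)` for FIH, with oxygen in the "tilde" convention).
#'
#' @param state named numeric vector with elements `H_tot` (all HIF-alpha),
#'   `H` (non-CAD-hydroxylated HIF-alpha) and `A` (unhydroxylated repeats).
#' @param o_tilde oxygen relative to the PHD Michaelis constant (>= 0).
#' @param p a [full_params()] object.
#' @return The corresponding specific hydroxylation rate (>= 0).
#' @seealso [free_substrate()], [ki_fh()], [rhs_full()]
#' @export
nu_p <- function(state, o_tilde, p) {
  full_rates(state, o_tilde, p)$nu_P
}

#' @rdname nu_p
#' @export
nu_fh <- function(state, o_tilde, p) {
  full_rates(state, o_tilde, p)$nu_FH
}

#' @rdname nu_p
#' @export
nu_fa <- function(state, o_tilde, p) {
  full_rates(state, o_tilde, p)$nu_FA
}

#' All Full-Model rate terms at a state
#'
#' Computes, in one pass, the free-substrate pools, the ankyrin-inflated
#' inhibition constant and the three hydroxylation rate functions.
#'
#' @inheritParams nu_p
#' @return A list with elements `H_P` (PHD-free HIF-alpha), `Ki_FH`,
#'   `H_F` (FIH-free non-CAD-hydroxylated HIF-alpha), `nu_P`, `nu_FH`,
#'   `nu_FA`.
#' @export
full_rates <- function(state, o_tilde, p) {
  if (o_tilde < 0) stop("oxygen must be >= 0")
  H_tot <- max(state[["H_tot"]], 0)
  H <- max(state[["H"]], 0)
  A <- min(max(state[["A"]], 0), p$A_tot)
  A_OH <- p$A_tot - A

  H_P <- free_substrate(H_tot, p$P_tot, p$KD_P)
  Ki <- ki_fh(A, A_OH, p)
  H_F <- free_substrate(H, p$F_tot, Ki)

  o_P <- o_tilde / (1 + o_tilde)
  o_F <- o_tilde / (p$alpha + o_tilde)

  nu_P <- p$kcat_P * p$P_tot / (p$KD_P + H_P + p$P_tot) * o_P
  nu_FH <- p$kcat_FH * p$F_tot / (Ki + H_F + p$F_tot) * o_F
  nu_FA <- p$kcat_FA * p$F_tot /
    (p$KD_FA * (1 + H_F / p$KD_FH) + A + p$gamma * A_OH) * o_F

  list(H_P = H_P, Ki_FH = Ki, H_F = H_F,
       nu_P = nu_P, nu_FH = nu_FH, nu_FA = nu_FA)
}

#' Right-hand sides of the three kinetic models
#'
#' `rhs_full()` gives the time derivatives of `(H_tot, H, A)` for the Full
#' Model: constant (unit) HIF-alpha synthesis, basal turnover, removal of
#' ODD-hydroxylated HIF-alpha, conversion of `H` by CAD-hydroxylation, and
#' ARD protein turnover slowed by the stability ratio `epsilon`. Time is in
#' units of the mean HIF-alpha lifetime in the absence of oxygen.
#'
#' `rhs_skm1()` is the two-variable reduction ignoring ankyrin repeats, with
#' Michaelis-Menten hydroxylation kinetics.
#'
#' `rhs_skm2()` is the one-variable FIH/ARD reduction: `a_hat` is the
#' fraction of repeats unhydroxylated, oxygen is in the "bar" convention,
#' and time is in units of the mean ARD protein lifetime.
#'
#' @inheritParams nu_p
#' @return Named numeric vector of derivatives matching the model's state.
#' @examples
#' p <- full_params()
#' rhs_full(c(H_tot = 1, H = 1, A = p$A_tot), 0, p)  # anoxic fixed point
#' @export
rhs_full <- function(state, o_tilde, p) {
  if (p$epsilon <= 0) stop("epsilon must be > 0")
  r <- full_rates(state, o_tilde, p)
  H_tot <- state[["H_tot"]]; H <- state[["H"]]; A <- state[["A"]]
  c(H_tot = 1 - H_tot * (1 + r$nu_P),
    H = 1 - H * (1 + r$nu_P + r$nu_FH),
    A = (p$A_tot - A * (1 + p$epsilon * r$nu_FA)) / p$epsilon)
}

#' @rdname rhs_full
#' @export
rhs_skm1 <- function(state, o_tilde, p) {
  if (o_tilde < 0) stop("oxygen must be >= 0")
  H_tot <- max(state[["H_tot"]], 0)
  H <- max(state[["H"]], 0)
  nu_P <- p$kcat_P * p$P_tot / (p$KD_P + H_tot) * o_tilde / (1 + o_tilde)
  nu_FH <- p$kcat_FH * p$F_tot / (p$KD_FH + H) *
    o_tilde / (p$alpha + o_tilde)
  c(H_tot = 1 - state[["H_tot"]] * (1 + nu_P),
    H = 1 - state[["H"]] * (1 + nu_P + nu_FH))
}

#' @rdname rhs_full
#' @param a_hat fraction of FIH-target repeats that is unhydroxylated, in
#'   `[0, 1]` (SKM2 state).
#' @param o_bar oxygen relative to the FIH Michaelis constant (>= 0).
#' @param q an [skm2_params()] object.
#' @export
rhs_skm2 <- function(a_hat, o_bar, q) {
  if (o_bar < 0) stop("oxygen must be >= 0")
  a <- min(max(a_hat, 0), 1)
  c(A = 1 - a_hat -
      q$beta * q$kappa * a / (1 + q$kappa * a) * o_bar / (1 + o_bar))
}

#' Fraction of FIH not sequestered by ARD proteins (SKM2)
#'
#' @param a_hat fraction of repeats unhydroxylated (>= 0).
#' @param q an [skm2_params()] object.
#' @return `1 / (1 + kappa * a_hat)`.
#' @examples
#' f_free(1, skm2_params(10, 50))   # anoxic sequestration floor, 1/11
#' @export
f_free <- function(a_hat, q) {
  if (any(a_hat < 0)) stop("a_hat must be >= 0")
  1 / (1 + q$kappa * a_hat)
}

#' Fraction of free FIH in the Full Model
#'
#' The Full Model does not carry free FIH as a dynamical species; the
#' fraction of FIH bound to neither HIF-alpha nor (un)hydroxylated repeats
#' follows from the same equilibrium-binding algebra as the rate laws:
#' `F_free = 1 / (1 + H_F/KD_FH + A/KD_FA + gamma * A_OH/KD_FA)
#'         = KD_FH / (Ki_FH + H_F)`,
#' which reduces to the SKM2 expression `1 / (1 + kappa * a_hat)` when
#' HIF-alpha is absent and `gamma = 0`.
#'
#' @inheritParams nu_p
#' @return Fraction of unbound FIH in `[0, 1]`.
#' @export
f_free_full <- function(state, p) {
  r <- full_rates(state, 0, p)
  p$KD_FH / (r$Ki_FH + r$H_F)
}
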