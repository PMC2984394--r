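#' Numerical data behind the standard analysis panels
#'
#' Recomputes, as plain data frames, the signal/response curves and time
#' courses of the package's standard analyses, suitable for plotting or CSV
#' export. Panels:
#' \describe{
#'   \item{`skm1_scan`}{SKM1 steady states while FIH's oxygen affinity is
#'     varied (`alpha` in `{1, 0.33, 0.1}`), showing how higher FIH
#'     activity shifts non-CAD-hydroxylated HIF-alpha to lower oxygen.}
#'   \item{`skm1_hre`}{SKM1 HRE occupancies and gene-expression regimes at
#'     `alpha = 0.33`.}
#'   \item{`skm2_kappa`, `skm2_beta`}{SKM2 steady-state curves varying the
#'     sequestration capacity at fixed efficiency, and vice versa.}
#'   \item{`skm2_reox_kappa`, `skm2_reox_beta`}{SKM2 reoxygenation time
#'     courses (equilibrated at `o_bar = 0.01`, stepped to `0.5`).}
#'   \item{`full_atot`, `full_gamma`, `full_epsilon`}{Full-Model scans
#'     varying the repeat pool size, the product-binding affinity ratio and
#'     the ARD stability ratio.}
#'   \item{`full_timecourses`}{Full-Model reoxygenation and hypoxia time
#'     courses with and without the FIH/AR interaction, from severe
#'     (`o_tilde = 0.001`) and moderate (`0.01`) hypoxia.}
#' }
#'
#' @param panel panel name (see Details).
#' @param n_oxygen grid size of steady-state scans.
#' @return A long-format data frame; the varied quantity is in a `curve`
#'   column.
#' @export
figure_data <- function(panel = c("skm1_scan", "skm1_hre", "skm2_kappa",
                                  "skm2_beta", "skm2_reox_kappa",
                                  "skm2_reox_beta", "full_atot",
                                  "full_gamma", "full_epsilon",
                                  "full_timecourses"),
                        n_oxygen = 60) {
  panel <- match.arg(panel)
  o_full <- oxygen_grid(1e-4, 1, n_oxygen)
  o_skm2 <- oxygen_grid(1e-4, 10, n_oxygen)
  skm1_p <- function(alpha)
    full_params(P_tot = 1, kcat_P = 100, F_tot = 1, kcat_FH = 100,
                alpha = alpha, A_tot = 0, gamma = 0, epsilon = 1)
  fig6_p <- function(A_tot)
    full_params(A_tot = A_tot, gamma = 0.02, epsilon = 5)

  bind_curves <- function(values, fun, label) {
    do.call(rbind, lapply(values, function(v) {
      df <- fun(v)
      cbind(curve = paste0(label, "=", v), df)
    }))
  }

  switch(panel,
    skm1_scan = bind_curves(c(1, 0.33, 0.1), function(a) {
      as.data.frame(response_scan("skm1", skm1_p(a), o_full))
    }, "alpha"),
    skm1_hre = {
      rc <- response_scan("skm1", skm1_p(0.33), o_full)
      cbind(as.data.frame(rc), gene_regimes(rc)[-1])
    },
    skm2_kappa = bind_curves(c(3, 10, 30, 100), function(k)
      as.data.frame(response_scan("skm2", skm2_params(k, 100), o_skm2)),
      "kappa"),
    skm2_beta = bind_curves(c(20, 50, 100, 200), function(b)
      as.data.frame(response_scan("skm2", skm2_params(30, b), o_skm2)),
      "beta"),
    skm2_reox_kappa = bind_curves(c(3, 10, 30, 100), function(k)
      as.data.frame(equilibrate_then_step("skm2", skm2_params(k, 100),
                                          0.01, 0.5, duration = 3,
                                          step = 0.005)), "kappa"),
    skm2_reox_beta = bind_curves(c(20, 50, 100, 200), function(b)
      as.data.frame(equilibrate_then_step("skm2", skm2_params(30, b),
                                          0.01, 0.5, duration = 3,
                                          step = 0.005)), "beta"),
    full_atot = bind_curves(c(0, 20, 100, 500), function(a)
      as.data.frame(response_scan("full",
        full_params(A_tot = a, gamma = 0, epsilon = 5), o_full)), "A_tot"),
    full_gamma = bind_curves(c(0, 0.02, 0.1), function(g)
      as.data.frame(response_scan("full",
        full_params(A_tot = 100, gamma = g, epsilon = 5), o_full)),
      "gamma"),
    full_epsilon = bind_curves(c(1, 5, 10), function(e)
      as.data.frame(response_scan("full",
        full_params(A_tot = 100, gamma = 0.02, epsilon = e), o_full)),
      "epsilon"),
    full_timecourses = {
      cases <- expand.grid(A_tot = c(0, 100), severe = c(TRUE, FALSE),
                           direction = c("reoxygenation", "hypoxia"),
                           stringsAsFactors = FALSE)
      # hypoxia responses are shown for the interacting system only
      cases <- cases[!(cases$direction == "hypoxia" & cases$A_tot == 0), ]
      do.call(rbind, lapply(seq_len(nrow(cases)), function(i) {
        cs <- cases[i, ]
        hyp <- if (cs$severe) 0.001 else 0.01
        from <- if (cs$direction == "reoxygenation") hyp else 0.5
        to <- if (cs$direction == "reoxygenation") 0.5 else hyp
        tr <- equilibrate_then_step("full", fig6_p(cs$A_tot), from, to,
                                    duration = 60, step = 0.02)
        cbind(curve = sprintf("%s A_tot=%g from O=%g", cs$direction,
                              cs$A_tot, from),
              as.data.frame(tr))
      }))
    })
}
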