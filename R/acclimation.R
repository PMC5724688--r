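# Photo-acclimation: each leaf distributes its photosynthetic nitrogen
# between capacity (Rubisco + CE + ETCF) and light capture (photosystems +
# antenna) so as to maximize its daily carbon uptake under its own diurnal
# growth light.  The search is one-dimensional: a capacity-vs-capture split,
# with the within-side composition held at the reference stoichiometry so the
# linearised pool relations apply jointly.

# nitrogen shares of each group at the reference composition
side_shares <- function(relations) {
  ref_n <- nitrogen_of_pools(relations$reference, relations$kinetics)$per_group
  cap <- c(rubisco = ref_n$rubisco, ce = ref_n$ce, etcf = ref_n$etcf)
  ps <- c(psii = ref_n$psii, psi = ref_n$psi, lhcii = ref_n$lhcii,
          lhci = ref_n$lhci)
  list(cap = cap / sum(cap), ps = ps / sum(ps))
}

# g N per unit pool for each group
n_per_unit <- function(kinetics) {
  kk <- kinetics
  f <- kk$n_frac_protein
  c(rubisco = f, ce = f, etcf = f,
    psii = kk$mw_psii * f * 1e-6 + kk$core_chl_psii * kk$chl_n_per_umol,
    psi = kk$mw_psi * f * 1e-6 + kk$core_chl_psi * kk$chl_n_per_umol,
    lhcii = kk$mw_lhc * f * 1e-6 + kk$chl_per_lhc * kk$chl_n_per_umol,
    lhci = kk$mw_lhc * f * 1e-6 + kk$chl_per_lhc * kk$chl_n_per_umol)
}

# pools realised by allocating x of total_n to the capacity side
# (x and total_n may be parallel vectors: one leaf per element)
pools_at_split <- function(x, total_n, relations) {
  sh <- side_shares(relations)
  npu <- n_per_unit(relations$kinetics)
  n_cap <- x * total_n
  n_ps <- (1 - x) * total_n
  enzyme_pools(rubisco = n_cap * sh$cap[["rubisco"]] / npu[["rubisco"]],
               ce = n_cap * sh$cap[["ce"]] / npu[["ce"]],
               etcf = n_cap * sh$cap[["etcf"]] / npu[["etcf"]],
               psii = n_ps * sh$ps[["psii"]] / npu[["psii"]],
               psi = n_ps * sh$ps[["psi"]] / npu[["psi"]],
               lhcii = n_ps * sh$ps[["lhcii"]] / npu[["lhcii"]],
               lhci = n_ps * sh$ps[["lhci"]] / npu[["lhci"]])
}

rel_coef <- function(relations, pool) {
  row <- relations$coef[relations$coef$pool == pool, ]
  c(a = row$a, b = row$b)
}

# Gross light-saturated rate the PSII complement can sustain (the electron
# throughput cap of the reaction centres themselves); keeps the frontier
# consistent with the mechanistic leaf model at photosystem-starved splits.
pmax_psii_cap <- function(psii, kinetics) {
  kk <- kinetics
  kk$k_psii * psii / 4 * (kk$ci - kk$gamma_star) / (kk$ci + 2 * kk$gamma_star)
}

#' P_max / phi trade-off frontier at fixed nitrogen
#'
#' Sweeps the allocation split `x` (fraction of the nitrogen budget in the
#' capacity pools) and converts each split into `(P_max, phi)` through the
#' calibrated linear relations, Rubisco/CE/ETCF co-scaling so the three
#' P_max relations stay jointly consistent.  The frontier is monotone:
#' larger `x` buys P_max at the cost of phi.
#'
#' @param total_n Photosynthetic nitrogen budget, g N m-2.
#' @param relations A [calibrate_linear_relations()] result.
#' @param n_points Number of frontier points.
#' @param x_range Range of the capacity share searched.
#' @return Data frame of class `pmax_phi_frontier`: `x`, `p_max`, `phi`,
#'   pool columns, and `n_total` (the per-point nitrogen audit).
#' @export
pmax_phi_frontier <- function(total_n, relations, n_points = 50,
                              x_range = c(0.05, 0.95)) {
  stopifnot(total_n > 0, n_points >= 2)
  xs <- seq(x_range[1], x_range[2], length.out = n_points)
  c1 <- rel_coef(relations, "rubisco")
  c4 <- rel_coef(relations, "psii")
  rows <- lapply(xs, function(x) {
    p <- pools_at_split(x, total_n, relations)
    data.frame(x = x,
               p_max = max(0.05, min(c1[["a"]] * p$rubisco + c1[["b"]],
                                     pmax_psii_cap(p$psii,
                                                   relations$kinetics))),
               phi = min(0.1249, max(1e-4, c4[["a"]] * p$psii + c4[["b"]])),
               rubisco = p$rubisco, ce = p$ce, etcf = p$etcf, psii = p$psii,
               psi = p$psi, lhcii = p$lhcii, lhci = p$lhci,
               n_total = nitrogen_of_pools(p, relations$kinetics)$total)
  })
  out <- do.call(rbind, rows)
  # beyond the PSII-cap peak further capacity investment is dominated
  # (both P_max and phi fall): prune so the frontier is a true trade-off
  out <- out[seq_len(which.max(out$p_max)), , drop = FALSE]
  class(out) <- c("pmax_phi_frontier", "data.frame")
  out
}

#' Daily carbon uptake of a light response under a diurnal course
#'
#' Rectangle-rule time integration (the course is a fixed-step grid) of the
#' nonrectangular hyperbola over the supplied diurnal PPFD curve.
#'
#' @param resp A [light_response()].
#' @param diurnal_ppfd Data frame with columns `hour` (fixed step) and
#'   `ppfd` (umol m-2 s-1).
#' @return Daily carbon uptake, mol CO2 m-2 per the covered span.
#' @export
daily_carbon <- function(resp, diurnal_ppfd) {
  if (!nrow(diurnal_ppfd)) stop("empty diurnal curve")
  h <- diurnal_ppfd$hour
  dt <- if (length(h) > 1) h[2] - h[1] else 1
  sum(nrh_predict(resp, diurnal_ppfd$ppfd)) * dt * 3600 * 1e-6
}

#' Optimal acclimation of one leaf
#'
#' Evaluates [daily_carbon()] over the [pmax_phi_frontier()] grid and
#' returns the argmax; ties break toward lower P_max (the
#' minimal-capacity-investment end).
#'
#' @param total_n Photosynthetic nitrogen budget, g N m-2.
#' @param diurnal_ppfd Data frame `hour`, `ppfd` of the leaf's growth light.
#' @param relations A [calibrate_linear_relations()] result.
#' @param grid_size Frontier grid resolution (>= 10).
#' @param x_range Capacity-share search range.
#' @return Object of class `acclimation_result`: `p_max_opt`, `phi_opt`,
#'   `pools`, `daily_carbon`, `x_opt`, `frontier`.
#' @export
optimize_acclimation <- function(total_n, diurnal_ppfd, relations,
                                 grid_size = 50, x_range = c(0.05, 0.95)) {
  stopifnot(grid_size >= 10)
  fr <- pmax_phi_frontier(total_n, relations, grid_size, x_range)
  dc <- vapply(seq_len(nrow(fr)), function(i) {
    daily_carbon(light_response(fr$p_max[i], fr$phi[i], relations$theta,
                                relations$r_d), diurnal_ppfd)
  }, 0)
  best <- which.max(dc)   # frontier is ordered by increasing p_max:
                          # first max is the lower-capacity tie-break
  pools <- enzyme_pools(fr$rubisco[best], fr$ce[best], fr$etcf[best],
                        fr$psii[best], fr$psi[best], fr$lhcii[best],
                        fr$lhci[best])
  structure(list(p_max_opt = fr$p_max[best], phi_opt = fr$phi[best],
                 pools = pools, daily_carbon = dc[best], x_opt = fr$x[best],
                 frontier = cbind(fr, daily_carbon = dc)),
            class = "acclimation_result")
}

#' @export
print.acclimation_result <- function(x, ...) {
  cat(sprintf("<acclimation_result> P_max %.2f, phi %.4f (x = %.2f), daily C %.4f mol m-2\n",
              x$p_max_opt, x$phi_opt, x$x_opt, x$daily_carbon))
  invisible(x)
}

#' Reallocate nitrogen when changing chlorophyll through the antenna
#'
#' Reduces (or grows) the peripheral antenna to hit `target_chl`
#' (antenna-size route, reaction-centre numbers fixed), then applies one of
#' the two nitrogen strategies: `lhc_only` leaves every other pool untouched
#' (leaf nitrogen changes by the LHC delta); `constant_total_n` spreads the
#' freed nitrogen over all non-LHC pools proportionally to their existing
#' nitrogen shares, conserving total photosynthetic nitrogen.
#'
#' @param pools An [enzyme_pools()].
#' @param target_chl Target chlorophyll, umol m-2 (>= the core-only bound).
#' @param strategy `"lhc_only"` or `"constant_total_n"`.
#' @param kinetics A [kinetic_params()].
#' @return Modified [enzyme_pools()].
#' @export
reallocate_nitrogen <- function(pools, target_chl,
                                strategy = c("lhc_only", "constant_total_n"),
                                kinetics = kinetic_params()) {
  strategy <- match.arg(strategy)
  n_before <- nitrogen_of_pools(pools, kinetics)$total
  out <- modify_chlorophyll(pools, target_chl, "antenna_size", kinetics)
  if (strategy == "lhc_only") return(out)
  n_after <- nitrogen_of_pools(out, kinetics)
  delta <- n_before - n_after$total
  per <- n_after$per_group
  n_non_lhc <- per$rubisco + per$ce + per$etcf + per$psii + per$psi
  lambda <- 1 + delta / n_non_lhc
  if (any(lambda < 0)) stop("infeasible target: non-LHC pools cannot absorb the change")
  for (g in c("rubisco", "ce", "etcf", "psii", "psi"))
    out[[g]] <- out[[g]] * lambda
  out
}
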