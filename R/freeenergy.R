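#' Forward and reverse work samples
#'
#' Work values (kJ/mol) measured for a transformation A to B in the forward
#' direction and B to A in the reverse direction, e.g. decoupling a solute
#' from its solvent in an alchemical simulation. Both directions are needed
#' for the Bennett Acceptance Ratio estimator; the two work distributions
#' must overlap for the estimate to be informative.
#'
#' @param forward Forward (A to B) work values, kJ/mol; nonempty.
#' @param reverse Reverse (B to A) work values, kJ/mol; nonempty.
#' @param temperature Temperature in K (default 298).
#' @return An object of class `ilx_work_samples`.
#' @export
work_samples <- function(forward, reverse, temperature = 298) {
  .check_number(forward, "forward")
  .check_number(reverse, "reverse")
  .check_number(temperature, "temperature", lower = 0, strict_lower = TRUE)
  structure(list(forward = as.numeric(forward),
                 reverse = as.numeric(reverse),
                 temperature = temperature),
            class = "ilx_work_samples")
}

#' @rdname work_samples
#' @param path Path to a CSV with header `direction,work_kj_per_mol`,
#'   direction one of `forward`, `reverse`.
#' @export
read_work_samples <- function(path, temperature = 298) {
  if (!file.exists(path)) .stop_parse("file not found: ", path)
  df <- tryCatch(read.csv(path, colClasses = "character", check.names = FALSE),
                 error = function(e) .stop_parse("cannot read ", path, ": ",
                                                 conditionMessage(e)))
  need <- c("direction", "work_kj_per_mol")
  if (!identical(names(df), need)) {
    .stop_parse(path, ": expected header '", paste(need, collapse = ","), "'")
  }
  bad <- which(!df$direction %in% c("forward", "reverse"))
  if (length(bad)) {
    .stop_parse(path, ": invalid direction '", df$direction[bad[1]],
                "' at line ", bad[1] + 1L)
  }
  w <- suppressWarnings(as.numeric(df$work_kj_per_mol))
  badw <- which(is.na(w))
  if (length(badw)) {
    .stop_parse(path, ": malformed value '", df$work_kj_per_mol[badw[1]],
                "' in column work_kj_per_mol at line ", badw[1] + 1L)
  }
  work_samples(w[df$direction == "forward"], w[df$direction == "reverse"],
               temperature = temperature)
}

#' @rdname work_samples
#' @param w A work-samples object.
#' @export
write_work_samples <- function(w, path) {
  stopifnot(inherits(w, "ilx_work_samples"))
  .write_csv_full(data.frame(
    direction = c(rep("forward", length(w$forward)),
                  rep("reverse", length(w$reverse))),
    work_kj_per_mol = c(w$forward, w$reverse)), path)
}

#' Bennett Acceptance Ratio free-energy estimate
#'
#' Solves the BAR self-consistent equation for the free-energy difference
#' `dG` between the end states,
#' \deqn{\sum_{i}^{n_F} \frac{1}{1 + e^{M + \beta(W_{F,i} - \Delta G)}} =
#'       \sum_{j}^{n_R} \frac{1}{1 + e^{-M + \beta(W_{R,j} + \Delta G)}},}
#' with `M = log(n_F/n_R)` the standard offset for unequal sample sizes and
#' `beta = 1/(kB T)`. The left side increases and the right decreases in
#' `dG`, so the root is unique; it is found by bisection-safeguarded root
#' search bracketed by the two exponential-averaging estimates. The
#' uncertainty is the asymptotic (maximum-likelihood) variance
#' \deqn{\mathrm{var}(\Delta G) = \beta^{-2}\left[\Big(\sum_i f_i(1-f_i)\Big)^{-1}
#'   - n_F^{-1} - n_R^{-1}\right]}
#' over the pooled samples, which diverges when the forward and negated
#' reverse work distributions do not overlap — reported as an overlap error.
#'
#' @param w An [work_samples()] object.
#' @param tol Convergence tolerance on `dG` in kJ/mol (default 1e-10).
#' @return An object of class `ilx_bar_estimate`: list with `dg` (kJ/mol),
#'   `uncertainty` (kJ/mol), `n_forward`, `n_reverse`, `temperature`,
#'   `overlap` (the pooled Fermi-information sum, larger is better).
#' @examples
#' w <- work_samples(forward = 10.5, reverse = -10.5)
#' bar_estimate(w)$dg # 10.5 exactly for a symmetric pair
#' @export
bar_estimate <- function(w, tol = 1e-10) {
  stopifnot(inherits(w, "ilx_work_samples"))
  beta <- 1 / (.kB * w$temperature)
  wf <- w$forward
  wr <- w$reverse
  nf <- length(wf)
  nr <- length(wr)
  M <- log(nf / nr)

  # g(dG) = sum_F fermi(...) - sum_R fermi(...), increasing in dG
  g <- function(dg) {
    sum(plogis(-(M + beta * (wf - dg)))) -
      sum(plogis(-(-M + beta * (wr + dg))))
  }

  bounds <- exp_average_estimates(w)
  lo <- min(bounds$forward, bounds$reverse) - 1 / beta
  hi <- max(bounds$forward, bounds$reverse) + 1 / beta
  tries <- 0
  while (g(lo) > 0 && tries < 200) { lo <- lo - 10 / beta; tries <- tries + 1 }
  while (g(hi) < 0 && tries < 400) { hi <- hi + 10 / beta; tries <- tries + 1 }
  if (g(lo) > 0 || g(hi) < 0) {
    stop(errorCondition("BAR root bracketing failed: work distributions may not overlap",
                        class = c("ilx_convergence_error", "ilx_error")))
  }
  root <- uniroot(g, c(lo, hi), tol = tol, maxiter = 2000)
  dg <- root$root

  # pooled Fermi information; pooled works enter as W_F and -W_R
  x <- c(M + beta * (wf - dg), M - beta * (wr + dg))
  f <- plogis(-x)
  info <- sum(f * (1 - f))
  if (info < 1e-8 * (nf + nr)) {
    stop(errorCondition(
      "work distributions do not overlap: BAR variance estimator diverges",
      class = c("ilx_overlap_error", "ilx_error")))
  }
  var_dg <- (1 / info - 1 / nf - 1 / nr) / beta^2
  if (!is.finite(var_dg) || var_dg < 0) var_dg <- 1 / (info * beta^2)

  structure(list(dg = dg, uncertainty = sqrt(var_dg),
                 n_forward = nf, n_reverse = nr,
                 temperature = w$temperature, overlap = info),
            class = "ilx_bar_estimate")
}

#' @export
print.ilx_bar_estimate <- function(x, ...) {
  cat(sprintf(
    "BAR estimate: dG = %.6g +/- %.3g kJ/mol (n_F = %d, n_R = %d, T = %g K)\n",
    x$dg, x$uncertainty, x$n_forward, x$n_reverse, x$temperature))
  invisible(x)
}

#' Exponential-averaging (one-sided) free-energy estimates
#'
#' Jarzynski-style estimates from each direction alone, computed with a
#' log-sum-exp for numerical stability:
#' `dG_F = -kT log mean(exp(-beta W_F))` and
#' `dG_R = +kT log mean(exp(-beta W_R))`. In expectation the forward
#' estimate overshoots and the reverse undershoots the true free-energy
#' difference, bracketing the (nearly unbiased) BAR estimate; on a single
#' finite sample the one-sided estimators are heavy-tailed and can land on
#' the same side of it. They are mainly useful as cheap diagnostics of
#' directional bias.
#'
#' @param w An [work_samples()] object.
#' @return List with elements `forward` and `reverse` (kJ/mol).
#' @export
exp_average_estimates <- function(w) {
  stopifnot(inherits(w, "ilx_work_samples"))
  beta <- 1 / (.kB * w$temperature)
  lse <- function(x) { m <- max(x); m + log(mean(exp(x - m))) }
  list(forward = -lse(-beta * w$forward) / beta,
       reverse = lse(-beta * w$reverse) / beta)
}

#' Free-energy leg of a thermodynamic cycle
#'
#' One estimated free-energy change (e.g. decoupling a solute from water)
#' with its uncertainty.
#'
#' @param label Text label, e.g. `"decouple-in-water"`.
#' @param dg Free-energy change in kJ/mol.
#' @param uncertainty One-sigma uncertainty in kJ/mol (>= 0).
#' @param solute Solute label (used to check cycle consistency).
#' @return An object of class `ilx_fe_leg`.
#' @export
free_energy_leg <- function(label, dg, uncertainty, solute = "") {
  .check_number(dg, "dg")
  .check_number(uncertainty, "uncertainty", lower = 0)
  structure(list(label = as.character(label)[1], dg = dg,
                 uncertainty = uncertainty,
                 solute = as.character(solute)[1]),
            class = "ilx_fe_leg")
}

#' @export
print.ilx_fe_leg <- function(x, ...) {
  cat(sprintf("%s%s: dG = %.1f +/- %.1f kJ/mol\n",
              x$label, if (nzchar(x$solute)) paste0(" (", x$solute, ")") else "",
              x$dg, x$uncertainty))
  invisible(x)
}

#' Water-to-ionic-liquid transfer cycle
#'
#' Combines two decoupling legs for the same solute into a transfer free
#' energy. Decoupling from water and re-coupling into the ionic liquid
#' closes the cycle, so
#' `dG_transfer(water -> IL) = dG_decouple(water) - dG_decouple(IL)`,
#' with uncertainties combined in quadrature. A negative transfer free
#' energy means the solute prefers the ionic liquid.
#'
#' @param leg_water Decoupling leg in water ([free_energy_leg()]).
#' @param leg_il Decoupling leg in the ionic liquid.
#' @param solute Solute label; must match any nonempty leg solute labels.
#' @return An object of class `ilx_transfer_cycle`.
#' @export
transfer_cycle <- function(leg_water, leg_il, solute = "") {
  stopifnot(inherits(leg_water, "ilx_fe_leg"), inherits(leg_il, "ilx_fe_leg"))
  labs <- c(leg_water$solute, leg_il$solute, solute)
  labs <- unique(labs[nzchar(labs)])
  if (length(labs) > 1) {
    .stop_validation("cycle legs refer to different solutes: ",
                     paste(labs, collapse = " vs "))
  }
  structure(list(leg_water = leg_water, leg_il = leg_il,
                 solute = if (length(labs)) labs else ""),
            class = "ilx_transfer_cycle")
}

#' Transfer free energy from a cycle
#'
#' @param cycle An [transfer_cycle()].
#' @return A [free_energy_leg()] labelled `"transfer water->IL"` with
#'   `dg = dg_water - dg_il` and quadrature-combined uncertainty.
#' @examples
#' cyc <- transfer_cycle(free_energy_leg("decouple-in-water", 10, 3),
#'                       free_energy_leg("decouple-in-IL", 10, 4))
#' transfer_free_energy(cyc) # 0 +/- 5
#' @export
transfer_free_energy <- function(cycle) {
  stopifnot(inherits(cycle, "ilx_transfer_cycle"))
  free_energy_leg(
    "transfer water->IL",
    dg = cycle$leg_water$dg - cycle$leg_il$dg,
    uncertainty = sqrt(cycle$leg_water$uncertainty^2 +
                         cycle$leg_il$uncertainty^2),
    solute = cycle$solute)
}

#' Classify solvent preference from a transfer free energy
#'
#' A water-to-ionic-liquid transfer free energy significantly below zero
#' (beyond `threshold_sigma` uncertainties) indicates the solute prefers the
#' ionic liquid; significantly above zero, water; otherwise the sign is not
#' resolved at that confidence and the call is `indeterminate`.
#'
#' @param leg A [free_energy_leg()] holding the transfer free energy.
#' @param threshold_sigma Significance multiple of the uncertainty
#'   (default 2).
#' @return One of `"IL-preferring"`, `"water-preferring"`, `"indeterminate"`.
#' @examples
#' classify_preference(free_energy_leg("transfer", -127.3, 5.1)) # IL-preferring
#' classify_preference(free_energy_leg("transfer", 5.0, 1.1))    # water-preferring
#' @export
classify_preference <- function(leg, threshold_sigma = 2) {
  stopifnot(inherits(leg, "ilx_fe_leg"))
  .check_number(threshold_sigma, "threshold_sigma", lower = 0)
  if (leg$dg < -threshold_sigma * leg$uncertainty) "IL-preferring"
  else if (leg$dg > threshold_sigma * leg$uncertainty) "water-preferring"
  else "indeterminate"
}
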