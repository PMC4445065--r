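#' Two-site equilibrium binding model
#'
#' Statistical-weight model of one protein binding a probe with two sites:
#' microstate weights are 1 (free), `K1*p` and `K2*p` (singly bound, the
#' two microstates co-migrate as one gel band) and `omega*K1*K2*p^2`
#' (doubly bound), with `p` the free protein concentration. `omega` is the
#' cooperativity factor: > 1 cooperative, ~1 additive, < 1 competitive.
#'
#' @param K1,K2 per-site association constants in 1/M (> 0). Symmetric
#'   palindromic probes use `K1 = K2` (the default when `K2` is omitted).
#' @param omega dimensionless cooperativity factor (>= 0).
#' @return An object of class `"two_site_model"`.
#' @export
two_site_model <- function(K1, K2 = K1, omega = 1) {
  if (K1 <= 0 || K2 <= 0) stop("association constants must be positive")
  if (omega < 0) stop("omega must be non-negative")
  structure(list(K1 = K1, K2 = K2, omega = omega), class = "two_site_model")
}

#' @export
print.two_site_model <- function(x, ...) {
  cat(sprintf("two-site model: K1 = %.3g /M, K2 = %.3g /M, omega = %.3g\n",
              x$K1, x$K2, x$omega))
  invisible(x)
}

#' Equilibrium band fractions at a given free protein concentration
#'
#' With `q1 = K1*p` and `q2 = K2*p`, the partition function is
#' `Z = 1 + q1 + q2 + omega*q1*q2` and the band fractions are
#' `f0 = 1/Z`, `f1 = (q1 + q2)/Z`, `f2 = omega*q1*q2/Z`.
#'
#' @param m a `"two_site_model"`.
#' @param p_free free protein concentration in M (vectorised, >= 0).
#' @return A matrix with columns `f0`, `f1`, `f2` (rows sum to 1).
#' @examples
#' boltzmann_fractions(two_site_model(1e7, omega = 10), 100e-9)
#' @export
boltzmann_fractions <- function(m, p_free) {
  if (any(p_free < 0)) stop("free protein concentration must be >= 0")
  q1 <- m$K1 * p_free
  q2 <- m$K2 * p_free
  Z <- 1 + q1 + q2 + m$omega * q1 * q2
  cbind(f0 = 1 / Z, f1 = (q1 + q2) / Z, f2 = m$omega * q1 * q2 / Z)
}

# vectorised bisection for the free-protein concentration satisfying
# mass balance: ptot = p + dtot * (f1 + 2*f2)(p).  Concentrations in M.
# The bound-protein term is increasing in p, so g is monotone and the
# root is bracketed by [0, ptot].
.solve_pfree <- function(m, protein_total, dna_total, iter = 80L) {
  g <- function(p) {
    fr <- boltzmann_fractions(m, p)
    p + dna_total * (fr[, "f1"] + 2 * fr[, "f2"]) - protein_total
  }
  lo <- rep(0, length(protein_total))
  hi <- protein_total
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    pos <- g(mid) > 0
    hi[pos] <- mid[pos]
    lo[!pos] <- mid[!pos]
  }
  (lo + hi) / 2
}

#' Solve the binding equilibrium under mass balance
#'
#' Finds the free protein concentration satisfying the conservation
#' equation `protein_total = p_free + dna_total * (f1 + 2*f2)` by
#' bracketed bisection on `[0, protein_total]`, then returns the band
#' fractions at that concentration. Full mass balance matters in EMSA
#' conditions where the probe (tens of nM) is not negligible relative to
#' the protein.
#'
#' @param m a `"two_site_model"`.
#' @param protein_total total protein in nM (vectorised, >= 0).
#' @param dna_total total probe in nM (>= 0).
#' @return A data.frame with columns `protein_total`, `p_free` (both nM),
#'   `f0`, `f1`, `f2`.
#' @export
solve_equilibrium <- function(m, protein_total, dna_total) {
  if (any(protein_total < 0) || dna_total < 0)
    stop("total concentrations must be >= 0")
  ptot <- protein_total * 1e-9
  dtot <- dna_total * 1e-9
  p <- .solve_pfree(m, ptot, dtot)
  fr <- boltzmann_fractions(m, p)
  resid <- abs(p + dtot * (fr[, "f1"] + 2 * fr[, "f2"]) - ptot)
  tol <- pmax(1e-9 * ptot, 1e-18)
  if (any(resid > tol))
    stop(sprintf(
      "equilibrium solver did not converge on bracket [0, %.3g M] (residual %.3g M)",
      max(ptot), max(resid)))
  data.frame(protein_total = protein_total, p_free = p * 1e9,
             f0 = fr[, "f0"], f1 = fr[, "f1"], f2 = fr[, "f2"])
}

#' Quantified EMSA lane
#'
#' @param protein_total total protein in nM (per protein for mixtures).
#' @param dna_total total probe in nM.
#' @param f0,f1,f2 free, singly-bound (monomer) and doubly-bound (dimer)
#'   band fractions; must lie in `[0, 1]` and sum to 1 within 0.02
#'   (densitometry tolerance).
#' @return An object of class `"emsa_lane"`.
#' @export
emsa_lane <- function(protein_total, dna_total, f0, f1, f2) {
  fr <- c(f0, f1, f2)
  if (any(fr < 0) || any(fr > 1))
    stop("band fractions must lie in [0, 1]")
  if (abs(sum(fr) - 1) > 0.02)
    stop(sprintf("band fractions sum to %.3f; must be 1 within 0.02", sum(fr)))
  structure(list(protein_total = protein_total, dna_total = dna_total,
                 f0 = f0, f1 = f1, f2 = f2), class = "emsa_lane")
}

#' EMSA titration (lane series at increasing protein concentration)
#'
#' @param lanes list of `"emsa_lane"` objects sharing `dna_total`, with
#'   strictly increasing protein concentrations; >= 3 lanes are required
#'   for fitting.
#' @return An object of class `"emsa_titration"`.
#' @export
emsa_titration <- function(lanes) {
  stopifnot(length(lanes) >= 1, all(vapply(lanes, inherits, logical(1),
                                           "emsa_lane")))
  ptot <- vapply(lanes, `[[`, numeric(1), "protein_total")
  dtot <- unique(vapply(lanes, `[[`, numeric(1), "dna_total"))
  if (length(dtot) != 1)
    stop("all lanes of a titration must share dna_total")
  if (any(diff(ptot) <= 0))
    stop("protein concentrations must be strictly increasing across lanes")
  structure(list(lanes = lanes, dna_total = dtot), class = "emsa_titration")
}

#' @export
print.emsa_titration <- function(x, ...) {
  cat(sprintf("EMSA titration: %d lanes, %g nM probe\n",
              length(x$lanes), x$dna_total))
  print(titration_table(x))
  invisible(x)
}

#' Titration as a data.frame
#' @param t an `"emsa_titration"`.
#' @return data.frame with columns `protein_total`, `dna_total`, `f0`,
#'   `f1`, `f2`.
#' @export
titration_table <- function(t) {
  do.call(rbind, lapply(t$lanes, function(l)
    data.frame(protein_total = l$protein_total, dna_total = l$dna_total,
               f0 = l$f0, f1 = l$f1, f2 = l$f2)))
}

#' Per-lane ratio estimator of the cooperativity factor
#'
#' For a symmetric probe (`K1 = K2`) the microstate ratio
#' `omega = 4 * f2 * f0 / f1^2` holds at any free protein concentration,
#' so each lane yields an estimate independent of K and of the
#' concentration scale. When the monomer band is absent (`f1 <= 0`) the
#' estimator diverges and the lane is flagged rather than given a number.
#'
#' @param lane an `"emsa_lane"`, or a numeric vector `c(f0, f1, f2)`.
#' @return A list with `omega` (numeric, `Inf` when flagged) and
#'   `reliable` (`FALSE` when `f1 <= 0`).
#' @examples
#' omega_from_lane(c(0.25, 0.5, 0.25))   # independent sites: omega = 1
#' omega_from_lane(c(0.25, 0.10, 0.65))  # 65
#' @export
omega_from_lane <- function(lane) {
  if (inherits(lane, "emsa_lane")) lane <- c(lane$f0, lane$f1, lane$f2)
  lane <- unname(lane)
  f0 <- lane[1]; f1 <- lane[2]; f2 <- lane[3]
  if (f1 <= 0)
    return(list(omega = Inf, reliable = FALSE,
                note = "monomer band absent; omega unreliable/infinite"))
  list(omega = 4 * f2 * f0 / f1^2, reliable = TRUE, note = "ok")
}

#' Classify the binding mode from a cooperativity estimate
#'
#' @param omega_hat numeric estimate, or `Inf` / the flagged result of
#'   [omega_from_lane()].
#' @param additive_band `(lo, hi)` interval around 1 treated as additive.
#' @return One of `"cooperative"`, `"additive"`, `"competitive"`,
#'   `"infinite"`.
#' @export
classify_binding <- function(omega_hat, additive_band = c(0.5, 2.0)) {
  if (is.list(omega_hat)) {
    if (!isTRUE(omega_hat$reliable)) return("infinite")
    omega_hat <- omega_hat$omega
  }
  if (!is.finite(omega_hat)) return("infinite")
  if (omega_hat < additive_band[1]) "competitive"
  else if (omega_hat <= additive_band[2]) "additive"
  else "cooperative"
}

# sum of squared deviations between observed and predicted fractions;
# parameters are clamped to a wide physical range so the optimiser cannot
# overflow the statistical weights
.titration_ssq <- function(logK, logomega, obs, dna_total) {
  logK <- min(max(logK, 0), 15)
  logomega <- min(max(logomega, -8), 10)
  m <- two_site_model(10^logK, omega = 10^logomega)
  pred <- try(solve_equilibrium(m, obs$protein_total, dna_total),
              silent = TRUE)
  if (inherits(pred, "try-error")) return(1e6)
  ssq <- sum((pred$f0 - obs$f0)^2 + (pred$f1 - obs$f1)^2 +
             (pred$f2 - obs$f2)^2)
  if (!is.finite(ssq)) 1e6 else ssq
}

#' Fit (K, omega) to a titration by least squares
#'
#' Minimises the summed squared deviation between observed band fractions
#' and the mass-balance predictions of [solve_equilibrium()], over
#' `log10(K)` and `log10(omega)`, with multi-start over a log-spaced grid
#' of initial values. The per-lane ratio estimates are reported alongside.
#' Following the gel-quantification reliability rule, a titration whose
#' monomer band stays below 2% in every lane is flagged
#' `"unreliable/infinite omega"`: the monomer band carries the information
#' separating K from omega.
#'
#' @param t an `"emsa_titration"` with >= 3 lanes.
#' @param symmetric must be `TRUE` (asymmetric probes with `K1 != K2`
#'   require resolved monomer bands, which pooled lane tables do not
#'   provide).
#' @param start_logK,start_logomega initial-value grids for the
#'   multi-start optimisation (log10 units).
#' @param f1_reliability_threshold maximum-monomer-fraction bound below
#'   which omega is reported as unreliable/infinite (default 2%).
#' @return A list with `K`, `omega` (point estimates), `reliability`
#'   (`"ok"` or `"unreliable/infinite omega"`), `lane_omegas` (per-lane
#'   ratio estimates), `ssq` and `converged`.
#' @export
fit_titration <- function(t, symmetric = TRUE,
                          start_logK = c(5, 6.5, 8, 9),
                          start_logomega = c(-1, 0.5, 2, 3.5),
                          f1_reliability_threshold = 0.02) {
  stopifnot(inherits(t, "emsa_titration"))
  if (!symmetric)
    stop("asymmetric fitting requires resolved monomer bands; only the symmetric model is supported")
  if (length(t$lanes) < 3) stop("fitting requires at least 3 lanes")
  obs <- titration_table(t)

  lane_est <- lapply(t$lanes, omega_from_lane)
  lane_omegas <- vapply(lane_est, `[[`, numeric(1), "omega")

  all_low_monomer <- all(obs$f1 < f1_reliability_threshold)
  all_saturated <- all(obs$f2 > 0.98)
  if (all_saturated) {
    return(list(K = NA_real_, omega = NA_real_,
                reliability = "unreliable/infinite omega",
                lane_omegas = lane_omegas, ssq = NA_real_,
                converged = FALSE))
  }

  best <- NULL
  for (k0 in start_logK) {
    for (w0 in start_logomega) {
      fit <- try(stats::optim(
        c(k0, w0),
        function(par) .titration_ssq(par[1], par[2], obs, t$dna_total),
        method = "Nelder-Mead",
        control = list(maxit = 500, reltol = 1e-12)), silent = TRUE)
      if (inherits(fit, "try-error")) next
      if (is.null(best) || fit$value < best$value) best <- fit
    }
  }
  if (is.null(best)) stop("titration fit failed from every start")
  best$par[1] <- min(max(best$par[1], 0), 15)
  best$par[2] <- min(max(best$par[2], -8), 10)
  list(K = 10^best$par[1], omega = 10^best$par[2],
       reliability = if (all_low_monomer) "unreliable/infinite omega" else "ok",
       lane_omegas = lane_omegas, ssq = best$value,
       converged = best$convergence == 0)
}

#' Mixture model for two proteins on a two-site probe
#'
#' Extends the two-site model to proteins A and B with pairwise
#' cooperativity factors, predicting the six gel species: free probe,
#' A monomer, B monomer, and the AA, AB, BB dimer bands.
#'
#' @param K_a,K_b per-site association constants (1/M).
#' @param omega_aa,omega_ab,omega_bb pairwise cooperativity factors
#'   (>= 0).
#' @return An object of class `"mixture_model"`.
#' @export
mixture_model <- function(K_a, K_b, omega_aa = 1, omega_ab = 1,
                          omega_bb = 1) {
  if (K_a <= 0 || K_b <= 0) stop("association constants must be positive")
  if (any(c(omega_aa, omega_ab, omega_bb) < 0))
    stop("cooperativity factors must be non-negative")
  structure(list(K_a = K_a, K_b = K_b, omega_aa = omega_aa,
                 omega_ab = omega_ab, omega_bb = omega_bb),
            class = "mixture_model")
}

#' Band fractions for a two-protein mixture
#'
#' Microstate weights: 1 (free); `2*K_a*pa` and `2*K_b*pb` for the A and B
#' monomers (two site assignments each); `omega_aa*(K_a*pa)^2`,
#' `omega_bb*(K_b*pb)^2` and `2*omega_ab*K_a*pa*K_b*pb` for the dimers
#' (AB and BA co-migrate). Weights are normalised by their sum.
#'
#' @param m a `"mixture_model"`.
#' @param pa_free,pb_free free concentrations of A and B in M (>= 0).
#' @return Named numeric vector over `free`, `monoA`, `monoB`, `AA`,
#'   `AB`, `BB`, summing to 1.
#' @export
mixture_fractions <- function(m, pa_free, pb_free) {
  if (pa_free < 0 || pb_free < 0) stop("concentrations must be >= 0")
  qa <- m$K_a * pa_free
  qb <- m$K_b * pb_free
  w <- c(free = 1, monoA = 2 * qa, monoB = 2 * qb,
         AA = m$omega_aa * qa^2, AB = 2 * m$omega_ab * qa * qb,
         BB = m$omega_bb * qb^2)
  w / sum(w)
}
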