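# Minimum-energy path and reaction force analysis (RFA).
#
# The reaction force F(s) = -dV/ds has a minimum (alpha) and a maximum
# (gamma) at the inflection points of V(s).  The interval [alpha, gamma] is
# the transition-state zone, where the primary electronic activity occurs;
# the IRC points inside it (excluding s = 0, whose optimized structure is
# already available) are the nonstationary points worth a frequency job for
# CVT.

#' Minimum-energy-path profile
#'
#' Ordered `(s, V)` points with the transition state at `s = 0`, reactants
#' at `s < 0` and products at `s > 0`; `V` is in kcal/mol relative to the
#' reactants.
#'
#' @param s Reaction coordinate in amu^1/2 bohr, strictly increasing.
#' @param V Potential energy in kcal/mol relative to the reactant
#'   asymptote.
#' @return Object of class `mep_profile`.
#' @export
mep_profile <- function(s, V) {
  stopifnot(length(s) == length(V), length(s) >= 3)
  if (any(diff(s) <= 0)) stop("`s` must be strictly increasing")
  ts_index <- which(s == 0)
  if (!length(ts_index)) stop("profile must contain the point s = 0")
  structure(list(s = as.numeric(s), V = as.numeric(V),
                 ts_index = ts_index[1]),
            class = "mep_profile")
}

#' @export
print.mep_profile <- function(x, ...) {
  cat(sprintf("<mep_profile> %d points, s in [%.3f, %.3f] amu^1/2 bohr\n",
              length(x$s), min(x$s), max(x$s)))
  cat(sprintf("  V(0) = %.4f kcal/mol above reactants\n", x$V[x$ts_index]))
  invisible(x)
}

#' Reaction force along the path
#'
#' `F(s) = -dV/ds`, evaluated at every input point by analytic
#' differentiation of an interpolating cubic spline (no smoothing; IRC
#' points are smooth and noise-free).  The spline uses the
#' Forsythe-Malcolm-Moler end conditions, which reproduce cubic
#' polynomials exactly.  A central finite-difference mode is provided as a
#' cross-check.
#'
#' @param profile An [mep_profile()] (or any list with `s` and `V`).
#' @param method `"spline"` (default) or `"fd"` for second-order central
#'   finite differences.
#' @return Data frame with columns `s` and `F` (kcal/mol per amu^1/2
#'   bohr).
#' @export
reaction_force <- function(profile, method = c("spline", "fd")) {
  method <- match.arg(method)
  s <- profile$s; V <- profile$V
  if (length(s) < 7) stop("need at least 7 path points")
  if (anyDuplicated(s)) stop("duplicated s values")
  if (any(diff(s) <= 0)) stop("`s` must be strictly increasing")
  if (method == "spline") {
    f <- stats::splinefun(s, V, method = "fmm")
    Fv <- -f(s, deriv = 1)
  } else {
    n <- length(s)
    Fv <- numeric(n)
    i <- 2:(n - 1)
    # three-point formula on a possibly nonuniform grid
    h1 <- s[i] - s[i - 1]; h2 <- s[i + 1] - s[i]
    Fv[i] <- -((V[i + 1] * h1^2 - V[i - 1] * h2^2 +
                V[i] * (h2^2 - h1^2)) / (h1 * h2 * (h1 + h2)))
    Fv[1] <- -(V[2] - V[1]) / (s[2] - s[1])
    Fv[n] <- -(V[n] - V[n - 1]) / (s[n] - s[n - 1])
  }
  data.frame(s = s, F = Fv)
}

#' Locate the reaction-force critical points
#'
#' Finds `alpha` (the minimum of `F` on the reactant side, `s < 0`) and
#' `gamma` (the maximum of `F` on the product side, `s > 0`); `beta`, the
#' zero of `F`, is the transition state at `s = 0`.  Both extrema are
#' reported at actual grid points - no sub-grid interpolation - because the
#' selected points must be IRC geometries a frequency job can be run on.
#' Ties are broken toward `s = 0`.  Every point is then assigned to the
#' reactant zone (`s < alpha`), the TS zone (`alpha <= s <= gamma`) or the
#' product zone (`s > gamma`).
#'
#' @param force Data frame with columns `s` and `F` as returned by
#'   [reaction_force()].
#' @return Object of class `rfa_result`: `alpha_s`, `beta_s = 0`,
#'   `gamma_s`, the `force_curve`, and a `zone` factor per point.
#' @export
locate_rfa_points <- function(force) {
  s <- force$s; Fv <- force$F
  if (!any(s < 0) || !any(s > 0))
    stop("force curve must cover both signs of s")
  neg <- which(s < 0); pos <- which(s > 0)
  a_val <- min(Fv[neg]); g_val <- max(Fv[pos])
  a_cand <- neg[Fv[neg] == a_val]
  g_cand <- pos[Fv[pos] == g_val]
  ia <- a_cand[which.min(abs(s[a_cand]))]   # tie-break: nearest s = 0
  ig <- g_cand[which.min(abs(s[g_cand]))]
  # monotone F has its extrema at the branch ends adjacent to the TS or at
  # the outer endpoints; no interior barrier structure either way
  interior_a <- ia != neg[1] && ia != neg[length(neg)]
  interior_g <- ig != pos[1] && ig != pos[length(pos)]
  if (!interior_a && !interior_g)
    stop("no barrier structure: reaction force has no interior extrema")
  if (!interior_a || !interior_g)
    warning("one branch truncated before F returns toward 0; ",
            "using the available extremum")
  alpha_s <- s[ia]; gamma_s <- s[ig]
  zone <- factor(ifelse(s < alpha_s, "reactant",
                        ifelse(s > gamma_s, "product", "TS")),
                 levels = c("reactant", "TS", "product"))
  structure(list(alpha_s = alpha_s, beta_s = 0, gamma_s = gamma_s,
                 force_curve = force, zone = zone),
            class = "rfa_result")
}

#' @export
print.rfa_result <- function(x, ...) {
  cat(sprintf("<rfa_result> alpha = %g, beta = 0, gamma = %g amu^1/2 bohr\n",
              x$alpha_s, x$gamma_s))
  print(table(x$zone))
  invisible(x)
}

#' Select the TS-zone nonstationary points
#'
#' All IRC points with `alpha <= s <= gamma` and `s != 0`, in increasing
#' order: the points whose projected frequency analyses CVT needs.  The
#' saddle point itself is excluded because its optimized structure and
#' frequencies are already part of the standard TST input.
#'
#' @param profile An [mep_profile()].
#' @param rfa An [locate_rfa_points()] result.
#' @return Numeric vector of selected `s` values.
#' @export
select_ts_zone <- function(profile, rfa) {
  s <- profile$s
  sel <- s[s >= rfa$alpha_s & s <= rfa$gamma_s & s != 0]
  if (!length(sel))
    stop("no TS-zone points between alpha and gamma; ",
         "recompute the IRC with a smaller step size")
  sort(sel)
}

#' Economy statistic of the TS-zone selection
#'
#' Percentage of IRC points that fall in the TS zone,
#' `100 * n_zone / n_irc`, reported to one decimal: the fraction of path
#' points that actually need a frequency analysis for CVT.
#'
#' @param n_zone Number of TS-zone points (excluding the saddle point).
#' @param n_irc Total number of nonstationary IRC points.
#' @return Percentage rounded to one decimal.
#' @export
pcvt_fraction <- function(n_zone, n_irc) {
  if (n_irc <= 0) stop("n_irc must be positive")
  if (n_zone < 0 || n_zone > n_irc)
    stop("n_zone must lie in [0, n_irc]")
  round(100 * n_zone / n_irc, 1)
}
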