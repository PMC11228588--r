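#' Ternary composition (water / ethanol / solute mass fractions)
#'
#' @param w_water,w_ethanol,w_solute mass fractions; each in \[0, 1\] and
#'   summing to 1 within 1e-9.
#' @return A named numeric vector of class `ternary_composition`.
#' @export
#' @examples
#' ternary(w_water = 0.6, w_ethanol = 0.3, w_solute = 0.1)
ternary <- function(w_water, w_ethanol, w_solute) {
  w <- c(w_water = w_water, w_ethanol = w_ethanol, w_solute = w_solute)
  if (any(w < -1e-12) || any(w > 1 + 1e-12)) {
    stop("mass fractions must lie in [0, 1]")
  }
  if (abs(sum(w) - 1) > 1e-9) {
    stop(sprintf("mass fractions must sum to 1 (got %.12f)", sum(w)))
  }
  structure(w, class = "ternary_composition")
}

components <- function() c("w_water", "w_ethanol", "w_solute")

#' Two-phase split of a ternary system
#'
#' Holds an overall composition plus the dense (oil) and light (aqueous)
#' phase compositions with their masses, as measured after an oiling-out
#' system has been left to settle and the phases separated. Volumes are
#' optional metadata. Construction does not enforce mass balance: that is
#' [check_mass_balance()]'s job, so imperfect lab measurements can be
#' represented and audited.
#'
#' @param overall,dense,light `ternary_composition` objects.
#' @param total_mass_g,dense_mass_g,light_mass_g masses in grams.
#' @param dense_volume_mL,light_volume_mL optional volumes.
#' @return A list of class `phase_split`.
#' @export
phase_split <- function(overall, total_mass_g, dense, dense_mass_g,
                        light, light_mass_g,
                        dense_volume_mL = NA_real_, light_volume_mL = NA_real_) {
  stopifnot(inherits(overall, "ternary_composition"),
            inherits(dense, "ternary_composition"),
            inherits(light, "ternary_composition"))
  if (total_mass_g < 0 || dense_mass_g < 0 || light_mass_g < 0) {
    stop("masses must be non-negative")
  }
  structure(
    list(overall = overall, total_mass_g = total_mass_g,
         dense = dense, dense_mass_g = dense_mass_g,
         light = light, light_mass_g = light_mass_g,
         dense_volume_mL = dense_volume_mL, light_volume_mL = light_volume_mL),
    class = "phase_split"
  )
}

#' Relative supersaturation
#'
#' `sigma = (C - C*) / C*` with `C` the actual and `C*` the saturated
#' concentration, in any shared unit (g solute per g solvent by default
#' convention). Negative values indicate undersaturation.
#'
#' @param C actual concentration (>= 0), vectorized.
#' @param C_star saturation concentration (> 0), same units.
#' @return sigma, dimensionless.
#' @export
#' @examples
#' supersaturation_sigma(0.35, 0.14)  # 1.5
supersaturation_sigma <- function(C, C_star) {
  if (any(C_star <= 0)) stop("saturation concentration must be positive")
  if (any(C < 0)) stop("concentration must be non-negative")
  (C - C_star) / C_star
}

#' Component-wise mass-balance audit of a two-phase split
#'
#' For each component c, compares the overall mass
#' `overall_c * M_total` with the sum of the phase masses
#' `dense_c * M_dense + light_c * M_light`; the relative residual is
#' their absolute difference over the overall component mass. A zero
#' overall component with nonzero phase content yields an infinite
#' residual (reported, not thrown). The total mass is audited too.
#'
#' @param split a [phase_split()].
#' @param tol relative tolerance for the pass verdict (default 1e-6).
#' @return A list of class `mass_balance_report`: `residuals` (named, per
#'   component), `mass_residual` (total-mass closure), `tol`, `pass`.
#' @export
check_mass_balance <- function(split, tol = 1e-6) {
  stopifnot(inherits(split, "phase_split"))
  comps <- components()
  overall_mass <- unclass(split$overall)[comps] * split$total_mass_g
  phase_mass <- unclass(split$dense)[comps] * split$dense_mass_g +
    unclass(split$light)[comps] * split$light_mass_g
  resid <- ifelse(
    overall_mass == 0,
    ifelse(phase_mass == 0, 0, Inf),
    abs(overall_mass - phase_mass) / overall_mass
  )
  names(resid) <- comps
  mass_resid <- if (split$total_mass_g == 0) {
    if (split$dense_mass_g + split$light_mass_g == 0) 0 else Inf
  } else {
    abs(split$total_mass_g - split$dense_mass_g - split$light_mass_g) /
      split$total_mass_g
  }
  structure(
    list(residuals = resid, mass_residual = mass_resid, tol = tol,
         pass = all(resid <= tol) && mass_resid <= tol),
    class = "mass_balance_report"
  )
}

#' @export
print.mass_balance_report <- function(x, ...) {
  cat(sprintf("Mass balance %s (tol %.1e)\n",
              if (x$pass) "PASS" else "FAIL", x$tol))
  for (nm in names(x$residuals)) {
    cat(sprintf("  %-10s residual %.3e\n", nm, x$residuals[[nm]]))
  }
  cat(sprintf("  total mass residual %.3e\n", x$mass_residual))
  invisible(x)
}

#' Lever-rule phase fractions along a tie-line
#'
#' Given overall, dense-phase and light-phase compositions and a chosen
#' component, the dense-phase mass fraction of the total is
#' `f_dense = (overall - light) / (dense - light)` evaluated on that
#' component, and `f_light = 1 - f_dense`. Values outside \[0, 1\] are
#' returned as-is with `consistent = FALSE`, signalling an inconsistent
#' tie-line, never clamped.
#'
#' @param overall,dense,light `ternary_composition` objects.
#' @param component one of `"w_water"`, `"w_ethanol"`, `"w_solute"`.
#' @return A list with `f_dense`, `f_light`, `component`, `consistent`.
#' @export
lever_fractions <- function(overall, dense, light,
                            component = c("w_solute", "w_water", "w_ethanol")) {
  component <- match.arg(component)
  d <- dense[[component]] - light[[component]]
  if (abs(d) <= 1e-12) {
    stop("degenerate tie-line: phases identical in ", component)
  }
  f_dense <- (overall[[component]] - light[[component]]) / d
  eps <- 1e-12
  list(f_dense = f_dense, f_light = 1 - f_dense, component = component,
       consistent = f_dense >= -eps && f_dense <= 1 + eps)
}

#' Ethanol mass fraction from an ethanol:water volume ratio
#'
#' Anti-solvent additions are often specified as volume multiples of the
#' water charge; this converts such a ratio to the ethanol mass fraction
#' of the mixed solvent assuming ideal (additive) volumes:
#' `w = r rho_e / (r rho_e + rho_w)`.
#'
#' @param ratio ethanol-to-water volume ratio (>= 0), vectorized.
#' @param rho_ethanol,rho_water densities in g/mL (defaults 0.789, 0.997
#'   at 25 C).
#' @return Ethanol mass fraction of the solvent mixture.
#' @export
#' @examples
#' volume_ratio_to_fraction(c(0.4, 1.0, 1.6))
volume_ratio_to_fraction <- function(ratio, rho_ethanol = 0.789,
                                     rho_water = 0.997) {
  if (any(ratio < 0)) stop("volume ratio must be non-negative")
  if (rho_ethanol <= 0 || rho_water <= 0) stop("densities must be positive")
  ratio * rho_ethanol / (ratio * rho_ethanol + rho_water)
}

#' Solubility lookup table
#'
#' A grid of saturation concentrations `C*` (g solute per g solvent)
#' indexed by temperature and ethanol mass fraction of the solvent.
#' Lookup is exact-match on temperature and nearest-neighbour on ethanol
#' fraction *within* the grid range; queries outside the grid are errors,
#' not extrapolations.
#'
#' @param temperature_K,ethanol_fraction,C_star parallel vectors defining
#'   grid points.
#' @return An object of class `solubility_table`.
#' @export
solubility_table <- function(temperature_K, ethanol_fraction, C_star) {
  df <- data.frame(temperature_K = temperature_K,
                   ethanol_fraction = ethanol_fraction, C_star = C_star)
  if (any(df$C_star <= 0)) stop("C* must be positive")
  structure(df, class = c("solubility_table", "data.frame"))
}

#' @rdname solubility_table
#' @param tab a `solubility_table`.
#' @param T_K,w_ethanol query point.
#' @export
lookup_solubility <- function(tab, T_K, w_ethanol) {
  sub <- tab[abs(tab$temperature_K - T_K) < 1e-9, , drop = FALSE]
  if (nrow(sub) == 0) {
    stop("no solubility data at T = ", T_K, " K")
  }
  if (w_ethanol < min(sub$ethanol_fraction) - 1e-12 ||
      w_ethanol > max(sub$ethanol_fraction) + 1e-12) {
    stop("ethanol fraction ", w_ethanol, " outside solubility grid")
  }
  sub$C_star[which.min(abs(sub$ethanol_fraction - w_ethanol))]
}

#' Oiling-out / nucleation boundary curve
#'
#' A boundary in the (solute concentration, anti-solvent amount) plane at
#' a stated temperature and ultrasound power, e.g. the locus where oil
#' droplets first appear as ethanol is pumped in.
#'
#' @param kind `"oiling-out"` or `"nucleation"`.
#' @param x,y curve knots; `x` must be strictly increasing, length >= 2.
#' @param temperature_K,ultrasound_W curve metadata.
#' @return An object of class `boundary_curve`.
#' @export
boundary_curve <- function(kind = c("oiling-out", "nucleation"), x, y,
                           temperature_K = 298.15, ultrasound_W = 0) {
  kind <- match.arg(kind)
  if (length(x) < 2 || length(x) != length(y)) {
    stop("need >= 2 (x, y) knots of equal length")
  }
  if (any(diff(x) <= 0)) stop("curve abscissa must be strictly increasing")
  structure(
    list(kind = kind, x = x, y = y,
         temperature_K = temperature_K, ultrasound_W = ultrasound_W),
    class = "boundary_curve"
  )
}

#' Interpolate a boundary curve
#'
#' Piecewise-linear interpolation, exact at knots. Querying outside the
#' curve's abscissa range is an error; the module never extrapolates a
#' measured boundary.
#'
#' @param curve a [boundary_curve()].
#' @param x_query abscissa value(s) within the curve range.
#' @return Interpolated ordinate(s).
#' @export
boundary_interp <- function(curve, x_query) {
  stopifnot(inherits(curve, "boundary_curve"))
  if (any(x_query < min(curve$x) - 1e-12) ||
      any(x_query > max(curve$x) + 1e-12)) {
    stop("query outside curve abscissa range [", min(curve$x), ", ",
         max(curve$x), "]; extrapolation refused")
  }
  stats::approx(curve$x, curve$y, xout = x_query, method = "linear",
                rule = 1)$y
}

#' Signed area between two boundary curves
#'
#' Trapezoidal integral of `curve_b - curve_a` over the overlap of their
#' abscissa ranges. A negative value with `curve_a` the silent and
#' `curve_b` the sonicated boundary quantifies a forward shift of the
#' boundary toward lower anti-solvent amounts.
#'
#' @param curve_a,curve_b [boundary_curve()] objects with overlapping range.
#' @param n number of quadrature points (default 257).
#' @return Signed area (b minus a).
#' @export
boundary_shift_area <- function(curve_a, curve_b, n = 257) {
  lo <- max(min(curve_a$x), min(curve_b$x))
  hi <- min(max(curve_a$x), max(curve_b$x))
  if (hi <= lo) stop("curves do not overlap in abscissa")
  xs <- seq(lo, hi, length.out = n)
  diff_y <- boundary_interp(curve_b, xs) - boundary_interp(curve_a, xs)
  sum((diff_y[-1] + diff_y[-n]) / 2 * diff(xs))
}

#' Read phase-split measurements from CSV
#'
#' Expects columns `phase` (overall | dense | light), `mass_g`,
#' `w_water`, `w_ethanol`, `w_solute`, and optionally `volume_mL`.
#'
#' @param path file path.
#' @return A [phase_split()].
#' @export
read_phase_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("phase", "mass_g", "w_water", "w_ethanol", "w_solute")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) stop("missing column(s): ", paste(miss, collapse = ", "))
  row_of <- function(ph) {
    i <- which(df$phase == ph)
    if (length(i) != 1) stop("need exactly one '", ph, "' row")
    df[i, , drop = FALSE]
  }
  ov <- row_of("overall"); de <- row_of("dense"); li <- row_of("light")
  vol <- function(r) if ("volume_mL" %in% names(r)) r$volume_mL else NA_real_
  phase_split(
    overall = ternary(ov$w_water, ov$w_ethanol, ov$w_solute),
    total_mass_g = ov$mass_g,
    dense = ternary(de$w_water, de$w_ethanol, de$w_solute),
    dense_mass_g = de$mass_g,
    light = ternary(li$w_water, li$w_ethanol, li$w_solute),
    light_mass_g = li$mass_g,
    dense_volume_mL = vol(de), light_volume_mL = vol(li)
  )
}

#' Read boundary curves from CSV
#'
#' Expects columns `kind`, `temperature_K`, `ultrasound_W`, `x`, `y`; one
#' curve per unique (kind, temperature_K, ultrasound_W) triple.
#'
#' @param path file path.
#' @return A list of [boundary_curve()] objects.
#' @export
read_boundary_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  key <- interaction(df$kind, df$temperature_K, df$ultrasound_W, drop = TRUE)
  lapply(split(df, key), function(g) {
    g <- g[order(g$x), , drop = FALSE]
    boundary_curve(g$kind[1], g$x, g$y, g$temperature_K[1], g$ultrasound_W[1])
  })
}

#' JSON-ready mass-balance report
#'
#' @param report a `mass_balance_report`.
#' @return A named list suitable for `jsonlite::write_json(...,
#'   auto_unbox = TRUE)`.
#' @export
balance_report_json <- function(report) {
  list(
    residuals = as.list(report$residuals),
    mass_residual = report$mass_residual,
    tol = report$tol,
    pass = report$pass,
    units = list(mass = "g", composition = "mass fraction")
  )
}
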