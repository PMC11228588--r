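#' Physical constants used by the nucleation formulas
#'
#' Exact SI (CODATA 2018) values of the Boltzmann constant and the
#' Avogadro number, as a locked-down list. Every classical-nucleation
#' formula in the package pulls `k` and `N_A` from here so that unit
#' conversions stay consistent.
#'
#' @return A list with elements `k` (J/K) and `N_A` (1/mol).
#' @export
#' @examples
#' physical_constants()$k
physical_constants <- function() {
  list(k = 1.380649e-23, N_A = 6.02214076e23)
}

# Conventional (2005-vintage IUPAC) atomic weights, g/mol. This is the
# table consistent with the solute's printed molecular weight.
.atomic_weights <- c(
  H = 1.00794, C = 12.0107, N = 14.0067, O = 15.9994,
  Na = 22.98977, P = 30.973762, S = 32.065, Cl = 35.453, K = 39.0983
)

#' Molecular weight from an element count map
#'
#' @param formula Named numeric vector or list mapping element symbol to
#'   atom count, e.g. `c(C = 6, H = 14, O = 12, P = 2)` for fructose
#'   1,6-diphosphate.
#' @return Molecular weight in g/mol.
#' @export
#' @examples
#' molecular_weight(c(C = 6, H = 14, O = 12, P = 2))  # 340.12 g/mol
molecular_weight <- function(formula) {
  formula <- unlist(formula)
  if (length(formula) == 0 || any(formula < 0)) {
    stop("formula must map elements to non-negative counts")
  }
  unknown <- setdiff(names(formula), names(.atomic_weights))
  if (length(unknown) > 0) {
    stop("unknown element(s): ", paste(unknown, collapse = ", "))
  }
  sum(.atomic_weights[names(formula)] * formula)
}

#' Molecular parameters for CNT calculations
#'
#' Bundles the per-molecule volume `v` (the quantity every CNT formula
#' needs) with the molecular weight and, optionally, the formula. When
#' both a formula and a molecular weight are given they must agree to
#' 0.05 g/mol.
#'
#' @param molecular_volume Volume of one molecule in m^3. Computed from
#'   `molecular_weight` and `density` when omitted.
#' @param molecular_weight g/mol; computed from `formula` when omitted.
#' @param formula optional element->count map (see [molecular_weight()]).
#' @param density optional crystal density in g/cm^3, used to derive
#'   `molecular_volume = MW / (density * N_A)` when the volume is not
#'   supplied directly.
#' @return An object of class `molecular_params`.
#' @export
#' @examples
#' molecular_params(formula = c(C = 6, H = 14, O = 12, P = 2), density = 1.6)
molecular_params <- function(molecular_volume = NULL, molecular_weight = NULL,
                             formula = NULL, density = NULL) {
  if (!is.null(formula)) {
    mw_formula <- sonocryst::molecular_weight(formula)
    if (is.null(molecular_weight)) {
      molecular_weight <- mw_formula
    } else if (abs(molecular_weight - mw_formula) > 0.05) {
      stop(sprintf(
        "molecular_weight %.4f inconsistent with formula (%.4f g/mol)",
        molecular_weight, mw_formula
      ))
    }
  }
  if (is.null(molecular_volume)) {
    if (is.null(molecular_weight) || is.null(density)) {
      stop("supply molecular_volume, or molecular_weight/formula plus density")
    }
    if (density <= 0) stop("density must be positive")
    # density g/cm^3 -> g/m^3 is *1e6
    molecular_volume <- molecular_weight / (density * 1e6 * physical_constants()$N_A)
  }
  if (!is.finite(molecular_volume) || molecular_volume <= 0) {
    stop("molecular_volume must be positive")
  }
  structure(
    list(
      molecular_volume = molecular_volume,
      molecular_weight = molecular_weight,
      formula = formula,
      density = density
    ),
    class = "molecular_params"
  )
}

#' @export
print.molecular_params <- function(x, ...) {
  cat("Molecular parameters\n")
  if (!is.null(x$formula)) {
    cat("  formula:", paste0(names(x$formula), unlist(x$formula), collapse = " "), "\n")
  }
  if (!is.null(x$molecular_weight)) {
    cat(sprintf("  molecular weight: %.4f g/mol\n", x$molecular_weight))
  }
  cat(sprintf("  molecular volume: %.4e m^3\n", x$molecular_volume))
  invisible(x)
}
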