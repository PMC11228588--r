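#' Induction-time records
#'
#' Builds the atomic data structure of the nucleation-kinetics module: one
#' row per induction-time measurement, holding the supersaturation ratio
#' `S = C/C*`, the induction time in seconds, the temperature in kelvin
#' and the ultrasound bath power in watts (0 for the silent condition).
#'
#' @param S numeric vector of supersaturation ratios, all > 1.
#' @param t_ind_s induction times in seconds, all > 0.
#' @param T_K temperature in kelvin (recycled), default 298.15.
#' @param ultrasound_W ultrasound power in watts (recycled), default 0.
#' @param ... further columns carried along untouched.
#' @return A `data.frame` of class `induction_records`.
#' @export
#' @examples
#' induction_records(S = c(1.8, 2.3), t_ind_s = c(19800, 9000),
#'                   ultrasound_W = 100)
induction_records <- function(S, t_ind_s, T_K = 298.15, ultrasound_W = 0, ...) {
  df <- data.frame(S = S, t_ind_s = t_ind_s, T_K = T_K,
                   ultrasound_W = ultrasound_W, ...)
  validate_induction_records(df)
}

validate_induction_records <- function(df) {
  req <- c("S", "t_ind_s", "T_K", "ultrasound_W")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0) stop("missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(df$S <= 1)
  if (length(bad) > 0) {
    stop(sprintf("supersaturation must exceed 1; offending row(s): %s (S = %s)",
                 paste(bad, collapse = ", "),
                 paste(signif(df$S[bad], 6), collapse = ", ")))
  }
  if (any(df$t_ind_s <= 0)) stop("induction times must be positive")
  if (any(df$T_K <= 0)) stop("temperatures must be positive")
  class(df) <- c("induction_records", "data.frame")
  df
}

#' Read induction-time measurements from CSV/TSV
#'
#' Expects header columns `S`, `t_ind_s`, `T_K`, `ultrasound_W`; extra
#' columns are preserved but not interpreted. The delimiter is sniffed
#' from the header line (comma or tab).
#'
#' @param path file path.
#' @return An `induction_records` data frame.
#' @export
read_induction_csv <- function(path) {
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  validate_induction_records(df)
}

#' Packaged induction-time tables for trisodium fructose 1,6-diphosphate
#'
#' The two published induction-time tables for FDPNa3 anti-solvent
#' crystallization ship as plain-text fixtures: one under a 100 W
#' ultrasound bath, one silent. Besides the measured (S, t) pairs the
#' fixtures carry the printed log-times and CNT parameter columns under a
#' `printed_` prefix, plus a `note` column flagging two typographical
#' quirks of the source table (a log-time printed as 10.134 where the
#' time rounds to 10.135, and one unparseable critical-nucleus entry,
#' stored as NA).
#'
#' @param condition `"ultrasound"` (100 W) or `"silent"`.
#' @return An `induction_records` data frame with printed reference columns.
#' @export
#' @examples
#' head(induction_table("ultrasound"))
induction_table <- function(condition = c("ultrasound", "silent")) {
  condition <- match.arg(condition)
  path <- system.file("extdata",
                      paste0("induction_", condition, ".csv"),
                      package = "sonocryst", mustWork = TRUE)
  read_induction_csv(path)
}

#' Linearizing axis transform for induction-time kinetics
#'
#' Classical nucleation theory predicts `ln t_ind` linear in
#' `1/(ln S)^2`; this maps each record to that plane.
#'
#' @param records an `induction_records` data frame (or anything with
#'   columns `S` and `t_ind_s`).
#' @return A data frame with columns `S`, `x = (ln S)^-2`, `y = ln t_ind`,
#'   row order preserved.
#' @export
#' @examples
#' transform_axes(induction_records(1.8, 19800))  # y = 9.893
transform_axes <- function(records) {
  bad <- which(records$S <= 1)
  if (length(bad) > 0) {
    stop(sprintf("supersaturation must exceed 1; offending row(s): %s",
                 paste(bad, collapse = ", ")))
  }
  data.frame(S = records$S,
             x = 1 / log(records$S)^2,
             y = log(records$t_ind_s))
}

# Closed-form ordinary least squares y = A + B x (normal equations).
ols_line <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  if (sxx == 0) stop("degenerate branch: all x identical")
  B <- sum((x - mx) * (y - my)) / sxx
  A <- my - B * mx
  rss <- sum((y - (A + B * x))^2)
  list(A = A, B = B, rss = rss)
}

new_branch_fit <- function(fit, S, gamma = NA_real_) {
  structure(
    list(A = fit$A, B = fit$B, gamma = gamma,
         s_range = range(S), s_values = sort(unique(S)),
         rss = fit$rss, n = length(S)),
    class = "cnt_branch_fit"
  )
}

#' @export
print.cnt_branch_fit <- function(x, ...) {
  cat(sprintf("CNT branch fit: ln t = %.4f + %.4f / (ln S)^2   [S in %.3g..%.3g, n = %d, RSS = %.3g]\n",
              x$A, x$B, x$s_range[1], x$s_range[2], x$n, x$rss))
  if (is.finite(x$gamma)) {
    cat(sprintf("  interfacial energy: %.4f mJ/m^2\n", x$gamma * 1e3))
  }
  invisible(x)
}

#' Two-branch linear fit of transformed induction-time data
#'
#' Induction-time curves of oiling-out systems commonly show two distinct
#' slopes in the `ln t` vs `1/(ln S)^2` plane, one per supersaturation
#' regime. This fits an ordinary-least-squares line per branch, splitting
#' the data either at an explicit supersaturation threshold or
#' automatically at the contiguous-in-S changepoint minimizing total
#' residual sum of squares (each side keeping at least two points).
#' Replicate S values always stay in the same branch; under an explicit
#' threshold, records with `S` equal to the threshold go to the low-S
#' branch.
#'
#' @param points a data frame with columns `x`, `y` and optionally `S`
#'   (as from [transform_axes()]), or an `induction_records` frame which
#'   is transformed first. Without an `S` column, S is reconstructed from
#'   `x` (branch contiguity is then contiguity in decreasing `x`).
#' @param split `"auto"` (default) or a numeric S threshold: records with
#'   `S <= split` form the low-S branch.
#' @return A list of class `cnt_two_branch` with elements `low` and
#'   `high` (each a `cnt_branch_fit`), `split_S` (midpoint between the
#'   branches' adjacent S values), `rss_total`, and `rss_tie` (TRUE when
#'   several split positions achieve the minimum RSS within 1e-9
#'   relative, e.g. on single-slope data).
#' @export
#' @examples
#' rec <- induction_table("ultrasound")
#' fit_two_branch(transform_axes(rec), split = 2.05)
fit_two_branch <- function(points, split = "auto") {
  if (!all(c("x", "y") %in% names(points))) {
    points <- transform_axes(points)
  }
  if (!"S" %in% names(points)) {
    points$S <- exp(1 / sqrt(points$x))
  }
  n <- nrow(points)
  if (n < 4) stop("need at least 4 points (2 per branch) for a two-branch fit")
  ord <- order(points$S)
  pts <- points[ord, , drop = FALSE]
  s_levels <- sort(unique(pts$S))
  if (length(s_levels) < 2) stop("need at least two distinct S values")

  fit_split <- function(low_idx, high_idx) {
    f_lo <- ols_line(pts$x[low_idx], pts$y[low_idx])
    f_hi <- ols_line(pts$x[high_idx], pts$y[high_idx])
    list(low = f_lo, high = f_hi, rss = f_lo$rss + f_hi$rss,
         low_idx = low_idx, high_idx = high_idx)
  }

  if (identical(split, "auto")) {
    cands <- list()
    for (i in seq_len(length(s_levels) - 1)) {
      thr <- s_levels[i]
      low_idx <- which(pts$S <= thr)
      high_idx <- which(pts$S > thr)
      if (length(low_idx) >= 2 && length(high_idx) >= 2) {
        cands[[length(cands) + 1]] <- c(fit_split(low_idx, high_idx),
                                        list(thr_i = i))
      }
    }
    if (length(cands) == 0) stop("no admissible split with >= 2 points per branch")
    rss <- vapply(cands, function(cc) cc$rss, numeric(1))
    best <- which.min(rss)
    scale <- max(rss[best], .Machine$double.eps)
    tie <- sum(rss - rss[best] <= 1e-9 * max(scale, 1)) > 1
    chosen <- cands[[best]]
    thr_i <- chosen$thr_i
    split_S <- mean(s_levels[c(thr_i, thr_i + 1)])
  } else {
    if (!is.numeric(split) || length(split) != 1) {
      stop("split must be \"auto\" or a single numeric S threshold")
    }
    low_idx <- which(pts$S <= split)
    high_idx <- which(pts$S > split)
    if (length(low_idx) < 2 || length(high_idx) < 2) {
      stop("explicit split leaves a branch with fewer than 2 points")
    }
    chosen <- fit_split(low_idx, high_idx)
    split_S <- split
    tie <- FALSE
  }

  structure(
    list(
      low = new_branch_fit(chosen$low, pts$S[chosen$low_idx]),
      high = new_branch_fit(chosen$high, pts$S[chosen$high_idx]),
      split_S = split_S,
      rss_total = chosen$low$rss + chosen$high$rss,
      rss_tie = tie
    ),
    class = "cnt_two_branch"
  )
}

#' @export
print.cnt_two_branch <- function(x, ...) {
  cat(sprintf("Two-branch CNT fit (split at S = %.4g%s)\n", x$split_S,
              if (isTRUE(x$rss_tie)) ", RSS tie: split indifferent" else ""))
  cat("low-S branch:  "); print(x$low)
  cat("high-S branch: "); print(x$high)
  invisible(x)
}

#' Interfacial energy from the induction-time slope
#'
#' Homogeneous spherical-nucleus CNT relates the slope `B` of `ln t` vs
#' `1/(ln S)^2` to the solid-solution interfacial energy via
#' `B = 16 pi gamma^3 v^2 / (3 k^3 T^3)`, inverted here as
#' `gamma = (3 B k^3 T^3 / (16 pi v^2))^(1/3)`.
#'
#' @param B slope (dimensionless), must be >= 0.
#' @param mol a [molecular_params()] object supplying the molecular
#'   volume `v` in m^3.
#' @param T_K temperature in kelvin.
#' @return Interfacial energy in J/m^2.
#' @export
interfacial_energy <- function(B, mol, T_K) {
  if (B < 0) stop("non-physical slope: B must be non-negative")
  if (T_K <= 0) stop("temperature must be positive")
  k <- physical_constants()$k
  v <- mol$molecular_volume
  (3 * B * (k * T_K)^3 / (16 * pi * v^2))^(1 / 3)
}

#' Induction-time slope implied by an interfacial energy
#'
#' Inverse of [interfacial_energy()]: `B = 16 pi gamma^3 v^2 / (3 (kT)^3)`.
#' Used by the synthetic generator and for round-trip checks.
#'
#' @inheritParams interfacial_energy
#' @param gamma interfacial energy in J/m^2.
#' @return Slope B (dimensionless).
#' @export
slope_from_gamma <- function(gamma, mol, T_K) {
  if (gamma < 0) stop("gamma must be non-negative")
  k <- physical_constants()$k
  v <- mol$molecular_volume
  16 * pi * gamma^3 * v^2 / (3 * (k * T_K)^3)
}

#' Per-supersaturation CNT point parameters
#'
#' For a spherical nucleus: critical radius
#' `r_c = 2 gamma v / (kT ln S)`, molar nucleation barrier
#' `dG_c = 16 pi gamma^3 v^2 / (3 (kT ln S)^2) * N_A`, and critical
#' nucleus size `N_c = (4 pi / 3) r_c^3 / v` molecules. The returned
#' values satisfy the identity `dG_c = (4 pi / 3) gamma r_c^2 N_A`.
#'
#' @param gamma interfacial energy, J/m^2 (>= 0).
#' @param mol a [molecular_params()] object.
#' @param T_K temperature, kelvin.
#' @param S supersaturation ratio (> 1), vectorized.
#' @return A data frame with columns `S`, `r_c_m`, `dG_c_J_mol`, `N_c`.
#' @export
point_params <- function(gamma, mol, T_K, S) {
  if (any(S <= 1)) stop("supersaturation must exceed 1")
  if (gamma < 0) stop("gamma must be non-negative")
  cst <- physical_constants()
  v <- mol$molecular_volume
  kTlnS <- cst$k * T_K * log(S)
  r_c <- 2 * gamma * v / kTlnS
  dG_c <- 16 * pi * gamma^3 * v^2 / (3 * kTlnS^2) * cst$N_A
  N_c <- (4 * pi / 3) * r_c^3 / v
  data.frame(S = S, r_c_m = r_c, dG_c_J_mol = dG_c, N_c = N_c)
}

#' Critical radius from the molar nucleation barrier
#'
#' Inverts the spherical-nucleus identity
#' `dG_c = (4 pi / 3) gamma r_c^2 N_A` to
#' `r_c = sqrt(3 dG_c / (4 pi gamma N_A))`; useful for cross-checking
#' published (gamma, barrier, radius) triples.
#'
#' @param gamma interfacial energy in J/m^2, > 0.
#' @param dG_c_J_mol molar nucleation barrier in J/mol, > 0.
#' @return Critical radius in metres.
#' @export
#' @examples
#' radius_from_barrier(5.552e-3, 2743.888) * 1e9  # 0.44 nm
radius_from_barrier <- function(gamma, dG_c_J_mol) {
  if (any(gamma <= 0) || any(dG_c_J_mol <= 0)) {
    stop("gamma and dG_c must be positive")
  }
  sqrt(3 * dG_c_J_mol / (4 * pi * gamma * physical_constants()$N_A))
}

#' Full CNT parameter table from induction-time records
#'
#' Composes the module: transforms records, fits the two-branch line,
#' converts each branch slope to an interfacial energy (using the mean
#' temperature of the branch's records), and evaluates the per-S point
#' parameters with the branch's gamma. Set `single_branch = TRUE` to fit
#' one line to all records (at least 2 needed); or supply `B` directly
#' to skip fitting (useful for an externally estimated slope, any number
#' of records).
#'
#' @param records an `induction_records` data frame.
#' @param mol a [molecular_params()] object.
#' @param split `"auto"` or numeric S threshold (see [fit_two_branch()]).
#' @param single_branch logical; fit one branch to all data.
#' @param B optional externally supplied slope (forces single branch).
#' @param units `"SI"` (m, J/m^2) or `"paper"` (nm, mJ/m^2) output columns.
#' @return A data frame, one row per record: `S`, `t_ind_s`, `ln_t_ind`,
#'   `branch`, gamma, `N_c`, barrier and radius columns (named per
#'   `units`), with the fit attached as attribute `"fit"`.
#' @export
#' @examples
#' mol <- molecular_params(formula = c(C = 6, H = 14, O = 12, P = 2),
#'                         density = 1.6)
#' cnt_table(induction_table("ultrasound"), mol, split = 2.05)
cnt_table <- function(records, mol, split = "auto", single_branch = FALSE,
                      B = NULL, units = c("SI", "paper")) {
  units <- match.arg(units)
  records <- validate_induction_records(as.data.frame(records))
  pts <- transform_axes(records)

  if (!is.null(B)) {
    branch <- rep("single", nrow(records))
    Tm <- mean(records$T_K)
    gam <- c(single = interfacial_energy(B, mol, Tm))
    Ts <- c(single = Tm)
    fit <- list(B = B, gamma = gam[["single"]])
  } else if (isTRUE(single_branch)) {
    if (nrow(records) < 2) stop("single-branch fit needs at least 2 points")
    f <- ols_line(pts$x, pts$y)
    branch <- rep("single", nrow(records))
    Tm <- mean(records$T_K)
    gam <- c(single = interfacial_energy(f$B, mol, Tm))
    Ts <- c(single = Tm)
    fit <- new_branch_fit(f, records$S, gamma = gam[["single"]])
  } else {
    fit <- fit_two_branch(pts, split = split)
    branch <- ifelse(records$S <= fit$split_S, "low", "high")
    Ts <- c(low = mean(records$T_K[branch == "low"]),
            high = mean(records$T_K[branch == "high"]))
    gam <- c(low = interfacial_energy(fit$low$B, mol, Ts[["low"]]),
             high = interfacial_energy(fit$high$B, mol, Ts[["high"]]))
    fit$low$gamma <- gam[["low"]]
    fit$high$gamma <- gam[["high"]]
  }

  pp <- do.call(rbind, lapply(seq_len(nrow(records)), function(i) {
    b <- branch[i]
    point_params(gam[[b]], mol, Ts[[b]], records$S[i])
  }))

  out <- data.frame(
    S = records$S,
    t_ind_s = records$t_ind_s,
    ln_t_ind = pts$y,
    branch = branch,
    gamma_J_m2 = unname(gam[branch]),
    N_c = pp$N_c,
    dG_c_J_mol = pp$dG_c_J_mol,
    r_c_m = pp$r_c_m
  )
  if (units == "paper") {
    out$gamma_mJ_m2 <- out$gamma_J_m2 * 1e3
    out$r_c_nm <- out$r_c_m * 1e9
    out$gamma_J_m2 <- NULL
    out$r_c_m <- NULL
    out <- out[, c("S", "t_ind_s", "ln_t_ind", "branch",
                   "gamma_mJ_m2", "N_c", "dG_c_J_mol", "r_c_nm")]
  }
  attr(out, "fit") <- fit
  attr(out, "T_K") <- Ts
  out
}

#' JSON-ready fit report for a two-branch CNT fit
#'
#' @param fit a `cnt_two_branch` object (optionally with gammas filled in
#'   by [cnt_table()]).
#' @param seed optional seed recorded for provenance.
#' @return A named list (serialize with `jsonlite::write_json(...,
#'   auto_unbox = TRUE)`).
#' @export
cnt_fit_report <- function(fit, seed = NULL) {
  br <- function(b) list(A = b$A, B = b$B,
                         gamma_J_m2 = if (is.finite(b$gamma)) b$gamma else NULL,
                         rss = b$rss, n = b$n, s_range = b$s_range)
  list(
    model = "ln t_ind = A + B / (ln S)^2",
    split_S = fit$split_S,
    rss_total = fit$rss_total,
    rss_tie = fit$rss_tie,
    low = br(fit$low),
    high = br(fit$high),
    seed = seed,
    units = list(gamma = "J/m^2", t_ind = "s", T = "K")
  )
}
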