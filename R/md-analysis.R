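#' Per-group-pair interaction-energy time series
#'
#' Container for MD-engine energy output: a strictly increasing time
#' axis (ps) and one kJ/mol column per (term, group-pair) combination,
#' with names like `"Coul-SR:FDP-FDP"` or `"LJ-SR:FDP-SOL"`. Columns
#' whose names do not follow the `term:pair` convention are preserved
#' verbatim under an `other:` namespace. Although MD logs often call
#' these quantities "forces", they are interaction energies in kJ/mol
#' and are labelled as such here.
#'
#' @param time numeric vector, ps, strictly increasing.
#' @param columns named list of numeric vectors, all `length(time)`.
#' @param metadata optional list (group definitions, provenance).
#' @return An object of class `energy_series`.
#' @export
energy_series <- function(time, columns, metadata = list()) {
  if (length(time) > 1 && any(diff(time) <= 0)) {
    stop("time must be strictly increasing")
  }
  if (length(columns) == 0 || is.null(names(columns)) ||
      any(!nzchar(names(columns)))) {
    stop("columns must be a non-empty named list")
  }
  lens <- vapply(columns, length, integer(1))
  if (any(lens != length(time))) stop("all columns must match time length")
  structure(list(time = time, columns = columns, metadata = metadata),
            class = "energy_series")
}

#' @export
print.energy_series <- function(x, ...) {
  cat(sprintf("Energy series: %d frames (%g..%g ps), %d column(s)\n",
              length(x$time), min(x$time), max(x$time), length(x$columns)))
  cat(" ", paste(names(x$columns), collapse = ", "), "\n")
  invisible(x)
}

parse_xvg_legends <- function(directives) {
  legends <- character(0)
  for (d in directives) {
    m <- regmatches(d, regexec('^@\\s*s(\\d+)\\s+legend\\s+"(.*)"', d))[[1]]
    if (length(m) == 3) legends[as.integer(m[2]) + 1] <- m[3]
  }
  legends
}

#' Read an XVG-dialect energy table
#'
#' Parses the tabular format emitted by MD energy extraction tools:
#' lines starting `#` are comments, lines starting `@` are plot
#' directives (of which `@ s<i> legend "<name>"` names data column i),
#' remaining lines are whitespace-separated numbers whose first column
#' is time (ps). Legends of the form `term:pair` with term `Coul-SR` or
#' `LJ-SR` are mapped to energy columns; any other legend is kept
#' verbatim under the `other:` namespace. Files without legends get
#' columns named `col1..colN` with a warning.
#'
#' @param path file path.
#' @return An [energy_series()].
#' @export
read_energy_table <- function(path) {
  lines <- readLines(path)
  directives <- lines[startsWith(lines, "@")]
  data_lines <- lines[!startsWith(lines, "#") & !startsWith(lines, "@") &
                        nzchar(trimws(lines))]
  if (length(data_lines) == 0) stop("no data rows in ", path)
  toks <- strsplit(trimws(data_lines), "\\s+")
  ncols <- unique(lengths(toks))
  if (length(ncols) != 1) {
    bad <- which(lengths(toks) != lengths(toks)[1])[1]
    stop("ragged row at data line ", bad, " of ", path)
  }
  mat <- matrix(as.numeric(unlist(toks)), ncol = ncols, byrow = TRUE)
  if (anyNA(mat)) stop("non-numeric data in ", path)
  nset <- ncols - 1
  legends <- parse_xvg_legends(directives)
  if (length(legends) == 0 || all(is.na(legends))) {
    warning("no legends found in ", path, "; naming columns col1..col", nset)
    legends <- paste0("col", seq_len(nset))
  }
  if (length(legends) < nset) {
    legends <- c(legends, paste0("col", seq(length(legends) + 1, nset)))
  }
  nm <- vapply(legends[seq_len(nset)], function(lg) {
    if (grepl("^(Coul-SR|LJ-SR):", lg)) lg else paste0("other:", lg)
  }, character(1))
  cols <- stats::setNames(lapply(seq_len(nset), function(j) mat[, j + 1]), nm)
  title <- grep('^@\\s*title', directives, value = TRUE)
  energy_series(mat[, 1], cols,
                metadata = list(source = path, title = title))
}

#' Write an energy series in XVG dialect
#'
#' Inverse of [read_energy_table()]: emits `@` legend directives and
#' whitespace-separated rows at 17 significant digits, so a read-back
#' reproduces the series exactly.
#'
#' @param series an [energy_series()].
#' @param path output path.
#' @param comments optional character vector written as `#` lines.
#' @return Invisibly, `path`.
#' @export
write_energy_table <- function(series, path, comments = character(0)) {
  nm <- sub("^other:", "", names(series$columns))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments) > 0) writeLines(paste("#", comments), con)
  writeLines('@    title "Interaction energies"', con)
  writeLines('@    xaxis  label "Time (ps)"', con)
  writeLines('@    yaxis  label "(kJ/mol)"', con)
  writeLines(sprintf('@ s%d legend "%s"', seq_along(nm) - 1, nm), con)
  mat <- cbind(series$time, do.call(cbind, series$columns))
  writeLines(apply(mat, 1, function(r) paste(sprintf("%.17g", r), collapse = " ")),
             con)
  invisible(path)
}

#' Total pair interaction energy and its steady-state tail mean
#'
#' The inter-component interaction measure is the sum of the short-range
#' Coulomb (`Coul-SR`) and Lennard-Jones (`LJ-SR`) terms for a group
#' pair. The tail mean averages the summed series over the final
#' fraction `f` of frames (a steady-state estimate).
#'
#' @param series an [energy_series()].
#' @param pair group-pair label, e.g. `"FDP-FDP"`.
#' @param f tail fraction in (0, 1], default 0.25.
#' @return A list with `total` (numeric vector, kJ/mol), `tail_mean`,
#'   `tail_n`, and `pair`.
#' @export
pair_energy <- function(series, pair, f = 0.25) {
  stopifnot(inherits(series, "energy_series"))
  if (f <= 0 || f > 1) stop("tail fraction f must be in (0, 1]")
  coul_nm <- paste0("Coul-SR:", pair)
  lj_nm <- paste0("LJ-SR:", pair)
  for (nm in c(coul_nm, lj_nm)) {
    if (!nm %in% names(series$columns)) {
      stop("missing energy column '", nm, "' for pair ", pair)
    }
  }
  total <- series$columns[[coul_nm]] + series$columns[[lj_nm]]
  n <- length(total)
  tail_n <- ceiling(f * n)
  list(total = total,
       tail_mean = mean(total[(n - tail_n + 1):n]),
       tail_n = tail_n, pair = pair)
}

#' Labelled particle frame in a periodic orthorhombic box
#'
#' @param positions n x 3 numeric matrix, nm.
#' @param species character vector of per-particle labels (e.g.
#'   `"solute"`, `"water"`, `"ethanol"`, `"ion"`).
#' @param box length-3 box edge lengths, nm (orthorhombic, periodic).
#' @param wrap if `TRUE`, wrap positions into `[0, box)` first; if
#'   `FALSE` (default) out-of-box coordinates are an error.
#' @return An object of class `particle_frame`.
#' @export
particle_frame <- function(positions, species, box, wrap = FALSE) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3) stop("positions must be n x 3")
  if (nrow(positions) < 1) stop("need at least one particle")
  if (length(species) != nrow(positions)) {
    stop("species must label every particle")
  }
  if (length(box) != 3 || any(box <= 0)) stop("box must be 3 positive lengths")
  if (wrap) {
    positions <- sweep(positions, 2, box, function(p, b) p - b * floor(p / b))
  } else {
    for (ax in 1:3) {
      if (any(positions[, ax] < 0) || any(positions[, ax] >= box[ax])) {
        stop("coordinates outside [0, box) on axis ", c("x", "y", "z")[ax],
             "; wrap positions first (wrap = TRUE)")
      }
    }
  }
  structure(list(positions = positions, species = as.character(species),
                 box = as.numeric(box)),
            class = "particle_frame")
}

gro_residue_names <- c(solute = "FDP", water = "SOL", ethanol = "ETH",
                       ion = "ION")

#' Read a GRO-format coordinate frame
#'
#' Fixed-column GRO: title, atom count, one line per atom (residue
#' number/name, atom name, atom number, x y z in nm), box vector line.
#' Residue names FDP/SOL/ETH/ION map to species solute/water/ethanol/
#' ion; other residue names are kept as lower-cased labels. Coordinates
#' are wrapped into the box (GRO files routinely carry small excursions).
#'
#' @param path file path.
#' @return A [particle_frame()].
#' @export
read_gro <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3) stop("truncated GRO file: ", path)
  n <- as.integer(trimws(lines[2]))
  if (is.na(n) || length(lines) < n + 3) stop("bad atom count in ", path)
  at <- lines[3:(2 + n)]
  resname <- trimws(substr(at, 6, 10))
  xyz <- cbind(as.numeric(substr(at, 21, 28)),
               as.numeric(substr(at, 29, 36)),
               as.numeric(substr(at, 37, 44)))
  if (anyNA(xyz)) stop("unparseable coordinates in ", path)
  box <- as.numeric(strsplit(trimws(lines[n + 3]), "\\s+")[[1]])
  if (length(box) > 3 && any(abs(box[-(1:3)]) > 1e-12)) {
    stop("triclinic box not supported; orthorhombic boxes only")
  }
  box <- box[1:3]
  rev_map <- stats::setNames(names(gro_residue_names), gro_residue_names)
  species <- ifelse(resname %in% names(rev_map), rev_map[resname],
                    tolower(resname))
  particle_frame(xyz, unname(species), box, wrap = TRUE)
}

#' Write a particle frame in GRO format
#'
#' @param frame a [particle_frame()].
#' @param path output path.
#' @param title title line content.
#' @return Invisibly, `path`.
#' @export
write_gro <- function(frame, path, title = "sonocryst frame") {
  res <- ifelse(frame$species %in% names(gro_residue_names),
                gro_residue_names[frame$species],
                toupper(substr(frame$species, 1, 5)))
  n <- nrow(frame$positions)
  lines <- c(
    title,
    sprintf("%5d", n),
    sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
            seq_len(n), res, substr(res, 1, 5), seq_len(n) %% 100000,
            frame$positions[, 1], frame$positions[, 2], frame$positions[, 3]),
    sprintf("%10.5f%10.5f%10.5f", frame$box[1], frame$box[2], frame$box[3])
  )
  writeLines(lines, path)
  invisible(path)
}

#' Per-species number-density profile along a box axis
#'
#' Uniform half-open bins `[edge_i, edge_{i+1})` over `[0, L_axis)`.
#' Density is count / (bin width x cross-sectional area), so summing
#' `density * bin_volume` over bins recovers each species' particle
#' count exactly.
#'
#' @param frame a [particle_frame()].
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param n_bins number of bins (>= 1).
#' @return A list of class `density_profile`: `axis`, `bin_edges` (nm),
#'   `counts` (species x bins matrix), `density` (count nm^-3),
#'   `bin_volume` (nm^3).
#' @export
density_profile <- function(frame, axis = c("x", "y", "z"), n_bins = 20) {
  stopifnot(inherits(frame, "particle_frame"))
  axis <- match.arg(axis)
  if (n_bins < 1) stop("n_bins must be >= 1")
  ai <- match(axis, c("x", "y", "z"))
  L <- frame$box[ai]
  coords <- frame$positions[, ai]
  if (any(coords < 0) || any(coords >= L)) {
    stop("coordinates outside [0, box) on axis ", axis, "; wrap first")
  }
  edges <- seq(0, L, length.out = n_bins + 1)
  idx <- pmin(floor(coords / (L / n_bins)) + 1, n_bins)
  sp <- sort(unique(frame$species))
  counts <- t(vapply(sp, function(s) {
    tabulate(idx[frame$species == s], nbins = n_bins)
  }, numeric(n_bins)))
  if (n_bins == 1) counts <- matrix(counts, nrow = length(sp),
                                    dimnames = list(sp, NULL))
  rownames(counts) <- sp
  cross <- prod(frame$box[-ai])
  bin_volume <- (L / n_bins) * cross
  structure(
    list(axis = axis, bin_edges = edges, counts = counts,
         density = counts / bin_volume, bin_volume = bin_volume),
    class = "density_profile"
  )
}

#' Demixing index between two species
#'
#' Half the total-variation distance between the two species' normalized
#' bin-occupancy distributions along the profile axis:
#' `d = 0.5 * sum_bins |p_a - p_b|`. Zero iff the normalized
#' distributions coincide; one iff their supports are disjoint (full
#' phase separation along that axis). Symmetric in its arguments.
#'
#' @param profile a [density_profile()].
#' @param species_a,species_b species labels present in the profile.
#' @return d in \[0, 1\].
#' @export
demixing_index <- function(profile, species_a, species_b) {
  stopifnot(inherits(profile, "density_profile"))
  for (s in c(species_a, species_b)) {
    if (!s %in% rownames(profile$counts) || sum(profile$counts[s, ]) == 0) {
      stop("species '", s, "' absent from profile")
    }
  }
  p_a <- profile$counts[species_a, ] / sum(profile$counts[species_a, ])
  p_b <- profile$counts[species_b, ] / sum(profile$counts[species_b, ])
  0.5 * sum(abs(p_a - p_b))
}

min_image_dist2 <- function(pos, box) {
  n <- nrow(pos)
  d2 <- matrix(0, n, n)
  for (ax in 1:3) {
    d <- outer(pos[, ax], pos[, ax], "-")
    d <- d - box[ax] * round(d / box[ax])
    d2 <- d2 + d^2
  }
  d2
}

#' Distance-cutoff clustering of one species under periodic boundaries
#'
#' Single-linkage connected components of the graph joining selected
#' particles whose minimum-image distance is at most `cutoff`
#' (orthorhombic boxes only). Cluster ids are deterministic: clusters
#' are numbered by the lowest original particle index they contain.
#'
#' @param frame a [particle_frame()].
#' @param species species label to cluster.
#' @param cutoff linkage distance, nm (> 0).
#' @return A list of class `cluster_set`: `particle_index` (indices into
#'   the frame), `cluster_id` (per selected particle), `sizes`
#'   (named by cluster id), `cutoff`.
#' @export
cluster_by_cutoff <- function(frame, species = "solute", cutoff) {
  stopifnot(inherits(frame, "particle_frame"))
  if (cutoff <= 0) stop("cutoff must be positive")
  sel <- which(frame$species == species)
  if (length(sel) == 0) {
    return(structure(list(particle_index = integer(0),
                          cluster_id = integer(0),
                          sizes = integer(0), cutoff = cutoff),
                     class = "cluster_set"))
  }
  pos <- frame$positions[sel, , drop = FALSE]
  n <- length(sel)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  d2 <- min_image_dist2(pos, frame$box)
  cut2 <- cutoff^2
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (d2[i, j] <= cut2) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  ids <- match(roots, sort(unique(roots)))
  sizes <- as.integer(table(ids))
  names(sizes) <- seq_along(sizes)
  structure(list(particle_index = sel, cluster_id = ids,
                 sizes = sizes, cutoff = cutoff),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("Cluster set: %d particle(s), %d cluster(s) at cutoff %g nm\n",
              length(x$particle_index), length(x$sizes), x$cutoff))
  if (length(x$sizes) > 0) {
    cat("  sizes:", paste(sort(x$sizes, decreasing = TRUE), collapse = " "), "\n")
  }
  invisible(x)
}

#' Onset detection on a particle-count series
#'
#' Emulates reading a focused-beam reflectance count trace for the
#' moment of a sudden signal change: the onset is the first index whose
#' count exceeds (baseline mean + k x baseline sd) for `m` consecutive
#' samples, the baseline being the first `baseline_frac` of the series.
#'
#' @param counts non-negative numeric vector.
#' @param k sd multiplier (default 5).
#' @param m required consecutive exceedances (default 3).
#' @param baseline_frac fraction of the series used as baseline
#'   (default 0.1; must give >= 2 samples).
#' @param times optional time axis aligned with `counts`.
#' @return `NULL` if the rule is never satisfied; otherwise a list with
#'   `index` (first index of the sustained exceedance), `time` (if
#'   `times` given), and `threshold`.
#' @export
onset_time <- function(counts, k = 5, m = 3, baseline_frac = 0.1,
                       times = NULL) {
  if (any(counts < 0)) stop("counts must be non-negative")
  nb <- floor(baseline_frac * length(counts))
  if (nb < 2) stop("series too short for baseline window (need >= 2 samples)")
  base <- counts[seq_len(nb)]
  thr <- mean(base) + k * stats::sd(base)
  exceed <- counts > thr
  run <- 0L
  for (i in seq_along(exceed)) {
    run <- if (exceed[i]) run + 1L else 0L
    if (run >= m) {
      idx <- i - m + 1L
      return(list(index = idx,
                  time = if (!is.null(times)) times[idx] else NULL,
                  threshold = thr))
    }
  }
  NULL
}
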