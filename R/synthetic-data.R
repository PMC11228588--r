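#' Specification for a synthetic two-branch induction-time dataset
#'
#' Defines the generating model `ln t = A_b + B_b / (ln S)^2 + eps`,
#' `eps ~ Normal(0, noise_sd)` (i.e. lognormal multiplicative noise on
#' the induction time), with one (A, B) pair per supersaturation branch
#' and an S threshold separating the branches.
#'
#' @param A1,B1 low-S branch intercept and slope.
#' @param A2,B2 high-S branch intercept and slope.
#' @param split_S branch threshold: records with `S <= split_S` belong
#'   to the low-S branch.
#' @param S_grid supersaturation values (> 1).
#' @param noise_sd lognormal noise sd (>= 0).
#' @param replicates measurements per S value.
#' @param T_K,ultrasound_W condition metadata stamped on each record.
#' @param seed RNG seed.
#' @return A list of class `induction_gen_spec`.
#' @export
induction_gen_spec <- function(A1, B1, A2, B2, split_S,
                               S_grid = c(seq(1.5, 2.0, by = 0.1),
                                          seq(2.1, 3.0, length.out = 6)),
                               noise_sd = 0.05, replicates = 1,
                               T_K = 298.15, ultrasound_W = 0, seed = 1) {
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (any(S_grid <= 1)) stop("all S values must exceed 1")
  if (replicates < 1) stop("replicates must be >= 1")
  structure(
    list(A1 = A1, B1 = B1, A2 = A2, B2 = B2, split_S = split_S,
         S_grid = S_grid, noise_sd = noise_sd, replicates = replicates,
         T_K = T_K, ultrasound_W = ultrasound_W, seed = seed),
    class = "induction_gen_spec"
  )
}

#' Generate a synthetic induction-time dataset
#'
#' Draws records from the two-branch log-linear model in an
#' [induction_gen_spec()]. The generating parameters (ground truth) are
#' attached as attribute `"ground_truth"` for recovery tests.
#'
#' @param spec an [induction_gen_spec()].
#' @return An `induction_records` data frame with a `branch_true` column.
#' @export
gen_induction_dataset <- function(spec) {
  stopifnot(inherits(spec, "induction_gen_spec"))
  S <- rep(spec$S_grid, each = spec$replicates)
  x <- 1 / log(S)^2
  low <- S <= spec$split_S
  mu <- ifelse(low, spec$A1 + spec$B1 * x, spec$A2 + spec$B2 * x)
  noise <- withr_seed(spec$seed, stats::rnorm(length(S), 0, spec$noise_sd))
  rec <- induction_records(
    S = S, t_ind_s = exp(mu + noise), T_K = spec$T_K,
    ultrasound_W = spec$ultrasound_W,
    branch_true = ifelse(low, "low", "high")
  )
  attr(rec, "ground_truth") <- spec
  rec
}

# Evaluate expr under a private RNG state seeded with `seed`, restoring
# the caller's state afterwards. Keeps every generator a pure function
# of its spec.
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Construct a mass-balanced two-phase split
#'
#' Partitions each component of an overall ternary mixture between a
#' dense and a light phase. Component c goes to the dense phase with
#' mass share `phi_c = K_c f / (K_c f + (1 - f))` where `K_c` is the
#' component's partition coefficient and `f` the nominal dense-phase
#' mass fraction; `K_c = 1` for every component reproduces the overall
#' composition in both phases, and `K_solute > 1` enriches the dense
#' (oil) phase in solute. The construction closes the component mass
#' balance exactly.
#'
#' @param overall a [ternary()] composition.
#' @param total_mass_g total mass, g.
#' @param partition named numeric vector of positive partition
#'   coefficients for `w_water`, `w_ethanol`, `w_solute` (missing names
#'   default to 1).
#' @param dense_fraction nominal dense-phase mass fraction in (0, 1).
#' @return A [phase_split()] whose [check_mass_balance()] residuals are
#'   at machine precision.
#' @export
gen_phase_split <- function(overall, total_mass_g, partition = c(w_solute = 5),
                            dense_fraction = 0.3) {
  stopifnot(inherits(overall, "ternary_composition"))
  if (total_mass_g <= 0) stop("total mass must be positive")
  if (dense_fraction <= 0 || dense_fraction >= 1) {
    stop("infeasible spec: dense_fraction must lie strictly in (0, 1), got ",
         dense_fraction)
  }
  K <- stats::setNames(rep(1, 3), components())
  K[names(partition)] <- partition
  if (any(K <= 0)) {
    stop("infeasible spec: partition coefficients must be positive")
  }
  f <- dense_fraction
  phi <- K * f / (K * f + (1 - f))
  comp_mass <- unclass(overall)[components()] * total_mass_g
  dense_mass_c <- comp_mass * phi
  light_mass_c <- comp_mass - dense_mass_c
  m_dense <- sum(dense_mass_c)
  m_light <- sum(light_mass_c)
  if (m_dense <= 0 || m_light <= 0) {
    stop("infeasible spec: a phase would carry non-positive mass")
  }
  mk <- function(m_c, m) {
    w <- m_c / m
    ternary(w[["w_water"]], w[["w_ethanol"]], w[["w_solute"]])
  }
  phase_split(
    overall = overall, total_mass_g = total_mass_g,
    dense = mk(dense_mass_c, m_dense), dense_mass_g = m_dense,
    light = mk(light_mass_c, m_light), light_mass_g = m_light
  )
}

#' Generate a noisy step-plus-ramp particle-count series
#'
#' Emulates an in-situ particle-count trace: a flat noisy baseline, then
#' at the onset index a step plus linear ramp. The generating onset is
#' attached as attribute `"onset_true"` for detector-recovery tests.
#' Counts are floored at zero.
#'
#' @param n series length.
#' @param onset_index 1-based index of the jump (must leave a baseline
#'   window before it).
#' @param baseline baseline level.
#' @param step jump height at onset.
#' @param slope post-onset ramp per sample.
#' @param noise_sd Gaussian noise sd.
#' @param seed RNG seed.
#' @return Numeric vector of counts with attribute `onset_true`.
#' @export
gen_counts_series <- function(n = 200, onset_index = 120, baseline = 50,
                              step = 40, slope = 1, noise_sd = 2, seed = 1) {
  if (onset_index <= floor(0.1 * n)) {
    stop("onset must come after the baseline window")
  }
  base <- rep(baseline, n)
  post <- seq_len(n) >= onset_index
  base[post] <- base[post] + step + slope * (seq_len(n)[post] - onset_index)
  counts <- pmax(0, base + withr_seed(seed, stats::rnorm(n, 0, noise_sd)))
  attr(counts, "onset_true") <- onset_index
  counts
}

#' Specification for the toy Brownian-dynamics demixing simulator
#'
#' A desk-scale surrogate for the all-atom MD system: point particles of
#' a few species in a periodic orthorhombic box, overdamped Langevin
#' dynamics, a bounded-force soft-core pair potential (harmonic
#' repulsion inside the core diameter, cosine-squared attractive well
#' of species-pair depth out to the range cutoff), a screened Coulomb
#' term for the charged solute, and an optional pulsed external field
#' coupling to charge along one axis. Defaults give a 5x5x5 nm box with
#' 300 particles and 5000 steps.
#'
#' @param counts named integer vector of particles per species; default
#'   `c(solute = 60, water = 150, ethanol = 90)`.
#' @param eps symmetric species-pair attraction matrix (dimensionless
#'   depths), dimnames matching `names(counts)`. The default makes
#'   solute-solute attraction dominant, the demixing driver.
#' @param box box edge lengths, nm.
#' @param dt time step, ps.
#' @param n_steps number of steps.
#' @param T_param thermal noise amplitude (per-axis displacement
#'   variance is `2 T_param dt`).
#' @param charge named per-species charge; default solute -3 (a
#'   trivalent anion), solvents neutral.
#' @param field optional [pulsed_field()] applied along its axis.
#' @param field_mobility drift per unit charge and field,
#'   nm ps^-1 / (V/nm); the toy coupling between field amplitude and
#'   particle motion.
#' @param sigma_core pair-potential core diameter, nm: below this
#'   separation pairs repel harmonically (bounded force), at it the
#'   attractive well is deepest.
#' @param cutoff pair-interaction range, nm (> `sigma_core`); the
#'   cosine-squared attractive well spans `[sigma_core, cutoff]` and the
#'   potential is exactly zero beyond.
#' @param repulsion harmonic core strength (energy units); the maximum
#'   repulsive pair force is `2 * repulsion / sigma_core`.
#' @param coulomb_strength prefactor of the screened-Coulomb term.
#' @param kappa screening constant, 1/nm.
#' @param d_max cap on the per-step displacement from deterministic
#'   forces, nm; steep-core overlaps relax at bounded speed (set 0 to
#'   disable, standard Brownian-dynamics displacement capping).
#' @param sample_every log frames/energies every this many steps.
#' @param field_heating dissipative-coupling coefficient: the work the
#'   field does dragging a charged particle is dissipated locally, so
#'   that particle's effective temperature is raised by
#'   `field_heating * (q mu E(t))^2` while the pulse is on. This is the
#'   model's surrogate for ultrasound disrupting the ordered solvent
#'   shell around the charged solute; set 0 to disable.
#' @param field_spatial `"uniform"` (default) applies the same drift to
#'   every charged particle; `"standing"` modulates it with a
#'   standing-wave phase `sin(2 pi x / L_axis)` along the field axis
#'   (acoustophoresis-style differential forcing).
#' @param init initial configuration: `"random"` (uniform placement),
#'   `"slab"` (solute confined to a central slab along x, solvents
#'   outside it), or `"droplet"` (solute packed in a sphere at the box
#'   centre, solvents outside - the oiled-out droplet state).
#' @param slab_width solute slab thickness as a fraction of the x box
#'   length (slab init only).
#' @param droplet_spacing nominal inter-particle spacing inside the
#'   initial droplet, nm (droplet init only).
#' @param init_positions optional n x 3 matrix of starting coordinates
#'   (nm, wrapped into the box), overriding `init`; particle order is
#'   species-blockwise in `names(counts)` order.
#' @param seed RNG seed.
#' @return A list of class `toy_sim_spec`.
#' @export
toy_sim_spec <- function(counts = c(solute = 60, water = 150, ethanol = 90),
                         eps = NULL,
                         box = c(5, 5, 5), dt = 0.002, n_steps = 5000,
                         T_param = 0.15, charge = NULL, field = NULL,
                         field_mobility = 0.01, sigma_core = 0.35,
                         cutoff = 0.6, repulsion = 10,
                         coulomb_strength = 0.05, kappa = 2,
                         d_max = 0.05, sample_every = 100,
                         field_heating = 12,
                         field_spatial = c("uniform", "standing"),
                         init = c("random", "slab", "droplet"),
                         slab_width = 0.3, droplet_spacing = 0.45,
                         init_positions = NULL, seed = 1) {
  field_spatial <- match.arg(field_spatial)
  init <- match.arg(init)
  if (cutoff <= sigma_core) stop("cutoff must exceed sigma_core")
  if (field_heating < 0) stop("field_heating must be non-negative")
  if (repulsion <= 0) stop("repulsion must be positive")
  if (slab_width <= 0 || slab_width >= 1) stop("slab_width must be in (0, 1)")
  if (droplet_spacing <= 0) stop("droplet_spacing must be positive")
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    stop("counts must be named by species")
  }
  if (any(counts < 0)) stop("counts must be non-negative")
  if (sum(counts) < 1) stop("need at least one particle")
  if (sum(counts) > 2000) stop("desk-scale guard: at most 2000 particles")
  sp <- names(counts)
  if (is.null(eps)) {
    eps <- matrix(0.2, length(sp), length(sp), dimnames = list(sp, sp))
    if ("solute" %in% sp) {
      eps["solute", "solute"] <- 2
      if ("water" %in% sp) {
        eps["solute", "water"] <- 0.4
        eps["water", "solute"] <- 0.4
      }
    }
  }
  eps <- as.matrix(eps)
  if (!isTRUE(all.equal(eps, t(eps)))) stop("eps must be symmetric")
  if (nrow(eps) != length(sp)) stop("eps must be species x species")
  if (is.null(charge)) {
    charge <- stats::setNames(rep(0, length(sp)), sp)
    if ("solute" %in% sp) charge["solute"] <- -3
  }
  if (dt <= 0 || n_steps <= 0) stop("dt and n_steps must be positive")
  if (T_param < 0) stop("T_param must be non-negative")
  if (!is.null(field)) stopifnot(inherits(field, "pulsed_field"))
  structure(
    list(counts = counts, eps = eps, box = box, dt = dt, n_steps = n_steps,
         T_param = T_param, charge = charge, field = field,
         field_mobility = field_mobility, sigma_core = sigma_core,
         repulsion = repulsion,
         cutoff = cutoff, coulomb_strength = coulomb_strength, kappa = kappa,
         d_max = d_max, sample_every = sample_every,
         field_heating = field_heating, field_spatial = field_spatial,
         init = init, slab_width = slab_width,
         droplet_spacing = droplet_spacing,
         init_positions = init_positions, seed = seed),
    class = "toy_sim_spec"
  )
}

#' Run the toy Brownian-dynamics simulator
#'
#' Overdamped update per particle:
#' `x <- x + dt (F_pair + q mu E(t) cos(2 pi x / L) e_axis) +
#' sqrt(2 T dt) N(0, 1)`, with periodic wrapping (the standing-wave
#' factor is dropped under `field_spatial = "uniform"`). Pair forces
#' come from the bounded soft-core potential with species-pair depths
#' `eps` plus a truncated screened-Coulomb term between charged
#' particles. Energies
#' are logged per species pair every `sample_every` steps, split into
#' `LJ-SR`- and `Coul-SR`-labelled terms so the MD-analysis readers
#' consume them unchanged; frames are logged at the same cadence.
#' Everything is reproducible from `spec$seed`.
#'
#' @param spec a [toy_sim_spec()].
#' @return A list of class `toy_sim_result`: `trajectory` (list of
#'   [particle_frame()]), `energies` (an [energy_series()] with columns
#'   `Coul-SR:<a>-<b>` / `LJ-SR:<a>-<b>`), and `spec`.
#' @export
#' @examples
#' \donttest{
#' res <- toy_simulate(toy_sim_spec(counts = c(solute = 10, water = 20),
#'                                  n_steps = 200, seed = 7))
#' length(res$trajectory)
#' }
toy_simulate <- function(spec) {
  stopifnot(inherits(spec, "toy_sim_spec"))
  sp <- names(spec$counts)
  species <- rep(sp, times = spec$counts)
  n <- length(species)
  species_idx <- match(species, sp) - 1L

  withr_seed(spec$seed, {
    pos <- cbind(stats::runif(n, 0, spec$box[1]),
                 stats::runif(n, 0, spec$box[2]),
                 stats::runif(n, 0, spec$box[3]))
    if (!is.null(spec$init_positions)) {
      pos <- as.matrix(spec$init_positions)
      if (nrow(pos) != n || ncol(pos) != 3) {
        stop("init_positions must be a ", n, " x 3 matrix")
      }
      pos <- sweep(pos, 2, spec$box, function(p, b) p - b * floor(p / b))
    } else if (spec$init == "droplet") {
      sol <- species == "solute"
      n_sol <- sum(sol)
      if (n_sol > 0) {
        # sphere radius holding n_sol particles at the nominal spacing
        r0 <- (3 * n_sol * spec$droplet_spacing^3 / (4 * pi))^(1 / 3)
        ctr <- spec$box / 2
        u <- matrix(stats::rnorm(3 * n_sol), ncol = 3)
        u <- u / sqrt(rowSums(u^2))
        rad <- r0 * stats::runif(n_sol)^(1 / 3)
        pos[sol, ] <- sweep(u * rad, 2, ctr, "+")
        # keep solvents out of the droplet: resample any inside
        for (pass in 1:20) {
          d2c <- rowSums(sweep(pos, 2, ctr, "-")^2)
          inside <- which(!sol & d2c < r0^2)
          if (length(inside) == 0) break
          pos[inside, ] <- cbind(stats::runif(length(inside), 0, spec$box[1]),
                                 stats::runif(length(inside), 0, spec$box[2]),
                                 stats::runif(length(inside), 0, spec$box[3]))
        }
      }
    }
    if (is.null(spec$init_positions) && spec$init == "slab") {
      half <- spec$slab_width * spec$box[1] / 2
      mid <- spec$box[1] / 2
      sol <- species == "solute"
      pos[sol, 1] <- stats::runif(sum(sol), mid - half, mid + half)
      # solvents occupy the complement, split across both sides
      out_w <- spec$box[1] - 2 * half
      u <- stats::runif(sum(!sol), 0, out_w)
      pos[!sol, 1] <- ifelse(u < mid - half, u, u + 2 * half)
    }
    # resolve (measure-zero) coincident placements by seeded jitter
    for (pass in 1:5) {
      d2 <- min_image_dist2(pos, spec$box)
      diag(d2) <- Inf
      clash <- unique(which(d2 < 1e-8, arr.ind = TRUE)[, 1])
      if (length(clash) == 0) break
      pos[clash, ] <- pos[clash, ] + stats::rnorm(3 * length(clash), 0, 1e-3)
      pos <- sweep(pos, 2, spec$box, function(p, b) p - b * floor(p / b))
    }

    field_drift <- if (is.null(spec$field)) {
      numeric(spec$n_steps)
    } else {
      t_grid <- (seq_len(spec$n_steps) - 1) * spec$dt
      spec$field_mobility * field_at(spec$field, t_grid)
    }
    axis <- if (is.null(spec$field)) 0L else {
      match(spec$field$axis, c("x", "y", "z")) - 1L
    }

    raw <- .run_toy_sim(
      pos, species_idx, spec$eps,
      unname(spec$charge[species]), spec$box, spec$dt,
      as.integer(spec$n_steps), sqrt(2 * spec$T_param * spec$dt),
      field_drift, axis, spec$sigma_core, spec$cutoff, spec$repulsion,
      spec$coulomb_strength, spec$kappa, as.integer(spec$sample_every),
      spec$d_max,
      if (is.null(spec$field) || spec$field_spatial == "uniform") 0 else
        2 * pi / spec$box[axis + 1L],
      spec$field_heating, spec$dt
    )

    if (isTRUE(raw$diverged)) {
      stop("step-size error: |F| dt exceeded box/2 at step ",
           raw$diverge_step, "; reduce dt or interaction strengths")
    }

    ns <- raw$n_samples
    trajectory <- lapply(raw$frames[seq_len(ns)], function(p) {
      particle_frame(p, species, spec$box, wrap = TRUE)
    })

    pair_names <- character(0)
    for (a in seq_along(sp)) {
      for (b in a:length(sp)) {
        pair_names <- c(pair_names, paste0(sp[a], "-", sp[b]))
      }
    }
    cols <- list()
    for (p in seq_along(pair_names)) {
      cols[[paste0("Coul-SR:", pair_names[p])]] <- raw$coul[seq_len(ns), p]
      cols[[paste0("LJ-SR:", pair_names[p])]] <- raw$lj[seq_len(ns), p]
    }
    time <- raw$t_ps[seq_len(ns)]
    # a single sample (n_steps < sample_every) still needs a valid series
    energies <- energy_series(time, cols,
                              metadata = list(spec = spec, groups = sp))
    structure(list(trajectory = trajectory, energies = energies, spec = spec),
              class = "toy_sim_result")
  })
}

#' @export
print.toy_sim_result <- function(x, ...) {
  cat(sprintf("Toy simulation: %d particles, %d frames, %d energy column(s)\n",
              nrow(x$trajectory[[1]]$positions), length(x$trajectory),
              length(x$energies$columns)))
  invisible(x)
}

#' Reference (pure-R) pair-energy evaluation for a frame
#'
#' Recomputes the simulator's per-species-pair potential energies for a
#' single configuration directly from the pair-potential definitions.
#' Intended for validating the simulator's energy log on small systems.
#'
#' @param frame a [particle_frame()].
#' @param spec the [toy_sim_spec()] whose potential parameters to use.
#' @return Named list: per species pair, `lj` and `coul` energy sums.
#' @export
pair_energy_reference <- function(frame, spec) {
  sp <- names(spec$counts)
  pos <- frame$positions
  n <- nrow(pos)
  r_floor <- 0.6 * spec$sigma_core
  well_w <- spec$cutoff - spec$sigma_core
  coul_shift <- exp(-spec$kappa * spec$cutoff) / spec$cutoff
  out <- list()
  q <- spec$charge[frame$species]
  for (a in seq_along(sp)) {
    for (b in a:length(sp)) {
      key <- paste0(sp[a], "-", sp[b])
      out[[key]] <- list(lj = 0, coul = 0)
    }
  }
  if (n < 2) return(out)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      d <- pos[i, ] - pos[j, ]
      d <- d - frame$box * round(d / frame$box)
      r <- sqrt(sum(d^2))
      if (r > spec$cutoff) next
      r_eff <- max(r, r_floor)
      a <- match(frame$species[i], sp); b <- match(frame$species[j], sp)
      key <- paste0(sp[min(a, b)], "-", sp[max(a, b)])
      e <- spec$eps[a, b]
      if (e != 0) {
        u <- if (r < spec$sigma_core) {
          spec$repulsion * (1 - r / spec$sigma_core)^2 - e
        } else {
          -e * cos(pi * (r - spec$sigma_core) / (2 * well_w))^2
        }
        out[[key]]$lj <- out[[key]]$lj + u
      }
      qq <- unname(q[i] * q[j])
      if (qq != 0 && spec$coulomb_strength != 0) {
        out[[key]]$coul <- out[[key]]$coul +
          spec$coulomb_strength * qq * (exp(-spec$kappa * r_eff) / r_eff -
                                          coul_shift)
      }
    }
  }
  out
}

#' Canonical pulsed field for the demixing scenario
#'
#' The pulse used in the field-amplitude sweeps: peak at three quarters
#' of the run, envelope width one eighth of the run, carrier frequency
#' 2 rad/ps, applied along x.
#'
#' @param amplitude peak field, V/nm; `0` returns `NULL` (silent run).
#' @param n_steps,dt the simulation schedule the pulse is matched to.
#' @return A [pulsed_field()], or `NULL` for amplitude 0.
#' @export
demixing_field <- function(amplitude, n_steps = 5000, dt = 0.002) {
  if (amplitude == 0) return(NULL)
  t_total <- n_steps * dt
  pulsed_field(E0 = amplitude, t0 = 0.75 * t_total, sigma_t = t_total / 8,
               omega_rad_per_ps = 2, axis = "x")
}

#' Canonical demixing scenario for the toy simulator
#'
#' The study conditions of the field-amplitude experiments: an
#' oiled-out solute droplet (droplet init) held together by dominant
#' solute-solute attraction, optionally worked on by the pulsed field.
#' Identical to `toy_sim_spec(init = "droplet", ...)` with the package
#' defaults; provided so sweeps vary only amplitude and seed.
#'
#' @param amplitude peak field in V/nm (0 = silent).
#' @param seed RNG seed.
#' @param n_steps number of steps (default 5000).
#' @return A [toy_sim_spec()].
#' @export
#' @examples
#' \donttest{
#' res <- toy_simulate(demixing_spec(amplitude = 15, seed = 1,
#'                                   n_steps = 500))
#' }
demixing_spec <- function(amplitude = 0, seed = 1, n_steps = 5000) {
  toy_sim_spec(n_steps = n_steps,
               field = demixing_field(amplitude, n_steps = n_steps),
               init = "droplet", seed = seed)
}
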