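make_xvg <- function(path, legends, rows, extra = character(0)) {
  lines <- c(
    "# created by an energy extraction run",
    '@    title "Interaction energies"',
    sprintf('@ s%d legend "%s"', seq_along(legends) - 1, legends),
    extra,
    rows
  )
  writeLines(lines, path)
  path
}

test_that("XVG energy tables parse legends, comments and data rows", {
  path <- withr::local_tempfile(fileext = ".xvg")
  make_xvg(path, c("Coul-SR:FDP-FDP", "LJ-SR:FDP-FDP"),
           c("0.0 -100.5 -45.5", "10.0 -101.0 -46.0", "20.0 -99.5 -46.5"))
  es <- read_energy_table(path)
  expect_s3_class(es, "energy_series")
  expect_length(es$time, 3)
  expect_named(es$columns, c("Coul-SR:FDP-FDP", "LJ-SR:FDP-FDP"))
  expect_equal(es$columns[["LJ-SR:FDP-FDP"]], c(-45.5, -46.0, -46.5))

  # unknown legends survive under the other: namespace
  p2 <- withr::local_tempfile(fileext = ".xvg")
  make_xvg(p2, c("Coul-SR:FDP-SOL", "Pressure"), c("0 1 2", "1 3 4"))
  es2 <- read_energy_table(p2)
  expect_true("other:Pressure" %in% names(es2$columns))
})

test_that("degenerate XVG inputs fail loudly", {
  p <- withr::local_tempfile(fileext = ".xvg")
  make_xvg(p, "Coul-SR:FDP-FDP", character(0))
  expect_error(read_energy_table(p), "no data rows")

  p2 <- withr::local_tempfile(fileext = ".xvg")
  make_xvg(p2, "Coul-SR:FDP-FDP", c("0 1", "1 2 3"))
  expect_error(read_energy_table(p2), "ragged row at data line 2")

  p3 <- withr::local_tempfile(fileext = ".xvg")
  writeLines(c("0 1", "1 2"), p3)
  expect_warning(es <- read_energy_table(p3), "no legends")
  expect_named(es$columns, "other:col1")
})

test_that("energy series survive a write/read round-trip", {
  es <- energy_series(
    time = c(0, 0.5, 1.5),
    columns = list("Coul-SR:solute-solute" = c(-1.25, -2.5, -3.75),
                   "LJ-SR:solute-solute" = c(0.1, -0.2, 0.3))
  )
  path <- withr::local_tempfile(fileext = ".xvg")
  write_energy_table(es, path)
  back <- read_energy_table(path)
  expect_identical(back$time, es$time)
  expect_identical(back$columns, es$columns)
})

test_that("pair energy sums Coul-SR and LJ-SR with a brute-force tail mean", {
  n <- 40
  es <- energy_series(
    time = seq_len(n),
    columns = list("Coul-SR:FDP-FDP" = rep(-100, n),
                   "LJ-SR:FDP-FDP" = rep(-46, n))
  )
  pe <- pair_energy(es, "FDP-FDP")
  expect_true(all(pe$total == -146))
  expect_equal(pe$tail_mean, -146)

  # zero LJ leaves the Coulomb series untouched
  set.seed(3)
  coul <- rnorm(n)
  es2 <- energy_series(seq_len(n),
                       list("Coul-SR:a-b" = coul, "LJ-SR:a-b" = rep(0, n)))
  expect_equal(pair_energy(es2, "a-b")$total, coul)

  # random series: tail mean equals the direct mean of the last ceil(f n)
  for (f in c(0.1, 0.25, 0.5, 1)) {
    set.seed(17)
    a <- rnorm(n); b <- rnorm(n)
    es3 <- energy_series(seq_len(n), list("Coul-SR:x-y" = a, "LJ-SR:x-y" = b))
    k <- ceiling(f * n)
    expect_equal(pair_energy(es3, "x-y", f = f)$tail_mean,
                 mean((a + b)[(n - k + 1):n]))
  }

  expect_error(pair_energy(es, "FDP-SOL"), "missing energy column")
})

test_that("particle frames enforce wrapped coordinates", {
  expect_error(particle_frame(rbind(c(5.5, 1, 1)), "solute", c(5, 5, 5)),
               "wrap")
  fr <- particle_frame(rbind(c(5.5, -0.5, 1)), "solute", c(5, 5, 5),
                       wrap = TRUE)
  expect_equal(fr$positions[1, ], c(0.5, 4.5, 1))
})

test_that("density profiles conserve particle counts", {
  # all particles at one point occupy a single bin
  pos <- matrix(rep(c(1.2, 2.0, 3.0), each = 5), ncol = 3)
  fr <- particle_frame(pos, rep("solute", 5), c(5, 5, 5))
  prof <- density_profile(fr, "x", 10)
  expect_equal(sum(prof$counts["solute", ] > 0), 1)
  expect_equal(sum(prof$counts["solute", ]), 5)

  # one bin over the whole box gives N / V
  prof1 <- density_profile(fr, "z", 1)
  expect_equal(unname(prof1$density["solute", 1]), 5 / 125)

  # conservation on 100 seeded random frames
  for (seed in 1:100) {
    fr <- random_frame(seed)
    prof <- density_profile(fr, c("x", "y", "z")[seed %% 3 + 1],
                            n_bins = seed %% 7 + 1)
    for (s in rownames(prof$counts)) {
      expect_equal(sum(prof$counts[s, ]), sum(fr$species == s))
      expect_equal(sum(prof$density[s, ] * prof$bin_volume),
                   sum(fr$species == s))
    }
  }
})

test_that("demixing index measures total-variation separation", {
  # 3-bin construction: p_a = (.5, .5, 0), p_b = (0, .5, .5)
  pos <- rbind(c(0.5, 1, 1), c(1.5, 1, 1),   # species a in bins 1, 2
               c(1.5, 2, 1), c(2.5, 2, 1))   # species b in bins 2, 3
  fr <- particle_frame(pos, c("a", "a", "b", "b"), c(3, 3, 3))
  prof <- density_profile(fr, "x", 3)
  expect_equal(demixing_index(prof, "a", "b"), 0.5)
  expect_equal(demixing_index(prof, "b", "a"), 0.5)  # symmetric

  # identical distributions
  fr2 <- particle_frame(rbind(c(0.5, 1, 1), c(0.5, 2, 1)), c("a", "b"),
                        c(3, 3, 3))
  expect_equal(demixing_index(density_profile(fr2, "x", 3), "a", "b"), 0)

  # disjoint half-boxes
  fr3 <- particle_frame(rbind(c(0.5, 1, 1), c(1.0, 1, 1),
                              c(2.2, 1, 1), c(2.8, 1, 1)),
                        c("a", "a", "b", "b"), c(3, 3, 3))
  expect_equal(demixing_index(density_profile(fr3, "x", 2), "a", "b"), 1)

  expect_error(demixing_index(prof, "a", "zzz"), "absent")
})

test_that("cutoff clustering matches a brute-force oracle under PBC", {
  # direct contact just inside the cutoff
  fr <- particle_frame(rbind(c(1, 1, 1), c(1.99, 1, 1)),
                       c("solute", "solute"), c(5, 5, 5))
  cs <- cluster_by_cutoff(fr, "solute", 1.0)
  expect_equal(length(cs$sizes), 1)
  expect_equal(unname(cs$sizes), 2L)

  # linked only through the periodic image
  fr2 <- particle_frame(rbind(c(0.1, 1, 1), c(4.9, 1, 1)),
                        c("solute", "solute"), c(5, 5, 5))
  expect_equal(length(cluster_by_cutoff(fr2, "solute", 0.3)$sizes), 1)
  expect_equal(length(cluster_by_cutoff(fr2, "solute", 0.1)$sizes), 2)

  # oracle equivalence on random frames
  for (seed in 1:40) {
    fr <- random_frame(seed, n = 10 + seed %% 41)
    cutoff <- runif(1, 0.3, 1.5)
    got <- cluster_by_cutoff(fr, "solute", cutoff)
    ora <- brute_cluster(fr, "solute", cutoff)
    expect_identical(got$particle_index, ora$particle_index)
    expect_true(same_partition(got$cluster_id, ora$cluster_id))
  }

  # no particles of the species: empty set, not an error
  empty <- cluster_by_cutoff(random_frame(1), "ethanol", 0.5)
  expect_length(empty$cluster_id, 0)
})

test_that("growing the cutoff never increases the cluster count", {
  for (seed in 1:10) {
    fr <- random_frame(seed, n = 40)
    ks <- vapply(c(0.2, 0.4, 0.6, 0.9, 1.3, 2.0), function(cc) {
      length(cluster_by_cutoff(fr, "solute", cc)$sizes)
    }, numeric(1))
    expect_true(all(diff(ks) <= 0))
  }
})

test_that("GRO frames round-trip with species mapping", {
  fr <- particle_frame(
    rbind(c(1.25, 2.5, 3.75), c(0.125, 4.875, 2.0), c(3.3, 1.1, 0.2)),
    c("solute", "water", "ethanol"), c(5, 5, 5)
  )
  path <- withr::local_tempfile(fileext = ".gro")
  write_gro(fr, path)
  back <- read_gro(path)
  expect_equal(back$species, fr$species)
  expect_equal(back$positions, fr$positions, tolerance = 1e-3)
  expect_equal(back$box, fr$box)

  # triclinic box vectors are refused
  lines <- readLines(path)
  lines[length(lines)] <- "   5.0   5.0   5.0   0.0   0.0   1.2"
  writeLines(lines, path)
  expect_error(read_gro(path), "triclinic")
})

test_that("onset detection finds sustained exceedances only", {
  expect_null(onset_time(rep(50, 100)))

  # clean step at a known index
  set.seed(1)
  counts <- c(rnorm(60, 50, 1), rnorm(40, 200, 1))
  res <- onset_time(counts)
  expect_equal(res$index, 61)

  # seeded noisy steps recovered within m samples
  for (seed in 1:20) {
    cs <- gen_counts_series(n = 150, onset_index = 90, step = 30,
                            noise_sd = 3, seed = seed)
    res <- onset_time(as.numeric(cs))
    expect_false(is.null(res))
    expect_lte(abs(res$index - 90), 3)
  }

  # zero step and slope: nothing to detect
  flat <- gen_counts_series(n = 100, onset_index = 50, step = 0, slope = 0,
                            noise_sd = 1, seed = 2)
  expect_null(onset_time(as.numeric(flat)))

  expect_error(onset_time(c(1, 2, 3)), "baseline")
  expect_error(onset_time(c(-1, rep(0, 30))), "non-negative")
})
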