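test_that("noiseless induction data invert exactly and runs are deterministic", {
  spec <- induction_gen_spec(A1 = 9.2, B1 = 0.4, A2 = 8.1, B2 = 0.9,
                             split_S = 2.05, noise_sd = 0, seed = 5)
  rec <- gen_induction_dataset(spec)
  fit <- fit_two_branch(transform_axes(rec), split = 2.05)
  expect_equal(fit$low$A, 9.2, tolerance = 1e-10)
  expect_equal(fit$low$B, 0.4, tolerance = 1e-10)
  expect_equal(fit$high$A, 8.1, tolerance = 1e-10)
  expect_equal(fit$high$B, 0.9, tolerance = 1e-10)

  # noiseless log-times are non-increasing in S within each branch
  for (b in c("low", "high")) {
    sub <- rec[rec$branch_true == b, ]
    sub <- sub[order(sub$S), ]
    expect_true(all(diff(log(sub$t_ind_s)) <= 0))
  }

  # identical bytes for identical specs
  noisy <- induction_gen_spec(A1 = 9, B1 = 0.4, A2 = 8, B2 = 0.9,
                              split_S = 2.05, noise_sd = 0.05, seed = 7)
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write.csv(as.data.frame(gen_induction_dataset(noisy)), p1, row.names = FALSE)
  write.csv(as.data.frame(gen_induction_dataset(noisy)), p2, row.names = FALSE)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
})

test_that("single-slope data leave the auto split indifferent", {
  spec <- induction_gen_spec(A1 = 9, B1 = 0.6, A2 = 9, B2 = 0.6,
                             split_S = 2.05, noise_sd = 0, seed = 1)
  fit <- fit_two_branch(transform_axes(gen_induction_dataset(spec)))
  expect_true(fit$rss_tie)
})

test_that("induction noise is lognormal in time (normal in log)", {
  spec <- induction_gen_spec(A1 = 9, B1 = 0.5, A2 = 9, B2 = 0.5,
                             split_S = 2.05, S_grid = rep(2, 1),
                             replicates = 1000, noise_sd = 0.05, seed = 99)
  rec <- gen_induction_dataset(spec)
  resid <- log(rec$t_ind_s) - (9 + 0.5 / log(2)^2)
  expect_gt(shapiro.test(resid[1:1000])$p.value, 0.01)
  expect_equal(sd(resid), 0.05, tolerance = 0.15)
})

test_that("generated phase splits close the balance and enrich the oil phase", {
  ov <- ternary(0.55, 0.30, 0.15)
  # unity partition coefficients clone the overall composition
  sp1 <- gen_phase_split(ov, 100, partition = c(w_solute = 1),
                         dense_fraction = 0.4)
  expect_equal(unclass(sp1$dense), unclass(ov), tolerance = 1e-12)
  expect_equal(unclass(sp1$light), unclass(ov), tolerance = 1e-12)
  expect_equal(sp1$dense_mass_g, 40, tolerance = 1e-12)

  set.seed(21)
  for (i in 1:20) {
    sp <- gen_phase_split(
      ov, runif(1, 10, 200),
      partition = c(w_solute = runif(1, 1.5, 10), w_water = runif(1, 0.2, 1)),
      dense_fraction = runif(1, 0.05, 0.95)
    )
    expect_true(all(check_mass_balance(sp, tol = 1e-12)$residuals < 1e-12))
    expect_gte(sp$dense[["w_solute"]], sp$light[["w_solute"]])
    expect_gt(sp$dense[["w_solute"]], ov[["w_solute"]])
  }

  expect_error(gen_phase_split(ov, 100, dense_fraction = 1.2),
               "infeasible")
  expect_error(gen_phase_split(ov, 100, partition = c(w_solute = -2)),
               "infeasible")
})

test_that("counts-series generator embeds a recoverable onset", {
  clean <- gen_counts_series(n = 200, onset_index = 120, noise_sd = 0, seed = 1)
  expect_equal(onset_time(as.numeric(clean), k = 5, m = 3)$index, 120)

  hits <- 0
  for (seed in 1:50) {
    cs <- gen_counts_series(n = 200, onset_index = 120, step = 40,
                            noise_sd = 4, seed = seed)
    res <- onset_time(as.numeric(cs))
    if (!is.null(res) && abs(res$index - 120) <= 3) hits <- hits + 1
  }
  expect_gte(hits, 45)  # >= 90 % recovery at 10 % relative noise
})

test_that("toy simulator is inert without interactions, noise or field", {
  spec <- toy_sim_spec(counts = c(solute = 5, water = 5),
                       eps = matrix(0, 2, 2,
                                    dimnames = list(c("solute", "water"),
                                                    c("solute", "water"))),
                       charge = c(solute = 0, water = 0),
                       T_param = 0, n_steps = 200, sample_every = 50,
                       seed = 3)
  res <- toy_simulate(spec)
  first <- res$trajectory[[1]]$positions
  last <- res$trajectory[[length(res$trajectory)]]$positions
  expect_identical(last, first)
  for (col in res$energies$columns) expect_true(all(col == 0))
})

test_that("logged pair energies match the closed-form potential on 3 particles", {
  pos <- rbind(c(1.0, 1.0, 1.0),   # solute
               c(1.3, 1.0, 1.0),   # solute, inside the core (r = 0.3)
               c(1.0, 1.45, 1.0))  # water, in the well of particle 1
  spec <- toy_sim_spec(counts = c(solute = 2, water = 1),
                       charge = c(solute = -3, water = 0),
                       T_param = 0, n_steps = 1, sample_every = 1,
                       init_positions = pos, seed = 1)
  res <- toy_simulate(spec)
  ref <- pair_energy_reference(res$trajectory[[1]], spec)

  # hand evaluation: core term A(1 - r/s)^2 - e at r = 0.3; well term
  # -e cos^2(pi (r - s) / (2 w)) for both solute-water separations
  # (0.45 and sqrt(0.3^2 + 0.45^2), both inside the 0.6 nm range)
  e_ss <- spec$eps["solute", "solute"]
  u_ss <- spec$repulsion * (1 - 0.3 / 0.35)^2 - e_ss
  w <- spec$cutoff - spec$sigma_core
  well <- function(r) {
    -spec$eps["solute", "water"] *
      cos(pi * (r - spec$sigma_core) / (2 * w))^2
  }
  u_sw <- well(0.45) + well(sqrt(0.3^2 + 0.45^2))
  expect_equal(ref[["solute-solute"]]$lj, u_ss, tolerance = 1e-12)
  expect_equal(ref[["solute-water"]]$lj, u_sw, tolerance = 1e-12)

  expect_equal(res$energies$columns[["LJ-SR:solute-solute"]][1], u_ss,
               tolerance = 1e-10)
  expect_equal(res$energies$columns[["LJ-SR:solute-water"]][1], u_sw,
               tolerance = 1e-10)

  # screened-Coulomb term at r = 0.3 between the charges
  q2 <- 9
  u_c <- spec$coulomb_strength * q2 *
    (exp(-spec$kappa * 0.3) / 0.3 - exp(-spec$kappa * spec$cutoff) / spec$cutoff)
  expect_equal(res$energies$columns[["Coul-SR:solute-solute"]][1], u_c,
               tolerance = 1e-10)
})

test_that("simulator energy log agrees with the pure-R reference on later frames", {
  spec <- toy_sim_spec(counts = c(solute = 8, water = 10, ethanol = 6),
                       n_steps = 300, sample_every = 100, seed = 12)
  res <- toy_simulate(spec)
  i_last <- length(res$trajectory)
  ref <- pair_energy_reference(res$trajectory[[i_last]], spec)
  for (pair in names(ref)) {
    expect_equal(res$energies$columns[[paste0("LJ-SR:", pair)]][i_last],
                 ref[[pair]]$lj, tolerance = 1e-8)
    expect_equal(res$energies$columns[[paste0("Coul-SR:", pair)]][i_last],
                 ref[[pair]]$coul, tolerance = 1e-8)
  }
})

test_that("toy runs conserve particles, stay wrapped and reproduce from seed", {
  spec <- toy_sim_spec(counts = c(solute = 15, water = 20, ethanol = 10),
                       n_steps = 400, sample_every = 100, seed = 8)
  res <- toy_simulate(spec)
  for (fr in res$trajectory) {
    expect_equal(sum(fr$species == "solute"), 15)
    expect_equal(sum(fr$species == "water"), 20)
    expect_true(all(fr$positions >= 0 & fr$positions < 5))
  }
  res2 <- toy_simulate(spec)
  expect_identical(res$trajectory[[5]]$positions,
                   res2$trajectory[[5]]$positions)
  expect_identical(res$energies$columns, res2$energies$columns)

  expect_error(toy_sim_spec(counts = c(solute = 3000)), "desk-scale")
})

test_that("generator outputs feed the analysis stages without coercion", {
  rec <- gen_induction_dataset(
    induction_gen_spec(A1 = 9, B1 = 0.4, A2 = 8, B2 = 0.9, split_S = 2.05,
                       seed = 2))
  expect_s3_class(cnt_table(rec, fdp_mol(), split = 2.05), "data.frame")

  res <- toy_simulate(toy_sim_spec(counts = c(solute = 10, water = 10),
                                   n_steps = 200, sample_every = 100,
                                   seed = 4))
  expect_s3_class(res$energies, "energy_series")
  pe <- pair_energy(res$energies, "solute-solute")
  expect_true(is.finite(pe$tail_mean))
  last <- res$trajectory[[length(res$trajectory)]]
  expect_s3_class(density_profile(last, "x", 8), "density_profile")
  expect_s3_class(cluster_by_cutoff(last, "solute", 0.5), "cluster_set")

  # round-trip through the on-disk formats the analysis modules read
  xvg <- withr::local_tempfile(fileext = ".xvg")
  write_energy_table(res$energies, xvg)
  expect_identical(read_energy_table(xvg)$columns, res$energies$columns)
  gro <- withr::local_tempfile(fileext = ".gro")
  write_gro(last, gro)
  expect_equal(read_gro(gro)$species, last$species)
})

test_that("the demixing scenario demixes without a field", {
  res <- toy_simulate(demixing_spec(amplitude = 0, seed = 11))
  last <- res$trajectory[[length(res$trajectory)]]
  d <- demixing_index(density_profile(last, "x", 10), "solute", "ethanol")
  expect_gt(d, 0.5)
  # a cohesive droplet has strongly negative solute-solute energy
  expect_lt(pair_energy(res$energies, "solute-solute")$tail_mean, -500)
})
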