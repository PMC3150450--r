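test_that("phage-free growth follows the exact logistic solution", {
  p <- phage_host_params(mu = 0.466)
  pr <- passage_protocol("copropagation", duration = 8, initial_cells = 3e5,
                         initial_phage = 0)
  tc <- simulate_within_day(p, pr, grid = 0.01)$time_courses$total_cells
  exact <- logistic_exact(tc$times, 3e5, p$mu, p$carrying_capacity)
  expect_lt(max(abs(tc$values - exact) / exact), 1e-6)
})

test_that("without cells the free phage stay constant", {
  p <- phage_host_params()
  pr <- passage_protocol("copropagation", duration = 6, initial_cells = 0,
                         initial_phage = 1e7)
  tc <- simulate_within_day(p, pr, grid = 0.05)$time_courses$free_phage
  expect_equal(tc$values, rep(1e7, length(tc$times)), tolerance = 1e-9)
})

test_that("without growth, uninfected plus latent cells only decrease by lysis", {
  p <- phage_host_params(mu = 0, burst_size = 50)
  pr <- passage_protocol("phage_only", duration = 4, initial_cells = 2e7,
                         initial_phage = 1e7)
  sim <- simulate_within_day(p, pr, grid = 0.01)
  cells <- sim$time_courses$total_cells$values  # S + sum(E)
  expect_true(all(diff(cells) <= 1e-6 * cells[1]))
})

test_that("the calibrated phage-only scenario amplifies about a thousandfold in six hours", {
  p <- phage_host_params(mu = 0.46)  # defaults carry the calibrated burst size
  pr <- passage_protocol("phage_only", duration = 6, initial_cells = 2e7,
                         initial_phage = 1e7)
  tc <- simulate_within_day(p, pr, grid = 0.01)$time_courses$free_phage
  fold <- tc$values[length(tc$values)] / tc$values[1]
  expect_gt(fold, 1000 / 3)
  expect_lt(fold, 1000 * 3)
})

test_that("burst-size bisection hits a requested amplification", {
  p <- phage_host_params(mu = 0.46)
  pr <- passage_protocol("phage_only", duration = 6, initial_cells = 2e7,
                         initial_phage = 1e7)
  b <- tune_burst_size(p, pr, target_fold = 500, grid = 0.02)
  p$burst_size <- b
  tc <- simulate_within_day(p, pr, grid = 0.02)$time_courses$free_phage
  fold <- tc$values[length(tc$values)] / tc$values[1]
  expect_equal(fold, 500, tolerance = 0.02)
})

test_that("seeded stochastic runs are reproducible and match the ODE mean at small counts", {
  p <- phage_host_params(mu = 0.4, carrying_capacity = 2000,
                         od_per_cell = 0.4 / 2000, k_ads = 2e-5,
                         burst_size = 20)
  pr <- passage_protocol("copropagation", duration = 3, initial_cells = 400,
                         initial_phage = 150)
  s1 <- simulate_within_day(p, pr, grid = 0.002, seed = 11, volume_ml = 1)
  s2 <- simulate_within_day(p, pr, grid = 0.002, seed = 11, volume_ml = 1)
  expect_identical(s1$trajectory, s2$trajectory)

  det <- simulate_within_day(p, pr, grid = 0.002, volume_ml = 1)
  runs <- lapply(1:200, function(s)
    simulate_within_day(p, pr, grid = 0.002, seed = s, volume_ml = 1))
  idx <- seq(51, length(det$time_courses$free_phage$values), by = 50)
  for (ent in c("free_phage", "total_cells", "infected_cells")) {
    detv <- det$time_courses[[ent]]$values[idx]
    mat <- vapply(runs, function(r) r$time_courses[[ent]]$values[idx],
                  numeric(length(idx)))
    m <- rowMeans(mat)
    se <- apply(mat, 1, sd) / sqrt(length(runs))
    expect_lt(max(abs(m - detv) / pmax(se, 1e-9)), 3)
  }
})

test_that("serial passages without phage repeat the same cell generations daily", {
  p <- phage_host_params()
  pr <- passage_protocol("copropagation", duration = 24, target = 0.05,
                         initial_cells = 3.75e7, initial_phage = 0)
  sim <- run_serial_passages(p, pr, days = 3)
  gs <- cumulative_generations(sim$records, "cells")
  expect_equal(gs$generations[2], gs$generations[3], tolerance = 1e-6)
  # each day regrows to the plateau, so daily doublings are log2(K / start)
  expect_equal(gs$generations[2],
               log2(p$carrying_capacity / (0.05 / p$od_per_cell)),
               tolerance = 1e-3)
})

test_that("serial-passage dilution bookkeeping is self-consistent", {
  p <- phage_host_params(mu = 0.46)
  pr <- passage_protocol("phage_only", duration = 6, initial_cells = 2e7,
                         initial_phage = 1e7)
  sim <- run_serial_passages(p, pr, days = 5)
  r <- sim$records
  # N_i(d+1) equals N_f(d) divided by day d+1's dilution factor
  expect_equal(r$n_i_phage[-1], r$n_f_phage[-nrow(r)] / r$dilution_factor[-1],
               tolerance = 1e-9)
  # the reader's derivation (N_i blank) reproduces the simulator's counter
  r2 <- r
  r2$n_i_phage[-1] <- NA
  gs <- cumulative_generations(r2, "phage")
  expect_equal(tail(gs$cumulative, 1), sim$phage_generations, tolerance = 1e-9)
})

test_that("partial resistance sustains host and phage through 50+ passages", {
  sc <- coexistence_scenario()
  sim <- run_serial_passages(sc$params, sc$protocol, days = 54)
  expect_equal(nrow(sim$events), 0L)
  r <- sim$records
  expect_true(all(r$n_f_cell > 1e8))
  expect_true(all(r$n_f_phage > 1e3))
  amp <- r$n_f_phage / r$n_i_phage
  # daily amplification inside the experimentally observed 2-20-fold band
  expect_true(all(amp > 2 & amp < 20))
})

test_that("stochastic serial passages are reproducible under one seed", {
  p <- phage_host_params(mu = 0.4, carrying_capacity = 2000,
                         od_per_cell = 0.4 / 2000, k_ads = 2e-5,
                         burst_size = 20)
  pr <- passage_protocol("copropagation", duration = 3, initial_cells = 400,
                         initial_phage = 150)
  s1 <- run_serial_passages(p, pr, days = 3, seed = 5, grid = 0.01, volume_ml = 1)
  s2 <- run_serial_passages(p, pr, days = 3, seed = 5, grid = 0.01, volume_ml = 1)
  expect_identical(s1$records, s2$records)
})

test_that("adsorption assays expose the closed form and seeded noise", {
  tc <- simulate_adsorption_assay(1.4e-9, 3e8, times = c(0, 5))
  expect_equal(tc$values[2] / tc$values[1], exp(-2.1), tolerance = 1e-12)
  flat <- simulate_adsorption_assay(0, 3e8, times = 0:5)
  expect_true(all(flat$values == flat$values[1]))
  n1 <- simulate_adsorption_assay(1.4e-9, 3e8, 0:5, noise_cv = 0.1, seed = 3)
  n2 <- simulate_adsorption_assay(1.4e-9, 3e8, 0:5, noise_cv = 0.1, seed = 3)
  expect_identical(n1$values, n2$values)
  expect_error(simulate_adsorption_assay(1e-9, 3e8, 0:5, noise_cv = -1),
               class = "coevo_parameter_error")
})

test_that("mutation histories have Poisson site counts and known trajectories", {
  ann <- genome_annotation(4217, data.frame(name = "A2", start = 61, end = 1323))
  empty <- simulate_mutation_history(substitution_process_params(0), ann, c(50, 100))
  expect_equal(nrow(empty$sites), 0L)

  counts <- vapply(1:200, function(s) {
    m <- simulate_mutation_history(substitution_process_params(1e-5), ann, 163,
                                   seed = s)
    nrow(m$sites)
  }, numeric(1))
  lambda <- 1e-5 * 4217 * 163
  expect_lt(abs(mean(counts) - lambda), 3 * sqrt(lambda / 200))

  # a long dwell makes every young site polymorphic, then fixed
  sub <- substitution_process_params(5e-5, polymorphic_dwell = 500)
  m <- simulate_mutation_history(sub, ann, c(100, 700), seed = 42)
  expect_true(all(m$status[, "G100"] %in% c("absent", "polymorphic")))
  young <- m$status[, "G100"] == "polymorphic"
  expect_true(all(m$status[young, "G700"] %in% c("polymorphic", "fixed")))

  # certain reversion: sites never fix, polymorphic sites vanish again
  subr <- substitution_process_params(5e-5, polymorphic_dwell = 50,
                                      reversion_prob = 1)
  mr <- simulate_mutation_history(subr, ann, c(25, 1000), seed = 7)
  expect_true(all(mr$status[, "G1000"] != "fixed"))
})

test_that("gene rate multipliers bias sites into the gene at the analytic fraction", {
  ann <- genome_annotation(4217, data.frame(name = "A2", start = 61, end = 1323))
  sub <- substitution_process_params(
    2e-5, gene_rate_multipliers = c(A2 = 5))
  in_gene <- total <- 0
  for (s in 1:300) {
    m <- simulate_mutation_history(sub, ann, 163, seed = s)
    pos <- m$sites$genome_position
    in_gene <- in_gene + sum(pos >= 61 & pos <= 1323)
    total <- total + length(pos)
  }
  frac_a2 <- 1263 / 4217
  expected <- 5 * frac_a2 / (5 * frac_a2 + (1 - frac_a2))
  se <- sqrt(expected * (1 - expected) / total)
  expect_lt(abs(in_gene / total - expected), 3 * se)
})
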