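fixed_cycles <- function(mean) list(family = "fixed", mean = mean, cv = 0)

test_that("synchronous fixed-cycle lineages hit the closed form exactly", {
  cfg <- simulation_config(n_founders = 4, cycle_time = fixed_cycles(16),
                           horizon = 32, recombination_time = 0, seed = 1)
  tree <- simulate_lineages(cfg)
  leaves <- tree[tree$fate != "divided", ]
  expect_true(all(leaves$true_divisions == 2))
  expect_equal(leaves$green / (leaves$green + leaves$red),
               rep(0.75, nrow(leaves)))
  # every node's noiseless state follows red = P * 2^-k
  expect_equal(tree$red, 100 * 2^-tree$true_divisions)
})

test_that("noiseless deterministic green fractions equal the closed form", {
  cfg <- simulation_config(n_founders = 30,
                           cycle_time = list(family = "lognormal", mean = 16,
                                             cv = 0.2),
                           horizon = 70, exit_prob = 0.25, seed = 4)
  tree <- simulate_lineages(cfg)
  expect_equal(tree$green / (tree$green + tree$red),
               green_fraction_after_divisions(tree$true_divisions, 1),
               tolerance = 1e-12)
  # child bookkeeping: birth at parent's division, one more division counted
  kids <- tree[!is.na(tree$parent_id), ]
  par <- tree[match(kids$parent_id, tree$cell_id), ]
  expect_equal(kids$birth_time, par$division_time)
  expect_equal(kids$true_divisions, par$true_divisions + 1L)
  expect_equal(kids$generation, par$generation + 1L)
})

test_that("exit_prob = 1 stops all division after the first generation", {
  cfg <- simulation_config(n_founders = 10, cycle_time = fixed_cycles(10),
                           horizon = 100, exit_prob = 1, seed = 2)
  tree <- simulate_lineages(cfg)
  founders <- tree[is.na(tree$parent_id), ]
  daughters <- tree[!is.na(tree$parent_id), ]
  expect_true(all(founders$fate == "divided"))
  expect_true(all(daughters$fate == "exited"))
  expect_true(all(daughters$true_divisions == 1L))
  # exited cells retain the stable tag ratio they were born with
  expect_equal(daughters$green / (daughters$green + daughters$red),
               rep(0.5, nrow(daughters)))
})

test_that("label totals are conserved across divisions in both modes", {
  for (partition in c("deterministic", "binomial")) {
    cfg <- simulation_config(n_founders = 10, cycle_time = fixed_cycles(12),
                             horizon = 48, partition = partition,
                             pool_size = 1000, seed = 3)
    tree <- simulate_lineages(cfg)
    parents <- tree[tree$fate == "divided", ]
    for (i in seq_len(nrow(parents))) {
      p <- parents[i, ]
      kids <- tree[!is.na(tree$parent_id) & tree$parent_id == p$cell_id, ]
      pool <- p$red + p$green + p$blue
      # daughters share the replication-doubled pool exactly
      expect_equal(sum(kids$red, kids$green, kids$blue), 2 * pool)
    }
    if (partition == "binomial") {
      expect_true(all(tree$red == round(tree$red)))
    }
  }
})

test_that("binomial partitioning is unbiased", {
  cfg <- simulation_config(n_founders = 250, cycle_time = fixed_cycles(16),
                           horizon = 32, partition = "binomial",
                           pool_size = 1e4, seed = 5)
  tree <- simulate_lineages(cfg)
  leaves <- tree[tree$fate != "divided", ]
  expect_equal(nrow(leaves), 1000)
  expect_true(all(leaves$true_divisions == 2))
  frac <- leaves$green / (leaves$green + leaves$red)
  se <- sd(frac) / sqrt(nrow(leaves))
  expect_lt(abs(mean(frac) - 0.75), 3 * se + 1e-12)
  # daughter expected red is half the parent's post-replication red
  parents <- tree[tree$fate == "divided" & tree$true_divisions == 1, ]
  kids <- tree[!is.na(tree$parent_id) &
                 tree$parent_id %in% parents$cell_id, ]
  expect_lt(abs(mean(kids$red) - mean(parents$red) / 2),
            3 * sd(kids$red) / sqrt(nrow(kids)))
})

test_that("simulation is reproducible from its seed", {
  cfg <- simulation_config(n_founders = 12, horizon = 60, exit_prob = 0.2,
                           recombined_fraction = 0.8, seed = 99)
  t1 <- simulate_lineages(cfg)
  t2 <- simulate_lineages(cfg)
  expect_identical(t1, t2)
  m1 <- apply_measurement_noise(t1, measurement_noise(0.1, 50, 10), seed = 7)
  m2 <- apply_measurement_noise(t2, measurement_noise(0.1, 50, 10), seed = 7)
  expect_identical(m1, m2)
  t3 <- simulate_lineages(cfg, seed = 100)
  expect_false(identical(t1, t3))
})

test_that("config validation rejects degenerate parameter values", {
  expect_error(simulation_config(cycle_time = list(family = "fixed",
                                                   mean = -1, cv = 0)),
               "positive")
  expect_error(simulation_config(cycle_time = list(family = "weibull",
                                                   mean = 16, cv = 0.1)),
               "family")
  expect_error(simulation_config(exit_prob = 1.5), "\\[0, 1\\]")
  expect_error(simulation_config(horizon = -1), "horizon")
  expect_error(simulation_config(partition = "binomial"), "pool_size")
  expect_error(simulate_lineages(simulation_config()), "seed")
})

test_that("measurement noise has the stated structure", {
  tree <- fake_lineage(red = rep(400, 1e4), green = rep(600, 1e4))
  # zero noise: raw = true + background_mean exactly
  m0 <- apply_measurement_noise(tree, measurement_noise(0, 25, 0), seed = 1)
  expect_equal(m0$raw_red, rep(425, 1e4))
  expect_equal(m0$background_green, rep(25, 1e4))
  # multiplicative CV is realised empirically
  m <- apply_measurement_noise(tree, measurement_noise(0.1, 0, 0), seed = 2)
  for (col in c("raw_red", "raw_green")) {
    cv_hat <- sd(m[[col]]) / mean(m[[col]])
    expect_lt(abs(cv_hat - 0.1), 0.01)
    expect_equal(mean(m[[col]]),
                 mean(tree[[sub("raw_", "", col)]]), tolerance = 0.01)
  }
  expect_error(measurement_noise(-0.1), "non-negative")
})

test_that("cortical branching model matches exhaustive enumeration", {
  # stationary differentiation probability 0.5, fixed cycles, 3 generations
  res <- simulate_cortical_population(4000, chase_hours = 48,
                                      cycle_time = fixed_cycles(16),
                                      diff_prob_schedule = 0.5, seed = 8,
                                      keep_tree = TRUE)
  exp_tab <- oracle_cortical_expected(0.5, g_max = 3)
  for (i in seq_len(nrow(exp_tab))) {
    per_f <- per_founder_counts(res$tree, exp_tab$divisions[i],
                                exp_tab$compartment[i])
    exact <- oracle_cortical_dist(0.5, 3, exp_tab$divisions[i],
                                  exp_tab$compartment[i])
    se <- exact$sd / sqrt(length(per_f))
    expect_lt(abs(mean(per_f) - exact$mean), 3 * se + 1e-9)
  }
  # degenerate schedules
  all_prog <- simulate_cortical_population(100, chase_hours = 32,
                                           cycle_time = fixed_cycles(16),
                                           diff_prob_schedule = 0, seed = 9)
  expect_equal(sum(all_prog$counts[, "neuron"]), 0)
  expect_equal(unname(all_prog$counts["2", "progenitor"]),
               all_prog$n_cells)
  all_neuron <- simulate_cortical_population(100, chase_hours = 64,
                                             cycle_time = fixed_cycles(16),
                                             diff_prob_schedule = 1, seed = 10)
  expect_equal(sum(all_neuron$counts) - sum(all_neuron$counts["1", ]), 0)
  expect_equal(unname(all_neuron$counts["1", "neuron"]), 200)
  expect_error(simulate_cortical_population(10, 10,
                                            diff_prob_schedule = numeric(0)),
               "empty")
})

test_that("exported datasets round-trip through their readers", {
  cfg <- simulation_config(n_founders = 5, cycle_time = fixed_cycles(14),
                           horizon = 50, recombined_fraction = 0.8, seed = 21)
  tree <- simulate_lineages(cfg)
  m <- apply_measurement_noise(tree, measurement_noise(0.05, 30, 5), seed = 22)
  dir <- withr::local_tempdir()
  files <- export_dataset(tree, dir, measurements = m)
  expect_true(all(file.exists(files)))
  truth <- read.csv(files[["truth"]])
  expect_equal(nrow(truth), nrow(m))  # one ground-truth row per measured cell
  back <- read_measurement_table(files[["measurements"]])
  expect_equal(back$raw_red, m$raw_red, tolerance = 1e-9)
  expect_equal(back$red_only, m$red_only)
  tree_back <- read_lineage_tree(files[["tree"]])
  expect_equal(tree_back$cell_id, tree$cell_id)
  expect_equal(tree_back$true_divisions, tree$true_divisions)
  expect_equal(tree_back$red, tree$red, tolerance = 1e-12)
})
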