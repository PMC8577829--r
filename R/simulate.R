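# Branching-lineage simulator: ground-truth trees, per-cell label states and
# noisy measurement tables emulating live-imaging / fixed-tissue experiments.

#' Measurement noise model
#'
#' Channel-wise noise applied to true integrated densities: a multiplicative
#' lognormal error with mean 1 and the stated coefficient of variation, plus
#' an additive Gaussian background (clipped at zero).  The drawn background
#' of every cell is recorded in the measurement table so the normalization
#' step can subtract it, mirroring per-cell background subtraction in image
#' analysis.
#'
#' @param multiplicative_cv per-channel coefficient of variation of the
#'   multiplicative error (dimensionless, >= 0).
#' @param background_mean,background_sd mean and standard deviation of the
#'   additive background, in the same arbitrary units as the label states.
#' @return an object of class `icount_noise`.
#' @export
measurement_noise <- function(multiplicative_cv = 0, background_mean = 0,
                              background_sd = 0) {
  vals <- c(multiplicative_cv, background_mean, background_sd)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("noise parameters must be finite and non-negative", call. = FALSE)
  }
  structure(list(multiplicative_cv = multiplicative_cv,
                 background_mean = background_mean,
                 background_sd = background_sd),
            class = "icount_noise")
}

#' Simulation configuration
#'
#' Collects and validates the parameters of the branching-lineage simulator.
#'
#' @param n_founders number of founder cells (all born at time 0).
#' @param cycle_time cell-cycle length specification: a list with `family`
#'   (`"lognormal"`, `"gamma"` or `"fixed"`), `mean` (hours, > 0) and `cv`
#'   (coefficient of variation, ignored for `"fixed"`).  Default lognormal,
#'   mean 16 h, CV 0.15.
#' @param recombination_time hour of the red-to-green switch (instantaneous
#'   and fully penetrant in recombined cells).
#' @param flp_time optional hour of the green-to-blue switch.
#' @param horizon end of the observation window (hours); must exceed
#'   `recombination_time`.
#' @param exit_prob probability that a newborn daughter permanently stops
#'   dividing (quiescence/differentiation).  Either a single value or a
#'   per-generation vector (generation g uses `exit_prob[min(g, length)]`).
#' @param partition `"deterministic"` (each daughter receives exactly half of
#'   each tag pool) or `"binomial"` (each of a finite number of tags segregates
#'   independently; requires `pool_size`).
#' @param pool_size number of tag units in the founder pool when
#'   `partition = "binomial"` (>= 1).
#' @param founder_pool founder pool level in arbitrary fluorescence units for
#'   the deterministic partition (default 100).
#' @param recombined_fraction fraction of founders that carry out the
#'   red-to-green switch; non-recombined founders stay red-only, as used for
#'   the 100% red normalization anchor (default 1).
#' @param noise a [measurement_noise()] object (used by
#'   [apply_measurement_noise()] and [run_pipeline()]).
#' @param seed default random seed for [simulate_lineages()].
#' @return an object of class `icount_sim_config`.
#' @export
simulation_config <- function(n_founders = 4,
                              cycle_time = list(family = "lognormal",
                                                mean = 16, cv = 0.15),
                              recombination_time = 0, flp_time = NULL,
                              horizon = 64, exit_prob = 0,
                              partition = c("deterministic", "binomial"),
                              pool_size = NULL, founder_pool = 100,
                              recombined_fraction = 1,
                              noise = measurement_noise(), seed = NULL) {
  partition <- match.arg(partition)
  if (!is.numeric(n_founders) || n_founders < 1) {
    stop("`n_founders` must be a positive integer", call. = FALSE)
  }
  cycle_time <- .check_cycle_spec(cycle_time)
  if (any(exit_prob < 0) || any(exit_prob > 1) || length(exit_prob) < 1L) {
    stop("`exit_prob` must be one or more probabilities in [0, 1]",
         call. = FALSE)
  }
  if (horizon <= recombination_time) {
    stop("`horizon` must exceed `recombination_time`", call. = FALSE)
  }
  if (!is.null(flp_time) && flp_time <= recombination_time) {
    stop("`flp_time` must be after `recombination_time`", call. = FALSE)
  }
  if (partition == "binomial") {
    if (is.null(pool_size) || pool_size < 1 || pool_size != round(pool_size)) {
      stop("binomial partition requires an integer `pool_size` >= 1",
           call. = FALSE)
    }
  }
  if (recombined_fraction < 0 || recombined_fraction > 1) {
    stop("`recombined_fraction` must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(inherits(noise, "icount_noise"))
  structure(list(n_founders = as.integer(n_founders), cycle_time = cycle_time,
                 recombination_time = recombination_time, flp_time = flp_time,
                 horizon = horizon, exit_prob = exit_prob,
                 partition = partition, pool_size = pool_size,
                 founder_pool = founder_pool,
                 recombined_fraction = recombined_fraction,
                 noise = noise, seed = seed),
            class = "icount_sim_config")
}

.check_cycle_spec <- function(spec) {
  if (!is.list(spec) || is.null(spec$family) || is.null(spec$mean)) {
    stop("`cycle_time` must be list(family =, mean =, cv =)", call. = FALSE)
  }
  if (!spec$family %in% c("lognormal", "gamma", "fixed")) {
    stop("cycle-time family must be lognormal, gamma or fixed", call. = FALSE)
  }
  if (!is.numeric(spec$mean) || spec$mean <= 0) {
    stop("cycle-time mean must be positive", call. = FALSE)
  }
  if (is.null(spec$cv)) spec$cv <- 0
  if (spec$cv < 0) stop("cycle-time cv must be >= 0", call. = FALSE)
  spec
}

.draw_cycles <- function(n, spec) {
  if (n == 0L) return(numeric(0))
  if (spec$family == "fixed" || spec$cv == 0) return(rep(spec$mean, n))
  if (spec$family == "lognormal") {
    sdlog <- sqrt(log(1 + spec$cv^2))
    rlnorm(n, meanlog = log(spec$mean) - sdlog^2 / 2, sdlog = sdlog)
  } else {
    shape <- 1 / spec$cv^2
    stats::rgamma(n, shape = shape, rate = shape / spec$mean)
  }
}

#' Simulate recombined cell lineages with label dilution
#'
#' Grows asynchronous branching lineages from `n_founders` founder cells and
#' tracks the red/green/blue tag content of every cell.  Cells draw a cycle
#' length, divide if the division completes within the horizon, and each
#' newborn daughter may permanently exit the cycle with probability
#' `exit_prob`.  At each division the parent's pool is doubled by
#' replication-coupled synthesis of the current tag (red before
#' recombination, green after, blue after the Flp switch) and partitioned
#' between the daughters either exactly in half (`deterministic`) or tag by
#' tag (`binomial`).  A cell's stored label is therefore its state at birth,
#' with a complete pool; exited and still-cycling cells retain it, reflecting
#' the stability of the tagged protein in non-dividing cells.
#'
#' With the deterministic partition and no noise, a cell with `k` completed
#' post-recombination divisions has exactly `red = P * 2^-k` and green
#' fraction `green_fraction_after_divisions(k, 1)`.
#'
#' @param config an [simulation_config()] object.
#' @param seed integer seed (defaults to `config$seed`); the result is
#'   reproducible from the seed.
#' @return a data frame of class `icount_lineage`, one row per cell, with
#'   columns `cell_id`, `parent_id` (NA for founders), `founder` (id of the
#'   clone's founder), `birth_time`, `division_time` (NA unless the cell
#'   divided), `fate` (`"divided"`, `"exited"` or `"alive_at_horizon"`),
#'   `generation` (divisions since the founder), `true_divisions` (completed
#'   divisions since `recombination_time`), `recombined`, and label columns
#'   `red`, `green`, `blue`.  The configuration is attached as attribute
#'   `config`.
#' @export
simulate_lineages <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "icount_sim_config"))
  if (is.null(seed)) stop("a seed is required for reproducibility",
                          call. = FALSE)
  withr::with_seed(as.integer(seed), .simulate_lineages_impl(config))
}

.simulate_lineages_impl <- function(config) {
  P <- if (config$partition == "binomial") config$pool_size else
    config$founder_pool
  nf <- config$n_founders
  recombined <- runif(nf) < config$recombined_fraction

  cohort <- data.frame(
    cell_id = seq_len(nf), parent_id = NA_integer_, founder = seq_len(nf),
    birth_time = 0, generation = 0L, true_divisions = 0L,
    recombined = recombined, red = P, green = 0, blue = 0, exited = FALSE)
  next_id <- nf + 1L
  done <- list()
  gi <- 0L

  while (nrow(cohort) > 0L) {
    n <- nrow(cohort)
    tau <- .draw_cycles(n, config$cycle_time)
    div_time <- cohort$birth_time + tau
    divides <- !cohort$exited & div_time <= config$horizon

    resolved <- cohort[, c("cell_id", "parent_id", "founder", "birth_time",
                           "generation", "true_divisions", "recombined",
                           "red", "green", "blue")]
    resolved$division_time <- ifelse(divides, div_time, NA_real_)
    resolved$fate <- ifelse(cohort$exited, "exited",
                            ifelse(divides, "divided", "alive_at_horizon"))
    gi <- gi + 1L
    done[[gi]] <- resolved

    if (!any(divides)) break
    par <- cohort[divides, , drop = FALSE]
    pt <- div_time[divides]
    np <- nrow(par)

    # replication-coupled synthesis of the current tag doubles the pool
    post_recomb <- par$recombined & pt > config$recombination_time
    flp <- if (is.null(config$flp_time)) Inf else config$flp_time
    synth <- ifelse(!post_recomb, "red", ifelse(pt > flp, "blue", "green"))
    pool_add <- par$red + par$green + par$blue  # one full pool's worth
    post <- cbind(red = par$red, green = par$green, blue = par$blue)
    for (ch in c("red", "green", "blue")) {
      post[synth == ch, ch] <- post[synth == ch, ch] + pool_add[synth == ch]
    }

    if (config$partition == "deterministic") {
      d1 <- post / 2
      d2 <- post / 2
    } else {
      d1 <- post
      for (j in seq_len(ncol(post))) {
        d1[, j] <- rbinom(np, size = post[, j], prob = 0.5)
      }
      d2 <- post - d1
    }

    kid_true <- par$true_divisions + as.integer(post_recomb)
    kid_gen <- par$generation + 1L
    p_exit <- config$exit_prob[pmin(kid_gen, length(config$exit_prob))]
    kids <- data.frame(
      cell_id = next_id + seq_len(2L * np) - 1L,
      parent_id = rep(par$cell_id, each = 2L),
      founder = rep(par$founder, each = 2L),
      birth_time = rep(pt, each = 2L),
      generation = rep(kid_gen, each = 2L),
      true_divisions = rep(kid_true, each = 2L),
      recombined = rep(par$recombined, each = 2L),
      red = as.vector(rbind(d1[, "red"], d2[, "red"])),
      green = as.vector(rbind(d1[, "green"], d2[, "green"])),
      blue = as.vector(rbind(d1[, "blue"], d2[, "blue"])),
      exited = runif(2L * np) < rep(p_exit, each = 2L))
    next_id <- next_id + 2L * np
    cohort <- kids
  }

  tree <- do.call(rbind, done)
  tree$exited <- NULL
  tree <- tree[order(tree$cell_id),
               c("cell_id", "parent_id", "founder", "birth_time",
                 "division_time", "fate", "generation", "true_divisions",
                 "recombined", "red", "green", "blue")]
  rownames(tree) <- NULL
  class(tree) <- c("icount_lineage", "data.frame")
  attr(tree, "config") <- config
  tree
}

#' Apply measurement noise to a simulated lineage
#'
#' Converts true per-cell label states into a raw measurement table:
#' `raw = true * f + b` per channel, where `f` is a lognormal factor with
#' mean 1 and CV `multiplicative_cv` and `b` a Gaussian background (clipped
#' at 0) whose drawn value is recorded in the `background_*` columns.
#'
#' @param tree an `icount_lineage` from [simulate_lineages()].
#' @param noise a [measurement_noise()] object.
#' @param seed integer seed; identical seeds give identical tables.
#' @param region region label attached to every cell (default `"sim"`).
#' @return a raw measurement data frame with columns `cell_id`, `region`,
#'   `raw_red`, `raw_green`, `raw_blue`, `background_red`, `background_green`,
#'   `background_blue`, and the marker flag `red_only` (TRUE for
#'   non-recombined cells).
#' @export
apply_measurement_noise <- function(tree, noise = measurement_noise(),
                                    seed = 1, region = "sim") {
  stopifnot(inherits(tree, "icount_lineage"), inherits(noise, "icount_noise"))
  withr::with_seed(as.integer(seed), {
    n <- nrow(tree)
    cv <- noise$multiplicative_cv
    sdlog <- sqrt(log(1 + cv^2))
    draw_channel <- function(true) {
      f <- if (cv > 0) rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog) else 1
      b <- pmax(rnorm(n, noise$background_mean, noise$background_sd), 0)
      list(raw = true * f + b, bg = b)
    }
    r <- draw_channel(tree$red)
    g <- draw_channel(tree$green)
    b <- draw_channel(tree$blue)
    data.frame(cell_id = tree$cell_id, region = region,
               raw_red = r$raw, raw_green = g$raw, raw_blue = b$raw,
               background_red = r$bg, background_green = g$bg,
               background_blue = b$bg,
               red_only = !tree$recombined)
  })
}

#' Ground-truth table of a simulated lineage
#'
#' @param tree an `icount_lineage`.
#' @return data frame with `cell_id`, `true_divisions`, `fate`, `recombined`.
#' @export
ground_truth <- function(tree) {
  stopifnot(inherits(tree, "icount_lineage"))
  tree[, c("cell_id", "true_divisions", "fate", "recombined")]
}

#' Simulate a cortical-development branching model
#'
#' Discrete-generation branching process standing in for models of cortical
#' neurogenesis: progenitors divide with the given cycle-time distribution
#' and every newborn daughter differentiates into a neuron (permanently
#' exiting the cycle) with a per-generation probability.  Returns the
#' distribution of completed divisions per surviving cell at the end of the
#' chase, split by compartment.
#'
#' @param progenitor_count number of starting progenitors.
#' @param chase_hours length of the chase (hours, > 0).
#' @param cycle_time cycle-length spec as in [simulation_config()].
#' @param diff_prob_schedule vector of per-generation differentiation
#'   probabilities in `[0, 1]`; generation g uses entry `min(g, length)`.
#' @param seed integer seed.
#' @param keep_tree also return the underlying lineage tree (for per-founder
#'   replicate statistics).
#' @return a list of class `icount_cortical` with `counts` (matrix: rows =
#'   divisions 0, 1, 2, ..., columns `progenitor` and `neuron`),
#'   `proportions`, `n_cells`, and the `tree` when `keep_tree = TRUE`.
#' @export
simulate_cortical_population <- function(progenitor_count, chase_hours,
                                         cycle_time = list(family = "fixed",
                                                           mean = 16, cv = 0),
                                         diff_prob_schedule, seed = 1,
                                         keep_tree = FALSE) {
  if (length(diff_prob_schedule) == 0L) {
    stop("`diff_prob_schedule` must not be empty", call. = FALSE)
  }
  if (any(diff_prob_schedule < 0) || any(diff_prob_schedule > 1)) {
    stop("differentiation probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (chase_hours <= 0) stop("`chase_hours` must be positive", call. = FALSE)
  cfg <- simulation_config(n_founders = progenitor_count,
                           cycle_time = cycle_time, recombination_time = 0,
                           horizon = chase_hours,
                           exit_prob = diff_prob_schedule, seed = seed)
  tree <- simulate_lineages(cfg)
  leaves <- tree[tree$fate != "divided", , drop = FALSE]
  compartment <- ifelse(leaves$fate == "exited", "neuron", "progenitor")
  kmax <- max(leaves$true_divisions)
  counts <- table(factor(leaves$true_divisions, levels = 0:kmax),
                  factor(compartment, levels = c("progenitor", "neuron")))
  counts <- unclass(counts)
  structure(list(counts = counts,
                 proportions = counts / sum(counts),
                 n_cells = sum(counts),
                 n_founders = progenitor_count,
                 tree = if (keep_tree) tree else NULL),
            class = "icount_cortical")
}

#' @export
print.icount_cortical <- function(x, ...) {
  cat(sprintf("Cortical branching model: %d cells from %d founders\n",
              x$n_cells, x$n_founders))
  print(x$counts)
  invisible(x)
}

#' Export a simulated dataset as plain-text files
#'
#' Writes the pieces of a simulated experiment in the formats the analysis
#' modules read back: the raw measurement table (`measurements.csv`), the
#' ground-truth table (`truth.csv`) and the lineage tree (`tree.json`, plus
#' `tree.nwk` when every founder divided at least once).
#'
#' @param tree an `icount_lineage`.
#' @param dir output directory (created if missing).
#' @param measurements optional raw measurement table from
#'   [apply_measurement_noise()]; omitted from disk when `NULL`.
#' @return named character vector of the files written, invisibly.
#' @export
export_dataset <- function(tree, dir, measurements = NULL) {
  stopifnot(inherits(tree, "icount_lineage"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- c(truth = file.path(dir, "truth.csv"),
             tree = file.path(dir, "tree.json"))
  write.csv(ground_truth(tree), files[["truth"]],
            row.names = FALSE, quote = FALSE)
  write_lineage_tree(tree, files[["tree"]], format = "json")
  founders <- tree$cell_id[is.na(tree$parent_id)]
  if (all(tree$fate[match(founders, tree$cell_id)] == "divided")) {
    files[["newick"]] <- file.path(dir, "tree.nwk")
    write_lineage_tree(tree, files[["newick"]], format = "newick")
  }
  if (!is.null(measurements)) {
    files[["measurements"]] <- file.path(dir, "measurements.csv")
    write_measurement_table(measurements, files[["measurements"]])
  }
  invisible(files)
}
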