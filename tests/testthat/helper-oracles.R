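# Independent oracles used to freeze expected values.  These deliberately
# avoid the closed forms implemented in R/: they do direct pool bookkeeping
# or exhaustive enumeration.

# Two-colour dilution by direct bookkeeping: the old-tag *fraction* of the
# pool halves at each division; intensities weight old tag by C, new by 1.
oracle_green_fraction <- function(n, C) {
  old_frac <- 1
  for (i in seq_len(n)) old_frac <- old_frac / 2
  red <- C * old_frac
  green <- 1 * (1 - old_frac)
  if (n == 0) 0 else green / (green + red)
}

# Three-colour bookkeeping on pool fractions (r, g, b), pool normalized to 1
# at cycle completion.  A division doubles the pool with the current tag and
# splits it in half: the synthesised channel gains 1/2, the others halve.
oracle_micount <- function(n_pre, n_post) {
  s <- c(1, 0, 0)  # (red, green, blue)
  for (i in seq_len(n_pre)) s <- c(s[1] / 2, s[2] / 2 + 0.5, s[3] / 2)
  for (i in seq_len(n_post)) s <- c(s[1] / 2, s[2] / 2, s[3] / 2 + 0.5)
  s
}

# Exhaustive enumeration of the discrete-generation cortical branching
# process: expected number of end-of-chase cells per founder, by completed
# divisions and compartment, enumerating every per-daughter fate path with
# its probability.  `g_max` is the number of whole generations in the chase.
oracle_cortical_expected <- function(diff_prob, g_max) {
  counts <- list()
  add <- function(k, type, w) {
    key <- paste(k, type)
    counts[[key]] <<- (if (is.null(counts[[key]])) 0 else counts[[key]]) + w
  }
  walk <- function(gen, weight) {
    # a cycling progenitor that has completed `gen` divisions
    if (gen == g_max) {
      add(gen, "progenitor", weight)
      return(invisible())
    }
    p <- diff_prob[min(gen + 1L, length(diff_prob))]
    for (daughter in 1:2) {
      if (p > 0) add(gen + 1L, "neuron", weight * p)
      if (p < 1) walk(gen + 1L, weight * (1 - p))
    }
  }
  walk(0L, 1)
  out <- do.call(rbind, lapply(names(counts), function(key) {
    parts <- strsplit(key, " ")[[1L]]
    data.frame(divisions = as.integer(parts[1L]), compartment = parts[2L],
               expected = counts[[key]])
  }))
  out[order(out$divisions, out$compartment), ]
}

# Exact per-founder distribution of the number of end-of-chase cells with a
# given division count and compartment, by recursive enumeration of every
# branch outcome (daughter distributions combined by convolution).  Returns
# the exact mean and standard deviation of the per-founder count.
oracle_cortical_dist <- function(diff_prob, g_max, divisions, compartment) {
  convolve_pmf <- function(a, b) {
    out <- numeric(length(a) + length(b) - 1L)
    for (i in seq_along(a)) {
      out[i + seq_along(b) - 1L] <- out[i + seq_along(b) - 1L] + a[i] * b
    }
    out
  }
  subtree_pmf <- function(gen) {
    # pmf (index = count + 1) of target cells below one cycling progenitor
    # that has completed `gen` divisions
    if (gen == g_max) {
      hit <- divisions == gen && compartment == "progenitor"
      return(if (hit) c(0, 1) else 1)
    }
    p <- diff_prob[min(gen + 1L, length(diff_prob))]
    neuron_hit <- divisions == gen + 1L && compartment == "neuron"
    neuron_pmf <- if (neuron_hit) c(0, 1) else 1
    prog_pmf <- subtree_pmf(gen + 1L)
    n_len <- max(length(neuron_pmf), length(prog_pmf))
    daughter <- numeric(n_len)
    daughter[seq_along(neuron_pmf)] <- p * neuron_pmf
    daughter[seq_along(prog_pmf)] <- daughter[seq_along(prog_pmf)] +
      (1 - p) * prog_pmf
    convolve_pmf(daughter, daughter)
  }
  pmf <- subtree_pmf(0L)
  counts <- seq_along(pmf) - 1
  m <- sum(counts * pmf)
  v <- sum((counts - m)^2 * pmf)
  list(mean = m, sd = sqrt(v))
}

# Small hand-built lineage with the icount_lineage class, for unit tests
# that need label states without running the simulator.
fake_lineage <- function(red, green, blue = 0, recombined = TRUE) {
  n <- length(red)
  tree <- data.frame(
    cell_id = seq_len(n), parent_id = NA_integer_, founder = seq_len(n),
    birth_time = 0, division_time = NA_real_, fate = "alive_at_horizon",
    generation = 0L, true_divisions = 0L,
    recombined = rep_len(recombined, n),
    red = red, green = green, blue = rep_len(blue, n))
  class(tree) <- c("icount_lineage", "data.frame")
  tree
}

# Per-founder counts of end-of-chase cells with a given division number and
# compartment, from a simulated lineage tree (for replicate-based SEs).
per_founder_counts <- function(tree, divisions, compartment) {
  leaves <- tree[tree$fate != "divided", , drop = FALSE]
  comp <- ifelse(leaves$fate == "exited", "neuron", "progenitor")
  hit <- leaves$true_divisions == divisions & comp == compartment
  tapply(hit, factor(leaves$founder, levels = sort(unique(tree$founder))),
         sum)
}
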