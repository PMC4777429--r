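# Independent oracles and fixture builders shared across the test files.

# Exhaustive-enumeration oracle for the minimum-divergence integer
# allocation: tries every composition of A units over length(q) partners.
# Exponential; only usable at toy sizes.
exhaustive_dmin <- function(A, q) {
  q <- q / sum(q)
  J <- length(q)
  best <- Inf
  recurse <- function(j, left, alloc) {
    if (j == J) {
      alloc[J] <- left
      p <- alloc / A
      use <- p > 0
      d <- sum(p[use] * log(p[use] / q[use]))
      if (d < best) best <<- d
      return(invisible(NULL))
    }
    for (n in 0:left) recurse(j + 1, left - n, { alloc[j] <- n; alloc })
  }
  recurse(1, A, numeric(J))
  best
}

# Random small integer count matrix with no all-zero rows or columns.
rand_count_matrix <- function(nr, nc, max_count = 6) {
  repeat {
    m <- matrix(rpois(nr * nc, 1.2), nr, nc)
    m[m > max_count] <- max_count
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) break
  }
  dimnames(m) <- list(paste0("p", seq_len(nr)), paste0("v", seq_len(nc)))
  m
}

# Minimal single-community census/survey pair: one plant, one visitor,
# one census; density 2 flowers/m2.
toy_tables <- function() {
  census <- data.frame(
    community = "X", date = as.Date("2020-05-03"), month_index = 1L,
    plant = "pA", duration_min = 3, flowers_observed = 20L,
    visitor = "vA", individuals = 2L, flowers_contacted = 6L,
    stringsAsFactors = FALSE)
  surveys <- data.frame(
    community = "X", date = as.Date("2020-05-07"), month_index = 1L,
    plant = "pA", open_flowers = 1L, area_m2 = 0.5,
    stringsAsFactors = FALSE)
  surveys$density <- surveys$open_flowers / surveys$area_m2
  list(census = census, surveys = surveys)
}

# Small simulation for tests that need full pipeline inputs quickly.
small_sim <- function(seed = 7) {
  simulate_community(sim_config(
    n_plants = 8, n_visitors = 10,
    archetype_mix = c(generalized = 2, specialized = 2, opportunistic = 2,
                      selective = 2, background = 2),
    seed = seed))
}
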