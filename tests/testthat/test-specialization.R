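# Linkage level, d', the d_min allocation, reliability filters and
# extreme-species selection.

test_that("linkage level counts positive-weight partners and is scale invariant", {
  w <- matrix(c(0.2, 0.4, 0, 0, 0.1, 0.3), 2, 3,
              dimnames = list(c("pA", "pB"), c("vA", "vB", "vC")))
  net <- interaction_network(w, community = "X")
  expect_equal(linkage_level(net, "pA"), 2)
  net10 <- interaction_network(w * 10, community = "X")
  expect_equal(linkage_level(net10, "pA"), linkage_level(net, "pA"))
  expect_error(linkage_level(net, "nope"), "not in network")
})

test_that("the worked 2x2 example matches the hand-derived d'", {
  m <- matrix(c(9, 1, 1, 9), 2, 2, byrow = TRUE,
              dimnames = list(c("p1", "p2"), c("v1", "v2")))
  net <- interaction_network(m, m, community = "X")
  res <- dprime(net, "p1", availability = "marginal")
  d_hand <- 0.9 * log(1.8) + 0.1 * log(0.2)
  expect_equal(res$d, d_hand, tolerance = 1e-12)
  # allocation (5,5) matches q = (0.5, 0.5) exactly
  expect_equal(res$d_min, 0, tolerance = 1e-12)
  expect_equal(res$d_max, log(2), tolerance = 1e-12)
  expect_equal(res$d_prime, d_hand / log(2), tolerance = 1e-12)
  # confirmed against brute force over all 11 allocations of 10 units
  expect_equal(res$d_min, exhaustive_dmin(10, c(0.5, 0.5)),
               tolerance = 1e-12)
})

test_that("apportionment plus local search reproduces the exhaustive d_min", {
  set.seed(101)
  for (i in 1:60) {
    nr <- sample(2:5, 1); nc <- sample(2:5, 1)
    m <- rand_count_matrix(nr, nc)
    i_row <- sample(nr, 1)
    A <- sum(m[i_row, ])
    if (A > 12) next
    q <- colSums(m) / sum(m)
    got <- dmin_allocation(A, q)$d
    want <- exhaustive_dmin(A, q)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("d' stays in [0,1] and is zero when use can match availability", {
  set.seed(202)
  for (i in 1:100) {
    m <- rand_count_matrix(sample(2:5, 1), sample(2:5, 1))
    net <- interaction_network(m, m, community = "X")
    for (sp in c(net$plants, net$visitors)) {
      dp <- dprime(net, sp)$d_prime
      expect_gte(dp, 0); expect_lte(dp, 1)
    }
  }
  # a row that is an exact integer multiple of q attains d = d_min
  m <- matrix(c(2, 4, 6, 1, 2, 3), 2, 3, byrow = TRUE,
              dimnames = list(c("pA", "pB"), c("vA", "vB", "vC")))
  res <- dprime(interaction_network(m, m, community = "X"), "pA")
  expect_equal(res$d_prime, 0, tolerance = 1e-12)
})

test_that("sole users of an exclusive partner attain maximal selectiveness", {
  for (AB in list(c(3, 5), c(1, 1), c(7, 2))) {
    m <- matrix(c(AB[1], 0, 0, AB[2]), 2, 2, byrow = TRUE,
                dimnames = list(c("p1", "p2"), c("v1", "v2")))
    res <- dprime(interaction_network(m, m, community = "X"), "p1")
    expect_equal(res$d, res$d_max, tolerance = 1e-12)
    if (res$d_min < res$d_max) expect_equal(res$d_prime, 1)
  }
})

test_that("d' is invariant to permuting partner order", {
  set.seed(303)
  m <- rand_count_matrix(4, 5)
  net <- interaction_network(m, m, community = "X")
  perm <- sample(ncol(m))
  net_p <- interaction_network(m[, perm], m[, perm], community = "X")
  for (sp in net$plants) {
    expect_equal(dprime(net_p, sp)$d_prime, dprime(net, sp)$d_prime,
                 tolerance = 1e-12)
  }
})

test_that("moving interaction mass toward availability never increases d", {
  set.seed(404)
  for (i in 1:50) {
    q <- as.numeric(rmultinom(1, 40, runif(4) + 0.1)) / 40
    if (any(q == 0)) next
    p <- as.numeric(rmultinom(1, 30, runif(4) + 0.1)) / 30
    kl <- function(p) sum(p[p > 0] * log(p[p > 0] / q[p > 0]))
    w <- runif(1)
    expect_lte(kl((1 - w) * p + w * q), kl(p) + 1e-12)
  }
})

test_that("a 1x1 network has d' = 0 by the degenerate-case rule", {
  m <- matrix(5, 1, 1, dimnames = list("pA", "vA"))
  res <- dprime(interaction_network(m, m, community = "X"), "pA")
  expect_equal(res$d, 0)
  expect_equal(res$d_max, 0)
  expect_equal(res$d_prime, 0)
})

test_that("external availability rejects zero-abundance used partners", {
  m <- matrix(c(3, 2, 1, 4), 2, 2,
              dimnames = list(c("pA", "pB"), c("vA", "vB")))
  net <- interaction_network(m, m, community = "X")
  expect_error(dprime(net, "vA", "external"), "needs partner abundances")
  expect_error(
    dprime(net, "vA", "external", abundances = c(pA = 0, pB = 2)),
    "zero abundance.*pA")
  ok <- dprime(net, "vA", "external", abundances = c(pA = 8, pB = 2))
  expect_equal(ok$d_max, -log(0.2), tolerance = 1e-12)
})

test_that("reliability filters use the stated strict boundaries", {
  records <- data.frame(
    community = "X",
    species = c("pShort", "pLong", "vFew", "vFive"),
    guild = c("plant", "plant", "visitor", "visitor"),
    L = 2L, A = c(10, 10, 4, 5), d = 0, d_min = 0, d_max = 1,
    d_prime = 0.5)
  census <- rbind(
    data.frame(community = "X", date = as.Date("2020-05-01"),
               month_index = 1L, plant = "pShort", duration_min = 25,
               flowers_observed = 5L, visitor = "vFew",
               individuals = 4L, flowers_contacted = 4L),
    data.frame(community = "X", date = as.Date("2020-05-02"),
               month_index = 1L, plant = "pLong", duration_min = 30,
               flowers_observed = 5L, visitor = "vFive",
               individuals = 5L, flowers_contacted = 5L),
    data.frame(community = "X", date = as.Date("2020-06-02"),
               month_index = 2L, plant = "pLong", duration_min = 30,
               flowers_observed = 5L, visitor = "vFive",
               individuals = 0L, flowers_contacted = 0L))
  census$visitor[3] <- "NONE"
  w1 <- matrix(c(4, 5), 1, 2,
               dimnames = list("pShort", c("vFew", "vFive")))
  w2 <- matrix(5, 1, 1, dimnames = list("pLong", "vFive"))
  monthly <- list(
    X.1 = interaction_network(w1, w1, community = "X", period = "month:1"),
    X.2 = interaction_network(w2, w2, community = "X", period = "month:2"),
    X.3 = interaction_network(w2, w2, community = "X", period = "month:3"))
  out <- apply_filters(records, census, monthly)
  # pShort: 25 min < 30 excluded; vFew: 4 individuals < 5 excluded;
  # pShort also in one network only; pLong 60 min, 2 networks retained;
  # vFive: 5 individuals (boundary inclusive), 3 networks retained
  expect_setequal(out$species, c("pLong", "vFive"))
  expect_equal(out$months_present[out$species == "vFive"], 3L)
})

test_that("extreme selection is an order statistic with deterministic ties", {
  records <- data.frame(
    community = "X", species = paste0("p", 1:8), guild = "plant",
    L = c(9, 8, 7, 6, 5, 5, 2, 1),
    A = c(50, 40, 30, 20, 10, 15, 5, 2),
    d = 0, d_min = 0, d_max = 1,
    d_prime = c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8))
  sel <- select_extremes(records, n = 5)
  gen <- sel$species[sel$category == "generalized"]
  # tie at L = 5 between p5 (A=10) and p6 (A=15): larger total wins
  expect_setequal(gen, c("p1", "p2", "p3", "p4", "p6"))
  spec <- sel$species[sel$category == "specialized"]
  expect_setequal(spec, c("p8", "p7", "p6", "p5", "p4"))
  opp <- sel$species[sel$category == "opportunistic"]
  expect_setequal(opp, paste0("p", 1:5))
  expect_true(all(table(sel$category) <= 5))
  # fewer eligible than n: take all with a warning
  expect_warning(sel2 <- select_extremes(records[1:3, ], n = 5),
                 "only 3")
  expect_equal(sum(sel2$category == "generalized"), 3)
  expect_error(select_extremes(records[0, ]), "no eligible")
})

test_that("specialization tables agree between matrix orientations", {
  set.seed(77)
  m <- rand_count_matrix(3, 4)
  net <- interaction_network(m, m, community = "X")
  tab <- specialization_table(net)
  expect_equal(nrow(tab), length(net$plants) + length(net$visitors))
  expect_true(all(tab$d_min <= tab$d + 1e-12))
  expect_true(all(tab$d <= tab$d_max + 1e-12))
  # L from the table matches direct counting
  for (i in seq_len(nrow(tab))) {
    expect_equal(tab$L[i], linkage_level(net, tab$species[i]))
  }
})
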