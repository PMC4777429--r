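# Synthetic census-data generator with planted interaction archetypes.
#
# Emulates the field design behind the analysis: four coastal communities
# sampled over a four-month flowering season, with fixed per-site census
# durations, equal observation time for every plant in bloom on a census
# day, and biweekly flower-density surveys. Visitor species are planted as
# archetypes controlling partner breadth (link_breadth) and abundance
# preference (gamma): opportunistic visitors use plants in proportion to
# flower density (gamma = +1), selective visitors favour rare plants
# (gamma = -1), generalized visitors spread over all plants and specialized
# visitors over one or two. Planted labels are returned as ground truth.

#' Default simulation configuration
#'
#' Returns the configuration of the synthetic census design. The four
#' communities mirror a two-island spring season: two sites starting in
#' April with 3- and 6-minute censuses, two starting in January with
#' 7.5-minute censuses. Defaults are chosen once to emulate a realistic
#' Mediterranean coastal community; see the methods vignette.
#'
#' @param n_plants plants per community.
#' @param n_visitors flower-visitor species per community.
#' @param n_months months in the season.
#' @param archetype_mix named integer vector over
#'   generalized/specialized/opportunistic/selective/background; must sum
#'   to \code{n_visitors}.
#' @param seed integer; fully determines the simulated data.
#' @param ... overrides for any other configuration entry.
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(n_plants = 16, n_visitors = 24, n_months = 4,
                       archetype_mix = c(generalized = 5, specialized = 5,
                                         opportunistic = 5, selective = 5,
                                         background = 4),
                       seed = 20160303, ...) {
  cfg <- list(
    communities = c("SB", "CM", "CB", "LC"),
    census_duration = c(SB = 3, CM = 6, CB = 7.5, LC = 7.5),  # minutes
    season_start = c(SB = "2010-04-01", CM = "2010-04-01",
                     CB = "2011-01-01", LC = "2011-01-01"),
    n_months = n_months,
    n_plants = n_plants,
    n_visitors = n_visitors,
    n_families = 8,
    functional_groups = visitor_functional_groups,
    density_meanlog = log(60),   # flowers per m2, species-level median
    density_sdlog = 1.2,         # between-species spread
    density_month_sdlog = 0.3,   # within-species month-to-month noise
    flowers_per_census = 12,     # mean open flowers on a focal patch
    census_days = c(3, 10, 17, 24),   # days of month, ~weekly censuses
    survey_days = c(7, 21),           # biweekly density surveys
    # total area surveyed per census date: ten 50 x 2 m belt transects at
    # SB, thirty 0.5 x 0.5 m random plots elsewhere
    survey_area_m2 = c(SB = 1000, CM = 7.5, CB = 7.5, LC = 7.5),
    contact_cap = 4,             # max flower contacts per individual
    archetype_mix = archetype_mix,
    # per-flower per-minute contact rates by archetype
    base_rate = c(generalized = 0.04, specialized = 0.05,
                  opportunistic = 0.06, selective = 0.06,
                  background = 0.04),
    # plant partner breadth by archetype; NA = all plants
    link_breadth = c(generalized = NA, specialized = 2,
                     opportunistic = 8, selective = 11, background = 5),
    # abundance-preference exponent gamma (weights ~ density^gamma)
    preference_exponent = c(generalized = 0, specialized = 0,
                            opportunistic = 1, selective = -1,
                            background = 0),
    seed = seed
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown sim_config entries: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(dots)] <- dots
  if (sum(cfg$archetype_mix) != cfg$n_visitors) {
    stop("archetype_mix must sum to n_visitors", call. = FALSE)
  }
  if (cfg$n_plants < 3 || cfg$n_months < 2) {
    stop("need at least 3 plants and 2 months", call. = FALSE)
  }
  class(cfg) <- c("sim_config", "list")
  cfg
}

#' Abundance-preference weights over a permitted plant set
#'
#' \code{w_i = density_i^gamma / sum(density^gamma)}: the share of a
#' visitor's expected contacts falling on each permitted in-bloom plant.
#' \code{gamma = +1} tracks abundance (opportunistic), \code{gamma = -1}
#' favours rare plants (selective), \code{gamma = 0} is indifferent.
#'
#' @param density positive flower densities of the permitted plants.
#' @param gamma preference exponent.
#' @return weights summing to 1.
#' @export
preference_weights <- function(density, gamma) {
  stopifnot(all(density > 0), is.finite(gamma))
  w <- density^gamma
  w / sum(w)
}

#' Simulate census, survey and taxonomy tables with planted archetypes
#'
#' For every community and census day, each plant in bloom receives one
#' focal census of the community's fixed duration (equal observation time
#' per plant). For each active visitor, expected flower contacts in a
#' census of plant i are \code{base_rate * duration * flowers_observed *
#' w_i} with \code{w_i} proportional to \code{density_i^gamma} over the
#' visitor's permitted plants in bloom, realized as Poisson counts;
#' individuals are \code{ceiling(contacts / contact_cap)}. Flower densities
#' are lognormal per species-month within each species' phenology window.
#' Censuses with no visits are kept as \code{"NONE"} rows so effort is
#' never lost.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with \code{census}, \code{surveys}, \code{taxonomy}
#'   data.frames, \code{truth} (visitor species -> planted archetype), and
#'   the \code{config}.
#' @export
simulate_community <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cen_l <- list(); sur_l <- list(); tax_l <- list(); tru_l <- list()
  for (comm in config$communities) {
    out <- simulate_one_community(comm, config)
    cen_l[[comm]] <- out$census
    sur_l[[comm]] <- out$surveys
    tax_l[[comm]] <- out$taxonomy
    tru_l[[comm]] <- out$truth
  }
  list(census = do.call(rbind, c(cen_l, make.row.names = FALSE)),
       surveys = do.call(rbind, c(sur_l, make.row.names = FALSE)),
       taxonomy = do.call(rbind, c(tax_l, make.row.names = FALSE)),
       truth = do.call(rbind, c(tru_l, make.row.names = FALSE)),
       config = config)
}

#' @noRd
simulate_one_community <- function(comm, cfg) {
  n_p <- cfg$n_plants; n_v <- cfg$n_visitors; n_m <- cfg$n_months
  plants <- sprintf("%s.P%02d", comm, seq_len(n_p))
  visitors <- sprintf("%s.V%02d", comm, seq_len(n_v))
  families <- sprintf("fam%02d", sample.int(cfg$n_families, n_p,
                                            replace = TRUE))
  vgroups <- sample(cfg$functional_groups, n_v, replace = TRUE)

  # phenology: first three plants bloom all season so no month is empty
  # and specialized visitors can pass the two-network presence filter
  ph_first <- c(rep(1L, 3), sample.int(n_m - 1, n_p - 3, replace = TRUE))
  ph_len <- c(rep(n_m, 3), sample(2:n_m, n_p - 3, replace = TRUE))
  ph_last <- pmin(ph_first + ph_len - 1L, n_m)
  in_bloom <- function(p_idx, m) ph_first[p_idx] <= m & ph_last[p_idx] >= m
  for (m in seq_len(n_m)) {
    if (!any(in_bloom(seq_len(n_p), m))) {
      stop("degenerate phenology: no plant in bloom in month ", m,
           call. = FALSE)
    }
  }

  # species-level log-density plus month-to-month noise, zero out of bloom;
  # the three guaranteed full-season bloomers are also the community
  # dominants (dominant shrubs flower longest); remaining densities are
  # assigned at random so rare species can flower long or short
  mu_draw <- sort(stats::rnorm(n_p, cfg$density_meanlog, cfg$density_sdlog),
                  decreasing = TRUE)
  mu <- numeric(n_p)
  mu[1:3] <- mu_draw[1:3]
  mu[4:n_p] <- sample(mu_draw[-(1:3)])
  dens <- matrix(0, n_p, n_m)
  for (m in seq_len(n_m)) {
    on <- in_bloom(seq_len(n_p), m)
    dens[on, m] <- exp(mu[on] + stats::rnorm(sum(on), 0,
                                             cfg$density_month_sdlog))
  }

  # visitor archetypes, link sets and activity windows
  mix <- cfg$archetype_mix
  arch <- rep(names(mix), times = mix)
  full_bloomers <- which(ph_first == 1 & ph_last == n_m)
  link_sets <- vector("list", n_v)
  active_first <- integer(n_v); active_last <- integer(n_v)
  by_abund <- order(-mu)
  for (v in seq_len(n_v)) {
    a <- arch[v]
    lb <- cfg$link_breadth[[a]]
    if (!is.na(lb)) lb <- min(lb, n_p)
    if (is.na(lb) || lb >= n_p) {
      link_sets[[v]] <- seq_len(n_p)
    } else if (a == "specialized") {
      # specialized species keep to one or two of the most abundant
      # full-season bloomers: few but common partners, recurring in
      # every monthly snapshot
      common <- full_bloomers[order(-mu[full_bloomers])]
      common <- common[seq_len(min(3, length(common)))]
      n_links <- sample.int(min(lb, length(common)), 1)
      link_sets[[v]] <- common[sample.int(length(common), n_links)]
    } else if (a == "opportunistic") {
      # abundance trackers forage where flowers are massed
      link_sets[[v]] <- by_abund[seq_len(lb)]
    } else if (a == "selective") {
      # rare-flower foragers work the scarce end of the community
      link_sets[[v]] <- rev(by_abund)[seq_len(lb)]
    } else {
      link_sets[[v]] <- sample.int(n_p, lb)
    }
    if (a == "background") {
      active_first[v] <- sample.int(n_m - 1, 1)
      active_last[v] <- min(active_first[v] + sample(1:(n_m - 1), 1), n_m)
    } else {
      active_first[v] <- 1L; active_last[v] <- n_m
    }
  }

  start <- as.Date(cfg$season_start[[comm]])
  month_date <- function(m, day) seq(start, by = "month",
                                     length.out = m)[m] + (day - 1)
  dur <- cfg$census_duration[[comm]]

  cen <- list(); k <- 0
  for (m in seq_len(n_m)) {
    bloom <- which(in_bloom(seq_len(n_p), m))
    act <- which(active_first <= m & active_last >= m)
    # preference weights per visitor over its permitted in-bloom plants
    wmat <- matrix(0, n_v, n_p)
    for (v in act) {
      perm <- intersect(link_sets[[v]], bloom)
      if (length(perm) == 0) next
      g <- cfg$preference_exponent[[arch[v]]]
      wmat[v, perm] <- preference_weights(dens[perm, m], g)
    }
    for (day in cfg$census_days) {
      date <- month_date(m, day)
      for (p in bloom) {
        flowers <- 1L + stats::rpois(1, cfg$flowers_per_census - 1)
        any_visit <- FALSE
        for (v in act) {
          if (wmat[v, p] <= 0) next
          lambda <- cfg$base_rate[[arch[v]]] * dur * flowers * wmat[v, p]
          contacts <- stats::rpois(1, lambda)
          if (contacts > 0) {
            any_visit <- TRUE
            k <- k + 1
            cen[[k]] <- data.frame(
              community = comm, date = date, month_index = m,
              plant = plants[p], duration_min = dur,
              flowers_observed = flowers, visitor = visitors[v],
              individuals = as.integer(ceiling(contacts / cfg$contact_cap)),
              flowers_contacted = contacts, stringsAsFactors = FALSE)
          }
        }
        if (!any_visit) {
          k <- k + 1
          cen[[k]] <- data.frame(
            community = comm, date = date, month_index = m,
            plant = plants[p], duration_min = dur,
            flowers_observed = flowers, visitor = NONE_LABEL,
            individuals = 0L, flowers_contacted = 0L,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  census <- do.call(rbind, cen)

  sur <- list(); k <- 0
  for (m in seq_len(n_m)) {
    for (day in cfg$survey_days) {
      date <- month_date(m, day)
      area <- cfg$survey_area_m2[[comm]]
      for (p in which(in_bloom(seq_len(n_p), m))) {
        k <- k + 1
        sur[[k]] <- data.frame(
          community = comm, date = date, month_index = m,
          plant = plants[p],
          open_flowers = stats::rpois(1, dens[p, m] * area),
          area_m2 = area, stringsAsFactors = FALSE)
      }
    }
  }
  surveys <- do.call(rbind, sur)
  surveys$density <- surveys$open_flowers / surveys$area_m2

  taxonomy <- rbind(
    data.frame(name = plants, guild = "plant", group = families,
               stringsAsFactors = FALSE),
    data.frame(name = visitors, guild = "visitor", group = vgroups,
               stringsAsFactors = FALSE))
  truth <- data.frame(community = comm, species = visitors,
                      guild = "visitor", archetype = arch,
                      stringsAsFactors = FALSE)
  list(census = census, surveys = surveys, taxonomy = taxonomy,
       truth = truth)
}

#' Cross-tabulate planted archetypes against recovered categories
#'
#' Compares the generator's planted archetype labels with the categories
#' recovered by \code{\link{select_extremes}}. The recovery fraction is
#' the share of planted extreme species (generalized, specialized,
#' opportunistic, selective; background excluded) that appear in the
#' matching recovered category of their community.
#'
#' @param truth data.frame with community, species, archetype.
#' @param assignment data.frame with community, species, category (as
#'   returned by \code{\link{select_extremes}}).
#' @return list with \code{table} (archetype x category counts) and
#'   \code{recovery_fraction}.
#' @export
planted_truth_report <- function(truth, assignment) {
  archetypes <- c("generalized", "specialized", "opportunistic",
                  "selective", "background")
  categories <- c("generalized", "specialized", "opportunistic",
                  "selective", "none")
  if (nrow(assignment) > 0 &&
      length(intersect(truth$species, assignment$species)) == 0) {
    stop("truth and recovered label sets cover disjoint species",
         call. = FALSE)
  }
  tab <- matrix(0L, length(archetypes), length(categories),
                dimnames = list(planted = archetypes,
                                recovered = categories))
  key <- function(comm, sp, cat) paste(comm, sp, cat, sep = "\r")
  rec <- if (nrow(assignment) > 0)
    key(assignment$community, assignment$species, assignment$category)
  else character(0)
  for (i in seq_len(nrow(truth))) {
    planted <- truth$archetype[i]
    hits <- categories[categories != "none" &
      key(truth$community[i], truth$species[i], categories) %in% rec]
    if (length(hits) == 0) {
      tab[planted, "none"] <- tab[planted, "none"] + 1L
    } else {
      for (h in hits) tab[planted, h] <- tab[planted, h] + 1L
    }
  }
  extreme <- truth$archetype != "background"
  n_extreme <- sum(extreme)
  recovered <- sum(vapply(which(extreme), function(i) {
    key(truth$community[i], truth$species[i], truth$archetype[i]) %in% rec
  }, logical(1)))
  list(table = tab,
       recovery_fraction = if (n_extreme == 0) 0
                           else recovered / n_extreme)
}
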