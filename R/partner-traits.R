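# Partner-trait profiles: evenness of partners' abundances (Pielou J'),
# partners' rank abundance (cascading 5..1 classifier), and partners'
# functional richness (distinct plant families / visitor functional
# groups). Profiles are computed per monthly network snapshot so seasonal
# shifts can be tested.

#' Pielou's evenness J'
#'
#' \code{J' = H' / ln(S)} with \code{H'} the Shannon entropy of the
#' abundance distribution and \code{S} the number of species. By
#' convention \code{J' = 1} for a single species (one interacting
#' partner).
#'
#' @param x non-negative abundances.
#' @return J' in [0, 1].
#' @export
pielou_evenness <- function(x) {
  if (any(x < 0)) stop("abundances must be non-negative", call. = FALSE)
  S <- length(x)
  if (S == 0) stop("empty abundance vector", call. = FALSE)
  if (S == 1) return(1)
  tot <- sum(x)
  if (tot <= 0) return(0)
  p <- x[x > 0] / tot
  H <- -sum(p * log(p))
  H / log(S)
}

#' Heterogeneity of abundances in a community-month
#'
#' Defined here as \code{1 - J'} over all abundances of one guild in a
#' community-month: 0 for perfectly even abundances, approaching 1 as
#' abundance concentrates on one species.
#'
#' @param x non-negative abundances (length >= 2 for a meaningful value).
#' @return value in [0, 1).
#' @export
community_heterogeneity <- function(x) {
  if (length(x) < 2) {
    warning("heterogeneity of a single abundance is defined as 0")
    return(0)
  }
  1 - pielou_evenness(x)
}

#' Cascading abundance-rank classification
#'
#' Assigns each species a rank from 5 (highly abundant) down to 1
#' (scarce) by successive relative thresholds against the remaining
#' maximum: species above 80% of the current maximum get rank 5; of the
#' remainder, those above 75% of the new maximum rank 4; then above 66%
#' rank 3; then above 50% rank 2; the rest rank 1. Thresholds are strict
#' and the stage maximum always qualifies for its own stage.
#'
#' @param x named non-negative abundances of one guild in one
#'   community-month.
#' @return named integer ranks in \code{5:1}.
#' @export
rank_cascade <- function(x) {
  if (length(x) == 0) stop("empty abundance table", call. = FALSE)
  if (any(x < 0)) stop("abundances must be non-negative", call. = FALSE)
  thresholds <- c(`5` = 0.80, `4` = 0.75, `3` = 0.66, `2` = 0.50)
  ranks <- stats::setNames(rep(1L, length(x)), names(x))
  remaining <- seq_along(x)
  for (r in names(thresholds)) {
    if (length(remaining) == 0) break
    M <- max(x[remaining])
    if (M <= 0) break   # zero-abundance tail is scarce by definition
    sel <- x[remaining] > thresholds[[r]] * M
    ranks[remaining[sel]] <- as.integer(r)
    remaining <- remaining[!sel]
  }
  ranks
}

#' Rank all species of an abundance table
#'
#' Applies \code{\link{rank_cascade}} separately per guild (plants are
#' ranked by flower density, visitors by observed individuals).
#'
#' @param abund data.frame from \code{\link{abundance_table}}.
#' @return the table with an added integer \code{rank} column.
#' @export
rank_abundances <- function(abund) {
  if (nrow(abund) == 0) stop("empty abundance table", call. = FALSE)
  abund$rank <- NA_integer_
  for (g in unique(abund$guild)) {
    i <- abund$guild == g
    abund$rank[i] <- rank_cascade(stats::setNames(abund$abundance[i],
                                                  abund$species[i]))
  }
  abund
}

#' Partner profile of one focal species in one monthly network
#'
#' Over the focal species' partners with positive weight: Pielou evenness
#' of the partners' abundances (J' = 1 for a single partner), the
#' unweighted mean of the partners' abundance ranks, and the number of
#' distinct partner families (plant partners) or functional groups
#' (visitor partners).
#'
#' @param net monthly \code{\link{interaction_network}}.
#' @param ranked ranked abundance table for the same community-month
#'   (\code{\link{rank_abundances}}).
#' @param taxonomy taxonomy data.frame (name, guild, group).
#' @param species focal species label.
#' @param weighted if TRUE, mean rank is weighted by interaction weight
#'   instead of unweighted over distinct partners.
#' @return one-row data.frame: species, guild, community, month_index,
#'   evenness, mean_rank, functional_richness, n_partners.
#' @export
partner_profile <- function(net, ranked, taxonomy, species,
                            weighted = FALSE) {
  w <- species_vector(net, species, "weights")
  k <- species_vector(net, species, "counts")
  # a recorded interaction counts as a partner even if its FVR weight is
  # zero (a plant can have zero measured flower density in a month)
  partners <- names(w)[w > 0 | k > 0]
  if (length(partners) == 0) {
    stop("species '", species, "' has no partners in this network",
         call. = FALSE)
  }
  guild <- if (species %in% net$plants) "plant" else "visitor"
  pg <- if (guild == "plant") "visitor" else "plant"
  idx <- match(partners, ranked$species[ranked$guild == pg])
  sub <- ranked[ranked$guild == pg, , drop = FALSE]
  if (any(is.na(idx))) {
    stop("partner(s) missing from abundance ranking: ",
         paste(partners[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  grp <- taxonomy$group[match(partners, taxonomy$name)]
  if (any(is.na(grp))) {
    stop("partner(s) missing from taxonomy: ",
         paste(partners[is.na(grp)], collapse = ", "), call. = FALSE)
  }
  ab <- sub$abundance[idx]
  rk <- sub$rank[idx]
  mean_rank <- if (weighted) {
    wt <- if (sum(w[partners]) > 0) w[partners] else k[partners]
    sum(rk * wt) / sum(wt)
  } else {
    mean(rk)
  }
  month <- normalize_period(net$period)$month
  data.frame(species = species, guild = guild, community = net$community,
             month_index = month, evenness = pielou_evenness(ab),
             mean_rank = mean_rank,
             functional_richness = length(unique(grp)),
             n_partners = length(partners), stringsAsFactors = FALSE)
}

#' Partner profiles for all selected species across monthly networks
#'
#' Computes a \code{\link{partner_profile}} for every (species, month)
#' where a selected species occurs in the monthly network. A species
#' selected in several categories yields one profile row per category.
#'
#' @param selection data.frame from \code{\link{select_extremes}}.
#' @param monthly named list of monthly networks.
#' @param census,surveys data frames with \code{month_index} columns.
#' @param taxonomy taxonomy data.frame.
#' @param weighted passed to \code{\link{partner_profile}}.
#' @return data.frame of profiles joined with category labels.
#' @export
partner_profiles <- function(selection, monthly, census, surveys,
                             taxonomy, weighted = FALSE) {
  rank_cache <- list()
  get_ranked <- function(cm, m) {
    key <- paste(cm, m)
    if (is.null(rank_cache[[key]])) {
      rank_cache[[key]] <<- rank_abundances(
        abundance_table(census, surveys, cm, m))
    }
    rank_cache[[key]]
  }
  rows <- list()
  for (nm in names(monthly)) {
    net <- monthly[[nm]]
    m <- normalize_period(net$period)$month
    sel <- selection[selection$community == net$community, , drop = FALSE]
    if (nrow(sel) == 0) next
    ranked <- NULL
    for (i in seq_len(nrow(sel))) {
      sp <- sel$species[i]
      present <- sp %in% net$plants || sp %in% net$visitors
      if (!present) next
      if (is.null(ranked)) ranked <- get_ranked(net$community, m)
      pr <- partner_profile(net, ranked, taxonomy, sp, weighted)
      pr$category <- sel$category[i]
      rows[[length(rows) + 1]] <- pr
    }
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}
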