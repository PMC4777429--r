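# Species-level specialization indices and extreme-species selection.
#
# L (linkage level) is the number of distinct partners in the season
# network. d is the Kullback-Leibler divergence (in nats) between a
# species' interaction proportions and partner availability; d' rescales
# it to [0,1] between the minimum divergence attainable by any integer
# allocation of the species' interactions (d_min) and the theoretical
# maximum (d_max). Low d' = opportunistic (use proportional to
# availability); high d' = selective (over-use of rare partners).

#' Linkage level of a species
#'
#' The number of partners with positive interaction weight in the network:
#' the qualitative generalization index.
#'
#' @param net an \code{\link{interaction_network}}.
#' @param species species label (plant or visitor).
#' @return integer L.
#' @export
linkage_level <- function(net, species) {
  row <- species_vector(net, species, "weights")
  sum(row > 0)
}

#' @noRd
species_vector <- function(net, species, layer) {
  if (species %in% net$plants) {
    net[[layer]][species, ]
  } else if (species %in% net$visitors) {
    net[[layer]][, species]
  } else {
    stop("species '", species, "' not in network", call. = FALSE)
  }
}

#' @noRd
kl_divergence <- function(p, q) {
  use <- p > 0
  sum(p[use] * log(p[use] / q[use]))
}

#' Minimum-divergence integer allocation
#'
#' Allocates \code{A} interaction units across partners with availability
#' \code{q} to minimize the KL divergence of the allocation proportions
#' from \code{q}: largest-remainder proportional apportionment followed by
#' single-unit local-search moves until no move lowers the divergence.
#'
#' @param A integer total units.
#' @param q availability distribution (sums to 1, all > 0).
#' @return list with \code{allocation} (integer vector) and \code{d}.
#' @export
dmin_allocation <- function(A, q) {
  stopifnot(A >= 1, all(q > 0))
  q <- q / sum(q)
  J <- length(q)
  n <- floor(A * q)
  rem <- A - sum(n)
  if (rem > 0) {
    # break remainder ties on larger q, then lower index
    frac <- A * q - n
    ord <- order(-frac, -q, seq_len(J))
    n[ord[seq_len(rem)]] <- n[ord[seq_len(rem)]] + 1
  }
  d_of <- function(n) kl_divergence(n / A, q)
  d <- d_of(n)
  repeat {
    best_d <- d; best <- NULL
    for (j in which(n > 0)) {
      for (k in seq_len(J)) {
        if (k == j) next
        cand <- n; cand[j] <- cand[j] - 1; cand[k] <- cand[k] + 1
        dc <- d_of(cand)
        if (dc < best_d - 1e-15) { best_d <- dc; best <- cand }
      }
    }
    if (is.null(best)) break
    n <- best; d <- best_d
  }
  list(allocation = as.integer(round(n)), d = d)
}

#' Complementary specialization index d'
#'
#' For a focal species with raw interaction counts \code{a_j} on each
#' partner (total \code{A}), partner availability \code{q_j}, and network
#' grand total \code{m}: \code{d = sum(p_j * ln(p_j / q_j))} over used
#' partners with \code{p_j = a_j / A}. In \code{"marginal"} mode the
#' availability is the partners' marginal totals of the same count matrix
#' and \code{d_max = ln(m / A)}; in \code{"external"} mode availability
#' comes from independent abundances and \code{d_max = -ln(min(q))}.
#' \code{d_min} is the divergence of the best integer allocation
#' (\code{\link{dmin_allocation}}). \code{d' = (d - d_min) / (d_max -
#' d_min)}, clamped to [0,1] and defined 0 when \code{d_max <= d_min}.
#'
#' @param net an \code{\link{interaction_network}} (the \code{counts}
#'   layer is used).
#' @param species focal species label.
#' @param availability \code{"marginal"} or \code{"external"}.
#' @param abundances named numeric vector of partner abundances (external
#'   mode only).
#' @return list with \code{d}, \code{d_min}, \code{d_max}, \code{d_prime}.
#' @export
dprime <- function(net, species, availability = c("marginal", "external"),
                   abundances = NULL) {
  availability <- match.arg(availability)
  a <- species_vector(net, species, "counts")
  A <- sum(a)
  if (A < 1) {
    stop("species '", species, "' has zero interactions; ",
         "it should have been pruned", call. = FALSE)
  }
  m <- sum(net$counts)
  partners <- names(a)
  if (availability == "marginal") {
    tot <- if (species %in% net$plants) colSums(net$counts)
           else rowSums(net$counts)
    q <- tot / m
    d_max <- log(m / A)
  } else {
    if (is.null(abundances)) {
      stop("external availability mode needs partner abundances",
           call. = FALSE)
    }
    ab <- abundances[partners]
    if (any(is.na(ab))) {
      stop("no abundance for partner(s): ",
           paste(partners[is.na(ab)], collapse = ", "), call. = FALSE)
    }
    if (any(a > 0 & ab <= 0)) {
      stop("partner(s) with zero abundance but positive interactions: ",
           paste(partners[a > 0 & ab <= 0], collapse = ", "),
           call. = FALSE)
    }
    q <- ab / sum(ab)
    d_max <- -log(min(q[q > 0]))
  }
  usable <- q > 0
  d <- kl_divergence(a[usable] / A, q[usable])
  d_min <- dmin_allocation(A, q[usable])$d
  d_prime <- if (d_max - d_min > 1e-12) {
    min(max((d - d_min) / (d_max - d_min), 0), 1)
  } else 0
  list(d = d, d_min = d_min, d_max = d_max, d_prime = d_prime)
}

#' Specialization table for one season network
#'
#' Computes L and d' for every species (both guilds) in the network.
#'
#' @inheritParams dprime
#' @return data.frame with one row per species: community, species, guild,
#'   L, A (season interaction total), d, d_min, d_max, d_prime.
#' @export
specialization_table <- function(net, availability = "marginal",
                                 abundances = NULL) {
  one <- function(sp, guild) {
    dd <- dprime(net, sp, availability, abundances)
    data.frame(community = net$community, species = sp, guild = guild,
               L = linkage_level(net, sp),
               A = sum(species_vector(net, sp, "counts")),
               d = dd$d, d_min = dd$d_min, d_max = dd$d_max,
               d_prime = dd$d_prime, stringsAsFactors = FALSE)
  }
  rows <- c(lapply(net$plants, one, guild = "plant"),
            lapply(net$visitors, one, guild = "visitor"))
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Apply the reliability filters to a specialization table
#'
#' Drops plants censused less than \code{min_census_min} minutes in total
#' over the season, visitors with fewer than \code{min_individuals}
#' observed individuals, and species present in fewer than
#' \code{min_networks} monthly networks. Boundaries: the time and
#' individual thresholds are strict ("less than"); network presence is
#' inclusive ("at least").
#'
#' @param records output of \code{\link{specialization_table}} (possibly
#'   several communities row-bound).
#' @param census the season's census data.frame.
#' @param monthly named list of monthly networks
#'   (\code{\link{build_all_networks}}\code{$monthly}).
#' @param min_census_min minimum total plant census minutes (default 30).
#' @param min_individuals minimum visitor individuals (default 5).
#' @param min_networks minimum monthly networks present (default 2).
#' @return filtered records with an added \code{months_present} column.
#' @export
apply_filters <- function(records, census, monthly, min_census_min = 30,
                          min_individuals = 5, min_networks = 2) {
  eff <- census[!duplicated(census[c("community", "date", "plant")]), ,
                drop = FALSE]
  t_key <- paste(eff$community, eff$plant)
  T_tot <- tapply(eff$duration_min, t_key, sum)
  vis <- census[census$visitor != NONE_LABEL, , drop = FALSE]
  v_key <- paste(vis$community, vis$visitor)
  I_tot <- tapply(vis$individuals, v_key, sum)

  months_present <- vapply(seq_len(nrow(records)), function(i) {
    sp <- records$species[i]; cm <- records$community[i]
    sum(vapply(monthly, function(nw) {
      nw$community == cm && (sp %in% nw$plants || sp %in% nw$visitors)
    }, logical(1)))
  }, integer(1))
  records$months_present <- months_present

  key <- paste(records$community, records$species)
  keep_plant <- records$guild != "plant" |
    (!is.na(T_tot[key]) & T_tot[key] >= min_census_min)
  keep_vis <- records$guild != "visitor" |
    (!is.na(I_tot[key]) & I_tot[key] >= min_individuals)
  keep <- keep_plant & keep_vis & months_present >= min_networks
  records[keep, , drop = FALSE]
}

#' Select the extreme species per community and guild
#'
#' Per community and guild: the \code{n} species with highest L are
#' generalized, lowest L specialized, lowest d' opportunistic, highest d'
#' selective. A species may fall in more than one category. Ties at the
#' cutoff are broken by larger season interaction total, then by species
#' name, so the selection is deterministic.
#'
#' @param records (filtered) specialization table.
#' @param n category size per guild (default 5).
#' @return data.frame with community, species, guild, category.
#' @export
select_extremes <- function(records, n = 5) {
  if (nrow(records) == 0) stop("no eligible species", call. = FALSE)
  out <- list()
  for (cm in unique(records$community)) {
    for (g in unique(records$guild)) {
      r <- records[records$community == cm & records$guild == g, ,
                   drop = FALSE]
      if (nrow(r) == 0) next
      if (nrow(r) < n) {
        warning(sprintf("only %d eligible %s species in %s (< %d): %s",
                        nrow(r), g, cm, n, "taking all"))
      }
      take <- function(metric, decreasing) {
        key <- if (decreasing) -r[[metric]] else r[[metric]]
        r$species[order(key, -r$A, r$species)][seq_len(min(n, nrow(r)))]
      }
      sel <- list(generalized = take("L", TRUE),
                  specialized = take("L", FALSE),
                  opportunistic = take("d_prime", FALSE),
                  selective = take("d_prime", TRUE))
      for (cat in names(sel)) {
        out[[length(out) + 1]] <- data.frame(
          community = cm, species = sel[[cat]], guild = g,
          category = cat, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}
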