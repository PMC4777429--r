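# Flower-visitation-rate computation and network assembly.
#
# Interaction weight is the flower visitation rate (FVR): flower contacts
# per observed flower per census minute, scaled by the plant's community-
# level flower abundance. Networks are assembled per community for the
# whole season or for one monthly snapshot; a parallel raw contact-count
# matrix is always retained because the d' index needs integer counts.

#' @noRd
normalize_period <- function(period) {
  if (identical(period, "season")) return(list(kind = "season", month = NA))
  if (is.numeric(period)) return(list(kind = "month",
                                      month = as.integer(period)))
  if (is.character(period) && grepl("^month:[0-9]+$", period)) {
    return(list(kind = "month",
                month = as.integer(sub("^month:", "", period))))
  }
  stop("period must be \"season\", \"month:k\" or an integer month",
       call. = FALSE)
}

#' @noRd
period_label <- function(p) {
  if (p$kind == "season") "season" else paste0("month:", p$month)
}

#' Flower visitation rate
#'
#' \code{FVR = (V / (F * T)) * D}: flower contacts \code{V} standardized
#' by total flowers observed \code{F} and total census minutes \code{T}
#' for the plant, scaled by the plant's flower density \code{D}
#' (flowers per square metre). The \code{mode} switch exposes alternative
#' readings of the abundance standardization: \code{"divide"} divides by
#' density instead, \code{"none"} omits it.
#'
#' @param V flowers contacted (pair total).
#' @param F_obs total flowers observed on the plant.
#' @param T_min total census minutes on the plant.
#' @param D plant flower density, flowers per square metre.
#' @param mode \code{"multiply"} (default), \code{"divide"} or
#'   \code{"none"}.
#' @return numeric FVR weight(s).
#' @export
compute_fvr <- function(V, F_obs, T_min, D,
                        mode = c("multiply", "divide", "none")) {
  mode <- match.arg(mode)
  if (any(V > 0 & (F_obs <= 0 | T_min <= 0))) {
    stop("positive contacts with zero observation effort", call. = FALSE)
  }
  rate <- ifelse(V == 0, 0, V / (F_obs * T_min))
  switch(mode,
    multiply = rate * D,
    divide = {
      if (any(rate > 0 & D <= 0)) {
        stop("cannot divide by zero flower density", call. = FALSE)
      }
      ifelse(rate == 0, 0, rate / D)
    },
    none = rate)
}

#' Observation-effort and density summary for one community-period
#'
#' @param census census data.frame with a \code{month_index} column.
#' @param surveys survey data.frame with \code{month_index} and
#'   \code{density} columns.
#' @param community community label.
#' @param period \code{"season"}, \code{"month:k"} or integer month.
#' @return list with \code{plants} (data.frame plant, T_min, F_obs, D) and
#'   \code{pairs} (data.frame plant, visitor, V).
#' @export
effort_summary <- function(census, surveys, community, period = "season") {
  p <- normalize_period(period)
  cen <- census[census$community == community, , drop = FALSE]
  sur <- surveys[surveys$community == community, , drop = FALSE]
  if (p$kind == "month") {
    cen <- cen[cen$month_index == p$month, , drop = FALSE]
    sur <- sur[sur$month_index == p$month, , drop = FALSE]
  }
  if (nrow(cen) == 0) {
    stop("no census records for ", community, " / ", period_label(p),
         call. = FALSE)
  }
  # effort counted once per census (community, date, plant), not per
  # visitor row
  eff <- cen[!duplicated(cen[c("date", "plant")]), , drop = FALSE]
  T_min <- tapply(eff$duration_min, eff$plant, sum)
  F_obs <- tapply(eff$flowers_observed, eff$plant, sum)
  plants <- sort(names(T_min))

  no_density <- setdiff(plants, unique(sur$plant))
  if (length(no_density) > 0) {
    stop("censused plant(s) missing from the period's surveys: ",
         paste(no_density, collapse = ", "), call. = FALSE)
  }
  D <- tapply(sur$density, sur$plant, mean)[plants]

  vis <- cen[cen$visitor != NONE_LABEL, , drop = FALSE]
  if (nrow(vis) > 0) {
    V <- stats::aggregate(flowers_contacted ~ plant + visitor, data = vis,
                          FUN = sum)
    names(V)[3] <- "V"
    ind <- stats::aggregate(individuals ~ plant + visitor, data = vis,
                            FUN = sum)
    V$individuals <- ind$individuals[match(paste(V$plant, V$visitor),
                                           paste(ind$plant, ind$visitor))]
  } else {
    V <- data.frame(plant = character(0), visitor = character(0),
                    V = numeric(0), individuals = numeric(0))
  }
  list(community = community, period = period_label(p),
       plants = data.frame(plant = plants,
                           T_min = as.numeric(T_min[plants]),
                           F_obs = as.numeric(F_obs[plants]),
                           D = as.numeric(D), stringsAsFactors = FALSE),
       pairs = V)
}

#' Build a quantitative flower-visitation network
#'
#' Aggregates census effort per plant over the period, flower contacts per
#' plant-visitor pair, and mean flower density per plant over the period's
#' surveys, then weights each pair by its flower visitation rate
#' (\code{\link{compute_fvr}}). Plants or visitors with no interactions in
#' the period are pruned. The raw contact-count matrix is retained in the
#' \code{counts} layer.
#'
#' @inheritParams effort_summary
#' @param fvr_mode abundance standardization mode, see
#'   \code{\link{compute_fvr}}.
#' @return an \code{\link{interaction_network}}.
#' @export
build_network <- function(census, surveys, community, period = "season",
                          fvr_mode = "multiply") {
  eff <- effort_summary(census, surveys, community, period)
  pl <- eff$plants; pr <- eff$pairs
  visitors <- sort(unique(pr$visitor))
  W <- matrix(0, nrow(pl), max(length(visitors), 0),
              dimnames = list(pl$plant, visitors))
  K <- W
  if (nrow(pr) > 0) {
    idx <- cbind(match(pr$plant, pl$plant), match(pr$visitor, visitors))
    K[idx] <- pr$V
    W[idx] <- compute_fvr(pr$V, pl$F_obs[idx[, 1]], pl$T_min[idx[, 1]],
                          pl$D[idx[, 1]], mode = fvr_mode)
  }
  interaction_network(W, K, community = community,
                      period = eff$period)
}

#' Build all monthly and season networks for every community
#'
#' @inheritParams build_network
#' @return list with \code{season} (one network per community) and
#'   \code{monthly} (named \code{"<community>.<month>"}).
#' @export
build_all_networks <- function(census, surveys, fvr_mode = "multiply") {
  comms <- sort(unique(census$community))
  months <- sort(unique(census$month_index))
  season <- lapply(comms, function(cm)
    build_network(census, surveys, cm, "season", fvr_mode))
  names(season) <- comms
  monthly <- list()
  for (cm in comms) {
    for (m in months[months %in%
                     census$month_index[census$community == cm]]) {
      monthly[[paste(cm, m, sep = ".")]] <-
        build_network(census, surveys, cm, m, fvr_mode)
    }
  }
  list(season = season, monthly = monthly)
}

#' Monthly abundance table for one community
#'
#' Plant abundance is the mean flower density (flowers per square metre)
#' over the month's surveys; visitor abundance is the total number of
#' individuals observed visiting flowers in the month's censuses — the
#' best available estimate when independent visitor counts cannot be
#' obtained.
#'
#' @inheritParams effort_summary
#' @param month integer month index.
#' @return data.frame with species, guild, abundance; attributes
#'   \code{community} and \code{month_index}.
#' @export
abundance_table <- function(census, surveys, community, month) {
  sur <- surveys[surveys$community == community &
                 surveys$month_index == month, , drop = FALSE]
  cen <- census[census$community == community &
                census$month_index == month, , drop = FALSE]
  if (nrow(sur) == 0) {
    stop("no surveys for ", community, " month ", month, call. = FALSE)
  }
  pd <- tapply(sur$density, sur$plant, mean)
  vis <- cen[cen$visitor != NONE_LABEL, , drop = FALSE]
  va <- if (nrow(vis) > 0) tapply(vis$individuals, vis$visitor, sum)
        else numeric(0)
  out <- rbind(
    data.frame(species = names(pd), guild = "plant",
               abundance = as.numeric(pd), stringsAsFactors = FALSE),
    data.frame(species = names(va), guild = "visitor",
               abundance = as.numeric(va), stringsAsFactors = FALSE))
  attr(out, "community") <- community
  attr(out, "month_index") <- month
  out
}
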