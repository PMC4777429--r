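# Domain tables, validation, and plain-text readers/writers.
#
# All tables are comma-separated UTF-8 with a header row. Validation is
# total: every malformed row yields a row-numbered diagnostic; rows are
# never silently dropped.

census_columns <- c("community", "date", "plant", "duration_min",
                    "flowers_observed", "visitor", "individuals",
                    "flowers_contacted")
survey_columns <- c("community", "date", "plant", "open_flowers", "area_m2")
taxonomy_columns <- c("name", "guild", "group")

#' @noRd
check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s: missing required column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

#' @noRd
fail_rows <- function(problems, what) {
  if (length(problems) > 0) {
    stop(sprintf("%s: %d invalid row(s):\n%s", what, length(problems),
                 paste(problems, collapse = "\n")), call. = FALSE)
  }
}

#' Assign within-season month indices from dates
#'
#' Month index 1 is the month containing the community's season start date;
#' subsequent calendar months count up from there. Communities may start
#' their season in different calendar months (e.g. April on Mallorca,
#' January on Lanzarote), so the mapping is per community.
#'
#' @param date Date vector (or string coercible with \code{as.Date}).
#' @param community character vector, recycled against \code{date}.
#' @param season_start named character/Date vector: community -> season
#'   start date.
#' @return integer month indices (1-based).
#' @export
month_index <- function(date, community, season_start) {
  date <- as.Date(date)
  miss <- setdiff(unique(community), names(season_start))
  if (length(miss) > 0) {
    stop("no season_start for community: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  start <- as.Date(unname(season_start[community]))
  ym <- function(d) as.integer(format(d, "%Y")) * 12L +
    as.integer(format(d, "%m"))
  ym(date) - ym(start) + 1L
}

#' Read a flower-visitation census table
#'
#' One row per plant-census x visitor-species observation. Censuses that
#' recorded no visits carry visitor \code{"NONE"} with zero individuals and
#' contacts, so observation effort is preserved. A census is identified by
#' (community, date, plant); duration and flowers observed must be constant
#' within that key.
#'
#' @param path CSV file with columns community, date, plant, duration_min,
#'   flowers_observed, visitor, individuals, flowers_contacted.
#' @param season_start optional named vector (community -> season start
#'   date); when given, a \code{month_index} column is added.
#' @return data.frame of validated census records.
#' @export
read_census <- function(path, season_start = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, census_columns, "census")
  if (nrow(df) == 0) {
    warning("census file ", path, " has a header but no rows")
    return(df)
  }
  df$date <- as.Date(df$date)
  probs <- validate_census(df)
  fail_rows(probs, "census")
  if (!is.null(season_start)) {
    df$month_index <- month_index(df$date, df$community, season_start)
  }
  df
}

#' @noRd
validate_census <- function(df) {
  probs <- character(0)
  add <- function(rows, msg) {
    if (any(rows)) c(probs, sprintf("row %d: %s", which(rows), msg)) else probs
  }
  probs <- add(is.na(df$date), "unparseable date")
  probs <- add(!is.na(df$duration_min) & df$duration_min <= 0,
               "duration_min must be > 0")
  probs <- add(!is.na(df$flowers_observed) & df$flowers_observed < 1,
               "flowers_observed must be >= 1")
  probs <- add(!is.na(df$individuals) & df$individuals < 0,
               "individuals must be >= 0")
  probs <- add(!is.na(df$flowers_contacted) & df$flowers_contacted < 0,
               "flowers_contacted must be >= 0")
  none <- df$visitor == NONE_LABEL
  probs <- add(none & df$flowers_contacted != 0,
               "flowers_contacted must be 0 when visitor is NONE")
  probs <- add(none & df$individuals != 0,
               "individuals must be 0 when visitor is NONE")
  probs <- add(!none & df$individuals < 1,
               "individuals must be >= 1 when visitor is present")
  # effort must be consistent within one census (community, date, plant)
  key <- paste(df$community, df$date, df$plant, sep = "\r")
  dup_d <- stats::ave(df$duration_min, key, FUN = function(x)
    length(unique(x))) > 1
  dup_f <- stats::ave(df$flowers_observed, key, FUN = function(x)
    length(unique(x))) > 1
  probs <- add(dup_d, "duration_min inconsistent within census")
  probs <- add(dup_f, "flowers_observed inconsistent within census")
  probs
}

#' Read a flower-density survey table
#'
#' One row per survey x plant species: an open-flower count over a known
#' surveyed area. Flower density is \code{open_flowers / area_m2}
#' (flowers per square metre). Tightly clustered inflorescences (e.g. a
#' capitulum) are counted as one flower by the data producer.
#'
#' @param path CSV with columns community, date, plant, open_flowers,
#'   area_m2.
#' @return data.frame of validated surveys with a derived \code{density}
#'   column.
#' @export
read_surveys <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, survey_columns, "surveys")
  if (nrow(df) == 0) {
    warning("survey file ", path, " has a header but no rows")
    df$density <- numeric(0)
    return(df)
  }
  df$date <- as.Date(df$date)
  probs <- character(0)
  bad_date <- is.na(df$date)
  bad_fl <- !is.na(df$open_flowers) & df$open_flowers < 0
  bad_ar <- !is.na(df$area_m2) & df$area_m2 <= 0
  if (any(bad_date)) probs <- c(probs, sprintf("row %d: unparseable date",
                                               which(bad_date)))
  if (any(bad_fl)) probs <- c(probs, sprintf(
    "row %d: open_flowers must be >= 0", which(bad_fl)))
  if (any(bad_ar)) probs <- c(probs, sprintf(
    "row %d: area_m2 must be > 0", which(bad_ar)))
  fail_rows(probs, "surveys")
  df$density <- df$open_flowers / df$area_m2
  df
}

#' Read a species taxonomy table
#'
#' Maps each species to its guild (plant or visitor) and group: a family
#' name for plants, a functional group for flower visitors. Visitor groups
#' are checked against a controlled vocabulary (default: the ten standard
#' insect functional groups).
#'
#' @param path CSV with columns name, guild, group.
#' @param groups character vector of allowed visitor functional groups;
#'   \code{NULL} disables the vocabulary check.
#' @return data.frame of validated species records.
#' @export
read_taxonomy <- function(path, groups = visitor_functional_groups) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, taxonomy_columns, "taxonomy")
  if (nrow(df) == 0) {
    warning("taxonomy file ", path, " has a header but no rows")
    return(df)
  }
  probs <- character(0)
  bad_guild <- !df$guild %in% c("plant", "visitor")
  if (any(bad_guild)) probs <- c(probs, sprintf(
    "row %d: guild must be 'plant' or 'visitor' (got '%s')",
    which(bad_guild), df$guild[bad_guild]))
  if (!is.null(groups)) {
    bad_grp <- df$guild == "visitor" & !df$group %in% groups
    if (any(bad_grp)) probs <- c(probs, sprintf(
      "row %d: visitor group '%s' not in controlled vocabulary",
      which(bad_grp), df$group[bad_grp]))
  }
  key <- paste(df$guild, df$name, sep = "\r")
  dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
  first_dup <- duplicated(key)
  if (any(first_dup)) probs <- c(probs, sprintf(
    "row %d: duplicate species name '%s' within guild '%s'",
    which(first_dup), df$name[first_dup], df$guild[first_dup]))
  fail_rows(probs, "taxonomy")
  df
}

# ---------------------------------------------------------------------------
# InteractionNetwork: weighted plant x visitor matrix plus the parallel raw
# contact-count matrix, scoped to a community and a period ("season" or
# "month:k"). Plants are rows, visitors columns, everywhere.

#' Construct an interaction network object
#'
#' @param weights numeric matrix, plants in rows and visitors in columns,
#'   with dimnames; typically flower-visitation rates.
#' @param counts integer matrix of the same shape: raw flower-contact
#'   counts (used for d' computation).
#' @param community community label.
#' @param period \code{"season"} or \code{"month:k"}.
#' @param prune drop all-zero rows/columns (both layers zero)? Default TRUE.
#' @return object of class \code{interaction_network}.
#' @export
interaction_network <- function(weights, counts = weights, community = "",
                                period = "season", prune = TRUE) {
  weights <- as.matrix(weights)
  counts <- as.matrix(counts)
  stopifnot(identical(dim(weights), dim(counts)))
  if (is.null(rownames(weights)) || is.null(colnames(weights))) {
    stop("network matrices need plant row names and visitor column names")
  }
  if (any(weights < 0) || any(counts < 0)) {
    stop("network weights must be non-negative")
  }
  dimnames(counts) <- dimnames(weights)
  if (prune) {
    keep_r <- rowSums(weights) > 0 | rowSums(counts) > 0
    keep_c <- colSums(weights) > 0 | colSums(counts) > 0
    if (!all(keep_r) || !all(keep_c)) {
      if (sum(keep_r) == 0 || sum(keep_c) == 0) {
        warning("network is empty after pruning all-zero rows/columns")
      }
      weights <- weights[keep_r, keep_c, drop = FALSE]
      counts <- counts[keep_r, keep_c, drop = FALSE]
    }
  }
  structure(list(community = community, period = period,
                 plants = rownames(weights), visitors = colnames(weights),
                 weights = weights, counts = counts),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf(
    "<interaction_network> %s / %s: %d plants x %d visitors, total weight %.4g\n",
    x$community, x$period, length(x$plants), length(x$visitors),
    sum(x$weights)))
  invisible(x)
}

#' Row, column and grand totals of a network layer
#'
#' @param net an \code{interaction_network}.
#' @param layer \code{"weights"} or \code{"counts"}.
#' @return list with \code{row_totals} (per plant), \code{col_totals}
#'   (per visitor) and \code{grand_total}.
#' @export
network_marginals <- function(net, layer = c("weights", "counts")) {
  layer <- match.arg(layer)
  m <- net[[layer]]
  list(row_totals = rowSums(m), col_totals = colSums(m),
       grand_total = sum(m))
}

#' Write / read an interaction network as plain text
#'
#' The file holds a small metadata header (community, period) followed by
#' the weight matrix and the raw count matrix as CSV blocks. Round-trips
#' are lossless to full double precision.
#'
#' @param net an \code{interaction_network}.
#' @param path output file.
#' @return \code{write_network}: the path, invisibly. \code{read_network}:
#'   an \code{interaction_network}.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "interaction_network"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c("# pollinet network v1",
               paste0("# community: ", net$community),
               paste0("# period: ", net$period)), con)
  dump_layer <- function(name, m) {
    writeLines(paste0("# layer: ", name), con)
    writeLines(paste(c("species", colnames(m)), collapse = ","), con)
    for (i in seq_len(nrow(m))) {
      writeLines(paste(c(rownames(m)[i],
                         format(m[i, ], digits = 17, trim = TRUE,
                                scientific = FALSE)), collapse = ","), con)
    }
  }
  dump_layer("weights", net$weights)
  dump_layer("counts", net$counts)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0 || lines[1] != "# pollinet network v1") {
    stop("not a pollinet network file: ", path, call. = FALSE)
  }
  meta_val <- function(key) {
    hit <- grep(paste0("^# ", key, ": "), lines, value = TRUE)
    if (length(hit) == 0) stop("network file missing metadata: ", key,
                               call. = FALSE)
    sub(paste0("^# ", key, ": "), "", hit[1])
  }
  layer_at <- which(grepl("^# layer: ", lines))
  if (length(layer_at) != 2) stop("malformed network file: expected 2 layers",
                                  call. = FALSE)
  parse_block <- function(from, to) {
    block <- lines[(from + 1):to]
    block <- block[nzchar(block)]
    df <- utils::read.csv(text = paste(block, collapse = "\n"),
                          check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    storage.mode(m) <- "double"
    m
  }
  w <- parse_block(layer_at[1], layer_at[2] - 1)
  k <- parse_block(layer_at[2], length(lines))
  interaction_network(w, k, community = meta_val("community"),
                      period = meta_val("period"))
}
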