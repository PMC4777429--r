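# One-shot reproducible pipeline: simulate (or ingest) census data, build
# season and monthly networks, compute specialization indices, apply the
# reliability filters, select extreme species, profile their partners and
# compare traits across categories; write all artifacts as plain text.

#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> build -> classify -> profile -> compare as a
#' pure function of the configuration and seed. With the default
#' synthetic configuration this produces 4 season and 16 monthly
#' networks, the specialization and selection tables, per-month partner
#' profiles, category and selectiveness comparisons per guild and trait,
#' and a recovery report against the planted archetypes. When
#' \code{out_dir} is given, all artifacts are written as CSV (networks in
#' the pollinet network format) together with a \code{run.yaml} recording
#' the configuration and its hash; each written table carries the config
#' hash in a \code{config_hash} column.
#'
#' @param sim a \code{\link{sim_config}}; ignored when \code{data} is
#'   supplied.
#' @param data optional list with census, surveys, taxonomy (and
#'   optionally truth) data.frames, bypassing simulation.
#' @param out_dir optional output directory.
#' @param fvr_mode abundance standardization for FVR weights.
#' @param availability \code{"marginal"} or \code{"external"} partner
#'   availability for d'.
#' @param min_census_min,min_individuals,min_networks reliability-filter
#'   thresholds (defaults 30 minutes, 5 individuals, 2 networks).
#' @param category_size species per category per guild (default 5).
#' @param method \code{"mixed_model"} or \code{"permutation"} for the
#'   category comparisons.
#' @param seed seed for the permutation method (simulation uses the seed
#'   inside \code{sim}).
#' @return (invisibly) list with data, networks, specialization,
#'   selection, profiles, comparisons, recovery, config_hash.
#' @export
run_pipeline <- function(sim = sim_config(), data = NULL, out_dir = NULL,
                         fvr_mode = "multiply", availability = "external",
                         min_census_min = 30, min_individuals = 5,
                         min_networks = 2, category_size = 5,
                         method = c("mixed_model", "permutation"),
                         seed = 1) {
  method <- match.arg(method)
  cfg <- list(sim = if (is.null(data)) unclass(sim) else NULL,
              fvr_mode = fvr_mode, availability = availability,
              min_census_min = min_census_min,
              min_individuals = min_individuals,
              min_networks = min_networks, category_size = category_size,
              method = method, seed = seed)
  cfg_hash <- rlang::hash(cfg)

  if (is.null(data)) data <- simulate_community(sim)
  log_stage("simulate", sprintf("%d census rows, %d survey rows",
                                nrow(data$census), nrow(data$surveys)))

  nets <- build_all_networks(data$census, data$surveys, fvr_mode)
  log_stage("build", sprintf("%d season + %d monthly networks",
                             length(nets$season), length(nets$monthly)))

  spec_tab <- do.call(rbind, c(lapply(nets$season, function(nw) {
    ab <- NULL
    if (availability == "external") {
      ab <- season_abundances(data$census, data$surveys, nw$community)
    }
    specialization_table(nw, availability, ab)
  }), make.row.names = FALSE))
  filtered <- apply_filters(spec_tab, data$census, nets$monthly,
                            min_census_min, min_individuals, min_networks)
  log_stage("classify", sprintf("%d species, %d after filters",
                                nrow(spec_tab), nrow(filtered)))

  selection <- select_extremes(filtered, n = category_size)
  profiles <- partner_profiles(selection, nets$monthly, data$census,
                               data$surveys, data$taxonomy)
  log_stage("profile", sprintf("%d selected species, %d profile rows",
                               nrow(selection), nrow(profiles)))

  comparisons <- compare_all(profiles, method, seed)
  log_stage("compare", sprintf("%d contrasts", nrow(comparisons)))

  recovery <- NULL
  if (!is.null(data$truth)) {
    recovery <- planted_truth_report(data$truth, selection)
    log_stage("recovery", sprintf("fraction %.3f",
                                  recovery$recovery_fraction))
  }

  out <- list(data = data, networks = nets, specialization = spec_tab,
              filtered = filtered, selection = selection,
              profiles = profiles, comparisons = comparisons,
              recovery = recovery, config_hash = cfg_hash)
  if (!is.null(out_dir)) write_artifacts(out, cfg, out_dir)
  invisible(out)
}

#' @noRd
log_stage <- function(stage, msg) {
  message(sprintf("[pollinet] %-9s %s", stage, msg))
}

#' @noRd
season_abundances <- function(census, surveys, community) {
  months <- sort(unique(census$month_index[census$community == community]))
  tabs <- lapply(months, function(m)
    abundance_table(census, surveys, community, m))
  all_tab <- do.call(rbind, tabs)
  out <- tapply(all_tab$abundance, all_tab$species, mean)
  stats::setNames(as.numeric(out), names(out))
}

# The paper-shaped comparison family: generalized vs specialized and
# opportunistic vs selective, per guild and trait; visitors' functional
# richness log-transformed in the linkage models.
#' @noRd
compare_all <- function(profiles, method, seed) {
  pairs <- list(linkage = c("generalized", "specialized"),
                selectiveness = c("opportunistic", "selective"))
  traits <- c("evenness", "mean_rank", "functional_richness")
  rows <- list()
  for (index in names(pairs)) {
    for (g in unique(profiles$guild)) {
      sub <- profiles[profiles$guild == g &
                      profiles$category %in% pairs[[index]], ,
                      drop = FALSE]
      for (tr in traits) {
        transform <- if (index == "linkage" && g == "visitor" &&
                         tr == "functional_richness") "log" else "none"
        res <- tryCatch({
          if (method == "mixed_model") {
            compare_categories(sub, tr, transform)
          } else {
            permutation_compare(sub, tr, transform, seed = seed)
          }
        }, error = function(e) {
          message("[pollinet] comparison skipped (", index, "/", g, "/",
                  tr, "): ", conditionMessage(e))
          NULL
        })
        if (is.null(res)) next
        res$index <- index
        res$guild <- g
        rows[[length(rows) + 1]] <- res
      }
    }
  }
  cols <- c("index", "guild", "trait", "transform", "contrast",
            "estimate", "p_raw", "p_adj", "n")
  out <- do.call(rbind, c(lapply(rows, function(r) {
    for (col in c("se", "z", "singular_fallback", "n_excluded_strata")) {
      if (is.null(r[[col]])) r[[col]] <- NA
    }
    r[c(cols, "se", "z", "singular_fallback", "n_excluded_strata")]
  }), make.row.names = FALSE))
  out
}

#' @noRd
write_artifacts <- function(out, cfg, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  net_dir <- file.path(out_dir, "networks")
  dir.create(net_dir, showWarnings = FALSE)
  for (nw in out$networks$season) {
    write_network(nw, file.path(net_dir,
                                paste0(nw$community, "_season.csv")))
  }
  for (nm in names(out$networks$monthly)) {
    write_network(out$networks$monthly[[nm]],
                  file.path(net_dir, paste0(gsub("\\.", "_month", nm),
                                            ".csv")))
  }
  dump <- function(df, name) {
    if (is.null(df) || nrow(df) == 0) return(invisible(NULL))
    df$config_hash <- out$config_hash
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }
  dump(out$data$census, "census.csv")
  dump(out$data$surveys, "surveys.csv")
  dump(out$data$taxonomy, "taxonomy.csv")
  dump(out$data$truth, "truth.csv")
  dump(out$specialization, "specialization.csv")
  dump(out$filtered, "specialization_filtered.csv")
  dump(out$selection, "selection.csv")
  dump(out$profiles, "profiles.csv")
  dump(out$comparisons, "comparisons.csv")
  if (!is.null(out$recovery)) {
    utils::write.csv(as.data.frame.matrix(out$recovery$table),
                     file.path(out_dir, "recovery_confusion.csv"))
    writeLines(format(out$recovery$recovery_fraction, digits = 17),
               file.path(out_dir, "recovery_fraction.txt"))
  }
  yaml::write_yaml(c(cfg, list(config_hash = out$config_hash)),
                   file.path(out_dir, "run.yaml"))
  invisible(out_dir)
}
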