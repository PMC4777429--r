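# Statistical comparison of partner traits between specificity categories
# and across months: linear mixed models (maximum likelihood) with random
# intercepts for community and month-within-community, multiplicity-
# adjusted contrasts, compact-letter grouping for month comparisons, and a
# stratified permutation fallback for small datasets.

#' @noRd
prepare_trait_data <- function(profiles, trait,
                               transform = c("none", "log")) {
  transform <- match.arg(transform)
  stopifnot(trait %in% names(profiles))
  df <- data.frame(
    value = profiles[[trait]],
    category = if ("category" %in% names(profiles))
      factor(profiles$category) else factor(rep("all", nrow(profiles))),
    community = factor(profiles$community),
    month = factor(profiles$month_index))
  if (transform == "log") {
    if (any(df$value <= 0)) {
      stop("log transform requires strictly positive trait values",
           call. = FALSE)
    }
    df$value <- log(df$value)
  }
  df
}

# Fit value ~ <fixed> with random intercepts for community and
# month-within-community; on a singular fit, drop the degenerate random
# term(s) and refit, down to a plain linear model if needed.
#' @noRd
fit_trait_model <- function(df, fixed) {
  forms <- c(
    paste0("value ~ ", fixed, " + (1 | community) + (1 | community:month)"),
    paste0("value ~ ", fixed, " + (1 | community)"),
    paste0("value ~ ", fixed))
  for (i in seq_along(forms)) {
    f <- stats::as.formula(forms[i])
    if (i < length(forms)) {
      fit <- suppressMessages(suppressWarnings(
        lme4::lmer(f, data = df, REML = FALSE)))
      if (!lme4::isSingular(fit, tol = 1e-5)) {
        return(list(fit = fit, singular_fallback = i > 1))
      }
    } else {
      return(list(fit = stats::lm(f, data = df), singular_fallback = TRUE))
    }
  }
}

#' @noRd
glht_results <- function(fit, factor_name, comparison, n, meta) {
  spec <- list(comparison)
  names(spec) <- factor_name
  gl <- multcomp::glht(fit, linfct = do.call(multcomp::mcp, spec))
  adj <- summary(gl, test = multcomp::adjusted("single-step"))
  raw <- summary(gl, test = multcomp::adjusted("none"))
  out <- data.frame(
    contrast = names(adj$test$coefficients),
    estimate = as.numeric(adj$test$coefficients),
    se = as.numeric(adj$test$sigma),
    z = as.numeric(adj$test$tstat),
    p_raw = as.numeric(raw$test$pvalues),
    p_adj = as.numeric(adj$test$pvalues),
    n = n, stringsAsFactors = FALSE)
  for (nm in names(meta)) out[[nm]] <- meta[[nm]]
  attr(out, "glht") <- gl
  out
}

#' Compare a partner trait between specificity categories
#'
#' Fits \code{trait ~ category} with random intercepts for community and
#' month-within-community (maximum likelihood), and reports the category
#' contrast(s) with Wald z statistics and single-step adjusted p-values.
#' On a singular fit the degenerate random term is dropped and the refit
#' flagged in \code{singular_fallback}.
#'
#' @param profiles data.frame from \code{\link{partner_profiles}} (or any
#'   table with the trait, category, community, month_index columns).
#' @param trait column name: \code{"evenness"}, \code{"mean_rank"} or
#'   \code{"functional_richness"}.
#' @param transform \code{"none"} or \code{"log"} (e.g. for visitor
#'   functional richness).
#' @param comparison contrast family passed to \code{multcomp::mcp}:
#'   \code{"Tukey"} (all pairs) or \code{"Dunnett"} (many-to-one).
#' @return data.frame of contrasts: estimate, se, z, raw and adjusted p.
#' @export
compare_categories <- function(profiles, trait, transform = "none",
                               comparison = "Tukey") {
  df <- prepare_trait_data(profiles, trait, transform)
  if (nlevels(df$category) < 2) {
    stop("need at least two categories to compare", call. = FALSE)
  }
  counts <- table(df$category)
  if (any(counts < 2)) {
    stop("each category needs at least two observations", call. = FALSE)
  }
  fm <- fit_trait_model(df, "category")
  glht_results(fm$fit, "category", comparison, nrow(df),
               list(trait = trait, transform = transform,
                    singular_fallback = fm$singular_fallback))
}

#' Compare a partner trait across months within one category
#'
#' All-pairs month contrasts with single-step adjustment, plus a
#' compact-letter display: months sharing a letter do not differ
#' significantly.
#'
#' @inheritParams compare_categories
#' @param alpha significance level for the letter grouping.
#' @return list with \code{contrasts} (data.frame) and \code{letters}
#'   (named character vector per month).
#' @export
compare_months <- function(profiles, trait, transform = "none",
                           alpha = 0.05) {
  df <- prepare_trait_data(profiles, trait, transform)
  keep <- table(df$month)
  drop <- names(keep)[keep < 2]
  if (length(drop) > 0) {
    warning("dropping month(s) with a single observation: ",
            paste(drop, collapse = ", "))
    df <- droplevels(df[!df$month %in% drop, , drop = FALSE])
  }
  if (nlevels(df$month) < 2) {
    stop("need at least two months to compare", call. = FALSE)
  }
  fm <- fit_trait_model(df, "month")
  res <- glht_results(fm$fit, "month", "Tukey", nrow(df),
                      list(trait = trait, transform = transform,
                           singular_fallback = fm$singular_fallback))
  letters <- multcomp::cld(attr(res, "glht"), level = alpha)$mcletters
  list(contrasts = res, letters = letters$Letters)
}

#' Stratified permutation comparison of two categories
#'
#' Permutes category labels within community-month strata and compares
#' the observed difference of means against the permutation distribution:
#' \code{p = (1 + #(|T_perm| >= |T_obs|)) / (1 + n_perm)}. Strata with
#' fewer than two observations cannot be permuted and are excluded (their
#' count is reported).
#'
#' @inheritParams compare_categories
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed; fixes the permutation stream.
#' @return data.frame with contrast, estimate (difference of means),
#'   p_raw, p_adj (identical: single test), n, n_excluded_strata.
#' @export
permutation_compare <- function(profiles, trait, transform = "none",
                                n_perm = 999, seed = 1) {
  if (n_perm < 99) stop("n_perm must be >= 99", call. = FALSE)
  df <- prepare_trait_data(profiles, trait, transform)
  lev <- levels(df$category)
  if (length(lev) != 2) {
    stop("permutation comparison needs exactly two categories",
         call. = FALSE)
  }
  strata <- interaction(df$community, df$month, drop = TRUE)
  sizes <- table(strata)
  small <- names(sizes)[sizes < 2]
  excluded <- length(small)
  keep <- !strata %in% small
  df <- df[keep, , drop = FALSE]
  strata <- droplevels(strata[keep])
  if (nrow(df) == 0 || length(unique(df$category)) < 2) {
    stop("no permutable strata with both categories", call. = FALSE)
  }
  stat <- function(labels) {
    mean(df$value[labels == lev[2]]) - mean(df$value[labels == lev[1]])
  }
  t_obs <- stat(df$category)
  idx_by_stratum <- split(seq_len(nrow(df)), strata)
  set.seed(seed)
  t_perm <- vapply(seq_len(n_perm), function(i) {
    lab <- df$category
    for (ix in idx_by_stratum) lab[ix] <- sample(lab[ix])
    stat(lab)
  }, numeric(1))
  p <- (1 + sum(abs(t_perm) >= abs(t_obs) - 1e-12)) / (1 + n_perm)
  data.frame(contrast = paste(lev[2], "-", lev[1]), estimate = t_obs,
             p_raw = p, p_adj = p, n = nrow(df),
             n_excluded_strata = excluded, trait = trait,
             transform = transform, stringsAsFactors = FALSE)
}
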