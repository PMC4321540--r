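#' Welch two-sample comparison of a trait between groups
#'
#' Unequal-variance t-test between the two levels of a grouping factor.
#' By default the test is run on species means (one value per species) to
#' avoid pseudoreplication of replicate leaves; set `level = "replicate"`
#' to test the raw rows.
#'
#' @param data Data frame with `species`, the grouping column and the trait.
#' @param trait Name of the trait column (string).
#' @param group Name of the two-level grouping column (string).
#' @param level `"species"` (default) or `"replicate"`.
#' @return A one-row tibble: group means, `t`, `df`, `p`, significance
#'   `stars` (`*` < 0.05, `**` < 0.01, `***` < 0.001, `ns` otherwise).
#' @export
welch_test <- function(data, trait, group, level = c("species", "replicate")) {
  level <- match.arg(level)
  if (!all(c(trait, group) %in% names(data))) {
    abort("`trait` and `group` must name columns of `data`.")
  }
  if (level == "species") {
    if (!"species" %in% names(data)) abort("`data` needs a `species` column.")
    data <- data |>
      dplyr::group_by(.data$species, .data[[group]]) |>
      dplyr::summarise(
        !!trait := mean(.data[[trait]], na.rm = TRUE), .groups = "drop"
      )
  }
  g <- factor(data[[group]])
  if (nlevels(g) != 2) abort("`group` must have exactly two levels.")
  y <- data[[trait]]
  n_per <- table(g[!is.na(y)])
  if (any(n_per < 2)) abort("need at least 2 values per group.")
  ht <- t.test(y ~ g, var.equal = FALSE)
  tibble::tibble(
    trait = trait,
    group1 = levels(g)[1], group2 = levels(g)[2],
    mean1 = unname(ht$estimate[1]), mean2 = unname(ht$estimate[2]),
    t = unname(ht$statistic), df = unname(ht$parameter),
    p = ht$p.value, stars = p_stars(ht$p.value)
  )
}

p_stars <- function(p) {
  dplyr::case_when(
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ "ns"
  )
}

#' Trait comparison table between two groups
#'
#' Builds a publication-style comparison table: per-group species-level
#' mean and standard error for each trait, with Welch-test significance
#' stars.
#'
#' @param data Replicate-level trait table with `species` and the grouping
#'   column.
#' @param traits Character vector of trait columns.
#' @param group Name of the two-level grouping column.
#' @return A tibble with one row per trait: means, SEMs, `t`, `p`, `stars`.
#' @export
trait_comparison_table <- function(data, traits, group) {
  sp <- data |>
    dplyr::group_by(.data$species, .data[[group]]) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(traits), \(x) mean(x, na.rm = TRUE)),
      .groups = "drop"
    )
  purrr::map_dfr(traits, function(tr) {
    sums <- sp |>
      dplyr::group_by(.data[[group]]) |>
      dplyr::summarise(
        mean = mean(.data[[tr]], na.rm = TRUE),
        sem = sd(.data[[tr]], na.rm = TRUE) / sqrt(sum(!is.na(.data[[tr]]))),
        .groups = "drop"
      )
    wt <- welch_test(sp, tr, group, level = "replicate")
    tibble::tibble(
      trait = tr,
      mean1 = sums$mean[1], sem1 = sums$sem[1],
      mean2 = sums$mean[2], sem2 = sums$sem[2],
      t = wt$t, p = wt$p, stars = wt$stars
    )
  })
}

#' Two-factor mixed model for a trait (species as random effect)
#'
#' Fits `trait ~ A * B + (1 | species)` by REML, the comparison design in
#' which subfamily and photosynthetic type (or a habitat water-availability
#' measure) are crossed fixed factors and species is a random intercept.
#' Marginal (type III) F-tests are reported for each fixed term. The
#' denominator degrees of freedom default to the between-species convention
#' `n_species - p`, with `p` the number of fixed-effect parameters (29 for a
#' 33-species 2 x 2 design); Satterthwaite df are available as a switch.
#' `factor_b` may be a continuous covariate such as MAP.
#'
#' With `random = FALSE` the species intercept is dropped (species variance
#' forced to zero) and the same table is computed from a two-way
#' fixed-effects ANOVA.
#'
#' @param data Replicate-level trait table with a `species` column.
#' @param trait Trait column name (string).
#' @param factor_a,factor_b Fixed-effect column names (strings).
#' @param random Keep the species random intercept (default TRUE).
#' @param ddf `"between-species"` (default) or `"satterthwaite"`.
#' @return An object of class `trait_mixed`: `table` (tibble of F-tests),
#'   `varcomp` (species and residual variances), `aic`, `fit`.
#' @export
fit_two_factor_mixed <- function(data, trait, factor_a = "subfamily",
                                 factor_b = "ptype", random = TRUE,
                                 ddf = c("between-species", "satterthwaite")) {
  ddf <- match.arg(ddf)
  need <- c(trait, factor_a, factor_b, "species")
  if (!all(need %in% names(data))) {
    abort(paste("`data` needs columns:", paste(need, collapse = ", ")))
  }
  for (fc in c(factor_a, factor_b)) {
    v <- data[[fc]]
    if ((is.character(v) || is.factor(v)) && length(unique(v)) < 2) {
      abort(sprintf("factor '%s' does not vary.", fc))
    }
  }
  d <- data.frame(
    y = data[[trait]], A = data[[factor_a]], B = data[[factor_b]],
    species = data$species
  )
  d <- d[complete.cases(d), ]
  n_species <- length(unique(d$species))
  X <- stats::model.matrix(~ A * B, d)
  p <- qr(X)$rank

  if (random) {
    fit <- lmerTest::lmer(y ~ A * B + (1 | species), data = d, REML = TRUE)
    vc <- as.data.frame(lme4::VarCorr(fit))
    species_var <- vc$vcov[vc$grp == "species"]
    resid_var <- vc$vcov[vc$grp == "Residual"]
    if (species_var < 1e-10) {
      warn("species variance estimated at the zero boundary.")
    }
    at <- stats::anova(fit, type = 3, ddf = "Satterthwaite")
    den_df <- if (ddf == "between-species") {
      rep(n_species - p, nrow(at))
    } else {
      at$DenDF
    }
    tab <- tibble::tibble(
      term = rownames(at), f = at$`F value`,
      num_df = at$NumDF, den_df = den_df
    )
    aic <- AIC(fit)
  } else {
    fit <- aov(y ~ A * B, data = d)
    at <- summary(fit)[[1]]
    k <- nrow(at) - 1
    tab <- tibble::tibble(
      term = trimws(rownames(at)[seq_len(k)]),
      f = at$`F value`[seq_len(k)],
      num_df = at$Df[seq_len(k)],
      den_df = at$Df[k + 1]
    )
    species_var <- 0
    resid_var <- at$`Mean Sq`[k + 1]
    aic <- AIC(fit)
  }
  tab$p <- pf(tab$f, tab$num_df, tab$den_df, lower.tail = FALSE)
  tab$stars <- p_stars(tab$p)
  structure(
    list(
      table = tab, trait = trait,
      varcomp = c(species = species_var, residual = resid_var),
      aic = aic, n_species = n_species, ddf = ddf, fit = fit
    ),
    class = "trait_mixed"
  )
}

#' @export
print.trait_mixed <- function(x, ...) {
  cat(sprintf(
    "Two-factor mixed model for '%s' (%d species; species var %.4g, residual %.4g, AIC %.1f)\n",
    x$trait, x$n_species, x$varcomp["species"], x$varcomp["residual"], x$aic
  ))
  print(as.data.frame(x$table), row.names = FALSE)
  invisible(x)
}

#' Compare water-availability encodings by AIC
#'
#' Fits the subfamily-by-water model three times, encoding habitat water
#' availability as continuous MAP, as the continuous water score, and as the
#' three-level habitat class, all with a species random intercept, by
#' maximum likelihood (so AIC values are comparable across fixed-effect
#' structures). The encoding with the lowest AIC is flagged.
#'
#' @param data Replicate-level trait table with columns `species`,
#'   `subfamily`, `map`, `water_score`, `habitat_class`.
#' @param trait Trait column name (string).
#' @return A tibble with one row per encoding: `encoding`, `aic`, `best`.
#' @export
compare_water_encodings <- function(data, trait) {
  encodings <- c(map = "map", water_score = "water_score",
                 habitat_class = "habitat_class")
  aic <- purrr::map_dbl(encodings, function(enc) {
    d <- data.frame(
      y = data[[trait]], A = data$subfamily, B = data[[enc]],
      species = data$species
    )
    fit <- lme4::lmer(y ~ A * B + (1 | species), data = d, REML = FALSE)
    AIC(fit)
  })
  tibble::tibble(
    encoding = names(encodings), aic = unname(aic),
    best = aic == min(aic)
  )
}
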