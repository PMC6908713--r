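#' Score clock predictions against known lifespans
#'
#' Computes the clock's evaluation battery on an aligned table of known and
#' predicted lifespans: squared Pearson correlation of ln lifespans (which
#' for the simple regression of known on predicted equals the regression
#' R^2, reported separately as `r_squared_lm` for transparency), the median
#' absolute error (MAE) in years, per-species relative errors, per-class R^2
#' for classes with at least 3 members, and Welch two-sample t-tests of the
#' absolute errors between training/testing species and between
#' captivity/wild lifespan sources when those columns are present.
#'
#' @param data Tibble with columns `species_id`, `known_years`,
#'   `predicted_years`; optionally `vertebrate_class`, `split` (values
#'   "train"/"test") and `source` (values "captivity"/"wild"/"unknown").
#' @return A list of class `clock_evaluation`: `summary` (one-row tibble),
#'   `per_species` (per-species errors), `per_class` (per-class R^2 and
#'   p-value), `group_tests` (Welch t-test p-values, when computable).
#' @export
score_predictions <- function(data) {
  data <- as_tibble(data)
  need <- c("species_id", "known_years", "predicted_years")
  if (!all(need %in% names(data))) {
    abort(sprintf("`data` must contain columns: %s.", paste(need, collapse = ", ")))
  }
  if (anyNA(data$known_years) || anyNA(data$predicted_years)) {
    abort("Known and predicted lifespans must not contain missing values.")
  }
  if (nrow(data) < 3L) abort("At least 3 species are required for scoring.")

  per_species <- data |>
    mutate(
      ln_known = log(.data$known_years),
      ln_predicted = log(.data$predicted_years),
      abs_error_years = abs(.data$predicted_years - .data$known_years),
      relative_error = abs(.data$predicted_years - .data$known_years) / .data$known_years
    )

  r <- stats::cor(per_species$ln_known, per_species$ln_predicted)
  fit <- stats::lm(ln_known ~ ln_predicted, data = per_species)
  summ <- tibble(
    n = nrow(per_species),
    r_squared_log = r^2,
    r_squared_lm = summary(fit)$r.squared,
    pearson_r = r,
    mae_years = stats::median(per_species$abs_error_years),
    max_relative_error = max(per_species$relative_error),
    median_relative_error = stats::median(per_species$relative_error)
  )

  per_class <- NULL
  if ("vertebrate_class" %in% names(data)) {
    eligible <- names(which(table(per_species$vertebrate_class) >= 3L))
    per_class <- purrr::map_dfr(eligible, function(cl) {
      g <- per_species[per_species$vertebrate_class == cl, ]
      ct <- stats::cor.test(g$ln_known, g$ln_predicted)
      tibble(vertebrate_class = cl, n = nrow(g),
             r_squared = unname(ct$estimate)^2, p_value = ct$p.value)
    })
  }

  group_tests <- list()
  welch_p <- function(v, g, lv) {
    a <- v[g == lv[1]]; b <- v[g == lv[2]]
    if (length(a) >= 2L && length(b) >= 2L) {
      stats::t.test(a, b)$p.value
    } else NA_real_
  }
  if ("split" %in% names(data)) {
    group_tests$train_vs_test_p <-
      welch_p(per_species$abs_error_years, per_species$split, c("train", "test"))
  }
  if ("source" %in% names(data)) {
    group_tests$captivity_vs_wild_p <-
      welch_p(per_species$abs_error_years, per_species$source, c("captivity", "wild"))
  }

  structure(
    list(summary = summ, per_species = per_species, per_class = per_class,
         group_tests = group_tests),
    class = "clock_evaluation"
  )
}

#' @export
print.clock_evaluation <- function(x, ...) {
  s <- x$summary
  cat("<clock_evaluation>\n")
  cat(sprintf("  n = %d species\n", s$n))
  cat(sprintf("  R^2 (ln scale, squared Pearson) = %.3f\n", s$r_squared_log))
  cat(sprintf("  MAE = %.2f years; max relative error = %.1f%%\n",
              s$mae_years, 100 * s$max_relative_error))
  if (!is.null(x$group_tests$train_vs_test_p)) {
    cat(sprintf("  train vs test abs-error t-test p = %.3g\n",
                x$group_tests$train_vs_test_p))
  }
  if (!is.null(x$group_tests$captivity_vs_wild_p)) {
    cat(sprintf("  captivity vs wild abs-error t-test p = %.3g\n",
                x$group_tests$captivity_vs_wild_p))
  }
  invisible(x)
}

#' @rdname score_predictions
#' @param x A `clock_evaluation`.
#' @param ... Unused.
#' @export
glance.clock_evaluation <- function(x, ...) x$summary

#' @rdname score_predictions
#' @export
tidy.clock_evaluation <- function(x, ...) {
  as_tibble(x$per_species)
}

#' Per-promoter correlations with lifespan
#'
#' Pearson correlation of each promoter's CpG density with ln maximum
#' lifespan across species, with two-sided p-values. Zero-variance columns
#' are flagged and report no correlation.
#'
#' @param densities Density tibble.
#' @param ln_lifespans Natural-log lifespans, named by species id or aligned
#'   with the density rows.
#' @return Tibble: `promoter_id`, `pearson_r`, `p_value`, `direction`
#'   (sign of r), `flagged` (TRUE for zero-variance columns).
#' @export
per_promoter_correlations <- function(densities, ln_lifespans) {
  m <- density_values(densities)
  y <- as.numeric(ln_lifespans)
  if (!is.null(names(ln_lifespans))) {
    y <- as.numeric(ln_lifespans[rownames(m)])
  }
  if (nrow(m) < 3L) abort("At least 3 species are required.")
  purrr::map_dfr(colnames(m), function(p) {
    v <- m[, p]
    if (stats::sd(v) == 0) {
      return(tibble(promoter_id = p, pearson_r = NA_real_, p_value = NA_real_,
                    direction = NA_real_, flagged = TRUE))
    }
    ct <- stats::cor.test(v, y)
    tibble(promoter_id = p, pearson_r = unname(ct$estimate),
           p_value = ct$p.value, direction = sign(unname(ct$estimate)),
           flagged = FALSE)
  })
}

#' Principal component analysis of the density matrix
#'
#' Correlation PCA of the species-by-promoter density matrix (columns centred
#' and scaled to unit variance). Zero-variance columns are dropped with a
#' warning before scaling.
#'
#' @param densities Density tibble.
#' @param n_components Number of components to return scores for (>= 2).
#' @return A list: `scores` (tibble with `species_id` and `PC1..PCk`),
#'   `explained_variance` (fractions, non-increasing).
#' @export
pca_densities <- function(densities, n_components = 2) {
  m <- density_values(densities)
  if (nrow(m) < 3L || ncol(m) < 2L) {
    abort("PCA needs at least 3 species and 2 promoters.")
  }
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    warn(sprintf("Dropping %d zero-variance promoter column(s) before scaling.",
                 sum(sds == 0)))
    m <- m[, sds > 0, drop = FALSE]
  }
  pc <- stats::prcomp(m, center = TRUE, scale. = TRUE)
  k <- min(max(2L, n_components), ncol(pc$x))
  scores <- bind_cols(tibble(species_id = rownames(m)),
                      as_tibble(pc$x[, seq_len(k), drop = FALSE]))
  list(
    scores = scores,
    explained_variance = pc$sdev^2 / sum(pc$sdev^2)
  )
}

#' ANCOVA for a vertebrate-class effect on predictions
#'
#' Tests whether vertebrate class carries information beyond the clock's
#' prediction: F-test p-value for the class factor in the sequential
#' (type-I) analysis of `known ~ predicted + class`, covariate first.
#'
#' @param known Known ln lifespans.
#' @param predicted Predicted ln lifespans.
#' @param classes Vertebrate class per species.
#' @return The class-effect p-value.
#' @export
ancova_class_effect <- function(known, predicted, classes) {
  classes <- as.factor(classes)
  if (nlevels(droplevels(classes)) < 2L) {
    abort("ANCOVA needs at least 2 vertebrate classes.")
  }
  if (any(table(classes) < 3L)) {
    warn("Some classes have fewer than 3 members; the class F-test may be unstable.")
  }
  fit <- stats::lm(known ~ predicted + classes)
  stats::anova(fit)["classes", "Pr(>F)"]
}
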