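#' Class-stratified train/test split
#'
#' Splits a species table into training and testing sets keeping each
#' vertebrate class represented in the published 70/30 proportions: within
#' each class, `round(train_fraction * n)` species are drawn uniformly at
#' random into training. A class with a single member goes to training, with
#' a warning. The split is reproducible given the seed.
#'
#' @param records Tibble with columns `species_id` and `vertebrate_class`.
#' @param train_fraction Fraction of each class assigned to training.
#' @param seed Integer seed controlling the draw.
#' @return A list with character vectors `train` and `test` of species ids.
#' @export
split_train_test <- function(records, train_fraction = 0.7, seed = 1) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  records <- as_tibble(records)
  if (anyDuplicated(records$species_id)) abort("Duplicate species ids in `records`.")
  singles <- records |>
    count(.data$vertebrate_class) |>
    filter(.data$n == 1L)
  if (nrow(singles) > 0L) {
    warn(sprintf("Class(es) with a single member assigned to training: %s.",
                 paste(singles$vertebrate_class, collapse = ", ")))
  }
  train <- withr::with_seed(seed, {
    records |>
      group_by(.data$vertebrate_class) |>
      group_map(function(g, key) {
        n_train <- max(1L, round(train_fraction * nrow(g)))
        sample(g$species_id, n_train)
      }) |>
      unlist()
  })
  list(train = sort(train), test = sort(setdiff(records$species_id, train)))
}

#' Fit the elastic-net stage of the clock
#'
#' Regresses natural-log maximum lifespan on promoter CpG densities under the
#' elastic-net penalty \eqn{(1/(2n)) \sum (y - w_0 - Xw)^2 + \lambda (\alpha
#' \sum |w_i| + ((1-\alpha)/2) \sum w_i^2)}. The penalty `lambda` is chosen
#' by k-fold cross-validation as the minimiser of mean squared error
#' (lambda.min), unless a fixed `lambda` is supplied. Predictors are
#' standardized internally when `standardize = TRUE`; returned weights are on
#' the original density scale and only nonzero weights are kept.
#'
#' @param densities Density tibble ([build_density_matrix()]) or plain numeric
#'   matrix of training rows.
#' @param y Natural-log lifespans, aligned with the rows of `densities`.
#' @param alpha Elastic-net mixing parameter in \[0, 1\]. Default 0.5.
#' @param cv_folds Cross-validation folds. Default 10.
#' @param seed Integer seed controlling fold assignment.
#' @param standardize Standardize predictors internally. Default TRUE.
#' @param lambda Optional fixed penalty; skips cross-validation.
#' @return A list: `weights` (named, nonzero only), `intercept`,
#'   `lambda`, `nonzero_path` (tibble of the number of nonzero weights at
#'   each path knot, for diagnostics).
#' @export
fit_elastic_net <- function(densities, y, alpha = 0.5, cv_folds = 10,
                            seed = 1, standardize = TRUE, lambda = NULL) {
  x <- if (is.matrix(densities)) densities else density_values(densities)
  y <- as.numeric(y)
  if (nrow(x) != length(y)) abort("`densities` rows and `y` length differ.")
  if (anyNA(x) || anyNA(y)) abort("Missing values are not allowed in the fit.")
  if (stats::sd(y) == 0) abort("`y` is constant; the regression is undefined.")
  # glmnet requires >= 2 columns; pad univariate designs with an inert column
  padded <- ncol(x) == 1L
  if (padded) x <- cbind(x, .pad = 0)
  fit <- glmnet::glmnet(x, y, alpha = alpha, standardize = standardize,
                        thresh = 1e-12)
  if (is.null(lambda)) {
    if (nrow(x) < cv_folds) {
      abort(sprintf("Need at least cv_folds (%d) training rows, got %d.",
                    cv_folds, nrow(x)))
    }
    foldid <- withr::with_seed(seed,
      sample(rep_len(seq_len(cv_folds), nrow(x))))
    cv <- glmnet::cv.glmnet(x, y, alpha = alpha, standardize = standardize,
                            foldid = foldid, thresh = 1e-12)
    lambda <- cv$lambda.min
    beta <- stats::coef(cv, s = "lambda.min")
  } else {
    beta <- stats::coef(fit, s = lambda, exact = TRUE, x = x, y = y,
                        alpha = alpha, standardize = standardize,
                        thresh = 1e-12)
  }
  beta <- as.matrix(beta)
  beta <- stats::setNames(as.numeric(beta), rownames(beta))
  w <- beta[-1]
  if (padded) w <- w[names(w) != ".pad"]
  nz_path <- tibble(lambda = fit$lambda, n_nonzero = fit$df)
  list(weights = w[w != 0], intercept = unname(beta[1]),
       lambda = lambda, nonzero_path = nz_path)
}

#' Raw clock score of a density vector
#'
#' The elastic-net linear predictor \eqn{x = w_0 + \sum_i w_i d_i} over the
#' clock's selected promoters. Promoters absent from the density input
#' contribute 0.
#'
#' @param model A `lifespan_clock`.
#' @param densities A density tibble (any number of rows), a named numeric
#'   vector, or a plain matrix with promoter columns.
#' @return Numeric vector of raw scores, named by species when available.
#' @export
raw_score <- function(model, densities) {
  stopifnot(inherits(model, "lifespan_clock"))
  w <- model$promoter_weights
  if (is.numeric(densities) && is.null(dim(densities))) {
    densities <- matrix(densities, nrow = 1,
                        dimnames = list(NULL, names(densities)))
  } else if (!is.matrix(densities)) {
    densities <- density_values(densities)
  }
  if (length(w) == 0L) {
    return(stats::setNames(rep(model$enet_intercept, nrow(densities)),
                           rownames(densities)))
  }
  d <- matrix(0, nrow = nrow(densities), ncol = length(w),
              dimnames = list(rownames(densities), names(w)))
  present <- intersect(names(w), colnames(densities))
  d[, present] <- densities[, present]
  drop(model$enet_intercept + d %*% w)
}

#' Brownian-motion trait covariance from divergence times
#'
#' Converts pairwise divergence times (or a time-calibrated tree) into the
#' species-by-species covariance a Brownian-motion trait accrues on the
#' phylogeny: with ultrametric depth `T` (the maximum pairwise divergence),
#' shared evolutionary time is `V_ij = max(0, T - t_ij)` and `V_ii = T`. From
#' a tree, `V_ij` is the root-to-MRCA path length (via [ape::vcv.phylo()]).
#'
#' @param divergence Either a symmetric numeric matrix / data frame of
#'   pairwise divergence times in million years (zero diagonal, species ids
#'   as dimnames), or an [ape::phylo] tree with branch lengths.
#' @return A symmetric covariance matrix with species ids as dimnames.
#' @export
covariance_from_divergence <- function(divergence) {
  if (inherits(divergence, "phylo")) {
    return(ape::vcv.phylo(divergence))
  }
  t_mat <- as.matrix(divergence)
  if (!is.numeric(t_mat)) storage.mode(t_mat) <- "double"
  if (nrow(t_mat) != ncol(t_mat) ||
      max(abs(t_mat - t(t_mat))) > 1e-8 * max(1, max(abs(t_mat)))) {
    abort("Divergence matrix must be square and symmetric.")
  }
  if (any(t_mat < 0)) abort("Divergence times must be non-negative.")
  if (any(diag(t_mat) != 0)) abort("Divergence matrix must have a zero diagonal.")
  depth <- max(t_mat)
  v <- pmax(depth - t_mat, 0)
  diag(v) <- depth
  dimnames(v) <- dimnames(t_mat)
  v
}

#' Read a divergence-time matrix from CSV
#'
#' Square CSV with species ids as the header row and first column, entries in
#' million years.
#'
#' @param path CSV path.
#' @return Numeric matrix with species dimnames.
#' @export
read_divergence_matrix <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  m <- as.matrix(d[, -1])
  rownames(m) <- d[[1]]
  storage.mode(m) <- "double"
  m
}

#' Phylogenetic class calibration of raw clock scores
#'
#' The second stage of the clock: a generalized least squares fit of
#' ln(maximum lifespan) on the raw score `x` with vertebrate-class intercept
#' and slope offsets, under the Brownian-motion covariance `V` —
#' \eqn{\hat\beta = (X^T V^{-1} X)^{-1} X^T V^{-1} y} on the design
#' `[1, x, class indicators, class:x]`. The reference class (Amphibia by
#' default, when present) is absorbed into the global intercept and slope, so
#' unlisted classes use `a = b = 0`. Classes with fewer than 2 members are
#' dropped from the indicators (they fall back to `a = b = 0`) with a
#' warning.
#'
#' @param x Raw scores (named by species, or aligned with `classes`).
#' @param y Natural-log maximum lifespans.
#' @param classes Vertebrate class per species.
#' @param V Covariance matrix from [covariance_from_divergence()]; `NULL`
#'   for an identity covariance (ordinary least squares).
#' @param ref_class Reference class absorbed into the global terms.
#' @return A list: `global_intercept`, `global_slope`, `class_coefficients`
#'   (per non-reference class, `a` = slope offset, `b` = intercept offset),
#'   `std_errors`, `sigma2`, `ref_class`, `n`.
#' @export
fit_pgls_calibration <- function(x, y, classes, V = NULL,
                                 ref_class = "Amphibia") {
  x <- as.numeric(x); y <- as.numeric(y); classes <- as.character(classes)
  n <- length(x)
  stopifnot(length(y) == n, length(classes) == n)
  if (is.null(V)) V <- diag(n)
  V <- as.matrix(V)
  if (!is.null(rownames(V)) && !is.null(names(x))) {
    V <- V[names(x), names(x), drop = FALSE]
  }
  if (nrow(V) != n) abort("Covariance matrix does not match the number of species.")

  tab <- table(classes)
  small <- names(tab)[tab < 2]
  if (length(small) > 0L) {
    warn(sprintf("Class(es) with < 2 members excluded from calibration (a = b = 0): %s.",
                 paste(small, collapse = ", ")))
  }
  lvls <- setdiff(names(tab), small)
  if (!ref_class %in% lvls) ref_class <- lvls[1]
  offset_lvls <- setdiff(lvls, ref_class)

  X <- cbind(`(Intercept)` = 1, x = x)
  for (cl in offset_lvls) {
    ind <- as.numeric(classes == cl)
    X <- cbind(X, ind, ind * x)
    colnames(X)[ncol(X) - 1:0] <- c(paste0("b:", cl), paste0("a:", cl))
  }

  R <- tryCatch(chol(V), error = function(e) {
    abort("Covariance matrix is not positive definite (not invertible).")
  })
  z <- backsolve(R, y, transpose = TRUE)
  W <- backsolve(R, X, transpose = TRUE)
  colnames(W) <- colnames(X)
  qrW <- qr(W)
  if (qrW$rank < ncol(W)) {
    dropped <- colnames(W)[qrW$pivot[(qrW$rank + 1):ncol(W)]]
    culprit <- sub("^[ab]:", "", dropped)
    abort(sprintf(
      "Singular calibration design (class with constant raw score?): %s.",
      paste(unique(culprit), collapse = ", ")))
  }
  beta <- qr.coef(qrW, z)
  resid <- z - W %*% beta
  sigma2 <- sum(resid^2) / (n - ncol(W))
  XtWX_inv <- solve(crossprod(W))
  se <- sqrt(sigma2 * diag(XtWX_inv))
  names(se) <- colnames(W)

  cc <- stats::setNames(lapply(offset_lvls, function(cl) {
    list(a = unname(beta[paste0("a:", cl)]), b = unname(beta[paste0("b:", cl)]))
  }), offset_lvls)
  list(
    global_intercept = unname(beta["(Intercept)"]),
    global_slope = unname(beta["x"]),
    class_coefficients = cc,
    std_errors = se,
    sigma2 = sigma2,
    ref_class = ref_class,
    n = n
  )
}

#' Train the full two-stage lifespan clock
#'
#' End-to-end training wrapper: class-stratified split, elastic net of ln
#' lifespan on promoter densities over the training species, raw-score
#' computation, and phylogenetic class calibration of the training raw
#' scores.
#'
#' @param densities Density tibble (all species).
#' @param species Species tibble: `species_id`, `vertebrate_class`,
#'   `max_lifespan` (years); optionally `source`.
#' @param divergence Divergence matrix, tree, or precomputed covariance
#'   matrix passed to [covariance_from_divergence()]; `NULL` for an identity
#'   covariance.
#' @inheritParams fit_elastic_net
#' @param train_fraction Per-class training fraction. Default 0.7.
#' @return A list of class `clock_fit`: `model` (a `lifespan_clock`),
#'   `train_ids`, `test_ids`, `enet` (the elastic-net stage), `calibration`.
#' @export
train_clock <- function(densities, species, divergence = NULL, alpha = 0.5,
                        cv_folds = 10, train_fraction = 0.7, seed = 1,
                        standardize = TRUE) {
  species <- as_tibble(species)
  stopifnot(all(c("species_id", "vertebrate_class", "max_lifespan") %in% names(species)))
  if (any(species$max_lifespan <= 0)) abort("Maximum lifespans must be positive.")
  split <- split_train_test(species, train_fraction = train_fraction, seed = seed)
  xmat <- density_values(densities)
  missing_sp <- setdiff(species$species_id, rownames(xmat))
  if (length(missing_sp) > 0L) {
    abort(sprintf("Species missing from the density matrix: %s.",
                  paste(utils::head(missing_sp, 5), collapse = ", ")))
  }
  y_all <- stats::setNames(log(species$max_lifespan), species$species_id)
  cls_all <- stats::setNames(species$vertebrate_class, species$species_id)

  enet <- fit_elastic_net(xmat[split$train, , drop = FALSE], y_all[split$train],
                          alpha = alpha, cv_folds = cv_folds, seed = seed,
                          standardize = standardize)
  pre <- lifespan_clock(enet$weights, enet$intercept, enet$lambda,
                        global_intercept = 0, global_slope = 1)
  x_train <- raw_score(pre, xmat[split$train, , drop = FALSE])

  V <- NULL
  if (!is.null(divergence)) {
    Vfull <- if (is.matrix(divergence) && !is.null(rownames(divergence)) &&
                 all(diag(as.matrix(divergence)) != 0)) {
      divergence  # already a covariance matrix
    } else {
      covariance_from_divergence(divergence)
    }
    V <- Vfull[split$train, split$train, drop = FALSE]
  }
  calibration <- fit_pgls_calibration(x_train, y_all[split$train],
                                      cls_all[split$train], V = V)
  model <- assemble_clock(enet$weights, enet$intercept, enet$lambda, calibration)
  structure(
    list(model = model, train_ids = split$train, test_ids = split$test,
         enet = enet, calibration = calibration),
    class = "clock_fit"
  )
}

#' @export
print.clock_fit <- function(x, ...) {
  cat(sprintf("<clock_fit> %d training / %d testing species\n",
              length(x$train_ids), length(x$test_ids)))
  print(x$model)
  invisible(x)
}

#' @rdname tidy.lifespan_clock
#' @export
tidy.clock_fit <- function(x, ...) tidy(x$model, ...)

#' @rdname glance.lifespan_clock
#' @export
glance.clock_fit <- function(x, ...) {
  bind_cols(glance(x$model),
            tibble(n_train = length(x$train_ids), n_test = length(x$test_ids)))
}
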