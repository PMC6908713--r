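#' Assemble a two-stage lifespan clock
#'
#' Bundles the two fitted stages of the clock into one object: the
#' elastic-net stage (nonzero promoter weights, intercept, selected penalty)
#' that maps a promoter CpG-density vector to a raw score `x`, and the
#' phylogenetic calibration stage `ln(max lifespan) = intercept + slope * x
#' + a * x + b` with class-specific `(a, b)`. Classes absent from
#' `class_coefficients` use `a = 0, b = 0`.
#'
#' @param promoter_weights Named numeric vector of nonzero promoter weights.
#' @param enet_intercept Elastic-net intercept (the `w0` in the raw score).
#' @param selected_lambda Penalty at which the weights were taken.
#' @param global_intercept,global_slope Calibration constants shared by all
#'   classes.
#' @param class_coefficients Named list, one element per vertebrate class,
#'   each a list/vector with components `a` (slope offset) and `b` (intercept
#'   offset).
#' @param promoter_order Optional promoter universe (defaults to the weight
#'   names).
#' @return An object of class `lifespan_clock`.
#' @export
lifespan_clock <- function(promoter_weights, enet_intercept, selected_lambda,
                           global_intercept, global_slope,
                           class_coefficients = list(),
                           promoter_order = names(promoter_weights)) {
  if (is.null(global_intercept) || is.null(global_slope) ||
      is.na(global_intercept) || is.na(global_slope)) {
    abort("A lifespan clock requires both a global intercept and a global slope.")
  }
  w <- as.numeric(promoter_weights)
  names(w) <- names(promoter_weights)
  w <- w[w != 0]
  structure(
    list(
      promoter_weights = w,
      enet_intercept = as.numeric(enet_intercept),
      selected_lambda = as.numeric(selected_lambda),
      global_intercept = as.numeric(global_intercept),
      global_slope = as.numeric(global_slope),
      class_coefficients = lapply(class_coefficients, function(cc) {
        list(a = as.numeric(cc[["a"]]), b = as.numeric(cc[["b"]]))
      }),
      promoter_order = as.character(promoter_order %||% character())
    ),
    class = "lifespan_clock"
  )
}

#' @rdname lifespan_clock
#' @param weights,calibration `assemble_clock()` is the pipeline-facing
#'   wrapper: `calibration` is the result of [fit_pgls_calibration()].
#' @export
assemble_clock <- function(weights, enet_intercept, selected_lambda, calibration) {
  lifespan_clock(
    promoter_weights = weights,
    enet_intercept = enet_intercept,
    selected_lambda = selected_lambda,
    global_intercept = calibration$global_intercept,
    global_slope = calibration$global_slope,
    class_coefficients = calibration$class_coefficients
  )
}

class_ab <- function(model, vertebrate_class) {
  cc <- model$class_coefficients[[vertebrate_class]]
  if (is.null(cc)) c(a = 0, b = 0) else c(a = cc$a, b = cc$b)
}

#' Write or read a lifespan clock as JSON
#'
#' The JSON carries the exact numeric values (`digits = NA`), so a model
#' round-trips through disk unchanged.
#'
#' @param model A `lifespan_clock`.
#' @param path JSON file path.
#' @export
write_clock <- function(model, path) {
  stopifnot(inherits(model, "lifespan_clock"))
  obj <- list(
    global_intercept = model$global_intercept,
    global_slope = model$global_slope,
    enet_intercept = model$enet_intercept,
    selected_lambda = model$selected_lambda,
    weights = as.list(model$promoter_weights),
    class_coefficients = model$class_coefficients,
    promoter_order = model$promoter_order
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_clock
#' @export
read_clock <- function(path) {
  obj <- jsonlite::read_json(path)
  lifespan_clock(
    promoter_weights = unlist(obj$weights) %||% stats::setNames(numeric(), character()),
    enet_intercept = obj$enet_intercept,
    selected_lambda = obj$selected_lambda,
    global_intercept = obj$global_intercept,
    global_slope = obj$global_slope,
    class_coefficients = obj$class_coefficients,
    promoter_order = unlist(obj$promoter_order)
  )
}

#' The published vertebrate lifespan clock constants
#'
#' Loads the packaged calibration of the clock as published for 252
#' vertebrate reference genomes: global constants (-4.38996, 2.57328) and the
#' per-class `(a, b)` coefficients for Aves, Fish, Mammalia and Reptilia
#' (Amphibia is the reference class, `a = b = 0`). The elastic-net promoter
#' weights of that fit are not redistributed here, so the weight slots are
#' empty placeholders: the object evaluates the calibration formula for a
#' given raw score `x` but cannot score a genome by itself.
#'
#' @return A `lifespan_clock` with the published calibration constants.
#' @export
published_clock <- function() {
  read_clock(system.file("extdata", "published_clock.json", package = "cpgclock",
                         mustWork = TRUE))
}

#' @export
print.lifespan_clock <- function(x, ...) {
  cat("<lifespan_clock>\n")
  cat(sprintf("  raw score: w0 = %.5g + %d promoter weight(s)\n",
              x$enet_intercept, length(x$promoter_weights)))
  cat(sprintf("  calibration: ln(lifespan) = %.5f + %.5f x + a x + b\n",
              x$global_intercept, x$global_slope))
  cls <- names(x$class_coefficients)
  if (length(cls)) {
    for (cl in cls) {
      cc <- x$class_coefficients[[cl]]
      cat(sprintf("    %-10s a = %9.5f  b = %9.5f\n", cl, cc$a, cc$b))
    }
  } else cat("    (no class coefficients: a = b = 0 for all classes)\n")
  cat(sprintf("  lambda = %.5g\n", x$selected_lambda))
  invisible(x)
}

#' Tidy a lifespan clock into a coefficient table
#'
#' One row per model term: the calibration constants, each class's `(a, b)`
#' offsets, the elastic-net intercept and every nonzero promoter weight.
#'
#' @param x A `lifespan_clock`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `stage`, `estimate`.
#' @export
tidy.lifespan_clock <- function(x, ...) {
  cal <- tibble(
    term = c("global_intercept", "global_slope"),
    stage = "calibration",
    estimate = c(x$global_intercept, x$global_slope)
  )
  cls <- purrr::imap_dfr(x$class_coefficients, function(cc, cl) {
    tibble(term = paste0(cl, c("_a", "_b")), stage = "calibration",
           estimate = c(cc$a, cc$b))
  })
  enet <- tibble(
    term = c("enet_intercept", names(x$promoter_weights)),
    stage = "elastic_net",
    estimate = c(x$enet_intercept, unname(x$promoter_weights))
  )
  bind_rows(cal, cls, enet)
}

#' Summarise a lifespan clock in one row
#'
#' @inheritParams tidy.lifespan_clock
#' @return A one-row tibble: number of selected promoters, selected penalty,
#'   calibration constants, number of calibrated classes.
#' @export
glance.lifespan_clock <- function(x, ...) {
  tibble(
    n_promoters = length(x$promoter_weights),
    selected_lambda = x$selected_lambda,
    global_intercept = x$global_intercept,
    global_slope = x$global_slope,
    n_classes = length(x$class_coefficients)
  )
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance
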