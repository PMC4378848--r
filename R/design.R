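#' Specify property objectives for inverse design
#'
#' Builds the target table consumed by [design_condition()]. Each objective
#' is `"target"` (hit a value), `"maximize"`, `"minimize"`, or `"ignore"`.
#'
#' @param ... named objectives, one per property, each either a string
#'   (`"maximize"`, `"minimize"`, `"ignore"`) or a list
#'   `list(target = value, band = half-width, weight = w)`.
#' @return Tibble with columns `property`, `objective`, `target`, `band`,
#'   `weight`.
#' @examples
#' design_targets(modulus_Pa = list(target = 2000),
#'                pore_diameter_um = "maximize",
#'                t_half_min = "minimize")
#' @export
design_targets <- function(...) {
  specs <- list(...)
  if (!length(specs)) stopf("at least one objective is required")
  rows <- imap(specs, function(sp, prop) {
    if (is.character(sp)) {
      obj <- match.arg(sp, c("maximize", "minimize", "ignore"))
      tibble(property = prop, objective = obj, target = NA_real_,
             band = NA_real_, weight = 1)
    } else {
      tibble(property = prop, objective = "target",
             target = sp$target %||% stopf("`%s`: target value missing", prop),
             band = sp$band %||% NA_real_, weight = sp$weight %||% 1)
    }
  })
  out <- bind_rows(rows)
  if (all(out$objective == "ignore")) stopf("all objectives are `ignore`")
  out
}

#' Desirability-based inverse design of fabrication conditions
#'
#' Grid search over the coded fabrication domain maximizing a
#' Derringer-type composite desirability. Per-property desirabilities are
#' linear ramps: for a target objective, d = max(0, 1 - |pred - target| /
#' band); for maximize/minimize, the prediction rescaled over its range on
#' the grid. The composite is the weighted geometric mean; the returned
#' condition is the grid argmax, with all ties (within numerical tolerance)
#' reported.
#'
#' When a target band is not supplied it defaults to the half-width of the
#' 95% prediction interval (models fitted from data) or 10% of the target
#' value (packaged published models, which carry no residual information).
#'
#' @param models named list of `hydrogel_model` objects covering the
#'   targeted properties (e.g. [published_models()]).
#' @param targets objective table from [design_targets()].
#' @param fixed named list of fabrication parameters held fixed, in natural
#'   units (e.g. `list(concentration_mg_ml = 6, temperature_C = 23)`).
#' @param resolution coded-unit grid step for free parameters (default 0.01).
#' @param temperature_discrete restrict free temperature to the two
#'   experimental levels 23 and 37 C (default `TRUE`, matching practice;
#'   set `FALSE` to treat it as continuous).
#'
#' @return A list of class `design_result`: `condition` (natural units),
#'   `predictions` (per-property predictions at the optimum), `desirability`,
#'   `ties` (equally desirable grid points), `n_grid`.
#' @examples
#' res <- design_condition(
#'   published_models(),
#'   design_targets(modulus_Pa = list(target = 2000, band = 200)),
#'   fixed = list(concentration_mg_ml = 6, temperature_C = 23)
#' )
#' res$condition
#' @export
design_condition <- function(models, targets, fixed = list(),
                             resolution = 0.01, temperature_discrete = TRUE) {
  targets <- as_tibble(targets)
  targets <- targets[targets$objective != "ignore", , drop = FALSE]
  if (!nrow(targets)) stopf("no active objectives")
  missing_models <- setdiff(targets$property, names(models))
  if (length(missing_models))
    stopf("no model supplied for propert%s: %s",
          ifelse(length(missing_models) > 1, "ies", "y"),
          paste(missing_models, collapse = ", "))
  models <- models[targets$property]

  facs <- unique(unlist(map(models, model_factors)))
  cn <- coded_names()
  axes <- map(setNames(facs, facs), function(f) {
    if (!is.null(fixed[[f]])) {
      z <- nondimensionalize(tibble(!!f := fixed[[f]]))[[cn[[f]]]]
      return(z)
    }
    if (f == "temperature_C" && temperature_discrete) return(c(0, 1))
    seq(0, 1, by = resolution)
  })
  coded_grid <- as_tibble(expand.grid(axes, KEEP.OUT.ATTRS = FALSE))
  names(coded_grid) <- unname(cn[facs])
  if (nrow(coded_grid) > 2e6)
    stopf("design grid too large (%d points); fix more parameters or coarsen",
          nrow(coded_grid))
  natural_grid <- decode_condition(coded_grid)[facs]

  d_all <- matrix(NA_real_, nrow(coded_grid), nrow(targets))
  preds <- matrix(NA_real_, nrow(coded_grid), nrow(targets))
  colnames(preds) <- targets$property
  for (i in seq_len(nrow(targets))) {
    prop <- targets$property[i]
    m <- models[[prop]]
    p <- predict(m, natural_grid)$.pred
    preds[, i] <- p
    d_all[, i] <- switch(
      targets$objective[i],
      target = {
        band <- targets$band[i]
        if (!is.finite(band)) {
          band <- if (!is.null(m$fit)) {
            pr <- predict(m, natural_grid, interval = "prediction")
            mean((pr$.upper - pr$.lower) / 2)
          } else 0.1 * abs(targets$target[i])
        }
        pmax(0, 1 - abs(p - targets$target[i]) / band)
      },
      maximize = if (diff(range(p)) > 0) (p - min(p)) / diff(range(p)) else rep(1, length(p)),
      minimize = if (diff(range(p)) > 0) (max(p) - p) / diff(range(p)) else rep(1, length(p))
    )
  }
  w <- targets$weight / sum(targets$weight)
  # weighted geometric mean; any zero desirability zeroes the composite
  composite <- exp(drop(log(pmax(d_all, 1e-300)) %*% w))
  composite[apply(d_all == 0, 1, any)] <- 0

  if (all(composite == 0))
    warnf(paste0("no grid point satisfies all objectives simultaneously; ",
                 "returning the first grid point with zero desirability"))
  best <- which.max(composite)
  tie_ix <- which(composite >= composite[best] - 1e-9)
  condition <- natural_grid[best, , drop = FALSE]
  structure(
    list(
      condition = as_tibble(condition),
      predictions = tibble(property = targets$property,
                           objective = targets$objective,
                           target = targets$target,
                           predicted = preds[best, ],
                           desirability = d_all[best, ]),
      desirability = composite[best],
      ties = as_tibble(natural_grid[tie_ix, , drop = FALSE]),
      n_grid = nrow(coded_grid)
    ),
    class = "design_result"
  )
}

#' @export
print.design_result <- function(x, ...) {
  cat("<design_result> composite desirability =", format(x$desirability, digits = 4),
      sprintf("(grid of %d points, %d tie%s)\n", x$n_grid, nrow(x$ties),
              ifelse(nrow(x$ties) == 1, "", "s")))
  cat("condition:\n"); print.data.frame(x$condition, row.names = FALSE)
  cat("predictions:\n"); print.data.frame(x$predictions, row.names = FALSE)
  invisible(x)
}

#' Plot normalized sensitivities of the property models
#'
#' Bar chart of coefficient sensitivities per property (largest-magnitude
#' term of each model is +/-1).
#'
#' @param models a `hydrogel_model` or list of them (see [sensitivity()]).
#' @return A ggplot object.
#' @export
plot_sensitivity <- function(models) {
  s <- sensitivity(models)
  ggplot(s, aes(x = .data$term, y = .data$sensitivity)) +
    geom_col(fill = "grey35") +
    geom_hline(yintercept = 0) +
    facet_wrap(~property) +
    coord_flip() +
    labs(x = NULL, y = "normalized sensitivity")
}
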