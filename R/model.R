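#' @section Coded units:
#' All regression models operate on non-dimensional (coded) fabrication
#' parameters, each spanning 0-1 over the experimental ranges:
#' \deqn{C' = (C - 4)/6,\quad T' = (T - 23)/14,\quad pH' = pH - 7.4,}
#' \deqn{(R_H^{-1})' = (R_H^{-1} - 1/8.5)/(1/1.4 - 1/8.5)}
#' with C in mg/ml, T in degrees C, and R_H in nm. Coding makes coefficients
#' directly comparable across parameters.
#' @name coded-units
#' @keywords internal
NULL

# experimental parameter ranges (natural units)
param_ranges <- function() {
  list(
    concentration_mg_ml = c(4, 10),
    temperature_C = c(23, 37),
    pH = c(7.4, 8.4),
    hydrodynamic_radius_nm = c(1.4, 8.5)
  )
}

# natural column name -> coded column name
coded_names <- function() {
  c(concentration_mg_ml = "c_prime", temperature_C = "t_prime",
    pH = "ph_prime", hydrodynamic_radius_nm = "inv_rh_prime")
}

natural_names <- function() {
  setNames(names(coded_names()), coded_names())
}

#' Transform fabrication parameters to coded (non-dimensional) units
#'
#' Maps each fabrication parameter linearly onto \[0, 1\] over its
#' experimental range; hydrodynamic radius is coded on the *inverse* radius so
#' that diffusivity is approximately linear in the coded parameter
#' (Stokes-Einstein scaling). The largest radius codes to 0 and the smallest
#' to 1.
#'
#' @param data data frame with any of the columns `concentration_mg_ml`
#'   (4-10), `temperature_C` (23-37), `pH` (7.4-8.4),
#'   `hydrodynamic_radius_nm` (1.4-8.5).
#' @param override allow evaluation outside the experimental ranges
#'   (extrapolation). When `FALSE` (default) an out-of-range value is an
#'   error naming the offending parameter.
#'
#' @return The input tibble with coded columns `c_prime`, `t_prime`,
#'   `ph_prime`, `inv_rh_prime` appended (those whose source column exists).
#' @examples
#' nondimensionalize(data.frame(concentration_mg_ml = 6, temperature_C = 23))
#' @export
nondimensionalize <- function(data, override = FALSE) {
  data <- as_tibble(data)
  rngs <- param_ranges()
  cn <- coded_names()
  tol <- 1e-8
  for (nat in intersect(names(cn), names(data))) {
    x <- data[[nat]]
    coded <- if (nat == "hydrodynamic_radius_nm") {
      (1 / x - 1 / rngs[[nat]][2]) / (1 / rngs[[nat]][1] - 1 / rngs[[nat]][2])
    } else {
      (x - rngs[[nat]][1]) / diff(rngs[[nat]])
    }
    bad <- which(is.finite(coded) & (coded < -tol | coded > 1 + tol))
    if (length(bad) && !override)
      stopf(paste0("`%s` = %g is outside the experimental range [%g, %g]; ",
                   "set `override = TRUE` to extrapolate"),
            nat, x[bad[1]], rngs[[nat]][1], rngs[[nat]][2])
    data[[cn[[nat]]]] <- coded
  }
  data
}

#' Invert coded units back to natural fabrication parameters
#'
#' @param data data frame with any of the coded columns `c_prime`, `t_prime`,
#'   `ph_prime`, `inv_rh_prime`.
#' @return The input tibble with natural-unit columns appended.
#' @export
decode_condition <- function(data) {
  data <- as_tibble(data)
  rngs <- param_ranges()
  nn <- natural_names()
  for (cod in intersect(names(nn), names(data))) {
    nat <- nn[[cod]]
    z <- data[[cod]]
    data[[nat]] <- if (nat == "hydrodynamic_radius_nm") {
      1 / (z * (1 / rngs[[nat]][1] - 1 / rngs[[nat]][2]) + 1 / rngs[[nat]][2])
    } else {
      rngs[[nat]][1] + z * diff(rngs[[nat]])
    }
  }
  data
}

new_hydrogel_model <- function(property, units, coefficients, terms, factors,
                               r_squared = NA_real_, fit = NULL,
                               fit_full = NULL, p_values = NULL,
                               source = "fitted", notes = NULL) {
  structure(
    list(property = property, units = units, coefficients = coefficients,
         terms = terms, factors = factors, r_squared = r_squared, fit = fit,
         fit_full = fit_full, p_values = p_values, source = source,
         notes = notes),
    class = "hydrogel_model"
  )
}

model_factors <- function(model) model$factors

#' @export
print.hydrogel_model <- function(x, ...) {
  cat(sprintf("<hydrogel_model> %s [%s] (%s)\n", x$property, x$units, x$source))
  co <- x$coefficients
  cat("  ", paste(sprintf("%s = %.4g", names(co), co), collapse = ", "), "\n")
  if (is.finite(x$r_squared)) cat(sprintf("  R^2 = %.3f\n", x$r_squared))
  invisible(x)
}

# evaluate the coded-unit design matrix for a term vector like
# c("c_prime", "c_prime:t_prime")
coded_model_matrix <- function(terms, coded) {
  cols <- map(terms, function(tm) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
    Reduce(`*`, map(parts, ~ coded[[.x]]))
  })
  mat <- do.call(cbind, c(list(rep(1, nrow(coded))), cols))
  colnames(mat) <- c("(Intercept)", terms)
  mat
}

#' Predict hydrogel properties at fabrication conditions
#'
#' Evaluates a fitted or packaged empirical model at fabrication conditions
#' given in natural units. Conditions are coded internally; evaluation
#' outside the experimental ranges requires `override = TRUE` and is flagged.
#'
#' @param object a `hydrogel_model`.
#' @param newdata data frame of fabrication conditions in natural units.
#' @param interval `"none"`, `"prediction"` or `"confidence"`; intervals are
#'   available only for models fitted from data (not the packaged published
#'   coefficients, which carry no residual information).
#' @param level interval coverage (default 0.95).
#' @param override allow extrapolation outside the experimental domain.
#' @param ... unused.
#'
#' @return A tibble with `.pred` (and `.lower`/`.upper` when an interval is
#'   requested) plus `.extrapolated`.
#' @examples
#' mods <- published_models()
#' predict(mods$modulus_Pa,
#'         data.frame(concentration_mg_ml = 4, temperature_C = 23, pH = 7.4))
#' @export
predict.hydrogel_model <- function(object, newdata, interval = "none",
                                   level = 0.95, override = FALSE, ...) {
  interval <- match.arg(interval, c("none", "prediction", "confidence"))
  newdata <- as_tibble(newdata)
  missing <- setdiff(object$factors, names(newdata))
  if (length(missing))
    stopf("`newdata` is missing fabrication column(s): %s",
          paste(missing, collapse = ", "))
  coded <- nondimensionalize(newdata, override = override)
  cn <- coded_names()[object$factors]
  extrap <- rep(FALSE, nrow(coded))
  for (cc in cn) extrap <- extrap | coded[[cc]] < -1e-8 | coded[[cc]] > 1 + 1e-8
  X <- coded_model_matrix(object$terms, coded)
  pred <- drop(X %*% object$coefficients[colnames(X)])
  out <- tibble(.pred = pred, .extrapolated = extrap)
  if (interval != "none") {
    if (is.null(object$fit))
      stopf("interval = \"%s\" requires a model fitted from data", interval)
    pr <- predict(object$fit, newdata = coded, interval = interval, level = level)
    out$.lower <- pr[, "lwr"]
    out$.upper <- pr[, "upr"]
  }
  out
}

#' Fit an empirical fabrication-property regression model
#'
#' Two-pass coded-unit multivariate least squares, mirroring the screening
#' procedure used for the published models: pass 1 fits all main effects plus
#' all pairwise interactions on coded units; pass 2 refits retaining main
#' effects significant at `primary_alpha` and interactions significant at
#' `interaction_alpha`, preserving hierarchy (a main effect participating in
#' a retained interaction is kept regardless of its own p-value).
#'
#' On noiseless (zero-residual) input, terms with exactly-zero coefficients
#' are treated as non-significant and all others as significant, so the
#' generating equation structure is recovered identically.
#'
#' @param data long property table with fabrication columns, `property` and
#'   `value` (see [sim_property_table()]).
#' @param property which property to fit (a value of `data$property`).
#' @param primary_alpha significance threshold for main effects (default 0.05).
#' @param interaction_alpha significance threshold for pairwise interactions
#'   (default 0.01).
#' @param units property units label (defaults to the property name's
#'   conventional units when recognized).
#'
#' @return A `hydrogel_model` with coefficients, retained terms, pass-1
#'   p-values, fit R^2, and the underlying `lm` fits (`fit` = pass 2,
#'   `fit_full` = pass 1).
#' @examples
#' tab <- sim_property_table(noise_sd = c(modulus_Pa = 0), reps = 1,
#'                           models = published_models()["modulus_Pa"])
#' fit_property_model(tab, "modulus_Pa")
#' @export
fit_property_model <- function(data, property,
                               primary_alpha = 0.05,
                               interaction_alpha = 0.01,
                               units = NULL) {
  data <- as_tibble(data)
  if (!all(c("property", "value") %in% names(data)))
    stopf("`data` must have `property` and `value` columns")
  rows <- data[data$property == property, , drop = FALSE]
  if (!nrow(rows)) stopf("no rows for property `%s`", property)

  facs <- intersect(names(param_ranges()), names(rows))
  facs <- facs[vapply(facs, function(f) {
    v <- rows[[f]]
    sum(!is.na(v)) > 0 && length(unique(v[!is.na(v)])) >= 2
  }, logical(1))]
  if (!length(facs)) stopf("no fabrication factor with >= 2 levels found")

  coded <- nondimensionalize(rows[c(facs, "value")])
  cn <- unname(coded_names()[facs])
  form <- stats::as.formula(paste(
    "value ~ (", paste(cn, collapse = " + "), ")^2"))
  fit1 <- lm(form, data = coded)
  if (anyNA(coef(fit1)))
    stopf("rank-deficient design; aliased terms: %s",
          paste(names(coef(fit1))[is.na(coef(fit1))], collapse = ", "))

  smry <- suppressWarnings(summary(fit1))  # zero-residual fits warn harmlessly
  est <- coef(fit1)
  scale <- max(abs(est), 1e-12)
  if (smry$sigma < 1e-8 * scale) {
    # noiseless (saturated-variance) input: zero coefficients are noise-free
    # zeros, everything else is exact signal
    pvals <- ifelse(abs(est) > 1e-8 * scale, 0, 1)
  } else {
    pvals <- smry$coefficients[, "Pr(>|t|)"]
  }
  term_names <- names(est)[-1]
  p_terms <- pvals[-1]
  is_int <- grepl(":", term_names, fixed = TRUE)
  keep <- (is_int & p_terms < interaction_alpha) |
          (!is_int & p_terms < primary_alpha)
  # hierarchy: mains of retained interactions stay in
  for (tm in term_names[is_int & keep])
    keep[term_names %in% strsplit(tm, ":", fixed = TRUE)[[1]]] <- TRUE
  retained <- term_names[keep]

  form2 <- if (length(retained)) {
    stats::as.formula(paste("value ~", paste(retained, collapse = " + ")))
  } else stats::as.formula("value ~ 1")
  fit2 <- lm(form2, data = coded)
  r2_pass2 <- suppressWarnings(summary(fit2))$r.squared

  default_units <- c(t_half_min = "min", modulus_Pa = "Pa",
                     pore_diameter_um = "um", diffusivity_um2_s = "um^2/s")
  new_hydrogel_model(
    property = property,
    units = units %||% default_units[[property]] %||% "",
    coefficients = coef(fit2),
    terms = retained,
    factors = facs,
    r_squared = r2_pass2,
    fit = fit2,
    fit_full = fit1,
    p_values = tibble(term = names(est), estimate_pass1 = unname(est),
                      p_value_pass1 = unname(pvals),
                      retained = names(est) %in% c("(Intercept)", retained)),
    source = "fitted"
  )
}

#' Packaged published fabrication-property models
#'
#' Returns the four empirical coded-unit regression models for polymerization
#' half-time (min), compression modulus (Pa), mean pore diameter (um) and
#' dextran diffusivity (um^2/s), with the published coefficients, usable for
#' prediction, sensitivity analysis and inverse design without refitting.
#'
#' The diffusivity model's pH x inverse-radius interaction coefficient is
#' typographically ambiguous in its source (the printed value matches the
#' *normalized* sensitivity entry); both readings are packaged and selectable:
#' `"as_printed"` (0.37, default) or `"rescaled"` (0.37 x 190.23, consistent
#' with the normalized sensitivity table).
#'
#' @param interaction which reading of the diffusivity interaction
#'   coefficient to use.
#' @return Named list of `hydrogel_model` objects.
#' @examples
#' mods <- published_models()
#' predict(mods$t_half_min, data.frame(concentration_mg_ml = 4, temperature_C = 23))
#' @export
published_models <- function(interaction = c("as_printed", "rescaled")) {
  interaction <- match.arg(interaction)
  path <- system.file("extdata", "published_models.json", package = "gelchar",
                      mustWork = TRUE)
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  nn <- natural_names()
  out <- imap(spec$models, function(m, prop) {
    co <- unlist(m$coefficients)
    if (prop == "diffusivity_um2_s") {
      co[["ph_prime:inv_rh_prime"]] <- unlist(m$interaction_readings)[[interaction]]
    }
    terms <- setdiff(names(co), "(Intercept)")
    mains <- unique(unlist(strsplit(terms, ":", fixed = TRUE)))
    new_hydrogel_model(
      property = prop, units = m$units, coefficients = co, terms = terms,
      factors = unname(nn[mains]), r_squared = m$r_squared,
      source = "published", notes = m$notes
    )
  })
  out
}

#' Normalized sensitivity of properties to fabrication parameters
#'
#' Divides each model coefficient by the largest-magnitude non-intercept
#' coefficient of that property's model, yielding dimensionless sensitivities
#' in \[-1, 1\] whose largest entry is exactly +/-1. Coefficients are already
#' on comparable (coded) scales, so this ranks the leverage each fabrication
#' parameter has over each property.
#'
#' @param models a single `hydrogel_model` or a (named) list of them.
#' @return A tibble with `property`, `term`, `coefficient`, `sensitivity`.
#' @examples
#' sensitivity(published_models())
#' @export
sensitivity <- function(models) {
  if (inherits(models, "hydrogel_model")) models <- list(models)
  rows <- map(models, function(m) {
    co <- m$coefficients[m$terms]
    if (!length(co))
      return(tibble(property = m$property, term = character(),
                    coefficient = numeric(), sensitivity = numeric()))
    tibble(property = m$property, term = names(co), coefficient = unname(co),
           sensitivity = unname(co) / max(abs(co)))
  })
  bind_rows(rows)
}

#' @describeIn fit_property_model broom-style coefficient table: one row per
#'   retained term, with the pass-1 p-value where available.
#' @param x a `hydrogel_model`.
#' @export
tidy.hydrogel_model <- function(x, ...) {
  out <- tibble(term = names(x$coefficients),
                estimate = unname(x$coefficients))
  if (!is.null(x$fit)) {
    s <- summary(x$fit)$coefficients
    out$std.error <- s[out$term, "Std. Error"]
    out$p.value <- s[out$term, "Pr(>|t|)"]
  }
  out
}

#' @describeIn fit_property_model broom-style one-row model summary.
#' @export
glance.hydrogel_model <- function(x, ...) {
  tibble(property = x$property, units = x$units, r.squared = x$r_squared,
         n_terms = length(x$terms),
         nobs = if (!is.null(x$fit)) length(resid(x$fit)) else NA_integer_,
         source = x$source)
}
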