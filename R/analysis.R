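#' Descriptive quartiles of slider responses
#'
#' Median, first and third quartile of each slider per (category, polarity)
#' cell. Medians are the preferred central tendency because slider responses
#' are bounded, integer-valued and usually skewed. Quartiles use the
#' linear-interpolation definition (R type 7).
#'
#' @param records A response tibble (see [generate_dataset()]).
#' @return A tibble with columns `category`, `polarity`, `component`
#'   (horizontal/vertical/velocity), `q1`, `median`, `q3`.
#' @export
descriptives <- function(records) {
  if (nrow(records) == 0) abort("no response records")
  records |>
    mutate(polarity = ifelse(.data$polarity == 1, "high", "low")) |>
    pivot_longer(c("s_h", "s_v", "s_vel"),
                 names_to = "component", values_to = "value") |>
    mutate(component = dplyr::recode(.data$component,
      s_h = "horizontal", s_v = "vertical", s_vel = "velocity"
    )) |>
    group_by(.data$category, .data$polarity, .data$component) |>
    summarise(
      q1 = quantile(.data$value, 0.25, type = 7, names = FALSE),
      median = median(.data$value),
      q3 = quantile(.data$value, 0.75, type = 7, names = FALSE),
      .groups = "drop"
    )
}

slider_terms <- function() c("s_h", "s_v", "s_vel")

# filter records to one category, check both polarities present
category_records <- function(records, category, call = rlang::caller_env()) {
  d <- records[records$category == category, ]
  if (nrow(d) == 0) abort(sprintf("no records for category '%s'", category), call = call)
  if (length(unique(d$polarity)) < 2) {
    abort(sprintf("category '%s' needs both high and low records", category), call = call)
  }
  d
}

#' Fit a logistic regression of item polarity on slider values
#'
#' Maximum-likelihood logistic regression of the high/low item coding
#' (high = 1) on one or more slider predictors, with intercept. Confidence
#' intervals are profile-likelihood based (falling back to Wald with a
#' warning if profiling fails); p-values are two-sided Wald tests. Complete
#' or quasi-complete separation raises an explicit error rather than
#' returning a silently diverged fit.
#'
#' @param records A response tibble.
#' @param category Category to analyse.
#' @param predictors Subset of `c("s_h", "s_v", "s_vel")` (default all three).
#' @return A `km_logit` object; see [tidy.km_logit()] and [glance.km_logit()].
#' @export
#' @examples
#' rec <- generate_dataset(10, response_profile("stick"), "stick", seed = 1)
#' fit <- fit_logistic(rec, "dominant", "s_v")
#' tidy(fit)
fit_logistic <- function(records, category, predictors = slider_terms()) {
  stopifnot(all(predictors %in% slider_terms()), length(predictors) >= 1)
  d <- category_records(records, category)
  for (p in predictors) {
    if (length(unique(d[[p]])) < 2) {
      abort(sprintf("predictor '%s' is constant for category '%s'", p, category))
    }
  }
  fml <- stats::as.formula(paste("polarity ~", paste(predictors, collapse = " + ")))
  sep_warned <- FALSE
  fit <- withCallingHandlers(
    glm(fml, family = binomial(), data = d),
    warning = function(w) {
      msg <- conditionMessage(w)
      if (grepl("fitted probabilities numerically 0 or 1", msg)) {
        sep_warned <<- TRUE
        invokeRestart("muffleWarning")
      } else if (grepl("algorithm did not converge", msg)) {
        # convergence is checked explicitly below
        invokeRestart("muffleWarning")
      }
    }
  )
  if (anyNA(coef(fit))) {
    abort(sprintf("predictors are collinear for category '%s' (rank deficient fit)", category))
  }
  big <- max(abs(coef(fit)[-1]))
  # complete separation: the fitted linear predictor orders the groups with a
  # gap and the deviance collapses to zero
  eta <- stats::predict(fit)
  complete <- min(eta[fit$y == 1]) > max(eta[fit$y == 0]) &&
    fit$deviance < 1e-5 * length(eta)
  if (complete || (sep_warned && big > 8) || !fit$converged || big > 50) {
    abort(paste0(
      "complete or quasi-complete separation detected for category '", category,
      "': the high/low groups are perfectly distinguished by the predictors, ",
      "so maximum-likelihood estimates diverge"
    ))
  }
  cf <- summary(fit)$coefficients
  ci <- tryCatch(
    suppressWarnings(suppressMessages(confint(fit, level = 0.95))),
    error = function(e) NULL
  )
  ci_method <- "profile"
  if (is.null(ci) || anyNA(ci)) {
    warn("profile-likelihood confidence intervals failed; using Wald intervals")
    ci <- cbind(cf[, 1] - 1.96 * cf[, 2], cf[, 1] + 1.96 * cf[, 2])
    ci_method <- "wald"
  }
  if (length(predictors) == 1 && is.null(dim(ci))) ci <- matrix(ci, nrow = 1) # never: ci is matrix
  structure(
    list(
      fit = fit,
      coefficients = tibble(
        term = rownames(cf),
        estimate = unname(cf[, 1]),
        std_error = unname(cf[, 2]),
        ci_low = unname(ci[, 1]),
        ci_high = unname(ci[, 2]),
        p_value = unname(cf[, 4])
      ),
      category = category,
      predictors = predictors,
      ci_method = ci_method,
      n = nrow(d)
    ),
    class = "km_logit"
  )
}

#' @export
print.km_logit <- function(x, ...) {
  cat(sprintf("Logistic fit: polarity ~ %s (category '%s', n = %d)\n",
              paste(x$predictors, collapse = " + "), x$category, x$n))
  print(x$coefficients)
  invisible(x)
}

#' Relative importance weights for a (possibly logistic) regression
#'
#' Decomposes a model's explained variance into nonnegative per-predictor
#' contributions that are unaffected by multicollinearity. The predictor
#' matrix is standardized and replaced by its closest orthogonal counterpart
#' via the singular value decomposition \eqn{X = P \Delta Q^T}: the
#' orthogonal surrogate is \eqn{Z \propto P Q^T} and the loadings
#' \eqn{\Lambda = Q \Delta Q^T / \sqrt{n-1}} (the symmetric square root of
#' the predictor correlation matrix). The outcome is regressed on Z (ordinary
#' least squares for a numeric outcome, logistic for a binary one), the
#' surrogate coefficients are standardized, and predictor j's weight is
#' \deqn{\epsilon_j = \sum_k \lambda_{jk}^2 \beta_k^{*2}.}
#' For a linear model the weights sum to the OLS \eqn{R^2} exactly; for a
#' logistic model they are rescaled so their sum equals a pseudo-R-squared
#' analog (by default the squared Pearson correlation between the outcome and
#' the fitted probabilities; alternatively McFadden's).
#'
#' @param x Numeric predictor matrix or data frame (n rows, p >= 2 columns,
#'   full column rank, no constant column).
#' @param y Outcome: numeric, or binary 0/1 for the logistic route.
#' @param family `"gaussian"` or `"binomial"`.
#' @param r2_type Rescaling total for the logistic route: `"cor_squared"`
#'   (default) or `"mcfadden"`.
#' @return A `km_relweights` object: tibble of weights plus the total.
#' @export
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
#' y <- x %*% c(1, 0.5, 0) + rnorm(100)
#' johnson_weights(x, y)
johnson_weights <- function(x, y, family = c("gaussian", "binomial"),
                            r2_type = c("cor_squared", "mcfadden")) {
  family <- match.arg(family)
  r2_type <- match.arg(r2_type)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  terms <- colnames(x) %||% paste0("x", seq_len(ncol(x)))
  n <- nrow(x)
  p <- ncol(x)
  if (n <= p + 1) abort("too few observations for a relative-weights decomposition")
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    abort(paste0("zero-variance predictor(s): ", paste(terms[sds == 0], collapse = ", ")))
  }
  xs <- scale(x)
  sv <- svd(xs)
  if (min(sv$d) / max(sv$d) < 1e-9) abort("predictor matrix is rank deficient")

  z <- sqrt(n - 1) * sv$u %*% t(sv$v) # orthogonal surrogate, unit variance
  lambda <- sv$v %*% (sv$d * t(sv$v)) / sqrt(n - 1) # cor(x_j, z_k)

  if (family == "gaussian") {
    ys <- as.numeric(scale(as.numeric(y)))
    bstar <- crossprod(z, ys) / (n - 1)
    eps <- as.numeric(lambda^2 %*% bstar^2)
    rsq <- sum(bstar^2)
    r2_type <- "ols"
  } else {
    yb <- as.numeric(y)
    if (!all(yb %in% c(0, 1))) abort("binomial outcome must be coded 0/1")
    fit <- suppressWarnings(glm(yb ~ z, family = binomial()))
    b <- coef(fit)[-1]
    eps_raw <- as.numeric(lambda^2 %*% b^2)
    rsq <- if (r2_type == "cor_squared") {
      cor(yb, stats::fitted(fit))^2
    } else {
      ll1 <- as.numeric(stats::logLik(fit))
      ll0 <- as.numeric(stats::logLik(glm(yb ~ 1, family = binomial())))
      1 - ll1 / ll0
    }
    eps <- if (sum(eps_raw) > 0) eps_raw * rsq / sum(eps_raw) else eps_raw
  }
  structure(
    list(
      weights = tibble(term = terms, weight = eps),
      rsq = rsq,
      r2_type = r2_type,
      family = family,
      n = n
    ),
    class = "km_relweights"
  )
}

#' Relative weights of the three motion sliders for one category
#'
#' Convenience wrapper around [johnson_weights()] for a response table:
#' logistic decomposition of the high/low polarity on horizontal amplitude,
#' vertical amplitude and velocity.
#'
#' @inheritParams fit_logistic
#' @param r2_type Pseudo-R-squared analog; see [johnson_weights()].
#' @return A `km_relweights` object with the category recorded.
#' @export
relative_weights <- function(records, category, r2_type = c("cor_squared", "mcfadden")) {
  d <- category_records(records, category)
  res <- johnson_weights(
    as.matrix(d[, slider_terms()]), d$polarity,
    family = "binomial", r2_type = match.arg(r2_type)
  )
  res$category <- category
  res
}

#' @export
print.km_relweights <- function(x, ...) {
  cat(sprintf(
    "Relative weights%s (%s, total = %.4f [%s])\n",
    if (!is.null(x$category)) paste0(" for '", x$category, "'") else "",
    x$family, x$rsq, x$r2_type
  ))
  print(x$weights)
  invisible(x)
}

#' Pearson correlations among the slider predictors
#'
#' Multicollinearity diagnostic: the correlation matrix of the three sliders
#' over one category's records (or all records).
#'
#' @inheritParams fit_logistic
#' @return A 3x3 symmetric correlation matrix with unit diagonal.
#'   Zero-variance predictors give `NA` entries with a warning.
#' @export
predictor_correlations <- function(records, category = NULL) {
  d <- if (is.null(category)) records else category_records(records, category)
  if (nrow(d) == 0) abort("no records")
  x <- as.matrix(d[, slider_terms()])
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    warn(paste0(
      "zero-variance predictor(s) give undefined correlations: ",
      paste(slider_terms()[sds == 0], collapse = ", ")
    ))
  }
  suppressWarnings(cor(x))
}

#' Bonferroni correction for a fixed test family
#'
#' Flags p-values against a Bonferroni-adjusted alpha of `0.05 / m`. For one
#' reverse-rating experiment the family size is 30: 5 categories x 3
#' predictors x 2 model families (multi- and single-predictor).
#'
#' @param pvalues Numeric vector of p-values.
#' @param m Family size (must be at least `length(pvalues)`).
#' @param alpha Family-wise error rate (default 0.05).
#' @return A tibble with columns `p_value`, `alpha_adjusted`, `significant`.
#' @export
#' @examples
#' bonferroni_family(c(0.001, 0.01), m = 30)
bonferroni_family <- function(pvalues, m = 30, alpha = 0.05) {
  if (!is.numeric(m) || m <= 0) abort("family size m must be positive")
  if (m < length(pvalues)) {
    abort(sprintf("family size m = %s is smaller than the %d p-values considered jointly",
                  m, length(pvalues)))
  }
  tibble(
    p_value = pvalues,
    alpha_adjusted = alpha / m,
    significant = pvalues < alpha / m
  )
}

#' Confidence-interval overlap verdict
#'
#' Interval-arithmetic reading of two 95% confidence intervals following the
#' Cumming & Finch guideline: intervals that are disjoint or touch in a
#' single point indicate a difference at roughly p < .01; overlapping
#' intervals support no claim. Symmetric in its arguments.
#'
#' @param ci_a,ci_b Numeric length-2 intervals `c(lower, upper)`.
#' @return One-row tibble with `relation` (`"disjoint_or_touching"` or
#'   `"overlapping"`) and a human-readable `interpretation`.
#' @export
#' @examples
#' ci_overlap(c(1, 2), c(2, 4))
ci_overlap <- function(ci_a, ci_b) {
  chk <- function(ci, nm) {
    if (length(ci) != 2 || anyNA(ci)) abort(paste0(nm, " must be a length-2 interval"))
    if (ci[1] > ci[2]) abort(paste0(nm, " is inverted: lower bound exceeds upper bound"))
  }
  chk(ci_a, "ci_a")
  chk(ci_b, "ci_b")
  apart <- ci_a[2] <= ci_b[1] || ci_b[2] <= ci_a[1]
  if (apart) {
    tibble(
      relation = "disjoint_or_touching",
      interpretation = "difference, p < .01 equivalent (Cumming & Finch guideline)"
    )
  } else {
    tibble(relation = "overlapping", interpretation = "overlapping - no claim")
  }
}

#' Build the full report for one experiment
#'
#' Runs the complete analysis over a response table: descriptive quartiles,
#' one multi-predictor logistic model per category with relative weights and
#' the pseudo-R-squared total, and single-predictor models for each slider.
#' Significance flags use a Bonferroni family of `family_m` tests across both
#' model families.
#'
#' @param records A response tibble.
#' @param experiment Optional filter: `"stick"` or `"dot"`.
#' @param family_m Bonferroni family size (default 30).
#' @param r2_type Pseudo-R-squared analog; see [johnson_weights()].
#' @return A `km_report`: list with tibbles `descriptives`, `multi`
#'   (term-level estimates, SEs, CIs, p-values, weights and the shared
#'   `r_squared` per category) and `single`.
#' @export
build_report <- function(records, experiment = NULL, family_m = 30,
                         r2_type = c("cor_squared", "mcfadden")) {
  r2_type <- match.arg(r2_type)
  if (!is.null(experiment)) records <- records[records$experiment == experiment, ]
  if (nrow(records) == 0) abort("no records to analyse")
  cats <- unique(records$category)

  one_cat <- function(cat) {
    multi <- fit_logistic(records, cat, slider_terms())
    rw <- relative_weights(records, cat, r2_type = r2_type)
    multi_tbl <- multi$coefficients |>
      filter(.data$term != "(Intercept)") |>
      left_join(rw$weights, by = "term") |>
      mutate(category = cat, r_squared = rw$rsq, n = multi$n)
    single_tbl <- purrr::map(slider_terms(), function(p) {
      f <- fit_logistic(records, cat, p)
      f$coefficients |>
        filter(.data$term != "(Intercept)") |>
        mutate(category = cat, n = f$n)
    }) |> list_rbind()
    list(multi = multi_tbl, single = single_tbl)
  }

  parts <- purrr::map(cats, function(cat) {
    tryCatch(one_cat(cat), error = function(e) {
      warn(paste0("category '", cat, "' omitted from the report: ", conditionMessage(e)))
      NULL
    })
  })
  parts <- purrr::compact(parts)
  if (length(parts) == 0) abort("no category could be analysed")
  multi <- list_rbind(purrr::map(parts, "multi"))
  single <- list_rbind(purrr::map(parts, "single"))
  alpha_adj <- 0.05 / family_m
  multi$significant <- multi$p_value < alpha_adj
  single$significant <- single$p_value < alpha_adj

  structure(
    list(
      descriptives = descriptives(records),
      multi = select(multi, "category", "term", "estimate", "std_error",
                     "ci_low", "ci_high", "p_value", "significant",
                     "weight", "r_squared", "n"),
      single = select(single, "category", "term", "estimate", "std_error",
                      "ci_low", "ci_high", "p_value", "significant", "n")
    ),
    experiment = experiment %||% "all",
    family_m = family_m,
    alpha_adjusted = alpha_adj,
    r2_type = r2_type,
    class = "km_report"
  )
}

#' @export
print.km_report <- function(x, ...) {
  cat(sprintf(
    "Reverse-rating report (%s experiment; Bonferroni family m = %d, alpha = %.5f)\n\n",
    attr(x, "experiment"), attr(x, "family_m"), attr(x, "alpha_adjusted")
  ))
  cat("Descriptives (median [Q1; Q3] per slider):\n")
  print(format_descriptives(x$descriptives), n = Inf)
  cat("\nMulti-predictor logistic models (estimate (SE) [CI], relative weight, R^2):\n")
  print(format_regression(x$multi, weights = TRUE), n = Inf)
  cat("\nSingle-predictor logistic models:\n")
  print(format_regression(x$single, weights = FALSE), n = Inf)
  invisible(x)
}

format_descriptives <- function(d) {
  d |>
    mutate(cell = sprintf("%g (%g;%g)", .data$median, .data$q1, .data$q3)) |>
    select("category", "polarity", "component", "cell") |>
    pivot_wider(names_from = "component", values_from = "cell")
}

format_regression <- function(tbl, weights = FALSE) {
  out <- tbl |>
    mutate(cell = sprintf(
      "%.2f%s (%.2f) [%.2f, %.2f]",
      .data$estimate, ifelse(.data$significant, "*", ""),
      .data$std_error, .data$ci_low, .data$ci_high
    ))
  if (weights) {
    out <- mutate(out, cell = sprintf("%s w=%.2f", .data$cell, .data$weight))
  }
  out <- out |>
    select("category", "term", "cell") |>
    pivot_wider(names_from = "term", values_from = "cell")
  if (weights) {
    out <- left_join(out, distinct(tbl, .data$category, .data$r_squared), by = "category")
  }
  out
}

#' Write a report to disk
#'
#' Writes the machine-readable report as JSON and the formatted tables as a
#' text file.
#'
#' @param report A `km_report` from [build_report()].
#' @param dir Output directory (created if needed).
#' @param stem File stem (default `"report"`).
#' @return Named character vector of the two file paths, invisibly.
#' @export
write_report <- function(report, dir, stem = "report") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  json_path <- file.path(dir, paste0(stem, ".json"))
  txt_path <- file.path(dir, paste0(stem, ".txt"))
  jsonlite::write_json(
    list(
      experiment = attr(report, "experiment"),
      family_m = attr(report, "family_m"),
      alpha_adjusted = attr(report, "alpha_adjusted"),
      r2_type = attr(report, "r2_type"),
      descriptives = report$descriptives,
      multi = report$multi,
      single = report$single
    ),
    json_path, auto_unbox = TRUE, digits = NA
  )
  sink(txt_path)
  on.exit(sink(), add = TRUE)
  print(report)
  invisible(c(json = json_path, text = txt_path))
}
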