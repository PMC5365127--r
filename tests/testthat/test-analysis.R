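# small deterministic response table builder: explicit slider values per
# polarity, one row per participant per polarity for one category
fake_records <- function(high, low, category = "dominant", experiment = "stick") {
  n <- nrow(high)
  dplyr::bind_rows(
    tibble::tibble(participant_id = seq_len(n), category = category, polarity = 1L,
                   s_h = high$s_h, s_v = high$s_v, s_vel = high$s_vel,
                   experiment = experiment),
    tibble::tibble(participant_id = seq_len(nrow(low)), category = category,
                   polarity = 0L, s_h = low$s_h, s_v = low$s_v, s_vel = low$s_vel,
                   experiment = experiment)
  )
}

test_that("descriptives report type-7 quartiles per cell", {
  rec <- fake_records(
    high = tibble::tibble(s_h = c(1, 2, 3), s_v = c(0, 10, 5), s_vel = c(4, 4, 4)),
    low = tibble::tibble(s_h = c(0, 10), s_v = c(2, 2), s_vel = c(1, 3))
  )
  d <- descriptives(rec)
  g <- function(pol, comp) d[d$polarity == pol & d$component == comp, ]
  expect_equal(g("high", "horizontal")$median, 2) # odd count
  expect_equal(g("low", "horizontal")$median, 5) # {0,10} -> midpoint
  r <- g("high", "velocity")
  expect_equal(c(r$q1, r$median, r$q3), c(4, 4, 4)) # constant group
  expect_true(all(d$q1 <= d$median & d$median <= d$q3))
  expect_error(descriptives(rec[0, ]), "no response records")
})

test_that("logistic fits recover symmetry, consistency and refuse separation", {
  # identical predictor values in both polarity groups: slope exactly zero
  vals <- tibble::tibble(s_h = c(1, 4, 6, 9), s_v = c(2, 3, 7, 8), s_vel = c(0, 5, 6, 10))
  rec <- fake_records(vals, vals)
  fit <- fit_logistic(rec, "dominant", c("s_h", "s_v", "s_vel"))
  expect_lt(max(abs(tidy(fit)$estimate)), 1e-8)

  # Monte-Carlo consistency: known log-odds slope 0.5 at n = 10,000
  withr::with_seed(5, {
    x <- round(runif(10000, 0, 10))
    y <- rbinom(10000, 1, plogis(-2.5 + 0.5 * x))
    big <- tibble::tibble(participant_id = 1:10000, category = "dominant",
                          polarity = y, s_h = x, s_v = 0L, s_vel = 0L,
                          experiment = "stick")
    f <- fit_logistic(big, "dominant", "s_h")
    expect_equal(tidy(f)$estimate[2], 0.5, tolerance = 0.05)
  })

  # complete separation is an explicit error, not a silent divergence
  sep <- fake_records(
    high = tibble::tibble(s_h = c(8, 9, 10, 8, 9, 10), s_v = c(10, 8, 9, 9, 10, 8),
                          s_vel = c(9, 10, 8, 10, 8, 9)),
    low = tibble::tibble(s_h = c(0, 1, 2, 0, 1, 2), s_v = c(2, 0, 1, 1, 2, 0),
                         s_vel = c(1, 2, 0, 2, 0, 1))
  )
  expect_error(fit_logistic(sep, "dominant"), "separation")

  # constant predictor is a rank error
  const <- fake_records(
    high = tibble::tibble(s_h = c(3, 5), s_v = c(5, 5), s_vel = c(2, 8)),
    low = tibble::tibble(s_h = c(1, 2), s_v = c(5, 5), s_vel = c(1, 4))
  )
  expect_error(fit_logistic(const, "dominant", "s_v"), "constant")
})

test_that("profile-likelihood intervals bracket the estimate and feed tidy()", {
  rec <- generate_dataset(20, response_profile("stick"), "stick", seed = 13)
  fit <- fit_logistic(rec, "dominant")
  td <- tidy(fit)
  expect_true(all(td$ci_low < td$estimate & td$estimate < td$ci_high))
  expect_equal(fit$ci_method, "profile")
  gl <- glance(fit)
  expect_equal(gl$n, 40)
  expect_true(gl$pseudo_r_squared >= 0 && gl$pseudo_r_squared <= 1)
})

test_that("relative weights sum to R-squared exactly in the linear case", {
  withr::with_seed(17, {
    for (i in 1:100) {
      n <- sample(30:80, 1)
      p <- sample(2:5, 1)
      x <- matrix(rnorm(n * p), n, p) %*%
        chol(0.5 * diag(p) + 0.5) # correlated predictors
      colnames(x) <- paste0("v", seq_len(p))
      y <- x %*% rnorm(p) + rnorm(n)
      rw <- johnson_weights(x, y, family = "gaussian")
      r2 <- summary(lm(y ~ x))$r.squared
      expect_true(all(rw$weights$weight >= -1e-12))
      expect_equal(rw$rsq, r2, tolerance = 1e-10)
      expect_equal(sum(rw$weights$weight), r2, tolerance = 1e-10)
    }
  })
})

test_that("orthogonal predictors give squared zero-order correlations as weights", {
  withr::with_seed(19, {
    # build exactly orthogonal standardized predictors from a QR basis
    n <- 60
    q <- qr.Q(qr(cbind(1, matrix(rnorm(n * 3), n, 3))))[, 2:4]
    x <- scale(q) # orthogonal, mean 0, sd 1
    colnames(x) <- c("a", "b", "c")
    y <- rnorm(n)
    rw <- johnson_weights(x, y, family = "gaussian")
    r2y <- as.numeric(cor(x, y))^2
    expect_equal(rw$weights$weight, r2y, tolerance = 1e-10)
  })
})

test_that("relative weights are invariant to predictor order and detect rank problems", {
  rec <- generate_dataset(25, response_profile("stick"), "stick", seed = 23)
  d <- rec[rec$category == "dominant", ]
  x <- as.matrix(d[, c("s_h", "s_v", "s_vel")])
  rw1 <- johnson_weights(x, d$polarity, family = "binomial")
  rw2 <- johnson_weights(x[, c(3, 1, 2)], d$polarity, family = "binomial")
  expect_equal(
    rw1$weights$weight[match(rw2$weights$term, rw1$weights$term)],
    rw2$weights$weight,
    tolerance = 1e-9
  )
  # the weights sum to the pseudo-R-squared analog
  expect_equal(sum(rw1$weights$weight), rw1$rsq, tolerance = 1e-9)
  fit <- suppressWarnings(glm(d$polarity ~ x, binomial()))
  expect_equal(rw1$rsq, cor(d$polarity, fitted(fit))^2, tolerance = 1e-9)

  dup <- cbind(x, s_dup = x[, 1])
  expect_error(johnson_weights(dup, d$polarity, family = "binomial"), "rank deficient")
  flat <- x; flat[, 2] <- 5
  expect_error(johnson_weights(flat, d$polarity, family = "binomial"), "zero-variance")
})

test_that("predictor correlations are symmetric with unit diagonal", {
  rec <- generate_dataset(15, response_profile("stick"), "stick", seed = 29)
  m <- predictor_correlations(rec, "dominant")
  expect_equal(diag(m), c(s_h = 1, s_v = 1, s_vel = 1))
  expect_equal(m, t(m), tolerance = 1e-12)

  # independent sliders: near-zero off-diagonals at n = 10,000
  withr::with_seed(31, {
    big <- tibble::tibble(
      participant_id = 1:10000, category = "dominant",
      polarity = rep(0:1, 5000),
      s_h = sample(0:10, 10000, TRUE), s_v = sample(0:10, 10000, TRUE),
      s_vel = sample(0:10, 10000, TRUE), experiment = "stick"
    )
    m2 <- predictor_correlations(big)
    expect_lt(max(abs(m2[upper.tri(m2)])), 0.05)
  })

  flat <- rec
  flat$s_vel <- 5L
  expect_warning(predictor_correlations(flat, "dominant"), "zero-variance")
})

test_that("Bonferroni flags use alpha divided by the family size", {
  b <- bonferroni_family(c(0.001, 0.01), m = 30)
  expect_equal(b$alpha_adjusted, rep(0.05 / 30, 2), tolerance = 1e-12)
  expect_identical(b$significant, c(TRUE, FALSE))
  expect_error(bonferroni_family(0.01, m = 0), "positive")
  expect_error(bonferroni_family(rep(0.01, 31), m = 30), "smaller than")
})

test_that("interval overlap verdicts follow the touch-or-disjoint rule", {
  expect_equal(ci_overlap(c(1, 2), c(3, 4))$relation, "disjoint_or_touching")
  expect_match(ci_overlap(c(1, 2), c(3, 4))$interpretation, "p < .01", fixed = TRUE)
  expect_equal(ci_overlap(c(1, 3), c(2, 4))$relation, "overlapping")
  expect_equal(ci_overlap(c(1, 2), c(2, 4))$relation, "disjoint_or_touching") # touching
  expect_identical(ci_overlap(c(1, 2), c(3, 4)), ci_overlap(c(3, 4), c(1, 2))) # symmetric
  expect_error(ci_overlap(c(2, 1), c(3, 4)), "inverted")
})

test_that("reports carry all categories with matching weight totals", {
  rec <- generate_dataset(30, response_profile("stick"), "stick", seed = 37)
  rep_ <- suppressWarnings(build_report(rec, "stick"))
  cats <- unique(rep_$multi$category)
  expect_true(length(cats) >= 4) # occasionally a separable category is omitted
  expect_equal(nrow(rep_$multi), 3 * length(cats))
  expect_equal(nrow(rep_$single), 3 * length(cats))
  # the R-squared column equals the summed relative weights per category
  sums <- rep_$multi |> dplyr::group_by(category) |>
    dplyr::summarise(s = sum(weight), r2 = dplyr::first(r_squared))
  expect_equal(sums$s, sums$r2, tolerance = 1e-9)
  expect_true(all(c("ci_low", "ci_high") %in% names(rep_$multi)))
  expect_true(all(c("ci_low", "ci_high") %in% names(rep_$single)))
  expect_equal(attr(rep_, "alpha_adjusted"), 0.05 / 30)

  withr::with_tempdir({
    paths <- write_report(rep_, "out")
    expect_true(file.exists(paths["json"]))
    expect_true(file.exists(paths["text"]))
    js <- jsonlite::fromJSON(paths["json"])
    expect_equal(js$family_m, 30)
  })
})
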