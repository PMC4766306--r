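test_that("Pearson correlation matches the direct formula", {
  model <- c(1, 30, 45)
  expect_equal(pearson_r(2 * model + 7, model), 1)
  expect_equal(pearson_r(c(1, 2, 3), c(3, 2, 1)), -1)

  # the two published G. elwesii bait rows correlate at ~0.992
  x <- c(2.24, 22.6, 71.7); y <- c(16.0, 49.3, 202)
  direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_r(x, y), direct)
  expect_equal(direct, 0.992, tolerance = 1e-3)

  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(pearson_r(c(1, 2), c(1, 3)), "3 tissues")
})

test_that("fold and background follow the floored ratio definition", {
  fb <- fold_and_background(c(0.01, 33.3, 140), floor = 1)
  expect_equal(fb$fold, 140)
  expect_equal(fb$background, 140)
  expect_equal(fold_and_background(c(5, 5, 5))$fold, 1)
  expect_equal(fold_and_background(c(0, 0, 8), floor = 1)$fold, 8)
  expect_true(is.na(fold_and_background(c(0, 0, 0))$fold))
})

test_that("correlation p-value is the two-sided t-test with df = n - 2", {
  expect_equal(correlation_pvalue(0, 5), 1)
  expect_equal(correlation_pvalue(0.9969, 3), 0.05, tolerance = 2e-2)
  expect_lt(correlation_pvalue(0.9995, 3), 0.05)
  expect_equal(correlation_pvalue(1, 3), 0)
  expect_error(correlation_pvalue(0.5, 2), "3 tissues")

  # with three tissues the p criterion dominates the 0.8 correlation
  # cutoff: p <= 0.05 iff |r| >= 0.99692
  r_crit <- qt(0.975, 1) / sqrt(1 + qt(0.975, 1)^2)
  expect_equal(r_crit, 0.9969, tolerance = 1e-4)
  for (r in c(0.8, 0.95, 0.99, 0.9965, 0.9970, 0.9995)) {
    expect_identical(correlation_pvalue(r, 3) <= 0.05, r >= r_crit)
  }
})

test_that("model matching applies all four criteria", {
  bait <- bait_model("demo", c(1, 30, 45))
  res <- model_match(3 * c(1, 30, 45), bait, transcript_id = "x")
  expect_true(res$passed)
  expect_identical(res$failed_criteria, "")

  rev <- model_match(c(45, 30, 1), bait)
  expect_false(rev$passed)
  expect_true(grepl("correlation", rev$failed_criteria))

  flat <- model_match(c(5, 5, 5), bait)
  expect_false(flat$passed)
  expect_true(grepl("fold", flat$failed_criteria))

  # positive rescaling leaves r and fold unchanged (background moves)
  v <- c(2, 61, 93)
  a <- model_match(v, bait)
  b <- model_match(10 * v, bait)
  expect_equal(a$r, b$r)
  expect_equal(a$fold, b$fold)
  expect_equal(b$background, 10 * a$background)
})

test_that("raising any cutoff never enlarges the passing set", {
  withr::local_seed(51)
  bait <- bait_model("demo", c(1, 30, 45))
  vs <- lapply(1:300, function(i) runif(3, 0.1, 200) * exp(rnorm(3, 0, 0.3)))
  pass_set <- function(criteria) {
    which(vapply(vs, function(v) model_match(v, bait, criteria)$passed,
                 logical(1)))
  }
  base <- match_criteria(corr_cutoff = 0.5, background_cutoff = 0.5,
                         fold_cutoff = 2, p_cutoff = 0.2)
  p0 <- pass_set(base)
  tighter <- list(
    match_criteria(corr_cutoff = 0.9, background_cutoff = 0.5,
                   fold_cutoff = 2, p_cutoff = 0.2),
    match_criteria(corr_cutoff = 0.5, background_cutoff = 5,
                   fold_cutoff = 2, p_cutoff = 0.2),
    match_criteria(corr_cutoff = 0.5, background_cutoff = 0.5,
                   fold_cutoff = 8, p_cutoff = 0.2),
    match_criteria(corr_cutoff = 0.5, background_cutoff = 0.5,
                   fold_cutoff = 2, p_cutoff = 0.01))
  for (cr in tighter) {
    expect_true(all(pass_set(cr) %in% p0))
  }
})

test_that("screening a matrix excludes the bait and sorts results", {
  withr::local_seed(52)
  vals <- rbind(
    bait  = c(1, 30, 45),
    tx_b  = c(2, 60, 90),
    tx_a  = c(2.1, 63, 93),
    noise = c(100, 3, 7))
  colnames(vals) <- c("leaf", "inflorescence", "bulb")
  mat <- expression_matrix(vals, "demo")
  bm <- bait_model("demo", c(1, 30, 45), bait_transcript_id = "bait")
  pass <- screen_matrix(mat, bm)
  expect_equal(pass$transcript_id, c("tx_a", "tx_b"))
  allres <- screen_matrix(mat, bm, all = TRUE)
  expect_equal(nrow(allres), 3)  # bait excluded
  expect_false("bait" %in% allres$transcript_id)

  # permissive limit: every non-degenerate transcript passes
  perm <- match_criteria(corr_cutoff = -1, background_cutoff = 1e-9,
                         fold_cutoff = 1e-9, use_p = FALSE)
  expect_equal(nrow(screen_matrix(mat, bm, perm)), 3)

  empty <- expression_matrix(vals[0, , drop = FALSE], "demo")
  expect_equal(nrow(screen_matrix(empty, bm)), 0)

  bad <- bait_model("demo", c(1, 30, 45), tissues = c("root", "stem", "bulb"))
  expect_error(screen_matrix(mat, bad), "tissues")
})
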