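ws <- example_worksheet()
bounds <- compute_feature_bounds(ws$table)

test_that("min-max normalization reproduces the worksheet user row", {
  expect_equal(round(normalize_feature(71, 27, 105), 3), 0.564)
  expect_equal(normalize_feature(27, 27, 105), 0)
  expect_equal(normalize_feature(105, 27, 105), 1)
  # the F4 inconsistency: the printed f4 = 0.739 corresponds to 118 N
  expect_equal(round(normalize_feature(118, 30, 149), 3), 0.739)
  expect_equal(round(normalize_feature(110, 30, 149), 3), 0.672)
})

test_that("out-of-bounds queries clamp with a warning; degenerate bounds give 0", {
  expect_warning(a <- normalize_feature(150, 27, 105),
                 class = "icz_clamp_warning")
  expect_equal(a, 1)
  expect_warning(b <- normalize_feature(10, 27, 105),
                 class = "icz_clamp_warning")
  expect_equal(b, 0)
  expect_warning(d <- normalize_feature(42, 50, 50),
                 class = "icz_degenerate_bounds_warning")
  expect_equal(d, 0)
})

test_that("per-feature similarity reproduces the printed entry 5 / entry 7 scores", {
  u_f1 <- unclass(ws$user_normalized)[["f1"]]
  f1_5 <- normalize_feature(66, 27, 105)
  f1_7 <- normalize_feature(88, 27, 105)
  expect_equal(round(feature_similarity(f1_5, u_f1), 3), 0.064)
  expect_equal(round(feature_similarity(f1_7, u_f1), 3), 0.218)
  expect_equal(feature_similarity(0.4, 0.4), 0)
  expect_error(feature_similarity(1.2, 0.5), class = "icz_validation_error")
})

test_that("the similarity statistic reproduces the printed totals", {
  norm_row <- function(i) normalize_features(
    as.data.frame(ws$table)[i, -1, drop = TRUE] |> unlist(), bounds)
  expect_equal(round(similarity(norm_row(7), ws$user_normalized)$total, 3), 0.085)
  expect_equal(round(similarity(norm_row(5), ws$user_normalized)$total, 3), 0.347)
  expect_equal(round(similarity(norm_row(6), ws$user_normalized)$total, 3), 0.492)
  expect_equal(similarity(ws$user_normalized, ws$user_normalized)$total, 0)
})

test_that("total is the weighted mean of per-feature scores", {
  for (seed in 1:10) {
    set.seed(seed)
    b <- normalized_features(runif(1), runif(1), runif(1), runif(1), runif(1))
    u <- normalized_features(runif(1), runif(1), runif(1), runif(1), runif(1))
    s <- similarity(b, u)
    expect_equal(s$total, mean(s$per_feature), tolerance = 1e-12)
    w <- runif(5); w <- w / sum(w)
    sw <- similarity(b, u, weights = w)
    expect_equal(sw$total, sum(w * sw$per_feature), tolerance = 1e-12)
    expect_gte(s$total, 0)
    expect_lte(s$total, 1)
  }
  expect_error(similarity(ws$user_normalized, ws$user_normalized,
                          weights = c(1, 1, 1, 1, 1)),
               class = "icz_validation_error")
})

test_that("the similarity statistic is a pseudometric on normalized vectors", {
  set.seed(99)
  rand <- function() normalized_features(runif(1), runif(1), runif(1),
                                         runif(1), runif(1))
  for (i in 1:30) {
    x <- rand(); y <- rand(); z <- rand()
    dxy <- similarity(x, y)$total
    expect_equal(dxy, similarity(y, x)$total, tolerance = 1e-12)
    expect_gte(dxy, 0)
    expect_equal(similarity(x, x)$total, 0)
    expect_lte(dxy, similarity(x, z)$total + similarity(z, y)$total + 1e-12)
  }
})

test_that("the full worksheet matrix is reproduced within 0.001", {
  m <- match_features(ws$table, ws$user_normalized)
  got <- m$results[order(as.integer(m$results$entry_id)), ]
  ref <- ws$similarity_reference
  for (col in c("sim_f1", "sim_f2", "sim_f3", "sim_f4", "sim_d1", "total")) {
    expect_true(all(abs(got[[col]] - ref[[col]]) <= 0.001),
                info = sprintf("column %s", col))
  }
  expect_equal(m$best_id, "7")
  expect_equal(round(m$best_total, 3), 0.085)
})

test_that("matching from raw features supports the alternative F4 convention", {
  # raw user (F4 = 110 N) normalizes to f4 = 0.672, entry 7 total ~0.095;
  # entry 7 is still the best match
  m <- match_features(ws$table, ws$user)
  expect_equal(m$best_id, "7")
  expect_equal(round(m$best_total, 3), 0.095)
})

test_that("thresholds flag unacceptable matches without hiding the best entry", {
  m <- match_features(ws$table, ws$user_normalized, threshold = 0.05)
  expect_false(m$accepted)
  expect_equal(m$best_id, "7")
  m2 <- match_features(ws$table, ws$user_normalized, threshold = 0.2)
  expect_true(m2$accepted)
  m3 <- match_features(ws$table, ws$user_normalized)
  expect_true(is.na(m3$accepted))
})

test_that("ties are broken by table order and ranking ignores input permutation", {
  two <- feature_table(data.frame(
    entry_id = c("first", "second"),
    F1_N = c(71, 71), F2_N = c(57, 57), F3_N = c(146, 146),
    F4_N = c(110, 110), D1_cm = c(68, 68)
  ))
  # degenerate bounds: every normalized value is 0 for both rows and the user
  m <- suppressWarnings(match_features(two, ws$user))
  expect_equal(m$results$total, c(0, 0))
  expect_equal(m$best_id, "first")

  set.seed(5)
  tab <- random_feature_table(20, seed = 21)
  user <- simplified_features(70, 60, 140, 100, 65)
  m1 <- match_features(tab, user)
  perm <- sample(nrow(tab))
  m2 <- match_features(feature_table(as.data.frame(tab)[perm, ]), user)
  expect_equal(m1$results$entry_id, m2$results$entry_id)
  expect_equal(m1$results$total, m2$results$total, tolerance = 1e-12)
})

test_that("the matcher equals a brute-force argmin on random repositories", {
  for (seed in 1:20) {
    tab <- random_feature_table(30, seed = 1000 + seed)
    set.seed(2000 + seed)
    raw <- c(runif(1, 20, 120), runif(1, 20, 100), runif(1, 40, 230),
             runif(1, 25, 155), runif(1, 50, 75))
    user <- simplified_features(raw[1], raw[2], raw[3], raw[4], raw[5])
    oracle <- brute_force_best_oracle(tab, raw)
    m <- suppressWarnings(match_features(tab, user))
    expect_equal(m$best_id, oracle$best)
    expect_equal(sort(m$results$total), sort(oracle$totals), tolerance = 1e-12)
  }
})

test_that("match reports serialize to JSON with display rounding", {
  path <- withr::local_tempfile(fileext = ".json")
  m <- match_features(ws$table, ws$user_normalized)
  write_match_report(m, path)
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(rep$best_id, "7")
  expect_equal(rep$best_total_display, 0.085)
  expect_equal(nrow(rep$results), 12)
})
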