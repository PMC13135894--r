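test_that("classification uses the five left-closed classes with closed top", {
  v <- c(0, 0.1, 0.2, 0.39, 0.4, 0.5, 0.6, 0.79, 0.8, 1.0)
  g <- small_ths(matrix(v, 5, 2))
  cl <- classify(g)
  got <- cl$labels[cl$codes]
  expect_identical(got, c("Minimal", "Minimal", "Minor", "Minor",
                          "Moderate", "Moderate", "Major", "Major",
                          "Massive", "Massive"))
  # boundary conventions highlighted
  expect_identical(cl$labels[cl$codes[matrix(v, 5, 2) == 0.4]], "Moderate")
  expect_identical(cl$labels[cl$codes[matrix(v, 5, 2) == 1.0]], "Massive")
  expect_identical(cl$labels[cl$codes[matrix(v, 5, 2) == 0.5]], "Moderate")
})

test_that("classification propagates nodata and rejects out-of-range input", {
  m <- matrix(0.5, 3, 3); m[2, 2] <- NA
  cl <- classify(small_ths(m))
  expect_true(is.na(cl$codes[2, 2]))
  expect_identical(sum(is.na(cl$codes)), 1L)

  bad <- structure(list(lat = c(10, 5), lon = c(0, 5),
                        values = matrix(c(0.5, 1.2, 0.1, 0.3), 2, 2)),
                   class = "ths_grid")
  expect_error(classify(bad), "outside \\[0, 1\\]")
})

test_that("classification is idempotent on its own value representation", {
  set.seed(8)
  g <- small_ths(matrix(runif(36), 6, 6))
  expect_identical(classify(g)$codes, classify(g)$codes)
})

test_that("extents use cosine-of-latitude area weighting in km^2", {
  # two same-class cells at latitudes 0 and 60: area ratio 1 : cos(60) = 2:1
  g <- ths_grid(lat = c(60, 0), lon = c(0, 10),
                values = matrix(c(0.9, 0.9, NA, NA), 2, 2))
  ext <- class_extents(classify(g))
  massive <- ext$area_km2[ext$class == "Massive"]
  expect_equal(massive, attr(ext, "total_area_km2"))
  area <- thermshift:::.area_matrix(g$lat, g$lon)
  expect_equal(area[2, 1] / area[1, 1], 1 / cos(60 * pi / 180) * cos(0),
               tolerance = 1e-12)
  expect_identical(ext$n_cells[ext$class == "Massive"], 2L)

  empty <- ths_grid(c(60, 0), c(0, 10), matrix(NA_real_, 2, 2))
  expect_true(all(class_extents(classify(empty))$area_km2 == 0))
})

test_that("class extents partition the total unmasked area", {
  set.seed(13)
  m <- matrix(runif(24 * 48), 24, 48)
  m[sample(length(m), 100)] <- NA
  ext <- class_extents(classify(small_ths(m)))
  expect_equal(sum(ext$area_km2), attr(ext, "total_area_km2"),
               tolerance = 1e-6)
  expect_identical(sum(ext$n_cells), sum(!is.na(m)))
})

test_that("delta grids subtract cell-wise and demand aligned masks", {
  b <- small_ths(matrix(0.5, 4, 4))
  f <- small_ths(matrix(0.6, 4, 4))
  d <- delta_ths(b, f)
  expect_equal(d$mean, 0.1)
  expect_equal(d$min, 0.1)
  expect_equal(d$max, 0.1)

  d0 <- delta_ths(b, b)
  expect_true(all(d0$delta == 0))
  expect_equal(d0$mean, 0)

  f_masked <- f; f_masked$values[1, 1] <- NA
  expect_error(delta_ths(b, f_masked), "different nodata masks")
  other <- ths_grid(b$lat + 5, b$lon, f$values)
  expect_error(delta_ths(b, other), "not aligned")
})

test_that("range expansion requires a strict increase in qualifying extent", {
  m <- matrix(0.3, 5, 5); m[1:2, 1:2] <- 0.7
  base <- small_ths(m)
  expect_false(range_expansion_flag(base, base)$expanding)

  m_up <- m; m_up[3, 3] <- 0.65
  expect_true(range_expansion_flag(base, small_ths(m_up))$expanding)

  m_down <- m; m_down[1, 1] <- 0.5
  expect_false(range_expansion_flag(base, small_ths(m_down))$expanding)
})

test_that("priority categories follow the screening thresholds", {
  expect_identical(priority_category(-30)$category, "Priority")
  expect_identical(priority_category(10)$category, "Surveillance")
  expect_identical(priority_category(0)$category, "NoIssue")
  expect_identical(priority_category(4.9)$category, "NoIssue")
  expect_identical(priority_category(5)$category, "Surveillance")
  expect_identical(priority_category(20)$category, "Priority")
  expect_identical(priority_category(Inf)$category, "Priority")
  expect_error(priority_category(10, high_threshold = 5, low_threshold = 20),
               "thresholds")
  expect_error(priority_category(10, high_threshold = -1, low_threshold = -5),
               "thresholds")
})

test_that("identical scenarios give the zero-change identity", {
  set.seed(17)
  m <- matrix(runif(36), 6, 6); m[c(3, 18)] <- NA
  base <- small_ths(m)
  s <- change_summary("sp", base, base)
  expect_true(all(s$classes$abs_change_km2 == 0))
  expect_true(all(s$classes$pct_change == 0, na.rm = FALSE))
  expect_equal(s$delta_ths_mean, 0)
  expect_false(s$range_expanding)
  expect_identical(s$priority, "NoIssue")
})

test_that("percent change is undefined for classes new since baseline", {
  b <- small_ths(matrix(0.1, 4, 4))
  f_m <- matrix(0.1, 4, 4); f_m[1, 1] <- 0.9
  s <- change_summary("sp", b, small_ths(f_m))
  expect_true(is.na(s$classes$pct_change[s$classes$class == "Massive"]))
  expect_gt(s$classes$abs_change_km2[s$classes$class == "Massive"], 0)
  # qualifying extent appeared from zero baseline: infinite percent change
  expect_identical(s$extent_ge_0_6_pct_change, Inf)
  expect_identical(s$priority, "Priority")
  expect_true(s$range_expanding)
})
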