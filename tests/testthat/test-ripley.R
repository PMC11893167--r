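# Ripley's K estimator, the surface-constrained CSR null, interval maxima
# and the Mann-Whitney U test.

test_that("K follows the uncorrected estimator on constructed cases", {
  pts <- rbind(c(0, 0, 0), c(0, 0, 10))
  expect_equal(ripley_k(pts, c(5, 9.999, 10, 15), 1000),
               c(0, 0, 1000, 1000))
  # all points farther apart than max(r): K identically zero
  far <- diag(3) * 1e5
  expect_true(all(ripley_k(far, c(10, 100), 1e6) == 0))
  expect_warning(k1 <- ripley_k(rbind(c(0, 0, 0)), c(1, 2), 10),
                 "undefined")
  expect_true(all(is.na(k1)))
  expect_error(ripley_k(pts, c(5, 10), -1), "positive")
  expect_error(ripley_k(pts, c(10, 5), 1), "ascending")
})

test_that("K matches the brute-force pair-count oracle", {
  set.seed(23)
  pts <- matrix(runif(150, 0, 100), ncol = 3)
  r <- seq(5, 120, by = 5)
  expect_equal(ripley_k(pts, r, 1e6), brute_ripley(pts, r, 1e6))
  # permuting point order leaves K bit-identical
  expect_identical(ripley_k(pts[sample(nrow(pts)), ], r, 1e6),
                   ripley_k(pts, r, 1e6))
})

test_that("CSR null: analytic closed form and Monte-Carlo monotonicity", {
  s <- scene_plain(level = 3)$omm
  expect_equal(k_csr_null(s, 10, 10, analytic = TRUE), 4 / 3 * pi * 1e3,
               tolerance = 1e-6)
  kc <- k_csr_null(s, 50, seq(100, 2000, by = 100), n_resamples = 10,
                   seed = 2)
  expect_true(all(diff(kc) >= 0))
})

test_that("surface-uniform points give K/K_CSR near 1 against the null", {
  sc <- scene_plain(level = 4)
  means <- vapply(1:2, function(s) {
    sp <- sample_surface_points(sc$omm, 300, seed = 100 + s)
    kc <- k_curve(sp$points, sc$omm, run_config(), n_resamples = 50,
                  seed = 200 + s)
    mean(kc$ratio, na.rm = TRUE)
  }, 0)
  expect_lt(abs(mean(means) - 1), 0.1)
})

test_that("interval maxima pick the per-interval brute-force maximum", {
  r <- seq(27, 166, length.out = 140)
  flat <- structure(data.frame(r_nm = r, k = 1, k_csr = 1, ratio = 1),
                    class = c("k_curve", "data.frame"))
  im <- interval_maxima(flat, 10)
  expect_true(all(im$max_ratio == 1))
  expect_true(any(im$lo == 30 & im$hi == 40))

  spike <- flat
  spike$ratio[which.min(abs(r - 35))] <- 2.5
  im2 <- interval_maxima(spike, 10)
  expect_equal(im2$max_ratio[im2$lo == 30], 2.5)

  set.seed(4)
  rnd <- flat
  rnd$ratio <- runif(140, 0.5, 3)
  im3 <- interval_maxima(rnd, 10)
  for (i in seq_len(nrow(im3))) {
    sel <- r > im3$lo[i] & r <= im3$hi[i]
    if (i == 1) sel <- sel | r == im3$lo[1]
    expect_equal(im3$max_ratio[i], max(rnd$ratio[sel]))
  }
  # interval wider than the range collapses to a single interval
  im4 <- interval_maxima(rnd, 1000)
  expect_equal(nrow(im4), 1L)
  expect_equal(im4$max_ratio, max(rnd$ratio))
})

test_that("clustered decorations score higher interval maxima than CSR", {
  sc <- scene_plain(level = 4)
  cfg <- run_config()
  score <- function(mode, seed) {
    deco <- decorate_particles(sc$omm, 150, import_fraction = 1,
                               mode = mode, cluster_scale = 35, seed = seed)
    kc <- k_curve(pc(deco$particles), sc$omm, cfg, n_resamples = 20,
                  standoff = 135, seed = seed + 5000)
    im <- interval_maxima(kc, 10)
    im$max_ratio[im$lo == 30]
  }
  clu <- vapply(1:6, function(s) score("clustered", s), 0)
  csr <- vapply(1:6, function(s) score("csr", s), 0)
  expect_gt(median(clu), median(csr))
  expect_lt(mann_whitney_u(clu, csr)$p_two_sided, 0.05)
})

test_that("Mann-Whitney U matches enumeration, symmetry and wilcox.test", {
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(r$U, 0)
  expect_equal(r$p_two_sided, 2 / 6)
  expect_identical(r$method, "exact")

  same <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$U, 9 / 2)
  expect_equal(same$p_two_sided, 1)

  deg <- mann_whitney_u(c(5, 5), c(5, 5, 5))
  expect_true(deg$degenerate)
  expect_equal(deg$p_two_sided, 1)

  # tie-free exact p agrees with wilcox.test's exact two-sided p
  set.seed(9)
  for (i in 1:20) {
    a <- sample(100, 5); b <- sample(200, 6) + 0.5
    got <- mann_whitney_u(a, b)
    want <- stats::wilcox.test(a, b, exact = TRUE)
    expect_equal(got$U, unname(want$statistic))
    expect_equal(got$p_two_sided, want$p.value, tolerance = 1e-12)
  }

  # normal approximation tracks exact enumeration at n = 6 + 6
  set.seed(10)
  for (i in 1:10) {
    a <- rnorm(6); b <- rnorm(6, 1)
    pe <- mann_whitney_u(a, b)$p_two_sided
    pn <- mann_whitney_u(a, b, exact_max = 0)$p_two_sided
    expect_lt(abs(pe - pn), 0.05)
  }
})
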