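test_that("point-to-surface distance handles the analytic cases", {
  sheet <- tri_mesh(rbind(c(0, 0, 0), c(10, 0, 0), c(10, 10, 0),
                          c(0, 10, 0)),
                    rbind(c(1, 2, 3), c(1, 3, 4)))
  on_surface <- matrix(c(3, 4, 0), 1)
  d0 <- point_to_surface_distance(on_surface, sheet)
  expect_equal(d0$unsigned, 0)

  above <- matrix(c(5, 5, 0.7), 1)
  d1 <- point_to_surface_distance(above, sheet)
  expect_equal(d1$unsigned, 0.7)
  expect_equal(d1$signed, 0.7) # outside, along +z
  below <- matrix(c(5, 5, -0.7), 1)
  expect_equal(point_to_surface_distance(below, sheet)$signed, -0.7)
})

test_that("accelerated search equals the exhaustive scan and the scalar
           oracle", {
  fx <- random_small_fixture(41)
  m <- fx$mesh
  set.seed(7)
  pts <- matrix(stats::runif(300, -15, 30), ncol = 3)
  dg <- point_to_surface_distance(pts, m, method = "grid")
  de <- point_to_surface_distance(pts, m, method = "exhaustive")
  expect_equal(dg$unsigned, de$unsigned, tolerance = 0)
  expect_lt(max(abs(dg$unsigned - oracle_closest_mesh(pts, m))), 1e-9)
})

test_that("both-way distances see identical meshes as zero and parallel
           sheets as the offset", {
  fx <- generate_chain(fixture_spec(n_lobes = 1, contact_radius = 4,
                                    lobe_height = 8, mesh_resolution = 2))
  s <- both_way_distances(fx$mesh, fx$mesh)
  expect_equal(max(s$unsigned), 0)
  expect_equal(nrow(s), 2 * nrow(fx$mesh$vertices))

  a <- grid_sheet(6, 6)
  b <- grid_sheet(6, 6, z = 0.5)
  s2 <- both_way_distances(a, b)
  expect_true(all(abs(s2$unsigned - 0.5) < 1e-12))
})

test_that("a protruding bump is the only source of nonzero distance", {
  ref <- grid_sheet(8, 8)
  test <- ref
  centre <- which(test$vertices[, 1] == 4 & test$vertices[, 2] == 4)
  test$vertices[centre, 3] <- 1.5
  test <- compute_vertex_normals(test)
  s <- point_to_surface_distance(test$vertices, ref)
  far <- sqrt((test$vertices[, 1] - 4)^2 + (test$vertices[, 2] - 4)^2) > 1.01
  expect_true(all(s$unsigned[far] == 0))
  expect_equal(s$unsigned[centre], 1.5)
})

test_that("report statistics match hand arithmetic and textbook formulas", {
  mk <- function(u, s = u) tibble::tibble(unsigned = u, signed = s)
  r <- compute_report(mk(c(0, 0, 0, 1)), tolerance = 0.2)
  expect_equal(r$assd, 0.25)
  expect_equal(r$rms, 0.5)
  expect_equal(r$max_error, 1)
  expect_equal(r$pct_below_tolerance, 75)

  r2 <- compute_report(mk(rep(0.15, 10)))
  expect_equal(r2$assd, 0.15)
  expect_equal(r2$rms, 0.15)
  expect_equal(r2$p95, 0.15)
  expect_equal(r2$max_error, 0.15)
  expect_equal(r2$pct_below_tolerance, 100)
  r3 <- compute_report(mk(rep(0.25, 10)))
  expect_equal(r3$pct_below_tolerance, 0)

  # simulated half-normal sample vs an independent recomputation
  set.seed(123)
  u <- abs(stats::rnorm(10000, 0, 0.3))
  sg <- sample(c(-1, 1), 10000, replace = TRUE)
  rep_ <- compute_report(mk(u, u * sg), tolerance = 0.2)
  expect_lt(abs(rep_$assd - sum(u) / length(u)), 1e-12)
  expect_lt(abs(rep_$aasd - sum(u * sg) / length(u)), 1e-12)
  expect_lt(abs(rep_$rms - sqrt(sum(u^2) / length(u))), 1e-12)
  expect_equal(rep_$max_error, max(u))
  srt <- sort(u)
  h <- (length(u) - 1) * 0.95 + 1 # linear interpolation between order stats
  p95 <- srt[floor(h)] + (h - floor(h)) * (srt[floor(h) + 1] - srt[floor(h)])
  expect_lt(abs(rep_$p95 - p95), 1e-12)
  expect_equal(rep_$pct_below_tolerance, 100 * sum(u < 0.2) / length(u))

  expect_error(compute_report(mk(numeric(0))), "no distance samples")
})

test_that("cumulative error curve is monotone and consistent with p95", {
  mk <- function(u) tibble::tibble(unsigned = u, signed = u)
  flat <- cumulative_error_curve(mk(rep(0.4, 50)))
  expect_true(all(flat$distance_mm == 0.4))

  set.seed(5)
  u <- stats::rexp(4000, 3)
  cur <- cumulative_error_curve(mk(u), percentiles = c(0, 25, 50, 75, 95, 100))
  expect_true(all(diff(cur$distance_mm) >= 0))
  expect_equal(cur$distance_mm[cur$percentile == 95],
               compute_report(mk(u))$p95)

  set.seed(6)
  uu <- stats::runif(100000)
  cid <- cumulative_error_curve(mk(uu), percentiles = 0:100)
  expect_lt(max(abs(cid$distance_mm - cid$percentile / 100)), 0.01)

  expect_error(cumulative_error_curve(mk(u), percentiles = c(-5)), "0, 100")
})

test_that("pooled statistics are symmetric in the two meshes and scale
           equivariant", {
  a <- random_small_fixture(51)$mesh
  b <- perturb_mesh(a, 0.3, 9)
  r1 <- compute_report(both_way_distances(a, b))
  r2 <- compute_report(both_way_distances(b, a))
  for (fld in c("assd", "rms", "max_error", "p95"))
    expect_equal(r1[[fld]], r2[[fld]])

  s <- 2.5
  as <- tri_mesh(a$vertices * s, a$faces)
  bs <- tri_mesh(b$vertices * s, b$faces)
  r3 <- compute_report(both_way_distances(as, bs))
  for (fld in c("assd", "rms", "max_error", "p95"))
    expect_equal(r3[[fld]], s * r1[[fld]], tolerance = 1e-9)

  # pct-below-tolerance is non-decreasing in the tolerance
  sam <- both_way_distances(a, b)
  pct <- vapply(c(0.05, 0.1, 0.2, 0.5, 1),
                function(tol) compute_report(sam, tol)$pct_below_tolerance,
                numeric(1))
  expect_true(all(diff(pct) >= 0))
})

test_that("plane partition splits the fixture and flips with the normal", {
  fx <- generate_chain(fixture_spec(n_lobes = 2, lobe_shape = "cube",
                                    contact_radius = 3, lobe_height = 12,
                                    mesh_resolution = 3))
  zmid <- mean(range(fx$mesh$vertices[, 3]))
  p <- partition_by_plane(fx$mesh, c(0, 0, zmid), c(0, 0, 1))
  expect_equal(sort(unique(fx$labels[p$positive])), 2L)
  expect_equal(sort(unique(fx$labels[p$negative])), 1L)

  p2 <- partition_by_plane(fx$mesh, c(0, 0, -100), c(0, 0, 1))
  expect_true(all(p2$positive))
  expect_false(any(p2$negative))

  pf <- partition_by_plane(fx$mesh, c(0, 0, zmid), c(0, 0, -1))
  on_plane <- abs(fx$mesh$vertices[, 3] - zmid) < 1e-12
  expect_identical(pf$positive[!on_plane], p$negative[!on_plane])
  expect_error(partition_by_plane(fx$mesh, c(0, 0, 0), c(0, 0, 0)),
               "nonzero")
})

test_that("ICC(2,1) matches an independent ANOVA recomputation", {
  m <- shrout_fleiss_ratings()
  fit <- icc(m)
  expect_lt(abs(fit$value - oracle_icc_aov(m)), 1e-6)
  expect_equal(fit$value, 0.2897637795, tolerance = 1e-9)

  same <- cbind(c(1, 2, 3, 4.5), c(1, 2, 3, 4.5))
  expect_equal(icc(same)$value, 1)

  r1 <- c(-2, -1, 1, 2)
  expect_lt(icc(cbind(r1, -r1))$value, 0)

  set.seed(8)
  rnd <- matrix(stats::rnorm(40), ncol = 4)
  expect_lt(abs(icc(rnd)$value - oracle_icc_aov(rnd)), 1e-6)

  expect_error(icc(matrix(1, 3, 3)), "zero total variance")
  expect_error(icc(matrix(1:4, 1)), "at least 2")
})

test_that("tidy/glance/autoplot expose the report", {
  a <- grid_sheet(4, 4)
  b <- grid_sheet(4, 4, z = 0.1)
  r <- compute_report(both_way_distances(a, b))
  expect_equal(nrow(tidy(r)), 6)
  gl <- glance(r)
  expect_equal(gl$assd, 0.1)
  expect_equal(gl$n_test_to_ref, 25L)
  p <- autoplot(cumulative_error_curve(both_way_distances(a, b)))
  expect_s3_class(p, "ggplot")
})
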