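test_that("seed snapping: zero distance, tie-break, conflicts, oracle", {
  sheet <- grid_sheet(4, 4)
  v7 <- unname(sheet$vertices[7, ])
  s <- snap_seeds(sheet, data.frame(x = v7[1], y = v7[2], z = v7[3],
                                    label = 1))
  expect_equal(s$vertex, 7L)

  # equidistant between vertices 3 and 9: lowest index wins
  mid <- (sheet$vertices[3, ] + sheet$vertices[9, ]) / 2
  s2 <- snap_seeds(sheet, data.frame(x = mid[1], y = mid[2], z = mid[3],
                                     label = 2))
  d3 <- sum((sheet$vertices[3, ] - mid)^2)
  d9 <- sum((sheet$vertices[9, ] - mid)^2)
  expect_equal(d3, d9)
  expect_equal(s2$vertex, 3L)

  expect_error(
    snap_seeds(sheet, data.frame(x = c(v7[1], v7[1] + 1e-4),
                                 y = v7[2], z = v7[3], label = c(1, 2))),
    "different labels")
  expect_error(snap_seeds(sheet, data.frame(x = numeric(0), y = numeric(0),
                                            z = numeric(0),
                                            label = integer(0))),
               "at least one seed")

  # random seeds agree with an exhaustive nearest-vertex scan
  fx <- random_small_fixture(21)
  set.seed(99)
  pts <- matrix(stats::runif(300, -10, 30), ncol = 3)
  got <- snap_seeds(fx$mesh, data.frame(x = pts[, 1], y = pts[, 2],
                                        z = pts[, 3], label = 1))$vertex
  want <- apply(pts, 1, function(p) {
    which.min(colSums((t(fx$mesh$vertices) - p)^2))
  })
  expect_equal(got, unname(want))
})

test_that("a growing pass floods flat regions and stops at sharp edges", {
  sheet <- grid_sheet(5, 5)
  st <- new_label_state(sheet)
  st$labels[1] <- 1L
  st <- region_grow_pass(sheet, st, 1L, theta = 0)
  expect_true(all(st$labels == 1L)) # all normal angles are 0 on a flat sheet

  # theta = 180: the constraint is vacuous, the whole component is taken
  fx <- generate_chain(fixture_spec(n_lobes = 2, mesh_resolution = 3))
  st2 <- new_label_state(fx$mesh)
  st2$labels[5] <- 1L
  st2 <- region_grow_pass(fx$mesh, st2, 5L, theta = 180)
  expect_true(all(st2$labels == 1L))
})

test_that("cube-face growth matches a brute-force reachability search", {
  fx <- generate_chain(fixture_spec(n_lobes = 2, lobe_shape = "cube",
                                    contact_radius = 3, lobe_height = 12,
                                    mesh_resolution = 3))
  m <- fx$mesh
  # seed in the middle of the first cube's -z face interior
  seed <- which.min(colSums((t(m$vertices) - c(0, 0, 0))^2))
  for (theta in c(30, 45)) {
    st <- new_label_state(m)
    st$labels[seed] <- 1L
    st <- region_grow_pass(m, st, seed, theta = theta)
    expect_setequal(which(st$labels == 1L), oracle_reachable(m, seed, theta))
  }
  # at 30 degrees only the face interior is reached (edge vertices sit at 45)
  st <- new_label_state(m)
  st$labels[seed] <- 1L
  st <- region_grow_pass(m, st, seed, theta = 30)
  lab <- which(st$labels == 1L)
  expect_true(all(m$vertices[lab, 3] == 0))
  expect_true(all(abs(m$vertices[lab, 1]) < 6 & abs(m$vertices[lab, 2]) < 6))
})

test_that("multi-label races resolve by strict FIFO order, like the naive
           transcription", {
  for (seed in c(31, 32, 33)) {
    fx <- random_small_fixture(seed)
    m <- fx$mesh
    s5 <- fx$seeds[fx$seeds$layout == "seeds5", ]
    snapped <- snap_seeds(m, s5)
    labels0 <- integer(nrow(m$vertices))
    labels0[snapped$vertex] <- snapped$label
    st <- new_label_state(m)
    st$labels <- labels0
    theta <- 25
    st <- region_grow_pass(m, st, snapped$vertex, theta = theta)
    expect_identical(st$labels,
                     oracle_grow_fifo(m, labels0, snapped$vertex, theta))
  }
})

test_that("iterative schedule recovers the ground truth exactly and is
           deterministic", {
  fx <- generate_chain(fixture_spec(n_lobes = 3, crease_angle = 60,
                                    mesh_resolution = 2))
  s5 <- fx$seeds[fx$seeds$layout == "seeds5", ]
  st1 <- iterative_segment(fx$mesh, s5, 5, 5, 55)
  expect_identical(st1$labels, fx$labels)
  st2 <- iterative_segment(fx$mesh, s5, 5, 5, 55)
  expect_identical(st2$labels, st1$labels)

  # vacuous ceiling: everything labelled on any connected mesh
  st3 <- iterative_segment(fx$mesh, s5[1, ], 5, 5, 180)
  expect_equal(sum(st3$labels == 0L), 0)

  # unreachable vertices at a low ceiling produce a warning with the count
  expect_warning(iterative_segment(fx$mesh, s5[1, ], 5, 5, 20),
                 "remain unlabelled")
})

test_that("undo reverts exactly one pass and the log replays to the labels", {
  fx <- generate_chain(fixture_spec(n_lobes = 2, mesh_resolution = 2.5))
  m <- fx$mesh
  s5 <- snap_seeds(m, fx$seeds[fx$seeds$layout == "seeds5", ])
  st <- new_label_state(m)
  st$labels[s5$vertex] <- s5$label
  before <- st$labels
  st1 <- region_grow_pass(m, st, s5$vertex, 10, seeds_added = s5)
  st2 <- region_grow_pass(m, st1, which(st1$labels > 0), 30)
  expect_identical(replay_log(st2), st2$labels)

  undone <- undo_last_pass(st2)
  expect_identical(undone$labels, st1$labels)
  expect_identical(replay_log(undone), st1$labels)

  undone2 <- undo_last_pass(undone)
  expect_true(all(undone2$labels == 0L)) # first pass carried the seeds

  expect_warning(res <- undo_last_pass(new_label_state(m)), "empty")
  expect_true(all(res$labels == 0L))
})

test_that("labelled sets grow monotonically and stay disjoint partitions", {
  fx <- generate_chain(fixture_spec(n_lobes = 3, crease_angle = 80,
                                    mesh_resolution = 2.5))
  s5 <- fx$seeds[fx$seeds$layout == "seeds5", ]
  st <- iterative_segment(fx$mesh, s5, 5, 5, 75)
  labs <- integer(0)
  run <- integer(length(st$labels))
  for (entry in st$pass_log) {
    expect_length(intersect(entry$labeled, labs), 0) # never relabelled
    labs <- c(labs, entry$labeled)
    run[entry$seed_vertices] <- entry$seed_labels
    run[entry$labeled] <- entry$labels_assigned
  }
  expect_identical(run, st$labels)

  # threshold monotonicity: region at ceiling t1 is within region at t2 >= t1
  prev <- NULL
  for (ceil in c(15, 35, 55, 75)) {
    sti <- suppressWarnings(iterative_segment(fx$mesh, s5, 5, 5, ceil))
    cur <- which(sti$labels != 0L)
    if (!is.null(prev)) expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("adding a seed in an unlabelled area never shrinks other regions", {
  fx <- generate_chain(fixture_spec(n_lobes = 2, crease_angle = 90,
                                    mesh_resolution = 2.5))
  s5 <- fx$seeds[fx$seeds$layout == "seeds5", ]
  only1 <- s5[s5$label == 1, ]
  st_a <- suppressWarnings(iterative_segment(fx$mesh, only1, 5, 5, 55))
  expect_gt(sum(st_a$labels == 0L), 0) # lobe 2 is starved without its seed
  st_b <- iterative_segment(fx$mesh, s5, 5, 5, 55)
  reg1_a <- which(st_a$labels == 1L)
  reg1_b <- which(st_b$labels == 1L)
  expect_true(all(reg1_a %in% reg1_b))
})

test_that("interactive hook can undo a pass and add seeds", {
  fx <- generate_chain(fixture_spec(n_lobes = 2, crease_angle = 90,
                                    mesh_resolution = 2.5))
  s5 <- fx$seeds[fx$seeds$layout == "seeds5", ]
  only1 <- s5[s5$label == 1, ]
  fired <- FALSE
  hook <- function(state, theta) {
    if (!fired) {
      fired <<- TRUE
      # undoing the first pass also reverts its seeds, so re-seed fully
      return(list(undo = TRUE, seeds = s5))
    }
    NULL
  }
  st <- iterative_segment(fx$mesh, only1, 5, 5, 85, hook = hook)
  expect_identical(st$labels, fx$labels)
})

test_that("segment export writes whole-label faces and reports spanning
           faces", {
  fx <- generate_chain(fixture_spec(n_lobes = 2, mesh_resolution = 2.5))
  st <- iterative_segment(fx$mesh, fx$seeds[fx$seeds$layout == "seeds5", ],
                          5, 5, 55)
  out_dir <- withr::local_tempdir()
  res <- export_segments(fx$mesh, st, out_dir)
  expect_equal(nrow(res), 2)
  expect_true(all(file.exists(res$path)))
  f <- fx$mesh$faces
  lab <- st$labels
  spanning <- sum(!(lab[f[, 1]] != 0 & lab[f[, 1]] == lab[f[, 2]] &
                      lab[f[, 2]] == lab[f[, 3]]))
  expect_equal(attr(res, "n_spanning_faces"), spanning)
  expect_equal(sum(res$n_faces), nrow(f) - spanning)

  # one label over everything: the export equals the input mesh
  st_all <- new_label_state(fx$mesh)
  st_all$labels[] <- 1L
  res_all <- export_segments(fx$mesh, st_all, withr::local_tempdir())
  m2 <- read_mesh(res_all$path[1])
  expect_equal(nrow(m2$vertices), nrow(fx$mesh$vertices))
  expect_equal(m2$faces, fx$mesh$faces)

  # unlabelled island: its faces land in no file and are counted
  st_half <- new_label_state(fx$mesh)
  st_half$labels[fx$labels == 1L] <- 1L
  res_half <- export_segments(fx$mesh, st_half, withr::local_tempdir())
  expect_equal(nrow(res_half), 1)
  expect_gt(attr(res_half, "n_spanning_faces"), 0)
  expect_error(export_segments(fx$mesh, new_label_state(fx$mesh),
                               withr::local_tempdir()),
               "no labelled vertices")
})

test_that("tidy and glance summarise a label state", {
  fx <- generate_chain(fixture_spec(n_lobes = 2, mesh_resolution = 3))
  st <- iterative_segment(fx$mesh, fx$seeds[fx$seeds$layout == "seeds5", ],
                          5, 5, 55)
  td <- tidy(st)
  expect_equal(nrow(td), nrow(fx$mesh$vertices))
  gl <- glance(st)
  expect_equal(gl$n_labeled + gl$n_unlabeled, gl$n_vertices)
  expect_equal(gl$n_labels, 2L)
})
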