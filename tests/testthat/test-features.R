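test_that("body basis handles the axis-aligned case and is orthonormal", {
  f <- canonical_skeleton()
  # shoulder_center directly above spine (+y), shoulder_left along -x
  f["shoulder_center", ] <- f["spine", ] + c(0, 0.33, 0)
  f["shoulder_left", ] <- f["spine", ] + c(-0.2, 0, 0)
  b <- compute_body_basis(f)
  expect_equal(b$u, c(0, 1, 0), tolerance = 1e-12)
  expect_equal(b$v, c(-1, 0, 0), tolerance = 1e-12)
  expect_equal(b$w, c(0, 0, 1), tolerance = 1e-12)  # u x v
})

test_that("body basis is orthonormal and rotation-equivariant", {
  set.seed(41)
  for (i in 1:100) {
    f <- random_frame()
    b <- compute_body_basis(f)
    expect_equal(sum(b$u^2), 1, tolerance = 1e-9)
    expect_equal(sum(b$v^2), 1, tolerance = 1e-9)
    expect_equal(sum(b$w^2), 1, tolerance = 1e-9)
    expect_lt(abs(sum(b$u * b$v)), 1e-9)
    expect_lt(abs(sum(b$u * b$w)), 1e-9)
    expect_lt(abs(sum(b$v * b$w)), 1e-9)
    R <- random_rotation()
    br <- compute_body_basis(rotate_frame(f, R))
    expect_equal(br$u, as.numeric(R %*% b$u), tolerance = 1e-9)
    expect_equal(br$v, as.numeric(R %*% b$v), tolerance = 1e-9)
    expect_equal(br$w, as.numeric(R %*% b$w), tolerance = 1e-9)
  }
})

test_that("degenerate shoulder geometry errors", {
  f <- canonical_skeleton()
  f["shoulder_center", ] <- f["spine", ]
  expect_error(compute_body_basis(f), "degenerate")
  f <- canonical_skeleton()
  f["shoulder_left", ] <- f["spine", ] +
    2 * (f["shoulder_center", ] - f["spine", ])  # collinear
  expect_error(compute_body_basis(f), "collinear")
})

test_that("body coordinates center the spine and are translation/rotation invariant", {
  set.seed(42)
  f <- random_frame()
  bc <- to_body_coordinates(f)
  expect_equal(unname(bc["spine", ]), c(0, 0, 0), tolerance = 1e-12)
  shifted <- skeleton_frame(sweep(f, 2, c(1.3, -0.4, 7), `+`))
  expect_equal(to_body_coordinates(shifted), bc, tolerance = 1e-12,
               ignore_attr = TRUE)
  rotated <- rotate_frame(f, rotation_y(45))
  expect_equal(to_body_coordinates(rotated), bc, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("feature vector has length 71 = 3 x 19 + 14 with documented layout", {
  v <- extract_features(canonical_skeleton())
  expect_length(v, 71L)
  expect_identical(nrow(skeleton_edges()), 19L)
  expect_identical(nrow(angle_sites()), 14L)
  # each 3-component segment block has unit norm
  seg <- matrix(v[1:57], ncol = 3, byrow = TRUE)
  expect_equal(rowSums(seg^2), rep(1, 19), tolerance = 1e-6)
  ang <- v[58:71]
  expect_true(all(ang >= 0 & ang <= pi))
})

test_that("elbow angle is 0 when straight and pi/2 when perpendicular", {
  f <- canonical_skeleton()
  sh <- f["shoulder_left", ]
  f["elbow_left", ] <- sh + c(0, -0.25, 0)
  f["wrist_left", ] <- sh + c(0, -0.5, 0)   # collinear chain
  f["hand_left", ] <- sh + c(0, -0.58, 0)
  v <- extract_features(f)
  expect_equal(unname(v["angle_elbow_left"]), 0, tolerance = 1e-9)
  f["wrist_left", ] <- f["elbow_left", ] + c(0, 0, 0.25)  # forearm forward
  f["hand_left", ] <- f["wrist_left", ] + c(0, 0, 0.08)
  v <- extract_features(f)
  expect_equal(unname(v["angle_elbow_left"]), pi / 2, tolerance = 1e-9)
})

test_that("features are invariant to translation, rotation and uniform scale", {
  set.seed(43)
  for (i in 1:20) {
    f <- random_frame()
    v <- extract_features(f)
    g <- skeleton_frame(sweep(f, 2, stats::rnorm(3), `+`))
    expect_equal(extract_features(g), v, tolerance = 1e-6)
    g <- rotate_frame(f, rotation_y(stats::runif(1, -180, 180)))
    expect_equal(extract_features(g), v, tolerance = 1e-6)
    s <- stats::runif(1, 0.5, 2)
    g <- skeleton_frame(sweep(sweep(f, 2, f["spine", ]) * s, 2, f["spine", ], `+`))
    expect_equal(extract_features(g), v, tolerance = 1e-6)
  }
})

test_that("extract_features is deterministic and errors on zero-length segments", {
  f <- random_frame()
  expect_identical(extract_features(f), extract_features(f))
  f["hand_left", ] <- f["wrist_left", ]
  expect_error(extract_features(f), "wrist_left->hand_left")
})

test_that("scaled features lie in [-1, 1]", {
  v <- extract_features(random_frame(), scale_angles = TRUE)
  expect_true(all(v >= -1 & v <= 1))
})

test_that("trajectory I/O round-trips through CSV and JSON-Lines", {
  set.seed(44)
  frames <- lapply(1:4, function(i) {
    f <- random_frame()
    attr(f, "timestamp") <- i / 30
    f
  })
  csv <- withr::local_tempfile(fileext = ".csv")
  write_frames_csv(frames, csv)
  back <- read_frames_csv(csv)
  expect_length(back, 4L)
  expect_equal(back[[2]], frames[[2]], tolerance = 1e-12, ignore_attr = FALSE)
  jl <- withr::local_tempfile(fileext = ".jsonl")
  write_frames_jsonl(frames, jl)
  back2 <- read_frames_jsonl(jl)
  expect_equal(back2[[3]], frames[[3]], tolerance = 1e-12)
  expect_equal(attr(back2[[1]], "timestamp"), 1 / 30)
})
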