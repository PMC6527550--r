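test_that("PDB write/read round trip preserves atoms to format precision", {
  set.seed(42)
  n <- 40
  at <- data.frame(
    element = sample(c("C", "N", "O", "S"), n, replace = TRUE),
    name = paste0("A", seq_len(n) %% 9),
    res_index = sort(sample(1:12, n, replace = TRUE)),
    res_name = "ALA",
    chain = "A",
    x = round(stats::runif(n, -40, 40), 3),
    y = round(stats::runif(n, -40, 40), 3),
    z = round(stats::runif(n, -40, 40), 3),
    occupancy = 1, stringsAsFactors = FALSE)
  s <- new_structure(at)
  f <- tempfile(fileext = ".pdb")
  write_pdb(s, f)
  s2 <- read_pdb(f)
  expect_equal(nrow(s2$atoms), n)
  expect_equal(s2$atoms$name, s$atoms$name)
  expect_equal(s2$atoms$res_index, s$atoms$res_index)
  expect_equal(coords(s2), coords(s), tolerance = 1e-3)
  # second round trip is exact
  f2 <- tempfile(fileext = ".pdb")
  write_pdb(s2, f2)
  s3 <- read_pdb(f2)
  expect_identical(coords(s3), coords(s2))
})

test_that("two-chain structures get TER records and re-read intact", {
  at <- data.frame(element = "C", name = c("CA", "CB", "CA"),
                   res_index = c(1, 1, 2),
                   res_name = "GLY", chain = c("A", "A", "B"),
                   x = 1:3, y = 0, z = 0, occupancy = 1,
                   stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".pdb")
  write_pdb(new_structure(at), f)
  lines <- readLines(f)
  expect_equal(sum(lines == "TER"), 2)
  s2 <- read_pdb(f)
  expect_equal(s2$atoms$chain, c("A", "A", "B"))
})

test_that("read_pdb applies the altloc and hydrogen policies", {
  lines <- c(
    "ATOM      1  CA AGLY A   1       1.000   2.000   3.000  0.30  0.00           C",
    "ATOM      2  CA BGLY A   1       4.000   5.000   6.000  0.70  0.00           C",
    "ATOM      3  H   GLY A   1       0.000   0.000   0.000  1.00  0.00           H",
    "ATOM      4  CB  GLY A   1       7.000   8.000   9.000  1.00  0.00           C",
    "END")
  f <- tempfile(fileext = ".pdb")
  writeLines(lines, f)
  s <- read_pdb(f)
  expect_equal(nrow(s$atoms), 2)              # hydrogens dropped
  ca <- s$atoms[s$atoms$name == "CA", ]
  expect_equal(c(ca$x, ca$y, ca$z), c(4, 5, 6))  # highest occupancy kept
  expect_equal(s$atoms$radius[s$atoms$name == "CB"],
               unname(default_vdw_radii["C"]))
})

test_that("degenerate PDB inputs raise errors", {
  expect_error(read_pdb(tempfile()), "not found")
  f <- tempfile(fileext = ".pdb")
  writeLines(c("HEADER  junk", "REMARK nothing"), f)
  expect_error(read_pdb(f))
})

test_that("geometric_center matches the brute-force mean and is
           translation-equivariant", {
  expect_equal(geometric_center(c(1, 1, 1)), c(1, 1, 1))
  expect_equal(geometric_center(rbind(c(0, 0, 0), c(2, 0, 0))), c(1, 0, 0))
  set.seed(7)
  X <- matrix(stats::rnorm(150), ncol = 3)
  brute <- c(mean(X[, 1]), mean(X[, 2]), mean(X[, 3]))
  expect_equal(geometric_center(X), brute, tolerance = 1e-12)
  t <- c(3, -2, 5)
  expect_equal(geometric_center(sweep(X, 2, t, `+`)),
               geometric_center(X) + t, tolerance = 1e-12)
  expect_error(geometric_center(X[0, , drop = FALSE]), "empty")
})

test_that("separation is the Euclidean metric", {
  expect_equal(separation(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(separation(c(0, 0, 0), c(3, 4, 0)), 5)
  set.seed(8)
  for (i in 1:25) {
    a <- stats::rnorm(3); b <- stats::rnorm(3); c_ <- stats::rnorm(3)
    expect_equal(separation(a, b), sqrt(sum((a - b)^2)))
    expect_equal(separation(a, b), separation(b, a))
    expect_lte(separation(a, c_), separation(a, b) + separation(b, c_) + 1e-12)
  }
})

test_that("poses compose rotation about the centroid with translation", {
  ref <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0))
  id <- new_pose()
  expect_equal(apply_pose(ref, id), ref)
  p <- new_pose(axis_angle_quat(c(0, 0, 1), 90), c(0, 0, 2))
  out <- apply_pose(ref, p)
  expect_equal(colMeans(out), colMeans(ref) + c(0, 0, 2), tolerance = 1e-12)
  # 4x 90-degree rotations return to start
  q4 <- Reduce(quat_multiply, rep(list(axis_angle_quat(c(0, 0, 1), 90)), 4))
  expect_equal(abs(q4[1]), 1, tolerance = 1e-12)
  expect_equal(sqrt(sum(p$rotation^2)), 1, tolerance = 1e-9)
  expect_error(new_pose(rotation = c(0, 0, 0, 0)), "quaternion")
})
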