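test_that("assign_shell respects the half-open shell boundaries", {
  sch <- shell_scheme()
  expect_equal(sch$radius, 7.5)
  expect_identical(assign_shell(0, sch), 0L)
  expect_identical(assign_shell(1.25, sch), 1L)  # lower-inclusive boundary
  expect_identical(assign_shell(1.2499, sch), 0L)
  expect_true(is.na(assign_shell(7.5, sch)))
  expect_true(is.na(assign_shell(100, sch)))
  expect_error(assign_shell(-0.1, sch), "negative")
})

test_that("featurize returns the 480-long shell-major descriptor", {
  m <- read_structure(write_toy_pdb())
  fv <- featurize(m, c(11, 7, -3))
  expect_s3_class(fv, "feature_vector")
  expect_length(fv$values, 480L)
  expect_equal(names(fv$values)[1], "s0_RES_ALA")
  expect_equal(names(fv$values)[81], "s1_RES_ALA")
})

test_that("a single atom lands its count in exactly one shell", {
  m <- make_structure(data.frame(name = "CB", resname = "ALA", resseq = 1,
                                 x = 3, y = 0, z = 0))
  fv <- featurize(m, c(0, 0, 0))
  idx_c <- which(names(fv$values) == sprintf("s%d_ELEM_C", 2))
  expect_equal(unname(fv$values[idx_c]), 1)
  other <- grep("_ELEM_C$", names(fv$values))
  expect_equal(sum(fv$values[other]), 1)  # no other shell counts it
})

test_that("featurize is rotation/translation invariant to 1e-9", {
  m <- read_structure(write_toy_pdb())
  center <- c(10.5, 8.5, -2)
  fv <- featurize(m, center)
  set.seed(42)
  for (k in 1:5) {
    R <- random_rotation(); t <- stats::rnorm(3, sd = 20)
    m2 <- rigid_move(m, R, t)
    fv2 <- featurize(m2, as.numeric(center %*% R) + t)
    expect_lt(max(abs(fv2$values - fv$values)), 1e-9)
  }
})

test_that("shell counts conserve the whole-sphere count", {
  ref <- generate_reference(30, seed = 7)
  m <- ref$model
  center <- with(m$atoms[m$atoms$name == "CA", ][15, ], c(x, y, z))
  fv <- featurize(m, center)
  # oracle: direct count of heavy polymer atoms within 7.5 A
  a <- m$atoms[m$atoms$record == "ATOM" & m$atoms$element != "H", ]
  d <- sqrt((a$x - center[1])^2 + (a$y - center[2])^2 + (a$z - center[3])^2)
  for (el in c("C", "N", "O", "S")) {
    shells <- fv$values[grep(sprintf("_ELEM_%s$", el), names(fv$values))]
    expect_equal(unname(sum(shells)), sum(d < 7.5 & a$element == el))
  }
})

test_that("mean-kind properties are zero in empty shells, not NaN", {
  m <- make_structure(data.frame(name = "CB", resname = "ALA", resseq = 1,
                                 x = 3, y = 0, z = 0, b = 25))
  fv <- featurize(m, c(0, 0, 0))
  bmeans <- fv$values[grep("_BFACTOR_MEAN$", names(fv$values))]
  expect_false(any(is.nan(bmeans)))
  expect_equal(unname(bmeans[3]), 25)   # shell 2 holds the atom
  expect_equal(unname(sum(bmeans)), 25) # all other shells empty -> 0
})

test_that("the default manifest holds exactly 80 uniquely-named rules", {
  man <- default_manifest()
  expect_equal(nrow(man), 80L)
  expect_false(anyDuplicated(man$name) > 0)
  expect_true(all(man$kind %in% c("count", "sum", "mean")))
  bad <- man; bad$kind[1] <- "max"
  expect_error(validate_manifest(bad), "count/sum/mean")
  expect_error(validate_manifest(man[-1, ]), "80")
  # JSON round-trip
  skip_if_not_installed("jsonlite")
  p <- tempfile(fileext = ".json")
  write_manifest(man, p)
  expect_equal(read_manifest(p), man)
})

test_that("build_background matches the direct mean/SD formulas", {
  # dim 1 alternates {0, 2}; remaining dims random so pair calibration varies
  set.seed(40)
  M <- cbind(rep(c(0, 2), 4), matrix(stats::rnorm(8 * 479, sd = 2), 8))
  bg <- build_background(M, classes = rep(c("hydroxyl", "amide"), each = 4),
                         n_pairs = 60, seed = 1)
  expect_equal(unname(bg$dim_mean[1]), 1)
  expect_equal(unname(bg$dim_std[1]), 1)  # population SD of {0,2,0,2,...}
  expect_equal(bg$retained, seq_len(480))  # every dim varies in this pool
  # direct formula on an arbitrary dimension
  expect_equal(unname(bg$dim_mean[7]), mean(M[, 7]))
  expect_equal(unname(bg$dim_std[7]), sqrt(mean((M[, 7] - mean(M[, 7]))^2)))
})

test_that("degenerate pools and pinned zero-variance dimensions error", {
  M <- rbind(rep(1, 480), rep(1, 480))
  expect_error(build_background(M, classes = c("amide", "amide")),
               "zero variance")
  M2 <- rbind(c(0, rep(5, 479)), c(2, rep(5, 479)),
              c(1, rep(5, 479)), c(3, rep(5, 479)))
  expect_error(build_background(M2, classes = rep("amide", 4), retain = c(1, 2)),
               "zero variance.*2")
  expect_error(build_background(M2[1:2, ], classes = c("amide", "hydroxyl")),
               "fewer than 2")
})

test_that("build_background is bit-identical under a fixed seed", {
  set.seed(123)
  M <- matrix(stats::rnorm(8 * 480), 8)
  cls <- rep(c("amide", "hydroxyl"), each = 4)
  b1 <- build_background(M, cls, n_pairs = 50, seed = 7)
  b2 <- build_background(M, cls, n_pairs = 50, seed = 7)
  expect_identical(b1, b2)
  b3 <- build_background(M, cls, n_pairs = 50, seed = 8)
  expect_false(identical(b1$pair_stats, b3$pair_stats))
})

test_that("standardize matches per-dimension scalar arithmetic", {
  set.seed(5)
  M <- matrix(stats::rnorm(6 * 480, mean = 2), 6)
  bg <- build_background(M, rep(c("amide", "amine"), 3), n_pairs = 20, seed = 1)
  expect_equal(unname(standardize(bg$dim_mean, bg)), rep(0, 480))
  expect_equal(unname(standardize(bg$dim_mean + bg$dim_std, bg)), rep(1, 480))
  v <- M[3, ]
  z <- standardize(v, bg)
  for (i in c(1, 17, 480))  # spot-check the scalar formula
    expect_equal(z[i], (v[i] - bg$dim_mean[i]) / bg$dim_std[i])
  expect_error(standardize(v[-1], bg), "mismatch")
})
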