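test_that("functional centers follow the residue mapping table", {
  m <- read_structure(write_toy_pdb())
  res <- residue_table(m)
  cen <- centers_from_residues(m, res)
  expect_equal(nrow(cen$centers), 3L)
  # SER -> OG, class hydroxyl
  ser <- cen$centers[cen$centers$resname == "SER", ]
  og <- m$atoms[m$atoms$name == "OG", ]
  expect_equal(c(ser$x, ser$y, ser$z), c(og$x, og$y, og$z))
  expect_equal(ser$chem_class, "hydroxyl")
  # ASP -> mean(OD1, OD2), class carboxylate
  asp <- cen$centers[cen$centers$resname == "ASP", ]
  od <- m$atoms[m$atoms$name %in% c("OD1", "OD2"), ]
  expect_equal(c(asp$x, asp$y, asp$z), c(mean(od$x), mean(od$y), mean(od$z)))
  expect_equal(asp$chem_class, "carboxylate")
  # ALA -> CB (terminal side-chain carbon), class aliphatic
  expect_equal(cen$centers$chem_class[cen$centers$resname == "ALA"], "aliphatic")
})

test_that("residues whose mapped atoms are all missing are skipped and reported", {
  m <- make_structure(data.frame(
    name = c("N", "C", "CA", "CB"), resname = c("GLY", "GLY", "ALA", "ALA"),
    resseq = c(1, 1, 2, 2), x = c(0, 1, 5, 6), y = 0, z = 0))
  cen <- centers_from_residues(m, residue_table(m))
  expect_equal(nrow(cen$centers), 1L)  # GLY has no CA -> skipped
  expect_equal(nrow(cen$miss), 1L)
  expect_equal(cen$miss$resname, "GLY")
})

test_that("holo-site extraction is inclusive at the cutoff and matches brute force", {
  mk <- function(dist) make_structure(data.frame(
    record = c("ATOM", "ATOM", "HETATM"),
    name = c("CA", "CA", "C1"), resname = c("GLY", "GLY", "LIG"),
    resseq = c(1, 2, 10), x = c(0, dist, 0), y = c(0, 0, 0), z = c(0, 0, 0)))
  expect_equal(extract_holo_site(mk(4.9), "LIG", 5.0)$resseq, c(1L, 2L))
  expect_equal(extract_holo_site(mk(5.1), "LIG", 5.0)$resseq, 1L)
  expect_equal(extract_holo_site(mk(5.0), "LIG", 5.0)$resseq, c(1L, 2L))
  expect_error(extract_holo_site(mk(4), "XYZ"), "not found")

  ref <- generate_reference(40, with_ligand = TRUE, seed = 11)
  got <- extract_holo_site(ref$model, "LIG", 5.0)
  expect_equal(sort(paste(got$chain, got$resseq)),
               oracle_holo_site(ref$model, "LIG", 5.0))
})

test_that("tanimoto obeys the set arithmetic and degenerate conventions", {
  z <- rep(0, 10)
  a <- z; a[c(2, 4, 6)] <- 2  # bits {2,4,6}
  b <- z; b[c(2, 4)] <- 2     # bits {2,4}
  expect_equal(tanimoto(a, a), 1)
  expect_equal(tanimoto(a, b), 2 / 3)
  expect_equal(tanimoto(z, z), 0)  # empty union convention
  expect_error(tanimoto(a, b[-1]), "mismatch")
  # always within [0,1], both modes
  set.seed(31)
  for (k in 1:20) {
    u <- stats::rnorm(50); v <- stats::rnorm(50)
    for (mode in c("binary", "continuous")) {
      tt <- tanimoto(u, v, mode = mode)
      expect_gte(tt, 0); expect_lte(tt, 1)
    }
  }
})

test_that("pair scores standardize the raw Tanimoto against the class background", {
  bg <- structure(list(pair_stats = list(amide = c(mu_t = 0.3, sigma_t = 0.1)),
                       threshold = 1.0), class = "background_stats")
  mk <- function(bits) { v <- rep(0, 20); v[bits] <- 2; v }
  # bit sets chosen so raw_t hits mu_t, mu_t + sigma, mu_t - 2 sigma exactly
  cases <- list(list(a = 1:6, b = c(1:3, 7:10), t = 0.3, s = 0),
                list(a = 1:3, b = c(1, 2, 4, 5), t = 0.4, s = -1),
                list(a = 1:5, b = c(1, 6:10), t = 0.1, s = 2))
  for (cs in cases) {
    ps <- pair_score(mk(cs$a), mk(cs$b), "amide", "amide", bg)
    expect_equal(ps$raw_t, cs$t, tolerance = 1e-12)
    expect_equal(ps$score, cs$s, tolerance = 1e-9)
  }
  expect_error(pair_score(mk(1:3), mk(1:3), "amide", "amine", bg),
               "not permissible")
  expect_error(pair_score(mk(1:3), mk(1:3), "hydroxyl", "hydroxyl", bg),
               "no calibrated background")
})

test_that("greedy matching reproduces the toy score matrix by hand", {
  S <- rbind(c(-2.0, -1.0), c(-1.5, -1.8), c(-0.2, -0.1))
  got <- pocketsim:::greedy_match(S, cutoff = -0.5)
  expect_equal(nrow(got), 2L)
  expect_equal(got[1, ], c(1L, 1L))  # A1-B1 at -2.0 first
  expect_equal(got[2, ], c(2L, 2L))  # then A2-B2 at -1.8; A3 above cutoff
  expect_equal(sum(S[got]), -3.8)
})

test_that("greedy matching equals the naive oracle on random matrices", {
  set.seed(77)
  for (k in 1:50) {
    na <- sample(2:6, 1); nb <- sample(2:6, 1)
    S <- matrix(stats::rnorm(na * nb, mean = -1), na, nb)
    S[sample(length(S), size = floor(length(S) / 4))] <- NA  # impermissible
    got <- pocketsim:::greedy_match(S, cutoff = -0.5)
    want <- oracle_greedy_match(S, cutoff = -0.5)
    expect_equal(unname(got), unname(want))
  }
})

make_fake_site <- function(Z, classes) {
  structure(list(Z = Z, chem_class = classes,
                 labels = sprintf("c%d", seq_len(nrow(Z))),
                 centers = NULL), class = "featurized_site")
}

make_fake_bg <- function(classes, mu = 0.2, sigma = 0.1) {
  ps <- lapply(classes, function(cl) c(mu_t = mu, sigma_t = sigma))
  names(ps) <- classes
  structure(list(pair_stats = ps, threshold = 1.0), class = "background_stats")
}

test_that("self-alignment matches every center and empty sites score zero", {
  set.seed(9)
  Z <- matrix(stats::rnorm(5 * 40, sd = 2), 5)
  cls <- c("amide", "amide", "hydroxyl", "amine", "amine")
  site <- make_fake_site(Z, cls)
  bg <- make_fake_bg(unique(cls))
  aln <- align_sites(site, site, bg)
  expect_equal(aln$n_matched, 5L)
  expect_equal(aln$matches$label_a, aln$matches$label_b)  # identity matching
  expect_equal(aln$total_score, 5 * -(1 - 0.2) / 0.1)
  expect_lte(aln$total_score, 0)

  empty <- make_fake_site(matrix(numeric(0), 0, 40), character(0))
  aln0 <- align_sites(site, empty, bg)
  expect_equal(aln0$n_matched, 0L)
  expect_equal(aln0$total_score, 0)
})

test_that("alignment total score is symmetric in its arguments", {
  set.seed(13)
  bg <- make_fake_bg(c("amide", "hydroxyl", "amine"))
  for (k in 1:20) {
    na <- sample(3:6, 1); nb <- sample(3:6, 1)
    A <- make_fake_site(matrix(stats::rnorm(na * 40, sd = 2), na),
                        sample(c("amide", "hydroxyl", "amine"), na, TRUE))
    B <- make_fake_site(matrix(stats::rnorm(nb * 40, sd = 2), nb),
                        sample(c("amide", "hydroxyl", "amine"), nb, TRUE))
    expect_equal(align_sites(A, B, bg)$total_score,
                 align_sites(B, A, bg)$total_score)
  }
})

test_that("self-alignment is at least as similar as alignment to a perturbed copy", {
  set.seed(21)
  bg <- make_fake_bg(c("amide", "hydroxyl"))
  Z <- matrix(stats::rnorm(6 * 40, sd = 2), 6)
  cls <- rep(c("amide", "hydroxyl"), 3)
  A <- make_fake_site(Z, cls)
  self_score <- align_sites(A, A, bg)$total_score
  for (k in 1:10) {
    B <- make_fake_site(Z + matrix(stats::rnorm(length(Z), sd = 0.8), nrow(Z)), cls)
    expect_lte(self_score, align_sites(A, B, bg)$total_score)
  }
})
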