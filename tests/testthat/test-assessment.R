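fake_records <- function(pf, source = sprintf("S%02d", seq_along(pf)),
                         midx = rep(1L, length(pf)), gdt = NULL,
                         rmsd = NULL) {
  data.frame(target_id = "T", site_id = "T-s1", source_id = source,
             model_index = midx, pf_score = pf,
             gdt_ts = if (is.null(gdt)) rev(seq_along(pf)) else gdt,
             tm = 0.5, rmsd_global = if (is.null(rmsd)) 3 else rmsd,
             rmsd_local = 1, stringsAsFactors = FALSE)
}

test_that("z-scores use the population SD and normalize the selected set", {
  r <- fake_records(c(2, 4, 6))
  z <- zscore_records(r, "all_models")
  expect_equal(z$pf_zscore, c(-1.224744871, 0, 1.224744871), tolerance = 1e-8)
  set.seed(1)
  r2 <- fake_records(stats::rnorm(20))
  z2 <- zscore_records(r2)
  expect_equal(mean(z2$pf_zscore), 0, tolerance = 1e-9)
  expect_equal(sqrt(mean(z2$pf_zscore^2)), 1, tolerance = 1e-9)
  expect_error(zscore_records(fake_records(rep(1, 5))), "zero variance")
  expect_error(zscore_records(fake_records(1:2)), ">= 3")
})

test_that("model-1 mode restricts to each predictor's declared best model", {
  r <- fake_records(c(1, 2, 3, 4, 5, 6, 8, 9, 10),
                    source = rep(c("A", "B", "C"), each = 3),
                    midx = rep(1:3, 3))
  z <- zscore_records(r, "model_1")
  expect_equal(nrow(z), 3L)
  expect_true(all(z$model_index == 1L))
  expect_equal(z$pf_score, c(1, 4, 8))
  za <- zscore_records(r, "all_models")
  expect_equal(nrow(za), 9L)
})

test_that("rank_by produces dense deterministic ranks in both directions", {
  r <- fake_records(c(-2, -1, 0))
  r$pf_zscore <- r$pf_score
  expect_equal(rank_by(r, "pf_zscore")$rank_functional, c(1L, 2L, 3L))
  expect_equal(rank_by(r, "pf_zscore", direction = "desc")$rank_functional,
               c(3L, 2L, 1L))
  # gdt ranks: higher is better by default
  expect_equal(rank_by(r, "gdt_ts")$rank_structural, c(1L, 2L, 3L))
  # ties break by (source_id, model_index), deterministically
  rt <- fake_records(c(1, 1, 1), source = c("C", "A", "B"))
  rt$pf_zscore <- rt$pf_score
  expect_equal(rank_by(rt, "pf_zscore")$rank_functional, c(3L, 1L, 2L))
})

test_that("spearman_rho matches the hand formula and the rank-formula oracle", {
  expect_equal(spearman_rho(1:5, 1:5), 1)
  expect_equal(spearman_rho(1:5, 5:1), -1)
  expect_equal(spearman_rho(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  set.seed(6)
  for (k in 1:20) {
    x <- sample(100, 8); y <- sample(100, 8)  # tie-free
    expect_equal(spearman_rho(x, y), oracle_spearman(x, y), tolerance = 1e-12)
  }
  expect_error(spearman_rho(rep(1, 4), 1:4), "zero rank variance")
  expect_error(spearman_rho(1:2, 1:2), ">= 3")
})

test_that("the RMSD filter is inclusive at the cutoff and gates on > min_count", {
  r <- fake_records(stats::rnorm(17), rmsd = c(rep(4, 12), rep(6, 5)))
  keep <- filter_models_by_rmsd(r)
  expect_equal(nrow(keep), 12L)
  expect_true(attr(keep, "report")$eligible)

  r8 <- fake_records(stats::rnorm(8), rmsd = rep(4, 8))
  out <- filter_models_by_rmsd(r8)
  expect_equal(nrow(out), 0L)
  expect_false(attr(out, "report")$eligible)
  expect_equal(attr(out, "report")$n_within, 8L)

  rb <- fake_records(stats::rnorm(12), rmsd = rep(5.0, 12))  # boundary
  expect_equal(nrow(filter_models_by_rmsd(rb)), 12L)
  # pure selection: input untouched
  expect_equal(nrow(r), 17L)
})

test_that("top_k selects in rank order without padding", {
  set.seed(2)
  r <- fake_records(stats::rnorm(40))
  r <- zscore_records(r)
  t30 <- top_k(r)
  expect_equal(nrow(t30), 30L)
  expect_equal(t30$pf_zscore, sort(r$pf_zscore)[1:30])
  expect_equal(nrow(top_k(r[1:20, ])), 20L)
  # deterministic boundary tie handling
  rt <- fake_records(rep(c(-1, 0), each = 4), source = LETTERS[1:8])
  rt$pf_zscore <- rt$pf_score
  expect_equal(top_k(rt, k = 6)$source_id, c("A", "B", "C", "D", "E", "F"))
})

test_that("exposure classes partition RelAcc at 0.09 and 0.36", {
  expect_equal(as.character(classify_exposure(c(0.05, 0.09, 0.20, 0.36, 0.5))),
               c("buried", "intermediate", "intermediate", "exposed", "exposed"))
  expect_equal(as.character(classify_exposure(0.0899999)), "buried")
  expect_equal(as.character(classify_exposure(0.3599999)), "intermediate")
  expect_error(classify_exposure(-0.01), "negative")
})

test_that("variant metrics match direct formulas", {
  ref <- c(0.2, 0.5)
  perfect <- rbind(ref, ref)
  m <- variant_site_metrics(perfect, ref, pred_ss = rbind(c("H", "E"), c("H", "E")),
                            ref_ss = c("H", "E"))
  expect_equal(m$relacc_std, 0)
  expect_equal(m$acc_err, 0)
  expect_equal(m$frac_ss_correct, 1)
  expect_equal(m$frac_exposure_correct, 1)

  two <- variant_site_metrics(matrix(c(0.1, 0.3), ncol = 1), 0.2)
  expect_equal(two$relacc_std, 0.1)
  expect_equal(two$acc_err, 0.1)

  wrong <- variant_site_metrics(rbind(c(0.5, 0.01), c(0.5, 0.01)), c(0.05, 0.5))
  expect_equal(wrong$frac_exposure_correct, 0)
  expect_error(variant_site_metrics(perfect, c(0.2, 0.5, 0.7)), "mismatch")
})

test_that("patch aggregation averages z-scores per target and model", {
  r <- data.frame(target_id = "T1", site_id = c("p1", "p2"),
                  source_id = "S01", model_index = 1L,
                  pf_zscore = c(-1, -2), stringsAsFactors = FALSE)
  agg <- aggregate_patches(r)
  expect_equal(agg$pf_zscore_mean, -1.5)
  expect_equal(agg$n_patches, 2L)
  single <- aggregate_patches(r[1, ])
  expect_equal(single$pf_zscore_mean, -1)
  # four synthetic patches: mean equals direct recomputation
  r4 <- data.frame(target_id = "T2", site_id = paste0("p", 1:4),
                   source_id = "S02", model_index = 1L,
                   pf_zscore = c(-0.4, -1.1, 0.3, -2.2), stringsAsFactors = FALSE)
  expect_equal(aggregate_patches(r4)$pf_zscore_mean, mean(r4$pf_zscore))
})

test_that("score_ensemble scores identical models at the self-alignment score", {
  ref <- generate_reference(40, seed = 31)
  cen <- centers_from_residues(ref$model, residue_table(ref$model))$centers
  vecs <- lapply(seq_len(nrow(cen)), function(i)
    featurize(atom_properties(ref$model), c(cen$x[i], cen$y[i], cen$z[i])))
  bg <- build_background(vecs, cen$chem_class, n_pairs = 100, seed = 1)
  clones <- lapply(1:3, function(i) {
    m <- ref$model; m$source_id <- sprintf("S%02d", i); m$model_index <- 1L; m
  })
  rec <- score_ensemble(ref$model, ref$site, clones, bg, structural = FALSE)
  expect_equal(nrow(rec), 3L)
  expect_equal(length(unique(rec$pf_score)), 1L)
  # self-alignment value
  sel <- resolve_selection(ref$model, ref$site$selectors)$hits
  sc <- centers_from_residues(ref$model, sel)$centers
  fs <- featurize_site(ref$model, sc, bg)
  expect_equal(rec$pf_score[1], align_sites(fs, fs, bg)$total_score)
})

test_that("models missing most of the site are excluded and reported", {
  ref <- generate_reference(40, seed = 31)
  cen <- centers_from_residues(ref$model, residue_table(ref$model))$centers
  vecs <- lapply(seq_len(nrow(cen)), function(i)
    featurize(atom_properties(ref$model), c(cen$x[i], cen$y[i], cen$z[i])))
  bg <- build_background(vecs, cen$chem_class, n_pairs = 100, seed = 1)
  gutted <- ref$model
  drop <- ref$site$selectors$resseq[-(1:2)]  # keep only 2 of 8 site residues
  gutted$atoms <- gutted$atoms[!(gutted$atoms$resseq %in% drop), ]
  gutted$source_id <- "S99"; gutted$model_index <- 1L
  ok <- ref$model; ok$source_id <- "S01"; ok$model_index <- 1L
  rec <- score_ensemble(ref$model, ref$site, list(ok, gutted), bg,
                        structural = FALSE)
  expect_equal(nrow(rec), 1L)
  expect_equal(attr(rec, "excluded"), "S99_1")
  expect_error(score_ensemble(ref$model, ref$site, list(gutted), bg,
                              structural = FALSE), "at least 3")
})
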