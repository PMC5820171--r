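# Ensemble assessment: site-similarity scores per predicted model, z-scoring
# in "all-models" and "model-1" modes, functional vs structural ranking and
# rank correlation, the 5 A / top-30 selection rules, exposure-status
# classification, and the variant-site accessibility metrics.

#' Score a model ensemble against the experimental site
#'
#' For each model, the site residues are resolved by author numbering,
#' converted to functional centers, featurized, standardized against `bg`,
#' and aligned to the reference site; the model's functional score
#' (`pf_score`) is the alignment total (more negative = more similar).
#' Structural scores are attached. Models missing more than
#' `max_missing_frac` of the site residues are excluded and reported via the
#' `"excluded"` attribute.
#'
#' @param reference experimental `structure_model`.
#' @param site a `site_definition`.
#' @param models list of predicted `structure_model`s.
#' @param bg a `background_stats` object.
#' @param manifest,scheme featurization parameters.
#' @param cutoff alignment significance cutoff.
#' @param max_missing_frac exclusion threshold on missing site residues
#'   (default 0.5).
#' @param structural compute GDT/TM/RMSD columns (default TRUE).
#' @return data.frame of assessment records (one row per retained model) with
#'   attribute `"excluded"` (character vector of model ids).
#' @export
score_ensemble <- function(reference, site, models, bg,
                           manifest = default_manifest(),
                           scheme = shell_scheme(), cutoff = -0.5,
                           max_missing_frac = 0.5, structural = TRUE) {
  sel <- resolve_selection(reference, site$selectors)
  assert_that(nrow(sel$hits) >= 3L, "site unresolvable in reference")
  ref_centers <- centers_from_residues(reference, sel$hits)$centers
  ref_site <- featurize_site(reference, ref_centers, bg, manifest, scheme)
  n_site <- nrow(site$selectors)
  rows <- list(); excluded <- character()
  any_ok <- FALSE
  for (m in models) {
    mid <- sprintf("%s_%d", m$source_id, m$model_index)
    msel <- resolve_selection(m, site$selectors)
    n_missing <- nrow(msel$miss)
    mc <- centers_from_residues(m, msel$hits)$centers
    if (n_missing / n_site > max_missing_frac || nrow(mc) < 3L) {
      excluded <- c(excluded, mid)
      next
    }
    any_ok <- TRUE
    msite <- featurize_site(m, mc, bg, manifest, scheme)
    aln <- align_sites(ref_site, msite, bg, cutoff = cutoff)
    ss <- if (structural) structural_scores(m, reference, site)
          else list(gdt_ts = NA_real_, tm = NA_real_,
                    rmsd_global = NA_real_, rmsd_local = NA_real_)
    rows[[length(rows) + 1L]] <- data.frame(
      target_id = site$target_id, site_id = site$site_id,
      source_id = m$source_id, model_index = m$model_index,
      pf_score = aln$total_score, n_matched = aln$n_matched,
      gdt_ts = ss$gdt_ts, tm = ss$tm, rmsd_global = ss$rmsd_global,
      rmsd_local = ss$rmsd_local, stringsAsFactors = FALSE)
  }
  assert_that(any_ok, "no model retains at least 3 site centers")
  records <- do.call(rbind, rows)
  rownames(records) <- NULL
  attr(records, "excluded") <- excluded
  records
}

#' Z-score functional scores within an evaluation set
#'
#' "all_models" uses every record; "model_1" restricts to each predictor's
#' self-declared best model (`model_index == 1`). The z-score uses the
#' population standard deviation, so the selected set has mean 0 and SD 1.
#'
#' @param records assessment records from [score_ensemble()].
#' @param mode "all_models" or "model_1".
#' @return the selected records with a `pf_zscore` column.
#' @export
zscore_records <- function(records, mode = c("all_models", "model_1")) {
  mode <- match.arg(mode)
  sel <- if (mode == "model_1") records[records$model_index == 1L, , drop = FALSE]
         else records
  assert_that(nrow(sel) >= 3L, "need >= 3 records to z-score, got %d", nrow(sel))
  s <- pop_sd(sel$pf_score)
  assert_that(s > 0, "zero variance: all functional scores identical")
  sel$pf_zscore <- (sel$pf_score - mean(sel$pf_score)) / s
  rownames(sel) <- NULL
  sel
}

#' Rank records by a key
#'
#' Dense ranks 1..N. For functional keys (`pf_score`, `pf_zscore`,
#' `rmsd_global`, `rmsd_local`) lower is better; for `gdt_ts`/`tm` higher is
#' better; override with `direction`. Ties break deterministically by
#' (source_id, model_index).
#'
#' @param records assessment records.
#' @param key column to rank by.
#' @param direction "asc" (rank 1 = smallest) or "desc"; default inferred
#'   from the key.
#' @param rank_col name of the added rank column.
#' @return records with the rank column added, original row order preserved.
#' @export
rank_by <- function(records, key, direction = NULL, rank_col = NULL) {
  assert_that(key %in% names(records), "key '%s' not present", key)
  if (is.null(direction))
    direction <- if (key %in% c("gdt_ts", "tm")) "desc" else "asc"
  v <- records[[key]]
  if (direction == "desc") v <- -v
  ord <- order(v, records$source_id, records$model_index)
  ranks <- integer(nrow(records))
  ranks[ord] <- seq_len(nrow(records))
  if (is.null(rank_col))
    rank_col <- if (key %in% c("pf_score", "pf_zscore")) "rank_functional"
                else "rank_structural"
  records[[rank_col]] <- ranks
  records
}

#' Spearman rank correlation
#'
#' Pearson correlation of rank-transformed values, average ranks for ties.
#'
#' @param x,y numeric vectors of equal length `>= 3`.
#' @return coefficient in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  assert_that(length(x) == length(y), "length mismatch")
  assert_that(length(x) >= 3L, "need >= 3 observations")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  sx <- pop_sd(rx); sy <- pop_sd(ry)
  assert_that(sx > 0 && sy > 0, "zero rank variance")
  mean((rx - mean(rx)) * (ry - mean(ry))) / (sx * sy)
}

#' Correlate functional vs structural rankings of an ensemble
#'
#' @param records z-scored assessment records.
#' @param structural_key structural column ("gdt_ts", "tm", "rmsd_global").
#' @param mode evaluation mode label for the report.
#' @return data.frame row: site_id, mode, coefficient, n_models.
#' @export
correlation_report <- function(records, structural_key = "gdt_ts",
                               mode = "all_models") {
  records <- rank_by(records, "pf_zscore")
  records <- rank_by(records, structural_key)
  data.frame(site_id = records$site_id[1], mode = mode,
             coefficient = spearman_rho(records$rank_functional,
                                        records$rank_structural),
             n_models = nrow(records), stringsAsFactors = FALSE)
}

#' Filter models by global RMSD and check site eligibility
#'
#' Keeps records with `rmsd_global <= max_rmsd` (inclusive). The site is
#' eligible only when strictly more than `min_count` predictions survive;
#' otherwise an empty set is returned with the counts in the `"report"`
#' attribute.
#'
#' @param records assessment records.
#' @param max_rmsd RMSD cutoff in Angstrom (default 5.0).
#' @param min_count eligibility threshold (default 10; "more than 10").
#' @return the retained records, or an empty data.frame if ineligible; both
#'   carry a `"report"` attribute.
#' @export
filter_models_by_rmsd <- function(records, max_rmsd = 5.0, min_count = 10L) {
  keep <- records[records$rmsd_global <= max_rmsd, , drop = FALSE]
  eligible <- nrow(keep) > min_count
  out <- if (eligible) keep else records[0, , drop = FALSE]
  attr(out, "report") <- list(n_total = nrow(records), n_within = nrow(keep),
                              eligible = eligible, max_rmsd = max_rmsd,
                              min_count = min_count)
  out
}

#' Select the top k models by a key
#'
#' @param records assessment records.
#' @param k number to select (default 30).
#' @param key ranking key (default `pf_zscore`, most negative first).
#' @param direction see [rank_by()].
#' @return the first `k` records in rank order (all records if fewer).
#' @export
top_k <- function(records, k = 30L, key = "pf_zscore", direction = NULL) {
  ranked <- rank_by(records, key, direction, rank_col = ".rank")
  out <- ranked[order(ranked$.rank), , drop = FALSE]
  out$.rank <- NULL
  utils::head(out, k)
}

#' Classify residue exposure from relative solvent accessibility
#'
#' buried: RelAcc < 0.09; intermediate: 0.09 <= RelAcc < 0.36; exposed:
#' RelAcc >= 0.36.
#'
#' @param relacc numeric vector of relative accessibilities, `>= 0`.
#' @return factor with levels buried/intermediate/exposed.
#' @export
classify_exposure <- function(relacc) {
  assert_that(all(relacc >= 0), "negative relative accessibility")
  cls <- ifelse(relacc < 0.09, "buried",
                ifelse(relacc < 0.36, "intermediate", "exposed"))
  factor(cls, levels = c("buried", "intermediate", "exposed"))
}

#' Accessibility and secondary-structure metrics at variant sites
#'
#' Inputs are consumed as given (e.g. from an external accessibility
#' assignment); the package does not compute solvent accessibility itself.
#'
#' @param pred_relacc models x residues matrix of predicted relative
#'   accessibilities.
#' @param ref_relacc reference relative accessibilities (length = residues).
#' @param pred_ss models x residues matrix of predicted secondary-structure
#'   labels (character).
#' @param ref_ss reference labels.
#' @return list with `relacc_std` (mean across-model population SD),
#'   `acc_err` (pooled RMSD of predicted vs reference RelAcc),
#'   `frac_ss_correct`, `frac_exposure_correct`.
#' @export
variant_site_metrics <- function(pred_relacc, ref_relacc, pred_ss = NULL,
                                 ref_ss = NULL) {
  pred_relacc <- as.matrix(pred_relacc)
  assert_that(ncol(pred_relacc) == length(ref_relacc),
              "residue count mismatch: %d vs %d", ncol(pred_relacc),
              length(ref_relacc))
  assert_that(nrow(pred_relacc) >= 2L, "need >= 2 models for the SD metric")
  relacc_std <- mean(apply(pred_relacc, 2, pop_sd))
  err <- sweep(pred_relacc, 2, ref_relacc)
  acc_err <- sqrt(mean(err^2))
  exp_ref <- as.character(classify_exposure(ref_relacc))
  exp_pred <- matrix(as.character(classify_exposure(as.vector(pred_relacc))),
                     nrow = nrow(pred_relacc))  # models x residues
  frac_exposure <- mean(t(exp_pred) == exp_ref)
  frac_ss <- NA_real_
  if (!is.null(pred_ss)) {
    pred_ss <- as.matrix(pred_ss)
    assert_that(ncol(pred_ss) == length(ref_ss), "SS length mismatch")
    frac_ss <- mean(t(pred_ss) == matrix(ref_ss, nrow = length(ref_ss),
                                         ncol = nrow(pred_ss)))
  }
  list(relacc_std = relacc_std, acc_err = acc_err,
       frac_ss_correct = frac_ss, frac_exposure_correct = frac_exposure)
}

#' Average the functional z-scores of a target's critical patches
#'
#' Several patches of one target (e.g. patches around individual mutations)
#' are summarized as the arithmetic mean of their z-scores per model.
#'
#' @param records z-scored records covering one or more patch `site_id`s.
#' @return data.frame (target_id, source_id, model_index, pf_zscore_mean,
#'   n_patches).
#' @export
aggregate_patches <- function(records) {
  key <- interaction(records$target_id, records$source_id,
                     records$model_index, drop = TRUE)
  agg <- lapply(split(records, key), function(g)
    data.frame(target_id = g$target_id[1], source_id = g$source_id[1],
               model_index = g$model_index[1],
               pf_zscore_mean = mean(g$pf_zscore), n_patches = nrow(g),
               stringsAsFactors = FALSE))
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out
}
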