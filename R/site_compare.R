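# Functional sites: residue-derived center points with chemistry classes,
# holo-site extraction around a bound ligand, Tanimoto scoring of
# standardized microenvironment pairs, and the greedy mutual-best-match
# alignment whose summed score is the site similarity (more negative =
# more similar than the random background).

#' Define a functional site
#'
#' @param target_id target identifier.
#' @param site_id site identifier.
#' @param category "holo", "apo" or "patch".
#' @param selectors residue selectors ([residue_selector()] rows).
#' @param ligand hetero residue code (required for holo sites).
#' @return object of class `site_definition`.
#' @export
site_definition <- function(target_id, site_id, category, selectors,
                            ligand = NULL) {
  category <- match.arg(category, c("holo", "apo", "patch"))
  assert_that(nrow(selectors) >= 1L, "a site needs at least one residue")
  if (category == "holo")
    assert_that(!is.null(ligand) && nzchar(ligand),
                "holo sites must carry a ligand code")
  structure(list(target_id = target_id, site_id = site_id,
                 category = category, selectors = selectors, ligand = ligand),
            class = "site_definition")
}

#' Derive functional centers from residues
#'
#' Each residue contributes one center via a fixed mapping (e.g. SER -> OG,
#' ASP -> mean(OD1, OD2), PHE/TYR/TRP -> ring centroid, fallback -> CA) with
#' a chemistry class. If some mapped atoms are missing the mean of those
#' present is used; residues with all mapped atoms missing are skipped and
#' reported.
#'
#' @param model a `structure_model`.
#' @param residues residue key table (e.g. from [resolve_selection()]).
#' @return list with `centers` (data.frame: chain, resseq, icode, resname,
#'   label, chem_class, x, y, z) and `miss` (skipped residues).
#' @export
centers_from_residues <- function(model, residues) {
  a <- model$atoms[model$atoms$record == "ATOM", ]
  out <- list(); miss <- list()
  for (i in seq_len(nrow(residues))) {
    r <- residues[i, ]
    rule <- center_rule(r$resname)
    ra <- a[a$chain == r$chain & a$resseq == r$resseq & a$icode == r$icode &
              a$name %in% rule$atoms, , drop = FALSE]
    if (nrow(ra) == 0L) { miss[[length(miss) + 1L]] <- r; next }
    out[[length(out) + 1L]] <- data.frame(
      chain = r$chain, resseq = r$resseq, icode = r$icode, resname = r$resname,
      label = sprintf("%s%d%s:%s", r$chain, r$resseq, r$icode, r$resname),
      chem_class = rule$class,
      x = mean(ra$x), y = mean(ra$y), z = mean(ra$z),
      stringsAsFactors = FALSE)
  }
  list(centers = if (length(out)) do.call(rbind, out) else
         data.frame(chain = character(), resseq = integer(), icode = character(),
                    resname = character(), label = character(),
                    chem_class = character(), x = numeric(), y = numeric(),
                    z = numeric()),
       miss = if (length(miss)) do.call(rbind, miss) else residues[0, ])
}

#' Extract a holo site around a bound ligand
#'
#' All polymer residues with at least one atom within `cutoff` (inclusive) of
#' any atom of the named hetero residue, in chain/sequence order.
#'
#' @param model a `structure_model`.
#' @param ligand_code hetero residue name (e.g. "HEM").
#' @param cutoff distance cutoff in Angstrom (default 5.0).
#' @return residue key table of the pocket residues.
#' @export
extract_holo_site <- function(model, ligand_code, cutoff = 5.0) {
  het <- model$atoms[model$atoms$record == "HETATM" &
                       model$atoms$resname == toupper(ligand_code), ]
  assert_that(nrow(het) > 0L, "ligand '%s' not found among hetero residues",
              ligand_code)
  poly <- model$atoms[model$atoms$record == "ATOM", ]
  assert_that(nrow(poly) > 0L, "no polymer atoms")
  lig_xyz <- cbind(het$x, het$y, het$z)
  near <- logical(nrow(poly))
  for (j in seq_len(nrow(lig_xyz))) {
    d <- dist_to_point(cbind(poly$x, poly$y, poly$z), lig_xyz[j, ])
    near <- near | (d <= cutoff)
  }
  keys <- unique(residue_key(poly$chain, poly$resseq, poly$icode)[near])
  res <- residue_table(model)
  hit <- res[residue_key(res$chain, res$resseq, res$icode) %in% keys, , drop = FALSE]
  hit[order(hit$chain, hit$resseq, hit$icode), , drop = FALSE]
}

#' Tanimoto similarity between two standardized microenvironments
#'
#' Binary mode (default): bit i is set iff `z_i > threshold`; the similarity
#' is `|A & B| / |A | B|`, defined as 0 when both bit sets are empty.
#' Continuous mode applies the min/max Tanimoto to the rectified excesses
#' `max(z - threshold, 0)`.
#'
#' @param a,b standardized numeric vectors of equal length.
#' @param threshold binarization threshold (default 1.0 background SD).
#' @param mode "binary" or "continuous".
#' @return similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b, threshold = 1.0, mode = c("binary", "continuous")) {
  mode <- match.arg(mode)
  assert_that(length(a) == length(b),
              "length mismatch: %d vs %d", length(a), length(b))
  if (mode == "binary") {
    A <- a > threshold; B <- b > threshold
    u <- sum(A | B)
    if (u == 0L) return(0)
    sum(A & B) / u
  } else {
    ra <- pmax(a - threshold, 0); rb <- pmax(b - threshold, 0)
    u <- sum(pmax(ra, rb))
    if (u == 0) return(0)
    sum(pmin(ra, rb)) / u
  }
}

#' Score one permissible microenvironment pair
#'
#' Only same-chemistry-class pairs are permissible. The raw Tanimoto is
#' standardized against the class background: `score = -(raw_t - mu_t) /
#' sigma_t`, so similarity above background is negative.
#'
#' @param za,zb standardized vectors.
#' @param class_a,class_b chemistry classes of the two centers.
#' @param bg a `background_stats` object.
#' @param threshold,mode passed to [tanimoto()]; `threshold` defaults to the
#'   background's calibration threshold.
#' @return list with `raw_t` and `score`.
#' @export
pair_score <- function(za, zb, class_a, class_b, bg,
                       threshold = bg$threshold, mode = "binary") {
  assert_that(identical(class_a, class_b),
              "pair not permissible: classes '%s' vs '%s'", class_a, class_b)
  st <- bg$pair_stats[[class_a]]
  assert_that(!is.null(st), "class '%s' has no calibrated background", class_a)
  raw_t <- tanimoto(za, zb, threshold = threshold, mode = mode)
  list(raw_t = raw_t, score = -(raw_t - st[["mu_t"]]) / st[["sigma_t"]])
}

#' Featurize a functional site
#'
#' @param model a `structure_model`.
#' @param centers center table from [centers_from_residues()].
#' @param bg background used to standardize; `NULL` leaves vectors raw.
#' @param manifest,scheme featurization parameters.
#' @return object of class `featurized_site`: list with `Z` (n x 480 matrix,
#'   standardized if `bg` given), `chem_class`, `labels`, `centers`.
#' @export
featurize_site <- function(model, centers, bg = NULL,
                           manifest = default_manifest(),
                           scheme = shell_scheme()) {
  ap <- atom_properties(model, manifest)
  n <- nrow(centers)
  Z <- matrix(0, n, scheme$n_shells * ncol(ap$P))
  for (i in seq_len(n)) {
    fv <- featurize(ap, c(centers$x[i], centers$y[i], centers$z[i]),
                    scheme = scheme, center_label = centers$label[i])
    Z[i, ] <- if (is.null(bg)) fv$values else standardize(fv, bg)
  }
  structure(list(Z = Z, chem_class = centers$chem_class,
                 labels = centers$label, centers = centers),
            class = "featurized_site")
}

# greedy global matching on a score matrix: repeatedly accept the lowest
# remaining permissible (non-NA) pair while its score is at or below cutoff.
# Tie-breaks are deterministic and mirrored under transposition: unordered
# index pair, then sorted label pair, then row index. Returns a k x 2 matrix
# of (row, col) indices in acceptance order.
greedy_match <- function(S, cutoff, labels_a = as.character(seq_len(nrow(S))),
                         labels_b = as.character(seq_len(ncol(S)))) {
  picked <- matrix(integer(0), ncol = 2)
  free_a <- rep(TRUE, nrow(S)); free_b <- rep(TRUE, ncol(S))
  repeat {
    W <- S
    W[!free_a, ] <- NA; W[, !free_b] <- NA
    if (all(is.na(W))) break
    best <- min(W, na.rm = TRUE)
    if (best > cutoff) break
    cand <- which(W == best, arr.ind = TRUE)
    if (nrow(cand) > 1L) {
      key <- apply(cand, 1, function(ij) {
        lab <- sort(c(labels_a[ij[1]], labels_b[ij[2]]))
        sprintf("%06d|%06d|%s|%s|%06d", min(ij), max(ij), lab[1], lab[2], ij[1])
      })
      cand <- cand[order(key)[1], , drop = FALSE]
    }
    picked <- rbind(picked, cand[1, , drop = FALSE])
    free_a[cand[1, 1]] <- FALSE; free_b[cand[1, 2]] <- FALSE
  }
  dimnames(picked) <- NULL
  picked
}

#' Align two featurized sites by greedy mutual best match
#'
#' All permissible (same-class) pairs are scored exhaustively; the globally
#' best (most negative) remaining pair is accepted while its score is at or
#' below `cutoff`, removing both centers. Tie-breaks are deterministic and
#' mirrored, so `align_sites(A, B)` and `align_sites(B, A)` produce the same
#' total score. The site similarity is the sum of accepted pair scores.
#'
#' @param site_a,site_b `featurized_site` objects built with the same
#'   manifest/scheme/background.
#' @param bg a `background_stats` object.
#' @param cutoff significance cutoff (default -0.5): pairs scoring above it
#'   are not matched.
#' @param threshold,mode passed to [tanimoto()].
#' @return object of class `site_alignment`: `matches` (data.frame label_a,
#'   label_b, chem_class, raw_t, score), `total_score`, `n_matched`.
#' @export
align_sites <- function(site_a, site_b, bg, cutoff = -0.5,
                        threshold = bg$threshold, mode = "binary") {
  na <- nrow(site_a$Z); nb <- nrow(site_b$Z)
  empty <- structure(list(matches = data.frame(label_a = character(),
                                               label_b = character(),
                                               chem_class = character(),
                                               raw_t = numeric(),
                                               score = numeric()),
                          total_score = 0, n_matched = 0L),
                     class = "site_alignment")
  if (na == 0L || nb == 0L) return(empty)
  S <- matrix(NA_real_, na, nb)
  Traw <- matrix(NA_real_, na, nb)
  for (i in seq_len(na)) for (j in seq_len(nb)) {
    if (!identical(site_a$chem_class[i], site_b$chem_class[j])) next
    ps <- pair_score(site_a$Z[i, ], site_b$Z[j, ], site_a$chem_class[i],
                     site_b$chem_class[j], bg, threshold = threshold,
                     mode = mode)
    S[i, j] <- ps$score; Traw[i, j] <- ps$raw_t
  }
  picked <- greedy_match(S, cutoff, site_a$labels, site_b$labels)
  if (nrow(picked) == 0L) return(empty)
  m <- data.frame(label_a = site_a$labels[picked[, 1]],
                  label_b = site_b$labels[picked[, 2]],
                  chem_class = site_a$chem_class[picked[, 1]],
                  raw_t = Traw[cbind(picked[, 1], picked[, 2])],
                  score = S[cbind(picked[, 1], picked[, 2])],
                  stringsAsFactors = FALSE)
  structure(list(matches = m, total_score = sum(m$score),
                 n_matched = nrow(m)),
            class = "site_alignment")
}

#' @export
print.site_alignment <- function(x, ...) {
  cat(sprintf("site_alignment: %d matched pairs, total score %.4f\n",
              x$n_matched, x$total_score))
  if (x$n_matched > 0L) print(x$matches, row.names = FALSE)
  invisible(x)
}

#' Write an alignment report as TSV
#'
#' One row per matched pair plus a trailing summary row.
#'
#' @param alignment a `site_alignment`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_alignment_tsv <- function(alignment, path) {
  m <- alignment$matches
  summary_row <- data.frame(label_a = "TOTAL", label_b = "",
                            chem_class = "", raw_t = NA_real_,
                            score = alignment$total_score,
                            stringsAsFactors = FALSE)
  utils::write.table(rbind(m, summary_row), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
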