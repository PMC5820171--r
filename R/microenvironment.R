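# Microenvironment featurization: 80 physicochemical properties aggregated
# over six concentric spherical shells (7.5 A total radius) around a
# functional center, plus background statistics used to standardize the
# descriptors and calibrate the raw Tanimoto similarity.

#' Concentric shell scheme
#'
#' Shells are half-open `[k*w, (k+1)*w)` for `k = 0..n_shells-1`; atoms at or
#' beyond `radius` are outside the microenvironment.
#'
#' @param n_shells number of shells (default 6).
#' @param shell_width shell width in Angstrom (default 1.25).
#' @return list with `n_shells`, `shell_width`, `radius`.
#' @export
shell_scheme <- function(n_shells = 6L, shell_width = 1.25) {
  assert_that(n_shells >= 1L && shell_width > 0, "invalid shell scheme")
  list(n_shells = as.integer(n_shells), shell_width = shell_width,
       radius = n_shells * shell_width)
}

#' Assign a distance to a shell
#'
#' @param distance distance(s) from the center, Angstrom, `>= 0`.
#' @param scheme a [shell_scheme()].
#' @return integer 0-based shell index, `NA` for distances at or beyond the
#'   sphere radius.
#' @export
assign_shell <- function(distance, scheme = shell_scheme()) {
  assert_that(all(distance >= 0), "negative distance")
  k <- floor(distance / scheme$shell_width)
  k[distance >= scheme$radius] <- NA_integer_
  as.integer(k)
}

#' Featurize a microenvironment
#'
#' Computes the shell-major descriptor (index = shell x 80 + property) around
#' `center`. Count/sum rules aggregate by summation; mean rules average over
#' the atoms in the shell and are 0 when the shell is empty. Only polymer
#' heavy atoms contribute.
#'
#' @param model a `structure_model`, or a precomputed [atom_properties()]
#'   object (preferred when featurizing many centers of one structure).
#' @param center numeric 3-vector, Angstrom.
#' @param manifest property manifest; ignored when `model` is already an
#'   `atom_properties` object.
#' @param scheme a [shell_scheme()].
#' @param center_label label stored on the vector.
#' @return object of class `feature_vector`: list with `values` (named numeric
#'   vector of length `n_shells * 80`), `center`, `center_label`.
#' @export
featurize <- function(model, center, manifest = default_manifest(),
                      scheme = shell_scheme(), center_label = "") {
  ap <- if (inherits(model, "atom_properties")) model
        else atom_properties(model, manifest)
  assert_that(length(center) == 3L && all(is.finite(center)),
              "center must be a finite 3-vector")
  nprop <- ncol(ap$P)
  vals <- numeric(scheme$n_shells * nprop)
  names(vals) <- as.vector(vapply(seq_len(scheme$n_shells) - 1L, function(k)
    paste0("s", k, "_", ap$names), character(nprop)))
  if (nrow(ap$xyz) > 0L) {
    d <- dist_to_point(ap$xyz, center)
    shell <- assign_shell(d, scheme)
    is_mean <- ap$kind == "mean"
    for (k in seq_len(scheme$n_shells) - 1L) {
      idx <- which(!is.na(shell) & shell == k)
      if (length(idx) == 0L) next
      agg <- colSums(ap$P[idx, , drop = FALSE])
      if (any(is_mean)) agg[is_mean] <- agg[is_mean] / length(idx)
      vals[k * nprop + seq_len(nprop)] <- agg
    }
  }
  structure(list(values = vals, center = as.numeric(center),
                 center_label = center_label),
            class = "feature_vector")
}

feature_matrix <- function(vectors) {
  if (is.matrix(vectors)) return(vectors)
  if (inherits(vectors, "feature_vector")) vectors <- list(vectors)
  do.call(rbind, lapply(vectors, function(v)
    if (inherits(v, "feature_vector")) v$values else v))
}

#' Build background statistics for standardization and Tanimoto calibration
#'
#' Per-dimension mean and population standard deviation are computed over the
#' pool; dimensions with zero variance are dropped from the retained set and
#' standardize to 0 (unless explicitly pinned via `retain`, in which case a
#' zero-variance retained dimension is an error naming it). The raw Tanimoto
#' background (`mu_t`, `sigma_t`) is estimated per chemistry class from
#' `n_pairs` seeded random same-class center pairs.
#'
#' @param vectors list of `feature_vector`s (or a numeric matrix, one row per
#'   center).
#' @param classes character vector: chemistry class per vector (see
#'   [chem_classes()]).
#' @param n_pairs pairs sampled per class (default 500).
#' @param seed RNG seed; results are deterministic given the pool and seed.
#' @param threshold binarization threshold used for the calibration Tanimoto.
#' @param retain optional integer vector of dimensions that must be retained.
#' @return object of class `background_stats`.
#' @export
build_background <- function(vectors, classes, n_pairs = 500L, seed = 1L,
                             threshold = 1.0, retain = NULL) {
  M <- feature_matrix(vectors)
  assert_that(nrow(M) >= 2L, "need at least 2 vectors to build a background")
  assert_that(length(classes) == nrow(M),
              "one chemistry class per vector required")
  dim_mean <- colMeans(M)
  dim_std <- apply(M, 2, pop_sd)
  if (is.null(retain)) {
    retained <- which(dim_std > 0)
    assert_that(length(retained) > 0L,
                "degenerate pool: all %d dimensions have zero variance", ncol(M))
  } else {
    retained <- as.integer(retain)
    bad <- retained[dim_std[retained] == 0]
    assert_that(length(bad) == 0L,
                "retained dimension(s) with zero variance: %s",
                paste(bad, collapse = ", "))
  }
  Z <- matrix(0, nrow(M), ncol(M))
  Z[, retained] <- sweep(sweep(M[, retained, drop = FALSE], 2, dim_mean[retained]),
                         2, dim_std[retained], "/")
  pair_stats <- list()
  with_seed(seed, {
    for (cl in sort(unique(classes))) {
      idx <- which(classes == cl)
      assert_that(length(idx) >= 2L,
                  "class '%s' has fewer than 2 calibration centers", cl)
      tt <- numeric(n_pairs)
      for (p in seq_len(n_pairs)) {
        ij <- sample(idx, 2L)
        tt[p] <- tanimoto(Z[ij[1], ], Z[ij[2], ], threshold = threshold)
      }
      mu <- mean(tt); sdv <- pop_sd(tt)
      assert_that(sdv > 0,
                  "degenerate Tanimoto background for class '%s' (sigma = 0)", cl)
      pair_stats[[cl]] <- c(mu_t = mu, sigma_t = sdv)
    }
  })
  structure(list(dim_mean = dim_mean, dim_std = dim_std, retained = retained,
                 pair_stats = pair_stats, pool_size = nrow(M),
                 n_pairs = as.integer(n_pairs), seed = as.integer(seed),
                 threshold = threshold),
            class = "background_stats")
}

#' Standardize a feature vector against background statistics
#'
#' `z_i = (v_i - mean_i) / std_i` on retained dimensions; dropped
#' (zero-variance) dimensions standardize to 0.
#'
#' @param vector `feature_vector` or numeric vector of matching length.
#' @param bg a `background_stats` object.
#' @return numeric standardized vector, same length.
#' @export
standardize <- function(vector, bg) {
  v <- if (inherits(vector, "feature_vector")) vector$values else vector
  assert_that(length(v) == length(bg$dim_mean),
              "dimension mismatch: vector %d vs background %d",
              length(v), length(bg$dim_mean))
  z <- numeric(length(v))
  r <- bg$retained
  z[r] <- (v[r] - bg$dim_mean[r]) / bg$dim_std[r]
  names(z) <- names(v)
  z
}

#' Write feature vectors to TSV
#'
#' One row per center: `center_label` followed by the shell-major descriptor
#' columns (e.g. `s0_RES_ALA`).
#'
#' @param vectors list of `feature_vector`s.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_feature_tsv <- function(vectors, path) {
  M <- feature_matrix(vectors)
  labels <- vapply(vectors, function(v) v$center_label, character(1))
  df <- data.frame(center_label = labels, M, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
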