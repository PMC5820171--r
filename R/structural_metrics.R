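# Companion structural-quality measures: least-squares (Kabsch) rigid
# superposition, GDT_TS and TM-score over a residue correspondence by author
# numbering, and site-local RMSD. These are in-package stand-ins for the
# official assessment programs: only ranking behavior is required, and small
# cases are pinned against exhaustive oracles in the tests.

#' Kabsch least-squares superposition
#'
#' Finds the proper rotation `R` (det = +1) and translation `t` minimizing
#' `|| p - (q R + t) ||`; `q %*% rotation + translation` superposes `q` onto
#' `p`.
#'
#' @param p,q n x 3 coordinate matrices (rows correspond), `n >= 3`.
#' @return list with `rotation` (3 x 3), `translation` (3-vector), `rmsd`.
#' @export
kabsch_superpose <- function(p, q) {
  p <- as.matrix(p); q <- as.matrix(q)
  assert_that(nrow(p) == nrow(q), "point sets differ in length: %d vs %d",
              nrow(p), nrow(q))
  assert_that(nrow(p) >= 3L, "need at least 3 points, got %d", nrow(p))
  assert_that(all(is.finite(p)) && all(is.finite(q)), "non-finite coordinates")
  pc <- colMeans(p); qc <- colMeans(q)
  P <- sweep(p, 2, pc); Q <- sweep(q, 2, qc)
  A <- t(Q) %*% P
  sv <- svd(A)
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  qr_ <- Q %*% R
  rmsd <- sqrt(mean(rowSums((P - qr_)^2)))
  list(rotation = R, translation = pc - as.numeric(qc %*% R), rmsd = rmsd)
}

apply_superposition <- function(q, sup) {
  sweep(as.matrix(q) %*% sup$rotation, 2, sup$translation, "+")
}

# Ca coordinates of a model matched to a reference by author numbering.
# Returns list(p = reference n x 3, q = model n x 3, keys).
ca_correspondence <- function(model, reference) {
  ca_of <- function(m) {
    a <- m$atoms[m$atoms$record == "ATOM" & m$atoms$name == "CA", ]
    key <- residue_key(a$chain, a$resseq, a$icode)
    a <- a[!duplicated(key), , drop = FALSE]
    rownames(a) <- residue_key(a$chain, a$resseq, a$icode)
    a
  }
  ar <- ca_of(reference); am <- ca_of(model)
  common <- intersect(rownames(ar), rownames(am))
  list(p = as.matrix(ar[common, c("x", "y", "z")]),
       q = as.matrix(am[common, c("x", "y", "z")]),
       keys = common)
}

# candidate superpositions for the GDT/TM searches: seeded from contiguous
# windows (lengths 3, 5, 7 and full-length), each refined by iterative
# extension at a distance cutoff. For tiny chains (<= 8 residues) all
# 3-subsets are used as seeds so the search is effectively exhaustive.
search_superpositions <- function(p, q, cutoffs) {
  n <- nrow(p)
  seeds <- list(seq_len(n))
  if (n <= 8L) {
    for (w in 3:4) {
      cmb <- utils::combn(n, w)
      for (j in seq_len(ncol(cmb))) seeds[[length(seeds) + 1L]] <- cmb[, j]
    }
  } else {
    for (w in c(3L, 5L, 7L)) {
      if (w > n) next
      for (s in seq_len(n - w + 1L)) seeds[[length(seeds) + 1L]] <- s:(s + w - 1L)
    }
  }
  sups <- list()
  for (seed_idx in seeds) {
    sup <- kabsch_superpose(p[seed_idx, , drop = FALSE],
                            q[seed_idx, , drop = FALSE])
    sups[[length(sups) + 1L]] <- sup
    for (cut in cutoffs) {
      sel <- seed_idx
      for (iter in 1:8) {
        qs <- apply_superposition(q, sup)
        d <- sqrt(rowSums((p - qs)^2))
        new_sel <- which(d <= cut)
        if (length(new_sel) < 3L || identical(new_sel, sel)) break
        sel <- new_sel
        sup <- kabsch_superpose(p[sel, , drop = FALSE], q[sel, , drop = FALSE])
        sups[[length(sups) + 1L]] <- sup
      }
    }
  }
  sups
}

#' GDT_TS of a model against a reference
#'
#' `GDT_TS = 25 (P1 + P2 + P4 + P8)` where `Pd` is the maximal fraction of
#' corresponding Ca atoms within `d` Angstrom over the searched
#' superpositions. Correspondence is by author residue numbering.
#'
#' @param model,reference `structure_model`s.
#' @return GDT_TS in 0..100.
#' @export
gdt_ts <- function(model, reference) {
  cc <- ca_correspondence(model, reference)
  assert_that(nrow(cc$p) >= 4L, "need >= 4 mapped Ca pairs, got %d", nrow(cc$p))
  thresholds <- c(1, 2, 4, 8)
  sups <- search_superpositions(cc$p, cc$q, thresholds)
  best <- numeric(4)
  for (sup in sups) {
    qs <- apply_superposition(cc$q, sup)
    d <- sqrt(rowSums((cc$p - qs)^2))
    frac <- vapply(thresholds, function(th) mean(d <= th), numeric(1))
    best <- pmax(best, frac)
  }
  25 * sum(best)
}

#' TM-score of a model against a reference
#'
#' `TM = max over superpositions of (1/L) sum 1 / (1 + (d_i/d0)^2)` with
#' `d0 = 1.24 (L - 15)^(1/3) - 1.8`, clamped below at 0.5 (short chains).
#'
#' @param model,reference `structure_model`s.
#' @return TM-score in (0, 1].
#' @export
tm_score <- function(model, reference) {
  cc <- ca_correspondence(model, reference)
  L <- nrow(cc$p)
  assert_that(L >= 3L, "need >= 3 mapped Ca pairs, got %d", L)
  d0 <- if (L > 15) 1.24 * (L - 15)^(1 / 3) - 1.8 else 0.5
  d0 <- max(d0, 0.5)
  sups <- search_superpositions(cc$p, cc$q, c(d0, 2 * d0, 4, 8))
  tm_of <- function(sup) {
    qs <- apply_superposition(cc$q, sup)
    mean(1 / (1 + rowSums((cc$p - qs)^2) / d0^2))
  }
  scores <- vapply(sups, tm_of, numeric(1))
  best <- max(scores)
  # polish: the TM optimum is a continuous rotation problem, not an RMSD
  # subset problem; refine the best few candidates against the TM objective
  rotmat <- function(ang) {
    ca <- cos(ang); sa <- sin(ang)
    matrix(c(ca[1], sa[1], 0, -sa[1], ca[1], 0, 0, 0, 1), 3) %*%
      matrix(c(ca[2], 0, -sa[2], 0, 1, 0, sa[2], 0, ca[2]), 3) %*%
      matrix(c(ca[3], sa[3], 0, -sa[3], ca[3], 0, 0, 0, 1), 3)
  }
  obj <- function(par) {
    qs <- sweep(cc$q %*% rotmat(par[1:3]), 2, par[4:6], "+")
    -mean(1 / (1 + rowSums((cc$p - qs)^2) / d0^2))
  }
  top <- order(scores, decreasing = TRUE)[seq_len(min(8L, length(scores)))]
  for (k in top) {
    sup <- sups[[k]]
    # recover Euler angles of the candidate rotation as the starting point
    R <- sup$rotation
    ang <- c(atan2(R[2, 3], R[1, 3]), acos(max(-1, min(1, R[3, 3]))),
             atan2(R[3, 2], -R[3, 1]))
    fit <- stats::optim(c(ang, sup$translation), obj, method = "Nelder-Mead",
                        control = list(maxit = 600, reltol = 1e-10))
    best <- max(best, -fit$value)
  }
  min(best, 1)
}

#' Global Ca RMSD of a model against a reference
#'
#' Kabsch RMSD over all corresponding Ca atoms.
#'
#' @param model,reference `structure_model`s.
#' @return RMSD in Angstrom.
#' @export
global_rmsd <- function(model, reference) {
  cc <- ca_correspondence(model, reference)
  assert_that(nrow(cc$p) >= 3L, "need >= 3 mapped Ca pairs")
  kabsch_superpose(cc$p, cc$q)$rmsd
}

#' Site-local RMSD
#'
#' Kabsch RMSD restricted to the site residues' Ca atoms plus the mapped
#' functional-center atoms present in both structures.
#'
#' @param model,reference `structure_model`s.
#' @param site a `site_definition`.
#' @return RMSD in Angstrom over the site atoms only.
#' @export
local_rmsd <- function(model, reference, site) {
  sel_ref <- resolve_selection(reference, site$selectors)$hits
  assert_that(nrow(sel_ref) >= 3L, "fewer than 3 site residues in reference")
  pick_atoms <- function(m, keys) {
    rows <- list()
    a <- m$atoms[m$atoms$record == "ATOM", ]
    for (i in seq_len(nrow(keys))) {
      r <- keys[i, ]
      rule <- center_rule(r$resname)
      ra <- a[a$chain == r$chain & a$resseq == r$resseq & a$icode == r$icode &
                a$name %in% unique(c("CA", rule$atoms)), , drop = FALSE]
      if (nrow(ra) == 0L) next
      ra$akey <- paste(residue_key(ra$chain, ra$resseq, ra$icode), ra$name)
      rows[[length(rows) + 1L]] <- ra
    }
    do.call(rbind, rows)
  }
  ar <- pick_atoms(reference, sel_ref)
  am <- pick_atoms(model, sel_ref)
  common <- intersect(ar$akey, am$akey)
  assert_that(length(common) >= 3L, "fewer than 3 mapped site atoms")
  rownames(ar) <- ar$akey; rownames(am) <- am$akey
  kabsch_superpose(as.matrix(ar[common, c("x", "y", "z")]),
                   as.matrix(am[common, c("x", "y", "z")]))$rmsd
}

#' All structural scores of a model against a reference
#'
#' @param model,reference `structure_model`s.
#' @param site optional `site_definition` for the local RMSD.
#' @return list with `gdt_ts`, `tm`, `rmsd_global`, `rmsd_local` (NA without
#'   a site).
#' @export
structural_scores <- function(model, reference, site = NULL) {
  list(gdt_ts = gdt_ts(model, reference),
       tm = tm_score(model, reference),
       rmsd_global = global_rmsd(model, reference),
       rmsd_local = if (is.null(site)) NA_real_
                    else local_rmsd(model, reference, site))
}
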