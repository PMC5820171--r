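# Fixtures are built in code; independent oracles live here and are kept
# deliberately naive (loops, enumeration, numerical optimization) so they
# never share a code path with the implementation they check.

# --- tiny PDB fixtures -------------------------------------------------------

toy_pdb_lines <- function(with_het = FALSE) {
  lines <- c(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00 10.00           N",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00 10.00           C",
    "ATOM      3  C   ALA A   1      10.697   6.745  -4.166  1.00 10.00           C",
    "ATOM      4  O   ALA A   1       9.555   6.322  -4.045  1.00 10.00           O",
    "ATOM      5  CB  ALA A   1      11.873   4.630  -4.717  1.00 10.00           C",
    "ATOM      6  N   SER A   2      11.169   7.787  -3.502  1.00 11.00           N",
    "ATOM      7  CA  SER A   2      10.370   8.506  -2.521  1.00 11.00           C",
    "ATOM      8  C   SER A   2      11.070   8.562  -1.171  1.00 11.00           C",
    "ATOM      9  O   SER A   2      12.285   8.410  -1.093  1.00 11.00           O",
    "ATOM     10  CB  SER A   2      10.107   9.920  -3.032  1.00 11.00           C",
    "ATOM     11  OG  SER A   2       9.344  10.681  -2.108  1.00 11.00           O",
    "ATOM     12  N   ASP A   3      10.303   8.782  -0.111  1.00 12.00           N",
    "ATOM     13  CA  ASP A   3      10.832   8.895   1.237  1.00 12.00           C",
    "ATOM     14  C   ASP A   3      10.115   9.986   2.017  1.00 12.00           C",
    "ATOM     15  O   ASP A   3       8.889  10.056   2.008  1.00 12.00           O",
    "ATOM     16  CB  ASP A   3      10.689   7.561   1.969  1.00 12.00           C",
    "ATOM     17  CG  ASP A   3      11.341   7.577   3.339  1.00 12.00           C",
    "ATOM     18  OD1 ASP A   3      12.119   8.505   3.627  1.00 12.00           O",
    "ATOM     19  OD2 ASP A   3      11.070   6.652   4.131  1.00 12.00           O")
  if (with_het)
    lines <- c(lines,
      "HETATM   20 FE   HEM A 101      13.500   8.000   1.000  1.00 15.00          FE")
  c(lines, "TER", "END")
}

write_toy_pdb <- function(with_het = FALSE) {
  path <- tempfile(fileext = ".pdb")
  writeLines(toy_pdb_lines(with_het), path)
  path
}

# minimal structure_model from a table of atoms; defaults fill PDB fields
make_structure <- function(df, ...) {
  defaults <- list(record = "ATOM", altloc = "", chain = "A", icode = "",
                   occ = 1, b = 10)
  for (nm in names(defaults)) if (is.null(df[[nm]])) df[[nm]] <- defaults[[nm]]
  if (is.null(df$serial)) df$serial <- seq_len(nrow(df))
  if (is.null(df$element)) df$element <- substr(sub("^[0-9]+", "", df$name), 1, 1)
  structure_model(df[c("record", "serial", "name", "altloc", "resname",
                       "chain", "resseq", "icode", "x", "y", "z", "occ", "b",
                       "element")], ...)
}

# Ca-only chain: one CA atom per residue at the given coordinates
make_ca_chain <- function(xyz, resnames = NULL, ...) {
  n <- nrow(xyz)
  if (is.null(resnames)) resnames <- rep("GLY", n)
  make_structure(data.frame(name = "CA", resname = resnames, resseq = seq_len(n),
                            x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                            stringsAsFactors = FALSE), ...)
}

random_rotation <- function() {
  M <- matrix(stats::rnorm(9), 3, 3)
  qr_ <- qr(M)
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

rigid_move <- function(model, R, t) {
  a <- model$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")]) %*% R
  a$x <- xyz[, 1] + t[1]; a$y <- xyz[, 2] + t[2]; a$z <- xyz[, 3] + t[3]
  structure_model(a, target_id = model$target_id, source_id = model$source_id,
                  model_index = model$model_index)
}

# --- independent oracles -----------------------------------------------------

# greedy matching oracle: naive repeated full scans of the score matrix
oracle_greedy_match <- function(S, cutoff) {
  matches <- list()
  used_a <- integer(0); used_b <- integer(0)
  repeat {
    best <- Inf; bi <- NA; bj <- NA
    for (i in seq_len(nrow(S))) for (j in seq_len(ncol(S))) {
      if (i %in% used_a || j %in% used_b || is.na(S[i, j])) next
      if (S[i, j] < best) { best <- S[i, j]; bi <- i; bj <- j }
    }
    if (!is.finite(best) || best > cutoff) break
    matches[[length(matches) + 1L]] <- c(bi, bj)
    used_a <- c(used_a, bi); used_b <- c(used_b, bj)
  }
  if (length(matches) == 0L) matrix(integer(0), ncol = 2)
  else do.call(rbind, matches)
}

# rigid superposition oracle: numerical optimization over Euler angles with
# multiple restarts (translation optimal at centroid match for fixed rotation)
oracle_superpose_rmsd <- function(p, q, n_starts = 12) {
  pc <- sweep(p, 2, colMeans(p)); qc <- sweep(q, 2, colMeans(q))
  rot <- function(ang) {
    ca <- cos(ang); sa <- sin(ang)
    Rz1 <- matrix(c(ca[1], sa[1], 0, -sa[1], ca[1], 0, 0, 0, 1), 3)
    Ry <- matrix(c(ca[2], 0, -sa[2], 0, 1, 0, sa[2], 0, ca[2]), 3)
    Rz2 <- matrix(c(ca[3], sa[3], 0, -sa[3], ca[3], 0, 0, 0, 1), 3)
    Rz1 %*% Ry %*% Rz2
  }
  obj <- function(ang) sqrt(mean(rowSums((pc - qc %*% rot(ang))^2)))
  best <- Inf
  for (s in seq_len(n_starts)) {
    ang0 <- stats::runif(3, 0, 2 * pi)
    fit <- stats::optim(ang0, obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    best <- min(best, fit$value)
  }
  best
}

# exhaustive GDT oracle: superpositions on every residue subset of size >= 3;
# per threshold, the max fraction of Ca within it over those superpositions
oracle_gdt <- function(p, q) {
  n <- nrow(p)
  fracs <- c(0, 0, 0, 0)
  thresholds <- c(1, 2, 4, 8)
  for (k in 3:n) {
    sub <- utils::combn(n, k)
    for (c_i in seq_len(ncol(sub))) {
      idx <- sub[, c_i]
      sup <- kabsch_superpose(p[idx, , drop = FALSE], q[idx, , drop = FALSE])
      qs <- sweep(q %*% sup$rotation, 2, sup$translation, "+")
      d <- sqrt(rowSums((p - qs)^2))
      for (t_i in 1:4) fracs[t_i] <- max(fracs[t_i], mean(d <= thresholds[t_i]))
    }
  }
  25 * sum(fracs)
}

# TM-score oracle: numerical optimization over rotation + translation, with
# many random restarts plus jittered restarts around the incumbent
oracle_tm <- function(p, q, n_starts = 48) {
  L <- nrow(p)
  d0 <- max(if (L > 15) 1.24 * (L - 15)^(1 / 3) - 1.8 else 0.5, 0.5)
  rot <- function(ang) {
    ca <- cos(ang); sa <- sin(ang)
    Rz1 <- matrix(c(ca[1], sa[1], 0, -sa[1], ca[1], 0, 0, 0, 1), 3)
    Ry <- matrix(c(ca[2], 0, -sa[2], 0, 1, 0, sa[2], 0, ca[2]), 3)
    Rz2 <- matrix(c(ca[3], sa[3], 0, -sa[3], ca[3], 0, 0, 0, 1), 3)
    Rz1 %*% Ry %*% Rz2
  }
  obj <- function(par) {
    qs <- sweep(q %*% rot(par[1:3]), 2, par[4:6], "+")
    -mean(1 / (1 + rowSums((p - qs)^2) / d0^2))
  }
  best <- -Inf; best_par <- NULL
  for (s in seq_len(n_starts)) {
    par0 <- c(stats::runif(3, 0, 2 * pi), colMeans(p) - colMeans(q) +
                stats::rnorm(3, sd = 2))
    fit <- stats::optim(par0, obj, method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-13))
    if (-fit$value > best) { best <- -fit$value; best_par <- fit$par }
  }
  for (s in 1:12) {  # refine around the incumbent
    fit <- stats::optim(best_par + stats::rnorm(6, sd = 0.15), obj,
                        method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-13))
    if (-fit$value > best) { best <- -fit$value; best_par <- fit$par }
  }
  best
}

# Spearman oracle for tie-free inputs: 1 - 6 sum(d^2) / (n (n^2 - 1))
oracle_spearman <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# brute-force holo-site oracle: all pairwise atom distances, no vectorization
oracle_holo_site <- function(model, ligand_code, cutoff) {
  a <- model$atoms
  lig <- a[a$record == "HETATM" & a$resname == ligand_code, ]
  poly <- a[a$record == "ATOM", ]
  hit_keys <- character(0)
  for (i in seq_len(nrow(poly))) for (j in seq_len(nrow(lig))) {
    d <- sqrt((poly$x[i] - lig$x[j])^2 + (poly$y[i] - lig$y[j])^2 +
                (poly$z[i] - lig$z[j])^2)
    if (d <= cutoff)
      hit_keys <- union(hit_keys, paste(poly$chain[i], poly$resseq[i]))
  }
  sort(hit_keys)
}
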