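# The property manifest: the ordered list of exactly 80 physicochemical rules
# evaluated per shell. Each rule is data (name, kind, extractor string), not
# code; the extractor engine below maps rules to per-atom numeric columns.
#
# kinds: "count" (sum of 0/1 indicators), "sum" (sum of a per-atom scalar),
# "mean" (mean of a per-atom scalar over the shell, 0 if the shell is empty).
# Every rule depends only on atom/residue identity and scalar attributes,
# never on absolute orientation, so the descriptor is rigid-motion invariant.

#' The default 80-property manifest
#'
#' Families: residue-type counts (20), element counts C/N/O/S (4), charge-class
#' counts + net formal-charge sum (4), Kyte-Doolittle hydropathy sum (1),
#' H-bond donor/acceptor counts (2), aromatic-ring atom count (1), backbone and
#' side-chain counts (2), B-factor and occupancy means (2), residue-class
#' counts (8), functional-group counts (6), backbone-dihedral secondary
#' structure proxy counts (3), and 27 named-atom counts.
#'
#' @return data.frame with columns `name`, `kind`, `extractor`; exactly 80 rows.
#' @export
default_manifest <- function() {
  rows <- list()
  add <- function(name, kind, extractor)
    rows[[length(rows) + 1L]] <<- data.frame(name = name, kind = kind,
                                             extractor = extractor,
                                             stringsAsFactors = FALSE)
  for (aa in AA3) add(paste0("RES_", aa), "count", paste0("resname:", aa))
  for (el in c("C", "N", "O", "S")) add(paste0("ELEM_", el), "count", paste0("element:", el))
  add("CHARGE_POS",   "count", "chargeclass:positive")
  add("CHARGE_NEG",   "count", "chargeclass:negative")
  add("CHARGE_NEUT",  "count", "chargeclass:neutral")
  add("CHARGE_NET",   "sum",   "attr:formal_charge")
  add("HYDROPATHY",   "sum",   "attr:kd_hydro")
  add("HB_DONOR",     "count", "role:donor")
  add("HB_ACCEPTOR",  "count", "role:acceptor")
  add("AROM_RING",    "count", "role:aromatic_ring")
  add("BACKBONE",     "count", "role:backbone")
  add("SIDECHAIN",    "count", "role:sidechain")
  add("BFACTOR_MEAN", "mean",  "attr:bfactor")
  add("OCC_MEAN",     "mean",  "attr:occupancy")
  for (cl in names(RESIDUE_CLASSES))
    add(paste0("CLASS_", toupper(cl)), "count", paste0("resclass:", cl))
  for (g in names(FUNCTIONAL_GROUPS))
    add(paste0("GROUP_", toupper(g)), "count", paste0("group:", g))
  add("SS_HELIX",    "count", "ss:helix")
  add("SS_EXTENDED", "count", "ss:extended")
  add("SS_OTHER",    "count", "ss:other")
  for (an in MANIFEST_ATOM_NAMES) add(paste0("ATOM_", an), "count", paste0("atomname:", an))
  manifest <- do.call(rbind, rows)
  validate_manifest(manifest)
  manifest
}

#' Validate a property manifest
#'
#' @param manifest data.frame with columns name, kind, extractor.
#' @return the manifest, invisibly, if valid; otherwise an error.
#' @export
validate_manifest <- function(manifest) {
  assert_that(is.data.frame(manifest) &&
                all(c("name", "kind", "extractor") %in% names(manifest)),
              "manifest must have columns name, kind, extractor")
  assert_that(nrow(manifest) == 80L,
              "manifest must have exactly 80 rules, got %d", nrow(manifest))
  assert_that(!anyDuplicated(manifest$name), "manifest names must be unique")
  assert_that(all(manifest$kind %in% c("count", "sum", "mean")),
              "manifest kinds must be count/sum/mean")
  invisible(manifest)
}

#' Write / read a manifest as JSON
#' @param manifest a manifest data.frame.
#' @param path file path.
#' @return `read_manifest` returns the validated manifest.
#' @export
write_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  jsonlite::write_json(manifest, path, dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  m <- as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  validate_manifest(m)
  m
}

# ---- per-atom attribute computation -----------------------------------------

in_table <- function(resname, name, tab) {
  out <- rep(FALSE, length(resname))
  for (rn in names(tab)) out <- out | (resname == rn & name %in% tab[[rn]])
  out
}

# backbone phi/psi secondary-structure proxy labels per residue
ss_proxy_labels <- function(model) {
  res <- residue_table(model)
  n <- nrow(res)
  lab <- rep("other", n)
  if (n == 0L) return(stats::setNames(lab, character(0)))
  a <- model$atoms[model$atoms$record == "ATOM", ]
  get_atom <- function(i, nm) {
    r <- a[a$chain == res$chain[i] & a$resseq == res$resseq[i] &
             a$icode == res$icode[i] & a$name == nm, , drop = FALSE]
    if (nrow(r) == 0L) NULL else c(r$x[1], r$y[1], r$z[1])
  }
  dihedral <- function(p1, p2, p3, p4) {
    b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
    n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
            b1[1] * b2[2] - b1[2] * b2[1])
    n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
            b2[1] * b3[2] - b2[2] * b3[1])
    m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
            n1[1] * b2[2] - n1[2] * b2[1]) / vnorm(b2)
    atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  }
  for (i in seq_len(n)) {
    if (i == 1L || i == n) next
    same_chain <- res$chain[i - 1] == res$chain[i] && res$chain[i + 1] == res$chain[i]
    if (!same_chain) next
    Cm <- get_atom(i - 1, "C"); Ni <- get_atom(i, "N"); CAi <- get_atom(i, "CA")
    Ci <- get_atom(i, "C"); Np <- get_atom(i + 1, "N")
    if (is.null(Cm) || is.null(Ni) || is.null(CAi) || is.null(Ci) || is.null(Np)) next
    phi <- dihedral(Cm, Ni, CAi, Ci)
    psi <- dihedral(Ni, CAi, Ci, Np)
    if (phi > -145 && phi < -35 && psi > -70 && psi < 50) lab[i] <- "helix"
    else if (phi > -180 && phi < -45 && (psi > 60 || psi < -150)) lab[i] <- "extended"
  }
  stats::setNames(lab, residue_key(res$chain, res$resseq, res$icode))
}

#' Per-atom property matrix for a structure
#'
#' Evaluates every manifest extractor once per atom over the featurizable
#' atoms of the model: polymer (ATOM) records, hydrogens excluded. The result
#' can be passed to [featurize()] to amortize the cost over many centers.
#'
#' @param model a `structure_model`.
#' @param manifest property manifest (default [default_manifest()]).
#' @return list with `xyz` (n x 3), `P` (n x 80 matrix, one column per rule)
#'   and `kind` (rule kinds), class `atom_properties`.
#' @export
atom_properties <- function(model, manifest = default_manifest()) {
  validate_manifest(manifest)
  a <- model$atoms[model$atoms$record == "ATOM" & model$atoms$element != "H" &
                     model$atoms$element != "D", , drop = FALSE]
  n <- nrow(a)
  resname <- a$resname; name <- a$name; element <- a$element
  is_bb <- name %in% BACKBONE_ATOMS
  fc <- numeric(n)
  for (rn in names(FORMAL_CHARGES)) {
    tab <- FORMAL_CHARGES[[rn]]
    for (an in names(tab)) fc[resname == rn & name == an] <- tab[[an]]
  }
  pos <- fc > 0; neg <- fc < 0
  kd <- KD_INDEX[resname]; kd[is.na(kd)] <- 0
  donors <- (name == "N") | in_table(resname, name, HB_DONOR_ATOMS)
  acceptors <- (name == "O" | name == "OXT") | in_table(resname, name, HB_ACCEPTOR_ATOMS)
  ring <- in_table(resname, name, AROMATIC_RING_ATOMS)
  ss <- ss_proxy_labels(model)
  atom_ss <- ifelse(name == "CA",
                    ss[residue_key(a$chain, a$resseq, a$icode)], NA_character_)
  P <- matrix(0, nrow = n, ncol = nrow(manifest),
              dimnames = list(NULL, manifest$name))
  for (j in seq_len(nrow(manifest))) {
    ex <- strsplit(manifest$extractor[j], ":", fixed = TRUE)[[1]]
    kindkey <- ex[1]; arg <- ex[2]
    col <- switch(kindkey,
      resname   = as.numeric(resname == arg),
      element   = as.numeric(element == arg),
      atomname  = as.numeric(name == arg),
      resclass  = as.numeric(resname %in% RESIDUE_CLASSES[[arg]]),
      chargeclass = switch(arg, positive = as.numeric(pos),
                           negative = as.numeric(neg),
                           neutral = as.numeric(!pos & !neg)),
      role      = switch(arg, donor = as.numeric(donors),
                         acceptor = as.numeric(acceptors),
                         aromatic_ring = as.numeric(ring),
                         backbone = as.numeric(is_bb),
                         sidechain = as.numeric(!is_bb)),
      group     = as.numeric(in_table(resname, name, FUNCTIONAL_GROUPS[[arg]])),
      ss        = as.numeric(!is.na(atom_ss) & atom_ss == arg),
      attr      = switch(arg, formal_charge = fc, kd_hydro = kd,
                         bfactor = a$b, occupancy = a$occ),
      stop(sprintf("unknown extractor '%s'", manifest$extractor[j]))
    )
    if (is.null(col)) stop(sprintf("unknown extractor '%s'", manifest$extractor[j]))
    P[, j] <- col
  }
  structure(list(xyz = cbind(a$x, a$y, a$z), P = P, kind = manifest$kind,
                 names = manifest$name),
            class = "atom_properties")
}
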