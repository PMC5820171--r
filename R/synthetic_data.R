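# Synthetic structures and decoy ensembles. The generator emulates the shape
# of the real assessment data: one experimental-like reference with a concave
# functional site (optionally ligand-bound), and server-style ensembles of
# perturbed models with independently controllable global and site-local
# coordinate noise, model_index 1 marking each synthetic server's best model.
#
# Noise is i.i.d. Gaussian per coordinate; nothing here is physics-based. The
# backbone is a solenoid (superhelical Ca trace, ideal 3.8 A Ca-Ca spacing)
# whose interior channel provides the concavity; site residue side chains
# point into the channel.

# one 20-residue block covering every chemistry class at least twice; the
# synthetic sequence cycles this block and is then shuffled, so background
# calibration always has >= 2 centers per class (n_residues >= 20)
BALANCED_BLOCK <- c("SER", "ASP", "ASN", "LYS", "ARG", "HIS", "CYS", "PHE",
                    "ALA", "GLY", "THR", "GLU", "GLN", "LYS", "ARG", "HIS",
                    "CYS", "TYR", "LEU", "GLY")

# side-chain proxy geometry: atoms placed along the side-chain direction at
# `along` Angstrom from CA, with `perp` Angstrom sideways offset (+/- pairs)
SIDECHAIN_SPEC <- list(
  ALA = list(c("CB", 1.53, 0)),
  GLY = list(),
  SER = list(c("CB", 1.53, 0), c("OG", 2.4, 0)),
  THR = list(c("CB", 1.53, 0), c("OG1", 2.4, 0.6), c("CG2", 2.4, -1.2)),
  CYS = list(c("CB", 1.53, 0), c("SG", 2.8, 0)),
  VAL = list(c("CB", 1.53, 0), c("CG1", 2.5, 1.1), c("CG2", 2.5, -1.1)),
  LEU = list(c("CB", 1.53, 0), c("CG", 2.5, 0), c("CD1", 3.3, 1.1),
             c("CD2", 3.3, -1.1)),
  ILE = list(c("CB", 1.53, 0), c("CG1", 2.5, 0.8), c("CG2", 2.5, -1.2),
             c("CD1", 3.9, 0.8)),
  PRO = list(c("CB", 1.53, 0), c("CG", 2.4, 0.5), c("CD", 1.9, 1.4)),
  MET = list(c("CB", 1.53, 0), c("CG", 2.4, 0), c("SD", 3.2, 0),
             c("CE", 4.0, 0.6)),
  ASP = list(c("CB", 1.53, 0), c("CG", 2.4, 0), c("OD1", 3.0, 1.1),
             c("OD2", 3.0, -1.1)),
  GLU = list(c("CB", 1.53, 0), c("CG", 2.4, 0), c("CD", 3.2, 0),
             c("OE1", 3.8, 1.1), c("OE2", 3.8, -1.1)),
  ASN = list(c("CB", 1.53, 0), c("CG", 2.4, 0), c("OD1", 3.0, 1.1),
             c("ND2", 3.0, -1.1)),
  GLN = list(c("CB", 1.53, 0), c("CG", 2.4, 0), c("CD", 3.2, 0),
             c("OE1", 3.8, 1.1), c("NE2", 3.8, -1.1)),
  LYS = list(c("CB", 1.53, 0), c("CG", 2.4, 0), c("CD", 3.2, 0),
             c("CE", 4.0, 0), c("NZ", 4.8, 0)),
  ARG = list(c("CB", 1.53, 0), c("CG", 2.4, 0), c("CD", 3.2, 0),
             c("NE", 3.9, 0), c("CZ", 4.6, 0), c("NH1", 5.2, 1.0),
             c("NH2", 5.2, -1.0)),
  HIS = list(c("CB", 1.53, 0), c("CG", 2.6, 0), c("ND1", 3.4, 1.1),
             c("CD2", 3.4, -1.1), c("CE1", 4.3, 0.7), c("NE2", 4.3, -0.7)),
  PHE = list(c("CB", 1.53, 0), c("CG", 2.6, 0), c("CD1", 3.3, 1.2),
             c("CD2", 3.3, -1.2), c("CE1", 4.7, 1.2), c("CE2", 4.7, -1.2),
             c("CZ", 5.4, 0)),
  TYR = list(c("CB", 1.53, 0), c("CG", 2.6, 0), c("CD1", 3.3, 1.2),
             c("CD2", 3.3, -1.2), c("CE1", 4.7, 1.2), c("CE2", 4.7, -1.2),
             c("CZ", 5.4, 0), c("OH", 6.8, 0)),
  TRP = list(c("CB", 1.53, 0), c("CG", 2.6, 0), c("CD1", 3.4, 1.2),
             c("CD2", 3.4, -1.0), c("NE1", 4.6, 1.4), c("CE2", 4.7, 0.2),
             c("CE3", 4.0, -2.2), c("CZ2", 6.0, 0.2), c("CZ3", 5.3, -2.3),
             c("CH2", 6.2, -1.2))
)

element_of <- function(name) substr(sub("^[0-9]+", "", name), 1, 1)

#' Generate a synthetic reference structure with a functional site
#'
#' Builds a solenoidal backbone (N, CA, C, O; consecutive Ca-Ca distances
#' 3.8 A) whose interior channel forms a concave site; side-chain proxy atoms
#' are placed consistently with the functional-center mapping, pointing into
#' the channel for site residues. With `with_ligand` a 4-atom hetero residue
#' ("LIG") is placed in the concavity with minimum protein distance in
#' [2.5, 4.5] A. Deterministic given `seed`.
#'
#' @param n_residues chain length, `>= 20`.
#' @param with_ligand place a ligand in the site (makes the site "holo").
#' @param site_size number of site residues (default 8).
#' @param seed RNG seed.
#' @param target_id target id stamped on the model.
#' @return list with `model` (a `structure_model`) and `site` (a
#'   [site_definition()]).
#' @export
generate_reference <- function(n_residues, with_ligand = FALSE,
                               site_size = 8L, seed = 1L,
                               target_id = "SYN1") {
  assert_that(n_residues >= 20L, "n_residues must be >= 20, got %d", n_residues)
  assert_that(site_size >= 3L, "site_size must be >= 3")
  with_seed(seed, {
    seqres <- sample(rep(BALANCED_BLOCK, length.out = max(n_residues, 20L)))
    seqres <- seqres[seq_len(n_residues)]
    # solenoid Ca trace
    Rsol <- 9.5; csol <- 1.7
    dt <- 3.8 / sqrt(Rsol^2 + csol^2)
    tpar <- (seq_len(n_residues) - 1) * dt
    CA <- cbind(Rsol * cos(tpar), Rsol * sin(tpar), csol * tpar)
    per_turn <- round(2 * pi / dt)
    mid <- floor(n_residues / 2)
    offsets <- c(0:3, per_turn + 0:2, 2 * per_turn + 0:2, -per_turn + 0:2,
                 4:6, 3 * per_turn + 0:2)
    site_idx <- unique(mid + offsets)
    site_idx <- site_idx[site_idx >= 2 & site_idx <= n_residues - 1]
    site_idx <- sort(site_idx[seq_len(min(site_size, length(site_idx)))])
    rows <- list(); serial <- 0L
    add_atom <- function(record, name, resname, resseq, xyz, b = 10) {
      serial <<- serial + 1L
      rows[[length(rows) + 1L]] <<- data.frame(
        record = record, serial = serial, name = name, altloc = "",
        resname = resname, chain = "A", resseq = resseq, icode = "",
        x = xyz[1], y = xyz[2], z = xyz[3], occ = 1, b = b,
        element = element_of(name), stringsAsFactors = FALSE)
    }
    for (i in seq_len(n_residues)) {
      u_next <- if (i < n_residues) unit(CA[i + 1, ] - CA[i, ])
                else unit(CA[i, ] - CA[i - 1, ])
      u_prev <- if (i > 1) unit(CA[i - 1, ] - CA[i, ]) else -u_next
      radial_out <- unit(c(CA[i, 1], CA[i, 2], 0))
      # N and C are tilted off the Ca-Ca axis so backbone dihedrals are
      # well defined (collinear placement makes phi/psi degenerate)
      add_atom("ATOM", "N", seqres[i], i,
               CA[i, ] + 1.45 * unit(u_prev + 0.35 * radial_out))
      add_atom("ATOM", "CA", seqres[i], i, CA[i, ])
      Cpos <- CA[i, ] + 1.52 * unit(u_next - 0.35 * radial_out)
      add_atom("ATOM", "C", seqres[i], i, Cpos)
      add_atom("ATOM", "O", seqres[i], i, Cpos + 1.23 * radial_out)
      # side chain along +/- radial with small seeded jitter
      inward <- i %in% site_idx
      dir <- unit((if (inward) -radial_out else radial_out) +
                    0.12 * stats::rnorm(3))
      perp <- unit(c(-dir[2], dir[1], 0) + c(0, 0, 0.3))
      for (spec in SIDECHAIN_SPEC[[seqres[i]]]) {
        pos <- CA[i, ] + as.numeric(spec[2]) * dir +
          as.numeric(spec[3]) * perp
        add_atom("ATOM", spec[1], seqres[i], i, pos)
      }
    }
    atoms <- do.call(rbind, rows)
    lig_code <- NULL
    if (with_ligand) {
      lig_code <- "LIG"
      # start at the site-tip centroid, then walk radially until the minimum
      # ligand-protein distance sits in [2.5, 4.5] A
      site_rows <- atoms[atoms$resseq %in% site_idx &
                           !(atoms$name %in% BACKBONE_ATOMS), ]
      p0 <- c(mean(site_rows$x), mean(site_rows$y), mean(site_rows$z))
      prot_xyz <- cbind(atoms$x, atoms$y, atoms$z)
      lig_local <- rbind(c(0, 0, 0), c(1.4, 0, 0), c(-0.7, 1.2, 0),
                         c(-0.7, -0.6, 1.1))
      min_dist <- function(p) {
        dd <- Inf
        for (j in 1:4) dd <- min(dd, min(dist_to_point(prot_xyz, p + lig_local[j, ])))
        dd
      }
      for (iter in 1:200) {
        d <- min_dist(p0)
        if (d >= 2.5 && d <= 4.5) break
        step <- if (d < 2.5) 0.15 else -0.15
        # move along the radial direction (channel axis is z)
        rad <- c(p0[1], p0[2], 0)
        dirv <- if (vnorm(rad) > 1e-6) unit(rad) else c(1, 0, 0)
        p0 <- p0 + step * dirv
      }
      for (j in 1:4)
        add_atom("HETATM", paste0("C", j), "LIG", n_residues + 1L,
                 p0 + lig_local[j, ])
      atoms <- do.call(rbind, rows)
    }
    model <- structure_model(atoms, target_id = target_id,
                             source_id = "experimental", model_index = 0L)
    site <- site_definition(
      target_id = target_id, site_id = paste0(target_id, "-site1"),
      category = if (with_ligand) "holo" else "apo",
      selectors = residue_selector("A", site_idx),
      ligand = lig_code)
    list(model = model, site = site)
  })
}

#' Perturb a structure with global and site-local Gaussian noise
#'
#' Adds i.i.d. zero-mean Gaussian noise with SD `global_sigma` to every
#' coordinate, plus independent noise with SD `local_sigma` to the atoms of
#' the site residues. Atom/residue identities and numbering are preserved.
#'
#' @param reference a `structure_model`.
#' @param global_sigma,local_sigma noise SDs in Angstrom, `>= 0`.
#' @param site a `site_definition` (needed when `local_sigma > 0`).
#' @param seed RNG seed.
#' @param source_id,model_index metadata stamped on the perturbed model.
#' @return a new `structure_model`.
#' @export
perturb_model <- function(reference, global_sigma, local_sigma = 0,
                          site = NULL, seed = 1L, source_id = "synthetic",
                          model_index = 1L) {
  assert_that(global_sigma >= 0 && local_sigma >= 0, "sigmas must be >= 0")
  a <- reference$atoms
  with_seed(seed, {
    n <- nrow(a)
    noise <- matrix(stats::rnorm(3 * n, sd = global_sigma), n, 3)
    if (local_sigma > 0) {
      assert_that(!is.null(site), "local noise requires a site definition")
      in_site <- a$record == "ATOM" & a$resseq %in% site$selectors$resseq &
        (a$chain %in% c(site$selectors$chain, "*") |
           any(site$selectors$chain == "*"))
      noise[in_site, ] <- noise[in_site, ] +
        matrix(stats::rnorm(3 * sum(in_site), sd = local_sigma),
               sum(in_site), 3)
    }
    a$x <- a$x + noise[, 1]; a$y <- a$y + noise[, 2]; a$z <- a$z + noise[, 3]
    structure_model(a, target_id = reference$target_id,
                    source_id = source_id, model_index = model_index)
  })
}

#' Ensemble generator configuration
#'
#' @param n_residues reference chain length.
#' @param n_models total models in the ensemble (servers submit up to 5,
#'   model 1 being each server's best).
#' @param global_sigma maximal per-coordinate global noise SD, Angstrom.
#' @param local_sigma maximal extra site-local noise SD, Angstrom.
#' @param site_size site residue count.
#' @param anti_coupled_fraction fraction of models given maximal global but
#'   zero local noise (good-local/bad-global injections).
#' @param with_ligand forward to [generate_reference()].
#' @param seed RNG seed controlling the whole ensemble.
#' @return list of class `ensemble_config`.
#' @export
ensemble_config <- function(n_residues = 60L, n_models = 50L,
                            global_sigma = 2.0, local_sigma = 2.0,
                            site_size = 8L, anti_coupled_fraction = 0,
                            with_ligand = FALSE, seed = 1L) {
  assert_that(n_models >= 3L, "n_models must be >= 3")
  assert_that(site_size >= 3L, "site_size must be >= 3")
  assert_that(global_sigma >= 0 && local_sigma >= 0, "sigmas must be >= 0")
  assert_that(anti_coupled_fraction >= 0 && anti_coupled_fraction <= 1,
              "anti_coupled_fraction must be in [0, 1]")
  structure(list(n_residues = as.integer(n_residues),
                 n_models = as.integer(n_models),
                 global_sigma = global_sigma, local_sigma = local_sigma,
                 site_size = as.integer(site_size),
                 anti_coupled_fraction = anti_coupled_fraction,
                 with_ligand = with_ligand, seed = as.integer(seed)),
            class = "ensemble_config")
}

#' Generate a noise-graded synthetic model ensemble
#'
#' Models are grouped into synthetic servers of five; server `s` has base
#' noise level `s / n_servers` and, within a server, model k carries
#' multiplier `0.6 + 0.1 (k - 1)`, so model_index 1 is each server's best
#' (emulating predictor self-ranking). Global and local noise are coupled
#' through the same level except for the anti-coupled injections, which get
#' maximal global and zero local noise. The manifest records the true noise
#' per model for parameter-recovery tests.
#'
#' @param config an [ensemble_config()].
#' @return list with `reference`, `site`, `models` (list of
#'   `structure_model`), `manifest` (data.frame: model_id, server_id,
#'   model_index, global_sigma, local_sigma, level, anti_coupled).
#' @export
generate_ensemble <- function(config = ensemble_config()) {
  assert_that(inherits(config, "ensemble_config"), "not an ensemble_config")
  ref <- generate_reference(config$n_residues, with_ligand = config$with_ligand,
                            site_size = config$site_size, seed = config$seed,
                            target_id = "SYN1")
  n <- config$n_models
  n_servers <- ceiling(n / 5)
  server <- rep(seq_len(n_servers), each = 5)[seq_len(n)]
  midx <- unlist(lapply(rle(server)$lengths, seq_len))
  level <- (server / n_servers) * (0.6 + 0.1 * (midx - 1))
  g_sig <- config$global_sigma * level
  l_sig <- config$local_sigma * level
  anti <- rep(FALSE, n)
  n_anti <- round(config$anti_coupled_fraction * n)
  if (n_anti > 0) {
    # injections are drawn from non-model-1 slots: predictors know their best
    # model, so the low-correlation mode lives in the deeper submissions
    pool <- which(midx != 1L)
    assert_that(length(pool) >= n_anti,
                "anti_coupled_fraction too large for this ensemble")
    anti_idx <- with_seed(config$seed + 101L, sample(pool, n_anti))
    anti[anti_idx] <- TRUE
    g_sig[anti] <- config$global_sigma
    l_sig[anti] <- 0
  }
  models <- vector("list", n)
  for (i in seq_len(n)) {
    models[[i]] <- perturb_model(
      ref$model, g_sig[i], l_sig[i], ref$site,
      seed = (config$seed + 7919L * i) %% 2147483629L,
      source_id = sprintf("S%03d", server[i]), model_index = midx[i])
  }
  manifest <- data.frame(
    model_id = sprintf("S%03d_%d", server, midx),
    server_id = sprintf("S%03d", server), model_index = midx,
    global_sigma = g_sig, local_sigma = l_sig, level = level,
    anti_coupled = anti, stringsAsFactors = FALSE)
  list(reference = ref$model, site = ref$site, models = models,
       manifest = manifest)
}

#' Write an ensemble to disk
#'
#' Emits one PDB file per model plus a TSV manifest (model path, server id,
#' model index, true noise levels).
#'
#' @param ensemble result of [generate_ensemble()].
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest path.
#' @export
write_ensemble <- function(ensemble, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_structure(ensemble$reference, file.path(dir, "reference.pdb"))
  man <- ensemble$manifest
  man$path <- file.path(dir, paste0(man$model_id, ".pdb"))
  for (i in seq_along(ensemble$models))
    write_structure(ensemble$models[[i]], man$path[i])
  manifest_path <- file.path(dir, "manifest.tsv")
  utils::write.table(man, manifest_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(manifest_path)
}

# md5 of the packaged site-inventory fixture (guards against corruption)
SITE_TABLE_MD5 <- "5554ca21683eb49d7041abdb39d98141"

#' Load the packaged functional-site inventory fixture
#'
#' A transcription of the assessed-site inventory: 28 sites across 25
#' targets, of which 9 holo (ligand-bound), 9 apo and 10 critical patches,
#' with center counts, model RMSD ranges, server counts and TBM/FM
#' classification. Checked against a stored checksum and the category
#' invariants at load.
#'
#' @return data.frame with columns target_id, site_id, n_centers, category,
#'   ligand, rmsd_min, rmsd_max, n_servers, classification.
#' @export
load_site_table <- function() {
  path <- system.file("extdata", "site_inventory.tsv", package = "pocketsim",
                      mustWork = TRUE)
  md5 <- unname(tools::md5sum(path))
  assert_that(identical(md5, SITE_TABLE_MD5),
              "site inventory fixture is corrupt (md5 %s)", md5)
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, quote = "")
  assert_that(nrow(tab) == 28L, "expected 28 sites, got %d", nrow(tab))
  counts <- table(tab$category)
  assert_that(identical(as.integer(counts[c("holo", "apo", "patch")]),
                        c(9L, 9L, 10L)),
              "category counts must be 9 holo / 9 apo / 10 patch")
  tab
}
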