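# Reading/writing protein structures in PDB and CASP tertiary-structure (TS)
# dialects, and resolving residue selections against a parsed model.
#
# A structure is held flat, bio3d-style: one data.frame of atom records plus
# model-level metadata. Residues are identified by (chain, resseq, icode).

ATOM_COLS <- c("record", "serial", "name", "altloc", "resname", "chain",
               "resseq", "icode", "x", "y", "z", "occ", "b", "element")

#' Construct a structure model
#'
#' @param atoms data.frame with columns `record` ("ATOM"/"HETATM"), `serial`,
#'   `name`, `altloc`, `resname`, `chain`, `resseq`, `icode`, `x`, `y`, `z`,
#'   `occ`, `b`, `element`.
#' @param target_id target identifier (e.g. "T0861"), or "".
#' @param source_id predictor/server id, or "experimental".
#' @param model_index integer 1..5 for predictions, 0 for experimental.
#' @return object of class `structure_model`.
#' @export
structure_model <- function(atoms, target_id = "", source_id = "experimental",
                            model_index = 0L) {
  assert_that(is.data.frame(atoms), "atoms must be a data.frame")
  missing_cols <- setdiff(ATOM_COLS, names(atoms))
  assert_that(length(missing_cols) == 0L,
              "atoms is missing columns: %s", paste(missing_cols, collapse = ", "))
  assert_that(all(is.finite(atoms$x)) && all(is.finite(atoms$y)) &&
                all(is.finite(atoms$z)), "atom coordinates must be finite")
  assert_that(model_index %in% 0:5, "model_index must be in 0..5")
  atoms$resname <- toupper(atoms$resname)
  rownames(atoms) <- NULL
  structure(list(atoms = atoms,
                 target_id = target_id,
                 source_id = source_id,
                 model_index = as.integer(model_index)),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  poly <- x$atoms$record == "ATOM"
  cat(sprintf("structure_model: target='%s' source='%s' model=%d\n",
              x$target_id, x$source_id, x$model_index))
  cat(sprintf("  %d polymer atoms in %d residues; %d hetero atoms in %d hetero residues\n",
              sum(poly), nrow(residue_table(x)),
              sum(!poly), nrow(residue_table(x, hetero = TRUE))))
  invisible(x)
}

residue_key <- function(chain, resseq, icode) {
  paste(chain, resseq, ifelse(is.na(icode) | icode == "", "_", icode), sep = "|")
}

#' Unique residues of a model as a key table
#'
#' @param model a `structure_model`.
#' @param hetero if TRUE list HETATM residues (ligands, ions) instead of
#'   polymer residues.
#' @return data.frame (chain, resseq, icode, resname) in file order.
#' @export
residue_table <- function(model, hetero = FALSE) {
  a <- model$atoms[model$atoms$record == (if (hetero) "HETATM" else "ATOM"), ]
  if (nrow(a) == 0L)
    return(data.frame(chain = character(), resseq = integer(),
                      icode = character(), resname = character(),
                      stringsAsFactors = FALSE))
  key <- residue_key(a$chain, a$resseq, a$icode)
  first <- !duplicated(key)
  data.frame(chain = a$chain[first], resseq = a$resseq[first],
             icode = a$icode[first], resname = a$resname[first],
             stringsAsFactors = FALSE)
}

# atoms belonging to one residue key set (keys df with chain/resseq/icode)
atoms_for_residues <- function(model, keys, hetero = FALSE) {
  a <- model$atoms[model$atoms$record == (if (hetero) "HETATM" else "ATOM"), ]
  ak <- residue_key(a$chain, a$resseq, a$icode)
  kk <- residue_key(keys$chain, keys$resseq, keys$icode)
  a[ak %in% kk, , drop = FALSE]
}

parse_coord_line <- function(line, lineno) {
  if (nchar(line) < 54)
    stop(sprintf("malformed coordinate record at line %d (too short): '%s'",
                 lineno, line), call. = FALSE)
  line <- formatC(line, width = 80, flag = "-")
  fx <- function(from, to) substr(line, from, to)
  num <- function(s, what) {
    v <- suppressWarnings(as.numeric(s))
    if (is.na(v) && trimws(s) != "")
      stop(sprintf("malformed %s field at line %d: '%s'", what, lineno, s),
           call. = FALSE)
    v
  }
  serial <- suppressWarnings(as.integer(trimws(fx(7, 11))))
  resseq <- suppressWarnings(as.integer(trimws(fx(23, 26))))
  if (is.na(resseq))
    stop(sprintf("malformed residue number at line %d", lineno), call. = FALSE)
  x <- num(fx(31, 38), "x"); y <- num(fx(39, 46), "y"); z <- num(fx(47, 54), "z")
  if (anyNA(c(x, y, z)))
    stop(sprintf("malformed coordinates at line %d", lineno), call. = FALSE)
  occ <- num(fx(55, 60), "occupancy"); if (is.na(occ)) occ <- 1
  b <- num(fx(61, 66), "bfactor");     if (is.na(b)) b <- 0
  elem <- trimws(fx(77, 78))
  name <- trimws(fx(13, 16))
  if (elem == "") {
    # derive element from the atom name, PDB convention: col 13 blank for C/N/O/S
    elem <- sub("[0-9'].*$", "", name)
    elem <- substr(elem, 1, ifelse(substr(name, 1, 1) %in% as.character(0:9), 2, 1))
    if (elem == "") elem <- substr(name, 1, 1)
  }
  list(record = trimws(fx(1, 6)), serial = serial, name = name,
       altloc = trimws(fx(17, 17)), resname = trimws(fx(18, 20)),
       chain = trimws(fx(22, 22)), resseq = resseq, icode = trimws(fx(27, 27)),
       x = x, y = y, z = z, occ = occ, b = b, element = toupper(elem))
}

#' Read a structure from a PDB or CASP-TS file
#'
#' CASP TS files are PDB coordinate records preceded by prediction headers
#' (`PFRMAT TS`, `TARGET`, `MODEL`, `AUTHOR`, `METHOD`, `PARENT`); these are
#' tolerated and, with `dialect = "casp_ts"`, the `TARGET` and `MODEL` fields
#' are captured into the model metadata. Only the first MODEL of a
#' multi-model file is kept (with a warning). Alternate locations are reduced
#' to the highest-occupancy conformer (ties broken alphabetically).
#'
#' @param path file path.
#' @param dialect "pdb" or "casp_ts".
#' @param source_id predictor id recorded on the model (default "experimental"
#'   for `pdb`, "unknown" for `casp_ts` unless the file names one).
#' @return a [structure_model()].
#' @export
read_structure <- function(path, dialect = c("pdb", "casp_ts"),
                           source_id = NULL) {
  dialect <- match.arg(dialect)
  assert_that(file.exists(path), "file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  assert_that(length(lines) > 0L && any(nzchar(trimws(lines))),
              "empty structure file: %s", path)
  target_id <- ""
  model_index <- if (dialect == "casp_ts") 1L else 0L
  rows <- vector("list", length(lines))
  n <- 0L
  n_model_blocks <- 0L
  in_skipped_model <- FALSE
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    rec <- substr(line, 1, 6)
    tag <- trimws(rec)
    if (tag == "MODEL") {
      n_model_blocks <- n_model_blocks + 1L
      if (n_model_blocks > 1L) { in_skipped_model <- TRUE; next }
      midx <- suppressWarnings(as.integer(trimws(substr(line, 7, 80))))
      if (dialect == "casp_ts" && !is.na(midx)) model_index <- midx
      next
    }
    if (tag == "ENDMDL") { in_skipped_model <- FALSE; next }
    if (in_skipped_model) next
    if (tag == "TARGET" && dialect == "casp_ts") {
      target_id <- trimws(substr(line, 7, 80)); next
    }
    if (tag == "AUTHOR" && dialect == "casp_ts" && is.null(source_id)) {
      source_id <- trimws(substr(line, 7, 80)); next
    }
    if (tag %in% c("ATOM", "HETATM")) {
      n <- n + 1L
      rows[[n]] <- parse_coord_line(line, i)
    }
  }
  if (n_model_blocks > 1L)
    warning(sprintf("%s: %d MODEL blocks; keeping the first only",
                    path, n_model_blocks))
  assert_that(n > 0L, "no ATOM/HETATM records in %s", path)
  atoms <- do.call(rbind, lapply(rows[seq_len(n)], as.data.frame))
  atoms <- reduce_altlocs(atoms)
  if (is.null(source_id))
    source_id <- if (dialect == "pdb") "experimental" else "unknown"
  if (dialect == "pdb") model_index <- 0L
  if (model_index > 5L) model_index <- 5L
  structure_model(atoms, target_id = target_id, source_id = source_id,
                  model_index = model_index)
}

# keep the highest-occupancy altloc per (residue, atom name); ties: 'A' < 'B'
reduce_altlocs <- function(atoms) {
  if (all(atoms$altloc == "")) return(atoms)
  key <- paste(residue_key(atoms$chain, atoms$resseq, atoms$icode),
               atoms$record, atoms$name, sep = "|")
  ord <- order(key, -atoms$occ, atoms$altloc)
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(key[ord]), , drop = FALSE]
  atoms <- atoms[order(atoms$serial), , drop = FALSE]
  atoms$altloc <- ""
  rownames(atoms) <- NULL
  atoms
}

#' Write a structure to a PDB file
#'
#' Coordinates are written to 3 decimals (PDB precision); hetero residues are
#' emitted as HETATM records after the polymer.
#'
#' @param model a `structure_model`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_structure <- function(model, path) {
  assert_that(inherits(model, "structure_model"), "not a structure_model")
  a <- model$atoms
  assert_that(nrow(a) > 0L, "refusing to write an empty structure")
  pad_name <- function(nm, el) {
    # element symbols of one char start in column 14
    ifelse(nchar(nm) >= 4, nm,
           ifelse(nchar(el) == 1, sprintf(" %-3s", nm), sprintf("%-4s", nm)))
  }
  fmt <- function(row) {
    sprintf("%-6s%5d %4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            row$record, row$serial %% 100000L, pad_name(row$name, row$element),
            row$altloc, row$resname, row$chain, row$resseq %% 10000L, row$icode,
            row$x, row$y, row$z, row$occ, row$b, row$element)
  }
  ord <- order(a$record != "ATOM")  # ATOM first, then HETATM
  a <- a[ord, , drop = FALSE]
  lines <- vapply(seq_len(nrow(a)), function(i) fmt(a[i, ]), character(1))
  con <- file(path, "w")
  on.exit(close(con))
  if (model$target_id != "" || model$model_index > 0L) {
    writeLines(c("PFRMAT TS",
                 sprintf("TARGET %s", model$target_id),
                 sprintf("MODEL  %d", model$model_index)), con)
  }
  writeLines(c(lines, "TER", "END"), con)
  invisible(path)
}

#' Build residue selectors
#'
#' @param chain chain id, or "*" to match any chain.
#' @param resseq author residue number(s).
#' @param icode insertion code(s), default "".
#' @return data.frame of selectors (one row per residue).
#' @export
residue_selector <- function(chain, resseq, icode = "") {
  data.frame(chain = chain, resseq = as.integer(resseq), icode = icode,
             stringsAsFactors = FALSE)
}

#' Resolve residue selectors against a structure
#'
#' Missing selectors are reported, never silently dropped. A wildcard chain
#' (`"*"`) matches every chain, expanded in chain-alphabetical order.
#'
#' @param model a `structure_model`.
#' @param selectors data.frame from [residue_selector()] (rows are OR-ed).
#' @return list with `hits` (residue key table, selector order) and `miss`
#'   (the selectors that matched nothing).
#' @export
resolve_selection <- function(model, selectors) {
  res <- residue_table(model)
  hits <- list(); miss <- list()
  for (i in seq_len(nrow(selectors))) {
    s <- selectors[i, ]
    m <- res$resseq == s$resseq &
      (is.na(s$icode) | s$icode == "" | res$icode == s$icode)
    if (!is.na(s$chain) && s$chain != "*") m <- m & res$chain == s$chain
    hit <- res[m, , drop = FALSE]
    if (nrow(hit) == 0L) miss[[length(miss) + 1L]] <- s
    else hits[[length(hits) + 1L]] <- hit[order(hit$chain), , drop = FALSE]
  }
  list(hits = if (length(hits)) do.call(rbind, hits) else res[0, ],
       miss = if (length(miss)) do.call(rbind, miss) else selectors[0, ])
}
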