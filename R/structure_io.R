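#' Parse a coordinate file into a structure model
#'
#' Reads a PDB or mmCIF file (via bio3d) into the package's structure model:
#' an atom table restricted to heavy atoms with alternate locations collapsed
#' to the highest-occupancy conformer, a derived residue table with 0-based
#' file-order indices per chain, and the quality metadata (resolution, R-free,
#' experimental method) scanned from the header records that bio3d does not
#' expose.
#'
#' @param path Path to a coordinate file.
#' @param dialect `"pdb"`, `"mmcif"`, or `"auto"` (by file extension).
#' @param structure_id Identifier for the model; defaults to the file base name.
#' @return An object of class `epi_structure`: a list with elements
#'   `structure_id`, `atoms` (data.frame: chain, resno, insert, resid, elety,
#'   elesy, x, y, z, o, alt, seq_index), `residues` (data.frame: chain,
#'   seq_index, resno, insert, resid, one_letter, is_standard, het),
#'   `resolution` (Angstrom or `NA`), `r_free` (or `NA`) and `method`.
#' @export
read_structure <- function(path, dialect = c("auto", "pdb", "mmcif"),
                           structure_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop("coordinate file not found: ", path)
  }
  if (dialect == "auto") {
    dialect <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  raw <- tryCatch(
    if (dialect == "pdb") {
      bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
    } else {
      suppressWarnings(bio3d::read.cif(path, rm.alt = FALSE, verbose = FALSE))
    },
    error = function(e) {
      stop("cannot parse ", dialect, " file '", path, "': ",
           conditionMessage(e), call. = FALSE)
    }
  )
  atoms <- raw$atom
  if (is.null(atoms) || nrow(atoms) == 0) {
    stop("no coordinates section in '", path, "'")
  }
  header <- .scan_quality_header(path, dialect)
  if (is.null(structure_id)) {
    structure_id <- sub("\\.[^.]*$", "", basename(path))
  }
  .build_structure(atoms, structure_id, header$resolution, header$r_free,
                   header$method)
}

# Assemble the epi_structure from a bio3d-style atom data.frame:
# drop hydrogens, collapse altlocs, index residues in file order.
.build_structure <- function(atoms, structure_id, resolution = NA_real_,
                             r_free = NA_real_, method = NA_character_) {
  atoms$insert[is.na(atoms$insert)] <- ""
  atoms$alt[is.na(atoms$alt)] <- ""
  atoms$chain[is.na(atoms$chain)] <- " "
  elesy <- atoms$elesy
  guess <- toupper(substr(gsub("[0-9' ]", "", atoms$elety), 1, 1))
  elesy[is.na(elesy) | elesy == ""] <- guess[is.na(elesy) | elesy == ""]
  atoms$elesy <- toupper(elesy)
  atoms <- atoms[!(atoms$elesy %in% c("H", "D")), , drop = FALSE]
  if (nrow(atoms) == 0) stop("structure contains no heavy atoms")
  if (is.na(atoms$o[1])) atoms$o[is.na(atoms$o)] <- 1
  atoms <- .collapse_altloc(atoms)

  res_key <- paste(atoms$chain, atoms$resno, atoms$insert, sep = "\r")
  first <- !duplicated(res_key)
  res <- data.frame(
    chain = atoms$chain[first],
    resno = atoms$resno[first],
    insert = atoms$insert[first],
    resid = atoms$resid[first],
    stringsAsFactors = FALSE
  )
  res$seq_index <- stats::ave(seq_len(nrow(res)), res$chain,
                              FUN = seq_along) - 1L
  has_ca <- vapply(split(atoms$elety, res_key)[unique(res_key)],
                   function(x) "CA" %in% x, logical(1))
  res$one_letter <- ifelse(res$resid %in% names(.AA3TO1),
                           .AA3TO1[res$resid], "X")
  res$is_standard <- res$resid %in% .STANDARD20 |
    (res$resid %in% names(.AA3TO1) & has_ca) |
    (res$resid == "UNK" & has_ca)
  res$het <- !res$is_standard

  atoms$seq_index <- res$seq_index[match(res_key, paste(res$chain, res$resno,
                                                        res$insert, sep = "\r"))]
  atoms <- atoms[, c("chain", "resno", "insert", "resid", "elety", "elesy",
                     "x", "y", "z", "o", "alt", "seq_index")]
  rownames(atoms) <- NULL
  rownames(res) <- NULL
  structure(
    list(structure_id = structure_id, atoms = atoms, residues = res,
         resolution = resolution, r_free = r_free, method = method),
    class = "epi_structure"
  )
}

# Keep one conformer per (chain, residue, atom name): highest occupancy,
# ties broken toward the alphabetically first altloc ('A' before 'B').
.collapse_altloc <- function(atoms) {
  file_order <- seq_len(nrow(atoms))
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety, sep = "\r")
  ord <- order(key, -atoms$o, atoms$alt)
  keep <- ord[!duplicated(key[ord])]
  atoms[sort(file_order[keep]), , drop = FALSE]
}

.scan_quality_header <- function(path, dialect) {
  lines <- readLines(path, warn = FALSE)
  resolution <- NA_real_
  r_free <- NA_real_
  method <- NA_character_
  num <- function(x) suppressWarnings(as.numeric(x))
  if (dialect == "pdb") {
    m <- grep("^REMARK   2 RESOLUTION\\.", lines, value = TRUE)
    if (length(m)) {
      hit <- regmatches(m[1], regexpr("[0-9]+\\.[0-9]+", m[1]))
      if (length(hit)) resolution <- num(hit)
    }
    m <- grep("^REMARK   3   FREE R VALUE +:", lines, value = TRUE)
    if (length(m)) {
      hit <- regmatches(m[1], regexpr("[0-9]*\\.[0-9]+", m[1]))
      if (length(hit)) r_free <- num(hit)
    }
    m <- grep("^EXPDTA", lines, value = TRUE)
    if (length(m)) method <- trimws(sub("^EXPDTA", "", m[1]))
  } else {
    grab <- function(tag) {
      m <- grep(paste0("^", tag, "\\s"), lines, value = TRUE)
      if (!length(m)) return(NA_character_)
      val <- trimws(sub(paste0("^", tag, "\\s+"), "", m[1]))
      val <- gsub("^'|'$", "", val)
      if (val %in% c("?", ".")) NA_character_ else val
    }
    resolution <- num(grab("_refine\\.ls_d_res_high"))
    if (is.na(resolution)) resolution <- num(grab("_reflns\\.d_resolution_high"))
    r_free <- num(grab("_refine\\.ls_R_factor_R_free"))
    method <- grab("_exptl\\.method")
  }
  list(resolution = resolution, r_free = r_free, method = method)
}

#' @export
print.epi_structure <- function(x, ...) {
  cat("<epi_structure>", x$structure_id, "\n")
  cat("  chains:", paste(unique(x$residues$chain), collapse = ", "), "\n")
  cat("  residues:", nrow(x$residues), " heavy atoms:", nrow(x$atoms), "\n")
  cat("  resolution:", x$resolution, " R-free:", x$r_free, "\n")
  invisible(x)
}

#' One-letter sequence of a chain
#'
#' One letter per standard residue in file order; non-standard residues are
#' skipped, so a fully non-peptidic chain yields `""`.
#'
#' @param model An `epi_structure`.
#' @param chain_id Chain identifier.
#' @return Character scalar.
#' @export
chain_sequence <- function(model, chain_id) {
  stopifnot(inherits(model, "epi_structure"))
  res <- model$residues
  res <- res[res$chain == chain_id & res$is_standard, , drop = FALSE]
  if (nrow(res) == 0) return("")
  paste(res$one_letter[order(res$seq_index)], collapse = "")
}

#' Molecule kind of a chain
#'
#' `"non-peptidic"` when the chain has no standard amino-acid residue,
#' `"peptide"` up to 30 standard residues, `"protein"` beyond.
#'
#' @inheritParams chain_sequence
#' @export
molecule_kind <- function(model, chain_id) {
  n <- nchar(chain_sequence(model, chain_id))
  if (n == 0) "non-peptidic" else if (n <= 30) "peptide" else "protein"
}

#' Assemble a complex record
#'
#' Binds a structure to its curated chain-role annotation: which chains are the
#' receptor (antibody heavy/light, TCR alpha/beta), which carry the MHC, and
#' which hold the antigen/ligand, plus optional IMGT numbering per receptor
#' chain and MHC class/organism annotation used by the pipeline filters.
#'
#' @param model An `epi_structure`.
#' @param complex_type One of `"AB_AG"`, `"TCR_PMHC"`, `"MHC_LIGAND"`.
#' @param chain_roles Named character vector, chain id -> role in
#'   `heavy, light, alpha, beta, mhc_a, mhc_b`.
#' @param antigen_chains Character vector of antigen/ligand chain ids.
#' @param numbering Named list (receptor chain id -> numbering data.frame with
#'   columns `imgt`, `ins`, `letter` and optionally `seq_index`), or `NULL`.
#' @param mhc_class,organism Optional annotation strings for the MHC
#'   class/organism filters.
#' @return An object of class `epi_complex`.
#' @export
complex_record <- function(model, complex_type, chain_roles = character(),
                           antigen_chains, numbering = NULL,
                           mhc_class = NA_character_,
                           organism = NA_character_) {
  stopifnot(inherits(model, "epi_structure"))
  complex_type <- match.arg(complex_type, .complex_types)
  roles <- unname(chain_roles)
  bad <- setdiff(roles, c(.receptor_roles, .mhc_roles))
  if (length(bad)) stop("unknown chain role(s): ", paste(bad, collapse = ", "))
  chains <- unique(model$residues$chain)
  missing <- setdiff(c(names(chain_roles), antigen_chains), chains)
  if (length(missing)) {
    stop("annotated chain(s) absent from structure: ",
         paste(missing, collapse = ", "))
  }
  if (length(antigen_chains) == 0) stop("antigen_chains must be non-empty")
  if (length(intersect(antigen_chains, names(chain_roles)))) {
    stop("antigen chains must be disjoint from receptor/MHC chains")
  }
  has <- function(r) any(roles %in% r)
  ok <- switch(complex_type,
    AB_AG = has(c("heavy", "light")) && !has(c("alpha", "beta", .mhc_roles)),
    TCR_PMHC = has(c("alpha", "beta")) && has(.mhc_roles),
    MHC_LIGAND = has(.mhc_roles) && !has(.receptor_roles)
  )
  if (!ok) stop("chain roles inconsistent with complex type ", complex_type)
  rec <- structure(
    list(structure = model, complex_type = complex_type,
         chain_roles = chain_roles, antigen_chains = antigen_chains,
         numbering = numbering, mhc_class = mhc_class, organism = organism),
    class = "epi_complex"
  )
  rec$antigen_is_peptidic <- classify_antigen(rec) == "peptidic"
  rec
}

#' Classify the antigen of a complex as peptidic or not
#'
#' Peptidic iff at least one antigen chain carries at least one standard
#' amino-acid residue; a purely non-peptidic ligand (glycan, small molecule)
#' is `"non_peptidic"`. A hybrid chain with any amino-acid content counts as
#' peptidic.
#'
#' @param record An `epi_complex`.
#' @return `"peptidic"` or `"non_peptidic"`.
#' @export
classify_antigen <- function(record) {
  stopifnot(inherits(record, "epi_complex"))
  pep <- any(vapply(record$antigen_chains, function(ch) {
    nchar(chain_sequence(record$structure, ch)) > 0
  }, logical(1)))
  if (pep) "peptidic" else "non_peptidic"
}

#' @export
print.epi_complex <- function(x, ...) {
  cat("<epi_complex>", x$structure$structure_id, x$complex_type,
      if (x$antigen_is_peptidic) "(peptidic)" else "(non-peptidic)", "\n")
  invisible(x)
}

# Heavy atoms of a chain set, solvent/ions/additives excluded; returns the
# atom data.frame restricted to those chains.
.contact_atoms <- function(model, chain_ids) {
  a <- model$atoms
  a[a$chain %in% chain_ids & !(a$resid %in% .SOLVENT_RESID), , drop = FALSE]
}

.receptor_chain_ids <- function(record, roles = .receptor_roles) {
  names(record$chain_roles)[record$chain_roles %in% roles]
}
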