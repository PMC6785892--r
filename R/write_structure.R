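#' Write a structure model to a PDB or mmCIF file
#'
#' Fixed-width PDB (REMARK 2 resolution, REMARK 3 R-free, EXPDTA, ATOM/HETATM)
#' or a minimal mmCIF with `refine`/`reflns`/`exptl` categories and the
#' standard RCSB `atom_site` column set. This is the dialect the synthetic
#' fixtures are written in; re-parsing with [read_structure()] round-trips
#' chains, residues, coordinates (to 1e-3 Angstrom, the PDB precision) and the
#' quality metadata.
#'
#' @param model An `epi_structure`.
#' @param path Output file path.
#' @param dialect `"pdb"` or `"mmcif"`.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path, dialect = c("pdb", "mmcif")) {
  stopifnot(inherits(model, "epi_structure"))
  dialect <- match.arg(dialect)
  if (dialect == "pdb") .write_pdb(model, path) else .write_cif(model, path)
  invisible(path)
}

.pdb_atom_name <- function(name, elesy) {
  # element right-justified in cols 13-14 for 1-char elements
  ifelse(nchar(name) >= 4, substr(name, 1, 4),
         ifelse(nchar(elesy) == 1, sprintf(" %-3s", name),
                sprintf("%-4s", name)))
}

.write_pdb <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.na(model$method)) {
    writeLines(sprintf("EXPDTA    %s", model$method), con)
  }
  if (!is.na(model$resolution)) {
    writeLines(sprintf("REMARK   2 RESOLUTION.    %.2f ANGSTROMS.",
                       model$resolution), con)
  }
  if (!is.na(model$r_free)) {
    writeLines(sprintf("REMARK   3   FREE R VALUE                     : %.3f",
                       model$r_free), con)
  }
  a <- model$atoms
  het <- model$residues$het[match(paste(a$chain, a$resno, a$insert),
                                  paste(model$residues$chain,
                                        model$residues$resno,
                                        model$residues$insert))]
  rec <- ifelse(het, "HETATM", "ATOM")
  lines <- sprintf(
    "%-6s%5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    rec, seq_len(nrow(a)), .pdb_atom_name(a$elety, a$elesy),
    substr(paste0(a$alt, " "), 1, 1), a$resid, a$chain, a$resno,
    substr(paste0(a$insert, " "), 1, 1), a$x, a$y, a$z, a$o, 0, a$elesy
  )
  writeLines(lines, con)
  writeLines("END", con)
}

.cif_atom_site_cols <- c(
  "group_PDB", "id", "type_symbol", "label_atom_id", "label_alt_id",
  "label_comp_id", "label_asym_id", "label_entity_id", "label_seq_id",
  "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
  "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id", "auth_comp_id",
  "auth_asym_id", "auth_atom_id", "pdbx_PDB_model_num"
)

.write_cif <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("data_%s", model$structure_id), con)
  writeLines("#", con)
  if (!is.na(model$method)) {
    writeLines(sprintf("_exptl.method '%s'", model$method), con)
  }
  if (!is.na(model$resolution)) {
    writeLines(sprintf("_refine.ls_d_res_high %.2f", model$resolution), con)
  }
  if (!is.na(model$r_free)) {
    writeLines(sprintf("_refine.ls_R_factor_R_free %.3f", model$r_free), con)
  }
  writeLines("#", con)
  writeLines("loop_", con)
  writeLines(paste0("_atom_site.", .cif_atom_site_cols), con)
  a <- model$atoms
  het <- model$residues$het[match(paste(a$chain, a$resno, a$insert),
                                  paste(model$residues$chain,
                                        model$residues$resno,
                                        model$residues$insert))]
  q <- function(x, blank = ".") ifelse(is.na(x) | x == "", blank, x)
  lines <- sprintf(
    "%s %d %s %s %s %s %s 1 %d %s %.3f %.3f %.3f %.2f 0.00 ? %d %s %s %s 1",
    ifelse(het, "HETATM", "ATOM"), seq_len(nrow(a)), a$elesy, a$elety,
    q(a$alt), a$resid, a$chain, a$resno, q(a$insert, "?"),
    a$x, a$y, a$z, a$o, a$resno, a$resid, a$chain, a$elety
  )
  writeLines(lines, con)
  writeLines("#", con)
}
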