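#' Read a per-complex annotation record
#'
#' One JSON document per complex: `structure_id`, `complex_type`,
#' `chain_roles` (chain id -> role), `antigen_chains`, optional `mhc_class`
#' and `organism`, and a `numbering` block per receptor chain (parallel arrays
#' `imgt`, `ins`, `letter`, optional `seq_index`, plus `role`), in structural
#' residue order.
#'
#' @param path Path to the annotation JSON.
#' @return The annotation as a list (class `epi_annotation`).
#' @export
read_annotation <- function(path) {
  ann <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("structure_id", "complex_type", "chain_roles", "antigen_chains")
  miss <- setdiff(need, names(ann))
  if (length(miss)) {
    stop("annotation ", path, " lacks field(s): ", paste(miss, collapse = ", "))
  }
  structure(ann, class = "epi_annotation")
}

#' Load a complex from coordinates plus annotation
#'
#' @param coordinates Path to the coordinate file.
#' @param annotation Path to the annotation JSON, or an already-read
#'   `epi_annotation`.
#' @param dialect Coordinate dialect, see [read_structure()].
#' @return An `epi_complex`.
#' @export
load_complex <- function(coordinates, annotation,
                         dialect = c("auto", "pdb", "mmcif")) {
  if (is.character(annotation)) annotation <- read_annotation(annotation)
  model <- read_structure(coordinates, match.arg(dialect),
                          structure_id = annotation$structure_id)
  numbering <- NULL
  if (!is.null(annotation$numbering)) {
    numbering <- lapply(names(annotation$numbering), function(ch) {
      blk <- annotation$numbering[[ch]]
      pos <- data.frame(imgt = as.integer(blk$imgt),
                        ins = as.character(blk$ins),
                        letter = as.character(blk$letter),
                        stringsAsFactors = FALSE)
      if (!is.null(blk$seq_index)) {
        pos$seq_index <- as.integer(blk$seq_index)
      }
      numbered_chain(ch, pos, role = blk$role)
    })
    names(numbering) <- names(annotation$numbering)
  }
  complex_record(
    model,
    complex_type = annotation$complex_type,
    chain_roles = unlist(annotation$chain_roles),
    antigen_chains = as.character(annotation$antigen_chains),
    numbering = numbering,
    mhc_class = if (is.null(annotation$mhc_class)) NA_character_ else annotation$mhc_class,
    organism = if (is.null(annotation$organism)) NA_character_ else annotation$organism
  )
}

#' Read a corpus manifest and load all complexes
#'
#' The manifest JSON lists the corpus: a `complexes` array of
#' `{coordinates, annotation, dialect}` entries (paths relative to the
#' manifest's directory) and optionally a `gdomain_refs` FASTA path.
#'
#' @param path Path to `manifest.json`.
#' @return List with `records` (list of `epi_complex`), `gdomain_refs`
#'   (data.frame or `NULL`) and `manifest` (the raw manifest list).
#' @export
read_manifest <- function(path) {
  man <- jsonlite::read_json(path, simplifyVector = FALSE)
  base <- dirname(path)
  records <- lapply(man$complexes, function(entry) {
    load_complex(
      file.path(base, entry$coordinates),
      file.path(base, entry$annotation),
      dialect = if (is.null(entry$dialect)) "auto" else entry$dialect
    )
  })
  refs <- NULL
  if (!is.null(man$gdomain_refs)) {
    refs <- read_gdomain_refs(file.path(base, man$gdomain_refs))
  }
  list(records = records, gdomain_refs = refs, manifest = man)
}

#' Run all four benchmark branches on a loaded corpus
#'
#' Splits the records by complex type and peptidic/non-peptidic content, runs
#' [run_ab_ag()], [run_tcr_pmhc()], [run_mhc_ligand()] and
#' [run_non_peptidic()], and returns their tables and counts under one roof.
#'
#' @param corpus Result of [read_manifest()], or a list of `epi_complex`.
#' @param config A [filter_config()].
#' @param gdomain_refs Optional G-domain reference data.frame; defaults to the
#'   corpus's own references when `corpus` comes from [read_manifest()].
#' @return Named list `ab_ag`, `tcr_pmhc`, `mhc_ligand`, `non_peptidic`, each
#'   with `table` and `counts`.
#' @export
run_benchmarks <- function(corpus, config = filter_config(),
                           gdomain_refs = NULL) {
  if (!is.null(corpus$records)) {
    if (is.null(gdomain_refs)) gdomain_refs <- corpus$gdomain_refs
    records <- corpus$records
  } else {
    records <- corpus
  }
  types <- vapply(records, function(r) r$complex_type, "")
  pep <- vapply(records, function(r) r$antigen_is_peptidic, logical(1))
  # each type branch sees all complexes of its type and does the peptidic
  # split itself; the non-peptidic branch collects the complement
  list(
    ab_ag = run_ab_ag(records[types == "AB_AG"], config),
    tcr_pmhc = run_tcr_pmhc(records[types == "TCR_PMHC"], config,
                            gdomain_refs),
    mhc_ligand = run_mhc_ligand(records[types == "MHC_LIGAND"], config,
                                gdomain_refs),
    non_peptidic = run_non_peptidic(records[!pep], config, gdomain_refs)
  )
}
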