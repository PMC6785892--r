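#' Filtering and clustering configuration
#'
#' Defaults follow the recommended benchmark-curation settings: 3.0 Angstrom
#' maximum resolution (inclusive; structures with no resolution value are
#' excluded while this filter is active), R-free filter disabled, removal of
#' complexes with missing CDR backbone, 50-residue minimum antigen length
#' (antibody-antigen only), 8-residue minimum core-epitope length (TCR-pMHC
#' and MHC-ligand), 4.0 Angstrom contact cutoff, 70 percent antigen identity,
#' 85 percent core-epitope identity, 0.5 Angstrom distance-match tolerance and
#' the (1.0, 0.9, 0.6) PMax/PMin decision rule.
#'
#' @param max_resolution Maximum resolution in Angstrom (inclusive).
#' @param max_r_free Maximum R-free, or `NA` to disable the filter.
#' @param drop_missing_cdr Drop complexes with missing CDR backbone?
#' @param min_antigen_len Minimum antigen length in residues (Ab-Ag).
#' @param min_core_len Minimum core-epitope length in residues.
#' @param contact_cutoff Contact cutoff in Angstrom.
#' @param antigen_identity Antigen identity threshold in percent.
#' @param core_identity Core-epitope identity threshold in percent.
#' @param pm_tol Distance-match tolerance in Angstrom.
#' @param pm_exact,pm_min,pm_max PMax/PMin decision-rule thresholds.
#' @param mhc_class_filter,mhc_organism_filter Optional exact-match selection
#'   on the complex annotation's MHC class / source organism.
#' @return A `filter_config` list.
#' @export
filter_config <- function(max_resolution = 3.0, max_r_free = NA,
                          drop_missing_cdr = TRUE, min_antigen_len = 50,
                          min_core_len = 8, contact_cutoff = 4.0,
                          antigen_identity = 70, core_identity = 85,
                          pm_tol = 0.5, pm_exact = 1.0, pm_min = 0.9,
                          pm_max = 0.6, mhc_class_filter = NULL,
                          mhc_organism_filter = NULL) {
  stopifnot(max_resolution > 0, min_core_len > 0, contact_cutoff > 0,
            antigen_identity > 0, antigen_identity <= 100,
            core_identity > 0, core_identity <= 100, pm_tol >= 0)
  structure(list(
    max_resolution = max_resolution, max_r_free = max_r_free,
    drop_missing_cdr = drop_missing_cdr, min_antigen_len = min_antigen_len,
    min_core_len = min_core_len, contact_cutoff = contact_cutoff,
    antigen_identity = antigen_identity, core_identity = core_identity,
    pm_tol = pm_tol, pm_exact = pm_exact, pm_min = pm_min, pm_max = pm_max,
    mhc_class_filter = mhc_class_filter,
    mhc_organism_filter = mhc_organism_filter
  ), class = "filter_config")
}

.record_ids <- function(records) {
  vapply(records, function(r) r$structure$structure_id, "")
}

.sort_records <- function(records) {
  records[order(.record_ids(records))]
}

# Longest antigen-chain sequence of a record (the clustering sequence).
.antigen_sequence <- function(record) {
  seqs <- vapply(record$antigen_chains,
                 function(ch) chain_sequence(record$structure, ch), "")
  if (all(!nzchar(seqs))) "" else seqs[which.max(nchar(seqs))]
}

.any_missing_cdr <- function(record) {
  chains <- names(record$chain_roles)[record$chain_roles %in% .receptor_roles]
  any(vapply(chains, function(ch) has_missing_cdr_backbone(record, ch),
             logical(1)))
}

#' Apply the structural-quality filters
#'
#' Sequential exclusion in a fixed order — resolution, R-free, missing CDR
#' backbone, length (antigen length for Ab-Ag, core-epitope length for
#' TCR-pMHC / MHC-ligand) — with per-filter attrition recorded. Filters
#' exclude records, they never raise. The order only affects which filter a
#' doubly-deficient complex is attributed to, not the kept set.
#'
#' @param records List of `epi_complex` objects.
#' @param config A [filter_config()].
#' @param length_filter `"antigen"`, `"core"` or `"none"`.
#' @return List with `kept` (records), `cores` (named list of `core_epitope`
#'   for the kept records, when the core filter ran) and `attrition` (named
#'   integer vector).
#' @export
apply_filters <- function(records, config,
                          length_filter = c("antigen", "core", "none")) {
  length_filter <- match.arg(length_filter)
  attrition <- c(resolution = 0L, r_free = 0L, missing_cdr = 0L, length = 0L)

  ok <- vapply(records, function(r) {
    res <- r$structure$resolution
    !is.na(res) && res <= config$max_resolution
  }, logical(1))
  attrition["resolution"] <- sum(!ok)
  records <- records[ok]

  if (!is.na(config$max_r_free)) {
    ok <- vapply(records, function(r) {
      rf <- r$structure$r_free
      !is.na(rf) && rf <= config$max_r_free
    }, logical(1))
    attrition["r_free"] <- sum(!ok)
    records <- records[ok]
  }

  if (isTRUE(config$drop_missing_cdr)) {
    has_receptor <- vapply(records, function(r) {
      any(r$chain_roles %in% .receptor_roles)
    }, logical(1))
    bad <- vapply(records, function(r) {
      if (!any(r$chain_roles %in% .receptor_roles)) return(FALSE)
      .any_missing_cdr(r)
    }, logical(1))
    attrition["missing_cdr"] <- sum(bad & has_receptor)
    records <- records[!bad]
  }

  cores <- NULL
  if (length_filter == "antigen") {
    ok <- vapply(records, function(r) {
      nchar(.antigen_sequence(r)) >= config$min_antigen_len
    }, logical(1))
    attrition["length"] <- sum(!ok)
    records <- records[ok]
  } else if (length_filter == "core") {
    cores <- lapply(records, core_epitope, cutoff = config$contact_cutoff)
    ok <- vapply(cores, function(cr) cr$length >= config$min_core_len,
                 logical(1))
    attrition["length"] <- sum(!ok)
    records <- records[ok]
    cores <- setNames(cores[ok], .record_ids(records))
  }

  list(kept = records, cores = cores, attrition = attrition)
}

.mhc_preselect <- function(records, config) {
  keep <- vapply(records, function(r) {
    ok <- TRUE
    if (!is.null(config$mhc_class_filter)) {
      ok <- ok && identical(r$mhc_class, config$mhc_class_filter)
    }
    if (!is.null(config$mhc_organism_filter)) {
      ok <- ok && identical(r$organism, config$mhc_organism_filter)
    }
    ok
  }, logical(1))
  records[keep]
}

.empty_result <- function(extra_counts = list()) {
  rows <- data.frame(structure_id = character(), complex_type = character(),
                     stringsAsFactors = FALSE)
  list(table = rows,
       counts = c(list(total = 0L, peptidic = 0L, post_filter = 0L,
                       distinct_pairs = 0L,
                       attrition = as.list(c(resolution = 0L, r_free = 0L,
                                             missing_cdr = 0L, length = 0L))),
                  extra_counts))
}

#' Antibody-antigen benchmark branch
#'
#' Splits off peptidic complexes, applies the quality filters, clusters
#' antigens at the identity threshold, groups antibodies by exact CDR
#' identity, clusters epitope conformations within each antibody group, and
#' reduces to distinct (antibody group, epitope conformation) pairs.
#'
#' @param records List of `epi_complex` objects of type `AB_AG`.
#' @param config A [filter_config()].
#' @return List with `table` (one row per kept complex: cluster labels,
#'   pair-cluster id, representative flag) and `counts` (stage counts with
#'   per-filter attrition and cluster counts).
#' @export
run_ab_ag <- function(records, config = filter_config()) {
  stopifnot(all(vapply(records, function(r) r$complex_type, "") == "AB_AG"))
  if (length(records) == 0) {
    return(.empty_result(list(antigen_clusters = 0L, receptor_clusters = 0L)))
  }
  records <- .sort_records(records)
  total <- length(records)
  pep <- Filter(function(r) r$antigen_is_peptidic, records)
  flt <- apply_filters(pep, config, length_filter = "antigen")
  kept <- flt$kept
  if (length(kept) == 0) {
    out <- .empty_result(list(antigen_clusters = 0L, receptor_clusters = 0L))
    out$counts$total <- total
    out$counts$peptidic <- length(pep)
    out$counts$attrition <- as.list(flt$attrition)
    return(out)
  }
  ids <- .record_ids(kept)

  ag <- cluster_antigens(setNames(vapply(kept, .antigen_sequence, ""), ids),
                         config$antigen_identity)
  rc <- cluster_receptors(kept)

  sites <- setNames(lapply(kept, epitope_site, cutoff = config$contact_cutoff),
                    ids)
  ep_labels <- setNames(character(length(ids)), ids)
  for (lab in unique(rc$labels)) {
    member_ids <- names(rc$labels)[rc$labels == lab]
    ec <- cluster_epitope_conformations(sites[member_ids], tol = config$pm_tol,
                                        pm_exact = config$pm_exact,
                                        pm_min = config$pm_min,
                                        pm_max = config$pm_max)
    ep_labels[member_ids] <- ec$labels[member_ids]
  }

  rows <- data.frame(
    structure_id = ids,
    complex_type = "AB_AG",
    antigen_cluster = unname(ag$labels[ids]),
    receptor_cluster = unname(rc$labels[ids]),
    epitope_cluster = unname(ep_labels[ids]),
    resolution = vapply(kept, function(r) r$structure$resolution, 0),
    r_free = vapply(kept, function(r) r$structure$r_free, 0),
    stringsAsFactors = FALSE
  )
  rows <- distinct_pairs(rows, c("receptor_cluster", "epitope_cluster"))
  list(table = rows, counts = list(
    total = total, peptidic = length(pep), post_filter = length(kept),
    distinct_pairs = attr(rows, "n_pairs"),
    attrition = as.list(flt$attrition),
    antigen_clusters = ag$partition$n_clusters,
    receptor_clusters = rc$partition$n_clusters
  ))
}

#' TCR-pMHC benchmark branch
#'
#' Peptidic split, quality filters including the minimum core-epitope length,
#' then clustering on core-epitope identity, TCR CDR identity and MHC
#' G-domain. Reports both the full (core, TCR, MHC) cluster count and the
#' coarser (core, TCR) TCR-epitope group count; the benchmark table's pair
#' id is the full cluster.
#'
#' @param records List of `epi_complex` objects of type `TCR_PMHC`.
#' @param config A [filter_config()].
#' @param gdomain_refs G-domain references from [read_gdomain_refs()] (or
#'   `NULL`: every MHC is then non-classical, clustered on full sequence).
#' @return List with `table` and `counts` (including `core_clusters`,
#'   `receptor_clusters`, `mhc_clusters`, `full_clusters`,
#'   `tcr_epitope_groups`).
#' @export
run_tcr_pmhc <- function(records, config = filter_config(),
                         gdomain_refs = NULL) {
  stopifnot(all(vapply(records, function(r) r$complex_type, "") == "TCR_PMHC"))
  extra0 <- list(core_clusters = 0L, receptor_clusters = 0L, mhc_clusters = 0L,
                 full_clusters = 0L, tcr_epitope_groups = 0L)
  records <- .mhc_preselect(records, config)
  if (length(records) == 0) return(.empty_result(extra0))
  records <- .sort_records(records)
  total <- length(records)
  pep <- Filter(function(r) r$antigen_is_peptidic, records)
  flt <- apply_filters(pep, config, length_filter = "core")
  kept <- flt$kept
  if (length(kept) == 0) {
    out <- .empty_result(extra0)
    out$counts$total <- total
    out$counts$peptidic <- length(pep)
    out$counts$attrition <- as.list(flt$attrition)
    return(out)
  }
  ids <- .record_ids(kept)

  cores <- flt$cores
  cc <- cluster_core_epitopes(
    setNames(vapply(cores, `[[`, "", "sequence"), ids),
    config$core_identity
  )
  rc <- cluster_receptors(kept)
  mc <- cluster_mhc(kept, gdomain_refs)

  rows <- data.frame(
    structure_id = ids,
    complex_type = "TCR_PMHC",
    core_cluster = unname(cc$labels[ids]),
    receptor_cluster = unname(rc$labels[ids]),
    mhc_cluster = unname(mc$labels[ids]),
    core_sequence = vapply(cores, `[[`, "", "sequence")[ids],
    resolution = vapply(kept, function(r) r$structure$resolution, 0),
    r_free = vapply(kept, function(r) r$structure$r_free, 0),
    stringsAsFactors = FALSE
  )
  rows <- distinct_pairs(rows, c("core_cluster", "receptor_cluster",
                                 "mhc_cluster"))
  full_clusters <- attr(rows, "n_pairs")
  tcr_epitope_groups <- length(unique(paste(rows$core_cluster,
                                            rows$receptor_cluster)))
  list(table = rows, counts = list(
    total = total, peptidic = length(pep), post_filter = length(kept),
    distinct_pairs = tcr_epitope_groups,
    attrition = as.list(flt$attrition),
    core_clusters = cc$partition$n_clusters,
    receptor_clusters = rc$partition$n_clusters,
    mhc_clusters = mc$partition$n_clusters,
    full_clusters = full_clusters,
    tcr_epitope_groups = tcr_epitope_groups
  ))
}

#' MHC-ligand benchmark branch
#'
#' Peptidic split, quality filters with the minimum core-peptide length, then
#' clustering on core-peptide identity and MHC G-domain; distinct pairs are
#' the (core, MHC) combinations.
#'
#' @inheritParams run_tcr_pmhc
#' @param records List of `epi_complex` objects of type `MHC_LIGAND`.
#' @export
run_mhc_ligand <- function(records, config = filter_config(),
                           gdomain_refs = NULL) {
  stopifnot(all(vapply(records, function(r) r$complex_type, "") == "MHC_LIGAND"))
  extra0 <- list(core_clusters = 0L, mhc_clusters = 0L)
  records <- .mhc_preselect(records, config)
  if (length(records) == 0) return(.empty_result(extra0))
  records <- .sort_records(records)
  total <- length(records)
  pep <- Filter(function(r) r$antigen_is_peptidic, records)
  flt <- apply_filters(pep, config, length_filter = "core")
  kept <- flt$kept
  if (length(kept) == 0) {
    out <- .empty_result(extra0)
    out$counts$total <- total
    out$counts$peptidic <- length(pep)
    out$counts$attrition <- as.list(flt$attrition)
    return(out)
  }
  ids <- .record_ids(kept)
  cores <- flt$cores
  cc <- cluster_core_epitopes(
    setNames(vapply(cores, `[[`, "", "sequence"), ids),
    config$core_identity
  )
  mc <- cluster_mhc(kept, gdomain_refs)
  rows <- data.frame(
    structure_id = ids,
    complex_type = "MHC_LIGAND",
    core_cluster = unname(cc$labels[ids]),
    mhc_cluster = unname(mc$labels[ids]),
    core_sequence = vapply(cores, `[[`, "", "sequence")[ids],
    resolution = vapply(kept, function(r) r$structure$resolution, 0),
    r_free = vapply(kept, function(r) r$structure$r_free, 0),
    stringsAsFactors = FALSE
  )
  rows <- distinct_pairs(rows, c("core_cluster", "mhc_cluster"))
  list(table = rows, counts = list(
    total = total, peptidic = length(pep), post_filter = length(kept),
    distinct_pairs = attr(rows, "n_pairs"),
    attrition = as.list(flt$attrition),
    core_clusters = cc$partition$n_clusters,
    mhc_clusters = mc$partition$n_clusters
  ))
}

#' Non-peptidic branch
#'
#' Complexes whose antigen/ligand carries no amino-acid content are filtered
#' on resolution and missing CDR backbone only, then grouped by receptor CDR
#' identity (Ab-Ag, TCR-pMHC) and MHC G-domain (TCR-pMHC, MHC-ligand). No
#' antigen, core or epitope-conformation clustering applies.
#'
#' @param records List of non-peptidic `epi_complex` objects (any type);
#'   passing a peptidic record is an error.
#' @param config A [filter_config()].
#' @param gdomain_refs Optional G-domain references.
#' @return List with `table` (structure id, type, receptor and/or MHC group)
#'   and `counts` (per-type group counts and attrition).
#' @export
run_non_peptidic <- function(records, config = filter_config(),
                             gdomain_refs = NULL) {
  if (any(vapply(records, function(r) r$antigen_is_peptidic, logical(1)))) {
    stop("run_non_peptidic received a peptidic complex")
  }
  counts <- list(total = length(records), post_filter = 0L,
                 attrition = list(resolution = 0L, r_free = 0L,
                                  missing_cdr = 0L, length = 0L),
                 ab_receptor_groups = 0L, tcr_receptor_groups = 0L,
                 tcr_mhc_groups = 0L, mhc_ligand_mhc_groups = 0L)
  rows <- data.frame(structure_id = character(), complex_type = character(),
                     receptor_cluster = character(), mhc_cluster = character(),
                     stringsAsFactors = FALSE)
  if (length(records) == 0) return(list(table = rows, counts = counts))
  records <- .sort_records(records)
  flt <- apply_filters(records, config, length_filter = "none")
  kept <- flt$kept
  counts$attrition <- as.list(flt$attrition)
  counts$post_filter <- length(kept)
  if (length(kept) == 0) return(list(table = rows, counts = counts))

  types <- vapply(kept, function(r) r$complex_type, "")
  pieces <- list()
  for (ty in unique(types)) {
    sub <- kept[types == ty]
    ids <- .record_ids(sub)
    rlab <- rep(NA_character_, length(ids))
    mlab <- rep(NA_character_, length(ids))
    if (ty %in% c("AB_AG", "TCR_PMHC")) {
      rc <- cluster_receptors(sub)
      rlab <- unname(rc$labels[ids])
      if (ty == "AB_AG") counts$ab_receptor_groups <- rc$partition$n_clusters
      if (ty == "TCR_PMHC") counts$tcr_receptor_groups <- rc$partition$n_clusters
    }
    if (ty %in% c("TCR_PMHC", "MHC_LIGAND")) {
      mc <- cluster_mhc(sub, gdomain_refs)
      mlab <- unname(mc$labels[ids])
      if (ty == "TCR_PMHC") counts$tcr_mhc_groups <- mc$partition$n_clusters
      if (ty == "MHC_LIGAND") counts$mhc_ligand_mhc_groups <- mc$partition$n_clusters
    }
    pieces[[ty]] <- data.frame(structure_id = ids, complex_type = ty,
                               receptor_cluster = rlab, mhc_cluster = mlab,
                               stringsAsFactors = FALSE)
  }
  rows <- do.call(rbind, pieces)
  rows <- rows[order(rows$structure_id), ]
  rownames(rows) <- NULL
  list(table = rows, counts = counts)
}

#' Write a benchmark table as TSV
#'
#' @param table data.frame from a pipeline branch.
#' @param path Output path.
#' @export
write_benchmark_tsv <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write stage counts as JSON
#'
#' @param counts Counts list from a pipeline branch (or a named list of them).
#' @param path Output path.
#' @export
write_counts_json <- function(counts, path) {
  jsonlite::write_json(counts, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
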