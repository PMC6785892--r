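#' Residue-residue contacts between two atom sets
#'
#' A residue pair is in contact iff the minimum Euclidean distance over its
#' heavy-atom pairs is at most `cutoff` (inclusive, 4 Angstrom by default, the
#' standard interface criterion). One row per contacting residue pair with the
#' minimal distance.
#'
#' @param atoms_a,atoms_b Atom data.frames (columns `chain`, `seq_index`, `x`,
#'   `y`, `z`), e.g. subsets of an `epi_structure`'s `atoms` table.
#' @param cutoff Distance cutoff in Angstrom.
#' @return data.frame with columns `chain_a`, `res_a`, `chain_b`, `res_b`,
#'   `min_distance`; empty (zero rows) when either set is empty or nothing is
#'   within the cutoff.
#' @export
compute_contacts <- function(atoms_a, atoms_b, cutoff = 4.0) {
  stopifnot(cutoff > 0)
  empty <- data.frame(chain_a = character(), res_a = integer(),
                      chain_b = character(), res_b = integer(),
                      min_distance = numeric(), stringsAsFactors = FALSE)
  if (NROW(atoms_a) == 0 || NROW(atoms_b) == 0) return(empty)
  d <- .cross_dist(atoms_a, atoms_b)
  hit <- which(d <= cutoff, arr.ind = TRUE)
  if (nrow(hit) == 0) return(empty)
  key_a <- paste(atoms_a$chain[hit[, 1]], atoms_a$seq_index[hit[, 1]], sep = "\r")
  key_b <- paste(atoms_b$chain[hit[, 2]], atoms_b$seq_index[hit[, 2]], sep = "\r")
  pair <- paste(key_a, key_b, sep = "\n")
  mins <- tapply(d[hit], pair, min)
  parts <- strsplit(names(mins), "\n", fixed = TRUE)
  pa <- strsplit(vapply(parts, `[`, "", 1), "\r", fixed = TRUE)
  pb <- strsplit(vapply(parts, `[`, "", 2), "\r", fixed = TRUE)
  out <- data.frame(
    chain_a = vapply(pa, `[`, "", 1),
    res_a = as.integer(vapply(pa, `[`, "", 2)),
    chain_b = vapply(pb, `[`, "", 1),
    res_b = as.integer(vapply(pb, `[`, "", 2)),
    min_distance = as.numeric(mins),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$chain_a, out$res_a, out$chain_b, out$res_b), ]
  rownames(out) <- NULL
  out
}

# Full cross distance matrix between two atom tables.
.cross_dist <- function(a, b) {
  A <- cbind(a$x, a$y, a$z)
  B <- cbind(b$x, b$y, b$z)
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

#' Epitope binding site of an antibody-antigen complex
#'
#' The epitope is the set of antigen residues with at least one heavy atom
#' within `cutoff` of any antibody-chain heavy atom; the site carries all
#' heavy atoms of those residues, which is the atom set scored for
#' conformational similarity.
#'
#' @param record An `epi_complex` of type `AB_AG` with a peptidic antigen.
#' @param cutoff Contact cutoff in Angstrom.
#' @return An `epitope_site`: list with `residues` (data.frame chain,
#'   seq_index), `atoms` (atom data.frame), `structure_id` and `empty` flag.
#'   An empty site (no contacts) is returned flagged, not an error, so the
#'   complex can be reported and skipped in conformational clustering.
#' @export
epitope_site <- function(record, cutoff = 4.0) {
  stopifnot(inherits(record, "epi_complex"),
            record$complex_type == "AB_AG")
  model <- record$structure
  rec_atoms <- .contact_atoms(model, .receptor_chain_ids(record, c("heavy", "light")))
  ant_atoms <- .contact_atoms(model, record$antigen_chains)
  contacts <- compute_contacts(ant_atoms, rec_atoms, cutoff)
  res <- unique(contacts[, c("chain_a", "res_a")])
  names(res) <- c("chain", "seq_index")
  res <- res[order(res$chain, res$seq_index), , drop = FALSE]
  rownames(res) <- NULL
  keep <- paste(ant_atoms$chain, ant_atoms$seq_index) %in%
    paste(res$chain, res$seq_index)
  structure(list(residues = res, atoms = ant_atoms[keep, , drop = FALSE],
                 structure_id = model$structure_id,
                 empty = nrow(res) == 0),
            class = "epitope_site")
}

#' Core-epitope (core-peptide) of a TCR-pMHC or MHC-ligand complex
#'
#' All residues between the first and the last residue of the antigen chain
#' lying within `cutoff` of any heavy atom of the TCR and MHC chains (TCR-pMHC)
#' or of the MHC chains alone (MHC-ligand) — a contiguous span that trims the
#' non-interacting peptide overhangs but keeps non-contacting interior
#' residues. With several antigen chains the span is computed per chain and
#' the longest returned; with no contacts the core has length 0, which the
#' pipeline's minimum-length filter then rejects.
#'
#' @param record An `epi_complex` of type `TCR_PMHC` or `MHC_LIGAND`.
#' @param cutoff Contact cutoff in Angstrom.
#' @return A `core_epitope`: list with `chain_id`, `start_index`, `end_index`,
#'   `sequence`, `length`.
#' @export
core_epitope <- function(record, cutoff = 4.0) {
  stopifnot(inherits(record, "epi_complex"),
            record$complex_type %in% c("TCR_PMHC", "MHC_LIGAND"))
  model <- record$structure
  roles <- if (record$complex_type == "TCR_PMHC") {
    c("alpha", "beta", .mhc_roles)
  } else {
    .mhc_roles
  }
  rec_atoms <- .contact_atoms(model, .receptor_chain_ids(record, roles))
  best <- list(chain_id = record$antigen_chains[1], start_index = NA_integer_,
               end_index = NA_integer_, sequence = "", length = 0L)
  for (ch in record$antigen_chains) {
    ant_atoms <- .contact_atoms(model, ch)
    contacts <- compute_contacts(ant_atoms, rec_atoms, cutoff)
    if (nrow(contacts) == 0) next
    lo <- min(contacts$res_a)
    hi <- max(contacts$res_a)
    res <- model$residues
    res <- res[res$chain == ch & res$seq_index >= lo & res$seq_index <= hi, ]
    res <- res[order(res$seq_index), , drop = FALSE]
    core <- list(chain_id = ch, start_index = lo, end_index = hi,
                 sequence = paste(res$one_letter, collapse = ""),
                 length = hi - lo + 1L)
    if (core$length > best$length) best <- core
  }
  structure(best, class = "core_epitope")
}

#' Export a contact list as TSV
#'
#' @param contacts data.frame from [compute_contacts()].
#' @param structure_id Identifier prepended as the first column.
#' @param path Output path.
#' @export
write_contacts_tsv <- function(contacts, structure_id, path) {
  out <- cbind(structure_id = structure_id, contacts)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
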