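# IMGT unique numbering puts the three CDR loops at fixed positions for
# antibody and TCR variable domains alike.
.IMGT_CDR_RANGES <- list(cdr1 = c(27L, 38L), cdr2 = c(56L, 65L),
                         cdr3 = c(105L, 117L))

#' Build a numbered receptor chain
#'
#' Wraps an IMGT numbering table for one receptor chain. Positions are given
#' in structural residue order (the order an IMGT numbering tool emits them
#' for the chain); each may carry an explicit `seq_index` into the chain's
#' residue list, with `NA` marking a numbered residue that has no coordinates.
#' When `seq_index` is absent, positions map 1:1 onto the chain's standard
#' residues in order, starting at `start_index`.
#'
#' @param chain_id Chain identifier.
#' @param positions data.frame with columns `imgt` (integer), `ins` (insertion
#'   code, `""` for none), `letter` (one-letter residue) and optionally
#'   `seq_index`.
#' @param role One of `"heavy"`, `"light"`, `"alpha"`, `"beta"`.
#' @param start_index 0-based offset used only when `seq_index` is absent.
#' @return An object of class `numbered_chain`.
#' @export
numbered_chain <- function(chain_id, positions, role, start_index = 0L) {
  role <- match.arg(role, .receptor_roles)
  stopifnot(is.data.frame(positions),
            all(c("imgt", "ins", "letter") %in% names(positions)))
  if (nrow(positions) == 0) stop("empty numbering for chain ", chain_id)
  positions$imgt <- as.integer(positions$imgt)
  positions$ins[is.na(positions$ins)] <- ""
  key <- paste(positions$imgt, positions$ins)
  if (anyDuplicated(key)) {
    stop("duplicate IMGT (number, insertion) in chain ", chain_id, ": ",
         key[duplicated(key)][1])
  }
  if (!"seq_index" %in% names(positions)) {
    positions$seq_index <- NA_integer_
    attr(positions, "auto_map") <- TRUE
  } else {
    attr(positions, "auto_map") <- NULL
  }
  structure(list(chain_id = chain_id, positions = positions, role = role,
                 start_index = as.integer(start_index)),
            class = "numbered_chain")
}

#' Extract CDR sequences from an IMGT-numbered chain
#'
#' CDR1 = IMGT 27-38, CDR2 = 56-65, CDR3 = 105-117, inclusive bounds,
#' insertions included. Residues are taken in the order of the numbering
#' table, which for IMGT output is the chain's structural order (and thus
#' follows the IMGT insertion convention around position 111/112). Positions
#' absent from the numbering are simply absent from the CDR.
#'
#' @param numbered A `numbered_chain`.
#' @return A `cdr_set`: list with `cdr1`, `cdr2`, `cdr3` (one-letter strings),
#'   `cdr_positions` (per-CDR data.frames of imgt/ins/seq_index) and
#'   `chain_role`.
#' @export
extract_cdrs <- function(numbered) {
  stopifnot(inherits(numbered, "numbered_chain"))
  pos <- numbered$positions
  out <- list()
  cdr_pos <- list()
  for (nm in names(.IMGT_CDR_RANGES)) {
    rng <- .IMGT_CDR_RANGES[[nm]]
    sel <- pos$imgt >= rng[1] & pos$imgt <= rng[2]
    out[[nm]] <- paste(pos$letter[sel], collapse = "")
    cdr_pos[[nm]] <- pos[sel, , drop = FALSE]
  }
  structure(list(cdr1 = out$cdr1, cdr2 = out$cdr2, cdr3 = out$cdr3,
                 cdr_positions = cdr_pos, chain_role = numbered$role,
                 chain_id = numbered$chain_id),
            class = "cdr_set")
}

#' Canonical CDR identity key for one receptor chain
#'
#' `CDR1|CDR2|CDR3`, upper-cased: two chains belong to the same receptor group
#' iff their keys are equal, regardless of framework sequence.
#'
#' @param cdrs A `cdr_set`.
#' @return Character scalar.
#' @export
cdr_key <- function(cdrs) {
  stopifnot(inherits(cdrs, "cdr_set"))
  toupper(paste(cdrs$cdr1, cdrs$cdr2, cdrs$cdr3, sep = "|"))
}

# Resolve numbering positions to residue seq_index values for a chain,
# honouring explicit indices (NA = missing from coordinates) or mapping by
# order onto the chain's standard residues.
.resolve_numbering <- function(record, chain_id, numbered) {
  res <- record$structure$residues
  res <- res[res$chain == chain_id, , drop = FALSE]
  if (nrow(res) == 0) stop("chain ", chain_id, " not in structure")
  res <- res[order(res$seq_index), , drop = FALSE]
  pos <- numbered$positions
  if (isTRUE(attr(pos, "auto_map")) || all(is.na(pos$seq_index))) {
    std <- res[res$is_standard, , drop = FALSE]
    idx <- numbered$start_index + seq_len(nrow(pos))  # 1-based into std rows
    if (max(idx) > nrow(std)) {
      stop("numbering for chain ", chain_id,
           " is longer than the chain's standard residues and carries no ",
           "explicit seq_index; cannot align by order")
    }
    pos$seq_index <- std$seq_index[idx]
  } else {
    known <- pos$seq_index[!is.na(pos$seq_index)]
    if (length(known) && !all(known %in% res$seq_index)) {
      stop("numbering for chain ", chain_id,
           " references residue indices absent from the structure")
    }
    ok <- !is.na(pos$seq_index)
    letters_there <- res$one_letter[match(pos$seq_index[ok], res$seq_index)]
    mism <- letters_there != pos$letter[ok] & letters_there != "X"
    if (any(mism)) {
      stop("numbering letters disagree with structure residues for chain ",
           chain_id, " (first at IMGT ", pos$imgt[ok][mism][1], ")")
    }
  }
  pos
}

#' Detect missing backbone in the CDR regions
#'
#' `TRUE` iff any CDR position of the chain either maps to no residue with
#' coordinates, or maps to a residue lacking any of the backbone atoms
#' N, CA, C. Carbonyl O alone does not count: the filter targets chain-trace
#' completeness of the loops, which is what degrades an interface benchmark.
#'
#' @param record An `epi_complex`.
#' @param chain_id Receptor chain to check.
#' @param cdrs Optional `cdr_set` for the chain (recomputed if omitted).
#' @return Logical scalar.
#' @export
has_missing_cdr_backbone <- function(record, chain_id, cdrs = NULL) {
  stopifnot(inherits(record, "epi_complex"))
  numbered <- record$numbering[[chain_id]]
  if (is.null(numbered)) stop("no numbering for chain ", chain_id)
  pos <- .resolve_numbering(record, chain_id, numbered)
  in_cdr <- rep(FALSE, nrow(pos))
  for (rng in .IMGT_CDR_RANGES) {
    in_cdr <- in_cdr | (pos$imgt >= rng[1] & pos$imgt <= rng[2])
  }
  cdr_pos <- pos[in_cdr, , drop = FALSE]
  if (nrow(cdr_pos) == 0) return(FALSE)
  if (anyNA(cdr_pos$seq_index)) return(TRUE)
  atoms <- record$structure$atoms
  atoms <- atoms[atoms$chain == chain_id, , drop = FALSE]
  for (si in cdr_pos$seq_index) {
    names_here <- atoms$elety[atoms$seq_index == si]
    if (!all(c("N", "CA", "C") %in% names_here)) return(TRUE)
  }
  FALSE
}
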