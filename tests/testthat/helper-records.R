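# Builders for small in-code complexes, assembled from the package's own
# geometry primitives (serpentine chains; contact residues whose CB probes
# 3.7 A above a target atom).

serp <- function(n, row_len = 15, origin = c(0, 0, 0)) {
  epibench:::.serpentine(n, row_len, origin)
}

mk_chain <- function(chain_id, seq, origin = c(0, 0, 0), row_len = 15,
                     targets = NULL) {
  epibench:::.make_chain_atoms(chain_id, seq, origin, row_len,
                               contact_targets = targets)
}

mk_model <- function(atoms, id = "toy1", resolution = 2.0, r_free = NA_real_,
                     method = "X-RAY DIFFRACTION") {
  epibench:::.build_structure(atoms, id, resolution = resolution,
                              r_free = r_free, method = method)
}

# 0-based epitope indices -> contact-target list keyed for .make_chain_atoms
targets_above <- function(ca, idx0) {
  setNames(lapply(idx0 + 1L, function(i) ca[i, ]), as.character(idx0))
}

# Antibody-antigen toy: antigen chain G (n_ag residues) plus a 6-residue
# heavy chain at z = 12 whose last residues are repositioned over the given
# antigen residues. `shift` displaces the whole antibody chain.
mk_abag <- function(id = "toy1", epitope_idx = c(3L, 4L, 7L), n_ag = 12,
                    ag_seq = NULL, resolution = 2.0, shift = c(0, 0, 0),
                    numbering = NULL, r_free = NA_real_) {
  if (is.null(ag_seq)) {
    ag_seq <- paste(rep_len(c("A", "C", "D", "E", "F", "G", "H", "I", "K",
                              "L", "M", "N"), n_ag), collapse = "")
  }
  ag_ca <- serp(nchar(ag_seq))
  ag <- mk_chain("G", ag_seq, c(0, 0, 0))
  n_para <- length(epitope_idx)
  h_seq <- paste(rep_len(c("Q", "R", "S", "T", "V", "W"), 6 + n_para),
                 collapse = "")
  tg <- if (n_para > 0) {
    tgt <- targets_above(ag_ca, epitope_idx)
    names(tgt) <- as.character((6 + n_para - n_para):(6 + n_para - 1))
    tgt
  }
  hv <- mk_chain("H", h_seq, c(0, 0, 12), targets = tg)
  hv$x <- hv$x + shift[1]; hv$y <- hv$y + shift[2]; hv$z <- hv$z + shift[3]
  model <- mk_model(rbind(ag, hv), id, resolution = resolution,
                    r_free = r_free)
  complex_record(model, "AB_AG", c(H = "heavy"), "G", numbering = numbering)
}

# Peptide-in-groove toy: peptide chain P plus an MHC chain M (and optionally
# a TCR alpha chain A) whose trailing residues contact the given 0-based
# peptide residues.
mk_pmhc <- function(id = "toy1", contact_idx = 1:9, pep_len = 11,
                    with_tcr = FALSE, mhc_seq = NULL, resolution = 2.0,
                    numbering = NULL) {
  pep_seq <- paste(rep_len(c("G", "I", "L", "V", "F", "M", "S", "T", "W",
                             "Y", "A"), pep_len), collapse = "")
  pep_ca <- serp(pep_len)
  pep <- mk_chain("P", pep_seq, c(0, 0, 0))
  if (is.null(mhc_seq)) {
    mhc_seq <- paste(rep_len(c("D", "E", "K", "R", "H", "N", "Q", "P"), 30),
                     collapse = "")
  }
  n_m <- nchar(mhc_seq)
  tg <- targets_above(pep_ca, contact_idx)
  names(tg) <- as.character((n_m - length(contact_idx)):(n_m - 1))
  mhc <- mk_chain("M", mhc_seq, c(0, 0, 24), row_len = 18, targets = tg)
  chains <- rbind(pep, mhc)
  roles <- c(M = "mhc_a")
  type <- "MHC_LIGAND"
  if (with_tcr) {
    a_seq <- paste(rep_len(c("A", "G", "S"), 27), collapse = "")
    chains <- rbind(chains, mk_chain("A", a_seq, c(0, 0, 12)))
    roles <- c(A = "alpha", roles)
    type <- "TCR_PMHC"
    if (is.null(numbering)) {
      numbering <- list(A = numbered_chain("A", data.frame(
        imgt = c(27:34, 56:62, 105:116), ins = "",
        letter = strsplit(a_seq, "")[[1]], stringsAsFactors = FALSE
      ), role = "alpha"))
    }
  }
  model <- mk_model(chains, id, resolution = resolution)
  complex_record(model, type, roles, "P", numbering = numbering)
}

# Receptor-only record for CDR grouping tests: chains carry just their CDR
# residues (plus optional framework residues outside the IMGT CDR windows).
mk_receptor_record <- function(id, heavy_cdrs, light_cdrs = NULL,
                               fw = "", resolution = 2.0) {
  mk_num <- function(cdrs, role) {
    seq <- paste0(fw, cdrs$cdr1, cdrs$cdr2, cdrs$cdr3)
    imgt <- c(if (nzchar(fw)) seq(10, length.out = nchar(fw)),
              27:(27 + nchar(cdrs$cdr1) - 1),
              56:(56 + nchar(cdrs$cdr2) - 1),
              105:(105 + nchar(cdrs$cdr3) - 1))
    list(seq = seq,
         num = numbered_chain(if (role == "heavy") "H" else "L",
                              data.frame(imgt = imgt, ins = "",
                                         letter = strsplit(seq, "")[[1]],
                                         stringsAsFactors = FALSE),
                              role = role))
  }
  h <- mk_num(heavy_cdrs, "heavy")
  chains <- rbind(mk_chain("G", "AGC", c(0, 0, 0)),
                  mk_chain("H", h$seq, c(0, 0, 12)))
  numbering <- list(H = h$num)
  roles <- c(H = "heavy")
  if (!is.null(light_cdrs)) {
    l <- mk_num(light_cdrs, "light")
    chains <- rbind(chains, mk_chain("L", l$seq, c(0, 0, 24)))
    numbering$L <- l$num
    roles <- c(roles, L = "light")
  }
  model <- mk_model(chains, id, resolution = resolution)
  complex_record(model, "AB_AG", roles, "G", numbering = numbering)
}

# Ab-Ag record with full receptor numbering so every quality filter can run.
mk_quality_record <- function(id, resolution, n_ag = 60, r_free = NA_real_) {
  ag <- paste(rep_len(c("A", "D", "E", "F", "G", "H", "I", "K", "L", "M"),
                      n_ag), collapse = "")
  rec <- mk_receptor_record(id, cdrs1, resolution = resolution)
  atoms <- rec$structure$atoms
  atoms$seq_index <- NULL
  atoms <- atoms[atoms$chain != "G", , drop = FALSE]
  atoms <- rbind(mk_chain("G", ag, c(0, 0, -20)), atoms)
  model <- mk_model(atoms, id, resolution = resolution, r_free = r_free)
  complex_record(model, "AB_AG", c(H = "heavy"), "G",
                 numbering = rec$numbering)
}

cdrs1 <- list(cdr1 = "AAAAAAAA", cdr2 = "CCCCCCC", cdr3 = "DDDDDDDDDDDD")
cdrs2 <- list(cdr1 = "EEEEEEEE", cdr2 = "FFFFFFF", cdr3 = "GGGGGGGGGGGG")
cdrs3 <- list(cdr1 = "AAAAAAAA", cdr2 = "CCCCCCC", cdr3 = "DDDDDDDDDDDW")
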