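# ---------------------------------------------------------------------------
# Synthetic-complex generator: toy receptor-antigen complexes with planted
# contacts, sequence identities, site conformations and quality defects, so
# every pipeline stage is testable offline with expected counts known in
# closed form from the plant.
# ---------------------------------------------------------------------------

.AA1TO3 <- setNames(names(.AA3TO1)[1:20], unname(.AA3TO1[1:20]))
.AA20 <- names(.AA1TO3)

# Serpentine CA trace: rows of `row_len` residues, 3.8 A CA-CA spacing along
# x, 6 A between rows, all in one z-plane. Keeps long chains inside the
# 100 A fixture box.
.serpentine <- function(n, row_len = 15, origin = c(0, 0, 0)) {
  i <- seq_len(n) - 1L
  cbind(origin[1] + (i %% row_len) * 3.8,
        origin[2] + (i %/% row_len) * 6,
        origin[3] + 0)
}

# Five heavy atoms per residue around a CA position. The idealized offsets
# keep every intra/inter-residue atom pair >= 1.0 A apart along a serpentine
# trace. `down = TRUE` points CB along -z (used for contact residues so the
# CB probes toward a target below).
.residue_atom_offsets <- function(down = FALSE) {
  if (down) {
    rbind(N = c(-1.3, 0.5, 0.4), CA = c(0, 0, 0), C = c(1.3, 0.5, -0.4),
          O = c(1.3, 1.7, -0.4), CB = c(0, 0, -1.5))
  } else {
    rbind(N = c(-1.3, 0.5, 0.4), CA = c(0, 0, 0), C = c(1.3, 0.5, -0.4),
          O = c(1.3, 1.7, -0.4), CB = c(0, -1.5, 0))
  }
}

.atoms_df <- function(chain, resno, resid, elety, elesy, xyz, o = 1) {
  data.frame(chain = chain, resno = as.integer(resno), insert = "",
             resid = resid, elety = elety, elesy = elesy,
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], o = o, alt = "",
             stringsAsFactors = FALSE)
}

# Build a protein chain as atoms: 5 heavy atoms per residue on a serpentine
# trace. `contact_map` repositions whole residues: a named list
# residue_index(0-based) -> target xyz; the residue's CA is placed 5.2 A
# above the target in +z with CB pointing down, putting its CB 3.7 A from
# the target (a contact at the 4 A cutoff) while every atom of any *other*
# residue near the target stays > 4 A away.
.make_chain_atoms <- function(chain_id, seq_letters, origin, row_len = 15,
                              contact_targets = NULL) {
  letters <- strsplit(seq_letters, "")[[1]]
  n <- length(letters)
  ca <- .serpentine(n, row_len, origin)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    target <- if (!is.null(contact_targets)) contact_targets[[as.character(i - 1)]]
    if (!is.null(target)) {
      off <- .residue_atom_offsets(down = TRUE)
      base <- target + c(0, 0, 5.2)
    } else {
      off <- .residue_atom_offsets(down = FALSE)
      base <- ca[i, ]
    }
    xyz <- sweep(off, 2, base, "+")
    res3 <- if (letters[i] %in% names(.AA1TO3)) .AA1TO3[[letters[i]]] else "UNK"
    rows[[i]] <- .atoms_df(chain_id, i, res3, rownames(off),
                           c("N", "C", "C", "O", "C"), xyz)
  }
  do.call(rbind, rows)
}

# A non-peptidic ligand: a sugar-like hexagon of heavy atoms, 1.5 A radius.
.make_ligand_atoms <- function(chain_id, origin = c(0, 0, 0)) {
  ang <- (0:5) * pi / 3
  xyz <- cbind(origin[1] + 1.5 * cos(ang), origin[2] + 1.5 * sin(ang),
               origin[3])
  .atoms_df(chain_id, 1L, "NAG", c("C1", "C2", "C3", "C4", "C5", "O5"),
            c("C", "C", "C", "C", "C", "O"), xyz)
}

# Random proper rotation matrix from the session RNG.
.random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Rigid transform: rotate about the centroid, then translate so the bounding
# box starts at `margin` on every axis (keeps fixtures inside the 100 A box).
.rigid_place <- function(atoms, rotation, margin = 2) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  ctr <- colMeans(xyz)
  xyz <- sweep(xyz, 2, ctr) %*% t(rotation)
  xyz <- sweep(xyz, 2, apply(xyz, 2, min) - margin)
  atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
  atoms
}

#' Build a pair of binding-site coordinate sets for similarity testing
#'
#' The second site is a rigid transform of the template with optional
#' per-atom isotropic Gaussian jitter. With `jitter = 0` the sorted distance
#' lists are identical, so PMax = PMin = 1; jitter much larger than the
#' match tolerance drives both scores toward 0.
#'
#' @param template Atom data.frame with `x`, `y`, `z` (e.g. an
#'   `epitope_site`'s `atoms`).
#' @param rotation 3x3 rotation matrix, or `NULL` for a random one drawn from
#'   the session RNG.
#' @param translation Length-3 translation vector.
#' @param jitter Per-atom Gaussian sd in Angstrom.
#' @return List with `site_a` (the template) and `site_b`.
#' @export
make_site_pair <- function(template, rotation = NULL,
                           translation = c(0, 0, 0), jitter = 0) {
  stopifnot(jitter >= 0)
  if (inherits(template, "epitope_site")) template <- template$atoms
  if (is.null(rotation)) rotation <- .random_rotation()
  xyz <- as.matrix(template[, c("x", "y", "z")]) %*% t(rotation)
  xyz <- sweep(xyz, 2, translation, "+")
  if (jitter > 0) xyz <- xyz + matrix(rnorm(length(xyz), sd = jitter),
                                      ncol = 3)
  site_b <- template
  site_b$x <- xyz[, 1]; site_b$y <- xyz[, 2]; site_b$z <- xyz[, 3]
  list(site_a = template, site_b = site_b)
}

# --- receptor domain layout ------------------------------------------------

# Framework/CDR segment lengths and the IMGT numbers written for them; CDR
# positions fall inside the standard IMGT CDR windows (27-38, 56-65, 105-117),
# frameworks outside.
.RECEPTOR_SEGMENTS <- list(
  fr1 = 10:25, cdr1 = 27:34, fr2 = 39:50, cdr2 = 56:62,
  fr3 = 66:90, cdr3 = 105:116, fr4 = 118:127
)

.receptor_sequence <- function(cdrs, framework) {
  paste0(framework$fr1, cdrs$cdr1, framework$fr2, cdrs$cdr2,
         framework$fr3, cdrs$cdr3, framework$fr4)
}

.receptor_imgt <- function() {
  unlist(.RECEPTOR_SEGMENTS, use.names = FALSE)
}

.rand_aa <- function(n) paste(sample(.AA20, n, replace = TRUE), collapse = "")

.mutate_aa <- function(seq, k) {
  letters <- strsplit(seq, "")[[1]]
  pos <- sample(length(letters), k)
  for (p in pos) {
    letters[p] <- sample(setdiff(.AA20, letters[p]), 1)
  }
  paste(letters, collapse = "")
}

# --- corpus design ---------------------------------------------------------

#' Describe a synthetic corpus
#'
#' A fixture specification: the seed and a per-complex design table with the
#' planted antigen family, receptor group, epitope conformer, core-peptide
#' cluster, MHC key and quality defect of every complex. The expected
#' benchmark counts are a closed-form function of this table.
#'
#' Profiles: `"minimal"` (7 complexes, no defects), `"standard"` (49
#' complexes: 20 peptidic Ab-Ag of which 5 carry planted quality defects, 12
#' TCR-pMHC, 10 MHC-ligand, 7 non-peptidic) and `"stress"` (the standard
#' design with every kept peptidic complex duplicated under a new id).
#'
#' @param profile `"minimal"`, `"standard"` or `"stress"`.
#' @param seed Integer seed; the corpus is a deterministic function of it.
#' @return A `fixture_spec` (list with `profile`, `seed`, `design`).
#' @export
fixture_spec <- function(profile = c("standard", "minimal", "stress"),
                         seed = 42) {
  profile <- match.arg(profile)
  design <- switch(profile,
    minimal = .design_minimal(),
    standard = .design_standard(),
    stress = .design_stress()
  )
  structure(list(profile = profile, seed = as.integer(seed), design = design),
            class = "fixture_spec")
}

.design_row <- function(id, type, peptidic = TRUE, defect = "none",
                        resolution = 2.0, r_free = 0.22,
                        antigen_key = NA, receptor_group = NA,
                        conformer = NA, core_key = NA, mhc_key = NA,
                        framework = 1L, nanobody = FALSE, dialect = "pdb") {
  data.frame(id = id, type = type, peptidic = peptidic, defect = defect,
             resolution = resolution, r_free = r_free,
             antigen_key = antigen_key, receptor_group = receptor_group,
             conformer = conformer, core_key = core_key, mhc_key = mhc_key,
             framework = framework, nanobody = nanobody, dialect = dialect,
             stringsAsFactors = FALSE)
}

.design_standard <- function() {
  ab_kept <- list(
    # receptor group, conformer, antigen key, framework
    list("R1", "A", "f1.0", 1L), list("R1", "A", "f1.0", 2L),
    list("R1", "B", "f1.1", 1L), list("R2", "A", "f1.2", 2L),
    list("R2", "A", "f2.0", 1L), list("R2", "A", "f2.0", 2L),
    list("R3", "A", "f2.1", 1L), list("R3", "B", "f3.0", 2L),
    list("R4", "A", "f3.0", 1L), list("R4", "A", "f4.0", 2L),
    list("R5", "A", "f4.1", 1L), list("R5", "B", "f5.0", 2L),
    list("R6", "A", "f5.0", 1L), list("R7", "B", "f6.0", 2L),
    list("R8", "A", "f6.0", 1L)
  )
  res <- c(2.0, 2.2, 2.5, 1.8, 2.8, 3.0, 2.1, 2.4, 2.6, 1.9, 2.3, 2.7,
           2.9, 2.05, 2.15)
  rf <- c(0.22, 0.24, 0.21, 0.19, 0.26, 0.25, 0.35, 0.23, 0.22, 0.20,
          0.27, 0.24, 0.28, 0.21, 0.22)
  rows <- lapply(seq_along(ab_kept), function(i) {
    k <- ab_kept[[i]]
    .design_row(sprintf("ab%02d", i), "AB_AG", resolution = res[i],
                r_free = rf[i], antigen_key = k[[3]], receptor_group = k[[1]],
                conformer = k[[2]], framework = k[[4]],
                nanobody = k[[1]] == "R8",
                dialect = if (i == 2) "mmcif" else "pdb")
  })
  rows <- c(rows, list(
    .design_row("ab16", "AB_AG", defect = "resolution", resolution = 3.2,
                antigen_key = "f1.0", receptor_group = "R1", conformer = "A"),
    .design_row("ab17", "AB_AG", defect = "resolution", resolution = 3.5,
                antigen_key = "f2.0", receptor_group = "R2", conformer = "A"),
    .design_row("ab18", "AB_AG", defect = "nmr", resolution = NA,
                antigen_key = "f3.0", receptor_group = "R3", conformer = "A"),
    .design_row("ab19", "AB_AG", defect = "missing_cdr", resolution = 2.0,
                antigen_key = "f4.0", receptor_group = "R4", conformer = "A"),
    .design_row("ab20", "AB_AG", defect = "short_antigen", resolution = 2.0,
                antigen_key = "fs.0", receptor_group = "R5", conformer = "A"),
    .design_row("abn1", "AB_AG", peptidic = FALSE, receptor_group = "R1",
                resolution = 2.1),
    .design_row("abn2", "AB_AG", peptidic = FALSE, receptor_group = "R1",
                resolution = 2.3, framework = 2L),
    .design_row("abn3", "AB_AG", peptidic = FALSE, receptor_group = "R2",
                defect = "resolution", resolution = 3.6)
  ))
  tc <- list(
    list("tc01", "c1.0", "T1", "gI_01", 1.9), list("tc02", "c1.0", "T1", "gI_02", 2.1),
    list("tc03", "c1.1", "T1", "gI_01", 2.3), list("tc04", "c2.0", "T2", "gI_01", 2.5),
    list("tc05", "c2.0", "T2", "gI_01", 2.7), list("tc06", "c2.1", "T3", "gI_02", 2.9),
    list("tc07", "c3.0", "T4", "II", 3.0), list("tc08", "c3.0", "T4", "II", 2.0),
    list("tc09", "c4.0", "T5", "gI_01", 2.2), list("tc10", "c4.0", "T5", "gI_01", 2.4)
  )
  rows <- c(rows, lapply(seq_along(tc), function(i) {
    k <- tc[[i]]
    .design_row(k[[1]], "TCR_PMHC", resolution = k[[5]], core_key = k[[2]],
                receptor_group = k[[3]], mhc_key = k[[4]],
                framework = if (i %% 2) 1L else 2L)
  }))
  rows <- c(rows, list(
    .design_row("tc11", "TCR_PMHC", defect = "resolution", resolution = 3.3,
                core_key = "c1.0", receptor_group = "T1", mhc_key = "gI_01"),
    .design_row("tc12", "TCR_PMHC", defect = "short_core", resolution = 2.0,
                core_key = "c1.0", receptor_group = "T1", mhc_key = "gI_01"),
    .design_row("tcn1", "TCR_PMHC", peptidic = FALSE, receptor_group = "T1",
                mhc_key = "gI_01", resolution = 2.0),
    .design_row("tcn2", "TCR_PMHC", peptidic = FALSE, receptor_group = "T1",
                mhc_key = "gI_01", resolution = 2.2, framework = 2L)
  ))
  mh <- list(
    list("mh01", "q1.0", "gI_01", 1.8), list("mh02", "q1.0", "gI_01", 2.0),
    list("mh03", "q1.1", "gI_03", 2.2), list("mh04", "q2.0", "gI_03", 2.4),
    list("mh05", "q2.0", "gI_03", 2.6), list("mh06", "q3.0", "NC1", 2.8),
    list("mh07", "q3.0", "NC1", 3.0), list("mh08", "q3.1", "NC1", 2.1)
  )
  rows <- c(rows, lapply(mh, function(k) {
    .design_row(k[[1]], "MHC_LIGAND", resolution = k[[4]], core_key = k[[2]],
                mhc_key = k[[3]])
  }))
  rows <- c(rows, list(
    .design_row("mh09", "MHC_LIGAND", defect = "resolution", resolution = 3.4,
                core_key = "q1.0", mhc_key = "gI_01"),
    .design_row("mh10", "MHC_LIGAND", defect = "short_core", resolution = 2.0,
                core_key = "q1.0", mhc_key = "gI_01"),
    .design_row("mhn1", "MHC_LIGAND", peptidic = FALSE, mhc_key = "gI_01",
                resolution = 2.0),
    .design_row("mhn2", "MHC_LIGAND", peptidic = FALSE, mhc_key = "gI_03",
                resolution = 2.2)
  ))
  do.call(rbind, rows)
}

.design_minimal <- function() {
  do.call(rbind, list(
    .design_row("ab01", "AB_AG", antigen_key = "f1.0", receptor_group = "R1",
                conformer = "A", resolution = 2.0),
    .design_row("ab02", "AB_AG", antigen_key = "f1.0", receptor_group = "R1",
                conformer = "A", resolution = 2.2, framework = 2L),
    .design_row("ab03", "AB_AG", antigen_key = "f2.0", receptor_group = "R2",
                conformer = "B", resolution = 2.4),
    .design_row("tc01", "TCR_PMHC", core_key = "c1.0", receptor_group = "T1",
                mhc_key = "gI_01", resolution = 2.0),
    .design_row("tc02", "TCR_PMHC", core_key = "c1.0", receptor_group = "T1",
                mhc_key = "gI_01", resolution = 2.2),
    .design_row("mh01", "MHC_LIGAND", core_key = "q1.0", mhc_key = "gI_01",
                resolution = 2.0),
    .design_row("abn1", "AB_AG", peptidic = FALSE, receptor_group = "R1",
                resolution = 2.0)
  ))
}

.design_stress <- function() {
  d <- .design_standard()
  dup <- d[d$defect == "none" & d$peptidic, , drop = FALSE]
  dup$id <- paste0(dup$id, "x")
  dup$dialect <- "pdb"
  rbind(d, dup)
}

# Epitope conformer templates: 0-based antigen residue indices whose heavy
# atoms form the binding site. The two templates differ in residue count and
# spread so their sorted distance lists share only the intra-residue
# distances, keeping PMax/PMin far below the clustering rule.
.CONFORMERS <- list(A = c(20L, 21L, 22L), B = c(20L, 26L, 32L, 38L))

# Peptide contact plans: 0-based peptide residue indices contacted by the
# groove (and TCR); the core-epitope is the contiguous span between the first
# and last. "short" spans only 7 residues and fails the 8-residue filter.
.PEPTIDE_CONTACTS <- list(full = 1:9, short = 2:8)

# --- sequence pools --------------------------------------------------------

.make_pools <- function(design) {
  pools <- list()
  # antigen families: base 60-mers, variants mutated at 7/60 positions
  # (~88% identity, above the 70% threshold); the short-antigen family is a
  # 45-mer (below the 50-residue filter)
  keys <- unique(stats::na.omit(design$antigen_key))
  fams <- unique(sub("\\..*", "", keys))
  base <- list()
  for (f in fams) base[[f]] <- .rand_aa(if (f == "fs") 45 else 60)
  pools$antigens <- list()
  for (k in keys) {
    f <- sub("\\..*", "", k)
    v <- as.integer(sub(".*\\.", "", k))
    pools$antigens[[k]] <- if (v == 0) base[[f]] else .mutate_aa(base[[f]], 7)
  }
  # core peptides: 11-mers; variants mutated at one core position (8/9 = 88.9%
  # core identity, above the 85% threshold)
  keys <- unique(stats::na.omit(design$core_key))
  cls <- unique(sub("\\..*", "", keys))
  pbase <- list()
  for (cl in cls) pbase[[cl]] <- .rand_aa(11)
  pools$peptides <- list()
  for (k in keys) {
    cl <- sub("\\..*", "", k)
    v <- as.integer(sub(".*\\.", "", k))
    s <- pbase[[cl]]
    if (v > 0) {
      letters <- strsplit(s, "")[[1]]
      letters[6] <- sample(setdiff(.AA20, letters[6]), 1)  # inside the core
      s <- paste(letters, collapse = "")
    }
    pools$peptides[[k]] <- s
  }
  # receptor groups: independent random CDR sets per group; heavy/light for
  # R*, alpha/beta for T*
  groups <- unique(stats::na.omit(design$receptor_group))
  pools$receptors <- list()
  for (g in groups) {
    mk <- function() list(cdr1 = .rand_aa(8), cdr2 = .rand_aa(7),
                          cdr3 = .rand_aa(12))
    pools$receptors[[g]] <- if (startsWith(g, "R")) {
      list(heavy = mk(), light = mk())
    } else {
      list(alpha = mk(), beta = mk())
    }
  }
  # two shared framework variants: same CDRs + different framework must still
  # group together
  pools$frameworks <- list(
    list(fr1 = .rand_aa(16), fr2 = .rand_aa(12), fr3 = .rand_aa(25),
         fr4 = .rand_aa(10)),
    list(fr1 = .rand_aa(16), fr2 = .rand_aa(12), fr3 = .rand_aa(25),
         fr4 = .rand_aa(10))
  )
  # G-domain references and MHC chain sequences (groove embedded between
  # 20-residue flanks; NC1 is unmappable, clustered on full sequence)
  pools$gdomain <- data.frame(
    ref_id = c("gI_01", "gI_02", "gI_03", "gII_A1", "gII_B1"),
    class = c("I", "I", "I", "II", "II"),
    domain = c("a", "a", "a", "a", "b"),
    seq = c(.rand_aa(60), .rand_aa(60), .rand_aa(60), .rand_aa(50),
            .rand_aa(50)),
    stringsAsFactors = FALSE
  )
  flank <- function() .rand_aa(20)
  groove <- function(id) pools$gdomain$seq[pools$gdomain$ref_id == id]
  pools$mhc_chains <- list()
  for (id in c("gI_01", "gI_02", "gI_03")) {
    pools$mhc_chains[[id]] <- list(M = paste0(flank(), groove(id), flank()))
  }
  pools$mhc_chains[["II"]] <- list(
    M = paste0(flank(), groove("gII_A1"), flank()),
    N = paste0(flank(), groove("gII_B1"), flank())
  )
  # 40 residues: shorter than 90% of any reference span, so the G-domain
  # search can never accept a hit, whatever the seed draws
  pools$mhc_chains[["NC1"]] <- list(M = .rand_aa(40))
  pools
}

# --- per-complex assembly --------------------------------------------------

# z-plane offsets for the chains of one complex
.CHAIN_Z <- c(antigen = 0, receptor1 = 12, receptor2 = 24, mhc_a = 36,
              mhc_b = 48)

.build_complex <- function(row, pools) {
  chains <- list()
  numbering <- list()
  antigen_ca <- NULL

  if (row$peptidic && row$type == "AB_AG") {
    ag_seq <- pools$antigens[[row$antigen_key]]
    antigen_ca <- .serpentine(nchar(ag_seq), 15, c(0, 0, .CHAIN_Z["antigen"]))
    chains$G <- .make_chain_atoms("G", ag_seq, c(0, 0, .CHAIN_Z["antigen"]))
  } else if (row$peptidic) {
    pep_seq <- pools$peptides[[row$core_key]]
    antigen_ca <- .serpentine(nchar(pep_seq), 15, c(0, 0, .CHAIN_Z["antigen"]))
    chains$P <- .make_chain_atoms("P", pep_seq, c(0, 0, .CHAIN_Z["antigen"]))
  } else {
    chains$X <- .make_ligand_atoms("X", c(5, 5, .CHAIN_Z["antigen"]))
    antigen_ca <- matrix(c(5 + 1.5, 5, 0), 1)  # ligand atom C1
  }

  fw <- pools$frameworks[[row$framework]]
  add_receptor <- function(chain_id, role, cdrs, zkey, targets = NULL,
                           drop_cdr3 = FALSE) {
    seq <- .receptor_sequence(cdrs, fw)
    n <- nchar(seq)
    ct <- NULL
    if (!is.null(targets)) {
      # reposition trailing framework residues over the targets
      idx <- (n - length(targets)):(n - 1L)
      ct <- setNames(targets, as.character(idx))
    }
    atoms <- .make_chain_atoms(chain_id, seq, c(0, 0, .CHAIN_Z[[zkey]]),
                               row_len = 18, contact_targets = ct)
    imgt <- .receptor_imgt()
    seq_index <- NULL
    if (drop_cdr3) {
      drop_at <- which(imgt == 110)  # a CDR3 residue, unresolved in the file
      atoms <- atoms[atoms$resno != drop_at, , drop = FALSE]
      seq_index <- rep(NA_integer_, n)
      seq_index[-drop_at] <- seq_len(n - 1L) - 1L
    }
    chains[[chain_id]] <<- atoms
    num <- list(role = role, imgt = imgt, ins = rep("", n),
                letter = strsplit(seq, "")[[1]])
    if (!is.null(seq_index)) num$seq_index <- seq_index
    numbering[[chain_id]] <<- num
  }
  target_list <- function(indices) {
    lapply(indices + 1L, function(i) antigen_ca[i, ])
  }

  roles <- character()
  if (row$type == "AB_AG") {
    cd <- pools$receptors[[row$receptor_group]]
    ep <- if (row$peptidic) .CONFORMERS[[row$conformer]] else 0L
    add_receptor("H", "heavy", cd$heavy, "receptor1", target_list(ep),
                 drop_cdr3 = identical(row$defect, "missing_cdr"))
    roles <- c(H = "heavy")
    if (!row$nanobody) {
      add_receptor("L", "light", cd$light, "receptor2")
      roles <- c(roles, L = "light")
    }
    antigen_chains <- if (row$peptidic) "G" else "X"
  } else {
    plan <- if (identical(row$defect, "short_core")) "short" else "full"
    pep_idx <- if (row$peptidic) .PEPTIDE_CONTACTS[[plan]] else 0L
    mhc <- pools$mhc_chains[[row$mhc_key]]
    if (row$type == "TCR_PMHC") {
      cd <- pools$receptors[[row$receptor_group]]
      tcr_idx <- if (row$peptidic) intersect(4:5, pep_idx) else 0L
      add_receptor("A", "alpha", cd$alpha, "receptor1",
                   target_list(tcr_idx))
      add_receptor("B", "beta", cd$beta, "receptor2")
      roles <- c(A = "alpha", B = "beta")
    }
    # groove contacts: MHC chain(s) cover the planted peptide span
    two_chain <- !is.null(mhc$N)
    split_at <- if (two_chain) ceiling(length(pep_idx) / 2) else length(pep_idx)
    idx_a <- pep_idx[seq_len(split_at)]
    add_mhc <- function(chain_id, seq, zkey, idx) {
      n <- nchar(seq)
      targets <- target_list(idx)
      ct <- setNames(targets, as.character((n - length(targets)):(n - 1L)))
      chains[[chain_id]] <<- .make_chain_atoms(chain_id, seq,
                                               c(0, 0, .CHAIN_Z[[zkey]]),
                                               row_len = 18,
                                               contact_targets = ct)
    }
    add_mhc("M", mhc$M, "mhc_a", idx_a)
    roles <- c(roles, M = "mhc_a")
    if (two_chain) {
      add_mhc("N", mhc$N, "mhc_b", pep_idx[-seq_len(split_at)])
      roles <- c(roles, N = "mhc_b")
    }
    antigen_chains <- if (row$peptidic) "P" else "X"
  }

  atoms <- do.call(rbind, unname(chains))
  atoms <- .rigid_place(atoms, .random_rotation())
  model <- .build_structure(atoms, row$id,
                            resolution = row$resolution,
                            r_free = row$r_free,
                            method = if (identical(row$defect, "nmr")) {
                              "SOLUTION NMR"
                            } else {
                              "X-RAY DIFFRACTION"
                            })
  annotation <- list(
    structure_id = row$id,
    complex_type = row$type,
    chain_roles = as.list(roles),
    antigen_chains = I(antigen_chains),
    mhc_class = if (is.na(row$mhc_key)) NULL
                else if (row$mhc_key == "II") "II"
                else if (row$mhc_key == "NC1") "non_classical" else "I",
    organism = "human",
    numbering = if (length(numbering)) numbering else NULL
  )
  list(model = model, annotation = annotation)
}

# --- expected counts (closed form from the design) -------------------------

.expected_counts <- function(design) {
  kept <- design$defect == "none"
  attr_of <- function(d) {
    list(resolution = sum(d$defect %in% c("resolution", "nmr")),
         r_free = 0L,
         missing_cdr = sum(d$defect == "missing_cdr"),
         length = sum(d$defect %in% c("short_antigen", "short_core")))
  }
  fam <- sub("\\..*", "", design$antigen_key)
  core_cl <- sub("\\..*", "", design$core_key)

  ab <- design$type == "AB_AG"
  abp <- ab & design$peptidic
  abk <- abp & kept
  ab_counts <- c(
    list(total = sum(ab), peptidic = sum(abp), post_filter = sum(abk),
         distinct_pairs = length(unique(paste(design$receptor_group,
                                              design$conformer)[abk])),
         attrition = attr_of(design[abp, ])),
    list(antigen_clusters = length(unique(fam[abk])),
         receptor_clusters = length(unique(design$receptor_group[abk])))
  )

  tc <- design$type == "TCR_PMHC"
  tcp <- tc & design$peptidic
  tck <- tcp & kept
  full <- unique(paste(core_cl, design$receptor_group,
                       design$mhc_key)[tck])
  tcr_ep <- unique(paste(core_cl, design$receptor_group)[tck])
  tc_counts <- list(
    total = sum(tc), peptidic = sum(tcp), post_filter = sum(tck),
    distinct_pairs = length(tcr_ep), attrition = attr_of(design[tcp, ]),
    core_clusters = length(unique(core_cl[tck])),
    receptor_clusters = length(unique(design$receptor_group[tck])),
    mhc_clusters = length(unique(design$mhc_key[tck])),
    full_clusters = length(full), tcr_epitope_groups = length(tcr_ep)
  )

  mh <- design$type == "MHC_LIGAND"
  mhp <- mh & design$peptidic
  mhk <- mhp & kept
  mh_counts <- list(
    total = sum(mh), peptidic = sum(mhp), post_filter = sum(mhk),
    distinct_pairs = length(unique(paste(core_cl, design$mhc_key)[mhk])),
    attrition = attr_of(design[mhp, ]),
    core_clusters = length(unique(core_cl[mhk])),
    mhc_clusters = length(unique(design$mhc_key[mhk]))
  )

  np <- !design$peptidic
  npk <- np & kept
  np_counts <- list(
    total = sum(np), post_filter = sum(npk),
    attrition = attr_of(design[np, ]),
    ab_receptor_groups = length(unique(
      design$receptor_group[npk & design$type == "AB_AG"])),
    tcr_receptor_groups = length(unique(
      design$receptor_group[npk & design$type == "TCR_PMHC"])),
    tcr_mhc_groups = length(unique(
      design$mhc_key[npk & design$type == "TCR_PMHC"])),
    mhc_ligand_mhc_groups = length(unique(
      design$mhc_key[npk & design$type == "MHC_LIGAND"]))
  )

  list(ab_ag = ab_counts, tcr_pmhc = tc_counts, mhc_ligand = mh_counts,
       non_peptidic = np_counts)
}

# --- generation-time plant verification (similarity kernels, not pipeline) --

.verify_plant <- function(design, pools) {
  # antigen identities: within-family variants join at 70%, distinct families
  # stay apart
  keys <- unique(stats::na.omit(design$antigen_key))
  fams <- split(keys, sub("\\..*", "", keys))
  for (f in names(fams)) {
    base <- pools$antigens[[paste0(f, ".0")]]
    for (k in fams[[f]]) {
      stopifnot(pairwise_identity(base, pools$antigens[[k]]) >= 70)
    }
  }
  bases <- vapply(names(fams), function(f) pools$antigens[[paste0(f, ".0")]], "")
  if (length(bases) > 1) {
    cmb <- utils::combn(length(bases), 2)
    for (j in seq_len(ncol(cmb))) {
      stopifnot(pairwise_identity(bases[cmb[1, j]], bases[cmb[2, j]]) < 70)
    }
  }
  # core identities at 85%
  keys <- unique(stats::na.omit(design$core_key))
  core_of <- function(k) substr(pools$peptides[[k]], 2, 10)
  cls <- split(keys, sub("\\..*", "", keys))
  for (cl in names(cls)) {
    base <- core_of(paste0(cl, ".0"))
    for (k in cls[[cl]]) stopifnot(pairwise_identity(base, core_of(k)) >= 85)
  }
  cbase <- vapply(names(cls), function(cl) core_of(paste0(cl, ".0")), "")
  if (length(cbase) > 1) {
    cmb <- utils::combn(length(cbase), 2)
    for (j in seq_len(ncol(cmb))) {
      stopifnot(pairwise_identity(cbase[cmb[1, j]], cbase[cmb[2, j]]) < 85)
    }
  }
  # conformer templates: identical templates score (1,1); the two templates
  # are not similar under the clustering rule
  site_of <- function(conf) {
    ca <- .serpentine(60, 15)
    do.call(rbind, lapply(.CONFORMERS[[conf]] + 1L, function(i) {
      xyz <- sweep(.residue_atom_offsets(), 2, ca[i, ], "+")
      data.frame(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
    }))
  }
  sA <- site_of("A"); sB <- site_of("B")
  pr <- make_site_pair(sA, rotation = .random_rotation(),
                       translation = c(3, 4, 5))
  sc <- pocketmatch_score(pr$site_a, pr$site_b)
  stopifnot(sc$pmax == 1, sc$pmin == 1)
  scAB <- pocketmatch_score(sA, sB)
  stopifnot(!sites_similar(scAB))
  # G-domain references recover exactly from the embedded chains
  for (key in c("gI_01", "gI_02", "gI_03")) {
    hit <- map_g_domain(pools$mhc_chains[[key]]$M, pools$gdomain)
    stopifnot(!is.null(hit), hit$ref_id == key,
              hit$mapped_sequence ==
                pools$gdomain$seq[pools$gdomain$ref_id == key])
  }
  stopifnot(is.null(map_g_domain(pools$mhc_chains$NC1$M, pools$gdomain)))
  list(conformer_scores = list(
    identical = c(pmax = 1, pmin = 1),
    cross = c(pmax = scAB$pmax, pmin = scAB$pmin)
  ))
}

# --- corpus writer ---------------------------------------------------------

#' Generate a synthetic corpus on disk
#'
#' Writes coordinate files (PDB, plus one mmCIF in the standard design),
#' per-complex annotation JSON with IMGT numbering, a synthetic G-domain
#' reference FASTA, a manifest, and an expected-counts JSON computed in
#' closed form from the planted design (never by running the pipeline).
#' Identical `spec` (profile + seed) produces byte-identical files.
#'
#' @param spec A [fixture_spec()].
#' @param out_dir Output directory (created if needed).
#' @return List with `manifest` (path), `expected_counts` (list) and
#'   `out_dir`, invisibly.
#' @export
make_corpus <- function(spec, out_dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(file.path(out_dir, "structures"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "annotations"), showWarnings = FALSE)
  design <- spec$design
  known <- c("none", "resolution", "nmr", "missing_cdr", "short_antigen",
             "short_core")
  if (!all(design$defect %in% known)) {
    stop("unknown planted defect: ",
         paste(setdiff(design$defect, known), collapse = ", "))
  }

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")

  pools <- .make_pools(design)
  verification <- .verify_plant(design, pools)

  entries <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    row <- design[i, ]
    built <- .build_complex(row, pools)
    ext <- if (row$dialect == "mmcif") "cif" else "pdb"
    coord_rel <- file.path("structures", paste0(row$id, ".", ext))
    ann_rel <- file.path("annotations", paste0(row$id, ".json"))
    write_structure(built$model, file.path(out_dir, coord_rel), row$dialect)
    jsonlite::write_json(built$annotation, file.path(out_dir, ann_rel),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null", na = "null")
    entries[[i]] <- list(structure_id = row$id, coordinates = coord_rel,
                         annotation = ann_rel, dialect = row$dialect)
  }

  refs_path <- file.path(out_dir, "gdomain_refs.fasta")
  hdr <- sprintf(">%s class=%s domain=%s", pools$gdomain$ref_id,
                 pools$gdomain$class, pools$gdomain$domain)
  writeLines(as.vector(rbind(hdr, pools$gdomain$seq)), refs_path)

  expected <- .expected_counts(design)
  expected$verification <- verification
  jsonlite::write_json(expected, file.path(out_dir, "expected_counts.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  manifest <- list(profile = spec$profile, seed = spec$seed,
                   gdomain_refs = "gdomain_refs.fasta",
                   expected_counts = "expected_counts.json",
                   complexes = entries)
  man_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(list(manifest = man_path, expected_counts = expected,
                 out_dir = out_dir))
}
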