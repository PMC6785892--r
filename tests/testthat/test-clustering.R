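test_that("single linkage equals brute-force connected components", {
  # no edges -> singletons; chained edges -> transitive closure
  p <- single_linkage_clusters(c("a", "b", "c"))
  expect_equal(p$n_clusters, 3L)
  p <- single_linkage_clusters(c("a", "b", "c"),
                               rbind(c("a", "b"), c("b", "c")))
  expect_equal(p$n_clusters, 1L)
  expect_equal(unname(p$cluster_of), c(0L, 0L, 0L))

  set.seed(7)
  for (k in 1:25) {
    n <- sample(2:15, 1)
    items <- sprintf("it%02d", 1:n)
    adj <- matrix(runif(n * n) < 0.15, n, n)
    adj <- adj | t(adj); diag(adj) <- FALSE
    idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
    pairs <- if (nrow(idx)) cbind(items[idx[, 1]], items[idx[, 2]])
    part <- single_linkage_clusters(items, pairs)
    want <- bf_components(adj)
    # same partition up to relabelling
    expect_equal(length(unique(want)), part$n_clusters)
    got_key <- split(items, part$cluster_of)
    want_key <- split(items, want)
    expect_setequal(unname(vapply(got_key, paste, "", collapse = ",")),
                    unname(vapply(want_key, paste, "", collapse = ",")))
    # partition validity: exhaustive, disjoint, contiguous indices
    expect_setequal(names(part$cluster_of), items)
    expect_equal(sort(unique(unname(part$cluster_of))),
                 0:(part$n_clusters - 1L))
  }
})

test_that("antigen clustering joins planted families at the 70% threshold", {
  set.seed(41)
  base <- epibench:::.rand_aa(60)
  fam <- c(s1 = base, s2 = base, s3 = epibench:::.mutate_aa(base, 7),
           s4 = epibench:::.rand_aa(60))
  expect_gte(pairwise_identity(fam["s1"], fam["s3"]), 70)
  expect_lt(pairwise_identity(fam["s1"], fam["s4"]), 70)

  cl <- cluster_antigens(fam, threshold = 70)
  expect_equal(unname(cl$labels["s1"]), unname(cl$labels["s3"]))
  expect_false(cl$labels[["s1"]] == cl$labels[["s4"]])
  expect_equal(cl$partition$n_clusters, 2L)
  expect_match(cl$labels, "^Ag[0-9]+$", all = TRUE)

  # at threshold 100 any mismatch separates
  cl100 <- cluster_antigens(fam, threshold = 100)
  expect_equal(cl100$partition$n_clusters, 3L)  # s1 == s2 stay together
})

test_that("cluster counts are monotone as the identity threshold rises", {
  set.seed(43)
  seqs <- character(0)
  for (f in 1:3) {
    b <- epibench:::.rand_aa(50)
    seqs <- c(seqs, b, epibench:::.mutate_aa(b, 5),
              epibench:::.mutate_aa(b, 12))
  }
  names(seqs) <- sprintf("s%02d", seq_along(seqs))
  counts <- vapply(c(50, 60, 70, 80, 90, 100), function(th) {
    cluster_antigens(seqs, th)$partition$n_clusters
  }, 0L)
  expect_true(all(diff(counts) >= 0))
})

test_that("receptors group on CDR identity, not framework", {
  recs <- list(
    mk_receptor_record("r1", cdrs1, cdrs2, fw = "AAAA"),
    mk_receptor_record("r2", cdrs1, cdrs2, fw = "WWWW"),  # same CDRs
    mk_receptor_record("r3", cdrs1, cdrs3, fw = "AAAA"),  # light differs
    mk_receptor_record("r4", cdrs2, cdrs2, fw = "AAAA"),  # heavy differs
    mk_receptor_record("r5", cdrs1)                       # nanobody
  )
  rc <- cluster_receptors(recs)
  expect_equal(unname(rc$labels["r1"]), "H1_L1")
  expect_equal(unname(rc$labels["r2"]), "H1_L1")
  expect_equal(unname(rc$labels["r3"]), "H1_L2")
  expect_equal(unname(rc$labels["r4"]), "H2_L1")
  expect_equal(unname(rc$labels["r5"]), "H1")
  expect_equal(rc$partition$n_clusters, 4L)
})

test_that("core-epitope clustering at 85% splits 2-mismatch 9-mers", {
  a <- "ALYGFVPKT"
  b <- "ALYGFVPKS"   # 1 mismatch, 88.9%
  c <- "ALYGAVPWT"   # 2 mismatches vs a, 77.8%
  expect_equal(pairwise_identity(a, b), 100 * 8 / 9)
  cl <- cluster_core_epitopes(c(x = a, y = b, z = c), threshold = 85)
  expect_equal(unname(cl$labels["x"]), unname(cl$labels["y"]))
  expect_false(cl$labels[["x"]] == cl$labels[["z"]])
})

test_that("epitope conformational clustering separates unrelated sites", {
  set.seed(55)
  ag_ca <- serp(60)
  site_of <- function(idx0) {
    atoms <- do.call(rbind, lapply(idx0 + 1L, function(i) {
      xyz <- sweep(epibench:::.residue_atom_offsets(), 2, ag_ca[i, ], "+")
      data.frame(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
    }))
    structure(list(residues = NULL, atoms = atoms, structure_id = "s",
                   empty = FALSE), class = "epitope_site")
  }
  sA <- site_of(c(20L, 21L, 22L))
  sA2 <- site_of(c(20L, 21L, 22L))
  pr <- make_site_pair(sA$atoms, translation = c(5, 5, 5))
  sA2$atoms <- pr$site_b
  sB <- site_of(c(20L, 26L, 32L, 38L))
  expect_false(sites_similar(pocketmatch_score(sA, sB)))

  cl <- cluster_epitope_conformations(list(p = sA, q = sA2, r = sB))
  expect_equal(unname(cl$labels["p"]), unname(cl$labels["q"]))
  expect_false(cl$labels[["p"]] == cl$labels[["r"]])

  # unscorable sites become singletons, not errors
  empty_site <- structure(list(residues = NULL,
                               atoms = sA$atoms[0, ], structure_id = "e",
                               empty = TRUE), class = "epitope_site")
  cl2 <- cluster_epitope_conformations(list(p = sA, e = empty_site))
  expect_equal(cl2$partition$n_clusters, 2L)
})

test_that("MHC clustering keys on G-domains with non-classical fallback", {
  set.seed(61)
  groove1 <- epibench:::.rand_aa(60)
  groove2 <- epibench:::.rand_aa(60)
  a1 <- epibench:::.rand_aa(50)
  b1 <- epibench:::.rand_aa(50)
  b2 <- epibench:::.rand_aa(50)
  refs <- data.frame(
    ref_id = c("g1", "g2", "iiA", "iiB1", "iiB2"),
    class = c("I", "I", "II", "II", "II"),
    domain = c("a", "a", "a", "b", "b"),
    seq = c(groove1, groove2, a1, b1, b2), stringsAsFactors = FALSE
  )
  mk_mhc_rec <- function(id, seq_m, seq_n = NULL) {
    chains <- rbind(mk_chain("P", "GILVFMSTA", c(0, 0, 0)),
                    mk_chain("M", seq_m, c(0, 0, 24), row_len = 18))
    roles <- c(M = "mhc_a")
    if (!is.null(seq_n)) {
      chains <- rbind(chains, mk_chain("N", seq_n, c(0, 0, 44), row_len = 18))
      roles <- c(roles, N = "mhc_b")
    }
    complex_record(mk_model(chains, id), "MHC_LIGAND", roles, "P")
  }
  recs <- list(
    # identical groove, different flanking domains -> same a-cluster
    m1 = mk_mhc_rec("m1", paste0(epibench:::.rand_aa(20), groove1,
                                 epibench:::.rand_aa(20))),
    m2 = mk_mhc_rec("m2", paste0(epibench:::.rand_aa(25), groove1,
                                 epibench:::.rand_aa(10))),
    m3 = mk_mhc_rec("m3", paste0(epibench:::.rand_aa(20), groove2,
                                 epibench:::.rand_aa(20))),
    # class II sharing alpha1, differing beta1 -> same a, different b
    m4 = mk_mhc_rec("m4", paste0(epibench:::.rand_aa(15), a1,
                                 epibench:::.rand_aa(15)),
                    paste0(epibench:::.rand_aa(15), b1,
                           epibench:::.rand_aa(15))),
    m5 = mk_mhc_rec("m5", paste0(epibench:::.rand_aa(15), a1,
                                 epibench:::.rand_aa(15)),
                    paste0(epibench:::.rand_aa(15), b2,
                           epibench:::.rand_aa(15))),
    # unmappable -> non-classical on full sequence
    m6 = mk_mhc_rec("m6", epibench:::.rand_aa(70))
  )
  mc <- cluster_mhc(unname(recs), refs)
  expect_equal(unname(mc$labels["m1"]), "a1")
  expect_equal(unname(mc$labels["m2"]), "a1")
  expect_equal(unname(mc$labels["m3"]), "a2")
  expect_match(unname(mc$labels["m4"]), "^a[0-9]+_b1$")
  expect_match(unname(mc$labels["m5"]), "^a[0-9]+_b2$")
  # class II complexes share the alpha1 index, differ in beta1
  expect_equal(sub("_b[0-9]+$", "", mc$labels[["m4"]]),
               sub("_b[0-9]+$", "", mc$labels[["m5"]]))
  expect_equal(unname(mc$labels["m6"]), "n1")
  expect_equal(mc$partition$n_clusters, 5L)
})

test_that("distinct pairs count unique label tuples with one representative", {
  rows <- data.frame(
    structure_id = c("s1", "s2", "s3", "s4", "s5"),
    resolution = c(2.5, 1.9, 2.0, 2.0, NA),
    receptor_cluster = c("H1_L1", "H1_L1", "H2_L1", "H3_L2", "H3_L2"),
    epitope_cluster = c("E1", "E1", "E1", "E1", "E1"),
    stringsAsFactors = FALSE
  )
  out <- distinct_pairs(rows, c("receptor_cluster", "epitope_cluster"))
  expect_equal(attr(out, "n_pairs"), 3L)
  expect_equal(sum(out$is_representative), 3L)
  # best resolution wins within a pair cluster
  expect_true(out$is_representative[out$structure_id == "s2"])
  # missing resolution sorts last
  expect_true(out$is_representative[out$structure_id == "s4"])

  # same TCR and core, different MHC: two full clusters, one receptor-epitope
  # group (the coarser grouping the benchmark table reports)
  rows <- data.frame(
    structure_id = c("t1", "t2"), resolution = c(2, 2),
    core_cluster = "E1", receptor_cluster = "A1_B1",
    mhc_cluster = c("a1", "a2"), stringsAsFactors = FALSE
  )
  full <- distinct_pairs(rows, c("core_cluster", "receptor_cluster",
                                 "mhc_cluster"))
  expect_equal(attr(full, "n_pairs"), 2L)
  expect_equal(length(unique(paste(rows$core_cluster,
                                   rows$receptor_cluster))), 1L)

  # all identical -> one pair, one representative
  rows <- data.frame(structure_id = c("x1", "x2"), resolution = c(2, 2),
                     receptor_cluster = "H1", epitope_cluster = "E1",
                     stringsAsFactors = FALSE)
  out <- distinct_pairs(rows, c("receptor_cluster", "epitope_cluster"))
  expect_equal(attr(out, "n_pairs"), 1L)
  expect_equal(sum(out$is_representative), 1L)
  expect_equal(out$structure_id[out$is_representative], "x1")  # lexicographic
})

test_that("cluster labels are stable under input reordering", {
  recs <- list(
    mk_receptor_record("r1", cdrs1, cdrs2),
    mk_receptor_record("r2", cdrs2, cdrs2),
    mk_receptor_record("r3", cdrs1, cdrs2)
  )
  fwd <- cluster_receptors(recs)
  rev <- cluster_receptors(recs[c(3, 1, 2)])
  expect_identical(fwd$labels[sort(names(fwd$labels))],
                   rev$labels[sort(names(rev$labels))])
})
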