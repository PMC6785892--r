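test_that("site distance lists are sorted all-pairs distances", {
  collinear <- data.frame(x = c(0, 3, 5), y = 0, z = 0)
  expect_equal(as.numeric(site_distances(collinear)), c(2, 3, 5))
  two <- data.frame(x = c(0, 1.7), y = 0, z = 0)
  expect_equal(as.numeric(site_distances(two)), 1.7)
  expect_error(site_distances(two[1, ]), "fewer than 2")

  set.seed(3)
  s <- random_site(10)
  d <- site_distances(s)
  expect_length(d, 45)
  # naive double-loop oracle
  want <- c()
  for (i in 1:9) for (j in (i + 1):10) {
    want <- c(want, sqrt(sum((s[i, ] - s[j, ])^2)))
  }
  expect_equal(as.numeric(d), sort(want))
})

test_that("greedy matching on sorted lists equals maximum matching", {
  expect_equal(match_distances(c(3, 4, 5), c(3, 4, 5), 0), 3L)
  expect_equal(match_distances(c(3, 4, 5), c(3.2), 0.5), 1L)
  expect_equal(match_distances(1, 9, 0.5), 0L)

  set.seed(17)
  for (k in 1:200) {
    a <- sort(round(runif(sample(0:8, 1), 0, 6), 2))
    b <- sort(round(runif(sample(0:8, 1), 0, 6), 2))
    tol <- sample(c(0, 0.1, 0.3, 0.5, 1), 1)
    expect_equal(match_distances(a, b, tol), bf_max_matching(a, b, tol),
                 info = sprintf("a=%s b=%s tol=%s", toString(a), toString(b),
                                tol))
  }
})

test_that("PMax/PMin follow the ratio definitions and their invariants", {
  set.seed(5)
  s <- random_site(8)
  sc <- pocketmatch_score(s, s)
  expect_identical(sc$pmax, 1)
  expect_identical(sc$pmin, 1)

  # 3-atom site (3 pairs) vs 2-atom site (1 pair) with exactly one matched
  a <- data.frame(x = c(0, 2, 9), y = 0, z = 0)   # pairs: 2, 7, 9
  b <- data.frame(x = c(0, 2), y = 0, z = 0)      # pair: 2
  sc <- pocketmatch_score(a, b, tol = 0.5)
  expect_equal(sc$matched, 1L)
  expect_equal(sc$pmax, 1 / 3)
  expect_equal(sc$pmin, 1)

  # symmetry and pmin >= pmax on random pairs
  for (k in 1:20) {
    sa <- random_site(sample(4:12, 1))
    sb <- random_site(sample(4:12, 1))
    ab <- pocketmatch_score(sa, sb)
    ba <- pocketmatch_score(sb, sa)
    expect_equal(ab$pmax, ba$pmax)
    expect_equal(ab$pmin, ba$pmin)
    expect_gte(ab$pmin, ab$pmax)
    expect_true(ab$pmax >= 0 && ab$pmin <= 1)
  }
})

test_that("scores are invariant under rigid-body transforms", {
  set.seed(9)
  s <- random_site(12)
  pr <- make_site_pair(s, translation = c(10, -4, 2))
  sc <- pocketmatch_score(pr$site_a, pr$site_b)
  expect_identical(sc$pmax, 1)
  expect_identical(sc$pmin, 1)
})

test_that("the epitope similarity rule reproduces its truth table", {
  truth <- list(
    list(pmax = 1.0, pmin = 1.0, want = TRUE),
    list(pmax = 0.2, pmin = 1.0, want = TRUE),
    list(pmax = 0.6, pmin = 0.9, want = TRUE),
    list(pmax = 0.59, pmin = 0.95, want = FALSE),
    list(pmax = 0.7, pmin = 0.89, want = FALSE)
  )
  for (tc in truth) {
    expect_identical(sites_similar(tc), tc$want,
                     info = sprintf("pmax=%s pmin=%s", tc$pmax, tc$pmin))
  }
})

test_that("pairwise identity uses the shorter-sequence denominator", {
  expect_equal(pairwise_identity("PEPTIDE", "PEPTIDE"), 100)
  expect_equal(pairwise_identity("AAAA", "AAAT"), 75)
  # a perfect fragment scores 100 against the full antigen
  expect_equal(pairwise_identity("PEPTIDE", "PEPTI"), 100)
  expect_equal(pairwise_identity("PEPTI", "PEPTIDE"), 100)
  expect_equal(pairwise_identity("MKTAYIAKQR", "MKTAYIAKQR"), 100)
  expect_error(pairwise_identity("", "AAA"), "empty")
  # symmetric on arbitrary pairs
  set.seed(21)
  for (k in 1:5) {
    a <- epibench:::.rand_aa(sample(10:40, 1))
    b <- epibench:::.rand_aa(sample(10:40, 1))
    expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))
  }
})

test_that("G-domain mapping recovers planted references exactly", {
  set.seed(33)
  refs <- data.frame(
    ref_id = c("gI_x", "gI_y", "gII_a", "gII_b"),
    class = c("I", "I", "II", "II"),
    domain = c("a", "a", "a", "b"),
    seq = c(epibench:::.rand_aa(60), epibench:::.rand_aa(60),
            epibench:::.rand_aa(50), epibench:::.rand_aa(50)),
    stringsAsFactors = FALSE
  )
  flank_l <- epibench:::.rand_aa(50)
  flank_r <- epibench:::.rand_aa(50)
  query <- paste0(flank_l, refs$seq[1], flank_r)
  hit <- map_g_domain(query, refs)
  expect_equal(hit$ref_id, "gI_x")
  expect_equal(hit$domain_tag, "a")
  expect_equal(hit$mhc_class, "I")
  expect_equal(hit$mapped_sequence, refs$seq[1])
  expect_gte(hit$scov, 85)
  expect_gte(hit$qcov, 90)

  # unrelated query -> no hit (caller labels non-classical)
  expect_null(map_g_domain(epibench:::.rand_aa(80), refs))

  # two plausible references: the higher-scoring (exact) one wins
  near <- epibench:::.mutate_aa(refs$seq[2], 6)
  refs2 <- rbind(refs, data.frame(ref_id = "gI_near", class = "I",
                                  domain = "a", seq = near))
  hit2 <- map_g_domain(paste0(flank_l, refs$seq[2], flank_r), refs2)
  expect_equal(hit2$ref_id, "gI_y")

  expect_error(map_g_domain("AAAA", refs[0, ]), "empty")
})

test_that("G-domain FASTA headers round-trip class and domain tags", {
  path <- tempfile(fileext = ".fasta")
  writeLines(c(">r1 class=I domain=a", "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ",
               ">r2 class=II domain=b", "APRGSHMKLVINGKTLKGETTTEAVDAATAEKV"),
             path)
  refs <- read_gdomain_refs(path)
  expect_equal(refs$ref_id, c("r1", "r2"))
  expect_equal(refs$class, c("I", "II"))
  expect_equal(refs$domain, c("a", "b"))
  expect_equal(nchar(refs$seq), c(33L, 33L))
})
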