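#' Sorted intra-site atom-pair distances
#'
#' All unordered heavy-atom pair distances within one binding site, sorted
#' ascending — the site's conformational fingerprint used by the PMax/PMin
#' comparison.
#'
#' @param site An `epitope_site`, or an atom data.frame with `x`, `y`, `z`.
#' @return Numeric vector of length `n*(n-1)/2`, sorted ascending, with
#'   attribute `n_atoms`.
#' @export
site_distances <- function(site) {
  atoms <- if (inherits(site, "epitope_site")) site$atoms else site
  n <- NROW(atoms)
  if (n < 2) stop("site has fewer than 2 atoms; unscorable")
  d <- sort(as.numeric(stats::dist(cbind(atoms$x, atoms$y, atoms$z))))
  attr(d, "n_atoms") <- n
  d
}

#' Match two sorted distance lists within a tolerance
#'
#' Greedy two-pointer walk over the sorted lists: when the heads differ by at
#' most `tol` both advance and a match is counted; otherwise the smaller head
#' advances. Each element is matched at most once. On sorted lists this greedy
#' sweep attains the maximum matching (verified against an exhaustive
#' bipartite-matching oracle in the test suite).
#'
#' @param list_a,list_b Sorted ascending numeric vectors.
#' @param tol Tolerance in Angstrom.
#' @return Integer match count.
#' @export
match_distances <- function(list_a, list_b, tol = 0.5) {
  stopifnot(tol >= 0)
  i <- 1L; j <- 1L; matched <- 0L
  na <- length(list_a); nb <- length(list_b)
  while (i <= na && j <= nb) {
    if (abs(list_a[i] - list_b[j]) <= tol) {
      matched <- matched + 1L
      i <- i + 1L; j <- j + 1L
    } else if (list_a[i] < list_b[j]) {
      i <- i + 1L
    } else {
      j <- j + 1L
    }
  }
  matched
}

#' PMax/PMin conformational similarity of two binding sites
#'
#' Compares the sorted all-against-all atom-distance lists of the two sites.
#' PMax = matched pairs / pair count of the larger site; PMin = matched pairs
#' / pair count of the smaller site. Both lie in `[0, 1]`, PMin >= PMax, and
#' both are invariant under rigid-body transforms of either site.
#'
#' @param site_a,site_b `epitope_site` objects (or atom data.frames).
#' @param tol Distance-match tolerance in Angstrom (default 0.5).
#' @return A `site_score`: list with `pmax`, `pmin`, `matched`, `pairs_a`,
#'   `pairs_b`.
#' @export
pocketmatch_score <- function(site_a, site_b, tol = 0.5) {
  da <- site_distances(site_a)
  db <- site_distances(site_b)
  matched <- match_distances(da, db, tol)
  pa <- length(da); pb <- length(db)
  structure(list(
    pmax = if (max(pa, pb) == 0) 0 else matched / max(pa, pb),
    pmin = if (min(pa, pb) == 0) 0 else matched / min(pa, pb),
    matched = matched, pairs_a = pa, pairs_b = pb
  ), class = "site_score")
}

#' Epitope conformational-similarity decision rule
#'
#' Two binding sites cluster together iff PMax is 1.0, or PMin is 1.0, or
#' PMin >= 0.9 and PMax >= 0.6 simultaneously.
#'
#' @param score A `site_score` (or list with `pmax`, `pmin`).
#' @param pm_exact,pm_min,pm_max The three rule thresholds.
#' @return Logical scalar.
#' @export
sites_similar <- function(score, pm_exact = 1.0, pm_min = 0.9, pm_max = 0.6) {
  score$pmax >= pm_exact || score$pmin >= pm_exact ||
    (score$pmin >= pm_min && score$pmax >= pm_max)
}

# Letters outside the BLOSUM62 alphabet (e.g. U for selenocysteine) read as X.
.blosum_safe <- function(x) {
  gsub("[^ARNDCQEGHILKMFPSTWYVBZX*]", "X", toupper(x))
}

.blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Pairwise global sequence identity
#'
#' Needleman-Wunsch global alignment (BLOSUM62, gap open 10, gap extend 0.5);
#' identity is the percentage of identical aligned positions over the length
#' of the shorter sequence (default), so a fragment of a longer antigen scores
#' 100 against it. Symmetric in its arguments.
#'
#' @param seq_a,seq_b Non-empty one-letter amino-acid strings.
#' @param denominator `"shorter"` (default) or `"alignment"`.
#' @return Identity percentage in `[0, 100]`.
#' @export
pairwise_identity <- function(seq_a, seq_b,
                              denominator = c("shorter", "alignment")) {
  denominator <- match.arg(denominator)
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("empty sequence")
  aln <- Biostrings::pairwiseAlignment(
    .blosum_safe(seq_a), .blosum_safe(seq_b), type = "global",
    substitutionMatrix = .blosum62(), gapOpening = 10, gapExtension = 0.5
  )
  idn <- Biostrings::nmatch(aln)
  den <- if (denominator == "shorter") {
    min(nchar(seq_a), nchar(seq_b))
  } else {
    Biostrings::nchar(Biostrings::alignedPattern(aln))
  }
  100 * idn / den
}

#' Read a G-domain reference set from FASTA
#'
#' Headers must carry `class=` (I, II or the literal class tag used in the
#' reference) and `domain=` (`a` for class I alpha1-alpha2 or class II alpha1,
#' `b` for class II beta1) key-value tags, e.g.
#' `>gI_01 class=I domain=a`.
#'
#' @param path FASTA file path.
#' @return data.frame with columns `ref_id`, `class`, `domain`, `seq`.
#' @export
read_gdomain_refs <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0) stop("empty G-domain reference set: ", path)
  hdr <- names(set)
  tag <- function(key) {
    m <- regmatches(hdr, regexpr(paste0(key, "=[^ ]+"), hdr))
    sub(paste0(key, "="), "", m)
  }
  data.frame(
    ref_id = vapply(strsplit(hdr, " "), `[`, "", 1),
    class = tag("class"),
    domain = tag("domain"),
    seq = as.character(set),
    stringsAsFactors = FALSE
  )
}

#' Map an MHC chain sequence onto a G-domain reference
#'
#' Local alignment (Smith-Waterman, BLOSUM62, gap open 10 / extend 0.5) of the
#' query against every reference; a candidate hit must cover at least
#' `min_scov` percent of the reference (subject coverage) and span a query
#' region of at least `min_qcov` percent of the reference length. The
#' best-scoring accepted hit wins; the query subsequence under the alignment
#' is the mapped G-domain.
#'
#' @param mhc_seq Query chain sequence.
#' @param refs Reference data.frame from [read_gdomain_refs()].
#' @param min_qcov,min_scov Coverage thresholds in percent (defaults 90 / 85).
#' @return A `gdomain_hit` (list: `mhc_class`, `domain_tag`,
#'   `mapped_sequence`, `ref_id`, `qcov`, `scov`, `score`) or `NULL` when no
#'   reference passes — the caller then treats the chain as non-classical and
#'   clusters on the full sequence.
#' @export
map_g_domain <- function(mhc_seq, refs, min_qcov = 90, min_scov = 85) {
  if (is.null(refs) || nrow(refs) == 0) stop("empty G-domain reference set")
  if (!nzchar(mhc_seq)) stop("empty query sequence")
  best <- NULL
  q <- .blosum_safe(mhc_seq)
  for (k in seq_len(nrow(refs))) {
    aln <- Biostrings::pairwiseAlignment(
      q, .blosum_safe(refs$seq[k]), type = "local",
      substitutionMatrix = .blosum62(), gapOpening = 10, gapExtension = 0.5
    )
    ref_len <- nchar(refs$seq[k])
    sub_rng <- Biostrings::subject(aln)
    pat_rng <- Biostrings::pattern(aln)
    scov <- 100 * (Biostrings::end(sub_rng) - Biostrings::start(sub_rng) + 1) /
      ref_len
    qspan <- Biostrings::end(pat_rng) - Biostrings::start(pat_rng) + 1
    qcov <- 100 * qspan / ref_len
    if (scov < min_scov || qcov < min_qcov) next
    sc <- Biostrings::score(aln)
    if (is.null(best) || sc > best$score) {
      best <- list(
        mhc_class = refs$class[k],
        domain_tag = refs$domain[k],
        mapped_sequence = substr(mhc_seq, Biostrings::start(pat_rng),
                                 Biostrings::end(pat_rng)),
        ref_id = refs$ref_id[k],
        qcov = qcov, scov = scov, score = sc
      )
    }
  }
  if (is.null(best)) return(NULL)
  structure(best, class = "gdomain_hit")
}
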