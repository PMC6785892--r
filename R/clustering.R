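#' Single-linkage clusters from a pairwise similarity relation
#'
#' Clusters are the connected components of the graph whose vertices are the
#' items and whose edges are the similar pairs; cluster indices are 0-based
#' and numbered by first appearance of each component in item order, so the
#' partition is deterministic for a fixed item order.
#'
#' @param items Character vector of item ids (order defines numbering).
#' @param pairs Two-column matrix/data.frame of similar item-id pairs (the
#'   relation is treated as symmetric); may have zero rows.
#' @return An `epi_partition`: list with `members`, `cluster_of` (named
#'   0-based integer vector) and `n_clusters`.
#' @export
single_linkage_clusters <- function(items, pairs = NULL) {
  stopifnot(!anyDuplicated(items))
  g <- igraph::make_empty_graph(n = length(items), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = items)
  if (!is.null(pairs) && NROW(pairs) > 0) {
    ed <- as.matrix(pairs[, 1:2])
    stopifnot(all(ed %in% items))
    g <- igraph::add_edges(g, t(matrix(match(ed, items), ncol = 2)))
  }
  comp <- igraph::components(g)$membership
  # renumber components by first appearance in item order, 0-based
  first <- comp[!duplicated(comp)]
  cluster_of <- match(comp, first) - 1L
  names(cluster_of) <- items
  structure(list(members = items, cluster_of = cluster_of,
                 n_clusters = length(first)),
            class = "epi_partition")
}

# Exact-match grouping: one cluster per distinct key, numbered by first
# appearance in item order.
.partition_from_keys <- function(items, keys) {
  stopifnot(length(items) == length(keys), !anyDuplicated(items))
  cluster_of <- match(keys, keys[!duplicated(keys)]) - 1L
  names(cluster_of) <- items
  structure(list(members = items, cluster_of = cluster_of,
                 n_clusters = length(unique(keys))),
            class = "epi_partition")
}

#' @export
print.epi_partition <- function(x, ...) {
  cat("<epi_partition>", length(x$members), "items in", x$n_clusters,
      "clusters\n")
  invisible(x)
}

# Threshold-based single-linkage over sequences: similar iff pairwise
# identity >= threshold (percent).
.cluster_sequences <- function(seqs, threshold) {
  ids <- names(seqs)
  stopifnot(!is.null(ids))
  edges <- NULL
  n <- length(seqs)
  if (n > 1) {
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    keep <- vapply(seq_len(nrow(idx)), function(k) {
      a <- idx[k, 1]; b <- idx[k, 2]
      if (seqs[[a]] == seqs[[b]]) return(TRUE)  # alignment-free fast path
      pairwise_identity(seqs[[a]], seqs[[b]]) >= threshold
    }, logical(1))
    if (any(keep)) {
      edges <- cbind(ids[idx[keep, 1]], ids[idx[keep, 2]])
    }
  }
  single_linkage_clusters(ids, edges)
}

#' Cluster antigens by sequence identity
#'
#' Single-linkage clustering of antigen sequences at an identity threshold
#' (default 70 percent, shorter-sequence denominator); labels `Ag1`, `Ag2`,
#' ... by first appearance in id order.
#'
#' @param seqs Named character vector (names = complex ids) of antigen
#'   sequences.
#' @param threshold Identity threshold in percent.
#' @return List with `partition` (an `epi_partition`) and `labels` (named
#'   character vector).
#' @export
cluster_antigens <- function(seqs, threshold = 70) {
  part <- .cluster_sequences(seqs, threshold)
  list(partition = part,
       labels = setNames(paste0("Ag", part$cluster_of + 1L), part$members))
}

#' Cluster core-epitopes / core-peptides by sequence identity
#'
#' Same machinery as [cluster_antigens()] at the core-epitope default of 85
#' percent; labels `E1`, `E2`, ...
#'
#' @inheritParams cluster_antigens
#' @export
cluster_core_epitopes <- function(seqs, threshold = 85) {
  part <- .cluster_sequences(seqs, threshold)
  list(partition = part,
       labels = setNames(paste0("E", part$cluster_of + 1L), part$members))
}

# CDR keys per receptor chain of a record: named list role -> key.
.record_cdr_keys <- function(record) {
  roles <- record$chain_roles[record$chain_roles %in% .receptor_roles]
  out <- list()
  for (ch in names(roles)) {
    numbered <- record$numbering[[ch]]
    if (is.null(numbered)) stop("no numbering for receptor chain ", ch,
                                " of ", record$structure$structure_id)
    out[[unname(roles[ch])]] <- cdr_key(extract_cdrs(numbered))
  }
  out
}

#' Group receptors by exact CDR identity
#'
#' Heavy and light (or TCR alpha and beta) chains are grouped independently on
#' exact CDR1|CDR2|CDR3 identity; a complex's receptor label concatenates its
#' per-chain cluster indices, e.g. `H1_L2` or `A2_B1`, omitting a missing
#' chain (a nanobody gets a bare `H<i>`). Framework differences outside the
#' CDRs never separate receptors.
#'
#' @param records List of `epi_complex` objects (processed in sorted
#'   structure-id order).
#' @return List with `labels` (named by structure id), `chain_partitions`
#'   (per-role `epi_partition`s) and `partition` (complex-level
#'   `epi_partition` over the labels).
#' @export
cluster_receptors <- function(records) {
  ids <- vapply(records, function(r) r$structure$structure_id, "")
  ord <- order(ids)
  records <- records[ord]; ids <- ids[ord]
  keys <- lapply(records, .record_cdr_keys)
  if (any(vapply(keys, length, 0L) == 0)) {
    stop("receptor with zero annotated chains")
  }
  prefixes <- c(heavy = "H", light = "L", alpha = "A", beta = "B")
  role_order <- names(prefixes)
  chain_partitions <- list()
  labels <- setNames(rep("", length(ids)), ids)
  for (role in role_order) {
    have <- vapply(keys, function(k) !is.null(k[[role]]), logical(1))
    if (!any(have)) next
    kv <- vapply(keys[have], `[[`, "", role)
    part <- .partition_from_keys(ids[have], kv)
    chain_partitions[[role]] <- part
    piece <- paste0(prefixes[[role]], part$cluster_of + 1L)
    labels[have] <- ifelse(nzchar(labels[have]),
                           paste(labels[have], piece, sep = "_"), piece)
  }
  list(labels = labels,
       chain_partitions = chain_partitions,
       partition = .partition_from_keys(ids, unname(labels)))
}

#' Cluster epitope conformations within one receptor group
#'
#' Pairs of binding sites join a cluster iff [sites_similar()] holds for their
#' PMax/PMin score; connected components give the clusters. Unscorable sites
#' (no contacts, or fewer than two atoms) are singletons. Labels `E1`, `E2`,
#' ... are scoped to the receptor group.
#'
#' @param sites Named list of `epitope_site` objects (names = complex ids).
#' @param tol Distance-match tolerance in Angstrom.
#' @param pm_exact,pm_min,pm_max Decision-rule thresholds, see
#'   [sites_similar()].
#' @return List with `partition` and `labels`.
#' @export
cluster_epitope_conformations <- function(sites, tol = 0.5, pm_exact = 1.0,
                                          pm_min = 0.9, pm_max = 0.6) {
  ids <- names(sites)
  stopifnot(!is.null(ids))
  scorable <- vapply(sites, function(s) !isTRUE(s$empty) && NROW(s$atoms) >= 2,
                     logical(1))
  edges <- NULL
  sc_ids <- ids[scorable]
  if (length(sc_ids) > 1) {
    dl <- lapply(sites[scorable], site_distances)
    n <- length(sc_ids)
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    for (k in seq_len(nrow(idx))) {
      a <- idx[k, 1]; b <- idx[k, 2]
      m <- match_distances(dl[[a]], dl[[b]], tol)
      pa <- length(dl[[a]]); pb <- length(dl[[b]])
      sc <- list(pmax = m / max(pa, pb), pmin = m / min(pa, pb))
      if (sites_similar(sc, pm_exact, pm_min, pm_max)) {
        edges <- rbind(edges, c(sc_ids[a], sc_ids[b]))
      }
    }
  }
  part <- single_linkage_clusters(ids, edges)
  list(partition = part,
       labels = setNames(paste0("E", part$cluster_of + 1L), part$members))
}

#' Cluster MHC molecules by G-domain sequence
#'
#' Each complex's MHC chains are mapped onto the G-domain references. A
#' complex with a class I groove hit is keyed on its mapped alpha1-alpha2
#' sequence (`a<i>`); a complex with a class II alpha1 hit on one chain and
#' beta1 hit on the other is keyed on the mapped pair (`a<i>_b<j>`); anything
#' else is non-classical and keyed on the full chain sequences (`n<i>`).
#' Grouping is exact sequence match on the keys. Class I and class II 'a'
#' indices draw from one shared counter, in first-appearance order.
#'
#' @param records List of `epi_complex` objects with MHC chains.
#' @param refs G-domain reference data.frame from [read_gdomain_refs()].
#' @param min_qcov,min_scov Coverage thresholds passed to [map_g_domain()].
#' @return List with `labels` (named by structure id), `keys` (complex-level
#'   grouping keys) and `partition`.
#' @export
cluster_mhc <- function(records, refs, min_qcov = 90, min_scov = 85) {
  ids <- vapply(records, function(r) r$structure$structure_id, "")
  ord <- order(ids)
  records <- records[ord]; ids <- ids[ord]
  info <- lapply(records, function(rec) {
    chains <- names(rec$chain_roles)[rec$chain_roles %in% .mhc_roles]
    if (length(chains) == 0) stop("complex ", rec$structure$structure_id,
                                  " has no MHC chain")
    chains <- sort(chains)
    seqs <- vapply(chains, function(ch) chain_sequence(rec$structure, ch), "")
    hits <- lapply(seqs, function(s) {
      if (is.null(refs) || !nzchar(s)) return(NULL)
      map_g_domain(s, refs, min_qcov, min_scov)
    })
    i_hits <- Filter(function(h) !is.null(h) && h$mhc_class == "I" &&
                       h$domain_tag == "a", hits)
    ii_a <- Filter(function(h) !is.null(h) && h$mhc_class == "II" &&
                     h$domain_tag == "a", hits)
    ii_b <- Filter(function(h) !is.null(h) && h$mhc_class == "II" &&
                     h$domain_tag == "b", hits)
    if (length(i_hits)) {
      best <- i_hits[[which.max(vapply(i_hits, `[[`, 0, "score"))]]
      list(type = "I", a = best$mapped_sequence, b = NA_character_,
           key = paste0("I|", best$mapped_sequence))
    } else if (length(ii_a) && length(ii_b)) {
      a <- ii_a[[which.max(vapply(ii_a, `[[`, 0, "score"))]]$mapped_sequence
      b <- ii_b[[which.max(vapply(ii_b, `[[`, 0, "score"))]]$mapped_sequence
      list(type = "II", a = a, b = b, key = paste0("II|", a, "|", b))
    } else {
      full <- paste(seqs, collapse = "|")
      list(type = "N", a = NA_character_, b = NA_character_,
           key = paste0("N|", full))
    }
  })
  types <- vapply(info, `[[`, "", "type")
  # shared 'a' namespace over class I groove keys and class II alpha1 keys
  a_keys <- ifelse(types == "I", paste0("I|", vapply(info, `[[`, "", "a")),
            ifelse(types == "II", paste0("II|", vapply(info, `[[`, "", "a")),
                   NA_character_))
  a_idx <- match(a_keys, unique(a_keys[!is.na(a_keys)]))
  b_keys <- ifelse(types == "II", vapply(info, `[[`, "", "b"), NA_character_)
  b_idx <- match(b_keys, unique(b_keys[!is.na(b_keys)]))
  n_keys <- ifelse(types == "N", vapply(info, `[[`, "", "key"), NA_character_)
  n_idx <- match(n_keys, unique(n_keys[!is.na(n_keys)]))
  labels <- character(length(ids))
  labels[types == "I"] <- paste0("a", a_idx[types == "I"])
  labels[types == "II"] <- paste0("a", a_idx[types == "II"], "_b",
                                  b_idx[types == "II"])
  labels[types == "N"] <- paste0("n", n_idx[types == "N"])
  keys <- vapply(info, `[[`, "", "key")
  list(labels = setNames(labels, ids),
       keys = setNames(keys, ids),
       partition = .partition_from_keys(ids, keys))
}

#' Assign distinct receptor-epitope pair clusters and representatives
#'
#' The pair-cluster id joins the given cluster-label columns with `|`; one
#' representative per pair cluster is the member with the numerically lowest
#' resolution (missing resolution sorts last), ties broken by lexicographically
#' smallest structure id.
#'
#' @param rows data.frame with columns `structure_id`, `resolution` and the
#'   label columns named in `id_cols`.
#' @param id_cols Character vector of column names forming the pair id.
#' @return `rows` with added `pair_cluster_id` and `is_representative`
#'   columns, plus attribute `n_pairs`.
#' @export
distinct_pairs <- function(rows, id_cols) {
  stopifnot(all(c("structure_id", "resolution", id_cols) %in% names(rows)))
  if (nrow(rows) == 0) {
    rows$pair_cluster_id <- character(0)
    rows$is_representative <- logical(0)
    attr(rows, "n_pairs") <- 0L
    return(rows)
  }
  pid <- do.call(paste, c(rows[id_cols], sep = "|"))
  rows$pair_cluster_id <- pid
  res <- ifelse(is.na(rows$resolution), Inf, rows$resolution)
  ord <- order(pid, res, rows$structure_id)
  rep_row <- ord[!duplicated(pid[ord])]
  rows$is_representative <- seq_len(nrow(rows)) %in% rep_row
  attr(rows, "n_pairs") <- length(unique(pid))
  rows
}

#' Export a partition as TSV
#'
#' @param labels Named character vector (item id -> cluster label).
#' @param path Output path.
#' @export
write_partition_tsv <- function(labels, path) {
  write.table(data.frame(item_id = names(labels), cluster_label = labels),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
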