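# Independent brute-force oracles, deliberately naive: they re-derive the
# quantities the package computes, by a different route.

# All-pairs residue contact oracle: explicit per-atom distance evaluation,
# aggregated to residue pairs by a running minimum.
bf_contacts <- function(atoms_a, atoms_b, cutoff = 4.0) {
  mins <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(atoms_a))) {
    d <- sqrt((atoms_a$x[i] - atoms_b$x)^2 + (atoms_a$y[i] - atoms_b$y)^2 +
              (atoms_a$z[i] - atoms_b$z)^2)
    for (j in which(d <= cutoff)) {
      key <- paste(atoms_a$chain[i], atoms_a$seq_index[i],
                   atoms_b$chain[j], atoms_b$seq_index[j], sep = "|")
      if (is.null(mins[[key]]) || d[j] < mins[[key]]) mins[[key]] <- d[j]
    }
  }
  keys <- ls(mins)
  if (length(keys) == 0) {
    return(data.frame(chain_a = character(), res_a = integer(),
                      chain_b = character(), res_b = integer(),
                      min_distance = numeric()))
  }
  parts <- strsplit(keys, "|", fixed = TRUE)
  res <- data.frame(
    chain_a = vapply(parts, `[`, "", 1),
    res_a = as.integer(vapply(parts, `[`, "", 2)),
    chain_b = vapply(parts, `[`, "", 3),
    res_b = as.integer(vapply(parts, `[`, "", 4)),
    min_distance = vapply(keys, function(k) mins[[k]], 0),
    stringsAsFactors = FALSE
  )
  res <- res[order(res$chain_a, res$res_a, res$chain_b, res$res_b), ]
  rownames(res) <- NULL
  res
}

# Maximum bipartite matching (Kuhn's augmenting paths) between two distance
# lists under |a - b| <= tol.
bf_max_matching <- function(a, b, tol) {
  na <- length(a); nb <- length(b)
  if (na == 0 || nb == 0) return(0L)
  adj <- lapply(seq_len(na), function(i) which(abs(a[i] - b) <= tol))
  match_b <- rep(0L, nb)
  seen <- rep(FALSE, nb)
  try_kuhn <- function(i) {
    for (j in adj[[i]]) {
      if (!seen[j]) {
        seen[j] <<- TRUE
        if (match_b[j] == 0L || try_kuhn(match_b[j])) {
          match_b[j] <<- i
          return(TRUE)
        }
      }
    }
    FALSE
  }
  matched <- 0L
  for (i in seq_len(na)) {
    seen <- rep(FALSE, nb)
    if (try_kuhn(i)) matched <- matched + 1L
  }
  matched
}

# Connected components by breadth-first search over an adjacency matrix.
bf_components <- function(adj) {
  n <- nrow(adj)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & is.na(comp))
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

# A random cloud of atoms grouped into residues, for contact oracles.
random_atom_set <- function(n_atoms, chain = "A", box = 30, n_res = NULL) {
  if (is.null(n_res)) n_res <- max(1L, n_atoms %/% 4L)
  data.frame(
    chain = chain,
    seq_index = sort(sample(seq_len(n_res), n_atoms, replace = TRUE)) - 1L,
    x = runif(n_atoms, 0, box), y = runif(n_atoms, 0, box),
    z = runif(n_atoms, 0, box),
    stringsAsFactors = FALSE
  )
}

random_site <- function(n_atoms, box = 30) {
  data.frame(x = runif(n_atoms, 0, box), y = runif(n_atoms, 0, box),
             z = runif(n_atoms, 0, box))
}
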