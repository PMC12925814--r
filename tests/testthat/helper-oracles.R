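# Independent oracles used to cross-check the package's implementations.
# Each deliberately takes a different computational route than the code
# under test (explicit enumeration, double loops, Monte Carlo).

# minimum-image distance by enumerating all 27 periodic image translations
oracle_min_image <- function(a, b, box) {
  best <- Inf
  for (ix in -1:1) for (iy in -1:1) for (iz in -1:1) {
    d <- b + c(ix, iy, iz) * box - a
    best <- min(best, sqrt(sum(d * d)))
  }
  best
}

# neighbour pairs by an O(n^2) double loop
oracle_pairs <- function(coords, box, sel_a, sel_b, cutoff) {
  out <- list()
  identical_sel <- length(sel_a) == length(sel_b) && all(sel_a == sel_b)
  for (i in sel_a) for (j in sel_b) {
    if (identical_sel && j <= i) next
    d <- if (is.null(box)) sqrt(sum((coords[i, ] - coords[j, ])^2))
         else oracle_min_image(coords[i, ], coords[j, ], box)
    if (d <= cutoff) out[[length(out) + 1L]] <- c(i, j)
  }
  if (!length(out)) return(matrix(integer(), 0, 2))
  m <- do.call(rbind, out)
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

# connected components of peptide molecules via igraph (independent of
# the union-find in the package)
oracle_components <- function(coords, mol_ids, box, cutoff) {
  mols <- sort(unique(mol_ids))
  n <- length(mols)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    A <- coords[mol_ids == mols[i], , drop = FALSE]
    B <- coords[mol_ids == mols[j], , drop = FALSE]
    linked <- FALSE
    for (p in seq_len(nrow(A))) for (q in seq_len(nrow(B))) {
      d <- if (is.null(box)) sqrt(sum((A[p, ] - B[q, ])^2))
           else oracle_min_image(A[p, ], B[q, ], box)
      if (d <= cutoff) { linked <- TRUE; break }
    }
    adj[i, j] <- adj[j, i] <- linked
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  unname(split(mols, comp))
}

# Monte-Carlo SASA: uniform random points on each expanded sphere
oracle_mc_sasa <- function(coords, radii, selection, probe,
                           n_mc = 1e5, seed = 99) {
  set.seed(seed)
  total <- 0
  for (i in selection) {
    ri <- radii[i] + probe
    z <- stats::runif(n_mc, -1, 1)
    phi <- stats::runif(n_mc, 0, 2 * pi)
    r <- sqrt(1 - z^2)
    pts <- cbind(r * cos(phi), r * sin(phi), z) * ri
    pts <- sweep(pts, 2, coords[i, ], "+")
    buried <- rep(FALSE, n_mc)
    for (j in seq_len(nrow(coords))) {
      if (j == i) next
      rj2 <- (radii[j] + probe)^2
      d2 <- (pts[, 1] - coords[j, 1])^2 + (pts[, 2] - coords[j, 2])^2 +
        (pts[, 3] - coords[j, 3])^2
      buried <- buried | d2 < rj2
    }
    total <- total + 4 * pi * ri^2 * mean(!buried)
  }
  total
}

# Spearman rho by explicit mid-ranking then Pearson on the ranks
oracle_spearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# --- Nei-Gojobori oracle: exhaustive neighbour / recursive pathway
# enumeration, written independently of the package's codon walk -------
oracle_code <- local({
  gc <- Biostrings::GENETIC_CODE
  names(gc) <- gsub("U", "T", names(gc))
  gc
})

oracle_sites <- function(codon) {
  aa <- oracle_code[[codon]]
  s <- 0; nts <- c("A", "C", "G", "T")
  for (pos in 1:3) {
    for (nt in nts) {
      if (substr(codon, pos, pos) == nt) next
      mut <- codon
      substr(mut, pos, pos) <- nt
      if (oracle_code[[mut]] == aa) s <- s + 1 / 3
    }
  }
  c(s, 3 - s)
}

# recursive pathway enumeration (rather than permutation tables):
# returns list of per-path c(syn, nonsyn), skipping stop intermediates
oracle_paths <- function(a, b) {
  if (a == b) return(list(c(0, 0)))
  out <- list()
  for (pos in 1:3) {
    if (substr(a, pos, pos) == substr(b, pos, pos)) next
    step <- a
    substr(step, pos, pos) <- substr(b, pos, pos)
    if (oracle_code[[step]] == "*" && step != b) next
    inc <- if (oracle_code[[a]] == oracle_code[[step]]) c(1, 0) else c(0, 1)
    for (tail_counts in oracle_paths(step, b))
      out[[length(out) + 1L]] <- inc + tail_counts
  }
  out
}

oracle_ng86 <- function(seq_a, seq_b) {
  n <- nchar(seq_a) / 3
  S <- N <- Sd <- Nd <- 0
  for (k in seq_len(n)) {
    a <- substr(seq_a, 3 * k - 2, 3 * k)
    b <- substr(seq_b, 3 * k - 2, 3 * k)
    if (grepl("[^ACGT]", a) || grepl("[^ACGT]", b)) next
    sa <- oracle_sites(a); sb <- oracle_sites(b)
    S <- S + (sa[1] + sb[1]) / 2
    N <- N + (sa[2] + sb[2]) / 2
    paths <- oracle_paths(a, b)
    if (!length(paths)) {
      # all pathways stop-blocked: fall back to unrestricted enumeration
      perms <- combinat_perms(which(strsplit(a, "")[[1]] !=
                                      strsplit(b, "")[[1]]))
      paths <- lapply(perms, function(ord) {
        cur <- a; cnt <- c(0, 0)
        for (pos in ord) {
          nxt <- cur
          substr(nxt, pos, pos) <- substr(b, pos, pos)
          if (oracle_code[[cur]] == oracle_code[[nxt]])
            cnt <- cnt + c(1, 0) else cnt <- cnt + c(0, 1)
          cur <- nxt
        }
        cnt
      })
    }
    m <- do.call(rbind, paths)
    Sd <- Sd + mean(m[, 1]); Nd <- Nd + mean(m[, 2])
  }
  list(S = S, N = N, Sd = Sd, Nd = Nd)
}

combinat_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in combinat_perms(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], rest)
  out
}

# random sense codon
random_codon <- function() {
  repeat {
    cd <- paste(sample(c("A", "C", "G", "T"), 3, replace = TRUE),
                collapse = "")
    if (oracle_code[[cd]] != "*") return(cd)
  }
}
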