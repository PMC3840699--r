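# Independent oracles, deliberately written by a different route than the
# package implementation (brute force / from-scratch recomputation).

random_dna <- function(n) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# brute-force scan for the first occurrence of `site` (1-based; 0 if none)
oracle_first_site <- function(seqs, site) {
  L <- nchar(seqs)
  w <- nchar(site)
  for (i in seq_len(L - w + 1)) {
    if (substr(seqs, i, i + w - 1) == site) return(i)
  }
  0L
}

# direct formula evaluation of the Bray-Curtis percent similarity
oracle_bray <- function(x, y) {
  100 * (1 - sum(abs(x - y)) / sum(x + y))
}

# exhaustive agglomeration recomputing linkage from the ORIGINAL distance
# matrix over cluster members at each step (no Lance-Williams updates);
# first minimal pair in lexicographic order merges.  Returns the cophenetic
# matrix (UPGMA) or the partition at `cutoff` (OTU clustering).
oracle_agglomerate <- function(d, linkage = "average", cutoff = Inf) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  repeat {
    if (length(clusters) == 1) break
    # order clusters by smallest member for lexicographic pair choice
    clusters <- clusters[order(vapply(clusters, min, 0L))]
    best <- NULL
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (j <= i) next
      cross <- d[clusters[[i]], clusters[[j]], drop = FALSE]
      h <- switch(linkage, average = mean(cross), nearest = min(cross),
                  furthest = max(cross))
      if (is.null(best) || h < best$h - 1e-12) best <- list(i = i, j = j, h = h)
    }
    if (best$h > cutoff) break
    coph[clusters[[best$i]], clusters[[best$j]]] <- best$h
    coph[clusters[[best$j]], clusters[[best$i]]] <- best$h
    clusters[[best$i]] <- sort(c(clusters[[best$i]], clusters[[best$j]]))
    clusters[[best$j]] <- NULL
  }
  part <- integer(n)
  for (cl in clusters) part[cl] <- min(cl)
  list(cophenetic = coph, partition = match(part, sort(unique(part))))
}

# random symmetric distance matrix with zero diagonal
random_dist <- function(n, max = 1) {
  d <- matrix(0, n, n)
  d[upper.tri(d)] <- runif(n * (n - 1) / 2, 0, max)
  d + t(d)
}

# a small, fast scenario for property tests
small_config <- function(seed, ...) {
  scenario_config(otu_pool_size = 40, seed = seed, ...)
}
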