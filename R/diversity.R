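#' Pairwise p-distance between two aligned sequences
#'
#' Fraction of comparable alignment columns at which the two sequences
#' differ.  Columns where either sequence carries a gap (`-` or `.`) or an
#' ambiguity code (anything other than A, C, G, T) are excluded from the
#' denominator.  Sequences must be pre-aligned to equal length.
#'
#' @param a,b Aligned DNA strings of equal length.
#' @return Proportion of differing comparable columns in [0, 1].
#' @export
#' @examples
#' pdistance("AC-T", "ACGT")  # gap column excluded -> 0
pdistance <- function(a, b) {
  ca <- strsplit(toupper(a), "", fixed = TRUE)[[1]]
  cb <- strsplit(toupper(b), "", fixed = TRUE)[[1]]
  if (length(ca) != length(cb))
    stop("sequences must be aligned to equal length", call. = FALSE)
  plain <- c("A", "C", "G", "T")
  ok <- ca %in% plain & cb %in% plain
  if (!any(ok))
    stop("no comparable columns", call. = FALSE)
  mean(ca[ok] != cb[ok])
}

# shared agglomeration engine (also used by upgma)
# d: symmetric distance matrix; returns list of merge steps
# (members of the two clusters, merge height) with lexicographic tie-break
agglomerate <- function(d, linkage = c("average", "nearest", "furthest"),
                        max_height = Inf) {
  linkage <- match.arg(linkage)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  sizes <- rep(1L, n)
  D <- d
  diag(D) <- Inf
  steps <- list()
  while (length(clusters) > 1) {
    # lexicographically smallest minimal pair, clusters ordered by first member
    ord <- order(vapply(clusters, min, 0L))
    best <- NULL
    for (ii in seq_along(ord)) {
      for (jj in seq_along(ord)) {
        if (jj <= ii) next
        i <- ord[ii]; j <- ord[jj]
        if (is.null(best) || D[i, j] < best$h - 1e-12) {
          best <- list(i = i, j = j, h = D[i, j])
        }
      }
    }
    if (best$h > max_height) break
    i <- best$i; j <- best$j
    steps[[length(steps) + 1]] <- list(left = clusters[[i]],
                                       right = clusters[[j]],
                                       height = best$h)
    new_d <- vapply(seq_along(clusters), function(k) {
      if (k == i || k == j) return(Inf)
      switch(linkage,
        average  = (sizes[i] * D[i, k] + sizes[j] * D[j, k]) /
                   (sizes[i] + sizes[j]),
        nearest  = min(D[i, k], D[j, k]),
        furthest = max(D[i, k], D[j, k]))
    }, 0)
    keep <- setdiff(seq_along(clusters), c(i, j))
    merged <- sort(c(clusters[[i]], clusters[[j]]))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], new_d[keep]),
               c(new_d[keep], Inf))
    sizes <- c(sizes[keep], sizes[i] + sizes[j])
    clusters <- c(clusters[keep], list(merged))
  }
  list(steps = steps, clusters = clusters)
}

#' Cluster sequences into OTUs by agglomeration of pairwise distances
#'
#' Agglomerative clustering of a pairwise distance matrix; merging
#' continues while the linkage distance of the closest pair is at most
#' `cutoff` (inclusive, matching the "sequences differing by < 2\%" OTU
#' convention of mothur-era workflows, implemented as distance <= 0.02).
#' Ties are broken deterministically: the lexicographically smallest
#' cluster pair (ordered by smallest member index) merges first.
#'
#' @param distances Symmetric numeric matrix of pairwise distances with
#'   zero diagonal (e.g. from [pdistance()]).
#' @param cutoff Maximum linkage distance at which merging is allowed
#'   (default 0.02).
#' @param linkage "average" (default), "nearest" or "furthest".
#' @return Integer vector of OTU assignments (1-based, numbered by each
#'   cluster's smallest member index), named if `distances` has rownames.
#' @export
#' @examples
#' d <- matrix(c(0, .01, .05, .01, 0, .05, .05, .05, 0), 3)
#' cluster_otus(d)  # 1 1 2
cluster_otus <- function(distances, cutoff = 0.02,
                         linkage = c("average", "nearest", "furthest")) {
  linkage <- match.arg(linkage)
  distances <- as.matrix(distances)
  if (nrow(distances) != ncol(distances) ||
      any(abs(distances - t(distances)) > 1e-9) ||
      any(abs(diag(distances)) > 1e-12))
    stop("distances must be a symmetric matrix with zero diagonal",
         call. = FALSE)
  res <- agglomerate(distances, linkage, max_height = cutoff)
  assign <- integer(nrow(distances))
  for (cl in res$clusters) assign[cl] <- min(cl)
  assign <- match(assign, sort(unique(assign)))
  names(assign) <- rownames(distances)
  assign
}

#' Alpha-diversity summary of one community
#'
#' Computes observed richness S, total count N, the Shannon index
#' H' = -sum p_i ln p_i (natural log by default), Margalef richness
#' SR = (S - 1) / ln N, and the bias-corrected Chao1 estimate
#' S + n1 (n1 - 1) / (2 (n2 + 1)), where n1 and n2 are the numbers of
#' singleton and doubleton OTUs.  When the input is not integer counts
#' (e.g. relative T-RFLP peak heights) only H' is computed from the
#' fractions; N, SR and Chao1 require true individuals and are NA.
#'
#' @param counts Non-negative per-OTU counts (or relative abundances).
#' @param base Logarithm base for H' (default `exp(1)`: nats).
#' @return Object of class `diversity_summary`: list with `S_obs`, `N`,
#'   `H_prime`, `SR`, `chao1`.
#' @export
#' @examples
#' diversity_summary(c(5, 1, 1))$chao1  # 4
diversity_summary <- function(counts, base = exp(1)) {
  counts <- counts[counts > 0]
  if (length(counts) == 0 || any(counts < 0))
    stop("counts must contain at least one positive value", call. = FALSE)
  S <- length(counts)
  p <- counts / sum(counts)
  H <- -sum(p * log(p, base = base))
  integerish <- all(abs(counts - round(counts)) < 1e-9)
  if (integerish) {
    counts <- round(counts)
    N <- sum(counts)
    SR <- if (S == 1) 0 else (S - 1) / log(N)
    n1 <- sum(counts == 1)
    n2 <- sum(counts == 2)
    chao1 <- S + n1 * (n1 - 1) / (2 * (n2 + 1))
  } else {
    N <- NA_real_; SR <- NA_real_; chao1 <- NA_real_
  }
  structure(list(S_obs = S, N = N, H_prime = H, SR = SR, chao1 = chao1),
            class = "diversity_summary")
}

#' @export
print.diversity_summary <- function(x, ...) {
  cat(sprintf("S_obs = %d, N = %s, H' = %.4f, SR = %s, Chao1 = %s\n",
              x$S_obs, format(x$N), x$H_prime, format(round(x$SR, 4)),
              format(round(x$chao1, 4))))
  invisible(x)
}

#' Analytic rarefaction curve
#'
#' Expected OTU richness in a random subsample of n individuals drawn
#' without replacement, E[S_n] = sum_i (1 - C(N - N_i, n) / C(N, n)),
#' evaluated exactly via log-binomial coefficients (no Monte Carlo).
#'
#' @param counts Non-negative integer per-OTU counts.
#' @param sizes Subsample sizes (0 <= n <= N).
#' @return data.frame with columns `n` and `expected_S`.
#' @export
#' @examples
#' rarefaction_curve(c(2, 1), 1)$expected_S  # 1
rarefaction_curve <- function(counts, sizes) {
  if (any(counts < 0) || any(abs(counts - round(counts)) > 1e-9))
    stop("counts must be non-negative integers", call. = FALSE)
  counts <- round(counts[counts > 0])
  N <- sum(counts)
  if (any(abs(sizes - round(sizes)) > 1e-9))
    stop("subsample sizes must be integers", call. = FALSE)
  sizes <- round(sizes)
  if (any(sizes < 0) || any(sizes > N))
    stop("subsample sizes must lie in [0, N]", call. = FALSE)
  es <- vapply(sizes, function(n) {
    if (n == 0) return(0)
    sum(1 - exp(lchoose(N - counts, n) - lchoose(N, n)))
  }, 0)
  data.frame(n = sizes, expected_S = es)
}

#' OTU incidence across water-mass groups
#'
#' Classifies each OTU by its incidence across sample groups: present in a
#' group when nonzero in at least one of its samples; ubiquitous when
#' present in every group; unique when present in exactly one.  Percentages
#' are rounded half away from zero to integers.  Additionally reports the
#' fraction of OTUs present in more than `prevalence_threshold` of all
#' samples.
#'
#' @param m Matrix of samples (rows) x OTUs (columns); any nonzero entry
#'   counts as presence.
#' @param groups Group label per sample: either a vector aligned with the
#'   rows of `m` or a named vector keyed by rownames.
#' @param prevalence_threshold Sample-prevalence cutoff for the
#'   high-prevalence fraction (default 0.70).
#' @return Object of class `incidence_summary`: list with `n_total`,
#'   `n_ubiquitous`, `pct_ubiquitous`, `n_unique`, `pct_unique`,
#'   `n_high_prevalence`, `pct_high_prevalence`, `prevalence` (named
#'   per-OTU sample prevalence), and `groups_per_otu`.
#' @export
incidence_summary <- function(m, groups, prevalence_threshold = 0.70) {
  m <- as.matrix(m)
  if (nrow(m) == 0 || ncol(m) == 0)
    stop("empty matrix", call. = FALSE)
  if (!is.null(names(groups)) && !is.null(rownames(m))) {
    miss <- setdiff(rownames(m), names(groups))
    if (length(miss) > 0)
      stop("samples without a group: ", paste(miss, collapse = ", "),
           call. = FALSE)
    groups <- groups[rownames(m)]
  }
  if (length(groups) != nrow(m))
    stop("one group label per sample required", call. = FALSE)
  pres <- m > 0
  detected <- colSums(pres) > 0
  glev <- unique(groups)
  in_group <- sapply(glev, function(g)
    colSums(pres[groups == g, , drop = FALSE]) > 0)
  if (is.vector(in_group)) in_group <- matrix(in_group, ncol = length(glev))
  n_groups_per_otu <- rowSums(in_group)
  n_total <- sum(detected)
  n_ubiq <- sum(detected & n_groups_per_otu == length(glev))
  n_uniq <- sum(detected & n_groups_per_otu == 1)
  prevalence <- colMeans(pres)
  n_high <- sum(detected & prevalence > prevalence_threshold)
  pct <- function(k) sign(k / n_total) * floor(abs(100 * k / n_total) + 0.5)
  structure(list(
    n_total = n_total, n_ubiquitous = n_ubiq, pct_ubiquitous = pct(n_ubiq),
    n_unique = n_uniq, pct_unique = pct(n_uniq),
    n_high_prevalence = n_high, pct_high_prevalence = pct(n_high),
    prevalence = prevalence, groups_per_otu = n_groups_per_otu
  ), class = "incidence_summary")
}

#' @export
print.incidence_summary <- function(x, ...) {
  cat(x$n_total, "OTUs detected;", x$n_ubiquitous,
      paste0("(", x$pct_ubiquitous, "%)"), "in all groups;",
      x$n_unique, paste0("(", x$pct_unique, "%)"), "in one group;",
      x$n_high_prevalence, paste0("(", x$pct_high_prevalence, "%)"),
      "high-prevalence\n")
  invisible(x)
}

#' Rank-abundance distribution
#'
#' @param counts Per-OTU counts or abundances (>= 1 positive entry).
#' @return Numeric vector of relative abundances sorted in descending
#'   order; ties keep input order.
#' @export
rank_abundance <- function(counts) {
  if (all(counts <= 0)) stop("all counts are zero", call. = FALSE)
  counts <- counts[counts > 0]
  p <- counts / sum(counts)
  p[order(-p)]
}
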