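#' Construct a resemblance matrix object
#'
#' @param values Symmetric numeric matrix with sample ids as dimnames.
#' @param kind "similarity-percent" (diagonal 100) or "distance"
#'   (diagonal 0).
#' @param metric Free-text metric tag (e.g. "bray-curtis").
#' @return Object of class `resemblance`.
#' @export
new_resemblance <- function(values, kind, metric) {
  stopifnot(kind %in% c("similarity-percent", "distance"))
  structure(list(values = values, kind = kind, metric = metric),
            class = "resemblance")
}

#' @export
print.resemblance <- function(x, ...) {
  cat(nrow(x$values), "x", ncol(x$values), x$kind, "matrix (", x$metric,
      ")\n")
  invisible(x)
}

# distance form of a resemblance matrix (similarity percent -> 100 - S)
as_distance_values <- function(r) {
  stopifnot(inherits(r, "resemblance"))
  if (r$kind == "distance") r$values else 100 - r$values
}

#' Bray-Curtis similarity matrix between samples
#'
#' S(x, y) = 100 * (1 - sum|x_i - y_i| / sum(x_i + y_i)), the percent
#' similarity used throughout community fingerprint analysis.  A pair of
#' all-zero samples has undefined similarity and is set to 0 with a
#' warning.
#'
#' @param m Numeric matrix of samples (rows) x OTUs/bins (columns), e.g. a
#'   `fingerprint_matrix` or a transposed OTU table.
#' @return A `resemblance` object (kind "similarity-percent", diagonal
#'   100).
#' @export
#' @examples
#' bray_curtis_matrix(rbind(a = c(1, 3), b = c(3, 1)))$values
bray_curtis_matrix <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m)
  if (n < 2) stop("need at least 2 samples", call. = FALSE)
  if (any(m < 0)) stop("negative abundances", call. = FALSE)
  ids <- rownames(m)
  if (is.null(ids)) ids <- paste0("sample_", seq_len(n))
  # sum|x_i - y_i| is the Manhattan distance; sum(x_i + y_i) the row-sum pair
  man <- as.matrix(stats::dist(m, method = "manhattan"))
  rs <- rowSums(m)
  tot <- outer(rs, rs, "+")
  S <- 100 * (1 - man / tot)
  if (any(tot == 0)) {
    warning("pair(s) of all-zero samples: similarity set to 0")
    S[tot == 0] <- 0
  }
  diag(S) <- 100
  dimnames(S) <- list(ids, ids)
  new_resemblance(S, "similarity-percent", "bray-curtis")
}

#' Euclidean distance matrix on (normalized) environmental variables
#'
#' Each selected variable is centered and scaled to unit standard deviation
#' (n - 1 denominator) across samples, then pairwise Euclidean distances
#' are computed.  Zero-variance variables cannot be scaled and are dropped
#' with a warning.
#'
#' @param metadata data.frame with one row per sample; sample ids taken
#'   from a `sample_id` column if present, else rownames.
#' @param variables Character vector of column names to use.
#' @param normalize Scale variables before computing distances
#'   (default TRUE).
#' @param log_transform Optional character vector of variables to
#'   log10(x + 1)-transform before normalization (e.g. cell abundances).
#' @return A `resemblance` object (kind "distance", metric "euclidean").
#' @export
env_distance_matrix <- function(metadata, variables, normalize = TRUE,
                                log_transform = character(0)) {
  if (nrow(metadata) < 2) stop("need at least 2 samples", call. = FALSE)
  miss <- setdiff(variables, names(metadata))
  if (length(miss) > 0)
    stop("variables not in metadata: ", paste(miss, collapse = ", "),
         call. = FALSE)
  ids <- if ("sample_id" %in% names(metadata)) metadata$sample_id
         else rownames(metadata)
  x <- as.matrix(metadata[, variables, drop = FALSE])
  if (!is.numeric(x)) stop("variables must be numeric", call. = FALSE)
  for (v in intersect(log_transform, variables))
    x[, v] <- log10(x[, v] + 1)
  if (normalize) {
    sds <- apply(x, 2, stats::sd)
    if (any(sds == 0)) {
      warning("zero-variance variable(s) dropped: ",
              paste(colnames(x)[sds == 0], collapse = ", "))
      x <- x[, sds > 0, drop = FALSE]
      if (ncol(x) == 0) stop("no variables left", call. = FALSE)
      sds <- sds[sds > 0]
    }
    x <- scale(x)
  }
  D <- as.matrix(stats::dist(x))
  dimnames(D) <- list(ids, ids)
  new_resemblance(D, "distance", "euclidean")
}

#' Group-average (UPGMA) hierarchical clustering of samples
#'
#' Agglomerative clustering with group-average linkage, the method used to
#' display water-mass structure in community-fingerprint dendrograms.
#' Similarity matrices are converted internally to distances (100 - S).
#' Ties are broken deterministically (lexicographically smallest pair).
#'
#' @param resemblance A `resemblance` object or symmetric distance matrix.
#' @return An object of classes `upgma` and `hclust` (plot, cut and
#'   convert with the standard tools, e.g. `ape::as.phylo`).
#' @export
upgma <- function(resemblance) {
  d <- if (inherits(resemblance, "resemblance"))
    as_distance_values(resemblance) else as.matrix(resemblance)
  n <- nrow(d)
  if (n < 2) stop("need at least 2 samples", call. = FALSE)
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("sample_", seq_len(n))
  res <- agglomerate(d, "average")
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  # hclust encoding: negative = singleton, positive = earlier merge index
  step_of <- rep(NA_integer_, n)  # last merge step containing each leaf
  for (k in seq_along(res$steps)) {
    st <- res$steps[[k]]
    enc <- function(members) {
      s <- step_of[members[1]]
      if (is.na(s)) -members[1] else s
    }
    merge[k, ] <- sort(c(enc(st$left), enc(st$right)))
    height[k] <- st$height
    step_of[c(st$left, st$right)] <- k
  }
  order <- unlist(order_dendro(merge, n - 1))
  structure(list(merge = merge, height = height, order = order,
                 labels = labels, method = "upgma",
                 call = match.call(), dist.method = "as-supplied"),
            class = c("upgma", "hclust"))
}

# leaf order for plotting, by recursive traversal of the merge matrix
order_dendro <- function(merge, k) {
  expand <- function(i) {
    if (i < 0) return(-i)
    c(expand(merge[i, 1]), expand(merge[i, 2]))
  }
  expand(k)
}

#' Write a dendrogram as a Newick tree
#'
#' Branch lengths are merge-height differences (ultrametric under
#' group-average linkage).
#'
#' @param dendro An `upgma`/`hclust` object.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_newick <- function(dendro, path) {
  phy <- ape::as.phylo(stats::as.hclust(dendro))
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Mantel-type rank correlation between two resemblance matrices
#'
#' The RELATE statistic: Spearman (or Kendall) rank correlation between the
#' lower-triangle entries of two resemblance matrices over the same
#' samples, with significance from a permutation null obtained by jointly
#' permuting the rows and columns of the second matrix.  The one-sided
#' p-value counts permuted correlations at least as large as the observed
#' one, with the observed configuration always included:
#' p = (1 + #\{rho_perm >= rho_obs\}) / (1 + n_perm).
#'
#' @param mA,mB `resemblance` objects (or symmetric matrices) over the same
#'   samples in the same order.
#' @param n_perm Number of permutations (default 9999).
#' @param seed Optional integer seed.
#' @param method "spearman" (default) or "kendall".
#' @return Object of class `mantel_result`: list with `rho`, `p`,
#'   `n_perm`, `method`.
#' @export
relate <- function(mA, mB, n_perm = 9999, seed = NULL,
                   method = c("spearman", "kendall")) {
  method <- match.arg(method)
  A <- if (inherits(mA, "resemblance")) mA$values else as.matrix(mA)
  B <- if (inherits(mB, "resemblance")) mB$values else as.matrix(mB)
  if (!identical(dim(A), dim(B)))
    stop("matrices must have identical dimensions", call. = FALSE)
  if (!is.null(rownames(A)) && !is.null(rownames(B)) &&
      !identical(rownames(A), rownames(B)))
    stop("matrices must cover the same samples in the same order",
         call. = FALSE)
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  n <- nrow(A)
  lt <- lower.tri(A)
  a <- A[lt]
  rho_obs <- stats::cor(a, B[lt], method = method)
  if (!is.null(seed)) set.seed(seed)
  count <- 0L
  for (k in seq_len(n_perm)) {
    idx <- sample.int(n)
    if (stats::cor(a, B[idx, idx][lt], method = method) >=
        rho_obs - 1e-12) count <- count + 1L
  }
  structure(list(rho = rho_obs, p = (1 + count) / (1 + n_perm),
                 n_perm = as.integer(n_perm), method = method),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("RELATE (%s): rho = %.3f, p = %.4g (%d permutations)\n",
              x$method, x$rho, x$p, x$n_perm))
  invisible(x)
}
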