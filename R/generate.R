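#' Standard primer pairs for community fingerprinting
#'
#' The 5'-labelled primer pairs commonly used for T-RFLP of marine
#' prokaryotes: the universal bacterial pair 27F/1492R and the
#' archaea-specific pair 21F/958R.  Forward primers carry the FAM label,
#' reverse primers the JOE label; labels matter only for channel naming.
#'
#' @return Named list with elements `bacteria` and `archaea`, each a list
#'   with `fwd` and `rev` primer sequences (IUPAC, 5'->3').
#' @export
primer_sets <- function() {
  list(
    bacteria = list(fwd = "AGAGTTTGATCMTGGCTCAG", rev = "GGTTACCTTGTTACGACTT"),
    archaea  = list(fwd = "TTCCGGTTGATCCYGCCGGA", rev = "YCCGGCGTTGAMTCCAATT")
  )
}

# deterministic instantiation of degenerate IUPAC positions (first expansion)
instantiate_primer <- function(primer) {
  codes <- iupac_codes()
  chars <- strsplit(toupper(primer), "", fixed = TRUE)[[1]]
  bad <- !chars %in% names(codes)
  if (any(bad))
    stop("invalid IUPAC character in primer: ", chars[bad][1], call. = FALSE)
  paste0(vapply(chars, function(ch) substr(codes[[ch]], 1, 1), ""),
         collapse = "")
}

rnd_half_up <- function(x) floor(x + 0.5)

# logarithmic-series variates by inverse CDF (integer counts >= 1)
rlogarithmic <- function(n, p) {
  kmax <- 1L
  # extend support until the tail mass is negligible
  pmf <- function(k) -p^k / (k * log(1 - p))
  repeat {
    kmax <- kmax * 2L
    if (sum(pmf(seq_len(kmax))) > 1 - 1e-12 || kmax > 1e6) break
  }
  cdf <- cumsum(pmf(seq_len(kmax)))
  findInterval(stats::runif(n) * cdf[kmax], cdf) + 1L
}

#' Generate synthetic OTU reference sequences with controlled T-RF lengths
#'
#' Builds `n` primer-flanked amplicon sequences whose forward terminal
#' restriction fragment lengths (first enzyme site on the top strand plus
#' the cut offset) are distinct integers drawn without replacement from
#' `trf_range`, so every OTU is resolvable by its T-RF.  Any spurious
#' enzyme site upstream of the intended one is removed by point mutation.
#'
#' @param n Number of sequences.
#' @param length Amplicon length in bp.
#' @param trf_range Integer (min, max) of admissible forward T-RF lengths.
#' @param seed Optional integer seed.
#' @param fwd_primer,rev_primer Primer pair (IUPAC); the sequence begins
#'   with the instantiated forward primer and ends with the reverse
#'   complement of the instantiated reverse primer.
#' @param site Restriction recognition site (default HhaI, GCGC).
#' @param cut_offset Cut position within the site (default 3: GCG^C).
#' @return Named character vector of uppercase DNA sequences with an
#'   integer attribute `trf_length` giving each sequence's forward T-RF.
#' @export
#' @examples
#' s <- generate_otu_sequences(3, 200, c(40, 150), seed = 1)
#' attr(s, "trf_length")
generate_otu_sequences <- function(n, length = 1000L, trf_range = c(34L, 966L),
                                   seed = NULL,
                                   fwd_primer = primer_sets()$bacteria$fwd,
                                   rev_primer = primer_sets()$bacteria$rev,
                                   site = "GCGC", cut_offset = 3L) {
  if (!is.null(seed)) set.seed(seed)
  fwd <- instantiate_primer(fwd_primer)
  rev_rc <- revcomp(instantiate_primer(rev_primer))
  if (grepl(site, fwd, fixed = TRUE) || grepl(site, rev_rc, fixed = TRUE))
    stop("primer region contains the restriction site; T-RF lengths ",
         "cannot be controlled", call. = FALSE)
  if (trf_range[2] > length)
    stop("trf_range exceeds amplicon length", call. = FALSE)
  lo <- max(trf_range[1], nchar(fwd) + cut_offset)
  hi <- min(trf_range[2], length - nchar(rev_rc) - nchar(site) + cut_offset)
  if (lo > hi || n > hi - lo + 1)
    stop("requested ", n, " distinct T-RF lengths but only ",
         max(0, hi - lo + 1), " are achievable in [", trf_range[1], ", ",
         trf_range[2], "]", call. = FALSE)
  lens <- sample(seq.int(lo, hi), n)
  mid_len <- length - nchar(fwd) - nchar(rev_rc)
  if (mid_len < nchar(site))
    stop("amplicon too short for primers plus a restriction site",
         call. = FALSE)
  seqs <- character(n)
  for (i in seq_len(n)) {
    mid <- paste0(sample(c("A", "C", "G", "T"), mid_len, replace = TRUE),
                  collapse = "")
    s <- paste0(fwd, mid, rev_rc)
    placed <- lens[i] - cut_offset + 1L  # 1-based start of intended site
    substr(s, placed, placed + nchar(site) - 1L) <- site
    # break any site occurrence upstream of the intended one
    repeat {
      pos <- regexpr(site, s, fixed = TRUE)[1]
      if (pos == placed) break
      win <- pos:(pos + nchar(site) - 1L)
      ok <- win[win > nchar(fwd) & win < placed]
      substr(s, max(ok), max(ok)) <- "A"
    }
    seqs[i] <- s
  }
  names(seqs) <- sprintf("otu_%0*d", max(3L, nchar(n)), seq_len(n))
  attr(seqs, "trf_length") <- stats::setNames(lens, names(seqs))
  seqs
}

# relative-abundance draw for S taxa under the configured abundance model
draw_abundances <- function(S, cfg) {
  x <- switch(cfg$abundance_model,
    lognormal = stats::rlnorm(S, meanlog = 0, sdlog = cfg$abundance_sigma),
    logseries = as.numeric(rlogarithmic(S, cfg$logseries_p))
  )
  x / sum(x)
}

#' Generate a synthetic water-mass transect scenario
#'
#' Creates the full ground truth the downstream analyses assume:
#' depth-stratified communities drawn from an OTU pool with configured
#' ubiquitous/unique sharing across water-mass groups, station metadata
#' drawn inside the water-mass environmental envelopes, and a gradual
#' along-path turnover of the succession layer's community.
#'
#' Turnover mechanism: within each succession sub-layer the present OTUs
#' are split into a base set (always containing the ubiquitous OTUs) and a
#' replacement set with disjoint support.  The community at along-path
#' distance d is the mixture (1 - f) * base + f * replacement with
#' f = min(1, succession_rate * d), so for disjoint supports the expected
#' Bray-Curtis similarity to the reference station is
#' 100 * (1 - min(1, succession_rate * d)) and the expected distance-decay
#' slope equals -100 * succession_rate percent per km.  All other layers are
#' homogeneous along the path up to multiplicative peak-height noise.
#'
#' @param config A `scenario_config` object.
#' @param sequences Logical; also generate OTU reference sequences
#'   (default TRUE; set FALSE for abundance-only simulation studies).
#' @return An object of class `transect_scenario`: a list with
#'   `otu_sequences` (or NULL), `abundance` (station x layer x OTU array of
#'   relative abundances, each station-layer slice summing to 1),
#'   `metadata` (one row per sample with layout and environmental
#'   variables), `otu_info` (role and group membership per OTU), and
#'   `config` (the ground truth used).
#' @export
#' @examples
#' sc <- generate_scenario(scenario_config(otu_pool_size = 30, seed = 7),
#'                         sequences = FALSE)
#' dim(sc$abundance)
generate_scenario <- function(config, sequences = TRUE) {
  cfg <- validate_scenario_config(config)
  env <- water_mass_envelopes()
  env <- env[match(cfg$layers, env$layer), ]
  groups <- unique(env$group)
  P <- cfg$otu_pool_size
  nG <- length(groups)

  ## --- OTU pool roles and group membership -------------------------------
  set.seed(derive_seed(cfg$seed, "otus"))
  n_ubiq <- rnd_half_up(cfg$frac_ubiquitous * P)
  n_uniq <- rnd_half_up(cfg$frac_unique * P)
  if (n_ubiq + n_uniq > P) n_uniq <- P - n_ubiq
  n_shared <- P - n_ubiq - n_uniq
  role <- sample(rep(c("ubiquitous", "unique", "shared"),
                     times = c(n_ubiq, n_uniq, n_shared)))
  membership <- matrix(FALSE, P, nG, dimnames = list(NULL, groups))
  membership[role == "ubiquitous", ] <- TRUE
  uniq_idx <- which(role == "unique")
  if (length(uniq_idx) > 0) {
    tgt <- rep(sample(groups), length.out = length(uniq_idx))
    for (k in seq_along(uniq_idx)) membership[uniq_idx[k], tgt[k]] <- TRUE
  }
  for (i in which(role == "shared")) {
    k <- if (nG >= 3) sample(2:(nG - 1), 1) else 1L
    membership[i, sample.int(nG, k)] <- TRUE
  }
  # every group must harbour at least one OTU
  for (g in which(colSums(membership) == 0)) {
    don <- which(role == "shared")[1]
    if (is.na(don)) don <- which(role == "ubiquitous")[1]
    membership[don, g] <- TRUE
  }
  otu_ids <- sprintf("otu_%0*d", max(3L, nchar(P)), seq_len(P))
  otu_info <- data.frame(
    otu_id = otu_ids, role = role,
    groups = apply(membership, 1, function(m) paste(groups[m], collapse = ";")),
    stringsAsFactors = FALSE
  )

  ## --- stations and layout ----------------------------------------------
  n_t <- cfg$n_stations_transect
  n_o <- cfg$n_stations_offpath
  spacing <- cfg$transect_length_km / (n_t - 1)
  dists <- c(seq(0, cfg$transect_length_km, length.out = n_t),
             cfg$transect_length_km + spacing * seq_len(n_o))
  n_st <- n_t + n_o
  stations <- sprintf("St%0*d", max(2L, nchar(n_st)), seq_len(n_st))
  region <- rep(c("transect", "offpath"), times = c(n_t, n_o))

  ## --- layer base (and replacement) communities --------------------------
  set.seed(derive_seed(cfg$seed, "communities"))
  nL <- length(cfg$layers)
  base <- matrix(0, nL, P, dimnames = list(cfg$layers, otu_ids))
  repl <- matrix(0, nL, P, dimnames = list(cfg$layers, otu_ids))
  is_succ <- env$water_mass == cfg$succession_layer
  for (l in seq_len(nL)) {
    present <- which(membership[, env$group[l]])
    if (is_succ[l] && cfg$succession_rate > 0) {
      forced <- intersect(present, which(role == "ubiquitous"))
      free <- setdiff(present, forced)
      if (length(free) < 2) {
        warning("layer ", cfg$layers[l], ": too few OTUs for a disjoint ",
                "replacement pool; turnover disabled there")
        base[l, present] <- draw_abundances(length(present), cfg)
        next
      }
      free <- sample(free)
      half <- floor(length(free) / 2)
      base_set <- c(forced, free[seq_len(length(free) - half)])
      repl_set <- free[seq.int(length(free) - half + 1, length(free))]
      base[l, base_set] <- draw_abundances(length(base_set), cfg)
      repl[l, repl_set] <- draw_abundances(length(repl_set), cfg)
    } else {
      base[l, present] <- draw_abundances(length(present), cfg)
    }
  }

  ## --- abundance tensor ---------------------------------------------------
  A <- array(0, dim = c(n_st, nL, P),
             dimnames = list(stations, cfg$layers, otu_ids))
  for (s in seq_len(n_st)) {
    f <- min(1, cfg$succession_rate * dists[s])
    for (l in seq_len(nL)) {
      A[s, l, ] <- if (is_succ[l] && cfg$succession_rate > 0 &&
                       any(repl[l, ] > 0))
        (1 - f) * base[l, ] + f * repl[l, ] else base[l, ]
    }
  }
  if (cfg$noise_cv > 0) {
    set.seed(derive_seed(cfg$seed, "noise"))
    s2 <- log(1 + cfg$noise_cv^2)
    for (s in seq_len(n_st)) for (l in seq_len(nL)) {
      v <- A[s, l, ]
      pos <- v > 0
      v[pos] <- v[pos] * stats::rlnorm(sum(pos), -s2 / 2, sqrt(s2))
      A[s, l, ] <- v / sum(v)
    }
  }

  ## --- metadata -----------------------------------------------------------
  set.seed(derive_seed(cfg$seed, "metadata"))
  md <- expand.grid(layer = cfg$layers, station = stations,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  md <- md[, c("station", "layer")]
  li <- match(md$layer, env$layer)
  md$sample_id <- paste(md$station, md$layer, sep = "_")
  md$water_mass <- env$water_mass[li]
  md$group <- env$group[li]
  md$region <- region[match(md$station, stations)]
  md$along_path_km <- dists[match(md$station, stations)]
  md$depth <- stats::runif(nrow(md), env$depth_min[li], env$depth_max[li])
  for (v in env_variables())
    md[[v]] <- stats::runif(nrow(md), env[[paste0(v, "_min")]][li],
                            env[[paste0(v, "_max")]][li])
  # optional biological variables: plausible depth attenuation, lognormal scatter
  md$prokaryotic_abundance <- 6e5 * exp(-md$depth / 1200) *
    stats::rlnorm(nrow(md), 0, 0.3) + 5e3
  md$leucine_incorporation <- 2 * exp(-md$depth / 800) *
    stats::rlnorm(nrow(md), 0, 0.4) + 0.005
  rownames(md) <- md$sample_id
  md <- md[, c("sample_id", setdiff(names(md), "sample_id"))]

  seqs <- NULL
  if (sequences)
    seqs <- generate_otu_sequences(P, cfg$amplicon_length, cfg$trf_range,
                                   seed = derive_seed(cfg$seed, "sequences"))

  structure(list(otu_sequences = seqs, abundance = A, metadata = md,
                 otu_info = otu_info, config = cfg),
            class = "transect_scenario")
}

#' @export
print.transect_scenario <- function(x, ...) {
  d <- dim(x$abundance)
  cat("Synthetic transect scenario: ", d[1], " stations x ", d[2],
      " layers x ", d[3], " OTUs\n", sep = "")
  cat("  succession in ", x$config$succession_layer, " at ",
      x$config$succession_rate, " per km\n", sep = "")
  invisible(x)
}

#' Flatten a scenario's abundance tensor to a sample-by-OTU matrix
#'
#' @param scenario A `transect_scenario`.
#' @return Numeric matrix with one row per sample (rownames matching
#'   `scenario$metadata$sample_id`) and one column per OTU; rows sum to 1.
#' @export
as_sample_matrix <- function(scenario) {
  stopifnot(inherits(scenario, "transect_scenario"))
  A <- scenario$abundance
  ids <- scenario$metadata$sample_id
  m <- matrix(0, length(ids), dim(A)[3],
              dimnames = list(ids, dimnames(A)[[3]]))
  for (i in seq_along(ids)) {
    st <- scenario$metadata$station[i]
    ly <- scenario$metadata$layer[i]
    m[i, ] <- A[st, ly, ]
  }
  m
}

#' Draw a clone library from a community abundance vector
#'
#' Multinomial sampling of sequenced clones from a community's relative
#' abundances, as when a 16S clone library is constructed from one sample.
#'
#' @param abundance Non-negative relative abundances summing to 1.
#' @param n_clones Number of clones to draw (>= 1).
#' @param seed Optional integer seed.
#' @return Named integer vector of per-OTU clone counts summing to
#'   `n_clones`.
#' @export
#' @examples
#' sample_clone_library(c(a = 0.5, b = 0.5), 10, seed = 1)
sample_clone_library <- function(abundance, n_clones, seed = NULL) {
  if (any(abundance < 0) || abs(sum(abundance) - 1) > 1e-8)
    stop("abundances must be non-negative and sum to 1", call. = FALSE)
  if (length(n_clones) != 1 || n_clones < 1 || n_clones != round(n_clones))
    stop("n_clones must be a positive integer", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  counts <- stats::rmultinom(1, n_clones, abundance)[, 1]
  names(counts) <- names(abundance)
  counts
}

#' Write a scenario's artefacts to disk
#'
#' Writes the OTU reference sequences (FASTA), the abundance table in long
#' format (`station,layer,otu_id,rel_abundance`), the sample metadata, and
#' the generating configuration (JSON).
#'
#' @param scenario A `transect_scenario`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_scenario <- function(scenario, dir) {
  stopifnot(inherits(scenario, "transect_scenario"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(fasta = file.path(dir, "otu_sequences.fasta"),
             abundance = file.path(dir, "abundance.csv"),
             metadata = file.path(dir, "metadata.csv"),
             config = file.path(dir, "scenario_config.json"))
  if (!is.null(scenario$otu_sequences))
    write_fasta(scenario$otu_sequences, paths["fasta"])
  A <- scenario$abundance
  long <- expand.grid(station = dimnames(A)[[1]], layer = dimnames(A)[[2]],
                      otu_id = dimnames(A)[[3]],
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  long$rel_abundance <- as.vector(A)
  long <- long[long$rel_abundance > 0, ]
  utils::write.csv(format_num_df(long), paths["abundance"],
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(format_num_df(scenario$metadata), paths["metadata"],
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(unclass(scenario$config), paths["config"],
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
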