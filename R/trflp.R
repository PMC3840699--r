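# IUPAC nucleotide codes and their expansions
iupac_codes <- function() {
  c(A = "A", C = "C", G = "G", T = "T",
    R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
    B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT")
}

iupac_complement <- function() {
  c(A = "T", C = "G", G = "C", T = "A",
    R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
    B = "V", D = "H", H = "D", V = "B", N = "N")
}

check_dna <- function(x, what = "sequence") {
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  bad <- !chars %in% names(iupac_codes())
  if (any(bad))
    stop("invalid IUPAC character '", chars[bad][1], "' in ", what,
         call. = FALSE)
  paste0(chars, collapse = "")
}

#' Reverse complement of an IUPAC DNA string
#' @param x DNA string (IUPAC codes allowed).
#' @return The reverse complement, uppercase.
#' @export
#' @examples
#' revcomp("GGATCC")
revcomp <- function(x) {
  comp <- iupac_complement()
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  paste0(rev(comp[chars]), collapse = "")
}

# regex from an IUPAC primer: degenerate codes become character classes
iupac_regex <- function(primer) {
  codes <- iupac_codes()
  chars <- strsplit(toupper(primer), "", fixed = TRUE)[[1]]
  paste0(vapply(chars, function(ch) {
    exp <- codes[[ch]]
    if (nchar(exp) == 1) exp else paste0("[", exp, "]")
  }, ""), collapse = "")
}

#' Extract the PCR product delimited by a primer pair
#'
#' Finds the first match of the forward primer on the top strand and the
#' first downstream match of the reverse complement of the reverse primer,
#' and returns the inclusive subsequence — the in-silico amplicon.
#' Degenerate IUPAC codes in the primers match their expansions exactly;
#' no mismatches are tolerated.
#'
#' @param template DNA template string (IUPAC).
#' @param fwd_primer,rev_primer Primer sequences, both written 5'->3' on
#'   their own strand (>= 4 bp).
#' @param multiple What to do when more than one product is possible:
#'   "first" (default) takes the first forward match and the first
#'   downstream reverse match; "error" aborts.
#' @param fwd_label,rev_label Dye names for the two labelled termini.
#' @return An object of class `amplicon`: list with `residues`, 0-based
#'   half-open coordinates `start`/`end` on the template, and the labels.
#' @export
#' @examples
#' amp <- find_amplicon("TTACGTAAAAGGATCCTT", "ACGT", "GGATCC")
#' amp$residues
find_amplicon <- function(template, fwd_primer, rev_primer,
                          multiple = c("first", "error"),
                          fwd_label = "FAM", rev_label = "JOE") {
  multiple <- match.arg(multiple)
  if (nchar(fwd_primer) < 4 || nchar(rev_primer) < 4)
    stop("primers must be at least 4 bp", call. = FALSE)
  template <- check_dna(template, "template")
  fwd_re <- iupac_regex(fwd_primer)
  rev_re <- iupac_regex(revcomp(rev_primer))
  fhits <- gregexpr(fwd_re, template, perl = TRUE)[[1]]
  if (fhits[1] == -1)
    stop("forward primer not found in template", call. = FALSE)
  fstart <- fhits[1]
  fend <- fstart + attr(fhits, "match.length")[1] - 1L
  rhits <- gregexpr(rev_re, template, perl = TRUE)[[1]]
  rlens <- attr(rhits, "match.length")
  down <- which(rhits > fend)
  if (length(down) == 0)
    stop("no reverse-primer site downstream of the forward primer",
         call. = FALSE)
  if (multiple == "error" && (length(fhits) > 1 || length(down) > 1))
    stop("multiple possible amplification products", call. = FALSE)
  rstart <- rhits[down[1]]
  rend <- rstart + rlens[down[1]] - 1L
  structure(list(residues = substr(template, fstart, rend),
                 start = fstart - 1L, end = rend,
                 fwd_label = fwd_label, rev_label = rev_label),
            class = "amplicon")
}

#' Predict the labelled terminal restriction fragment of an amplicon
#'
#' T-RFLP sizes only the fluorescently labelled terminal fragment: the
#' stretch from the labelled 5' end to the first restriction cut.  The
#' forward channel scans the top strand for the first site occurrence; the
#' reverse channel applies the same rule to the reverse-complement strand
#' (for a palindromic site such as HhaI's GCGC the sites coincide but the
#' two terminal lengths differ).  An amplicon without a site yields an
#' uncut pseudo-T-RF of the full amplicon length, flagged `cut = FALSE`.
#'
#' @param amplicon An `amplicon` object or a DNA string.
#' @param site Recognition sequence (default "GCGC", HhaI).
#' @param cut_offset Cut position within the site, 0..nchar(site)
#'   (default 3, i.e. GCG^C).
#' @param channel "forward" or "reverse".
#' @return Object of class `terminal_fragment`: list with `length` (bp),
#'   `channel`, and `cut` (FALSE for pseudo-T-RFs).
#' @export
#' @examples
#' terminal_fragment("AAAGCGCTTTT")$length           # 6
#' terminal_fragment("AAAGCGCTTTT", channel = "reverse")$length  # 7
terminal_fragment <- function(amplicon, site = "GCGC", cut_offset = 3L,
                              channel = c("forward", "reverse")) {
  channel <- match.arg(channel)
  seqs <- if (inherits(amplicon, "amplicon")) amplicon$residues
          else check_dna(amplicon, "amplicon")
  if (nchar(site) < 1 || cut_offset < 0 || cut_offset > nchar(site))
    stop("invalid site/cut_offset", call. = FALSE)
  strand <- if (channel == "forward") seqs else revcomp(seqs)
  pos <- regexpr(site, strand, fixed = TRUE)[1]
  if (pos == -1)
    return(structure(list(length = nchar(seqs), channel = channel,
                          cut = FALSE), class = "terminal_fragment"))
  structure(list(length = (pos - 1L) + cut_offset, channel = channel,
                 cut = TRUE), class = "terminal_fragment")
}

#' In-silico digestion of a set of OTU sequences
#'
#' Runs primer matching and terminal-fragment prediction over a named set
#' of template sequences, for both dye channels.
#'
#' @param sequences Named character vector of DNA templates.
#' @param fwd_primer,rev_primer Primer pair (default bacterial 27F/1492R).
#' @param site,cut_offset Restriction enzyme (default HhaI GCG^C).
#' @param multiple Passed to [find_amplicon()].
#' @return data.frame with columns `otu_id`, `channel`, `length`, `cut`,
#'   `amplicon_length`.
#' @export
digest_otus <- function(sequences,
                        fwd_primer = primer_sets()$bacteria$fwd,
                        rev_primer = primer_sets()$bacteria$rev,
                        site = "GCGC", cut_offset = 3L,
                        multiple = "first") {
  if (is.null(names(sequences)))
    names(sequences) <- sprintf("seq_%03d", seq_along(sequences))
  rows <- lapply(names(sequences), function(id) {
    amp <- find_amplicon(sequences[[id]], fwd_primer, rev_primer,
                         multiple = multiple)
    do.call(rbind, lapply(c("forward", "reverse"), function(ch) {
      tf <- terminal_fragment(amp, site, cut_offset, ch)
      data.frame(otu_id = id, channel = ch, length = tf$length,
                 cut = tf$cut, amplicon_length = nchar(amp$residues),
                 stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}

#' Build a sample's electropherogram peak profile from a community
#'
#' Maps relative OTU abundances to fluorescence peak heights: OTUs whose
#' terminal fragments share a length co-migrate into a single peak whose
#' height is `scale` times their summed abundance, optionally perturbed by
#' multiplicative lognormal noise with coefficient of variation `noise_cv`
#' (unit mean).
#'
#' @param community Named numeric vector of relative abundances summing
#'   to 1.
#' @param fragments Named integer vector of T-RF lengths (bp) covering the
#'   community's OTUs, or a data.frame as returned by [digest_otus()]
#'   (its rows for the requested channel are used).
#' @param scale Height of a peak carrying the whole community (> 0).
#' @param noise_cv Coefficient of variation of peak-height noise.
#' @param seed Optional integer seed.
#' @param sample_id,channel Identifiers stored in the profile.
#' @return Object of class `peak_profile`: list with `sample_id`,
#'   `channel`, and `peaks` (data.frame `size_bp`, `height`, sizes strictly
#'   increasing).
#' @export
profile_sample <- function(community, fragments, scale = 10000,
                           noise_cv = 0, seed = NULL,
                           sample_id = "sample", channel = "forward") {
  if (any(community < 0) || abs(sum(community) - 1) > 1e-8)
    stop("community abundances must be non-negative and sum to 1",
         call. = FALSE)
  if (scale < 0) stop("scale must be non-negative", call. = FALSE)
  if (is.data.frame(fragments)) {
    fragments <- fragments[fragments$channel == channel, ]
    fragments <- stats::setNames(fragments$length, fragments$otu_id)
  }
  ids <- names(community)[community > 0]
  miss <- setdiff(ids, names(fragments))
  if (length(miss) > 0)
    stop("no fragment length for OTU(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  h <- tapply(community[ids], fragments[ids], sum)
  sizes <- as.numeric(names(h))
  o <- order(sizes)
  sizes <- sizes[o]
  heights <- as.numeric(h)[o] * scale
  if (noise_cv > 0) {
    if (!is.null(seed)) set.seed(seed)
    s2 <- log(1 + noise_cv^2)
    heights <- heights * stats::rlnorm(length(heights), -s2 / 2, sqrt(s2))
  }
  structure(list(sample_id = sample_id, channel = channel,
                 peaks = data.frame(size_bp = sizes, height = heights)),
            class = "peak_profile")
}

#' Bin peak profiles into a standardized fingerprint matrix
#'
#' Discards peaks outside the size window, assigns the rest to fixed
#' half-open bins `[size_min + k*w, size_min + (k+1)*w)` (a peak exactly at
#' `size_max` falls in the last bin), converts heights to fractions of each
#' sample's retained total, zeroes fractions below `rel_threshold` and
#' renormalizes, then drops bins that are zero in every sample.
#'
#' @param profiles A `peak_profile` or list of them.
#' @param bin_width Bin width in bp (>= 1, default 1).
#' @param size_min,size_max Retained size window in bp (defaults 34 and
#'   966, the span of observed bacterial T-RFs).
#' @param rel_threshold Per-sample relative-height threshold below which a
#'   bin is zeroed (default 0).
#' @return A numeric matrix (class `fingerprint_matrix`) of samples x bins
#'   with bin centers as column names and attributes `bin_lower` and
#'   `bin_width`; each row sums to 1 or is all zero.
#' @export
bin_and_standardize <- function(profiles, bin_width = 1, size_min = 34,
                                size_max = 966, rel_threshold = 0) {
  if (inherits(profiles, "peak_profile")) profiles <- list(profiles)
  if (size_min >= size_max) stop("size_min must be < size_max", call. = FALSE)
  if (bin_width < 1) stop("bin_width must be >= 1", call. = FALSE)
  n_bins <- floor((size_max - size_min) / bin_width) + 1L
  lower <- size_min + bin_width * (seq_len(n_bins) - 1L)
  ids <- vapply(profiles, function(p) p$sample_id, "")
  m <- matrix(0, length(profiles), n_bins,
              dimnames = list(ids, format(lower + bin_width / 2)))
  for (i in seq_along(profiles)) {
    pk <- profiles[[i]]$peaks
    keep <- pk$size_bp >= size_min & pk$size_bp <= size_max
    pk <- pk[keep, , drop = FALSE]
    if (nrow(pk) == 0) next
    b <- pmin(floor((pk$size_bp - size_min) / bin_width) + 1L, n_bins)
    for (j in seq_len(nrow(pk))) m[i, b[j]] <- m[i, b[j]] + pk$height[j]
    tot <- sum(m[i, ])
    if (tot > 0) m[i, ] <- m[i, ] / tot
    if (rel_threshold > 0) {
      m[i, m[i, ] < rel_threshold] <- 0
      tot <- sum(m[i, ])
      if (tot > 0) m[i, ] <- m[i, ] / tot
    }
  }
  if (all(m == 0)) {
    warning("all peaks fell outside the size window; matrix is all-zero")
    keep_bins <- rep(TRUE, n_bins)
  } else {
    keep_bins <- colSums(m) > 0
  }
  m <- m[, keep_bins, drop = FALSE]
  structure(m, bin_lower = lower[keep_bins], bin_width = bin_width,
            class = c("fingerprint_matrix", "matrix"))
}

#' Fingerprint a whole synthetic scenario
#'
#' Convenience chain: digest the scenario's OTU sequences, build one peak
#' profile per sample from the (already noisy) abundance tensor, and bin
#' into the standardized fingerprint matrix.
#'
#' @param scenario A `transect_scenario` with sequences.
#' @param channel Dye channel analysed (default "forward", the FAM-labelled
#'   terminus).
#' @param bin_width,size_min,size_max,rel_threshold Passed to
#'   [bin_and_standardize()].
#' @param scale Peak-height scale.
#' @return A `fingerprint_matrix` with one row per scenario sample.
#' @export
scenario_fingerprint <- function(scenario, channel = "forward",
                                 bin_width = 1, size_min = 34,
                                 size_max = 966, rel_threshold = 0,
                                 scale = 10000) {
  stopifnot(inherits(scenario, "transect_scenario"))
  if (is.null(scenario$otu_sequences))
    stop("scenario was generated without sequences", call. = FALSE)
  trf <- digest_otus(scenario$otu_sequences)
  m <- as_sample_matrix(scenario)
  profiles <- lapply(rownames(m), function(id)
    profile_sample(m[id, ], trf, scale = scale, noise_cv = 0,
                   sample_id = id, channel = channel))
  bin_and_standardize(profiles, bin_width, size_min, size_max, rel_threshold)
}
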