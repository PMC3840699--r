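# format numeric columns to 12 significant digits for stable round-trips
format_num_df <- function(df) {
  for (v in names(df)) {
    if (is.numeric(df[[v]]) && !is.integer(df[[v]]))
      df[[v]] <- trimws(formatC(df[[v]], digits = 12, format = "g"))
  }
  df
}

#' Read a FASTA file of DNA sequences
#'
#' Wraps `Biostrings::readDNAStringSet`, preserving record order and ids,
#' uppercasing residues and validating the IUPAC alphabet.  Malformed
#' records are reported with the offending line number.
#'
#' @param path FASTA file.
#' @return Named character vector of uppercase sequences (possibly empty,
#'   with a warning).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  # validation pass with line numbers (Biostrings silently drops bad codes)
  lines <- readLines(path, warn = FALSE)
  in_seq <- FALSE
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (startsWith(ln, ">")) { in_seq <- TRUE; next }
    if (nzchar(trimws(ln))) {
      if (!in_seq)
        stop("malformed FASTA: sequence data before any header at line ",
             i, call. = FALSE)
      ch <- strsplit(toupper(ln), "", fixed = TRUE)[[1]]
      bad <- !ch %in% c(names(iupac_codes()), "-", ".")
      if (any(bad))
        stop("invalid residue '", ch[bad][1], "' at line ", i,
             call. = FALSE)
    }
  }
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0) {
    warning("empty FASTA file: ", path)
    return(stats::setNames(character(0), character(0)))
  }
  seqs <- toupper(as.character(set))
  # ids: first whitespace-delimited token, as sequence tools conventionally use
  names(seqs) <- sub("\\s.*$", "", names(set))
  seqs
}

#' Write named DNA sequences as FASTA
#' @param sequences Named character vector.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(sequences, path) {
  set <- Biostrings::DNAStringSet(unlist(sequences))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a peak table CSV into peak profiles
#'
#' Expected header: `sample,channel,size_bp,height`.
#'
#' @param path CSV file.
#' @return List of `peak_profile` objects, one per sample x channel, with
#'   sizes sorted increasing.
#' @export
read_peak_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample", "channel", "size_bp", "height")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("peak table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!is.numeric(df$size_bp) || !is.numeric(df$height))
    stop("size_bp and height must be numeric", call. = FALSE)
  if (any(!is.finite(df$size_bp)) || any(!is.finite(df$height)))
    stop("non-finite sizes or heights", call. = FALSE)
  if (any(df$height < 0))
    stop("negative peak height", call. = FALSE)
  keys <- unique(df[, c("sample", "channel")])
  lapply(seq_len(nrow(keys)), function(i) {
    sub <- df[df$sample == keys$sample[i] & df$channel == keys$channel[i], ]
    sub <- sub[order(sub$size_bp), ]
    structure(list(sample_id = keys$sample[i], channel = keys$channel[i],
                   peaks = data.frame(size_bp = sub$size_bp,
                                      height = sub$height)),
              class = "peak_profile")
  })
}

#' Write peak profiles as a peak table CSV
#' @param profiles A `peak_profile` or list of them.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_peak_table <- function(profiles, path) {
  if (inherits(profiles, "peak_profile")) profiles <- list(profiles)
  rows <- do.call(rbind, lapply(profiles, function(p)
    data.frame(sample = p$sample_id, channel = p$channel,
               size_bp = p$peaks$size_bp, height = p$peaks$height,
               stringsAsFactors = FALSE)))
  utils::write.csv(format_num_df(rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Write / read a fingerprint matrix as CSV
#'
#' Samples as rows, bin centers as column headers, first column `sample`.
#'
#' @param m A `fingerprint_matrix` (or plain matrix).
#' @param path CSV file.
#' @return `write_fingerprint` returns `path` invisibly; `read_fingerprint`
#'   a `fingerprint_matrix`.
#' @export
write_fingerprint <- function(m, path) {
  df <- data.frame(sample = rownames(m), as.matrix(m),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(format_num_df(df), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_fingerprint
#' @export
read_fingerprint <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "sample")
    stop("fingerprint CSV must start with a 'sample' column", call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric fingerprint values", call. = FALSE)
  rownames(m) <- df$sample
  structure(m, class = c("fingerprint_matrix", "matrix"))
}

#' Write / read a resemblance matrix as square CSV
#'
#' Square layout with sample ids as both header row and first column.
#' Reading checks symmetry to 1e-9 and infers the kind from the diagonal
#' (100 = similarity-percent, 0 = distance).
#'
#' @param r A `resemblance` object.
#' @param path CSV file.
#' @param metric Metric tag recorded on read.
#' @return `write_resemblance` returns `path` invisibly;
#'   `read_resemblance` a `resemblance` object.
#' @export
write_resemblance <- function(r, path) {
  stopifnot(inherits(r, "resemblance"))
  df <- data.frame(sample = rownames(r$values), r$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(format_num_df(df), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_resemblance
#' @export
read_resemblance <- function(path, metric = "unknown") {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!identical(colnames(m), as.character(ids)))
    stop("resemblance CSV row and column ids differ", call. = FALSE)
  rownames(m) <- ids
  if (max(abs(m - t(m))) > 1e-9)
    stop("asymmetric resemblance matrix (tolerance 1e-9)", call. = FALSE)
  kind <- if (all(abs(diag(m) - 100) < 1e-9)) "similarity-percent"
          else if (all(abs(diag(m)) < 1e-9)) "distance"
          else stop("diagonal is neither 100 (similarity) nor 0 (distance)",
                    call. = FALSE)
  new_resemblance(m, kind, metric)
}
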