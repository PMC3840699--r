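test_that("find_amplicon extracts the primer-delimited product", {
  amp <- find_amplicon("TTACGTAAAAGGATCCTT", "ACGT", "GGATCC")
  expect_equal(amp$residues, "ACGTAAAAGGATCC")
  expect_equal(nchar(amp$residues), 14)
  expect_equal(amp$start, 2)  # 0-based

  expect_error(find_amplicon("TTTTTTTT", "ACGT", "GGATCC"),
               "forward primer not found")
  expect_error(find_amplicon("ACGTAAAA", "ACGT", "GGATCC"),
               "no reverse-primer site")

  # template exactly fwd + revcomp(rev) is its own amplicon
  tmpl <- paste0("ACGTACGT", revcomp("TTGGCCAA"))
  amp2 <- find_amplicon(tmpl, "ACGTACGT", "TTGGCCAA")
  expect_equal(amp2$residues, tmpl)

  # degenerate primer positions match their expansions
  amp3 <- find_amplicon("TTACGTAAAAGGATCCTT", "ACGW", "GGATCC")
  expect_equal(amp3$residues, "ACGTAAAAGGATCC")

  expect_error(find_amplicon("ACGTACGTAAAAGGATCCAAGGATCCTT",
                             "ACGT", "GGATCC", multiple = "error"),
               "multiple")
})

test_that("terminal fragments follow the first-site rule on each strand", {
  # first GCGC at 0-based index 3; 3 + cut_offset 3 = 6
  expect_equal(terminal_fragment("AAAGCGCTTTT")$length, 6)
  # revcomp is AAAAGCGCTTT: site at index 4; 4 + 3 = 7
  rv <- terminal_fragment("AAAGCGCTTTT", channel = "reverse")
  expect_equal(rv$length, 7)
  expect_true(rv$cut)

  un <- terminal_fragment("AAATTTCCC")
  expect_false(un$cut)
  expect_equal(un$length, 9)
})

test_that("digestion agrees with a brute-force site scanner", {
  set.seed(42)
  for (k in 1:300) {
    s <- random_dna(sample(20:200, 1))
    pos <- oracle_first_site(s, "GCGC")
    tf <- terminal_fragment(s)
    if (pos == 0) {
      expect_false(tf$cut)
      expect_equal(tf$length, nchar(s))
    } else {
      expect_equal(tf$length, (pos - 1) + 3)
    }
    rc <- revcomp(s)
    posr <- oracle_first_site(rc, "GCGC")
    tr <- terminal_fragment(s, channel = "reverse")
    expect_equal(tr$length, if (posr == 0) nchar(s) else (posr - 1) + 3)
  }
})

test_that("forward + reverse T-RFs overlap the single palindromic site", {
  set.seed(7)
  found <- 0
  while (found < 50) {
    s <- random_dna(80)
    # count occurrences allowing overlaps (gregexpr misses e.g. GCGCGC)
    hits <- sum(vapply(seq_len(nchar(s) - 3), function(i)
      substr(s, i, i + 3) == "GCGC", TRUE))
    if (hits != 1) next
    found <- found + 1
    fl <- terminal_fragment(s)$length
    rl <- terminal_fragment(s, channel = "reverse")$length
    # with one palindromic GCGC at 0-based pos s: fl = s + 3 and
    # rl = len - s - 1, so the fragments overlap by exactly 2 bp
    expect_equal(fl + rl, nchar(s) + 2)
    expect_gte(fl + rl, nchar(s))
  }
})

test_that("digestion is position-consistent under prefix extension", {
  set.seed(8)
  for (k in 1:50) {
    s <- random_dna(100)
    if (oracle_first_site(s, "GCGC") == 0) next
    prefix <- gsub("G", "A", random_dna(sample(1:20, 1)))  # site-free
    s2 <- paste0(prefix, s)
    # prefix has no G so it cannot create or contain a GCGC overlapping s
    expect_equal(terminal_fragment(s2)$length,
                 terminal_fragment(s)$length + nchar(prefix))
  }
})

test_that("peak profiles map abundance to height with co-migration", {
  p1 <- profile_sample(c(a = 1), c(a = 100), scale = 5000)
  expect_equal(p1$peaks$height, 5000)
  expect_equal(p1$peaks$size_bp, 100)

  # co-migration: shared T-RF lengths sum into one peak
  p2 <- profile_sample(c(a = 0.3, b = 0.7), c(a = 120, b = 120),
                       scale = 1000)
  expect_equal(nrow(p2$peaks), 1)
  expect_equal(p2$peaks$height, 1000)

  p3 <- profile_sample(c(a = 0.3, b = 0.7), c(a = 120, b = 240),
                       scale = 1000)
  expect_equal(p3$peaks$height, c(300, 700))
  expect_true(all(diff(p3$peaks$size_bp) > 0))

  expect_error(profile_sample(c(a = 0.4, b = 0.4), c(a = 1, b = 2)),
               "sum to 1")
  expect_error(profile_sample(c(a = 1), c(a = 10), scale = -1),
               "scale")
})

test_that("binning and standardization follow the half-open convention", {
  mk <- function(id, sizes, heights)
    structure(list(sample_id = id, channel = "forward",
                   peaks = data.frame(size_bp = sizes, height = heights)),
              class = "peak_profile")
  # two peaks in the same 1-bp bin merge
  fp <- bin_and_standardize(mk("s1", c(100.4, 100.6), c(10, 30)),
                            size_min = 34, size_max = 966)
  expect_equal(ncol(fp), 1)
  expect_equal(unname(fp[1, 1]), 1)

  # direct normalization
  fp2 <- bin_and_standardize(mk("s1", c(100, 200), c(20, 80)),
                             size_min = 34, size_max = 966)
  expect_equal(unname(fp2[1, ]), c(0.2, 0.8))

  # peaks outside the window are discarded
  fp3 <- bin_and_standardize(list(mk("s1", c(20, 100), c(50, 50))),
                             size_min = 34, size_max = 966)
  expect_equal(ncol(fp3), 1)
  expect_equal(unname(fp3[1, 1]), 1)

  expect_warning(bin_and_standardize(mk("s1", 20, 10), size_min = 34,
                                     size_max = 966), "all-zero")

  # relative threshold zeroes, renormalizes, and the emptied bin is dropped
  fp4 <- bin_and_standardize(mk("s1", c(100, 200, 300), c(2, 49, 49)),
                             size_min = 34, size_max = 966,
                             rel_threshold = 0.05)
  expect_equal(unname(fp4[1, ]), c(0.5, 0.5))
})

test_that("noise-free fingerprints recover the community exactly", {
  sc <- generate_scenario(small_config(seed = 9, noise_cv = 0))
  fp <- scenario_fingerprint(sc)
  m <- as_sample_matrix(sc)
  trf <- attr(sc$otu_sequences, "trf_length")
  expect_true(all(abs(rowSums(fp) - 1) < 1e-12))
  # distinct integer T-RFs with 1-bp bins: fingerprint row == abundance row
  for (id in rownames(m)[c(1, 50, 100)]) {
    got <- fp[id, ][order(as.numeric(colnames(fp)))]
    want <- m[id, order(trf)]
    nz <- want > 0
    expect_equal(unname(got[got > 0]), unname(want[nz]), tolerance = 1e-12)
  }
})
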