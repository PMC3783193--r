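# Independent oracles and small generators used across the suite. These are
# deliberately written with different machinery than the package internals
# (seqinr for translation/complement, literal mass tables, naive string
# scans) so that agreement is evidence, not tautology.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# reverse complement via seqinr (oracle for the package's chartr version)
oracle_revcomp <- function(s) {
  toupper(paste(rev(seqinr::comp(strsplit(s, "")[[1]], forceToLower = FALSE)),
                collapse = ""))
}

# naive scan for all occurrences of `pat`, doubling manually for circles
oracle_find <- function(s, pat, circular = FALSE) {
  L <- nchar(s)
  subject <- if (circular) paste0(s, substr(s, 1, nchar(pat) - 1)) else s
  hits <- integer(0)
  for (i in seq_len(nchar(subject) - nchar(pat) + 1)) {
    if (substr(subject, i, i + nchar(pat) - 1) == pat) hits <- c(hits, i)
  }
  hits[hits <= L]
}

# literal monoisotopic residue masses (standard reference table, Da) --
# independent of the package's elemental-composition route
oracle_residue_mass <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)

oracle_peptide_mass <- function(seq) {
  sum(oracle_residue_mass[strsplit(seq, "")[[1]]]) + 18.01056
}

# brute-force six-frame ORF enumeration using seqinr translation
oracle_orfs <- function(s, min_aa, require_atg = TRUE) {
  L <- nchar(s)
  out <- list()
  for (strand in c("+", "-")) {
    t <- if (strand == "+") s else oracle_revcomp(s)
    for (off in 0:2) {
      n_codons <- (L - off) %/% 3
      if (n_codons < 1) next
      aa <- paste(seqinr::translate(strsplit(substr(t, off + 1, off + 3 * n_codons),
                                             "")[[1]]), collapse = "")
      chars <- strsplit(aa, "")[[1]]
      stops <- which(chars == "*")
      seg_from <- c(1, stops + 1)
      seg_to <- c(stops - 1, length(chars))
      for (i in seq_along(seg_from)) {
        a <- seg_from[i]; b <- seg_to[i]
        if (a > b || i > length(stops)) next    # partials excluded
        if (require_atg) {
          ms <- which(chars[a:b] == "M")
          if (!length(ms)) next
          a <- a + ms[1] - 1
        }
        if (b - a + 1 < min_aa) next
        nt_from <- off + (a - 1) * 3 + 1
        nt_to <- off + b * 3
        if (strand == "+") { start <- nt_from; end <- nt_to }
        else { start <- L - nt_to + 1; end <- L - nt_from + 1 }
        out[[length(out) + 1]] <- data.frame(
          frame = paste0(strand, off + 1), start = start, end = end,
          protein = paste(chars[a:b], collapse = ""), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(data.frame(frame = character(0), start = integer(0),
                                      end = integer(0), protein = character(0)))
  df <- do.call(rbind, out)
  df[order(df$frame, df$start), , drop = FALSE]
}

# analytic splice the design pipeline must reproduce after Cre excision:
# left flank + CDS-without-stop + pad + tag CDS + loxP + XhoI remnant +
# stop codon + right flank
oracle_post_cre <- function(locus, vec) {
  g <- locus$sequence$seq
  ss <- locus$stop_start
  tag <- substr(vec$sequence$seq,
                vec$features$start[vec$features$label == "tag_cds"],
                vec$features$end[vec$features$label == "tag_cds"])
  paste0(substr(g, 1, ss - 1), "AGCTTG", tag, loxp_site(), "CTCGA",
         substr(g, ss, nchar(g)))
}

# small design bundle reused by several tests (full defaults, fixed seed)
design_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- fixture_config(seed = 1)
      locus <- make_locus(cfg)
      vec <- make_vector(cfg)
      cache <<- list(cfg = cfg, locus = locus, vec = vec,
                     design = design_construct(locus, vec))
    }
    cache
  }
})
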