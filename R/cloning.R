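#' Restriction fragments
#'
#' A fragment is a linear duplex recorded by its top-strand projection: the
#' string spans from the top-strand cut of the upstream site to the
#' bottom-strand cut of the downstream site, so a cohesive 5' extension
#' appears once at each end of the string and adjacent fragments from the
#' same digest share (duplicate) the extension bases. `end5`/`end3` hold the
#' extension sequences (`""` = blunt). Compatibility for ligation is exact
#' string equality of the extensions.
#'
#' @param seq top-strand string including terminal extensions.
#' @param end5,end3 single-stranded extension at each end, `""` for blunt.
#' @return Object of class `dna_fragment`.
#' @export
dna_fragment <- function(seq, end5 = "", end3 = "") {
  seq <- toupper(seq)
  if (nchar(end5) > 0 && substr(seq, 1, nchar(end5)) != end5)
    tk_stop("end5 extension is not a prefix of the fragment sequence", "bad_fragment")
  if (nchar(end3) > 0 && substr(seq, nchar(seq) - nchar(end3) + 1, nchar(seq)) != end3)
    tk_stop("end3 extension is not a suffix of the fragment sequence", "bad_fragment")
  structure(list(seq = seq, end5 = toupper(end5), end3 = toupper(end3)),
            class = "dna_fragment")
}

#' @export
print.dna_fragment <- function(x, ...) {
  lab <- function(e) if (nchar(e) == 0) "blunt" else e
  cat(sprintf("<fragment> %d bp | 5':%s 3':%s\n", nchar(x$seq), lab(x$end5), lab(x$end3)))
  invisible(x)
}

#' Digest a molecule with one or more restriction enzymes
#'
#' Fragments are returned in sequence order. A linear molecule with n sites
#' yields n+1 fragments; a circular molecule yields n (and raises an "uncut"
#' error for n = 0). Because each cohesive extension is recorded at both
#' flanking fragments, fragment lengths sum to the input length plus one
#' extension copy per cut; concatenating cores (counting each extension once)
#' reconstructs the input.
#'
#' @param x a `dna_seq`.
#' @param enzymes one enzyme or a list/vector of enzymes (names or objects).
#' @return List of [dna_fragment()].
#' @export
digest <- function(x, enzymes) {
  if (!is_dna_seq(x)) tk_stop("`x` must be a dna_seq", "bad_sequence")
  if (inherits(enzymes, "restriction_enzyme") || is.character(enzymes) && length(enzymes) == 1L)
    enzymes <- list(enzymes)
  enzymes <- lapply(enzymes, get_enzyme)
  s <- x$seq
  L <- nchar(s)
  cuts <- data.frame(pos = integer(0), top = integer(0), bottom = integer(0))
  for (e in enzymes) {
    p <- find_sites(x, e)
    if (length(p))
      cuts <- rbind(cuts, data.frame(pos = p, top = p + e$cut_top, bottom = p + e$cut_bottom))
  }
  circular <- x$topology == "circular"
  if (nrow(cuts) == 0L) {
    if (circular) tk_stop(sprintf("'%s' has no site for the given enzyme(s): uncut", x$id), "uncut")
    return(list(dna_fragment(s)))
  }
  cuts <- cuts[order(cuts$pos), , drop = FALSE]
  # fragment between consecutive cuts i -> j spans top positions [top_i, bottom_j - 1]
  ext <- function(i) substr(paste0(s, s), cuts$top[i], cuts$bottom[i] - 1L)
  frags <- list()
  if (circular) {
    s3 <- paste0(s, s, s)  # cuts near the origin can push spans past 2L
    n <- nrow(cuts)
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      from <- cuts$top[i]
      to <- cuts$bottom[j] - 1L + if (i == n) L else 0L
      frags[[i]] <- dna_fragment(substr(s3, from, to), end5 = ext(i), end3 = ext(j))
    }
  } else {
    n <- nrow(cuts)
    frags[[1L]] <- dna_fragment(substr(s, 1L, cuts$bottom[1L] - 1L), end5 = "", end3 = ext(1L))
    if (n > 1L) for (i in seq_len(n - 1L)) {
      frags[[i + 1L]] <- dna_fragment(substr(s, cuts$top[i], cuts$bottom[i + 1L] - 1L),
                                      end5 = ext(i), end3 = ext(i + 1L))
    }
    frags[[n + 1L]] <- dna_fragment(substr(s, cuts$top[n], L), end5 = ext(n), end3 = "")
  }
  frags
}

#' Self-ligate a fragment into a circle
#'
#' Requires both ends blunt or both carrying identical cohesive extensions
#' (exact-sequence compatibility). For cohesive ends the circle is one
#' duplicated extension copy shorter than the fragment string.
#'
#' @param frag a [dna_fragment()].
#' @param id id for the resulting molecule.
#' @return Circular `dna_seq`.
#' @export
self_circularize <- function(frag, id = "circle") {
  if (!inherits(frag, "dna_fragment")) tk_stop("`frag` must be a dna_fragment", "bad_fragment")
  if (frag$end5 != frag$end3)
    tk_stop("incompatible ends: ligation failure", "ligation_failure")
  k <- nchar(frag$end3)
  s <- if (k > 0) substr(frag$seq, 1L, nchar(frag$seq) - k) else frag$seq
  if (nchar(s) == 0L) tk_stop("fragment too short to circularize", "ligation_failure")
  dna_seq(s, id = id, topology = "circular")
}

#' Simulate PCR amplification
#'
#' Perfect-match annealing only: each primer's annealing region must occur
#' exactly once in the template (counting both strands), otherwise a
#' "non-specific priming" error is raised. On circular templates the amplicon
#' may span the origin, which is how an insert flanked by outward-facing
#' primers on a self-ligated circle comes out with its two halves inverted
#' relative to the genome.
#'
#' @param template a `dna_seq`.
#' @param fwd,rev [primer()] objects; `fwd$anneal` matches the plus strand,
#'   `rev$anneal` the minus strand.
#' @param max_len maximum amplicon length (default 12 kb).
#' @return Linear `dna_seq`: `fwd$overhang` + template span + revcomp of
#'   `rev$overhang`.
#' @export
simulate_pcr <- function(template, fwd, rev, max_len = 12000L) {
  if (!is_dna_seq(template)) tk_stop("`template` must be a dna_seq", "bad_sequence")
  stopifnot(inherits(fwd, "tk_primer"), inherits(rev, "tk_primer"))
  s <- template$seq
  L <- nchar(s)
  circular <- template$topology == "circular"
  binding <- function(anneal) {
    plus <- find_pattern(template, anneal)
    minus <- find_pattern(template, revcomp(anneal))
    list(plus = plus, minus = minus, n = length(plus) + length(minus))
  }
  bf <- binding(fwd$anneal)
  br <- binding(rev$anneal)
  if (bf$n != 1L)
    tk_stop(sprintf("forward primer '%s' has %d binding sites: non-specific priming",
                    fwd$name, bf$n), "nonspecific_priming")
  if (br$n != 1L)
    tk_stop(sprintf("reverse primer '%s' has %d binding sites: non-specific priming",
                    rev$name, br$n), "nonspecific_priming")
  if (length(bf$plus) != 1L)
    tk_stop(sprintf("forward primer '%s' anneals to the minus strand only: no product",
                    fwd$name), "no_product")
  if (length(br$minus) != 1L)
    tk_stop(sprintf("reverse primer '%s' anneals to the plus strand only: no product",
                    rev$name), "no_product")
  f <- bf$plus
  r_end <- br$minus + nchar(rev$anneal) - 1L   # plus-strand end of the rev site
  if (circular) {
    core_len <- ((r_end - f) %% L) + 1L
    core <- substr(paste0(s, s), f, f + core_len - 1L)
  } else {
    if (r_end < f)
      tk_stop("primers face away from each other on a linear template: no product",
              "no_product")
    core <- substr(s, f, r_end)
    core_len <- nchar(core)
  }
  if (core_len + nchar(fwd$overhang) + nchar(rev$overhang) > max_len)
    tk_stop(sprintf("amplicon of %d bp exceeds max_len = %d", core_len, max_len),
            "no_product")
  dna_seq(paste0(fwd$overhang, core, revcomp(rev$overhang)),
          id = sprintf("pcr_%s_%s", fwd$name, rev$name), topology = "linear")
}

#' SLIC assembly of a linearized vector and an insert
#'
#' Models sequence- and ligation-independent cloning at the level of its
#' design contract: the terminal `min_overlap` bases of each vector end must
#' exactly match a terminus of the insert (chew-back/anneal chemistry and
#' bacterial gap repair are abstracted away). The insert orientation is
#' auto-detected by trying both strands; success on both is reported as
#' ambiguous.
#'
#' @param vector,insert linear `dna_seq` molecules.
#' @param min_overlap minimum exact terminal identity per junction (default 25).
#' @param max_overlap cap on the reported maximal identity search.
#' @param id id for the assembled plasmid.
#' @return List with `product` (circular `dna_seq`), `overlap5`/`overlap3`
#'   (realised maximal exact identities at the vector-3'/insert and
#'   insert/vector-5' junctions) and `insert_strand` (`"+"` or `"-"`).
#' @export
slic_assemble <- function(vector, insert, min_overlap = 25L, max_overlap = 500L,
                          id = "slic_product") {
  if (!is_dna_seq(vector) || vector$topology != "linear")
    tk_stop("`vector` must be a linear dna_seq", "bad_sequence")
  if (!is_dna_seq(insert) || insert$topology != "linear")
    tk_stop("`insert` must be a linear dna_seq", "bad_sequence")
  v <- vector$seq
  lv <- nchar(v)
  try_orientation <- function(ins) {
    li <- nchar(ins)
    cap <- min(max_overlap, lv, li)
    # vector 3' end vs insert 5' end
    o5 <- 0L
    for (k in seq_len(cap)) {
      if (substr(v, lv - k + 1L, lv) == substr(ins, 1L, k)) o5 <- k
    }
    # insert 3' end vs vector 5' end
    o3 <- 0L
    for (k in seq_len(cap)) {
      if (substr(ins, li - k + 1L, li) == substr(v, 1L, k)) o3 <- k
    }
    list(o5 = o5, o3 = o3)
  }
  fwd <- try_orientation(insert$seq)
  rev <- try_orientation(revcomp(insert$seq))
  ok_f <- fwd$o5 >= min_overlap && fwd$o3 >= min_overlap
  ok_r <- rev$o5 >= min_overlap && rev$o3 >= min_overlap
  if (ok_f && ok_r)
    tk_stop("both insert orientations assemble: ambiguous assembly", "ambiguous_assembly")
  if (!ok_f && !ok_r)
    tk_stop(sprintf(paste0("terminal identities (+: %d/%d, -: %d/%d) below min_overlap = %d: ",
                           "insufficient homology"),
                    fwd$o5, fwd$o3, rev$o5, rev$o3, min_overlap),
            "insufficient_homology")
  ov <- if (ok_f) fwd else rev
  ins <- if (ok_f) insert$seq else revcomp(insert$seq)
  li <- nchar(ins)
  product <- dna_seq(paste0(v, substr(ins, ov$o5 + 1L, li - ov$o3)),
                     id = id, topology = "circular")
  list(product = product, overlap5 = ov$o5, overlap3 = ov$o3,
       insert_strand = if (ok_f) "+" else "-")
}

#' Canonical wild-type loxP site (34 bp)
#'
#' 13-bp inverted repeats around an asymmetric 8-bp spacer; the spacer
#' orientation defines the site's direction. The same wild-type sequence is
#' used for both site copies in a vector: Cre excision between two
#' same-orientation wild-type sites is the modelled behaviour.
#'
#' @return Character scalar of length 34.
#' @export
loxp_site <- function() "ATAACTTCGTATAATGTATGCTATACGAAGTTAT"

#' Cre-mediated excision between two same-orientation loxP sites
#'
#' The segment between the sites leaves as a circle carrying one loxP copy;
#' the remaining molecule keeps the other copy. Material is conserved:
#' `len(remaining) + len(excised) == len(input)`. Opposite-orientation site
#' pairs (inversion substrates) are rejected rather than modelled.
#'
#' @param x a `dna_seq` (typically the pre-Cre tagged locus, linear).
#' @param loxp the loxP sequence; default [loxp_site()].
#' @return List with `remaining` (same topology as input) and `excised`
#'   (circular `dna_seq`).
#' @export
cre_excise <- function(x, loxp = loxp_site()) {
  if (!is_dna_seq(x)) tk_stop("`x` must be a dna_seq", "bad_sequence")
  loxp <- toupper(loxp)
  plus <- find_pattern(x, loxp)
  minus <- find_pattern(x, revcomp(loxp))
  if (length(plus) + length(minus) != 2L)
    tk_stop(sprintf("found %d loxP copies; Cre excision needs exactly 2",
                    length(plus) + length(minus)), "loxp_count")
  if (length(plus) == 1L && length(minus) == 1L)
    tk_stop("loxP sites in opposite orientation (inversion substrate): not modelled",
            "loxp_orientation")
  if (length(minus) == 2L) {
    flipped <- cre_excise(revcomp(x), loxp)
    flipped$remaining <- revcomp(flipped$remaining)
    flipped$excised <- revcomp(flipped$excised)
    return(flipped)
  }
  p <- sort(plus)
  k <- nchar(loxp)
  s <- x$seq
  L <- nchar(s)
  if (x$topology == "circular") {
    # rotate so the first site starts at position 1, then treat linearly
    rot <- rotate_string(s, p[1])
    p <- c(1L, ((p[2] - p[1]) %% L) + 1L)
    s <- rot
  }
  remaining <- paste0(substr(s, 1L, p[1] - 1L), loxp, substr(s, p[2] + k, L))
  excised <- paste0(substr(s, p[1] + k, p[2] - 1L), loxp)
  list(remaining = dna_seq(remaining, id = paste0(x$id, "_postCre"), topology = x$topology),
       excised = dna_seq(excised, id = paste0(x$id, "_excised"), topology = "circular"))
}

#' Targeted integration by homologous recombination
#'
#' Models the designed outcome of gene targeting: the construct's terminal
#' homology arms pair with their unique genomic copies and the inter-arm
#' cassette replaces whatever lies between the genomic arm copies (for
#' stop-codon tagging the arms are adjacent and nothing is lost). Short
#' non-homologous terminal tails (restriction-site remnants from construct
#' linearization, up to `max_tail` nt) are tolerated, mirroring their removal
#' by end resection in vivo. The construct is tried on both strands; failure
#' to locate unique, colinear arm copies raises a "targeting failure".
#'
#' @param genome linear `dna_seq` of the locus.
#' @param construct linear `dna_seq`: left arm + cassette + right arm (plus
#'   optional short tails).
#' @param min_arm minimum exact arm match demanded at each construct end.
#' @param max_tail longest tolerated non-homologous terminal tail.
#' @return Linear `dna_seq` of the targeted locus.
#' @export
simulate_hr_integration <- function(genome, construct, min_arm = 2200L, max_tail = 10L) {
  if (!is_dna_seq(genome) || genome$topology != "linear")
    tk_stop("`genome` must be a linear dna_seq", "bad_sequence")
  if (!is_dna_seq(construct) || construct$topology != "linear")
    tk_stop("`construct` must be a linear dna_seq", "bad_sequence")
  g <- genome$seq
  Lg <- nchar(g)
  attempt <- function(cs) {
    Lc <- nchar(cs)
    if (Lc < 2L * min_arm) return(NULL)
    # left arm: seed of min_arm starting within the first max_tail+1 positions
    left <- NULL
    for (t in 0:max_tail) {
      seed <- substr(cs, t + 1L, t + min_arm)
      if (nchar(seed) < min_arm) break
      occ <- str_find_all(g, seed)
      if (length(occ) > 1L) return(NULL)      # not unique
      if (length(occ) == 1L) {
        left <- list(tail = t, g_start = occ)
        break
      }
    }
    if (is.null(left)) return(NULL)
    # right arm: seed of min_arm ending within the last max_tail+1 positions
    right <- NULL
    for (t in 0:max_tail) {
      to <- Lc - t
      if (to - min_arm + 1L <= left$tail + min_arm) break
      seed <- substr(cs, to - min_arm + 1L, to)
      occ <- str_find_all(g, seed)
      if (length(occ) > 1L) return(NULL)
      if (length(occ) == 1L) {
        right <- list(g_seed_start = occ, g_end = occ + min_arm - 1L, c_end = to)
        break
      }
    }
    if (is.null(right)) return(NULL)
    # colinearity: the two seed regions must not overlap in the genome and
    # the right arm copy must lie downstream of the left arm copy
    if (right$g_seed_start <= left$g_start + min_arm - 1L) return(NULL)
    core <- substr(cs, left$tail + 1L, right$c_end)
    paste0(substr(g, 1L, left$g_start - 1L), core, substr(g, right$g_end + 1L, Lg))
  }
  out <- attempt(construct$seq)
  if (is.null(out)) out <- attempt(revcomp(construct$seq))
  if (is.null(out))
    tk_stop("homology arms not found, not unique, or not colinear: targeting failure",
            "targeting_failure")
  dna_seq(out, id = paste0(genome$id, "_targeted"), topology = "linear")
}
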