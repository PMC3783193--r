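# End-to-end targeting construct designer: homology arms around the stop
# codon, two-PCR arm inversion, SLIC-competent insert, assembled construct,
# verification primers, and the predicted pre-/post-Cre tagged locus and
# fusion protein.

#' Genomic locus model
#'
#' A locus is stored on the gene's coding strand: minus-strand input is
#' reverse-complemented at construction and the stop coordinate remapped, so
#' every downstream design works on the plus strand.
#'
#' `orf_start` is optional: when the coding sequence is contiguous (no
#' introns, as in the synthetic fixtures) it allows the full fusion protein
#' to be predicted; without it the design still runs but reports only the
#' tagged locus, not the fusion translation.
#'
#' @param sequence `dna_seq` (linear) or character string.
#' @param stop_start 1-based position of the first base of the ORF's
#'   termination codon on the supplied strand.
#' @param strand `"+"` or `"-"` (strand the gene is encoded on in `sequence`).
#' @param gene_id gene identifier.
#' @param orf_start optional 1-based start of a contiguous ORF (the A of ATG)
#'   on the supplied strand.
#' @return Object of class `locus_model`, coordinates on the coding strand.
#' @export
locus_model <- function(sequence, stop_start, strand = "+", gene_id = "gene",
                        orf_start = NULL) {
  if (!is_dna_seq(sequence)) sequence <- dna_seq(sequence, id = gene_id)
  if (sequence$topology != "linear")
    tk_stop("locus must be a linear sequence", "bad_locus")
  L <- seq_length(sequence)
  stop_start <- as.integer(stop_start)
  if (strand == "-") {
    sequence <- revcomp(sequence)
    stop_start <- L - (stop_start + 2L) + 1L
    if (!is.null(orf_start)) orf_start <- L - (orf_start + 2L) + 1L
  } else if (strand != "+") tk_stop("strand must be '+' or '-'", "bad_locus")
  codon <- substr(sequence$seq, stop_start, stop_start + 2L)
  if (!codon %in% c("TAA", "TAG", "TGA"))
    tk_stop(sprintf("no termination codon at position %d (found '%s')",
                    stop_start, codon), "bad_locus")
  if (!is.null(orf_start)) {
    orf_start <- as.integer(orf_start)
    if (substr(sequence$seq, orf_start, orf_start + 2L) != "ATG")
      tk_stop("orf_start does not point at an ATG", "bad_locus")
    if ((stop_start - orf_start) %% 3L != 0L || orf_start >= stop_start)
      tk_stop("orf_start is not in frame with the stop codon", "bad_locus")
  }
  structure(list(sequence = sequence, stop_start = stop_start, strand = strand,
                 gene_id = gene_id, orf_start = orf_start),
            class = "locus_model")
}

#' @export
print.locus_model <- function(x, ...) {
  cat(sprintf("<locus> %s | %d bp | stop codon at %d (strand %s)\n",
              x$gene_id, seq_length(x$sequence), x$stop_start, x$strand))
  invisible(x)
}

#' Tagging vector template
#'
#' A circular vector with the canonical feature order of the C-terminal
#' tagging vectors: upstream cloning site (HindIII), tag CDS (quantification
#' remnant + TEV site + reporter + stop), loxP L, beta-actin 3'UTR, selection
#' cassette (SV40 promoter + marker CDS), backbone (ori + bacterial marker),
#' loxP R, downstream cloning site (XhoI). Feature intervals are 1-based
#' inclusive on the stored circular sequence and must be non-overlapping and
#' in that circular order.
#'
#' @param sequence circular `dna_seq`.
#' @param features data.frame with columns `label`, `start`, `end`.
#' @return Object of class `vector_template`.
#' @export
vector_template <- function(sequence, features) {
  if (!is_dna_seq(sequence) || sequence$topology != "circular")
    tk_stop("vector must be a circular dna_seq", "bad_vector")
  need <- c("label", "start", "end")
  if (!all(need %in% names(features)))
    tk_stop("features need columns label/start/end", "bad_vector")
  if (is.unsorted(features$start) || any(features$end < features$start))
    tk_stop("features must be ordered and non-degenerate", "bad_vector")
  if (any(features$start[-1] <= features$end[-nrow(features)]))
    tk_stop("features overlap", "bad_vector")
  tag <- feature_seq(sequence, features, "tag_cds")
  if (nchar(tag) %% 3L != 0L)
    tk_stop("tag CDS length must be divisible by 3", "bad_vector")
  aa <- translate_dna(tag)
  if (!endsWith(aa, "*") || grepl("\\*", substr(aa, 1, nchar(aa) - 1L)))
    tk_stop("tag CDS must end with its stop codon and contain no internal stop",
            "bad_vector")
  structure(list(sequence = sequence, features = features), class = "vector_template")
}

feature_seq <- function(sequence, features, label) {
  i <- match(label, features$label)
  if (is.na(i)) tk_stop(sprintf("vector lacks feature '%s'", label), "bad_vector")
  substr(sequence$seq, features$start[i], features$end[i])
}

#' @export
print.vector_template <- function(x, ...) {
  cat(sprintf("<vector> %s | %d bp circular | %d features\n",
              x$sequence$id, seq_length(x$sequence), nrow(x$features)))
  print(x$features)
  invisible(x)
}

#' Extract homology arms around the stop codon
#'
#' The left arm ends right before the termination codon (its last codon is
#' the ORF's final sense codon); the right arm starts with the termination
#' codon. Arm lengths of 2.2-2.5 kb are the working range for efficient
#' targeting.
#'
#' @param locus a [locus_model()].
#' @param arm_len arm length in bp.
#' @return List with `left_arm` and `right_arm` (character strings).
#' @export
extract_arms <- function(locus, arm_len) {
  stopifnot(inherits(locus, "locus_model"))
  arm_len <- as.integer(arm_len)
  if (arm_len < 1L) tk_stop("arm_len must be positive", "bad_design")
  s <- locus$sequence$seq
  L <- nchar(s)
  max_left <- locus$stop_start - 1L
  max_right <- L - locus$stop_start + 1L
  if (arm_len > max_left || arm_len > max_right)
    tk_stop(sprintf("insufficient flanking sequence: maximum feasible arm length is %d",
                    min(max_left, max_right)), "insufficient_flank")
  list(left_arm = substr(s, locus$stop_start - arm_len, locus$stop_start - 1L),
       right_arm = substr(s, locus$stop_start, locus$stop_start + arm_len - 1L))
}

#' Outer primers: amplify both arms in one genomic PCR
#'
#' 5F anneals at the left arm's 5' terminus, 3R at the right arm's 3'
#' terminus; both carry an overhang of a 4-bp spacer (for efficient cutting
#' near termini) plus the circularization enzyme's recognition site, so the
#' single PCR product can be digested and self-ligated into a circle. The
#' amplified region must not contain a site for that enzyme.
#'
#' @param locus a [locus_model()].
#' @param arm_len arm length in bp.
#' @param circ_enzyme circularization enzyme (default NotI).
#' @param spacer fixed bases placed 5' of the recognition site.
#' @return List `fwd` (5F), `rev` (3R) of [primer()] objects.
#' @export
design_outer_primers <- function(locus, arm_len, circ_enzyme = "NotI",
                                 spacer = "CAGT") {
  stopifnot(inherits(locus, "locus_model"))
  enz <- get_enzyme(circ_enzyme)
  arms <- extract_arms(locus, arm_len)
  region <- dna_seq(paste0(arms$left_arm, arms$right_arm), id = "arm_region")
  if (length(find_sites(region, enz))) {
    alt <- Filter(function(nm) !length(find_sites(region, nm)), enzyme_table()$name)
    tk_stop(sprintf("amplified region contains a %s site; site-free alternatives: %s",
                    enz$name, paste(alt, collapse = ", ")), "internal_site")
  }
  overhang <- paste0(spacer, enz$recognition)
  fwd <- tune_anneal(function(l) substr(arms$left_arm, 1L, l))
  rc_right <- revcomp(arms$right_arm)
  rev <- tune_anneal(function(l) substr(rc_right, 1L, l))
  list(fwd = primer(fwd$anneal, overhang, name = "5F"),
       rev = primer(rev$anneal, overhang, name = "3R"))
}

#' Linearize a tagging vector for SLIC
#'
#' Double-digests the circular vector with the two cloning-site enzymes and
#' returns the fragment that carries the tag CDS (the stuffer between the
#' sites is discarded). The returned linear molecule starts at the
#' HindIII-side end (tag CDS) and ends at the XhoI-side end (after loxP R).
#'
#' @param vector a [vector_template()].
#' @param enzymes the two cloning-site enzymes.
#' @return Linear `dna_seq`.
#' @export
linearize_vector <- function(vector, enzymes = c("HindIII", "XhoI")) {
  stopifnot(inherits(vector, "vector_template"))
  frags <- digest(vector$sequence, as.list(enzymes))
  if (length(frags) != 2L)
    tk_stop(sprintf("double digest yields %d fragments; cloning sites must be unique",
                    length(frags)), "bad_vector")
  tag <- feature_seq(vector$sequence, vector$features, "tag_cds")
  has_tag <- vapply(frags, function(f) grepl(tag, f$seq, fixed = TRUE), logical(1))
  if (sum(has_tag) != 1L)
    tk_stop("cannot identify the tag-bearing vector fragment", "bad_vector")
  dna_seq(frags[[which(has_tag)]]$seq, id = paste0(vector$sequence$id, "_linear"),
          topology = "linear")
}

#' Inner primers: invert the arms and add SLIC homology
#'
#' On the self-ligated arm circle, 3F anneals at the right arm's 5' end (the
#' stop codon side) and 5R at the left arm's 3' end (just before the stop);
#' amplification across the circle's junction inverts the arms. The primer
#' overhangs carry exactly `overlap` bases identical to the corresponding
#' termini of the linearized vector — 3F carries the vector's XhoI-side
#' terminus, 5R the (reverse complement of the) HindIII-side terminus — so
#' the product is SLIC-competent and the tag fuses in frame to the ORF's
#' final sense codon.
#'
#' @param locus a [locus_model()].
#' @param vector a [vector_template()].
#' @param arm_len arm length in bp.
#' @param overlap SLIC homology length added on each overhang (default 30).
#' @param circ_enzyme circularization enzyme whose site must not occur inside
#'   the overlap regions.
#' @return List `fwd` (3F), `rev` (5R) of [primer()] objects.
#' @export
design_inner_primers <- function(locus, vector, arm_len, overlap = 30L,
                                 circ_enzyme = "NotI") {
  stopifnot(inherits(locus, "locus_model"))
  enz <- get_enzyme(circ_enzyme)
  lin <- linearize_vector(vector)
  lv <- seq_length(lin)
  if (overlap < 15L || overlap > lv %/% 2L)
    tk_stop("unusable SLIC overlap length", "bad_design")
  tail3 <- substr(lin$seq, lv - overlap + 1L, lv)   # XhoI-side terminus
  head5 <- substr(lin$seq, 1L, overlap)             # HindIII-side terminus
  for (ov in c(tail3, head5)) {
    if (length(find_sites(dna_seq(ov), enz)))
      tk_stop(sprintf("SLIC overlap region contains a %s site", enz$name),
              "internal_site")
  }
  arms <- extract_arms(locus, arm_len)
  fwd <- tune_anneal(function(l) substr(arms$right_arm, 1L, l))
  rc_left <- revcomp(arms$left_arm)
  rev <- tune_anneal(function(l) substr(rc_left, 1L, l))
  list(fwd = primer(fwd$anneal, tail3, name = "3F"),
       rev = primer(rev$anneal, revcomp(head5), name = "5R"))
}

#' Design configuration
#'
#' @param arm_len homology arm length (bp); working range 2200-2500.
#' @param min_arm_len lower bound enforced on `arm_len`.
#' @param overlap SLIC homology length (bp).
#' @param min_overlap minimum overlap accepted by the assembler.
#' @param circ_enzyme circularization / linearization enzyme.
#' @param max_amplicon PCR product cap (bp).
#' @return List of validated settings.
#' @export
design_config <- function(arm_len = 2500L, min_arm_len = 2200L, overlap = 30L,
                          min_overlap = 25L, circ_enzyme = "NotI",
                          max_amplicon = 12000L) {
  if (arm_len < min_arm_len)
    tk_stop(sprintf("arm_len %d below the minimum of %d bp", arm_len, min_arm_len),
            "bad_design")
  list(arm_len = as.integer(arm_len), min_arm_len = as.integer(min_arm_len),
       overlap = as.integer(overlap), min_overlap = as.integer(min_overlap),
       circ_enzyme = circ_enzyme, max_amplicon = as.integer(max_amplicon))
}

# run a pipeline stage, re-raising any error with the stage name attached
design_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    tk_stop(sprintf("[%s] %s", stage, conditionMessage(e)), "design_stage")
  })
}

#' Design a complete targeting construct
#'
#' Reproduces the full cloning chain in silico:
#' genomic PCR of both arms (outer primers, restriction-site overhangs) ->
#' digest -> self-circularization -> second PCR across the junction (inner
#' primers; inverts the arms and adds SLIC homology) -> SLIC assembly into
#' the HindIII/XhoI-linearized vector -> uniqueness check of the
#' linearization site -> linearization -> homologous-recombination
#' integration into the locus -> Cre excision of the selection cassette.
#' Verification primers and the predicted fusion protein are attached.
#'
#' @param locus a [locus_model()].
#' @param vector a [vector_template()].
#' @param config a [design_config()].
#' @return Object of class `targeting_design` with fields `left_arm`,
#'   `right_arm`, `outer_primers`, `inner_primers`, `insert`, `construct`,
#'   `linearized`, `verification_primers`, `tagged_locus_pre_cre`,
#'   `tagged_locus_post_cre`, `fusion_protein`, `report`.
#' @export
design_construct <- function(locus, vector, config = design_config()) {
  stopifnot(inherits(locus, "locus_model"), inherits(vector, "vector_template"))
  arms <- design_stage("extract_arms", extract_arms(locus, config$arm_len))
  outer <- design_stage("design_outer_primers",
                        design_outer_primers(locus, config$arm_len, config$circ_enzyme))
  pcr1 <- design_stage("pcr_arms",
                       simulate_pcr(locus$sequence, outer$fwd, outer$rev,
                                    max_len = config$max_amplicon))
  frags <- design_stage("digest_amplicon", digest(pcr1, config$circ_enzyme))
  cohesive <- vapply(frags, function(f) nchar(f$end5) > 0 && nchar(f$end3) > 0, logical(1))
  if (sum(cohesive) != 1L)
    tk_stop("[digest_amplicon] expected exactly one doubly-cohesive arm fragment",
            "design_stage")
  circle <- design_stage("self_circularize",
                         self_circularize(frags[[which(cohesive)]], id = "arm_circle"))
  inner <- design_stage("design_inner_primers",
                        design_inner_primers(locus, vector, config$arm_len,
                                             config$overlap, config$circ_enzyme))
  insert <- design_stage("pcr_inversion",
                         simulate_pcr(circle, inner$fwd, inner$rev,
                                      max_len = config$max_amplicon))
  lin_vec <- design_stage("linearize_vector", linearize_vector(vector))
  asm <- design_stage("slic_assemble",
                      slic_assemble(lin_vec, insert, min_overlap = config$min_overlap,
                                    id = paste0(locus$gene_id, "_targeting")))
  construct <- asm$product
  n_sites <- length(find_sites(construct, config$circ_enzyme))
  if (n_sites != 1L)
    tk_stop(sprintf("[linearization_check] construct has %d %s sites; need exactly 1",
                    n_sites, get_enzyme(config$circ_enzyme)$name), "design_stage")
  lin_frag <- design_stage("linearize_construct", digest(construct, config$circ_enzyme))
  linearized <- dna_seq(lin_frag[[1L]]$seq, id = paste0(construct$id, "_linear"),
                        topology = "linear")
  pre_cre <- design_stage("hr_integration",
                          simulate_hr_integration(locus$sequence, linearized,
                                                  min_arm = config$min_arm_len))
  cre <- design_stage("cre_excision", cre_excise(pre_cre))
  fusion <- predict_fusion_protein(locus, cre$remaining)
  design <- structure(list(
    gene_id = locus$gene_id,
    left_arm = arms$left_arm, right_arm = arms$right_arm,
    outer_primers = outer, inner_primers = inner,
    insert = insert, construct = construct, linearized = linearized,
    tagged_locus_pre_cre = pre_cre, tagged_locus_post_cre = cre$remaining,
    excised_circle = cre$excised,
    fusion_protein = fusion,
    slic_overlaps = c(asm$overlap5, asm$overlap3),
    verification_primers = NULL,
    config = config,
    report = list(arm_len = config$arm_len,
                  insert_bp = seq_length(insert),
                  construct_bp = seq_length(construct),
                  vector_bp = seq_length(vector$sequence),
                  slic_overlaps = c(asm$overlap5, asm$overlap3))),
    class = "targeting_design")
  design$verification_primers <-
    design_stage("verification_primers",
                 design_verification_primers(design, locus$sequence, vector))
  design
}

#' @export
print.targeting_design <- function(x, ...) {
  r <- x$report
  cat(sprintf(paste0("<targeting_design> %s\n  arms: %d bp | insert: %d bp | ",
                     "construct: %d bp (circular)\n  SLIC overlaps: %d / %d bp\n"),
              x$gene_id, r$arm_len, r$insert_bp, r$construct_bp,
              r$slic_overlaps[1], r$slic_overlaps[2]))
  if (!is.null(x$fusion_protein))
    cat(sprintf("  fusion protein: %d aa\n", nchar(x$fusion_protein)))
  invisible(x)
}

# translate the tagged post-Cre locus from the (optional) contiguous ORF start
predict_fusion_protein <- function(locus, post_cre) {
  if (is.null(locus$orf_start)) return(NULL)
  cds <- substr(post_cre$seq, locus$orf_start, seq_length(post_cre))
  translate_dna(cds, to_stop = TRUE)
}

# search offsets 0..max_offset for an annealing region that reaches the Tm
# band AND is unique on the given template; gen_anneal(off, l) supplies the
# candidate (or NULL when infeasible). Deterministic; errors when exhausted.
pick_unique_primer <- function(gen_anneal, template, name, max_offset = 60L) {
  for (off in 0:max_offset) {
    got <- tryCatch({
      cand <- tune_anneal(function(l) gen_anneal(off, l))
      if (!isTRUE(cand$in_band)) NULL
      else {
        n_hits <- length(find_pattern(template, cand$anneal)) +
          length(find_pattern(template, revcomp(cand$anneal)))
        if (n_hits == 1L) primer(cand$anneal, name = name) else NULL
      }
    }, error = function(e) NULL)
    if (!is.null(got)) return(got)
  }
  tk_stop(sprintf("no unique primer within length/Tm constraints for '%s'", name),
          "no_primer_site")
}

#' Verification primers for targeted-integration PCR
#'
#' Designs two diagnostic pairs on the targeted allele: (1) a genomic forward
#' primer located outside the left arm paired with a reverse primer at (or
#' sliding downstream of) the 3' end of the selection cassette — its product
#' spans the entire resistance cassette; (2) a forward primer at the cassette
#' 5' end paired with a genomic reverse primer outside the right arm. Each
#' pair is verified by simulated PCR to amplify exactly one product on the
#' targeted allele and none on the wild-type locus (the cassette primer has
#' no wild-type binding site).
#'
#' @param design a `targeting_design` (needs `tagged_locus_pre_cre`).
#' @param genome the wild-type locus `dna_seq`.
#' @param vector the [vector_template()] used in the design.
#' @param max_amplicon PCR product cap used for verification.
#' @return List of two pair lists, each with `fwd`, `rev`, `product_bp` and
#'   `spans_cassette`.
#' @export
design_verification_primers <- function(design, genome, vector,
                                        max_amplicon = 12000L) {
  pre <- design$tagged_locus_pre_cre
  if (is.null(pre)) tk_stop("design lacks the pre-Cre tagged locus", "bad_design")
  g <- genome$seq
  Lg <- nchar(g)
  Lp <- seq_length(pre)
  cassette <- feature_seq(vector$sequence, vector$features, "selection_cassette")
  cass_pos <- find_pattern(pre, cassette)
  if (length(cass_pos) != 1L)
    tk_stop("selection cassette not unique in the tagged locus", "bad_design")
  cass_end <- cass_pos + nchar(cassette) - 1L
  la_start <- str_find_all(g, design$left_arm)
  ra_start <- str_find_all(g, design$right_arm)
  if (length(la_start) != 1L || length(ra_start) != 1L)
    tk_stop("homology arms not unique in the genome", "bad_design")
  ra_end <- ra_start + nchar(design$right_arm) - 1L
  ps <- pre$seq
  # pair 1: genomic fwd outside the left arm + rev at the cassette 3' end
  up_fwd <- pick_unique_primer(function(off, l) {
    to <- la_start - 1L - off
    if (to - l + 1L < 1L) return(NULL)
    substr(g, to - l + 1L, to)
  }, pre, name = "ver_up_F")
  cass_rev <- pick_unique_primer(function(off, l) {
    e <- cass_end + off
    if (e > Lp) return(NULL)
    revcomp(substr(ps, e - l + 1L, e))
  }, pre, name = "ver_cass_R")
  # pair 2: fwd at the cassette 5' end + genomic rev outside the right arm
  cass_fwd <- pick_unique_primer(function(off, l) {
    from <- cass_pos + off
    if (from + l - 1L > cass_end) return(NULL)
    substr(ps, from, from + l - 1L)
  }, pre, name = "ver_cass_F")
  dn_rev <- pick_unique_primer(function(off, l) {
    p <- ra_end + 1L + off
    if (p + l - 1L > Lg) return(NULL)
    revcomp(substr(g, p, p + l - 1L))
  }, pre, name = "ver_dn_R")
  pairs <- list(list(fwd = up_fwd, rev = cass_rev),
                list(fwd = cass_fwd, rev = dn_rev))
  out <- lapply(pairs, function(pair) {
    product <- simulate_pcr(pre, pair$fwd, pair$rev, max_len = max_amplicon)
    wt <- tryCatch({ simulate_pcr(genome, pair$fwd, pair$rev); TRUE },
                   error = function(e) FALSE)
    if (wt)
      tk_stop(sprintf("verification pair %s/%s amplifies the wild-type locus",
                      pair$fwd$name, pair$rev$name), "no_primer_site")
    list(fwd = pair$fwd, rev = pair$rev, product_bp = seq_length(product),
         spans_cassette = grepl(cassette, product$seq, fixed = TRUE))
  })
  if (!out[[1L]]$spans_cassette)
    tk_stop("cassette-spanning verification product does not contain the cassette",
            "no_primer_site")
  out
}
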