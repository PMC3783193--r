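# Deterministic, seeded generators for every input the pipeline consumes:
# genomic loci, tagging vectors, protein-group intensity tables, heavy/light
# quantification measurements and assembled transcripts with alignment hits.
# All generators are pure functions of the fixture configuration (seed
# included); the same config always yields byte-identical fixtures.

.stop_codons <- c("TAA", "TAG", "TGA")

# one fixed (commonly used) codon per amino acid, for encoding designed
# peptides into placeholder CDSs deterministically
.codon_of <- c(A = "GCC", R = "AGA", N = "AAC", D = "GAC", C = "TGC",
               Q = "CAG", E = "GAG", G = "GGC", H = "CAC", I = "ATC",
               L = "CTG", K = "AAG", M = "ATG", F = "TTC", P = "CCA",
               S = "AGC", T = "ACC", V = "GTG", W = "TGG", Y = "TAC")

encode_aa <- function(aa) paste(.codon_of[strsplit(toupper(aa), "")[[1]]], collapse = "")

all_codons <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}
.sense_codons <- setdiff(all_codons(), .stop_codons)

random_bases <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                  collapse = "")
random_sense_codons <- function(n) paste(sample(.sense_codons, n, replace = TRUE),
                                         collapse = "")

#' Fixture configuration
#'
#' One object drives every generator. Defaults encode the reference study
#' conditions: 2.5-kb homology arms on a ~6-kb locus, a ~5-kb tagging
#' vector, two bait replicates against one control with 10% intensity noise,
#' a 500-fmol heavy spike into eluates from 4e7 cells at 50% yield, and
#' planted copy numbers matching the reference eluate amounts
#' (69 / 20 / 134 / 194 fmol).
#'
#' @param seed integer seed; every generator derives its stream from it.
#' @param locus_len,arm_len,flank_len,orf_nt locus geometry (nt); `orf_nt`
#'   includes the stop codon and must be a multiple of 3.
#' @param reporter_aa,marker_aa,utr_len,promoter_len,backbone_len,stuffer_len
#'   vector feature sizes (aa for CDSs, nt otherwise).
#' @param n_background_proteins,planted_interactors,noise_cv,n_bait_reps,n_control_runs
#'   CoIP table settings; `planted_interactors` is a data.frame with columns
#'   `id`, `enrichment` (> 1), `mw`, `in_control`.
#' @param planted_copies data.frame `protein`, `copies`, `n_cells`, `yield`
#'   for the quantification generator.
#' @param quant_noise_cv multiplicative CV on simulated peak volumes.
#' @param spike_fmol heavy standard spiked per run.
#' @param n_transcript_groups transcript-fixture group count.
#' @return List of class `fixture_config`.
#' @export
fixture_config <- function(seed = 1L,
                           locus_len = 6200L, arm_len = 2500L, flank_len = 300L,
                           orf_nt = 1203L,
                           reporter_aa = 239L, marker_aa = 200L, utr_len = 600L,
                           promoter_len = 350L, backbone_len = 2500L,
                           stuffer_len = 100L,
                           n_background_proteins = 200L,
                           planted_interactors = data.frame(
                             id = c("planted_1", "planted_2", "planted_3"),
                             enrichment = c(50, 20, 8),
                             mw = c(50, 110, 25),
                             in_control = TRUE,
                             stringsAsFactors = FALSE),
                           noise_cv = 0.10,
                           n_bait_reps = 2L, n_control_runs = 1L,
                           planted_copies = data.frame(
                             protein = c("CNOT7", "EXOSC8", "EXOSC9", "UPF1"),
                             copies = c(2077.6, 602.2, 4034.8, 5841.5),
                             n_cells = 4e7, yield = 0.5,
                             stringsAsFactors = FALSE),
                           quant_noise_cv = 0.05,
                           spike_fmol = 500,
                           n_transcript_groups = 12L) {
  if (orf_nt %% 3L != 0L || orf_nt < 9L)
    tk_stop("orf_nt must be a multiple of 3 (>= 9)", "bad_config")
  stop_start <- arm_len + flank_len + 1L
  if (locus_len < stop_start + 2L + arm_len + flank_len)
    tk_stop("locus_len too small for the requested arms and flanks", "bad_config")
  if (orf_nt > arm_len + flank_len - 3L)
    tk_stop("ORF does not fit upstream of the stop position", "bad_config")
  if (any(planted_interactors$enrichment <= 1))
    tk_stop("planted enrichments must exceed 1", "bad_config")
  cfg <- as.list(environment())
  cfg$stop_start <- stop_start
  structure(cfg, class = "fixture_config")
}

.design_sites <- c("GCGGCCGC", "AAGCTT", "CTCGAG")  # NotI, HindIII, XhoI

in_ranges <- function(pos, ranges) {
  any(vapply(ranges, function(r) pos >= r[1] && pos <= r[2], logical(1)))
}

# remove accidental occurrences of the design restriction sites by point
# mutation / codon re-sampling; `cds` ranges are repaired codon-wise to stay
# stop-free in frame, `protected` ranges are never touched. Deterministic
# under the caller's RNG state.
clean_sites <- function(s, sites = .design_sites, cds = list(), protected = list(),
                        max_iter = 100L) {
  for (iter in seq_len(max_iter)) {
    occ <- list()
    for (site in sites) {
      for (p in str_find_all(s, site))
        occ[[length(occ) + 1L]] <- c(p, p + nchar(site) - 1L)
    }
    # occurrences fully inside a protected range are designed sites: keep them
    occ <- Filter(function(r) {
      !any(vapply(protected, function(pr) r[1] >= pr[1] && r[2] <= pr[2], logical(1)))
    }, occ)
    if (!length(occ)) return(s)
    r <- occ[[1L]]
    fixed <- FALSE
    for (pos in sample(seq(r[1], r[2]))) {
      if (in_ranges(pos, protected)) next
      cds_hit <- Filter(function(cr) pos >= cr[1] && pos <= cr[2], cds)
      if (length(cds_hit)) {
        cr <- cds_hit[[1L]]
        ci <- (pos - cr[1]) %/% 3L                 # codon index within the CDS
        c_from <- cr[1] + 3L * ci
        c_to <- c_from + 2L
        if (c_to > cr[2] || in_ranges(c_from, protected) || in_ranges(c_to, protected))
          next
        old <- substr(s, c_from, c_to)
        new <- sample(setdiff(.sense_codons, old), 1L)
        substr(s, c_from, c_to) <- new
      } else {
        old <- substr(s, pos, pos)
        substr(s, pos, pos) <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
      }
      fixed <- TRUE
      break
    }
    if (!fixed)
      tk_stop("cannot remove a restriction site without touching protected bases",
              "bad_config")
  }
  tk_stop("site cleaning did not converge", "bad_config")
}

#' Generate a synthetic genomic locus
#'
#' A random locus carrying one contiguous ORF whose termination codon sits at
#' a known position, with enough flanking sequence for the configured
#' homology arms plus verification primers, and no NotI/HindIII/XhoI site
#' anywhere (accidental sites are repaired by seeded point mutations, ORF
#' codons re-sampled in frame).
#'
#' @param cfg a [fixture_config()].
#' @return A [locus_model()] with `orf_start` set.
#' @export
make_locus <- function(cfg) {
  stopifnot(inherits(cfg, "fixture_config"))
  with_seed(cfg$seed + 101L, {
    stop_start <- cfg$stop_start
    orf_start <- stop_start - (cfg$orf_nt - 3L)
    upstream <- random_bases(orf_start - 1L)
    orf <- paste0("ATG", random_sense_codons((cfg$orf_nt - 6L) %/% 3L), "TAA")
    downstream <- random_bases(cfg$locus_len - (stop_start + 2L))
    s <- paste0(upstream, orf, downstream)
    s <- clean_sites(s,
                     cds = list(c(orf_start, stop_start + 2L)),
                     protected = list(c(orf_start, orf_start + 2L),
                                      c(stop_start, stop_start + 2L)))
    locus_model(dna_seq(s, id = "synthetic_locus"), stop_start = stop_start,
                strand = "+", gene_id = "synthetic_locus", orf_start = orf_start)
  })
}

#' Generate a synthetic tagging vector
#'
#' Realises the canonical feature order — HindIII cloning site, tag CDS
#' (quantification remnant + TEV site + G + reporter + stop), loxP L,
#' 3'UTR, selection cassette (promoter + marker CDS), backbone, loxP R,
#' XhoI cloning site, stuffer — as a circular molecule of about 5 kb.
#' Placeholder CDSs are random sense codons (layout, not identity, is what
#' the contracts depend on); the designed peptides are encoded with fixed
#' codons. One base of padding after the HindIII site keeps the tag CDS in
#' frame with an upstream ORF whose last sense codon abuts the cloning site.
#'
#' @param cfg a [fixture_config()].
#' @param reporter reporter label for the tag (EGFP/ProtA/FLAG).
#' @param arch a [tag_architecture()]; its remnant and TEV site are encoded
#'   at the start of the tag CDS.
#' @return A [vector_template()].
#' @export
make_vector <- function(cfg, reporter = "EGFP", arch = tag_architecture(reporter = reporter)) {
  stopifnot(inherits(cfg, "fixture_config"))
  with_seed(cfg$seed + 202L, {
    fixed_prefix <- paste0(encode_aa(arch$quant_remnant), encode_aa(arch$tev_site),
                           encode_aa("G"))
    tag_cds <- paste0(fixed_prefix, random_sense_codons(cfg$reporter_aa), "TAA")
    marker_cds <- paste0("ATG", random_sense_codons(cfg$marker_aa - 2L), "TAA")
    lox <- loxp_site()
    parts <- list(
      cloning_site_upstream = "AAGCTT",
      pad = "G",
      tag_cds = tag_cds,
      loxp_L = lox,
      actin3utr = random_bases(cfg$utr_len),
      selection_cassette = paste0(random_bases(cfg$promoter_len), marker_cds),
      backbone = random_bases(cfg$backbone_len),
      loxp_R = lox,
      cloning_site_downstream = "CTCGAG",
      stuffer = random_bases(cfg$stuffer_len))
    lens <- vapply(parts, nchar, integer(1))
    ends <- cumsum(lens)
    starts <- ends - lens + 1L
    s <- paste(unlist(parts), collapse = "")
    tag_start <- starts[["tag_cds"]]
    cass_start <- starts[["selection_cassette"]]
    marker_start <- cass_start + cfg$promoter_len
    s <- clean_sites(
      s,
      cds = list(c(tag_start, ends[["tag_cds"]]),
                 c(marker_start, ends[["selection_cassette"]])),
      protected = list(c(starts[["cloning_site_upstream"]], ends[["cloning_site_upstream"]]),
                       c(starts[["cloning_site_downstream"]], ends[["cloning_site_downstream"]]),
                       c(tag_start, tag_start + nchar(fixed_prefix) - 1L),
                       c(ends[["tag_cds"]] - 2L, ends[["tag_cds"]]),
                       c(marker_start, marker_start + 2L),
                       c(ends[["selection_cassette"]] - 2L, ends[["selection_cassette"]]),
                       c(starts[["loxp_L"]], ends[["loxp_L"]]),
                       c(starts[["loxp_R"]], ends[["loxp_R"]])))
    s <- fix_vector_wrap(s)
    keep <- setdiff(names(parts), "pad")
    features <- data.frame(label = keep, start = unname(starts[keep]),
                           end = unname(ends[keep]), stringsAsFactors = FALSE)
    vector_template(dna_seq(s, id = paste0("pQuant", arch$reporter), topology = "circular"),
                    features)
  })
}

# kill design-enzyme sites that straddle the circular origin (the junction is
# stuffer -> HindIII site, so the mutable side is always the stuffer tail)
fix_vector_wrap <- function(s) {
  repeat {
    L <- nchar(s)
    wrap <- paste0(substr(s, L - 6L, L), substr(s, 1L, 7L))
    hit <- NULL
    for (site in .design_sites) {
      for (p in str_find_all(wrap, site)) {
        if (p <= 7L && p + nchar(site) - 1L >= 8L) { hit <- p; break }
      }
      if (!is.null(hit)) break
    }
    if (is.null(hit)) return(s)
    gpos <- L - 7L + hit
    substr(s, gpos, gpos) <- sample(setdiff(c("A", "C", "G", "T"),
                                            substr(s, gpos, gpos)), 1L)
  }
}

lognorm_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sigma <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, mean = -sigma^2 / 2, sd = sigma))
}

#' Generate a synthetic protein-group intensity table
#'
#' Background proteins draw a log-normal base intensity shared between bait
#' and control runs; planted interactors are multiplied by their enrichment
#' in the bait runs (and optionally zeroed in control). Multiplicative
#' log-normal noise with the configured CV (mean 1) is applied per run, so at
#' zero noise the specificity of a planted protein equals its enrichment
#' exactly.
#'
#' @param cfg a [fixture_config()].
#' @return List: `table` (a [proteingroup_table()] with runs `bait_1..` /
#'   `control_1..`) and `truth` (the planted-interactor data.frame).
#' @export
make_proteingroups <- function(cfg) {
  stopifnot(inherits(cfg, "fixture_config"))
  with_seed(cfg$seed + 303L, {
    pl <- cfg$planted_interactors
    nb <- cfg$n_background_proteins
    ids <- c(pl$id, sprintf("bg_%03d", seq_len(nb)))
    mw <- c(pl$mw, round(stats::runif(nb, 10, 250), 1))
    base <- stats::rlnorm(length(ids), meanlog = log(1e7), sdlog = 1)
    enrich <- c(pl$enrichment, rep(1, nb))
    in_ctl <- c(pl$in_control, rep(TRUE, nb))
    runs <- c(paste0("bait_", seq_len(cfg$n_bait_reps)),
              paste0("control_", seq_len(cfg$n_control_runs)))
    ints <- matrix(0, nrow = length(ids), ncol = length(runs),
                   dimnames = list(NULL, runs))
    for (j in seq_len(cfg$n_bait_reps))
      ints[, j] <- base * enrich * lognorm_noise(length(ids), cfg$noise_cv)
    for (j in seq_len(cfg$n_control_runs))
      ints[, cfg$n_bait_reps + j] <-
        ifelse(in_ctl, base * lognorm_noise(length(ids), cfg$noise_cv), 0)
    list(table = proteingroup_table(ids, mw, ints), truth = pl)
  })
}

#' Generate synthetic heavy/light quantification measurements
#'
#' Inverts the copies-per-cell relation: each planted copy number is turned
#' into an eluate amount, and light/heavy peak volumes are emitted whose
#' ratio times the spike recovers that amount (up to the configured
#' multiplicative noise).
#'
#' @param cfg a [fixture_config()].
#' @param n_replicates technical replicates per protein.
#' @return List: `measurements` (data.frame in [absquant_table()] layout) and
#'   `truth` (planted copies with the implied eluate fmol).
#' @export
make_quant_measurements <- function(cfg, n_replicates = 2L) {
  stopifnot(inherits(cfg, "fixture_config"))
  with_seed(cfg$seed + 404L, {
    pc <- cfg$planted_copies
    fmol <- pc$copies * pc$n_cells * pc$yield / (1e-15 * 6.02214076e23)
    rows <- list()
    for (i in seq_len(nrow(pc))) {
      for (r in seq_len(n_replicates)) {
        heavy <- 1e6 * lognorm_noise(1, cfg$quant_noise_cv)
        light <- 1e6 * (fmol[i] / cfg$spike_fmol) * lognorm_noise(1, cfg$quant_noise_cv)
        rows[[length(rows) + 1L]] <- data.frame(
          protein = pc$protein[i], replicate = r,
          light_volume = light, heavy_volume = heavy,
          spike_fmol = cfg$spike_fmol, n_cells = pc$n_cells[i],
          stringsAsFactors = FALSE)
      }
    }
    truth <- cbind(pc, fmol_true = fmol)
    list(measurements = do.call(rbind, rows), truth = truth)
  })
}

#' Generate synthetic transcripts with alignment hits
#'
#' Transcript groups with 1-3 isoforms of differing ORF lengths (short UTRs
#' around a single ATG-initiated ORF; isoforms are rejection-sampled so the
#' planted ORF is the only one of at least `min_aa` residues). The hit table
#' plants chicken/human best hits for most group representatives, including
#' tie pairs resolved by bit score and sub-cutoff decoys (e-value 1e-5) that
#' must never annotate.
#'
#' @param cfg a [fixture_config()].
#' @param min_aa ORF-calling threshold the fixture is built against.
#' @return List: `transcripts` (list of [transcript_record()]), `hits`
#'   (12-column data.frame plus `subject_species`), `truth` (manifest
#'   data.frame: group, representative transcript, ORF id, protein length,
#'   expected chicken/human names).
#' @export
make_transcripts <- function(cfg, min_aa = 100L) {
  stopifnot(inherits(cfg, "fixture_config"))
  with_seed(cfg$seed + 505L, {
    transcripts <- list()
    truth_rows <- list()
    hit_rows <- list()
    for (g in seq_len(cfg$n_transcript_groups)) {
      n_iso <- sample(1:3, 1L)
      aa_lens <- sort(sample(seq(min_aa, 260L), n_iso), decreasing = FALSE)
      gid <- sprintf("SYNT_DN%d_c0_g1", g)
      for (k in seq_len(n_iso)) {
        tid <- sprintf("%s_i%d", gid, k)
        seq <- make_single_orf_transcript(aa_lens[k], min_aa)
        transcripts[[tid]] <- transcript_record(tid, seq)
      }
      rep_tid <- sprintf("%s_i%d", gid, n_iso)      # longest isoform
      rep_orf <- paste0(rep_tid, ".p1")
      status <- g %% 4L
      chick <- human <- NA_character_
      if (status != 0L) {                            # 3 of 4 groups annotated
        chick <- sprintf("GG_PROT%02d", g)
        human <- sprintf("HS_PROT%02d", g)
        e_ch <- 10^-stats::runif(1, 20, 60)
        # chicken: a tie pair at equal e-value resolved by higher bit score
        hit_rows[[length(hit_rows) + 1L]] <-
          hit_row(rep_orf, chick, e_ch, bit = 250)
        hit_rows[[length(hit_rows) + 1L]] <-
          hit_row(rep_orf, sprintf("GG_DECOY%02d", g), e_ch, bit = 120)
        hit_rows[[length(hit_rows) + 1L]] <-
          hit_row(rep_orf, human, 10^-stats::runif(1, 15, 40), bit = 180)
      } else {                                       # decoy-only group: sub-cutoff
        hit_rows[[length(hit_rows) + 1L]] <-
          hit_row(rep_orf, sprintf("GG_WEAK%02d", g), 1e-5, bit = 40)
      }
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        group_id = gid, representative = rep_tid, orf_id = rep_orf,
        aa_len = aa_lens[n_iso], name_chicken = chick, name_human = human,
        stringsAsFactors = FALSE)
    }
    list(transcripts = transcripts,
         hits = do.call(rbind, hit_rows),
         truth = do.call(rbind, truth_rows))
  })
}

hit_row <- function(query, subject, e, bit) {
  data.frame(query_id = query, subject_id = subject, pct_identity = 90,
             align_len = 100, mismatches = 10, gap_opens = 0,
             q_start = 1, q_end = 100, s_start = 1, s_end = 100,
             e_value = e, bit_score = bit, stringsAsFactors = FALSE)
}

# one transcript = 5'UTR + ATG ORF + stop + 3'UTR, rejection-sampled until
# the planted ORF is the only >= min_aa ORF in any of the six frames
make_single_orf_transcript <- function(aa_len, min_aa, max_tries = 50L) {
  for (i in seq_len(max_tries)) {
    s <- paste0(random_bases(sample(40:80, 1L)),
                "ATG", random_sense_codons(aa_len - 1L), "TAA",
                random_bases(sample(40:80, 1L)))
    orfs <- find_orfs(s, min_aa = min_aa, require_atg = TRUE, id = "tmp")
    if (nrow(orfs) == 1L && nchar(orfs$protein[1]) == aa_len) return(s)
  }
  tk_stop("could not build a single-ORF transcript", "bad_config")
}

#' Write fixture bundles to disk
#'
#' Materialises a fixture preset as plain-text files (FASTA/TSV) plus a JSON
#' ground-truth manifest, for use from the command line.
#'
#' @param cfg a [fixture_config()].
#' @param preset one of locus/vector/coip/quant/transcripts/all.
#' @param out_dir output directory (created).
#' @return Invisibly, the paths written.
#' @export
write_fixtures <- function(cfg, preset = c("all", "locus", "vector", "coip",
                                           "quant", "transcripts"), out_dir) {
  preset <- match.arg(preset)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  emit <- function(name) preset %in% c("all", name)
  manifest <- list(seed = cfg$seed)
  if (emit("locus")) {
    locus <- make_locus(cfg)
    p <- file.path(out_dir, "locus.fasta")
    write_fasta_dna(locus$sequence, p)
    manifest$locus <- list(stop_start = locus$stop_start, orf_start = locus$orf_start,
                           length = seq_length(locus$sequence))
    paths <- c(paths, p)
  }
  if (emit("vector")) {
    vec <- make_vector(cfg)
    p <- file.path(out_dir, "vector.fasta")
    write_fasta_dna(vec$sequence, p)
    pf <- file.path(out_dir, "vector_features.tsv")
    write.table(vec$features, pf, sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$vector <- list(length = seq_length(vec$sequence))
    paths <- c(paths, p, pf)
  }
  if (emit("coip")) {
    pg <- make_proteingroups(cfg)
    p <- file.path(out_dir, "proteingroups.tsv")
    tab <- pg$table
    names(tab)[-(1:3)] <- paste0("intensity_", names(tab)[-(1:3)])
    write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$coip <- pg$truth
    paths <- c(paths, p)
  }
  if (emit("quant")) {
    qm <- make_quant_measurements(cfg)
    p <- file.path(out_dir, "quant_measurements.tsv")
    write.table(qm$measurements, p, sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$quant <- qm$truth
    paths <- c(paths, p)
  }
  if (emit("transcripts")) {
    tr <- make_transcripts(cfg)
    p <- file.path(out_dir, "transcripts.fasta")
    write_fasta_dna(lapply(tr$transcripts, function(t)
      dna_seq(t$seq, id = t$transcript_id)), p)
    ph <- file.path(out_dir, "hits.tsv")
    write.table(tr$hits[, 1:12], ph, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    manifest$transcripts <- tr$truth
    paths <- c(paths, p, ph)
  }
  pm <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, pm, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, pm))
}
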