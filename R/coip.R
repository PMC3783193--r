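# Semiquantitative AP-MS interaction scoring: per-protein abundance
# (mean bait intensity / molecular mass) and bait-vs-control specificity.

#' Protein-group intensity tables
#'
#' Container for per-protein MS intensities across bait replicates and
#' control runs, as exported by MaxQuant-style post-processing. Missing
#' intensities are recorded as 0 — the background-floor rule of the
#' specificity score makes zeros meaningful.
#'
#' @param group_id character vector of protein-group ids.
#' @param mol_weight_kda molecular weights in kDa (> 0).
#' @param intensities numeric matrix, one column per run, rows aligned with
#'   `group_id`; NA is coerced to 0.
#' @param protein_ids optional per-group protein id annotation.
#' @return Object of class `proteingroup_table` (a data.frame).
#' @export
proteingroup_table <- function(group_id, mol_weight_kda, intensities, protein_ids = NULL) {
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  intensities[is.na(intensities)] <- 0
  if (any(intensities < 0))
    tk_stop("negative intensities are not meaningful", "bad_table")
  if (any(!is.finite(mol_weight_kda)) || any(mol_weight_kda <= 0))
    tk_stop("molecular weights must be positive", "bad_table")
  if (length(group_id) != nrow(intensities) || length(mol_weight_kda) != nrow(intensities))
    tk_stop("group_id / mol_weight / intensity dimensions disagree", "bad_table")
  if (anyDuplicated(group_id))
    tk_stop("duplicate group ids", "bad_table")
  df <- data.frame(group_id = as.character(group_id),
                   protein_ids = if (is.null(protein_ids)) as.character(group_id)
                                 else as.character(protein_ids),
                   mol_weight_kda = as.numeric(mol_weight_kda),
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(intensities))
  class(df) <- c("proteingroup_table", "data.frame")
  attr(df, "runs") <- colnames(intensities)
  df
}

#' Read a MaxQuant-style proteinGroups TSV
#'
#' Tolerant reader for the proteinGroups dialect: the id, molecular-weight
#' and per-run intensity columns are selected by a configurable name map, so
#' both real MaxQuant exports and the simple fixture dialect load through the
#' same call.
#'
#' @param path TSV path.
#' @param id_col,mw_col column names for group id and molecular weight (kDa).
#' @param intensity_prefix per-run intensity columns are those starting with
#'   this prefix; run labels are the remainders of the column names.
#' @param protein_ids_col optional protein-ids column.
#' @return A [proteingroup_table()].
#' @export
read_proteingroups <- function(path, id_col = "group_id",
                               mw_col = "mol_weight_kda",
                               intensity_prefix = "intensity_",
                               protein_ids_col = NULL) {
  raw <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  for (col in c(id_col, mw_col))
    if (!col %in% names(raw))
      tk_stop(sprintf("column '%s' not found in %s", col, path), "bad_table")
  int_cols <- grep(paste0("^", intensity_prefix), names(raw), value = TRUE)
  if (!length(int_cols))
    tk_stop(sprintf("no columns matching intensity prefix '%s'", intensity_prefix),
            "bad_table")
  ints <- as.matrix(raw[int_cols])
  colnames(ints) <- sub(paste0("^", intensity_prefix), "", int_cols)
  proteingroup_table(raw[[id_col]], raw[[mw_col]], ints,
                     protein_ids = if (!is.null(protein_ids_col)) raw[[protein_ids_col]])
}

run_matrix <- function(table, runs) {
  runs <- as.character(runs)
  missing <- setdiff(runs, attr(table, "runs"))
  if (length(missing))
    tk_stop(sprintf("unknown run label(s): %s", paste(missing, collapse = ", ")),
            "bad_table")
  as.matrix(table[, runs, drop = FALSE])
}

#' CoIP abundance score
#'
#' Abundance = mean signal intensity over the bait replicates (missing = 0)
#' divided by the protein's molecular mass, in intensity units per kDa.
#'
#' @param table a [proteingroup_table()].
#' @param bait_runs run labels of the bait replicates.
#' @return Numeric vector aligned with the table rows.
#' @export
compute_abundance <- function(table, bait_runs) {
  b <- run_matrix(table, bait_runs)
  rowMeans(b) / table$mol_weight_kda
}

#' CoIP specificity score
#'
#' Specificity = mean bait intensity / mean control intensity. For proteins
#' undetected in every control run the denominator is the background floor
#' (1 intensity unit by convention), so bait-only proteins get their bait
#' intensity as specificity rather than infinity.
#'
#' @param table a [proteingroup_table()].
#' @param bait_runs,control_runs run labels.
#' @param background_floor denominator used when all control intensities are 0.
#' @return Numeric vector aligned with the table rows.
#' @export
compute_specificity <- function(table, bait_runs, control_runs, background_floor = 1) {
  b <- rowMeans(run_matrix(table, bait_runs))
  ctl <- run_matrix(table, control_runs)
  m_ctl <- rowMeans(ctl)
  denom <- ifelse(m_ctl > 0, m_ctl, background_floor)
  b / denom
}

#' Score a CoIP protein-group table
#'
#' Computes abundance and specificity per protein group and returns them
#' sorted by descending specificity, ties broken by descending abundance.
#' Optionally writes a plot-ready scatter TSV with log10 axes.
#'
#' @param table a [proteingroup_table()].
#' @param bait_runs,control_runs run labels.
#' @param background_floor see [compute_specificity()].
#' @param scatter_path optional path for a TSV with `log10_abundance` /
#'   `log10_specificity` columns (zero scores become NA on the log scale).
#' @return data.frame with columns `group_id`, `abundance`, `specificity`,
#'   `detected_in_control`.
#' @export
score_table <- function(table, bait_runs, control_runs, background_floor = 1,
                        scatter_path = NULL) {
  ab <- compute_abundance(table, bait_runs)
  sp <- compute_specificity(table, bait_runs, control_runs, background_floor)
  in_ctl <- rowMeans(run_matrix(table, control_runs)) > 0
  out <- data.frame(group_id = table$group_id, abundance = ab, specificity = sp,
                    detected_in_control = in_ctl, stringsAsFactors = FALSE)
  out <- out[order(-out$specificity, -out$abundance, out$group_id), ]
  rownames(out) <- NULL
  if (!is.null(scatter_path)) {
    sc <- data.frame(group_id = out$group_id,
                     log10_abundance = ifelse(out$abundance > 0, log10(out$abundance), NA),
                     log10_specificity = ifelse(out$specificity > 0, log10(out$specificity), NA))
    write.table(sc, scatter_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

#' @rdname score_table
#' @param scores result of `score_table()`.
#' @param path output TSV path.
#' @export
write_coip_scores <- function(scores, path) {
  write.table(scores, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
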