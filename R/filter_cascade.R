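# Six-step filtering workflow reducing raw annotated calls to
# high-confidence candidates: depth -> consequence -> panel -> frequency ->
# deleteriousness vote, with ClinVar/HGMD reconciliation annotating (not
# filtering) the survivors. Each filter is a stateless predicate, so the
# cascade order affects only the attribution of failures, never the
# survivor set.

.step_result <- function(pass, reason) {
  data.frame(pass = pass, reason = reason, stringsAsFactors = FALSE)
}

#' Depth filter
#'
#' Pass iff read depth >= `cfg$min_depth` (boundary inclusive). A missing
#' depth fails with reason `"no-depth"`.
#'
#' @param v an `epivar_variants` table (vectorized over rows).
#' @param cfg an [pipeline_config()] object.
#' @return data.frame with logical `pass` and character `reason`.
#' @export
filter_by_depth <- function(v, cfg = pipeline_config()) {
  nodepth <- is.na(v$depth)
  pass <- !nodepth & v$depth >= cfg$min_depth
  reason <- ifelse(nodepth, "no-depth",
            ifelse(pass, "", sprintf("depth %g < %g", v$depth, cfg$min_depth)))
  .step_result(pass, reason)
}

#' Consequence filter
#'
#' Pass iff the consequence is protein-disrupting: frameshift, nonsense,
#' missense, in-frame indel, or canonical splice site. Synonymous and
#' other classes fail.
#'
#' @inheritParams filter_by_depth
#' @return data.frame with `pass` and `reason`.
#' @export
filter_by_consequence <- function(v) {
  pass <- v$consequence %in% damaging_consequences()
  .step_result(pass, ifelse(pass, "",
                            paste0("consequence '", v$consequence,
                                   "' not protein-disrupting")))
}

#' Panel-membership filter
#'
#' Pass iff the gene symbol is a panel symbol; the match is case-sensitive
#' and exact (aliases are resolved only in metadata lookups, not here).
#'
#' @inheritParams filter_by_depth
#' @param panel gene panel from [read_gene_panel()].
#' @return data.frame with `pass` and `reason`.
#' @export
filter_by_panel <- function(v, panel) {
  if (nrow(panel) == 0) stop("empty gene panel", call. = FALSE)
  pass <- v$gene %in% panel$gene
  .step_result(pass, ifelse(pass, "",
                            paste0("gene ", v$gene, " not on panel")))
}

#' Population-frequency filter
#'
#' Fail iff any reference-panel frequency is strictly above
#' `cfg$maf_threshold` (a frequency exactly at the threshold passes, and a
#' variant absent from every panel passes).
#'
#' @inheritParams filter_by_depth
#' @return data.frame with `pass` and `reason`.
#' @export
filter_by_frequency <- function(v, cfg = pipeline_config()) {
  mafcols <- grep("^maf_", names(v), value = TRUE)
  if (length(mafcols) == 0) {
    return(.step_result(rep(TRUE, nrow(v)), rep("", nrow(v))))
  }
  m <- as.matrix(as.data.frame(v)[, mafcols, drop = FALSE])
  common <- rowSums(m > cfg$maf_threshold, na.rm = TRUE) > 0
  .step_result(!common, ifelse(common,
                               sprintf("MAF > %g in a reference panel",
                                       cfg$maf_threshold), ""))
}

#' Ensemble deleteriousness vote count
#'
#' Nine voting units over the eleven predictors: the strongly correlated
#' pairs PolyPhen-2 HDIV/HVAR and MetaSVM/MetaLR each collapse to one unit,
#' SIFT, MutationTaster, MutationAssessor, LRT, FATHMM and PROVEAN vote
#' singly, and GERP++ votes deleterious iff its RS score is at or above
#' `cfg$gerp_deleterious_cutoff`. Under the default `pair_rule = "either"`
#' a pair votes deleterious when either member does; missing calls never
#' vote.
#'
#' @inheritParams filter_by_depth
#' @return integer vector of votes in \[0, 9\].
#' @export
deleteriousness_votes <- function(v, cfg = pipeline_config()) {
  del <- function(col) !is.na(v[[col]]) & v[[col]] == "deleterious"
  pair <- function(a, b) {
    if (cfg$pair_rule == "either") del(a) | del(b) else del(a) & del(b)
  }
  units <- cbind(
    pair("Polyphen2_HDIV", "Polyphen2_HVAR"),
    pair("MetaSVM", "MetaLR"),
    del("SIFT"), del("MutationTaster"), del("MutationAssessor"),
    del("LRT"), del("FATHMM"), del("PROVEAN"),
    !is.na(v$gerp_rs) & v$gerp_rs >= cfg$gerp_deleterious_cutoff)
  as.integer(rowSums(units))
}

# votes on the tolerated side, mirror image of deleteriousness_votes():
# a unit votes tolerated when it carries a call and does not vote
# deleterious under the same pair rule
tolerated_votes <- function(v, cfg = pipeline_config()) {
  tol <- function(col) !is.na(v[[col]]) & v[[col]] == "tolerated"
  del <- function(col) !is.na(v[[col]]) & v[[col]] == "deleterious"
  pair_tol <- function(a, b) {
    if (cfg$pair_rule == "either") (tol(a) | tol(b)) & !(del(a) | del(b))
    else tol(a) & tol(b)
  }
  units <- cbind(
    pair_tol("Polyphen2_HDIV", "Polyphen2_HVAR"),
    pair_tol("MetaSVM", "MetaLR"),
    tol("SIFT"), tol("MutationTaster"), tol("MutationAssessor"),
    tol("LRT"), tol("FATHMM"), tol("PROVEAN"),
    !is.na(v$gerp_rs) & v$gerp_rs < cfg$gerp_deleterious_cutoff)
  as.integer(rowSums(units))
}

#' Deleteriousness filter
#'
#' Pass iff [deleteriousness_votes()] is at least
#' `cfg$min_deleterious_votes` (default: two or more).
#'
#' @inheritParams filter_by_depth
#' @return data.frame with `pass` and `reason`.
#' @export
filter_by_deleteriousness <- function(v, cfg = pipeline_config()) {
  votes <- deleteriousness_votes(v, cfg)
  pass <- votes >= cfg$min_deleterious_votes
  .step_result(pass, ifelse(pass, "",
                            sprintf("%d deleteriousness votes < %d",
                                    votes, cfg$min_deleterious_votes)))
}

#' Reconcile ClinVar and HGMD assertions
#'
#' `consistent_pathogenic` when every non-absent source asserts a
#' disease-causing status and at least one source is non-absent;
#' `consistent_benign` symmetrically; any inconsistency (or no evidence at
#' all) is `uncertain`.
#'
#' @inheritParams filter_by_depth
#' @return character vector over
#'   `{consistent_pathogenic, consistent_benign, uncertain}`.
#' @export
reconcile_database_assertions <- function(v) {
  cv <- v$clinvar
  hg <- v$hgmd
  n_present <- (cv != "absent") + (hg != "absent")
  cv_path <- cv %in% c("pathogenic", "absent")
  hg_path <- hg %in% c("disease_mutation", "absent")
  cv_ben <- cv %in% c("benign", "absent")
  hg_ben <- hg %in% c("benign", "absent")
  out <- rep("uncertain", length(cv))
  out[n_present > 0 & cv_path & hg_path] <- "consistent_pathogenic"
  out[n_present > 0 & cv_ben & hg_ben] <- "consistent_benign"
  out
}

#' Run the filter cascade
#'
#' Applies depth, consequence, panel, frequency, and deleteriousness in
#' order, short-circuiting at the first failing step per variant, then
#' attaches the database-reconciliation status to the survivors (the
#' reconciliation annotates later evidence assignment; it never filters).
#'
#' @param variants an `epivar_variants` table.
#' @param panel gene panel from [read_gene_panel()].
#' @param cfg an [pipeline_config()] object.
#' @return list with `survivors` (the surviving rows plus a `db_status`
#'   column) and `trace` (class `epivar_trace`): per-step surviving counts
#'   and the per-variant step log.
#' @export
run_cascade <- function(variants, panel, cfg = pipeline_config()) {
  steps <- list(
    depth = function(v) filter_by_depth(v, cfg),
    consequence = function(v) filter_by_consequence(v),
    panel = function(v) filter_by_panel(v, panel),
    frequency = function(v) filter_by_frequency(v, cfg),
    deleteriousness = function(v) filter_by_deleteriousness(v, cfg))
  n <- nrow(variants)
  alive <- rep(TRUE, n)
  counts <- c(input = n)
  log <- vector("list", length(steps))
  key <- if (n) paste(variants$patient_id, variant_key(variants)) else character()
  for (k in seq_along(steps)) {
    nm <- names(steps)[k]
    if (any(alive)) {
      res <- steps[[k]](variants[alive, , drop = FALSE])
      log[[k]] <- data.frame(variant = key[alive], step = nm,
                             pass = res$pass, reason = res$reason,
                             stringsAsFactors = FALSE)
      alive[alive] <- res$pass
    } else {
      log[[k]] <- data.frame(variant = character(), step = character(),
                             pass = logical(), reason = character(),
                             stringsAsFactors = FALSE)
    }
    counts[nm] <- sum(alive)
  }
  survivors <- variants[alive, , drop = FALSE]
  rownames(survivors) <- NULL
  survivors$db_status <- if (nrow(survivors))
    reconcile_database_assertions(survivors) else character()
  trace <- structure(list(counts = counts, detail = do.call(rbind, log)),
                     class = "epivar_trace")
  list(survivors = survivors, trace = trace)
}

#' @export
print.epivar_trace <- function(x, ...) {
  cat("<filter cascade trace>\n")
  print(x$counts)
  invisible(x)
}

#' Write the per-step surviving counts of a cascade trace
#' @param trace an `epivar_trace`.
#' @param path destination TSV.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  utils::write.table(
    data.frame(step = names(trace$counts), surviving = unname(trace$counts)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
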