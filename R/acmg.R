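# ACMG/AMP evidence assignment and the five-class combination engine.
# Evidence codes carry a strength determined purely by their prefix
# (PVS very strong, PS strong, PM moderate, PP supporting; BA stand-alone
# benign, BS strong benign, BP supporting benign); the combining rules are
# evaluated on strength counts alone.

.acmg_codes <- function() {
  c("PVS1", paste0("PS", 1:4), paste0("PM", 1:6), paste0("PP", 1:5),
    "BA1", paste0("BS", 1:4), paste0("BP", 1:7))
}

#' Strength of ACMG evidence codes
#'
#' @param code character vector of codes (e.g. `"PS4"`).
#' @return character vector over `{very_strong, strong, moderate,
#'   supporting, stand_alone_benign, strong_benign, supporting_benign}`.
#' @export
evidence_strength <- function(code) {
  bad <- !(code %in% .acmg_codes())
  if (any(bad))
    stop("unknown ACMG code: ", code[bad][1], call. = FALSE)
  prefix <- sub("[0-9]+$", "", code)
  unname(c(PVS = "very_strong", PS = "strong", PM = "moderate",
           PP = "supporting", BA = "stand_alone_benign",
           BS = "strong_benign", BP = "supporting_benign")[prefix])
}

#' Parse a comma-joined criteria string into an evidence set
#' @param s strings like `"PS4, PM6, PP3, PP5"`.
#' @return list of character vectors (duplicates removed).
#' @export
parse_criteria <- function(s) {
  lapply(strsplit(s, "[,;]\\s*"), function(x) {
    x <- trimws(x)
    x <- x[nzchar(x)]
    unique(x)
  })
}

#' Serialize an evidence set as the display string
#' @param codes character vector of codes.
#' @return single string, codes comma-joined in assignment order.
#' @export
format_criteria <- function(codes) paste(codes, collapse = ", ")

#' Assign ACMG evidence codes to one cascade survivor
#'
#' Deterministic rule evaluation over the variant's annotations, its
#' case-control association, the reconciled database status, and the panel
#' entry:
#' * `PVS1` — null consequence (nonsense/frameshift/canonical splice) in a
#'   gene where loss of function is a known disease mechanism (curated
#'   `lof_mechanism_gene` flag);
#' * `PS1` — same amino-acid change as a known pathogenic variant
#'   (curated); `PS3` — well-established functional studies show damage
#'   (curated); `PS4` — case-control odds-ratio evidence;
#' * `PM2` — absent from all frequency panels; `PM5` — different missense
#'   change at a residue with a known pathogenic missense (curated);
#'   `PM6` — assumed de novo (parents untested);
#' * `PP3` — ensemble deleteriousness vote at or above the config
#'   threshold; `PP5` — reconciled reputable-source assertion of
#'   pathogenicity (disabled by `cfg$use_pp5 = FALSE`);
#' * benign side: `BA1` — any panel frequency above 5%; `BP4` — no
#'   deleterious votes and at least two tolerated votes; `BP6` —
#'   reconciled benign assertion.
#'
#' @param v single-row `epivar_variants` table.
#' @param assoc an `epivar_assoc` result (or a list with `ps4`), or `NULL`
#'   when no association evidence exists.
#' @param db_status value from [reconcile_database_assertions()].
#' @param panel_entry one row of the gene panel (unused fields tolerated).
#' @param cfg an [pipeline_config()] object.
#' @return character vector of assigned codes (an EvidenceSet).
#' @export
assign_evidence <- function(v, assoc = NULL, db_status = "uncertain",
                            panel_entry = NULL, cfg = pipeline_config()) {
  stopifnot(nrow(v) == 1L)
  codes <- character()
  mafcols <- grep("^maf_", names(v), value = TRUE)
  mafs <- if (length(mafcols)) as.numeric(v[1, mafcols]) else numeric()
  lof_gene <- isTRUE(v$lof_mechanism_gene) ||
    isTRUE(panel_entry$lof_mechanism)
  votes <- deleteriousness_votes(v, cfg)
  tvotes <- tolerated_votes(v, cfg)

  if (v$consequence %in% c("nonsense", "frameshift", "canonical_splice") &&
      lof_gene) codes <- c(codes, "PVS1")
  if (isTRUE(v$same_aa_change_known_pathogenic)) codes <- c(codes, "PS1")
  if (isTRUE(v$functional_study_damaging)) codes <- c(codes, "PS3")
  if (!is.null(assoc) && isTRUE(assoc$ps4)) codes <- c(codes, "PS4")
  if (length(mafs) == 0 || all(is.na(mafs))) codes <- c(codes, "PM2")
  if (isTRUE(v$other_missense_same_residue_pathogenic))
    codes <- c(codes, "PM5")
  if (isTRUE(v$assumed_de_novo)) codes <- c(codes, "PM6")
  if (votes >= cfg$min_deleterious_votes) codes <- c(codes, "PP3")
  if (cfg$use_pp5 && db_status == "consistent_pathogenic")
    codes <- c(codes, "PP5")
  if (any(!is.na(mafs) & mafs > 0.05)) codes <- c(codes, "BA1")
  if (votes == 0 && tvotes >= 2) codes <- c(codes, "BP4")
  if (cfg$use_pp5 && db_status == "consistent_benign")
    codes <- c(codes, "BP6")
  unique(codes)
}

#' Combine an ACMG evidence set into the five-class verdict
#'
#' Combining rules (evaluated on strength counts; `pvs` = PVS1 present,
#' `ps`/`pm`/`pp` pathogenic-side counts, `ba1`/`bs`/`bp` benign-side):
#'
#' **Pathogenic** — PVS1 with (>=1 strong, or >=2 moderate, or 1 moderate +
#' 1 supporting, or >=2 supporting); or >=2 strong; or 1 strong with
#' (>=3 moderate, or 2 moderate + >=2 supporting, or 1 moderate +
#' >=4 supporting).
#'
#' **Likely pathogenic** — PVS1 + 1 moderate; or 1 strong + 1-2 moderate;
#' or 1 strong + >=2 supporting; or >=3 moderate; or 2 moderate +
#' >=2 supporting; or 1 moderate + >=4 supporting.
#'
#' **Benign** — BA1, or >=2 strong benign. **Likely benign** — 1 strong
#' benign + 1 supporting benign, or >=2 supporting benign.
#'
#' When a pathogenic-side and a benign-side rule fire simultaneously the
#' verdict is uncertain significance with `conflict = TRUE`; with no rule
#' fired it is uncertain significance.
#'
#' @param codes character vector of evidence codes.
#' @return list of class `epivar_classification`: `label` (one of
#'   `pathogenic`, `likely_pathogenic`, `uncertain_significance`,
#'   `likely_benign`, `benign`), `fired_rule`, `conflict`.
#' @export
combine_evidence <- function(codes) {
  if (length(codes)) evidence_strength(codes)  # validates tokens
  codes <- unique(codes)
  pvs <- "PVS1" %in% codes
  ps <- sum(grepl("^PS[0-9]+$", codes))
  pm <- sum(grepl("^PM[0-9]+$", codes))
  pp <- sum(grepl("^PP[0-9]+$", codes))
  ba1 <- "BA1" %in% codes
  bs <- sum(grepl("^BS[0-9]+$", codes))
  bp <- sum(grepl("^BP[0-9]+$", codes))

  path_rule <- if (pvs && (ps >= 1 || pm >= 2 || (pm == 1 && pp == 1) ||
                           pp >= 2)) "pathogenic_ia"
    else if (ps >= 2) "pathogenic_ii"
    else if (ps == 1 && (pm >= 3 || (pm == 2 && pp >= 2) ||
                         (pm == 1 && pp >= 4))) "pathogenic_iii"
    else NULL
  lp_rule <- if (pvs && pm == 1) "likely_pathogenic_i"
    else if (ps == 1 && pm >= 1 && pm <= 2) "likely_pathogenic_ii"
    else if (ps == 1 && pp >= 2) "likely_pathogenic_iii"
    else if (pm >= 3) "likely_pathogenic_iv"
    else if (pm == 2 && pp >= 2) "likely_pathogenic_v"
    else if (pm == 1 && pp >= 4) "likely_pathogenic_vi"
    else NULL
  benign_rule <- if (ba1) "benign_stand_alone"
    else if (bs >= 2) "benign_ii"
    else NULL
  lb_rule <- if (bs == 1 && bp >= 1) "likely_benign_i"
    else if (bp >= 2) "likely_benign_ii"
    else NULL

  path_side <- if (!is.null(path_rule)) path_rule else lp_rule
  benign_side <- if (!is.null(benign_rule)) benign_rule else lb_rule

  if (!is.null(path_side) && !is.null(benign_side)) {
    out <- list(label = "uncertain_significance",
                fired_rule = paste(path_side, benign_side, sep = "+"),
                conflict = TRUE)
  } else if (!is.null(path_rule)) {
    out <- list(label = "pathogenic", fired_rule = path_rule,
                conflict = FALSE)
  } else if (!is.null(lp_rule)) {
    out <- list(label = "likely_pathogenic", fired_rule = lp_rule,
                conflict = FALSE)
  } else if (!is.null(benign_rule)) {
    out <- list(label = "benign", fired_rule = benign_rule, conflict = FALSE)
  } else if (!is.null(lb_rule)) {
    out <- list(label = "likely_benign", fired_rule = lb_rule,
                conflict = FALSE)
  } else {
    out <- list(label = "uncertain_significance", fired_rule = "none",
                conflict = FALSE)
  }
  class(out) <- "epivar_classification"
  out
}

#' Classify one cascade survivor
#'
#' Composition of [assign_evidence()] and [combine_evidence()].
#'
#' @inheritParams assign_evidence
#' @return list with `evidence` (character vector) and `classification`
#'   (an `epivar_classification`).
#' @export
classify_variant <- function(v, assoc = NULL, db_status = "uncertain",
                             panel_entry = NULL, cfg = pipeline_config()) {
  ev <- assign_evidence(v, assoc, db_status, panel_entry, cfg)
  list(evidence = ev, classification = combine_evidence(ev))
}

#' Classify all cascade survivors
#'
#' Joins per-variant association results and panel metadata, then applies
#' the ACMG engine row by row.
#'
#' @param survivors cascade survivor table (with `db_status` column, as
#'   produced by [run_cascade()]).
#' @param assoc association table from [associate_variants()].
#' @param panel gene panel from [read_gene_panel()].
#' @param cfg an [pipeline_config()] object.
#' @return the survivor table with added columns `evidence` (comma-joined
#'   string), `label`, `fired_rule`, `conflict`.
#' @export
classify_variants <- function(survivors, assoc, panel,
                              cfg = pipeline_config()) {
  out <- survivors
  out$evidence <- character(nrow(out))
  out$label <- character(nrow(out))
  out$fired_rule <- character(nrow(out))
  out$conflict <- logical(nrow(out))
  if (nrow(out) == 0) return(out)
  akey <- variant_key(assoc)
  vkey <- variant_key(survivors)
  pidx <- panel_match(survivors$gene, panel)
  for (i in seq_len(nrow(out))) {
    ai <- match(vkey[i], akey)
    a <- if (is.na(ai)) NULL else list(ps4 = assoc$ps4[ai])
    pe <- if (is.na(pidx[i])) NULL else panel[pidx[i], , drop = FALSE]
    res <- classify_variant(out[i, , drop = FALSE], a, out$db_status[i],
                            pe, cfg)
    out$evidence[i] <- format_criteria(res$evidence)
    out$label[i] <- res$classification$label
    out$fired_rule[i] <- res$classification$fired_rule
    out$conflict[i] <- res$classification$conflict
  }
  out
}
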