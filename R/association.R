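# Case-control evidence: allele-count odds ratios against reference-panel
# frequencies, Woolf (log-normal) confidence intervals with
# Haldane-Anscombe zero-cell correction, and the PS4 decision
# (OR > 5.0 with a CI excluding 1.0).

#' Reconstruct control allele counts from a panel frequency
#'
#' `control_alt = round(freq * allele_number)` (round half to even, the R
#' default), `control_ref = allele_number - control_alt`.
#'
#' @param freq allele frequency in \[0, 1\].
#' @param allele_number total control alleles (> 0).
#' @return named numeric vector `c(control_alt, control_ref)`.
#' @export
control_counts_from_frequency <- function(freq, allele_number) {
  if (is.na(freq) || freq < 0 || freq > 1)
    stop("freq must lie in [0, 1]", call. = FALSE)
  stopifnot(allele_number > 0)
  alt <- round(freq * allele_number)
  c(control_alt = alt, control_ref = allele_number - alt)
}

#' Build a 2x2 allele-count table
#' @param case_alt,case_ref,control_alt,control_ref non-negative allele
#'   counts; cases must have at least one allele.
#' @return list of class `epivar_counts`.
#' @export
allele_counts <- function(case_alt, case_ref, control_alt, control_ref) {
  x <- c(case_alt = unname(case_alt), case_ref = unname(case_ref),
         control_alt = unname(control_alt), control_ref = unname(control_ref))
  if (any(is.na(x)) || any(x < 0))
    stop("allele counts must be non-negative", call. = FALSE)
  if (case_alt + case_ref <= 0)
    stop("cases must contribute at least one allele", call. = FALSE)
  structure(as.list(x), class = "epivar_counts")
}

# Haldane-Anscombe: add 0.5 to every cell when any cell is zero
.correct_cells <- function(c) {
  cells <- unlist(c[c("case_alt", "case_ref", "control_alt", "control_ref")])
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  list(cells = cells, corrected = corrected)
}

#' Odds ratio of a 2x2 allele-count table
#'
#' `(case_alt * control_ref) / (case_ref * control_alt)`, with the
#' Haldane-Anscombe +0.5 correction applied to all cells when any cell is
#' zero. When the variant is declared unobserved in the control panel
#' (`control_absent = TRUE`), the OR is missing rather than corrected.
#'
#' @param c an [allele_counts()] table.
#' @param control_absent logical; control data absent (variant never looked
#'   up / unobserved in any panel).
#' @return list with `or` (numeric or `NA`) and `zero_cell_corrected`.
#' @export
odds_ratio <- function(c, control_absent = FALSE) {
  if (control_absent && c$control_alt == 0)
    return(list(or = NA_real_, zero_cell_corrected = FALSE))
  cells <- unlist(c[c("case_alt", "case_ref", "control_alt", "control_ref")])
  if (all(cells == 0)) stop("all-zero 2x2 table", call. = FALSE)
  cc <- .correct_cells(c)
  x <- cc$cells
  list(or = unname((x[["case_alt"]] * x[["control_ref"]]) /
                   (x[["case_ref"]] * x[["control_alt"]])),
       zero_cell_corrected = cc$corrected)
}

#' Woolf confidence interval for an odds ratio
#'
#' `exp(ln OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))` on the (zero-cell
#' corrected) cells, with `z` the standard-normal quantile at the stated
#' level.
#'
#' @param c an [allele_counts()] table.
#' @param level confidence level in (0, 1).
#' @param control_absent as in [odds_ratio()].
#' @return named numeric vector `c(ci_low, ci_high)` (`NA` when the OR is
#'   missing).
#' @export
woolf_ci <- function(c, level = 0.95, control_absent = FALSE) {
  orr <- odds_ratio(c, control_absent)
  if (is.na(orr$or)) return(c(ci_low = NA_real_, ci_high = NA_real_))
  x <- .correct_cells(c)$cells
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(sum(1 / x))
  lo <- log(orr$or)
  c(ci_low = exp(lo - z * se), ci_high = exp(lo + z * se))
}

#' Full association result for one variant
#'
#' @param c an [allele_counts()] table.
#' @param cfg an [pipeline_config()] object (gives `ci_level` and the PS4
#'   threshold).
#' @param control_absent as in [odds_ratio()].
#' @return list of class `epivar_assoc`: `or_value`, `ci_low`, `ci_high`,
#'   `ci_level`, `ps4`, `zero_cell_corrected`.
#' @export
assoc_result <- function(c, cfg = pipeline_config(), control_absent = FALSE) {
  orr <- odds_ratio(c, control_absent)
  ci <- woolf_ci(c, cfg$ci_level, control_absent)
  r <- structure(list(or_value = unname(orr$or),
                      ci_low = unname(ci["ci_low"]),
                      ci_high = unname(ci["ci_high"]),
                      ci_level = cfg$ci_level,
                      ps4 = FALSE,
                      zero_cell_corrected = orr$zero_cell_corrected),
                 class = "epivar_assoc")
  r$ps4 <- ps4_decision(r, cfg)
  r
}

#' PS4 decision
#'
#' Case-control prevalence evidence: true iff the odds ratio exceeds
#' `cfg$or_threshold` and the confidence interval excludes 1.0. A missing
#' OR (variant absent from controls) is never PS4.
#'
#' @param r an `epivar_assoc` result (or any list with `or_value`,
#'   `ci_low`, `ci_high`).
#' @param cfg an [pipeline_config()] object.
#' @return logical.
#' @export
ps4_decision <- function(r, cfg = pipeline_config()) {
  if (is.na(r$or_value) || is.na(r$ci_low) || is.na(r$ci_high)) return(FALSE)
  r$or_value > cfg$or_threshold && (r$ci_low > 1 || r$ci_high < 1)
}

#' Per-variant case-control association over a cohort
#'
#' Counts case alleles per distinct variant across the cohort (a
#' heterozygote contributes one alternate allele, a homozygote two; the
#' case allele number is twice the patient count), reconstructs control
#' counts from the `cfg$control_panel` rows of the frequency table, and
#' computes OR, Woolf CI, and PS4 per variant. A variant with no row in
#' the control panel has a missing OR and never fires PS4.
#'
#' @param survivors an `epivar_variants` table (typically cascade
#'   survivors).
#' @param freqs frequency table from [read_frequency_table()].
#' @param n_patients number of screened patients (cases).
#' @param cfg an [pipeline_config()] object.
#' @return data.frame keyed by `chrom`, `pos`, `ref`, `alt` with columns
#'   `case_alt`, `case_ref`, `control_alt`, `control_ref`, `or_value`,
#'   `ci_low`, `ci_high`, `ps4`, `zero_cell_corrected`, `control_absent`.
#' @export
associate_variants <- function(survivors, freqs, n_patients,
                               cfg = pipeline_config()) {
  key <- variant_key(survivors)
  alt_per_call <- ifelse(survivors$genotype == "hom_alt", 2L, 1L)
  case_alt <- tapply(alt_per_call, key, sum)
  uniq <- survivors[!duplicated(key), c("chrom", "pos", "ref", "alt")]
  ukey <- variant_key(uniq)
  uniq$case_alt <- as.integer(case_alt[ukey])
  uniq$case_ref <- 2L * n_patients - uniq$case_alt

  ctrl <- freqs[tolower(freqs$panel) == tolower(cfg$control_panel), ,
                drop = FALSE]
  ckey <- variant_key(ctrl)
  m <- match(ukey, ckey)
  out <- uniq
  nu <- nrow(out)
  out$control_alt <- rep(NA_real_, nu)
  out$control_ref <- rep(NA_real_, nu)
  out$or_value <- rep(NA_real_, nu)
  out$ci_low <- rep(NA_real_, nu)
  out$ci_high <- rep(NA_real_, nu)
  out$ps4 <- rep(FALSE, nu)
  out$zero_cell_corrected <- rep(FALSE, nu)
  ctrl_af <- if (nrow(ctrl)) ctrl$af[ifelse(is.na(m), 1L, m)] else
    rep(NA_real_, nu)
  out$control_absent <- is.na(m) | is.na(ctrl_af)
  for (i in seq_len(nrow(out))) {
    if (out$control_absent[i]) next
    an <- ctrl$allele_number[m[i]]
    if (is.na(an)) an <- cfg$control_allele_number_default
    cc <- control_counts_from_frequency(ctrl$af[m[i]], an)
    tab <- allele_counts(out$case_alt[i], out$case_ref[i],
                         cc["control_alt"], cc["control_ref"])
    r <- assoc_result(tab, cfg, control_absent = FALSE)
    out$control_alt[i] <- cc[["control_alt"]]
    out$control_ref[i] <- cc[["control_ref"]]
    out$or_value[i] <- r$or_value
    out$ci_low[i] <- r$ci_low
    out$ci_high[i] <- r$ci_high
    out$ps4[i] <- r$ps4
    out$zero_cell_corrected[i] <- r$zero_cell_corrected
  }
  rownames(out) <- NULL
  out
}

#' Round an odds ratio or CI bound for display
#'
#' One decimal place, half up, matching the published table's display.
#' @param x numeric vector.
#' @return numeric vector rounded for reports.
#' @export
format_or <- function(x) round_half_up(x, 1)
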