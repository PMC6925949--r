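#' Pipeline configuration
#'
#' Collects every tunable threshold of the pipeline in one validated object.
#' Defaults encode the published screen: depth >= 30x, MAF strictly > 1%
#' excluded, two or more deleteriousness votes required, GERP++ rejected-
#' substitutions cutoff 4.4, PS4 at OR > 5.0 with a 95% CI excluding 1.0,
#' and a control panel of 121,412 alleles when a site-specific allele number
#' is unavailable.
#'
#' @param min_depth minimum read depth (x) for a call to be trusted.
#' @param maf_threshold allele-frequency cutoff; variants with any panel
#'   frequency strictly above it are excluded (boundary passes).
#' @param min_deleterious_votes minimum ensemble votes (of 9 voting units)
#'   for a variant to be kept and for PP3.
#' @param gerp_deleterious_cutoff GERP++ RS score at or above which the
#'   conservation unit votes deleterious.
#' @param or_threshold odds ratio that case-control evidence must exceed
#'   for PS4.
#' @param ci_level confidence level of the Woolf interval.
#' @param control_allele_number_default control allele count used when the
#'   frequency table does not state one.
#' @param infantile_max,childhood_max upper bounds (years, inclusive) of the
#'   infantile and childhood onset strata; onset above `childhood_max` is
#'   adulthood.
#' @param pair_rule how a collapsed predictor pair votes: `"either"` (a pair
#'   is deleterious if either member is) or `"both"`.
#' @param use_pp5 logical; assign the reputable-source codes PP5/BP6.
#' @param control_panel name of the frequency panel used as the case-control
#'   comparator (matched case-insensitively).
#' @param seed integer seed recorded for downstream generators.
#'
#' @return an object of class `epivar_config` (a validated named list).
#' @examples
#' cfg <- pipeline_config()
#' cfg$min_depth
#' @export
pipeline_config <- function(min_depth = 30,
                            maf_threshold = 0.01,
                            min_deleterious_votes = 2,
                            gerp_deleterious_cutoff = 4.4,
                            or_threshold = 5.0,
                            ci_level = 0.95,
                            control_allele_number_default = 121412,
                            infantile_max = 1,
                            childhood_max = 18,
                            pair_rule = c("either", "both"),
                            use_pp5 = TRUE,
                            control_panel = "ExAC",
                            seed = 1L) {
  pair_rule <- match.arg(pair_rule)
  cfg <- list(
    min_depth = min_depth,
    maf_threshold = maf_threshold,
    min_deleterious_votes = min_deleterious_votes,
    gerp_deleterious_cutoff = gerp_deleterious_cutoff,
    or_threshold = or_threshold,
    ci_level = ci_level,
    control_allele_number_default = control_allele_number_default,
    infantile_max = infantile_max,
    childhood_max = childhood_max,
    pair_rule = pair_rule,
    use_pp5 = isTRUE(use_pp5),
    control_panel = control_panel,
    seed = as.integer(seed))
  class(cfg) <- "epivar_config"
  validate_config(cfg)
}

validate_config <- function(cfg) {
  num <- c("min_depth", "maf_threshold", "min_deleterious_votes",
           "gerp_deleterious_cutoff", "or_threshold", "ci_level",
           "control_allele_number_default")
  for (f in num) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0)
      stop("config field '", f, "' must be a single positive number",
           call. = FALSE)
  }
  if (cfg$ci_level >= 1)
    stop("ci_level must be in (0, 1)", call. = FALSE)
  if (cfg$infantile_max < 0 || cfg$childhood_max <= cfg$infantile_max)
    stop("onset strata bounds must satisfy 0 <= infantile_max < childhood_max",
         call. = FALSE)
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected so that typos do not silently fall back to
#' defaults; absent keys take the [pipeline_config()] defaults.
#'
#' @param path path to a YAML file whose keys mirror [pipeline_config()]
#'   arguments.
#' @return an `epivar_config` object.
#' @export
read_config_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  do.call(pipeline_config, raw)
}

#' Write a pipeline configuration as YAML
#'
#' @param cfg an `epivar_config` object.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_config_yaml <- function(cfg, path) {
  stopifnot(inherits(cfg, "epivar_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @export
print.epivar_config <- function(x, ...) {
  cat("<epivar pipeline configuration>\n")
  for (f in names(x)) cat(sprintf("  %-30s %s\n", f, format(x[[f]])))
  invisible(x)
}

# round half away from zero, as printed percentages in clinical reports are
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
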