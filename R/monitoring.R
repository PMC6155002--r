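# Long-term full-scale-system summaries: removal-efficiency series,
# per-OTU relative and biomass-scaled absolute abundances, yearly means,
# and alpha diversity of each library.

#' Yearly mean relative abundance of an OTU at a location
#'
#' Unweighted arithmetic mean over sampling dates.
#'
#' @param abundance Long tibble with columns `date`, `location`, `otu_id`,
#'   `relative_abundance_percent`.
#' @param otu_id OTU to average.
#' @param location `"aeration_tank"` or `"return_line"`.
#' @return Mean relative abundance (percent).
#' @export
yearly_mean_abundance <- function(abundance, otu_id,
                                  location = c("aeration_tank", "return_line")) {
  location <- match.arg(location)
  if (!otu_id %in% abundance$otu_id) stop("unknown OTU: ", otu_id)
  sel <- abundance$otu_id == otu_id & abundance$location == location
  if (!any(sel)) stop("no records for OTU ", otu_id, " at ", location)
  mean(abundance$relative_abundance_percent[sel])
}

#' Biomass-scaled absolute abundance
#'
#' Scales a relative abundance by the mixed liquor suspended solids
#' (MLSS), the total-biomass proxy of activated sludge.
#'
#' @param relative_percent Relative abundance (percent, >= 0).
#' @param mlss_mg_per_l MLSS (mg/l, >= 0).
#' @return Abundance in MLSS mg/l equivalents.
#' @export
#' @examples
#' absolute_abundance(1, 10100)  # 101
absolute_abundance <- function(relative_percent, mlss_mg_per_l) {
  if (any(relative_percent < 0) || any(mlss_mg_per_l < 0))
    stop("inputs must be >= 0")
  relative_percent / 100 * mlss_mg_per_l
}

#' Alpha diversity of one library
#'
#' Chao1 richness (classic estimator, S_obs + F1^2/(2 F2), with the
#' F2 = 0 fallback S_obs + F1(F1-1)/2), Shannon entropy (natural log by
#' default) and the reciprocal Simpson index, plus the observed richness
#' and singleton/doubleton counts.
#'
#' @param counts Non-negative integer count vector for one library
#'   (total > 0).
#' @param log_base Base of the Shannon logarithm (default `exp(1)`).
#' @return A one-row tibble: `s_obs`, `f1`, `f2`, `chao1`, `shannon`,
#'   `simpson_reciprocal`, `library_size`.
#' @export
#' @examples
#' alpha_diversity(rep(5L, 8))  # chao1 = 8, shannon = log(8)
alpha_diversity <- function(counts, log_base = exp(1)) {
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  total <- sum(counts)
  if (total == 0) stop("empty library: total count is 0")
  counts <- counts[counts > 0]
  s_obs <- length(counts)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  chao1 <- if (f2 > 0) s_obs + f1^2 / (2 * f2) else s_obs + f1 * (f1 - 1) / 2
  p <- counts / total
  shannon <- -sum(p * log(p, base = log_base))
  tibble::tibble(s_obs = s_obs, f1 = f1, f2 = f2, chao1 = chao1,
                 shannon = shannon, simpson_reciprocal = 1 / sum(p^2),
                 library_size = total)
}

#' Summarize full-scale system monitoring
#'
#' Aligns the reactor chemistry with the community data: computes the
#' per-date removal-efficiency series, per-OTU relative and MLSS-scaled
#' absolute abundance series, yearly mean abundances per OTU and
#' location, and per-library alpha diversity.
#'
#' @param env Tibble with one row per (date, location):
#'   `date`, `location`, `mlss_mg_per_l`, `influent_dioxane_mg_per_l`,
#'   `effluent_dioxane_mg_per_l` (additional physicochemical columns are
#'   carried through).
#' @param abundance Long tibble with `date`, `location`, `otu_id`,
#'   `relative_abundance_percent`.
#' @param counts Optional OTU x library count matrix whose columns are
#'   `date|location` keys, for alpha diversity.
#' @return A list with `efficiency`, `series`, `yearly` and (if `counts`
#'   given) `diversity` tibbles.
#' @export
summarize_monitoring <- function(env, abundance, counts = NULL) {
  if (anyDuplicated(paste(env$date, env$location)))
    stop("duplicate (date, location) rows in env")
  efficiency <- dplyr::mutate(
    env,
    removal_efficiency_percent = removal_efficiency(
      .data$influent_dioxane_mg_per_l, .data$effluent_dioxane_mg_per_l))
  series <- abundance |>
    dplyr::left_join(
      dplyr::select(env, "date", "location", "mlss_mg_per_l"),
      by = c("date", "location")) |>
    dplyr::mutate(absolute_abundance_mg_per_l = absolute_abundance(
      .data$relative_abundance_percent, .data$mlss_mg_per_l))
  yearly <- abundance |>
    dplyr::group_by(.data$otu_id, .data$location) |>
    dplyr::summarise(
      yearly_mean_percent = mean(.data$relative_abundance_percent),
      n_dates = dplyr::n(), .groups = "drop")
  out <- list(efficiency = efficiency, series = series, yearly = yearly)
  if (!is.null(counts)) {
    counts <- validate_count_matrix(counts)
    out$diversity <- dplyr::bind_rows(lapply(colnames(counts), function(lib) {
      dplyr::bind_cols(tibble::tibble(library_id = lib),
                       alpha_diversity(counts[, lib]))
    }))
  }
  out
}
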