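# Fraction-matched incorporator detection: for every OTU and every heavy
# fraction, compare replicate relative abundances between the 13C and
# unlabeled gradients with a pooled-variance Student's t-test and a
# fold-change floor. This is the core inference of high-sensitivity
# rRNA-SIP: a taxon whose rRNA is significantly enriched in a heavy
# fraction of the labeled treatment is called a 13C incorporator.

#' Assign fraction labels to libraries by buoyant density
#'
#' Labels each library with the fraction window containing its buoyant
#' density; densities outside all windows are labeled `"unassigned"`.
#' Libraries with a pre-existing label are relabeled from their density.
#'
#' @param metadata Library metadata tibble (see [read_count_table()]).
#' @param windows Fraction windows; overlapping windows are a
#'   configuration error.
#' @return `metadata` with `fraction_label` filled.
#' @export
assign_fraction_windows <- function(metadata, windows = default_fraction_windows()) {
  validate_fraction_windows(windows)
  bd <- metadata$buoyant_density
  lab <- rep("unassigned", length(bd))
  for (w in names(windows)) {
    win <- windows[[w]]
    hit <- !is.na(bd) & bd >= win[1] & bd <= win[2]
    lab[hit] <- w
  }
  metadata$fraction_label <- lab
  metadata
}

#' Select the unlabeled comparator fraction
#'
#' The unlabeled-treatment fraction against which a heavy 13C fraction is
#' compared: the same label when available, otherwise the nearest lighter
#' heavy fraction present. The light (L) fraction is never used as a
#' comparator; if no heavy comparator exists the fraction is skipped with
#' a warning.
#'
#' @param fraction_label One of "1H", "2H", "3H".
#' @param available_unlabeled_labels Fraction labels present (with enough
#'   replicates) in the unlabeled treatment.
#' @return The comparator label, or `NA_character_` (with a warning) if
#'   none is eligible.
#' @export
#' @examples
#' select_comparator("1H", c("2H", "3H", "L"))  # "2H"
select_comparator <- function(fraction_label, available_unlabeled_labels) {
  fraction_label <- match.arg(fraction_label, HEAVY_FRACTIONS)
  if (!length(available_unlabeled_labels)) stop("no available unlabeled labels")
  heavy_avail <- intersect(HEAVY_FRACTIONS, available_unlabeled_labels)
  if (fraction_label %in% heavy_avail) return(fraction_label)
  pos <- match(fraction_label, HEAVY_FRACTIONS)
  lighter <- HEAVY_FRACTIONS[seq_along(HEAVY_FRACTIONS) > pos]
  cand <- intersect(lighter, heavy_avail)
  if (length(cand)) return(cand[1])
  warning("no eligible unlabeled comparator for fraction ", fraction_label,
          "; skipping")
  NA_character_
}

# Pooled-variance two-sample t on vectors; returns c(t, df, p).
# Zero pooled variance: equal means -> t = 0, p = 1; unequal means ->
# t = +/-Inf, p = 0.
pooled_t <- function(x, y, one_sided = FALSE) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop("need >= 2 replicates per group")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  d <- mean(x) - mean(y)
  if (se == 0) {
    t <- if (d == 0) 0 else sign(d) * Inf
  } else {
    t <- d / se
  }
  p <- if (one_sided) pt(t, df, lower.tail = FALSE) else 2 * pt(-abs(t), df)
  c(t = t, df = df, p = p)
}

#' Compare one OTU between treatments in one fraction
#'
#' Pooled-variance Student's t-test (two-sided by default) on replicate
#' relative abundances, plus the fold change of group means with a
#' pseudo-abundance floor on the denominator. An OTU is significant when
#' p < alpha and fold change > min_fold.
#'
#' @param otu_id OTU identifier (echoed in the result).
#' @param abundances_13c,abundances_unlabeled Replicate relative
#'   abundances (percent), >= 2 values each.
#' @param alpha Significance level.
#' @param min_fold Minimum fold change.
#' @param pseudo_abundance Denominator floor (percent).
#' @param one_sided One-sided (13C greater) test if `TRUE`.
#' @return A one-row tibble (an incorporator call).
#' @export
#' @examples
#' compare_otu("x", c(2.0, 2.2, 1.8), c(1.0, 1.1, 0.9))
compare_otu <- function(otu_id, abundances_13c, abundances_unlabeled,
                        alpha = 0.05, min_fold = 1,
                        pseudo_abundance = 100 / 64000,
                        one_sided = FALSE) {
  tt <- pooled_t(abundances_13c, abundances_unlabeled, one_sided)
  m1 <- mean(abundances_13c); m2 <- mean(abundances_unlabeled)
  fold <- m1 / max(m2, pseudo_abundance)
  tibble::tibble(
    otu_id = otu_id,
    mean_13c_percent = m1,
    mean_unlabeled_percent = m2,
    fold_change = fold,
    t_statistic = tt[["t"]],
    df = tt[["df"]],
    p_value = tt[["p"]],
    significant = tt[["p"]] < alpha & fold > min_fold
  )
}

# Vectorized pooled t over the rows of two matrices (OTUs x replicates).
row_pooled_t <- function(x, y, one_sided = FALSE) {
  n1 <- ncol(x); n2 <- ncol(y)
  df <- n1 + n2 - 2
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- rowSums((x - m1)^2) / (n1 - 1)
  v2 <- rowSums((y - m2)^2) / (n2 - 1)
  se <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / df * (1 / n1 + 1 / n2))
  d <- m1 - m2
  t <- ifelse(se == 0, ifelse(d == 0, 0, sign(d) * Inf), d / se)
  p <- if (one_sided) pt(t, df, lower.tail = FALSE) else 2 * pt(-abs(t), df)
  list(m1 = unname(m1), m2 = unname(m2), t = unname(t), df = df,
       p = unname(p))
}

#' Detect 13C-incorporating OTUs
#'
#' For every OTU and every heavy fraction (1H, 2H, 3H) sequenced in the
#' 13C treatment, compares replicate relative abundances against the
#' selected unlabeled comparator fraction. OTUs absent from all libraries
#' of a comparison are skipped (never tested 0 vs 0). Calls are aggregated
#' per OTU: an incorporator is significant in at least one heavy fraction;
#' confirmation in two or more independent fraction assays is flagged
#' separately. A Benjamini-Hochberg adjusted p-value column is reported
#' for reference but does not affect the calls.
#'
#' @param counts OTU x library count matrix.
#' @param metadata Library metadata.
#' @param config A [sip_config()].
#' @return A list with `calls` (one row per OTU x fraction) and `summary`
#'   (one row per tested OTU, sorted by confirmations then maximum fold
#'   change).
#' @export
detect_incorporators <- function(counts, metadata, config = sip_config()) {
  counts <- validate_count_matrix(counts)
  validate_library_metadata(metadata, counts)
  if (!any(metadata$treatment == "unlabeled"))
    stop("metadata contains no unlabeled treatment")
  rel <- relative_abundance(counts)
  if (config$log_transform)
    rel <- log10(rel + config$pseudo_abundance)
  unl_tab <- table(metadata$fraction_label[metadata$treatment == "unlabeled"])
  avail_unl <- names(unl_tab)[unl_tab >= 2]
  calls <- list()
  for (fl in HEAVY_FRACTIONS) {
    libs13 <- metadata$library_id[metadata$treatment == "13C" &
                                    metadata$fraction_label == fl]
    if (length(libs13) < 2) next
    comp <- select_comparator(fl, avail_unl)
    if (is.na(comp)) next
    libs_unl <- metadata$library_id[metadata$treatment == "unlabeled" &
                                      metadata$fraction_label == comp]
    x <- rel[, libs13, drop = FALSE]
    y <- rel[, libs_unl, drop = FALSE]
    tested <- rowSums(counts[, c(libs13, libs_unl), drop = FALSE]) > 0
    if (!any(tested)) next
    tt <- row_pooled_t(x[tested, , drop = FALSE], y[tested, , drop = FALSE],
                       config$one_sided)
    fold <- tt$m1 / pmax(tt$m2, config$pseudo_abundance)
    calls[[fl]] <- tibble::tibble(
      otu_id = rownames(rel)[tested],
      fraction_label = fl,
      comparator_fraction_label = comp,
      n_13c = length(libs13), n_unlabeled = length(libs_unl),
      mean_13c_percent = tt$m1,
      mean_unlabeled_percent = tt$m2,
      fold_change = fold,
      t_statistic = tt$t,
      df = tt$df,
      p_value = tt$p,
      significant = tt$p < config$alpha & fold > config$min_fold
    )
  }
  if (!length(calls))
    stop("no heavy fraction with >= 2 replicates in both treatments")
  calls <- dplyr::bind_rows(calls)
  calls$p_adjusted_bh <- stats::p.adjust(calls$p_value, method = "BH")
  summary <- calls |>
    dplyr::group_by(.data$otu_id) |>
    dplyr::summarise(
      fractions_tested = dplyr::n(),
      fractions_significant = paste(
        .data$fraction_label[.data$significant], collapse = ","),
      n_confirmations = sum(.data$significant),
      max_fold_change = max(.data$fold_change),
      min_p_value = min(.data$p_value),
      .groups = "drop") |>
    dplyr::mutate(
      is_incorporator = .data$n_confirmations >= 1,
      multi_fraction_confirmed = .data$n_confirmations >= 2) |>
    dplyr::arrange(dplyr::desc(.data$n_confirmations),
                   dplyr::desc(.data$max_fold_change))
  list(calls = calls, summary = summary)
}
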