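# Per-OTU rRNA expression over the SIP time course: qPCR totals scaled by
# amplicon relative abundances, qPCR standard-curve fitting, and
# trajectory classification by a one- vs two-segment BIC contest.

#' Per-OTU rRNA molecules from qPCR totals and relative abundance
#'
#' @param total_copies_per_ml Total bacterial 16S rRNA copies/ml (>= 0).
#' @param relative_abundance_percent Relative abundance of the OTU
#'   (percent, 0-100).
#' @return Estimated copies/ml for the OTU.
#' @export
#' @examples
#' rrna_molecules(5.9e13, 0.5)  # 2.95e11
rrna_molecules <- function(total_copies_per_ml, relative_abundance_percent) {
  if (any(total_copies_per_ml < 0) || any(relative_abundance_percent < 0))
    stop("inputs must be >= 0")
  if (any(relative_abundance_percent > 100))
    stop("relative_abundance_percent must be <= 100")
  total_copies_per_ml * relative_abundance_percent / 100
}

#' Fit a qPCR standard curve
#'
#' Ordinary least squares of quantification cycle (Cq) on log10 template
#' copies over a serial dilution series. Amplification efficiency is
#' 10^(-1/slope) - 1 (1 = perfect doubling per cycle).
#'
#' @param log10_copies log10 copy numbers of the standards (>= 3 points
#'   spanning >= 2 orders of magnitude).
#' @param cq_values Measured Cq values.
#' @return A list of class `standard_curve` with `slope`, `intercept`,
#'   `r_squared` and `efficiency`.
#' @export
#' @examples
#' fit_standard_curve(4:8, 40 - log10(2)^-1 * 0 - 3.3219 * (4:8))
fit_standard_curve <- function(log10_copies, cq_values) {
  if (length(log10_copies) != length(cq_values))
    stop("log10_copies and cq_values must have equal length")
  if (length(log10_copies) < 3)
    stop("standard curve needs >= 3 dilution points")
  if (diff(range(log10_copies)) < 2)
    stop("standards must span >= 2 orders of magnitude")
  fit <- lm(cq_values ~ log10_copies)
  slope <- unname(coef(fit)[2]); intercept <- unname(coef(fit)[1])
  if (!is.finite(slope) || slope >= 0)
    stop("invalid standard curve: slope must be negative")
  # noiseless standards trip lm's perfect-fit warning; R^2 = 1 is valid
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(slope = slope, intercept = intercept, r_squared = r2,
                 efficiency = 10^(-1 / slope) - 1),
            class = "standard_curve")
}

#' Copy number from a Cq value and a fitted standard curve
#'
#' @param cq Quantification cycle value(s).
#' @param curve A [fit_standard_curve()] result.
#' @return Template copies, 10^((Cq - intercept)/slope).
#' @export
copies_from_cq <- function(cq, curve) {
  10^((cq - curve$intercept) / curve$slope)
}

#' Classify an rRNA expression trajectory
#'
#' Labels a per-OTU copies-per-ml time series as `"none"` (maximum below
#' the noise floor, or non-increasing overall trend), `"linear_increase"`
#' (a single rising line) or `"two_step"` (a broken-stick with one
#' breakpoint at an interior observed time wins a BIC contest against the
#' single line). The broken-stick alternative represents an accelerating
#' two-step rise, so its slope change is constrained positive (a second
#' rise resuming after a plateau); BIC is n log(RSS/n) + k log(n) with
#' k = 3 for the line (intercept, slope, residual scale) and k = 6 for
#' the broken stick (+ slope change, plus a two-parameter charge for the
#' discretely optimized breakpoint, which buys more flexibility than a
#' regular coefficient).
#'
#' @param times_h Sampling times (h, >= 4 points, ascending).
#' @param copies_per_ml Copy numbers at those times.
#' @param noise_floor Values series with maximum below this are "none".
#' @return One of "none", "linear_increase", "two_step".
#' @export
#' @examples
#' classify_trajectory(c(0, 2, 4, 6, 8), c(1, 2, 3, 4, 5), 0.1)
classify_trajectory <- function(times_h, copies_per_ml, noise_floor = 0) {
  n <- length(times_h)
  if (n < 4) stop("need >= 4 time points")
  if (length(copies_per_ml) != n)
    stop("times_h and copies_per_ml must have equal length")
  if (is.unsorted(times_h, strictly = TRUE)) stop("times_h must be ascending")
  y <- copies_per_ml
  if (max(y) < noise_floor) return("none")
  fit1 <- lm(y ~ times_h)
  # slope must raise the series by more than numerical noise over the
  # sampled span to count as an increase
  if (coef(fit1)[2] * diff(range(times_h)) <= 1e-9 * max(abs(y)))
    return("none")
  rss1 <- sum(fit1$residuals^2)
  scale <- sum(y^2)
  if (rss1 <= 1e-12 * scale) return("linear_increase")
  breaks <- times_h[-c(1, n)]
  rss2 <- min(vapply(breaks, function(b) {
    hinge <- pmax(0, times_h - b)
    fit2 <- lm(y ~ times_h + hinge)
    if (is.na(coef(fit2)[3]) || coef(fit2)[3] <= 0) return(Inf)
    sum(fit2$residuals^2)
  }, numeric(1)))
  if (!is.finite(rss2)) return("linear_increase")
  bic1 <- n * log(rss1 / n) + 3 * log(n)
  bic2 <- n * log(max(rss2, 1e-12 * scale) / n) + 6 * log(n)
  if (bic2 < bic1) "two_step" else "linear_increase"
}

#' Estimate and classify per-OTU expression series
#'
#' Combines qPCR totals with per-time amplicon relative abundances to
#' estimate each target OTU's rRNA copies/ml over the time course, then
#' classifies each trajectory. The default noise floor is 1% of the
#' maximum total copy number observed, flagging OTUs with no measurable
#' expression.
#'
#' @param totals Tibble with `time_h` and `total_copies_per_ml`.
#' @param counts OTU x time count matrix (columns in the order of
#'   `totals$time_h`).
#' @param otu_ids OTUs to estimate (default: all rows of `counts`).
#' @param noise_floor Copies/ml floor for the "none" label; default
#'   `0.01 * max(totals$total_copies_per_ml)`.
#' @return A tibble with one row per OTU x time (`otu_id`, `time_h`,
#'   `relative_abundance_percent`, `copies_per_ml`, `shape`).
#' @export
estimate_expression <- function(totals, counts, otu_ids = rownames(counts),
                                noise_floor = NULL) {
  if (ncol(counts) != nrow(totals))
    stop("counts must have one column per time point")
  missing_otus <- setdiff(otu_ids, rownames(counts))
  if (length(missing_otus))
    stop("unknown OTU(s): ", paste(missing_otus, collapse = ", "))
  if (is.null(noise_floor))
    noise_floor <- 0.01 * max(totals$total_copies_per_ml)
  rel <- relative_abundance(counts)
  out <- lapply(otu_ids, function(o) {
    copies <- rrna_molecules(totals$total_copies_per_ml, rel[o, ])
    tibble::tibble(
      otu_id = o, time_h = totals$time_h,
      relative_abundance_percent = unname(rel[o, ]),
      copies_per_ml = unname(copies),
      shape = classify_trajectory(totals$time_h, copies, noise_floor))
  })
  dplyr::bind_rows(out)
}
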