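#' @keywords internal
"_PACKAGE"

#' @importFrom stats lm coef pnorm pt rlnorm rmultinom runif rnorm setNames var
#' @importFrom utils read.delim write.table
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr .data
NULL

TREATMENTS <- c("13C", "unlabeled", "heat_killed")
FRACTION_LABELS <- c("1H", "2H", "3H", "L", "unassigned")
HEAVY_FRACTIONS <- c("1H", "2H", "3H")

#' Default buoyant-density fraction windows
#'
#' Closed CsTFA buoyant-density intervals (g/ml) delimiting the heaviest
#' (1H), second-heaviest (2H), third-heaviest (3H) and light (L) RNA
#' fractions analyzed in a gradient, ordered from heavy to light.
#'
#' @return Named list of length-2 numeric vectors `c(lower, upper)`.
#' @export
#' @examples
#' default_fraction_windows()
default_fraction_windows <- function() {
  list(
    "1H" = c(1.803, 1.808),
    "2H" = c(1.796, 1.800),
    "3H" = c(1.788, 1.793),
    "L"  = c(1.769, 1.771)
  )
}

validate_fraction_windows <- function(windows) {
  if (!is.list(windows) || is.null(names(windows)) || any(names(windows) == ""))
    stop("`windows` must be a named list of c(lower, upper) intervals")
  for (nm in names(windows)) {
    w <- windows[[nm]]
    if (length(w) != 2L || !is.numeric(w) || w[1] > w[2])
      stop("window '", nm, "' must be numeric c(lower, upper) with lower <= upper")
  }
  nms <- names(windows)
  if (anyDuplicated(nms)) stop("duplicate window labels")
  if (length(windows) > 1L) {
    for (i in seq_along(windows)) for (j in seq_along(windows)) {
      if (i >= j) next
      a <- windows[[i]]; b <- windows[[j]]
      if (a[1] <= b[2] && b[1] <= a[2])
        stop("fraction windows '", nms[i], "' and '", nms[j], "' overlap")
    }
  }
  # sorted heavy to light
  lows <- vapply(windows, `[`, numeric(1), 1)
  if (is.unsorted(rev(lows), strictly = TRUE))
    stop("fraction windows must be sorted descending by buoyant density")
  invisible(windows)
}

#' Pipeline configuration
#'
#' Bundles the tunable parameters shared by the pipeline stages: the
#' buoyant-density fraction windows, the significance level and minimum
#' fold change of the incorporator test, the pseudo-abundance floor used
#' for fold-change denominators, the random seed, and the log level.
#'
#' @param windows Named list of buoyant-density windows, heavy to light
#'   (see [default_fraction_windows()]).
#' @param alpha Significance level of the per-OTU t-test (0 < alpha < 1).
#' @param min_fold Minimum 13C/unlabeled mean-abundance ratio required in
#'   addition to significance (>= 1; default 1 means any enrichment).
#' @param pseudo_abundance Floor (percent) for the fold-change denominator;
#'   default corresponds to a single read at 64,000 reads per library.
#' @param one_sided If `TRUE`, the t-test is one-sided (13C greater);
#'   default two-sided.
#' @param log_transform If `TRUE`, compare log10 abundances (pseudo-counted)
#'   instead of raw percentages; default off.
#' @param seed Integer seed from which all pipeline randomness flows.
#' @param log_level One of "DEBUG", "INFO", "WARN", "ERROR".
#' @return A list of class `sip_config`.
#' @export
#' @examples
#' cfg <- sip_config(alpha = 0.01)
#' cfg$windows[["1H"]]
sip_config <- function(windows = default_fraction_windows(),
                       alpha = 0.05,
                       min_fold = 1,
                       pseudo_abundance = 100 / 64000,
                       one_sided = FALSE,
                       log_transform = FALSE,
                       seed = 1L,
                       log_level = "INFO") {
  validate_fraction_windows(windows)
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1)
  stopifnot(is.numeric(min_fold), length(min_fold) == 1L, min_fold >= 1)
  stopifnot(is.numeric(pseudo_abundance), pseudo_abundance > 0)
  log_level <- match.arg(log_level, c("DEBUG", "INFO", "WARN", "ERROR"))
  structure(
    list(windows = windows, alpha = alpha, min_fold = min_fold,
         pseudo_abundance = pseudo_abundance, one_sided = isTRUE(one_sided),
         log_transform = isTRUE(log_transform), seed = as.integer(seed),
         log_level = log_level),
    class = "sip_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' The file is a flat key-value mapping; recognised keys are the arguments
#' of [sip_config()], with windows given as `windows: {1H: [1.803, 1.808], ...}`.
#' Unknown keys raise an error.
#'
#' @param path Path to a YAML (or flat `key: value`) file.
#' @return A `sip_config` list.
#' @export
read_sip_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(sip_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  if (!is.null(raw$windows)) raw$windows <- lapply(raw$windows, as.numeric)
  do.call(sip_config, raw)
}

#' Write a pipeline configuration to a YAML file
#' @param config A `sip_config` list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sip_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

.log_levels <- c(DEBUG = 1L, INFO = 2L, WARN = 3L, ERROR = 4L)

#' Log a message to stderr with an ISO-8601 timestamp
#'
#' Messages below the threshold level (option `rrnasip.log_level`,
#' default "INFO") are suppressed.
#'
#' @param ... Message parts, pasted together.
#' @param level One of "DEBUG", "INFO", "WARN", "ERROR".
#' @return `NULL`, invisibly.
#' @export
sip_log <- function(..., level = "INFO") {
  level <- match.arg(level, names(.log_levels))
  threshold <- getOption("rrnasip.log_level", "INFO")
  if (.log_levels[[level]] < .log_levels[[threshold]]) return(invisible(NULL))
  stamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  message(sprintf("[%s] %s %s", stamp, level, paste0(..., collapse = "")))
  invisible(NULL)
}

#' Validate an OTU-by-library count matrix
#'
#' Checks that counts are a non-negative integer-valued matrix with unique,
#' non-missing OTU row names and library column names.
#'
#' @param counts Numeric matrix, taxa as rows, libraries as columns.
#' @return `counts`, invisibly, with integer storage.
#' @export
validate_count_matrix <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("counts must be a numeric matrix (taxa x libraries)")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have OTU row names and library column names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate otu_ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate library_ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  bad <- which(is.na(counts) | counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("invalid count at row '", rownames(counts)[bad[1, 1]],
         "', column '", colnames(counts)[bad[1, 2]],
         "': counts must be non-negative integers")
  }
  storage.mode(counts) <- "integer"
  invisible(counts)
}

validate_library_metadata <- function(metadata, counts = NULL) {
  req <- c("library_id", "treatment", "replicate", "fraction_label",
           "buoyant_density")
  miss <- setdiff(req, names(metadata))
  if (length(miss)) stop("metadata missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(metadata$library_id))
    stop("duplicate library_id in metadata: ",
         paste(unique(metadata$library_id[duplicated(metadata$library_id)]),
               collapse = ", "))
  bad_tr <- setdiff(unique(metadata$treatment), TREATMENTS)
  if (length(bad_tr)) stop("unknown treatment(s): ", paste(bad_tr, collapse = ", "))
  bad_fl <- setdiff(unique(metadata$fraction_label), FRACTION_LABELS)
  if (length(bad_fl)) stop("unknown fraction_label(s): ", paste(bad_fl, collapse = ", "))
  if (any(!is.na(metadata$replicate) &
          (metadata$replicate < 1 | metadata$replicate != round(metadata$replicate))))
    stop("replicate must be a positive integer")
  bd <- metadata$buoyant_density
  off <- which(!is.na(bd) & (bd < 1.60 | bd > 1.90))
  if (length(off))
    stop("buoyant_density outside [1.60, 1.90] for library ",
         paste(metadata$library_id[off], collapse = ", "))
  assigned <- metadata$fraction_label != "unassigned"
  key <- paste(metadata$treatment, metadata$replicate,
               metadata$fraction_label)[assigned]
  if (anyDuplicated(key))
    stop("duplicate (treatment, replicate, fraction_label) triple: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  if (!is.null(counts)) {
    unmatched <- setdiff(metadata$library_id, colnames(counts))
    if (length(unmatched))
      stop("metadata libraries absent from count table: ",
           paste(unmatched, collapse = ", "))
  }
  invisible(metadata)
}

#' Read an OTU count table and its library metadata
#'
#' The count table is tab-separated with a header row of library ids and a
#' first column `otu_id`; the metadata table has one row per library with
#' columns `library_id`, `treatment`, `replicate`, `fraction_label` and
#' `buoyant_density` (g/ml). Both are validated; unmatched or malformed
#' entries raise an error naming the offenders.
#'
#' @param path Path to the tab-separated count table.
#' @param metadata_path Path to the tab-separated metadata table, or `NULL`
#'   to read counts only.
#' @return A list with elements `counts` (integer matrix) and `metadata`
#'   (tibble, or `NULL`).
#' @export
read_count_table <- function(path, metadata_path = NULL) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!ncol(tab) || names(tab)[1] != "otu_id")
    stop("count table must have 'otu_id' as its first column")
  counts <- as.matrix(tab[, -1, drop = FALSE])
  rownames(counts) <- as.character(tab[[1]])
  counts <- validate_count_matrix(counts)
  metadata <- NULL
  if (!is.null(metadata_path)) {
    metadata <- as_tibble(read.delim(metadata_path, check.names = FALSE,
                                     stringsAsFactors = FALSE))
    metadata$library_id <- as.character(metadata$library_id)
    validate_library_metadata(metadata, counts)
  }
  list(counts = counts, metadata = metadata)
}

#' Write an OTU count table (tab-separated, canonical formatting)
#' @param counts Validated count matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(counts, path) {
  counts <- validate_count_matrix(counts)
  df <- data.frame(otu_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a library metadata table (tab-separated)
#' @param metadata Library metadata tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_library_metadata <- function(metadata, path) {
  validate_library_metadata(metadata)
  write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-library relative abundances (percent)
#'
#' Converts a count matrix to percentages of the per-library total, the
#' scale on which incorporator comparisons are made. Every column of the
#' result sums to 100.
#'
#' @param counts Count matrix (taxa x libraries).
#' @return Numeric matrix of percentages with the same dimnames.
#' @export
#' @examples
#' m <- matrix(c(20038L, 79962L), 2, 1,
#'             dimnames = list(c("a", "b"), "lib1"))
#' relative_abundance(m)
relative_abundance <- function(counts) {
  counts <- validate_count_matrix(counts)
  tot <- colSums(counts)
  zero <- names(tot)[tot == 0]
  if (length(zero))
    stop("library with zero total count: ", paste(zero, collapse = ", "))
  sweep(counts, 2, tot, "/") * 100
}
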