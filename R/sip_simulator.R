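# Synthetic rRNA-SIP experiment generator: lognormal community, isotopic
# labeling as a buoyant-density shift, Gaussian band broadening in the
# gradient, multinomial sequencing, qPCR totals, and a deterministic
# closed-vial chemistry series. Every stochastic step draws from the RNG
# stream seeded once in `simulate_gradients()` / the scenario seed.

#' Simulation scenario for a density-gradient SIP experiment
#'
#' Encodes the study conditions being emulated: triplicate gradients per
#' treatment, ~64,000 reads per library, a lognormal community of 200
#' OTUs, and five seeded incorporators spanning atom-fraction excess
#' 0.5-0.99 at baseline abundances 0.1-2%. Density parameters place
#' unlabeled rRNA near the light window (mean buoyant density ~1.775 g/ml,
#' band spread 0.008 g/ml) and shift fully labeled rRNA by 0.035 g/ml.
#'
#' @param n_otus Number of OTUs (>= 2).
#' @param lognormal_sigma sdlog of the lognormal baseline community.
#' @param depth Reads per sequenced library (> 0).
#' @param replicates Gradients per treatment (>= 2).
#' @param incorporator_excess Atom-fraction excess of the seeded
#'   incorporators (each in [0, 0.99]).
#' @param incorporator_abundance Baseline relative abundances (fractions)
#'   assigned to the incorporators.
#' @param windows Fraction windows (see [default_fraction_windows()]).
#' @param sigma_bd Gaussian spread of an OTU's rRNA over buoyant density
#'   (g/ml).
#' @param max_density_shift Buoyant-density shift of fully 13C-labeled
#'   rRNA (g/ml); the shift is linear in atom-fraction excess.
#' @param bd_mean,bd_sd,bd_range Mean, sd and truncation range of the
#'   per-OTU unlabeled mean buoyant density (g/ml).
#' @param amplification_floor A fraction whose expected share of the total
#'   gradient RNA mass falls below this value yields no library
#'   (RT-PCR amplification failure).
#' @param seed Integer seed.
#' @return A list of class `sip_scenario`.
#' @export
sip_scenario <- function(n_otus = 200,
                         lognormal_sigma = 2,
                         depth = 64000,
                         replicates = 3,
                         incorporator_excess = c(0.99, 0.9, 0.8, 0.7, 0.5),
                         incorporator_abundance = c(0.02, 0.01, 0.005, 0.002, 0.001),
                         windows = default_fraction_windows(),
                         sigma_bd = 0.008,
                         max_density_shift = 0.035,
                         bd_mean = 1.775,
                         bd_sd = 0.002,
                         bd_range = c(1.768, 1.782),
                         amplification_floor = 0.005,
                         seed = 1L) {
  stopifnot(n_otus >= 2, depth > 0, replicates >= 2,
            length(incorporator_excess) == length(incorporator_abundance),
            all(incorporator_excess >= 0), all(incorporator_excess <= 0.99),
            all(incorporator_abundance > 0), sum(incorporator_abundance) < 1,
            sigma_bd > 0, max_density_shift >= 0,
            amplification_floor >= 0)
  validate_fraction_windows(windows)
  structure(
    list(n_otus = as.integer(n_otus), lognormal_sigma = lognormal_sigma,
         depth = as.integer(depth), replicates = as.integer(replicates),
         incorporator_excess = incorporator_excess,
         incorporator_abundance = incorporator_abundance,
         windows = windows, sigma_bd = sigma_bd,
         max_density_shift = max_density_shift, bd_mean = bd_mean,
         bd_sd = bd_sd, bd_range = bd_range,
         amplification_floor = amplification_floor, seed = as.integer(seed)),
    class = "sip_scenario"
  )
}

#' Simulate a lognormal community abundance profile
#'
#' @param n_otus Number of OTUs (>= 2).
#' @param lognormal_sigma sdlog of the lognormal; 0 gives a uniform
#'   community.
#' @param seed Optional seed; if `NULL` the current RNG stream is used.
#' @return Positive fractions summing to 1.
#' @export
#' @examples
#' simulate_community(5, 0)
simulate_community <- function(n_otus, lognormal_sigma, seed = NULL) {
  if (n_otus < 2) stop("n_otus must be >= 2")
  if (lognormal_sigma < 0) stop("lognormal_sigma must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  x <- rlnorm(n_otus, meanlog = 0, sdlog = lognormal_sigma)
  x / sum(x)
}

#' Ground truth of a simulated SIP experiment
#'
#' Draws the baseline community, assigns the scenario's incorporators
#' (atom-fraction excess > 0) to randomly chosen OTUs at the configured
#' baseline abundances (the remaining OTUs are rescaled to keep the total
#' at 1), and draws each OTU's unlabeled mean buoyant density from a
#' truncated normal.
#'
#' @param scenario A [sip_scenario()]. Uses the current RNG stream; seed
#'   upstream (see [simulate_gradients()]).
#' @return A list of class `simulation_truth` with `otus` (tibble:
#'   `otu_id`, `baseline`, `excess`, `bd_unlabeled`), `sigma_bd` and
#'   `max_density_shift`.
#' @export
simulation_truth <- function(scenario) {
  n <- scenario$n_otus
  k <- length(scenario$incorporator_excess)
  if (k >= n) stop("more incorporators than OTUs")
  baseline <- simulate_community(n, scenario$lognormal_sigma)
  idx <- sample.int(n, k)
  baseline[idx] <- 0
  baseline <- baseline / sum(baseline) * (1 - sum(scenario$incorporator_abundance))
  baseline[idx] <- scenario$incorporator_abundance
  excess <- numeric(n)
  excess[idx] <- scenario$incorporator_excess
  bd <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      b <- rnorm(1, scenario$bd_mean, scenario$bd_sd)
      if (b >= scenario$bd_range[1] && b <= scenario$bd_range[2]) break
    }
    bd[i] <- b
  }
  structure(
    list(otus = tibble::tibble(
           otu_id = sprintf("OTU_%04d", seq_len(n)),
           baseline = baseline, excess = excess, bd_unlabeled = bd),
         sigma_bd = scenario$sigma_bd,
         max_density_shift = scenario$max_density_shift),
    class = "simulation_truth"
  )
}

#' Expected per-OTU composition of each density-fraction window
#'
#' Each OTU's rRNA mass is a Gaussian over buoyant density centred at its
#' unlabeled mean plus `max_density_shift` times its atom-fraction excess
#' (forced to 0 outside the 13C treatment), with spread `sigma_bd`. A
#' window's expected composition is the per-OTU window integral weighted
#' by baseline abundance and renormalized within the window.
#'
#' @param truth A [simulation_truth()].
#' @param treatment `"13C"`, `"unlabeled"` or `"heat_killed"`.
#' @param windows Fraction windows.
#' @return A list with `composition` (OTU x window matrix of probability
#'   vectors), `window_mass` (expected share of the total gradient RNA
#'   mass in each window) and `integrals` (per-OTU window integrals).
#' @export
fraction_composition <- function(truth, treatment,
                                 windows = default_fraction_windows()) {
  treatment <- match.arg(treatment, TREATMENTS)
  validate_fraction_windows(windows)
  rng <- range(unlist(windows))
  if (rng[1] < 1.60 || rng[2] > 1.90)
    stop("windows must lie within [1.60, 1.90] g/ml")
  ot <- truth$otus
  excess <- if (treatment == "13C") ot$excess else rep(0, nrow(ot))
  mu <- ot$bd_unlabeled + truth$max_density_shift * excess
  integrals <- vapply(windows, function(w) {
    pnorm(w[2], mu, truth$sigma_bd) - pnorm(w[1], mu, truth$sigma_bd)
  }, numeric(nrow(ot)))
  if (any(vapply(windows, function(w) w[1] == w[2], logical(1))))
    stop("empty (zero-width) window")
  rownames(integrals) <- ot$otu_id
  mass <- integrals * ot$baseline
  window_mass <- colSums(mass)
  if (any(window_mass <= 0))
    stop("window with zero expected mass: ",
         paste(names(window_mass)[window_mass <= 0], collapse = ", "))
  composition <- sweep(mass, 2, window_mass, "/")
  list(composition = composition, window_mass = window_mass,
       integrals = integrals)
}

#' Sequence the fractions of simulated gradients
#'
#' Draws one multinomial library of `scenario$depth` reads per
#' (replicate, window) from the expected window composition. Windows whose
#' expected RNA mass share falls below the amplification floor yield no
#' library, mimicking RT-PCR failure on near-empty fractions. Buoyant
#' densities are drawn uniformly within each window and reported to 3
#' decimals.
#'
#' @param composition Result of [fraction_composition()].
#' @param scenario A [sip_scenario()].
#' @param treatment Treatment label recorded in the metadata.
#' @return A list with `counts` (OTU x library integer matrix) and
#'   `metadata` (tibble, one row per library).
#' @export
sequence_fractions <- function(composition, scenario, treatment) {
  treatment <- match.arg(treatment, TREATMENTS)
  present <- names(which(composition$window_mass >= scenario$amplification_floor))
  cols <- list(); meta <- list()
  for (r in seq_len(scenario$replicates)) {
    for (w in present) {
      p <- composition$composition[, w]
      lib <- paste(treatment, paste0("r", r), w, sep = "_")
      cols[[lib]] <- rmultinom(1, scenario$depth, p)[, 1]
      win <- scenario$windows[[w]]
      meta[[lib]] <- tibble::tibble(
        library_id = lib, treatment = treatment, replicate = r,
        fraction_label = w,
        buoyant_density = round(runif(1, win[1], win[2]), 3))
    }
  }
  counts <- do.call(cbind, cols)
  rownames(counts) <- rownames(composition$composition)
  storage.mode(counts) <- "integer"
  list(counts = counts, metadata = dplyr::bind_rows(meta))
}

#' Simulate a full density-gradient SIP sequencing experiment
#'
#' Seeds the RNG from the scenario, draws the ground truth, and sequences
#' the 13C and unlabeled gradients.
#'
#' @param scenario A [sip_scenario()].
#' @return A list with `counts`, `metadata` (both treatments combined) and
#'   `truth`.
#' @export
#' @examples
#' sim <- simulate_gradients(sip_scenario(n_otus = 20, depth = 1000, seed = 7))
#' dim(sim$counts)
simulate_gradients <- function(scenario) {
  set.seed(scenario$seed)
  truth <- simulation_truth(scenario)
  parts <- lapply(c("13C", "unlabeled"), function(tr) {
    comp <- fraction_composition(truth, tr, scenario$windows)
    sequence_fractions(comp, scenario, tr)
  })
  counts <- do.call(cbind, lapply(parts, `[[`, "counts"))
  metadata <- dplyr::bind_rows(lapply(parts, `[[`, "metadata"))
  validate_count_matrix(counts)
  validate_library_metadata(metadata, counts)
  list(counts = counts, metadata = metadata, truth = truth)
}

#' Simulate the closed-vial incubation chemistry
#'
#' Deterministic generator of the chemistry time series for the 13C,
#' unlabeled and heat-killed treatments. 1,4-dioxane declines linearly
#' after a lag; a fixed fraction of the degraded carbon is mineralized and
#' placed in the headspace-CO2 and dissolved-bicarbonate pools by a fixed
#' mass partition, while carbon isotopes equilibrate across the two pools
#' via the gaseous-CO2/bicarbonate fractionation; endogenous (unlabeled)
#' respiration adds background CO2. The mass balance closes exactly: at
#' every time, gaseous + dissolved + residual tracer carbon equals the
#' degraded tracer carbon.
#'
#' @param rate_mg_per_l_h Linear dioxane degradation rate after the lag
#'   (mg/l/h, >= 0); the default consumes ~50 mg/l over an 8-h incubation.
#' @param lag_h Lag before degradation and respiration start (h).
#' @param times Sampling times (h, ascending).
#' @param geometry A [vessel_geometry()].
#' @param mineralization_fraction Fraction of degraded carbon mineralized
#'   to inorganic carbon (the rest remains as intermediates/biomass).
#' @param gas_partition Share of mineralized carbon placed in the
#'   headspace (the rest enters the dissolved pool).
#' @param initial_dioxane_mg_per_l Starting dioxane concentration (mg/l).
#' @param initial_ic_mg_per_l Baseline dissolved inorganic carbon (mg C/l).
#' @param initial_co2_atm Initial headspace CO2 partial pressure (atm).
#' @param endogenous_co2_mmol_per_h Endogenous respiration rate after the
#'   lag (mmol CO2/h, at natural abundance).
#' @param cod0_mg_per_l COD of the sludge before substrate addition (mg/l).
#' @param cod_per_dioxane Empirical COD equivalent of dioxane (g COD per g).
#' @return A list with `samples` (tibble of per-treatment, per-time
#'   chemistry measurements) and `truth` (tibble of tracer carbon pools,
#'   mmol per vessel, for the 13C treatment).
#' @export
simulate_chemistry <- function(rate_mg_per_l_h = 50 / 6,
                               lag_h = 2,
                               times = c(0, 2, 4, 6, 8),
                               geometry = vessel_geometry(),
                               mineralization_fraction = 0.74,
                               gas_partition = 0.4174,
                               initial_dioxane_mg_per_l = 200,
                               initial_ic_mg_per_l = 136,
                               initial_co2_atm = 4e-4,
                               endogenous_co2_mmol_per_h = 0.0183,
                               cod0_mg_per_l = 27,
                               cod_per_dioxane = 2.12) {
  if (rate_mg_per_l_h < 0) stop("rate_mg_per_l_h must be >= 0")
  if (is.unsorted(times, strictly = TRUE)) stop("times must be ascending")
  stopifnot(mineralization_fraction >= 0, mineralization_fraction <= 1,
            gas_partition >= 0, gas_partition <= 1)
  k <- sip_constants()
  beta <- 1 / (1 + k$epsilon_hco3 / 1000)
  n0 <- headspace_mmol(initial_co2_atm, geometry)
  d0 <- initial_ic_mg_per_l * geometry$liquid_volume_l / k$carbon_molar_mass
  f <- mineralization_fraction
  g <- gas_partition
  one_treatment <- function(tr) {
    active <- tr != "heat_killed"
    el <- pmax(0, times - lag_h)
    decline <- if (active) pmin(initial_dioxane_mg_per_l,
                                rate_mg_per_l_h * el) else 0 * el
    c_deg <- dioxane_13c_mmol(decline, geometry$liquid_volume_l)
    c_min <- f * c_deg
    e_gas <- if (active) endogenous_co2_mmol_per_h * el else 0 * el
    n_gas <- n0 + e_gas + g * c_min
    n_dis <- d0 + (1 - g) * c_min
    a_tracer <- if (tr == "13C") k$tracer_atom_percent else
      k$background_atom_percent
    # isotopic equilibrium across the gas + bicarbonate pools:
    # N a_g + D a_d conserves 13C, with a_d = beta * a_g from the
    # epsilon relation
    a_gas <- (k$background_atom_percent * (n0 + e_gas + d0) +
                a_tracer * c_min) / (n_gas + n_dis * beta)
    tibble::tibble(
      treatment = tr, time_h = times,
      dioxane_mg_per_l = initial_dioxane_mg_per_l - decline,
      cod_mg_per_l = cod0_mg_per_l +
        cod_per_dioxane * (initial_dioxane_mg_per_l - decline),
      co2_headspace_atm = n_gas / 1000 * k$gas_constant *
        geometry$temperature_K / geometry$headspace_volume_l,
      delta13c_co2_per_mil = atom_percent_to_delta(a_gas),
      o2_headspace_atm = 0.200 - (e_gas + g * c_min) / 1000 *
        k$gas_constant * geometry$temperature_K / geometry$headspace_volume_l,
      ic_mg_per_l = n_dis * k$carbon_molar_mass / geometry$liquid_volume_l,
      ph = 8.2)
  }
  samples <- dplyr::bind_rows(lapply(TREATMENTS, one_treatment))
  el <- pmax(0, times - lag_h)
  decline <- pmin(initial_dioxane_mg_per_l, rate_mg_per_l_h * el)
  c_deg <- dioxane_13c_mmol(decline, geometry$liquid_volume_l)
  truth <- tibble::tibble(
    time_h = times,
    degraded_13c_mmol = c_deg,
    gaseous_13c_mmol = g * f * c_deg,
    dissolved_13c_mmol = (1 - g) * f * c_deg,
    residual_13c_mmol = (1 - f) * c_deg,
    mineralization_fraction = f
  )
  list(samples = samples, truth = truth)
}

#' Simulate per-OTU rRNA expression over the SIP time course
#'
#' Per-OTU rRNA copy numbers follow an assigned trajectory shape with
#' multiplicative lognormal noise:
#' \describe{
#'   \item{linear_increase}{a straight rise, baseline times
#'     (1 + rise_rate * t) across the whole incubation.}
#'   \item{two_step}{a `step_factor`-fold multiplicative rise across each
#'     of two step windows (defaults: hours 2-4 and 6-8) with a plateau
#'     between.}
#'   \item{none}{flat at baseline (0 for silent OTUs).}
#' }
#' qPCR totals are the per-time sums; one multinomial amplicon library of
#' `depth` reads is drawn per time point.
#'
#' @param shapes Tibble with columns `otu_id`, `shape` (one of
#'   "linear_increase", "two_step", "none") and `baseline_copies_per_ml`.
#' @param times Sampling times (h, ascending).
#' @param noise_sigma sdlog of the multiplicative lognormal noise.
#' @param depth Reads per per-time amplicon library.
#' @param seed Optional seed; `NULL` uses the current RNG stream.
#' @param rise_rate Linear rise per hour (1/h).
#' @param step_factor Fold rise across each step window.
#' @param step_windows List of two `c(start, end)` step windows (h).
#' @return A list with `totals` (tibble `time_h`, `total_copies_per_ml`),
#'   `counts` (OTU x time matrix), `copies` (noisy per-OTU copies/ml) and
#'   `truth` (= `shapes`).
#' @export
simulate_expression <- function(shapes, times = c(0, 2, 4, 6, 8),
                                noise_sigma = 0.1, depth = 64000,
                                seed = NULL, rise_rate = 0.5,
                                step_factor = 3,
                                step_windows = list(c(2, 4), c(6, 8))) {
  if (is.unsorted(times, strictly = TRUE)) stop("times must be ascending")
  bad <- setdiff(unique(shapes$shape), c("linear_increase", "two_step", "none"))
  if (length(bad)) stop("unknown shape label(s): ", paste(bad, collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  mult <- function(shape) {
    switch(shape,
      linear_increase = 1 + rise_rate * times,
      two_step = {
        s <- Reduce(`+`, lapply(step_windows, function(w)
          pmin(1, pmax(0, (times - w[1]) / (w[2] - w[1])))))
        step_factor^s
      },
      none = rep(1, length(times)))
  }
  expected <- t(vapply(shapes$shape, mult, numeric(length(times))))
  expected <- expected * shapes$baseline_copies_per_ml
  noise <- matrix(rlnorm(length(expected), 0, noise_sigma), nrow(expected))
  copies <- expected * noise
  dimnames(copies) <- list(shapes$otu_id, paste0("h", times))
  totals <- colSums(copies)
  counts <- vapply(seq_along(times), function(j) {
    p <- copies[, j]
    if (sum(p) == 0) return(integer(nrow(copies)))
    rmultinom(1, depth, p / sum(p))[, 1]
  }, integer(nrow(copies)))
  dimnames(counts) <- dimnames(copies)
  list(totals = tibble::tibble(time_h = times, total_copies_per_ml = totals),
       counts = counts, copies = copies, truth = shapes)
}

#' Three-shape rRNA expression benchmark truth
#'
#' Assigns the three trajectory shapes round-robin to `n_otus` OTUs.
#' Active OTUs draw lognormal baselines around 1e9 copies/ml within about
#' a decade (a degrader guild of comparable expression levels); silent
#' ("none") OTUs have zero expression, as observed for non-degraders.
#'
#' @param n_otus Number of OTUs.
#' @param seed Optional seed.
#' @return A `shapes` tibble for [simulate_expression()].
#' @export
expression_benchmark_truth <- function(n_otus = 30, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  shape <- rep(c("linear_increase", "two_step", "none"), length.out = n_otus)
  baseline <- rlnorm(n_otus, log(1e9), 0.5)
  baseline[shape == "none"] <- 0
  tibble::tibble(otu_id = sprintf("OTU_%04d", seq_len(n_otus)),
                 shape = shape, baseline_copies_per_ml = baseline)
}
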