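#' Define a native-metabolomics screen scenario
#'
#' Describes the paired acquisition the generator emulates: a native run in
#' which the apoprotein is infused post-column (charge envelope in a high m/z
#' window) and ligands eluting from the gradient form protein-ligand complex
#' envelopes mass-shifted by the ligand mass, plus a metabolomics LC-MS/MS
#' run of the same gradient carrying the [M+H]+ features and data-dependent
#' MS/MS of binders and decoys.
#'
#' @param apo_mass Apoprotein neutral mass, Da.
#' @param binders `data.frame` of planted binders (see [default_binders()]):
#'   columns `id`, `ligand_mass` (neutral Da; sets the complex mass shift),
#'   `mz` (optional [M+H]+ override for the metabolomics run), `rt` (apex,
#'   min), `width` (Gaussian sigma, min), `ratio` (complex/apo at apex),
#'   `stoichiometry`, `family`, `apex_intensity` (metabolomics side).
#' @param decoys `data.frame` of non-binding metabolite features (same
#'   columns minus `ratio`/`stoichiometry`).
#' @param z_range,z_mean,z_sd Charge envelope: range and Gaussian abundance.
#' @param gradient_min Gradient length, minutes.
#' @param scan_interval MS1 scan spacing, minutes.
#' @param mz_window Native-run acquisition window (m/z).
#' @param met_mz_window Metabolomics-run acquisition window (m/z).
#' @param apo_tic Total apoprotein ion current per scan (arbitrary units).
#' @param noise List: `intensity_sd` (log-normal sigma on peak intensities),
#'   `mz_ppm` (Gaussian m/z jitter, ppm), `floor` (additive noise-peak
#'   intensity scale), `n_noise_peaks` (noise centroids per native scan;
#'   the metabolomics run uses a fifth of this).
#' @param seed Integer seed fixing all randomness.
#' @return List of class `"screen_scenario"`.
#' @export
screen_scenario <- function(apo_mass = 25232.6,
                            binders = default_binders(),
                            decoys = default_decoys(),
                            z_range = c(6L, 11L), z_mean = 8.5, z_sd = 1.2,
                            gradient_min = 10, scan_interval = 0.02,
                            mz_window = c(2500, 4000),
                            met_mz_window = c(300, 2000),
                            apo_tic = 1e6,
                            noise = list(intensity_sd = 0.05, mz_ppm = 2,
                                         floor = 50, n_noise_peaks = 150L),
                            seed = 42L) {
  stopifnot(apo_mass > 0, gradient_min > 0, scan_interval > 0)
  if (!is.null(binders) && nrow(binders)) {
    if (any(binders$rt < 0 | binders$rt > gradient_min)) {
      stop("binder rt outside the gradient")
    }
    if (any(binders$ratio < 0)) stop("binder ratios must be >= 0")
    if (is.null(binders$mz)) binders$mz <- binders$ligand_mass + PROTON_MASS
    binders$mz <- ifelse(is.na(binders$mz), binders$ligand_mass + PROTON_MASS,
                         binders$mz)
    if (is.null(binders$stoichiometry)) binders$stoichiometry <- 1L
  }
  defaults <- list(intensity_sd = 0.05, mz_ppm = 2, floor = 50,
                   n_noise_peaks = 150L)
  noise <- utils::modifyList(defaults, as.list(noise))
  structure(list(apo_mass = apo_mass, binders = binders, decoys = decoys,
                 z_range = as.integer(z_range), z_mean = z_mean, z_sd = z_sd,
                 gradient_min = gradient_min, scan_interval = scan_interval,
                 mz_window = mz_window, met_mz_window = met_mz_window,
                 apo_tic = apo_tic, noise = noise, seed = as.integer(seed)),
            class = "screen_scenario")
}

#' Default planted binder and decoy tables
#'
#' Thirty binders with neutral masses in the cyclodepsipeptide range
#' (700-1400 Da), apexes spread over the usable gradient, Gaussian elution
#' width 0.03 min, apex complex/apo ratios between 0.2 and 0.8, grouped into
#' structural families of about five analogs that share an MS/MS fragment
#' ladder. Decoys are lighter non-binding features with unique ladders.
#'
#' @param n Number of binders (or decoys).
#' @param seed Seed for the drawn masses/RTs.
#' @return `data.frame` of compounds.
#' @export
default_binders <- function(n = 30L, seed = 1L) {
  r <- .rng_local(seed)
  on.exit(r())
  data.frame(
    id = sprintf("bind%02d", seq_len(n)),
    ligand_mass = round(stats::runif(n, 700, 1400), 4),
    mz = NA_real_,
    rt = round(stats::runif(n, 1.5, 8.5), 3),
    width = 0.03,
    ratio = round(stats::runif(n, 0.2, 0.8), 3),
    stoichiometry = 1L,
    family = paste0("fam", 1L + (seq_len(n) - 1L) %/% 5L),
    apex_intensity = round(stats::runif(n, 1e5, 5e5)),
    stringsAsFactors = FALSE
  )
}

#' @rdname default_binders
#' @export
default_decoys <- function(n = 20L, seed = 2L) {
  r <- .rng_local(seed)
  on.exit(r())
  data.frame(
    id = sprintf("decoy%02d", seq_len(n)),
    ligand_mass = round(stats::runif(n, 320, 680), 4),
    mz = NA_real_,
    rt = round(stats::runif(n, 1.5, 8.5), 3),
    width = 0.03,
    ratio = 0,
    stoichiometry = 0L,
    family = sprintf("decoyfam%02d", seq_len(n)),
    apex_intensity = round(stats::runif(n, 1e5, 5e5)),
    stringsAsFactors = FALSE
  )
}

# run expressions under a fixed seed, restoring the caller's RNG state
.rng_local <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}

#' Synthesize the charge envelope of one neutral species
#'
#' One centroid per charge state (no isotopic structure), with charge
#' abundance proportional to a Gaussian over the charge range. Charge states
#' whose m/z falls outside the acquisition window are not recorded, as on the
#' instrument; an error lists the offending charges if the entire envelope
#' misses the window.
#'
#' @param mass Neutral mass, Da.
#' @param total_intensity Summed envelope intensity.
#' @param z_range,z_mean,z_sd Charge range and Gaussian abundance parameters.
#' @param mz_window Acquisition window `c(low, high)`.
#' @return `data.frame` of (mz, intensity, z).
#' @export
synthesize_envelope <- function(mass, total_intensity, z_range = c(6L, 11L),
                                z_mean = 8.5, z_sd = 1.2,
                                mz_window = c(2500, 4000)) {
  zs <- seq(z_range[1], z_range[2])
  mz <- mz_from_mass(mass, zs)
  inside <- mz >= mz_window[1] & mz <= mz_window[2]
  if (!any(inside)) {
    stop("envelope of mass ", round(mass, 1), " Da falls entirely outside m/z [",
         mz_window[1], ", ", mz_window[2], "]: charges ",
         paste0(zs, " (m/z ", round(mz, 1), ")", collapse = ", "))
  }
  w <- exp(-(zs[inside] - z_mean)^2 / (2 * z_sd^2))
  data.frame(mz = mz[inside], intensity = total_intensity * w / sum(w),
             z = zs[inside])
}

#' Synthesize one centroided native-MS scan
#'
#' Superimposes the charge envelopes of several neutral species into a single
#' MS1 spectrum, e.g. an apoprotein plus its ligand complexes.
#'
#' @param masses Neutral masses, Da.
#' @param intensities Total envelope intensity per species.
#' @inheritParams synthesize_envelope
#' @param rt Retention time, minutes.
#' @param scan_id Scan identifier.
#' @return An MS1 [ms_spectrum()].
#' @export
synthesize_native_scan <- function(masses, intensities, z_range = c(6L, 11L),
                                   z_mean = 8.5, z_sd = 1.2,
                                   mz_window = c(2500, 4000),
                                   rt = 0, scan_id = "scan1") {
  stopifnot(length(masses) == length(intensities))
  env <- do.call(rbind, lapply(seq_along(masses), function(i) {
    synthesize_envelope(masses[i], intensities[i], z_range, z_mean, z_sd,
                        mz_window)
  }))
  ms_spectrum(scan_id = scan_id, rt = rt, ms_level = 1L,
           mz = env$mz, intensity = env$intensity)
}

.gauss_profile <- function(rt, apex, sigma) exp(-(rt - apex)^2 / (2 * sigma^2))

.jitter_peaks <- function(mz, intensity, noise) {
  if (noise$mz_ppm > 0) {
    mz <- mz * (1 + stats::rnorm(length(mz), 0, noise$mz_ppm * 1e-6))
  }
  if (noise$intensity_sd > 0) {
    intensity <- intensity * exp(stats::rnorm(length(intensity), 0, noise$intensity_sd))
  }
  list(mz = mz, intensity = intensity)
}

.noise_peaks <- function(n, mz_window, floor) {
  if (n < 1L || floor <= 0) return(list(mz = numeric(0), intensity = numeric(0)))
  list(mz = stats::runif(n, mz_window[1], mz_window[2]),
       intensity = floor * exp(stats::rnorm(n, 0, 1)))
}

#' Simulate the native (protein-infusion) run of a screen
#'
#' Every scan contains the apoprotein envelope; around each planted binder's
#' retention time a complex envelope appears at
#' `apo_mass + stoichiometry * ligand_mass`, its intensity following a
#' Gaussian elution profile. Total protein ion current is conserved per scan:
#' intensity gained by complexes is drawn from the apo envelope, which
#' produces the characteristic depletion dips in the apo chromatogram.
#'
#' @param s A [screen_scenario()].
#' @return List with `run` (a [ms_run()]) and `truth` (planted ground-truth
#'   tables: `complexes`, `expected_matches`).
#' @export
simulate_native_run <- function(s) {
  stopifnot(inherits(s, "screen_scenario"))
  restore <- .rng_local(s$seed)
  on.exit(restore())
  rts <- seq(0, s$gradient_min, by = s$scan_interval)
  binders <- s$binders
  nb <- if (is.null(binders)) 0L else nrow(binders)
  spectra <- vector("list", length(rts))
  for (k in seq_along(rts)) {
    rt <- rts[k]
    frac <- if (nb) {
      binders$ratio / (1 + binders$ratio) *
        .gauss_profile(rt, binders$rt, binders$width)
    } else numeric(0)
    total <- sum(frac)
    if (total > 0.95) frac <- frac * 0.95 / total
    live <- which(frac > 1e-4)
    masses <- c(s$apo_mass,
                if (length(live)) s$apo_mass +
                  binders$stoichiometry[live] * binders$ligand_mass[live])
    intens <- s$apo_tic * c(1 - sum(frac[live]), frac[live])
    env <- do.call(rbind, lapply(seq_along(masses), function(i) {
      synthesize_envelope(masses[i], intens[i], s$z_range, s$z_mean, s$z_sd,
                          s$mz_window)
    }))
    jit <- .jitter_peaks(env$mz, env$intensity, s$noise)
    noi <- .noise_peaks(s$noise$n_noise_peaks, s$mz_window, s$noise$floor)
    spectra[[k]] <- ms_spectrum(
      scan_id = sprintf("native_scan%04d", k), rt = rt, ms_level = 1L,
      mz = c(jit$mz, noi$mz), intensity = c(jit$intensity, noi$intensity)
    )
  }
  truth <- if (nb) {
    data.frame(
      binder_id = binders$id,
      complex_mass = s$apo_mass + binders$stoichiometry * binders$ligand_mass,
      ligand_mass = binders$ligand_mass,
      ligand_mz = binders$mz,
      rt = binders$rt,
      stoichiometry = binders$stoichiometry,
      ratio = binders$ratio,
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(binder_id = character(0), complex_mass = numeric(0),
               ligand_mass = numeric(0), ligand_mz = numeric(0),
               rt = numeric(0), stoichiometry = integer(0), ratio = numeric(0))
  }
  list(run = ms_run(spectra,
                    metadata = list(description = "synthetic native run",
                                    mz_window = s$mz_window)),
       truth = list(complexes = truth, expected_matches = truth))
}

# deterministic fragment ladder shared within a compound family
.family_ladder <- function(family, seed, n_frag = 12L) {
  set.seed(seed + sum(utf8ToInt(family)))
  list(frag = sort(stats::runif(n_frag, 150, 900)),
       inten = stats::runif(n_frag, 0.2, 1) * 1e4)
}

.member_ms2 <- function(ladder, member_mz, ref_mz, n_common = 8L) {
  frag <- ladder$frag
  n <- length(frag)
  shift_ix <- (n_common + 1L):n
  frag[shift_ix] <- frag[shift_ix] + (member_mz - ref_mz)
  keep <- frag > 50 & frag < member_mz
  list(mz = frag[keep], intensity = ladder$inten[keep])
}

#' Simulate the metabolomics LC-MS/MS run of a screen
#'
#' MS1 features appear at the [M+H]+ of every planted binder and decoy with
#' the same Gaussian elution profiles as the native run. Data-dependent MS/MS
#' picks up to two precursors per duty cycle near their apex (with dynamic
#' exclusion). Members of a compound family share a fragment ladder in which
#' some fragments are common and the rest shift with the precursor, so
#' modified-cosine networking groups analogs into components.
#'
#' @param s A [screen_scenario()].
#' @param dda_top_n Precursors fragmented per duty cycle.
#' @param dda_min_intensity Minimum MS1 intensity to trigger MS/MS.
#' @param dda_exclusion Dynamic exclusion window, minutes.
#' @return List with `run` (MS1 + MS2 [ms_run()]) and `truth` (planted
#'   feature table).
#' @export
simulate_metabolomics_run <- function(s, dda_top_n = 2L,
                                      dda_min_intensity = 1e4,
                                      dda_exclusion = 0.1) {
  stopifnot(inherits(s, "screen_scenario"))
  restore <- .rng_local(s$seed + 1L)
  on.exit(restore())
  comp <- rbind(
    if (!is.null(s$binders) && nrow(s$binders)) s$binders[, c("id", "ligand_mass", "mz", "rt", "width", "family", "apex_intensity")],
    if (!is.null(s$decoys) && nrow(s$decoys)) s$decoys[, c("id", "ligand_mass", "mz", "rt", "width", "family", "apex_intensity")]
  )
  if (is.null(comp) || !nrow(comp)) stop("scenario has no compounds to simulate")
  comp$mz <- ifelse(is.na(comp$mz), comp$ligand_mass + PROTON_MASS, comp$mz)
  fam_ids <- unique(comp$family)
  ladders <- lapply(fam_ids, .family_ladder, seed = s$seed)
  names(ladders) <- fam_ids
  fam_ref_mz <- vapply(fam_ids, function(f) comp$mz[comp$family == f][1], numeric(1))
  names(fam_ref_mz) <- fam_ids

  rts <- seq(0, s$gradient_min, by = s$scan_interval)
  n_noise <- max(0L, as.integer(s$noise$n_noise_peaks / 5L))
  spectra <- list()
  last_ms2 <- stats::setNames(rep(-Inf, nrow(comp)), comp$id)
  k2 <- 0L
  for (k in seq_along(rts)) {
    rt <- rts[k]
    inten <- comp$apex_intensity * .gauss_profile(rt, comp$rt, comp$width)
    live <- which(inten > 1)
    jit <- .jitter_peaks(comp$mz[live], inten[live], s$noise)
    noi <- .noise_peaks(n_noise, s$met_mz_window, s$noise$floor)
    spectra[[length(spectra) + 1L]] <- ms_spectrum(
      scan_id = sprintf("met_scan%04d", k), rt = rt, ms_level = 1L,
      mz = c(jit$mz, noi$mz), intensity = c(jit$intensity, noi$intensity)
    )
    eligible <- live[inten[live] >= dda_min_intensity &
                       rt - last_ms2[comp$id[live]] >= dda_exclusion]
    if (length(eligible)) {
      picked <- eligible[order(-inten[eligible])][seq_len(min(dda_top_n, length(eligible)))]
      for (p in seq_along(picked)) {
        i <- picked[p]
        k2 <- k2 + 1L
        frag <- .member_ms2(ladders[[comp$family[i]]], comp$mz[i],
                            fam_ref_mz[[comp$family[i]]])
        spectra[[length(spectra) + 1L]] <- ms_spectrum(
          scan_id = sprintf("met_ms2_%04d", k2),
          rt = rt + p * s$scan_interval / (dda_top_n + 1L),
          ms_level = 2L, mz = frag$mz, intensity = frag$intensity,
          precursor_mz = comp$mz[i], precursor_charge = 1L
        )
        last_ms2[comp$id[i]] <- rt
      }
    }
  }
  truth <- data.frame(
    compound_id = comp$id, mz = comp$mz, neutral_mass = comp$mz - PROTON_MASS,
    rt = comp$rt, family = comp$family,
    is_binder = comp$id %in% (if (is.null(s$binders)) character(0) else s$binders$id),
    stringsAsFactors = FALSE
  )
  list(run = ms_run(spectra,
                    metadata = list(description = "synthetic metabolomics run",
                                    mz_window = s$met_mz_window)),
       truth = list(features = truth))
}

#' Simulate a titration series from the hyperbolic binding model
#'
#' @param kd,rmax Model parameters (`ratio = rmax * c / (kd + c)`).
#' @param concentrations Ligand concentrations.
#' @param noise Log-normal sigma applied to the ratios (0 = exact).
#' @param seed Seed.
#' @param apo_area Constant apoprotein area used to back out bound areas.
#' @return `data.frame(concentration, bound_area, apo_area, ratio)`.
#' @export
simulate_titration <- function(kd, rmax, concentrations = c(0.1, 0.25, 0.5, 1, 2, 5),
                               noise = 0, seed = 1L, apo_area = 1e6) {
  restore <- .rng_local(seed)
  on.exit(restore())
  ratio <- rmax * concentrations / (kd + concentrations)
  if (noise > 0) ratio <- ratio * exp(stats::rnorm(length(ratio), 0, noise))
  data.frame(concentration = concentrations, bound_area = ratio * apo_area,
             apo_area = apo_area, ratio = ratio)
}

#' Simulate dose-response data from the 4PL model
#'
#' @param ic50,hill,top,bottom 4PL parameters.
#' @param doses Concentrations; default eight half-log doses from 0.1 to 300.
#' @param noise Multiplicative log-normal sigma (0.05 = 5% noise).
#' @param replicates Replicates per dose.
#' @param seed Seed.
#' @return `data.frame(concentration, response, replicate)`.
#' @export
simulate_dose_response <- function(ic50, hill = 1, top = 100, bottom = 0,
                                   doses = 10^seq(-1, 2.5, by = 0.5),
                                   noise = 0.05, replicates = 3L, seed = 1L) {
  restore <- .rng_local(seed)
  on.exit(restore())
  grid <- expand.grid(replicate = seq_len(replicates), concentration = doses)
  y <- bottom + (top - bottom) / (1 + (grid$concentration / ic50)^hill)
  if (noise > 0) y <- y * exp(stats::rnorm(length(y), 0, noise))
  data.frame(concentration = grid$concentration, response = y,
             replicate = grid$replicate)
}
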