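#' Specify a synthetic two-group cohort
#'
#' A cohort is defined by its group sizes, the per-band effects implanted on
#' the generator parameters, covariate distributions, and a master seed.
#' Band-wise dynamics are steered through five generator knobs, one per
#' metric axis:
#'
#' | metric axis | generator knob               | subject-level scale    |
#' |-------------|------------------------------|------------------------|
#' | `dfa`       | Hurst exponent H             | identity               |
#' | `bis`       | mean dwell time              | log                    |
#' | `ei_hlp`    | high-mode occupancy w_hi     | logit                  |
#' | `ei_hls`    | mode separation mu_hi/mu_lo  | log10                  |
#' | `fei`       | amplitude-fluctuation rho    | identity               |
#'
#' An implanted effect of size `d` is a standardized mean difference
#' (Cohen's d, MDD minus HC) targeted on the *metric* scale: the generator
#' converts it into a knob-mean shift through per-axis transmission gains
#' calibrated once by simulation at the baseline parameters (negative for
#' `fei`: raising the coupling lowers the fE/I ratio). Subjects draw their
#' own knob values around the shifted group mean. Transmission varies
#' somewhat across bands, so realized downstream effects carry the
#' calibration's uncertainty (roughly 25%).
#'
#' @param n_hc,n_mdd Group sizes (>= 2; defaults 133 and 183).
#' @param effect_map Named list: band label -> named numeric vector of
#'   signed effect sizes per metric axis, e.g.
#'   `list("8.3-10.5" = c(bis = -0.8))`. Keys must be bands from
#'   [make_bands()]; metric names must be steerable axes.
#' @param bands Band labels to simulate oscillatory components in
#'   (default: all 13). Unsimulated bands contain only background.
#' @param age_mean,age_sd Age distribution (years), truncated to 18-80.
#' @param p_male Probability of male sex (coded `"male"`/`"female"`).
#' @param fs Sampling rate of generated recordings (Hz).
#' @param n_channels Channels per recording.
#' @param seed Master seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_hc = 133, n_mdd = 183, effect_map = list(),
                        bands = NULL, age_mean = 47, age_sd = 16,
                        p_male = 0.4, fs = 200, n_channels = 1, seed = 1) {
  stopifnot(n_hc >= 2, n_mdd >= 2, fs > 0, n_channels >= 1)
  all_bands <- make_bands()$band
  bands <- bands %||% all_bands
  if (!all(bands %in% all_bands))
    stop("unknown band label(s): ", paste(setdiff(bands, all_bands), collapse = ", "))
  steerable <- c("dfa", "bis", "ei_hlp", "ei_hls", "fei")
  if (length(effect_map)) {
    if (!all(names(effect_map) %in% all_bands))
      stop("effect_map keys must be band labels from make_bands(); offending: ",
           paste(setdiff(names(effect_map), all_bands), collapse = ", "))
    for (band in names(effect_map)) {
      bad <- setdiff(names(effect_map[[band]]), steerable)
      if (length(bad))
        stop("cannot steer metric '", bad[1], "'; steerable axes: ",
             paste(steerable, collapse = ", "))
    }
    bands <- union(bands, names(effect_map))
  }
  structure(list(n_hc = n_hc, n_mdd = n_mdd, effect_map = effect_map,
                 bands = bands, age_mean = age_mean, age_sd = age_sd,
                 p_male = p_male, fs = fs, n_channels = n_channels,
                 seed = seed),
            class = "cohort_spec")
}

# baseline generator parameters (subject-level scale), between-subject SDs,
# and transmission gains: the downstream standardized group difference of
# the metric produced by a +1 SD shift of the knob (measured once by
# simulation at the baselines; negative for fei because raising the
# coupling rho lowers the fE/I ratio). An implanted effect of d on the
# metric axis therefore shifts the knob by d / gain SDs.
cohort_baselines <- function() {
  list(
    dfa    = list(mean = 0.72,          sd = 0.05, gain = 0.34),
    bis    = list(mean = log(0.4),      sd = 0.30, gain = 0.25),  # log dwell (s)
    ei_hlp = list(mean = stats::qlogis(0.4), sd = 0.30, gain = 0.35),
    ei_hls = list(mean = 1.5,           sd = 0.25, gain = 1.21),  # log10(mu_hi/mu_lo)
    fei    = list(mean = 0,             sd = 0.25, gain = -0.44)  # rho
  )
}

#' Generate a synthetic two-group cohort
#'
#' Draws subject-level generator parameters per band (see [cohort_spec()]),
#' realizes one recording per subject with [gen_subject()], and returns the
#' recordings together with a ground-truth manifest. Deterministic under
#' the cohort's master seed, independent of processing order.
#'
#' @param spec A [cohort_spec()].
#' @return List with `recordings` (list of `recording`) and `manifest`
#'   (tibble: subject, group, age, sex, seed, then one column per
#'   knob x band named `"knob@band"` holding the subject's true parameter).
#' @export
gen_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  base <- cohort_baselines()
  bands_tbl <- make_bands()
  n_tot <- spec$n_hc + spec$n_mdd
  groups <- rep(c("HC", "MDD"), c(spec$n_hc, spec$n_mdd))
  ids <- sprintf("sub-%03d", seq_len(n_tot))

  rec_list <- vector("list", n_tot)
  man_rows <- vector("list", n_tot)
  for (i in seq_len(n_tot)) {
    sseed <- child_seed(spec$seed, "cohort", ids[i])
    covs <- with_seed(child_seed(sseed, "covariates"), {
      age <- stats::rnorm(1, spec$age_mean, spec$age_sd)
      while (age < 18 || age > 80) age <- stats::rnorm(1, spec$age_mean, spec$age_sd)
      list(age = round(age, 1),
           sex = if (stats::runif(1) < spec$p_male) "male" else "female")
    })
    params <- with_seed(child_seed(sseed, "params"), {
      lapply(stats::setNames(spec$bands, spec$bands), function(band) {
        eff <- spec$effect_map[[band]]
        vapply(names(base), function(axis) {
          shift <- if (groups[i] == "MDD" && !is.null(eff) && axis %in% names(eff))
            eff[[axis]] / base[[axis]]$gain * base[[axis]]$sd else 0
          stats::rnorm(1, base[[axis]]$mean + shift, base[[axis]]$sd)
        }, numeric(1))
      })
    })
    profiles <- lapply(stats::setNames(spec$bands, spec$bands), function(band) {
      p <- params[[band]]
      row <- match(band, bands_tbl$band)
      envelope_profile(
        kind = "composite",
        H = min(max(p[["dfa"]], 0.51), 0.97),
        mu_lo = 1, mu_hi = 10^max(p[["ei_hls"]], 0.2),
        w_hi = stats::plogis(p[["ei_hlp"]]),
        dwell = exp(p[["bis"]]),
        rho = min(max(p[["fei"]], -0.9), 0.9),
        baseline = bands_tbl$f_lo[row]^(-0.5), sigma = 0.2)
    })
    rec_list[[i]] <- gen_subject(
      band_profiles = profiles, fs = spec$fs, n_channels = spec$n_channels,
      subject = ids[i], group = groups[i],
      age = covs$age, sex = covs$sex, seed = sseed)
    flat <- unlist(lapply(spec$bands, function(b)
      stats::setNames(params[[b]], paste0(names(params[[b]]), "@", b))))
    man_rows[[i]] <- tibble::tibble(subject = ids[i], group = groups[i],
                                    age = covs$age, sex = covs$sex,
                                    seed = sseed, !!!as.list(flat))
  }
  manifest <- dplyr::bind_rows(man_rows)
  implants <- if (length(spec$effect_map)) {
    dplyr::bind_rows(lapply(names(spec$effect_map), function(band)
      tibble::tibble(band = band, metric = names(spec$effect_map[[band]]),
                     effect = unname(unlist(spec$effect_map[[band]])))))
  } else tibble::tibble(band = character(), metric = character(),
                        effect = numeric())
  list(recordings = rec_list, manifest = manifest, implants = implants)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort spec> ", x$n_hc, " HC + ", x$n_mdd, " MDD, ",
      length(x$bands), " band(s), ", x$n_channels, " channel(s) @ ",
      x$fs, " Hz, seed ", x$seed, "\n", sep = "")
  if (length(x$effect_map))
    for (b in names(x$effect_map))
      cat("  implant ", b, ": ",
          paste(names(x$effect_map[[b]]), signif(unlist(x$effect_map[[b]]), 3),
                sep = " = ", collapse = ", "), "\n", sep = "")
  invisible(x)
}
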