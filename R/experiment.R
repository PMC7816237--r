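## Subject-level random draws for the synthetic cohort. Heart rate is
## Normal(64, 10) bpm truncated below at 40; true MBF is Normal(mean, sd)
## truncated below at 0.5 ml/g/min; the geometry scale is Normal(1, sd)
## truncated to [0.85, 1.15]. Truncation is by redraw.

truncNorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      x <- stats::rnorm(1, mean, sd)
      if (x >= lower && x <= upper) break
    }
    out[i] <- x
  }
  out
}

#' Sample subject heart rates
#'
#' Heart rates in bpm from a Normal(64, 10) distribution truncated below
#' at 40, matching a resting healthy-adult cohort.
#'
#' @param n number of subjects.
#' @param meanBpm,sdBpm distribution parameters.
#' @param minBpm lower truncation bound.
#' @return numeric vector of heart rates.
#' @export
sampleHeartRates <- function(n, meanBpm = 64, sdBpm = 10, minBpm = 40) {
  truncNorm(n, meanBpm, sdBpm, lower = minBpm)
}

#' Run the three-protocol synthetic experiment
#'
#' Simulates a cohort of synthetic subjects and pushes each through the
#' full pipeline under every protocol. Per subject, a heart rate
#' (Normal(64, 10) bpm, truncated at 40), a true resting MBF
#' (Normal(`spec@trueMbf`, `subjectMbfSd`) ml/g/min, truncated at 0.5)
#' and a geometry scale (Normal(1, `subjectGeomSd`), truncated to
#' [0.85, 1.15], applied to all four radii) are drawn, shared across the
#' subject's protocols; the nominal inversion time is one cardiac cycle,
#' `60000 / heart rate` ms. Per subject and protocol the phantom series
#' is simulated, preprocessed ([preprocessSeries()]) and quantified
#' ([mbfMap()]); the analysis mask is the phase-matched ground-truth
#' myocardium (cropped to the ROI); the six per-pair maps
#' ([perPairMaps()]) yield the TSNR. All per-subject randomness derives
#' from `seed`.
#'
#' @param nSubjects number of synthetic subjects (default 12).
#' @param seed master seed.
#' @param spec base [PhantomSpec-class]; per-subject fields (seed, true
#'   MBF, radii) are derived from it.
#' @param protocols protocol preset names (see [fairProtocol()]) or a
#'   named list of [AcquisitionProtocol-class] objects.
#' @param registration `FALSE` disables both registration stages
#'   everywhere (ablation).
#' @param tsnrMode `"roi"` or `"pixel"`, see [tsnr()].
#' @param subjectMbfSd between-subject SD of true MBF, ml/g/min.
#' @param subjectGeomSd between-subject SD of the geometry scale.
#' @param sizePx ROI crop size, pixels.
#' @param regional include per-sector mean MBF columns.
#' @param alpha significance threshold for the comparisons.
#' @return list with `results` (data.frame: one row per subject x
#'   protocol with mean_mbf, tsnr, n_pixels and optional regional
#'   columns), `reports` (named list of [ComparisonReport-class] for
#'   mean_mbf, tsnr and n_pixels), `subjects` (the drawn subject
#'   parameters) and `config`.
#' @export
runExperiment <- function(nSubjects = 12, seed = 1,
                          spec = PhantomSpec(),
                          protocols = c("FAIR-PI2_D", "FAIR-PI2_S",
                                        "FAIR-CS3_S"),
                          registration = TRUE,
                          tsnrMode = c("roi", "pixel"),
                          subjectMbfSd = 0.3,
                          subjectGeomSd = 0.05,
                          sizePx = 64,
                          regional = TRUE,
                          alpha = 0.05) {
  tsnrMode <- match.arg(tsnrMode)
  if (is.character(protocols)) {
    protNames <- protocols
    protocols <- lapply(protocols, fairProtocol)
    names(protocols) <- protNames
  }
  stopifnot(length(protocols) >= 2, nSubjects >= 2)

  set.seed(as.integer(seed))
  hr <- sampleHeartRates(nSubjects)
  mbfTrue <- truncNorm(nSubjects, spec@trueMbf, subjectMbfSd, lower = 0.5)
  geomScale <- truncNorm(nSubjects, 1, subjectGeomSd, 0.85, 1.15)
  subjectSeeds <- sample.int(2^31 - 2, nSubjects)

  rows <- list()
  for (s in seq_len(nSubjects)) {
    specS <- spec
    specS@trueMbf <- mbfTrue[s]
    specS@diastoleRadiiMm <- spec@diastoleRadiiMm * geomScale[s]
    specS@systoleRadiiMm <- spec@systoleRadiiMm * geomScale[s]
    for (pIdx in seq_along(protocols)) {
      prot <- protocols[[pIdx]]
      prot@nominalTiMs <- 60000 / hr[s]
      specS@seed <- (subjectSeeds[s] + 7919 * pIdx) %% (2^31 - 1)
      sim <- simulateSeries(specS, prot, heartRateBpm = hr[s])
      prep <- preprocessSeries(sim$series, sizePx = sizePx,
                               registration = registration)
      myoCrop <- cropMatrix(sim$truth@myoMask, sizePx = sizePx)
      map <- mbfMap(prep@controlAvg, prep@taggedAvg, prep@m0,
                    prep@tiControlMs, prep@tiTaggedMs,
                    t1Ms = sim$series@bloodT1Ms, myo = myoCrop)
      pair <- perPairMaps(sim$series, sizePx = sizePx,
                          registration = registration, myo = myoCrop)
      row <- data.frame(
        subject = sprintf("S%02d", s),
        protocol = names(protocols)[pIdx],
        heart_rate_bpm = hr[s],
        true_mbf = mbfTrue[s],
        mean_mbf = mean(map@values[map@myoMask]),
        sd_mbf = stats::sd(map@values[map@myoMask]),
        tsnr = as.numeric(tsnr(pair, mask = myoCrop, mode = tsnrMode)),
        n_pixels = sum(map@myoMask))
      if (regional) {
        sect <- regionalSectors(myoCrop,
                                rvDirectionDeg = spec@rvDirectionDeg)
        sm <- summarizeMap(map, mask = myoCrop, regions = sect)
        for (k in seq_len(nrow(sm$regional)))
          row[[paste0("mbf_", sm$regional$region[k])]] <-
            sm$regional$mean_mbf[k]
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  results <- do.call(rbind, rows)
  reports <- list(
    mean_mbf = compareMethods(results, "mean_mbf", alpha),
    tsnr = compareMethods(results, "tsnr", alpha),
    n_pixels = compareMethods(results, "n_pixels", alpha))
  list(results = results,
       reports = reports,
       subjects = data.frame(subject = sprintf("S%02d", seq_len(nSubjects)),
                             heart_rate_bpm = hr, true_mbf = mbfTrue,
                             geom_scale = geomScale, seed = subjectSeeds),
       config = list(nSubjects = nSubjects, seed = seed,
                     protocols = names(protocols),
                     registration = registration, tsnrMode = tsnrMode,
                     subjectMbfSd = subjectMbfSd,
                     subjectGeomSd = subjectGeomSd, sizePx = sizePx,
                     alpha = alpha))
}
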