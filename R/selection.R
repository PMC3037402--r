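## Automatic identification of functionally relevant components.

#' Default component-selection criteria
#'
#' A component is kept when its spatial map correlates with the grey
#' matter prior at least `gmCorrMin` and more strongly than with the
#' white matter and CSF priors (a rank-based rule, robust to the overall
#' correlation scale), and when at least `powerFractionMin` of its
#' time-course spectral power lies in the low-frequency band.
#'
#' @param lowband numeric(2), low-frequency band in Hz (default 0.01-0.05).
#' @param powerFractionMin minimum in-band power fraction (default 0.5).
#' @param gmCorrMin minimum grey-matter correlation (default 0.15).
#' @return A named list of criteria.
#' @export
selectionCriteria <- function(lowband = c(0.01, 0.05), powerFractionMin = 0.5,
                              gmCorrMin = 0.15) {
  stopifnot(powerFractionMin >= 0, powerFractionMin <= 1,
            lowband[1L] > 0, lowband[1L] < lowband[2L])
  list(lowband = lowband, powerFractionMin = powerFractionMin,
       gmCorrMin = gmCorrMin)
}

#' Correlation of a component map with tissue priors
#'
#' Pearson correlation of a spatial map with the grey matter, white
#' matter and CSF probability volumes over in-brain voxels (prior sum
#' above `brainThresh`).
#'
#' @param map 3D array (or in-mask vector, with `mask` supplied).
#' @param priors list with 3D arrays `gm`, `wm`, `csf`.
#' @param mask optional 3D logical array the vector `map` is defined on.
#' @param brainThresh in-brain threshold on the prior sum (default 0.05).
#' @return Named numeric: gm, wm, csf correlations.
#' @export
tissueCorrelation <- function(map, priors, mask = NULL, brainThresh = 0.05) {
  for (nm in c("gm", "wm", "csf")) {
    if (is.null(priors[[nm]])) stop("priors must contain gm, wm, csf", call. = FALSE)
    if (all(priors[[nm]] == 0)) {
      stop(sprintf("invalid prior: %s is all zero", nm), call. = FALSE)
    }
  }
  if (!is.null(mask) && is.null(dim(map)) && length(map) == sum(mask)) {
    full <- rep(NA_real_, length(priors$gm))
    full[which(as.logical(mask))] <- map
    map <- array(full, dim(priors$gm))
  }
  brain <- (priors$gm + priors$wm + priors$csf) > brainThresh
  brain <- brain & !is.na(map)
  v <- as.numeric(map)[brain]
  c(gm = stats::cor(v, as.numeric(priors$gm)[brain]),
    wm = stats::cor(v, as.numeric(priors$wm)[brain]),
    csf = stats::cor(v, as.numeric(priors$csf)[brain]))
}

#' Fraction of spectral power in a low-frequency band
#'
#' Periodogram power of the time course in `lowband` divided by the total
#' power over (0, Nyquist]; the DC term is excluded. The fraction is
#' invariant to amplitude scaling and mean offset.
#'
#' @param timecourse numeric vector (length >= 16).
#' @param TR sampling interval in seconds.
#' @param lowband numeric(2) band in Hz (default 0.01-0.05).
#' @return Fraction in [0, 1].
#' @export
spectralPowerFraction <- function(timecourse, TR, lowband = c(0.01, 0.05)) {
  T_ <- length(timecourse)
  if (T_ < 16L) stop("time course too short (need >= 16 samples)", call. = FALSE)
  x <- timecourse - mean(timecourse)
  if (all(abs(x) < 1e-14)) {
    stop("undefined fraction: constant time course", call. = FALSE)
  }
  p <- Mod(stats::fft(x))^2
  half <- 2:(floor(T_ / 2) + 1L)       # positive frequencies, DC excluded
  f <- (half - 1L) / (T_ * TR)
  inband <- f >= lowband[1L] & f <= lowband[2L]
  sum(p[half][inband]) / sum(p[half])
}

#' Select functionally relevant components
#'
#' Applies the two selection criteria to every component of a fitted
#' decomposition: (i) tissue association - keep components whose maps
#' correlate with grey matter at least `gmCorrMin` and more than with
#' white matter or CSF; (ii) spectral content - keep components whose
#' subject time courses carry at least `powerFractionMin` of their power
#' below `max(lowband)`. The per-component power fraction is the mean
#' over subjects.
#'
#' @param cset a [ComponentSet-class].
#' @param priors list of 3D tissue probability arrays `gm`, `wm`, `csf`.
#' @param criteria a list from [selectionCriteria()].
#' @return data.frame per component: tissue correlations, power fraction,
#'   the two criterion flags, and `keep`.
#' @export
selectComponents <- function(cset, priors, criteria = selectionCriteria()) {
  K <- cset@K
  TR <- cset@grid@TR
  out <- data.frame(component = seq_len(K), gm = NA_real_, wm = NA_real_,
                    csf = NA_real_, powerFraction = NA_real_,
                    tissueOk = NA, spectralOk = NA, keep = NA)
  for (k in seq_len(K)) {
    vol <- vectorToVolume(cset@groupMaps[k, ], cset@grid, cset@mask)
    tc_ <- tissueCorrelation(vol, priors)
    out$gm[k] <- tc_["gm"]; out$wm[k] <- tc_["wm"]; out$csf[k] <- tc_["csf"]
    pf <- vapply(cset@timecourses, function(tc) {
      spectralPowerFraction(tc[, k], TR, criteria$lowband)
    }, numeric(1))
    out$powerFraction[k] <- mean(pf)
    out$tissueOk[k] <- tc_["gm"] >= criteria$gmCorrMin &&
      tc_["gm"] > tc_["wm"] && tc_["gm"] > tc_["csf"]
    out$spectralOk[k] <- out$powerFraction[k] >= criteria$powerFractionMin
    out$keep[k] <- out$tissueOk[k] && out$spectralOk[k]
  }
  out
}

#' Match selected components to template network maps
#'
#' Sorts retained components by their absolute spatial correlation with
#' user-supplied template maps (e.g. canonical resting-state network
#' templates), with a greedy one-to-one assignment.
#'
#' @param cset a [ComponentSet-class].
#' @param templates K_t x N matrix (rows: template maps over the mask) or
#'   list of 3D arrays.
#' @param keep optional logical/integer subset of components to match.
#' @return data.frame: template, component, r.
#' @export
matchTemplates <- function(cset, templates, keep = NULL) {
  if (is.list(templates)) {
    templates <- t(vapply(templates, function(v) {
      as.numeric(v)[as.logical(cset@mask)]
    }, numeric(sum(cset@mask))))
  }
  comp <- cset@groupMaps
  idx <- seq_len(nrow(comp))
  if (!is.null(keep)) idx <- idx[keep]
  R <- row_cor(templates, comp[idx, , drop = FALSE])
  m <- greedy_match(R)
  data.frame(template = m$row, component = idx[m$col], r = m$value)
}
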