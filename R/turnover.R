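#' @include AllClasses.R detect.R mixture.R
NULL

# re-align one row so its minimum sits at `troughIndex`, padding with the
# edge value; shifts are typically 0 or +/-1 sample
realignRow <- function(row, troughIndex = 17L) {
  shift <- troughIndex - which.min(row)
  n <- length(row)
  if (shift == 0L) return(row)
  if (shift > 0L) c(rep(row[1], shift), row[seq_len(n - shift)])
  else c(row[(1L - shift):n], rep(row[n], -shift))
}

#' Sample, re-align and standardise accepted waveforms for one day
#'
#' Draws up to `n` accepted snippets uniformly without replacement (all
#' of them, flagged undersized, when fewer are available), re-aligns
#' each row so its trough sits at column 17, and standardises each row
#' to mean 0 and SD 1 across its 48 points. Electrodes with fewer than
#' `minEvents` accepted snippets cannot support a day-pair comparison
#' and yield a [nonComparable()] marker instead.
#'
#' @param snippets A [SnippetMatrix-class].
#' @param n Target sample size (default 1000).
#' @param seed Sampling seed.
#' @param day Day index recorded in the sample.
#' @param minEvents Comparability floor (default 100 accepted snippets).
#' @return A [WaveformSample-class], or a [nonComparable()] marker.
#' @export
sampleWaveforms <- function(snippets, n = 1000L, seed = 1L,
                            day = NA_integer_, minEvents = 100L) {
  acc <- acceptedSnippets(snippets)
  if (nrow(acc) < minEvents) {
    return(nonComparable(snippets@electrode, as.integer(day), nrow(acc)))
  }
  idx <- if (nrow(acc) > n) {
    sort(withSeed(seed, sample.int(nrow(acc), n)))
  } else {
    seq_len(nrow(acc))
  }
  m <- .realignRows(acc[idx, , drop = FALSE], 17L)
  mu <- rowMeans(m)
  ctr <- m - mu
  s <- sqrt(rowSums(ctr^2) / (ncol(m) - 1L))
  keep <- s > 0
  m <- ctr[keep, , drop = FALSE] / s[keep]
  new("WaveformSample",
    electrode = snippets@electrode, day = as.integer(day), mat = m,
    undersized = nrow(acc) < n, samplingSeed = as.integer(seed)
  )
}

#' Project a day pair into the first day's top two principal axes
#'
#' The basis is the top two principal axes of the day-a sample: the
#' leading right singular vectors of its standardised waveform matrix
#' (uncentred, so the first axis captures the dominant waveform shape
#' itself, not a contrast around the centroid). Both days' waveforms
#' are projected onto this same basis, and radii are measured from the
#' origin of the shared frame -- the zero waveform. A point's radius
#' therefore measures how much of its (unit-variance) energy lies in
#' the previous day's dominant waveform subspace: matching waveforms
#' keep their radius, while waveforms that no longer resemble the
#' previous day's shapes (noise after silencing, replaced units)
#' project weakly and shrink toward the origin. This is what gives the
#' radius change its sign semantics: loss drives delta-r strongly
#' negative. Each axis is oriented so that its largest-magnitude
#' loading is positive, fixing the sign convention.
#'
#' @param sampleA,sampleB [WaveformSample-class] objects from the same
#'   electrode.
#' @return List with `pointsA` and `pointsB` (n x 2 coordinate
#'   matrices).
#' @export
projectPair <- function(sampleA, sampleB) {
  abortIf(
    !is.na(sampleA@electrode) && !is.na(sampleB@electrode) &&
      sampleA@electrode != sampleB@electrode,
    "samples come from different electrodes"
  )
  a <- sampleA@mat
  # identical rows span a single direction: no 2-D structure to project
  # into, and the day pair cannot be scored
  abortIf(max(abs(sweep(a, 2, colMeans(a)))) < 1e-10,
          "degenerate sample: all waveforms identical")
  sv <- svd(a, nu = 0, nv = 2)
  v <- sv$v
  for (j in 1:2) {
    if (v[which.max(abs(v[, j])), j] < 0) v[, j] <- -v[, j]
  }
  list(
    pointsA = a %*% v,
    pointsB = sampleB@mat %*% v
  )
}

#' Median radius of a projected waveform cloud
#'
#' The median of the Euclidean norms of the points, measured from the
#' origin of the shared day-a projection frame. For even counts the
#' lower median is used, so the radius is always an observed norm.
#'
#' @param points n x 2 coordinate matrix.
#' @return Median radius (scalar).
#' @examples
#' medianRadius(cbind(c(3, 0), c(4, 2))) # norms 5, 2 -> lower median 2
#' @export
medianRadius <- function(points) {
  points <- rbind(points)
  abortIf(nrow(points) == 0L, "empty point set")
  r <- sort(sqrt(rowSums(points^2)))
  r[ceiling(length(r) / 2)]
}

#' Change in median radius between a day pair
#'
#' `delta_r = medianRadius(day b) - medianRadius(day a)` in day-a's
#' projection space. Values near zero indicate an unchanged multi-unit
#' composition; strongly negative values indicate putative neuron loss
#' or silencing, strongly positive values putative gain.
#'
#' @param sampleA,sampleB [WaveformSample-class] objects from the same
#'   electrode (day a first).
#' @return Signed radius change.
#' @export
deltaR <- function(sampleA, sampleB) {
  pr <- projectPair(sampleA, sampleB)
  medianRadius(pr$pointsB) - medianRadius(pr$pointsA)
}

#' Percent of array electrodes in the "match" category for one day pair
#'
#' @param categories Factor/character vector of per-electrode categories
#'   (as from [categorizeDeltaR()], plus the forced categories for
#'   non-comparable electrodes).
#' @param nElectrodes Denominator: the array's total electrode count
#'   (default 96).
#' @return Percentage in `[0, 100]`.
#' @examples
#' percentMatch(rep(c("match", "small_increase"), c(48, 48))) # 50
#' @export
percentMatch <- function(categories, nElectrodes = 96L) {
  abortIf(!(nElectrodes > 0), "nElectrodes must be positive")
  100 * sum(categories == "match", na.rm = TRUE) / nElectrodes
}

# precompute the day-a side of a projection: basis and own radius
prepProjection <- function(ws) {
  a <- ws@mat
  if (max(abs(sweep(a, 2, colMeans(a)))) < 1e-10) return(NULL) # degenerate
  sv <- svd(a, nu = 0, nv = 2)
  v <- sv$v
  for (j in 1:2) {
    if (v[which.max(abs(v[, j])), j] < 0) v[, j] <- -v[, j]
  }
  list(v = v, r = medianRadius(a %*% v))
}

# per-electrode day-pair records before categorisation.
# status: "comparable" (delta_r computed), "silenced" (a comparable,
# b non-comparable -> forced large_decrease), "gained" (mirror),
# "non_comparable_both" (forced match: nothing observable changed)
comparePairRecords <- function(samplesA, samplesB, electrodes,
                               projA = NULL) {
  rows <- lapply(seq_along(electrodes), function(i) {
    a <- samplesA[[i]]
    b <- samplesB[[i]]
    aOk <- !isNonComparable(a)
    bOk <- !isNonComparable(b)
    if (aOk && bOk) {
      pa <- if (!is.null(projA)) projA[[i]] else prepProjection(a)
      if (is.null(pa)) {
        return(data.frame(
          electrode = electrodes[i], r_a = NA_real_, r_b = NA_real_,
          delta_r = NA_real_, status = "non_comparable_both"
        ))
      }
      ra <- pa$r
      rb <- medianRadius(b@mat %*% pa$v)
      data.frame(
        electrode = electrodes[i], r_a = ra, r_b = rb,
        delta_r = rb - ra, status = "comparable"
      )
    } else {
      status <- if (!aOk && !bOk) "non_comparable_both"
                else if (aOk) "silenced" else "gained"
      data.frame(
        electrode = electrodes[i], r_a = NA_real_, r_b = NA_real_,
        delta_r = NA_real_, status = status
      )
    }
  })
  do.call(rbind, rows)
}

forcedCategory <- function(status) {
  switch(status,
    non_comparable_both = "match",
    silenced = "large_decrease",
    gained = "large_increase",
    NA_character_
  )
}

#' Day-to-day waveform-turnover analysis across an array
#'
#' The full turnover statistic for a set of daily recording sessions:
#' for every qualifying day pair (see [buildDayPairs()]) and every
#' electrode, waveforms are sampled and standardised
#' ([sampleWaveforms()]), the second day is projected into the first
#' day's top two principal components ([projectPair()]), and the change
#' in median radius delta-r is computed. Delta-r values are pooled per
#' group (pre-pre, pre-post, post-post) and fitted with per-group
#' Gaussian mixtures ([fitDeltaRMixture()]) -- the cluster-count
#' evidence -- plus one global mixture over all groups whose match
#' component (mean nearest zero) defines the five change categories
#' with a single reference, keeping percent-match values comparable
#' across groups. Percent match is computed per day pair. Finally Mood's median test compares the groups' percent
#' match distributions with Bonferroni correction ([medianTest()]).
#'
#' Electrodes below the comparability floor on both days count as
#' `match` (nothing observably changed; the 96-electrode denominator is
#' fixed). An electrode comparable on day a but near-silent on day b is
#' assigned `large_decrease` (putative silencing), and the mirror case
#' `large_increase`.
#'
#' @param sessionSnippets Named list: one entry per day index (as
#'   character), each a list of [SnippetMatrix-class] per electrode (as
#'   produced by [detectSession()]`$snippets`).
#' @param days Integer vector of session day indices (strictly
#'   increasing).
#' @param lesionDay Sessions with `day <= lesionDay` are pre-lesion.
#' @param nSample Waveforms sampled per electrode-day (default 1000).
#' @param minEvents Comparability floor (default 100).
#' @param kMax Maximum mixture components (default 5).
#' @param seed Master seed for sampling and mixture restarts.
#' @param maxSeparation,acuteLimit,lateWindow Grouping parameters, see
#'   [buildDayPairs()].
#' @param alpha,nComparisons Significance level and Bonferroni divisor
#'   for the median tests.
#' @param nElectrodes Percent-match denominator (default: number of
#'   electrodes in `sessionSnippets`).
#' @return List with `pairComparisons` (per electrode and day pair:
#'   radii, delta-r, status, category), `mixtureFits` (per group, the
#'   cluster-count evidence), `globalFit` (the pooled fit whose match
#'   component defines the categories), `percentMatch` (per day pair),
#'   `tests` (median-test results), and `groups` (the day-pair group
#'   table).
#' @export
turnoverAnalysis <- function(sessionSnippets, days, lesionDay,
                             nSample = 1000L, minEvents = 100L, kMax = 5L,
                             seed = 1L, maxSeparation = 4L, acuteLimit = 3L,
                             lateWindow = c(4L, 7L), alpha = 0.05,
                             nComparisons = 3L, nElectrodes = NULL) {
  days <- as.integer(days)
  abortIf(is.unsorted(days, strictly = TRUE), "days must be strictly increasing")
  abortIf(!all(as.character(days) %in% names(sessionSnippets)),
          "sessionSnippets must contain an entry for every day")
  electrodes <- vapply(sessionSnippets[[as.character(days[1])]],
                       function(s) s@electrode, integer(1))
  if (is.null(nElectrodes)) nElectrodes <- length(electrodes)

  groups <- buildDayPairs(days, lesionDay, maxSeparation, acuteLimit,
                          lateWindow)
  usedDays <- sort(unique(c(groups$day_a, groups$day_b)))

  # one waveform sample per (day, electrode), reused across pairs
  samples <- lapply(usedDays, function(d) {
    snl <- sessionSnippets[[as.character(d)]]
    lapply(seq_along(electrodes), function(i) {
      sampleWaveforms(snl[[i]], n = nSample,
                      seed = deriveSeed(seed, d, electrodes[i]),
                      day = d, minEvents = minEvents)
    })
  })
  names(samples) <- usedDays

  # day-a projection bases are reused across the (up to four) pairs the
  # day anchors
  projections <- lapply(samples, function(dayS) {
    lapply(dayS, function(ws) {
      if (isNonComparable(ws)) NULL else prepProjection(ws)
    })
  })

  recs <- lapply(seq_len(nrow(groups)), function(p) {
    rec <- comparePairRecords(
      samples[[as.character(groups$day_a[p])]],
      samples[[as.character(groups$day_b[p])]],
      electrodes,
      projA = projections[[as.character(groups$day_a[p])]]
    )
    rec$day_a <- groups$day_a[p]
    rec$day_b <- groups$day_b[p]
    rec$group <- groups$group[p]
    rec
  })
  recs <- do.call(rbind, recs)

  grpLevels <- c("pre_pre", "pre_post", "post_post")
  # per-group fits carry the cluster-count evidence (does an extra,
  # negative component appear after the lesion?)
  mixtureFits <- list()
  for (g in grpLevels) {
    vals <- recs$delta_r[recs$group == g & is.finite(recs$delta_r)]
    mixtureFits[[g]] <- if (length(vals) >= 10L) {
      fitDeltaRMixture(vals, kMax = kMax, seed = deriveSeed(seed, match(g, grpLevels)))
    } else {
      NULL
    }
  }

  # categories use one global fit over all groups' delta-r, so "the
  # median cluster value" defining match is a single reference and the
  # groups' percent-match values are directly comparable
  allVals <- recs$delta_r[is.finite(recs$delta_r)]
  globalFit <- if (length(allVals) >= 10L) {
    fitDeltaRMixture(allVals, kMax = kMax, seed = deriveSeed(seed, 99L))
  } else {
    NULL
  }
  recs$category <- NA_character_
  sel <- recs$status == "comparable"
  if (any(sel) && !is.null(globalFit)) {
    recs$category[sel] <-
      as.character(categorizeDeltaR(recs$delta_r[sel], globalFit))
  }
  forced <- recs$status != "comparable"
  recs$category[forced] <- vapply(recs$status[forced], forcedCategory,
                                  character(1))

  pm <- do.call(rbind, lapply(seq_len(nrow(groups)), function(p) {
    sel <- recs$day_a == groups$day_a[p] & recs$day_b == groups$day_b[p]
    data.frame(
      day_a = groups$day_a[p], day_b = groups$day_b[p],
      group = groups$group[p],
      pct_match = percentMatch(recs$category[sel], nElectrodes)
    )
  }))

  comps <- list(
    c("pre_pre", "pre_post"), c("pre_pre", "post_post"),
    c("pre_post", "post_post")
  )
  tests <- do.call(rbind, lapply(comps, function(cp) {
    x <- pm$pct_match[pm$group == cp[1]]
    y <- pm$pct_match[pm$group == cp[2]]
    if (!length(x) || !length(y)) {
      return(data.frame(
        comparison = paste(cp, collapse = " vs "), statistic = NA_real_,
        p_value = NA_real_, alpha_corrected = alpha / nComparisons,
        significant = NA
      ))
    }
    mt <- medianTest(x, y, alpha = alpha, nComparisons = nComparisons)
    data.frame(
      comparison = paste(cp, collapse = " vs "), statistic = mt$statistic,
      p_value = mt$p_value, alpha_corrected = mt$alpha_corrected,
      significant = mt$significant
    )
  }))

  list(
    pairComparisons = recs, mixtureFits = mixtureFits,
    globalFit = globalFit, percentMatch = pm, tests = tests,
    groups = groups
  )
}
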