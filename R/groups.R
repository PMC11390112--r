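#' @include AllClasses.R
NULL

#' Enumerate qualifying day pairs and assign them to comparison groups
#'
#' Ordered session pairs `(day_a < day_b)` separated by at most
#' `maxSeparation` days are assigned to three groups relative to the
#' lesion: `pre_pre` (both sessions pre-lesion), `pre_post` (a
#' pre-lesion session against an acute post-lesion session, up to
#' `acuteLimit` days after the lesion), and `post_post` (two sessions in
#' the late window, `lateWindow[1]` to `lateWindow[2]` days after the
#' lesion). Pairs spanning the acute and late periods, or exceeding the
#' separation limit, are discarded. The separation limit defaults to 4
#' days (pairs separated by 24, 48, 72 or 96 h); a stricter 3-day limit
#' can be requested.
#'
#' @param days Strictly increasing integer vector of session day
#'   indices.
#' @param lesionDay The lesion occurs after this session day; post-day
#'   `p` of a session is `day - lesionDay`.
#' @param maxSeparation Maximum pair separation in days (default 4).
#' @param acuteLimit Last post-lesion day of the acute period (default
#'   3).
#' @param lateWindow Post-lesion day range of the late period (default
#'   `c(4, 7)`).
#' @return data.frame with columns `day_a`, `day_b`, `separation`,
#'   `group`. Empty groups are reported with a warning.
#' @examples
#' g <- buildDayPairs(1:13, lesionDay = 4)
#' table(g$group)
#' @export
buildDayPairs <- function(days, lesionDay, maxSeparation = 4L,
                          acuteLimit = 3L, lateWindow = c(4L, 7L)) {
  days <- as.integer(days)
  abortIf(is.unsorted(days, strictly = TRUE),
          "days must be strictly increasing")
  abortIf(lesionDay < min(days) || lesionDay > max(days),
          "lesionDay outside the session range")
  pairs <- expand.grid(day_a = days, day_b = days)
  pairs <- pairs[pairs$day_b > pairs$day_a, ]
  pairs$separation <- pairs$day_b - pairs$day_a
  pairs <- pairs[pairs$separation <= maxSeparation, ]

  post <- function(d) d - lesionDay # <= 0 for pre-lesion sessions
  pa <- post(pairs$day_a)
  pb <- post(pairs$day_b)
  isPre <- function(p) p <= 0
  isAcute <- function(p) p >= 1 & p <= acuteLimit
  isLate <- function(p) p >= lateWindow[1] & p <= lateWindow[2]

  pairs$group <- NA_character_
  pairs$group[isPre(pa) & isPre(pb)] <- "pre_pre"
  pairs$group[isPre(pa) & isAcute(pb)] <- "pre_post"
  pairs$group[isLate(pa) & isLate(pb)] <- "post_post"
  pairs <- pairs[!is.na(pairs$group), ]
  pairs <- pairs[order(pairs$day_a, pairs$day_b), ]
  rownames(pairs) <- NULL

  for (g in c("pre_pre", "pre_post", "post_post")) {
    if (!any(pairs$group == g)) {
      warning("no qualifying day pair in group ", g)
    }
  }
  pairs
}

#' Mood's median test for two groups of percent-match values
#'
#' Pools both groups, takes the grand median, and forms the 2x2
#' contingency table of counts above versus at-or-below the grand
#' median per group (ties with the grand median count in the
#' "at-or-below" cell). The statistic is the 1-df chi-square of that
#' table, without continuity correction unless requested. Significance
#' is declared at the Bonferroni-corrected level `alpha /
#' nComparisons`. When all pooled values are identical (a degenerate
#' table), the statistic is 0 and p = 1.
#'
#' @param x,y Numeric vectors (e.g. percent-match values of two
#'   day-pair groups); both non-empty.
#' @param alpha Family significance level (default 0.05).
#' @param nComparisons Bonferroni divisor (default 3: the three group
#'   comparisons).
#' @param continuity Apply Yates' continuity correction (default FALSE).
#' @return List with `statistic`, `p_value`, `alpha_corrected`,
#'   `significant`, and the 2x2 `table`.
#' @examples
#' medianTest(c(1, 2, 3), c(4, 5, 6)) # chi-square 6, p ~ 0.0143
#' @export
medianTest <- function(x, y, alpha = 0.05, nComparisons = 3L,
                       continuity = FALSE) {
  abortIf(!length(x) || !length(y), "both groups must be non-empty")
  m <- stats::median(c(x, y))
  tab <- rbind(
    c(sum(x > m), sum(x <= m)),
    c(sum(y > m), sum(y <= m))
  )
  dimnames(tab) <- list(group = c("x", "y"), side = c("above", "at_or_below"))

  rs <- rowSums(tab)
  cs <- colSums(tab)
  n <- sum(tab)
  if (any(cs == 0) || any(rs == 0)) {
    stat <- 0
    p <- 1
  } else {
    d <- abs(tab[1, 1] * tab[2, 2] - tab[1, 2] * tab[2, 1])
    if (continuity) d <- max(0, d - n / 2)
    stat <- n * d^2 / prod(rs, cs)
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }
  alphaC <- alpha / nComparisons
  list(
    statistic = stat, p_value = p, alpha_corrected = alphaC,
    significant = p < alphaC, table = tab
  )
}
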