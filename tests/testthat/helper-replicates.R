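# One full desk-scale experiment replicate: 13 simulated daily
# sessions on the 96-channel array (4 pre-lesion + 9 post-lesion days;
# the analysis window uses days 1-11, the last day entering any
# qualifying pair), rendered, detected and analysed with all-default
# parameters. Returns the turnoverAnalysis() result.
experimentReplicate <- function(seed, lesion = FALSE, durationS = 4) {
  geom <- utahGeometry()
  pop <- generatePopulation(geom, nDays = 13, seed = seed)
  if (lesion) {
    cfg <- defaultRunConfig()$simulate$lesion
    pop <- applyLesion(
      pop,
      lesionSpec(cfg$anode, cfg$cathode, cfg$current_ua, cfg$duration_s,
                 dayOfLesion = 4),
      volumeModel = cfg$volume_mm3, annulusUm = cfg$annulus_um,
      annulusAmpMult = cfg$annulus_amp_mult,
      annulusRateMult = cfg$annulus_rate_mult
    )
  }
  snips <- list()
  for (d in 1:11) {
    rec <- renderSession(pop, d, durationS = durationS,
                         seed = seed * 1000L + d)
    snips[[as.character(d)]] <- detectSession(rec)$snippets
  }
  suppressWarnings(
    turnoverAnalysis(snips, 1:11, lesionDay = 4, seed = seed + 17L)
  )
}

groupMeanPct <- function(ana, group) {
  mean(ana$percentMatch$pct_match[ana$percentMatch$group == group])
}
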