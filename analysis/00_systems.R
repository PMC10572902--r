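# Shared definition of the three study systems (sourced by the numbered
# analysis scripts): the VHH-like wild type and two humanized variants.
#
# wt   : the built-in 121-position template (dfbdcfb CDR1 loop at 23-29).
# hum  : CDR1 loop switched to the e/d/j/d motif in 62.5% of frames at
#        positions 24-27 (analytic delta-PB 1.25 per position).
# hum2 : as hum, plus a 25% occupancy shift f -> m at position 104 in CDR3
#        (analytic delta-PB 0.50 between the two humanized variants there).

suppressMessages(library(pbflex))

build_study_profiles <- function() {
  prof_wt <- vhh_template_profiles()
  dom <- attr(prof_wt, "dominant")

  cdr1 <- 24:27
  alt_motif <- c("e", "d", "j", "d")
  prof_hum <- prof_wt
  for (i in seq_along(cdr1)) {
    p <- cdr1[i]
    f <- setNames(rep(0, 16), PB_LETTERS)
    f[dom[p]] <- 0.375
    f[alt_motif[i]] <- f[alt_motif[i]] + 0.625
    prof_hum[p, ] <- f
  }

  prof_hum2 <- prof_hum
  f104 <- prof_hum2[104, ]
  f104["f"] <- f104["f"] - 0.25
  f104["m"] <- f104["m"] + 0.25
  prof_hum2[104, ] <- f104

  list(wt = prof_wt, hum = prof_hum, hum2 = prof_hum2,
       cdr1_window = cdr1, dominant = dom)
}

study_sequences <- function() {
  wt <- vhh_synthetic_sequence()
  list(wt = wt,
       hum = apply_mutations(wt, hl6_humanization_mutations("sequence")),
       hum2 = apply_mutations(wt, hl6_humanization_mutations("structure")))
}
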