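# Support-field extraction presets, one section per caller.
# Strategies are tried top to bottom until alt depth, total depth and VAF
# are all resolved; unresolved fields stay unknown.
#
#   af:FIELD        FORMAT field holding a fractional allele frequency
#   ad:FIELD        Number=R ref,alt depth pair; VAF = alt/(ref+alt)
#   percent:FIELD   percent-string frequency, e.g. "10%"
#   alt_dp:ALT,DP   single ALT-read count plus total depth; VAF = alt/DP
#   dp:FIELD        total depth only
#   dp4:FIELD       ref-fwd,ref-rev,alt-fwd,alt-rev strand counts
#   strelka_snv     tiered per-base counts AU/CU/GU/TU (tier 1)
#   strelka_indel   tiered indel counts TAR/TIR (tier 1)

[muse]
strategy = ad:AD
strategy = dp:DP

[mutect]
strategy = af:FA
strategy = ad:AD
strategy = dp:DP

[mutect2]
strategy = af:AF
strategy = ad:AD
strategy = dp:DP

[pindel]
strategy = ad:AD
strategy = dp:DP

[somaticsniper]
strategy = dp4:DP4
strategy = ad:AD
strategy = dp:DP

[vardict]
strategy = af:AF
strategy = ad:AD
strategy = dp:DP

[varscan]
strategy = percent:FREQ
strategy = alt_dp:AD,DP
strategy = dp:DP

[strelka]
strategy = strelka_snv
strategy = strelka_indel
strategy = dp:DP

[generic]
strategy = af:AF
strategy = ad:AD
strategy = percent:FREQ
strategy = alt_dp:AD,DP
strategy = dp:DP
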