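# Hypermutated gene families with no established cancer driver role,
# removed by convention before mutual-exclusivity analysis.
# One entry per line; entries are anchored case-insensitive regular
# expressions, so plain symbols match exactly.

# olfactory receptors (OR family-subfamily-member, e.g. OR1A1, OR51E2)
OR[0-9]+[A-Z][0-9]*[A-Z]?[0-9]*

# mucins (MUC1, MUC16, MUC5B, ...)
MUC[0-9]+[A-Z]*

# titin
TTN
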