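# The eight tissue classes of the labeling protocol. Grouping at the tissue
# scale maps structures to these classes with fixed ids 1..8 in this order.
TISSUE_CLASSES <- c("CSF", "cGM", "cWM", "sGM", "ceGM", "ceWM", "BS", "WML")

TISSUE_CLASS_IDS <- stats::setNames(seq_along(TISSUE_CLASSES), TISSUE_CLASSES)
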